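# Grantham (1974) amino-acid difference data: the residue property triples
# (composition c, polarity p, molecular volume v) and the published integer
# distance table. The published table is the canonical source used for
# classification (it is what variant annotators ship); the formula route
# from the property triples is kept alongside as an independent oracle.

grantham_properties_tab <- function() {
  tibble::tibble(
    aa = c("S", "R", "L", "P", "T", "A", "V", "G", "I", "F",
           "Y", "C", "H", "Q", "N", "K", "D", "E", "M", "W"),
    composition = c(1.42, 0.65, 0, 0.39, 0.71, 0, 0, 0.74, 0, 0,
                    0.20, 2.75, 0.58, 0.89, 1.33, 0.33, 1.38, 0.92, 0,
                    0.13),
    polarity = c(9.2, 10.5, 4.9, 8.0, 8.6, 8.1, 5.9, 9.0, 5.2, 5.2,
                 6.2, 5.5, 10.4, 10.5, 11.6, 11.3, 13.0, 12.3, 5.7, 5.4),
    volume = c(32, 124, 111, 32.5, 61, 31, 84, 3, 111, 132,
               136, 55, 96, 85, 56, 119, 54, 83, 105, 170))
}

# published integer distances, upper triangle in the order of
# grantham_properties_tab()$aa
grantham_published_upper <- function() {
  list(
    S = c(R = 110, L = 145, P = 74, T = 58, A = 99, V = 124, G = 56,
          I = 142, F = 155, Y = 144, C = 112, H = 89, Q = 68, N = 46,
          K = 121, D = 65, E = 80, M = 135, W = 177),
    R = c(L = 102, P = 103, T = 71, A = 112, V = 96, G = 125, I = 97,
          F = 97, Y = 77, C = 180, H = 29, Q = 43, N = 86, K = 26,
          D = 96, E = 54, M = 91, W = 101),
    L = c(P = 98, T = 92, A = 96, V = 32, G = 138, I = 5, F = 22,
          Y = 36, C = 198, H = 99, Q = 113, N = 153, K = 107, D = 172,
          E = 138, M = 15, W = 61),
    P = c(T = 38, A = 27, V = 68, G = 42, I = 95, F = 114, Y = 110,
          C = 169, H = 77, Q = 76, N = 91, K = 103, D = 108, E = 93,
          M = 87, W = 147),
    T = c(A = 58, V = 69, G = 59, I = 89, F = 103, Y = 92, C = 149,
          H = 47, Q = 42, N = 65, K = 78, D = 85, E = 65, M = 81,
          W = 128),
    A = c(V = 64, G = 60, I = 94, F = 113, Y = 112, C = 195, H = 86,
          Q = 91, N = 111, K = 106, D = 126, E = 107, M = 84, W = 148),
    V = c(G = 109, I = 29, F = 50, Y = 55, C = 192, H = 84, Q = 96,
          N = 133, K = 97, D = 152, E = 121, M = 21, W = 88),
    G = c(I = 135, F = 153, Y = 147, C = 159, H = 98, Q = 87, N = 80,
          K = 127, D = 94, E = 98, M = 127, W = 184),
    I = c(F = 21, Y = 33, C = 198, H = 94, Q = 109, N = 149, K = 102,
          D = 168, E = 134, M = 10, W = 61),
    F = c(Y = 22, C = 205, H = 100, Q = 116, N = 158, K = 102, D = 177,
          E = 140, M = 28, W = 40),
    Y = c(C = 194, H = 83, Q = 99, N = 143, K = 85, D = 160, E = 122,
          M = 36, W = 37),
    C = c(H = 174, Q = 154, N = 139, K = 202, D = 154, E = 170,
          M = 196, W = 215),
    H = c(Q = 24, N = 68, K = 32, D = 81, E = 40, M = 87, W = 115),
    Q = c(N = 46, K = 53, D = 61, E = 29, M = 101, W = 130),
    N = c(K = 94, D = 23, E = 42, M = 142, W = 174),
    K = c(D = 101, E = 56, M = 95, W = 110),
    D = c(E = 45, M = 160, W = 181),
    E = c(M = 126, W = 152),
    M = c(W = 67))
}

grantham_env <- new.env(parent = emptyenv())

#' Grantham distance matrix
#'
#' The published 20 x 20 integer amino-acid distance matrix (symmetric,
#' zero diagonal, off-diagonal range 5 for Leu-Ile to 215 for Cys-Trp).
#'
#' @return A named 20 x 20 integer matrix (single-letter residue codes).
#' @export
grantham_matrix <- function() {
  if (!is.null(grantham_env$matrix)) return(grantham_env$matrix)
  aa <- grantham_properties_tab()$aa
  m <- matrix(0L, 20, 20, dimnames = list(aa, aa))
  up <- grantham_published_upper()
  for (a1 in names(up)) {
    for (a2 in names(up[[a1]])) {
      m[a1, a2] <- m[a2, a1] <- as.integer(up[[a1]][[a2]])
    }
  }
  grantham_env$matrix <- m
  m
}

#' @rdname grantham_matrix
#' @details `grantham_residues()` returns the 20 single-letter codes.
#' @export
grantham_residues <- function() grantham_properties_tab()$aa

# all 190 unordered pairs with their published score
grantham_pairs <- function() {
  m <- grantham_matrix()
  aa <- rownames(m)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(aa1 = aa[idx[, 1]], aa2 = aa[idx[, 2]],
                 score = m[idx])
}

#' Grantham score of an amino-acid substitution
#'
#' @param residue1,residue2 Single-letter amino-acid codes (vectorized).
#' @return Integer score(s) from the published table; 0 for identical
#'   residues.
#' @export
#' @examples
#' grantham_score("L", "I")  # 5, the table minimum
#' grantham_score("C", "W")  # 215, the table maximum
grantham_score <- function(residue1, residue2) {
  m <- grantham_matrix()
  ok <- residue1 %in% rownames(m) & residue2 %in% rownames(m)
  if (!all(ok)) {
    stop("nonstandard residue(s): ",
         paste(unique(c(residue1, residue2)[
           !c(residue1, residue2) %in% rownames(m)]), collapse = ", "))
  }
  m[cbind(residue1, residue2)]
}

#' Grantham distances recomputed from the physicochemical formula
#'
#' Recomputes the distance matrix from the residue property triples:
#' `D_ij = rho * sqrt(alpha (c_i - c_j)^2 + beta (p_i - p_j)^2 +
#' gamma (v_i - v_j)^2)` with alpha = 1.833, beta = 0.1018,
#' gamma = 0.000399 and `rho` normalizing the mean over the 190 pairs to
#' 100. This is the independent oracle against the published table; the
#' two agree exactly at the extremes (5 and 215) and within one unit
#' almost everywhere, but the published table cannot be regenerated
#' exactly — most famously Asp-Trp, printed 181 where the formula gives
#' 191.
#'
#' @param round Round to integers (default TRUE).
#' @return A 20 x 20 numeric (or integer) matrix.
#' @export
grantham_from_properties <- function(round = TRUE) {
  pr <- grantham_properties_tab()
  alpha <- 1.833; beta <- 0.1018; gamma <- 0.000399
  d <- sqrt(alpha * outer(pr$composition, pr$composition, "-")^2 +
              beta * outer(pr$polarity, pr$polarity, "-")^2 +
              gamma * outer(pr$volume, pr$volume, "-")^2)
  rho <- 100 / mean(d[upper.tri(d)])
  d <- d * rho
  dimnames(d) <- list(pr$aa, pr$aa)
  if (round) round(d) else d
}
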