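# ---- Weir & Cockerham (1984) variance components, two populations ----

# per-site components a, b, c from diploid counts, allele frequencies and
# observed heterozygote fractions; vectorized over sites
wc_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) *
       (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  list(a = a, b = b, c = c)
}

#' Weir-Cockerham FST between two populations
#'
#' Computes the Weir & Cockerham (1984) variance components a (among
#' populations), b (among individuals within populations) and c (within
#' individuals) per biallelic site, and the genome-wide estimate as the
#' ratio of sums `sum(a) / sum(a + b + c)` — the multi-locus form the
#' estimator's authors recommend. Negative per-site components are kept in
#' the sums, never truncated. Sites are usable when both populations have
#' at least two called diploids and the pooled sample is polymorphic.
#'
#' @param gm A [geno_matrix()].
#' @param pm A [pop_map()].
#' @param pop_a,pop_b Population labels.
#' @return An object of class `fst_est`: list with `estimate`, `by_site`
#'   (tibble with per-site `a`, `b`, `c`, `usable`), and the pair labels.
#' @export
wc_fst <- function(gm, pm, pop_a, pop_b) {
  ga <- gm$calls[, population_cols(gm, pm, pop_a), drop = FALSE]
  gb <- gm$calls[, population_cols(gm, pm, pop_b), drop = FALSE]
  n1 <- rowSums(!is.na(ga)); n2 <- rowSums(!is.na(gb))
  p1 <- rowSums(ga, na.rm = TRUE) / (2 * pmax(n1, 1))
  p2 <- rowSums(gb, na.rm = TRUE) / (2 * pmax(n2, 1))
  h1 <- rowSums(ga == 1L, na.rm = TRUE) / pmax(n1, 1)
  h2 <- rowSums(gb == 1L, na.rm = TRUE) / pmax(n2, 1)
  pooled_p <- (2 * n1 * p1 + 2 * n2 * p2) / (2 * (n1 + n2))
  usable <- n1 >= 2 & n2 >= 2 & pooled_p > 0 & pooled_p < 1
  comp <- wc_components(n1, p1, h1, n2, p2, h2)
  comp$a[!usable] <- comp$b[!usable] <- comp$c[!usable] <- NA_real_
  if (!any(usable)) stop("no usable sites for FST")
  est <- sum(comp$a[usable]) /
    sum(comp$a[usable] + comp$b[usable] + comp$c[usable])
  structure(
    list(estimate = est, pop_a = pop_a, pop_b = pop_b,
         n_usable = sum(usable),
         by_site = tibble::tibble(
           scaffold = gm$sites$scaffold, pos = gm$sites$pos,
           a = comp$a, b = comp$b, c = comp$c, usable = usable)),
    class = "fst_est")
}

#' @export
print.fst_est <- function(x, ...) {
  cat(sprintf("<fst_est> FST(%s, %s) = %.4f over %d sites\n",
              x$pop_a, x$pop_b, x$estimate, x$n_usable))
  invisible(x)
}

#' Pairwise FST matrix
#'
#' @inheritParams wc_fst
#' @return A tibble of all unordered study-population pairs with their
#'   genome-wide Weir-Cockerham FST.
#' @export
fst_matrix <- function(gm, pm) {
  pops <- study_populations(pm)
  pairs <- utils::combn(pops, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    f <- wc_fst(gm, pm, pairs[1, i], pairs[2, i])
    tibble::tibble(pop_a = pairs[1, i], pop_b = pairs[2, i],
                   fst = f$estimate, n_sites = f$n_usable)
  })
}

# ---- weighted block jackknife (Busing et al. 1999) ----

# theta_hat: full estimate; theta_j: leave-one-block estimates;
# weights m_j: per-block informative mass
weighted_jackknife <- function(theta_hat, theta_j, m_j) {
  keep <- m_j > 0
  theta_j <- theta_j[keep]; m_j <- m_j[keep]
  g <- length(theta_j)
  if (g < 2) stop("block jackknife needs >= 2 non-empty blocks")
  n <- sum(m_j)
  h <- n / m_j
  theta_dot <- g * theta_hat - sum((1 - m_j / n) * theta_j)
  pseudo <- h * theta_hat - (h - 1) * theta_j
  var_j <- sum((pseudo - theta_dot)^2 / (h - 1)) / g
  se <- sqrt(var_j)
  z <- if (se > 0) theta_hat / se else sign(theta_hat) * Inf
  if (se == 0) warning("degenerate jackknife variance: SE = 0")
  tibble::tibble(point_estimate = theta_hat, standard_error = se, Z = z,
                 n_blocks = g)
}

#' ABBA-BABA D statistic with block jackknife
#'
#' Frequency-based (population) D for the topology ((A, B), (X, outgroup)).
#' Per site with known ancestral state, with derived-allele frequencies
#' pA, pB, pX (the outgroup acting as polarizer, ancestral frequency 0):
#' `ABBA += (1 - pA) pB pX` and `BABA += pA (1 - pB) pX`;
#' `D = (ABBA - BABA) / (ABBA + BABA)`. The standard error comes from a
#' weighted block jackknife over contiguous genomic blocks with the
#' per-block informative mass (ABBA + BABA) as weights; `|Z| > 3` flags a
#' significant departure from tree-ness.
#'
#' @param gm A polarized [geno_matrix()].
#' @param pm A [pop_map()].
#' @param pop_a,pop_b,pop_x Population labels for A, B, X.
#' @param layout A [genome_layout()].
#' @param block_length Jackknife block length in bp (default 5 Mb).
#' @return An object of class `dstat`: list with `D`, `abba`, `baba`,
#'   `jackknife` (tibble), `significant` (`|Z| > 3`), `blocks` (per-block
#'   masses) and the labels.
#' @export
d_statistic <- function(gm, pm, pop_a, pop_b, pop_x, layout,
                        block_length = 5e6) {
  stopifnot(block_length > 0)
  der <- derived_freqs(gm, pm, c(pop_a, pop_b, pop_x))
  ok <- stats::complete.cases(der)
  pa <- der[[pop_a]]; pb <- der[[pop_b]]; px <- der[[pop_x]]
  abba <- ifelse(ok, (1 - pa) * pb * px, 0)
  baba <- ifelse(ok, pa * (1 - pb) * px, 0)
  blk <- assign_blocks(gm$sites$scaffold, gm$sites$pos, layout,
                       block_length)
  f <- factor(blk)
  abba_b <- tapply(abba, f, sum)
  baba_b <- tapply(baba, f, sum)
  tot_abba <- sum(abba_b); tot_baba <- sum(baba_b)
  if (tot_abba + tot_baba == 0) stop("no informative sites for D")
  D <- (tot_abba - tot_baba) / (tot_abba + tot_baba)
  loo <- (tot_abba - abba_b - (tot_baba - baba_b)) /
    (tot_abba - abba_b + tot_baba - baba_b)
  m_j <- abba_b + baba_b
  jk <- weighted_jackknife(D, as.numeric(loo), as.numeric(m_j))
  structure(
    list(pop_a = pop_a, pop_b = pop_b, pop_x = pop_x,
         D = D, abba = tot_abba, baba = tot_baba,
         jackknife = jk, significant = abs(jk$Z) > 3,
         block_length = block_length,
         blocks = tibble::tibble(block = as.integer(names(abba_b)),
                                 abba = as.numeric(abba_b),
                                 baba = as.numeric(baba_b))),
    class = "dstat")
}

#' @export
print.dstat <- function(x, ...) {
  cat(sprintf("<dstat> D(%s, %s; %s) = %.4f, Z = %.2f%s\n",
              x$pop_a, x$pop_b, x$pop_x, x$D, x$jackknife$Z,
              if (x$significant) " *" else ""))
  invisible(x)
}

# per-site derived-allele frequencies for a set of populations; NA at
# sites with unknown ancestral state or no called genotypes
derived_freqs <- function(gm, pm, pops) {
  anc <- gm$sites$ancestral
  out <- tibble::as_tibble(purrr::map(stats::setNames(pops, pops),
    function(p) {
      af <- pop_freq(gm, pm, p)
      d <- ifelse(anc == "ref", af, ifelse(anc == "alt", 1 - af, NA_real_))
      d
    }))
  out
}

#' Three-population F3 test
#'
#' `F3(target; source1, source2)` is the mean over sites of
#' `(x - a)(x - b)` minus the finite-sample correction
#' `x(1 - x) / (n_x - 1)` for the target's allele-frequency sampling noise
#' (`x`, `a`, `b` are sample derived-allele frequencies; `n_x` the number
#' of called target alleles). A significantly negative F3 (Z < -3) means
#' the target cannot be a simple descendant of either source — it is
#' admixed. Reported unnormalized, with a weighted block jackknife Z.
#'
#' @param gm A polarized [geno_matrix()].
#' @param pm A [pop_map()].
#' @param target,source1,source2 Population labels.
#' @param layout A [genome_layout()].
#' @param block_length Jackknife block length in bp (default 5 Mb).
#' @return An object of class `f3_est`: list with `F3`, `jackknife`,
#'   `admixed` (`Z < -3`) and the labels. Symmetric in the two sources.
#' @export
f3 <- function(gm, pm, target, source1, source2, layout,
               block_length = 5e6) {
  if (length(population_samples(pm, target)) < 2) {
    stop("F3 bias correction needs >= 2 target samples")
  }
  der <- derived_freqs(gm, pm, c(target, source1, source2))
  g <- gm$calls[, population_cols(gm, pm, target), drop = FALSE]
  n_x <- 2 * rowSums(!is.na(g))
  x <- der[[target]]; a <- der[[source1]]; b <- der[[source2]]
  ok <- stats::complete.cases(der) & n_x >= 2
  if (!any(ok)) stop("no usable sites for F3")
  stat <- (x - a) * (x - b) - x * (1 - x) / (n_x - 1)
  stat[!ok] <- NA_real_
  blk <- assign_blocks(gm$sites$scaffold, gm$sites$pos, layout,
                       block_length)
  f <- factor(blk[ok])
  s_b <- tapply(stat[ok], f, sum)
  n_b <- tapply(rep(1, sum(ok)), f, sum)
  total_s <- sum(s_b); total_n <- sum(n_b)
  F3_hat <- total_s / total_n
  loo <- (total_s - s_b) / (total_n - n_b)
  jk <- weighted_jackknife(F3_hat, as.numeric(loo), as.numeric(n_b))
  structure(
    list(target = target, source1 = source1, source2 = source2,
         F3 = F3_hat, jackknife = jk, admixed = jk$Z < -3,
         n_sites = total_n, block_length = block_length),
    class = "f3_est")
}

#' @export
print.f3_est <- function(x, ...) {
  cat(sprintf("<f3_est> F3(%s; %s, %s) = %.5f, Z = %.2f%s\n",
              x$target, x$source1, x$source2, x$F3, x$jackknife$Z,
              if (x$admixed) " [admixed]" else ""))
  invisible(x)
}
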