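#' Per-sample heterozygosity
#'
#' He is the fraction of heterozygous genotypes per individual. The
#' denominator is either the individual's callable sites in the matrix
#' (`"callable_sites"`, the default — comparable across SNP sets) or the
#' total genome length from the layout (`"genome_length"` — a per-bp
#' heterozygosity). Reports always carry the denominator used.
#'
#' @param gm A [geno_matrix()].
#' @param denominator `"callable_sites"` or `"genome_length"`.
#' @param layout A [genome_layout()], required for `"genome_length"`.
#' @return A tibble with `sample`, `n_het`, `denominator_n`, `He` and
#'   `denominator`.
#' @export
heterozygosity <- function(gm, denominator = c("callable_sites",
                                               "genome_length"),
                           layout = NULL) {
  denominator <- match.arg(denominator)
  n_het <- colSums(gm$calls == 1L, na.rm = TRUE)
  if (denominator == "callable_sites") {
    den <- colSums(!is.na(gm$calls))
  } else {
    if (is.null(layout)) stop("genome_length denominator requires a layout")
    den <- rep(layout$total_length, length(gm$samples))
  }
  if (any(den == 0)) stop("zero denominator for sample(s): ",
                          paste(gm$samples[den == 0], collapse = ", "))
  tibble::tibble(sample = gm$samples, n_het = unname(n_het),
                 denominator_n = unname(den),
                 He = unname(n_het / den), denominator = denominator)
}

#' Windowed nucleotide diversity
#'
#' Computes pi in non-overlapping windows tiling each scaffold left to
#' right (the last, partial window is kept and normalized by its own
#' length). Per site the unbiased estimator `2 p (1 - p) n / (n - 1)` is
#' used, with `p` the sample alternate-allele frequency and `n` the number
#' of called alleles; window pi is the per-site sum divided by the window
#' length in bp. Windows with no called site report pi = 0.
#'
#' @param gm A [geno_matrix()].
#' @param pm A [pop_map()].
#' @param population Population label (needs >= 2 samples).
#' @param layout A [genome_layout()].
#' @param window Window length in bp.
#' @return A list with `windows` (tibble: `scaffold`, `start`, `end`,
#'   `n_sites`, `pi`) and `mean_pi` (the length-weighted genome-wide
#'   mean).
#' @export
nucleotide_diversity <- function(gm, pm, population, layout,
                                 window = 1e6) {
  stopifnot(window > 0)
  cols <- population_cols(gm, pm, population)
  if (length(cols) < 2) stop("population must have >= 2 samples")
  g <- gm$calls[, cols, drop = FALSE]
  called <- 2 * rowSums(!is.na(g))
  p <- ifelse(called > 0, rowSums(g, na.rm = TRUE) / called, NA_real_)
  site_pi <- ifelse(called >= 2, 2 * p * (1 - p) * called / (called - 1), 0)
  site_pi[is.na(site_pi)] <- 0

  win <- make_blocks(layout, window)
  blk <- assign_blocks(gm$sites$scaffold, gm$sites$pos, layout, window)
  sums <- tapply(site_pi, factor(blk, levels = win$block), sum,
                 default = 0)
  counts <- tapply(rep(1, length(blk)), factor(blk, levels = win$block),
                   sum, default = 0)
  windows <- tibble::tibble(
    scaffold = win$scaffold, start = win$start, end = win$end,
    n_sites = as.integer(counts),
    pi = as.numeric(sums) / (win$end - win$start + 1))
  list(windows = windows,
       mean_pi = sum(as.numeric(sums)) / layout$total_length)
}

#' Genotype PCA with Patterson normalization
#'
#' Genotypes are coded as alt-allele dosage 0/1/2, mean-centred per site
#' and scaled by `sqrt(p (1 - p))` with `p` the site allele frequency;
#' missing genotypes are mean-imputed (zero after centring) and sites
#' monomorphic among the used samples are dropped. Sample coordinates are
#' eigenvectors of the sample covariance scaled by the square root of
#' their eigenvalues, so Euclidean distances in the retained subspace
#' approximate those of the normalized data.
#'
#' @param gm A [geno_matrix()].
#' @param pm A [pop_map()] (outgroup samples are excluded).
#' @param n_components Number of components to return.
#' @return An object of class `geno_pca`: list with `scores` (tibble:
#'   `sample`, `population`, `PC1` ...), `explained` (eigenvalue
#'   fractions), `n_sites_used`.
#' @export
pca_genotypes <- function(gm, pm, n_components = 2) {
  samples <- population_samples(pm, "all")
  cols <- match(samples, gm$samples)
  if (length(cols) < 2) stop("PCA needs >= 2 samples")
  if (n_components > length(cols)) {
    stop("n_components exceeds the sample count")
  }
  g <- gm$calls[, cols, drop = FALSE]
  called <- rowSums(!is.na(g))
  p <- rowSums(g, na.rm = TRUE) / (2 * pmax(called, 1))
  poly <- called > 0 & p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic sites for PCA")
  g <- g[poly, , drop = FALSE]
  p <- p[poly]
  m <- (g - 2 * p) / sqrt(p * (1 - p))
  m[is.na(m)] <- 0
  cv <- crossprod(m) / nrow(m)
  eig <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  k <- n_components
  scores <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(k)]), k)
  colnames(scores) <- paste0("PC", seq_len(k))
  out <- list(
    scores = dplyr::bind_cols(
      tibble::tibble(sample = samples,
                     population = pm$population[match(samples, pm$sample)]),
      tibble::as_tibble(scores)),
    explained = ev / sum(ev),
    n_sites_used = nrow(m))
  class(out) <- "geno_pca"
  out
}

#' @export
print.geno_pca <- function(x, ...) {
  cat(sprintf("<geno_pca> %d samples, %d sites; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$scores), x$n_sites_used, 100 * x$explained[1],
              100 * x$explained[2]))
  invisible(x)
}

#' Per-population segregating-site counts
#'
#' A site counts as segregating in a population iff both alleles are
#' observed among its called genotypes there. Counts are also broken down
#' by consequence category; the category subtotals partition the total.
#'
#' @param gm A [geno_matrix()].
#' @param pm A [pop_map()].
#' @return A tibble with `population`, `consequence`, `n_segregating`,
#'   plus a `total` row per population (consequence `"all"`).
#' @export
snp_counts <- function(gm, pm) {
  pops <- study_populations(pm)
  purrr::map_dfr(pops, function(p) {
    g <- gm$calls[, population_cols(gm, pm, p), drop = FALSE]
    called <- rowSums(!is.na(g))
    alt <- rowSums(g, na.rm = TRUE)
    seg <- called > 0 & alt > 0 & alt < 2 * called
    per_cat <- dplyr::count(
      tibble::tibble(consequence = gm$sites$consequence[seg]),
      .data$consequence, name = "n_segregating")
    dplyr::bind_rows(
      tibble::tibble(population = p, consequence = "all",
                     n_segregating = sum(seg)),
      dplyr::mutate(per_cat, population = p, .before = 1))
  })
}
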