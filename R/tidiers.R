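#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an FST estimate
#'
#' @param x An `fst_est` from [wc_fst()].
#' @param ... Unused.
#' @return One row per site with the Weir-Cockerham components.
#' @method tidy fst_est
#' @export
tidy.fst_est <- function(x, ...) x$by_site

#' @rdname tidy.fst_est
#' @method glance fst_est
#' @export
glance.fst_est <- function(x, ...) {
  tibble::tibble(pop_a = x$pop_a, pop_b = x$pop_b, fst = x$estimate,
                 n_sites = x$n_usable)
}

#' Tidy a D-statistic result
#'
#' @param x A `dstat` from [d_statistic()].
#' @param ... Unused.
#' @return Per-block ABBA/BABA masses.
#' @method tidy dstat
#' @export
tidy.dstat <- function(x, ...) x$blocks

#' @rdname tidy.dstat
#' @method glance dstat
#' @export
glance.dstat <- function(x, ...) {
  tibble::tibble(A = x$pop_a, B = x$pop_b, X = x$pop_x, D = x$D,
                 abba = x$abba, baba = x$baba,
                 se = x$jackknife$standard_error, Z = x$jackknife$Z,
                 n_blocks = x$jackknife$n_blocks,
                 significant = x$significant)
}

#' Tidy an F3 estimate
#'
#' @param x An `f3_est` from [f3()].
#' @param ... Unused.
#' @return A one-row tibble with the estimate, Z and admixture flag.
#' @method tidy f3_est
#' @export
tidy.f3_est <- function(x, ...) glance.f3_est(x)

#' @rdname tidy.f3_est
#' @method glance f3_est
#' @export
glance.f3_est <- function(x, ...) {
  tibble::tibble(target = x$target, source1 = x$source1,
                 source2 = x$source2, F3 = x$F3,
                 se = x$jackknife$standard_error, Z = x$jackknife$Z,
                 n_sites = x$n_sites, admixed = x$admixed)
}

#' Tidy an iHS scan
#'
#' @param x An `ihs_scan` from [ihs()].
#' @param ... Unused.
#' @return The per-site score tibble.
#' @method tidy ihs_scan
#' @export
tidy.ihs_scan <- function(x, ...) x$sites

#' @rdname tidy.ihs_scan
#' @method glance ihs_scan
#' @export
glance.ihs_scan <- function(x, ...) {
  v <- x$sites[x$sites$valid, ]
  tibble::tibble(population = x$population, n_scored = nrow(v),
                 n_cores = nrow(x$sites),
                 mean_std = mean(v$std_ihs), sd_std = stats::sd(v$std_ihs))
}

#' Tidy a genotype PCA
#'
#' @param x A `geno_pca` from [pca_genotypes()].
#' @param ... Unused.
#' @return The sample score tibble.
#' @method tidy geno_pca
#' @export
tidy.geno_pca <- function(x, ...) x$scores

#' @rdname tidy.geno_pca
#' @method glance geno_pca
#' @export
glance.geno_pca <- function(x, ...) {
  tibble::tibble(component = seq_along(x$explained),
                 explained = x$explained)
}
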