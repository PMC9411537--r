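#' Polarize alleles against the outgroup
#'
#' Infers the ancestral state of every site from the outgroup genotypes: if
#' all non-missing outgroup calls are homozygous reference the ancestral
#' allele is `ref`; if all are homozygous alternate it is `alt`; any
#' heterozygous, discordant or entirely missing outgroup leaves the site
#' `unknown`. Sites with unknown state are retained but excluded by every
#' downstream derived-allele computation (D statistic, mutational load,
#' iHS). Polarizing an already polarized matrix gives the same answer: the
#' operation only rewrites the `ancestral` column from the outgroup calls.
#'
#' @param gm A [geno_matrix()].
#' @param pm A [pop_map()] with at least one `OUTGROUP` sample.
#' @return `gm` with the `ancestral` site column filled in.
#' @export
polarize_by_outgroup <- function(gm, pm) {
  og <- outgroup_samples(pm)
  if (length(og) == 0) stop("population map has no OUTGROUP samples")
  cols <- match(og, gm$samples)
  if (anyNA(cols)) stop("outgroup samples absent from the matrix")
  g <- gm$calls[, cols, drop = FALSE]
  all_ref <- rowSums(g != 0L, na.rm = TRUE) == 0 & rowSums(!is.na(g)) > 0
  all_alt <- rowSums(g != 2L, na.rm = TRUE) == 0 & rowSums(!is.na(g)) > 0
  gm$sites$ancestral <- dplyr::case_when(all_ref ~ "ref",
                                         all_alt ~ "alt",
                                         TRUE ~ "unknown")
  gm
}

#' Per-site alternate-allele frequencies
#'
#' @param gm A [geno_matrix()].
#' @param pm A [pop_map()].
#' @param population A population label, or `"all"` for the pooled study
#'   panel (outgroup always excluded).
#' @return A tibble with one row per site: `scaffold`, `pos`, `alt_freq`
#'   (alt allele count over called alleles; `NA` where no genotype was
#'   called) and `called_n` (number of called alleles, i.e. 2 x called
#'   genotypes).
#' @export
allele_frequencies <- function(gm, pm, population = "all") {
  cols <- population_cols(gm, pm, population)
  g <- gm$calls[, cols, drop = FALSE]
  called <- rowSums(!is.na(g))
  alt <- rowSums(g, na.rm = TRUE)
  tibble::tibble(
    scaffold = gm$sites$scaffold,
    pos = gm$sites$pos,
    alt_freq = ifelse(called > 0, alt / (2 * called), NA_real_),
    called_n = 2L * called
  )
}

# per-site frequency vector for a single population (internal fast path)
pop_freq <- function(gm, pm, population) {
  cols <- population_cols(gm, pm, population)
  g <- gm$calls[, cols, drop = FALSE]
  called <- rowSums(!is.na(g))
  ifelse(called > 0, rowSums(g, na.rm = TRUE) / (2 * called), NA_real_)
}

#' Filter sites by scaffold length and allele frequency
#'
#' Reproduces the post-calling site filters of resequencing studies of
#' non-model genomes: SNPs on scaffolds shorter than `min_scaffold_kb`
#' (default 100 kb) are removed, and when `af_threshold > 0`, SNPs whose
#' minor allele frequency in the pooled study panel is not strictly larger
#' than the threshold are removed. Calling with `af_threshold` 0, 0.05 and
#' 0.20 yields the three nested SNP sets typically analyzed (all SNPs,
#' MAF > 5%, MAF > 20%).
#'
#' @inheritParams allele_frequencies
#' @param layout A [genome_layout()] providing a length for every scaffold
#'   present in the matrix.
#' @param af_threshold Minor-allele-frequency threshold (strict `>` to
#'   keep); 0 disables the frequency filter.
#' @param min_scaffold_kb Minimum scaffold length in kb (default 100).
#' @return A filtered [geno_matrix()] (a subset of the input sites).
#' @export
filter_sites <- function(gm, pm, layout, af_threshold = 0,
                         min_scaffold_kb = 100) {
  len <- scaffold_length(layout, gm$sites$scaffold)
  keep <- len >= min_scaffold_kb * 1000
  if (af_threshold > 0) {
    p <- pop_freq(gm, pm, "all")
    maf <- pmin(p, 1 - p)
    keep <- keep & !is.na(maf) & maf > af_threshold
  }
  subset_sites(gm, which(keep))
}

#' Minor-allele-frequency spectrum
#'
#' Tabulates polymorphic sites (MAF > 0 in the pooled study panel) into MAF
#' bins. Each site falls in exactly one bin; bins are left-open,
#' right-closed intervals of (0, 0.5].
#'
#' @inheritParams allele_frequencies
#' @param bin_edges Increasing break points starting at 0 and ending at
#'   0.5.
#' @return A tibble with `bin` (label), `lower`, `upper`, `n_snps` and
#'   `proportion` (proportions sum to 1 over polymorphic sites).
#' @export
maf_spectrum <- function(gm, pm,
                         bin_edges = c(0, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5)) {
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop("bin_edges must be strictly increasing")
  }
  if (bin_edges[1] != 0 || bin_edges[length(bin_edges)] != 0.5) {
    stop("bins must cover (0, 0.5]")
  }
  p <- pop_freq(gm, pm, "all")
  maf <- pmin(p, 1 - p)
  maf <- maf[!is.na(maf) & maf > 0]  # monomorphic sites carry no spectrum
  bin <- cut(maf, breaks = bin_edges, include.lowest = FALSE)
  counts <- tabulate(bin, nbins = length(bin_edges) - 1)
  tibble::tibble(
    bin = levels(bin),
    lower = bin_edges[-length(bin_edges)],
    upper = bin_edges[-1],
    n_snps = counts,
    proportion = if (sum(counts) > 0) counts / sum(counts) else 0
  )
}
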