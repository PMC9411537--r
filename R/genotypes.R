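#' Genotype matrix
#'
#' The substrate of every statistic in the package: biallelic SNP sites by
#' diploid samples. Genotype calls are stored as alt-allele dosages (0 =
#' hom ref, 1 = het, 2 = hom alt, `NA` = missing); optionally, phased
#' haplotypes are carried as a sites x (2 * samples) matrix of 0/1 alleles.
#'
#' @param sites A data frame of per-site metadata; required columns
#'   `scaffold`, `pos`, `ref`, `alt`. Optional columns `ancestral` (one of
#'   `"ref"`, `"alt"`, `"unknown"`), `consequence` (one of `"synonymous"`,
#'   `"missense"`, `"lof_splice_donor"`, `"lof_splice_acceptor"`,
#'   `"lof_stop_gained"`, `"other"`, `"none"`), `aa_ref`, `aa_alt`
#'   (single-letter amino acids for coding annotations) and `gene_id`;
#'   missing optional columns are filled with defaults.
#' @param calls Integer matrix, sites x samples, values 0/1/2/`NA`.
#' @param samples Character vector of sample names (defaults to the column
#'   names of `calls`).
#' @param haplotypes Optional integer matrix, sites x (2 * samples), of 0/1
#'   alleles; columns are ordered sample1-hapA, sample1-hapB, sample2-hapA,
#'   ... Collapsing each haplotype pair must reproduce `calls` at every
#'   non-missing genotype.
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(sites, calls, samples = colnames(calls),
                        haplotypes = NULL) {
  sites <- tibble::as_tibble(sites)
  stopifnot(all(c("scaffold", "pos", "ref", "alt") %in% names(sites)))
  if (!"ancestral" %in% names(sites)) sites$ancestral <- "unknown"
  if (!"consequence" %in% names(sites)) sites$consequence <- "none"
  if (!"aa_ref" %in% names(sites)) sites$aa_ref <- NA_character_
  if (!"aa_alt" %in% names(sites)) sites$aa_alt <- NA_character_
  if (!"gene_id" %in% names(sites)) sites$gene_id <- NA_character_
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != nrow(sites)) {
    stop("calls must have one row per site")
  }
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(calls)))
  if (ncol(calls) != length(samples)) {
    stop("calls must have one column per sample")
  }
  if (any(sites$ref == sites$alt)) stop("ref and alt alleles must differ")
  if (any(sites$pos < 1)) stop("positions are 1-based and must be >= 1")
  ok <- is.na(calls) | (calls >= 0L & calls <= 2L)
  if (!all(ok)) stop("calls must be 0, 1, 2 or NA")
  if (!is.null(haplotypes)) {
    haplotypes <- as.matrix(haplotypes)
    storage.mode(haplotypes) <- "integer"
    if (nrow(haplotypes) != nrow(sites) ||
        ncol(haplotypes) != 2L * length(samples)) {
      stop("haplotypes must be sites x (2 * samples)")
    }
    collapsed <- haplotypes[, seq(1, ncol(haplotypes), 2), drop = FALSE] +
      haplotypes[, seq(2, ncol(haplotypes), 2), drop = FALSE]
    bad <- !is.na(calls) & !is.na(collapsed) & collapsed != calls
    if (any(bad)) stop("haplotype pairs do not collapse to the calls")
  }
  # canonical site order: scaffold, then position
  ord <- order(sites$scaffold, sites$pos, method = "radix")
  if (is.unsorted(ord)) {
    sites <- sites[ord, ]
    calls <- calls[ord, , drop = FALSE]
    if (!is.null(haplotypes)) haplotypes <- haplotypes[ord, , drop = FALSE]
  }
  colnames(calls) <- samples
  structure(
    list(sites = sites, calls = calls, samples = samples,
         haplotypes = haplotypes),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d sites x %d samples%s\n",
              nrow(x$sites), length(x$samples),
              if (is.null(x$haplotypes)) "" else " (phased)"))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) c(nrow(x$sites), length(x$samples))

n_sites <- function(gm) nrow(gm$sites)

is_phased <- function(gm) !is.null(gm$haplotypes)

# subset a geno_matrix by site index, keeping metadata and phase in step
subset_sites <- function(gm, idx) {
  geno_matrix(gm$sites[idx, , drop = FALSE],
              gm$calls[idx, , drop = FALSE],
              gm$samples,
              if (is_phased(gm)) gm$haplotypes[idx, , drop = FALSE])
}

#' Population map
#'
#' Assigns every sample of a genotype matrix to a study population or to the
#' outgroup. The outgroup (for example the Malayan pangolin relative to the
#' three Chinese pangolin populations) is flagged by the reserved population
#' label `"OUTGROUP"` and is used only for ancestral-allele polarization.
#'
#' @param assignments A data frame with columns `sample` and `population`,
#'   or a named character vector mapping sample name to population label.
#' @return An object of class `pop_map`: a tibble with columns `sample` and
#'   `population`.
#' @export
#' @examples
#' pop_map(c(a1 = "CPA", b1 = "CPB", og = "OUTGROUP"))
pop_map <- function(assignments) {
  if (is.character(assignments) && !is.null(names(assignments))) {
    assignments <- tibble::tibble(sample = names(assignments),
                                  population = unname(assignments))
  }
  pm <- tibble::as_tibble(assignments)[, c("sample", "population")]
  if (anyDuplicated(pm$sample)) stop("duplicate sample in population map")
  structure(pm, class = c("pop_map", class(pm)))
}

#' Read a population map from TSV
#'
#' Expects a header with columns `sample_id` and `population`; outgroup
#' samples carry the reserved label `OUTGROUP`.
#'
#' @param path Path to the TSV file.
#' @return A [pop_map()].
#' @export
read_pop_map <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), population = readr::col_character()))
  pop_map(tibble::tibble(sample = tab$sample_id, population = tab$population))
}

#' @export
#' @rdname pop_map
#' @param pm A `pop_map`.
study_populations <- function(pm) {
  setdiff(unique(pm$population), "OUTGROUP")
}

#' @export
#' @rdname pop_map
outgroup_samples <- function(pm) pm$sample[pm$population == "OUTGROUP"]

#' @export
#' @rdname pop_map
#' @param population A population label, or `"all"` for every
#'   non-outgroup sample.
population_samples <- function(pm, population) {
  if (identical(population, "all")) {
    return(pm$sample[pm$population != "OUTGROUP"])
  }
  s <- pm$sample[pm$population == population]
  if (length(s) == 0) stop("unknown or empty population: ", population)
  s
}

# column indices of a population's samples within a geno_matrix
population_cols <- function(gm, pm, population) {
  s <- population_samples(pm, population)
  i <- match(s, gm$samples)
  if (anyNA(i)) stop("population map names samples absent from the matrix")
  i
}

# haplotype column indices for a set of sample column indices
hap_cols <- function(sample_cols) {
  as.vector(rbind(2L * sample_cols - 1L, 2L * sample_cols))
}
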