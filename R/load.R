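#' Classify variants by functional severity
#'
#' Loss-of-function (LoF) comprises splice donor, splice acceptor and stop
#' gained. Missense variants with Grantham score >= 150 (boundary
#' inclusive) are deleterious missense; below, tolerated missense.
#'
#' @param sites A site tibble (as in a [geno_matrix()]) with columns
#'   `consequence`, `aa_ref`, `aa_alt`.
#' @return Character vector: one of `"lof"`, `"deleterious_missense"`,
#'   `"tolerated_missense"`, `"synonymous"`, `"other"`.
#' @export
classify_variants <- function(sites) {
  lof_classes <- c("lof_splice_donor", "lof_splice_acceptor",
                   "lof_stop_gained")
  is_mis <- sites$consequence == "missense"
  if (any(is_mis & (is.na(sites$aa_ref) | is.na(sites$aa_alt)))) {
    stop("missense site without an amino-acid change annotation")
  }
  gs <- rep(NA_integer_, nrow(sites))
  if (any(is_mis)) {
    gs[is_mis] <- grantham_score(sites$aa_ref[is_mis],
                                 sites$aa_alt[is_mis])
  }
  dplyr::case_when(
    sites$consequence %in% lof_classes ~ "lof",
    is_mis & gs >= 150 ~ "deleterious_missense",
    is_mis ~ "tolerated_missense",
    sites$consequence == "synonymous" ~ "synonymous",
    TRUE ~ "other")
}

# per-sample derived-allele dosage matrix; NA at unknown-ancestral sites
derived_dosage <- function(gm) {
  anc <- gm$sites$ancestral
  d <- gm$calls
  flip <- anc == "alt"
  d[flip, ] <- 2L - d[flip, ]
  d[anc == "unknown", ] <- NA_integer_
  d
}

#' Derived mutational-load accounting
#'
#' Counts, per individual, the sites where the individual carries at least
#' one derived allele, split by severity category (LoF, deleterious
#' missense, tolerated missense, synonymous) and zygosity (homozygous
#' derived vs heterozygous). Sites with unknown ancestral state are
#' excluded everywhere. Population-level ratios are computed from pooled
#' counts: `deleterious / nsSNP` and `LoF / nsSNP`, with nsSNP the total
#' missense (deleterious + tolerated) site count.
#'
#' @param gm A polarized, consequence-annotated [geno_matrix()].
#' @param pm A [pop_map()].
#' @return An object of class `load_summary`: list with `per_sample`
#'   (tibble: `sample`, `population`, `category`, `n_sites`, `n_hom`,
#'   `n_het`) and `per_population` (means, SDs and pooled ratios).
#' @export
derived_load_counts <- function(gm, pm) {
  if (all(gm$sites$ancestral == "unknown")) {
    stop("matrix is not polarized: run polarize_by_outgroup() first")
  }
  cat <- classify_variants(gm$sites)
  d <- derived_dosage(gm)
  samples <- population_samples(pm, "all")
  cols <- match(samples, gm$samples)
  cats <- c("lof", "deleterious_missense", "tolerated_missense",
            "synonymous")
  per_sample <- purrr::map_dfr(cats, function(cc) {
    rows <- which(cat == cc)
    dd <- d[rows, cols, drop = FALSE]
    tibble::tibble(
      sample = samples,
      population = pm$population[match(samples, pm$sample)],
      category = cc,
      n_sites = unname(colSums(dd >= 1L, na.rm = TRUE)),
      n_hom = unname(colSums(dd == 2L, na.rm = TRUE)),
      n_het = unname(colSums(dd == 1L, na.rm = TRUE)))
  })
  per_population <- per_sample |>
    dplyr::group_by(.data$population, .data$category) |>
    dplyr::summarise(mean_sites = mean(.data$n_sites),
                     sd_sites = stats::sd(.data$n_sites),
                     pooled_sites = sum(.data$n_sites),
                     pooled_hom = sum(.data$n_hom),
                     pooled_het = sum(.data$n_het),
                     .groups = "drop")
  ns_tot <- per_population |>
    dplyr::filter(.data$category %in% c("deleterious_missense",
                                        "tolerated_missense")) |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(nssnp = sum(.data$pooled_sites))
  per_population <- per_population |>
    dplyr::left_join(ns_tot, by = "population") |>
    dplyr::mutate(ratio_to_nssnp = ifelse(.data$nssnp > 0,
                                          .data$pooled_sites / .data$nssnp,
                                          NA_real_))
  structure(list(per_sample = per_sample,
                 per_population = per_population),
            class = "load_summary")
}

#' @export
print.load_summary <- function(x, ...) {
  cat("<load_summary>\n")
  print(x$per_population, n = 20)
  invisible(x)
}

#' Zygosity ratio of a load category
#'
#' The ratio of homozygous-derived sites to homozygous plus heterozygous
#' sites, pooled over a population's members (sites are counted once per
#' carrier). Values near 1 mean the category's derived alleles are mostly
#' exposed in homozygous state. A zero denominator yields `NA` with a
#' warning, never 0.
#'
#' @param summary A `load_summary` from [derived_load_counts()].
#' @param category One of `"lof"`, `"missense"` (deleterious + tolerated)
#'   or `"deleterious_missense"`.
#' @param population A population label, or `"all"` to pool study
#'   populations.
#' @param per_individual If TRUE, also return the per-individual ratios.
#' @return A tibble with `population`, `category`, `n_hom`, `n_het`,
#'   `ratio`; with `per_individual`, a list adding the per-sample tibble.
#' @export
zygosity_ratio <- function(summary, category = c("lof", "missense",
                                                 "deleterious_missense"),
                           population = "all", per_individual = FALSE) {
  category <- match.arg(category)
  cats <- switch(category,
                 missense = c("deleterious_missense", "tolerated_missense"),
                 category)
  ps <- summary$per_sample |>
    dplyr::filter(.data$category %in% cats)
  if (!identical(population, "all")) {
    ps <- dplyr::filter(ps, .data$population == !!population)
  }
  hom <- sum(ps$n_hom); het <- sum(ps$n_het)
  ratio <- if (hom + het == 0) {
    warning("no sites in category '", category, "': ratio undefined")
    NA_real_
  } else hom / (hom + het)
  out <- tibble::tibble(population = population, category = category,
                        n_hom = hom, n_het = het, ratio = ratio)
  if (per_individual) {
    byind <- ps |>
      dplyr::group_by(.data$sample, .data$population) |>
      dplyr::summarise(n_hom = sum(.data$n_hom), n_het = sum(.data$n_het),
                       .groups = "drop") |>
      dplyr::mutate(ratio = ifelse(.data$n_hom + .data$n_het > 0,
                                   .data$n_hom /
                                     (.data$n_hom + .data$n_het),
                                   NA_real_))
    return(list(pooled = out, per_individual = byind))
  }
  out
}

#' Predict LoF variants introduced by translocation
#'
#' For a candidate genetic-rescue move of individuals from a donor
#' population into a receiver population: for each donor individual,
#' counts the LoF sites at which that individual carries at least one
#' derived allele while the derived allele is absent from every called
#' genotype of the receiver population — the LoF variants the move would
#' newly introduce. Missing receiver genotypes do not veto novelty (the
#' count is an upper-bound style prediction; this is recorded in the
#' output). Direction matters: donor -> receiver differs from the
#' reverse.
#'
#' @param gm A polarized, annotated [geno_matrix()].
#' @param pm A [pop_map()].
#' @param donor,receiver Distinct population labels.
#' @return An object of class `translocation_prediction`: list with
#'   `per_donor` (tibble: `sample`, `introduced_lof`), `min`, `max`,
#'   `mean`, the labels and the novelty rule note.
#' @export
predict_translocation_lof <- function(gm, pm, donor, receiver) {
  if (identical(donor, receiver)) stop("donor and receiver must differ")
  cat <- classify_variants(gm$sites)
  d <- derived_dosage(gm)
  lof_rows <- which(cat == "lof")
  d_cols <- population_cols(gm, pm, donor)
  r_cols <- population_cols(gm, pm, receiver)
  dr <- d[lof_rows, r_cols, drop = FALSE]
  novel <- rowSums(dr >= 1L, na.rm = TRUE) == 0 &
    rowSums(!is.na(dr)) > 0  # receiver must be observed at the site
  dd <- d[lof_rows, d_cols, drop = FALSE][novel, , drop = FALSE]
  counts <- colSums(dd >= 1L, na.rm = TRUE)
  donors <- gm$samples[d_cols]
  structure(
    list(donor = donor, receiver = receiver,
         per_donor = tibble::tibble(sample = donors,
                                    introduced_lof = unname(counts)),
         min = min(counts), max = max(counts), mean = mean(counts),
         rule = paste("novel = derived allele absent among called",
                      "receiver genotypes; missing receiver genotypes",
                      "do not veto novelty")),
    class = "translocation_prediction")
}

#' @export
print.translocation_prediction <- function(x, ...) {
  cat(sprintf(
    "<translocation_prediction> %s -> %s: %d-%d introduced LoF (mean %.1f)\n",
    x$donor, x$receiver, x$min, x$max, x$mean))
  invisible(x)
}

#' Directional translocation matrix over all population pairs
#'
#' @inheritParams predict_translocation_lof
#' @return A tibble with `donor`, `receiver`, `min`, `max`, `mean`
#'   introduced-LoF counts for every ordered pair of study populations.
#' @export
translocation_matrix <- function(gm, pm) {
  pops <- study_populations(pm)
  grid <- tidyr::expand_grid(donor = pops, receiver = pops) |>
    dplyr::filter(.data$donor != .data$receiver)
  purrr::pmap_dfr(grid, function(donor, receiver) {
    p <- predict_translocation_lof(gm, pm, donor, receiver)
    tibble::tibble(donor = donor, receiver = receiver,
                   min = p$min, max = p$max, mean = p$mean)
  })
}

#' Genes affected by derived LoF alleles
#'
#' @param gm A polarized, annotated [geno_matrix()].
#' @param pm A [pop_map()].
#' @param population Population label or `"all"`.
#' @return Character vector of gene ids carrying at least one derived LoF
#'   allele in the population (for external enrichment analysis).
#' @export
lof_affected_genes <- function(gm, pm, population = "all") {
  cat <- classify_variants(gm$sites)
  d <- derived_dosage(gm)
  cols <- population_cols(gm, pm, population)
  rows <- which(cat == "lof" &
                  rowSums(d[, cols, drop = FALSE] >= 1L, na.rm = TRUE) > 0)
  sort(unique(gm$sites$gene_id[rows][!is.na(gm$sites$gene_id[rows])]))
}
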