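#' Detect runs of homozygosity in one sample
#'
#' A PLINK-style sliding-window scan. A window of `window_snps` consecutive
#' SNPs is homozygous when it contains at most `het_allowance`
#' heterozygotes and at most `missing_allowance` missing calls. Each SNP is
#' scored by the fraction of windows covering it that are homozygous; SNPs
#' with a fraction of at least `hit_threshold` are "in ROH". Maximal runs
#' of in-ROH SNPs — split where adjacent SNPs are more than `max_gap_kb`
#' apart — with at least `min_snps` SNPs and spanning at least
#' `min_length_kb` become segments. Segments are classed `medium`
#' (100 kb - 1 Mb) or `long` (> 1 Mb); runs shorter than 100 kb are never
#' emitted, reflecting the convention that only ROHs above 100 kb are
#' interpretable as autozygosity in low-density resequencing panels.
#'
#' @param gm A [geno_matrix()].
#' @param sample Sample name.
#' @param window_snps Window size in SNPs (default 50).
#' @param het_allowance Maximum heterozygotes per homozygous window
#'   (default 1).
#' @param missing_allowance Maximum missing calls per window (default 5).
#' @param min_length_kb Minimum segment length in kb (default 100; values
#'   below 100 are raised to 100).
#' @param min_snps Minimum SNPs per segment (default 50).
#' @param max_gap_kb Maximum gap between consecutive segment SNPs in kb
#'   (default 100).
#' @param hit_threshold Minimum fraction of homozygous covering windows
#'   for a SNP to count as in-ROH (default 0.05).
#' @return A tibble of segments: `sample`, `scaffold`, `start`, `end`,
#'   `length` (bp, 1-based inclusive), `n_snps`, `size_class`.
#' @export
detect_roh <- function(gm, sample, window_snps = 50, het_allowance = 1,
                       missing_allowance = 5, min_length_kb = 100,
                       min_snps = 50, max_gap_kb = 100,
                       hit_threshold = 0.05) {
  stopifnot(window_snps >= 1, min_snps >= 1, max_gap_kb > 0)
  min_length_kb <- max(min_length_kb, 100)
  col <- match(sample, gm$samples)
  if (is.na(col)) stop("unknown sample: ", sample)
  gt <- gm$calls[, col]
  scaffolds <- split(seq_along(gt), gm$sites$scaffold)
  if (all(vapply(scaffolds, length, 1L) < window_snps)) {
    stop("window_snps exceeds the SNP count on every scaffold")
  }
  segs <- purrr::imap_dfr(scaffolds, function(idx, scname) {
    g <- gt[idx]
    pos <- gm$sites$pos[idx]
    ns <- length(g)
    if (ns < window_snps) return(NULL)
    het <- as.numeric(!is.na(g) & g == 1L)
    mis <- as.numeric(is.na(g))
    run <- function(x) {
      cs <- c(0, cumsum(x))
      cs[(window_snps + 1):(ns + 1)] - cs[1:(ns - window_snps + 1)]
    }
    win_ok <- run(het) <= het_allowance & run(mis) <= missing_allowance
    nwin <- length(win_ok)
    # SNP i is covered by windows max(1, i - w + 1) .. min(nwin, i)
    cs <- c(0, cumsum(as.numeric(win_ok)))
    i <- seq_len(ns)
    lo <- pmax(1L, i - window_snps + 1L)
    hi <- pmin(nwin, i)
    cover <- pmax(hi - lo + 1L, 0L)
    hits <- ifelse(cover > 0, cs[hi + 1L] - cs[lo], 0)
    in_roh <- cover > 0 & hits / pmax(cover, 1L) >= hit_threshold
    if (!any(in_roh)) return(NULL)
    # maximal runs, split at gaps > max_gap_kb
    gap_break <- c(FALSE, diff(pos) > max_gap_kb * 1000)
    grp <- cumsum(!in_roh | gap_break)
    runs <- which(in_roh)
    if (length(runs) == 0) return(NULL)
    spl <- split(runs, grp[runs])
    purrr::map_dfr(spl, function(r) {
      tibble::tibble(start = pos[r[1]], end = pos[r[length(r)]],
                     n_snps = length(r))
    }) |>
      dplyr::mutate(scaffold = scname)
  })
  if (nrow(segs) == 0) {
    return(tibble::tibble(sample = character(), scaffold = character(),
                          start = numeric(), end = numeric(),
                          length = numeric(), n_snps = integer(),
                          size_class = character()))
  }
  segs |>
    dplyr::mutate(length = .data$end - .data$start + 1,
                  sample = sample) |>
    dplyr::filter(.data$n_snps >= min_snps,
                  .data$length >= min_length_kb * 1000) |>
    dplyr::mutate(size_class = dplyr::if_else(.data$length > 1e6,
                                              "long", "medium")) |>
    dplyr::select("sample", "scaffold", "start", "end", "length",
                  "n_snps", "size_class")
}

#' Detect ROH for every non-outgroup sample
#'
#' @inheritParams detect_roh
#' @param pm A [pop_map()].
#' @param ... Passed to [detect_roh()].
#' @return Row-bound segment tibble over all study samples.
#' @export
detect_roh_all <- function(gm, pm, ...) {
  purrr::map_dfr(population_samples(pm, "all"),
                 function(s) detect_roh(gm, s, ...))
}

#' F_ROH: genome fraction in runs of homozygosity
#'
#' Per sample and size class, F_ROH is the summed segment length divided
#' by the total genome (layout) length. Population summaries are means and
#' SDs over member samples.
#'
#' @param segments A segment tibble from [detect_roh()]/[detect_roh_all()].
#' @param layout A [genome_layout()].
#' @param pm Optional [pop_map()] for population summaries.
#' @return A list with `per_sample` (tibble: `sample`, `size_class`,
#'   `total_length`, `froh`) and, when `pm` is given, `per_population`
#'   (mean and SD of F_ROH per class).
#' @export
froh <- function(segments, layout, pm = NULL) {
  stopifnot(layout$total_length > 0)
  if (nrow(segments) > 0) {
    too_long <- segments$end > scaffold_length(layout, segments$scaffold)
    if (any(too_long)) stop("segment extends beyond its scaffold end")
  }
  grid <- tidyr::expand_grid(
    sample = unique(segments$sample),
    size_class = c("medium", "long"))
  per_sample <- segments |>
    dplyr::group_by(.data$sample, .data$size_class) |>
    dplyr::summarise(total_length = sum(.data$length), .groups = "drop") |>
    dplyr::right_join(grid, by = c("sample", "size_class")) |>
    dplyr::mutate(total_length = dplyr::coalesce(.data$total_length, 0),
                  froh = .data$total_length / layout$total_length) |>
    dplyr::arrange(.data$sample, .data$size_class)
  out <- list(per_sample = per_sample)
  if (!is.null(pm)) {
    out$per_population <- per_sample |>
      dplyr::mutate(population =
                      pm$population[match(.data$sample, pm$sample)]) |>
      dplyr::group_by(.data$population, .data$size_class) |>
      dplyr::summarise(mean_froh = mean(.data$froh),
                       sd_froh = stats::sd(.data$froh),
                       total_mb = sum(.data$total_length) / 1e6,
                       .groups = "drop")
  }
  out
}

#' Expected age of inbreeding from ROH length
#'
#' The expected number of generations back to the common ancestor of the
#' two haplotypes forming an autozygous tract of genetic length L cM is
#' `g = 100 / (2 L)`. Physical length converts to genetic length with the
#' layout's flat map (default 1 cM/Mb), so a 1 Mb ROH dates to 50
#' generations; with a 1-year generation time, every ROH longer than 1 Mb
#' reflects inbreeding within the last 50 years.
#'
#' @param length_bp ROH length(s) in bp.
#' @param layout A [genome_layout()] (supplies `map_rate`).
#' @param generation_time Years per generation (default 1).
#' @return A tibble with `length_bp`, `length_cm`, `generations`, `years`.
#' @export
#' @examples
#' generations_from_roh(1e6, genome_layout(c(s = 1e7)))
generations_from_roh <- function(length_bp, layout, generation_time = 1) {
  if (any(length_bp <= 0)) stop("ROH length must be positive")
  l_cm <- length_bp * layout$map_rate / 1e6
  gens <- 100 / (2 * l_cm)
  tibble::tibble(length_bp = length_bp, length_cm = l_cm,
                 generations = gens, years = gens * generation_time)
}
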