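# ---- extended haplotype homozygosity ----

# one-directional EHH walk from a core marker. H: scaffold haplotype
# matrix (sites x haplotypes), pos: bp positions, carriers: haplotype
# column indices sharing the core allele. Returns the cM-weighted
# integral (iHH contribution) and, optionally, the curve. Integration
# adds the trapezoid into the first marker whose EHH drops below the
# truncation floor, then stops; a gap larger than max_gap_bp between
# consecutive markers ends the curve (unassembled-region guard).
ehh_walk <- function(H, pos, core_idx, carriers, direction, truncation,
                     max_gap_bp, cm_per_bp, max_extension_cm = Inf,
                     keep_curve = FALSE) {
  K <- length(carriers)
  n <- nrow(H)
  pair_tot <- K * (K - 1) / 2
  grp <- rep(1L, K)
  ehh_prev <- 1
  pos_prev <- pos[core_idx]
  ihh <- 0
  curve <- if (keep_curve) list(list(pos = pos[core_idx], ehh = 1))
  i <- core_idx
  repeat {
    i <- i + direction
    if (i < 1 || i > n) break
    if (abs(pos[i] - pos_prev) > max_gap_bp) break
    if (abs(pos[i] - pos[core_idx]) * cm_per_bp > max_extension_cm) break
    a <- H[i, carriers]
    if (anyNA(a)) break
    grp <- grp * 2L + a
    grp <- match(grp, unique(grp))
    tab <- tabulate(grp)
    ehh <- sum(tab * (tab - 1) / 2) / pair_tot
    d_cm <- abs(pos[i] - pos_prev) * cm_per_bp
    ihh <- ihh + (ehh_prev + ehh) / 2 * d_cm
    if (keep_curve) curve[[length(curve) + 1]] <- list(pos = pos[i],
                                                       ehh = ehh)
    if (ehh < truncation) break
    ehh_prev <- ehh
    pos_prev <- pos[i]
  }
  list(ihh = ihh,
       curve = if (keep_curve) dplyr::bind_rows(curve))
}

#' EHH curve around a core site
#'
#' Extended haplotype homozygosity: at marker m, the probability that two
#' randomly chosen carrier haplotypes of the core allele are identical at
#' every marker between the core and m —
#' `sum over groups of C(k_g, 2) / C(K, 2)` for the partition of the K
#' carriers into haplotype groups. EHH is 1 at the core and non-increasing
#' outward.
#'
#' @param gm A phased, polarized [geno_matrix()].
#' @param pm A [pop_map()].
#' @param population Population whose haplotypes are used.
#' @param scaffold,position Core site location.
#' @param allele `"derived"` or `"ancestral"` carrier set.
#' @param layout A [genome_layout()] (map rate).
#' @param truncation EHH floor below which the curve stops (default 0.05).
#' @param max_gap_kb Marker gap that ends the curve (default 200).
#' @param max_extension_cm Maximum extension from the core in cM.
#' @return A tibble with `direction` (`upstream`/`downstream`), `pos`,
#'   `ehh`, or `NULL` (with a warning) when fewer than 2 carrier
#'   haplotypes exist.
#' @export
ehh <- function(gm, pm, population, scaffold, position,
                allele = c("derived", "ancestral"), layout,
                truncation = 0.05, max_gap_kb = 200,
                max_extension_cm = Inf) {
  allele <- match.arg(allele)
  if (!is_phased(gm)) stop("EHH requires phased haplotypes")
  cols <- hap_cols(population_cols(gm, pm, population))
  on_sc <- which(gm$sites$scaffold == scaffold)
  H <- gm$haplotypes[on_sc, cols, drop = FALSE]
  pos <- gm$sites$pos[on_sc]
  core_idx <- which(pos == position)
  if (length(core_idx) != 1) stop("core site not found on scaffold")
  anc <- gm$sites$ancestral[on_sc[core_idx]]
  if (anc == "unknown") stop("core site has unknown ancestral state")
  derived_code <- if (anc == "ref") 1L else 0L
  want <- if (allele == "derived") derived_code else 1L - derived_code
  carriers <- which(!is.na(H[core_idx, ]) & H[core_idx, ] == want)
  if (length(carriers) < 2) {
    warning("fewer than 2 carrier haplotypes: no curve")
    return(NULL)
  }
  cm_per_bp <- layout$map_rate / 1e6
  up <- ehh_walk(H, pos, core_idx, carriers, -1L, truncation,
                 max_gap_kb * 1000, cm_per_bp, max_extension_cm,
                 keep_curve = TRUE)
  dn <- ehh_walk(H, pos, core_idx, carriers, 1L, truncation,
                 max_gap_kb * 1000, cm_per_bp, max_extension_cm,
                 keep_curve = TRUE)
  dplyr::bind_rows(
    dplyr::mutate(up$curve, direction = "upstream"),
    dplyr::mutate(dn$curve, direction = "downstream"))
}

#' iHS selection scan
#'
#' For every core SNP with known ancestral state and derived-allele
#' frequency in `[maf_min, 1 - maf_min]` within the population, integrates
#' the EHH of ancestral-carrier and derived-carrier haplotype sets against
#' genetic distance (trapezoid rule, cM units from the layout's flat map,
#' truncated at the EHH floor) in both directions, giving iHH_A and
#' iHH_D. The unstandardized score is `ln(iHH_A / iHH_D)`; standardized
#' iHS subtracts the mean and divides by the SD within derived-frequency
#' bins (equal-count), so scores are comparable across frequencies.
#' Strongly negative iHS marks unusually long derived haplotypes — the
#' footprint of a recent or ongoing sweep.
#'
#' @param gm A phased, polarized [geno_matrix()].
#' @param pm A [pop_map()].
#' @param population Population scanned (scans are per-population).
#' @param layout A [genome_layout()].
#' @param maf_min Minimum derived/ancestral frequency (default 0.05).
#' @param truncation EHH integration floor (default 0.05).
#' @param bins Number of equal-count frequency bins for standardization
#'   (default 20).
#' @param max_gap_kb Marker gap that invalidates the curve beyond it
#'   (default 200).
#' @return An object of class `ihs_scan`: list with `sites` (tibble:
#'   `scaffold`, `pos`, `derived_freq`, `ihh_a`, `ihh_d`, `uihs`,
#'   `std_ihs`, `valid`, `bin`), the scan parameters and the population.
#' @export
ihs <- function(gm, pm, population, layout, maf_min = 0.05,
                truncation = 0.05, bins = 20, max_gap_kb = 200) {
  if (!is_phased(gm)) stop("iHS requires phased haplotypes")
  cols <- hap_cols(population_cols(gm, pm, population))
  cm_per_bp <- layout$map_rate / 1e6
  max_gap_bp <- max_gap_kb * 1000

  res <- purrr::map_dfr(split(seq_len(n_sites(gm)), gm$sites$scaffold),
                        function(on_sc) {
    H <- gm$haplotypes[on_sc, cols, drop = FALSE]
    pos <- gm$sites$pos[on_sc]
    anc <- gm$sites$ancestral[on_sc]
    derived_code <- ifelse(anc == "ref", 1L, ifelse(anc == "alt", 0L,
                                                    NA_integer_))
    called <- rowSums(!is.na(H))
    nder <- rowSums(H == rep(derived_code, ncol(H)), na.rm = TRUE)
    pder <- ifelse(called > 0 & !is.na(derived_code),
                   nder / called, NA_real_)
    eligible <- !is.na(pder) & pder >= maf_min & pder <= 1 - maf_min
    out <- tibble::tibble(
      scaffold = gm$sites$scaffold[on_sc], pos = pos,
      derived_freq = pder, ihh_a = NA_real_, ihh_d = NA_real_)
    for (j in which(eligible)) {
      der <- which(!is.na(H[j, ]) & H[j, ] == derived_code[j])
      anc_c <- which(!is.na(H[j, ]) & H[j, ] == 1L - derived_code[j])
      if (length(der) < 2 || length(anc_c) < 2) next
      ihh_d <- ehh_walk(H, pos, j, der, -1L, truncation, max_gap_bp,
                        cm_per_bp)$ihh +
        ehh_walk(H, pos, j, der, 1L, truncation, max_gap_bp,
                 cm_per_bp)$ihh
      ihh_a <- ehh_walk(H, pos, j, anc_c, -1L, truncation, max_gap_bp,
                        cm_per_bp)$ihh +
        ehh_walk(H, pos, j, anc_c, 1L, truncation, max_gap_bp,
                 cm_per_bp)$ihh
      out$ihh_a[j] <- ihh_a
      out$ihh_d[j] <- ihh_d
    }
    out
  })

  res$uihs <- ifelse(res$ihh_a > 0 & res$ihh_d > 0,
                     log(res$ihh_a / res$ihh_d), NA_real_)
  res$valid <- !is.na(res$uihs)
  res$bin <- NA_integer_
  res$std_ihs <- NA_real_
  v <- which(res$valid)
  if (length(v) > 0) {
    nb <- max(1, min(bins, floor(length(v) / 2)))
    qs <- stats::quantile(res$derived_freq[v],
                          probs = seq(0, 1, length.out = nb + 1))
    qs[1] <- -Inf; qs[nb + 1] <- Inf
    bin <- cut(res$derived_freq[v], breaks = unique(qs), labels = FALSE)
    res$bin[v] <- bin
    for (b in unique(bin)) {
      ii <- v[bin == b]
      mu <- mean(res$uihs[ii])
      sdv <- stats::sd(res$uihs[ii])
      res$std_ihs[ii] <- if (!is.na(sdv) && sdv > 0) {
        (res$uihs[ii] - mu) / sdv
      } else 0
    }
  }
  structure(list(sites = res, population = population,
                 maf_min = maf_min, truncation = truncation,
                 bins = bins, max_gap_kb = max_gap_kb),
            class = "ihs_scan")
}

#' @export
print.ihs_scan <- function(x, ...) {
  cat(sprintf("<ihs_scan> %s: %d sites scored (%d eligible cores)\n",
              x$population, sum(x$sites$valid), nrow(x$sites)))
  invisible(x)
}

#' Candidate sites from an iHS scan
#'
#' Sites whose absolute standardized iHS reaches the top `quantile`
#' fraction of valid scores; ties at the threshold are all included.
#'
#' @param scan An `ihs_scan`.
#' @param quantile Upper tail fraction (default 0.001, the top 0.1%).
#' @return A tibble of candidate sites (`scaffold`, `pos`, `std_ihs`).
#' @export
candidate_sites <- function(scan, quantile = 0.001) {
  s <- scan$sites[scan$sites$valid, ]
  if (nrow(s) == 0) stop("no valid iHS results")
  thr <- stats::quantile(abs(s$std_ihs), 1 - quantile, names = FALSE)
  if (min(abs(s$std_ihs)) == max(abs(s$std_ihs))) {
    warning("all scores tied: every site is a candidate")
  }
  s[abs(s$std_ihs) >= thr, c("scaffold", "pos", "std_ihs")]
}

#' Screen candidate regions around selected sites
#'
#' Implements the three region-screening methods used with iHS scans:
#' (a) blocks of 50 consecutive scored SNPs, (b) 100-kb windows stepped by
#' 50 kb, and (c) 5-kb flanks around each candidate site, merged when
#' overlapping. Per method, each region containing at least one candidate
#' site gets a siHS score — the sum of |standardized iHS| over its
#' candidate sites (set `signed = TRUE` to sum signed scores instead) —
#' and regions in the top `top_fraction` of siHS (among candidate-
#' containing regions of that method) are kept. Kept regions are mapped
#' to overlapping gene features; the final gene set is the intersection
#' across the three methods.
#'
#' @param candidates Candidate-site tibble from [candidate_sites()].
#' @param scan The `ihs_scan` the candidates came from.
#' @param layout A [genome_layout()].
#' @param genes Feature tibble (`scaffold`, `start`, `end`, `gene_id`),
#'   e.g. from [read_features()] or [tile_genes()]; `NULL` skips gene
#'   mapping with a warning.
#' @param consecutive_snps,window_kb,step_kb,flank_kb Method parameters
#'   (defaults 50 SNPs, 100 kb / 50 kb, 5 kb).
#' @param top_fraction Fraction of candidate-containing regions kept per
#'   method (default 0.10).
#' @param signed Sum signed instead of absolute scores (default FALSE).
#' @return A list with `regions` (tibble: `method`, `scaffold`, `start`,
#'   `end`, `n_candidates`, `sihs`, `kept`), `genes_by_method` and
#'   `genes_intersection`.
#' @export
screen_regions <- function(candidates, scan, layout, genes = NULL,
                           consecutive_snps = 50, window_kb = 100,
                           step_kb = 50, flank_kb = 5,
                           top_fraction = 0.10, signed = FALSE) {
  scored <- scan$sites[scan$sites$valid, ]
  empty <- tibble::tibble(method = character(), scaffold = character(),
                          start = numeric(), end = numeric(),
                          n_candidates = integer(), sihs = numeric(),
                          kept = logical())
  if (nrow(candidates) == 0) {
    return(list(regions = empty, genes_by_method = list(),
                genes_intersection = character()))
  }

  # method a: consecutive disjoint blocks of scored SNPs
  reg_a <- scored |>
    dplyr::group_by(.data$scaffold) |>
    dplyr::arrange(.data$pos, .by_group = TRUE) |>
    dplyr::mutate(chunk = (dplyr::row_number() - 1) %/%
                    consecutive_snps) |>
    dplyr::group_by(.data$scaffold, .data$chunk) |>
    dplyr::summarise(start = min(.data$pos), end = max(.data$pos),
                     .groups = "drop") |>
    dplyr::mutate(method = "consecutive_snp") |>
    dplyr::select(-"chunk")

  # method b: sliding windows over the layout
  reg_b <- purrr::pmap_dfr(layout$scaffolds, function(name, length) {
    starts <- seq(1, max(1, length - 1), by = step_kb * 1000)
    tibble::tibble(scaffold = name, start = starts,
                   end = pmin(starts + window_kb * 1000 - 1, length))
  }) |>
    dplyr::mutate(method = "sliding_window")

  # method c: merged flanks around candidate sites
  reg_c <- candidates |>
    dplyr::mutate(start = pmax(1, .data$pos - flank_kb * 1000),
                  end = .data$pos + flank_kb * 1000) |>
    dplyr::group_by(.data$scaffold) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(gap = .data$start >
                    cummax(dplyr::lag(.data$end,
                                      default = dplyr::first(.data$end))) ,
                  cluster = cumsum(dplyr::coalesce(.data$gap, FALSE))) |>
    dplyr::group_by(.data$scaffold, .data$cluster) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop") |>
    dplyr::mutate(method = "flanking") |>
    dplyr::select(-"cluster")

  cand <- dplyr::rename(candidates, start2 = "pos")
  cand$end2 <- cand$start2
  score_regions <- function(reg) {
    hits <- dplyr::inner_join(
      reg, cand,
      by = dplyr::join_by(scaffold, start <= start2, end >= end2),
      relationship = "many-to-many") |>
      dplyr::group_by(.data$method, .data$scaffold, .data$start,
                      .data$end) |>
      dplyr::summarise(
        n_candidates = dplyr::n(),
        sihs = if (signed) sum(.data$std_ihs) else sum(abs(.data$std_ihs)),
        .groups = "drop")
    if (nrow(hits) == 0) return(dplyr::mutate(hits, kept = logical(0)))
    thr <- stats::quantile(hits$sihs, 1 - top_fraction, names = FALSE)
    dplyr::mutate(hits, kept = .data$sihs >= thr)
  }
  regions <- dplyr::bind_rows(score_regions(reg_a), score_regions(reg_b),
                              score_regions(reg_c))

  genes_by_method <- list()
  genes_intersection <- character()
  if (is.null(genes) || nrow(tibble::as_tibble(genes)) == 0) {
    warning("no gene annotation: gene mapping skipped")
  } else {
    g <- dplyr::rename(tibble::as_tibble(genes),
                       start2 = "start", end2 = "end")
    kept <- dplyr::filter(regions, .data$kept)
    genes_by_method <- purrr::map(
      stats::setNames(unique(regions$method), unique(regions$method)),
      function(m) {
        r <- dplyr::filter(kept, .data$method == m)
        hit <- dplyr::inner_join(
          r, g, by = dplyr::join_by(scaffold, start <= end2,
                                    end >= start2),
          relationship = "many-to-many")
        sort(unique(hit$gene_id))
      })
    genes_intersection <- purrr::reduce(genes_by_method, intersect)
  }
  list(regions = regions, genes_by_method = genes_by_method,
       genes_intersection = genes_intersection)
}
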