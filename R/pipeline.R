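#' Run the full population-genomic pipeline
#'
#' Orchestrates the analysis stages in dependency order — input (VCF +
#' population map or simulation), outgroup polarization, site filtering,
#' then any of diversity, differentiation (FST/F3/D), ROH, mutational
#' load and iHS selection — and writes one TSV per result table into the
#' output directory together with a YAML manifest recording every
#' parameter, default and seed, so a run is reproducible from its
#' manifest alone.
#'
#' @param config A named list (or path to a YAML file) with entries:
#'   * `seed`: integer (required).
#'   * either `simulate` (a list of [sim_config()] arguments) or `input`
#'     (list with `vcf`, `pop_map`, `layout` paths and optional `genes`);
#'   * `stages`: character subset of `c("diversity", "differentiation",
#'     "roh", "load", "selection")` (default: the first four; selection
#'     requires phased input);
#'   * `af_threshold`: site-filter MAF threshold (default 0);
#'   * `block_length`: jackknife block bp (default 5e6);
#'   * `roh`, `ihs`: named lists of parameter overrides;
#'   * `generation_time`: years (default 1);
#'   * `out_dir`: output directory (required).
#' @return Invisibly, a list of the computed result objects
#'   (`AnalysisReport`): paths of written tables in `$files`, plus the
#'   in-memory results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(!is.null(config$out_dir), !is.null(config$seed))
  if (is.null(config$simulate) == is.null(config$input)) {
    stop("exactly one of 'simulate' or 'input' must be configured")
  }
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages %||%
    c("diversity", "differentiation", "roh", "load")
  set.seed(config$seed)

  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% config$seed
    cfg <- do.call(sim_config, sim_args)
    panel <- simulate_panel(cfg)
    gm <- panel$genotypes; pm <- panel$populations
    layout <- cfg$layout
  } else {
    inp <- config$input
    layout <- read_layout_tsv(inp$layout,
                              map_rate = config$map_rate %||% 1)
    gm <- read_vcf(inp$vcf, layout)
    pm <- read_pop_map(inp$pop_map)
  }
  genes <- if (!is.null(config$input$genes)) {
    read_features(config$input$genes)
  } else if (!is.null(config$simulate)) tile_genes(layout)

  gm <- polarize_by_outgroup(gm, pm)
  gm <- filter_sites(gm, pm, layout,
                     af_threshold = config$af_threshold %||% 0)
  if (n_sites(gm) == 0) stop("no sites left after filtering")

  results <- list()
  files <- character()
  wtsv <- function(tab, name, params = "") {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    header <- sprintf("# pangopop %s | seed=%s%s", name, config$seed,
                      if (nzchar(params)) paste0(" | ", params) else "")
    writeLines(header, path)
    suppressWarnings(readr::write_tsv(tab, path, append = TRUE,
                                      col_names = TRUE))
    files <<- c(files, path)
    message(sprintf("stage %-16s -> %s (%d rows)", name, path, nrow(tab)))
  }
  blen <- config$block_length %||% 5e6

  if ("diversity" %in% stages) {
    he <- heterozygosity(gm)
    wtsv(he, "heterozygosity")
    pi_tab <- purrr::map_dfr(study_populations(pm), function(p) {
      nd <- nucleotide_diversity(gm, pm, p, layout,
                                 window = config$pi_window %||% 1e6)
      tibble::tibble(population = p, mean_pi = nd$mean_pi)
    })
    wtsv(pi_tab, "nucleotide_diversity")
    wtsv(snp_counts(gm, pm), "snp_counts")
    pca <- pca_genotypes(gm, pm,
                         n_components = config$n_components %||% 2)
    wtsv(pca$scores, "pca_scores")
    results$diversity <- list(he = he, pi = pi_tab, pca = pca)
  }

  if ("differentiation" %in% stages) {
    fstm <- fst_matrix(gm, pm)
    wtsv(fstm, "fst_matrix")
    pops <- study_populations(pm)
    f3_tab <- purrr::map_dfr(pops, function(tg) {
      src <- setdiff(pops, tg)
      r <- f3(gm, pm, tg, src[1], src[2], layout, blen)
      tibble::tibble(target = tg, source1 = src[1], source2 = src[2],
                     F3 = r$F3, Z = r$jackknife$Z, admixed = r$admixed)
    })
    wtsv(f3_tab, "f3", sprintf("block_length=%g", blen))
    d_tab <- if (length(pops) >= 3) {
      combs <- list(c(pops[1], pops[2], pops[3]),
                    c(pops[1], pops[3], pops[2]),
                    c(pops[2], pops[3], pops[1]))
      purrr::map_dfr(combs, function(cc) {
        d <- d_statistic(gm, pm, cc[1], cc[2], cc[3], layout, blen)
        tibble::tibble(A = cc[1], B = cc[2], X = cc[3], D = d$D,
                       Z = d$jackknife$Z, significant = d$significant)
      })
    } else tibble::tibble()
    wtsv(d_tab, "dstat", sprintf("block_length=%g", blen))
    results$differentiation <- list(fst = fstm, f3 = f3_tab, d = d_tab)
  }

  if ("roh" %in% stages) {
    roh_args <- config$roh %||% list()
    segs <- do.call(detect_roh_all, c(list(gm, pm), roh_args))
    wtsv(segs, "roh_segments",
         paste(names(roh_args), unlist(roh_args), sep = "=",
               collapse = " "))
    fr <- froh(segs, layout, pm)
    wtsv(fr$per_sample, "froh_per_sample")
    wtsv(fr$per_population, "froh_per_population")
    if (nrow(segs) > 0) {
      ages <- dplyr::bind_cols(
        segs[, c("sample", "scaffold", "start", "end")],
        generations_from_roh(segs$length, layout,
                             config$generation_time %||% 1))
      wtsv(ages, "roh_ages")
    }
    results$roh <- list(segments = segs, froh = fr)
  }

  if ("load" %in% stages) {
    ls_ <- derived_load_counts(gm, pm)
    wtsv(ls_$per_sample, "load_per_sample")
    wtsv(ls_$per_population, "load_per_population")
    zr <- purrr::map_dfr(
      c("lof", "missense", "deleterious_missense"),
      function(cc) dplyr::bind_rows(
        zygosity_ratio(ls_, cc, "all"),
        purrr::map_dfr(study_populations(pm),
                       function(p) zygosity_ratio(ls_, cc, p))))
    wtsv(zr, "zygosity_ratios")
    tm <- translocation_matrix(gm, pm)
    wtsv(tm, "translocation_matrix")
    results$load <- list(summary = ls_, zygosity = zr,
                         translocation = tm)
  }

  if ("selection" %in% stages) {
    if (!is_phased(gm)) {
      stop("selection stage requires phased haplotypes ",
           "(phased GT in the input VCF)")
    }
    ihs_args <- config$ihs %||% list()
    sel <- purrr::map(
      stats::setNames(study_populations(pm), study_populations(pm)),
      function(p) {
        scan <- do.call(ihs, c(list(gm, pm, p, layout), ihs_args))
        cand <- candidate_sites(scan,
                                quantile = config$ihs_quantile %||% 0.001)
        scr <- screen_regions(cand, scan, layout, genes)
        list(scan = scan, candidates = cand, screen = scr)
      })
    ihs_tab <- purrr::imap_dfr(sel, function(s, p) {
      dplyr::mutate(s$candidates, population = p, .before = 1)
    })
    wtsv(ihs_tab, "ihs_candidates")
    gene_tab <- purrr::imap_dfr(sel, function(s, p) {
      tibble::tibble(population = p,
                     gene_id = s$screen$genes_intersection)
    })
    wtsv(gene_tab, "selected_genes")
    results$selection <- sel
  }

  manifest <- list(
    package = "pangopop",
    version = as.character(utils::packageVersion("pangopop")),
    seed = config$seed, stages = stages,
    af_threshold = config$af_threshold %||% 0,
    block_length = blen,
    generation_time = config$generation_time %||% 1,
    config = config[setdiff(names(config), "out_dir")],
    n_sites = n_sites(gm), n_samples = length(gm$samples))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  results$files <- c(files, file.path(out_dir, "manifest.yaml"))
  invisible(results)
}

#' Pairwise summary tables from a pipeline run
#'
#' Reshapes the differentiation and load results of [run_pipeline()] into
#' the pairwise matrices conservation reports use: a symmetric FST matrix
#' with zero diagonal, the directional donor x receiver translocation
#' matrix, and the D-statistic table.
#'
#' @param results The (invisible) return value of [run_pipeline()].
#' @return A list with `fst` (matrix), `translocation` (matrix, rows =
#'   donor), `d` (tibble).
#' @export
summarize_pairwise <- function(results) {
  out <- list()
  if (!is.null(results$differentiation)) {
    ft <- results$differentiation$fst
    pops <- sort(unique(c(ft$pop_a, ft$pop_b)))
    m <- matrix(0, length(pops), length(pops),
                dimnames = list(pops, pops))
    for (i in seq_len(nrow(ft))) {
      m[ft$pop_a[i], ft$pop_b[i]] <- m[ft$pop_b[i], ft$pop_a[i]] <-
        ft$fst[i]
    }
    out$fst <- m
    out$d <- results$differentiation$d
  }
  if (!is.null(results$load)) {
    tm <- results$load$translocation
    pops <- sort(unique(c(tm$donor, tm$receiver)))
    m <- matrix(NA_real_, length(pops), length(pops),
                dimnames = list(pops, pops))
    for (i in seq_len(nrow(tm))) m[tm$donor[i], tm$receiver[i]] <- tm$mean[i]
    out$translocation <- m
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
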