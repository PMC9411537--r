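#' Simulation configuration
#'
#' Describes a synthetic resequencing panel with the hierarchical
#' three-population structure typical of fragmented populations of a
#' threatened species: two sister populations separated by a shallow split
#' (drift parameter `branch_F["shallow"]`), both separated from a third
#' population by a deep split (`branch_F["deep"]`), plus an outgroup fixed
#' for the ancestral allele. Population allele frequencies follow the
#' Balding-Nichols model: a daughter frequency is drawn from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` around the parent frequency `p`, so `F`
#' is the FST-like differentiation accrued on that branch and genome-wide
#' Weir-Cockerham FST between two independently drifted daughters recovers
#' `F` — the handle every parameter-recovery test relies on.
#'
#' The defaults emulate the study conditions of a three-population pangolin
#' panel: sample sizes 11/18/8 diploids plus one outgroup genome, deep and
#' shallow differentiation of 0.5 and 0.1 (the regime of genome-wide FST
#' values near 0.54 and 0.10), an ancestral-frequency draw shaped
#' Beta(0.3, 0.3) truncated to (0.01, 0.99) so roughly half of the SNPs
#' segregate at MAF < 5%, and a coding-enriched consequence mix so load
#' statistics have usable counts at desk-scale site numbers.
#'
#' @param seed Integer seed; one global seed governs all draws.
#' @param layout A [genome_layout()]. Default: ten 10-Mb scaffolds.
#' @param n_sites Number of SNP sites to simulate.
#' @param sample_sizes Named integer vector of diploid counts; names are
#'   the population labels. The first two study populations are the sister
#'   (shallow) pair, the third is the deep branch; the reserved name
#'   `OUTGROUP` sizes the outgroup.
#' @param branch_F Named numeric vector `c(deep = , shallow = )`, each in
#'   \[0, 1) (0 means no drift on that branch).
#' @param admixture Optional `list(donor = , receiver = , f = )`: after the
#'   frequency draws, the receiver's frequencies become
#'   `(1 - f) * p_receiver + f * p_donor`.
#' @param ancestral_beta Shape parameters `c(a, b)` of the ancestral
#'   allele-frequency Beta draw.
#' @param ancestral_trunc Truncation interval of the ancestral draw.
#' @param consequence_mix Named proportions for `synonymous`, `missense`
#'   and `lof` sites (LoF split evenly between splice donor, splice
#'   acceptor and stop gained); the remainder is noncoding.
#' @param deleterious_missense_fraction Target fraction of missense sites
#'   whose amino-acid change has Grantham score >= 150.
#' @param missing_rate Per-genotype missingness probability.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       layout = genome_layout(stats::setNames(
                         rep(1e7, 10), sprintf("scf%02d", 1:10))),
                       n_sites = 20000,
                       sample_sizes = c(CPA = 11, CPB = 18, CPC = 8,
                                        OUTGROUP = 1),
                       branch_F = c(deep = 0.5, shallow = 0.1),
                       admixture = NULL,
                       ancestral_beta = c(0.3, 0.3),
                       ancestral_trunc = c(0.01, 0.99),
                       consequence_mix = c(synonymous = 0.10,
                                           missense = 0.08, lof = 0.01),
                       deleterious_missense_fraction = 0.2,
                       missing_rate = 0.02) {
  stopifnot(all(branch_F >= 0), all(branch_F < 1),
            all(c("deep", "shallow") %in% names(branch_F)),
            sum(consequence_mix) <= 1, all(consequence_mix >= 0),
            all(sample_sizes >= 1), n_sites >= 1,
            missing_rate >= 0, missing_rate < 1)
  if (!is.null(admixture)) {
    stopifnot(all(c("donor", "receiver", "f") %in% names(admixture)),
              admixture$f >= 0, admixture$f <= 1)
  }
  structure(as.list(environment()), class = "sim_config")
}

# Balding-Nichols daughter frequencies around parent p with drift F
bn_draw <- function(p, F) {
  if (F == 0) return(p)
  stats::rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
}

# uniform site positions, unique within scaffold, sorted
draw_positions <- function(layout, n_sites) {
  sc <- layout$scaffolds
  n_per <- stats::rmultinom(1, n_sites, sc$length / sum(sc$length))[, 1]
  purrr::map2_dfr(sc$name, seq_along(n_per), function(nm, i) {
    k <- n_per[i]
    if (k == 0) return(NULL)
    tibble::tibble(scaffold = nm,
                   pos = sort(sample.int(sc$length[i], k)))
  })
}

# draw amino-acid change pairs so the realized GS >= 150 fraction matches
# the target; pairs come from the published Grantham catalog
draw_aa_pairs <- function(n, deleterious_fraction) {
  cat_all <- grantham_pairs()
  del <- cat_all[cat_all$score >= 150, ]
  tol <- cat_all[cat_all$score < 150, ]
  take_del <- stats::rbinom(n, 1, deleterious_fraction) == 1
  i_del <- sample.int(nrow(del), sum(take_del), replace = TRUE)
  i_tol <- sample.int(nrow(tol), sum(!take_del), replace = TRUE)
  out <- tibble::tibble(aa_ref = character(n), aa_alt = character(n))
  out$aa_ref[take_del] <- del$aa1[i_del]
  out$aa_alt[take_del] <- del$aa2[i_del]
  out$aa_ref[!take_del] <- tol$aa1[i_tol]
  out$aa_alt[!take_del] <- tol$aa2[i_tol]
  out
}

#' Simulate a three-population panel with known truth
#'
#' Draws per-site ancestral frequencies, propagates them down the
#' two-level population tree under the Balding-Nichols model, applies an
#' optional admixture pulse, and samples Hardy-Weinberg diploid genotypes
#' per population. The outgroup is fixed homozygous for the ancestral
#' allele (which is the reference allele for a random half of the sites),
#' so outgroup polarization can be exercised end to end. Consequence
#' classes and amino-acid changes are assigned so that load accounting has
#' known composition; coding sites carry gene ids matching [tile_genes()].
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `genotypes` (a [geno_matrix()] with
#'   ancestral states and consequences filled in), `populations` (a
#'   [pop_map()]) and `truth` (a tibble of per-site ancestral and
#'   per-population allele frequencies, on the derived-allele scale of the
#'   simulation).
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  pops <- setdiff(names(cfg$sample_sizes), "OUTGROUP")
  if (length(pops) != 3) stop("need exactly three study populations")
  n_og <- if ("OUTGROUP" %in% names(cfg$sample_sizes)) {
    cfg$sample_sizes[["OUTGROUP"]]
  } else 0
  if (n_og < 1) stop("an outgroup sample is required for polarization")

  sites <- draw_positions(cfg$layout, cfg$n_sites)
  n <- nrow(sites)

  # ancestral (derived-allele) frequency, truncated Beta
  ab <- cfg$ancestral_beta
  lo <- stats::pbeta(cfg$ancestral_trunc[1], ab[1], ab[2])
  hi <- stats::pbeta(cfg$ancestral_trunc[2], ab[1], ab[2])
  p0 <- stats::qbeta(stats::runif(n, lo, hi), ab[1], ab[2])

  Fd <- cfg$branch_F[["deep"]]
  Fs <- cfg$branch_F[["shallow"]]
  p_ab <- bn_draw(p0, Fd)
  freqs <- list()
  freqs[[pops[1]]] <- bn_draw(p_ab, Fs)
  freqs[[pops[2]]] <- bn_draw(p_ab, Fs)
  freqs[[pops[3]]] <- bn_draw(p0, Fd)
  if (!is.null(cfg$admixture)) {
    a <- cfg$admixture
    freqs[[a$receiver]] <- (1 - a$f) * freqs[[a$receiver]] +
      a$f * freqs[[a$donor]]
  }

  # alleles: ancestral is REF for a random half of sites
  nt <- c("A", "C", "G", "T")
  ref <- sample(nt, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1), character(1))
  anc_is_ref <- stats::runif(n) < 0.5

  # genotypes: HWE binomial sampling of the derived allele, then converted
  # to alt dosage (derived = alt where ancestral = ref, else ref)
  gl <- list()
  sample_names <- character(0)
  pm_tab <- list()
  for (p in pops) {
    k <- cfg$sample_sizes[[p]]
    der <- matrix(stats::rbinom(n * k, 2, freqs[[p]]), nrow = n)
    der[!anc_is_ref, ] <- 2L - der[!anc_is_ref, ]  # convert to alt dosage
    gl[[p]] <- der
    nm <- sprintf("%s_%02d", p, seq_len(k))
    sample_names <- c(sample_names, nm)
    pm_tab[[p]] <- tibble::tibble(sample = nm, population = p)
  }
  og <- matrix(ifelse(anc_is_ref, 0L, 2L), nrow = n, ncol = n_og)
  nm <- sprintf("OUTGROUP_%02d", seq_len(n_og))
  sample_names <- c(sample_names, nm)
  pm_tab$OUTGROUP <- tibble::tibble(sample = nm, population = "OUTGROUP")
  calls <- cbind(do.call(cbind, gl[pops]), og)
  storage.mode(calls) <- "integer"
  if (cfg$missing_rate > 0) {
    calls[stats::runif(length(calls)) < cfg$missing_rate] <- NA_integer_
  }

  # consequence classes and amino-acid changes
  mix <- cfg$consequence_mix
  lof_classes <- c("lof_splice_donor", "lof_splice_acceptor",
                   "lof_stop_gained")
  csq <- sample(
    c("synonymous", "missense", lof_classes, "none"), n, replace = TRUE,
    prob = c(mix[["synonymous"]], mix[["missense"]],
             rep(mix[["lof"]] / 3, 3), 1 - sum(mix)))
  aa_ref <- rep(NA_character_, n)
  aa_alt <- rep(NA_character_, n)
  is_mis <- csq == "missense"
  if (any(is_mis)) {
    pairs <- draw_aa_pairs(sum(is_mis), cfg$deleterious_missense_fraction)
    aa_ref[is_mis] <- pairs$aa_ref
    aa_alt[is_mis] <- pairs$aa_alt
  }
  is_syn <- csq == "synonymous"
  aa_ref[is_syn] <- aa_alt[is_syn] <- sample(grantham_residues(),
                                             sum(is_syn), replace = TRUE)
  coding <- csq != "none"
  gene_id <- rep(NA_character_, n)
  gene_id[coding] <- sprintf("%s_g%04d", sites$scaffold[coding],
                             (sites$pos[coding] - 1) %/% 50000 + 1)

  site_tab <- tibble::tibble(
    scaffold = sites$scaffold, pos = sites$pos, ref = ref, alt = alt,
    ancestral = ifelse(anc_is_ref, "ref", "alt"),
    consequence = csq, aa_ref = aa_ref, aa_alt = aa_alt, gene_id = gene_id)

  truth <- tibble::tibble(
    scaffold = sites$scaffold, pos = sites$pos,
    ancestral_allele = ifelse(anc_is_ref, ref, alt),
    p_ancestral = p0, p_internal = p_ab)
  for (p in pops) truth[[paste0("p_", p)]] <- freqs[[p]]

  list(genotypes = geno_matrix(site_tab, calls, sample_names),
       populations = pop_map(dplyr::bind_rows(pm_tab)),
       truth = truth)
}

#' Gene features matching the simulated gene tiling
#'
#' Coding sites simulated by [simulate_panel()] carry gene ids laid out on
#' a fixed tiling of the genome; this returns those tiles as a feature
#' table usable by [screen_regions()].
#'
#' @param layout A [genome_layout()].
#' @param tile_kb Tile length in kb (default 50, matching the generator).
#' @return A tibble with `scaffold`, `start`, `end`, `gene_id`.
#' @export
tile_genes <- function(layout, tile_kb = 50) {
  purrr::pmap_dfr(layout$scaffolds, function(name, length) {
    starts <- seq(1, length, by = tile_kb * 1000)
    tibble::tibble(
      scaffold = name, start = starts,
      end = pmin(starts + tile_kb * 1000 - 1, length),
      gene_id = sprintf("%s_g%04d", name, seq_along(starts)))
  })
}

# draw phased background haplotypes for every population under the
# hierarchical Balding-Nichols model; linkage equilibrium between sites
build_phased <- function(cfg, extra_site = NULL) {
  pops <- setdiff(names(cfg$sample_sizes), "OUTGROUP")
  sites <- draw_positions(cfg$layout,
                          cfg$n_sites - !is.null(extra_site))
  if (!is.null(extra_site)) {
    sites <- dplyr::arrange(
      dplyr::distinct(dplyr::bind_rows(sites, extra_site)),
      scaffold, pos)
  }
  n <- nrow(sites)
  ab <- cfg$ancestral_beta
  lo <- stats::pbeta(cfg$ancestral_trunc[1], ab[1], ab[2])
  hi <- stats::pbeta(cfg$ancestral_trunc[2], ab[1], ab[2])
  p0 <- stats::qbeta(stats::runif(n, lo, hi), ab[1], ab[2])
  Fd <- cfg$branch_F[["deep"]]
  Fs <- cfg$branch_F[["shallow"]]
  p_ab <- bn_draw(p0, Fd)
  freqs <- list()
  freqs[[pops[1]]] <- bn_draw(p_ab, Fs)
  freqs[[pops[2]]] <- bn_draw(p_ab, Fs)
  freqs[[pops[3]]] <- bn_draw(p0, Fd)
  hap_list <- list()
  sample_names <- character(0)
  pm_tab <- list()
  for (p in pops) {
    k <- cfg$sample_sizes[[p]]
    hap_list[[p]] <- matrix(stats::rbinom(n * 2 * k, 1, freqs[[p]]),
                            nrow = n)
    nm <- sprintf("%s_%02d", p, seq_len(k))
    sample_names <- c(sample_names, nm)
    pm_tab[[p]] <- tibble::tibble(sample = nm, population = p)
  }
  list(sites = sites, p0 = p0, freqs = freqs, hap_list = hap_list,
       sample_names = sample_names, pm_tab = pm_tab, pops = pops)
}

# assemble a phased geno_matrix from build_phased() state
assemble_phased <- function(cfg, st) {
  n <- nrow(st$sites)
  n_og <- cfg$sample_sizes[["OUTGROUP"]]
  haplotypes <- cbind(do.call(cbind, st$hap_list[st$pops]),
                      matrix(0L, nrow = n, ncol = 2 * n_og))
  nm <- sprintf("OUTGROUP_%02d", seq_len(n_og))
  sample_names <- c(st$sample_names, nm)
  st$pm_tab$OUTGROUP <- tibble::tibble(sample = nm,
                                       population = "OUTGROUP")
  calls <- haplotypes[, seq(1, ncol(haplotypes), 2), drop = FALSE] +
    haplotypes[, seq(2, ncol(haplotypes), 2), drop = FALSE]
  nt <- c("A", "C", "G", "T")
  ref <- sample(nt, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1), character(1))
  site_tab <- tibble::tibble(
    scaffold = st$sites$scaffold, pos = st$sites$pos, ref = ref,
    alt = alt,
    ancestral = "ref")  # haplotype allele 1 is the derived (alt) allele
  gm <- geno_matrix(site_tab, calls, sample_names, haplotypes)
  list(genotypes = gm,
       populations = pop_map(dplyr::bind_rows(st$pm_tab)),
       truth = tibble::tibble(scaffold = st$sites$scaffold,
                              pos = st$sites$pos, p_ancestral = st$p0))
}

#' Simulate a neutral phased panel
#'
#' Background haplotypes only: per site, haplotype alleles are drawn
#' independently from the hierarchical Balding-Nichols population
#' frequencies (linkage equilibrium), so EHH decays rapidly everywhere
#' and an iHS scan on this panel is a null scan.
#'
#' @param cfg A [sim_config()].
#' @return As [simulate_panel()], with phased genotypes.
#' @export
simulate_phased_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  assemble_phased(cfg, build_phased(cfg))
}

#' Simulate phased haplotypes carrying a sweep
#'
#' As [simulate_phased_panel()], except that haplotypes carrying the
#' derived allele at the sweep core are copies of a single founder
#' haplotype over a tract of `copy_length` bp centred on the core, with
#' sparse private mutations. This is the generative analogue of a recent
#' hard/soft sweep: extended haplotype homozygosity among derived
#' carriers, and the contrast iHS measures.
#'
#' @param cfg A [sim_config()].
#' @param core_scaffold,core_position Core site location (a SNP is placed
#'   exactly there).
#' @param target_population Population carrying the sweep.
#' @param derived_frequency Derived-allele frequency at the core in the
#'   target population (needs at least 2 carrier haplotypes).
#' @param copy_length Tract length in bp over which carriers copy the
#'   founder.
#' @param background_mutation_rate Per-site, per-carrier probability of a
#'   private mutation on the copied tract.
#' @return As [simulate_panel()], with `genotypes` phased and the core
#'   site's location attached as `attr(x, "core")`.
#' @export
simulate_haplotypes_with_sweep <- function(cfg, core_scaffold,
                                           core_position,
                                           target_population,
                                           derived_frequency = 0.5,
                                           copy_length = 5e5,
                                           background_mutation_rate = 0.002) {
  stopifnot(inherits(cfg, "sim_config"),
            derived_frequency > 0, derived_frequency < 1)
  set.seed(cfg$seed)
  if (copy_length > scaffold_length(cfg$layout, core_scaffold)) {
    stop("copy_length exceeds the core scaffold length")
  }
  st <- build_phased(cfg, tibble::tibble(scaffold = core_scaffold,
                                         pos = core_position))
  if (!target_population %in% st$pops) stop("unknown target population")
  sites <- st$sites
  core_idx <- which(sites$scaffold == core_scaffold &
                      sites$pos == core_position)

  # sweep: derived carriers at the core copy a single founder haplotype
  ht <- st$hap_list[[target_population]]
  K <- ncol(ht)
  n_car <- round(derived_frequency * K)
  if (n_car < 2) stop("derived_frequency too low: need >= 2 carriers")
  carriers <- sample.int(K, n_car)
  ht[core_idx, ] <- 0L
  ht[core_idx, carriers] <- 1L
  tract <- which(sites$scaffold == core_scaffold &
                   abs(sites$pos - core_position) <= copy_length / 2)
  founder <- ht[tract, carriers[1]]
  ht[tract, carriers] <- founder
  if (background_mutation_rate > 0) {
    mut <- matrix(stats::runif(length(tract) * n_car) <
                    background_mutation_rate,
                  nrow = length(tract))
    mut[sites$pos[tract] == core_position, ] <- FALSE
    sub <- ht[tract, carriers, drop = FALSE]
    sub[mut] <- 1L - sub[mut]
    ht[tract, carriers] <- sub
  }
  st$hap_list[[target_population]] <- ht

  out <- assemble_phased(cfg, st)
  attr(out, "core") <- list(scaffold = core_scaffold, pos = core_position)
  out
}

#' Inject autozygous tracts into one sample
#'
#' Forces the sample homozygous inside each tract: at every site of a
#' tract one allele is drawn by its frequency in the sample's population
#' and the genotype becomes homozygous for it (missing genotypes become
#' called homozygotes). This plants ground-truth runs of homozygosity for
#' detector-recovery tests.
#'
#' @param gm A [geno_matrix()].
#' @param pm A [pop_map()].
#' @param sample Sample name.
#' @param tracts A data frame with columns `scaffold`, `start`, `end`
#'   (1-based inclusive); tracts must not overlap.
#' @return The modified [geno_matrix()].
#' @export
inject_roh <- function(gm, pm, sample, tracts) {
  tracts <- tibble::as_tibble(tracts)
  if (nrow(tracts) == 0) return(gm)
  stopifnot(all(tracts$end > tracts$start))
  by_sc <- split(tracts, tracts$scaffold)
  for (tr in by_sc) {
    tr <- tr[order(tr$start), ]
    if (nrow(tr) > 1 && any(tr$start[-1] <= tr$end[-nrow(tr)])) {
      stop("tracts overlap within sample ", sample)
    }
  }
  col <- match(sample, gm$samples)
  if (is.na(col)) stop("unknown sample: ", sample)
  pop <- pm$population[match(sample, pm$sample)]
  p <- pop_freq(gm, pm, pop)
  for (i in seq_len(nrow(tracts))) {
    idx <- which(gm$sites$scaffold == tracts$scaffold[i] &
                   gm$sites$pos >= tracts$start[i] &
                   gm$sites$pos <= tracts$end[i])
    if (length(idx) == 0) next
    allele <- stats::rbinom(length(idx), 1,
                            ifelse(is.na(p[idx]), 0.5, p[idx]))
    gm$calls[idx, col] <- 2L * allele
    if (is_phased(gm)) {
      gm$haplotypes[idx, 2L * col - 1L] <- allele
      gm$haplotypes[idx, 2L * col] <- allele
    }
  }
  gm
}
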