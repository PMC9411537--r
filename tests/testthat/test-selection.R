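sweep_panel <- function(seed, n_sites = 20000, freq = 0.5,
                        copy = 5e5, mut = 0.002) {
  cfg <- sim_config(seed = seed, n_sites = n_sites,
                    layout = genome_layout(c(sA = 1e7, sB = 1e7,
                                             sC = 1e7)),
                    sample_sizes = c(CPA = 15, CPB = 15, CPC = 15,
                                     OUTGROUP = 1))
  simulate_haplotypes_with_sweep(cfg, "sB", 5e6, "CPA",
                                 derived_frequency = freq,
                                 copy_length = copy,
                                 background_mutation_rate = mut)
}

test_that("EHH follows the group-combinatorics definition", {
  # 4 carrier haplotypes splitting into groups {2,2} one marker out
  hap <- rbind(c(1L, 1L, 1L, 1L),   # core: all carry derived
               c(0L, 0L, 1L, 1L),   # split into two groups of 2
               c(0L, 1L, 0L, 1L))   # all four distinct
  calls <- hap[, c(1, 3)] + hap[, c(2, 4)]
  gm <- toy_gm(calls, pos = c(1000, 2000, 3000), haplotypes = hap,
               samples = c("S1", "S2"))
  pm <- pop_map(c(S1 = "P", S2 = "P"))
  curve <- ehh(gm, pm, "P", "s1", 1000, "derived",
               toy_layout(c(s1 = 1e6)), truncation = 0)
  dn <- curve[curve$direction == "downstream", ]
  expect_equal(dn$ehh, c(1, 2 / 6, 0))
  # monotone non-increasing outward
  expect_true(all(diff(dn$ehh) <= 0))
})

test_that("identical carrier haplotypes keep EHH at 1 across the tract", {
  sw <- sweep_panel(70, mut = 0)
  gm <- sw$genotypes; pm <- sw$populations
  curve <- ehh(gm, pm, "CPA", "sB", 5e6, "derived",
               genome_layout(c(sA = 1e7, sB = 1e7, sC = 1e7)),
               truncation = 0.05)
  inside <- curve[abs(curve$pos - 5e6) <= 2.4e5, ]
  expect_true(all(inside$ehh == 1))
  # too few carriers: warning and NULL
  cfg <- sim_config(seed = 71, n_sites = 200,
                    layout = genome_layout(c(sA = 1e6)))
  expect_error(simulate_haplotypes_with_sweep(
    cfg, "sA", 5e5, "CPA", derived_frequency = 0.01), "carriers")
})

test_that("iHS is zero for mirror-symmetric decay and flags the sweep", {
  sw <- sweep_panel(72)
  gm <- sw$genotypes; pm <- sw$populations
  layout <- genome_layout(c(sA = 1e7, sB = 1e7, sC = 1e7))
  scan <- ihs(gm, pm, "CPA", layout)
  v <- scan$sites[scan$sites$valid, ]
  core <- v[v$scaffold == "sB" & v$pos == 5e6, ]
  expect_equal(nrow(core), 1)
  expect_lt(core$std_ihs, 0)  # long derived haplotypes
  thr <- stats::quantile(abs(v$std_ihs), 0.999)
  expect_gte(abs(core$std_ihs), thr)
  # standardization contract per bin
  chk <- dplyr::summarise(dplyr::group_by(v, bin),
                          m = mean(std_ihs), s = sd(std_ihs))
  expect_true(all(abs(chk$m) < 1e-10))
  expect_true(all(abs(chk$s - 1) < 1e-10))
  # invariant under sample relabeling: swap two CPA sample names in the
  # population map only (reorders which haplotype columns come first)
  cpa <- which(pm$population == "CPA")
  pm2 <- pm; pm2$sample[cpa[1:2]] <- pm$sample[cpa[2:1]]
  scan2 <- ihs(gm, pm2, "CPA", layout)
  expect_equal(scan2$sites$std_ihs, scan$sites$std_ihs)
})

test_that("candidate selection takes the top quantile with ties", {
  sites <- tibble::tibble(
    scaffold = "s", pos = 1:1000, derived_freq = 0.5,
    ihh_a = 1, ihh_d = 1, uihs = 0,
    std_ihs = c(rep(0, 990), rep(5, 10)), valid = TRUE, bin = 1L)
  scan <- structure(list(sites = sites, population = "P"),
                    class = "ihs_scan")
  cand <- candidate_sites(scan, quantile = 0.001)
  expect_equal(sort(cand$pos), 991:1000)  # ties at the threshold included
  expect_equal(nrow(candidate_sites(scan, quantile = 1)), 1000)
  tied <- scan
  tied$sites$std_ihs <- 1
  expect_warning(ct <- candidate_sites(tied, 0.001), "tied")
  expect_equal(nrow(ct), 1000)
})

test_that("region screening runs all three methods and intersects genes", {
  sw <- sweep_panel(74)
  gm <- sw$genotypes; pm <- sw$populations
  layout <- genome_layout(c(sA = 1e7, sB = 1e7, sC = 1e7))
  scan <- ihs(gm, pm, "CPA", layout)
  cand <- candidate_sites(scan, 0.001)
  genes <- tile_genes(layout)
  scr <- screen_regions(cand, scan, layout, genes)
  expect_setequal(unique(scr$regions$method),
                  c("consecutive_snp", "sliding_window", "flanking"))
  expect_true(all(scr$regions$sihs >= 0))
  expect_true(all(scr$regions$n_candidates >= 1))
  # the sweep core's gene should survive every method
  core_gene <- genes$gene_id[genes$scaffold == "sB" &
                               genes$start <= 5e6 & genes$end >= 5e6]
  expect_true(core_gene %in% scr$genes_intersection)
  # without candidates: empty everything
  empty <- screen_regions(cand[0, ], scan, layout, genes)
  expect_equal(nrow(empty$regions), 0)
  expect_length(empty$genes_intersection, 0)
  # no gene annotation: warning, no gene sets
  expect_warning(scr2 <- screen_regions(cand, scan, layout, NULL),
                 "skipped")
  expect_length(scr2$genes_intersection, 0)
})

test_that("a flank that misses a gene excludes it from the intersection", {
  # hand-built scan: candidate at 100 kb; gene sits 8 kb away, inside the
  # consecutive-SNP and window regions but outside the 5 kb flank
  pos <- seq(1000, 2e5, by = 1000)
  n <- length(pos)
  sites <- tibble::tibble(
    scaffold = "s", pos = pos, derived_freq = 0.5, ihh_a = 1, ihh_d = 1,
    uihs = 0, std_ihs = ifelse(pos == 1e5, 6, 0.01), valid = TRUE,
    bin = 1L)
  scan <- structure(list(sites = sites, population = "P"),
                    class = "ihs_scan")
  layout <- genome_layout(c(s = 2e5))
  cand <- candidate_sites(scan, 0.001)
  expect_equal(cand$pos, 1e5)
  near <- tibble::tibble(scaffold = "s", start = 99000, end = 101000,
                         gene_id = "gene_near")
  far <- tibble::tibble(scaffold = "s", start = 108000, end = 109000,
                        gene_id = "gene_far")
  scr <- screen_regions(cand, scan, layout, rbind(near, far))
  expect_true("gene_near" %in% scr$genes_intersection)
  expect_true("gene_far" %in% scr$genes_by_method$consecutive_snp |
                "gene_far" %in% scr$genes_by_method$sliding_window)
  expect_false("gene_far" %in% scr$genes_by_method$flanking)
  expect_false("gene_far" %in% scr$genes_intersection)
})
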