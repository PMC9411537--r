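test_that("the Grantham table has the published landmarks and symmetry", {
  m <- grantham_matrix()
  expect_equal(dim(m), c(20L, 20L))
  expect_true(all(m == t(m)))
  expect_true(all(diag(m) == 0))
  off <- m[upper.tri(m)]
  expect_equal(range(off), c(5L, 215L))
  expect_equal(grantham_score("L", "I"), 5L)
  expect_equal(grantham_score("C", "W"), 215L)
  expect_equal(grantham_score("I", "L"), grantham_score("L", "I"))
  expect_equal(grantham_score("A", "A"), 0L)
  expect_error(grantham_score("B", "A"), "nonstandard")
})

test_that("the physicochemical formula reproduces the table extremes", {
  f <- grantham_from_properties()
  expect_equal(f["L", "I"], 5)
  expect_equal(f["C", "W"], 215)
  expect_equal(unname(range(f[upper.tri(f)])), c(5, 215))
  # near-total agreement with the published integers
  m <- grantham_matrix()
  expect_gte(mean(abs(f - m) <= 1), 0.99)
})

test_that("variant classification applies the LoF list and the GS >= 150
          boundary", {
  sites <- tibble::tibble(
    scaffold = "s", pos = 1:6, ref = "A", alt = "G",
    consequence = c("lof_stop_gained", "lof_splice_donor", "missense",
                    "missense", "synonymous", "none"),
    aa_ref = c(NA, NA, "W", "L", "K", NA),
    aa_alt = c(NA, NA, "G", "I", "K", NA))
  # W->G scores exactly... pick a pair at the boundary instead:
  # C->R = 180 (>=150), L->I = 5 (<150)
  sites$aa_ref[3] <- "C"; sites$aa_alt[3] <- "R"
  cls <- classify_variants(sites)
  expect_equal(cls, c("lof", "lof", "deleterious_missense",
                      "tolerated_missense", "synonymous", "other"))
  # inclusive boundary: find a pair scoring exactly 150 via the table
  m <- grantham_matrix()
  idx <- which(m == 150, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    s150 <- tibble::tibble(scaffold = "s", pos = 1, ref = "A", alt = "G",
                           consequence = "missense",
                           aa_ref = rownames(m)[idx[1, 1]],
                           aa_alt = colnames(m)[idx[1, 2]])
    expect_equal(classify_variants(s150), "deleterious_missense")
  }
  bad <- sites[3, ]; bad$aa_ref <- NA
  expect_error(classify_variants(bad), "amino-acid")
})

test_that("derived load counts equal exhaustive hand enumeration", {
  samples <- paste0("S", 1:3)
  pm <- pop_map(setNames(c("P1", "P1", "P2"), samples))
  calls <- rbind(c(2, 1, 0),
                 c(1, 0, 2),
                 c(0, 2, 1),
                 c(2, 2, 2),
                 c(1, NA, 0))
  anc <- c("ref", "alt", "ref", "unknown", "ref")
  gm <- toy_gm(calls, ancestral = anc,
               consequence = c("lof_stop_gained", "lof_splice_acceptor",
                               "missense", "lof_stop_gained", "missense"),
               aa_ref = c(NA, NA, "C", NA, "L"),
               aa_alt = c(NA, NA, "W", NA, "I"),
               samples = samples)
  ls_ <- derived_load_counts(gm, pm)
  s1 <- ls_$per_sample[ls_$per_sample$sample == "S1", ]
  # S1: site1 derived(ref-anc) = 2 hom; site2 anc=alt, call 1 -> derived 1
  # het; site4 unknown skipped
  lof1 <- s1[s1$category == "lof", ]
  expect_equal(lof1$n_sites, 2L)
  expect_equal(lof1$n_hom, 1L)
  expect_equal(lof1$n_het, 1L)
  # S2: lof sites: site1 het(1), site2 derived = 2-0 = 2 hom
  s2lof <- ls_$per_sample[ls_$per_sample$sample == "S2" &
                            ls_$per_sample$category == "lof", ]
  expect_equal(c(s2lof$n_sites, s2lof$n_hom, s2lof$n_het), c(2L, 1L, 1L))
  expect_error(derived_load_counts(toy_gm(calls, ancestral = "unknown",
                                          samples = samples), pm),
               "polarized")
})

test_that("category counts partition the derived coding total", {
  cfg <- sim_config(seed = 44, n_sites = 5000)
  p <- simulate_panel(cfg)
  ls_ <- derived_load_counts(p$genotypes, p$populations)
  ps <- ls_$per_sample
  wide <- tidyr::pivot_wider(ps[, c("sample", "category", "n_sites")],
                             names_from = "category",
                             values_from = "n_sites")
  expect_true(all(wide$lof + wide$deleterious_missense +
                    wide$tolerated_missense >= 0))
  # deleterious <= missense <= nsSNP total, per population pooled
  pp <- ls_$per_population
  for (pop in unique(pp$population)) {
    del <- pp$pooled_sites[pp$population == pop &
                             pp$category == "deleterious_missense"]
    mis <- del + pp$pooled_sites[pp$population == pop &
                                   pp$category == "tolerated_missense"]
    expect_lte(del, mis)
    expect_equal(pp$nssnp[pp$population == pop &
                            pp$category == "lof"], mis)
  }
})

test_that("zygosity ratios match the pooled brute-force enumeration", {
  samples <- paste0("S", 1:4)
  pm <- pop_map(setNames(c("P1", "P1", "P2", "P2"), samples))
  set.seed(7)
  calls <- matrix(sample(c(0:2, NA), 40, replace = TRUE,
                         prob = c(.3, .3, .3, .1)), nrow = 10)
  anc <- sample(c("ref", "alt", "unknown"), 10, replace = TRUE,
                prob = c(.45, .45, .1))
  csq <- sample(c("lof_stop_gained", "missense", "synonymous"), 10,
                replace = TRUE)
  gm <- toy_gm(calls, ancestral = anc, consequence = csq,
               aa_ref = ifelse(csq == "missense", "C", NA),
               aa_alt = ifelse(csq == "missense", "W", NA),
               samples = samples)
  ls_ <- derived_load_counts(gm, pm)
  zr <- zygosity_ratio(ls_, "lof", "all")
  expect_equal(zr$ratio,
               oracle_zygosity(calls, anc, csq == "lof_stop_gained"))
  zr_m <- zygosity_ratio(ls_, "missense", "P1")
  expect_equal(zr_m$ratio,
               oracle_zygosity(calls[, 1:2], anc, csq == "missense"))
  # degenerate: a category with no sites is NA with a warning
  gm2 <- toy_gm(calls, ancestral = anc, consequence = "synonymous",
                samples = samples)
  ls2 <- derived_load_counts(gm2, pm)
  expect_warning(z2 <- zygosity_ratio(ls2, "lof"), "undefined")
  expect_true(is.na(z2$ratio))
})

test_that("translocation predictions equal brute-force set arithmetic
          and are anti-monotone in receiver diversity", {
  samples <- paste0("S", 1:6)
  pm <- pop_map(setNames(rep(c("D", "R"), each = 3), samples))
  # donor S1 carries derived LoF at sites 1,2,3; receiver segregates
  # the derived allele only at site 2
  calls <- rbind(c(2, 0, 0, 0, 0, 0),
                 c(1, 0, 0, 0, 1, 0),
                 c(1, 1, 0, 0, 0, 0),
                 c(0, 0, 0, 2, 2, 2))
  gm <- toy_gm(calls, ancestral = "ref",
               consequence = "lof_stop_gained", samples = samples)
  tp <- predict_translocation_lof(gm, pm, "D", "R")
  expect_equal(tp$per_donor$introduced_lof[1], 2L)
  expect_equal(tp$per_donor$introduced_lof,
               unname(oracle_translocation(calls, rep("ref", 4),
                                           rep(TRUE, 4), 1:3, 4:6)))
  expect_lte(tp$min, tp$mean)
  expect_lte(tp$mean, tp$max)
  # direction matters
  rev <- predict_translocation_lof(gm, pm, "R", "D")
  expect_false(identical(tp$per_donor$introduced_lof,
                         rev$per_donor$introduced_lof))
  expect_error(predict_translocation_lof(gm, pm, "D", "D"), "differ")
  # adding a derived carrier to the receiver never increases counts
  calls2 <- calls; calls2[1, 5] <- 1
  gm2 <- toy_gm(calls2, ancestral = "ref",
                consequence = "lof_stop_gained", samples = samples)
  tp2 <- predict_translocation_lof(gm2, pm, "D", "R")
  expect_true(all(tp2$per_donor$introduced_lof <=
                    tp$per_donor$introduced_lof))
})
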