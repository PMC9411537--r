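test_that("complete fixation gives FST = 1 and the estimator is symmetric", {
  samples <- paste0("S", 1:20)
  pm <- pop_map(setNames(rep(c("PA", "PB"), each = 10), samples))
  calls <- cbind(matrix(0L, 100, 10), matrix(2L, 100, 10))
  gm <- toy_gm(calls, pos = (1:100) * 100, samples = samples)
  f <- wc_fst(gm, pm, "PA", "PB")
  expect_equal(f$estimate, 1)
  expect_equal(wc_fst(gm, pm, "PB", "PA")$estimate, f$estimate)
})

test_that("a random split of one panel gives FST near zero", {
  set.seed(12)
  n <- 10000
  p <- runif(n, 0.05, 0.95)
  calls <- matrix(rbinom(n * 40, 2, rep(p, 40)), nrow = n)
  samples <- paste0("S", 1:40)
  pm <- pop_map(setNames(sample(rep(c("PA", "PB"), each = 20)), samples))
  gm <- toy_gm(calls, pos = 1:n * 10, samples = samples)
  expect_lt(abs(wc_fst(gm, pm, "PA", "PB")$estimate), 0.01)
})

test_that("per-site components match the brute-force 1984 oracle", {
  # fixed genotype table, incl. missing data and unequal sample sizes
  callsA <- rbind(c(0, 1, 2, 1, NA), c(1, 1, 0, 0, 0), c(2, 2, 2, 1, 1))
  callsB <- rbind(c(2, 2, 1, NA, NA), c(0, 1, 1, 2, 0), c(0, 0, 1, 0, 2))
  samples <- paste0("S", 1:10)
  pm <- pop_map(setNames(rep(c("PA", "PB"), each = 5), samples))
  gm <- toy_gm(cbind(callsA, callsB), samples = samples)
  f <- wc_fst(gm, pm, "PA", "PB")
  for (i in 1:3) {
    abc <- oracle_wc_site(callsA[i, ], callsB[i, ])
    expect_equal(f$by_site$a[i], unname(abc["a"]))
    expect_equal(f$by_site$b[i], unname(abc["b"]))
    expect_equal(f$by_site$c[i], unname(abc["c"]))
  }
  expect_equal(f$estimate, oracle_wc_fst(callsA, callsB))
})

test_that("blocks tile scaffolds with the last partial block kept", {
  expect_equal(nrow(make_blocks(genome_layout(c(s = 10e6)), 5e6)), 2)
  b <- make_blocks(genome_layout(c(s = 11e6)), 5e6)
  expect_equal(nrow(b), 3)
  expect_equal(b$end[3] - b$start[3] + 1, 1e6)
  # boundary site joins the later block (half-open convention)
  layout <- genome_layout(c(s = 10e6))
  expect_equal(assign_blocks("s", 5e6 + 1, layout, 5e6), 2L)
  expect_equal(assign_blocks("s", 5e6, layout, 5e6), 1L)
})

test_that("D is zero under symmetry, sign-flips, and matches the oracle", {
  set.seed(3)
  samples <- paste0("S", 1:12)
  pm <- pop_map(setNames(rep(c("PA", "PB", "PX"), each = 4), samples))
  layout <- toy_layout(c(s1 = 1e6))
  # pA = pB at every site: identical genotype blocks
  block <- matrix(rbinom(40, 2, 0.4), nrow = 10)
  gmAB <- toy_gm(cbind(block, block, matrix(rbinom(40, 2, 0.6), 10)),
                 pos = 1:10 * 1000, samples = samples)
  expect_warning(
    d0 <- d_statistic(gmAB, pm, "PA", "PB", "PX", layout,
                      block_length = 2000),
    "degenerate")  # constant per-block D: SE = 0, Z reported as infinite
  expect_equal(d0$D, 0)
  expect_true(is.infinite(d0$jackknife$Z) | is.nan(d0$jackknife$Z))

  calls <- matrix(sample(0:2, 120, replace = TRUE), nrow = 10)
  gm <- toy_gm(calls, pos = 1:10 * 1000, samples = samples,
               ancestral = sample(c("ref", "alt", "unknown"), 10,
                                  replace = TRUE))
  d1 <- d_statistic(gm, pm, "PA", "PB", "PX", layout, block_length = 2000)
  d2 <- d_statistic(gm, pm, "PB", "PA", "PX", layout, block_length = 2000)
  expect_equal(d1$D, -d2$D)
  expect_equal(d1$D, oracle_d_stat(calls[, 1:4], calls[, 5:8],
                                   calls[, 9:12], gm$sites$ancestral))
})

test_that("directional introgression yields a significant positive D", {
  cfg <- sim_config(seed = 55, n_sites = 10000,
                    admixture = list(donor = "CPC", receiver = "CPB",
                                     f = 0.3))
  p <- simulate_panel(cfg)
  d <- d_statistic(p$genotypes, p$populations, "CPA", "CPB", "CPC",
                   cfg$layout)
  expect_gt(d$D, 0)
  expect_true(d$significant)
})

test_that("the jackknife reduces to delete-one with equal weights and\n          flags degenerate variance", {
  theta_j <- c(0.1, 0.2, 0.15, 0.05)
  theta <- mean(theta_j)
  jk <- weighted_jackknife(theta, theta_j, rep(10, 4))
  g <- 4
  expect_equal(jk$standard_error,
               sqrt((g - 1) / g * sum((theta_j - mean(theta_j))^2)))
  expect_warning(jkc <- weighted_jackknife(0.5, rep(0.5, 5), rep(1, 5)),
                 "degenerate")
  expect_true(is.infinite(jkc$Z))
})

test_that("F3 is source-symmetric, matches the oracle, and detects an
          admixed target", {
  set.seed(9)
  samples <- paste0("S", 1:9)
  pm <- pop_map(setNames(rep(c("PX", "PA", "PB"), each = 3), samples))
  layout <- toy_layout(c(s1 = 1e6))
  calls <- matrix(sample(0:2, 90, replace = TRUE), nrow = 10)
  gm <- toy_gm(calls, pos = 1:10 * 1000, samples = samples)
  r1 <- f3(gm, pm, "PX", "PA", "PB", layout, block_length = 2000)
  r2 <- f3(gm, pm, "PX", "PB", "PA", layout, block_length = 2000)
  expect_equal(r1$F3, r2$F3)
  expect_equal(r1$F3, oracle_f3(calls[, 1:3], calls[, 4:6], calls[, 7:9],
                                gm$sites$ancestral))

  # target built as a 50/50 mixture of two strongly diverged sources
  set.seed(10)
  n <- 8000
  pA <- rbeta(n, 0.2, 0.2)
  pB <- rbeta(n, 0.2, 0.2)
  pX <- 0.5 * pA + 0.5 * pB
  big_samples <- paste0("T", 1:30)
  pmb <- pop_map(setNames(rep(c("PA", "PB", "PX"), each = 10),
                          big_samples))
  mk <- function(p, k) matrix(rbinom(n * k, 2, rep(p, k)), nrow = n)
  gmb <- toy_gm(cbind(mk(pA, 10), mk(pB, 10), mk(pX, 10)),
                pos = 1:n * 100, samples = big_samples,
                scaffold = "s1")
  lay <- toy_layout(c(s1 = 1e6))
  rx <- f3(gmb, pmb, "PX", "PA", "PB", lay, block_length = 5e4)
  expect_lt(rx$F3, 0)
  expect_lt(rx$jackknife$Z, -3)
  expect_true(rx$admixed)
})
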