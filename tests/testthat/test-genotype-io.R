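test_that("read_vcf decodes genotypes, skips non-biallelic SNPs, keeps phase", {
  path <- write_test_vcf(c(
    vcf_header(c("s1", "s2")),
    vcf_line("chr1", 100, "A", "G", c("0/0", "0/1")),
    vcf_line("chr1", 200, "A", "G,T", c("0/0", "0/1")),   # multi-allelic
    vcf_line("chr1", 300, "AT", "A", c("0/0", "1/1")),    # indel
    vcf_line("chr1", 400, "C", "T", c("0|1", "1|0")),
    vcf_line("chr1", 500, "G", "A", c("./.", "1/1"))))
  expect_message(gm <- read_vcf(path), "skipped 2")
  expect_equal(attr(gm, "skipped"), 2)
  expect_equal(dim(gm), c(3L, 2L))
  expect_equal(unname(gm$calls[1, ]), c(0L, 1L))
  expect_true(is.na(gm$calls[3, 1]) && gm$calls[3, 2] == 2L)
  # phase at the phased site: alleles (0,1) and (1,0)
  expect_equal(unname(gm$haplotypes[2, ]), c(0L, 1L, 1L, 0L))
})

test_that("VCF round-trip preserves sites, genotypes, phase and annotation", {
  cfg <- sim_config(seed = 21, n_sites = 200,
                    layout = genome_layout(c(sA = 2e5, sB = 2e5)))
  gm <- simulate_panel(cfg)$genotypes
  path <- tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  gm2 <- read_vcf(path)
  expect_equal(gm2$sites$scaffold, gm$sites$scaffold)
  expect_equal(gm2$sites$pos, gm$sites$pos)
  expect_equal(gm2$sites$ancestral, gm$sites$ancestral)
  expect_equal(gm2$sites$consequence, gm$sites$consequence)
  expect_equal(gm2$sites$aa_ref, gm$sites$aa_ref)
  expect_equal(gm2$sites$gene_id, gm$sites$gene_id)
  expect_equal(unname(gm2$calls), unname(gm$calls))

  sw <- simulate_haplotypes_with_sweep(
    cfg, "sA", 1e5, "CPA", derived_frequency = 0.5, copy_length = 5e4)
  path2 <- tempfile(fileext = ".vcf")
  write_vcf(sw$genotypes, path2)
  back <- read_vcf(path2)
  expect_equal(unname(back$haplotypes), unname(sw$genotypes$haplotypes))
})

test_that("polarization follows the outgroup and is involution-safe", {
  pm <- pop_map(c(S1 = "CPA", S2 = "CPA", S3 = "OUTGROUP"))
  gm <- toy_gm(rbind(c(0, 1, 0),    # outgroup hom ref -> ancestral ref
                     c(2, 1, 2),    # outgroup hom alt -> ancestral alt
                     c(1, 0, 1),    # outgroup het -> unknown
                     c(0, 2, NA)),  # outgroup missing -> unknown
               ancestral = "unknown")
  g1 <- polarize_by_outgroup(gm, pm)
  expect_equal(g1$sites$ancestral, c("ref", "alt", "unknown", "unknown"))
  g2 <- polarize_by_outgroup(g1, pm)
  expect_identical(g2$sites$ancestral, g1$sites$ancestral)
  expect_error(polarize_by_outgroup(gm, pop_map(c(S1 = "CPA", S2 = "CPA",
                                                  S3 = "CPA"))),
               "OUTGROUP")
})

test_that("site filters apply the scaffold floor and strict MAF rule", {
  # scaffold s_small = 90 kb, s_big = 1 Mb
  layout <- genome_layout(c(s_big = 1e6, s_small = 9e4))
  pm <- pop_map(c(S1 = "P1", S2 = "P1", S3 = "P1", S4 = "P1", S5 = "P1"))
  # MAF with 5 diploids (10 alleles): counts 0..5 give 0, .1, .2, ...
  calls <- rbind(
    c(1, 0, 0, 0, 0),   # MAF 0.1  > 0.05 -> kept at 0.05
    c(0, 0, 0, 0, 0),   # monomorphic
    c(1, 1, 1, 1, 1),   # MAF 0.5
    c(2, 2, 1, 1, 2))   # alt freq 0.8 -> MAF 0.2, NOT > 0.2
  gm <- toy_gm(calls, pos = c(1e4, 2e4, 3e4, 4e4), scaffold = "s_big")
  small <- toy_gm(matrix(c(1, 1, 1, 1, 1), 1), pos = 5e4,
                  scaffold = "s_small")
  both <- geno_matrix(dplyr::bind_rows(gm$sites, small$sites),
                      rbind(gm$calls, small$calls), gm$samples)

  f0 <- filter_sites(both, pm, layout, 0)
  expect_equal(f0$sites$scaffold, rep("s_big", 4))  # scaffold filter only
  f5 <- filter_sites(both, pm, layout, 0.05)
  expect_equal(f5$sites$pos, c(1e4, 3e4, 4e4))      # monomorphic dropped
  f20 <- filter_sites(both, pm, layout, 0.20)
  expect_equal(f20$sites$pos, 3e4)                  # strict 'larger than'
  # filters commute and output is a subset of input
  expect_true(all(f20$sites$pos %in% f5$sites$pos))
  expect_error(filter_sites(toy_gm(matrix(0, 1, 1), scaffold = "nope"),
                            pm, layout), "absent")
})

test_that("allele frequencies and the MAF spectrum count correctly", {
  pm <- pop_map(c(S1 = "P1", S2 = "P1", S3 = "P1"))
  gm <- toy_gm(rbind(c(0, 1, 2),
                     c(NA, NA, NA),
                     c(2, 2, NA)))
  af <- allele_frequencies(gm, pm)
  expect_equal(af$alt_freq, c(0.5, NA, 1))
  expect_equal(af$called_n, c(6L, 0L, 4L))

  # 10 polymorphic SNPs, 4 with MAF < 0.05
  n_samp <- 50
  calls <- rbind(
    matrix(rep(c(1, rep(0, n_samp - 1)), 4), nrow = 4, byrow = TRUE),
    matrix(rep(c(rep(1, 30), rep(0, n_samp - 30)), 6), nrow = 6,
           byrow = TRUE),
    matrix(0, nrow = 3, ncol = n_samp))  # monomorphic: excluded
  gm2 <- toy_gm(calls, samples = paste0("x", 1:n_samp))
  pm2 <- pop_map(setNames(rep("P1", n_samp), paste0("x", 1:n_samp)))
  sp <- maf_spectrum(gm2, pm2, bin_edges = c(0, 0.05, 0.5))
  expect_equal(sum(sp$n_snps), 10)
  expect_equal(sp$proportion[1], 0.4)
  expect_equal(sum(sp$proportion), 1)
  expect_error(maf_spectrum(gm2, pm2, bin_edges = c(0, 0.5, 0.05)),
               "increasing")
})

test_that("bundled example files load through the standard readers", {
  vcf <- system.file("extdata", "example_panel.vcf", package = "pangopop")
  map <- system.file("extdata", "example_popmap.tsv",
                     package = "pangopop")
  lay <- system.file("extdata", "example_layout.tsv",
                     package = "pangopop")
  bed <- system.file("extdata", "example_genes.bed",
                     package = "pangopop")
  layout <- read_layout_tsv(lay)
  gm <- read_vcf(vcf, layout)
  pm <- read_pop_map(map)
  expect_equal(length(gm$samples), nrow(pm))
  expect_true(all(gm$sites$ancestral %in% c("ref", "alt", "unknown")))
  genes <- read_features(bed)
  expect_equal(names(genes), c("scaffold", "start", "end", "gene_id"))
  expect_equal(min(genes$start), 1)  # BED 0-based start converted
  # polarization from file agrees with the stored ancestral annotation
  repol <- polarize_by_outgroup(gm, pm)
  known <- repol$sites$ancestral != "unknown"  # outgroup called there
  expect_gt(sum(known), 0)
  expect_equal(repol$sites$ancestral[known], gm$sites$ancestral[known])
})
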