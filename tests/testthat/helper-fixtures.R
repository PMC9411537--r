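# small hand-built genotype matrices and plain-text file fixtures

toy_gm <- function(calls, pos = NULL, scaffold = "s1",
                   ancestral = "ref", consequence = "none",
                   aa_ref = NA_character_, aa_alt = NA_character_,
                   gene_id = NA_character_, samples = NULL,
                   haplotypes = NULL) {
  calls <- as.matrix(calls)
  n <- nrow(calls)
  if (is.null(pos)) pos <- seq_len(n) * 1000
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(calls)))
  sites <- tibble::tibble(
    scaffold = rep_len(scaffold, n), pos = pos,
    ref = "A", alt = "G",
    ancestral = rep_len(ancestral, n),
    consequence = rep_len(consequence, n),
    aa_ref = rep_len(aa_ref, n), aa_alt = rep_len(aa_alt, n),
    gene_id = rep_len(gene_id, n))
  geno_matrix(sites, calls, samples, haplotypes)
}

toy_layout <- function(lengths = c(s1 = 1e6), map_rate = 1) {
  genome_layout(lengths, map_rate)
}

write_test_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

vcf_header <- function(samples) {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"))
}

vcf_line <- function(chrom, pos, ref, alt, gts, info = ".") {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", info, "GT", gts),
        collapse = "\t")
}
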