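#' Read a multi-sample VCF into a genotype matrix
#'
#' Loads biallelic SNP records from a VCF v4.x file. Unphased genotypes
#' `0/0`, `0/1` (or `1/0`) and `1/1` become alt-allele dosages 0, 1 and 2;
#' `./.` becomes missing. Phased genotypes (`0|1`) additionally populate the
#' haplotype matrix. Multi-allelic records and indels are skipped and the
#' skip count is reported via a message and stored in the result.
#'
#' If the INFO field carries `AA` (ancestral allele) or `CSQCLASS`
#' (consequence class, as written by [write_vcf()]), these populate the site
#' metadata, so a polarized and annotated matrix round-trips through disk.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param layout Optional [genome_layout()]; if supplied, records on
#'   scaffolds absent from the layout raise an error.
#'
#' @return A [geno_matrix()]. The number of skipped non-biallelic-SNP
#'   records is available as `attr(x, "skipped")`.
#' @export
read_vcf <- function(path, layout = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF contains no records")
  fmt <- v@gt[, 1]
  if (!all(vapply(strsplit(fmt, ":"), function(f) "GT" %in% f, logical(1)))) {
    stop("VCF records lack a GT format field")
  }
  nt <- c("A", "C", "G", "T")
  keep <- fix$REF %in% nt & fix$ALT %in% nt
  skipped <- sum(!keep)
  if (skipped > 0) {
    message(sprintf("read_vcf: skipped %d non-biallelic-SNP record(s)",
                    skipped))
  }
  v <- v[keep, ]
  fix <- fix[keep, , drop = FALSE]
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  gt[gt == "."] <- NA_character_

  shape <- function(x) matrix(x, nrow = nrow(gt), ncol = ncol(gt))
  allele1 <- shape(suppressWarnings(as.integer(substr(gt, 1, 1))))
  allele2 <- shape(suppressWarnings(as.integer(substr(gt, 3, 3))))
  calls <- allele1 + allele2
  phased <- shape(!is.na(gt) & substr(gt, 2, 2) == "|")

  haplotypes <- NULL
  if (any(phased)) {
    n <- length(samples)
    haplotypes <- matrix(NA_integer_, nrow = nrow(gt), ncol = 2L * n)
    haplotypes[, seq(1, 2 * n, 2)] <- ifelse(phased, allele1, NA_integer_)
    haplotypes[, seq(2, 2 * n, 2)] <- ifelse(phased, allele2, NA_integer_)
  }

  info <- fix$INFO
  anc <- rep("unknown", nrow(fix))
  csq <- rep("none", nrow(fix))
  if (!is.null(info) && !all(is.na(info))) {
    aa <- stringr::str_match(info, "(?:^|;)AA=([ACGT])")[, 2]
    anc <- dplyr::case_when(aa == fix$REF ~ "ref",
                            aa == fix$ALT ~ "alt",
                            TRUE ~ "unknown")
    cs <- stringr::str_match(info, "(?:^|;)CSQCLASS=([A-Za-z_]+)")[, 2]
    csq <- ifelse(is.na(cs), "none", cs)
  }
  aach <- stringr::str_match(ifelse(is.na(info), "", info),
                             "(?:^|;)AACHANGE=([A-Z])/([A-Z])")
  gene <- stringr::str_match(ifelse(is.na(info), "", info),
                             "(?:^|;)GENE=([^;]+)")[, 2]

  sites <- tibble::tibble(
    scaffold = fix$CHROM,
    pos = as.numeric(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    ancestral = anc,
    consequence = csq,
    aa_ref = aach[, 2],
    aa_alt = aach[, 3],
    gene_id = gene
  )
  if (!is.null(layout)) scaffold_length(layout, unique(sites$scaffold))
  gm <- geno_matrix(sites, calls, samples, haplotypes)
  attr(gm, "skipped") <- skipped
  gm
}

#' Write a genotype matrix to VCF v4.2
#'
#' Emits the ancestral state as the conventional `AA` INFO key and the
#' consequence class, amino-acid change and gene as `CSQCLASS`, `AACHANGE`
#' and `GENE`, so a matrix annotated in R round-trips losslessly through
#' [read_vcf()]. Phased haplotypes are written with `|` separators.
#'
#' @param gm A [geno_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  s <- gm$sites
  info <- rep(".", nrow(s))
  parts <- cbind(
    ifelse(s$ancestral == "ref", paste0("AA=", s$ref),
           ifelse(s$ancestral == "alt", paste0("AA=", s$alt), NA)),
    ifelse(s$consequence == "none", NA, paste0("CSQCLASS=", s$consequence)),
    ifelse(is.na(s$aa_ref), NA, paste0("AACHANGE=", s$aa_ref, "/", s$aa_alt)),
    ifelse(is.na(s$gene_id), NA, paste0("GENE=", s$gene_id))
  )
  info <- apply(parts, 1, function(p) {
    p <- p[!is.na(p)]
    if (length(p) == 0) "." else paste(p, collapse = ";")
  })

  if (is_phased(gm)) {
    h1 <- gm$haplotypes[, seq(1, ncol(gm$haplotypes), 2), drop = FALSE]
    h2 <- gm$haplotypes[, seq(2, ncol(gm$haplotypes), 2), drop = FALSE]
    gtxt <- matrix(paste0(h1, "|", h2), nrow = nrow(h1))
    unph <- is.na(h1) | is.na(h2)
    gtxt[unph] <- c("0/0", "0/1", "1/1")[gm$calls[unph] + 1L]
    gtxt[unph & is.na(gm$calls)] <- "./."
  } else {
    gtxt <- matrix(c("0/0", "0/1", "1/1")[gm$calls + 1L],
                   nrow = nrow(gm$calls))
    gtxt[is.na(gm$calls)] <- "./."
  }

  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=Character,Description=\"Ancestral allele\">",
    paste0("##INFO=<ID=CSQCLASS,Number=1,Type=String,",
           "Description=\"Consequence class\">"),
    paste0("##INFO=<ID=AACHANGE,Number=1,Type=String,",
           "Description=\"Amino acid change ref/alt\">"),
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene id\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  )
  body <- paste(s$scaffold, format(s$pos, scientific = FALSE, trim = TRUE),
                ".", s$ref, s$alt, ".", "PASS", info, "GT",
                apply(gtxt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read gene features from BED or GFF3
#'
#' Accepts a BED (3+ columns, 0-based half-open, optional name in column 4)
#' or GFF3 file (1-based inclusive; the gene id is taken from the `ID=` or
#' `gene_id=` attribute). Coordinates are returned 1-based inclusive.
#'
#' @param path Path to a `.bed`, `.gff`, `.gff3` file.
#' @return A tibble with columns `scaffold`, `start`, `end`, `gene_id`.
#' @export
read_features <- function(path) {
  if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) {
    tab <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                           col_types = readr::cols())
    tibble::tibble(
      scaffold = as.character(tab[[1]]),
      start = as.numeric(tab[[2]]) + 1,  # BED is 0-based half-open
      end = as.numeric(tab[[3]]),
      gene_id = if (ncol(tab) >= 4) as.character(tab[[4]]) else
        paste0("feature", seq_len(nrow(tab)))
    )
  } else {
    tab <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                           col_types = readr::cols())
    id <- stringr::str_match(as.character(tab[[9]]),
                             "(?:^|;)(?:ID|gene_id)=([^;]+)")[, 2]
    tibble::tibble(
      scaffold = as.character(tab[[1]]),
      start = as.numeric(tab[[4]]),
      end = as.numeric(tab[[5]]),
      gene_id = ifelse(is.na(id), paste0("feature", seq_len(nrow(tab))), id)
    )
  }
}
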