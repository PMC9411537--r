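#' Genome layout
#'
#' A lightweight description of the assembly the variants live on: scaffold
#' names and lengths plus the recombination-map constant used to convert
#' physical to genetic distance. The default map rate of 1 cM/Mb is the flat
#' map commonly assumed for non-model mammals without a linkage map.
#'
#' @param scaffolds A data frame with columns `name` and `length` (bp), or a
#'   named numeric vector of scaffold lengths.
#' @param map_rate Genetic map rate in cM per Mb. Default 1.
#'
#' @return An object of class `genome_layout`: a list with elements
#'   `scaffolds` (tibble with `name`, `length`), `total_length` (bp) and
#'   `map_rate` (cM/Mb).
#' @export
#' @examples
#' genome_layout(c(scf1 = 1e7, scf2 = 5e6))
genome_layout <- function(scaffolds, map_rate = 1) {
  if (is.numeric(scaffolds)) {
    stopifnot(!is.null(names(scaffolds)))
    scaffolds <- tibble::tibble(name = names(scaffolds),
                                length = unname(scaffolds))
  }
  scaffolds <- tibble::as_tibble(scaffolds)[, c("name", "length")]
  if (anyDuplicated(scaffolds$name)) stop("scaffold names must be unique")
  if (any(scaffolds$length <= 0)) stop("scaffold lengths must be positive")
  if (!is.numeric(map_rate) || map_rate <= 0) stop("map_rate must be > 0")
  structure(
    list(scaffolds = scaffolds,
         total_length = sum(scaffolds$length),
         map_rate = map_rate),
    class = "genome_layout"
  )
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("<genome_layout> %d scaffolds, %.3f Mb total, %g cM/Mb\n",
              nrow(x$scaffolds), x$total_length / 1e6, x$map_rate))
  invisible(x)
}

scaffold_length <- function(layout, scaffold) {
  i <- match(scaffold, layout$scaffolds$name)
  if (anyNA(i)) {
    stop("scaffold(s) absent from layout: ",
         paste(unique(scaffold[is.na(i)]), collapse = ", "))
  }
  layout$scaffolds$length[i]
}

#' Read a scaffold layout from a TSV file
#'
#' Expects two columns, `name` and `length_bp`, with a header line.
#'
#' @param path Path to the TSV file.
#' @inheritParams genome_layout
#' @return A `genome_layout`.
#' @export
read_layout_tsv <- function(path, map_rate = 1) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    name = readr::col_character(), length_bp = readr::col_double()))
  genome_layout(tibble::tibble(name = tab$name, length = tab$length_bp),
                map_rate = map_rate)
}

#' Tile a genome into contiguous blocks
#'
#' Blocks are the resampling unit of the block jackknife used for D and F3
#' standard errors. Each scaffold is tiled left to right; the last, possibly
#' partial block is kept. Block boundaries follow the half-open convention:
#' a site at a boundary position belongs to the later block.
#'
#' @param layout A [genome_layout()].
#' @param block_length Block length in bp.
#'
#' @return A tibble with columns `block` (integer id), `scaffold`, `start`,
#'   `end` (1-based inclusive bp).
#' @export
#' @examples
#' make_blocks(genome_layout(c(s = 11e6)), 5e6)
make_blocks <- function(layout, block_length) {
  stopifnot(block_length > 0)
  res <- purrr::pmap_dfr(layout$scaffolds, function(name, length) {
    starts <- seq(1, length, by = block_length)
    tibble::tibble(scaffold = name, start = starts,
                   end = pmin(starts + block_length - 1, length))
  })
  dplyr::mutate(res, block = dplyr::row_number(), .before = 1)
}

# Map sites to block ids; every site maps to exactly one block.
assign_blocks <- function(scaffold, position, layout, block_length) {
  blocks <- make_blocks(layout, block_length)
  first_block <- blocks$block[!duplicated(blocks$scaffold)]
  names(first_block) <- blocks$scaffold[!duplicated(blocks$scaffold)]
  fb <- first_block[scaffold]
  if (anyNA(fb)) stop("site scaffold absent from layout")
  as.integer(fb + (position - 1) %/% block_length)
}
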