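#' Build a genetic-code object
#'
#' Wraps an NCBI translation table as used throughout the package: codon to
#' amino-acid map, synonymous families, and the sense-codon inventory.
#' The default is table 5 (invertebrate mitochondrial), under which all
#' analyses in this package are performed unless stated otherwise. Table 5
#' has 62 sense codons: AGA/AGG code for Ser (an 8-fold Ser family), TGA for
#' Trp and ATA for Met, leaving TAA and TAG as the only stops.
#'
#' @param table_id NCBI translation table identifier (integer or string),
#'   passed to [Biostrings::getGeneticCode()]. Default `5`.
#' @return An object of class `genetic_code`: a list with `table_id`,
#'   `codon_to_aa` (named character over 64 codons), `families` (list
#'   amino-acid -> synonymous codon set, stops excluded), `sense_codons`,
#'   `sense_codon_count`, and `stop_codons`.
#' @examples
#' code <- genetic_code(5)
#' code$sense_codon_count  # 62
#' @export
genetic_code <- function(table_id = 5) {
  tab <- Biostrings::getGeneticCode(as.character(table_id))
  stops <- names(tab)[tab == "*"]
  sense <- names(tab)[tab != "*"]
  fams <- split(sense, tab[sense])
  structure(
    list(
      table_id = as.integer(table_id),
      codon_to_aa = tab,
      families = fams,
      sense_codons = sense,
      sense_codon_count = length(sense),
      stop_codons = stops
    ),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat(sprintf(
    "<genetic_code> table %d: %d sense codons, %d amino-acid families, stops: %s\n",
    x$table_id, x$sense_codon_count, length(x$families),
    paste(x$stop_codons, collapse = ", ")
  ))
  invisible(x)
}

is_stop_codon <- function(codon, code) codon %in% code$stop_codons

# family size keyed by codon, as a named integer vector
codon_family_size <- function(code) {
  sizes <- lengths(code$families)
  aa <- code$codon_to_aa[code$sense_codons]
  stats::setNames(as.integer(sizes[aa]), code$sense_codons)
}
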