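# Nucleotide composition and strand asymmetry.
#
# Skews follow the standard definitions AT-skew = (A - T)/(A + T) and
# GC-skew = (G - C)/(G + C), computed on the deposited J strand for whole
# genomes. Ambiguity codes are excluded from every numerator and denominator.

#' Summarize nucleotide composition and strand skews
#'
#' @param seq Nonempty nucleotide string (case-insensitive; U treated as T).
#' @return A list of class `composition_summary`: counts `a`, `c`, `g`, `t`,
#'   `n_ambiguous`, percentages `at_content` and `gc_content`, and `at_skew`,
#'   `gc_skew` (each `NA` when its denominator is zero -- an undefined skew is
#'   reported explicitly, never as 0).
#' @examples
#' summarize_composition("AAAT")$at_skew  # 0.5
#' @export
summarize_composition <- function(seq) {
  if (length(seq) != 1 || is.na(seq) || nchar(seq) == 0)
    stop("empty sequence")
  s <- gsub("U", "T", toupper(seq), fixed = TRUE)
  counts <- base_counts(s)
  a <- counts[["A"]]; cc <- counts[["C"]]; g <- counts[["G"]]; t <- counts[["T"]]
  acgt <- a + cc + g + t
  structure(list(
    a = a, c = cc, g = g, t = t,
    n_ambiguous = nchar(s) - acgt,
    at_content = if (acgt > 0) 100 * (a + t) / acgt else NA_real_,
    gc_content = if (acgt > 0) 100 * (g + cc) / acgt else NA_real_,
    at_skew = if (a + t > 0) (a - t) / (a + t) else NA_real_,
    gc_skew = if (g + cc > 0) (g - cc) / (g + cc) else NA_real_
  ), class = "composition_summary")
}

base_counts <- function(s) {
  chars <- strsplit(s, "")[[1]]
  vapply(c("A", "C", "G", "T"), function(b) sum(chars == b), integer(1))
}

#' Per-codon-position A+T and G+C composition
#'
#' Computed over complete codons of an in-frame coding sequence (frame 0;
#' a trailing partial codon is ignored). `gc12` is the mean of the G+C
#' percentages at positions 1 and 2, as used on the ordinate of neutrality
#' plots.
#'
#' @param cds In-frame nucleotide string of length >= 3.
#' @return List of class `positional_composition`: `at1`, `at2`, `at3`,
#'   `gc1`, `gc2`, `gc3`, `gc12` (percent), `n_codons`.
#' @export
positional_composition <- function(cds) {
  s <- gsub("U", "T", toupper(cds), fixed = TRUE)
  n <- nchar(s)
  if (n < 3) stop("need at least one complete codon")
  ncod <- n %/% 3L
  chars <- strsplit(substr(s, 1L, 3L * ncod), "")[[1]]
  pos <- rep(1:3, ncod)
  pc <- function(p, bases) {
    at_pos <- chars[pos == p]
    denom <- sum(at_pos %in% c("A", "C", "G", "T"))
    if (denom == 0) return(NA_real_)
    100 * sum(at_pos %in% bases) / denom
  }
  at <- vapply(1:3, pc, numeric(1), bases = c("A", "T"))
  gc <- vapply(1:3, pc, numeric(1), bases = c("G", "C"))
  structure(list(at1 = at[1], at2 = at[2], at3 = at[3],
                 gc1 = gc[1], gc2 = gc[2], gc3 = gc[3],
                 gc12 = mean(gc[1:2]), n_codons = ncod),
            class = "positional_composition")
}

#' Composition table for a set of records
#'
#' One row per record with the whole-genome (J-strand) composition summary,
#' suitable for TSV export.
#'
#' @param records List of [mito_record()] objects.
#' @return `data.frame` with columns `accession`, `length_bp`, `a_pct`,
#'   `c_pct`, `g_pct`, `t_pct`, `at_content`, `at_skew`, `gc_skew`.
#' @export
composition_table <- function(records) {
  rows <- lapply(records, function(r) {
    cs <- summarize_composition(r$sequence)
    acgt <- cs$a + cs$c + cs$g + cs$t
    data.frame(accession = r$accession, length_bp = r$length_bp,
               a_pct = 100 * cs$a / acgt, c_pct = 100 * cs$c / acgt,
               g_pct = 100 * cs$g / acgt, t_pct = 100 * cs$t / acgt,
               at_content = cs$at_content, at_skew = cs$at_skew,
               gc_skew = cs$gc_skew, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
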