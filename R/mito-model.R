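#' @useDynLib mitoclover, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Canonical 37-gene vocabulary ------------------------------------------------

PCG_NAMES <- c("atp6", "atp8", "cob", "cox1", "cox2", "cox3",
               "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6")
RRNA_NAMES <- c("rrnL", "rrnS")
TRNA_NAMES <- c("trnA", "trnR", "trnN", "trnD", "trnC", "trnE", "trnQ",
                "trnG", "trnH", "trnI", "trnL1", "trnL2", "trnK", "trnM",
                "trnF", "trnP", "trnS1", "trnS2", "trnT", "trnW", "trnY",
                "trnV")
GENE_VOCABULARY <- c(PCG_NAMES, RRNA_NAMES, TRNA_NAMES, "control_region")

role_of_name <- function(name) {
  ifelse(name %in% PCG_NAMES, "PCG",
  ifelse(name %in% RRNA_NAMES, "rRNA",
  ifelse(name %in% TRNA_NAMES, "tRNA",
  ifelse(name == "control_region", "control_region", NA_character_))))
}

IUPAC_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

# Record constructor ----------------------------------------------------------

#' Construct an annotated mitogenome record
#'
#' The unit of all analyses: one circular annotated mitochondrial genome in
#' its deposited (J-strand) orientation, with an ordered feature table.
#'
#' Feature coordinates are 0-based half-open on the stored strand. A feature
#' may cross the origin of the circular molecule; such a feature has
#' `wrap = TRUE` and its span runs from `start` to the sequence end and
#' continues from position 0 to `end`.
#'
#' @param accession Identifier string.
#' @param organism Free-text organism name.
#' @param sequence Nucleotide string over the IUPAC alphabet (case
#'   insensitive; stored upper-case, U converted to T).
#' @param features `data.frame` with columns `name` (canonical token from the
#'   37-gene vocabulary plus `control_region`), `start`, `end` (0-based
#'   half-open), `wrap` (logical), `strand` (`"J"` or `"N"`), `anticodon`
#'   (3-mer for tRNAs, `NA` otherwise).
#' @param circular Logical flag; mitogenomes are circular.
#' @return An object of class `mito_record`.
#' @export
mito_record <- function(accession, organism, sequence, features,
                        circular = TRUE) {
  sequence <- toupper(sequence)
  sequence <- gsub("U", "T", sequence, fixed = TRUE)
  chars <- unique(strsplit(sequence, "")[[1]])
  bad <- setdiff(chars, IUPAC_CHARS)
  if (length(bad) > 0)
    stop("sequence contains non-IUPAC characters: ",
         paste(bad, collapse = ", "))
  len <- nchar(sequence)
  stopifnot(is.data.frame(features))
  needed <- c("name", "start", "end", "wrap", "strand", "anticodon")
  missing_cols <- setdiff(needed, names(features))
  if (length(missing_cols) > 0)
    stop("features is missing columns: ", paste(missing_cols, collapse = ", "))
  features <- features[, needed]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  features$wrap <- as.logical(features$wrap)
  features$anticodon <- normalize_anticodon(features$anticodon)
  unknown <- setdiff(features$name, GENE_VOCABULARY)
  if (length(unknown) > 0)
    stop("unknown feature names: ", paste(unknown, collapse = ", "))
  if (any(features$start < 0L | features$start >= len |
          features$end < 0L | features$end > len))
    stop("feature spans outside [0, length_bp)")
  if (any(!features$strand %in% c("J", "N")))
    stop("strand must be 'J' or 'N'")
  if (sum(features$name == "control_region") > 1L)
    stop("at most one control_region feature allowed")
  is_trna <- features$name %in% TRNA_NAMES
  bad_ac <- is_trna & (is.na(features$anticodon) |
                         nchar(features$anticodon) != 3L)
  if (any(bad_ac))
    stop("tRNA features must carry a 3-mer anticodon: ",
         paste(features$name[bad_ac], collapse = ", "))
  features$role <- role_of_name(features$name)
  ord <- order(features$start, features$end)
  features <- features[ord, , drop = FALSE]
  rownames(features) <- NULL
  structure(
    list(accession = accession, organism = organism, sequence = sequence,
         length_bp = len, circular = circular, features = features),
    class = "mito_record"
  )
}

#' @export
print.mito_record <- function(x, ...) {
  cat(sprintf("<mito_record> %s (%s): %d bp, %d features (%s)\n",
              x$accession, x$organism, x$length_bp, nrow(x$features),
              paste(sprintf("%d %s", table(x$features$role),
                            names(table(x$features$role))), collapse = ", ")))
  invisible(x)
}

normalize_anticodon <- function(x) {
  x <- toupper(as.character(x))
  x <- gsub("U", "T", x, fixed = TRUE)
  x[x %in% c("", "NA")] <- NA_character_
  x
}

feature_span_length <- function(feature, genome_length) {
  ifelse(feature$wrap,
         genome_length - feature$start + feature$end,
         feature$end - feature$start)
}

# Name canonicalization -------------------------------------------------------

#' Canonicalize a gene label
#'
#' Maps the many GenBank spellings of mitochondrial gene names (COI, COX1,
#' ND4L, CYTB, 16S, tRNA-Leu, ...) onto the package's fixed 37-token
#' vocabulary. The two leucine and two serine tRNAs are disambiguated by
#' anticodon when given (`trnL1` = CUN codons, anticodon TAG; `trnL2` = UUR,
#' anticodon TAA; `trnS1` = AGN, anticodon GCT/TCT; `trnS2` = UCN, anticodon
#' TGA), else by a product note containing the codon-family tag.
#'
#' @param raw_label Raw gene/product label from an annotation.
#' @param anticodon Optional 3-mer anticodon (DNA or RNA alphabet).
#' @param product Optional free-text product note used as a fallback for
#'   Leu/Ser disambiguation (looks for CUN/UUR/AGN/UCN).
#' @return A canonical token. Unmappable labels are an error, never a guess.
#' @examples
#' canonical_name("COI")                      # "cox1"
#' canonical_name("tRNA-Ser", anticodon = "GCT")  # "trnS1"
#' @export
canonical_name <- function(raw_label, anticodon = NULL, product = NULL) {
  key <- toupper(trimws(raw_label))
  key <- gsub("[ _]", "-", key)
  direct <- c(
    "COI" = "cox1", "CO1" = "cox1", "COX1" = "cox1", "COXI" = "cox1",
    "COII" = "cox2", "CO2" = "cox2", "COX2" = "cox2", "COXII" = "cox2",
    "COIII" = "cox3", "CO3" = "cox3", "COX3" = "cox3", "COXIII" = "cox3",
    "ND1" = "nad1", "NAD1" = "nad1", "NADH1" = "nad1",
    "ND2" = "nad2", "NAD2" = "nad2", "NADH2" = "nad2",
    "ND3" = "nad3", "NAD3" = "nad3", "NADH3" = "nad3",
    "ND4" = "nad4", "NAD4" = "nad4", "NADH4" = "nad4",
    "ND4L" = "nad4L", "NAD4L" = "nad4L", "NADH4L" = "nad4L",
    "ND5" = "nad5", "NAD5" = "nad5", "NADH5" = "nad5",
    "ND6" = "nad6", "NAD6" = "nad6", "NADH6" = "nad6",
    "ATP6" = "atp6", "ATPASE6" = "atp6", "ATPASE-6" = "atp6",
    "ATP8" = "atp8", "ATPASE8" = "atp8", "ATPASE-8" = "atp8",
    "CYTB" = "cob", "COB" = "cob", "CYT-B" = "cob", "CB" = "cob",
    "16S" = "rrnL", "RRNL" = "rrnL", "L-RRNA" = "rrnL",
    "16S-RIBOSOMAL-RNA" = "rrnL", "LARGE-SUBUNIT-RIBOSOMAL-RNA" = "rrnL",
    "12S" = "rrnS", "RRNS" = "rrnS", "S-RRNA" = "rrnS",
    "12S-RIBOSOMAL-RNA" = "rrnS", "SMALL-SUBUNIT-RIBOSOMAL-RNA" = "rrnS",
    "CONTROL-REGION" = "control_region", "D-LOOP" = "control_region",
    "A+T-RICH-REGION" = "control_region", "AT-RICH-REGION" = "control_region"
  )
  if (key %in% names(direct)) return(unname(direct[key]))
  if (key %in% toupper(GENE_VOCABULARY))
    return(GENE_VOCABULARY[match(key, toupper(GENE_VOCABULARY))])

  aa3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLU = "E",
           GLN = "Q", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
           MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
           TYR = "Y", VAL = "V")
  m <- regmatches(key, regexec("^TRNA?-?([A-Z]{3})", key))[[1]]
  if (length(m) == 2 && m[2] %in% names(aa3)) {
    aa <- unname(aa3[m[2]])
    if (!aa %in% c("L", "S")) return(paste0("trn", aa))
    ac <- if (!is.null(anticodon)) normalize_anticodon(anticodon) else NA
    if (!is.na(ac)) {
      if (aa == "L") {
        if (ac == "TAG") return("trnL1")
        if (ac == "TAA") return("trnL2")
      } else {
        if (ac %in% c("GCT", "TCT")) return("trnS1")
        if (ac == "TGA") return("trnS2")
      }
    }
    if (!is.null(product)) {
      p <- toupper(product)
      if (aa == "L") {
        if (grepl("CUN", p)) return("trnL1")
        if (grepl("UUR", p)) return("trnL2")
      } else {
        if (grepl("AGN", p)) return("trnS1")
        if (grepl("UCN", p)) return("trnS2")
      }
    }
    stop("cannot disambiguate ", raw_label,
         ": no informative anticodon or product note")
  }
  stop("unmappable gene label: ", raw_label)
}

# Sequence access -------------------------------------------------------------

reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

slice_span <- function(sequence, start, end, wrap) {
  # 0-based half-open on the stored strand; wrap crosses the origin
  if (!wrap) {
    substr(sequence, start + 1L, end)
  } else {
    paste0(substr(sequence, start + 1L, nchar(sequence)),
           substr(sequence, 1L, end))
  }
}

#' Extract the sense-strand sequence of a gene
#'
#' Returns the 5'->3' sense sequence of a named feature: the verbatim slice
#' for J-strand genes, the reverse complement for N-strand genes. Spans
#' crossing the origin are concatenated tail+head before orientation.
#'
#' @param record A [mito_record()].
#' @param name Canonical gene token present in the record.
#' @return Nucleotide string.
#' @export
gene_sequence <- function(record, name) {
  i <- which(record$features$name == name)
  if (length(i) == 0) stop("gene not present in record: ", name)
  f <- record$features[i[1], ]
  s <- slice_span(record$sequence, f$start, f$end, f$wrap)
  if (f$strand == "N") s <- reverse_complement(s)
  s
}

# Intergenic map --------------------------------------------------------------

#' Map intergenic spacers and gene overlaps
#'
#' Walks the features in genome order (circular adjacency included) and
#' reports the gap between each consecutive pair; negative gaps are overlaps.
#'
#' @param record A [mito_record()].
#' @param include_control_region Include the control_region feature as a
#'   member of the adjacency walk (default TRUE).
#' @return `data.frame` with columns `upstream`, `downstream`, `gap_bp`.
#' @export
intergenic_map <- function(record, include_control_region = TRUE) {
  f <- record$features
  if (!include_control_region) f <- f[f$name != "control_region", ]
  if (nrow(f) < 2) stop("need at least 2 features")
  # order by start; a wrapped feature is placed by its start
  f <- f[order(f$start), ]
  n <- nrow(f)
  L <- record$length_bp
  up <- f$name
  down <- c(f$name[-1], f$name[1])
  ends <- ifelse(f$wrap, f$end + L, f$end)  # linearized end
  starts <- c(f$start[-1], f$start[1] + L)
  gap <- as.integer(starts - ends)
  # circular closure: last->first gap computed through the origin
  data.frame(upstream = up, downstream = down, gap_bp = gap,
             stringsAsFactors = FALSE)
}

# PCG validation --------------------------------------------------------------

#' Validate protein-coding gene annotations
#'
#' Report-only check of each PCG: start codon (ATN expected in insect
#' mitogenomes), stop-codon class (complete TAA/TAG, or the TA-/T-truncated
#' stops completed by polyadenylation), and presence of in-frame internal
#' stop codons. Nothing is fatal; downstream analyses decide what to do.
#'
#' @param record A [mito_record()].
#' @param code A [genetic_code()]; defaults to table 5.
#' @return `data.frame` with one row per PCG: `gene`, `start_codon`,
#'   `atn_start`, `stop_class` (one of `TAA`, `TAG`, `TA-truncated`,
#'   `T-truncated`, `other`), `internal_stops` (count).
#' @export
validate_pcgs <- function(record, code = genetic_code(5)) {
  pcgs <- record$features$name[record$features$role == "PCG"]
  if (length(pcgs) == 0) stop("record has no PCG features")
  rows <- lapply(pcgs, function(g) {
    s <- gene_sequence(record, g)
    n <- nchar(s)
    start_codon <- substr(s, 1, 3)
    rem <- n %% 3L
    stop_class <- if (rem == 1L) {
      if (substr(s, n, n) == "T") "T-truncated" else "other"
    } else if (rem == 2L) {
      if (substr(s, n - 1, n) == "TA") "TA-truncated" else "other"
    } else {
      last <- substr(s, n - 2, n)
      if (last %in% code$stop_codons) last else "other"
    }
    ncod <- n %/% 3L
    # internal codons exclude the final (possibly stop) codon
    internal <- 0L
    if (ncod > 1L) {
      cods <- substring(s, seq(1L, by = 3L, length.out = ncod - 1L),
                        seq(3L, by = 3L, length.out = ncod - 1L))
      internal <- sum(cods %in% code$stop_codons)
    }
    data.frame(gene = g, start_codon = start_codon,
               atn_start = grepl("^AT[ACGT]$", start_codon),
               stop_class = stop_class, internal_stops = internal,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Genome closure check --------------------------------------------------------

# sum of feature lengths plus gaps (overlaps negative) closes the circle
circular_closure_ok <- function(record, include_control_region = TRUE) {
  f <- record$features
  if (!include_control_region) f <- f[f$name != "control_region", ]
  ig <- intergenic_map(record, include_control_region)
  total <- sum(feature_span_length(f, record$length_bp)) + sum(ig$gap_bp)
  total == record$length_bp
}
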