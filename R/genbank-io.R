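# GenBank flat-file dialect reader/writer.
#
# Handles the subset of the format that annotated mitogenome deposits use:
# LOCUS/ACCESSION/ORGANISM headers, a FEATURES table with CDS/tRNA/rRNA/D-loop
# keys (locations as n..m, complement(...), and two-segment join(...) across
# the origin), and an ORIGIN sequence block. Coordinates are converted between
# GenBank 1-based closed and the internal 0-based half-open representation at
# this boundary only.

#' Parse a GenBank flat file into a mitogenome record
#'
#' @param path Path to a `.gb`/`.gbk` flat file with an ORIGIN sequence block
#'   and gene features. Feature names are canonicalized via
#'   [canonical_name()]; unrecognized feature keys are ignored.
#' @return A [mito_record()].
#' @export
parse_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty file: ", path)

  locus <- grep("^LOCUS", lines, value = TRUE)
  accession <- NA_character_
  acc_line <- grep("^ACCESSION", lines, value = TRUE)
  if (length(acc_line) > 0)
    accession <- strsplit(trimws(sub("^ACCESSION", "", acc_line[1])), "\\s+")[[1]][1]
  if (is.na(accession) && length(locus) > 0)
    accession <- strsplit(trimws(sub("^LOCUS", "", locus[1])), "\\s+")[[1]][1]
  organism <- ""
  org_line <- grep("^\\s+ORGANISM", lines, value = TRUE)
  if (length(org_line) > 0) organism <- trimws(sub("^\\s+ORGANISM", "", org_line[1]))
  circular <- any(grepl("circular", locus, ignore.case = TRUE))

  ori <- grep("^ORIGIN", lines)
  if (length(ori) == 0) stop("no ORIGIN block in ", path)
  endseq <- grep("^//", lines)
  endseq <- if (length(endseq) > 0) endseq[endseq > ori[1]][1] else length(lines) + 1L
  seq_lines <- lines[(ori[1] + 1L):(endseq - 1L)]
  sequence <- toupper(gsub("[0-9 /]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0) stop("ORIGIN block contains no sequence in ", path)

  feat_start <- grep("^FEATURES", lines)
  if (length(feat_start) == 0) stop("no FEATURES table in ", path)
  feat_lines <- lines[(feat_start[1] + 1L):(ori[1] - 1L)]
  feats <- parse_feature_block(feat_lines, nchar(sequence))
  if (nrow(feats) == 0) stop("no recognized gene features in ", path)
  mito_record(accession = accession, organism = organism, sequence = sequence,
              features = feats, circular = circular)
}

# split the FEATURES block into (key, location, qualifiers) entries
parse_feature_block <- function(lines, genome_length) {
  is_new <- grepl("^ {5}\\S", lines)
  idx <- which(is_new)
  out <- list()
  for (k in seq_along(idx)) {
    block <- lines[idx[k]:(if (k < length(idx)) idx[k + 1] - 1L else length(lines))]
    head <- block[1]
    key <- sub("^ {5}(\\S+).*$", "\\1", head)
    if (!key %in% c("CDS", "tRNA", "rRNA", "D-loop", "misc_feature")) next
    loc <- trimws(sub("^ {5}\\S+\\s+", "", head))
    rest <- block[-1]
    # location may continue until the first qualifier line
    qstart <- grep("^\\s+/", rest)
    if (length(qstart) > 0 && qstart[1] > 1)
      loc <- paste0(loc, paste(trimws(rest[seq_len(qstart[1] - 1)]), collapse = ""))
    quals <- parse_qualifiers(rest)
    span <- parse_location(loc, genome_length)
    raw <- quals[["gene"]] %||% quals[["product"]] %||%
      (if (key == "D-loop") "D-loop" else NA_character_)
    if (key == "misc_feature") {
      note <- tolower(quals[["note"]] %||% "")
      if (grepl("control region|a\\+t-rich", note)) raw <- "control region"
      else next  # unknown misc_features preserved upstream formats, ignored here
    }
    if (is.na(raw)) next
    ac <- parse_anticodon_qual(quals[["anticodon"]])
    name <- canonical_name(raw, anticodon = ac, product = quals[["product"]])
    out[[length(out) + 1L]] <- data.frame(
      name = name, start = span$start, end = span$end, wrap = span$wrap,
      strand = if (span$complement) "N" else "J",
      anticodon = if (is.null(ac)) NA_character_ else ac,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(name = character(), start = integer(), end = integer(),
                      wrap = logical(), strand = character(),
                      anticodon = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

parse_qualifiers <- function(lines) {
  qlines <- grep("^\\s+/", lines, value = TRUE)
  quals <- list()
  for (q in trimws(qlines)) {
    m <- regmatches(q, regexec('^/([A-Za-z_]+)=?"?([^"]*)"?$', q))[[1]]
    if (length(m) == 3) quals[[m[2]]] <- m[3]
  }
  quals
}

parse_anticodon_qual <- function(q) {
  if (is.null(q)) return(NULL)
  m <- regmatches(q, regexec("seq:([A-Za-z]{3})", q))[[1]]
  if (length(m) == 2) return(toupper(m[2]))
  if (grepl("^[A-Za-z]{3}$", q)) return(toupper(q))
  NULL
}

parse_location <- function(loc, genome_length) {
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  complement <- grepl("^complement\\(", loc)
  if (complement) loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",")[[1]]
    if (length(parts) != 2)
      stop("only two-segment joins (origin wrap) are supported: ", loc)
    a <- as.integer(strsplit(parts[1], "\\.\\.")[[1]])
    b <- as.integer(strsplit(parts[2], "\\.\\.")[[1]])
    if (a[2] != genome_length || b[1] != 1L)
      stop("join does not describe an origin wrap: ", loc)
    return(list(start = a[1] - 1L, end = b[2], wrap = TRUE,
                complement = complement))
  }
  nums <- as.integer(strsplit(loc, "\\.\\.")[[1]])
  if (length(nums) == 1) nums <- c(nums, nums)
  list(start = nums[1] - 1L, end = nums[2], wrap = FALSE,
       complement = complement)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a mitogenome record as a GenBank flat file
#'
#' Emits the minimal dialect read back by [parse_genbank()]; a parsed record
#' written and re-parsed round-trips to an identical data model.
#'
#' @param record A [mito_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path) {
  f <- record$features
  L <- record$length_bp
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("LOCUS       %s %d bp    DNA     %s   INV",
     record$accession, L, if (record$circular) "circular" else "linear")
  wl("ACCESSION   %s", record$accession)
  wl("  ORGANISM  %s", record$organism)
  wl("FEATURES             Location/Qualifiers")
  wl("     source          1..%d", L)
  for (i in seq_len(nrow(f))) {
    ft <- f[i, ]
    loc <- if (ft$wrap) sprintf("join(%d..%d,1..%d)", ft$start + 1L, L, ft$end)
           else sprintf("%d..%d", ft$start + 1L, ft$end)
    if (ft$strand == "N") loc <- sprintf("complement(%s)", loc)
    key <- switch(ft$role, PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                  control_region = "D-loop")
    wl("     %-15s %s", key, loc)
    wl("                     /gene=\"%s\"", ft$name)
    if (!is.na(ft$anticodon))
      wl("                     /anticodon=\"(pos:0..0,aa:Xxx,seq:%s)\"",
         tolower(ft$anticodon))
  }
  wl("ORIGIN")
  s <- tolower(record$sequence)
  pos <- seq(1L, nchar(s), by = 60L)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59L, nchar(s)))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    wl("%9d %s", p, paste(groups, collapse = " "))
  }
  wl("//")
  invisible(path)
}

#' Read a record from FASTA plus a tab-separated feature table
#'
#' Fallback dialect for records not available as GenBank flat files. The
#' table has columns `name`, `start`, `end` (1-based closed, `start > end`
#' marks an origin-wrapping span), `strand` (`J`/`N`), `type`, `anticodon`
#' (blank or `-` if none).
#'
#' @param fasta_path Single-record FASTA file.
#' @param table_path Tab-separated feature table with a header row.
#' @param accession,organism Optional overrides; default from the FASTA
#'   header.
#' @return A [mito_record()].
#' @export
parse_feature_table <- function(fasta_path, table_path,
                                accession = NULL, organism = NULL) {
  dna <- Biostrings::readDNAStringSet(fasta_path)
  if (length(dna) != 1) stop("expected a single-record FASTA")
  header <- names(dna)[1]
  sequence <- as.character(dna[[1]])
  tab <- utils::read.delim(table_path, stringsAsFactors = FALSE)
  needed <- c("name", "start", "end", "strand", "type", "anticodon")
  if (!all(needed %in% names(tab)))
    stop("feature table must have columns: ", paste(needed, collapse = ", "))
  ac <- as.character(tab$anticodon)
  ac[ac %in% c("", "-", ".")] <- NA_character_
  wrap <- tab$start > tab$end
  feats <- data.frame(
    name = vapply(seq_len(nrow(tab)), function(i)
      canonical_name(tab$name[i], anticodon = ac[i]), character(1)),
    start = tab$start - 1L,
    end = tab$end,
    wrap = wrap, strand = tab$strand, anticodon = ac,
    stringsAsFactors = FALSE)
  hdr <- strsplit(sub("^>", "", header), "\\s+")[[1]]
  mito_record(
    accession = accession %||% hdr[1],
    organism = organism %||% trimws(sub("^\\S+\\s*", "", header)),
    sequence = sequence, features = feats)
}

#' Serialize a record to JSON
#'
#' Normalized dump of the full data model (accession, organism, sequence,
#' feature table with 0-based half-open coordinates).
#'
#' @param record A [mito_record()].
#' @param path Optional path; when given the JSON is written there.
#' @return JSON string (invisibly when `path` is given).
#' @export
record_to_json <- function(record, path = NULL) {
  obj <- list(accession = record$accession, organism = record$organism,
              length_bp = record$length_bp, circular = record$circular,
              sequence = record$sequence,
              features = record$features)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
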