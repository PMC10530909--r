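# Pipeline driver and phylogenetic-dataset export.

#' Run the full comparative pipeline over a set of record files
#'
#' Parses each input (GenBank flat file), then runs composition, codon
#' usage, per-gene Ka/Ks (when at least two records parse), control-region
#' extraction and repeat cataloguing, and the tRNA-like scan. Per-file parse
#' failures are collected and the run continues; it is an error only if all
#' inputs fail.
#'
#' @param paths Character vector of GenBank file paths, or a list of
#'   [mito_record()] objects.
#' @param out_dir Optional directory; when given, summary and per-stage
#'   tables are written there as TSV/JSON with deterministic content.
#' @param code A [genetic_code()].
#' @param scan_args Named list of overrides passed to
#'   [scan_control_region()].
#' @param verbose Log thresholds and stage progress (default FALSE).
#' @return List of class `cohort_result`: `summary` (one row per record),
#'   `composition`, `usage`, `rates` (NULL for cohorts of 1), `hits` (named
#'   list of hit frames), `census`, `failures` (named character of error
#'   messages).
#' @export
run_pipeline <- function(paths, out_dir = NULL, code = genetic_code(5),
                         scan_args = list(), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  records <- list()
  failures <- character(0)
  if (is.list(paths) && length(paths) > 0 && inherits(paths[[1]], "mito_record")) {
    records <- paths
    names(records) <- vapply(records, `[[`, character(1), "accession")
  } else {
    for (p in paths) {
      rec <- tryCatch(parse_genbank(p), error = function(e) e)
      if (inherits(rec, "error")) {
        failures[p] <- conditionMessage(rec)
        warning("failed to parse ", p, ": ", conditionMessage(rec),
                call. = FALSE)
      } else records[[rec$accession]] <- rec
    }
  }
  if (length(records) == 0) stop("no parseable records")

  say("composition over %d records", length(records))
  comp <- composition_table(records)
  usage <- usage_table(records, code)
  rates <- NULL
  if (length(records) >= 2) {
    say("Ka/Ks across %d records", length(records))
    rates <- rates_table(records, code = code)
  } else say("selection stage skipped: cohort of 1")

  hits <- list()
  cr_len <- integer(0)
  for (id in names(records)) {
    rec <- records[[id]]
    cr <- tryCatch(extract_control_region(rec), error = function(e) NULL)
    if (is.null(cr)) {
      hits[[id]] <- empty_hit_frame()
      cr_len[id] <- NA_integer_
      next
    }
    cr_len[id] <- cr$length_bp
    refs <- trna_references(rec)
    hits[[id]] <- do.call(scan_control_region,
                          c(list(cr = cr, references = refs), scan_args))
  }
  census <- family_census(hits)

  summary <- data.frame(
    accession = comp$accession,
    organism = vapply(records, `[[`, character(1), "organism"),
    length_bp = comp$length_bp,
    at_content = comp$at_content,
    at_skew = comp$at_skew,
    gc_skew = comp$gc_skew,
    enc = usage$enc, cbi = usage$cbi, gc3 = usage$gc3,
    cr_length = unname(cr_len[comp$accession]),
    n_trna_like = vapply(comp$accession, function(id)
      nrow(hits[[id]]), integer(1)),
    families = vapply(comp$accession, function(id)
      paste(sort(unique(stats::na.omit(hits[[id]]$family))), collapse = ","),
      character(1)),
    stringsAsFactors = FALSE, row.names = NULL)

  out <- structure(list(summary = summary, composition = comp,
                        usage = usage, rates = rates, hits = hits,
                        census = census, failures = failures),
                   class = "cohort_result")
  if (!is.null(out_dir)) write_cohort_result(out, out_dir)
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_cohort_result <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(x$summary, file.path(out_dir, "summary.tsv"))
  write_tsv(x$composition, file.path(out_dir, "composition.tsv"))
  write_tsv(x$usage, file.path(out_dir, "codon_usage.tsv"))
  if (!is.null(x$rates))
    write_tsv(x$rates, file.path(out_dir, "kaks.tsv"))
  all_hits <- do.call(rbind, lapply(names(x$hits), function(id) {
    h <- x$hits[[id]]
    if (nrow(h) == 0) return(NULL)
    cbind(data.frame(accession = id, stringsAsFactors = FALSE), h)
  }))
  if (!is.null(all_hits))
    write_tsv(all_hits, file.path(out_dir, "trna_like_hits.tsv"))
  writeLines(jsonlite::toJSON(x$census, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(out_dir, "census.json"))
  invisible(out_dir)
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %d records, %d parse failures\n",
              nrow(x$summary), length(x$failures)))
  print(x$summary)
  invisible(x)
}

# Supermatrix export ----------------------------------------------------------

#' Build a phylogenetic supermatrix from per-gene alignments
#'
#' Concatenates per-gene alignments into one of the standard mitogenomic
#' datasets: `P123` (all codon positions of the 13 PCGs), `P123AA` (their
#' translation), or `P123RNA` (P123 plus the two rRNA alignments). Partition
#' definitions are produced per gene, and additionally per codon position
#' for the nucleotide datasets.
#'
#' @param alignments Named list (gene -> named character vector of aligned,
#'   equal-length sequences; names are taxa). PCG alignments must have
#'   length divisible by 3 for `P123AA`.
#' @param dataset One of `"P123"`, `"P123AA"`, `"P123RNA"`.
#' @param rrna_alignments Named list with elements `rrnL` and `rrnS`
#'   (required for `P123RNA`).
#' @param pad_missing Pad taxa absent from an alignment with gaps instead of
#'   erroring (default FALSE).
#' @param code A [genetic_code()] used for translation; codons containing a
#'   stop are exported as `X` with a warning.
#' @return List of class `supermatrix`: `sequences` (named character vector,
#'   one entry per taxon), `width`, `partitions` (`data.frame`: `name`,
#'   `start`, `end`, 1-based closed), `dataset`.
#' @export
build_supermatrix <- function(alignments, dataset = c("P123", "P123AA",
                                                      "P123RNA"),
                              rrna_alignments = NULL, pad_missing = FALSE,
                              code = genetic_code(5)) {
  dataset <- match.arg(dataset)
  alignments <- lapply(alignments, unlist_alignment)
  taxa <- sort(unique(unlist(lapply(alignments, names))))
  blocks <- alignments
  if (dataset == "P123RNA") {
    if (is.null(rrna_alignments) ||
        !all(c("rrnL", "rrnS") %in% names(rrna_alignments)))
      stop("P123RNA requires rrna_alignments with rrnL and rrnS")
    rr <- lapply(rrna_alignments, unlist_alignment)
    blocks <- c(blocks, rr)
    taxa <- sort(unique(c(taxa, unlist(lapply(rr, names)))))
  }
  for (g in names(blocks)) {
    aln <- blocks[[g]]
    if (length(unique(nchar(aln))) != 1)
      stop("alignment for ", g, " has unequal sequence lengths")
    missing <- setdiff(taxa, names(aln))
    if (length(missing) > 0) {
      if (!pad_missing)
        stop("taxa missing from ", g, ": ", paste(missing, collapse = ", "),
             " (set pad_missing = TRUE to pad with gaps)")
      pad <- strrep("-", nchar(aln[1]))
      aln[missing] <- pad
    }
    blocks[[g]] <- aln[taxa]
  }
  if (dataset == "P123AA") {
    for (g in names(blocks)) {
      if (nchar(blocks[[g]][1]) %% 3L != 0L)
        stop("alignment for ", g, " is not a multiple of 3; cannot translate")
      blocks[[g]] <- vapply(blocks[[g]], translate_alignment_row,
                            character(1), code = code)
    }
  }
  widths <- vapply(blocks, function(a) nchar(a[1]), integer(1))
  seqs <- stats::setNames(rep("", length(taxa)), taxa)
  parts <- list()
  at <- 0L
  for (g in names(blocks)) {
    seqs <- paste0(seqs, blocks[[g]])
    w <- widths[[g]]
    parts[[length(parts) + 1L]] <- data.frame(
      name = g, start = at + 1L, end = at + w, stringsAsFactors = FALSE)
    if (dataset %in% c("P123", "P123RNA") && g %in% PCG_NAMES) {
      for (cp in 1:3)
        parts[[length(parts) + 1L]] <- data.frame(
          name = sprintf("%s_pos%d", g, cp), start = at + cp, end = at + w,
          stringsAsFactors = FALSE)
    }
    at <- at + w
  }
  names(seqs) <- taxa
  partitions <- do.call(rbind, parts)
  partitions$codon_step <- ifelse(grepl("_pos[123]$", partitions$name), 3L, 1L)
  structure(list(sequences = seqs, width = at, partitions = partitions,
                 dataset = dataset),
            class = "supermatrix")
}

unlist_alignment <- function(a) {
  if (inherits(a, "DNAStringSet") || inherits(a, "AAStringSet"))
    return(stats::setNames(as.character(a), names(a)))
  unlist(a)
}

translate_alignment_row <- function(s, code) {
  cods <- split_codons(s)
  aa <- vapply(cods, function(cd) {
    if (cd == "---") return("-")
    if (grepl("-", cd, fixed = TRUE)) return("X")
    if (!cd %in% names(code$codon_to_aa)) return("X")
    a <- code$codon_to_aa[[cd]]
    if (a == "*") {
      warning("stop codon in alignment exported as X", call. = FALSE)
      return("X")
    }
    a
  }, character(1))
  paste(aa, collapse = "")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %s: %d taxa x %d columns, %d charsets\n",
              x$dataset, length(x$sequences), x$width, nrow(x$partitions)))
  invisible(x)
}

#' Write a supermatrix in relaxed PHYLIP format
#'
#' @param sm A [build_supermatrix()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(sm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(sm$sequences), sm$width), con)
  nm <- gsub("\\s", "_", names(sm$sequences))
  writeLines(sprintf("%-*s  %s", max(nchar(nm)), nm, sm$sequences), con)
  invisible(path)
}

#' Write a supermatrix as NEXUS with charset partitions
#'
#' @param sm A [build_supermatrix()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nexus <- function(sm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  datatype <- if (sm$dataset == "P123AA") "PROTEIN" else "DNA"
  writeLines("#NEXUS", con)
  writeLines("BEGIN DATA;", con)
  writeLines(sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;",
                     length(sm$sequences), sm$width), con)
  writeLines(sprintf("  FORMAT DATATYPE=%s MISSING=? GAP=-;", datatype), con)
  writeLines("  MATRIX", con)
  nm <- gsub("\\s", "_", names(sm$sequences))
  writeLines(sprintf("    %-*s  %s", max(nchar(nm)), nm, sm$sequences), con)
  writeLines("  ;", con)
  writeLines("END;", con)
  writeLines("BEGIN SETS;", con)
  for (i in seq_len(nrow(sm$partitions))) {
    p <- sm$partitions[i, ]
    rng <- if (p$codon_step > 1L)
      sprintf("%d-%d\\%d", p$start, p$end, p$codon_step)
    else sprintf("%d-%d", p$start, p$end)
    writeLines(sprintf("  CHARSET %s = %s;", p$name, rng), con)
  }
  writeLines("END;", con)
  invisible(path)
}

#' Extract per-gene sequence sets from a cohort for alignment
#'
#' Convenience for supermatrix construction on cohorts without indels
#' (e.g. [evolve_cohort()] output): returns the sense sequences keyed by
#' accession for each requested gene.
#'
#' @param records List of [mito_record()] objects.
#' @param genes Canonical tokens (default all 13 PCGs).
#' @param drop_stop Drop a terminal stop codon from each PCG (default TRUE).
#' @return Named list gene -> named character vector.
#' @export
cohort_gene_sets <- function(records, genes = PCG_NAMES, drop_stop = TRUE) {
  code <- genetic_code(5)
  out <- list()
  for (g in genes) {
    seqs <- vapply(records, function(r) gene_sequence(r, g), character(1))
    names(seqs) <- vapply(records, `[[`, character(1), "accession")
    if (drop_stop && g %in% PCG_NAMES) {
      seqs <- vapply(seqs, function(s) {
        cods <- split_codons(s)
        if (length(cods) > 0 && cods[length(cods)] %in%
            genetic_code(5)$stop_codons)
          s <- substr(s, 1L, nchar(s) - 3L)
        substr(s, 1L, 3L * (nchar(s) %/% 3L))
      }, character(1))
    }
    out[[g]] <- seqs
  }
  out
}
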