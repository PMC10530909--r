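# Control-region extraction and repeat-architecture cataloguing.
#
# The control region (A+T-rich region) of an insect mitogenome is the
# largest non-coding segment, lying between rrnS and trnI and containing the
# replication origin. Its repeat inventory here covers tandem repeats,
# poly-N tracts, TA dinucleotide repeats and G+C-rich windows. All reported
# intervals are 0-based half-open within the scanned sequence.

#' Extract the control region of a record
#'
#' An explicit `control_region` feature takes precedence; otherwise the
#' region is the gap from the end of `rrnS` to the start of `trnI` in genome
#' orientation, wrapping the origin when needed.
#'
#' @param record A [mito_record()].
#' @return Object of class `control_region`: `span` (`start`, `end`, `wrap`;
#'   0-based half-open genome coordinates), `sequence`, `length_bp`,
#'   `at_content` (percent), `source` (`"feature"` or `"flanks"`).
#' @export
extract_control_region <- function(record) {
  f <- record$features
  cr <- f[f$name == "control_region", ]
  if (nrow(cr) == 1) {
    s <- slice_span(record$sequence, cr$start, cr$end, cr$wrap)
    span <- list(start = cr$start, end = cr$end, wrap = cr$wrap)
    src <- "feature"
  } else {
    rrns <- f[f$name == "rrnS", ]
    trni <- f[f$name == "trnI", ]
    if (nrow(rrns) == 0 || nrow(trni) == 0)
      stop("record lacks rrnS/trnI flanks and has no control_region feature")
    start <- if (rrns$wrap) rrns$end else rrns$end %% record$length_bp
    end <- trni$start
    wrap <- start > end
    s <- slice_span(record$sequence, start, end, wrap)
    span <- list(start = start, end = end, wrap = wrap)
    src <- "flanks"
  }
  structure(list(span = span, sequence = s, length_bp = nchar(s),
                 at_content = summarize_composition(s)$at_content,
                 source = src),
            class = "control_region")
}

#' @export
print.control_region <- function(x, ...) {
  cat(sprintf("<control_region> %d bp (A+T %.1f%%), span [%d, %d)%s [%s]\n",
              x$length_bp, x$at_content, x$span$start, x$span$end,
              if (x$span$wrap) " wrapping origin" else "", x$source))
  invisible(x)
}

# Tandem repeats --------------------------------------------------------------

# Reported repeat definition (shared by the scanner and the brute-force
# oracle used in tests): for period p, compare s[k] with s[k - p]. Every
# match position a seeds one candidate run [a, e], where e is the match
# position maximizing matches - mismatches subject to identity >=
# min_identity over [a, e] (ties toward the shorter extension) -- the
# best-supported extent, so chance matches in the flanks do not dilute a
# clean array. Candidates below the copy-number floor are dropped; the rest
# are selected greedily by descending score into a non-overlapping set per
# period. A repeat's sequence span is [a - p, e], its unit the first p
# bases, copies = span/p (fractional).

#' Scan for tandem repeats
#'
#' Deterministic scanner over all periods in range: for each period the
#' self-offset match profile is computed and match-bounded,
#' identity-thresholded runs are reported at their best-supported extent
#' (maximizing matches minus mismatches, so chance matches in the
#' flanks do not dilute a clean array). Overlapping reports are reduced
#' by keeping the highest `copies * identity` (ties: smaller period, then
#' leftmost start).
#'
#' @param seq Nonempty nucleotide string.
#' @param min_period Minimum repeat unit length (default 10).
#' @param max_period Maximum unit length (default `floor(nchar(seq)/2)`).
#' @param min_copies Minimum (fractional) copy number (default 1.9).
#' @param min_identity Minimum identity of the offset self-match (default
#'   0.8).
#' @return `data.frame` of class `repeat_features`: `kind` (`"tandem"`),
#'   `unit`, `period`, `copies`, `start`, `end` (0-based half-open),
#'   `identity`; ordered by start.
#' @export
find_tandem_repeats <- function(seq, min_period = 10L, max_period = NULL,
                                min_copies = 1.9, min_identity = 0.8) {
  s <- gsub("U", "T", toupper(seq), fixed = TRUE)
  L <- nchar(s)
  stopifnot(L > 0)
  if (is.null(max_period)) max_period <- L %/% 2L
  chars <- strsplit(s, "")[[1]]
  cand <- list()
  for (p in seq(min_period, max_period)) {
    if (2 * p > L) break
    m <- chars[(p + 1):L] == chars[1:(L - p)]  # m[k]: position k+p matches k
    runs <- scored_identity_runs(m, min_identity, p, min_copies)
    for (r in runs) {
      a <- r[1]; e <- r[2]  # indices into m: m[k] compares seq[k + p] vs seq[k]
      # repeat span in the sequence is [a, e + p] 1-based closed
      len <- e + p - a + 1L
      cand[[length(cand) + 1L]] <- data.frame(
        kind = "tandem", unit = substr(s, a, a + p - 1L), period = p,
        copies = len / p, start = a - 1L, end = e + p,
        identity = mean(m[a:e]), stringsAsFactors = FALSE)
    }
  }
  if (length(cand) == 0)
    return(empty_repeat_frame())
  out <- do.call(rbind, cand)
  out <- merge_overlapping_repeats(out)
  out <- out[order(out$start, out$period), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("repeat_features", class(out))
  out
}

empty_repeat_frame <- function() {
  out <- data.frame(kind = character(), unit = character(),
                    period = integer(), copies = numeric(),
                    start = integer(), end = integer(),
                    identity = numeric(), stringsAsFactors = FALSE)
  class(out) <- c("repeat_features", class(out))
  out
}

# candidate runs in a logical vector: one per match position (best-scoring
# end, identity >= thr), copy-number filtered, then greedily selected by
# descending score into a non-overlapping set; returns list of
# c(start_index, end_index)
scored_identity_runs <- function(m, thr, period, min_copies) {
  idx <- which(m)
  if (length(idx) == 0) return(list())
  cs <- cumsum(m)
  cand_a <- integer(0); cand_e <- integer(0)
  cand_score <- numeric(0); cand_ident <- numeric(0)
  for (a in idx) {
    ends <- idx[idx >= a]
    matches <- cs[ends] - cs[a] + 1L
    ident <- matches / (ends - a + 1L)
    ok <- ident >= thr
    ends <- ends[ok]; matches <- matches[ok]
    score <- 2L * matches - (ends - a + 1L)   # matches - mismatches
    e <- min(ends[score == max(score)])
    if ((e + period - a + 1L) / period < min_copies) next
    cand_a <- c(cand_a, a)
    cand_e <- c(cand_e, e)
    cand_score <- c(cand_score, max(score))
    cand_ident <- c(cand_ident, (cs[e] - cs[a] + 1L) / (e - a + 1L))
  }
  if (length(cand_a) == 0) return(list())
  # ties on score resolved toward the cleaner (higher-identity) run
  ord <- order(-cand_score, -cand_ident, cand_a, -cand_e)
  runs <- list()
  for (i in ord) {
    # a run's sequence span is [a - 1, e + p) 0-based half-open
    clash <- any(vapply(runs, function(r)
      cand_a[i] - 1L < r[2] + period && r[1] - 1L < cand_e[i] + period,
      logical(1)))
    if (!clash) runs[[length(runs) + 1L]] <- c(cand_a[i], cand_e[i])
  }
  runs[order(vapply(runs, `[`, integer(1), 1))]
}

# keep the best of every overlapping pair by copies * identity
# (ties: smaller period, then leftmost)
merge_overlapping_repeats <- function(df) {
  score <- df$copies * df$identity
  ord <- order(-score, df$period, df$start)
  df <- df[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!keep[i]) next
    if (i == nrow(df)) break
    for (j in (i + 1):nrow(df)) {
      if (!keep[j]) next
      if (df$start[j] < df$end[i] && df$start[i] < df$end[j])
        keep[j] <- FALSE
    }
  }
  df[keep, , drop = FALSE]
}

# Tracts and TA repeats -------------------------------------------------------

#' Find homopolymer tracts
#'
#' Maximal runs of a single base of at least `min_len`.
#'
#' @param seq Nonempty nucleotide string.
#' @param base Single nucleotide (default `"T"`, the poly-T tracts of insect
#'   control regions).
#' @param min_len Minimum run length (default 5).
#' @return `data.frame`: `kind` (`"poly_<base>"`), `start`, `end` (0-based
#'   half-open), `length`.
#' @export
find_tracts <- function(seq, base = "T", min_len = 5L) {
  s <- gsub("U", "T", toupper(seq), fixed = TRUE)
  stopifnot(nchar(s) > 0, nchar(base) == 1)
  base <- toupper(base)
  r <- rle(strsplit(s, "")[[1]] == base)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- r$values & r$lengths >= min_len
  data.frame(kind = rep(paste0("poly_", base), sum(hit)),
             start = starts[hit] - 1L, end = ends[hit],
             length = r$lengths[hit], stringsAsFactors = FALSE)
}

#' Find TA dinucleotide repeats
#'
#' Maximal runs of alternating T/A (TATA... units) with at least
#' `min_copies` dinucleotide copies. Phase ambiguity (TA vs AT) is
#' canonicalized to the earliest start coordinate.
#'
#' @param seq Nonempty nucleotide string.
#' @param min_copies Minimum number of dinucleotide units (default 3).
#' @return `data.frame`: `kind` (`"ta_unit"`), `unit`, `period` (2),
#'   `copies`, `start`, `end`, `identity` (1).
#' @export
find_ta_repeats <- function(seq, min_copies = 3L) {
  s <- gsub("U", "T", toupper(seq), fixed = TRUE)
  stopifnot(nchar(s) > 0)
  chars <- strsplit(s, "")[[1]]
  L <- length(chars)
  is_ta <- chars %in% c("T", "A")
  alt <- c(FALSE, chars[-1] != chars[-L])  # alt[k]: differs from previous
  out <- list()
  k <- 1L
  while (k <= L) {
    if (!is_ta[k]) { k <- k + 1L; next }
    e <- k
    while (e < L && is_ta[e + 1L] && chars[e + 1L] != chars[e]) e <- e + 1L
    len <- e - k + 1L
    copies <- len %/% 2L
    if (copies >= min_copies) {
      out[[length(out) + 1L]] <- data.frame(
        kind = "ta_unit", unit = substr(s, k, k + 1L), period = 2L,
        copies = as.numeric(copies), start = k - 1L,
        end = k - 1L + 2L * copies, identity = 1,
        stringsAsFactors = FALSE)
    }
    k <- e + 1L
  }
  if (length(out) == 0) return(empty_repeat_frame()[, c("kind", "unit",
    "period", "copies", "start", "end", "identity")])
  do.call(rbind, out)
}

# G+C-rich windows ------------------------------------------------------------

#' Find G+C-rich intervals
#'
#' A position belongs to a reported interval when every length-`window`
#' window covering it has G+C percent above `threshold`; qualifying
#' positions are merged into maximal intervals.
#'
#' @param seq Nucleotide string with `nchar(seq) >= window`.
#' @param window Window size in bp (default 20).
#' @param threshold G+C percent that every covering window must exceed
#'   (default 50).
#' @return `data.frame`: `start`, `end` (0-based half-open), `length`.
#' @export
gc_rich_windows <- function(seq, window = 20L, threshold = 50) {
  s <- gsub("U", "T", toupper(seq), fixed = TRUE)
  L <- nchar(s)
  stopifnot(window <= L)
  gcv <- strsplit(s, "")[[1]] %in% c("G", "C")
  cs <- c(0, cumsum(gcv))
  starts <- 1:(L - window + 1L)
  gc_pct <- 100 * (cs[starts + window] - cs[starts]) / window
  fail <- gc_pct <= threshold
  covered_by_fail <- rep(FALSE, L)
  for (i in which(fail)) covered_by_fail[i:(i + window - 1L)] <- TRUE
  ok <- !covered_by_fail
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  st <- ends - r$lengths + 1L
  hit <- r$values
  data.frame(start = st[hit] - 1L, end = ends[hit],
             length = r$lengths[hit], stringsAsFactors = FALSE)
}

# Spacer consensus ------------------------------------------------------------

#' Conserved blocks of a set of intergenic spacers
#'
#' Center-star progressive alignment (all sequences aligned to the medoid by
#' global pairwise alignment), then columns with conservation at or above
#' `min_conservation` are merged into blocks of at least `min_block`
#' columns. Used for the conserved trnS2-nad1 spacer motifs.
#'
#' @param spacers Character vector of >= 2 nucleotide strings whose lengths
#'   are within a factor of 2 of each other.
#' @param min_conservation Column conservation threshold (default 0.9);
#'   gaps count against conservation.
#' @param min_block Minimum block width in columns (default 4).
#' @return `data.frame`: `consensus`, `col_start`, `col_end` (0-based
#'   half-open alignment columns), `conservation` (mean over the block).
#' @export
spacer_consensus <- function(spacers, min_conservation = 0.9, min_block = 4L) {
  if (length(spacers) < 2) stop("need at least 2 spacers")
  lens <- nchar(spacers)
  if (max(lens) > 2 * min(lens))
    stop("spacer lengths differ by more than 2x")
  aln <- center_star_align(toupper(spacers))
  mat <- do.call(rbind, strsplit(aln, ""))
  ncolu <- ncol(mat)
  cons_frac <- numeric(ncolu)
  cons_char <- character(ncolu)
  n <- nrow(mat)
  for (j in seq_len(ncolu)) {
    col <- mat[, j]
    tab <- table(col[col != "-"])
    if (length(tab) == 0) { cons_frac[j] <- 0; cons_char[j] <- "-"; next }
    best <- sort(names(tab)[tab == max(tab)])[1]
    cons_frac[j] <- max(tab) / n
    cons_char[j] <- best
  }
  ok <- cons_frac >= min_conservation
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= min_block)
  rows <- lapply(hit, function(i) {
    a <- starts[i]; b <- ends[i]
    data.frame(consensus = paste(cons_char[a:b], collapse = ""),
               col_start = a - 1L, col_end = b,
               conservation = mean(cons_frac[a:b]),
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0)
    return(data.frame(consensus = character(), col_start = integer(),
                      col_end = integer(), conservation = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# align all sequences to the medoid (max summed pairwise score); merge by
# center coordinates, inserting center-gap columns as needed
center_star_align <- function(seqs) {
  n <- length(seqs)
  if (length(unique(nchar(seqs))) == 1 && n > 0) {
    # equal lengths: positional stacking is already an alignment
    return(seqs)
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(1, -1)
  score <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sc <- Biostrings::pairwiseAlignment(
      seqs[i], seqs[j], type = "global", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = 2, scoreOnly = TRUE)
    score[i, j] <- sc; score[j, i] <- sc
  }
  center <- which.max(rowSums(score))
  aligned <- list()
  center_rows <- list()
  for (i in seq_len(n)) {
    if (i == center) next
    a <- Biostrings::pairwiseAlignment(
      seqs[center], seqs[i], type = "global", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = 2)
    center_rows[[length(center_rows) + 1L]] <-
      strsplit(as.character(Biostrings::alignedPattern(a)), "")[[1]]
    aligned[[length(aligned) + 1L]] <-
      strsplit(as.character(Biostrings::alignedSubject(a)), "")[[1]]
  }
  # build the union gap pattern of the center across all pairwise alignments
  merged_center <- character(0)
  pointers <- rep(1L, length(center_rows))
  center_len <- nchar(seqs[center])
  out_rows <- lapply(seq_along(aligned), function(i) character(0))
  cpos <- 1L
  repeat {
    gap_here <- vapply(seq_along(center_rows), function(i) {
      p <- pointers[i]
      p <= length(center_rows[[i]]) && center_rows[[i]][p] == "-"
    }, logical(1))
    if (any(gap_here)) {
      merged_center <- c(merged_center, "-")
      for (i in seq_along(aligned)) {
        if (gap_here[i]) {
          out_rows[[i]] <- c(out_rows[[i]], aligned[[i]][pointers[i]])
          pointers[i] <- pointers[i] + 1L
        } else out_rows[[i]] <- c(out_rows[[i]], "-")
      }
    } else {
      if (cpos > center_len) break
      merged_center <- c(merged_center, substr(seqs[center], cpos, cpos))
      for (i in seq_along(aligned)) {
        out_rows[[i]] <- c(out_rows[[i]], aligned[[i]][pointers[i]])
        pointers[i] <- pointers[i] + 1L
      }
      cpos <- cpos + 1L
    }
    if (cpos > center_len &&
        all(pointers > lengths(center_rows))) break
  }
  rows <- vapply(out_rows, paste, character(1), collapse = "")
  out <- character(length(seqs))
  out[center] <- paste(merged_center, collapse = "")
  out[setdiff(seq_along(seqs), center)] <- rows
  out
}

#' Full repeat catalogue of a control region
#'
#' @param cr A [extract_control_region()] result (or nucleotide string).
#' @param min_period,min_copies,min_identity Passed to
#'   [find_tandem_repeats()].
#' @param polyt_min Minimum poly-T tract length.
#' @param ta_min_copies Minimum TA unit count.
#' @param gc_window,gc_threshold Passed to [gc_rich_windows()].
#' @return List with elements `tandem`, `poly_t`, `ta`, `gc_rich` and the
#'   scanned `length_bp` / `at_content`.
#' @export
control_region_features <- function(cr, min_period = 10L, min_copies = 1.9,
                                    min_identity = 0.8, polyt_min = 5L,
                                    ta_min_copies = 3L, gc_window = 20L,
                                    gc_threshold = 50) {
  s <- if (inherits(cr, "control_region")) cr$sequence else cr
  list(
    tandem = find_tandem_repeats(s, min_period = min_period,
                                 min_copies = min_copies,
                                 min_identity = min_identity),
    poly_t = find_tracts(s, "T", polyt_min),
    ta = find_ta_repeats(s, ta_min_copies),
    gc_rich = if (nchar(s) >= gc_window)
      gc_rich_windows(s, gc_window, gc_threshold)
      else data.frame(start = integer(), end = integer(), length = integer()),
    length_bp = nchar(s),
    at_content = summarize_composition(s)$at_content
  )
}
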