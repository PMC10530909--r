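# Detection of tRNA-like structures in mitochondrial control regions.
#
# A control-region segment is called tRNA-like when it folds into the
# canonical four-arm cloverleaf (imperfect stem pairing allowed, G-U counted
# as a valid pair) and carries an anticodon identical to one of the genome's
# own 22 conventional tRNAs -- the anticodon-identity criterion. Hits are
# scored by global-alignment percent identity against the same-anticodon
# conventional tRNA and tiered at 65%.

encode_dna <- function(seq) {
  chartr_map <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  chars <- strsplit(gsub("U", "T", toupper(seq), fixed = TRUE), "")[[1]]
  out <- unname(chartr_map[chars])
  out[is.na(out)] <- -1L
  out
}

#' Fold a sequence into a constrained cloverleaf
#'
#' Exhaustive search over arm-boundary placements within the canonical tRNA
#' geometry: acceptor stem 7 bp, D stem 3-4 bp with a 3-12 nt loop,
#' anticodon stem 5 bp with a 7-nt loop (anticodon = central triplet),
#' variable loop 3-23 nt, T stem 4-5 bp with a 3-9 nt loop, and a 0-4 nt
#' 3' tail. The structure must span the whole input. The placement
#' maximizing the number of paired bases is returned, ties broken by fewer
#' mismatches, then leftmost anticodon.
#'
#' @param seq Nucleotide string of 50-90 nt.
#' @param max_stem_mismatch Maximum mismatches allowed in any single stem
#'   (default 1).
#' @param min_paired Minimum total paired (non-mismatch) bases (default 14).
#' @return A `cloverleaf` object, or `NULL` when no placement satisfies the
#'   constraints. Fields: `length`, arm descriptions (`acceptor`, `d_arm`,
#'   `anticodon_arm`, `t_arm`, each with stem spans and mismatch count),
#'   `variable_loop` span, `anticodon` (3-mer, DNA alphabet), `anticodon_span`,
#'   `mismatches` (total), `paired_total`, `dot_bracket`.
#' @export
fold_cloverleaf <- function(seq, max_stem_mismatch = 1L, min_paired = 14L) {
  L <- nchar(seq)
  if (L < 50 || L > 90)
    stop("sequence length must be within 50-90 nt, got ", L)
  enc <- encode_dna(seq)
  m <- cpp_cloverleaf_scan(enc, 0L, 0L, L, L,
                           as.integer(max_stem_mismatch),
                           as.integer(min_paired))
  if (nrow(m) == 0) return(NULL)
  placement_to_structure(m[1, ], seq)
}

placement_to_structure <- function(p, seq) {
  s <- gsub("U", "T", toupper(seq), fixed = TRUE)
  start <- p[["start"]]
  d <- p[["d"]]; t <- p[["t"]]
  acc5 <- start
  d5 <- acc5 + 7L + p[["s1"]]
  d3 <- d5 + d + p[["dloop"]]
  q <- d3 + d + p[["s2"]]
  r <- q + 17L + p[["v"]]
  u <- r + 2L * t + p[["tloop"]]
  span <- function(a, b) c(start = a, end = b)  # 0-based half-open
  ac_start <- p[["ac_pos"]]
  anticodon <- substr(s, ac_start + 1L, ac_start + 3L)
  # dot-bracket over the full input: paired stem positions get brackets,
  # mismatched pairs and loops are dots
  db <- rep(".", nchar(s))
  enc <- encode_dna(s)
  mark_stem <- function(a5, a3, n, db) {
    for (i in 0:(n - 1L)) {
      x <- a5 + i; y <- a3 + n - 1L - i
      if (pair_ok(enc[x + 1L], enc[y + 1L])) {
        db[x + 1L] <- "("; db[y + 1L] <- ")"
      }
    }
    db
  }
  db <- mark_stem(acc5, u, 7L, db)
  db <- mark_stem(d5, d3, d, db)
  db <- mark_stem(q, q + 12L, 5L, db)
  db <- mark_stem(r, r + t + p[["tloop"]], t, db)
  structure(list(
    length = nchar(s),
    acceptor = list(stem5 = span(acc5, acc5 + 7L), stem3 = span(u, u + 7L),
                    mismatches = p[["mm_acc"]]),
    d_arm = list(stem5 = span(d5, d5 + d), loop = span(d5 + d, d3),
                 stem3 = span(d3, d3 + d), mismatches = p[["mm_d"]]),
    anticodon_arm = list(stem5 = span(q, q + 5L), loop = span(q + 5L, q + 12L),
                         stem3 = span(q + 12L, q + 17L),
                         mismatches = p[["mm_ac"]]),
    variable_loop = span(q + 17L, r),
    t_arm = list(stem5 = span(r, r + t),
                 loop = span(r + t, r + t + p[["tloop"]]),
                 stem3 = span(r + t + p[["tloop"]], u),
                 mismatches = p[["mm_t"]]),
    tail = span(u + 7L, start + p[["len"]]),
    anticodon = anticodon,
    anticodon_span = span(ac_start, ac_start + 3L),
    mismatches = p[["mm_acc"]] + p[["mm_d"]] + p[["mm_ac"]] + p[["mm_t"]],
    paired_total = p[["paired"]],
    dot_bracket = paste(db, collapse = "")
  ), class = "cloverleaf")
}

pair_ok <- function(a, b) {
  if (a < 0 || b < 0) return(FALSE)
  (a + b == 3) || (a == 2 && b == 3) || (a == 3 && b == 2)
}

#' @export
print.cloverleaf <- function(x, ...) {
  cat(sprintf(
    "<cloverleaf> %d nt, anticodon %s @ [%d,%d), %d paired, %d mismatches\n%s\n",
    x$length, x$anticodon, x$anticodon_span["start"], x$anticodon_span["end"],
    x$paired_total, x$mismatches, x$dot_bracket))
  invisible(x)
}

#' Percent identity between a candidate and its reference tRNA
#'
#' Global (Needleman-Wunsch) alignment with match +1, mismatch -1, linear
#' gap -2; identity is matching columns over all alignment columns
#' (gap columns included in the denominator) times 100.
#'
#' @param candidate,reference Nonempty nucleotide strings.
#' @param denominator `"alignment"` (default; all alignment columns) or
#'   `"shorter"` (length of the shorter sequence).
#' @return Percent identity in \[0, 100\].
#' @export
match_percent <- function(candidate, reference,
                          denominator = c("alignment", "shorter")) {
  denominator <- match.arg(denominator)
  stopifnot(nchar(candidate) > 0, nchar(reference) > 0)
  a <- toupper(gsub("U", "T", candidate, fixed = TRUE))
  b <- toupper(gsub("U", "T", reference, fixed = TRUE))
  mat <- Biostrings::nucleotideSubstitutionMatrix(1, -1)
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ident <- sum(pa == pb & pa != "-")
  denom <- if (denominator == "alignment") length(pa)
           else min(nchar(a), nchar(b))
  100 * ident / denom
}

#' Proportion of differing sites between two sequences
#'
#' For unequal lengths the sequences are globally aligned first and gap
#' columns dropped; the p-distance is differing sites over compared sites.
#'
#' @param a,b Nucleotide strings.
#' @return Fraction in \[0, 1\].
#' @export
p_distance <- function(a, b) {
  a <- toupper(gsub("U", "T", a, fixed = TRUE))
  b <- toupper(gsub("U", "T", b, fixed = TRUE))
  if (nchar(a) != nchar(b)) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(1, -1)
    aln <- Biostrings::pairwiseAlignment(
      a, b, type = "global", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = 2)
    a <- as.character(Biostrings::alignedPattern(aln))
    b <- as.character(Biostrings::alignedSubject(aln))
  }
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  keep <- ca != "-" & cb != "-"
  if (sum(keep) == 0) stop("zero compared sites")
  sum(ca[keep] != cb[keep]) / sum(keep)
}

#' Conventional tRNA reference set of a record
#'
#' @param record A [mito_record()].
#' @return `data.frame`: `family`, `anticodon`, `sequence` (sense strand).
#' @export
trna_references <- function(record) {
  f <- record$features[record$features$role == "tRNA", ]
  data.frame(
    family = f$name,
    anticodon = f$anticodon,
    sequence = vapply(f$name, function(g) gene_sequence(record, g),
                      character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Scan a control region for tRNA-like structures
#'
#' Slides windows of `win_min`-`win_max` nt over both strands, folds each
#' into a constrained cloverleaf, and keeps candidates whose anticodon is
#' identical to a reference tRNA's (the anticodon-identity criterion).
#' Each hit is assigned the family of that reference, scored by
#' [match_percent()] and [p_distance()] against it, and tiered at 65%
#' (inclusive, on the percent rounded to one decimal). Overlapping hits are
#' greedily deduplicated keeping the highest match percent.
#'
#' @param cr A [extract_control_region()] result or nucleotide string.
#' @param references Reference tRNAs as returned by [trna_references()]
#'   (columns `family`, `anticodon`, `sequence`); must be nonempty.
#' @param win_min,win_max Window bounds in nt (defaults 55 and 90).
#' @param max_stem_mismatch,min_paired Folding constraints as in
#'   [fold_cloverleaf()], but with a stricter scanning default
#'   (`min_paired = 20`): the scanner's operating point was calibrated on a
#'   seeded A+T-rich null model so that unplanted random sequence yields
#'   essentially no calls (about 0.1 per kb); lower it to admit more heavily
#'   mismatched structures at the cost of false positives.
#' @param loop_signature Require the semi-invariant bases of genuine tRNAs
#'   (U33 immediately 5' of the anticodon, a purine at 37, T54 opening the
#'   T loop) in every candidate (default TRUE). This is the classical
#'   invariant-base constraint of tRNA gene searches; it suppresses the
#'   spurious cloverleafs that A+T-rich sequence folds by chance.
#' @param both_strands Scan the reverse complement too (default TRUE).
#' @param tier_threshold Match percent at and above which a hit is tier
#'   `"high"` (default 65).
#' @param relaxed_anticodon Non-default mode: keep any folded candidate
#'   regardless of anticodon identity (family assigned `NA` when no
#'   reference shares the anticodon).
#' @return `data.frame` of class `trna_like_hits`: `start`, `end` (0-based
#'   half-open on the forward control-region sequence), `strand`
#'   (`"forward"`/`"reverse"`), `family` (e.g. `"trnL2-like"`), `anticodon`,
#'   `match_percent`, `tier`, `p_dist`, `paired_total`, `mismatches`,
#'   `dot_bracket`; ordered by `start`.
#' @export
scan_control_region <- function(cr, references, win_min = 55L, win_max = 90L,
                                max_stem_mismatch = 1L, min_paired = 20L,
                                loop_signature = TRUE,
                                both_strands = TRUE, tier_threshold = 65,
                                relaxed_anticodon = FALSE) {
  s <- if (inherits(cr, "control_region")) cr$sequence else cr
  s <- gsub("U", "T", toupper(s), fixed = TRUE)
  if (!relaxed_anticodon && (is.null(references) || nrow(references) == 0))
    stop("references must be nonempty")
  L <- nchar(s)
  strands <- if (both_strands) c("forward", "reverse") else "forward"
  hits <- list()
  for (strand in strands) {
    sseq <- if (strand == "forward") s else reverse_complement(s)
    if (nchar(sseq) < win_min) next
    enc <- encode_dna(sseq)
    m <- cpp_cloverleaf_scan(enc, 0L, nchar(sseq) - 1L,
                             as.integer(win_min), as.integer(win_max),
                             as.integer(max_stem_mismatch),
                             as.integer(min_paired), loop_signature)
    if (nrow(m) == 0) next
    # windows sharing an anticodon anchor describe the same candidate
    # structure; within an anchor keep the placements with the most paired
    # bases and fewest mismatches, and among those tied windows let the
    # reference alignment decide the reported extent (a planted or genuine
    # copy then scores against its full span, tail included)
    df <- as.data.frame(m)
    df$mm_tot <- df$mm_acc + df$mm_d + df$mm_ac + df$mm_t
    df <- df[order(df$ac_pos, -df$paired, df$mm_tot, df$len, df$start), ,
             drop = FALSE]
    for (grp in split(df, df$ac_pos)) {
      grp <- grp[grp$paired == grp$paired[1] & grp$mm_tot == grp$mm_tot[1], ,
                 drop = FALSE]
      ac <- substr(sseq, grp$ac_pos[1] + 1L, grp$ac_pos[1] + 3L)
      ref_idx <- which(references$anticodon == ac)
      if (length(ref_idx) == 0 && !relaxed_anticodon) next
      if (length(ref_idx) > 0) {
        best_k <- 1L; best_ref <- ref_idx[1]; mpct <- -1
        for (k in seq_len(nrow(grp))) {
          cs <- substr(sseq, grp$start[k] + 1L, grp$start[k] + grp$len[k])
          mps <- vapply(ref_idx, function(j)
            match_percent(cs, references$sequence[j]), numeric(1))
          if (max(mps) > mpct + 1e-9) {
            mpct <- max(mps)
            best_k <- k
            best_ref <- ref_idx[which.max(mps)]
          }
        }
        p <- grp[best_k, ]
        cand_seq <- substr(sseq, p$start + 1L, p$start + p$len)
        fam <- paste0(references$family[best_ref], "-like")
        pd <- p_distance(cand_seq, references$sequence[best_ref])
      } else {
        p <- grp[1, ]
        cand_seq <- substr(sseq, p$start + 1L, p$start + p$len)
        fam <- NA_character_; mpct <- NA_real_; pd <- NA_real_
      }
      # map the span back to forward coordinates
      a <- p$start; b <- p$start + p$len
      if (strand == "reverse") { tmp <- a; a <- L - b; b <- L - tmp }
      hits[[length(hits) + 1L]] <- data.frame(
        start = a, end = b, strand = strand, family = fam, anticodon = ac,
        match_percent = mpct,
        tier = if (!is.na(mpct) && round(mpct, 1) >= tier_threshold)
          "high" else "low",
        p_dist = pd,
        paired_total = p$paired,
        mismatches = p$mm_tot,
        dot_bracket = local({
          p2 <- as.integer(p[1, colnames(m)])
          names(p2) <- colnames(m)
          p2[["ac_pos"]] <- p2[["ac_pos"]] - p2[["start"]]
          p2[["start"]] <- 0L
          placement_to_structure(p2, cand_seq)$dot_bracket
        }),
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0) return(empty_hit_frame())
  df <- do.call(rbind, hits)
  # greedy dedupe: best match percent first (ties: more paired, leftmost,
  # forward strand), drop anything overlapping a kept hit
  ord <- order(-ifelse(is.na(df$match_percent), -1, df$match_percent),
               -df$paired_total, df$start, df$strand)
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
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("trna_like_hits", class(df))
  df
}

empty_hit_frame <- function() {
  df <- data.frame(start = integer(), end = integer(), strand = character(),
                   family = character(), anticodon = character(),
                   match_percent = numeric(), tier = character(),
                   p_dist = numeric(), paired_total = integer(),
                   mismatches = integer(), dot_bracket = character(),
                   stringsAsFactors = FALSE)
  class(df) <- c("trna_like_hits", class(df))
  df
}

#' Census of tRNA-like families across records
#'
#' @param hits_by_record Named list mapping record identifiers to
#'   [scan_control_region()] hit frames.
#' @return List: `families` (`data.frame` with `family`, `total`,
#'   `n_records`), `n_records_with_hits`, `n_records`.
#' @export
family_census <- function(hits_by_record) {
  fams <- list()
  n_with <- 0L
  for (id in names(hits_by_record)) {
    h <- hits_by_record[[id]]
    if (!is.null(h) && nrow(h) > 0) n_with <- n_with + 1L
    for (f in unique(stats::na.omit(h$family))) {
      cnt <- sum(h$family == f, na.rm = TRUE)
      if (is.null(fams[[f]])) fams[[f]] <- c(total = 0L, n_records = 0L)
      fams[[f]]["total"] <- fams[[f]]["total"] + cnt
      fams[[f]]["n_records"] <- fams[[f]]["n_records"] + 1L
    }
  }
  if (length(fams) == 0) {
    tab <- data.frame(family = character(), total = integer(),
                      n_records = integer(), stringsAsFactors = FALSE)
  } else {
    tab <- data.frame(family = names(fams),
                      total = vapply(fams, `[[`, integer(1), "total"),
                      n_records = vapply(fams, `[[`, integer(1), "n_records"),
                      stringsAsFactors = FALSE, row.names = NULL)
    tab <- tab[order(-tab$total, tab$family), , drop = FALSE]
    rownames(tab) <- NULL
  }
  list(families = tab, n_records_with_hits = n_with,
       n_records = length(hits_by_record))
}
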