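# Pairwise Ka/Ks under Nei-Gojobori (1986) counting with Jukes-Cantor
# correction.
#
# Synonymous/nonsynonymous site fractions are computed per codon position
# over the alternative nucleotides that do not create a stop codon, so that
# S + N = 3 x (codons compared) holds exactly. Codons differing at several
# positions are resolved by averaging over all minimal mutational pathways
# with equal weights; pathways passing through a stop codon are discarded
# (if every pathway does, all are kept).

BASES <- c("A", "C", "G", "T")

# per-codon expected synonymous sites, memoized per genetic code
ng86_sites <- function(codon, code) {
  cache <- ng86_cache(code)
  hit <- cache$sites[[codon]]
  if (!is.null(hit)) return(hit)
  aa <- code$codon_to_aa[[codon]]
  s <- 0
  for (pos in 1:3) {
    alts <- alt_codons(codon, pos)
    keep <- !alts %in% code$stop_codons
    if (!any(keep)) next
    s <- s + sum(code$codon_to_aa[alts[keep]] == aa) / sum(keep)
  }
  cache$sites[[codon]] <- s
  s
}

alt_codons <- function(codon, pos) {
  b <- substr(codon, pos, pos)
  vapply(setdiff(BASES, b), function(nb) {
    x <- codon
    substr(x, pos, pos) <- nb
    x
  }, character(1))
}

# observed synonymous/nonsynonymous differences for one codon pair,
# averaged over minimal mutational pathways
ng86_pair_diffs <- function(c1, c2, code) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  key <- paste0(c1, c2)
  cache <- ng86_cache(code)
  hit <- cache$diffs[[key]]
  if (!is.null(hit)) return(hit)
  pos_diff <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  perms <- permutations_of(pos_diff)
  paths <- lapply(perms, function(ord) {
    cur <- c1
    sd <- 0; nd <- 0; valid <- TRUE
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (nxt %in% code$stop_codons) { valid <- FALSE; break }
      if (code$codon_to_aa[[cur]] == code$codon_to_aa[[nxt]]) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    list(sd = sd, nd = nd, valid = valid)
  })
  ok <- vapply(paths, `[[`, logical(1), "valid")
  use <- if (any(ok)) paths[ok] else paths
  res <- c(sd = mean(vapply(use, `[[`, numeric(1), "sd")),
           nd = mean(vapply(use, `[[`, numeric(1), "nd")))
  cache$diffs[[key]] <- res
  res
}

permutations_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in permutations_of(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

ng86_cache_store <- new.env(parent = emptyenv())
ng86_cache <- function(code) {
  key <- as.character(code$table_id)
  if (is.null(ng86_cache_store[[key]]))
    ng86_cache_store[[key]] <- list2env(
      list(sites = list(), diffs = list()), parent = emptyenv())
  ng86_cache_store[[key]]
}

jc69 <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' Nei-Gojobori pairwise Ka/Ks estimate
#'
#' @param cds_a,cds_b Equal-length, in-frame, gap-free aligned coding
#'   sequences (the caller aligns; see [gene_mean_rates()]). Codon pairs in
#'   which either codon contains an ambiguity character or is a stop codon
#'   are skipped and counted.
#' @param code A [genetic_code()].
#' @return Object of class `substitution_estimate`: `S`, `N` (expected
#'   synonymous / nonsynonymous sites, averaged over the two sequences),
#'   `Sd`, `Nd` (pathway-averaged observed differences), `ps`, `pn`
#'   (proportions), `ks`, `ka` (Jukes-Cantor corrected; `NA` with
#'   `correction_undefined = TRUE` when p >= 3/4), `omega` (`NA` when
#'   `ks` is 0 or undefined), `n_codons` compared, `n_skipped`.
#' @export
ng86_pair <- function(cds_a, cds_b, code = genetic_code(5)) {
  ca <- split_codons(cds_a)
  cb <- split_codons(cds_b)
  if (nchar(cds_a) != nchar(cds_b))
    stop("sequences must have equal length")
  usable <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb) &
    !(ca %in% code$stop_codons) & !(cb %in% code$stop_codons)
  n_skipped <- sum(!usable)
  ca <- ca[usable]; cb <- cb[usable]
  ncod <- length(ca)
  if (ncod == 0) stop("no comparable codons")
  Sa <- sum(vapply(ca, ng86_sites, numeric(1), code = code))
  Sb <- sum(vapply(cb, ng86_sites, numeric(1), code = code))
  S <- (Sa + Sb) / 2
  N <- 3 * ncod - S
  d <- vapply(seq_len(ncod), function(i)
    ng86_pair_diffs(ca[i], cb[i], code), numeric(2))
  Sd <- sum(d["sd", ]); Nd <- sum(d["nd", ])
  ps <- if (S > 0) Sd / S else NA_real_
  pn <- if (N > 0) Nd / N else NA_real_
  ks <- jc69(ps); ka <- jc69(pn)
  undef <- (!is.na(ps) && ps >= 0.75) || (!is.na(pn) && pn >= 0.75)
  omega <- if (!is.na(ks) && !is.na(ka) && ks > 0) ka / ks else NA_real_
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
                 ks = ks, ka = ka, omega = omega,
                 correction_undefined = undef,
                 n_codons = ncod, n_skipped = n_skipped),
            class = "substitution_estimate")
}

translate_codons <- function(cods, code) {
  aa <- rep("X", length(cods))
  ok <- cods %in% names(code$codon_to_aa)
  aa[ok] <- unname(code$codon_to_aa[cods[ok]])
  paste(aa, collapse = "")
}

# codon-aware pairwise alignment: amino-acid global alignment (identity
# scoring, linear gap penalty) back-threaded to codons; returns the two
# codon vectors with gap columns dropped
align_codons_pair <- function(cds_a, cds_b, code, gap = -5) {
  ca <- split_codons(cds_a); cb <- split_codons(cds_b)
  # drop terminal stop codons before aligning
  if (length(ca) > 0 && ca[length(ca)] %in% code$stop_codons) ca <- ca[-length(ca)]
  if (length(cb) > 0 && cb[length(cb)] %in% code$stop_codons) cb <- cb[-length(cb)]
  if (length(ca) == length(cb))
    return(list(a = ca, b = cb))
  aa_a <- translate_codons(ca, code)
  aa_b <- translate_codons(cb, code)
  alphabet <- unique(strsplit(paste0(aa_a, aa_b, "X*"), "")[[1]])
  mat <- matrix(-1, length(alphabet), length(alphabet),
                dimnames = list(alphabet, alphabet))
  diag(mat) <- 2
  aln <- Biostrings::pairwiseAlignment(
    aa_a, aa_b, type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = -gap)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- 0L; ib <- 0L
  outa <- character(0); outb <- character(0)
  for (k in seq_along(pa)) {
    ga <- pa[k] == "-"; gb <- pb[k] == "-"
    if (!ga) ia <- ia + 1L
    if (!gb) ib <- ib + 1L
    if (!ga && !gb) {
      outa <- c(outa, ca[ia]); outb <- c(outb, cb[ib])
    }
  }
  list(a = outa, b = outb)
}

#' Mean per-gene substitution rates across a record set
#'
#' Computes [ng86_pair()] for every unordered pair of records carrying the
#' gene (after codon-aware pairwise alignment when lengths differ) and
#' returns simple means. Pairs whose Jukes-Cantor correction is undefined
#' are excluded from the means and counted.
#'
#' @param records List of [mito_record()] objects.
#' @param gene Canonical gene token.
#' @param code A [genetic_code()].
#' @return List: `gene`, `mean_ka`, `mean_ks`, `mean_omega`, `n_pairs`,
#'   `n_excluded`.
#' @export
gene_mean_rates <- function(records, gene, code = genetic_code(5)) {
  have <- vapply(records, function(r) gene %in% r$features$name, logical(1))
  if (!any(have)) stop("gene absent from all records: ", gene)
  recs <- records[have]
  if (length(recs) < 2) stop("gene present in fewer than 2 records: ", gene)
  seqs <- lapply(recs, gene_sequence, name = gene)
  ka <- c(); ks <- c(); om <- c()
  n_excluded <- 0L
  for (i in seq_len(length(seqs) - 1)) {
    for (j in (i + 1):length(seqs)) {
      al <- align_codons_pair(seqs[[i]], seqs[[j]], code)
      if (length(al$a) == 0) { n_excluded <- n_excluded + 1L; next }
      est <- ng86_pair(paste(al$a, collapse = ""),
                       paste(al$b, collapse = ""), code)
      if (est$correction_undefined || is.na(est$ks) || is.na(est$ka)) {
        n_excluded <- n_excluded + 1L
        next
      }
      ka <- c(ka, est$ka); ks <- c(ks, est$ks)
      if (!is.na(est$omega)) om <- c(om, est$omega)
    }
  }
  list(gene = gene,
       mean_ka = if (length(ka) > 0) mean(ka) else NA_real_,
       mean_ks = if (length(ks) > 0) mean(ks) else NA_real_,
       mean_omega = if (length(om) > 0) mean(om) else NA_real_,
       n_pairs = length(ka), n_excluded = n_excluded)
}

#' Per-gene rate table across records
#'
#' @param records List of [mito_record()] objects.
#' @param genes Canonical gene tokens (default: all 13 PCGs).
#' @param code A [genetic_code()].
#' @return `data.frame`: `gene`, `mean_ka`, `mean_ks`, `mean_omega`,
#'   `n_pairs`, `n_excluded`, `gc_content` (mean per-gene G+C percent across
#'   records).
#' @export
rates_table <- function(records, genes = PCG_NAMES, code = genetic_code(5)) {
  rows <- lapply(genes, function(g) {
    r <- gene_mean_rates(records, g, code)
    gcs <- vapply(records, function(rec) {
      if (!g %in% rec$features$name) return(NA_real_)
      summarize_composition(gene_sequence(rec, g))$gc_content
    }, numeric(1))
    data.frame(gene = g, mean_ka = r$mean_ka, mean_ks = r$mean_ks,
               mean_omega = r$mean_omega, n_pairs = r$n_pairs,
               n_excluded = r$n_excluded,
               gc_content = mean(gcs, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Correlation of per-gene omega with gene G+C content
#'
#' @param omega Numeric vector of per-gene Ka/Ks values.
#' @param gc Numeric vector of per-gene G+C content, same length.
#' @return List `r2`, `p_value`, `slope_sign`, `degenerate` (TRUE when
#'   n = 2, where r-squared is 1 by construction).
#' @export
rates_vs_gc <- function(omega, gc) {
  stopifnot(length(omega) == length(gc))
  if (length(omega) == 2) {
    return(list(r2 = 1, p_value = NA_real_,
                slope_sign = sign(diff(omega) * diff(gc)), degenerate = TRUE))
  }
  c(correlate(gc, omega), list(degenerate = FALSE))
}
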