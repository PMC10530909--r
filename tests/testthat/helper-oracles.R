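# Independent oracles and fixtures shared across the suite. Each oracle is a
# direct, unoptimized implementation kept separate from the package's code
# paths.

# --- tiny handcrafted record ------------------------------------------------

# a 120 bp toy "genome": one J-strand PCG, one N-strand tRNA, one wrapped
# control region; sequence built so each feature is identifiable
make_toy_record <- function() {
  pcg <- "ATGTTTAAACCCGGGTAA"                     # 18 bp: ATG..TAA
  trna_sense <- paste0(strrep("GA", 10), "TAGCA") # arbitrary 25-mer
  filler <- strrep("ACGT", 10)
  cr_tail <- strrep("AT", 10)                     # wraps: 12 bp tail + 8 head
  cr_head <- "TTTTAAAA"
  genome <- paste0(cr_head, pcg, filler,
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(trna_sense))),
                   strrep("C", 9), cr_tail)
  L <- nchar(genome)
  feats <- data.frame(
    name = c("cox1", "trnW", "control_region"),
    start = c(8L, 8L + 18L + 40L, L - 20L),
    end = c(8L + 18L, 8L + 18L + 40L + 25L, 8L),
    wrap = c(FALSE, FALSE, TRUE),
    strand = c("J", "N", "J"),
    anticodon = c(NA, "TCA", NA),
    stringsAsFactors = FALSE)
  mito_record("TOY1", "toy organism", genome, feats)
}

random_dna_str <- function(n, probs = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

at_rich_dna <- function(n, at = 0.85) {
  random_dna_str(n, c(A = at / 2, T = at / 2, G = (1 - at) / 2,
                      C = (1 - at) / 2))
}

# --- RSCU / homozygosity by naive enumeration -------------------------------

oracle_rscu <- function(counts_vec, code) {
  out <- numeric(0)
  for (aa in names(code$families)) {
    fam <- code$families[[aa]]
    tot <- 0
    for (cd in fam) tot <- tot + counts_vec[[cd]]
    for (cd in fam) {
      out[cd] <- if (tot == 0) 0 else length(fam) * counts_vec[[cd]] / tot
    }
  }
  out[names(counts_vec)]
}

oracle_fhat <- function(counts_vec, code) {
  out <- numeric(0)
  for (aa in names(code$families)) {
    fam <- code$families[[aa]]
    n <- sum(vapply(fam, function(cd) counts_vec[[cd]], numeric(1)))
    if (n < 2) next
    sp2 <- 0
    for (cd in fam) sp2 <- sp2 + (counts_vec[[cd]] / n)^2
    out[aa] <- (n * sp2 - 1) / (n - 1)
  }
  out
}

# --- NG86 by direct recursion ------------------------------------------------

oracle_ng86 <- function(a, b, code) {
  codons <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  ca <- codons(a); cb <- codons(b)
  aa_of <- function(cd) code$codon_to_aa[[cd]]
  is_stop <- function(cd) cd %in% code$stop_codons
  site_s <- function(cd) {
    s <- 0
    for (pos in 1:3) {
      syn <- 0; tot <- 0
      for (nb in c("A", "C", "G", "T")) {
        if (nb == substr(cd, pos, pos)) next
        alt <- cd; substr(alt, pos, pos) <- nb
        if (is_stop(alt)) next
        tot <- tot + 1
        if (aa_of(alt) == aa_of(cd)) syn <- syn + 1
      }
      if (tot > 0) s <- s + syn / tot
    }
    s
  }
  # enumerate pathways recursively
  paths <- function(cur, target) {
    dif <- which(strsplit(cur, "")[[1]] != strsplit(target, "")[[1]])
    if (length(dif) == 0)
      return(list(list(sd = 0, nd = 0, valid = TRUE)))
    out <- list()
    for (pos in dif) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(target, pos, pos)
      if (is_stop(nxt)) {
        # every completion of this branch is invalid
        n_rest <- factorial(length(dif) - 1)
        for (k in seq_len(n_rest))
          out[[length(out) + 1]] <- list(sd = NA, nd = NA, valid = FALSE)
        next
      }
      step_syn <- aa_of(cur) == aa_of(nxt)
      for (rest in paths(nxt, target)) {
        out[[length(out) + 1]] <- list(
          sd = if (rest$valid) rest$sd + as.numeric(step_syn) else NA,
          nd = if (rest$valid) rest$nd + as.numeric(!step_syn) else NA,
          valid = rest$valid)
      }
    }
    out
  }
  S <- 0; Sd <- 0; Nd <- 0; ncmp <- 0
  for (i in seq_along(ca)) {
    if (is_stop(ca[i]) || is_stop(cb[i])) next
    if (grepl("[^ACGT]", ca[i]) || grepl("[^ACGT]", cb[i])) next
    ncmp <- ncmp + 1
    S <- S + (site_s(ca[i]) + site_s(cb[i])) / 2
    pp <- paths(ca[i], cb[i])
    ok <- Filter(function(p) p$valid, pp)
    use <- if (length(ok) > 0) ok else lapply(pp, function(p) {
      # all-stop fallback: recompute ignoring validity
      p
    })
    if (length(ok) == 0) {
      # recompute all pathways counting through stops
      perms <- function(v) {
        if (length(v) <= 1) return(list(v))
        out <- list()
        for (ii in seq_along(v))
          for (r in perms(v[-ii])) out[[length(out) + 1]] <- c(v[ii], r)
        out
      }
      dif <- which(strsplit(ca[i], "")[[1]] != strsplit(cb[i], "")[[1]])
      use <- lapply(perms(dif), function(ord) {
        cur <- ca[i]; sd <- 0; nd <- 0
        for (pos in ord) {
          nxt <- cur; substr(nxt, pos, pos) <- substr(cb[i], pos, pos)
          if (aa_of(cur) == aa_of(nxt)) sd <- sd + 1 else nd <- nd + 1
          cur <- nxt
        }
        list(sd = sd, nd = nd, valid = TRUE)
      })
    }
    Sd <- Sd + mean(vapply(use, `[[`, numeric(1), "sd"))
    Nd <- Nd + mean(vapply(use, `[[`, numeric(1), "nd"))
  }
  N <- 3 * ncmp - S
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd,
       ks = jc(Sd / S), ka = jc(Nd / N))
}

# --- tandem repeats by all-(start, period) enumeration ----------------------

oracle_tandem <- function(s, min_period, min_copies, min_identity,
                          max_period = nchar(s) %/% 2L) {
  chars <- strsplit(toupper(s), "")[[1]]
  L <- length(chars)
  cand <- list()
  for (p in seq(min_period, max_period)) {
    if (2 * p > L) break
    m <- logical(L - p)
    for (k in seq_len(L - p)) m[k] <- chars[k + p] == chars[k]
    # one candidate per seed: best-scoring end under the identity floor
    seeds <- list()
    for (a in seq_len(L - p)) {
      if (!m[a]) next
      best_e <- a; best_score <- -Inf
      for (e in a:(L - p)) {
        if (!m[e]) next
        matches <- sum(m[a:e])
        if (matches / (e - a + 1) < min_identity) next
        score <- 2 * matches - (e - a + 1)
        if (score > best_score) { best_score <- score; best_e <- e }
      }
      if ((best_e + p - a + 1) / p < min_copies) next
      seeds[[length(seeds) + 1]] <- c(a = a, e = best_e, score = best_score,
                                      ident = mean(m[a:best_e]))
    }
    # greedy non-overlapping selection by descending score, then identity
    if (length(seeds) > 0) {
      sm <- do.call(rbind, seeds)
      sm <- sm[order(-sm[, "score"], -sm[, "ident"], sm[, "a"],
                     -sm[, "e"]), , drop = FALSE]
      kept <- list()
      for (i in seq_len(nrow(sm))) {
        a <- unname(sm[i, "a"]); e <- unname(sm[i, "e"])
        clash <- FALSE
        for (r in kept)
          if (a - 1 < r["e"] + p && r["a"] - 1 < e + p) clash <- TRUE
        if (clash) next
        kept[[length(kept) + 1]] <- c(a = a, e = e)
        cand[[length(cand) + 1]] <- data.frame(
          kind = "tandem", unit = paste(chars[a:(a + p - 1)], collapse = ""),
          period = p, copies = (e + p - a + 1) / p, start = a - 1L,
          end = e + p, identity = mean(m[a:e]), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(cand) == 0) return(NULL)
  df <- do.call(rbind, cand)
  # keep best of overlapping pairs by copies * identity (ties: smaller
  # period, then leftmost)
  ord <- order(-(df$copies * df$identity), df$period, df$start)
  df <- df[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!keep[i] || i == nrow(df)) next
    for (j in (i + 1):nrow(df)) {
      if (keep[j] && df$start[j] < df$end[i] && df$start[i] < df$end[j])
        keep[j] <- FALSE
    }
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$start, df$period), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# --- cloverleaf by exhaustive placement enumeration -------------------------

oracle_cloverleaf <- function(s, max_stem_mismatch = 1, min_paired = 14) {
  code <- c(A = 0, C = 1, G = 2, T = 3)
  x <- unname(code[strsplit(toupper(s), "")[[1]]])
  x[is.na(x)] <- -1
  L <- length(x)
  ok_pair <- function(a, b) {
    if (is.na(a) || is.na(b) || a < 0 || b < 0) return(FALSE)
    (a + b == 3) || (a == 2 && b == 3) || (a == 3 && b == 2)
  }
  stem_mm <- function(i5, i3, n) {
    mm <- 0
    for (k in 0:(n - 1))
      if (!ok_pair(x[i5 + k + 1], x[i3 + n - k])) mm <- mm + 1
    mm
  }
  best <- NULL
  for (s1 in 1:3) for (d in 3:4) for (dl in 3:12) for (s2 in 0:2)
    for (v in 3:23) for (t in 4:5) for (tl in 3:9) for (tail in 0:4) {
      total <- 7 + s1 + 2 * d + dl + s2 + 17 + v + 2 * t + tl + 7 + tail
      if (total != L) next
      d5 <- 7 + s1
      d3 <- d5 + d + dl
      q <- d3 + d + s2
      r <- q + 17 + v
      u <- r + 2 * t + tl
      mmA <- stem_mm(0, u, 7)
      mmD <- stem_mm(d5, d3, d)
      mmC <- stem_mm(q, q + 12, 5)
      mmT <- stem_mm(r, r + t + tl, t)
      if (max(mmA, mmD, mmC, mmT) > max_stem_mismatch) next
      paired <- (7 - mmA) + (d - mmD) + (5 - mmC) + (t - mmT)
      if (paired < min_paired) next
      mm <- mmA + mmD + mmC + mmT
      ac <- q + 7
      cand <- list(paired = paired, mm = mm, ac = ac,
                   anticodon = substr(toupper(s), ac + 1, ac + 3))
      if (is.null(best) || cand$paired > best$paired ||
          (cand$paired == best$paired && cand$mm < best$mm) ||
          (cand$paired == best$paired && cand$mm == best$mm &&
           cand$ac < best$ac))
        best <- cand
    }
  best
}
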