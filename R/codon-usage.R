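# Codon usage bias under the invertebrate mitochondrial code.
#
# RSCU, Wright's effective number of codons (ENC) generalized to the family
# size structure of the code in use, the Bennetzen-Hall codon bias index
# (CBI), and the ENC-plot null expectation ENC*(GC3).

split_codons <- function(cds) {
  s <- gsub("U", "T", toupper(cds), fixed = TRUE)
  ncod <- nchar(s) %/% 3L
  if (ncod == 0) return(character(0))
  substring(s, seq(1L, by = 3L, length.out = ncod),
            seq(3L, by = 3L, length.out = ncod))
}

#' Count sense codons across a set of coding sequences
#'
#' Each CDS is read in frame 0. Trailing partial codons and a terminal stop
#' codon are dropped; internal stop codons and codons containing ambiguity
#' characters are excluded from the counts and tallied in diagnostics.
#'
#' @param cds_list Character vector or list of in-frame nucleotide strings.
#' @param code A [genetic_code()].
#' @return Object of class `codon_counts`: `counts` (named integer over the
#'   sense codons), `total`, and `diagnostics` (`internal_stops`,
#'   `ambiguous_codons`).
#' @export
count_codons <- function(cds_list, code = genetic_code(5)) {
  counts <- stats::setNames(integer(length(code$sense_codons)),
                            code$sense_codons)
  internal_stops <- 0L
  ambiguous <- 0L
  for (cds in cds_list) {
    cods <- split_codons(cds)
    n <- length(cods)
    if (n == 0) next
    if (cods[n] %in% code$stop_codons) cods <- cods[-n]
    ok <- grepl("^[ACGT]{3}$", cods)
    ambiguous <- ambiguous + sum(!ok)
    cods <- cods[ok]
    is_stop <- cods %in% code$stop_codons
    internal_stops <- internal_stops + sum(is_stop)
    cods <- cods[!is_stop]
    tab <- table(cods)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  structure(list(counts = counts, total = sum(counts),
                 diagnostics = list(internal_stops = internal_stops,
                                    ambiguous_codons = ambiguous)),
            class = "codon_counts")
}

#' Relative synonymous codon usage
#'
#' RSCU of codon c is its observed count divided by the mean count of its
#' synonymous family: `family_size * count_c / family_total`. A family with
#' zero total usage gets RSCU 0 for all members, so that within every family
#' with nonzero usage the RSCU values sum to the family size.
#'
#' @param counts A [count_codons()] result.
#' @param code A [genetic_code()].
#' @return Named numeric vector over the sense codons.
#' @export
rscu <- function(counts, code = genetic_code(5)) {
  out <- stats::setNames(numeric(length(code$sense_codons)),
                         code$sense_codons)
  for (fam in code$families) {
    tot <- sum(counts$counts[fam])
    if (tot > 0) out[fam] <- length(fam) * counts$counts[fam] / tot
  }
  out
}

#' Effective number of codons (ENC)
#'
#' Wright's ENC generalized to the synonymous-family size structure of the
#' genetic code in use. Under the invertebrate mitochondrial code the size
#' classes are 2-, 4-, 6- and 8-fold (serine spans TCN plus AGN) and there is
#' no single-codon class, so the maximum is the sense-codon count, 62. Per
#' amino acid with n >= `min_family_n` codons the homozygosity is
#' F = (n * sum(p^2) - 1)/(n - 1); F is averaged within each size class and
#' ENC = sum over classes of (number of families in class) / mean F. A size
#' class with no measurable family is imputed by interpolation from the
#' adjacent available classes (Wright's averaging rule). The result is
#' clamped to [2, sense-codon count].
#'
#' @param counts A [count_codons()] result.
#' @param code A [genetic_code()].
#' @param min_family_n Minimum codon count for a family to contribute
#'   (default 2, as in Wright's estimator).
#' @return ENC value (numeric scalar).
#' @export
enc <- function(counts, code = genetic_code(5), min_family_n = 2L) {
  if (counts$total == 0) stop("record with zero codons")
  sizes <- lengths(code$families)
  by_size <- split(names(code$families), sizes)
  size_levels <- sort(as.integer(names(by_size)))
  # single-codon families contribute their count directly
  n_single <- sum(sizes == 1L)
  fbar <- numeric(0)
  nfam <- integer(0)
  for (k in size_levels) {
    if (k == 1L) next
    fams <- by_size[[as.character(k)]]
    fvals <- numeric(0)
    for (aa in fams) {
      cod <- code$families[[aa]]
      n <- sum(counts$counts[cod])
      if (n < min_family_n) next
      p <- counts$counts[cod] / n
      f <- (n * sum(p^2) - 1) / (n - 1)
      if (f > 0) fvals <- c(fvals, f)
    }
    fbar[as.character(k)] <- if (length(fvals) > 0) mean(fvals) else NA_real_
    nfam[as.character(k)] <- length(fams)
  }
  # impute missing classes from adjacent available classes
  miss <- which(is.na(fbar))
  if (length(miss) == length(fbar)) stop("no family has enough codons for ENC")
  for (i in miss) {
    avail <- which(!is.na(fbar))
    lower <- avail[avail < i]
    upper <- avail[avail > i]
    neigh <- c(if (length(lower) > 0) max(lower), if (length(upper) > 0) min(upper))
    fbar[i] <- mean(fbar[neigh])
  }
  val <- n_single + sum(nfam / fbar)
  min(max(val, 2), code$sense_codon_count)
}

#' Codon bias index (CBI)
#'
#' Bennetzen-Hall CBI: `(N_pref - N_rand) / (N_total - N_rand)` over the
#' degenerate (size >= 2) families, where `N_pref` counts codons belonging to
#' the preferred set and `N_rand` is the count expected if usage were uniform
#' within each family. By default the preferred codon of each family is the
#' modal codon of the record itself (ties broken alphabetically); a fixed
#' preferred set can be supplied for sensitivity analysis.
#'
#' @param counts A [count_codons()] result.
#' @param code A [genetic_code()].
#' @param preferred Optional character vector naming one preferred codon per
#'   degenerate family; default `NULL` uses the record's modal codons.
#' @return CBI value: 0 under uniform usage, 1 when each family uses a
#'   single codon.
#' @export
cbi <- function(counts, code = genetic_code(5), preferred = NULL) {
  fams <- code$families[lengths(code$families) >= 2L]
  n_tot <- 0
  n_pref <- 0
  n_rand <- 0
  for (aa in names(fams)) {
    cod <- fams[[aa]]
    n <- sum(counts$counts[cod])
    if (n == 0) next
    pref <- if (is.null(preferred)) {
      cs <- counts$counts[cod]
      sort(cod[cs == max(cs)])[1]
    } else {
      p <- intersect(preferred, cod)
      if (length(p) != 1)
        stop("preferred set must name exactly one codon in family ", aa)
      p
    }
    n_tot <- n_tot + n
    n_pref <- n_pref + counts$counts[[pref]]
    n_rand <- n_rand + n / length(cod)
  }
  if (n_tot == 0) stop("zero degenerate-codon usage")
  (n_pref - n_rand) / (n_tot - n_rand)
}

#' ENC-plot null expectation
#'
#' Expected ENC under composition alone as a function of GC3:
#' `ENC* = 2 + gc3 + 29 / (gc3^2 + (1 - gc3)^2)`.
#'
#' @param gc3 G+C fraction at third codon positions, in \[0, 1\].
#' @return Expected ENC.
#' @examples
#' enc_expected(0.5)  # 60.5
#' @export
enc_expected <- function(gc3) {
  stopifnot(all(gc3 >= 0 & gc3 <= 1))
  2 + gc3 + 29 / (gc3^2 + (1 - gc3)^2)
}

#' Pearson correlation with r-squared and p-value
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return List `r2`, `p_value`, `slope_sign` (+1/-1/0). A constant vector
#'   yields an explicit undefined result (`r2 = NA`).
#' @export
correlate <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r2 = NA_real_, p_value = NA_real_, slope_sign = NA_integer_))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r2 = unname(ct$estimate)^2, p_value = ct$p.value,
       slope_sign = sign(unname(ct$estimate)))
}

#' Per-record codon-usage statistics
#'
#' Pools all 13 protein-coding genes of a record (frame 0, terminal stops
#' dropped) and computes the full usage-bias panel.
#'
#' @param record A [mito_record()].
#' @param code A [genetic_code()].
#' @return Object of class `usage_stats`: `accession`, `counts`
#'   (`codon_counts`), `rscu`, `enc`, `cbi`, `gc`, `gc3`, `gc12` (percent),
#'   `enc_expected` (ENC* at the observed GC3), `n_codons`,
#'   `n_distinct_codons`.
#' @export
usage_stats <- function(record, code = genetic_code(5)) {
  pcgs <- record$features$name[record$features$role == "PCG"]
  if (length(pcgs) == 0) stop("record has no PCGs")
  cds <- vapply(pcgs, function(g) gene_sequence(record, g), character(1))
  counts <- count_codons(cds, code)
  # positional composition over the pooled coding codons
  pooled <- paste(vapply(cds, function(s)
    substr(s, 1L, 3L * (nchar(s) %/% 3L)), character(1)), collapse = "")
  pc <- positional_composition(pooled)
  gc_all <- mean(c(pc$gc1, pc$gc2, pc$gc3))
  structure(list(
    accession = record$accession,
    counts = counts,
    rscu = rscu(counts, code),
    enc = enc(counts, code),
    cbi = cbi(counts, code),
    gc = gc_all, gc3 = pc$gc3, gc12 = pc$gc12,
    enc_expected = enc_expected(pc$gc3 / 100),
    n_codons = counts$total,
    n_distinct_codons = sum(counts$counts > 0)
  ), class = "usage_stats")
}

#' Codon-usage table for a set of records
#'
#' @param records List of [mito_record()] objects.
#' @param code A [genetic_code()].
#' @return `data.frame`: `accession`, `n_codons`, `n_distinct_codons`,
#'   `enc`, `cbi`, `gc`, `gc3`, `gc12`, `enc_expected`.
#' @export
usage_table <- function(records, code = genetic_code(5)) {
  rows <- lapply(records, function(r) {
    u <- usage_stats(r, code)
    data.frame(accession = u$accession, n_codons = u$n_codons,
               n_distinct_codons = u$n_distinct_codons, enc = u$enc,
               cbi = u$cbi, gc = u$gc, gc3 = u$gc3, gc12 = u$gc12,
               enc_expected = u$enc_expected, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
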