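# Deterministic synthetic mitogenome generator.
#
# Emulates the organization of a tenebrionid (darkling beetle) mitogenome:
# a circular 15-16 kb molecule with 13 protein-coding genes, 22 tRNAs and 2
# rRNAs in the typical invertebrate gene order, a 23/14 majority/minority
# (J/N) strand split, strong A+T bias, and a control region between rrnS and
# trnI that can carry planted tandem repeats and tRNA-like copies of the
# genome's own tRNAs mutated at a controlled rate. Every generated tRNA is
# built from the cloverleaf template with perfectly complementary stems, so
# it folds with zero mismatches by construction.

# typical invertebrate mitochondrial gene order with strand and PCG lengths
GENE_ORDER <- data.frame(
  name = c("trnI", "trnQ", "trnM", "nad2", "trnW", "trnC", "trnY", "cox1",
           "trnL2", "cox2", "trnK", "trnD", "atp8", "atp6", "cox3", "trnG",
           "nad3", "trnA", "trnR", "trnN", "trnS1", "trnE", "trnF", "nad5",
           "trnH", "nad4", "nad4L", "trnT", "trnP", "nad6", "cob", "trnS2",
           "nad1", "trnL1", "rrnL", "trnV", "rrnS"),
  strand = c("J", "N", "J", "J", "J", "N", "N", "J", "J", "J", "J", "J",
             "J", "J", "J", "J", "J", "J", "J", "J", "J", "J", "N", "N",
             "N", "N", "N", "J", "N", "J", "J", "J", "N", "N", "N", "N",
             "N"),
  length = c(NA, NA, NA, 1023L, NA, NA, NA, 1536L, NA, 684L, NA, NA, 159L,
             678L, 789L, NA, 354L, NA, NA, NA, NA, NA, NA, 1719L, NA,
             1341L, 291L, NA, NA, 522L, 1137L, NA, 936L, NA, 1280L, NA,
             780L),
  stringsAsFactors = FALSE)

# anticodons (DNA alphabet) of the 22 conventional tRNAs
TRNA_ANTICODONS <- c(
  trnI = "GAT", trnQ = "TTG", trnM = "CAT", trnW = "TCA", trnC = "GCA",
  trnY = "GTA", trnL2 = "TAA", trnK = "CTT", trnD = "GTC", trnG = "TCC",
  trnA = "TGC", trnR = "TCG", trnN = "GTT", trnS1 = "GCT", trnE = "TTC",
  trnF = "GAA", trnH = "GTG", trnT = "TGT", trnP = "TGG", trnS2 = "TGA",
  trnL1 = "TAG", trnV = "TAC")

WC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Simulation configuration
#'
#' Defaults reflect the structure observed across tenebrionid mitogenomes:
#' genome A+T content 71%, AT-skew 0.11, GC-skew -0.26 (J strand), a 1000 bp
#' control region at 85% A+T, and 33-species cohorts.
#'
#' @param seed Integer RNG seed.
#' @param genome_at Genome A+T fraction (default 0.71).
#' @param genome_at_skew J-strand AT-skew (default 0.11).
#' @param genome_gc_skew J-strand GC-skew (default -0.26).
#' @param cr_length Control-region length in bp (default 1000).
#' @param cr_at Control-region A+T fraction (default 0.85).
#' @param planted_trnas List of lists with fields `family`, `mutation_rate`,
#'   and optional `position` (0-based offset within the control region).
#' @param tandem_plants List of lists with fields `unit`, `copies`, and
#'   optional `position`.
#' @param n_species Cohort size for [evolve_cohort()] (default 33).
#' @param branch_rate Per-site, per-branch substitution rate for cohort
#'   evolution (default 0.05).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, genome_at = 0.71,
                              genome_at_skew = 0.11, genome_gc_skew = -0.26,
                              cr_length = 1000L, cr_at = 0.85,
                              planted_trnas = list(), tandem_plants = list(),
                              n_species = 33L, branch_rate = 0.05) {
  stopifnot(genome_at >= 0, genome_at <= 1, cr_at >= 0, cr_at <= 1,
            cr_length > 0)
  for (p in planted_trnas)
    if (!is.null(p$position) && p$position >= cr_length)
      stop("planted tRNA position outside control region")
  for (p in tandem_plants)
    if (!is.null(p$position) && p$position >= cr_length)
      stop("tandem plant position outside control region")
  structure(list(seed = as.integer(seed), genome_at = genome_at,
                 genome_at_skew = genome_at_skew,
                 genome_gc_skew = genome_gc_skew,
                 cr_length = as.integer(cr_length), cr_at = cr_at,
                 planted_trnas = planted_trnas,
                 tandem_plants = tandem_plants,
                 n_species = as.integer(n_species),
                 branch_rate = branch_rate),
            class = "simulation_config")
}

base_probs <- function(at, at_skew, gc_skew) {
  gc <- 1 - at
  c(A = at * (1 + at_skew) / 2, T = at * (1 - at_skew) / 2,
    G = gc * (1 + gc_skew) / 2, C = gc * (1 - gc_skew) / 2)
}

random_dna <- function(n, probs) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

# sample ncod sense codons (no stops) weighted by independent per-base probs
sample_codons <- function(ncod, probs, code) {
  cods <- code$sense_codons
  w <- vapply(cods, function(cd) {
    b <- strsplit(cd, "")[[1]]
    probs[[b[1]]] * probs[[b[2]]] * probs[[b[3]]]
  }, numeric(1))
  sample(cods, ncod, replace = TRUE, prob = w / sum(w))
}

# build one tRNA from the cloverleaf template: perfectly complementary
# stems (Watson-Crick only, so pairing is exact), designed anticodon, and
# the semi-invariant bases of real tRNAs (U33 before the anticodon, purine
# 37 after it, T54 opening the T loop)
build_trna <- function(anticodon, probs) {
  rand <- function(n) strsplit(random_dna(n, probs), "")[[1]]
  acc5 <- rand(7)
  d5 <- rand(4)
  ac5 <- rand(5)
  t5 <- rand(5)
  rc <- function(x) rev(unname(WC_COMPLEMENT[x]))
  paste(c(acc5, rand(2), d5, rand(8), rc(d5), rand(1),
          ac5, rand(1), "T", strsplit(anticodon, "")[[1]],
          sample(c("A", "G"), 1), rand(1), rc(ac5),
          rand(4), t5, "T", "T", "C", rand(4), rc(t5), rc(acc5), rand(1)),
        collapse = "")
}

#' Generate a synthetic annotated mitogenome
#'
#' @param config A [simulation_config()]. The same seed yields a
#'   byte-identical record.
#' @return A [mito_record()] with 37 genes plus a control_region feature in
#'   the typical invertebrate order; every PCG starts ATN, ends TAA and has
#'   no internal stops under the invertebrate mitochondrial code. A ground
#'   truth manifest of planted control-region features is attached as
#'   `attr(record, "manifest")`.
#' @export
generate_mitogenome <- function(config = simulation_config()) {
  set.seed(config$seed)
  code <- genetic_code(5)
  probs <- base_probs(config$genome_at, config$genome_at_skew,
                      config$genome_gc_skew)
  # genes on the minority strand are reverse-complemented into the genome,
  # so their sense content is sampled with mirrored skews to preserve the
  # configured J-strand asymmetry
  probs_n <- base_probs(config$genome_at, -config$genome_at_skew,
                        -config$genome_gc_skew)
  cr_probs <- base_probs(config$cr_at, config$genome_at_skew, 0)
  pieces <- character(0)
  feats <- list()
  pos <- 0L
  anticodons <- list()
  for (i in seq_len(nrow(GENE_ORDER))) {
    g <- GENE_ORDER[i, ]
    role <- role_of_name(g$name)
    p_gene <- if (g$strand == "N") probs_n else probs
    if (role == "PCG") {
      ncod <- g$length %/% 3L
      cods <- sample_codons(ncod - 2L, p_gene, code)
      sense <- paste(c(sample(c("ATG", "ATA", "ATT"), 1), cods, "TAA"),
                     collapse = "")
    } else if (role == "tRNA") {
      sense <- build_trna(TRNA_ANTICODONS[[g$name]], p_gene)
    } else {
      sense <- random_dna(g$length, p_gene)
    }
    placed <- if (g$strand == "N") reverse_complement(sense) else sense
    feats[[length(feats) + 1L]] <- data.frame(
      name = g$name, start = pos, end = pos + nchar(placed), wrap = FALSE,
      strand = g$strand,
      anticodon = if (role == "tRNA") TRNA_ANTICODONS[[g$name]]
                  else NA_character_,
      stringsAsFactors = FALSE)
    pieces <- c(pieces, placed)
    pos <- pos + nchar(placed)
    # short intergenic spacer; the trnS2-nad1 junction gets a larger one
    nxt <- if (i < nrow(GENE_ORDER)) GENE_ORDER$name[i + 1] else NA
    gap <- if (identical(g$name, "trnS2")) 18L else sample(0:3, 1)
    if (!is.na(nxt) && gap > 0) {
      pieces <- c(pieces, random_dna(gap, probs))
      pos <- pos + gap
    }
  }
  # control region between rrnS and trnI closes the circle
  cr_seq <- random_dna(config$cr_length, cr_probs)
  feats[[length(feats) + 1L]] <- data.frame(
    name = "control_region", start = pos, end = pos + config$cr_length,
    wrap = FALSE, strand = "J", anticodon = NA_character_,
    stringsAsFactors = FALSE)
  pieces <- c(pieces, cr_seq)
  record <- mito_record(
    accession = sprintf("SYN%07d", config$seed),
    organism = "synthetic tenebrionid mitogenome",
    sequence = paste(pieces, collapse = ""),
    features = do.call(rbind, feats))
  manifest <- list()
  for (p in config$tandem_plants) {
    res <- plant_tandem_repeat(record, p$unit, p$copies,
                               position = p$position)
    record <- res$record
    manifest[[length(manifest) + 1L]] <- res$manifest
  }
  for (p in config$planted_trnas) {
    res <- plant_trna_like(record, p$family, p$mutation_rate,
                           position = p$position)
    record <- res$record
    manifest[[length(manifest) + 1L]] <- res$manifest
  }
  attr(record, "manifest") <- if (length(manifest) > 0)
    do.call(rbind, manifest) else NULL
  record
}

cr_feature_index <- function(record) {
  i <- which(record$features$name == "control_region")
  if (length(i) == 0) stop("record has no control_region feature")
  i[1]
}

replace_cr_segment <- function(record, offset, replacement) {
  i <- cr_feature_index(record)
  f <- record$features[i, ]
  cr_len <- feature_span_length(f, record$length_bp)
  if (offset + nchar(replacement) > cr_len)
    stop("replacement does not fit in the control region")
  gstart <- (f$start + offset) %% record$length_bp
  s <- record$sequence
  gend <- gstart + nchar(replacement)
  if (gend <= record$length_bp) {
    substr(s, gstart + 1L, gend) <- replacement
  } else {
    head_len <- record$length_bp - gstart
    substr(s, gstart + 1L, record$length_bp) <-
      substr(replacement, 1L, head_len)
    substr(s, 1L, gend - record$length_bp) <-
      substr(replacement, head_len + 1L, nchar(replacement))
  }
  record$sequence <- s
  record
}

#' Plant a mutated tRNA copy into the control region
#'
#' Copies the named conventional tRNA into the control region and mutates
#' its non-anticodon positions i.i.d. at `mutation_rate` (each mutated base
#' drawn uniformly from the other three). The anticodon triplet is never
#' touched, honoring the anticodon-identity criterion used downstream.
#'
#' @param record A [mito_record()] with a control_region feature.
#' @param family tRNA family among the record's 22 tRNAs.
#' @param mutation_rate Per-base substitution probability in \[0, 1\].
#' @param position 0-based offset within the control region (default:
#'   drawn uniformly from the feasible range).
#' @param seed Optional seed applied before mutation draws.
#' @return List `record` (modified copy) and `manifest` (one-row
#'   `data.frame`: `kind`, `family`, `anticodon`, `cr_start`, `cr_end`,
#'   `mutation_rate`, `n_mutated`).
#' @export
plant_trna_like <- function(record, family, mutation_rate, position = NULL,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!family %in% record$features$name)
    stop("family absent from record: ", family)
  trna_seq <- gene_sequence(record, family)
  fi <- which(record$features$name == family)[1]
  anticodon <- record$features$anticodon[fi]
  # locate the anticodon within the tRNA via the folder; fall back to the
  # first occurrence of the triplet
  st <- tryCatch(fold_cloverleaf(trna_seq), error = function(e) NULL)
  ac_at <- if (!is.null(st) && st$anticodon == anticodon)
    st$anticodon_span[["start"]]
  else as.integer(regexpr(anticodon, trna_seq, fixed = TRUE)) - 1L
  if (ac_at < 0) stop("cannot locate anticodon in ", family)
  chars <- strsplit(trna_seq, "")[[1]]
  protected <- seq(ac_at + 1L, ac_at + 3L)
  mutate <- which(stats::runif(length(chars)) < mutation_rate)
  mutate <- setdiff(mutate, protected)
  for (k in mutate)
    chars[k] <- sample(setdiff(c("A", "C", "G", "T"), chars[k]), 1)
  planted <- paste(chars, collapse = "")
  i <- cr_feature_index(record)
  cr_len <- feature_span_length(record$features[i, ], record$length_bp)
  max_off <- cr_len - nchar(planted)
  if (max_off < 0) stop("control region shorter than the planted tRNA")
  if (is.null(position)) position <- sample(0:max_off, 1)
  record <- replace_cr_segment(record, position, planted)
  list(record = record,
       manifest = data.frame(
         kind = "trna_like", family = family, anticodon = anticodon,
         cr_start = position, cr_end = position + nchar(planted),
         mutation_rate = mutation_rate, n_mutated = length(mutate),
         stringsAsFactors = FALSE))
}

#' Plant a perfect tandem repeat into the control region
#'
#' @param record A [mito_record()] with a control_region feature.
#' @param unit Repeat unit string.
#' @param copies Number of copies (may be fractional).
#' @param position 0-based offset within the control region (default:
#'   uniform over the feasible range).
#' @param seed Optional seed.
#' @return List `record` and one-row `manifest`.
#' @export
plant_tandem_repeat <- function(record, unit, copies, position = NULL,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  unit <- toupper(unit)
  total <- floor(nchar(unit) * copies)
  rep_seq <- substr(paste(rep(unit, ceiling(copies)), collapse = ""),
                    1L, total)
  i <- cr_feature_index(record)
  cr_len <- feature_span_length(record$features[i, ], record$length_bp)
  max_off <- cr_len - total
  if (max_off < 0) stop("control region shorter than the repeat array")
  if (is.null(position)) position <- sample(0:max_off, 1)
  record <- replace_cr_segment(record, position, rep_seq)
  list(record = record,
       manifest = data.frame(
         kind = "tandem", family = NA_character_, anticodon = NA_character_,
         cr_start = position, cr_end = position + total,
         mutation_rate = 0, n_mutated = 0L, stringsAsFactors = FALSE))
}

#' Evolve a star-phylogeny cohort from an ancestor record
#'
#' Each descendant is an independent copy of the ancestor whose
#' protein-coding genes accumulate substitutions at `rate` per site.
#' Proposals are biased between synonymous and nonsynonymous codon changes
#' via `syn_bias`; `mode = "synonymous_only"` accepts only synonymous,
#' stop-free replacements. Annotations are preserved (substitutions only).
#'
#' @param ancestor A [mito_record()].
#' @param n_species Number of descendants (>= 2).
#' @param rate Per-site, per-branch substitution probability.
#' @param seed Integer seed.
#' @param mode `"mixed"` (default) or `"synonymous_only"`.
#' @param syn_bias In mixed mode, relative weight of synonymous proposals
#'   (default 3: transitions toward silent change are favored, emulating
#'   purifying selection on the protein).
#' @param code A [genetic_code()].
#' @return List of `n_species` records.
#' @export
evolve_cohort <- function(ancestor, n_species, rate, seed = 1L,
                          mode = c("mixed", "synonymous_only"),
                          syn_bias = 3, code = genetic_code(5)) {
  mode <- match.arg(mode)
  stopifnot(n_species >= 2)
  set.seed(seed)
  lapply(seq_len(n_species), function(i) {
    rec <- ancestor
    rec$accession <- sprintf("%s_sp%02d", ancestor$accession, i)
    rec$organism <- sprintf("%s descendant %d", ancestor$organism, i)
    pcgs <- rec$features$name[rec$features$role == "PCG"]
    for (g in pcgs) {
      sense <- mutate_cds(gene_sequence(rec, g), rate, mode, syn_bias, code)
      rec <- write_gene_sequence(rec, g, sense)
    }
    rec
  })
}

mutate_cds <- function(cds, rate, mode, syn_bias, code) {
  cods <- split_codons(cds)
  n_sites <- 3L * length(cods)
  hit_sites <- which(stats::runif(n_sites) < rate)
  for (site in hit_sites) {
    ci <- (site - 1L) %/% 3L + 1L
    pos <- (site - 1L) %% 3L + 1L
    cur <- cods[ci]
    if (cur %in% code$stop_codons) next  # terminal stop left untouched
    alts <- alt_codons(cur, pos)
    alts <- alts[!alts %in% code$stop_codons]
    if (length(alts) == 0) next
    syn <- code$codon_to_aa[alts] == code$codon_to_aa[[cur]]
    if (mode == "synonymous_only") {
      # only third-position silent changes: these are closed within a
      # synonymous family, so codons of any two cohort members differ only
      # by within-family third positions and parsimony pathway counting can
      # never read the history as nonsynonymous (first-position silent
      # changes, e.g. Leu CTA <-> TTA, would open mixed pathways between
      # descendants)
      if (pos != 3L) next
      alts <- alts[syn]
      if (length(alts) == 0) next
      cods[ci] <- sample(alts, 1)
    } else {
      w <- ifelse(syn, syn_bias, 1)
      cods[ci] <- sample(alts, 1, prob = w / sum(w))
    }
  }
  paste(cods, collapse = "")
}

# write a gene's sense sequence back into the genome
write_gene_sequence <- function(record, name, sense) {
  i <- which(record$features$name == name)[1]
  f <- record$features[i, ]
  placed <- if (f$strand == "N") reverse_complement(sense) else sense
  if (nchar(placed) != feature_span_length(f, record$length_bp))
    stop("replacement length differs from the feature span")
  s <- record$sequence
  if (!f$wrap) {
    substr(s, f$start + 1L, f$end) <- placed
  } else {
    head_len <- record$length_bp - f$start
    substr(s, f$start + 1L, record$length_bp) <- substr(placed, 1L, head_len)
    substr(s, 1L, f$end) <- substr(placed, head_len + 1L, nchar(placed))
  }
  record$sequence <- s
  record
}
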