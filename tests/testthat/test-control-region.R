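test_that("control region extraction honors precedence and flanks", {
  rec <- generate_mitogenome(simulation_config(seed = 6, cr_length = 400))
  cr <- extract_control_region(rec)
  expect_equal(cr$source, "feature")
  expect_equal(cr$length_bp, 400)

  # drop the explicit feature: the rrnS..trnI gap must give the same span
  rec2 <- rec
  rec2$features <- rec2$features[rec2$features$name != "control_region", ]
  cr2 <- extract_control_region(rec2)
  expect_equal(cr2$source, "flanks")
  expect_equal(cr2$sequence, cr$sequence)

  rec3 <- rec2
  rec3$features <- rec3$features[rec3$features$name != "rrnS", ]
  expect_error(extract_control_region(rec3), "rrnS")
})

test_that("control region wraps the origin when annotations demand it", {
  # rotate a generated genome so the CR spans the origin
  rec <- generate_mitogenome(simulation_config(seed = 6, cr_length = 400))
  cr <- extract_control_region(rec)
  shift <- 200L
  L <- rec$length_bp
  rot <- paste0(substr(rec$sequence, L - shift + 1L, L),
                substr(rec$sequence, 1L, L - shift))
  f <- rec$features
  f$start <- (f$start + shift) %% L
  f$end_new <- (f$end + shift) %% L
  f$wrap <- f$start > f$end_new | (f$end + shift) > L
  f$end <- ifelse(f$end_new == 0L, L, f$end_new)
  f$wrap <- f$start >= f$end & f$end < L | f$wrap & f$end < L
  f$end_new <- NULL
  # only the control region (last feature) actually crosses the origin here
  rec_rot <- mito_record(rec$accession, rec$organism, rot, f)
  cr_rot <- extract_control_region(rec_rot)
  expect_equal(cr_rot$sequence, cr$sequence)
  expect_true(cr_rot$span$wrap)
})

test_that("tandem scanner recovers textbook and planted repeats", {
  r <- find_tandem_repeats("ACGTACGTACGT", min_period = 2, min_copies = 1.9,
                           min_identity = 0.8)
  expect_equal(nrow(r), 1)
  expect_equal(r$unit, "ACGT")
  expect_equal(r$period, 4L)
  expect_equal(r$copies, 3)
  expect_equal(r$identity, 1)

  set.seed(77)
  unit <- random_dna_str(120)
  bg1 <- random_dna_str(380); bg2 <- random_dna_str(380)
  s <- paste0(bg1, unit, unit, bg2)
  hits <- find_tandem_repeats(s)   # defaults: period >= 10, copies >= 1.9
  big <- hits[hits$period >= 100, ]
  expect_equal(nrow(big), 1)
  expect_gte(big$identity, 0.99)
  expect_true(big$start <= 380 && big$end >= 380 + 240)
})

test_that("tandem scanner equals the all-(start, period) oracle", {
  set.seed(31)
  for (i in 1:12) {
    n <- sample(60:200, 1)
    s <- if (i %% 2 == 0) at_rich_dna(n) else random_dna_str(n)
    if (i %% 3 == 0) {
      u <- random_dna_str(12)
      s <- paste0(substr(s, 1, 20), u, u, substr(s, 21, n))
    }
    got <- find_tandem_repeats(s, min_period = 5, min_copies = 1.9,
                               min_identity = 0.8)
    want <- oracle_tandem(s, min_period = 5, min_copies = 1.9,
                          min_identity = 0.8)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(nrow(got), nrow(want))
      expect_equal(got$start, want$start)
      expect_equal(got$period, want$period)
      expect_equal(got$copies, want$copies, tolerance = 1e-12)
      expect_equal(got$identity, want$identity, tolerance = 1e-12)
    }
  }
})

test_that("reported repeats never extend outside the input and do not overlap", {
  set.seed(8)
  for (i in 1:6) {
    s <- at_rich_dna(300)
    h <- find_tandem_repeats(s, min_period = 5)
    if (nrow(h) == 0) next
    expect_true(all(h$start >= 0 & h$end <= nchar(s)))
    if (nrow(h) > 1) {
      o <- order(h$start)
      expect_true(all(h$end[o][-nrow(h)] <= h$start[o][-1]))
    }
  }
})

test_that("poly-T tracts report maximal runs only", {
  tr <- find_tracts("AATTTTTTGG", base = "T", min_len = 5)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$length, 6)
  expect_equal(tr$start, 2L)
  expect_equal(tr$end, 8L)
  expect_equal(nrow(find_tracts("ACGACG", base = "T", min_len = 5)), 0)
})

test_that("TA repeats are maximal and phase-canonicalized to earliest start", {
  ta <- find_ta_repeats("GTATATATAC")
  expect_equal(nrow(ta), 1)
  expect_equal(ta$copies, 4)
  expect_equal(ta$start, 1L)       # earliest alternating start
  expect_equal(ta$unit, "TA")
  expect_equal(nrow(find_ta_repeats("GGTACC")), 0)
})

test_that("GC-rich windows merge positions covered only by passing windows", {
  all_g <- gc_rich_windows(strrep("G", 50), window = 20, threshold = 50)
  expect_equal(nrow(all_g), 1)
  expect_equal(c(all_g$start, all_g$end), c(0, 50))
  expect_equal(nrow(gc_rich_windows(strrep("A", 50), window = 20)), 0)
  set.seed(5)
  s <- paste0(at_rich_dna(200, at = 1), strrep("GC", 15),
              at_rich_dna(200, at = 1))
  w <- gc_rich_windows(s, window = 20, threshold = 50)
  expect_equal(nrow(w), 1)
  expect_true(w$start >= 200 && w$end <= 230)   # inside the planted block
})

test_that("spacer consensus finds conserved blocks", {
  sp <- c("ATTTACATTAGC", "ATTTACATTAGC", "ATTTACATTAGC")
  blocks <- spacer_consensus(sp)
  expect_equal(nrow(blocks), 1)
  expect_equal(blocks$consensus, sp[1])
  expect_equal(blocks$conservation, 1)

  varied <- c("ATTTACATTAGC", "ATTTACTTTAGC", "ATTTACATTAGC")
  b2 <- spacer_consensus(varied, min_conservation = 0.9, min_block = 4)
  expect_equal(nrow(b2), 2)     # split at the single variable column

  expect_error(spacer_consensus("ATT"), "at least 2")
  expect_error(spacer_consensus(c("ATTT", "ATTTATTTATTT")), "2x")
})

test_that("spacer consensus handles length variation via alignment", {
  sp <- c("AATTTACGGATTTT", "AATTTACGGATTT", "AATTTACGGATTTT")
  b <- spacer_consensus(sp, min_conservation = 0.9, min_block = 4)
  expect_gte(nrow(b), 1)
  expect_true(any(grepl("AATTTACGGA", b$consensus)))
})

test_that("control_region_features catalogs every class at once", {
  set.seed(10)
  unit <- random_dna_str(30)
  s <- paste0(at_rich_dna(100), strrep("T", 8), at_rich_dna(30),
              strrep("TA", 6), at_rich_dna(40), unit, unit,
              at_rich_dna(60), strrep("GC", 12), at_rich_dna(80))
  feats <- control_region_features(s)
  expect_gte(nrow(feats$poly_t), 1)
  expect_gte(nrow(feats$ta), 1)
  expect_gte(nrow(feats$tandem), 1)
  expect_gte(nrow(feats$gc_rich), 1)
  expect_equal(feats$length_bp, nchar(s))
})
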