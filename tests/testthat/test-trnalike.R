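test_that("template-built tRNAs fold perfectly with the designed anticodon", {
  set.seed(3)
  probs <- c(A = .35, T = .35, G = .15, C = .15)
  for (ac in c("TAA", "GTT", "TCA")) {
    s <- mitoclover:::build_trna(ac, probs)
    st <- fold_cloverleaf(s)
    expect_false(is.null(st))
    expect_equal(st$mismatches, 0)
    expect_equal(st$anticodon, ac)
    expect_equal(nchar(st$dot_bracket), nchar(s))
    expect_equal(st$paired_total, 21)    # 7 + 4 + 5 + 5
  }
})

test_that("sequences that cannot pair return no structure", {
  expect_null(fold_cloverleaf(strrep("A", 72)))
  expect_error(fold_cloverleaf(strrep("A", 40)), "50-90")
  expect_error(fold_cloverleaf(strrep("A", 95)), "50-90")
})

test_that("every annotated tRNA of a generated record folds consistently", {
  rec <- generate_mitogenome(simulation_config(seed = 29))
  refs <- trna_references(rec)
  ok <- 0
  for (i in seq_len(nrow(refs))) {
    st <- fold_cloverleaf(refs$sequence[i])
    if (!is.null(st) && st$anticodon == refs$anticodon[i]) ok <- ok + 1
  }
  expect_gte(ok, 20)   # >= 20 of 22, as for real annotation sets
})

test_that("the folder agrees with brute-force placement enumeration", {
  set.seed(61)
  checked <- 0
  for (i in 1:40) {
    n <- sample(55:75, 1)
    s <- at_rich_dna(n, at = 0.7)
    got <- fold_cloverleaf(s)
    want <- oracle_cloverleaf(s)
    if (is.null(want)) {
      expect_null(got)
    } else {
      checked <- checked + 1
      expect_equal(got$paired_total, want$paired)
      expect_equal(got$mismatches, want$mm)
      expect_equal(unname(got$anticodon_span["start"]), want$ac)
      expect_equal(got$anticodon, want$anticodon)
    }
  }
  # also check on template tRNAs, where a structure must exist
  probs <- c(A = .35, T = .35, G = .15, C = .15)
  s <- mitoclover:::build_trna("GAT", probs)
  got <- fold_cloverleaf(s)
  want <- oracle_cloverleaf(s)
  expect_equal(got$paired_total, want$paired)
  expect_equal(unname(got$anticodon_span["start"]), want$ac)
})

test_that("match_percent follows the alignment-identity contract", {
  expect_equal(match_percent("ACGTACGT", "ACGTACGT"), 100)
  expect_equal(match_percent("AAAA", "CCCC"), 0)
  set.seed(14)
  for (i in 1:5) {
    a <- random_dna_str(60); b <- random_dna_str(60)
    expect_equal(match_percent(a, b), match_percent(b, a))
  }
  # gap columns count in the denominator by default, not under "shorter"
  expect_lt(match_percent("ACGTACGT", "ACGT"),
            match_percent("ACGTACGT", "ACGT", denominator = "shorter") + 1e-9)
})

test_that("p-distance counts differing sites over compared sites", {
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_equal(p_distance("ACGT", "ACGA"), 0.25)
  # unequal lengths are aligned first, gap columns dropped
  expect_lte(p_distance("ACGTACGT", "ACGTACG"), 1 / 7)
})

test_that("a planted unmutated tRNA copy is recovered exactly", {
  cfg <- simulation_config(
    seed = 100,
    planted_trnas = list(list(family = "trnL2", mutation_rate = 0,
                              position = 300)))
  rec <- generate_mitogenome(cfg)
  cr <- extract_control_region(rec)
  hits <- scan_control_region(cr, trna_references(rec))
  man <- attr(rec, "manifest")
  planted <- hits[hits$family == "trnL2-like" &
                    hits$start < man$cr_end & hits$end > man$cr_start, ]
  expect_equal(nrow(planted), 1)
  expect_equal(planted$match_percent, 100)
  expect_equal(planted$tier, "high")
  expect_equal(planted$anticodon, "TAA")
})

test_that("random AT-rich sequence yields essentially no calls", {
  rec <- generate_mitogenome(simulation_config(seed = 70))
  refs <- trna_references(rec)
  zero_seeds <- 0
  for (s in 1:10) {
    set.seed(7000 + s)
    fp <- scan_control_region(at_rich_dna(1000), refs)
    if (nrow(fp) == 0) zero_seeds <- zero_seeds + 1
  }
  expect_gte(zero_seeds, 8)
})

test_that("no hit ever carries an anticodon different from its family's", {
  total_hits <- 0L
  for (seed in c(201, 202)) {
    cfg <- simulation_config(
      seed = seed,
      planted_trnas = list(list(family = "trnW", mutation_rate = 0,
                                position = 100),
                           list(family = "trnV", mutation_rate = 0.05,
                                position = 600)))
    rec <- generate_mitogenome(cfg)
    refs <- trna_references(rec)
    hits <- scan_control_region(extract_control_region(rec), refs)
    total_hits <- total_hits + nrow(hits)
    for (i in seq_len(nrow(hits))) {
      fam <- sub("-like$", "", hits$family[i])
      expect_equal(hits$anticodon[i],
                   refs$anticodon[refs$family == fam])
    }
  }
  expect_gte(total_hits, 1)   # the rate-0.05 plants are recoverable
})

test_that("family census aggregates totals and record presence", {
  none <- family_census(list(a = mitoclover:::empty_hit_frame()))
  expect_equal(nrow(none$families), 0)
  expect_equal(none$n_records_with_hits, 0)

  h1 <- data.frame(family = c("trnL2-like", "trnL2-like", "trnW-like"),
                   stringsAsFactors = FALSE)
  h2 <- data.frame(family = "trnW-like", stringsAsFactors = FALSE)
  cen <- family_census(list(r1 = h1, r2 = h2))
  fam <- cen$families
  expect_equal(fam$total[fam$family == "trnL2-like"], 2L)
  expect_equal(fam$total[fam$family == "trnW-like"], 2L)
  expect_equal(fam$n_records[fam$family == "trnW-like"], 2L)
  expect_equal(cen$n_records_with_hits, 2L)
})

test_that("census of a planted cohort equals the planting manifest", {
  plant_spec <- list(
    list(fam = "trnL2", pos = 200), list(fam = "trnL2", pos = 500),
    list(fam = "trnW", pos = 350))
  hits_by_rec <- list()
  expected <- c(`trnL2-like` = 0L, `trnW-like` = 0L)
  for (k in seq_along(plant_spec)) {
    cfg <- simulation_config(
      seed = 300 + k,
      planted_trnas = list(list(family = plant_spec[[k]]$fam,
                                mutation_rate = 0,
                                position = plant_spec[[k]]$pos)))
    rec <- generate_mitogenome(cfg)
    hits <- scan_control_region(extract_control_region(rec),
                                trna_references(rec))
    hits_by_rec[[rec$accession]] <- hits
    expected[paste0(plant_spec[[k]]$fam, "-like")] <-
      expected[paste0(plant_spec[[k]]$fam, "-like")] + 1L
  }
  cen <- family_census(hits_by_rec)
  for (f in names(expected)) {
    got <- cen$families$total[cen$families$family == f]
    expect_equal(got, unname(expected[f]))
  }
  expect_equal(cen$n_records_with_hits, 3L)
})
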