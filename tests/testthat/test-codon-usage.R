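code5 <- genetic_code(5)

test_that("the invertebrate mitochondrial code has the expected structure", {
  expect_equal(code5$sense_codon_count, 62)
  expect_setequal(code5$stop_codons, c("TAA", "TAG"))
  expect_equal(sort(unique(lengths(code5$families))), c(2, 4, 6, 8))
  expect_equal(length(code5$families[["S"]]), 8)  # TCN + AGN serine
})

test_that("codon counting drops terminal stops and partial codons", {
  cc <- count_codons(c("ATGTTTTAA"), code5)
  expect_equal(cc$total, 2)
  expect_equal(unname(cc$counts[["ATG"]]), 1L)
  expect_equal(unname(cc$counts[["TTT"]]), 1L)
  cc2 <- count_codons(c("ATGT"), code5)
  expect_equal(cc2$total, 1)
  cc3 <- count_codons(c("ATGTAACCCTAA"), code5)  # internal TAA excluded
  expect_equal(cc3$total, 2)
  expect_equal(cc3$diagnostics$internal_stops, 1L)
  cc4 <- count_codons(c("ATGNNTTTTTAA"), code5)
  expect_equal(cc4$diagnostics$ambiguous_codons, 1L)
})

test_that("RSCU matches its definition and conserves family sums", {
  cc <- count_codons(c("TTTTTTTTC"), code5)      # Phe family (2, 1)...
  r <- rscu(cc, code5)
  expect_equal(unname(r[["TTT"]]), 2 * 2 / 3)
  expect_equal(unname(r[["TTC"]]), 2 * 1 / 3)
  # two-codon family with counts (2, 0) -> (2, 0)
  cc2 <- count_codons(c("AAAAAA"), code5)        # Lys AAA x2
  r2 <- rscu(cc2, code5)
  expect_equal(unname(r2[["AAA"]]), 2)
  expect_equal(unname(r2[["AAG"]]), 0)
  # perfectly uniform usage -> all RSCU 1
  uni <- list(counts = stats::setNames(rep(5L, 62), code5$sense_codons),
              total = 310L)
  class(uni) <- "codon_counts"
  expect_true(all(abs(rscu(uni, code5) - 1) < 1e-12))
})

test_that("RSCU and family homozygosity match naive enumeration exactly", {
  set.seed(404)
  for (i in 1:20) {
    counts <- stats::setNames(as.integer(rpois(62, lambda = 7)),
                              code5$sense_codons)
    cc <- structure(list(counts = counts, total = sum(counts)),
                    class = "codon_counts")
    expect_identical(rscu(cc, code5), oracle_rscu(as.list(counts), code5))
  }
})

test_that("ENC hits its closed-form extremes", {
  uni <- structure(list(counts = stats::setNames(rep(1000L, 62),
                                                 code5$sense_codons),
                        total = 62000L), class = "codon_counts")
  expect_equal(enc(uni, code5), 62)
  one_per <- stats::setNames(rep(0L, 62), code5$sense_codons)
  for (fam in code5$families) one_per[fam[1]] <- 500L
  op <- structure(list(counts = one_per, total = sum(one_per)),
                  class = "codon_counts")
  expect_equal(enc(op, code5), length(code5$families))
  expect_error(enc(structure(list(counts = stats::setNames(rep(0L, 62),
                                                           code5$sense_codons),
                                  total = 0L), class = "codon_counts"),
                   code5), "zero codons")
})

test_that("concentrating usage within a family never increases ENC", {
  set.seed(7)
  counts <- stats::setNames(as.integer(rpois(62, 30) + 1L),
                            code5$sense_codons)
  cc <- structure(list(counts = counts, total = sum(counts)),
                  class = "codon_counts")
  base_enc <- enc(cc, code5)
  for (aa in c("L", "S", "V", "F")) {
    fam <- code5$families[[aa]]
    conc <- counts
    conc[fam] <- 0L
    conc[fam[1]] <- sum(counts[fam])  # same total, all on one codon
    cc2 <- structure(list(counts = conc, total = sum(conc)),
                     class = "codon_counts")
    expect_lte(enc(cc2, code5), base_enc + 1e-9)
  }
})

test_that("CBI is 0 under uniform usage and 1 under exclusive usage", {
  uni <- structure(list(counts = stats::setNames(rep(50L, 62),
                                                 code5$sense_codons),
                        total = 3100L), class = "codon_counts")
  expect_equal(cbi(uni, code5), 0)
  one_per <- stats::setNames(rep(0L, 62), code5$sense_codons)
  for (fam in code5$families) one_per[fam[1]] <- 100L
  op <- structure(list(counts = one_per, total = sum(one_per)),
                  class = "codon_counts")
  expect_equal(cbi(op, code5), 1)
  zero <- structure(list(counts = stats::setNames(rep(0L, 62),
                                                  code5$sense_codons),
                         total = 0L), class = "codon_counts")
  expect_error(cbi(zero, code5), "zero degenerate")
})

test_that("the ENC-plot expectation follows its closed form", {
  expect_equal(enc_expected(0.5), 60.5)
  expect_equal(enc_expected(0), 31)
  expect_equal(enc_expected(1), 32)
  expect_error(enc_expected(1.2))
})

test_that("correlate returns r-squared with a two-sided p", {
  x <- 1:10
  out <- correlate(x, 2 * x + 1)
  expect_equal(out$r2, 1)
  expect_equal(out$slope_sign, 1)
  const <- correlate(x, rep(3, 10))
  expect_true(is.na(const$r2))
  set.seed(12)
  noise <- correlate(rnorm(1000), rnorm(1000))
  expect_lt(noise$r2, 0.01)
})

test_that("generated selection-free genomes sit at or below the ENC curve", {
  # neutral codon sampling leaves ENC governed by composition alone, so the
  # observed ENC should not exceed ENC*(GC3) by more than sampling noise
  for (seed in c(2, 9, 31)) {
    rec <- generate_mitogenome(simulation_config(seed = seed))
    u <- usage_stats(rec, code5)
    expect_lte(u$enc, enc_expected(u$gc3 / 100) + 2.5)
  }
})

test_that("usage stats pool the 13 PCGs per record", {
  rec <- generate_mitogenome(simulation_config(seed = 13))
  u <- usage_stats(rec, code5)
  expect_gt(u$n_codons, 3000)
  expect_true(u$enc >= 2 && u$enc <= 62)
  expect_true(u$n_distinct_codons <= 62)
  tab <- usage_table(list(rec), code5)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$enc, u$enc)
})
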