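test_that("record construction enforces the data-model invariants", {
  rec <- make_toy_record()
  expect_s3_class(rec, "mito_record")
  expect_equal(rec$length_bp, nchar(rec$sequence))
  expect_true(all(diff(rec$features$start) >= 0))  # sorted by start

  bad <- rec$features
  bad$name[1] <- "nonsense_gene"
  expect_error(mito_record("X", "o", rec$sequence, bad), "unknown feature")

  two_cr <- rbind(rec$features, rec$features[3, ])
  expect_error(mito_record("X", "o", rec$sequence, two_cr),
               "control_region")

  no_ac <- rec$features
  no_ac$anticodon[no_ac$name == "trnW"] <- NA
  expect_error(mito_record("X", "o", rec$sequence, no_ac), "anticodon")

  expect_error(mito_record("X", "o", "ACGT!!", rec$features), "non-IUPAC")
})

test_that("canonical_name maps the field's label variants deterministically", {
  expect_equal(canonical_name("COI"), "cox1")
  expect_equal(canonical_name("cytb"), "cob")
  expect_equal(canonical_name("ND4L"), "nad4L")
  expect_equal(canonical_name("16S ribosomal RNA"), "rrnL")
  expect_equal(canonical_name("tRNA-Ser", anticodon = "GCT"), "trnS1")
  expect_equal(canonical_name("tRNA-Ser", anticodon = "TGA"), "trnS2")
  expect_equal(canonical_name("tRNA-Leu", anticodon = "UAA"), "trnL2")
  expect_equal(canonical_name("tRNA-Leu", product = "tRNA-Leu (CUN)"),
               "trnL1")
  expect_equal(canonical_name("tRNA-Trp"), "trnW")
  expect_error(canonical_name("hypothetical"), "unmappable")
  expect_error(canonical_name("tRNA-Leu"), "disambiguate")
})

test_that("gene_sequence honors strand and origin wrap", {
  rec <- make_toy_record()
  expect_equal(gene_sequence(rec, "cox1"), "ATGTTTAAACCCGGGTAA")
  expect_equal(gene_sequence(rec, "trnW"),
               paste0(strrep("GA", 10), "TAGCA"))
  cr <- gene_sequence(rec, "control_region")
  expect_equal(nchar(cr), 28)            # tail (20) + head (8)
  expect_equal(cr, paste0(strrep("AT", 10), "TTTTAAAA"))
  expect_error(gene_sequence(rec, "nad5"), "not present")
})

test_that("gene_sequence length equals span length for every feature", {
  rec <- generate_mitogenome(simulation_config(seed = 11))
  f <- rec$features
  for (i in seq_len(nrow(f))) {
    span_len <- if (f$wrap[i]) rec$length_bp - f$start[i] + f$end[i]
                else f$end[i] - f$start[i]
    expect_equal(nchar(gene_sequence(rec, f$name[i])), span_len)
  }
})

test_that("intergenic map reports gaps, overlaps and circular closure", {
  seqs <- strrep("A", 100)
  feats <- data.frame(
    name = c("cox1", "cox2", "cox3"),
    start = c(0L, 30L, 25L), end = c(30L, 60L, 30L)[c(1, 3, 2)],
    wrap = FALSE, strand = "J", anticodon = NA_character_,
    stringsAsFactors = FALSE)
  # cox1 [0,30), cox3 [25,30): overlap -5 with cox1; cox2 [30,60)
  feats$start <- c(0L, 25L, 30L); feats$end <- c(30L, 30L, 60L)
  feats$name <- c("cox1", "cox3", "cox2")
  rec <- mito_record("T", "t", seqs, feats)
  ig <- intergenic_map(rec)
  expect_equal(ig$gap_bp[ig$upstream == "cox1" & ig$downstream == "cox3"], -5L)
  expect_equal(ig$gap_bp[ig$upstream == "cox3" & ig$downstream == "cox2"], 0L)
  # circular closure: cox2 end 60 -> cox1 start 0 (+100)
  expect_equal(ig$gap_bp[ig$upstream == "cox2" & ig$downstream == "cox1"], 40L)
  expect_error(intergenic_map(
    mito_record("T", "t", seqs, feats[1, , drop = FALSE])), "at least 2")
})

test_that("genome closure holds on generated records", {
  rec <- generate_mitogenome(simulation_config(seed = 3))
  ig <- intergenic_map(rec)
  f <- rec$features
  lens <- ifelse(f$wrap, rec$length_bp - f$start + f$end, f$end - f$start)
  expect_equal(sum(lens) + sum(ig$gap_bp), rec$length_bp)
})

test_that("validate_pcgs classifies starts, stops and internal stops", {
  mk <- function(cds) {
    feats <- data.frame(name = "cox1", start = 0L, end = nchar(cds),
                        wrap = FALSE, strand = "J",
                        anticodon = NA_character_, stringsAsFactors = FALSE)
    mito_record("V", "v", cds, feats)
  }
  full <- validate_pcgs(mk("ATGTTTAAACCCTAA"))
  expect_true(full$atn_start)
  expect_equal(full$stop_class, "TAA")
  expect_equal(full$internal_stops, 0L)

  trunc_t <- validate_pcgs(mk("ATGTTTCCCT"))       # length 10 = 1 mod 3
  expect_equal(trunc_t$stop_class, "T-truncated")
  trunc_ta <- validate_pcgs(mk("ATGTTTCCCTA"))     # length 11 = 2 mod 3
  expect_equal(trunc_ta$stop_class, "TA-truncated")

  internal <- validate_pcgs(mk("ATGTAACCCTAG"))    # TAA mid-sequence
  expect_equal(internal$internal_stops, 1L)
  expect_equal(internal$stop_class, "TAG")

  nonatn <- validate_pcgs(mk("TTGTTTAAACCCTAA"))
  expect_false(nonatn$atn_start)
})

test_that("GenBank writer/parser round-trips the full data model", {
  rec <- generate_mitogenome(simulation_config(seed = 5, cr_length = 300))
  path <- tempfile(fileext = ".gb")
  write_genbank(rec, path)
  back <- parse_genbank(path)
  expect_equal(back$accession, rec$accession)
  expect_equal(back$sequence, rec$sequence)
  expect_equal(back$length_bp, rec$length_bp)
  expect_equal(back$features, rec$features)
})

test_that("parser rejects malformed flat files", {
  p1 <- tempfile(); writeLines(c("LOCUS  X 10 bp", "FEATURES", "//"), p1)
  expect_error(parse_genbank(p1), "ORIGIN")
  p2 <- tempfile()
  writeLines(c("LOCUS  X 8 bp circular", "FEATURES",
               "ORIGIN", "        1 acgtacgt", "//"), p2)
  expect_error(parse_genbank(p2), "recognized")
})

test_that("FASTA + feature-table fallback dialect parses, wrap via start>end", {
  rec <- make_toy_record()
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">TOY1 toy organism", rec$sequence), fa)
  tsv <- tempfile(fileext = ".tsv")
  f <- rec$features
  # convert to 1-based closed; the wrapped CR becomes start > end
  utils::write.table(
    data.frame(name = c("COI", "tRNA-Trp", "control region"),
               start = c(9, 67, 101), end = c(26, 91, 8),
               strand = f$strand, type = f$role,
               anticodon = c("-", "TCA", "-")),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- parse_feature_table(fa, tsv)
  expect_equal(back$features$name, rec$features$name)
  expect_equal(back$features$start, rec$features$start)
  expect_equal(back$features$end, rec$features$end)
  expect_equal(back$features$wrap, rec$features$wrap)
})

test_that("JSON dump serializes the normalized record", {
  rec <- make_toy_record()
  js <- jsonlite::fromJSON(record_to_json(rec))
  expect_equal(js$accession, "TOY1")
  expect_equal(js$length_bp, rec$length_bp)
  expect_equal(nrow(js$features), nrow(rec$features))
})
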