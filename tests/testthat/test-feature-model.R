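test_that("the packaged ledger parses with the published dimensions", {
  g <- lsinicus_genome()
  expect_s3_class(g, "annotated_genome")
  expect_equal(nrow(g$features), 38)  # 37 genes + AT-rich region
  expect_equal(g$length, 15405)
  expect_true(g$circular)
  expect_equal(g$organism, "Labriocimbex sinicus")

  trnI <- g$features[g$features$name == "trnI", ]
  expect_equal(trnI$strand, "J")
  expect_equal(trnI$start, 1)
  expect_equal(trnI$stop, 67)
  expect_equal(trnI$anticodon, "GAU")
  expect_equal(trnI$declared_ign, 1)
  expect_equal(gene_category("trnI"), "tRNA")

  nd5 <- g$features[g$features$name == "ND5", ]
  expect_equal(nd5$stop_codon, "T")
  expect_equal(nd5$strand, "N")
})

test_that("feature tables round-trip field-for-field and handle the empty case", {
  sim <- simulate_genome(simulation_params(seed = 11L))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(sim$genome, tf)
  back <- read_feature_table(tf)
  cols <- c("name", "strand", "start", "stop", "declared_length",
            "start_codon", "stop_codon", "anticodon")
  expect_equal(back$features[, cols], sim$genome$features[, cols])
  expect_equal(back$length, sim$genome$length)
  # a second round trip is byte-identical (writer is deterministic)
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(back, tf2)
  expect_identical(readLines(tf), readLines(tf2))

  # header-only file
  tf3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("Gene\tStrand\tStart\tStop", tf3)
  empty <- read_feature_table(tf3, length = 100)
  expect_equal(nrow(empty$features), 0)
})

test_that("malformed feature tables are rejected with a pointer to the row", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Gene\tStrand\tStart\tStop", "ORFX\tJ\t1\t10"), tf)
  expect_error(read_feature_table(tf, length = 50), "ORFX")
  writeLines(c("Gene\tStrand\tStart\tStop", "COI\tJ\tabc\t10"), tf)
  expect_error(read_feature_table(tf, length = 50), "non-integer")
  writeLines(c("Gene\tStrand\tStart\tStop", "COI\t+\t1\t10"), tf)
  expect_error(read_feature_table(tf, length = 50), "strand")
})

test_that("type constructors enforce their invariants", {
  expect_error(gene_feature("COI", "J", 10, 5), "start")
  expect_error(gene_feature("trnA", "J", 1, 60, start_codon = "ATG"),
               "must not carry")
  f <- rbind(gene_feature("COI", "J", 1, 30), gene_feature("COI", "N", 40, 60))
  expect_error(annotated_genome(f, length = 100), "duplicate")
  expect_error(annotated_genome(gene_feature("COI", "J", 1, 200), length = 100),
               "beyond")
  expect_error(annotated_genome(gene_feature("COI", "J", 1, 30), length = 100,
                                sequence = "ACGT"), "does not match")
})

test_that("validation flags the published inconsistencies", {
  v <- validate_annotation(lsinicus_genome())
  # trnT: declared length 65 but printed coordinates span 245
  r1 <- v[v$rule == "r1", ]
  expect_equal(r1$feature, "trnT")
  expect_match(r1$message, "245")
  expect_equal(r1$severity, "error")
  # ND5 is a truncated-stop gene: span 1714 = 1 mod 3 with stop T passes r2
  expect_false(any(v$feature == "ND5" & v$rule == "r2"))
  # published anticodon typos are warnings, not errors
  r5 <- v[v$rule == "r5", ]
  expect_true(all(r5$severity == "warning"))
  expect_true(all(c("trnQ", "trnV", "trnL1", "trnC") %in% r5$feature))
  # overlaps (e.g. ATP8/ATP6) are warnings, never errors
  r6 <- v[v$rule == "r6", ]
  expect_true(all(r6$severity == "warning"))
  expect_true("ATP6" %in% r6$feature)
})

test_that("validation catches bad codons and passes clean annotations", {
  f <- rbind(gene_feature("COI", "J", 1, 9, start_codon = "CTG",
                          stop_codon = "TCC"))
  v <- validate_annotation(annotated_genome(f, length = 20))
  expect_true(any(v$rule == "r3" & v$severity == "error"))
  expect_true(any(v$rule == "r4" & v$severity == "error"))

  clean <- validate_annotation(toy_genome())
  expect_equal(nrow(clean[clean$severity == "error", ]), 0)
})

test_that("GenBank output round-trips against the generator's ground truth", {
  sim <- simulate_genome(simulation_params(seed = 3L))
  gb <- withr::local_tempfile(fileext = ".gb")
  write_genbank(sim$genome, gb)
  back <- read_genbank(gb)
  cols <- c("name", "strand", "start", "stop")
  expect_equal(back$features[, cols], sim$genome$features[, cols])
  expect_identical(back$sequence, sim$genome$sequence)
  expect_equal(back$length, sim$genome$length)
  expect_true(back$circular)
})

test_that("GenBank parsing maps dialects and rejects the unsupported", {
  rec <- c(
    "LOCUS       TEST             60 bp    DNA     circular INV",
    "FEATURES             Location/Qualifiers",
    "     source          1..60",
    "     CDS             complement(11..40)",
    '                     /gene="COX1"',
    "ORIGIN",
    paste0("        1 ", paste(rep("acgtacgtac", 6), collapse = " ")),
    "//")
  tf <- withr::local_tempfile(fileext = ".gb")
  writeLines(rec, tf)
  g <- read_genbank(tf)
  expect_equal(nrow(g$features), 1)
  expect_equal(g$features$name, "COI")   # COX1 resolved via synonyms
  expect_equal(g$features$strand, "N")   # complement => minority strand

  writeLines(sub('/gene="COX1"', '/gene="ORF1"', rec), tf)
  expect_error(read_genbank(tf), "ORF1")

  writeLines(sub("complement\\(11..40\\)", "join(11..20,30..40)", rec), tf)
  expect_error(read_genbank(tf), "join")

  writeLines(c(rec, rec), tf)
  expect_error(read_genbank(tf), "one LOCUS")
})
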