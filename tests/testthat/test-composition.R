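test_that("base counting matches an independent tally and rejects bad input", {
  expect_equal(count_bases("AAAA"), c(a = 4, c = 0, g = 0, t = 0, other = 0))
  expect_equal(count_bases("ACGTN"), c(a = 1, c = 1, g = 1, t = 1, other = 1))
  expect_equal(count_bases("acgt"), count_bases("ACGT"))

  set.seed(42)
  for (i in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T", "N", "R"), 1000, TRUE,
                      prob = c(.3, .2, .1, .3, .05, .05)), collapse = "")
    expect_equal(count_bases(s), oracle_count(s))
    # cross-check ACGT counts against Biostrings
    af <- Biostrings::alphabetFrequency(Biostrings::DNAString(s))
    expect_equal(unname(count_bases(s)[c("a", "c", "g", "t")]),
                 unname(af[c("A", "C", "G", "T")]))
  }

  expect_error(count_bases(""), "non-empty")
  expect_error(count_bases("ACGXGT"), "position 4")
})

test_that("skews reproduce the published whole-genome and PCG values", {
  sk <- skew_pair(43.5, 37.7, 7.7, 11.1)
  expect_equal(round(sk[["at_skew"]], 4), 0.0714)
  expect_equal(round(sk[["gc_skew"]], 4), -0.1809)
  sk2 <- skew_pair(34.4, 45.5, 10.4, 9.7)
  expect_equal(round(sk2[["at_skew"]], 4), -0.1389)
  expect_equal(round(sk2[["gc_skew"]], 4), 0.0348)
  expect_equal(skew_pair(25, 25, 25, 25), c(at_skew = 0, gc_skew = 0))
})

test_that("skew_pair is antisymmetric under base exchange and flags degeneracy", {
  set.seed(7)
  for (i in 1:25) {
    v <- runif(4, 0, 50)
    a <- skew_pair(v[1], v[2], v[3], v[4])
    b <- skew_pair(v[2], v[1], v[3], v[4])  # swap a <-> t
    expect_equal(a[["at_skew"]], -b[["at_skew"]])
    d <- skew_pair(v[1], v[2], v[4], v[3])  # swap g <-> c
    expect_equal(a[["gc_skew"]], -d[["gc_skew"]])
  }
  expect_true(is.na(skew_pair(0, 0, 10, 10)[["at_skew"]]))
  expect_true(is.na(skew_pair(10, 10, 0, 0)[["gc_skew"]]))
  expect_error(skew_pair(-1, 2, 3, 4), "non-negative")
})

test_that("codon-position slices index correctly and recombine losslessly", {
  sl <- codon_position_slices(list("ATGAAA"))
  expect_equal(sl, list(pos1 = "AA", pos2 = "TA", pos3 = "GA"))
  expect_equal(codon_position_slices(list()),
               list(pos1 = "", pos2 = "", pos3 = ""))
  expect_error(codon_position_slices(list("ATGA")), "divisible")

  set.seed(11)
  for (i in 1:10) {
    cds <- replicate(3, random_dna(3 * sample(5:40, 1)))
    sl <- codon_position_slices(cds)
    expect_equal(unique(nchar(unlist(sl))), sum(nchar(cds)) / 3)
    # zipping the slices back together restores the codon multiset
    rebuilt <- paste0(strsplit(sl$pos1, "")[[1]],
                      strsplit(sl$pos2, "")[[1]],
                      strsplit(sl$pos3, "")[[1]])
    original <- unlist(lapply(cds, function(s)
      substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))))
    expect_equal(sort(rebuilt), sort(original))
  }
})

test_that("reverse complement swaps the A/T and G/C counts exactly", {
  set.seed(3)
  for (i in 1:10) {
    s <- random_dna(500)
    n <- count_bases(s)
    m <- count_bases(as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s))))
    expect_equal(m[["a"]], n[["t"]])
    expect_equal(m[["t"]], n[["a"]])
    expect_equal(m[["g"]], n[["c"]])
    expect_equal(m[["c"]], n[["g"]])
  }
})

test_that("the composition report has the ledger structure", {
  sim <- simulate_genome(simulation_params(seed = 2L))
  comp <- composition_report(sim$genome)
  # 1 whole + 3 PCG sets x (1 + 3 positions) + 13 PCGs + 2 rRNAs
  expect_equal(nrow(comp), 1 + 3 * 4 + 13 + 2)
  expect_setequal(
    comp$region[1:13],
    c("whole_genome",
      as.vector(outer(c("PCG_all", "PCG_J", "PCG_N"),
                      c("", "_pos1", "_pos2", "_pos3"), paste0))))
  # percentages are consistent: A+T column equals pct_a + pct_t
  expect_equal(comp$pct_at, comp$pct_a + comp$pct_t)
  # PCG rows are coding-sense: every PCG starts with an ATN codon,
  # so N-strand genes must not look like their J-strand complement
  expect_true(all(comp$length[comp$region == "PCG_all_pos1"] ==
                    comp$length[comp$region == "PCG_all_pos2"]))
  expect_error(composition_report(lsinicus_genome()), "sequence")
})

test_that("a uniform-composition genome has near-zero skews", {
  sim <- simulate_genome(simulation_params(seed = 8L))
  g <- sim$genome
  unif <- annotated_genome(g$features, length = g$length,
                           organism = g$organism,
                           sequence = strrep("ACGT", ceiling(g$length / 4)) |>
                             substring(1, g$length))
  row <- composition_report(unif)
  wg <- row[row$region == "whole_genome", ]
  expect_lt(abs(wg$at_skew), 1e-3)
  expect_lt(abs(wg$gc_skew), 1e-3)
})

test_that("planted A+T fraction is recovered at 15 kb", {
  sim <- simulate_genome(simulation_params(seed = 13L, at_fraction = 0.80))
  comp <- composition_report(sim$genome)
  at <- comp$pct_at[comp$region == "whole_genome"] / 100
  expect_lt(abs(at - 0.80), 0.02)
})

test_that("rendering rounds half-up to the table's decimals", {
  rep_ <- data.frame(region = "x", length = 10, pct_a = 43.45, pct_c = 11.05,
                     pct_g = 7.75, pct_t = 37.75, pct_at = 81.2,
                     at_skew = 0.07145, gc_skew = -0.18085)
  out <- render_composition(rep_)
  expect_equal(out$pct_a, 43.5)
  expect_equal(out$pct_c, 11.1)
  expect_equal(out$at_skew, 0.0715)
  expect_equal(out$gc_skew, -0.1809)
})
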