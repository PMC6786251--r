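test_that("gene orders encode from annotation with the strand signs", {
  obs <- encode_order(lsinicus_genome())
  expect_equal(length(obs), 37)  # control region excluded by default
  toks <- format_signed(obs)
  expect_equal(toks[1:4], c("trnI", "ND2", "trnW", "COI"))
  expect_true("trnY" %in% toks)        # J strand => "+" (no prefix)
  expect_true("-trnC" %in% toks)
  with_cr <- encode_order(lsinicus_genome(), include_control_region = TRUE)
  expect_equal(length(with_cr), 38)

  one <- annotated_genome(gene_feature("COI", "N", 1, 30), length = 50)
  expect_equal(format_signed(encode_order(one)), "-COI")
})

test_that("gene-order files round-trip", {
  anc <- ancestral_insect_order()
  expect_equal(length(anc), 37)
  tf <- withr::local_tempfile(fileext = ".txt")
  write_gene_order(anc, tf)
  back <- read_gene_order(tf)
  expect_true(orders_equal(anc, back))
  expect_equal(format_signed(anc)[1:3], c("trnI", "-trnQ", "trnM"))
})

test_that("breakpoint distance is rotation-invariant and symmetric", {
  anc <- ancestral_insect_order()
  expect_equal(breakpoint_distance(anc, anc), 0)
  set.seed(31)
  for (k in c(0, 5, 13, 20)) {
    rot <- signed_gene_order(
      c(anc$symbols[(k + 1):37], anc$symbols[seq_len(k)]),
      c(anc$orientation[(k + 1):37], anc$orientation[seq_len(k)]))
    expect_equal(breakpoint_distance(anc, rot), 0)
  }
  for (i in 1:20) {
    a <- random_signed_order(8)
    b <- random_signed_order(8)
    expect_equal(breakpoint_distance(a, b), breakpoint_distance(b, a))
  }
  bad <- signed_gene_order(c("g1", "g2"), c("+", "+"))
  expect_error(breakpoint_distance(bad, random_signed_order(8)), "differ")
})

test_that("breakpoint distance equals the brute-force adjacency oracle", {
  set.seed(101)
  for (i in 1:100) {
    a <- random_signed_order(8)
    b <- random_signed_order(8)
    expect_equal(breakpoint_distance(a, b), oracle_breakpoints(a, b))
  }
})

test_that("distance zero corresponds to equality up to rotation", {
  set.seed(17)
  for (i in 1:50) {
    a <- random_signed_order(7)
    b <- random_signed_order(7)
    d <- breakpoint_distance(a, b)
    eq <- orders_equal(a, b) || orders_equal(a, b, reflection = TRUE)
    if (d == 0) expect_true(eq) else expect_false(orders_equal(a, b))
  }
})

test_that("the published rearrangement events are recovered", {
  anc <- ancestral_insect_order()
  obs <- encode_order(lsinicus_genome())
  ev <- classify_events(anc, obs)
  expect_equal(unname(ev$per_gene[["trnT"]]), "inverted")
  expect_equal(unname(ev$per_gene[["trnY"]]), "remote_inversion")
  expect_equal(unname(ev$per_gene[["trnC"]]), "translocated")
  expect_equal(unname(ev$per_gene[["trnM"]]), "translocated")
  expect_equal(unname(ev$per_gene[["trnQ"]]), "translocated")
  # trnM and trnQ exchanged mutual positions while moving
  expect_true(any(vapply(ev$swapped_pairs, function(p)
    setequal(p, c("trnM", "trnQ")), logical(1))))
  # everything else stayed put
  expect_true(all(ev$per_gene[setdiff(names(ev$per_gene),
                                      c("trnT", "trnY", "trnC", "trnM", "trnQ"))]
                  == "in_place"))
})

test_that("self-comparison reports no events", {
  anc <- ancestral_insect_order()
  ev <- classify_events(anc, anc)
  expect_true(all(ev$per_gene == "in_place"))
  expect_equal(ev$breakpoints, 0)
  expect_equal(length(ev$conserved_blocks), 1)
})

test_that("a single planted translocation is labelled as such", {
  anc <- ancestral_insect_order()
  res <- apply_rearrangements(
    anc, list(list(op = "translocate", genes = "trnC", after = "ND3")))
  ev <- classify_events(anc, res$order)
  expect_equal(unname(ev$per_gene[["trnC"]]), "translocated")
  expect_true(all(ev$per_gene[names(ev$per_gene) != "trnC"] == "in_place"))
})

test_that("the COI-through-rrnS block is conserved across the cimbicid orders", {
  path <- function(f) system.file("extdata", f, package = "mitoprofile")
  orders <- list(
    lsinicus = encode_order(lsinicus_genome()),
    trichiosoma = read_gene_order(path("trichiosoma_order_figure_derived.txt")),
    corynis = read_gene_order(path("corynis_order_figure_derived.txt")))
  run <- c("COI", "trnL2", "COII", "trnK", "trnD", "ATP8", "ATP6", "COIII",
           "trnG", "ND3", "trnA", "trnR", "trnN", "trnS1", "trnE", "trnF",
           "ND5", "trnH", "ND4", "ND4L", "trnT", "trnP", "ND6", "CYTB",
           "trnS2", "ND1", "trnL1", "rrnL", "trnV", "rrnS")
  pairs <- combn(names(orders), 2, simplify = FALSE)
  for (p in pairs) {
    blocks <- conserved_blocks(orders[[p[1]]], orders[[p[2]]],
                               ignore_orientation = TRUE)
    has_run <- any(vapply(blocks, function(b) {
      syms <- sub("^-", "", b)
      any(vapply(seq_len(max(length(syms) - length(run) + 1, 0)), function(s)
        identical(syms[s:(s + length(run) - 1)], run), logical(1)))
    }, logical(1)))
    expect_true(has_run, label = paste("COI..rrnS block conserved:",
                                       p[1], "vs", p[2]))
  }
})

test_that("in-context swaps of adjacent genes are labelled swapped", {
  anc <- ancestral_insect_order()
  res <- apply_rearrangements(anc, list(list(op = "swap",
                                             genes = c("trnQ", "trnM"))))
  ev <- classify_events(anc, res$order)
  expect_equal(unname(ev$per_gene[["trnQ"]]), "swapped")
  expect_equal(unname(ev$per_gene[["trnM"]]), "swapped")
  expect_true(all(ev$per_gene[setdiff(names(ev$per_gene),
                                      c("trnQ", "trnM"))] == "in_place"))
})
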