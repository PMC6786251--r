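test_that("the generator is deterministic per seed", {
  a <- simulate_genome(simulation_params(seed = 5L))
  b <- simulate_genome(simulation_params(seed = 5L))
  fa <- withr::local_tempfile(fileext = ".gb")
  fb <- withr::local_tempfile(fileext = ".gb")
  write_genbank(a$genome, fa)
  write_genbank(b$genome, fb)
  expect_identical(readLines(fa), readLines(fb))  # byte-identical output
  c_ <- simulate_genome(simulation_params(seed = 6L))
  expect_false(identical(a$genome$sequence, c_$genome$sequence))
})

test_that("generated genomes validate cleanly and obey the conservation law", {
  for (seed in c(2L, 9L, 23L)) {
    sim <- simulate_genome(simulation_params(seed = seed))
    g <- sim$genome
    v <- validate_annotation(g)
    expect_equal(sum(v$severity == "error"), 0)
    expect_equal(g$length, 15405L)
    led <- adjacency_ledger(g)
    lhs <- sum(g$features$stop - g$features$start + 1L) +
      sum(led$gap[led$gap > 0]) - sum(-led$gap[led$gap < 0])
    expect_equal(lhs, g$length)
  }
})

test_that("the gap model is honoured", {
  abutting <- simulate_genome(simulation_params(
    seed = 3L, gap_model = list(p_zero = 1, max_gap = 6L)))
  s <- geometry_summary(adjacency_ledger(abutting$genome))
  expect_equal(s$n_abutting, s$n_pairs)

  with_ov <- simulate_genome(simulation_params(
    seed = 3L, gap_model = list(p_zero = 0.4, max_gap = 6L,
                                overlap_pairs = c("ATP8|ATP6" = 7L))))
  led <- adjacency_ledger(with_ov$genome)
  expect_equal(led$gap[led$downstream == "ATP6"], -7L)
  lhs <- sum(with_ov$genome$features$stop - with_ov$genome$features$start + 1L) +
    sum(led$gap[led$gap > 0]) - sum(-led$gap[led$gap < 0])
  expect_equal(lhs, with_ov$genome$length)

  expect_error(simulate_genome(simulation_params(
    seed = 1L, genome_length_target = 14000L)), "infeasible")
})

test_that("codon draws converge to the codon weights", {
  # pool three genomes so that well over 10,000 codons are compared
  counts <- 0
  w <- simulation_params()$codon_weights
  for (seed in c(4L, 14L, 24L)) {
    sim <- simulate_genome(simulation_params(seed = seed,
                                             pos3_reweight = FALSE))
    tab <- tally_codons(pcg_coding_sequences(sim$genome))
    counts <- counts + setNames(tab$count, tab$codon)[names(w)]
  }
  expect_gt(sum(counts), 10000)
  tvd <- sum(abs(counts / sum(counts) - w / sum(w))) / 2
  expect_lt(tvd, 0.05)
})

test_that("planted rearrangements are recovered by the classifier", {
  anc <- ancestral_insect_order()
  n <- length(anc)
  set.seed(55)
  for (trial in 1:100) {
    n_ops <- sample(1:3, 1)
    # spread the touched genes far apart so single-gene events cannot
    # interact (positions at circular distance >= 5)
    pos <- seq(3, n - 3, by = max(6, floor(n / (n_ops + 1))))[seq_len(n_ops)]
    pos <- (pos + sample(0:2, n_ops, TRUE)) %% n + 1L
    genes <- anc$symbols[pos]
    # events must not interact for their labels to be recoverable:
    # block every planted gene's neighborhood from use as a destination
    # or swap partner
    nbhd <- function(sym) {
      i <- match(sym, anc$symbols)
      anc$symbols[((i + c(-2:2) - 1L) %% n) + 1L]
    }
    blocked <- unique(unlist(lapply(genes, nbhd)))
    ops <- list()
    for (k in seq_len(n_ops)) {
      type <- sample(c("translocate", "invert", "swap", "remote"), 1)
      g <- genes[k]
      i <- match(g, anc$symbols)
      nb <- anc$symbols[(i %% n) + 1L]
      if (type == "swap" && !nb %in% setdiff(blocked, nbhd(g))) {
        ops[[length(ops) + 1L]] <- list(op = "swap", genes = c(g, nb))
        blocked <- unique(c(blocked, nbhd(nb)))
      } else if (type %in% c("translocate", "remote")) {
        far <- setdiff(anc$symbols[((i + 8:14) %% n) + 1L], blocked)
        if (!length(far)) {
          ops[[length(ops) + 1L]] <- list(op = "invert", genes = g)
          next
        }
        dest <- sample(far, 1)
        blocked <- unique(c(blocked, nbhd(dest)))
        ops[[length(ops) + 1L]] <- list(op = "translocate", genes = g,
                                        after = dest)
        if (type == "remote")
          ops[[length(ops) + 1L]] <- list(op = "invert", genes = g)
      } else {
        ops[[length(ops) + 1L]] <- list(op = "invert", genes = g)
      }
    }
    res <- apply_rearrangements(anc, ops, seed = trial)
    ev <- classify_events(anc, res$order)
    for (g in names(res$labels)) {
      expect_equal(unname(ev$per_gene[[g]]), unname(res$labels[[g]]),
                   label = sprintf("trial %d gene %s", trial, g))
    }
  }
})

test_that("rearrangement operations respect their contracts", {
  anc <- ancestral_insect_order()
  none <- apply_rearrangements(anc, list())
  expect_true(orders_equal(none$order, anc))
  expect_equal(length(none$labels), 0)

  inv <- apply_rearrangements(anc, list(list(op = "invert", genes = "trnT")))
  expect_equal(inv$order$symbols, anc$symbols)     # order untouched
  flip <- which(inv$order$orientation != anc$orientation)
  expect_equal(anc$symbols[flip], "trnT")          # only trnT flipped
  expect_equal(unname(inv$labels[["trnT"]]), "inverted")

  expect_error(apply_rearrangements(
    anc, list(list(op = "invert", genes = "trnX"))), "missing")
  expect_error(apply_rearrangements(
    anc, list(list(op = "swap", genes = c("trnI", "COI")))), "adjacent")
})

test_that("simulated tRNAs carry their planted truth", {
  a <- simulate_trna(seed = 8L)
  b <- simulate_trna(seed = 8L)
  expect_identical(a$sequence, b$sequence)
  expect_identical(a$structure, b$structure)

  tr <- simulate_trna(n_gu = 3L, mismatches = c("U-U" = 2L, "A-C" = 1L),
                      seed = 15L)
  cc <- classify_pairs(tr$paired)
  expect_equal(cc$gu_wobble, 3)
  expect_equal(sum(cc$mismatches), 3)
  expect_equal(cc$noncanonical, 6)

  expect_error(simulate_trna(aa_bp = 2, dhu_bp = 1, ac_bp = 1, tpsic_bp = 1,
                             n_gu = 10), "stem positions")
})

test_that("the ground-truth sidecar round-trips through YAML", {
  sim <- simulate_genome(simulation_params(seed = 19L))
  tf <- withr::local_tempfile(fileext = ".yaml")
  write_simulation_truth(sim$truth, tf)
  back <- yaml::read_yaml(tf)
  expect_equal(back$seed, 19)
  expect_equal(back$genome_length_target, 15405)
  expect_equal(back$gene_order, format_signed(sim$truth$order))
  expect_equal(unlist(back$lengths), sim$truth$lengths, ignore_attr = TRUE)
})
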