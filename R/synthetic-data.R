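## Synthetic annotated mitogenomes, tRNA cloverleaf structures and
## rearranged gene orders with known ground truth, so every analysis
## stage is testable without downloads.
##
## One integer seed drives a named random substream per sub-generator
## (genome layout, PCG codons, each tRNA, rRNA, spacers), so adding a
## generator does not perturb the draws of the others.

stream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483399) + 1L
}

## Evaluate expr under a named substream, restoring the caller's RNG.
with_stream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(stream_seed(seed, name))
  expr
}

## Typical insect mitochondrial PCG lengths (bp, incl. complete stop;
## all divisible by 3) used by the generator.
SIM_PCG_LENGTHS <- c(ND2 = 1044L, COI = 1539L, COII = 684L, ATP8 = 162L,
                     ATP6 = 690L, COIII = 786L, ND3 = 351L, ND5 = 1716L,
                     ND4 = 1353L, ND4L = 282L, ND6 = 504L, CYTB = 1134L,
                     ND1 = 951L)
SIM_RRNA_LENGTHS <- c(rrnL = 1341L, rrnS = 791L)

## Base-emission probabilities (A, C, G, T) from an A+T fraction and the
## two skews.
emission_probs <- function(at_fraction, at_skew, gc_skew) {
  stopifnot(at_fraction > 0, at_fraction < 1,
            abs(at_skew) < 1, abs(gc_skew) < 1)
  c(A = at_fraction * (1 + at_skew) / 2,
    C = (1 - at_fraction) * (1 - gc_skew) / 2,
    G = (1 - at_fraction) * (1 + gc_skew) / 2,
    T = at_fraction * (1 - at_skew) / 2)
}

sample_bases <- function(n, probs) {
  if (n <= 0L) return("")
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

#' Parameters for the synthetic mitogenome generator
#'
#' Defaults emulate the study conditions of a sequenced cimbicid sawfly
#' mitogenome: 15,405 bp target length, the ancestral insect gene order
#' plus a control region between `rrnS` and `trnI`, 81.2% A+T with
#' AT-skew 0.0714 and GC-skew -0.1809 in the non-coding emission, and
#' PCG codons drawn from the published codon-usage bias.
#'
#' @param genome_length_target target circle length (bp).
#' @param gene_order a [signed_gene_order()] of the 37 genes.
#' @param at_fraction,at_skew_target,gc_skew_target emission targets for
#'   non-coding sequence (spacers, rRNAs, control region, tRNA loops).
#' @param codon_weights named positive weights per sense codon driving
#'   PCG codon sampling (default: the packaged published codon counts).
#' @param gap_model list: `p_zero` (probability an adjacency abuts),
#'   `max_gap` (uniform 1..max_gap otherwise), `overlap_pairs` (named
#'   integer vector `"upstream|downstream" = bp` of planted overlaps).
#' @param rearrangement_ops operations handed to
#'   [apply_rearrangements()] before layout.
#' @param pos3_reweight steer composition toward `at_fraction` through
#'   the freely-varying positions (third codon positions within each
#'   synonymous family, tRNA stems, and all non-coding emission), first
#'   and second codon positions being constrained by amino-acid choice.
#'   When `FALSE`, codons are drawn exactly proportional to
#'   `codon_weights` and only non-coding emission follows the targets.
#' @param seed integer seed.
#' @return list of class `simulation_params`.
#' @export
simulation_params <- function(genome_length_target = 15405L,
                              gene_order = ancestral_insect_order(),
                              at_fraction = 0.812,
                              at_skew_target = 0.0714,
                              gc_skew_target = -0.1809,
                              codon_weights = NULL,
                              gap_model = list(p_zero = 0.4, max_gap = 6L,
                                               overlap_pairs = NULL),
                              rearrangement_ops = list(),
                              pos3_reweight = TRUE,
                              seed = 1L) {
  if (is.null(codon_weights)) {
    cc <- lsinicus_codon_counts()
    codon_weights <- setNames(as.numeric(cc$Count), cc$Codon)
    codon_weights <- codon_weights[!names(codon_weights) %in% c("TAA", "TAG")]
  }
  if (any(codon_weights < 0)) stop("codon weights must be non-negative")
  structure(list(genome_length_target = as.integer(genome_length_target),
                 gene_order = gene_order,
                 at_fraction = at_fraction,
                 at_skew_target = at_skew_target,
                 gc_skew_target = gc_skew_target,
                 codon_weights = codon_weights,
                 gap_model = gap_model,
                 rearrangement_ops = rearrangement_ops,
                 pos3_reweight = isTRUE(pos3_reweight),
                 seed = as.integer(seed)),
            class = "simulation_params")
}

## Draw one PCG coding sequence: ATN start ~ weight-proportional, internal
## codons ~ codon_weights (stops excluded), complete TAA stop.
sim_pcg_sequence <- function(len, weights, code = genetic_code()) {
  stopifnot(len %% 3L == 0L, len >= 9L)
  w <- weights[!names(weights) %in% code$stop_codons]
  starts <- w[intersect(c("ATT", "ATC", "ATA", "ATG"), names(w))]
  if (!sum(starts)) starts <- c(ATT = 1, ATC = 1, ATA = 1, ATG = 1)
  start <- sample(names(starts), 1L, prob = starts)
  n_int <- len %/% 3L - 2L
  internal <- sample(names(w), n_int, replace = TRUE, prob = w)
  paste(c(start, internal, "TAA"), collapse = "")
}

#' Simulate an annotated mitogenome with known ground truth
#'
#' Features tile the circle in the (optionally rearranged) gene order
#' with gaps from the gap model; the control region absorbs the length
#' budget so the target length is met exactly.  PCG sequences are drawn
#' codon-wise from the codon weights with an ATN start and a complete
#' TAA stop; tRNAs are folded cloverleaves from [simulate_trna()] with
#' the standard anticodon planted; rRNAs, spacers and the control region
#' are emitted base-wise at the composition targets.  Minority-strand
#' genes are reverse-complemented into the J-strand sequence.  Where an
#' overlap is planted, the downstream feature's sequence overwrites the
#' tail of the upstream one (as in real shared-motif overlaps), so
#' declared metadata stays consistent.
#'
#' Deterministic per seed: identical params give byte-identical output.
#'
#' @param params a [simulation_params()].
#' @return list: `genome` (an [annotated_genome()] with sequence),
#'   `truth` (list: realized gaps, per-feature lengths and sequences,
#'   planted rearrangement labels, tRNA structures, params).
#' @export
simulate_genome <- function(params = simulation_params()) {
  p <- params
  order <- p$gene_order
  planted <- list(order = order, labels = setNames(character(0), character(0)))
  if (length(p$rearrangement_ops)) {
    planted <- apply_rearrangements(order, p$rearrangement_ops, seed = p$seed)
    order <- planted$order
  }

  symbols <- c(format_signed(order), CONTROL_REGION)
  neg <- grepl("^-", symbols)
  names_ <- sub("^-", "", symbols)
  strands <- ifelse(neg, "N", "J")
  strands[names_ == CONTROL_REGION] <- "J"
  n <- length(names_)

  ## feature lengths
  trna_specs <- list()
  lens <- integer(n)
  for (i in seq_len(n)) {
    nm <- names_[i]
    cat_i <- gene_category(nm)
    lens[i] <- switch(cat_i,
      PCG = SIM_PCG_LENGTHS[[nm]],
      rRNA = SIM_RRNA_LENGTHS[[nm]],
      tRNA = {
        spec <- with_stream(p$seed, paste0("arm_", nm), list(
          dhu_loop = sample(5:7, 1L), variable_nt = sample(3:5, 1L)))
        spec$anticodon <- STANDARD_ANTICODONS[[nm]]
        if (nm == "trnS1") spec$dhu_bp <- 0L  # AGN serine lacks the DHU arm
        trna_specs[[nm]] <- spec
        NA_integer_  # fixed after structure generation
      },
      control_region = NA_integer_)
  }

  ## Composition control.  First and second codon positions are fixed by
  ## amino-acid choice, so the A+T target is solved for on the freely
  ## varying fraction (third positions, tRNA stems/loops, rRNA, spacers,
  ## control region): emit those at a_ctrl such that the expected
  ## whole-genome A+T equals at_fraction.  Third positions are steered by
  ## reweighting codons within each synonymous family by the ratio of the
  ## target third-base distribution to the weights' own third-base
  ## marginal, so the relative within-family bias shape is preserved.
  at_of <- function(b) as.numeric(b %in% c("A", "T"))
  w <- p$codon_weights / sum(p$codon_weights)
  b1 <- substring(names(w), 1L, 1L); b2 <- substring(names(w), 2L, 2L)
  b3 <- substring(names(w), 3L, 3L)
  a_fix <- sum(w * (at_of(b1) + at_of(b2))) / 2
  f_fix <- (2 / 3) * sum(SIM_PCG_LENGTHS) / p$genome_length_target
  a_ctrl <- if (p$pos3_reweight)
    min(max((p$at_fraction - f_fix * a_fix) / (1 - f_fix), 0.05), 0.98)
  else p$at_fraction
  pcg_weights <- p$codon_weights
  if (p$pos3_reweight) {
    q <- emission_probs(a_ctrl, p$at_skew_target, p$gc_skew_target)
    q0 <- vapply(c("A", "C", "G", "T"), function(b) sum(w[b3 == b]), numeric(1))
    adj <- (q / pmax(q0, 1e-9))[b3]
    pcg_weights <- p$codon_weights * adj
  }

  ## tRNA structures (also fixes their lengths)
  trna_out <- list()
  for (nm in names(trna_specs)) {
    s <- trna_specs[[nm]]
    trna_out[[nm]] <- simulate_trna(
      aa_bp = 7L, dhu_bp = s$dhu_bp %||% 4L, dhu_loop = s$dhu_loop,
      ac_bp = 5L, ac_loop = 7L, tpsic_bp = 5L, tpsic_loop = 5L,
      variable_nt = s$variable_nt, anticodon = s$anticodon,
      n_gu = 0L, mismatches = NULL,
      at_fraction = a_ctrl, seed = stream_seed(p$seed, paste0("trna_", nm)),
      label = nm)
    lens[match(nm, names_)] <- nchar(trna_out[[nm]]$sequence)
  }

  ## adjacency gaps (gap before feature i+1; wrap gap after control region = 0)
  gaps <- with_stream(p$seed, "gaps", {
    g <- integer(n - 1L)
    for (i in seq_len(n - 1L)) {
      g[i] <- if (runif(1L) < (p$gap_model$p_zero %||% 0.4)) 0L
      else sample.int(p$gap_model$max_gap %||% 6L, 1L)
    }
    g
  })
  ov <- p$gap_model$overlap_pairs
  if (!is.null(ov)) {
    keys <- paste(names_[-n], names_[-1L], sep = "|")
    hit <- match(names(ov), keys)
    if (anyNA(hit))
      stop("overlap pair(s) not adjacent in this order: ",
           paste(names(ov)[is.na(hit)], collapse = ", "))
    gaps[hit] <- -as.integer(ov)
  }

  ## control region absorbs the remaining budget
  known <- sum(lens, na.rm = TRUE)
  cr_len <- p$genome_length_target - known - sum(gaps)
  if (cr_len < 50L)
    stop("infeasible layout: control region would be ", cr_len,
         " bp; raise genome_length_target or shrink gaps")
  lens[names_ == CONTROL_REGION] <- cr_len

  ## place features
  starts <- integer(n); stops <- integer(n)
  pos <- 1L
  for (i in seq_len(n)) {
    if (i > 1L) pos <- stops[i - 1L] + gaps[i - 1L] + 1L
    starts[i] <- pos
    stops[i] <- pos + lens[i] - 1L
  }
  glen <- stops[n]  # wrap gap 0: control region abuts trnI across the origin
  stopifnot(glen == p$genome_length_target)

  ## sequences (coding sense), then paint the J strand
  noncoding_probs <- emission_probs(a_ctrl, p$at_skew_target,
                                    p$gc_skew_target)
  seqs <- character(n)
  for (i in seq_len(n)) {
    nm <- names_[i]
    seqs[i] <- switch(gene_category(nm),
      PCG = with_stream(p$seed, paste0("pcg_", nm),
                        sim_pcg_sequence(lens[i], pcg_weights)),
      tRNA = chartr("U", "T", trna_out[[nm]]$sequence),
      with_stream(p$seed, paste0("nc_", nm),
                  sample_bases(lens[i], noncoding_probs)))
  }
  genome_seq <- chars(with_stream(p$seed, "spacers",
                                  sample_bases(glen, noncoding_probs)))
  for (i in seq_len(n)) {
    s <- seqs[i]
    if (strands[i] == "N") s <- revcomp(s)
    genome_seq[starts[i]:stops[i]] <- chars(s)
  }
  genome_seq <- paste(genome_seq, collapse = "")

  feats <- do.call(rbind, lapply(seq_len(n), function(i) {
    nm <- names_[i]
    cat_i <- gene_category(nm)
    cs <- seqs[i]
    gene_feature(
      name = nm, strand = strands[i], start = starts[i], stop = stops[i],
      declared_length = lens[i],
      start_codon = if (cat_i == "PCG") substring(cs, 1L, 3L) else NA,
      stop_codon = if (cat_i == "PCG")
        substring(cs, nchar(cs) - 2L, nchar(cs)) else NA,
      anticodon = if (cat_i == "tRNA") STANDARD_ANTICODONS[[nm]] else NA,
      declared_ign = if (i == 1L) 0L else gaps[i - 1L])
  }))

  genome <- annotated_genome(feats, length = glen, circular = TRUE,
                             organism = "synthetic mitogenome",
                             accession = sprintf("SYN%06d", p$seed %% 1000000L),
                             sequence = genome_seq)
  list(genome = genome,
       truth = list(order = order, gaps = gaps, lengths = setNames(lens, names_),
                    sequences = setNames(seqs, names_),
                    rearrangement_labels = planted$labels,
                    trna = trna_out, params = p))
}

#' Apply rearrangement operations to a gene order
#'
#' Operations are applied left to right.  Each op is a list with `op` in
#' `translocate` / `invert` / `swap` and `genes` (one symbol, or the two
#' adjacent symbols of a swap); `translocate` takes an optional `after`
#' symbol (destination; drawn at random, seeded, when absent).  Emitted
#' ground-truth labels use the event-classification vocabulary: a gene
#' both translocated and inverted is labelled `remote_inversion`.
#'
#' @param order a [signed_gene_order()].
#' @param ops list of operations.
#' @param seed integer seed (used for unspecified destinations).
#' @return list: `order` (rearranged), `labels` (named character vector
#'   over the affected genes).
#' @export
apply_rearrangements <- function(order, ops, seed = 1L) {
  syms <- order$symbols
  ori <- order$orientation
  touched <- list()
  note <- function(g, what) touched[[g]] <<- union(touched[[g]], what)
  k <- 0L
  for (op in ops) {
    k <- k + 1L
    genes <- op$genes
    if (any(!genes %in% syms))
      stop("operation on missing symbol(s): ",
           paste(setdiff(genes, syms), collapse = ", "))
    if (op$op == "invert") {
      i <- match(genes[1L], syms)
      ori[i] <- if (ori[i] == "+") "-" else "+"
      note(genes[1L], "invert")
    } else if (op$op == "swap") {
      stopifnot(length(genes) == 2L)
      i <- match(genes[1L], syms); j <- match(genes[2L], syms)
      n <- length(syms)
      if (!(j - i) %% n %in% c(1L, n - 1L))
        stop("swap requires adjacent genes: ", paste(genes, collapse = ", "))
      tmp <- syms[i]; syms[i] <- syms[j]; syms[j] <- tmp
      tmp <- ori[i]; ori[i] <- ori[j]; ori[j] <- tmp
      note(genes[1L], "swap"); note(genes[2L], "swap")
    } else if (op$op == "translocate") {
      g <- genes[1L]
      i <- match(g, syms)
      o_g <- ori[i]
      syms <- syms[-i]; ori <- ori[-i]
      dest <- op$after
      if (is.null(dest)) {
        dest <- with_stream(seed, paste0("translocate_", k), {
          # land somewhere that actually changes both neighbors
          cand <- setdiff(syms, c(g))
          pos <- match(g, order$symbols)
          old_left <- order$symbols[((pos - 2L) %% length(order$symbols)) + 1L]
          sample(setdiff(cand, old_left), 1L)
        })
      }
      if (!dest %in% syms) stop("translocate destination missing: ", dest)
      j <- match(dest, syms)
      syms <- append(syms, g, after = j)
      ori <- append(ori, o_g, after = j)
      note(g, "translocate")
    } else stop("unknown op: ", op$op)
  }
  labels <- vapply(names(touched), function(g) {
    w <- touched[[g]]
    if (all(c("translocate", "invert") %in% w)) "remote_inversion"
    else if ("swap" %in% w) "swapped"
    else if ("translocate" %in% w) "translocated"
    else "inverted"
  }, character(1L))
  list(order = signed_gene_order(syms, ori), labels = labels)
}

#' Simulate a tRNA cloverleaf with planted pair classes
#'
#' Builds a cloverleaf dot-bracket with the requested arm lengths, fills
#' stems with Watson-Crick pairs, then plants the requested number of
#' G:U wobbles and named mismatches at distinct random stem positions.
#' The anticodon occupies the central triplet of the anticodon loop.
#'
#' @param aa_bp,dhu_bp,ac_bp,tpsic_bp stem lengths in bp (`dhu_bp = 0`
#'   or `tpsic_bp = 0` omits that arm).
#' @param dhu_loop,ac_loop,tpsic_loop,variable_nt loop/linker lengths
#'   in nt.
#' @param anticodon RNA triplet planted in the AC loop.
#' @param n_gu number of planted G:U pairs.
#' @param mismatches named integer vector of planted mismatches, e.g.
#'   `c("U-U" = 2, "A-C" = 1)`.
#' @param at_fraction A+U richness of unpaired positions.
#' @param seed integer seed.
#' @param label structure name.
#' @return list of class `trna_simulation`: `sequence` (RNA),
#'   `structure` (dot-bracket), `paired` (a `paired_structure`), `truth`
#'   (arm lengths and planted class counts).
#' @export
simulate_trna <- function(aa_bp = 7L, dhu_bp = 4L, dhu_loop = 6L,
                          ac_bp = 5L, ac_loop = 7L, tpsic_bp = 5L,
                          tpsic_loop = 5L, variable_nt = 4L,
                          anticodon = "UCA", n_gu = 0L, mismatches = NULL,
                          at_fraction = 0.8, seed = 1L, label = "trna") {
  stopifnot(aa_bp >= 1L, ac_bp >= 1L, ac_loop >= 3L, ac_loop %% 2L == 1L)
  db <- c(rep("(", aa_bp), rep(".", 2L))
  if (dhu_bp > 0L)
    db <- c(db, rep("(", dhu_bp), rep(".", dhu_loop), rep(")", dhu_bp), ".")
  else db <- c(db, rep(".", max(dhu_loop, 1L)))
  db <- c(db, rep("(", ac_bp), rep(".", ac_loop), rep(")", ac_bp))
  db <- c(db, rep(".", variable_nt))
  if (tpsic_bp > 0L)
    db <- c(db, rep("(", tpsic_bp), rep(".", tpsic_loop), rep(")", tpsic_bp))
  db <- c(db, rep(")", aa_bp))
  db <- paste(db, collapse = "")

  skel <- parse_dotbracket(strrep("N", nchar(db)), db, label = label)
  pairs <- skel$pairs
  n_pl <- nrow(pairs)
  planted_total <- n_gu + sum(mismatches %||% 0L)
  if (planted_total > n_pl)
    stop("requested ", planted_total, " non-WC pairs but only ", n_pl,
         " stem positions")

  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  probs <- emission_probs(at_fraction, 0, 0)
  names(probs) <- c("A", "C", "G", "U")
  seqc <- chars(chartr("T", "U", sample_bases(nchar(db), probs)))

  slots <- sample.int(n_pl, planted_total)
  gu_slots <- head(slots, n_gu)
  mm_slots <- tail(slots, length(slots) - n_gu)
  wc <- list(c("A", "U"), c("U", "A"), c("G", "C"), c("C", "G"))
  for (k in seq_len(n_pl)) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    if (k %in% gu_slots) {
      b <- if (runif(1L) < 0.5) c("G", "U") else c("U", "G")
    } else if (k %in% mm_slots) {
      mm_names <- rep(names(mismatches), mismatches)
      b <- strsplit(mm_names[match(k, mm_slots)], "-", fixed = TRUE)[[1L]]
      if (runif(1L) < 0.5) b <- rev(b)
    } else {
      # A:U vs G:C stacked pairs follow the A+U richness target
      b <- wc[[sample.int(4L, 1L,
                          prob = c(at_fraction, at_fraction,
                                   1 - at_fraction, 1 - at_fraction))]]
    }
    seqc[i] <- b[1L]; seqc[j] <- b[2L]
  }
  # plant the anticodon at the centre of the AC loop
  ac_open <- aa_bp + 2L + (if (dhu_bp > 0L) 2L * dhu_bp + dhu_loop + 1L
                           else max(dhu_loop, 1L)) + ac_bp
  mid <- ac_open + (ac_loop + 1L) %/% 2L
  seqc[(mid - 1L):(mid + 1L)] <- chars(toupper(anticodon))

  seq <- paste(seqc, collapse = "")
  structure(
    list(sequence = seq, structure = db,
         paired = parse_dotbracket(seq, db, label = label),
         truth = list(aa_bp = aa_bp, dhu_bp = dhu_bp, ac_bp = ac_bp,
                      tpsic_bp = tpsic_bp, ac_loop = ac_loop,
                      variable_nt = variable_nt, anticodon = toupper(anticodon),
                      n_gu = n_gu, mismatches = mismatches)),
    class = "trna_simulation")
}

#' Write the ground-truth sidecar of a simulation
#'
#' @param truth the `truth` element returned by [simulate_genome()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_simulation_truth <- function(truth, path) {
  out <- list(
    gene_order = format_signed(truth$order),
    gaps = as.integer(truth$gaps),
    lengths = as.list(truth$lengths),
    rearrangement_labels = as.list(truth$rearrangement_labels),
    seed = truth$params$seed,
    genome_length_target = truth$params$genome_length_target,
    at_fraction = truth$params$at_fraction)
  yaml::write_yaml(out, path)
  invisible(path)
}
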