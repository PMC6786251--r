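## RNA secondary-structure statistics: dot-bracket parsing, base-pair
## classification, and the tRNA cloverleaf arm audit.

#' Parse a dot-bracket secondary structure
#'
#' @param seq RNA (or DNA; `T` read as `U`) string.
#' @param structure dot-bracket string of the same length, `(`/`)`/`.`.
#' @param label name of the RNA gene.
#' @param allow_pseudoknots accept additional bracket tiers `[]`, `{}`
#'   (pairs then need not nest).  Default `FALSE`: crossing pairs are an
#'   error.
#' @return object of class `paired_structure`: `sequence` (RNA,
#'   upper-case), `pairs` (two-column matrix of 1-based indices, i < j),
#'   `label`.
#' @export
parse_dotbracket <- function(seq, structure, label = "",
                             allow_pseudoknots = FALSE) {
  if (nchar(seq) != nchar(structure))
    stop("sequence and structure lengths differ (", nchar(seq), " vs ",
         nchar(structure), ")")
  rna <- chartr("Tt", "Uu", toupper(seq))
  ch <- chars(structure)
  tiers <- list(c("(", ")"))
  if (allow_pseudoknots) tiers <- c(tiers, list(c("[", "]"), c("{", "}")))
  allowed <- c(".", unlist(tiers))
  bad <- which(!ch %in% allowed)
  if (length(bad))
    stop("invalid structure character '", ch[bad[1L]], "' at position ", bad[1L])
  pairs <- matrix(integer(0), ncol = 2L)
  for (tier in tiers) {
    stack <- integer(0)
    for (i in seq_along(ch)) {
      if (ch[i] == tier[1L]) stack <- c(stack, i)
      else if (ch[i] == tier[2L]) {
        if (!length(stack))
          stop("unbalanced '", tier[2L], "' at position ", i)
        pairs <- rbind(pairs, c(stack[length(stack)], i))
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack))
      stop("unbalanced '", tier[1L], "' at position ", stack[length(stack)])
  }
  if (nrow(pairs)) pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  if (!allow_pseudoknots && nrow(pairs) > 1L) {
    # stack parsing of a single tier cannot produce crossings, but guard
    # the invariant for programmatically built inputs
    for (k in seq_len(nrow(pairs) - 1L)) {
      i <- pairs[k, 1L]; j <- pairs[k, 2L]
      l <- pairs[k + 1L, 1L]; m <- pairs[k + 1L, 2L]
      if (l < j && m > j)
        stop("crossing pairs (", i, ",", j, ") and (", l, ",", m, ")")
    }
  }
  structure(list(sequence = toupper(rna), pairs = pairs, label = label),
            class = "paired_structure")
}

#' Read dot-bracket structure files
#'
#' Two dialects: a plain two-line file (sequence line, structure line) or
#' a multi-record file of `> name` headers each followed by sequence and
#' structure lines.
#'
#' @param path file path.
#' @param allow_pseudoknots passed to [parse_dotbracket()].
#' @return list of `paired_structure` objects (length one for the plain
#'   dialect).
#' @export
read_dotbracket <- function(path, allow_pseudoknots = FALSE) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty structure file: ", path)
  out <- list()
  if (startsWith(lines[1L], ">")) {
    heads <- grep("^>", lines)
    if (any(diff(c(heads, length(lines) + 1L)) != 3L))
      stop("multi-record dot-bracket file must have 2 lines per record")
    for (h in heads) {
      nm <- trimws(sub("^>", "", lines[h]))
      out[[nm]] <- parse_dotbracket(lines[h + 1L], lines[h + 2L], label = nm,
                                    allow_pseudoknots = allow_pseudoknots)
    }
  } else {
    if (length(lines) != 2L)
      stop("plain dot-bracket file must have exactly 2 lines")
    nm <- tools::file_path_sans_ext(basename(path))
    out[[nm]] <- parse_dotbracket(lines[1L], lines[2L], label = nm,
                                  allow_pseudoknots = allow_pseudoknots)
  }
  out
}

#' Write dot-bracket structures
#'
#' @param structures list of `paired_structure` objects (nested pairs).
#' @param path output path (multi-record `> name` dialect).
#' @return `path`, invisibly.
#' @export
write_dotbracket <- function(structures, path) {
  con <- file(path, "wt"); on.exit(close(con))
  for (s in structures) {
    db <- rep(".", nchar(s$sequence))
    if (nrow(s$pairs)) {
      db[s$pairs[, 1L]] <- "("
      db[s$pairs[, 2L]] <- ")"
    }
    writeLines(c(paste0("> ", s$label), s$sequence,
                 paste(db, collapse = "")), con)
  }
  invisible(path)
}

#' Classify base pairs of a structure
#'
#' Watson-Crick pairs are A:U and G:C; G:U is the wobble class; anything
#' else is a named mismatch.  Because published tRNA mismatch censuses
#' commonly count G:U among the "unmatched" pairs, the noncanonical tally
#' (`wobble + mismatches`) is reported alongside the strict classes.
#'
#' @param structure a `paired_structure`.
#' @return list of class `pair_class_counts`: `n_pairs`, `watson_crick`,
#'   `gu_wobble`, `mismatches` (named integer vector, e.g. `"U-U"`),
#'   `noncanonical` (= `gu_wobble + sum(mismatches)`).
#' @export
classify_pairs <- function(structure) {
  p <- structure$pairs
  ch <- chars(structure$sequence)
  wc <- 0L; gu <- 0L
  mism <- integer(0)
  for (k in seq_len(nrow(p))) {
    b <- sort(c(ch[p[k, 1L]], ch[p[k, 2L]]))
    key <- paste(b, collapse = "-")
    if (key %in% c("A-U", "C-G")) wc <- wc + 1L
    else if (key == "G-U") gu <- gu + 1L
    else mism[key] <- (if (is.na(mism[key])) 0L else mism[key]) + 1L
  }
  structure(list(n_pairs = nrow(p), watson_crick = wc, gu_wobble = gu,
                 mismatches = mism,
                 noncanonical = gu + sum(mism)),
            class = "pair_class_counts")
}

#' @export
print.pair_class_counts <- function(x, ...) {
  cat("Base-pair classes over", x$n_pairs, "pairs\n")
  cat("  Watson-Crick:", x$watson_crick, "\n")
  cat("  G-U wobble:  ", x$gu_wobble, "\n")
  if (length(x$mismatches))
    cat("  mismatches:  ",
        paste(sprintf("%s x%d", names(x$mismatches), x$mismatches),
              collapse = ", "), "\n")
  cat("  noncanonical (wobble + mismatches):", x$noncanonical, "\n")
  invisible(x)
}

## Decompose nested pairs into helical stems: maximal runs of stacked
## pairs (i, j), (i+1, j-1), ...
find_stems <- function(pairs) {
  if (!nrow(pairs)) return(list())
  pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  stems <- list()
  cur <- pairs[1L, , drop = FALSE]
  for (k in seq_len(nrow(pairs))[-1L]) {
    prev <- cur[nrow(cur), ]
    if (pairs[k, 1L] == prev[1L] + 1L && pairs[k, 2L] == prev[2L] - 1L) {
      cur <- rbind(cur, pairs[k, ])
    } else {
      stems[[length(stems) + 1L]] <- cur
      cur <- pairs[k, , drop = FALSE]
    }
  }
  stems[[length(stems) + 1L]] <- cur
  stems
}

#' Audit a tRNA cloverleaf structure
#'
#' Decomposes the (nested) pairs of a tRNA-like fold into the four
#' canonical stems: the amino-acid acceptor (AA) stem is the outermost
#' helix; the helices branching off the central multiloop are, in 5'
#' to 3' order, the DHU arm, the anticodon (AC) arm and the T\eqn{\Psi}C
#' arm.  When only two multiloop helices are present, the AC arm is taken
#' as the helix whose loop length is closest to the canonical 7 nt (later
#' helix on ties) and the absent arm (DHU or T\eqn{\Psi}C, by position)
#' is reported in `missing_arms`.  The anticodon is the central triplet
#' of the AC loop.  An unpaired 3' tail (discriminator/CCA) is ignored.
#'
#' @param structure a `paired_structure` with nested pairs.
#' @return list of class `cloverleaf_audit`: `aa_stem_bp`, `dhu_arm_bp`,
#'   `ac_arm_bp`, `tpsic_arm_bp` (`NA` when the arm is missing),
#'   `dhu_loop_nt`, `ac_loop_nt`, `tpsic_loop_nt`, `variable_loop_nt`,
#'   `anticodon`, `missing_arms`.
#' @export
cloverleaf_audit <- function(structure) {
  p <- structure$pairs
  if (!nrow(p)) stop("structure has no pairs; not tRNA-like")
  stems <- find_stems(p)
  # outermost stem: contains the pair with the smallest i (and largest j)
  outer_idx <- which.min(vapply(stems, function(s) s[1L, 1L], numeric(1)))
  aa <- stems[[outer_idx]]
  inner <- stems[-outer_idx]
  # helices hanging directly off the multiloop enclosed by the AA stem
  aa_i <- aa[nrow(aa), 1L]; aa_j <- aa[nrow(aa), 2L]
  inner <- inner[vapply(inner, function(s)
    s[1L, 1L] > aa_i & s[1L, 2L] < aa_j, logical(1))]
  # keep only top-level helices (not nested inside another inner stem)
  if (length(inner) > 1L) {
    top <- vapply(seq_along(inner), function(k) {
      s <- inner[[k]]
      !any(vapply(inner[-k], function(t)
        t[1L, 1L] < s[1L, 1L] & t[1L, 2L] > s[1L, 2L], logical(1)))
    }, logical(1))
    inner <- inner[top]
  }
  if (length(inner) > 3L)
    stop("more than 3 helices off the multiloop; not tRNA-like")
  if (length(inner) < 1L)
    stop("no helices off the multiloop; not tRNA-like")
  inner <- inner[order(vapply(inner, function(s) s[1L, 1L], numeric(1)))]
  loop_len <- function(s) s[nrow(s), 2L] - s[nrow(s), 1L] - 1L

  missing <- character(0)
  if (length(inner) == 3L) {
    dhu <- inner[[1L]]; ac <- inner[[2L]]; tpc <- inner[[3L]]
  } else if (length(inner) == 2L) {
    d <- abs(vapply(inner, loop_len, numeric(1)) - 7)
    ac_k <- if (d[2L] <= d[1L]) 2L else 1L
    ac <- inner[[ac_k]]
    other <- inner[[3L - ac_k]]
    if (ac_k == 2L) { dhu <- other; tpc <- NULL; missing <- "TPSIC" }
    else { dhu <- NULL; tpc <- other; missing <- "DHU" }
  } else {
    ac <- inner[[1L]]; dhu <- NULL; tpc <- NULL; missing <- c("DHU", "TPSIC")
  }

  ac_loop <- loop_len(ac)
  ac_inner <- ac[nrow(ac), ]
  mid <- ac_inner[1L] + (ac_loop + 1L) %/% 2L
  anticodon <- substring(structure$sequence, mid - 1L, mid + 1L)

  structure(
    list(aa_stem_bp = nrow(aa),
         dhu_arm_bp = if (is.null(dhu)) NA_integer_ else nrow(dhu),
         ac_arm_bp = nrow(ac),
         tpsic_arm_bp = if (is.null(tpc)) NA_integer_ else nrow(tpc),
         dhu_loop_nt = if (is.null(dhu)) NA_integer_ else loop_len(dhu),
         ac_loop_nt = ac_loop,
         tpsic_loop_nt = if (is.null(tpc)) NA_integer_ else loop_len(tpc),
         variable_loop_nt = if (is.null(tpc)) NA_integer_ else
           tpc[1L, 1L] - ac[1L, 2L] - 1L,
         anticodon = anticodon,
         missing_arms = missing),
    class = "cloverleaf_audit")
}

#' @export
print.cloverleaf_audit <- function(x, ...) {
  cat("Cloverleaf audit\n")
  cat(sprintf("  AA stem %d bp | DHU %s bp | AC %d bp (loop %d nt) | TPsiC %s bp\n",
              x$aa_stem_bp, x$dhu_arm_bp, x$ac_arm_bp, x$ac_loop_nt,
              x$tpsic_arm_bp))
  cat("  anticodon:", x$anticodon, "\n")
  if (length(x$missing_arms))
    cat("  missing arms:", paste(x$missing_arms, collapse = ", "), "\n")
  invisible(x)
}

#' Structure census over a set of RNA structures
#'
#' Per-structure pair-class counts plus grand totals, in the style of a
#' per-genome tRNA mismatch census.
#'
#' @param structures list of `paired_structure` objects.
#' @return data.frame with one row per structure and a `total` row.
#' @export
structure_census <- function(structures) {
  rows <- lapply(structures, function(s) {
    cc <- classify_pairs(s)
    data.frame(label = s$label, n_pairs = cc$n_pairs,
               watson_crick = cc$watson_crick, gu_wobble = cc$gu_wobble,
               other_mismatch = sum(cc$mismatches),
               noncanonical = cc$noncanonical, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  total <- data.frame(label = "total", n_pairs = sum(out$n_pairs),
                      watson_crick = sum(out$watson_crick),
                      gu_wobble = sum(out$gu_wobble),
                      other_mismatch = sum(out$other_mismatch),
                      noncanonical = sum(out$noncanonical),
                      stringsAsFactors = FALSE)
  out <- rbind(out, total)
  rownames(out) <- NULL
  out
}
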