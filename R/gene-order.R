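## Signed circular gene orders, breakpoint distance and rearrangement-event
## classification against a reference arrangement.
##
## Orientation convention: J strand = "+", N strand = "-".  Equality of
## orders is defined up to rotation; equality up to full reflection with
## sign flip is available as an option but off by default (mitogenomes
## have a fixed majority strand).

#' Construct a signed circular gene order
#'
#' @param symbols character vector of unique gene symbols, in circular
#'   order.
#' @param orientation character vector of `"+"`/`"-"`, one per symbol.
#' @return object of class `signed_gene_order` with elements `symbols`,
#'   `orientation` and `origin` (index of `trnI` when present, else 1).
#' @export
signed_gene_order <- function(symbols, orientation = rep("+", length(symbols))) {
  symbols <- as.character(symbols)
  orientation <- as.character(orientation)
  if (length(symbols) != length(orientation))
    stop("symbols and orientation lengths differ")
  if (!length(symbols)) stop("empty gene order")
  if (anyDuplicated(symbols))
    stop("duplicate symbols: ",
         paste(unique(symbols[duplicated(symbols)]), collapse = ", "))
  if (!all(orientation %in% c("+", "-")))
    stop("orientation must be '+' or '-'")
  origin <- match("trnI", symbols)
  structure(list(symbols = symbols, orientation = orientation,
                 origin = if (is.na(origin)) 1L else origin),
            class = "signed_gene_order")
}

#' @export
print.signed_gene_order <- function(x, ...) {
  cat("Signed circular gene order (", length(x$symbols), " genes)\n  ",
      paste(format_signed(x), collapse = ","), "\n", sep = "")
  invisible(x)
}

#' @export
length.signed_gene_order <- function(x) length(x$symbols)

#' Signed tokens of a gene order
#'
#' @param order a [signed_gene_order()].
#' @return character vector of tokens (`"-trnQ"`, `"trnM"`, ...), read
#'   from the conventional origin (`trnI` when present).
#' @export
format_signed <- function(order) {
  x <- rotate_order(order, order$origin)
  paste0(ifelse(x$orientation == "-", "-", ""), x$symbols)
}

## Rotate so position `i` becomes first.
rotate_order <- function(order, i) {
  n <- length(order$symbols)
  idx <- ((seq_len(n) + i - 2L) %% n) + 1L
  signed_gene_order(order$symbols[idx], order$orientation[idx])
}

## Reflect and flip signs (read the circle backwards on the other strand).
reflect_order <- function(order) {
  signed_gene_order(rev(order$symbols),
                    ifelse(rev(order$orientation) == "+", "-", "+"))
}

#' Test equality of signed circular orders
#'
#' @param a,b `signed_gene_order` objects over the same symbols.
#' @param reflection also accept equality up to full reflection with sign
#'   flip (default `FALSE`).
#' @return logical.
#' @export
orders_equal <- function(a, b, reflection = FALSE) {
  if (!setequal(a$symbols, b$symbols) || length(a) != length(b)) return(FALSE)
  sa <- paste(format_signed(rotate_order(a, match(a$symbols[1L], a$symbols))),
              collapse = ",")
  eq_rot <- function(x) {
    i <- match(a$symbols[1L], x$symbols)
    if (is.na(i)) return(FALSE)
    identical(sa, paste(format_signed_from(x, i), collapse = ","))
  }
  if (eq_rot(b)) return(TRUE)
  if (reflection && eq_rot(reflect_order(b))) return(TRUE)
  FALSE
}

## Signed tokens starting at index i (no origin convention).
format_signed_from <- function(order, i) {
  x <- rotate_order(order, i)
  paste0(ifelse(x$orientation == "-", "-", ""), x$symbols)
}

#' Encode the gene order of an annotated genome
#'
#' Features sorted by start position become a signed circular permutation:
#' strand J maps to `+`, strand N to `-`.  The control region is excluded
#' by default (it is not a gene).
#'
#' @param genome an [annotated_genome()].
#' @param include_control_region keep the control region as an element.
#' @return a [signed_gene_order()].
#' @export
encode_order <- function(genome, include_control_region = FALSE) {
  f <- genome$features[order(genome$features$start), , drop = FALSE]
  if (!include_control_region)
    f <- f[f$category != "control_region", , drop = FALSE]
  if (!nrow(f)) stop("no features to encode")
  signed_gene_order(f$name, ifelse(f$strand == "N", "-", "+"))
}

#' Read / write plain-text gene-order files
#'
#' Format: one comma-separated line of signed symbols, `-` prefix for the
#' minority strand; `#` lines are comments.
#'
#' @param path file path.
#' @return [signed_gene_order()] (reader); `path` invisibly (writer).
#' @export
read_gene_order <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines[!grepl("^\\s*#", lines)])
  lines <- lines[nzchar(lines)]
  if (length(lines) != 1L)
    stop("gene-order file must contain exactly one order line: ", path)
  toks <- trimws(strsplit(lines, ",", fixed = TRUE)[[1L]])
  neg <- grepl("^-", toks)
  signed_gene_order(sub("^-", "", toks), ifelse(neg, "-", "+"))
}

#' @rdname read_gene_order
#' @param order a [signed_gene_order()].
#' @export
write_gene_order <- function(order, path) {
  writeLines(paste(format_signed(order), collapse = ","), path)
  invisible(path)
}

## Canonical signed adjacency tokens of a circular order:
## (x, y) is identified with (-y, -x).
adjacency_tokens <- function(order) {
  n <- length(order$symbols)
  if (n < 2L) return(character(0))
  tok <- paste0(ifelse(order$orientation == "-", "-", ""), order$symbols)
  neg <- function(t) ifelse(grepl("^-", t), sub("^-", "", t), paste0("-", t))
  x <- tok
  y <- c(tok[-1L], tok[1L])
  fwd <- paste(x, y, sep = "|")
  rev <- paste(neg(y), neg(x), sep = "|")
  pmin(fwd, rev)
}

#' Breakpoint distance between signed circular gene orders
#'
#' The number of signed adjacencies of `a` (circular, orientation-aware,
#' with `(x, y)` identified with `(-y, -x)`) that are absent from `b`.
#' Symmetric, zero for rotations of the same order.
#'
#' @param a,b `signed_gene_order` objects over identical symbol sets.
#' @return non-negative integer.
#' @export
breakpoint_distance <- function(a, b) {
  if (!setequal(a$symbols, b$symbols))
    stop("symbol sets differ; only in a: ",
         paste(setdiff(a$symbols, b$symbols), collapse = ", "),
         "; only in b: ",
         paste(setdiff(b$symbols, a$symbols), collapse = ", "))
  length(setdiff(adjacency_tokens(a), adjacency_tokens(b)))
}

# ---------------------------------------------------------------------------
# Event classification

## Backbone = largest set of genes with equal orientation in both orders
## whose cyclic sequence is common to both (longest common cyclic signed
## subsequence).  Anchored search: each candidate gene is tried as the
## rotation anchor; ties resolve to the earliest anchor in the reference
## order with the standard leftmost LIS, so results are deterministic.
order_backbone <- function(ref, obs) {
  n <- length(ref$symbols)
  ref_tok <- ref$symbols
  obs_pos <- match(ref$symbols, obs$symbols)
  sign_ok <- ref$orientation ==
    obs$orientation[obs_pos]
  cand <- which(sign_ok)
  if (!length(cand)) return(character(0))
  best <- character(0)
  for (a in cand) {
    # rotate ref so anchor is first; obs positions re-based at anchor
    ridx <- c(a:n, seq_len(a - 1L))
    ridx <- ridx[ridx %in% cand]
    p <- (obs_pos[ridx] - obs_pos[a]) %% length(obs$symbols)
    lis <- lis_indices(p)
    if (length(lis) > length(best)) best <- ref$symbols[ridx[lis]]
  }
  best
}

## Leftmost longest strictly increasing subsequence; returns indices.
lis_indices <- function(p) {
  n <- length(p)
  if (!n) return(integer(0))
  tails <- integer(0)      # indices of smallest tail per LIS length
  prev <- integer(n)
  for (i in seq_len(n)) {
    lo <- 1L; hi <- length(tails) + 1L
    while (lo < hi) {
      mid <- (lo + hi) %/% 2L
      if (p[tails[mid]] < p[i]) lo <- mid + 1L else hi <- mid
    }
    prev[i] <- if (lo > 1L) tails[lo - 1L] else 0L
    tails[lo] <- i
  }
  out <- integer(length(tails))
  k <- tails[length(tails)]
  for (j in rev(seq_along(tails))) { out[j] <- k; k <- prev[k] }
  out
}

## Circular neighbors (signed tokens) of each gene in an order.
neighbor_map <- function(order) {
  n <- length(order$symbols)
  tok <- paste0(ifelse(order$orientation == "-", "-", ""), order$symbols)
  left <- tok[((seq_len(n) - 2L) %% n) + 1L]
  right <- tok[(seq_len(n) %% n) + 1L]
  list(left = setNames(left, order$symbols),
       right = setNames(right, order$symbols))
}

## Nearest backbone gene on each side (plain symbols) of every gene.
backbone_flanks <- function(order, backbone) {
  n <- length(order$symbols)
  in_bb <- order$symbols %in% backbone
  left <- right <- rep(NA_character_, n)
  if (any(in_bb)) {
    for (i in seq_len(n)) {
      for (d in seq_len(n)) {
        j <- ((i - 1L - d) %% n) + 1L
        if (in_bb[j]) { left[i] <- order$symbols[j]; break }
      }
      for (d in seq_len(n)) {
        j <- ((i - 1L + d) %% n) + 1L
        if (in_bb[j]) { right[i] <- order$symbols[j]; break }
      }
    }
  }
  list(left = setNames(left, order$symbols),
       right = setNames(right, order$symbols))
}

#' Classify rearrangement events against a reference order
#'
#' Deterministic heuristic labelling, not a minimal-rearrangement
#' inference.  A backbone of genes common to both orders (same
#' orientation, same cyclic sequence; longest such set, leftmost on
#' ties) is labelled `in_place`.  Every other gene is compared to the
#' reference by orientation and by its nearest backbone flanks:
#' orientation flipped in an otherwise matched position is `inverted`;
#' displaced with matching orientation is `translocated`; displaced and
#' flipped is `remote_inversion`.  Two adjacent genes that exchanged
#' positions within a matched flanking context are labelled `swapped`;
#' mutual exchanges of adjacent genes are additionally reported in
#' `swapped_pairs` even when the pair also moved.
#'
#' @param ref,obs `signed_gene_order` objects over identical symbol sets.
#' @return list of class `event_report`: `per_gene` (named character),
#'   `conserved_blocks` (list of signed-token runs present in both
#'   orders), `breakpoints` (the breakpoint distance), `swapped_pairs`.
#' @export
classify_events <- function(ref, obs) {
  if (!setequal(ref$symbols, obs$symbols))
    stop("symbol sets differ; only in ref: ",
         paste(setdiff(ref$symbols, obs$symbols), collapse = ", "),
         "; only in obs: ",
         paste(setdiff(obs$symbols, ref$symbols), collapse = ", "))
  backbone <- order_backbone(ref, obs)
  labels <- setNames(rep("in_place", length(obs$symbols)), obs$symbols)

  ref_sign <- setNames(ref$orientation, ref$symbols)
  obs_sign <- setNames(obs$orientation, obs$symbols)
  fl_ref <- backbone_flanks(ref, backbone)
  fl_obs <- backbone_flanks(obs, backbone)
  moved <- setdiff(obs$symbols, backbone)
  for (g in moved) {
    pos_ok <- identical(fl_ref$left[[g]], fl_obs$left[[g]]) &&
      identical(fl_ref$right[[g]], fl_obs$right[[g]])
    sign_ok <- identical(ref_sign[[g]], obs_sign[[g]])
    labels[g] <- if (pos_ok && !sign_ok) "inverted"
    else if (!pos_ok && sign_ok) "translocated"
    else if (!pos_ok && !sign_ok) "remote_inversion"
    else "in_place"  # LIS left it out on a tie; position and sign agree
  }

  # mutual exchanges of adjacent genes (obs has X,Y where ref has Y,X)
  nb_ref <- neighbor_map(ref)
  nb_obs <- neighbor_map(obs)
  tok <- function(g, sgn) paste0(ifelse(sgn[[g]] == "-", "-", ""), g)
  swapped_pairs <- list()
  n <- length(obs$symbols)
  for (i in seq_len(n)) {
    x <- obs$symbols[i]
    y <- obs$symbols[(i %% n) + 1L]
    # ref must have y immediately before x, with each gene's sign kept
    if (identical(nb_ref$right[[y]], tok(x, ref_sign)) &&
        identical(obs_sign[[x]], ref_sign[[x]]) &&
        identical(obs_sign[[y]], ref_sign[[y]]) &&
        !identical(x, y) &&
        !(labels[[x]] == "in_place" && labels[[y]] == "in_place")) {
      swapped_pairs[[length(swapped_pairs) + 1L]] <- c(x, y)
      context_ok <- identical(nb_obs$left[[x]], nb_ref$left[[y]]) &&
        identical(nb_obs$right[[y]], nb_ref$right[[x]])
      if (context_ok) labels[c(x, y)] <- "swapped"
    }
  }

  structure(
    list(per_gene = labels,
         conserved_blocks = conserved_blocks(ref, obs),
         breakpoints = breakpoint_distance(ref, obs),
         swapped_pairs = swapped_pairs),
    class = "event_report")
}

#' Maximal conserved runs between two gene orders
#'
#' Splits the observed circular order at every adjacency whose successor
#' relation differs from the reference.  By default conservation is
#' orientation-aware (a strand flip breaks a block); with
#' `ignore_orientation = TRUE` only the order of gene symbols counts,
#' which is how gene-order conservation across species is usually
#' described.
#'
#' @param ref,obs `signed_gene_order` objects over identical symbol sets.
#' @param ignore_orientation disregard strand when judging conservation.
#' @return list of character vectors of signed tokens (observed
#'   orientation), each a maximal conserved run.
#' @export
conserved_blocks <- function(ref, obs, ignore_orientation = FALSE) {
  n <- length(obs$symbols)
  tok_obs <- paste0(ifelse(obs$orientation == "-", "-", ""), obs$symbols)
  nb_ref <- neighbor_map(ref)
  ref_sign <- setNames(ref$orientation, ref$symbols)
  same_sign <- ignore_orientation | obs$orientation ==
    ref_sign[obs$symbols]
  conserved <- logical(n)  # adjacency i -> i+1 conserved?
  for (i in seq_len(n)) {
    x <- obs$symbols[i]
    y <- obs$symbols[(i %% n) + 1L]
    succ <- nb_ref$right[[x]]
    if (ignore_orientation) succ <- sub("^-", "", succ)
    conserved[i] <- same_sign[i] && same_sign[(i %% n) + 1L] &&
      identical(succ, if (ignore_orientation) y else
        paste0(ifelse(ref_sign[[y]] == "-", "-", ""), y))
  }
  if (all(conserved)) return(list(tok_obs))
  # split the circle at broken adjacencies; start after a break
  start <- (which(!conserved)[1L] %% n) + 1L
  idx <- ((seq_len(n) + start - 2L) %% n) + 1L
  blocks <- list()
  cur <- integer(0)
  for (i in idx) {
    cur <- c(cur, i)
    if (!conserved[i]) { blocks[[length(blocks) + 1L]] <- tok_obs[cur]; cur <- integer(0) }
  }
  if (length(cur)) blocks[[length(blocks) + 1L]] <- tok_obs[cur]
  blocks
}

#' @export
print.event_report <- function(x, ...) {
  cat("Rearrangement report:", x$breakpoints, "breakpoints\n")
  ev <- x$per_gene[x$per_gene != "in_place"]
  if (!length(ev)) {
    cat("  all genes in place\n")
  } else {
    for (g in names(ev)) cat(sprintf("  %-6s %s\n", g, ev[[g]]))
  }
  if (length(x$swapped_pairs))
    cat("  mutual exchanges:",
        paste(vapply(x$swapped_pairs, paste, "", collapse = "<->"),
              collapse = ", "), "\n")
  invisible(x)
}

#' Render two gene orders as an aligned text gene map
#'
#' @param ref,obs `signed_gene_order` objects.
#' @param labels names for the two rows.
#' @return character vector of lines (also printed invisibly-friendly).
#' @export
render_gene_map <- function(ref, obs, labels = c("reference", "observed")) {
  fmt <- function(o) paste(format_signed(o), collapse = " ")
  out <- c(sprintf("%-12s %s", labels[1L], fmt(ref)),
           sprintf("%-12s %s", labels[2L], fmt(obs)))
  out
}
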