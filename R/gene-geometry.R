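## Adjacency geometry of the circular gene ledger: intergenic gaps
## (positive IGN), abutting pairs (0) and overlaps (negative IGN).

#' Adjacency ledger of a genome
#'
#' One record per consecutive feature pair in positional order, plus one
#' wrap record (last feature back to the first across the origin) when
#' the genome is circular.  For non-wrap pairs
#' `gap = downstream.start - upstream.stop - 1`; for the wrap pair
#' `gap = (genome length - last.stop) + (first.start - 1)`.
#'
#' @param genome an [annotated_genome()].
#' @param declared use the declared IGN column of the ledger instead of
#'   recomputing gaps from coordinates (the declared IGN of a feature is
#'   the gap *preceding* it; the first feature's declared IGN is the wrap
#'   gap).  Default `FALSE` (recompute).
#' @return data.frame with columns `upstream`, `downstream`, `gap`,
#'   `wrap`.
#' @export
adjacency_ledger <- function(genome, declared = FALSE) {
  f <- genome$features
  empty <- data.frame(upstream = character(0), downstream = character(0),
                      gap = integer(0), wrap = logical(0),
                      stringsAsFactors = FALSE)
  if (nrow(f) == 0L) return(empty)
  o <- order(f$start, f$stop)
  f <- f[o, , drop = FALSE]
  n <- nrow(f)
  up <- f$name
  down <- c(f$name[-1L], f$name[1L])
  gap <- c(f$start[-1L] - f$stop[-n] - 1L,
           (genome$length - f$stop[n]) + (f$start[1L] - 1L))
  wrap <- c(rep(FALSE, n - 1L), TRUE)
  if (!genome$circular) {
    up <- up[-n]; down <- down[-n]; gap <- gap[-n]; wrap <- wrap[-n]
  }
  if (declared) {
    ign <- f$declared_ign[match(down, f$name)]
    if (anyNA(ign))
      stop("declared = TRUE but IGN missing for: ",
           paste(down[is.na(ign)], collapse = ", "))
    gap <- ign
  }
  out <- data.frame(upstream = up, downstream = down, gap = as.integer(gap),
                    wrap = wrap, stringsAsFactors = FALSE)
  # flag suspicious annotations: overlap longer than half of either feature
  len <- setNames(f$stop - f$start + 1L, f$name)
  bad <- out$gap < 0 & (-out$gap > pmin(len[out$upstream], len[out$downstream]) / 2)
  if (any(bad, na.rm = TRUE))
    warning("overlap exceeds 50% of a feature (annotation suspect): ",
            paste(sprintf("%s/%s", out$upstream[bad], out$downstream[bad]),
                  collapse = ", "))
  out
}

#' Summary statistics of an adjacency ledger
#'
#' Counts and totals over the three gap classes.  A "location" is one
#' adjacent pair with a nonzero gap of the given sign.
#'
#' @param records data.frame from [adjacency_ledger()].
#' @param include_wrap include the wrap record(s) (default `TRUE`).
#' @return list of class `geometry_summary`: `n_pairs`, `n_abutting`,
#'   `n_intergenic`, `total_intergenic`, `intergenic_range`, `n_overlap`,
#'   `total_overlap`, `overlap_range`.
#' @export
geometry_summary <- function(records, include_wrap = TRUE) {
  if (!include_wrap) records <- records[!records$wrap, , drop = FALSE]
  g <- records$gap
  pos <- g[g > 0L]; neg <- g[g < 0L]
  structure(
    list(n_pairs = length(g),
         n_abutting = sum(g == 0L),
         n_intergenic = length(pos),
         total_intergenic = as.integer(sum(pos)),
         intergenic_range = if (length(pos)) range(pos) else c(NA_integer_, NA_integer_),
         n_overlap = length(neg),
         total_overlap = as.integer(sum(-neg)),
         overlap_range = if (length(neg)) range(-neg) else c(NA_integer_, NA_integer_)),
    class = "geometry_summary")
}

#' @export
print.geometry_summary <- function(x, ...) {
  cat("Gene-ledger geometry over", x$n_pairs, "adjacent pairs\n")
  cat(sprintf("  abutting:   %d pairs\n", x$n_abutting))
  cat(sprintf("  intergenic: %d bp over %d locations (range %s-%s bp)\n",
              x$total_intergenic, x$n_intergenic,
              x$intergenic_range[1L], x$intergenic_range[2L]))
  cat(sprintf("  overlap:    %d bp over %d locations (range %s-%s bp)\n",
              x$total_overlap, x$n_overlap,
              x$overlap_range[1L], x$overlap_range[2L]))
  invisible(x)
}
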