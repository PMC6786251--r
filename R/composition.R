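## Base composition and strand-skew statistics.
##
## AT-skew = (A - T)/(A + T) and GC-skew = (G - C)/(G + C), computed for
## the strand that encodes the majority of the PCGs (the J strand), or on
## coding-sense sequence for per-gene rows.  Ambiguity codes are excluded
## from both numerator and denominator of percentages, so the printed
## percentage arithmetic is exactly reproducible.

IUPAC_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-", ".")

#' Count bases in a DNA sequence
#'
#' @param seq DNA string (case-insensitive; `U` counted as `T`).
#' @return named integer vector `a`, `c`, `g`, `t`, `other` (`other` =
#'   non-ACGT IUPAC symbols).
#' @export
count_bases <- function(seq) {
  if (!is_string(seq) || nchar(seq) == 0L) stop("sequence must be non-empty")
  ch <- chars(toupper(seq))
  bad <- which(!ch %in% IUPAC_CHARS)
  if (length(bad))
    stop("non-IUPAC character '", ch[bad[1L]], "' at position ", bad[1L])
  ch[ch == "U"] <- "T"
  n <- tabulate(factor(ch, levels = c("A", "C", "G", "T")), nbins = 4L)
  c(a = n[1L], c = n[2L], g = n[3L], t = n[4L],
    other = length(ch) - sum(n))
}

#' AT and GC skew from base quantities
#'
#' Accepts counts, fractions or percentages on a common scale.
#'
#' @param a,t,g,c non-negative base quantities.
#' @return named numeric vector `at_skew = (a - t)/(a + t)`,
#'   `gc_skew = (g - c)/(g + c)`; `NA` where a denominator is zero.
#' @export
skew_pair <- function(a, t, g, c) {
  v <- c(a = a, t = t, g = g, c = c)
  if (any(!is.finite(v)) || any(v < 0)) stop("base quantities must be non-negative")
  c(at_skew = if (a + t > 0) (a - t) / (a + t) else NA_real_,
    gc_skew = if (g + c > 0) (g - c) / (g + c) else NA_real_)
}

#' Slice a set of coding sequences by codon position
#'
#' @param cds_set character vector/list of coding-sense DNA strings, each
#'   trimmed to complete codons.
#' @return list of three strings (`pos1`, `pos2`, `pos3`), each of length
#'   = total number of codons.
#' @export
codon_position_slices <- function(cds_set) {
  cds_set <- as.character(unlist(cds_set))
  if (any(nchar(cds_set) %% 3L != 0L))
    stop("CDS length not divisible by 3; trim incomplete terminal codon first")
  s <- paste(cds_set, collapse = "")
  if (!nchar(s)) return(list(pos1 = "", pos2 = "", pos3 = ""))
  ch <- chars(s)
  list(pos1 = paste(ch[seq(1L, length(ch), 3L)], collapse = ""),
       pos2 = paste(ch[seq(2L, length(ch), 3L)], collapse = ""),
       pos3 = paste(ch[seq(3L, length(ch), 3L)], collapse = ""))
}

## One composition row from a sequence (full precision; rendering rounds).
composition_row <- function(region, seq) {
  n <- count_bases(seq)
  tot <- sum(n[c("a", "c", "g", "t")])
  pct <- if (tot > 0) 100 * n[c("a", "c", "g", "t")] / tot else rep(NA_real_, 4)
  sk <- skew_pair(n[["a"]], n[["t"]], n[["g"]], n[["c"]])
  data.frame(region = region, length = nchar(seq),
             pct_a = pct[[1L]], pct_c = pct[[2L]], pct_g = pct[[3L]],
             pct_t = pct[[4L]], pct_at = pct[[1L]] + pct[[4L]],
             at_skew = sk[["at_skew"]], gc_skew = sk[["gc_skew"]],
             stringsAsFactors = FALSE)
}

#' Coding-sense PCG sequences of a genome
#'
#' Extracts every protein-coding gene in coding sense (minority-strand
#' genes reverse-complemented) and trims each to complete codons, i.e.
#' drops the 1-2 nt of a truncated terminal stop.
#'
#' @param genome an [annotated_genome()] with sequence.
#' @param strand restrict to one strand class (`"J"`/`"N"`) or take all
#'   PCGs (`"both"`, default).
#' @return named list of DNA strings.
#' @export
pcg_coding_sequences <- function(genome, strand = c("both", "J", "N")) {
  strand <- match.arg(strand)
  f <- genome$features
  keep <- f$category == "PCG"
  if (strand != "both") keep <- keep & f$strand == strand
  nm <- f$name[keep]
  out <- vapply(nm, function(g) {
    s <- feature_sequence(genome, g, coding_sense = TRUE)
    substring(s, 1L, 3L * (nchar(s) %/% 3L))
  }, character(1L))
  setNames(as.list(out), nm)
}

#' Composition report for an annotated genome
#'
#' Rows for the whole genome; the full, J-strand and N-strand PCG sets
#' (coding sense) each with their three codon-position slices; every
#' individual PCG; and the two rRNAs.  Values are kept at full precision;
#' [render_composition()] applies the table rounding (percentages to one
#' decimal, skews to four).
#'
#' @param genome an [annotated_genome()] with sequence.
#' @return data.frame of composition rows.
#' @export
composition_report <- function(genome) {
  if (is.null(genome$sequence))
    stop("genome carries no sequence; supply one (e.g. via FASTA)")
  rows <- list(composition_row("whole_genome", genome$sequence))
  for (set in c("both", "J", "N")) {
    cds <- pcg_coding_sequences(genome, set)
    if (!length(cds)) next
    lab <- switch(set, both = "PCG_all", J = "PCG_J", N = "PCG_N")
    rows[[length(rows) + 1L]] <- composition_row(lab, paste(unlist(cds), collapse = ""))
    sl <- codon_position_slices(cds)
    for (p in 1:3)
      rows[[length(rows) + 1L]] <-
        composition_row(sprintf("%s_pos%d", lab, p), sl[[p]])
  }
  f <- genome$features
  for (g in f$name[f$category == "PCG"])
    rows[[length(rows) + 1L]] <-
      composition_row(g, feature_sequence(genome, g, coding_sense = TRUE))
  for (g in intersect(c("rrnS", "rrnL"), f$name))
    rows[[length(rows) + 1L]] <-
      composition_row(g, feature_sequence(genome, g, coding_sense = TRUE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render a composition report with table rounding
#'
#' @param report data.frame from [composition_report()].
#' @return data.frame with percentages rounded (half-up) to 1 decimal and
#'   skews to 4 decimals.
#' @export
render_composition <- function(report) {
  for (col in c("pct_a", "pct_c", "pct_g", "pct_t", "pct_at"))
    report[[col]] <- round_half_up(report[[col]], 1L)
  for (col in c("at_skew", "gc_skew"))
    report[[col]] <- round_half_up(report[[col]], 4L)
  report
}
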