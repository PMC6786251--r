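## Codon tallies, relative synonymous codon usage (RSCU), the GC-rich /
## AT-rich codon-class ratio, and the start/stop codon survey, all under
## the invertebrate mitochondrial genetic code (NCBI table 5).
##
## Conventions forced by the published accounting: terminal stop codons
## (complete TAA/TAG or truncated T/TA) are excluded from usage counts;
## start codons are included.

ALL_CODONS <- as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                                    paste0), c("T", "C", "A", "G"), paste0))

#' Tally codons of a coding-sequence set
#'
#' Codons are read in frame from position 1 of each coding-sense CDS.  A
#' trailing incomplete codon (truncated stop) is dropped; a final complete
#' stop codon is excluded from the tally.  Internal stop codons raise a
#' warning naming the sequence and codon position.
#'
#' @param cds_set character vector/list of coding-sense DNA strings
#'   (each beginning at its annotated start codon).
#' @param code a [genetic_code()].
#' @return object of class `codon_usage_table`: data.frame with columns
#'   `aa` (family symbol), `codon`, `count` and `rscu` (`NA` until
#'   [rscu()] fills it).
#' @export
tally_codons <- function(cds_set, code = genetic_code()) {
  cds_set <- toupper(as.character(unlist(cds_set)))
  counts <- setNames(integer(length(ALL_CODONS)), ALL_CODONS)
  nm <- names(cds_set) %||% paste0("cds", seq_along(cds_set))
  for (k in seq_along(cds_set)) {
    s <- cds_set[[k]]
    if (nchar(s) < 6L)
      stop("CDS ", nm[k], " shorter than 6 nt")
    s <- substring(s, 1L, 3L * (nchar(s) %/% 3L))  # drop truncated stop
    cod <- codons_of(s)
    if (cod[length(cod)] %in% code$stop_codons)    # drop complete stop
      cod <- cod[-length(cod)]
    internal <- which(cod %in% code$stop_codons)
    if (length(internal))
      warning("internal stop codon in ", nm[k], " at codon position(s) ",
              paste(internal, collapse = ", "))
    tab <- table(factor(cod, levels = ALL_CODONS))
    counts <- counts + as.integer(tab)
  }
  codon_usage_table(counts, code)
}

#' Build a codon usage table from per-codon counts
#'
#' @param counts named integer vector (codon -> count); missing codons
#'   count 0.
#' @param code a [genetic_code()].
#' @return `codon_usage_table` (counts only; RSCU `NA`).
#' @export
codon_usage_table <- function(counts, code = genetic_code()) {
  full <- setNames(integer(length(ALL_CODONS)), ALL_CODONS)
  counts <- counts[!is.na(names(counts))]
  if (any(!names(counts) %in% ALL_CODONS))
    stop("unknown codon(s): ",
         paste(setdiff(names(counts), ALL_CODONS), collapse = ", "))
  full[names(counts)] <- as.integer(counts)
  aa <- code$codon_to_aa[ALL_CODONS]
  out <- data.frame(aa = unname(aa), codon = ALL_CODONS,
                    count = unname(full), rscu = NA_real_,
                    stringsAsFactors = FALSE)
  structure(out, class = c("codon_usage_table", "data.frame"), code = code)
}

#' Relative synonymous codon usage
#'
#' For codon *i* in a synonymous family of size *k* with family total
#' *n > 0*: `rscu_i = count_i * k / n` (the codon count divided by the
#' family mean).  Families with zero total get `NA`; stop codons are not
#' a family.
#'
#' @param table a `codon_usage_table`.
#' @param code a [genetic_code()]; defaults to the table's own code.
#' @return the table with the `rscu` column filled (full precision;
#'   render with 2 decimals for display).
#' @export
rscu <- function(table, code = attr(table, "code") %||% genetic_code()) {
  for (fam in code$families) {
    idx <- match(fam, table$codon)
    tot <- sum(table$count[idx])
    table$rscu[idx] <- if (tot > 0)
      table$count[idx] * length(fam) / tot else NA_real_
  }
  table$rscu[table$aa == "*"] <- NA_real_
  table
}

#' @export
print.codon_usage_table <- function(x, ...) {
  cat("Codon usage table (", sum(x$count), " codons)\n", sep = "")
  y <- x
  y$aa <- ifelse(y$aa == "*", "End", AA3[y$aa])
  y$rscu <- ifelse(is.na(y$rscu), NA, round_half_up(y$rscu, 2L))
  print.data.frame(y[y$count > 0 | !is.na(y$rscu), ], row.names = FALSE)
  invisible(x)
}

## Amino-acid classes of the codon-class ratio (by family symbol).
GC_RICH_AAS <- c("P", "A", "R", "G")            # Pro, Ala, Arg, Gly
AT_RICH_AAS <- c("F", "I", "M", "Y", "N", "K")  # Phe, Ile, Met, Tyr, Asn, Lys

#' GC-rich to AT-rich codon-class ratio
#'
#' Total usage of the G+C-rich families (Pro, Ala, Arg, Gly) divided by
#' the total usage of the A+T-rich families (Phe, Ile, Met, Tyr, Asn,
#' Lys).  In strongly AT-biased mitogenomes this ratio is well below 1.
#'
#' @param table a `codon_usage_table`.
#' @return the ratio (full precision; display at 2 decimals).
#' @export
gc_at_rich_ratio <- function(table) {
  num <- sum(table$count[table$aa %in% GC_RICH_AAS])
  den <- sum(table$count[table$aa %in% AT_RICH_AAS])
  if (den == 0) stop("AT-rich codon-class total is zero")
  num / den
}

#' Start/stop codon survey of the protein-coding genes
#'
#' One row per PCG.  When the genome carries a sequence, codons are read
#' from it (start = first 3 nt in coding sense; stop = the trailing
#' complete or truncated stop implied by span mod 3) and any disagreement
#' with declared codons is reported in `note`; otherwise declared codons
#' are surveyed.
#'
#' @param genome an [annotated_genome()].
#' @param code a [genetic_code()].
#' @return data.frame with columns `gene`, `start_codon`, `stop_codon`,
#'   `complete_stop` (`FALSE` iff stop is truncated `T`/`TA`), `atn_start`,
#'   `note`.
#' @export
start_stop_survey <- function(genome, code = genetic_code()) {
  f <- genome$features
  pcg <- f[f$category == "PCG", , drop = FALSE]
  if (!nrow(pcg))
    return(data.frame(gene = character(0), start_codon = character(0),
                      stop_codon = character(0), complete_stop = logical(0),
                      atn_start = logical(0), note = character(0),
                      stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(pcg)), function(i) {
    g <- pcg$name[i]
    note <- ""
    if (!is.null(genome$sequence)) {
      s <- feature_sequence(genome, g, coding_sense = TRUE)
      start <- substring(s, 1L, 3L)
      rem <- nchar(s) %% 3L
      stop_c <- if (rem > 0L) {
        substring(s, nchar(s) - rem + 1L, nchar(s))
      } else {
        last <- substring(s, nchar(s) - 2L, nchar(s))
        if (last %in% code$stop_codons) last else ""
      }
      if (!is.na(pcg$start_codon[i]) && !identical(start, pcg$start_codon[i]))
        note <- sprintf("declared start %s disagrees with sequence %s",
                        pcg$start_codon[i], start)
      if (!is.na(pcg$stop_codon[i]) && !identical(stop_c, pcg$stop_codon[i]))
        note <- paste0(note, if (nzchar(note)) "; ",
                       sprintf("declared stop %s disagrees with sequence %s",
                               pcg$stop_codon[i], stop_c))
    } else {
      start <- pcg$start_codon[i]
      stop_c <- pcg$stop_codon[i]
    }
    data.frame(gene = g, start_codon = start, stop_codon = stop_c,
               complete_stop = !stop_c %in% c("T", "TA"),
               atn_start = grepl("^AT[ACGT]$", start), note = note,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
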