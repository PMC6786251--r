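#' @keywords internal
"_PACKAGE"

#' @importFrom stats runif setNames
#' @importFrom utils read.delim write.table head tail
NULL

#' Round half away from zero
#'
#' Table rendering uses half-up rounding at a fixed number of decimals
#' (base R's `round()` rounds half to even, which does not reproduce
#' printed table values).
#'
#' @param x numeric vector.
#' @param digits decimals to keep.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Reverse complement of a plain DNA character string (delegates to Biostrings).
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## Split a string into single characters.
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

## Codons of an in-frame sequence (length must be divisible by 3).
codons_of <- function(x) {
  n <- nchar(x)
  stopifnot(n %% 3L == 0L)
  if (n == 0L) return(character(0))
  substring(x, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

## Read a FASTA file and return the (single or named multi) sequence(s)
## as upper-case character strings.
read_fasta_seq <- function(path) {
  set <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

write_fasta_seq <- function(seqs, path, width = 70L) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    if (nchar(s) == 0L) next
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
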