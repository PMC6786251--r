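## Canonical gene vocabulary of the standard 37-gene insect mitogenome,
## plus the non-coding control (AT-rich) region.

PCG_NAMES <- c("ND2", "COI", "COII", "ATP8", "ATP6", "COIII", "ND3",
               "ND5", "ND4", "ND4L", "ND6", "CYTB", "ND1")

TRNA_NAMES <- c("trnI", "trnQ", "trnM", "trnW", "trnC", "trnY", "trnL2",
                "trnK", "trnD", "trnG", "trnA", "trnR", "trnN", "trnS1",
                "trnE", "trnF", "trnH", "trnT", "trnP", "trnS2", "trnL1",
                "trnV")

RRNA_NAMES <- c("rrnL", "rrnS")

CONTROL_REGION <- "control_region"

ALL_GENE_NAMES <- c(PCG_NAMES, TRNA_NAMES, RRNA_NAMES, CONTROL_REGION)

#' Category implied by a canonical gene symbol
#'
#' @param name character vector of canonical symbols.
#' @return character vector in `PCG`, `tRNA`, `rRNA`, `control_region`.
#' @export
gene_category <- function(name) {
  out <- rep(NA_character_, length(name))
  out[name %in% PCG_NAMES] <- "PCG"
  out[name %in% TRNA_NAMES] <- "tRNA"
  out[name %in% RRNA_NAMES] <- "rRNA"
  out[name %in% CONTROL_REGION] <- "control_region"
  if (anyNA(out))
    stop("unknown gene symbol(s): ",
         paste(unique(name[is.na(out)]), collapse = ", "))
  out
}

## Standard anticodons (RNA alphabet) of the 22 insect mitochondrial tRNAs.
## trnS1 (AGN) reads with anticodon UCU and trnS2 (UCN) with UGA.
STANDARD_ANTICODONS <- c(
  trnI = "GAU", trnQ = "UUG", trnM = "CAU", trnW = "UCA", trnC = "GCA",
  trnY = "GUA", trnL2 = "UAA", trnK = "CUU", trnD = "GUC", trnG = "UCC",
  trnA = "UGC", trnR = "UCG", trnN = "GUU", trnS1 = "UCU", trnE = "UUC",
  trnF = "GAA", trnH = "GUG", trnT = "UGU", trnP = "UGG", trnS2 = "UGA",
  trnL1 = "UAG", trnV = "UAC")

#' Gene-name synonym table
#'
#' Maps annotation dialects (e.g. `COX1`, `CO1`, `16S`, `l-rRNA`,
#' `D-loop`) onto the canonical symbols used throughout the package.  The
#' packaged table ships as editable YAML so further dialects can be added.
#'
#' @param path YAML file mapping canonical symbol -> list of synonyms;
#'   defaults to the packaged table.
#' @return named character vector: `names()` are upper-cased synonyms,
#'   values are canonical symbols.  Canonical names map to themselves.
#' @export
gene_synonyms <- function(path = system.file("extdata", "gene_synonyms.yaml",
                                             package = "mitoprofile")) {
  raw <- yaml::read_yaml(path)
  syn <- character(0)
  for (canon in names(raw)) {
    alts <- toupper(unlist(raw[[canon]]))
    syn[alts] <- canon
  }
  syn[toupper(ALL_GENE_NAMES)] <- ALL_GENE_NAMES
  syn
}

## Resolve an arbitrary annotation label to a canonical symbol (or NA).
resolve_gene_name <- function(label, synonyms = gene_synonyms()) {
  unname(synonyms[toupper(trimws(label))])
}

#' Invertebrate mitochondrial genetic code
#'
#' The genetic code used for all codon work: NCBI translation table 5
#' (AGA/AGG = Ser, ATA = Met, TGA = Trp; stops TAA/TAG), with the ATN
#' start-codon pattern of insect mitochondrial PCGs.
#'
#' @param table_id NCBI translation table identifier (default 5).
#' @return object of class `genetic_code` with elements `table_id`,
#'   `codon_to_aa` (named character, 64 codons, stops as `*`),
#'   `stop_codons`, `start_pattern`, and `families` (list of sense codons
#'   per amino-acid family).
#' @export
genetic_code <- function(table_id = 5L) {
  map <- Biostrings::getGeneticCode(as.character(table_id))
  map <- setNames(as.character(map), names(map))
  stops <- names(map)[map == "*"]
  sense <- map[map != "*"]
  families <- split(names(sense), sense)
  structure(
    list(table_id = as.integer(table_id),
         codon_to_aa = map,
         stop_codons = stops,
         start_pattern = "ATN",
         families = families),
    class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code, NCBI table", x$table_id, "\n")
  cat("  stop codons:", paste(x$stop_codons, collapse = ", "), "\n")
  cat("  start pattern:", x$start_pattern, "\n")
  cat("  synonymous families:", length(x$families), "\n")
  invisible(x)
}

## Three-letter amino-acid labels used in rendered codon tables.
AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val")
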