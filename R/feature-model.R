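## Domain containers and I/O for annotated circular mitogenomes.
##
## Coordinates are 1-based inclusive on the J (majority) strand, GenBank
## style.  No feature may wrap the origin; wrap-spanning annotations are
## rejected rather than silently split.

FEATURE_COLS <- c("name", "strand", "start", "stop", "declared_length",
                  "start_codon", "stop_codon", "anticodon", "declared_ign",
                  "category")

#' Construct a single gene feature
#'
#' @param name canonical gene symbol (see [gene_category()]).
#' @param strand `"J"` (majority) or `"N"` (minority).
#' @param start,stop 1-based inclusive coordinates on the J strand.
#' @param declared_length declared length in bp, or `NA` (recorded as
#'   declared metadata; geometry is always recomputed from coordinates).
#' @param start_codon,stop_codon declared codons (PCGs only) or `NA`.
#' @param anticodon declared anticodon, RNA alphabet (tRNAs only) or `NA`.
#' @param declared_ign declared intergenic-nucleotide count preceding this
#'   feature, or `NA`.
#' @return one-row data.frame of class `gene_feature`.
#' @export
gene_feature <- function(name, strand, start, stop, declared_length = NA,
                         start_codon = NA, stop_codon = NA, anticodon = NA,
                         declared_ign = NA) {
  category <- gene_category(name)
  start <- as.integer(start); stop <- as.integer(stop)
  if (is.na(start) || is.na(stop) || start < 1L || start > stop)
    stop("feature ", name, ": need 1 <= start <= stop")
  if (!strand %in% c("J", "N"))
    stop("feature ", name, ": strand must be J or N, got ", strand)
  has_codon <- !is.na(start_codon) || !is.na(stop_codon)
  if (category != "PCG" && has_codon)
    stop("feature ", name, " (", category, ") must not carry start/stop codons")
  structure(
    data.frame(name = name, strand = strand, start = start, stop = stop,
               declared_length = as.integer(declared_length),
               start_codon = as.character(start_codon),
               stop_codon = as.character(stop_codon),
               anticodon = as.character(anticodon),
               declared_ign = as.integer(declared_ign),
               category = category,
               stringsAsFactors = FALSE),
    class = c("gene_feature", "data.frame"))
}

#' Construct an annotated genome
#'
#' @param features data.frame of feature rows (as built by [gene_feature()]
#'   or a compatible data.frame); re-sorted by start position.
#' @param length genome length in bp.
#' @param circular logical; circular molecule (default `TRUE`).
#' @param organism,accession free-text metadata.
#' @param sequence IUPAC DNA string on the J strand, or `NULL`.
#' @return object of class `annotated_genome`.
#' @export
annotated_genome <- function(features, length, circular = TRUE,
                             organism = "", accession = NA_character_,
                             sequence = NULL) {
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stop("genome length must be a positive integer")
  if (is.null(features) || nrow(features) == 0L) {
    features <- data.frame(name = character(0), strand = character(0),
                           start = integer(0), stop = integer(0),
                           declared_length = integer(0),
                           start_codon = character(0), stop_codon = character(0),
                           anticodon = character(0), declared_ign = integer(0),
                           category = character(0), stringsAsFactors = FALSE)
  }
  features <- as.data.frame(features)[, FEATURE_COLS]
  if (anyDuplicated(features$name))
    stop("duplicate feature names: ",
         paste(unique(features$name[duplicated(features$name)]), collapse = ", "))
  if (nrow(features) && any(features$stop > length))
    stop("feature(s) extend beyond genome length ", length, ": ",
         paste(features$name[features$stop > length], collapse = ", "))
  features <- features[order(features$start, features$stop), , drop = FALSE]
  rownames(features) <- NULL
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    if (nchar(sequence) != length)
      stop("sequence length (", nchar(sequence),
           ") does not match declared genome length (", length, ")")
  }
  structure(
    list(organism = organism, accession = accession, length = length,
         circular = isTRUE(circular), features = features, sequence = sequence),
    class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat("Annotated", if (x$circular) "circular" else "linear", "mitogenome\n")
  if (nzchar(x$organism)) cat("  organism: ", x$organism, "\n", sep = "")
  if (!is.na(x$accession)) cat("  accession: ", x$accession, "\n", sep = "")
  cat("  length:   ", x$length, " bp", if (is.null(x$sequence))
    " (no sequence attached)" else " (sequence attached)", "\n", sep = "")
  tab <- table(factor(x$features$category,
                      c("PCG", "tRNA", "rRNA", "control_region")))
  cat("  features: ", nrow(x$features), " (",
      paste(paste0(tab, " ", names(tab)), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

## Extract the J-strand subsequence of a feature; coding sense when asked.
feature_sequence <- function(genome, name, coding_sense = TRUE) {
  if (is.null(genome$sequence))
    stop("genome carries no sequence; supply one (e.g. via FASTA)")
  i <- match(name, genome$features$name)
  if (is.na(i)) stop("no feature named ", name)
  s <- substring(genome$sequence, genome$features$start[i],
                 genome$features$stop[i])
  if (coding_sense && genome$features$strand[i] == "N") s <- revcomp(s)
  s
}

# ---------------------------------------------------------------------------
# Tab-delimited feature tables (published-ledger dialect)

#' Read a tab-delimited feature table
#'
#' Reads the ledger dialect with columns `Gene`, `Strand`, `Start`, `Stop`
#' and optionally `Length`, `StartCodon`, `StopCodon`, `Anticodon`, `IGN`.
#' Lines starting with `#` are comments; a comment of `key=value` pairs
#' (e.g. `# organism=X	length=15405	circular=true`) supplies genome
#' metadata.  The `IGN` column is retained as declared metadata and never
#' trusted over coordinates.
#'
#' @param path file path.
#' @param length genome length; overrides/completes the metadata line.
#' @param organism,accession,circular metadata overrides.
#' @return an [annotated_genome()] (without sequence).
#' @export
read_feature_table <- function(path, length = NULL, organism = NULL,
                               accession = NULL, circular = NULL) {
  lines <- readLines(path)
  meta_raw <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_raw) {
    hits <- regmatches(ln, gregexpr("[A-Za-z_]+=[^\t ]+", ln))[[1L]]
    for (h in hits) {
      kv <- strsplit(h, "=", fixed = TRUE)[[1L]]
      meta[[kv[1L]]] <- kv[2L]
    }
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(body)) stop("feature table has no header row: ", path)
  tab <- read.delim(text = paste(body, collapse = "\n"),
                    stringsAsFactors = FALSE, colClasses = "character")
  names(tab) <- tolower(names(tab))
  need <- c("gene", "strand", "start", "stop")
  if (!all(need %in% names(tab)))
    stop("feature table must name columns gene, strand, start, stop")

  length <- as.integer(length %||% meta$length %||% NA)
  if (is.na(length)) {
    if (nrow(tab) == 0L)
      stop("genome length must be supplied (metadata line or argument)")
    length <- max(as.integer(tab$stop))
  }
  circular <- circular %||% !identical(tolower(meta$circular %||% "true"), "false")
  organism <- organism %||% gsub("_", " ", meta$organism %||% "")
  accession <- accession %||% (meta$accession %||% NA_character_)

  grab <- function(col) if (col %in% names(tab)) tab[[col]] else rep(NA, nrow(tab))
  blank_na <- function(x) ifelse(is.na(x) | !nzchar(trimws(x)), NA, trimws(x))
  int_col <- function(x, what) {
    x <- blank_na(x)
    out <- suppressWarnings(as.integer(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad))
      stop("non-integer ", what, " in row(s) ", paste(bad, collapse = ", "),
           " (", paste(tab$gene[bad], collapse = ", "), ")")
    out
  }

  rows <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    nm <- trimws(tab$gene[i])
    if (!nm %in% ALL_GENE_NAMES)
      stop("row ", i, ": unknown gene symbol '", nm, "'")
    strand <- trimws(tab$strand[i])
    if (!strand %in% c("J", "N"))
      stop("row ", i, " (", nm, "): strand must be J or N, got '", strand, "'")
    rows[[i]] <- gene_feature(
      name = nm, strand = strand,
      start = int_col(tab$start, "start")[i],
      stop = int_col(tab$stop, "stop")[i],
      declared_length = int_col(grab("length"), "length")[i],
      start_codon = blank_na(grab("startcodon"))[i],
      stop_codon = blank_na(grab("stopcodon"))[i],
      anticodon = blank_na(grab("anticodon"))[i],
      declared_ign = int_col(grab("ign"), "IGN")[i])
  }
  feats <- if (length(rows)) do.call(rbind, rows) else NULL
  annotated_genome(feats, length = length, circular = circular,
                   organism = organism, accession = accession)
}

#' Write a feature table
#'
#' Emits the same tab-delimited dialect read by [read_feature_table()],
#' in ledger column order.  The `IGN` column is recomputed from the
#' coordinates via [adjacency_ledger()], never copied from declared values.
#'
#' @param genome an [annotated_genome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(genome, path) {
  f <- genome$features
  ign <- rep(NA_integer_, nrow(f))
  if (nrow(f) >= 1L) {
    led <- adjacency_ledger(genome)
    # gap preceding each feature = record whose downstream is that feature
    ign[match(led$downstream, f$name)] <- led$gap
    if (!genome$circular && nrow(f)) ign[1L] <- NA_integer_
  }
  out <- data.frame(Gene = f$name, Strand = f$strand, Start = f$start,
                    Stop = f$stop, Length = f$stop - f$start + 1L,
                    StartCodon = ifelse(is.na(f$start_codon), "", f$start_codon),
                    StopCodon = ifelse(is.na(f$stop_codon), "", f$stop_codon),
                    Anticodon = ifelse(is.na(f$anticodon), "", f$anticodon),
                    IGN = ign, stringsAsFactors = FALSE)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# organism=%s\taccession=%s\tlength=%d\tcircular=%s",
                     gsub(" ", "_", genome$organism),
                     ifelse(is.na(genome$accession), "", genome$accession),
                     genome$length,
                     tolower(as.character(genome$circular))), con)
  suppressWarnings(write.table(out, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

# ---------------------------------------------------------------------------
# Validation

VALIDATION_RULES <- c(
  r1 = "declared length equals stop - start + 1",
  r2 = "PCG span mod 3 consistent with complete or truncated stop",
  r3 = "start codon matches ATN",
  r4 = "stop codon in {TAA, TAG, TA, T}",
  r5 = "anticodon agrees with the standard anticodon table",
  r6 = "features do not overlap")

#' Validate an annotation against the standard ledger rules
#'
#' Applies, per feature: (r1) declared length vs. coordinate span; (r2) PCG
#' span mod 3 must be 0, or 1 with a truncated `T` stop, or 2 with `TA`;
#' (r3) start codon matches `ATN`; (r4) stop codon in `TAA`/`TAG`/`TA`/`T`;
#' (r5) tRNA anticodon agrees with the packaged standard table (mismatch is
#' a warning); (r6) overlapping features are reported as warnings, never
#' errors.  All findings land in the report; nothing is thrown.
#'
#' @param genome an [annotated_genome()].
#' @return data.frame of class `validation_report` with columns `feature`,
#'   `rule`, `severity`, `message` (zero rows iff all rules pass).
#' @export
validate_annotation <- function(genome) {
  f <- genome$features
  findings <- list()
  add <- function(feature, rule, severity, message) {
    findings[[length(findings) + 1L]] <<- data.frame(
      feature = feature, rule = rule, severity = severity, message = message,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(f))) {
    span <- f$stop[i] - f$start[i] + 1L
    if (!is.na(f$declared_length[i]) && f$declared_length[i] != span)
      add(f$name[i], "r1", "error",
          sprintf("declared length %d but coordinate span %d",
                  f$declared_length[i], span))
    if (f$category[i] == "PCG") {
      rem <- span %% 3L
      sc <- f$stop_codon[i]
      ok <- (rem == 0L) || (rem == 1L && identical(sc, "T")) ||
        (rem == 2L && identical(sc, "TA"))
      if (!ok)
        add(f$name[i], "r2", "error",
            sprintf("span %d = %d mod 3 inconsistent with stop codon '%s'",
                    span, rem, ifelse(is.na(sc), "", sc)))
      if (!is.na(f$start_codon[i]) &&
          !grepl("^AT[ACGT]$", f$start_codon[i]))
        add(f$name[i], "r3", "error",
            sprintf("start codon '%s' does not match ATN", f$start_codon[i]))
      if (!is.na(sc) && !sc %in% c("TAA", "TAG", "TA", "T"))
        add(f$name[i], "r4", "error",
            sprintf("stop codon '%s' not in {TAA, TAG, TA, T}", sc))
    }
    if (f$category[i] == "tRNA" && !is.na(f$anticodon[i])) {
      std <- STANDARD_ANTICODONS[[f$name[i]]]
      if (!identical(toupper(f$anticodon[i]), std))
        add(f$name[i], "r5", "warning",
            sprintf("anticodon '%s' differs from standard '%s'",
                    f$anticodon[i], std))
    }
  }
  if (nrow(f) > 1L) {
    o <- order(f$start, f$stop)
    for (k in seq_len(nrow(f) - 1L)) {
      i <- o[k]; j <- o[k + 1L]
      if (f$start[j] <= f$stop[i])
        add(f$name[j], "r6", "warning",
            sprintf("overlaps upstream feature %s by %d bp",
                    f$name[i], f$stop[i] - f$start[j] + 1L))
    }
  }
  rep <- if (length(findings)) do.call(rbind, findings) else
    data.frame(feature = character(0), rule = character(0),
               severity = character(0), message = character(0),
               stringsAsFactors = FALSE)
  class(rep) <- c("validation_report", "data.frame")
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  if (!nrow(x)) {
    cat("Annotation validation: all rules pass\n")
  } else {
    cat("Annotation validation:", sum(x$severity == "error"), "error(s),",
        sum(x$severity == "warning"), "warning(s)\n")
    print.data.frame(x, row.names = FALSE)
  }
  invisible(x)
}
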