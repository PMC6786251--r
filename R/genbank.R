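## Minimal single-record GenBank flat-file I/O for circular mitogenomes.
## Only simple `start..stop` / `complement(start..stop)` locations are
## supported; join/order (wrap-spanning) locations are rejected, matching
## the package-wide rule that no feature wraps the origin.

GB_PRODUCTS <- c(
  ND1 = "NADH dehydrogenase subunit 1", ND2 = "NADH dehydrogenase subunit 2",
  ND3 = "NADH dehydrogenase subunit 3", ND4 = "NADH dehydrogenase subunit 4",
  ND4L = "NADH dehydrogenase subunit 4L", ND5 = "NADH dehydrogenase subunit 5",
  ND6 = "NADH dehydrogenase subunit 6",
  COI = "cytochrome c oxidase subunit 1",
  COII = "cytochrome c oxidase subunit 2",
  COIII = "cytochrome c oxidase subunit 3",
  ATP6 = "ATP synthase F0 subunit 6", ATP8 = "ATP synthase F0 subunit 8",
  CYTB = "cytochrome b",
  rrnS = "12S ribosomal RNA", rrnL = "16S ribosomal RNA")

#' Read a single-record GenBank flat file
#'
#' Parses a single circular DNA record with `CDS`/`tRNA`/`rRNA`/
#' `misc_feature`/`D-loop` features, maps their labels to canonical
#' symbols through the synonym table, attaches the ORIGIN sequence, and
#' assigns complement-strand features to strand `N`.
#'
#' @param path GenBank flat file (one record).
#' @param synonyms synonym table from [gene_synonyms()].
#' @return an [annotated_genome()] with sequence.
#' @export
read_genbank <- function(path, synonyms = gene_synonyms()) {
  lines <- readLines(path)
  loci <- grep("^LOCUS", lines)
  if (length(loci) != 1L)
    stop("expected exactly one LOCUS record, found ", length(loci))
  locus <- strsplit(trimws(lines[loci]), "\\s+")[[1L]]
  glen <- as.integer(locus[3L])
  circular <- any(tolower(locus) == "circular")
  acc <- NA_character_
  a <- grep("^ACCESSION", lines, value = TRUE)
  if (length(a)) acc <- strsplit(trimws(a[1L]), "\\s+")[[1L]][2L] %||% NA_character_
  org <- ""
  o <- grep("^\\s{2}ORGANISM", lines, value = TRUE)
  if (length(o)) org <- trimws(sub("^\\s*ORGANISM\\s*", "", o[1L]))

  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (!length(fstart)) stop("no FEATURES section in ", path)
  fend <- if (length(ostart)) ostart[1L] - 1L else length(lines)
  flines <- lines[(fstart[1L] + 1L):fend]
  flines <- flines[nzchar(trimws(flines))]

  # group feature entries: a new entry starts at indent 5 (non-blank col 6)
  is_head <- grepl("^\\s{1,10}\\S", flines) & !grepl("^\\s{11,}", flines)
  idx <- cumsum(is_head)
  feats <- list()
  for (g in unique(idx)) {
    block <- flines[idx == g]
    head <- strsplit(trimws(block[1L]), "\\s+")[[1L]]
    key <- head[1L]
    loc <- paste(head[-1L], collapse = "")
    quals <- block[-1L]
    # continuation lines of the location come before any qualifier
    qstart <- grep("^\\s*/", quals)
    if (length(qstart) && qstart[1L] > 1L) {
      loc <- paste0(loc, paste(trimws(quals[seq_len(qstart[1L] - 1L)]),
                               collapse = ""))
      quals <- quals[-seq_len(qstart[1L] - 1L)]
    }
    qual_txt <- paste(trimws(quals), collapse = " ")
    get_qual <- function(q) {
      m <- regmatches(qual_txt,
                      regexpr(paste0("/", q, '="[^"]*"'), qual_txt))
      if (!length(m)) return(NA_character_)
      sub('"$', "", sub(paste0("^/", q, '="'), "", m))
    }
    if (key %in% c("source", "gene")) next
    if (!key %in% c("CDS", "tRNA", "rRNA", "misc_feature", "D-loop")) next
    if (grepl("join|order", loc))
      stop("feature with join/order location is unsupported: ", loc)
    strand <- if (grepl("^complement\\(", loc)) "N" else "J"
    nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1L]]
    if (length(nums) != 2L) stop("cannot parse feature location: ", loc)
    label <- get_qual("gene")
    if (is.na(label)) label <- get_qual("product")
    if (is.na(label)) label <- get_qual("note")
    if (key == "D-loop" && is.na(label)) label <- "control region"
    canon <- resolve_gene_name(label %||% "", synonyms)
    if (is.na(label) || is.na(canon))
      stop("unknown gene/product label '", label, "' in ", key, " feature")
    feats[[length(feats) + 1L]] <- gene_feature(
      name = canon, strand = strand,
      start = as.integer(nums[1L]), stop = as.integer(nums[2L]),
      start_codon = NA, stop_codon = NA, anticodon = NA)
  }

  seq <- NULL
  if (length(ostart)) {
    send <- grep("^//", lines)
    send <- if (length(send)) send[1L] - 1L else length(lines)
    raw <- paste(lines[(ostart[1L] + 1L):send], collapse = "")
    seq <- toupper(gsub("[^A-Za-z]", "", raw))
  }
  annotated_genome(if (length(feats)) do.call(rbind, feats) else NULL,
                   length = glen %||% nchar(seq), circular = circular,
                   organism = org, accession = acc, sequence = seq)
}

#' Write a GenBank flat file
#'
#' Emits a single-record flat file with `gene` + `CDS`/`tRNA`/`rRNA`
#' features (control region as `D-loop`) and the ORIGIN sequence.  Output
#' is deterministic: identical genomes yield byte-identical files.
#'
#' @param genome an [annotated_genome()] with sequence.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  if (is.null(genome$sequence))
    stop("write_genbank needs a genome with sequence")
  con <- file(path, open = "wt")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w(sprintf("LOCUS       %-16s %d bp    DNA     %-8s INV",
            ifelse(is.na(genome$accession), "UNKNOWN", genome$accession),
            genome$length,
            if (genome$circular) "circular" else "linear"))
  w("DEFINITION  ", ifelse(nzchar(genome$organism), genome$organism, "synthetic"),
    " mitochondrion, complete genome.")
  if (!is.na(genome$accession)) w("ACCESSION   ", genome$accession)
  w("  ORGANISM  ", ifelse(nzchar(genome$organism), genome$organism, "synthetic"))
  w("FEATURES             Location/Qualifiers")
  fmt_loc <- function(i) {
    f <- genome$features
    loc <- sprintf("%d..%d", f$start[i], f$stop[i])
    if (f$strand[i] == "N") loc <- sprintf("complement(%s)", loc)
    loc
  }
  w(sprintf("     %-16s%s", "source", sprintf("1..%d", genome$length)))
  w(sprintf('                     /organism="%s"',
            ifelse(nzchar(genome$organism), genome$organism, "synthetic")))
  f <- genome$features
  for (i in seq_len(nrow(f))) {
    loc <- fmt_loc(i)
    cat_i <- f$category[i]
    if (cat_i == "control_region") {
      w(sprintf("     %-16s%s", "D-loop", loc))
      w('                     /note="control region"')
      next
    }
    w(sprintf("     %-16s%s", "gene", loc))
    w(sprintf('                     /gene="%s"', f$name[i]))
    key <- switch(cat_i, PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA")
    w(sprintf("     %-16s%s", key, loc))
    w(sprintf('                     /gene="%s"', f$name[i]))
    if (cat_i == "PCG") {
      w('                     /codon_start=1')
      w('                     /transl_table=5')
      w(sprintf('                     /product="%s"', GB_PRODUCTS[[f$name[i]]]))
    } else if (cat_i == "rRNA") {
      w(sprintf('                     /product="%s"', GB_PRODUCTS[[f$name[i]]]))
    } else {
      w(sprintf('                     /product="%s"', f$name[i]))
    }
  }
  w("ORIGIN")
  s <- tolower(genome$sequence)
  pos <- seq(1L, nchar(s), by = 60L)
  for (p in pos) {
    chunk <- substring(s, p, min(p + 59L, nchar(s)))
    parts <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                       pmin(seq(10L, nchar(chunk) + 9L, by = 10L), nchar(chunk)))
    w(sprintf("%9d %s", p, paste(parts, collapse = " ")))
  }
  w("//")
  invisible(path)
}

#' Packaged example ledgers and tables
#'
#' Accessors for the packaged fixtures: the published *Labriocimbex
#' sinicus* mitogenome feature ledger, its composition table, its codon
#' usage counts, and the reference gene orders.
#'
#' @return `lsinicus_genome()`: an [annotated_genome()] (no sequence);
#'   `lsinicus_composition()` and `lsinicus_codon_counts()`: data.frames;
#'   `ancestral_insect_order()`: a [signed_gene_order()].
#' @name fixtures
NULL

#' @rdname fixtures
#' @export
lsinicus_genome <- function() {
  read_feature_table(system.file("extdata", "lsinicus_features.tsv",
                                 package = "mitoprofile"))
}

#' @rdname fixtures
#' @export
lsinicus_composition <- function() {
  read.delim(system.file("extdata", "lsinicus_composition.tsv",
                         package = "mitoprofile"), comment.char = "#")
}

#' @rdname fixtures
#' @export
lsinicus_codon_counts <- function() {
  read.delim(system.file("extdata", "lsinicus_codon_counts.tsv",
                         package = "mitoprofile"), comment.char = "#")
}

#' @rdname fixtures
#' @export
ancestral_insect_order <- function() {
  read_gene_order(system.file("extdata", "ancestral_insect_order.txt",
                              package = "mitoprofile"))
}
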