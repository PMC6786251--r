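## Supermatrix concatenation and a-priori partition emission.
##
## Alignment itself is out of scope; inputs are pre-aligned FASTA.
## Partition-model selection is ingested from config, never inferred.

#' Construct an alignment block
#'
#' @param gene gene name.
#' @param rows named character vector of equal-length aligned sequences
#'   (taxon -> sequence).
#' @param is_coding whether the block is protein-coding (enables by-codon
#'   partitioning).
#' @return object of class `alignment_block`.
#' @export
alignment_block <- function(gene, rows, is_coding = FALSE) {
  if (!length(rows)) stop("block ", gene, " has no rows")
  if (is.null(names(rows)) || any(!nzchar(names(rows))))
    stop("block ", gene, ": rows must be named by taxon")
  if (anyDuplicated(names(rows)))
    stop("block ", gene, ": duplicate taxon ",
         paste(unique(names(rows)[duplicated(names(rows))]), collapse = ", "))
  w <- unique(nchar(rows))
  if (length(w) != 1L)
    stop("block ", gene, ": rows have unequal lengths (",
         paste(w, collapse = ", "), ")")
  structure(list(gene = gene, taxa = names(rows),
                 rows = toupper(rows), length = w,
                 is_coding = isTRUE(is_coding)),
            class = "alignment_block")
}

#' Read a per-gene alignment from FASTA
#'
#' @param path aligned FASTA.
#' @param gene gene name; defaults to the file name stem.
#' @param is_coding see [alignment_block()].
#' @return an `alignment_block`.
#' @export
read_alignment <- function(path, gene = tools::file_path_sans_ext(basename(path)),
                           is_coding = FALSE) {
  alignment_block(gene, read_fasta_seq(path), is_coding = is_coding)
}

#' Concatenate alignment blocks into a supermatrix
#'
#' Blocks are laid out in input order; taxa absent from a block are
#' gap-filled with `-` over its columns.
#'
#' @param blocks list of `alignment_block` objects (or several blocks as
#'   `...` arguments).
#' @return object of class `supermatrix`: `taxa`, `matrix` (named
#'   character vector of concatenated rows), `map` (data.frame `gene`,
#'   `start`, `stop`, `is_coding`; columns 1-based inclusive).
#' @export
concatenate <- function(blocks, ...) {
  if (inherits(blocks, "alignment_block")) blocks <- list(blocks, ...)
  if (!length(blocks)) stop("need at least one alignment block")
  taxa <- unique(unlist(lapply(blocks, `[[`, "taxa")))
  widths <- vapply(blocks, `[[`, integer(1L), "length")
  stops <- cumsum(widths)
  starts <- stops - widths + 1L
  rows <- setNames(rep("", length(taxa)), taxa)
  for (b in blocks) {
    fill <- strrep("-", b$length)
    seg <- setNames(rep(fill, length(taxa)), taxa)
    seg[b$taxa] <- b$rows
    rows <- paste0(rows, seg)
  }
  names(rows) <- taxa
  map <- data.frame(gene = vapply(blocks, `[[`, character(1L), "gene"),
                    start = starts, stop = stops,
                    is_coding = vapply(blocks, `[[`, logical(1L), "is_coding"),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(map$gene))
    stop("duplicate block genes: ",
         paste(unique(map$gene[duplicated(map$gene)]), collapse = ", "))
  structure(list(taxa = taxa, matrix = rows, map = map),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("Supermatrix:", length(x$taxa), "taxa x",
      max(x$map$stop), "columns in", nrow(x$map), "blocks\n")
  invisible(x)
}

#' Extract one gene's block back out of a supermatrix
#'
#' @param sm a `supermatrix`.
#' @param gene block name.
#' @return an `alignment_block` (gap-filled taxa included).
#' @export
extract_block <- function(sm, gene) {
  i <- match(gene, sm$map$gene)
  if (is.na(i)) stop("no block named ", gene)
  rows <- substring(sm$matrix, sm$map$start[i], sm$map$stop[i])
  names(rows) <- sm$taxa
  alignment_block(gene, rows, is_coding = sm$map$is_coding[i])
}

#' Emit an a-priori partition scheme
#'
#' `by_gene`: one subset per block.  `by_gene_codon`: three stride-3
#' subsets per coding block (named `<gene>_1st`, `_2nd`, `_3rd`) and one
#' per non-coding block.  An optional merge map (e.g. transcribed from a
#' published partitioning) combines named subsets.
#'
#' @param sm a `supermatrix`.
#' @param mode `"by_gene"` or `"by_gene_codon"`.
#' @param merge named list: partition name -> character vector of subset
#'   names to merge (must cover subsets exactly once if supplied).
#' @param models optional named character vector of model names per
#'   (merged) subset.
#' @return object of class `partition_scheme`: list `subsets` (name ->
#'   sorted integer column set), `models`.
#' @export
emit_partitions <- function(sm, mode = c("by_gene", "by_gene_codon"),
                            merge = NULL, models = NULL) {
  mode <- match.arg(mode)
  subsets <- list()
  for (i in seq_len(nrow(sm$map))) {
    g <- sm$map$gene[i]; a <- sm$map$start[i]; b <- sm$map$stop[i]
    if (mode == "by_gene_codon" && sm$map$is_coding[i]) {
      if ((b - a + 1L) %% 3L != 0L)
        stop("coding block ", g, " width not divisible by 3")
      subsets[[paste0(g, "_1st")]] <- seq(a, b, by = 3L)
      subsets[[paste0(g, "_2nd")]] <- seq(a + 1L, b, by = 3L)
      subsets[[paste0(g, "_3rd")]] <- seq(a + 2L, b, by = 3L)
    } else {
      subsets[[g]] <- seq(a, b)
    }
  }
  if (!is.null(merge)) {
    used <- unlist(merge)
    if (anyDuplicated(used))
      stop("merge map uses subset(s) twice: ",
           paste(unique(used[duplicated(used)]), collapse = ", "))
    if (!setequal(used, names(subsets)))
      stop("merge map must cover all subsets exactly once; missing: ",
           paste(setdiff(names(subsets), used), collapse = ", "),
           "; unknown: ", paste(setdiff(used, names(subsets)), collapse = ", "))
    subsets <- lapply(merge, function(members)
      sort(unlist(subsets[members], use.names = FALSE)))
  }
  structure(list(subsets = subsets, models = models),
            class = "partition_scheme")
}

#' @export
print.partition_scheme <- function(x, ...) {
  cat("Partition scheme:", length(x$subsets), "subsets\n")
  for (nm in names(x$subsets))
    cat(sprintf("  %-12s %d sites%s\n", nm, length(x$subsets[[nm]]),
                if (!is.null(x$models) && nm %in% names(x$models))
                  paste0(" [", x$models[[nm]], "]") else ""))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Writers (deterministic, bit-exact ordering)

#' Write a supermatrix
#'
#' @param sm a `supermatrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @name write_supermatrix
NULL

#' @rdname write_supermatrix
#' @export
write_supermatrix_fasta <- function(sm, path) {
  write_fasta_seq(sm$matrix, path)
}

#' @rdname write_supermatrix
#' @export
write_supermatrix_phylip <- function(sm, path) {
  ncol <- if (nrow(sm$map)) max(sm$map$stop) else 0L
  con <- file(path, "wt"); on.exit(close(con))
  writeLines(sprintf("%d %d", length(sm$taxa), ncol), con)
  writeLines(sprintf("%s  %s", names(sm$matrix), sm$matrix), con)
  invisible(path)
}

## Collapse a sorted integer set into RAxML/NEXUS range notation,
## using stride-3 notation (a-b\3) where the set is a regular stride.
format_column_set <- function(cols, nexus = FALSE) {
  cols <- sort(cols)
  if (length(cols) >= 2L) {
    d <- unique(diff(cols))
    if (identical(d, 3L)) {
      sep <- if (nexus) "\\3" else "\\3"
      return(sprintf("%d-%d%s", cols[1L], cols[length(cols)], sep))
    }
  }
  runs <- split(cols, cumsum(c(1L, diff(cols) != 1L)))
  paste(vapply(runs, function(r)
    if (length(r) == 1L) as.character(r[1L])
    else sprintf("%d-%d", r[1L], r[length(r)]), character(1L)),
    collapse = if (nexus) " " else ",")
}

#' Write partition definitions
#'
#' `write_partitions_raxml()` emits RAxML-style lines
#' (`DNA, name = 1-351\3`); `write_partitions_nexus()` emits a NEXUS
#' `sets` block of `charset` lines.
#'
#' @param scheme a `partition_scheme`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partitions_raxml <- function(scheme, path) {
  lines <- vapply(names(scheme$subsets), function(nm) {
    sprintf("DNA, %s = %s", nm, format_column_set(scheme$subsets[[nm]]))
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_partitions_raxml
#' @export
write_partitions_nexus <- function(scheme, path) {
  con <- file(path, "wt"); on.exit(close(con))
  writeLines("#NEXUS", con)
  writeLines("begin sets;", con)
  for (nm in names(scheme$subsets))
    writeLines(sprintf("    charset %s = %s;", nm,
                       format_column_set(scheme$subsets[[nm]], nexus = TRUE)),
               con)
  writeLines("end;", con)
  invisible(path)
}
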