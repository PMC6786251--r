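## End-to-end profiling: ties the stages together and renders the
## ledger-style reports (feature table, composition, codon usage,
## geometry, gene-order events, structure census, supermatrix).

#' Run the full characterization profile
#'
#' Reads an annotated genome (tab-delimited ledger or GenBank), attaches
#' an optional FASTA sequence, and writes every report the inputs allow:
#' `features.tsv` (ledger layout with recomputed IGN), `validation.tsv`,
#' `geometry.json` (recomputed ledger; declared-IGN summary too when the
#' input carries IGNs), and - when sequence is present -
#' `composition.tsv` and `codon_usage.tsv`; with a reference order,
#' `gene_order_events.json`; with structures, `structure_census.tsv`;
#' with alignments, supermatrix and partition files.  Re-running with
#' identical inputs produces byte-identical reports.
#'
#' All input paths are checked before anything is written, so a missing
#' input leaves no partial reports behind.
#'
#' @param genome path to a feature table (`.tsv`) or GenBank flat file,
#'   or an [annotated_genome()].
#' @param fasta optional FASTA with the J-strand genome sequence.
#' @param reference_order optional gene-order file (see
#'   [read_gene_order()]) for rearrangement classification.
#' @param structures optional multi-record dot-bracket file.
#' @param alignments optional character vector of aligned per-gene FASTA
#'   files for supermatrix construction.
#' @param merge_map optional YAML file: partition name -> subset names.
#' @param out_dir output directory (created if needed).
#' @param verbose log each stage to stderr.
#' @return invisibly, a character vector of the files written.
#' @export
run_profile <- function(genome, fasta = NULL, reference_order = NULL,
                        structures = NULL, alignments = NULL,
                        merge_map = NULL, out_dir = "mitoprofile_out",
                        verbose = TRUE) {
  say <- function(...) if (verbose) message("[", ..., "]")
  paths <- c(if (is.character(genome)) genome, fasta, reference_order,
             structures, alignments, merge_map)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input: missing input path(s): ", paste(missing, collapse = ", "))

  if (is.character(genome)) {
    say("read ", genome)
    genome <- tryCatch({
      if (grepl("\\.(tsv|txt|tab)$", genome, ignore.case = TRUE))
        read_feature_table(genome)
      else read_genbank(genome)
    }, error = function(e) stop("read: ", conditionMessage(e), call. = FALSE))
  }
  if (!is.null(fasta)) {
    s <- read_fasta_seq(fasta)
    if (length(s) != 1L) stop("read: genome FASTA must hold one sequence")
    genome <- annotated_genome(genome$features, length = nchar(s[[1L]]),
                               circular = genome$circular,
                               organism = genome$organism,
                               accession = genome$accession,
                               sequence = s[[1L]])
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(name) {
    written <<- c(written, file.path(out_dir, name))
    file.path(out_dir, name)
  }

  say("features")
  write_feature_table(genome, emit("features.tsv"))

  say("validate")
  v <- validate_annotation(genome)
  suppressWarnings(write.table(v, emit("validation.tsv"), sep = "\t",
                               quote = FALSE, row.names = FALSE))

  say("geometry")
  led <- suppressWarnings(adjacency_ledger(genome))
  geo <- list(recomputed = unclass(geometry_summary(led)))
  if (!anyNA(genome$features$declared_ign)) {
    dled <- adjacency_ledger(genome, declared = TRUE)
    geo$declared <- unclass(geometry_summary(dled, include_wrap = FALSE))
  }
  jsonlite::write_json(geo, emit("geometry.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  if (!is.null(genome$sequence)) {
    say("composition")
    comp <- render_composition(composition_report(genome))
    suppressWarnings(write.table(comp, emit("composition.tsv"), sep = "\t",
                                 quote = FALSE, row.names = FALSE))
    say("codon usage")
    cds <- pcg_coding_sequences(genome)
    if (length(cds)) {
      tab <- rscu(tally_codons(cds))
      out <- data.frame(AminoAcid = ifelse(tab$aa == "*", "End", AA3[tab$aa]),
                        Codon = tab$codon, Count = tab$count,
                        RSCU = ifelse(is.na(tab$rscu), 0,
                                      round_half_up(tab$rscu, 2L)))
      suppressWarnings(write.table(out, emit("codon_usage.tsv"), sep = "\t",
                                   quote = FALSE, row.names = FALSE))
    }
    say("start/stop survey")
    suppressWarnings(write.table(start_stop_survey(genome),
                                 emit("start_stop.tsv"), sep = "\t",
                                 quote = FALSE, row.names = FALSE))
  }

  if (!is.null(reference_order)) {
    say("gene order")
    ref <- read_gene_order(reference_order)
    obs <- encode_order(genome)
    ev <- classify_events(ref, obs)
    jsonlite::write_json(
      list(breakpoints = ev$breakpoints,
           per_gene = as.list(ev$per_gene),
           swapped_pairs = ev$swapped_pairs,
           conserved_blocks = ev$conserved_blocks),
      emit("gene_order_events.json"), auto_unbox = TRUE, pretty = TRUE)
  }

  if (!is.null(structures)) {
    say("structures")
    census <- structure_census(read_dotbracket(structures))
    suppressWarnings(write.table(census, emit("structure_census.tsv"),
                                 sep = "\t", quote = FALSE, row.names = FALSE))
  }

  if (!is.null(alignments)) {
    say("supermatrix")
    blocks <- lapply(alignments, function(p) {
      g <- tools::file_path_sans_ext(basename(p))
      read_alignment(p, gene = g, is_coding = g %in% PCG_NAMES)
    })
    sm <- concatenate(blocks)
    write_supermatrix_fasta(sm, emit("supermatrix.fasta"))
    write_supermatrix_phylip(sm, emit("supermatrix.phy"))
    codon_ok <- all(!sm$map$is_coding |
                      (sm$map$stop - sm$map$start + 1L) %% 3L == 0L)
    mode <- if (codon_ok) "by_gene_codon" else "by_gene"
    merge <- if (!is.null(merge_map)) yaml::read_yaml(merge_map) else NULL
    scheme <- emit_partitions(sm, mode = mode, merge = merge)
    write_partitions_raxml(scheme, emit("partitions_raxml.txt"))
    write_partitions_nexus(scheme, emit("partitions.nex"))
  }

  say("done: ", length(written), " report(s) in ", out_dir)
  invisible(written)
}
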