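# Shared helpers: tiny genomes built in code, independent oracles used
# against the package implementations, and random-case generators.

# A toy circular genome whose features tile the circle with known gaps.
toy_genome <- function() {
  feats <- rbind(
    gene_feature("trnI", "J", 1, 67),
    gene_feature("ND2", "J", 70, 1113, start_codon = "ATG", stop_codon = "TAA"),
    gene_feature("trnW", "J", 1117, 1181),
    gene_feature("COI", "N", 1182, 2720, start_codon = "ATT", stop_codon = "TAA"))
  annotated_genome(feats, length = 2730, organism = "toy")
}

# Independent per-character tally (oracle for count_bases).
oracle_count <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  ch[ch == "U"] <- "T"
  c(a = sum(ch == "A"), c = sum(ch == "C"),
    g = sum(ch == "G"), t = sum(ch == "T"),
    other = sum(!ch %in% c("A", "C", "G", "T")))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# Random signed circular order over k symbols.
random_signed_order <- function(k, symbols = paste0("g", seq_len(k))) {
  signed_gene_order(sample(symbols), sample(c("+", "-"), k, TRUE))
}

# Brute-force breakpoint oracle: for each adjacency of `a`, scan all
# adjacencies of `b` in both readings and count the misses.
oracle_breakpoints <- function(a, b) {
  adjacencies <- function(o) {
    n <- length(o$symbols)
    tok <- paste0(ifelse(o$orientation == "-", "-", ""), o$symbols)
    lapply(seq_len(n), function(i) c(tok[i], tok[(i %% n) + 1L]))
  }
  flip <- function(t) ifelse(grepl("^-", t), sub("^-", "", t), paste0("-", t))
  bb <- adjacencies(b)
  misses <- 0L
  for (ad in adjacencies(a)) {
    found <- FALSE
    for (bd in bb) {
      if (identical(ad, bd) ||
          identical(c(flip(ad[2]), flip(ad[1])), bd)) { found <- TRUE; break }
    }
    if (!found) misses <- misses + 1L
  }
  misses
}

# Independent dot-bracket pairing oracle: repeatedly resolve the first
# ')' against the nearest preceding unmatched '(' (O(n^2), no stack).
oracle_pairs <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  out <- NULL
  repeat {
    j <- which(ch == ")")[1]
    if (is.na(j)) break
    i <- max(which(ch[seq_len(j)] == "("))
    out <- rbind(out, c(i, j))
    ch[c(i, j)] <- "*"
  }
  if (is.null(out)) matrix(integer(0), ncol = 2) else
    out[order(out[, 1]), , drop = FALSE]
}

# Random balanced dot-bracket string of length n.
random_dotbracket <- function(n) {
  open <- 0L
  ch <- character(n)
  for (i in seq_len(n)) {
    can_close <- open > 0L
    can_open <- (n - i) >= open + 1L
    pick <- sample(c(if (can_open) "(", if (can_close) ")", "."), 1L)
    ch[i] <- pick
    if (pick == "(") open <- open + 1L
    if (pick == ")") open <- open - 1L
  }
  # neutralize any unmatched '(' left at the end
  if (open > 0L) {
    stack <- integer(0)
    for (i in seq_len(n)) {
      if (ch[i] == "(") stack <- c(stack, i)
      else if (ch[i] == ")") stack <- stack[-length(stack)]
    }
    ch[stack] <- "."
  }
  paste(ch, collapse = "")
}
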