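---
title: "Profiling annotated insect mitogenomes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling annotated insect mitogenomes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoprofile)
```

## Scope and model of the data

`mitoprofile` computes the descriptive statistics that routinely
accompany the report of a newly sequenced insect mitochondrial genome:
base composition and strand skews, relative synonymous codon usage
(RSCU), the intergenic/overlap geometry of the annotated gene ledger,
gene-order rearrangements against the ancestral insect arrangement,
secondary-structure pair statistics for the RNA genes, and the
concatenated supermatrix with a-priori partitions that downstream
phylogenetic software consumes.  It deliberately does *not* assemble
reads, infer annotations, predict RNA structure, select partition
models, or build trees; those belong to dedicated tools, and this
package starts where they end — with an annotation and, optionally, a
sequence.

The central data model is the `annotated_genome`: a circular molecule of
known length carrying an ordered ledger of features (13 protein-coding
genes, 22 tRNAs, two rRNAs, and a control region), each with a strand
label, 1-based inclusive coordinates on the majority strand, and
declared metadata (length, start/stop codons, anticodon, intergenic
nucleotides).  Two conventions are fixed throughout:

* **Strands are called J and N** (maJority / miNority), the vocabulary
  used in mitogenome tables; GenBank's `complement(...)` maps to N at
  I/O time.
* **No feature wraps the origin.**  Wrap-spanning annotations (GenBank
  `join` locations) are rejected rather than silently split, because
  every downstream statistic assumes each feature is one contiguous
  interval.  The wrap *gap* between the last and first feature is still
  part of the adjacency ledger.

Declared metadata is never trusted over coordinates: the IGN column of
an input table is retained verbatim, but all geometry is recomputed, and
`validate_annotation()` reports every internal disagreement (declared
length vs. span, frame vs. stop codon, `ATN` start pattern, anticodon
vs. the standard table, overlaps).  Real published tables do contain
such disagreements — the packaged *Labriocimbex sinicus* ledger has a
tRNA row whose printed coordinates span 245 bp against a declared length
of 65, and several anticodon typos — and the validator is expected to
surface them as findings rather than refuse the input.  Overlaps are
always warnings, never errors: genuine gene overlaps (e.g. the shared
`ATGATAA` motif of *ATP8*/*ATP6*) are a biological feature.

## Composition and skews

For a base vector the two asymmetry statistics are

$$\mathrm{AT\text{-}skew} = \frac{A - T}{A + T}, \qquad
  \mathrm{GC\text{-}skew} = \frac{G - C}{G + C},$$

computed for the J strand (whole genome) or for coding-sense sequence
(gene and strand-class rows).  Percentages exclude ambiguity codes from
both numerator and denominator, so arithmetic on printed percentages is
exactly reproducible from the table itself.  `composition_report()`
emits the standard table layout: whole genome; the full, J-strand and
N-strand PCG sets, each with its three codon-position slices; every
individual PCG; and the two rRNAs — 28 rows for a standard 37-gene
genome.  PCG composition is computed on coding-sense sequence (the
biologically standard convention); each PCG is first trimmed to complete
codons so a truncated terminal stop (`T`/`TA`) never contributes a
partial codon.  Values are carried at full precision and rounded only at
rendering — percentages to 1 decimal, skews to 4 — using half-up
rounding, since that is how the printed tables round (base R's
round-half-to-even would disagree on exact halves).

## Codon usage

All codon work uses the invertebrate mitochondrial genetic code (NCBI
translation table 5: `AGA`/`AGG` = Ser, giving one 8-codon serine
family, `ATA` = Met, `TGA` = Trp).  For codon $i$ in a synonymous family
of size $k$ with family total $n$,

$$\mathrm{RSCU}_i = \frac{k\, n_i}{n},$$

so the family mean is exactly 1 and the family sum exactly $k$.  Two
tallying conventions are fixed by how published codon tables are
evidently computed: terminal stop codons — complete or truncated — are
**excluded** (published tables print 0 for `TAA` although every gene
ends with it), and start codons are **included** (published `ATN` counts
exceed the gene count).  Truncated stops are dropped, not padded.  The
codon-class ratio divides usage of the G+C-rich families (Pro, Ala, Arg,
Gly) by the A+T-rich families (Phe, Ile, Met, Tyr, Asn, Lys); in
strongly AT-biased mitogenomes it sits near 0.3.

## Ledger geometry

`adjacency_ledger()` emits one record per consecutive feature pair
(positional order), plus a wrap record on circular molecules with
$\mathrm{gap} = (L - \mathrm{stop}_{last}) + (\mathrm{start}_{first} -
1)$.  The IGN printed on a ledger row is interpreted as the gap
*preceding* that row's gene — verifiable from any published table by
differencing coordinates.  `geometry_summary()` counts a "location" as
one adjacent pair with a nonzero gap of the given sign, and reports
wrap and non-wrap pairs separately because published totals typically
count only the non-wrap adjacencies.  On every genome whose features
tile the circle, feature lengths plus intergenic totals minus overlap
totals equal the genome length exactly; this conservation law is a
standing test of the generator and the ledger code.

## Gene-order rearrangements

Gene orders are signed circular permutations (J = `+`, N = `-`; the
control region is excluded by default, and `trnI` is the conventional
origin).  The breakpoint distance counts signed adjacencies of one order
absent from the other, with `(x, y)` identified with `(-y, -x)`, so it
is symmetric and rotation-invariant.  Reflection equivalence of whole
orders is available but off by default: mitogenomes have a fixed
majority strand, so a mirrored genome is not "the same arrangement".

Event classification is a deterministic heuristic, not a
minimal-rearrangement optimization (narrative descriptions of
rearrangements in the literature are not optimization problems).  A
*backbone* — the largest set of genes with matching orientation whose
cyclic sequence is common to both orders, found by anchored longest
increasing subsequence with leftmost tie-breaking — is labelled
`in_place`.  Every other gene is compared to the reference by
orientation and by its nearest backbone flanks: flipped in a matched
position is `inverted`; displaced with matching orientation
`translocated`; displaced and flipped `remote_inversion`; two adjacent
genes that exchanged positions within a matched flanking context are
`swapped`, and mutual exchanges of adjacent genes that also moved are
reported separately as `swapped_pairs`.  On the packaged sawfly ledger
against the ancestral insect order this recovers exactly the three
published event clusters: *trnM*/*trnQ* swapped and translocated
downstream of *rrnS*, the remote inversion of *trnY* with the
translocation of *trnC*, and the in-place inversion of *trnT*.

Conserved blocks can be computed orientation-aware (default; a strand
flip breaks a block) or orientation-agnostic.  Cross-species claims of
the form "the order from *COI* to *rrnS* is conserved" are
symbol-order claims — a single-gene strand flip inside the block does
not break them — so that property is checked with
`ignore_orientation = TRUE`.

## RNA structure statistics

Dot-bracket structures are parsed with a stack; pseudoknots are rejected
by default (a permissive flag accepts extra bracket tiers and skips the
cloverleaf audit, which assumes nesting).  Pair classes are Watson-Crick
(`A:U`, `G:C`), `G:U` wobble, and named mismatches; because published
tRNA censuses count wobbles among "unmatched" pairs, a combined
noncanonical tally (wobble + mismatches) is always reported alongside
the strict classes, so both accountings are available without guessing
which one a given table used.

The cloverleaf audit decomposes nested pairs into helical stems: the
outermost helix is the amino-acid acceptor stem; the helices off the
central multiloop are, 5′→3′, the DHU, anticodon and TΨC arms.  With
only two multiloop helices the anticodon arm is identified as the helix
whose loop is closest to the canonical 7 nt (later helix on ties) and
the absent arm is reported by position — the common real case being the
missing DHU arm of *trnS1* (AGN).  The anticodon is the central triplet
of the anticodon loop.  The audit ignores labels and unpaired 3′ tails
(discriminator/CCA), and refuses folds with more than three multiloop
helices as non-tRNA-like.

## The synthetic-data generator

`simulate_genome()` exists so that every stage can be tested against
known ground truth without downloads.  Its defaults are the study
conditions of a sequenced cimbicid sawfly mitogenome: 15,405 bp target
length; the ancestral insect gene order with the control region between
*rrnS* and *trnI*; A+T fraction 0.812 with AT-skew 0.0714 and GC-skew
−0.1809; PCG codons drawn from the packaged published codon-usage
counts; small intergenic gaps (40% abutting, otherwise 1–6 bp) and no
overlaps unless planted.  Typical PCG and rRNA lengths are fixed
constants; tRNAs are genuine folded cloverleaves from `simulate_trna()`
with the standard anticodon planted (and no DHU arm for *trnS1*), so
structure statistics on generator output have exact expectations.

Composition control works through the freely varying positions.  First
and second codon positions are constrained by amino-acid choice, so the
generator solves for the emission A+T $a_{\mathrm{ctrl}}$ on the
controllable fraction (third positions, tRNA stems and loops, rRNAs,
spacers, control region) such that the *expected* whole-genome A+T
equals the target; third positions are steered by reweighting codons
within each synonymous family by the ratio of the target third-base
distribution to the weight table's own third-base marginal, which
preserves the relative within-family bias shape.  The realized
composition is checked post hoc, not guaranteed exactly; at 15 kb the
whole-genome A+T lands within well under ±0.02 of the target.  Setting
`pos3_reweight = FALSE` disables the steering, making codon draws
exactly proportional to the weights (the mode under which codon-count
convergence is tested).

One integer seed drives a named random substream per sub-generator
(layout, each PCG, each tRNA, each non-coding region), so adding a
generator does not perturb the others, and identical parameters give
byte-identical GenBank output.  Planted rearrangements
(`apply_rearrangements()`) return ground-truth labels in the
classifier's vocabulary; a gene both translocated and inverted is
labelled `remote_inversion`.

What the generator does **not** emulate: real within-gene composition
heterogeneity, genuine overlap motifs (planted overlaps overwrite the
upstream tail with the downstream sequence), rRNA secondary structure,
replication-origin skew gradients along the circle, and sequencing or
annotation error.  Tests passing on generator output therefore certify
the statistics code, not the biology of real annotations; the packaged
published ledger — typos included — is the fixture that exercises the
real-data pathologies.

## Numerical choices and degenerate inputs

* Skews with a zero denominator are `NA`, flagged, never `Inf`.
* Rounding is half-up, applied only at rendering; internal values keep
  full precision.
* Empty inputs return empty-but-typed results (header-only tables, zero
  PCG genomes, empty adjacency lists), never errors, except where the
  operation is meaningless (composition without a sequence).
* Tie-breaks in the event classifier (anchor choice, LIS) resolve
  leftmost-in-reference, making reports deterministic.
* Supermatrix and partition writers emit bit-exact deterministic output
  (fixed block order, stride notation `a-b\3` where a subset is a
  regular codon stride).

## Problem sizes in the test suite

The suite runs the generator at full 15.4 kb scale (a handful of seeds),
100-case property loops for breakpoint distances, planted-event
recovery and dot-bracket parsing, and 22-structure tRNA censuses —
about ten seconds end to end, so the whole suite including the
published-table checks stays far inside interactive time.

## Known limitations

* GenBank I/O is deliberately minimal: single record, simple locations,
  the qualifiers mitogenome submissions actually use.  It is not a
  general GenBank parser.
* Event labels are heuristic; for heavily shuffled genomes (many
  interacting events) a compound rearrangement has no unique
  single-event description, and labels should be read as a description
  of differences, not a history.
* Partition models are ingested, never inferred; alignment is assumed
  done upstream.
* The ancestral insect order ships as an editable reference; other
  outgroups or origins can be supplied as plain-text order files.
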