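---
title: "Detecting circular RNAs with a scrambled exome reference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting circular RNAs with a scrambled exome reference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scramblex)
library(dplyr)
```

## The problem and the model

Circular RNAs (circRNAs) arise when the spliceosome joins the 3′ end of a
downstream exon head-to-tail to the 5′ start of an upstream exon — a
*backsplice*. On a linear reference genome this junction does not exist, so
standard RNA-seq alignment cannot see it. scramblex detects circRNAs the
way several junction-library callers do: it constructs a **scrambled
exome**, the set of all intragenic exon pairs (exon1 upstream, exon2
downstream, including the pair of an exon with itself) written in
backspliced order — the transcribed-orientation sequence of exon2 followed
by exon1, with the junction at offset `len(exon2)` — and places paired-end
reads on those junction entries.

Two kinds of read-pair evidence support a backsplice:

* **junctional** — one mate crosses the junction point with at least
  `min_overlap` (default 10) bases anchored in *each* exon, while its mate
  lies anywhere on the entry;
* **supportive** — no mate crosses the junction, but the forward mate lies
  wholly in the exon2 segment and the reverse mate wholly in the exon1
  segment. On the genome such a pair is divergent (outward-facing), which
  only a circular template explains.

Pairs with both mates inside one exon segment are indistinguishable from
linear reads and count as nothing. A junction becomes a candidate circRNA
when it accrues, in a sample, at least `min_junctional = 3` junctional
fragments **or** at least `min_supported = 10` backsplice-consistent
fragments. The published phrasing of the second threshold ("ten supporting
read pairs") is ambiguous about whether junctional fragments count toward
it; we default to the total-count reading (**policy A**:
junctional + supportive ≥ 10) and provide the strict supportive-only
reading as **policy B**. Both are exercised by the tests; one
mixed-evidence case (2 junctional + 9 supportive) distinguishes them.

The 10 bp anchor rule is read as "at least 10 bases on each side of the
junction". The permissive alternative ("overlaps at least one exon by
10 bp") is vacuous — any junction-crossing 50 bp read satisfies it — so
only the two-sided reading yields a usable rule.

## Mapping

The production path imports external SAM/BAM alignments against the
junction FASTA (secondary and supplementary records dropped, PCR
duplicates removed by outer fragment coordinates and orientation, exactly
as `samtools rmdup` collapses them). For a self-contained, deterministic
pipeline the package also ships a small ungapped k-mer seed-and-extend
paired-end mapper (`k = 15`, per-mate mismatch ceiling 2, FR orientation
required, ties broken by mismatch count, then entry id, then leftmost
position). Junction entries are short exonic sequences and the reads are
~50 bp, so ungapped placement is adequate; the scientific content lives in
the classification layer, not the aligner.

Single-exon backsplice entries are written as the exon duplicated
(sequence + sequence). A read sampled across the circularisation point of
a single-exon circle is then contiguous on the entry, which is what makes
those circles detectable at all read positions.

## The simulator and its study conditions

`make_fixture_genome()` emulates a compact exome: by default 50 genes of
2–4 exons, exon lengths 90–120 bp, uniform base composition, both strands.
`simulate_reads()` draws, per planted circle, a fixed number of fragments
("depth" is a fragment count, not coverage) uniformly around the
circularised backsplice sequence — positions wrap, so junction-spanning
and non-spanning fragments both occur — plus a linear background of
fragments from each gene's canonical transcript. Reads are 50 bp,
fragments normal with mean 100 and sd 5 (truncated at two read lengths),
substitution errors i.i.d. at 1%.

These defaults were fixed analytically before any end-to-end run, from the
position geometry of the two-exon circle model. A circle whose junction
entry has length $L$ offers $2(r - 2 \cdot \text{min\_overlap} + 1) = 62$
fragment start positions (for $r = 50$) at which a mate crosses the
junction with sufficient anchors, so the per-fragment junctional
probability is roughly $62/L$; fragments that cross the circle's *other*
(linear) junction are not contiguous on the entry and are lost to the
junction reference. For 20 fragments per circle to yield at least three
junctional ones with high probability, mean entry length must stay below
roughly 210 bp — hence short exons and a short insert. Under the defaults
the expected per-circle detection probability is ≈ 0.97–0.98. Longer
exons or larger inserts degrade sensitivity sharply at fixed depth; that
is a property of the circle geometry, not of the implementation.

What the simulation does **not** model: multi-exon circle interiors (the
circle is exon2 + exon1 only), indels and quality-dependent errors,
coverage biases, intron retention, and trans-splicing. Passing the
simulated benchmark therefore demonstrates the correctness of the
evidence logic and thresholds under clean conditions, not performance on
real libraries.

Two negative controls re-run the identical pipeline: a **randomized**
reference (each exon's sequence shuffled once, composition preserved,
seed recorded) and a **flipped-exon2** reference (exon1 followed by the
reverse complement of exon2 — a head-to-head junction). Linear-only reads
must produce zero candidates on both, and flipped-control calls must not
intersect the real candidate set.

```{r controls, eval = FALSE}
fix <- make_fixture_genome(n_genes = 50, seed = 1)
pairs <- enumerate_backsplices(fix$exons)
entries <- build_junction_reference(pairs, fix$genome)
ctrl <- build_control_reference(pairs, fix$genome, "randomized", seed = 3)
```

## Quantification

Circular expression per junction and sample is the number of distinct
backsplice-consistent fragments (junctional + supportive). Linear
expression for the same exon pair counts concordant genomic fragments
overlapping either exon by at least one base — deliberately conservative,
since reads inside an exon cannot be assigned to the circular or linear
isoform, and assigning them all to the linear form biases the
circular:linear ratio downward, never upward. The ratio reports `Inf`
with a `circ_only` flag when linear evidence is absent and drops
junctions with no evidence at all.

Transforms: FPKM is `count / (length_kb × mapped_millions)`; the
RNase-R-style enrichment compares per-feature fold changes
`(treated + 1) / (untreated + 1)` between circRNA and mRNA classes with a
one-sided Wilcoxon rank-sum test; the expression heat-map transform is a
per-row z-score of `log2(cpm + 0.5)`, with constant rows mapped to zero
rather than NaN. The pseudocounts (1 for fold changes, 0.5 inside the
log) avoid division by zero and vanish at high counts. The
low-expression prefilter keeps rows with at least 3 counts in at least 3
samples; differential testing itself is delegated to edgeR/DESeq2-class
tools, which ingest the exported TSV count matrices directly.

The RNase-R experiment is simulated at the count level: treated means for
linear features are divided by the depletion factor (default 10), circles
keep theirs, and observed counts are Poisson. This mirrors the
exonuclease's effect on abundances without modelling digestion kinetics.

## miRNA sponge scoring

`find_seed_matches()` reports canonical seed sites — 8mer
(revcomp of miRNA bases 2–8 followed by A), 7mer-m8 (revcomp of 2–8),
7mer-A1 (revcomp of 2–6 … 7 followed by A) — at every position, keeping
the strongest type per position. Note that an 8mer site necessarily
contains a 7mer-A1 site one base downstream; both are reported, at their
own positions. circRNA targets can be scanned as circles
(`circular = TRUE`), so sites straddling the backsplice seam are found —
the circle is covalently closed. Thermodynamic filtering (context+
scores, cofold energies) is out of scope; externally computed scores can
be joined onto the match table.

The sponge statistic over a circRNA → miRNA → gene network is

$$E_{circ}(\text{miR-}x) = \frac{1}{N}\sum_{i=1}^{N} n_{xi}\, x_i,$$

the mean over the $N$ circRNAs targeting miR-*x* of seed-match count
times fold change, and **Average E_circ** for a gene is the mean of
$E_{circ}$ over the miRNAs targeting it (per-miRNA averaging, matching
the per-gene reading of the definition; the alternative — averaging over
circRNA–miRNA pairs — differs only when a gene's miRNAs have unequal
circle counts). The fold change $x_i$ is taken as the log2 fold change
from an upstream differential-expression table; the definition says only
"fold change expression", and the log scale keeps up- and
down-regulation symmetric around zero. miRNA→gene edges are consumed
from a user-supplied table, not predicted.

## Numerical and design choices

* Coordinates are 0-based half-open internally; GTF input and output are
  1-based inclusive.
* Exons are collapsed per gene across transcripts before enumeration
  (the junction sample space is per-gene, not per-transcript); a gene
  with $n$ exons yields $n(n+1)/2$ entries.
* No maximum genomic span is imposed on exon pairs; a configurable
  per-gene exon cap exists for pathological annotations (off by
  default).
* Full-length exon concatenation (not a junction window) is used so that
  supportive mates landing anywhere on either exon align to a single
  target.
* All tie-breaks (mapper placement, duplicate representative, output
  order) are deterministic, so a fixed config and seed reproduce outputs
  byte for byte.
* Problem sizes in the shipped tests and acceptance script — a 50-gene
  fixture, 200 planted circles, depths 2–20, five replicate seeds — were
  chosen as the smallest sizes at which the binomial noise on
  sensitivity (≈ 0.01 at 200 circles) is comfortably below the margins
  being tested.

## Known limitations

Annotation-free junction discovery, exon-intron circles, fusion or
trans-spliced junctions, gapped or quality-aware alignment, and built-in
differential testing are out of scope. Sensitivity claims transfer to
real data only to the extent that real insert sizes and exon lengths
resemble the simulated geometry; with 300 bp exons and 250 bp inserts,
depth-20 circles are genuinely hard to call under these thresholds, and
a user should expect the depth titration curves to shift right.
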