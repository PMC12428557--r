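---
title: "Models and methods behind splicedown"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind splicedown}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicedown)
```

splicedown annotates the downstream consequences of differential alternative
splicing events (DASEs) called from junction-count tables in the rMATS
dialect. This vignette explains the models the package implements, the
parameters that matter, the numerical choices made where the design was
open, and what the synthetic-data generator does and does not emulate.

## Event quantification and filtering

Percent spliced in for one replicate is the length-normalised fraction of
junction reads supporting inclusion,

$$\psi = \frac{I/\ell_I}{I/\ell_I + S/\ell_S},$$

where $I$ and $S$ are inclusion and skipping junction counts and
$\ell_I, \ell_S$ their effective lengths (for a skipped exon, two inclusion
junctions against one skipping junction). When a replicate has no reads at
all its $\psi$ is undefined and reported as `NA`, never silently 0.
$\Delta\mathrm{PSI}$ is the mean treatment $\psi$ minus the mean control
$\psi$; sample group 1 of the input tables is treated as the treatment
group, so a positive $\Delta\mathrm{PSI}$ means more inclusion after
treatment.

`filter_dases()` retains events with FDR $\le 0.05$,
$|\Delta\mathrm{PSI}| \ge 0.1$ and mean junction coverage strictly greater
than 5. Coverage is defined as the mean over all replicates of both groups
of $I + S$; the alternative reading (inclusion reads only) is plausible but
we fixed the inclusive definition once and test against it. The filter is
idempotent and order-preserving, and events with missing FDR are rejected
loudly rather than passed through.

`call_dases()` exists so synthetic data can be carried end to end without
the original event-calling tool: it is a pooled two-group likelihood-ratio
test of equal versus separate binomial inclusion probabilities, with
Benjamini-Hochberg adjustment across all events jointly. The LRT uses the
raw pooled counts rather than length-normalised counts: with equal
effective lengths in both groups, equality of inclusion probability is
equivalent to equality of PSI, and a binomial likelihood is only defined
for integer counts. It deliberately ignores replicate-level variability
(no hierarchical model) and is documented as a stand-in for synthetic
data, not a re-implementation of the consumed tool.

## Target regions

Each event class maps to one genomic interval that the sequence analyses
consume: the target exon (SE); the first exon on `+` and the second on `-`
(MXE); the retained intron, i.e. upstream exon end to downstream exon start
(RI); and the long exon minus its overlap with the short exon (A3SS/A5SS),
which requires the short exon to sit flush against one boundary of the long
exon. All internal coordinates are 0-based half-open, matching the
`exonStart_0base`/`exonEnd` convention of the input tables; GTF input is
converted from 1-based inclusive on read. Sequences are extracted strand
aware (reverse complement on `-`), so every downstream scan operates in
transcript orientation.

## Premature termination codons in retained introns

`scan_premature_stops()` reads codons from offset `frame - 1` in steps of
three and reports every in-frame TAG/TAA/TGA that lies fully inside the
retained-intron sequence. Codons straddling the exon-intron boundary are
not counted, and codons containing `N` never match. Positions are 1-based
offsets of the codon's first nucleotide within the transcript-oriented
intron; this is the natural convention for an intron-local scan, but
first-position values from other tools may use transcript-relative or
codon-index conventions, so stop *counts* are the robust comparison
quantity.

The reading frame at the intron is derived from annotation:
`determine_frame()` finds CDS segments whose transcript-orientation 3' end
abuts the intron, carries the codon phase across the junction
(`frame = 1 + ((3 - carry) mod 3)`, with `carry` the number of bases of the
interrupted codon already consumed), prefers the longest-CDS transcript
when isoforms disagree, and accepts a user-supplied frame override for
events whose frame was established by manual genome-browser inspection.

## miRNA-target hybridization

`duplex_mfe()` is an intermolecular-only duplex dynamic programme: the
miRNA is aligned antiparallel against a target window, helices accumulate
nearest-neighbour stack energies (G-U wobbles allowed), and helix
interruptions pay tabulated bulge or interior-loop penalties, with loop
sizes capped at 15 nt per strand and an interior asymmetry term capped at
3 kcal/mol. Intramolecular structure in either strand is not modelled —
the package treats target-site accessibility as out of scope. The
parameter file ships Turner-style RNA/RNA stacks (21 unique physical
stacks expanded by strand symmetry), bulge and interior initiation by loop
size, and a duplex initiation penalty of +4.1 kcal/mol. Energies from
other hybridization programs agree only approximately (a couple of
kcal/mol); nothing downstream depends on matching an external
implementation exactly, and the engine is validated instead against
exhaustive enumeration of every loop-bounded pairing on small instances.

The cascade then mirrors the standard analysis: keep the single best hit
per miRNA-region pair (ties broken toward the smallest target start); keep
hits with mfe $\le -30$ kcal/mol (the threshold is printed both as "lower
than" and as "$\le$" in common usage; we adopt the inclusive form and make
it configurable); classify seed pairing; drop unclassifiable hits; and
keep only miRNAs in the tissue high-expression range.

Site classes use miRNA positions 2-7 (seed) and 13-16 (post-seed):
`Strong` pairs both perfectly by Watson-Crick pairing, `Canonical` pairs
only the seed perfectly, `Compensatory` has seed defects offset by a
perfect post-seed. G-U wobbles are energetically favourable but count as
non-Watson-Crick for classification. The A1 check — adenosine opposite
miRNA position 1, i.e. the target base immediately 3' of the base opposite
position 2 — is an annotation only and never filters.

The expression filter takes the q-th percentile (default 85, linear
interpolation between order statistics) of the positive expression values
and retains miRNAs at or above it, boundary inclusive.

## RBP motif maps

`build_region_layout()` decomposes each event into the sub-regions familiar
from RNA-map servers: exonic flanks of up to 50 nt and intronic flanks of
up to 250 nt around the class-specific splice sites, labelled R1..Rn in
transcript orientation and collapsed to Upstream / Exon / Downstream (for
RI the retained intron itself is the Exon region). Features shorter than
the nominal flanks are truncated without double-counting: the first slice
of a feature takes up to its nominal size and the last slice takes what
remains. Each sub-region is anchored at its splice-site-proximal end
within the nominal window, so windows align at splice sites across events
of different sizes, and an event contributes only to windows that lie
fully inside its actual sequence.

Motif "density" is the fraction of nucleotides of a 50-nt window (step
1 nt; windows never span sub-region boundaries) covered by at least one
IUPAC motif occurrence. The original server's exact score normalisation is
not public; the coverage-fraction definition is pinned by our own oracle
tests. Group curves (up: $\Delta\mathrm{PSI}>0$; down: $<0$; background:
tested events failing the DASE filter) are means over events, and each
window is tested by a two-sided Wilcoxon rank-sum of the regulated group
against background — exact enumeration (midranks, ties respected) when
both groups have at most 8 events, otherwise the normal approximation with
tie and continuity corrections. Per-window p-values are deliberately not
multiplicity-corrected, mirroring the per-window dotted p-value curves of
the emulated server; the coherence step's notion of "significant" is any
window below $\alpha = 0.05$ within the collapsed region (a sustained-run
criterion would be stricter; the any-window reading is recorded as the
design choice). `coherent_occurrences()` then keeps motif occurrences only
where the (class, $\Delta\mathrm{PSI}$ direction, collapsed region)
combination is enriched, and events with $\Delta\mathrm{PSI}$ exactly 0
belong to neither direction.

`reduce_rbp_network()` keeps every differentially expressed RBP node plus
every node connected to one by any path, dropping the rest — a plain
connected-components computation.

## Over-representation

`fisher_ora()` computes, per term, the one-sided hypergeometric upper-tail
probability of at least $k$ study hits, fold enrichment $(k/n)/(K/N)$ and
Benjamini-Hochberg FDR across terms, sorted by decreasing fold enrichment.
The background universe defaults to all genes in the annotation map — term
databases define their own backgrounds and analyses rarely state theirs —
and is configurable. Only the over-representation tail is offered.

## The synthetic-data generator

`simulate_dataset()` emits a toy genome (one contig per gene/event), a
GTF-style annotation with phased CDS on retained-intron genes, per-class
junction-count tables, miRNAs with a brain-style expression table, an RBP
motif list, a PPI fixture with DEG flags, a term-to-gene map, and a truth
record that can be re-derived from the emitted sequences. Its defaults
mirror the emulated study design: two biological replicates per group and
binomial junction counts at a target depth per event, with the inclusion
probability implied by the true PSI through the class effective lengths.
Exons default to 30-500 nt and introns to 80-5000 nt so that flank
truncation is exercised. Counts are binomial without overdispersion —
real replicate variability is larger, which is why the stand-in caller's
p-values are only used against synthetic truth. Planted features are
constructed, not sampled: premature stops are planted after the frame is
cleaned of accidental stops; miRNA sites are perfect reverse complements
(with optional recorded mutations) whose planted miRNAs are placed in the
high-expression range; motif enrichment plants extra occurrences so a
chosen collapsed region reaches a chosen multiple of the background
expectation. Passing tests on these data demonstrates correctness of the
pipeline's logic, not performance on real RNA-seq: the generator has no
alignment artefacts, no overdispersion, no isoform mixtures, and iid base
composition.

Problem sizes used by the checks were fixed once as realistic smallest
sizes that give stable rates: 600 events (200 per group) for null error
control, 300 events with a third regulated for enrichment power over 50
replicates (20 in the acceptance script), 140 mixed-class events at depth
200 for filter recovery, and 10,000 events at depth 500 for estimator
bias.

## Numerical choices and degenerate inputs

Ties in the duplex traceback resolve toward the smallest target start;
events are sorted by (class, chromosome, start, id) wherever an order is
emitted; the exact rank-sum enumeration uses midranks so tied data remain
exact; a duplex whose best energy is non-negative is a no-hit (mfe 0,
empty pairing) rather than a positive-energy "hit"; empty sequences,
empty groups and empty filter results propagate as empty tibbles with
stable schemas. Reruns of the generator and pipeline under one seed are
byte-identical; the pipeline itself is deterministic given its inputs.

## Known limitations

The stand-in significance test is not the consumed tool's hierarchical
model; duplex energies approximate but do not reproduce any specific
external program; motif coherence uses raw per-window p-values; secondary
structure and site accessibility are not modelled; and the premature-stop
first-position convention, while internally consistent, is not guaranteed
to match manually curated reports that used a different offset origin.
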