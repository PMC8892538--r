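---
title: "Methods: 3D comparative scaffotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D comparative scaffotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaffotyper)
```

## Overview

`scaffotyper` assigns chromosome-scale scaffolds of one or more target
species to the chromosomes of a reference species, using two independent
signals: conserved gene order (homologous synteny blocks chained from
pairwise whole-genome alignments) and conserved chromosome-scale chromatin
conformation (Hi-C A/B compartment eigenvectors compared at orthologous
positions). This vignette documents the model, every tunable parameter, the
numerical choices, what the synthetic-data generator does and does not
emulate, and the known limitations.

## Synteny blocks

Input alignment blocks are gap-free aligned interval pairs, either a 7-column
BED-pair TSV or a UCSC chain file (chains are decomposed into their aligned
segments, with minus-strand query coordinates converted to forward-strand
0-based half-open intervals). All coordinates are 0-based half-open
internally. Target scaffolds shorter than `min_scaffold_len` (default
50,000 bp) are excluded before analysis; the boundary is inclusive-keep
(a 50,000-bp scaffold is retained).

Chaining is greedy and colinear. Blocks sharing
`(ref_chrom, tgt_scaffold, orientation)` merge when they are diagonal-
consistent on both genomes and the inter-block gap is below the working
`resolution` (default 300,000 bp) on both genomes; merged blocks whose span
is below `resolution` on either genome are discarded. When a block could
extend several open chains, the chain with the larger accumulated reference
span wins, ties going to the smaller reference start. Where surviving blocks
overlap on the reference, the longer block keeps its interval and the other
is trimmed. This deliberately does not reimplement the A-Bruijn-graph
synteny-block algorithms used by alignment post-processors; at the working
resolution, greedy chaining with max-gap = min-span = resolution produces
equivalent block sets on inputs whose segments are separated by more than
one resolution unit, which is the regime the classifier requires anyway.
Boundary placement may differ from other chainers by up to about one block
at segment edges.

## Rearrangement classification

HSBs ordered along each target scaffold are grouped into *segments*: maximal
runs sharing one reference chromosome, regardless of orientation. Each
segment records a majority orientation, weighted by reference span. Counting
is then purely combinatorial: with `N_seg` segments over `N_tgt` scaffolds
and `N_ref` reference chromosomes, `n_fusions = N_seg - N_tgt` and
`n_fissions = N_seg - N_ref`. Both quantities are order-independent, and
the karyotype accounting identity `N_tgt = N_ref - n_fusions + n_fissions`
holds by construction, so the package verifies it on every run as an
internal-consistency check rather than assuming it.

Within a segment, every maximal run of HSBs oriented against the majority is
one inversion, sized by its reference span. A segment that is entirely
minus-oriented is treated as a strand assignment of the whole fragment, not
an inversion — this matches how comparative chromosome browsers display
whole-fragment orientation, and makes detection invariant under a global
strand flip (a tested property). A reference chromosome contributing two or
more separate segments to the same scaffold is reported as a translocation
(the non-colinear, "internal rearrangement" pattern).

Inversions shared between species are deduplicated by 50% reciprocal overlap
of their reference intervals, collapsing transitively (connected components
of the overlap graph). The 50% threshold is a declared package choice; no
published rule exists for this step, and visually curated shared-event
counts could differ near the threshold. The X chromosome is excluded from
fusion/fission accounting by default (`exclude = "X"`), since sex
chromosomes are conventionally treated separately.

## Compartment eigenvectors

Per-scaffold contact matrices (sparse upper-triangle triplets plus a bin
table; 500-kb bins by default) are processed as:

1. **Masking.** Bins whose raw marginal is zero or below the 5th percentile
   of nonzero marginals are masked throughout. The percentile is
   configurable (`mask_quantile`); low-coverage bins otherwise dominate the
   correlation structure.
2. **Balancing.** Symmetric Sinkhorn iteration to the equal-row-sum matrix
   scaling fixed point — the same fixed point that Knight–Ruiz Newton
   solvers converge to, with simpler convergence control. Tolerance `1e-6`
   on the relative row-sum spread, capped at 3000 iterations; rows that
   fail to converge are masked with a warning. The balanced matrix
   satisfies `max/min` valid row sums `<= 1 + 10*tol` (tested).
3. **Distance normalisation.** Each entry is divided by the mean of valid
   entries at the same bin distance, so every off-diagonal of the
   observed/expected matrix has mean one.
4. **Correlation.** Pearson correlation of every pair of valid O/E rows;
   constant rows are masked; fewer than three valid bins is an error
   ("scaffold too short for compartment analysis").
5. **Leading component.** Principal component 1 of the correlation matrix:
   columns are centred and the first singular direction's scores are
   normalised to unit Euclidean norm. `explained_fraction` is the share of
   total variance on the first component. Centring follows the
   principal-component definition of the eigenvector used in Hi-C practice;
   note that for degenerate 2-bin matrices the centred and uncentred
   definitions disagree, which is irrelevant here because step 4 already
   requires three valid bins. A zero spectrum (constant correlation) yields
   a masked profile with a warning rather than an arbitrary vector.
6. **Sign.** A principal component's sign is arbitrary. With an anchor
   profile the sign is chosen to make the correlation with the anchor
   non-negative; without one, the first valid bin is made non-negative.
   Positive values are labelled compartment A. This is a labelling
   convention, fixed so that all species share one orientation; it does not
   claim to identify the biologically active compartment without an
   external covariate (e.g. gene density), which the package deliberately
   does not require.

The display cap of 1000 counts used by `autoplot()` for heatmaps is
cosmetic and never enters computation.

## Cross-species comparison

Target eigenvectors are lifted onto reference coordinates through the HSBs
by bin-midpoint mapping: each reference bin covered at least half by an HSB
takes the value of the target bin its midpoint maps to. Proportional
averaging is deliberately avoided — the bin size equals the eigenvector
resolution, so sub-bin precision would be illusory. Within minus-oriented
HSBs the bin order is reversed; values are *reordered, not negated*,
because a locus's compartment identity does not depend on the strand on
which it is assembled. Lifting through rearrangement-free HSBs is the exact
identity on valid bins (tested to 1e-12 through the similarity path).

Per-segment similarity is the Pearson correlation over overlapping valid
bins, reported as not-assessed below `min_bins = 10` overlapping bins.
Compartment shifts are maximal runs of at least `min_run = 2` consecutive
bins (1 Mb at default bins) where the sign-anchored profiles disagree;
direction is read off the reference sign (A→B when the reference bin is
positive). The 2-bin minimum is a package choice: published compartment
"switch" calls at this scale are typically visual, with no printed
threshold to calibrate against; single-bin disagreements are indistinguishable
from eigenvector noise at realistic depth.

## Orthology table and naming

Each species' segments become fragments of a scaffotype table, ordered along
each reference chromosome and joined with `+` in the rendered form.
Scaffolds contributing one segment stay unlettered; scaffolds split into
k ≥ 2 segments get letters `a..` by ascending target-start coordinate, so
letters encode position along the scaffold and are stable under any
reordering of the input (tested by permutation). Beyond 26 fragments the
letters continue `aa, ab, ...`. Overlapping claims by one species on a
reference interval are an error, not silently resolved: the method's value
is that assignments are unambiguous, so ambiguity must surface.
Segments whose eigenvector similarity falls below `warn_threshold = 0.5`
are flagged but never removed — sequence evidence keeps them in the table,
the flag directs human attention.

The printed-table parser is whitespace-tolerant around `+` because
published table typography is inconsistent; the emitter writes the
canonical no-space form, and parse→emit on the packaged carnivore table is
byte-identical. Naming recommendations encode three published rules and
nothing more: the reference should be the most ancestral karyotype in the
clade and must have >90% of sequence anchored to chromosomes; reference
chromosome names may be adopted only with a full complement of 1:1
orthologs; otherwise scaffolds are named by size rank with the table as the
orthology lookup. Fuller rule systems in supplementary material of the
source literature are intentionally out of scope.

## The synthetic-data generator

The generator exists so every stage is testable against planted truth with
no external data. It emulates:

* multi-chromosome genomes with a two-state compartment profile in blocks
  of geometric length (mean 8 bins at 500-kb bins — megabase-scale
  compartment domains);
* scripted inversion / fission / fusion / translocation histories applied
  sequentially, emitting ground-truth alignment blocks (the maximal
  conserved segments) in the same BED-pair dialect the reader consumes;
* intrachromosomal Hi-C counts with power-law distance decay
  (`lambda_ij = R * s^-alpha * (1 + c * a_i * a_j)`, `s = max(|i-j|, 1)`,
  defaults `alpha = 1` for generic polymer scaling, `c = 0.3`, `R = 50`
  reads per bin pair on the first off-diagonal), drawn as symmetric Poisson
  counts, deterministic per seed.

Breakpoints of distinct random events are kept at least two bins apart and
away from chromosome ends, with the margin scaled up to an inversion's own
length so a planted inversion can never become the majority orientation of
its segment; histories violating the spacing are rejected at generation
rather than silently kept. This guarantees the classifier's recovery
preconditions, which is the point: the 100%-recovery property states that
*well-separated* events are never miscounted, not that arbitrarily dense
histories are resolvable at a finite resolution.

The generator does not emulate: read-level data (FASTQ, restriction
fragments, duplicates), trans contacts, copy-number or assembly errors,
coverage heterogeneity along chromosomes, TAD-scale structure, or
alignment noise (truth blocks are exact). Passing tests therefore
demonstrate correctness of the algorithms under the stated model, not
robustness to every artefact of real Hi-C libraries; on real data the
coverage mask and the similarity flags carry that burden.

Poisson counts with a multiplicative checkerboard were chosen because the
leading principal component of the resulting correlation matrix provably
aligns with the planted profile as depth grows, giving an unambiguous
ground truth; recovery strengthens monotonically with `c` and with depth
(tested on a seed-averaged grid). At the default conditions (`c = 0.3`,
50 reads/bin-pair, 60-bin scaffolds) the seed-averaged recovery correlation
exceeds 0.9, with single-seed values occasionally in the high 0.8s — an
honest reflection of eigenvector noise at that depth.

## Problem sizes and determinism

The shipped tests run the planted-event recovery over 200 seeded histories
of four chromosomes (10–20 Mb) with five events each, compartment recovery
over 20 seeds of a 60-bin scaffold, spectral-oracle equivalence up to
50-bin matrices, and brute-force chaining equivalence on inputs up to six
blocks — sizes chosen so the full suite completes in well under a minute
while still exercising every code path at meaningful scale. All randomness
flows through explicit integer seeds via R's generator; simulation
functions save and restore the caller's RNG state, and identical inputs
give bitwise-identical eigenvectors.

## Known limitations

* Greedy chaining can differ from graph-based synteny tools by roughly one
  block at segment boundaries; fragment *counts* are robust to this,
  boundary coordinates to within one resolution unit are not guaranteed.
* Only intrachromosomal (cis) matrices are processed; fusions that manifest
  first as trans contacts are seen only through the alignment signal.
* The HDF5/cooler container dialect is not read directly; matrices must be
  exported to sparse triplet text upstream.
* Eigenvector comparability assumes comparable cell type and library
  protocol between species; the package quantifies similarity but cannot
  correct for tissue effects.
* The A/B labelling is an internal convention anchored to the reference;
  mapping it onto the biologically active compartment requires an external
  covariate not used here.
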