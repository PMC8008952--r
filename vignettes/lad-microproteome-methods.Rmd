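---
title: "Methods: LAD calling and nuclear-periphery micro-proteome analysis"
author: "ladkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LAD calling and nuclear-periphery micro-proteome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ladkit)
```

## Scope

`ladkit` implements the computational core of a nuclear-periphery
micro-proteome study: calling lamina-associated domains (LADs) from DamID-seq
fragment counts, quantifying proximity-biotinylation (BioID/BioSITe) site
tables into protein-level enrichment calls, integrating protein sets from
several interactome studies into interface "zones", and the genomic interval
statistics used to cross-validate proteomic hits against chromatin maps.
Everything upstream of these steps — read alignment, peptide-spectrum
matching and FDR control, ontology enrichment — is out of scope; the package
consumes the standard exported tables (BED intervals, site-level TSVs,
protein FASTA).

Because the deposited datasets of any particular study are external inputs,
the package ships a first-class synthetic-data module that generates every
input with known ground truth, so the complete pipeline is exercised and
verified without network access.

## DamID scoring and LAD calling

DamID marks DNA near a Dam-methyltransferase fusion protein at GATC motifs;
the unit of quantification is the DpnI restriction fragment, the interval
between consecutive GATC cut sites.

**Fragment map.** `scan_gatc_sites()` finds every literal GATC
(case-insensitive; `N` never matches, as DpnI recognises the exact
sequence), and `build_fragment_map()` places cuts at motif start + 2 — the
enzyme's true blunt GA^TC position. The cut offset is a convention: any
consistent choice shifts all bins by at most 2 bp. Terminal sub-fragments at
chromosome ends are retained as bins, and a motif-free chromosome is a
single bin. Coordinates are 0-based half-open internally and BED on disk.

**Counting.** `count_reads_per_fragment()` assigns each aligned read to
every fragment it overlaps by at least one base, so a read straddling a cut
site counts toward both neighbours. The library size is the number of input
reads, not the column sum.

**Scoring.** `compute_damid_scores()` forms per-fragment
`log2(fusion / control)`. Rules, in order:

* fragments overlapping an optional mask (e.g. unalignable regions) are
  missing;
* fragments with zero reads in *both* samples are missing — never an
  accidental score of 0;
* with `normalize = TRUE` (default) counts are scaled to reads per million
  before the ratio, since unequal sequencing depths otherwise bias every
  score; a flag disables this for the literal ratio of raw counts;
* a raw zero in exactly one sample is replaced by the 0.5 pseudocount
  (after scaling, on the raw-zero side);
* by default scores are then centred on the genome-wide mean
  (`center = "mean"`). The zero point of the raw log-ratio depends on the
  relative read composition of the two libraries — a fusion library that
  spends a larger share of its reads inside target regions shifts every
  score — so "positive signal" is only well defined relative to the
  genome-wide average. Centring also makes the degenerate signal-free case
  exact: a chromosome with no real signal segments into a single zero-mean
  segment and yields no LADs. `center = "none"` reproduces the plain ratio.

**Segmentation.** `segment_scores()` partitions each chromosome into
constant-mean segments by recursive binary splitting in the spirit of
circular binary segmentation: the candidate split maximising the two-sample
partial-sum statistic

$$ T(i) = \frac{|S_i - \tfrac{i}{m} S_m|}{\hat\sigma\sqrt{i(m-i)/m}} $$

is accepted iff its permutation p-value is below `alpha` (default 0.01),
and accepted splits are recursed. Because $\hat\sigma$ and $\sqrt{m}$ are
invariant under permutation, the implementation compares the squared
unscaled statistic, which changes no decision. Up to `n_perm` (default
10,000) seeded Fisher–Yates permutations are drawn per tested split, with
sequential early stopping in both directions: testing stops as soon as the
exceedance count proves p ≥ alpha, and stops early *accepting* at interim
checkpoints (500/1,000/2,000/5,000 permutations) when the 99.9% upper
confidence bound on the permutation p-value is already below alpha. A clear
changepoint therefore costs roughly 1,000 permutations rather than 10,000,
with a decision identical in distribution to the full test at the stated
confidence. Ties between equally good splits resolve to the leftmost.
Missing fragments are skipped in all statistics and inherit the enclosing
segment afterwards (a missing run between two segments attaches to its
left). The whole procedure is deterministic given the seed.

**Classification.** `call_lads()` maps positive segments (mean score
strictly above zero, with a 1e-9 numerical tolerance so a centred
zero-mean segment never counts as positive) to genomic intervals, merges
consecutive positive intervals across negative spans shorter than `max_gap`
(default 10 kb; a single left-to-right pass reaches the fixpoint because
merging is associative), and keeps merged regions of at least `min_lad`
(default 100 kb, inclusive — "100 kb or greater"). LAD boundaries always
lie at outermost positive-segment edges.

The defaults (alpha 0.01, 10,000 permutations) are conventional
segmentation settings rather than values tied to any particular dataset;
both are configuration keys, as are the length and gap thresholds.

## Biotinylation-site quantification

BioSITe yields one row per biotinylated-peptide observation with a
site-resolved position and an MS1 intensity. `summarize_proteins()` sums
abundance per protein/condition/replicate and counts distinct sites
(identity `(protein_id, site_pos)`, so peptides sharing a lysine collapse).

`compute_enrichment()` computes one numerator/denominator ratio per
replicate and averages them arithmetically — "average ratio between
replicates" — rather than averaging abundances first; the alternative
(`method = "ratio_of_means"`) and a geometric mean are provided behind
flags because the two readings are both defensible. A protein missing from
the denominator in a replicate would yield an infinite ratio; its
denominator is instead imputed as the smallest positive abundance observed
in that replicate of the denominator condition (a detection-floor argument)
and the protein flagged `imputed`. Proteins quantified in a subset of
replicates are averaged over the available ones with `n_replicates`
reported; proteins absent from the numerator entirely are excluded with a
note. Enrichment is strict (`mean_ratio > threshold`); the conventional
thresholds are 2.0 for a bait-versus-tracer comparison and 1.6 for a
+shield/−shield comparison, and enriched sets are monotone in the
threshold by construction.

`degree_of_biotinylation()` ranks proteins by biotinylated lysines over
total lysines in the sequence — a proximity/abundance ranking in [0, 1] —
with deterministic lexicographic tie-breaks. Integrity failures (site
beyond the sequence, non-lysine at the stated position, protein missing
from the FASTA) remove only the affected protein and are reported as error
records. `map_site_topology()` places each site into the annotated
topological domain containing it (`unannotated` / `unassigned` for absent
annotation or gaps; overlapping domain annotations are rejected; a site
beyond the annotated span errors by default).

## Zone integration

`normalize_symbols()` uppercases and trims symbols and applies an optional
alias table, because interactome studies mix species casing and synonyms
and rarely state their matching rule. `meta_laminome()` applies the
observed-in-k-of-n rule (default 3). `assign_zones()` partitions the
universe: zone 1 = (laminome ∪ bait interactome) \ LADome (lamina-only),
zone 2 = LADome ∩ (laminome ∪ bait) (the "middlemen" interface), zone 3 =
LADome only, `none` = the rest. The partition property is asserted on every
run. The universe defaults to the union of the inputs unless supplied
explicitly. Published overlap counts depend on the original deposited
lists, which users must supply as inputs; the package ships a 12-protein
worked micro-fixture (`inst/extdata/zones/`) instead.

## Interval statistics

`interval_set()` merges inputs before any arithmetic so self-overlapping
BED files cannot inflate coverage; all features are unstranded.
`base_coverage_overlap()` reports the percentage of each set's bases inside
the other. `peak_fraction_within()` uses the midpoint rule by default
(midpoint of [start, end) is base `floor((start+end)/2)`), with
`any_overlap` as the alternative, since "peaks residing within" a domain is
otherwise ambiguous.

`boundary_profile()` anchors half-open offset bins `[o, o + step)` at both
boundaries of every region at least `min_region` long, mirroring right-hand
boundaries so positive offsets always point into the region; the anchor
sits at offset 0 on the inside edge. Bin values are base-weighted track
means, and each offset averages over the anchors that have data there, so
windows running off a chromosome contribute only in-bounds bins.
`anchor_profile()` is the unmirrored point-anchor variant. Default flank
and step (100 kb / 10 kb) match the ±100 kb axes customary for LAD boundary
plots.

## Synthetic data: what it emulates and what it does not

The generators (`simulate_genome()`, `plant_lads()`,
`simulate_damid_counts()`, `simulate_biosite_table()`,
`simulate_peaks()`) are pure functions of a validated
`sim_config()`; each sets the RNG internally (with a small fixed offset per
generator) so every stage is independently reproducible, and truth objects
are always returned or written beside the data.

Default study conditions are a mouse-like scale-down: one 10 Mb chromosome
with a GATC roughly every 250 bp (the random background is scrubbed of
accidental GATCs so motif density is governed by the configured rate, and
the truth is a fresh scan of the final sequence); 15 planted LADs of
100–500 kb with at least 100 kb spacing; Dam-fusion counts at 4-fold
enrichment inside LADs over a mean depth of 10 reads per fragment, Poisson
by default with a negative-binomial option (real DamID is overdispersed);
a 500-protein site table with 50 proteins planted at 3-fold enrichment
under multiplicative log-normal noise (sd 0.2) across duplicate
replicates; and 500 peaks placed to hit a target midpoint-in-region
fraction of 0.8.

Under these conditions the pipeline recovers planted LADs with
base-coverage Jaccard above 0.99 and boundaries within two fragments, and
planted enrichment with recall ≥ 0.98 at zero observed false discoveries
(see `tests/testthat/test-acceptance.R` and `scripts/acceptance.R`, which
recompute these quantities from scratch).

What passing these tests does *not* show about real data: the generators
draw independent counts per fragment (no PCR duplication structure, no
mappability or GC bias, no Dam expression-level artifacts, no fragment-size
effects), plant LADs with hard boundaries (real LAD borders are gradual and
cell-to-cell variable), and draw site abundances independently across
proteins (no shared-peptide ambiguity, no missingness correlated with
abundance as in real MS). Recovery rates on real libraries will be lower
and parameter choices (alpha, minimum LAD size, fold thresholds) matter
more than they do here.

## Numerical choices and degenerate inputs

* Zero-count handling: pseudocount 0.5 replaces a raw zero in exactly one
  sample; both-zero and masked fragments are missing, and
  scored + missing always equals the fragment count.
* Segment positivity uses a 1e-9 tolerance around zero; exact-zero-mean
  segments are non-positive.
* Segmentation of fewer than two scored fragments returns a single
  segment; an all-missing chromosome is skipped with a warning.
* Tiny segments (m = 2–3) can never reach permutation significance at
  alpha = 0.01 and are therefore never split, which acts as an implicit
  minimum segment width.
* Empty interval sets give `NA` overlap percentages with a warning rather
  than silent zeros; empty peak sets are an error.
* The profile bin at an offset with no covered bases is excluded from the
  anchor average rather than treated as zero.

## Problem sizes

The shipped test-suite and acceptance runs use the default 10 Mb / ~40,000
fragment chromosome for the end-to-end LAD study, 1 Mb genomes for
generator unit tests, toy chromosomes of ≤ 10 kb wherever a per-base
brute-force oracle is the comparator, and the default 500-protein site
table. These sizes were chosen so each stage remains large enough to
exhibit its statistical behaviour (tens of segments, hundreds of planted
positives) while a full verification run completes in minutes on a laptop.
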