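---
title: "Methods: enriched amplicon concatemer sequencing in concatseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enriched amplicon concatemer sequencing in concatseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(concatseq)
```

## The assay, computationally

`concatseq` models a targeted nanopore assay in which (1) blocker
displacement amplification (BDA) enriches variant alleles before sequencing,
and (2) short amplicons are ligated into long concatemers through a universal
junction adapter so that a single nanopore read carries many amplicon copies.
The package implements everything downstream of basecalling — and, because
public raw data cannot be assumed available at development scale, everything
upstream too, as a first-class simulator whose ground truth every pipeline
stage is tested against.

## Enrichment model

Enrichment is modelled as a single terminal fold `E` acting multiplicatively
on allele *odds*:

$$\mathrm{VRF}(v, E) = \frac{E\,v/(1-v)}{1 + E\,v/(1-v)}$$

with `v` the sample VAF. This form was chosen over a linear `VRF = E·v`
because a linear ratio cannot saturate as VRF approaches 1, while the odds
form is self-inverse: `estimate_vaf(enriched_fraction(v, E), E) = v` exactly,
which the test suite asserts to 1e-9 over random `(v, E)`. A per-PCR-cycle
amplification model is deliberately excluded: the assay is characterised only
by its terminal fold, calibrated per locus from spike-ins of known VAF as the
odds ratio of observed VRF to known VAF (geometric mean across replicate
records; records with VAF = 0 or VRF = 1 are excluded as infinite odds).
Estimation refuses to guess when a locus has no calibrated fold.

Saturation: above `saturation_vrf` (default 0.90) the wildtype remainder is
comparable to the sequencing error rate and the back-calculated VAF is
unreliable, so the locus is flagged saturated and classified high-VAF (> 5%)
irrespective of the calculated value. Multi-nucleotide indels enrich more
strongly than the substitutions used in calibration, so their estimates carry
an informational over-estimation caveat (`indel_caveat`).

## Synthetic data generator

`simulate_sample()` emulates, in order:

* **the post-enrichment amplicon pool** — each monomer is a full copy of a
  uniformly chosen panel amplicon; each configured variant is present with
  probability `enriched_fraction(vaf, E)`; strand is +/- with probability 1/2.
  Variants must lie in the blocker-covered enrichment region (a variant under
  a primer cannot be enriched and is rejected).
* **concatemer assembly** — `adapter + monomer (+ junction + monomer)^(k-1)`,
  with `k` drawn from a truncated geometric distribution on 1-40
  reparameterised by its mean (default 13.5, the centre of the 12-15 range
  that capillary electrophoresis shows for this chemistry; the distribution
  family is a modelling choice, since only the mean range is known). Monomers
  are sampled uniformly with replacement — stochastic incorporation without
  regard to amplicon identity.
* **nanopore-like errors** — independent per-base substitution / insertion /
  deletion events, defaults `(0.035, 0.015, 0.02)` summing to 0.07, the
  concatemer-read error regime (phred ≈ 11.5); monomer-style reads would sit
  near 0.10. Deletion probability is multiplied by 3 inside homopolymer runs
  of length ≥ 3 — elevated homopolymer deletion error is well documented for
  this platform but unquantified, so the multiplier is a package default, not
  a measured value. Emitted qualities are constant at the phred equivalent of
  the total configured rate, which lets the caller recover the error-rate
  parameter from the data itself.

What the simulator does **not** emulate: signal-level artefacts, chimeric or
off-target amplicons, PCR stochasticity at low template counts, strand bias,
and context-dependent substitution spectra. Passing tests therefore
demonstrate the pipeline's correctness and its behaviour under the stated
error regimes, not performance on real flow-cell data.

All randomness flows from a single integer seed; the pipeline derives
per-stage substreams deterministically, and identical config + seed gives a
byte-identical call table.

## Deconcatenation

Junction hits are approximate occurrences of the adapter (both orientations)
under a bit-parallel Myers edit-distance scan, budget
`max_edit_fraction = 0.25` of the adapter length: at 7-10% read error a
20-24-mer adapter carries 1.4-2.4 expected errors, so a quarter-length budget
retains sensitivity while random 24-mers sit far away in edit distance.
Overlapping candidates are resolved greedily (lowest edit distance, then
leftmost start) rather than by optimal interval scheduling — hits are sparse
and separated by monomer length. Segments between consecutive hits shorter
than `min_segment_length` (default half the shortest panel amplicon) are
dropped as uninformative; base counts are conserved exactly
(`segments + junction spans + dropped = input`). The implementation requires
the full junction sequence, not just the 4-nt sticky end: a 4-mer is
unmatchable at these error rates, which is also why adapters shorter than
10 nt are rejected. Segments are not strand-normalised here; orientation is
resolved at alignment.

The panel generator rejects amplicon sequences containing a near-match to the
adapter (edit distance ≤ budget + 2 in either orientation) — the biological
analogue is that an internal restriction/adapter site would be destroyed
during assembly — which makes deconcatenation of error-free reads exactly
recoverable, a property the tests assert.

## Alignment and pileup

Segments are assigned by a shared-11-mer screen over (amplicon, strand) pairs
and then aligned with an affine-gap Gotoh aligner (match +2, mismatch −4, gap
open −4, extend −2 per base — nanopore-typical) that is end-free in both
sequences: segments may be truncated at junctions, so unaligned reference
flanks cost nothing. Minus-strand segments are aligned as their reverse
complement, keeping all coordinates in forward amplicon space. Three guards
make assignment conservative: score ties across two amplicons discard the
segment as ambiguous (the pseudogene cross-mapping failure mode); alignment
identity < 0.7 is reported unaligned; and alignments covering < 50% of the
segment are rejected (random sequence can otherwise produce short
high-identity overlaps under end-free scoring). On score ties the traceback
prefers consuming the reference over trailing gap runs, the textbook
canonical alignment, so the pileup matches an independent aligner's
per-column tally exactly on substitution-only reads.

Pileup semantics: matches and substitutions increment base counts at
reference positions; a deletion increments the deletion count at every
deleted reference position; an insertion increments an insertion-after count
**once per event** at its anchor position (a per-position variant table
cannot meaningfully count a 3-base insertion three times). Depth is
`A + C + G + T + del`, asserted as a column-conservation invariant.

Downsampling retains a uniform random subset of `max_depth − 1` segments per
amplicon whenever the cap would otherwise be reached (coverage strictly below
150x by default — the regime the score gate was tuned for, since
high-coverage pileups inflate confidence against a whole-genome-trained
caller's expectations). It operates on segments, not pileup columns, so the
score gate and the VRF see exactly the same reads. In `run_pipeline()` the
cheap k-mer classification feeds downsampling and only retained segments get
the full alignment; at ~1.4e5 monomer segments per 10,000-read sample this is
what keeps a sample at a few seconds without changing what the pileup sees.

## Calling

The per-position VRF is the highest-frequency single-base change (three
substitutions in alphabetical order, then insertion, then deletion — the tie
order is fixed and documented because it is otherwise unspecified). A call
requires **all** of: VRF ≥ 0.20 (inclusive — the threshold is stated as
"≥ 20%"), confidence score ≥ 180, coverage ≥ 50x, position inside the
enrichment region (primer-region variants are structurally unobservable after
enrichment), and not blacklisted. Near-miss loci stay in the table with
per-gate flags.

The default score provider maps a binomial log10 likelihood ratio (observed
fraction vs an error null) onto 0-999 with scale factor 45, chosen so the
gate value 180 is attainable exactly at the stated operating floor (VRF 0.2,
depth 50, error 0.1). The null for a specific substitution is `e/3`; for
indels at homopolymer runs of length L ≥ 3 the deletion null is inflated by
`3·L` (rate inflation × the alignment's canonical gap placement concentrating
L positions' deletions onto one column) and the insertion null by `L`. That
locus awareness is the essential service an ML-based external caller provides;
without it, homopolymer deletion pileups at 7% error score as confident
variants. The provider is pluggable — any function of (count, depth), or an
explicit score table parsed from an external caller's VCF — reflecting that
the score gate is a replaceable component.

ΔVRF mode subtracts a matched normal: for each position the normal's VRF *of
the tumor's top variant* is subtracted, and a z-score is computed against the
leave-one-out median and scaled MAD of ΔVRF over unmasked positions. Robust
statistics are used because top-variant VRFs are heavy-tailed at
homopolymers; whether the original σ construction was global or per-position
is not stated anywhere, so the global leave-one-out form is the documented
default.

## Concordance and benchmarking

The assessed universe is every enrichment-region position × sample;
`concordance()` errors on calls outside it rather than letting denominators
drift. Comparator positivity in NGS mode is strict `VRF > 5%` at `≥ 80x`.
Precision-recall curves sweep the calculated-VAF cutoff over all distinct
estimates with saturated loci ranked above every finite estimate (they are
high-VAF calls at any cutoff); AUC is the trapezoid over recall anchored at
recall 0 with the highest-cutoff precision — the integration rule is stated
here because conventions differ. A depth-stratified discordance histogram
(configurable bins, default width 100) localises comparator-negative /
assay-positive loci to low comparator depth.

## Problem sizes and test design

The test and acceptance workloads use: 2,000 simulated concatemers (~27,000
monomers) for deconcatenation recovery; 10,000 concatemer reads per sample
(the analysis read cap default) for limit-of-detection sweeps over spike-ins
at 0.05-1% VAF with E = 1000, 20 seeds per condition plus pure-wildtype
controls; 1,000 random pairs for the enrichment round trip; and 20 segments
for exact pileup-oracle comparisons against `Biostrings::pairwiseAlignment`.
The oracle comparison uses substitution-only corruption so the optimal
alignment is unique and agreement must be exact; indel pileup semantics are
pinned by hand-constructed cases instead.

## Known limitations

* VAF quantitation has a narrow dynamic range by construction: near
  saturation, large VAF differences map to tiny VRF differences (hence the
  saturation rule), and indel folds are overestimated relative to
  substitution-calibrated folds.
* The default score provider is a deliberately simple binomial LLR; it
  encodes homopolymer nulls but none of the signal-level context an ML caller
  uses. The provider interface exists precisely so a stronger caller can be
  substituted.
* Panels are limited to 32 amplicons (classification bitmask); amplicon-space
  alignment assumes panel amplicons are the only plausible sources of
  segments — off-target products are only handled by the identity and
  aligned-fraction guards.
* The simulator's iid error model understates the clustering of real
  nanopore errors; recovery and LoD results on simulated data are therefore
  upper bounds on real-data performance.
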