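---
title: "Methods: de novo enhancer gain detection from sequence trios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: de novo enhancer gain detection from sequence trios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its models, its numerical
choices, and what its synthetic benchmarks do and do not demonstrate.

## The trio model of enhancer gain and loss

The unit of analysis is a 1-kb enhancer: an H3K27ac peak extended to
1 kb from its centre (`make_enhancers()`), with windows overlapping any
promoter — the ±1000 bp around every supplied TSS, alternative TSSs
included — removed.  The centre of an even-width peak is
`floor((start + end)/2)`, a deterministic tie-break; windows running off
a chromosome end are clamped, flagged, and dropped by default, because
downstream stages assume the fixed 1-kb width.  All interval arithmetic
is 0-based half-open (BED convention); positions *within* a sequence
are 1-based, the natural R string convention.

Orthologs are consumed as precomputed mapping tables
(`pair_orthologs()`): only reciprocal pairs whose lengths differ by at
most 50 bp are retained; conflicting duplicate mappings are dropped
outright.  Aligned pairs yield one substitution record per mismatching
non-gap column (`extract_mutations()`); gap columns yield nothing,
because the mutation model is strictly single-nucleotide.

Classification (`classify_status()`) combines peak evidence with model
scores in human (h), macaque (m) and the reconstructed ancestor (a):

* **gained**: human peak, s_h ≥ t, no macaque peak, s_m < t, s_a < t;
* **lost**: macaque peak, s_m ≥ t, s_a ≥ t, no human peak, s_h < t;
* **conserved**: peaks in both species and min(s_h, s_m, s_a) ≥ t;
* otherwise **ambiguous**.

"Active" is `score >= t` and "inactive" is strictly below the same
threshold — one cutoff, split at ≥, mirroring how a single published
threshold (0.197 at FPR 0.1) is used for both directions.  A trio
without an ancestor score is always ambiguous: the ancestor is what
distinguishes a human gain from a macaque loss, and guessing without it
would silently change the meaning of the call.

## The convolutional activity scorer

`enhancer_cnn()` fits a 1-D convolutional network on one-hot encoded
sequence (channel order A, C, G, T; `N` becomes 0.25 in every channel).
Each convolution is valid (length `L - w + 1`) with ReLU, followed by
non-overlapping max pooling with floor division; a dense ReLU layer and
a single sigmoid output complete the model.  The implementation is
plain base-R matrix algebra (im2col convolutions, Adam on binary
cross-entropy), which keeps the scorer dependency-free and exactly
reproducible under a seed.

Data splitting is by chromosome: chr8 and chr9 are held out for
testing, chr6 is the validation set driving early stopping, everything
else trains.  Every training sample is presented in both orientations
(sequence and reverse complement).  At inference the score is the
average of the forward and reverse-complement outputs, which turns the
orientation convention into an exact, testable invariance:
`score(s) == score(revcomp(s))` for every input.

Training hyperparameters are not part of the published architecture
description, so they are package defaults, documented here: Adam with
learning rate 0.01, batch size 64, at most 15 epochs, early stopping
after 4 non-improving validation epochs, He initialisation, zero
biases.  The desk-scale default architecture is two convolution layers
(32 kernels of width 11, then 32 of width 7), max-pool 4 after the
first layer and a *global* max pool after the second, a 32-unit dense
layer, and 200-bp input.  The global final pool matters: motif
occurrence is position-free evidence, and pooling positions away before
the dense layer is what lets a few thousand training sequences suffice.

Problem sizes in the test suite — 2,000 positive plus 2,000 negative
200-bp sequences, 200 synthetic trios, 1,000 neutral-simulation
replicates — were chosen as the smallest sets on which the respective
checks are statistically meaningful, and they keep the whole suite to a
few minutes on one CPU.

### The full-scale reference architecture

The full-scale network is described by its kernel counts
(320/320/240/240/480), its 180-unit dense layer, its 1000-bp input and
its trainable-parameter total, 3,631,401 — but not by its kernel
widths, pool sizes or output-unit count.
`solve_reference_architecture()` closes that gap with a deterministic
constraint search: kernel widths 2–26, pool sizes 1–8, output units 1–2
are enumerated lexicographically and the first configuration whose
parameter count matches the target exactly is returned.  Parameter
counting (`count_parameters()`) is closed-form — per conv layer
`in_channels * width * kernels + kernels`, dense
`flat * units + units`, output `units * out + out` — and is verified in
the tests against the instantiated network's own weight-array totals.
Two output units turn out to be infeasible for the reference target
(the residual violates a divisibility constraint of the parameter
arithmetic), so the reference model ends in a single sigmoid unit; the
frozen solution is `reference_config()` (widths 3/4/4/2/4, pools
1/1/1/5/7, flattened length 11).  Every retrained model recalibrates
its own activity threshold at FPR 0.1 via `calibrate_threshold()`; the
printed 0.197 belongs to the original full-scale model and data and is
never hard-coded.

`calibrate_threshold()` returns the smallest observed negative score
such that the fraction of negatives at or above it does not exceed the
target FPR.  When every candidate is too permissive (e.g. all negatives
share one score) the threshold is placed just above the maximum so that
nothing passes — the conservative resolution of a degenerate input.

## Essential mutations and minimal activating sets

`single_mutation_effects()` requires an inactive starting sequence
(otherwise "essential" is undefined and the function refuses), applies
each human allele alone, and calls a mutation essential when the edited
score reaches the threshold.  `find_minimal_activating_set()` sweeps
m = 1, 2, …: all `choose(n, m)` combinations are evaluated when that
number is within the cap (default 10,000); otherwise exactly `cap`
distinct combinations are sampled without replacement — by sampling
combination ranks and unranking them lexicographically when the space
is indexable, by rejection with deduplication when it is not.  Among
activating combinations of the minimal size, the largest score change
wins; remaining ties resolve by lexicographic position order.  Two
consistency properties are enforced by tests: applying all n alleles
reconstructs the human sequence exactly (string equality, and the full
delta equals `score(human) − score(macaque)` exactly), and for n ≤ 12
with the cap disabled the search agrees with brute-force enumeration.
The mirrored direction, `deactivating_essential()`, asks whether a
single variant drops an active sequence below threshold — the form used
for de novo variants in active enhancers; a full minimal-deactivating
search for lost enhancers is intentionally not implemented.

## Allelic imbalance

Replicates are merged by summing allele counts per site
(`merge_replicates()`; summation is associative, so replicate order is
irrelevant).  `call_imbalance()` then applies an exact binomial test at
p = 0.5 to the human-allele count out of the site total.  A site is
imbalanced when total ≥ 6, human:macaque ratio > 1.3 (strict; a zero
macaque count is an infinite ratio and passes), and p ≤ 1e-3.  The test
is two-sided by default — the conservative reading where the direction
requirement is supplied by the ratio filter — with a `"greater"`
alternative available as a flag.  Class-level enrichment
(`imbalance_enrichment()`) reports per-class imbalance fractions and
Fisher tests against the preserved-enhancer background.

## Selection statistics

`dos()` computes `Dn/(Dn+Ds) − Pn/(Pn+Ps)` on a contingency of fixed
versus polymorphic sites, foreground versus a fourfold-degenerate
background (`fourfold_sites()` identifies third-codon positions of
fourfold codon families under the standard genetic code, table-driven
so alternative codes could be added).  Fixed/polymorphic status is an
input column: it comes from population data upstream and the statistic
layer does not re-derive it.  Both margins must be positive; a zero
margin is an error, not a silent NaN.

`daf_compare()` is a rank-sum comparison of derived allele frequencies.
For combined samples of at most 20 the null distribution is enumerated
exactly over all group assignments — a permutation formulation chosen
deliberately because the classical exact rank-sum tables cannot handle
ties, while tied frequencies are routine in small DAF sets.  Larger
samples use the normal approximation with tie correction.

## Motif scanning, TF roles and the network

PWMs score windows by base-2 log-odds against the background after a
1e-3 per-cell pseudocount (renormalised), so zero probabilities stay
finite.  Both strands are scanned; the reverse strand reuses the
forward pass with a reverse-complemented score matrix, which makes
strand symmetry exact.  `calibrate_pwm_threshold()` fixes each motif's
threshold as the smallest observed score keeping the hit rate on ≥100
kb of background sequence at or below 5 per 10 kb (both strands
counted); a motif too degenerate to ever meet the budget gets a
beyond-maximum threshold and simply never fires.

A substitution is a binding-site *gain* when a hit overlaps the
position under the human allele but not the macaque allele, a *loss* in
the converse case (`site_gain_loss()`).  `classify_tf_role()` calls a
TF an activator when its essential-mutation gain:loss ratio exceeds 1.2
times the common-SNP ratio, a repressor for the loss:gain direction;
all four counts take a 0.5 pseudocount (Haldane–Anscombe) so empty
cells stay finite.

The published network construction states only that an edge reflects
"enrichment of motif density" in gained versus conserved enhancers near
the target gene; the decision rule itself is under-determined.
`build_network()` therefore uses explicit, configurable defaults:
density = hits per kb aggregated over the target's enhancers, edge if
the fold enrichment is ≥ 1.5 *and* a one-sided binomial test of the
foreground hit count at the background per-bp rate (0.5 pseudo-hit)
gives p ≤ 0.05.  Self-edges are allowed (autoregulation), and
`hierarchy()` counts a self-edge in both degrees; the master regulator
is the maximal out-degree TF with lexicographic tie-break.

## The synthetic-data generator

`sim_config()` fixes the study conditions the pipeline assumes: 1-kb
enhancers, a mean of 50 human–macaque substitutions per kb (Poisson
counts), 30× read depth and a 4:1 allele ratio at truly imbalanced
sites, and sharp built-in 8-mer motifs (94% dominant base) whose
thresholds sit at 80% of their maximal score — high enough that a
consensus match passes and *any* single-base mismatch fails, which is
precisely what makes planted essential mutations exactly recoverable.

`simulate_trio()` builds each scenario constructively: for a gain, the
ancestor and macaque carry the motif broken at its most informative
position (lowest-entropy row, first on ties, replaced by its least
likely base) and the human sequence restores the consensus through one
designated substitution; losses mirror this; conserved trios carry the
intact motif in all three genomes; neutral trios carry none.  All other
substitutions land outside the motif footprint, each assigned to the
human or macaque lineage with probability one half.  Every generated
trio is verified by a motif scan — against *all* configured activator
motifs for the absence conditions — and regenerated on failure, so the
ground truth is exact rather than probabilistic.  Background sequence
is i.i.d. uniform ACGT; enhancer signal, where needed, uses log-normal
noise (`simulate_signal()`), a stand-in chosen because no noise model
for the intensity data is published.

What passing these benchmarks shows: the pipeline's logic — planting,
scoring, classification, mutagenesis search, the statistics — is
internally consistent and recovers known truth without noise.  What it
does not show: performance on real epigenomic data, where motifs are
degenerate, activity is combinatorial, alignment and mapping errors
exist, and H3K27ac is a noisy proxy.  The generator deliberately omits
indels, phylogenetic structure beyond a three-node star, read-level
artifacts (mapping bias, duplicates) and inter-motif interactions.

## Known limitations

* The scorer is a compact CNN; it reproduces the architecture *family*
  and the full-scale parameter count, but no claim is made that a
  desk-scale model trained on synthetic data matches published
  real-data accuracy.
* Lost enhancers get the single-variant deactivation test, not a full
  minimal-deactivating-set search.
* The network edge rule and several test thresholds (coexpression 0.3,
  enrichment 1.5) are explicit defaults standing in for unpublished
  choices, and are parameters, not constants.
* Percentage reporting rounds half away from zero, so printed fractions
  are bit-stable; one published count/percent pair (2246 of 2925 at the
  occipital time point) is internally inconsistent by this arithmetic
  and recomputes to 76.8%.
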