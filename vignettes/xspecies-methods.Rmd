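---
title: "Cross-species microarray analysis with gDNA probe masking: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species microarray analysis with gDNA probe masking: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xspecies)
```

## The problem

Expression profiling of a species without its own microarray platform can
borrow a chip from a related model organism — a heterologous, or
*cross-species*, hybridization. The price is sequence divergence: a 25-mer
probe that mismatches the target transcript binds weakly or not at all, so a
probe-set summarized over all of its probes mixes informative with
uninformative measurements.

The remedy implemented here is genomic-DNA-based probe masking. Genomic DNA
of the target species is hybridized to the chip once; because every gene is
present in gDNA at equal copy number, the gDNA signal of a probe measures how
well that probe can bind target sequence at all. Probes whose mean gDNA
signal does not exceed a threshold are discarded (*strict* `>`; ties at the
threshold drop), and a probe-set is kept only if at least two of its
probe-pairs survive. The threshold itself is chosen empirically: the
expression pipeline is run across a sweep (0 to 500 in steps of 25) and the
threshold that maximizes the differential-expression yield wins, with ties
resolved to the smallest threshold (the largest retained chip).

All computations operate on plain TSV stand-ins for the binary CEL/CDF
containers: the methods are agnostic to container format and desk-scale
testing needs human-readable fixtures. PM probes carry the analysis; MM
probes travel in the data model but are unused, since the summarization is
PM-only.

## The synthetic study generator

Every stage is validated against simulated cross-species hybridizations with
known ground truth. Per probe *i* of probe-set *s*:

* probe affinity `a_i ~ Normal(0, sd 0.5)` on the log2 scale, shared across
  arrays (affinity is a sequence property; median polish absorbs it);
* divergence indicator with probability `divergence_fraction`; a diverged
  probe's linear-scale binding is multiplied by `attenuation` in **both**
  gDNA and RNA hybridizations — the shared probe/target mismatch that makes
  gDNA masking informative about RNA measurements;
* probe-set abundance `mu_s ~ Normal(0, 1)`; a planted log2 fold change
  `delta_s` (magnitude `de_log2fc`, half up / half down) in a fraction
  `de_fraction` of probe-sets;
* per-measurement log-scale noise `eps ~ Normal(0, noise_sd)`;
* hybridization signal `2^(baseline + mu_s + delta_s + a_i + eps) * b_i`
  (RNA) or `2^(gdna_level + a_i + eps) * b_i` (gDNA).

The **measured** intensity adds an optical background:
`X = S + B`, `B ~ Normal(optical_bg_mean, optical_bg_sd)` truncated at zero
and drawn fresh per probe and array. This additive component is essential,
not cosmetic. It is exactly the convolution model the RMA background
correction assumes, and it is what makes a weakly hybridizing probe
*uninformative* rather than merely dim: once the attenuated signal falls
below the background level, the fold change is no longer measurable on that
probe and its log-scale measurement error explodes. Without it, a constant
multiplicative attenuation is absorbed entirely by the median-polish probe
effects, diverged probes remain fully informative, and masking could never
improve the analysis — the method's premise would be untestable.

Defaults describe the emulated design: 1000 probe-sets of 11 probe-pairs, one
gDNA array, a triplicate of RNA arrays per ripening stage (unripe, ripe),
40% divergence, attenuation 0.1, 10% DE at one log2 unit, noise sd 0.2,
baseline and gDNA level 2^8 ~ 256 units, background 50 +/- 15 units — chosen
so that conserved probes sit well above background and attenuated probes
inside it, as on a real heterologous chip. What the generator does **not**
emulate: spatial chip artifacts, saturation, MM cross-hybridization,
sequence-dependent (GC) affinity, and correlated probe failure. Passing
tests therefore demonstrate correctness of the algorithms under the stated
generative model, not performance on any real chip.

## Mask-aware RMA

Summarization follows the robust multichip average in three stages over the
retained PM probes.

**Background correction.** Under `X = S + B` with `S ~ Exponential(alpha)`
and `B ~ Normal(mu, sigma^2)`, the corrected intensity is the posterior mean
`E[S | X = x] = a + sigma * phi(a/sigma) / Phi(a/sigma)`,
`a = x - mu - sigma^2 * alpha`: strictly positive, strictly increasing, and
verified in the tests against direct numerical integration of the
convolution density. Parameters are estimated per array by a deterministic
mode-based procedure: the kernel-density mode of a normal + exponential
mixture sits `sigma * z` above the background mean, where
`phi(z)/Phi(z) = sigma * alpha`, so the estimator alternates between the
left-of-mode spread (`sigma`), the reciprocal mean excess (`alpha`) and that
mode correction (three sweeps suffice). Two points matter in the masked
setting:

* the model is estimated from the array's **complete** intensity table and
  then applied to the retained probes. Background is a property of the
  array; a heavily masked chip no longer contains the background-dominated
  probes the estimator needs, and estimating on the retained subset mistakes
  the signal mode for background.
* correction is a toggle (default on). On data simulated without an optical
  background the correction has nothing to remove, and noiseless identity
  checks run with it off.

**Quantile normalization.** Standard sort–average–assign across arrays, ties
resolved by stable sort order of the probe index for reproducibility (via
`limma::normalizeQuantiles(ties = FALSE)`). Idempotent to 1e-12. It is a
between-array method: when the two conditions genuinely differ in
distribution it perturbs group differences slightly, which is why the exact
noiseless recovery check isolates the summarization step with normalization
off, and why normalization is also a toggle.

**Median polish.** Tukey's alternating removal of row (probe) and column
(array) medians on the log2 matrix of each probe-set, row sweep first, with
expression = overall + column effect. Iteration runs to convergence of the
absolute-residual total (relative tolerance 1e-10 inside `stats::medpolish`,
cap 500 sweeps) rather than a fixed small sweep count: on random matrices a
10-sweep cap routinely leaves residual medians near 1e-2. With an odd number
of probes (the chip's 11) the algorithm reaches a true fixed point with
residual row/column medians below 1e-6; with an even number it can finish on
a two-cycle because medians of even-length vectors are interval midpoints —
the summaries remain well defined. Log2 of corrected intensities is floored
at `2^-20`.

## Differential expression and mask optimization

For two conditions with at least two replicate arrays each, the per-set fold
change is the difference of group means on the log2 scale and the raw p-value
comes from a pooled-variance one-way ANOVA F-test (identical to the
two-sided equal-variance t-test for two groups; the vectorized implementation
is cross-checked against `stats::oneway.test`). Benjamini–Hochberg adjustment
is applied across probe-sets. A probe-set is *selected* when
`|log2fc| > log2(1.25)` (about 0.3219) and the p-value is at most 0.05 — on
the adjusted scale by default, switchable to raw, since published
fold/p cutoffs of this kind do not always say which scale they mean.
Zero within-group variance (noiseless fixtures) is handled with a variance
floor of 1e-12 and flagged rather than raised as an error.

Mask optimization composes the stages — mask, apply, summarize, test — at
each threshold of the sweep and returns the full DE-count curve with the
argmax. A threshold that eliminates every probe-set contributes a count of
zero rather than an error, so the sweep can safely cross the point where the
chip runs out.

## Clustering, enrichment, and cross-platform comparison

DE probe-sets are clustered on their log2 expression vectors with
complete-linkage agglomeration under the **chord distance**, the Euclidean
distance between vectors rescaled to unit length
(`sqrt(2 - 2 cos theta)`, range [0, 2], scale-invariant). The tree is cut at
`k` clusters; `k = 8` is the default, and the cut count is a parameter
because a published cluster count alone does not determine whether it arose
from a height cut or a k cut. Determinism is inherited from
`stats::hclust`'s stable pair ordering.

Functional-bin enrichment applies a two-sided Mann–Whitney rank-sum test of
each bin's fold changes against all non-members: exact enumeration when the
smaller group has at most 8 values and there are no ties, otherwise the
normal approximation with midranks, tie correction and continuity
correction; BH across bins; the direction (up/down) is reported separately
from the two-sided p as the sign of the member-vs-non-member median
difference.

The cross-platform comparison takes per-species tables of gene-identifier →
log2 fold change, thresholds at 0.3 log2 units, and reports every Venn cell.
Identifier-based matching is the explicit, documented semantics; matching by
anything weaker (e.g. by expression values alone) is not well defined across
platforms and is deliberately not guessed at.

## qPCR quantification

The relative standard curve method: ordinary least squares of Ct on log10
template quantity over a dilution series (at least three distinct points)
gives slope, intercept, r² and amplification efficiency
`E = 10^(-1/slope) - 1`; a slope of `-1/log10(2)` (about -3.3219) is perfect
doubling. Quantities invert the curve, `10^((ct - intercept)/slope)`.
Technical replicates are averaged at the Ct level before quantification.
Normalization divides the target quantity by the **geometric mean** of the
reference-gene quantities — the symmetric choice when two references (actin
and 18S rRNA) are combined and no combination rule is stated — and scales so
the calibrator sample (first day after harvest) equals exactly 1.
Significance across time points uses one-way ANOVA followed by Tukey's HSD
(Tukey–Kramer under imbalance) at alpha 0.05, reporting per-sample
differs-from-calibrator flags; the studentized-range computation is
cross-checked in the tests against a published q-table value.

## Neighbor-joining trees

The comparative stage consumes pre-aligned amino-acid FASTA. Distances are
uncorrected p-distances with pairwise gap deletion (differences divided by
comparable positions; a pair with no comparable positions is an error naming
the pair). p-distance is the dependency-free choice closest to the
percent-identity distances of classic alignment tools; it can violate the
triangle inequality, which NJ tolerates. Saitou–Nei neighbor joining (via
`ape::nj`) reproduces additive distances exactly — verified by regenerating
random 5-taxon trees — and negative branch lengths on non-additive input are
retained as computed, preserving additivity diagnostics, rather than clamped.
Trees are unrooted. Newick output formats branch lengths to six decimals and
serializes sibling subtrees in alphabetical order of their smallest tip
label, so equal trees produce byte-identical files.

## Problem sizes and reproducibility

The test suite and the acceptance script run the full pipeline on simulated
studies of 1000 probe-sets x 11 pairs x 7 arrays, sweep 21 mask thresholds,
and use 50–200 replicate null simulations of 2000 probe-sets for calibration
checks; these sizes exercise every code path at comfortable desk scale.
Every random quantity is seeded: the generator reproduces datasets
bit-identically from one seed, and the end-to-end pipeline (simulate → mask
→ optimize → cluster → enrich) is verified to produce byte-identical output
files across reruns.

## Known limitations

* The generative model is intentionally simple; see above for what it omits.
  In particular it cannot say how masking behaves under correlated probe
  failure or saturation.
* The DE test is a pooled-variance test per probe-set with no
  variance moderation across probe-sets; at n = 3 per group a moderated test
  would be more powerful on real data.
* Enrichment treats bins as flat labels: no ontology hierarchy propagation.
* The exact distance model behind any particular published tree is rarely
  stated; p-distance topologies should be compared with that caveat in mind.
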