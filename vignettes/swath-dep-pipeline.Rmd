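---
title: "SWATH-MS bilateral-concordance differential expression: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SWATH-MS bilateral-concordance differential expression: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swathdep)
```

## The experimental design this package models

A paired-eye developmental proteomics study: vitreous from the left (OS) and
right (OD) eye of several animals is pooled per side per timepoint (days 7,
14, 21, 28 post-hatch), each pool injected three times in SWATH-MS mode
(24 injections), and quantified against an ion library built from combined
IDA searches. Differential expression candidates are then re-measured in a
separate batch of individual animals (n = 4 per day, days 7 and 14) by
targeted MRM(HR).

The pooled design has no biological replication within a timepoint, so the
discovery arm uses **no p-values at all**. Its false-positive control is
structural: the left and right eye pools are biologically independent
samples of the same developmental state, so a real change should appear in
both. A protein is called differentially expressed at day *d* only when both
eye pools pass the fold-change cutoff vs day 7 in the same direction and the
protein is supported by at least two peptides. We document this prominently:
**the DEP lists are screening calls, not inferential results**, and no
multiple-testing machinery exists in this arm because there is nothing to
correct. Inference happens only in the targeted arm, where individual
animals provide real replication for an unpaired t-test.

## Roll-up

Transition areas are aggregated by *sum* of the top 6 transitions per
peptide, then *sum* of the top 10 peptides per protein, per injection —
the convention of DIA extraction software for pooled quantities. The
targeted arm instead uses *means* of the top 3 transitions and top 3
peptides. The two arms differ on purpose; they mirror the two different
vendor pipelines they emulate.

Only library peptides with identification confidence >= 0.90 are used
(`min_confidence`), and peptides mapping to more than one protein accession
are removed entirely: a shared peptide's signal cannot be attributed. Top-k
ties are broken lexically by fragment label (peptide name at the protein
level) so results are independent of input row order.

### Peptide support of a DEP call

Two notions of "peptides per protein" coexist:

* `quant_matrix$peptide_counts` — the minimum per-injection count across the
  injections where the protein is observed: the most conservative global
  summary, following the roll-up contract.
* the per-contrast `n_peptides` used by `find_deps()` — summarized from the
  per-(protein, injection) count grid over the *contrast's* injections, with
  `count_rule = "max"` by default.

The default matters. Peptide support is a property of the quantification
evidence (which library peptides yield signal for this protein), not of the
worst single injection: with even a few percent of peptide-injection
dropout, the minimum over 12–24 injections falls to 1 for roughly half of
all genuinely 2-peptide proteins, irrespective of abundance or effect size —
a bookkeeping exclusion, not a quality filter, and not what library-driven
DIA software reports. The worst-injection reading remains available as
`filter_config(count_rule = "min")`.

## MLR normalization

Injections differ by loading and spray efficiency: a multiplicative bias per
injection. The most-likely-ratio estimate of that bias for injection *j*
against a reference column is `2^m_j`, where `m_j` is the **mode** of the
log2 protein-ratio distribution. The mode — unlike the mean or median — is
insensitive to the regulated minority, which moves the tails of the ratio
distribution but not its peak.

Numerical choices:

* Gaussian kernel density with Silverman's rule-of-thumb bandwidth
  (`bw.nrd0`), evaluated on a 512-point grid spanning `[min - 1, max + 1]`
  log2 units of the observed ratios; the mode is the grid argmax refined by
  parabolic interpolation through its two neighbours (removing grid
  quantization, worth a ~2x improvement in factor recovery).
* Fewer than `min_shared = 50` shared proteins make a density mode
  unreliable; the estimator falls back to `2^median` and flags it.
* A zero-spread ratio vector short-circuits to its common value (the
  Silverman bandwidth would be 0).
* Zero areas in shared proteins are excluded and counted, never an error;
  a pair with no shared proteins is an error (not normalizable).
* The default reference is a per-protein **median pseudo-reference** across
  all injections — robust and symmetric in a design with no distinguished
  injection; any named injection can be pinned instead (its factor is then
  exactly 1). With a pseudo-reference the overall scale of the factors is
  undefined, so the convention is fixed at geometric mean 1.

The vendor software that popularized MLR does not publish its exact
algorithm; this estimator is documented on its own terms and is not claimed
to be bit-identical to any vendor implementation.

## The bilateral filter

* Fold change per eye = ratio of arithmetic means over technical replicates
  (day *d* over the reference day); the replicate summary is configurable
  (`center = "median"`), since the order of operations is a convention.
* UP iff both eyes' FC >= `up_cutoff` (1.5); DOWN iff both <= `down_cutoff`
  (0.7). The down cutoff follows the reporting convention of the reference
  table rather than the symmetric 1/1.5 ≈ 0.667; both are configurable.
  Cutoffs are inclusive; a missing fold change yields NONE with a
  not-evaluable flag.
* The reported spread of the two eyes is the two-value sample standard
  deviation `|FC_OD − FC_OS|/√2`, which reproduces the reference table's
  printed `± SD` cells.
* Display rounding is round-half-away-from-zero to 2 decimals
  (`round_half_away()`), matching how such tables are printed; numeric
  checks use a ±0.005 tolerance instead of string equality, because values
  derived from printed (already rounded) inputs carry that rounding. For the
  two-value SD the worst-case propagation of 2-dp input rounding is
  `0.01/√2 ≈ 0.0071`, so one reference SD cell can legitimately differ from
  its re-derivation by slightly more than half a printed unit.
* `intersect_deps()` requires the same direction at every contrast.
  `zscore_matrix()` standardizes each protein row by its non-missing mean
  and sample SD; zero-variance rows become all-zero and are flagged,
  single-observation rows are flagged and not standardized.

## The targeted MRM(HR) arm

Transitions below signal-to-noise 20 are discarded; "above 20" is
implemented as `snr >= 20` with a strict `>` available
(`snr_exclusive = TRUE`) — boundary rows are rare and the choice is
recorded. When fewer than k items survive a top-k mean, the mean of the
survivors is used. Housekeeping normalization divides every protein by the
GAPDH-analog intensity of the same injection (error if the housekeeping
protein is missing anywhere), which cancels per-injection scaling exactly;
the housekeeping row is exactly 1 by construction. The group fold change is
the ratio of group means (day 14 / day 7) over individual animals, and the
default test is the pooled-variance Student t-test — the plain "unpaired
t-test" — with Welch available by flag. Degenerate inputs (fewer than two
values per group, or zero variance in both) return a flagged result with no
p-value rather than an error. No correction across targets is applied;
per-protein p-values are reported as such.

## The synthetic-data generator

`generate_swath()` / `generate_mrmhr()` emulate the statistical structure of
the two arms with known ground truth, sharing one truth per master seed
(fixed substreams per component, so either arm can be regenerated
independently):

* protein baseline `log2` abundance ~ Normal(17, 2) (arbitrary area units);
* 2–15 peptides per protein with fixed Normal(0, 1) offsets; fixed
  Dirichlet(1, …, 1) transition fractions;
* true effects vs day 7: a `de_fraction` of proteins get same-sign log2
  fold changes in both eyes (magnitude uniform in 0.8–2.5 by default);
  a `decoy_fraction` get *opposite-sign* effects across eyes — built
  specifically to be rejected by the bilateral filter; per-eye
  Normal(0, 0.1) jitter on non-null effects;
* pooling: one biological abundance per (protein, day, eye) shared by its
  technical replicates; the MRM arm instead draws per-animal deviations with
  biological CV 0.20;
* per-injection loading bias uniform in log2 [−1, 1], applied to every area
  of the injection — exactly the nuisance MLR removes;
* multiplicative log-normal measurement noise with CV 0.10 per transition
  observation;
* logistic abundance-dependent dropout of peptide-injection observations,
  midpoint log2 12 and steepness 1.5 by default (~3% of peptide-injection
  observations, ~98% of protein rows complete across 24 injections). Real
  replicate CVs and missingness rates are not published for this design;
  these are stated defaults, chosen once as plausible for library-driven DIA
  extraction (where a library peptide nearly always yields an area), and
  exposed in `synth_config()` rather than estimated from real data;
* MRM(HR) signal-to-noise proportional to area over a noise floor set so
  that `snr_low_fraction` (default 10%) of transitions fall below 20; the
  housekeeping analog is pinned at baseline mean + 2 SD so it is
  quantifiable in every injection, as a usable normalizer must be.

**What passing synthetic benchmarks does and does not show.** The generator
reproduces the design's *structure* — pooling, bilateral concordance versus
discordance, injection biases, abundance-dependent missingness, small-n
targeted validation — so it can falsify the pipeline's logic (factor
recovery, filter sensitivity and decoy rejection, type-I behaviour). It does
not reproduce chromatography, interference, retention-time drift, the real
abundance distribution, or identification-level FDR, so synthetic results
say nothing about how many proteins a real instrument would yield;
dataset-scale counts from real studies are treated as direction-only
contrasts (e.g. DIA-style extraction keeps more proteins complete than
IDA-style sampling under matched truth).

## Problem sizes used by the tests and the acceptance script

Chosen as the smallest sizes at which the estimates are stable: 1,000
proteins × 24 injections for normalization and filter benchmarks (50
concordant effects with |log2 FC| ≥ 1, 50 discordant decoys, 900 nulls);
3,000 simulated cohorts for the null-target type-I rate of the targeted arm,
compared against the binomial band implied by 1,000 cohorts (more replicates,
same tolerance); 200 cohorts for spiked fold-change recovery; 300–400
proteins for the direction-only contrasts.

## Known limitations

* Protein identity is the accession string; no isoform collapsing or
  protein-inference model beyond unique-peptide mapping.
* The discovery arm's filter has no error-rate guarantee; its decoy
  pass-rate is a property of the simulated discordance model, not of real
  biology.
* The MLR estimator is one defensible reading of "most likely ratio"; other
  implementations (pairwise iteration, most-intense-sample referencing) may
  differ within grid/bandwidth resolution.
* I/O covers the bespoke long-format TSV/CSV dialects only; vendor raw
  formats, mzML and spectral-library formats are out of scope.
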