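---
title: "Quantifying ecological guilds: model, design choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ecological guilds: model, design choices, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guildquant)
```

## The model

A guild is quantified per function, not per species: for every marker gene
we ask how abundant the function is and how diverse its genetic
implementations are, within each taxon and environmental context. The
observation unit is the *stratum* — one (gene, taxon, context) cell — with
two measurements: abundance `A` in globally normalized features per
million, and observed richness `d_obs`, the number of distinct predicted
ORFs.

Richness grows with abundance: sampling more reads of a gene uncovers more
of its sequence variants. Within a gene this is well described by a power
law,

$$d_{exp} = c \, A^{\gamma},$$

which is linear on log–log axes. The *diversification statistic* is the
ratio of observed to expected richness,

$$\delta = d_{obs} / d_{exp},$$

and the guild-importance score is $k = \delta \, A$: a guild is rewarded
for carrying more distinct sequence variants than its abundance predicts
(presumed stability and adaptability under changing conditions) and
penalized for carrying fewer. On the log scale, $\log\delta = 0$ is the
"exactly as expected" reference point around which per-context
distributions are compared.

Assumptions worth stating:

* **One power law per gene.** The exponent is fitted per gene, pooling
  taxa and environments. With one `(A, d_obs)` point per stratum, any
  finer subscripting of `c` and `γ` would leave the regression
  under-determined; per-gene pooling is the only reading that makes the
  fit well-posed, and the empirical richness–abundance relationship is
  indeed gene-wise. A per-(gene, taxon) fit is available via
  `fit_diversity_models(per_taxon = TRUE)` for datasets dense enough to
  support it.
* **Multiplicative, roughly lognormal richness scatter.** The fit is
  ordinary least squares on log axes, where lognormal scatter is exactly
  homoscedastic and additive. This is also what the synthetic generator
  produces, so fitted-versus-true comparisons are clean.
* **Each predicted ORF is one "unique sequence".** No identity-threshold
  clustering is applied to collapse near-identical ORFs; richness is the
  count of distinct ORF ids in the stratum (an ORF recurring in several
  samples of one context counts once).

## Normalization and filtering

FPM is a global normalization: each count is divided by the grand total of
raw reads over the entire dataset and scaled by $10^6$, so the whole
dataset sums to exactly one million FPM and values are comparable across
samples. No gene-length correction is applied — the feature counts this
package consumes are per-ORF read tallies without an accompanying length
model; if per-feature length correction is wanted, apply it to
`raw_count` before normalization.

Normalization runs **after** paralog purging, so that the one-million
total is carried entirely by retained, truly functional features.
Re-normalizing after any further subsetting rescales every FPM by one
global factor, which cancels in δ-based comparisons within a fit.

Purging itself is curator-driven: reference trees arrive with labelled
clades and a rules table (clade → retain/discard; by default functional →
retain). A query inherits the verdict of the *smallest* labelled clade
containing its best placement — a defined rule for nested labels, which
reduces to the obvious one when only top-level clusters are labelled.
Defaults that matter:

* `weight_threshold = 0.5`: a best placement with likelihood weight ratio
  below one half cannot be confirmed and is discarded as
  `low_confidence`. The threshold is a package default, configurable.
* Ties between equally weighted placements break toward `discard` — the
  conservative direction for a purging step.
* A gene with no reference tree passes through untouched (`no_tree`); a
  placed-but-tree-covered gene whose query has no placement is discarded
  (`unplaced`), since it cannot be confirmed functional.

## Environmental contexts

Depth strata follow the standard pelagic split — epipelagic 0–200 m,
mesopelagic 200–1000 m, bathypelagic 1000–4000 m — with upper-inclusive
boundaries (200 m is epipelagic, 1000 m mesopelagic). The side that owns
the boundary is a convention; real bottle depths do not sit on it.

Station classes are chosen from N:P (NOx:PO4) vertical profiles. The
mesopelagic maximum is searched down to 1000 m (ties to the shallower
depth). A station is flagged anomalous when, below a pivot depth
(default 600 m, the deeper of the two transition depths at which the
anomalous columns separate from the rest), its ratio is *strictly* below
the minimum (or above the maximum) of every other station at comparable
depths. "Comparable" is nearest-depth pairing within ±50 m — profiles are
not interpolated. Strictness means a duplicated typical profile can never
be flagged; it also means the flag is only meaningful when profiles carry
real differences, so noise-free identical profiles are all `typical`.

## The GLM contrasts

Per-context effects on diversification are estimated with a Gaussian
identity-link GLM fitted by iteratively reweighted least squares. For
this family the working weights are constant and IRLS converges to the
ordinary-least-squares solution — which the test suite exploits by
checking IRLS coefficients against an independent normal-equations oracle
to $10^{-8}$.

Instead of one over-parameterized joint model, the same GLM is refitted
once per focal context with a single focal-vs-rest indicator
(rotation-by-reference). Coefficients are *marginal* shifts: the station
contrasts ignore depth, the layer contrasts ignore station. Choices:

* **Response: `log_delta`** (default). δ is a ratio; its distributions
  are roughly symmetric on the log scale, which is what an identity link
  with Gaussian errors presumes. Raw δ is available via
  `response = "delta"`; the sign pattern of the contrasts is the same
  under either choice on synthetic cruises.
* **p-values from the normal (z) approximation**, not the
  t-distribution, matching standard IRLS GLM software output.
* **Observations are strata, unweighted.**
* **No multiple-testing correction** is applied across the rotated
  contrasts; they are descriptive marginal effects, reported with their
  individual p-values.
* **Pseudo-R² (Cragg–Uhler):** the likelihood-ratio R²
  $1-(L_0/L_1)^{2/n}$ rescaled by its ceiling $1-L_0^{2/n}$. With a
  continuous response the null *density* can exceed 1, making the ceiling
  undefined; the uncorrected likelihood-ratio R² (equal to the classical
  R² for the Gaussian family) is reported in that case, keeping the
  metric in [0, 1].

## Kernel densities

Per-context log δ clouds are smoothed with a Gaussian kernel and
Silverman's rule-of-thumb bandwidth (both overridable — the kernel and
bandwidth are declared package defaults, not estimates of anything). The
default grid is 512 points spanning the data range ± 3 bandwidths; the
curve is renormalized by its trapezoidal integral over that finite grid,
since the grid truncates a fraction of kernel tail mass that would
otherwise leave the curve slightly sub-unit for small samples. Comparison
reports the mode shift, the mean shift of the underlying samples, and a
sign label with a dead-band of 0.1 natural-log units around zero — a
presentation convention for "centered", not a statistical test. Formal
context comparisons belong to the GLM contrasts.

## The synthetic cruise

The generator encodes the study conditions the analysis is designed for,
and its defaults are fixed rather than tuned per experiment:

* **Cruise geometry:** 11 stations × 7 bottle depths (3–4000 m; 77
  samples), spanning all three layers. The first three stations are the
  OMZ-like, high-N:P (NAtl-like), and separately tracked SAtl columns;
  the rest are average ocean.
* **N:P shapes:** every profile rises from a nutrient-depleted surface to
  a mesopelagic maximum and relaxes to a deep asymptote. Averages peak at
  16.3 near 500 m and relax to 15.3 (just under the Redfield 16), with
  per-station jitter (sd 0.1) on peak and asymptote; the OMZ-like column
  peaks low and shallow (12.4 at 210 m, asymptote 11.3) and the
  NAtl-like column high (18.96, asymptote 16.4, never nitrogen-scarce).
  These shape constants reproduce the qualitative orderings the N:P
  flagging step is designed to detect.
* **Abundance:** stratum read weights are lognormal (median 80 FPM,
  log-sd 1.5), giving the orders-of-magnitude spread across strata that
  radial log-k plots display; a stratum is realized with probability 0.25
  (not every taxon carries every gene in every context).
* **Richness:** `d = max(1, round(c · A^γ · m · ε))` with per-gene true
  constants (`c` 1.6–3.0, `γ` 0.30–0.60 across the 18 markers), `m` the
  injected per-context δ multiplier, and ε lognormal with unit median
  (sd 0.2 by default). Rounding is half-away-from-zero; richness is
  floored at one ORF and capped at one read per ORF.
* **Turnover:** mesopelagic taxa share a fraction 0.3 of the epipelagic
  pool, bathypelagic 0.8 of the mesopelagic — strong turnover at the
  epi/meso transition, similar deep communities.
* **Determinism:** one integer seed fixes the full output; the metadata
  and feature stages draw from deterministic sub-seeds.

What the generator deliberately does **not** emulate: read-level
sequencing error, assembly and binning artifacts, chimeras and
contamination, taxonomic misassignment, compositional coupling between
genes, or spatial autocorrelation between stations. Passing tests
therefore demonstrate that the statistical machinery recovers truth under
the model's own assumptions — not that those assumptions hold for any
particular real survey.

## Validation scales

The test suite validates at sizes chosen to make Monte-Carlo error small
relative to the tolerances asserted: power-law recovery on 500 strata
(with a 20-replicate bias check of $\hat\gamma$ within ±0.02);
injected-shift detection on 20 full synthetic cruises (≈2000 strata
each); type-I error of the focal contrast on 500 null replicates of 400
strata; IRLS-vs-OLS agreement on 100 random designs. On-curve noiseless
data must recover `c` and `γ` to at least six significant digits and
score δ = 1 exactly up to integer rounding of richness
($|\log\delta| \le \log(1 + 1/d_{obs})$).

## Known limitations

* The power law is fitted to strata that passed filtering and have
  `d_obs ≥ 1`, `A > 0`; very sparse genes (fewer than 3 usable strata)
  are skipped, not extrapolated.
* δ inherits discreteness from integer richness at low abundance: for
  `d_obs = 1` strata, log δ can only take values on a lattice, which
  fattens the left tail of δ densities. Comparisons between contexts are
  unaffected as long as their abundance profiles are similar.
* The one-vs-rest rotation reuses the data across refits; its
  coefficients are correlated by construction and sum to approximately
  zero across categories. They are descriptive marginal contrasts, not
  independent tests.
* The N:P flagging rule is strict-extremal and intentionally simple; it
  will not flag a station that is anomalous over only part of the deep
  profile.
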