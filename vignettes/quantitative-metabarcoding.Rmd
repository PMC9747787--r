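---
title: "Quantitative eDNA metabarcoding: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative eDNA metabarcoding: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ednaquant)
```

## The calibration model

Quantitative metabarcoding rests on one assumption: within a single sample,
sequence reads are proportional to template copy number. Between samples the
proportionality constant varies wildly (PCR inhibition, template quality,
library pooling), which is why raw reads cannot be compared across samples.
Spiking each sample with internal standard DNAs of known copy number — by
default 5, 25 and 50 copies per reaction — measures that constant directly.

For sample $s$ with standard copies $x_i$ and standard reads $y_i$, the
package fits the through-origin least-squares line

$$\hat b_s = \frac{\sum_i x_i y_i}{\sum_i x_i^2} \quad \text{(reads per copy)},$$

and converts each biological taxon's reads $r$ to
$\text{copies/reaction} = r / \hat b_s$. The intercept is pinned at zero
because zero copies must produce zero expected reads; an unconstrained
intercept would let blank-level noise leak into every estimate.

Fit quality is reported as the *uncentered* coefficient of determination
$R^2_u = 1 - \mathrm{SSE} / \sum_i y_i^2$, the convention for through-origin
regression (the centered definition can be negative and rewards an intercept
the model does not have), and a $t$ test of the slope with $n-1$ degrees of
freedom. A standard line is usable only if the slope is positive and at
least two standards amplified; otherwise every estimate for that sample is
missing (`NA`), never zero — absence of calibration is not absence of DNA.

### Scaling to copies per litre

$$\text{copies/L} = \text{copies/reaction} \times
  \frac{\text{elution volume (µL)}}{\text{template volume (µL)}} \, / \,
  \text{water volume (L)}.$$

Defaults are 100 µL elution, 2 µL template per 12-µL reaction, and 1 L of
filtered water. The template volume in particular is a protocol constant
that field studies rarely print, so it is explicit and configurable in the
sample manifest; within a fixed protocol it is a common multiplier, so
every rank-based or ratio-based statistic downstream is unaffected by its
value. Only the absolute copies/L scale depends on it.

### Blank correction and filters

Each field sample maps to the cooler blank transported with it. Copy
numbers detected in the blank are subtracted taxon-wise and floored at zero
(a negative concentration is physically meaningless; floored cells carry a
`floored_to_zero` provenance flag). Subtraction happens after per-litre
scaling; because both sides are linear in the same protocol constants, the
order is immaterial. PCR negatives receive no standards and are never
calibrated or subtracted — their raw reads are summarized in the QC report
and flagged above a configurable threshold (default 100 reads), mirroring
the practice of reporting, not correcting, negligible negative-control
contamination.

Taxon filters drop excluded taxa (e.g. saltwater fishes detected in a
freshwater survey), merge designated taxa into one (e.g. two congeners
indistinguishable in ecology), and optionally zero read cells below a
minimum count. The per-cell read threshold defaults to 0 because the usual
"10 or more reads" rule operates upstream, at sequence-merging inside the
bioinformatic pipeline that produces the count table this package consumes.

## Community structure

Bray–Curtis dissimilarity, $d(u,v) = 1 - 2\sum_t \min(u_t, v_t) /
(\sum_t u_t + \sum_t v_t)$, is computed on untransformed copies/L so the
quantitative information participates (a `log10(x+1)` option exists for
heavily skewed tables). Sites with no detected taxa are removed before
ordination: their dissimilarity to everything is undefined-to-maximal and
they would dominate the embedding. A pair of two all-zero communities is
assigned dissimilarity 0 with a warning.

NMDS keeps the best (lowest Kruskal stress-1) configuration over a fixed
number of random starts — 500 by default, a "500 permutations" convention
read here as 500 restarts, since permutations play no role in fitting NMDS.
k-means clustering needs a Euclidean space, while Bray–Curtis is not
Euclidean; the package therefore clusters the 2-D NMDS coordinates by
default (the raw copy matrix can be passed instead). For each candidate
$k$ (default 2–8) the best of 50 Lloyd runs is scored by the
Calinski–Harabasz criterion $\mathrm{CH}(k) = [B/(k-1)]/[W/(n-k)]$, and the
smallest $k$ wins ties. All stages are deterministic given a seed.

## Copies versus capture data

Kendall's tau-b compares copies/L with electrofishing abundance or biomass
over pooled (site, taxon) pairs, and separately within each site cluster.
Tau-b applies the tie correction (ties are ubiquitous: zeros); the p-value
is exact by full enumeration of permutations when $n \le 8$ and otherwise
uses the normal approximation with the tie-adjusted variance of the
$S$ statistic.

**Double-zero pairs** — taxa undetected by both methods at a site — are
excluded by default: they would manufacture concordance out of shared
absence. The trade-off is worth stating plainly: conditioning on "not both
zero" makes two *independent* zero-heavy variables negatively dependent, so
the excluded-pair test is anticonservative as a test of independence in
sparse tables. It is kept as the default because the scientific question is
whether *detected* quantities co-rank, but `drop_double_zero = FALSE`
restores the unconditioned test, and that is the configuration under which
the package's null-calibration property (type-I error ≈ 0.05) is asserted.

Per-taxon models use only taxa detected at ≥ 3 sites by *both* methods —
below that the fit is numerology. Negative-binomial GLMs with log link
regress copies/L on abundance or biomass, matching the saturating
copy-abundance relationships reported across the eDNA literature;
per-guild fits pool all (site, taxon) rows of a group's members. The NB
likelihood needs integer responses, so copies/L are rounded to the nearest
integer, with a warning if rounding shifts values by more than 1% on
average (copy concentrations are typically in the tens to thousands, where
rounding is negligible). No multiple-testing correction is applied by
default — each taxon is reported at $\alpha = 0.05$, as is conventional for
these per-taxon tables; `p.adjust` can be applied by the caller.

The qPCR cross-validation is an ordinary regression with intercept of
metabarcoding concentration on species-specific qPCR concentration, on the
raw scale by default (log10 optional, dropping zero pairs with a warning).

## What the generator emulates

`simulate_experiment()` produces the full survey layout: one field sample
per site, one cooler blank per river/sampling day, two PCR negatives, and
internal standards added only to field samples and blanks.

* **Slopes**: lognormal with 2.5–97.5% quantiles ≈ 120–950 reads/copy,
  truncated to [100, 1000] — the order of magnitude observed for
  iSeq-scale libraries.
* **Reads**: independent Poisson with mean slope × copies. Poisson rather
  than multinomial because per-sample totals are not fixed by the model;
  the slope absorbs depth. A consequence the pipeline inherits: scaling
  all of a sample's reads by a constant leaves its copy estimates exactly
  unchanged (depth invariance), which the tests assert at machine
  precision.
* **Communities**: sites and taxa belong to latent habitats (default 4);
  a taxon occupies sites of its habitat with probability 0.8 and others
  with 0.15, and abundance where present is negative binomial (mean 20,
  size 1). This gives site communities real cluster structure, as upstream
  and downstream assemblages have in the field.
* **Coupling**: copies/L $= a_t N^\gamma \varepsilon$ with default
  $a = 50$ copies/L per individual, per-taxon lognormal shedding variation
  (sdlog 0.5), $\gamma = 1$ and lognormal noise (sdlog 0.5). With
  $\gamma$ = `NA` the generator produces a *null* scenario: copies drawn
  iid across cells, independent of abundance and free of the habitat
  structure (a shared structure would make the "null" dependent).
* **Capture survey**: binomial thinning of latent abundance with per-taxon
  efficiency drawn Uniform(0.2, 1) by default — electrofishing catches
  benthic and pelagic fishes very unequally — plus lognormal biomass noise.
* **Blanks and negatives**: each taxon leaks into a blank with probability
  0.1 at exponential mean 2 copies/L, exercising the subtraction floor;
  negatives get Poisson(0.2) stray reads per taxon.

Defaults are chosen for test power at a desk-scale problem (20 sites × 15
taxa), not as a calibrated model of any river system. What passing tests
show is that the machinery is correct and well-calibrated *under the
model's assumptions* — linear read response, independent Poisson noise,
binomial catchability. They do not show robustness to primer bias,
inhibition that breaks linearity at high template, eDNA transport between
sites, or taxon mis-assignment, none of which the generator attempts.

## Numerical and degenerate-input choices

* Slope estimation is closed-form; the test suite checks it against a
  brute-force SSE minimizer (grid + golden section) to 1e−6 relative.
* $R^2_u$ is clipped to [0, 1]; a perfect fit yields $p = 0$ rather than a
  0/0 `NaN`.
* Uncalibratable samples propagate `NA`, never 0; `subtract_blank` can
  floor but never go negative.
* Kendall: constant input returns `NA` with a reason code rather than an
  error, so pooled analyses degrade gracefully; exact-p enumeration is
  capped at $n = 8$ (40 320 permutations).
* CH ties choose the smallest $k$; cluster labels are renumbered in order
  of first appearance so labellings are deterministic.
* Wide tables are written with lexicographic row/column order and 17
  significant digits, making writes byte-reproducible and read-backs exact.

## Problem sizes in the test suite

The tests run the generator at 6–20 sites and 6–15 taxa; calibration
recovery uses 50 replicates of the default 20 × 15 design, GLM calibration
uses 200 coverage and 500 null replicates at $n = 200$ observations, the
Kendall oracle checks are exhaustive over $\{1,2,3\}^n$ for $n \le 6$ plus
1000 random tied vectors at $n = 8$, and the null-level property uses 500
replicates of an 8 × 6 design. These sizes were picked so the full suite
exercises every statistical claim while remaining a routine desk run.

## Limitations

* Absolute copies/L inherit the template-volume convention; compare
  absolute concentrations across studies only with matched protocols.
* The blank-subtraction floor biases low-concentration cells upward
  relative to signed subtraction; provenance flags record where it acted.
* k-means on NMDS coordinates inherits the ordination's 2-D compression;
  with stress above ~0.2 the clustering should be read cautiously.
* The excluded-double-zero Kendall default tests co-ranking of detections,
  not independence; see above for the calibrated alternative.
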