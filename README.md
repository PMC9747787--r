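# ednaquant

Quantitative eDNA metabarcoding with internal-standard calibration.

## The problem

Metabarcoding of environmental DNA (eDNA) from stream water identifies which
fish taxa are present, but raw read counts are not comparable across samples:
PCR efficiency, template quality and sequencing depth differ from sample to
sample. The quantitative approach implemented here spikes every field sample
(and every cooler blank) with internal standard DNAs of known copy number —
by default 5, 25 and 50 copies per PCR reaction — that amplify with the same
universal primers but occur nowhere in nature. The standards turn each
sample into its own calibration experiment.

For sample *s*, a zero-intercept least-squares line is fitted through the
standard points:

    reads = b_s * copies,     b_s = Σ(x·y) / Σ(x²)   [reads per copy]

and every taxon's reads are converted to copy numbers:

    copies/reaction = reads / b_s
    copies/L        = copies/reaction × (elution µL / template µL) / water L

Copy numbers observed in the matched cooler blank are subtracted (floored at
zero), saltwater or otherwise excluded taxa are dropped, and designated taxon
pairs are merged. PCR negatives carry no standards; their reads are only
reported in the QC summary.

Downstream, the package reproduces the standard community and validation
analyses on the copy table:

* **Community structure** — Bray–Curtis dissimilarity on copies/L, NMDS
  ordination (best of *n* random starts), and k-means clustering of the
  ordination with the Calinski–Harabasz criterion
  CH(k) = [B/(k−1)]/[W/(n−k)] choosing the number of clusters.
* **Copies vs capture surveys** — Kendall rank correlation (tau-b with tie
  correction; exact permutation p for n ≤ 8) of copies/L against
  electrofishing abundance or biomass, pooled and per site cluster; and
  per-taxon / per-guild negative-binomial GLMs (log link) of copy number on
  abundance or biomass.
* **qPCR cross-validation** — ordinary regression of metabarcoding
  concentrations on species-specific qPCR concentrations.

A synthetic-data generator (`simulate_experiment()`) emulates the whole
survey — per-sample slopes of order 10²–10³ reads/copy, Poisson read noise,
habitat-structured fish communities, blank contamination, binomially thinned
capture data, noisy qPCR — with full ground truth, so every stage is
testable without field data.

## Worked example

```r
library(ednaquant)

sim <- simulate_experiment(sim_config(seed = 42))   # 20 sites x 15 taxa
cal <- calibrate_run(sim$counts, sim$manifest)
cal
#> qMiSeq calibration: 15 taxa x 20 field samples (copies/L)
#> standard lines: 24/24 valid; slopes 128.0-959.0 reads/copy

copies <- copies_by_site(cal)
cs <- community_structure(copies, seed = 42)
cs$ordination
#> NMDS ordination: 20 sites in 2 dimensions, stress = 0.1394 (500 restarts)

correlate_copies_vs_capture(copies, sim$capture, cs$clustering, "abundance")[1, ]
#>       scope tau_b  p_value n_pairs
#> 1 all_sites 0.581 7.25e-15      86

qt <- unique(sim$qpcr$taxon)[1]
q  <- sim$qpcr[sim$qpcr$taxon == qt, ]
compare_with_qpcr(copies[qt, q$site_id], q$qpcr_copies_L)
#> qPCR cross-validation (raw scale): slope 1.350, intercept -7.44, R2 0.914, p 5.2e-11, n 20
```

Each standard line converted reads to absolute copies/L per sample; the
pooled Kendall tau of 0.58 (86 site×taxon pairs, double zeros excluded)
says copy concentrations rank sites and taxa much like the capture survey
does, and the qPCR regression close to the 1:1 line confirms the absolute
scale for the assayed taxon.

A command-line front end over the same functions lives in
`inst/cli/ednaquant.R` (`simulate`, `calibrate`, `community`, `compare`
subcommands).

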