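# symbioTrace

Stable-isotope tracing metabolomics for symbiotic carbon and nitrogen
exchange.

## What problem this solves

In photosymbiotic animals — coral larvae hosting Symbiodiniaceae being
the motivating system — the algal symbiont fixes dissolved inorganic
carbon and translocates photosynthates (chiefly glucose) to the host.
Incubating the holobiont with ¹³C-labeled bicarbonate turns this flux
into a mass-spectrometric signal: metabolites built from freshly fixed
carbon acquire heavy isotopologues. `symbioTrace` is the analysis side
of such an experiment, for researchers who already have MAVEN-style
isotopologue intensity tables (plus respirometry traces and scalar
physiology measurements) and need to go from ion counts to statements
like *"glucose translocation was maintained while glycolysis slowed
down."*

The pipeline:

1. **Natural-abundance correction.** The observed spectrum of an
   *n*-carbon metabolite is `y = C f`, where
   `C[k,j] = choose(n-j, k-j) p^(k-j) (1-p)^(n-k)` is the binomial
   probability of observing mass shift *k* given *j* tracer-labeled
   carbons at natural ¹³C abundance `p = 0.0107`. The true
   labeled-count fractions `f` are recovered by non-negative least
   squares and renormalized.
2. **Enrichment metrics.** Atom-fraction enrichment
   `E = sum(i * f_i) / n` and carbon-specific enrichment (each `f_i`).
3. **Pool sizes.** Total ion counts per metabolite, median-normalized
   within each sample, then `log(x + 1)` transformed.
4. **Treatment discrimination.** PERMANOVA on Euclidean distances (999
   permutations, seeded), PCA for visualization, and a from-scratch
   NIPALS two-group PLS-DA with variable-importance-in-projection
   scoring: `VIP_j = sqrt(p * sum_a(SSY_a w_aj^2) / sum_a SSY_a)`,
   selection at `VIP >= 1`, fold changes as relative differences
   `(high - ambient) / ambient`.
5. **Quadrant classification.** Pool-size and enrichment responses are
   combined into the turnover/accumulation framework: high pool + high
   enrichment = synthesis exceeding use (ii); high pool without higher
   enrichment = accumulation (iv); higher enrichment without a larger
   pool = turnover (i); both lower = reduced biosynthesis and use
   (iii); with per-pathway reporting (glycolysis, pentose phosphate,
   TCA, ammonium assimilation, urea cycle, dipeptide synthesis).
6. **Methodological controls.** Label-presence PERMANOVA (isotope ×
   temperature), light-vs-dark enrichment validation with FDR-adjusted
   marginal-means contrasts, and label-saturation peak windows.
7. **Respirometry & physiology.** Ranked local linear regression for
   oxygen-trace slopes (`alpha = 0.4`), blank/volume/individual/size
   normalization, gross photosynthesis and P:R, chlorophyll equations,
   elliptical-sphere larval volume, settlement and density.
8. **Synthetic data.** A generator reproducing the full experimental
   design (labeled/unlabeled/dark vials, binomial labeling convolved
   with natural abundance, lognormal pools and noise), so everything
   above runs and is tested without any download.

## Worked example

```r
library(symbioTrace)

sim <- simulateIsotopologueDataset(simulationConfig(seed = 2024))
res <- runPipeline(sim$spectra, sim$metadata, pipelineConfig(seed = 2024))
res
#> symbioTrace pipeline result
#>   samples: 28  metabolites: 36
#>   temperature PERMANOVA p (pool): 0.01  (enrichment): 0.002
#>   VIP-selected metabolites: pool 8 | enrichment 11
```

Both response matrices separate the temperature treatments (permutation
p = 0.01 for pool sizes, 0.002 for enrichment), and the PLS-DA selects
8 and 11 discriminating metabolites respectively. The quadrant calls
for three focal metabolites:

```r
subset(res$quadrants,
       metabolite %in% c("glucose", "glutamine", "arginine-glutamine"))
#>          metabolite pool_fc pool_vip  enr_fc enr_vip quadrant
#>  arginine-glutamine  0.8542    1.931  1.2670    1.95       ii
#>             glucose  0.0284    0.766 -0.0804    1.12       iv
#>           glutamine -0.0661    0.694  0.3976    1.65        i
```

The arginine–glutamine dipeptide roughly doubles in both pool and
enrichment (quadrant ii, synthesis exceeding downstream use); glutamine
shows a ~40% enrichment increase at stable pool (quadrant i, turnover —
the signature of increased ammonium assimilation); glucose falls in
quadrant iv (accumulation without increased turnover). The light–dark
control confirms the label enters through photosynthesis:

```r
ld <- res$lightDark$perMetabolite
ld[ld$metabolite == "glucose", c("light_mean", "dark_mean")]
#>   light_mean  dark_mean
#>        0.184    0.00092
```

Respirometry, from a simulated trace with an equilibration artifact:

```r
tr <- simulateOxygenTrace(-0.5, noiseSd = 0.5,
                          equilibrationFraction = 0.2, seed = 7)
est <- extractRate(tr)
est
#> RateEstimate: slope = -0.50763 umol L^-1 min^-1; window 22 - 117
normalizeRate(est$slope, blankSlope = -0.02, wellVolume = 80e-6,
              nIndividuals = 6, meanSizeMm3 = 0.11)
#> $perIndividual
#> [1] -0.006501797
#> $sizeNormalized
#> [1] -0.05910725
```

The ranked-window regression skips the curved first ~5 minutes (window
starts at point 22) and recovers the generating slope of −0.5 within
2%; normalization yields nmol O₂ individual⁻¹ min⁻¹ and
nmol O₂ mm⁻³ min⁻¹.

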