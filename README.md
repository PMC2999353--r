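# icpd — information-combining peak detection for high-resolution LC/MS

`icpd` detects peptide features in centroided, high-resolution LC/MS maps.
Its target problem is the one that limits label-free proteomics most:
**low-abundance peptides**. A peptide does not appear as one peak — it elutes
over many MS scans and disperses over charge states and isotope positions, so
its evidence is scattered across dozens of weak peaks. Detectors that score
one scan and one charge state at a time throw most of that evidence away.
`icpd` combines all of it before scoring.

## The model and the score

A peptide candidate *i* with neutral mass *M*, total abundance *A*, elution
profile *C(t)* (summing to 1 over scans), charge-state distribution *f(cs)*
and isotope distribution *f(iso)* contributes expected intensity

    P(t, cs, iso) = A · C(t) · f(cs) · f(iso)

at m/z `(M + cs·w_p + iso·w_n) / cs`, where `w_p` is the proton mass and
`w_n` the C13–C12 isotope spacing. *f(iso)* is predicted from mass alone via
the averagine composition, as a convolution of Poisson counts of +1 Da and
+2 Da heavy-isotope substitutions.

For every candidate the detector extracts the observed intensity grid
`y(t, cs, iso)` inside ±`dmz` ppm windows, sums it over charge states
(*f(cs)* sums to 1 and cancels) and combines scans with matched-filter
weights `w(t) = C(t)/Σ C(t)²`, giving

    ŷ(iso) = Σ_t Σ_cs w(t) · y(t, cs, iso),   E[ŷ(iso)] = A · f(iso).

`ŷ` is a noise-corrupted copy of the theoretical pattern; by the central
limit theorem its noise is Gaussian with variance `σ'² = c · Â^p`, a power
law in the abundance estimate `Â = Σ ŷ` with exponent `p ∈ {1, 2, 3}` and a
constant `c` calibrated from the data. The isotope matching score is the
standardized mismatch of the Gaussian log-likelihood,

    score = − Σ_iso ( ŷ(iso) − Â·f(iso) )² / (2 σ'²),

whose maximum (0) is a perfect averagine match; thresholding it separates
peptides from contaminants, which lack averagine-like envelopes. A
single-scan baseline scorer (best scan, highest peak as abundance) is
included to quantify what the combining buys.

The package also ships the generative simulator (arbitrary elution shapes,
charge dispersion, power-law noise, non-peptide contaminants, m/z jitter)
and ROC / precision-recall benchmarking against simulated ground truth.

## Worked example

```r
library(icpd)

bm  <- make_benchmark("noise_free")   # 20 clean peptides, known truth
fit <- icpd(bm$map)                   # detect: dmz = 10 ppm, CS = 4, p = 3
fit
#> <icpd> 800 scored candidates (dmz 10 ppm, CS 4, n_iso 5, p 3)
#>   noise constant c = 4.947e-07 (single-scan 7.627e-06)
#>   top candidates:
#>       mass cs rt_start rt_end        score volume
#> 1 1219.053  3       37     59 -1.40179e-15  1e+06
#> 2 1387.809  3       20     27 -8.39116e-15  1e+06
#> 3 1645.904  3       23     32 -1.77658e-14  1e+06
#> 4 1728.385  3       17     25 -2.55052e-14  1e+06
#> 5  879.648  3       41     59 -2.80858e-14  1e+06

sweep_curves(fit$outlist, bm$truth, dmz = 10)
#> <icpd_curves> criterion 'score': 20 truth, 760 negatives
#>   ROC AUC 1.0000, PR AUC 1.0000
```

Each m/z trace spawns one candidate per charge hypothesis (here 200 traces ×
4 charges = 800 candidates). On clean data every true peptide's correct
hypothesis scores essentially 0 (a perfect isotope match, `volume` = its
full abundance of 10⁶) while wrong-charge and isotope-misanchored duplicates
fall orders of magnitude lower, so the ranking is perfect (ROC AUC 1.0). On
noisy maps the same sweep quantifies how far the score separates peptides
from contaminants; `plot(fit)` shows the score–volume cloud and
`plot(curves)` the ROC/PR curves.

A shell interface wraps the same functions:

```sh
Rscript inst/scripts/icpd.R simulate --out sim --preset low_snr_sweep
Rscript inst/scripts/icpd.R detect   --input sim/map.tsv --out det --p 3
Rscript inst/scripts/icpd.R evaluate --outlist det/outlist.tsv --truth sim/truth.tsv --out eval
Rscript inst/scripts/icpd.R benchmark --out bench --preset dynamic_range
```

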