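---
title: "Isotope-pattern detection by information combining: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotope-pattern detection by information combining: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icpd)
```

## The signal model

A peptide species in an LC/MS run does not produce a single peak. It elutes
over a window of MS scans according to a chromatographic profile $C(t)$
(non-negative, summing to one), is split over charge states according to a
distribution $f(cs)$, and over isotopologues according to an isotope
distribution $f(iso)$. The expected intensity of candidate $i$ at scan $t$,
charge $cs$ and isotope position $iso$ is therefore

$$P_i(t, cs, iso) = A_i \, C_i(t) \, f(cs) \, f(iso),$$

with $A_i$ the total abundance, observed at mass-to-charge
$(M_i + cs\,w_p + iso\,w_n)/cs$. Two constants matter here: $w_p = 1.007276$
Da is the proton mass, and $w_n = 1.003355$ Da is the spacing between
adjacent isotope peaks. We deliberately use the C13–C12 mass difference for
$w_n$, not the free-neutron mass (1.008665 Da): the spacing a
high-resolution instrument actually observes between isotopologue peaks is
the carbon isotope shift, and at 10 ppm windows the distinction matters
above ~1 kDa.

Observations are the model intensity plus noise whose distribution is
instrument-dependent and, in general, unknown. This is the core difficulty:
without a trustworthy noise model, evidence from single cells of the
(scan × charge × isotope) grid cannot be weighed against each other reliably,
and single-scan detectors inherit the full per-cell noise.

## The isotope pattern from mass alone

Sequence information is unavailable at detection time, so $f(iso)$ is
predicted from the neutral mass with the averagine model: an average
elemental composition per 111.1254 Da of peptide (4.9384 C, 7.7583 H,
1.3577 N, 1.4773 O, 0.0417 S). We model the number of heavy-isotope
substitutions as two independent Poisson counts: one for +1 Da shifts
(C13 dominates, with smaller contributions from H2, N15, O17, S33) and one
for +2 Da shifts (O18, S34). The envelope is their convolution, truncated to
`n_iso` positions and renormalised to sum to one.

Keeping the +2 channel separate is not pedantry. A single Poisson on the
carbon count alone deviates from the exact elemental convolution by a total
variation distance of 0.03–0.11 over 500–3000 Da — well above what the
likelihood can absorb — whereas the two-channel model stays below 0.02 over
the whole range (the test suite checks this against a brute-force
convolution oracle of the rounded averagine formula). The analytic Poisson
form is retained because the pre-truncation ratio $f_1/f_0$ equals the +1
rate exactly, which makes the model easy to reason about and test.

`n_iso` defaults to 5, which covers essentially the entire envelope for
tryptic peptides up to ~3 kDa.

## Candidate generation

Detection starts from centroided scans (profile data can be centroided by
local-maximum picking, but centroiding is not this package's contribution).
All centroid m/z values are pooled and binned greedily on the sorted m/z
axis: a new bin opens when the next value exceeds the current bin's first
member by more than $2\,d_{mz}$ ppm, and each bin's upper edge is extended
$d_{mz}$ ppm into its successor, so boundary centroids join both bins. The
greedy-by-anchor rule was chosen because it is single-pass and
deterministic; the duplicates that bin overlap creates are removed later.

Each bin's summed intensity trace is segmented into elution windows:
maximal non-zero runs, merged across gaps of at most `g` scans (interleaved
fragmentation duty cycles punch such gaps), discarded if they contain fewer
than `s` non-zero scans. `s` is a lower bound on LC peak width and should
stay small (2–3) so no real peptide is excluded; `g` defaults to 2 scans.
One candidate per segment is emitted with an intensity-weighted mean m/z —
plain means are vulnerable to low-intensity stragglers at the window edge.
Candidates within $d_{mz}$ ppm whose windows share a scan are merged
(union window, weighted mean m/z), globally and to a fixpoint, with
candidates processed in ascending (m/z, start) order for determinism.
Finally each surviving m/z candidate is expanded into one mass hypothesis
per charge state 1..CS, assuming the observed peak is monoisotopic.

## Combining the grid and scoring

For each mass hypothesis the (scan × charge × isotope) grid is extracted
with half-open ±$d_{mz}$ ppm windows. The elution profile is estimated as
the scan-wise grid total, normalised; the combined pattern is

$$\hat y(iso) = \sum_t \sum_{cs} w(t)\, y(t, cs, iso), \qquad
  w(t) = \frac{C(t)}{\sum_t C(t)^2}.$$

Summing over charge states makes $f(cs)$ cancel (it sums to one), so the
charge-state distribution never has to be estimated. The matched-filter
weights are the minimum-variance linear combination over scans under
i.i.d. per-cell noise, and they make the coefficient exactly one:
$E[\hat y(iso)] = A f(iso)$. With the profile estimated from the grid
itself, $\hat A = \sum_{iso} \hat y(iso)$ reduces algebraically to the total
grid volume; passing the true profile instead (as the estimator-contract
tests do) gives the textbook matched filter with variance
$\sigma^2_{cell}\, CS \sum_t w(t)^2$ per isotope position.

The summed noise in $\hat y$ is treated as Gaussian (central limit theorem
over the many cells combined) with a single variance
$\sigma'^2 = c\,\hat A^{\,p}$ following a power law of abundance. Both
reported exponents from the literature are supported — $p=1$ (Poisson-like
counting noise) and $p=2$ (quadratic growth) — plus $p=3$, under which
signal-to-noise worsens with intensity; the default is $p=3$ and the choice
should be adapted to the instrument (the benchmark command sweeps all
three). The constant $c$ is nuisance: it is calibrated as the median over
candidates of the mean squared isotope residual divided by $\hat A^p$.
The median is essential — the candidate list is deliberately permissive, and
well over half of its entries are wrong-charge or isotope-misanchored
hypotheses whose residuals reflect model mismatch, not noise. If every
residual is zero (degenerate input) the constant is floored at
$10^{-12}\max(\hat A)^p$ with a warning.

### Why the score is the standardized mismatch

The Gaussian log-density of $\hat y$ under the candidate hypothesis is

$$-\sum_{iso} \frac{(\hat y - \hat A f)^2}{2\sigma'^2}
  \;-\; \frac{n_{iso}}{2}\log(2\pi\sigma'^2).$$

Per candidate the two forms are monotone-equivalent, but across candidates
the normalisation term adds $-(n_{iso}p/2)\log \hat A$, a reward for *small*
estimated abundance that is independent of fit quality. With $p=3$ that
reward reaches several score units and systematically ranks low-abundance
near-matches (e.g. a candidate anchored one isotope position off, whose
shifted envelope still resembles averagine at ~40% of the true abundance)
above exact matches. We therefore rank by the exponent alone: its maximum is
0 for every candidate, one threshold means the same thing at every
abundance, and ranking is invariant under global intensity rescaling once
$c$ is recalibrated. `matching_score(..., normalized = TRUE)` provides the
full log-density for users who want the proper likelihood value. Empty
candidates ($\hat A = 0$) score $-\infty$; inside the variance, $\hat A$ is
floored at the smallest positive intensity of the map to avoid division by
zero.

The single-scan baseline replicates the scan-at-a-time strategy: take the
(scan, charge) row with the largest summed intensity, use it directly as the
pattern estimate, and take its highest single peak as the abundance. It is
scored with the same formula and its own calibration of $c$. Its pattern
estimate carries the full per-cell noise, which is exactly what the
combining removes.

## The simulator

`simulate_map()` implements the generative model literally: intensities
$A\,C(t)\,f(cs)\,f(iso)$ at the predicted m/z positions, per-cell additive
Gaussian noise with variance $c A^p$ plus a baseline floor, clamping of
negative values to zero (instruments emit non-negative centroids), optional
drop threshold (centroided data carry no explicit zeros), and Gaussian m/z
jitter (default $\sigma = d_{mz}/3$, so mass accuracy genuinely exercises
the ppm windows). Four elution shapes — Gaussian, exponentially modified
Gaussian, asymmetric triangle, plateau — cover the non-Gaussian LC peaks
that shape-fitting detectors misclassify; the detector itself assumes no
shape. Profile support is defined as the region at or above 0.1% of the
apex: peak bounds at a fixed small fraction of apex are standard practice,
and an unbounded exponential tail would otherwise stretch "support" over
half the map while contributing nothing but rectified noise. Contaminants
come in three kinds without averagine structure: single spikes, doublets at
half the isotope spacing, and flat four-peak multiplets.

Choices a user should know about: noise is Gaussian because the detector's
likelihood argument concerns the *summed* noise, and the per-cell
distribution is instrument-dependent anyway; clamping introduces a small
upward intensity bias that matters only at very low per-cell SNR (the
variance-match test therefore conditions on cells at SNR ≥ 5); per-cell SNR
of a peptide is defined as its apex monoisotopic cell of the dominant charge
divided by the per-cell noise standard deviation. With a fixed seed the
simulator is byte-reproducible.

What passing tests on simulated maps do **not** show: real instruments add
correlated noise, ion suppression, dynamic exclusion artefacts, co-eluting
isobaric interference and retention-time drift, none of which are modelled.
The simulation results demonstrate the estimator's contracts and the
*relative* ordering of scoring strategies under controlled conditions, not
absolute real-data performance.

## Benchmark presets and problem sizes

The presets fix the study conditions used by the test suite and
`scripts/acceptance.R`: `noise_free` (20 equal-abundance peptides, no
noise), `low_snr_sweep` (15 peptides at each per-cell SNR of 2, 5, 10, 20,
plus 40 contaminants), `dynamic_range` (40 peptides log-spaced over four
orders of abundance with decade tiers, 30 contaminants, quadratic noise plus
floor), `info_combining` (300 peptides at SNR 3 plus 300 contaminants of
comparable apex intensity), and `abundance_recovery` (200 peptides at
SNR 20). These sizes give a few thousand to ~25 000 scored candidates per
map — enough for stable AUCs and medians while a full suite run stays
around half a minute.

On these presets the combined score dominates the single-scan score (ROC
AUC ~0.97 vs ~0.52 at SNR 3, with many-fold higher precision at 50% recall)
and beats peak volume on the weakest tier; the benchmark's exponent sweep
produces genuinely different rankings for $p = 1, 2, 3$. Which $p$ wins
depends on the simulated noise law, as it does on real instruments.

## Evaluation protocol

A detection hits a truth peptide if its mass is within $d_{mz}$ ppm and the
elution windows overlap by at least one scan. Matching is one-to-one,
best-score-wins: otherwise a single peptide detected at several charge
hypotheses would inflate the true-positive count. Detections matching only
already-claimed truth entries are labelled duplicates and removed from the
candidate universe rather than counted as false positives. The negative
universe is list-based (non-hit candidates); there is no pixel-level notion
of a true negative. We use the standard definitions precision
$= TP/(TP+FP)$ and recall $= TP/(TP+FN)$, and trapezoidal ROC AUC. Per-tier
curves restrict the positives to one tier and exclude other tiers' hits from
the universe entirely, so tiers do not pollute each other's false-positive
counts.

## Degenerate inputs and numerical conventions

Scan indices are 0-based and elution windows are inclusive index pairs;
ppm windows are half-open $[lo, hi)$ so a centroid on a shared boundary is
counted once. Retention times are seconds. An all-zero candidate grid yields
a flagged empty profile and a $-\infty$ score; an empty map yields an empty
output list; empty files are a validation error. Coincident centroids
within a scan are summed on construction. Ties in candidate merging are
broken by ascending (m/z, start scan); ties in truth matching by smaller
relative mass error.

## Known limitations

Overlapping envelopes are not deconvolved — co-eluting peptides whose
windows collide contaminate each other's grids (collisions are allowed, and
logged as upper-tail abundance errors in the recovery benchmark). The
charge-state distribution is never estimated, only cancelled; per-charge
abundances are not reported. The score is a ranking statistic, not a
calibrated false-discovery rate. And the averagine envelope is wrong for
sulfur-rich or heavily modified peptides by construction.
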