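---
title: "Validating a targeted LC-MS/MS quantification method: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a targeted LC-MS/MS quantification method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otval)
library(dplyr)
```

## The problem

Quantifying trace organotin compounds (tributyltin, TBT; triphenyltin, TPhT)
in bottom sediments by targeted LC-MS/MS runs into two coupled difficulties.
First, electrospray ionization is suppressed by co-extracted matrix
components — organic carbon, petroleum-derived aromatics, sulfur species —
so the same amount of analyte gives a smaller signal in a dirty sediment
extract than in water. Second, the extraction itself recovers less than
100 % of the analyte, and both effects vary from sediment to sediment.
A defensible monitoring result therefore requires a validated method:
calibration with known uncertainty, quantification limits tied to
signal-to-noise, guideline acceptance tests (accuracy/precision,
selectivity, carry-over, stability), explicit matrix-effect and recovery
characterisation, and a trueness check against a certified reference
material. `otval` implements that entire quantitative workflow, starting
from integrated peak areas (it deliberately does no chromatogram
processing), together with a synthetic-data generator that produces whole
studies with known latent truth.

## The measurement model

Every stage consumes one long table of peak-area observations. A row
carries the analyte, its role in the design (calibrant, QC, blank, CRM,
pre-/post-extraction spike, stability, carry-over blank, aqueous reference,
real sample), the run and replicate indices, the nominal concentration in
ng analyte per g dry sediment, the analyte peak area, the internal-standard
(IS) peak area, and a baseline-noise estimate.

The implicit signal model is

$$A = m \cdot r \cdot a\,x + b + \varepsilon,$$

where $a$ and $b$ are the aqueous response line, $m \in (0, 1.3]$ the
matrix's ionization suppression (1 = none), $r \in (0, 1.1]$ its extraction
recovery, and $\varepsilon$ heteroscedastic noise. The isotope-labelled IS
(deuterated TBT) is co-extracted and co-suppressed, so the analyte/IS area
ratio largely cancels $m$ and $r$ — which is why quantification calibrates
on the ratio, while matrix-effect estimation must use raw areas (a ratio
response would absorb the very effect being measured).

## Weighted calibration

The response is proportional to concentration with noise whose standard
deviation grows roughly in proportion — so ordinary least squares
over-weights the high standards and produces poor back-calculated accuracy
at the bottom of the range. The package fits

$$\min_{a,b} \sum_i w_i (y_i - a x_i - b)^2, \qquad w_i = 1/x_i,$$

the conventional compromise weighting for MS calibration (1/x², none, are
also available). Standard errors and two-sided p-values come from the t
distribution with $n-2$ degrees of freedom; R² is reported in weighted form
with the unweighted value alongside. Blanks are never calibration points
($x = 0$ is incompatible with 1/x weights). A property test in the suite
confirms the motivation: across simulated heteroscedastic curves, 1/x
weighting visibly tightens the spread of back-calculated concentrations at
the lowest level relative to the unweighted fit.

The acceptance logic gates calibration on *slope* significance only. An
intercept statistically indistinguishable from zero is the desirable
outcome for a blank-free method, so requiring intercept significance would
fail an ideal calibration; slope significance is what linearity needs.

## Quantification limits

The lower limit of quantification (LLOQ) is the lowest calibration level
whose replicates simultaneously achieve mean S/N ≥ 5, CV ≤ 20 % and mean
back-calculated accuracy within 100 ± 20 %. S/N is `peak_area / noise_sd`
with the supplied baseline-noise estimate — no chromatograms exist at this
layer, so the noise figure is an input. The limit of detection scales S/N
linearly down from the LLOQ point:

$$\mathrm{LOD} = \mathrm{LLOQ} \cdot \frac{3}{S/N(\mathrm{LLOQ})}.$$

This is the simplest rule consistent with an S/N = 3 detection criterion;
it is a package decision, and `decide_limits()` reports the measured
S/N so users can apply a different convention. The rule is monotone by
construction: raising the S/N threshold can never lower the LLOQ (tested as
a property).

## Guideline acceptance metrics

* **Accuracy** = 100 · mean(back-calculated)/nominal; **precision** =
  replicate CV (sample sd). Windows: 85–115 % and ≤ 15 % at QC levels,
  80–120 % and ≤ 20 % at the LLOQ. Within-run cells are computed per run
  (n = 5 in the default design) and reported alongside the pooled
  between-run cell (n = 15). Between-run statistics pool all runs rather
  than averaging run means — with balanced designs the accuracy is
  identical and the pooled CV is the conservative choice.
* **Selectivity** = 100 · mean(blank area)/mean(LLOQ area); accepted below
  20 % for analytes and 5 % for the IS.
* **Carry-over** = 100 · A(blank after high standard)/A(LLOQ); same
  thresholds.
* **Stability** = 100 · mean(stored)/mean(fresh reference), accepted within
  85–115 %. Stability is referenced to freshly prepared reference samples,
  not to nominal, so calibration bias cancels.
* **Relative matrix effect** (below) accepted under 15 % CV.

`evaluate_acceptance()` is a pure function of the computed cells: each
block passes iff all its cells pass, and the study verdict is the
conjunction. Blocks not run are reported as such and excluded.

## Matrix effects, recovery, trueness

The **absolute matrix effect** is a slope ratio: a five-level spike curve
is prepared in the post-extraction sediment extract and in water, both fit
on raw areas with the same 1/x weighting as the main calibration
(the weighting for these short curves is a package choice), and

$$ME_A = 100 \cdot a_\mathrm{matrix} / a_\mathrm{water}.$$

Values below 100 % are suppression. The IS sits at a single working level,
so its matrix effect is measured as the ratio of mean IS areas
(matrix-matched vs aqueous) rather than a slope ratio. The **relative
matrix effect** is the CV across matrices of the analyte-to-IS ME ratio —
exactly zero when the IS tracks the analyte's suppression in every matrix,
which is the structural property that makes IS-ratio quantification
matrix-independent.

**Extraction recovery** compares samples spiked before extraction with a
reference spiked after extraction (isolating extraction losses from
ionization effects), as a ratio of mean areas at a common level
(1000 ng/g by default).

**Trueness** against a CRM uses the expanded uncertainty of the bias:
$\Delta = |c_\mathrm{certified} - \bar{c}|$ is compatible when
$\Delta \le U_\Delta = k\sqrt{u_\mathrm{ref}^2 + s_m^2/n}$ with $k = 2$
(~95 % confidence) and $s_m$ the sample standard deviation (n − 1
denominator). The boundary counts as compatible, and compatibility is
monotone in both $u_\mathrm{ref}$ and $k$. Sieved/unsieved matrix-effect
comparisons use a *paired* two-sided t-test — the same sediments are
measured twice, so pairing is the correct analysis even though a plain
"t-test" leaves the choice open; the degenerate all-equal case reports
t = 0, p = 1.

## Exploratory statistics

Per-matrix $ME_A$ and recovery values are screened against sediment
geochemistry (TOC, N, H, AVS, P, heavy metals, PAH, grain-size fractions)
with Spearman correlation: average ranks for ties, two-sided p from the
t approximation with n − 2 df (adequate at n ≈ 10), missing values dropped
pairwise, and no multiple-testing correction — raw p-values are returned so
the user can apply one. PCA standardizes all variables (the profile mixes
%, mS, mg/kg and µg/kg, so covariance PCA would be meaningless) and drops
incomplete rows listwise; variance explained is reported per component and
sums to 100 %. Note a consequence of standardization: the spectrum is
invariant under signed permutations of variables but not under general
rotations of the raw data, since rotation does not commute with per-column
scaling. Biplot output is coordinates only (scores, plus loadings scaled by
the component standard deviations); `autoplot()` renders them but the core
has no plotting side effects. `welch_t_from_summary()` compares groups
reported only as mean ± sd with n, the form condition-optimisation results
are tabulated in.

## Censored reporting

Real samples are back-calculated from the IS-ratio response, replicates
averaged, and censored: below the LOD reports `below_lod`, between LOD and
LLOQ reports `below_lloq`, otherwise a number. Censored entries never enter
summaries' max/min; counts are tracked separately. The bundled ten-sediment
monitoring table keeps its "<5" entries as censor flags at the 5 ng/g TPhT
quantification limit, matching how the results were published.

## The synthetic-data generator

`simulate_study()` realises the full design from a `simulation_truth()`
(latent parameters) and a `scenario_spec()` (design layout). The defaults
*are* the study conditions: 7 calibration levels spanning 1–4000 ng/g
(TBT; 5–4000 for TPhT) with 6 replicate curves, QC at 3/2500/4000 and
15/2500/4000 ng/g plus the LLOQ level measured 5× per run over 3 runs,
matrix-spike curves at 50–2500 ng/g in quadruplicate across 10 matrices,
pre/post spikes at 1000 ng/g, 6 blanks and 6 carry-over blanks, five
stability conditions, 6 CRM replicates (certified 480/29 ng/g, u_ref
40/5.5), and ten real samples at the published concentrations. Suppression
factors span 0.58–0.92 (the observed ME_A range), recoveries 0.86–1.04, the
IS tracks suppression to within a few percent (ME_R ≈ 4–5 % CV), carry-over
is ~1.2 % of the LLOQ signal, and blank interference 6.1 %/3.8 %/1.2 % for
TBT/TPhT/IS.

Noise is multiplicative-plus-floor: area = expected · (1 + N(0, cv)) +
N(0, floor), truncated at zero, with cv = 5 % and a floor of 0.3 % of the
LLOQ-level area. Two noise figures are deliberately distinct: the additive
area-integration floor, and the *baseline* noise written to the `noise_sd`
column from which S/N is computed (set so expected S/N at the LLOQ is
5.3/7.2). On a real instrument these are different quantities — a single
figure serving both roles would force either ~19 % CV at the LLOQ or
S/N ≫ 5 there, neither of which describes the instrument being emulated.
Carry-over blanks are a fixed fraction of the preceding top-standard area;
because the top standard is 4000× the LLOQ, that fraction is tiny (~3·10⁻⁶)
even though the measured carry-over is ~1.2 % of the LLOQ signal. A single
seed drives everything through fixed per-block substream offsets, so each
block is individually reproducible.

Sediment profiles are generated so that PAH is a monotone transform of
(1 − suppression) on a log scale spanning ~500–74,000 µg/kg, with TOC, AVS
and heavy metals partially co-varying, sand decreasing and silt increasing
with suppression — emulating the empirical pattern in which polluted,
fine-grained, organic-rich sediments suppress ionization most. Grain-size
fractions sum to exactly 100.

What the generator does *not* emulate: retention-time or peak-shape
phenomena, correlated injection noise between analyte and IS within one
injection (areas are drawn independently, which makes simulated ratio
responses somewhat noisier than a real co-injected IS would be),
run-to-run calibration drift, and interference structure beyond a constant
blank fraction. Passing tests on generated data therefore demonstrate
correctness of the estimators under the stated model, not robustness to
every real-data pathology.

## Numerical choices and degenerate inputs

Zero denominators (water slope, LLOQ area, reference mean, IS matrix
effect) raise classed degenerate-input errors rather than returning Inf.
Back-calculation may legitimately return negative concentrations; censoring
is downstream. Perfect monotone Spearman inputs would give p = 0 under the
t approximation; the p-value is clamped to the smallest positive double so
the (0, 1] contract holds. The paired t and Welch tests report p = 1 when
the difference is identically zero. Negative simulated areas are truncated
at zero rather than resampled (recorded in the truth object's
documentation); at the default parameters truncation is vanishingly rare
outside carry-over blanks, where it is still < 10⁻⁴.

## What a seed's verdict means

With ~66 guideline cells per study and realistic 5 % proportional noise,
single borderline cells occasionally fail by chance: within-run LLOQ
accuracy has an sd of ~9 % (dominated by the shared calibration-intercept
error, consistent with the large printed slope uncertainty of the original
curve), and stability ratios have sd ~4.5 % against a ±15 % window. Across
seeds, roughly 8 or 9 in 10 simulated studies pass every cell; the rest
fail exactly one or two near-boundary cells. A conjunction over dozens of
noisy cells is inherently a near-boundary event, which is why the
acceptance script reports the fraction of cells passing rather than a
binary verdict.

## Problem sizes used in the test suite

The suite's simulation-based checks use 50-seed batches for parameter
recovery (slope, suppression, recovery, carry-over, CRM bias) and 100 seeds
for the PAH-link detection rate; the oracle-equivalence checks use 20–25
random instances per formula. These sizes give Monte-Carlo standard errors
comfortably below the tested tolerances (e.g. ±2 percentage points on mean
ME_A) while keeping the default test run to about a minute.

## A worked run

```{r pipeline}
sim <- simulate_study(simulation_truth(seed = 7), scenario_spec())
res <- run_study(sim$measurements, study_config(),
                 crm = list(certified = c(TBT = 480, TPhT = 29),
                            u_ref = c(TBT = 40, TPhT = 5.5)))
res$limits
res$matrix_effects$me_r
res$trueness
res$summary
```

```{r biplot, fig.width = 6, fig.height = 5}
model <- pca_profiles(sim$profiles)
autoplot(model, components = c(1, 2))
```

## Known limitations

The pipeline starts at integrated peak areas and trusts the supplied
baseline-noise estimates; it fits only straight lines (no quadratic or 4PL
models); the LOD rule is a linear-scaling convention; between-run precision
is a pooled CV, not a variance-components decomposition; and the
exploratory screen's p-values are uncorrected. Real-sample concentrations
refer to the sieved fine fraction actually analysed — no re-normalization
to whole sediment is attempted.
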