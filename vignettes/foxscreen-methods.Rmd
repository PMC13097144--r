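---
title: "foxscreen: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{foxscreen: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foxscreen)
```

# The assay and its statistics

The screen this package analyzes treats primary human T cells in 384-well
plates with one compound per well (10 µM is the usual screening
concentration), stains them for CD4 and FoxP3, and records each well by
flow cytometry. The readout per well is the percentage of FoxP3⁺ cells
within CD4⁺ T cells, obtained through a fixed gating hierarchy:
lymphocytes by forward/side scatter, singlets by the FSC-H/FSC-A ratio,
CD4⁺ by a threshold on the CD4 detector, and a FoxP3⁺/FoxP3⁻ threshold
partition on the V450 detector. Every downstream statistic is a count, a
fraction, or a median fluorescence intensity (MFI) of one of these
populations; no distributional assumptions are made at the event level.

Three per-well statistics drive triage:

* **FoxP3 fold** — well FoxP3% ÷ mean FoxP3% of the plate's DMSO wells.
  Hits are ±50% deviations (fold ≥ 1.5 or ≤ 0.5, boundaries inclusive).
* **Δratio** — lymphocyte FSC-H median ÷ pooled DMSO FSC-H median on the
  same plate. Toxic compounds change lymphocyte morphology, which moves
  forward scatter; outliers at |z| ≥ 3 SD of the compound-well Δratio
  distribution are flagged toxic.
* **V450 MFI stain ratio** — V450 median of FoxP3⁺ ÷ V450 median of
  FoxP3⁻ in the same well. Compound autofluorescence adds signal to both
  populations on the linear scale, pulling the ratio toward 1 (i.e. below
  the plate average); |z| ≥ 3 grades `high`, z in [−3, −1] grades
  `low_moderate`.

Plate quality is the screening-window statistic computed from the FoxP3%
readout of control wells,

$$Z' = 1 - \frac{3(\sigma_p + \sigma_n)}{|\mu_p - \mu_n|},$$

with DMSO wells (CD4 + FoxP3 stained) as positives and CD4-only wells as
negatives; a plate passes at Z′ ≥ 0.5 (boundary inclusive). SDs are
sample SDs (n−1): control groups are small (8 and 4 wells by default) and
the unbiased-variance convention is the conservative choice where the
formula's source does not specify one.

# Stream segmentation

Plate samplers of the iQue type emit one continuous timed event file per
plate. Well boundaries are not recorded; they must be recovered from the
acquisition rhythm: each well is sipped for 13.5 s, followed by 1 s of
"up time", with a 4 s shake every 6 wells, a block of three 1 s rinses
every 12 wells, and a 30 s initial plate shake. `segment_stream()` bins
event times (0.2 s bins), marks bins below 10% of the median non-empty
bin count as inactive, and takes inactive runs of ≥ 0.5 s as gaps; the
bursts between gaps are wells, mapped onto the plate layout strictly in
acquisition order.

Three refinements beyond that sketch, all configurable:

* *Opening*: above-threshold runs shorter than the minimum gap duration
  are reclassified as background — without this, a single carry-over
  event inside a 1 s up-time gap can bridge two wells.
* *Minimum burst duration* (2 s): bursts shorter than this are stray
  background clusters, not 13.5 s sips.
* *Edge padding*: burst windows are widened by one bin on each side,
  because a sip's partial first/last bin can fall under the rate
  threshold while still holding that well's events.

Misassignment is never repaired silently. If the burst count does not
equal the layout's well count, segmentation stops with diagnostics.
`validate_segmentation()` then uses the assay's built-in controls — the
CD4-only wells must show (near-)zero FoxP3⁺ and unstained wells
(near-)zero CD4⁺ — to confirm the well mapping, and on failure reports
the circular shift that minimizes control violations (an off-by-k
diagnosis, not a fix).

Detection limits: rate-threshold segmentation needs the in-well event
rate to dominate the inter-well background. At the instrument-realistic
rates the simulator defaults to (~150 events/s in-well vs ~0.5/s
background) detection is essentially error-free; below ~100 events/s
with several background events per second, 1 s gaps become
information-theoretically marginal for any rate detector, which is why
the test suite exercises the sparse-background regime at the higher
event rate where that regime is defined.

# Gating choices

* **MFI = median** throughout, never the mean; the even-count median is
  the mean of the middle two order statistics.
* **Thresholds are fit on asinh-transformed values** (cofactor 150) so
  that negative post-compensation values are handled; the returned cut
  is in raw units. `auto_threshold()` takes the minimum-density valley
  between the two largest modes of a kernel density estimate; if the
  density is effectively unimodal (secondary mode below 5% of the
  primary's height) it falls back to a quantile (99.5th percentile) of a
  designated negative-control sample. For the FoxP3 cut the negative
  control is the CD4⁺ population of the plate's CD4-only wells — cells
  carried through the identical gate with no FoxP3 antibody present.
* **Gates are plate-global**: one CD4 and one FoxP3 threshold per plate,
  fit on pooled DMSO wells, mirroring manual analysis where one gate is
  drawn per plate. Per-well override is available.
* Boundary conventions are explicit because the FoxP3⁺/FoxP3⁻ pair must
  partition CD4⁺ exactly: positive means value ≥ cut, negative means
  value < cut; polygon boundaries count as inside.
* Populations below 100 events (configurable) are flagged
  `insufficient`; the V450 stain ratio additionally requires ≥ 20 events
  in each of FoxP3⁺/FoxP3⁻ and reports `indeterminate` otherwise rather
  than returning an unstable ratio.

# Triage rules

The hit threshold is interpreted as linear relative change (0.5× / 1.5×),
with a log-scale option (cutoffs 1.5 and 1/1.5, symmetric in log10)
since screen overview plots are customarily drawn on a log axis and the
operative scale is not always stated.

The toxicity outlier mean/SD are computed over **compound wells only**,
controls excluded — control wells cluster tightly and would shrink the SD
artificially. Both documented scopes are implemented: screen-wide
(default, matching the Methods-style description) and per-plate (matching
the per-plate plots); they can genuinely disagree and both are reported.
Flagging is two-sided in |z| by default (morphology shifts in either
direction are suspect), with one-sided options.

A consequence worth stating explicitly: because the outlier statistics
include the outliers themselves, a screen with k strongly toxic wells
among n has its SD inflated by roughly $\sqrt{n/k}$ relative to the
neutral spread, which *suppresses* false positives below the nominal
2·Φ(−3) ≈ 0.27% Gaussian tail rate. The null calibration (flag rate ≈
tail rate) therefore holds on neutral screens and is tested there; on
spiked screens the acceptance check bounds false positives from above
only.

Autofluorescence `high` flags are two-sided (strong artifacts have been
observed pushing the ratio far above the average as well), while the
graded `low_moderate` band is one-sided negative, the direction additive
compound fluorescence moves the ratio. Down-hits whose only liability is
autofluorescence are kept on the candidate list with a
`retest_alt_fluor` flag: added fluorescence inflates apparent FoxP3 and
cannot explain a *decreased* signal, but the call should be confirmed
with a different fluorochrome. The candidate list is otherwise hits
minus toxic minus high-autofluorescence.

# Dose–response fitting

The model is the four-parameter logistic on the log10-dose axis,

$$y = \text{bottom} + \frac{\text{top} - \text{bottom}}
      {1 + 10^{(\log_{10} x - \log_{10}\text{IC50})\cdot h}},$$

fit by bounded multi-start least squares (five deterministic starts from
data quantiles, L-BFGS-B, best RSS wins with ties broken toward the
smaller IC50) followed by a Gauss–Newton polish. Two variants:

* `variable_slope` (default): all four parameters free, asymptotes
  bounded in [0, 120]% — validation curves often plateau above 0, and an
  unbounded top can run away on noisy data.
* `fixed_asymptotes`: top = 100, bottom = 0, the "normalized response"
  convention where DMSO is pinned to 100%.

Which variant matters for precision, not correctness: with 8 doses × 3
replicates at 5% response noise, the fixed-asymptote fit recovers IC50
within ±15% in ~95% of runs, while the free-asymptote fit achieves only
~77% — purely estimator variance from two extra parameters on 24 points.
The package's Monte-Carlo recovery checks accordingly use the
fixed-asymptote variant, which is also the model matched to how the
normalized data are generated. Degenerate inputs (flat series, fitted
span below 5 response units) are reported `converged = FALSE` with no
IC50 rather than force-fit. The optional IC50 confidence interval uses
profile likelihood (F-test inversion on an 81-point log-dose grid), not
asymptotic standard errors, because n is small. The log10-IC50 search
box is data-relative (min dose ÷ 100 to max dose × 100), which makes
dose-unit rescaling an exact symmetry of the fit up to optimizer
tolerance (~1e-8 relative in practice).

# The synthetic plate: what it emulates, and what it does not

The simulator is first-class, tested code: it is the ground truth against
which every pipeline stage is validated. Its defaults describe one
realistic stated world; none of the distribution parameters are measured
values from a specific instrument, and the generator is deliberately not
tuned against any published number.

* **Scatter**: three bivariate-Gaussian populations on (FSC-A, SSC-A) —
  lymphocytes (70%, centered 50k/30k), debris (18%, 12k/8k), doublets
  (12%, FSC-A doubled at 100k with FSC-H/FSC-A ≈ 0.5, the standard basis
  for singlet gating; live singlets have the ratio ≈ 1 with 3%
  log-normal noise).
* **Stains**: log10-normal mixtures, exponentiated. CD4 marks 65% of
  cells (negatives at log10 ≈ 2.0, positives at 3.8); FoxP3 marks 6% of
  CD4⁺ at baseline (negatives 1.7, positives 3.3). A 6% baseline with
  ~2000 gated CD4⁺ events per well puts the DMSO FoxP3% counting noise
  near 0.5% absolute, which is what makes the default plates pass Z′ ≥
  0.5 with a realistic margin rather than trivially.
* **Compound effects**: a FoxP3 multiplier scales the stain's positive
  fraction (capped at 1); a dead fraction converts cells to a
  shifted-scatter population (FSC-A ×0.60, FSC-H ×0.55, SSC-A ×1.25 —
  shrunken forward scatter, raised granularity; direction and magnitude
  are config, since the assay literature reports only that toxicity
  changes morphology); additive autofluorescence is applied per channel
  on the linear scale after the log-normal draw, which reproduces
  whole-population shifts; an optional event-loss fraction models cell
  loss.
* **Acquisition**: the timing profile above, with per-well events placed
  uniformly in their sip window and Poisson background (default 0.5
  events/s) in the gaps.
* The spiked autofluorescent compound default (+150 linear units on
  VL1-A, ~3× the unstained V450 baseline median) is chosen to produce
  the documented artifact — an apparent FoxP3 increase plus a stain
  ratio far below the plate average — while keeping a FoxP3⁻ population;
  a much larger additive empties FoxP3⁻ entirely and the well is then
  correctly reported indeterminate rather than flagged.

Not emulated: donor-to-donor biological variance, spectral spillover
physics beyond a linear mixing matrix, instrument electronics (pulse
shapes, baseline restoration), edge/evaporation plate effects, and any
compound mechanism beyond the three injected phenomena. A green test
therefore establishes that the pipeline recovers *injected* effects of
realistic magnitude from *statistically* realistic events — not that it
would survive every pathology of real instrument data.

# Determinism and seeds

Every generator takes an explicit integer seed; identical seeds and
configurations give bit-identical output. Multi-well and multi-plate
simulations derive per-unit child seeds (kept below 2³¹) from the master
seed, so adding wells does not reshuffle existing ones. The 4PL fit's
multi-start is deterministic (quantile-derived starts, no RNG).

# Known limitations

* The FCS reader supports list-mode files with float/double data and
  linear amplification — the output of modern plate cytometers — not
  log-amplified integer data from legacy instruments, and it does not
  implement the doubled-delimiter escape in TEXT keyword values.
* Burst-to-well mapping is strictly positional; a dropped well shifts
  all subsequent assignments (detected by the control-well validation,
  but not repaired).
* The valley-based threshold assumes at most two meaningful modes per
  marker; markers with genuine trimodality would need explicit cuts.
* Screen-stage multiple-testing correction is deliberately absent, as is
  any row/column (B-score) plate normalization: triage reproduces the
  assay's published decision rules, which use neither.
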