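---
title: "Methods: islet functional connectivity from calcium imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: islet functional connectivity from calcium imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletconn)
```

# The analysis problem

A pancreatic islet is a cluster of endocrine cells — insulin-secreting
beta cells forming a core, glucagon-secreting alpha cells on the mantle,
somatostatin-secreting delta cells interspersed — whose coordinated
calcium activity underlies pulsatile hormone secretion. In vivo
volumetric calcium imaging (a slow genetically encoded indicator such as
GCaMP6s, z-stacks every 5 s for 1–2 h) yields one fluorescence trace per
segmented cell, together with the cell's type label and 3D centroid, and
sometimes a trace of an adjacent peri-islet neuron. Typical questions:
how strongly are cells of each type pair coupled, does coupling decay
with inter-cell distance, which endocrine cells follow the neuron's
activity, and how do glucose stimulation or loss of neural input change
these quantities.

`isletconn` implements that analysis as a reusable pipeline:

1. **Preprocessing** — per-cell min-max normalisation within each
   condition window (basal `LG`, glucose-stimulated `HG`, and optional
   post-perturbation windows), plus binarisation into active/silent
   states.
2. **Connectivity** — pairwise Pearson correlation matrices; the average
   correlation coefficient $R_{avg}$ per cell-type pair and animal;
   classification of cells with a *neural activity connection*;
   thresholded connectivity graphs.
3. **Spatial structure** — distance to the islet core per cell type, and
   $R_{avg}$ as a function of pairwise-distance rank with a two-group
   slope/elevation comparison.
4. **Fraction-time analysis** — for each nearest heterotypic cell pair,
   the occupancy of the four joint states (both active, both silent, two
   directional mixed states).
5. **Transient metrics** — event frequency, peak height and duration.
6. **Group statistics** — paired t, one/two-way ANOVA with Holm–Sidak
   adjusted contrasts.

Because raw in-vivo imaging data of this kind are rarely deposited, the
package ships a synthetic-islet generator with known ground truth; every
stage is validated against it or against independent oracles in the test
suite.

# Preprocessing decisions

**Normalisation** is per-cell min-max within one analysis window
(`normalize_traces()`), matching the 0–1 trace axes conventional for
these recordings. Pearson correlation is invariant to any per-cell
positive affine map, so this choice does not affect connectivity; it
matters only for binarisation and peak heights, and the scaling
constants are stored in the result for provenance. `zscore` is available
behind a flag, as is an optional linear detrend (off by default — no
photobleach correction is applied unless asked for).

**Binarisation threshold** defaults to 0.25 of the normalised range.
Published analyses of this kind rarely state their active/silent
criterion; 0.25 sits above the noise floor of the generator's default
SNR (noise SD 5% of the single-event amplitude) while catching most of
each indicator transient. It is a declared package default, surfaced in
`analysis_config()` and echoed into every output, not an inference about
any particular study's choice; the test suite includes a sensitivity
check that the active fraction is monotone in the threshold.

# Connectivity decisions

The coupling measure is zero-lag Pearson correlation computed within one
condition window (Spearman is not offered; no lag-shifted
cross-correlation — the claims supported are undirected and
instantaneous at the 5-s frame scale). $R_{avg}$ for a type pair is the
arithmetic mean of $R$ over all unordered distinct pairs of that
composition — the mean over *pairs*, not over per-cell means, which
differs when group sizes are unbalanced. Cells with constant traces have
undefined correlations; they are recorded as missing and excluded from
every average. "Unknown"-type cells stay in the full matrix but never
enter typed summaries. Neurons are never counted in endocrine
percentages.

A cell has a **neural activity connection** when its best correlation
with any imaged neuron reaches the `connection_threshold` (default 0.5).
An optional significance guard (circular-shift null, 1000 shifts,
$\alpha = 0.05$) can be layered on top for real recordings, where
slow common drift can inflate threshold crossings; it is off by default
because the generator's traces are stationary.

# The synthetic islet generator

`simulation_config()` describes one imaged animal. Geometry: beta cells
uniform within 0.6 × radius, alpha cells on the 0.85–1.0 shell, delta
cells throughout, neurons just outside the surface — which reproduces
the qualitative core/mantle ordering (mean distance to centre: beta <
delta < alpha) without claiming any particular measured values.

Activity is generated as binary per-frame event trains mixing three
routes:

* a **private** Bernoulli train (rate = `private_frac` × the condition
  rate);
* one **shared drive train per type pair**: a cell of type $a$ at
  distance $d$ from the islet core accepts each event of the $(a,b)$
  drive with probability
  $c_{ab}\, e^{-d/\lambda}\, \rho$, where $c_{ab}$ is the coupling
  weight, $\lambda$ the decay length and $\rho$ the perturbation factor;
* for **neuron-driven** cells (a configurable fraction of each type,
  flagged as ground truth), the neuron's own train accepted with the
  drive weight.

Event trains are convolved with a double-exponential indicator kernel
(rise 0.5 s, decay 2.5 s — GCaMP6s order of magnitude at 5-s sampling)
and Gaussian noise is added. Because each component is white across
frames and all cells share the same kernel, the frame-level event
correlation of a pair survives filtering unchanged, which gives the test
suite a closed-form oracle: for a single shared drive the joint
active/silent probabilities of a pair follow from the acceptance
probabilities alone, and the simulated Pearson matrix must match that
closed form within Monte-Carlo error.

Shared-event thinning (rather than correlated Gaussian noise) was chosen
deliberately so that the binarisation and fraction-time stages see
realistic on/off structure.

## Default study conditions

| parameter | default | meaning |
|---|---|---|
| `n_beta, n_alpha, n_delta, n_neuron` | 40, 12, 8, 1 | cells per islet |
| `islet_radius_um` | 20 | islet radius (µm) |
| `frame_interval_s` | 5 | acquisition interval |
| `windows` | LG 360 + HG 360 frames | 30 min basal, 30 min stimulated |
| `rate_lg`, `rate_hg` | 0.8, 2 events/min | drive/private event rates |
| `private_frac` | 0.15 | private share of a cell's event budget |
| `coupling` beta–beta | 0.8 | strongest homotypic weight |
| `lambda_um` | 15 | coupling decay length (µm) |
| `neuron_drive_frac`, weight | 0.5, 0.8 | driven fraction and acceptance |
| `neuron_rate_factor` | 2 | neuron rate ÷ endocrine drive rate |
| `tau_rise_s`, `tau_decay_s` | 0.5, 2.5 | indicator kernel (s) |
| `noise_sd` | 0.05 | noise SD ÷ event amplitude |

Two of these deserve comment. Islet-cell activity in vivo is dominantly
coordinated — that is precisely why these recordings are analysed with
correlation matrices — so most of a cell's event budget flows through
the shared drives (`private_frac` 0.15) rather than private firing.
And the peri-islet (vagal) neuron fires on a faster timescale than the
slow endocrine calcium oscillation (`neuron_rate_factor` 2), which makes
the neuron train the dominant activity component of driven cells; under
these conditions driven cells sit at a neuron correlation of roughly
0.65–0.7 while undriven cells sit near 0, so the default classification
threshold of 0.5 separates them cleanly, as the acceptance checks
verify against the generator's ground-truth labels.

Perturbations (chronic toxin-mediated silencing, acute ablation or
photo-inhibition of the peri-islet neurons) are represented *only* as
the factor $\rho \le 1$ multiplying all coupling and drive weights —
chronic mode attenuates every window, acute mode only post-baseline
(`HGa`/`HGlambda`) windows. No biophysics of the perturbation, and no
gap-junction or paracrine mechanism, is modelled.

## What the generator does not emulate

Passing the in-silico checks says the *pipeline* recovers what the
generative model plants; it does not certify performance on real data,
which additionally shows slow baseline drift and photobleaching, motion
and segmentation errors, indicator saturation, genuine oscillatory
(rather than renewal) dynamics, state-dependent rates, and possible
inhibitory interactions (e.g. delta→beta), none of which are generated.
The raw-concordance subtlety below is one concrete consequence of the
model's simplicity.

# Spatial coupling decisions

The **islet core** is the unweighted centroid of all non-neuron cells
(the notion of "core" is not standardised; the centroid is the simplest
declared choice). The **distance axis** for coupling-versus-distance
plots is the per-animal decile rank (1 = closest, 10 = farthest) of
pairwise Euclidean distance: fixed physical bins would leave some
animals with empty categories, whereas ranks give every animal the full
axis. Binning is by stable sort, so ties resolve deterministically and
bin sizes differ by at most one pair. If an animal has fewer pairs than
ranks the rank count is reduced with a recorded warning.

**Slope/elevation comparison.** Two groups are compared by the classic
two-phase sequence: first the slope difference, then — slopes being
compatible — the elevation (intercept) difference under a common slope.
`coupling_regression()` offers two methods:

* `method = "pooled"` fits OLS to every animal-by-rank point and tests
  the slope×group interaction, then the group term of the common-slope
  model. This is the comparison as graphing software typically runs it,
  but it treats all points as independent. Each animal contributes a
  whole curve, and whole curves shift up or down together (shared-drive
  sampling noise and geometry vary by animal), so under a true null the
  pooled elevation test rejects far too often — in the package's own
  50-run null calibration at the default conditions it retained the
  null only about half the time.
* `method = "animal"` (the default) summarises each animal by its own
  OLS slope and its elevation (mean R across its ranks, i.e. the fitted
  value at the centre of the rank axis) and compares groups by
  two-sample t-tests on those per-animal summaries. Animals are the
  independent units, so this test is calibrated (null retention ≈ 95%
  in the same check) and it is the method the acceptance criteria are
  evaluated with.

# Fraction-time decisions

Pairing is directional from the first-listed type: each delta cell is
paired with its Euclidean-nearest beta cell for the delta–beta analysis
(partners may repeat; distance ties break to the lowest partner id).
This makes the number of pairs equal to the number of first-type cells,
matching per-animal pair accounting. The two mixed states are kept
directional. Both pair-level and per-animal aggregation of the
fractions are possible downstream; the pipeline writes pair-level rows.

Two numerical points:

* **Exact conservation.** Three occupancies are plain count/n ratios;
  the both-silent occupancy is computed as the complement of a
  swap-invariant partial sum. With four independently rounded ratios
  the sum differs from 1 by an ulp in a noticeable fraction of random
  cases; with the complement construction conservation and A/B swap
  symmetry hold *exactly* in floating point, and the tests assert
  equality, not closeness.
* **Raw versus chance-corrected concordance.** In this generative model
  a larger coupling weight also raises a cell's marginal activity (more
  accepted events), so the raw concordance
  $f_{both\,active}+f_{both\,silent}$ is *not* monotone in the coupling
  weight. The monotone quantity is the chance-corrected concordance —
  observed concordance minus the independence expectation
  $p_a p_b + (1-p_a)(1-p_b)$ computed from the same marginals — and
  that is what the property test checks.

# Transient detection

Peaks are local maxima of the normalised trace with topographic
prominence ≥ `min_prominence` (default 0.2); of any two retained peaks
closer than `min_spacing_frames` (default 2) only the higher survives.
Duration is the width at half prominence with linear interpolation
(full-width-at-base is not offered; half-prominence width is robust to
baseline level), converted to seconds. Frequency is
$60\,n_{events}/(n_{frames}\,\Delta t)$ per minute. All parameters are
surfaced in `analysis_config()` and recorded in outputs.

A resolution limit worth knowing: at the default 5-s frame interval
with a 2.5-s decay kernel, two events landing in the same or adjacent
frames produce a single local maximum — they are unresolvable in
principle, giving a deterministic undercount of roughly the
probability of a ≤2-frame gap (about 15% at 2 events/min). The
frequency-recovery validation therefore runs the generator at 1-s
frames, where the kernel is properly sampled; at that resolution the
detector recovers the planted rate to within ten percent, limited by
residual ≤2-s collisions. Oscillation-frequency comparisons *between*
conditions at 5 s are still meaningful (the undercount is common to
both groups), but absolute rates at 5-s sampling are lower bounds.

# Group statistics

The tests themselves (t, paired t, one/two-way ANOVA) are delegated to
R's `stats` machinery; what is implemented in-package is the
**Holm–Sidak step-down adjustment**, since no base-R `p.adjust` method
provides it: with ordered raw p-values $p_{(1)} \le \dots \le p_{(m)}$,

$$\tilde p_{(i)} = 1 - (1 - p_{(i)})^{\,m-i+1},$$

monotonised by a running maximum and capped at 1. Pairwise contrasts
after ANOVA use pooled-variance t statistics on the model's residual
error (the convention of the graphing software typically used with such
figures), adjusted across all contrasts; for the two-way design the
contrasts are group differences within each level of the second factor.
The acceptance suite verifies the adjustment against closed-form hand
computations and the two-sample comparison's type-I error against a
1000-replicate simulated null.

# Problem sizes used in the packaged checks

The default in-silico experiment is 10 intact versus 10 perturbed
animals (perturbation factor 0.4), 40 beta cells per islet, 720 frames
at 5 s; null calibrations rerun the same design 50 times with both
groups intact; distance-decay sign checks use 50 five-animal cohorts;
classification checks pool 50 single-islet runs; the statistical null
uses 1000 replicates. These sizes were chosen to estimate each
operating characteristic to within a few percent while keeping the full
suite runnable on a laptop in about a minute.

# Known limitations

* Perturbations are a single multiplicative factor on coupling weights;
  sign-changing effects (e.g. a delta-active/beta-silent state that
  *increases* under inhibition) are outside the default generative
  model, though an inhibitory interaction could be added on top.
* The pooled regression comparison is provided for compatibility but is
  anticonservative with clustered (per-animal) points; use the default
  animal-level method for inference.
* No ΔF/F with rolling baseline, motion correction, or microscope-format
  ingestion: the pipeline starts from segmented ROI traces in CSV form.
* Absolute event rates at 5-s sampling are lower bounds (see transient
  detection above).
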