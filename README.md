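# isletconn

Functional-connectivity analysis of multicellular calcium imaging in
pancreatic islets.

In vivo volumetric calcium imaging of an islet (a slow indicator such as
GCaMP6s, one z-stack every 5 s for 1–2 h) yields a fluorescence trace per
segmented cell together with its type label (beta / alpha / delta /
unknown, plus peri-islet neurons) and 3D centroid. `isletconn` turns those
ROI tables into the quantities such studies report, and ships a
synthetic-islet generator with known ground truth so the whole pipeline
can be exercised, calibrated and power-analysed without any raw imaging
data. It is written for systems-biology and islet-physiology labs doing
network-level analysis of endocrine coordination and its neural
modulation.

## What it computes

* **Coupling.** Pairwise Pearson correlation matrices per condition
  window (basal `LG`, glucose-stimulated `HG`, post-perturbation), and
  the average correlation coefficient over all unordered pairs of a type
  composition,

  $$R_{avg}(a,b) = \frac{1}{|P_{ab}|}\sum_{(i,j)\in P_{ab}} R_{ij},$$

  per animal — homotypic (beta–beta, …) and heterotypic (delta–beta, …).
* **Neural activity connection.** An endocrine cell is *connected* when
  its best correlation with an imaged peri-islet neuron reaches a
  criterion (default 0.5); per-type percentages are normalised to the
  number of cells imaged, and homotypic coupling can be split by
  connection status for paired tests.
* **Connectivity maps.** Thresholded graphs with node degree and edge
  weight, exportable with cell coordinates for plotting.
* **Distance dependence.** $R_{avg}$ by per-animal decile rank of
  pairwise distance (1 = closest, 10 = farthest), with OLS fits per
  group and the classic two-phase slope/elevation comparison between
  groups (a calibrated animal-level method is the default; the pooled
  point-wise comparison is available).
* **Fraction-time analysis.** For each nearest heterotypic pair, the
  occupancy of the four joint states — both active, both silent, and the
  two directional mixed states — on binarised traces; the four fractions
  sum to 1 exactly.
* **Transient metrics.** Prominence-based peak detection: event
  frequency (events/min), peak height, half-prominence duration.
* **Group statistics.** Two-sample and paired t-tests, one/two-way
  ANOVA contrasts with the Holm–Sidak step-down adjustment
  $\tilde p_{(i)} = 1-(1-p_{(i)})^{m-i+1}$ (monotonised).

The simulator plants a beta-core/alpha-mantle geometry and generates
binary event trains: a private Poisson component, one shared drive train
per type pair accepted with probability
`coupling × exp(−d/λ) × perturbation_factor`, and a neuron train driving
a flagged subset of cells; trains are convolved with a double-exponential
indicator kernel and noise is added. Chronic/acute neural-inhibition
experiments are emulated purely as the coupling-attenuation factor.

## Worked example

Ten-versus-ten is the default in-silico experiment; here a smaller one:
six intact animals against six with all coupling attenuated to 0.4
(chronic neural inhibition), analysed in the glucose-stimulated window.

```r
library(isletconn)

cfg <- simulation_config(perturbation_factor = 0.4, seed = 42)
intact    <- make_cohort(cfg, n_animals = 6, seed = 42)
perturbed <- make_cohort(cfg, n_animals = 6, perturbed = TRUE, seed = 43)

summarise_animal <- function(an) {
  nt   <- normalize_traces(an$traces, "HG")
  corr <- correlation_matrix(nt, an$cells)
  list(ravg = as.numeric(r_avg(corr, "beta", "beta")),
       dc   = rank_distances(an$cells, corr, "beta", "beta"))
}
si <- lapply(intact, summarise_animal)
sp <- lapply(perturbed, summarise_animal)

round(vapply(si, `[[`, numeric(1), "ravg"), 3)
#> [1] 0.264 0.264 0.252 0.239 0.267 0.249
round(vapply(sp, `[[`, numeric(1), "ravg"), 3)
#> [1] 0.089 0.094 0.076 0.087 0.090 0.093
```

Per-animal beta–beta `R_avg` sits around 0.26 in intact islets and drops
to about 0.09 under attenuation. The group test and the
coupling-versus-distance comparison:

```r
cmp <- compare_groups(
  data.frame(r = c(vapply(si, `[[`, numeric(1), "ravg"),
                   vapply(sp, `[[`, numeric(1), "ravg")),
             group = rep(c("intact", "perturbed"), each = 6)),
  "r", "group", design = "t")
cmp
#> <comparison_result> t with holm_sidak adjustment
#>             contrast  estimate        p_raw n_a n_b        p_adj
#>  intact vs perturbed 0.1675358 1.862075e-11   6   6 1.862077e-11

reg <- coupling_regression(lapply(si, `[[`, "dc"), lapply(sp, `[[`, "dc"),
                           labels = c("intact", "perturbed"))
reg
#> <coupling_regression> method: animal
#>      group        slope     slope_lo     slope_hi  intercept intercept_lo
#>     intact -0.004628538 -0.006521724 -0.002735351 0.28117586   0.26942895
#>  perturbed -0.001314904 -0.002341153 -0.000288655 0.09541503   0.08904732
#>  intercept_hi
#>     0.2929228
#>     0.1017827
#> p(slope diff) = 0.04317, p(elevation diff) = 1.862e-11
```

Coupling declines with distance rank in both groups (negative slopes),
and the attenuated cohort's regression sits far below the intact one —
an elevation difference at `p ≈ 2e-11` — which is exactly the signature
a loss of coordinating input leaves on islet connectivity.

`run_islet_pipeline()` packages all stages (simulate → preprocess →
connectivity → spatial → fraction-time → spikes → compare) into one
reproducible run that writes every stage table, optional diagnostic
figures, and a JSON manifest; `inst/scripts/isletconn.R` is a thin
command-line wrapper around it.

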