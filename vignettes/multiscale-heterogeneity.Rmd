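---
title: "Multiscale heterogeneity mapping of normative deviations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale heterogeneity mapping of normative deviations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Case–control comparisons of regional brain phenotypes (for example grey
matter volume, GMV) average over individuals, yet individuals with the
same diagnosis rarely express abnormalities in the same places. normhet
implements an individual-first alternative: a **normative model** learns
the reference range of each region's phenotype given age, sex and scan
site in a training cohort of controls; held-out individuals are scored
as deviation z-maps; and the *spatial overlap* of each group's extreme
deviations is then analysed at three scales — single regions, the
functional circuits coupled to deviant regions, and extended functional
networks — under two complementary permutation null models.

# The normative model

For subject $i$ and region $j$, the phenotype is first Box–Cox
transformed ($\lambda_j$ estimated per region by maximum likelihood on
the training controls, searched on $[-2, 2]$ with ties toward the
identity). The transformed value $y_{ij}$ is modelled within each
(site, sex) *batch* $b$ as

$$y_{ij} = \alpha_{bj} + \beta_{bj}\,(\mathrm{age}_i - \bar a) +
  \varepsilon_{ij},\qquad \varepsilon_{ij} \sim N(0, \sigma_{bj}^2),$$

with partial pooling of the batch intercepts and age slopes toward
shared priors. The fitting backend is a two-stage empirical-Bayes
procedure: per-batch least squares, then conjugate shrinkage toward
method-of-moments hyperpriors. Three choices deserve note:

* **Between-batch variances are pooled across regions.** The unbiased
  moment estimate of the between-batch variance $\tau^2$ is averaged
  over regions before truncation at zero. For a volumetric phenotype
  the dominant site and sex effects are global (scanner hardware,
  sequence, head size), so the cross-region average is well targeted;
  statistically it removes the upward bias that per-region truncated
  estimators suffer when batches are actually exchangeable, which is
  what makes the model collapse cleanly to the pooled fit on
  single-site-like data. This mirrors how variance moderation pools
  hyperparameters across genes in differential-expression models.
* **Noise scales are estimated per batch, without pooling.** Deviation
  z-scores divide by the noise scale, so any pull of a genuinely quiet
  or noisy site toward the prior mean mis-scales that site's entire
  z-map one-for-one; with at least `min_batch` training subjects per
  batch the unpooled estimates are stable, and held-out z calibration
  — the quantity the model exists to deliver — is measurably better
  without the pull. The shared-prior hyperparameters for the noise are
  still estimated and reported for inspection.
* **The z denominator combines two scales.** Deviations are
  $z_{ij} = (y_{ij} - \hat y_{ij})\,/\sqrt{\sigma_{ij}^2 +
  \sigma_{nj}^2}$, where $\sigma_{ij}$ is the epistemic standard error
  of the prediction at the subject's age and batch (posterior variance
  of the shrunken coefficients) and $\sigma_{nj}$ is the batch noise
  scale (the normative population spread). On held-out controls from a
  correctly specified generator these z-scores are standard normal,
  which the test suite checks directly.

Batches with fewer than `min_batch = 10` training controls are
excluded, sites keep all controls for training unless they have at
least 30 (then 10% are held out), and a site whose cases drop below 10
after cell exclusion is dropped — the multi-site stratification rules
the train/test split enforces.

Model quality is monitored by explained variance, standardised MSE and
mean standardised log-loss under stratified 5-fold cross-validation,
and by a *site-leakage* diagnostic: one-versus-all linear SVMs (slack
parameter 1, two-fold CV) trying to decode the scan site from the
z-maps. Balanced accuracy at 50% means the site variance has been
absorbed by the model rather than leaking into the deviations. Because
a single two-fold split of a small held-out set is noisy, the score
supports repeated splits (`repeats`), which lowers the Monte-Carlo
error of the same estimand.

# Extreme deviations and the three scales

A region is an extreme deviation when $z > 2.6$ (positive) or
$z < -2.6$ (negative) — strict inequalities; 2.6 corresponds to an
uncorrected one-sided tail below 0.005. Positive and negative extremes
run through separate, parallel pipelines.

* **Regional overlap** — per region, the proportion of a group's
  members with an extreme there; the unit of inference is the
  case-minus-control difference (Δ overlap). A threshold-weighted
  variant integrates survival proportions over 100 log-spaced
  thresholds in (1.64, 3.10), weighted by the linear ramp
  $W_{th} = 2(th - z_{\min})/(z_{\max} - z_{\min})$ and normalised by
  the maximum attainable weighted area so values lie in $[0, 1]$. (The
  printed ramp reaches 2 at $z_{\max}$; normalising by the total
  weight is the reading that makes the advertised $[0,1]$ range exact.
  Weights are applied before integrating over thresholds.)
* **Circuit overlap** — each deviant region is used as a seed in a
  normative functional-connectivity atlas: seed-mean time course,
  Pearson correlation to every grayordinate, Fisher r-to-z, a
  one-sample t-test across atlas subjects, threshold-free cluster
  enhancement (TFCE) on the grayordinate graph, and max-statistic
  sign-flip FWE thresholding at 0.025 per compartment (0.05 halved
  across cortex and subcortex, run separately). A region joins the
  seed's circuit when strictly more than 50% (alternatively 75%) of
  its grayordinates survive. Per subject, the union (OR) of the
  circuits of that person's extremes gives the union map; circuit
  overlap is the group proportion of union maps covering each region.
  Circuits are computed once per unique seed and cached; the spatial
  null requires the cache to cover every region, so the pipeline
  builds all of them up front.
* **Network overlap** — a network (10-level: 7 canonical cortical
  networks plus medial temporal lobe, thalamus, basal ganglia;
  20-level: 17 cortical subnetworks plus the same 3) is deviant for a
  subject when at least one member region is extreme. Comparisons are
  case versus control within a network; between-network comparisons
  are confounded by network size and are not an output.

# Two null models

* **Group-label permutation** exchanges case/control labels (10,000
  permutations by default) and recomputes Δ overlap. It detects any
  difference in overlap, including differences driven simply by cases
  carrying more deviations (higher burden).
* **Spatial spin permutation** preserves burden. Each subject's
  unthresholded cortical deviation map is rotated on the sphere and
  re-assigned to regions by a cost-minimising bipartite assignment
  (Hungarian/Jonker–Volgenant), which is a bijection: the value
  multiset, and therefore the number of extremes per person, is
  preserved exactly. Subcortical values, for which no sphere exists,
  are shuffled per subject — a more lenient surrogate, acknowledged as
  such. One rotation is drawn per spin and applied to the right
  hemisphere with its mirror image on the left, preserving homotopy.
  Each subject draws its *own* spin per permutation from a precomputed
  pool shared between the circuit- and network-level tests. The
  per-subject draw is what realises the intended null — "the same
  number of seeds per person, placed at random": with a single
  rotation shared by all subjects the whole group's effect cluster
  travels together and the null at any one region becomes heavy-tailed,
  which destroys power for exactly the targeting effect the test
  exists to detect.

A region significant under both nulls indicates *preferential
targeting* of that circuitry; significant under the group test only,
the difference is attributable to burden. The cross-scale contrast
(circuit-level Δ minus regional Δ, inferred by group permutation)
asks whether case–control differences are larger at the circuit than
the regional scale; because both levels are group means of
subject-level indicators, the permutation reduces to a group test on
their elementwise difference.

# Permutation p-values and multiplicity

One-sided tail proportions use the add-one estimator
$(1 + \#\{T^\ast \ge T\})/(1 + n_{\mathrm{perm}})$, which never returns
zero and is exactly super-uniform under exchangeability. Two-tailed
p-values are $\min(1,\, 2\min(p_{\mathrm{up}}, p_{\mathrm{lo}}))$.
Very small p-values are refined with a generalized Pareto tail:
exceedances over the empirical 90th percentile are fitted by maximum
likelihood, screened by an Anderson–Darling test (parametric
bootstrap, 49 replicates), and the threshold is lowered 10 order
statistics at a time until the fit is accepted. The refinement is
applied **only when fewer than 10 permutation values reach the
observed statistic** — i.e. for extrapolation beyond counting
resolution. On the lattice-valued overlap statistics this guard
matters: a smooth tail model evaluated inside the countable range
undercounts tied mass and visibly inflates the type-I error, which the
calibration suite would catch. Benjamini–Hochberg correction at
q = 0.05 (two-tailed) is applied per sign, per scale and per null
model.

TFCE uses $E = 0.5$, $H = 2$ (the standard surface/graph setting) with
an adaptive step $dh = \max(\mathrm{stat})/100$ floored at $10^{-3}$;
only the positive part of the t-map is enhanced. The one-sample
aggregation of Fisher-z maps is read as a one-sample t against zero,
and its permutation null sign-flips whole subjects, exchangeable under
a symmetric null.

# The synthetic cohort generator

No clinical imaging data ship with the package; a generator produces
every input at configurable scale and is itself first-class, tested
code.

* **Parcellation** — cortical regions on a Fibonacci lattice per
  hemisphere (mirrored across the midline), subcortical regions in a
  central ball; 7 cortical networks as spherical Voronoi patches
  (spin tests need contiguous patches), refined into 17 nested
  subnetworks; grayordinates jittered around region centroids with a
  within-compartment k-nearest-neighbour adjacency, bridged to exactly
  one component per compartment.
* **Phenotype** — generated on the log scale and exponentiated:
  $y = \exp(b_j + \beta_{\mathrm{age}}\,\mathrm{age} +
  \beta_{\mathrm{sex}}\,1[\mathrm M] + u_{\mathrm{site}} +
  \varepsilon)$, $\varepsilon \sim N(0, s_{\mathrm{site}}^2)$. Strict
  positivity gives the Box–Cox step real work ($\hat\lambda \approx
  0$ expected). Defaults: ages uniform on 18–64, age slope −0.004
  log-units/year (a gentle volumetric decline), sex offset 0.05, site
  offsets $N(0, 0.05^2)$, site noise scales 0.08–0.14 — the scale of
  multi-site morphometry after segmentation.
* **Deviation scenarios** — cases receive $k$ seeded deviations, $k$
  zero-inflated Poisson ($p_0 = 0.25$, $\lambda = 8$; mean burden 6 —
  the observed burden distribution of a clinical group is not pinned
  down beyond totals, so the ZIP is a tunable default). At each seed
  the log-phenotype is shifted by `effect_size` (default 4) times the
  site noise scale, so the expected normative z at the seed equals
  −`effect_size` — calibrating the injection in z units makes
  detection probability controllable. Seeds are placed uniformly
  (`burden_only`), preferentially among regions whose normative
  coupling to a hub set exceeds the 80th percentile
  (`circuit_convergent`), or in a fixed list (`region_focal`).
* **FC atlas** — grayordinate series mix a latent per fine (20-level)
  network patch (weight `community_strength`, default 0.6), a weaker
  latent per coarse network (`community_strength * mix10`,
  `mix10 = 0.3`), an optional hub latent broadcast to the hub regions
  (weight 0.8), and unit noise. Communities at the fine scale keep
  seed circuits spatially specific — if whole coarse networks were
  the community unit, six random seeds per case would cover most of
  the brain's circuits and the targeting contrast would saturate.

What the generator does *not* emulate: cortical folding and real
geometry, spatially smooth phenotype noise, distance-dependent FC,
scanner drift, age nonlinearity, or diagnosis-specific spatial
patterns. Passing tests therefore demonstrate the *machinery* —
calibration, exactness, power under known truth — not fidelity to any
particular clinical population.

# Problem sizes and numerical choices

The test and acceptance suites run at desk scale, chosen as the
smallest sizes at which the contrasts of interest are identifiable:
200 regions (192 cortical + 8 subcortical, 4 grayordinates each), four
sites with 150 controls and 15 cases each (60 cases versus 60 held-out
controls after the 90/10 split), a 20-subject atlas with 150
timepoints, 500 sign-flip permutations for circuit FWE, and 2,000
permutations for the group and spatial tests. Type-I calibration is
probed two ways. The continuous per-region deviation values passed
through both tests verify that the machinery attains its nominal 5%
level. The thresholded indicators are probed at $z = 1$ (at $z = 2.6$
with 60 subjects per group most regions see no extreme in either
group, the Δ-overlap statistic is identically zero under permutation
and p = 1 by construction, so a rejection-rate check there would be
vacuous); being a discrete exact test on a lattice with spacing 1/60,
its attainable size is a little below nominal — around 4% — which is
the correct behaviour of an exact test, so the suite asserts the
guarantee it actually has: never above nominal, and not vacuously
conservative.

Degenerate inputs are handled explicitly: non-positive phenotypes are
a load error naming the offending cell; a batch with constant age or
constant phenotype is a fit error naming the batch; noise-free linear
data yield exact predictions with zero noise scales (and scoring such
data is then a division error, as it should be); correlations of
exactly ±1 are clamped before the Fisher transform; zero
across-subject variance in a t-map becomes a signed infinite sentinel
mapped to just above the largest finite height before enhancement.

# Limitations

The empirical-Bayes backend approximates the full posterior: slopes
and intercepts are shrunk independently (their finite-sample
covariance is dropped after centring age) and hyperparameter
uncertainty enters only through a plug-in variance term. Age enters
linearly. The subcortical spatial null is value-preserving but not
autocorrelation-preserving. Circuits are estimated in a normative
atlas and take no account of disorder-specific connectivity change.
Network labels are inputs, not discovered structure.
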