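# normhet

Normative modelling and multiscale heterogeneity mapping of regional
brain phenotypes.

## The problem

Individuals who share a psychiatric diagnosis rarely share the
location of their brain abnormalities, so group-average case–control
maps can misrepresent every individual in the group. normhet
implements an individual-first workflow for parcellated phenotypes
such as regional grey-matter volume (GMV):

1. **Normative model.** For each region $j$, the Box–Cox-transformed
   phenotype is regressed on age with (site × sex)-specific
   intercepts, slopes and noise scales, partially pooled toward
   shared priors (empirical-Bayes two-stage fit). Held-out individuals
   are scored as deviation z-maps:

   $$z_{ij} = \frac{y_{ij} - \hat y_{ij}}
     {\sqrt{\sigma_{ij}^2 + \sigma_{nj}^2}},$$

   where $\sigma_{ij}$ is the predictive (epistemic) uncertainty and
   $\sigma_{nj}$ the normative (population) scale. Extreme deviations
   are $|z| > 2.6$ (one-sided tail < 0.005), split by sign.

2. **Overlap at three scales.** Per group: the proportion of members
   with an extreme in each *region*; in each *circuit* (regions
   significantly functionally coupled to any of the person's deviant
   regions in a normative FC atlas — seed correlation, Fisher z,
   one-sample t, graph TFCE, sign-flip FWE at 0.025 per compartment,
   parcel rule > 50%); and in each functional *network* (deviant when
   ≥ 1 member region is extreme).

3. **Two permutation null models.** Case-minus-control overlap
   differences are tested by (a) group-label permutation, sensitive to
   any difference including deviation *burden*, and (b) a spatial spin
   null that rotates each subject's cortical deviation map on the
   sphere (value-preserving Hungarian assignment, per-subject
   rotations) and shuffles subcortical values — preserving each
   person's burden exactly, so significance means *preferential
   targeting* of that circuitry. Permutation p-values use add-one
   counting with a generalized Pareto tail for values beyond counting
   resolution, and Benjamini–Hochberg correction at q = 0.05.

A synthetic-cohort generator (spherical parcellation with nested
network labels, multi-site log-normal phenotypes with age/sex/site
effects, configurable deviation scenarios, and a community-structured
FC atlas) makes the entire pipeline runnable and testable without any
clinical data.

## Worked example

A four-site cohort (60 controls + 15 cases per site) with deviations
preferentially injected into regions coupled to a hub set, then the
full scoring and the burden-preserving spatial test:

```r
library(normhet)
scheme <- make_parcellation(n_cortex = 100, n_subcortex = 8,
                            gray_per_region = 4, seed = 1)
atlas  <- make_fc_atlas(scheme, n_subjects = 15, T = 150,
                        community_strength = 0.7,
                        hub_regions = c(5, 10, 15), seed = 2)
coupling <- region_coupling(atlas, scheme)
cohort <- make_cohort(scheme,
                      data.frame(site = paste0("site", 1:4),
                                 n_hc = 60, n_case = 15), seed = 3)
scenario <- deviation_scenario("circuit_convergent",
                               hub_set = c(5, 10, 15), seed = 4)
cohort <- inject_case_deviations(cohort, scheme, coupling, scenario)
cohort <- split_train_test(cohort, seed = 5)

fit <- normative(cohort)
fit
#> Hierarchical normative model: 108 regions, 8 batches (216 subjects)
#>   Box-Cox lambda: median -0.046 [-0.872, 1.359]
#>   reference age: 41.4 years

dev <- deviations(fit, cohort)
dev
#> Deviation maps: 84 subjects x 108 regions (|z| > 2.60)
#>   extremes: 79 positive, 351 negative

grp  <- dev$subjects$group
case <- which(startsWith(grp, "case")); ctrl <- which(grp == "HC_test")
burden <- deviation_burden(dev)
round(c(case = mean(burden$n_total[case]),
        control = mean(burden$n_total[ctrl])), 2)
#>    case control
#>    6.57    1.50

circuits <- build_circuits(atlas, scheme, n_perm = 200, seed = 6)
spatial <- spatial_null_test(dev, case, ctrl, scheme,
                             downstream = "circuit",
                             circuits = circuits, n_perm = 1000, seed = 7)
spatial
#> Permutation test (spatial null): 108 units, 69 significant at FDR
#>  unit       delta         p_unc         p_fdr sig_unc sig_fdr
#>     1 -0.02500000 4.450148e-308 1.044817e-307    TRUE    TRUE
#>     2  0.56666667 4.450148e-308 1.044817e-307    TRUE    TRUE
#>     5  0.58333333 4.450148e-308 1.044817e-307    TRUE    TRUE
#>     6 -0.03333333 4.450148e-308 1.044817e-307    TRUE    TRUE
#>     9 -0.02500000 4.450148e-308 1.044817e-307    TRUE    TRUE
```

Reading the output: the Box–Cox estimates sit near 0 (the generator is
log-normal, so the log transform is recovered); cases carry a mean
burden of 6.57 extreme deviations versus 1.50 in held-out controls
(the generator's zero-inflated Poisson has mean 6); and because the
injected deviations converge on the hub circuitry, the
burden-preserving spatial test is significant both where cases
over-couple (hub regions 2 and 5, Δ overlap ≈ 0.57–0.58 above random
placement) and where they under-couple (regions 1, 6 and 9, observed
Δ slightly negative against a strongly positive null of random seed
placement). p-values far below the
permutation resolution come from the generalized-Pareto tail; values
beyond the fitted tail's support are floored at the smallest
representable double. A `group_permutation_test()` on the same union
maps, a regional analysis on `dev$neg`, network-level aggregation via
`assign_networks()`/`network_deviance()`, and the circuit-versus-
regional `crossscale_contrast()` complete the picture; `run_pipeline()`
orchestrates all of it onto disk with a manifest.

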