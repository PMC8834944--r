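# outletndi

Bayesian shared-component index models for tobacco and alcohol retail
outlet rates.

## The problem

Tobacco retail outlets (TROs), alcohol retail outlets (AROs), and outlets
selling both (TAROs) cluster unevenly across neighborhoods, and their
density is a community-level risk factor for tobacco and alcohol use. Two
questions drive the analyses this package supports:

1. **Which businesses sell both products?** TRO and ARO listings come from
   different registries with discordant names, addresses and geocodes, so
   dual outlets must be identified by record linkage.
2. **How do outlet rates relate to neighborhood disadvantage?** Rather than
   fixing an index of disadvantage a priori, the weights of the index are
   estimated jointly with its association with each outlet type, while
   spatially structured confounding is absorbed by shared and
   outlet-specific random effects.

The package is aimed at spatial epidemiologists and health-policy
researchers working with areal (block-group level) outlet counts and
sociodemographic covariates.

## The methods

**Record linkage.** Listings are normalized (upper case, punctuation
stripped except `&`, canonical street suffixes, store identification
numbers removed), then every TRO/ARO pair within a block group is scored

```
sim(t, a) = 0.25 namesim(t,a) + 0.25 addresssim(t,a)
          + 0.20 I(dist(t,a) < 520.9 ft) + 0.30 I(dist(t,a) < 260.45 ft)
```

where string similarity is one minus the optimal-string-alignment
(restricted Damerau–Levenshtein) distance divided by the longer length,
and `dist` is the great-circle distance. Pairs scoring ≥ 0.70 are matched
greedily one-to-one; matched pairs become TAROs. Block groups with only one
class fall back to a list of known dual-selling chains.

**The model.** Counts per block group i and outlet type k follow

```
y_ik ~ Poisson(theta_ik * E_ik),    E_ik = r_k * p_i
log(theta_ik) = alpha_k + beta_k * (sum_j w_j q_ij) + u_i + v_i + s_ik
```

with decile-scored covariates `q_ij` (per-capita income inverted first),
index weights `w` on the simplex with a Dirichlet prior, flat intercepts,
`beta_k ~ Normal(1, sigma_beta^2)` with `sigma_beta ~ Uniform(0, 100)`,
`u_i` iid normal (shared, unstructured), and intrinsic CAR priors on the
shared `v_i` and outlet-specific `s_ik` with `Gamma(0.05, 0.005)`
precisions. `exp(beta_k)` is the relative risk per one-decile increase of
the neighborhood disadvantage index (NDI); `exp(u_i + v_i)` is the risk
surface shared by all three outlet types. Fitting is adaptive
Metropolis-within-Gibbs (C++ core), with exceedance probabilities
`Pr(theta_ik > 1) >= 0.90` flagging significantly elevated units.

## Worked example

Everything below runs on synthetic data with known truth (no external data
needed). The generator simulates a lattice of block groups from the model
above with true effects `beta = log(1.12, 1.15, 1.21)` and weights
`(0.60, 0.23, 0.09, six small)` attached to the first covariates:

```r
library(outletndi)
cfg   <- synthetic_config(lattice_rows = 15, lattice_cols = 15,
                          baseline_rate = 0.01, seed = 1)
synth <- generate_areal_dataset(cfg)
dat   <- prepare_ndi_data(filter_units(synth$block_groups)$records,
                          synth$adjacency)
fit   <- fit_shared_car(dat, config = model_config(n_iter = 8000,
                                                   n_burnin = 4000, seed = 1))
fit
#> ndi_draws: 4000 stored draws x 2 chain(s); 225 units, 9 index weights
#> posterior median RR per decile of disadvantage: TRO 1.144, ARO 1.183, TARO 1.260

ndi_effect_rr(fit)$effects
#>   outlet_type rr_median rr_lo rr_hi
#> 1         TRO      1.14  1.12  1.17
#> 2         ARO      1.18  1.16  1.21
#> 3        TARO      1.26  1.23  1.30
```

The fitted NDI effects reproduce the generating ordering (TARO > ARO >
TRO, with `Pr(beta_TARO > beta_ARO) = 1.00` across draws); the TARO
estimate runs slightly above its true value 1.21 because the weight
posterior is still shrunk toward uniformity at 225 units (see the methods
vignette). The leading index weight is recovered:

```r
ws <- ndi_summary(fit)$weights
ws[order(-ws$weight_median), 1:4][1:2, ]
#>      covariate weight_median weight_lo weight_hi
#> 1    seg_black          0.55    0.4579      0.67
#> 2 seg_hispanic          0.13    0.0342      0.21
```

(`seg_black` is the first covariate column, i.e. the one carrying the true
weight 0.60.) Density-category summaries report the mean posterior-median
relative risk and the fraction of units flagged elevated
(`Pr(theta > 1) >= 0.90`) per rural/suburban/urban stratum:

```r
rr <- summarize_rr(fit)
density_table(rr, dat$records)
#>    density outlet_type mean_rr pct_significant n_units
#> 1    rural         TRO   0.963           0.234     188
#> 3    urban         TRO   1.192           0.389      18
#> ...
```

Record linkage runs the same way on listing tables:

```r
lsim <- generate_listing_pairs(listing_sim_config(n_taro_true = 200, seed = 1))
m    <- run_matching(lsim$listings, lsim$known_chains)
m
#> ndi_match: 40 block groups; 54 TRO, 54 ARO, 196 TARO
```

196 of the 200 true dual outlets are linked despite the injected typos and
coordinate jitter (sensitivity 0.98 against the generator's ground truth);
the four missed pairs remain in the single-class counts.

A subcommand CLI (`inst/cli/outletndi`) chains the stages
(`simulate | match | prepare | fit | summarize | pipeline`) over CSV/YAML
files and writes a JSON run manifest per stage.

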