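# fearspace

Searchlight cross-decoding of conditioned and phobic fear representations
in fMRI — an R implementation of the full analysis chain, exercised
end-to-end on synthetic data with known representational geometry.

## The question and the method

Fear conditioning changes how a previously neutral stimulus is represented
in the brain. Does the new representation move *toward* the representation
of a pre-existing feared (phobic) stimulus — i.e., toward an abstract "state
of fear" — and back after extinction? `fearspace` implements the analysis
designed to answer this with three stimulus classes: a neutral class (NS), a
phobic class (PS), and a to-be-conditioned class (CS+), measured across
baseline, conditioned and extinction phases (plus one conditioning run that
is never analyzed).

The chain, stage by stage:

1. **Single-trial GLM** (`fit_trial_tmaps`): one gamma-HRF-convolved
   regressor per trial (least-squares-all), six motion nuisance regressors,
   discrete-cosine high-pass (100 s cutoff); the classifier consumes the
   per-trial *t*-score maps. Shock-reinforced CS+ trials are modeled
   separately and never tested.
2. **Searchlight cross-decoding** (`cross_decode`): in every 50-voxel
   searchlight, a shrinkage-regularized linear discriminant
   (Σ + λ·mean(diag Σ)·I, λ = 0.01) learns NS vs PS pooled across phases,
   then labels the held-out run's CS+ trials under leave-one-run-out
   cross-validation. The per-voxel, per-phase statistic is
   P(CS+ labeled PS) — the probability the conditioned stimulus is read as
   phobic.
3. **Group inference** (`quadratic_coefficients`, `signflip_null`,
   `threshold_clusters`): the three-phase profile is summarized per voxel by
   the quadratic coefficient *a* = (y₁ + y₃)/2 − y₂ at phase codes
   (−1, 0, +1); an inverted-U (conditioning effect) means *a* < 0. One-tailed
   one-sample *t* maps are corrected by sign-flip Monte Carlo resampling with
   threshold-free cluster enhancement (E = 0.5, H = 2, dh = 0.1) and
   max-statistic FWER control, with empirical p = (b + 1)/(m + 1); maps are
   thresholded at z = 2.5758 (p < 0.005) and clusters extracted at
   26-connectivity.
4. **Representational similarity** (`similarity_table`, `compare_models`):
   around each surviving cluster's peak, cos∠(NS, CS+) and cos∠(PS, CS+) of
   detrended class-average patterns adjudicate among three models of the
   conditioning effect — CS+ moves toward PS (θ_p shrinks by ε₂), away from
   NS (θ_n grows by ε₁), or both — and Fisher-transformed cosines are
   correlated with decoding performance (Pearson r, family-wise threshold
   p < 0.005).
5. **ROI control** (`roi_decode`): within-phase CS+ vs PS decoding and
   CS+/PS cosines in a fixed region, with repeated-measures F tests across
   phases — the check that phase effects are not mere changes in visual
   category information.

The **synthetic-data generator** (`design_config`,
`representational_geometry`, `simulate_cohort`, `generate_bold`) reproduces
the experimental design — 8 runs (2 baseline, 1 conditioning, 3 conditioned,
2 extinction), 36 trials per standard run (6 images × 2 repetitions × 3
classes) and 24 in the conditioning run, no class more than twice in a row,
inter-trial intervals 6 + X s with X ~ geom(0.3) truncated at 10 s (8 s
while conditioning), shocks on 6/12 CS+ trials while conditioning and 4/12
in each conditioned run — and plants class prototypes whose pairwise angles
evolve exactly as a chosen geometric model prescribes, so every stage can be
tested against ground truth.

## Worked example

A desk-scale cohort (8 participants, 8×8×8 grid, 3×3×3 informative block)
generated under model B — θ_p: 60° → 20° → 60°, θ_n fixed at 40°:

```r
library(fearspace)
mask <- array(FALSE, c(8, 8, 8)); mask[3:5, 3:5, 3:5] <- TRUE
cfg <- pipeline_config(
  design   = design_config(n_participants = 8),
  geometry = representational_geometry("B", grid_shape = c(8, 8, 8),
                                       informative_mask = mask),
  searchlight_n = 33, n_permutations = 200, seed = 11)
res <- run_pipeline(cfg)

res$report$phase_profile
#>                   phase informative background
#> baseline       baseline       0.272      0.467
#> conditioned conditioned       0.608      0.506
#> extinction   extinction       0.273      0.472
```

Inside the informative block the probability of calling the CS+ phobic goes
low/high/low over the phases (the inverted-U signature); background voxels
stay near chance. Group inference localizes the effect:

```r
as.data.frame(res$inference$clusters)
#>   cluster_id n_voxels peak_i peak_j peak_k peak_stat  p_fwer z_of_p
#> 1          1       24      3      4      3     -6.11 0.00498   2.58
```

One cluster of 24 voxels survives FWER correction, peak t(7) = −6.11
(negative curvature) at voxel (3,4,3) — inside the planted block. The
similarity follow-up recovers the generating model:

```r
res$similarity[[1]]$verdict$verdict        # "B"
res$similarity[[1]]$verdict$delta_theta_p_deg  # -27: theta_p shrank
res$similarity[[1]]$correlation
#> r_p = 0.749 (p = 2.5e-05)   r_n = -0.400 (p = 0.053)
```

The PS–CS+ cosine correlates with decoding performance (significant at the
0.005 family-wise threshold); the NS–CS+ cosine does not — the classifier's
behavior is driven by the CS+ moving toward the phobic representation, not
away from the neutral one.

See `vignettes/fearspace-methods.Rmd` for the model assumptions, parameter
choices and limitations.

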