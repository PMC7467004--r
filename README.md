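# convmode

Composite-likelihood inference of modes of convergent adaptation from
population allele frequencies.

When the same locus shows evidence of selection in several populations,
the adaptive allele may have arisen independently in each population, may
have spread between them by migration from a single origin, or may have
been standing at low frequency in their common ancestor before selection
began. These histories leave distinct footprints in the covariance of
allele frequencies around the selected site. convmode fits
coalescent-based models of each mode by composite likelihood over a
user-chosen parameter grid and reports maximum composite-likelihood
estimates (MCLEs) in one tidy table, for population geneticists analyzing
candidate regions across three or more selected and three or more
non-selected populations.

## The model in brief

Per site, each population's sample frequency is standardized against the
across-population mean ε: `z_i = (x_i − ε) / sqrt(ε(1−ε))`. Under drift
the deviations are approximately multivariate normal with covariance
`ε(1−ε) F`, where the coancestry matrix `F` is estimated from unlinked
neutral sites. Each mode of convergent adaptation transforms `F` into a
model covariance `F'(r)` at recombination distance `r` from a proposed
selected site, built from the probability a lineage stays attached to the
sweeping haplotype through the sweep,

    y(r) = exp(−(r/s) · ln(4 Ne s)),

plus mode-specific terms: forced within-population coalescence for
independent origins (`F'_ii = y² + (1−y²) F_ii`), coalescence on the
shared standing haplotype at rate `κ = 1/(2 Ne g)` for standing variation,
and tracing into the source with probability `q = y·exp(−r/m)` for
migration. The composite log-likelihood sums the per-site Gaussian
log-density of mean-centered deviations under
`Σ(r) = C (F'(r) + diag(1/n)) Cᵀ` over the candidate region, evaluated on
a grid of selection coefficients, migration rates, standing times and
frequencies, source populations and proposed sites. Mixed modes assign
different modes to disjoint subsets of the selected populations. See the
methods vignette (`vignettes/convergent-adaptation-cle.Rmd`) for the full
derivations and design choices.

## Worked example

Simulate the reference scenario — six populations, three of which
(indices 1, 3, 5) independently fixed a beneficial mutation at position 0
with s = 0.05 — and fit the neutral, independent and migration models on
the reference parameter grid:

```r
library(convmode)
library(dplyr)

scn <- simulation_scenario(seed = 1)
dat <- simulate_scenario(scn)
grid <- example_grid()
cfg <- run_config(Ne = 10000, rec = 0.005, selected_pops = c(1, 3, 5),
                  n_sites = 10, num_bins = 50,
                  sels = grid$sels, migs = grid$migs, times = grid$times,
                  gs = grid$gs, sources = grid$sources,
                  locus_name = "test_locus")
ctx <- build_context(dat$neutral, dat$selected, cfg)

neut <- fit_mode(ctx, "neutral")
all_mods <- bind_rows(fit_mode(ctx, "independent"),
                      fit_mode(ctx, "migration"))
all_mods %>% mcle_summary() %>% select(selected_sites, sels, cle, model)
#> # A tibble: 2 × 4
#>   selected_sites  sels   cle model
#>            <dbl> <dbl> <dbl> <chr>
#> 1              0  0.03 -691. independent
#> 2              0  0.03 -691. migration

unique(neut$cle)
#> [1] -877.99
```

Both selection models place the selected site at the grid position nearest
the true site (0) and far above the neutral composite log-likelihood
(−691 vs −878); the estimated selection coefficient (0.03) sits one to two
grid cells below the simulated truth (0.05), a known small-sample behavior
of the method discussed in the vignette. `plot_profile(all_mods,
unique(neut$cle))` draws the composite-likelihood surface along the region;
`tidy()` and `glance()` give broom-style summaries; `write_results()` /
`read_results()` round-trip the 10-column results table through CSV. A thin
command-line wrapper is installed as `exec/convmode`
(`convmode fit|simulate|summarize`).

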