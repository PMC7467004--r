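---
title: "Composite-likelihood inference of modes of convergent adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite-likelihood inference of modes of convergent adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

When several populations adapt to the same pressure at the same locus, the
adaptive allele can have reached them in qualitatively different ways: each
population may have gained its own mutation (independent origin), a single
mutation may have spread between populations by migration, or the allele
may have been standing at low frequency in their common ancestor before
selection began. These histories leave different footprints in allele
frequencies around the selected site, and convmode infers which history
fits best by comparing composite likelihoods across a user-chosen parameter
grid.

```{r setup}
library(convmode)
library(dplyr)
```

## The model

### Neutral baseline

The data are sample allele frequencies: a populations-by-sites matrix for
putatively neutral, unlinked sites, and another for the candidate region,
with genomic positions for the latter. At every site, each population's
frequency is expressed as a standardized deviation from the
across-population mean $\epsilon$ (a proxy for the ancestral frequency):

$$ z_i = \frac{x_i - \epsilon}{\sqrt{\epsilon(1-\epsilon)}}. $$

Sites whose mean frequency is exactly 0 or 1 carry no information and are
dropped (counted and reported). Under neutral drift the deviations across
$k$ populations are approximately multivariate normal with covariance
$\epsilon(1-\epsilon)\,F$, where $F$ is the coancestry matrix shared by all
analyses. `estimate_neutral_coancestry()` averages outer products
$z_i z_j$ over neutral sites.

Two subtleties follow from the standardization. First, because $\epsilon$
is the mean over the populations themselves, deviations sum to zero at
every site; $F$ therefore lives on the mean-centered scale and its $k
\times k$ form is singular. The likelihood works in the $(k-1)$-dimensional
image of the centering projection (`centering_projection()`), which keeps
the Cholesky fast path available. Second, sample frequencies carry binomial
noise of roughly $1/n_i$ per population on the standardized scale ($n_i$
haploid samples). The model covariance adds $\mathrm{diag}(1/n_i)$
explicitly, so the estimator removes the expected sampling contribution
$A\,\mathrm{diag}(1/n_i)\,A$ (with $A = I - J/k$) from the raw average —
noise must be counted exactly once. With this correction the estimator is
consistent for a centered drift coancestry: on 200k simulated sites it
recovers the generating matrix to within 0.02 in max-abs error even at
sample size 10 (the test suite and the acceptance script both recompute
this).

### Sweep kernels

Each mode of convergent adaptation transforms $F$ into a model covariance
$F'(r)$ at recombination distance $r$ (Morgans/generation) from a proposed
selected site; $r = \mathrm{rec} \cdot |\mathrm{position} -
\mathrm{proposed\ site}|$, with positions used verbatim in their native
units. The shared ingredient is the probability that a lineage stays
associated with the sweeping haplotype through the sweep,

$$ y(r) = \exp\!\left(-\frac{r}{s}\,\ln(4 N_e s)\right), $$

using the classical hard-sweep duration $\ln(4N_e s)/s$ generations. The
precondition $4 N_e s > 1$ is enforced; $y(0) = 1$ and $y$ decays
monotonically.

* **Independent mutations.** Two lineages in a selected population both
  retained through its sweep coalesce there:
  $F'_{ii} = y^2 + (1-y^2)F_{ii}$. Nothing else changes — independent
  origins add no cross-population coancestry.

* **Standing variation.** Before selection, the variant segregated at
  frequency $g$ for $t$ generations. On that background two lineages
  coalesce at rate $\kappa = 1/(2 N_e g)$ while each escapes by
  recombination at rate $r$ (total $2r$), giving the within-phase
  coalescence probability
  $p_{\mathrm{coal}} = \frac{\kappa}{\kappa + 2r}\left(1 -
  e^{-(\kappa+2r)t}\right)$, and — for lineages from different populations
  meeting on the shared ancestral standing haplotype — the unbounded-time
  version $p_{\mathrm{shared}} = \kappa/(\kappa + 2r)$. Selected
  off-diagonals become $y^2(p_{\mathrm{shared}} +
  (1-p_{\mathrm{shared}})F_{ij}) + (1-y^2)F_{ij}$. Within a population,
  lineage pairs that neither coalesce nor recombine during their own
  $t$-generation standing phase (probability $e^{-(\kappa+2r)t}$) continue
  into that same ancestral standing haplotype, so the diagonal uses
  $p_{\mathrm{within}} = p_{\mathrm{coal}} +
  e^{-(\kappa+2r)t}\,p_{\mathrm{shared}}$. This continuation term matters:
  without it the diagonal would fall below the off-diagonal at small $t$
  (equality holds at $t = 0$), and the model covariance would be
  indefinite — a coalescent process cannot make two lineages from
  different populations more related than two from the same population.
  With a source population, the source's diagonal takes the
  independent-sweep form.

* **Migration.** The allele arose in a source population and reached each
  recipient by migration at rate $m$; the expected establishment delay
  $1/m$ generations exposes the migrant haplotype to recombination, so a
  recipient lineage retained through its own sweep traces into the source
  with probability $q = y\,e^{-r/m}$. Recipient–source coancestry becomes
  $q\,(y + (1-y)F_{ij}) + (1-q)F_{ij}$ and two recipients share $q^2$.
  Diagonals take the within-sweep (independent) form $y^2 + (1-y^2)F_{ii}$
  for source and recipients alike: two retained lineages sit on the single
  migrant haplotype and coalesce at the sweep regardless of whether they
  trace back further, so the within-sweep event (probability $y^2 \ge
  q^2$) dominates and tracing into the source matters only for
  cross-population entries.

* **Mixed modes.** `update_mode()` partitions the selected populations
  into groups, each with its own mode; groups are independent convergence
  events, so no coancestry beyond $F$ is added between groups. A single
  grid point carries one source index, so at most one group may use a
  source-requiring mode (migration or standing-with-source), and the
  sources axis is restricted to members of that group.

All kernels leave non-selected populations untouched and return $F$ as $r
\to \infty$.

### Composite likelihood

For a proposed selected site and one point of the parameter grid, the
composite log-likelihood sums, over usable sites of the candidate region,
the zero-mean multivariate normal log-density of the centered deviations
$w = Cz$ under $\Sigma(r) = C\,(F'(r) + \mathrm{diag}(1/n_i))\,C^\top$.
Sites are treated as independent — a composite, not a full, likelihood —
so the result supports point estimation by grid maximization
(`mcle_summary()`) but not likelihood-ratio calibration.

Two linear-algebra paths are available: Cholesky factorization (inverse and
log-determinant from the factor; the default) and a pseudo-inverse path
(`MASS::ginv` plus the log of the product of nonzero eigenvalues) for
covariances that are not numerically positive definite. If a Cholesky
fails, one round of diagonal jitter ($10^{-10}\,\mathrm{tr}\,\Sigma/k$) is
tried, then the fit falls back to the pseudo-inverse for that matrix and
reports it — a fit never aborts. On random positive-definite covariances
the two paths agree to a relative $10^{-6}$ (tested on 100 draws).

### Distance binning

Evaluating a kernel at every site is wasteful when many sites sit at
similar distances. Distances from the proposed site are grouped into
`num_bins` bins and each bin is evaluated once at its midpoint. When the
number of distinct distances does not exceed `num_bins`, each distinct
distance becomes its own bin with the distance itself as midpoint, so
binning is exact; otherwise bins are uniform right-closed intervals over
$[0, \max r]$. Binning is per proposed site, deterministic, and
order-independent; the per-bin scatter matrices are precomputed once per
proposed site, so each additional grid point costs one small factorization
per occupied bin regardless of the number of sites.

## Parameters that matter

| argument | meaning | units | notes |
|---|---|---|---|
| `Ne` | effective population size | diploids | single value for all populations |
| `rec` | recombination rate | Morgans per position unit per generation | positions are never rescaled |
| `sels` | proposed selection coefficients | per generation | must satisfy $4 N_e s > 1$ |
| `migs` | proposed migration rates | migrant fraction per generation | strictly positive; 0 is not a rate |
| `times` | proposed standing times | generations | 0 allowed |
| `gs` | proposed standing frequencies | frequency | strictly inside $(0,1)$ |
| `sources` | candidate source populations | indices | must be selected populations |
| `n_sites` / `sel_sites` | proposed selected sites | positions | uniform placement or explicit list; mutually exclusive |
| `num_bins` | distance-binning resolution | count | exact when it exceeds the distinct-distance count |
| `sample_sizes` | haploid sample sizes | alleles | twice the diploid count |

Grid density is the main cost lever: the number of evaluated grid points is
the product of the mode's axis lengths times the number of proposed sites,
and each point costs one factorization per occupied bin.

## The output contract

Every fit returns the same 10 columns — `selected_sites`, `sels`, `migs`,
`times`, `gs`, `sources`, `cle`, `selected_pops`, `locus_name`, `model` —
with `NA` in grid parameters a mode does not use, so tables from different
modes concatenate directly with `bind_rows()` for model comparison. Rows
follow the deterministic nested order with `selected_sites` outermost and
`sources` innermost; ties at the maximum are broken by first occurrence in
that order. The neutral fit replicates its single composite likelihood
once per proposed site to keep the contract. `write_results()` stores
numbers with 17 significant digits so a written table reads back
bit-identically.

## What the synthetic-data generator emulates

`simulation_scenario()` defaults describe the reference conditions used
throughout the package's tests: six populations, of which populations 1, 3
and 5 independently acquired the beneficial mutation at position 0 with $s
= 0.05$; 200 polymorphic sites on positions spanning $[0, 1]$; 1000
neutral sites; haploid sample sizes of 10; $N_e = 10^4$; `rec` $= 0.005$
per position unit. The true coancestry defaults to the centered
exchangeable-drift matrix $0.1\,(I - J/6)$ — centered because the
mean-standardization makes the centered scale the one on which the model's
$F$ actually lives. `example_grid()` carries the reference grid (23
selection coefficients from $10^{-4}$ to 0.6, 9 standing times from 0 to
$10^6$, 5 standing frequencies from $1/(2N_e)$ to 0.1, 5 migration rates
from $10^{-5}$ to 1, three candidate sources).

The generator is the likelihood's own mirror, not a population simulator.
Neutral sites: ancestral frequency $\epsilon \sim U(0.05, 0.95)$, Gaussian
deviations with covariance $\epsilon(1-\epsilon)F$, clamp to $[0,1]$,
binomial sampling. Selected region: the same drift background plus the
sweep component drawn through its coalescent meaning — with probability
$a_i = (F'_{ii} - F_{ii})/(1 - F_{ii})$ the sampled lineages of selected
population $i$ coalesced on the sweeping haplotype and the population
frequency is that haplotype's allele, a Bernoulli($\epsilon$) draw of 0 or
1; switched populations share one haplotype allele with probabilities
fitted (rank-one, in logs) to the kernel's cross-population coancestry.
This reproduces the target covariance $\epsilon(1-\epsilon)F'(r)$ exactly
on the diagonal and to high accuracy elsewhere (validated against analytic
moments in the test suite), while staying inside $[0,1]$. A clamped
Gaussian would not: at sweep-scale variance, truncation to $[0,1]$ removes
roughly half the hitchhiking variance (a standard normal clamped at $\pm 1$
SD keeps variance 0.52) and that deficit masquerades as a weaker selection
coefficient, biasing recovery tests in a way that has nothing to do with
the estimator.

What passing recovery tests do show: the grid fit finds the selected site
and approximately the right selection strength when the data follow the
model's covariance. What they do not show: robustness to demographic
misspecification, linked selection among neutral sites, ascertainment of
the candidate region, or non-equilibrium sampling noise — real data
violate the generator's assumptions in all these ways, and a forward or
coalescent simulator (outside this package's scope) is the right tool to
probe them.

Two residual biases are expected and visible in the tests: the model adds
a flat $\mathrm{diag}(1/n)$ sampling term although swept sites sit at
boundary frequencies where binomial noise vanishes, and the
standardization scale is contaminated by the swept populations near the
selected site. Both push the estimated $s$ slightly below truth at small
sample sizes (typically one grid cell at the reference conditions, e.g.
0.03–0.04 for a true 0.05).

## Numerical choices

* Tie-breaks at the maximum: first occurrence in the deterministic row
  order.
* Monomorphic sites: dropped with a message, never an error.
* Non-positive-definite model covariances: one jitter attempt, then
  pseudo-inverse; logged once per session.
* All randomness flows from a single integer seed through R's default
  generator; the same seed reproduces the same data on any platform.
* Problem sizes in the shipped tests and acceptance script are chosen for
  desk-scale runs: 20 recovery replicates at the reference scenario, 200k
  sites for the estimator-consistency check, 50–1000 distance bins
  depending on the fit's grid size.

## Worked example

```{r example, eval = FALSE}
scn <- simulation_scenario(seed = 1)
dat <- simulate_scenario(scn)
grid <- example_grid()
cfg <- run_config(
  Ne = 10000, rec = 0.005, selected_pops = c(1, 3, 5),
  n_sites = 10, num_bins = 1000,
  sels = grid$sels, migs = grid$migs, times = grid$times,
  gs = grid$gs, sources = grid$sources, locus_name = "test_locus"
)
ctx <- build_context(dat$neutral, dat$selected, cfg)

neut <- fit_mode(ctx, "neutral")
ind <- fit_mode(ctx, "independent")
mig <- fit_mode(ctx, "migration")

all_mods <- bind_rows(ind, mig)
mcle_summary(all_mods)
plot_profile(all_mods, unique(neut$cle), "selected_sites")
```

## Known limitations

* Grid evaluation only — no gradients, no optimization, no bootstrap
  calibration of mode comparisons.
* One effective population size for all populations; no population-size
  variation, deletions, or concurrent-sweep models.
* Composite likelihoods ignore linkage between sites of the candidate
  region; differences between modes should be read as relative support,
  not calibrated evidence.
* The migration and standing kernels follow the package's own coalescent
  derivations described above; alternative placements of the cross terms
  exist in the literature and would shift composite likelihoods slightly
  without changing the workflow.
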