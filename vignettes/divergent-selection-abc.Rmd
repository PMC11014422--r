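---
title: "Estimating divergent selection by simulation and ABC: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating divergent selection by simulation and ABC: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divselABC)
```

This vignette is the package's own account of the science it implements:
the population-genetic model, the statistics, the inference machinery, and
— most importantly for a reviewer — the places where the design was
genuinely open and what we chose.

## The model

Two haploid-represented populations of constant size `Ne`, each an
`Ne x L` matrix of 0/1 alleles at equally spaced bi-allelic SNPs, diverge
under a cyclic regime. Within a cycle of `t_star` generations, the first
`t_star - 1` generations are isolated and asexual: carrier `n` of
population X has additive fitness

\[ \omega_n = \sum_{i \in \text{sel}} \bigl(1 + \mathbb{1}[\text{carrier }
n \text{ has allele } a_i]\, s_i\bigr), \]

and the next generation's parents are drawn
`Multinomial(Ne, p)` with `p_n = omega_n / sum(omega)`. Population Y is
always neutral: each of its carriers contributes `(1 + 0)` per selected
locus, so its reproduction is uniform. At the cycle boundary
(`t = c * t_star`), `round(Ne * m)` uniformly chosen carriers are swapped
in each direction, then each population produces `Ne` offspring without
fitness weighting — clonally (`sex = 0`) or by random mating with
recombination (`sex = 1`). The run ends at
`t_final = n_cycles * t_star - 1`, the last generation before what would
be the next migration, so `n_cycles - 1` migration events occur.

Assumptions worth making explicit:

* **Haploid rows.** Carriers are single haplotype rows even though the
  motivating organism is diploid; the reproduction rules never pair rows
  within a carrier, so diploidy would be representational only.
* **Additive fitness with baseline `L_s`.** The fitness sum over selected
  loci literally evaluates to `L_s + sum I s_i`, so the neutral baseline is
  the number of selected loci, not 1. Only the ratios in the reproduction
  probabilities matter, so this is equivalent to any positive rescaling;
  with zero selected loci the empty sum is taken as 1 (pure drift).
* **Selection never acts at migration generations**, whose reproduction is
  explicitly fitness-free; it acts at every other generation, including
  the first of each cycle.
* **One recombination rate.** `r` is a single genome-average rate; variable
  or locus-specific rates are out of scope (they confound the selection
  signal and are deferred by the source experiments as well).

## Founding and recombination

Founding builds two F1 pools whose carriers are constant rows of all-0 or
all-1 (probability 0.5 each, independently per carrier), then makes each
F2 population of `Ne` offspring by recombining one uniformly chosen parent
from each pool. Expected allele frequency at every locus is 0.5 at `t = 0`
and the F2 populations start in maximal linkage disequilibrium — which is
what makes hitchhiking and its decay observable downstream.

Crossovers per meiosis are `nr ~ Binomial(L * snp_spacing - 1, r)` on the
base-pair axis. Each bp position maps to the SNP interval
`ceil(pos / snp_spacing)` clipped to `[1, L-1]`; a breakpoint `k` switches
the template between SNP `k` and `k + 1`, and duplicate intervals collapse
to a single switch (at most one observable crossover between consecutive
SNPs). With probability 0.5 the parental roles are swapped before copying.
The defaults `(L = 100, spacing = 165, r = 3e-4)` and
`(L = 1500, spacing = 165, r = 2e-5)` both give an expected 4.95
crossovers per meiosis — the two map configurations are deliberately
matched in recombination intensity.

The per-offspring stitching loop is implemented in C++ (`src/cross.cpp`)
because the evaluation harness simulates tens of thousands of genomes; the
kernel draws from R's global RNG in exactly the order of the R-level
primitives `sample_crossovers()` + `recombine_offspring()`, and a test
verifies draw-for-draw agreement under a shared seed. All randomness in
the package flows through R's single global stream (`set.seed()`).

## Summary statistics

* **FST** uses the two-population (divisor-2) variance,
  `sigma_p^2 = (pX - pY)^2 / 4`, normalized by `pbar (1 - pbar)`. This
  choice is forced by the signed statistic's stated range `[-1, 1]`: the
  divisor-1 sample variance would allow FST = 2. Monomorphic loci return
  0 — no differentiation is measurable there, and this avoids 0/0.
* **signFST** is `-FST` where `pX < pY`, `+FST` otherwise (ties get `+`,
  which is immaterial since FST is then 0).
* **EHH** around a core locus groups carriers by their allele string over
  the two-sided window `[core - v, core + v]` clipped to the chromosome,
  with `EHH(v) = sum_z n_z^2 / (n0^2 + n1^2)`. Two deliberate fidelity
  notes: the homozygosity uses squared counts `n^2` rather than the
  conventional unbiased `n (n - 1)` form — implemented exactly as the
  source defines it, and flagged here for users comparing against other
  software; and the `L x L` profile matrix is *not* forced to be
  symmetric, because with core-based normalization entry `(i, j)` need not
  equal `(j, i)` — the per-core profile is the primitive.
* **XP-EHH** thresholds both profiles at `cutoff = 0.05`, integrates over
  `v` by a unit-step rectangle sum (distances are discrete SNP units; no
  normalization, since `r` is constant across the genome), and takes the
  log ratio X/Y. `EHH(0) = 1` always survives the cutoff, so both
  integrals are at least 1 and the statistic is finite by construction.
* **Outlier scan**: the cutoff is the empirical 95% quantile (R's default
  interpolated type-7 quantile) of the per-locus FST values, with strict
  inequality for membership — deterministic, and at most `ceil(0.05 L)`
  candidates when values are distinct.

The concatenation order for ABC distances is fixed —
`signFST, pdiff, FST, XPEHH`, restricted to the requested subset — and
recorded in every summary object, so distances are reproducible.

## ABC

Statistics are standardized by the median absolute deviation of each
dimension over the simulated table (zero-MAD dimensions get scale 1 and a
degenerate flag), and plain Euclidean distance is taken to the observed
vector. `M = floor(tolerance * n_sim)` smallest distances are accepted,
ties broken by simulation index. Kernel weights on `t = d / d_M` use
`0.75 (1 - t^2)` (Epanechnikov) or `exp(-t^2 / 2)` (Gaussian);
multiplicative kernel constants cancel in weighted least squares, so only
the shapes matter — and the two kernels are empirically interchangeable
here (tested: mean absolute difference of posterior medians below the
posterior SD across seeded runs).

The regression correction fits, per parameter, a weighted least squares of
the accepted draws on the centred predictors
(scaled statistics minus scaled observation, plus intercept), and adjusts
`theta* = theta - beta' (S - S_obs)`. Numerical choices:

* An exact-match row (distance 0) has zero predictors and is unadjusted.
* Zero-weight rows (Epanechnikov at `t = 1`) do not influence the fit but
  are still adjusted with the fitted coefficients.
* Predictor columns that are constant across the accepted set — within a
  `1e-8` relative range tolerance — are dropped silently. The tolerance
  matters in practice: statistics live on a `1/Ne` frequency grid, so an
  accepted set can share one grid value while differing by `1e-16`
  rounding, which would otherwise feed a numerically singular fit.
  Genuinely collinear varying columns are dropped with a warning.
* Migration rate and reproduction mode are categorical nuisance
  parameters: they are *never* regression-adjusted, only summarized as
  accepted-draw frequencies.

The point estimator throughout is the per-parameter posterior median.

## Deterministic oracle

The infinite-population expectation of the reproduction scheme for one
selected locus is `p' = p (1 + s) / (1 + p s)` (derive it by summing
fitness over the two allele classes); migration mixes linearly,
`pX' = (1 - m) pX + m pY`. `det_trajectory()` runs this recursion on
exactly the simulator's schedule — including fitness-free migration
generations, resolving in the simulator's favour a genuine ambiguity in
the source description. The acceptance suite verifies that the mean of
500 simulated trajectories at `Ne = 2000` tracks the recursion within
three Monte-Carlo standard errors at every generation.

## Scenario harness and priors

The prior: the selected-locus set is uniform over the admissible subsets
of the candidates of size 0, 1, 2; coefficients are
`Uniform(-s_bound, s_bound)` with `s_bound = 0.25` for `t_star = 5` and
`0.025` for `t_star = 50` (ten-fold longer cycles pair with ten-fold
weaker selection); migration and reproduction mode are drawn uniformly
over the four combinations actually explored —
`(m, sex) in {(0,0), (0,1), (0.2,1), (0.5,1)}` — not the full product
set. Candidate loci for the fixed-loci method are
`round(L/3), round(L/2), round(2L/3)`.

**Method 1** (fixed candidates) builds one shared reference table and
reuses it for every pseudo-observed data set. **Method 2** runs the FST
outlier scan on each observed data set first, then builds a fresh table
whose selected loci are restricted to the scan's candidates (all other
loci pinned at `s = 0`), with `(m, sex)` re-drawn per row; the number of
selected loci among candidates is uniform on `{0, 1, 2}` clipped to the
candidate count. Loci outside the candidate set have a forced estimate of
0, and an empty candidate set is recorded as the zero-selection model.

One design decision deserves emphasis. For method 1 we restrict the ABC
statistic vector to the candidate loci (the `stat_loci` default) rather
than using all `L` statistics. At the published scale the acceptance count
is `M = 100` while the full statistic vector has `L = 100` dimensions — a
weighted regression with 101 coefficients from 100 points is
underdetermined, so the original analysis cannot have used the full
vector; and at desk scale we measured the full-vector regression
*overfitting* (adjusted MSE above rejection-only MSE, contradicting the
known ordering). Restricting to candidate-locus statistics mirrors what
the outlier-scan method does explicitly, and restores the expected
regression-beats-rejection behaviour. The full vector remains one
argument away.

Estimator evaluation bins the true coefficients into 20 equal-width bins
over the prior support and decomposes the error `e = est - true` within
each bin as `MSE = mean(e^2)`, `variance = mean((e - mean(e))^2)`,
`bias^2 = mean(e)^2`, so the identity `MSE = variance + bias^2` holds
exactly by construction — the aggregation rule the source leaves
unstated.

## What the synthetic data do and do not establish

The generator *is* the stated world of the model: founding F2 linkage
disequilibrium, cyclic migration-selection, matched crossover intensity
across map configurations. Desk-scale defaults (`Ne = 500`,
`n_sim = 5000`, `n_abc = 50`, tolerance 0.02 so `M = 100`) keep a scenario
on one CPU in minutes; the published scale (`Ne = 10000`,
`n_sim = 100000`, 10 million simulations per scenario) is a cluster
workload reachable via `full_scale = TRUE`. A green test therefore
establishes correctness of the machinery and the *direction* of the
published effects (migration and multi-locus selection degrade estimation;
clonal reproduction amplifies hitchhiking; signFST beats the raw frequency
difference under deterministic observations) — not the published error
magnitudes, which are full-scale quantities.

Real sequencing data differ in ways the generator does not emulate:
unequal SNP spacing, recombination-rate heterogeneity and gene conversion,
genotyping error, finite sampling of carriers from much larger census
populations, and demography beyond the two-population island exchange.

## Known limitations

* Clonal sweeps defeat the outlier scan by construction: with `sex = 0`
  the entire genome hitchhikes, so no locus is an outlier relative to its
  background. This is a property of the method, not a bug, and is visible
  in the harness output.
* `pX - pY` and FST-family statistics sit on a `1/Ne` grid; at small `Ne`
  exact ties in distances and degenerate accepted sets are common and are
  handled as described above.
* Estimates of weak selection (`|s|` small relative to drift,
  i.e. `s` within a few times `1/Ne` per generation times `t_final`) are
  prior-dominated; the bias plots from `evaluate_estimates()` make this
  regime explicit.
* Selection coefficients near the prior boundary are shrunk inward by the
  local-linear adjustment (no boundary correction such as logit transforms
  is applied).
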