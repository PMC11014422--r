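# divselABC

Forward-in-time simulation of divergent selection between two populations,
and approximate Bayesian computation (ABC) for jointly estimating *which*
loci are under selection and *how strong* that selection is.

## The problem

Two populations of a haploid-genotyped organism (the motivating system is
experimentally evolved baker's yeast) adapt to contrasting environments.
Population X experiences locus-specific selection; population Y is neutral.
Every `t*` generations of isolated clonal selection are punctuated by one
generation of symmetric migration followed by sexual or asexual
reproduction, for `n_cycles` cycles, ending at
`t_final = n_cycles * t* - 1`. The likelihood of the resulting SNP data is
intractable, so inference goes through simulation:

1. **Simulator** — each population is an `Ne x L` binary haplotype matrix.
   Within a cycle, carrier `n` reproduces with probability proportional to
   its additive fitness `w_n = sum_i (1 + I(carrier has allele a_i) s_i)`
   over the selected loci, with offspring counts `Multinomial(Ne, p)`,
   `p_n = w_n / sum(w)`. At migration generations, `round(Ne * m)` carriers
   are exchanged in each direction and reproduction is fitness-free, clonal
   (`sex = 0`) or with recombination (`sex = 1`). Crossovers per meiosis
   are `Binomial(L * spacing - 1, r)` on the bp axis, mapped to SNP
   intervals.
2. **Summary statistics** — per locus: `FST = sigma_p^2 / (pbar (1 - pbar))`
   with the two-population variance `(pX - pY)^2 / 4`; signed FST
   (`-FST` where `pX < pY`); the raw frequency difference `pX - pY`; and
   XP-EHH, the log-ratio of integrated extended haplotype homozygosity
   (`EHH(v) = sum_z n_z^2 / (n0^2 + n1^2)`) between the populations.
3. **Outlier scan** — candidate loci are those with FST above the empirical
   95% quantile across loci; non-candidates are fixed at `s = 0`.
4. **ABC** — reference tables of prior draws and their simulated
   statistics; MAD-standardized Euclidean distances; rejection of all but
   the `tolerance` fraction; kernel-weighted (Gaussian or Epanechnikov)
   local-linear regression adjustment of the accepted selection
   coefficients; posterior medians as point estimates.
5. **Oracle & evaluation** — a deterministic single-locus recursion
   `p' = p (1 + s) / (1 + p s)` on the same migration-selection schedule
   validates the simulator, and a scenario harness decomposes estimator
   error into MSE = variance + bias².

## Worked example

Simulate 19 generations of divergence with selection `s = 0.2` on SNP 50 of
100, scan for outliers, and estimate the selection coefficients at the
candidate loci by ABC:

```r
library(divselABC)
set.seed(42)

fx <- fixed_params(r = 3e-4, t_star = 5, n_cycles = 4, Ne = 500, L = 100,
                   snp_spacing = 165)
truth <- drawn_params(sel_loci = 50, sel_coeffs = 0.2, m = 0, sex = 1, L = 100)
pair <- run_simulation(fx, truth)

sv <- summarize_pair(pair, stats = c("signFST", "FST"))
scan <- fst_outlier_scan(sv$FST)
scan
#> FST outlier scan: 5 candidate loci above cutoff 0.08758
#>   loci: 49, 50, 52, 53, 54

prior <- prior_spec(s_bound = 0.25, candidate_loci = scan$loci)
obs <- summarize_pair(pair, stats = "signFST", loci = scan$loci)$values
tab <- build_reference_table(fx, prior, n_sim = 2000, stats = "signFST",
                             loci = scan$loci, obs = obs)
res <- regression_adjust(abc_rejection(tab, tolerance = 0.05))
res
#> ABC result: 100 accepted draws (max distance 6.305)
#>   regression-adjusted (gaussian kernel) posterior medians:
#>           median         q2.5     q97.5         sd
#> s_49  0.02657663 -0.076517692 0.2076089 0.07511891
#> s_50  0.07949616  0.003078012 0.2756217 0.07574694
#> s_52 -0.02836598 -0.090881848 0.1586708 0.06940188
#> s_53  0.01162149 -0.030454928 0.2178053 0.07161289
#> s_54  0.02059877 -0.032176508 0.2272469 0.06864096
#> m     0.00000000  0.000000000 0.2000000 0.07550503
#> sex   0.50000000  0.000000000 1.0000000 0.50251891
```

The scan catches the true locus (50) plus four hitchhiking neighbours. The
posterior median at locus 50 is the largest of the candidates and its 95%
interval excludes 0; at this deliberately small reference-table size
(`n_sim = 2000`) the point estimate is shrunk towards the prior — the
scenario harness (`run_method1()` / `run_method2()`) quantifies exactly
this bias/variance behaviour across migration rates, reproduction modes
and numbers of selected loci. `m` and `sex` are nuisance draws: they vary
across simulations but are summarized only as accepted-draw frequencies,
never regression-adjusted.

A command-line interface wrapping the same pipeline
(`simulate`, `sumstats`, `outlier-scan`, `abc`, `oracle`, `scenario`) is
installed at `inst/cli/divsel`.

## Documentation

The methods vignette (`vignettes/divergent-selection-abc.Rmd`) describes
the model and its assumptions, every tunable parameter with its default
and units, what the synthetic data do and do not emulate, and the
numerical and design choices (tie-breaking, degenerate predictors,
migration scheduling, the candidate-loci statistic restriction).
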