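#' Default candidate loci for the fixed-loci method
#'
#' The three admissible positions `L/3`, `L/2`, `2L/3` (rounded), e.g. the
#' 33rd, 50th and 67th SNP for `L = 100`.
#'
#' @param L Number of SNPs.
#' @return Integer vector of three loci.
#' @export
default_candidate_loci <- function(L) {
  as.integer(round(c(L / 3, L / 2, 2 * L / 3)))
}

# The four migration/reproduction combinations actually explored:
# asexual only without migration; sexual with m in {0, 0.2, 0.5}.
MSEX_PAIRS <- cbind(m = c(0, 0, 0.2, 0.5), sex = c(0, 1, 1, 1))

#' Prior specification for the unknown parameters
#'
#' Encodes the joint prior: the number of selected loci is uniform over the
#' admissible subsets of the candidate loci of size 0, 1 or 2; each selected
#' coefficient is `Uniform(-s_bound, s_bound)` independently; the migration
#' rate and reproduction mode are drawn uniformly over the four admissible
#' `(m, sex)` combinations `(0,0), (0,1), (0.2,1), (0.5,1)`.
#'
#' @param s_bound Half-width of the uniform selection-coefficient prior
#'   (0.25 for `t_star = 5`, 0.025 for `t_star = 50`).
#' @param candidate_loci Ordered integer vector of admissible selected loci.
#' @param max_loci Maximum number of simultaneously selected loci (default 2).
#' @param msex_pairs Two-column matrix of admissible `(m, sex)` pairs.
#' @return An object of class `prior_spec`, including the enumerated
#'   `locus_combos` list.
#' @export
prior_spec <- function(s_bound, candidate_loci, max_loci = 2,
                       msex_pairs = MSEX_PAIRS) {
  stopifnot(s_bound > 0, !anyDuplicated(candidate_loci),
            ncol(msex_pairs) == 2)
  candidate_loci <- as.integer(candidate_loci)
  combos <- list(integer(0))
  for (k in seq_len(min(max_loci, length(candidate_loci)))) {
    ck <- utils::combn(candidate_loci, k, simplify = FALSE)
    combos <- c(combos, lapply(ck, as.integer))
  }
  structure(list(s_bound = s_bound, candidate_loci = candidate_loci,
                 locus_combos = combos, msex_pairs = msex_pairs),
            class = "prior_spec")
}

#' Draw one joint parameter realisation from the prior
#'
#' @param prior A [prior_spec()].
#' @return A [drawn_params()] object.
#' @export
sample_prior <- function(prior) {
  stopifnot(inherits(prior, "prior_spec"))
  loci <- prior$locus_combos[[sample.int(length(prior$locus_combos), 1L)]]
  s <- stats::runif(length(loci), -prior$s_bound, prior$s_bound)
  pair <- prior$msex_pairs[sample.int(nrow(prior$msex_pairs), 1L), ]
  drawn_params(sel_loci = loci, sel_coeffs = s, m = pair[["m"]],
               sex = pair[["sex"]])
}

#' Scenario definitions
#'
#' Instantiates one of the four canonical scenarios.  At full scale these
#' use `Ne = 10000`, `n_sim = 100000` and (for the outlier-scan method)
#' `n_abc = 100` (10 for scenario 4); the desk scale substitutes
#' `Ne = 500`, `n_sim = 5000`, `n_abc = 50` so a scenario is runnable on one
#' CPU in minutes.  Scenario t_final values are 19, 199, 99 and 199.
#'
#' @param name Scenario number 1-4.
#' @param method `"fixed_loci"` (shared reference table, candidate loci
#'   `L/3, L/2, 2L/3`, no outlier scan) or `"outlier_scan"` (fresh table per
#'   observed data set, candidates from the FST scan).
#' @param full_scale Use the full-scale sizes (cluster workload) instead of
#'   the desk-scale defaults.
#' @param Ne,L,n_sim,n_abc Optional overrides of the scale defaults (useful
#'   for quick experiments; candidate loci track the overridden `L`).
#' @return An object of class `scenario_spec` with elements `name`,
#'   `method`, `fixed` ([fixed_params()]), `prior` ([prior_spec()]),
#'   `n_sim`, `n_abc`.
#' @export
scenario_spec <- function(name = 1, method = c("fixed_loci", "outlier_scan"),
                          full_scale = FALSE, Ne = NULL, L = NULL,
                          n_sim = NULL, n_abc = NULL) {
  method <- match.arg(method)
  stopifnot(name %in% 1:4)
  row <- list(`1` = list(L = 100L,  r = 3e-4, t_star = 5L,  n_cycles = 4L, s_bound = 0.25),
              `2` = list(L = 100L,  r = 3e-4, t_star = 50L, n_cycles = 4L, s_bound = 0.025),
              `3` = list(L = 100L,  r = 3e-4, t_star = 50L, n_cycles = 2L, s_bound = 0.025),
              `4` = list(L = 1500L, r = 2e-5, t_star = 50L, n_cycles = 4L, s_bound = 0.025)
  )[[as.character(name)]]
  if (is.null(Ne)) Ne <- if (full_scale) 10000L else 500L
  if (is.null(L)) L <- row$L
  if (is.null(n_sim)) n_sim <- if (full_scale) 100000L else 5000L
  if (is.null(n_abc))
    n_abc <- if (!full_scale) 50L
             else if (method == "fixed_loci") 10000L
             else if (name == 4) 10L else 100L
  fixed <- fixed_params(r = row$r, t_star = row$t_star, n_cycles = row$n_cycles,
                        Ne = Ne, L = L, snp_spacing = 165L)
  prior <- prior_spec(row$s_bound, default_candidate_loci(L))
  structure(list(name = name, method = method, fixed = fixed, prior = prior,
                 n_sim = n_sim, n_abc = n_abc, full_scale = full_scale),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Scenario %d (%s, %s scale): t_final = %d, s ~ Unif[%+g, %+g]\n",
              x$name, x$method, if (x$full_scale) "full" else "desk",
              x$fixed$t_final, -x$prior$s_bound, x$prior$s_bound))
  cat(sprintf("  n_sim = %d, n_abc = %d, Ne = %d, L = %d\n",
              x$n_sim, x$n_abc, x$fixed$Ne, x$fixed$L))
  invisible(x)
}

# Flatten a drawn_params to the fixed-order numeric vector used in the
# reference table: one selection coefficient per candidate locus, then m, sex.
flatten_params <- function(drawn, candidate_loci) {
  s <- numeric(length(candidate_loci))
  if (length(drawn$sel_loci))
    s[match(drawn$sel_loci, candidate_loci)] <- drawn$sel_coeffs
  c(s, drawn$m, drawn$sex)
}

param_names_for <- function(candidate_loci) {
  c(paste0("s_", candidate_loci), "m", "sex")
}

#' Build an ABC reference table by forward simulation
#'
#' Draws `n_sim` parameter sets from the prior, simulates each to `t_final`,
#' and summarizes with the requested statistics (restricted to `loci` when
#' the outlier scan narrows the candidates).
#'
#' @param fixed A [fixed_params()].
#' @param prior A [prior_spec()].
#' @param n_sim Number of simulations.
#' @param stats Statistic subset for [summarize_pair()].
#' @param loci Loci to which the statistics are restricted (default: all).
#' @param obs Observed summary vector (may be attached later via
#'   [abc_rejection()]'s `obs` argument); defaults to zeros.
#' @return A [reference_table()].
#' @export
build_reference_table <- function(fixed, prior, n_sim, stats = "signFST",
                                  loci = NULL, obs = NULL) {
  draws <- vector("list", n_sim)
  stat_rows <- vector("list", n_sim)
  for (i in seq_len(n_sim)) {
    dr <- sample_prior(prior)
    pair <- run_simulation(fixed, dr)
    sv <- summarize_pair(pair, stats = stats, loci = loci)
    draws[[i]] <- flatten_params(dr, prior$candidate_loci)
    stat_rows[[i]] <- sv$values
  }
  sv1 <- summarize_pair(pop_pair(matrix(0L, 2, fixed$L), matrix(0L, 2, fixed$L)),
                        stats = stats, loci = loci)
  S <- do.call(rbind, stat_rows)
  P <- do.call(rbind, draws)
  if (is.null(obs)) obs <- numeric(ncol(S))
  reference_table(P, S, obs, stat_names = sv1$stat_names,
                  param_names = param_names_for(prior$candidate_loci))
}

#' Method 1: ABC with fixed candidate loci and a shared reference table
#'
#' Builds one reference table of `n_sim` simulations, then for each of
#' `n_abc` pseudo-observed data sets (fresh prior draw + simulation) runs
#' ABC rejection followed by regression adjustment, and records the
#' posterior-median selection-coefficient estimate at each candidate locus
#' alongside the truth and condition labels.
#'
#' @param scenario A [scenario_spec()] with `method = "fixed_loci"`.
#' @param n_abc,n_sim Overrides of the scenario sizes.
#' @param tolerance ABC acceptance proportion (desk default 0.02, i.e.
#'   `M = 100` of 5000; the full-scale analogue is 0.001 of 100000).
#' @param kernel Regression-adjustment kernel.
#' @param stats Statistic subset used for the ABC distance.
#' @param stat_loci Loci entering the statistic vectors.  Defaults to the
#'   candidate loci: with the acceptance count `M` of the same order as the
#'   number of SNPs, a local-linear adjustment on the full-genome statistic
#'   vector would be (near-)underdetermined, so the ABC operates on the
#'   statistics at the loci where selection can act — mirroring how the
#'   outlier-scan method restricts statistics to its candidate set.  Pass
#'   `seq_len(L)` for the full vector.
#' @return An object of class `eval_report`: list with the per-record data
#'   frame `records` (columns `iter`, `locus`, `true_s`, `est`, `est_rej`,
#'   `m`, `sex`, `n_loci`) and run metadata.
#' @export
run_method1 <- function(scenario, n_abc = scenario$n_abc,
                        n_sim = scenario$n_sim, tolerance = 0.02,
                        kernel = "gaussian", stats = "signFST",
                        stat_loci = scenario$prior$candidate_loci) {
  stopifnot(inherits(scenario, "scenario_spec"), scenario$method == "fixed_loci")
  fixed <- scenario$fixed; prior <- scenario$prior
  table <- build_reference_table(fixed, prior, n_sim, stats = stats,
                                 loci = stat_loci)
  s_cols <- paste0("s_", prior$candidate_loci)
  recs <- vector("list", n_abc)
  for (j in seq_len(n_abc)) {
    truth <- sample_prior(prior)
    pair <- run_simulation(fixed, truth)
    obs <- summarize_pair(pair, stats = stats, loci = stat_loci)$values
    res <- abc_rejection(table, tolerance, obs = obs)
    res <- regression_adjust(res, kernel = kernel)
    med_adj <- apply(res$adjusted_draws[, s_cols, drop = FALSE], 2, stats::median)
    med_rej <- apply(res$raw_draws[, s_cols, drop = FALSE], 2, stats::median)
    true_s <- flatten_params(truth, prior$candidate_loci)[seq_along(s_cols)]
    recs[[j]] <- data.frame(iter = j, locus = prior$candidate_loci,
                            true_s = true_s, est = unname(med_adj),
                            est_rej = unname(med_rej), m = truth$m,
                            sex = truth$sex, n_loci = length(truth$sel_loci))
  }
  records <- do.call(rbind, recs)
  structure(list(records = records, method = "fixed_loci",
                 scenario = scenario$name, n_abc = n_abc, n_sim = n_sim,
                 tolerance = tolerance, kernel = kernel, stats = stats,
                 evaluation = evaluate_estimates(records,
                                                 s_bound = prior$s_bound)),
            class = "eval_report")
}

# Truth sampler for method 2: loci anywhere on the genome.
sample_truth_anywhere <- function(fixed, s_bound, msex_pairs = MSEX_PAIRS) {
  k <- sample(0:2, 1L)
  loci <- if (k > 0) sort(sample.int(fixed$L, k)) else integer(0)
  pair <- msex_pairs[sample.int(nrow(msex_pairs), 1L), ]
  drawn_params(sel_loci = loci,
               sel_coeffs = stats::runif(k, -s_bound, s_bound),
               m = pair[["m"]], sex = pair[["sex"]], L = fixed$L)
}

#' Method 2: outlier-scan-constrained ABC
#'
#' Per observed data set: (1) simulate a pseudo-observed pair whose selected
#' loci may lie anywhere in `[1, L]`; (2) run the FST outlier scan on the
#' observed FST vector; (3) build a fresh reference table whose selected
#' loci are restricted to the outlier candidates (non-outliers fixed to
#' `s = 0`), with `(m, sex)` re-drawn from the prior per row; (4) run ABC
#' (rejection + regression adjustment) on statistics restricted to the
#' outlier loci; (5) record posterior medians.  A locus outside the outlier
#' set has a forced estimate of 0.  An empty outlier set skips ABC (the
#' zero-selection model is the only candidate) and records estimates of 0.
#'
#' @param scenario A [scenario_spec()] with `method = "outlier_scan"`.
#' @param n_abc,n_sim Overrides of the scenario sizes.
#' @param tolerance,kernel,stats As in [run_method1()].
#' @param quantile Outlier-scan quantile (default 0.95).
#' @return An `eval_report`; `records` additionally carries `in_outlier_set`
#'   and `n_outliers`, and the per-iteration outlier sets are kept in
#'   `outlier_sets`.
#' @export
run_method2 <- function(scenario, n_abc = scenario$n_abc,
                        n_sim = scenario$n_sim, tolerance = 0.02,
                        kernel = "gaussian", stats = "signFST",
                        quantile = 0.95) {
  stopifnot(inherits(scenario, "scenario_spec"),
            scenario$method == "outlier_scan")
  fixed <- scenario$fixed
  s_bound <- scenario$prior$s_bound
  recs <- vector("list", n_abc)
  scans <- vector("list", n_abc)
  for (j in seq_len(n_abc)) {
    truth <- sample_truth_anywhere(fixed, s_bound)
    pair <- run_simulation(fixed, truth)
    pX <- allele_freq(pair$X); pY <- allele_freq(pair$Y)
    scan <- fst_outlier_scan(fst_per_locus(pX, pY), quantile)
    scans[[j]] <- scan
    cand <- scan$loci
    est <- stats::setNames(numeric(length(cand)), paste0("s_", cand))
    if (length(cand) > 0) {
      prior_j <- prior_spec(s_bound, cand)
      obs <- summarize_pair(pair, stats = stats, loci = cand)$values
      table <- build_reference_table(fixed, prior_j, n_sim, stats = stats,
                                     loci = cand, obs = obs)
      res <- abc_rejection(table, tolerance)
      res <- regression_adjust(res, kernel = kernel)
      est[] <- apply(res$adjusted_draws[, names(est), drop = FALSE], 2,
                     stats::median)
    }
    report_loci <- sort(union(truth$sel_loci, cand))
    true_s <- numeric(length(report_loci))
    true_s[match(truth$sel_loci, report_loci)] <- truth$sel_coeffs
    est_full <- numeric(length(report_loci))
    hit <- report_loci %in% cand
    est_full[hit] <- est[paste0("s_", report_loci[hit])]
    recs[[j]] <- data.frame(iter = j, locus = report_loci, true_s = true_s,
                            est = est_full, est_rej = NA_real_, m = truth$m,
                            sex = truth$sex, n_loci = length(truth$sel_loci),
                            in_outlier_set = hit, n_outliers = length(cand))
  }
  records <- do.call(rbind, recs)
  structure(list(records = records, method = "outlier_scan",
                 scenario = scenario$name, n_abc = n_abc, n_sim = n_sim,
                 tolerance = tolerance, kernel = kernel, stats = stats,
                 quantile = quantile, outlier_sets = scans,
                 evaluation = evaluate_estimates(records, s_bound = s_bound)),
            class = "eval_report")
}

#' Bias/variance evaluation of posterior-median estimates
#'
#' Bins the true selection coefficients into equal-width intervals over the
#' prior support and, per bin, decomposes the estimation error
#' `e = est - true_s` into `MSE = mean(e^2)`,
#' `variance = mean((e - mean(e))^2)` and `bias2 = mean(e)^2`, so that
#' `MSE = variance + bias2` holds exactly within each bin.
#'
#' @param records Data frame with columns `true_s` and an estimate column.
#' @param s_bound Half-width of the prior support (bins span
#'   `[-s_bound, s_bound]`).
#' @param n_bins Number of equal-width bins (default 20).
#' @param est_col Name of the estimate column (default `"est"`).
#' @param by Optional name of a grouping column (e.g. `"m"` or `"n_loci"`);
#'   when given, bins are computed within each group.
#' @return Data frame with one row per (group,) bin: `bin_mid`, `n`, `mse`,
#'   `variance`, `bias2`.
#' @export
evaluate_estimates <- function(records, s_bound, n_bins = 20, est_col = "est",
                               by = NULL) {
  stopifnot(all(c("true_s", est_col) %in% names(records)))
  breaks <- seq(-s_bound, s_bound, length.out = n_bins + 1)
  bin <- cut(records$true_s, breaks, include.lowest = TRUE, labels = FALSE)
  err <- records[[est_col]] - records$true_s
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  group <- if (is.null(by)) rep("all", nrow(records)) else records[[by]]
  cells <- unique(data.frame(group = group, bin = bin))
  cells <- cells[order(cells$group, cells$bin), , drop = FALSE]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    e <- err[group == cells$group[i] & bin == cells$bin[i]]
    data.frame(bin_mid = mids[cells$bin[i]], n = length(e), mse = mean(e^2),
               variance = mean((e - mean(e))^2), bias2 = mean(e)^2)
  })
  res <- do.call(rbind, rows)
  if (!is.null(by)) res <- cbind(stats::setNames(cells["group"], by), res)
  res <- res[order(res$bin_mid), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' @export
print.eval_report <- function(x, ...) {
  r <- x$records
  sel <- r$true_s != 0
  cat(sprintf("Evaluation report: scenario %s, %s method, %d ABC iterations\n",
              x$scenario, x$method, x$n_abc))
  cat(sprintf("  overall MSE (selected loci): %.4g over %d records\n",
              mean((r$est - r$true_s)[sel]^2), sum(sel)))
  invisible(x)
}
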