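#' Reference table for ABC
#'
#' Couples the flattened prior draws with their simulated summary
#' statistics and the observed summary vector.
#'
#' @param params `n_sim x n_param` numeric matrix of flattened parameter
#'   draws (one selection coefficient per candidate locus, then `m`, `sex`).
#' @param stats `n_sim x n_stat` numeric matrix of summary statistics.
#' @param obs Length-`n_stat` observed summary vector.
#' @param stat_names,param_names Optional labels (defaulting to the column
#'   names of `stats` / `params`).
#' @return An object of class `reference_table`.
#' @export
reference_table <- function(params, stats, obs, stat_names = colnames(stats),
                            param_names = colnames(params)) {
  params <- as.matrix(params); stats <- as.matrix(stats)
  stopifnot(nrow(params) == nrow(stats), length(obs) == ncol(stats),
            !anyNA(params), !anyNA(stats), !anyNA(obs))
  if (is.null(stat_names)) stat_names <- paste0("S", seq_len(ncol(stats)))
  if (is.null(param_names)) param_names <- paste0("theta", seq_len(ncol(params)))
  colnames(stats) <- stat_names; colnames(params) <- param_names
  structure(list(params = params, stats = stats, obs = as.numeric(obs),
                 stat_names = stat_names, param_names = param_names),
            class = "reference_table")
}

#' Standardize summary statistics by the median absolute deviation
#'
#' Each statistic dimension is divided by its MAD (median of absolute
#' deviations from the median, unscaled) computed over the simulated table,
#' so every dimension contributes comparably to the Euclidean distance.
#' Dimensions with zero MAD get scale 1 and are flagged degenerate.
#'
#' @param stats `n_sim x n_stat` matrix of simulated statistics.
#' @param obs Length-`n_stat` observed vector.
#' @return List with `stats` and `obs` scaled, the `scale` vector, and a
#'   logical `degenerate` flag per dimension.
#' @export
mad_scale <- function(stats, obs) {
  stats <- as.matrix(stats)
  stopifnot(nrow(stats) >= 2, length(obs) == ncol(stats))
  scale <- apply(stats, 2, function(x) stats::median(abs(x - stats::median(x))))
  degenerate <- scale == 0
  scale[degenerate] <- 1
  list(stats = sweep(stats, 2, scale, "/"),
       obs = unname(as.numeric(obs) / scale),
       scale = scale, degenerate = degenerate)
}

#' Euclidean distances from each simulated row to the observed vector
#'
#' @param scaled_stats `n_sim x n_stat` matrix (typically MAD-scaled).
#' @param scaled_obs Length-`n_stat` vector on the same scale.
#' @return Length-`n_sim` vector of non-negative distances.
#' @export
euclidean_distances <- function(scaled_stats, scaled_obs) {
  sqrt(colSums((t(scaled_stats) - scaled_obs)^2))
}

#' ABC rejection sampling
#'
#' MAD-scales the table, computes Euclidean distances to the observed
#' vector, and accepts the `M = floor(tolerance * n_sim)` simulations with
#' the smallest distances (ties broken by simulation index).
#'
#' @param table A [reference_table()].
#' @param tolerance Acceptance proportion in (0, 1\]; must yield `M >= 2`.
#' @param obs Optional replacement observed vector (reusing one table for
#'   many observed data sets).
#' @return An object of class `abc_result` holding accepted indices, sorted
#'   accepted distances, raw accepted draws, the scaled accepted statistics
#'   and observed vector, and the MAD scale metadata.
#' @export
abc_rejection <- function(table, tolerance, obs = NULL) {
  stopifnot(inherits(table, "reference_table"), tolerance > 0, tolerance <= 1)
  if (!is.null(obs)) {
    stopifnot(length(obs) == ncol(table$stats))
    table$obs <- as.numeric(obs)
  }
  n_sim <- nrow(table$stats)
  M <- floor(tolerance * n_sim + 1e-9)  # epsilon guards float representation
  if (M < 2) stop("tolerance * n_sim must be >= 2")
  sc <- mad_scale(table$stats, table$obs)
  d <- euclidean_distances(sc$stats, sc$obs)
  acc <- order(d)[seq_len(M)]  # order() is stable: distance ties keep row order
  structure(list(accepted_idx = acc,
                 distances = d[acc],
                 raw_draws = table$params[acc, , drop = FALSE],
                 adjusted_draws = NULL,
                 scaled_stats = sc$stats[acc, , drop = FALSE],
                 scaled_obs = sc$obs,
                 scale = sc$scale,
                 degenerate = sc$degenerate,
                 all_distances = d,
                 param_names = table$param_names),
            class = "abc_result")
}

#' Kernel weights for accepted distances
#'
#' Distances are rescaled by the bandwidth `d_M` (the largest accepted
#' distance); `t = d / d_M` is weighted by `0.75 (1 - t^2)` (Epanechnikov)
#' or `exp(-t^2 / 2)` (Gaussian).  Weights are non-increasing in distance,
#' so the closest accepted simulation is adjusted the least by the
#' regression step.  If `d_M = 0` (all exact matches) all weights are 1.
#'
#' @param distances Sorted accepted distances (non-negative).
#' @param kernel `"gaussian"` or `"epanechnikov"`.
#' @return Numeric weights of the same length.
#' @export
kernel_weights <- function(distances, kernel = c("gaussian", "epanechnikov")) {
  kernel <- match.arg(kernel)
  dM <- max(distances)
  if (dM == 0) return(rep(1, length(distances)))
  t <- distances / dM
  switch(kernel,
         epanechnikov = 0.75 * pmax(1 - t^2, 0),
         gaussian = exp(-t^2 / 2))
}

#' Kernel-weighted local-linear regression adjustment
#'
#' For each continuous parameter independently, fits a weighted least
#' squares regression of the accepted raw draws on the centred predictors
#' (scaled accepted statistics minus the scaled observed vector, with
#' intercept), then corrects each draw by
#' `theta* = theta - beta' (S_scaled - S_obs_scaled)`.  An exact-match row
#' (distance 0) has zero predictors and is left unadjusted; zero-weight
#' rows (Epanechnikov at `t = 1`) do not influence the fit but are still
#' adjusted with the fitted coefficients.  Collinear or constant predictor
#' columns yield `NA` coefficients and are dropped from the correction with
#' a warning.
#'
#' @param result An `abc_result` from [abc_rejection()].
#' @param kernel Kernel for the weights (see [kernel_weights()]).
#' @param adjust_params Columns (names or indices) of the parameter matrix
#'   to adjust; defaults to every column except `m` and `sex`, which are
#'   categorical and only ever summarized as accepted-draw frequencies.
#' @return The `abc_result` with `adjusted_draws` and `weights` filled in.
#' @export
regression_adjust <- function(result, kernel = c("gaussian", "epanechnikov"),
                              adjust_params = NULL) {
  stopifnot(inherits(result, "abc_result"))
  kernel <- match.arg(kernel)
  w <- kernel_weights(result$distances, kernel)
  Z <- sweep(result$scaled_stats, 2, result$scaled_obs)  # centred predictors
  if (is.null(adjust_params))
    adjust_params <- setdiff(colnames(result$raw_draws), c("m", "sex"))
  adjusted <- result$raw_draws
  fit_w <- w
  if (all(fit_w == 0)) fit_w[] <- 1  # degenerate: fall back to OLS
  # constant predictors carry no local information; drop them silently.
  # "constant" is judged with a small relative tolerance: accepted statistics
  # that share one value on the 1/Ne frequency grid can differ by rounding
  # noise (~1e-16) that would otherwise feed a numerically singular fit.
  keep <- apply(Z, 2, function(z) {
    rz <- range(z)
    (rz[2] - rz[1]) > 1e-8 * max(1, abs(rz[1]))
  })
  Zk <- Z[, keep, drop = FALSE]
  X <- cbind(`(Intercept)` = 1, Zk)
  for (p in adjust_params) {
    theta <- result$raw_draws[, p]
    if (ncol(Zk) == 0) { adjusted[, p] <- theta; next }
    fit <- stats::lm.wfit(x = X, y = theta, w = fit_w)
    beta <- fit$coefficients[-1]
    if (anyNA(beta)) {
      warning("dropping ", sum(is.na(beta)),
              " collinear predictor column(s) in regression adjustment")
      beta[is.na(beta)] <- 0
    }
    adjusted[, p] <- theta - as.vector(Zk %*% beta)
  }
  result$adjusted_draws <- adjusted
  result$weights <- w
  result$kernel <- kernel
  result
}

#' Posterior summary of accepted (or adjusted) draws
#'
#' The per-parameter posterior median is the point estimator; 2.5%/97.5%
#' quantiles and the standard deviation are reported alongside.
#'
#' @param draws Numeric matrix of draws (rows) by parameters (columns), or a
#'   vector for a single parameter.
#' @return Data frame with one row per parameter: `median`, `q2.5`, `q97.5`,
#'   `sd`.
#' @export
posterior_summary <- function(draws) {
  draws <- as.matrix(draws)
  stopifnot(nrow(draws) >= 2)
  out <- data.frame(
    median = apply(draws, 2, stats::median),
    q2.5 = apply(draws, 2, stats::quantile, probs = 0.025, names = FALSE),
    q97.5 = apply(draws, 2, stats::quantile, probs = 0.975, names = FALSE),
    sd = apply(draws, 2, stats::sd))
  rownames(out) <- colnames(draws)
  out
}

#' @export
print.abc_result <- function(x, ...) {
  cat(sprintf("ABC result: %d accepted draws (max distance %.4g)\n",
              length(x$accepted_idx), max(x$distances)))
  draws <- if (is.null(x$adjusted_draws)) x$raw_draws else x$adjusted_draws
  cat(if (is.null(x$adjusted_draws)) "  rejection-only posterior medians:\n"
      else sprintf("  regression-adjusted (%s kernel) posterior medians:\n",
                   x$kernel))
  print(posterior_summary(draws))
  invisible(x)
}
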