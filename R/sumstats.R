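#' Per-locus allele-1 frequency
#'
#' @param pop `Ne x L` binary matrix.
#' @return Length-`L` numeric vector of column means in \[0, 1\].
#' @export
allele_freq <- function(pop) colMeans(pop)

#' Per-locus fixation index between two populations
#'
#' `FST = sigma_p^2 / (pbar * (1 - pbar))` with the two-population
#' (divisor-2) variance `sigma_p^2 = (pX - pY)^2 / 4` and mean frequency
#' `pbar = (pX + pY) / 2`.  The divisor-2 form keeps FST in \[0, 1\] (the
#' divisor-1 sample variance would allow values up to 2).  Monomorphic loci
#' (`pbar` 0 or 1) return 0: no differentiation is measurable there.
#'
#' @param pX,pY Allele-frequency vectors in \[0, 1\] of equal length.
#' @return Length-`L` FST vector in \[0, 1\].
#' @examples
#' fst_per_locus(0.8, 0.2)  # 0.36
#' @export
fst_per_locus <- function(pX, pY) {
  stopifnot(length(pX) == length(pY))
  pbar <- (pX + pY) / 2
  denom <- pbar * (1 - pbar)
  sigma2 <- (pX - pY)^2 / 4
  fst <- ifelse(denom > 0, sigma2 / denom, 0)
  pmin(pmax(fst, 0), 1)
}

#' Signed per-locus FST
#'
#' FST given the sign of `pX - pY`: negative where population X has the
#' lower allele-1 frequency.  Captures which population carries the
#' advantaged allele; range \[-1, 1\].
#'
#' @inheritParams fst_per_locus
#' @return Length-`L` signed FST vector.
#' @export
sign_fst_per_locus <- function(pX, pY) {
  ifelse(pX - pY < 0, -1, 1) * fst_per_locus(pX, pY)
}

#' Extended haplotype homozygosity profile around a core locus
#'
#' For each distance `v = 0, ..., L-1` (SNP units), carriers are grouped by
#' their allele string over the two-sided window `[core - v, core + v]`
#' clipped to `[1, L]`, and
#' `EHH(v) = sum_z n_z^2 / (n0^2 + n1^2)` where `n0`, `n1` count carriers
#' with allele 0/1 at the core.  `EHH(0) = 1` exactly, and the profile is
#' non-increasing in `v` because widening the window can only refine groups.
#' The squared-count (rather than `n (n - 1)`) homozygosity form is used
#' deliberately; see the methods vignette.
#'
#' @param pop `Ne x L` binary matrix.
#' @param core_locus Core SNP index in `[1, L]`.
#' @return Numeric vector of length `L`: `EHH(v)` for `v = 0, ..., L-1`.
#' @export
ehh_profile <- function(pop, core_locus) {
  L <- ncol(pop)
  stopifnot(core_locus >= 1, core_locus <= L)
  a <- pop[, core_locus]
  n0 <- sum(a == 0L)
  denom <- n0^2 + (length(a) - n0)^2
  ehh <- numeric(L)
  ehh[1] <- 1
  g <- a + 1L  # window-string group ids, refined as the window widens
  if (L > 1) for (v in seq_len(L - 1L)) {
    lo <- core_locus - v
    hi <- core_locus + v
    key <- g
    if (lo >= 1L) key <- key * 2L + pop[, lo]
    if (hi <= L)  key <- key * 2L + pop[, hi]
    g <- match(key, unique(key))
    ehh[v + 1L] <- sum(tabulate(g)^2) / denom
  }
  ehh
}

#' Cross-population extended haplotype homozygosity
#'
#' Per core locus, both populations' EHH profiles are thresholded (values
#' below `cutoff` set to 0), integrated over `v` by a unit-step rectangle
#' sum, and compared as `XP-EHH = log(integral_X / integral_Y)`.  Because
#' `EHH(0) = 1` survives any cutoff below 1, both integrals are >= 1 and the
#' log is always finite.  Positive values indicate slower homozygosity decay
#' (stronger hitchhiking) in population X.
#'
#' @param popX,popY Binary matrices with the same number of loci.
#' @param cutoff EHH threshold defining the integration domain (default
#'   0.05).
#' @param loci Core loci to evaluate (default: all `L`).
#' @return Numeric vector on the log-ratio scale, one value per core locus.
#' @export
xp_ehh <- function(popX, popY, cutoff = 0.05, loci = seq_len(ncol(popX))) {
  stopifnot(ncol(popX) == ncol(popY), cutoff > 0, cutoff < 1)
  vapply(loci, function(core) {
    ex <- ehh_profile(popX, core)
    ey <- ehh_profile(popY, core)
    ex[ex < cutoff] <- 0
    ey[ey < cutoff] <- 0
    log(sum(ex) / sum(ey))
  }, numeric(1))
}

#' FST outlier scan
#'
#' Flags loci whose FST lies strictly above the empirical upper quantile
#' (default 95%) of all per-locus FST values; these become the candidate
#' loci under selection.  The quantile uses R's default linear interpolation
#' (type 7), so with all-distinct values at most `ceil((1 - quantile) * L)`
#' loci are flagged, and a constant vector yields an empty set.
#'
#' @param fst_vector Length-`L` FST vector.
#' @param quantile Upper-tail quantile defining the cutoff (default 0.95).
#' @return An object of class `outlier_set`: list with `loci` (1-based
#'   indices) and `cutoff_value`.
#' @export
fst_outlier_scan <- function(fst_vector, quantile = 0.95) {
  stopifnot(quantile > 0, quantile < 1)
  cutoff <- stats::quantile(fst_vector, quantile, names = FALSE)
  structure(list(loci = which(fst_vector > cutoff), cutoff_value = cutoff),
            class = "outlier_set")
}

#' @export
print.outlier_set <- function(x, ...) {
  cat(sprintf("FST outlier scan: %d candidate loci above cutoff %.4g\n",
              length(x$loci), x$cutoff_value))
  if (length(x$loci)) cat("  loci:", paste(x$loci, collapse = ", "), "\n")
  invisible(x)
}

# Fixed concatenation order for the ABC distance; subsets keep this order.
STAT_ORDER <- c("signFST", "pdiff", "FST", "XPEHH")

#' Summarize a population pair into per-locus statistic vectors
#'
#' Computes the requested per-locus statistics and concatenates them in the
#' fixed order `signFST, pdiff, FST, XPEHH` (restricted to the requested
#' subset) so ABC distances are reproducible.
#'
#' @param pair A [pop_pair()] (or any list with binary matrices `X`, `Y`).
#' @param stats Character subset of `c("signFST", "pdiff", "FST", "XPEHH")`.
#' @param loci Optional integer vector restricting every statistic to these
#'   loci (used when the outlier scan narrows the candidate set).
#' @param xpehh_cutoff EHH integration cutoff passed to [xp_ehh()].
#' @return An object of class `summary_vector`: list with the per-statistic
#'   vectors, the concatenated `values` vector, `stat_names` labels of the
#'   same length, and the loci used.
#' @export
summarize_pair <- function(pair, stats = "signFST", loci = NULL,
                           xpehh_cutoff = 0.05) {
  stats <- unique(stats)
  unknown <- setdiff(stats, STAT_ORDER)
  if (length(unknown))
    stop("unknown summary statistic(s): ", paste(unknown, collapse = ", "))
  stats <- STAT_ORDER[STAT_ORDER %in% stats]
  L <- ncol(pair$X)
  if (is.null(loci)) loci <- seq_len(L)
  pX <- allele_freq(pair$X)
  pY <- allele_freq(pair$Y)
  per_stat <- list()
  if ("signFST" %in% stats) per_stat$signFST <- sign_fst_per_locus(pX, pY)[loci]
  if ("pdiff" %in% stats)   per_stat$pdiff <- (pX - pY)[loci]
  if ("FST" %in% stats)     per_stat$FST <- fst_per_locus(pX, pY)[loci]
  if ("XPEHH" %in% stats)
    per_stat$XPEHH <- xp_ehh(pair$X, pair$Y, xpehh_cutoff, loci = loci)
  values <- unlist(per_stat, use.names = FALSE)
  stat_names <- unlist(lapply(stats, function(s) paste0(s, "_", loci)))
  structure(c(per_stat,
              list(values = values, stat_names = stat_names, loci = loci)),
            class = "summary_vector")
}
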