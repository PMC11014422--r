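#' Deterministic one-generation selection update
#'
#' Infinite-population expectation of the fitness-weighted multinomial
#' reproduction for a single selected locus: a fraction `p` of carriers has
#' fitness `1 + s` and the rest fitness 1, so the next-generation frequency
#' is `p' = p (1 + s) / (1 + p s)`.  Frequencies 0 and 1 are absorbing.
#'
#' @param p Allele frequency in \[0, 1\].
#' @param s Selection coefficient (|s| <= 0.25 keeps the denominator
#'   positive with a wide margin).
#' @return Updated frequency.
#' @export
det_step_selection <- function(p, s) {
  stopifnot(all(p >= 0), all(p <= 1))
  denom <- 1 + p * s
  if (any(denom <= 0)) stop("1 + p * s must be positive")
  p * (1 + s) / denom
}

#' Deterministic symmetric migration update
#'
#' Linear mixing of the two populations' frequencies:
#' `pX' = (1 - m) pX + m pY` and symmetrically for Y.  The mean frequency
#' `(pX + pY) / 2` is conserved.
#'
#' @param pX,pY Frequencies in \[0, 1\].
#' @param m Migration rate in \[0, 1).
#' @return List with updated `pX` and `pY`.
#' @export
det_step_migration <- function(pX, pY, m) {
  stopifnot(m >= 0, m < 1)
  list(pX = (1 - m) * pX + m * pY,
       pY = (1 - m) * pY + m * pX)
}

#' Deterministic single-locus trajectory
#'
#' Runs the infinite-population expectation model on exactly the simulator's
#' schedule: selection updates on population X (Y neutral) at every
#' generation not divisible by `t_star`, and symmetric migration mixing at
#' generations `t_star, 2 t_star, ..., (n_cycles - 1) t_star`.  The
#' migration generation itself applies no selection, mirroring the
#' simulator's fitness-free migration reproduction.
#'
#' @param p0 Founding frequency at t = 0 (default 0.5).
#' @param s Selection coefficient for population X.
#' @param m Migration rate.
#' @param fixed A [fixed_params()] object supplying `t_star`, `n_cycles`.
#' @return An object of class `det_trajectory`: list with vectors `pX`, `pY`
#'   over `t = 0, ..., t_final` (length `t_final + 1`), the parameters, and
#'   the deterministic `fst`, `sign_fst` and `pdiff` at `t_final`.
#' @export
det_trajectory <- function(p0 = 0.5, s, m = 0, fixed) {
  stopifnot(inherits(fixed, "fixed_params"), p0 >= 0, p0 <= 1)
  tf <- fixed$t_final
  pX <- pY <- numeric(tf + 1)
  pX[1] <- pY[1] <- p0
  for (t in seq_len(tf)) {
    if (t %% fixed$t_star == 0L) {
      mixed <- det_step_migration(pX[t], pY[t], m)
      pX[t + 1] <- mixed$pX
      pY[t + 1] <- mixed$pY
    } else {
      pX[t + 1] <- det_step_selection(pX[t], s)
      pY[t + 1] <- pY[t]
    }
  }
  structure(list(pX = pX, pY = pY,
                 params = list(p0 = p0, s = s, m = m, t_star = fixed$t_star,
                               n_cycles = fixed$n_cycles),
                 fst = fst_per_locus(pX[tf + 1], pY[tf + 1]),
                 sign_fst = sign_fst_per_locus(pX[tf + 1], pY[tf + 1]),
                 pdiff = pX[tf + 1] - pY[tf + 1]),
            class = "det_trajectory")
}

#' @export
print.det_trajectory <- function(x, ...) {
  tf <- length(x$pX) - 1
  cat(sprintf("Deterministic single-locus trajectory (s = %g, m = %g, %d generations)\n",
              x$params$s, x$params$m, tf))
  cat(sprintf("  final pX = %.4f, pY = %.4f, signFST = %.4f\n",
              x$pX[tf + 1], x$pY[tf + 1], x$sign_fst))
  invisible(x)
}
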