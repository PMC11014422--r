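#' Found the two populations (F2 at generation 0)
#'
#' Builds each F1 pool by giving every carrier a constant genome of all-0 or
#' all-1 alleles (each with probability 0.5, independently per carrier), then
#' produces each F2 population of `Ne` offspring by recombining one uniformly
#' chosen parent from the X F1 pool with one uniformly chosen parent from the
#' Y F1 pool.  Both F2 populations draw from the same two F1 pools, so the
#' expected allele frequency at every locus is 0.5 at t = 0.
#'
#' @param fixed A [fixed_params()] object.
#' @return A [pop_pair()] at generation `t = 0`.
#' @export
found_populations <- function(fixed) {
  stopifnot(inherits(fixed, "fixed_params"))
  Ne <- fixed$Ne; L <- fixed$L
  constant_pool <- function() {
    a <- sample(0:1, Ne, replace = TRUE)
    matrix(as.integer(a), nrow = Ne, ncol = L)  # row n is constant a[n]
  }
  XF1 <- constant_pool()
  YF1 <- constant_pool()
  cross_f2 <- function() {
    p1 <- sample.int(Ne, Ne, replace = TRUE)
    p2 <- sample.int(Ne, Ne, replace = TRUE)
    cpp_cross_parents(XF1[p1, , drop = FALSE], YF1[p2, , drop = FALSE],
                      fixed$snp_spacing, fixed$r)
  }
  pop_pair(cross_f2(), cross_f2(), t = 0L)
}

#' Sample crossover breakpoints for one meiosis
#'
#' Draws the crossover count `nr ~ Binomial(L * snp_spacing - 1, r)` on the
#' bp axis, places the events uniformly on `[1, L * snp_spacing - 1]`, and
#' maps each bp position to the SNP interval `ceil(pos / snp_spacing)`
#' clipped to `[1, L - 1]`.  A breakpoint `k` means the offspring switches
#' parent between SNP `k` and SNP `k + 1`; duplicate intervals collapse to a
#' single switch (at most one observable crossover between consecutive SNPs).
#'
#' @param fixed A [fixed_params()] object.
#' @return Sorted, deduplicated integer vector of SNP-interval breakpoints
#'   (possibly empty).
#' @export
sample_crossovers <- function(fixed) {
  nbp <- as.double(fixed$L) * fixed$snp_spacing - 1
  nr <- stats::rbinom(1L, size = nbp, prob = fixed$r)
  if (nr == 0L) return(integer(0))
  pos <- floor(stats::runif(nr, 0, nbp)) + 1       # bp positions 1 .. nbp
  iv <- pmin.int(pmax.int(ceiling(pos / fixed$snp_spacing), 1L), fixed$L - 1L)
  sort(unique(as.integer(iv)))
}

#' Recombine two parental haplotypes into one offspring
#'
#' With probability 0.5 the parental roles are swapped; the offspring then
#' copies the current parent's alleles left to right and switches parent
#' after each breakpoint SNP.
#'
#' @param p1,p2 Integer vectors of equal length `L` over \{0, 1\}.
#' @param breakpoints Sorted SNP-interval breakpoints in `[1, L - 1]`
#'   (e.g. from [sample_crossovers()]); breakpoint `k` switches the template
#'   after SNP `k`.
#' @param swap Optional logical overriding the random role swap (used for
#'   deterministic checks); `NULL` (default) draws it from the RNG.
#' @return Integer offspring haplotype of length `L`.
#' @examples
#' recombine_offspring(rep(0L, 6), rep(1L, 6), breakpoints = 3, swap = FALSE)
#' @export
recombine_offspring <- function(p1, p2, breakpoints = integer(), swap = NULL) {
  L <- length(p1)
  stopifnot(length(p2) == L)
  if (length(breakpoints) > 0)
    stopifnot(all(breakpoints >= 1L), all(breakpoints <= L - 1L))
  if (is.null(swap)) swap <- stats::runif(1) < 0.5
  if (swap) { tmp <- p1; p1 <- p2; p2 <- tmp }
  if (length(breakpoints) == 0) return(as.integer(p1))
  # parent indicator per locus: number of breakpoints strictly before locus, mod 2
  use2 <- (findInterval(seq_len(L) - 1L, sort(breakpoints)) %% 2L) == 1L
  as.integer(ifelse(use2, p2, p1))
}

#' Absolute fitness of every carrier
#'
#' Fitness is additive over the selected loci: for population X,
#' `w_n = sum_i (1 + I(carrier n has the selected allele at locus i) * s_i)`.
#' Population Y never experiences selection, so every Y carrier contributes
#' `(1 + 0)` per selected locus and all fitnesses are equal.  With zero
#' selected loci the empty sum is taken as 1 for every carrier (any positive
#' constant gives the same reproduction probabilities).
#'
#' Note the additive form makes the neutral baseline equal the number of
#' selected loci, not 1; only fitness ratios matter for reproduction.
#'
#' @param pop `Ne x L` binary matrix.
#' @param drawn A [drawn_params()] object.
#' @param which `"X"` (selected population) or `"Y"` (neutral).
#' @return Numeric vector of `Ne` absolute fitnesses.
#' @export
fitness_vector <- function(pop, drawn, which = c("X", "Y")) {
  which <- match.arg(which)
  Ne <- nrow(pop)
  k <- length(drawn$sel_loci)
  if (k == 0L || which == "Y") return(rep(max(k, 1L), Ne))
  carried <- pop[, drawn$sel_loci, drop = FALSE]
  has_allele <- carried == matrix(drawn$sel_alleles, Ne, k, byrow = TRUE)
  as.vector(k + has_allele %*% drawn$sel_coeffs)
}

#' Fitness-weighted reproduction probabilities
#'
#' @param w Numeric vector of positive absolute fitnesses.
#' @return Probabilities `w / sum(w)` (sum to 1).
#' @export
offspring_probs <- function(w) {
  if (any(w <= 0) || sum(w) <= 0)
    stop("non-positive fitness: invalid selection parameters")
  w / sum(w)
}

#' One generation of within-cycle selection and clonal reproduction
#'
#' Draws offspring counts from `Multinomial(Ne, p)` with `p` the normalized
#' fitnesses; each offspring is an exact clonal copy of its parent.
#'
#' @inheritParams fitness_vector
#' @param fixed A [fixed_params()] object (unused beyond validation; kept for
#'   a uniform generation-step signature).
#' @return The next-generation `Ne x L` matrix.
#' @export
selection_generation <- function(pop, drawn, which = c("X", "Y"), fixed = NULL) {
  which <- match.arg(which)
  Ne <- nrow(pop)
  p <- offspring_probs(fitness_vector(pop, drawn, which))
  counts <- as.vector(stats::rmultinom(1L, Ne, p))
  pop[rep.int(seq_len(Ne), counts), , drop = FALSE]
}

#' Swap migrants between the two populations
#'
#' Symmetric migration: `round(Ne * m)` carriers (banker's rounding) are
#' chosen uniformly without replacement in each population, independently of
#' each other, and exchanged simultaneously, conserving both population
#' sizes.
#'
#' @param pair A [pop_pair()].
#' @param m Migration rate in \[0, 1) with `round(Ne * m) < Ne`.
#' @return The pair after the swap (generation counter untouched).
#' @export
migrate_swap <- function(pair, m) {
  stopifnot(m >= 0, m < 1)
  Ne <- nrow(pair$X)
  n_mig <- round(Ne * m)
  stopifnot(n_mig < Ne)
  if (n_mig > 0) {
    ix <- sample.int(Ne, n_mig)
    iy <- sample.int(Ne, n_mig)
    tmp <- pair$X[ix, , drop = FALSE]
    pair$X[ix, ] <- pair$Y[iy, , drop = FALSE]
    pair$Y[iy, ] <- tmp
  }
  pair
}

#' Migration generation: migrant exchange then neutral reproduction
#'
#' Applies [migrate_swap()], then within each post-migration population
#' produces `Ne` offspring without fitness weighting: if `sex = 0` each
#' offspring clones a uniformly chosen parent; if `sex = 1` each offspring
#' recombines two uniformly, independently chosen parents (crossovers drawn
#' as in [sample_crossovers()]).
#'
#' @param pair A [pop_pair()].
#' @param drawn A [drawn_params()] supplying `m` and `sex`.
#' @param fixed A [fixed_params()] object.
#' @return The reproduced [pop_pair()] (caller advances the counter).
#' @export
migration_generation <- function(pair, drawn, fixed) {
  pair <- migrate_swap(pair, drawn$m)
  Ne <- nrow(pair$X)
  reproduce <- function(P) {
    if (drawn$sex == 0L) {
      P[sample.int(Ne, Ne, replace = TRUE), , drop = FALSE]
    } else {
      p1 <- sample.int(Ne, Ne, replace = TRUE)
      p2 <- sample.int(Ne, Ne, replace = TRUE)
      cpp_cross_parents(P[p1, , drop = FALSE], P[p2, , drop = FALSE],
                        fixed$snp_spacing, fixed$r)
    }
  }
  pair$X <- reproduce(pair$X)
  pair$Y <- reproduce(pair$Y)
  pair
}

#' Run the full migration-selection simulation
#'
#' From the founded F2 pair at `t = 0`, applies [selection_generation()] to X
#' (with selection) and Y (neutral) at every generation not divisible by
#' `t_star`, and [migration_generation()] at generations `c * t_star` for
#' `c = 1, ..., n_cycles - 1`.  The run halts at
#' `t_final = n_cycles * t_star - 1`, the last generation before what would
#' be the final migration, so there are `n_cycles - 1` migration events.
#'
#' @param fixed A [fixed_params()] object.
#' @param drawn A [drawn_params()] object.
#' @param pair Optional starting [pop_pair()] (default: a fresh founding).
#' @param trace_loci Optional locus indices whose allele frequencies are
#'   recorded at every generation; the result then carries a `trace` element
#'   with `(t_final + 1) x length(trace_loci)` matrices `pX` and `pY`.
#' @return The [pop_pair()] at generation `t_final`.
#' @export
run_simulation <- function(fixed, drawn, pair = NULL, trace_loci = NULL) {
  stopifnot(inherits(fixed, "fixed_params"), inherits(drawn, "drawn_params"))
  if (length(drawn$sel_loci)) stopifnot(all(drawn$sel_loci <= fixed$L))
  if (is.null(pair)) pair <- found_populations(fixed)
  tracing <- !is.null(trace_loci)
  if (tracing) {
    trX <- trY <- matrix(NA_real_, fixed$t_final + 1L, length(trace_loci))
    trX[1, ] <- allele_freq(pair$X[, trace_loci, drop = FALSE])
    trY[1, ] <- allele_freq(pair$Y[, trace_loci, drop = FALSE])
  }
  for (t in seq_len(fixed$t_final)) {
    if (t %% fixed$t_star == 0L) {
      pair <- migration_generation(pair, drawn, fixed)
    } else {
      pair$X <- selection_generation(pair$X, drawn, "X", fixed)
      pair$Y <- selection_generation(pair$Y, drawn, "Y", fixed)
    }
    pair$t <- t
    if (tracing) {
      trX[t + 1L, ] <- allele_freq(pair$X[, trace_loci, drop = FALSE])
      trY[t + 1L, ] <- allele_freq(pair$Y[, trace_loci, drop = FALSE])
    }
  }
  if (tracing) pair$trace <- list(loci = trace_loci, pX = trX, pY = trY)
  pair
}
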