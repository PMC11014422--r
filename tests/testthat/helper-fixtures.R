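# Shared fixtures and independent oracles used across the test files.

# Small fixed-parameter bundle; override any field via ...
fx_small <- function(...) {
  args <- utils::modifyList(
    list(r = 3e-4, t_star = 5, n_cycles = 4, Ne = 50, L = 20,
         snp_spacing = 165), list(...))
  do.call(fixed_params, args)
}

# Random binary haplotype matrix
rand_pop <- function(Ne, L, p = 0.5) {
  matrix(as.integer(stats::runif(Ne * L) < p), Ne, L)
}

# Brute-force EHH oracle: group haplotypes by the pasted window string.
ehh_oracle <- function(pop, core) {
  Ne <- nrow(pop); L <- ncol(pop)
  n0 <- sum(pop[, core] == 0)
  denom <- n0^2 + (Ne - n0)^2
  vapply(0:(L - 1), function(v) {
    win <- max(1, core - v):min(L, core + v)
    key <- apply(pop[, win, drop = FALSE], 1, paste, collapse = "")
    sum(table(key)^2) / denom
  }, numeric(1))
}

# Synthetic reference table with stats linear in the parameters plus noise:
# theta ~ Unif(-1,1)^n_param, stats = theta %*% t(A) + noise.
linear_table <- function(n_sim = 500, n_param = 2, n_stat = 3, noise = 0,
                         theta_obs = NULL) {
  A <- matrix(seq_len(n_stat * n_param), n_stat, n_param)
  theta <- matrix(stats::runif(n_sim * n_param, -1, 1), n_sim, n_param)
  S <- theta %*% t(A) + matrix(stats::rnorm(n_sim * n_stat, 0, noise),
                               n_sim, n_stat)
  if (is.null(theta_obs)) theta_obs <- rep(0.25, n_param)
  obs <- as.vector(A %*% theta_obs)
  list(table = reference_table(theta, S, obs,
                               stat_names = paste0("S", seq_len(n_stat)),
                               param_names = paste0("theta", seq_len(n_param))),
       theta_obs = theta_obs)
}
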