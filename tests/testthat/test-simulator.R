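test_that("fixed_params validates inputs and derives t_final", {
  fx <- fx_small(t_star = 5, n_cycles = 4)
  expect_s3_class(fx, "fixed_params")
  expect_identical(fx$t_final, 19L)
  expect_error(fx_small(r = 0))
  expect_error(fx_small(t_star = 1))
  expect_error(fx_small(Ne = 1))
})

test_that("drawn_params enforces its invariants", {
  d <- drawn_params(sel_loci = c(3, 7), sel_coeffs = c(0.1, -0.2), m = 0.2,
                    sex = 1, L = 10)
  expect_identical(d$sel_alleles, c(1L, 1L))
  expect_error(drawn_params(sel_loci = c(3, 3), sel_coeffs = c(0.1, 0.1)))
  expect_error(drawn_params(sel_loci = 11, sel_coeffs = 0.1, L = 10))
  expect_error(drawn_params(m = 1))
  expect_error(drawn_params(sex = 2))
})

test_that("founding produces valid matrices and near-constant rows when r is tiny", {
  set.seed(11)
  fx <- fx_small(Ne = 40, L = 15)
  pair <- found_populations(fx)
  for (M in list(pair$X, pair$Y)) {
    expect_identical(dim(M), c(40L, 15L))
    expect_true(all(M %in% 0:1))
  }
  expect_identical(pair$t, 0L)

  # r -> 0: no crossovers, so each offspring equals one constant F1 parent
  fx0 <- fx_small(r = 1e-12, Ne = 30, L = 12)
  pair0 <- found_populations(fx0)
  row_constant <- function(M) apply(M, 1, function(x) all(x == x[1]))
  expect_true(all(row_constant(pair0$X)))
  expect_true(all(row_constant(pair0$Y)))
})

test_that("founding allele frequency is centred on 0.5", {
  set.seed(12)
  # averaged over 200 seeded foundings the per-locus frequency is symmetric
  fx <- fx_small(Ne = 10000, L = 100)
  means <- replicate(200, mean(allele_freq(found_populations(fx)$X)))
  se <- stats::sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 0.5), 4 * se + 1e-6)
})

test_that("sample_crossovers respects the bp-to-interval convention", {
  set.seed(13)
  fx <- fx_small(L = 100, snp_spacing = 165, r = 3e-4)
  for (i in 1:50) {
    bk <- sample_crossovers(fx)
    expect_true(all(bk >= 1 & bk <= fx$L - 1))
    expect_identical(bk, sort(unique(bk)))
  }
  fx_tiny_r <- fx_small(r = 1e-12)
  expect_identical(sample_crossovers(fx_tiny_r), integer(0))
})

test_that("recombine_offspring follows the alternation rule", {
  p1 <- rep(0L, 6); p2 <- rep(1L, 6)
  expect_identical(recombine_offspring(p1, p2, breakpoints = 3, swap = FALSE),
                   c(0L, 0L, 0L, 1L, 1L, 1L))
  expect_identical(recombine_offspring(p1, p2, breakpoints = 3, swap = TRUE),
                   c(1L, 1L, 1L, 0L, 0L, 0L))
  expect_identical(recombine_offspring(p1, p2, breakpoints = c(2, 4),
                                       swap = FALSE),
                   c(0L, 0L, 1L, 1L, 0L, 0L))
  # identical parents: breakpoints irrelevant
  set.seed(14)
  expect_identical(recombine_offspring(p1, p1, breakpoints = c(1, 3, 5)), p1)
  # empty breakpoints: each parent chosen with probability ~ 0.5
  set.seed(15)
  from_p1 <- replicate(1000, recombine_offspring(p1, p2)[1] == 0L)
  expect_lt(abs(mean(from_p1) - 0.5), 3 * sqrt(0.25 / 1000))
  expect_error(recombine_offspring(p1, p2, breakpoints = 6))
})

test_that("the batch C++ crossing kernel matches the R primitives draw-for-draw", {
  fx <- fx_small(L = 30, r = 5e-4, snp_spacing = 165)
  for (seed in 101:130) {
    set.seed(seed)
    p1 <- rand_pop(1, 30)[1, ]; p2 <- rand_pop(1, 30)[1, ]
    set.seed(seed * 7)
    bk <- sample_crossovers(fx)
    off_r <- recombine_offspring(p1, p2, bk)
    set.seed(seed * 7)
    off_c <- divselABC:::cpp_cross_parents(rbind(p1), rbind(p2),
                                           fx$snp_spacing, fx$r)[1, ]
    expect_identical(off_c, off_r)
  }
})

test_that("fitness follows the additive form with Y always neutral", {
  pop <- rbind(c(1L, 1L, 0L), c(0L, 1L, 1L))
  d1 <- drawn_params(sel_loci = 1, sel_coeffs = 0.25, L = 3)
  expect_equal(fitness_vector(pop, d1, "X"), c(1.25, 1.0))
  d2 <- drawn_params(sel_loci = c(1, 2), sel_coeffs = c(-0.025, -0.025), L = 3)
  expect_equal(fitness_vector(pop, d2, "X"), c(1.95, 1.975))
  # population Y: always equal fitness whatever the genotypes
  expect_true(length(unique(fitness_vector(pop, d2, "Y"))) == 1)
  # zero selected loci: flat fitness of 1
  d0 <- drawn_params()
  expect_equal(fitness_vector(pop, d0, "X"), c(1, 1))
})

test_that("offspring probabilities normalize as in the reproduction rule", {
  expect_equal(offspring_probs(c(1.25, 1.0)), c(5 / 9, 4 / 9))
  expect_equal(sum(offspring_probs(stats::runif(50, 0.5, 2))), 1,
               tolerance = 1e-12)
  expect_error(offspring_probs(c(1, 0)))
})

test_that("neutral multinomial reproduction is an unbiased resampling", {
  set.seed(16)
  pop <- rand_pop(200, 4, p = 0.3)
  p_parent <- allele_freq(pop)
  d0 <- drawn_params()
  means <- rowMeans(replicate(500, allele_freq(
    selection_generation(pop, d0, "X"))))
  se <- sqrt(p_parent * (1 - p_parent) / 200 / 500)
  expect_true(all(abs(means - p_parent) < 4 * se))
})

test_that("migrant swap exchanges round(Ne*m) rows symmetrically", {
  set.seed(17)
  Ne <- 40
  pair <- pop_pair(matrix(1L, Ne, 5), matrix(0L, Ne, 5))
  swapped <- migrate_swap(pair, 0.5)
  expect_identical(sum(rowSums(swapped$X) == 0), as.integer(round(Ne / 2)))
  expect_identical(sum(rowSums(swapped$Y) == 5), as.integer(round(Ne / 2)))
  # m = 0 is a no-op
  expect_identical(migrate_swap(pair, 0)$X, pair$X)
  expect_error(migrate_swap(pair, 1))
})

test_that("migration generation preserves shape, entries and (m=0,sex=0) expectations", {
  set.seed(18)
  fx <- fx_small(Ne = 60, L = 8)
  pair <- pop_pair(rand_pop(60, 8), rand_pop(60, 8))
  d <- drawn_params(m = 0.2, sex = 1)
  out <- migration_generation(pair, d, fx)
  expect_identical(dim(out$X), dim(pair$X))
  expect_true(all(out$X %in% 0:1) && all(out$Y %in% 0:1))

  # m=0, sex=0: uniform cloning leaves marginal frequencies unbiased
  p0 <- allele_freq(pair$X)
  reps <- replicate(400, allele_freq(
    migration_generation(pair, drawn_params(m = 0, sex = 0), fx)$X))
  se <- sqrt(p0 * (1 - p0) / 60 / 400)
  expect_true(all(abs(rowMeans(reps) - p0) < 4 * se))
})

test_that("run_simulation halts at t_final with valid state", {
  set.seed(19)
  fx <- fx_small(Ne = 40, L = 10, t_star = 5, n_cycles = 4)
  d <- drawn_params(sel_loci = 5, sel_coeffs = 0.2, m = 0.2, sex = 1, L = 10)
  pair <- run_simulation(fx, d)
  expect_identical(pair$t, 19L)
  expect_identical(dim(pair$X), c(40L, 10L))
  expect_true(all(pair$X %in% 0:1) && all(pair$Y %in% 0:1))

  fx2 <- fx_small(t_star = 50, n_cycles = 4, Ne = 10, L = 4)
  expect_identical(fx2$t_final, 199L)
})

test_that("neutral drift preserves the mean frequency across whole runs", {
  set.seed(20)
  fx <- fx_small(Ne = 200, L = 5, t_star = 5, n_cycles = 4)
  d0 <- drawn_params(m = 0, sex = 0)
  finals <- replicate(200, mean(allele_freq(run_simulation(fx, d0)$X)))
  se <- stats::sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - 0.5), 4 * se)
})
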