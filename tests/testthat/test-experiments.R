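test_that("scenario presets reproduce the published schedule arithmetic", {
  expect_identical(scenario_spec(1)$fixed$t_final, 19L)
  expect_identical(scenario_spec(2)$fixed$t_final, 199L)
  expect_identical(scenario_spec(3)$fixed$t_final, 99L)
  expect_identical(scenario_spec(4)$fixed$t_final, 199L)
  expect_equal(scenario_spec(1)$prior$s_bound, 0.25)
  expect_equal(scenario_spec(2)$prior$s_bound, 0.025)
  expect_equal(scenario_spec(4)$fixed$r, 2e-5)
  sc_full <- scenario_spec(4, "outlier_scan", full_scale = TRUE)
  expect_identical(sc_full$n_abc, 10L)
  expect_identical(sc_full$n_sim, 100000L)
})

test_that("candidate loci sit at thirds and the middle of the genome", {
  expect_identical(default_candidate_loci(100), c(33L, 50L, 67L))
  expect_identical(default_candidate_loci(60), c(20L, 30L, 40L))
  expect_identical(default_candidate_loci(1500), c(500L, 750L, 1000L))
})

test_that("the prior draws locus combinations uniformly and respects bounds", {
  set.seed(51)
  prior <- prior_spec(0.025, c(33L, 50L, 67L))
  expect_length(prior$locus_combos, 7)  # {}, 3 singles, 3 pairs

  n <- 7000
  draws <- replicate(n, {
    d <- sample_prior(prior)
    paste(d$sel_loci, collapse = "-")
  })
  freq <- table(draws) / n
  expect_length(freq, 7)
  se <- sqrt((1 / 7) * (6 / 7) / n)
  expect_true(all(abs(freq - 1 / 7) < 4 * se))

  set.seed(52)
  ds <- replicate(2000, sample_prior(prior), simplify = FALSE)
  ss <- unlist(lapply(ds, `[[`, "sel_coeffs"))
  expect_true(all(abs(ss) <= 0.025))
  expect_true(all(unlist(lapply(ds, `[[`, "sel_loci")) %in% c(33, 50, 67)))
  # only the four admissible (m, sex) combinations ever occur
  msex <- unique(t(vapply(ds, function(d) c(d$m, d$sex), numeric(2))))
  expect_true(all(apply(msex, 1, paste, collapse = "/") %in%
                    c("0/0", "0/1", "0.2/1", "0.5/1")))
})

test_that("parameter flattening is positional and invertible on the candidates", {
  d <- drawn_params(sel_loci = c(67L, 33L), sel_coeffs = c(0.1, -0.2),
                    m = 0.2, sex = 1)
  v <- divselABC:::flatten_params(d, c(33L, 50L, 67L))
  expect_equal(v, c(-0.2, 0, 0.1, 0.2, 1))
  expect_identical(divselABC:::param_names_for(c(33L, 50L, 67L)),
                   c("s_33", "s_50", "s_67", "m", "sex"))
})

test_that("error decomposition satisfies MSE = variance + bias^2", {
  set.seed(53)
  rec <- data.frame(true_s = stats::runif(400, -0.25, 0.25))
  rec$est <- rec$true_s + stats::rnorm(400, mean = 0.02, sd = 0.05)
  ev <- evaluate_estimates(rec, s_bound = 0.25, n_bins = 10)
  expect_equal(ev$mse, ev$variance + ev$bias2, tolerance = 1e-10)
  expect_equal(sum(ev$n), 400)

  # loop oracle for one bin
  bin1 <- rec[rec$true_s >= -0.25 & rec$true_s <= -0.20, ]
  e <- bin1$est - bin1$true_s
  expect_equal(ev$mse[1], mean(e^2))

  # exact estimates: all zero; constant offset: pure bias
  rec0 <- data.frame(true_s = stats::runif(50, -0.2, 0.2))
  rec0$est <- rec0$true_s
  ev0 <- evaluate_estimates(rec0, s_bound = 0.25)
  expect_true(all(ev0$mse == 0) && all(ev0$bias2 == 0))
  rec0$est <- rec0$true_s + 0.03
  evc <- evaluate_estimates(rec0, s_bound = 0.25)
  expect_equal(evc$bias2, rep(0.03^2, nrow(evc)), tolerance = 1e-12)
  expect_true(all(evc$variance < 1e-12))

  # grouped evaluation keeps the identity per group
  rec$m <- sample(c(0, 0.5), 400, replace = TRUE)
  evg <- evaluate_estimates(rec, s_bound = 0.25, n_bins = 5, by = "m")
  expect_equal(evg$mse, evg$variance + evg$bias2, tolerance = 1e-10)
})

test_that("method 1 pipeline runs end to end at smoke scale", {
  set.seed(54)
  sc <- scenario_spec(1, "fixed_loci", Ne = 100L, L = 30L,
                      n_sim = 400L, n_abc = 5L)
  rep1 <- run_method1(sc, tolerance = 0.2,
                      stat_loci = sc$prior$candidate_loci)
  expect_s3_class(rep1, "eval_report")
  expect_identical(nrow(rep1$records), 15L)  # 5 iterations x 3 candidate loci
  expect_true(all(is.finite(rep1$records$est)))
  expect_true(all(is.finite(rep1$records$est_rej)))
  expect_true(all(rep1$records$locus %in% c(10, 15, 20)))
  expect_true(all(abs(rep1$records$true_s) <= 0.25))
})

test_that("method 2 restricts estimates to the outlier candidates", {
  set.seed(55)
  sc <- scenario_spec(1, "outlier_scan", Ne = 100L, L = 40L,
                      n_sim = 150L, n_abc = 3L)
  rep2 <- run_method2(sc, tolerance = 0.1)
  r <- rep2$records
  expect_s3_class(rep2, "eval_report")
  expect_length(rep2$outlier_sets, 3)
  # any locus outside the outlier set has a forced estimate of zero
  expect_true(all(r$est[!r$in_outlier_set] == 0))
  expect_true(all(is.finite(r$est)))
  # outlier sets stay within the 5% budget
  expect_true(all(r$n_outliers <= ceiling(0.05 * 40)))
})

test_that("a strongly selected locus is usually caught by the outlier scan", {
  set.seed(56)
  # sexual reproduction at migration generations: recombination breaks up the
  # clonal background, so the scan can separate the selected locus from its
  # hitchhikers (under sex = 0 the entire genome sweeps together and no locus
  # is an outlier relative to the rest)
  fx <- fx_small(Ne = 500, L = 60, t_star = 5, n_cycles = 4)  # desk-scale Ne
  hits <- vapply(1:20, function(i) {
    d <- drawn_params(sel_loci = 30, sel_coeffs = 0.25, m = 0, sex = 1, L = 60)
    pair <- run_simulation(fx, d)
    scan <- fst_outlier_scan(fst_per_locus(allele_freq(pair$X),
                                           allele_freq(pair$Y)))
    30 %in% scan$loci
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("observed signFST geography: migration and sex suppress the signal", {
  set.seed(57)
  fx <- fx_small(Ne = 300, L = 40, t_star = 5, n_cycles = 4)
  # |signFST| at the selected locus (core) and averaged over flanking
  # neutral loci, where hitchhiking lives
  sel_signal <- function(m, sex, n = 25) {
    out <- vapply(seq_len(n), function(i) {
      d <- drawn_params(sel_loci = 20, sel_coeffs = 0.25, m = m, sex = sex,
                        L = 40)
      pair <- run_simulation(fx, d)
      sf <- abs(sign_fst_per_locus(allele_freq(pair$X), allele_freq(pair$Y)))
      c(core = sf[20], flank = mean(sf[c(10:19, 21:30)]))
    }, numeric(2))
    rowMeans(out)
  }
  s_m0_sex0 <- sel_signal(0, 0)
  s_m0_sex1 <- sel_signal(0, 1)
  s_m5_sex1 <- sel_signal(0.5, 1)
  expect_gt(s_m0_sex1[["core"]], s_m5_sex1[["core"]])  # migration erodes divergence
  # without recombination the whole background hitchhikes with the sweep
  expect_gt(s_m0_sex0[["flank"]], s_m0_sex1[["flank"]])
})
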