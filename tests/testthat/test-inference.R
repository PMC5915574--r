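test_that("IQR0 is the standard-normal interquartile range", {
  expect_equal(IQR0, qnorm(0.75) - qnorm(0.25))
  expect_equal(round(IQR0, 3), 1.349)
})

test_that("estimate_mu0: constant series, method contracts, errors", {
  expect_equal(estimate_mu0(rep(3.7, 10), method = "mean_dvars2"), 3.7)
  expect_equal(estimate_mu0(rep(3.7, 10), method = "median_dvars2"), 3.7)
  expect_error(estimate_mu0(1), "at least 2")
  expect_error(estimate_mu0(c(1, 2), method = "median_voxel_sigmaD"),
               "diffdata")
  expect_error(estimate_mu0(rep(0, 10)), "degenerate null")
})

test_that("voxelwise sigma_Di^2 is consistent and needs no extra factor", {
  set.seed(41)
  # one voxel with known differenced-data SD: IQR/IQR0 squared -> sigma_D^2
  sd_d <- 3
  diffd <- matrix(rnorm(20000, sd = sd_d), nrow = 1)
  est <- estimate_mu0(c(1, 1), diffdata = diffd, method = "mean_voxel_sigmaD")
  expect_equal(est, sd_d^2, tolerance = 0.05)
  # mu0 = mean sigma_Di^2 = 2 * mean sigma_i^2: the Eq-level truth at scale
  sim <- simulate_null(simulation_spec(I = 10000, T = 1200, sigma_min = 200,
                                       sigma_max = 500))
  Y <- sim$data
  dv2 <- 4 * compute_dse_timeseries(Y)$whole$D
  diffdata <- Y[, -1] - Y[, -ncol(Y)]
  mu_vox <- estimate_mu0(dv2, diffdata, "mean_voxel_sigmaD")
  expect_equal(mu_vox, sim$mu0_true, tolerance = 0.02)
  # and the default median-of-DVARS^2 estimator is within 1% at T = 1200
  expect_equal(estimate_mu0(dv2), sim$mu0_true, tolerance = 0.01)
})

test_that("estimate_sigma0_sq: hIQR ignores upward contamination; errors", {
  set.seed(43)
  x <- rchisq(199, df = 50)
  base <- estimate_sigma0_sq(x, "hiqr", d = 1 / 3)
  spiked <- x
  spiked[spiked > median(x)] <- spiked[spiked > median(x)] * 10
  expect_equal(estimate_sigma0_sq(spiked, "hiqr", d = 1 / 3,
                                  mu0 = median(x)), base)
  # full IQR is affected by the same contamination
  expect_gt(estimate_sigma0_sq(spiked, "iqr", d = 1 / 3, mu0 = median(x)),
            estimate_sigma0_sq(x, "iqr", d = 1 / 3, mu0 = median(x)))
  expect_error(estimate_sigma0_sq(rep(2, 10)), "degenerate null")
  expect_error(estimate_sigma0_sq(x, "hiqr", d = 0.4), "d must be")
  expect_error(estimate_sigma0_sq(c(1, 2)), "at least 4")
  # sample variance route
  expect_equal(estimate_sigma0_sq(x, "sample"), var(x))
})

test_that("null moments recovered on a null simulation", {
  set.seed(47)
  sim <- simulate_null(simulation_spec(I = 10000, T = 1200, sigma_min = 200,
                                       sigma_max = 500))
  dv2 <- 4 * compute_dse_timeseries(sim$data)$whole$D
  for (vm in c("iqr", "hiqr")) {
    est <- estimate_sigma0_sq(dv2, vm, d = 1 / 3)
    expect_equal(est, sim$sigma0_sq_true, tolerance = 0.12)
  }
  null <- estimate_null_model(dv2)
  # nu close to the effective spatial-element count I * m2^2/m4
  nu_pop <- sim$spec$I * mean(sim$true_sigma^2)^2 / mean(sim$true_sigma^4)
  expect_gt(null$nu / nu_pop, 0.5)
  expect_lt(null$nu / nu_pop, 2)
})

test_that("dvars_test algebra and p-value validity", {
  null <- null_model(mu0 = 8, sigma0_sq = 2)
  t1 <- dvars_test(8, null)
  expect_equal(t1$x_stat, null$nu)   # statistic equals its null mean
  expect_equal(null$nu, 2 * 8^2 / 2)
  # two-sided doubles the smaller tail
  t2 <- dvars_test(8, null, sided = "two")
  expect_true(t2$p_value <= 1)
  set.seed(53)
  sim <- simulate_null(simulation_spec(I = 10000, T = 1200, sigma_min = 200,
                                       sigma_max = 500))
  dv2 <- 4 * compute_dse_timeseries(sim$data)$whole$D
  p <- dvars_test(dv2, estimate_null_model(dv2))$p_value
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("z_scores: center, monotonicity, underflow fallback, agreement", {
  null <- null_model(mu0 = 1, sigma0_sq = 1e-4)  # nu = 2e4
  expect_equal(z_scores(0.5, 1, null), 0)
  p <- c(0.9, 0.5, 0.1, 1e-5)
  expect_true(all(diff(z_scores(p, rep(1, 4), null)) > 0))
  # p underflows at mu0 + 40 sigma0 once nu is large enough that the
  # chi-squared tail matches the normal one; fallback returns exactly 40
  nullb <- null_model(mu0 = 1, sigma0_sq = 2e-8)  # nu = 1e8
  dv2 <- nullb$mu0 + 40 * sqrt(nullb$sigma0_sq)
  pu <- dvars_test(dv2, nullb)$p_value
  expect_identical(pu, 0)
  expect_equal(z_scores(pu, dv2, nullb), 40)
  # chi-squared and normal-approximation Z agree for large nu in (4, 8)
  big <- null_model(mu0 = 1, sigma0_sq = 2 / 1e8)  # nu = 1e8
  z_in <- seq(4.5, 7.5, by = 0.5)
  dv2 <- big$mu0 + z_in * sqrt(big$sigma0_sq)
  z_chi <- z_scores(dvars_test(dv2, big)$p_value, dv2, big)
  expect_lt(max(abs(z_chi - z_in)), 0.01)
})

test_that("standardized variants: null point, definitions, Table-3 pairing", {
  D <- c(0.5, 0.25, 0.7016)
  dse <- fake_dse(D, A_avg = 1, I = 50L)
  null <- null_model(mu0 = 4 * 0.2896, sigma0_sq = 0.01)
  sv <- standardized_variants(dse, null)
  expect_equal(sv$pct_dvar, 100 * D)        # D = A/2 -> 50%
  expect_equal(sv$dvars, 2 * sqrt(D))
  expect_equal(sv$delta_pct_dvar[3], 41.20, tolerance = 1e-3)
  expect_equal(sv$delta_pct_dvar, sv$pct_dvar - 100 * null$mu0 / 4)
  # DVARS^2 = mu0 is the null point: delta = 0, relative DVARS = 1
  dse0 <- fake_dse(null$mu0 / 4, A_avg = 1)
  sv0 <- standardized_variants(dse0, null)
  expect_equal(sv0$delta_pct_dvar, 0)
  expect_equal(sv0$rel_dvars, 1)
})

test_that("flagging: thresholds, subset property, pair reporting", {
  base <- data.frame(t = 1:4, p_value = c(0.9, 1e-12, 1e-12, 0.5),
                     delta_pct_dvar = c(0, 41.2, 4.95, 60))
  fl <- flag_scans(base, alpha = 0.05, delta_threshold = 5)
  expect_equal(fl$flag_statistical, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(fl$flag_practical, c(FALSE, TRUE, FALSE, FALSE))
  pairs <- attr(fl, "flagged_pairs")
  expect_equal(pairs$t, c(2L, 3L))
  expect_equal(pairs$t_plus_1, c(3L, 4L))
  # no flags when p is large everywhere
  none <- flag_scans(transform(base, p_value = 0.9))
  expect_false(any(none$flag_statistical))
  # practical subset of statistical on random inputs
  set.seed(59)
  rnd <- data.frame(t = 1:200, p_value = runif(200)^4,
                    delta_pct_dvar = rnorm(200, 0, 10))
  rf <- flag_scans(rnd)
  expect_true(all(rf$flag_statistical[rf$flag_practical]))
})

test_that("median/hIQR null estimates resist spike contamination", {
  # same noise realization with and without spikes (shared seed + explicit
  # spike placement leaves the RNG stream identical)
  spec0 <- simulation_spec(I = 2000, T = 600, rho = 0.2, seed = 61)
  clean <- simulate_ar1_spikes(spec0)
  dv2c <- 4 * compute_dse_timeseries(clean$data)$whole$D
  mu_c <- estimate_mu0(dv2c)
  s2_c <- estimate_sigma0_sq(dv2c)

  # 10% of timepoints spiked (~20% of pairs): the median mean estimate
  # moves < 5%
  spiked10 <- simulate_ar1_spikes(spec0, spike_times = sample(599, 60))
  dv2s10 <- 4 * compute_dse_timeseries(spiked10$data)$whole$D
  expect_lt(abs(estimate_mu0(dv2s10) - mu_c) / mu_c, 0.05)
  # the hIQR variance estimate is perturbed (its quartiles shift once ~20%
  # of pairs move up) but orders of magnitude less than the sample variance
  rel <- function(x) abs(x - s2_c) / s2_c
  expect_lt(rel(estimate_sigma0_sq(dv2s10)) * 10,
            rel(estimate_sigma0_sq(dv2s10, "sample")))

  # at a 1% spike rate (~2% of pairs) both robust estimates hold within 5%
  spiked1 <- simulate_ar1_spikes(spec0, spike_times = sample(599, 6))
  dv2s1 <- 4 * compute_dse_timeseries(spiked1$data)$whole$D
  expect_lt(abs(estimate_mu0(dv2s1) - mu_c) / mu_c, 0.05)
  expect_lt(rel(estimate_sigma0_sq(dv2s1)), 0.05)
})

test_that("dvars_inference end-to-end with voxelwise estimator option", {
  set.seed(67)
  sim <- simulate_null(simulation_spec(I = 1000, T = 300))
  dse <- compute_dse_timeseries(sim$data)
  inf <- dvars_inference(dse, data = sim$data,
                         mu0_method = "median_voxel_sigmaD")
  expect_s3_class(inf, "dse_inference")
  expect_true(all(inf$p_value >= 0 & inf$p_value <= 1))
  null <- attr(inf, "null")
  expect_equal(null$mu0_method, "median_voxel_sigmaD")
  expect_equal(inf$delta_pct_dvar,
               inf$pct_dvar - 100 * null$mu0 / (4 * dse$averages$whole$A))
})
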