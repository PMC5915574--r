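#' Specification of a synthetic 4D noise simulation
#'
#' Describes the generator used by the bias, calibration and power
#' experiments: heteroscedastic Gaussian voxel noise with per-voxel SD drawn
#' uniformly on [sigma_min, sigma_max], optional voxelwise AR(1) temporal
#' autocorrelation with common lag-1 coefficient rho (innovation SD
#' \eqn{\sigma_i\sqrt{1-\rho^2}} so the marginal variance stays
#' \eqn{\sigma_i^2}), and variance spikes injected by multiplying the
#' innovation SD by `spike_factor` at `round(spike_rate * T)` timepoints.
#' The stock variance scenarios are homogeneous (200, 200), low
#' heterogeneity (200, 250) and high heterogeneity (200, 500), with T in
#' {100, 200, 600, 1200} and rho in {0, 0.2, 0.4, 0.6}.
#'
#' @param I number of voxels (desk-scale default 10000; full scale 90000).
#' @param T number of timepoints.
#' @param sigma_min,sigma_max bounds of the uniform voxel-SD distribution.
#' @param rho AR(1) lag-1 coefficient, 0 <= rho < 1.
#' @param spike_rate fraction of timepoints spiked, 0 <= rate < 1.
#' @param spike_factor multiplier on the innovation SD at spiked timepoints
#'   (>= 1; the declared stand-in spike amplitude model, default 2).
#' @param seed optional RNG seed for reproducibility.
#' @param replicates replicate count for experiment drivers (desk-scale
#'   default 200; full scale 1000).
#' @return object of class `dse_sim_spec`.
#' @export
simulation_spec <- function(I = 10000, T = 600, sigma_min = 200,
                            sigma_max = 500, rho = 0, spike_rate = 0,
                            spike_factor = 2, seed = NULL, replicates = 200) {
  stopifnot(I >= 1, T >= 2, sigma_min > 0, sigma_min <= sigma_max,
            rho >= 0, rho < 1, spike_rate >= 0, spike_rate < 1,
            spike_factor >= 1)
  structure(list(I = as.integer(I), T = as.integer(T),
                 sigma_min = sigma_min, sigma_max = sigma_max, rho = rho,
                 spike_rate = spike_rate, spike_factor = spike_factor,
                 seed = seed, replicates = as.integer(replicates)),
            class = "dse_sim_spec")
}

#' Simulate artifact-free independent Gaussian noise
#'
#' \eqn{Y_{it} \sim N(0, \sigma_i^2)} independently over voxels and time,
#' \eqn{\sigma_i \sim U(\sigma_{min}, \sigma_{max})}. This is the null world
#' of the calibration experiments; its closed-form DVARS-squared moments are
#' \eqn{\mu_0 = 2\sum_i \sigma_i^2 / I} and
#' \eqn{\sigma_0^2 = 8\sum_i\sigma_i^4/I^2}.
#'
#' @param spec a `dse_sim_spec` with `rho = 0` and `spike_rate = 0`.
#' @return object of class `dse_sim`: list with `data` (I x T matrix),
#'   `true_sigma`, `spike_times` (empty), `spike_pairs` (empty), `spec`,
#'   and the closed-form truths `mu0_true`, `sigma0_sq_true`.
#' @export
simulate_null <- function(spec) {
  stopifnot(inherits(spec, "dse_sim_spec"))
  if (spec$rho != 0 || spec$spike_rate != 0)
    stop("simulate_null requires rho = 0 and spike_rate = 0")
  simulate_ar1_spikes(spec)
}

#' Simulate AR(1) voxel noise with injected variance spikes
#'
#' Each voxel follows a stationary AR(1) process with lag-1 coefficient rho
#' and marginal SD \eqn{\sigma_i}; at spiked timepoints the innovation SD is
#' multiplied by `spike_factor`. A spiked timepoint t contaminates scan
#' pairs (t-1, t) and (t, t+1); both pair indices are recorded as
#' true-positive opportunities in `spike_pairs`. With `rho = 0` and
#' `spike_rate = 0` this reduces to [simulate_null()].
#'
#' @param spec a `dse_sim_spec`.
#' @param spike_times optional explicit set of spiked timepoints in
#'   1..T-1, overriding random placement; useful for paired
#'   spiked/spike-free comparisons on the same noise realization (the RNG
#'   stream is then identical to a `spike_rate = 0` run with the same seed).
#' @return object of class `dse_sim`, see [simulate_null()].
#' @export
simulate_ar1_spikes <- function(spec, spike_times = NULL) {
  stopifnot(inherits(spec, "dse_sim_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  I <- spec$I; nT <- spec$T
  sigma <- stats::runif(I, spec$sigma_min, spec$sigma_max)
  if (is.null(spike_times)) {
    n_spikes <- round(spec$spike_rate * nT)
    spike_times <- if (n_spikes > 0) sort(sample.int(nT - 1L, n_spikes)) else integer(0)
  } else {
    spike_times <- sort(as.integer(spike_times))
    stopifnot(all(spike_times >= 1L), all(spike_times <= nT - 1L))
  }
  fac <- rep(1, nT)
  fac[spike_times] <- spec$spike_factor

  rho <- spec$rho
  Y <- matrix(stats::rnorm(I * nT), I, nT)
  if (rho == 0) {
    Y <- Y * sigma
    Y <- sweep(Y, 2L, fac, "*")
  } else {
    innov_sd <- sigma * sqrt(1 - rho^2)
    # t = 1 draws the stationary marginal; a spike at t scales innovation t
    Y[, 1L] <- Y[, 1L] * sigma * fac[1L]
    for (t in 2:nT) {
      Y[, t] <- rho * Y[, t - 1L] + Y[, t] * innov_sd * fac[t]
    }
  }
  spike_pairs <- sort(unique(c(spike_times - 1L, spike_times)))
  spike_pairs <- spike_pairs[spike_pairs >= 1L & spike_pairs <= nT - 1L]
  structure(list(data = Y, true_sigma = sigma, spike_times = spike_times,
                 spike_pairs = spike_pairs, spec = spec,
                 mu0_true = 2 * mean(sigma^2),
                 sigma0_sq_true = 8 * sum(sigma^4) / I^2),
            class = "dse_sim")
}

#' @export
print.dse_sim <- function(x, ...) {
  s <- x$spec
  cat(sprintf("Simulated dataset: I = %d, T = %d, sigma ~ U(%g, %g), rho = %g\n",
              s$I, s$T, s$sigma_min, s$sigma_max, s$rho))
  if (length(x$spike_times))
    cat(sprintf("  %d spiked timepoints (innovation SD x %g), %d contaminated pairs\n",
                length(x$spike_times), s$spike_factor, length(x$spike_pairs)))
  invisible(x)
}

# DVARS^2 series of a simulated (already centered-in-expectation) matrix,
# without the scan-pair decomposition overhead.
dvars_sq_of <- function(Y) {
  nT <- ncol(Y)
  d <- Y[, -1L, drop = FALSE] - Y[, -nT, drop = FALSE]
  colMeans(d^2)
}

# The three stock variance scenarios.
stock_scenarios <- function() {
  list(homogeneous = c(200, 200), low = c(200, 250), high = c(200, 500))
}

#' Bias experiment for the null-moment estimators
#'
#' Simulates R artifact-free datasets per (T, scenario) cell and measures
#' the percent bias \eqn{(\hat\theta - \theta)/\theta \times 100} of each
#' requested mu0 and sigma0^2 estimator against the closed-form truths
#' \eqn{\mu_0 = 2\sum\sigma_i^2/I}, \eqn{\sigma_0^2 = 8\sum\sigma_i^4/I^2}
#' (recomputed from the drawn sigma of each replicate). Mean bias over
#' replicates is reported per estimator.
#'
#' @param T_grid timepoint counts to cover.
#' @param scenarios named list of `c(sigma_min, sigma_max)` pairs; default
#'   the three stock scenarios.
#' @param I voxel count.
#' @param R replicates per cell.
#' @param mu0_methods character vector of [estimate_mu0()] methods (the
#'   voxelwise ones cost an IQR per voxel; pass `character(0)` to skip).
#' @param var_methods character vector of [estimate_sigma0_sq()] methods.
#' @param d_grid power-transform exponents crossed with the IQR-type
#'   variance methods.
#' @param seed RNG seed.
#' @return data.frame with one row per (T, scenario, parameter, estimator):
#'   columns `T`, `scenario`, `parameter` ("mu0" or "sigma0_sq"),
#'   `estimator`, `bias_pct` (mean percent bias), `bias_sd` (SD over
#'   replicates), `R`, `I`.
#' @export
run_bias_experiment <- function(T_grid = c(100, 200, 600, 1200),
                                scenarios = stock_scenarios(),
                                I = 10000, R = 200,
                                mu0_methods = c("mean_dvars2", "median_dvars2",
                                                "mean_voxel_sigmaD",
                                                "median_voxel_sigmaD"),
                                var_methods = c("sample", "iqr", "hiqr"),
                                d_grid = c(1, 1 / 2, 1 / 3, 1 / 4),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  var_est <- list()
  for (vm in var_methods) {
    if (vm == "sample") {
      var_est[["sample"]] <- list(method = "sample", d = NA_real_)
    } else {
      for (d in d_grid)
        var_est[[sprintf("%s_d=%s", vm, format(d, digits = 3))]] <-
          list(method = vm, d = d)
    }
  }
  out <- list()
  for (nT in T_grid) {
    for (sc in names(scenarios)) {
      bnds <- scenarios[[sc]]
      mu_bias <- matrix(NA_real_, R, length(mu0_methods),
                        dimnames = list(NULL, mu0_methods))
      var_bias <- matrix(NA_real_, R, length(var_est),
                         dimnames = list(NULL, names(var_est)))
      for (r in seq_len(R)) {
        sim <- simulate_ar1_spikes(simulation_spec(
          I = I, T = nT, sigma_min = bnds[1], sigma_max = bnds[2]))
        dv2 <- dvars_sq_of(sim$data)
        diffdata <- NULL
        if (any(mu0_methods %in% c("mean_voxel_sigmaD", "median_voxel_sigmaD")))
          diffdata <- sim$data[, -1L, drop = FALSE] -
            sim$data[, -ncol(sim$data), drop = FALSE]
        for (m in mu0_methods)
          mu_bias[r, m] <- (estimate_mu0(dv2, diffdata, m) - sim$mu0_true) /
            sim$mu0_true * 100
        for (vn in names(var_est)) {
          ve <- var_est[[vn]]
          est <- estimate_sigma0_sq(dv2, ve$method,
                                    d = if (is.na(ve$d)) 1 / 3 else ve$d)
          var_bias[r, vn] <- (est - sim$sigma0_sq_true) / sim$sigma0_sq_true * 100
        }
      }
      row <- function(param, est, b) data.frame(
        T = nT, scenario = sc, parameter = param, estimator = est,
        bias_pct = mean(b), bias_sd = stats::sd(b), R = R, I = I,
        stringsAsFactors = FALSE)
      for (m in mu0_methods)
        out[[length(out) + 1L]] <- row("mu0", m, mu_bias[, m])
      for (vn in names(var_est))
        out[[length(out) + 1L]] <- row("sigma0_sq", vn, var_bias[, vn])
    }
  }
  do.call(rbind, out)
}

#' Calibration (validity) experiment for the DVARS test
#'
#' Runs R artifact-free replicates, estimates the null model per replicate
#' with each requested estimator setting, and assesses the one-sided
#' p-values: pooled empirical rejection rates at a grid of uncorrected
#' levels, per-replicate rates, a one-sided KS statistic against U(0, 1),
#' and a classification into `"valid"` (uniform or conservative) versus
#' `"anti-conservative"`. Because p-values within a replicate share the
#' estimated null moments, the classification uses replicate-level rates:
#' anti-conservative means the mean rejection rate exceeds alpha by more
#' than 3 standard errors of the replicate mean at any tested alpha.
#'
#' @param spec a null `dse_sim_spec` (rho and spike_rate 0).
#' @param settings list of lists with elements `mu0_method`, `var_method`,
#'   `d` naming the estimator combination(s) to assess.
#' @param R replicates.
#' @param alphas uncorrected test levels examined.
#' @param seed RNG seed.
#' @return list keyed by setting label; each element has `rates`
#'   (data.frame alpha / rate / se), `ks_stat` (one-sided D+ of pooled
#'   p-values), `classification`, and `p_pooled` (sorted pooled p-values,
#'   capped at 200000 for memory).
#' @export
run_validity_experiment <- function(spec, settings = list(
                                      list(mu0_method = "median_dvars2",
                                           var_method = "hiqr", d = 1 / 3)),
                                    R = 200, alphas = c(0.01, 0.05),
                                    seed = NULL) {
  stopifnot(inherits(spec, "dse_sim_spec"), spec$rho == 0,
            spec$spike_rate == 0)
  if (!is.null(seed)) set.seed(seed)
  labels <- vapply(settings, function(s)
    sprintf("%s+%s(d=%.3g)", s$mu0_method, s$var_method, s$d), "")
  rej <- lapply(settings, function(s)
    matrix(NA_real_, R, length(alphas), dimnames = list(NULL, alphas)))
  pvals <- lapply(settings, function(s) vector("list", R))
  needs_diff <- any(vapply(settings, function(s)
    s$mu0_method %in% c("mean_voxel_sigmaD", "median_voxel_sigmaD"), TRUE))
  for (r in seq_len(R)) {
    sim <- simulate_ar1_spikes(spec)
    dv2 <- dvars_sq_of(sim$data)
    diffdata <- if (needs_diff)
      sim$data[, -1L, drop = FALSE] - sim$data[, -ncol(sim$data), drop = FALSE]
    for (k in seq_along(settings)) {
      s <- settings[[k]]
      null <- estimate_null_model(dv2, diffdata, s$mu0_method, s$var_method,
                                  s$d)
      p <- dvars_test(dv2, null)$p_value
      rej[[k]][r, ] <- vapply(alphas, function(a) mean(p <= a), 0)
      pvals[[k]][[r]] <- p
    }
  }
  out <- list()
  for (k in seq_along(settings)) {
    rates <- data.frame(alpha = alphas,
                        rate = colMeans(rej[[k]]),
                        se = apply(rej[[k]], 2L, stats::sd) / sqrt(R))
    p_pool <- sort(unlist(pvals[[k]]))
    if (length(p_pool) > 200000L)
      p_pool <- p_pool[round(seq(1, length(p_pool), length.out = 200000L))]
    # one-sided KS distance D+ = sup(ECDF - x): excess small p-values
    ks_plus <- max(seq_along(p_pool) / length(p_pool) - p_pool)
    anti <- any(rates$rate > rates$alpha + 3 * rates$se)
    conservative <- all(rates$rate < rates$alpha - 3 * rates$se)
    out[[labels[k]]] <- list(
      rates = rates, ks_stat = ks_plus,
      classification = if (anti) "anti-conservative"
                       else if (conservative) "conservative" else "valid",
      p_pooled = p_pool)
  }
  out
}

#' Power experiment: sensitivity and specificity of spike detection
#'
#' For each (rho, spike_rate) cell, simulates R spiked AR(1) datasets, runs
#' the DVARS test (one-sided, Bonferroni over the T-1 pairs) and scores
#' flagged pairs against the recorded ground truth. Sensitivity is the
#' fraction of truly contaminated pairs flagged; specificity the fraction
#' of clean pairs not flagged (expected about 1 - alpha/(T-1) under the
#' null). Power rises with rho and falls as spikes become so prevalent that
#' they contaminate the robust null estimates themselves.
#'
#' @param I,T,sigma_min,sigma_max,spike_factor generator settings shared
#'   across cells.
#' @param rho_grid,spike_rate_grid the experimental grid.
#' @param R replicates per cell.
#' @param alpha familywise level for the Bonferroni flagging.
#' @param mu0_method,var_method,d null-moment estimators.
#' @param seed RNG seed.
#' @return data.frame with one row per cell: `rho`, `spike_rate`,
#'   `sensitivity`, `specificity` (both in percent), `sens_sd` (SD of
#'   per-replicate sensitivity), `R`.
#' @export
run_power_experiment <- function(I = 10000, T = 600, sigma_min = 200,
                                 sigma_max = 500, spike_factor = 2,
                                 rho_grid = c(0, 0.2, 0.4, 0.6),
                                 spike_rate_grid = c(0.01, 0.05, 0.1, 0.2),
                                 R = 100, alpha = 0.05,
                                 mu0_method = "median_dvars2",
                                 var_method = "hiqr", d = 1 / 3,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (rho in rho_grid) {
    for (rate in spike_rate_grid) {
      sens <- spec_rate <- numeric(R)
      for (r in seq_len(R)) {
        sim <- simulate_ar1_spikes(simulation_spec(
          I = I, T = T, sigma_min = sigma_min, sigma_max = sigma_max,
          rho = rho, spike_rate = rate, spike_factor = spike_factor))
        dv2 <- dvars_sq_of(sim$data)
        null <- estimate_null_model(dv2, NULL, mu0_method, var_method, d)
        p <- dvars_test(dv2, null)$p_value
        flagged <- which(p <= alpha / length(p))
        truth <- sim$spike_pairs
        clean <- setdiff(seq_along(p), truth)
        sens[r] <- if (length(truth)) mean(truth %in% flagged) else NA_real_
        spec_rate[r] <- if (length(clean)) mean(!(clean %in% flagged)) else NA_real_
      }
      out[[length(out) + 1L]] <- data.frame(
        rho = rho, spike_rate = rate,
        sensitivity = 100 * mean(sens, na.rm = TRUE),
        specificity = 100 * mean(spec_rate, na.rm = TRUE),
        sens_sd = 100 * stats::sd(sens), R = R)
    }
  }
  do.call(rbind, out)
}
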