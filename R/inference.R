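#' Interquartile range of a standard normal
#'
#' \eqn{\mathrm{IQR}_0 = \Phi^{-1}(0.75) - \Phi^{-1}(0.25) \approx 1.349},
#' the constant converting sample IQRs of approximately Gaussian series into
#' standard deviations. The half-IQR analogue (median minus first quartile)
#' uses \eqn{\mathrm{hIQR}_0 = \mathrm{IQR}_0/2}.
#'
#' @format length-1 numeric.
#' @export
IQR0 <- stats::qnorm(0.75) - stats::qnorm(0.25)

# Sample quantiles used throughout: linear-interpolation (R type 7). The
# IQR-based moment estimates depend on the quantile rule, so it is fixed here.
.quart <- function(x, p) stats::quantile(x, p, names = FALSE, type = 7)

#' Estimate the null mean of DVARS-squared
#'
#' Under temporal homogeneity the expected DVARS-squared equals the average
#' differenced-data variance \eqn{\mu_0 = \frac1I \sum_i \sigma^2_{Di}}.
#' Estimators:
#' \describe{
#'   \item{`median_dvars2` (default)}{median of the observed
#'     \eqn{\{\mathrm{DVARS}_t^2\}}; robust to spikes, and the only variant
#'     robust to spatial variance heterogeneity.}
#'   \item{`mean_dvars2`}{sample mean of the series; non-robust, kept for
#'     comparison.}
#'   \item{`median_voxel_sigmaD` / `mean_voxel_sigmaD`}{median or mean over
#'     voxels of \eqn{\hat\sigma^2_{Di} = (\mathrm{IQR}(\Delta
#'     Y_i)/\mathrm{IQR}_0)^2}, the robust per-voxel differenced-data
#'     variances; requires `diffdata`.}
#' }
#'
#' @param dvars_sq numeric vector of DVARS-squared values, length T-1 >= 2.
#' @param diffdata I x (T-1) matrix of differenced voxel series
#'   \eqn{Y_{i,t+1} - Y_{it}} (only for the voxelwise methods).
#' @param method estimator, see above.
#' @return scalar \eqn{\hat\mu_0}.
#' @export
estimate_mu0 <- function(dvars_sq,
                         diffdata = NULL,
                         method = c("median_dvars2", "mean_dvars2",
                                    "median_voxel_sigmaD", "mean_voxel_sigmaD")) {
  method <- match.arg(method)
  if (length(dvars_sq) < 2L) stop("need at least 2 scan pairs")
  mu0 <- switch(method,
    median_dvars2 = stats::median(dvars_sq),
    mean_dvars2 = mean(dvars_sq),
    median_voxel_sigmaD = ,
    mean_voxel_sigmaD = {
      if (is.null(diffdata)) stop("voxelwise methods require diffdata")
      iqr <- apply(diffdata, 1L, function(v) .quart(v, 0.75) - .quart(v, 0.25))
      sig2 <- (iqr / IQR0)^2
      if (method == "median_voxel_sigmaD") stats::median(sig2) else mean(sig2)
    })
  if (!is.finite(mu0) || mu0 <= 0) stop("degenerate null: mu0 estimate not positive")
  mu0
}

#' Estimate the null variance of DVARS-squared
#'
#' Robust spread of the DVARS-squared series after an optional power
#' transform. With \eqn{X_t = (\mathrm{DVARS}_t^2)^d}, the spread of X is
#' estimated by IQR(X)/IQR0 or hIQR(X)/hIQR0 (hIQR = median minus first
#' quartile, insensitive to anything above the median, hence to upward
#' spikes), then mapped back by the delta method
#' \eqn{\hat\sigma_0 = \mathrm{spread}(X) / (d\, \hat\mu_0^{d-1})}.
#' The cube-root transform (d = 1/3, the Wilson-Hilferty normalization of a
#' chi-squared variate) is the default; `var_method = "sample"` is the
#' non-robust sample variance, kept for comparison.
#'
#' @inheritParams estimate_mu0
#' @param var_method `"hiqr"` (default), `"iqr"`, or `"sample"`.
#' @param d power-transform exponent, one of 1, 1/2, 1/3, 1/4.
#' @param mu0 center used by the delta-method back-transform; defaults to
#'   the median of `dvars_sq` (the default mean estimator).
#' @return scalar \eqn{\hat\sigma^2_0}.
#' @export
estimate_sigma0_sq <- function(dvars_sq, var_method = c("hiqr", "iqr", "sample"),
                               d = 1 / 3, mu0 = NULL) {
  var_method <- match.arg(var_method)
  if (length(dvars_sq) < 4L) stop("need at least 4 scan pairs")
  if (var_method == "sample") return(stats::var(dvars_sq))
  allowed <- c(1, 1 / 2, 1 / 3, 1 / 4)
  hit <- which(abs(d - allowed) < 1e-6)  # tolerate config round-tripping
  if (!length(hit)) stop("d must be one of 1, 1/2, 1/3, 1/4")
  d <- allowed[hit[1L]]
  if (is.null(mu0)) mu0 <- stats::median(dvars_sq)
  x <- dvars_sq^d
  spread <- if (var_method == "iqr") {
    (.quart(x, 0.75) - .quart(x, 0.25)) / IQR0
  } else {
    (.quart(x, 0.5) - .quart(x, 0.25)) / (IQR0 / 2)
  }
  if (!is.finite(spread) || spread <= 0) stop("degenerate null: zero spread")
  sigma0 <- spread / (d * mu0^(d - 1))
  sigma0^2
}

#' Estimate the DVARS-squared null model
#'
#' Bundles the null-moment estimates into the model driving the chi-squared
#' test: mean \eqn{\mu_0}, variance \eqn{\sigma_0^2}, and degrees of freedom
#' \eqn{\nu = 2\mu_0^2/\sigma_0^2}. Under complete spatial independence nu
#' equals the number of voxels, so nu can be read as an effective number of
#' spatial elements — with the caveat that it is very sensitive to the
#' moment estimators used and is unlikely to be meaningful in other contexts
#' (e.g. as a spatial Bonferroni correction).
#'
#' @inheritParams estimate_mu0
#' @inheritParams estimate_sigma0_sq
#' @param mu0_method mean estimator, see [estimate_mu0()].
#' @return object of class `dse_null`: list with `mu0`, `sigma0_sq`, `nu`,
#'   `mu0_method`, `var_method`, `d`.
#' @export
estimate_null_model <- function(dvars_sq, diffdata = NULL,
                                mu0_method = "median_dvars2",
                                var_method = "hiqr", d = 1 / 3) {
  mu0 <- estimate_mu0(dvars_sq, diffdata, mu0_method)
  sigma0_sq <- estimate_sigma0_sq(dvars_sq, var_method, d, mu0 = mu0)
  null_model(mu0, sigma0_sq, mu0_method = mu0_method, var_method = var_method,
             d = d)
}

#' Construct a DVARS-squared null model from known moments
#'
#' @param mu0 null mean of DVARS-squared (> 0).
#' @param sigma0_sq null variance (> 0).
#' @param mu0_method,var_method,d provenance labels (see
#'   [estimate_null_model()]); `"known"` for externally supplied moments.
#' @return object of class `dse_null`.
#' @export
null_model <- function(mu0, sigma0_sq, mu0_method = "known",
                       var_method = "known", d = NA_real_) {
  stopifnot(is.finite(mu0), mu0 > 0, is.finite(sigma0_sq), sigma0_sq > 0)
  structure(list(mu0 = mu0, sigma0_sq = sigma0_sq,
                 nu = 2 * mu0^2 / sigma0_sq,
                 mu0_method = mu0_method, var_method = var_method, d = d),
            class = "dse_null")
}

#' @export
print.dse_null <- function(x, ...) {
  cat(sprintf("DVARS^2 null model: mu0 = %.4g, sigma0^2 = %.4g, nu = %.4g\n",
              x$mu0, x$sigma0_sq, x$nu))
  cat(sprintf("  estimators: mean = %s, variance = %s (d = %s)\n",
              x$mu0_method, x$var_method, format(x$d)))
  invisible(x)
}

#' Chi-squared test for DVARS spikes
#'
#' Tests the null of temporal homogeneity
#' \eqn{H_0: E(\mathrm{DVARS}_t^2) = \mu_0} with the moment-matched statistic
#' \eqn{X_t = (2\mu_0/\sigma_0^2)\,\mathrm{DVARS}_t^2 \sim \chi^2_\nu},
#' \eqn{\nu = 2\mu_0^2/\sigma_0^2}. One-sided (upper tail) by default — the
#' artifact alternative is excess fast variability; the two-sided variant
#' (doubling the smaller tail) also catches down-spikes, e.g. left behind by
#' aggressive denoising.
#'
#' @param dvars_sq numeric vector of DVARS-squared values.
#' @param null a `dse_null` object.
#' @param sided `"one"` (upper tail, default) or `"two"`.
#' @return list with `x_stat`, `p_value`, `nu`.
#' @export
dvars_test <- function(dvars_sq, null, sided = c("one", "two")) {
  sided <- match.arg(sided)
  stopifnot(inherits(null, "dse_null"))
  x <- (2 * null$mu0 / null$sigma0_sq) * dvars_sq
  up <- stats::pchisq(x, df = null$nu, lower.tail = FALSE)
  p <- if (sided == "one") up else pmin(1, 2 * pmin(up, 1 - up))
  list(x_stat = x, p_value = p, nu = null$nu)
}

#' Z-score equivalents of DVARS p-values
#'
#' \eqn{Z_t = \Phi^{-1}(1 - p_t)}. For extreme spikes the chi-squared upper
#' tail underflows to p = 0; there the approximate Z is computed directly as
#' \eqn{(\mathrm{DVARS}_t^2 - \mu_0)/\sigma_0}, the normal-approximation
#' limit of the chi-squared score.
#'
#' @param p_values p-values from [dvars_test()].
#' @param dvars_sq the DVARS-squared series (for the underflow fallback).
#' @param null a `dse_null` object.
#' @return numeric vector of Z-scores.
#' @export
z_scores <- function(p_values, dvars_sq, null) {
  stopifnot(inherits(null, "dse_null"))
  z <- stats::qnorm(p_values, lower.tail = FALSE)
  bad <- !is.finite(z)
  if (any(bad))
    z[bad] <- (dvars_sq[bad] - null$mu0) / sqrt(null$sigma0_sq)
  z
}

#' Standardized DVARS variants
#'
#' The six per-pair measures that make raw DVARS interpretable within and
#' across cohorts:
#' \describe{
#'   \item{`dvars`}{\eqn{2\sqrt{D_t}}, the original spatial RMS of the
#'     differenced image.}
#'   \item{`sqrt_dvar`}{\eqn{\mathrm{DVARS}_t/2 = \sqrt{D_t}}, the fast
#'     noise component in RMS units.}
#'   \item{`pct_dvar`}{\eqn{100\,D_t/A}, fast variability as a percentage of
#'     average total variability (IID data sits near 50%).}
#'   \item{`delta_pct_dvar`}{\eqn{100\,(\mathrm{DVARS}_t^2 - \mu_0)/(4A)},
#'     the excess fast variability over the null baseline as a percentage of
#'     A — the practical-significance measure (conventional cut-off 5%).}
#'   \item{`rel_dvars`}{\eqn{\mathrm{DVARS}_t/\sqrt{\mu_0}}, near 1 for good
#'     scans.}
#'   \item{`z_score`}{see [z_scores()].}
#' }
#'
#' @param dse a `dse_series` object.
#' @param null a `dse_null` object.
#' @param sided test sidedness, see [dvars_test()].
#' @return data.frame with one row per scan pair (columns `t`, `dvars`,
#'   `sqrt_dvar`, `dvar`, `pct_dvar`, `delta_pct_dvar`, `rel_dvars`,
#'   `x_stat`, `p_value`, `z_score`).
#' @export
standardized_variants <- function(dse, null, sided = "one") {
  stopifnot(inherits(dse, "dse_series"), inherits(null, "dse_null"))
  D <- dse$whole$D
  A <- dse$averages$whole$A
  if (!is.finite(A) || A <= 0) stop("average total variability A must be positive")
  dvars_sq <- 4 * D
  test <- dvars_test(dvars_sq, null, sided = sided)
  pct <- 100 * D / A
  data.frame(
    t = seq_along(D),
    dvars = 2 * sqrt(D),
    sqrt_dvar = sqrt(D),
    dvar = D,
    pct_dvar = pct,
    delta_pct_dvar = pct - 100 * null$mu0 / (4 * A),
    rel_dvars = 2 * sqrt(D) / sqrt(null$mu0),
    x_stat = test$x_stat,
    p_value = test$p_value,
    z_score = z_scores(test$p_value, dvars_sq, null))
}

#' Flag scan pairs by statistical and practical significance
#'
#' A pair (t, t+1) is statistically significant when its one-sided p-value
#' passes the familywise threshold (Bonferroni over the T-1 pairs:
#' p <= alpha/(T-1)), and practically significant when, in addition, its
#' excess fast variability exceeds `delta_threshold` percent of average
#' variability. Practical flags are always a subset of statistical flags;
#' the conjunction is the recommended scrubbing candidate set. Which scan of
#' a flagged pair to delete is the caller's policy; both indices are listed.
#'
#' @param result data.frame from [standardized_variants()] (or a
#'   `dse_inference` object, whose flags are recomputed).
#' @param alpha familywise error level.
#' @param correction only `"bonferroni"` in this version.
#' @param delta_threshold practical-significance cut-off on
#'   `delta_pct_dvar`, in percent.
#' @return the input data.frame with logical columns `flag_statistical`,
#'   `flag_practical`, plus attribute `flagged_pairs` (data.frame of
#'   `t`, `t_plus_1` for statistically flagged pairs with their flags).
#' @export
flag_scans <- function(result, alpha = 0.05, correction = "bonferroni",
                       delta_threshold = 5) {
  correction <- match.arg(correction, "bonferroni")
  n_pairs <- nrow(result)
  thr <- alpha / n_pairs
  result$flag_statistical <- result$p_value <= thr
  result$flag_practical <- result$flag_statistical &
    result$delta_pct_dvar > delta_threshold
  flagged <- result[result$flag_statistical, , drop = FALSE]
  attr(result, "flagged_pairs") <- data.frame(
    t = flagged$t, t_plus_1 = flagged$t + 1L,
    practical = flagged$flag_practical)
  attr(result, "alpha") <- alpha
  attr(result, "delta_threshold") <- delta_threshold
  result
}

#' Full DVARS inference for one dataset
#'
#' Convenience wrapper: estimates the null model from the decomposition,
#' computes all standardized variants, the chi-squared test, Z-scores, and
#' statistical/practical flags.
#'
#' @inheritParams standardized_variants
#' @inheritParams flag_scans
#' @param data optional `dse_scaled` object or matrix; required when
#'   `mu0_method` is voxelwise (needs the differenced data).
#' @param mu0_method,var_method,d null-moment estimators, see
#'   [estimate_null_model()].
#' @return object of class `dse_inference`: the flagged data.frame of
#'   [flag_scans()] with attribute `null` (the `dse_null` model) and the
#'   flag parameters.
#' @export
dvars_inference <- function(dse, data = NULL, mu0_method = "median_dvars2",
                            var_method = "hiqr", d = 1 / 3, alpha = 0.05,
                            delta_threshold = 5, sided = "one") {
  stopifnot(inherits(dse, "dse_series"))
  dvars_sq <- 4 * dse$whole$D
  diffdata <- NULL
  if (mu0_method %in% c("median_voxel_sigmaD", "mean_voxel_sigmaD")) {
    Y <- as_dse_matrix(data)
    diffdata <- Y[, -1L, drop = FALSE] - Y[, -ncol(Y), drop = FALSE]
  }
  null <- estimate_null_model(dvars_sq, diffdata, mu0_method, var_method, d)
  res <- standardized_variants(dse, null, sided = sided)
  res <- flag_scans(res, alpha = alpha, delta_threshold = delta_threshold)
  attr(res, "null") <- null
  class(res) <- c("dse_inference", class(res))
  res
}

#' @export
print.dse_inference <- function(x, ...) {
  null <- attr(x, "null")
  fl <- attr(x, "flagged_pairs")
  cat(sprintf("DVARS inference over %d scan pairs\n", nrow(x)))
  print(null)
  cat(sprintf("  flagged: %d statistical (alpha = %g, Bonferroni), %d also practical (delta %%D-var > %g%%)\n",
              nrow(fl), attr(x, "alpha"), sum(fl$practical),
              attr(x, "delta_threshold")))
  if (nrow(fl)) {
    lab <- sprintf("%d & %d%s", fl$t, fl$t_plus_1,
                   ifelse(fl$practical, "*", ""))
    cat("  pairs:", paste(lab, collapse = ", "), "\n")
  }
  invisible(x)
}
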