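# IID expectations of the A-var-normalized components; the denominators of
# the "relative to IID" column. Global rows are normalized to A, not AG.
iid_fractions <- function(I, T) {
  d <- 0.5 * (T - 1) / T
  c(A = 1, D = d, S = d, E = 1 / T,
    AG = 1 / I, DG = d / I, SG = d / I, EG = 1 / (I * T),
    AN = 1 - 1 / I, DN = d * (1 - 1 / I), SN = d * (1 - 1 / I),
    EN = (1 / T) * (1 - 1 / I))
}

component_labels <- c(
  A = "A - All", D = "D - Fast", S = "S - Slow", E = "E - Edge",
  AG = "AG - All Global", DG = "DG - Fast Global", SG = "SG - Slow Global",
  EG = "EG - Edge Global", AN = "AN - All Non-Global",
  DN = "DN - Fast Non-Global", SN = "SN - Slow Non-Global",
  EN = "EN - Edge Non-Global")

build_dse_table <- function(ms, I, T, include_nonglobal = FALSE) {
  keys <- c("A", "D", "S", "E", "AG", "DG", "SG", "EG")
  if (include_nonglobal) keys <- c(keys, c("AN", "DN", "SN", "EN"))
  ms <- ms[keys]
  A <- ms[["A"]]
  if (!is.finite(A) || A <= 0) stop("total variability A must be positive")
  frac <- iid_fractions(I, T)[keys]
  out <- data.frame(
    source = unname(component_labels[keys]),
    component = keys,
    ms = unname(ms),
    rms = sqrt(unname(ms)),
    pct_avar = 100 * unname(ms) / A,
    rel_iid = (unname(ms) / A) / unname(frac),
    stringsAsFactors = FALSE)
  rownames(out) <- keys
  structure(out, I = I, T = T, class = c("dse_table", "data.frame"))
}

#' DSE summary table
#'
#' Summarizes a DSE decomposition as the field's standard "DSE table": one
#' row per component (A, D, S, E and their global counterparts), reporting
#' \itemize{
#'   \item `rms` — square root of the scan-average mean square, in data units
#'     (comparable to a noise standard deviation);
#'   \item `pct_avar` — the mean square as a percentage of total A-var;
#'   \item `rel_iid` — the A-var-normalized value divided by its expectation
#'     under IID noise (1.0 indicates nominal behavior; `rel_iid(D)` well
#'     below 1 with `rel_iid(S)` above 1 indicates temporal autocorrelation,
#'     large `rel_iid(AG)` indicates strong spatial structure).
#' }
#' IID expectations: D, S \eqn{\to \frac12 (T-1)/T}; E \eqn{\to 1/T};
#' AG \eqn{\to 1/I}; DG, SG \eqn{\to \frac12 (T-1)/(TI)}; EG
#' \eqn{\to 1/(IT)}. Global rows are normalized to whole-brain A (not AG).
#'
#' @param dse a `dse_series` object.
#' @param I,T dimensions; defaults taken from `dse`. Supplying inconsistent
#'   values is an error.
#' @param include_nonglobal also emit the four non-global rows (hidden by
#'   default; they are the whole-minus-global complement).
#' @return A `dse_table` data.frame with columns `source`, `component`, `ms`,
#'   `rms`, `pct_avar`, `rel_iid`; attributes `I` and `T`.
#' @export
dse_table <- function(dse, I = dse$I, T = dse$T, include_nonglobal = FALSE) {
  stopifnot(inherits(dse, "dse_series"))
  if (I != dse$I || T != dse$T)
    stop(sprintf("I/T (%d/%d) inconsistent with the decomposition (%d/%d)",
                 I, T, dse$I, dse$T))
  ms <- c(unlist(dse$averages$whole),
          unlist(dse$averages$global),
          unlist(dse$averages$nonglobal))
  names(ms) <- c("A", "D", "S", "E", "AG", "DG", "SG", "EG",
                 "AN", "DN", "SN", "EN")
  build_dse_table(ms, I, T, include_nonglobal)
}

#' Expected DSE table under a reference noise model
#'
#' Closed-form expected mean squares of every DSE component under either the
#' time-space-separable model (arbitrary spatial covariance, common lag-1
#' temporal autocorrelation rho) or the IID model. Writing \eqn{\bar\sigma^2}
#' for the average voxel variance and \eqn{\bar{\bar\sigma}^2} for the
#' average element of the spatial covariance matrix:
#' whole-brain A \eqn{= \bar\sigma^2},
#' D \eqn{= \bar\sigma^2 \frac12 \frac{T-1}{T}(1-\rho)},
#' S \eqn{= \bar\sigma^2 \frac12 \frac{T-1}{T}(1+\rho)},
#' E \eqn{= \bar\sigma^2/T}; global rows replace \eqn{\bar\sigma^2} with
#' \eqn{\bar{\bar\sigma}^2}. The IID model is the separable model with
#' \eqn{\rho = 0} and \eqn{\bar{\bar\sigma}^2 = \bar\sigma^2/I}. Under
#' independence D and S are equal; when normalized to A they differ by about
#' rho: \eqn{S - D = \rho(T-1)/T}.
#'
#' @param kind `"separable"` or `"iid"`.
#' @param sigma_bar_sq average voxel variance \eqn{\bar\sigma^2 > 0}.
#' @param rho common lag-1 autocorrelation, |rho| < 1 (separable model).
#' @param sigma_dbar_sq average spatial covariance \eqn{\bar{\bar\sigma}^2}
#'   (must be <= `sigma_bar_sq`); defaults to `sigma_bar_sq / I` (no spatial
#'   structure beyond self-covariance), which the IID model forces.
#' @param I,T dimensions of the nominal dataset.
#' @inheritParams dse_table
#' @return A `dse_table` data.frame of expected values (see [dse_table()]).
#' @examples
#' expected_dse_table("iid", sigma_bar_sq = 4, I = 100, T = 100)["D", "pct_avar"]
#' # = 100 * 0.5 * 99/100 = 49.5
#' @export
expected_dse_table <- function(kind = c("separable", "iid"), sigma_bar_sq = 1,
                               rho = 0, sigma_dbar_sq = NULL, I, T,
                               include_nonglobal = FALSE) {
  kind <- match.arg(kind)
  if (kind == "iid") {
    rho <- 0
    sigma_dbar_sq <- sigma_bar_sq / I
  }
  if (is.null(sigma_dbar_sq)) sigma_dbar_sq <- sigma_bar_sq / I
  stopifnot(sigma_bar_sq > 0, abs(rho) < 1, sigma_dbar_sq <= sigma_bar_sq)
  half <- 0.5 * (T - 1) / T
  comp <- function(s2) c(A = s2, D = s2 * half * (1 - rho),
                         S = s2 * half * (1 + rho), E = s2 / T)
  w <- comp(sigma_bar_sq)
  g <- comp(sigma_dbar_sq)
  ms <- c(w, g, w - g)
  names(ms) <- c("A", "D", "S", "E", "AG", "DG", "SG", "EG",
                 "AN", "DN", "SN", "EN")
  build_dse_table(ms, I, T, include_nonglobal)
}

#' Lag-1 temporal autocorrelation heuristic from the S-D gap
#'
#' Under any stationary model the A-var-normalized gap between the slow and
#' fast components estimates the (variance-weighted) average lag-1 temporal
#' autocorrelation: \eqn{S - D = \rho (T-1)/T} when both are normalized to A.
#' Returns the scan-level estimate and the per-pair series, rescaled by
#' T/(T-1) so the estimand is rho itself. Values are not clamped; genuine
#' data yields estimates in [-1, 1] up to sampling noise. Convergence of D
#' and S (rho close to 0) is the signature of successfully cleaned data.
#'
#' @param dse a `dse_series` object with T >= 2.
#' @return list with `rho_hat` (scalar), `rho_t` (length T-1 series, on the
#'   D/S abscissa t + 1/2).
#' @export
lag1_estimate <- function(dse) {
  stopifnot(inherits(dse, "dse_series"))
  if (dse$T < 2L) stop("lag-1 autocorrelation undefined for T < 2")
  a <- dse$averages$whole
  f <- dse$T / (dse$T - 1)
  list(rho_hat = (a$S - a$D) / a$A * f,
       rho_t = (dse$whole$S - dse$whole$D) / a$A * f)
}

#' @export
print.dse_table <- function(x, digits = 3, ...) {
  cat(sprintf("DSE table (I = %d, T = %d)\n", attr(x, "I"), attr(x, "T")))
  cat(sprintf("%-22s %10s %12s %15s\n", "Source", "RMS", "% of A-var",
              "Relative to IID"))
  for (k in seq_len(nrow(x))) {
    cat(sprintf("%-22s %10.3f %12.3f %15.3f\n", x$source[k], x$rms[k],
                x$pct_avar[k], x$rel_iid[k]))
  }
  invisible(x)
}

#' Write a DSE table to disk
#'
#' @param x a `dse_table`.
#' @param path output file.
#' @param format `"tsv"` (tab-separated, columns as in the data.frame),
#'   `"json"` (records plus an object of dimensions), or `"txt"` (the pretty
#'   rendering of the print method).
#' @return `path`, invisibly.
#' @export
write_dse_table <- function(x, path, format = c("tsv", "json", "txt")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (format == "json") {
    jsonlite::write_json(list(I = attr(x, "I"), T = attr(x, "T"),
                              rows = as.data.frame(x)),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    txt <- utils::capture.output(print(x))
    writeLines(txt, path)
  }
  invisible(path)
}
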