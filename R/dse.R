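#' Compute the DSE (D-var / S-var / E-var) time series
#'
#' Decomposes the sum of squares of a centered voxels-by-time matrix into
#' fast (D), slow (S) and edge (E) variability, at whole-brain, global-signal
#' and non-global scopes. With \eqn{\bar Y_t} the spatial mean at time t:
#' \itemize{
#'   \item \eqn{A_t = \frac1I\sum_i Y_{it}^2} — total variability at scan t;
#'   \item \eqn{D_t = \frac1I\sum_i (Y_{i,t+1}-Y_{it})^2/4} — half-difference
#'     of adjacent scans, squared and averaged over space ("fast");
#'   \item \eqn{S_t = \frac1I\sum_i (Y_{it}+Y_{i,t+1})^2/4} — average of
#'     adjacent scans, squared and averaged over space ("slow");
#'   \item \eqn{E_t = A_t/2} at t = 1 and t = T, zero elsewhere ("edge").
#' }
#' These satisfy \eqn{D_t + S_t = (A_t + A_{t+1})/2} pairwise and, for the
#' scan averages (each series' sum divided by T), \eqn{A = D + S + E}.
#' The same identities hold within the global scope (series of
#' \eqn{\bar Y_t}) and the non-global scope (spatially demeaned data), and
#' whole = global + non-global component-wise. DVARS is recovered as
#' \eqn{\mathrm{DVARS}_t = 2\sqrt{D_t}}.
#'
#' @param data a `dse_scaled` object from [scale_center()], or a numeric
#'   voxels-by-time matrix already centered by the caller.
#' @return An object of class `dse_series`: a list with elements `whole`,
#'   `global`, `nonglobal` (each a list of vectors `A` (length T), `D`, `S`
#'   (length T-1), `E` (length T, nonzero only at 1 and T)), `averages`
#'   (scan-level averages per scope and component), `global_mean` (the
#'   length-T spatial mean series), `abscissa` (plotting x positions: A, E at
#'   t; D, S at t + 1/2), and dimensions `I`, `T`.
#' @examples
#' dse <- compute_dse_timeseries(matrix(c(1, 3), nrow = 1))
#' dse$averages$whole  # A = 5, D = 0.5, S = 2, E = 2.5
#' @export
compute_dse_timeseries <- function(data) {
  Y <- as_dse_matrix(data)
  nT <- ncol(Y)
  if (nT < 2L) stop("T < 2: the DSE decomposition needs at least two timepoints")
  I <- nrow(Y)

  gm <- colMeans(Y)
  scope_series <- function(M, mean_square) {
    A <- mean_square(M)
    half_d <- (M[, -1L, drop = FALSE] - M[, -nT, drop = FALSE]) / 2
    half_s <- (M[, -1L, drop = FALSE] + M[, -nT, drop = FALSE]) / 2
    D <- mean_square(half_d)
    S <- mean_square(half_s)
    E <- numeric(nT)
    E[c(1L, nT)] <- A[c(1L, nT)] / 2
    list(A = A, D = D, S = S, E = E)
  }
  col_ms <- function(M) colMeans(M^2)
  whole <- scope_series(Y, col_ms)
  global <- scope_series(matrix(gm, nrow = 1L), function(M) as.numeric(M^2))
  Yn <- Y - rep(gm, each = I)  # spatially demeaned
  nonglobal <- scope_series(Yn, col_ms)

  avg <- function(s) lapply(s, function(v) sum(v) / nT)
  structure(list(
    whole = whole, global = global, nonglobal = nonglobal,
    averages = list(whole = avg(whole), global = avg(global),
                    nonglobal = avg(nonglobal)),
    global_mean = gm,
    abscissa = list(A = seq_len(nT), D = seq_len(nT - 1L) + 0.5,
                    S = seq_len(nT - 1L) + 0.5, E = seq_len(nT)),
    I = I, T = nT
  ), class = "dse_series")
}

#' @export
print.dse_series <- function(x, digits = 4, ...) {
  cat(sprintf("DSE time series: I = %d voxels, T = %d timepoints\n", x$I, x$T))
  a <- x$averages$whole
  cat(sprintf("  scan averages: A = %.*g, D = %.*g, S = %.*g, E = %.*g\n",
              digits, a$A, digits, a$D, digits, a$S, digits, a$E))
  cat(sprintf("  A - (D+S+E) = %.2e\n", a$A - (a$D + a$S + a$E)))
  invisible(x)
}

#' Tidy (long) representation of the DSE time series
#'
#' One row per (component, scope, index) with the plotting abscissa; the
#' layout used by the TSV writer. The edge series is emitted at every t for
#' a rectangular layout; it is zero away from t = 1 and t = T.
#'
#' @param x a `dse_series` object.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with columns `index`, `abscissa`, `component`, `scope`,
#'   `value`.
#' @export
as.data.frame.dse_series <- function(x, row.names = NULL, optional = FALSE, ...) {
  out <- list()
  for (scope in c("whole", "global", "nonglobal")) {
    s <- x[[scope]]
    for (comp in c("A", "D", "S", "E")) {
      idx <- seq_along(s[[comp]])
      out[[length(out) + 1L]] <- data.frame(
        index = idx, abscissa = x$abscissa[[comp]][idx],
        component = comp, scope = scope, value = s[[comp]],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' D-var, S-var and A-var variance images
#'
#' Per-voxel counterparts of the scan-level averages: for voxel i,
#' \eqn{A_i = \sum_t Y_{it}^2/T}, \eqn{D_i = \sum_t (Y_{i,t+1}-Y_{it})^2/(4T)},
#' \eqn{S_i = \sum_t (Y_{it}+Y_{i,t+1})^2/(4T)}. Their spatial means equal the
#' scan averages A, D and S. Mapped back to voxel space they localize fast
#' and slow noise structure (e.g. vascular or physiological artifacts).
#'
#' @inheritParams compute_dse_timeseries
#' @return An object of class `dse_images`: list with numeric vectors
#'   `A_img`, `D_img`, `S_img` (length I) and `geometry` (for NIfTI-backed
#'   input, carried through so maps can be written in the input grid).
#' @export
compute_dse_images <- function(data) {
  Y <- as_dse_matrix(data)
  nT <- ncol(Y)
  if (nT < 2L) stop("T < 2")
  dmat <- (Y[, -1L, drop = FALSE] - Y[, -nT, drop = FALSE]) / 2
  smat <- (Y[, -1L, drop = FALSE] + Y[, -nT, drop = FALSE]) / 2
  structure(list(
    A_img = rowSums(Y^2) / nT,
    D_img = rowSums(dmat^2) / nT,
    S_img = rowSums(smat^2) / nT,
    geometry = if (inherits(data, "dse_scaled")) data$geometry,
    retained = if (inherits(data, "dse_scaled")) data$retained
  ), class = "dse_images")
}

#' DVARS time series from the fast component
#'
#' \eqn{\mathrm{DVARS}_t = 2\sqrt{D_t}} for t = 1..T-1, the spatial RMS of
#' the differenced image pair (t, t+1); round-trips exactly as
#' \eqn{\mathrm{DVARS}_t^2/4 = D_t}.
#'
#' @param dse a `dse_series` object (or a numeric vector of D-var values).
#' @return numeric vector of length T-1.
#' @export
dvars_series <- function(dse) {
  D <- if (inherits(dse, "dse_series")) dse$whole$D else as.numeric(dse)
  2 * sqrt(D)
}

#' Check the algebraic identities of the DSE decomposition
#'
#' Reports the maximum residuals, relative to the scan-average A, of the
#' pairwise identity \eqn{D_t + S_t = (A_t + A_{t+1})/2}, the scan-level
#' identity \eqn{A = D + S + E} (in every scope), and scope additivity
#' (whole = global + non-global, per component and index). Useful as a
#' numerical self-check after any data manipulation.
#'
#' @param dse a `dse_series` object.
#' @param tol relative tolerance; any residual above `tol` flags a violation.
#' @return list with `pairwise`, `total`, `scope` (max relative residuals),
#'   `tol` and logical `ok`.
#' @export
verify_identities <- function(dse, tol = 1e-8) {
  stopifnot(inherits(dse, "dse_series"))
  Aref <- dse$averages$whole$A
  if (Aref <= 0) Aref <- 1  # degenerate all-zero data: absolute residuals
  w <- dse$whole
  pairwise <- max(abs(w$D + w$S - (w$A[-dse$T] + w$A[-1L]) / 2)) / Aref
  total <- max(vapply(dse$averages, function(a) abs(a$A - (a$D + a$S + a$E)),
                      numeric(1))) / Aref
  scope <- 0
  for (comp in c("A", "D", "S", "E")) {
    scope <- max(scope, max(abs(dse$whole[[comp]] - dse$global[[comp]] -
                                  dse$nonglobal[[comp]])))
  }
  scope <- scope / Aref
  res <- list(pairwise = pairwise, total = total, scope = scope, tol = tol,
              ok = max(pairwise, total, scope) <= tol)
  res
}
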