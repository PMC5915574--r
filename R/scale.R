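#' Center and scale an fMRI data matrix
#'
#' Converts a raw voxels-by-time matrix \eqn{Y^R} (arbitrary scanner units)
#' into the centered, intensity-normalized form used by all DSE computations:
#' \deqn{Y_{it} = (Y^R_{it} - M^R_i) / m^R \times \mathrm{target},}
#' where \eqn{M^R_i} is the temporal mean of voxel \eqn{i} and \eqn{m^R} is an
#' overall summary (median or mean) of the in-mask voxel means. The scaling
#' puts typical pre-centering brain intensities at `target` (default 100) so
#' that variance diagnostics are comparable across scanners and protocols.
#'
#' Voxels with any non-finite value or with zero temporal variance (including
#' constant-zero background) are excluded before \eqn{m^R} is computed, and
#' recorded with a reason; such voxels would otherwise corrupt the IQR-based
#' null-moment estimates downstream.
#'
#' @param values numeric matrix, voxels in rows, timepoints in columns. A
#'   `dse_raw` object from [read_nifti_4d()] is also accepted.
#' @param scale_mode one of `"median"` (median of in-mask voxel means, the
#'   default, robust to residual extra-cranial voxels), `"mean"`, `"user"`
#'   (supply `m`), or `"none"` (center only, no intensity scaling).
#' @param target scalar the overall mean is mapped to; conventionally 100.
#' @param m user-supplied overall mean, required when `scale_mode = "user"`.
#' @return An object of class `dse_scaled`: list with `values` (I x T centered
#'   matrix), `voxel_means`, `overall_mean`, `scale_mode`, `target`,
#'   `excluded` (data.frame of dropped voxels with reasons), `retained`
#'   (row indices into the input), `I`, `T`, and `geometry` (NULL for plain
#'   matrix input; volume geometry for NIfTI input, used to write maps back).
#' @examples
#' y <- rbind(c(98, 102, 100), c(101, 99, 103))
#' s <- scale_center(y)
#' rowSums(s$values)  # each row centered to 0
#' @export
scale_center <- function(values, scale_mode = c("median", "mean", "user", "none"),
                         target = 100, m = NULL) {
  scale_mode <- match.arg(scale_mode)
  geometry <- NULL
  if (inherits(values, "dse_raw")) {
    geometry <- values$geometry
    values <- values$values
  }
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  nT <- ncol(values)
  if (nT < 2L) stop("need at least T = 2 timepoints")

  finite_ok <- rowSums(!is.finite(values)) == 0L
  rng <- rep(FALSE, nrow(values))
  if (any(finite_ok)) {
    v <- values[finite_ok, , drop = FALSE]
    rng[finite_ok] <- (apply(v, 1L, max) - apply(v, 1L, min)) > 0
  }
  keep <- finite_ok & rng
  reason <- character(0); idx <- integer(0)
  if (any(!finite_ok)) {
    idx <- which(!finite_ok); reason <- rep("nonfinite", length(idx))
  }
  zv <- which(finite_ok & !rng)
  if (length(zv)) {
    idx <- c(idx, zv); reason <- c(reason, rep("zero_variance", length(zv)))
  }
  if (!any(keep)) stop("empty mask: all voxels excluded")

  Y <- values[keep, , drop = FALSE]
  M <- rowMeans(Y)
  Yc <- Y - M
  if (scale_mode == "none") {
    mR <- NA_real_
  } else {
    mR <- switch(scale_mode,
      median = stats::median(M),
      mean   = mean(M),
      user   = {
        if (is.null(m)) stop("scale_mode = 'user' requires m")
        as.numeric(m)
      })
    if (!is.finite(mR) || mR <= 0) stop("bad scale: overall mean m^R must be finite and positive")
    Yc <- Yc / mR * target
  }

  structure(list(
    values = Yc,
    voxel_means = M,
    overall_mean = mR,
    scale_mode = scale_mode,
    target = target,
    excluded = data.frame(index = idx, reason = reason, stringsAsFactors = FALSE),
    retained = which(keep),
    I = nrow(Yc),
    T = nT,
    geometry = geometry
  ), class = "dse_scaled")
}

#' @export
print.dse_scaled <- function(x, ...) {
  cat(sprintf("Scaled fMRI data: I = %d voxels x T = %d timepoints\n", x$I, x$T))
  cat(sprintf("  scale_mode = %s", x$scale_mode))
  if (!is.na(x$overall_mean))
    cat(sprintf(", overall mean m^R = %.4g -> target %g", x$overall_mean, x$target))
  cat("\n")
  if (nrow(x$excluded))
    cat(sprintf("  excluded %d voxel(s): %s\n", nrow(x$excluded),
                paste(sprintf("%s=%d", names(table(x$excluded$reason)),
                              table(x$excluded$reason)), collapse = ", ")))
  invisible(x)
}

# Accept either a dse_scaled object or a bare numeric matrix already
# centered/scaled by the caller; returns the I x T matrix.
as_dse_matrix <- function(data) {
  if (inherits(data, "dse_scaled")) return(data$values)
  if (is.matrix(data) && is.numeric(data)) return(data)
  stop("expected a 'dse_scaled' object or a numeric matrix")
}
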