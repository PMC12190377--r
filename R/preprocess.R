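#' Preprocessing configuration
#'
#' Bundles the band-pass edges, the mean-FD exclusion threshold and the head
#' radius used to convert rotations to displacements.
#'
#' @param band_low,band_high pass-band edges in Hz (defaults 0.01 and 0.1);
#'   must satisfy `0 < band_low < band_high` and `band_high` below Nyquist
#'   for the volume being filtered.
#' @param fd_threshold mean framewise-displacement exclusion threshold in mm
#'   (default 0.2; exclusion is strict `>`).
#' @param head_radius head radius in mm for the rotation term of FD
#'   (default 50).
#' @param per_voxel logical; if `TRUE`, [intensityNormalize()] z-scores each
#'   in-mask voxel's time series separately instead of the whole 4D grid.
#' @return a classed list of validated fields.
#' @export
preprocConfig <- function(band_low = 0.01, band_high = 0.1, fd_threshold = 0.2,
                          head_radius = 50, per_voxel = FALSE) {
  stopifnot(band_low > 0, band_high > band_low, fd_threshold > 0, head_radius > 0)
  structure(list(band_low = band_low, band_high = band_high,
                 fd_threshold = fd_threshold, head_radius = head_radius,
                 per_voxel = per_voxel),
            class = "preprocConfig")
}

maskVector <- function(vol) {
  if (is.null(vol@mask)) rep(TRUE, prod(spatialDims(vol))) else as.vector(vol@mask)
}

#' Intensity normalization
#'
#' Rescales in-mask intensities to mean 0 and standard deviation 1, removing
#' scanner-dependent intensity scale and offset. By default the z-scoring is
#' global over all in-mask voxels and time points; with
#' `cfg$per_voxel = TRUE` each voxel's time series is z-scored separately.
#' Out-of-mask voxels are set to zero.
#'
#' @param vol a [Volume4D-class].
#' @param cfg a [preprocConfig()].
#' @return a normalized [Volume4D-class].
#' @export
intensityNormalize <- function(vol, cfg = preprocConfig()) {
  X <- voxelMatrix(vol)
  m <- maskVector(vol)
  if (cfg$per_voxel) {
    mu <- rowMeans(X[m, , drop = FALSE])
    s <- apply(X[m, , drop = FALSE], 1, stats::sd)
    if (any(s == 0)) stop("degenerate volume: constant voxel time series")
    X[m, ] <- (X[m, , drop = FALSE] - mu) / s
  } else {
    v <- X[m, ]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) stop("degenerate volume: zero in-mask variance")
    X[m, ] <- (X[m, , drop = FALSE] - mean(v)) / s
  }
  X[!m, ] <- 0
  Volume4D(array(X, dim(vol@data)), tr = vol@tr, mask = vol@mask)
}

#' Global signal regression
#'
#' Replaces every voxel time series by its least-squares residual after
#' regressing out an intercept and the global signal (the mean over in-mask
#' voxels at each time point). Residuals are exactly orthogonal to the
#' global signal.
#'
#' @param vol a [Volume4D-class].
#' @return a [Volume4D-class] of residuals (out-of-mask voxels untouched).
#' @export
globalSignalRegress <- function(vol) {
  X <- voxelMatrix(vol)
  m <- maskVector(vol)
  g <- colMeans(X[m, , drop = FALSE])
  if (stats::sd(g) == 0) stop("constant global signal")
  D <- cbind(1, g)
  # residual for all voxel rows at once: X - X D (D'D)^-1 D'
  P <- D %*% solve(crossprod(D), t(D))
  X[m, ] <- X[m, , drop = FALSE] - X[m, , drop = FALSE] %*% t(P)
  Volume4D(array(X, dim(vol@data)), tr = vol@tr, mask = vol@mask)
}

#' Temporal band-pass filter
#'
#' Filters every voxel time series to the `[band_low, band_high]` Hz
#' pass-band with a 4th-order Butterworth filter applied forward and
#' backward (zero phase). Each series is demeaned (DC lies outside the
#' pass-band) and padded by odd reflection at both ends before the
#' forward-backward pass to suppress edge transients; the series must be
#' longer than three times the filter length (t >= 25 for the default
#' 4th-order band-pass) for the padding to be defined.
#'
#' @param vol a [Volume4D-class].
#' @param cfg a [preprocConfig()].
#' @return a filtered [Volume4D-class].
#' @export
bandpassFilter <- function(vol, cfg = preprocConfig()) {
  fs <- 1 / vol@tr
  nyq <- fs / 2
  if (cfg$band_high >= nyq)
    stop("band_high (", cfg$band_high, " Hz) at or above Nyquist (", nyq, " Hz)")
  t <- nTimepoints(vol)
  if (t < 25) stop("series too short for the band-pass filter (need t >= 25)")
  bf <- signal::butter(4, c(cfg$band_low, cfg$band_high) / nyq, type = "pass")
  np <- min(24L, t - 1L)   # odd-reflection pad, 3 x filter length
  X <- voxelMatrix(vol)
  m <- which(maskVector(vol))
  for (i in m) {
    x <- X[i, ] - mean(X[i, ])
    padded <- c(2 * x[1] - x[(np + 1):2], x, 2 * x[t] - x[(t - 1):(t - np)])
    X[i, ] <- signal::filtfilt(bf, padded)[(np + 1):(np + t)]
  }
  Volume4D(array(X, dim(vol@data)), tr = vol@tr, mask = vol@mask)
}

#' Framewise displacement
#'
#' Per-transition framewise displacement in mm following the standard
#' sum-of-absolute-differences convention: `FD_i = |d dx| + |d dy| + |d dz|
#' + r (|d a| + |d b| + |d g|)` with rotations converted to arc length on a
#' sphere of radius `head_radius` (default 50 mm).
#'
#' @param trace T x 6 motion trace (translations mm, rotations rad), T >= 2.
#' @param cfg a [preprocConfig()].
#' @return list with `fd` (length T-1 numeric) and `mean_fd`, class
#'   `"FDSeries"`.
#' @export
framewiseDisplacement <- function(trace, cfg = preprocConfig()) {
  stopifnot(is.matrix(trace), ncol(trace) == 6L)
  if (nrow(trace) < 2L) stop("motion trace must have at least 2 frames")
  d <- abs(diff(trace))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    cfg$head_radius * rowSums(d[, 4:6, drop = FALSE])
  structure(list(fd = unname(fd), mean_fd = mean(fd)), class = "FDSeries")
}

#' Motion quality control
#'
#' Splits subject records into retained and excluded sets: subjects whose
#' mean framewise displacement strictly exceeds `cfg$fd_threshold` (default
#' 0.2 mm) are excluded. Both returned data.frames carry `mean_fd` and
#' `qc_pass` filled in, and together partition the input.
#'
#' @param records subject-record data.frame with a `subject_id` column.
#' @param fdList named list of `"FDSeries"` (one per subject) or a numeric
#'   vector of mean FDs, aligned with `records$subject_id`.
#' @param cfg a [preprocConfig()].
#' @return list with `retained`, `excluded` (data.frames) and `report` (a
#'   data.frame with `subject_id`, `mean_fd`, `qc_pass`).
#' @export
applyQC <- function(records, fdList, cfg = preprocConfig()) {
  mfd <- if (is.numeric(fdList)) fdList else
    vapply(records$subject_id, function(id) fdList[[id]]$mean_fd, numeric(1))
  stopifnot(length(mfd) == nrow(records))
  records$mean_fd <- unname(mfd)
  records$qc_pass <- records$mean_fd <= cfg$fd_threshold
  report <- records[, c("subject_id", "mean_fd", "qc_pass")]
  list(retained = records[records$qc_pass, , drop = FALSE],
       excluded = records[!records$qc_pass, , drop = FALSE],
       report = report)
}

#' Write a QC report as TSV
#' @param qc result of [applyQC()].
#' @param path output TSV path.
#' @export
writeQCReport <- function(qc, path) {
  utils::write.table(qc$report, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Preprocess one subject
#'
#' Runs the in-scope preprocessing chain in its fixed order -- intensity
#' normalization, then global signal regression, then band-pass filtering --
#' and computes the motion QC verdict from the subject's trace. Spatial
#' registration, slice-timing and motion correction are delegated upstream:
#' this function expects already-aligned volumes (the synthetic generator
#' produces them).
#'
#' @param vol a [Volume4D-class].
#' @param trace T x 6 motion trace.
#' @param cfg a [preprocConfig()].
#' @param callback optional function called with the stage name
#'   (`"normalize"`, `"gsr"`, `"bandpass"`) as each stage starts; useful for
#'   instrumentation.
#' @return list with `volume` (processed [Volume4D-class]), `fd`
#'   (`"FDSeries"`) and `qc_pass` (logical).
#' @export
preprocessSubject <- function(vol, trace, cfg = preprocConfig(), callback = NULL) {
  note <- function(stage) if (!is.null(callback)) callback(stage)
  note("normalize"); vol <- intensityNormalize(vol, cfg)
  note("gsr"); vol <- globalSignalRegress(vol)
  note("bandpass"); vol <- bandpassFilter(vol, cfg)
  fd <- framewiseDisplacement(trace, cfg)
  list(volume = vol, fd = fd, qc_pass = fd$mean_fd <= cfg$fd_threshold)
}

#' Preprocess a loaded cohort
#'
#' Applies [preprocessSubject()] to every subject of a [loadCohort()] result
#' and fills the QC columns of the records.
#'
#' @param cohort list as returned by [loadCohort()].
#' @param cfg a [preprocConfig()].
#' @param keep_excluded if `FALSE` (default) QC-failing subjects are dropped
#'   from the returned `records` and `volumes`.
#' @return cohort list with processed `volumes`, updated `records`, and a
#'   `qc` element as from [applyQC()].
#' @export
preprocessCohort <- function(cohort, cfg = preprocConfig(), keep_excluded = FALSE) {
  ids <- cohort$records$subject_id
  fds <- vector("list", length(ids)); names(fds) <- ids
  for (id in ids) {
    pp <- preprocessSubject(cohort$volumes[[id]], cohort$traces[[id]], cfg)
    cohort$volumes[[id]] <- pp$volume
    fds[[id]] <- pp$fd
  }
  qc <- applyQC(cohort$records, fds, cfg)
  cohort$qc <- qc
  cohort$records <- if (keep_excluded) rbind(qc$retained, qc$excluded) else qc$retained
  if (!keep_excluded) {
    keep <- cohort$records$subject_id
    cohort$volumes <- cohort$volumes[keep]
    cohort$traces <- cohort$traces[keep]
  }
  cohort
}
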