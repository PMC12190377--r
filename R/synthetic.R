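#' Acquisition, class-signal and noise specifications
#'
#' `acquisitionSpec()` fixes the synthetic scan geometry: spatial grid,
#' number of time points, repetition time and voxel size. The default is a
#' deliberately small desk-scale acquisition (16 x 16 x 12 voxels, 50 time
#' points, TR 2 s) on which the whole pipeline trains in minutes; full-scale
#' MNI-space dimensions (99 x 117 x 95) are available via
#' `fullScaleAcquisition()` for shape bookkeeping.
#'
#' @param shape integer length-3 spatial grid (X, Y, Z), all >= 4.
#' @param t integer number of time points, >= 2.
#' @param tr repetition time in seconds, > 0.
#' @param voxel_size numeric length-3 voxel edge lengths in mm.
#' @return a classed list of validated fields.
#' @export
acquisitionSpec <- function(shape = c(16L, 16L, 12L), t = 50L, tr = 2,
                            voxel_size = c(3, 3, 3)) {
  shape <- as.integer(shape); t <- as.integer(t)
  stopifnot(length(shape) == 3L, all(shape >= 4L), t >= 2L, tr > 0,
            length(voxel_size) == 3L, all(voxel_size > 0))
  structure(list(shape = shape, t = t, tr = tr, voxel_size = voxel_size),
            class = "acquisitionSpec")
}

#' @rdname acquisitionSpec
#' @export
fullScaleAcquisition <- function(t = 50L, tr = 2) {
  acquisitionSpec(shape = c(99L, 117L, 95L), t = t, tr = tr, voxel_size = c(2, 2, 2))
}

#' @rdname acquisitionSpec
#' @param blob_center integer length-3 voxel coordinates of the signal blob.
#' @param blob_radius blob radius in voxels.
#' @param freq_class0,freq_class1 class-specific sinusoid frequencies in Hz;
#'   both must lie strictly inside (0, Nyquist) for the acquisition's TR.
#' @param amplitude sinusoid amplitude in signal units, >= 0.
#' @param mode `"frequency"` (classes differ in frequency; the default, so
#'   classes are temporally rather than statically separable) or
#'   `"amplitude"` (both classes at `freq_class0`; class 1 at twice the
#'   amplitude).
#' @export
classSignalSpec <- function(blob_center = c(8L, 8L, 6L), blob_radius = 3,
                            freq_class0 = 0.03, freq_class1 = 0.08,
                            amplitude = 1, mode = c("frequency", "amplitude")) {
  mode <- match.arg(mode)
  stopifnot(length(blob_center) == 3L, blob_radius > 0,
            freq_class0 > 0, freq_class1 > 0, amplitude >= 0)
  structure(list(blob_center = as.numeric(blob_center), blob_radius = blob_radius,
                 freq_class0 = freq_class0, freq_class1 = freq_class1,
                 amplitude = amplitude, mode = mode),
            class = "classSignalSpec")
}

#' @rdname acquisitionSpec
#' @param white_sd white-noise standard deviation in signal units.
#' @param drift_amp amplitude of the shared low-frequency scanner drift
#'   (linear + half-cosine, below 0.01 Hz).
#' @param motion_amp per-frame translation random-walk step scale in mm.
#' @param rot_amp per-frame rotation random-walk step scale in radians.
#' @export
noiseSpec <- function(white_sd = 0.5, drift_amp = 1, motion_amp = 0, rot_amp = 0) {
  stopifnot(white_sd >= 0, drift_amp >= 0, motion_amp >= 0, rot_amp >= 0)
  structure(list(white_sd = white_sd, drift_amp = drift_amp,
                 motion_amp = motion_amp, rot_amp = rot_amp),
            class = "noiseSpec")
}

# Ellipsoidal "brain" mask with semi-axes at 45% of each grid dimension.
ellipsoidMask <- function(shape) {
  ctr <- (shape + 1) / 2
  ax <- pmax(shape * 0.45, 1)
  g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]), z = seq_len(shape[3]))
  inside <- ((g$x - ctr[1]) / ax[1])^2 + ((g$y - ctr[2]) / ax[2])^2 +
    ((g$z - ctr[3]) / ax[3])^2 <= 1
  array(inside, dim = shape)
}

blobMask <- function(shape, center, radius) {
  g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]), z = seq_len(shape[3]))
  inside <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2 <= radius^2
  array(inside, dim = shape)
}

# Low-frequency drift: linear trend + half-cosine over the scan duration
# (frequency 1/(2 * duration), below 0.01 Hz for scans longer than 50 s).
driftSeries <- function(tt, drift_amp, a, b) {
  dur <- max(tt[length(tt)], 1e-9)
  drift_amp * (a * (tt / dur - 0.5) + b * cos(pi * tt / dur))
}

#' Generate one synthetic subject
#'
#' Produces a 4D volume whose in-blob voxels carry a sinusoid at the label's
#' class frequency plus shared low-frequency drift and white noise, whose
#' remaining in-brain voxels carry drift and white noise only, and whose
#' out-of-brain voxels are zero, together with a T x 6 motion trace (all
#' zero when `motion_amp = rot_amp = 0`). When the trace is non-zero the
#' corresponding rigid motion is applied to the volume frames. Fully
#' deterministic given `seed`.
#'
#' @param acq an [acquisitionSpec()].
#' @param sig a [classSignalSpec()].
#' @param noise a [noiseSpec()].
#' @param label subject class, 0 (control) or 1 (case).
#' @param seed integer seed.
#' @return list with elements `volume` ([Volume4D-class]) and `trace`
#'   (T x 6 matrix: 3 translations in mm, 3 rotations in radians).
#' @examples
#' sub <- generateSubject(acquisitionSpec(), classSignalSpec(), noiseSpec(),
#'                        label = 1, seed = 7)
#' sub$volume
#' @export
generateSubject <- function(acq, sig, noise, label, seed) {
  stopifnot(is(acq, "acquisitionSpec"), is(sig, "classSignalSpec"),
            is(noise, "noiseSpec"), label %in% c(0, 1))
  nyq <- 1 / (2 * acq$tr)
  if (sig$freq_class0 >= nyq || sig$freq_class1 >= nyq)
    stop("class frequency at or above Nyquist (", nyq, " Hz) for TR ", acq$tr)
  if (any(sig$blob_center - sig$blob_radius < 1) ||
      any(sig$blob_center + sig$blob_radius > acq$shape))
    stop("signal blob extends outside the volume")

  shape <- acq$shape; t <- acq$t; V <- prod(shape)
  mask <- ellipsoidMask(shape) | blobMask(shape, sig$blob_center, sig$blob_radius)
  blob <- blobMask(shape, sig$blob_center, sig$blob_radius)
  tt <- (seq_len(t) - 1) * acq$tr

  withSeed(seed, {
    phase <- runif(1, 0, 2 * pi)
    a <- runif(1, -1, 1); b <- runif(1, -1, 1)
    freq <- if (label == 1 && sig$mode == "frequency") sig$freq_class1 else sig$freq_class0
    amp <- if (label == 1 && sig$mode == "amplitude") 2 * sig$amplitude else sig$amplitude
    sinus <- amp * sin(2 * pi * freq * tt + phase)
    drift <- driftSeries(tt, noise$drift_amp, a, b)

    X <- matrix(0, V, t)
    mvec <- as.vector(mask); bvec <- as.vector(blob)
    nm <- sum(mvec)
    if (noise$white_sd > 0) {
      X[mvec, ] <- rnorm(nm * t, sd = noise$white_sd)
    }
    X[mvec, ] <- X[mvec, ] + rep(drift, each = nm)
    X[bvec, ] <- X[bvec, ] + rep(sinus, each = sum(bvec))

    trace <- matrix(0, t, 6)
    if (noise$motion_amp > 0 || noise$rot_amp > 0) {
      steps <- cbind(matrix(rnorm((t - 1) * 3, sd = noise$motion_amp), t - 1),
                     matrix(rnorm((t - 1) * 3, sd = noise$rot_amp), t - 1))
      trace[-1, ] <- apply(steps, 2, cumsum)
    }

    vol <- Volume4D(array(X, c(shape, t)), tr = acq$tr, mask = mask)
    if (any(trace != 0)) vol <- injectMotion(vol, trace, voxel_size = acq$voxel_size)
    list(volume = vol, trace = trace)
  })
}

#' Apply rigid head motion to a volume series
#'
#' Each frame is rigidly resampled according to its motion-trace row:
#' rotations (radians, about the volume centre, applied exactly with
#' nearest-neighbour resampling) followed by translations (mm, converted to
#' voxels and rounded to the nearest voxel). Frames whose trace row is all
#' zero -- in particular the first frame of traces produced by
#' [generateSubject()] -- are returned untouched; voxels pulled from outside
#' the grid become zero.
#'
#' @param vol a [Volume4D-class].
#' @param trace T x 6 motion trace (3 translations mm, 3 rotations rad).
#' @param voxel_size voxel edge lengths in mm used to convert translations.
#' @return a [Volume4D-class] with moved frames.
#' @export
injectMotion <- function(vol, trace, voxel_size = c(3, 3, 3)) {
  stopifnot(is(vol, "Volume4D"), is.matrix(trace), ncol(trace) == 6L)
  t <- nTimepoints(vol)
  if (nrow(trace) != t)
    stop("motion trace length (", nrow(trace), ") does not match time points (", t, ")")
  shape <- spatialDims(vol)
  ctr <- (shape + 1) / 2
  grid <- as.matrix(expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                                z = seq_len(shape[3])))
  out <- vol@data
  for (i in seq_len(t)) {
    if (all(trace[i, ] == 0)) next
    tvox <- trace[i, 1:3] / voxel_size
    ang <- trace[i, 4:6]
    ca <- cos(ang); sa <- sin(ang)
    Rx <- rbind(c(1, 0, 0), c(0, ca[1], -sa[1]), c(0, sa[1], ca[1]))
    Ry <- rbind(c(ca[2], 0, sa[2]), c(0, 1, 0), c(-sa[2], 0, ca[2]))
    Rz <- rbind(c(ca[3], -sa[3], 0), c(sa[3], ca[3], 0), c(0, 0, 1))
    R <- Rx %*% Ry %*% Rz
    # pull: source = R^-1 (target - centre - t) + centre
    src <- sweep(grid, 2, ctr + tvox) %*% R  # R^-1 = t(R), applied as x' R
    src <- round(sweep(src, 2, ctr, "+"))
    ok <- src[, 1] >= 1 & src[, 1] <= shape[1] &
      src[, 2] >= 1 & src[, 2] <= shape[2] &
      src[, 3] >= 1 & src[, 3] <= shape[3]
    lin <- (src[, 3] - 1) * shape[1] * shape[2] + (src[, 2] - 1) * shape[1] + src[, 1]
    frame <- as.vector(out[, , , i])
    newframe <- numeric(length(frame))
    newframe[ok] <- frame[lin[ok]]
    out[, , , i] <- newframe
  }
  Volume4D(out, tr = vol@tr, mask = vol@mask)
}

#' Generate a multi-site synthetic cohort on disk
#'
#' Writes `2 * n_per_class` subjects with balanced labels (controls first,
#' then cases, so the round-robin site assignment gives every site both
#' classes rather than confounding site with label), volumes as
#' `.nii.gz`, motion traces as 6-column text, and a `phenotype.tsv` with
#' columns `subject_id`, `site`, `label`. Per-subject seeds are derived
#' deterministically from the master seed.
#'
#' @inheritParams generateSubject
#' @param n_per_class subjects per class, >= 1.
#' @param sites character vector of site labels, length >= 1.
#' @param dir output directory (created if missing).
#' @return data.frame of subject records (`subject_id`, `site`, `label`,
#'   `volume_path`, `motion_path`, `mean_fd`, `qc_pass`).
#' @export
generateCohort <- function(acq, sig, noise, n_per_class, sites, seed, dir) {
  stopifnot(n_per_class >= 1, length(sites) >= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- 2L * as.integer(n_per_class)
  ids <- sprintf("sub%03d", seq_len(n))
  if (anyDuplicated(ids)) stop("duplicate subject ids")
  labels <- rep(c(0L, 1L), each = n_per_class)
  site <- rep(sites, length.out = n)
  records <- data.frame(subject_id = ids, site = site, label = labels,
                        volume_path = file.path(dir, paste0(ids, ".nii.gz")),
                        motion_path = file.path(dir, paste0(ids, "_motion.txt")),
                        mean_fd = NA_real_, qc_pass = NA,
                        stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    sub <- generateSubject(acq, sig, noise, labels[i], seed = deriveSeed(seed, i))
    writeVolume4D(sub$volume, records$volume_path[i], voxel_size = acq$voxel_size)
    writeMotionTrace(sub$trace, records$motion_path[i])
  }
  utils::write.table(records[, c("subject_id", "site", "label")],
                     file.path(dir, "phenotype.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  records
}

#' Load a cohort directory into memory
#'
#' Reads `phenotype.tsv` plus every subject's volume and motion trace.
#'
#' @param dir a directory written by [generateCohort()] (or following its
#'   layout).
#' @param mask optional logical mask attached to every volume.
#' @return list with `records` (data.frame), `volumes` (named list of
#'   [Volume4D-class]) and `traces` (named list of T x 6 matrices).
#' @export
loadCohort <- function(dir, mask = NULL) {
  ph <- utils::read.table(file.path(dir, "phenotype.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  ids <- ph$subject_id
  vols <- lapply(ids, function(id)
    readVolume4D(file.path(dir, paste0(id, ".nii.gz")), mask = mask))
  traces <- lapply(ids, function(id)
    readMotionTrace(file.path(dir, paste0(id, "_motion.txt"))))
  names(vols) <- names(traces) <- ids
  ph$volume_path <- file.path(dir, paste0(ids, ".nii.gz"))
  ph$motion_path <- file.path(dir, paste0(ids, "_motion.txt"))
  ph$mean_fd <- NA_real_
  ph$qc_pass <- NA
  list(records = ph, volumes = vols, traces = traces)
}

#' Dominant discrete-Fourier frequency of a series
#'
#' Frequency (Hz) of the non-DC Fourier bin with the largest modulus, given
#' the sampling interval `tr`. Used as a simple spectral oracle for the
#' synthetic class signal.
#'
#' @param x numeric series.
#' @param tr sampling interval in seconds.
#' @return frequency in Hz.
#' @export
dominantFrequency <- function(x, tr) {
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x)))[2:floor(n / 2 + 1)]
  which.max(sp) / (n * tr)
}
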