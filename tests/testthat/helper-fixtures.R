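# Shared fixtures: everything is generated in code at test time.

tinyShape <- c(10L, 10L, 8L)

tinyAcq <- function(t = 30L) {
  acquisitionSpec(shape = tinyShape, t = t, tr = 2, voxel_size = c(3, 3, 3))
}

tinySig <- function(...) {
  classSignalSpec(blob_center = c(5L, 5L, 4L), blob_radius = 2, ...)
}

tinyMask <- function(shape = tinyShape, center = c(5, 5, 4), radius = 2) {
  fmriSTC:::ellipsoidMask(shape) | fmriSTC:::blobMask(shape, center, radius)
}

# In-memory cohort (no disk round-trip) with balanced interleaved labels.
makeCohort <- function(n_per_class, acq, sig, noise, seed, sites = c("A", "B")) {
  n <- 2L * n_per_class
  ids <- sprintf("sub%03d", seq_len(n))
  labels <- rep(c(0L, 1L), length.out = n)
  volumes <- list(); traces <- list()
  for (i in seq_len(n)) {
    s <- generateSubject(acq, sig, noise, labels[i],
                         seed = fmriSTC:::deriveSeed(seed, i))
    volumes[[ids[i]]] <- s$volume
    traces[[ids[i]]] <- s$trace
  }
  list(records = data.frame(subject_id = ids,
                            site = rep(sites, length.out = n),
                            label = labels, stringsAsFactors = FALSE),
       volumes = volumes, traces = traces)
}

# Random noise volume with the tiny mask (for preprocessing properties).
randomVolume <- function(shape = c(6L, 6L, 4L), t = 20L, tr = 2, seed = 1) {
  set.seed(seed)
  mask <- fmriSTC:::ellipsoidMask(shape)
  X <- array(0, c(shape, t))
  Xm <- matrix(rnorm(sum(mask) * t), sum(mask), t)
  Xf <- matrix(X, prod(shape), t)
  Xf[as.vector(mask), ] <- Xm
  Volume4D(array(Xf, c(shape, t)), tr = tr, mask = mask)
}

# Spectral oracle classifier: label by which class frequency the mean
# in-blob series' dominant frequency is closer to. Independent of the
# learned pipeline.
oracleClassify <- function(vol, sig) {
  bl <- fmriSTC:::blobMask(spatialDims(vol), sig$blob_center, sig$blob_radius)
  series <- colMeans(voxelMatrix(vol)[as.vector(bl), , drop = FALSE])
  f <- dominantFrequency(series, repetitionTime(vol))
  as.integer(abs(f - sig$freq_class1) < abs(f - sig$freq_class0))
}

# FFT amplitude at the bin nearest `freq` for a series sampled at 1/tr Hz.
fftAmplitude <- function(x, tr, freq) {
  n <- length(x)
  bins <- (seq_len(n) - 1) / (n * tr)
  Mod(stats::fft(x))[which.min(abs(bins - freq))]
}
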