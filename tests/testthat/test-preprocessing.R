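test_that("intensity normalization z-scores in-mask values and is affine-invariant", {
  v <- randomVolume(seed = 4)
  n <- intensityNormalize(v)
  m <- as.vector(brainMask(v))
  vals <- voxelMatrix(n)[m, ]
  expect_lt(abs(mean(vals)), 1e-6)
  expect_lt(abs(sd(vals) - 1), 1e-6)
  expect_true(all(voxelMatrix(n)[!m, ] == 0))

  shifted <- Volume4D(volData(v) * 3 + 10, tr = v@tr, mask = brainMask(v))
  expect_equal(volData(intensityNormalize(shifted)), volData(n), tolerance = 1e-12)

  const <- Volume4D(array(5, dim(volData(v))), tr = 2, mask = brainMask(v))
  expect_error(intensityNormalize(const), "degenerate")
})

test_that("GSR residuals are orthogonal to the global signal across random volumes", {
  for (seed in 1:100) {
    v <- randomVolume(shape = c(5L, 5L, 4L), t = 12L, seed = seed)
    g <- globalSignalRegress(v)
    m <- as.vector(brainMask(v))
    gs <- colMeans(voxelMatrix(v)[m, ])
    R <- voxelMatrix(g)[m, ]
    cors <- abs(R %*% (gs - mean(gs))) / (sqrt(rowSums(scale(t(R), scale = FALSE)^2)) *
                                            sqrt(sum((gs - mean(gs))^2)))
    cors <- cors[is.finite(cors)]
    expect_lt(max(cors), 1e-8)
  }
  expect_identical(dim(volData(globalSignalRegress(randomVolume()))),
                   dim(volData(randomVolume())))
})

test_that("a voxel that is an affine function of the global signal is zeroed by GSR", {
  v <- randomVolume(seed = 8)
  X <- voxelMatrix(v)
  m <- which(as.vector(brainMask(v)))
  nm <- length(m)
  g0 <- colMeans(X[m, ])
  j <- m[1]
  # choose the new row so that, after replacement, row j = 2*global + 5 exactly
  gnew <- (g0 + (5 - X[j, ]) / nm) / (1 - 2 / nm)
  X[j, ] <- 2 * gnew + 5
  v2 <- Volume4D(array(X, dim(volData(v))), tr = v@tr, mask = brainMask(v))
  res <- voxelMatrix(globalSignalRegress(v2))[j, ]
  expect_lt(max(abs(res)), 1e-8)
})

test_that("band-pass keeps in-band and rejects out-of-band power (FFT oracle)", {
  for (tr in c(1, 2, 3)) {
    t <- 200L
    nyq <- 1 / (2 * tr)
    mkvol <- function(freq) {
      tt <- (0:(t - 1)) * tr
      series <- sin(2 * pi * freq * tt)
      Volume4D(array(rep(series, each = 4 * 4 * 4), c(4, 4, 4, t)), tr = tr)
    }
    cfg <- preprocConfig()
    passed <- bandpassFilter(mkvol(0.05), cfg)
    r_pass <- fftAmplitude(voxelMatrix(passed)[1, ], tr, 0.05) /
      fftAmplitude(voxelMatrix(mkvol(0.05))[1, ], tr, 0.05)
    expect_gte(r_pass, 0.9)

    f_stop <- 0.8 * nyq
    stopped <- bandpassFilter(mkvol(f_stop), cfg)
    r_stop <- fftAmplitude(voxelMatrix(stopped)[1, ], tr, f_stop) /
      fftAmplitude(voxelMatrix(mkvol(f_stop))[1, ], tr, f_stop)
    expect_lte(r_stop, 0.1)

    const <- Volume4D(array(1, c(4, 4, 4, t)), tr = tr)
    expect_lt(max(abs(volData(bandpassFilter(const, cfg)))), 1e-6)
  }
  # band above Nyquist must error (TR 5 s -> Nyquist 0.1 Hz)
  slow <- Volume4D(array(rnorm(4^3 * 30), c(4, 4, 4, 30)), tr = 5)
  expect_error(bandpassFilter(slow), "Nyquist")
})

test_that("framewise displacement matches hand-evaluated cases", {
  cfg <- preprocConfig()
  zero <- matrix(0, 50, 6)
  fd0 <- framewiseDisplacement(zero, cfg)
  expect_equal(fd0$fd, rep(0, 49))
  expect_equal(fd0$mean_fd, 0)

  tr <- zero; tr[5:50, 1] <- 0.1  # one 0.1 mm x-jump between frames 4 and 5
  fd <- framewiseDisplacement(tr, cfg)
  expect_equal(sum(fd$fd != 0), 1L)
  expect_equal(fd$fd[4], 0.1)
  expect_equal(fd$mean_fd, 0.1 / 49)

  rot <- zero; rot[10:50, 4:6] <- 0.002  # 0.002 rad on each axis, radius 50
  expect_equal(framewiseDisplacement(rot, cfg)$fd[9], 0.3)

  expect_error(framewiseDisplacement(zero[1, , drop = FALSE], cfg), "at least 2")
})

test_that("FD is invariant to a constant offset of the whole trace", {
  for (seed in 1:20) {
    set.seed(seed)
    tr <- matrix(rnorm(30 * 6, sd = 0.1), 30, 6)
    off <- sweep(tr, 2, rnorm(6), "+")
    expect_equal(framewiseDisplacement(tr)$fd, framewiseDisplacement(off)$fd)
  }
})

test_that("QC excludes strictly above threshold and partitions the cohort", {
  rec <- data.frame(subject_id = sprintf("s%02d", 1:5),
                    site = "A", label = c(0, 1, 0, 1, 0),
                    stringsAsFactors = FALSE)
  qc <- applyQC(rec, c(0.25, 0, 0.2, 0.1999, 0.4))
  expect_identical(qc$excluded$subject_id, c("s01", "s05"))   # > 0.2 only
  expect_identical(qc$retained$subject_id, c("s02", "s03", "s04"))  # 0.2 retained
  expect_setequal(c(qc$retained$subject_id, qc$excluded$subject_id), rec$subject_id)
  expect_length(intersect(qc$retained$subject_id, qc$excluded$subject_id), 0)
  expect_true(all(!qc$excluded$qc_pass) && all(qc$retained$qc_pass))
  # empty input -> two empty sets
  qc0 <- applyQC(rec[0, ], numeric(0))
  expect_equal(nrow(qc0$retained) + nrow(qc0$excluded), 0L)
})

test_that("preprocessSubject runs normalize -> GSR -> band-pass and flags motion", {
  acq <- tinyAcq(t = 30L)
  s <- generateSubject(acq, tinySig(), noiseSpec(), 1, seed = 21)
  stages <- character(0)
  pp <- preprocessSubject(s$volume, s$trace, callback = function(x)
    stages <<- c(stages, x))
  expect_identical(stages, c("normalize", "gsr", "bandpass"))
  expect_identical(dim(volData(pp$volume)), dim(volData(s$volume)))
  expect_true(all(is.finite(volData(pp$volume))))
  expect_true(pp$qc_pass)

  # inject a trace with mean FD 0.3: constant 0.3 mm jump at every transition
  tr <- apply(matrix(c(rep(0.3, 29 * 1), rep(0, 29 * 5)), 29, 6), 2, cumsum)
  tr <- rbind(0, tr)
  pp2 <- preprocessSubject(s$volume, tr)
  expect_equal(pp2$fd$mean_fd, 0.3)
  expect_false(pp2$qc_pass)
})
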