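test_that("fusion concatenates the window's temporal row with its first-frame spatial row", {
  ws <- segmentWindows(windowConfig(20, 5, 2))   # starts 0, 2, ..., k odd-enforced
  set.seed(1)
  tem <- matrix(rnorm(ws$k * 6), ws$k, 6)
  sp <- matrix(rnorm(20 * 4), 20, 4)
  fused <- fuseFeatures(tem, sp, ws)
  expect_identical(dim(fused), c(ws$k, 10L))       # d1 + d2 = 4 + 6
  # window 1 pairs with spatial row 0 (0-based), whatever the stride
  expect_equal(fused[1, ], c(tem[1, ], sp[1, ]))
  # stride 2, window 3 -> 0-based spatial index 4
  expect_equal(attr(fused, "spatial_index")[3], 4L)
  expect_equal(fused[3, 7:10], sp[5, ])

  short <- sp[seq_len(max(ws$starts)), , drop = FALSE]
  expect_error(fuseFeatures(tem, short, ws), "too few rows")
})

test_that("majority vote matches a brute-force counter exhaustively", {
  expect_equal(majorityVote(c(1, 1, 0)), 1L)
  expect_equal(majorityVote(c(0, 0, 0, 0, 1)), 0L)
  for (k in c(1L, 3L, 5L, 7L)) {
    vecs <- as.matrix(expand.grid(rep(list(0:1), k)))
    for (r in seq_len(nrow(vecs))) {
      v <- vecs[r, ]
      brute <- if (sum(v == 1) > sum(v == 0)) 1L else 0L  # count comparison
      expect_identical(majorityVote(v), brute)
    }
  }
  expect_error(majorityVote(c(0, 1)), "odd")
  expect_error(majorityVote(c(0, 1, 2)), "binary")
})

test_that("the GBDT separates well-separated clusters and is seeded", {
  set.seed(2)
  n <- 60
  X <- rbind(matrix(rnorm(n * 5), n, 5), matrix(rnorm(n * 5, mean = 10), n, 5))
  y <- rep(c(0, 1), each = n)
  m <- trainWindowClassifier(X, y, gbdtConfig(seed = 3))
  p <- predict(m, xgboost::xgb.DMatrix(X))
  expect_equal(mean((p > 0.5) == y), 1)

  expect_error(trainWindowClassifier(X, rep(1, 2 * n)), "single class")

  probe <- matrix(rnorm(20 * 5), 20, 5)
  m2 <- trainWindowClassifier(X, y, gbdtConfig(seed = 3))
  expect_identical(predict(m, xgboost::xgb.DMatrix(probe)),
                   predict(m2, xgboost::xgb.DMatrix(probe)))
})

test_that("trainPipeline validates the cohort and is deterministic end to end", {
  acq <- tinyAcq(t = 21L)
  co <- makeCohort(3, acq, tinySig(), noiseSpec(drift_amp = 0), seed = 50)
  cfg <- pipelineConfig(window = windowConfig(21, 6, 3),
                        spatial = spatialEncoderConfig(kernel_sizes = c(3, 5),
                                                       channels_per_kernel = 2,
                                                       d1 = 6),
                        temporal = temporalEncoderConfig(hidden_units = 8),
                        gbdt = gbdtConfig(n_trees = 20),
                        train = trainConfig(epochs = 1, batch_size = 8))
  m1 <- trainPipeline(co, cfg, seed = 9)
  m2 <- trainPipeline(co, cfg, seed = 9)
  probe <- generateSubject(acq, tinySig(), noiseSpec(drift_amp = 0), 1, seed = 999)
  p1 <- classifySubject(m1, probe$volume)
  p2 <- classifySubject(m2, probe$volume)
  expect_identical(p1@probabilities, p2@probabilities)
  expect_identical(p1@voted, p2@voted)

  # window predictions contract
  expect_true(all(p1@probabilities >= 0 & p1@probabilities <= 1))
  expect_identical(p1@labels, as.integer(p1@probabilities > 0.5))
  expect_equal(length(p1@labels) %% 2L, 1L)
  expect_identical(p1@voted, majorityVote(p1@labels))

  # single-class cohort
  co1 <- co; co1$records$label <- 1L
  expect_error(trainPipeline(co1, cfg, seed = 1), "single class")
  # shape mismatch names the offending subject
  co2 <- co
  co2$volumes[["sub004"]] <- Volume4D(array(0, c(tinyShape, 22)), tr = 2)
  expect_error(trainPipeline(co2, cfg, seed = 1), "sub004")
  # series-length mismatch at prediction time
  expect_error(classifySubject(m1, Volume4D(array(0, c(tinyShape, 10)), tr = 2)),
               "does not match")
})

test_that("the spatial-only variant trains and votes without a temporal encoder", {
  acq <- tinyAcq(t = 21L)
  co <- makeCohort(3, acq, tinySig(), noiseSpec(drift_amp = 0), seed = 60)
  cfg <- pipelineConfig(window = windowConfig(21, 6, 3),
                        spatial = spatialEncoderConfig(kernel_sizes = 3,
                                                       channels_per_kernel = 2,
                                                       d1 = 6),
                        gbdt = gbdtConfig(n_trees = 10),
                        train = trainConfig(epochs = 1, batch_size = 8),
                        variant = "spatial")
  m <- trainPipeline(co, cfg, seed = 4)
  expect_null(m@temporal)
  expect_equal(m@metadata$d2, 0L)
  pr <- classifySubject(m, co$volumes[[1]])
  expect_s4_class(pr, "WindowPredictions")
})

test_that("model serialization round-trips predictions", {
  acq <- tinyAcq(t = 21L)
  co <- makeCohort(2, acq, tinySig(), noiseSpec(drift_amp = 0), seed = 70)
  cfg <- pipelineConfig(window = windowConfig(21, 6, 3),
                        spatial = spatialEncoderConfig(kernel_sizes = 3,
                                                       channels_per_kernel = 2, d1 = 4),
                        temporal = temporalEncoderConfig(hidden_units = 4),
                        gbdt = gbdtConfig(n_trees = 10),
                        train = trainConfig(epochs = 0))
  m <- trainPipeline(co, cfg, seed = 2)
  d <- withr::local_tempdir()
  savePipelineModel(m, d)
  m2 <- loadPipelineModel(d)
  pr1 <- classifySubject(m, co$volumes[[1]])
  pr2 <- classifySubject(m2, co$volumes[[1]])
  expect_equal(pr1@probabilities, pr2@probabilities, tolerance = 1e-6)
  expect_identical(pr1@voted, pr2@voted)
})
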