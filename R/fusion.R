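#' GBDT and training configuration
#'
#' `gbdtConfig()` sets the gradient-boosted tree hyperparameters (fitted
#' with the binary cross-entropy / logistic loss); `trainConfig()` sets the
#' stage-1 encoder-training regime.
#'
#' @param n_trees boosting rounds (default 100).
#' @param max_depth tree depth (default 3).
#' @param learning_rate shrinkage (default 0.1).
#' @param seed integer seed for the booster.
#' @return a classed list of validated fields.
#' @export
gbdtConfig <- function(n_trees = 100L, max_depth = 3L, learning_rate = 0.1,
                       seed = 1L) {
  stopifnot(n_trees >= 1, max_depth >= 1, learning_rate > 0)
  structure(list(n_trees = as.integer(n_trees), max_depth = as.integer(max_depth),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "gbdtConfig")
}

#' @rdname gbdtConfig
#' @param lr Adam learning rate for stage-1 encoder training (default 0.001).
#' @param batch_size minibatch size in windows (default 32).
#' @param epochs stage-1 epochs (default 50; the toy profile uses 2).
#' @export
trainConfig <- function(lr = 0.001, batch_size = 32L, epochs = 50L) {
  stopifnot(lr > 0, batch_size >= 1, epochs >= 0)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs)),
            class = "trainConfig")
}

#' Pipeline configuration
#'
#' Bundles every stage's configuration. `variant = "spatial"` drops the
#' temporal pathway (3D-CNN + GBDT ablation); `weighted_vote = TRUE`
#' replaces the unweighted majority by a probability-weighted decision
#' (mean window probability > 0.5) -- off by default.
#'
#' @param window a [windowConfig()].
#' @param spatial a [spatialEncoderConfig()].
#' @param temporal a [temporalEncoderConfig()].
#' @param gbdt a [gbdtConfig()].
#' @param train a [trainConfig()].
#' @param variant `"full"` or `"spatial"`.
#' @param weighted_vote logical.
#' @return a classed list.
#' @export
pipelineConfig <- function(window = windowConfig(), spatial = spatialEncoderConfig(),
                           temporal = temporalEncoderConfig(), gbdt = gbdtConfig(),
                           train = trainConfig(), variant = c("full", "spatial"),
                           weighted_vote = FALSE) {
  variant <- match.arg(variant)
  structure(list(window = window, spatial = spatial, temporal = temporal,
                 gbdt = gbdt, train = train, variant = variant,
                 weighted_vote = weighted_vote),
            class = "pipelineConfig")
}

#' @rdname pipelineConfig
#' @param t series length of the cohort the profile will be applied to.
#' @export
toyPipelineConfig <- function(t = 50L, variant = "full") {
  pipelineConfig(window = windowConfig(t = t), spatial = toySpatialConfig(),
                 temporal = toyTemporalConfig(),
                 train = trainConfig(epochs = 2L), variant = variant)
}

#' Fuse temporal and spatial features per window
#'
#' Row `j` (1-based) concatenates the window's temporal feature with the
#' spatial feature of the window's first time point, i.e. 0-based spatial
#' index `(j - 1) * s`, giving width `d1 + d2`.
#'
#' @param tem k x d2 temporal feature matrix (rows aligned with `windows`).
#' @param sp t x d1 spatial feature matrix (row i = time point i).
#' @param windows a `"windowSet"` from [segmentWindows()].
#' @return k x (d2 + d1) matrix with attributes `window_index` and
#'   `spatial_index` (0-based) recording each row's provenance.
#' @export
fuseFeatures <- function(tem, sp, windows) {
  stopifnot(is(windows, "windowSet"), nrow(tem) == windows$k)
  sidx <- windows$starts          # 0-based first frame of each window
  if (max(sidx) + 1L > nrow(sp))
    stop("spatial feature matrix has too few rows for the window starts")
  fused <- cbind(tem, sp[sidx + 1L, , drop = FALSE])
  attr(fused, "window_index") <- seq_len(windows$k)
  attr(fused, "spatial_index") <- sidx
  fused
}

#' Majority vote over per-window labels
#'
#' Returns 1 iff the count of 1-votes strictly exceeds `k / 2`. The window
#' count must be odd (ties are then impossible); an even count indicates an
#' upstream windowing bug and is a hard error.
#'
#' @param labels binary vector of odd length.
#' @return 0 or 1.
#' @examples
#' majorityVote(c(1, 1, 0))  # 1
#' @export
majorityVote <- function(labels) {
  k <- length(labels)
  if (k %% 2L == 0L) stop("majority vote requires an odd number of windows")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  as.integer(sum(labels) > k / 2)
}

#' Train the window-level GBDT classifier
#'
#' Fits a gradient-boosted tree ensemble on pooled per-window fused feature
#' rows with the binary cross-entropy (logistic) loss. Deterministic given
#' the config seed (single-threaded).
#'
#' @param features numeric matrix, one row per training window.
#' @param labels binary vector of inherited subject labels, one per row.
#' @param cfg a [gbdtConfig()].
#' @return an `xgb.Booster`.
#' @export
trainWindowClassifier <- function(features, labels, cfg = gbdtConfig()) {
  stopifnot(nrow(features) == length(labels), !anyNA(features))
  if (length(unique(labels)) < 2L)
    stop("training set contains a single class")
  dtrain <- xgboost::xgb.DMatrix(features, label = as.numeric(labels))
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = cfg$max_depth,
                  eta = cfg$learning_rate, nthread = 1, seed = cfg$seed),
    data = dtrain, nrounds = cfg$n_trees, verbose = 0)
}

# Fused feature rows for one subject given trained encoders.
subjectFusedFeatures <- function(spatial, temporal, vol, windows, variant) {
  sidx <- windows$starts + 1L
  sp <- extractSpatialFeatures(spatial, vol, timepoints = sidx)
  # rows of `sp` are already aligned to window starts
  if (variant == "spatial") {
    fused <- sp
    attr(fused, "window_index") <- seq_len(windows$k)
    attr(fused, "spatial_index") <- windows$starts
    return(fused)
  }
  tem <- extractTemporalFeatures(temporal, vol, windows)
  fused <- cbind(tem, sp)
  attr(fused, "window_index") <- seq_len(windows$k)
  attr(fused, "spatial_index") <- windows$starts
  fused
}

#' Classify one subject
#'
#' Runs the full inference path: per-time-point spatial features, sliding
#' windows, per-window temporal features, fusion, per-window GBDT
#' probabilities and labels (1 iff p > 0.5), then the majority vote.
#' Label 1 denotes the case (ASD) class, 0 the control class.
#'
#' @param model a [PipelineModel-class].
#' @param vol a preprocessed [Volume4D-class] matching the model's expected
#'   spatial shape and series length.
#' @return a [WindowPredictions-class].
#' @export
classifySubject <- function(model, vol) {
  stopifnot(is(model, "PipelineModel"), is(vol, "Volume4D"))
  md <- model@metadata
  if (!identical(spatialDims(vol), model@spatial$in_shape))
    stop("volume spatial shape does not match the model")
  if (nTimepoints(vol) != model@window$t)
    stop("volume series length (", nTimepoints(vol), ") does not match the model (",
         model@window$t, ")")
  windows <- segmentWindows(model@window)
  fused <- subjectFusedFeatures(model@spatial, model@temporal, vol, windows,
                                md$variant)
  p <- predict(model@gbdt, xgboost::xgb.DMatrix(fused))
  labels <- as.integer(p > 0.5)
  voted <- if (isTRUE(md$weighted_vote)) as.integer(mean(p) > 0.5)
           else majorityVote(labels)
  new("WindowPredictions", labels = labels, probabilities = as.numeric(p),
      voted = voted, starts = windows$starts)
}

#' Train the full pipeline on a cohort
#'
#' Three stages. Stage 1 trains the spatial and temporal encoders jointly
#' with a temporary linear head on window-level binary cross-entropy
#' (every window inherits its subject's label; Adam, configurable learning
#' rate / batch size / epochs). Stage 2 freezes the encoders, extracts the
#' fused features of every training window and fits the GBDT. Stage 3
#' packages everything as a [PipelineModel-class]. Fully seeded.
#'
#' @param cohort list with `records` (data.frame incl. `subject_id`,
#'   `label`) and `volumes` (named list of preprocessed, QC-passed
#'   [Volume4D-class]), as produced by [loadCohort()] +
#'   [preprocessCohort()].
#' @param config a [pipelineConfig()]; the window config's `t` must match
#'   the volumes' series length.
#' @param seed integer master seed.
#' @return a [PipelineModel-class].
#' @export
trainPipeline <- function(cohort, config = toyPipelineConfig(), seed = 1L) {
  records <- cohort$records
  volumes <- cohort$volumes[records$subject_id]
  labels <- records$label
  if (length(unique(labels)) < 2L) stop("cohort contains a single class")
  if (min(table(labels)) < 2L) stop("need at least 2 subjects per class")

  in_shape <- spatialDims(volumes[[1]])
  for (i in seq_along(volumes)) {
    v <- volumes[[i]]
    if (!identical(spatialDims(v), in_shape) || nTimepoints(v) != config$window$t)
      stop("subject ", records$subject_id[i], " fails the shape check")
  }
  windows <- segmentWindows(config$window)
  V <- prod(in_shape)
  Xmats <- lapply(volumes, voxelMatrix)

  spatial <- buildSpatialEncoder(config$spatial, in_shape, seed = deriveSeed(seed, 1))
  temporal <- if (config$variant == "full")
    buildTemporalEncoder(config$temporal, V, seed = deriveSeed(seed, 2))
  d1 <- config$spatial$d1
  d2 <- if (config$variant == "full") config$temporal$d2 else 0L

  withSeed(deriveSeed(seed, 3), {
    head_par <- list(w = rnorm(d1 + d2, sd = 0.1), b = 0)
    params <- list(spatial = spatial$params, head = head_par)
    if (config$variant == "full") params$temporal <- temporal$params
    opt <- adamInit(params)

    # window sample table: (subject index, 0-based start)
    ns <- length(Xmats)
    samp_subj <- rep(seq_len(ns), each = windows$k)
    samp_start <- rep(windows$starts, times = ns)
    samp_y <- labels[samp_subj]
    n_samp <- length(samp_subj)
    bs <- config$train$batch_size

    for (epoch in seq_len(config$train$epochs)) {
      ord <- sample.int(n_samp)
      for (ofs in seq(1L, n_samp, by = bs)) {
        idx <- ord[ofs:min(ofs + bs - 1L, n_samp)]
        B <- length(idx)
        sb <- samp_subj[idx]; st <- samp_start[idx]; y <- samp_y[idx]

        fws <- vector("list", B)
        Fsp <- matrix(0, B, d1)
        for (b in seq_len(B)) {
          fws[[b]] <- cnnForward(spatial, Xmats[[sb[b]]][, st[b] + 1L], cache = TRUE)
          Fsp[b, ] <- fws[[b]]$f
        }
        if (config$variant == "full") {
          steps <- windowSteps(Xmats, sb, st, windows$w)
          lf <- lstmForward(temporal, steps, cache = TRUE)
          fused <- cbind(lf$h, Fsp)
        } else fused <- Fsp

        logits <- drop(fused %*% params$head$w) + params$head$b
        prob <- sigmoid(logits)
        dlogit <- (prob - y) / B
        grads <- list(
          spatial = NULL,
          head = list(w = drop(crossprod(fused, dlogit)), b = sum(dlogit)))
        dfused <- outer(dlogit, params$head$w)
        if (config$variant == "full") {
          grads$temporal <- lstmBackward(temporal, lf$caches,
                                         dfused[, seq_len(d2), drop = FALSE])
          dFsp <- dfused[, d2 + seq_len(d1), drop = FALSE]
        } else dFsp <- dfused

        gs <- NULL
        for (b in seq_len(B)) {
          gb <- cnnBackward(spatial, fws[[b]], dFsp[b, ])
          gs <- if (is.null(gs)) gb else mapTrees(gs, gb, `+`)
        }
        grads$spatial <- gs

        upd <- adamStep(params, grads, opt, lr = config$train$lr)
        params <- upd$params; opt <- upd$state
        spatial$params <- params$spatial
        if (config$variant == "full") temporal$params <- params$temporal
      }
    }
  })

  # Stage 2: frozen-encoder fused features, GBDT fit
  feats <- vector("list", length(Xmats))
  for (i in seq_along(volumes))
    feats[[i]] <- subjectFusedFeatures(spatial, temporal, volumes[[i]], windows,
                                       config$variant)
  all_feats <- do.call(rbind, feats)
  all_labels <- rep(labels, each = windows$k)
  gcfg <- config$gbdt
  gcfg$seed <- deriveSeed(seed, 4)
  gbdt <- trainWindowClassifier(all_feats, all_labels, gcfg)

  new("PipelineModel", spatial = spatial,
      temporal = if (config$variant == "full") temporal else NULL,
      gbdt = gbdt,
      window = config$window,
      metadata = list(variant = config$variant, seed = seed,
                      d1 = d1, d2 = d2, k = windows$k,
                      epochs = config$train$epochs, lr = config$train$lr,
                      batch_size = config$train$batch_size,
                      weighted_vote = config$weighted_vote,
                      in_shape = in_shape))
}
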