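#' Volume4D: a 4D fMRI volume series
#'
#' Container for an X-by-Y-by-Z-by-T grid of voxel intensities with its
#' repetition time (TR, seconds between consecutive volumes) and an optional
#' boolean brain mask over the spatial grid.
#'
#' @slot data numeric 4D array (X, Y, Z, T), finite values.
#' @slot tr repetition time in seconds, positive scalar.
#' @slot mask logical 3D array matching the spatial grid, or `NULL`.
#' @export
setClass("Volume4D", representation(data = "array", tr = "numeric", mask = "ANY"),
         prototype(mask = NULL))

setValidity("Volume4D", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L) return("data must be a 4D array")
  if (!all(is.finite(object@data))) return("data must be finite")
  if (length(object@tr) != 1L || !is.finite(object@tr) || object@tr <= 0)
    return("tr must be a positive scalar")
  if (!is.null(object@mask)) {
    if (!is.logical(object@mask) || !identical(dim(object@mask), d[1:3]))
      return("mask must be a logical array matching the spatial grid")
  }
  TRUE
})

#' WindowPredictions: per-window decisions and the voted subject label
#'
#' Holds per-window GBDT probabilities `p_j`, the thresholded window labels
#' (1 iff `p_j > 0.5`), and the majority-voted subject label (1 = case,
#' 0 = control).
#'
#' @slot labels integer vector of per-window labels in {0, 1}, odd length.
#' @slot probabilities numeric vector in \[0, 1\], same length as `labels`.
#' @slot voted integer scalar in {0, 1}.
#' @slot starts integer vector of 0-based window start indices.
#' @export
setClass("WindowPredictions",
         representation(labels = "integer", probabilities = "numeric",
                        voted = "integer", starts = "integer"))

setValidity("WindowPredictions", function(object) {
  k <- length(object@labels)
  if (k %% 2L == 0L) return("window count must be odd")
  if (length(object@probabilities) != k) return("probabilities/labels length mismatch")
  if (!all(object@labels %in% c(0L, 1L))) return("labels must be binary")
  if (any(object@probabilities < 0 | object@probabilities > 1))
    return("probabilities must lie in [0, 1]")
  if (!identical(object@labels, as.integer(object@probabilities > 0.5)))
    return("labels must equal probabilities > 0.5")
  if (!object@voted %in% c(0L, 1L)) return("voted label must be binary")
  TRUE
})

#' PipelineModel: the trained spatial + temporal + GBDT classifier
#'
#' Bundles the trained spatial convolutional encoder, the temporal LSTM
#' encoder, the fitted gradient-boosted tree classifier, the window
#' configuration and the training metadata (seeds, epochs, dimensions).
#'
#' @slot spatial trained spatial encoder (see [buildSpatialEncoder()]).
#' @slot temporal trained temporal encoder, or `NULL` for the spatial-only
#'   ablation variant.
#' @slot gbdt fitted `xgb.Booster`.
#' @slot window window configuration (see [windowConfig()]).
#' @slot metadata list of training metadata (variant, seed, d1, d2, k, epochs).
#' @export
setClass("PipelineModel",
         representation(spatial = "ANY", temporal = "ANY", gbdt = "ANY",
                        window = "ANY", metadata = "list"))

setValidity("PipelineModel", function(object) {
  md <- object@metadata
  if (is.null(md$variant) || !md$variant %in% c("full", "spatial"))
    return("metadata$variant must be 'full' or 'spatial'")
  if (md$variant == "full" && is.null(object@temporal))
    return("full variant requires a temporal encoder")
  TRUE
})
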