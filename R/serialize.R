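#' Save / load a trained pipeline model
#'
#' A model is serialized as a directory: `encoders.rds` (spatial and
#' temporal encoder configs and weights), `gbdt.json` (the booster, in
#' xgboost's portable JSON format) and `metadata.json` (variant, seeds,
#' dimensions, window configuration).
#'
#' @param model a [PipelineModel-class].
#' @param dir model directory.
#' @return `loadPipelineModel()` returns a [PipelineModel-class];
#'   `savePipelineModel()` returns `dir` invisibly.
#' @export
savePipelineModel <- function(model, dir) {
  stopifnot(is(model, "PipelineModel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(list(spatial = model@spatial, temporal = model@temporal,
               window = model@window),
          file.path(dir, "encoders.rds"))
  xgboost::xgb.save(model@gbdt, file.path(dir, "gbdt.json"))
  jsonlite::write_json(model@metadata, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname savePipelineModel
#' @export
loadPipelineModel <- function(dir) {
  enc <- readRDS(file.path(dir, "encoders.rds"))
  md <- jsonlite::read_json(file.path(dir, "metadata.json"), simplifyVector = TRUE)
  md$in_shape <- as.integer(md$in_shape)
  new("PipelineModel", spatial = enc$spatial, temporal = enc$temporal,
      gbdt = xgboost::xgb.load(file.path(dir, "gbdt.json")),
      window = enc$window, metadata = md)
}

setMethod("show", "PipelineModel", function(object) {
  md <- object@metadata
  cat(sprintf("PipelineModel (%s): d1 = %d, d2 = %d, k = %d windows, seed %d\n",
              md$variant, md$d1, md$d2, md$k, md$seed))
  cat(sprintf("  input: %s voxels, t = %d, w = %d, s = %d\n",
              paste(md$in_shape, collapse = "x"), object@window$t,
              object@window$w, object@window$s))
  invisible(object)
})

setMethod("show", "WindowPredictions", function(object) {
  cat(sprintf("WindowPredictions: %d windows, %d votes for class 1 -> label %d\n",
              length(object@labels), sum(object@labels), object@voted))
  invisible(object)
})

#' Export per-window features as TSV
#'
#' @param features a feature matrix (spatial t x d1 or temporal k x d2 with
#'   a `starts` attribute).
#' @param path output TSV path.
#' @export
writeFeatureTSV <- function(features, path) {
  df <- as.data.frame(features)
  names(df) <- paste0("f", seq_len(ncol(features)))
  st <- attr(features, "starts")
  if (!is.null(st)) df <- cbind(start = st, df)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
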