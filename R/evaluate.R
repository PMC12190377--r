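#' Contingency-table classification metrics
#'
#' Computes accuracy, precision, recall (sensitivity), F1 and specificity
#' from true/false positive/negative counts. A metric whose denominator is
#' zero is returned as `NA` and flagged in `undefined` rather than coerced
#' to 0, so that small-fold averages are not silently biased.
#'
#' @param tp,tn,fp,fn non-negative integer counts; their total must be > 0.
#' @return a `"classMetrics"` list with the four counts, the five metrics,
#'   and an `undefined` logical vector.
#' @examples
#' m <- contingencyMetrics(3, 4, 1, 2)
#' m$accuracy   # 0.7
#' @export
contingencyMetrics <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  n <- tp + tn + fp + fn
  if (n == 0) stop("all contingency counts are zero")
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- rat(tp, tp + fp)
  recall <- rat(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  out <- list(tp = tp, tn = tn, fp = fp, fn = fn,
              accuracy = (tp + tn) / n,
              precision = precision, recall = recall, f1 = f1,
              specificity = rat(tn, tn + fp))
  out$undefined <- vapply(out[c("accuracy", "precision", "recall", "f1",
                                "specificity")], is.na, logical(1))
  structure(out, class = "classMetrics")
}

#' Subject-level k-fold assignment
#'
#' Partitions subjects into K folds that are disjoint, covering, and
#' size-balanced (sizes differ by at most 1). With `stratified = TRUE` (the
#' default) per-fold class counts deviate from proportionality by at most 1.
#' Deterministic given `seed`.
#'
#' @param records subject-record data.frame with `subject_id` and `label`.
#' @param K number of folds, `2 <= K <= nrow(records)`.
#' @param stratified balance class counts across folds.
#' @param seed integer seed.
#' @return integer vector of 0-based fold indices named by subject id, with
#'   attributes `K`, `stratified`, `seed`.
#' @export
kfoldSplit <- function(records, K, stratified = TRUE, seed = 1L) {
  n <- nrow(records)
  if (K < 2L) stop("K must be at least 2")
  if (K > n) stop("K exceeds the number of subjects")
  fold <- integer(n)
  withSeed(seed, {
    if (stratified) {
      offset <- 0L
      for (cl in sort(unique(records$label))) {
        ix <- which(records$label == cl)
        ix <- ix[sample.int(length(ix))]
        fold[ix] <- (offset + seq_along(ix) - 1L) %% K
        offset <- offset + length(ix)
      }
    } else {
      fold[sample.int(n)] <- (seq_len(n) - 1L) %% K
    }
  })
  structure(stats::setNames(fold, records$subject_id),
            K = K, stratified = stratified, seed = seed)
}

metricNames <- c("accuracy", "precision", "recall", "f1", "specificity")

#' Cross-validated pipeline evaluation
#'
#' Runs subject-level K-fold cross-validation: for each fold the pipeline
#' is trained on the training subjects and every held-out subject is
#' classified; subject-level contingency counts accumulate into per-fold
#' metrics, reported with their mean and a t-distribution 95% half-width
#' confidence interval across folds (undefined per-fold metrics are
#' excluded from the average). All windows of a subject stay on one side of
#' every split.
#'
#' @param cohort list with `records` and `volumes` (preprocessed).
#' @param config a [pipelineConfig()].
#' @param K number of folds (the study profile uses 5 or 10).
#' @param seed integer master seed (fold assignment and per-fold training).
#' @param stratified stratify folds by class (default `TRUE`).
#' @param per_site also aggregate subject-level counts per site.
#' @param trainer training function `(cohort, config, seed) -> model`;
#'   defaults to [trainPipeline()]. Replaceable by stubs for testing.
#' @param classifier prediction function `(model, vol, record) -> 0/1`;
#'   defaults to the voted label of [classifySubject()].
#' @return an `"evaluationReport"` list: `folds` (per-fold data.frame),
#'   `mean`, `ci`, `per_site`, `predictions`, `metadata`.
#' @export
crossValidate <- function(cohort, config = toyPipelineConfig(), K = 5L, seed = 1L,
                          stratified = TRUE, per_site = TRUE,
                          trainer = NULL, classifier = NULL) {
  if (is.null(trainer)) trainer <- function(co, cfg, s) trainPipeline(co, cfg, s)
  if (is.null(classifier))
    classifier <- function(model, vol, record) classifySubject(model, vol)@voted
  records <- cohort$records
  fold <- kfoldSplit(records, K, stratified = stratified, seed = seed)
  folds_df <- NULL
  preds <- data.frame(subject_id = records$subject_id, site = records$site,
                      label = records$label, fold = unname(fold),
                      predicted = NA_integer_, stringsAsFactors = FALSE)
  for (f in 0:(K - 1L)) {
    tr_ix <- which(fold != f); te_ix <- which(fold == f)
    tr_rec <- records[tr_ix, , drop = FALSE]
    if (length(unique(tr_rec$label)) < 2L)
      stop("fold ", f, " leaves a single-class training set; use stratification")
    tr_cohort <- list(records = tr_rec,
                      volumes = cohort$volumes[tr_rec$subject_id])
    model <- trainer(tr_cohort, config, deriveSeed(seed, 100L + f))
    for (i in te_ix)
      preds$predicted[i] <- classifier(model, cohort$volumes[[records$subject_id[i]]],
                                       records[i, , drop = FALSE])
    y <- records$label[te_ix]; yhat <- preds$predicted[te_ix]
    m <- contingencyMetrics(sum(yhat == 1 & y == 1), sum(yhat == 0 & y == 0),
                            sum(yhat == 1 & y == 0), sum(yhat == 0 & y == 1))
    folds_df <- rbind(folds_df,
                      data.frame(fold = f, tp = m$tp, tn = m$tn, fp = m$fp,
                                 fn = m$fn,
                                 as.data.frame(m[metricNames])))
  }
  means <- vapply(metricNames, function(nm) mean(folds_df[[nm]], na.rm = TRUE),
                  numeric(1))
  cis <- vapply(metricNames, function(nm) {
    v <- folds_df[[nm]][!is.na(folds_df[[nm]])]
    if (length(v) < 2L) return(NA_real_)
    stats::qt(0.975, length(v) - 1L) * stats::sd(v) / sqrt(length(v))
  }, numeric(1))
  site_df <- NULL
  if (per_site) {
    for (s in unique(records$site)) {
      ix <- which(records$site == s)
      y <- records$label[ix]; yhat <- preds$predicted[ix]
      m <- contingencyMetrics(sum(yhat == 1 & y == 1), sum(yhat == 0 & y == 0),
                              sum(yhat == 1 & y == 0), sum(yhat == 0 & y == 1))
      site_df <- rbind(site_df, data.frame(site = s, n = length(ix),
                                           as.data.frame(m[metricNames])))
    }
  }
  cfg_plain <- rapply(unclass(config), identity, how = "replace")
  structure(list(folds = folds_df, mean = as.list(means), ci = as.list(cis),
                 per_site = site_df, predictions = preds,
                 metadata = list(K = K, seed = seed, stratified = stratified,
                                 n_subjects = nrow(records),
                                 config_hash = contentHash(cfg_plain))),
            class = "evaluationReport")
}

#' Write an evaluation report to a directory
#'
#' Emits `report.json` (full report), `folds.tsv`, `per_site.tsv` (when
#' present) and `manifest.json` (seed, fold count and the config hash --
#' the reproducibility manifest). Output is byte-stable for identical runs.
#'
#' @param report an `"evaluationReport"` from [crossValidate()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeEvaluationReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(mean = report$mean, ci = report$ci, folds = report$folds,
         per_site = report$per_site, predictions = report$predictions,
         metadata = report$metadata),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.table(report$folds, file.path(dir, "folds.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(report$per_site))
    utils::write.table(report$per_site, file.path(dir, "per_site.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  jsonlite::write_json(report$metadata, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' t-SNE embedding of feature rows
#'
#' Exact (O(n^2)) t-distributed stochastic neighbour embedding to 2
#' dimensions: Gaussian input affinities calibrated to the target
#' perplexity by per-point binary search, Student-t output kernel, gradient
#' descent with momentum and early exaggeration. Deterministic given
#' `seed`. Optionally writes a scatter plot coloured by label.
#'
#' @param features numeric n x d matrix, `n >= 5`, `d >= 2`.
#' @param labels vector of class labels for colouring (optional).
#' @param seed integer seed for the embedding initialization.
#' @param perplexity target perplexity (default `min(30, (n - 1) / 3)`).
#' @param max_iter gradient iterations (default 400).
#' @param plot_file optional path of a PNG to write.
#' @return n x 2 matrix of embedding coordinates.
#' @export
tsneEmbed <- function(features, labels = NULL, seed = 1L, perplexity = NULL,
                      max_iter = 400L, plot_file = NULL) {
  n <- nrow(features)
  if (n < 5L) stop("t-SNE needs at least 5 rows")
  if (ncol(features) < 2L) stop("t-SNE needs at least 2 feature columns")
  if (is.null(perplexity)) perplexity <- min(30, (n - 1) / 3)
  D2 <- as.matrix(stats::dist(features))^2
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { H <- 0 } else {
        pr <- w / sw
        H <- -sum(pr[pr > 0] * log(pr[pr > 0]))
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- w / max(sum(w), .Machine$double.eps)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  Y <- withSeed(seed, matrix(rnorm(n * 2, sd = 1e-4), n, 2))
  gain <- matrix(1, n, 2); inc <- matrix(0, n, 2)
  eta <- 100
  for (it in seq_len(max_iter)) {
    Pe <- if (it <= 100) P * 4 else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    mom <- if (it <= 250) 0.5 else 0.8
    gain <- pmax(0.01, ifelse(sign(grad) == sign(inc), gain * 0.8, gain + 0.2))
    inc <- mom * inc - eta * gain * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  if (!is.null(plot_file)) {
    grDevices::png(plot_file, width = 700, height = 600)
    cols <- if (is.null(labels)) "black" else as.integer(factor(labels)) + 1L
    graphics::plot(Y, col = cols, pch = 19, xlab = "t-SNE 1", ylab = "t-SNE 2",
                   main = "t-SNE embedding of fused features")
    if (!is.null(labels))
      graphics::legend("topright", legend = levels(factor(labels)),
                       col = seq_along(levels(factor(labels))) + 1L, pch = 19)
    grDevices::dev.off()
  }
  Y
}
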