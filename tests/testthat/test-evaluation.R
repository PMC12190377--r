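directMetrics <- function(tp, tn, fp, fn) {
  # independent, literal formula evaluation (NaN when a denominator is 0)
  p <- tp / (tp + fp); r <- tp / (tp + fn)
  list(accuracy = (tp + tn) / (tp + tn + fp + fn), precision = p, recall = r,
       f1 = 2 * p * r / (p + r), specificity = tn / (tn + fp))
}

test_that("contingency metrics match the worked case and flag degeneracies", {
  m <- contingencyMetrics(2, 2, 0, 0)
  expect_equal(unlist(m[c("accuracy", "precision", "recall", "f1", "specificity")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1, specificity = 1))

  m <- contingencyMetrics(3, 4, 1, 2)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / 1.35)
  expect_equal(m$specificity, 0.8)
  expect_false(any(m$undefined))

  m <- contingencyMetrics(0, 5, 0, 5)
  expect_true(is.na(m$precision) && m$undefined["precision"])
  expect_equal(m$recall, 0)
  expect_equal(m$specificity, 1)

  expect_error(contingencyMetrics(0, 0, 0, 0), "zero")
})

test_that("metric identities and F1 harmonic-mean bounds hold on a count grid", {
  for (tp in 0:4) for (tn in 0:4) for (fp in 0:4) for (fn in 0:4) {
    if (tp + tn + fp + fn == 0) next
    m <- contingencyMetrics(tp, tn, fp, fn)
    d <- directMetrics(tp, tn, fp, fn)
    for (nm in names(d)) {
      if (is.na(m[[nm]])) expect_true(is.nan(d[[nm]]) || is.na(d[[nm]]))
      else expect_equal(m[[nm]], d[[nm]])
    }
    p <- m$precision; r <- m$recall; f1 <- m$f1
    if (!is.na(p) && !is.na(r) && !is.na(f1)) {
      expect_gte(f1, min(p, r) - 1e-12)
      expect_lte(f1, (p + r) / 2 + 1e-12)
      if (abs(p - r) > 1e-12) expect_lt(f1, (p + r) / 2)
    }
  }
})

test_that("k-fold splits are disjoint, covering, balanced and stratified", {
  rec <- data.frame(subject_id = sprintf("s%02d", 1:10),
                    label = rep(c(0, 1), 5), stringsAsFactors = FALSE)
  f <- kfoldSplit(rec, 5, seed = 1)
  expect_equal(as.integer(table(f)), rep(2L, 5))
  expect_setequal(names(f), rec$subject_id)

  rec2 <- data.frame(subject_id = sprintf("s%02d", 1:40),
                     label = rep(c(0, 1), each = 20), stringsAsFactors = FALSE)
  f2 <- kfoldSplit(rec2, 5, stratified = TRUE, seed = 2)
  for (k in 0:4)
    expect_equal(as.integer(table(rec2$label[f2 == k])), c(4L, 4L))

  expect_identical(kfoldSplit(rec2, 5, seed = 7), kfoldSplit(rec2, 5, seed = 7))
  expect_false(identical(kfoldSplit(rec2, 5, seed = 7), kfoldSplit(rec2, 5, seed = 8)))
  expect_error(kfoldSplit(rec, 11), "exceeds")

  for (seed in 1:100) {
    n <- 7 + (seed %% 13)
    rec3 <- data.frame(subject_id = as.character(seq_len(n)),
                       label = rep_len(c(0, 1), n))
    K <- 2 + (seed %% 4)
    fs <- kfoldSplit(rec3, K, stratified = (seed %% 2 == 0), seed = seed)
    expect_length(fs, n)                                   # covering
    expect_true(all(fs %in% 0:(K - 1)))
    expect_lte(diff(range(table(factor(fs, levels = 0:(K - 1))))), 1)  # balanced
  }
})

test_that("cross-validation with oracle and constant stubs yields the induced metrics", {
  n <- 20
  rec <- data.frame(subject_id = sprintf("s%02d", 1:n),
                    site = rep(c("A", "B"), n / 2),
                    label = rep(c(0, 1), n / 2), stringsAsFactors = FALSE)
  cohort <- list(records = rec,
                 volumes = stats::setNames(vector("list", n), rec$subject_id))

  oracle <- crossValidate(cohort, K = 5, seed = 1,
                          trainer = function(co, cfg, s) NULL,
                          classifier = function(model, vol, record) record$label)
  for (nm in c("accuracy", "precision", "recall", "f1", "specificity"))
    expect_equal(oracle$mean[[nm]], 1)

  zeros <- crossValidate(cohort, K = 5, seed = 1,
                         trainer = function(co, cfg, s) NULL,
                         classifier = function(model, vol, record) 0L)
  expect_equal(zeros$mean$accuracy, 0.5)
  expect_equal(zeros$mean$recall, 0)
  expect_equal(zeros$mean$specificity, 1)
  # precision is undefined in every fold (no positive predictions)
  expect_true(all(is.na(zeros$folds$precision)))

  # reported means equal the arithmetic mean of per-fold values
  expect_equal(zeros$mean$accuracy, mean(zeros$folds$accuracy))
  # per-site table covers both sites
  expect_setequal(zeros$per_site$site, c("A", "B"))
})

test_that("no subject appears on both sides of any fold (id tracking)", {
  n <- 12
  rec <- data.frame(subject_id = sprintf("s%02d", 1:n), site = "A",
                    label = rep(c(0, 1), n / 2), stringsAsFactors = FALSE)
  cohort <- list(records = rec,
                 volumes = stats::setNames(vector("list", n), rec$subject_id))
  seen <- list()
  crossValidate(cohort, K = 4, seed = 3,
                trainer = function(co, cfg, s) {
                  seen[[length(seen) + 1]] <<- co$records$subject_id
                  NULL
                },
                classifier = function(model, vol, record) {
                  train_ids <- seen[[length(seen)]]
                  expect_false(record$subject_id %in% train_ids)
                  record$label
                })
  expect_length(seen, 4)
})

test_that("t-SNE embeds seeded, with separable clusters staying separable", {
  set.seed(9)
  X <- rbind(matrix(rnorm(30 * 6), 30, 6), matrix(rnorm(30 * 6, mean = 10), 30, 6))
  lab <- rep(c(0, 1), each = 30)
  Y1 <- tsneEmbed(X, lab, seed = 4)
  expect_identical(dim(Y1), c(60L, 2L))
  Y2 <- tsneEmbed(X, lab, seed = 4)
  expect_identical(Y1, Y2)

  skip_if_not_installed("cluster")
  sil <- cluster::silhouette(lab + 1L, stats::dist(Y1))
  expect_gt(mean(sil[, "sil_width"]), 0.5)

  f <- tempfile(fileext = ".png")
  tsneEmbed(X, lab, seed = 4, max_iter = 50, plot_file = f)
  expect_true(file.exists(f) && file.size(f) > 0)

  expect_error(tsneEmbed(X[1:3, ], seed = 1), "at least 5")
  expect_error(tsneEmbed(X[, 1, drop = FALSE], seed = 1), "at least 2")
})

test_that("evaluation reports are written completely and reproducibly", {
  n <- 10
  rec <- data.frame(subject_id = sprintf("s%02d", 1:n), site = "A",
                    label = rep(c(0, 1), n / 2), stringsAsFactors = FALSE)
  cohort <- list(records = rec,
                 volumes = stats::setNames(vector("list", n), rec$subject_id))
  rep1 <- crossValidate(cohort, K = 5, seed = 2,
                        trainer = function(co, cfg, s) NULL,
                        classifier = function(model, vol, record) record$label)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeEvaluationReport(rep1, d1)
  writeEvaluationReport(rep1, d2)
  for (f in c("report.json", "folds.tsv", "manifest.json")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})
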