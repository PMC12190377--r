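# Internal numeric and seeding helpers.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Stable per-subject seed derivation from a master seed and a subject index.
# Kept below 2^31 and exact in double arithmetic.
deriveSeed <- function(master, index) {
  as.integer(((master %% 100000) * 69069 + index * 1013904223) %% 2147483647)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# --- parameter trees -------------------------------------------------------
# Model parameters are nested lists whose leaves are numeric arrays. The
# helpers below walk matching trees, powering the Adam optimizer updates.

mapTrees <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- mapTrees(a[[i]], b[[i]], f)
    out
  } else f(a, b)
}

zeroLike <- function(a) {
  if (is.list(a)) lapply(a, zeroLike) else a * 0
}

adamInit <- function(params) list(m = zeroLike(params), v = zeroLike(params), t = 0L)

adamStep <- function(params, grads, state, lr = 1e-3,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- mapTrees(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- mapTrees(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g * g)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mv <- mapTrees(state$m, state$v, function(m, v) (m / bc1) / (sqrt(v / bc2) + eps))
  params <- mapTrees(params, mv, function(p, s) p - lr * s)
  list(params = params, state = state)
}

# Short content hash for reproducibility manifests (md5 of a serialized file).
contentHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE), f)
  unname(tools::md5sum(f))
}
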