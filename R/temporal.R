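#' Sliding-window configuration and segmentation
#'
#' `windowConfig()` describes the sliding-window segmentation of a length-`t`
#' series into windows of length `w` advanced by stride `s`. The raw window
#' count is the closed form `k = floor((t - w) / s) + 1`; when
#' `enforce_odd_k` is set (the default) and `k` comes out even, the last
#' window is dropped so the downstream majority vote cannot tie. With the
#' default full-profile values (t = 50, w = 10, s = 1) k = 41, already odd.
#'
#' @param t series length in time points.
#' @param w window length, `1 <= w <= t`.
#' @param s stride, >= 1.
#' @param enforce_odd_k drop the final window when the count is even.
#' @return a classed list of validated fields.
#' @export
windowConfig <- function(t = 50L, w = 10L, s = 1L, enforce_odd_k = TRUE) {
  t <- as.integer(t); w <- as.integer(w); s <- as.integer(s)
  stopifnot(w >= 1L, s >= 1L, t >= 1L)
  if (w > t) stop("window length w exceeds series length t")
  structure(list(t = t, w = w, s = s, enforce_odd_k = enforce_odd_k),
            class = "windowConfig")
}

#' @rdname windowConfig
#' @param cfg a `windowConfig`.
#' @return `segmentWindows()` returns a `"windowSet"` list with 0-based
#'   `starts`, the window length `w`, stride `s`, series length `t` and the
#'   (odd-enforced) count `k`.
#' @examples
#' segmentWindows(windowConfig(50, 10, 1))$k   # 41
#' @export
segmentWindows <- function(cfg) {
  stopifnot(is(cfg, "windowConfig"))
  k <- (cfg$t - cfg$w) %/% cfg$s + 1L
  starts <- (seq_len(k) - 1L) * cfg$s
  if (cfg$enforce_odd_k && k %% 2L == 0L) {
    k <- k - 1L
    starts <- starts[seq_len(k)]
  }
  structure(list(starts = starts, w = cfg$w, s = cfg$s, t = cfg$t, k = k),
            class = "windowSet")
}

#' Temporal encoder configuration
#'
#' Configures the LSTM that maps each window's frame sequence to a temporal
#' feature vector: the final hidden state, of dimension `d2 = hidden_units`.
#' At full scale the raw voxel vector per time step is infeasible as LSTM
#' input, so an optional learned linear projection to
#' `input_projection_dim` can be inserted before the recurrence (trained
#' jointly); the toy profile feeds the small volume's raw flatten directly.
#'
#' @param hidden_units LSTM hidden state size (default 500; toy 32).
#' @param d2 output feature dimension; fixed at `hidden_units`.
#' @param input_projection_dim optional integer; `NULL` feeds raw voxel
#'   vectors.
#' @return a classed list of validated fields.
#' @export
temporalEncoderConfig <- function(hidden_units = 500L, d2 = hidden_units,
                                  input_projection_dim = NULL) {
  hidden_units <- as.integer(hidden_units)
  stopifnot(hidden_units >= 1L, d2 == hidden_units)
  if (!is.null(input_projection_dim))
    stopifnot(input_projection_dim >= 1L)
  structure(list(hidden_units = hidden_units, d2 = hidden_units,
                 input_projection_dim = input_projection_dim),
            class = "temporalEncoderConfig")
}

#' @rdname temporalEncoderConfig
#' @export
toyTemporalConfig <- function() temporalEncoderConfig(hidden_units = 32L)

#' Build the temporal encoder
#'
#' Initializes LSTM parameters (gate order input / forget / cell / output;
#' uniform init scaled by fan-in, forget-gate bias 1) and, if configured,
#' the input projection. Deterministic given `seed`.
#'
#' @param cfg a [temporalEncoderConfig()].
#' @param input_dim voxel-vector length V of the volumes to encode.
#' @param seed integer seed.
#' @return a `"temporalEncoder"` list with `cfg`, `input_dim` and `params`
#'   (`Wx`, `Wh`, `b`, optionally `proj$W`).
#' @export
buildTemporalEncoder <- function(cfg, input_dim, seed) {
  stopifnot(is(cfg, "temporalEncoderConfig"), input_dim >= 1)
  H <- cfg$hidden_units
  p <- cfg$input_projection_dim
  xdim <- if (is.null(p)) input_dim else p
  withSeed(seed, {
    params <- list(
      Wx = matrix(runif(xdim * 4 * H, -1, 1) / sqrt(xdim), xdim, 4 * H),
      Wh = matrix(runif(H * 4 * H, -1, 1) / sqrt(H), H, 4 * H),
      b = c(numeric(H), rep(1, H), numeric(2 * H))  # forget bias 1
    )
    if (!is.null(p))
      params$proj <- list(W = matrix(runif(input_dim * p, -1, 1) / sqrt(input_dim),
                                     input_dim, p))
    structure(list(cfg = cfg, input_dim = input_dim, params = params),
              class = "temporalEncoder")
  })
}

# Batched LSTM forward over a list of per-step B x V matrices. Returns the
# final hidden state (B x H) and, when cache = TRUE, the per-step state
# needed by backpropagation through time.
lstmForward <- function(enc, steps, cache = FALSE) {
  pr <- enc$params
  H <- enc$cfg$hidden_units
  B <- nrow(steps[[1]])
  h <- matrix(0, B, H); cst <- matrix(0, B, H)
  caches <- if (cache) vector("list", length(steps))
  ii <- 1:H; ff <- (H + 1):(2 * H); gg <- (2 * H + 1):(3 * H); oo <- (3 * H + 1):(4 * H)
  for (s in seq_along(steps)) {
    x <- steps[[s]]
    xp <- if (is.null(pr$proj)) x else x %*% pr$proj$W
    G <- xp %*% pr$Wx + h %*% pr$Wh
    G <- sweep(G, 2, pr$b, "+")
    i <- sigmoid(G[, ii, drop = FALSE]); f <- sigmoid(G[, ff, drop = FALSE])
    g <- tanh(G[, gg, drop = FALSE]);    o <- sigmoid(G[, oo, drop = FALSE])
    c_prev <- cst
    cst <- f * c_prev + i * g
    tc <- tanh(cst)
    h_prev <- h
    h <- o * tc
    if (cache)
      caches[[s]] <- list(x = if (is.null(pr$proj)) NULL else x, xp = xp,
                          i = i, f = f, g = g, o = o,
                          c_prev = c_prev, tc = tc, h_prev = h_prev)
  }
  if (cache) list(h = h, caches = caches) else h
}

# BPTT given the gradient of the loss w.r.t. the final hidden state.
lstmBackward <- function(enc, caches, dH) {
  pr <- enc$params
  H <- enc$cfg$hidden_units
  g <- list(Wx = pr$Wx * 0, Wh = pr$Wh * 0, b = pr$b * 0)
  if (!is.null(pr$proj)) g$proj <- list(W = pr$proj$W * 0)
  dh <- dH; dc <- dH * 0
  for (s in rev(seq_along(caches))) {
    ca <- caches[[s]]
    do <- dh * ca$tc * ca$o * (1 - ca$o)
    dc <- dc + dh * ca$o * (1 - ca$tc^2)
    di <- dc * ca$g * ca$i * (1 - ca$i)
    df <- dc * ca$c_prev * ca$f * (1 - ca$f)
    dg <- dc * ca$i * (1 - ca$g^2)
    dG <- cbind(di, df, dg, do)
    g$Wx <- g$Wx + crossprod(ca$xp, dG)
    g$Wh <- g$Wh + crossprod(ca$h_prev, dG)
    g$b <- g$b + colSums(dG)
    if (!is.null(pr$proj))
      g$proj$W <- g$proj$W + crossprod(ca$x, dG %*% t(pr$Wx))
    dh <- dG %*% t(pr$Wh)
    dc <- dc * ca$f
  }
  g
}

# Assemble the list of per-step B x V matrices for a batch of windows given
# a list of V x T voxel matrices, the subject index and start per window.
windowSteps <- function(Xmats, subj, starts, w) {
  lapply(seq_len(w), function(s) {
    t(vapply(seq_along(subj),
             function(b) Xmats[[subj[b]]][, starts[b] + s],
             numeric(nrow(Xmats[[1]]))))
  })
}

#' Extract per-window temporal features
#'
#' Feeds each window's frames to the LSTM in temporal order and takes the
#' final hidden state as the window's `d2`-dimensional feature. Each row is
#' a pure function of its own window's frames.
#'
#' @param encoder a `"temporalEncoder"` from [buildTemporalEncoder()].
#' @param vol a [Volume4D-class].
#' @param windows a `"windowSet"` from [segmentWindows()] valid for the
#'   volume's number of time points.
#' @return numeric matrix k x d2 with attribute `starts` (0-based).
#' @export
extractTemporalFeatures <- function(encoder, vol, windows) {
  stopifnot(is(encoder, "temporalEncoder"), is(vol, "Volume4D"),
            is(windows, "windowSet"))
  t <- nTimepoints(vol)
  if (any(windows$starts + windows$w > t))
    stop("window exceeds series length")
  X <- voxelMatrix(vol)
  if (nrow(X) != encoder$input_dim)
    stop("volume voxel count does not match the encoder's input dimension")
  steps <- windowSteps(list(X), rep(1L, windows$k), windows$starts, windows$w)
  h <- lstmForward(encoder, steps)
  attr(h, "starts") <- windows$starts
  h
}
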