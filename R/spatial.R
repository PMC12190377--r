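#' Spatial encoder configuration
#'
#' Configures the multi-scale 3D convolutional encoder: per layer, parallel
#' same-padded convolutions at each kernel size are channel-concatenated,
#' passed through a rectifier and max-pooled; after the last layer the
#' pooled map is flattened and a single fully connected layer maps it to the
#' `d1`-dimensional spatial feature vector.
#'
#' @param n_layers number of conv+pool layers (default 2).
#' @param kernel_sizes odd cubic kernel edge lengths (default 3, 5, 7).
#' @param channels_per_kernel output channels per parallel kernel (default
#'   8; the toy profile uses 4).
#' @param pool_size,pool_stride max-pooling kernel and stride (default 2/2).
#' @param d1 output spatial feature dimension (default 128; toy 16).
#' @return a classed list of validated fields.
#' @export
spatialEncoderConfig <- function(n_layers = 2L, kernel_sizes = c(3L, 5L, 7L),
                                 channels_per_kernel = 8L, pool_size = 2L,
                                 pool_stride = 2L, d1 = 128L) {
  kernel_sizes <- as.integer(kernel_sizes)
  stopifnot(n_layers >= 1, all(kernel_sizes >= 3L), all(kernel_sizes %% 2L == 1L),
            channels_per_kernel >= 1, pool_size >= 1, pool_stride >= 1, d1 >= 1)
  structure(list(n_layers = as.integer(n_layers), kernel_sizes = kernel_sizes,
                 channels_per_kernel = as.integer(channels_per_kernel),
                 pool_size = as.integer(pool_size),
                 pool_stride = as.integer(pool_stride), d1 = as.integer(d1)),
            class = "spatialEncoderConfig")
}

#' @rdname spatialEncoderConfig
#' @export
toySpatialConfig <- function() spatialEncoderConfig(channels_per_kernel = 4L, d1 = 16L)

#' Spatial shape after one conv + pool stage
#'
#' A same-padded convolution preserves the spatial shape; max-pooling with
#' kernel `pool_size` and stride `pool_stride` then maps each dimension `n`
#' to `floor((n - pool_size) / pool_stride) + 1`.
#'
#' @param in_shape integer length-3 spatial shape.
#' @param kernel convolution kernel size (odd; irrelevant to the output
#'   shape under same padding, kept for the interface contract).
#' @param padding only `"same"` is supported.
#' @param pool_size,pool_stride pooling kernel and stride.
#' @return integer length-3 pooled shape.
#' @examples
#' convOutputShape(c(16, 16, 12))            # 8 8 6
#' convOutputShape(convOutputShape(c(99, 117, 95)))  # two stages: 24 29 23
#' @export
convOutputShape <- function(in_shape, kernel = 3L, padding = "same",
                            pool_size = 2L, pool_stride = 2L) {
  stopifnot(all(in_shape >= 1), identical(padding, "same"))
  out <- (as.integer(in_shape) - pool_size) %/% pool_stride + 1L
  if (any(out < 1L)) stop("volume too small for config")
  out
}

#' Build the spatial encoder
#'
#' Initializes a multi-scale 3D convolutional encoder for volumes of shape
#' `in_shape` (He-normal weights, zero biases, deterministic given `seed`).
#' The returned object is a list with elements `cfg`, `in_shape`, `shapes`
#' (per-layer input shape / channels), `n_flat`, and `params` (nested list
#' of weight arrays, editable in place).
#'
#' @param cfg a [spatialEncoderConfig()].
#' @param in_shape integer length-3 input spatial shape.
#' @param seed integer seed for the weight initialization.
#' @return a `"spatialEncoder"` list.
#' @export
buildSpatialEncoder <- function(cfg, in_shape, seed) {
  stopifnot(is(cfg, "spatialEncoderConfig"), length(in_shape) == 3L)
  in_shape <- as.integer(in_shape)
  n_branch <- length(cfg$kernel_sizes)
  c_out <- n_branch * cfg$channels_per_kernel
  shapes <- vector("list", cfg$n_layers)
  dims <- in_shape; c_in <- 1L
  for (l in seq_len(cfg$n_layers)) {
    out_dims <- convOutputShape(dims, pool_size = cfg$pool_size,
                                pool_stride = cfg$pool_stride)
    shapes[[l]] <- list(in_dims = dims, out_dims = out_dims,
                        c_in = c_in, c_out = c_out)
    dims <- out_dims; c_in <- c_out
  }
  n_flat <- prod(dims) * c_out
  withSeed(seed, {
    layers <- lapply(shapes, function(sh) {
      branches <- lapply(cfg$kernel_sizes, function(k) {
        fan_in <- k^3 * sh$c_in
        list(W = matrix(rnorm(fan_in * cfg$channels_per_kernel,
                              sd = sqrt(2 / fan_in)),
                        fan_in, cfg$channels_per_kernel),
             b = numeric(cfg$channels_per_kernel))
      })
      names(branches) <- paste0("k", cfg$kernel_sizes)
      list(branches = branches)
    })
    fc <- list(W = matrix(rnorm(n_flat * cfg$d1, sd = sqrt(2 / n_flat)),
                          n_flat, cfg$d1),
               b = numeric(cfg$d1))
    structure(list(cfg = cfg, in_shape = in_shape, shapes = shapes,
                   n_flat = n_flat,
                   params = list(layers = layers, fc = fc)),
              class = "spatialEncoder")
  })
}

# Forward pass for one frame. `x` is a length-V voxel vector; returns the
# d1 feature vector, plus per-layer caches when `cache = TRUE`.
cnnForward <- function(enc, x, cache = FALSE) {
  cfg <- enc$cfg
  M <- matrix(x, ncol = 1L)
  caches <- if (cache) vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    sh <- enc$shapes[[l]]
    br <- enc$params$layers[[l]]$branches
    Z <- do.call(cbind, lapply(seq_along(cfg$kernel_sizes), function(i) {
      k <- cfg$kernel_sizes[i]
      sweep(cpp_conv3_fwd(M, sh$in_dims, br[[i]]$W, k), 2, br[[i]]$b, "+")
    }))
    A <- Z * (Z > 0)
    pl <- cpp_maxpool3(A, sh$in_dims, cfg$pool_size, cfg$pool_stride)
    if (cache) caches[[l]] <- list(input = M, Z = Z, idx = pl$idx)
    M <- pl$values
  }
  flat <- as.vector(M)
  f <- as.vector(crossprod(enc$params$fc$W, flat)) + enc$params$fc$b
  if (cache) list(f = f, flat = flat, caches = caches) else f
}

# Backward pass for one frame given the cached forward state and the
# gradient of the loss w.r.t. the d1 feature vector. Returns a gradient
# tree matching enc$params. im2col matrices are recomputed rather than
# cached to bound memory.
cnnBackward <- function(enc, fw, df) {
  cfg <- enc$cfg
  g <- list(layers = vector("list", cfg$n_layers),
            fc = list(W = outer(fw$flat, df), b = df))
  dM <- matrix(enc$params$fc$W %*% df,
               ncol = enc$shapes[[cfg$n_layers]]$c_out)
  for (l in rev(seq_len(cfg$n_layers))) {
    sh <- enc$shapes[[l]]
    ca <- fw$caches[[l]]
    dA <- cpp_maxpool3_backward(dM, ca$idx, prod(sh$in_dims))
    dZ <- dA * (ca$Z > 0)
    cpk <- cfg$channels_per_kernel
    branches <- vector("list", length(cfg$kernel_sizes))
    dIn <- if (l > 1L) matrix(0, prod(sh$in_dims), sh$c_in)
    for (i in seq_along(cfg$kernel_sizes)) {
      k <- cfg$kernel_sizes[i]
      block <- ((i - 1L) * cpk + 1L):(i * cpk)
      dY <- dZ[, block, drop = FALSE]
      branches[[i]] <- list(W = cpp_conv3_bwd_weights(ca$input, dY, sh$in_dims, k),
                            b = colSums(dY))
      if (l > 1L)
        dIn <- dIn + cpp_conv3_bwd_input(dY, sh$in_dims,
                                         enc$params$layers[[l]]$branches[[i]]$W,
                                         k, sh$c_in)
    }
    names(branches) <- names(enc$params$layers[[l]]$branches)
    g$layers[[l]] <- list(branches = branches)
    if (l > 1L) dM <- dIn
  }
  g
}

#' Extract per-time-point spatial features
#'
#' Applies the spatial encoder independently to each of the `t` per-time-
#' point 3D volumes, producing one `d1`-dimensional feature row per time
#' point. The encoder is purely per-frame: no temporal mixing occurs.
#'
#' @param encoder a `"spatialEncoder"` from [buildSpatialEncoder()].
#' @param vol a [Volume4D-class] whose spatial shape matches the encoder.
#' @param timepoints optional integer vector of 1-based time indices to
#'   encode (default: all).
#' @return numeric matrix `length(timepoints)` x `d1`.
#' @export
extractSpatialFeatures <- function(encoder, vol, timepoints = NULL) {
  stopifnot(is(encoder, "spatialEncoder"), is(vol, "Volume4D"))
  if (!identical(spatialDims(vol), encoder$in_shape))
    stop("volume spatial shape does not match the encoder's build shape")
  X <- voxelMatrix(vol)
  if (is.null(timepoints)) timepoints <- seq_len(ncol(X))
  out <- matrix(NA_real_, length(timepoints), encoder$cfg$d1)
  for (i in seq_along(timepoints)) out[i, ] <- cnnForward(encoder, X[, timepoints[i]])
  out
}
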