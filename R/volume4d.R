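#' Construct a Volume4D
#'
#' @param data numeric 4D array (X, Y, Z, T).
#' @param tr repetition time in seconds.
#' @param mask optional logical 3D array over the spatial grid.
#' @return A validated [Volume4D-class] object.
#' @examples
#' v <- Volume4D(array(rnorm(4 * 4 * 4 * 5), c(4, 4, 4, 5)), tr = 2)
#' nTimepoints(v)
#' @export
Volume4D <- function(data, tr, mask = NULL) {
  new("Volume4D", data = data, tr = tr, mask = mask)
}

#' @describeIn Volume4D-class number of time points T.
#' @param x,object a `Volume4D`.
#' @export
nTimepoints <- function(x) dim(x@data)[4L]

#' @describeIn Volume4D-class spatial grid dimensions (X, Y, Z).
#' @export
spatialDims <- function(x) dim(x@data)[1:3]

#' @describeIn Volume4D-class the voxel data array.
#' @export
volData <- function(x) x@data

#' @describeIn Volume4D-class repetition time in seconds.
#' @export
repetitionTime <- function(x) x@tr

#' @describeIn Volume4D-class the brain mask (logical 3D array or `NULL`).
#' @export
brainMask <- function(x) x@mask

setMethod("show", "Volume4D", function(object) {
  d <- dim(object@data)
  cat(sprintf("Volume4D: %d x %d x %d voxels, %d time points, TR = %g s\n",
              d[1], d[2], d[3], d[4], object@tr))
  if (!is.null(object@mask))
    cat(sprintf("  mask: %d of %d voxels in-brain\n",
                sum(object@mask), prod(d[1:3])))
  invisible(object)
})

#' Reshape a Volume4D into a voxels-by-time matrix
#'
#' Flattens the spatial grid into V rows (column-major, x fastest) against
#' T time-point columns, the `X in R^{V x T}` layout the encoders consume.
#'
#' @param vol a [Volume4D-class].
#' @return numeric matrix V x T.
#' @export
voxelMatrix <- function(vol) {
  d <- dim(vol@data)
  matrix(vol@data, nrow = prod(d[1:3]), ncol = d[4])
}

#' Read / write Volume4D as NIfTI
#'
#' Volumes are stored as compressed NIfTI (`.nii.gz`) with the repetition
#' time recorded in the header's fourth pixdim entry. Masks are not stored
#' in the NIfTI file; `readVolume4D()` accepts one separately.
#'
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @param vol a [Volume4D-class].
#' @param voxel_size numeric length-3 voxel edge lengths in mm.
#' @param mask optional logical 3D array to attach on read.
#' @return `readVolume4D()` returns a [Volume4D-class]; `writeVolume4D()`
#'   returns `path` invisibly.
#' @export
writeVolume4D <- function(vol, path, voxel_size = c(3, 3, 3)) {
  img <- RNifti::asNifti(vol@data)
  RNifti::pixdim(img) <- c(voxel_size, vol@tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVolume4D
#' @export
readVolume4D <- function(path, mask = NULL) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  tr <- if (length(pd) >= 4 && is.finite(pd[4]) && pd[4] > 0) pd[4] else 1
  Volume4D(array(as.numeric(img), dim = dim(img)), tr = tr, mask = mask)
}

#' Read / write motion-parameter traces
#'
#' Motion traces are T-row, 6-column whitespace-delimited text files: three
#' translations (mm) then three rotations (radians) per time point.
#'
#' @param trace numeric T x 6 matrix.
#' @param path text file path.
#' @return `readMotionTrace()` returns the T x 6 matrix.
#' @export
writeMotionTrace <- function(trace, path) {
  stopifnot(is.matrix(trace), ncol(trace) == 6L)
  utils::write.table(format(trace, digits = 17), path, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeMotionTrace
#' @export
readMotionTrace <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  if (ncol(m) != 6L) stop("motion trace must have 6 columns")
  m
}
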