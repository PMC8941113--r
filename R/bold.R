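#' BOLD voxel-by-time matrix
#'
#' Container for preprocessed BOLD signals: one row per voxel, one column per
#' time point, together with the voxel identifiers, their integer grid indices,
#' their MNI coordinates in millimetres and the repetition time.
#'
#' Voxel identifiers are 0-based flattened grid indices in C order (last grid
#' axis fastest), which fixes a deterministic voxel ordering across reads.
#'
#' @param values numeric matrix, n_voxels x n_timepoints, finite.
#' @param voxel_ids integer vector of unique voxel identifiers (0-based).
#' @param grid_index integer matrix n x 3 of (i, j, k) grid positions (0-based).
#' @param mni_mm numeric matrix n x 3 of MNI coordinates in mm.
#' @param tr_seconds positive scalar, repetition time in seconds.
#' @return An object of class \code{bold_matrix}.
#' @export
bold_matrix <- function(values, voxel_ids, grid_index, mni_mm, tr_seconds) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop_hc("BOLD values contain non-finite entries")
  if (ncol(values) < 2L) stop_hc("BOLD matrix needs at least 2 timepoints")
  voxel_ids <- as.integer(voxel_ids)
  if (anyDuplicated(voxel_ids)) stop_hc("voxel_ids must be unique")
  if (length(voxel_ids) != nrow(values))
    stop_hc("length(voxel_ids) must equal nrow(values)")
  grid_index <- matrix(as.integer(grid_index), ncol = 3)
  mni_mm <- matrix(as.numeric(mni_mm), ncol = 3)
  if (nrow(grid_index) != nrow(values) || nrow(mni_mm) != nrow(values))
    stop_hc("grid_index and mni_mm must have one row per voxel")
  check_scalar(tr_seconds, "tr_seconds")
  if (tr_seconds <= 0) stop_hc("tr_seconds must be positive")
  structure(
    list(values = values, voxel_ids = voxel_ids, grid_index = grid_index,
         mni_mm = mni_mm, tr_seconds = tr_seconds),
    class = "bold_matrix")
}

#' @export
print.bold_matrix <- function(x, ...) {
  cat(sprintf("BOLD matrix: %d voxels x %d timepoints (TR = %g s)\n",
              nrow(x$values), ncol(x$values), x$tr_seconds))
  invisible(x)
}

#' @export
dim.bold_matrix <- function(x) dim(x$values)

## 0-based C-order flat index of 0-based (i, j, k) on an (ni, nj, nk) grid.
flat_index <- function(ijk, dims) {
  (ijk[, 1] * dims[2] + ijk[, 2]) * dims[3] + ijk[, 3]
}

## All 0-based (i, j, k) triples of a grid, ordered by ascending flat index.
grid_triples <- function(dims) {
  g <- expand.grid(k = seq_len(dims[3]) - 1L, j = seq_len(dims[2]) - 1L,
                   i = seq_len(dims[1]) - 1L)
  cbind(i = g$i, j = g$j, k = g$k)
}

#' Read a 4D BOLD image (or a plain matrix table) into a BOLD matrix
#'
#' NIfTI input is flattened to one row per in-mask voxel, ordered by ascending
#' C-order flat grid index; MNI coordinates come from the image affine. A
#' plain-text table (whitespace- or comma-separated, voxels in rows) is
#' accepted as a fallback for non-imaging inputs, with synthetic grid indices
#' along the first axis.
#'
#' @param path path to a 4D NIfTI file or a plain matrix table.
#' @param mask optional path to a 3D NIfTI mask (non-zero = keep); spatial
#'   dimensions must match the image.
#' @param tr_seconds repetition time; for NIfTI input the header value is used
#'   unless overridden here.
#' @return A \code{\link{bold_matrix}}.
#' @export
read_bold <- function(path, mask = NULL, tr_seconds = NULL) {
  if (!file.exists(path)) stop_hc("file not found: ", path)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) != 4L) stop_hc("expected a 4D image")
    dims <- dim(arr)[1:3]
    nt <- dim(arr)[4]
    if (nt < 2L) stop_hc("BOLD matrix needs at least 2 timepoints")
    keep <- rep(TRUE, prod(dims))
    if (!is.null(mask)) {
      m <- as.array(RNifti::readNifti(mask))
      if (!identical(dim(m)[1:3], dims))
        stop_hc("mask dimensions do not match image dimensions")
      keep <- as.vector(m != 0)
    }
    trip <- grid_triples(dims)            # ascending C-order flat index
    # map C-order triples to R's column-major array offsets
    col_major <- trip[, 1] + dims[1] * (trip[, 2] + dims[2] * trip[, 3]) + 1L
    keep_c <- keep[col_major]
    if (!any(keep_c)) stop_hc("empty mask")
    trip <- trip[keep_c, , drop = FALSE]
    mat <- matrix(arr, nrow = prod(dims))[col_major[keep_c], , drop = FALSE]
    xf <- RNifti::xform(img)
    mni <- cbind(trip, 1) %*% t(xf[1:3, ])
    tr <- tr_seconds %||% RNifti::pixdim(img)[4]
    if (!is.finite(tr) || tr <= 0) tr <- 1
    bold_matrix(mat, flat_index(trip, dims), trip, mni, tr)
  } else {
    mat <- as.matrix(utils::read.table(path, header = FALSE,
                                       sep = "", comment.char = "#"))
    n <- nrow(mat)
    trip <- cbind(seq_len(n) - 1L, 0L, 0L)
    bold_matrix(mat, seq_len(n) - 1L, trip, trip, tr_seconds %||% 1)
  }
}

#' Zero-phase band-pass filter of BOLD series
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass of order 4 to
#' every voxel time series; the DC component is removed, so each output row has
#' mean approximately zero. Standard resting-state band is 0.01-0.1 Hz.
#'
#' @param b a \code{\link{bold_matrix}}.
#' @param low_hz,high_hz band edges in Hz; need 0 < low < high < Nyquist.
#' @param order Butterworth order (default 4).
#' @return A filtered \code{\link{bold_matrix}} of the same shape.
#' @export
bandpass_filter <- function(b, low_hz, high_hz, order = 4) {
  stopifnot(inherits(b, "bold_matrix"))
  nyq <- 1 / (2 * b$tr_seconds)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop_hc(sprintf("band (%g, %g) Hz outside (0, Nyquist = %g)",
                    low_hz, high_hz, nyq))
  if (!all(is.finite(b$values))) stop_hc("non-finite input")
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  nt <- ncol(b$values)
  npad <- min(nt - 1L, 3L * 10L * order)   # odd-extension padding
  filt <- t(apply(b$values, 1, function(x) {
    x0 <- x - mean(x)
    head_ext <- 2 * x0[1] - x0[(npad + 1L):2L]
    tail_ext <- 2 * x0[nt] - x0[(nt - 1L):(nt - npad)]
    y <- signal::filtfilt(bf, c(head_ext, x0, tail_ext))
    y[(npad + 1L):(npad + nt)]
  }))
  out <- b
  out$values <- filt
  out
}

#' Downsample a BOLD matrix by grid-block averaging
#'
#' Groups voxels into cubes of \code{factor}^3 grid cells and replaces each
#' occupied block by the mean time series of its in-mask constituents. Axis
#' lengths divide with ceiling, matching e.g. a 31 x 37 x 31 grid at factor 3
#' giving 11 x 13 x 11 blocks. Blocks with no constituent voxel are dropped.
#'
#' @param b a \code{\link{bold_matrix}}.
#' @param factor positive integer block edge length in voxels.
#' @return A \code{\link{bold_matrix}} over the block grid.
#' @export
downsample_blocks <- function(b, factor) {
  stopifnot(inherits(b, "bold_matrix"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop_hc("factor must be a positive integer")
  if (factor == 1L) return(b)
  block <- b$grid_index %/% factor
  bdims <- pmax(1L, as.integer(ceiling((apply(b$grid_index, 2, max) + 1L) / factor)))
  bid <- flat_index(block, bdims)
  ord <- order(bid)
  groups <- split(ord, bid[ord])           # names sort ascending numerically?
  ids <- as.integer(names(groups))
  o2 <- order(ids)                         # ascending flat block index
  groups <- groups[o2]
  ids <- ids[o2]
  vals <- t(vapply(groups, function(ix) colMeans(b$values[ix, , drop = FALSE]),
                   numeric(ncol(b$values))))
  gi <- t(vapply(groups, function(ix) as.integer(block[ix[1], ]), integer(3)))
  mni <- t(vapply(groups, function(ix) colMeans(b$mni_mm[ix, , drop = FALSE]),
                  numeric(3)))
  bold_matrix(vals, ids, gi, mni, b$tr_seconds)
}
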