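#' 3D greyscale CT volume
#'
#' Container for a reconstructed CT volume on an isotropic voxel grid. The
#' canonical storage convention for every grid object in this package is
#' `dim(data) == c(nx, ny, nz)` with `data[x, y, z]`, i.e. the x axis varies
#' fastest in memory (the usual C-order `(z, y, x)` slice-stack layout);
#' `data[, , k]` is the k-th axial slice. All physical quantities are in
#' millimetres.
#'
#' @param data numeric 3D array of greyscale intensities (finite values).
#' @param voxel_size_mm positive scalar; isotropic voxel edge length in mm.
#' @return An object of class `nut_volume`: a list with elements `data` and
#'   `voxel_size_mm`.
#' @examples
#' v <- volume3d(array(runif(8 * 8 * 8), c(8, 8, 8)), voxel_size_mm = 0.1)
#' dim(v$data)
#' @export
volume3d <- function(data, voxel_size_mm) {
  data <- check_grid(data)
  if (!is.numeric(data)) stop("volume data must be numeric")
  if (!all(is.finite(data))) stop("volume intensities must be finite")
  check_voxel_size(voxel_size_mm)
  structure(list(data = data, voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "nut_volume")
}

#' Binary foreground mask
#'
#' A boolean voxel grid (same layout conventions as [volume3d()]), typically
#' the thresholded foreground of a CT volume.
#'
#' @param data logical 3D array.
#' @param voxel_size_mm positive scalar, mm.
#' @return An object of class `nut_mask`.
#' @export
binary_mask <- function(data, voxel_size_mm) {
  data <- check_grid(data)
  if (!is.logical(data)) storage.mode(data) <- "logical"
  if (anyNA(data)) stop("mask must not contain NA")
  check_voxel_size(voxel_size_mm)
  structure(list(data = data, voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "nut_mask")
}

#' Per-object integer label map
#'
#' Integer voxel grid with background 0 and object labels exactly
#' `1..n_labels`; each positive label is one connected component under the
#' connectivity used to create it.
#'
#' @param data integer 3D array (non-negative).
#' @param voxel_size_mm positive scalar, mm.
#' @param n_labels number of positive labels; inferred from `data` if missing.
#' @return An object of class `nut_labels`.
#' @export
label_map <- function(data, voxel_size_mm, n_labels = NULL) {
  data <- check_grid(data)
  storage.mode(data) <- "integer"
  if (anyNA(data) || min(data) < 0) stop("labels must be non-negative integers")
  if (is.null(n_labels)) n_labels <- max(data)
  present <- sort(unique(as.integer(data[data > 0L])))
  if (length(present) &&
      !identical(present, seq_len(as.integer(n_labels))))
    stop("labels must be consecutive 1..n with 0 background")
  check_voxel_size(voxel_size_mm)
  structure(list(data = data, voxel_size_mm = as.numeric(voxel_size_mm),
                 n_labels = as.integer(n_labels)),
            class = "nut_labels")
}

#' Per-voxel nut compartment labels
#'
#' Segmentation of a single nut sub-volume into background (0), shell (1),
#' kernel (2) and enclosed empty space (3). The encoding is fixed across the
#' package and in files written by [write_volume()].
#'
#' @param data integer 3D array with values in 0:3.
#' @param voxel_size_mm positive scalar, mm.
#' @return An object of class `nut_parts`.
#' @export
part_label_map <- function(data, voxel_size_mm) {
  data <- check_grid(data)
  storage.mode(data) <- "integer"
  if (anyNA(data) || !all(data %in% 0:3))
    stop("part labels must be in 0 (background), 1 (shell), 2 (kernel), 3 (empty)")
  check_voxel_size(voxel_size_mm)
  structure(list(data = data, voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "nut_parts")
}

#' @export
print.nut_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<nut_volume> %d x %d x %d voxels @ %g mm (range %.3g..%.3g)\n",
              d[1], d[2], d[3], x$voxel_size_mm, min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.nut_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<nut_mask> %d x %d x %d voxels @ %g mm (%d foreground)\n",
              d[1], d[2], d[3], x$voxel_size_mm, sum(x$data)))
  invisible(x)
}

#' @export
print.nut_labels <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<nut_labels> %d x %d x %d voxels @ %g mm, %d objects\n",
              d[1], d[2], d[3], x$voxel_size_mm, x$n_labels))
  invisible(x)
}

#' @export
print.nut_parts <- function(x, ...) {
  d <- dim(x$data)
  n <- tabulate(x$data + 1L, 4L)
  cat(sprintf(
    "<nut_parts> %d x %d x %d voxels @ %g mm (shell %d, kernel %d, empty %d)\n",
    d[1], d[2], d[3], x$voxel_size_mm, n[2], n[3], n[4]))
  invisible(x)
}

check_grid <- function(data) {
  if (is.null(dim(data)) || length(dim(data)) != 3L)
    stop("grid data must be a 3D array")
  if (any(dim(data) < 1L)) stop("all three dimensions must be >= 1")
  data
}

check_voxel_size <- function(v) {
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
    stop("voxel_size_mm must be a single positive number")
  invisible(v)
}

grid_dims <- function(x) as.integer(dim(x$data))

#' Physical volume of one voxel
#' @param x any grid object with a `voxel_size_mm` element.
#' @return Voxel volume in mm^3.
#' @export
voxel_volume <- function(x) x$voxel_size_mm^3

# voxel-centre coordinates (mm) of TRUE voxels of a logical array;
# voxel (i, j, k) (1-based) maps to ((i-1) * v, (j-1) * v, (k-1) * v)
voxel_coords_mm <- function(arr, voxel_size_mm) {
  idx <- which(arr)
  d <- dim(arr)
  i <- (idx - 1L) %% d[1]
  r <- (idx - 1L) %/% d[1]
  j <- r %% d[2]
  k <- r %/% d[2]
  cbind(i, j, k) * voxel_size_mm
}

# boundary voxels of a mask: foreground with at least one 6-neighbour outside
# (voxels on the array border count as boundary)
boundary_voxels <- function(mask_arr) {
  d <- dim(mask_arr)
  if (any(d < 3L)) return(mask_arr)
  i <- 2:(d[1] - 1); j <- 2:(d[2] - 1); k <- 2:(d[3] - 1)
  core <- mask_arr[i, j, k] &
    mask_arr[i - 1, j, k] & mask_arr[i + 1, j, k] &
    mask_arr[i, j - 1, k] & mask_arr[i, j + 1, k] &
    mask_arr[i, j, k - 1] & mask_arr[i, j, k + 1]
  solid <- array(FALSE, d)
  solid[i, j, k] <- core
  mask_arr & !solid
}
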