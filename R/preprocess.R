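#' Preprocessing parameters
#'
#' Bundles the denoising/thresholding settings applied before
#' individualization: a Gaussian filter, a greyscale threshold `tau` (strict:
#' a voxel is foreground iff its intensity exceeds `tau`), and morphological
#' cleanup. With `tau = NULL` the threshold is estimated automatically from
#' the intensity histogram (see [estimate_tau()]), reproducing the
#' histogram-driven manual choice of the original workflow while remaining
#' overridable.
#'
#' @param tau greyscale threshold, or `NULL` for automatic estimation.
#' @param gaussian_sigma_mm standard deviation of the denoising Gaussian, mm.
#'   Default 0.1 mm (one voxel at the reference 0.1 mm scan resolution).
#' @param morph_radius_vox radius (voxels) of the ball structuring element for
#'   the opening/closing cleanup.
#' @param min_spot_mm3 connected components smaller than this volume are
#'   discarded as noise spots. Default 100 mm^3, two orders of magnitude below
#'   the smallest real nut (~10,000 mm^3).
#' @return An object of class `preprocess_params`.
#' @export
preprocess_params <- function(tau = NULL, gaussian_sigma_mm = 0.1,
                              morph_radius_vox = 1L, min_spot_mm3 = 100) {
  stopifnot(is.null(tau) || (is.numeric(tau) && is.finite(tau)),
            gaussian_sigma_mm >= 0, morph_radius_vox >= 0, min_spot_mm3 >= 0)
  structure(list(tau = tau, gaussian_sigma_mm = gaussian_sigma_mm,
                 morph_radius_vox = as.integer(morph_radius_vox),
                 min_spot_mm3 = min_spot_mm3),
            class = "preprocess_params")
}

#' Gaussian smoothing of a volume
#'
#' Separable Gaussian filter; `sigma_mm` is expressed in millimetres and
#' converted to voxels internally. `sigma_mm = 0` is the identity.
#'
#' @param vol a [volume3d()].
#' @param sigma_mm standard deviation in mm (>= 0).
#' @return A smoothed [volume3d()].
#' @export
gaussian_smooth <- function(vol, sigma_mm) {
  stopifnot(inherits(vol, "nut_volume"), sigma_mm >= 0)
  if (sigma_mm == 0) return(vol)
  d <- grid_dims(vol)
  sm <- cpp_gauss3d(as.vector(vol$data), d, sigma_mm / vol$voxel_size_mm)
  volume3d(array(sm, d), vol$voxel_size_mm)
}

#' Threshold a volume into a foreground mask
#'
#' Strict thresholding: a voxel is foreground iff its intensity is greater
#' than `tau` (intensity exactly equal to `tau` is background).
#'
#' @param vol a [volume3d()].
#' @param tau finite greyscale threshold.
#' @return A [binary_mask()].
#' @export
binarize <- function(vol, tau) {
  stopifnot(inherits(vol, "nut_volume"), is.finite(tau))
  binary_mask(vol$data > tau, vol$voxel_size_mm)
}

#' Estimate the foreground threshold from the intensity histogram
#'
#' Clusters the intensity histogram (see [cluster_histogram()]) and places the
#' threshold at the boundary below the kernel cluster: with the default
#' `k = 4` (air, foam, kernel, shell) that is the midpoint between the foam
#' and kernel cluster centres, so both air and the low-attenuation foam holder
#' fall below the threshold. If the histogram has fewer occupied intensity
#' levels than `k`, `k` is reduced accordingly (a two-level image yields the
#' midpoint of the two levels).
#'
#' @param vol a [volume3d()].
#' @param k requested number of intensity clusters (default 4).
#' @return Scalar threshold.
#' @export
estimate_tau <- function(vol, k = 4L) {
  stopifnot(inherits(vol, "nut_volume"))
  if (diff(range(vol$data)) == 0)
    stop("cannot estimate tau: volume is constant (single intensity mode)")
  cl <- cluster_histogram(vol, k, allow_fewer = TRUE)
  b <- max(1L, cl$k - 2L)
  unname(cl$ranges[b, 2])
}

#' Morphological cleanup of a binary mask
#'
#' Opening followed by closing with a ball structuring element (implemented
#' exactly via the Euclidean distance transform), then removal of connected
#' components smaller than `min_spot_mm3`.
#'
#' @param mask a [binary_mask()].
#' @param morph_radius_vox ball radius in voxels (>= 0; 0 skips morphology).
#' @param min_spot_mm3 minimum component volume retained, mm^3.
#' @param connectivity connectivity for the spot removal (6, 18 or 26).
#' @return A cleaned [binary_mask()].
#' @export
clean_mask <- function(mask, morph_radius_vox = 1L, min_spot_mm3 = 100,
                       connectivity = 26L) {
  stopifnot(inherits(mask, "nut_mask"), morph_radius_vox >= 0)
  d <- grid_dims(mask)
  m <- mask$data
  if (morph_radius_vox > 0) {
    m <- mask_close(mask_open(m, morph_radius_vox), morph_radius_vox)
  }
  if (min_spot_mm3 > 0) {
    lab <- cpp_label3d(as.vector(m), d, as.integer(connectivity))
    nlab <- attr(lab, "n_labels")
    if (nlab > 0) {
      sizes <- tabulate(lab, nlab) * voxel_volume(mask)
      keep <- which(sizes >= min_spot_mm3)
      m <- array(lab %in% keep, d)
    }
  }
  binary_mask(m, mask$voxel_size_mm)
}

#' Full preprocessing chain: smooth, threshold, clean
#'
#' Applies [gaussian_smooth()], [binarize()] (estimating `tau` when not given)
#' and [clean_mask()], and reports the parameters actually used.
#'
#' @param vol a [volume3d()].
#' @param params a [preprocess_params()].
#' @return A list with elements `mask` (a [binary_mask()]), `tau` (threshold
#'   used) and `params`.
#' @export
preprocess_volume <- function(vol, params = preprocess_params()) {
  stopifnot(inherits(vol, "nut_volume"), inherits(params, "preprocess_params"))
  sm <- gaussian_smooth(vol, params$gaussian_sigma_mm)
  tau <- if (is.null(params$tau)) estimate_tau(sm) else params$tau
  mask <- clean_mask(binarize(sm, tau), params$morph_radius_vox,
                     params$min_spot_mm3)
  list(mask = mask, tau = tau, params = params)
}

# ---- ball-structuring-element morphology on logical arrays ------------------
# erosion keeps foreground voxels whose distance to background exceeds r;
# dilation adds background voxels within distance r of foreground. Exact for
# the Euclidean ball via the squared distance transform.

mask_erode <- function(arr, r) {
  d <- dim(arr)
  ed <- cpp_edt_sq(as.vector(arr), as.integer(d))
  array(arr & ed > r^2, d)
}

mask_dilate <- function(arr, r) {
  d <- dim(arr)
  ed <- cpp_edt_sq(as.vector(!arr), as.integer(d))
  array(arr | ed <= r^2, d)
}

mask_open <- function(arr, r) mask_dilate(mask_erode(arr, r), r)
mask_close <- function(arr, r) mask_erode(mask_dilate(arr, r), r)
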