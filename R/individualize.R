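#' Label individual walnuts by 3D connectivity
#'
#' Connected-component labelling of the cleaned foreground mask, followed by
#' enclosure merging: a thresholded walnut is topologically a shell plus its
#' contents, and a dried kernel that has shrunk away from the inner wall
#' forms its own connected component floating inside the cavity. Any
#' component that cannot reach the volume border without crossing foreground
#' is therefore assigned the label of the component that encloses it. Labels
#' are renumbered consecutively from 1 to n in the order each final
#' component's first voxel appears in canonical scan order, so the numbering
#' is deterministic across runs and platforms. An empty mask yields n = 0.
#'
#' @param mask a [binary_mask()] (typically from [preprocess_volume()]).
#' @param connectivity 6, 18 or 26 (default 26, the standard for solid
#'   objects).
#' @return A [label_map()].
#' @export
label_walnuts <- function(mask, connectivity = 26L) {
  stopifnot(inherits(mask, "nut_mask"), connectivity %in% c(6L, 18L, 26L))
  d <- grid_dims(mask)
  lab <- array(cpp_label3d(as.vector(mask$data), d,
                           as.integer(connectivity)), d)
  n <- max(lab)
  if (n == 0L)
    return(label_map(lab, mask$voxel_size_mm, n_labels = 0L))
  # components adjacent to the exterior air are nut surfaces; the rest are
  # enclosed contents to be merged into their surrounding nut
  exterior <- array(cpp_flood_from_border(as.vector(mask$data), d, 6L), d)
  adj <- neighbours6_any(exterior)
  outer_labels <- sort(unique(lab[mask$data & adj]))
  inner_labels <- setdiff(seq_len(n), outer_labels)
  for (il in inner_labels) {
    idx <- which(lab == il)[1]
    pos <- arrayInd(idx, d)
    row <- lab[pos[1]:d[1], pos[2], pos[3]]
    owner <- row[row %in% outer_labels][1]
    if (is.na(owner)) {  # cannot happen for a truly enclosed component
      owner <- outer_labels[1]
    }
    lab[lab == il] <- owner
  }
  relabel_consecutive(lab, mask$voxel_size_mm)
}

# TRUE where any of the six face neighbours of `arr` is TRUE
neighbours6_any <- function(arr) {
  d <- dim(arr)
  out <- array(FALSE, d)
  out[-d[1], , ] <- out[-d[1], , ] | arr[-1, , ]
  out[-1, , ]    <- out[-1, , ]    | arr[-d[1], , ]
  out[, -d[2], ] <- out[, -d[2], ] | arr[, -1, ]
  out[, -1, ]    <- out[, -1, ]    | arr[, -d[2], ]
  out[, , -d[3]] <- out[, , -d[3]] | arr[, , -1]
  out[, , -1]    <- out[, , -1]    | arr[, , -d[3]]
  out
}

#' Split touching walnuts by distance-transform watershed
#'
#' Opt-in splitter for components that contain more than one nut. For each
#' labelled component, seeds are the connected blobs of the region where the
#' Euclidean distance to the component boundary exceeds `seed_level` times
#' the component's maximum distance. A component is split only when it has
#' at least two seed blobs whose centroids are more than
#' `min_seed_distance_mm` apart -- two fused nuts have two deep distance
#' maxima, while a single bumpy nut has one -- and the split is performed by
#' marker-based watershed on the negated distance transform. All labels are
#' renumbered consecutively in scan order afterwards; maps without fused
#' components are returned unchanged (idempotent on separated input).
#'
#' @param labelmap a [label_map()].
#' @param min_seed_distance_mm minimum seed separation to declare a fusion
#'   (default 10 mm, about a third of a small nut diameter).
#' @param seed_level fraction of the per-component maximum boundary distance
#'   defining the seed region.
#' @return A [label_map()].
#' @export
split_touching <- function(labelmap, min_seed_distance_mm = 10,
                           seed_level = 0.6) {
  stopifnot(inherits(labelmap, "nut_labels"))
  if (labelmap$n_labels == 0L) return(labelmap)
  d <- grid_dims(labelmap)
  vs <- labelmap$voxel_size_mm
  out <- labelmap$data
  next_extra <- labelmap$n_labels
  changed <- FALSE
  for (lb in seq_len(labelmap$n_labels)) {
    comp <- labelmap$data == lb
    bb <- mask_bbox(comp, margin = 2L)
    sub <- comp[bb[1, 1]:bb[1, 2], bb[2, 1]:bb[2, 2], bb[3, 1]:bb[3, 2],
                drop = FALSE]
    ds <- dim(sub)
    # fill internal cavities first so the distance transform measures nut
    # radii, not shell half-thicknesses
    filled <- !array(cpp_flood_from_border(as.vector(sub), ds, 6L), ds)
    ed <- cpp_edt_sq(as.vector(filled), ds)
    rmax2 <- max(ed)
    seeds <- array(ed >= (seed_level^2) * rmax2, ds)
    slab <- array(cpp_label3d(as.vector(seeds), ds, 26L), ds)
    ns <- max(slab)
    if (ns < 2) next
    cent <- t(vapply(seq_len(ns), function(s)
      colMeans(voxel_coords_mm(slab == s, vs)), numeric(3)))
    groups <- cluster_by_distance(cent, min_seed_distance_mm)
    if (max(groups) < 2) next
    markers <- array(0L, ds)
    markers[seeds] <- groups[slab[seeds]]
    ws <- array(cpp_watershed(-sqrt(ed), as.vector(markers),
                              as.vector(filled), ds, 26L), ds)
    changed <- TRUE
    for (s in 2:max(groups)) {
      next_extra <- next_extra + 1L
      piece <- array(FALSE, d)
      piece[bb[1, 1]:bb[1, 2], bb[2, 1]:bb[2, 2], bb[3, 1]:bb[3, 2]] <-
        ws == s & sub
      out[piece] <- next_extra
    }
  }
  if (!changed) return(labelmap)
  relabel_consecutive(out, vs)
}

# single-linkage grouping of points closer than `linkdist`; returns group ids
cluster_by_distance <- function(pts, linkdist) {
  n <- nrow(pts)
  grp <- seq_len(n)
  repeat {
    merged <- FALSE
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (grp[i] != grp[j] &&
          sqrt(sum((pts[i, ] - pts[j, ])^2)) <= linkdist) {
        grp[grp == grp[j]] <- grp[i]
        merged <- TRUE
      }
    }
    if (!merged) break
  }
  match(grp, unique(grp))
}

# renumber positive labels 1..n by first-voxel scan order
relabel_consecutive <- function(arr, voxel_size_mm) {
  pos <- which(arr > 0L)
  first <- pos[!duplicated(arr[pos])]
  old <- arr[first][order(first)]
  map <- integer(max(arr))
  map[old] <- seq_along(old)
  arr[pos] <- map[arr[pos]]
  label_map(arr, voxel_size_mm, n_labels = length(old))
}

#' Per-walnut binary masks
#'
#' One mask per positive label; the masks are pairwise disjoint and their
#' union is the labelled foreground.
#'
#' @param labelmap a [label_map()].
#' @return A list of [binary_mask()] objects, one per label (empty list for
#'   n = 0).
#' @export
component_masks <- function(labelmap) {
  stopifnot(inherits(labelmap, "nut_labels"))
  lapply(seq_len(labelmap$n_labels), function(lb)
    binary_mask(labelmap$data == lb, labelmap$voxel_size_mm))
}

#' Convex hull of a walnut mask
#'
#' The hull is estimated by support-function sampling: hull vertices are the
#' extreme boundary voxels over a quasi-uniform set of directions, and the
#' filled hull mask is the sampled half-space intersection, rasterised
#' exactly per (y, z) column (the feasible x-range of a convex region is an
#' interval). With the default 1280 directions the overshoot relative to the
#' true hull is well below a voxel for nut-sized objects.
#'
#' @param mask a non-empty [binary_mask()].
#' @param n_directions number of support directions.
#' @return A list with `mask` (filled hull, [binary_mask()]) and `vertices`
#'   (matrix of hull vertex coordinates in mm, consumed by [feret_shape()]).
#' @export
convex_hull_mask <- function(mask, n_directions = 1280L) {
  stopifnot(inherits(mask, "nut_mask"))
  if (!any(mask$data)) stop("empty mask has no convex hull")
  vs <- mask$voxel_size_mm
  pts <- voxel_coords_mm(boundary_voxels(mask$data), vs)
  ctr <- colMeans(pts)
  if (nrow(pts) < 4 ||
      sum(svd(sweep(pts, 2, ctr))$d > 1e-9 * max(1, max(abs(pts)))) < 3)
    stop("mask needs at least 4 non-coplanar voxels for a 3D hull")
  dirs <- fibonacci_sphere(n_directions)
  ex <- cpp_support_extremes(pts, dirs)
  verts <- pts[sort(unique(as.vector(ex))), , drop = FALSE]
  hvals <- rowSums(dirs * pts[ex[, 1], , drop = FALSE])
  d <- grid_dims(mask)
  hull <- array(cpp_hull_fill(dirs, hvals, d, c(0, 0, 0), vs), d)
  list(mask = binary_mask(hull, vs), vertices = verts)
}

#' Crop per-walnut sub-volumes
#'
#' Extracts one sub-volume per label: the label's tight bounding box plus
#' `margin_mm`, with every voxel outside the owner's (slightly dilated) mask
#' reset to a background air level, so neighbouring nuts and foam never leak
#' into the export.
#'
#' @param vol the source [volume3d()].
#' @param labelmap a [label_map()] derived from `vol`.
#' @param margin_mm margin added around the bounding box (>= 0).
#' @param background_value intensity written outside the owner mask; default
#'   is the volume minimum (air).
#' @param mask_dilate_vox dilation (voxels) of the owner mask before masking,
#'   preserving the partial-intensity rim of the nut itself.
#' @return A list with one entry per label: `volume` (a [volume3d()]),
#'   `label`, `bbox` (3 x 2 voxel indices into `vol`) and `n_voxels`.
#' @export
crop_subvolumes <- function(vol, labelmap, margin_mm = 1,
                            background_value = NULL, mask_dilate_vox = 2L) {
  stopifnot(inherits(vol, "nut_volume"), inherits(labelmap, "nut_labels"))
  if (!identical(grid_dims(vol), grid_dims(labelmap)))
    stop("labelmap does not match the volume dimensions")
  if (margin_mm < 0) stop("margin_mm must be >= 0")
  if (is.null(background_value)) background_value <- min(vol$data)
  vs <- vol$voxel_size_mm
  mvox <- as.integer(round(margin_mm / vs))
  lapply(seq_len(labelmap$n_labels), function(lb) {
    comp <- labelmap$data == lb
    bb <- mask_bbox(comp, margin = mvox)
    ix <- bb[1, 1]:bb[1, 2]; iy <- bb[2, 1]:bb[2, 2]; iz <- bb[3, 1]:bb[3, 2]
    sub <- vol$data[ix, iy, iz, drop = FALSE]
    own <- comp[ix, iy, iz, drop = FALSE]
    if (mask_dilate_vox > 0) own <- mask_dilate(own, mask_dilate_vox)
    sub[!own] <- background_value
    list(volume = volume3d(sub, vs), label = lb, bbox = bb,
         n_voxels = sum(comp))
  })
}

# tight bounding box of TRUE voxels, clamped margin; 3 x 2 matrix of indices
mask_bbox <- function(arr, margin = 0L) {
  d <- dim(arr)
  idx <- which(arr)
  if (!length(idx)) stop("empty mask has no bounding box")
  i <- (idx - 1L) %% d[1]
  r <- (idx - 1L) %/% d[1]
  j <- r %% d[2]
  k <- r %/% d[2]
  lo <- pmax(1L, c(min(i), min(j), min(k)) + 1L - margin)
  hi <- pmin(d, c(max(i), max(j), max(k)) + 1L + margin)
  matrix(c(lo[1], hi[1], lo[2], hi[2], lo[3], hi[3]), 3, 2, byrow = TRUE,
         dimnames = list(c("x", "y", "z"), c("lo", "hi")))
}
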