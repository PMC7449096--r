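#' Cluster the intensity histogram of a sub-volume
#'
#' Unsupervised 1-D clustering of voxel intensities, the basis for all
#' threshold choices in the pipeline. Intensities are binned (default 1024
#' bins; each occupied bin is represented by the mean intensity of its
#' voxels, so exact greyscale levels are recovered exactly), and the binned
#' distribution is partitioned into `k` contiguous clusters by exact weighted
#' 1-D k-means (dynamic programming over cluster boundaries). This is fully
#' deterministic: no random initialisation, no seed sensitivity.
#'
#' Cluster ranges are reported as `(low, high]` greyscale intervals whose
#' interior boundaries are midpoints between adjacent cluster centres; the
#' outer boundaries are the observed minimum and maximum, so the ranges
#' partition the observed intensity span.
#'
#' @param subvol a [volume3d()] (non-constant).
#' @param k number of clusters (>= 2). Default 4: air, foam, kernel, shell.
#' @param nbins number of histogram bins.
#' @param allow_fewer if `TRUE`, reduce `k` to the number of occupied
#'   intensity levels when that is smaller (but at least 2) instead of
#'   erroring.
#' @return An object of class `histogram_clusters`: list with `k`, `centers`
#'   (ascending), `ranges` (k x 2 matrix), `fractions` (summing to 1) and
#'   `span` (observed intensity range).
#' @export
cluster_histogram <- function(subvol, k = 4L, nbins = 1024L,
                              allow_fewer = FALSE) {
  stopifnot(inherits(subvol, "nut_volume"), k >= 2)
  v <- as.vector(subvol$data)
  rg <- range(v)
  if (diff(rg) == 0) stop("cannot cluster a constant volume")
  bi <- pmin(nbins, pmax(1L, as.integer(
    floor((v - rg[1]) / diff(rg) * nbins) + 1L)))
  w <- tabulate(bi, nbins)
  occ <- which(w > 0)
  if (length(occ) < k) {
    if (allow_fewer && length(occ) >= 2) k <- length(occ)
    else stop("fewer than k = ", k, " distinct intensity levels in volume")
  }
  sums <- rep(0, nbins)
  agg <- rowsum(v, bi)
  sums[as.integer(rownames(agg))] <- agg
  x <- sums[occ] / w[occ]      # per-bin mean intensity
  wt <- w[occ]
  grp <- kmeans1d_dp(x, wt, k)
  centers <- vapply(seq_len(k), function(g)
    sum(x[grp == g] * wt[grp == g]) / sum(wt[grp == g]), numeric(1))
  fractions <- vapply(seq_len(k), function(g)
    sum(wt[grp == g]), numeric(1)) / sum(wt)
  mids <- (centers[-k] + centers[-1]) / 2
  ranges <- cbind(low = c(rg[1], mids), high = c(mids, rg[2]))
  structure(list(k = as.integer(k), centers = centers, ranges = ranges,
                 fractions = fractions, span = rg),
            class = "histogram_clusters")
}

#' @export
print.histogram_clusters <- function(x, ...) {
  cat(sprintf("<histogram_clusters> k = %d\n", x$k))
  for (i in seq_len(x$k))
    cat(sprintf("  center %8.3f  range (%8.3f, %8.3f]  %5.1f%%\n",
                x$centers[i], x$ranges[i, 1], x$ranges[i, 2],
                100 * x$fractions[i]))
  invisible(x)
}

# exact weighted 1-D k-means by dynamic programming over contiguous groups
# (optimal clusters of sorted 1-D data are contiguous); returns group index
# 1..k per point, groups ordered by ascending value
kmeans1d_dp <- function(x, w, k) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  n <- length(x)
  W <- cumsum(w); S <- cumsum(w * x); Q <- cumsum(w * x^2)
  css <- function(j, i) {
    # within-cluster weighted sum of squares for points j..i (vector over j)
    Wji <- W[i] - c(0, W)[j]
    Sji <- S[i] - c(0, S)[j]
    Qji <- Q[i] - c(0, Q)[j]
    Qji - Sji^2 / Wji
  }
  D <- matrix(Inf, k, n)
  B <- matrix(1L, k, n)
  for (i in seq_len(n)) D[1, i] <- css(1L, i)
  if (k > 1) {
    for (m in 2:k) {
      for (i in m:n) {
        j <- m:i
        cand <- D[m - 1, j - 1] + css(j, i)
        b <- which.min(cand)
        D[m, i] <- cand[b]
        B[m, i] <- j[b]
      }
    }
  }
  grp <- integer(n)
  hi <- n
  for (m in k:1) {
    lo <- if (m == 1) 1L else B[m, hi]
    grp[lo:hi] <- m
    hi <- lo - 1L
  }
  out <- integer(n)
  out[o] <- grp
  out
}

#' Segment a nut sub-volume into shell, kernel and empty space
#'
#' Multi-level thresholding from histogram clusters plus marker-based
#' watershed refinement:
#' \enumerate{
#'   \item shell = voxels in the top intensity cluster, cleaned by a
#'     radius-1 opening/closing;
#'   \item interior = region enclosed by the shell (hole filling: voxels not
#'     reachable from the volume border without crossing shell; the border
#'     flood uses 6-connectivity so a watertight shell cannot leak
#'     diagonally). Empty space is thus defined geometrically, by enclosure,
#'     not by greyscale -- cavity air and exterior air share intensity;
#'   \item kernel = interior voxels claimed by a marker-based watershed on
#'     the gradient magnitude, with markers taken from high-confidence
#'     cluster cores (intensity within the central 50% of the kernel and air
#'     cluster ranges respectively);
#'   \item empty space = the rest of the interior; background = everything
#'     else.
#' }
#' By construction shell, kernel and empty space are disjoint and their union
#' is the nut foreground, so the volume additivity Vn = Vs + Vk + Ve is exact.
#' Because every threshold derives from the clusters, the segmentation is
#' invariant under affine rescaling of the intensities.
#'
#' If the shell encloses no interior (open or damaged shell) the result has
#' no kernel/empty voxels and is flagged; [qc_shell_integrity()] then fails it.
#'
#' @param subvol a [volume3d()] containing a single nut.
#' @param clusters a [cluster_histogram()] result for `subvol` (k >= 3:
#'   air, \[foam,\] kernel, shell).
#' @param morph_radius_vox cleanup radius for the shell mask, voxels.
#' @return A [part_label_map()] (0 background, 1 shell, 2 kernel, 3 empty).
#' @export
segment_nut_parts <- function(subvol, clusters, morph_radius_vox = 1L) {
  stopifnot(inherits(subvol, "nut_volume"),
            inherits(clusters, "histogram_clusters"))
  k <- clusters$k
  if (k < 3) stop("need at least 3 intensity clusters (air, kernel, shell)")
  d <- grid_dims(subvol)
  v <- subvol$data
  shell <- v > clusters$ranges[k, 1]
  if (morph_radius_vox > 0)
    shell <- mask_close(mask_open(shell, morph_radius_vox), morph_radius_vox)

  reached <- array(cpp_flood_from_border(as.vector(shell), d, 6L), d)
  interior <- !shell & !reached

  parts <- array(0L, d)
  parts[shell] <- 1L
  if (!any(interior)) {
    pm <- part_label_map(parts, subvol$voxel_size_mm)
    attr(pm, "no_interior") <- TRUE
    return(pm)
  }

  # high-confidence cluster cores: within a quarter range-width of the
  # cluster centre (centred on the centre, not the range, so a cluster
  # sitting at the observed extreme -- e.g. noise-free air at the minimum --
  # still yields markers)
  core <- function(i) {
    wdt <- clusters$ranges[i, 2] - clusters$ranges[i, 1]
    abs(v - clusters$centers[i]) <= 0.25 * wdt
  }
  markers <- array(0L, d)
  markers[interior & core(1L)] <- 3L       # air / empty cluster
  markers[interior & core(k - 1L)] <- 2L   # kernel cluster
  grad <- cpp_gradmag(as.vector(v), d)
  ws <- array(cpp_watershed(grad, as.vector(markers), as.vector(interior),
                            d, 26L), d)
  parts[interior] <- 3L           # unclaimed interior counts as empty space
  parts[interior & ws == 2L] <- 2L
  part_label_map(parts, subvol$voxel_size_mm)
}

#' Shell-integrity quality control
#'
#' A nut fails QC when its cavity is open to the exterior (interior air
#' reachable from the volume border without crossing shell) or when the shell
#' is not a single connected component -- the signature of shell damage, which
#' makes the shell/empty-space segmentation unreliable. Failed nuts must be
#' excluded from trait reporting.
#'
#' @param partmap a [part_label_map()] from [segment_nut_parts()].
#' @return A list with `pass` (logical) and `reason` (diagnostic text).
#' @export
qc_shell_integrity <- function(partmap) {
  stopifnot(inherits(partmap, "nut_parts"))
  d <- grid_dims(partmap)
  shell <- partmap$data == 1L
  if (!any(shell))
    return(list(pass = FALSE, reason = "no shell voxels segmented"))
  lab <- cpp_label3d(as.vector(shell), d, 26L)
  ncomp <- attr(lab, "n_labels")
  if (ncomp > 1) {
    sizes <- tabulate(lab, ncomp)
    # ignore dust specks below 0.1% of the shell; real fragmentation fails
    big <- sum(sizes > 0.001 * sum(sizes))
    if (big > 1)
      return(list(pass = FALSE,
                  reason = sprintf("shell fragmented into %d components", big)))
  }
  inside <- partmap$data == 2L | partmap$data == 3L
  if (!any(inside))
    return(list(pass = FALSE,
                reason = "no enclosed interior (open or damaged shell)"))
  reached <- array(cpp_flood_from_border(as.vector(shell), d, 6L), d)
  if (any(reached & inside))
    return(list(pass = FALSE,
                reason = "interior air connects to the exterior (pierced shell)"))
  list(pass = TRUE, reason = "intact closed shell")
}
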