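# Shared fixtures and small utilities. Heavier phantoms are built once per
# test run and memoised here; unit tests deliberately use coarse voxels
# (0.15-0.4 mm) so the whole suite stays fast, while the acceptance tests
# use the reference 0.1 mm resolution.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# digitised solid ellipsoid mask (axis-aligned), semi-axes in mm
ellipsoid_mask <- function(semi_mm, voxel, margin_mm = 1) {
  half <- semi_mm + margin_mm
  d <- 2L * as.integer(ceiling(half / voxel)) + 1L
  ctr <- (d - 1) / 2
  idx <- arrayInd(seq_len(prod(d)), d)
  q <- sweep(idx - 1, 2, ctr) * voxel
  w <- (q[, 1] / semi_mm[1])^2 + (q[, 2] / semi_mm[2])^2 +
       (q[, 3] / semi_mm[3])^2
  binary_mask(array(w <= 1, d), voxel)
}

sphere_mask <- function(r_mm, voxel, margin_mm = 1) {
  ellipsoid_mask(rep(r_mm, 3), voxel, margin_mm)
}

# standard small spherical test phantom (noisy) and its segmentation
small_sphere_phantom <- function() {
  fixture("small_sphere", function() {
    ph <- make_spherical_nut(6, 1, 3, voxel_size_mm = 0.15,
                             noise_sigma = 5, seed = 3)
    cl <- cluster_histogram(ph$volume, 3)
    pm <- segment_nut_parts(ph$volume, cl)
    list(ph = ph, clusters = cl, parts = pm)
  })
}

# small 5-nut scan used by individualization and pipeline tests
small_scan <- function() {
  fixture("small_scan", function() {
    sp <- phantom_spec(outer_radii_mm = c(6.5, 5.2, 5.6),
                       shell_thickness_mm = 1.2, bump_amplitude_mm = 0.3,
                       kernel_fill_target = 0.3, noise_sigma = 4, seed = 21)
    make_scan(5, sp, layout = "grid", foam = TRUE, voxel_size_mm = 0.3,
              seed = 11)
  })
}

# synthetic trait table with consistent derived indices; per-accession
# structure for ranking tests
synthetic_trait_table <- function(n_acc = 8, per_acc = 5, seed = 42) {
  with_seed_local(seed, {
    n <- n_acc * per_acc
    size <- rep(stats::rnorm(n_acc, 0, 1), each = per_acc) +
      stats::rnorm(n, 0, 0.3)
    L <- 38 + 3 * size + stats::rnorm(n, 0, 0.8)
    Fd <- 32 + 2 * size + stats::rnorm(n, 0, 0.7)
    P <- 33 + 2 * size + stats::rnorm(n, 0, 0.7)
    Vn <- 19000 + 2600 * size + stats::rnorm(n, 0, 500)
    A <- 4000 + 400 * size + stats::rnorm(n, 0, 60)
    Vs <- 4000 + 600 * size + stats::rnorm(n, 0, 150)
    Vk <- 5700 + 700 * stats::rnorm(n)
    Ve <- Vn - Vs - Vk
    Tm <- 1.03 + 0.1 * rep(stats::rnorm(n_acc), each = per_acc) +
      stats::rnorm(n, 0, 0.03)
    data.frame(
      accession_id = rep(sprintf("ACC%02d", seq_len(n_acc)), each = per_acc),
      nut_id = as.character(rep(seq_len(per_acc), n_acc)),
      L_mm = L, F_mm = Fd, P_mm = P, Vn_mm3 = Vn,
      VA3D = shape_va3d(Vn, A), Feret3D = 1.25 + 0.05 * stats::rnorm(n),
      A_mm2 = A, Sphericity = sphericity(Vn, A), Vs_mm3 = Vs, T_mm = Tm,
      Rugosity = rugosity(Vn, A), Vk_mm3 = Vk,
      FillingRatio_pct = 100 * Vk / Vn, Ve_mm3 = Ve,
      stringsAsFactors = FALSE)
  })
}

with_seed_local <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# best-overlap Dice of a truth part map (solid classes) against a label map
truth_label_dice <- function(truth, labelmap) {
  tm <- truth$part_map$data %in% 1:2
  bb <- attr(truth$part_map, "bbox")
  crop <- labelmap$data[bb[1, 1]:bb[2, 1], bb[1, 2]:bb[2, 2],
                        bb[1, 3]:bb[2, 3]]
  tab <- table(crop[tm])
  tab <- tab[names(tab) != "0"]
  k <- as.integer(names(tab)[which.max(tab)])
  list(label = k, dice = 2 * sum(tm & crop == k) /
         (sum(tm) + sum(labelmap$data == k)))
}
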