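test_that("histogram clustering recovers exact levels on noise-free data", {
  lv <- c(0, 25, 90, 160)
  v <- volume3d(array(rep(lv, times = c(6000, 1500, 400, 600)),
                      c(10, 10, 85)), 0.3)
  cl <- cluster_histogram(v, 4)
  expect_equal(cl$centers, lv, tolerance = 1e-9)
  expect_equal(sum(cl$fractions), 1, tolerance = 1e-9)
  expect_equal(cl$fractions, c(6000, 1500, 400, 600) / 8500,
               tolerance = 1e-9)
  expect_true(all(diff(cl$centers) > 0))
  # ranges partition the observed span with midpoints between centers
  expect_equal(unname(cl$ranges[1, 1]), 0)
  expect_equal(unname(cl$ranges[4, 2]), 160)
  expect_equal(unname(cl$ranges[2, 2]), (25 + 90) / 2)
})

test_that("two-level clustering thresholds midway; degenerate input errors", {
  v <- volume3d(array(rep(c(10, 100), 500), c(10, 10, 10)), 1)
  cl <- cluster_histogram(v, 2)
  expect_equal(unname(cl$ranges[1, 2]), 55, tolerance = 1e-9)
  expect_error(cluster_histogram(v, 4), "distinct intensity levels")
  expect_error(cluster_histogram(volume3d(array(1, c(4, 4, 4)), 1), 2),
               "constant")
})

test_that("cluster centres survive 5% noise within 2% of scale (10 seeds)", {
  lv <- c(air = 0, foam = 25, kernel = 90, shell = 160)
  sigma <- 0.05 * lv[["shell"]]
  # overlapping neighbour clusters truncate each other at the shared
  # boundary, so accuracy is bounded by the intensity scale, not by each
  # (possibly tiny) level value
  for (seed in 1:10) {
    counts <- c(20000, 6000, 2000, 3000)
    vals <- with_seed_local(seed,
      rep(lv, times = counts) + stats::rnorm(sum(counts), 0, sigma))
    v <- volume3d(array(vals, c(31, 25, 40)), 0.3)
    cl <- cluster_histogram(v, 4)
    for (i in 1:4)
      expect_lt(abs(cl$centers[i] - lv[i]) / lv[["shell"]], 0.02)
  }
})

test_that("cross-check: DP clustering matches stats::kmeans optimum", {
  vals <- with_seed_local(2, c(stats::rnorm(2000, 0, 4),
                               stats::rnorm(500, 90, 5),
                               stats::rnorm(800, 160, 6)))
  v <- volume3d(array(vals, c(10, 10, 33)), 0.3)
  cl <- cluster_histogram(v, 3)
  km <- with_seed_local(7, stats::kmeans(vals, centers = 3, nstart = 25))
  expect_lt(max(abs(cl$centers - sort(unname(km$centers[, 1])))), 0.5)
})

test_that("part segmentation matches ground truth on a noisy sphere", {
  fx <- small_sphere_phantom()
  truth <- fx$ph$truth$part_map$data
  got <- fx$parts$data
  for (cls in 1:3)
    expect_gt(dice(got == cls, truth == cls), 0.97)
  # partition property: classes disjoint by construction, additivity exact
  v <- part_volumes(fx$parts)
  expect_identical(v[["Vn"]], v[["Vs"]] + v[["Vk"]] + v[["Ve"]])
})

test_that("segmentation is invariant under affine intensity rescaling", {
  fx <- small_sphere_phantom()
  v2 <- volume3d(fx$ph$volume$data * 3.7 + 120, fx$ph$volume$voxel_size_mm)
  pm2 <- segment_nut_parts(v2, cluster_histogram(v2, 3))
  expect_identical(pm2$data, fx$parts$data)
})

test_that("kernel fill of a segmented phantom lands within one point", {
  sp <- phantom_spec(outer_radii_mm = c(6, 5, 5.4), shell_thickness_mm = 1.1,
                     bump_amplitude_mm = 0.3, kernel_fill_target = 0.30,
                     noise_sigma = 4, seed = 17)
  ph <- make_bumpy_nut(sp, voxel_size_mm = 0.2, truth_method = "none")
  pm <- segment_nut_parts(ph$volume, cluster_histogram(ph$volume, 3))
  v <- part_volumes(pm)
  expect_lt(abs(100 * v[["Vk"]] / v[["Vn"]] - 30), 1)
})

test_that("class volumes stay within 3% under 5% noise (10 seeds)", {
  for (seed in 1:10) {
    sp <- phantom_spec(outer_radii_mm = c(5.5, 4.6, 5),
                       shell_thickness_mm = 1.1, bump_amplitude_mm = 0.3,
                       kernel_fill_target = 0.3,
                       noise_sigma = 0.05 * 160, seed = seed)
    ph <- make_bumpy_nut(sp, voxel_size_mm = 0.25, truth_method = "none")
    pm <- segment_nut_parts(ph$volume, cluster_histogram(ph$volume, 3))
    got <- part_volumes(pm)
    want <- part_volumes(ph$truth$part_map)
    for (k in c("Vs", "Vk", "Ve", "Vn"))
      expect_lt(abs(got[[k]] - want[[k]]) / want[[k]], 0.03)
  }
})

test_that("shell-integrity QC separates intact from pierced nuts", {
  fx <- small_sphere_phantom()
  expect_true(qc_shell_integrity(fx$parts)$pass)
  dmg <- damage_shell(fx$ph$volume, fx$ph$truth, hole_radius_mm = 3)
  pm <- segment_nut_parts(dmg, cluster_histogram(dmg, 3))
  qc <- qc_shell_integrity(pm)
  expect_false(qc$pass)
  expect_match(qc$reason, "interior|shell")
})
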