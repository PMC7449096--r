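test_that("shape indices: closed forms and algebraic identities", {
  r <- 7.3
  V <- 4 / 3 * pi * r^3; A <- 4 * pi * r^2
  expect_equal(sphericity(V, A), 1, tolerance = 1e-12)
  expect_equal(rugosity(V, A), 1, tolerance = 1e-12)
  expect_equal(shape_va3d(V, A), 1, tolerance = 1e-12)
  # unit cube
  expect_equal(sphericity(1, 6), pi^(1 / 3) * 6^(2 / 3) / 6,
               tolerance = 1e-12)
  expect_equal(sphericity(1, 6), 0.80600, tolerance = 1e-5)
  expect_equal(rugosity(1, 6), 1 / 0.80600, tolerance = 1e-4)
  # identities hold for arbitrary positive (Vn, A)
  for (i in 1:25) {
    Vn <- stats::runif(1, 1, 1e5); Aa <- stats::runif(1, 1, 1e4)
    expect_equal(sphericity(Vn, Aa) * rugosity(Vn, Aa), 1,
                 tolerance = 1e-12)
    expect_equal(shape_va3d(Vn, Aa), rugosity(Vn, Aa)^3, tolerance = 1e-12)
  }
  expect_error(sphericity(-1, 5))
  expect_error(rugosity(5, 0))
})

test_that("part_volumes counts compartments and degenerate maps", {
  arr <- array(0L, c(6, 6, 6))
  arr[2:5, 2:5, 2:5] <- 2L          # all-kernel toy nut
  pm <- part_label_map(arr, 0.5)
  v <- part_volumes(pm)
  expect_identical(v[["Vk"]], 64 * 0.125)
  expect_identical(v[["Vs"]], 0)
  expect_identical(v[["Ve"]], 0)
  expect_identical(v[["Vn"]], v[["Vk"]])
})

test_that("principal axes recover ellipsoid extents and sphere symmetry", {
  el <- ellipsoid_mask(c(20, 15, 15), 0.25)
  ax <- principal_axes(el)
  expect_equal(ax$L, 40, tolerance = 0.3)
  expect_equal(ax$F, 30, tolerance = 0.3)
  expect_equal(ax$P, 30, tolerance = 0.3)
  sw <- principal_axes(el, swap_face_profile = TRUE)
  expect_identical(sw$F, ax$P)
  expect_identical(sw$P, ax$F)

  sph <- sphere_mask(5, 0.25)
  axs <- principal_axes(sph)
  expect_lt(max(abs(c(axs$L, axs$F, axs$P) - 10)), 0.25 + 1e-9)

  flat <- array(FALSE, c(10, 10, 10)); flat[2:9, 2:9, 5] <- TRUE
  expect_error(principal_axes(binary_mask(flat, 1)), "degenerate")
})

test_that("principal extents are stable under rigid rotation", {
  base <- phantom_spec(outer_radii_mm = c(7, 5.2, 5.8),
                       shell_thickness_mm = 1.2, bump_amplitude_mm = 0,
                       noise_sigma = 0, seed = 1)
  vals <- vapply(1:5, function(s) {
    sc <- make_scan(1, base, layout = "grid", foam = FALSE,
                    voxel_size_mm = 0.25, seed = 100 + s)  # random rotation
    mask <- binary_mask(sc$label_map$data > 0, 0.25)
    # fill the cavity so the solid is the full nut
    d <- dim(mask$data)
    filled <- !array(nutct:::cpp_flood_from_border(as.vector(mask$data), d,
                                                   6L), d)
    ax <- principal_axes(binary_mask(filled, 0.25))
    c(ax$L, ax$F, ax$P)
  }, numeric(3))
  # spread stays within about one voxel (0.25 mm on a 10-14 mm extent)
  for (j in 1:3)
    expect_lt(diff(range(vals[j, ])) / mean(vals[j, ]), 0.025)
  expect_equal(mean(vals[1, ]), 14, tolerance = 0.3)
})

test_that("surface area: sphere closed form, quadratic scaling, face-count bias", {
  m10 <- sphere_mask(10, 0.1)
  A10 <- surface_area(m10)
  expect_lt(abs(A10 - 1256.64) / 1256.64, 0.015)

  m5 <- sphere_mask(5, 0.1)
  A5 <- surface_area(m5)
  expect_equal(A10 / A5, 4, tolerance = 0.01 * 4)

  # voxel-face counting would be ~1.5x too large; the mesh estimate must not
  faces <- 0
  arr <- m10$data; d <- dim(arr)
  faces <- sum(arr[-1, , ] != arr[-d[1], , ]) +
    sum(arr[, -1, ] != arr[, -d[2], ]) + sum(arr[, , -1] != arr[, , -d[3]])
  A_faces <- faces * m10$voxel_size_mm^2
  expect_gt(A_faces / 1256.64, 1.3)
})

test_that("feret_shape: sphere, box vertices, convergence", {
  sph <- sphere_mask(8, 0.1)
  h <- convex_hull_mask(sph)
  fs <- feret_shape(h$vertices)
  expect_equal(fs$S2, 1, tolerance = 0.01)

  corners <- as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 2)))
  fb <- feret_shape(corners)
  expect_equal(fb$d, 1, tolerance = 0.005)
  expect_equal(fb$D, sqrt(5), tolerance = 0.01)
  expect_equal(fb$S2, 2.236, tolerance = 0.01)

  el <- ellipsoid_mask(c(8, 5.5, 6.5), 0.15)
  hv <- convex_hull_mask(el)$vertices
  s_lo <- feret_shape(hv, n_directions = 2000L)$S2
  s_hi <- feret_shape(hv, n_directions = 4000L)$S2
  expect_lt(abs(s_hi - s_lo) / s_lo, 0.005)
  expect_equal(s_lo, 8 / 5.5, tolerance = 0.02 * 8 / 5.5)
})

test_that("shell thickness: annuli at and below 1 mm, convergence", {
  annulus <- function(r, t, voxel) {
    outer <- sphere_mask(r, voxel)$data
    inner <- sphere_mask(r - t, voxel, margin_mm = 1 + t)$data
    binary_mask(outer & !inner, voxel)
  }
  a1 <- annulus(6, 1, 0.1)
  expect_equal(shell_thickness(a1), 1, tolerance = 0.1)
  a073 <- annulus(6, 0.73, 0.1)
  expect_lt(abs(shell_thickness(a073) - 0.73) / 0.73, 0.15)
  # halving the voxel size should at least halve the error
  e_coarse <- abs(shell_thickness(annulus(6, 1, 0.2)) - 1)
  e_fine <- abs(shell_thickness(a1) - 1)
  expect_lt(e_fine, e_coarse * 0.7)
})

test_that("measure_walnut recovers every spherical-phantom trait", {
  fx <- small_sphere_phantom()
  row <- measure_walnut(fx$parts, accession_id = "PH", nut_id = "1")
  expect_identical(row$qc, "pass")
  tr <- fx$ph$truth$traits
  expect_lt(abs(row$Vn_mm3 - tr$Vn_mm3) / tr$Vn_mm3, 0.03)
  expect_lt(abs(row$Vs_mm3 - tr$Vs_mm3) / tr$Vs_mm3, 0.03)
  expect_lt(abs(row$Vk_mm3 - tr$Vk_mm3) / tr$Vk_mm3, 0.03)
  expect_lt(abs(row$T_mm - tr$T_mm) / tr$T_mm, 0.1)
  expect_lt(abs(row$FillingRatio_pct - tr$FillingRatio_pct), 1)
  expect_lt(abs(row$Sphericity - 1), 0.01)
  expect_lt(abs(row$Feret3D - 1), 0.02)
  expect_lt(abs(row$L_mm - tr$L_mm) / tr$L_mm, 0.03)
  # identities hold on the measured row to machine precision
  expect_equal(row$Sphericity * row$Rugosity, 1, tolerance = 1e-9)
  expect_equal(row$VA3D, row$Rugosity^3, tolerance = 1e-9)
  expect_identical(row$Vn_mm3, row$Vs_mm3 + row$Vk_mm3 + row$Ve_mm3)
})

test_that("damaged nuts yield qc = fail with no trait values", {
  fx <- small_sphere_phantom()
  dmg <- damage_shell(fx$ph$volume, fx$ph$truth, hole_radius_mm = 3)
  pm <- segment_nut_parts(dmg, cluster_histogram(dmg, 3))
  row <- measure_walnut(pm, accession_id = "PH", nut_id = "dmg")
  expect_identical(row$qc, "fail")
  expect_true(all(is.na(unlist(row[names(trait_columns())]))))
})

test_that("all 14 traits are rotation-invariant within 1 percent", {
  sp <- phantom_spec(outer_radii_mm = c(6.2, 5, 5.5),
                     shell_thickness_mm = 1.2, bump_amplitude_mm = 0.35,
                     kernel_fill_target = 0.3, noise_sigma = 0, seed = 31)
  rows <- lapply(c(201, 202, 203), function(s) {
    sc <- make_scan(1, sp, layout = "grid", foam = FALSE,
                    voxel_size_mm = 0.2, seed = s)
    pm <- segment_nut_parts(sc$volume, cluster_histogram(sc$volume, 3))
    measure_walnut(pm)
  })
  tab <- do.call(rbind, rows)
  # tolerance reflects the test resolution: one 0.2 mm voxel on a ~12 mm nut
  for (cn in names(trait_columns())) {
    v <- tab[[cn]]
    expect_lt(diff(range(v)) / abs(mean(v)), 0.02)
  }
})
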