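test_that("labelling: single object, empty mask, scan-order numbering", {
  sph <- sphere_mask(3, 0.3)
  labs <- label_walnuts(sph)
  expect_identical(labs$n_labels, 1L)
  empty <- binary_mask(array(FALSE, c(8, 8, 8)), 0.3)
  expect_identical(label_walnuts(empty)$n_labels, 0L)

  # two separated blobs are numbered by first voxel in scan order
  two <- array(FALSE, c(30, 10, 10))
  two[3:7, 3:7, 3:7] <- TRUE
  two[20:24, 3:7, 3:7] <- TRUE
  lm <- label_walnuts(binary_mask(two, 0.3))
  expect_identical(lm$n_labels, 2L)
  expect_identical(lm$data[3, 3, 3], 1L)
  expect_identical(lm$data[20, 3, 3], 2L)
})

test_that("26-connectivity joins diagonal contact; 6-connectivity does not", {
  m <- array(FALSE, c(10, 10, 10))
  m[2:4, 2:4, 2:4] <- TRUE
  m[5:7, 5:7, 5:7] <- TRUE     # touch only at the (4,4,4)-(5,5,5) corner
  expect_identical(label_walnuts(binary_mask(m, 1), 26L)$n_labels, 1L)
  expect_identical(label_walnuts(binary_mask(m, 1), 6L)$n_labels, 2L)
})

test_that("a detached kernel floating in the cavity joins its nut", {
  # hollow sphere shell + separate inner blob = one walnut
  outer <- sphere_mask(4, 0.25, margin_mm = 1.5)$data
  inner <- sphere_mask(3, 0.25, margin_mm = 2.5)$data
  shell <- outer & !inner
  kernel <- sphere_mask(1.2, 0.25, margin_mm = 4.3)$data
  stopifnot(dim(shell) == dim(kernel), !any(shell & kernel))
  labs <- label_walnuts(binary_mask(shell | kernel, 0.25))
  expect_identical(labs$n_labels, 1L)
  expect_true(all(labs$data[kernel] == 1L))
})

test_that("scan labelling matches ground truth nuts with high Dice", {
  sc <- small_scan()
  pre <- preprocess_volume(sc$volume)
  labs <- label_walnuts(pre$mask)
  expect_identical(labs$n_labels, 5L)
  matched <- integer(0)
  # boundary recovery carries about one voxel of rim uncertainty, so the
  # attainable Dice scales with voxel/nut-radius; at this coarse test
  # resolution (0.3 mm on ~11 mm nuts) that bounds Dice near 0.98
  for (i in seq_len(5)) {
    md <- truth_label_dice(sc$truths[[i]], labs)
    expect_gt(md$dice, 0.975)
    matched <- c(matched, md$label)
  }
  expect_identical(sort(matched), 1:5)   # a bijection, order may permute
})

test_that("split_touching separates fused nuts and leaves others alone", {
  sp <- phantom_spec(outer_radii_mm = rep(7, 3), shell_thickness_mm = 1.2,
                     bump_amplitude_mm = 0, noise_sigma = 3, seed = 2)
  sc <- make_scan(2, sp, layout = "touching", foam = TRUE,
                  voxel_size_mm = 0.25, seed = 3)
  pre <- preprocess_volume(sc$volume)
  labs <- label_walnuts(pre$mask)
  expect_identical(labs$n_labels, 1L)     # fused pair
  split <- split_touching(labs, min_seed_distance_mm = 6)
  expect_identical(split$n_labels, 2L)
  for (i in 1:2) {
    tm <- sc$truths[[i]]$part_map$data %in% 1:2
    bb <- attr(sc$truths[[i]]$part_map, "bbox")
    crop <- split$data[bb[1, 1]:bb[2, 1], bb[1, 2]:bb[2, 2],
                       bb[1, 3]:bb[2, 3]]
    k <- as.integer(names(which.max(table(crop[tm & crop > 0]))))
    expect_gt(sum(tm & crop == k) / sum(tm), 0.95)
  }

  # a single nut is never split, and separated nuts pass through unchanged
  one <- label_walnuts(sphere_mask(4, 0.25))
  expect_identical(split_touching(one, 6)$data, one$data)
  sc5 <- small_scan()
  l5 <- label_walnuts(preprocess_volume(sc5$volume)$mask)
  expect_identical(split_touching(l5, 10)$data, l5$data)
})

test_that("component_masks partition the foreground", {
  sc <- small_scan()
  labs <- label_walnuts(preprocess_volume(sc$volume)$mask)
  masks <- component_masks(labs)
  expect_length(masks, 5L)
  overlap <- Reduce(`+`, lapply(masks, function(m) m$data * 1L))
  expect_true(all(overlap <= 1L))                     # pairwise disjoint
  expect_identical(overlap == 1L, labs$data > 0L)     # union = foreground
  expect_identical(sum(vapply(masks, function(m) sum(m$data), integer(1))),
                   sum(labs$data > 0L))
  none <- label_walnuts(binary_mask(array(FALSE, c(5, 5, 5)), 1))
  expect_length(component_masks(none), 0L)
})

test_that("convex hull: covers input tightly, fills concavities, idempotent", {
  sph <- sphere_mask(4, 0.25)
  h <- convex_hull_mask(sph)
  expect_true(all(!sph$data | h$mask$data))            # hull contains input
  expect_lte(sum(h$mask$data) / sum(sph$data), 1.02)   # tight on convex input

  lsh <- array(FALSE, c(30, 30, 14))
  lsh[4:26, 4:10, 4:10] <- TRUE
  lsh[4:10, 4:26, 4:10] <- TRUE
  hl <- convex_hull_mask(binary_mask(lsh, 0.5))
  expect_gt(sum(hl$mask$data), sum(lsh))               # concavity filled
  expect_true(hl$mask$data[17, 17, 7])                 # inside the notch

  h2 <- convex_hull_mask(h$mask)
  expect_gte(sum(h2$mask$data & h$mask$data) / sum(h$mask$data), 0.999)
  expect_true(all(!h2$mask$data | h$mask$data))        # no growth

  flat <- array(FALSE, c(10, 10, 10)); flat[3:7, 3:7, 5] <- TRUE
  expect_error(convex_hull_mask(binary_mask(flat, 1)), "non-coplanar")
})

test_that("crops isolate exactly one nut each with the owner's voxels", {
  sc <- small_scan()
  labs <- label_walnuts(preprocess_volume(sc$volume)$mask)
  crops <- crop_subvolumes(sc$volume, labs, margin_mm = 1)
  expect_length(crops, 5L)
  for (cr in crops) {
    pre <- preprocess_volume(cr$volume, preprocess_params(min_spot_mm3 = 10))
    relab <- label_walnuts(pre$mask)
    expect_identical(relab$n_labels, 1L)
  }
  # margin 0 gives the tight bounding box of the component
  c0 <- crop_subvolumes(sc$volume, labs, margin_mm = 0)[[1]]
  comp <- labs$data == 1L
  bb <- nutct:::mask_bbox(comp)
  expect_identical(unname(dim(c0$volume$data)), unname(bb[, 2] - bb[, 1] + 1L))
  expect_error(crop_subvolumes(sc$volume, labs, margin_mm = -1), "margin")
})
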