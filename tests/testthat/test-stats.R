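test_that("summarize_traits matches brute-force statistics", {
  tab <- synthetic_trait_table(3, 2)
  sm <- summarize_traits(tab)
  expect_identical(nrow(sm), 14L)
  for (cn in c("L_mm", "Vn_mm3", "T_mm")) {
    v <- tab[[cn]]
    row <- sm[sm$column == cn, ]
    expect_equal(row$mean, sum(v) / length(v), tolerance = 1e-12)
    expect_equal(row$sd,
                 sqrt(sum((v - mean(v))^2) / (length(v) - 1)),
                 tolerance = 1e-12)
    expect_identical(row$min, min(v))
    expect_identical(row$max, max(v))
    expect_true(row$min <= row$mean && row$mean <= row$max)
  }
})

test_that("single-row tables flag an undefined SD as 0", {
  tab <- synthetic_trait_table(1, 1)
  sm <- summarize_traits(tab)
  expect_true(all(sm$sd == 0))
  expect_true(all(!sm$sd_defined))
  expect_equal(sm$mean[sm$column == "L_mm"], tab$L_mm)
})

test_that("correlation matrix: symmetry, diagonal, p-values", {
  tab <- synthetic_trait_table(8, 5)
  cm <- correlation_matrix(tab)
  expect_identical(cm$r, t(cm$r))
  expect_true(all(diag(cm$r) == 1))
  expect_true(all(abs(cm$r) <= 1 + 1e-12))
  # p-value cross-check against cor.test
  ct <- stats::cor.test(tab$L_mm, tab$Vn_mm3)
  expect_equal(cm$r["L_mm", "Vn_mm3"], unname(ct$estimate),
               tolerance = 1e-12)
  expect_equal(cm$p["L_mm", "Vn_mm3"], ct$p.value, tolerance = 1e-9)
  # bonferroni only inflates
  cb <- correlation_matrix(tab, adjust = "bonferroni")
  expect_true(all(cb$p >= cm$p - 1e-15, na.rm = TRUE))
})

test_that("sphericity and rugosity are perfectly negatively correlated", {
  tab <- synthetic_trait_table(8, 5)
  cm <- correlation_matrix(tab)
  expect_lt(cm$r["Sphericity", "Rugosity"], -0.99)
})

test_that("zero-variance columns give NA correlations with a warning", {
  tab <- synthetic_trait_table(4, 3)
  tab$T_mm <- 1
  expect_warning(cm <- correlation_matrix(tab), "zero-variance")
  expect_true(all(is.na(cm$r["T_mm", ])))
  expect_false(anyNA(cm$r["L_mm", setdiff(colnames(cm$r), "T_mm")]))
})

test_that("PCA: variance accounting, ordering, sign convention, cos2", {
  tab <- synthetic_trait_table(10, 4)
  pc <- run_pca(tab)
  expect_equal(sum(pc$explained_variance_pct), 100, tolerance = 1e-9)
  expect_true(all(diff(pc$explained_variance_pct) <= 1e-9))
  # matches a direct eigendecomposition of the correlation matrix
  ev <- eigen(stats::cor(as.matrix(tab[names(trait_columns())])))$values
  expect_equal(pc$explained_variance_pct, 100 * ev / sum(ev),
               tolerance = 1e-8)
  # sign convention: largest |loading| positive per component
  for (j in seq_len(ncol(pc$loadings))) {
    l <- pc$loadings[, j]
    expect_gt(l[which.max(abs(l))], 0)
  }
  expect_equal(rowSums(pc$squared_cosines), rep(1, nrow(pc$scores)),
               tolerance = 1e-9)
  expect_error(run_pca(within(tab, T_mm <- 2)), "constant")
})

test_that("a rank-1 pair of traits loads 100% on dimension 1", {
  n <- 30
  x <- with_seed_local(5, stats::rnorm(n))
  tab <- data.frame(accession_id = "A", nut_id = as.character(seq_len(n)),
                    t1 = x, t2 = 3 * x + 2)
  pc <- run_pca(tab, columns = c("t1", "t2"))
  expect_equal(pc$explained_variance_pct[1], 100, tolerance = 1e-9)
})

test_that("top_accessions ranks means in both directions", {
  tab <- synthetic_trait_table(8, 5)
  asc <- top_accessions(tab, "T_mm", "asc", 3)
  expect_identical(nrow(asc), 3L)
  expect_true(all(diff(asc$mean) >= 0))
  by_hand <- sort(tapply(tab$T_mm, tab$accession_id, mean))
  expect_identical(asc$accession_id[1], names(by_hand)[1])
  expect_equal(asc$mean[1], unname(by_hand[1]), tolerance = 1e-12)
  expect_equal(asc$sd[1],
               stats::sd(tab$T_mm[tab$accession_id == asc$accession_id[1]]),
               tolerance = 1e-12)

  dsc <- top_accessions(tab, "Kernel filling ratio", "desc", 2)
  by_hand2 <- sort(tapply(tab$FillingRatio_pct, tab$accession_id, mean),
                   decreasing = TRUE)
  expect_identical(dsc$accession_id[1], names(by_hand2)[1])

  expect_error(top_accessions(tab, "no-such-trait"), "unknown trait")
  one <- top_accessions(synthetic_trait_table(1, 4), "T_mm", "asc", 1)
  expect_identical(nrow(one), 1L)
})
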