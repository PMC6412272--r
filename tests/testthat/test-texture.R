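test_that("minimum bounding rectangles are minimal and masked", {
  # single-pixel region at (5, 7) in 0-based half-open coordinates
  restored <- const_image(10, 10, c(50, 0, 0))
  lab <- matrix(0L, 10, 10); lab[6, 8] <- 1L
  p <- crop_region_patch(lab, restored, 1)
  expect_equal(unname(p$bbox), c(5L, 7L, 6L, 8L))
  expect_equal(dim(p$gray), c(1L, 1L))
  expect_equal(p$area, 1L)

  # L-shaped region spanning rows 2-10, cols 3-4 (0-based)
  restored12 <- const_image(12, 12, c(50, 0, 0))
  lab2 <- matrix(0L, 12, 12)
  lab2[3:11, 4] <- 1L
  lab2[11, 4:5] <- 1L
  p2 <- crop_region_patch(lab2, restored12, 1)
  expect_equal(unname(p2$bbox), c(2L, 3L, 11L, 5L))
  # background inside the rectangle is zeroed
  expect_true(all(p2$gray[p2$mask == 0] == 0L))
  expect_true(all(p2$gray[p2$mask == 1] == 50L))

  # random blob: bbox equals brute-force min/max row/col scan
  set.seed(61)
  for (i in 1:5) {
    m <- matrix(0L, 30, 30)
    m[disk_mask(30, 30, sample(8:22, 1), sample(8:22, 1), 5) == 1] <- 1L
    p3 <- crop_region_patch(m, const_image(30, 30, c(99, 0, 0)), 1)
    idx <- which(m == 1, arr.ind = TRUE)
    expect_equal(unname(p3$bbox),
                 c(min(idx[, 1]) - 1L, min(idx[, 2]) - 1L,
                   max(idx[, 1]), max(idx[, 2])))
  }

  expect_error(crop_region_patch(lab, restored, 5),
               class = "msx_validation_error")
})

test_that("quantization bins [0, 255] uniformly", {
  expect_equal(quantize_gray(0L, 16), 0L)
  expect_equal(quantize_gray(255L, 16), 15L)
  expect_equal(quantize_gray(128L, 2), 1L)
  bins <- table(quantize_gray(0:255, 8))
  expect_true(all(bins == 32))
})

test_that("GLCM construction matches brute-force pair enumeration", {
  # constant patch: single point mass at (k, k)
  q <- matrix(3L, 4, 4)
  g <- glcm(q, c(0, 1), 16)
  expect_equal(g$matrix[4, 4], 1)
  expect_equal(sum(g$matrix), 1)

  # 1x4 patch [0,1,0,1]: symmetrized entries (0,1) = (1,0) = 0.5
  q2 <- matrix(c(0L, 1L, 0L, 1L), 1, 4)
  g2 <- glcm(q2, c(0, 1), 2)
  expect_equal(g2$matrix[1, 2], 0.5)
  expect_equal(g2$matrix[2, 1], 0.5)
  expect_equal(g2$matrix[1, 1] + g2$matrix[2, 2], 0)

  # symmetry and normalization on random patches, all four step-2 offsets
  set.seed(71)
  offsets <- list(c(0, 2), c(-2, 2), c(-2, 0), c(-2, -2))
  for (i in 1:10) {
    q3 <- matrix(sample(0:15, 20 * 20, replace = TRUE), 20, 20)
    for (off in offsets) {
      g3 <- glcm(q3, off, 16)
      expect_identical(g3$matrix, t(g3$matrix))
      expect_equal(sum(g3$matrix), 1, tolerance = 1e-12)
      expect_equal(g3$matrix, oracle_glcm_matrix(q3, off, 16))
    }
  }

  # degenerate: patch smaller than the offset in both dimensions
  gd <- glcm(matrix(0L, 1, 1), c(0, 2), 4)
  expect_true(gd$degenerate)
  expect_equal(sum(gd$matrix), 1)
})

test_that("contrast, entropy and correlation match direct summation", {
  # point mass: all three degenerate to 0
  g <- glcm(matrix(5L, 4, 4), c(0, 1), 16)
  expect_equal(glcm_contrast(g), 0)
  expect_equal(glcm_entropy(g), 0)
  expect_equal(glcm_correlation(g), 0)

  # hand-evaluated 2-level GLCM with p(0,1) = p(1,0) = 0.5
  g2 <- glcm(matrix(c(0L, 1L), 1, 2), c(0, 1), 2)
  expect_equal(glcm_contrast(g2), 1)
  expect_equal(glcm_entropy(g2, 2), 1)      # 1 bit
  expect_equal(glcm_correlation(g2), -1)

  # random GLCMs vs independent double-loop sums
  set.seed(81)
  for (i in 1:10) {
    q <- matrix(sample(0:7, 144, replace = TRUE), 12, 12)
    g3 <- glcm(q, c(0, 2), 8)
    ref <- oracle_glcm_features(g3$matrix, base = 2)
    expect_equal(glcm_contrast(g3), ref$contrast, tolerance = 1e-9)
    expect_equal(glcm_entropy(g3, 2), ref$entropy, tolerance = 1e-9)
    expect_equal(glcm_correlation(g3), ref$correlation, tolerance = 1e-9)
  }

  # unnormalized input is rejected
  fake <- structure(list(matrix = matrix(1, 2, 2), levels = 2,
                         normalized = TRUE), class = "msx_glcm")
  expect_error(glcm_contrast(fake), class = "msx_validation_error")
})

test_that("region features average the four directions exactly", {
  scene <- quick_scene(91)
  pre <- preprocess_image(scene$image)
  cfg <- msx_config()
  for (id in seq_len(min(3, n_regions(pre$labels)))) {
    patch <- crop_region_patch(pre$labels, pre$restored, id)
    f <- region_features(patch, cfg)
    expect_equal(f$contrast, mean(f$per_direction$contrast))
    expect_equal(f$entropy, mean(f$per_direction$entropy))
    expect_equal(f$correlation, mean(f$per_direction$correlation))
    # near-isotropic regions: per-direction contrasts within 3x of each other
    cpd <- f$per_direction$contrast
    expect_lt(max(cpd) / max(min(cpd), 1e-12), 3)
  }

  # constant patch: averaged contrast and entropy are 0
  lab <- matrix(0L, 8, 8); lab[3:6, 3:6] <- 1L
  img <- const_image(8, 8, c(77, 0, 0))
  pc <- crop_region_patch(lab, restore_color(img, (lab > 0) * 1L), 1)
  fc <- region_features(pc, cfg)
  expect_equal(fc$contrast, 0)
  expect_equal(fc$entropy, 0)

  # single-pixel region is degenerate
  lab1 <- matrix(0L, 8, 8); lab1[4, 4] <- 1L
  p1 <- crop_region_patch(lab1, restore_color(img, (lab1 > 0) * 1L), 1)
  f1 <- region_features(p1, cfg)
  expect_true(f1$degenerate)
  expect_equal(f1$contrast, 0)
})

test_that("soil-like speckle scores higher contrast and lower entropy than fruit", {
  scene <- quick_scene(95)
  pre <- preprocess_image(scene$image)
  f <- extract_features(pre)
  soil <- fruit <- c()
  for (id in f$region_id) {
    px <- pre$labels == id
    if (sum(scene$confounder_mask[px]) / sum(px) > 0.5) soil <- c(soil, id)
    else if (sum(scene$fruit_mask[px]) / sum(px) > 0.5) fruit <- c(fruit, id)
  }
  expect_true(length(soil) >= 1 && length(fruit) >= 1)
  expect_gt(min(f$contrast[f$region_id %in% soil]),
            mean(f$contrast[f$region_id %in% fruit]))
  expect_gt(mean(f$entropy[f$region_id %in% fruit]),
            mean(f$entropy[f$region_id %in% soil]))
})
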