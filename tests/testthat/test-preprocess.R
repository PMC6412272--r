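test_that("red-component grayscale is a pure channel projection", {
  img <- const_image(4, 4, c(200, 50, 10))
  expect_true(all(to_red_gray(img) == 200L))
  expect_true(all(to_red_gray(const_image(3, 3, c(0, 0, 0))) == 0L))

  pattern <- matrix((seq_len(6) - 1L) %% 256L, 6, 5)
  img2 <- array(0L, c(6, 5, 3))
  img2[, , 1] <- pattern
  img2[, , 2] <- 99L
  expect_identical(to_red_gray(img2), pattern)
})

test_that("Otsu picks the exhaustive between-class-variance maximizer", {
  # perfect bimodal: mask is 1 exactly on the bright pixels
  g <- matrix(c(rep(0L, 8), rep(255L, 8)), 4, 4)
  t <- otsu_threshold(g)
  expect_false(attr(t, "degenerate"))
  expect_identical(binarize(g, t), (g == 255L) * 1L)

  # constant image: degenerate, threshold equals the constant, mask all zero
  gc <- matrix(7L, 5, 5)
  tc <- otsu_threshold(gc)
  expect_true(attr(tc, "degenerate"))
  expect_equal(as.integer(tc), 7L)
  expect_true(all(binarize(gc, tc) == 0L))

  # random images against the brute-force oracle
  set.seed(101)
  for (i in 1:20) {
    g <- matrix(sample(0:255, 64 * 64, replace = TRUE), 64, 64)
    expect_equal(as.integer(otsu_threshold(g)), oracle_otsu(g))
  }
})

test_that("disk opening matches brute force and satisfies its laws", {
  # radius 0 is the identity
  set.seed(21)
  m <- random_mask(15, 15, 0.5)
  expect_identical(morph_open_disk(m, 0), m)

  # an isolated pixel is removed by radius-1 opening
  single <- matrix(0L, 9, 9); single[5, 5] <- 1L
  expect_true(all(morph_open_disk(single, 1) == 0L))

  # a disk of radius 5 essentially survives radius-3 opening (discrete
  # Euclidean disks can lose a few boundary pixels), and the result equals
  # the brute-force erosion/dilation composition
  big <- disk_mask(21, 21, 11, 11, 5)
  opened_big <- morph_open_disk(big, 3)
  expect_identical(opened_big, oracle_open(big, 3))
  expect_true(all(opened_big <= big))
  expect_gte(sum(opened_big), 0.88 * sum(big))

  # random masks vs brute force, idempotence, anti-extensivity
  set.seed(22)
  for (i in 1:8) {
    m <- random_mask(18, 18, stats::runif(1, 0.3, 0.7))
    for (r in c(1, 2)) {
      opened <- morph_open_disk(m, r)
      expect_identical(opened, oracle_open(m, r))
      expect_identical(morph_open_disk(opened, r), opened)   # idempotent
      expect_true(all(opened <= m))                          # anti-extensive
    }
  }
})

test_that("labeling matches flood fill and uses raster-scan label order", {
  # connectivity semantics on diagonal touch
  diag2 <- matrix(0L, 4, 4); diag2[2, 2] <- 1L; diag2[3, 3] <- 1L
  expect_equal(n_regions(label_regions(diag2, 8)), 1L)
  expect_equal(n_regions(label_regions(diag2, 4)), 2L)

  expect_equal(n_regions(label_regions(matrix(0L, 5, 5), 8)), 0L)

  set.seed(31)
  for (i in 1:6) {
    m <- random_mask(24, 24, 0.45)
    for (conn in c(4, 8)) {
      lab <- label_regions(m, conn)
      expect_identical(lab, oracle_flood_label(m, conn))
    }
  }
})

test_that("small-area removal keeps exactly components larger than fraction * max", {
  # areas {100, 11, 9} at fraction 0.1: threshold 10, strict
  m <- matrix(0L, 30, 40)
  m[2:11, 2:11] <- 1L          # 100
  m[14:24, 14] <- 1L           # 11
  m[27:29, 20:22] <- 1L        # 9
  out <- remove_small_regions(m, 0.1, 8)
  expect_equal(sum(out[2:11, 2:11]), 100)
  expect_equal(sum(out[14:24, 14]), 11)
  expect_equal(sum(out[27:29, 20:22]), 0)

  # boundary case: area exactly fraction * max is NOT kept
  m2 <- matrix(0L, 30, 40)
  m2[2:11, 2:11] <- 1L         # 100
  m2[20, 2:11] <- 1L           # 10
  out2 <- remove_small_regions(m2, 0.1, 8)
  expect_equal(sum(out2[20, ]), 0)
  expect_equal(sum(out2), 100)

  # random rectangle scenes vs an oracle built from flood-fill areas
  for (seed in c(41, 42)) {
    m3 <- stamp_rects(64, 64, 30, seed = seed)
    lab <- oracle_flood_label(m3, 8)
    areas <- tabulate(lab[lab > 0])
    keep <- which(areas > 0.1 * max(areas))
    expected <- matrix(as.integer(lab %in% keep & lab > 0), 64, 64)
    expect_identical(remove_small_regions(m3, 0.1, 8), expected)
  }
})

test_that("color restoration applies the pointwise mask rule", {
  img <- const_image(6, 6, c(10, 20, 30))
  expect_identical(restore_color(img, matrix(1L, 6, 6)), img)
  expect_true(all(restore_color(img, matrix(0L, 6, 6)) == 0L))

  chk <- matrix(as.integer((row(matrix(0, 6, 6)) + col(matrix(0, 6, 6))) %% 2), 6, 6)
  out <- restore_color(img, chk)
  expect_true(all(out[, , 2][chk == 1] == 20L))
  expect_true(all(out[, , 2][chk == 0] == 0L))
  expect_error(restore_color(img, matrix(1L, 3, 3)),
               class = "msx_validation_error")
})

test_that("the pre-processing chain recovers constructed scenes", {
  # three bright smooth blobs + salt noise -> exactly 3 labeled regions
  set.seed(51)
  img <- const_image(120, 160, c(40, 60, 120))
  red <- img[, , 1]
  for (b in list(c(30, 40), c(60, 110), c(95, 60))) {
    d <- disk_mask(120, 160, b[1], b[2], 13)
    red[d == 1] <- 220L
  }
  salt <- matrix(stats::runif(120 * 160) < 0.01, 120, 160)
  red[salt] <- 255L
  img[, , 1] <- red
  pre <- preprocess_image(img, msx_config())
  expect_equal(n_regions(pre$labels), 3L)

  # invariants: restored equals input inside the clean mask, black outside;
  # labels nonzero exactly on the clean mask
  expect_true(all((pre$labels > 0) == (pre$binary_clean == 1)))
  for (ch in 1:3) {
    plane <- pre$restored[, , ch]
    expect_true(all(plane[pre$binary_clean == 1] ==
                      img[, , ch][pre$binary_clean == 1]))
    expect_true(all(plane[pre$binary_clean == 0] == 0L))
  }

  # component count never increases along the cleanup chain
  n_raw <- n_regions(label_regions(pre$binary_raw, 8))
  opened <- morph_open_disk(pre$binary_raw, 3)
  n_open <- n_regions(label_regions(opened, 8))
  n_clean <- n_regions(pre$labels)
  expect_true(n_raw >= n_open && n_open >= n_clean)

  # all-black image: no regions, empty restored image
  pre0 <- preprocess_image(const_image(40, 40, c(0, 0, 0)))
  expect_equal(n_regions(pre0$labels), 0L)
  expect_true(all(pre0$restored == 0L))

  # the one-tenth rule fires inside the pipeline: blob of ~400 px plus a
  # compact speck that survives opening but not the area filter
  img2 <- const_image(100, 100, c(40, 60, 120))
  red2 <- img2[, , 1]
  red2[disk_mask(100, 100, 40, 40, 11) == 1] <- 220L   # area ~397
  red2[70:73, 70:72] <- 220L                           # area 12
  img2[, , 1] <- red2
  pre2 <- preprocess_image(img2, msx_config(disk_radius = 1))
  expect_equal(n_regions(pre2$labels), 1L)
})

test_that("the pipeline is deterministic for identical input and config", {
  scene <- quick_scene(77)
  a <- preprocess_image(scene$image)
  b <- preprocess_image(scene$image)
  expect_identical(a$labels, b$labels)
  expect_identical(a$restored, b$restored)
  expect_identical(as.integer(a$otsu_threshold), as.integer(b$otsu_threshold))
})
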