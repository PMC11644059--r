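test_that("the raw map is the rectified gradient-weighted channel sum", {
  # two 2x2 channels with weights 1 and 0.5 -> raw map [[1,0],[0,1]]
  A <- array(0, dim = c(2, 2, 2))
  A[1, 1, 1] <- 1; A[2, 2, 2] <- 2
  G <- array(rep(c(1, 0.5), each = 4), dim = c(2, 2, 2))
  hm <- gradcam_map(A, G)
  expect_equal(hm, matrix(c(1, 0, 0, 1), 2))

  # uniform positive gradient on one channel: ReLU(A)/max
  A1 <- array(stats::rnorm(64), dim = c(8, 8, 1))
  G1 <- array(0.3, dim = c(8, 8, 1))
  r <- pmax(A1[, , 1], 0)
  expect_equal(gradcam_map(A1, G1), r / max(r))

  # zero gradients give an identically zero map
  expect_equal(gradcam_map(A1, G1 * 0), matrix(0, 8, 8))
})

test_that("heatmaps are invariant to channel permutation and positive scaling", {
  set.seed(12)
  A <- array(stats::rnorm(6 * 5 * 7), dim = c(6, 5, 7))
  G <- array(stats::rnorm(6 * 5 * 7), dim = c(6, 5, 7))
  base <- gradcam_map(A, G)
  perm <- sample(7)
  # permuting channels reorders the floating-point summation, so agreement
  # is to accumulation roundoff, not bitwise
  expect_equal(gradcam_map(A[, , perm], G[, , perm]), base, tolerance = 1e-12)
  expect_equal(gradcam_map(A * 37.5, G), base, tolerance = 1e-12)
})

test_that("model-level heatmaps are normalized, input-sized, and validated", {
  m <- sononet_model(build_lpc_sononet(9), seed = 8)
  img <- unclass(generate_image("femur", c(48, 48), speckle = 0.1, seed = 8))
  hm <- gradcam(m, img, target_class = 2)
  expect_equal(dim(hm), c(48L, 48L))
  expect_gte(min(hm), 0)
  expect_equal(max(hm), 1)  # non-degenerate map is max-normalized
  expect_equal(attr(hm, "layer_id"), "block4.fuse.relu")
  expect_error(gradcam(m, img, target_class = 2, layer = "nope"),
               "unknown layer id")
  expect_error(gradcam(m, img, target_class = 12), "1..9")
  # text grid round-trip
  path <- withr::local_tempfile(fileext = ".txt")
  write_heatmap(hm, path)
  expect_equal(read_heatmap(path), unclass(hm), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("overlays blend dimensions faithfully and respect a zero heatmap", {
  img <- generate_image("thorax", c(40, 40), speckle = 0.1, seed = 3)
  img <- matrix(img, 40, 40)  # strip generator attributes
  zero <- matrix(0, 40, 40)
  ov <- overlay_heatmap(zero, img)
  expect_equal(dim(ov), c(40L, 40L, 3L))
  for (ch in 1:3) expect_equal(ov[, , ch], 0.6 * img)
  expect_error(overlay_heatmap(matrix(0, 2, 2), img), "must match")
  path <- withr::local_tempfile(fileext = ".png")
  overlay_heatmap(matrix(runif(1600), 40), img, path = path)
  expect_equal(dim(png::readPNG(path)), c(40L, 40L, 3L))
})

test_that("trained-model heatmaps localize the femur bar", {
  fit <- convergence_fit(convergence_seeds()[1])
  femur_class <- match("femur", fit$categories)
  n <- 50L; inside <- 0L
  for (k in seq_len(n)) {
    img <- generate_image("femur", c(64, 64), speckle = 0.1,
                          seed = 900000L + k)
    roi <- attr(img, "roi")
    hm <- gradcam(fit$model, unclass(img), target_class = femur_class)
    w <- sum(hm)
    centroid_r <- sum(row(hm) * hm) / w
    centroid_c <- sum(col(hm) * hm) / w
    if (centroid_r >= roi["row_min"] && centroid_r <= roi["row_max"] &&
        centroid_c >= roi["col_min"] && centroid_c <= roi["col_max"]) {
      inside <- inside + 1L
    }
  }
  expect_gte(inside / n, 0.8)
})
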