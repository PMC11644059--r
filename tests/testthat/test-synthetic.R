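test_that("phantom generation is a pure function of its arguments", {
  a <- generate_image("thorax", c(48, 48), speckle = 0.2, seed = 9)
  b <- generate_image("thorax", c(48, 48), speckle = 0.2, seed = 9)
  expect_identical(unclass(a), unclass(b))
  c <- generate_image("thorax", c(48, 48), speckle = 0.2, seed = 10)
  expect_false(identical(unclass(a), unclass(c)))
})

test_that("intensities stay in [0,1] for any speckle strength", {
  for (s in c(0, 0.1, 0.8, 2)) {
    for (cat in plane_categories("nine")) {
      img <- generate_image(cat, c(32, 32), speckle = s, seed = 3)
      expect_gte(min(img), 0)
      expect_lte(max(img), 1)
    }
  }
})

test_that("noise-free femur bars are strictly brighter than the background", {
  for (seed in 1:5) {
    img <- generate_image("femur", c(64, 64), speckle = 0, seed = seed)
    vals <- sort(unique(as.numeric(img)))
    expect_length(vals, 2L)             # hard two-band construction
    bar <- img == max(vals)
    expect_true(min(img[bar]) > max(img[!bar]))
    roi <- attr(img, "roi")
    on_rows <- which(rowSums(bar) > 0)
    expect_equal(range(on_rows), unname(roi[c("row_min", "row_max")]))
  }
})

test_that("brain planes share the rim and differ only inside it", {
  for (seed in c(2, 7, 21)) {
    tt <- generate_image("trans_thalamic", c(64, 64), speckle = 0, seed = seed)
    ob <- generate_image("other_brain", c(64, 64), speckle = 0, seed = seed)
    diff <- which(unclass(tt) != unclass(ob))
    expect_gt(length(diff), 0)
    # every differing pixel sits on the other-brain interior (value 0.35)
    expect_true(all(ob[diff] == 0.35))
  }
})

test_that("dataset generation writes the requested counts with a manifest", {
  dir <- withr::local_tempdir()
  counts <- stats::setNames(rep(4L, 9), plane_categories("nine"))
  counts[["other_brain"]] <- 0L
  man <- generate_dataset(counts, dir, image_size = c(32, 32), speckle = 0.1,
                          seed = 5)
  expect_equal(nrow(man), sum(counts))
  expect_false("other_brain" %in% man$category)
  expect_true(all(file.exists(man$path)))
  expect_true(all(man$provenance == "original"))
  # regenerating with the same seed reproduces identical images
  dir2 <- withr::local_tempdir()
  man2 <- generate_dataset(counts, dir2, image_size = c(32, 32), speckle = 0.1,
                           seed = 5)
  expect_identical(png::readPNG(man$path[1]), png::readPNG(man2$path[1]))
  expect_error(generate_dataset(c(bogus = 3L), dir), "phantom categories")
})

test_that("preset counts preserve the published class imbalance", {
  tenth <- phantom_counts("table2", scale = 0.1)
  expect_equal(unname(tenth[["other_brain"]]), 14L)
  expect_equal(unname(tenth[["other"]]), 421L)
  expect_equal(sum(phantom_counts("table2")), 12400L)
  expect_equal(sum(phantom_counts("table1")), 12400L)
})

test_that("a linear classifier separates downsampled phantom categories", {
  skip_if_not_installed("MASS")
  cats <- plane_categories("nine")
  n_train <- 35L; n_test <- 10L
  feats <- function(idx_range, seed_base) {
    X <- matrix(0, length(cats) * length(idx_range), 256)
    y <- character(nrow(X))
    r <- 0L
    for (ci in seq_along(cats)) {
      for (k in idx_range) {
        r <- r + 1L
        img <- generate_image(cats[ci], c(32, 32), speckle = 0.1,
                              seed = seed_base + 1000L * ci + k)
        small <- EBImage::imageData(EBImage::resize(EBImage::Image(img),
                                                    w = 16, h = 16))
        X[r, ] <- as.numeric(small)
        y[r] <- cats[ci]
      }
    }
    list(X = X, y = factor(y, levels = cats))
  }
  tr <- feats(seq_len(n_train), 0L)
  te <- feats(n_train + seq_len(n_test), 0L)
  fit <- MASS::lda(tr$X, tr$y)
  acc <- mean(predict(fit, te$X)$class == te$y)
  expect_gte(acc, 0.70)
})
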