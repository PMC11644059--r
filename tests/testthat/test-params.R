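test_that("closed-form parameter counts reproduce the published budgets", {
  p_sono <- count_parameters(build_sononet64(6))
  p_lpc <- count_parameters(build_lpc_sononet(6))
  expect_equal(p_sono$total, 14850892)
  expect_equal(p_sono$total_millions, 14.9)
  expect_equal(p_lpc$total, 4321900)
  expect_equal(p_lpc$total_millions, 4.3)
  expect_equal(p_sono$total, sum(p_sono$per_layer$count))
  # "about one-third" of the baseline
  expect_gt(p_lpc$total / p_sono$total, 0.25)
  expect_lt(p_lpc$total / p_sono$total, 0.35)
})

test_that("per-layer accounting enumerates every learnable layer once", {
  p <- count_parameters(build_sononet64(6))
  conv <- p$per_layer[startsWith(p$per_layer$type, "conv"), ]
  # 13 3x3 convs in the ladder (2+2+3+3+3) plus 2 1x1 head convs
  expect_equal(nrow(conv), 15L)
  expect_equal(sum(conv$type == "conv3x3"), 13L)
  expect_equal(sum(conv$type == "conv1x1"), 2L)
  expect_equal(anyDuplicated(p$per_layer$layer), 0L)
  # one batch-norm per convolution under the pinned design
  expect_equal(sum(p$per_layer$type == "batch_norm"), 15L)
})

test_that("single LPC block parameter arithmetic matches the closed form", {
  # cfg(1, 32, 64): 9*1*32 + 9*32*32 + (1+2*32)*64 + norms 2*(32+32+64)
  spec <- lpcsononet:::new_archspec(
    "one_block", 1L, 2L,
    blocks = list(list(type = "lpc", config = lpc_block_config(1, 32, 64),
                       pool_after = FALSE)),
    head = NULL)
  expect_equal(count_parameters(spec)$total, 13920)
  # smallest learnable unit: a 1x1 conv 1->1 plus its norm
  expect_equal(lpcsononet:::conv_params(1, 1, 1) + lpcsononet:::bn_params(1), 3)
})

test_that("enumerating instantiated tensors agrees exactly with the closed form", {
  for (builder in list(build_sononet64, build_lpc_sononet)) {
    spec <- builder(6)
    report <- count_parameters(spec)
    model <- sononet_model(spec, seed = 3)
    tensors <- model_parameters(model, learnable_only = TRUE)
    expect_equal(sum(vapply(tensors, length, numeric(1))), report$total)
    # tensor-by-tensor: conv kernels and batch-norm scale/shift
    by_layer <- vapply(report$per_layer$layer, function(l) {
      if (paste0(l, ".W") %in% names(tensors)) {
        length(tensors[[paste0(l, ".W")]])
      } else {
        length(tensors[[paste0(l, ".gamma")]]) + length(tensors[[paste0(l, ".beta")]])
      }
    }, numeric(1))
    expect_equal(unname(by_layer), report$per_layer$count)
  }
})

test_that("the pinned LPC ladder is the budget-calibrated choice", {
  # The lightweight network is described only as SonoNet64 with one block
  # removed, the rest replaced by LPC blocks, and a 4.3M budget. Enumerate
  # remove-one-block ladders x hidden-width ratios and check the pinned
  # combination ((64,256,512,512), hidden = out/2) lands on the printed
  # budget while recording the full calibration grid.
  base <- c(64L, 128L, 256L, 512L, 512L)
  grid <- expand.grid(drop = 1:5, ratio = c(0.25, 0.5, 1))
  grid$millions <- NA_real_
  for (i in seq_len(nrow(grid))) {
    ladder <- base[-grid$drop[i]]
    hidden <- pmax(1L, as.integer(ladder * grid$ratio[i]))
    blocks <- list(); in_ch <- 1L
    for (j in seq_along(ladder)) {
      blocks[[j]] <- list(type = "lpc",
                          config = lpc_block_config(in_ch, hidden[j], ladder[j]),
                          pool_after = j < length(ladder))
      in_ch <- ladder[j]
    }
    spec <- lpcsononet:::new_archspec(
      "cand", 1L, 6L, blocks,
      head = list(in_ch = in_ch, mid_ch = in_ch %/% 2L, num_classes = 6L))
    grid$millions[i] <- count_parameters(spec)$total_millions
  }
  pinned <- grid$millions[grid$drop == 2 & grid$ratio == 0.5]
  expect_equal(pinned, 4.3)
  # and the shipped builder is that configuration
  expect_equal(count_parameters(build_lpc_sononet(6))$total_millions, 4.3)
})

test_that("channel load reports per-convolution widths and their mean", {
  two <- lpcsononet:::new_archspec(
    "two_convs", 100L, 2L,
    blocks = list(list(type = "conv_stack", in_ch = 100L,
                       channels = c(300L, 8L), pool_after = FALSE)),
    head = NULL)
  r <- channel_load(two)
  expect_equal(r$per_layer_channels, c(100L, 300L))
  expect_equal(r$mean_channels, 200)

  sono <- channel_load(build_sononet64(6))
  lpc <- channel_load(build_lpc_sononet(6))
  expect_equal(nrow(sono$per_layer), 15L)
  expect_equal(sono$mean_channels, mean(sono$per_layer_channels))
  # the pyramid design narrows the mean *output* width of the network
  expect_lt(lpc$mean_out_channels, sono$mean_out_channels)
})
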