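#' Light pyramid convolution (LPC) block configuration
#'
#' An LPC block passes its input through two stacked 3x3 convolutions (small
#' and large receptive field), concatenates the input with both intermediate
#' maps along the channel axis, and fuses the three scales with a 1x1
#' convolution. Every convolution is bias-free and followed by batch
#' normalization and a rectifier; spatial dimensions are preserved.
#'
#' @param in_ch Input channel count (positive integer).
#' @param hidden_ch Channel count of the two 3x3 pyramid convolutions.
#' @param out_ch Channel count after the 1x1 fusion convolution.
#' @return An object of class `lpc_block_config` with fields `in_ch`,
#'   `hidden_ch`, `out_ch` and the derived `concat_width`
#'   (`in_ch + 2 * hidden_ch`).
#' @examples
#' cfg <- lpc_block_config(64, 128, 256)
#' cfg$concat_width  # 64 + 2*128 = 320
#' @export
lpc_block_config <- function(in_ch, hidden_ch, out_ch) {
  for (v in list(in_ch, hidden_ch, out_ch)) {
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v)) {
      stop("lpc_block_config: channel counts must be positive integers",
           call. = FALSE)
    }
  }
  structure(
    list(in_ch = as.integer(in_ch), hidden_ch = as.integer(hidden_ch),
         out_ch = as.integer(out_ch),
         concat_width = as.integer(in_ch + 2L * hidden_ch)),
    class = "lpc_block_config"
  )
}

#' @export
print.lpc_block_config <- function(x, ...) {
  cat(sprintf("<LPC block> in %d -> pyramid 2 x 3x3 @ %d -> concat %d -> fuse 1x1 -> out %d\n",
              x$in_ch, x$hidden_ch, x$concat_width, x$out_ch))
  invisible(x)
}

new_archspec <- function(name, input_channels, num_classes, blocks, head) {
  structure(
    list(name = name, input_channels = as.integer(input_channels),
         num_classes = as.integer(num_classes), blocks = blocks, head = head),
    class = "archspec"
  )
}

check_classes <- function(num_classes) {
  if (!is.numeric(num_classes) || length(num_classes) != 1L ||
      num_classes < 2 || num_classes != round(num_classes)) {
    stop("invalid configuration: num_classes must be an integer >= 2",
         call. = FALSE)
  }
  as.integer(num_classes)
}

#' Build the SonoNet64 reference architecture
#'
#' A VGG-style fully convolutional classifier with five convolutional blocks
#' (channel ladder 64,64 | 128,128 | 256,256,256 | 512,512,512 | 512,512,512;
#' 3x3 kernels, stride 1, padding 1, each convolution bias-free and followed
#' by batch normalization and a rectifier), 2x2 max-pooling after blocks 1-4,
#' and an adaptation head: a 1x1 convolution 512 -> 256 with normalization and
#' rectifier, a 1x1 convolution 256 -> K with normalization, and a global
#' spatial max-pool producing class scores. The head accepts arbitrary input
#' sizes and implicitly localizes the most discriminative region.
#'
#' @param num_classes Number of standard-plane categories K (>= 2).
#' @return An `archspec` object.
#' @examples
#' spec <- build_sononet64(6)
#' count_parameters(spec)$total_millions  # 14.9
#' @seealso [build_lpc_sononet()], [count_parameters()]
#' @export
build_sononet64 <- function(num_classes) {
  K <- check_classes(num_classes)
  ladder <- list(c(64L, 64L), c(128L, 128L), c(256L, 256L, 256L),
                 c(512L, 512L, 512L), c(512L, 512L, 512L))
  blocks <- vector("list", 5L)
  in_ch <- 1L
  for (i in seq_along(ladder)) {
    blocks[[i]] <- list(type = "conv_stack", in_ch = in_ch,
                        channels = ladder[[i]], pool_after = i <= 4L)
    in_ch <- ladder[[i]][length(ladder[[i]])]
  }
  new_archspec("sononet64", 1L, K, blocks,
               head = list(in_ch = 512L, mid_ch = 256L, num_classes = K))
}

#' Build the LPC-SonoNet architecture
#'
#' The lightweight counterpart of [build_sononet64()]: one convolutional
#' block is removed and the remaining four are replaced by LPC blocks (see
#' [lpc_block_config()]), with output channel ladder 64, 256, 512, 512 and
#' pyramid (hidden) widths equal to half the block output (32, 128, 256,
#' 256). 2x2 max-pooling follows blocks 1-3; block 4 feeds the adaptation
#' head at full resolution. The head is identical to the SonoNet64 head
#' (1x1 conv 512 -> 256, 1x1 conv 256 -> K, global spatial max-pool).
#'
#' The ladder and hidden widths are pinned by calibration against the
#' network's closed-form parameter budget of 4.3 million at K = 6, roughly a
#' third of the 14.9 million of SonoNet64.
#'
#' @inheritParams build_sononet64
#' @return An `archspec` object with exactly four LPC blocks and one head.
#' @examples
#' spec <- build_lpc_sononet(6)
#' count_parameters(spec)$total_millions  # 4.3
#' @export
build_lpc_sononet <- function(num_classes) {
  K <- check_classes(num_classes)
  ladder <- c(64L, 256L, 512L, 512L)
  hidden <- ladder %/% 2L
  blocks <- vector("list", 4L)
  in_ch <- 1L
  for (i in seq_along(ladder)) {
    blocks[[i]] <- list(type = "lpc",
                        config = lpc_block_config(in_ch, hidden[i], ladder[i]),
                        pool_after = i <= 3L)
    in_ch <- ladder[i]
  }
  new_archspec("lpc_sononet", 1L, K, blocks,
               head = list(in_ch = 512L, mid_ch = 256L, num_classes = K))
}

block_in_ch <- function(b) if (b$type == "lpc") b$config$in_ch else b$in_ch
block_out_ch <- function(b) {
  if (b$type == "lpc") b$config$out_ch else b$channels[length(b$channels)]
}

validate_archspec <- function(spec) {
  stopifnot(inherits(spec, "archspec"))
  in_ch <- spec$input_channels
  for (i in seq_along(spec$blocks)) {
    b <- spec$blocks[[i]]
    if (block_in_ch(b) != in_ch) {
      stop(sprintf("archspec: block %d expects %d input channels but receives %d",
                   i, block_in_ch(b), in_ch), call. = FALSE)
    }
    in_ch <- block_out_ch(b)
  }
  if (!is.null(spec$head) && spec$head$in_ch != in_ch) {
    stop(sprintf("archspec: head expects %d input channels but receives %d",
                 spec$head$in_ch, in_ch), call. = FALSE)
  }
  invisible(spec)
}

n_pools <- function(spec) {
  sum(vapply(spec$blocks, function(b) isTRUE(b$pool_after), logical(1)))
}

#' Minimum spatial input size of an architecture
#'
#' Each 2x2 max-pooling stage halves the spatial dimensions (rounding down),
#' so every dimension must be at least `2 ^ n_pools` for a well-defined
#' forward pass.
#'
#' @param spec An `archspec`.
#' @return A single integer: the minimum height and width in pixels.
#' @export
min_input_size <- function(spec) {
  validate_archspec(spec)
  2L^n_pools(spec)
}

#' @export
print.archspec <- function(x, ...) {
  cat(sprintf("<archspec: %s> %d input channel(s), %d classes, %d blocks\n",
              x$name, x$input_channels, x$num_classes, length(x$blocks)))
  for (i in seq_along(x$blocks)) {
    b <- x$blocks[[i]]
    pool <- if (isTRUE(b$pool_after)) " + 2x2 max-pool" else ""
    if (b$type == "lpc") {
      cat(sprintf("  block %d: LPC %d -> (%d,%d) -> %d%s\n", i,
                  b$config$in_ch, b$config$hidden_ch, b$config$hidden_ch,
                  b$config$out_ch, pool))
    } else {
      cat(sprintf("  block %d: conv3x3 stack %d -> %s%s\n", i, b$in_ch,
                  paste(b$channels, collapse = ","), pool))
    }
  }
  if (!is.null(x$head)) {
    cat(sprintf("  head: 1x1 %d -> %d -> %d, global max-pool\n",
                x$head$in_ch, x$head$mid_ch, x$head$num_classes))
  }
  invisible(x)
}

# Lower an archspec to the flat node graph consumed by the C++ engine.
# Node ids are 1-based; parents always precede children.
lower_to_ir <- function(spec) {
  validate_archspec(spec)
  nodes <- list()
  nid <- function() length(nodes) + 1L
  add <- function(name, kind, parents = integer(), kernel = 0L,
                  in_ch = 0L, out_ch = 0L, channels) {
    nodes[[nid()]] <<- list(name = name, kind = kind,
                            parents = as.integer(parents),
                            kernel = as.integer(kernel),
                            `in` = as.integer(in_ch), out = as.integer(out_ch),
                            channels = as.integer(channels))
    length(nodes)
  }
  conv_bn_relu <- function(prefix, parent, kernel, in_ch, out_ch) {
    cid <- add(paste0(prefix, ".conv"), "conv", parent, kernel, in_ch, out_ch, out_ch)
    bid <- add(paste0(prefix, ".bn"), "bn", cid, channels = out_ch)
    add(paste0(prefix, ".relu"), "relu", bid, channels = out_ch)
  }
  cur <- add("input", "input", channels = spec$input_channels)
  for (i in seq_along(spec$blocks)) {
    b <- spec$blocks[[i]]
    pre <- sprintf("block%d", i)
    if (b$type == "lpc") {
      cfg <- b$config
      x_id <- cur
      y1 <- conv_bn_relu(paste0(pre, ".pyr1"), x_id, 3L, cfg$in_ch, cfg$hidden_ch)
      y2 <- conv_bn_relu(paste0(pre, ".pyr2"), y1, 3L, cfg$hidden_ch, cfg$hidden_ch)
      cc <- add(paste0(pre, ".concat"), "concat", c(x_id, y1, y2),
                channels = cfg$concat_width)
      cur <- conv_bn_relu(paste0(pre, ".fuse"), cc, 1L, cfg$concat_width, cfg$out_ch)
    } else {
      in_ch <- b$in_ch
      for (j in seq_along(b$channels)) {
        cur <- conv_bn_relu(sprintf("%s.conv%d", pre, j), cur, 3L, in_ch,
                            b$channels[j])
        in_ch <- b$channels[j]
      }
    }
    if (isTRUE(b$pool_after)) {
      cur <- add(paste0(pre, ".pool"), "pool", cur, channels = block_out_ch(b))
    }
  }
  h <- spec$head
  if (!is.null(h)) {
    cur <- conv_bn_relu("head.reduce", cur, 1L, h$in_ch, h$mid_ch)
    cid <- add("head.classify.conv", "conv", cur, 1L, h$mid_ch, h$num_classes,
               h$num_classes)
    bid <- add("head.classify.bn", "bn", cid, channels = h$num_classes)
    add("head.logits", "gmax", bid, channels = h$num_classes)
  }
  nodes
}

#' Serialize an architecture specification to YAML
#'
#' The written file fully determines the architecture, so experiments are
#' reproducible from configuration alone. [read_archspec()] restores an
#' identical `archspec` (round-trip stable).
#'
#' @param spec An `archspec`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_archspec <- function(spec, path) {
  validate_archspec(spec)
  blocks <- lapply(spec$blocks, function(b) {
    if (b$type == "lpc") {
      list(type = "lpc", in_ch = b$config$in_ch, hidden_ch = b$config$hidden_ch,
           out_ch = b$config$out_ch, pool_after = isTRUE(b$pool_after))
    } else {
      list(type = "conv_stack", in_ch = b$in_ch, channels = as.list(b$channels),
           pool_after = isTRUE(b$pool_after))
    }
  })
  obj <- list(name = spec$name, input_channels = spec$input_channels,
              num_classes = spec$num_classes, blocks = blocks,
              head = spec$head)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read an architecture specification from YAML
#'
#' @param path A file written by [write_archspec()].
#' @return An `archspec`.
#' @export
read_archspec <- function(path) {
  obj <- yaml::read_yaml(path)
  blocks <- lapply(obj$blocks, function(b) {
    if (b$type == "lpc") {
      list(type = "lpc",
           config = lpc_block_config(b$in_ch, b$hidden_ch, b$out_ch),
           pool_after = isTRUE(b$pool_after))
    } else {
      list(type = "conv_stack", in_ch = as.integer(b$in_ch),
           channels = as.integer(unlist(b$channels)),
           pool_after = isTRUE(b$pool_after))
    }
  })
  head <- if (!is.null(obj$head)) {
    list(in_ch = as.integer(obj$head$in_ch), mid_ch = as.integer(obj$head$mid_ch),
         num_classes = as.integer(obj$head$num_classes))
  }
  spec <- new_archspec(obj$name, obj$input_channels, obj$num_classes, blocks, head)
  validate_archspec(spec)
  spec
}
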