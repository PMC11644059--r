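conv_params <- function(kernel, in_ch, out_ch) as.numeric(kernel^2 * in_ch * out_ch)
bn_params <- function(channels) 2 * as.numeric(channels)

round_half_up <- function(x, digits = 1L) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Count trainable parameters of an architecture, layer by layer
#'
#' Closed-form accounting: a k x k convolution with `in` input and `out`
#' output channels holds `k^2 * in * out` weights (convolutions are bias-free
#' because each is followed by batch normalization), and each batch-norm
#' layer holds a scale and a shift per channel (`2 * channels`; running
#' statistics are not trainable). Pooling, rectifiers, and concatenation have
#' no parameters.
#'
#' The closed form agrees exactly, tensor by tensor, with enumerating the
#' learnable tensors of a model instantiated from the same spec (see
#' [model_parameters()]).
#'
#' @param spec An `archspec`.
#' @return An object of class `param_report`: a list with `per_layer` (a
#'   data frame with columns `layer`, `type`, `count`), integer `total`, and
#'   `total_millions` (total / 1e6 rounded half-up to one decimal).
#' @examples
#' count_parameters(build_sononet64(6))$total_millions   # 14.9
#' count_parameters(build_lpc_sononet(6))$total_millions # 4.3
#' @export
count_parameters <- function(spec) {
  validate_archspec(spec)
  ir <- lower_to_ir(spec)
  layer <- character(); type <- character(); count <- numeric()
  for (nd in ir) {
    if (nd$kind == "conv") {
      layer <- c(layer, paste0(nd$name))
      type <- c(type, sprintf("conv%dx%d", nd$kernel, nd$kernel))
      count <- c(count, conv_params(nd$kernel, nd$`in`, nd$out))
    } else if (nd$kind == "bn") {
      layer <- c(layer, nd$name)
      type <- c(type, "batch_norm")
      count <- c(count, bn_params(nd$channels))
    }
  }
  per_layer <- data.frame(layer = layer, type = type, count = count,
                          stringsAsFactors = FALSE)
  total <- sum(per_layer$count)
  structure(
    list(per_layer = per_layer, total = total,
         total_millions = round_half_up(total / 1e6, 1L)),
    class = "param_report"
  )
}

#' @export
print.param_report <- function(x, ...) {
  cat(sprintf("<param report> %d learnable layers, total %s parameters (%.1f million)\n",
              nrow(x$per_layer), format(x$total, big.mark = ","),
              x$total_millions))
  conv <- x$per_layer[startsWith(x$per_layer$type, "conv"), ]
  cat(sprintf("  convolutions: %d layers, %s parameters\n", nrow(conv),
              format(sum(conv$count), big.mark = ",")))
  bn <- x$per_layer[x$per_layer$type == "batch_norm", ]
  cat(sprintf("  batch norm:   %d layers, %s parameters\n", nrow(bn),
              format(sum(bn$count), big.mark = ",")))
  invisible(x)
}

#' Channel load of an architecture (diagnostic)
#'
#' Reports, for every convolution layer including the head, the number of
#' input channels it processes and their arithmetic mean. Output channel
#' counts and their mean are reported alongside, since the two summaries
#' capture different aspects of per-layer tensor width: the pyramid design
#' lowers the mean *output* width markedly while its concatenation layers
#' widen some *inputs*. This is a descriptive diagnostic of per-layer tensor
#' widths, not an evaluation metric.
#'
#' @param spec An `archspec`.
#' @return An object of class `channel_load_report`: list with `per_layer`
#'   (data frame: `layer`, `in_channels`, `out_channels`), `per_layer_channels`
#'   (the input-channel vector), `mean_channels` (mean of input channels) and
#'   `mean_out_channels`.
#' @export
channel_load <- function(spec) {
  validate_archspec(spec)
  ir <- lower_to_ir(spec)
  conv <- Filter(function(nd) nd$kind == "conv", ir)
  per_layer <- data.frame(
    layer = vapply(conv, function(nd) nd$name, character(1)),
    in_channels = vapply(conv, function(nd) nd$`in`, integer(1)),
    out_channels = vapply(conv, function(nd) nd$out, integer(1)),
    stringsAsFactors = FALSE
  )
  structure(
    list(per_layer = per_layer,
         per_layer_channels = per_layer$in_channels,
         mean_channels = mean(per_layer$in_channels),
         mean_out_channels = mean(per_layer$out_channels)),
    class = "channel_load_report"
  )
}

#' @export
print.channel_load_report <- function(x, ...) {
  cat(sprintf("<channel load> %d convolution layers; mean input width %.1f, mean output width %.1f\n",
              nrow(x$per_layer), x$mean_channels, x$mean_out_channels))
  invisible(x)
}
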