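#' Raw GradCAM map from feature maps and their gradients
#'
#' Pure arithmetic core of gradient-weighted class activation mapping: each
#' channel weight is the spatial mean of the class-score gradient over that
#' channel, the raw map is the rectified weighted sum of channels, and the
#' map is scaled so its maximum is 1 (an identically zero map stays zero).
#'
#' @param features `(h, w, C)` array of feature maps.
#' @param gradients `(h, w, C)` array of the class score's gradients with
#'   respect to `features`.
#' @return An `h x w` matrix in `[0, 1]`.
#' @examples
#' A <- array(c(1, 0, 0, 0, 0, 0, 0, 2), dim = c(2, 2, 2))
#' G <- array(rep(c(1, 0.5), each = 4), dim = c(2, 2, 2))
#' gradcam_map(A, G)  # max 1 at both hot corners
#' @export
gradcam_map <- function(features, gradients) {
  stopifnot(is.array(features), length(dim(features)) == 3L,
            all(dim(features) == dim(gradients)))
  C <- dim(features)[3]
  w <- apply(gradients, 3L, mean)
  raw <- matrix(0, dim(features)[1], dim(features)[2])
  for (c in seq_len(C)) raw <- raw + w[c] * features[, , c]
  raw[raw < 0] <- 0
  m <- max(raw)
  if (m > 0) raw / m else raw
}

#' GradCAM heatmap for one image and class
#'
#' Runs the model forward in inference mode, backpropagates the chosen class
#' score to the requested feature layer, forms the rectified
#' gradient-weighted channel sum ([gradcam_map()]), and upsamples it
#' bilinearly to the input size with max-normalization. The default layer is
#' the rectified output of the last feature block, the deepest spatial layer
#' before the adaptation head.
#'
#' @param model A `sononet_model` (typically a trained checkpoint).
#' @param image Numeric matrix in `[0, 1]`; standardized internally exactly
#'   as during training.
#' @param target_class Class index in `1..K`.
#' @param layer Feature layer name (see [layer_names()]); `NULL` for the
#'   default.
#' @param standardize Standardize the image before the forward pass.
#' @return An object of class `heatmap`: the `H x W` matrix in `[0, 1]`,
#'   with attributes `target_class`, `layer_id` and `logits`.
#' @export
gradcam <- function(model, image, target_class, layer = NULL,
                    standardize = TRUE) {
  stopifnot(inherits(model, "sononet_model"), is.matrix(image))
  if (is.null(layer)) layer <- default_gradcam_layer(model)
  if (!(layer %in% layer_names(model))) {
    stop(sprintf("unknown layer id: %s (see layer_names())", layer),
         call. = FALSE)
  }
  K <- model$spec$num_classes
  if (target_class < 1 || target_class > K) {
    stop(sprintf("target_class must lie in 1..%d", K), call. = FALSE)
  }
  x <- array(image, dim = c(nrow(image), ncol(image), 1L))
  if (standardize) x <- standardize_batch(x)
  check_input_batch(model, x)
  cap <- .net_capture(model$ptr, x, as.integer(target_class) - 1L, layer)
  small <- gradcam_map(cap$features, cap$gradients)
  up <- if (all(dim(small) == dim(image))) {
    small
  } else {
    m <- EBImage::imageData(EBImage::resize(EBImage::Image(small),
                                            w = nrow(image), h = ncol(image)))
    matrix(m, nrow(image), ncol(image))
  }
  up[up < 0] <- 0
  mx <- max(up)
  if (mx > 0) up <- up / mx
  structure(up, class = c("heatmap", "matrix"),
            target_class = as.integer(target_class), layer_id = layer,
            logits = cap$logits)
}

#' Write or read a heatmap as a plain-text grid
#'
#' @param heatmap A matrix heatmap.
#' @param path Text file path (one image row per line, space-separated).
#' @return `write_heatmap()` returns `path` invisibly; `read_heatmap()` the
#'   matrix.
#' @export
write_heatmap <- function(heatmap, path) {
  utils::write.table(format(unclass(heatmap), digits = 8), path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_heatmap
#' @export
read_heatmap <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE))
}

#' Overlay a heatmap on a grayscale image
#'
#' Blends the dimmed grayscale image with a warm colormap (black-red-yellow)
#' driven by the heatmap, the standard rendering for attention maps. A zero
#' heatmap therefore returns the dimmed image unchanged.
#'
#' @param heatmap `H x W` matrix in `[0, 1]`.
#' @param image `H x W` grayscale matrix in `[0, 1]`.
#' @param alpha Maximum heatmap opacity.
#' @param path Optional PNG output path.
#' @return An `(H, W, 3)` RGB array in `[0, 1]` (invisibly if `path` is
#'   given).
#' @export
overlay_heatmap <- function(heatmap, image, alpha = 0.6, path = NULL) {
  if (!all(dim(heatmap) == dim(image))) {
    stop("heatmap and image dimensions must match", call. = FALSE)
  }
  h <- as.numeric(heatmap)
  ramp <- grDevices::colorRamp(c("black", "darkred", "red", "orange", "yellow"))
  cols <- ramp(h) / 255
  H <- nrow(image); W <- ncol(image)
  out <- array(0, dim = c(H, W, 3))
  base <- 0.6 * image
  a <- alpha * h
  for (ch in 1:3) {
    out[, , ch] <- (1 - a) * base + a * matrix(cols[, ch], H, W)
  }
  out <- pmin(pmax(out, 0), 1)
  if (!is.null(path)) {
    png::writePNG(out, path)
    return(invisible(out))
  }
  out
}
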