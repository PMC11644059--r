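#' Instantiate a runnable model from an architecture specification
#'
#' Allocates the C++ network graph and initializes all weights with a seeded,
#' fan-in-scaled normal scheme (sd = sqrt(2 / fan_in), the standard choice
#' for rectifier networks); batch-norm scales start at 1 and shifts at 0.
#' Two instantiations from the same spec and seed are bit-identical.
#'
#' @param spec An `archspec` from [build_sononet64()] or [build_lpc_sononet()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `sononet_model`.
#' @examples
#' m <- sononet_model(build_lpc_sononet(6), seed = 1)
#' x <- array(runif(64 * 64 * 2), dim = c(64, 64, 2))
#' dim(forward(m, x))  # 2 x 6
#' @export
sononet_model <- function(spec, seed = 1L) {
  validate_archspec(spec)
  ir <- lower_to_ir(spec)
  ptr <- .net_create(ir)
  init <- init_params(ir, seed)
  .net_set_params(ptr, init)
  structure(
    list(spec = spec, ir = ir, ptr = ptr, seed = as.integer(seed)),
    class = "sononet_model"
  )
}

# He-normal initialization for every conv tensor, in IR order, from one
# seeded stream. Returns the full named parameter list (incl. BN tensors).
init_params <- function(ir, seed) {
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  out <- list()
  for (nd in ir) {
    if (nd$kind == "conv") {
      fan_in <- nd$kernel^2 * nd$`in`
      W <- matrix(stats::rnorm(nd$out * fan_in, sd = sqrt(2 / fan_in)),
                  nrow = nd$out, ncol = fan_in)
      out[[paste0(nd$name, ".W")]] <- W
    } else if (nd$kind == "bn") {
      out[[paste0(nd$name, ".gamma")]] <- rep(1, nd$channels)
      out[[paste0(nd$name, ".beta")]] <- rep(0, nd$channels)
      out[[paste0(nd$name, ".running_mean")]] <- rep(0, nd$channels)
      out[[paste0(nd$name, ".running_var")]] <- rep(1, nd$channels)
    }
  }
  out
}

check_input_batch <- function(model, x) {
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop("input must be an (H, W, N) array of grayscale images", call. = FALSE)
  }
  ms <- min_input_size(model$spec)
  d <- dim(x)
  if (d[1] < ms || d[2] < ms) {
    stop(sprintf(paste0("input %dx%d is too small: '%s' applies %d 2x2 ",
                        "max-pooling stages, so both spatial dimensions must ",
                        "be at least %d"),
                 d[1], d[2], model$spec$name, n_pools(model$spec), ms),
         call. = FALSE)
  }
  invisible(x)
}

#' Run a forward pass
#'
#' The fully convolutional design accepts any input height and width at or
#' above [min_input_size()]; the output shape is `(N, K)` regardless of the
#' spatial size of the batch.
#'
#' @param model A `sononet_model`.
#' @param x Numeric array `(H, W, N)` of grayscale images.
#' @param train Logical; if `TRUE`, batch normalization uses batch statistics
#'   and updates its running averages. Defaults to inference mode.
#' @return An `(N, K)` matrix of class logits.
#' @export
forward <- function(model, x, train = FALSE) {
  stopifnot(inherits(model, "sononet_model"))
  check_input_batch(model, x)
  .net_forward(model$ptr, x, train)
}

#' Predict classes or logits for a batch of images
#'
#' @param object A `sononet_model`.
#' @param x Numeric array `(H, W, N)` in `[0, 1]`; images are standardized
#'   per image (zero mean, unit variance) before the forward pass when
#'   `standardize = TRUE`.
#' @param type `"class"` for 1-based class indices (argmax with lowest-index
#'   tie-break), `"logits"` for the raw score matrix.
#' @param standardize Standardize each image before the forward pass.
#' @param ... Unused.
#' @return Integer vector of class indices, or an `(N, K)` logit matrix.
#' @export
predict.sononet_model <- function(object, x, type = c("class", "logits"),
                                  standardize = TRUE, ...) {
  type <- match.arg(type)
  if (standardize) x <- standardize_batch(x)
  logits <- forward(object, x, train = FALSE)
  if (type == "logits") return(logits)
  apply(logits, 1L, which.max)  # which.max breaks ties at the lowest index
}

# Per-image standardization: zero mean, unit variance (constant images map
# to all zeros rather than dividing by zero).
standardize_batch <- function(x) {
  stopifnot(is.array(x), length(dim(x)) == 3L)
  for (n in seq_len(dim(x)[3])) {
    img <- x[, , n]
    s <- stats::sd(img)
    x[, , n] <- if (s > 0) (img - mean(img)) / s else img * 0
  }
  x
}

#' Extract model parameters as named R arrays
#'
#' Returns every learnable tensor (convolution kernels, batch-norm scales and
#' shifts) plus the batch-norm running statistics, named by layer. The sum of
#' element counts over learnable tensors equals [count_parameters()]'s total
#' exactly.
#'
#' @param model A `sononet_model`.
#' @param learnable_only Drop the (non-trainable) running statistics.
#' @return A named list of numeric matrices/vectors.
#' @export
model_parameters <- function(model, learnable_only = FALSE) {
  stopifnot(inherits(model, "sononet_model"))
  p <- .net_get_params(model$ptr)
  if (learnable_only) {
    keep <- !grepl("\\.running_(mean|var)$", names(p))
    p <- p[keep]
  }
  p
}

#' Overwrite model parameters
#'
#' @param model A `sononet_model`.
#' @param params Named list as returned by [model_parameters()] (with running
#'   statistics included).
#' @return The model, invisibly.
#' @export
set_model_parameters <- function(model, params) {
  stopifnot(inherits(model, "sononet_model"))
  .net_set_params(model$ptr, params)
  invisible(model)
}

#' Gradients from the most recent training step
#'
#' @param model A `sononet_model` that has taken at least one training step.
#' @return Named list of gradient tensors for every learnable tensor.
#' @export
model_gradients <- function(model) {
  stopifnot(inherits(model, "sononet_model"))
  .net_get_grads(model$ptr)
}

#' Names of the feature layers available to GradCAM
#'
#' @param model A `sononet_model`.
#' @return Character vector of node names in the computation graph.
#' @export
layer_names <- function(model) {
  stopifnot(inherits(model, "sononet_model"))
  as.character(.net_node_names(model$ptr))
}

# Default GradCAM target: the rectified output of the last feature block
# (the deepest spatial layer before the adaptation head).
default_gradcam_layer <- function(model) {
  nb <- length(model$spec$blocks)
  last_block <- model$spec$blocks[[nb]]
  if (last_block$type == "lpc") {
    sprintf("block%d.fuse.relu", nb)
  } else {
    sprintf("block%d.conv%d.relu", nb, length(last_block$channels))
  }
}

#' Save a model checkpoint
#'
#' The checkpoint stores the architecture spec, all parameters (including
#' batch-norm running statistics), and optional metadata; [load_checkpoint()]
#' reconstructs a model producing identical predictions.
#'
#' @param model A `sononet_model`.
#' @param path Output file path (RDS).
#' @param history Optional training history to store alongside.
#' @param config Optional training configuration to store alongside.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path, history = NULL, config = NULL) {
  stopifnot(inherits(model, "sononet_model"))
  obj <- list(spec = model$spec, params = model_parameters(model),
              seed = model$seed, history = history, config = config)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path A file written by [save_checkpoint()].
#' @return A `sononet_model`; stored history/config are attached as
#'   attributes `history` and `config`.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  model <- sononet_model(obj$spec, seed = obj$seed)
  set_model_parameters(model, obj$params)
  attr(model, "history") <- obj$history
  attr(model, "config") <- obj$config
  model
}
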