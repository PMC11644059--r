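transform_kinds <- c("hflip", "rotate", "brightness", "contrast", "gaussian_blur")

# Pinned, label-preserving parameter ranges for ultrasound augmentation.
transform_ranges <- list(
  rotate = c(-15, 15),          # degrees, counter-clockwise
  brightness = c(0.7, 1.3),     # multiplicative factor
  contrast = c(0.7, 1.3),       # factor about the image mean
  gaussian_blur = c(0.5, 1.5)   # kernel sigma in pixels
)

#' Construct an augmentation transform specification
#'
#' @param kind One of `"hflip"`, `"rotate"`, `"brightness"`, `"contrast"`,
#'   `"gaussian_blur"`.
#' @param parameter The transform parameter: rotation angle in degrees in
#'   `[-15, 15]`; brightness/contrast factor in `[0.7, 1.3]`; blur sigma in
#'   `[0.5, 1.5]`. `hflip` takes none.
#' @return An object of class `transform_spec`.
#' @export
transform_spec <- function(kind, parameter = NULL) {
  if (!is.character(kind) || length(kind) != 1L || !(kind %in% transform_kinds)) {
    stop(sprintf("unknown transform kind: %s", paste(kind, collapse = ", ")),
         call. = FALSE)
  }
  if (kind == "hflip") {
    if (!is.null(parameter)) stop("hflip takes no parameter", call. = FALSE)
  } else {
    rng <- transform_ranges[[kind]]
    if (!is.numeric(parameter) || length(parameter) != 1L ||
        parameter < rng[1] || parameter > rng[2]) {
      stop(sprintf("%s parameter must be a number in [%g, %g]",
                   kind, rng[1], rng[2]), call. = FALSE)
    }
  }
  structure(list(kind = kind, parameter = parameter), class = "transform_spec")
}

format_transform <- function(spec) {
  if (spec$kind == "hflip") return("hflip")
  pname <- switch(spec$kind, rotate = "angle", gaussian_blur = "sigma", "factor")
  sprintf("%s(%s=%.6g)", spec$kind, pname, spec$parameter)
}

#' @export
print.transform_spec <- function(x, ...) {
  cat("<transform>", format_transform(x), "\n")
  invisible(x)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Apply an augmentation transform to a grayscale image
#'
#' Inputs and outputs are matrices with intensities in `[0, 1]` and identical
#' dimensions. Horizontal flips are exact involutions; rotation is bilinear
#' about the image center (counter-clockwise for positive angles) with
#' exposed corners filled with 0, and a zero angle returns the input
#' bit-exactly; brightness multiplies intensities by the factor; contrast
#' scales deviations from the image mean by the factor; Gaussian blur
#' convolves with a normalized kernel, so constant images are preserved.
#' Outputs are clipped back to `[0, 1]`.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param spec A [transform_spec()].
#' @return Transformed matrix, same dimensions, values in `[0, 1]`.
#' @export
apply_transform <- function(image, spec) {
  if (!inherits(spec, "transform_spec")) {
    if (is.list(spec) && !is.null(spec$kind)) {
      spec <- transform_spec(spec$kind, spec$parameter)
    } else {
      stop("spec must be a transform_spec", call. = FALSE)
    }
  }
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("image must be a numeric matrix", call. = FALSE)
  }
  if (min(image) < 0 || max(image) > 1) {
    stop("image intensities must lie in [0, 1]", call. = FALSE)
  }
  out <- switch(spec$kind,
    hflip = image[, ncol(image):1, drop = FALSE],
    rotate = {
      if (spec$parameter == 0) image
      else {
        r <- EBImage::rotate(EBImage::Image(image), -spec$parameter,
                             output.dim = dim(image), bg.col = 0)
        EBImage::imageData(r)
      }
    },
    brightness = image * spec$parameter,
    contrast = (image - mean(image)) * spec$parameter + mean(image),
    gaussian_blur = EBImage::imageData(
      EBImage::gblur(EBImage::Image(image), sigma = spec$parameter)),
    stop(sprintf("unknown transform kind: %s", spec$kind), call. = FALSE)
  )
  clip01(matrix(out, nrow(image), ncol(image)))
}

# Draw one transform spec from the pinned families, excluding identity
# parameters and any spec already used on the same source image.
sample_transform <- function(existing = character()) {
  for (attempt in 1:100) {
    kinds <- transform_kinds
    if ("hflip" %in% existing) kinds <- setdiff(kinds, "hflip")
    kind <- kinds[sample.int(length(kinds), 1L)]
    spec <- if (kind == "hflip") {
      transform_spec("hflip")
    } else {
      rng <- transform_ranges[[kind]]
      p <- stats::runif(1, rng[1], rng[2])
      identity_p <- switch(kind, rotate = 0, gaussian_blur = NA_real_, 1)
      if (!is.na(identity_p) && p == identity_p) next
      transform_spec(kind, p)
    }
    if (!(format_transform(spec) %in% existing)) return(spec)
  }
  stop("could not draw a fresh transform spec after 100 attempts", call. = FALSE)
}
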