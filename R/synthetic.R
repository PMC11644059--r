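#' Standard-plane category labels
#'
#' The six-category scheme distinguishes abdomen, brain, femur, thorax,
#' maternal cervix and other; the nine-category scheme splits the brain into
#' its trans-ventricular, trans-thalamic, trans-cerebellum and other-brain
#' axial planes.
#'
#' @param scheme `"nine"` or `"six"`.
#' @return Character vector of lowercase snake-case category tokens.
#' @export
plane_categories <- function(scheme = c("nine", "six")) {
  scheme <- match.arg(scheme)
  if (scheme == "six") {
    c("abdomen", "brain", "femur", "thorax", "maternal_cervix", "other")
  } else {
    c("abdomen", "trans_ventricular", "trans_thalamic", "trans_cerebellum",
      "other_brain", "femur", "thorax", "maternal_cervix", "other")
  }
}

phantom_category_set <- function() unique(c(plane_categories("nine"), "brain"))

#' Default geometry jitter for phantom generation
#'
#' @param center Maximum center offset as a fraction of the half-image.
#' @param scale Two-element range of the global size factor.
#' @param rotation Maximum rotation in degrees for most categories.
#' @param femur_rotation Maximum rotation in degrees for the femur bar, which
#'   tolerates (and clinically shows) much larger obliquity.
#' @return A list of jitter parameters.
#' @export
phantom_jitter <- function(center = 0.08, scale = c(0.9, 1.1),
                           rotation = 10, femur_rotation = 30) {
  list(center = center, scale = scale, rotation = rotation,
       femur_rotation = femur_rotation)
}

#' Generate one synthetic ultrasound phantom image
#'
#' Draws a grayscale image in `[0, 1]` whose geometry is discriminative for
#' the requested standard-plane category: abdomen, a bright-rimmed disc with
#' one dark interior blob (stomach bubble); the brain planes, a bright
#' elliptical rim (skull) whose interior carries the plane-specific
#' structure (an off-axis dark slit for trans-ventricular, central paired
#' blobs for trans-thalamic, a posterior dumbbell for trans-cerebellum,
#' nothing for other-brain); femur, a bright elongated bar at a jittered
#' angle; thorax, a disc with an interior cross; maternal cervix, a bright
#' narrowing wedge band; other, a featureless speckle field. The six-class
#' `"brain"` label reuses the trans-thalamic geometry.
#'
#' Speckle is applied multiplicatively, `pixel <- clip(pixel * (1 + s * eta))`
#' with per-pixel standard-normal `eta`, emulating the signal-dependent
#' granular noise of ultrasound. Geometry jitter (center offset, scale,
#' rotation) is drawn before any category-specific parameter, so phantoms of
#' different categories generated from the same seed share their outline.
#'
#' @param category One of [plane_categories()] (either scheme).
#' @param image_size `(H, W)` in pixels, each at least 32.
#' @param speckle Speckle strength `s >= 0`.
#' @param seed Integer seed; the image is a pure function of the arguments.
#' @param jitter Geometry jitter parameters, see [phantom_jitter()].
#' @return An `H x W` matrix in `[0, 1]` with attributes `category` and (for
#'   categories with a localized structure) `roi`, the bounding box of the
#'   discriminative structure as `c(row_min, row_max, col_min, col_max)`.
#' @examples
#' img <- generate_image("femur", c(64, 64), speckle = 0, seed = 7)
#' attr(img, "roi")
#' @export
generate_image <- function(category, image_size = c(64L, 64L), speckle = 0.1,
                           seed = 1L, jitter = phantom_jitter()) {
  if (!is.character(category) || length(category) != 1L ||
      !(category %in% phantom_category_set())) {
    stop(sprintf("unknown phantom category: %s",
                 paste(category, collapse = ", ")), call. = FALSE)
  }
  if (length(image_size) == 1L) image_size <- c(image_size, image_size)
  H <- as.integer(image_size[1]); W <- as.integer(image_size[2])
  if (H < 32L || W < 32L) stop("image_size must be at least 32x32", call. = FALSE)
  if (!is.numeric(speckle) || speckle < 0) stop("speckle must be >= 0", call. = FALSE)

  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  # shared outline jitter, drawn in fixed order before category extras
  dx <- stats::runif(1, -jitter$center, jitter$center)
  dy <- stats::runif(1, -jitter$center, jitter$center)
  sc <- stats::runif(1, jitter$scale[1], jitter$scale[2])
  rot_max <- if (category == "femur") jitter$femur_rotation else jitter$rotation
  th <- stats::runif(1, -rot_max, rot_max) * pi / 180

  # normalized coordinates in [-1, 1], rotated about the jittered center
  xs <- (seq_len(W) - (W + 1) / 2) / (W / 2) - dx
  ys <- (seq_len(H) - (H + 1) / 2) / (H / 2) - dy
  X <- matrix(xs, H, W, byrow = TRUE)
  Y <- matrix(ys, H, W)
  U <- cos(th) * X + sin(th) * Y
  V <- -sin(th) * X + cos(th) * Y

  img <- matrix(0.10, H, W)
  roi <- NULL
  bbox <- function(mask) {
    rows <- which(rowSums(mask) > 0); cols <- which(colSums(mask) > 0)
    c(row_min = min(rows), row_max = max(rows),
      col_min = min(cols), col_max = max(cols))
  }

  if (category == "other") {
    img[] <- 0.35
  } else if (category == "femur") {
    bar <- abs(U) < 0.75 * sc & abs(V) < 0.07 * sc
    img[bar] <- 0.90
    roi <- bbox(bar)
  } else if (category %in% c("abdomen", "thorax")) {
    R <- if (category == "abdomen") 0.68 * sc else 0.56 * sc
    r <- sqrt(U^2 + V^2)
    interior <- r < R - 0.05
    img[interior] <- if (category == "abdomen") 0.50 else 0.30
    img[abs(r - R) <= 0.05] <- if (category == "abdomen") 0.80 else 0.75
    if (category == "abdomen") {
      phi <- stats::runif(1, 0, 2 * pi)
      bu <- 0.35 * R * cos(phi); bv <- 0.35 * R * sin(phi)
      blob <- (U - bu)^2 + (V - bv)^2 < (0.22 * R)^2
      img[blob & interior] <- 0.15
      roi <- bbox(blob & interior)
    } else {
      cross <- (abs(U) < 0.09 * R & abs(V) < 0.62 * R) |
        (abs(V) < 0.09 * R & abs(U) < 0.62 * R)
      img[cross & interior] <- 0.65
      roi <- bbox(cross & interior)
    }
  } else if (category == "maternal_cervix") {
    half_w <- 0.32 - 0.20 * (U + 1) / 2
    band <- abs(V) < half_w & abs(U) < 0.95
    img[band] <- 0.80
    roi <- bbox(band)
  } else {
    # brain family: shared elliptical skull rim
    a <- 0.75 * sc; b <- 0.55 * sc
    e <- sqrt((U / a)^2 + (V / b)^2)
    rim <- abs(e - 1) < 0.09
    interior <- e < 1 - 0.09
    img[interior] <- 0.35
    img[rim] <- 0.85
    if (category == "trans_ventricular") {
      slit <- interior & abs(U) < 0.45 * a & abs(V - 0.35 * b) < 0.10 * b
      img[slit] <- 0.12
      roi <- bbox(slit)
    } else if (category %in% c("trans_thalamic", "brain")) {
      blobs <- interior &
        (((U - 0.20 * a)^2 + V^2 < (0.17 * b)^2) |
           ((U + 0.20 * a)^2 + V^2 < (0.17 * b)^2))
      img[blobs] <- 0.65
      roi <- bbox(blobs)
    } else if (category == "trans_cerebellum") {
      dumb <- interior &
        (((U - 0.24 * a)^2 + (V - 0.45 * b)^2 < (0.15 * b)^2) |
           ((U + 0.24 * a)^2 + (V - 0.45 * b)^2 < (0.15 * b)^2) |
           (abs(U) < 0.24 * a & abs(V - 0.45 * b) < 0.08 * b))
      img[dumb] <- 0.65
      roi <- bbox(dumb)
    }
    # other_brain: rim only
  }

  if (speckle > 0) {
    eta <- matrix(stats::rnorm(H * W), H, W)
    img <- img * (1 + speckle * eta)
  }
  img <- pmin(pmax(img, 0), 1)
  attr(img, "category") <- category
  if (!is.null(roi)) attr(img, "roi") <- roi
  img
}

#' Per-category image counts for phantom datasets
#'
#' Shipped presets mirror the class imbalance of the public fetal-plane
#' collection this generator stands in for: `"table1"` carries the
#' six-category totals (711, 3092, 1040, 1718, 1626, 4213) and `"table2"`
#' the nine-category totals (711, 597, 1638, 714, 143, 1040, 1718, 1626,
#' 4213); `"tiny"` is a balanced 10 per category for smoke tests. A `scale`
#' factor shrinks the profile while preserving the imbalance (counts are
#' rounded, minimum 1).
#'
#' @param preset `"table1"`, `"table2"` or `"tiny"`.
#' @param scale Positive multiplier applied to the preset counts.
#' @return Named integer vector of per-category counts.
#' @examples
#' phantom_counts("table2", scale = 0.1)
#' @export
phantom_counts <- function(preset = c("table2", "table1", "tiny"), scale = 1) {
  preset <- match.arg(preset)
  counts <- switch(preset,
    table1 = c(abdomen = 711, brain = 3092, femur = 1040, thorax = 1718,
               maternal_cervix = 1626, other = 4213),
    table2 = c(abdomen = 711, trans_ventricular = 597, trans_thalamic = 1638,
               trans_cerebellum = 714, other_brain = 143, femur = 1040,
               thorax = 1718, maternal_cervix = 1626, other = 4213),
    tiny = stats::setNames(rep(10, 9), plane_categories("nine"))
  )
  if (scale != 1) counts <- pmax(round(counts * scale), 1L)
  stats::setNames(as.integer(counts), names(counts))
}

#' Generate a phantom image dataset on disk
#'
#' Writes `counts[c]` 8-bit grayscale PNG images for each category `c` with
#' deterministically derived per-image seeds, and returns a manifest listing
#' every file. The manifest has no split assignment yet; see [make_split()].
#'
#' @param counts Named vector of per-category counts; names must be phantom
#'   categories. Zero-count categories are simply absent from the output.
#' @param out_dir Output directory (created if needed).
#' @param image_size `(H, W)` in pixels.
#' @param speckle Speckle strength, see [generate_image()].
#' @param seed Integer master seed; the dataset is a pure function of
#'   `(counts, image_size, speckle, seed)`.
#' @param jitter Geometry jitter parameters.
#' @return A manifest data frame with columns `path`, `category`, `split`
#'   (`NA`), `provenance` (`"original"`).
#' @export
generate_dataset <- function(counts, out_dir, image_size = c(64L, 64L),
                             speckle = 0.1, seed = 1L,
                             jitter = phantom_jitter()) {
  if (is.null(names(counts)) || !all(names(counts) %in% phantom_category_set())) {
    stop("counts must be a named vector over phantom categories", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  idx <- 0L
  for (cat in names(counts)) {
    n <- as.integer(counts[[cat]])
    if (n == 0L) next
    for (k in seq_len(n)) {
      idx <- idx + 1L
      img_seed <- as.integer((as.numeric(seed) * 1000003 + idx) %% 2147483647)
      img <- generate_image(cat, image_size, speckle, img_seed, jitter)
      path <- file.path(out_dir, sprintf("%s_%04d.png", cat, k))
      png::writePNG(img, path)
      rows[[idx]] <- data.frame(path = path, category = cat,
                                split = NA_character_,
                                provenance = "original",
                                stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
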