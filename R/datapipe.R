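#' Read or write a dataset manifest
#'
#' A manifest is the single source of truth for split membership and
#' augmentation bookkeeping: a UTF-8 CSV with header
#' `path,category,split,provenance`, one record per image. Categories are
#' lowercase snake-case tokens; `split` is `train`, `val`, `test` or empty;
#' `provenance` is `"original"` or an `augmented(...)` tag naming the source
#' image and transform.
#'
#' @param path CSV file path.
#' @param manifest A manifest data frame.
#' @return `read_manifest()` returns the manifest data frame;
#'   `write_manifest()` returns `path` invisibly.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("path", "category", "split", "provenance")
  if (!all(required %in% names(m))) {
    stop("manifest must have columns path, category, split, provenance",
         call. = FALSE)
  }
  m$split[m$split == ""] <- NA_character_
  m[required]
}

#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  m <- manifest
  m$split[is.na(m$split)] <- ""
  utils::write.csv(m, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

check_manifest <- function(manifest) {
  if (!is.data.frame(manifest) ||
      !all(c("path", "category", "split", "provenance") %in% names(manifest))) {
    stop("manifest must be a data frame with columns path, category, split, provenance",
         call. = FALSE)
  }
  bad <- is.na(manifest$category) | manifest$category == ""
  if (any(bad)) {
    stop(sprintf("manifest has %d unlabeled record(s) (first: %s)",
                 sum(bad), manifest$path[which(bad)[1]]), call. = FALSE)
  }
  invisible(manifest)
}

#' Split a manifest into train/validation/test sets per category
#'
#' Performs a stratified random partition. With the default 8:1:1 ratios
#' each category contributes `floor(0.8 n)` training images; the remainder
#' is split validation-first (`ceil(rem/2)` validation, the rest test).
#' Assignment within a category is randomized by `seed` and fully
#' deterministic given it. Alternatively an explicit per-category counts
#' table is honored verbatim (columns `category`, `train`, `val`, `test`),
#' which reproduces published split tables whose rounding differs by one.
#'
#' @param manifest A manifest data frame (split column is overwritten).
#' @param ratios Positive length-3 weights for train/val/test.
#' @param seed Integer seed for the within-category shuffling.
#' @param counts Optional explicit counts data frame; each row must sum to
#'   the category's total in the manifest.
#' @return A list with `manifest` (split column filled) and `plan` (a data
#'   frame with per-category `n_train`, `n_val`, `n_test`).
#' @examples
#' # a category of 1040 images divides as 832 / 104 / 104
#' @export
make_split <- function(manifest, ratios = c(8, 1, 1), seed = 1L, counts = NULL) {
  check_manifest(manifest)
  if (length(ratios) != 3L || any(ratios <= 0)) {
    stop("ratios must be three positive numbers", call. = FALSE)
  }
  p <- ratios / sum(ratios)
  cats <- sort(unique(manifest$category))
  if (!is.null(counts)) {
    if (!all(c("category", "train", "val", "test") %in% names(counts))) {
      stop("counts must have columns category, train, val, test", call. = FALSE)
    }
    missing_cat <- setdiff(cats, counts$category)
    if (length(missing_cat)) {
      stop(sprintf("counts table lacks categories: %s",
                   paste(missing_cat, collapse = ", ")), call. = FALSE)
    }
  }
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  manifest$split <- NA_character_
  plan <- data.frame(category = cats, n_total = 0L, n_train = 0L,
                     n_val = 0L, n_test = 0L, stringsAsFactors = FALSE)
  for (i in seq_along(cats)) {
    idx <- which(manifest$category == cats[i])
    n <- length(idx)
    if (is.null(counts)) {
      n_train <- floor(p[1] * n)
      rem <- n - n_train
      n_val <- ceiling(rem * p[2] / (p[2] + p[3]))
      n_test <- rem - n_val
    } else {
      row <- counts[counts$category == cats[i], ][1, ]
      n_train <- as.integer(row$train); n_val <- as.integer(row$val)
      n_test <- as.integer(row$test)
      if (n_train + n_val + n_test != n) {
        stop(sprintf("explicit counts for '%s' sum to %d but the manifest has %d images",
                     cats[i], n_train + n_val + n_test, n), call. = FALSE)
      }
    }
    perm <- idx[sample.int(n)]
    manifest$split[perm[seq_len(n_train)]] <- "train"
    if (n_val > 0) manifest$split[perm[n_train + seq_len(n_val)]] <- "val"
    if (n_test > 0) manifest$split[perm[n_train + n_val + seq_len(n_test)]] <- "test"
    plan[i, c("n_total", "n_train", "n_val", "n_test")] <-
      c(n, n_train, n_val, n_test)
  }
  attr(plan, "ratios") <- ratios
  attr(plan, "seed") <- as.integer(seed)
  list(manifest = manifest, plan = plan)
}

#' Plan augmentation jobs that bring each category to a target count
#'
#' Augmentation applies only to the training split. For each category with a
#' target, the deficit `d = target - n_originals` is distributed round-robin
#' over the category's source images in a seeded order: each source receives
#' `floor(d/n)` jobs and the first `d mod n` sources (in that order) one
#' more. Each job draws a transform from the pinned families ([apply_transform()])
#' through the same seeded stream; identity parameters are excluded and no
#' two jobs on one source share an identical spec. The plan is a pure
#' function of `(manifest, targets, seed)`.
#'
#' @param manifest A manifest with split assignments.
#' @param targets Named vector of per-category target training counts; each
#'   target must be at least the category's current training count.
#' @param seed Integer seed.
#' @return An object of class `augmentation_plan`: list with `jobs` (data
#'   frame: `category`, `source_path`, `job_index`, `kind`, `parameter`,
#'   `spec`), `targets`, `seed`.
#' @export
plan_augmentation <- function(manifest, targets, seed = 1L) {
  check_manifest(manifest)
  if (is.null(names(targets)) || any(names(targets) == "")) {
    stop("targets must be a named vector of per-category counts", call. = FALSE)
  }
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  train <- manifest[manifest$split %in% "train" &
                      manifest$provenance == "original", , drop = FALSE]
  jobs <- list()
  for (cat in sort(names(targets))) {
    target <- as.integer(targets[[cat]])
    src <- train$path[train$category == cat]
    n <- length(src)
    if (target < n) {
      stop(sprintf("invalid target for category '%s': %d is below the %d training originals",
                   cat, target, n), call. = FALSE)
    }
    d <- target - n
    if (d == 0L) next
    if (n == 0L) {
      stop(sprintf("invalid target for category '%s': no training originals to augment",
                   cat), call. = FALSE)
    }
    perm <- sample.int(n)
    per_source <- rep(d %/% n, n)
    extra <- d %% n
    if (extra > 0) per_source[seq_len(extra)] <- per_source[seq_len(extra)] + 1L
    for (i in seq_len(n)) {
      if (per_source[i] == 0L) next
      path_i <- src[perm[i]]
      used <- character()
      for (j in seq_len(per_source[i])) {
        sp <- sample_transform(used)
        used <- c(used, format_transform(sp), sp$kind)
        jobs[[length(jobs) + 1L]] <- data.frame(
          category = cat, source_path = path_i, job_index = j,
          kind = sp$kind,
          parameter = if (is.null(sp$parameter)) NA_real_ else sp$parameter,
          spec = format_transform(sp), stringsAsFactors = FALSE)
      }
    }
  }
  jobs <- if (length(jobs)) {
    do.call(rbind, c(jobs, list(make.row.names = FALSE)))
  } else {
    data.frame(category = character(), source_path = character(),
               job_index = integer(), kind = character(),
               parameter = numeric(), spec = character(),
               stringsAsFactors = FALSE)
  }
  structure(list(jobs = jobs, targets = targets, seed = as.integer(seed)),
            class = "augmentation_plan")
}

#' @export
print.augmentation_plan <- function(x, ...) {
  cat(sprintf("<augmentation plan> %d jobs over %d categories (seed %d)\n",
              nrow(x$jobs), length(unique(x$jobs$category)), x$seed))
  if (nrow(x$jobs)) print(table(x$jobs$category))
  invisible(x)
}

read_gray_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:3, drop = FALSE], c(1, 2), mean)
  img
}

#' Execute an augmentation plan
#'
#' Reads each source image, applies the planned transform, and writes the
#' augmented image as an 8-bit grayscale PNG named
#' `<source stem>_aug<job index>_<kind>.png` under `out_dir`. Original,
#' validation and test records are untouched; the returned manifest appends
#' one `train` record per job with an `augmented(...)` provenance tag, so
#' per-category training counts equal the planned targets exactly.
#' Re-running with the same plan reproduces byte-identical file names and
#' manifest ordering.
#'
#' @param manifest The manifest the plan was built from.
#' @param plan An [plan_augmentation()] result.
#' @param out_dir Directory for augmented images (created if needed).
#' @return The augmented manifest data frame.
#' @export
execute_plan <- function(manifest, plan, out_dir) {
  check_manifest(manifest)
  stopifnot(inherits(plan, "augmentation_plan"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jobs <- plan$jobs
  if (nrow(jobs) == 0L) return(manifest)
  rows <- vector("list", nrow(jobs))
  for (i in seq_len(nrow(jobs))) {
    job <- jobs[i, ]
    img <- tryCatch(read_gray_png(job$source_path), error = function(e) {
      stop(sprintf("augmentation aborted at job %d/%d: cannot read %s (%s); %d image(s) were already written to %s",
                   i, nrow(jobs), job$source_path, conditionMessage(e),
                   i - 1L, out_dir), call. = FALSE)
    })
    sp <- if (job$kind == "hflip") transform_spec("hflip") else
      transform_spec(job$kind, job$parameter)
    out <- apply_transform(img, sp)
    stem <- sub("\\.[^.]*$", "", basename(job$source_path))
    dest <- file.path(out_dir, sprintf("%s_aug%02d_%s.png", stem,
                                       job$job_index, job$kind))
    png::writePNG(out, dest)
    rows[[i]] <- data.frame(
      path = dest, category = job$category, split = "train",
      provenance = sprintf("augmented(src=%s; %s)", basename(job$source_path),
                           job$spec),
      stringsAsFactors = FALSE)
  }
  rbind(manifest, do.call(rbind, c(rows, list(make.row.names = FALSE))))
}
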