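# Shared fixtures. Heavy objects (trained fits, phantom datasets) are built
# once per test run and cached, so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

nine_cats <- function() plane_categories("nine")

# Small phantom dataset written to a tempdir; cached by its parameters.
phantom_dataset <- function(n_per_cat, image_size = c(32L, 32L), speckle = 0.1,
                            seed = 1L, categories = nine_cats()) {
  key <- paste("ds", n_per_cat, paste(image_size, collapse = "x"), speckle,
               seed, paste(categories, collapse = "+"), sep = "_")
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  dir <- file.path(tempdir(), paste0("lpcsononet_", substr(digest_key(key), 1, 12)))
  counts <- stats::setNames(rep(as.integer(n_per_cat), length(categories)),
                            categories)
  man <- generate_dataset(counts, dir, image_size = image_size,
                          speckle = speckle, seed = seed)
  .fixture_cache[[key]] <- man
  man
}

digest_key <- function(x) {
  # tiny stable hash (sum of char codes in two rolling bases); enough to
  # keep tempdir names distinct within one run
  v <- utf8ToInt(x)
  sprintf("%08x%08x", sum(v * seq_along(v)) %% .Machine$integer.max,
          sum(v * rev(seq_along(v))) %% .Machine$integer.max)
}

# The scaled-down convergence experiment: LPC-SonoNet on 9-class 64x64
# phantoms at speckle 0.1, batch 32, initial lr 0.001 decayed x10 every 5
# epochs; 40/class training and 15/class validation images, 6 epochs.
convergence_config <- function(seed) {
  train_config(epochs = 6L, initial_lr = 0.001, decay_factor = 10,
               decay_every = 5L, batch_size = 32L, input_size = c(64L, 64L),
               seed = seed)
}

convergence_fit <- function(seed) {
  key <- paste0("fit_", seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  man <- phantom_dataset(55L, image_size = c(64L, 64L), speckle = 0.1,
                         seed = seed)
  split_counts <- data.frame(category = nine_cats(), train = 40L, val = 15L,
                             test = 0L)
  sp <- make_split(man, seed = seed, counts = split_counts)
  fit <- train_network(build_lpc_sononet(9), sp$manifest,
                       convergence_config(seed))
  .fixture_cache[[key]] <- fit
  fit
}

convergence_seeds <- function() c(401L, 402L, 403L)

# Brute-force metric recomputation straight from raw label vectors, kept
# deliberately independent of confusion()/classification_metrics().
brute_force_metrics <- function(true, pred, K) {
  acc <- mean(true == pred)
  sens <- spec <- rep(NA_real_, K)
  for (c in seq_len(K)) {
    tp <- sum(true == c & pred == c)
    fn <- sum(true == c & pred != c)
    fp <- sum(true != c & pred == c)
    tn <- sum(true != c & pred != c)
    if (tp + fn > 0) sens[c] <- tp / (tp + fn)
    spec[c] <- tn / (tn + fp)
  }
  list(accuracy = acc, sensitivity = mean(sens, na.rm = TRUE),
       specificity = mean(spec))
}

# A manifest of n tiny images per category already marked "train", for
# augmentation tests that need real files.
train_only_manifest <- function(per_cat_counts, seed = 7L) {
  dir <- file.path(tempdir(),
                   paste0("aug_", substr(digest_key(paste(
                     names(per_cat_counts), per_cat_counts, seed,
                     collapse = "_")), 1, 12)))
  man <- generate_dataset(per_cat_counts, dir, image_size = c(32L, 32L),
                          speckle = 0.05, seed = seed)
  man$split <- "train"
  man
}
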