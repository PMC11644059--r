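fake_manifest <- function(counts) {
  do.call(rbind, lapply(names(counts), function(cat) {
    n <- counts[[cat]]
    data.frame(path = sprintf("%s_%04d.png", cat, seq_len(n)),
               category = cat, split = NA_character_,
               provenance = "original", stringsAsFactors = FALSE)
  }))
}

test_that("8:1:1 split counts follow the floor/ceil rule on published totals", {
  man <- fake_manifest(c(femur = 1040, abdomen = 711, ten = 10))
  sp <- make_split(man, seed = 1)
  plan <- sp$plan
  expect_equal(unlist(plan[plan$category == "femur", c("n_train", "n_val", "n_test")],
                      use.names = FALSE), c(832, 104, 104))
  expect_equal(unlist(plan[plan$category == "abdomen", c("n_train", "n_val", "n_test")],
                      use.names = FALSE), c(568, 72, 71))
  expect_equal(unlist(plan[plan$category == "ten", c("n_train", "n_val", "n_test")],
                      use.names = FALSE), c(8, 1, 1))
})

test_that("splits partition every category, deterministically in the seed", {
  set.seed(99)
  for (rep in 1:10) {
    counts <- stats::setNames(sample(1:200, 4), paste0("c", 1:4))
    man <- fake_manifest(counts)
    seed <- sample.int(1e6, 1)
    sp <- make_split(man, seed = seed)
    expect_false(anyNA(sp$manifest$split))
    for (cat in names(counts)) {
      sub <- sp$manifest[sp$manifest$category == cat, ]
      expect_equal(nrow(sub), counts[[cat]])
      expect_equal(anyDuplicated(sub$path), 0L)
    }
    expect_identical(make_split(man, seed = seed)$manifest, sp$manifest)
    if (min(counts) >= 10) {
      expect_false(identical(make_split(man, seed = seed + 1)$manifest,
                             sp$manifest))
    }
  }
})

test_that("explicit-counts mode mirrors a published table verbatim", {
  man <- fake_manifest(c(brain = 3092))
  counts <- data.frame(category = "brain", train = 2472, val = 310, test = 310)
  sp <- make_split(man, seed = 3, counts = counts)
  expect_equal(unlist(sp$plan[1, c("n_train", "n_val", "n_test")],
                      use.names = FALSE), c(2472, 310, 310))
  bad <- data.frame(category = "brain", train = 2000, val = 310, test = 310)
  expect_error(make_split(man, seed = 3, counts = bad), "sum to 2620")
  man$category[5] <- NA
  expect_error(make_split(man, seed = 3), "unlabeled")
})

test_that("augmentation plans distribute the deficit round-robin", {
  # 114 originals to 1368: deficit 1254 = 11 jobs for every original
  man <- fake_manifest(c(other_brain = 114))
  man$split <- "train"
  plan <- plan_augmentation(man, c(other_brain = 1368), seed = 2)
  expect_equal(nrow(plan$jobs), 1254L)
  per_src <- table(plan$jobs$source_path)
  expect_equal(length(per_src), 114L)
  expect_true(all(per_src == 11))

  # 568 originals to 1300: 732 jobs; 164 sources get 2, 404 get 1
  man2 <- fake_manifest(c(abdominal = 568))
  man2$split <- "train"
  plan2 <- plan_augmentation(man2, c(abdominal = 1300), seed = 2)
  expect_equal(nrow(plan2$jobs), 732L)
  per_src2 <- table(table(plan2$jobs$source_path))
  expect_equal(unname(per_src2[["1"]]), 404L)
  expect_equal(unname(per_src2[["2"]]), 164L)

  # a target equal to the original count plans nothing
  plan3 <- plan_augmentation(man2, c(abdominal = 568), seed = 2)
  expect_equal(nrow(plan3$jobs), 0L)
  expect_error(plan_augmentation(man2, c(abdominal = 100), seed = 2),
               "invalid target for category 'abdominal'")
})

test_that("planned transforms never repeat on one source and exclude identities", {
  man <- fake_manifest(c(cat_a = 3))
  man$split <- "train"
  plan <- plan_augmentation(man, c(cat_a = 40), seed = 11)
  for (src in unique(plan$jobs$source_path)) {
    specs <- plan$jobs$spec[plan$jobs$source_path == src]
    expect_equal(anyDuplicated(specs), 0L)
    expect_lte(sum(specs == "hflip"), 1L)
  }
  expect_false(any(plan$jobs$kind == "rotate" & plan$jobs$parameter == 0))
  expect_false(any(plan$jobs$kind %in% c("brightness", "contrast") &
                     plan$jobs$parameter == 1))
  # plans are pure functions of (manifest, targets, seed); a different seed
  # changes at least one drawn transform (checked over 10 seeds)
  again <- plan_augmentation(man, c(cat_a = 40), seed = 11)
  expect_identical(again$jobs, plan$jobs)
  for (s in 12:21) {
    other <- plan_augmentation(man, c(cat_a = 40), seed = s)
    expect_false(identical(other$jobs$spec, plan$jobs$spec))
  }
})

test_that("executing a plan reaches targets exactly and leaves val/test alone", {
  counts <- c(femur = 4L, thorax = 6L, other = 8L)
  man <- generate_dataset(counts, withr::local_tempdir(),
                          image_size = c(32, 32), speckle = 0.05, seed = 31)
  sp <- make_split(man, ratios = c(2, 1, 1), seed = 31)
  targets <- c(femur = 7L, thorax = 9L)
  plan <- plan_augmentation(sp$manifest, targets, seed = 31)
  out_dir <- withr::local_tempdir()
  aug <- execute_plan(sp$manifest, plan, out_dir)

  for (cat in names(targets)) {
    n_train <- sum(aug$category == cat & aug$split == "train")
    expect_equal(n_train, unname(targets[[cat]]))
  }
  # untouched: originals, val and test rows identical
  expect_identical(aug[seq_len(nrow(sp$manifest)), ], sp$manifest)
  expect_identical(aug[aug$split %in% c("val", "test"), ],
                   sp$manifest[sp$manifest$split %in% c("val", "test"), ])
  # augmented records only in train, with provenance tags and real files
  added <- aug[-seq_len(nrow(sp$manifest)), ]
  expect_true(all(added$split == "train"))
  expect_true(all(grepl("^augmented\\(src=", added$provenance)))
  expect_true(all(file.exists(added$path)))
  # each augmented image differs from its source
  src_of <- sub("^augmented\\(src=([^;]+);.*$", "\\1", added$provenance)
  for (i in seq_len(nrow(added))) {
    src_path <- man$path[basename(man$path) == src_of[i]]
    expect_false(identical(png::readPNG(added$path[i]), png::readPNG(src_path)))
  }
  # deterministic re-run: same file names, same manifest
  aug2 <- execute_plan(sp$manifest, plan, withr::local_tempdir())
  expect_identical(basename(aug2$path), basename(aug$path))
  # an empty plan is a no-op
  none <- plan_augmentation(sp$manifest, c(femur = sum(sp$manifest$category == "femur" &
                                                        sp$manifest$split == "train")),
                            seed = 1)
  expect_identical(execute_plan(sp$manifest, none, out_dir), sp$manifest)
})

test_that("manifests round-trip through CSV", {
  man <- fake_manifest(c(a = 3, b = 2))
  man$split <- c("train", "val", NA, "test", "train")
  path <- withr::local_tempfile(fileext = ".csv")
  write_manifest(man, path)
  back <- read_manifest(path)
  expect_identical(back, man)
  header <- readLines(path, n = 1)
  expect_match(header, "path", fixed = TRUE)
})
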