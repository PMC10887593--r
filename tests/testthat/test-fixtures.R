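test_that("generator writes the split/class layout with the requested counts", {
  fx <- small_dataset(image_size = 32, n_train = 10, n_val = 4, n_test = 4)
  man <- fx$manifest
  expect_equal(nrow(man), 2 * (10 + 4 + 4))
  expect_setequal(unique(man$split), c("train", "val", "test"))
  tr <- subset_manifest(man, "train")
  expect_equal(unname(class_counts(tr)), c(10L, 10L))
  expect_named(class_counts(tr), c("normal", "pneumonia"))
  expect_true(all(file.exists(man$path)))
})

test_that("a zero-count config yields an empty manifest but the class dirs exist", {
  dir <- file.path(tempdir(), "pn-empty")
  cfg <- synthetic_config(n_train = 0, n_val = 0, n_test = 0, image_size = 16)
  man <- generate_synthetic_dataset(cfg, dir)
  expect_equal(nrow(man), 0L)
  expect_true(dir.exists(file.path(dir, "train", "normal")))
  expect_true(dir.exists(file.path(dir, "test", "pneumonia")))
})

test_that("identical config and seed reproduce byte-identical image files", {
  d1 <- file.path(tempdir(), "pn-det1"); d2 <- file.path(tempdir(), "pn-det2")
  cfg <- synthetic_config(n_train = 2, n_val = 1, n_test = 1, image_size = 24,
                          blob_sigma = 2, seed = 7)
  m1 <- generate_synthetic_dataset(cfg, d1)
  m2 <- generate_synthetic_dataset(cfg, d2)
  expect_equal(nrow(m1), nrow(m2))
  for (i in seq_len(nrow(m1))) {
    expect_identical(readBin(m1$path[i], "raw", 1e6), readBin(m2$path[i], "raw", 1e6))
  }
})

test_that("generate -> load round-trips counts, labels and sorted order", {
  fx <- small_dataset(image_size = 32, n_train = 25, n_val = 2, n_test = 2,
                      seed = 5)
  man <- load_image_directory(file.path(fx$dir, "train"))
  expect_equal(nrow(man), 50L)
  expect_equal(unname(class_counts(man)), c(25L, 25L))
  expect_identical(man$path, sort(man$path))
  expect_length(attr(man, "skipped"), 0L)
  expect_equal(man$split[1], "train")
})

test_that("loader enforces exactly two class subdirectories", {
  root <- file.path(tempdir(), "pn-threeclass")
  for (d in c("a", "b", "c")) dir.create(file.path(root, d), recursive = TRUE,
                                         showWarnings = FALSE)
  expect_error(load_image_directory(root), "exactly 2")
  root2 <- file.path(tempdir(), "pn-emptyclasses")
  for (d in c("normal", "pneumonia")) dir.create(file.path(root2, d),
                                                 recursive = TRUE,
                                                 showWarnings = FALSE)
  man <- load_image_directory(root2)
  expect_equal(nrow(man), 0L)
})

test_that("undecodable files go to the skip report, not silently dropped", {
  fx <- small_dataset()
  root <- file.path(tempdir(), "pn-skip")
  for (d in c("normal", "pneumonia")) dir.create(file.path(root, d),
                                                 recursive = TRUE,
                                                 showWarnings = FALSE)
  ok <- fx$manifest$path[fx$manifest$label == "normal"][1]
  file.copy(ok, file.path(root, "normal", "ok.png"))
  writeLines("this is not an image", file.path(root, "pneumonia", "bad.png"))
  man <- load_image_directory(root)
  expect_equal(nrow(man), 1L)
  expect_length(attr(man, "skipped"), 1L)
  expect_match(attr(man, "skipped"), "bad.png")
})

test_that("pneumonia images are brighter on average than normal images", {
  fx <- small_dataset(image_size = 64, n_train = 8, n_val = 2, n_test = 2,
                      seed = 3, blob_sigma = 3)
  tr <- subset_manifest(fx$manifest, "train")
  means <- vapply(tr$path, function(p) mean(read_image(p)), numeric(1))
  mn <- mean(means[tr$label == "normal"])
  mp <- mean(means[tr$label == "pneumonia"])
  expect_gt(mp, mn)
  # per-image, not just on average
  expect_true(min(means[tr$label == "pneumonia"]) > max(means[tr$label == "normal"]) - 2)
})

test_that("manifest CSV export round-trips", {
  fx <- small_dataset()
  p <- file.path(tempdir(), "man.csv")
  write_manifest_csv(fx$manifest, p)
  back <- read_manifest_csv(p)
  expect_equal(back$path, fx$manifest$path)
  expect_equal(back$label, fx$manifest$label)
})

test_that("imbalanced named counts mirror the study proportions", {
  sc <- study_split_counts(scale = 0.02)
  expect_equal(unname(sc$n_train), c(ceiling(1341 * 0.02), ceiling(3875 * 0.02)))
  expect_equal(unname(sc$n_test), c(ceiling(234 * 0.02), ceiling(390 * 0.02)))
  d <- file.path(tempdir(), "pn-imb")
  cfg <- synthetic_config(n_train = c(normal = 3, pneumonia = 8),
                          n_val = 1, n_test = 1, image_size = 16)
  man <- generate_synthetic_dataset(cfg, d)
  tr <- subset_manifest(man, "train")
  expect_equal(class_counts(tr), c(normal = 3L, pneumonia = 8L))
})

test_that("invalid generator configs are rejected", {
  expect_error(synthetic_config(image_size = 4), "image_size")
  expect_error(synthetic_config(n_train = -1), "counts")
  expect_error(synthetic_config(opacity_count_range = c(5, 2)), "opacity")
})
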