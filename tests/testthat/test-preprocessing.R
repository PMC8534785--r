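write_test_folder <- function(n_benign = 3, n_malignant = 2, size = 16) {
  root <- withr::local_tempdir(.local_envir = parent.frame())
  dir.create(file.path(root, "benign"))
  dir.create(file.path(root, "malignant"))
  withr::with_seed(2, {
    for (i in seq_len(n_benign)) {
      png::writePNG(matrix(stats::runif(size^2), size, size),
                    file.path(root, "benign", sprintf("b%02d.png", i)))
    }
    for (i in seq_len(n_malignant)) {
      png::writePNG(matrix(stats::runif(size^2), size, size),
                    file.path(root, "malignant", sprintf("m%02d.png", i)))
    }
  })
  root
}

test_that("class folders load with labels, sorted order, and exact 8-bit scaling", {
  root <- write_test_folder()
  s <- load_image_folder(root)
  expect_equal(nrow(s), 5)
  expect_equal(sum(s$label == "benign"), 3)
  expect_equal(s$path, sort(s$path))
  expect_true(all(vapply(s$pixels, function(p) all(p >= 0 & p <= 1), logical(1))))
  # constant 8-bit white decodes to exactly 1.0
  png::writePNG(matrix(1, 8, 8), file.path(root, "benign", "white.png"))
  s <- load_image_folder(root)
  w <- s$pixels[[which(s$id == "white")]]
  expect_true(all(w == 1.0))
})

test_that("malformed folders and files produce informative errors", {
  root <- write_test_folder()
  dir.create(file.path(root, "suspicious"))
  expect_error(load_image_folder(root), "3")
  unlink(file.path(root, "suspicious"), recursive = TRUE)
  writeBin(as.raw(1:20), file.path(root, "benign", "broken.png"))
  expect_error(load_image_folder(root), "broken\\.png")
  file.remove(file.path(root, "benign", "broken.png"))
  # empty class folder loads with a warning
  for (f in list.files(file.path(root, "malignant"), full.names = TRUE)) file.remove(f)
  expect_warning(s <- load_image_folder(root), "empty")
  expect_equal(sum(s$label == "malignant"), 0)
})

test_that("bilinear resize matches a per-pixel oracle and preserves bounds", {
  # constant image stays constant at any size
  expect_true(all(resize_image(matrix(0.37, 5, 5), 12) == 0.37))
  # identity when the size already matches
  x <- matrix(stats::runif(64), 8, 8)
  expect_identical(resize_image(x, 8), x)
  # 2x2 checkerboard upsampled x2 against the hand-computed formula
  cb <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(resize_image(cb, 4), bilinear_oracle(cb, 4, 4)[, , 1],
               tolerance = 1e-12)
  withr::with_seed(8, {
    for (rep in 1:5) {
      x <- matrix(stats::runif(36), 6, 6)
      target <- sample(c(8, 9, 13), 1)
      expect_equal(resize_image(x, target),
                   bilinear_oracle(x, target, target)[, , 1], tolerance = 1e-12)
      out <- resize_image(x, target)
      expect_gte(min(out), min(x) - 1e-12)
      expect_lte(max(out), max(x) + 1e-12)
    }
  })
  expect_error(resize_image(x, 1), "target")
})

test_that("normalization modes behave and min-max is idempotent", {
  x <- matrix(seq(0.2, 0.7, length.out = 25), 5, 5)
  n <- normalize_image(x, "minmax_per_image")
  expect_equal(range(n), c(0, 1))
  expect_identical(normalize_image(n, "minmax_per_image"), n)
  expect_true(all(normalize_image(matrix(0.4, 3, 3), "minmax_per_image") == 0))
  expect_error(normalize_image(x, "dataset_zscore"), "statistics")
  s <- random_samples(4, size = 8, seed = 3)
  stats <- compute_normalization(s)
  z <- lapply(s$pixels, normalize_image, mode = "dataset_zscore", stats = stats)
  all_z <- unlist(z)
  expect_equal(mean(all_z), 0, tolerance = 1e-6)
  expect_equal(sd(all_z), 1, tolerance = 1e-6)
})

test_that("the stratified split is an exact partition with the stated rounding", {
  m <- random_samples(100, size = 8, seed = 1)[, c("id", "label")]
  sp <- split_dataset(m, seed = 4)
  tab <- table(sp$label, sp$partition)
  expect_true(all(tab["benign", c("train", "validation", "test")] == c(75, 10, 15)))
  expect_true(all(tab["malignant", c("train", "validation", "test")] == c(75, 10, 15)))
  # deterministic under the seed
  expect_identical(sp, split_dataset(m, seed = 4))
  expect_false(identical(sp$partition, split_dataset(m, seed = 5)$partition))
})

test_that("split covers the study composition of 249 + 190", {
  m <- tibble::tibble(
    id = as.character(1:439),
    label = rep(c("benign", "malignant"), c(249, 190))
  )
  sp <- split_dataset(m, seed = 1)
  expect_equal(nrow(sp), 439)
  expect_equal(anyDuplicated(sp$id), 0)
  tab <- table(sp$label, sp$partition)
  # rounding policy: test = ceil(0.15 n), validation = round(0.10 n)
  expect_equal(unname(tab["benign", "test"]), ceiling(0.15 * 249))
  expect_equal(unname(tab["benign", "validation"]), round(0.10 * 249))
  expect_equal(unname(tab["malignant", "test"]), ceiling(0.15 * 190))
  expect_equal(sum(tab), 439)
})

test_that("split partitions any class size of at least 3", {
  withr::with_seed(6, {
    for (rep in 1:20) {
      n_b <- sample(3:120, 1)
      n_m <- sample(3:120, 1)
      m <- tibble::tibble(
        id = as.character(seq_len(n_b + n_m)),
        label = rep(c("benign", "malignant"), c(n_b, n_m))
      )
      sp <- split_dataset(m, seed = rep)
      expect_equal(sort(unique(sp$partition)) %in% c("test", "train", "validation"),
                   rep(TRUE, length(unique(sp$partition))))
      expect_equal(nrow(sp), n_b + n_m)
      expect_equal(anyDuplicated(sp$id), 0)
      for (cls in c("benign", "malignant")) {
        n <- sum(sp$label == cls)
        tab <- table(sp$partition[sp$label == cls])
        got <- function(p) if (p %in% names(tab)) tab[[p]] else 0
        # exact rounding policy: test = ceil, validation = round, train = rest
        expect_equal(got("test"), ceiling(0.15 * n))
        expect_equal(got("validation"), round(0.10 * n))
        expect_equal(got("train"), n - ceiling(0.15 * n) - round(0.10 * n))
        # proportions track the fractions (ceil + round can shift train by
        # up to 1.5 samples)
        for (p in c("train", "validation", "test")) {
          frac <- c(train = 0.75, validation = 0.10, test = 0.15)[[p]]
          expect_lte(abs(got(p) - frac * n), 1.5)
        }
      }
    }
  })
  expect_error(
    split_dataset(tibble::tibble(id = c("a", "b", "c", "d"),
                                 label = c(rep("benign", 3), "malignant"))),
    "malignant")
})
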