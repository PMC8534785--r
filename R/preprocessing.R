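# Image ingestion and the stratified 75/10/15 train/validation/test split.
# Images live as numeric matrices (grayscale) or (H, W, 3) arrays in a
# list-column of the samples tibble, always scaled to [0, 1].

read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop_input("reading JPEG requires the EBImage package: %s", path)
    }
    aperm(as.array(EBImage::readImage(path)))
  } else {
    stop_input("unsupported image format '%s': %s", ext, path)
  }
  d <- dim(img)
  if (length(d) == 3) {
    if (d[3] == 4) img <- img[, , 1:3, drop = FALSE] # drop alpha
    if (dim(img)[3] == 1) img <- img[, , 1]
  }
  clamp(img, 0, 1)
}

#' Load a two-class image folder
#'
#' Reads every PNG/JPEG under `root/<class>/` into a samples tibble. Labels
#' come from the class folder names; ordering is deterministic (sorted
#' path).
#'
#' @param root Directory containing exactly two class subfolders.
#' @return A tibble with columns `id`, `path`, `label` and list-column
#'   `pixels` (matrices or H x W x 3 arrays in \[0, 1\]).
#' @export
load_image_folder <- function(root) {
  if (!dir.exists(root)) stop_input("folder does not exist: %s", root)
  classes <- sort(basename(list.dirs(root, recursive = FALSE)))
  if (length(classes) != 2) {
    stop_input("expected exactly 2 class folders under %s, found %d (%s)",
               root, length(classes), paste(classes, collapse = ", "))
  }
  rows <- purrr::map(classes, function(cls) {
    files <- sort(list.files(file.path(root, cls),
                             pattern = "\\.(png|jpe?g)$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0) {
      warn(sprintf("class folder '%s' is empty", cls))
      return(NULL)
    }
    failed <- character()
    pixels <- purrr::map(files, function(f) {
      tryCatch(read_gray_image(f), error = function(e) {
        failed <<- c(failed, f)
        NULL
      })
    })
    if (length(failed) > 0) {
      stop_input("could not decode: %s", paste(failed, collapse = ", "))
    }
    tibble(id = tools::file_path_sans_ext(basename(files)),
           path = files, label = cls, pixels = pixels)
  })
  dplyr::bind_rows(rows)
}

#' Resize an image by bilinear interpolation
#'
#' @param pixels A numeric matrix or (H, W, C) array in \[0, 1\].
#' @param target Output side in pixels, at least 2; output is
#'   `target` x `target` (non-square inputs are stretched).
#' @return The resized image, same channel count, values still in \[0, 1\].
#' @export
#' @examples
#' resize_image(matrix(runif(16), 4), 8) |> dim()
resize_image <- function(pixels, target) {
  if (!is_count(target) || target < 2) stop_input("target must be an integer >= 2")
  was_matrix <- is.matrix(pixels)
  out <- bilinear_resize(as_map(pixels), target, target)
  out <- clamp(out, 0, 1)
  if (was_matrix) out[, , 1] else out
}

#' Normalize image intensities
#'
#' `minmax_per_image` maps each image to span exactly \[0, 1\] (a constant
#' image maps to all zeros); `dataset_zscore` applies stored train-set
#' statistics from [compute_normalization()].
#'
#' @inheritParams resize_image
#' @param mode `"minmax_per_image"` or `"dataset_zscore"`.
#' @param stats For `dataset_zscore`, the list returned by
#'   [compute_normalization()].
#' @return The normalized image.
#' @export
normalize_image <- function(pixels, mode = c("minmax_per_image", "dataset_zscore"),
                            stats = NULL) {
  mode <- match.arg(mode)
  if (length(pixels) == 0) stop_input("cannot normalize an empty image")
  if (mode == "minmax_per_image") {
    rng <- range(pixels)
    if (rng[2] - rng[1] == 0) return(pixels * 0)
    (pixels - rng[1]) / (rng[2] - rng[1])
  } else {
    if (is.null(stats)) {
      stop_input("dataset_zscore requested before statistics were computed; call compute_normalization() on the training set first")
    }
    (pixels - stats$mean) / stats$sd
  }
}

#' Train-set normalization statistics
#'
#' Pixel mean and standard deviation pooled over a set of images, persisted
#' with a model so the identical transform is applied at inference.
#'
#' @param samples A samples tibble with a `pixels` list-column.
#' @return A list with `mean` and `sd`.
#' @export
compute_normalization <- function(samples) {
  px <- unlist(purrr::map(samples$pixels, as.numeric))
  if (length(px) == 0) stop_input("no pixels to compute statistics from")
  list(mean = mean(px), sd = stats::sd(px))
}

#' Stratified train/validation/test split
#'
#' Splits a samples or manifest tibble per class into train, validation and
#' test partitions. Rounding policy per class: test takes the ceiling of
#' its fraction, validation rounds, train takes the remainder, so the
#' partitions always form an exact partition of the input.
#'
#' @param samples A tibble with a `label` column (and one row per sample).
#' @param fractions Train, validation, test fractions summing to 1.
#' @param seed Integer seed controlling the shuffle.
#' @return The input tibble with a `partition` column
#'   (`train`/`validation`/`test`); attributes `fractions` and `seed`.
#' @export
#' @examples
#' m <- tibble::tibble(id = as.character(1:20),
#'                     label = rep(c("benign", "malignant"), each = 10))
#' table(split_dataset(m, seed = 1)$partition)
split_dataset <- function(samples, fractions = c(0.75, 0.10, 0.15), seed = 1) {
  stopifnot(length(fractions) == 3, all(fractions >= 0))
  if (abs(sum(fractions) - 1) > 1e-9) stop_input("fractions must sum to 1")
  counts <- table(samples$label)
  small <- names(counts)[counts < 3]
  if (length(small) > 0) {
    stop_input("class '%s' has fewer samples than partitions", small[1])
  }
  out <- with_local_seed(seed, {
    samples |>
      dplyr::group_by(.data$label) |>
      dplyr::group_modify(function(df, key) {
        n <- nrow(df)
        n_test <- ceiling(fractions[3] * n)
        n_val <- round(fractions[2] * n)
        n_train <- n - n_test - n_val
        if (n_train < 1) stop_input("class '%s' has too few samples to fill all partitions", key$label)
        part <- rep(c("train", "validation", "test"), c(n_train, n_val, n_test))
        df$partition <- part[sample.int(n)]
        df
      }) |>
      dplyr::ungroup()
  })
  attr(out, "fractions") <- fractions
  attr(out, "seed") <- seed
  out
}

# Load rendered images for manifest rows, resized and normalized, ready
# for the network.
#' Prepare manifest rows as network-ready samples
#'
#' Reads each manifest row's image from disk (or regenerates it from its
#' stored spec when `from_spec = TRUE`), resizes to `input_size` and
#' min-max normalizes.
#'
#' @param manifest A manifest tibble from [generate_dataset()] or a split
#'   from [split_dataset()].
#' @param input_size Network input side in pixels.
#' @param from_spec Regenerate pixels from the stored lesion spec instead
#'   of reading files (no disk I/O).
#' @param speckle_sigma Speckle level when `from_spec = TRUE`.
#' @return The manifest with a `pixels` list-column added.
#' @export
prepare_samples <- function(manifest, input_size = 128, from_spec = FALSE,
                            speckle_sigma = 0.15) {
  pixels <- purrr::pmap(manifest, function(...) {
    row <- list(...)
    img <- if (from_spec) {
      generate_lesion_image(manifest_spec(row), size = max(32, input_size),
                            noise = speckle_sigma, seed = row$image_seed)
    } else {
      read_gray_image(row$path)
    }
    if (!all(dim(img)[1:2] == input_size)) img <- resize_image(img, input_size)
    normalize_image(img, "minmax_per_image")
  })
  manifest$pixels <- pixels
  manifest
}
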