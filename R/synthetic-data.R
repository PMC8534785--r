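# Synthetic breast-ultrasound phantoms: lesions are darker, roughly
# elliptical regions on a speckled background. Benign lesions are smooth
# ovals; malignant lesions carry an irregular, spiculated margin modelled
# as low-order sinusoidal harmonics on the polar boundary radius. Speckle
# is first-order multiplicative Gaussian noise.

#' Describe one synthetic lesion
#'
#' @param class_label `"benign"` or `"malignant"`.
#' @param center Fractional (row, col) image coordinates of the lesion
#'   centre, each in \[0, 1\].
#' @param axes Semi-major and semi-minor axes as fractions of the image
#'   side.
#' @param margin_irregularity Non-negative amplitude of the radial boundary
#'   perturbation; benign specs must sit below
#'   `benign_irregularity_threshold()`, malignant at or above it.
#' @param echo_contrast How much darker the lesion interior is than the
#'   background, in (0, 1\]; 0 is allowed as the degenerate no-lesion case.
#' @return A `lesion_spec` list.
#' @export
#' @examples
#' lesion_spec("benign", center = c(0.5, 0.5), axes = c(0.2, 0.15),
#'             margin_irregularity = 0.02, echo_contrast = 0.5)
lesion_spec <- function(class_label = c("benign", "malignant"),
                        center = c(0.5, 0.5),
                        axes = c(0.2, 0.15),
                        margin_irregularity = 0,
                        echo_contrast = 0.5) {
  class_label <- match.arg(class_label)
  stopifnot(length(center) == 2, all(center >= 0 & center <= 1),
            length(axes) == 2, all(axes > 0),
            margin_irregularity >= 0,
            echo_contrast >= 0, echo_contrast <= 1)
  thr <- benign_irregularity_threshold()
  if (class_label == "benign" && margin_irregularity >= thr) {
    stop_input("margin_irregularity (%.3f) of a benign spec must be below %.3f",
               margin_irregularity, thr)
  }
  if (class_label == "malignant" && margin_irregularity < thr) {
    stop_input("margin_irregularity (%.3f) of a malignant spec must be at least %.3f",
               margin_irregularity, thr)
  }
  structure(list(class_label = class_label, center = center, axes = axes,
                 margin_irregularity = margin_irregularity,
                 echo_contrast = echo_contrast),
            class = "lesion_spec")
}

#' Margin-irregularity threshold separating benign from malignant specs
#' @return A single number.
#' @export
benign_irregularity_threshold <- function() 0.10

# Background echo level of the phantom before speckle.
background_level <- function() 0.55

# Low-order harmonics perturbing the polar boundary radius. Drawn from a
# dedicated stream so the analytic boundary can be reconstructed from
# (spec, seed) without regenerating the image.
draw_harmonics <- function(seed) {
  with_local_seed(seed, {
    n <- sample(3:8, 1)
    k <- sample(2:9, n)
    w <- rnorm(n)
    w <- w / sum(abs(w)) # total perturbation bounded by margin_irregularity
    list(k = k, w = w, phase = runif(n, 0, 2 * pi))
  })
}

radius_modulation <- function(theta, harmonics, irregularity) {
  r <- rep(1, length(theta))
  for (j in seq_along(harmonics$k)) {
    r <- r + irregularity * harmonics$w[j] *
      sin(harmonics$k[j] * theta + harmonics$phase[j])
  }
  r
}

check_spec_fits <- function(spec) {
  reach <- max(spec$axes) * (1 + spec$margin_irregularity)
  if (spec$center[1] - reach < 0 || spec$center[1] + reach > 1 ||
      spec$center[2] - reach < 0 || spec$center[2] + reach > 1) {
    stop_input(paste0(
      "lesion does not fit inside the image: center (%.2f, %.2f) with axes ",
      "(%.2f, %.2f) and margin_irregularity %.2f reaches outside [0, 1]"),
      spec$center[1], spec$center[2], spec$axes[1], spec$axes[2],
      spec$margin_irregularity)
  }
  invisible(spec)
}

#' Render one synthetic lesion image
#'
#' Produces a single-channel image in \[0, 1\]: a constant background at
#' the phantom echo level with a darker elliptical lesion whose boundary
#' radius is modulated by low-order random harmonics scaled by
#' `margin_irregularity`, then multiplicative speckle
#' `pixel * (1 + N(0, noise))` clipped to \[0, 1\]. Deterministic for a
#' fixed `(spec, size, noise, seed)`.
#'
#' @param spec A [lesion_spec()].
#' @param size Image side in pixels, at least 32.
#' @param noise Speckle standard deviation, non-negative.
#' @param seed Integer seed for harmonics and speckle.
#' @return A `size` x `size` numeric matrix in \[0, 1\].
#' @export
#' @examples
#' img <- generate_lesion_image(lesion_spec("benign"), size = 64,
#'                              noise = 0.1, seed = 1)
#' range(img)
generate_lesion_image <- function(spec, size = 128, noise = 0.15, seed = 1) {
  stopifnot(inherits(spec, "lesion_spec"))
  if (!is_count(size) || size < 32) stop_input("size must be an integer >= 32")
  if (noise < 0) stop_input("noise must be non-negative")
  check_spec_fits(spec)

  harmonics <- draw_harmonics(seed)
  centre <- (seq_len(size) - 0.5) / size
  u <- outer((centre - spec$center[1]) / spec$axes[1], rep(1, size))
  v <- outer(rep(1, size), (centre - spec$center[2]) / spec$axes[2])
  rho <- sqrt(u^2 + v^2)
  theta <- atan2(v, u)
  inside <- rho <= radius_modulation(theta, harmonics, spec$margin_irregularity)

  img <- background_level() * (1 - spec$echo_contrast * inside)
  if (noise > 0) {
    speckle <- with_local_seed(derive_seed(seed, 1, salt = 97), {
      matrix(rnorm(size * size, 0, noise), size, size)
    })
    img <- img * (1 + speckle)
  }
  clamp(img, 0, 1)
}

# Analytic boundary polygon of a spec at a given seed; used for geometric
# features (e.g. perimeter^2 / area compactness) without touching pixels.
#' Boundary polygon of a lesion spec
#'
#' Samples the analytic lesion boundary (the same harmonics the rendered
#' image uses for this seed) at `n` angles, in fractional image
#' coordinates.
#'
#' @inheritParams generate_lesion_image
#' @param n Number of boundary vertices.
#' @return A tibble with columns `row`, `col`.
#' @export
lesion_boundary <- function(spec, seed = 1, n = 720) {
  stopifnot(inherits(spec, "lesion_spec"))
  harmonics <- draw_harmonics(seed)
  theta <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- radius_modulation(theta, harmonics, spec$margin_irregularity)
  tibble(
    row = spec$center[1] + r * spec$axes[1] * cos(theta),
    col = spec$center[2] + r * spec$axes[2] * sin(theta)
  )
}

#' Boundary compactness of a lesion spec
#'
#' Perimeter squared over area of the analytic boundary polygon; 4*pi for a
#' circle, larger for irregular margins. A threshold on this single feature
#' separates smooth benign from spiculated malignant specs when the
#' irregularity gap is wide.
#'
#' @inheritParams lesion_boundary
#' @return A single number.
#' @export
boundary_compactness <- function(spec, seed = 1, n = 720) {
  b <- lesion_boundary(spec, seed, n)
  nxt <- c(seq_len(nrow(b))[-1], 1L)
  per <- sum(sqrt((b$row[nxt] - b$row)^2 + (b$col[nxt] - b$col)^2))
  area <- abs(sum(b$row * b$col[nxt] - b$row[nxt] * b$col)) / 2
  per^2 / area
}

#' Configuration for a synthetic dataset
#'
#' Defaults reproduce the composition of the combined study data: 249
#' benign and 190 malignant images, resized targets of 128 pixels.
#'
#' @param n_benign,n_malignant Class counts, non-negative.
#' @param image_size Pixels per side, at least 32.
#' @param speckle_sigma Multiplicative speckle standard deviation.
#' @param seed Integer master seed; each image derives its own stream from
#'   `(seed, sample index)` so generation order is irrelevant.
#' @param output_format `"png"` (default) or `"jpeg"` (requires EBImage).
#' @param benign_irregularity,malignant_irregularity Length-2 ranges the
#'   per-class margin irregularity is drawn from.
#' @param benign_echo,malignant_echo Length-2 ranges the per-class echo
#'   contrast is drawn from; malignant lesions are markedly hypoechoic
#'   (darker) relative to benign ones.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_benign = 249, n_malignant = 190,
                         image_size = 128, speckle_sigma = 0.15,
                         seed = 1, output_format = c("png", "jpeg"),
                         benign_irregularity = c(0, 0.05),
                         malignant_irregularity = c(0.15, 0.35),
                         benign_echo = c(0.30, 0.50),
                         malignant_echo = c(0.50, 0.70)) {
  output_format <- match.arg(output_format)
  if (!is_count(n_benign) || !is_count(n_malignant)) {
    stop_input("class counts must be non-negative integers")
  }
  if (!is_count(image_size) || image_size < 32) {
    stop_input("image_size must be an integer >= 32")
  }
  if (speckle_sigma < 0) stop_input("speckle_sigma must be non-negative")
  thr <- benign_irregularity_threshold()
  stopifnot(length(benign_irregularity) == 2, length(malignant_irregularity) == 2,
            max(benign_irregularity) < thr, min(malignant_irregularity) >= thr)
  stopifnot(length(benign_echo) == 2, length(malignant_echo) == 2,
            all(c(benign_echo, malignant_echo) >= 0),
            all(c(benign_echo, malignant_echo) <= 1))
  structure(list(n_benign = n_benign, n_malignant = n_malignant,
                 image_size = image_size, speckle_sigma = speckle_sigma,
                 seed = seed, output_format = output_format,
                 benign_irregularity = benign_irregularity,
                 malignant_irregularity = malignant_irregularity,
                 benign_echo = benign_echo,
                 malignant_echo = malignant_echo),
            class = "synth_config")
}

# Lesion diameters in cm by class: truncated normals matching the study
# population (benign 1.4 +/- 1.0 cm in [0.3, 5]; malignant 2.1 +/- 1.2 cm
# in [0.5, 9]), mapped onto a fixed field of view.
lesion_size_cm <- function(label) {
  if (label == "benign") list(mean = 1.4, sd = 1.0, range = c(0.3, 5)) else
    list(mean = 2.1, sd = 1.2, range = c(0.5, 9))
}

field_of_view_cm <- function() 6

rtrunc_norm1 <- function(mean, sd, range) {
  for (i in 1:200) {
    x <- rnorm(1, mean, sd)
    if (x >= range[1] && x <= range[2]) return(x)
  }
  mean
}

# Draw a random spec for one sample from its derived stream. Benign
# lesions are smooth ovals; malignant lesions are more eccentric with a
# spiculated margin and are larger on average, following the class-wise
# lesion-size spread of the study population.
draw_spec <- function(label, seed, config) {
  with_local_seed(seed, {
    irr_range <- if (label == "benign") config$benign_irregularity else
      config$malignant_irregularity
    irr <- runif(1, irr_range[1], irr_range[2])
    sz <- lesion_size_cm(label)
    a <- rtrunc_norm1(sz$mean, sz$sd, sz$range) / 2 / field_of_view_cm()
    a <- clamp(a, 0.04, 0.26) # keep the perturbed boundary inside the frame
    ratio <- if (label == "benign") runif(1, 0.6, 0.85) else runif(1, 0.45, 0.9)
    reach <- a * (1 + irr) + 0.02
    lesion_spec(
      class_label = label,
      center = runif(2, reach, 1 - reach),
      axes = c(a, a * ratio),
      margin_irregularity = irr,
      # malignant lesions are markedly hypoechoic relative to benign ones
      echo_contrast = if (label == "benign") {
        runif(1, config$benign_echo[1], config$benign_echo[2])
      } else {
        runif(1, config$malignant_echo[1], config$malignant_echo[2])
      }
    )
  })
}

spec_row <- function(spec) {
  tibble(center_row = spec$center[1], center_col = spec$center[2],
         axis_major = spec$axes[1], axis_minor = spec$axes[2],
         margin_irregularity = spec$margin_irregularity,
         echo_contrast = spec$echo_contrast)
}

manifest_spec <- function(row) {
  lesion_spec(row$label, center = c(row$center_row, row$center_col),
              axes = c(row$axis_major, row$axis_minor),
              margin_irregularity = row$margin_irregularity,
              echo_contrast = row$echo_contrast)
}

write_gray_image <- function(img, path, format) {
  if (format == "png") {
    png::writePNG(img, path)
  } else {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop_input("JPEG output requires the EBImage package; use output_format = 'png'")
    }
    EBImage::writeImage(EBImage::Image(t(img)), path, type = "jpeg", quality = 95)
  }
}

#' Generate a labelled synthetic lesion dataset on disk
#'
#' Writes one image file per sample into `<out_dir>/benign/` and
#' `<out_dir>/malignant/` and a `manifest.csv` alongside. Each sample's
#' random stream is derived from `(config$seed, sample index)`, so the
#' same configuration always produces byte-identical files.
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory; created if missing.
#' @return Invisibly, the manifest tibble: `id`, `path`, `label`,
#'   `image_seed` and the spec fields.
#' @export
#' @examples
#' d <- generate_dataset(synth_config(n_benign = 2, n_malignant = 2,
#'                                    image_size = 32),
#'                       out_dir = tempfile())
#' d$label
generate_dataset <- function(config = synth_config(), out_dir) {
  stopifnot(inherits(config, "synth_config"))
  for (cls in c("benign", "malignant")) {
    ok <- dir.create(file.path(out_dir, cls), recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(file.path(out_dir, cls))) {
      stop_input("cannot create output directory %s", file.path(out_dir, cls))
    }
  }
  labels <- rep(c("benign", "malignant"), c(config$n_benign, config$n_malignant))
  ext <- if (config$output_format == "png") "png" else "jpg"
  rows <- purrr::imap(labels, function(label, i) {
    img_seed <- derive_seed(config$seed, i)
    spec <- draw_spec(label, derive_seed(img_seed, 1, salt = 11), config)
    img <- generate_lesion_image(spec, size = config$image_size,
                                 noise = config$speckle_sigma, seed = img_seed)
    n_in_class <- sum(labels[seq_len(i)] == label)
    id <- sprintf("%s_%04d", label, n_in_class)
    path <- file.path(out_dir, label, paste0(id, ".", ext))
    write_gray_image(img, path, config$output_format)
    dplyr::bind_cols(tibble(id = id, path = path, label = label,
                            image_seed = img_seed), spec_row(spec))
  })
  empty <- tibble(id = character(), path = character(), label = character(),
                  image_seed = numeric(), center_row = numeric(),
                  center_col = numeric(), axis_major = numeric(),
                  axis_minor = numeric(), margin_irregularity = numeric(),
                  echo_contrast = numeric())
  manifest <- dplyr::bind_rows(empty, rows)
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  invisible(manifest)
}
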