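# The model-by-loss comparison: {plain VGG16, attention-VGG16} crossed
# with {CE, logCosh, CE-logCosh}, every cell trained on the same split
# with the same seeds so differences come from the architecture and the
# objective alone.

#' Train and evaluate the model-by-loss comparison grid
#'
#' Runs every combination of the requested model variants and losses on a
#' shared train/validation/test split, evaluates each trained cell on the
#' test partition and collects the six metrics.
#'
#' @param split_samples A tibble from [split_dataset()] with a `pixels`
#'   list-column (see [prepare_samples()]).
#' @param models Character subset of `c("plain", "attention")`.
#' @param losses Character subset of `c("ce", "logcosh", "ce_logcosh")`.
#' @param network A [network_config()] used for every cell (its
#'   `use_attention` flag is overridden per cell).
#' @param train A [train_config()] shared by every cell.
#' @param verbose Print per-epoch progress.
#' @return An `attnvgg_grid` tibble: one row per cell with columns
#'   `model`, `loss`, the six metrics, and list-columns `confusion` and
#'   `history`.
#' @export
compare_grid <- function(split_samples,
                         models = c("plain", "attention"),
                         losses = c("ce", "logcosh", "ce_logcosh"),
                         network = network_config(),
                         train = train_config(),
                         verbose = FALSE) {
  models <- match.arg(models, several.ok = TRUE)
  losses <- match.arg(losses, several.ok = TRUE)
  stopifnot("partition" %in% names(split_samples),
            "pixels" %in% names(split_samples))
  parts <- split(split_samples, split_samples$partition)
  data <- list(train = parts$train, validation = parts$validation)
  test <- parts$test
  if (is.null(test) || nrow(test) == 0) stop_input("split has no test partition")

  cells <- tidyr::expand_grid(model = models, loss = losses)
  rows <- purrr::pmap(cells, function(model, loss) {
    cfg <- network
    cfg$use_attention <- model == "attention"
    net <- build_model(cfg)
    fit <- train_model(net, data, loss = loss_config(loss), config = train,
                       verbose = verbose)
    ev <- evaluate_model(fit, test)
    dplyr::bind_cols(
      tibble(model = model, loss = loss),
      ev$metrics,
      tibble(confusion = list(ev$confusion), history = list(fit$history))
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("attnvgg_grid", class(out))
  out
}

#' Write a comparison grid to CSV (plus per-cell confusion matrices)
#'
#' The CSV holds one row per cell with full-precision metrics; each cell's
#' confusion matrix goes to `<dir>/confusion_<model>_<loss>.json`.
#'
#' @param grid An `attnvgg_grid` from [compare_grid()].
#' @param dir Output directory, created if missing.
#' @return Invisibly, the CSV path.
#' @export
write_grid <- function(grid, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "comparison.csv")
  readr::write_csv(dplyr::select(grid, -dplyr::any_of(c("confusion", "history"))), csv)
  purrr::pwalk(grid[, c("model", "loss", "confusion")],
               function(model, loss, confusion) {
                 jsonlite::write_json(unclass(confusion),
                                      file.path(dir, sprintf("confusion_%s_%s.json", model, loss)),
                                      auto_unbox = TRUE)
               })
  invisible(csv)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted model's training history
#'
#' @param x An `attnvgg_fit`.
#' @param ... Unused.
#' @return The per-epoch history in long form: `epoch`, `metric`, `value`.
#' @exportS3Method generics::tidy
tidy.attnvgg_fit <- function(x, ...) {
  tidyr::pivot_longer(x$history, -"epoch",
                      names_to = "metric", values_to = "value")
}

#' One-row summary of a fitted model
#'
#' @param x An `attnvgg_fit`.
#' @param ... Unused.
#' @return A one-row tibble: loss name and weights, epochs run, best
#'   epoch, best validation accuracy, parameter count.
#' @exportS3Method generics::glance
glance.attnvgg_fit <- function(x, ...) {
  tibble(
    loss = x$loss$name, alpha = x$loss$alpha, beta = x$loss$beta,
    epochs = nrow(x$history), best_epoch = x$best_epoch,
    best_val_accuracy = x$best_val_accuracy,
    n_parameters = count_parameters(x$model)
  )
}

#' Per-layer parameter summary of a model
#'
#' @param x An `attnvgg_model`.
#' @param ... Unused.
#' @return Tibble with one row per parameter tensor: `term`, `shape`,
#'   `n_parameters`.
#' @exportS3Method generics::tidy
tidy.attnvgg_model <- function(x, ...) {
  tibble(
    term = names(x$params),
    shape = vapply(x$params, function(p) {
      paste(dim(p) %||% length(p), collapse = "x")
    }, character(1), USE.NAMES = FALSE),
    n_parameters = vapply(x$params, length, integer(1), USE.NAMES = FALSE)
  )
}

#' @rdname tidy.attnvgg_model
#' @exportS3Method generics::glance
glance.attnvgg_model <- function(x, ...) {
  cfg <- x$config
  tibble(
    architecture = if (cfg$use_attention) "attention-VGG16" else "VGG16",
    input_size = cfg$input_size, width_multiplier = cfg$width_multiplier,
    head_hidden_units = cfg$head_hidden_units,
    n_parameters = count_parameters(x)
  )
}

#' Plot a training history
#'
#' @param object An `attnvgg_fit`.
#' @param ... Unused.
#' @return A ggplot of per-epoch loss and accuracy curves.
#' @exportS3Method ggplot2::autoplot
autoplot.attnvgg_fit <- function(object, ...) {
  long <- tidy(object) |>
    dplyr::filter(.data$metric != "lr") |>
    tidyr::separate_wider_delim("metric", "_", names = c("partition", "metric"),
                                too_many = "merge") |>
    dplyr::mutate(partition = dplyr::recode(.data$partition,
                                            train = "train", val = "validation"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$partition)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a comparison grid
#'
#' @param object An `attnvgg_grid`.
#' @param ... Unused.
#' @return A ggplot dot chart of the six metrics across cells.
#' @exportS3Method ggplot2::autoplot
autoplot.attnvgg_grid <- function(object, ...) {
  long <- object |>
    dplyr::select(-dplyr::any_of(c("confusion", "history"))) |>
    tidyr::pivot_longer(-c("model", "loss"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$loss,
                                     colour = .data$model)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = NULL, y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an attention coefficient map over its input image
#'
#' @param model An attention-enabled `attnvgg_model` or `attnvgg_fit`.
#' @param img A single image sized to the network input.
#' @return A ggplot heatmap of the attention coefficients.
#' @export
plot_attention <- function(model, img) {
  if (inherits(model, "attnvgg_fit")) model <- model$model
  coef <- attention_map(model, img)
  df <- tidyr::expand_grid(row = seq_len(nrow(coef)), col = seq_len(ncol(coef)))
  df$coefficient <- as.vector(coef)[(df$col - 1) * nrow(coef) + df$row]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$coefficient)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "attention") +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
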