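# Training loop: RMSprop with the classic time-based learning-rate decay
# lr_t = lr0 / (1 + decay * t), t counting completed updates. Defaults are
# the faithful recipe (lr 2e-6, decay 1e-6, 250 epochs, batch 32); the
# desk profile (see training_profile()) scales the run to minutes on one
# CPU without changing any mechanism.

#' Training configuration
#'
#' @param learning_rate Initial RMSprop learning rate; default `2e-6`.
#' @param decay Time-based decay: the effective rate after `t` updates is
#'   `learning_rate / (1 + decay * t)`; default `1e-6`.
#' @param epochs Training epochs; default 250.
#' @param batch_size Mini-batch size; default 32.
#' @param seed Seed controlling initial shuffle order and dropout.
#' @param rho RMSprop moving-average coefficient.
#' @param eps RMSprop denominator floor.
#' @param early_stop_patience Stop after this many epochs without a new
#'   best validation accuracy; `NULL` disables.
#' @param stop_at_val_accuracy Stop as soon as validation accuracy reaches
#'   this value; `NULL` disables.
#' @param checkpoint_dir Directory for the best-model checkpoint and
#'   history CSV; `NULL` keeps everything in memory.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 2e-6, decay = 1e-6, epochs = 250,
                         batch_size = 32, seed = 1, rho = 0.9, eps = 1e-7,
                         early_stop_patience = NULL,
                         stop_at_val_accuracy = NULL,
                         checkpoint_dir = NULL) {
  if (learning_rate < 0) stop_input("learning_rate must be non-negative")
  if (!is_count(epochs) || epochs < 1) stop_input("epochs must be a positive integer")
  if (!is_count(batch_size) || batch_size < 1) stop_input("batch_size must be a positive integer")
  structure(list(learning_rate = learning_rate, decay = decay,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 seed = seed, rho = rho, eps = eps,
                 early_stop_patience = early_stop_patience,
                 stop_at_val_accuracy = stop_at_val_accuracy,
                 checkpoint_dir = checkpoint_dir),
            class = "train_config")
}

#' Effective learning rate after a number of updates
#'
#' @param config A [train_config()].
#' @param t Number of completed parameter updates (0 for the first).
#' @return The decayed learning rate `lr0 / (1 + decay * t)`.
#' @export
#' @examples
#' effective_learning_rate(train_config(learning_rate = 0.1, decay = 0.5), 0:3)
effective_learning_rate <- function(config, t) {
  config$learning_rate / (1 + config$decay * t)
}

#' Bundled configuration profiles
#'
#' `"paper"` is the faithful recipe: full-width network at 128 px input,
#' RMSprop at 2e-6 with 1e-6 decay, 250 epochs, batch 32. `"desk"` keeps
#' every mechanism but scales to one CPU: width multiplier 1/8, 64 px
#' input, learning rate 1e-4, at most 30 epochs, batch 4 (small batches
#' buy more optimiser updates per epoch, which matters far more than
#' gradient smoothness at this scale), lighter dropout, and training
#' stops once validation accuracy saturates.
#'
#' @param name `"paper"` or `"desk"`.
#' @param seed Seed applied to both configs.
#' @param use_attention Build the attention-gated variant.
#' @return List with elements `network` ([network_config()]) and `train`
#'   ([train_config()]).
#' @export
training_profile <- function(name = c("desk", "paper"), seed = 1,
                             use_attention = TRUE) {
  name <- match.arg(name)
  if (name == "paper") {
    list(
      network = network_config(input_size = 128, width_multiplier = 1,
                               use_attention = use_attention, seed = seed),
      train = train_config(seed = seed)
    )
  } else {
    list(
      network = network_config(input_size = 64, width_multiplier = 0.125,
                               dropout_rate = 0,
                               use_attention = use_attention, seed = seed),
      train = train_config(learning_rate = 1e-4, decay = 1e-6, epochs = 30,
                           batch_size = 4, seed = seed,
                           stop_at_val_accuracy = 1)
    )
  }
}

#' Generate a separable benchmark and train the desk-profile classifier
#'
#' The end-to-end smoke benchmark: draws a 50 + 50 synthetic set with a
#' wide benign/malignant margin-irregularity gap and low speckle, splits
#' it 75/10/15, z-scores with train statistics, and trains the
#' desk-profile attention model on the CE-logCosh loss.
#'
#' @param seed Integer seed driving generation, split, initialization and
#'   training.
#' @param loss A [loss_config()].
#' @param out_dir Where the synthetic images are written; defaults to a
#'   session temporary directory.
#' @param use_attention Train the attention variant (default) or the
#'   plain one.
#' @return List: `fit` (an `attnvgg_fit`), `test` ([evaluate_model()]
#'   output on the test partition), `best_val_accuracy`.
#' @export
separable_benchmark <- function(seed = 1, loss = loss_config("ce_logcosh"),
                                out_dir = NULL, use_attention = TRUE) {
  out_dir <- out_dir %||% file.path(tempdir(), sprintf("attnvgg-smoke-%d", seed))
  prof <- training_profile("desk", seed = seed, use_attention = use_attention)
  scfg <- synth_config(
    n_benign = 50, n_malignant = 50,
    image_size = prof$network$input_size, speckle_sigma = 0.02,
    seed = derive_seed(seed, 1, salt = 29),
    benign_irregularity = c(0, 0.02),
    malignant_irregularity = c(0.25, 0.4),
    benign_echo = c(0.25, 0.45),
    malignant_echo = c(0.55, 0.75)
  )
  manifest <- generate_dataset(scfg, out_dir)
  sp <- split_dataset(manifest, seed = seed)
  sp <- prepare_samples(sp, input_size = prof$network$input_size)
  parts <- split(sp, sp$partition)
  stats <- compute_normalization(parts$train)
  parts <- lapply(parts, function(p) {
    p$pixels <- lapply(p$pixels, normalize_image, mode = "dataset_zscore",
                       stats = stats)
    p
  })
  model <- build_model(prof$network)
  fit <- train_model(model, list(train = parts$train, validation = parts$validation),
                     loss = loss, config = prof$train)
  list(fit = fit, test = evaluate_model(fit, parts$test),
       best_val_accuracy = max(fit$history$val_accuracy, na.rm = TRUE))
}

rmsprop_update <- function(params, grads, state, lr, rho, eps, frozen) {
  for (nm in names(grads)) {
    if (nm %in% frozen) next
    g <- grads[[nm]]
    s <- state[[nm]]
    s <- if (is.null(s)) (1 - rho) * g^2 else rho * s + (1 - rho) * g^2
    state[[nm]] <- s
    params[[nm]] <- params[[nm]] - lr * g / (sqrt(s) + eps)
  }
  list(params = params, state = state)
}

accumulate_grads <- function(total, g) {
  if (is.null(total)) return(g)
  for (nm in names(g)) total[[nm]] <- total[[nm]] + g[[nm]]
  total
}

batch_loss_accuracy <- function(model, samples, loss_cfg) {
  probs <- predict_proba(model, samples)
  y <- one_hot(samples$label, model$config$n_classes)
  pred <- class_levels()[max.col(probs, ties.method = "first")]
  list(loss = ensemble_loss(y, probs, loss_cfg),
       accuracy = mean(pred == samples$label))
}

#' Train a model
#'
#' Mini-batch RMSprop on the configured ensemble loss. The run is fully
#' seeded (shuffles and dropout draw from one stream started at
#' `config$seed`), per-epoch train/validation loss and accuracy are
#' recorded, and the parameters with the best validation accuracy are
#' retained alongside the final ones.
#'
#' @param model An `attnvgg_model` from [build_model()].
#' @param data List with elements `train` and `validation`, each a samples
#'   tibble (columns `label` and `pixels`, images sized to the network
#'   input).
#' @param loss A [loss_config()].
#' @param config A [train_config()].
#' @param verbose Print one line per epoch.
#' @return An `attnvgg_fit` list: `model` (best-validation weights),
#'   `final_model`, `history` (tibble: epoch, train_loss, train_accuracy,
#'   val_loss, val_accuracy, lr), `best_epoch`, `loss`, `train_config`.
#' @export
train_model <- function(model, data, loss = loss_config(),
                        config = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "attnvgg_model"), inherits(config, "train_config"))
  train <- data$train
  val <- data$validation
  if (is.null(train) || nrow(train) == 0) stop_input("training partition is empty")
  n <- nrow(train)
  y_all <- one_hot(train$label, model$config$n_classes)

  state <- list()
  t_updates <- 0
  best <- list(acc = -Inf, params = model$params, epoch = 0L)
  history <- vector("list", config$epochs)
  since_best <- 0L

  with_local_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      order <- sample.int(n)
      batches <- split(order, ceiling(seq_along(order) / config$batch_size))
      epoch_loss <- 0
      epoch_correct <- 0
      for (bi in seq_along(batches)) {
        idx <- batches[[bi]]
        grads <- NULL
        batch_loss <- 0
        for (j in idx) {
          fw <- model_forward(model, train$pixels[[j]], training = TRUE,
                              keep_cache = TRUE)
          y <- y_all[j, ]
          batch_loss <- batch_loss +
            ensemble_loss(y, fw$probs, loss)
          epoch_correct <- epoch_correct + (which.max(fw$probs) == which.max(y))
          gz <- ensemble_logit_grad(y, fw$probs, loss)
          grads <- accumulate_grads(grads, model_backward(model, fw$cache, gz))
        }
        batch_loss <- batch_loss / length(idx)
        if (!is.finite(batch_loss)) {
          stop_input("non-finite loss at epoch %d, batch %d; aborting", epoch, bi)
        }
        grads <- lapply(grads, function(g) g / length(idx))
        lr_t <- effective_learning_rate(config, t_updates)
        up <- rmsprop_update(model$params, grads, state, lr_t,
                             config$rho, config$eps, model$frozen)
        model$params <- up$params
        state <- up$state
        t_updates <- t_updates + 1
        epoch_loss <- epoch_loss + batch_loss * length(idx)
      }
      val_stats <- if (!is.null(val) && nrow(val) > 0) {
        batch_loss_accuracy(model, val, loss)
      } else {
        list(loss = NA_real_, accuracy = NA_real_)
      }
      history[[epoch]] <- tibble(
        epoch = epoch,
        train_loss = epoch_loss / n,
        train_accuracy = epoch_correct / n,
        val_loss = val_stats$loss,
        val_accuracy = val_stats$accuracy,
        lr = effective_learning_rate(config, t_updates)
      )
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  acc %.3f  val_acc %s",
                        epoch, epoch_loss / n, epoch_correct / n,
                        format(val_stats$accuracy, digits = 3)))
      }
      if (!is.na(val_stats$accuracy) && val_stats$accuracy > best$acc) {
        best <- list(acc = val_stats$accuracy, params = model$params,
                     epoch = epoch)
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
      }
      if (!is.null(config$stop_at_val_accuracy) && !is.na(val_stats$accuracy) &&
          val_stats$accuracy >= config$stop_at_val_accuracy) break
      if (!is.null(config$early_stop_patience) &&
          since_best >= config$early_stop_patience) break
    }
  })

  history <- dplyr::bind_rows(history)
  best_model <- model
  if (is.finite(best$acc)) best_model$params <- best$params
  fit <- structure(list(
    model = best_model, final_model = model, history = history,
    best_epoch = if (is.finite(best$acc)) best$epoch else nrow(history),
    best_val_accuracy = if (is.finite(best$acc)) best$acc else NA_real_,
    loss = loss, train_config = config
  ), class = "attnvgg_fit")
  if (!is.null(config$checkpoint_dir)) {
    dir.create(config$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
    saveRDS(best_model, file.path(config$checkpoint_dir, "best_model.rds"))
    readr::write_csv(history, file.path(config$checkpoint_dir, "history.csv"))
    jsonlite::write_json(
      list(network = unclass(best_model$config), train = unclass(config),
           loss = unclass(fit$loss), best_epoch = fit$best_epoch),
      file.path(config$checkpoint_dir, "run.json"),
      auto_unbox = TRUE, null = "null")
  }
  fit
}

#' @export
print.attnvgg_fit <- function(x, ...) {
  cat(sprintf("<attnvgg_fit> %d epochs, best val accuracy %s (epoch %d), loss %s\n",
              nrow(x$history), format(x$best_val_accuracy, digits = 3),
              x$best_epoch, x$loss$name))
  invisible(x)
}

#' Evaluate a model on a partition
#'
#' Argmax classification with malignant as the positive class.
#'
#' @param model An `attnvgg_model` or `attnvgg_fit` (its best-validation
#'   model is used).
#' @param samples A samples tibble with `label` and `pixels`.
#' @return List: `predictions` (tibble `id`, `truth`, `predicted`,
#'   `p_malignant`), `confusion` (a [confusion_matrix()]), `metrics`
#'   (from [compute_metrics()]).
#' @export
evaluate_model <- function(model, samples) {
  if (inherits(model, "attnvgg_fit")) model <- model$model
  if (is.null(samples) || nrow(samples) == 0) stop_input("cannot evaluate an empty partition")
  probs <- predict_proba(model, samples)
  predicted <- class_levels()[max.col(probs, ties.method = "first")]
  predictions <- tibble(
    id = samples$id %||% as.character(seq_len(nrow(samples))),
    truth = samples$label, predicted = predicted,
    p_malignant = probs[, "malignant"]
  )
  confusion <- confusion_from_labels(predictions$truth, predictions$predicted)
  list(predictions = predictions, confusion = confusion,
       metrics = compute_metrics(confusion))
}
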