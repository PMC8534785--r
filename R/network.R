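# Modified VGG16 classifier. The backbone is the standard 13-conv/5-pool
# VGG16 stack (3x3 kernels, ReLU, 2x2 max-pool stride 2 after each block).
# In sequential indexing (convs and pools interleaved, 18 layers total)
# layer 13 is the last conv of block 4 and layer 18 the block-5 pool; the
# attention gate takes layer 13 as input features x and layer 18 as the
# gating signal g, the only reading under which g is strictly coarser
# than x. The gated features are fused with the upsampled gating context,
# global-average-pooled and classified by a small dense head
# (default 10 hidden units).

vgg16_layer_types <- function() {
  c("conv", "conv", "pool",
    "conv", "conv", "pool",
    "conv", "conv", "conv", "pool",
    "conv", "conv", "conv", "pool",
    "conv", "conv", "conv", "pool")
}

vgg16_base_channels <- function() {
  c(64, 64, 128, 128, 256, 256, 256, 512, 512, 512, 512, 512, 512)
}

# Spatial side of each sequential layer's output for a given input side:
# halves at every pool, unchanged by convs (stride 1, padding 1).
layer_spatial_sizes <- function(input_size) {
  input_size / 2^cumsum(vgg16_layer_types() == "pool")
}

#' Network configuration
#'
#' @param input_size Input side in pixels; must be a multiple of 32 (five
#'   stride-2 pools). Default 128.
#' @param in_channels Input channels fed to the backbone (grayscale images
#'   are replicated); default 3.
#' @param width_multiplier Scales every channel count, in (0, 1\];
#'   sub-unit values give desk-scale models that train in minutes on one
#'   CPU while keeping the architecture intact.
#' @param attention_x_layer Sequential index of the layer whose output is
#'   the attention input features (default 13, the last conv of block 4).
#' @param attention_g_layer Sequential index supplying the gating signal
#'   (default 18, the block-5 pool output); must be strictly deeper, i.e.
#'   at least one pool after `attention_x_layer`.
#' @param head_hidden_units Hidden units in the dense head; default 10.
#' @param dropout_rate Dropout probability in the head, in \[0, 1).
#' @param n_classes Output classes; default 2 (benign, malignant).
#' @param use_attention `FALSE` builds the plain modified-VGG16
#'   comparator: identical backbone and head, no gate.
#' @param fuse_channels Output channels of the pointwise fusion conv;
#'   defaults to the x-layer channel count.
#' @param seed Seed for weight initialization.
#' @return A `network_config` list.
#' @export
network_config <- function(input_size = 128, in_channels = 3,
                           width_multiplier = 1,
                           attention_x_layer = 13, attention_g_layer = 18,
                           head_hidden_units = 10, dropout_rate = 0.5,
                           n_classes = 2, use_attention = TRUE,
                           fuse_channels = NULL, seed = 1) {
  if (!is_count(input_size) || input_size < 32 || input_size %% 32 != 0) {
    stop_input("input_size must be a multiple of 32 (five stride-2 pools), got %s",
               format(input_size))
  }
  if (width_multiplier <= 0 || width_multiplier > 1) {
    stop_input("width_multiplier must be in (0, 1]")
  }
  if (!is_count(head_hidden_units) || head_hidden_units < 1) {
    stop_input("head_hidden_units must be a positive integer")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) stop_input("dropout_rate must be in [0, 1)")
  types <- vgg16_layer_types()
  n_layers <- length(types)
  if (!is_count(attention_x_layer) || attention_x_layer < 1 ||
      attention_x_layer > n_layers || types[attention_x_layer] != "conv") {
    stop_input("attention_x_layer must index a conv layer (1..%d), got %s",
               n_layers, format(attention_x_layer))
  }
  if (!is_count(attention_g_layer) || attention_g_layer > n_layers ||
      attention_g_layer <= attention_x_layer) {
    stop_input("attention_g_layer (%s) must lie after attention_x_layer (%s)",
               format(attention_g_layer), format(attention_x_layer))
  }
  pools_between <- sum(types[(attention_x_layer + 1):attention_g_layer] == "pool")
  if (pools_between < 1) {
    stop_input("the gating layer must be spatially coarser than the input-feature layer (no pooling between layers %d and %d)",
               attention_x_layer, attention_g_layer)
  }
  structure(list(
    input_size = as.integer(input_size), in_channels = as.integer(in_channels),
    width_multiplier = width_multiplier,
    attention_x_layer = as.integer(attention_x_layer),
    attention_g_layer = as.integer(attention_g_layer),
    head_hidden_units = as.integer(head_hidden_units),
    dropout_rate = dropout_rate, n_classes = as.integer(n_classes),
    use_attention = isTRUE(use_attention),
    fuse_channels = fuse_channels, seed = seed
  ), class = "network_config")
}

scaled_channels <- function(config) {
  pmax(1L, as.integer(round(vgg16_base_channels() * config$width_multiplier)))
}

# Channel count of a sequential layer's output.
layer_channels <- function(config, index) {
  types <- vgg16_layer_types()
  conv_ids <- cumsum(types == "conv")
  scaled_channels(config)[conv_ids[index]]
}

#' Build an attention-VGG16 (or plain VGG16) classifier
#'
#' Instantiates every weight of the configured network with He
#' initialization under `config$seed`. The returned model is a plain R
#' object; [predict_proba()] runs it and [train_model()] fits it.
#'
#' @param config A [network_config()].
#' @return An `attnvgg_model` list with elements `config` and `params`
#'   (flat named list of weight arrays).
#' @export
#' @examples
#' m <- build_model(network_config(width_multiplier = 1 / 32, input_size = 32))
#' count_parameters(m)
build_model <- function(config = network_config()) {
  stopifnot(inherits(config, "network_config"))
  ch <- scaled_channels(config)
  types <- vgg16_layer_types()
  params <- list()
  with_local_seed(config$seed, {
    c_in <- config$in_channels
    for (k in seq_along(ch)) {
      fan_in <- 9 * c_in
      params[[sprintf("conv%02d.w", k)]] <-
        matrix(rnorm(fan_in * ch[k], 0, sqrt(2 / fan_in)), fan_in, ch[k])
      params[[sprintf("conv%02d.b", k)]] <- rep(0, ch[k])
      c_in <- ch[k]
    }
    c_x <- layer_channels(config, config$attention_x_layer)
    c_g <- layer_channels(config, config$attention_g_layer)
    if (config$use_attention) {
      ag <- ag_params(c_x, c_g, seed = derive_seed(config$seed, 1, salt = 3))
      for (nm in names(ag)) params[[paste0("attn.", nm)]] <- ag[[nm]]
      c_fuse <- config$fuse_channels %||% c_x
      fan_in <- c_x + c_g
      params[["fuse.w"]] <-
        matrix(rnorm(fan_in * c_fuse, 0, sqrt(2 / fan_in)), fan_in, c_fuse)
      params[["fuse.b"]] <- rep(0, c_fuse)
      head_in <- c_fuse
    } else {
      head_in <- c_g
    }
    h <- config$head_hidden_units
    params[["fc1.w"]] <- matrix(rnorm(head_in * h, 0, sqrt(2 / head_in)), head_in, h)
    params[["fc1.b"]] <- rep(0, h)
    params[["fc2.w"]] <- matrix(rnorm(h * config$n_classes, 0, sqrt(2 / h)),
                                h, config$n_classes)
    params[["fc2.b"]] <- rep(0, config$n_classes)
  })
  structure(list(config = config, params = params, frozen = character()),
            class = "attnvgg_model")
}

#' @export
print.attnvgg_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<attnvgg_model> %s, input %dx%dx%d, width x%.3g, %s parameters\n",
              if (cfg$use_attention) "attention-VGG16" else "VGG16",
              cfg$input_size, cfg$input_size, cfg$in_channels,
              cfg$width_multiplier,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#'
#' @param model An `attnvgg_model`.
#' @return Integer number of scalar weights.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "attnvgg_model"))
  sum(vapply(model$params, length, integer(1)))
}

prepare_input <- function(config, img) {
  img <- as_map(img)
  d <- dim(img)
  if (d[1] != config$input_size || d[2] != config$input_size) {
    stop_input("image is %dx%d but the network expects %dx%d",
               d[1], d[2], config$input_size, config$input_size)
  }
  if (d[3] == 1 && config$in_channels == 3) {
    img <- array(rep(img, 3), c(d[1], d[2], 3)) # replicate grayscale
  } else if (d[3] != config$in_channels) {
    stop_input("image has %d channels but the network expects %d",
               d[3], config$in_channels)
  }
  img
}

# Full forward pass for one image. With keep_cache = TRUE every
# intermediate needed by model_backward() is retained. Dropout draws from
# the current RNG stream and only fires when training = TRUE.
model_forward <- function(model, img, training = FALSE, keep_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  x <- prepare_input(cfg, img)
  types <- vgg16_layer_types()
  n_run <- if (cfg$use_attention) max(cfg$attention_g_layer, 18L) else 18L
  acts <- vector("list", n_run)
  caches <- vector("list", n_run)
  conv_id <- 0L
  cur <- x
  for (i in seq_len(n_run)) {
    if (types[i] == "conv") {
      conv_id <- conv_id + 1L
      f <- conv3x3_forward(cur, p[[sprintf("conv%02d.w", conv_id)]],
                           p[[sprintf("conv%02d.b", conv_id)]],
                           keep_cache = keep_cache)
      cur <- relu(f$out)
      if (keep_cache) caches[[i]] <- list(type = "conv", id = conv_id,
                                          conv = f$cache, out = cur)
    } else {
      f <- maxpool2_forward(cur)
      cur <- f$out
      if (keep_cache) caches[[i]] <- list(type = "pool", pool = f$cache)
    }
    acts[[i]] <- if (keep_cache || i %in% c(cfg$attention_x_layer, cfg$attention_g_layer)) cur else NULL
  }

  if (cfg$use_attention) {
    x_map <- acts[[cfg$attention_x_layer]]
    g_map <- acts[[cfg$attention_g_layer]]
    gate <- attention_gate(x_map, g_map, list(
      w_x = p[["attn.w_x"]], w_g = p[["attn.w_g"]], b_g = p[["attn.b_g"]],
      psi = p[["attn.psi"]], b_psi = p[["attn.b_psi"]]
    ), keep_cache = keep_cache)
    fused <- fuse_attended(gate$gated, g_map, p[["fuse.w"]], p[["fuse.b"]],
                           keep_cache = keep_cache)
    feat <- fused
  } else {
    feat <- acts[[18L]]
  }
  df <- dim(feat)
  v <- colMeans(matrix(feat, nrow = df[1] * df[2])) # global average pool

  pre1 <- drop(crossprod(p[["fc1.w"]], v)) + p[["fc1.b"]]
  h <- relu(pre1)
  if (training && cfg$dropout_rate > 0) {
    keep <- stats::rbinom(length(h), 1, 1 - cfg$dropout_rate) / (1 - cfg$dropout_rate)
  } else {
    keep <- rep(1, length(h))
  }
  h_drop <- h * keep
  z <- drop(crossprod(p[["fc2.w"]], h_drop)) + p[["fc2.b"]]
  probs <- softmax_(z)

  out <- list(probs = probs, logits = z,
              coefficients = if (cfg$use_attention) gate$coefficients else NULL)
  if (keep_cache) {
    out$cache <- list(caches = caches, acts = acts, feat_dim = df,
                      v = v, pre1 = pre1, h = h, keep = keep, h_drop = h_drop,
                      probs = probs,
                      gate = if (cfg$use_attention) gate else NULL,
                      fused = if (cfg$use_attention) fused else NULL,
                      n_run = n_run)
  }
  out
}

# Reverse pass from the logit gradient; returns a flat named list of
# parameter gradients aligned with model$params.
model_backward <- function(model, cache, g_logits) {
  cfg <- model$config
  p <- model$params
  grads <- list()

  grads[["fc2.w"]] <- outer(cache$h_drop, g_logits)
  grads[["fc2.b"]] <- g_logits
  g_h <- drop(p[["fc2.w"]] %*% g_logits) * cache$keep
  g_pre1 <- g_h * (cache$pre1 > 0)
  grads[["fc1.w"]] <- outer(cache$v, g_pre1)
  grads[["fc1.b"]] <- g_pre1
  g_v <- drop(p[["fc1.w"]] %*% g_pre1)

  df <- cache$feat_dim
  g_feat <- array(rep(g_v / (df[1] * df[2]), each = df[1] * df[2]), df)

  types <- vgg16_layer_types()
  g_x_extra <- NULL
  if (cfg$use_attention) {
    fb <- fuse_attended_backward(g_feat, p[["fuse.w"]], attr(cache$fused, "cache"))
    grads[["fuse.w"]] <- fb$gw
    grads[["fuse.b"]] <- fb$gb
    ab <- attention_gate_backward(fb$g_gated, list(
      w_x = p[["attn.w_x"]], w_g = p[["attn.w_g"]], b_g = p[["attn.b_g"]],
      psi = p[["attn.psi"]], b_psi = p[["attn.b_psi"]]
    ), cache$gate$cache)
    for (nm in names(ab$grads)) grads[[paste0("attn.", nm)]] <- ab$grads[[nm]]
    g_cur <- ab$gg + fb$g_context
    g_x_extra <- ab$gx
    top <- cfg$attention_g_layer
  } else {
    g_cur <- g_feat
    top <- 18L
  }

  for (i in seq(top, 1L)) {
    lc <- cache$caches[[i]]
    if (lc$type == "conv") {
      g_cur <- g_cur * (lc$out > 0)
      cb <- conv3x3_backward(g_cur, p[[sprintf("conv%02d.w", lc$id)]], lc$conv)
      grads[[sprintf("conv%02d.w", lc$id)]] <- cb$gw
      grads[[sprintf("conv%02d.b", lc$id)]] <- cb$gb
      g_cur <- cb$gx
    } else {
      g_cur <- maxpool2_backward(g_cur, lc$pool)
    }
    if (!is.null(g_x_extra) && (i - 1L) == cfg$attention_x_layer) {
      g_cur <- g_cur + g_x_extra
    }
  }
  grads
}

#' Class probabilities for a batch of samples
#'
#' Runs the network in evaluation mode (no dropout); deterministic for a
#' fixed model.
#'
#' @param model An `attnvgg_model`.
#' @param samples A samples tibble with a `pixels` list-column, or a list
#'   of images, or a single image.
#' @return An n x `n_classes` matrix of probabilities, columns
#'   `benign`, `malignant`; each row sums to 1.
#' @export
predict_proba <- function(model, samples) {
  imgs <- if (is.data.frame(samples)) {
    samples$pixels
  } else if (is.list(samples)) {
    samples
  } else {
    list(samples)
  }
  out <- t(vapply(imgs, function(im) model_forward(model, im)$probs,
                  numeric(model$config$n_classes)))
  colnames(out) <- class_levels()[seq_len(model$config$n_classes)]
  out
}

class_levels <- function() c("benign", "malignant")

one_hot <- function(labels, n_classes = 2) {
  idx <- match(labels, class_levels())
  if (anyNA(idx)) stop_input("unknown class label")
  y <- matrix(0, length(labels), n_classes)
  y[cbind(seq_along(labels), idx)] <- 1
  y
}

#' Attention coefficient map for one image
#'
#' @param model An attention-enabled `attnvgg_model`.
#' @param img A single image sized to the network input.
#' @return Matrix of attention coefficients in \[0, 1\] on the x-layer
#'   grid.
#' @export
attention_map <- function(model, img) {
  if (!model$config$use_attention) stop_input("model was built without an attention gate")
  model_forward(model, img)$coefficients
}

#' Load pretrained backbone convolution weights
#'
#' Copies conv weights from a named list (`conv01.w`, `conv01.b`, ...,
#' `conv13.w`, `conv13.b`) into a full-width model; the classification
#' head always keeps its fresh initialization. No weight file ships with
#' the package and none of its tests require one; this is the optional
#' transfer-learning hook.
#'
#' @param model A full-width (`width_multiplier = 1`) `attnvgg_model`.
#' @param weights Named list of conv weight arrays, or path to an RDS file
#'   containing one.
#' @param freeze Character vector of conv blocks to freeze, e.g.
#'   `c("conv01", "conv02")`; frozen parameters are skipped by the
#'   optimiser.
#' @return The model with backbone weights replaced.
#' @export
load_pretrained_backbone <- function(model, weights, freeze = character()) {
  stopifnot(inherits(model, "attnvgg_model"))
  if (model$config$width_multiplier != 1) {
    stop_input("pretrained backbone weights require width_multiplier = 1")
  }
  if (is.character(weights)) {
    if (!file.exists(weights)) {
      stop_input("weight file not found: %s (pretrained weights are optional; tests never require them)",
                 weights)
    }
    weights <- readRDS(weights)
  }
  conv_names <- grep("^conv", names(model$params), value = TRUE)
  missing <- setdiff(conv_names, names(weights))
  if (length(missing) > 0) {
    stop_input("weight list is missing: %s", paste(missing, collapse = ", "))
  }
  for (nm in conv_names) {
    w <- weights[[nm]]
    if (!all(dim(w) %||% length(w) == dim(model$params[[nm]]) %||% length(model$params[[nm]]))) {
      stop_input("shape mismatch for %s", nm)
    }
    model$params[[nm]] <- w
  }
  model$frozen <- unlist(lapply(freeze, function(f) paste0(f, c(".w", ".b"))))
  model
}
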