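test_that("feature-map sizes trace 128 -> 16x16 at the x layer and 4x4 at the g layer", {
  cfg <- network_config(input_size = 128, width_multiplier = 1 / 64, seed = 2)
  m <- build_model(cfg)
  fw <- model_forward(m, matrix(0.5, 128, 128), keep_cache = TRUE)
  expect_equal(dim(fw$cache$acts[[cfg$attention_x_layer]])[1:2], c(16, 16))
  expect_equal(dim(fw$cache$acts[[cfg$attention_g_layer]])[1:2], c(4, 4))
  # one factor-2 pooling stage between them at 64 input too
  sizes <- layer_spatial_sizes(64)
  expect_equal(sizes[13] / sizes[18], 4) # two pools between layers 13 and 18
  expect_equal(sizes[13], 8)
})

test_that("outputs are probability vectors on the simplex", {
  withr::with_seed(31, {
    for (seed in 1:3) {
      m <- build_model(tiny_net(seed = seed))
      batch <- lapply(1:3, function(i) matrix(stats::runif(32 * 32), 32, 32))
      p <- predict_proba(m, batch)
      expect_equal(dim(p), c(3, 2))
      expect_true(all(p >= 0))
      expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
    }
  })
})

test_that("forward passes are deterministic in evaluation mode and finite on degenerate input", {
  m <- build_model(tiny_net())
  batch <- list(matrix(0, 32, 32), matrix(1, 32, 32))
  p1 <- predict_proba(m, batch)
  p2 <- predict_proba(m, batch)
  expect_identical(p1, p2)
  expect_true(all(is.finite(p1)))
  expect_error(predict_proba(m, matrix(0, 16, 16)), "expects")
})

test_that("parameter counts follow closed forms and scale with width", {
  small <- build_model(network_config(width_multiplier = 0.125))
  expect_lt(count_parameters(small),
            sum(vapply(build_model(network_config(width_multiplier = 0.25))$params,
                       length, integer(1))))
  # dense layer k -> m with bias holds k*m + m parameters
  tv <- tidy(small)
  h <- small$config$head_hidden_units
  expect_equal(tv$n_parameters[tv$term == "fc2.w"], h * 2)
  expect_equal(tv$n_parameters[tv$term == "fc2.b"], 2)
  k <- nrow(small$params[["fc1.w"]])
  expect_equal(sum(tv$n_parameters[tv$term %in% c("fc1.w", "fc1.b")]), k * h + h)
  # a 10-unit head is strictly smaller than a 4096-unit head
  big_head <- build_model(network_config(width_multiplier = 0.125,
                                         head_hidden_units = 4096))
  expect_lt(count_parameters(small), count_parameters(big_head))
})

test_that("attention adds exactly the hand-computed gate and fusion parameters", {
  cfg_a <- tiny_net(use_attention = TRUE)
  cfg_p <- tiny_net(use_attention = FALSE)
  with_gate <- build_model(cfg_a)
  without <- build_model(cfg_p)
  c_x <- layer_channels(cfg_a, cfg_a$attention_x_layer)
  c_g <- layer_channels(cfg_a, cfg_a$attention_g_layer)
  c_i <- max(1, floor(c_x / 2))
  c_f <- c_x
  gate_params <- c_x * c_i + c_g * c_i + c_i + # w_x, w_g, b_g
    c_i + 1 + # psi, b_psi
    (c_x + c_g) * c_f + c_f # pointwise fusion
  # the plain head reads c_g channels, the attended head c_f
  head_diff <- (c_f - c_g) * cfg_a$head_hidden_units
  expect_equal(count_parameters(with_gate) - count_parameters(without),
               gate_params + head_diff)
})

test_that("invalid configurations are rejected", {
  expect_error(network_config(input_size = 100), "multiple of 32")
  expect_error(network_config(attention_x_layer = 3), "conv layer")
  expect_error(network_config(attention_x_layer = 15, attention_g_layer = 17),
               "coarser")
  expect_error(network_config(attention_x_layer = 13, attention_g_layer = 10),
               "after")
  expect_error(network_config(attention_x_layer = 18), "conv layer")
  expect_error(network_config(width_multiplier = 0), "width_multiplier")
  expect_error(network_config(dropout_rate = 1), "dropout_rate")
})

test_that("whole-network gradients match central finite differences", {
  m <- build_model(tiny_net(seed = 3))
  withr::with_seed(12, {
    img <- matrix(stats::runif(32 * 32), 32, 32)
    y <- c(0, 1)
    lc <- loss_config("ce_logcosh")
    fw <- model_forward(m, img, keep_cache = TRUE)
    grads <- model_backward(m, fw$cache, ensemble_logit_grad(y, fw$probs, lc))
    loss_at <- function(params) {
      m2 <- m; m2$params <- params
      ensemble_loss(y, model_forward(m2, img)$probs, lc)
    }
    checked <- 0
    for (nm in c("conv01.w", "conv07.b", "conv13.w", "attn.w_x", "attn.w_g",
                 "attn.b_g", "attn.psi", "attn.b_psi", "fuse.w", "fc1.w",
                 "fc1.b", "fc2.w", "fc2.b")) {
      i <- sample(length(m$params[[nm]]), 1)
      eps <- 1e-5
      pp <- m$params
      pp[[nm]][i] <- pp[[nm]][i] + eps
      up <- loss_at(pp)
      pp[[nm]][i] <- pp[[nm]][i] - 2 * eps
      dn <- loss_at(pp)
      expect_equal(grads[[nm]][i], (up - dn) / (2 * eps), tolerance = 1e-5,
                   ignore_attr = TRUE)
      checked <- checked + 1
    }
    expect_equal(checked, 13)
  })
})

test_that("pretrained backbone loading validates width, shapes, and freezing", {
  m <- build_model(tiny_net())
  expect_error(load_pretrained_backbone(m, list()), "width_multiplier")
  full <- build_model(network_config(seed = 1))
  donor <- build_model(network_config(seed = 99))
  conv_names <- grep("^conv", names(donor$params), value = TRUE)
  loaded <- load_pretrained_backbone(full, donor$params[conv_names],
                                     freeze = c("conv01", "conv02"))
  expect_identical(loaded$params[["conv01.w"]], donor$params[["conv01.w"]])
  # head stays freshly initialized
  expect_identical(loaded$params[["fc1.w"]], full$params[["fc1.w"]])
  expect_setequal(loaded$frozen, c("conv01.w", "conv01.b", "conv02.w", "conv02.b"))
  expect_error(load_pretrained_backbone(full, donor$params[conv_names[-1]]),
               "missing")
  expect_error(load_pretrained_backbone(full, "/nonexistent/weights.rds"),
               "optional")
})
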