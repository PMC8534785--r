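test_that("history records one row per epoch with the tracked metrics", {
  s <- random_samples(4, size = 32, seed = 2)
  m <- build_model(tiny_net())
  fit <- train_model(m, list(train = s, validation = s[1:2, ]),
                     loss = loss_config("ce"),
                     config = train_config(learning_rate = 1e-4, epochs = 1,
                                           batch_size = 4, seed = 1))
  expect_equal(nrow(fit$history), 1)
  expect_named(fit$history, c("epoch", "train_loss", "train_accuracy",
                              "val_loss", "val_accuracy", "lr"))
  expect_true(all(is.finite(unlist(fit$history))))
})

test_that("a zero learning rate leaves every weight untouched", {
  s <- random_samples(3, size = 32, seed = 5)
  m <- build_model(tiny_net(seed = 11))
  fit <- train_model(m, list(train = s, validation = NULL),
                     config = train_config(learning_rate = 0, epochs = 2,
                                           batch_size = 2, seed = 3))
  expect_identical(fit$final_model$params, m$params)
})

test_that("the decay schedule follows lr0 / (1 + decay * t) exactly", {
  cfg <- train_config(learning_rate = 0.1, decay = 0.5)
  expect_equal(effective_learning_rate(cfg, 0:4),
               c(0.1, 0.1 / 1.5, 0.1 / 2, 0.1 / 2.5, 0.1 / 3))
  cfg <- train_config(learning_rate = 2e-6, decay = 1e-6)
  expect_equal(effective_learning_rate(cfg, 1000), 2e-6 / (1 + 1e-3))
})

test_that("training is reproducible under a fixed seed", {
  s <- random_samples(4, size = 32, seed = 7)
  run <- function() {
    m <- build_model(tiny_net(seed = 2))
    train_model(m, list(train = s, validation = s[c(1, 8), ]),
                config = train_config(learning_rate = 1e-3, epochs = 2,
                                      batch_size = 4, seed = 9))
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$history, f2$history)
  expect_identical(f1$final_model$params[["conv05.w"]],
                   f2$final_model$params[["conv05.w"]])
})

test_that("all three losses reduce the loss on a two-sample memorization task", {
  withr::with_seed(23, {
    tr <- tibble::tibble(
      id = c("a", "b"), label = c("benign", "malignant"),
      pixels = list(matrix(stats::runif(1024, 0, 0.5), 32, 32),
                    matrix(stats::runif(1024, 0.5, 1), 32, 32))
    )
  })
  for (loss_name in c("ce", "logcosh", "ce_logcosh")) {
    cfg <- tiny_net(seed = 4, dropout_rate = 0)
    fit <- train_model(build_model(cfg), list(train = tr, validation = NULL),
                       loss = loss_config(loss_name),
                       config = train_config(learning_rate = 1e-3, epochs = 50,
                                             batch_size = 2, seed = 6))
    expect_lt(fit$history$train_loss[50], fit$history$train_loss[1])
  }
})

test_that("non-finite losses abort with the offending epoch and batch", {
  s <- random_samples(2, size = 32, seed = 1)
  s$pixels[[2]][1, 1] <- NaN
  m <- build_model(tiny_net())
  expect_error(
    train_model(m, list(train = s, validation = NULL),
                config = train_config(learning_rate = 1e-4, epochs = 1,
                                      batch_size = 4, seed = 1)),
    "epoch 1, batch 1"
  )
})

test_that("frozen parameters are skipped by the optimiser", {
  s <- random_samples(3, size = 32, seed = 9)
  m <- build_model(tiny_net(seed = 8))
  m$frozen <- c("conv01.w", "conv01.b")
  fit <- train_model(m, list(train = s, validation = NULL),
                     config = train_config(learning_rate = 1e-3, epochs = 1,
                                           batch_size = 3, seed = 2))
  expect_identical(fit$final_model$params[["conv01.w"]], m$params[["conv01.w"]])
  expect_false(identical(fit$final_model$params[["conv02.w"]],
                         m$params[["conv02.w"]]))
})

test_that("evaluation produces a conserving confusion matrix and argmax labels", {
  s <- random_samples(5, size = 32, seed = 12)
  m <- build_model(tiny_net(seed = 21))
  ev <- evaluate_model(m, s)
  cm <- ev$confusion
  expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, nrow(s))
  expect_equal(nrow(ev$predictions), nrow(s))
  expect_true(all(ev$predictions$predicted %in% c("benign", "malignant")))
  expect_error(evaluate_model(m, s[0, ]), "empty")
  # a constant benign predictor on 5 malignant samples: TP = 0, FN = 5
  cm0 <- confusion_from_labels(rep("malignant", 5), rep("benign", 5))
  expect_equal(c(cm0$tp, cm0$fn), c(0, 5))
})

test_that("fit accessors summarise the run", {
  s <- random_samples(3, size = 32, seed = 2)
  fit <- train_model(build_model(tiny_net()),
                     list(train = s, validation = s[1:2, ]),
                     config = train_config(learning_rate = 1e-4, epochs = 2,
                                           batch_size = 3, seed = 1))
  g <- glance(fit)
  expect_equal(g$epochs, 2)
  expect_equal(g$loss, "ce_logcosh")
  td <- tidy(fit)
  expect_setequal(unique(td$metric),
                  c("train_loss", "train_accuracy", "val_loss", "val_accuracy", "lr"))
  expect_s3_class(autoplot(fit), "ggplot")
})
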