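test_that("conv and pool output lengths follow the floor formulas", {
  expect_identical(conv_output_length(846, 3, 1, 0), 844L)
  expect_identical(conv_output_length(100, 1, 1, 0), 100L)
  expect_identical(conv_output_length(422, 3), 420L)
  expect_identical(conv_output_length(420, 3), 418L)
  expect_identical(pool_output_length(844, 2), 422L)
  expect_identical(pool_output_length(102, 2), 51L)
  expect_identical(pool_output_length(5, 2), 2L)  # trailing element dropped
  expect_error(conv_output_length(2, 3), "kernel")
  expect_error(pool_output_length(1, 2), "window")
})

test_that("declared layout matches an actual forward pass for random specs", {
  withr::with_seed(42, {
    for (i in 1:8) {
      spec <- network_spec(
        input_length = sample(40:120, 1),
        blocks = sample(2:6, sample(1:3, 1), replace = TRUE),
        fc_sizes = c(sample(5:12, 1), 3L))
      model <- build_network(spec, seed = i)
      layout <- tidy(model)
      x <- matrix(runif(spec$input_length), nrow = 1)
      fwd <- conformotif:::nn_forward(model, x, record = TRUE)
      # observed output of layer li is the input recorded at layer li+1
      for (li in seq_len(length(model$layers) - 1)) {
        out_obs <- fwd$caches[[li + 1]]$input
        declared <- layout[layout$layer == li, ]
        if (declared$type %in% c("conv", "relu", "pool") &&
            length(dim(out_obs)) == 3) {
          expect_identical(dim(out_obs)[1], as.integer(declared$out_length))
          expect_identical(dim(out_obs)[2], as.integer(declared$out_channels))
        } else if (declared$type %in% c("flatten", "dense")) {
          expect_identical(ncol(out_obs), as.integer(declared$out_length))
        }
      }
      expect_identical(ncol(fwd$logits), as.integer(tail(spec$fc_sizes, 1)))
      # parameter_count equals the trainable scalars actually allocated
      actual <- sum(vapply(model$layers, function(ly) {
        if (!is.null(ly$W)) length(ly$W) + length(ly$b) else 0L
      }, numeric(1)))
      expect_equal(actual, sum(layout$n_parameters))
    }
  })
})

test_that("a spec that shrinks below the kernel is rejected at build", {
  expect_error(network_spec(input_length = 20,
                            blocks = c(4, 4, 4, 4, 4)),
               "losing relevant information")
})

test_that("initialisation is deterministic given the seed", {
  spec <- network_spec(input_length = 30, blocks = c(4L),
                       fc_sizes = c(8L, 3L))
  m1 <- build_network(spec, seed = 5)
  m2 <- build_network(spec, seed = 5)
  expect_identical(m1$layers, m2$layers)
  m3 <- build_network(spec, seed = 6)
  expect_false(identical(m1$layers[[1]]$W, m3$layers[[1]]$W))
})

test_that("prediction takes the argmax with lowest-index tie-break", {
  spec <- network_spec(input_length = 12, blocks = c(4L),
                       fc_sizes = c(8L, 3L))
  m <- build_network(spec, seed = 1)
  # overwrite the head so the logits are controlled
  dense_idx <- which(vapply(m$layers, function(l) l$type, "") == "dense")
  last <- dense_idx[length(dense_idx)]
  m$layers[[last]]$W <- matrix(0, nrow(m$layers[[last]]$W), 3)
  m$layers[[last]]$b <- c(2.0, 0.1, -1.0)
  x <- matrix(runif(12 * 5), nrow = 5)
  expect_identical(predict(m, x), rep("active", 5))
  m$layers[[last]]$b <- c(1.0, 1.0, 0.0)  # tie between classes 1 and 2
  expect_identical(predict(m, x[1, , drop = FALSE]), "active")
  expect_error(predict(m, matrix(1, 1, 11)), "features")
})

test_that("zero-epoch training returns the model unchanged", {
  spec <- network_spec(input_length = 12, blocks = c(4L),
                       fc_sizes = c(8L, 3L))
  m <- build_network(spec, seed = 1)
  x <- matrix(runif(24), 2)
  m2 <- train_cnn(m, x, c("active", "inactive"),
                  train_config(epochs = 0, seed = 1))
  expect_identical(m2$layers, m$layers)
})

test_that("one epoch of training decreases the loss on a fixed batch", {
  tt <- tiny_trained_model()
  spec <- network_spec(input_length = 12, blocks = c(4L),
                       fc_sizes = c(8L, 3L))
  m0 <- build_network(spec, seed = 3)
  logits0 <- predict(m0, tt$x, type = "logits")
  loss0 <- conformotif:::cross_entropy(
    logits0, conformotif:::labels_to_index(tt$y, m0$class_levels))
  m1 <- train_cnn(m0, tt$x, tt$y,
                  train_config(epochs = 1, batch_size = 30,
                               learning_rate = 1e-2, seed = 4))
  logits1 <- predict(m1, tt$x, type = "logits")
  loss1 <- conformotif:::cross_entropy(
    logits1, conformotif:::labels_to_index(tt$y, m1$class_levels))
  expect_lt(loss1, loss0)
})

test_that("a separable synthetic set is learned to >= 99% in 50 epochs", {
  tt <- tiny_trained_model()  # trained 40 epochs on separated class means
  acc <- mean(predict(tt$model, tt$x) == tt$y)
  expect_gte(acc, 0.99)
  expect_lte(max(tt$model$history$epoch), 50)
})

test_that("training is reproducible seed for seed", {
  tt <- tiny_trained_model()
  spec <- network_spec(input_length = 12, blocks = c(4L),
                       fc_sizes = c(8L, 3L))
  cfg <- train_config(epochs = 3, batch_size = 30, learning_rate = 1e-2,
                      seed = 11)
  m1 <- train_cnn(build_network(spec, seed = 2), tt$x, tt$y, cfg)
  m2 <- train_cnn(build_network(spec, seed = 2), tt$x, tt$y, cfg)
  expect_identical(m1$layers, m2$layers)
  expect_identical(m1$history, m2$history)
})

test_that("tidiers summarise architecture and training", {
  tt <- tiny_trained_model()
  td <- tidy(tt$model)
  expect_true(all(c("layer", "type", "n_parameters") %in% names(td)))
  g <- glance(tt$model)
  expect_true(g$trained)
  expect_identical(g$n_parameters, sum(td$n_parameters))
  expect_lt(g$final_loss, 1.1)  # well below ln(3), the chance-level loss
})
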