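# Shared fixtures, built in code. The reference study condition: a
# 60-residue receptor, 200 trajectories x 30 frames, 6 planted residues
# with displacement-to-noise ratio delta/sigma = 5; trained for a reduced
# 50-epoch run on a compact 3-block network. Heavy results are cached so
# several test files can assert on one run.

.fixture_cache <- new.env(parent = emptyenv())

fixture_synth_config <- function() synth_config(seed = 11L)

fixture_spec <- function() {
  network_spec(input_length = 180L, blocks = c(16L, 32L, 64L),
               fc_sizes = c(128L, 3L))
}

fixture_train_config <- function(epochs = 50L) {
  train_config(epochs = epochs, batch_size = 256L, learning_rate = 1e-3,
               seed = 5L)
}

# generate + undersample + split + normalize + train + evaluate, once
fixture_run <- function() {
  if (!is.null(.fixture_cache$run)) return(.fixture_cache$run)
  ens <- generate_ensemble(fixture_synth_config())
  ef <- ensemble_features(ens$trajectories)
  keep <- undersample(ef$frame_info$label, seed = 2L)
  split <- stratified_split(keep, ef$frame_info$label[keep],
                            train_fraction = 0.7, seed = 3L)
  scaler <- fit_minmax(ef$features[split$train, , drop = FALSE])
  x <- apply_minmax(scaler, ef$features)
  model <- build_network(fixture_spec(), seed = 4L)
  model <- train_cnn(model, x[split$train, , drop = FALSE],
                     ef$frame_info$label[split$train],
                     fixture_train_config())
  evaluation <- evaluate_model(model, x[split$validation, , drop = FALSE],
                               ef$frame_info$label[split$validation])
  .fixture_cache$run <- list(ensemble = ens, ef = ef, split = split,
                             x = x, model = model, evaluation = evaluation)
  .fixture_cache$run
}

# a tiny trained dense-head CNN for cheap contract tests
tiny_trained_model <- function() {
  if (!is.null(.fixture_cache$tiny)) return(.fixture_cache$tiny)
  withr::with_seed(99, {
    n <- 90
    centers <- matrix(c(0, 3, 6), nrow = 3, ncol = 12)
    y <- rep(state_levels(), each = n / 3)
    x <- centers[rep(1:3, each = n / 3), ] +
      matrix(rnorm(n * 12, 0, 0.3), n)
  })
  x <- apply_minmax(fit_minmax(x), x)
  spec <- network_spec(input_length = 12L, blocks = c(8L),
                       fc_sizes = c(16L, 3L), dropout = 0)
  m <- build_network(spec, seed = 1L)
  m <- train_cnn(m, x, y, train_config(epochs = 40L, batch_size = 30L,
                                       learning_rate = 1e-2, seed = 2L))
  .fixture_cache$tiny <- list(model = m, x = x, y = y)
  .fixture_cache$tiny
}

# independent oracle: analytic gradient of one logit w.r.t. the input of a
# dense ReLU network, via masked weight products (no shared code with the
# relevance engine)
dense_logit_gradient <- function(model, x, class_idx) {
  a <- as.numeric(x)
  mats <- list()
  for (ly in model$layers) {
    if (ly$type == "dense") {
      z <- drop(a %*% ly$W) + ly$b
      mats[[length(mats) + 1]] <- ly$W
      a <- z
    } else if (ly$type == "relu") {
      mats[[length(mats)]] <- sweep(mats[[length(mats)]], 2,
                                    as.numeric(a > 0), "*")
      a <- pmax(a, 0)
    }
  }
  Reduce(`%*%`, mats)[, class_idx]
}

# independent oracle: unroll a 1D convolution (stride 1, no padding) into
# its dense weight matrix over flattened [L, C] inputs (column-major, as
# the package flattens)
unroll_conv_matrix <- function(W, L_in) {
  K <- dim(W)[1]; C_in <- dim(W)[2]; C_out <- dim(W)[3]
  L_out <- L_in - K + 1
  dense <- matrix(0, L_in * C_in, L_out * C_out)
  for (o in seq_len(C_out))
    for (t in seq_len(L_out))
      for (c in seq_len(C_in))
        for (k in seq_len(K)) {
          dense[(c - 1) * L_in + t + k - 1, (o - 1) * L_out + t] <-
            W[k, c, o]
        }
  dense
}
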