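# Small fully connected networks. Used for experimentation and for
# validating the relevance rules against closed-form oracles (for bias-free
# ReLU networks LRP-0 coincides with gradient x input).

#' Build a small dense ReLU network
#'
#' A plain fully connected ReLU network sharing the `conformo_cnn`
#' machinery (forward pass, prediction, relevance propagation). Mainly a
#' harness for studying the propagation rules on architectures where
#' closed-form references are easy to compute.
#'
#' @param sizes Integer vector of layer widths, input first, classes last
#'   (e.g. `c(3, 5, 4, 3)`).
#' @param seed Seed for the Kaiming-uniform initialisation.
#' @param bias If `FALSE`, all biases are fixed at zero (the regime in
#'   which the basic rule conserves relevance exactly).
#' @return A `conformo_cnn` whose layers are dense/ReLU only.
#' @export
dense_network <- function(sizes, seed = 1L, bias = TRUE) {
  if (length(sizes) < 2) abort("need at least input and output sizes")
  layers <- withr::with_seed(seed, {
    lst <- list(list(type = "flatten"))
    for (i in seq_len(length(sizes) - 1)) {
      lst[[length(lst) + 1]] <- list(
        type = "dense",
        W = kaiming_uniform(c(sizes[i], sizes[i + 1]), fan_in = sizes[i]),
        b = if (bias) stats::runif(sizes[i + 1], -0.1, 0.1) else
          numeric(sizes[i + 1]))
      if (i < length(sizes) - 1) {
        lst[[length(lst) + 1]] <- list(type = "relu")
      }
    }
    lst
  })
  spec <- structure(list(input_length = as.integer(sizes[1]), blocks = integer(),
                         kernel = NA_integer_, stride = NA_integer_,
                         padding = NA_integer_, pool_window = NA_integer_,
                         fc_sizes = as.integer(sizes[-1]), dropout = 0),
                    class = "network_spec")
  structure(list(spec = spec, layers = layers,
                 class_levels = paste0("class", seq_len(sizes[length(sizes)])),
                 history = tibble(epoch = integer(), loss = numeric(),
                                  accuracy = numeric()),
                 trained = FALSE),
            class = "conformo_cnn")
}
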