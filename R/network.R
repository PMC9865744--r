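# Block-structured 1D-CNN: spec, shape arithmetic, parameter counting,
# construction, and the forward pass. Convolutions use kernel 3, stride 1,
# no padding; each block is conv -> ReLU -> max-pool(2). The classifier head
# is flatten -> dense -> ReLU -> dropout -> dense.

#' Network architecture specification
#'
#' Describes the block-growth 1D-CNN. The default reproduces the
#' four-block reference architecture for an 846-long input (282 residues x
#' 3 coordinates): filter ladder 64/128/256/512, kernel 3, stride 1, no
#' padding, max-pool window 2, then fully connected 1024 -> 3 with dropout
#' 0.5 after the first dense layer.
#'
#' @param input_length Input vector length (3M). Default 846.
#' @param blocks Integer vector of per-block filter counts.
#' @param kernel,stride,padding Convolution geometry (defaults 3/1/0).
#' @param pool_window Max-pool window (default 2).
#' @param fc_sizes Sizes of the dense head; last entry is the class count.
#' @param dropout Dropout rate after the first dense layer.
#' @return Object of class `network_spec`.
#' @export
network_spec <- function(input_length = 846L, blocks = c(64L, 128L, 256L, 512L),
                         kernel = 3L, stride = 1L, padding = 0L,
                         pool_window = 2L, fc_sizes = c(1024L, 3L),
                         dropout = 0.5) {
  spec <- structure(
    list(input_length = as.integer(input_length),
         blocks = as.integer(blocks), kernel = as.integer(kernel),
         stride = as.integer(stride), padding = as.integer(padding),
         pool_window = as.integer(pool_window),
         fc_sizes = as.integer(fc_sizes), dropout = dropout),
    class = "network_spec")
  invisible(spec_layout(spec))  # validates the shape recursion
  spec
}

#' Output length of a 1D convolution
#'
#' `floor((L + 2 padding - kernel) / stride) + 1`.
#'
#' @param length Input length.
#' @param kernel,stride,padding Convolution geometry.
#' @return Integer output length.
#' @export
conv_output_length <- function(length, kernel = 3L, stride = 1L,
                               padding = 0L) {
  if (length + 2 * padding < kernel) {
    abort(paste0("degenerate convolution: input length ", length,
                 " shorter than kernel ", kernel,
                 ". Adding more blocks would lead to losing relevant ",
                 "information."))
  }
  as.integer(floor((length + 2 * padding - kernel) / stride) + 1)
}

#' Output length of a 1D max-pool
#'
#' `floor(L / window)`; a trailing remainder shorter than the window is
#' dropped.
#'
#' @param length Input length.
#' @param window Pool window.
#' @return Integer output length.
#' @export
pool_output_length <- function(length, window = 2L) {
  if (length < window) {
    abort(paste0("degenerate pooling: input length ", length,
                 " shorter than window ", window,
                 ". Adding more blocks would lead to losing relevant ",
                 "information."))
  }
  as.integer(floor(length / window))
}

# Layer-by-layer layout of a spec: type, channels, output length, parameter
# count. The single source of truth for shapes and counts.
spec_layout <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  rows <- list()
  len <- spec$input_length
  ch <- 1L
  for (f in spec$blocks) {
    len <- conv_output_length(len, spec$kernel, spec$stride, spec$padding)
    rows[[length(rows) + 1]] <- list(
      type = "conv", out_channels = f, out_length = len,
      n_parameters = f * (ch * spec$kernel) + f)
    rows[[length(rows) + 1]] <- list(
      type = "relu", out_channels = f, out_length = len, n_parameters = 0L)
    len <- pool_output_length(len, spec$pool_window)
    rows[[length(rows) + 1]] <- list(
      type = "pool", out_channels = f, out_length = len, n_parameters = 0L)
    ch <- f
  }
  flat <- ch * len
  if (flat <= 0) abort("flatten length is zero")
  rows[[length(rows) + 1]] <- list(type = "flatten", out_channels = NA_integer_,
                                   out_length = flat, n_parameters = 0L)
  fan_in <- flat
  for (i in seq_along(spec$fc_sizes)) {
    out <- spec$fc_sizes[i]
    rows[[length(rows) + 1]] <- list(
      type = "dense", out_channels = NA_integer_, out_length = out,
      n_parameters = out * fan_in + out)
    if (i < length(spec$fc_sizes)) {
      rows[[length(rows) + 1]] <- list(type = "relu",
                                       out_channels = NA_integer_,
                                       out_length = out, n_parameters = 0L)
      if (spec$dropout > 0) {
        rows[[length(rows) + 1]] <- list(type = "dropout",
                                         out_channels = NA_integer_,
                                         out_length = out, n_parameters = 0L)
      }
    }
    fan_in <- out
  }
  out <- dplyr::bind_rows(lapply(rows, as_tibble))
  out$layer <- seq_len(nrow(out))
  select(out, "layer", "type", "out_channels", "out_length", "n_parameters")
}

#' Per-layer and total trainable parameter counts
#'
#' Conv layer: `filters * (in_channels * kernel) + filters`; dense layer:
#' `out * in + out`; pooling, activations, dropout and flatten contribute
#' nothing.
#'
#' @param spec A [network_spec()].
#' @return Tibble `layer,type,out_channels,out_length,n_parameters`, with
#'   attribute `total` (sum over layers).
#' @export
parameter_count <- function(spec) {
  layout <- spec_layout(spec)
  attr(layout, "total") <- sum(layout$n_parameters)
  layout
}

#' Flattened feature length entering the dense head
#' @param spec A [network_spec()].
#' @return Integer: channels x length after the last pooling layer.
#' @export
flatten_length <- function(spec) {
  layout <- spec_layout(spec)
  as.integer(layout$out_length[layout$type == "flatten"])
}

kaiming_uniform <- function(dims, fan_in) {
  bound <- sqrt(6 / fan_in)  # He et al. uniform bound for ReLU gain
  array(stats::runif(prod(dims), -bound, bound), dim = dims)
}

#' Build an (untrained) network from a spec
#'
#' Weights are initialised with the Kaiming uniform scheme
#' (`U(-sqrt(6/fan_in), sqrt(6/fan_in))`, the ReLU-gain form), biases at
#' zero; identical seeds give bit-identical weights.
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed for the initialisation.
#' @return Object of class `conformo_cnn` (untrained: empty history).
#' @export
build_network <- function(spec = network_spec(), seed = 1L) {
  layout <- spec_layout(spec)
  layers <- withr::with_seed(seed, {
    lst <- list()
    ch <- 1L
    for (f in spec$blocks) {
      lst[[length(lst) + 1]] <- list(
        type = "conv",
        W = kaiming_uniform(c(spec$kernel, ch, f), fan_in = ch * spec$kernel),
        b = numeric(f))
      lst[[length(lst) + 1]] <- list(type = "relu")
      lst[[length(lst) + 1]] <- list(type = "pool", window = spec$pool_window)
      ch <- f
    }
    lst[[length(lst) + 1]] <- list(type = "flatten")
    fan_in <- flatten_length(spec)
    for (i in seq_along(spec$fc_sizes)) {
      out <- spec$fc_sizes[i]
      lst[[length(lst) + 1]] <- list(
        type = "dense", W = kaiming_uniform(c(fan_in, out), fan_in = fan_in),
        b = numeric(out))
      if (i < length(spec$fc_sizes)) {
        lst[[length(lst) + 1]] <- list(type = "relu")
        if (spec$dropout > 0) {
          lst[[length(lst) + 1]] <- list(type = "dropout", p = spec$dropout)
        }
      }
      fan_in <- out
    }
    lst
  })
  structure(list(spec = spec, layers = layers, class_levels = STATE_LEVELS,
                 history = tibble(epoch = integer(), loss = numeric(),
                                  accuracy = numeric()),
                 trained = FALSE),
            class = "conformo_cnn")
}

#' @export
print.conformo_cnn <- function(x, ...) {
  layout <- spec_layout(x$spec)
  cat(sprintf("<conformo_cnn: %d-block 1D-CNN, input %d, %s parameters%s>\n",
              length(x$spec$blocks), x$spec$input_length,
              format(sum(layout$n_parameters), big.mark = ","),
              if (x$trained) sprintf(", trained %d epochs",
                                     max(x$history$epoch)) else ", untrained"))
  invisible(x)
}

as_input_cube <- function(x, input_length) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != input_length) {
    abort(paste0("input has ", ncol(x), " features, network expects ",
                 input_length))
  }
  array(t(x), dim = c(input_length, 1L, nrow(x)))  # [L, C=1, N]
}

# Forward pass over a batch. X is [N, input_length]. When `record` is TRUE
# the per-layer input activations (and pool argmax indices) are kept -
# needed for backprop and for relevance propagation. Dropout masks are
# applied only when `train_rng` is supplied.
nn_forward <- function(model, x, record = FALSE, train_rng = FALSE) {
  cur <- as_input_cube(x, model$spec$input_length)
  n <- dim(cur)[3]
  caches <- if (record) vector("list", length(model$layers))
  dense_mode <- FALSE
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    if (record) caches[[i]] <- list(input = cur)
    if (ly$type == "conv") {
      cur <- conv1d_fwd_cpp(cur, ly$W, ly$b)
    } else if (ly$type == "relu") {
      cur <- pmax(cur, 0)
    } else if (ly$type == "pool") {
      res <- maxpool1d_fwd_cpp(cur, ly$window)
      cur <- res$out
      if (record) caches[[i]]$argmax <- res$argmax
    } else if (ly$type == "flatten") {
      cur <- t(matrix(cur, nrow = dim(cur)[1] * dim(cur)[2]))  # [N, F]
      dense_mode <- TRUE
    } else if (ly$type == "dense") {
      cur <- sweep(cur %*% ly$W, 2, ly$b, "+")
    } else if (ly$type == "dropout") {
      if (train_rng) {
        keep <- 1 - ly$p
        mask <- matrix(stats::rbinom(length(cur), 1, keep) / keep,
                       nrow = nrow(cur))
        if (record) caches[[i]]$mask <- mask
        cur <- cur * mask
      }
      # inference / explanation: identity
    } else {
      abort(paste0("unknown layer type: ", ly$type))
    }
  }
  if (record) list(logits = cur, caches = caches) else cur
}

#' Predict conformational states
#'
#' @param object A trained (or untrained) `conformo_cnn`.
#' @param x Feature matrix (rows = frames, `input_length` columns),
#'   normalized like the training data.
#' @param type `"state"` (default; argmax class, ties broken toward the
#'   lowest class index), `"logits"`, or `"prob"` (softmax).
#' @param ... Unused.
#' @return Character vector of states, or an N x 3 matrix for
#'   `"logits"`/`"prob"` (columns in [state_levels()] order).
#' @export
predict.conformo_cnn <- function(object, x, type = c("state", "logits",
                                                     "prob"), ...) {
  type <- match.arg(type)
  logits <- nn_forward(object, x)
  colnames(logits) <- object$class_levels
  if (type == "logits") return(logits)
  if (type == "prob") {
    e <- exp(logits - apply(logits, 1, max))
    return(e / rowSums(e))
  }
  object$class_levels[apply(logits, 1, which.max)]  # which.max: lowest index wins ties
}
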