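# Layer-wise relevance propagation, implemented directly on the recorded
# activations and weights of the network. Two rules are provided:
#
#   basic rule (LRP-0):  R_j = sum_k  a_j w_jk / z_k            * R_k
#   epsilon rule      :  R_j = sum_k  a_j w_jk / (z_k + eps_k)  * R_k
#
# where z_k = sum_j a_j w_jk + b_k (the bias takes part in the denominator
# but its relevance share is absorbed, not propagated) and the stabiliser
# is sign-matched, eps_k = eps * sign(z_k) with sign(0) = +1, so it never
# flips the sign of a share. With eps = 0 and zero biases the total
# relevance of every layer equals the seeded output logit (conservation).
# Max-pooling redistributes winner-takes-all (ties split equally); ReLU and
# dropout pass relevance through unchanged.

#' LRP configuration
#'
#' @param rule `"lrp0"` (basic rule) or `"lrp_epsilon"`.
#' @param epsilon Nonnegative stabiliser; ignored (treated as 0) under
#'   `"lrp0"`. Default 1e-2.
#' @return List of class `lrp_config`.
#' @export
lrp_config <- function(rule = c("lrp_epsilon", "lrp0"), epsilon = 1e-2) {
  rule <- match.arg(rule)
  if (epsilon < 0) abort("epsilon must be nonnegative")
  if (rule == "lrp0") epsilon <- 0
  structure(list(rule = rule, epsilon = epsilon), class = "lrp_config")
}

sign0 <- function(z) ifelse(z >= 0, 1, -1)

# stabilised denominator; errors on exact zeros that carry relevance
stabilise <- function(z, r_upper, epsilon) {
  if (epsilon == 0) {
    dead <- z == 0 & r_upper != 0
    if (any(dead)) {
      abort(paste0("exact zero denominator under the basic rule (unit ",
                   which(dead)[1], "); use the epsilon rule (lrp_config(",
                   "'lrp_epsilon'))"))
    }
    ifelse(z == 0, 1, z)  # 0/0 shares: numerator is 0 too, treat as 0
  } else {
    z + epsilon * sign0(z)
  }
}

#' Record a forward pass for relevance propagation
#'
#' Runs the network once on a single frame with dropout disabled, keeping
#' every layer's input activations, the max-pool argmax positions and the
#' output logits.
#'
#' @param model A `conformo_cnn`.
#' @param x Length-`input_length` numeric vector (one normalized frame).
#' @return Object of class `activation_trace` with elements `logits`,
#'   `caches` (per-layer), `layers`.
#' @export
record_activations <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (nrow(x) != 1) abort("record_activations explains one frame at a time")
  fwd <- nn_forward(model, x, record = TRUE, train_rng = FALSE)
  structure(list(logits = drop(fwd$logits), caches = fwd$caches,
                 layers = model$layers, class_levels = model$class_levels),
            class = "activation_trace")
}

#' Seed the output-layer relevance
#'
#' The initial relevance vector at the output layer: the explained class
#' keeps its raw logit, every other class gets zero.
#'
#' @param logits Numeric vector of output logits.
#' @param class_idx 1-based index of the explained class.
#' @return Numeric vector, same length as `logits`.
#' @export
seed_output_relevance <- function(logits, class_idx) {
  if (class_idx < 1 || class_idx > length(logits)) {
    abort(paste0("class index ", class_idx, " out of range 1..",
                 length(logits)))
  }
  r <- numeric(length(logits))
  r[class_idx] <- logits[class_idx]
  r
}

#' Relevance propagation through a dense layer
#'
#' @param a Input activation vector (length J).
#' @param W J x K weight matrix.
#' @param b Length-K bias (participates in the denominator only).
#' @param r_upper Length-K relevance arriving from above.
#' @param cfg An [lrp_config()].
#' @return Length-J relevance vector.
#' @export
lrp_dense <- function(a, W, b, r_upper, cfg = lrp_config()) {
  a <- as.numeric(a)
  if (length(a) != nrow(W) || length(r_upper) != ncol(W)) {
    abort("lrp_dense: inconsistent shapes")
  }
  z <- drop(a %*% W) + b
  s <- r_upper / stabilise(z, r_upper, cfg$epsilon)
  a * drop(W %*% s)
}

#' Relevance propagation through a 1D convolution
#'
#' Identical to [lrp_dense()] applied to the unrolled convolution matrix,
#' computed without unrolling via a conv forward (denominators) and a
#' transposed-conv backward (shares).
#'
#' @param a Input activation map, L x C_in matrix.
#' @param W Kernel array `[kernel, C_in, C_out]`.
#' @param b Length-C_out bias.
#' @param r_upper L_out x C_out relevance from above.
#' @param cfg An [lrp_config()].
#' @return L x C_in relevance matrix.
#' @export
lrp_conv1d <- function(a, W, b, r_upper, cfg = lrp_config()) {
  a <- as.matrix(a)
  acube <- array(a, dim = c(nrow(a), ncol(a), 1L))
  z <- conv1d_fwd_cpp(acube, W, b)[, , 1, drop = FALSE]
  r_upper <- array(r_upper, dim = dim(z))
  s <- r_upper / array(stabilise(z, r_upper, cfg$epsilon), dim = dim(z))
  low <- conv1d_bwd_input_cpp(W, s, nrow(a))[, , 1]
  a * matrix(low, nrow = nrow(a))
}

#' Relevance redistribution through max-pooling
#'
#' Winner-takes-all: each pooled output's relevance goes to the maximal
#' input of its window; exact ties split it equally.
#'
#' @param a Input activation map, L x C matrix.
#' @param r_upper L_out x C relevance from above.
#' @param window Pool window.
#' @return L x C relevance matrix.
#' @export
lrp_maxpool <- function(a, r_upper, window) {
  a <- as.matrix(a)
  l_out <- nrow(as.matrix(r_upper))
  r_upper <- matrix(r_upper, nrow = l_out)
  out <- matrix(0, nrow(a), ncol(a))
  for (t in seq_len(l_out)) {
    rows <- ((t - 1) * window + 1):(t * window)
    blk <- a[rows, , drop = FALSE]
    winners <- sweep(blk, 2, apply(blk, 2, max), "==")
    shares <- sweep(winners, 2,
                    r_upper[t, ] / colSums(winners), "*")
    out[rows, ] <- out[rows, ] + shares
  }
  out
}

#' Relevance pass-through for ReLU
#'
#' The activations entering the rules are already the rectified outputs, so
#' the nonlinearity re-routes nothing: identity.
#'
#' @param r_upper Relevance from above.
#' @return `r_upper` unchanged.
#' @export
lrp_relu <- function(r_upper) r_upper

#' Explain one prediction down to the input features
#'
#' Seeds the explained class's logit at the output layer and composes the
#' per-layer rules back to the input. Deterministic; dropout is identity.
#'
#' @param model A trained `conformo_cnn`.
#' @param x One normalized frame (length-`input_length` vector).
#' @param class Explained class: a state name or 1-based index. Defaults to
#'   the predicted class.
#' @param cfg An [lrp_config()].
#' @return Tibble `feature_index,res_index,coord,relevance` of length 3M,
#'   with attributes `logits`, `explained_class`, and `layer_sums` (tibble
#'   `layer,type,relevance_sum` from output to input - the conservation
#'   report's raw material).
#' @export
explain <- function(model, x, class = NULL, cfg = lrp_config()) {
  trace <- record_activations(model, as.numeric(x))
  explain_trace(trace, class = class, cfg = cfg)
}

#' @rdname explain
#' @param trace An [record_activations()] trace (alternative entry point
#'   that reuses a recorded forward pass).
#' @export
explain_trace <- function(trace, class = NULL, cfg = lrp_config()) {
  stopifnot(inherits(trace, "activation_trace"))
  logits <- trace$logits
  if (is.null(class)) class <- which.max(logits)
  if (is.character(class)) {
    class <- match(class, trace$class_levels)
    if (is.na(class)) abort("unknown class name")
  }
  r <- seed_output_relevance(logits, class)
  sums <- list(tibble(layer = length(trace$layers) + 1L, type = "output",
                      relevance_sum = sum(r)))
  for (i in rev(seq_along(trace$layers))) {
    ly <- trace$layers[[i]]
    inp <- trace$caches[[i]]$input
    if (ly$type == "dense") {
      r <- lrp_dense(drop(inp), ly$W, ly$b, r, cfg)
    } else if (ly$type == "relu" || ly$type == "dropout") {
      r <- lrp_relu(r)
    } else if (ly$type == "flatten") {
      # inp is the [L, C, 1] cube that was flattened
      r <- matrix(r, nrow = dim(inp)[1])
    } else if (ly$type == "pool") {
      r <- lrp_maxpool(inp[, , 1], r, ly$window)
    } else if (ly$type == "conv") {
      r <- lrp_conv1d(inp[, , 1], ly$W, ly$b, r, cfg)
    }
    sums[[length(sums) + 1]] <- tibble(layer = i, type = ly$type,
                                       relevance_sum = sum(r))
  }
  rel <- as.numeric(r)
  triplet <- length(rel) %% 3L == 0L
  out <- tibble(
    feature_index = seq_along(rel),
    res_index = if (triplet) (seq_along(rel) - 1L) %/% 3L + 1L else
      NA_integer_,
    coord = if (triplet) c("x", "y", "z")[(seq_along(rel) - 1L) %% 3L + 1L]
      else NA_character_,
    relevance = rel
  )
  attr(out, "logits") <- logits
  attr(out, "explained_class") <- trace$class_levels[class]
  attr(out, "layer_sums") <- dplyr::bind_rows(rev(sums))
  out
}

#' Per-layer conservation report
#'
#' Summarises how much relevance each propagation step absorbed. With
#' `epsilon = 0` and a bias-free network every layer's total equals the
#' seeded logit; biases and the epsilon stabiliser absorb relevance, which
#' this report quantifies.
#'
#' @param relevance An [explain()] result.
#' @return Tibble `layer,type,relevance_sum,deficit` where `deficit` is
#'   `seeded logit - relevance_sum`.
#' @export
conservation_report <- function(relevance) {
  sums <- attr(relevance, "layer_sums")
  if (is.null(sums)) abort("not an explain() result (no layer_sums)")
  seedv <- sums$relevance_sum[sums$type == "output"][1]
  mutate(sums, deficit = seedv - .data$relevance_sum)
}
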