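# Training: mini-batch Adam on the cross-entropy loss, with L2 weight decay
# folded into the gradient and inverted dropout. All randomness (shuffling,
# dropout masks) is derived from the config seed; the global RNG is left
# untouched.

#' Training configuration
#'
#' Defaults follow the reference protocol: 500 epochs, batch size 1024,
#' Adam with learning rate 1e-4 and weight decay 1e-5, cross-entropy loss.
#'
#' @param epochs Number of passes over the training set (>= 0; 0 returns
#'   the model unchanged).
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param weight_decay L2 penalty coefficient added to the gradient.
#' @param beta1,beta2,adam_eps Adam moment decay rates and stabiliser.
#' @param seed Master seed; per-epoch shuffles and per-batch dropout masks
#'   are derived from it.
#' @return List of class `train_config`.
#' @export
train_config <- function(epochs = 500L, batch_size = 1024L,
                         learning_rate = 1e-4, weight_decay = 1e-5,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                         seed = 1L) {
  stopifnot(epochs >= 0, batch_size >= 1, learning_rate > 0,
            weight_decay >= 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 seed = as.integer(seed)),
            class = "train_config")
}

# deterministic sub-seed derivation, kept inside 32-bit range
derive_seed <- function(master, ...) {
  parts <- c(master, ...)
  s <- 0
  for (p in parts) s <- (s * 7919 + (p %% 104729) + 1) %% 2147483629
  as.integer(s)
}

labels_to_index <- function(y, class_levels) {
  y <- as.character(y)
  bad <- setdiff(unique(y), class_levels)
  if (length(bad) > 0) abort(paste0("unknown class label: ", bad[1]))
  match(y, class_levels)
}

softmax_rows <- function(logits) {
  e <- exp(logits - apply(logits, 1, max))
  e / rowSums(e)
}

cross_entropy <- function(logits, y_idx) {
  p <- softmax_rows(logits)
  -mean(log(pmax(p[cbind(seq_along(y_idx), y_idx)], 1e-300)))
}

nn_backward <- function(model, caches, dlogits) {
  grads <- vector("list", length(model$layers))
  dcur <- dlogits
  for (i in rev(seq_along(model$layers))) {
    ly <- model$layers[[i]]
    inp <- caches[[i]]$input
    if (ly$type == "dense") {
      grads[[i]] <- list(dW = crossprod(inp, dcur), db = colSums(dcur))
      dcur <- tcrossprod(dcur, ly$W)
    } else if (ly$type == "dropout") {
      if (!is.null(caches[[i]]$mask)) dcur <- dcur * caches[[i]]$mask
    } else if (ly$type == "relu") {
      dcur <- dcur * (inp > 0)
    } else if (ly$type == "flatten") {
      d <- dim(inp)
      dcur <- array(t(dcur), dim = d)
    } else if (ly$type == "pool") {
      dcur <- maxpool1d_bwd_cpp(caches[[i]]$argmax, dcur, dim(inp)[1])
    } else if (ly$type == "conv") {
      g <- conv1d_bwd_cpp(inp, ly$W, dcur)
      grads[[i]] <- list(dW = g$dW, db = g$db)
      dcur <- g$dX
    }
  }
  grads
}

#' Train the CNN classifier
#'
#' Mini-batch Adam on softmax cross-entropy. Per-epoch training loss and
#' accuracy are recorded in the model's `history`. Dropout is active only
#' here; prediction and relevance propagation see the deterministic
#' network. Given the same data, config and platform BLAS, training is
#' reproducible seed-for-seed.
#'
#' @param model A [build_network()] result.
#' @param x Normalized feature matrix (rows = frames).
#' @param y Frame states (character/factor in [state_levels()]).
#' @param config A [train_config()].
#' @return The trained `conformo_cnn` (history filled, `trained = TRUE`).
#' @export
train_cnn <- function(model, x, y, config = train_config()) {
  stopifnot(inherits(model, "conformo_cnn"), inherits(config, "train_config"))
  x <- as.matrix(x)
  y_idx <- labels_to_index(y, model$class_levels)
  if (nrow(x) != length(y_idx)) abort("x and y sizes differ")
  if (config$epochs == 0L) return(model)
  n <- nrow(x)
  n_class <- length(model$class_levels)

  adam <- lapply(model$layers, function(ly) {
    if (ly$type %in% c("conv", "dense")) {
      list(mW = array(0, dim(ly$W)), vW = array(0, dim(ly$W)),
           mb = numeric(length(ly$b)), vb = numeric(length(ly$b)))
    }
  })
  step <- 0L
  history <- vector("list", config$epochs)

  for (epoch in seq_len(config$epochs)) {
    perm <- withr::with_seed(derive_seed(config$seed, epoch, 1L), sample(n))
    batch_starts <- seq(1L, n, by = config$batch_size)
    ep_loss <- 0
    ep_correct <- 0L
    for (bi in seq_along(batch_starts)) {
      ix <- perm[batch_starts[bi]:min(batch_starts[bi] + config$batch_size - 1L, n)]
      xb <- x[ix, , drop = FALSE]
      yb <- y_idx[ix]
      fwd <- withr::with_seed(
        derive_seed(config$seed, epoch, bi, 2L),
        nn_forward(model, xb, record = TRUE, train_rng = TRUE))
      loss <- cross_entropy(fwd$logits, yb)
      if (!is.finite(loss)) {
        abort(paste0("training aborted: non-finite loss at epoch ", epoch,
                     ", batch ", bi,
                     " (consider a lower learning rate or checking inputs)"))
      }
      ep_loss <- ep_loss + loss * length(ix)
      ep_correct <- ep_correct +
        sum(max.col(fwd$logits, ties.method = "first") == yb)
      p <- softmax_rows(fwd$logits)
      onehot <- matrix(0, nrow(p), n_class)
      onehot[cbind(seq_along(yb), yb)] <- 1
      grads <- nn_backward(model, fwd$caches, (p - onehot) / length(ix))
      step <- step + 1L
      bc1 <- 1 - config$beta1^step
      bc2 <- 1 - config$beta2^step
      for (li in seq_along(model$layers)) {
        if (is.null(grads[[li]])) next
        ly <- model$layers[[li]]
        st <- adam[[li]]
        gW <- grads[[li]]$dW + config$weight_decay * ly$W
        gb <- grads[[li]]$db + config$weight_decay * ly$b
        st$mW <- config$beta1 * st$mW + (1 - config$beta1) * gW
        st$vW <- config$beta2 * st$vW + (1 - config$beta2) * gW^2
        st$mb <- config$beta1 * st$mb + (1 - config$beta1) * gb
        st$vb <- config$beta2 * st$vb + (1 - config$beta2) * gb^2
        ly$W <- ly$W - config$learning_rate * (st$mW / bc1) /
          (sqrt(st$vW / bc2) + config$adam_eps)
        ly$b <- ly$b - config$learning_rate * (st$mb / bc1) /
          (sqrt(st$vb / bc2) + config$adam_eps)
        model$layers[[li]] <- ly
        adam[[li]] <- st
      }
    }
    history[[epoch]] <- tibble(epoch = epoch, loss = ep_loss / n,
                               accuracy = ep_correct / n)
  }
  model$history <- dplyr::bind_rows(history)
  model$trained <- TRUE
  model$train_config <- config
  model
}
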