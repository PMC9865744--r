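# broom-style tidiers for the fitted network and the evaluation report.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted (or built) network
#'
#' One row per layer with its type, output shape and trainable parameter
#' count - the architecture summary table.
#'
#' @param x A `conformo_cnn`.
#' @param ... Unused.
#' @return Tibble `layer,type,out_channels,out_length,n_parameters`.
#' @export
tidy.conformo_cnn <- function(x, ...) spec_layout(x$spec)

#' One-row summary of a fitted network
#'
#' @param x A `conformo_cnn`.
#' @param ... Unused.
#' @return Tibble with `n_layers`, `n_parameters`, `trained`, `epochs`,
#'   `final_loss`, `final_accuracy` (training-set values; `NA` when
#'   untrained).
#' @export
glance.conformo_cnn <- function(x, ...) {
  layout <- spec_layout(x$spec)
  h <- x$history
  tibble(n_layers = nrow(layout),
         n_parameters = sum(layout$n_parameters),
         trained = x$trained,
         epochs = if (nrow(h) > 0) max(h$epoch) else 0L,
         final_loss = if (nrow(h) > 0) h$loss[nrow(h)] else NA_real_,
         final_accuracy = if (nrow(h) > 0) h$accuracy[nrow(h)] else NA_real_)
}

#' Tidy an evaluation report
#'
#' @param x A `conformo_eval`.
#' @param ... Unused.
#' @return The per-class metrics tibble
#'   (`class,precision,recall,f1,support`).
#' @export
tidy.conformo_eval <- function(x, ...) x$metrics

#' One-row summary of an evaluation report
#'
#' @param x A `conformo_eval`.
#' @param ... Unused.
#' @return Tibble `accuracy,macro_f1,n`.
#' @export
glance.conformo_eval <- function(x, ...) {
  tibble(accuracy = x$accuracy, macro_f1 = x$macro_f1,
         n = sum(x$confusion))
}
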