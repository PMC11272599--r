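#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-class metrics of an evaluation report
#'
#' @param x A `shock_eval`.
#' @param ... Unused.
#' @return Tibble with one row per class: precision, recall, specificity,
#'   F1, AUC and support.
#' @export
tidy.shock_eval <- function(x, ...) {
  out <- x$metrics
  out$auc <- as.numeric(x$auc[out$class])
  out
}

#' One-row summary of an evaluation report
#'
#' @param x A `shock_eval`.
#' @param ... Unused.
#' @return One-row tibble of accuracy and macro-averaged metrics.
#' @export
glance.shock_eval <- function(x, ...) {
  x$macro
}

#' Tidy the training history of a fit
#'
#' @param x A `shock_fit`.
#' @param ... Unused.
#' @return The per-epoch history in long-friendly wide form (`epoch`,
#'   `train_loss`, `train_accuracy`, `val_loss`, `val_accuracy`).
#' @export
tidy.shock_fit <- function(x, ...) {
  x$history
}

#' One-row summary of a fit
#'
#' @param x A `shock_fit`.
#' @param ... Unused.
#' @return One-row tibble: epochs run, best epoch, final/best accuracies
#'   and the trainable parameter count.
#' @export
glance.shock_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    epochs = nrow(h),
    best_epoch = x$best_epoch,
    train_accuracy = h$train_accuracy[nrow(h)],
    val_accuracy = h$val_accuracy[nrow(h)],
    best_val_accuracy = if (nrow(h) > 0) max(h$val_accuracy) else NA_real_,
    n_parameters = count_parameters(x$model$config)
  )
}

#' Tidy a model's layer table
#'
#' @param x A `shock_model`.
#' @param ... Unused.
#' @return The layer shape table of [model_shapes()].
#' @export
tidy.shock_model <- function(x, ...) {
  model_shapes(x$config)
}

#' One-row summary of a model
#'
#' @param x A `shock_model`.
#' @param ... Unused.
#' @return One-row tibble with variant, input size and parameter count.
#' @export
glance.shock_model <- function(x, ...) {
  tibble::tibble(
    variant = x$config$variant,
    input_size = x$config$input_size,
    n_classes = x$config$n_classes,
    n_parameters = count_parameters(x$config)
  )
}

#' Tidy cross-validation results
#'
#' @param x A `shock_cv`.
#' @param ... Unused.
#' @return The per-fold accuracy/loss tibble.
#' @export
tidy.shock_cv <- function(x, ...) {
  x$folds
}

#' One-row summary of cross-validation results
#'
#' @param x A `shock_cv`.
#' @param ... Unused.
#' @return One-row tibble of mean accuracy and loss.
#' @export
glance.shock_cv <- function(x, ...) {
  x$mean
}
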