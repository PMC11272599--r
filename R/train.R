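#' Train/validation/test split specification
#'
#' @param ratios Length-3 positive ratios (train, val, test) summing to 1.
#' @param stratified Split within each class.
#' @param seed Integer seed for the permutation.
#' @return A list of class `split_spec`.
#' @export
split_spec <- function(ratios = c(0.8, 0.1, 0.1), stratified = TRUE,
                       seed = 1L) {
  stopifnot(length(ratios) == 3, all(ratios >= 0),
            abs(sum(ratios) - 1) < 1e-9)
  structure(list(ratios = ratios, stratified = stratified,
                 seed = as.integer(seed)),
            class = "split_spec")
}

# Partition n indices: val and test get round(n * ratio), remainder train.
split_sizes <- function(n, ratios) {
  nval <- round(n * ratios[2])
  ntest <- round(n * ratios[3])
  c(train = n - nval - ntest, val = nval, test = ntest)
}

#' Split a dataset into train/validation/test partitions
#'
#' Validation and test sizes are `round(n * ratio)` (per class when
#' stratified) with the remainder going to train, so an 80/10/10 split of
#' 4,000 balanced fragments yields 3,200/400/400 with 800/100/100 per
#' class. Deterministic under the supplied seed; the three partitions are
#' disjoint and cover the input.
#'
#' @param data A tibble with a `label` column (fragments or scalograms).
#' @param spec A [split_spec()].
#' @return A list with tibbles `train`, `val`, `test`.
#' @export
split_dataset <- function(data, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"), "label" %in% names(data))
  assign_one <- function(idx) {
    sz <- split_sizes(length(idx), spec$ratios)
    perm <- sample(idx)
    list(train = perm[seq_len(sz[1])],
         val = perm[sz[1] + seq_len(sz[2])],
         test = perm[sz[1] + sz[2] + seq_len(sz[3])])
  }
  parts <- withr::with_seed(spec$seed, {
    if (spec$stratified) {
      by_class <- split(seq_len(nrow(data)), data$label)
      ps <- purrr::map(by_class, assign_one)
      list(train = sort(unlist(purrr::map(ps, "train"), use.names = FALSE)),
           val = sort(unlist(purrr::map(ps, "val"), use.names = FALSE)),
           test = sort(unlist(purrr::map(ps, "test"), use.names = FALSE)))
    } else {
      assign_one(seq_len(nrow(data)))
    }
  })
  purrr::map(parts, function(i) data[i, ])
}

#' Training configuration
#'
#' Defaults follow the reference training recipe: Adam with learning rate
#' 0.001 and legacy per-update decay 1e-6 (the effective rate is
#' `lr / (1 + decay * step)`), batch size 16, categorical cross-entropy,
#' 400 epochs.
#'
#' @param learning_rate Adam base learning rate.
#' @param decay Legacy per-update learning-rate decay.
#' @param batch_size Mini-batch size.
#' @param epochs Number of passes over the training set.
#' @param seed Integer seed for shuffling and dropout.
#' @param select Which weights a fit keeps for prediction: the best
#'   validation-accuracy checkpoint (default) or the last epoch.
#' @param precision Engine arithmetic; single precision is the training
#'   default, double is available for verification work.
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, decay = 1e-6,
                         batch_size = 16, epochs = 400, seed = 1L,
                         select = c("best", "last"),
                         precision = c("single", "double")) {
  stopifnot(learning_rate >= 0, decay >= 0, batch_size >= 1, epochs >= 1)
  structure(
    list(learning_rate = learning_rate, decay = decay,
         batch_size = as.integer(batch_size), epochs = as.integer(epochs),
         seed = as.integer(seed), select = match.arg(select),
         precision = match.arg(precision)),
    class = "train_config"
  )
}

#' Train the scalogram classifier
#'
#' Runs mini-batch Adam with seeded shuffling for `cfg$epochs` epochs,
#' recording per-epoch training and validation loss/accuracy and retaining
#' the parameters of the best validation-accuracy epoch. Images are scaled
#' to `[0, 1]` (pixel / 255) before entering the network.
#'
#' @param model A `shock_model` from [build_model()].
#' @param train,val Scalogram tibbles with `image` and `label` columns
#'   (`val` may have zero rows).
#' @param cfg A [train_config()].
#' @return An object of class `shock_fit`: the trained `model` (final
#'   weights), `best_params`, `best_epoch`, the per-epoch `history` tibble
#'   and the configs used.
#' @export
train_model <- function(model, train, val, cfg = train_config()) {
  stopifnot(inherits(model, "shock_model"), inherits(cfg, "train_config"),
            nrow(train) > 0)
  classes <- model$config$classes
  xtr <- prepare_images(train)
  ytr <- label_index(train$label, classes)
  if (nrow(val) > 0) {
    xval <- prepare_images(val)
    yval <- label_index(val$label, classes)
  } else {
    xval <- array(0, dim = c(dim(xtr)[1:3], 0))
    yval <- integer(0)
  }
  res <- cpp_train(model$params, unclass(model$config), xtr, ytr, xval, yval,
                   unclass(cfg),
                   ifelse(cfg$precision == "double", "double", "float"))
  res$params <- align_params(res$params, model$params)
  res$best_params <- align_params(res$best_params, model$params)
  history <- tibble::tibble(
    epoch = seq_len(nrow(res$history)),
    train_loss = res$history[, 1], train_accuracy = res$history[, 2],
    val_loss = res$history[, 3], val_accuracy = res$history[, 4]
  )
  trained <- model
  trained$params <- res$params
  structure(
    list(model = trained,
         best_params = if (cfg$select == "best") res$best_params
                       else res$params,
         best_epoch = if (cfg$select == "best") res$best_epoch
                      else cfg$epochs,
         history = history, train_config = cfg),
    class = "shock_fit"
  )
}

#' @export
print.shock_fit <- function(x, ...) {
  h <- x$history
  cat("<shock_fit>", nrow(h), "epochs; best epoch", x$best_epoch, "\n")
  cat(sprintf("  final train acc %.3f / val acc %.3f\n",
              h$train_accuracy[nrow(h)], h$val_accuracy[nrow(h)]))
  invisible(x)
}

# ---- metric suite ----------------------------------------------------------

#' Classification report from truth and class scores
#'
#' Builds the full evaluation report used throughout the package: the
#' confusion matrix (rows = true class, columns = predicted), per-class
#' precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, specificity `TN/(TN+FP)`
#' and F1 `2PR/(P+R)` (0 when `P + R = 0`), their unweighted macro
#' averages, overall accuracy, and one-vs-rest ROC curves with
#' trapezoidal AUC (equal scores are treated as a single threshold step).
#'
#' @param truth Character/factor vector of true labels.
#' @param probs Numeric `N x K` matrix of class scores with class column
#'   names (rows need not be normalised); predictions are the columnwise
#'   argmax.
#' @param classes Class labels in report order (defaults to the score
#'   columns).
#' @return An object of class `shock_eval`: list with `confusion`,
#'   `metrics` (per-class tibble), `macro` (one-row tibble with macro
#'   averages and accuracy), `roc` (tibble of ROC points per class) and
#'   `auc` (named vector).
#' @export
eval_report <- function(truth, probs, classes = colnames(probs)) {
  stopifnot(nrow(probs) == length(truth), !is.null(classes))
  pred <- classes[max.col(probs, ties.method = "first")]
  truth <- as.character(truth)
  confusion <- table(factor(truth, levels = classes),
                     factor(pred, levels = classes))
  confusion <- matrix(as.integer(confusion), nrow = length(classes),
                      dimnames = list(true = classes, predicted = classes))
  n <- sum(confusion)
  per <- purrr::map(seq_along(classes), function(k) {
    tp <- confusion[k, k]
    fn <- sum(confusion[k, ]) - tp
    fp <- sum(confusion[, k]) - tp
    tn <- n - tp - fn - fp
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    specificity <- if (tn + fp > 0) tn / (tn + fp) else 0
    f1 <- if (precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else {
      0
    }
    tibble::tibble(class = classes[k], precision = precision,
                   recall = recall, specificity = specificity, f1 = f1,
                   support = tp + fn)
  })
  metrics <- dplyr::bind_rows(per)
  roc <- purrr::map(seq_along(classes), function(k) {
    r <- roc_points(truth == classes[k], probs[, k])
    r$class <- classes[k]
    r
  })
  roc_tbl <- dplyr::bind_rows(roc)
  auc <- purrr::map_dbl(split(roc_tbl, roc_tbl$class)[classes], function(r) {
    sum(diff(r$fpr) * (utils::head(r$tpr, -1) + utils::tail(r$tpr, -1)) / 2)
  })
  macro <- tibble::tibble(
    accuracy = sum(diag(confusion)) / n,
    precision = mean(metrics$precision), recall = mean(metrics$recall),
    specificity = mean(metrics$specificity), f1 = mean(metrics$f1),
    macro_auc = mean(auc)
  )
  structure(list(confusion = confusion, metrics = metrics, macro = macro,
                 roc = roc_tbl, auc = auc),
            class = "shock_eval")
}

# One-vs-rest ROC: thresholds at each distinct score (ties = one step),
# points ordered from (0,0) to (1,1).
roc_points <- function(is_pos, score) {
  np <- sum(is_pos)
  nn <- sum(!is_pos)
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]
  y <- is_pos[ord]
  keep <- c(diff(s) != 0, TRUE) # last index of each tied block
  tp <- cumsum(y)[keep]
  fp <- cumsum(!y)[keep]
  tibble::tibble(
    fpr = c(0, if (nn > 0) fp / nn else fp * 0),
    tpr = c(0, if (np > 0) tp / np else tp * 0)
  )
}

#' Evaluate a fitted classifier on a test set
#'
#' @param fit A `shock_fit` (or `shock_model`).
#' @param test Scalogram tibble with `image` and `label` columns.
#' @param ... Passed to [predict_proba()].
#' @return A `shock_eval` report.
#' @export
evaluate_model <- function(fit, test, ...) {
  stopifnot(nrow(test) > 0)
  probs <- predict_proba(fit, test, ...)
  eval_report(test$label, probs)
}

#' @export
print.shock_eval <- function(x, ...) {
  cat("<shock_eval> accuracy", sprintf("%.4f", x$macro$accuracy), "\n")
  print(x$confusion)
  print(as.data.frame(x$metrics), digits = 3)
  invisible(x)
}

# ---- cross-validation ------------------------------------------------------

#' Stratified k-fold cross-validation
#'
#' Splits the data into `k` stratified folds; each fold serves once as the
#' test set while the remaining folds train a fresh model. Reports
#' per-fold test accuracy and loss plus their means.
#'
#' @param data Scalogram tibble with `image` and `label`.
#' @param k Number of folds.
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param seed Seed for fold assignment and per-fold model init.
#' @return A list of class `shock_cv`: `folds` tibble
#'   (`fold`, `accuracy`, `loss`) and `mean` one-row tibble.
#' @export
cross_validate <- function(data, k = 5, model_cfg = model_config(),
                           train_cfg = train_config(), seed = 1L) {
  stopifnot(k >= 2, "label" %in% names(data))
  counts <- table(data$label)
  if (any(counts < k)) {
    stop("class ", names(counts)[which.min(counts)], " has fewer than k = ",
         k, " members", call. = FALSE)
  }
  fold_of <- integer(nrow(data))
  withr::with_seed(as.integer(seed), {
    for (cls in names(counts)) {
      idx <- sample(which(data$label == cls))
      fold_of[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  rows <- purrr::map(seq_len(k), function(f) {
    tr <- data[fold_of != f, ]
    te <- data[fold_of == f, ]
    model <- build_model(model_cfg, seed = seed + f)
    fit <- train_model(model, tr, te, train_cfg)
    probs <- predict_proba(fit, te)
    pred <- model_cfg$classes[max.col(probs, ties.method = "first")]
    yi <- label_index(te$label, model_cfg$classes)
    loss <- -mean(log(pmax(probs[cbind(seq_len(nrow(te)), yi + 1)], 1e-12)))
    tibble::tibble(fold = f, accuracy = mean(pred == te$label), loss = loss)
  })
  folds <- dplyr::bind_rows(rows)
  structure(
    list(folds = folds,
         mean = tibble::tibble(accuracy = mean(folds$accuracy),
                               loss = mean(folds$loss)),
         fold_of = fold_of),
    class = "shock_cv"
  )
}

#' @export
print.shock_cv <- function(x, ...) {
  print(as.data.frame(x$folds), digits = 4)
  cat(sprintf("mean accuracy %.4f, mean loss %.4f\n",
              x$mean$accuracy, x$mean$loss))
  invisible(x)
}

# ---- hyperparameter sweep --------------------------------------------------

#' Grid sweep over training hyperparameters
#'
#' Trains one seeded model per grid cell and records the resulting
#' validation accuracy. Rows are sorted by decreasing accuracy, ties
#' broken toward the smaller batch size; the best row is flagged.
#'
#' @param train,val Scalogram tibbles.
#' @param grid Data frame with columns among `learning_rate`, `decay`,
#'   `batch_size` (one row per configuration).
#' @param model_cfg A [model_config()].
#' @param base_cfg A [train_config()] supplying the remaining settings.
#' @param seed Seed reused for every cell (so cells differ only in their
#'   hyperparameters).
#' @return A tibble: the grid columns plus `accuracy` and `best`.
#' @export
sweep_hyperparameters <- function(train, val, grid,
                                  model_cfg = model_config(),
                                  base_cfg = train_config(), seed = 1L) {
  stopifnot(nrow(grid) >= 1)
  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    cfg <- base_cfg
    for (nm in intersect(names(grid), c("learning_rate", "decay",
                                        "batch_size"))) {
      cfg[[nm]] <- grid[[nm]][i]
    }
    cfg$batch_size <- as.integer(cfg$batch_size)
    cfg$seed <- as.integer(seed)
    model <- build_model(model_cfg, seed = seed)
    fit <- train_model(model, train, val, cfg)
    probs <- predict_proba(fit, val)
    pred <- model_cfg$classes[max.col(probs, ties.method = "first")]
    out <- tibble::as_tibble(grid[i, , drop = FALSE])
    out$accuracy <- mean(pred == val$label)
    out
  })
  res <- dplyr::bind_rows(rows)
  ord <- order(-res$accuracy,
               if ("batch_size" %in% names(res)) res$batch_size
               else seq_len(nrow(res)))
  res <- res[ord, ]
  res$best <- seq_len(nrow(res)) == 1L
  res
}
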