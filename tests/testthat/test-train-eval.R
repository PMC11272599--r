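make_labeled <- function(counts, seed = 1) {
  tibble::tibble(
    id = as.character(seq_len(sum(counts))),
    label = rep(names(counts), times = counts)
  )
}

test_that("stratified 80/10/10 splits give the expected partition sizes", {
  # 4,000 balanced -> 3,200 / 400 / 400 with 800/100/100 per class
  d <- make_labeled(c(C1 = 1000, C2 = 1000, C3 = 1000, C4 = 1000))
  p <- split_dataset(d, split_spec(seed = 3))
  expect_equal(sapply(p, nrow), c(train = 3200, val = 400, test = 400))
  for (nm in names(p)) {
    tab <- table(p[[nm]]$label)
    expect_true(all(tab == tab[1]))
  }
  expect_equal(as.vector(table(p$train$label)), rep(800L, 4))

  # the imbalanced reference composition: 578 -> 462 / 58 / 58
  d2 <- make_labeled(c(C1 = 97, C2 = 240, C3 = 72, C4 = 169))
  p2 <- split_dataset(d2, split_spec(seed = 1))
  expect_equal(sapply(p2, nrow), c(train = 462, val = 58, test = 58))

  # partitions are disjoint and cover the data
  ids <- c(p2$train$id, p2$val$id, p2$test$id)
  expect_equal(sort(as.integer(ids)), seq_len(578))

  # degenerate ratios and determinism
  p3 <- split_dataset(d2, split_spec(c(1, 0, 0)))
  expect_equal(nrow(p3$train), 578)
  a <- split_dataset(d2, split_spec(seed = 9))
  b <- split_dataset(d2, split_spec(seed = 9))
  expect_identical(a$test$id, b$test$id)
  expect_error(split_spec(c(0.5, 0.2, 0.2)), "sum")
})

test_that("oversample-then-split bookkeeping holds for any seed", {
  for (seed in c(2, 77)) {
    frags <- generate_dataset(c(C1 = 97, C2 = 240, C3 = 72, C4 = 169),
                              synth_config(seed = seed, duration = 0.2))
    bal <- smote_resample(frags, 1000, seed = seed)
    expect_equal(nrow(bal), 4000)
    p <- split_dataset(bal, split_spec(seed = seed))
    expect_equal(sapply(p, nrow), c(train = 3200, val = 400, test = 400))
  }
})

test_that("a zero learning rate leaves the weights unchanged", {
  sc <- make_tiny_scalograms(4)
  m <- build_model(model_config(input_size = 32), seed = 5)
  fit <- train_model(m, sc, sc[1:4, ],
                     train_config(learning_rate = 0, epochs = 1, seed = 1,
                                  precision = "double"))
  expect_equal(fit$model$params, m$params, tolerance = 1e-12)
  expect_equal(nrow(fit$history), 1)
  # untrained and "trained" models give identical predictions
  expect_equal(predict_proba(m, sc), predict_proba(fit, sc),
               tolerance = 1e-6)
})

test_that("training history has one row per epoch and a best checkpoint", {
  sc <- make_tiny_scalograms(6)
  p <- split_dataset(sc, split_spec(c(0.7, 0.15, 0.15), seed = 2))
  m <- build_model(model_config(input_size = 32), seed = 5)
  fit <- train_model(m, p$train, p$val, train_config(epochs = 3, seed = 4))
  expect_equal(nrow(fit$history), 3)
  expect_named(fit$history, c("epoch", "train_loss", "train_accuracy",
                              "val_loss", "val_accuracy"))
  expect_gte(fit$best_epoch, 1)
  expect_lte(fit$best_epoch, 3)
  expect_equal(max(fit$history$val_accuracy),
               fit$history$val_accuracy[fit$best_epoch])
  # label outside the class set is rejected
  bad <- p$train
  bad$label[1] <- "X9"
  expect_error(train_model(m, bad, p$val, train_config(epochs = 1)),
               "outside the model's class set")
})

test_that("training learns on a small synthetic four-class task", {
  sc <- make_tiny_scalograms(25, seed = 202)
  p <- split_dataset(sc, split_spec(seed = 3))
  m <- build_model(model_config(input_size = 32), seed = 6)
  fit <- train_model(m, p$train, p$val,
                     train_config(epochs = 8, seed = 7))
  h <- fit$history
  expect_gt(h$train_accuracy[8], h$train_accuracy[1])
  expect_lt(h$train_loss[8], h$train_loss[1])
})

test_that("the metric suite is exact on hand-computed cases", {
  # perfect predictor on 8 samples, 2 per class
  truth <- rep(shock_classes, each = 2)
  probs <- matrix(0.01, 8, 4, dimnames = list(NULL, shock_classes))
  probs[cbind(1:8, rep(1:4, each = 2))] <- 0.97
  r <- eval_report(truth, probs)
  expect_equal(unname(diag(r$confusion)), rep(2L, 4))
  expect_equal(sum(r$confusion) - sum(diag(r$confusion)), 0)
  expect_equal(r$macro$accuracy, 1)
  expect_true(all(r$metrics$precision == 1))
  expect_true(all(r$metrics$f1 == 1))
  expect_true(all(r$auc == 1))

  # binary toy confusion [[93, 7], [0, 100]]
  truth2 <- c(rep("A", 100), rep("B", 100))
  pred2 <- c(rep("A", 93), rep("B", 7), rep("B", 100))
  p2 <- matrix(0, 200, 2, dimnames = list(NULL, c("A", "B")))
  p2[cbind(1:200, ifelse(pred2 == "A", 1, 2))] <- 1
  r2 <- eval_report(truth2, p2)
  expect_equal(r2$confusion["A", ], c(A = 93L, B = 7L))
  expect_equal(r2$metrics$precision[1], 1.0)
  expect_equal(r2$metrics$recall[1], 0.93)
  expect_equal(r2$metrics$specificity[1], 1.0)
  expect_equal(r2$metrics$precision[2], 100 / 107)
  expect_equal(r2$macro$accuracy, 193 / 200)

  # constant single-class predictor on a balanced set
  truth3 <- rep(shock_classes, each = 5)
  p3 <- matrix(0, 20, 4, dimnames = list(NULL, shock_classes))
  p3[, 2] <- 1
  r3 <- eval_report(truth3, p3)
  expect_equal(r3$metrics$recall, c(0, 1, 0, 0))
  expect_equal(r3$macro$accuracy, 0.25)
  expect_equal(r3$metrics$f1[1], 0) # degenerate P + R = 0 case
})

test_that("metrics match brute-force one-vs-rest tallies on random data", {
  withr::local_seed(33)
  for (rep in 1:8) {
    n <- 120
    truth <- sample(shock_classes, n, replace = TRUE)
    probs <- matrix(stats::runif(n * 4), n, 4,
                    dimnames = list(NULL, shock_classes))
    r <- eval_report(truth, probs)
    pred <- shock_classes[max.col(probs, ties.method = "first")]
    bf <- brute_metrics(truth, pred, shock_classes)
    expect_equal(r$metrics$precision, bf$precision)
    expect_equal(r$metrics$recall, bf$recall)
    expect_equal(r$metrics$specificity, bf$specificity)
    expect_equal(r$macro$accuracy, mean(truth == pred))
    expect_equal(unname(rowSums(r$confusion)),
                 as.vector(table(factor(truth, shock_classes))))
  }
})

test_that("AUC behaves at its reference points and matches pROC", {
  # all-tied scores: a single threshold step, AUC 1/2
  truth <- c(rep("A", 6), rep("B", 6))
  p <- matrix(0.5, 12, 2, dimnames = list(NULL, c("A", "B")))
  r <- eval_report(truth, p)
  expect_equal(unname(r$auc["A"]), 0.5)

  # perfectly separating score
  p2 <- cbind(A = c(seq(0.9, 0.99, length.out = 6),
                    seq(0.1, 0.2, length.out = 6)))
  p2 <- cbind(p2, B = 1 - p2[, 1])
  r2 <- eval_report(truth, p2)
  expect_equal(unname(r2$auc["A"]), 1)

  withr::local_seed(9)
  score <- stats::runif(40)
  truth3 <- sample(c("A", "B"), 40, replace = TRUE)
  p3 <- cbind(A = score, B = 1 - score)
  r3 <- eval_report(truth3, p3)
  ref <- suppressMessages(pROC::auc(pROC::roc(truth3 == "A", score,
                                              direction = "<")))
  expect_equal(unname(r3$auc["A"]), as.numeric(ref), tolerance = 1e-12)
})

test_that("five-fold cross-validation partitions and averages correctly", {
  sc <- make_tiny_scalograms(10)
  cv <- cross_validate(sc, k = 5,
                       model_cfg = model_config(input_size = 32),
                       train_cfg = train_config(epochs = 1, seed = 2),
                       seed = 3)
  expect_equal(nrow(cv$folds), 5)
  expect_equal(as.vector(table(cv$fold_of)), rep(8L, 5))
  expect_equal(cv$mean$accuracy, mean(cv$folds$accuracy), tolerance = 1e-12)
  expect_equal(cv$mean$loss, mean(cv$folds$loss), tolerance = 1e-12)
  expect_error(cross_validate(sc[c(1:2, 11:12, 21:22, 31:32), ], k = 5),
               "fewer than k")
})

test_that("hyperparameter sweeps are sorted and flag the best row", {
  sc <- make_tiny_scalograms(6)
  p <- split_dataset(sc, split_spec(c(0.6, 0.2, 0.2), seed = 1))
  single <- sweep_hyperparameters(
    p$train, p$val, data.frame(learning_rate = 0.001, batch_size = 16),
    model_cfg = model_config(input_size = 32),
    base_cfg = train_config(epochs = 1), seed = 2
  )
  expect_equal(nrow(single), 1)
  expect_true(single$best)

  # zero learning rate makes every cell identical: ties break toward the
  # smaller batch
  grid <- data.frame(learning_rate = 0, batch_size = c(64, 8, 16))
  sw <- sweep_hyperparameters(p$train, p$val, grid,
                              model_cfg = model_config(input_size = 32),
                              base_cfg = train_config(epochs = 1), seed = 2)
  expect_equal(sw$batch_size, c(8, 16, 64))
  expect_true(all(diff(sw$accuracy) <= 0))
  expect_equal(which(sw$best), 1L)
})
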