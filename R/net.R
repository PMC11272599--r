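#' Architecture configuration for the hybrid 2DCNN-GRU classifier
#'
#' The full variant is: input `(H, H, 3)` -> five blocks of 3x3
#' same-padding convolution (ReLU) + 2x2 max pooling, with dropout after
#' pools 3-5 -> global average pooling -> reshape of the resulting
#' feature vector into a sequence of scalar steps -> GRU -> dense ReLU ->
#' dense softmax. `cnn_only` drops the GRU (GAP feeds the dense head);
#' `gru_only` drops the convolutions and feeds the image rows (one step per
#' row, `width * 3` features) straight into the GRU.
#'
#' The per-layer widths default to a configuration that respects every
#' structural constraint of the architecture while keeping the trainable
#' parameter total under 208,000.
#'
#' @param input_size Input image side in pixels; must be at least 32 so
#'   five poolings survive.
#' @param conv_filters Integer vector of 5 filter counts.
#' @param gru_units GRU hidden size.
#' @param dense_units Width of the penultimate dense layer.
#' @param dropout Three dropout rates applied after pools 3, 4 and 5.
#' @param classes Class labels, in output order.
#' @param variant `"full"`, `"cnn_only"` or `"gru_only"`.
#' @return A list of class `model_config`.
#' @export
model_config <- function(input_size = 227,
                         conv_filters = c(16, 32, 64, 64, 128),
                         gru_units = 128,
                         dense_units = 128,
                         dropout = c(0.25, 0.25, 0.5),
                         classes = shock_classes,
                         variant = c("full", "cnn_only", "gru_only")) {
  variant <- match.arg(variant)
  stopifnot(length(conv_filters) == 5, all(conv_filters >= 1),
            length(dropout) == 3, all(dropout > 0), all(dropout < 1),
            gru_units >= 1, dense_units >= 1, length(classes) >= 2)
  if (variant != "gru_only" && input_size < 32) {
    stop("input_size must be at least 32 for five 2x2 poolings",
         call. = FALSE)
  }
  structure(
    list(input_size = as.integer(input_size),
         conv_filters = as.integer(conv_filters),
         gru_units = as.integer(gru_units),
         dense_units = as.integer(dense_units),
         dropout = as.numeric(dropout),
         classes = as.character(classes),
         n_classes = length(classes),
         variant = variant),
    class = "model_config"
  )
}

# Sequence length and input width the GRU sees, by variant.
gru_dims <- function(cfg) {
  switch(cfg$variant,
    full = list(steps = cfg$conv_filters[5], d = 1L),
    gru_only = list(steps = cfg$input_size, d = 3L * cfg$input_size),
    NULL
  )
}

dense_in <- function(cfg) {
  if (cfg$variant == "cnn_only") cfg$conv_filters[5] else cfg$gru_units
}

#' Layer-by-layer shape table for a model configuration
#'
#' @param cfg A [model_config()].
#' @return A tibble with one row per layer: `layer`, `output_shape`
#'   (character) and `spatial` (side length of the feature maps, `NA` for
#'   non-spatial layers).
#' @export
model_shapes <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  rows <- list(tibble::tibble(layer = "input",
                              output_shape = sprintf("%dx%dx3", cfg$input_size,
                                                     cfg$input_size),
                              spatial = cfg$input_size))
  s <- cfg$input_size
  if (cfg$variant != "gru_only") {
    for (l in 1:5) {
      f <- cfg$conv_filters[l]
      rows <- c(rows, list(tibble::tibble(
        layer = paste0("conv", l),
        output_shape = sprintf("%dx%dx%d", s, s, f), spatial = s)))
      s <- s %/% 2L
      rows <- c(rows, list(tibble::tibble(
        layer = paste0("pool", l),
        output_shape = sprintf("%dx%dx%d", s, s, f), spatial = s)))
    }
    rows <- c(rows, list(tibble::tibble(
      layer = "gap", output_shape = as.character(cfg$conv_filters[5]),
      spatial = NA_integer_)))
  }
  if (cfg$variant != "cnn_only") {
    rows <- c(rows, list(tibble::tibble(
      layer = "gru", output_shape = as.character(cfg$gru_units),
      spatial = NA_integer_)))
  }
  rows <- c(rows, list(
    tibble::tibble(layer = "dense", output_shape = as.character(cfg$dense_units),
                   spatial = NA_integer_),
    tibble::tibble(layer = "softmax", output_shape = as.character(cfg$n_classes),
                   spatial = NA_integer_)
  ))
  dplyr::bind_rows(rows)
}

#' Closed-form trainable parameter count
#'
#' Each 3x3 convolution over `c_in` input maps with `f` filters contributes
#' `(9 * c_in + 1) * f` parameters; the GRU contributes
#' `3 * (u * (u + d) + u)` (three gate weight matrices over the
#' concatenated state and input, plus one bias per gate, the convention
#' used by the training engine); dense layers are standard affine counts.
#' With `biases = FALSE` all bias terms are dropped, matching the bias-free
#' gate equations of the reference [gru_step()].
#'
#' @param cfg A [model_config()].
#' @param biases Include bias terms (the engine's convention).
#' @return Integer total of trainable parameters.
#' @export
count_parameters <- function(cfg, biases = TRUE) {
  stopifnot(inherits(cfg, "model_config"))
  b <- as.integer(biases)
  total <- 0L
  if (cfg$variant != "gru_only") {
    c_in <- 3L
    for (l in 1:5) {
      f <- cfg$conv_filters[l]
      total <- total + (9L * c_in + b) * f
      c_in <- f
    }
  }
  if (cfg$variant != "cnn_only") {
    g <- gru_dims(cfg)
    u <- cfg$gru_units
    total <- total + 3L * (u * (u + g$d) + b * u)
  }
  nin <- dense_in(cfg)
  total <- total + nin * cfg$dense_units + b * cfg$dense_units
  total <- total + cfg$dense_units * cfg$n_classes + b * cfg$n_classes
  as.integer(total)
}

glorot <- function(nrow, ncol, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

#' Build an untrained model
#'
#' Initialises all weights (Glorot-uniform, biases zero) for the given
#' configuration using R's RNG, so the result is reproducible under
#' `set.seed()` / the `seed` argument.
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed for the weight draw.
#' @return An object of class `shock_model`: a list with `config` and the
#'   named parameter list `params`.
#' @export
build_model <- function(cfg = model_config(), seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  params <- withr::with_seed(as.integer(seed) %% 2147483647L, {
    p <- list()
    if (cfg$variant != "gru_only") {
      c_in <- 3L
      for (l in 1:5) {
        f <- cfg$conv_filters[l]
        p[[paste0("Wc", l)]] <- glorot(f, 9 * c_in, 9 * c_in, 9 * f)
        p[[paste0("bc", l)]] <- numeric(f)
        c_in <- f
      }
    }
    if (cfg$variant != "cnn_only") {
      g <- gru_dims(cfg)
      u <- cfg$gru_units
      for (nm in c("Wz", "Wr", "Wh")) {
        p[[nm]] <- glorot(u, u + g$d, u + g$d, u)
      }
      p$bz <- numeric(u); p$br <- numeric(u); p$bh <- numeric(u)
    }
    nin <- dense_in(cfg)
    p$Wd1 <- glorot(cfg$dense_units, nin, nin, cfg$dense_units)
    p$bd1 <- numeric(cfg$dense_units)
    p$Wd2 <- glorot(cfg$n_classes, cfg$dense_units, cfg$dense_units,
                    cfg$n_classes)
    p$bd2 <- numeric(cfg$n_classes)
    p
  })
  structure(list(config = cfg, params = params), class = "shock_model")
}

#' One reference GRU step
#'
#' Bias-free gate equations, evaluated exactly as written: update gate
#' `z_t = sigmoid(W_z [h, x])`, reset gate `r_t = sigmoid(W_r [h, x])`,
#' candidate `h~ = tanh(W [r_t * h, x])`, new state
#' `h' = (1 - z_t) * h + z_t * h~` (elementwise products). This is the
#' mathematical reference implementation; the training engine's cell adds
#' one bias vector per gate and must agree with this function when those
#' biases are zero.
#'
#' @param W_z,W_r,W Gate weight matrices of shape `(u, u + d)` acting on
#'   the concatenation of the previous state and the input.
#' @param h_prev Previous hidden state (length `u`).
#' @param x Current input (length `d`).
#' @return A list with `z`, `r`, `h_tilde`, `h`.
#' @export
gru_step <- function(W_z, W_r, W, h_prev, x) {
  u <- length(h_prev)
  stopifnot(nrow(W_z) == u, nrow(W_r) == u, nrow(W) == u,
            ncol(W_z) == u + length(x), ncol(W_r) == u + length(x),
            ncol(W) == u + length(x))
  sig <- function(v) 1 / (1 + exp(-v))
  hx <- c(h_prev, x)
  z <- sig(as.vector(W_z %*% hx))
  r <- sig(as.vector(W_r %*% hx))
  h_tilde <- tanh(as.vector(W %*% c(r * h_prev, x)))
  h <- (1 - z) * h_prev + z * h_tilde
  list(z = z, r = r, h_tilde = h_tilde, h = h)
}

# Match the shapes of an engine-returned parameter list to a template
# (bias vectors come back as one-column matrices).
align_params <- function(params, template) {
  out <- template
  for (nm in names(template)) {
    out[[nm]] <- if (is.matrix(template[[nm]])) {
      matrix(params[[nm]], nrow(template[[nm]]), ncol(template[[nm]]))
    } else {
      as.numeric(params[[nm]])
    }
  }
  out
}

# Stack a scalogram tibble (or list of images) into the (H, W, 3, N) array
# the engine expects, applying the /255 input normalisation.
prepare_images <- function(x) {
  imgs <- if (is.data.frame(x)) x$image else x
  stopifnot(length(imgs) > 0)
  d <- dim(imgs[[1]])
  arr <- array(0, dim = c(d[1], d[2], d[3], length(imgs)))
  for (i in seq_along(imgs)) arr[, , , i] <- normalize_for_model(imgs[[i]])
  arr
}

label_index <- function(labels, classes) {
  idx <- match(labels, classes)
  if (anyNA(idx)) {
    stop("label(s) outside the model's class set: ",
         paste(unique(labels[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  as.integer(idx - 1L)
}

#' Class probabilities for scalogram images
#'
#' @param object A `shock_model` or `shock_fit`.
#' @param images A scalogram tibble with an `image` list-column, a list of
#'   images, or a pre-built `(H, W, 3, N)` array already scaled to
#'   `[0, 1]`.
#' @param params Which parameter set of a fit to use (`"best"` retains the
#'   best-validation-accuracy checkpoint).
#' @param precision Engine arithmetic: `"single"` or `"double"`.
#' @return An `N x n_classes` matrix of softmax probabilities with class
#'   column names.
#' @export
predict_proba <- function(object, images, params = c("best", "last"),
                          precision = c("single", "double")) {
  params <- match.arg(params)
  precision <- match.arg(precision)
  if (inherits(object, "shock_fit")) {
    p <- if (params == "best") object$best_params else object$model$params
    cfg <- object$model$config
  } else {
    stopifnot(inherits(object, "shock_model"))
    p <- object$params
    cfg <- object$config
  }
  arr <- if (is.array(images) && length(dim(images)) == 4) images
         else prepare_images(images)
  pr <- cpp_predict(p, unclass(cfg), arr,
                    ifelse(precision == "double", "double", "float"))
  colnames(pr) <- cfg$classes
  pr
}

#' @export
print.shock_model <- function(x, ...) {
  cat("<shock_model> variant:", x$config$variant,
      "input:", x$config$input_size, "\n")
  cat("  trainable parameters:", count_parameters(x$config), "\n")
  invisible(x)
}
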