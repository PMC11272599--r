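#' Regular-grid superpixel partition of an image
#'
#' Partitions an `H x W` image into square blocks (edge blocks may be
#' smaller), yielding `ceiling(H/block) * ceiling(W/block)` spatially
#' contiguous superpixels labelled `0 .. S-1` in row-block-major order.
#' Grid superpixels suit smooth scalograms and keep the explanation free
#' of any segmentation dependency; any other label image with contiguous
#' integer labels can be supplied to [explain_prediction()] instead.
#'
#' @param height,width Image dimensions in pixels (or pass an image/array
#'   as `height` and its dims are used).
#' @param block Superpixel side length in pixels.
#' @return An object of class `superpixel_map`: integer `H x W` label
#'   matrix with attribute `S` (number of superpixels).
#' @export
segment_grid <- function(height, width = NULL, block = 32) {
  if (!is.null(dim(height))) {
    d <- dim(height)
    width <- d[2]
    height <- d[1]
  }
  stopifnot(block >= 1, height >= 1, width >= 1)
  bi <- (seq_len(height) - 1) %/% block
  bj <- (seq_len(width) - 1) %/% block
  nbj <- max(bj) + 1
  lab <- outer(bi, bj, function(i, j) i * nbj + j)
  structure(matrix(as.integer(lab), height, width),
            S = as.integer(max(lab) + 1), class = "superpixel_map")
}

#' Explain one scalogram prediction with a local linear surrogate
#'
#' LIME-style explanation: `n` binary on/off patterns over the superpixels
#' are drawn (each superpixel kept with probability 1/2), masked-off
#' regions are filled with the image's mean colour, the model's probability
#' for the target class is collected for every perturbed image, and a
#' kernel-weighted ridge regression of those probabilities on the binary
#' patterns yields one weight per superpixel. Weights are positive where
#' unmasking the region raises the class probability. Sample weights are
#' `exp(-d^2 / kernel_width^2)` with `d` the cosine distance between the
#' pattern and the unperturbed all-ones pattern.
#'
#' @param image One scalogram image (8-bit array, as produced by
#'   [render_scalogram()]).
#' @param model A `shock_fit`/`shock_model`, or a function mapping an
#'   `(H, W, 3, N)` array in `[0, 1]` to an `N x K` probability matrix.
#' @param class Target class: a column name or index of the model output.
#' @param map A `superpixel_map` (defaults to a `block`-sized grid).
#' @param n Number of perturbations; at least the number of superpixels is
#'   recommended (a warning is issued otherwise).
#' @param kernel_width Locality kernel width on cosine distance.
#' @param ridge Ridge penalty of the surrogate.
#' @param block Grid block size used when `map` is not supplied.
#' @param fill `"mean"` (whole-image mean colour) or `"black"` for the
#'   masked-region replacement.
#' @param seed Integer seed; the explanation is reproducible under it.
#' @return An object of class `shock_explanation`: a tibble with
#'   `superpixel` and `weight` (sorted by label), plus attributes `map`,
#'   `class`, `n`, `kernel_width`, `seed`.
#' @export
explain_prediction <- function(image, model, class, map = NULL, n = 1000,
                               kernel_width = 0.25, ridge = 1, block = 32,
                               fill = c("mean", "black"), seed = 1L) {
  fill <- match.arg(fill)
  img <- normalize_for_model(image)
  d <- dim(img)
  stopifnot(length(d) == 3)
  if (is.null(map)) map <- segment_grid(d[1], d[2], block)
  s <- attr(map, "S")
  if (n < s) {
    warning("n = ", n, " perturbations for ", s,
            " superpixels; consider n >= S")
  }
  predict_fun <- if (is.function(model)) {
    model
  } else {
    function(arr) predict_proba(model, arr)
  }
  masks <- withr::with_seed(as.integer(seed) %% 2147483647L, {
    matrix(stats::runif(n * s) < 0.5, n, s) * 1
  })
  if (nrow(unique(masks)) < 2) {
    stop("all perturbations are identical; increase n", call. = FALSE)
  }
  fill_col <- if (fill == "mean") apply(img, 3, mean) else c(0, 0, 0)
  fill_img <- array(rep(fill_col, each = d[1] * d[2]), dim = d)
  # evaluate the model on perturbed images in chunks
  probs <- numeric(n)
  chunk <- 64L
  for (s0 in seq(1, n, by = chunk)) {
    s1 <- min(n, s0 + chunk - 1L)
    arr <- array(0, dim = c(d, s1 - s0 + 1L))
    for (i in s0:s1) {
      off_labels <- which(masks[i, ] == 0) - 1L
      keep <- array(rep(!(unclass(map) %in% off_labels), times = d[3]),
                    dim = d)
      arr[, , , i - s0 + 1L] <- ifelse(keep, img, fill_img)
    }
    p <- predict_fun(arr)
    ci <- if (is.character(class)) match(class, colnames(p)) else class
    if (is.na(ci)) stop("unknown class: ", class, call. = FALSE)
    probs[s0:s1] <- p[, ci]
  }
  # locality kernel on cosine distance to the all-ones pattern
  on_count <- rowSums(masks)
  cosdist <- 1 - on_count / (sqrt(s) * sqrt(pmax(on_count, 1e-12)))
  w <- exp(-cosdist^2 / kernel_width^2)
  # weighted ridge with unpenalised intercept
  x <- cbind(1, masks)
  a <- crossprod(x, x * w)
  pen <- diag(c(0, rep(ridge, s)))
  beta <- solve(a + pen, crossprod(x, probs * w))
  out <- tibble::tibble(superpixel = seq_len(s) - 1L,
                        weight = as.numeric(beta[-1]))
  structure(out, map = map, target_class = class, n = n,
            kernel_width = kernel_width, seed = seed,
            class = c("shock_explanation", class(out)))
}

#' Top influential superpixels of an explanation
#'
#' @param explanation A `shock_explanation`.
#' @param k How many superpixels to return.
#' @return The `k` rows with the largest positive weights.
#' @export
top_superpixels <- function(explanation, k = 5) {
  ord <- order(-explanation$weight)
  explanation[ord[seq_len(min(k, nrow(explanation)))], ]
}
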