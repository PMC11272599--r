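#' SMOTE oversampling of minority-class ECG fragments
#'
#' Balances the per-class fragment counts by synthesizing minority-class
#' fragments through linear interpolation in the raw signal domain: each
#' synthetic fragment is `x_i + u * (x_z - x_i)` where `x_i` is a real
#' class member (chosen round-robin), `x_z` is one of its `k` nearest
#' same-class neighbours under Euclidean distance on the raw sample
#' vectors, and `u` is uniform on `[0, 1]`. Interpolating signals (rather
#' than scalogram pixels) guarantees every synthetic fragment is still a
#' valid signal whose scalogram is well defined.
#'
#' Classes with fewer members than `k + 1` get `k` clipped to `n - 1` with
#' a message; a class that needs oversampling but has fewer than 2 real
#' members is an error.
#'
#' @param fragments A fragment tibble; all fragments of a class must share
#'   one length.
#' @param target_count Desired total per class (every class with fewer
#'   members is oversampled up to it; classes at or above it are left
#'   untouched).
#' @param k Number of nearest neighbours considered (default 5, the
#'   canonical SMOTE setting).
#' @param seed Integer seed driving base/neighbour/interpolation draws.
#' @return The input tibble with synthetic fragments appended per class
#'   (ids `<class>_syn_<n>`, `synthetic = TRUE`).
#' @export
smote_resample <- function(fragments, target_count, k = 5, seed = 1L) {
  check_fragments(fragments)
  stopifnot(target_count >= 1, k >= 1)
  if (!"synthetic" %in% names(fragments)) fragments$synthetic <- FALSE
  counts <- table(fragments$label)
  over <- names(counts)[counts < target_count]
  if (length(over) == 0) return(fragments)
  bad <- names(counts)[counts < 2 & counts < target_count]
  if (length(bad) > 0) {
    stop("class ", paste(bad, collapse = ", "),
         " has fewer than 2 real members and cannot be oversampled",
         call. = FALSE)
  }
  synth <- withr::with_seed(as.integer(seed) %% 2147483647L, {
    purrr::map(over, function(cls) {
      idx <- which(fragments$label == cls)
      x <- do.call(rbind, fragments$samples[idx])
      n <- nrow(x)
      kc <- k
      if (kc > n - 1) {
        message("class ", cls, ": k clipped from ", k, " to ", n - 1)
        kc <- n - 1
      }
      nn <- knn_indices(x, kc)
      need <- target_count - n
      base <- rep(seq_len(n), length.out = need) # round-robin over the class
      nbr_pick <- sample.int(kc, need, replace = TRUE)
      u <- stats::runif(need)
      rows <- purrr::map(seq_len(need), function(j) {
        i <- base[j]
        z <- nn[i, nbr_pick[j]]
        s <- x[i, ] + u[j] * (x[z, ] - x[i, ])
        tibble::tibble(
          id = sprintf("%s_syn_%05d", cls, j - 1L),
          label = cls, fs = fragments$fs[idx[1]], synthetic = TRUE,
          samples = list(s)
        )
      })
      dplyr::bind_rows(rows)
    })
  })
  dplyr::bind_rows(fragments, dplyr::bind_rows(synth))
}

# k nearest same-set neighbours (excluding self) by Euclidean distance;
# returns an n x k index matrix, ties broken by index order.
knn_indices <- function(x, k) {
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  t(apply(d, 1, function(row) order(row)[seq_len(k)]))
}

#' Tally real and synthetic fragments per class
#'
#' @param fragments A fragment tibble (with or without a `synthetic`
#'   column; absent means all real).
#' @return A tibble with one row per class: `label`, `real`, `synthetic`,
#'   `total`, ordered `C1..C4` first then any other labels.
#' @export
class_counts <- function(fragments) {
  if (nrow(fragments) == 0) {
    return(tibble::tibble(label = character(), real = integer(),
                          synthetic = integer(), total = integer()))
  }
  if (!"synthetic" %in% names(fragments)) fragments$synthetic <- FALSE
  out <- fragments |>
    dplyr::count(.data$label, .data$synthetic) |>
    tidyr::pivot_wider(names_from = "synthetic", values_from = "n",
                       values_fill = 0L)
  real <- if ("FALSE" %in% names(out)) out[["FALSE"]] else 0L
  syn <- if ("TRUE" %in% names(out)) out[["TRUE"]] else 0L
  res <- tibble::tibble(label = out$label, real = as.integer(real),
                        synthetic = as.integer(syn))
  res$total <- res$real + res$synthetic
  ord <- order(match(res$label, shock_classes, nomatch = 99L), res$label)
  res[ord, ]
}
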