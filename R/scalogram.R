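#' Morlet mother wavelet
#'
#' The complex Morlet wavelet `psi(t) = exp(2*pi*i*t) * exp(-t^2 / (2*sigma^2))`:
#' a unit-frequency complex carrier under a Gaussian envelope of width
#' `sigma`. With this carrier the wavelet's centre frequency is one cycle
#' per unit of wavelet time, so a scale of `a` seconds responds most to
#' signal content near the pseudo-frequency `1/a` Hz.
#'
#' @param t Numeric vector of (dimensionless) wavelet time.
#' @param sigma Gaussian envelope width, `> 0`.
#' @return Complex vector of wavelet values.
#' @export
morlet <- function(t, sigma = 1) {
  stopifnot(sigma > 0)
  exp(2i * pi * t) * exp(-t^2 / (2 * sigma^2))
}

#' Logarithmic grid of wavelet scales
#'
#' `n_scales` log-spaced scales (seconds) whose pseudo-frequencies `1/a`
#' cover `freq_range`. The default 1-50 Hz brackets the fundamentals and
#' low harmonics of all four rhythm classes at typical ECG sampling rates.
#'
#' @param n_scales Number of scales.
#' @param freq_range Length-2 pseudo-frequency range in Hz.
#' @return Strictly increasing numeric vector of scales in seconds (so the
#'   first scale is the highest frequency).
#' @export
scale_grid <- function(n_scales = 64, freq_range = c(1, 50)) {
  stopifnot(n_scales >= 2, all(freq_range > 0), freq_range[1] < freq_range[2])
  exp(seq(log(1 / freq_range[2]), log(1 / freq_range[1]),
          length.out = n_scales))
}

# Envelope support half-width in samples for scale a: where the Gaussian
# falls below 1e-8 of its peak.
cwt_halfwidth <- function(a, fs, sigma) {
  ceiling(a * fs * sigma * sqrt(2 * log(1e8)))
}

# Precomputed FFT kernels shared by every fragment of the same length/rate.
cwt_plan <- function(n, fs, scales, sigma) {
  lmax <- cwt_halfwidth(max(scales), fs, sigma)
  m <- stats::nextn(n + 2 * lmax + 1)
  kernels <- purrr::map(scales, function(a) {
    l <- cwt_halfwidth(a, fs, sigma)
    j <- -l:l
    kk <- Conj(morlet(j / (fs * a), sigma)) # kk_j = conj(psi(j / (fs a)))
    g <- complex(length.out = m)            # g_j = kk_{-j}, circular layout
    g[1] <- kk[l + 1]
    g[1 + seq_len(l)] <- kk[l + 1 - seq_len(l)]
    g[m + 1 - seq_len(l)] <- kk[l + 1 + seq_len(l)]
    stats::fft(g)
  })
  list(n = n, m = m, fs = fs, scales = scales, sigma = sigma,
       kernels = kernels)
}

#' Continuous wavelet transform with the Morlet wavelet
#'
#' Computes, for every scale `a` on the grid and every shift `b` at the
#' sample positions, the coefficient
#' `(1/sqrt(a)) * sum_t f(t) * Conj(psi((t - b)/a)) * dt` with
#' `dt = 1/fs`, i.e. the discretised CWT integral with the standard
#' conjugated analysing wavelet. The wavelet support is truncated where its
#' envelope falls below `1e-8` of the peak and the correlations are
#' evaluated by FFT; the result matches the direct double-loop summation to
#' numerical precision.
#'
#' @param samples Numeric vector of signal samples (mV).
#' @param fs Sampling rate in Hz.
#' @param scales Strictly increasing positive scales in seconds, e.g. from
#'   [scale_grid()].
#' @param sigma Morlet envelope width.
#' @param plan Optional precomputed plan (internal; built automatically).
#' @return An object of class `cwt_coefficients`: a list with the complex
#'   `values` matrix (`length(scales)` rows by `length(samples)` columns),
#'   `scales`, `shifts` (seconds) and `fs`.
#' @export
cwt <- function(samples, fs, scales = scale_grid(), sigma = 1, plan = NULL) {
  if (length(scales) == 0) stop("scale grid is empty", call. = FALSE)
  stopifnot(length(samples) > 0, all(is.finite(samples)), all(scales > 0),
            all(diff(scales) > 0))
  n <- length(samples)
  if (is.null(plan)) plan <- cwt_plan(n, fs, scales, sigma)
  stopifnot(plan$n == n)
  fpad <- complex(length.out = plan$m)
  fpad[seq_len(n)] <- samples
  ffft <- stats::fft(fpad)
  vals <- matrix(0i, nrow = length(scales), ncol = n)
  for (s in seq_along(scales)) {
    conv <- stats::fft(ffft * plan$kernels[[s]], inverse = TRUE) / plan$m
    vals[s, ] <- conv[seq_len(n)] / (sqrt(scales[s]) * fs)
  }
  structure(
    list(values = vals, scales = scales, shifts = (seq_len(n) - 1) / fs,
         fs = fs),
    class = "cwt_coefficients"
  )
}

# ---- Rendering -------------------------------------------------------------

# MATLAB-style rainbow ("jet") anchors plus a grayscale fallback.
colormap_anchors <- function(name) {
  switch(name,
    jet = list(
      pos = c(0, 0.125, 0.375, 0.625, 0.875, 1),
      rgb = rbind(c(0, 0, 0.5), c(0, 0, 1), c(0, 1, 1),
                  c(1, 1, 0), c(1, 0, 0), c(0.5, 0, 0))
    ),
    gray = list(pos = c(0, 1), rgb = rbind(c(0, 0, 0), c(1, 1, 1))),
    stop("unknown colormap: ", name, call. = FALSE)
  )
}

apply_colormap <- function(v, name) {
  a <- colormap_anchors(name)
  out <- array(0, dim = c(dim(v), 3))
  for (ch in 1:3) {
    out[, , ch] <- matrix(
      stats::approx(a$pos, a$rgb[, ch], xout = as.vector(v), rule = 2)$y,
      nrow = nrow(v)
    )
  }
  out
}

resize_bilinear <- function(arr, height, width) {
  # EBImage indexes images [x, y, channel]; our convention is [row, col, ch]
  img <- EBImage::Image(aperm(arr, c(2, 1, 3)), colormode = "Color")
  out <- EBImage::resize(img, w = width, h = height, filter = "bilinear")
  aperm(EBImage::imageData(out), c(2, 1, 3))
}

#' Render CWT coefficients as a fixed-size RGB scalogram image
#'
#' Coefficient magnitudes are min-max scaled to `[0, 1]` per image (a
#' constant matrix maps to all zeros), passed through a colormap, resized
#' with bilinear interpolation to `size` x `size`, and quantised to 8-bit.
#' Row 1 of the image is the smallest scale, so high frequencies sit at the
#' top. Per-image scaling makes the image invariant to positive rescaling
#' of the signal; pass an explicit `range` for global normalisation across
#' a dataset.
#'
#' @param coeffs A `cwt_coefficients` object (or a numeric magnitude
#'   matrix, scales in rows).
#' @param size Output height and width in pixels (227 matches the
#'   classifier's native input).
#' @param colormap `"jet"` (default) or `"gray"`.
#' @param log Take `log1p` of the magnitudes before scaling.
#' @param range Optional fixed `c(min, max)` magnitude range for global
#'   normalisation.
#' @return An integer array `size` x `size` x 3 of class `scalogram_image`
#'   with values in `[0, 255]`.
#' @export
render_scalogram <- function(coeffs, size = 227, colormap = "jet",
                             log = FALSE, range = NULL) {
  mag <- if (inherits(coeffs, "cwt_coefficients")) abs(coeffs$values)
         else abs(coeffs)
  stopifnot(all(is.finite(mag)), size >= 2)
  if (log) mag <- log1p(mag)
  r <- if (is.null(range)) base::range(mag) else range
  v <- if (diff(r) > 0) pmin(pmax((mag - r[1]) / diff(r), 0), 1)
       else matrix(0, nrow(mag), ncol(mag))
  rgb <- apply_colormap(v, colormap)
  res <- resize_bilinear(rgb, size, size)
  img <- array(as.integer(round(pmin(pmax(res, 0), 1) * 255)),
               dim = dim(res))
  structure(img, class = c("scalogram_image", class(img)))
}

#' Scale an 8-bit scalogram image to the model's `[0, 1]` input range
#'
#' Divides every channel value by 255, the normalisation applied to all
#' images before training or prediction.
#'
#' @param img A `scalogram_image` (or any array of 8-bit values).
#' @return A numeric array of the same shape with values in `[0, 1]`.
#' @export
normalize_for_model <- function(img) {
  unclass(img) / 255
}

#' Transform a table of fragments into scalogram images
#'
#' Applies [cwt()] and [render_scalogram()] to every fragment, sharing the
#' FFT kernels across fragments of equal length and sampling rate.
#'
#' @param fragments A fragment tibble (see [generate_dataset()]).
#' @param scales Scale grid in seconds.
#' @param sigma Morlet envelope width.
#' @param size Output image size in pixels.
#' @param colormap,log,range Passed to [render_scalogram()].
#' @return The input tibble without `samples`, plus a list-column `image`
#'   of `scalogram_image` arrays.
#' @export
fragments_to_scalograms <- function(fragments, scales = scale_grid(),
                                    sigma = 1, size = 227,
                                    colormap = "jet", log = FALSE,
                                    range = NULL) {
  check_fragments(fragments)
  keys <- paste(fragments$fs, lengths(fragments$samples))
  plans <- new.env(parent = emptyenv())
  images <- purrr::map2(fragments$samples, seq_len(nrow(fragments)),
    function(x, i) {
      key <- keys[i]
      if (is.null(plans[[key]])) {
        plans[[key]] <- cwt_plan(length(x), fragments$fs[i], scales, sigma)
      }
      co <- cwt(x, fragments$fs[i], scales, sigma, plan = plans[[key]])
      render_scalogram(co, size = size, colormap = colormap, log = log,
                       range = range)
    })
  out <- fragments[setdiff(names(fragments), "samples")]
  out$image <- images
  out
}
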