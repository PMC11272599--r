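#' Shockable-rhythm classes
#'
#' The four shockable ventricular arrhythmia classes handled throughout the
#' package: `C1` ventricular flutter (VFL), `C2` ventricular fibrillation
#' (VF), `C3` torsade de pointes (VTTdP), `C4` high-rate monomorphic
#' ventricular tachycardia (VTHR).
#'
#' @export
shock_classes <- c("C1", "C2", "C3", "C4")

#' Configuration for the synthetic ECG fragment generator
#'
#' Bundles every knob of the four-class generator. The defaults emulate
#' 2-second single-lead Holter fragments sampled at 250 Hz with the four
#' rhythm morphologies: VFL as a fast near-sinusoid, VF as an irregular sum
#' of drifting sinusoids, torsade de pointes as a wide-QRS pulse train whose
#' amplitude twists around the isoelectric line, and high-rate VT as a
#' strictly regular wide-QRS pulse train of constant amplitude.
#'
#' @param fs Sampling rate in Hz.
#' @param duration Fragment length in seconds.
#' @param noise_sd Standard deviation of additive Gaussian noise, in mV.
#' @param amplitude Peak absolute amplitude of the clean waveform, in mV.
#' @param seed Integer master seed; together with the class label and
#'   fragment index it fully determines each fragment, so inserting
#'   fragments never changes existing ones.
#' @param c1_rate,c2_rate,c3_rate,c4_rate Length-2 numeric ranges (Hz) from
#'   which the per-fragment fundamental / pulse rate is drawn uniformly.
#' @param c2_components Range of how many sinusoidal components build a VF
#'   fragment (at least 5 by default, so no stable period exists).
#' @param c3_mod_rate Range (Hz) of the slow sinusoidal envelope modulation
#'   of the torsade pulse train.
#' @param c3_mod_depth Modulation depth in `[0, 1]`; depths above 0.5 make
#'   the envelope cross zero so pulse polarity alternates about the isoline.
#' @param pulse_width Width parameter (seconds) of the Gaussian-derivative
#'   lobe used as the wide ventricular complex for C3/C4.
#'
#' @return A list of class `synth_config`.
#' @seealso [generate_fragment()], [generate_dataset()]
#' @export
synth_config <- function(fs = 250,
                         duration = 2,
                         noise_sd = 0.05,
                         amplitude = 1,
                         seed = 1L,
                         c1_rate = c(4, 6),
                         c2_rate = c(3, 8),
                         c2_components = c(5, 8),
                         c3_rate = c(3, 5),
                         c3_mod_rate = c(0.2, 0.5),
                         c3_mod_depth = 0.8,
                         c4_rate = c(2.5, 4),
                         pulse_width = 0.025) {
  stopifnot(fs > 0, duration > 0, noise_sd >= 0, amplitude > 0)
  for (r in list(c1_rate, c2_rate, c3_rate, c4_rate, c3_mod_rate)) {
    stopifnot(length(r) == 2, all(r > 0), r[1] <= r[2])
  }
  stopifnot(c3_mod_depth >= 0, c3_mod_depth <= 1)
  structure(
    list(
      fs = fs, duration = duration, noise_sd = noise_sd,
      amplitude = amplitude, seed = as.integer(seed),
      c1_rate = c1_rate, c2_rate = c2_rate, c2_components = c2_components,
      c3_rate = c3_rate, c3_mod_rate = c3_mod_rate,
      c3_mod_depth = c3_mod_depth, c4_rate = c4_rate,
      pulse_width = pulse_width
    ),
    class = "synth_config"
  )
}

# Deterministic per-fragment seed: a fixed integer hash of (master seed,
# class, index) kept inside the 32-bit signed range. Each fragment gets its
# own stream, so generation order is irrelevant.
fragment_seed <- function(seed, cls, index) {
  ci <- match(cls, shock_classes)
  s <- (as.double(seed) * 2654435761 + ci * 97003969 + as.double(index) * 7919) %%
    2147483647
  as.integer(s)
}

# Gaussian-derivative lobe standing in for a wide ventricular QRS complex:
# biphasic, zero-mean, peak normalised to 1.
qrs_lobe <- function(t, width) {
  x <- t / width
  -x * exp(-x^2 / 2) / exp(-0.5)
}

# Strictly periodic pulse train with per-pulse amplitudes `amps`.
pulse_train <- function(t, rate, phase, width, amps_fun) {
  period <- 1 / rate
  # enough pulses to cover [0, max(t)] plus margins for edge lobes
  k <- seq(-2, ceiling(max(t) / period) + 2)
  centers <- phase + k * period
  out <- numeric(length(t))
  for (i in seq_along(centers)) {
    out <- out + amps_fun(centers[i]) * qrs_lobe(t - centers[i], width)
  }
  out
}

runif1 <- function(range) stats::runif(1, range[1], range[2])

#' Generate one synthetic ECG fragment
#'
#' Draws a single 2-s single-lead fragment of the requested shockable-rhythm
#' class. Deterministic in `(cls, cfg$seed, index)`: calling twice with the
#' same arguments returns identical samples.
#'
#' Morphologies: `C1` is a near-sinusoid whose fundamental is drawn from
#' `cfg$c1_rate`; `C2` sums at least five sinusoids with random frequencies,
#' phases and slowly drifting amplitudes (no stable period); `C3` is a
#' periodic wide-pulse train whose amplitude envelope is sinusoidally
#' modulated at `cfg$c3_mod_rate` and alternates polarity about the
#' isoelectric line; `C4` is a strictly periodic wide-pulse train of
#' constant amplitude. The clean waveform is scaled to peak at
#' `cfg$amplitude` mV and Gaussian noise of sd `cfg$noise_sd` is added.
#'
#' @param cls One of `"C1"`, `"C2"`, `"C3"`, `"C4"`.
#' @param cfg A [synth_config()].
#' @param index Non-negative integer identifying the fragment within its
#'   class.
#' @return A one-row fragment tibble with columns `id`, `label`, `fs`,
#'   `synthetic` and the list-column `samples`.
#' @export
generate_fragment <- function(cls, cfg = synth_config(), index = 0L) {
  if (!is.character(cls) || length(cls) != 1 || !cls %in% shock_classes) {
    stop("unknown class label '", paste(cls, collapse = ","),
         "'; valid labels are ", paste(shock_classes, collapse = ", "),
         call. = FALSE)
  }
  n <- round(cfg$fs * cfg$duration)
  t <- seq(0, by = 1 / cfg$fs, length.out = n)
  clean <- withr::with_seed(fragment_seed(cfg$seed, cls, index), {
    x <- switch(cls,
      C1 = { # ventricular flutter: fast near-sinusoidal waves
        f0 <- runif1(cfg$c1_rate)
        ph <- stats::runif(2, 0, 2 * pi)
        sin(2 * pi * f0 * t + ph[1]) + 0.1 * sin(2 * pi * 2 * f0 * t + ph[2])
      },
      C2 = { # fibrillation: irregular sum of drifting sinusoids
        k <- sample(seq(cfg$c2_components[1], cfg$c2_components[2]), 1)
        f <- stats::runif(k, cfg$c2_rate[1], cfg$c2_rate[2])
        ph <- stats::runif(k, 0, 2 * pi)
        base <- stats::runif(k, 0.4, 1)
        drift_f <- stats::runif(k, 0.1, 0.5)
        drift_ph <- stats::runif(k, 0, 2 * pi)
        x <- numeric(n)
        for (j in seq_len(k)) {
          amp <- base[j] * (1 + 0.5 * sin(2 * pi * drift_f[j] * t + drift_ph[j]))
          x <- x + amp * sin(2 * pi * f[j] * t + ph[j])
        }
        x
      },
      C3 = { # torsade: pulse train twisting about the isoline
        rate <- runif1(cfg$c3_rate)
        fmod <- runif1(cfg$c3_mod_rate)
        ph <- stats::runif(1, 0, 1 / rate)
        mod_ph <- stats::runif(1, 0, 2 * pi)
        d <- cfg$c3_mod_depth
        train <- pulse_train(t, rate, ph, cfg$pulse_width, function(...) 1)
        train * ((1 - d) + d * sin(2 * pi * fmod * t + mod_ph))
      },
      C4 = { # high-rate VT: strictly regular, constant amplitude
        rate <- runif1(cfg$c4_rate)
        ph <- stats::runif(1, 0, 1 / rate)
        pulse_train(t, rate, ph, cfg$pulse_width, function(...) 1)
      }
    )
    x <- cfg$amplitude * x / max(abs(x))
    if (cfg$noise_sd > 0) x <- x + stats::rnorm(n, 0, cfg$noise_sd)
    x
  })
  tibble::tibble(
    id = sprintf("%s_%05d", cls, as.integer(index)),
    label = cls,
    fs = cfg$fs,
    synthetic = FALSE,
    samples = list(clean)
  )
}

#' Generate a class-blocked synthetic ECG dataset
#'
#' @param counts Named integer vector (names in `C1`-`C4`) of how many
#'   fragments to draw per class.
#' @param cfg A [synth_config()].
#' @return A fragment tibble, class-blocked in `C1..C4` order then
#'   index-ordered, with unique ids. Deterministic in `cfg$seed`.
#' @examples
#' frags <- generate_dataset(c(C1 = 5, C2 = 5, C3 = 5, C4 = 5), synth_config())
#' @export
generate_dataset <- function(counts, cfg = synth_config()) {
  stopifnot(!is.null(names(counts)), all(names(counts) %in% shock_classes),
            all(counts >= 0))
  out <- purrr::map(shock_classes, function(cls) {
    nc <- if (cls %in% names(counts)) counts[[cls]] else 0L
    if (nc == 0) return(NULL)
    purrr::map(seq_len(nc) - 1L, function(i) generate_fragment(cls, cfg, i))
  })
  rows <- purrr::compact(purrr::flatten(out))
  if (length(rows) == 0) {
    return(tibble::tibble(id = character(), label = character(),
                          fs = double(), synthetic = logical(),
                          samples = list()))
  }
  dplyr::bind_rows(rows)
}

# Internal validator used by downstream stages.
check_fragments <- function(fragments) {
  need <- c("id", "label", "fs", "samples")
  missing <- setdiff(need, names(fragments))
  if (length(missing) > 0) {
    stop("fragment table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(fragments$id) > 0) stop("fragment ids must be unique",
                                            call. = FALSE)
  invisible(fragments)
}
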