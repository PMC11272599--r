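#' Read a single-lead signal record
#'
#' Reads either a two-column CSV (`time_s`, `mV`, with header) or a WFDB
#' header/signal pair into a signal record: a list with `samples` (mV),
#' `fs` (Hz) and optional `annotations`.
#'
#' For CSV the sampling rate is inferred as the reciprocal of the median
#' time step; a non-monotone time column is an error. For WFDB the rate
#' comes from the header and ADC units are converted to mV via each
#' channel's gain and baseline. Multi-channel WFDB records are reduced to
#' one channel (`channel`, default the first), with a message noting the
#' choice. If a sibling `.atr` annotation file exists it is read
#' automatically.
#'
#' @param path Path to the `.csv` file or to the WFDB record (with or
#'   without the `.hea` extension).
#' @param format `"csv"` or `"wfdb"`; guessed from the extension by default.
#' @param channel 1-based channel to keep from multi-channel WFDB records.
#' @return A list of class `signal_record` with elements `samples`, `fs`
#'   and `annotations` (a tibble with `sample` and `symbol`, or `NULL`).
#' @export
read_record <- function(path, format = c("auto", "csv", "wfdb"), channel = 1L) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "wfdb"
  }
  if (format == "csv") read_record_csv(path) else read_record_wfdb(path, channel)
}

new_signal_record <- function(samples, fs, annotations = NULL) {
  stopifnot(all(is.finite(samples)), fs > 0)
  if (!is.null(annotations)) {
    stopifnot(all(diff(annotations$sample) > 0),
              all(annotations$sample >= 0),
              all(annotations$sample < length(samples)))
  }
  structure(list(samples = as.numeric(samples), fs = fs,
                 annotations = annotations),
            class = "signal_record")
}

read_record_csv <- function(path) {
  if (!file.exists(path)) stop("unreadable file: ", path, call. = FALSE)
  d <- utils::read.csv(path)
  if (ncol(d) < 2) stop("CSV must have at least two columns (time, mV): ",
                        path, call. = FALSE)
  tm <- d[[1]]
  dt <- diff(tm)
  if (any(dt <= 0)) stop("non-monotone time column in ", path, call. = FALSE)
  fs <- 1 / stats::median(dt)
  if (!is.finite(fs) || fs <= 0) {
    stop("could not infer sampling rate from the time column of ", path,
         call. = FALSE)
  }
  new_signal_record(d[[2]], fs)
}

# ---- WFDB (.hea/.dat/.atr), minimal subset --------------------------------
# Supports signal formats 16 (int16 little-endian, interleaved) and
# 212 (packed 12-bit pairs). Gains default to 200 adu/mV when absent.

parse_hea <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(top[3]) else 250
  nsamp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  sig <- purrr::map(lines[1 + seq_len(nsig)], function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    gain <- 200; baseline <- 0
    if (length(f) >= 3) {
      g <- f[3]
      m <- regmatches(g, regexec("^([-0-9.]+)(\\(([-0-9]+)\\))?", g))[[1]]
      if (length(m) > 1 && nzchar(m[2]) && as.numeric(m[2]) != 0) {
        gain <- as.numeric(m[2])
      }
      if (length(m) > 3 && nzchar(m[4])) baseline <- as.numeric(m[4])
    }
    list(file = f[1], format = as.integer(sub(":.*|x.*|\\+.*", "", f[2])),
         gain = gain, baseline = baseline)
  })
  list(record = top[1], nsig = nsig, fs = fs, nsamp = nsamp, signals = sig)
}

read_dat_16 <- function(path, nsig, nsamp) {
  sz <- file.info(path)$size
  n <- sz %/% (2 * nsig)
  if (!is.na(nsamp) && nsamp > 0) n <- min(n, nsamp)
  raw <- readBin(path, "integer", n = n * nsig, size = 2, signed = TRUE,
                 endian = "little")
  matrix(raw, ncol = nsig, byrow = TRUE)
}

read_dat_212 <- function(path, nsig, nsamp) {
  bytes <- readBin(path, "integer", n = file.info(path)$size, size = 1,
                   signed = FALSE)
  npairs <- length(bytes) %/% 3
  b1 <- bytes[seq(1, npairs * 3, 3)]
  b2 <- bytes[seq(2, npairs * 3, 3)]
  b3 <- bytes[seq(3, npairs * 3, 3)]
  s1 <- b1 + bitwShiftL(bitwAnd(b2, 15L), 8)
  s2 <- b3 + bitwShiftL(bitwShiftR(b2, 4L), 8)
  tosigned <- function(v) ifelse(v >= 2048, v - 4096, v)
  flat <- as.vector(rbind(tosigned(s1), tosigned(s2)))
  n <- length(flat) %/% nsig
  if (!is.na(nsamp) && nsamp > 0) n <- min(n, nsamp)
  matrix(flat[seq_len(n * nsig)], ncol = nsig, byrow = TRUE)
}

read_record_wfdb <- function(path, channel = 1L) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("unreadable file: ", hea, call. = FALSE)
  h <- parse_hea(hea)
  dat <- file.path(dirname(hea), h$signals[[1]]$file)
  if (!file.exists(dat)) stop("unreadable file: ", dat, call. = FALSE)
  fmt <- h$signals[[1]]$format
  adc <- switch(as.character(fmt),
    "16" = read_dat_16(dat, h$nsig, h$nsamp),
    "212" = read_dat_212(dat, h$nsig, h$nsamp),
    stop("unsupported WFDB signal format: ", fmt, call. = FALSE)
  )
  if (h$nsig > 1) {
    message("record ", h$record, " has ", h$nsig,
            " channels; keeping channel ", channel)
  }
  ch <- h$signals[[channel]]
  mv <- (adc[, channel] - ch$baseline) / ch$gain
  atr <- sub("\\.hea$", ".atr", hea)
  ann <- if (file.exists(atr)) read_wfdb_annotations(atr) else NULL
  new_signal_record(mv, h$fs, ann)
}

#' Write a WFDB record (format 16)
#'
#' Minimal writer used to create WFDB fixtures and to export synthetic
#' signals: one `.hea` header plus an int16 little-endian `.dat`.
#'
#' @param signals Numeric matrix, one column per channel, in mV.
#' @param record Record name (file stem).
#' @param dir Output directory.
#' @param fs Sampling rate (Hz).
#' @param gain ADC units per mV.
#' @return The header path, invisibly.
#' @export
write_wfdb <- function(signals, record, dir, fs = 250, gain = 200) {
  signals <- as.matrix(signals)
  nsig <- ncol(signals)
  n <- nrow(signals)
  adc <- round(signals * gain)
  stopifnot(all(abs(adc) < 32768))
  dat <- file.path(dir, paste0(record, ".dat"))
  hea <- file.path(dir, paste0(record, ".hea"))
  con <- file(dat, "wb")
  writeBin(as.integer(t(adc)), con, size = 2, endian = "little")
  close(con)
  sig_lines <- sprintf("%s.dat 16 %g(0)/mV 16 0 0 0 0 ch%d",
                       record, gain, seq_len(nsig))
  writeLines(c(sprintf("%s %d %g %d", record, nsig, fs, n), sig_lines), hea)
  invisible(hea)
}

# MIT annotation format: 2-byte little-endian words, type code in the high
# 6 bits, time increment in the low 10 bits. Code 0 with zero increment
# terminates; codes 59-63 are control words (SKIP/NUM/SUB/CHN/AUX).
mit_ann_symbols <- c("N", "L", "R", "a", "V", "F", "J", "A", "S", "E",
                     "j", "/", "Q", "~")

#' Read a WFDB annotation file (MIT format subset)
#'
#' @param path Path to the `.atr` file.
#' @return Tibble with columns `sample` (0-based index) and `symbol`.
#' @export
read_wfdb_annotations <- function(path) {
  words <- readBin(path, "integer", n = file.info(path)$size %/% 2, size = 2,
                   signed = FALSE, endian = "little")
  samples <- integer(0); symbols <- character(0)
  tcur <- 0; i <- 1
  while (i <= length(words)) {
    w <- words[i]
    code <- bitwShiftR(w, 10L)
    inc <- bitwAnd(w, 1023L)
    if (code == 0 && inc == 0) break
    if (code == 59) { # SKIP: next two words hold a long interval (high first)
      tcur <- tcur + words[i + 1] * 65536 + words[i + 2]
      i <- i + 3
      next
    }
    if (code == 63) { # AUX: inc bytes of payload, padded to even
      i <- i + 1 + ceiling(inc / 2)
      next
    }
    if (code %in% c(60, 61, 62)) { # NUM/SUB/CHN carry no time
      i <- i + 1
      next
    }
    tcur <- tcur + inc
    samples <- c(samples, tcur)
    symbols <- c(symbols,
                 if (code <= length(mit_ann_symbols)) mit_ann_symbols[code]
                 else "?")
    i <- i + 1
  }
  tibble::tibble(sample = samples - 1L, symbol = symbols) # 0-based
}

#' Write a WFDB annotation file (MIT format subset)
#'
#' @param annotations Tibble with `sample` (0-based) and `symbol`.
#' @param path Output `.atr` path.
#' @return `path`, invisibly.
#' @export
write_wfdb_annotations <- function(annotations, path) {
  codes <- match(annotations$symbol, mit_ann_symbols)
  codes[is.na(codes)] <- 13L # 'Q' unknown beat
  prev <- 0
  words <- integer(0)
  for (i in seq_len(nrow(annotations))) {
    s <- annotations$sample[i] + 1L
    delta <- s - prev
    if (delta > 1023) { # SKIP word + 4-byte interval (high word first)
      words <- c(words, bitwShiftL(59L, 10L), delta %/% 65536, delta %% 65536)
      delta <- 0
    }
    words <- c(words, bitwShiftL(codes[i], 10L) + delta)
    prev <- s
  }
  con <- file(path, "wb")
  writeBin(as.integer(c(words, 0L)), con, size = 2, endian = "little")
  close(con)
  invisible(path)
}

# ---- Fragment CSV layout ---------------------------------------------------

#' Write fragments as per-fragment CSVs plus a manifest
#'
#' Each fragment becomes `<id>.csv` with header `time_s,mV`; the manifest
#' `labels.csv` lists `id,label,fs,synthetic`.
#'
#' @param fragments A fragment tibble.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fragments <- function(fragments, dir) {
  check_fragments(fragments)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  purrr::pwalk(fragments[c("id", "fs", "samples")], function(id, fs, samples) {
    d <- data.frame(time_s = (seq_along(samples) - 1) / fs, mV = samples)
    utils::write.csv(d, file.path(dir, paste0(id, ".csv")), row.names = FALSE)
  })
  man <- fragments[c("id", "label", "fs")]
  man$synthetic <- if ("synthetic" %in% names(fragments)) {
    fragments$synthetic
  } else {
    FALSE
  }
  utils::write.csv(man, file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read fragments written by [write_fragments()]
#'
#' @param dir Directory holding per-fragment CSVs and `labels.csv`.
#' @return A fragment tibble.
#' @export
read_fragments <- function(dir) {
  man <- utils::read.csv(file.path(dir, "labels.csv"),
                         colClasses = c(id = "character"))
  rows <- purrr::pmap(man, function(id, label, fs, synthetic) {
    rec <- read_record_csv(file.path(dir, paste0(id, ".csv")))
    tibble::tibble(id = id, label = label, fs = rec$fs,
                   synthetic = isTRUE(synthetic), samples = list(rec$samples))
  })
  check_fragments(dplyr::bind_rows(rows))
}

# ---- Segmentation ----------------------------------------------------------

fragment_rows <- function(rec, starts, w, prefix) {
  purrr::imap(starts, function(s, i) {
    tibble::tibble(
      id = sprintf("%s_%05d", prefix, i - 1L),
      label = NA_character_, fs = rec$fs, synthetic = FALSE,
      samples = list(rec$samples[(s + 1):(s + w)]) # s is 0-based
    )
  })
}

#' Cut a record into fixed-length windows
#'
#' Windows are half-open `[start, start + W)` in 0-based sample
#' coordinates, with `W = round(window_s * fs)` and stride
#' `S = round(stride_s * fs)`; a trailing partial window is dropped, so the
#' number of fragments is `floor((N - W) / S) + 1` (0 when the window is
#' longer than the record).
#'
#' @param rec A `signal_record`.
#' @param window_s Window length in seconds (default the 2-s analysis
#'   window used throughout the package).
#' @param stride_s Stride in seconds; equal to `window_s` gives
#'   non-overlapping windows.
#' @param prefix Id prefix for the resulting fragments.
#' @return A fragment tibble (possibly empty) with `label = NA`.
#' @export
segment_fixed <- function(rec, window_s = 2, stride_s = window_s,
                          prefix = "seg") {
  stopifnot(inherits(rec, "signal_record"), stride_s > 0)
  w <- round(window_s * rec$fs)
  s <- round(stride_s * rec$fs)
  n <- length(rec$samples)
  stopifnot(w >= 2)
  if (w > n) {
    message("window (", w, " samples) longer than record (", n,
            " samples); no fragments")
    return(dplyr::bind_rows(fragment_rows(rec, integer(0), w, prefix)))
  }
  k <- floor((n - w) / s) + 1
  starts <- (seq_len(k) - 1L) * s
  dplyr::bind_rows(fragment_rows(rec, starts, w, prefix))
}

#' Cut annotation-centred windows from a record
#'
#' One window per annotation, centred so that the annotated sample sits at
#' 0-based offset `floor(W / 2)` within the fragment
#' (`W = round(window_s * fs)`; for even `W` the centre ties toward the
#' earlier sample). Annotations whose window would cross the record bounds
#' are skipped and counted in a message.
#'
#' @inheritParams segment_fixed
#' @param window_s Window length in seconds (e.g. 0.6 s beat windows).
#' @return A fragment tibble; `label` carries the annotation symbol.
#' @export
segment_around_annotations <- function(rec, window_s, prefix = "ann") {
  stopifnot(inherits(rec, "signal_record"))
  if (is.null(rec$annotations) || nrow(rec$annotations) == 0) {
    stop("record has no annotations", call. = FALSE)
  }
  w <- round(window_s * rec$fs)
  n <- length(rec$samples)
  starts <- rec$annotations$sample - floor(w / 2)
  ok <- starts >= 0 & (starts + w) <= n
  if (any(!ok)) {
    message(sum(!ok), " annotation(s) skipped: window crosses record bounds")
  }
  out <- dplyr::bind_rows(fragment_rows(rec, starts[ok], w, prefix))
  if (nrow(out) > 0) out$label <- rec$annotations$symbol[ok]
  out
}
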