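test_that("fragment CSVs round-trip through write and read", {
  d <- generate_dataset(c(C1 = 2, C3 = 2), synth_config(seed = 3))
  dir <- withr::local_tempdir()
  write_fragments(d, dir)
  back <- read_fragments(dir)
  expect_equal(back$id, d$id)
  expect_equal(back$label, d$label)
  expect_equal(back$fs, d$fs)
  expect_equal(back$samples, d$samples, tolerance = 1e-12)
})

test_that("sampling rate is inferred from the CSV time column", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(time_s = c(0, 0.004, 0.008), mV = c(0, 1, 0)), f,
            row.names = FALSE)
  rec <- read_record(f)
  expect_equal(rec$fs, 250)
  expect_equal(rec$samples, c(0, 1, 0))

  g <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(time_s = c(0, 0.01, 0.005), mV = 1:3), g,
            row.names = FALSE)
  expect_error(read_record(g), "non-monotone")
  expect_error(read_record(file.path(tempdir(), "nope.csv")), "unreadable")
})

test_that("WFDB records round-trip and multi-channel selects channel 0", {
  dir <- withr::local_tempdir()
  fs <- 250
  sig <- cbind(sin(2 * pi * 5 * (0:499) / fs), cos(2 * pi * 3 * (0:499) / fs))
  write_wfdb(sig, "two", dir, fs = fs, gain = 1000)
  expect_message(rec <- read_record(file.path(dir, "two")), "channel 1")
  expect_equal(rec$fs, fs)
  # quantisation to 1/1000 mV
  expect_equal(rec$samples, sig[, 1], tolerance = 1e-3)

  rec2 <- suppressMessages(read_record(file.path(dir, "two"), channel = 2))
  expect_equal(rec2$samples, sig[, 2], tolerance = 1e-3)
})

test_that("format 212 packed samples are decoded", {
  # hand-pack two known 12-bit samples per 3 bytes
  dir <- withr::local_tempdir()
  vals <- c(100L, -200L, 2047L, -2048L, 0L, 5L)
  tw <- function(v) ifelse(v < 0, v + 4096L, v)
  bytes <- integer(0)
  for (i in seq(1, length(vals), 2)) {
    a <- tw(vals[i]); b <- tw(vals[i + 1])
    bytes <- c(bytes, a %% 256, (a %/% 256) + 16 * (b %/% 256), b %% 256)
  }
  writeBin(as.raw(bytes), file.path(dir, "p212.dat"))
  writeLines(c("p212 1 360 6", "p212.dat 212 200(0)/mV 12 0 0 0 0 ch1"),
             file.path(dir, "p212.hea"))
  rec <- read_record(file.path(dir, "p212"))
  expect_equal(rec$fs, 360)
  expect_equal(rec$samples, vals / 200)
})

test_that("annotations round-trip including long gaps", {
  dir <- withr::local_tempdir()
  ann <- tibble::tibble(sample = c(10L, 500L, 5000L, 90000L),
                        symbol = c("N", "V", "N", "L"))
  path <- file.path(dir, "r.atr")
  write_wfdb_annotations(ann, path)
  back <- read_wfdb_annotations(path)
  expect_equal(back$sample, ann$sample)
  expect_equal(back$symbol, ann$symbol)
})

test_that("fixed windows follow the floor((N - W)/S) + 1 count", {
  rec <- function(n) shockscale:::new_signal_record(seq_len(n) * 0.001, 250)
  expect_equal(nrow(segment_fixed(rec(500), 2, 2)), 1)
  expect_length(segment_fixed(rec(500), 2, 2)$samples[[1]], 500)

  s <- segment_fixed(rec(1250), 2, 2)
  expect_equal(nrow(s), 2) # trailing 250 samples dropped
  expect_equal(s$samples[[2]], (501:1000) * 0.001)

  expect_equal(nrow(segment_fixed(rec(499), 2, 2)), 0)
  expect_message(segment_fixed(rec(100), 2, 2), "longer than record")

  # overlapping stride
  expect_equal(nrow(segment_fixed(rec(1000), 2, 1)), 3)
})

test_that("fixed segmentation slices are contiguous and non-overlapping", {
  x <- stats::rnorm(1700)
  rec <- shockscale:::new_signal_record(x, 250)
  segs <- segment_fixed(rec, 2, 2)
  expect_equal(nrow(segs), 3)
  for (k in seq_len(nrow(segs))) {
    start <- (k - 1) * 500
    expect_identical(segs$samples[[k]], x[(start + 1):(start + 500)])
  }
  # partition: windows cover disjoint index ranges
  ranges <- lapply(seq_len(nrow(segs)), function(k) (k - 1) * 500 + 1:500)
  expect_equal(length(unique(unlist(ranges))), 1500)
})

test_that("annotation-centred windows place the beat at floor(W/2)", {
  fs <- 360
  n <- 2000
  x <- numeric(n)
  centers <- c(10L, 400L, 1000L, 1600L, 1995L)
  x[centers + 1] <- 1 # impulses at the annotated samples (0-based)
  ann <- tibble::tibble(sample = centers, symbol = rep("N", 5))
  rec <- shockscale:::new_signal_record(x, fs, ann)

  expect_message(segs <- segment_around_annotations(rec, 0.6), "2 annotation")
  w <- round(0.6 * fs)
  expect_equal(w, 216)
  expect_equal(nrow(segs), 3) # indices 10 and 1995 underflow/overflow
  for (k in seq_len(nrow(segs))) {
    expect_length(segs$samples[[k]], 216)
    expect_equal(which(segs$samples[[k]] == 1) - 1, floor(w / 2))
  }
  expect_equal(segs$label, rep("N", 3))
})
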