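test_that("gru_step reproduces the gate equations in closed form", {
  u <- 1
  w0 <- matrix(0, 1, 2)
  s <- gru_step(w0, w0, w0, h_prev = 0.4, x = 0)
  expect_equal(s$z, 0.5)
  expect_equal(s$r, 0.5)
  expect_equal(s$h_tilde, 0)
  expect_equal(s$h, 0.2)

  # saturating update gate forwards the candidate state
  wbig <- matrix(1e3, 1, 2)
  withr::local_seed(1)
  w <- matrix(stats::rnorm(2), 1, 2)
  s2 <- gru_step(wbig, w, w, h_prev = 0.7, x = 0.3)
  expect_equal(s2$z, 1)
  expect_equal(s2$h, s2$h_tilde)
})

test_that("gru_step matches a scalar-by-scalar hand evaluation", {
  withr::local_seed(5)
  u <- 2; d <- 1
  Wz <- matrix(stats::rnorm(u * (u + d), sd = 0.5), u)
  Wr <- matrix(stats::rnorm(u * (u + d), sd = 0.5), u)
  W <- matrix(stats::rnorm(u * (u + d), sd = 0.5), u)
  h <- c(0.2, -0.4); x <- 0.8
  # scalar oracle, written independently of the vectorised code
  sg <- function(v) 1 / (1 + exp(-v))
  hx <- c(h[1], h[2], x)
  z1 <- sg(Wz[1, 1] * hx[1] + Wz[1, 2] * hx[2] + Wz[1, 3] * hx[3])
  z2 <- sg(Wz[2, 1] * hx[1] + Wz[2, 2] * hx[2] + Wz[2, 3] * hx[3])
  r1 <- sg(Wr[1, 1] * hx[1] + Wr[1, 2] * hx[2] + Wr[1, 3] * hx[3])
  r2 <- sg(Wr[2, 1] * hx[1] + Wr[2, 2] * hx[2] + Wr[2, 3] * hx[3])
  rh <- c(r1 * h[1], r2 * h[2], x)
  t1 <- tanh(W[1, 1] * rh[1] + W[1, 2] * rh[2] + W[1, 3] * rh[3])
  t2 <- tanh(W[2, 1] * rh[1] + W[2, 2] * rh[2] + W[2, 3] * rh[3])
  hn <- c((1 - z1) * h[1] + z1 * t1, (1 - z2) * h[2] + z2 * t2)

  got <- gru_step(Wz, Wr, W, h, x)
  expect_equal(got$z, c(z1, z2), tolerance = 1e-10)
  expect_equal(got$r, c(r1, r2), tolerance = 1e-10)
  expect_equal(got$h_tilde, c(t1, t2), tolerance = 1e-10)
  expect_equal(got$h, hn, tolerance = 1e-10)
})

test_that("the engine's GRU cell matches the reference with zero biases", {
  withr::local_seed(11)
  for (dims in list(c(4, 2), c(8, 3), c(128, 1))) {
    u <- dims[1]; d <- dims[2]
    Wz <- matrix(stats::rnorm(u * (u + d), sd = 0.3), u)
    Wr <- matrix(stats::rnorm(u * (u + d), sd = 0.3), u)
    W <- matrix(stats::rnorm(u * (u + d), sd = 0.3), u)
    h <- stats::rnorm(u, sd = 0.5)
    x <- stats::rnorm(d)
    ref <- gru_step(Wz, Wr, W, h, x)
    z0 <- numeric(u)
    eng <- shockscale:::cpp_gru_cell(Wz, Wr, W, z0, z0, z0, h, x, "float")
    expect_lt(max(abs(ref$h - eng$h)), 1e-5)
    expect_lt(max(abs(ref$z - eng$z)), 1e-5)
    expect_lt(max(abs(ref$r - eng$r)), 1e-5)
    expect_lt(max(abs(ref$h_tilde - eng$h_tilde)), 1e-5)
    engd <- shockscale:::cpp_gru_cell(Wz, Wr, W, z0, z0, z0, h, x, "double")
    expect_equal(ref$h, as.numeric(engd$h), tolerance = 1e-12)
  }
})

test_that("feature maps shrink 227 -> 113, 56, 28, 14, 7 under pooling", {
  cfg <- model_config(input_size = 227)
  sh <- model_shapes(cfg)
  pools <- sh$spatial[grepl("^pool", sh$layer)]
  expect_equal(pools, c(113, 56, 28, 14, 7))
  expect_equal(sh$spatial[sh$layer == "input"], 227)
})

test_that("parameter accounting matches the engine and the printed budget", {
  cfg <- model_config(input_size = 64)
  # independent arithmetic oracle for the default widths
  conv <- (9 * 3 + 1) * 16 + (9 * 16 + 1) * 32 + (9 * 32 + 1) * 64 +
    (9 * 64 + 1) * 64 + (9 * 64 + 1) * 128
  gru <- 3 * (128 * (128 + 1) + 128)
  dense <- (128 * 128 + 128) + (128 * 4 + 4)
  expect_equal(conv, 134368)
  expect_equal(gru, 49920)
  expect_equal(count_parameters(cfg), conv + gru + dense)
  expect_equal(count_parameters(cfg), 201316)
  expect_lte(count_parameters(cfg), 208000)

  # the engine's own report: element count of the initialised parameters
  for (variant in c("full", "cnn_only", "gru_only")) {
    vcfg <- model_config(input_size = 64, variant = variant)
    m <- build_model(vcfg, seed = 1)
    expect_equal(count_parameters(vcfg), sum(lengths(m$params)))
  }

  # monotonicity: wider conv stacks have strictly more parameters
  wide <- model_config(input_size = 64,
                       conv_filters = 2 * c(16, 32, 64, 64, 128))
  expect_gt(count_parameters(wide), count_parameters(cfg))

  # bias-free convention drops exactly the bias terms
  expect_equal(count_parameters(cfg) - count_parameters(cfg, biases = FALSE),
               16 + 32 + 64 + 64 + 128 + 3 * 128 + 128 + 4)
})

test_that("variants differ only in their processing blocks", {
  full <- build_model(model_config(input_size = 32), seed = 1)
  cnn <- build_model(model_config(input_size = 32, variant = "cnn_only"),
                     seed = 1)
  gru <- build_model(model_config(input_size = 32, variant = "gru_only"),
                     seed = 1)
  expect_true(all(c("Wz", "Wr", "Wh") %in% names(full$params)))
  expect_false(any(c("Wz", "Wr", "Wh") %in% names(cnn$params)))
  expect_false(any(grepl("^Wc", names(gru$params))))
  expect_setdiff <- setdiff(names(full$params), names(cnn$params))
  expect_equal(sort(expect_setdiff), sort(c("Wz", "Wr", "Wh",
                                            "bz", "br", "bh")))
  expect_error(model_config(input_size = 31), "at least 32")
})

test_that("softmax outputs are normalised and finite on extreme inputs", {
  withr::local_seed(3)
  for (variant in c("full", "cnn_only", "gru_only")) {
    m <- build_model(model_config(input_size = 32, variant = variant),
                     seed = 2)
    for (fill in list(0, 1)) {
      x <- array(fill, dim = c(32, 32, 3, 2))
      p <- predict_proba(m, x)
      expect_true(all(is.finite(p)))
      expect_equal(rowSums(p), c(1, 1), tolerance = 1e-6)
    }
    x <- array(stats::runif(32 * 32 * 3 * 3), dim = c(32, 32, 3, 3))
    p <- predict_proba(m, x)
    expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
    expect_equal(colnames(p), shock_classes)
  }
})

test_that("analytic gradients match finite differences (double engine)", {
  withr::local_seed(21)
  cfg <- model_config(input_size = 32, conv_filters = c(2, 3, 3, 4, 5),
                      gru_units = 4, dense_units = 6)
  m <- build_model(cfg, seed = 3)
  n <- 4
  x <- array(stats::runif(32 * 32 * 3 * n), dim = c(32, 32, 3, n))
  y <- 0:3
  lg <- shockscale:::cpp_loss_grad(m$params, unclass(cfg), x, y, "double")
  eps <- 1e-6
  for (nm in names(m$params)) {
    ks <- sample(length(m$params[[nm]]), min(3, length(m$params[[nm]])))
    for (k in ks) {
      p1 <- m$params; p1[[nm]][k] <- p1[[nm]][k] + eps
      p2 <- m$params; p2[[nm]][k] <- p2[[nm]][k] - eps
      fd <- (shockscale:::cpp_loss_grad(p1, unclass(cfg), x, y,
                                        "double")$loss -
             shockscale:::cpp_loss_grad(p2, unclass(cfg), x, y,
                                        "double")$loss) / (2 * eps)
      an <- lg$grads[[nm]][k]
      if (max(abs(fd), abs(an)) > 1e-6) {
        expect_lt(abs(fd - an) / max(abs(fd), abs(an)), 1e-4)
      }
    }
  }
})
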