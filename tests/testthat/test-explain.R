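# A model whose class probability is 1 exactly when one planted superpixel
# is left unperturbed, used as the recoverability oracle.
planted_model <- function(img_norm, map, planted) {
  region <- unclass(map) == planted
  function(arr) {
    n <- dim(arr)[4]
    p <- vapply(seq_len(n), function(i) {
      as.numeric(all(arr[, , , i][region] == img_norm[region]))
    }, numeric(1))
    matrix(p, n, 1, dimnames = list(NULL, "C1"))
  }
}

test_that("grid segmentation partitions the image", {
  sp <- segment_grid(227, 227, block = 32)
  expect_equal(attr(sp, "S"), 64) # ceiling(227/32)^2
  expect_equal(dim(sp), c(227, 227))
  expect_equal(sort(unique(as.vector(sp))), 0:63)
  # edge blocks are smaller but present
  expect_equal(sum(sp == 63), 3 * 3)
  expect_equal(sum(sp == 0), 32 * 32)

  one <- segment_grid(40, 30, block = 50)
  expect_equal(attr(one, "S"), 1)
  expect_true(all(one == 0))

  img <- array(0L, c(64, 48, 3))
  auto <- segment_grid(img, block = 16)
  expect_equal(attr(auto, "S"), 4 * 3)
})

test_that("the planted superpixel receives the largest positive weight", {
  cfg <- synth_config(seed = 15)
  img <- render_scalogram(cwt(generate_fragment("C3", cfg, 0)$samples[[1]],
                              cfg$fs), size = 64)
  map <- segment_grid(64, 64, block = 16) # 16 superpixels
  model <- planted_model(normalize_for_model(img), map, planted = 5L)
  ex <- explain_prediction(img, model, "C1", map = map, n = 300, seed = 4)
  expect_equal(nrow(ex), 16)
  expect_equal(ex$superpixel[which.max(ex$weight)], 5L)
  expect_gt(max(ex$weight), 0)
  expect_equal(top_superpixels(ex, 1)$superpixel, 5L)
})

test_that("a constant model yields (near) zero weights", {
  img <- array(128L, c(32, 32, 3))
  const <- function(arr) matrix(0.7, dim(arr)[4], 1,
                                dimnames = list(NULL, "C1"))
  ex <- explain_prediction(img, const, "C1", block = 8, n = 200, seed = 2)
  expect_lt(max(abs(ex$weight)), 1e-8)
})

test_that("explanations are reproducible under a fixed seed", {
  cfg <- synth_config(seed = 20)
  img <- render_scalogram(cwt(generate_fragment("C1", cfg, 1)$samples[[1]],
                              cfg$fs), size = 32)
  map <- segment_grid(32, 32, block = 8)
  model <- planted_model(normalize_for_model(img), map, planted = 3L)
  a <- explain_prediction(img, model, "C1", map = map, n = 150, seed = 7)
  b <- explain_prediction(img, model, "C1", map = map, n = 150, seed = 7)
  expect_identical(a$weight, b$weight)
  c2 <- explain_prediction(img, model, "C1", map = map, n = 150, seed = 8)
  expect_false(identical(a$weight, c2$weight))
})

test_that("weights follow a relabelling of the superpixel map", {
  cfg <- synth_config(seed = 25)
  img <- render_scalogram(cwt(generate_fragment("C4", cfg, 2)$samples[[1]],
                              cfg$fs), size = 32)
  map <- segment_grid(32, 32, block = 8) # 16 superpixels
  s <- attr(map, "S")
  perm <- c(s:1) - 1L # reverse labels
  pmap <- structure(matrix(perm[unclass(map) + 1L], 32, 32), S = s,
                    class = "superpixel_map")
  planted_spatial <- 6L
  model <- planted_model(normalize_for_model(img), map, planted_spatial)
  ex1 <- explain_prediction(img, model, "C1", map = map, n = 400, seed = 3)
  ex2 <- explain_prediction(img, model, "C1", map = pmap, n = 400, seed = 3)
  expect_equal(ex1$superpixel[which.max(ex1$weight)], planted_spatial)
  expect_equal(ex2$superpixel[which.max(ex2$weight)],
               perm[planted_spatial + 1L])
})

test_that("degenerate perturbation draws and small n are flagged", {
  img <- array(0L, c(16, 16, 3))
  const <- function(arr) matrix(1, dim(arr)[4], 1,
                                dimnames = list(NULL, "C1"))
  expect_warning(
    explain_prediction(img, const, "C1", block = 4, n = 10, seed = 1),
    "consider n >= S"
  )
  expect_error(
    suppressWarnings(explain_prediction(img, const, "C1", block = 16, n = 1,
                                        seed = 1)),
    "increase n"
  )
})

test_that("explaining a trained classifier runs end to end", {
  sc <- make_tiny_scalograms(8)
  m <- build_model(model_config(input_size = 32), seed = 1)
  fit <- train_model(m, sc, sc[seq(1, 32, by = 4), ],
                     train_config(epochs = 2, seed = 2))
  ex <- explain_prediction(sc$image[[1]], fit, "C1", block = 8, n = 100,
                           seed = 5)
  expect_equal(nrow(ex), 16)
  expect_true(all(is.finite(ex$weight)))
})
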