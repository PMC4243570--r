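test_that("the stock architecture has the documented 19 x 19 x 7 decision patch", {
  spec <- rgc_network_spec()
  expect_identical(receptive_field(spec), c(19L, 19L, 7L))
  expect_equal(receptive_field(spec) * c(0.4, 0.4, 0.5), c(7.6, 7.6, 3.5))
})

test_that("receptive-field arithmetic handles edge specs and rejects even filters", {
  expect_identical(receptive_field(network_spec(list(c(1, 1, 1)), 1)),
                   c(1L, 1L, 1L))
  expect_identical(receptive_field(network_spec(list(c(3, 3, 3), c(3, 3, 3)),
                                                c(2, 1))),
                   c(5L, 5L, 5L))
  expect_error(network_spec(list(c(4, 3, 3)), 1), "odd")
})

# measure the output support of an impulse probe against a zero baseline
impulse_support <- function(spec, seed, n = NULL) {
  rf <- receptive_field(spec)
  if (is.null(n)) n <- rf + 6L
  w <- random_weights(spec, seed = seed)
  g <- voxel_grid(n, c(1, 1, 1))
  zero <- image_stack(array(0, n), g)
  delta <- array(0, n)
  mid <- (n + 1L) %/% 2L
  delta[mid[1], mid[2], mid[3]] <- 1
  d0 <- forward(spec, w, zero)$values
  d1 <- forward(spec, w, image_stack(delta, g))$values
  moved <- which(abs(d1 - d0) > 1e-12, arr.ind = TRUE)
  apply(moved, 2, function(v) diff(range(v)) + 1L)
}

test_that("receptive field equals the measured impulse support on random specs", {
  set.seed(20)
  for (rep in 1:20) {
    nl <- sample(1:3, 1)
    filters <- replicate(nl, sample(c(1L, 3L, 5L), 3, replace = TRUE),
                         simplify = FALSE)
    features <- c(sample(1:3, max(nl - 1, 0), replace = TRUE), 1L)
    spec <- network_spec(filters, features)
    expect_equal(as.integer(impulse_support(spec, seed = rep)),
                 as.integer(receptive_field(spec)))
  }
})

test_that("the stock spec's impulse support is 19 x 19 x 7", {
  # thin two-feature stand-in with the stock filter sizes keeps this fast
  spec <- network_spec(rgc_network_spec()$filters, c(2, 2, 2, 2, 2, 2, 2, 1))
  expect_equal(as.integer(impulse_support(spec, seed = 7)), c(19L, 19L, 7L))
})

test_that("forward pass has the documented closed-form special cases", {
  g <- voxel_grid(c(6, 5, 4), c(1, 1, 1))
  set.seed(2)
  x <- array(runif(prod(g$shape)), g$shape)
  stk <- image_stack(x, g)

  spec1 <- network_spec(list(c(3, 3, 3), c(1, 1, 1)), c(4, 1))
  w0 <- random_weights(spec1, seed = 1, sd = 0)
  out0 <- forward(spec1, w0, stk)
  expect_true(all(abs(out0$values - 0.5) < 1e-12))   # sigmoid(0) everywhere

  ident <- network_spec(list(c(1, 1, 1)), 1)
  wi <- list(list(w = array(1, c(1, 1, 1, 1, 1)), b = 0))
  expect_equal(forward(ident, wi, stk)$values, 1 / (1 + exp(-x)),
               tolerance = 1e-12)
})

test_that("forward is translation-equivariant away from borders", {
  spec <- network_spec(list(c(3, 3, 1), c(3, 1, 3)), c(2, 1))
  w <- random_weights(spec, seed = 9)
  g <- voxel_grid(c(20, 14, 12), c(1, 1, 1))
  set.seed(11)
  x <- array(0, g$shape)
  x[7:9, 6:8, 5:7] <- runif(27)
  y1 <- forward(spec, w, image_stack(x, g))$values
  sh <- c(3L, 2L, 1L)
  x2 <- array(0, g$shape)
  x2[7:9 + sh[1], 6:8 + sh[2], 5:7 + sh[3]] <- x[7:9, 6:8, 5:7]
  y2 <- forward(spec, w, image_stack(x2, g))$values
  interior <- y1[6:12, 5:9, 4:8]
  shifted <- y2[6:12 + sh[1], 5:9 + sh[2], 4:8 + sh[3]]
  expect_equal(shifted, interior, tolerance = 1e-10)
})

test_that("forward validates weights and input range", {
  spec <- network_spec(list(c(3, 3, 3)), 1)
  w <- random_weights(spec, 1)
  g <- voxel_grid(c(5, 5, 5), c(1, 1, 1))
  big <- image_stack(array(2, c(5, 5, 5)), g)
  expect_error(forward(spec, w, big), "normalized")
  wrong <- list(list(w = array(0, c(3, 3, 3, 1, 2)), b = c(0, 0)))
  expect_error(forward(spec, wrong, image_stack(array(0.5, c(5, 5, 5)), g)),
               "mismatch")
})

test_that("threshold binarization cuts at the documented level and nests", {
  g <- voxel_grid(c(4, 4, 4), c(1, 1, 1))
  set.seed(5)
  x <- array(runif(64) * 200, c(4, 4, 4))
  x[2, 2, 2] <- 200
  stk <- image_stack(x, g)
  m6 <- threshold_binarize(stk, 0.6)
  expect_identical(m6$mask, x >= 120)
  m10 <- threshold_binarize(stk, 1.0)
  expect_identical(which(m10$mask), which(x == max(x)))
  m3 <- threshold_binarize(stk, 0.3)
  expect_true(all(m3$mask >= m6$mask))   # lower cut keeps a superset
  expect_error(threshold_binarize(image_stack(array(0, c(4, 4, 4)), g), 0.6),
               "all-zero")
})
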