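# Brute-force simple-point oracle: embed the 3x3x3 patch in a 5x5x5 volume
# padded with background, flip the centre, and compare the global topology
# summaries. This goes through the global labeling/Euler path, independent of
# the local topological-number characterization being tested.
brute_simple <- function(patch) {
  vol <- array(FALSE, c(5, 5, 5))
  vol[2:4, 2:4, 2:4] <- patch
  a <- vol
  b <- vol
  b[3, 3, 3] <- !b[3, 3, 3]
  identical(topology_summary(a), topology_summary(b))
}

test_that("simple-point decisions match the textbook cases", {
  endpoint <- array(FALSE, c(3, 3, 3))
  endpoint[2, 2, 2] <- TRUE; endpoint[1, 2, 2] <- TRUE
  expect_true(is_simple_point(endpoint))

  isolated <- array(FALSE, c(3, 3, 3))
  isolated[2, 2, 2] <- TRUE
  expect_false(is_simple_point(isolated))

  bridge <- array(FALSE, c(3, 3, 3))
  bridge[2, 2, 2] <- TRUE; bridge[1, 2, 2] <- TRUE; bridge[3, 2, 2] <- TRUE
  expect_false(is_simple_point(bridge))
  expect_false(brute_simple(bridge))
})

test_that("simple-point test agrees exactly with the brute-force oracle", {
  set.seed(101)
  n <- 2000   # the full 1e5-patch sweep runs in the acceptance suite
  dens <- runif(n)
  patches <- matrix(runif(n * 27), n, 27) < dens   # density varies per patch
  got <- is_simple_point(1L * patches)
  want <- vapply(seq_len(n), function(r)
    brute_simple(array(patches[r, ], c(3, 3, 3))), logical(1))
  expect_identical(got, want)
})

test_that("topology summaries of canonical solids are correct", {
  expect_equal(topology_summary(array(FALSE, c(4, 4, 4))),
               list(components = 0L, cavities = 0L, euler = 0L))
  expect_equal(topology_summary(array(TRUE, c(3, 3, 3))),
               list(components = 1L, cavities = 0L, euler = 1L))
  shell <- array(TRUE, c(5, 5, 5)); shell[2:4, 2:4, 2:4] <- FALSE
  expect_equal(topology_summary(shell),
               list(components = 1L, cavities = 1L, euler = 2L))
  # solid torus: tube of radius 3 around a circle of radius 10
  tor <- array(FALSE, c(31, 31, 11))
  ii <- which(!tor, arr.ind = TRUE)
  r <- sqrt((ii[, 1] - 16)^2 + (ii[, 2] - 16)^2)
  tor[ii[(r - 10)^2 + (ii[, 3] - 6)^2 <= 9, ]] <- TRUE
  expect_equal(topology_summary(tor),
               list(components = 1L, cavities = 0L, euler = 0L))
})

test_that("component counts agree with an independent R flood fill", {
  set.seed(3)
  m <- array(runif(12^3) < 0.25, c(12, 12, 12))
  expect_equal(topology_summary(m)$components,
               length(r_component_sizes(m, 26)))
})

make_ball_stack <- function(n = 15, r = 5, bright = 1000) {
  ii <- expand.grid(1:n, 1:n, 1:n)
  ball <- array(0, c(n, n, n))
  c0 <- (n + 1) / 2
  ball[as.matrix(ii)[rowSums(sweep(ii, 2, c0)^2) <= r^2, ]] <- bright
  image_stack(ball, voxel_grid(c(n, n, n), c(1, 1, 1)))
}

test_that("inflation targets exactly the 60%-of-max set and respects it", {
  raw <- make_ball_stack()
  raw$values[8, 8, 8] <- 1000
  tr <- array(FALSE, c(15, 15, 15)); tr[8, 8, 8] <- TRUE
  trace <- binary_volume(tr, raw$grid)
  out <- inflate_trace(raw, trace, max_radius = 62, threshold_frac = 0.6)
  target <- raw$values >= 0.6 * 1000
  expect_true(all(out$mask[tr]))                  # superset of trace
  expect_false(any(out$mask & !tr & !target))     # subset of trace | target
  expect_gte(sum(out$mask & target) / sum(target), 0.95)
  expect_equal(topology_summary(out), topology_summary(trace))
})

test_that("inflation is a no-op when the target equals the trace", {
  raw <- make_ball_stack()
  tr <- raw$values >= 600
  trace <- binary_volume(tr, raw$grid)
  out <- inflate_trace(raw, trace, max_radius = 10, threshold_frac = 0.6)
  expect_identical(out$mask, trace$mask)
})

test_that("inflation grows monotonically and is idempotent at convergence", {
  raw <- make_ball_stack()
  tr <- array(FALSE, c(15, 15, 15)); tr[8, 8, 8] <- TRUE
  trace <- binary_volume(tr, raw$grid)
  prev <- trace
  for (r in c(1, 2, 4, 8, 16)) {
    cur <- inflate_trace(raw, trace, max_radius = r)
    expect_true(all(cur$mask >= prev$mask))   # never shrinks across rounds
    prev <- cur
  }
  conv <- inflate_trace(raw, trace, max_radius = 40)
  again <- inflate_trace(raw, binary_volume(conv$mask, raw$grid), max_radius = 10)
  expect_identical(again$mask, conv$mask)
})

test_that("inflation preserves the trace topology on random trees", {
  # fast spot check; the 50-tree sweep runs in the acceptance suite
  for (seed in 1:5) {
    s <- random_tree_skeleton(n = 20, seed = seed)
    g <- voxel_grid(c(26, 26, 26), c(1, 1, 1))
    trace <- rasterize_skeleton(s, g)
    set.seed(seed + 500)
    raw <- image_stack(array(runif(26^3), c(26, 26, 26)), g)
    out <- inflate_trace(raw, trace, max_radius = 5, threshold_frac = 0.6)
    expect_equal(topology_summary(out), topology_summary(trace))
  }
})

test_that("inflation validates its inputs", {
  raw <- make_ball_stack()
  empty <- binary_volume(array(FALSE, c(15, 15, 15)), raw$grid)
  expect_error(inflate_trace(raw, empty), "nonempty")
  other <- binary_volume(array(TRUE, c(4, 4, 4)), voxel_grid(c(4, 4, 4)))
  expect_error(inflate_trace(raw, other), "grid")
  tr <- array(FALSE, c(15, 15, 15)); tr[8, 8, 8] <- TRUE
  expect_error(inflate_trace(raw, binary_volume(tr, raw$grid),
                             threshold_frac = 0), "threshold_frac")
})

test_that("absorbable diameter follows the single-layer growth arithmetic", {
  expect_equal(max_absorbable_diameter(62, 0.4), 50)
  expect_equal(max_absorbable_diameter(0, 0.4), 0.4)
  expect_equal(max_absorbable_diameter(10, 0.5), 10.5)
  expect_error(max_absorbable_diameter(-1, 0.4), ">= 0")
})

test_that("simulated growth covers the full axis diameter the formula promises", {
  # seed in the centre of a bright ball of radius 10 voxels; after 10 rounds
  # the axis-aligned diameter (21 voxels) is fully covered
  n <- 23
  raw <- make_ball_stack(n = n, r = 10)
  tr <- array(FALSE, c(n, n, n)); tr[12, 12, 12] <- TRUE
  out <- inflate_trace(raw, binary_volume(tr, raw$grid), max_radius = 10)
  expect_true(all(out$mask[2:22, 12, 12]))
  expect_true(all(out$mask[12, 2:22, 12]))
  expect_true(all(out$mask[12, 12, 2:22]))
})
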