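# two flat noiseless laminae rendered as single bright slices
flat_lamina_stack <- function(k_on = 21, k_off = 45, d = c(24, 24, 64)) {
  v <- array(0, d)
  v[, , k_on] <- 100
  v[, , k_off] <- 100
  image_stack(v, voxel_grid(d, c(0.4, 0.4, 0.5)), role = "fiducial")
}

test_that("flat noiseless laminae are detected at exact slice heights", {
  surf <- detect_surfaces(flat_lamina_stack())
  expect_equal(surf$on$label, "On")
  expect_true(all(abs(surf$on$heights - 20 * 0.5) < 1e-9))
  expect_true(all(abs(surf$off$heights - 44 * 0.5) < 1e-9))
  expect_true(all(surf$on$heights < surf$off$heights))
})

test_that("single-lamina input is a detection failure", {
  d <- c(24, 24, 64)
  v <- array(0, d)
  v[, , 30] <- 100
  stk <- image_stack(v, voxel_grid(d, c(0.4, 0.4, 0.5)), role = "fiducial")
  expect_error(detect_surfaces(stk), "detection failure")
})

test_that("wavy noisy laminae are recovered to sub-half-micron RMS", {
  ph <- make_phantom(small_phantom_spec(seed = 1))
  surf <- detect_surfaces(ph$chat)
  rms_on <- sqrt(mean((surf$on$heights - ph$truth$on$heights)^2))
  rms_off <- sqrt(mean((surf$off$heights - ph$truth$off$heights)^2))
  expect_lt(rms_on, 0.5)
  expect_lt(rms_off, 0.5)
})

planar_surface <- function(nx = 40, ny = 40, z = 10, pitch = c(1, 1, 1)) {
  surface(matrix(z, nx, ny), matrix(TRUE, nx, ny), "On",
          voxel_grid(c(nx, ny, 20), pitch))
}

test_that("a planar surface flattens with zero distortion (rigid motion)", {
  m <- flatten_lscm(planar_surface())
  expect_lt(m$total_energy, 1e-8)
  expect_equal(m$n_folded, 0L)
  # pairwise distances preserved: the map is a rigid motion of the plane
  pick <- c(1, 17, 300, 900, nrow(m$verts))
  d3 <- dist(m$verts[pick, 1:2])
  d2 <- dist(m$uv[pick, ])
  expect_equal(as.numeric(d2), as.numeric(d3), tolerance = 1e-8)
})

test_that("solver objective equals the direct conformal-energy evaluation", {
  # hemisphere-like cap z = sqrt(R^2 - r^2)
  nx <- 30
  g <- voxel_grid(c(nx, nx, 40), c(1, 1, 1))
  xv <- seq_len(nx) - (nx + 1) / 2
  r2 <- outer(xv^2, xv^2, "+")
  h <- sqrt(pmax(30^2 - r2, 0))
  s <- surface(h, matrix(TRUE, nx, nx), "On", g)
  m <- flatten_lscm(s)
  # direct evaluation from the definition, per triangle
  direct <- 0
  for (t in seq_len(nrow(m$tri))) {
    P <- m$verts[m$tri[t, ], ]
    e1 <- P[2, ] - P[1, ]; l1 <- sqrt(sum(e1^2)); e1 <- e1 / l1
    d3 <- P[3, ] - P[1, ]
    pr <- sum(d3 * e1)
    e2 <- d3 - pr * e1; l2 <- sqrt(sum(e2^2)); e2 <- e2 / l2
    x <- c(0, l1, pr); y <- c(0, 0, l2)
    A <- 0.5 * l1 * l2
    Wr <- c(x[3] - x[2], x[1] - x[3], x[2] - x[1]) / sqrt(2 * A)
    Wi <- c(y[3] - y[2], y[1] - y[3], y[2] - y[1]) / sqrt(2 * A)
    u <- m$uv[m$tri[t, ], 1]; v <- m$uv[m$tri[t, ], 2]
    direct <- direct + (sum(Wr * u) - sum(Wi * v))^2 +
                       (sum(Wi * u) + sum(Wr * v))^2
  }
  expect_equal(m$total_energy, direct, tolerance = 1e-10)
  expect_equal(m$total_energy, sum(m$energy), tolerance = 1e-12)
})

sinusoid_surface <- function(nx = 120, ny = 120, amp = 4, wl = 100,
                             pitch = c(1, 1, 1)) {
  xv <- (seq_len(nx) - 1) * pitch[1]
  h <- outer(amp * sin(2 * pi * xv / wl), rep(1, ny)) + 20
  surface(h, matrix(TRUE, nx, ny), "On",
          voxel_grid(c(nx, ny, 60), pitch))
}

tri_angles <- function(P) {
  a <- sqrt(sum((P[2, ] - P[3, ])^2))
  b <- sqrt(sum((P[1, ] - P[3, ])^2))
  cc <- sqrt(sum((P[1, ] - P[2, ])^2))
  acos(pmin(pmax(c((b^2 + cc^2 - a^2) / (2 * b * cc),
                   (a^2 + cc^2 - b^2) / (2 * a * cc),
                   (a^2 + b^2 - cc^2) / (2 * a * b)), -1), 1))
}

test_that("sinusoidal lamina flattens with small angle distortion, no folds", {
  m <- flatten_lscm(sinusoid_surface())
  expect_equal(m$n_folded, 0L)
  worst <- 0
  for (t in seq_len(nrow(m$tri))) {
    a3 <- tri_angles(m$verts[m$tri[t, ], ])
    a2 <- tri_angles(cbind(m$uv[m$tri[t, ], ], 0))
    worst <- max(worst, max(abs(a3 - a2)))
  }
  expect_lt(worst * 180 / pi, 5)
})

test_that("registration of flat surfaces anchors at the domain centre and is idempotent", {
  g <- voxel_grid(c(40, 40, 30), c(1, 1, 1))
  on <- surface(matrix(10, 40, 40), matrix(TRUE, 40, 40), "On", g)
  off <- surface(matrix(22, 40, 40), matrix(TRUE, 40, 40), "Off", g)
  mon <- flatten_lscm(on); moff <- flatten_lscm(off)
  reg <- register_inplane(mon, moff, on, off, window_um = 16)
  # globally flat: tie rule picks the smallest (x, y) window
  expect_equal(reg$anchor, c(8, 8))
  moff2 <- apply_offset(moff, reg$offset)
  reg2 <- register_inplane(mon, moff2, on, off, window_um = 16)
  expect_equal(reg2$offset, c(0, 0), tolerance = 1e-9)
  expect_error(register_inplane(mon, moff, on, off, window_um = 100),
               "window larger")
})

test_that("registration finds a deliberately flat pocket", {
  nx <- 100
  g <- voxel_grid(c(nx, nx, 60), c(1, 1, 1))
  xv <- seq_len(nx) - 1
  rough <- outer(3 * sin(2 * pi * xv / 23), 1 + 0.5 * cos(2 * pi * xv / 31))
  # flatten a 40 um pocket around (70, 30)
  w <- outer(exp(-((xv - 70) / 18)^2), exp(-((xv - 30) / 18)^2))
  h <- 15 + rough * (1 - pmin(w * 4, 1))
  on <- surface(h, matrix(TRUE, nx, nx), "On", g)
  off <- surface(h + 12, matrix(TRUE, nx, nx), "Off", g)
  mon <- flatten_lscm(on); moff <- flatten_lscm(off)
  reg <- register_inplane(mon, moff, on, off, window_um = 40)
  expect_lt(max(abs(reg$anchor - c(70, 30))), 20)   # within one stride
})

test_that("the identity case yields unit weights and (u, v) a rigid motion of (x, y)", {
  g <- voxel_grid(c(48, 48, 40), c(1, 1, 1))
  on <- surface(matrix(10, 48, 48), matrix(TRUE, 48, 48), "On", g)
  off <- surface(matrix(22, 48, 48), matrix(TRUE, 48, 48), "Off", g)
  mon <- flatten_lscm(on); moff <- flatten_lscm(off)
  reg <- register_inplane(mon, moff, on, off, window_um = 20)
  moff <- apply_offset(moff, reg$offset)
  wf <- build_warp(mon, moff, on, off, g, fit_radius_um = 12,
                   control_spacing_um = 4, sample_spacing_um = 2)
  set.seed(4)
  ijk <- cbind(sample(5:44, 60, TRUE), sample(5:44, 60, TRUE),
               sample(2:39, 60, TRUE))
  pts <- warp_points(wf, ijk)
  expect_true(all(abs(pts$weight - 1) < 1e-6))
  xyz <- index_to_um(g, ijk)
  # rigid in-plane: distances preserved
  d_in <- dist(xyz[1:20, 1:2])
  d_uv <- dist(cbind(pts$u, pts$v)[1:20, ])
  expect_equal(as.numeric(d_uv), as.numeric(d_in), tolerance = 1e-6)
  # depth: On at 10 -> 0, Off at 22 -> 12, linear between and beyond
  expect_equal(pts$depth_um, xyz[, 3] - 10, tolerance = 1e-9)
})

test_that("surfaces map to their nominal depths and depth increases along z", {
  ph <- make_phantom(small_phantom_spec(seed = 3))
  surf <- detect_surfaces(ph$chat)
  mon <- flatten_lscm(surf$on); moff <- flatten_lscm(surf$off)
  reg <- register_inplane(mon, moff, surf$on, surf$off, 24)
  moff <- apply_offset(moff, reg$offset)
  g <- ph$neuron$grid
  wf <- build_warp(mon, moff, surf$on, surf$off, g)
  # voxels nearest the detected surfaces land at 0 / 12 um (within fit tol)
  nx <- g$shape[1]; ny <- g$shape[2]
  cols <- cbind(rep(seq(4, nx - 3, by = 7), times = 14),
                rep(seq(4, ny - 3, by = 7), each = 14))
  k_on <- round(surf$on$heights[cols] / g$pitch[3]) + 1
  k_off <- round(surf$off$heights[cols] / g$pitch[3]) + 1
  on_d <- warp_points(wf, cbind(cols, as.integer(k_on)))$depth_um
  off_d <- warp_points(wf, cbind(cols, as.integer(k_off)))$depth_um
  expect_lt(max(abs(on_d)), 0.3)
  expect_lt(max(abs(off_d - 12)), 0.3)
  # monotone depth along every sampled column
  for (r in c(1, 50, 100)) {
    ks <- 2:(g$shape[3] - 1)
    dcol <- warp_points(wf, cbind(cols[r, 1], cols[r, 2], ks))$depth_um
    expect_true(all(diff(dcol) > 0))
  }
  # midway voxel sits at 6 um
  k_mid <- round((surf$on$heights[cols] + surf$off$heights[cols]) / 2 /
                 g$pitch[3]) + 1
  mid_d <- warp_points(wf, cbind(cols, as.integer(k_mid)))$depth_um
  expect_lt(max(abs(mid_d - 6)), 0.4)
})
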