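# Independent oracles used across the suite: plain-R flood fill, enumerated
# ball morphology, nearest-bin histogram, random tree generator. These
# deliberately avoid the package's compiled code paths.

r_label3d <- function(mask, connectivity = 26) {
  d <- dim(mask)
  lab <- array(0L, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  cur <- 0L
  idx <- which(mask)
  for (s in idx) {
    if (lab[s]) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- ((v - 1L) %% d[1]) + 1L
      r <- (v - 1L) %/% d[1]
      j <- (r %% d[2]) + 1L
      k <- (r %/% d[2]) + 1L
      for (o in seq_len(nrow(offs))) {
        ii <- i + offs[o, 1]; jj <- j + offs[o, 2]; kk <- k + offs[o, 3]
        if (ii < 1 || jj < 1 || kk < 1 || ii > d[1] || jj > d[2] || kk > d[3])
          next
        w <- ii + d[1] * ((jj - 1L) + d[2] * (kk - 1L))
        if (mask[w] && !lab[w]) { lab[w] <- cur; queue <- c(queue, w) }
      }
    }
  }
  lab
}

r_component_sizes <- function(mask, connectivity = 26) {
  lab <- r_label3d(mask, connectivity)
  if (max(lab) == 0L) integer(0) else tabulate(lab)
}

# enumerated digital-ball offsets (voxel units)
ball_offsets <- function(r) {
  o <- as.matrix(expand.grid(-r:r, -r:r, -r:r))
  o[rowSums(o^2) <= r^2 + 1e-9, , drop = FALSE]
}

r_dilate_ball <- function(mask, r) {
  d <- dim(mask)
  out <- array(FALSE, d)
  offs <- ball_offsets(r)
  idx <- which(mask, arr.ind = TRUE)
  for (o in seq_len(nrow(offs))) {
    p <- sweep(idx, 2, offs[o, ], "+")
    ok <- p[, 1] >= 1 & p[, 2] >= 1 & p[, 3] >= 1 &
          p[, 1] <= d[1] & p[, 2] <= d[2] & p[, 3] <= d[3]
    out[p[ok, , drop = FALSE]] <- TRUE
  }
  out
}

r_erode_ball <- function(mask, r) !r_dilate_ball(!mask, r)

r_open_ball <- function(mask, r) r_dilate_ball(r_erode_ball(mask, r), r)

# nearest-bin weighted histogram on the standard profile grid
nearest_bin_hist <- function(depths, weights, bin = 0.5, support = c(-20, 25)) {
  centres <- seq(support[1], support[2], by = bin)
  j <- pmin(pmax(round((depths - support[1]) / bin) + 1, 1), length(centres))
  out <- numeric(length(centres))
  for (q in seq_along(j)) out[j[q]] <- out[j[q]] + weights[q]
  out
}

# random tree skeleton in um within a box, nodes ~`n`, step ~2 um
random_tree_skeleton <- function(n = 30, box = c(24, 24, 24), seed = 1) {
  set.seed(seed)
  pos <- matrix(box / 2, 1, 3)
  parent <- -1L
  while (nrow(pos) < n) {
    from <- sample.int(nrow(pos), 1)
    dir <- rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    p <- pos[from, ] + dir * runif(1, 1.5, 3)
    if (any(p < 2) || any(p > box - 2)) next
    pos <- rbind(pos, p)
    parent <- c(parent, from)
  }
  skeleton(data.frame(id = seq_len(nrow(pos)), type = 3L,
                      x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      radius = 0.5, parent = parent))
}

# random tree whose rasterization self-intersects only at shared skeleton
# nodes: new segments must stay >= 2 voxels away from already-drawn voxels
# (except near their attachment), so the digital image keeps tree homotopy
separated_tree_skeleton <- function(n_segments = 12, box = 40, seed = 1) {
  set.seed(seed)
  draw_line <- function(a, b) {
    steps <- max(abs(b - a))
    t(vapply(0:steps, function(t)
      ceiling(a + (b - a) * t / max(steps, 1) - 0.5 + 1e-9), numeric(3)))
  }
  nodes <- matrix(round(c(box / 2, box / 2, box / 2)), 1, 3)
  parent <- -1L
  drawn <- nodes
  tries <- 0
  while (nrow(nodes) < n_segments + 1 && tries < 500) {
    tries <- tries + 1
    from <- sample.int(nrow(nodes), 1)
    dir <- sample(c(-1, 0, 1), 3, replace = TRUE)
    if (all(dir == 0)) next
    b <- nodes[from, ] + dir * sample(4:8, 1)
    if (any(b < 3) || any(b > box - 2)) next
    seg <- draw_line(nodes[from, ], b)
    far <- seg[-1, , drop = FALSE]                 # skip the attachment voxel
    ok <- TRUE
    for (r in seq_len(nrow(far))) {
      dmin <- min(sqrt(rowSums(sweep(drawn, 2, far[r, ])^2)))
      near_attach <- sqrt(sum((far[r, ] - nodes[from, ])^2)) <= 1.5
      if (!near_attach && dmin < 2) { ok <- FALSE; break }
    }
    if (!ok) next
    nodes <- rbind(nodes, b)
    parent <- c(parent, from)
    drawn <- rbind(drawn, seg)
  }
  skeleton(data.frame(id = seq_len(nrow(nodes)), type = 3L,
                      x = nodes[, 1], y = nodes[, 2], z = nodes[, 3],
                      radius = 0.5, parent = parent))
}

# small stand-in phantom spec for fast laminar tests (64 x 64 x 60 grid)
small_phantom_spec <- function(type = "W3", seed = 1, ...) {
  phantom_spec(type, shape = c(96, 96, 100), warp_amplitude = 2,
               warp_wavelength = 60, arbor_nodes = 120, max_path = 25,
               seed = seed, ...)
}
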