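#' Fiducial surface: a laminar height map
#'
#' A starburst (ChAT) lamina represented as a height map `z(x, y)` in um over
#' the in-plane voxel lattice, with a validity mask marking columns where the
#' lamina was actually observed (invalid columns are filled by harmonic
#' interpolation). `label` distinguishes the On lamina (ganglion-cell side,
#' smaller z) from the Off lamina.
#'
#' @param heights nx x ny numeric matrix of z positions, um.
#' @param valid nx x ny logical matrix.
#' @param label `"On"` or `"Off"`.
#' @param grid the [voxel_grid()] of the source stack.
#' @return A `surface` object.
#' @export
surface <- function(heights, valid, label = c("On", "Off"), grid) {
  label <- match.arg(label)
  stopifnot(is.matrix(heights), is.matrix(valid),
            all(dim(heights) == dim(valid)))
  if (any(!is.finite(heights[valid])))
    stop("surface heights must be finite where valid")
  structure(list(heights = heights, valid = valid, label = label,
                 grid = grid), class = "surface")
}

#' @export
print.surface <- function(x, ...) {
  cat(sprintf("<surface [%s] %d x %d, %.1f%% valid, mean z %.2f um>\n",
              x$label, nrow(x$heights), ncol(x$heights),
              100 * mean(x$valid), mean(x$heights)))
  invisible(x)
}

#' Export a surface height map as a single-page float TIFF
#'
#' @param s a [surface()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_surface <- function(s, path) {
  stopifnot(inherits(s, "surface"))
  tiff::writeTIFF(t(s$heights), path, bits.per.sample = 32L)
  invisible(path)
}

#' Detect the two starburst laminae in a fiducial stack
#'
#' Per (x, y) column of the Gaussian-smoothed stack, the two strongest
#' intensity peaks along z (with 3-point parabolic sub-voxel refinement)
#' become the On/Off height samples; by convention the smaller-z lamina is
#' On (ganglion-cell side). Height samples farther than `mad_mult`
#' median-absolute-deviations from a 5 x 5 median-filtered height map are
#' invalidated, and gaps are filled by harmonic interpolation over the valid
#' mask.
#'
#' @param chat fiducial-channel [image_stack()] with two dominant laminae.
#' @param smooth_sigma Gaussian smoothing sigma in voxels (all axes).
#' @param min_sep_um minimum peak separation along z, um.
#' @param mad_mult outlier rejection multiplier.
#' @return A list `(on, off)` of [surface()] objects.
#' @export
detect_surfaces <- function(chat, smooth_sigma = 1, min_sep_um = 3,
                            mad_mult = 3) {
  stopifnot(inherits(chat, "image_stack"))
  d <- dim(chat$values)
  g <- chat$grid
  sm <- cpp_gauss_blur(as.numeric(chat$values), d, rep(smooth_sigma, 3))
  pk <- cpp_column_peaks(sm, d, max(1L, as.integer(ceiling(min_sep_um / g$pitch[3]))))
  has2 <- is.finite(pk$z1) & is.finite(pk$z2)
  if (mean(has2) < 0.5)
    stop("surface detection failure: fewer than 2 peaks in more than 50% of columns")
  lo <- pmin(pk$z1, pk$z2)
  hi <- pmax(pk$z1, pk$z2)
  make_surf <- function(hslice, label) {
    h <- g$origin[3] + hslice * g$pitch[3]
    valid <- is.finite(h) & has2
    h[!valid] <- NA_real_
    med <- cpp_medfilt2(h, 2L)
    resid <- abs(h - med)
    madv <- median(resid[valid], na.rm = TRUE)
    if (is.finite(madv) && madv > 0)
      valid <- valid & !is.na(resid) & resid <= mad_mult * madv
    h[!valid] <- NA_real_
    h <- harmonic_fill(h, valid)
    surface(h, valid, label, g)
  }
  list(on = make_surf(lo, "On"), off = make_surf(hi, "Off"))
}

# Fill NA nodes of a height map by solving the Laplace equation with the
# valid nodes as Dirichlet data (4-neighbour graph, natural boundary).
harmonic_fill <- function(h, valid) {
  if (all(valid)) return(h)
  if (!any(valid)) stop("cannot fill a fully invalid height map")
  nx <- nrow(h); ny <- ncol(h)
  unk <- which(!valid)
  id <- matrix(0L, nx, ny)
  id[unk] <- seq_along(unk)
  ii <- ((unk - 1L) %% nx) + 1L
  jj <- ((unk - 1L) %/% nx) + 1L
  ti <- tj <- tv <- integer(0)
  b <- numeric(length(unk))
  deg <- numeric(length(unk))
  ti <- c(); tj <- c(); tv <- c()
  for (o in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    ni <- ii + o[1]; nj <- jj + o[2]
    inb <- ni >= 1L & ni <= nx & nj >= 1L & nj <= ny
    w <- which(inb)
    nidx <- (nj[w] - 1L) * nx + ni[w]
    deg[w] <- deg[w] + 1
    isval <- valid[nidx]
    b[w[isval]] <- b[w[isval]] + h[nidx[isval]]
    wu <- w[!isval]
    ti <- c(ti, wu)
    tj <- c(tj, id[nidx[!isval]])
    tv <- c(tv, rep(-1, length(wu)))
  }
  A <- Matrix::sparseMatrix(i = c(seq_along(unk), ti), j = c(seq_along(unk), tj),
                            x = c(deg, tv),
                            dims = c(length(unk), length(unk)))
  sol <- as.numeric(Matrix::solve(A, b))
  h[unk] <- sol
  h
}

#' Least-squares conformal flattening of a surface
#'
#' Triangulates the (downsampled) height map and computes the
#' least-squares conformal parameterization: planar coordinates `(u, v)` per
#' vertex minimizing the summed per-triangle conformal energy, which
#' maximally preserves local angles. The gauge is fixed by pinning two
#' mutually distant boundary vertices at their 3-D separation, and the
#' orientation so that planar triangle areas are positive.
#'
#' @param s a [surface()]; the valid region must be connected.
#' @param max_vertices mesh vertex budget before the sparse solve.
#' @return A `conformal_map`: mesh vertices (um), triangles, planar `uv`
#'   coordinates (um), per-triangle conformal energy `energy` and its sum
#'   `total_energy`, and the count of non-positively oriented (folded)
#'   triangles `n_folded`.
#' @export
flatten_lscm <- function(s, max_vertices = 1e4) {
  stopifnot(inherits(s, "surface"))
  nx <- nrow(s$heights); ny <- ncol(s$heights)
  # isolated outlier-rejected nodes are fine (harmonic fill bridges them), but
  # a genuinely fragmented observation domain is not
  if (any(s$valid)) {
    lab <- cpp_label3d(as.logical(s$valid), c(nx, ny, 1L), 6L)
    if (max(lab) > 1L && max(tabulate(lab)) < 0.95 * sum(s$valid))
      stop("usage error: the valid region of the surface is disconnected")
  }
  g <- s$grid
  step <- max(1L, as.integer(ceiling(sqrt(nx * ny / max_vertices))))
  xi <- unique(c(seq(1L, nx, by = step), nx))
  yi <- unique(c(seq(1L, ny, by = step), ny))
  nxi <- length(xi); nyi <- length(yi)
  xu <- g$origin[1] + (xi - 1) * g$pitch[1]
  yu <- g$origin[2] + (yi - 1) * g$pitch[2]
  V <- cbind(rep(xu, times = nyi), rep(yu, each = nxi),
             as.numeric(s$heights[xi, yi]))
  vid <- matrix(seq_len(nxi * nyi), nxi, nyi)
  # two triangles per quad
  q1 <- as.vector(vid[-nxi, -nyi]); q2 <- as.vector(vid[-1, -nyi])
  q3 <- as.vector(vid[-1, -1]);     q4 <- as.vector(vid[-nxi, -1])
  tri <- rbind(cbind(q1, q2, q3), cbind(q1, q3, q4))
  nT <- nrow(tri); nV <- nrow(V)

  # local orthonormal 2-D frames per triangle
  p1 <- V[tri[, 1], , drop = FALSE]
  p2 <- V[tri[, 2], , drop = FALSE]
  p3 <- V[tri[, 3], , drop = FALSE]
  e1 <- p2 - p1
  l1 <- sqrt(rowSums(e1^2)); e1 <- e1 / l1
  d3 <- p3 - p1
  proj <- rowSums(d3 * e1)
  e2 <- d3 - proj * e1
  l2 <- sqrt(rowSums(e2^2))
  if (any(l2 < 1e-12)) stop("degenerate triangle in surface mesh")
  e2 <- e2 / l2
  # local planar coords: P1 = (0,0), P2 = (l1, 0), P3 = (proj, l2)
  x1 <- 0; y1 <- 0; x2 <- l1; y2 <- 0; x3 <- proj; y3 <- l2
  area <- 0.5 * (l1 * l2)
  sc <- 1 / sqrt(2 * area)
  # complex gradient coefficients W_j = (x_{j+2} - x_{j+1}) + i (y_{j+2} - y_{j+1})
  Wr <- cbind(x3 - x2, x1 - x3, x2 - x1) * sc
  Wi <- cbind(y3 - y2, y1 - y3, y2 - y1) * sc

  # pin two mutually distant boundary vertices (opposite lattice corners)
  pinA <- vid[1, 1]; pinB <- vid[nxi, nyi]
  pinD <- sqrt(sum((V[pinA, ] - V[pinB, ])^2))
  pin_u <- c(0, pinD); pin_v <- c(0, 0)
  free <- setdiff(seq_len(nV), c(pinA, pinB))
  colof <- integer(nV); colof[free] <- seq_along(free)
  nF <- length(free)

  # rows: real and imaginary residual per triangle; unknowns: (u_free, v_free)
  rows <- rep(seq_len(nT), 3L)
  verts <- as.vector(tri)
  wr <- as.vector(Wr); wi <- as.vector(Wi)
  isfree <- colof[verts] > 0L
  # A entries: real row: wr*u - wi*v ; imag row: wi*u + wr*v
  iA <- c(rows[isfree],            rows[isfree],
          rows[isfree] + nT,       rows[isfree] + nT)
  jA <- c(colof[verts[isfree]],    colof[verts[isfree]] + nF,
          colof[verts[isfree]],    colof[verts[isfree]] + nF)
  xA <- c(wr[isfree],             -wi[isfree],
          wi[isfree],              wr[isfree])
  A <- Matrix::sparseMatrix(i = iA, j = jA, x = xA, dims = c(2L * nT, 2L * nF))
  b <- numeric(2L * nT)
  pin_idx <- !isfree
  pv <- verts[pin_idx]
  pu_val <- ifelse(pv == pinA, pin_u[1], pin_u[2])
  pv_val <- ifelse(pv == pinA, pin_v[1], pin_v[2])
  rr <- rows[pin_idx]
  for (t in seq_along(pv)) {
    b[rr[t]]      <- b[rr[t]]      - (wr[pin_idx][t] * pu_val[t] - wi[pin_idx][t] * pv_val[t])
    b[rr[t] + nT] <- b[rr[t] + nT] - (wi[pin_idx][t] * pu_val[t] + wr[pin_idx][t] * pv_val[t])
  }
  M <- Matrix::crossprod(A)
  rhs <- Matrix::crossprod(A, b)
  sol <- as.numeric(Matrix::solve(M, rhs))
  u <- numeric(nV); v <- numeric(nV)
  u[free] <- sol[seq_len(nF)]; v[free] <- sol[nF + seq_len(nF)]
  u[c(pinA, pinB)] <- pin_u; v[c(pinA, pinB)] <- pin_v

  sa <- 0.5 * ((u[tri[, 2]] - u[tri[, 1]]) * (v[tri[, 3]] - v[tri[, 1]]) -
               (u[tri[, 3]] - u[tri[, 1]]) * (v[tri[, 2]] - v[tri[, 1]]))
  if (sum(sa) < 0) { v <- -v; sa <- -sa }

  # per-triangle conformal energy from the solved coordinates
  er <- rowSums(Wr * cbind(u[tri[, 1]], u[tri[, 2]], u[tri[, 3]])) -
        rowSums(Wi * cbind(v[tri[, 1]], v[tri[, 2]], v[tri[, 3]]))
  ei <- rowSums(Wi * cbind(u[tri[, 1]], u[tri[, 2]], u[tri[, 3]])) +
        rowSums(Wr * cbind(v[tri[, 1]], v[tri[, 2]], v[tri[, 3]]))
  energy <- er^2 + ei^2

  structure(list(xi = xi, yi = yi, x_um = xu, y_um = yu,
                 verts = V, tri = tri, uv = cbind(u, v),
                 u_grid = matrix(u, nxi, nyi), v_grid = matrix(v, nxi, nyi),
                 energy = energy, total_energy = sum(energy),
                 n_folded = sum(sa <= 0), label = s$label, grid = g),
            class = "conformal_map")
}

#' @export
print.conformal_map <- function(x, ...) {
  cat(sprintf("<conformal_map [%s] %d vertices, %d triangles, energy %.3g, %d folded>\n",
              x$label, nrow(x$verts), nrow(x$tri), x$total_energy, x$n_folded))
  invisible(x)
}

# bilinear interpolation of per-vertex planar coords at physical (x, y)
map_uv <- function(map, xy) {
  xy <- rbind(xy)
  bilin2(map$u_grid, map$v_grid, map$x_um, map$y_um, xy[, 1], xy[, 2])
}

bilin2 <- function(fu, fv, xc, yc, x, y) {
  ix <- findInterval(x, xc, all.inside = TRUE)
  iy <- findInterval(y, yc, all.inside = TRUE)
  tx <- (x - xc[ix]) / (xc[ix + 1] - xc[ix])
  ty <- (y - yc[iy]) / (yc[iy + 1] - yc[iy])
  tx <- pmin(pmax(tx, 0), 1); ty <- pmin(pmax(ty, 0), 1)
  g <- function(f) {
    f[cbind(ix, iy)] * (1 - tx) * (1 - ty) +
      f[cbind(ix + 1, iy)] * tx * (1 - ty) +
      f[cbind(ix, iy + 1)] * (1 - tx) * ty +
      f[cbind(ix + 1, iy + 1)] * tx * ty
  }
  cbind(g(fu), g(fv))
}

bilin1 <- function(f, xc, yc, x, y) bilin2(f, f, xc, yc, x, y)[, 1]

#' In-plane registration of the two flattened laminae
#'
#' Scans square windows (side `window_um`, stride half a window) over the
#' in-plane domain; the flatness of a window is the sum over both surfaces of
#' the height variance inside it, and the minimizing window (ties broken
#' toward the smallest (x, y)) anchors the registration. The returned offset
#' `(du, dv)`, added to the Off map's planar coordinates, makes the two
#' flattened images of the anchor centre coincide.
#'
#' @param on_map,off_map [flatten_lscm()] maps of the two surfaces of one
#'   stack.
#' @param on,off the corresponding [surface()] objects.
#' @param window_um anchor window side, um.
#' @return A list: `offset` = c(du, dv) um, `anchor` = c(x, y) um of the
#'   chosen window centre.
#' @export
register_inplane <- function(on_map, off_map, on, off, window_um = 32) {
  stopifnot(inherits(on_map, "conformal_map"), inherits(off_map, "conformal_map"))
  g <- on$grid
  nx <- nrow(on$heights); ny <- ncol(on$heights)
  ext <- (c(nx, ny) - 1) * g$pitch[1:2]
  if (window_um > min(ext))
    stop("usage error: flatness window larger than the valid region")
  stride <- window_um / 2
  x0 <- seq(0, ext[1] - window_um, by = stride)
  y0 <- seq(0, ext[2] - window_um, by = stride)
  wfl <- matrix(Inf, length(x0), length(y0))
  for (b in seq_along(y0)) {
    j1 <- floor(y0[b] / g$pitch[2]) + 1L
    j2 <- min(ny, ceiling((y0[b] + window_um) / g$pitch[2]) + 1L)
    for (a in seq_along(x0)) {
      i1 <- floor(x0[a] / g$pitch[1]) + 1L
      i2 <- min(nx, ceiling((x0[a] + window_um) / g$pitch[1]) + 1L)
      wfl[a, b] <- var(as.numeric(on$heights[i1:i2, j1:j2])) +
                   var(as.numeric(off$heights[i1:i2, j1:j2]))
    }
  }
  best <- which.min(wfl)   # column-major: x varies fastest -> smallest (x, y) tie rule
  a <- ((best - 1L) %% length(x0)) + 1L
  b <- ((best - 1L) %/% length(x0)) + 1L
  centre <- g$origin[1:2] + c(x0[a], y0[b]) + window_um / 2
  duv <- map_uv(on_map, centre) - map_uv(off_map, centre)
  list(offset = as.numeric(duv), anchor = as.numeric(centre))
}

#' Shift a conformal map's planar coordinates
#'
#' @param map a [flatten_lscm()] map.
#' @param offset `c(du, dv)` in um.
#' @return The shifted map.
#' @export
apply_offset <- function(map, offset) {
  map$uv <- sweep(map$uv, 2, offset, "+")
  map$u_grid <- map$u_grid + offset[1]
  map$v_grid <- map$v_grid + offset[2]
  map
}

#' Extend the surface flattening to the whole volume
#'
#' Builds a per-voxel mapping to flattened coordinates `(u, v, depth)`.
#' In-plane coordinates come from weighted least-squares local polynomial
#' models (monomials `1, x, y, x^2, xy, y^2, z, xz, yz` - quadratic in-plane,
#' linear axially) fitted to the surface correspondence points within
#' `fit_radius_um` of each control column (Gaussian weights, sigma = half the
#' radius), then interpolated between control columns. Depth is the
#' per-column affine map placing the On surface at 0 um and the Off surface
#' at `off_depth_um` (12 um by convention), extended linearly beyond the
#' surfaces. Each voxel also carries a volume-compensation weight: the
#' absolute local volume expansion factor of the mapping, from central finite
#' differences.
#'
#' @param on_map,off_map flattened maps, already registered in-plane (apply
#'   [register_inplane()]'s offset to `off_map` first).
#' @param on,off the [surface()] objects.
#' @param grid the full [voxel_grid()] of the stack.
#' @param fit_radius_um local fit radius; doubled once if a fit is rank
#'   deficient, after which a rank-deficient fit is an error.
#' @param control_spacing_um spacing of the control-column lattice.
#' @param sample_spacing_um spacing of the surface correspondence samples.
#' @param off_depth_um depth assigned to the Off surface.
#' @return A `warp_field` object; evaluate it with [warp_points()].
#' @export
build_warp <- function(on_map, off_map, on, off, grid,
                       fit_radius_um = 25, control_spacing_um = 3.2,
                       sample_spacing_um = 2.4, off_depth_um = 12) {
  stopifnot(inherits(on_map, "conformal_map"), inherits(off_map, "conformal_map"))
  g <- grid
  nx <- g$shape[1]; ny <- g$shape[2]
  ss <- max(1L, as.integer(round(sample_spacing_um / g$pitch[1])))
  xi <- seq(1L, nx, by = ss); yi <- seq(1L, ny, by = ss)
  xs <- g$origin[1] + (xi - 1) * g$pitch[1]
  ys <- g$origin[2] + (yi - 1) * g$pitch[2]
  mk_samples <- function(surf, map) {
    xy <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xi)))
    uv <- map_uv(map, xy)
    cbind(xy, as.numeric(surf$heights[xi, yi]), uv)
  }
  S <- rbind(mk_samples(on, on_map), mk_samples(off, off_map))
  nxi <- length(xi)
  nsamp_on <- nxi * length(yi)

  cs <- max(1L, as.integer(round(control_spacing_um / g$pitch[1])))
  cxi <- unique(c(seq(1L, nx, by = cs), nx))
  cyi <- unique(c(seq(1L, ny, by = cs), ny))
  cxu <- g$origin[1] + (cxi - 1) * g$pitch[1]
  cyu <- g$origin[2] + (cyi - 1) * g$pitch[2]
  u0 <- uz <- v0 <- vz <- matrix(NA_real_, length(cxi), length(cyi))
  sigma <- fit_radius_um / 2

  fit_at <- function(xc, yc, radius) {
    # samples lie on a regular lattice: select by index window
    ia <- which(xs >= xc - radius & xs <= xc + radius)
    ja <- which(ys >= yc - radius & ys <= yc + radius)
    if (length(ia) < 2L || length(ja) < 2L) return(NULL)
    pick <- as.vector(outer(ia, (ja - 1L) * nxi, "+"))
    pick <- c(pick, pick + nsamp_on)
    P <- S[pick, , drop = FALSE]
    r2 <- (P[, 1] - xc)^2 + (P[, 2] - yc)^2
    keep <- r2 <= radius^2
    if (sum(keep) < 12L) return(NULL)
    P <- P[keep, , drop = FALSE]
    w <- exp(-r2[keep] / (2 * sigma^2))
    dx_ <- P[, 1] - xc; dy_ <- P[, 2] - yc
    zc <- mean(P[, 3]); dz_ <- P[, 3] - zc
    X <- cbind(1, dx_, dy_, dx_^2, dx_ * dy_, dy_^2, dz_, dx_ * dz_, dy_ * dz_)
    XtW <- t(X * w)
    M <- XtW %*% X
    bet <- tryCatch(solve(M, XtW %*% P[, 4:5]), error = function(e) NULL)
    if (is.null(bet)) return(NULL)
    # at the control column (dx_ = dy_ = 0): coord = b1 + b7 * (z - zc)
    list(u0 = bet[1, 1] - bet[7, 1] * zc, uz = bet[7, 1],
         v0 = bet[1, 2] - bet[7, 2] * zc, vz = bet[7, 2])
  }
  for (b in seq_along(cyi)) for (a in seq_along(cxi)) {
    f <- fit_at(cxu[a], cyu[b], fit_radius_um)
    if (is.null(f)) f <- fit_at(cxu[a], cyu[b], 2 * fit_radius_um)
    if (is.null(f)) stop("rank-deficient local polynomial fit")
    u0[a, b] <- f$u0; uz[a, b] <- f$uz; v0[a, b] <- f$v0; vz[a, b] <- f$vz
  }

  grad2 <- function(f, xc, yc) {
    gx <- f; gy <- f
    n1 <- nrow(f); n2 <- ncol(f)
    il <- pmax(seq_len(n1) - 1L, 1L); ir <- pmin(seq_len(n1) + 1L, n1)
    gx <- (f[ir, , drop = FALSE] - f[il, , drop = FALSE]) / (xc[ir] - xc[il])
    jl <- pmax(seq_len(n2) - 1L, 1L); jr <- pmin(seq_len(n2) + 1L, n2)
    gy <- (f[, jr, drop = FALSE] - f[, jl, drop = FALSE])
    gy <- sweep(gy, 2, yc[jr] - yc[jl], "/")
    list(gx = gx, gy = gy)
  }
  gu0 <- grad2(u0, cxu, cyu); guz <- grad2(uz, cxu, cyu)
  gv0 <- grad2(v0, cxu, cyu); gvz <- grad2(vz, cxu, cyu)

  xun <- g$origin[1] + (seq_len(nx) - 1) * g$pitch[1]
  yun <- g$origin[2] + (seq_len(ny) - 1) * g$pitch[2]
  gzon <- grad2(on$heights, xun, yun)
  gzoff <- grad2(off$heights, xun, yun)

  structure(list(grid = g, cxu = cxu, cyu = cyu,
                 u0 = u0, uz = uz, v0 = v0, vz = vz,
                 du0dx = gu0$gx, du0dy = gu0$gy, duzdx = guz$gx, duzdy = guz$gy,
                 dv0dx = gv0$gx, dv0dy = gv0$gy, dvzdx = gvz$gx, dvzdy = gvz$gy,
                 zon = on$heights, zoff = off$heights,
                 dzondx = gzon$gx, dzondy = gzon$gy,
                 dzoffdx = gzoff$gx, dzoffdy = gzoff$gy,
                 off_depth = off_depth_um),
            class = "warp_field")
}

#' @export
print.warp_field <- function(x, ...) {
  cat(sprintf("<warp_field on %d x %d x %d grid, Off depth %.1f um>\n",
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3], x$off_depth))
  invisible(x)
}

#' Evaluate a warp field at voxel indices
#'
#' @param wf a [build_warp()] field.
#' @param ijk n x 3 matrix of 1-based voxel indices.
#' @return Data frame with columns `i, j, k, u, v, depth_um, weight`.
#' @export
warp_points <- function(wf, ijk) {
  stopifnot(inherits(wf, "warp_field"))
  ijk <- rbind(ijk)
  g <- wf$grid
  if (any(ijk < 1L) || any(sweep(ijk, 2, g$shape, ">")))
    stop("voxel index outside the grid")
  xyz <- index_to_um(g, ijk)
  x <- xyz[, 1]; y <- xyz[, 2]; z <- xyz[, 3]
  bl <- function(f) bilin1(f, wf$cxu, wf$cyu, x, y)
  u0p <- bl(wf$u0); uzp <- bl(wf$uz); v0p <- bl(wf$v0); vzp <- bl(wf$vz)
  u <- u0p + uzp * z
  v <- v0p + vzp * z
  sub <- cbind(ijk[, 1], ijk[, 2])
  zon <- wf$zon[sub]; zoff <- wf$zoff[sub]
  delta <- zoff - zon
  depth <- wf$off_depth * (z - zon) / delta
  # Jacobian of (u, v, depth) wrt (x, y, z)
  dudx <- bl(wf$du0dx) + bl(wf$duzdx) * z
  dudy <- bl(wf$du0dy) + bl(wf$duzdy) * z
  dvdx <- bl(wf$dv0dx) + bl(wf$dvzdx) * z
  dvdy <- bl(wf$dv0dy) + bl(wf$dvzdy) * z
  dzon_dx <- wf$dzondx[sub]; dzon_dy <- wf$dzondy[sub]
  dzoff_dx <- wf$dzoffdx[sub]; dzoff_dy <- wf$dzoffdy[sub]
  dddz <- wf$off_depth / delta
  dddx <- wf$off_depth * (-dzon_dx * delta - (z - zon) * (dzoff_dx - dzon_dx)) / delta^2
  dddy <- wf$off_depth * (-dzon_dy * delta - (z - zon) * (dzoff_dy - dzon_dy)) / delta^2
  det <- dudx * (dvdy * dddz - vzp * dddy) -
         dudy * (dvdx * dddz - vzp * dddx) +
         uzp  * (dvdx * dddy - dvdy * dddx)
  data.frame(i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
             u = u, v = v, depth_um = depth, weight = abs(det))
}

#' Warp all foreground voxels of a reconstruction
#'
#' @param wf a [build_warp()] field.
#' @param v a [binary_volume()] on the same grid.
#' @return Data frame as in [warp_points()], one row per foreground voxel.
#' @export
warp_volume_points <- function(wf, v) {
  stopifnot(inherits(v, "binary_volume"))
  idx <- which(v$mask, arr.ind = TRUE)
  colnames(idx) <- NULL
  warp_points(wf, idx)
}
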