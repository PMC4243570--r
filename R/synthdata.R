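#' Phantom specification
#'
#' Fully specifies a synthetic two-channel confocal stack: a sparsely labeled
#' branching arbor stratifying at a type-specific laminar depth (with
#' submicron cell-to-cell jitter), two wavy starburst laminae, a soma, and
#' confocal-like blur and shot noise. The stock cell types and their target
#' depths (distance from the On starburst surface) are JAMB at 15.6 um, W3
#' at 5.5 um, and the bistratified BDa at 0.3 and 12.3 um (0.3 um distal to
#' the Off surface).
#'
#' @param type `"JAMB"`, `"W3"` or `"BDa"`.
#' @param shape,pitch stack geometry; default 256 x 256 x 120 voxels at
#'   0.4 x 0.4 x 0.5 um.
#' @param jitter per-cell laminar stratification jitter (SD of the cell's
#'   depth offset from the type target), um.
#' @param node_jitter within-arbor depth roughness per skeleton node, um.
#' @param warp_amplitude,warp_wavelength amplitude (um) and base wavelength
#'   (um) of the sum-of-sinusoids tissue warp applied to both laminae and the
#'   arbor.
#' @param z_on_base nominal On-lamina z position, um.
#' @param soma_diameter,soma_depth soma size (um) and its depth relative to
#'   the On surface (um; ganglion side is negative).
#' @param dendrite_radius `c(base, tip)` tube radii, um (linear taper with
#'   path distance).
#' @param blur_sigma optical blur SD per axis, um.
#' @param peak_intensity mean photon count on thick structures.
#' @param read_noise_frac Gaussian read-noise SD as a fraction of
#'   `peak_intensity`.
#' @param lamina_intensity,lamina_sigma brightness and axial SD (um) of the
#'   rendered starburst laminae.
#' @param branch_prob,step_um,persistence,arbor_nodes,max_path arbor growth
#'   model: per-step branching probability, step length (um), in-plane
#'   direction persistence, node budget per stratum, maximum tip path length
#'   (um).
#' @param seed integer seed; all phantom randomness derives from it.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(type = c("W3", "JAMB", "BDa"),
                         shape = c(256, 256, 120), pitch = c(0.4, 0.4, 0.5),
                         jitter = 0.25, node_jitter = 0.1,
                         warp_amplitude = 4, warp_wavelength = 100,
                         z_on_base = 20, soma_diameter = 12, soma_depth = -6,
                         dendrite_radius = c(1.5, 0.3),
                         blur_sigma = c(0.3, 0.3, 0.6),
                         peak_intensity = 200, read_noise_frac = 0.02,
                         lamina_intensity = 150, lamina_sigma = 0.8,
                         branch_prob = 0.05, step_um = 1, persistence = 0.8,
                         arbor_nodes = 350, max_path = 45, seed = 0L) {
  type <- match.arg(type)
  depths <- switch(type, JAMB = 15.6, W3 = 5.5, BDa = c(0.3, 12.3))
  grid <- voxel_grid(shape, pitch)
  zmax <- (shape[3] - 1) * pitch[3]
  if (z_on_base - warp_amplitude < 5 ||
      z_on_base + 12 + warp_amplitude > zmax - 5)
    stop("warp amplitude leaves laminae closer than 5 um to the stack border")
  if (any(depths < -20 + 5) || any(depths > 25 - 5))
    stop("target depths incompatible with the profile support")
  structure(list(type = type, target_depths = depths, grid = grid,
                 jitter = jitter, node_jitter = node_jitter,
                 warp_amplitude = warp_amplitude,
                 warp_wavelength = warp_wavelength, z_on_base = z_on_base,
                 soma_diameter = soma_diameter, soma_depth = soma_depth,
                 dendrite_radius = dendrite_radius, blur_sigma = blur_sigma,
                 peak_intensity = peak_intensity,
                 read_noise_frac = read_noise_frac,
                 lamina_intensity = lamina_intensity,
                 lamina_sigma = lamina_sigma, branch_prob = branch_prob,
                 step_um = step_um, persistence = persistence,
                 arbor_nodes = arbor_nodes, max_path = max_path,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# tissue warp: laminar z displacement field, um; phases drawn from the seed
phantom_warp_fun <- function(spec, phases) {
  A <- spec$warp_amplitude
  l1 <- spec$warp_wavelength
  l2 <- 0.8 * spec$warp_wavelength
  function(x, y)
    A * (0.6 * sin(2 * pi * x / l1 + phases[1]) +
         0.4 * sin(2 * pi * y / l2 + phases[2]))
}

#' Generate a synthetic two-channel phantom
#'
#' Grows a random branching arbor confined to its type's target depth(s)
#' (per-cell Gaussian stratification jitter plus per-node roughness), renders
#' it as tapered tubes plus a soma ball, renders the two starburst laminae as
#' bright sheets following the tissue warp, then blurs both channels and adds
#' Poisson shot noise with Gaussian read noise (intensities saturate at 1.2x
#' the nominal peak, as a detector would). All randomness derives from
#' `spec$seed`; two calls with the same spec are identical.
#'
#' @param spec a [phantom_spec()].
#' @return A list: `neuron` and `chat` [image_stack()]s, and `truth` with
#'   fields `skeleton` ([skeleton()], um), `volume` (noise-free
#'   [binary_volume()] of the rendered cell), `on`/`off` (true [surface()]s),
#'   `depths` (data frame: foreground voxel indices and their true depth,
#'   um), `cell_offsets` (the drawn per-stratum depth offsets, um).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  g <- spec$grid
  nx <- g$shape[1]; ny <- g$shape[2]; nz <- g$shape[3]
  ext <- (g$shape[1:2] - 1) * g$pitch[1:2]
  phases <- runif(2, 0, 2 * pi)
  warpf <- phantom_warp_fun(spec, phases)
  zon_of <- function(x, y) spec$z_on_base + warpf(x, y)

  # ---- skeleton growth ----------------------------------------------------
  margin <- 8
  offsets <- rnorm(length(spec$target_depths), 0, spec$jitter)
  soma_xy <- ext / 2 + runif(2, -5, 5)
  nodes <- list()  # x, y, depth, parent, pathdist
  add_node <- function(x, y, depth, parent, pd) {
    nodes[[length(nodes) + 1L]] <<- c(x, y, depth, parent, pd)
    length(nodes)
  }
  root <- add_node(soma_xy[1], soma_xy[2], spec$soma_depth, -1L, 0)
  grow_arbor <- function(attach_id, target) {
    att <- nodes[[attach_id]]
    # trunk: climb in depth from the attachment to the stratum
    dsteps <- seq(att[3], target, by = sign(target - att[3]) * spec$step_um)
    parent <- attach_id; pd <- att[5]
    x <- att[1]; y <- att[2]
    for (dd in dsteps[-1]) {
      pd <- pd + spec$step_um
      parent <- add_node(x + rnorm(1, 0, 0.2), y + rnorm(1, 0, 0.2), dd,
                         parent, pd)
    }
    top <- parent
    # primary dendrites
    tips <- lapply(runif(3, 0, 2 * pi), function(th)
      list(id = top, dir = c(cos(th), sin(th)), pd = nodes[[top]][5]))
    budget <- spec$arbor_nodes
    while (budget > 0L && length(tips) > 0L) {
      newtips <- list()
      for (tp in tips) {
        if (budget <= 0L) break
        nd <- nodes[[tp$id]]
        dir <- tp$dir
        rnd <- runif(1, 0, 2 * pi)
        dir <- spec$persistence * dir + (1 - spec$persistence) * c(cos(rnd), sin(rnd))
        dir <- dir / sqrt(sum(dir^2))
        x <- nd[1] + spec$step_um * dir[1]
        y <- nd[2] + spec$step_um * dir[2]
        if (x < margin || x > ext[1] - margin) { dir[1] <- -dir[1]; x <- nd[1] + spec$step_um * dir[1] }
        if (y < margin || y > ext[2] - margin) { dir[2] <- -dir[2]; y <- nd[2] + spec$step_um * dir[2] }
        pd <- tp$pd + spec$step_um
        if (pd - nodes[[top]][5] > spec$max_path) next
        id <- add_node(x, y, target + rnorm(1, 0, spec$node_jitter), tp$id, pd)
        budget <- budget - 1L
        newtips[[length(newtips) + 1L]] <- list(id = id, dir = dir, pd = pd)
        if (runif(1) < spec$branch_prob && budget > 0L) {
          ang <- atan2(dir[2], dir[1]) + sample(c(-1, 1), 1) * runif(1, pi / 4, pi / 2)
          newtips[[length(newtips) + 1L]] <-
            list(id = id, dir = c(cos(ang), sin(ang)), pd = pd)
        }
      }
      tips <- newtips
    }
    top
  }
  attach_id <- root
  for (t in seq_along(spec$target_depths))
    attach_id <- grow_arbor(attach_id,
                            spec$target_depths[t] + offsets[t])

  nm <- do.call(rbind, nodes)
  colnames(nm) <- c("x", "y", "depth", "parent", "pathdist")
  zum <- zon_of(nm[, "x"], nm[, "y"]) + nm[, "depth"]
  rb <- spec$dendrite_radius[1]; rt <- spec$dendrite_radius[2]
  dmax <- max(nm[, "pathdist"])
  radius <- rb + (rt - rb) * nm[, "pathdist"] / max(dmax, 1)
  skel <- skeleton(data.frame(id = seq_len(nrow(nm)),
                              type = ifelse(nm[, "parent"] == -1L, 1L, 3L),
                              x = nm[, "x"], y = nm[, "y"], z = zum,
                              radius = radius, parent = nm[, "parent"]))

  # ---- render the cell ----------------------------------------------------
  # densified tube samples along each edge, painted as balls of the node radius
  pidx <- nm[, "parent"]
  has_par <- which(pidx > 0)
  seg_a <- cbind(nm[has_par, "x"], nm[has_par, "y"], zum[has_par])
  seg_b <- cbind(nm[pidx[has_par], "x"], nm[pidx[has_par], "y"], zum[pidx[has_par]])
  sub <- 3L
  pts <- list(); rads <- list()
  for (t in 0:sub) {
    fr <- t / sub
    pts[[t + 1]] <- seg_a + fr * (seg_b - seg_a)
    rads[[t + 1]] <- radius[has_par] * (1 - fr) + radius[pidx[has_par]] * fr
  }
  P <- do.call(rbind, pts)
  R <- pmax(do.call(c, rads), 0.9 * min(g$pitch))   # keep thin tips connected
  centers <- um_to_index(g, P) - 1L
  mask <- array(FALSE, dim = g$shape)
  mask <- array(cpp_paint_balls(mask, g$shape, centers, R, g$pitch),
                dim = g$shape)
  soma_c <- um_to_index(g, cbind(soma_xy[1], soma_xy[2],
                                 zon_of(soma_xy[1], soma_xy[2]) + spec$soma_depth)) - 1L
  mask <- array(cpp_paint_balls(mask, g$shape, soma_c, spec$soma_diameter / 2,
                                g$pitch), dim = g$shape)
  truth_vol <- binary_volume(mask, g)

  # true depth of every foreground voxel: its z minus the local On height
  fg <- which(mask, arr.ind = TRUE)
  xyz <- index_to_um(g, fg)
  depths_df <- data.frame(i = fg[, 1], j = fg[, 2], k = fg[, 3],
                          depth_um = xyz[, 3] - zon_of(xyz[, 1], xyz[, 2]))

  # ---- true surfaces ------------------------------------------------------
  xv <- g$origin[1] + (seq_len(nx) - 1) * g$pitch[1]
  yv <- g$origin[2] + (seq_len(ny) - 1) * g$pitch[2]
  zon_mat <- outer(xv, yv, zon_of)
  all_valid <- matrix(TRUE, nx, ny)
  s_on <- surface(zon_mat, all_valid, "On", g)
  s_off <- surface(zon_mat + 12, all_valid, "Off", g)

  # ---- intensities --------------------------------------------------------
  blur_vox <- spec$blur_sigma / g$pitch
  neuron_I <- cpp_gauss_blur(as.numeric(mask) * spec$peak_intensity,
                             g$shape, blur_vox)
  zv <- g$origin[3] + (seq_len(nz) - 1) * g$pitch[3]
  chat_I <- array(0, dim = g$shape)
  s2 <- 2 * spec$lamina_sigma^2
  for (k in seq_len(nz)) {
    chat_I[, , k] <- spec$lamina_intensity *
      (exp(-(zv[k] - zon_mat)^2 / s2) + exp(-(zv[k] - zon_mat - 12)^2 / s2))
  }
  chat_I <- cpp_gauss_blur(as.numeric(chat_I), g$shape, blur_vox)
  noisy <- function(I) {
    v <- rpois(length(I), lambda = pmax(I, 0)) +
      rnorm(length(I), 0, spec$read_noise_frac * spec$peak_intensity)
    v <- pmin(pmax(v, 0), 1.2 * spec$peak_intensity)   # detector saturation
    array(v, dim = g$shape)
  }
  neuron <- image_stack(noisy(neuron_I), g, "neuron")
  chat <- image_stack(noisy(chat_I), g, "fiducial")

  list(neuron = neuron, chat = chat,
       truth = list(skeleton = skel, volume = truth_vol, on = s_on,
                    off = s_off, depths = depths_df, cell_offsets = offsets,
                    warp_phases = phases, spec = spec))
}

#' Add distractor objects to a phantom's neuron channel
#'
#' Adds `count` disconnected bright objects - alternating compact blobs and
#' short neurite fragments - at least 20 um away from the true arbor (and at
#' least 8 um from each other), emulating somata and neurites of other cells
#' in insufficiently sparse labeling. The phantom truth is unchanged.
#'
#' @param neuron the phantom's neuron-channel [image_stack()].
#' @param truth the phantom's `truth` list (from [make_phantom()]).
#' @param count number of distractors, >= 0.
#' @param seed RNG seed for placement.
#' @return The augmented [image_stack()].
#' @export
add_distractors <- function(neuron, truth, count, seed = 1L) {
  stopifnot(inherits(neuron, "image_stack"), count >= 0)
  if (count == 0L) return(neuron)
  set.seed(seed)
  g <- neuron$grid
  spec <- truth$spec
  dsq <- cpp_edt_sq(as.logical(truth$volume$mask), g$shape, g$pitch)
  far <- array(dsq >= 20^2, dim = g$shape)
  marg <- ceiling(5 / g$pitch)
  far[c(seq_len(marg[1]), (g$shape[1] - marg[1] + 1):g$shape[1]), , ] <- FALSE
  far[, c(seq_len(marg[2]), (g$shape[2] - marg[2] + 1):g$shape[2]), ] <- FALSE
  far[, , c(seq_len(marg[3]), (g$shape[3] - marg[3] + 1):g$shape[3])] <- FALSE
  cand <- which(far)
  # objects can reach ~7 um from their anchor (fragment length + radius), so
  # keep anchors at least 8 um from every painted sample of earlier objects
  occupied <- matrix(numeric(0), 0, 3)
  mask <- array(FALSE, dim = g$shape)
  if (length(cand) == 0L)
    stop("no room for distractors: every voxel is within 20 um of the arbor")
  for (q in seq_len(count)) {
    tries <- 0L
    repeat {
      tries <- tries + 1L
      if (tries > 2000L)
        stop("cannot place ", count, " distractors with the required ",
             "separations in this field of view")
      s <- cand[sample.int(length(cand), 1L)]
      i <- ((s - 1) %% g$shape[1]) + 1
      r <- (s - 1) %/% g$shape[1]
      j <- (r %% g$shape[2]) + 1
      k <- (r %/% g$shape[2]) + 1
      p <- index_to_um(g, cbind(i, j, k))
      if (nrow(occupied) == 0 ||
          min(sqrt(rowSums(sweep(occupied, 2, as.numeric(p))^2))) >= 15) break
    }
    if (q %% 2L == 1L) {      # blob
      mask <- array(cpp_paint_balls(mask, g$shape, um_to_index(g, p) - 1L,
                                    runif(1, 1.5, 3), g$pitch), dim = g$shape)
      occupied <- rbind(occupied, p)
    } else {                  # short neurite fragment
      th <- runif(1, 0, 2 * pi)
      segp <- t(vapply(seq(0, 6, by = 0.4), function(d)
        as.numeric(p) + d * c(cos(th), sin(th), 0), numeric(3)))
      hi <- g$origin + (g$shape - 1) * g$pitch
      for (ax in 1:3)
        segp[, ax] <- pmin(pmax(segp[, ax], g$origin[ax]), hi[ax])
      mask <- array(cpp_paint_balls(mask, g$shape, um_to_index(g, segp) - 1L,
                                    rep(1.2, nrow(segp)), g$pitch),
                    dim = g$shape)
      occupied <- rbind(occupied, segp)
    }
  }
  sig <- cpp_gauss_blur(as.numeric(mask) * spec$peak_intensity, g$shape,
                        spec$blur_sigma / g$pitch)
  vals <- pmin(neuron$values + array(sig, dim = g$shape),
               1.2 * spec$peak_intensity)
  image_stack(vals, g, "neuron")
}
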