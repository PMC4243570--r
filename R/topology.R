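#' Simple-point test under the (26, 6) adjacency pair
#'
#' A voxel is *simple* when flipping its value leaves the topology of the
#' digital image unchanged (no objects, cavities, tunnels, splits or mergers
#' created or destroyed), with the foreground 26-connected and the background
#' 6-connected. The test uses the topological-number characterization: the
#' point is simple iff both the number of 26-components of the foreground
#' within the 26-neighbourhood and the number of 6-components of the
#' background within the 18-neighbourhood that touch the centre by a face
#' equal 1. The centre's own value does not enter the decision.
#'
#' @param patch a 3 x 3 x 3 logical array (or length-27 vector in x-fastest
#'   order), or an n x 27 matrix of such patches.
#' @return Logical: `TRUE` where the centre voxel is simple.
#' @examples
#' p <- array(FALSE, c(3, 3, 3)); p[2, 2, 2] <- TRUE; p[1, 2, 2] <- TRUE
#' is_simple_point(p)   # curve endpoint: TRUE
#' @export
is_simple_point <- function(patch) {
  if (is.matrix(patch) && ncol(patch) == 27L) {
    m <- patch
  } else {
    patch <- as.array(patch)
    if (length(patch) != 27L) stop("patch must have 27 cells")
    m <- matrix(as.integer(patch), nrow = 1)
  }
  storage.mode(m) <- "integer"
  if (any(is.na(m))) stop("patch must not contain NA")
  res <- cpp_is_simple_batch(m)
  if (nrow(m) == 1L) res[1] else res
}

#' Global topology summary of a binary volume
#'
#' Counts computed on the volume conceptually padded by one background layer:
#' `components` is the number of 26-connected foreground components,
#' `cavities` the number of 6-connected background components fully enclosed
#' by foreground, and `euler` the Euler characteristic under the (26, 6)
#' pair (computed from the cell counts of the union of closed unit cubes,
#' whose connectivity realizes that pair).
#'
#' @param v a [binary_volume()] or logical 3-D array.
#' @return A list with integer fields `components`, `cavities`, `euler`.
#' @examples
#' cube <- array(TRUE, c(3, 3, 3))
#' topology_summary(cube)              # 1 component, 0 cavities, euler 1
#' @export
topology_summary <- function(v) {
  mask <- if (inherits(v, "binary_volume")) v$mask else as.array(v)
  storage.mode(mask) <- "logical"
  d <- dim(mask)
  if (length(d) != 3L) stop("need a 3-D volume")
  if (!any(mask))
    return(list(components = 0L, cavities = 0L, euler = 0L))
  lab <- cpp_label3d(as.logical(mask), d, 26L)
  ncomp <- max(lab)
  bg <- cpp_label3d(!as.logical(mask), d, 6L)
  nbg <- max(bg)
  if (nbg > 0L) {
    bga <- array(bg, dim = d)
    border <- unique(c(bga[c(1, d[1]), , ], bga[, c(1, d[2]), ],
                       bga[, , c(1, d[3])]))
    ncav <- nbg - length(setdiff(unique(border), 0L))
  } else ncav <- 0L
  cc <- cpp_cell_counts(as.logical(mask), d)
  list(components = as.integer(ncomp), cavities = as.integer(ncav),
       euler = as.integer(cc[1] - cc[2] + cc[3] - cc[4]))
}

#' Topologically constrained inflation of a trace
#'
#' Grows a rasterized trace outward into the bright voxels of the raw stack
#' while flipping only simple points, so the result keeps exactly the
#' topology of the trace. The brightness target is the set of voxels with
#' intensity at or above `threshold_frac` of the stack's global maximum (the
#' pipeline default is 60%). Each of `max_radius` rounds dilates by at most
#' one 6-neighbourhood voxel layer; within a round, candidate voxels are
#' visited in raster order (x fastest) and flipped one at a time when simple,
#' repeating until the count of remaining candidates stabilizes.
#'
#' By default the simple-point test reads the live, partially updated volume,
#' which is what makes sequential flips provably topology preserving.
#' `stale_copy = TRUE` instead evaluates all tests of a round against a
#' snapshot taken at the round's start, for comparison.
#'
#' @param raw an [image_stack()].
#' @param trace a nonempty [binary_volume()] on the same grid.
#' @param max_radius number of growth rounds; 62 rounds at 0.4 um pitch
#'   suffice to absorb a 50 um soma along its diameter (see
#'   [max_absorbable_diameter()]).
#' @param threshold_frac fraction of the global maximum, in (0, 1].
#' @param stale_copy use the literal per-round snapshot variant.
#' @param sweep_cap hard cap on inner sweeps per round (guards pathological
#'   inputs); default `10 * max(shape)`.
#' @return A [binary_volume()]: a superset of the trace, a subset of
#'   trace-union-target, with the same [topology_summary()] as the trace.
#' @export
inflate_trace <- function(raw, trace, max_radius = 62L, threshold_frac = 0.6,
                          stale_copy = FALSE, sweep_cap = NULL) {
  stopifnot(inherits(raw, "image_stack"), inherits(trace, "binary_volume"))
  if (!grids_equal(raw$grid, trace$grid))
    stop("`raw` and `trace` must share a voxel grid")
  if (!any(trace$mask)) stop("`trace` must be nonempty")
  if (!is.numeric(threshold_frac) || threshold_frac <= 0 || threshold_frac > 1)
    stop("`threshold_frac` must be in (0, 1]")
  if (max_radius < 0L) stop("`max_radius` must be >= 0")
  if (is.null(sweep_cap)) sweep_cap <- 10L * max(raw$grid$shape)
  target <- raw$values >= threshold_frac * max(raw$values)
  out <- cpp_inflate(as.logical(trace$mask), as.logical(target),
                     raw$grid$shape, as.integer(max_radius),
                     isTRUE(stale_copy), as.integer(sweep_cap))
  binary_volume(array(out, dim = raw$grid$shape), raw$grid)
}

#' Largest soma diameter absorbable by constrained inflation
#'
#' Each inflation round grows the volume by at most one voxel layer along
#' every axis, so after `max_radius` rounds a seed voxel has reached
#' `max_radius` voxels in each axis direction: the largest axis-aligned
#' diameter fully absorbed from a central seed is
#' `(2 * max_radius + 1) * pitch`. With the default 62 rounds at 0.4 um
#' in-plane pitch this is 50 um, covering retinal ganglion somata. (Growth
#' uses the 6-neighbourhood, so voxels along diagonals need proportionally
#' more rounds; the guarantee is about the diameter through the seed.)
#'
#' @param max_radius number of growth rounds, >= 0.
#' @param pitch voxel pitch along the relevant axis, um.
#' @return Diameter in um.
#' @examples
#' max_absorbable_diameter(62, 0.4)   # 50
#' @export
max_absorbable_diameter <- function(max_radius, pitch) {
  if (max_radius < 0) stop("`max_radius` must be >= 0")
  if (pitch <= 0) stop("`pitch` must be > 0")
  (2 * max_radius + 1) * pitch
}
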