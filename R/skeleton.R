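#' Rasterize a skeleton onto a voxel grid
#'
#' Every edge of the trace is drawn as a 26-connected digital line of
#' single-voxel width (3-D stepping along the dominant axis; rounding ties
#' break toward the smaller index). Node radii are ignored: thickness is
#' supplied later by [inflate_trace()].
#'
#' @param s a [skeleton()] with node coordinates in um.
#' @param grid a [voxel_grid()]; the skeleton bounding box must fit it.
#' @return A [binary_volume()] containing the rasterized trace.
#' @examples
#' g <- voxel_grid(c(16, 16, 16), c(1, 1, 1))
#' s <- skeleton(data.frame(id = 1:2, type = 0, x = c(2, 12), y = 2, z = 2,
#'                          radius = 1, parent = c(-1, 1)))
#' sum(rasterize_skeleton(s, g)$mask)  # 11 voxels on one line
#' @export
rasterize_skeleton <- function(s, grid) {
  stopifnot(inherits(s, "skeleton"), inherits(grid, "voxel_grid"))
  n <- s$nodes
  idx <- um_to_index(grid, cbind(n$x, n$y, n$z))
  if (any(idx < 1L) || any(sweep(idx, 2, grid$shape, ">")))
    stop("skeleton node outside the voxel grid")
  pidx <- match(n$parent, n$id)
  edge <- which(!is.na(pidx))
  if (length(edge)) {
    a <- idx[edge, , drop = FALSE] - 1L
    b <- idx[pidx[edge], , drop = FALSE] - 1L
  } else {
    a <- b <- idx[0, , drop = FALSE]
  }
  # isolated roots still mark their own voxel
  roots <- which(is.na(pidx))
  a <- rbind(a, idx[roots, , drop = FALSE] - 1L)
  b <- rbind(b, idx[roots, , drop = FALSE] - 1L)
  m <- cpp_draw_segments(a, b, grid$shape)
  binary_volume(array(m, dim = grid$shape), grid)
}
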