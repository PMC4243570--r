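#' Voxel grid geometry
#'
#' A voxel grid couples an array shape to a physical coordinate frame. The
#' physical position of voxel index `(i, j, k)` (1-based in R) is
#' `origin + ((i-1)*dx, (j-1)*dy, (k-1)*dz)` in micrometres. `z` is the
#' laminar axis: slice index increases from the ganglion-cell side toward the
#' inner nuclear layer.
#'
#' @param shape integer triple `(nx, ny, nz)`, all >= 1.
#' @param pitch voxel pitch in um, `(dx, dy, dz)`, all > 0. The confocal
#'   default used throughout the package is `c(0.4, 0.4, 0.5)`.
#' @param origin physical position of voxel `(1, 1, 1)` in um.
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(c(64, 64, 32), c(0.4, 0.4, 0.5))
#' index_to_um(g, cbind(1, 1, 11))  # (0, 0, 5) um
#' @export
voxel_grid <- function(shape, pitch = c(0.4, 0.4, 0.5), origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  pitch <- as.numeric(pitch)
  origin <- as.numeric(origin)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("`shape` must be an integer triple with all components >= 1")
  if (length(pitch) != 3L || any(!is.finite(pitch)) || any(pitch <= 0))
    stop("`pitch` must be a positive um triple")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be a finite um triple")
  structure(list(shape = shape, pitch = pitch, origin = origin),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid %d x %d x %d, pitch %.3g x %.3g x %.3g um>\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$pitch[1], x$pitch[2], x$pitch[3]))
  invisible(x)
}

grids_equal <- function(a, b) {
  identical(a$shape, b$shape) &&
    isTRUE(all.equal(a$pitch, b$pitch)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

#' Convert between voxel indices and physical coordinates
#'
#' @param grid a [voxel_grid()].
#' @param ijk n x 3 matrix of 1-based voxel indices.
#' @param xyz n x 3 matrix of physical um coordinates.
#' @return `index_to_um`: n x 3 matrix of um coordinates of the voxel
#'   centres; `um_to_index`: n x 3 integer matrix of nearest voxel indices
#'   (ties rounded toward the smaller index).
#' @export
index_to_um <- function(grid, ijk) {
  ijk <- rbind(ijk)
  sweep(sweep(ijk - 1, 2, grid$pitch, "*"), 2, grid$origin, "+")
}

#' @rdname index_to_um
#' @export
um_to_index <- function(grid, xyz) {
  xyz <- rbind(xyz)
  v <- sweep(sweep(xyz, 2, grid$origin, "-"), 2, grid$pitch, "/")
  idx <- ceiling(v - 0.5) + 1L      # ties toward the smaller index
  storage.mode(idx) <- "integer"
  idx
}

#' 3-D grayscale image stack
#'
#' A single-channel scalar volume on a [voxel_grid()], tagged with its channel
#' role: `"neuron"` (the labeled cell) or `"fiducial"` (the ChAT/starburst
#' channel).
#'
#' @param values numeric array with `dim == grid$shape`; finite, nonnegative.
#' @param grid a [voxel_grid()]; defaults to unit origin with `pitch`.
#' @param role `"neuron"` or `"fiducial"`.
#' @param pitch shortcut used when `grid` is missing.
#' @return An object of class `image_stack` with fields `values`, `grid`,
#'   `role`.
#' @export
image_stack <- function(values, grid = NULL, role = c("neuron", "fiducial"),
                        pitch = c(0.4, 0.4, 0.5)) {
  role <- match.arg(role)
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3-D array")
  if (is.null(grid)) grid <- voxel_grid(dim(values), pitch)
  if (!identical(as.integer(dim(values)), grid$shape))
    stop("array shape does not match the grid")
  if (any(!is.finite(values)))
    stop("stack values must be finite")
  if (any(values < 0))
    stop("stack values must be nonnegative")
  structure(list(values = values, grid = grid, role = role),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack [%s] %d x %d x %d, range [%.4g, %.4g]>\n",
              x$role, dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' 3-D binary mask
#'
#' @param mask logical array with `dim == grid$shape`.
#' @param grid a [voxel_grid()].
#' @param pitch shortcut used when `grid` is missing.
#' @return An object of class `binary_volume`.
#' @export
binary_volume <- function(mask, grid = NULL, pitch = c(0.4, 0.4, 0.5)) {
  mask <- as.array(mask)
  if (length(dim(mask)) != 3L) stop("`mask` must be a 3-D array")
  if (is.null(grid)) grid <- voxel_grid(dim(mask), pitch)
  if (!identical(as.integer(dim(mask)), grid$shape))
    stop("mask shape does not match the grid")
  storage.mode(mask) <- "logical"
  if (any(is.na(mask))) stop("mask must not contain NA")
  structure(list(mask = mask, grid = grid), class = "binary_volume")
}

#' @export
print.binary_volume <- function(x, ...) {
  cat(sprintf("<binary_volume %d x %d x %d, %d foreground voxels>\n",
              dim(x$mask)[1], dim(x$mask)[2], dim(x$mask)[3], sum(x$mask)))
  invisible(x)
}

#' View a binary volume as a 0/1 image stack
#'
#' Used by the thresholding pipeline path, where [postprocess()] consumes the
#' binarized stack directly.
#'
#' @param v a [binary_volume()].
#' @param role channel role for the resulting stack.
#' @return An [image_stack()] of 0/1 values.
#' @export
as_image_stack <- function(v, role = "neuron") {
  stopifnot(inherits(v, "binary_volume"))
  image_stack(array(as.numeric(v$mask), dim = dim(v$mask)), v$grid, role)
}
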