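#' Read a multi-page grayscale TIFF as an image stack
#'
#' Pixel values are read losslessly (`as.is`): 8/16-bit unsigned data keep
#' their integer values, float data their stored values. Page index maps to
#' the z index.
#'
#' @param path path to a single-channel multi-page TIFF.
#' @param pitch voxel pitch in um (the file format carries no calibrated
#'   pitch, so the caller must supply it).
#' @param role channel role, `"neuron"` or `"fiducial"`.
#' @return An [image_stack()] of shape `(nx, ny, nz)` where `nx` is the TIFF
#'   page width, `ny` the height and `nz` the page count.
#' @seealso [write_stack()]
#' @export
read_stack <- function(path, pitch = c(0.4, 0.4, 0.5), role = "neuron") {
  if (!file.exists(path)) stop("cannot read TIFF: ", path)
  pitch <- as.numeric(pitch)
  if (length(pitch) != 3L || any(!is.finite(pitch)) || any(pitch <= 0))
    stop("`pitch` components must be positive")
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) stop("cannot read TIFF '", path, "': ",
                                             conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  for (p in pages)
    if (length(dim(p)) != 2L)
      stop("multi-sample (non-grayscale) TIFF pages are not supported")
  nzp <- length(pages)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  vals <- array(0, dim = c(nx, ny, nzp))
  for (k in seq_len(nzp)) vals[, , k] <- t(pages[[k]])   # page rows are y
  image_stack(vals, voxel_grid(c(nx, ny, nzp), pitch), role)
}

#' Write an image stack or binary volume as a multi-page TIFF
#'
#' `mode = "uint16"` stores `round(values)` as 16-bit unsigned integers
#' (lossless for integer data in 0..65535); `"uint8"` likewise for 0..255;
#' `"float32"` stores single-precision floats; `"binary"` writes a mask as
#' 8-bit 0/255.
#'
#' @param x an [image_stack()] or [binary_volume()].
#' @param path output file path.
#' @param mode storage mode, see above.
#' @return `path`, invisibly.
#' @export
write_stack <- function(x, path, mode = c("uint16", "uint8", "float32", "binary")) {
  mode <- match.arg(mode)
  if (inherits(x, "binary_volume")) {
    vals <- array(as.numeric(x$mask), dim = dim(x$mask))
    mode <- "binary"
  } else {
    stopifnot(inherits(x, "image_stack"))
    vals <- x$values
  }
  nzp <- dim(vals)[3]
  pages <- vector("list", nzp)
  if (mode == "uint16") {
    if (max(vals) > 65535) stop("values exceed 16-bit range")
    for (k in seq_len(nzp)) pages[[k]] <- t(round(vals[, , k]) / 65535)
    bits <- 16L
  } else if (mode == "uint8") {
    if (max(vals) > 255) stop("values exceed 8-bit range")
    for (k in seq_len(nzp)) pages[[k]] <- t(round(vals[, , k]) / 255)
    bits <- 8L
  } else if (mode == "binary") {
    for (k in seq_len(nzp)) pages[[k]] <- t(vals[, , k])
    bits <- 8L
  } else {
    for (k in seq_len(nzp)) pages[[k]] <- t(vals[, , k])
    bits <- 32L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  invisible(path)
}

#' Read a skeleton trace in SWC format
#'
#' SWC dialect: whitespace-separated rows of
#' `id type x y z radius parent`, `#` comments, coordinates and radii in um,
#' `parent = -1` for roots. Node order is preserved. Radii are parsed but the
#' downstream rasterization ignores them: dendrite thickness comes from
#' topologically constrained inflation, not from the trace.
#'
#' @param path path to an SWC file.
#' @return A `skeleton` object: data frame `nodes` with columns
#'   `id, type, x, y, z, radius, parent`.
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop("cannot read SWC: ", path)
  raw <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  if (length(keep) == 0L) stop("SWC file has no node lines: ", path)
  parse_line <- function(ln) {
    f <- strsplit(trimws(raw[ln]), "\\s+")[[1]]
    if (length(f) != 7L)
      stop("SWC format error at line ", ln, ": expected 7 fields, got ",
           length(f))
    v <- suppressWarnings(as.numeric(f))
    if (any(is.na(v)))
      stop("SWC format error at line ", ln, ": non-numeric field")
    v
  }
  m <- t(vapply(keep, parse_line, numeric(7)))
  nodes <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                      x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
                      parent = as.integer(m[, 7]), line = keep)
  dup <- which(duplicated(nodes$id))
  if (length(dup))
    stop("SWC format error at line ", nodes$line[dup[1]],
         ": duplicate node id ", nodes$id[dup[1]])
  bad <- which(nodes$parent != -1L & !(nodes$parent %in% nodes$id))
  if (length(bad))
    stop("SWC format error at line ", nodes$line[bad[1]],
         ": parent id ", nodes$parent[bad[1]], " does not exist")
  skeleton(nodes[setdiff(names(nodes), "line")])
}

#' Construct and validate a skeleton
#'
#' @param nodes data frame with columns `id, type, x, y, z, radius, parent`
#'   (um units, `parent = -1` for roots).
#' @return A `skeleton` object.
#' @export
skeleton <- function(nodes) {
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(need %in% names(nodes))) stop("skeleton nodes need columns: ",
                                         paste(need, collapse = ", "))
  if (anyDuplicated(nodes$id)) stop("skeleton node ids must be unique")
  if (!all(nodes$parent == -1L | nodes$parent %in% nodes$id))
    stop("skeleton parent ids must refer to existing nodes")
  # acyclicity: walking up the parent chain must always reach a root
  idx <- match(nodes$parent, nodes$id)      # NA at roots
  state <- integer(nrow(nodes))             # 0 unseen, 1 in progress, 2 done
  for (s in seq_len(nrow(nodes))) {
    v <- s
    path <- integer(0)
    while (!is.na(v) && state[v] == 0L) {
      state[v] <- 1L
      path <- c(path, v)
      v <- idx[v]
    }
    if (!is.na(v) && state[v] == 1L) stop("skeleton contains a parent cycle")
    state[path] <- 2L
  }
  structure(list(nodes = nodes), class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("<skeleton, %d nodes, %d root(s)>\n", nrow(x$nodes),
              sum(x$nodes$parent == -1L)))
  invisible(x)
}

#' Write a skeleton to SWC
#'
#' @param s a [skeleton()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(s, path) {
  stopifnot(inherits(s, "skeleton"))
  n <- s$nodes
  lines <- sprintf("%d %d %.6g %.6g %.6g %.6g %d",
                   n$id, n$type, n$x, n$y, n$z, n$radius, n$parent)
  writeLines(c("# SWC written by arbordepth", lines), path)
  invisible(path)
}

#' Depth-profile CSV round trip
#'
#' The on-disk format is a header plus one row per bin: `depth_um, mass`.
#'
#' @param p a [depth_profile()] object.
#' @param path CSV path.
#' @return `write_profile_csv`: `path` invisibly; `read_profile_csv`: a
#'   `depth_profile` object.
#' @export
write_profile_csv <- function(p, path) {
  stopifnot(inherits(p, "depth_profile"))
  write.csv(data.frame(depth_um = p$depth, mass = p$mass), path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  d <- read.csv(path)
  if (!all(c("depth_um", "mass") %in% names(d)))
    stop("profile CSV needs columns depth_um, mass")
  new_depth_profile(d$depth_um, d$mass)
}
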