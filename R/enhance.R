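#' Convolutional enhancement-network architecture
#'
#' Describes a feed-forward network of 3-D convolutional filters with
#' all-to-all connectivity between consecutive layers and a sigmoid
#' nonlinearity after every layer. Filter sizes must be odd in every
#' dimension so that, with mirror padding, the output shape equals the input
#' shape. Fully connected layers are realized as 1 x 1 x 1 convolutions (their
#' dense equivalent), so inference stays convolutional.
#'
#' @param filters list of integer triples, one filter size per layer.
#' @param features integer vector of output feature-map counts per layer; the
#'   final entry should be 1 (the per-voxel neurite probability).
#' @return A `network_spec` object.
#' @seealso [rgc_network_spec()] for the stock 8-layer architecture.
#' @export
network_spec <- function(filters, features) {
  if (length(filters) < 1L) stop("need at least one layer")
  if (length(filters) != length(features))
    stop("`filters` and `features` must have one entry per layer")
  filters <- lapply(filters, function(f) {
    f <- as.integer(f)
    if (length(f) != 3L || any(f < 1L)) stop("filter sizes must be positive triples")
    if (any(f %% 2L == 0L)) stop("filter sizes must be odd in every dimension")
    f
  })
  features <- as.integer(features)
  if (any(features < 1L)) stop("feature counts must be >= 1")
  structure(list(filters = filters, features = features,
                 nonlinearity = "sigmoid"), class = "network_spec")
}

#' The stock 8-layer RGC enhancement architecture
#'
#' Eight layers with 8 feature maps in each hidden layer except the seventh,
#' which is a fully connected layer of 100 units (realized as a 1 x 1 x 1
#' convolution); per-layer filter sizes 5x5x1, 5x5x1, 3x3x3, 5x5x1, 3x3x3,
#' 3x3x3, 1x1x1, 1x1x1. Its receptive field is 19 x 19 x 7 voxels, i.e. the
#' patch consulted to decide whether the central voxel belongs to a neurite
#' (7.6 x 7.6 x 3.5 um at 0.4 x 0.4 x 0.5 um pitch).
#'
#' @return A [network_spec()].
#' @export
rgc_network_spec <- function() {
  network_spec(
    filters = list(c(5, 5, 1), c(5, 5, 1), c(3, 3, 3), c(5, 5, 1),
                   c(3, 3, 3), c(3, 3, 3), c(1, 1, 1), c(1, 1, 1)),
    features = c(8, 8, 8, 8, 8, 8, 100, 1))
}

#' Receptive field of a network spec
#'
#' Extent, per axis, of the input patch that influences a single output
#' voxel: `1 + sum(filter_size - 1)` over the layers.
#'
#' @param spec a [network_spec()].
#' @return Integer triple of voxel extents.
#' @examples
#' receptive_field(rgc_network_spec())   # 19 19 7
#' @export
receptive_field <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  ext <- c(1L, 1L, 1L)
  for (f in spec$filters) ext <- ext + (f - 1L)
  ext
}

#' Random or zero network weights
#'
#' Generates a dimensionally consistent parameter set for a spec: one array
#' of shape `(kx, ky, kz, c_in, c_out)` plus a bias vector per layer.
#'
#' @param spec a [network_spec()].
#' @param seed RNG seed.
#' @param sd standard deviation of the weight draws; 0 gives all-zero
#'   parameters.
#' @return A list of `list(w = array, b = numeric)` per layer.
#' @export
random_weights <- function(spec, seed = 1L, sd = 0.3) {
  stopifnot(inherits(spec, "network_spec"))
  set.seed(seed)
  cin <- 1L
  lapply(seq_along(spec$filters), function(l) {
    f <- spec$filters[[l]]
    cout <- spec$features[l]
    w <- array(rnorm(prod(f) * cin * cout, sd = sd), dim = c(f, cin, cout))
    b <- rnorm(cout, sd = sd)
    cin <<- cout
    list(w = w, b = b)
  })
}

#' Save / load a network parameter set
#'
#' A simple serialized tensor container (one `w` array and `b` vector per
#' layer).
#'
#' @param weights a parameter set as produced by [random_weights()].
#' @param path file path.
#' @return `load_weights` returns the parameter set.
#' @export
save_weights <- function(weights, path) {
  saveRDS(weights, path)
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(path) readRDS(path)

check_weights <- function(spec, weights) {
  if (length(weights) != length(spec$filters))
    stop("weights/spec mismatch: wrong number of layers")
  cin <- 1L
  for (l in seq_along(weights)) {
    w <- weights[[l]]$w
    f <- spec$filters[[l]]
    cout <- spec$features[l]
    if (!identical(as.integer(dim(w)), as.integer(c(f, cin, cout))))
      stop("weights/spec mismatch at layer ", l)
    if (length(weights[[l]]$b) != cout)
      stop("weights/spec mismatch at layer ", l, " (bias)")
    cin <- cout
  }
  invisible(TRUE)
}

#' Forward pass of the enhancement network
#'
#' Dense per-voxel inference: each layer is a cross-correlation with mirror
#' padding (so the output shape equals the input shape) followed by a
#' sigmoid. The final single feature map is the per-voxel neurite
#' probability.
#'
#' @param spec a [network_spec()].
#' @param weights a dimensionally consistent parameter set.
#' @param stack an [image_stack()] with values normalized to `[0, 1]`.
#' @return An [image_stack()] of probabilities in (0, 1) on the same grid.
#' @export
forward <- function(spec, weights, stack) {
  stopifnot(inherits(spec, "network_spec"), inherits(stack, "image_stack"))
  check_weights(spec, weights)
  if (max(stack$values) > 1 + 1e-12)
    stop("input must be normalized to [0, 1]")
  d <- dim(stack$values)
  cur <- as.numeric(stack$values)
  cin <- 1L
  for (l in seq_along(weights)) {
    cout <- spec$features[l]
    cur <- cpp_conv3d(cur, d, cin, as.numeric(weights[[l]]$w),
                      spec$filters[[l]], cout, as.numeric(weights[[l]]$b))
    cur <- 1 / (1 + exp(-cur))
    cin <- cout
  }
  if (cin != 1L) cur <- cur[seq_len(prod(d))]  # first map if spec ends wide
  image_stack(array(cur, dim = d), stack$grid, stack$role)
}

#' Threshold binarization at a fraction of the global maximum
#'
#' The enhancement baseline used when no trained network weights are
#' available: keep voxels whose intensity reaches `frac` of the stack's
#' maximum brightness (pipeline default 60%).
#'
#' @param stack an [image_stack()]; must not be identically zero.
#' @param frac fraction in (0, 1].
#' @return A [binary_volume()].
#' @export
threshold_binarize <- function(stack, frac = 0.6) {
  stopifnot(inherits(stack, "image_stack"))
  if (!is.numeric(frac) || frac <= 0 || frac > 1)
    stop("`frac` must be in (0, 1]")
  mx <- max(stack$values)
  if (mx == 0) stop("degenerate input: all-zero stack")
  binary_volume(stack$values >= frac * mx, stack$grid)
}
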