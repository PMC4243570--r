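#' Kaiser-Bessel gridding of depth samples
#'
#' Bins weighted depth samples onto a uniform 0.5 um grid using a
#' Kaiser-Bessel interpolation kernel (width 3 bins, shape beta = 6 by
#' default), the standard window for convolution-based gridding of
#' non-uniform samples. Each sample's kernel is normalized over the bins it
#' touches, so the total mass equals the total sample weight exactly.
#'
#' @param depths depth samples, um.
#' @param weights positive per-sample weights (volume compensation); recycled.
#' @param bin bin width, um.
#' @param support depth range covered by the grid, um.
#' @param kb_width kernel width in bins.
#' @param kb_beta kernel shape parameter.
#' @return A `depth_profile`: bin centres `depth`, per-bin `mass`,
#'   `normalized` flag.
#' @examples
#' p <- depth_profile(c(0, 0.1), c(1, 1))
#' sum(p$mass)  # 2: mass is conserved
#' @export
depth_profile <- function(depths, weights = 1, bin = 0.5,
                          support = c(-20, 25), kb_width = 3, kb_beta = 6) {
  depths <- as.numeric(depths)
  if (length(depths) == 0L) stop("degenerate input: empty point list")
  weights <- rep_len(as.numeric(weights), length(depths))
  if (any(!is.finite(depths)) || any(!is.finite(weights)))
    stop("depths and weights must be finite")
  if (any(weights <= 0)) stop("weights must be > 0")
  centres <- seq(support[1], support[2], by = bin)
  nb <- length(centres)
  pos <- (depths - support[1]) / bin + 1      # fractional bin coordinate
  half <- kb_width / 2
  kb <- function(un) {
    t <- 1 - (2 * un / kb_width)^2
    ifelse(t >= 0, besselI(kb_beta * sqrt(pmax(t, 0)), 0) / besselI(kb_beta, 0), 0)
  }
  offs <- seq.int(floor(-half) - 1L, ceiling(half) + 1L)
  J <- outer(floor(pos), offs, "+")
  Wk <- kb(J - pos)
  Wk[J < 1L | J > nb] <- 0
  rs <- rowSums(Wk)
  if (any(rs <= 0)) stop("depth sample falls outside the profile support")
  Wk <- Wk / rs * weights
  keep <- Wk > 0
  acc <- rowsum(Wk[keep], as.integer(J[keep]))
  mass <- numeric(nb)
  mass[as.integer(rownames(acc))] <- acc
  new_depth_profile(centres, mass)
}

new_depth_profile <- function(depth, mass, normalized = FALSE) {
  structure(list(depth = depth, mass = mass, normalized = normalized),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("<depth_profile %d bins [%g, %g] um, total mass %.4g%s>\n",
              length(x$depth), min(x$depth), max(x$depth), sum(x$mass),
              if (x$normalized) ", unit norm" else ""))
  invisible(x)
}

#' Normalize a profile to unit Euclidean norm
#'
#' The convention under which the profile SNR is defined; peak positions and
#' the crest factor are scale invariant, so only the SNR depends on it.
#'
#' @param p a [depth_profile()].
#' @return The normalized profile.
#' @export
normalize_profile <- function(p) {
  stopifnot(inherits(p, "depth_profile"))
  nrm <- sqrt(sum(p$mass^2))
  if (nrm == 0) stop("cannot normalize an all-zero profile")
  new_depth_profile(p$depth, p$mass / nrm, normalized = TRUE)
}

#' Drop the shallow (ganglion-cell side) part of a profile
#'
#' Used for the thresholding path, whose spurious build-ups near the
#' ganglion-cell layer are excluded by removing bins below `min_depth`
#' before peak detection.
#'
#' @param p a [depth_profile()].
#' @param min_depth keep bins with centre depth >= this value, um.
#' @return The truncated profile.
#' @export
truncate_profile <- function(p, min_depth = -6) {
  stopifnot(inherits(p, "depth_profile"))
  keep <- p$depth >= min_depth
  new_depth_profile(p$depth[keep], p$mass[keep], p$normalized)
}

#' Stratification peak positions of a profile
#'
#' The first peak is the depth (signed distance from the On starburst
#' surface) at which the profile achieves its maximum (ties break toward the
#' smaller depth). For bistratified cells a second peak is also reported: the
#' depth at least `exclusion` um away from the first (half the 12 um
#' starburst separation by default) at which the remaining profile is
#' maximal.
#'
#' @param p a nonempty [depth_profile()].
#' @param bistratified report a second peak?
#' @param exclusion minimum separation of the second peak, um.
#' @return A list `peak1`, `peak2` (NA when not requested or not available),
#'   `exclusion`.
#' @export
find_peaks <- function(p, bistratified = FALSE, exclusion = 6) {
  stopifnot(inherits(p, "depth_profile"))
  if (length(p$mass) == 0L) stop("empty profile")
  i1 <- which.max(p$mass)              # first maximum = smallest depth on ties
  peak1 <- p$depth[i1]
  peak2 <- NA_real_
  if (bistratified) {
    ok <- abs(p$depth - peak1) >= exclusion
    if (any(ok)) peak2 <- p$depth[ok][which.max(p$mass[ok])]
  }
  list(peak1 = peak1, peak2 = peak2, exclusion = exclusion)
}

#' Crest factor of a depth profile
#'
#' Peak amplitude divided by the root-mean-square value of the profile: a
#' scale-invariant measure of how extreme the stratification peak is
#' (sharper, more localized profiles score higher). A mean-value denominator
#' is available as a variant.
#'
#' @param p a [depth_profile()], not all zero.
#' @param denominator `"rms"` (the definition) or `"mean"`.
#' @return The crest factor (>= 1 for `"rms"` on nonnegative profiles).
#' @export
crest_factor <- function(p, denominator = c("rms", "mean")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(p, "depth_profile"))
  if (all(p$mass == 0)) stop("degenerate input: all-zero profile")
  pk <- max(p$mass)
  den <- if (denominator == "rms") sqrt(mean(p$mass^2)) else mean(p$mass)
  pk / den
}

#' Profile signal-to-noise ratio of a cell type
#'
#' The "signal" of a type is the average unit-normalized profile over its
#' cells; the "noise" of each cell is its deviation from the signal. The SNR
#' is the mean over cells of the Euclidean norm of the signal divided by the
#' Euclidean norm of that cell's noise.
#'
#' @param profiles a list of [depth_profile()]s or a bins x cells numeric
#'   matrix; at least 2 cells on a common depth grid. Profiles are
#'   unit-normalized internally.
#' @return The SNR.
#' @export
snr <- function(profiles) {
  M <- profiles_as_matrix(profiles)
  if (ncol(M) < 2L) stop("need at least 2 profiles")
  nrm <- sqrt(colSums(M^2))
  if (any(nrm == 0)) stop("degenerate input: all-zero profile")
  M <- sweep(M, 2, nrm, "/")
  sig <- rowMeans(M)
  signorm <- sqrt(sum(sig^2))
  noise <- sqrt(colSums((M - sig)^2))
  if (any(noise < 1e-12))
    stop("degenerate input: a profile equals the mean profile (infinite SNR)")
  mean(signorm / noise)
}

profiles_as_matrix <- function(profiles) {
  if (is.matrix(profiles)) return(profiles)
  if (inherits(profiles, "depth_profile")) profiles <- list(profiles)
  stopifnot(all(vapply(profiles, inherits, TRUE, "depth_profile")))
  nb <- vapply(profiles, function(p) length(p$mass), 1L)
  if (length(unique(nb)) != 1L) stop("profiles must share a depth grid")
  vapply(profiles, function(p) p$mass, numeric(nb[1]))
}

#' Confidence interval for a standard deviation
#'
#' The symmetrical 95% (by default) confidence interval for the population
#' standard deviation sigma of i.i.d. normal observations, given the sample
#' standard deviation `s` of `n` observations:
#' `[sqrt((n-1) s^2 / q_hi), sqrt((n-1) s^2 / q_lo)]` with `q` the
#' chi-squared quantiles of the tail probabilities.
#'
#' @param s sample standard deviation (um in the stratification analysis).
#' @param n sample size, >= 2.
#' @param level confidence level.
#' @return A list `s, n, lo, hi`.
#' @examples
#' sigma_ci(0.23, 15)
#' @export
sigma_ci <- function(s, n, level = 0.95) {
  if (n < 2) stop("usage error: need n >= 2")
  if (s < 0) stop("`s` must be >= 0")
  a <- (1 - level) / 2
  lo <- sqrt((n - 1) * s^2 / qchisq(1 - a, df = n - 1))
  hi <- sqrt((n - 1) * s^2 / qchisq(a, df = n - 1))
  list(s = s, n = as.integer(n), lo = lo, hi = hi)
}

#' Brown-Forsythe test for equality of variances
#'
#' One-way ANOVA F statistic computed on the absolute deviations from the
#' group medians, with the p-value from the upper tail of F(k-1, N-k). Used
#' to ask whether different reconstruction methods yield significantly
#' different variances of the peak stratification position.
#'
#' @param groups list of numeric vectors, each of length >= 2.
#' @return A list `statistic`, `p.value`, `df`.
#' @export
brown_forsythe <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2L))
    stop("each group needs at least 2 values")
  dev <- lapply(groups, function(x) abs(x - median(x)))
  k <- length(dev)
  n <- vapply(dev, length, 1L)
  N <- sum(n)
  m <- vapply(dev, mean, 1)
  grand <- sum(unlist(dev)) / N
  ssb <- sum(n * (m - grand)^2)
  ssw <- sum(vapply(seq_len(k), function(g) sum((dev[[g]] - m[g])^2), 1))
  if (ssw <= 0) stop("undefined statistic: zero within-group spread of deviations")
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  list(statistic = f, p.value = pf(f, k - 1, N - k, lower.tail = FALSE),
       df = c(k - 1, N - k))
}

#' Exact right-sided Wilcoxon signed-rank p-value
#'
#' For small samples the null distribution of the signed-rank statistic
#' `W+` (sum of the ranks of the positive differences) is enumerated over
#' all `2^n` sign assignments; the right-tail p-value is `P(W >= W+)`.
#'
#' @param diffs paired differences, `1 <= n <= 15`, none zero (the
#'   signed-rank statistic is undefined for zero differences; they are
#'   refused rather than silently dropped).
#' @return The exact right-tail p-value.
#' @examples
#' signed_rank_right_p(c(1, -2, -3))   # W+ = 1 of ranks {1,2,3}
#' @export
signed_rank_right_p <- function(diffs) {
  n <- length(diffs)
  if (n < 1L || n > 15L) stop("exact enumeration supports 1 <= n <= 15")
  if (any(diffs == 0)) stop("tie-handling error: zero difference")
  r <- rank(abs(diffs))
  wobs <- sum(r[diffs > 0])
  signs <- vapply(0:(2^n - 1), function(m) bitwAnd(m, 2^(0:(n - 1))) > 0,
                  logical(n))
  w <- colSums(matrix(r, n, 2^n) * signs)
  mean(w >= wobs - 1e-9)
}

#' Per-type summary of stratification statistics
#'
#' Aggregates per-cell depth profiles into the per-type table used to compare
#' reconstruction methods: peak position mean and SD (and second-peak
#' statistics for bistratified types), mean crest factor and profile SNR.
#'
#' @param profiles list of [depth_profile()]s.
#' @param types character vector of type labels, one per profile.
#' @param bistratified character vector of type labels with two peaks.
#' @param method method label stored in the output (e.g. `"trace"`,
#'   `"automated"`, `"threshold"`).
#' @param truncate_below if non-`NULL`, drop bins below this depth before
#'   peak detection (the threshold-path convention is -6 um).
#' @return A data frame with one row per type: `method, type, n, peak_mean,
#'   peak_sd, peak2_mean, peak2_sd, crest, snr`.
#' @export
type_summary <- function(profiles, types, bistratified = character(),
                         method = "automated", truncate_below = NULL) {
  stopifnot(length(profiles) == length(types))
  out <- lapply(unique(types), function(ty) {
    ps <- profiles[types == ty]
    if (!is.null(truncate_below))
      ps <- lapply(ps, truncate_profile, min_depth = truncate_below)
    bis <- ty %in% bistratified
    pk <- lapply(ps, find_peaks, bistratified = bis)
    p1 <- vapply(pk, `[[`, 1, "peak1")
    p2 <- vapply(pk, `[[`, 1, "peak2")
    data.frame(method = method, type = ty, n = length(ps),
               peak_mean = mean(p1), peak_sd = sd(p1),
               peak2_mean = if (bis) mean(p2) else NA_real_,
               peak2_sd = if (bis) sd(p2) else NA_real_,
               crest = mean(vapply(ps, crest_factor, 1)),
               snr = if (length(ps) >= 2) snr(ps) else NA_real_)
  })
  do.call(rbind, out)
}
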