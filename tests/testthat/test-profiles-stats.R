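test_that("gridding conserves mass and centres a single sample correctly", {
  p <- depth_profile(0, 1)
  expect_equal(sum(p$mass), 1, tolerance = 1e-12)
  expect_equal(p$depth[which.max(p$mass)], 0)
  expect_equal(diff(p$depth)[1], 0.5)

  set.seed(6)
  d <- runif(500, -15, 20)
  w <- runif(500, 0.5, 2)
  p2 <- depth_profile(d, w)
  expect_equal(sum(p2$mass), sum(w), tolerance = 1e-6 * sum(w))
  expect_error(depth_profile(numeric(0)), "empty")
})

test_that("Kaiser-Bessel gridding stays close to the nearest-bin histogram", {
  set.seed(3)
  d <- runif(1e4, -18, 23)
  w <- rep(1, 1e4)
  p <- depth_profile(d, w)
  nb <- nearest_bin_hist(d, w)
  expect_lt(sum(abs(p$mass - nb)), 0.05 * sum(w))
})

test_that("unit normalization holds exactly and is idempotent", {
  p <- normalize_profile(depth_profile(c(1, 4, 4.2), c(2, 1, 3)))
  expect_equal(sqrt(sum(p$mass^2)), 1, tolerance = 1e-9)
  expect_true(p$normalized)
  expect_equal(normalize_profile(p)$mass, p$mass)
})

test_that("peak detection: bistratified, tie and shift behaviour", {
  # bimodal profile with modes at the BDa strata (0.3 and 12.3 um)
  set.seed(9)
  d <- c(rnorm(4000, 0.3, 0.4), rnorm(3000, 12.3, 0.4))
  p <- depth_profile(d, 1)
  pk <- find_peaks(p, bistratified = TRUE)
  expect_equal(sort(c(pk$peak1, pk$peak2)), c(0.5, 12.5), tolerance = 0.3)
  expect_gte(abs(pk$peak2 - pk$peak1), 6)

  # unimodal at 5.5: second peak is the best bin of the excluded-region tail
  d2 <- rnorm(5000, 5.5, 0.8)
  p2 <- depth_profile(d2, 1)
  pk2 <- find_peaks(p2, bistratified = TRUE)
  expect_equal(pk2$peak1, 5.5)
  ok <- abs(p2$depth - pk2$peak1) >= 6
  expect_equal(pk2$peak2, p2$depth[ok][which.max(p2$mass[ok])])

  # exact tie breaks toward the smaller depth
  m <- numeric(91)
  m[c(20, 60)] <- 7
  pt <- find_peaks(arbordepth:::new_depth_profile(seq(-20, 25, 0.5), m))
  expect_equal(pt$peak1, seq(-20, 25, 0.5)[20])

  # shift equivariance
  d3 <- d2 + 2
  pk3 <- find_peaks(depth_profile(d3, 1))
  expect_equal(pk3$peak1, pk2$peak1 + 2)
})

test_that("crest factor matches hand-computed values and is scale invariant", {
  const <- arbordepth:::new_depth_profile(1:100 / 2, rep(3, 100))
  expect_equal(crest_factor(const), 1)
  single <- arbordepth:::new_depth_profile(1:100 / 2, c(5, rep(0, 99)))
  expect_equal(crest_factor(single), 10)     # peak / (peak / sqrt(100))
  set.seed(2)
  p <- arbordepth:::new_depth_profile(1:50, runif(50))
  expect_equal(crest_factor(p), crest_factor(
    arbordepth:::new_depth_profile(1:50, 7.3 * p$mass)))
  expect_gt(crest_factor(p, denominator = "mean"), 0)
  expect_error(crest_factor(arbordepth:::new_depth_profile(1:3, c(0, 0, 0))),
               "all-zero")
})

test_that("SNR equals 1 for two orthogonal profiles and diverges as noise vanishes", {
  a <- c(1, rep(0, 9)); b <- c(0, 1, rep(0, 8))
  expect_equal(snr(cbind(a, b)), 1, tolerance = 1e-12)
  # signal + epsilon * orthogonal perturbations: SNR grows monotonically in 1/eps
  sig <- rep(1 / sqrt(10), 10)
  pert <- c(1, -1, rep(0, 8)) / sqrt(2)
  vals <- vapply(c(0.3, 0.1, 0.03), function(eps)
    snr(cbind(sig + eps * pert, sig - eps * pert)), 1)
  expect_true(all(diff(vals) > 0))
  expect_error(snr(cbind(sig, sig)), "degenerate")
})

test_that("sigma confidence intervals match the chi-squared closed form", {
  z <- sigma_ci(0, 15)
  expect_equal(c(z$lo, z$hi), c(0, 0))
  ci <- sigma_ci(0.23, 15)
  expect_equal(ci$lo, 0.1684, tolerance = 1e-3)
  expect_equal(ci$hi, 0.3627, tolerance = 1e-3)
  expect_true(ci$lo <= ci$s && ci$s <= ci$hi)
  wide <- sigma_ci(0.4, 10); narrow <- sigma_ci(0.4, 100)
  expect_lt(narrow$hi - narrow$lo, wide$hi - wide$lo)
  expect_error(sigma_ci(0.2, 1), "n >= 2")
})

test_that("Brown-Forsythe matches an arithmetic oracle and an independent implementation", {
  g1 <- c(1, 2, 3, 4); g2 <- c(2, 4, 6, 8)
  bf <- brown_forsythe(list(g1, g2))
  # arithmetic oracle on the 8 numbers: ANOVA of |x - median| by hand
  d1 <- abs(g1 - 2.5); d2 <- abs(g2 - 5)
  m1 <- mean(d1); m2 <- mean(d2); gm <- mean(c(d1, d2))
  ssb <- 4 * (m1 - gm)^2 + 4 * (m2 - gm)^2
  ssw <- sum((d1 - m1)^2) + sum((d2 - m2)^2)
  f_hand <- (ssb / 1) / (ssw / 6)
  expect_equal(bf$statistic, f_hand, tolerance = 1e-12)
  expect_equal(bf$p.value, pf(f_hand, 1, 6, lower.tail = FALSE))

  # identical deviation sets in both groups -> F = 0, p = 1
  same <- brown_forsythe(list(c(1, 2, 3), c(11, 12, 13)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  skip_if_not_installed("car")
  set.seed(12)
  gs <- list(rnorm(9), rnorm(11, sd = 2), rnorm(8))
  mine <- brown_forsythe(gs)
  dfr <- data.frame(y = unlist(gs),
                    g = factor(rep(seq_along(gs), lengths(gs))))
  ref <- car::leveneTest(y ~ g, data = dfr, center = median)
  expect_equal(mine$statistic, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(mine$p.value, ref$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("exact signed-rank p-values match the quoted case and wilcox.test", {
  # n = 3 with W+ = 2: 6 of the 8 sign patterns reach W >= 2
  expect_equal(signed_rank_right_p(c(-1, 2, -3)), 0.75)
  expect_equal(signed_rank_right_p(c(-1, -2, -3)), 1.0)
  set.seed(15)
  d <- round(rnorm(10), 3)
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  ref <- wilcox.test(d, alternative = "greater", exact = TRUE)$p.value
  expect_equal(signed_rank_right_p(d), ref, tolerance = 1e-12)
  expect_error(signed_rank_right_p(c(1, 0, 2)), "zero difference")
})

test_that("profile truncation implements the threshold-path rule", {
  set.seed(1)
  p <- depth_profile(runif(200, -15, 20), 1)
  tp <- truncate_profile(p, -6)
  expect_true(all(tp$depth >= -6))
  expect_equal(tp$mass, p$mass[p$depth >= -6])
})

test_that("type summaries aggregate peaks, crest and SNR per type", {
  set.seed(30)
  mk <- function(mu) depth_profile(rnorm(2000, mu, 0.5), 1)
  profs <- c(lapply(c(5.5, 5.4, 5.6), mk), lapply(c(15.5, 15.7), mk))
  tab <- type_summary(profs, c("W3", "W3", "W3", "JAMB", "JAMB"))
  expect_equal(nrow(tab), 2)
  w3 <- tab[tab$type == "W3", ]
  expect_equal(w3$n, 3)
  expect_lt(abs(w3$peak_mean - 5.5), 0.3)
  expect_gt(w3$crest, 1)
  expect_gt(w3$snr, 1)
})
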