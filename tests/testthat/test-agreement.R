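test_that("event matching applies the tolerance and the rate formula", {
  m <- match_events(1.000, 1.004, tol_s = 0.020)
  expect_equal(m$tp, 1L)
  expect_equal(m$matched$error_s, -0.004)

  m2 <- match_events(1.000, 1.050, tol_s = 0.020)
  expect_equal(c(m2$tp, m2$fn, m2$fp), c(0L, 1L, 1L))

  # 69 of 80 reference events matched -> 86.25%
  ref <- seq_len(80)
  det <- ref[1:69] + 0.003
  m3 <- match_events(det, ref)
  expect_equal(m3$detection_rate, 86.25)
  expect_equal(m3$tp + m3$fn, 80L)
})

test_that("matching is greedy one-to-one by smallest time error", {
  # one detection between two references pairs with the closer one
  m <- match_events(c(1.001, 1.015), c(1.000, 1.014))
  expect_equal(m$matched$det_time_s, c(1.001, 1.015))
  expect_equal(m$tp, 2L)
  # shifting both lists together changes nothing
  m_shift <- match_events(c(1.001, 1.015) + 50, c(1.000, 1.014) + 50)
  expect_equal(m_shift$matched$error_s, m$matched$error_s)
  expect_equal(m_shift$tp, m$tp)
})

test_that("CV% (RMS) matches hand evaluation and is scale invariant", {
  expect_equal(cv_percent_rms(cbind(c(1, 2, 3), c(1, 2, 3))), 0)
  single <- cv_percent_rms(cbind(0.80, 0.82))
  expect_equal(single, 100 * 0.02 / (sqrt(2) * 0.81), tolerance = 1e-12)
  expect_equal(round(single, 3), 1.746)
  set.seed(3)
  p <- cbind(runif(10, 0.5, 1), runif(10, 0.5, 1))
  expect_equal(cv_percent_rms(p), cv_percent_rms(p * 7.3), tolerance = 1e-12)
})

test_that("ICC(3,1) equals the ANOVA mean-squares oracle and frozen value", {
  x <- c(0.81, 0.75, 0.90, 0.66, 0.84, 0.79, 0.88, 0.72)
  y <- c(0.83, 0.74, 0.93, 0.67, 0.82, 0.80, 0.90, 0.70)
  out <- icc_3_1(cbind(x, y))
  # brute-force two-way ANOVA oracle
  p <- cbind(x, y); n <- 8; k <- 2
  grand <- mean(p)
  msr <- k * sum((rowMeans(p) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(p) - grand)^2) / (k - 1)
  mse <- (sum((p - grand)^2) - msr * (n - 1) - msc * (k - 1)) /
    ((n - 1) * (k - 1))
  expect_equal(out$icc, (msr - mse) / (msr + mse), tolerance = 1e-12)
  expect_equal(out$icc, 0.975256, tolerance = 1e-6)   # frozen external oracle
  expect_equal(round(out$ci95, 2), c(0.88, 0.99))

  # identical columns (with subject variance) give ICC 1
  expect_equal(icc_3_1(cbind(x, x))$icc, 1)
  # consistency form ignores a constant rater offset
  expect_equal(icc_3_1(cbind(x, x + 0.3))$icc, 1)
  # no between-subject variance is undefined
  expect_warning(out0 <- icc_3_1(cbind(rep(1, 5), rep(1, 5))), "undefined")
  expect_true(is.na(out0$icc))
})

test_that("weighted kappa matches frozen external oracle values", {
  # pairs whose 0.04 s binning yields the 3x3 table
  # [[5,2,0],[1,6,2],[0,1,5]] over bins centred at 0.02, 0.06, 0.10
  O <- matrix(c(5, 1, 0, 2, 6, 1, 0, 2, 5), 3)
  centres <- c(0.02, 0.06, 0.10)
  pairs <- do.call(rbind, lapply(1:3, function(i) do.call(rbind, lapply(1:3,
    function(j) if (O[i, j] > 0)
      matrix(rep(c(centres[i], centres[j]), O[i, j]), ncol = 2, byrow = TRUE)))))
  q <- weighted_kappa(pairs)
  expect_equal(q$kappa, 0.7700348432055749, tolerance = 1e-10)
  expect_equal(q$se, 0.09079086500745985, tolerance = 1e-8)
  l <- weighted_kappa(pairs, weights = "linear")
  expect_equal(l$kappa, 0.6732673267326733, tolerance = 1e-10)
  expect_equal(l$se, 0.12035468721379619, tolerance = 1e-8)
})

test_that("weighted kappa limiting cases and symmetries hold", {
  x <- c(0.02, 0.06, 0.10, 0.14, 0.02, 0.06)
  expect_equal(weighted_kappa(cbind(x, x))$kappa, 1)
  # independent margins: observed equals expected -> kappa 0
  ind <- cbind(rep(c(0.02, 0.06), each = 4),
               rep(c(0.02, 0.06), times = 4))
  expect_equal(weighted_kappa(ind)$kappa, 0, tolerance = 1e-12)
  # reversing the bin order (negating timings) leaves kappa unchanged
  set.seed(8)
  p <- cbind(runif(20, 0.4, 0.9), runif(20, 0.4, 0.9))
  expect_equal(weighted_kappa(p)$kappa, weighted_kappa(-p)$kappa,
               tolerance = 1e-12)
  expect_warning(one <- weighted_kappa(cbind(c(0.01, 0.02), c(0.011, 0.02))),
                 "one bin")
  expect_true(is.na(one$kappa))
})

test_that("Bland-Altman agrees with direct formula evaluation", {
  x <- c(0.80, 0.75, 0.90, 0.66)
  ba0 <- bland_altman(cbind(x, x))
  expect_equal(ba0$mean_diff, 0)
  expect_equal(diff(ba0$loa), 0)

  bac <- bland_altman(cbind(x, x + 0.05))
  expect_equal(bac$mean_diff, 0.05)
  expect_equal(bac$sd_diff, 0)

  set.seed(12)
  p <- cbind(rnorm(15, 0.8, 0.1), rnorm(15, 0.8, 0.1))
  ba <- bland_altman(p)
  d <- p[, 2] - p[, 1]
  expect_equal(ba$mean_diff, mean(d))
  expect_equal(ba$loa, mean(d) + c(-1.96, 1.96) * sd(d))
  expect_equal(ba$ci_mean,
               mean(d) + c(-1, 1) * qt(0.975, 14) * sd(d) / sqrt(15))
  expect_equal(ba$ci_loa_upper,
               mean(d) + 1.96 * sd(d) + c(-1, 1) * qt(0.975, 14) *
                 sd(d) * sqrt(3 / 15))
})

test_that("Spearman correlation handles monotone maps, ties and base R", {
  x <- c(0.5, 0.6, 0.7, 0.9)
  expect_equal(spearman_rho(cbind(x, exp(x)))$rho, 1)
  expect_equal(spearman_rho(cbind(x, -x))$rho, -1)
  tied <- cbind(c(1, 2, 2, 3, 4), c(2, 1, 3, 3, 5))
  mine <- spearman_rho(tied)
  expect_equal(mine$rho, cor(rank(tied[, 1]), rank(tied[, 2])),
               tolerance = 1e-12)
  expect_equal(mine$rho, cor(tied[, 1], tied[, 2], method = "spearman"),
               tolerance = 1e-12)
  const <- spearman_rho(cbind(rep(1, 4), 1:4))
  expect_true(is.na(const$rho))
})

test_that("Mann-Whitney matches enumeration and wilcox.test", {
  # all of A below all of B forces U = 0 for A
  expect_equal(mann_whitney(1:3, 11:13)$u, 0)
  # identical groups: the observed U sits at the distribution centre
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # exact path equals wilcox.test's exact two-sided p without ties
  set.seed(2)
  a <- rnorm(5); b <- rnorm(6) + 0.5
  mine <- mann_whitney(a, b)
  ref <- wilcox.test(a, b, exact = TRUE)
  expect_equal(mine$u, unname(ref$statistic))
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  # large-sample path tracks the tie-corrected normal approximation
  set.seed(4)
  a2 <- round(rnorm(20), 1); b2 <- round(rnorm(25) + 0.3, 1)
  mine2 <- mann_whitney(a2, b2)
  ref2 <- wilcox.test(a2, b2, exact = FALSE, correct = TRUE)
  expect_equal(mine2$u, unname(ref2$statistic))
  expect_equal(mine2$p_value, ref2$p.value, tolerance = 1e-9)
})

test_that("the bundled agreement report reproduces its parts", {
  set.seed(19)
  ref <- rnorm(30, 0.8, 0.08)
  sys <- ref + rnorm(30, 0.005, 0.02)
  rep <- agreement_report(cbind(ref, sys))
  expect_equal(rep$n, 30L)
  expect_equal(rep$cv_percent, cv_percent_rms(cbind(ref, sys)))
  expect_equal(rep$icc, icc_3_1(cbind(ref, sys))$icc)
  expect_gt(rep$rho, 0.8)
  expect_gt(rep$icc, 0.9)
  expect_lt(rep$cv_percent, 5)
})
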