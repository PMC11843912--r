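# Detection accounting and inter-method agreement statistics. The installed
# R stack has no ICC / weighted-kappa / CV%RMS implementation, so these
# follow the standard constructions (Shrout-Fleiss; Fleiss-Cohen-Everitt SE;
# RMS coefficient of variation for paired repeated measurements).

#' Match detected events against reference annotations
#'
#' Greedy one-to-one matching by smallest absolute time difference within
#' `tol_s`. Unmatched reference events are false negatives; unmatched
#' detections are false positives. The detection rate is
#' `100 * TP / (TP + FN)`.
#'
#' @param detected,reference sorted numeric vectors of event times (s).
#' @param tol_s matching tolerance in seconds (default 0.020, five times the
#'   4 ms reference-video frame error).
#' @return a `match_result`: list with `tp`, `fn`, `fp`, `matched` (data
#'   frame `ref_time_s`, `det_time_s`, `error_s`), `detection_rate` (%).
#' @export
match_events <- function(detected, reference, tol_s = 0.020) {
  detected <- as.numeric(detected)
  reference <- as.numeric(reference)
  pairs <- expand.grid(d = seq_along(detected), r = seq_along(reference))
  if (nrow(pairs)) {
    pairs$err <- abs(detected[pairs$d] - reference[pairs$r])
    pairs <- pairs[pairs$err <= tol_s, , drop = FALSE]
    pairs <- pairs[order(pairs$err), , drop = FALSE]
  }
  used_d <- logical(length(detected))
  used_r <- logical(length(reference))
  keep <- integer(0)
  for (i in seq_len(nrow(pairs))) {
    d <- pairs$d[i]; r <- pairs$r[i]
    if (!used_d[d] && !used_r[r]) {
      used_d[d] <- TRUE; used_r[r] <- TRUE; keep <- c(keep, i)
    }
  }
  m <- pairs[keep, , drop = FALSE]
  matched <- data.frame(ref_time_s = reference[m$r],
                        det_time_s = detected[m$d],
                        error_s = detected[m$d] - reference[m$r])
  matched <- matched[order(matched$ref_time_s), , drop = FALSE]
  rownames(matched) <- NULL
  tp <- nrow(matched)
  structure(list(tp = tp, fn = length(reference) - tp,
                 fp = length(detected) - tp, matched = matched,
                 detection_rate = if (length(reference))
                   100 * tp / length(reference) else NA_real_),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> TP %d, FN %d, FP %d; detection rate %.2f%%\n",
              x$tp, x$fn, x$fp, x$detection_rate))
  invisible(x)
}

as_pair_matrix <- function(pairs) {
  p <- as.matrix(as.data.frame(pairs))
  stopifnot(ncol(p) == 2, all(is.finite(p)))
  p
}

#' Coefficient of variation for paired measurements (RMS method)
#'
#' `CV% = 100 * sqrt(mean(d_i^2 / (2 * m_i^2)))` over pairs with difference
#' `d_i` and pair mean `m_i`. Pairs with zero mean are excluded with a
#' warning.
#'
#' @param pairs two-column matrix/data frame of paired measurements.
#' @return CV as a percentage.
#' @export
cv_percent_rms <- function(pairs) {
  p <- as_pair_matrix(pairs)
  d <- p[, 1] - p[, 2]
  m <- rowMeans(p)
  if (any(m == 0)) {
    warnf("cv_percent_rms: %d pair(s) with zero mean excluded", sum(m == 0))
    d <- d[m != 0]; m <- m[m != 0]
  }
  if (!length(m)) return(NA_real_)
  100 * sqrt(mean(d^2 / (2 * m^2)))
}

#' Intraclass correlation ICC(3,1) with 95% CI
#'
#' Two-way mixed model, single rater, consistency:
#' `(MS_R - MS_E) / (MS_R + (k-1) MS_E)` with k = 2 raters; the confidence
#' interval follows the Shrout-Fleiss F-bound construction.
#'
#' @param pairs two-column matrix/data frame (n >= 3 rows).
#' @return list with `icc`, `ci95` (length-2), and the mean squares.
#' @export
icc_3_1 <- function(pairs) {
  p <- as_pair_matrix(pairs)
  n <- nrow(p); k <- ncol(p)
  if (n < 3) stopf("need at least 3 pairs")
  grand <- mean(p)
  ss_rows <- k * sum((rowMeans(p) - grand)^2)
  ss_cols <- n * sum((colMeans(p) - grand)^2)
  ss_tot <- sum((p - grand)^2)
  ms_r <- ss_rows / (n - 1)
  ms_c <- ss_cols / (k - 1)
  ms_e <- (ss_tot - ss_rows - ss_cols) / ((n - 1) * (k - 1))
  if (ms_r <= 0) {
    warnf("zero between-subject variance: ICC undefined")
    return(list(icc = NA_real_, ci95 = c(NA_real_, NA_real_),
                ms_rows = ms_r, ms_cols = ms_c, ms_error = ms_e))
  }
  icc <- (ms_r - ms_e) / (ms_r + (k - 1) * ms_e)
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  if (ms_e > 0) {
    f <- ms_r / ms_e
    fl <- f / stats::qf(0.975, df1, df2)
    fu <- f * stats::qf(0.975, df2, df1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  } else ci <- c(1, 1)
  list(icc = icc, ci95 = ci, ms_rows = ms_r, ms_cols = ms_c, ms_error = ms_e)
}

#' Cohen's weighted kappa with standard error for binned timings
#'
#' Continuous paired timings are binned on a common grid of width
#' `bin_width_s`; kappa uses quadratic (default) or linear disagreement
#' weights, `kappa = 1 - sum(w O) / sum(w E)`; the standard error is the
#' Fleiss-Cohen-Everitt large-sample form.
#'
#' @param pairs two-column matrix/data frame of paired timings (s).
#' @param bin_width_s bin width in seconds (default 0.04).
#' @param weights `"quadratic"` (default) or `"linear"`.
#' @return list with `kappa`, `se`, `n_bins`, `bin_width_s`, `weights`.
#' @export
weighted_kappa <- function(pairs, bin_width_s = 0.04,
                           weights = c("quadratic", "linear")) {
  weights <- match.arg(weights)
  p <- as_pair_matrix(pairs)
  lo <- floor(min(p) / bin_width_s) * bin_width_s
  hi <- ceiling(max(p) / bin_width_s + 1e-9) * bin_width_s
  breaks <- seq(lo, hi + bin_width_s / 2, by = bin_width_s)
  b1 <- cut(p[, 1], breaks, include.lowest = TRUE, labels = FALSE)
  b2 <- cut(p[, 2], breaks, include.lowest = TRUE, labels = FALSE)
  nk <- length(breaks) - 1L
  if (length(unique(c(b1, b2))) < 2) {
    warnf("all timings fall in one bin: kappa undefined")
    return(list(kappa = NA_real_, se = NA_real_, n_bins = nk,
                bin_width_s = bin_width_s, weights = weights))
  }
  kappa_se_weighted(b1, b2, nk, weights, bin_width_s)
}

# kappa + SE on binned categories; agreement weights v = 1 - disagreement
kappa_se_weighted <- function(b1, b2, nk, weights, bin_width_s) {
  n <- length(b1)
  O <- matrix(0, nk, nk)
  for (i in seq_len(n)) O[b1[i], b2[i]] <- O[b1[i], b2[i]] + 1
  P <- O / n
  ri <- rowSums(P); cj <- colSums(P)
  dis <- abs(outer(seq_len(nk), seq_len(nk), "-")) / (nk - 1)
  if (weights == "quadratic") dis <- dis^2
  v <- 1 - dis
  po <- sum(v * P)
  pe <- sum(v * outer(ri, cj))
  kappa <- (po - pe) / (1 - pe)
  vi <- as.vector(v %*% cj)        # v_i. = sum_j v_ij c_j
  vj <- as.vector(ri %*% v)        # v_.j = sum_i r_i v_ij
  term <- (v * (1 - pe) - outer(vi, vj, "+") * (1 - po))^2
  var_k <- (sum(P * term) - (po * pe - 2 * pe + po)^2) / (n * (1 - pe)^4)
  list(kappa = kappa, se = sqrt(max(var_k, 0)), n_bins = nk,
       bin_width_s = bin_width_s, weights = weights)
}

#' Bland-Altman agreement analysis
#'
#' Differences are system minus reference (second minus first column). The
#' CI of the mean difference uses the t quantile; the CIs of the limits of
#' agreement use the standard `SD * sqrt(3/n)` standard error.
#'
#' @param pairs two-column matrix/data frame `(reference, system)`, n >= 2.
#' @return list with `mean_diff`, `sd_diff`, `loa` (lower, upper),
#'   `ci_mean`, `ci_loa_lower`, `ci_loa_upper`.
#' @export
bland_altman <- function(pairs) {
  p <- as_pair_matrix(pairs)
  if (nrow(p) < 2) stopf("need at least 2 pairs")
  d <- p[, 2] - p[, 1]
  n <- length(d)
  md <- mean(d); sd_d <- stats::sd(d)
  tq <- stats::qt(0.975, n - 1)
  loa <- md + c(-1, 1) * 1.96 * sd_d
  se_loa <- sd_d * sqrt(3 / n)
  list(mean_diff = md, sd_diff = sd_d, loa = loa,
       ci_mean = md + c(-1, 1) * tq * sd_d / sqrt(n),
       ci_loa_lower = loa[1] + c(-1, 1) * tq * se_loa,
       ci_loa_upper = loa[2] + c(-1, 1) * tq * se_loa)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of mid-ranks (tie-aware); two-sided p from the
#' t distribution with n - 2 degrees of freedom.
#'
#' @param pairs two-column matrix/data frame (n >= 3).
#' @return list with `rho`, `p_value`, `n`.
#' @export
spearman_rho <- function(pairs) {
  p <- as_pair_matrix(pairs)
  n <- nrow(p)
  if (n < 3) stopf("need at least 3 pairs")
  r1 <- rank(p[, 1]); r2 <- rank(p[, 2])
  if (stats::sd(r1) == 0 || stats::sd(r2) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  rho <- stats::cor(r1, r2)
  if (abs(rho) >= 1) return(list(rho = rho, p_value = 0, n = n))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p_value = 2 * stats::pt(-abs(tstat), n - 2), n = n)
}

#' Mann-Whitney U test
#'
#' Rank-sum U for group A with a two-sided p-value: exact enumeration of
#' rank assignments when both groups have <= 8 observations (tie-aware),
#' otherwise the tie-corrected normal approximation with continuity
#' correction.
#'
#' @param a,b numeric vectors (non-empty).
#' @return list with `u` (for group `a`), `p_value`, `method`.
#' @export
mann_whitney <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  u_a <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (max(na, nb) <= 8) {
    combos <- utils::combn(n, na)
    us <- apply(combos, 2, function(idx) sum(r[idx])) - na * (na + 1) / 2
    mu <- mean(us)
    p <- mean(abs(us - mu) >= abs(u_a - mu) - 1e-12)
    return(list(u = u_a, p_value = p, method = "exact enumeration"))
  }
  mu <- na * nb / 2
  ties <- table(r)
  sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (u_a - mu - sign(u_a - mu) * 0.5) / sqrt(sigma2)
  list(u = u_a, p_value = 2 * stats::pnorm(-abs(z)),
       method = "normal approximation (tie-corrected)")
}

#' Full agreement report for paired timings
#'
#' Bundles the agreement statistics into one object mirroring the reported
#' table layout (n, median, IQR, Spearman rho, CV%, ICC + CI, kappa + SE).
#'
#' @param pairs two-column matrix/data frame `(reference, system)` of paired
#'   timings in seconds.
#' @param bin_width_s kappa bin width (default 0.04 s).
#' @return an `agreement_report` list.
#' @export
agreement_report <- function(pairs, bin_width_s = 0.04) {
  p <- as_pair_matrix(pairs)
  icc <- icc_3_1(p)
  kap <- weighted_kappa(p, bin_width_s)
  sp <- spearman_rho(p)
  mw <- mann_whitney(p[, 1], p[, 2])
  structure(list(
    n = nrow(p),
    median_reference = stats::median(p[, 1]),
    iqr_reference = unname(diff(stats::quantile(p[, 1], c(0.25, 0.75)))),
    median_system = stats::median(p[, 2]),
    iqr_system = unname(diff(stats::quantile(p[, 2], c(0.25, 0.75)))),
    rho = sp$rho, rho_p = sp$p_value,
    cv_percent = cv_percent_rms(p),
    icc = icc$icc, icc_ci95 = icc$ci95,
    kappa = kap$kappa, kappa_se = kap$se,
    mann_whitney_u = mw$u, mann_whitney_p = mw$p_value,
    bland_altman = bland_altman(p)), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    paste0("<agreement_report> n = %d\n",
           "  median (ref) %.3f; IQR %.3f | median (sys) %.3f; IQR %.3f\n",
           "  rho = %.3f (p = %.3g), CV%% = %.2f, ICC(3,1) = %.3f ",
           "[%.3f, %.3f]\n  kappa = %.3f (SE %.3f), Mann-Whitney p = %.3g\n",
           "  Bland-Altman mean diff %.4f s, LoA [%.4f, %.4f]\n"),
    x$n, x$median_reference, x$iqr_reference, x$median_system, x$iqr_system,
    x$rho, x$rho_p, x$cv_percent, x$icc, x$icc_ci95[1], x$icc_ci95[2],
    x$kappa, x$kappa_se, x$mann_whitney_p,
    x$bland_altman$mean_diff, x$bland_altman$loa[1], x$bland_altman$loa[2]))
  invisible(x)
}
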