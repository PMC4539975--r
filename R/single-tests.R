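## Single-table association statistics: CATT, Pearson 2-df, allele-based
## test, and the Hardy-Weinberg disequilibrium trend test, plus the plug-in
## null correlations among them that the model-selection p-values need.

rr_test_result <- function(label, statistic, p_value, df = NA_real_,
                           score = NA_real_) {
  structure(list(label = label, statistic = statistic, p_value = p_value,
                 df = df, score = score),
            class = "rr_test")
}

#' @export
print.rr_test <- function(x, ...) {
  cat(x$label,
      if (!is.na(x$score)) sprintf("(score x = %g)", x$score),
      sprintf(": statistic = %.4f, p = %.4g", x$statistic, x$p_value),
      if (!is.na(x$df)) sprintf("on %g df", x$df), "\n")
  invisible(x)
}

#' Cochran-Armitage trend test
#'
#' Score test on the 2x3 genotype table with scores `(0, x, 1)` for
#' `(AA, AB, BB)`.  `x = 0`, `1/2` and `1` are optimal for recessive,
#' additive/multiplicative, and dominant penetrance models.  The statistic
#' is standard normal under the null; its sign is positive when the `B`
#' allele is over-represented in cases under that scoring.
#'
#' @param counts A [genotype_counts()] object.
#' @param x Heterozygote score in `[0, 1]`.
#' @return An `"rr_test"` object with `statistic` (z) and two-sided
#'   `p_value` = `2 * (1 - pnorm(|z|))`.
#' @examples
#' catt(genotype_counts(c(10, 10, 20), c(20, 10, 10)), x = 1)
#' @export
catt <- function(counts, x = 0.5) {
  check_testable(counts)
  if (!is.numeric(x) || length(x) != 1L || x < 0 || x > 1)
    rr_stop("score x must be in [0, 1]", "rr_input_error")
  z <- zcatt_vec(counts_row(counts), x)
  if (!is.finite(z))
    rr_stop("trend test undefined: zero variance of genotype scores",
            "rr_degenerate_error")
  rr_test_result("CATT", z, 2 * stats::pnorm(-abs(z)), score = x)
}

#' Pearson's chi-square test on the 2x3 genotype table
#'
#' General association test comparing the full genotype distributions of
#' cases and controls; asymptotically chi-square with 2 df.  A pooled
#' genotype class with zero count contributes nothing and drops one degree
#' of freedom.
#'
#' @inheritParams catt
#' @return An `"rr_test"` with `statistic` (chi-square), `df`, and upper
#'   tail `p_value`.
#' @export
pearson_chi2 <- function(counts) {
  check_testable(counts)
  keep <- counts$n_geno > 0
  df <- sum(keep) - 1L
  if (df < 1L)
    rr_stop("chi-square test undefined for a single genotype class",
            "rr_degenerate_error")
  r <- counts$n_cases; s <- counts$n_controls; n <- counts$n
  er <- counts$n_geno * r / n
  es <- counts$n_geno * s / n
  stat <- sum(((counts$r - er)^2 / er + (counts$s - es)^2 / es)[keep])
  rr_test_result("chi2", stat, stats::pchisq(stat, df, lower.tail = FALSE),
                 df = df)
}

#' Allele-based test
#'
#' Two-sample z-test comparing the `B` allele frequencies of cases and
#' controls with the pooled-variance estimate.  The standard-normal null
#' distribution is valid only under Hardy-Weinberg equilibrium; without HWE
#' the correlation between an individual's two alleles invalidates it, which
#' is the usual reason to prefer the trend test.
#'
#' @inheritParams catt
#' @return An `"rr_test"` with z `statistic` and two-sided `p_value`.
#' @export
abt <- function(counts) {
  check_testable(counts)
  r <- counts$n_cases; s <- counts$n_controls; n <- counts$n
  bp <- (2 * counts$r[3] + counts$r[2]) / (2 * r)
  bq <- (2 * counts$s[3] + counts$s[2]) / (2 * s)
  pb <- (2 * counts$n_geno[3] + counts$n_geno[2]) / (2 * n)
  v <- pb * (1 - pb) * (1 / (2 * r) + 1 / (2 * s))
  if (v <= 0)
    rr_stop("allele-based test undefined: pooled allele frequency is 0 or 1",
            "rr_degenerate_error")
  z <- (bp - bq) / sqrt(v)
  rr_test_result("ABT", z, 2 * stats::pnorm(-abs(z)))
}

#' Hardy-Weinberg disequilibrium trend test
#'
#' Compares the HWD coefficients of cases and controls,
#' `delta = Pr(BB) - (Pr(AB)/2 + Pr(BB))^2`, estimated separately in each
#' group.  Under a recessive model cases are enriched for `BB` beyond HWE
#' (`delta_p > 0`), under a dominant model depleted, so the sign of the
#' statistic carries genetic-model information; the model selection and
#' exclusion procedures use it to pick or rule out trend scores.
#'
#' @inheritParams catt
#' @return An object of class `"rr_hwdtt"`: list with `z_H` (standard
#'   normal under the null), HWD estimates `delta_p` (cases) and `delta_q`
#'   (controls), and two-sided `p_value`.
#' @export
hwdtt <- function(counts) {
  if (!inherits(counts, "genotype_counts"))
    rr_stop("`counts` must be a genotype_counts object", "rr_input_error")
  if (counts$n_cases == 0 || counts$n_controls == 0)
    rr_stop("both cases and controls are required", "rr_input_error")
  r <- counts$n_cases; s <- counts$n_controls; n <- counts$n
  ph <- counts$r / r
  qh <- counts$s / s
  dp <- ph[3] - (ph[3] + ph[2] / 2)^2
  dq <- qh[3] - (qh[3] + qh[2] / 2)^2
  pb <- counts$n_geno[3] / n + counts$n_geno[2] / (2 * n)
  den <- (1 - pb) * pb
  if (den <= 0)
    rr_stop("HWD trend test undefined: pooled allele frequency is 0 or 1",
            "rr_degenerate_error")
  z <- sqrt(r * s / n) * (dp - dq) / den
  structure(list(z_H = z, delta_p = dp, delta_q = dq,
                 p_value = 2 * stats::pnorm(-abs(z))),
            class = "rr_hwdtt")
}

#' @export
print.rr_hwdtt <- function(x, ...) {
  cat(sprintf("HWD trend test: z_H = %.4f (delta cases %.4f, controls %.4f), p = %.4g\n",
              x$z_H, x$delta_p, x$delta_q, x$p_value))
  invisible(x)
}

#' Plug-in null correlations among the trend and HWD statistics
#'
#' Estimates the asymptotic null correlations among the recessive, additive
#' and dominant trend statistics `(Z_0, Z_1/2, Z_1)` and the HWD trend
#' statistic `Z_H`, replacing the unknown genotype probabilities with the
#' pooled sample frequencies `n_i / n`.  Trend-trend correlations follow the
#' closed multinomial covariance of the score sums; trend-HWD correlations
#' use the delta method, linearising the HWD coefficient in the genotype
#' proportions.  Because every statistic is (to first order) a linear
#' functional of the same two free genotype-proportion contrasts, the
#' implied 4x4 correlation matrix has rank 2; the selection-adjusted
#' p-values exploit this to reduce their region integrals to one dimension.
#'
#' @inheritParams catt
#' @return An object of class `"rr_correlations"`: list with `rho_0_half`,
#'   `rho_1_half` (REC and DOM trend vs additive trend), `rho_0`, `rho_1`,
#'   `rho_half` (each trend vs `Z_H`), and `g`, the pooled genotype
#'   frequencies used.
#' @export
estimate_correlations <- function(counts) {
  check_testable(counts)
  g <- counts$n_geno / counts$n
  est <- corr_from_freqs(g)
  structure(c(est, list(g = g)), class = "rr_correlations")
}

## correlations from a genotype frequency vector; shared with the
## vectorised simulation engine (which passes matrices).
corr_from_freqs <- function(g0, g1 = NULL, g2 = NULL) {
  if (is.null(g1)) { g1 <- g0[2]; g2 <- g0[3]; g0 <- g0[1] }
  a <- g2 + g1 / 2                       # pooled B allele frequency
  ## centred-score covariance under multinomial(g):
  ## scores enter through weights on (p1, p2): w = (x1 - x0, x2 - x0)
  cov_w <- function(w1, w2, v1, v2) {
    w1 * v1 * g1 * (1 - g1) + w2 * v2 * g2 * (1 - g2) -
      (w1 * v2 + w2 * v1) * g1 * g2
  }
  w_rec <- list(0, 1)                    # scores (0,0,1)
  w_add <- list(0.5, 1)                  # scores (0,.5,1)
  w_dom <- list(1, 1)                    # scores (0,1,1)
  w_hwd <- list(-a, 1 - 2 * a)           # gradient of delta at g
  cc <- function(u, v) {
    cov_w(u[[1]], u[[2]], v[[1]], v[[2]]) /
      sqrt(cov_w(u[[1]], u[[2]], u[[1]], u[[2]]) *
           cov_w(v[[1]], v[[2]], v[[1]], v[[2]]))
  }
  list(rho_0_half = cc(w_rec, w_add),
       rho_1_half = cc(w_dom, w_add),
       rho_0      = cc(w_rec, w_hwd),
       rho_1      = cc(w_dom, w_hwd),
       rho_half   = cc(w_add, w_hwd),
       rho_0_1    = cc(w_rec, w_dom))
}

#' @export
as.matrix.rr_correlations <- function(x, ...) {
  m <- diag(4)
  dimnames(m) <- list(c("Z0", "Zhalf", "Z1", "ZH"),
                      c("Z0", "Zhalf", "Z1", "ZH"))
  m["Z0", "Zhalf"] <- m["Zhalf", "Z0"] <- x$rho_0_half
  m["Z1", "Zhalf"] <- m["Zhalf", "Z1"] <- x$rho_1_half
  m["Z0", "Z1"] <- m["Z1", "Z0"] <- x$rho_0_1
  m["Z0", "ZH"] <- m["ZH", "Z0"] <- x$rho_0
  m["Z1", "ZH"] <- m["ZH", "Z1"] <- x$rho_1
  m["Zhalf", "ZH"] <- m["ZH", "Zhalf"] <- x$rho_half
  m
}

#' @export
print.rr_correlations <- function(x, ...) {
  cat("Plug-in null correlations (rank-2):\n")
  print(round(as.matrix(x), 4))
  invisible(x)
}

## ---- vectorised statistic kernels -----------------------------------
## `m` is an N x 6 matrix with columns r0 r1 r2 s0 s1 s2; these back both
## the scalar tests above and the simulation engine.

counts_row <- function(counts) {
  matrix(c(counts$r, counts$s), nrow = 1)
}

zcatt_vec <- function(m, x) {
  xs <- c(0, x, 1)
  r <- m[, 1] + m[, 2] + m[, 3]
  s <- m[, 4] + m[, 5] + m[, 6]
  n <- r + s
  n1 <- m[, 2] + m[, 5]; n2 <- m[, 3] + m[, 6]
  num <- sqrt(n) * (xs[2] * (s * m[, 2] - r * m[, 5]) +
                    xs[3] * (s * m[, 3] - r * m[, 6]))
  sx2 <- xs[2]^2 * n1 + xs[3]^2 * n2
  sx1 <- xs[2] * n1 + xs[3] * n2
  den2 <- r * s * (n * sx2 - sx1^2)
  out <- rep(NaN, nrow(m))
  ok <- den2 > 0
  out[ok] <- num[ok] / sqrt(den2[ok])
  out
}

chi2_vec <- function(m) {
  r <- m[, 1] + m[, 2] + m[, 3]
  s <- m[, 4] + m[, 5] + m[, 6]
  n <- r + s
  stat <- numeric(nrow(m)); df <- integer(nrow(m))
  for (j in 1:3) {
    nj <- m[, j] + m[, j + 3]
    er <- nj * r / n; es <- nj * s / n
    pos <- nj > 0
    stat[pos] <- stat[pos] + (m[pos, j] - er[pos])^2 / er[pos] +
      (m[pos, j + 3] - es[pos])^2 / es[pos]
    df <- df + as.integer(pos)
  }
  df <- df - 1L
  p <- rep(NaN, nrow(m))
  ok <- df >= 1L
  p[ok] <- stats::pchisq(stat[ok], df[ok], lower.tail = FALSE)
  list(stat = stat, df = df, p = p)
}

zhwdtt_vec <- function(m) {
  r <- m[, 1] + m[, 2] + m[, 3]
  s <- m[, 4] + m[, 5] + m[, 6]
  n <- r + s
  dp <- m[, 3] / r - (m[, 3] / r + m[, 2] / (2 * r))^2
  dq <- m[, 6] / s - (m[, 6] / s + m[, 5] / (2 * s))^2
  pb <- (m[, 3] + m[, 6]) / n + (m[, 2] + m[, 5]) / (2 * n)
  sqrt(r * s / n) * (dp - dq) / ((1 - pb) * pb)
}

## N x 6 matrix of plug-in correlations per table
corr_vec <- function(m) {
  n <- rowSums(m)
  g1 <- (m[, 2] + m[, 5]) / n
  g2 <- (m[, 3] + m[, 6]) / n
  est <- corr_from_freqs(1 - g1 - g2, g1, g2)
  do.call(cbind, est)
}
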