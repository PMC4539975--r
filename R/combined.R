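## Joint discovery + replication evidence: Fisher and inverse-normal
## combinations of the two stages' p-values, with significance assessed
## conditionally on the marker having passed the discovery threshold.

#' Configuration for the combined tests
#'
#' @param alpha_D Discovery-stage significance level: only markers with
#'   discovery p-value below `alpha_D` are carried to replication, and the
#'   combined p-values condition on that selection.
#' @param weights `"equal"` (w1 = w2 = 1) or `"sample_size"`
#'   (w1 = 2 pi_s, w2 = 2 (1 - pi_s) for the Fisher combination).
#' @param pi_s Fraction of the total sample in the discovery stage;
#'   required for sample-size weights and for the inverse-normal weights
#'   `sqrt(pi_s)`, `sqrt(1 - pi_s)`.
#' @return A list of class `"rr_combine_config"`.
#' @export
combine_config <- function(alpha_D, weights = c("equal", "sample_size"),
                           pi_s = NULL) {
  weights <- match.arg(weights)
  if (!is.numeric(alpha_D) || alpha_D <= 0 || alpha_D > 1)
    rr_stop("alpha_D must be in (0, 1]", "rr_input_error")
  if (weights == "sample_size" &&
      (is.null(pi_s) || pi_s <= 0 || pi_s >= 1))
    rr_stop("sample-size weights need pi_s in (0, 1)", "rr_input_error")
  structure(list(alpha_D = alpha_D, weights = weights, pi_s = pi_s),
            class = "rr_combine_config")
}

fc_weights <- function(config) {
  if (config$weights == "equal") c(1, 1)
  else c(2 * config$pi_s, 2 * (1 - config$pi_s))
}

lc_weights <- function(config) {
  if (is.null(config$pi_s)) c(1, 1) / sqrt(2)
  else c(sqrt(config$pi_s), sqrt(1 - config$pi_s))
}

#' Fisher combination statistic
#'
#' `z_FC = -2 w1 ln(p1) - 2 w2 ln(p2)` (natural logarithm).
#'
#' @param p1,p2 Discovery and replication p-values in `(0, 1]`.
#' @param w1,w2 Positive stage weights.
#' @return The combination statistic (non-negative for unit weights).
#' @export
fisher_stat <- function(p1, p2, w1 = 1, w2 = 1) {
  if (any(c(p1, p2) <= 0) || any(c(p1, p2) > 1))
    rr_stop("p-values must be in (0, 1]", "rr_input_error")
  if (w1 <= 0 || w2 <= 0)
    rr_stop("weights must be positive", "rr_input_error")
  -2 * w1 * log(p1) - 2 * w2 * log(p2)
}

#' Conditional p-value of the Fisher combination
#'
#' Evaluates `Pr(P1 < alpha_D, Z_FC > z)` under the null, i.e. the joint
#' probability of passing discovery selection and exceeding the observed
#' combination statistic.  Closed forms: with equal weights
#' `exp(-z/2) (1 + z/2 + ln alpha_D)` for `z > -2 ln alpha_D`; with unequal
#' weights the two-exponential form
#' `w1/(w1-w2) exp(-z/(2 w1)) - w2/(w1-w2) exp(-z/(2 w2)) alpha_D^{-(w1-w2)/w2}`
#' for `z > -2 w1 ln alpha_D`.  At `alpha_D = 1` the equal-weight form is
#' the classical 4-df chi-square survival function.
#'
#' @param z_fc Observed combination statistic.
#' @param config A [combine_config()] object.
#' @return A list of class `"rr_combined"` with `statistic`, `p_value`,
#'   `weights`, and `valid` (TRUE when `z_fc` lies above the support
#'   threshold implied by the selection event).
#' @export
fisher_pvalue <- function(z_fc, config) {
  stopifnot(inherits(config, "rr_combine_config"))
  w <- fc_weights(config)
  aD <- config$alpha_D
  if (abs(w[1] - w[2]) < 1e-9) {
    zz <- z_fc / w[1]
    if (zz <= -2 * log(aD))
      rr_stop("statistic below the selection support: the marker could not have passed the discovery threshold alpha_D with this combined value",
              "rr_support_error")
    p <- exp(-zz / 2) * (1 + zz / 2 + log(aD))
  } else {
    if (z_fc <= -2 * w[1] * log(aD))
      rr_stop("statistic below the selection support: the marker could not have passed the discovery threshold alpha_D with this combined value",
              "rr_support_error")
    p <- w[1] / (w[1] - w[2]) * exp(-z_fc / (2 * w[1])) -
      w[2] / (w[1] - w[2]) * exp(-z_fc / (2 * w[2])) *
        aD^(-(w[1] - w[2]) / w[2])
  }
  structure(list(method = "FC", statistic = z_fc,
                 p_value = min(max(p, 0), aD), weights = w, valid = TRUE),
            class = "rr_combined")
}

#' @export
print.rr_combined <- function(x, ...) {
  cat(sprintf("%s combination: statistic = %.4f, conditional p = %.4g\n",
              x$method, x$statistic, x$p_value))
  invisible(x)
}

#' Inverse-normal (linear) combination statistic
#'
#' `z_LC = (w1 qnorm(1 - p1/2) + w2 qnorm(1 - p2)) / sqrt(w1^2 + w2^2)`.
#' The discovery p-value is two-sided and is halved before the probit; the
#' replication p-value is already one-sided (it inherited the discovery
#' direction) and is not.
#'
#' @param p1 Two-sided discovery p-value in `(0, 1]`.
#' @param p2 One-sided replication p-value in `(0, 1)`.
#' @param config A [combine_config()] object (for the weights).
#' @return The combination statistic.
#' @export
lc_stat <- function(p1, p2, config) {
  stopifnot(inherits(config, "rr_combine_config"))
  if (p1 <= 0 || p1 > 1 || p2 <= 0 || p2 >= 1)
    rr_stop("need p1 in (0, 1] and p2 in (0, 1)", "rr_input_error")
  w <- lc_weights(config)
  (w[1] * stats::qnorm(1 - p1 / 2) + w[2] * stats::qnorm(1 - p2)) /
    sqrt(sum(w^2))
}

#' Conditional p-value of the inverse-normal combination
#'
#' Evaluates
#' `Pr(P1 < alpha_D, Z_LC > z) = int_{z_{1-alpha_D/2}}^inf 2 phi(u) (1 -
#' Phi((sqrt(w1^2+w2^2) z - w1 u) / w2)) du`
#' by adaptive quadrature, for `z` above the support threshold
#' `qnorm(1 - alpha_D/2)`.  The discovery probit `qnorm(1 - P1/2)` of a
#' two-sided p-value is half-normal under the null (density `2 phi(u)` on
#' `u > 0`), which is where the factor 2 comes from; the selection event
#' is the probit exceeding its `alpha_D/2` upper quantile, so the
#' conditional p-value is bounded by `alpha_D`.  (Writing the integrand
#' with `phi` instead of `2 phi` would halve the probability and make a
#' threshold calibrated from it reject twice too often; the half-normal
#' form is the one consistent with the statistic's definition, and the
#' package's Monte-Carlo cross-checks test exactly this probability.)
#'
#' @param z_lc Observed combination statistic.
#' @inheritParams fisher_pvalue
#' @return A list of class `"rr_combined"` as for [fisher_pvalue()].
#' @export
lc_pvalue <- function(z_lc, config) {
  stopifnot(inherits(config, "rr_combine_config"))
  w <- lc_weights(config)
  zb <- stats::qnorm(1 - config$alpha_D / 2)
  if (z_lc <= zb)
    rr_stop("statistic below the selection support: the marker could not have passed the discovery threshold alpha_D with this combined value",
            "rr_support_error")
  sw <- sqrt(sum(w^2))
  f <- function(u) {
    2 * stats::dnorm(u) *
      stats::pnorm((sw * z_lc - w[1] * u) / w[2], lower.tail = FALSE)
  }
  upper <- max(RR_TRUNC, sw * z_lc / w[1] + RR_TRUNC * w[2] / w[1])
  p <- stats::integrate(f, zb, upper, rel.tol = 1e-10, abs.tol = 1e-15,
                        stop.on.error = FALSE)$value
  structure(list(method = "LC", statistic = z_lc,
                 p_value = min(max(p, 0), config$alpha_D),
                 weights = w, valid = TRUE),
            class = "rr_combined")
}

#' Rejection threshold of the Fisher combination
#'
#' Finds the critical value `C` with
#' `Pr(P1 < alpha_D, Z_FC > C) = alpha`, by monotone root bracketing on
#' [fisher_pvalue()].  At `alpha_D = 1` this is the classical 4-df
#' chi-square upper quantile.
#'
#' @param alpha Target per-marker level; must be below `alpha_D`.
#' @inheritParams fisher_pvalue
#' @return The threshold `C` (solves the equation to ~1e-12).
#' @export
fc_threshold <- function(alpha, config) {
  stopifnot(inherits(config, "rr_combine_config"))
  if (alpha >= config$alpha_D)
    rr_stop("alpha must be below alpha_D: selection alone already occurs with probability alpha_D",
            "rr_input_error")
  w <- fc_weights(config)
  lo <- -2 * w[1] * log(config$alpha_D)
  f <- function(z) fisher_pvalue(z, config)$p_value - alpha
  hi <- lo + 1
  while (f(hi) > 0) hi <- hi * 2
  stats::uniroot(f, c(lo + 1e-12, hi), tol = 1e-13)$root
}

#' Rejection threshold of the inverse-normal combination
#'
#' Counterpart of [fc_threshold()] for [lc_pvalue()]; requires
#' `alpha < alpha_D` (the ceiling of the conditional p-value).
#'
#' @inheritParams fc_threshold
#' @return The threshold on the combination statistic.
#' @export
lc_threshold <- function(alpha, config) {
  stopifnot(inherits(config, "rr_combine_config"))
  if (alpha >= config$alpha_D)
    rr_stop("alpha must be below alpha_D: selection alone already occurs with probability alpha_D",
            "rr_input_error")
  zb <- stats::qnorm(1 - config$alpha_D / 2)
  f <- function(z) lc_pvalue(z, config)$p_value - alpha
  if (f(zb + 1e-10) < 0)
    rr_stop("alpha is not achievable: even at the selection boundary the conditional probability of a larger combination statistic falls short of alpha",
            "rr_input_error")
  hi <- zb + 1
  while (f(hi) > 0) hi <- hi + 1
  stats::uniroot(f, c(zb + 1e-10, hi), tol = 1e-13)$root
}
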