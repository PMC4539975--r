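## Numerical evaluation of the selection-adjusted null p-values.
##
## Asymptotically, (Z_0, Z_1/2, Z_1, Z_H) are all linear functionals of the
## two free genotype-proportion contrasts, so their joint null law is a
## rank-2 Gaussian.  Writing e1 for the Z_H direction and e2 for the
## orthogonal direction, every statistic S decomposes as
##     S = rho_SH * e1 + tau_S * e2,   tau_S = +/- sqrt(1 - rho_SH^2),
## with the sign of tau_S fixed by Corr(S, Z_1/2).  Region probabilities
## over (Z_H, Z_1/2, component) therefore collapse to one-dimensional
## adaptive quadrature over e1 with closed-form normal interval
## probabilities inside.  Infinite limits are truncated at |e1| = 8.5
## (normal mass beyond is < 1e-16).

RR_TRUNC <- 8.5

## coefficients (rho_SH, tau_S) of a statistic in the rank-2 basis
rank2_coef <- function(rho_sh, rho_s_half, rho_half_h) {
  tau_half <- sqrt(max(0, 1 - rho_half_h^2))
  tau <- sign1(rho_s_half - rho_sh * rho_half_h) * sqrt(max(0, 1 - rho_sh^2))
  list(rho = rho_sh, tau = tau, tau_half = tau_half)
}

## Pr(e2 satisfies tau1*e2 > b1 and tau2*e2 > b2), vectorised over b1/b2
interval_above2 <- function(tau1, b1, tau2, b2) {
  lo <- rep(-Inf, length(b1))
  hi <- rep(Inf, length(b1))
  if (tau1 > 0) lo <- pmax(lo, b1 / tau1)
  else if (tau1 < 0) hi <- pmin(hi, b1 / tau1)
  else hi[b1 >= 0] <- -Inf
  if (tau2 > 0) lo <- pmax(lo, b2 / tau2)
  else if (tau2 < 0) hi <- pmin(hi, b2 / tau2)
  else hi[b2 >= 0] <- -Inf
  pmax(0, stats::pnorm(hi) - stats::pnorm(lo))
}

## Pr(Z_H in (lo, hi), Z_1/2 > 0, component > t) for one component with
## rank-2 coefficients (rho, tau); rho_half_h, tau_half for Z_1/2.
sel_region_prob <- function(t, lo, hi, rho, tau, rho_half_h, tau_half,
                            rel.tol = 1e-9) {
  if (lo >= hi) return(0)
  f <- function(h) {
    stats::dnorm(h) *
      interval_above2(tau_half, -rho_half_h * h, tau, t - rho * h)
  }
  stats::integrate(f, lo, hi, rel.tol = rel.tol, abs.tol = 1e-13,
                   stop.on.error = FALSE)$value
}

## Selection-adjusted p-value shared by the model-selection (GMS) and
## model-exclusion (GME) procedures: given the observed aligned statistic t,
##   p(t) = 2 [ Pr(Z_H > c,  Z_1/2 > 0, C0 > t)
##            + Pr(Z_H < -c, Z_1/2 > 0, C1 > t)
##            + Pr(|Z_H| <= c, Z_1/2 > max(t, 0)) ],
## where (C0, C1) are the REC/DOM components (plain trend statistics for
## GMS, averaged-and-rescaled ones for GME).  The factor 2 accounts exactly
## for the mirrored branches in which the other allele is taken as the risk
## allele (a global sign flip of the Gaussian field maps one set of
## branches onto the other).
p_selection_adjusted <- function(t, corr, alpha_H = 0.05, starred = FALSE,
                                 rel.tol = 1e-9) {
  cthr <- stats::qnorm(1 - alpha_H)
  rho_ah <- corr$rho_half
  tau_half <- sqrt(max(0, 1 - rho_ah^2))
  if (starred) {
    k0 <- sqrt(2 * (1 + corr$rho_0_half))
    k1 <- sqrt(2 * (1 + corr$rho_1_half))
    c0 <- rank2_coef((corr$rho_0 + corr$rho_half) / k0,
                     (corr$rho_0_half + 1) / k0, rho_ah)
    c1 <- rank2_coef((corr$rho_1 + corr$rho_half) / k1,
                     (corr$rho_1_half + 1) / k1, rho_ah)
  } else {
    c0 <- rank2_coef(corr$rho_0, corr$rho_0_half, rho_ah)
    c1 <- rank2_coef(corr$rho_1, corr$rho_1_half, rho_ah)
  }
  i1 <- sel_region_prob(t, cthr, RR_TRUNC, c0$rho, c0$tau, rho_ah, tau_half,
                        rel.tol)
  i2 <- sel_region_prob(t, -RR_TRUNC, -cthr, c1$rho, c1$tau, rho_ah,
                        tau_half, rel.tol)
  m <- max(t, 0)
  f3 <- function(h) {
    stats::dnorm(h) *
      stats::pnorm((m - rho_ah * h) / tau_half, lower.tail = FALSE)
  }
  i3 <- stats::integrate(f3, -cthr, cthr, rel.tol = rel.tol,
                         abs.tol = 1e-13, stop.on.error = FALSE)$value
  min(1, max(0, 2 * (i1 + i2 + i3)))
}

## Asymptotic null survival function of the maximum of the three absolute
## trend statistics: Pr(max(|Z_0|, |Z_1/2|, |Z_1|) > t), computed in the
## same rank-2 basis (one outer quadrature, interval intersections inside).
max3_p_asymptotic <- function(t, corr, rel.tol = 1e-9) {
  if (t <= 0) return(1)
  rho_ah <- corr$rho_half
  tau_half <- sqrt(max(0, 1 - rho_ah^2))
  c0 <- rank2_coef(corr$rho_0, corr$rho_0_half, rho_ah)
  c1 <- rank2_coef(corr$rho_1, corr$rho_1_half, rho_ah)
  comps <- list(c(c0$rho, c0$tau), c(rho_ah, tau_half), c(c1$rho, c1$tau))
  f <- function(h) {
    lo <- rep(-Inf, length(h)); hi <- rep(Inf, length(h))
    for (cm in comps) {
      b1 <- (-t - cm[1] * h) / cm[2]
      b2 <- (t - cm[1] * h) / cm[2]
      lo <- pmax(lo, pmin(b1, b2))
      hi <- pmin(hi, pmax(b1, b2))
    }
    stats::dnorm(h) * pmax(0, stats::pnorm(hi) - stats::pnorm(lo))
  }
  box <- stats::integrate(f, -RR_TRUNC, RR_TRUNC, rel.tol = rel.tol,
                          abs.tol = 1e-13, stop.on.error = FALSE)$value
  min(1, max(0, 1 - box))
}

## Null distribution adjustment for the smaller of the 2-df Pearson p-value
## and the additive-trend p-value: Pr(min(P_chi2, P_1/2) <= m) under H0.
## Uses the representation T_chi2 = Z_1/2^2 + W with W an independent 1-df
## chi-square; the remaining one-dimensional integral is evaluated by
## adaptive quadrature.
min2_null_cdf <- function(m, rel.tol = 1e-10) {
  if (m <= 0 || m > 1)
    rr_stop("MIN2 statistic must be in (0, 1]", "rr_input_error")
  if (m == 1) return(1)
  a <- stats::qchisq(1 - m, 1)
  b <- -2 * log(m)                     # the 2-df quantile at 1 - m
  out <- 0.5 * exp(-a / 2) + 0.5 * m
  if (b > a) {
    f <- function(v) {
      exp(-v / 2) * asin(pmin(pmax(2 * a / v - 1, -1), 1))
    }
    I <- stats::integrate(f, a, b, rel.tol = rel.tol, abs.tol = 1e-15,
                          stop.on.error = FALSE)$value
    out <- out - I / (2 * pi)
  }
  min(1, max(0, out))
}

## smallest observed MIN2 value whose adjusted p-value reaches `level`;
## used to vectorise stage-1 selection in the simulation engine.
min2_crit <- function(level) {
  stats::uniroot(function(m) min2_null_cdf(m) - level,
                 lower = level / 2, upper = level, tol = 1e-14)$root
}
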