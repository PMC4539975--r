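## Synthetic two-stage case-control genotype generator and the
## type-I-error / power engine.

#' Genotype frequencies from allele frequency and inbreeding coefficient
#'
#' `g0 = (1-p)^2 + F p (1-p)`, `g1 = 2 p (1-p) (1-F)`,
#' `g2 = p^2 + F p (1-p)` — the standard inbreeding parametrisation of
#' Hardy-Weinberg departure.  The implied HWD coefficient is
#' `delta = g2 - (g1/2 + g2)^2 = F p (1-p)`.
#'
#' @param maf Frequency of the `B` allele, in (0, 1).
#' @param F Inbreeding-type HWD coefficient; `F = 0` is HWE.
#' @return Numeric vector `(g0, g1, g2)` summing to 1.
#' @export
genotype_freqs <- function(maf, F = 0) {
  if (maf <= 0 || maf >= 1)
    rr_stop("maf must be in (0, 1)", "rr_input_error")
  pq <- maf * (1 - maf)
  g <- c((1 - maf)^2 + F * pq, 2 * pq * (1 - F), maf^2 + F * pq)
  if (any(g < 0))
    rr_stop("F is infeasible for this allele frequency (negative genotype frequency)",
            "rr_input_error")
  g
}

#' Penetrances from genotype relative risks and prevalence
#'
#' Solves `f0` from `K = f0 (g0 + lambda1 g1 + lambda2 g2)` with the
#' heterozygote relative risk implied by the genetic model:
#' recessive `lambda1 = 1`, additive `lambda1 = (1 + lambda2)/2`,
#' multiplicative `lambda1 = sqrt(lambda2)`, dominant `lambda1 = lambda2`.
#'
#' @param model One of `"REC"`, `"ADD"`, `"MUL"`, `"DOM"`.
#' @param lambda2 Homozygote genotype relative risk `f2 / f0` (>= 1).
#' @param K Disease prevalence in (0, 1).
#' @param freqs Genotype frequencies from [genotype_freqs()].
#' @return Numeric vector of penetrances `(f0, f1, f2)`.
#' @export
penetrance_solve <- function(model = c("REC", "ADD", "MUL", "DOM"),
                             lambda2, K, freqs) {
  model <- match.arg(model)
  if (lambda2 < 1) rr_stop("lambda2 must be >= 1", "rr_input_error")
  if (K <= 0 || K >= 1) rr_stop("K must be in (0, 1)", "rr_input_error")
  lambda1 <- switch(model, REC = 1, ADD = (1 + lambda2) / 2,
                    MUL = sqrt(lambda2), DOM = lambda2)
  f0 <- K / sum(freqs * c(1, lambda1, lambda2))
  f <- f0 * c(1, lambda1, lambda2)
  if (any(f > 1))
    rr_stop("scenario infeasible: implied penetrance exceeds 1",
            "rr_input_error")
  f
}

#' Case and control genotype probabilities
#'
#' Bayes inversion of the penetrances: cases carry genotype `i` with
#' probability `f_i g_i / K`, controls with `(1 - f_i) g_i / (1 - K)`.
#'
#' @param f Penetrances from [penetrance_solve()].
#' @param freqs Genotype frequencies.
#' @param K Disease prevalence.
#' @return List with `p` (cases) and `q` (controls), each summing to 1.
#' @export
case_control_probs <- function(f, freqs, K) {
  list(p = f * freqs / K, q = (1 - f) * freqs / (1 - K))
}

#' Two-stage simulation scenario
#'
#' Bundles everything that defines a two-stage design simulation: the
#' marker model (allele frequency, HWD coefficient, prevalence, genetic
#' model and homozygote relative risk, optionally different between
#' stages), the design (sample sizes, discovery fraction `pi_s`, number of
#' markers `M`), and the analysis levels (genome-wide `alpha` with
#' Bonferroni over `M`, discovery threshold `alpha_D`, model-selection
#' level `alpha_H`).
#'
#' @param model Genetic model, see [penetrance_solve()].
#' @param lambda2 Homozygote GRR in the discovery stage; 1 gives the null.
#' @param lambda2_stage2 Replication-stage GRR (defaults to `lambda2`);
#'   between-stage effect heterogeneity re-solves the penetrances per
#'   stage at the same allele frequency and prevalence.
#' @param maf,F,K See [genotype_freqs()] and [penetrance_solve()].
#' @param n_cases,n_controls Total sample sizes across both stages.
#' @param pi_s Fraction allocated to the discovery stage; stage-1 sizes are
#'   `round(pi_s * n)`, the remainder goes to replication.
#' @param M Number of independent markers; per-marker level is `alpha / M`.
#' @param alpha Genome-wide type-I-error level.
#' @param alpha_D Discovery-stage selection level.
#' @param alpha_H Model-selection level for GMS/GME.
#' @param weights Fisher-combination weight scheme, see [combine_config()].
#' @param n_reps Number of simulation replicates.
#' @param seed RNG seed.
#' @return A list of class `"rr_scenario"`.
#' @export
simulation_scenario <- function(model = "ADD", lambda2 = 1,
                                lambda2_stage2 = NULL,
                                maf = 0.3, F = 0, K = 0.1,
                                n_cases = 1500, n_controls = 1500,
                                pi_s = 0.5, M = 10,
                                alpha = 0.05, alpha_D = 0.05,
                                alpha_H = 0.05, weights = "equal",
                                n_reps = 1000, seed = 1) {
  if (pi_s <= 0 || pi_s >= 1) rr_stop("pi_s must be in (0, 1)", "rr_input_error")
  if (M < 1) rr_stop("M must be >= 1", "rr_input_error")
  for (nm in c("alpha", "alpha_D", "alpha_H")) {
    v <- get(nm)
    if (v <= 0 || v > 1) rr_stop(paste(nm, "must be in (0, 1]"), "rr_input_error")
  }
  sc <- list(model = model, lambda2 = lambda2,
             lambda2_stage2 = if (is.null(lambda2_stage2)) lambda2
                              else lambda2_stage2,
             maf = maf, F = F, K = K,
             n_cases = n_cases, n_controls = n_controls,
             pi_s = pi_s, M = as.integer(M),
             alpha = alpha, alpha_D = alpha_D, alpha_H = alpha_H,
             weights = weights,
             n_reps = as.integer(n_reps), seed = as.integer(seed))
  sc$n1_cases <- round(pi_s * n_cases)
  sc$n1_controls <- round(pi_s * n_controls)
  sc$n2_cases <- n_cases - sc$n1_cases
  sc$n2_controls <- n_controls - sc$n1_controls
  if (min(sc$n1_cases, sc$n1_controls, sc$n2_cases, sc$n2_controls) < 1)
    rr_stop("stage sample sizes must all be at least 1", "rr_input_error")
  structure(sc, class = "rr_scenario")
}

## stage-specific case/control genotype probabilities
scenario_probs <- function(sc) {
  g <- genotype_freqs(sc$maf, sc$F)
  one <- function(l2) {
    if (l2 == 1) return(list(p = g, q = g))
    case_control_probs(penetrance_solve(sc$model, l2, sc$K, g), g, sc$K)
  }
  list(stage1 = one(sc$lambda2), stage2 = one(sc$lambda2_stage2), g = g)
}

#' Draw the two stage tables for one replicate
#'
#' Samples, for each of the scenario's `M` markers, independent multinomial
#' case and control genotype vectors for both stages.  Deterministic given
#' `(seed, rep_index)`; markers are independent.
#'
#' @param scenario An [simulation_scenario()] object.
#' @param rep_index Replicate number (>= 1); part of the seed derivation.
#' @return A list of `M` elements, each a list with `stage1` and `stage2`
#'   [genotype_counts()].
#' @export
sample_two_stage <- function(scenario, rep_index = 1) {
  stopifnot(inherits(scenario, "rr_scenario"))
  pr <- scenario_probs(scenario)
  with_seed((scenario$seed + 10007 * as.integer(rep_index)) %% 2147483647L, {
    lapply(seq_len(scenario$M), function(m) {
      list(stage1 = genotype_counts(
             stats::rmultinom(1, scenario$n1_cases, pr$stage1$p),
             stats::rmultinom(1, scenario$n1_controls, pr$stage1$q),
             snp = sprintf("m%d", m)),
           stage2 = genotype_counts(
             stats::rmultinom(1, scenario$n2_cases, pr$stage2$p),
             stats::rmultinom(1, scenario$n2_controls, pr$stage2$q),
             snp = sprintf("m%d", m)))
    })
  })
}

## bulk draw: N = n_reps * M tables per stage, as N x 6 matrices
draw_tables <- function(sc) {
  pr <- scenario_probs(sc)
  N <- sc$n_reps * sc$M
  m1 <- cbind(t(stats::rmultinom(N, sc$n1_cases, pr$stage1$p)),
              t(stats::rmultinom(N, sc$n1_controls, pr$stage1$q)))
  m2 <- cbind(t(stats::rmultinom(N, sc$n2_cases, pr$stage2$p)),
              t(stats::rmultinom(N, sc$n2_controls, pr$stage2$q)))
  list(m1 = m1, m2 = m2)
}

## correlation row (plain list) usable by the quadrature routines
corr_row <- function(co, i) {
  list(rho_0_half = co[i, 1], rho_1_half = co[i, 2], rho_0 = co[i, 3],
       rho_1 = co[i, 4], rho_half = co[i, 5])
}

#' Run a two-stage simulation scenario
#'
#' Simulates the scenario and, for each requested test, applies the three
#' analysis strategies to every replicate x marker:
#' \describe{
#'   \item{REP}{replication-based: discovery p below `alpha_D` and
#'     replication p below `(alpha/M) / alpha_D`.  Because the two stages'
#'     p-values are independent under the null, the product of the two
#'     levels makes the per-marker null rejection rate exactly `alpha/M`.}
#'   \item{FC}{joint Fisher combination: discovery p below `alpha_D` and
#'     `z_FC` above [fc_threshold()] at `alpha / M`.}
#'   \item{LC}{joint inverse-normal combination, analogously via
#'     [lc_threshold()].}
#' }
#' Stage-1 p-values for MAX3 use the deterministic asymptotic path;
#' GMS/GME use the selection-adjusted quadrature with per-table plug-in
#' correlations (at a relaxed relative tolerance of 1e-7).  Tables whose
#' cheap lower bound already exceeds `alpha_D` skip the quadrature.
#'
#' @param scenario An [simulation_scenario()] object.
#' @param tests Character subset of
#'   `c("catt_add", "chi2", "max3", "min2", "gms", "gme")`.
#' @param keep_pvalues If TRUE, attach per-observation stage-1/stage-2
#'   p-values and selection flags (for diagnostics; memory ~ N per test).
#' @return An object of class `"rr_sim_summary"`: a data frame with one
#'   row per test x strategy (`rejections`, `n`, `rate`,
#'   `se = sqrt(rate (1-rate) / n)`), the scenario, and optionally the
#'   per-observation detail.
#' @export
run_scenario <- function(scenario,
                         tests = c("catt_add", "chi2", "max3", "min2",
                                   "gms", "gme"),
                         keep_pvalues = FALSE) {
  stopifnot(inherits(scenario, "rr_scenario"))
  tests <- match.arg(tests, several.ok = TRUE)
  sc <- scenario
  set.seed(sc$seed %% 2147483647L)
  tabs <- draw_tables(sc)
  m1 <- tabs$m1; m2 <- tabs$m2
  N <- nrow(m1)
  per_marker <- sc$alpha / sc$M

  ## decision thresholds, computed once
  beta_rep <- per_marker / sc$alpha_D
  cfg_fc <- combine_config(sc$alpha_D, sc$weights, sc$pi_s)
  cfg_lc <- combine_config(sc$alpha_D, "equal", sc$pi_s)
  C_fc <- fc_threshold(per_marker, cfg_fc)
  C_lc <- lc_threshold(per_marker, cfg_lc)
  w_fc <- fc_weights(cfg_fc)
  w_lc <- lc_weights(cfg_lc)

  ## stage-1 statistics shared across tests
  z0_1 <- zcatt_vec(m1, 0); zA_1 <- zcatt_vec(m1, 0.5); z1_1 <- zcatt_vec(m1, 1)
  zh_1 <- zhwdtt_vec(m1)
  z0_2 <- zcatt_vec(m2, 0); zA_2 <- zcatt_vec(m2, 0.5); z1_2 <- zcatt_vec(m2, 1)
  need_corr1 <- any(c("max3", "gms", "gme") %in% tests)
  co1 <- if (need_corr1) corr_vec(m1) else NULL
  co2 <- if ("gme" %in% tests) corr_vec(m2) else NULL
  cthr <- stats::qnorm(1 - sc$alpha_H)
  chi1 <- if (any(c("chi2", "min2") %in% tests)) chi2_vec(m1) else NULL
  chi2_ <- if (any(c("chi2", "min2") %in% tests)) chi2_vec(m2) else NULL

  one_test <- function(test) {
    p1 <- rep(NA_real_, N); p2 <- rep(NA_real_, N)
    if (test == "catt_add") {
      p1 <- 2 * stats::pnorm(-abs(zA_1))
      sel <- !is.na(p1) & p1 < sc$alpha_D
      p2[sel] <- stats::pnorm(sign1(zA_1[sel]) * zA_2[sel],
                              lower.tail = FALSE)
    } else if (test == "chi2") {
      p1 <- chi1$p
      sel <- !is.na(p1) & p1 < sc$alpha_D
      p2[sel] <- chi2_$p[sel]
    } else if (test == "min2") {
      pA <- 2 * stats::pnorm(-abs(zA_1))
      mn <- pmin(pA, chi1$p)
      mcrit <- min2_crit(sc$alpha_D)
      sel <- !is.na(mn) & mn < mcrit
      idx <- which(sel)
      p1[idx] <- vapply(mn[idx], min2_null_cdf, 0)
      add_branch <- pA <= chi1$p
      i_add <- idx[add_branch[idx]]
      i_chi <- idx[!add_branch[idx]]
      p2[i_add] <- stats::pnorm(sign1(zA_1[i_add]) * zA_2[i_add],
                                lower.tail = FALSE)
      p2[i_chi] <- chi2_$p[i_chi]
    } else if (test == "max3") {
      t1 <- pmax(abs(z0_1), abs(zA_1), abs(z1_1))
      cand <- which(!is.na(t1) & 2 * stats::pnorm(-t1) < sc$alpha_D)
      p1[cand] <- vapply(cand, function(i)
        max3_p_asymptotic(t1[i], corr_row(co1, i), rel.tol = 1e-7), 0)
      sel <- !is.na(p1) & p1 < sc$alpha_D
      idx <- which(sel)
      ## replicate the score with the smallest discovery p-value
      zmat1 <- cbind(zA_1[idx], z0_1[idx], z1_1[idx])   # additive-first ties
      zmat2 <- cbind(zA_2[idx], z0_2[idx], z1_2[idx])
      win <- max.col(abs(zmat1), ties.method = "first")
      pick <- cbind(seq_along(idx), win)
      p2[idx] <- stats::pnorm(sign1(zmat1[pick]) * zmat2[pick],
                              lower.tail = FALSE)
    } else { # gms / gme
      starred <- test == "gme"
      if (starred) {
        k0 <- sqrt(2 * (1 + co1[, 1])); k1 <- sqrt(2 * (1 + co1[, 2]))
        zr1 <- (z0_1 + zA_1) / k0; zd1 <- (z1_1 + zA_1) / k1
        k0b <- sqrt(2 * (1 + co2[, 1])); k1b <- sqrt(2 * (1 + co2[, 2]))
        zr2 <- (z0_2 + zA_2) / k0b; zd2 <- (z1_2 + zA_2) / k1b
      } else {
        zr1 <- z0_1; zd1 <- z1_1; zr2 <- z0_2; zd2 <- z1_2
      }
      pos <- zA_1 > 0
      region <- ifelse(abs(zh_1) <= cthr, 0L, ifelse(zh_1 > cthr, 1L, -1L))
      tstat <- ifelse(region == 0L, abs(zA_1),
               ifelse(region == 1L, ifelse(pos, zr1, -zd1),
                                    ifelse(pos, zd1, -zr1)))
      ## p >= 2 pnorm(-t) - 2 alpha_H, so small t cannot be selected
      cand <- which(is.finite(tstat) &
                    2 * stats::pnorm(-pmax(tstat, 0)) - 2 * sc$alpha_H <
                      sc$alpha_D & tstat > 0)
      p1[cand] <- vapply(cand, function(i)
        p_selection_adjusted(tstat[i], corr_row(co1, i),
                             alpha_H = sc$alpha_H, starred = starred,
                             rel.tol = 1e-7), 0)
      sel <- !is.na(p1) & p1 < sc$alpha_D
      idx <- which(sel)
      ## stage-2 component fixed by the stage-1 region and direction
      comp2 <- numeric(length(idx)); comp1 <- numeric(length(idx))
      ri <- region[idx]; pi_ <- pos[idx]
      use_rec <- (ri == 1L & pi_) | (ri == -1L & !pi_)
      use_dom <- (ri == 1L & !pi_) | (ri == -1L & pi_)
      use_add <- ri == 0L
      comp1[use_add] <- zA_1[idx[use_add]]
      comp2[use_add] <- zA_2[idx[use_add]]
      comp1[use_rec] <- zr1[idx[use_rec]]
      comp2[use_rec] <- zr2[idx[use_rec]]
      comp1[use_dom] <- zd1[idx[use_dom]]
      comp2[use_dom] <- zd2[idx[use_dom]]
      p2[idx] <- stats::pnorm(sign1(comp1) * comp2, lower.tail = FALSE)
    }
    sel[is.na(sel)] <- FALSE
    ok <- sel & !is.na(p2) & p2 > 0
    zfc <- rep(NA_real_, N); zlc <- rep(NA_real_, N)
    zfc[ok] <- -2 * w_fc[1] * log(p1[ok]) - 2 * w_fc[2] * log(p2[ok])
    zlc[ok] <- (w_lc[1] * stats::qnorm(1 - p1[ok] / 2) +
                w_lc[2] * stats::qnorm(1 - pmin(p2[ok], 1 - 1e-16))) /
      sqrt(sum(w_lc^2))
    list(summary = data.frame(
           test = test,
           strategy = c("REP", "FC", "LC"),
           rejections = c(sum(sel & !is.na(p2) & p2 < beta_rep),
                          sum(ok & zfc > C_fc),
                          sum(ok & zlc > C_lc)),
           n = N,
           stringsAsFactors = FALSE),
         detail = if (keep_pvalues)
           data.frame(p1 = p1, p2 = p2, sel = sel) else NULL)
  }

  parts <- lapply(tests, one_test)
  res <- do.call(rbind, lapply(parts, `[[`, "summary"))
  res$rate <- res$rejections / res$n
  res$se <- sqrt(res$rate * (1 - res$rate) / res$n)
  structure(list(summary = res, scenario = scenario,
                 detail = if (keep_pvalues)
                   stats::setNames(lapply(parts, `[[`, "detail"), tests)
                 else NULL),
            class = "rr_sim_summary")
}

#' @export
print.rr_sim_summary <- function(x, ...) {
  sc <- x$scenario
  cat(sprintf(
    "Two-stage simulation: %s model, lambda2 = %g/%g, MAF %g, F %g, K %g\n",
    sc$model, sc$lambda2, sc$lambda2_stage2, sc$maf, sc$F, sc$K))
  cat(sprintf("  %d+%d samples, pi_s %g, M %d, %d reps, per-marker level %g\n",
              sc$n_cases, sc$n_controls, sc$pi_s, sc$M, sc$n_reps,
              sc$alpha / sc$M))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
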