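## Model-robust association tests for a single (discovery) dataset:
## MAX3, MIN2, and the two-phase genetic model selection (GMS) and
## exclusion (GME) procedures.

MODEL_SCORES <- c(REC = 0, ADD = 0.5, DOM = 1)

rr_robust_result <- function(method, statistic, p_value = NA_real_,
                             selected_score = NA_real_,
                             component = NA_character_,
                             model = NA_character_,
                             direction = NA_real_,
                             z_H = NA_real_, c_threshold = NA_real_,
                             alpha_H = NA_real_) {
  structure(list(method = method, statistic = statistic, p_value = p_value,
                 selected_score = selected_score, component = component,
                 model = model, direction = direction, z_H = z_H,
                 c_threshold = c_threshold, alpha_H = alpha_H),
            class = "rr_robust")
}

#' @export
print.rr_robust <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f", x$method, x$statistic))
  if (!is.na(x$p_value)) cat(sprintf(", p = %.4g", x$p_value))
  if (!is.na(x$selected_score))
    cat(sprintf(" [selected score x = %g]", x$selected_score))
  if (!is.na(x$component) && is.na(x$selected_score))
    cat(sprintf(" [component: %s]", x$component))
  cat("\n")
  invisible(x)
}

## the three trend statistics at the model-optimal scores
trend_triple <- function(counts) {
  m <- counts_row(counts)
  z <- c(zcatt_vec(m, 0), zcatt_vec(m, 0.5), zcatt_vec(m, 1))
  if (any(!is.finite(z)))
    rr_stop("trend statistics undefined for this table", "rr_degenerate_error")
  names(z) <- names(MODEL_SCORES)
  z
}

#' MAX3 statistic
#'
#' Maximum of the absolute trend statistics at the recessive, additive and
#' dominant scores, `max(|Z_0|, |Z_1/2|, |Z_1|)`; robust against
#' misspecification of the genetic model.  Exact ties are broken toward the
#' additive score.
#'
#' @inheritParams catt
#' @return An `"rr_robust"` object with `statistic`, the winning
#'   `selected_score` and `direction` (sign of the winning statistic,
#'   with sign(0) taken as +1).
#' @export
max3_stat <- function(counts) {
  check_testable(counts)
  z <- trend_triple(counts)
  ord <- c("ADD", "REC", "DOM")          # tie-break toward additive
  win <- ord[which.max(abs(z)[ord])]
  rr_robust_result("MAX3", max(abs(z)),
                   selected_score = unname(MODEL_SCORES[win]),
                   model = win, direction = sign1(z[[win]]))
}

#' MAX3 p-value
#'
#' Null p-value of [max3_stat()].  The default is a parametric bootstrap:
#' case and control genotype vectors are redrawn from multinomials with the
#' pooled genotype frequencies `n_i / n` at the observed sample sizes, and
#' the add-one estimator `(1 + #{MAX3* >= observed}) / (B + 1)` is
#' returned.  `method = "asymptotic"` instead evaluates the survival
#' function of the limiting rank-2 Gaussian maximum by one-dimensional
#' adaptive quadrature (deterministic, no Monte-Carlo error); this is the
#' path used inside large simulations.
#'
#' @inheritParams catt
#' @param B Number of bootstrap replicates (ignored for the asymptotic
#'   method).
#' @param seed Optional integer seed for the bootstrap; the RNG state is
#'   restored afterwards.
#' @param method `"bootstrap"` (default) or `"asymptotic"`.
#' @return An `"rr_robust"` object with `p_value` filled in.
#' @export
max3_pvalue <- function(counts, B = 1e5, seed = NULL,
                        method = c("bootstrap", "asymptotic")) {
  method <- match.arg(method)
  res <- max3_stat(counts)
  if (method == "asymptotic") {
    res$p_value <- max3_p_asymptotic(res$statistic,
                                     estimate_correlations(counts))
    return(res)
  }
  if (B < 1000)
    rr_stop("at least 1000 bootstrap replicates are required",
            "rr_input_error")
  g <- counts$n_geno / counts$n
  boot <- with_seed(seed, {
    bc <- t(stats::rmultinom(B, counts$n_cases, g))
    bs <- t(stats::rmultinom(B, counts$n_controls, g))
    m <- cbind(bc, bs)
    pmax(abs(zcatt_vec(m, 0)), abs(zcatt_vec(m, 0.5)),
         abs(zcatt_vec(m, 1)))
  })
  ## undefined bootstrap tables (degenerate redraws) never exceed
  res$p_value <- (1 + sum(boot >= res$statistic, na.rm = TRUE)) / (B + 1)
  res
}

#' MIN2 statistic
#'
#' The smaller of the Pearson 2-df p-value and the additive trend p-value,
#' `MIN2 = min(P_chi2, P_1/2)`.  Because it is a minimum of two dependent
#' p-values it is not itself a p-value; [min2_pvalue()] applies the
#' selection adjustment.  A tie selects the additive component.
#'
#' @inheritParams catt
#' @return An `"rr_robust"` object; `statistic` is the observed minimum,
#'   `component` records which test attained it (`"additive"` or
#'   `"chi2"`), `direction` the sign of the additive trend statistic.
#' @export
min2_stat <- function(counts) {
  check_testable(counts)
  p_half <- catt(counts, 0.5)
  p_chi <- pearson_chi2(counts)
  additive <- p_half$p_value <= p_chi$p_value
  rr_robust_result("MIN2", min(p_half$p_value, p_chi$p_value),
                   component = if (additive) "additive" else "chi2",
                   direction = sign1(p_half$statistic))
}

#' Selection-adjusted p-value for MIN2
#'
#' Evaluates `Pr(min(P_chi2, P_1/2) <= m)` under the asymptotic null, using
#' the joint law in which the 2-df statistic decomposes as the squared
#' additive trend statistic plus an independent 1-df chi-square.  The
#' result always lies in `[m, 2m]`.
#'
#' @param min2 Observed MIN2 value in `(0, 1]`, or an `"rr_robust"` object
#'   from [min2_stat()].
#' @return The adjusted p-value (numeric scalar), or the updated
#'   `"rr_robust"` object when one was supplied.
#' @export
min2_pvalue <- function(min2) {
  if (inherits(min2, "rr_robust")) {
    min2$p_value <- min2_null_cdf(min2$statistic)
    return(min2)
  }
  min2_null_cdf(min2)
}

## shared selection rule for the two-phase procedures.  `z` holds the three
## (possibly starred) components named REC/ADD/DOM; returns the aligned
## statistic and bookkeeping.
select_by_hwd <- function(z, z_H, c_threshold) {
  pos <- z[["ADD"]] > 0
  if (abs(z_H) <= c_threshold) {
    list(statistic = if (pos) z[["ADD"]] else -z[["ADD"]],
         component = "ADD", model = "ADD")
  } else if (z_H > c_threshold) {
    ## excess homozygosity in cases: recessive-type model for the risk allele
    list(statistic = if (pos) z[["REC"]] else -z[["DOM"]],
         component = if (pos) "REC" else "DOM", model = "REC")
  } else {
    list(statistic = if (pos) z[["DOM"]] else -z[["REC"]],
         component = if (pos) "DOM" else "REC", model = "DOM")
  }
}

#' Genetic model selection (GMS) statistic
#'
#' Two-phase procedure: the HWD trend statistic `Z_H` picks the genetic
#' model (recessive if `Z_H > c`, dominant if `Z_H < -c`, additive
#' otherwise, with `c = qnorm(1 - alpha_H)`), and the trend statistic
#' optimal for that model is then used, aligned with the risk allele
#' implied by the sign of `Z_1/2`.  When `Z_1/2 <= 0` the other allele is
#' taken as the risk allele, which negates the statistic and swaps the
#' recessive/dominant components.
#'
#' @inheritParams catt
#' @param alpha_H Level of the model-selection phase; the default 0.05 is
#'   the conventional choice.
#' @return An `"rr_robust"` object with the aligned `statistic`,
#'   `component` (which trend score was used: REC/ADD/DOM), `model` (the
#'   genetic model for the risk allele), `direction` = sign of `Z_1/2`
#'   (sign(0) = +1), `z_H` and the threshold used.
#' @export
gms_select <- function(counts, alpha_H = 0.05) {
  check_testable(counts)
  z <- trend_triple(counts)
  h <- hwdtt(counts)
  cthr <- stats::qnorm(1 - alpha_H)
  sel <- select_by_hwd(z, h$z_H, cthr)
  rr_robust_result("GMS", sel$statistic,
                   selected_score = unname(MODEL_SCORES[sel$component]),
                   component = sel$component, model = sel$model,
                   direction = sign1(z[["ADD"]]), z_H = h$z_H,
                   c_threshold = cthr, alpha_H = alpha_H)
}

#' GMS p-value
#'
#' Selection-adjusted null p-value of the [gms_select()] statistic.  The
#' probability that the HWD-selected, risk-allele-aligned statistic exceeds
#' the observed value is written as a sum over the three selection regions
#' and both risk-allele directions; with the plug-in correlation estimates
#' the rank-2 structure of the limiting Gaussian reduces each region term
#' to one-dimensional adaptive quadrature (absolute tolerance ~1e-13,
#' infinite limits truncated at 8.5).
#'
#' @param gms An `"rr_robust"` object from [gms_select()].
#' @param corr An `"rr_correlations"` object from [estimate_correlations()],
#'   normally computed from the same table.
#' @return The updated `"rr_robust"` object with `p_value` set.
#' @export
gms_pvalue <- function(gms, corr) {
  stopifnot(inherits(gms, "rr_robust"), gms$method == "GMS")
  check_corr(corr)
  gms$p_value <- p_selection_adjusted(gms$statistic, corr,
                                      alpha_H = gms$alpha_H,
                                      starred = FALSE)
  gms
}

#' Genetic model exclusion (GME) statistic
#'
#' Same selection regions as [gms_select()], but each extreme-model trend
#' statistic is replaced by the standardised average with the additive one,
#' `Z*_x = (Z_x + Z_1/2) / sqrt(2 (1 + rho_x_half))`, which hedges against
#' the low probability of `Z_H` selecting the true extreme model: rather
#' than committing to recessive (say), the unlikely dominant model is
#' merely excluded.  `Z*_1/2` equals `Z_1/2`.
#'
#' @inheritParams gms_select
#' @return An `"rr_robust"` object as for [gms_select()].
#' @export
gme_stat <- function(counts, alpha_H = 0.05) {
  check_testable(counts)
  z <- trend_triple(counts)
  corr <- estimate_correlations(counts)
  zs <- c(REC = (z[["REC"]] + z[["ADD"]]) / sqrt(2 * (1 + corr$rho_0_half)),
          ADD = z[["ADD"]],
          DOM = (z[["DOM"]] + z[["ADD"]]) / sqrt(2 * (1 + corr$rho_1_half)))
  h <- hwdtt(counts)
  cthr <- stats::qnorm(1 - alpha_H)
  sel <- select_by_hwd(zs, h$z_H, cthr)
  rr_robust_result("GME", sel$statistic,
                   selected_score = unname(MODEL_SCORES[sel$component]),
                   component = sel$component, model = sel$model,
                   direction = sign1(z[["ADD"]]), z_H = h$z_H,
                   c_threshold = cthr, alpha_H = alpha_H)
}

#' GME p-value
#'
#' Selection-adjusted p-value of the [gme_stat()] statistic, evaluated like
#' [gms_pvalue()] but with the averaged-and-rescaled components in the
#' extreme-model regions.
#'
#' @param gme An `"rr_robust"` object from [gme_stat()].
#' @inheritParams gms_pvalue
#' @return The updated `"rr_robust"` object with `p_value` set.
#' @export
gme_pvalue <- function(gme, corr) {
  stopifnot(inherits(gme, "rr_robust"), gme$method == "GME")
  check_corr(corr)
  gme$p_value <- p_selection_adjusted(gme$statistic, corr,
                                      alpha_H = gme$alpha_H,
                                      starred = TRUE)
  gme
}

check_corr <- function(corr) {
  if (!inherits(corr, "rr_correlations"))
    rr_stop("`corr` must come from estimate_correlations()", "rr_input_error")
  vals <- unlist(corr[c("rho_0_half", "rho_1_half", "rho_0", "rho_1",
                        "rho_half")])
  if (any(!is.finite(vals)) || any(abs(vals) >= 1))
    rr_stop("correlation estimates must lie strictly inside (-1, 1)",
            "rr_input_error")
  invisible(corr)
}

## run one RNG-consuming expression under an optional local seed
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else rm(".Random.seed", envir = globalenv()))
  }
  expr
}
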