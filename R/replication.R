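## Replication-stage p-values that inherit the discovery-stage method,
## selected genetic model and risk-allele direction.

#' Discovery-stage record for a marker
#'
#' Computes, from the discovery-stage counts, everything the replication
#' stage needs: the method's own p-value, the selected score or component,
#' the HWD selection region, and the signs of the plain and averaged trend
#' statistics.  Conditioning the replication stage on this record is what
#' makes the two stages' p-values independent under the null: the sign of
#' `Z_1/2` is +/- with probability 1/2 and each selection region has fixed
#' null probability, none of which involves the replication data.
#'
#' @inheritParams catt
#' @param method One of `"catt"`, `"chi2"`, `"max3"`, `"min2"`, `"gms"`,
#'   `"gme"`.
#' @param x Heterozygote score when `method = "catt"`.
#' @param alpha_H Model-selection level for GMS/GME.
#' @param B,seed,max3_method Passed to [max3_pvalue()] when
#'   `method = "max3"`.
#' @return An object of class `"rr_stage1"`: a flat list of the fields
#'   above (see [as.data.frame.rr_stage1()] for the serialised layout).
#' @export
stage1_record <- function(counts, method = c("catt", "chi2", "max3", "min2",
                                             "gms", "gme"),
                          x = 0.5, alpha_H = 0.05, B = 1e5, seed = NULL,
                          max3_method = "bootstrap") {
  method <- match.arg(method)
  check_testable(counts)
  z <- trend_triple(counts)
  h <- hwdtt(counts)
  corr <- estimate_correlations(counts)
  p2sided <- 2 * stats::pnorm(-abs(z))
  chi <- pearson_chi2(counts)
  cthr <- stats::qnorm(1 - alpha_H)
  zs <- c(REC = (z[["REC"]] + z[["ADD"]]) / sqrt(2 * (1 + corr$rho_0_half)),
          ADD = z[["ADD"]],
          DOM = (z[["DOM"]] + z[["ADD"]]) / sqrt(2 * (1 + corr$rho_1_half)))
  region <- if (abs(h$z_H) <= cthr) "ADD" else if (h$z_H > cthr) "REC" else "DOM"

  p1 <- switch(method,
    catt = catt(counts, x)$p_value,
    chi2 = chi$p_value,
    max3 = max3_pvalue(counts, B = B, seed = seed,
                       method = max3_method)$p_value,
    min2 = min2_pvalue(min2_stat(counts))$p_value,
    gms = gms_pvalue(gms_select(counts, alpha_H), corr)$p_value,
    gme = gme_pvalue(gme_stat(counts, alpha_H), corr)$p_value)

  structure(list(
    snp = counts$snp, method = method, p_value = p1,
    x = if (method == "catt") x else NA_real_,
    alpha_H = alpha_H, c_threshold = cthr, region = region,
    sign_add = sign1(z[["ADD"]]),
    sign_rec = sign1(z[["REC"]]), sign_dom = sign1(z[["DOM"]]),
    sign_rec_star = sign1(zs[["REC"]]), sign_dom_star = sign1(zs[["DOM"]]),
    p_rec = p2sided[["REC"]], p_add = p2sided[["ADD"]],
    p_dom = p2sided[["DOM"]], p_chi2 = chi$p_value
  ), class = "rr_stage1")
}

#' @export
print.rr_stage1 <- function(x, ...) {
  cat(sprintf("Stage-1 record (%s): p1 = %.4g, region = %s, sign(Z_1/2) = %+d\n",
              x$method, x$p_value, x$region, x$sign_add))
  invisible(x)
}

#' Serialise / restore a discovery-stage record
#'
#' `as.data.frame()` flattens the record to one row; `stage1_from_row()`
#' rebuilds an identical record from such a row (e.g. read back from a
#' TSV), so that a precomputed-summary workflow matches the counts-based
#' one exactly.
#'
#' @param x An `"rr_stage1"` object.
#' @param ... Unused.
#' @export
as.data.frame.rr_stage1 <- function(x, ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}

#' @rdname as.data.frame.rr_stage1
#' @param row A one-row data frame with the columns produced by
#'   `as.data.frame()`.
#' @export
stage1_from_row <- function(row) {
  row <- as.list(row)
  structure(row[c("snp", "method", "p_value", "x", "alpha_H", "c_threshold",
                  "region", "sign_add", "sign_rec", "sign_dom",
                  "sign_rec_star", "sign_dom_star", "p_rec", "p_add",
                  "p_dom", "p_chi2")],
            class = "rr_stage1")
}

## one-sided normal p aligned to a stage-1 sign
aligned_p <- function(sign1_stage1, z2) {
  stats::pnorm(sign1_stage1 * z2, lower.tail = FALSE)
}

#' Replication-stage p-value
#'
#' One-sided replication p-value that adopts the discovery stage's analytic
#' method, selected genetic model and risk-allele direction.  For a trend
#' statistic with score `x`, `P^(2) = 1 - pnorm(sign(Z_x^(1)) * Z_x^(2))`.
#' MAX3 replicates the score with the smallest discovery p-value; MIN2
#' replicates whichever of the additive trend and the 2-df Pearson test won
#' at discovery (ties to additive; the Pearson p-value is inherently
#' one-sided); GMS and GME replicate the component fixed by the discovery
#' HWD region and the sign of the discovery `Z_1/2`, GME with the
#' averaged components standardised by the replication-stage correlation
#' estimate.
#'
#' @param record An `"rr_stage1"` object from [stage1_record()].
#' @param counts2 Replication-stage [genotype_counts()].
#' @return A list with `p_value`, the replication `statistic` used, and
#'   the `component` replicated.
#' @export
stage2_pvalue <- function(record, counts2) {
  if (!inherits(record, "rr_stage1"))
    rr_stop("`record` must come from stage1_record()", "rr_input_error")
  check_testable(counts2)
  z2 <- trend_triple(counts2)

  if (record$method == "catt") {
    if (is.na(record$x))
      rr_stop("stage-1 record lacks the trend score", "rr_input_error")
    zx <- zcatt_vec(counts_row(counts2), record$x)
    sg <- if (record$x < 0.5) record$sign_rec
          else if (record$x > 0.5) record$sign_dom else record$sign_add
    return(list(p_value = aligned_p(sg, zx), statistic = zx,
                component = sprintf("x=%g", record$x)))
  }
  if (record$method == "chi2") {
    chi <- pearson_chi2(counts2)
    return(list(p_value = chi$p_value, statistic = chi$statistic,
                component = "chi2"))
  }
  if (record$method == "max3") {
    p1 <- c(REC = record$p_rec, ADD = record$p_add, DOM = record$p_dom)
    ord <- c("ADD", "REC", "DOM")
    win <- ord[which.min(p1[ord])]
    sg <- switch(win, REC = record$sign_rec, ADD = record$sign_add,
                 DOM = record$sign_dom)
    return(list(p_value = aligned_p(sg, z2[[win]]), statistic = z2[[win]],
                component = win))
  }
  if (record$method == "min2") {
    if (record$p_add <= record$p_chi2) {
      return(list(p_value = aligned_p(record$sign_add, z2[["ADD"]]),
                  statistic = z2[["ADD"]], component = "additive"))
    }
    chi <- pearson_chi2(counts2)
    return(list(p_value = chi$p_value, statistic = chi$statistic,
                component = "chi2"))
  }
  if (record$method == "gms") {
    comp <- gms_stage2_component(record)
    sg <- switch(comp, REC = record$sign_rec, ADD = record$sign_add,
                 DOM = record$sign_dom)
    return(list(p_value = aligned_p(sg, z2[[comp]]), statistic = z2[[comp]],
                component = comp))
  }
  ## gme: averaged components standardised with replication-stage estimates
  corr2 <- estimate_correlations(counts2)
  zs2 <- c(REC = (z2[["REC"]] + z2[["ADD"]]) / sqrt(2 * (1 + corr2$rho_0_half)),
           ADD = z2[["ADD"]],
           DOM = (z2[["DOM"]] + z2[["ADD"]]) / sqrt(2 * (1 + corr2$rho_1_half)))
  comp <- gms_stage2_component(record)
  sg <- switch(comp, REC = record$sign_rec_star, ADD = record$sign_add,
               DOM = record$sign_dom_star)
  list(p_value = aligned_p(sg, zs2[[comp]]), statistic = zs2[[comp]],
       component = comp)
}

## which trend component the two-phase procedures replicate: the discovery
## HWD region, with the REC/DOM roles exchanged when the discovery Z_1/2
## pointed at the other allele.
gms_stage2_component <- function(record) {
  if (record$region == "ADD") return("ADD")
  pos <- record$sign_add > 0
  if (record$region == "REC") { if (pos) "REC" else "DOM" }
  else { if (pos) "DOM" else "REC" }
}
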