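test_that("MAX3 dominates its components and is allele-relabel invariant", {
  eq <- genotype_counts(c(10, 20, 30), c(10, 20, 30))
  expect_equal(max3_stat(eq)$statistic, 0)
  expect_equal(max3_stat(eq)$selected_score, 0.5)  # tie -> additive

  set.seed(5)
  for (i in 1:15) {
    gc <- rand_counts()
    m3 <- max3_stat(gc)
    expect_gte(m3$statistic, abs(catt(gc, 0.5)$statistic))
    expect_equal(max3_stat(relabel(gc))$statistic, m3$statistic,
                 tolerance = 1e-12)
    expect_equal(max3_stat(swap(gc))$statistic, m3$statistic,
                 tolerance = 1e-12)
  }
})

test_that("bootstrap MAX3 p-value is bounded, seed-stable and Bonferroni-bracketed", {
  set.seed(17)
  gc <- rand_counts(150)
  B <- 20000
  res1 <- max3_pvalue(gc, B = B, seed = 1)
  res2 <- max3_pvalue(gc, B = B, seed = 2)
  expect_gte(res1$p_value, 1 / (B + 1))
  expect_lte(res1$p_value, 1)
  ## identical seed reproduces exactly; different seeds agree within MC error
  expect_identical(res1$p_value, max3_pvalue(gc, B = B, seed = 1)$p_value)
  se <- sqrt(res1$p_value * (1 - res1$p_value) / B)
  expect_within_3se(res2$p_value, res1$p_value, sqrt(2) * se,
                    "bootstrap self-consistency")

  for (i in 1:5) {
    gc <- rand_counts()
    p <- max3_pvalue(gc, B = 5000, seed = i)$p_value
    best_single <- min(catt(gc, 0)$p_value, catt(gc, 0.5)$p_value,
                       catt(gc, 1)$p_value)
    mc_slack <- 3 * sqrt(p * (1 - p) / 5000)
    expect_lte(p, 3 * best_single + mc_slack)
    expect_gte(p, best_single - mc_slack)
  }
})

test_that("asymptotic MAX3 p-value agrees with the parametric bootstrap", {
  set.seed(19)
  gc <- genotype_counts(c(40, 55, 25), c(55, 50, 15))
  B <- 50000
  pb <- max3_pvalue(gc, B = B, seed = 3)$p_value
  pa <- max3_pvalue(gc, method = "asymptotic")$p_value
  expect_within_3se(pa, pb, sqrt(pb * (1 - pb) / B), "asymptotic vs bootstrap")
})

test_that("MIN2 statistic takes the smaller component p-value", {
  eq <- genotype_counts(c(10, 20, 30), c(10, 20, 30))
  res <- min2_stat(eq)
  expect_equal(res$statistic, 1)
  expect_equal(res$component, "additive")  # tie rule

  set.seed(29)
  for (i in 1:10) {
    gc <- rand_counts()
    res <- min2_stat(gc)
    expect_lte(res$statistic, catt(gc, 0.5)$p_value)
    expect_lte(res$statistic, pearson_chi2(gc)$p_value)
    expect_equal(min2_stat(relabel(gc))$statistic, res$statistic,
                 tolerance = 1e-12)
  }
})

test_that("MIN2 selection adjustment matches its Monte-Carlo null and stays within the Bonferroni bracket", {
  expect_equal(min2_pvalue(1), 1)
  expect_error(min2_pvalue(0), class = "rr_input_error")
  expect_error(min2_pvalue(1.5), class = "rr_input_error")

  ## null representation: 2-df statistic = additive-z^2 + independent 1-df
  set.seed(31)
  N <- 1e6
  z1 <- rnorm(N); z2 <- rnorm(N)
  p_add <- pchisq(z1^2, 1, lower.tail = FALSE)
  p_chi <- pchisq(z1^2 + z2^2, 2, lower.tail = FALSE)
  mn <- pmin(p_add, p_chi)
  for (m in c(0.05, 0.01, 1e-4)) {
    mc <- mean(mn <= m)
    se <- sqrt(max(mc, 1 / N) * (1 - mc) / N)
    expect_within_3se(min2_pvalue(m), mc, se, sprintf("MIN2 oracle m=%g", m))
  }

  grid <- 10^seq(-7, 0, by = 0.5)
  padj <- vapply(grid, min2_pvalue, 0)
  expect_true(all(diff(padj) > 0))              # strictly increasing
  expect_true(all(padj >= grid & padj <= 2 * grid))
})

test_that("model selection follows the HWD statistic and the risk-allele direction", {
  ## strong excess homozygosity in cases -> recessive region
  gc_rec <- genotype_counts(c(40, 10, 50), c(25, 50, 25))
  sel <- gms_select(gc_rec)
  expect_gt(sel$z_H, qnorm(0.95))
  if (sel$direction > 0) {
    expect_equal(sel$component, "REC")
    expect_equal(sel$statistic, catt(gc_rec, 0)$statistic, tolerance = 1e-12)
  } else {
    expect_equal(sel$component, "DOM")
    expect_equal(sel$statistic, -catt(gc_rec, 1)$statistic, tolerance = 1e-12)
  }
  expect_equal(sel$model, "REC")

  ## HWD in the neutral band -> additive component regardless
  gc_add <- genotype_counts(c(40, 50, 20), c(55, 45, 10))
  sel <- gms_select(gc_add)
  expect_lte(abs(sel$z_H), qnorm(0.95))
  expect_equal(sel$component, "ADD")
  expect_equal(abs(sel$statistic), abs(catt(gc_add, 0.5)$statistic),
               tolerance = 1e-12)

  set.seed(37)
  for (i in 1:15) {
    gc <- rand_counts()
    expect_equal(gms_select(relabel(gc))$statistic,
                 gms_select(gc)$statistic, tolerance = 1e-12)
    expect_equal(gme_stat(relabel(gc))$statistic,
                 gme_stat(gc)$statistic, tolerance = 1e-10)
  }
})

test_that("model exclusion components are unit-scaled and reduce to model selection in the additive region", {
  set.seed(41)
  for (i in 1:10) {
    gc <- rand_counts()
    sel <- gms_select(gc)
    if (sel$component == "ADD")
      expect_equal(gme_stat(gc)$statistic, sel$statistic, tolerance = 1e-12)
  }
  ## Var((Z_x + Z_1/2) / sqrt(2 (1 + rho))) = 1 by construction: check on
  ## bootstrap replicates
  gc <- genotype_counts(c(60, 80, 60), c(70, 90, 50))
  est <- estimate_correlations(gc)
  B <- 50000
  m <- null_tables(B, gc$n_cases, gc$n_controls, gc$n_geno / gc$n)
  zstar <- (robrep:::zcatt_vec(m, 0) + robrep:::zcatt_vec(m, 0.5)) /
    sqrt(2 * (1 + est$rho_0_half))
  expect_lt(abs(sd(zstar, na.rm = TRUE) - 1), 3 / sqrt(2 * B) + 0.01)
})

test_that("selection-adjusted p-values match the Monte-Carlo oracle of the full rule", {
  set.seed(43)
  gc <- genotype_counts(c(50, 70, 40), c(65, 70, 25))
  est <- estimate_correlations(gc)
  N <- 1e6
  Z <- draw_null_field(N, as.matrix(est))
  cthr <- qnorm(0.95)
  zg <- oracle_select(Z[, 1], Z[, 2], Z[, 3], Z[, 4], cthr)
  k0 <- sqrt(2 * (1 + est$rho_0_half)); k1 <- sqrt(2 * (1 + est$rho_1_half))
  ze <- oracle_select((Z[, 1] + Z[, 2]) / k0, Z[, 2],
                      (Z[, 3] + Z[, 2]) / k1, Z[, 4], cthr)
  for (t in c(1.5, 2.5, 3.5)) {
    mc_g <- mean(zg > t)
    se_g <- sqrt(mc_g * (1 - mc_g) / N)
    pg <- robrep:::p_selection_adjusted(t, est, alpha_H = 0.05,
                                        starred = FALSE)
    expect_within_3se(pg, mc_g, se_g, sprintf("GMS oracle t=%g", t))
    mc_e <- mean(ze > t)
    se_e <- sqrt(mc_e * (1 - mc_e) / N)
    pe <- robrep:::p_selection_adjusted(t, est, alpha_H = 0.05,
                                        starred = TRUE)
    expect_within_3se(pe, mc_e, se_e, sprintf("GME oracle t=%g", t))
  }
  ## survival-type monotonicity
  ts <- seq(0.5, 4.5, by = 0.5)
  pg <- vapply(ts, robrep:::p_selection_adjusted, 0, corr = est)
  expect_true(all(diff(pg) < 0))
})

test_that("GMS and GME p-values are calibrated end to end under a genotype-sampling null", {
  set.seed(47)
  N <- 10000
  g <- c(0.49, 0.42, 0.09)
  m <- null_tables(N, 750, 750, g)
  z0 <- robrep:::zcatt_vec(m, 0); zA <- robrep:::zcatt_vec(m, 0.5)
  z1 <- robrep:::zcatt_vec(m, 1); zh <- robrep:::zhwdtt_vec(m)
  co <- robrep:::corr_vec(m)
  cthr <- qnorm(0.95)
  level <- 0.05
  rej <- function(starred) {
    if (starred) {
      zr <- (z0 + zA) / sqrt(2 * (1 + co[, 1]))
      zd <- (z1 + zA) / sqrt(2 * (1 + co[, 2]))
    } else { zr <- z0; zd <- z1 }
    t <- oracle_select(zr, zA, zd, zh, cthr)
    ## lower bound 2 pnorm(-t) - 2 alpha_H rules out small t cheaply
    cand <- which(t > 0 & 2 * pnorm(-t) - 0.1 < level)
    p <- vapply(cand, function(i)
      robrep:::p_selection_adjusted(t[i], robrep:::corr_row(co, i),
                                    alpha_H = 0.05, starred = starred,
                                    rel.tol = 1e-7), 0)
    sum(p < level) / N
  }
  se <- sqrt(level * (1 - level) / N)
  expect_within_3se(rej(FALSE), level, se, "GMS null level")
  expect_within_3se(rej(TRUE), level, se, "GME null level")
})
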