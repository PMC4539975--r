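test_that("trend test matches its closed-form special cases", {
  eq <- genotype_counts(c(10, 20, 30), c(10, 20, 30))
  for (x in c(0, 0.25, 0.5, 1))
    expect_equal(catt(eq, x)$statistic, 0)

  ## dominant coding reduces to the pooled two-proportion z-test on
  ## carrier fractions 30/40 vs 20/40
  gc <- genotype_counts(c(10, 10, 20), c(20, 10, 10))
  p1 <- 30 / 40; p2 <- 20 / 40; pb <- 50 / 80
  z_two_prop <- (p1 - p2) / sqrt(pb * (1 - pb) * (1 / 40 + 1 / 40))
  expect_equal(catt(gc, 1)$statistic, z_two_prop, tolerance = 1e-12)
  expect_equal(catt(gc, 1)$statistic, 2.3094, tolerance = 1e-4)
  expect_equal(catt(gc, 1)$p_value,
               2 * pnorm(-abs(catt(gc, 1)$statistic)))
})

test_that("trend statistics flip sign under case/control swap and map to the mirrored score under allele relabelling", {
  set.seed(42)
  for (i in 1:20) {
    gc <- rand_counts()
    for (x in c(0, 0.3, 0.5, 1)) {
      expect_equal(catt(swap(gc), x)$statistic, -catt(gc, x)$statistic,
                   tolerance = 1e-12)
      expect_equal(catt(relabel(gc), x)$statistic,
                   -catt(gc, 1 - x)$statistic, tolerance = 1e-12)
    }
  }
})

test_that("Pearson test agrees with the six-cell brute-force formula and is relabel-invariant", {
  eq <- genotype_counts(c(10, 20, 30), c(10, 20, 30))
  expect_equal(pearson_chi2(eq)$statistic, 0)
  expect_equal(pearson_chi2(eq)$p_value, 1)

  set.seed(7)
  for (i in 1:20) {
    gc <- rand_counts()
    obs <- c(gc$r, gc$s)
    expd <- c(gc$n_geno * gc$n_cases / gc$n, gc$n_geno * gc$n_controls / gc$n)
    brute <- sum((obs - expd)^2 / expd)
    res <- pearson_chi2(gc)
    expect_equal(res$statistic, brute, tolerance = 1e-12)
    expect_equal(pearson_chi2(relabel(gc))$statistic, res$statistic,
                 tolerance = 1e-12)
    expect_equal(pearson_chi2(swap(gc))$statistic, res$statistic,
                 tolerance = 1e-12)
  }
})

test_that("Pearson test drops a df when a pooled genotype class is empty", {
  gc <- genotype_counts(c(0, 10, 20), c(0, 20, 10))
  res <- pearson_chi2(gc)
  expect_equal(res$df, 1)
  expect_equal(res$p_value, pchisq(res$statistic, 1, lower.tail = FALSE))
})

test_that("degenerate and invalid tables raise typed errors", {
  mono <- genotype_counts(c(0, 0, 30), c(0, 0, 30))
  expect_error(catt(mono), class = "rr_degenerate_error")
  expect_error(pearson_chi2(mono), class = "rr_degenerate_error")
  expect_error(abt(mono), class = "rr_degenerate_error")
  expect_error(max3_stat(mono), class = "rr_degenerate_error")
  expect_error(genotype_counts(c(-1, 2, 3), c(1, 1, 1)),
               class = "rr_input_error")
  expect_error(catt(genotype_counts(c(1, 2, 3), c(0, 0, 0))),
               class = "rr_input_error")
  expect_error(catt(genotype_counts(c(1, 2, 3), c(1, 1, 1)), x = 1.5),
               class = "rr_input_error")
})

test_that("allele-based test is centred and calibrated under an HWE null", {
  eq <- genotype_counts(c(10, 20, 30), c(10, 20, 30))
  expect_equal(abt(eq)$statistic, 0)
  gc <- rand_counts()
  expect_equal(abt(swap(gc))$statistic, -abt(gc)$statistic,
               tolerance = 1e-12)

  set.seed(11)
  g <- c(0.49, 0.42, 0.09)  # HWE, allele frequency 0.3
  N <- 5000
  m <- null_tables(N, 500, 500, g)
  zab <- apply(m, 1, function(row)
    abt(genotype_counts(row[1:3], row[4:6]))$statistic)
  rej <- mean(abs(zab) > qnorm(0.975))
  expect_within_3se(rej, 0.05, sqrt(0.05 * 0.95 / N), "ABT null level")
})

test_that("HWD trend test recovers the disequilibrium coefficients", {
  hw <- genotype_counts(c(25, 50, 25), c(25, 50, 25))
  res <- hwdtt(hw)
  expect_equal(res$delta_p, 0)
  expect_equal(res$delta_q, 0)
  expect_equal(res$z_H, 0)

  gc <- genotype_counts(c(50, 0, 50), c(25, 50, 25))
  res <- hwdtt(gc)
  expect_equal(res$delta_p, 0.25)
  expect_equal(res$delta_q, 0)
  expect_gt(res$z_H, 0)
  expect_equal(hwdtt(swap(gc))$z_H, -res$z_H, tolerance = 1e-12)
})

test_that("every z statistic is calibrated under a multinomial null", {
  set.seed(13)
  g <- c(0.36, 0.48, 0.16)
  N <- 20000
  m <- null_tables(N, 400, 600, g)
  se <- sqrt(0.05 * 0.95 / N)
  for (x in c(0, 0.5, 1)) {
    z <- robrep:::zcatt_vec(m, x)
    expect_within_3se(mean(2 * pnorm(-abs(z)) < 0.05), 0.05, se,
                      sprintf("CATT x=%g", x))
  }
  zh <- robrep:::zhwdtt_vec(m)
  expect_within_3se(mean(2 * pnorm(-abs(zh)) < 0.05), 0.05, se, "HWDTT")
  chi <- robrep:::chi2_vec(m)
  expect_within_3se(mean(chi$p < 0.05), 0.05, se, "Pearson")
})

test_that("plug-in correlations match a parametric-bootstrap oracle and form a PSD matrix", {
  set.seed(23)
  ## pooled frequencies symmetric about the heterozygote: REC and DOM
  ## scores play mirror-image roles
  sym <- genotype_counts(c(25, 50, 25), c(25, 50, 25))
  cs <- estimate_correlations(sym)

  for (i in 1:3) {
    gc <- rand_counts(150)
    est <- estimate_correlations(gc)
    vals <- unlist(est[c("rho_0_half", "rho_1_half", "rho_0", "rho_1",
                         "rho_half")])
    expect_true(all(abs(vals) < 1))
    expect_true(all(eigen(as.matrix(est), symmetric = TRUE,
                          only.values = TRUE)$values > -1e-8))

    ## bootstrap from the table's own margins
    B <- 100000
    g <- gc$n_geno / gc$n
    m <- null_tables(B, gc$n_cases, gc$n_controls, g)
    z0 <- robrep:::zcatt_vec(m, 0)
    zA <- robrep:::zcatt_vec(m, 0.5)
    z1 <- robrep:::zcatt_vec(m, 1)
    zh <- robrep:::zhwdtt_vec(m)
    ok <- is.finite(z0) & is.finite(zA) & is.finite(z1) & is.finite(zh)
    se_cor <- function(rho) (1 - rho^2) / sqrt(sum(ok))
    pairs <- list(
      list(est$rho_0_half, z0, zA), list(est$rho_1_half, z1, zA),
      list(est$rho_0, z0, zh), list(est$rho_1, z1, zh),
      list(est$rho_half, zA, zh))
    for (p in pairs) {
      emp <- cor(p[[2]][ok], p[[3]][ok])
      expect_within_3se(p[[1]], emp, se_cor(emp), "plug-in vs bootstrap")
    }
  }

  ## genotype-frequency symmetry makes the REC and DOM scores mirror
  ## images about the additive one
  expect_equal(cs$rho_0_half, cs$rho_1_half, tolerance = 1e-12)
})
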