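## Shared fixtures and small oracles for the test suite.

## random non-degenerate genotype table
rand_counts <- function(n_each = 100) {
  repeat {
    g <- as.vector(stats::rmultinom(1, 3, rep(1, 3))) + 1
    g <- g / sum(g)
    r <- as.vector(stats::rmultinom(1, n_each, g))
    s <- as.vector(stats::rmultinom(1, n_each, g))
    gc <- genotype_counts(r, s)
    if (!is_degenerate(gc) && all(gc$n_geno > 0)) return(gc)
  }
}

## allele-relabelled table: reverse genotype order
relabel <- function(counts) {
  genotype_counts(rev(counts$r), rev(counts$s), counts$snp)
}

## case/control swap
swap <- function(counts) {
  genotype_counts(counts$s, counts$r, counts$snp)
}

## N null tables (shared case/control genotype probabilities) as an N x 6
## matrix, for the vectorised statistic kernels
null_tables <- function(N, r, s, g) {
  cbind(t(stats::rmultinom(N, r, g)), t(stats::rmultinom(N, s, g)))
}

## draw N samples of (Z_0, Z_1/2, Z_1, Z_H) from the multivariate normal
## with the given 4x4 correlation matrix (possibly singular), via eigen
## decomposition -- an oracle route independent of the package's internal
## rank-2 reduction.
draw_null_field <- function(N, corr_matrix) {
  ev <- eigen(corr_matrix, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  A <- ev$vectors %*% diag(sqrt(lam))
  matrix(stats::rnorm(N * 4), N, 4) %*% t(A)
}

## the HWD-driven selection rule applied to sampled fields; mirrors the
## published verbal rule, not the package internals
oracle_select <- function(z0, zA, z1, zh, cthr) {
  pos <- zA > 0
  ifelse(abs(zh) <= cthr, ifelse(pos, zA, -zA),
  ifelse(zh > cthr, ifelse(pos, z0, -z1),
                    ifelse(pos, z1, -z0)))
}

expect_within_3se <- function(estimate, target, se, info = NULL) {
  expect_lt(abs(estimate - target), 3 * se, label = info)
}
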