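#' Genotype counts for one marker
#'
#' Container for the 2x3 case/control genotype table of a single biallelic
#' marker.  Genotypes are ordered `G0 = AA`, `G1 = AB`, `G2 = BB`, where `B`
#' is the candidate risk allele.  All association tests in the package take
#' one of these objects as input.
#'
#' @param r Integer vector of length 3: case counts `(r0, r1, r2)` for
#'   genotypes `(AA, AB, BB)`.
#' @param s Integer vector of length 3: control counts `(s0, s1, s2)`.
#' @param snp Optional marker identifier.
#'
#' @return An object of class `"genotype_counts"`: a list with elements
#'   `r`, `s` (length-3 count vectors), `snp`, and the derived totals
#'   `n_cases`, `n_controls`, `n`, `n_geno` (pooled per-genotype counts).
#'
#' @examples
#' gc <- genotype_counts(c(10, 10, 20), c(20, 10, 10))
#' catt(gc, x = 0.5)
#' @export
genotype_counts <- function(r, s, snp = NA_character_) {
  r <- as.numeric(r); s <- as.numeric(s)
  if (length(r) != 3L || length(s) != 3L)
    rr_stop("genotype counts must have three genotype classes", "rr_input_error")
  if (anyNA(r) || anyNA(s))
    rr_stop("genotype counts contain NA", "rr_input_error")
  if (any(r < 0) || any(s < 0))
    rr_stop("genotype counts must be non-negative", "rr_input_error")
  if (any(r != round(r)) || any(s != round(s)))
    rr_stop("genotype counts must be integers", "rr_input_error")
  structure(list(
    r = r, s = s, snp = snp,
    n_cases = sum(r), n_controls = sum(s),
    n = sum(r) + sum(s), n_geno = r + s
  ), class = "genotype_counts")
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat("Genotype counts", if (!is.na(x$snp)) paste0("for ", x$snp), "\n")
  m <- rbind(cases = x$r, controls = x$s)
  colnames(m) <- c("AA", "AB", "BB")
  print(m)
  invisible(x)
}

#' Test whether a marker's table is degenerate
#'
#' A table is degenerate when every observation carries the same genotype
#' (one pooled genotype class holds all `n` subjects), in which case none of
#' the trend-type statistics are defined.
#'
#' @param counts A [genotype_counts()] object.
#' @return Logical scalar.
#' @export
is_degenerate <- function(counts) {
  any(counts$n_geno == counts$n)
}

## internal: common preconditions for the single-table tests
check_testable <- function(counts) {
  if (!inherits(counts, "genotype_counts"))
    rr_stop("`counts` must be a genotype_counts object", "rr_input_error")
  if (counts$n_cases == 0 || counts$n_controls == 0)
    rr_stop("both cases and controls are required", "rr_input_error")
  if (is_degenerate(counts))
    rr_stop("degenerate marker: all observations share one genotype",
            "rr_degenerate_error")
  invisible(counts)
}

rr_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "rr_error")))
}

## sign convention used throughout: sign(0) == +1
sign1 <- function(x) ifelse(x >= 0, 1, -1)
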