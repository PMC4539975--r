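## Tab-separated genotype-count tables and result output.

COUNT_COLS <- c("snp", "r0", "r1", "r2", "s0", "s1", "s2")

#' Read a genotype-count table
#'
#' Reads a UTF-8 tab-separated file with header
#' `snp r0 r1 r2 s0 s1 s2`: one marker per row, case counts `(r0, r1, r2)`
#' and control counts `(s0, s1, s2)` for genotypes `(AA, AB, BB)`.
#' Degenerate markers (all observations in one genotype class) are kept
#' but flagged; downstream batch runs report them as NA rows.
#'
#' @param path File path.
#' @return A data frame with the seven columns plus a logical `degenerate`
#'   column; attribute `"file"` records the provenance.
#' @export
read_counts <- function(path) {
  if (!file.exists(path))
    rr_stop(paste("no such file:", path), "rr_io_error")
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!identical(names(df), COUNT_COLS))
    rr_stop(sprintf("malformed header in %s: expected '%s'", path,
                    paste(COUNT_COLS, collapse = "\t")), "rr_io_error")
  if (nrow(df) == 0) {
    warning(sprintf("%s contains a header but no markers", path))
  }
  num <- df[, -1, drop = FALSE]
  for (j in seq_along(num)) {
    col <- num[[j]]
    bad <- which(!is.finite(col) | col < 0 | col != round(col))
    if (length(bad))
      rr_stop(sprintf("invalid count in %s, line %d, column %s",
                      path, bad[1] + 1L, names(num)[j]), "rr_io_error")
  }
  if (anyDuplicated(df$snp))
    rr_stop(sprintf("duplicate snp id in %s: %s", path,
                    df$snp[duplicated(df$snp)][1]), "rr_io_error")
  tot <- rowSums(num)
  gmax <- pmax(num$r0 + num$s0, num$r1 + num$s1, num$r2 + num$s2)
  df$degenerate <- tot == 0 | gmax == tot
  attr(df, "file") <- path
  df
}

## one row -> genotype_counts
counts_from_row <- function(row) {
  genotype_counts(c(row$r0, row$r1, row$r2), c(row$s0, row$s1, row$s2),
                  snp = row$snp)
}

#' Write a results table
#'
#' Deterministic TSV output: fixed column order, p-values and statistics
#' in scientific notation with six significant digits (so genome-wide
#' scale p-values survive write/read round trips), `NA` for markers whose
#' tests were undefined.
#'
#' @param results A data frame.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(results, path) {
  if (is.null(results))
    rr_stop("results must not be NULL", "rr_input_error")
  out <- results
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !all(out[[j]] == round(out[[j]]), na.rm = TRUE))
      out[[j]] <- ifelse(is.na(out[[j]]), NA,
                         formatC(out[[j]], digits = 6, format = "g"))
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) rr_stop(paste("cannot write to", path), "rr_io_error")
  invisible(path)
}
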