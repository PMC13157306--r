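#' Missingness diagnostics for a two-wave panel
#'
#' Tabulates per-column missing counts and percentages and the pairwise
#' (phi) correlations between missingness indicators, the usual first look
#' at whether missingness clusters systematically (MAR-like) or appears
#' unrelated across variables (MCAR-like).
#'
#' @param data A [clpn_panel()].
#' @param mar_corr_threshold Mean absolute indicator correlation above which
#'   a column is hinted `"MAR-like"` (default 0.1).
#' @return An object of class `clpn_missingness` with `summary` (data frame:
#'   `column`, `n_missing`, `pct_missing`, `hint`) and `indicator_cor`
#'   (correlation matrix of missingness indicators; `NA` where a column has
#'   no missing or fully missing values).
#' @export
missingness_report <- function(data, mar_corr_threshold = 0.1) {
  stopifnot(inherits(data, "clpn_panel"))
  M <- cbind(data$t1, data$t2)
  colnames(M) <- c(paste0(colnames(data$t1), "_t1"),
                   paste0(colnames(data$t2), "_t2"))
  ind <- is.na(M) * 1L
  n <- nrow(M)
  n_missing <- colSums(ind)
  pct <- 100 * n_missing / n

  # indicator correlations are undefined for constant indicators
  sds <- apply(ind, 2, sd)
  C <- matrix(NA_real_, ncol(M), ncol(M),
              dimnames = list(colnames(M), colnames(M)))
  ok <- which(sds > 0)
  if (length(ok) >= 2) C[ok, ok] <- cor(ind[, ok, drop = FALSE])
  diag(C)[sds > 0] <- 1

  mean_abs <- vapply(seq_len(ncol(M)), function(j) {
    v <- abs(C[j, -j]); if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  hint <- ifelse(is.na(mean_abs), "not-applicable",
                 ifelse(mean_abs > mar_corr_threshold, "MAR-like", "MCAR-like"))

  structure(list(
    summary = data.frame(column = colnames(M), n_missing = n_missing,
                         pct_missing = pct, hint = hint,
                         row.names = NULL, stringsAsFactors = FALSE),
    indicator_cor = C, n = n), class = "clpn_missingness")
}

#' @export
print.clpn_missingness <- function(x, ...) {
  rng <- range(x$summary$pct_missing)
  cat(sprintf("<clpn_missingness> %d columns, missing %.2f%%-%.2f%%\n",
              nrow(x$summary), rng[1], rng[2]))
  print(head(x$summary, 8))
  invisible(x)
}

#' Write a missingness report to CSV
#'
#' @param report A [missingness_report()] result.
#' @param summary_path,cor_path Output paths for the per-column summary and
#'   the indicator correlation matrix.
#' @return `summary_path`, invisibly.
#' @export
write_missingness_csv <- function(report, summary_path, cor_path = NULL) {
  stopifnot(inherits(report, "clpn_missingness"))
  write.csv(report$summary, summary_path, row.names = FALSE)
  if (!is.null(cor_path)) write.csv(report$indicator_cor, cor_path)
  invisible(summary_path)
}

#' Listwise deletion on MCAR covariates
#'
#' Drops participants with missing values in the named covariate columns
#' (used for covariates whose missingness is deemed MCAR and rare, which
#' are excluded rather than imputed).
#'
#' @param data A [clpn_panel()] with covariates.
#' @param covariate_cols Character vector of covariate column names.
#' @return The filtered panel.
#' @export
drop_missing_covariates <- function(data, covariate_cols) {
  stopifnot(inherits(data, "clpn_panel"))
  if (is.null(data$covariates) || !length(covariate_cols)) return(data)
  covariate_cols <- intersect(covariate_cols, names(data$covariates))
  if (!length(covariate_cols)) return(data)
  keep <- complete.cases(data$covariates[covariate_cols])
  data$t1 <- data$t1[keep, , drop = FALSE]
  data$t2 <- data$t2[keep, , drop = FALSE]
  data$covariates <- data$covariates[keep, , drop = FALSE]
  data
}
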