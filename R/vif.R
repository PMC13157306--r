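#' Variance inflation factors
#'
#' Computes `VIF_j = 1 / (1 - R2_j)` where `R2_j` is the coefficient of
#' determination from regressing predictor j on all remaining predictors.
#' Values of 5 or more flag problematic multicollinearity; a perfectly
#' collinear predictor is reported with an infinite VIF rather than raising
#' an error.
#'
#' @param X Numeric matrix or data frame of complete predictors (at least
#'   two columns, no missing cells).
#' @param flag_threshold Threshold for the collinearity flag (default 5).
#' @return Data frame with `variable`, `vif`, `flagged`.
#' @export
vif_check <- function(X, flag_threshold = 5) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("VIF needs at least 2 predictors")
  if (anyNA(X)) stop("predictor matrix must be complete")
  vifs <- vapply(seq_len(ncol(X)), function(j) {
    y <- X[, j]
    Z <- cbind(1, X[, -j, drop = FALSE])
    fit <- lm.fit(Z, y)
    res <- fit$residuals
    tss <- sum((y - mean(y))^2)
    if (tss == 0) return(Inf)  # constant column: degenerate
    r2 <- 1 - sum(res^2) / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(variable = colnames(X) %||% paste0("V", seq_len(ncol(X))),
             vif = vifs, flagged = vifs >= flag_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}
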