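#' Multiple imputation by chained equations
#'
#' Fills missing item responses with m independent chained-equation chains.
#' Every item column of both waves (plus any complete covariates) enters
#' each conditional model. Per-variable conditional models are chosen by
#' item type: predictive-mean matching (PMM, 5 donors) for ordinal items by
#' default (proportional-odds available via `ordinal_method = "polr"`), and
#' logistic regression with Bernoulli draws for binary items (falling back
#' to PMM when the logistic fit is degenerate, e.g. near-separated rare
#' indicators). Columns are visited in order of increasing missingness at
#' every iteration. Imputed codes always lie in the item's admissible range
#' because PMM donors and logistic draws are observed-value based.
#'
#' @param data A [clpn_panel()] with missing cells.
#' @param m Number of imputed datasets (default 5).
#' @param iterations Chained-equation iterations per chain (default 10).
#' @param seed Integer seed; chains use independent derived substreams.
#' @param ordinal_method `"pmm"` (default) or `"polr"` (proportional odds,
#'   requires the MASS package).
#' @return An object of class `clpn_imputation_set`: list with `datasets`
#'   (m complete panels), `m`, `iterations`, `seed`.
#' @export
impute_chained <- function(data, m = 5, iterations = 10, seed = 1,
                           ordinal_method = c("pmm", "polr")) {
  stopifnot(inherits(data, "clpn_panel"), m >= 1, iterations >= 1)
  ordinal_method <- match.arg(ordinal_method)
  items <- data$items
  p <- nrow(items)
  Y <- cbind(data$t1, data$t2)
  colnames(Y) <- c(paste0(items$node_id, "_t1"), paste0(items$node_id, "_t2"))
  type <- rep(items$item_type, 2)
  n <- nrow(Y)

  nmis <- colSums(is.na(Y))
  if (any(nmis == n))
    stop("column(s) with zero observed values: ",
         paste(colnames(Y)[nmis == n], collapse = ", "))
  mis_cols <- which(nmis > 0)

  covmat <- NULL
  if (!is.null(data$covariates)) {
    num <- vapply(data$covariates, is.numeric, logical(1))
    cv <- data$covariates[num]
    cv <- cv[, colSums(is.na(cv)) == 0, drop = FALSE]
    if (ncol(cv)) covmat <- as.matrix(cv)
  }

  if (!length(mis_cols)) {
    return(structure(list(datasets = replicate(m, data, simplify = FALSE),
                          m = m, iterations = iterations, seed = seed),
                     class = "clpn_imputation_set"))
  }

  visit <- mis_cols[order(nmis[mis_cols])]
  mis_idx <- lapply(visit, function(j) which(is.na(Y[, j])))
  obs_idx <- lapply(visit, function(j) which(!is.na(Y[, j])))
  names(mis_idx) <- names(obs_idx) <- as.character(visit)

  run_chain <- function(chain) with_seed(
    seed_stream(seed, paste0("mice-chain-", chain)), {
    Z <- Y
    for (j in visit) {  # initialize by sampling observed values
      oi <- obs_idx[[as.character(j)]]
      mi <- mis_idx[[as.character(j)]]
      Z[mi, j] <- sample(Z[oi, j], length(mi), replace = TRUE)
    }
    for (it in seq_len(iterations)) {
      for (j in visit) {
        oi <- obs_idx[[as.character(j)]]
        mi <- mis_idx[[as.character(j)]]
        X <- cbind(1, Z[, -j, drop = FALSE], covmat)
        yv <- Z[, j]
        imp <- if (type[j] == "binary")
          impute_logistic(X, yv, oi, mi)
        else if (ordinal_method == "polr")
          impute_polr(Z[, -j, drop = FALSE], covmat, yv, oi, mi)
        else NULL
        if (is.null(imp)) imp <- impute_pmm(X, yv, oi, mi)
        Z[mi, j] <- imp
      }
    }
    out <- data
    storage.mode(Z) <- "integer"  # codes are integral by construction
    out$t1 <- Z[, seq_len(p), drop = FALSE]
    out$t2 <- Z[, p + seq_len(p), drop = FALSE]
    colnames(out$t1) <- colnames(out$t2) <- items$node_id
    out
  })

  datasets <- lapply(seq_len(m), run_chain)
  structure(list(datasets = datasets, m = m, iterations = iterations,
                 seed = seed), class = "clpn_imputation_set")
}

# Predictive-mean matching with 5 donors: OLS on observed rows, match each
# missing row's prediction to nearby observed predictions, copy the donor's
# observed value. Keeps imputations on the observed code scale.
impute_pmm <- function(X, y, oi, mi, donors = 5L) {
  fit <- lm.fit(X[oi, , drop = FALSE], y[oi])
  b <- fit$coefficients
  b[is.na(b)] <- 0
  pred_obs <- as.numeric(X[oi, , drop = FALSE] %*% b)
  pred_mis <- as.numeric(X[mi, , drop = FALSE] %*% b)
  ord <- order(pred_obs)
  s <- pred_obs[ord]
  yo <- y[oi][ord]
  no <- length(s)
  k <- min(donors, no)
  pos <- findInterval(pred_mis, s)
  vapply(seq_along(pred_mis), function(i) {
    lo <- max(1L, pos[i] - k)
    hi <- min(no, pos[i] + k)
    win <- lo:hi
    d <- abs(s[win] - pred_mis[i])
    cand <- win[order(d)[seq_len(min(k, length(win)))]]
    yo[cand[sample.int(length(cand), 1L)]]
  }, numeric(1))
}

# Logistic conditional model for a binary column; NULL signals fallback.
impute_logistic <- function(X, y, oi, mi) {
  if (sum(y[oi] == 1) < 10 || sum(y[oi] == 0) < 10) return(NULL)
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(X[oi, , drop = FALSE], y[oi],
                                    family = binomial())),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(NULL)
  b <- fit$coefficients
  b[is.na(b)] <- 0
  pr <- plogis(as.numeric(X[mi, , drop = FALSE] %*% b))
  rbinom(length(mi), 1L, pr)
}

# Proportional-odds conditional model for an ordinal column; NULL on failure.
impute_polr <- function(Z, covmat, y, oi, mi) {
  if (!requireNamespace("MASS", quietly = TRUE)) return(NULL)
  df <- as.data.frame(cbind(Z, covmat))
  df$.y <- factor(y, levels = sort(unique(y[oi])), ordered = TRUE)
  if (nlevels(df$.y) < 3) return(NULL)
  fit <- tryCatch(
    suppressWarnings(MASS::polr(.y ~ ., data = df[oi, , drop = FALSE])),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  pr <- predict(fit, newdata = df[mi, , drop = FALSE], type = "probs")
  pr <- matrix(pr, nrow = length(mi))
  lev <- as.numeric(levels(df$.y))
  vapply(seq_len(nrow(pr)), function(i)
    lev[sample.int(length(lev), 1L, prob = pr[i, ])], numeric(1))
}

#' @export
print.clpn_imputation_set <- function(x, ...) {
  cat(sprintf("<clpn_imputation_set> m = %d datasets, %d iterations\n",
              x$m, x$iterations))
  invisible(x)
}

#' Write an imputation set to a directory
#'
#' One wide CSV per completed dataset plus a `manifest.json` recording m,
#' iterations and seed.
#'
#' @param imps A [impute_chained()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_imputation_set <- function(imps, dir) {
  stopifnot(inherits(imps, "clpn_imputation_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(imps$m)
  for (i in seq_len(imps$m)) {
    paths[i] <- file.path(dir, sprintf("imputation_%02d.csv", i))
    write_panel_csv(imps$datasets[[i]], paths[i])
  }
  jsonlite::write_json(list(m = imps$m, iterations = imps$iterations,
                            seed = imps$seed, files = basename(paths)),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
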