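#' Standardize the item matrices of a complete panel
#'
#' Centers each item-wave column to mean 0 and scales it to sample standard
#' deviation 1 (divisor n - 1), so the L1 penalty is comparable across
#' predictors and the resulting coefficients are standardized betas.
#'
#' @param data A complete [clpn_panel()].
#' @return List with `t1`, `t2` (n x p standardized matrices) and `scaling`
#'   (data frame of the centers and SDs used, for reporting).
#' @export
standardize <- function(data) {
  stopifnot(inherits(data, "clpn_panel"))
  if (!panel_complete(data)) stop("panel has missing cells; impute first")
  M <- cbind(data$t1, data$t2)
  colnames(M) <- c(paste0(colnames(data$t1), "_t1"),
                   paste0(colnames(data$t2), "_t2"))
  ctr <- colMeans(M)
  sds <- apply(M, 2, sd)
  zv <- which(sds == 0)
  if (length(zv))
    stop("zero-variance column(s): ", paste(names(zv), collapse = ", "))
  S <- sweep(sweep(M, 2, ctr), 2, sds, "/")
  p <- ncol(data$t1)
  list(t1 = S[, seq_len(p), drop = FALSE],
       t2 = S[, p + seq_len(p), drop = FALSE],
       scaling = data.frame(column = colnames(M), center = ctr, sd = sds,
                            row.names = NULL))
}

# Standard lambda grid: 100 log-spaced values from the smallest lambda
# nulling all coefficients down to 0.001 of it.
default_lambda_grid <- function(X, y, alpha, nlambda = 100,
                                lambda_min_ratio = 0.001) {
  n <- nrow(X)
  lmax <- max(abs(crossprod(X, y))) / (n * max(alpha, 1e-3))
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
}

#' Fit one penalized node-wise regression with cross-validated lambda
#'
#' Minimizes `(1/2n) ||y - X b||^2 + lambda [alpha ||b||_1 +
#' (1-alpha)/2 ||b||_2^2]` by coordinate descent over a decreasing lambda
#' path with warm starts, choosing lambda as the grid value minimizing the
#' k-fold cross-validated mean squared prediction error and refitting on the
#' full sample at that value. Inputs are expected standardized, so no
#' intercept is estimated.
#'
#' @param X n x p standardized predictor matrix (wave-1 items).
#' @param y Standardized outcome column (one wave-2 item).
#' @param alpha Elastic-net mixing parameter in `[0, 1]`; 1 = LASSO
#'   (default).
#' @param k Number of CV folds (default 10); plain random folds.
#' @param lambda_grid Optional decreasing penalty grid; default 100
#'   log-spaced values from `lambda_max` down to `0.001 lambda_max`. A
#'   single value (including 0) skips grid selection.
#' @param seed Integer seed controlling the fold assignment.
#' @param tol,maxit Coordinate-descent convergence controls.
#' @return List with `coefficients` (length p, named), `lambda` (chosen),
#'   `cv_mse` (curve over the grid), `lambda_grid`.
#' @export
fit_outcome <- function(X, y, alpha = 1, k = 10, lambda_grid = NULL,
                        seed = 1, tol = 1e-9, maxit = 100000L) {
  X <- as.matrix(X)
  n <- nrow(X)
  assert_scalar_num(alpha, "alpha", 0, 1)
  if (k < 2 || k > n) stop("need n > k >= 2 folds (n = ", n, ", k = ", k, ")")
  if (!is.null(lambda_grid)) {
    if (!length(lambda_grid)) stop("empty lambda grid")
    if (any(lambda_grid < 0)) stop("lambda values must be nonnegative")
    lambda_grid <- sort(unique(as.numeric(lambda_grid)), decreasing = TRUE)
  } else {
    lambda_grid <- default_lambda_grid(X, y, alpha)
  }

  if (length(lambda_grid) == 1L) {
    # no selection needed; warm-start through an internal path for stability
    path <- unique(c(default_lambda_grid(X, y, alpha, nlambda = 20),
                     lambda_grid[1]))
    path <- sort(path[path >= lambda_grid[1]], decreasing = TRUE)
    path <- c(path, lambda_grid[1])[!duplicated(c(path, lambda_grid[1]))]
    bp <- cpp_enet_path(X, y, path, alpha, tol, maxit)
    co <- bp[, length(path)]
    names(co) <- colnames(X)
    return(list(coefficients = co, lambda = lambda_grid[1],
                cv_mse = NULL, lambda_grid = lambda_grid))
  }

  foldid <- with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  fit <- cpp_enet_cv(X, y, foldid, lambda_grid, alpha, tol, maxit)
  co <- fit$beta_path[, fit$best]
  names(co) <- colnames(X)
  list(coefficients = co, lambda = lambda_grid[fit$best],
       cv_mse = as.numeric(fit$cvm), lambda_grid = lambda_grid)
}

#' Estimate a cross-lagged panel network
#'
#' Runs one penalized regression per wave-2 item on all standardized wave-1
#' items and assembles the p x p directed coefficient matrix `B`, with
#' `B[i, j]` the standardized effect of item i at wave 1 on item j at wave
#' 2; the diagonal holds autoregressive effects. Fold splits are drawn
#' independently per outcome from the master seed.
#'
#' @param data A complete [clpn_panel()]. Raw-scale panels are
#'   reverse-scored first when `use_reverse` is `TRUE` (default), so all
#'   depressive nodes point in the depression direction.
#' @param alpha Elastic-net mixing (default 1, the LASSO).
#' @param k CV folds (default 10).
#' @param seed Master integer seed.
#' @param lambda_grid Optional shared penalty grid (default per-outcome
#'   data-driven grid).
#' @param use_reverse Reverse-score raw panels before estimation?
#' @return An object of class `clpn_network`: list with `B`, `lambda`
#'   (per-outcome chosen values), `alpha`, `k`, `seed`, `items`.
#' @export
estimate_clpn <- function(data, alpha = 1, k = 10, seed = 1,
                          lambda_grid = NULL, use_reverse = TRUE) {
  stopifnot(inherits(data, "clpn_panel"))
  if (data$scale == "raw" && use_reverse) data <- reverse_score_panel(data)
  S <- standardize(data)
  p <- ncol(S$t1)
  ids <- data$items$node_id
  B <- matrix(0, p, p, dimnames = list(ids, ids))
  lam <- numeric(p)
  for (j in seq_len(p)) {
    f <- fit_outcome(S$t1, S$t2[, j], alpha = alpha, k = k,
                     lambda_grid = lambda_grid,
                     seed = seed_stream(seed, paste0("cv-outcome-", j)))
    B[, j] <- f$coefficients
    lam[j] <- f$lambda
  }
  structure(list(B = B, lambda = stats::setNames(lam, colnames(B)),
                 alpha = alpha, k = k, seed = seed, items = data$items),
            class = "clpn_network")
}

#' @export
print.clpn_network <- function(x, ...) {
  off <- x$B[row(x$B) != col(x$B)]
  cat(sprintf("<clpn_network> %d nodes; %d nonzero cross-lagged edges; ",
              ncol(x$B), sum(off != 0)))
  cat(sprintf("max |cross| = %.3f\n", max(abs(off))))
  invisible(x)
}

#' Pool networks across imputed datasets
#'
#' Element-wise arithmetic mean of the coefficient matrices (the
#' point-estimation step of Rubin's rules); per-imputation chosen lambdas
#' are kept in the metadata.
#'
#' @param networks List of [estimate_clpn()] results with identical node
#'   order.
#' @return A pooled `clpn_network` with attribute `m` and `lambda_per_imp`.
#' @export
pool_networks <- function(networks) {
  stopifnot(length(networks) >= 1)
  ref <- networks[[1]]
  for (nw in networks) {
    stopifnot(inherits(nw, "clpn_network"))
    if (!identical(dimnames(nw$B), dimnames(ref$B)))
      stop("networks differ in dimensions or node order")
  }
  B <- Reduce(`+`, lapply(networks, `[[`, "B")) / length(networks)
  out <- ref
  out$B <- B
  out$m <- length(networks)
  out$lambda_per_imp <- lapply(networks, `[[`, "lambda")
  out$lambda <- Reduce(`+`, out$lambda_per_imp) / length(networks)
  out
}

#' Apply the display filter to a network
#'
#' Marks edges retained for visualization: `|beta| >= threshold`, by default
#' excluding the autoregressive diagonal. The filter is a display device
#' only; centralities and stability use the unfiltered network.
#'
#' @param network A `clpn_network`.
#' @param threshold Minimum absolute edge weight (default 0.05).
#' @param drop_autoregressive Exclude diagonal edges? (default `TRUE`)
#' @return A `clpn_display` object: the network plus a logical `retained`
#'   mask of the same dimensions.
#' @export
filter_display <- function(network, threshold = 0.05,
                           drop_autoregressive = TRUE) {
  stopifnot(inherits(network, "clpn_network"))
  if (threshold < 0) stop("threshold must be nonnegative")
  keep <- abs(network$B) >= threshold
  if (drop_autoregressive) keep[row(keep) == col(keep)] <- FALSE
  structure(list(network = network, retained = keep,
                 threshold = threshold,
                 drop_autoregressive = drop_autoregressive),
            class = "clpn_display")
}

#' @export
print.clpn_display <- function(x, ...) {
  cat(sprintf("<clpn_display> %d retained edges (|beta| >= %g%s)\n",
              sum(x$retained), x$threshold,
              if (x$drop_autoregressive) ", autoregressive dropped" else ""))
  invisible(x)
}

#' Write a network adjacency matrix to CSV
#'
#' Full-precision labeled adjacency; rows are wave-1 predictors, columns
#' wave-2 outcomes.
#'
#' @param network A `clpn_network` or `clpn_display` (the latter writes the
#'   masked matrix, non-retained edges as 0).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_network_csv <- function(network, path) {
  B <- if (inherits(network, "clpn_display"))
    network$network$B * network$retained else network$B
  write.csv(format(as.data.frame(B), digits = 17, scientific = FALSE,
                   trim = TRUE), path)
  invisible(path)
}

#' Export a network as GraphML
#'
#' Directed graph with `weight`, `sign` and `retained` edge attributes;
#' nodes carry their community and long item name.
#'
#' @param network A `clpn_network`.
#' @param path Output `.graphml` path.
#' @param threshold,drop_autoregressive Display-filter settings used for the
#'   `retained` attribute.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path, threshold = 0.05,
                                  drop_autoregressive = TRUE) {
  stopifnot(inherits(network, "clpn_network"))
  disp <- filter_display(network, threshold, drop_autoregressive)
  B <- network$B
  idx <- which(B != 0, arr.ind = TRUE)
  edges <- data.frame(from = rownames(B)[idx[, 1]],
                      to = colnames(B)[idx[, 2]],
                      weight = B[idx],
                      sign = ifelse(B[idx] > 0, "positive", "negative"),
                      retained = disp$retained[idx])
  verts <- data.frame(name = network$items$node_id,
                      label = network$items$name,
                      community = network$items$community)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = verts)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
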