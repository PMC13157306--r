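# Bootstrap robustness machinery: case-dropping stability (CS-coefficients),
# nonparametric edge-weight CIs, and bootstrapped difference tests. All of
# it is estimator-agnostic: estimation enters only through a callable
# `data -> clpn_network`, so tests can inject stubs.

#' Build a network estimator callable
#'
#' Packages [estimate_clpn()] settings into a single-argument function
#' (panel -> network), the contract all bootstrap routines use.
#'
#' @param alpha,k,seed,lambda_grid Passed to [estimate_clpn()].
#' @return A function of one `clpn_panel` argument.
#' @export
clpn_estimator <- function(alpha = 1, k = 10, seed = 1, lambda_grid = NULL) {
  function(data) estimate_clpn(data, alpha = alpha, k = k, seed = seed,
                               lambda_grid = lambda_grid)
}

panel_subset <- function(panel, idx) {
  panel$t1 <- panel$t1[idx, , drop = FALSE]
  panel$t2 <- panel$t2[idx, , drop = FALSE]
  if (!is.null(panel$covariates))
    panel$covariates <- panel$covariates[idx, , drop = FALSE]
  panel
}

centrality_vec <- function(network, index, partition) {
  switch(index,
         out_ei = rowSums(network$B) - diag(network$B),
         in_ei = colSums(network$B) - diag(network$B),
         bridge_ei = {
           ids <- rownames(network$B)
           vapply(ids, function(v) bridge_ei(network, v, partition),
                  numeric(1))
         },
         stop("unknown centrality index: ", index))
}

# Correlation between a subsample and the full-sample centrality vector.
# Convention for degenerate (constant) vectors: both constant -> 1 (a
# constant estimator is perfectly stable), exactly one constant -> 0.
stability_cor <- function(sub, full) {
  s1 <- sd(sub); s2 <- sd(full)
  if (s1 == 0 && s2 == 0) return(1)
  if (s1 == 0 || s2 == 0) return(0)
  cor(sub, full)
}

#' Case-dropping bootstrap for centrality stability
#'
#' Draws subsamples without replacement at each drop proportion of the
#' grid, re-estimates the network, and correlates each subsample's
#' centralities with the full-sample centralities. The `B` replicates are
#' allocated evenly across the grid, so the total number of network
#' re-estimations is about `B` regardless of grid size.
#'
#' @param data A complete [clpn_panel()].
#' @param estimator Callable `panel -> clpn_network` (default
#'   [clpn_estimator()]).
#' @param drop_grid Proportions of cases to drop (default 0.05 to 0.75 in
#'   steps of 0.05); all must lie in (0, 0.9).
#' @param B Total number of bootstrap replicates (default 1000; >= 50).
#' @param seed Integer seed.
#' @param partition Community map for Bridge-EI.
#' @param indices Centrality indices to track.
#' @return List of class `clpn_case_drop` with `correlations` (per index, a
#'   list over drop proportions of correlation vectors), `drop_grid`, `B`,
#'   `full` (full-sample centralities).
#' @export
case_dropping_bootstrap <- function(data, estimator = clpn_estimator(),
                                    drop_grid = seq(0.05, 0.75, by = 0.05),
                                    B = 1000, seed = 1,
                                    partition = clpn_partition(),
                                    indices = c("out_ei", "in_ei",
                                                "bridge_ei")) {
  stopifnot(inherits(data, "clpn_panel"), B >= 50)
  if (any(drop_grid <= 0 | drop_grid >= 0.9))
    stop("drop proportions must lie in (0, 0.9)")
  drop_grid <- sort(drop_grid)
  n <- n_participants(data)
  full_net <- estimator(data)
  full <- lapply(stats::setNames(indices, indices),
                 function(ix) centrality_vec(full_net, ix, partition))

  per_d <- max(1L, ceiling(B / length(drop_grid)))
  corrs <- lapply(full, function(.)
    stats::setNames(vector("list", length(drop_grid)),
                    as.character(drop_grid)))
  # all subsamples (including redraw attempts for degenerate subsamples)
  # are drawn up front so an estimator's internal RNG use cannot perturb
  # the resampling stream
  draw_sets <- with_seed(seed_stream(seed, "case-drop"),
    lapply(drop_grid, function(d) {
      m <- ceiling(n * (1 - d))
      if (m < 30) return(NULL)
      lapply(seq_len(per_d), function(b)
        replicate(5, sample.int(n, m), simplify = FALSE))
    }))
  for (di in seq_along(drop_grid)) {
    d <- drop_grid[di]
    if (is.null(draw_sets[[di]])) {
      warning("drop proportion ", d, " leaves fewer than 30 cases; skipped")
      for (ix in indices) corrs[[ix]][[di]] <- numeric(0)
      next
    }
    cc <- matrix(NA_real_, per_d, length(indices),
                 dimnames = list(NULL, indices))
    for (b in seq_len(per_d)) {
      # degenerate subsamples (e.g. a rare item with no endorsements left)
      # are redrawn a few times; a persistently failing replicate stays NA
      # and counts against stability
      net_b <- NULL
      for (idx in draw_sets[[di]][[b]]) {
        net_b <- tryCatch(estimator(panel_subset(data, idx)),
                          error = function(e) NULL)
        if (!is.null(net_b)) break
      }
      if (is.null(net_b)) next
      for (ix in indices)
        cc[b, ix] <- stability_cor(centrality_vec(net_b, ix, partition),
                                   full[[ix]])
    }
    for (ix in indices) corrs[[ix]][[di]] <- cc[, ix]
  }
  structure(list(correlations = corrs, drop_grid = drop_grid,
                 B = per_d * length(drop_grid), per_drop = per_d,
                 full = full, seed = seed),
            class = "clpn_case_drop")
}

# CS from per-drop correlation vectors: largest d such that at every grid
# value <= d at least `prob` of the correlations reach `corr_threshold`.
cs_from_correlations <- function(corr_list, drop_grid, corr_threshold = 0.7,
                                 prob = 0.95) {
  cs <- 0
  for (di in seq_along(drop_grid)) {
    v <- corr_list[[di]]
    if (!length(v) || mean(!is.na(v) & v >= corr_threshold) < prob) break
    cs <- drop_grid[di]
  }
  cs
}

#' Correlation stability coefficient of a centrality index
#'
#' The CS-coefficient is the largest proportion of cases that can be
#' dropped such that, with probability `prob`, the subsample centralities
#' still correlate at least `corr_threshold` with the full-sample
#' centralities. Values of 0.25 are considered minimally acceptable and
#' 0.5 preferred.
#'
#' @inheritParams case_dropping_bootstrap
#' @param index `"out_ei"`, `"in_ei"` or `"bridge_ei"`.
#' @param corr_threshold Correlation bar (default 0.7).
#' @param prob Required probability of clearing the bar (default 0.95).
#' @param boot Optional precomputed [case_dropping_bootstrap()] result to
#'   reuse across indices.
#' @return List with `cs` (the coefficient), `index`, `correlations` (per
#'   drop proportion) and `drop_grid`.
#' @export
cs_coefficient <- function(data, estimator = clpn_estimator(),
                           index = c("out_ei", "in_ei", "bridge_ei"),
                           drop_grid = seq(0.05, 0.75, by = 0.05),
                           B = 1000, corr_threshold = 0.7, prob = 0.95,
                           seed = 1, partition = clpn_partition(),
                           boot = NULL) {
  index <- match.arg(index)
  if (is.null(boot))
    boot <- case_dropping_bootstrap(data, estimator, drop_grid, B, seed,
                                    partition, indices = index)
  cl <- boot$correlations[[index]]
  list(cs = cs_from_correlations(cl, boot$drop_grid, corr_threshold, prob),
       index = index, correlations = cl, drop_grid = boot$drop_grid,
       B = boot$B)
}

#' Nonparametric bootstrap of edge weights and centralities
#'
#' Resamples participants with replacement `B` times, re-estimates the
#' network for each resample, and returns percentile confidence intervals
#' for every edge plus the raw edge and centrality draws (used by
#' [difference_tests()]).
#'
#' @inheritParams case_dropping_bootstrap
#' @param level Interval level (default 0.95).
#' @return Object of class `clpn_boot`: `edge_ci` (data frame: `edge`,
#'   `from`, `to`, `observed`, `boot_mean`, `lower`, `upper`, `width`),
#'   `edge_draws` (B x p^2), `centrality_draws` (per index, B x p),
#'   `observed` network, `level`, `seed`.
#' @export
edge_ci_bootstrap <- function(data, estimator = clpn_estimator(), B = 1000,
                              level = 0.95, seed = 1,
                              partition = clpn_partition(),
                              indices = c("out_ei", "in_ei", "bridge_ei")) {
  stopifnot(inherits(data, "clpn_panel"), B >= 2)
  n <- n_participants(data)
  obs_net <- estimator(data)
  p <- ncol(obs_net$B)
  ids <- rownames(obs_net$B)
  edge_names <- as.vector(outer(ids, ids, function(a, b) paste0(a, "->", b)))

  edge_draws <- matrix(NA_real_, B, p * p, dimnames = list(NULL, edge_names))
  cent_draws <- lapply(stats::setNames(indices, indices), function(.)
    matrix(NA_real_, B, p, dimnames = list(NULL, ids)))
  idx_draws <- with_seed(seed_stream(seed, "edge-boot"),
    lapply(seq_len(B), function(b) sample.int(n, n, replace = TRUE)))
  for (b in seq_len(B)) {
    net_b <- estimator(panel_subset(data, idx_draws[[b]]))
    edge_draws[b, ] <- as.vector(net_b$B)
    for (ix in indices)
      cent_draws[[ix]][b, ] <- centrality_vec(net_b, ix, partition)
  }

  a <- (1 - level) / 2
  qs <- apply(edge_draws, 2, quantile, probs = c(a, 1 - a), names = FALSE)
  from <- rep(ids, times = p); to <- rep(ids, each = p)
  edge_ci <- data.frame(edge = edge_names, from = from, to = to,
                        observed = as.vector(obs_net$B),
                        boot_mean = colMeans(edge_draws),
                        lower = qs[1, ], upper = qs[2, ],
                        width = qs[2, ] - qs[1, ],
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(list(edge_ci = edge_ci, edge_draws = edge_draws,
                 centrality_draws = cent_draws, observed = obs_net,
                 level = level, B = B, seed = seed),
            class = "clpn_boot")
}

#' @export
print.clpn_boot <- function(x, ...) {
  cat(sprintf("<clpn_boot> B = %d resamples, %d edges, %g%% intervals\n",
              x$B, nrow(x$edge_ci), 100 * x$level))
  invisible(x)
}

#' Bootstrapped pairwise difference tests
#'
#' For every pair of edges (or of node centralities on one index), the
#' bootstrap distribution of their difference is formed from the stored
#' draws; a pair differs significantly when the percentile interval of the
#' difference excludes zero. The returned mask is symmetric with a `FALSE`
#' diagonal.
#'
#' @param boot A [edge_ci_bootstrap()] result.
#' @param what `"edges"` or `"centrality"`.
#' @param index Centrality index when `what = "centrality"`.
#' @param level Interval level (default 0.95).
#' @return Symmetric logical matrix of significant differences.
#' @export
difference_tests <- function(boot, what = c("edges", "centrality"),
                             index = c("out_ei", "in_ei", "bridge_ei"),
                             level = 0.95) {
  stopifnot(inherits(boot, "clpn_boot"))
  what <- match.arg(what)
  index <- match.arg(index)
  draws <- if (what == "edges") boot$edge_draws else
    boot$centrality_draws[[index]]
  if (is.null(draws) || nrow(draws) < 200)
    stop("difference tests need at least 200 bootstrap draws")
  K <- ncol(draws)
  a <- (1 - level) / 2
  sig <- matrix(FALSE, K, K, dimnames = list(colnames(draws),
                                             colnames(draws)))
  sorted <- apply(draws, 2, sort)
  for (i in seq_len(K - 1)) {
    di <- draws[, i]
    for (j in (i + 1):K) {
      q <- quantile(di - draws[, j], probs = c(a, 1 - a), names = FALSE)
      s <- q[1] > 0 || q[2] < 0
      sig[i, j] <- s; sig[j, i] <- s
    }
  }
  sig
}

#' Assemble a stability report
#'
#' Convenience wrapper running the case-dropping bootstrap (for all three
#' centrality indices) and the edge-weight bootstrap, and collecting
#' CS-coefficients, edge CIs and difference-test masks in one object.
#'
#' @inheritParams case_dropping_bootstrap
#' @param B_case,B_edge Replicates for the two bootstraps.
#' @param level CI level.
#' @param diff_tests Also compute pairwise difference masks?
#' @return Object of class `clpn_stability` with `cs` (named list),
#'   `case_drop`, `boot`, and optionally `edge_diff` / `centrality_diff`.
#' @export
stability_report <- function(data, estimator = clpn_estimator(),
                             drop_grid = seq(0.05, 0.75, by = 0.05),
                             B_case = 1000, B_edge = 1000, level = 0.95,
                             seed = 1, partition = clpn_partition(),
                             diff_tests = TRUE) {
  cd <- case_dropping_bootstrap(data, estimator, drop_grid, B_case, seed,
                                partition)
  cs <- lapply(stats::setNames(names(cd$correlations),
                               names(cd$correlations)), function(ix)
    cs_from_correlations(cd$correlations[[ix]], cd$drop_grid))
  bt <- edge_ci_bootstrap(data, estimator, B_edge, level,
                          seed_stream(seed, "edge-stage"), partition)
  out <- list(cs = cs, case_drop = cd, boot = bt, seed = seed)
  if (diff_tests && bt$B >= 200) {
    out$edge_diff <- difference_tests(bt, "edges", level = level)
    out$centrality_diff <- lapply(
      stats::setNames(names(bt$centrality_draws),
                      names(bt$centrality_draws)),
      function(ix) difference_tests(bt, "centrality", ix, level))
  }
  structure(out, class = "clpn_stability")
}

#' @export
print.clpn_stability <- function(x, ...) {
  cat("<clpn_stability> CS-coefficients:\n")
  for (ix in names(x$cs)) cat(sprintf("  %s: %.3f\n", ix, x$cs[[ix]]))
  invisible(x)
}

#' Write stability outputs to CSV
#'
#' Emits a CS summary, the per-edge CI table, and (when present) the
#' difference-test masks.
#'
#' @param report A [stability_report()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_stability_csv <- function(report, dir) {
  stopifnot(inherits(report, "clpn_stability"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cs_df <- data.frame(index = names(report$cs),
                      cs = unlist(report$cs), row.names = NULL)
  write.csv(cs_df, file.path(dir, "cs_coefficients.csv"), row.names = FALSE)
  write.csv(report$boot$edge_ci, file.path(dir, "edge_ci.csv"),
            row.names = FALSE)
  if (!is.null(report$edge_diff))
    write.csv(report$edge_diff, file.path(dir, "edge_difference_tests.csv"))
  if (!is.null(report$centrality_diff))
    for (ix in names(report$centrality_diff))
      write.csv(report$centrality_diff[[ix]],
                file.path(dir, paste0("centrality_difference_", ix, ".csv")))
  invisible(dir)
}
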