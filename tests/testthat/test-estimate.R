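std_fixture <- function(n = 2000, seed = 51) {
  m <- recovery_model(seed)
  pan <- simulate_panel(m, n, seed = seed)
  list(model = m, panel = pan, std = standardize(pan))
}

test_that("standardization centers and scales every item-wave column", {
  fx <- std_fixture(n = 500)
  M <- cbind(fx$std$t1, fx$std$t2)
  expect_true(all(abs(colMeans(M)) < 1e-12))
  expect_true(all(abs(apply(M, 2, sd) - 1) < 1e-12))
  expect_equal(nrow(fx$std$scaling), 30)

  # a balanced binary column standardizes to +/- sqrt((n-1)/n)
  x <- rep(c(0L, 1L), 50)
  z <- (x - mean(x)) / sd(x)
  expect_equal(sort(unique(z)), c(-1, 1) * sqrt(99 / 100), tolerance = 1e-10)

  broken <- fx$panel
  broken$t1[, "In5"] <- 0L
  expect_error(standardize(broken), "In5_t1")
  incomplete <- fx$panel
  incomplete$t1[1, 1] <- NA
  expect_error(standardize(incomplete), "missing")
})

test_that("the penalty nulls all coefficients at and above lambda_max", {
  fx <- std_fixture()
  X <- fx$std$t1; y <- fx$std$t2[, 1]
  lmax <- max(abs(crossprod(X, y))) / nrow(X)
  f <- fit_outcome(X, y, alpha = 1, lambda_grid = lmax * 1.0001)
  expect_true(all(f$coefficients == 0))
  f2 <- fit_outcome(X, y, alpha = 1, lambda_grid = lmax * 0.5)
  expect_gt(sum(f2$coefficients != 0), 0)
})

test_that("lambda = 0 reproduces the least-squares solution", {
  fx <- std_fixture(n = 2000)
  X <- fx$std$t1
  for (j in c(1, 8, 15)) {
    y <- fx$std$t2[, j]
    f <- fit_outcome(X, y, alpha = 1, lambda_grid = 0)
    ols <- solve(crossprod(X), crossprod(X, y))
    expect_lt(max(abs(f$coefficients - ols)), 1e-4)
  }
})

test_that("orthonormal designs soft-threshold the univariate coefficients", {
  set.seed(52)
  n <- 600; p <- 12
  Q <- qr.Q(qr(matrix(rnorm(n * p), n, p))) * sqrt(n)  # crossprod(Q)/n = I
  y <- rnorm(n)
  bu <- crossprod(Q, y) / n
  for (lam in c(0.01, 0.05, 0.1)) {
    f <- fit_outcome(Q, y, alpha = 1, lambda_grid = lam)
    st <- sign(bu) * pmax(abs(bu) - lam, 0)
    expect_lt(max(abs(f$coefficients - st)), 1e-6)
  }
})

test_that("coordinate descent agrees with glmnet along a shared path", {
  skip_if_not_installed("glmnet")
  fx <- std_fixture(n = 1500)
  X <- fx$std$t1; y <- fx$std$t2[, 4]
  grid <- exp(seq(log(0.2), log(0.002), length.out = 40))
  for (alpha in c(1, 0.5)) {
    g <- glmnet::glmnet(X, y, alpha = alpha, lambda = grid,
                        standardize = FALSE, intercept = FALSE,
                        thresh = 1e-12)
    ours <- clpnet:::cpp_enet_path(X, y, grid, alpha, 1e-10, 100000L)
    expect_lt(max(abs(ours - as.matrix(g$beta))), 1e-5)
  }
})

test_that("fit_outcome validates folds and grids", {
  set.seed(50)
  X <- matrix(rnorm(100 * 15), 100, 15)
  y <- rnorm(100)
  expect_error(fit_outcome(X, y, k = 101), "folds")
  expect_error(fit_outcome(X, y, lambda_grid = numeric(0)), "empty")
  expect_error(fit_outcome(X, y, lambda_grid = -0.1), "nonnegative")
  expect_error(fit_outcome(X, y, alpha = 2), "alpha")
})

test_that("nonzero count grows monotonically down the LASSO path", {
  fx <- std_fixture()
  X <- fx$std$t1
  for (j in c(2, 9)) {
    y <- fx$std$t2[, j]
    grid <- clpnet:::default_lambda_grid(X, y, 1)
    path <- clpnet:::cpp_enet_path(X, y, grid, 1, 1e-9, 100000L)
    nz <- colSums(path != 0)
    expect_true(all(diff(nz) >= 0))
  }
})

test_that("cross-validation never beats the null model's unit MSE by
          selection alone", {
  fx <- std_fixture(n = 1500)
  X <- fx$std$t1
  for (j in seq_len(15)) {
    f <- fit_outcome(X, fx$std$t2[, j], seed = 60 + j)
    expect_lte(min(f$cv_mse), 1.02)
  }
})

test_that("estimate_clpn is deterministic and recovers a planted edge", {
  m <- make_ground_truth(n_nonzero_cross = 0, seed = 53)
  m$true_B["De2", "De7"] <- 0.3
  m$noise_sd <- sqrt(1 - diag(t(m$true_B) %*% m$Sigma1 %*% m$true_B))
  pan <- simulate_panel(m, 10000, seed = 53)
  net1 <- estimate_clpn(pan, seed = 54)
  net2 <- estimate_clpn(pan, seed = 54)
  expect_identical(net1$B, net2$B)
  expect_gt(net1$B["De2", "De7"], 0)
  off <- net1$B; diag(off) <- 0
  ord <- order(abs(off), decreasing = TRUE)
  expect_true(which(rownames(off) == "De2") ==
                arrayInd(ord[1], dim(off))[1] ||
              abs(off["De2", "De7"]) >= sort(abs(off[off != 0]),
                                             decreasing = TRUE)[3])
})

test_that("the display filter retains exactly the edges above threshold", {
  B <- matrix(0, 15, 15)
  B[1, 2] <- -0.19; B[2, 3] <- 0.04; diag(B) <- 0.3
  nw <- as_network(B)
  d <- filter_display(nw)
  expect_true(d$retained[1, 2])        # strong negative edge kept
  expect_false(d$retained[2, 3])       # below 0.05
  expect_false(any(diag(d$retained)))  # autoregressive dropped

  d0 <- filter_display(nw, threshold = 0, drop_autoregressive = FALSE)
  expect_true(all(d0$retained))
  expect_error(filter_display(nw, threshold = -0.1), "nonnegative")
})

test_that("network CSV and GraphML exports round-trip edge structure", {
  fx <- std_fixture(n = 600)
  net <- estimate_clpn(fx$panel, seed = 55)
  f <- tempfile(fileext = ".csv")
  write_network_csv(net, f)
  back <- as.matrix(read.csv(f, row.names = 1))
  expect_equal(unname(back), unname(net$B), tolerance = 1e-12)

  g <- tempfile(fileext = ".graphml")
  write_network_graphml(net, g)
  gr <- igraph::read_graph(g, format = "graphml")
  expect_equal(igraph::gsize(gr), sum(net$B != 0))
  expect_equal(sort(igraph::V(gr)$name), sort(rownames(net$B)))
})
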