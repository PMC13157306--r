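make_missing_fixture <- function(n = 5000, seed = 21) {
  m <- make_ground_truth(seed = seed)
  complete <- simulate_panel(m, n, seed = seed)
  list(model = m, complete = complete,
       missing = inject_missingness(complete, m, seed = seed))
}

test_that("missingness report summarizes complete and degenerate data", {
  fx <- make_missing_fixture(n = 300)
  rep0 <- missingness_report(fx$complete)
  expect_true(all(rep0$summary$pct_missing == 0))
  expect_true(all(rep0$summary$hint == "not-applicable"))

  onecol <- fx$complete
  onecol$t1[, "De2"] <- NA
  rep1 <- missingness_report(onecol)
  expect_equal(rep1$summary$pct_missing[rep1$summary$column == "De2_t1"], 100)
})

test_that("MAR fixture shows stronger indicator correlation among
          depressive items than internet items", {
  fx <- make_missing_fixture()
  rep <- missingness_report(fx$missing)
  C <- rep$indicator_cor
  dep <- paste0("De", 1:10, "_t1")
  int <- paste0("In", 1:5, "_t1")
  dd <- C[dep, dep][upper.tri(diag(10))]
  ii <- C[int, int][upper.tri(diag(5))]
  expect_gt(mean(dd, na.rm = TRUE), mean(ii, na.rm = TRUE))
  # report is symmetric with unit diagonal where defined
  expect_equal(C, t(C))
  expect_true(all(diag(C) == 1, na.rm = TRUE))
})

test_that("imputation preserves observed cells and is seed-deterministic", {
  fx <- make_missing_fixture(n = 1200)
  imps <- impute_chained(fx$missing, m = 2, iterations = 2, seed = 31)
  expect_length(imps$datasets, 2)
  for (d in imps$datasets) {
    expect_false(anyNA(d$t1) || anyNA(d$t2))
    obs <- !is.na(fx$missing$t1)
    expect_identical(d$t1[obs], fx$missing$t1[obs])
    obs2 <- !is.na(fx$missing$t2)
    expect_identical(d$t2[obs2], fx$missing$t2[obs2])
    # imputed codes stay in range (constructor enforces on rebuild)
    expect_true(all(d$t1[, 1:10] %in% 0:3) && all(d$t1[, 11:15] %in% 0:1))
  }
  again <- impute_chained(fx$missing, m = 2, iterations = 2, seed = 31)
  expect_identical(imps$datasets[[1]]$t1, again$datasets[[1]]$t1)
  expect_false(identical(imps$datasets[[1]]$t1, imps$datasets[[2]]$t1))
})

test_that("imputing complete data returns m identical copies", {
  fx <- make_missing_fixture(n = 200)
  imps <- impute_chained(fx$complete, m = 3, iterations = 2, seed = 1)
  expect_identical(imps$datasets[[1]]$t1, fx$complete$t1)
  expect_identical(imps$datasets[[3]]$t2, fx$complete$t2)
})

test_that("a column with no observed values aborts with its name", {
  fx <- make_missing_fixture(n = 100)
  broken <- fx$complete
  broken$t2[, "In2"] <- NA
  expect_error(impute_chained(broken, m = 1, iterations = 1), "In2_t2")
})

test_that("imputation approximately preserves marginals under MCAR", {
  m <- make_ground_truth(seed = 33, missing_type = "MCAR")
  m$missing$rates[] <- 0.10
  complete <- simulate_panel(m, 5000, seed = 33)
  mis <- inject_missingness(complete, m, seed = 33)
  imps <- impute_chained(mis, m = 2, iterations = 5, seed = 33)
  for (d in imps$datasets) {
    truth <- colMeans(complete$t1 > 0)
    got <- colMeans(d$t1 > 0)
    expect_true(all(abs(got - truth) < 0.03))
  }
})

test_that("variance inflation factors match their closed forms", {
  set.seed(41)
  n <- 4000
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("x", 1:4)))
  v <- vif_check(X)
  expect_true(all(v$vif < 1.1))
  expect_false(any(v$flagged))

  Xd <- cbind(X, x5 = X[, 1])
  vd <- vif_check(Xd)
  expect_true(is.infinite(vd$vif[vd$variable == "x5"]))
  expect_true(vd$flagged[vd$variable == "x5"])

  # x3 = x1 + x2 + noise with var 0.2: R2 = 2/2.2, VIF = 11 analytically
  Xn <- X[, 1:2]
  Xn <- cbind(Xn, x3 = X[, 1] + X[, 2] + rnorm(n, sd = sqrt(0.2)))
  vn <- vif_check(Xn)
  expect_gt(vn$vif[3], 5)
  expect_equal(vn$vif[3], 11, tolerance = 0.15)

  expect_error(vif_check(X[, 1, drop = FALSE]), "at least 2")
  Xna <- X; Xna[1, 1] <- NA
  expect_error(vif_check(Xna), "complete")
})

test_that("network pooling is the elementwise mean and is permutation
          invariant", {
  base <- as_network(matrix(0, 4, 4, dimnames = NULL))
  nets <- lapply(c(0.1, 0.2, 0.3, 0.4, 0.5), function(v) {
    nw <- base; nw$B[2, 3] <- v; nw
  })
  pooled <- pool_networks(nets)
  expect_equal(pooled$B[2, 3], 0.3)
  expect_equal(pool_networks(nets[sample(5)])$B, pooled$B)

  two <- list(nets[[1]], nets[[1]])
  two[[1]]$B[1, 2] <- 0.1; two[[2]]$B[1, 2] <- -0.1
  expect_equal(pool_networks(two)$B[1, 2], 0)
  expect_equal(pool_networks(list(nets[[2]]))$B, nets[[2]]$B)

  small <- as_network(matrix(0, 3, 3))
  expect_error(pool_networks(list(base, small)), "dimensions|node order")
})
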