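test_that("ground-truth models are reproducible and respect construction", {
  m1 <- make_ground_truth(seed = 5)
  m2 <- make_ground_truth(seed = 5)
  expect_identical(m1$true_B, m2$true_B)
  expect_identical(m1$thresholds, m2$thresholds)

  d <- make_ground_truth(n_nonzero_cross = 0, seed = 5)
  expect_true(all(d$true_B[row(d$true_B) != col(d$true_B)] == 0))

  r <- make_ground_truth(n_nonzero_cross = 10,
                         effect_range = c(0.15, 0.20), seed = 5)
  off <- r$true_B[row(r$true_B) != col(r$true_B)]
  nz <- abs(off[off != 0])
  expect_length(nz, 10)
  expect_true(all(nz >= 0.15 & nz <= 0.20))

  expect_error(make_ground_truth(n_nonzero_cross = 1000), "infeasible")
  expect_error(make_ground_truth(effect_range = c(0.1, 0.6)), "effect_range")
})

test_that("wave-1 latent covariance is positive definite and B is stable", {
  m <- make_ground_truth(seed = 3)
  ev <- eigen(m$Sigma1, only.values = TRUE)$values
  expect_true(min(ev) > 0)
  expect_lt(max(Mod(eigen(m$true_B, only.values = TRUE)$values)), 1)
  expect_true(all(m$noise_sd > 0))
})

test_that("simulated panels are deterministic in the seed", {
  m <- make_ground_truth(seed = 8)
  p1 <- simulate_panel(m, 400, seed = 9)
  p2 <- simulate_panel(m, 400, seed = 9)
  p3 <- simulate_panel(m, 400, seed = 10)
  expect_identical(p1$t1, p2$t1)
  expect_identical(p1$t2, p2$t2)
  expect_false(identical(p1$t1, p3$t1))
})

test_that("discretization is monotone in the latent value", {
  m <- make_ground_truth(seed = 2)
  pan <- simulate_panel(m, 1000, seed = 2)
  z <- attr(pan, "latent")$z1
  for (j in c(1, 5, 11, 15)) {
    codes <- pan$t1[order(z[, j]), j]
    expect_true(all(diff(codes) >= 0))
  }
})

test_that("degenerate dynamics reproduce wave 1 exactly at wave 2", {
  m <- make_ground_truth(seed = 4)
  m$true_B <- diag(m$p)
  m$noise_sd <- rep(0, m$p)
  pan <- simulate_panel(m, 200, seed = 4)
  lat <- attr(pan, "latent")
  expect_equal(lat$z1, lat$z2)
})

test_that("zero dynamics leave no cross-wave latent correlation", {
  m <- make_ground_truth(n_nonzero_cross = 0,
                         autoregressive_range = c(0, 0), seed = 6)
  pan <- simulate_panel(m, 50000, seed = 6)
  lat <- attr(pan, "latent")
  cc <- cor(lat$z1, lat$z2)
  expect_true(all(abs(cc) < 3 / sqrt(50000)))  # 3 Monte-Carlo SEs of 0
})

test_that("a single planted latent edge reproduces its analytic correlation", {
  m <- make_ground_truth(n_nonzero_cross = 0,
                         autoregressive_range = c(0, 0), seed = 7)
  m$Sigma1 <- diag(m$p)               # identity: cor(z1_i, z2_j) = B[i, j]
  m$true_B[2, 4] <- 0.3
  m$noise_sd <- sqrt(1 - diag(t(m$true_B) %*% m$Sigma1 %*% m$true_B))
  pan <- simulate_panel(m, 50000, seed = 7)
  lat <- attr(pan, "latent")
  expect_equal(cor(lat$z1[, 2], lat$z2[, 4]), 0.3, tolerance = 0.05)
  # observed codes are attenuated relative to the latent correlation
  expect_lt(cor(pan$t1[, 2], pan$t2[, 4]), 0.3)
})

test_that("binary endorsement rates track their calibrated thresholds", {
  m <- make_ground_truth(seed = 9)
  pan <- simulate_panel(m, 9290, seed = 9)
  target_t2 <- c(.111, .147, .144, .025, .008)
  got <- colMeans(pan$t2[, 11:15])
  expect_true(all(abs(got - target_t2) < 0.02))
})

test_that("missingness injection hits target rates and correlates under MAR", {
  m <- make_ground_truth(seed = 10)

  m0 <- m; m0$missing$rates[] <- 0
  pan <- simulate_panel(m, 5000, seed = 10)
  expect_identical(inject_missingness(pan, m0, seed = 1)$t1, pan$t1)

  mis <- inject_missingness(pan, m, seed = 10)
  rates <- colMeans(is.na(mis$t1))
  expect_true(all(abs(rates - m$missing$rates) < 0.02))

  # shared logistic driver induces positive missingness correlation among
  # depressive items
  ind <- is.na(mis$t1[, 1:10]) * 1
  cc <- cor(ind)
  expect_gt(mean(cc[upper.tri(cc)]), 0.05)

  mbad <- m; mbad$missing$rates[1] <- 0.5
  expect_error(inject_missingness(pan, mbad, seed = 1), "0.30")
})

test_that("MCAR injection matches binomial concentration at one item", {
  m <- make_ground_truth(seed = 11, missing_type = "MCAR")
  m$missing$rates[] <- 0
  m$missing$rates["De3"] <- 0.10
  pan <- simulate_panel(m, 20000, seed = 11)
  mis <- inject_missingness(pan, m, seed = 11)
  prop <- mean(is.na(mis$t1[, "De3"]))
  expect_gt(prop, 0.08); expect_lt(prop, 0.12)
  expect_equal(sum(is.na(mis$t1[, -3])), 0)
})

test_that("panel CSV and ground-truth JSON writers round-trip", {
  m <- make_ground_truth(seed = 12)
  pan <- inject_missingness(simulate_panel(m, 150, seed = 12), m, seed = 12)
  f <- tempfile(fileext = ".csv")
  write_panel_csv(pan, f)
  back <- read_panel_csv(f, scale = "scored")
  expect_identical(back$t1, pan$t1)
  expect_identical(back$t2, pan$t2)
  expect_equal(back$covariates$age, pan$covariates$age)

  g <- tempfile(fileext = ".json")
  write_ground_truth_json(m, g)
  js <- jsonlite::read_json(g, simplifyVector = TRUE)
  expect_equal(js$true_B, unname(m$true_B))
})
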