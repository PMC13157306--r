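small_panel <- function(n = 300, seed = 81) {
  m <- make_ground_truth(seed = seed, endorsement = moderate_rates())
  simulate_panel(m, n, seed = seed)
}

test_that("a constant estimator is maximally stable by convention", {
  pan <- small_panel()
  B <- matrix(rnorm(225), 15, 15)
  cs <- cs_coefficient(pan, stub_constant(B), "out_ei", B = 60, seed = 1)
  expect_equal(cs$cs, 0.75)
  expect_true(all(unlist(cs$correlations) == 1))
})

test_that("CS is nonincreasing as the correlation bar rises", {
  pan <- small_panel(n = 400)
  boot <- case_dropping_bootstrap(pan, stub_crosscor, B = 100, seed = 2)
  cs_vals <- vapply(c(0.3, 0.5, 0.7, 0.9), function(thr)
    cs_coefficient(pan, boot = boot, index = "out_ei",
                   corr_threshold = thr)$cs, numeric(1))
  expect_true(all(diff(cs_vals) <= 0))
})

test_that("replicates are allocated evenly across the drop grid", {
  pan <- small_panel(n = 200)
  boot <- case_dropping_bootstrap(pan, stub_crosscor, B = 90,
                                  drop_grid = c(0.1, 0.3, 0.5), seed = 3)
  expect_equal(boot$per_drop, 30)
  expect_length(boot$correlations$out_ei, 3)
  expect_length(boot$correlations$out_ei[[1]], 30)
  expect_error(case_dropping_bootstrap(pan, stub_crosscor, B = 100,
                                       drop_grid = c(0.5, 0.95)),
               "0, 0.9")
})

test_that("an estimator invariant to resampling yields zero-width edge CIs", {
  pan <- small_panel(n = 150)
  colmean_stub <- function(data)
    as_network(outer(colMeans(data$t1) * 0, colMeans(data$t2) * 0) + 0.2)
  bt <- edge_ci_bootstrap(pan, colmean_stub, B = 50, seed = 4)
  expect_true(all(bt$edge_ci$width == 0))
  expect_true(all(bt$edge_ci$lower == 0.2))
})

test_that("edge CI intervals are ordered and centred on the bootstrap
          distribution", {
  pan <- small_panel(n = 400)
  bt <- edge_ci_bootstrap(pan, stub_crosscor, B = 120, seed = 5)
  with(bt$edge_ci, {
    expect_true(all(lower <= boot_mean + 1e-12))
    expect_true(all(boot_mean <= upper + 1e-12))
    expect_true(all(width >= 0))
  })
  # the bootstrap stream is independent of estimator internals: rerunning
  # gives identical draws
  bt2 <- edge_ci_bootstrap(pan, stub_crosscor, B = 120, seed = 5)
  expect_identical(bt$edge_draws, bt2$edge_draws)
})

test_that("median edge CI width shrinks with sample size", {
  widths <- vapply(c(1000, 4000), function(n) {
    pan <- small_panel(n = n, seed = 88)
    bt <- edge_ci_bootstrap(pan, stub_crosscor, B = 80, seed = 6)
    median(bt$edge_ci$width)
  }, numeric(1))
  expect_lt(widths[2], widths[1])
})

test_that("difference tests: an edge never differs from itself, and clearly
          separated draws do", {
  set.seed(91)
  B_draws <- 400
  draws <- cbind(e1 = rnorm(B_draws, 0.30, 0.01),
                 e2 = rnorm(B_draws, 0.05, 0.01),
                 e3 = rnorm(B_draws, 0.049, 0.05))
  fake <- structure(list(edge_draws = draws,
                         centrality_draws = list(out_ei = draws),
                         level = 0.95, B = B_draws),
                    class = "clpn_boot")
  sig <- difference_tests(fake, "edges")
  expect_false(any(diag(sig)))
  expect_true(sig["e1", "e2"])
  expect_equal(sig, t(sig))
  expect_false(sig["e2", "e3"])  # overlapping distributions

  few <- fake; few$edge_draws <- draws[1:50, ]
  expect_error(difference_tests(few, "edges"), "200")
})

test_that("stability_report bundles CS values, CIs and masks coherently", {
  pan <- small_panel(n = 350)
  rep <- stability_report(pan, stub_crosscor, B_case = 60, B_edge = 200,
                          seed = 7)
  expect_named(rep$cs, c("out_ei", "in_ei", "bridge_ei"))
  expect_true(all(unlist(rep$cs) %in% c(0, seq(0.05, 0.75, by = 0.05))))
  expect_equal(dim(rep$edge_diff), c(225, 225))
  expect_false(any(diag(rep$edge_diff)))
  expect_equal(dim(rep$centrality_diff$out_ei), c(15, 15))

  d <- tempfile()
  write_stability_csv(rep, d)
  expect_true(file.exists(file.path(d, "cs_coefficients.csv")))
  expect_true(file.exists(file.path(d, "edge_ci.csv")))
})
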