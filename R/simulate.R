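#' Simulate a complete two-wave panel from a ground-truth model
#'
#' Wave-1 latent vectors are drawn from `N(0, Sigma1)`; wave-2 latents are
#' `t(true_B) %*% z1` plus Gaussian noise with the model's residual SDs.
#' Each latent value is discretized through its item's thresholds (monotone:
#' a larger latent value never yields a smaller code). Covariates (age,
#' gender, education) are generated alongside; they drive the MAR
#' missingness mechanism and are not network nodes.
#'
#' @param model A [make_ground_truth()] object.
#' @param n Number of participants.
#' @param seed Integer seed.
#' @return A complete [clpn_panel()] on the `"scored"` scale, with the
#'   latent matrices attached as `attr(, "latent")` (list `z1`, `z2`).
#' @export
simulate_panel <- function(model, n, seed = 1) {
  stopifnot(inherits(model, "clpn_ground_truth"), n >= 1)
  p <- model$p
  draws <- with_seed(seed_stream(seed, "panel"), {
    R <- chol(model$Sigma1)
    z1 <- matrix(rnorm(n * p), n, p) %*% R
    z2 <- z1 %*% model$true_B +
      matrix(rnorm(n * p), n, p) %*% diag(model$noise_sd, p)
    list(z1 = z1, z2 = z2,
         covariates = data.frame(
           age = round(rnorm(n, 68.8, 6.8), 1),
           gender = rbinom(n, 1, 0.485),
           education = rbinom(n, 1, 0.461)))
  })
  z1 <- draws$z1; z2 <- draws$z2
  colnames(z1) <- colnames(z2) <- model$items$node_id

  discretize <- function(z, thr) {
    out <- matrix(0L, nrow(z), ncol(z), dimnames = dimnames(z))
    for (j in seq_len(ncol(z)))
      out[, j] <- findInterval(z[, j], thr[[j]])
    out
  }
  t1 <- discretize(z1, model$thresholds$t1)
  t2 <- discretize(z2, model$thresholds$t2)

  panel <- clpn_panel(t1, t2, model$items, draws$covariates,
                      scale = "scored")
  attr(panel, "latent") <- list(z1 = z1, z2 = z2)
  panel
}

#' Mask cells of a complete panel according to the model's missingness
#' mechanism
#'
#' Under MCAR every item-wave cell is masked independently at the item's
#' rate. Under MAR, depressive-item cells are masked with probability
#' `plogis(a_j + w * driver)` where the driver is a standardized function of
#' the observed covariates (older age and no formal education increase
#' missingness), shared across depressive items so their missingness
#' indicators are positively correlated; internet items remain MCAR. The
#' intercepts `a_j` are calibrated against the realized driver values so
#' each item's expected missing rate equals its target.
#'
#' @param data A complete [clpn_panel()] with covariates.
#' @param model The [make_ground_truth()] model holding rates and mechanism.
#' @param seed Integer seed.
#' @return The panel with `NA`s injected.
#' @export
inject_missingness <- function(data, model, seed = 1) {
  stopifnot(inherits(data, "clpn_panel"), inherits(model, "clpn_ground_truth"))
  if (!panel_complete(data)) stop("`data` must be complete")
  rates <- model$missing$rates
  if (any(rates < 0 | rates > 0.30))
    stop("per-item missingness rates must lie in [0, 0.30]")
  n <- n_participants(data)
  driver <- NULL
  if (model$missing$type == "MAR") {
    cv <- data$covariates
    if (is.null(cv)) stop("MAR mechanism requires covariates")
    raw <- as.numeric(scale(cv$age)) + 0.8 * (1 - cv$education)
    driver <- as.numeric(scale(raw))
  }

  mask_probs <- function(target, item_is_dep) {
    if (model$missing$type == "MAR" && item_is_dep && target > 0) {
      w <- model$missing$mar_weight
      f <- function(a) mean(plogis(a + w * driver)) - target
      a <- uniroot(f, c(-20, 20))$root
      plogis(a + w * driver)
    } else rep(target, n)
  }

  items <- model$items
  with_seed(seed_stream(seed, "missingness"), {
    for (j in seq_len(model$p)) {
      pr <- mask_probs(rates[[items$node_id[j]]],
                       items$community[j] == "depressive")
      for (w in 1:2) {
        hit <- runif(n) < pr
        if (w == 1) data$t1[hit, j] <- NA else data$t2[hit, j] <- NA
      }
    }
  })
  attr(data, "latent") <- NULL
  data
}

#' One-call synthetic dataset presets
#'
#' Bundles [make_ground_truth()], [simulate_panel()] and (optionally)
#' [inject_missingness()] under named presets:
#' \describe{
#'   \item{`"desk"`}{n = 5000, default sparse structure - the workbench
#'     scale used throughout the test-suite fixtures.}
#'   \item{`"charls_like"`}{n = 9290, 15 items, marginal endorsement and
#'     missingness rates emulating the two-wave cohort of older adults the
#'     method was designed for.}
#' }
#'
#' @param preset `"desk"` or `"charls_like"`.
#' @param seed Integer master seed.
#' @param missing Inject missingness? (default `TRUE`)
#' @param n Override the preset's sample size.
#' @return List with `model` (ground truth) and `panel`.
#' @export
synthetic_preset <- function(preset = c("desk", "charls_like"), seed = 1,
                             missing = TRUE, n = NULL) {
  preset <- match.arg(preset)
  n <- n %||% switch(preset, desk = 5000, charls_like = 9290)
  model <- make_ground_truth(seed = seed)
  panel <- simulate_panel(model, n, seed = seed)
  if (missing) panel <- inject_missingness(panel, model, seed = seed)
  list(model = model, panel = panel)
}

#' Write a ground-truth model as JSON
#'
#' Companion writer to [write_panel_csv()] so a simulated dataset can be
#' archived with its generative parameters.
#'
#' @param model A [make_ground_truth()] object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(model, path) {
  stopifnot(inherits(model, "clpn_ground_truth"))
  out <- list(p = model$p, node_id = model$items$node_id,
              true_B = model$true_B, Sigma1 = model$Sigma1,
              noise_sd = model$noise_sd,
              thresholds = model$thresholds,
              missing = model$missing, seed = model$seed)
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}
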