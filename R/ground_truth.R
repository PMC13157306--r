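# Generative ground truth for synthetic two-wave panels.
#
# The generator is linear-Gaussian in a latent layer: wave-1 latents are
# multivariate normal, wave-2 latents follow a lag-1 linear map through the
# true cross-lagged matrix, and observed codes arise by thresholding each
# latent. This keeps latent correlations analytically checkable while
# reproducing the mixed binary/ordinal measurement of the instruments.

# Default per-wave endorsement rates P(code >= 1), emulating the marginal
# frequencies of a CHARLS-like cohort of older adults. Reverse-worded CES-D
# items (5, 8) are expressed on the scored (depression-direction) scale, so
# their raw endorsement is complemented.
default_endorsement <- function() {
  dep_t1 <- c(.455, .477, .484, .430, .643, .211, .534, .522, .319, .245)
  dep_t2 <- c(.492, .511, .483, .509, .690, .224, .524, .565, .316, .260)
  rev <- c(5, 8)
  dep_t1[rev] <- 1 - dep_t1[rev]
  dep_t2[rev] <- 1 - dep_t2[rev]
  list(dep_t1 = dep_t1, dep_t2 = dep_t2,
       int_t1 = c(.037, .050, .040, .016, .005),
       int_t2 = c(.111, .147, .144, .025, .008))
}

# Thresholds for one wave: ordinal items get 3 increasing cutpoints with the
# first matching the endorsement rate and higher categories progressively
# rarer; binary items get a single cutpoint.
make_thresholds <- function(dep_rates, int_rates, ord_step = 0.8) {
  c(lapply(dep_rates, function(r) qnorm(1 - r) + ord_step * (0:2)),
    lapply(int_rates, function(r) qnorm(1 - r)))
}

#' Build a ground-truth generative model for synthetic panels
#'
#' Draws a sparse true cross-lagged coefficient matrix `true_B` (rows =
#' wave-1 predictors, columns = wave-2 outcomes, diagonal = autoregressive
#' effects), a wave-1 latent covariance with within-community correlation,
#' per-item discretization thresholds calibrated to low endorsement rates
#' for the Internet-purpose indicators and skewed ordinal margins for the
#' depressive items, and a missingness mechanism.
#'
#' @param n_internet,n_dep Number of binary internet-purpose and ordinal
#'   depressive items (defaults 5 and 10, the canonical instruments).
#' @param n_nonzero_cross Number of nonzero off-diagonal (cross-lagged)
#'   entries of `true_B` (default 12).
#' @param effect_range Magnitude interval for cross-lagged effects, signs
#'   random (default `c(0.05, 0.20)`, matching the scale of reported
#'   temporal-network edges).
#' @param autoregressive_range Magnitude interval for the (positive)
#'   diagonal autoregressive effects.
#' @param seed Integer seed; the model is fully reproducible from it.
#' @param missing_type `"MAR"` (depressive-item missingness driven by a
#'   shared logistic function of covariates, internet items independently)
#'   or `"MCAR"` (all independent).
#' @param missing_rates Optional named per-item missingness rates in
#'   `[0, 0.30]`, applied to both wave columns. Default: depressive items
#'   evenly spaced 0.10-0.27, internet items 0.10.
#' @param endorsement Optional list overriding the default per-wave
#'   endorsement rates (fields `dep_t1`, `dep_t2`, `int_t1`, `int_t2`).
#'   Useful for small-sample fixtures where the default sub-1% purpose
#'   rates would leave items without observed endorsements.
#' @return An object of class `clpn_ground_truth` with fields `p`, `items`,
#'   `true_B`, `Sigma1`, `noise_sd`, `thresholds` (`$t1`, `$t2` lists of
#'   cutpoints), `missing` and `seed`.
#' @export
make_ground_truth <- function(n_internet = 5, n_dep = 10,
                              n_nonzero_cross = 12,
                              effect_range = c(0.05, 0.20),
                              autoregressive_range = c(0.15, 0.35),
                              seed = 1,
                              missing_type = c("MAR", "MCAR"),
                              missing_rates = NULL,
                              endorsement = NULL) {
  missing_type <- match.arg(missing_type)
  stopifnot(n_internet >= 1, n_dep >= 1)
  if (any(abs(effect_range) >= 0.5))
    stop("effect_range must lie within (-0.5, 0.5)")
  p <- n_internet + n_dep
  if (n_nonzero_cross > p^2 - p)
    stop("infeasible sparsity: n_nonzero_cross exceeds available ",
         "off-diagonal cells (", p^2 - p, ")")

  items <- if (n_dep == 10 && n_internet == 5) clpn_items() else
    data.frame(node_id = c(paste0("De", seq_len(n_dep)),
                           paste0("In", seq_len(n_internet))),
               name = c(paste0("Depressive item ", seq_len(n_dep)),
                        paste0("Internet purpose ", seq_len(n_internet))),
               item_type = rep(c("ordinal_0_3", "binary"),
                               c(n_dep, n_internet)),
               community = rep(c("depressive", "internet"),
                               c(n_dep, n_internet)),
               reverse_scored = FALSE, stringsAsFactors = FALSE)

  B <- with_seed(seed_stream(seed, "ground-truth"), {
    B <- matrix(0, p, p, dimnames = list(items$node_id, items$node_id))
    diag(B) <- runif(p, autoregressive_range[1], autoregressive_range[2])
    off <- which(row(B) != col(B))
    pick <- sample(off, n_nonzero_cross)
    B[pick] <- runif(n_nonzero_cross, abs(effect_range[1]),
                     abs(effect_range[2])) *
      sample(c(-1, 1), n_nonzero_cross, replace = TRUE)
    B
  })
  sr <- max(Mod(eigen(B, only.values = TRUE)$values))
  if (sr >= 1) B <- B * (0.95 / sr)

  # exchangeable-within-community latent correlations, weak cross-block
  comm <- items$community
  Sigma1 <- matrix(0.05, p, p, dimnames = dimnames(B))
  Sigma1[comm == "depressive", comm == "depressive"] <- 0.35
  Sigma1[comm == "internet", comm == "internet"] <- 0.30
  diag(Sigma1) <- 1
  stopifnot(min(eigen(Sigma1, only.values = TRUE)$values) > 0)

  # residual SDs calibrated so each wave-2 latent has unit variance,
  # keeping one set of thresholds valid at both waves
  expl <- diag(t(B) %*% Sigma1 %*% B)
  if (any(expl >= 0.9)) {
    B <- B * sqrt(0.9 / max(expl))
    expl <- diag(t(B) %*% Sigma1 %*% B)
  }
  noise_sd <- sqrt(1 - expl)

  rates <- modifyList(default_endorsement(), endorsement %||% list())
  dep_idx <- seq_len(n_dep); int_idx <- seq_len(n_internet)
  thresholds <- list(
    t1 = make_thresholds(rep_len(rates$dep_t1, n_dep)[dep_idx],
                         rep_len(rates$int_t1, n_internet)[int_idx]),
    t2 = make_thresholds(rep_len(rates$dep_t2, n_dep)[dep_idx],
                         rep_len(rates$int_t2, n_internet)[int_idx]))
  names(thresholds$t1) <- names(thresholds$t2) <- items$node_id

  if (is.null(missing_rates)) {
    missing_rates <- stats::setNames(
      c(seq(0.10, 0.27, length.out = n_dep), rep(0.10, n_internet)),
      items$node_id)
  }
  if (any(missing_rates < 0 | missing_rates > 0.30))
    stop("per-item missingness rates must lie in [0, 0.30]")

  structure(list(p = p, items = items, true_B = B, Sigma1 = Sigma1,
                 noise_sd = noise_sd, thresholds = thresholds,
                 missing = list(type = missing_type, rates = missing_rates,
                                mar_weight = 1.2),
                 seed = seed),
            class = "clpn_ground_truth")
}

#' @export
print.clpn_ground_truth <- function(x, ...) {
  k <- sum(x$true_B[row(x$true_B) != col(x$true_B)] != 0)
  cat(sprintf("<clpn_ground_truth> p = %d (%d depressive, %d internet)\n",
              x$p, sum(x$items$community == "depressive"),
              sum(x$items$community == "internet")))
  cat(sprintf("  cross-lagged nonzeros: %d; missingness: %s\n",
              k, x$missing$type))
  invisible(x)
}
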