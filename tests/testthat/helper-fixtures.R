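# Shared fixtures and independent oracles, all built in code.

# Strong planted-structure model: 20 cross-lagged effects of latent
# magnitude 0.15-0.30, the workbench recovery fixture.
recovery_model <- function(seed = 42) {
  make_ground_truth(n_nonzero_cross = 20, effect_range = c(0.15, 0.30),
                    seed = seed)
}

# Moderate endorsement rates for small-n fixtures, where the default
# sub-1% purpose rates would leave binary items unobserved.
moderate_rates <- function() {
  list(int_t1 = c(0.12, 0.15, 0.13, 0.10, 0.11),
       int_t2 = c(0.12, 0.15, 0.13, 0.10, 0.11))
}

# Brute-force loop oracles for the expected-influence indices; written
# independently of the package's vectorized implementations.
oracle_out_ei <- function(B, i) {
  s <- 0
  for (j in seq_len(ncol(B))) if (j != i) s <- s + B[i, j]
  s
}
oracle_in_ei <- function(B, j) {
  s <- 0
  for (i in seq_len(nrow(B))) if (i != j) s <- s + B[i, j]
  s
}
oracle_bridge_ei <- function(B, i, comm) {
  s <- 0
  for (j in seq_len(ncol(B)))
    if (j != i && comm[j] != comm[i]) s <- s + B[i, j]
  s
}

# Minimal network object wrapping a raw matrix, for centrality unit tests.
as_network <- function(B, ids = NULL) {
  ids <- ids %||% clpn_items()$node_id[seq_len(ncol(B))]
  dimnames(B) <- list(ids, ids)
  structure(list(B = B, items = clpn_items()[seq_len(ncol(B)), ]),
            class = "clpn_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cheap deterministic data-dependent estimator stub for bootstrap tests:
# cross-wave correlation matrix in place of the penalized fit.
stub_crosscor <- function(data) {
  B <- suppressWarnings(cor(data$t1, data$t2))
  B[!is.finite(B)] <- 0
  structure(list(B = B, items = data$items), class = "clpn_network")
}

# Estimator stub ignoring the data entirely (perfectly stable).
stub_constant <- function(B) function(data) as_network(B)
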