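# Expected-influence centralities for directed cross-lagged networks.
# All three indices ignore the autoregressive diagonal and use signed edge
# weights, so positive and negative influences can cancel.

resolve_node <- function(network, node) {
  ids <- rownames(network$B)
  if (is.character(node)) {
    i <- match(node, ids)
    if (is.na(i)) stop("unknown node: ", node)
    i
  } else {
    if (node < 1 || node > length(ids)) stop("unknown node index: ", node)
    as.integer(node)
  }
}

#' Out expected influence of a node
#'
#' Sum of the node's outgoing signed edge weights `B[i, j]`, `j != i`: how
#' strongly the node at wave 1 predicts all other nodes at wave 2.
#'
#' @param network A `clpn_network`.
#' @param node Node id or index.
#' @return Numeric scalar.
#' @export
out_ei <- function(network, node) {
  i <- resolve_node(network, node)
  # ordered elementwise accumulation: deterministic IEEE result
  s <- 0
  for (j in seq_len(ncol(network$B))) if (j != i) s <- s + network$B[i, j]
  s
}

#' In expected influence of a node
#'
#' Sum of the node's incoming signed edge weights `B[i, j]`, `i != j`: how
#' strongly the node at wave 2 is predicted by all other wave-1 nodes.
#'
#' @inheritParams out_ei
#' @return Numeric scalar.
#' @export
in_ei <- function(network, node) {
  j <- resolve_node(network, node)
  s <- 0
  for (i in seq_len(nrow(network$B))) if (i != j) s <- s + network$B[i, j]
  s
}

#' Bridge expected influence of a node
#'
#' Sum of the node's outgoing signed edges into the other community
#' (internet vs depressive), quantifying its one-step influence on the
#' other construct. Set `direction = "in"` for the incoming variant.
#'
#' @inheritParams out_ei
#' @param partition Named vector mapping every node id to a community
#'   (default [clpn_partition()]).
#' @param direction `"out"` (default) or `"in"`.
#' @return Numeric scalar.
#' @export
bridge_ei <- function(network, node, partition = clpn_partition(),
                      direction = c("out", "in")) {
  direction <- match.arg(direction)
  i <- resolve_node(network, node)
  ids <- rownames(network$B)
  if (anyNA(partition[ids]))
    stop("unpartitioned node(s): ",
         paste(ids[is.na(partition[ids])], collapse = ", "))
  mine <- partition[[ids[i]]]
  s <- 0
  for (j in seq_along(ids)) {
    if (j == i || partition[[ids[j]]] == mine) next
    s <- s + (if (direction == "out") network$B[i, j] else network$B[j, i])
  }
  s
}

#' Centrality table for all nodes
#'
#' Out-EI, In-EI and Bridge-EI for every node in canonical order, with
#' optional z-standardized columns (the convention of centrality plots).
#'
#' @param network A `clpn_network`.
#' @param partition Named community map (default [clpn_partition()]).
#' @param standardized Add z-scored columns? (default `TRUE`)
#' @return Data frame of class `clpn_centrality` with columns `node_id`,
#'   `community`, `out_ei`, `in_ei`, `bridge_ei` (and `*_z` if requested).
#' @export
centrality_table <- function(network, partition = clpn_partition(),
                             standardized = TRUE) {
  stopifnot(inherits(network, "clpn_network"))
  ids <- rownames(network$B)
  tab <- data.frame(
    node_id = ids,
    community = unname(partition[ids]),
    out_ei = vapply(ids, function(v) out_ei(network, v), numeric(1)),
    in_ei = vapply(ids, function(v) in_ei(network, v), numeric(1)),
    bridge_ei = vapply(ids, function(v) bridge_ei(network, v, partition),
                       numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  if (standardized) {
    z <- function(v) if (sd(v) > 0) (v - mean(v)) / sd(v) else v * 0
    tab$out_ei_z <- z(tab$out_ei)
    tab$in_ei_z <- z(tab$in_ei)
    tab$bridge_ei_z <- z(tab$bridge_ei)
  }
  class(tab) <- c("clpn_centrality", "data.frame")
  tab
}

#' Write a centrality table to CSV
#'
#' @param tab A [centrality_table()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_centrality_csv <- function(tab, path) {
  write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}
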