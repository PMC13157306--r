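#' Canonical item registry
#'
#' The two instruments analysed by the package: the 10-item CES-D depression
#' screener (ordinal, 0-3 Likert codes; items 5 and 8 are positively worded
#' and reverse-scored) and the 5-item Internet-use-purpose checklist (binary
#' 0/1 indicators). Node identifiers `De1`..`De10` and `In1`..`In5` index all
#' downstream matrices in this fixed order.
#'
#' @return A data frame with one row per item and columns `node_id`, `name`,
#'   `item_type` (`"ordinal_0_3"` or `"binary"`), `community` (`"depressive"`
#'   or `"internet"`) and `reverse_scored`.
#' @examples
#' clpn_items()
#' @export
clpn_items <- function() {
  data.frame(
    node_id = c(paste0("De", 1:10), paste0("In", 1:5)),
    name = c("Unusually bothered", "Mind adrift", "Felt depressed",
             "Everything was an effort", "Felt hopeful about the future",
             "Felt fearful", "Restless sleep", "Lack of happiness",
             "Loneliness", "Inability get going",
             "Chatting", "Watching news", "Watching videos",
             "Playing games", "Financial management"),
    item_type = rep(c("ordinal_0_3", "binary"), c(10, 5)),
    community = rep(c("depressive", "internet"), c(10, 5)),
    reverse_scored = c(rep(FALSE, 4), TRUE, FALSE, FALSE, TRUE,
                       rep(FALSE, 2), rep(FALSE, 5)),
    stringsAsFactors = FALSE
  )
}

#' Community partition of the canonical nodes
#'
#' @return Named character vector mapping each node id to its community.
#' @export
clpn_partition <- function() {
  items <- clpn_items()
  stats::setNames(items$community, items$node_id)
}

# validate a user-supplied registry against the structural invariants
validate_items <- function(items) {
  req <- c("node_id", "name", "item_type", "community", "reverse_scored")
  if (!all(req %in% names(items)))
    stop("item registry must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(items$node_id))
    stop("item registry node_ids must be unique")
  if (!all(items$item_type %in% c("ordinal_0_3", "binary")))
    stop("unknown item_type in registry")
  bad <- items$reverse_scored & items$item_type != "ordinal_0_3"
  if (any(bad))
    stop("reverse_scored requires ordinal_0_3 type: ",
         paste(items$node_id[bad], collapse = ", "))
  invisible(items)
}
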