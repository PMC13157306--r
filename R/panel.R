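#' Construct a two-wave panel dataset
#'
#' Holds one row per participant and one column per item at each wave, with
#' `NA` marking missing responses. Ordinal items carry codes 0-3, binary
#' items 0/1. The `scale` attribute records whether reverse-scored CES-D
#' items (5 and 8) are stored as administered (`"raw"`) or already flipped
#' into the depression direction (`"scored"`); network estimation operates
#' on the scored scale.
#'
#' @param t1,t2 Integer matrices (n x p) of wave-1 / wave-2 item codes with
#'   columns named by node id; `NA` = missing.
#' @param items Item registry data frame (see [clpn_items()]).
#' @param covariates Optional data frame of per-participant covariates.
#' @param scale `"raw"` or `"scored"`.
#' @return An object of class `clpn_panel`.
#' @export
clpn_panel <- function(t1, t2, items = clpn_items(), covariates = NULL,
                       scale = c("raw", "scored")) {
  scale <- match.arg(scale)
  validate_items(items)
  t1 <- as.matrix(t1); t2 <- as.matrix(t2)
  p <- nrow(items)
  if (ncol(t1) != p || ncol(t2) != p)
    stop("wave matrices must have one column per registry item (", p, ")")
  if (nrow(t1) != nrow(t2))
    stop("wave matrices must have the same number of rows")
  if (is.null(colnames(t1))) colnames(t1) <- items$node_id
  if (is.null(colnames(t2))) colnames(t2) <- items$node_id
  if (!identical(colnames(t1), items$node_id) ||
      !identical(colnames(t2), items$node_id))
    stop("wave matrix columns must match registry node order")
  for (j in seq_len(p)) {
    rng <- if (items$item_type[j] == "binary") 0:1 else 0:3
    for (w in 1:2) {
      v <- (if (w == 1) t1 else t2)[, j]
      bad <- which(!is.na(v) & !(v %in% rng))
      if (length(bad))
        stop(sprintf("out-of-range code %s at row %d, column %s_t%d",
                     v[bad[1]], bad[1], items$node_id[j], w))
    }
  }
  if (!is.null(covariates) && nrow(covariates) != nrow(t1))
    stop("covariates must have one row per participant")
  structure(list(t1 = t1, t2 = t2, items = items,
                 covariates = covariates, scale = scale),
            class = "clpn_panel")
}

#' @export
print.clpn_panel <- function(x, ...) {
  nmis <- sum(is.na(x$t1)) + sum(is.na(x$t2))
  cat(sprintf("<clpn_panel> %d participants x %d items x 2 waves (%s scale)\n",
              nrow(x$t1), ncol(x$t1), x$scale))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", nmis,
              100 * nmis / (2 * length(x$t1))))
  invisible(x)
}

n_participants <- function(panel) nrow(panel$t1)

panel_complete <- function(panel) !anyNA(panel$t1) && !anyNA(panel$t2)

#' Flip reverse-worded CES-D items into the depression direction
#'
#' Applies `v -> 3 - v` to the reverse-scored registry items (CES-D items 5
#' and 8) at both waves and marks the panel as `"scored"`.
#'
#' @param panel A `clpn_panel` on the `"raw"` scale.
#' @return The panel on the `"scored"` scale.
#' @export
reverse_score_panel <- function(panel) {
  stopifnot(inherits(panel, "clpn_panel"))
  if (panel$scale == "scored")
    stop("panel is already on the scored scale")
  idx <- which(panel$items$reverse_scored)
  panel$t1[, idx] <- 3L - panel$t1[, idx]
  panel$t2[, idx] <- 3L - panel$t2[, idx]
  panel$scale <- "scored"
  panel
}

#' Read a wide two-wave panel CSV
#'
#' Expects one column per item and wave named `<node_id>_t1` /
#' `<node_id>_t2`; empty cells are treated as missing. Any remaining columns
#' are kept as covariates. Codes are range-validated against the registry.
#'
#' @param path CSV file path.
#' @param items Item registry (default canonical).
#' @param scale Scale the stored values are on (default `"raw"`).
#' @return A [clpn_panel()].
#' @export
read_panel_csv <- function(path, items = clpn_items(),
                           scale = c("raw", "scored")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(read.csv(path, check.names = FALSE),
                 error = function(e) stop("could not parse ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0 || ncol(df) == 0) stop("empty panel file: ", path)
  need <- c(paste0(items$node_id, "_t1"), paste0(items$node_id, "_t2"))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  t1 <- as.matrix(df[paste0(items$node_id, "_t1")])
  t2 <- as.matrix(df[paste0(items$node_id, "_t2")])
  colnames(t1) <- colnames(t2) <- items$node_id
  cov_cols <- setdiff(names(df), need)
  covariates <- if (length(cov_cols)) df[cov_cols] else NULL
  clpn_panel(t1, t2, items, covariates, scale = scale)
}

#' Write a panel to a wide CSV
#'
#' Inverse of [read_panel_csv()]: columns `<node_id>_t1`, `<node_id>_t2`
#' then covariates; missing values become empty cells.
#'
#' @param panel A `clpn_panel`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(panel, path) {
  stopifnot(inherits(panel, "clpn_panel"))
  df1 <- as.data.frame(panel$t1)
  names(df1) <- paste0(names(df1), "_t1")
  df2 <- as.data.frame(panel$t2)
  names(df2) <- paste0(names(df2), "_t2")
  df <- cbind(df1, df2)
  if (!is.null(panel$covariates)) df <- cbind(df, panel$covariates)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
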