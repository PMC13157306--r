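#' Score the 10-item CES-D
#'
#' Items are coded 0 (rarely or none of the time) to 3 (most or all of the
#' time). The positively worded items 5 ("Felt hopeful about the future") and
#' 8 ("Lack of happiness" stem, worded as happiness) are reverse-scored
#' (`v -> 3 - v`) before summation, so the total ranges 0-30 with higher
#' scores meaning more severe symptoms. Totals of 10 or more indicate
#' clinically relevant depressive symptoms.
#'
#' @param responses Numeric vector of length 10 with values in `{0,1,2,3}`,
#'   in item order `De1`..`De10`, on the raw (as-administered) scale.
#' @param cutoff Clinical cutoff applied to the total (default 10).
#' @return A list with `total_score` (integer, 0-30), `above_cutoff`
#'   (logical) and `scored` (the 10 item scores after reverse-coding).
#' @examples
#' score_cesd(rep(0, 10))$total_score   # 6: items 5 and 8 contribute 3 each
#' @export
score_cesd <- function(responses, cutoff = 10) {
  if (length(responses) != 10)
    stop("`responses` must have exactly 10 values, got ", length(responses))
  bad <- which(is.na(responses) | !(responses %in% 0:3))
  if (length(bad))
    stop("invalid CES-D response at item(s) ",
         paste(bad, collapse = ", "), ": values must be in {0,1,2,3}")
  scored <- as.integer(responses)
  rev_idx <- which(clpn_items()$reverse_scored[1:10])
  scored[rev_idx] <- 3L - scored[rev_idx]
  total <- sum(scored)
  list(total_score = total,
       above_cutoff = total >= cutoff,
       scored = scored)
}

#' Encode Internet-use-purpose selections as binary indicators
#'
#' Respondents tick any subset of five purposes ("What do you usually do on
#' the Internet?"); a ticked purpose is coded 1, otherwise 0.
#'
#' @param selected Character vector of selected purpose labels (possibly
#'   empty), drawn from the canonical five labels in [clpn_items()].
#' @return Named integer vector of length 5 (`In1`..`In5`) of 0/1 codes.
#' @examples
#' encode_purposes(c("Chatting", "Playing games"))
#' @export
encode_purposes <- function(selected = character()) {
  items <- clpn_items()
  purp <- items[items$community == "internet", ]
  unknown <- setdiff(selected, purp$name)
  if (length(unknown))
    stop("unknown purpose label(s): ", paste(unknown, collapse = ", "))
  stats::setNames(as.integer(purp$name %in% selected), purp$node_id)
}
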