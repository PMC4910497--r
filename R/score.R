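#' Point weights for match confidence
#'
#' The point scheme that feeds the confidence sigmoid. Weights are
#' calibrated so that the scheme's outputs land on the published anchor
#' confidences of the scoring approach it implements: an exact uninomial
#' match scores 1 point (confidence 0.75); a binomial canonical match 4
#' points (0.988); full authorship agreement adds 2.3 (0.999 for an
#' agreeing binomial); an authorship conflict subtracts 3 (back to 0.75);
#' each edit-distance unit subtracts 2, placing an ED-2 binomial match
#' exactly at the 0.5 human-check boundary; each extra competing target
#' subtracts 1.
#'
#' @param uninomial,binomial,trinomial_plus points for the matched rank.
#' @param authorship_agree bonus when source and target authorship agree.
#' @param authorship_conflict penalty when both carry authorship and they
#'   disagree.
#' @param per_edit penalty per unit of edit distance.
#' @param multi_target penalty when more than one target ties.
#' @param sigmoid_base base of the logistic curve (see [gn_sigmoid()]).
#' @return a named list of weights.
#' @export
score_weights <- function(uninomial = 1, binomial = 4, trinomial_plus = 4,
                          authorship_agree = 2.3, authorship_conflict = -3,
                          per_edit = -2, multi_target = -1,
                          sigmoid_base = 3) {
  list(
    uninomial = uninomial, binomial = binomial,
    trinomial_plus = trinomial_plus,
    authorship_agree = authorship_agree,
    authorship_conflict = authorship_conflict,
    per_edit = per_edit, multi_target = multi_target,
    sigmoid_base = sigmoid_base
  )
}

#' Point total for a set of match features
#'
#' Adds and subtracts points for the features of a match: the rank of the
#' matched canonical (uninomial / binomial / trinomial or deeper), the
#' state of the authorship comparison, the edit distance of the match and
#' whether several targets tied.
#'
#' @param matched_rank one of \code{"uninomial"}, \code{"binomial"},
#'   \code{"trinomial_plus"} (vectorized).
#' @param authorship_state one of \code{"absent"}, \code{"agrees"},
#'   \code{"conflicts"}.
#' @param edit_distance non-negative integer edit distance.
#' @param multi_target logical; more than one target at the winning tier.
#' @param weights weight list from [score_weights()].
#' @return numeric vector of point totals.
#' @examples
#' gn_points("uninomial", "absent", 0)   # 1
#' gn_points("binomial", "absent", 0)    # 4
#' @export
gn_points <- function(matched_rank, authorship_state = "absent",
                      edit_distance = 0L, multi_target = FALSE,
                      weights = score_weights()) {
  matched_rank <- match.arg(
    matched_rank, c("uninomial", "binomial", "trinomial_plus"),
    several.ok = TRUE
  )
  authorship_state <- match.arg(
    authorship_state, c("absent", "agrees", "conflicts"), several.ok = TRUE
  )
  stopifnot(all(edit_distance >= 0))
  base <- unlist(weights[matched_rank], use.names = FALSE)
  auth <- ifelse(
    authorship_state == "agrees", weights$authorship_agree,
    ifelse(authorship_state == "conflicts", weights$authorship_conflict, 0)
  )
  base + auth + weights$per_edit * edit_distance +
    weights$multi_target * as.numeric(multi_target)
}

#' Sigmoid mapping from points to confidence
#'
#' Converts a point total into a confidence value in (0, 1) with a base-3
#' logistic curve: \eqn{1 / (1 + 3^{-p})}. Zero points give the neutral
#' confidence 0.5; the curve exaggerates initial strong or weak evidence
#' and damps the effect of further points.
#'
#' @param points numeric vector of point totals.
#' @param base base of the logistic (default 3).
#' @return numeric vector of confidences in (0, 1).
#' @examples
#' gn_sigmoid(c(0, 1, 4))
#' @export
gn_sigmoid <- function(points, base = 3) {
  1 / (1 + base^(-points))
}

#' Confidence score for a match
#'
#' Combines [gn_points()] and [gn_sigmoid()] and applies the human-check
#' rule: results with confidence at or below 0.5 need confirmation by a
#' human check.
#'
#' @inheritParams gn_points
#' @return a tibble with columns \code{points}, \code{confidence} and
#'   \code{needs_human_check}.
#' @examples
#' gn_confidence("binomial", "agrees", 0)
#' @export
gn_confidence <- function(matched_rank, authorship_state = "absent",
                          edit_distance = 0L, multi_target = FALSE,
                          weights = score_weights()) {
  p <- gn_points(matched_rank, authorship_state, edit_distance,
                 multi_target, weights)
  conf <- gn_sigmoid(p, base = weights$sigmoid_base)
  tibble::tibble(
    points = p,
    confidence = conf,
    needs_human_check = conf <= 0.5
  )
}
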