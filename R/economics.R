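#' Incremental cost-effectiveness ratio
#'
#' `(cost_a - cost_b) / (effect_a - effect_b)` for a strategy `a` that is more
#' effective than comparator `b`.
#'
#' @param a,b Lists (or one-row data frames) with elements `cost` and
#'   `effect`; `a$effect` must strictly exceed `b$effect`.
#' @return Money per unit of effect.
#' @examples
#' icer(list(cost = 1000, effect = 0.5), list(cost = 500, effect = 0.4))
#' @export
icer <- function(a, b) {
  if (!(a$effect > b$effect)) {
    stop("ICER is undefined unless a is strictly more effective than b",
         call. = FALSE)
  }
  (a$cost - b$cost) / (a$effect - b$effect)
}

#' Net monetary benefit
#'
#' `threshold * effect - cost`: the monetary value of a strategy's effect at
#' a willingness-to-pay threshold, net of its cost. The strategy maximising
#' net benefit at a threshold is the cost-effective choice there.
#'
#' @param point List or data frame with `effect` and `cost` (vectorised).
#' @param threshold Willingness to pay per unit of effect (>= 0).
#' @return Money (vectorised over rows of `point`).
#' @export
net_benefit <- function(point, threshold) {
  stopifnot(all(threshold >= 0))
  threshold * point$effect - point$cost
}

#' Cost-effectiveness efficiency frontier
#'
#' Identifies the strategies not excluded by dominance (another strategy
#' costs no more and is at least as effective, strictly better on one axis)
#' or extended dominance (a strategy whose ICER versus the previous frontier
#' member exceeds the ICER of the next member). The frontier is ordered by
#' strictly increasing effect and cost, and its ICER sequence is strictly
#' increasing. Exact ties on both axes keep the lexicographically first
#' label.
#'
#' @param points Data frame with columns `label`, `effect`, `cost`
#'   (cost >= 0, effect finite).
#' @return A data frame of class `cea_frontier`: input rows plus
#'   `on_frontier`, `status` (`"frontier"`, `"dominated"`,
#'   `"extended_dominated"`) and `icer` (versus the previous frontier member;
#'   `NA` for the least costly member and for non-members), ordered by
#'   increasing effect.
#' @export
efficiency_frontier <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("label", "effect", "cost") %in% names(points)),
            nrow(points) >= 1)
  if (any(!is.finite(points$effect)) || any(points$cost < 0)) {
    stop("effects must be finite and costs non-negative", call. = FALSE)
  }
  if (anyDuplicated(points$label)) {
    stop("strategy labels must be unique", call. = FALSE)
  }
  pts <- as.data.frame(points)[, c("label", "effect", "cost")]
  n <- nrow(pts)
  status <- rep(NA_character_, n)

  # dominance (weak: equal on one axis, strictly better on the other;
  # exact ties on both axes resolved by label order)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      better <- pts$cost[j] <= pts$cost[i] && pts$effect[j] >= pts$effect[i]
      strict <- pts$cost[j] < pts$cost[i] || pts$effect[j] > pts$effect[i]
      tie <- pts$cost[j] == pts$cost[i] && pts$effect[j] == pts$effect[i]
      if ((better && strict) || (tie && pts$label[j] < pts$label[i])) {
        status[i] <- "dominated"
        break
      }
    }
  }

  # greedy hull over the undominated points: start at the least costly,
  # repeatedly take the point with the smallest ICER versus the current one
  # (ties broken towards the largest effect, which drops collinear
  # intermediate points as extended dominated)
  alive <- which(is.na(status))
  start <- alive[order(pts$cost[alive], -pts$effect[alive],
                       pts$label[alive])][1]
  frontier <- start
  current <- start
  repeat {
    cand <- alive[pts$effect[alive] > pts$effect[current]]
    if (!length(cand)) break
    icers <- (pts$cost[cand] - pts$cost[current]) /
      (pts$effect[cand] - pts$effect[current])
    best <- cand[order(icers, -pts$effect[cand])][1]
    frontier <- c(frontier, best)
    current <- best
  }
  status[frontier] <- "frontier"
  status[is.na(status)] <- "extended_dominated"

  pts$on_frontier <- status == "frontier"
  pts$status <- status
  pts$icer <- NA_real_
  if (length(frontier) > 1) {
    for (k in 2:length(frontier)) {
      i <- frontier[k]
      j <- frontier[k - 1]
      pts$icer[i] <- (pts$cost[i] - pts$cost[j]) /
        (pts$effect[i] - pts$effect[j])
    }
  }
  pts <- pts[order(pts$effect, pts$cost, pts$label), , drop = FALSE]
  rownames(pts) <- NULL
  class(pts) <- c("cea_frontier", "data.frame")
  pts
}

#' Detection-per-pound efficiency frontier
#'
#' [efficiency_frontier()] applied in the (testing cost, CS cancers detected)
#' plane.
#'
#' @param points Data frame with columns `label`, `detected` (CS cancers
#'   detected per man) and `testing_cost` (money per man).
#' @return A `cea_frontier` (with `effect` = detection, `cost` = testing
#'   cost).
#' @export
detection_frontier <- function(points) {
  stopifnot(all(c("label", "detected", "testing_cost") %in% names(points)))
  efficiency_frontier(data.frame(label = points$label,
                                 effect = points$detected,
                                 cost = points$testing_cost))
}
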