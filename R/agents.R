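#' Construct a negotiating agent specification
#'
#' Four bidder types share the same acceptance machinery but differ in how
#' they pick counteroffers and (for \code{"time"}) in how the threshold
#' falls:
#' \describe{
#'   \item{\code{"ga"}}{multi-state concession strategy plus a
#'     genetic-algorithm opponent model; counteroffers maximize the estimated
#'     opponent satisfaction among own offers at or above the threshold.}
#'   \item{\code{"distance"}}{same concession strategy but no opponent model;
#'     counteroffers minimize the normalized distance to the opponent's last
#'     offer.}
#'   \item{\code{"time"}}{purely time-dependent threshold
#'     \eqn{\theta_r = 1 - (1 - u_{min})\tau(r)}; distance-based bidding.}
#'   \item{\code{"oracle"}}{complete information: as \code{"ga"} but the true
#'     opponent profile replaces the learned estimate (no GA run).}
#' }
#'
#' @param type Agent type, see above.
#' @param strategy A \code{\link{strategy_params}} (or
#'   \code{\link{named_strategy}} name).
#' @param ga A \code{\link{ga_params}} (used by \code{type = "ga"}).
#' @param u_min Reservation satisfaction of the \code{"time"} agent; with the
#'   default 0 its threshold reaches 0 at the deadline, so it always accepts
#'   the final offer.
#' @param sample_budget Offers examined per proposal: grids at most this
#'   large are enumerated exhaustively, larger ones are sampled (seeded) with
#'   single-issue greedy repair.
#' @param bid_objective For \code{"ga"}/\code{"oracle"}: maximize the
#'   (estimated) opponent satisfaction alone (\code{"opponent"}, default) or
#'   the product of own and opponent satisfaction (\code{"product"}).
#' @return An object of class \code{"agent_spec"}.
#' @export
negotiation_agent <- function(type = c("ga", "distance", "time", "oracle"),
                              strategy = strategy_params(),
                              ga = ga_params(), u_min = 0,
                              sample_budget = 5000L,
                              bid_objective = c("opponent", "product")) {
  type <- match.arg(type)
  if (is.character(strategy)) strategy <- named_strategy(strategy)
  stopifnot(inherits(strategy, "strategy_params"), inherits(ga, "ga_params"),
            u_min >= 0, u_min <= 1, sample_budget >= 1)
  structure(list(type = type, strategy = strategy, ga = ga, u_min = u_min,
                 sample_budget = as.integer(sample_budget),
                 bid_objective = match.arg(bid_objective)),
            class = "agent_spec")
}

#' Candidate offers at or above a satisfaction threshold
#'
#' Returns grid offers whose own satisfaction reaches \code{theta}. When the
#' discretized solution space has at most \code{sample_budget} points it is
#' enumerated exhaustively; otherwise \code{sample_budget} offers are sampled
#' uniformly from the grid and offers below the threshold are repaired by
#' greedily resetting single issues (heaviest weight first) to the agent's
#' best grid value until they qualify. The agent's own best offer is always
#' included, so the set is never empty if any grid offer meets the threshold.
#'
#' @param profile The bidding agent's \code{\link{preference_profile}}.
#' @param theta Satisfaction threshold in \code{[0, 1]}.
#' @param sample_budget Maximum number of offers examined.
#' @return A list with \code{offers} (matrix, one offer per row) and
#'   \code{psi} (own satisfaction of each row).
#' @export
candidate_set <- function(profile, theta, sample_budget = 5000L) {
  domains <- profile$domains
  n <- length(domains)
  ks <- vapply(domains, function(d) d$k, 0L)
  grid_size <- prod(as.numeric(ks))
  tol <- 1e-9
  if (grid_size <= sample_budget) {
    vals <- lapply(domains, domain_values)
    X <- as.matrix(expand.grid(vals, KEEP.OUT.ATTRS = FALSE))
    colnames(X) <- NULL
  } else {
    # stratified sampling: half the budget uniform over the full grid, half
    # restricted to the agent's own support per issue -- uniform draws alone
    # almost never land inside the support on every issue at once, so the
    # acceptable region (and with it any finely conceding offer) would be
    # represented only by repaired, plateau-heavy offers
    n_half <- sample_budget %/% 2L
    X <- vapply(seq_len(n), function(i) {
      d <- domains[[i]]
      v <- domain_values(d)
      mf <- profile$memberships[[i]]
      inside <- v[v >= mf$a & v <= mf$d]
      if (length(inside) == 0L) inside <- v
      c(v[sample.int(d$k, n_half, replace = TRUE)],
        inside[sample.int(length(inside), sample_budget - n_half,
                          replace = TRUE)])
    }, numeric(sample_budget))
    if (is.null(dim(X))) X <- matrix(X, ncol = n)
    psi <- satisfaction_batch(profile, X)
    best <- own_best_offer(profile)
    ord <- order(profile$weights, decreasing = TRUE)
    for (i in ord) {
      bad <- psi < theta - tol
      if (!any(bad)) break
      X[bad, i] <- best[i]
      psi[bad] <- satisfaction_batch(profile, X[bad, , drop = FALSE])
    }
    X <- rbind(X, best)
    X <- X[!duplicated(X), , drop = FALSE]
  }
  psi <- satisfaction_batch(profile, X)
  keep <- psi >= theta - tol
  if (!any(keep)) {
    X <- matrix(own_best_offer(profile), nrow = 1L)
    psi <- satisfaction_batch(profile, X)
    keep <- TRUE
  }
  list(offers = X[keep, , drop = FALSE], psi = psi[keep])
}

# Deterministic tie-break: among rows of X attaining the max of `score`
# (within tol), prefer the offer closest to `anchor` (the opponent's last
# offer) when one is given -- trapezoid estimates are flat on their plateaus,
# so exact score ties over large regions are common and an arbitrary pick
# would discard what the offer history reveals -- then fall back to the
# lexicographically smallest offer (lowest issue index, lowest value).
argmax_offer <- function(X, score, tol = 1e-9, anchor = NULL, D = NULL,
                         own_psi = NULL) {
  top <- which(score >= max(score) - tol)
  if (length(top) > 1L && !is.null(anchor)) {
    sub <- X[top, , drop = FALSE]
    L2 <- sweep(abs(sweep(sub, 2L, anchor)), 2L, D, "/")^2
    dist <- sqrt(rowMeans(L2))
    top <- top[dist <= min(dist) + 1e-12]
  }
  if (length(top) > 1L) {
    sub <- X[top, , drop = FALSE]
    o <- do.call(order, as.data.frame(sub))
    top <- top[o[1L]]
  }
  X[top[1L], ]
}

#' Propose a counteroffer maximizing (estimated) opponent satisfaction
#'
#' The first proposal is the agent's own best offer. Thereafter the agent
#' searches its candidate set (own satisfaction at or above the current
#' threshold) for the offer with maximal satisfaction under the opponent
#' estimate; the complete-information variant passes the true opponent
#' profile as the estimate.
#'
#' @param profile Own \code{\link{preference_profile}}.
#' @param estimate_profile The estimated (or true) opponent profile.
#' @param theta Current acceptance threshold.
#' @param sample_budget See \code{\link{candidate_set}}.
#' @param bid_objective \code{"opponent"} (default) or \code{"product"}.
#' @param opp_last_offer Optional: the opponent's most recent offer, used to
#'   choose among shortlisted candidates (closest offer wins).
#' @param shortlist_tol Candidates within this margin of the maximal
#'   estimated satisfaction form the shortlist from which the behaviorally
#'   closest offer is picked; \code{0} gives the exact argmax. The default
#'   0.02 guards against the winner's curse of maximizing a noisy estimate.
#' @return The proposed offer (numeric vector).
#' @export
propose_model_based <- function(profile, estimate_profile, theta,
                                sample_budget = 5000L,
                                bid_objective = "opponent",
                                opp_last_offer = NULL,
                                shortlist_tol = 0.02) {
  cs <- candidate_set(profile, theta, sample_budget)
  score <- satisfaction_batch(estimate_profile, cs$offers)
  if (bid_objective == "product") score <- score * cs$psi
  argmax_offer(cs$offers, score, tol = shortlist_tol,
               anchor = opp_last_offer,
               D = domain_widths(profile$domains), own_psi = cs$psi)
}

#' Propose a counteroffer minimizing distance to the opponent's last offer
#'
#' Bidding rule of the model-free agents: among own offers at or above the
#' threshold, pick the one closest (normalized RMS distance) to the
#' opponent's most recent offer.
#'
#' @inheritParams propose_model_based
#' @param opp_last_offer The opponent's most recent offer.
#' @return The proposed offer.
#' @export
propose_distance_based <- function(profile, opp_last_offer, theta,
                                   sample_budget = 5000L) {
  cs <- candidate_set(profile, theta, sample_budget)
  D <- domain_widths(profile$domains)
  L2 <- sweep(abs(sweep(cs$offers, 2L, opp_last_offer)), 2L, D, "/")^2
  dist <- sqrt(rowMeans(L2))
  argmax_offer(cs$offers, -dist, tol = 1e-12)
}

#' Time-dependent acceptance threshold
#'
#' \eqn{\theta_r = 1 - (1 - u_{min})\,\tau(r)}: starts at \eqn{1 - \lambda}
#' before the first round and falls to \code{u_min} at the deadline.
#'
#' @param r Current round.
#' @param rmax Deadline.
#' @param params A \code{\link{strategy_params}} (supplies \eqn{\lambda},
#'   \eqn{\beta}).
#' @param u_min Reservation satisfaction (default 0).
#' @return The threshold at round \code{r}.
#' @export
threshold_time <- function(r, rmax, params, u_min = 0) {
  1 - (1 - u_min) * time_pressure(r, rmax, params)
}
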