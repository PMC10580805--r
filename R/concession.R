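#' Concession strategy parameters
#'
#' @param omega Concession exponent \eqn{\omega > 0}. Smaller values concede
#'   faster for bases in (0, 1): the reference settings are competition 1.2,
#'   collaboration 0.8, win-win 1.0 (see \code{\link{named_strategy}}).
#' @param lam Minimum initial concession \eqn{\lambda \in [0, 1]}; the time
#'   pressure at round 0.
#' @param beta_t Time concession rate \eqn{\beta \in (0, 1]}; smaller values
#'   keep time pressure low until close to the deadline.
#' @return An object of class \code{"strategy_params"}.
#' @export
strategy_params <- function(omega = 1, lam = 0.1, beta_t = 0.25) {
  if (!(omega > 0)) stop("omega must be > 0")
  if (!(lam >= 0 && lam <= 1)) stop("lam must lie in [0, 1]")
  if (!(beta_t > 0 && beta_t <= 1)) stop("beta_t must lie in (0, 1]")
  structure(list(omega = omega, lam = lam, beta_t = beta_t),
            class = "strategy_params")
}

#' Named concession strategies
#'
#' Binds \code{omega} for the three reference strategy types: competition
#' (1.2), collaboration (0.8) and win-win (1.0), with the shared defaults
#' \code{lam = 0.1}, \code{beta_t = 0.25}.
#'
#' @param name One of \code{"competition"}, \code{"collaboration"},
#'   \code{"win_win"}.
#' @param lam,beta_t Overrides for the shared parameters.
#' @return A \code{\link{strategy_params}} object.
#' @export
named_strategy <- function(name = c("competition", "collaboration", "win_win"),
                           lam = 0.1, beta_t = 0.25) {
  name <- match.arg(name)
  omega <- switch(name, competition = 1.2, collaboration = 0.8, win_win = 1.0)
  strategy_params(omega = omega, lam = lam, beta_t = beta_t)
}

#' Normalized distance between two offers
#'
#' Root-mean-square of per-issue domain-normalized absolute differences:
#' \eqn{G(A,B) = \sqrt{\frac{1}{n}\sum_i (|A_i-B_i|/D_i)^2}}, in \code{[0, 1]}.
#'
#' @param A,B Numeric offers aligned to \code{domains}.
#' @param domains List of \code{\link{issue_domain}}.
#' @return A distance in \code{[0, 1]}.
#' @export
offer_distance <- function(A, B, domains) {
  D <- domain_widths(domains)
  if (any(D <= 0)) stop("zero-width domain")
  L <- abs(A - B) / D
  sqrt(mean(L^2))
}

#' Opponent response state
#'
#' Measures how much the offer gap has closed relative to the opening gap:
#' \eqn{\sigma = 1 - (G(A_0,B_0) - G(A,B))/G(A_0,B_0) = G(A,B)/G(A_0,B_0)},
#' clamped to \code{[0, 1]}. \eqn{A_0, B_0} are the first own offer and first
#' counteroffer; \eqn{A, B} the latest pair. When the opening offers already
#' coincide (\eqn{G(A_0,B_0)=0}) the state is 0.
#'
#' @param A0,B0 Opening own offer and opening counteroffer.
#' @param A,B Latest own offer and latest incoming offer.
#' @param domains List of \code{\link{issue_domain}}.
#' @return \eqn{\sigma \in [0, 1]}.
#' @export
response_state <- function(A0, B0, A, B, domains) {
  g0 <- offer_distance(A0, B0, domains)
  if (g0 == 0) return(0)
  g <- offer_distance(A, B, domains)
  min(1, max(0, g / g0))
}

#' Internal state: own satisfaction and threshold tightness
#'
#' \eqn{\rho = \Psi(A)} is the satisfaction of the agent's latest own offer
#' and \eqn{\delta = 1 - (\rho - \theta)} its tightness against the
#' acceptance threshold currently in force.
#'
#' @param profile The agent's \code{\link{preference_profile}}.
#' @param last_own_offer The agent's most recent own offer.
#' @param theta_prev Acceptance threshold before this round's update.
#' @return A list with components \code{rho} and \code{delta}.
#' @export
internal_state <- function(profile, last_own_offer, theta_prev) {
  rho <- aggregate_satisfaction(profile, last_own_offer)
  list(rho = rho, delta = 1 - (rho - theta_prev))
}

#' Time pressure
#'
#' \eqn{\tau = \lambda + (1-\lambda)(r/r_{max})^{1/\beta}}: \eqn{\lambda} at
#' round 0, 1 at the deadline, monotone non-decreasing in between.
#'
#' @param r Current round, \code{0 <= r <= rmax}.
#' @param rmax Negotiation deadline (total number of offers allowed).
#' @param params A \code{\link{strategy_params}}.
#' @return \eqn{\tau \in [\lambda, 1]}.
#' @export
time_pressure <- function(r, rmax, params) {
  stopifnot(rmax >= 1)
  if (r < 0 || r > rmax) stop("round r must lie in [0, rmax]")
  params$lam + (1 - params$lam) * (r / rmax)^(1 / params$beta_t)
}

#' Per-round concession value
#'
#' Aggregates the three desire states (opponent response \eqn{\sigma}, own
#' satisfaction \eqn{\rho}, tightness \eqn{\delta}) and the time pressure
#' \eqn{\tau} into the amount by which the acceptance threshold drops this
#' round: \deqn{\Delta = \left(\frac{1 - (\sigma+\rho+\delta)/3 +
#' \tau}{4}\right)^{\omega},} with a negative base clamped to 0 before
#' exponentiation. When the opponent stalls (\eqn{\sigma=\rho=\delta=1}) this
#' reduces to \eqn{(\tau/4)^\omega}, so early-round concessions are small and
#' driven by the deadline.
#'
#' @param state List with numeric components \code{sigma}, \code{rho},
#'   \code{delta}, \code{tau}.
#' @param params A \code{\link{strategy_params}}.
#' @return Concession value \eqn{\Delta \ge 0}.
#' @export
concession_value <- function(state, params) {
  base <- (1 - (state$sigma + state$rho + state$delta) / 3 + state$tau) / 4
  max(0, base)^params$omega
}

#' Update the acceptance threshold
#'
#' \eqn{\theta_r = \max(0, \theta_{r-1} - \Delta)}; monotone non-increasing
#' over rounds.
#'
#' @param theta_prev Previous threshold.
#' @param delta_conc Concession value from \code{\link{concession_value}}.
#' @return The new threshold.
#' @export
update_threshold <- function(theta_prev, delta_conc) {
  max(0, theta_prev - delta_conc)
}

#' Accept-or-counter decision
#'
#' @param theta_r Acceptance threshold in force this round.
#' @param incoming_satisfaction Own satisfaction of the incoming offer.
#' @return \code{"Accept"} iff the satisfaction reaches the threshold
#'   (inclusive), else \code{"Offer"}.
#' @export
decide_action <- function(theta_r, incoming_satisfaction) {
  if (incoming_satisfaction >= theta_r) "Accept" else "Offer"
}
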