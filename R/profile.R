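#' Negotiation issue domain
#'
#' One negotiable attribute of a treatment plan, with a finite discretized
#' value set \code{lo, lo + step, ..., hi} (k = floor((hi - lo)/step) + 1
#' points). Satisfaction is still evaluated on real values, so offers off the
#' grid (e.g. a printed agreement value) score exactly.
#'
#' @param name Issue name.
#' @param lo,hi Domain bounds, \code{lo < hi}.
#' @param step Discretization resolution; defaults to \code{(hi - lo)/100}.
#' @return An object of class \code{"issue_domain"}.
#' @export
issue_domain <- function(name, lo, hi, step = (hi - lo) / 100) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!(lo < hi)) stop("issue domain requires lo < hi")
  if (!(step > 0)) stop("issue domain requires step > 0")
  k <- as.integer(floor((hi - lo) / step + 1e-9)) + 1L
  if (k < 2L) stop("issue domain must contain at least 2 grid values")
  structure(list(name = name, lo = lo, hi = hi, step = step, k = k,
                 width = hi - lo),
            class = "issue_domain")
}

# Grid of admissible values for one issue.
domain_values <- function(dom) {
  dom$lo + dom$step * seq.int(0L, dom$k - 1L)
}

domain_widths <- function(domains) vapply(domains, function(d) d$width, 0)

#' Fuzzy preference profile
#'
#' An agent's private utility: for each issue (in a fixed order) an importance
#' weight and a trapezoidal satisfaction function. Weights must sum to 1
#' within 1e-6 and are renormalized exactly; a larger deviation is an error.
#'
#' @param weights Numeric vector of per-issue weights.
#' @param memberships List of \code{\link{trapezoid_mf}}, one per issue.
#' @param domains List of \code{\link{issue_domain}}, one per issue. Each
#'   trapezoid's support \code{[a, d]} must lie inside its domain.
#' @return An object of class \code{"preference_profile"}.
#' @export
preference_profile <- function(weights, memberships, domains) {
  stopifnot(is.numeric(weights), is.list(memberships), is.list(domains))
  n <- length(domains)
  if (length(weights) != n || length(memberships) != n) {
    stop("weights, memberships and domains must have one entry per issue")
  }
  if (any(weights < 0)) stop("weights must be non-negative")
  s <- sum(weights)
  if (abs(s - 1) > 1e-6) {
    stop(sprintf("weights must sum to 1 (got %.8f)", s))
  }
  weights <- weights / s
  for (i in seq_len(n)) {
    mf <- memberships[[i]]
    if (!inherits(mf, "trapezoid_mf")) stop("memberships must be trapezoid_mf")
    dom <- domains[[i]]
    if (mf$a < dom$lo - 1e-9 || mf$d > dom$hi + 1e-9) {
      stop(sprintf("trapezoid support of issue '%s' outside its domain",
                   dom$name))
    }
  }
  structure(list(weights = weights, memberships = memberships,
                 domains = domains, n = n),
            class = "preference_profile")
}

#' Aggregated fuzzy satisfaction of an offer
#'
#' The agent's utility for an offer: the weighted sum of per-issue trapezoid
#' memberships, \eqn{\Psi(O) = \sum_i w_i \mu_i(v_i)}. With all plateau
#' heights at 1 the result lies in \code{[0, 1]}.
#'
#' @param profile A \code{\link{preference_profile}}.
#' @param offer Numeric vector, one value per issue in profile order.
#' @return A single satisfaction value.
#' @examples
#' sc <- table2_fixture()
#' aggregate_satisfaction(sc$pa, c(5.16, 9, 0.158, 0.108, 9))  # 0.76452
#' @export
aggregate_satisfaction <- function(profile, offer) {
  stopifnot(inherits(profile, "preference_profile"))
  if (length(offer) != profile$n) {
    stop("offer length must equal the number of issues")
  }
  s <- 0
  for (i in seq_len(profile$n)) {
    s <- s + profile$weights[i] * eval_membership(profile$memberships[[i]],
                                                  offer[i])
  }
  s
}

# Vectorized satisfaction of many offers (rows of X) under one profile.
satisfaction_batch <- function(profile, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  s <- numeric(nrow(X))
  for (i in seq_len(profile$n)) {
    s <- s + profile$weights[i] * eval_membership(profile$memberships[[i]],
                                                  X[, i])
  }
  s
}

# Offer with maximal own satisfaction on the discretized grid; ties broken by
# the lowest value per issue (and hence lexicographically over issues).
own_best_offer <- function(profile) {
  vapply(seq_len(profile$n), function(i) {
    v <- domain_values(profile$domains[[i]])
    mu <- eval_membership(profile$memberships[[i]], v)
    v[which.max(mu)]  # which.max returns the first (lowest-value) maximum
  }, 0)
}

validate_offer <- function(offer, domains) {
  stopifnot(is.numeric(offer), length(offer) == length(domains))
  for (i in seq_along(domains)) {
    if (offer[i] < domains[[i]]$lo - 1e-9 || offer[i] > domains[[i]]$hi + 1e-9)
      stop(sprintf("offer value %g outside domain '%s'", offer[i],
                   domains[[i]]$name))
  }
  invisible(offer)
}

#' @export
print.preference_profile <- function(x, ...) {
  cat(sprintf("<preference_profile: %d issues>\n", x$n))
  for (i in seq_len(x$n)) {
    mf <- x$memberships[[i]]
    cat(sprintf("  %-14s w=%.3f  (%g, %g, %g, %g) beta=%g\n",
                x$domains[[i]]$name, x$weights[i], mf$a, mf$b, mf$c, mf$d,
                mf$beta))
  }
  invisible(x)
}
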