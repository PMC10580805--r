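# Small scenarios built in code for brute-force-checkable tests.

# Two issues, 11 grid points each (121 offers): exhaustively enumerable.
two_issue_scenario <- function() {
  domains <- list(issue_domain("x", 0, 10, step = 1),
                  issue_domain("y", 0, 10, step = 1))
  pa <- preference_profile(
    c(0.6, 0.4),
    list(trapezoid_mf(0, 2, 4, 8), trapezoid_mf(1, 3, 5, 9)),
    domains)
  da <- preference_profile(
    c(0.5, 0.5),
    list(trapezoid_mf(2, 6, 8, 10), trapezoid_mf(3, 6, 7, 10)),
    domains)
  scenario(domains, pa, da, label = "two-issue-test")
}

# One issue with a full-domain support for hand-computable GA fitness.
one_issue_profile <- function(a, b, c, d, domains = NULL) {
  if (is.null(domains)) domains <- list(issue_domain("x", 0, 10, step = 0.5))
  preference_profile(1, list(trapezoid_mf(a, b, c, d)), domains)
}

random_trapezoid <- function(lo = 0, hi = 10) {
  p <- sort(stats::runif(4, lo, hi))
  trapezoid_mf(p[1], p[2], p[3], p[4], beta = stats::runif(1, 0.2, 1))
}

random_profile <- function(domains, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(domains)
  w <- stats::runif(n)
  mfs <- lapply(domains, function(d) random_trapezoid(d$lo, d$hi))
  preference_profile(w / sum(w), mfs, domains)
}

# Independent re-implementation of the trapezoid formula used as a
# dense-grid oracle: direct piecewise translation, no shared code path.
trapezoid_oracle <- function(a, b, c, d, beta, x) {
  sapply(x, function(v) {
    if (v >= b && v <= c) return(beta)             # plateau (checked first)
    if (v <= a || v >= d) return(0)
    if (v < b) return(beta * (1 - ((v - b) / (b - a))^2))
    beta * (1 - ((v - c) / (c - d))^2)
  })
}
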