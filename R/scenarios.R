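#' Construct a negotiation scenario
#'
#' @param domains Ordered list of \code{\link{issue_domain}}.
#' @param pa,da \code{\link{preference_profile}}s over the same domains.
#' @param label Optional scenario label.
#' @return An object of class \code{"scenario"}.
#' @export
scenario <- function(domains, pa, da, label = NULL) {
  stopifnot(inherits(pa, "preference_profile"),
            inherits(da, "preference_profile"),
            pa$n == length(domains), da$n == length(domains))
  structure(list(domains = domains, pa = pa, da = da, label = label),
            class = "scenario")
}

#' The five-issue worked-example scenario
#'
#' The questionnaire-derived doctor/patient preference fixture used
#' throughout the documentation and tests: five treatment-plan issues (cost
#' in thousands of RMB, effectiveness rank, side-effect probability, risk
#' probability, convenience rank) with printed trapezoids and weights, all
#' plateau heights 1.
#'
#' @param step_fraction Grid resolution as a fraction of each domain width
#'   (default 1/100).
#' @return A \code{"scenario"}.
#' @examples
#' sc <- table2_fixture()
#' aggregate_satisfaction(sc$da, c(5.16, 9, 0.158, 0.108, 9))  # exactly 0.75
#' @export
table2_fixture <- function(step_fraction = 1 / 100) {
  dom <- function(name, lo, hi) issue_domain(name, lo, hi,
                                             step = (hi - lo) * step_fraction)
  domains <- list(dom("Cost", 0, 8), dom("Effective", 1, 10),
                  dom("Side-effects", 0, 1), dom("Risk", 0, 1),
                  dom("Convenience", 1, 10))
  tz <- function(a, b, c, d) trapezoid_mf(a, b, c, d, beta = 1)
  pa <- preference_profile(
    weights = c(0.2, 0.1, 0.2, 0.3, 0.2),
    memberships = list(tz(2, 3.5, 4, 6), tz(8, 9, 10, 10),
                       tz(0, 0.05, 0.1, 0.2), tz(0, 0.02, 0.05, 0.15),
                       tz(8, 9, 10, 10)),
    domains = domains)
  da <- preference_profile(
    weights = c(0.25, 0.15, 0.3, 0.2, 0.1),
    memberships = list(tz(4, 5, 7, 8), tz(6, 7, 8, 9),
                       tz(0.1, 0.15, 0.2, 0.25), tz(0.05, 0.1, 0.15, 0.2),
                       tz(6, 7, 8, 9)),
    domains = domains)
  scenario(domains, pa, da, label = "five-issue-worked-example")
}

#' Synthetic scenario generator configuration
#'
#' Emulates questionnaire-style preference data: per issue each party has a
#' trapezoid whose support covers \code{support_fraction} of the domain and
#' whose plateau covers \code{plateau_fraction} of the support; the
#' \code{overlap} parameter moves the two parties' plateaus from coincident
#' (1) to maximally separated (0). Weights are Dirichlet-distributed with
#' concentration \code{weight_concentration}.
#'
#' @param n_issues Number of issues.
#' @param plateau_fraction Plateau width relative to the support, in (0, 1).
#' @param support_fraction Support width relative to the domain, in (0, 1].
#' @param overlap Expected alignment of the two plateaus in [0, 1]
#'   (0 adversarial, 1 identical preferences).
#' @param weight_concentration Dirichlet concentration of the sampled
#'   weights (> 0); 1 is uniform on the simplex.
#' @param domain_lo,domain_hi Issue domain bounds (shared by all issues).
#' @param step_fraction Grid resolution as a fraction of the domain width.
#' @return An object of class \code{"generator_config"}.
#' @export
generator_config <- function(n_issues = 5L, plateau_fraction = 0.25,
                             support_fraction = 0.6, overlap = 0.5,
                             weight_concentration = 1,
                             domain_lo = 0, domain_hi = 10,
                             step_fraction = 1 / 100) {
  stopifnot(n_issues >= 1,
            plateau_fraction > 0, plateau_fraction < 1,
            support_fraction > 0, support_fraction <= 1,
            overlap >= 0, overlap <= 1, weight_concentration > 0,
            domain_lo < domain_hi)
  structure(list(n_issues = as.integer(n_issues),
                 plateau_fraction = plateau_fraction,
                 support_fraction = support_fraction, overlap = overlap,
                 weight_concentration = weight_concentration,
                 domain_lo = domain_lo, domain_hi = domain_hi,
                 step_fraction = step_fraction),
            class = "generator_config")
}

#' Sample a synthetic scenario
#'
#' Per issue: the two plateau centres are placed a distance
#' \code{(1 - overlap) * (D - w)} apart (jittered by about 10 percent,
#' \code{w} the plateau width), at a uniformly drawn location; each party's
#' support is positioned around its plateau with a randomly drawn shoulder
#' facing the opponent, and supports are nudged toward each other when
#' needed so that with \code{overlap > 0} the supports of every issue
#' intersect (hence some offer satisfies both parties with positive
#' satisfaction). Weights are Dirichlet draws. Seed-deterministic.
#'
#' @param config A \code{\link{generator_config}}.
#' @param seed Optional integer seed.
#' @return A \code{"scenario"}.
#' @export
sample_scenario <- function(config = generator_config(), seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(seed)) set.seed(seed)
  lo <- config$domain_lo; hi <- config$domain_hi
  D <- hi - lo
  S <- config$support_fraction * D
  w_pl <- config$plateau_fraction * S
  if (S > D + 1e-9) stop("infeasible generator config: support wider than domain")
  n <- config$n_issues
  domains <- lapply(seq_len(n), function(i) {
    issue_domain(sprintf("issue_%d", i), lo, hi, step = D * config$step_fraction)
  })
  shoulder <- S - w_pl  # total shoulder budget per party

  side_mf <- function(center, facing, dir) {
    # dir = +1 when the opponent lies to the right of this party's plateau
    b <- center - w_pl / 2
    c <- center + w_pl / 2
    facing <- min(facing, shoulder)
    back <- shoulder - facing
    if (dir > 0) { a <- b - back; d <- c + facing }
    else { a <- b - facing; d <- c + back }
    # truncate at the domain bounds: the back shoulder may be cut short near
    # an edge, which leaves the region between the plateaus untouched
    a <- max(a, lo); d <- min(d, hi)
    if (a > b || d < c) stop("infeasible generator config: cannot place support")
    trapezoid_mf(a, b, c, d, beta = 1)
  }

  mfs_pa <- vector("list", n); mfs_da <- vector("list", n)
  for (i in seq_len(n)) {
    u <- stats::runif(1, 0.9, 1.1)
    d_c <- min((1 - config$overlap) * (D - w_pl) * u, D - w_pl)
    mid_lo <- lo + w_pl / 2 + d_c / 2
    mid_hi <- hi - w_pl / 2 - d_c / 2
    M <- stats::runif(1, mid_lo, mid_hi)
    s <- sample(c(-1, 1), 1L)
    c_pa <- M - s * d_c / 2
    c_da <- M + s * d_c / 2
    # Facing shoulders scale with the plateau gap: the ratio f/gap sets how
    # much satisfaction each party can reach between the plateaus (the
    # midpoint satisfaction is 1 - (gap/2f)^2), i.e. the hardness of the
    # issue. The draw is scale-invariant in the gap, so issue hardness is
    # stable across separations; the cap is the shoulder budget S - w.
    gap <- max(d_c - w_pl, w_pl)
    f_pa <- min(stats::runif(1, 0.68, 0.74) * gap, shoulder)
    f_da <- min(stats::runif(1, 0.68, 0.74) * gap, shoulder)
    if (config$overlap > 0 && f_pa + f_da <= max(0, d_c - w_pl)) {
      stop("infeasible generator config: supports cannot overlap")
    }
    mfs_pa[[i]] <- side_mf(c_pa, f_pa, dir = s)
    mfs_da[[i]] <- side_mf(c_da, f_da, dir = -s)
  }
  # Both parties draw importance weights around a shared issue-salience
  # base: doctor and patient in shared decision-making broadly agree on
  # which issues matter (cf. the worked fixture, whose two weight vectors
  # correlate positively) while disagreeing on the preferred values.
  dirichlet <- function() {
    g <- stats::rgamma(n, shape = config$weight_concentration)
    if (sum(g) <= 0) g <- rep(1, n)
    g / sum(g)
  }
  base_w <- dirichlet()
  mix_w <- function() {
    w <- 0.7 * base_w + 0.3 * dirichlet()
    w / sum(w)
  }
  pa <- preference_profile(mix_w(), mfs_pa, domains)
  da <- preference_profile(mix_w(), mfs_da, domains)
  scenario(domains, pa, da, label = sprintf("synthetic-n%d", n))
}

#' Write a scenario to JSON
#'
#' The on-disk format lists the ordered issues (\code{name, lo, hi, step})
#' and, for each party, the weight vector and the trapezoid rows
#' \code{[a, b, c, d, beta]}.
#'
#' @param sc A \code{"scenario"}.
#' @param path Output file path.
#' @export
write_scenario <- function(sc, path) {
  enc_profile <- function(p) {
    list(weights = p$weights,
         membership = lapply(p$memberships,
                             function(m) c(m$a, m$b, m$c, m$d, m$beta)))
  }
  obj <- list(label = sc$label,
              issues = lapply(sc$domains, function(d) {
                list(name = d$name, lo = d$lo, hi = d$hi, step = d$step)
              }),
              pa = enc_profile(sc$pa), da = enc_profile(sc$da))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a scenario from JSON
#'
#' @param path Path to a file written by \code{\link{write_scenario}}.
#' @return A \code{"scenario"}.
#' @export
read_scenario <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  domains <- lapply(obj$issues, function(d) {
    issue_domain(d$name, d$lo, d$hi, d$step)
  })
  dec_profile <- function(p) {
    rows <- p$membership
    if (is.matrix(rows)) rows <- asplit(rows, 1)  # jsonlite may simplify
    mfs <- lapply(rows, function(v) {
      v <- as.numeric(v)
      trapezoid_mf(v[1], v[2], v[3], v[4], beta = v[5])
    })
    preference_profile(unlist(p$weights), mfs, domains)
  }
  scenario(domains, dec_profile(obj$pa), dec_profile(obj$da),
           label = obj$label)
}
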