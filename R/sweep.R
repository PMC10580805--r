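# Deterministic 31-bit sub-seed from a master seed and index coordinates, so
# batches are reproducible and every roster entry sees identical scenarios.
derive_seed <- function(master, ...) {
  v <- c(master, ...)
  s <- 0
  for (x in v) s <- (s * 1000003 + (as.numeric(x) %% 97561)) %% 2147483629
  as.integer(s) + 1L
}

#' Default agent rosters for the experiment sweeps
#'
#' \code{"deadline"} and \code{"issues"} compare the time-dependent baseline
#' with the three concession strategy types of the model-based agent
#' (self-play); \code{"information"} compares the opponent-model agent, the
#' model-free distance bidder and the complete-information oracle, all with
#' the collaboration strategy.
#'
#' @param kind Sweep kind.
#' @return Named list of \code{\link{negotiation_agent}} specs.
#' @export
default_roster <- function(kind = c("deadline", "issues", "information")) {
  kind <- match.arg(kind)
  if (kind == "information") {
    list(complete_info = negotiation_agent("oracle",
                                           named_strategy("collaboration")),
         ga = negotiation_agent("ga", named_strategy("collaboration")),
         distance = negotiation_agent("distance",
                                      named_strategy("collaboration")))
  } else {
    list(time = negotiation_agent("time", named_strategy("collaboration")),
         collaboration = negotiation_agent("ga",
                                           named_strategy("collaboration")),
         win_win = negotiation_agent("ga", named_strategy("win_win")),
         competition = negotiation_agent("ga", named_strategy("competition")))
  }
}

#' Run an experiment sweep
#'
#' For each sweep point, generates \code{T_all} synthetic scenarios and runs
#' every roster agent in self-play on the same scenarios and negotiation
#' seeds (matched-seed discipline), then reports one metrics row per
#' (sweep point, agent).
#'
#' @param kind \code{"deadline"} (varies the deadline at fixed issue count),
#'   \code{"issues"} (varies the issue count at a fixed deadline) or
#'   \code{"information"} (deadline sweep with the information-environment
#'   roster).
#' @param gen A \code{\link{generator_config}}; its \code{n_issues} is
#'   overridden per point in the issues sweep.
#' @param roster Named list of \code{\link{negotiation_agent}} specs;
#'   defaults to \code{\link{default_roster}(kind)}.
#' @param deadlines Deadlines for the deadline/information sweeps.
#' @param issue_counts Issue counts for the issues sweep.
#' @param rmax_issues Fixed deadline of the issues sweep.
#' @param T_all Scenarios per sweep point (desk scale; the reference protocol
#'   uses 200).
#' @param seed Master seed.
#' @param progress Print one line per sweep point.
#' @return Data frame with columns \code{sweep_var}, \code{value},
#'   \code{agent}, \code{AJS}, \code{ANR}, \code{NSR}, \code{T_suc},
#'   \code{T_all}.
#' @export
run_sweep <- function(kind = c("deadline", "issues", "information"),
                      gen = generator_config(),
                      roster = default_roster(kind),
                      deadlines = c(10, 15, 20, 25, 30),
                      issue_counts = c(1, 3, 5, 7, 9),
                      rmax_issues = 20, T_all = 50, seed = 1,
                      progress = FALSE) {
  kind <- match.arg(kind)
  points <- if (kind == "issues") issue_counts else deadlines
  out <- list()
  for (p_i in seq_along(points)) {
    p <- points[p_i]
    g <- gen
    rmax <- if (kind == "issues") rmax_issues else p
    if (kind == "issues") {
      g <- generator_config(n_issues = p,
                            plateau_fraction = gen$plateau_fraction,
                            support_fraction = gen$support_fraction,
                            overlap = gen$overlap,
                            weight_concentration = gen$weight_concentration,
                            domain_lo = gen$domain_lo,
                            domain_hi = gen$domain_hi,
                            step_fraction = gen$step_fraction)
    }
    scens <- lapply(seq_len(T_all), function(i) {
      sample_scenario(g, seed = derive_seed(seed, p_i, i))
    })
    for (a_i in seq_along(roster)) {
      nm <- names(roster)[a_i]
      spec <- roster[[a_i]]
      ts <- lapply(seq_len(T_all), function(i) {
        run_negotiation(scens[[i]], spec, spec, rmax = rmax,
                        seed = derive_seed(seed, p_i, i, 7919))
      })
      mt <- compute_metrics(ts)
      out[[length(out) + 1L]] <- cbind(
        data.frame(sweep_var = kind, value = p, agent = nm), mt)
      if (progress) {
        message(sprintf("%s=%s %-14s NSR=%.2f AJS=%.3f ANR=%.2f",
                        kind, p, nm, mt$NSR, mt$AJS, mt$ANR))
      }
    }
  }
  do.call(rbind, out)
}

#' Plot sweep metrics
#'
#' Base-graphics line plot of one metric against the sweep variable, one line
#' per agent.
#'
#' @param df Output of \code{\link{run_sweep}}.
#' @param metric One of \code{"AJS"}, \code{"ANR"}, \code{"NSR"}.
#' @param ... Passed to \code{matplot}.
#' @export
plot_metrics <- function(df, metric = c("AJS", "ANR", "NSR"), ...) {
  metric <- match.arg(metric)
  agents <- unique(df$agent)
  xs <- sort(unique(df$value))
  Y <- vapply(agents, function(a) {
    d <- df[df$agent == a, ]
    d[[metric]][match(xs, d$value)]
  }, numeric(length(xs)))
  graphics::matplot(xs, Y, type = "b", pch = seq_along(agents), lty = 1,
                    xlab = unique(df$sweep_var)[1], ylab = metric, ...)
  graphics::legend("topright", legend = agents, pch = seq_along(agents),
                   col = seq_along(agents), lty = 1, bty = "n")
  invisible(Y)
}
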