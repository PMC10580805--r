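#' Run one alternating-offers negotiation
#'
#' Plays the stacked alternating-offers protocol between a patient-side (PA)
#' and doctor-side (DA) agent on a scenario. One round is one offer by one
#' side. The receiver of each offer updates its states (opponent response,
#' own satisfaction, tightness, time pressure), concedes, and accepts when
#' its satisfaction of the incoming offer reaches the updated threshold;
#' otherwise it counters (agents with an opponent model re-learn the
#' estimate from the full accumulated history first). Failure is declared
#' when round \code{rmax} completes without acceptance. Fully reproducible
#' from \code{seed}.
#'
#' @param scenario A \code{"scenario"} (see \code{\link{table2_fixture}},
#'   \code{\link{sample_scenario}}).
#' @param agent_pa,agent_da \code{\link{negotiation_agent}} specifications.
#' @param rmax Deadline: total number of offers allowed (\code{>= 1}).
#' @param first_mover \code{"PA"} (default) or \code{"DA"}.
#' @param seed Optional integer seed.
#' @return A list of class \code{"transcript"}: per-round log (data frame
#'   with round, proposer, receiver threshold, receiver satisfaction,
#'   action), the offers matrix, outcome (\code{"Agreement"} or
#'   \code{"Failure"}), the agreement offer and both final satisfactions when
#'   successful, and bookkeeping (\code{rmax}, \code{seed}, per-agent
#'   threshold histories).
#' @export
run_negotiation <- function(scenario, agent_pa, agent_da, rmax,
                            first_mover = c("PA", "DA"), seed = NULL) {
  stopifnot(inherits(scenario, "scenario"), rmax >= 1,
            inherits(agent_pa, "agent_spec"), inherits(agent_da, "agent_spec"))
  first_mover <- match.arg(first_mover)
  if (!is.null(seed)) set.seed(seed)
  domains <- scenario$domains
  n <- length(domains)

  new_state <- function(spec, profile, opp_profile) {
    list(spec = spec, profile = profile,
         true_opp = opp_profile,                  # used by type "oracle" only
         best = own_best_offer(profile),
         theta = NA_real_,                        # set below
         own = matrix(numeric(0), 0, n), opp = matrix(numeric(0), 0, n),
         ledger = new_concession_ledger(domains),
         estimate = NULL, ga_pop = NULL,
         theta_hist = numeric(0))
  }
  ag <- list(PA = new_state(agent_pa, scenario$pa, scenario$da),
             DA = new_state(agent_da, scenario$da, scenario$pa))
  for (id in c("PA", "DA")) {
    ag[[id]]$theta <- aggregate_satisfaction(ag[[id]]$profile, ag[[id]]$best)
  }

  # own offer paired with the j-th received counteroffer for the GA history:
  # the offer standing when B_j arrived (own best before the first proposal).
  paired_history <- function(st, moved_first) {
    N <- nrow(st$opp)
    own <- if (moved_first) {
      st$own[seq_len(N), , drop = FALSE]
    } else {
      rbind(st$best, st$own)[seq_len(N), , drop = FALSE]
    }
    list(own = own, opp = st$opp)
  }

  proposer <- first_mover
  offers <- matrix(NA_real_, rmax, n)
  log <- data.frame(round = integer(0), proposer = character(0),
                    threshold = numeric(0), psi_in = numeric(0),
                    action = character(0))
  outcome <- "Failure"
  agreement <- NULL

  for (r in seq_len(rmax)) {
    prop <- ag[[proposer]]
    receiver <- setdiff(c("PA", "DA"), proposer)
    rec <- ag[[receiver]]

    offer <- if (nrow(prop$own) == 0L) {
      prop$best
    } else {
      switch(prop$spec$type,
        ga = propose_model_based(prop$profile, prop$estimate$profile,
                                 prop$theta, prop$spec$sample_budget,
                                 prop$spec$bid_objective,
                                 prop$opp[nrow(prop$opp), ]),
        oracle = propose_model_based(prop$profile, prop$true_opp, prop$theta,
                                     prop$spec$sample_budget,
                                     prop$spec$bid_objective,
                                     prop$opp[nrow(prop$opp), ]),
        propose_distance_based(prop$profile, prop$opp[nrow(prop$opp), ],
                               prop$theta, prop$spec$sample_budget))
    }
    offers[r, ] <- offer
    prop$own <- rbind(prop$own, offer)
    ag[[proposer]] <- prop

    # receiver ingests the offer
    if (nrow(rec$opp) >= 1L) {
      rec$ledger <- update_ledger(rec$ledger, rec$opp[nrow(rec$opp), ], offer)
    }
    rec$opp <- rbind(rec$opp, offer)

    # concession
    if (rec$spec$type == "time") {
      theta_r <- threshold_time(r, rmax, rec$spec$strategy, rec$spec$u_min)
      theta_r <- min(theta_r, rec$theta)  # keep monotone under any u_min
    } else {
      A <- if (nrow(rec$own) > 0L) rec$own[nrow(rec$own), ] else rec$best
      A0 <- if (nrow(rec$own) > 0L) rec$own[1L, ] else rec$best
      B0 <- rec$opp[1L, ]
      st <- internal_state(rec$profile, A, rec$theta)
      state <- list(sigma = response_state(A0, B0, A, offer, domains),
                    rho = st$rho, delta = st$delta,
                    tau = time_pressure(r, rmax, rec$spec$strategy))
      theta_r <- update_threshold(rec$theta,
                                  concession_value(state, rec$spec$strategy))
    }
    rec$theta <- theta_r
    rec$theta_hist <- c(rec$theta_hist, theta_r)

    psi_in <- aggregate_satisfaction(rec$profile, offer)
    action <- decide_action(theta_r, psi_in)
    log <- rbind(log, data.frame(round = r, proposer = proposer,
                                 threshold = theta_r, psi_in = psi_in,
                                 action = action))
    if (action == "Accept") {
      ag[[receiver]] <- rec
      outcome <- "Agreement"
      agreement <- offer
      break
    }
    # counteroffer preparation: refresh the opponent model
    if (rec$spec$type == "ga" && r < rmax) {
      hist <- paired_history(rec, moved_first = (receiver == first_mover))
      res <- ga_evolve(rec$profile, domains, hist, rec$spec$ga,
                       init_pop = if (rec$spec$ga$warm_start) rec$ga_pop)
      w_c <- concession_weights(rec$ledger)
      w <- refine_weights(res$weights, w_c)
      est_profile <- preference_profile(w, res$best$memberships, domains)
      rec$estimate <- list(profile = est_profile, ga_profile = res$best,
                           w_g = res$weights, w_c = w_c, w_refined = w,
                           fitness = res$fitness)
      rec$ga_pop <- res$population
    }
    ag[[receiver]] <- rec
    proposer <- receiver
  }

  n_rounds <- nrow(log)
  psi_pa <- if (!is.null(agreement))
    aggregate_satisfaction(scenario$pa, agreement) else NA_real_
  psi_da <- if (!is.null(agreement))
    aggregate_satisfaction(scenario$da, agreement) else NA_real_
  structure(list(label = scenario$label, first_mover = first_mover,
                 rmax = rmax, seed = seed,
                 rounds = log, offers = offers[seq_len(n_rounds), ,
                                               drop = FALSE],
                 outcome = outcome, agreement = agreement,
                 psi_pa = psi_pa, psi_da = psi_da, n_rounds = n_rounds,
                 theta_pa = ag$PA$theta_hist, theta_da = ag$DA$theta_hist,
                 estimate_pa = strip_estimate(ag$PA$estimate),
                 estimate_da = strip_estimate(ag$DA$estimate)),
            class = "transcript")
}

# Final opponent estimate without the heavyweight profile objects: the
# GA-learned, concession-derived and refined weight vectors plus fitness.
strip_estimate <- function(est) {
  if (is.null(est)) return(NULL)
  est[c("w_g", "w_c", "w_refined", "fitness")]
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("<transcript: %s in %d/%d rounds", x$outcome, x$n_rounds,
              x$rmax))
  if (x$outcome == "Agreement") {
    cat(sprintf("; Psi_PA=%.3f Psi_DA=%.3f", x$psi_pa, x$psi_da))
  }
  cat(">\n")
  invisible(x)
}

#' Outcome metrics over a batch of transcripts
#'
#' Average joint satisfaction (AJS, the mean over successful negotiations of
#' the two final satisfactions summed), average negotiation round (ANR) and
#' negotiation success rate (NSR). When no negotiation succeeds the reporting
#' convention is AJS = 0 and ANR = \code{rmax}.
#'
#' @param transcripts Non-empty list of \code{"transcript"} objects.
#' @return A one-row data frame with columns \code{AJS}, \code{ANR},
#'   \code{NSR}, \code{T_suc}, \code{T_all}.
#' @export
compute_metrics <- function(transcripts) {
  if (length(transcripts) == 0L) stop("transcript list must be non-empty")
  suc <- vapply(transcripts, function(t) t$outcome == "Agreement", TRUE)
  T_all <- length(transcripts)
  T_suc <- sum(suc)
  rmax <- max(vapply(transcripts, function(t) t$rmax, 0))
  if (T_suc == 0L) {
    ajs <- 0
    anr <- rmax
  } else {
    ajs <- mean(vapply(transcripts[suc], function(t) t$psi_pa + t$psi_da, 0))
    anr <- mean(vapply(transcripts[suc], function(t) t$n_rounds, 0))
  }
  data.frame(AJS = ajs, ANR = anr, NSR = T_suc / T_all,
             T_suc = T_suc, T_all = T_all)
}

#' Serialize a transcript to JSON
#'
#' @param transcript A \code{"transcript"}.
#' @param path Output file path.
#' @export
write_transcript <- function(transcript, path) {
  out <- transcript
  out$rounds <- as.list(out$rounds)
  jsonlite::write_json(unclass(out), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
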