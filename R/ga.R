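#' Genetic-algorithm parameters for opponent-preference learning
#'
#' @param population_size Number of candidate profiles \code{m >= 2}.
#' @param max_iteration Number of generations before termination.
#' @param mutation_rate Per-child probability that one uniformly chosen
#'   issue's genes (weight, plateau breakpoints) are redrawn at random.
#' @param elite_rate Fraction of the population copied unchanged into the
#'   next generation; the elite count \code{round(elite_rate * m)} must be
#'   smaller than \code{m}.
#' @param potential_stock_rate Probability that a crossover parent is drawn
#'   uniformly from the previous population instead of from the selected
#'   (elite + roulette) pool, so low-fitness "potential stock" individuals
#'   keep a chance to reproduce.
#' @param mutation_granularity \code{"issue"} redraws one whole issue per
#'   mutated child (default); \code{"gene"} applies an independent Bernoulli
#'   redraw per gene.
#' @param warm_start If \code{TRUE}, an agent reuses its previous round's
#'   final population as the starting point; default is a fresh random
#'   population each round.
#' @return An object of class \code{"ga_params"}.
#' @export
ga_params <- function(population_size = 100L, max_iteration = 50L,
                      mutation_rate = 0.5, elite_rate = 0.1,
                      potential_stock_rate = 0.1,
                      mutation_granularity = c("issue", "gene"),
                      warm_start = FALSE) {
  stopifnot(population_size >= 2, max_iteration >= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            elite_rate >= 0, elite_rate < 1,
            potential_stock_rate >= 0, potential_stock_rate <= 1)
  e <- round(elite_rate * population_size)
  if (e >= population_size) stop("elite count must be smaller than m")
  structure(list(population_size = as.integer(population_size),
                 max_iteration = as.integer(max_iteration),
                 mutation_rate = mutation_rate, elite_rate = elite_rate,
                 potential_stock_rate = potential_stock_rate,
                 mutation_granularity = match.arg(mutation_granularity),
                 warm_start = isTRUE(warm_start)),
            class = "ga_params")
}

# A population is stored column-per-issue in three m x n matrices (weights,
# plateau starts b, plateau ends c) plus the fixed per-issue supports a, d
# inherited from the learning agent; beta is fixed to 1.
new_ga_population <- function(w, b, c, a, d) {
  structure(list(w = w, b = b, c = c, a = a, d = d,
                 m = nrow(w), n = ncol(w)),
            class = "ga_population")
}

#' Initialize a random candidate population
#'
#' Each individual draws per-issue weights uniformly in (0, 1) (renormalized
#' to sum 1) and plateau breakpoints \code{b <= c} uniformly inside the
#' learning agent's own support \code{[a, d]}; \code{a}, \code{d} are copied
#' from the agent's own profile and the plateau height is fixed to 1.
#'
#' @param own_profile The learning agent's \code{\link{preference_profile}}.
#' @param domains List of \code{\link{issue_domain}} (issue order reference).
#' @param params A \code{\link{ga_params}}.
#' @param seed Optional integer seed for reproducible initialization.
#' @return A \code{"ga_population"} of \code{population_size} candidates.
#' @export
ga_init_population <- function(own_profile, domains, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- params$population_size
  n <- own_profile$n
  a <- vapply(own_profile$memberships, function(mf) mf$a, 0)
  d <- vapply(own_profile$memberships, function(mf) mf$d, 0)
  w <- matrix(stats::runif(m * n), m, n)
  w <- w / rowSums(w)
  u1 <- matrix(stats::runif(m * n), m, n)
  u2 <- matrix(stats::runif(m * n), m, n)
  A <- matrix(a, m, n, byrow = TRUE)
  D <- matrix(d, m, n, byrow = TRUE)
  x1 <- A + u1 * (D - A)
  x2 <- A + u2 * (D - A)
  new_ga_population(w = w, b = pmin(x1, x2), c = pmax(x1, x2), a = a, d = d)
}

# Extract candidate j of a population as a preference_profile.
ga_candidate <- function(pop, j, domains) {
  mfs <- lapply(seq_len(pop$n), function(i) {
    trapezoid_mf(pop$a[i], pop$b[j, i], pop$c[j, i], pop$d[i], beta = 1)
  })
  preference_profile(pop$w[j, ], mfs, domains)
}

#' Fitness of a candidate opponent profile
#'
#' Scores how well a candidate explains the negotiation so far: the mean over
#' exchanged offer pairs of the agent's own satisfaction of its own past
#' offers times the candidate's satisfaction of the opponent's offers,
#' \eqn{f = \frac{1}{N_r}\sum_r \Psi_{own}(A_r)\,\Psi_{cand}(B_r)}.
#'
#' @param candidate A candidate \code{\link{preference_profile}}.
#' @param own_profile The learning agent's own profile.
#' @param history List with matrices \code{own} and \code{opp} (one offer per
#'   row, aligned by round); must contain at least one pair.
#' @return Fitness in \code{[0, 1]} when all plateau heights are 1.
#' @export
ga_fitness <- function(candidate, own_profile, history) {
  check_history(history)
  psi_own <- satisfaction_batch(own_profile, history$own)
  psi_cand <- satisfaction_batch(candidate, history$opp)
  mean(psi_own * psi_cand)
}

check_history <- function(history) {
  if (is.null(history$own) || is.null(history$opp) ||
      nrow(history$own) < 1L || nrow(history$opp) != nrow(history$own)) {
    stop("history must contain at least one aligned (own, opponent) offer pair")
  }
  invisible(history)
}

# Vectorized fitness of every candidate in a population. psi_own can be
# precomputed once per GA run.
ga_fitness_pop <- function(pop, own_profile, history,
                           psi_own = satisfaction_batch(own_profile,
                                                        history$own)) {
  check_history(history)
  N <- nrow(history$opp)
  psi_cand <- matrix(0, pop$m, N)
  for (i in seq_len(pop$n)) {
    M <- trapezoid_eval_many(pop$a[i], pop$b[, i], pop$c[, i], pop$d[i],
                             history$opp[, i])
    psi_cand <- psi_cand + pop$w[, i] * M
  }
  as.numeric(psi_cand %*% psi_own) / N
}

#' Elite-plus-roulette selection
#'
#' The \code{e = round(elite_rate * m)} highest-fitness individuals pass
#' unchanged; the remaining \code{m - e} slots are filled by sampling with
#' replacement with probability proportional to fitness (uniformly if all
#' fitnesses are zero).
#'
#' @param pop A \code{"ga_population"}.
#' @param fitnesses Numeric vector of non-negative fitnesses, length \code{m}.
#' @param params A \code{\link{ga_params}}.
#' @return A new \code{"ga_population"} of the same size; the elites occupy
#'   the first \code{e} rows.
#' @export
ga_select <- function(pop, fitnesses, params) {
  stopifnot(length(fitnesses) == pop$m, all(is.finite(fitnesses)),
            all(fitnesses >= 0))
  m <- pop$m
  e <- round(params$elite_rate * m)
  elite_idx <- order(fitnesses, decreasing = TRUE)[seq_len(e)]
  prob <- if (sum(fitnesses) > 0) fitnesses else rep(1, m)
  drawn <- sample.int(m, m - e, replace = TRUE, prob = prob)
  idx <- c(elite_idx, drawn)
  new_ga_population(pop$w[idx, , drop = FALSE], pop$b[idx, , drop = FALSE],
                    pop$c[idx, , drop = FALSE], pop$a, pop$d)
}

#' Crossover of two candidate profiles
#'
#' With probability 1/2 the child copies, per issue, the whole
#' (weight, b, c) triple from either parent with equal probability
#' (\code{rule = "copy"}); otherwise it takes the per-gene arithmetic mean
#' (\code{rule = "mean"}). Weights are renormalized and breakpoints remain
#' ordered inside the shared fixed support.
#'
#' @param p1,p2 Parent \code{\link{preference_profile}}s sharing issue order
#'   and supports.
#' @param domains List of \code{\link{issue_domain}}.
#' @param rule Force a crossover rule, or \code{NULL} (default) to pick one
#'   at random.
#' @return A child \code{\link{preference_profile}}.
#' @export
ga_crossover <- function(p1, p2, domains, rule = NULL) {
  stopifnot(p1$n == p2$n)
  n <- p1$n
  if (is.null(rule)) rule <- if (stats::runif(1) < 0.5) "copy" else "mean"
  rule <- match.arg(rule, c("copy", "mean"))
  if (rule == "copy") {
    take1 <- stats::runif(n) < 0.5
    w <- ifelse(take1, p1$weights, p2$weights)
    mfs <- lapply(seq_len(n), function(i) {
      if (take1[i]) p1$memberships[[i]] else p2$memberships[[i]]
    })
  } else {
    w <- (p1$weights + p2$weights) / 2
    mfs <- lapply(seq_len(n), function(i) {
      m1 <- p1$memberships[[i]]; m2 <- p2$memberships[[i]]
      trapezoid_mf(m1$a, (m1$b + m2$b) / 2, (m1$c + m2$c) / 2, m1$d, beta = 1)
    })
  }
  preference_profile(w / sum(w), mfs, domains)
}

#' Mutate a candidate profile
#'
#' With probability \code{mutation_rate} one uniformly chosen issue has its
#' weight and plateau breakpoints redrawn as at initialization; weights are
#' renormalized afterwards so all invariants are restored.
#'
#' @param child A candidate \code{\link{preference_profile}}.
#' @param params A \code{\link{ga_params}}.
#' @param domains List of \code{\link{issue_domain}}.
#' @return The (possibly) mutated \code{\link{preference_profile}}.
#' @export
ga_mutate <- function(child, params, domains) {
  if (stats::runif(1) >= params$mutation_rate) return(child)
  n <- child$n
  i <- sample.int(n, 1L)
  w <- child$weights
  w[i] <- stats::runif(1)
  mf <- child$memberships[[i]]
  x <- sort(stats::runif(2, mf$a, mf$d))
  mfs <- child$memberships
  mfs[[i]] <- trapezoid_mf(mf$a, x[1], x[2], mf$d, beta = 1)
  preference_profile(w / sum(w), mfs, domains)
}

# Vectorized crossover + mutation kernels used by ga_evolve. Semantics match
# ga_crossover/ga_mutate per child; the RNG draw order differs, so agreement
# with the scalar ops is checked by invariants and distribution, not by
# stream identity.
ga_offspring <- function(sel, old, n_children, params) {
  m <- sel$m; n <- sel$n
  psr <- params$potential_stock_rate
  pick_parent <- function() {
    from_old <- stats::runif(n_children) < psr
    idx <- sample.int(m, n_children, replace = TRUE)
    list(from_old = from_old, idx = idx)
  }
  par_rows <- function(pk, field) {
    out <- sel[[field]][pk$idx, , drop = FALSE]
    if (any(pk$from_old)) {
      out[pk$from_old, ] <- old[[field]][pk$idx[pk$from_old], , drop = FALSE]
    }
    out
  }
  pk1 <- pick_parent(); pk2 <- pick_parent()
  W1 <- par_rows(pk1, "w"); W2 <- par_rows(pk2, "w")
  B1 <- par_rows(pk1, "b"); B2 <- par_rows(pk2, "b")
  C1 <- par_rows(pk1, "c"); C2 <- par_rows(pk2, "c")
  mean_rule <- stats::runif(n_children) < 0.5
  take1 <- matrix(stats::runif(n_children * n) < 0.5, n_children, n)
  cmb <- function(X1, X2) {
    out <- ifelse(take1, X1, X2)
    out[mean_rule, ] <- (X1[mean_rule, , drop = FALSE] +
                           X2[mean_rule, , drop = FALSE]) / 2
    out
  }
  W <- cmb(W1, W2); B <- cmb(B1, B2); C <- cmb(C1, C2)
  # mutation: one redrawn issue per selected child
  mut <- stats::runif(n_children) < params$mutation_rate
  if (params$mutation_granularity == "issue") {
    rows <- which(mut)
    if (length(rows)) {
      cols <- sample.int(n, length(rows), replace = TRUE)
      idx <- cbind(rows, cols)
      W[idx] <- stats::runif(length(rows))
      a <- sel$a[cols]; d <- sel$d[cols]
      x1 <- a + stats::runif(length(rows)) * (d - a)
      x2 <- a + stats::runif(length(rows)) * (d - a)
      B[idx] <- pmin(x1, x2)
      C[idx] <- pmax(x1, x2)
    }
  } else {
    G <- matrix(stats::runif(n_children * n) < params$mutation_rate,
                n_children, n)
    if (any(G)) {
      A <- matrix(sel$a, n_children, n, byrow = TRUE)
      D <- matrix(sel$d, n_children, n, byrow = TRUE)
      x1 <- A + matrix(stats::runif(n_children * n), n_children, n) * (D - A)
      x2 <- A + matrix(stats::runif(n_children * n), n_children, n) * (D - A)
      W[G] <- stats::runif(sum(G))
      B[G] <- pmin(x1, x2)[G]
      C[G] <- pmax(x1, x2)[G]
    }
  }
  W <- W / rowSums(W)
  list(w = W, b = B, c = C)
}

#' Evolve a candidate opponent profile from the offer history
#'
#' Runs \code{max_iteration} generations of selection, crossover and mutation
#' starting from a random population (or \code{init_pop} when warm-starting)
#' and returns the highest-fitness individual of the final generation. With
#' elitism the best-of-generation fitness is non-decreasing.
#'
#' @inheritParams ga_fitness
#' @param domains List of \code{\link{issue_domain}}.
#' @param params A \code{\link{ga_params}}.
#' @param init_pop Optional \code{"ga_population"} to start from.
#' @return A list of class \code{"ga_result"}: \code{best} (the best
#'   candidate as a \code{\link{preference_profile}}), \code{weights} (its
#'   weight vector), \code{fitness}, \code{trace} (best fitness per
#'   generation) and \code{population} (final population, for warm starts).
#' @export
ga_evolve <- function(own_profile, domains, history, params,
                      init_pop = NULL) {
  check_history(history)
  psi_own <- satisfaction_batch(own_profile, history$own)
  pop <- if (is.null(init_pop)) {
    ga_init_population(own_profile, domains, params)
  } else init_pop
  m <- params$population_size
  e <- round(params$elite_rate * m)
  trace <- numeric(params$max_iteration)
  fit <- ga_fitness_pop(pop, own_profile, history, psi_own)
  for (g in seq_len(params$max_iteration)) {
    sel <- ga_select(pop, fit, params)
    child <- ga_offspring(sel, pop, m - e, params)
    nw <- rbind(sel$w[seq_len(e), , drop = FALSE], child$w)
    nb <- rbind(sel$b[seq_len(e), , drop = FALSE], child$b)
    nc <- rbind(sel$c[seq_len(e), , drop = FALSE], child$c)
    pop <- new_ga_population(nw, nb, nc, pop$a, pop$d)
    fit <- ga_fitness_pop(pop, own_profile, history, psi_own)
    trace[g] <- max(fit)
  }
  # Deterministic tie-break among equally fit final candidates: prefer the
  # one whose plateaus lie closest to the opponent's observed offers. Ties
  # are common precisely when the history is uninformative (all opponent
  # offers outside the agent's support give every candidate fitness 0); the
  # nearest-plateau candidate is then the least arbitrary estimate.
  top <- which(fit >= max(fit) - 1e-12)
  if (length(top) > 1L) {
    Dw <- pop$d - pop$a
    Dw[Dw <= 0] <- 1
    mid <- (pop$b[top, , drop = FALSE] + pop$c[top, , drop = FALSE]) / 2
    Bbar <- colMeans(history$opp)
    dev <- abs(sweep(mid, 2L, Bbar)) / matrix(Dw, length(top), pop$n,
                                              byrow = TRUE)
    j <- top[which.min(rowMeans(dev))]
  } else {
    j <- top
  }
  best <- ga_candidate(pop, j, domains)
  # Per-issue unidentifiability: when every observed opponent offer on an
  # issue lies outside the agent's support, no candidate can score it and
  # the fitted trapezoid for that issue is unconstrained noise -- yet the
  # concession-refined weights may rank the issue highly, so a noise plateau
  # would steer bidding in an arbitrary direction. Collapse such plateaus to
  # the support point nearest the opponent's observed mean.
  for (i in seq_len(pop$n)) {
    mu_obs <- eval_membership(best$memberships[[i]], history$opp[, i])
    if (all(mu_obs == 0)) {
      a_i <- pop$a[i]; d_i <- pop$d[i]
      x <- min(max(mean(history$opp[, i]), a_i), d_i)
      best$memberships[[i]] <- trapezoid_mf(a_i, x, x, d_i, beta = 1)
    }
  }
  structure(list(best = best, weights = best$weights, fitness = fit[j],
                 trace = trace, population = pop),
            class = "ga_result")
}

#' Concession-derived opponent weights
#'
#' From the per-issue accumulated concessions observed in the opponent's
#' counteroffers: a larger overall concession on an issue implies a smaller
#' weight, \eqn{w_i^c \propto 1/(c_i D_i)} normalized to sum 1. Zero
#' concessions are floored at the issue's grid step before inversion.
#'
#' @param ledger A concession ledger as built by
#'   \code{\link{new_concession_ledger}} / \code{\link{update_ledger}}: a list
#'   with numeric vectors \code{c} (accumulated concession per issue),
#'   \code{D} (domain widths) and \code{step} (grid steps).
#' @return A weight vector summing to 1.
#' @export
concession_weights <- function(ledger) {
  ci <- pmax(ledger$c, ledger$step)
  raw <- 1 / (ci * ledger$D)
  raw / sum(raw)
}

#' Create an empty concession ledger
#'
#' @param domains List of \code{\link{issue_domain}}.
#' @return A ledger list with zero accumulated concessions.
#' @export
new_concession_ledger <- function(domains) {
  list(c = numeric(length(domains)),
       D = domain_widths(domains),
       step = vapply(domains, function(d) d$step, 0))
}

#' Record a received counteroffer in a concession ledger
#'
#' From the second received counteroffer on, each issue accumulates the
#' absolute offer-to-offer movement \code{|B_r - B_{r-1}|}.
#'
#' @param ledger A concession ledger.
#' @param prev,curr The previous and current received counteroffers.
#' @return The updated ledger.
#' @export
update_ledger <- function(ledger, prev, curr) {
  ledger$c <- ledger$c + abs(curr - prev)
  ledger
}

#' Refine GA weights with concession weights
#'
#' Element-wise mean of the GA-learned and concession-derived weight vectors,
#' \eqn{w_i = (w_i^g + w_i^c)/2}; sums to 1 when both inputs do.
#'
#' @param w_g,w_c Weight vectors of equal length.
#' @return The refined weight vector.
#' @export
refine_weights <- function(w_g, w_c) {
  if (length(w_g) != length(w_c)) stop("weight vectors must share length")
  (w_g + w_c) / 2
}
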