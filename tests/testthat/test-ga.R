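ga_domains <- function() list(issue_domain("u", 0, 10, 0.5),
                              issue_domain("v", 0, 10, 0.5),
                              issue_domain("w", 0, 10, 0.5))

test_that("population initialization satisfies all candidate invariants", {
  doms <- ga_domains()
  own <- random_profile(doms, seed = 42)
  par <- ga_params(population_size = 100)
  pop <- ga_init_population(own, doms, par, seed = 1)
  expect_equal(pop$m, 100L)
  expect_equal(rowSums(pop$w), rep(1, 100), tolerance = 1e-12)
  a <- vapply(own$memberships, function(m) m$a, 0)
  d <- vapply(own$memberships, function(m) m$d, 0)
  expect_equal(pop$a, a)
  expect_equal(pop$d, d)
  for (i in 1:3) {
    expect_true(all(pop$b[, i] >= a[i] & pop$b[, i] <= pop$c[, i] &
                      pop$c[, i] <= d[i]))
  }
  # fixed seed reproduces the population exactly
  pop2 <- ga_init_population(own, doms, par, seed = 1)
  expect_identical(pop, pop2)
  # single issue forces unit weights
  d1 <- list(issue_domain("x", 0, 10, 0.5))
  own1 <- one_issue_profile(1, 3, 6, 9, d1)
  pop1 <- ga_init_population(own1, d1, ga_params(population_size = 10),
                             seed = 2)
  expect_equal(as.numeric(pop1$w), rep(1, 10))
})

test_that("fitness is the mean product of the two satisfaction streams", {
  d1 <- list(issue_domain("x", 0, 10, 0.5))
  own <- one_issue_profile(0, 5, 10, 10, d1)     # mu(2.5) = 0.75
  cand <- one_issue_profile(0, 0, 5, 10, d1)     # mu(7.5) = 0.75
  h1 <- list(own = matrix(2.5), opp = matrix(7.5))
  expect_equal(ga_fitness(cand, own, h1), 0.75 * 0.75, tolerance = 1e-12)
  # two rounds average the per-round products
  h2 <- list(own = matrix(c(2.5, 5)), opp = matrix(c(7.5, 2.5)))
  expect_equal(ga_fitness(cand, own, h2),
               mean(c(0.75 * 0.75, 1 * 1)), tolerance = 1e-12)
  # candidate plateau covering every opponent offer reduces to mean own psi
  wide <- one_issue_profile(0, 0, 10, 10, d1)
  expect_equal(ga_fitness(wide, own, h2), mean(c(0.75, 1)),
               tolerance = 1e-12)
  expect_error(ga_fitness(cand, own, list(own = matrix(numeric(0), 0, 1),
                                          opp = matrix(numeric(0), 0, 1))),
               "at least one")
})

test_that("vectorized population fitness agrees with the scalar op", {
  set.seed(9)
  doms <- ga_domains()
  own <- random_profile(doms)
  par <- ga_params(population_size = 25)
  pop <- ga_init_population(own, doms, par)
  hist <- list(own = matrix(runif(12, 0, 10), 4),
               opp = matrix(runif(12, 0, 10), 4))
  fp <- fuzzneg:::ga_fitness_pop(pop, own, hist)
  fs <- sapply(seq_len(pop$m), function(j) {
    ga_fitness(fuzzneg:::ga_candidate(pop, j, doms), own, hist)
  })
  expect_equal(fp, fs, tolerance = 1e-12)
})

test_that("selection is elitist and fitness-proportional", {
  doms <- ga_domains()
  own <- random_profile(doms, seed = 3)
  pop <- ga_init_population(own, doms, ga_params(population_size = 2),
                            seed = 4)
  par0 <- ga_params(population_size = 2, elite_rate = 0)
  # fitnesses (1, 3): expected selection probabilities (0.25, 0.75)
  set.seed(100)
  picks <- replicate(5000, {
    sel <- ga_select(pop, c(1, 3), par0)
    sum(sel$w[, 1] == pop$w[2, 1])
  })
  expect_equal(sum(picks) / 10000, 0.75, tolerance = 0.02)
  # elitism: the argmax individual appears in every output
  par1 <- ga_params(population_size = 2, elite_rate = 0.5)
  for (rep in 1:25) {
    sel <- ga_select(pop, c(1, 3), par1)
    expect_true(any(sel$w[, 1] == pop$w[2, 1]))
  }
  # all-zero fitness falls back to uniform sampling without error
  sel0 <- ga_select(pop, c(0, 0), par0)
  expect_equal(sel0$m, 2L)
})

test_that("crossover follows the copy and mean rules", {
  doms <- ga_domains()
  set.seed(15)
  p1 <- preference_profile(c(0.2, 0.5, 0.3),
    list(trapezoid_mf(0, 3, 4, 8), trapezoid_mf(1, 2, 5, 9),
         trapezoid_mf(0, 1, 2, 7)), doms)
  p2 <- preference_profile(c(0.4, 0.3, 0.3),
    list(trapezoid_mf(0, 4, 6, 8), trapezoid_mf(1, 3, 6, 9),
         trapezoid_mf(0, 2, 5, 7)), doms)
  # identical parents: child equals parent under either rule
  for (rule in c("copy", "mean")) {
    ch <- ga_crossover(p1, p1, doms, rule = rule)
    expect_equal(ch$weights, p1$weights)
    expect_equal(ch$memberships, p1$memberships)
  }
  # mean rule averages per gene
  chm <- ga_crossover(p1, p2, doms, rule = "mean")
  expect_equal(chm$weights, c(0.3, 0.4, 0.3))
  expect_equal(chm$memberships[[1]]$b, 3.5)
  expect_equal(chm$memberships[[1]]$c, 5)
  # copy rule takes whole (w, b, c) triples from one parent per issue
  for (rep in 1:10) {
    chc <- ga_crossover(p1, p2, doms, rule = "copy")
    for (i in 1:3) {
      from1 <- isTRUE(all.equal(chc$memberships[[i]]$b,
                                p1$memberships[[i]]$b))
      src <- if (from1) p1 else p2
      expect_equal(chc$memberships[[i]]$c, src$memberships[[i]]$c)
    }
    expect_equal(sum(chc$weights), 1, tolerance = 1e-12)
  }
})

test_that("mutation redraws a single issue and restores invariants", {
  doms <- ga_domains()
  own <- random_profile(doms, seed = 21)
  child <- random_profile(doms, seed = 22)
  expect_identical(ga_mutate(child, ga_params(mutation_rate = 0), doms),
                   child)
  set.seed(30)
  for (rep in 1:50) {
    m <- ga_mutate(child, ga_params(mutation_rate = 1), doms)
    expect_equal(sum(m$weights), 1, tolerance = 1e-12)
    for (i in 1:3) {
      mf <- m$memberships[[i]]
      expect_true(mf$a <= mf$b && mf$b <= mf$c && mf$c <= mf$d)
      expect_equal(mf$a, child$memberships[[i]]$a)
      expect_equal(mf$d, child$memberships[[i]]$d)
    }
  }
  d1 <- list(issue_domain("x", 0, 10, 0.5))
  ch1 <- one_issue_profile(1, 3, 6, 9, d1)
  m1 <- ga_mutate(ch1, ga_params(mutation_rate = 1), d1)
  expect_equal(m1$weights, 1)
})

test_that("evolution is elitist-monotone and returns the final best", {
  set.seed(41)
  doms <- ga_domains()
  own <- random_profile(doms)
  opp <- random_profile(doms)
  hist <- list(own = matrix(runif(15, 0, 10), 5),
               opp = t(replicate(5, sapply(opp$memberships, function(m) {
                 runif(1, m$b, m$c)
               }))))
  par <- ga_params(population_size = 40, max_iteration = 50)
  res <- ga_evolve(own, doms, hist, par)
  expect_s3_class(res$best, "preference_profile")
  expect_true(all(diff(res$trace) >= -1e-12))
  expect_equal(res$fitness, max(fuzzneg:::ga_fitness_pop(res$population,
                                                         own, hist)),
               tolerance = 1e-12)
  # final population satisfies candidate invariants
  pop <- res$population
  expect_equal(rowSums(pop$w), rep(1, pop$m), tolerance = 1e-9)
  for (i in 1:3) {
    expect_true(all(pop$b[, i] <= pop$c[, i]))
    expect_true(all(pop$b[, i] >= pop$a[i] - 1e-12))
    expect_true(all(pop$c[, i] <= pop$d[i] + 1e-12))
  }
  # minimal configuration runs one cycle
  res2 <- ga_evolve(own, doms, hist,
                    ga_params(population_size = 2, max_iteration = 1,
                              elite_rate = 0))
  expect_length(res2$trace, 1)
  # deterministic under a fixed RNG state
  set.seed(99); a <- ga_evolve(own, doms, hist, par)
  set.seed(99); b <- ga_evolve(own, doms, hist, par)
  expect_identical(a$weights, b$weights)
})

test_that("evolved candidates beat random profiles on fitness", {
  # scaled-down Monte Carlo: 20 seeded runs (the design-level experiment
  # uses 100); the evolved candidate must beat a uniform-random profile
  set.seed(55)
  doms <- ga_domains()
  wins <- replicate(20, {
    own <- random_profile(doms)
    opp <- random_profile(doms)
    hist <- list(own = t(replicate(10, sapply(own$memberships, function(m) {
                   runif(1, m$a, m$d)
                 }))),
                 opp = t(replicate(10, sapply(opp$memberships, function(m) {
                   runif(1, m$a, m$d)
                 }))))
    res <- ga_evolve(own, doms, hist,
                     ga_params(population_size = 100, max_iteration = 50))
    rnd <- fuzzneg:::ga_candidate(
      ga_init_population(own, doms, ga_params(population_size = 2)), 1, doms)
    res$fitness >= ga_fitness(rnd, own, hist)
  })
  expect_gte(mean(wins), 0.95)
})

test_that("concession weights invert accumulated movement", {
  led <- list(c = c(0.1, 0.4), D = c(1, 1), step = c(0.01, 0.01))
  expect_equal(concession_weights(led), c(0.8, 0.2), tolerance = 1e-12)
  led_eq <- list(c = c(0.3, 0.3, 0.3), D = rep(2, 3), step = rep(0.01, 3))
  expect_equal(concession_weights(led_eq), rep(1 / 3, 3))
  led_1 <- list(c = 5, D = 10, step = 0.1)
  expect_equal(concession_weights(led_1), 1)
  # zero concession floored at the step before inversion
  led_0 <- list(c = c(0, 0.4), D = c(1, 1), step = c(0.1, 0.1))
  expect_equal(concession_weights(led_0), c(10, 2.5) / 12.5)
})

test_that("ledger accumulates absolute per-issue movement", {
  doms <- ga_domains()
  led <- new_concession_ledger(doms)
  expect_equal(led$c, rep(0, 3))
  led <- update_ledger(led, c(1, 2, 3), c(2, 2, 1))
  led <- update_ledger(led, c(2, 2, 1), c(1.5, 3, 1))
  expect_equal(led$c, c(1.5, 1, 2))
})

test_that("weight refinement is the element-wise mean", {
  expect_equal(refine_weights(c(0.6, 0.4), c(0.2, 0.8)), c(0.4, 0.6))
  w <- c(0.3, 0.7)
  expect_equal(refine_weights(w, w), w)
  set.seed(61)
  for (rep in 1:10) {
    a <- runif(4); a <- a / sum(a)
    b <- runif(4); b <- b / sum(b)
    expect_equal(sum(refine_weights(a, b)), 1, tolerance = 1e-12)
  }
  expect_error(refine_weights(c(0.5, 0.5), c(1)), "length")
})
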