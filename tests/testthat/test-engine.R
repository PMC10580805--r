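# lightweight fabricated transcripts for metric tests
fake_transcript <- function(outcome, psi_pa = NA, psi_da = NA, rounds = 1,
                            rmax = 10) {
  structure(list(outcome = outcome, psi_pa = psi_pa, psi_da = psi_da,
                 n_rounds = rounds, rmax = rmax),
            class = "transcript")
}

test_that("identical profiles agree in round one with joint satisfaction 2", {
  sc0 <- two_issue_scenario()
  sc <- scenario(sc0$domains, sc0$pa, sc0$pa)
  t <- run_negotiation(sc, negotiation_agent("ga", "collaboration"),
                       negotiation_agent("ga", "collaboration"),
                       rmax = 10, seed = 1)
  expect_identical(t$outcome, "Agreement")
  expect_equal(t$n_rounds, 1L)
  expect_equal(t$psi_pa + t$psi_da, 2)
})

test_that("disjoint supports under competition fail by the deadline", {
  domains <- list(issue_domain("x", 0, 10, 0.5))
  pa <- preference_profile(1, list(trapezoid_mf(0, 1, 2, 3)), domains)
  da <- preference_profile(1, list(trapezoid_mf(7, 8, 9, 10)), domains)
  sc <- scenario(domains, pa, da)
  t <- run_negotiation(sc, negotiation_agent("ga", "competition"),
                       negotiation_agent("ga", "competition"),
                       rmax = 4, seed = 2)
  expect_identical(t$outcome, "Failure")
  expect_equal(t$n_rounds, 4L)
})

test_that("negotiations are reproducible from the seed", {
  sc <- sample_scenario(generator_config(), seed = 10)
  ag <- negotiation_agent("ga", "collaboration")
  t1 <- run_negotiation(sc, ag, ag, rmax = 8, seed = 77)
  t2 <- run_negotiation(sc, ag, ag, rmax = 8, seed = 77)
  expect_identical(t1$offers, t2$offers)
  expect_identical(t1$rounds, t2$rounds)
})

test_that("transcripts satisfy the protocol invariants", {
  gen <- generator_config()
  specs <- list(negotiation_agent("ga", "collaboration"),
                negotiation_agent("distance", "win_win"),
                negotiation_agent("time", "collaboration"),
                negotiation_agent("oracle", "competition"))
  set.seed(5)
  for (k in 1:4) {
    sc <- sample_scenario(gen, seed = 100 + k)
    t <- run_negotiation(sc, specs[[k]], specs[[(k %% 4) + 1]],
                         rmax = 8, seed = 200 + k)
    expect_lte(t$n_rounds, 8)
    # per-agent acceptance thresholds never increase
    expect_true(all(diff(t$theta_pa) <= 1e-12))
    expect_true(all(diff(t$theta_da) <= 1e-12))
    # replaying offers reproduces the logged receiver satisfactions
    for (r in seq_len(t$n_rounds)) {
      receiver <- if (t$rounds$proposer[r] == "PA") sc$da else sc$pa
      expect_equal(t$rounds$psi_in[r],
                   aggregate_satisfaction(receiver, t$offers[r, ]),
                   tolerance = 1e-12)
    }
    # acceptance only at or above the logged threshold; agreement replay
    last <- t$n_rounds
    if (t$outcome == "Agreement") {
      expect_identical(t$rounds$action[last], "Accept")
      expect_gte(t$rounds$psi_in[last], t$rounds$threshold[last])
      expect_equal(t$psi_pa, aggregate_satisfaction(sc$pa, t$agreement))
      expect_equal(t$psi_da, aggregate_satisfaction(sc$da, t$agreement))
    } else {
      expect_true(all(t$rounds$action == "Offer"))
    }
    # every proposal satisfies the proposer's own threshold in force
    for (r in seq_len(t$n_rounds)) {
      prop_profile <- if (t$rounds$proposer[r] == "PA") sc$pa else sc$da
      th_hist <- if (t$rounds$proposer[r] == "PA") t$theta_pa else t$theta_da
      # threshold in force = last concession made before proposing
      rec_rounds <- which(t$rounds$proposer[seq_len(r - 1)] !=
                            t$rounds$proposer[r])
      th <- if (length(rec_rounds)) th_hist[length(rec_rounds)] else 1
      expect_gte(aggregate_satisfaction(prop_profile, t$offers[r, ]),
                 th - 1e-9)
    }
  }
})

test_that("metrics aggregate transcripts with the zero-success convention", {
  ts <- list(fake_transcript("Agreement", 0.7, 0.8, rounds = 4),
             fake_transcript("Agreement", 0.9, 0.8, rounds = 6),
             fake_transcript("Failure"))
  m <- compute_metrics(ts)
  expect_equal(m$AJS, mean(c(1.5, 1.7)))
  expect_equal(m$ANR, 5)
  expect_equal(m$NSR, 2 / 3)
  expect_identical(m$NSR * m$T_all, as.numeric(m$T_suc))
  # 150 of 200 successes
  ts2 <- c(replicate(150, fake_transcript("Agreement", 0.5, 0.5),
                     simplify = FALSE),
           replicate(50, fake_transcript("Failure"), simplify = FALSE))
  expect_equal(compute_metrics(ts2)$NSR, 0.75)
  # zero successes: AJS 0, ANR rmax
  ts0 <- replicate(3, fake_transcript("Failure", rmax = 10),
                   simplify = FALSE)
  m0 <- compute_metrics(ts0)
  expect_equal(m0$AJS, 0)
  expect_equal(m0$ANR, 10)
  expect_equal(m0$NSR, 0)
  expect_error(compute_metrics(list()), "non-empty")
})

test_that("transcripts serialize to JSON", {
  sc <- two_issue_scenario()
  t <- run_negotiation(sc, negotiation_agent("distance", "collaboration"),
                       negotiation_agent("distance", "collaboration"),
                       rmax = 6, seed = 3)
  path <- tempfile(fileext = ".json")
  write_transcript(t, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(back$outcome, t$outcome)
  expect_equal(back$rmax, 6)
})
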