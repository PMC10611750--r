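test_that("composite values average the three feature values", {
  st <- rl_state()
  expect_equal(composite_value(st, c(1, 4, 7)), 0)
  st$v[c(1, 4, 7)] <- c(0.9, 0.3, 0)
  expect_equal(composite_value(st, c(1, 4, 7)), 0.4)
  expect_equal(composite_value(st, c(7, 1, 4)), 0.4)  # order-invariant
  expect_error(composite_value(st, c(1, 4, 10)))
})

test_that("softmax choice probabilities behave across temperatures", {
  st <- rl_state()
  lay <- fixed_layout()
  expect_equal(rl_choice_probs(st, lay, beta = 3), rep(1 / 3, 3))
  st$v[c(1, 4, 7)] <- 1  # column 1 composite value 1, others 0
  expect_equal(rl_choice_probs(st, lay, beta = 1e-9), rep(1 / 3, 3),
               tolerance = 1e-6)
  pr <- rl_choice_probs(st, lay, beta = 2)
  expect_equal(pr, c(exp(2), 1, 1) / (exp(2) + 2))
  expect_equal(sum(pr), 1)
})

test_that("rl_update applies the Rescorla-Wagner rules", {
  lay <- fixed_layout()
  p <- rl_params("ba", alpha = 0.5, beta = 1)
  st <- rl_state()
  out <- rl_update(st, lay, choice = 1, reward = 1, p)
  expect_equal(out$trace$delta, 1)
  expect_equal(unname(out$state$v[c(1, 4, 7)]), rep(0.5, 3))
  expect_equal(unname(out$state$v[c(2, 3, 5, 6, 8, 9)]), rep(0, 6))

  # full forgetting wipes the unchosen values
  pf <- rl_params("baf", alpha = 0.5, beta = 1, phi = 1)
  st2 <- rl_state(); st2$v[] <- 0.4
  out2 <- rl_update(st2, lay, 2, 1, pf)
  expect_equal(unname(out2$state$v[c(1, 3, 4, 6, 7, 9)]), rep(0, 6))

  # kappa = 0 reduces the confidence modulation to the plain split rates
  pc <- rl_params("bafc", alpha_p = 0.7, alpha_n = 0.2, beta = 1,
                  phi = 0, gamma = 0.5, kappa = 0)
  st3 <- rl_state()
  out3 <- rl_update(st3, lay, 1, 1, pc)
  expect_equal(out3$trace$alpha_used, 0.7)
  st4 <- rl_state(); st4$v[] <- 0.5
  out4 <- rl_update(st4, lay, 1, 0, pc)
  expect_equal(out4$trace$alpha_used, 0.2)
})

test_that("confidence converges to 1 under vanishing prediction errors", {
  # Conf fixed point for |delta| = 0 is (2 - 0)/2 = 1, approached at rate gamma
  p <- rl_params("bafc", alpha_p = 0.5, alpha_n = 0.5, beta = 1,
                 phi = 0, gamma = 0.3, kappa = 1)
  lay <- fixed_layout()
  st <- rl_state()
  st$v[c(1, 4, 7)] <- 1  # V(col 1) = 1 => delta = 0 on rewarded col-1 choices
  conf <- numeric(40)
  for (i in 1:40) {
    out <- rl_update(st, lay, 1, 1, p)
    st <- out$state
    st$v[c(1, 4, 7)] <- 1
    conf[i] <- out$trace$conf_after
  }
  expect_equal(conf[1], 0.5 + 0.3 * (1 - 0.5))
  expect_gt(conf[40], 0.999)
  expect_true(all(diff(conf) >= 0))
})

test_that("a frozen learner has exactly chance likelihood", {
  s <- random_toy_session(125, seed = 31)
  # alpha tiny and values start at 0: state never moves, choices are uniform
  p <- rl_params("ba", alpha = 1e-12, beta = 1)
  expect_equal(rl_loglik(p, s), 125 * log(1 / 3), tolerance = 1e-9)
})

test_that("compiled RL likelihoods equal the step-composed R versions", {
  set.seed(32)
  for (rep in 1:5) {
    s <- random_toy_session(60, seed = 320 + rep)
    pars <- list(
      rl_params("ba", alpha = runif(1, 0.1, 0.9), beta = runif(1, 0.5, 5)),
      rl_params("baf", alpha = runif(1, 0.1, 0.9), beta = runif(1, 0.5, 5),
                phi = runif(1, 0.05, 0.6)),
      rl_params("bafc", alpha_p = runif(1, 0.1, 0.9),
                alpha_n = runif(1, 0.1, 0.9), beta = runif(1, 0.5, 5),
                phi = runif(1, 0.05, 0.6), gamma = runif(1, 0.1, 0.9),
                kappa = runif(1, 0, 2))
    )
    for (p in pars) {
      expect_equal(rl_loglik(p, s), rl_loglik_steps(p, s), tolerance = 1e-12)
    }
  }
})

test_that("model nesting gives identical likelihoods", {
  s <- random_toy_session(80, seed = 33)
  ll_ba <- rl_loglik(rl_params("ba", alpha = 0.4, beta = 2.5), s)
  ll_baf0 <- rl_loglik(rl_params("baf", alpha = 0.4, beta = 2.5, phi = 0), s)
  expect_equal(ll_ba, ll_baf0, tolerance = 1e-12)
  ll_baf <- rl_loglik(rl_params("baf", alpha = 0.4, beta = 2.5, phi = 0.3), s)
  ll_bafc0 <- rl_loglik(rl_params("bafc", alpha_p = 0.4, alpha_n = 0.4,
                                  beta = 2.5, phi = 0.3, gamma = 0.5,
                                  kappa = 0), s)
  expect_equal(ll_baf, ll_bafc0, tolerance = 1e-12)
})

test_that("RL likelihood is invariant to consistent image relabelling", {
  s <- random_toy_session(50, seed = 34)
  # swap the images within each category: 1<->2, 4<->5, 7<->8
  perm <- c(2L, 1L, 3L, 5L, 4L, 6L, 8L, 7L, 9L)
  s2 <- s
  s2$layouts <- matrix(perm[s$layouts], nrow(s$trials), 9)
  s2$trials$target <- perm[s$trials$target]
  p <- rl_params("baf", alpha = 0.3, beta = 2, phi = 0.2)
  expect_equal(rl_loglik(p, s), rl_loglik(p, s2), tolerance = 1e-12)
})

test_that("image values do not diverge under binary rewards", {
  # The shared composite prediction error can push single feature values
  # outside [-1, 1] across shuffling coalitions, but the chosen composite
  # value is always pulled into the convex hull of {old V, reward} and the
  # ensemble stays bounded.
  set.seed(35)
  p <- rl_params("bafc", alpha_p = 0.9, alpha_n = 0.9, beta = 1,
                 phi = 0.3, gamma = 0.7, kappa = 3)
  st <- rl_state()
  for (t in 1:300) {
    lay <- shuffle_layout()
    ch <- sample.int(3, 1); r <- rbinom(1, 1, 0.5)
    V_old <- composite_value(st, lay[, ch])
    out <- rl_update(st, lay, ch, r, p)
    st <- out$state
    V_new <- composite_value(st, lay[, ch])
    lohi <- range(V_old, r)
    expect_gte(V_new, lohi[1] - 1e-12)
    expect_lte(V_new, lohi[2] + 1e-12)
    expect_true(all(abs(st$v) <= 3))
  }
})

test_that("signalled sessions reset values at each game boundary", {
  cfg <- task_config("signalled")
  set.seed(36)
  s <- run_session(rl_agent(rl_params("ba", alpha = 0.5, beta = 2)), cfg)
  p <- rl_params("ba", alpha = 0.5, beta = 2)
  expect_equal(rl_loglik(p, s), rl_loglik_steps(p, s), tolerance = 1e-12)
})
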