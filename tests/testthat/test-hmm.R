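test_that("belief_update renormalises the chosen/unchosen likelihoods", {
  b <- uniform_belief()
  # reward with q = p = 0.8: chosen mass 0.8/9 each, unchosen 0.2/9,
  # normaliser (3*0.8 + 6*0.2)/9 = 3.6/9
  b2 <- belief_update(b, c(1, 4, 7), reward = 1, q = 0.8, p = 0.8)
  expect_equal(unname(b2[c(1, 4, 7)]), rep(0.8 / 3.6, 3))
  expect_equal(unname(b2[c(2, 3, 5, 6, 8, 9)]), rep(0.2 / 3.6, 6))
  expect_equal(sum(b2), 1)

  # q = p = 0.5 carries no information
  expect_equal(belief_update(b, c(2, 5, 8), 0, 0.5, 0.5), b)

  # a point mass stays where it is
  pm <- setNames(c(0, 1, rep(0, 7)), names(b))
  out <- belief_update(pm, c(1, 4, 7), 0, 0.7, 0.6)
  expect_equal(unname(out[2]), 1, tolerance = 1e-12)
})

test_that("the transition smears belief toward uniform", {
  b <- uniform_belief()
  expect_equal(apply_transition(b, 0.3), b)           # uniform fixed point
  pm <- setNames(c(1, rep(0, 8)), names(b))
  expect_equal(apply_transition(pm, 0), pm)           # tr = 0 is identity
  out <- apply_transition(pm, 0.08)
  expect_equal(unname(out[1]), 0.92)
  expect_equal(unname(out[-1]), rep(0.01, 8))
  # repeated application converges to uniform for any tr in (0,1)
  x <- pm
  for (i in 1:500) x <- apply_transition(x, 0.1)
  expect_equal(unname(x), rep(1 / 9, 9), tolerance = 1e-10)
  expect_equal(sum(out), 1, tolerance = 1e-14)
})

test_that("probability matching sums column belief mass", {
  b <- uniform_belief()
  lay <- fixed_layout()
  expect_equal(hmm_choice_probs(b, lay), rep(1 / 3, 3))
  b2 <- setNames(c(0.8, rep(0.025, 8)), names(b))
  pr <- hmm_choice_probs(b2, lay)
  expect_equal(pr[1], 0.8 + 2 * 0.025)   # column 1 holds images 1,4,7
  # large power concentrates on the column holding the argmax belief
  pr_sharp <- hmm_choice_probs(b2, lay, power = 50)
  expect_gt(pr_sharp[1], 0.999)
})

test_that("the compiled filter matches brute-force path enumeration", {
  set.seed(41)
  for (rep in 1:10) {
    s <- random_toy_session(4, seed = 410 + rep)
    params <- hmm_params(runif(1, 0.55, 0.95), runif(1, 0.55, 0.95),
                         runif(1, 0.02, 0.3))
    got <- hmm_filter(params, s)$beliefs
    want <- brute_force_beliefs(params, s)
    expect_lt(max(abs(got - want)), 1e-10)
  }
})

test_that("compiled HMM likelihood equals the step-composed R version", {
  for (rep in 1:5) {
    s <- random_toy_session(60, seed = 420 + rep)
    params <- hmm_params(0.6 + 0.05 * rep, 0.9 - 0.04 * rep, 0.02 * rep)
    expect_equal(hmm_loglik(params, s), hmm_loglik_steps(params, s),
                 tolerance = 1e-10)
    p4 <- hmm_params(0.8, 0.8, 0.1, power = 0.5 + 0.5 * rep)
    expect_equal(hmm_loglik(p4, s), hmm_loglik_steps(p4, s),
                 tolerance = 1e-10)
  }
})

test_that("an uninformative observer scores exactly chance", {
  s <- random_toy_session(125, seed = 43)
  expect_equal(hmm_loglik(hmm_params(0.5, 0.5, 0.2), s), 125 * log(1 / 3),
               tolerance = 1e-10)
})

test_that("the belief stays on the simplex across a long session", {
  s <- hmm_simulate(hmm_params(0.9, 0.95, 0.03), seed = 44)
  f <- hmm_filter(hmm_params(0.9, 0.95, 0.03), s)
  sums <- rowSums(f$beliefs)
  expect_lt(max(abs(sums - 1)), 1e-12)
  expect_true(all(f$beliefs >= 0))
})

test_that("HMM likelihood is invariant to consistent image relabelling", {
  s <- random_toy_session(50, seed = 45)
  perm <- c(3L, 1L, 2L, 6L, 4L, 5L, 9L, 7L, 8L)
  s2 <- s
  s2$layouts <- matrix(perm[s$layouts], nrow(s$trials), 9)
  s2$trials$target <- perm[s$trials$target]
  params <- hmm_params(0.75, 0.85, 0.07)
  expect_equal(hmm_loglik(params, s), hmm_loglik(params, s2),
               tolerance = 1e-12)
})

test_that("hmm_simulate is deterministic under a fixed seed", {
  a <- hmm_simulate(hmm_params(0.8, 0.8, 0.05), seed = 46)
  b <- hmm_simulate(hmm_params(0.8, 0.8, 0.05), seed = 46)
  expect_identical(a, b)
})

test_that("near-certain volatility keeps accuracy at chance", {
  set.seed(47)
  acc <- mean(vapply(1:30, function(i) {
    s <- hmm_simulate(hmm_params(0.8, 0.8, 0.95))
    mean(score_accuracy(s)$correct)
  }, 0))
  expect_lt(acc, 0.42)
})

test_that("higher volatility beliefs produce more post-negative shifts", {
  # shift after negative feedback on a correct, learned choice: the core
  # mechanism linking tr to probabilistic errors
  set.seed(48)
  grid <- c(0.01, 0.05, 0.1, 0.2)
  shift_rate <- vapply(grid, function(tr) {
    mean(vapply(1:60, function(i) {
      s <- hmm_simulate(hmm_params(0.8, 0.8, tr))
      pe <- probabilistic_errors(s)
      if (pe$eligible) pe$proportion else NA_real_
    }, 0), na.rm = TRUE)
  }, 0)
  expect_true(all(diff(shift_rate) > 0))
})
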