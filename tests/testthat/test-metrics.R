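test_that("accuracy scoring codes target choices and non-responses", {
  cfg <- task_config("reversal")
  sched <- volbandit:::with_seed(61, make_target_schedule(cfg))
  s <- run_session(omniscient_agent(sched), cfg, seed = 62, targets = sched)
  acc <- score_accuracy(s)
  expect_true(all(acc$correct == 1))
  expect_equal(range(acc$trial_c), c(-62, 62))
  expect_equal(mean(acc$trial_c), 0)

  # a non-response is an error
  s$trials$choice[10] <- NA
  expect_equal(score_accuracy(s)$correct[10], 0L)
})

test_that("probabilistic errors follow the five-consecutive-correct rule", {
  # Constant layout, target image 1 lives in column 1 throughout.
  # 5 correct rewarded trials, then two correct-but-unrewarded trials:
  # shift after the first (col 2 on trial 7), stay after the second.
  lay <- matrix(rep(layout_row(fixed_layout()), 9), 9, byrow = TRUE)
  choice <- c(1, 1, 1, 1, 1, 1, 2, 1, 1)
  reward <- c(1, 1, 1, 1, 1, 0, 0, 0, 1)
  s <- make_session(lay, choice, reward, targets = rep(1L, 9))
  pe <- probabilistic_errors(s, criterion = 5)
  # opportunities: trial 6 (correct, r=0, next shifts) and trial 8
  # (correct, r=0, next stays); trial 7 is incorrect, not an opportunity
  expect_equal(pe$n_opportunities, 2L)
  expect_equal(pe$n_shifts, 1L)
  expect_equal(pe$proportion, 0.5)
  expect_true(pe$eligible)
})

test_that("subjects without post-criterion negative feedback are ineligible", {
  lay <- matrix(rep(layout_row(fixed_layout()), 8), 8, byrow = TRUE)
  # always correct, always rewarded: no opportunity ever arises
  s1 <- make_session(lay, rep(1, 8), rep(1, 8), targets = rep(1L, 8))
  expect_false(probabilistic_errors(s1)$eligible)
  # never five consecutive correct
  s2 <- make_session(lay, c(1, 1, 2, 1, 1, 2, 1, 1), rep(1, 8),
                     targets = rep(1L, 8))
  expect_false(probabilistic_errors(s2)$eligible)
})

test_that("pre-criterion history and the segment end do not leak in", {
  lay <- matrix(rep(layout_row(fixed_layout()), 14), 14, byrow = TRUE)
  base_choice <- c(2, 3, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1)
  base_reward <- c(0, 1, 1, 1, 1, 1, 1, 0, 1, 1, 1, 1, 1, 1)
  s <- make_session(lay, base_choice, base_reward, targets = rep(1L, 14))
  pe <- probabilistic_errors(s)
  # criterion met at trial 7; the only opportunity is trial 8 (stay)
  expect_equal(pe$n_opportunities, 1L)
  expect_equal(pe$n_shifts, 0L)
  # scrambling the pre-criterion prefix changes nothing
  s2 <- make_session(lay, c(3, 2, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
                     c(1, 0, 1, 1, 1, 1, 1, 0, 1, 1, 1, 1, 1, 1),
                     targets = rep(1L, 14))
  expect_equal(probabilistic_errors(s2)$proportion, pe$proportion)
})

test_that("an opportunity on the last pre-reversal trial is judged across it", {
  lay <- matrix(rep(layout_row(fixed_layout()), 8), 8, byrow = TRUE)
  targets <- c(rep(1L, 6), 5L, 5L)       # reversal after trial 6
  choice <- c(1, 1, 1, 1, 1, 1, 2, 2)
  reward <- c(1, 1, 1, 1, 1, 0, 1, 1)
  s <- make_session(lay, choice, reward, targets = targets)
  pe <- probabilistic_errors(s, judge_across_reversal = TRUE)
  expect_equal(pe$n_opportunities, 1L)   # trial 6, judged against trial 7
  expect_equal(pe$n_shifts, 1L)          # trial 7's column 2 lacks image 1
  pe2 <- probabilistic_errors(s, judge_across_reversal = FALSE)
  expect_false(pe2$eligible)
})

test_that("the proportion estimator is unbiased for a known shift rate", {
  # Agent that picks the target unless told to shift with probability 0.3
  # after a correct unrewarded trial.
  set.seed(63)
  # single-target session: isolates the shift probability from reversals
  cfg <- task_config("reversal", reversal_interval = c(125L, 125L))
  true_rate <- 0.3
  props <- c(); weights <- c()
  for (i in 1:150) {
    sched <- make_target_schedule(cfg)
    shift_next <- FALSE
    env <- environment()
    t <- 0L
    agent <- list(
      reset = function() NULL,
      choose = function(layout) {
        assign("t", t + 1L, envir = env)
        tgt_col <- which(apply(layout, 2, function(cl) sched[env$t] %in% cl))
        if (env$shift_next) {
          assign("shift_next", FALSE, envir = env)
          sample(setdiff(1:3, tgt_col), 1L)
        } else tgt_col
      },
      observe = function(layout, choice, reward) {
        correct <- sched[env$t] %in% layout[, choice]
        if (correct && reward == 0 && runif(1) < true_rate)
          assign("shift_next", TRUE, envir = env)
      }
    )
    s <- run_session(agent, cfg, targets = sched)
    pe <- probabilistic_errors(s)
    if (pe$eligible) {
      props <- c(props, pe$proportion)
      weights <- c(weights, pe$n_opportunities)
    }
  }
  est <- sum(props * weights) / sum(weights)
  expect_lt(abs(est - true_rate), 0.02)
})

sim_accuracy_cohort <- function(n_subj, slope_fun, seed) {
  set.seed(seed)
  trial_c <- (0:124) - 62
  do.call(rbind, lapply(seq_len(n_subj), function(i) {
    data.frame(subject_id = sprintf("s%03d", i), trial = 0:124,
               trial_c = trial_c,
               correct = rbinom(125, 1, plogis(slope_fun(i) * trial_c)))
  }))
}

test_that("learning slopes recover planted logistic trends", {
  # 12 improving subjects (true slope 0.03 per trial) vs 12 flat ones
  acc <- sim_accuracy_cohort(24, function(i) if (i <= 12) 0.03 else 0,
                             seed = 64)
  ls <- learning_slopes(acc)
  expect_equal(nrow(ls$slopes), 24)
  good <- ls$slopes$subject_id %in% sprintf("s%03d", 1:12)
  expect_gt(mean(ls$slopes$slope[good]), 0.015)
  expect_lt(mean(ls$slopes$slope[!good]), 0.01)
  if (ls$method == "glmm") {
    expect_gt(ls$fixed["trial_c", "Estimate"], 0.005)
  }
  # per-subject ridge fallback agrees in ordering
  r_good <- volbandit:::ridge_logit_slope(acc$trial_c[acc$subject_id == "s001"],
                                          acc$correct[acc$subject_id == "s001"])
  expect_gt(r_good, 0.015)
})

test_that("a random cohort has a near-zero group trial effect", {
  set.seed(65)
  sessions <- lapply(1:14, function(i)
    run_session(random_agent(), task_config("reversal"),
                subject_id = sprintf("r%02d", i)))
  acc <- do.call(rbind, lapply(sessions, score_accuracy))
  ls <- learning_slopes(acc)
  expect_lt(abs(mean(ls$slopes$slope)), 0.01)
})

test_that("factor GLMM detects a planted learning modulation", {
  # per-subject true slope 0.02 - 0.012 * score: a negative Factor x Trial
  # interaction of known size
  n <- 40
  score <- scale(seq_len(n))[, 1]
  acc <- sim_accuracy_cohort(n, function(i) 0.02 - 0.012 * score[i],
                             seed = 66)
  scores <- data.frame(subject_id = sprintf("s%03d", 1:n), vol = score)
  tab <- factor_glmm(acc, scores, "vol")
  expect_true("trial_c:vol" %in% rownames(tab))
  expect_lt(tab["trial_c:vol", "Estimate"], 0)
  expect_lt(tab["trial_c:vol", "Pr(>|z|)"], 0.05)
  # a pure-noise factor shows no interaction
  set.seed(67)
  scores$noise <- rnorm(n)
  tab2 <- factor_glmm(acc, scores, "noise")
  expect_gt(tab2["trial_c:noise", "Pr(>|z|)"], 0.01)
  # degenerate predictor
  scores$flat <- 1
  expect_error(factor_glmm(acc, scores, "flat"), "zero variance")
})

test_that("behaviour_metrics bundles per-subject summaries", {
  set.seed(67)
  sessions <- lapply(1:4, function(i)
    hmm_simulate(hmm_params(0.8, 0.8, 0.05), subject_id = paste0("s", i)))
  m <- behaviour_metrics(sessions)
  expect_equal(nrow(m), 4)
  expect_true(all(m$mean_accuracy >= 0 & m$mean_accuracy <= 1))
  expect_true(all(is.na(m$proportion) | (m$proportion >= 0 & m$proportion <= 1)))
})
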