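# Independent oracles and fixture builders used across the suite.

`%or%` <- function(a, b) if (is.null(a)) b else a

# Build a session_log directly from explicit trial components.
make_session <- function(layouts, choice, reward, targets = NULL,
                         config = NULL, game = NULL, subject_id = "toy") {
  n <- length(choice)
  config <- config %or% task_config("reversal", trials_per_game = n)
  structure(list(
    config = config, subject_id = subject_id,
    trials = data.frame(
      trial = seq_len(n) - 1L,
      game = game %or% rep(1L, n),
      target = targets %or% rep(1L, n),
      choice = as.integer(choice), reward = as.integer(reward)
    ),
    layouts = layouts
  ), class = "session_log")
}

# Canonical fixed layout: row r holds images (r-1)*3 + 1:3 in column order,
# so column j = {j, j+3, j+6}.
fixed_layout <- function() matrix(1:9, 3, 3, byrow = TRUE)

layout_row <- function(lay) as.integer(t(lay))

# Random toy session (random layouts, choices, rewards).
random_toy_session <- function(n, seed) {
  withr_seed <- seed
  set.seed(withr_seed)
  layouts <- t(vapply(seq_len(n), function(t) layout_row(shuffle_layout()),
                      integer(9)))
  make_session(layouts, sample.int(3L, n, replace = TRUE),
               rbinom(n, 1, 0.5))
}

# Brute-force filtered beliefs by enumeration over all 9^t target-path
# prefixes: the belief before trial t uses emissions 1..t-1 and transitions
# 1..t-1, with a uniform prior over the initial target.
brute_force_beliefs <- function(params, session) {
  tr <- session$trials
  n <- nrow(tr)
  M <- matrix(params$tr / 8, 9, 9)
  diag(M) <- 1 - params$tr
  E <- matrix(0, n, 9)
  for (t in seq_len(n)) {
    chosen <- session$layouts[t, (0:2) * 3 + tr$choice[t]]
    for (i in 1:9) {
      inch <- i %in% chosen
      E[t, i] <- if (tr$reward[t] == 1) {
        if (inch) params$q else 1 - params$p
      } else {
        if (inch) 1 - params$q else params$p
      }
    }
  }
  beliefs <- matrix(0, n, 9)
  for (t in seq_len(n)) {
    paths <- as.matrix(expand.grid(rep(list(1:9), t)))
    w <- rep(1 / 9, nrow(paths))
    if (t > 1) {
      for (s in 1:(t - 1)) {
        w <- w * E[s, paths[, s]] * M[cbind(paths[, s], paths[, s + 1])]
      }
    }
    for (i in 1:9) beliefs[t, i] <- sum(w[paths[, t] == i])
    beliefs[t, ] <- beliefs[t, ] / sum(beliefs[t, ])
  }
  beliefs
}

# HMM session log-likelihood recomposed in R from the exported single-step
# operations (independent of the compiled filter).
hmm_loglik_steps <- function(params, session) {
  tr <- session$trials
  pw <- if (is.null(params$power)) 1 else params$power
  b <- uniform_belief()
  ll <- 0
  for (t in seq_len(nrow(tr))) {
    if (session$config$task_kind == "signalled" && t > 1 &&
        tr$game[t] != tr$game[t - 1]) {
      b <- uniform_belief()
    }
    if (is.na(tr$choice[t])) next
    lay <- matrix(session$layouts[t, ], 3, 3, byrow = TRUE)
    ll <- ll + log(hmm_choice_probs(b, lay, pw)[tr$choice[t]])
    b <- belief_update(b, lay[, tr$choice[t]], tr$reward[t],
                       params$q, params$p)
    b <- apply_transition(b, params$tr)
  }
  ll
}

# RL session log-likelihood recomposed from the exported step operations.
rl_loglik_steps <- function(params, session) {
  tr <- session$trials
  st <- rl_state()
  ll <- 0
  for (t in seq_len(nrow(tr))) {
    if (session$config$task_kind == "signalled" && t > 1 &&
        tr$game[t] != tr$game[t - 1]) {
      st$v[] <- 0
    }
    if (is.na(tr$choice[t])) next
    lay <- matrix(session$layouts[t, ], 3, 3, byrow = TRUE)
    ll <- ll + log(rl_choice_probs(st, lay, params$beta)[tr$choice[t]])
    st <- rl_update(st, lay, tr$choice[t], tr$reward[t], params)$state
  }
  ll
}

# Constant-layout 3-trial session used by the hand-trace likelihood tests.
hand_trace_session <- function(choice, reward) {
  make_session(
    layouts = matrix(rep(layout_row(fixed_layout()), length(choice)),
                     nrow = length(choice), byrow = TRUE),
    choice = choice, reward = reward
  )
}
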