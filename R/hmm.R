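#' Hidden Markov observer parameters
#'
#' The winning observer treats the target identity as a hidden state over
#' the nine images and filters a belief from reward feedback. Parameters:
#' `q`, the subjective probability of reward when the chosen column contains
#' the target; `p`, the subjective probability of *no* reward when it does
#' not; `tr`, the expected per-trial probability that the target changes
#' identity (off-diagonal transition mass `tr/8` to each other image); and,
#' for the augmented four-parameter variant only, `power`, a
#' belief-sharpening exponent in (0, 5) applied to the hidden states before
#' probability matching (power = 1 recovers exact matching; larger values
#' over-match, smaller under-match).
#'
#' @param q,p,tr probabilities in (0,1).
#' @param power optional sharpening exponent in (0,5); NULL for the
#'   3-parameter model.
#' @return an `hmm_params` list.
#' @export
hmm_params <- function(q, p, tr, power = NULL) {
  stopifnot(q > 0, q < 1, p > 0, p < 1, tr >= 0, tr < 1)
  if (!is.null(power)) stopifnot(power > 0, power < 5)
  structure(list(q = q, p = p, tr = tr, power = power), class = "hmm_params")
}

#' Uniform initial belief over target identity
#'
#' @return named numeric vector of 9 probabilities summing to 1.
#' @export
uniform_belief <- function() setNames(rep(1 / 9, 9), image_label(1:9))

#' Bayesian belief update from one outcome
#'
#' The three chosen features are scored with likelihood `q` (reward) or
#' `1 - q` (no reward); the six unchosen features with `1 - p` (reward) or
#' `p` (no reward); the posterior is renormalised to the simplex. A floor of
#' 1e-300 guards underflow on long sessions.
#'
#' @param belief belief vector (9 probabilities).
#' @param chosen_features the three image ids of the chosen column.
#' @param reward 0 or 1.
#' @param q,p emission parameters in (0,1).
#' @return updated belief vector.
#' @export
belief_update <- function(belief, chosen_features, reward, q, p) {
  stopifnot(length(chosen_features) == 3, all(chosen_features %in% 1:9))
  lik <- rep(if (reward == 1) 1 - p else p, 9)
  lik[chosen_features] <- if (reward == 1) q else 1 - q
  post <- pmax(belief * lik, 1e-300)
  s <- sum(post)
  if (!is.finite(s) || s <= 0) stop("degenerate posterior in belief_update")
  post / s
}

#' Apply the target-change transition
#'
#' The 9x9 transition matrix has diagonal `1 - tr` and off-diagonal entries
#' `tr/8`: with probability `tr` the target jumps uniformly to one of the
#' eight other images. The map is linear and doubly stochastic, so the
#' simplex is preserved exactly and repeated application diffuses any belief
#' toward uniform.
#'
#' @param belief belief vector (9 probabilities).
#' @param tr transition parameter in \[0, 1).
#' @return diffused belief vector.
#' @export
apply_transition <- function(belief, tr) {
  (1 - tr) * belief + (tr / 8) * (sum(belief) - belief)
}

#' Probability-matching choice probabilities
#'
#' Each column is chosen with probability proportional to the summed belief
#' mass of its three images; with `power != 1` the hidden states are raised
#' elementwise to the exponent before summation, allowing under- and
#' over-matching.
#'
#' @param belief belief vector (9 probabilities).
#' @param layout 3x3 layout matrix.
#' @param power sharpening exponent (default 1 = exact matching).
#' @return probability triple over columns.
#' @export
hmm_choice_probs <- function(belief, layout, power = 1) {
  a <- if (power == 1) belief else belief^power
  cs <- vapply(1:3, function(c) sum(a[layout[, c]]), 0)
  cs / sum(cs)
}

hmm_reset_games <- function(session) session$config$task_kind == "signalled"

#' Log-likelihood of a session under the HMM observer
#'
#' Filters the belief forward (choice from the current belief, then emission
#' update, then transition) and sums the log probability-matching
#' probabilities of the recorded choices. The belief is initialised uniform
#' at session start, and additionally at each game start in the signalled
#' task (where target changes are announced). Non-response trials are
#' skipped entirely.
#'
#' @param params an [hmm_params()].
#' @param session a `session_log`.
#' @return scalar log-likelihood.
#' @export
hmm_loglik <- function(params, session) {
  tr <- session$trials
  hmm_loglik_cpp(session$layouts, tr$choice, tr$reward, tr$game,
                 params$q, params$p, params$tr, params$power %||% 1,
                 hmm_reset_games(session))
}

#' Filtered beliefs for a recorded session
#'
#' Returns the belief held immediately before each trial's choice, plus the
#' per-trial log choice probability (NA on skipped trials).
#'
#' @param params an [hmm_params()].
#' @param session a `session_log`.
#' @return list with `beliefs` (n x 9 matrix) and `logp` (length-n vector).
#' @export
hmm_filter <- function(params, session) {
  tr <- session$trials
  out <- hmm_filter_cpp(session$layouts, tr$choice, tr$reward, tr$game,
                        params$q, params$p, params$tr, params$power %||% 1,
                        hmm_reset_games(session))
  colnames(out$beliefs) <- image_label(1:9)
  out
}

#' HMM simulation agent
#'
#' Closed-loop agent for [run_session()]: chooses by probability matching on
#' the current belief, then updates and diffuses it. The belief is reset to
#' uniform at announced game boundaries of the signalled task.
#'
#' @param params an [hmm_params()].
#' @return an agent list (`reset`, `choose`, `observe`, `new_game`).
#' @export
hmm_agent <- function(params) {
  belief <- uniform_belief()
  env <- environment()
  pw <- params$power %||% 1
  list(
    reset = function() assign("belief", uniform_belief(), envir = env),
    new_game = function() assign("belief", uniform_belief(), envir = env),
    choose = function(layout) {
      sample.int(3L, 1L, prob = hmm_choice_probs(env$belief, layout, pw))
    },
    observe = function(layout, choice, reward) {
      b <- belief_update(env$belief, layout[, choice], reward,
                         params$q, params$p)
      assign("belief", apply_transition(b, params$tr), envir = env)
    }
  )
}

#' Simulate one HMM subject
#'
#' Convenience wrapper around [run_session()] with an [hmm_agent()].
#'
#' @param params an [hmm_params()].
#' @param config a [task_config()].
#' @param subject_id stored subject id.
#' @param seed optional RNG seed.
#' @return a `session_log`.
#' @export
hmm_simulate <- function(params, config = task_config("reversal"),
                         subject_id = "s1", seed = NULL) {
  run_session(hmm_agent(params), config, subject_id = subject_id, seed = seed)
}
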