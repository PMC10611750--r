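#' Reinforcement-learning model parameters
#'
#' The Rescorla-Wagner model family over the nine image features.
#' Three variants are supported:
#' * `ba` -- learning rate `alpha` and softmax inverse temperature `beta`;
#' * `baf` -- adds a forget rate `phi` relaxing the six unchosen images
#'   toward their initial value 0;
#' * `bafc` -- adds valence-split learning rates (`alpha_p` for positive,
#'   `alpha_n` for non-positive prediction errors), a confidence trace
#'   updated from the absolute prediction error at rate `gamma`, and a
#'   modulation weight `kappa` through which confidence raises the positive
#'   and lowers the negative learning rate.
#'
#' @param variant "ba", "baf" or "bafc".
#' @param alpha learning rate in (0,1) (ba/baf; used for both valences).
#' @param alpha_p,alpha_n valence-specific learning rates (bafc).
#' @param beta softmax inverse temperature, > 0.
#' @param phi forget rate in (0,1) (baf/bafc).
#' @param gamma confidence learning rate in (0,1) (bafc).
#' @param kappa confidence-modulation weight, >= 0 (bafc).
#' @return an `rl_params` list with fields `alpha_p`, `alpha_n`, `beta`,
#'   `phi`, `gamma`, `kappa`, `variant`.
#' @export
rl_params <- function(variant = c("ba", "baf", "bafc"),
                      alpha = NULL, alpha_p = NULL, alpha_n = NULL,
                      beta = 1, phi = 0, gamma = 0, kappa = 0) {
  variant <- match.arg(variant)
  if (variant %in% c("ba", "baf")) {
    if (is.null(alpha)) stop(variant, " uses a single learning rate `alpha`")
    alpha_p <- alpha_n <- alpha
    if (variant == "ba") phi <- 0
    gamma <- 0; kappa <- 0
  } else {
    if (is.null(alpha_p) || is.null(alpha_n))
      stop("bafc requires alpha_p and alpha_n")
  }
  stopifnot(alpha_p > 0, alpha_p < 1, alpha_n > 0, alpha_n < 1,
            beta > 0, phi >= 0, phi <= 1, gamma >= 0, gamma <= 1, kappa >= 0)
  structure(list(alpha_p = alpha_p, alpha_n = alpha_n, beta = beta,
                 phi = phi, gamma = gamma, kappa = kappa, variant = variant),
            class = "rl_params")
}

#' Initial learner state
#'
#' Image values start at 0; the confidence trace starts at 0.5, the lower
#' bound of its fixed-point range under rewards in \{0, 1\}.
#'
#' @return an `rl_state` list with `v` (9 named values) and `conf`.
#' @export
rl_state <- function() {
  list(v = setNames(numeric(9), image_label(1:9)), conf = 0.5)
}

#' Value of a composite stimulus
#'
#' The arithmetic mean of the three feature values in a column (each image
#' contributes with weight 1/3).
#'
#' @param state an [rl_state()].
#' @param column_images three distinct image ids (a layout column).
#' @return scalar value.
#' @export
composite_value <- function(state, column_images) {
  stopifnot(length(column_images) == 3, all(column_images %in% 1:9))
  mean(state$v[column_images])
}

#' Softmax choice probabilities over the three columns
#'
#' @param state an [rl_state()].
#' @param layout 3x3 layout matrix.
#' @param beta inverse temperature, > 0.
#' @return probability triple over columns (sums to 1).
#' @export
rl_choice_probs <- function(state, layout, beta) {
  stopifnot(beta > 0)
  V <- vapply(1:3, function(c) composite_value(state, layout[, c]), 0)
  e <- exp(beta * (V - max(V)))
  e / sum(e)
}

#' One Rescorla-Wagner update
#'
#' Computes the prediction error against the chosen composite value, updates
#' the three chosen images by the effective learning rate, relaxes the six
#' unchosen images toward 0 by the forget rate (baf/bafc), and -- for bafc --
#' first updates the confidence trace from the absolute prediction error and
#' then derives the trial's effective learning rate from it.
#'
#' @param state an [rl_state()].
#' @param layout 3x3 layout matrix.
#' @param choice chosen column, 1..3.
#' @param reward observed reward, 0 or 1.
#' @param params an [rl_params()].
#' @return list with `state` (updated) and `trace` (delta, alpha_used,
#'   conf_after, V_chosen).
#' @export
rl_update <- function(state, layout, choice, reward, params) {
  stopifnot(choice %in% 1:3, reward %in% c(0, 1))
  chosen <- layout[, choice]
  V_c <- composite_value(state, chosen)
  delta <- reward - V_c
  if (params$variant == "bafc") {
    state$conf <- state$conf +
      params$gamma * ((2 - abs(delta)) / 2 - state$conf)
    alpha_t <- if (delta > 0) {
      (params$alpha_p + params$kappa * state$conf) /
        (1 + params$kappa * state$conf)
    } else {
      params$alpha_n / (1 + params$kappa * state$conf)
    }
  } else {
    alpha_t <- if (delta > 0) params$alpha_p else params$alpha_n
  }
  state$v[chosen] <- state$v[chosen] + alpha_t * delta
  if (params$variant != "ba") {
    unchosen <- setdiff(1:9, chosen)
    state$v[unchosen] <- state$v[unchosen] * (1 - params$phi)
  }
  list(state = state,
       trace = list(delta = delta, alpha_used = alpha_t,
                    conf_after = state$conf, V_chosen = V_c))
}

#' Log-likelihood of a session under an RL model
#'
#' Sums the log softmax probabilities of the recorded choices while evolving
#' the learner state trial by trial. Values are reset at every game boundary
#' in the signalled task and only at session start in the reversal task; the
#' confidence trace is never reset within a session. Non-response trials
#' (NA choice, imported data only) contribute no likelihood term and leave
#' the state untouched.
#'
#' @param params an [rl_params()].
#' @param session a `session_log`.
#' @return scalar log-likelihood (<= 0).
#' @export
rl_loglik <- function(params, session) {
  tr <- session$trials
  variant <- match(params$variant, c("ba", "baf", "bafc")) - 1L
  rl_loglik_cpp(session$layouts, tr$choice, tr$reward, tr$game,
                params$alpha_p, params$alpha_n, params$beta,
                params$phi, params$gamma, params$kappa,
                variant, session$config$task_kind == "signalled")
}

#' RL simulation agent
#'
#' Closed-loop agent for [run_session()]: chooses by softmax over composite
#' values and learns by [rl_update()]. In the signalled task the value table
#' is cleared at each announced game boundary; the confidence trace carries
#' across games.
#'
#' @param params an [rl_params()].
#' @return an agent list (`reset`, `choose`, `observe`, `new_game`).
#' @export
rl_agent <- function(params) {
  state <- rl_state()
  env <- environment()
  list(
    reset = function() assign("state", rl_state(), envir = env),
    new_game = function() {
      s <- env$state
      s$v[] <- 0
      assign("state", s, envir = env)
    },
    choose = function(layout) {
      sample.int(3L, 1L, prob = rl_choice_probs(env$state, layout, params$beta))
    },
    observe = function(layout, choice, reward) {
      assign("state", rl_update(env$state, layout, choice, reward, params)$state,
             envir = env)
    }
  )
}
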