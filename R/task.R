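#' Task configuration for the composite-stimulus three-armed bandit
#'
#' Builds the configuration of either task variant. In the *signalled* task
#' the target image changes at announced game boundaries (5 games of 25
#' trials, reward probabilities 0.75/0.25). In the *reversal* task a single
#' 125-trial game contains silent reversals every 20--30 trials (reward
#' probabilities 0.8/0.2). Nine images are arranged in a 3x3 grid: each row
#' holds the three images of one category and each column (the composite
#' stimulus) holds one image per category.
#'
#' @param task_kind "reversal" or "signalled".
#' @param n_games number of games (default 1 reversal, 5 signalled).
#' @param trials_per_game trials per game (default 125 reversal, 25 signalled).
#' @param p_reward_target probability of reward when the chosen column
#'   contains the target (default 0.8 reversal, 0.75 signalled).
#' @param p_reward_nontarget probability of reward otherwise
#'   (default 0.2 reversal, 0.25 signalled).
#' @param reversal_interval integer range (min, max) of trials between silent
#'   target changes; reversal task only.
#' @return A `task_config` list.
#' @export
task_config <- function(task_kind = c("reversal", "signalled"),
                        n_games = NULL, trials_per_game = NULL,
                        p_reward_target = NULL, p_reward_nontarget = NULL,
                        reversal_interval = c(20L, 30L)) {
  task_kind <- match.arg(task_kind)
  if (task_kind == "reversal") {
    n_games <- n_games %||% 1L
    trials_per_game <- trials_per_game %||% 125L
    p_reward_target <- p_reward_target %||% 0.8
    p_reward_nontarget <- p_reward_nontarget %||% 0.2
  } else {
    n_games <- n_games %||% 5L
    trials_per_game <- trials_per_game %||% 25L
    p_reward_target <- p_reward_target %||% 0.75
    p_reward_nontarget <- p_reward_nontarget %||% 0.25
  }
  stopifnot(
    p_reward_target >= 0, p_reward_target <= 1,
    p_reward_nontarget >= 0, p_reward_nontarget <= 1,
    n_games >= 1, trials_per_game >= 1,
    length(reversal_interval) == 2,
    reversal_interval[1] <= reversal_interval[2],
    reversal_interval[1] >= 1
  )
  structure(list(
    task_kind = task_kind,
    n_games = as.integer(n_games),
    trials_per_game = as.integer(trials_per_game),
    p_reward_target = p_reward_target,
    p_reward_nontarget = p_reward_nontarget,
    reversal_interval = as.integer(reversal_interval),
    n_images = 9L, n_categories = 3L, n_columns = 3L
  ), class = "task_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

n_trials <- function(config) config$n_games * config$trials_per_game

#' Image identity labels
#'
#' Images are coded 1..9; image `i` belongs to category `(i - 1) %/% 3 + 1`.
#' Labels follow the `"cat<k>_img<j>"` convention (0-based) used in the
#' session CSV format.
#'
#' @param ids integer image ids in 1..9.
#' @return character labels.
#' @export
image_label <- function(ids) {
  stopifnot(all(ids %in% 1:9))
  sprintf("cat%d_img%d", (ids - 1L) %/% 3L, (ids - 1L) %% 3L)
}

#' @rdname image_label
#' @param labels labels of the form "cat0_img0" .. "cat2_img2".
#' @export
image_id <- function(labels) {
  m <- regmatches(labels, regexec("^cat([0-2])_img([0-2])$", labels))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("invalid image label(s): ", paste(labels[bad], collapse = ", "))
  cat <- as.integer(vapply(m, `[`, "", 2L))
  img <- as.integer(vapply(m, `[`, "", 3L))
  cat * 3L + img + 1L
}

#' Draw the per-trial target schedule
#'
#' Signalled task: one uniformly drawn target per game, with consecutive
#' games forced to differ. Reversal task: segment lengths drawn uniformly
#' from the configured interval (default 20..30 trials), the final segment
#' truncated at the session end; each new target is drawn uniformly from the
#' eight other images.
#'
#' @param config a [task_config()].
#' @return integer vector of image ids, one per trial.
#' @export
make_target_schedule <- function(config) {
  nt <- n_trials(config)
  if (config$task_kind == "signalled") {
    targets <- integer(config$n_games)
    targets[1] <- sample.int(9L, 1L)
    if (config$n_games > 1) {
      for (g in 2:config$n_games) {
        targets[g] <- sample(setdiff(1:9, targets[g - 1]), 1L)
      }
    }
    return(rep(targets, each = config$trials_per_game))
  }
  lo <- config$reversal_interval[1]; hi <- config$reversal_interval[2]
  schedule <- integer(0)
  target <- sample.int(9L, 1L)
  while (length(schedule) < nt) {
    len <- if (lo == hi) lo else sample(seq.int(lo, hi), 1L)
    schedule <- c(schedule, rep(target, len))
    target <- sample(setdiff(1:9, target), 1L)
  }
  schedule[seq_len(nt)]
}

#' Shuffle a trial layout
#'
#' Each category row is an independent uniform permutation of its three
#' images, so every column (composite stimulus) contains exactly one image
#' from each category.
#'
#' @return a 3x3 integer matrix; entry `[r, c]` is the image shown at
#'   category row `r`, column `c`.
#' @export
shuffle_layout <- function() {
  m <- matrix(0L, 3, 3)
  for (r in 1:3) m[r, ] <- sample((r - 1L) * 3L + 1:3)
  m
}

layout_column <- function(layout, col) layout[, col]

validate_layout <- function(layout) {
  if (!is.matrix(layout) || !all(dim(layout) == c(3, 3)))
    stop("layout must be a 3x3 matrix")
  for (r in 1:3) {
    if (!setequal(layout[r, ], (r - 1L) * 3L + 1:3))
      stop("layout row ", r, " does not contain the three images of category ", r)
  }
  invisible(layout)
}

#' Sample a reward outcome for a choice
#'
#' Bernoulli with the target reward probability if the chosen column
#' contains the current target, the non-target probability otherwise.
#'
#' @param choice_col chosen column, 1..3.
#' @param layout 3x3 layout matrix (see [shuffle_layout()]).
#' @param target image id of the current target.
#' @param config a [task_config()].
#' @return reward, 0 or 1.
#' @export
emit_outcome <- function(choice_col, layout, target, config) {
  if (is.na(choice_col) || !(choice_col %in% 1:3))
    stop("choice_col must be 1, 2 or 3 (simulation never produces a non-response)")
  hit <- target %in% layout[, choice_col]
  pr <- if (hit) config$p_reward_target else config$p_reward_nontarget
  rbinom(1L, 1L, pr)
}

#' Run a closed-loop session
#'
#' Drives an agent through one full session of either task. An agent is a
#' list of closures: `reset()` called at session start, `choose(layout)`
#' returning a column in 1..3, and `observe(layout, choice, reward)`. If the
#' agent provides `new_game()`, it is called at every game boundary of the
#' signalled task (target changes are announced there).
#'
#' @param agent agent object (see e.g. [hmm_agent()], [rl_agent()]).
#' @param config a [task_config()].
#' @param subject_id subject identifier stored in the log.
#' @param seed optional RNG seed; the caller's RNG state is restored.
#' @param targets optional precomputed target schedule (one image id per
#'   trial); drawn from `config` when NULL.
#' @return a `session_log`: list with `config`, `subject_id`, a trial
#'   data frame (`trial` 0-based, `game` 1-based, `target`, `choice`,
#'   `reward`) and an `n x 9` layout matrix in row-major (category, column)
#'   order.
#' @export
run_session <- function(agent, config, subject_id = "s1", seed = NULL,
                        targets = NULL) {
  with_seed(seed, {
    nt <- n_trials(config)
    targets <- targets %||% make_target_schedule(config)
    stopifnot(length(targets) == nt, all(targets %in% 1:9))
    game <- rep(seq_len(config$n_games), each = config$trials_per_game)
    layouts <- matrix(0L, nt, 9L)
    choice <- integer(nt); reward <- integer(nt)
    agent$reset()
    for (t in seq_len(nt)) {
      if (t > 1 && game[t] != game[t - 1] && config$task_kind == "signalled" &&
          is.function(agent$new_game)) {
        agent$new_game()
      }
      lay <- shuffle_layout()
      layouts[t, ] <- as.integer(t(lay))  # row-major: (r-1)*3 + c
      ch <- agent$choose(lay)
      if (length(ch) != 1L || is.na(ch) || !(ch %in% 1:3))
        stop("agent returned an invalid column at trial ", t)
      rw <- emit_outcome(ch, lay, targets[t], config)
      agent$observe(lay, ch, rw)
      choice[t] <- as.integer(ch); reward[t] <- as.integer(rw)
    }
    structure(list(
      config = config,
      subject_id = subject_id,
      trials = data.frame(
        trial = seq_len(nt) - 1L, game = game, target = targets,
        choice = choice, reward = reward
      ),
      layouts = layouts
    ), class = "session_log")
  })
}

#' @exportS3Method base::print
print.session_log <- function(x, ...) {
  cat(sprintf(
    "<session_log> subject %s, %s task, %d trials, mean reward %.3f\n",
    x$subject_id, x$config$task_kind, nrow(x$trials), mean(x$trials$reward)
  ))
  invisible(x)
}

# Layout of trial t as a 3x3 matrix.
trial_layout <- function(session, t) {
  matrix(session$layouts[t, ], 3, 3, byrow = TRUE)
}

# Does the chosen column of trial t contain image `img`? NA choice -> FALSE.
choice_contains <- function(session, t, img) {
  ch <- session$trials$choice[t]
  if (is.na(ch)) return(FALSE)
  img %in% session$layouts[t, (0:2) * 3L + ch]
}

#' Simple reference agents
#'
#' `omniscient_agent()` always picks the column containing the true target
#' (it must be told the schedule); `random_agent()` chooses uniformly.
#' Mainly used in tests and illustrations.
#'
#' @param targets per-trial target schedule for the omniscient agent.
#' @return an agent list.
#' @export
random_agent <- function() {
  list(reset = function() NULL,
       choose = function(layout) sample.int(3L, 1L),
       observe = function(layout, choice, reward) NULL)
}

#' @rdname random_agent
#' @export
omniscient_agent <- function(targets) {
  t <- 0L
  env <- environment()
  list(
    reset = function() assign("t", 0L, envir = env),
    choose = function(layout) {
      assign("t", t + 1L, envir = env)
      which(apply(layout, 2, function(col) env$targets[env$t] %in% col))
    },
    observe = function(layout, choice, reward) NULL
  )
}
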