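#' Trial-wise accuracy record
#'
#' A choice is correct when the chosen column contains the current true
#' target; non-responses (NA choice, imported data only) are scored as
#' errors. Trial indices are centred around 0 (for a 125-trial session:
#' -62..62), the convention used by the learning mixed models.
#'
#' @param session a `session_log`.
#' @return data frame: `subject_id`, `trial` (0-based), `trial_c` (centred),
#'   `correct` (0/1).
#' @export
score_accuracy <- function(session) {
  tr <- session$trials
  n <- nrow(tr)
  ch <- tr$choice
  idx <- (0:2) * 3L
  correct <- vapply(seq_len(n), function(t) {
    if (is.na(ch[t])) return(0L)
    as.integer(tr$target[t] %in% session$layouts[t, idx + ch[t]])
  }, 0L)
  data.frame(
    subject_id = session$subject_id,
    trial = tr$trial,
    trial_c = tr$trial - (n - 1) / 2,
    correct = correct
  )
}

#' Probabilistic-error statistics for one reversal session
#'
#' Within each true-target segment, the subject reaches the learning
#' criterion at the first run of `criterion` consecutive correct choices.
#' Every later trial in the segment where the subject chose the still-true
#' target but received (probabilistic) negative feedback is an
#' *opportunity*; it counts as a probabilistic error (*shift*) when the next
#' trial's choice column does not contain that target. The criterion resets
#' at every reversal. Opportunities on the final trial of a segment are, by
#' default, judged against the first post-reversal choice (the subject
#' cannot know the reversal occurred); opportunities on the session's last
#' trial, or followed by a non-response, are dropped. Subjects with no
#' opportunities are flagged ineligible.
#'
#' @param session a reversal-task `session_log`.
#' @param criterion consecutive correct choices defining learning (default 5).
#' @param judge_across_reversal keep opportunities whose next trial falls
#'   after a reversal (default TRUE).
#' @return data frame: `subject_id`, `n_opportunities`, `n_shifts`,
#'   `proportion` (NA when ineligible), `eligible`.
#' @export
probabilistic_errors <- function(session, criterion = 5,
                                 judge_across_reversal = TRUE) {
  tr <- session$trials
  n <- nrow(tr)
  idx <- (0:2) * 3L
  contains <- function(t, img) {
    ch <- tr$choice[t]
    !is.na(ch) && img %in% session$layouts[t, idx + ch]
  }
  correct <- vapply(seq_len(n), function(t) contains(t, tr$target[t]), FALSE)

  segs <- rle(tr$target)
  ends <- cumsum(segs$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)

  n_opp <- 0L; n_shift <- 0L
  for (k in seq_along(starts)) {
    s <- starts[k]; e <- ends[k]
    target <- segs$values[k]
    # first completion of `criterion` consecutive correct choices
    run <- 0L; crit_at <- NA_integer_
    for (t in s:e) {
      run <- if (correct[t]) run + 1L else 0L
      if (run >= criterion) { crit_at <- t; break }
    }
    if (is.na(crit_at) || crit_at + 1L > e) next
    for (t in seq.int(crit_at + 1L, e)) {
      if (!correct[t] || tr$reward[t] != 0) next
      nxt <- t + 1L
      if (nxt > n) next                       # no next choice: dropped
      if (t == e && !judge_across_reversal) next
      if (is.na(tr$choice[nxt])) next         # non-response: dropped
      n_opp <- n_opp + 1L
      if (!contains(nxt, target)) n_shift <- n_shift + 1L
    }
  }
  data.frame(
    subject_id = session$subject_id,
    n_opportunities = n_opp, n_shifts = n_shift,
    proportion = if (n_opp > 0) n_shift / n_opp else NA_real_,
    eligible = n_opp > 0L
  )
}

ridge_logit_slope <- function(trial_c, correct, lambda = 0.01) {
  X <- cbind(1, trial_c)
  b <- c(0, 0)
  for (i in 1:50) {
    eta <- drop(X %*% b)
    mu <- plogis(eta)
    W <- mu * (1 - mu)
    P <- diag(c(1e-8, lambda))
    H <- crossprod(X, X * W) + P
    g <- crossprod(X, correct - mu) - P %*% b
    step <- solve(H, g)
    b <- b + drop(step)
    if (max(abs(step)) < 1e-8) break
  }
  b[2]
}

#' Group learning model and per-subject learning slopes
#'
#' Fits the mixed logistic learning model `correct ~ trial_c` with
#' by-subject random intercepts and trial slopes, and returns the group
#' fixed effects together with the per-subject conditional (shrunken)
#' slopes used as the learning outcome in downstream trait analyses. If the
#' mixed model fails to converge, per-subject ridge-penalised logistic
#' slopes are returned instead (flagged in the result).
#'
#' @param acc stacked accuracy records (see [score_accuracy()]).
#' @param nagq `nAGQ` passed to [lme4::glmer()]; the default 0 uses the
#'   faster penalised-least-squares approximation, adequate for slope
#'   extraction at cohort scale.
#' @return list: `fixed` (coefficient table), `slopes` (data frame
#'   `subject_id`, `slope`), `method` ("glmm" or "ridge"), `model` (the
#'   fitted merMod or NULL).
#' @export
learning_slopes <- function(acc, nagq = 0) {
  stopifnot(length(unique(acc$subject_id)) >= 2)
  fit <- tryCatch(
    lme4::glmer(correct ~ trial_c + (trial_c | subject_id),
                data = acc, family = binomial, nAGQ = nagq,
                control = lme4::glmerControl(calc.derivs = FALSE)),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (!is.null(fit)) {
    co <- coef(fit)$subject_id
    slopes <- data.frame(subject_id = rownames(co), slope = co$trial_c)
    fixed <- coef(summary(fit))
    return(list(fixed = fixed, slopes = slopes, method = "glmm", model = fit))
  }
  by_subj <- split(acc, acc$subject_id)
  slopes <- data.frame(
    subject_id = names(by_subj),
    slope = vapply(by_subj, function(d)
      ridge_logit_slope(d$trial_c, d$correct), 0)
  )
  list(fixed = NULL, slopes = slopes, method = "ridge", model = NULL)
}

#' Factor-score learning mixed model
#'
#' The trait-learning model: `correct ~ trial_c * score` with by-subject
#' random intercepts and trial slopes. Run once per factor; the Factor x
#' Trial interaction is the learning-modulation effect of interest.
#'
#' @param acc stacked accuracy records.
#' @param scores data frame with `subject_id` and the factor column.
#' @param factor_name name of the factor column in `scores`.
#' @param nagq `nAGQ` for [lme4::glmer()].
#' @return coefficient table (log odds, se, z, p) with rows for the
#'   intercept, Trial, the factor main effect and the Factor x Trial
#'   interaction.
#' @export
factor_glmm <- function(acc, scores, factor_name, nagq = 0) {
  stopifnot(factor_name %in% names(scores))
  if (sd(scores[[factor_name]]) == 0)
    stop("factor '", factor_name, "' has zero variance")
  d <- merge(acc, scores[, c("subject_id", factor_name)], by = "subject_id")
  d$score <- d[[factor_name]]
  fit <- lme4::glmer(correct ~ trial_c * score + (trial_c | subject_id),
                     data = d, family = binomial, nAGQ = nagq,
                     control = lme4::glmerControl(calc.derivs = FALSE))
  tab <- coef(summary(fit))
  rownames(tab) <- sub("score", factor_name, rownames(tab))
  tab
}

#' Per-subject behavioural metrics table
#'
#' Convenience wrapper combining mean accuracy and probabilistic-error
#' statistics for a list of sessions.
#'
#' @param sessions list of `session_log`s.
#' @param criterion learning criterion for [probabilistic_errors()].
#' @return data frame, one row per subject.
#' @export
behaviour_metrics <- function(sessions, criterion = 5) {
  rows <- lapply(sessions, function(s) {
    acc <- score_accuracy(s)
    pe <- probabilistic_errors(s, criterion = criterion)
    cbind(data.frame(subject_id = s$subject_id,
                     mean_accuracy = mean(acc$correct)),
          pe[, c("n_opportunities", "n_shifts", "proportion", "eligible")])
  })
  do.call(rbind, rows)
}
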