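#' Synthetic cohort configuration
#'
#' Defines the study conditions of a simulated cohort: 427 subjects, each
#' described by nine trait factor scores and a three-parameter HMM agent
#' performing one 125-trial reversal session. Uncontrollable Stress and
#' (negatively-framed) State Anxiety are correlated standard normals; State
#' Anxiety is linked to the agent's volatility belief through
#' `logit(tr) = mu_tr + b * anxiety + noise`. The default slope `b = 0.124`
#' with residual sd `sqrt(1 - 0.124^2)` keeps the marginal sd of `logit(tr)`
#' at 1 and plants a population anxiety-logit(tr) correlation of exactly
#' 0.124. `q` and `p` are logit-normal: `q` centred below the true reward
#' probability 0.8, `p` skewed toward 1. The remaining seven factors are
#' independent standard-normal nuisance scores.
#'
#' @param n_subjects cohort size (default 427).
#' @param rho correlation between stress and state anxiety (default 0.5).
#' @param b anxiety-to-logit(tr) slope (default 0.124).
#' @param noise_sd residual sd of logit(tr) (default `sqrt(1 - b^2)` at the
#'   default `b`).
#' @param mu_tr baseline of logit(tr) (default -2.5).
#' @param q_mean,q_sd,p_mean,p_sd logit-scale distributions of q and p.
#' @param agent_model generative agent for every subject (default "hmm3").
#' @param task a [task_config()] (default reversal task).
#' @param seed master seed.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 427, rho = 0.5, b = 0.124,
                          noise_sd = sqrt(1 - 0.124^2), mu_tr = -2.5,
                          q_mean = 0.5, q_sd = 0.8,
                          p_mean = 2.2, p_sd = 0.8,
                          agent_model = "hmm3",
                          task = task_config("reversal"),
                          seed = 20201L) {
  stopifnot(n_subjects >= 2, rho > -1, rho < 1, noise_sd >= 0,
            agent_model %in% c("ba", "baf", "bafc", "hmm3", "hmm4"))
  structure(list(
    n_subjects = as.integer(n_subjects), rho = rho, b = b,
    noise_sd = noise_sd, mu_tr = mu_tr,
    q_mean = q_mean, q_sd = q_sd, p_mean = p_mean, p_sd = p_sd,
    agent_model = agent_model, task = task, seed = as.integer(seed)
  ), class = "cohort_config")
}

trait_factor_names <- function() {
  c("uncontrollable_stress", "state_anxiety_neg", "state_anxiety_pos",
    "trait_anxiety_neg", "trait_anxiety_pos", "lack_self_efficacy",
    "depression", "covid_likelihood", "covid_severity")
}

#' Sample the trait table of a synthetic cohort
#'
#' Draws the nine factor scores and each subject's true generative
#' parameters. Only `tr` is trait-linked (to negatively-framed State
#' Anxiety); stress correlates with anxiety at `rho`; the other seven
#' factors are independent noise.
#'
#' @param config a [cohort_config()].
#' @param seed optional seed (defaults to a child of the config seed).
#' @return data frame: `subject_id`, the nine factor columns, `true_q`,
#'   `true_p`, `true_tr`.
#' @export
sample_traits <- function(config, seed = child_seed(config$seed, "traits")) {
  with_seed(seed, {
    n <- config$n_subjects
    anxiety <- rnorm(n)
    stress <- config$rho * anxiety + sqrt(1 - config$rho^2) * rnorm(n)
    logit_tr <- config$mu_tr + config$b * anxiety +
      rnorm(n, sd = config$noise_sd)
    traits <- data.frame(
      subject_id = sprintf("sub%04d", seq_len(n)),
      uncontrollable_stress = stress,
      state_anxiety_neg = anxiety
    )
    for (nm in setdiff(trait_factor_names(),
                       c("uncontrollable_stress", "state_anxiety_neg"))) {
      traits[[nm]] <- rnorm(n)
    }
    traits$true_q <- plogis(rnorm(n, config$q_mean, config$q_sd))
    traits$true_p <- plogis(rnorm(n, config$p_mean, config$p_sd))
    traits$true_tr <- plogis(logit_tr)
    traits
  })
}

#' Build a full synthetic cohort
#'
#' Samples the trait table and runs each subject's generative agent through
#' one closed-loop session of the configured task. Deterministic given the
#' config's master seed (per-subject child seeds are derived by a fixed
#' rule).
#'
#' @param config a [cohort_config()].
#' @return a `cohort` list: `traits`, `sessions` (one `session_log` per
#'   subject), `config`.
#' @export
build_cohort <- function(config = cohort_config()) {
  traits <- sample_traits(config)
  sessions <- lapply(seq_len(config$n_subjects), function(i) {
    nat <- c(q = traits$true_q[i], p = traits$true_p[i], tr = traits$true_tr[i])
    if (config$agent_model == "hmm4") nat <- c(nat, power = 1)
    simulate_model(config$agent_model, nat, config$task,
                   subject_id = traits$subject_id[i],
                   seed = child_seed(config$seed, "session", i))
  })
  structure(list(traits = traits, sessions = sessions, config = config),
            class = "cohort")
}

#' @exportS3Method base::print
print.cohort <- function(x, ...) {
  acc <- vapply(x$sessions, function(s) mean(score_accuracy(s)$correct), 0)
  cat(sprintf("<cohort> %d subjects, %s agents on the %s task, mean accuracy %.3f\n",
              x$config$n_subjects, x$config$agent_model,
              x$config$task$task_kind, mean(acc)))
  invisible(x)
}

#' End-to-end synthetic analysis pipeline
#'
#' One-command replication of the analysis chain on a synthetic cohort:
#' build the cohort, fit the three-parameter HMM to every subject by MAP,
#' compute behavioural metrics and learning slopes, correlate State Anxiety
#' with the fitted transition parameter, and run the two trait mediations
#' (anxiety -> tr -> learning slopes; anxiety -> tr -> probabilistic-error
#' proportion, eligible subjects only).
#'
#' @param config a [cohort_config()].
#' @param n_boot mediation bootstrap resamples (default 1000).
#' @param n_restarts optimizer restarts per subject fit.
#' @param seed master seed for fitting/bootstrap streams (defaults to the
#'   config seed).
#' @param cohort optionally, a pre-built cohort (skips simulation).
#' @return a `pipeline_report` list: `cohort`, `fits`, `metrics`, `slopes`,
#'   `cor_anxiety_tr`, `mediation_slopes`, `mediation_prob_errors`.
#' @export
end_to_end <- function(config = cohort_config(), n_boot = 1000,
                       n_restarts = 5, seed = config$seed, cohort = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cohort <- cohort %||% stage("build_cohort", build_cohort(config))
  fits <- stage("fit_hmm3", {
    lapply(seq_along(cohort$sessions), function(i) {
      fit_subject(cohort$sessions[[i]],
                  fit_spec("hmm3", n_restarts = n_restarts,
                           seed = child_seed(seed, "fit", i)))
    })
  })
  tr_hat <- vapply(fits, function(f) f$estimate[["tr"]], 0)
  acc <- stage("accuracy", do.call(rbind, lapply(cohort$sessions, score_accuracy)))
  slopes <- stage("learning_slopes", learning_slopes(acc))
  metrics <- stage("metrics", behaviour_metrics(cohort$sessions))
  ord <- match(cohort$traits$subject_id, slopes$slopes$subject_id)
  slope_vec <- slopes$slopes$slope[ord]
  anxiety <- cohort$traits$state_anxiety_neg
  cor_tr <- stage("correlate", correlate(anxiety, tr_hat))
  med_slopes <- stage("mediation_slopes",
    mediate(anxiety, tr_hat, slope_vec, n_boot = n_boot,
            seed = child_seed(seed, "boot_slopes")))
  elig <- metrics$eligible[match(cohort$traits$subject_id, metrics$subject_id)]
  med_pe <- stage("mediation_prob_errors",
    mediate(anxiety[elig], tr_hat[elig],
            metrics$proportion[match(cohort$traits$subject_id,
                                     metrics$subject_id)][elig],
            n_boot = n_boot, seed = child_seed(seed, "boot_pe")))
  structure(list(
    cohort = cohort, fits = fits, metrics = metrics, slopes = slopes,
    tr_hat = setNames(tr_hat, cohort$traits$subject_id),
    cor_anxiety_tr = cor_tr,
    mediation_slopes = med_slopes,
    mediation_prob_errors = med_pe
  ), class = "pipeline_report")
}

#' @exportS3Method base::print
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  cohort: %d subjects, mean accuracy %.3f (%d eligible for prob errors)\n",
              nrow(x$cohort$traits), mean(x$metrics$mean_accuracy),
              sum(x$metrics$eligible)))
  cat(sprintf("  corr(state anxiety, fitted tr): r = %.3f, p = %.4f\n",
              x$cor_anxiety_tr$r, x$cor_anxiety_tr$p))
  cat(sprintf("  ACME anxiety -> tr -> learning slopes: %.4f (p = %.4f)\n",
              x$mediation_slopes$acme$estimate, x$mediation_slopes$acme$p))
  cat(sprintf("  ACME anxiety -> tr -> prob errors:     %.4f (p = %.4f)\n",
              x$mediation_prob_errors$acme$estimate,
              x$mediation_prob_errors$acme$p))
  invisible(x)
}
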