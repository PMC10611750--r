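#' Model space and parameter transforms
#'
#' Five candidate models are fitted on a shared unconstrained scale:
#' `ba`, `baf`, `bafc` (the RL family), `hmm3` and `hmm4` (the hidden
#' Markov observers). Parameters in (0,1) are logit-transformed, strictly
#' positive parameters log-transformed, and the sharpening exponent of
#' `hmm4` uses a scaled logit onto (0,5).
#'
#' @param model model id.
#' @return list with `names` and `trans` (one transform per parameter).
#' @export
model_param_info <- function(model) {
  switch(model,
    ba   = list(names = c("alpha", "beta"),
                trans = c("logit", "log")),
    baf  = list(names = c("alpha", "beta", "phi"),
                trans = c("logit", "log", "logit")),
    bafc = list(names = c("alpha_p", "alpha_n", "beta", "phi", "gamma", "kappa"),
                trans = c("logit", "logit", "log", "logit", "logit", "log")),
    hmm3 = list(names = c("q", "p", "tr"),
                trans = c("logit", "logit", "logit")),
    hmm4 = list(names = c("q", "p", "tr", "power"),
                trans = c("logit", "logit", "logit", "logit5")),
    stop("unknown model: ", model)
  )
}

to_natural <- function(theta, trans) {
  out <- theta
  out[trans == "logit"] <- plogis(theta[trans == "logit"])
  out[trans == "log"] <- exp(theta[trans == "log"])
  out[trans == "logit5"] <- 5 * plogis(theta[trans == "logit5"])
  out
}

to_transformed <- function(nat, trans) {
  out <- nat
  out[trans == "logit"] <- qlogis(nat[trans == "logit"])
  out[trans == "log"] <- log(nat[trans == "log"])
  out[trans == "logit5"] <- qlogis(nat[trans == "logit5"] / 5)
  out
}

# Build the parameter object for `model` from a named natural-scale vector.
make_model_params <- function(model, nat) {
  nat <- as.list(nat)
  switch(model,
    ba   = rl_params("ba", alpha = nat$alpha, beta = nat$beta),
    baf  = rl_params("baf", alpha = nat$alpha, beta = nat$beta, phi = nat$phi),
    bafc = rl_params("bafc", alpha_p = nat$alpha_p, alpha_n = nat$alpha_n,
                     beta = nat$beta, phi = nat$phi, gamma = nat$gamma,
                     kappa = nat$kappa),
    hmm3 = hmm_params(q = nat$q, p = nat$p, tr = nat$tr),
    hmm4 = hmm_params(q = nat$q, p = nat$p, tr = nat$tr, power = nat$power),
    stop("unknown model: ", model)
  )
}

#' Session log-likelihood for any model in the space
#'
#' @param model model id.
#' @param nat named natural-scale parameter vector.
#' @param session a `session_log`.
#' @return scalar log-likelihood.
#' @export
model_loglik <- function(model, nat, session) {
  params <- make_model_params(model, nat)
  if (inherits(params, "hmm_params")) hmm_loglik(params, session)
  else rl_loglik(params, session)
}

#' Fit specification
#'
#' Bundles a model id with its transformed-scale Gaussian prior, the number
#' of optimizer restarts (drawn from the prior, plus the prior mean itself),
#' and optimizer controls. The default prior N(0, 3^2) is weakly
#' informative on every transformed parameter.
#'
#' @param model model id.
#' @param prior_mean,prior_sd prior location/scale, recycled over parameters.
#' @param n_restarts optimizer restarts (prior draws; the prior mean is
#'   always the first start).
#' @param maxit BFGS iteration cap per restart.
#' @param seed optional seed for the restart draws.
#' @return a `fit_spec` list.
#' @export
fit_spec <- function(model, prior_mean = 0, prior_sd = 3,
                     n_restarts = 5, maxit = 500, seed = NULL) {
  info <- model_param_info(model)
  d <- length(info$names)
  structure(list(
    model = model,
    par_names = info$names,
    trans = info$trans,
    prior_mean = setNames(rep_len(prior_mean, d), info$names),
    prior_sd = setNames(rep_len(prior_sd, d), info$names),
    n_restarts = n_restarts,
    maxit = maxit,
    seed = seed
  ), class = "fit_spec")
}

#' Fit one subject by MAP with a Laplace evidence
#'
#' Maximises the log joint (log-likelihood plus transformed-scale Gaussian
#' log prior) by multi-restart BFGS and approximates the log model evidence
#' by the Laplace formula: log joint at the MAP plus `d/2 * log(2*pi)` minus
#' half the log determinant of the negative Hessian. A non-positive-definite
#' Hessian is ridge-regularised; if every restart fails the fit is flagged
#' and carries a `-Inf` evidence sentinel.
#'
#' @param session a `session_log`.
#' @param spec a [fit_spec()].
#' @return a `subject_fit` list: natural and transformed estimates,
#'   log-likelihood, log evidence, convergence flag.
#' @export
fit_subject <- function(session, spec) {
  d <- length(spec$par_names)
  negjoint <- function(theta) {
    ll <- tryCatch(
      model_loglik(spec$model, setNames(to_natural(theta, spec$trans),
                                        spec$par_names), session),
      error = function(e) -Inf
    )
    lp <- sum(dnorm(theta, spec$prior_mean, spec$prior_sd, log = TRUE))
    out <- -(ll + lp)
    if (!is.finite(out)) 1e10 else out
  }
  starts <- with_seed(spec$seed, {
    s <- matrix(rnorm((spec$n_restarts - 1) * d,
                      mean = rep(spec$prior_mean, each = spec$n_restarts - 1),
                      sd = rep(spec$prior_sd, each = spec$n_restarts - 1)),
                ncol = d)
    rbind(spec$prior_mean, s)
  })
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    res <- tryCatch(
      optim(starts[k, ], negjoint, method = "BFGS",
            control = list(maxit = spec$maxit)),
      error = function(e) NULL
    )
    if (!is.null(res) && is.finite(res$value) && res$value < 1e9 &&
        (is.null(best) || res$value < best$value)) {
      best <- res
    }
  }
  if (is.null(best)) {
    return(structure(list(
      subject_id = session$subject_id, model = spec$model,
      estimate = setNames(rep(NA_real_, d), spec$par_names),
      theta = setNames(rep(NA_real_, d), spec$par_names),
      loglik = NA_real_, log_evidence = -Inf, convergence = FALSE
    ), class = "subject_fit"))
  }
  theta <- setNames(best$par, spec$par_names)
  nat <- setNames(to_natural(theta, spec$trans), spec$par_names)
  H <- tryCatch(optimHess(best$par, negjoint), error = function(e) NULL)
  logdet <- NA_real_
  ok <- TRUE
  if (!is.null(H)) {
    H <- (H + t(H)) / 2
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) {
      ev <- pmax(ev, 1e-6)  # ridge the flat directions
      ok <- FALSE
    }
    logdet <- sum(log(ev))
  } else {
    ok <- FALSE
    logdet <- d * log(1e6)  # conservative fallback: sharp curvature
  }
  ll <- model_loglik(spec$model, nat, session)
  evidence <- -best$value + d / 2 * log(2 * pi) - logdet / 2
  structure(list(
    subject_id = session$subject_id, model = spec$model,
    estimate = nat, theta = theta,
    loglik = ll, log_evidence = evidence,
    convergence = ok && best$convergence == 0
  ), class = "subject_fit")
}

#' @exportS3Method base::print
print.subject_fit <- function(x, ...) {
  cat(sprintf("<subject_fit> %s, model %s, logev %.2f\n",
              x$subject_id, x$model, x$log_evidence))
  print(round(x$estimate, 4))
  invisible(x)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Empirical-Bayes hierarchical fitting across models
#'
#' A simplified random-effects loop in the spirit of hierarchical Bayesian
#' inference toolboxes: (1) fit each subject under each model's current
#' transformed-scale Gaussian prior; (2) convert per-subject log evidences
#' into model responsibilities; (3) re-estimate each model's prior as the
#' responsibility-weighted mean and standard deviation of the subject MAPs,
#' so that subjects contribute to a model's group estimates in proportion to
#' how likely that model is for them. Iterates to a prior-change tolerance
#' or `max_iter`. Prior standard deviations are floored at 0.1.
#'
#' @param sessions list of `session_log`s (>= 2 subjects).
#' @param specs named list of [fit_spec()]s, one per candidate model.
#' @param max_iter maximum empirical-Bayes iterations (1 = a single pass of
#'   independently regularised fits).
#' @param tol stop when no prior mean or sd moves more than this.
#' @return list with `group` (a `group_fit`: responsibilities, model
#'   frequencies, per-model priors) and `fits` (per-model lists of
#'   `subject_fit`s).
#' @export
empirical_bayes <- function(sessions, specs, max_iter = 10, tol = 1e-2) {
  stopifnot(length(sessions) >= 2, length(specs) >= 1)
  models <- names(specs)
  if (is.null(models)) {
    models <- vapply(specs, `[[`, "", "model")
    names(specs) <- models
  }
  n <- length(sessions)
  fits <- NULL
  resp <- NULL
  for (iter in seq_len(max_iter)) {
    fits <- lapply(specs, function(sp) lapply(sessions, fit_subject, spec = sp))
    L <- vapply(fits, function(fm) vapply(fm, `[[`, 0, "log_evidence"),
                numeric(n))
    L <- matrix(L, nrow = n, dimnames = list(NULL, models))
    resp <- t(apply(L, 1, function(row) {
      w <- row - logsumexp(row)
      exp(w)
    }))
    resp <- matrix(resp, nrow = n, dimnames = list(NULL, models))
    if (iter == max_iter) break
    moved <- 0
    for (m in models) {
      th <- t(vapply(fits[[m]], `[[`, numeric(length(specs[[m]]$par_names)),
                     "theta"))
      th <- matrix(th, nrow = n)
      w <- resp[, m]
      if (sum(w) < 1e-8) next  # model carries no mass; keep its prior
      wm <- colSums(w * th) / sum(w)
      wv <- colSums(w * sweep(th, 2, wm)^2) / sum(w)
      ws <- pmax(sqrt(wv), 0.1)
      moved <- max(moved,
                   max(abs(wm - specs[[m]]$prior_mean)),
                   max(abs(ws - specs[[m]]$prior_sd)))
      specs[[m]]$prior_mean[] <- wm
      specs[[m]]$prior_sd[] <- ws
    }
    if (moved < tol) break
  }
  group <- structure(list(
    models = models,
    responsibilities = resp,
    frequency = colMeans(resp),
    priors = lapply(specs, function(sp)
      list(mean = sp$prior_mean, sd = sp$prior_sd))
  ), class = "group_fit")
  list(group = group, fits = fits)
}

#' Random-effects model comparison
#'
#' Model frequencies are the mean responsibilities; exceedance probabilities
#' are the posterior probability that each model's population frequency is
#' the largest, under a Dirichlet posterior with concentration
#' `1 + column sums of responsibilities`, estimated by Monte-Carlo draws.
#'
#' @param group a `group_fit` (from [empirical_bayes()]).
#' @param n_draws Dirichlet Monte-Carlo draws (default 1e5).
#' @param seed optional seed for the draws.
#' @return list with `frequency` and `exceedance`, both named and summing
#'   to 1.
#' @export
compare_models <- function(group, n_draws = 1e5, seed = NULL) {
  resp <- group$responsibilities
  conc <- 1 + colSums(resp)
  k <- length(conc)
  exceed <- with_seed(seed, {
    g <- matrix(rgamma(n_draws * k, shape = rep(conc, each = n_draws)),
                nrow = n_draws)
    win <- max.col(g, ties.method = "first")
    tabulate(win, nbins = k) / n_draws
  })
  list(frequency = setNames(colMeans(resp), group$models),
       exceedance = setNames(exceed, group$models))
}

#' Generative sampling distributions for recoverability runs
#'
#' Transformed-scale Gaussian distributions from which simulated subjects'
#' parameters are drawn. HMM parameters follow the package's default study
#' conditions (q ~ logit-N(0.5, 0.8^2) -- underestimating the true 0.8
#' reward probability; p ~ logit-N(2.2, 0.8^2) -- skewed toward 1;
#' tr ~ logit-N(-2.5, 1)); RL parameters use moderate logit-/log-normals.
#'
#' @return named list: per model, `mean` and `sd` vectors on the
#'   transformed scale.
#' @export
default_generative_dists <- function() {
  list(
    ba   = list(mean = c(alpha = 0, beta = 1),
                sd   = c(alpha = 1, beta = 0.5)),
    baf  = list(mean = c(alpha = 0, beta = 1, phi = -1),
                sd   = c(alpha = 1, beta = 0.5, phi = 1)),
    bafc = list(mean = c(alpha_p = 0, alpha_n = 0, beta = 1, phi = -1,
                         gamma = -1, kappa = -0.5),
                sd   = c(alpha_p = 1, alpha_n = 1, beta = 0.5, phi = 1,
                         gamma = 1, kappa = 0.5)),
    hmm3 = list(mean = c(q = 0.5, p = 2.2, tr = -2.5),
                sd   = c(q = 0.8, p = 0.8, tr = 1.0)),
    hmm4 = list(mean = c(q = 0.5, p = 2.2, tr = -2.5, power = 0),
                sd   = c(q = 0.8, p = 0.8, tr = 1.0, power = 1))
  )
}

#' Sample natural-scale parameters for simulated subjects
#'
#' @param model model id.
#' @param n number of subjects.
#' @param dists generative distributions (see [default_generative_dists()]).
#' @return data frame of natural-scale parameters, one row per subject.
#' @export
sample_generative_params <- function(model, n, dists = default_generative_dists()) {
  info <- model_param_info(model)
  g <- dists[[model]]
  stopifnot(!is.null(g), setequal(names(g$mean), info$names))
  th <- vapply(info$names, function(nm) rnorm(n, g$mean[[nm]], g$sd[[nm]]),
               numeric(n))
  th <- matrix(th, nrow = n, dimnames = list(NULL, info$names))
  nat <- th
  for (j in seq_along(info$names))
    nat[, j] <- to_natural(th[, j], rep(info$trans[j], n))
  as.data.frame(nat)
}

#' Simulate a session from any model in the space
#'
#' @param model model id.
#' @param nat named natural-scale parameter vector.
#' @param config a [task_config()].
#' @param subject_id,seed passed to [run_session()].
#' @return a `session_log`.
#' @export
simulate_model <- function(model, nat, config = task_config("reversal"),
                           subject_id = "s1", seed = NULL) {
  params <- make_model_params(model, nat)
  ag <- if (inherits(params, "hmm_params")) hmm_agent(params)
        else rl_agent(params)
  run_session(ag, config, subject_id = subject_id, seed = seed)
}

#' Recoverability pipeline
#'
#' For each generative model: draw `n_sims` parameter sets, simulate one
#' session each, fit every candidate model standalone (independent MAP fits
#' under the default prior), convert evidences into responsibilities and
#' model frequencies (one confusion-matrix row), and correlate the
#' generative against the recovered parameters for the generative model's
#' own fits.
#'
#' @param generative_models models to simulate from.
#' @param n_sims simulated subjects per generative model.
#' @param fit_models models fitted to each data set (default: the
#'   generative set).
#' @param config a [task_config()].
#' @param dists generative sampling distributions.
#' @param seed master seed.
#' @param n_restarts optimizer restarts per fit.
#' @return a `recovery_report`: `confusion` (generative x fitted model
#'   frequencies), `exceedance` (same shape), `correlations` (per model,
#'   named Pearson r per parameter), `params` (generative and recovered
#'   values), `n_sims`, `seed`.
#' @export
recoverability <- function(generative_models = c("ba", "baf", "bafc", "hmm3"),
                           n_sims = 100,
                           fit_models = generative_models,
                           config = task_config("reversal"),
                           dists = default_generative_dists(),
                           seed = 1, n_restarts = 5) {
  confusion <- matrix(NA_real_, length(generative_models), length(fit_models),
                      dimnames = list(generative_models, fit_models))
  exceed <- confusion
  correlations <- list()
  params_out <- list()
  for (g in generative_models) {
    gen <- with_seed(child_seed(seed, "genpar", match(g, generative_models)),
                     sample_generative_params(g, n_sims, dists))
    sessions <- lapply(seq_len(n_sims), function(i) {
      simulate_model(g, unlist(gen[i, ]), config,
                     subject_id = sprintf("%s_%03d", g, i),
                     seed = child_seed(seed, paste0("sim_", g), i))
    })
    specs <- lapply(fit_models, function(m)
      fit_spec(m, n_restarts = n_restarts,
               seed = child_seed(seed, paste0("fit_", g, "_", m))))
    names(specs) <- fit_models
    eb <- empirical_bayes(sessions, specs, max_iter = 1)
    cmp <- compare_models(eb$group, seed = child_seed(seed, paste0("dir_", g)))
    confusion[g, ] <- cmp$frequency
    exceed[g, ] <- cmp$exceedance
    if (g %in% fit_models) {
      rec <- t(vapply(eb$fits[[g]], `[[`,
                      numeric(length(model_param_info(g)$names)), "estimate"))
      rec <- as.data.frame(matrix(rec, nrow = n_sims,
                                  dimnames = list(NULL, model_param_info(g)$names)))
      correlations[[g]] <- vapply(names(gen), function(nm)
        suppressWarnings(cor(gen[[nm]], rec[[nm]])), 0)
      params_out[[g]] <- list(generative = gen, recovered = rec)
    }
  }
  structure(list(confusion = confusion, exceedance = exceed,
                 correlations = correlations, params = params_out,
                 n_sims = n_sims, seed = seed),
            class = "recovery_report")
}

#' @exportS3Method base::print
print.recovery_report <- function(x, ...) {
  cat("<recovery_report> model frequencies (rows = generative):\n")
  print(round(x$confusion, 3))
  for (m in names(x$correlations)) {
    cat(sprintf("%s parameter recovery r: %s\n", m,
                paste(sprintf("%s=%.3f", names(x$correlations[[m]]),
                              x$correlations[[m]]), collapse = ", ")))
  }
  invisible(x)
}
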