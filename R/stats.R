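#' Holm step-down multiple-comparison correction
#'
#' P-values are ordered from smallest to largest; the rank-`k` p-value is
#' significant when `p_k < alpha / (m + 1 - k)` and all smaller ranks were
#' significant (the step-down stops at the first failure, so the set of
#' rejections is a prefix of the sorted order).
#'
#' @param pvalues numeric p-values in \[0, 1\].
#' @param alpha family-wise error level (default 0.05).
#' @return a `holm_result` data frame, in input order: `p`, `rank`,
#'   `threshold`, `significant`.
#' @export
holm <- function(pvalues, alpha = 0.05) {
  if (length(pvalues) == 0) stop("empty p-value vector")
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  m <- length(pvalues)
  ord <- order(pvalues)
  rank <- integer(m); rank[ord] <- seq_len(m)
  threshold <- alpha / (m + 1 - rank)
  pass <- pvalues[ord] < alpha / (m + 1 - seq_len(m))
  keep <- cumprod(pass) == 1          # step-down: stop at first failure
  significant <- logical(m)
  significant[ord] <- keep
  structure(
    data.frame(p = pvalues, rank = rank, threshold = threshold,
               significant = significant),
    class = c("holm_result", "data.frame"), alpha = alpha
  )
}

#' Pearson correlation with a two-sided t-test
#'
#' @param x,y paired finite numeric vectors.
#' @return list with `r`, `p`, `n`, `conf_int`.
#' @export
correlate <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) stop("constant input in correlate()")
  ct <- cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       conf_int = unname(ct$conf.int))
}

#' Bootstrap causal mediation (linear structural equations)
#'
#' Fits `mediator ~ predictor` and `outcome ~ predictor + mediator` by
#' ordinary least squares. The average causal mediated effect (ACME) is the
#' product of the predictor-to-mediator and mediator-to-outcome
#' coefficients; the average direct effect (ADE) is the predictor
#' coefficient of the outcome model; the total effect is their sum, and the
#' proportion mediated is ACME / total at the point estimates. Confidence
#' intervals and p-values come from a nonparametric subject-resampling
#' percentile bootstrap.
#'
#' @param predictor,mediator,outcome numeric vectors (complete triples).
#' @param n_boot bootstrap resamples (default 10000).
#' @param conf confidence level (default 0.95).
#' @param seed optional bootstrap seed (recorded in the result).
#' @return a `mediation_result` list: per effect (`acme`, `ade`, `total`,
#'   `prop_mediated`) the point estimate, CI and bootstrap p-value, plus
#'   `n`, `n_boot`, `seed`.
#' @export
mediate <- function(predictor, mediator, outcome, n_boot = 10000,
                    conf = 0.95, seed = NULL) {
  ok <- complete.cases(predictor, mediator, outcome)
  x <- predictor[ok]; m <- mediator[ok]; y <- outcome[ok]
  n <- length(x)
  if (n < 10) stop("mediation requires at least 10 complete cases")

  effects <- function(x, m, y) {
    a <- .lm.fit(cbind(1, x), m)$coefficients[2]
    cb <- .lm.fit(cbind(1, x, m), y)$coefficients
    acme <- a * cb[3]
    ade <- cb[2]
    c(acme = unname(acme), ade = unname(ade), total = unname(acme + ade))
  }
  pt <- effects(x, m, y)
  pt <- c(pt, prop_mediated = unname(pt["acme"] / pt["total"]))

  boots <- with_seed(seed, {
    t(vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      e <- effects(x[i], m[i], y[i])
      c(e, prop_mediated = unname(e["acme"] / e["total"]))
    }, numeric(4)))
  })
  lo <- (1 - conf) / 2
  summarise <- function(k) {
    bs <- boots[, k]
    bs <- bs[is.finite(bs)]
    ci <- quantile(bs, c(lo, 1 - lo), names = FALSE)
    pv <- min(1, 2 * min(mean(bs <= 0), mean(bs >= 0)))
    list(estimate = unname(pt[k]), ci_lower = ci[1], ci_upper = ci[2], p = pv)
  }
  structure(list(
    acme = summarise("acme"), ade = summarise("ade"),
    total = summarise("total"), prop_mediated = summarise("prop_mediated"),
    n = n, n_boot = n_boot, seed = seed
  ), class = "mediation_result")
}

#' @exportS3Method base::print
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> n = %d, %d bootstraps\n", x$n, x$n_boot))
  for (k in c("acme", "ade", "total", "prop_mediated")) {
    e <- x[[k]]
    cat(sprintf("  %-14s %8.4f  [%.4f, %.4f]  p = %.4f\n",
                toupper(k), e$estimate, e$ci_lower, e$ci_upper, e$p))
  }
  invisible(x)
}

#' Two-way random-effects intraclass correlation (absolute agreement,
#' single measures)
#'
#' Test-retest agreement between two sessions from the standard two-way
#' ANOVA mean-squares decomposition (subjects and sessions both random):
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` with `k = 2`
#' raters. The p-value uses `F = MSR / MSE` on (n-1, (n-1)(k-1)) degrees of
#' freedom; the confidence interval follows the Satterthwaite approximation
#' of McGraw and Wong.
#'
#' @param session1,session2 paired measurements (n >= 3).
#' @param conf confidence level (default 0.95).
#' @return an `icc_result` list: `icc`, `p`, `ci_lower`, `ci_upper`, `n`.
#' @export
icc_two_way <- function(session1, session2, conf = 0.95) {
  ok <- complete.cases(session1, session2)
  x <- cbind(session1[ok], session2[ok])
  n <- nrow(x); k <- 2
  if (n < 3) stop("ICC requires at least 3 paired measurements")
  row_m <- rowMeans(x); col_m <- colMeans(x); grand <- mean(x)
  if (var(row_m) == 0 && var(col_m) == 0)
    stop("zero variance in both subjects and sessions")
  SSR <- k * sum((row_m - grand)^2)
  SSC <- n * sum((col_m - grand)^2)
  SST <- sum((x - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1); MSC <- SSC / (k - 1); MSE <- SSE / ((n - 1) * (k - 1))
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  Fv <- MSR / MSE
  p <- 1 - pf(Fv, n - 1, (n - 1) * (k - 1))
  alpha <- 1 - conf
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  FL <- qf(1 - alpha / 2, n - 1, v)
  FU <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  upper <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  structure(list(icc = icc, p = p, ci_lower = lower, ci_upper = upper, n = n),
            class = "icc_result")
}

#' @exportS3Method base::print
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC = %.3f, p = %.4f, %d%% CI [%.3f, %.3f], n = %d\n",
              x$icc, x$p, 95L, x$ci_lower, x$ci_upper, x$n))
  invisible(x)
}
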