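## Survival and association statistics: Kaplan-Meier, log-rank, Cox with
## stepwise selection and an explained-variation R2, logistic regression,
## 2x2 odds ratios with Wald intervals, rank correlation and two-group
## comparisons.  Ordinary model fits are delegated to the survival package
## and stats::glm; the log-rank statistic itself is computed here because
## the running-cutpoint scan needs it as a bare function.

## Multi-group log-rank chi-square (O-E form with the hypergeometric
## covariance), identical to the score test of a Cox fit on the group
## indicator with Breslow ties.
.logrank_chisq <- function(time, event, group) {
  g <- as.factor(group)
  lv <- levels(g)
  k <- length(lv)
  if (k < 2) stop("log-rank needs at least 2 groups")
  if (any(table(g) == 0)) stop("a group has zero subjects")
  et <- sort(unique(time[event == 1]))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in et) {
    at_risk <- time >= t
    N <- sum(at_risk)
    if (N < 1) next
    d <- sum(event == 1 & time == t)
    n_g <- vapply(lv, function(l) sum(at_risk & g == l), numeric(1))
    d_g <- vapply(lv, function(l) sum(event == 1 & time == t & g == l),
                  numeric(1))
    O <- O + d_g
    E <- E + n_g * d / N
    if (N > 1) {
      c1 <- d * (N - d) / (N - 1)
      V <- V + c1 * (diag(n_g, k) * N - outer(n_g, n_g)) / N^2
    }
  }
  u <- (O - E)[-k]
  Vm <- V[-k, -k, drop = FALSE]
  chi <- tryCatch(drop(t(u) %*% solve(Vm, u)), error = function(e) 0)
  list(chi_square = chi, df = k - 1, observed = O, expected = E)
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimate with Greenwood-based confidence bands (via
#' \pkg{survival}).
#'
#' @param time,event follow-up time and event indicator.
#' @param conf_level confidence level (0.95).
#' @return object of class `km_fit` wrapping the `survfit` object with a
#'   step table (`time`, `n_risk`, `n_event`, `surv`, `lower`, `upper`).
#' @export
km_estimate <- function(time, event, conf_level = 0.95) {
  if (length(time) < 1) stop("at least one subject is required")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.int = conf_level)
  tab <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, surv = fit$surv,
                    lower = fit$lower, upper = fit$upper)
  structure(list(fit = fit, table = tab), class = "km_fit")
}

#' Survival probability at given times
#'
#' @param km a [km_estimate()] result.
#' @param times query times.
#' @export
km_surv_prob <- function(km, times) {
  stopifnot(inherits(km, "km_fit"))
  s <- summary(km$fit, times = times, extend = TRUE)
  stats::setNames(s$surv, times)
}

#' Log-rank test
#'
#' @param time,event follow-up time and event indicator.
#' @param group group membership (2 or more groups).
#' @return list with `chi_square`, `df` and `p`.
#' @export
logrank_test <- function(time, event, group) {
  lr <- .logrank_chisq(time, event, group)
  lr$p <- stats::pchisq(lr$chi_square, lr$df, lower.tail = FALSE)
  lr
}

.model_fit <- function(terms, coef, se, effect_label, lr_stat, lr_df, n,
                       r2 = NULL, flags = character()) {
  coef <- unname(coef); se <- unname(se)
  z <- coef / se
  fit <- data.frame(term = terms, coef = coef, se = se,
                    effect = exp(coef),
                    lower = exp(coef - 1.96 * se),
                    upper = exp(coef + 1.96 * se),
                    p = 2 * stats::pnorm(-abs(z)), row.names = NULL)
  names(fit)[names(fit) == "effect"] <- effect_label
  structure(list(terms = fit, lr_stat = lr_stat, lr_df = lr_df, n = n,
                 r2 = r2, flags = flags),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  eff <- setdiff(names(x$terms), c("term", "coef", "se", "lower", "upper", "p"))
  cat(sprintf("model fit (n = %d)\n", x$n))
  for (i in seq_len(nrow(x$terms)))
    cat(sprintf("  %-24s %s %.2f (%.2f, %.2f)  p = %.4g\n",
                x$terms$term[i], eff, x$terms[[eff]][i],
                x$terms$lower[i], x$terms$upper[i], x$terms$p[i]))
  if (!is.null(x$r2)) cat(sprintf("  R2 = %.4f\n", x$r2))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit (Breslow tie handling) with Wald intervals and
#' p-values per term, the global likelihood-ratio statistic, and an
#' explained-variation statistic R2 = 1 - exp(-LR/n).
#'
#' @param covariates data frame of covariates (numeric or 0/1).
#' @param time,event follow-up time and event indicator.
#' @return a `model_fit` with hazard ratios (`hr`).
#' @export
cox_fit <- function(covariates, time, event) {
  covariates <- as.data.frame(covariates)
  if (sum(event) < ncol(covariates))
    stop("fewer events than model terms")
  dat <- cbind(covariates, .time = time, .event = event)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(sprintf("`%s`", names(covariates)),
                                       collapse = " + ")))
  flags <- character()
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "breslow"),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w)))
        flags <<- unique(c(flags, "possible_separation_or_nonconvergence"))
      invokeRestart("muffleWarning")
    })
  if (anyNA(stats::coef(fit)))
    stop("singular model: collinear covariates")
  lr <- 2 * diff(fit$loglik)
  n <- fit$n
  .model_fit(names(stats::coef(fit)), stats::coef(fit),
             sqrt(diag(fit$var)), "hr", lr, length(stats::coef(fit)), n,
             r2 = 1 - exp(-lr / n), flags = flags)
}

#' Logistic regression fit
#'
#' Maximum-likelihood logistic regression with Wald odds-ratio intervals.
#' On a single binary covariate this reproduces [odds_ratio_2x2()].
#'
#' @param covariates data frame of covariates.
#' @param outcome binary outcome (both classes must be present).
#' @return a `model_fit` with odds ratios (`or`).
#' @export
logistic_fit <- function(covariates, outcome) {
  covariates <- as.data.frame(covariates)
  if (length(unique(outcome)) != 2) stop("outcome must have both classes")
  dat <- cbind(covariates, .y = as.numeric(outcome))
  fml <- stats::as.formula(paste(".y ~",
                                 paste(sprintf("`%s`", names(covariates)),
                                       collapse = " + ")))
  flags <- character()
  fit <- withCallingHandlers(
    stats::glm(fml, data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities|converge", conditionMessage(w)))
        flags <<- unique(c(flags, "possible_separation"))
      invokeRestart("muffleWarning")
    })
  cf <- stats::coef(fit)[-1]
  if (anyNA(cf)) stop("singular model: constant or collinear covariates")
  se <- sqrt(diag(stats::vcov(fit)))[-1]
  lr <- fit$null.deviance - fit$deviance
  .model_fit(names(cf), cf, se, "or", lr, length(cf), nrow(dat),
             flags = flags)
}

#' Forward-stepwise selection with backward checks
#'
#' Classic stepwise selection at the published thresholds: at each step
#' the candidate with the smallest Wald p-value enters if it is below
#' `entry`; after each entry, any non-forced term whose Wald p-value
#' exceeds `stay` is removed (worst first).  Ties are broken by input
#' order, so the procedure is deterministic.
#'
#' @param candidates data frame of candidate covariates.
#' @param time,event survival outcome (Cox model).
#' @param outcome binary outcome (logistic model).
#' @param model `"cox"` or `"logistic"`.
#' @param entry,stay entry and stay significance levels (0.10 and 0.05).
#' @param forced names of variables forced into the model (never removed).
#' @return list with `selected` (term names) and `fit` (the final
#'   `model_fit`, `NULL` when nothing is selected).
#' @export
stepwise_select <- function(candidates, time = NULL, event = NULL,
                            outcome = NULL, model = c("cox", "logistic"),
                            entry = 0.10, stay = 0.05, forced = character()) {
  model <- match.arg(model)
  candidates <- as.data.frame(candidates)
  if (ncol(candidates) < 1) stop("at least one candidate is required")
  fit_fun <- function(vars) {
    if (model == "cox") cox_fit(candidates[, vars, drop = FALSE], time, event)
    else logistic_fit(candidates[, vars, drop = FALSE], outcome)
  }
  term_p <- function(fit, var) fit$terms$p[match(var, fit$terms$term)]
  current <- forced
  seen <- character()   # cycling guard: a variable with stay < p < entry
                        # would otherwise enter and leave indefinitely
  repeat {
    sig <- paste(sort(current), collapse = "|")
    if (sig %in% seen) break
    seen <- c(seen, sig)
    pool <- setdiff(names(candidates), current)
    added <- FALSE
    if (length(pool)) {
      pv <- vapply(pool, function(v) {
        f <- tryCatch(fit_fun(c(current, v)), error = function(e) NULL)
        if (is.null(f)) NA_real_ else term_p(f, v)
      }, numeric(1))
      if (any(is.finite(pv)) && min(pv, na.rm = TRUE) < entry) {
        current <- c(current, pool[which.min(pv)])
        added <- TRUE
      }
    }
    ## backward pass: drop the worst removable term while any exceeds stay
    repeat {
      removable <- setdiff(current, forced)
      if (!length(removable)) break
      f <- fit_fun(current)
      pv <- vapply(removable, function(v) term_p(f, v), numeric(1))
      if (max(pv) <= stay) break
      current <- setdiff(current, removable[which.max(pv)])
    }
    if (!added) break
  }
  if (!length(current)) return(list(selected = character(), fit = NULL))
  list(selected = current, fit = fit_fun(current))
}

#' Odds ratio of a 2x2 table with Wald interval
#'
#' Counts follow the exposed/unexposed layout: `a` exposed with outcome,
#' `b` exposed without, `c` unexposed with, `d` unexposed without.  A zero
#' cell triggers the Haldane 0.5 correction (flagged) unless disabled.
#'
#' @param a,b,c,d non-negative integer counts.
#' @param haldane apply the 0.5 correction on zero cells (default TRUE).
#' @return list with `or`, `ci` (Wald 95\%), `p` (Wald z), `corrected`.
#' @export
odds_ratio_2x2 <- function(a, b, c, d, haldane = TRUE) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  corrected <- FALSE
  if (any(counts == 0)) {
    if (!haldane) stop("zero cell with the Haldane correction disabled")
    counts <- counts + 0.5
    corrected <- TRUE
  }
  or <- counts[1] * counts[4] / (counts[2] * counts[3])
  se <- sqrt(sum(1 / counts))
  ci <- exp(log(or) + c(-1.96, 1.96) * se)
  p <- 2 * stats::pnorm(-abs(log(or) / se))
  list(or = or, ci = ci, p = p, corrected = corrected)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks.
#' @param x,y paired observations (at least 3 pairs).
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 3) stop("at least 3 pairs are required")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    stop("constant vector has no rank correlation")
  stats::cor(x, y, method = "spearman")
}

#' Two-group comparison
#'
#' `"chi2"`: Pearson chi-square without continuity correction, on a 2x2
#' count matrix or on two categorical vectors.  `"t"`: Student's
#' two-sample t-test (equal variances).  `"mannwhitney"`: delegates to
#' [wilcoxon_rank_sum()].
#'
#' @param x,y the two samples (or, for `"chi2"` with `y = NULL`, a count
#'   matrix).
#' @param kind one of `"chi2"`, `"t"`, `"mannwhitney"`.
#' @return list with `statistic`, `p` and `kind`.
#' @export
group_compare <- function(x, y = NULL, kind = c("chi2", "t", "mannwhitney")) {
  kind <- match.arg(kind)
  if (kind == "chi2") {
    tab <- if (is.matrix(x)) x else table(x, y)
    ct <- stats::chisq.test(tab, correct = FALSE)
    return(list(statistic = unname(ct$statistic), p = ct$p.value, kind = kind))
  }
  if (kind == "t") {
    tt <- stats::t.test(x, y, var.equal = TRUE)
    return(list(statistic = unname(tt$statistic), p = tt$p.value, kind = kind))
  }
  w <- wilcoxon_rank_sum(x, y)
  list(statistic = w$statistic, p = w$p, kind = kind)
}
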