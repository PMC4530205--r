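## Synthetic patient cohort: low-CIg status, linked adverse covariates,
## log2 expression with 12 designated signature probes among null probes,
## and exponential OS/PFS with independent uniform censoring.

#' Parameters for a simulated cohort
#'
#' Defaults emulate the defining cohort: 139 patients, low-CIg prevalence
#' 60/139, covariate marginal prevalences and low-CIg log-odds links at
#' the published univariate associations, signature probe group means
#' from the packaged 12-probe table, homoskedastic log2 noise.
#'
#' @param n_patients cohort size.
#' @param n_probes number of null (non-signature) probes.
#' @param signature_probe_means data frame with `probe_id`,
#'   `mean_low_cig`, `mean_high_cig` (default: the packaged 12-probe
#'   table).
#' @param noise_sd residual SD of log2 expression, shared by all probes.
#' @param prevalence_low_cig probability of the low-CIg state.
#' @param covariate_link named numeric vector of log-odds coefficients
#'   tying each boolean covariate to low-CIg status; marginal covariate
#'   prevalences are supplied via `covariate_prevalence` and the
#'   intercepts solved so the marginals hold.
#' @param covariate_prevalence named numeric vector of marginal
#'   prevalences, same names as `covariate_link`.
#' @param os_baseline,pfs_baseline baseline exponential hazards per month.
#' @param log_hr named log hazard ratios applied to `low_cig` and/or
#'   covariates for both endpoints.
#' @param censor_horizon censoring is uniform on (0, horizon) months.
#' @param seed integer seed.
#' @return object of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(n_patients = 139,
                              n_probes = 1000,
                              signature_probe_means = NULL,
                              noise_sd = 0.5,
                              prevalence_low_cig = 60 / 139,
                              covariate_link = c(b2m_high = log(3.98),
                                                 crp_high = log(2.77),
                                                 centrosome_high = log(3.93),
                                                 lcr_high = log(5.54)),
                              covariate_prevalence = c(b2m_high = 0.31,
                                                       crp_high = 0.32,
                                                       centrosome_high = 0.50,
                                                       lcr_high = 0.20),
                              os_baseline = 0.0044,
                              pfs_baseline = 0.0056,
                              log_hr = c(low_cig = log(2.2)),
                              censor_horizon = 96,
                              seed = NULL) {
  if (n_patients < 4) stop("'n_patients' must be at least 4")
  if (n_probes < 0) stop("'n_probes' must be non-negative")
  if (!(prevalence_low_cig > 0 && prevalence_low_cig < 1))
    stop("'prevalence_low_cig' must be in (0, 1)")
  if (os_baseline <= 0 || pfs_baseline <= 0)
    stop("hazard rates must be positive")
  if (!setequal(names(covariate_link), names(covariate_prevalence)))
    stop("'covariate_link' and 'covariate_prevalence' must share names")
  if (is.null(signature_probe_means)) signature_probe_means <- cig12_probes()
  need <- c("probe_id", "mean_low_cig", "mean_high_cig")
  if (!all(need %in% names(signature_probe_means)))
    stop("'signature_probe_means' needs columns ",
         paste(need, collapse = ", "))
  if (nrow(signature_probe_means) != 12)
    stop("the signature mean table must have 12 probes")
  p <- list(n_patients = as.integer(n_patients),
            n_probes = as.integer(n_probes),
            signature_probe_means = signature_probe_means,
            noise_sd = noise_sd, prevalence_low_cig = prevalence_low_cig,
            covariate_link = covariate_link,
            covariate_prevalence = covariate_prevalence,
            os_baseline = os_baseline, pfs_baseline = pfs_baseline,
            log_hr = log_hr, censor_horizon = censor_horizon, seed = seed)
  class(p) <- "cohort_sim_params"
  p
}

## Solve the intercept so that the covariate's marginal prevalence holds
## given the low-CIg prevalence and the log-odds link.
.link_intercept <- function(p_marg, beta, prev_low) {
  f <- function(a) prev_low * stats::plogis(a + beta) +
    (1 - prev_low) * stats::plogis(a) - p_marg
  stats::uniroot(f, c(-20, 20))$root
}

#' Simulate a cohort: clinical flags, expression, survival
#'
#' Low-CIg status is drawn at its prevalence; each boolean covariate is
#' drawn from a logistic link on low-CIg status with the intercept solved
#' to preserve its marginal prevalence.  The 12 designated probes take
#' their group-specific means; null probes share a common
#' patient-independent baseline (drawn once per cohort from N(8, 1.5)).
#' OS and PFS are exponential with log-hazard equal to the sum of the
#' flagged coefficients, censored independently by a uniform time on
#' (0, `censor_horizon`).
#'
#' @param params a [cohort_sim_params()] object.
#' @return list with `clinical` (data frame: `sample_id`, `low_cig`,
#'   covariate flags), `expression` (log2 matrix, probes x samples) and
#'   `survival` (data frame: `sample_id`, `os_time`, `os_event`,
#'   `pfs_time`, `pfs_event`).
#' @export
gen_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_sim_params"))
  p <- params
  with_seed(p$seed, {
    n <- p$n_patients
    ids <- sprintf("P%03d", seq_len(n))
    low <- stats::runif(n) < p$prevalence_low_cig
    clinical <- data.frame(sample_id = ids, low_cig = low)
    for (nm in names(p$covariate_link)) {
      a <- .link_intercept(p$covariate_prevalence[[nm]],
                           p$covariate_link[[nm]], p$prevalence_low_cig)
      clinical[[nm]] <- stats::runif(n) <
        stats::plogis(a + p$covariate_link[[nm]] * low)
    }

    sig <- p$signature_probe_means
    null_ids <- sprintf("null_%04d", seq_len(p$n_probes))
    null_base <- stats::rnorm(p$n_probes, 8, 1.5)
    expr <- matrix(0, nrow = p$n_probes + 12, ncol = n,
                   dimnames = list(c(sig$probe_id, null_ids), ids))
    mu_sig <- ifelse(matrix(low, nrow = 12, ncol = n, byrow = TRUE),
                     sig$mean_low_cig, sig$mean_high_cig)
    expr[seq_len(12), ] <- mu_sig +
      stats::rnorm(12 * n, 0, p$noise_sd)
    if (p$n_probes > 0)
      expr[12 + seq_len(p$n_probes), ] <- null_base +
        stats::rnorm(p$n_probes * n, 0, p$noise_sd)

    lp <- rep(0, n)
    flags <- cbind(low_cig = low,
                   as.matrix(clinical[names(p$covariate_link)]))
    for (nm in names(p$log_hr)) {
      if (!nm %in% colnames(flags))
        stop("unknown hazard term: ", nm)
      lp <- lp + p$log_hr[[nm]] * flags[, nm]
    }
    draw_endpoint <- function(base) {
      t_event <- stats::rexp(n, rate = base * exp(lp))
      cens <- stats::runif(n, 0, p$censor_horizon)
      data.frame(time = pmin(t_event, cens),
                 event = as.integer(t_event <= cens))
    }
    os <- draw_endpoint(p$os_baseline)
    pfs <- draw_endpoint(p$pfs_baseline)
    survival <- data.frame(sample_id = ids,
                           os_time = os$time, os_event = os$event,
                           pfs_time = pfs$time, pfs_event = pfs$event)
    list(clinical = clinical, expression = expr, survival = survival)
  })
}
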