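## End-to-end orchestration: simulate (or load) -> flow profiles ->
## low-CIg grouping -> differential expression -> signature -> scoring ->
## cutpoint -> survival and association models.

#' Pipeline configuration
#'
#' All thresholds default to the published operating points: CIg cutoff
#' 2.8, selection thresholds p < 1e-4 and q < 0.10, stepwise entry 0.10 /
#' stay 0.05, risk-score endpoint PFS.  `score_cutoff = NULL` derives the
#' score cutoff by running log-rank on the configured endpoint; a fixed
#' value (e.g. 5.35) can be supplied instead.
#'
#' @param seed integer seed (mandatory: every stochastic stage derives its
#'   stream from it).
#' @param simulate generate the cohort and flow tubes (`TRUE`) or load
#'   them from the `*_path` entries.
#' @param cohort a [cohort_sim_params()]; `seed` is overridden.
#' @param flow_n_events events per simulated tube.
#' @param expression_path,clinical_path,survival_path TSV inputs when
#'   `simulate = FALSE`; the clinical table must then contain a `low_cig`
#'   column.
#' @param cig_cutoff,p_max,q_max,score_cutoff,endpoint,n_perm analysis
#'   thresholds (see above).
#' @return a validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            simulate = TRUE,
                            cohort = cohort_sim_params(n_patients = 60,
                                                       n_probes = 500),
                            flow_n_events = 5000,
                            expression_path = NULL,
                            clinical_path = NULL,
                            survival_path = NULL,
                            cig_cutoff = 2.8,
                            p_max = 1e-4,
                            q_max = 0.10,
                            score_cutoff = NULL,
                            endpoint = c("pfs", "os"),
                            n_perm = 1000) {
  if (missing(seed) || is.null(seed)) stop("'seed' is mandatory")
  endpoint <- match.arg(endpoint)
  for (nm in c("cig_cutoff", "p_max", "q_max"))
    if (get(nm) <= 0) stop("'", nm, "' must be positive")
  if (!simulate) {
    for (nm in c("expression_path", "clinical_path", "survival_path")) {
      pth <- get(nm)
      if (is.null(pth)) stop("'", nm, "' is required when simulate = FALSE")
      if (!file.exists(pth)) stop(nm, " does not exist: ", pth)
    }
  } else {
    stopifnot(inherits(cohort, "cohort_sim_params"))
  }
  structure(list(seed = as.integer(seed), simulate = simulate,
                 cohort = cohort, flow_n_events = flow_n_events,
                 expression_path = expression_path,
                 clinical_path = clinical_path,
                 survival_path = survival_path,
                 cig_cutoff = cig_cutoff, p_max = p_max, q_max = q_max,
                 score_cutoff = score_cutoff, endpoint = endpoint,
                 n_perm = n_perm),
            class = "pipeline_config")
}

## Specimen-level flow parameters consistent with a patient's low-CIg
## state: at least one stem line below the CIg cutoff for low-CIg
## patients, all lines clearly above it otherwise.
.patient_flow_params <- function(low_cig, n_events, seed) {
  n_lines <- sample(1:2, 1, prob = c(0.25, 0.75))
  di <- if (stats::runif(1) < 0.4) 1.0 else stats::runif(1, 1.03, 1.15)
  dis <- di
  if (n_lines == 2) dis <- c(di, di + stats::runif(1, 0.08, 0.2))
  cigs <- if (low_cig) stats::runif(n_lines, 1.3, 2.5)
          else stats::runif(n_lines, 3.2, 6.0)
  fr <- if (n_lines == 2) {f <- stats::runif(1, 0.35, 0.65); c(f, 1 - f)} else 1
  lines <- lapply(seq_len(n_lines), function(i)
    list(di = dis[i], fraction = fr[i], cig = cigs[i]))
  flow_sim_params(n_events = n_events, stem_lines = lines,
                  involved_chain = sample(c("kappa", "lambda"), 1),
                  lcr_fraction = stats::runif(1, 0.15, 0.5),
                  seed = seed)
}

#' Run the full analysis pipeline
#'
#' Stages: (1) simulate or load the cohort; (2) per-specimen DNA/CIg flow
#' profiling and low-CIg grouping; (3) probe-wise rank-sum testing with
#' permutation FDR; (4) directional signature selection; (5) cohort
#' scoring; (6) running log-rank cutpoint on the configured endpoint;
#' (7) risk stratification with log-rank and Cox fits, and covariate
#' odds ratios against the low-CIg group.  Re-running with the same
#' configuration reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, every stage's outputs
#'   are written there (TSV/JSON) without overwriting inputs.
#' @return (invisibly) a list with `clinical`, `profiles`, `low_group`,
#'   `diffexpr`, `signature`, `scores`, `cutpoint`, `models`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  if (cfg$simulate) {
    cohort_params <- cfg$cohort
    cohort_params$seed <- cfg$seed
    cohort <- gen_cohort(cohort_params)
    clinical <- cohort$clinical
    expr <- cohort$expression
    surv <- cohort$survival
    n <- nrow(clinical)
    profiles <- with_seed(cfg$seed + 1L, {
      specimen_seeds <- sample.int(.Machine$integer.max, n)
      lapply(seq_len(n), function(i) {
        fp <- .patient_flow_params(clinical$low_cig[i], cfg$flow_n_events,
                                   specimen_seeds[i])
        tubes <- gen_flow_tubes(fp)
        build_profile(tubes$kappa, tubes$lambda, cig_cutoff = cfg$cig_cutoff)
      })
    })
    low_group <- vapply(profiles, function(p) isTRUE(p$any_cig_below),
                        logical(1))
  } else {
    expr <- load_expression(cfg$expression_path)
    clinical <- load_clinical(cfg$clinical_path)
    surv <- load_survival(cfg$survival_path)
    if (!"low_cig" %in% names(clinical))
      stop("clinical table must contain a 'low_cig' column")
    profiles <- NULL
    low_group <- as.logical(clinical$low_cig)
  }

  de <- run_diffexpr(expr, low_group, n_perm = cfg$n_perm,
                     seed = cfg$seed + 2L)
  sig <- select_signature(de, p_max = cfg$p_max, q_max = cfg$q_max)
  n_sig <- length(sig$up_in_low) + length(sig$down_in_low)
  if (n_sig == 0) {
    warning("no probe passed the selection thresholds; scoring skipped")
    return(invisible(list(clinical = clinical, profiles = profiles,
                          low_group = low_group, diffexpr = de,
                          signature = sig, scores = NULL, cutpoint = NULL,
                          models = NULL)))
  }
  scores <- score_cohort(expr, sig)
  tcol <- paste0(cfg$endpoint, "_time"); ecol <- paste0(cfg$endpoint, "_event")
  cut <- if (is.null(cfg$score_cutoff)) {
    running_logrank_cutpoint(scores$score, surv[[tcol]], surv[[ecol]],
                             endpoint = toupper(cfg$endpoint))
  } else {
    list(cutoff = cfg$score_cutoff, max_statistic = NA_real_,
         endpoint = toupper(cfg$endpoint), scan = NULL)
  }
  scores$risk_flag <- stratify(scores$score, cut$cutoff)

  models <- list()
  for (e in c("os", "pfs")) {
    tt <- surv[[paste0(e, "_time")]]; ee <- surv[[paste0(e, "_event")]]
    models[[paste0("logrank_", e)]] <- logrank_test(tt, ee, scores$risk_flag)
    models[[paste0("cox_", e)]] <- tryCatch(
      cox_fit(data.frame(gep_risk = as.numeric(scores$risk_flag)), tt, ee),
      error = function(err) NULL)
  }
  covars <- setdiff(names(clinical), c("sample_id", "low_cig"))
  if (length(covars)) {
    models$odds_ratios <- do.call(rbind, lapply(covars, function(v) {
      f <- as.logical(clinical[[v]])
      o <- odds_ratio_2x2(sum(f & low_group), sum(f & !low_group),
                          sum(!f & low_group), sum(!f & !low_group))
      data.frame(factor = v, or = o$or, ci_lo = o$ci[1], ci_hi = o$ci[2],
                 p = o$p)
    }))
  }

  result <- list(clinical = clinical, profiles = profiles,
                 low_group = low_group, diffexpr = de, signature = sig,
                 scores = scores, cutpoint = cut, models = models)
  if (!is.null(out_dir)) .write_run(result, cfg, out_dir)
  invisible(result)
}

.write_run <- function(result, cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    cfg[setdiff(names(cfg), "cohort")],
    file.path(out_dir, "config.json"), auto_unbox = TRUE, null = "null")
  utils::write.table(result$diffexpr, file.path(out_dir, "diffexpr.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(up_in_low = result$signature$up_in_low,
                            down_in_low = result$signature$down_in_low),
                       file.path(out_dir, "signature.json"))
  if (!is.null(result$scores))
    utils::write.table(result$scores, file.path(out_dir, "scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$cutpoint$scan))
    utils::write.table(result$cutpoint$scan,
                       file.path(out_dir, "cutpoint_scan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$profiles)) {
    prof <- do.call(rbind, lapply(seq_along(result$profiles), function(i) {
      p <- result$profiles[[i]]
      data.frame(specimen = i, involved = p$involved_chain,
                 lcr_pct = p$lcr_pct, n_stem_lines = p$n_stem_lines,
                 ploidy = ifelse(is.na(p$ploidy), NA, p$ploidy),
                 any_cig_below = p$any_cig_below)
    }))
    utils::write.table(prof, file.path(out_dir, "profiles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  summary_lines <- c(
    sprintf("signature probes: %d up_in_low, %d down_in_low",
            length(result$signature$up_in_low),
            length(result$signature$down_in_low)),
    sprintf("score cutoff (%s): %.4f", result$cutpoint$endpoint,
            result$cutpoint$cutoff),
    sprintf("high-risk fraction: %.3f", mean(result$scores$risk_flag)))
  writeLines(summary_lines, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}
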