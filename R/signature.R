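## The GEP12 risk score and running log-rank optimal-cutpoint selection.

#' Directional probe signature
#'
#' @param up_in_low probe identifiers over-expressed in the low-CIg group.
#' @param down_in_low probe identifiers under-expressed in the low-CIg
#'   group.
#' @param allow_empty permit an empty signature (used by
#'   [select_signature()] when no probe passes the thresholds).
#' @return an object of class `signature_def`.
#' @export
signature_def <- function(up_in_low, down_in_low, allow_empty = FALSE) {
  up_in_low <- as.character(up_in_low); down_in_low <- as.character(down_in_low)
  if (length(intersect(up_in_low, down_in_low)) > 0)
    stop("a probe cannot be both up- and down-regulated")
  if (!allow_empty && length(up_in_low) + length(down_in_low) == 0)
    stop("empty signature")
  structure(list(up_in_low = up_in_low, down_in_low = down_in_low),
            class = "signature_def")
}

#' @export
print.signature_def <- function(x, ...) {
  cat(sprintf("probe signature: %d up_in_low, %d down_in_low\n",
              length(x$up_in_low), length(x$down_in_low)))
  invisible(x)
}

#' GEP12-style risk score of one expression profile
#'
#' The score subtracts the summed expression of the probes over-expressed
#' in the low-CIg group from the summed expression of the probes
#' under-expressed in that group, and divides by the total number of
#' probes.  Low scores are therefore characteristic of the low-CIg
#' (adverse) state.
#'
#' @param expr named numeric vector of log2 expression values containing
#'   every signature probe.
#' @param signature a [signature_def()].
#' @return the score, on the log2 expression scale.
#' @export
gep12_score <- function(expr, signature) {
  stopifnot(inherits(signature, "signature_def"))
  probes <- c(signature$up_in_low, signature$down_in_low)
  if (length(probes) == 0) stop("empty signature")
  missing <- setdiff(probes, names(expr))
  if (length(missing) > 0)
    stop("missing signature probes: ", paste(missing, collapse = ", "))
  (sum(expr[signature$down_in_low]) - sum(expr[signature$up_in_low])) /
    length(probes)
}

#' Score every sample of an expression matrix
#'
#' @param mat log2 expression matrix, probes x samples, with dimnames.
#' @param signature a [signature_def()].
#' @param cutoff optional risk cutoff; when given, `risk_flag` marks
#'   samples with score strictly below it.
#' @return data frame with `sample_id`, `score` and (with a cutoff)
#'   `risk_flag`.
#' @export
score_cohort <- function(mat, signature, cutoff = NULL) {
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("expression matrix needs probe and sample dimnames")
  scores <- vapply(seq_len(ncol(mat)), function(j)
    gep12_score(stats::setNames(mat[, j], rownames(mat)), signature),
    numeric(1))
  out <- data.frame(sample_id = colnames(mat), score = scores,
                    row.names = NULL)
  if (!is.null(cutoff)) out$risk_flag <- stratify(out$score, cutoff)
  out
}

#' Dichotomise scores at a cutoff
#'
#' Strict inequality: a score below the cutoff is high risk; a score equal
#' to the cutoff is standard risk.
#' @param scores numeric scores.
#' @param cutoff the risk cutoff.
#' @return logical vector, `TRUE` = high risk.
#' @export
stratify <- function(scores, cutoff) scores < cutoff

#' Running log-rank optimal cutpoint
#'
#' Scans every midpoint between consecutive distinct marker values whose
#' dichotomisation leaves at least `min_group_frac` of the subjects on
#' each side, computes the two-group log-rank chi-square at each
#' candidate, and returns the candidate maximising it (ties broken toward
#' the smallest candidate).  No multiplicity adjustment is applied to the
#' maximum -- the naive p-value of the selected split is anti-conservative
#' -- so the full scan trace is always returned for audit.
#'
#' @param marker per-subject continuous marker values.
#' @param time,event follow-up time and event indicator.
#' @param endpoint label stored with the result (e.g. `"PFS"`).
#' @param min_group_frac minimum fraction of subjects per side (0.10).
#' @param min_events minimum total events required (20).
#' @return object of class `cutpoint_result`: `cutoff`, `max_statistic`,
#'   `endpoint` and the `scan` data frame (`candidate`, `statistic`,
#'   `n_below`).
#' @export
running_logrank_cutpoint <- function(marker, time, event, endpoint = "PFS",
                                     min_group_frac = 0.10, min_events = 20) {
  n <- length(marker)
  stopifnot(length(time) == n, length(event) == n)
  if (sum(event) < min_events)
    stop(sprintf("need at least %d events, got %d", min_events, sum(event)))
  sv <- sort(unique(marker))
  if (length(sv) < 2) stop("no candidate cutoffs: marker is constant")
  cand <- (sv[-length(sv)] + sv[-1]) / 2
  n_below <- vapply(cand, function(cc) sum(marker < cc), numeric(1))
  ok <- n_below >= min_group_frac * n & (n - n_below) >= min_group_frac * n
  cand <- cand[ok]; n_below <- n_below[ok]
  if (length(cand) == 0)
    stop("no candidate cutoff satisfies the group-size constraint")
  stat <- vapply(cand, function(cc)
    .logrank_chisq(time, event, marker < cc)$chi_square, numeric(1))
  best <- which.max(stat)
  structure(list(cutoff = cand[best], max_statistic = stat[best],
                 endpoint = endpoint,
                 scan = data.frame(candidate = cand, statistic = stat,
                                   n_below = n_below)),
            class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf("running log-rank cutpoint (%s): %.4g (chi-square %.2f over %d candidates)\n",
              x$endpoint, x$cutoff, x$max_statistic, nrow(x$scan)))
  invisible(x)
}
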