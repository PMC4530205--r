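## Probe-wise two-group Wilcoxon rank-sum testing with SAM-style
## permutation false-discovery control, and directional signature
## selection.  Rank statistics are fed directly into the permutation FDR
## machinery; no variance-stabilising fudge factor is needed because ranks
## already have fixed scale.

#' Wilcoxon rank-sum test
#'
#' Mid-ranks for ties.  The two-sided p-value is computed by exact
#' enumeration of all group assignments when the combined sample size is
#' at most 12, and by a normal approximation with continuity and tie
#' corrections otherwise.  With all values identical the p-value is 1.
#'
#' @param x,y numeric vectors for the two groups (each of length >= 2).
#' @return list with `statistic` (rank sum of `x`), `p` (two-sided) and
#'   `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  m <- length(x); n <- length(y); N <- m + n
  if (m < 2 || n < 2) stop("each group needs at least 2 values")
  if (!all(is.finite(c(x, y)))) stop("non-finite values")
  r <- rank(c(x, y))
  W <- sum(r[seq_len(m)])
  mu <- m * (N + 1) / 2
  if (length(unique(c(x, y))) == 1L)
    return(list(statistic = W, p = 1, method = "degenerate"))
  if (N <= 12) {
    idx <- utils::combn(N, m)
    sums <- colSums(matrix(r[idx], nrow = m))
    p <- mean(abs(sums - mu) >= abs(W - mu) - 1e-9)
    return(list(statistic = W, p = p, method = "exact"))
  }
  tt <- table(r)
  tie_term <- sum(tt^3 - tt)
  sigma2 <- m * n / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) return(list(statistic = W, p = 1, method = "degenerate"))
  z <- (abs(W - mu) - 0.5) / sqrt(sigma2)
  list(statistic = W, p = min(1, 2 * stats::pnorm(-max(z, 0))),
       method = "normal")
}

## Rank-sum machinery for a whole matrix: per-probe mid-ranks, null mean
## and tie-corrected SD, standardised statistics for arbitrary group
## indicator columns.  `ind` is an n x B 0/1 matrix.
.ranksum_z <- function(ranks, ind, mu, sigma) {
  W <- ranks %*% ind
  sweep(abs(sweep(W, 1, mu)), 1, pmax(sigma, 1e-12), "/")
}

#' SAM-style permutation false-discovery rate for rank-sum statistics
#'
#' Probes are ordered by their standardised rank-sum statistic.  For each
#' probe the expected number of null statistics at or above its observed
#' value is taken as the median over label permutations; dividing by the
#' probe's rank gives a q-value, which is clipped to [0, 1] and
#' monotonised (non-decreasing in p-rank).
#'
#' @param mat numeric matrix, probes x samples.
#' @param labels logical or two-level vector marking group membership
#'   (`TRUE` = group of interest); both groups need >= 2 samples.
#' @param n_perm number of label permutations (default 1000; fewer than 50
#'   triggers a warning).
#' @param seed integer seed for the permutations (required).
#' @return numeric vector of q-values, one per probe, in input order.
#' @export
permutation_fdr <- function(mat, labels, n_perm = 1000, seed) {
  if (missing(seed) || is.null(seed)) stop("'seed' is required")
  if (n_perm < 1) stop("'n_perm' must be a positive count")
  if (n_perm < 50) warning("fewer than 50 permutations gives unstable q-values")
  lab <- .as_group_logical(labels)
  nA <- sum(lab); nB <- sum(!lab); n <- length(lab)
  if (nA < 2 || nB < 2) stop("both groups need at least 2 samples")
  if (ncol(mat) != n) stop("label length must match the number of samples")

  ranks <- t(apply(mat, 1, rank))
  mu <- nA * (n + 1) / 2
  tie_term <- apply(ranks, 1, function(r) { tt <- table(r); sum(tt^3 - tt) })
  sigma <- sqrt(nA * nB / 12 * ((n + 1) - tie_term / (n * (n - 1))))

  z_obs <- as.vector(.ranksum_z(ranks, matrix(as.numeric(lab)), mu, sigma))
  perm_ind <- with_seed(seed, vapply(seq_len(n_perm), function(b)
    as.numeric(sample(lab)), numeric(n)))
  z_perm <- .ranksum_z(ranks, perm_ind, mu, sigma)

  ord <- order(z_obs, decreasing = TRUE)
  thr <- z_obs[ord]
  ## exceedance counts per permutation at each observed threshold
  counts <- vapply(seq_len(n_perm), function(b) {
    s <- sort(z_perm[, b])
    length(s) - findInterval(thr - 1e-12, s)
  }, numeric(length(thr)))
  counts <- matrix(counts, nrow = length(thr))
  med_false <- apply(counts, 1, stats::median)
  rank_called <- vapply(thr, function(t) sum(z_obs >= t - 1e-12), numeric(1))
  q_sorted <- pmin(pmax(med_false / rank_called, 0), 1)
  q_sorted <- rev(cummin(rev(q_sorted)))   # monotone non-decreasing in rank
  q <- numeric(length(z_obs))
  q[ord] <- q_sorted
  q
}

.as_group_logical <- function(labels) {
  if (is.logical(labels)) return(labels)
  lv <- unique(labels)
  if (length(lv) != 2) stop("labels must have exactly two levels")
  labels == lv[1]
}

#' Probe-wise differential expression between two groups
#'
#' Runs the rank-sum test on every probe (normal approximation with
#' continuity and tie corrections; sample sizes here are far beyond the
#' exact-enumeration range), attaches SAM-style permutation q-values and
#' the direction of change.
#'
#' @param mat log2 expression matrix, probes x samples, with probe row
#'   names.
#' @param low logical vector: `TRUE` for samples in the low-CIg (or other
#'   index) group.
#' @inheritParams permutation_fdr
#' @return data frame with columns `probe_id`, `statistic`, `p`, `q`,
#'   `mean_low`, `mean_high`, `direction` (`"up_in_low"`/`"down_in_low"`).
#' @export
run_diffexpr <- function(mat, low, n_perm = 1000, seed) {
  if (is.null(rownames(mat))) stop("expression matrix needs probe row names")
  if (anyNA(mat) || !all(is.finite(mat)))
    stop("expression matrix contains missing or non-finite values")
  low <- .as_group_logical(low)
  nA <- sum(low); nB <- sum(!low); n <- length(low)
  if (ncol(mat) != n) stop("label length must match the number of samples")

  ranks <- t(apply(mat, 1, rank))
  W <- as.vector(ranks %*% as.numeric(low))
  mu <- nA * (n + 1) / 2
  tie_term <- apply(ranks, 1, function(r) { tt <- table(r); sum(tt^3 - tt) })
  sigma <- sqrt(nA * nB / 12 * ((n + 1) - tie_term / (n * (n - 1))))
  z <- (abs(W - mu) - 0.5) / pmax(sigma, 1e-12)
  p <- pmin(1, 2 * stats::pnorm(-pmax(z, 0)))
  p[sigma <= 0] <- 1

  q <- permutation_fdr(mat, low, n_perm = n_perm, seed = seed)
  mean_low <- rowMeans(mat[, low, drop = FALSE])
  mean_high <- rowMeans(mat[, !low, drop = FALSE])
  data.frame(probe_id = rownames(mat), statistic = W, p = p, q = q,
             mean_low = mean_low, mean_high = mean_high,
             direction = ifelse(mean_low > mean_high, "up_in_low", "down_in_low"),
             row.names = NULL)
}

#' Select a directional probe signature
#'
#' Retains probes meeting both the p-value and q-value thresholds and
#' splits them by direction of change (a probe is `up_in_low` when its
#' mean in the low group exceeds its mean in the high group).  An empty
#' selection returns an empty signature, not an error.
#'
#' @param results data frame from [run_diffexpr()].
#' @param p_max,q_max selection thresholds (defaults 1e-4 and 0.10).
#' @return a [signature_def()] object.
#' @export
select_signature <- function(results, p_max = 1e-4, q_max = 0.10) {
  keep <- results$p < p_max & results$q < q_max
  sel <- results[keep, , drop = FALSE]
  signature_def(up_in_low = sel$probe_id[sel$direction == "up_in_low"],
                down_in_low = sel$probe_id[sel$direction == "down_in_low"],
                allow_empty = TRUE)
}
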