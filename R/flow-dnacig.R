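## DNA/CIg profile of a specimen from kappa- and lambda-tube event tables.
##
## Pipeline: QC gate -> pulse-width doublet gate -> light-chain
## classification (involved chain, LCR mask) -> G0/1 peak finding in the
## light-chain-negative (diploid reference) and light-chain-positive (stem
## line) compartments -> DNA index, ploidy class, per-stem-line CIg.

#' Quality-control gate for a flow event table
#'
#' Drops events with non-finite channels, non-positive DNA or pulse width,
#' negative light-chain signal, or any channel at or beyond the linear
#' range.  Assays retaining fewer than `min_events` events are rejected.
#'
#' @param events data frame with columns `dna`, `lc`, `width`.
#' @param min_events minimum gated events for an interpretable assay (500).
#' @param linear_max upper bound of the linear range; saturated rows are
#'   dropped.
#' @return the gated table, with attributes `n_input` and `n_dropped`.
#' @export
qc_gate <- function(events, min_events = 500, linear_max = 1023) {
  stopifnot(all(c("dna", "lc", "width") %in% names(events)))
  ok <- is.finite(events$dna) & is.finite(events$lc) & is.finite(events$width) &
    events$dna > 0 & events$width > 0 & events$lc >= 0 &
    events$dna < linear_max & events$lc < linear_max & events$width < linear_max
  gated <- events[ok, , drop = FALSE]
  if (nrow(gated) < min_events) {
    stop(structure(class = c("dnacig_rejected_low_events", "error", "condition"),
                   list(message = sprintf(
                     "assay rejected: %d gated events (fewer than %d)",
                     nrow(gated), min_events), call = sys.call(-1))))
  }
  truth <- attr(events, "truth")
  if (!is.null(truth)) attr(gated, "truth") <- truth[ok, , drop = FALSE]
  attr(gated, "tube") <- attr(events, "tube")
  attr(gated, "n_input") <- nrow(events)
  attr(gated, "n_dropped") <- nrow(events) - nrow(gated)
  gated
}

#' Pulse-width doublet gate
#'
#' Aggregated nuclei (doublets) carry roughly twice the DNA of a singlet
#' and a broader pulse.  The gate is fitted from the dominant width mode:
#' events with width above mode + `k` robust SDs are removed.  The spread
#' is estimated from the left half of the singlet mode only, so the
#' doublet tail cannot inflate it.  With all widths identical the gate is
#' disabled with a warning and the input returned unchanged.
#'
#' @param events QC-gated event table.
#' @param k gate width in robust SDs above the mode (default 3).
#' @return singlet events; attributes `width_gate` and `removed_fraction`.
#' @export
discriminate_doublets <- function(events, k = 3) {
  w <- events$width
  if (length(unique(w)) == 1L) {
    warning("degenerate pulse-width distribution; doublet gate disabled")
    attr(events, "width_gate") <- NA_real_
    attr(events, "removed_fraction") <- 0
    return(events)
  }
  ms <- mode_and_left_spread(w)
  if (!is.finite(ms$sigma) || ms$sigma <= 0) {
    warning("pulse-width spread could not be estimated; doublet gate disabled")
    attr(events, "width_gate") <- NA_real_
    attr(events, "removed_fraction") <- 0
    return(events)
  }
  gate <- ms$mode + k * ms$sigma
  keep <- w <= gate
  out <- events[keep, , drop = FALSE]
  truth <- attr(events, "truth")
  if (!is.null(truth)) attr(out, "truth") <- truth[keep, , drop = FALSE]
  attr(out, "tube") <- attr(events, "tube")
  attr(out, "width_gate") <- gate
  attr(out, "removed_fraction") <- 1 - mean(keep)
  out
}

## K-component 1-D Gaussian EM, initialised at the kernel-density modes.
## Refines the mode locations into unbiased peak means when adjacent G0/1
## peaks overlap.  `x` must already be restricted to the peak regions.
.gauss_em <- function(x, mu0, sd0, max_iter = 200, tol = 1e-8) {
  k <- length(mu0)
  mu <- mu0; sdv <- sd0; w <- rep(1 / k, k)
  n <- length(x)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j)
      w[j] * stats::dnorm(x, mu[j], sdv[j]), numeric(n))
    dens <- matrix(dens, nrow = n)
    tot <- rowSums(dens)
    tot[tot < 1e-300] <- 1e-300
    r <- dens / tot
    nk <- colSums(r)
    nk[nk < 1e-8] <- 1e-8
    mu <- colSums(r * x) / nk
    sdv <- sqrt(colSums(r * (x - rep(mu, each = n))^2) / nk)
    sdv <- pmax(sdv, 1e-6)
    w <- nk / n
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  list(mu = mu, sd = sdv, w = w, resp = r)
}

#' Locate G0/1 DNA peaks
#'
#' Local maxima of a Gaussian-kernel density (Sheather-Jones plug-in
#' bandwidth) above a prominence floor are taken as candidate G0/1 peaks;
#' their means and SDs are then refined with a Gaussian-mixture EM
#' restricted to the peak neighbourhoods, which keeps overlapping peaks
#' from biasing each other's means.  Peaks with CV above 5\% are flagged.
#'
#' @param dna linear DNA channel values.
#' @param prominence_frac a mode must reach this fraction of the tallest
#'   mode's density to count as a peak (default 0.05).
#' @param min_values minimum number of values (default 500).
#' @param cv_flag peaks with CV above this are flagged (default 0.05).
#' @return data frame with one row per peak (sorted by mean): `mean`, `sd`,
#'   `cv`, `lower`, `upper` (mean +/- 2 SD), `weight`, `height`, `flagged`.
#' @export
find_g01_peaks <- function(dna, prominence_frac = 0.05, min_values = 500,
                           cv_flag = 0.05) {
  if (length(dna) < min_values)
    stop(sprintf("peak finding needs at least %d values, got %d",
                 min_values, length(dna)))
  bw <- tryCatch(stats::bw.SJ(dna), error = function(e) stats::bw.nrd0(dna))
  d <- stats::density(dna, bw = bw, n = 1024)
  y <- d$y
  is_max <- c(FALSE, y[2:1023] > y[1:1022] & y[2:1023] >= y[3:1024], FALSE)
  peaks_i <- which(is_max & y >= prominence_frac * max(y))
  ## degenerate input (e.g. uniform noise): no mode clearly dominates the
  ## bulk of the density
  if (length(peaks_i) == 0L || max(y) < 2 * stats::median(y))
    stop("no detectable G0/1 peak")
  modes <- d$x[peaks_i]
  heights <- y[peaks_i]

  ## initial SD per mode from the half-width at half height, bounded by
  ## the neighbouring valley
  sd0 <- vapply(seq_along(peaks_i), function(j) {
    i <- peaks_i[j]; half <- y[i] / 2
    li <- i; while (li > 1 && y[li] > half) li <- li - 1
    ri <- i; while (ri < 1024 && y[ri] > half) ri <- ri + 1
    hw <- min(d$x[i] - d$x[li], d$x[ri] - d$x[i])
    max(hw / 1.1774, bw / 2)
  }, numeric(1))

  in_window <- rep(FALSE, length(dna))
  for (j in seq_along(modes))
    in_window <- in_window | (dna >= modes[j] - 3 * sd0[j] &
                              dna <= modes[j] + 3 * sd0[j])
  xw <- dna[in_window]
  fit <- .gauss_em(xw, modes, sd0)
  ## merge components that the mixture cannot actually separate: a kernel
  ## wiggle in the saddle between two peaks seeds a broad parasitic
  ## component that overlaps its neighbours and dilutes every event's
  ## responsibility.  Adjacent components closer than one SD are merged
  ## (moment-matched) and the mixture refitted.
  repeat {
    k <- length(fit$mu)
    if (k < 2) break
    ord <- order(fit$mu)
    mu <- fit$mu[ord]; sdv <- fit$sd[ord]; w <- fit$w[ord]
    gap <- diff(mu)
    sep <- gap / pmax(sdv[-k], sdv[-1])
    if (min(sep) >= 1) { fit <- list(mu = mu, sd = sdv, w = w); break }
    i <- which.min(sep)
    wm <- w[i] + w[i + 1]
    mm <- (w[i] * mu[i] + w[i + 1] * mu[i + 1]) / wm
    sm <- sqrt((w[i] * (sdv[i]^2 + mu[i]^2) +
                w[i + 1] * (sdv[i + 1]^2 + mu[i + 1]^2)) / wm - mm^2)
    mu <- c(mu[-(i:(i + 1))], mm); sdv <- c(sdv[-(i:(i + 1))], sm)
    fit <- .gauss_em(xw, mu, sdv)
  }
  ord <- order(fit$mu)
  mu <- fit$mu[ord]
  height <- stats::approx(d$x, d$y, xout = mu, rule = 2)$y
  res <- data.frame(mean = mu, sd = fit$sd[ord],
                    cv = fit$sd[ord] / mu,
                    lower = mu - 2 * fit$sd[ord],
                    upper = mu + 2 * fit$sd[ord],
                    weight = fit$w[ord], height = height)
  res$flagged <- res$cv > cv_flag
  res
}

## Assign events to peaks: a member of peak j lies within [lower_j, upper_j]
## and carries posterior responsibility for j above `conf` under the fitted
## mixture.  Events in the ambiguity zone between overlapping peaks are left
## unassigned (NA) so they cannot cross-contaminate per-peak statistics.
.assign_peak <- function(x, peaks, conf = 0.9) {
  k <- nrow(peaks)
  dens <- vapply(seq_len(k), function(j)
    peaks$weight[j] * stats::dnorm(x, peaks$mean[j], peaks$sd[j]),
    numeric(length(x)))
  dens <- matrix(dens, nrow = length(x))
  tot <- rowSums(dens)
  best <- max.col(dens, ties.method = "first")
  r_best <- dens[cbind(seq_along(x), best)] / pmax(tot, 1e-300)
  in_bounds <- x >= peaks$lower[best] & x <= peaks$upper[best]
  out <- ifelse(in_bounds & r_best >= conf, best, NA_integer_)
  as.integer(out)
}

#' Classify the involved light chain and gate the LCR population
#'
#' Per tube, the light-chain-negative background mode is located on the
#' log-intensity density (the lowest substantial mode) and its spread
#' estimated from the left half of that cluster; events above the 99.5th
#' percentile of the fitted background are light-chain positive.  The tube
#' with the larger positive fraction identifies the involved chain; the
#' call is `indeterminate` when both fractions are below `min_pos` or when
#' they differ by less than `margin`.
#'
#' @param kappa_tube,lambda_tube QC-gated, doublet-gated event tables.
#' @param quantile background quantile defining positivity (0.995).
#' @param margin minimum difference between the tubes' positive fractions
#'   for a determinate call (0.02).
#' @param min_pos minimum positive fraction for a determinate call (0.02).
#' @return list with `involved` (`"kappa"`, `"lambda"` or
#'   `"indeterminate"`), `positive` (list of logical masks per tube),
#'   `fraction` (named positive fractions) and `threshold` (per tube, on
#'   the linear light-chain scale).
#' @export
classify_light_chain <- function(kappa_tube, lambda_tube, quantile = 0.995,
                                 margin = 0.02, min_pos = 0.02) {
  one <- function(ev) {
    lc <- ev$lc
    pos_floor <- if (any(lc > 0)) min(lc[lc > 0]) / 2 else 1e-6
    lx <- log(pmax(lc, pos_floor))
    d <- stats::density(lx, n = 512)
    y <- d$y
    is_max <- c(FALSE, y[2:511] > y[1:510] & y[2:511] >= y[3:512], FALSE)
    ## the background is the lowest substantial mode; the floor is high
    ## enough (25% of the tallest mode) that kernel wiggles on the flank
    ## of the background cluster are not mistaken for it
    cand <- which(is_max & y >= 0.25 * max(y))
    if (length(cand) == 0L) cand <- which.max(y)
    bg_mode <- d$x[min(cand)]
    ## refine the background fit on the cluster itself: the kernel mode
    ## has too much wobble to anchor a 99.5th-percentile threshold, so
    ## the location is the cluster median and the spread comes from the
    ## left half only (the positive tail cannot inflate it)
    below0 <- lx[lx <= bg_mode]
    sigma0 <- max(stats::median(bg_mode - below0) / 0.6745, 1e-6)
    cluster <- lx[lx <= bg_mode + 2.5 * sigma0]
    med <- stats::median(cluster)
    sigma <- max(stats::median(med - cluster[cluster <= med]) / 0.6745, 1e-6)
    thr <- med + stats::qnorm(quantile) * sigma
    list(mask = lx > thr, threshold = exp(thr))
  }
  k <- one(kappa_tube); l <- one(lambda_tube)
  fk <- mean(k$mask); fl <- mean(l$mask)
  involved <- if (max(fk, fl) < min_pos || abs(fk - fl) < margin)
    "indeterminate" else if (fk > fl) "kappa" else "lambda"
  list(involved = involved,
       positive = list(kappa = k$mask, lambda = l$mask),
       fraction = c(kappa = fk, lambda = fl),
       threshold = c(kappa = k$threshold, lambda = l$threshold))
}

#' DNA index of a stem line
#'
#' Ratio of the mean DNA channel of a light-chain-positive G0/1 peak to
#' the mean of the light-chain-negative diploid G0/1 peak.
#' @param lcr_peak_mean,reference_peak_mean G0/1 peak means (linear scale).
#' @export
compute_di <- function(lcr_peak_mean, reference_peak_mean) {
  if (any(reference_peak_mean <= 0)) stop("reference peak mean must be positive")
  if (any(lcr_peak_mean <= 0)) stop("LCR peak mean must be positive")
  lcr_peak_mean / reference_peak_mean
}

#' Ploidy class from a DNA index
#'
#' Diploid for DI in the closed interval [0.99, 1.01], hyperdiploid above
#' 1.01, hypodiploid below 0.99.
#' @param di DNA index (vectorised).
#' @export
classify_ploidy <- function(di) {
  if (any(di <= 0)) stop("DNA index must be positive")
  ifelse(di > 1.01, "hyperdiploid", ifelse(di < 0.99, "hypodiploid", "diploid"))
}

#' Cytoplasmic immunoglobulin index
#'
#' Ratio of the geometric mean light-chain fluorescence of the
#' light-chain-positive G0/1 events to that of the light-chain-negative
#' diploid G0/1 events.  Zero intensities are floored to half the smallest
#' positive recorded value before taking logs.
#'
#' @param lc_positive,lc_negative light-chain intensities of the two G0/1
#'   populations.
#' @export
compute_cig <- function(lc_positive, lc_negative) {
  if (length(lc_positive) == 0L || length(lc_negative) == 0L)
    stop("empty G0/1 peak membership")
  all_lc <- c(lc_positive, lc_negative)
  pos <- all_lc[all_lc > 0]
  if (length(pos) == 0L) stop("all light-chain intensities are zero")
  fl <- min(pos) / 2
  geomean(lc_positive, floor_value = fl) / geomean(lc_negative, floor_value = fl)
}

#' Build the DNA/CIg profile of a specimen
#'
#' Composes the full analysis: QC and doublet gates on both tubes,
#' light-chain classification, diploid reference peak from the
#' light-chain-negative compartment of the involved tube (its tallest
#' G0/1 peak), stem lines as the light-chain-positive G0/1 peaks with DNA
#' index, percentage of gated events and per-line CIg.  The stem line with
#' the highest percentage is dominant and sets the ploidy class.
#'
#' @param kappa_tube,lambda_tube raw event tables for the two tubes.
#' @param cig_cutoff low-CIg threshold; `any_cig_below` is `TRUE` when the
#'   minimum stem-line CIg falls below it (default 2.8).
#' @param min_events QC minimum per tube (500).
#' @param linear_max upper bound of the linear channel range (see
#'   [qc_gate()]).
#' @param min_peak_events minimum light-chain-positive events required to
#'   search for stem-line peaks (default 100).
#' @param ... passed to [classify_light_chain()].
#' @return an object of class `dnacig_profile`: `involved_chain`,
#'   `lcr_pct`, `stem_lines` (data frame with `di`, `pct_of_gated`, `cig`,
#'   `ploidy`, `dominant`), `n_stem_lines`, `ploidy`, `any_cig_below`,
#'   `qc` diagnostics.
#' @export
build_profile <- function(kappa_tube, lambda_tube, cig_cutoff = 2.8,
                          min_events = 500, linear_max = 1023,
                          min_peak_events = 100, ...) {
  kg <- discriminate_doublets(qc_gate(kappa_tube, min_events = min_events,
                                      linear_max = linear_max))
  lg <- discriminate_doublets(qc_gate(lambda_tube, min_events = min_events,
                                      linear_max = linear_max))
  cl <- classify_light_chain(kg, lg, ...)
  qc <- list(passed = TRUE,
             n_gated = c(kappa = nrow(kg), lambda = nrow(lg)),
             doublet_fraction = c(kappa = attr(kg, "removed_fraction"),
                                  lambda = attr(lg, "removed_fraction")),
             lc_threshold = cl$threshold)
  empty <- list(involved_chain = cl$involved, lcr_pct = NA_real_,
                stem_lines = data.frame(), n_stem_lines = 0L,
                ploidy = NA_character_, any_cig_below = NA, qc = qc)
  if (cl$involved == "indeterminate") {
    return(structure(empty, class = "dnacig_profile"))
  }
  inv <- if (cl$involved == "kappa") kg else lg
  pos <- cl$positive[[cl$involved]]
  n_gated <- nrow(inv)
  neg <- inv[!pos, , drop = FALSE]
  positives <- inv[pos, , drop = FALSE]
  if (nrow(positives) < min_peak_events)
    stop("too few light-chain-positive events to resolve stem lines")

  ref_peaks <- find_g01_peaks(neg$dna)
  ref <- ref_peaks[which.max(ref_peaks$weight), , drop = FALSE]
  neg_assign <- .assign_peak(neg$dna, ref_peaks)
  ref_members <- which(neg_assign == which.max(ref_peaks$weight))

  stem_peaks <- find_g01_peaks(positives$dna,
                               min_values = min(min_peak_events, 500))
  pos_assign <- .assign_peak(positives$dna, stem_peaks)
  if (all(is.na(pos_assign)))   # heavily overlapping peaks: fall back to
    pos_assign <- .assign_peak(positives$dna, stem_peaks, conf = 0.5)

  ## a mode with no confident members is not a stem line (it can happen
  ## for a marginal density wiggle); drop it before building the table
  n_memb <- vapply(seq_len(nrow(stem_peaks)), function(j)
    sum(pos_assign == j, na.rm = TRUE), numeric(1))
  keep_peaks <- which(n_memb > 0)
  if (!length(keep_peaks)) stop("no populated stem-line peak")
  stem_peaks <- stem_peaks[keep_peaks, , drop = FALSE]
  pos_assign <- match(pos_assign, keep_peaks)

  k <- nrow(stem_peaks)
  di <- compute_di(stem_peaks$mean, ref$mean)
  pct <- vapply(seq_len(k), function(j)
    100 * sum(pos_assign == j, na.rm = TRUE) / n_gated, numeric(1))
  cig <- vapply(seq_len(k), function(j)
    compute_cig(positives$lc[which(pos_assign == j)], neg$lc[ref_members]),
    numeric(1))
  dominant <- seq_len(k) == which.max(pct)
  stem <- data.frame(di = di, pct_of_gated = pct, cig = cig,
                     ploidy = classify_ploidy(di), dominant = dominant,
                     cv = stem_peaks$cv, flagged = stem_peaks$flagged)
  out <- list(involved_chain = cl$involved,
              lcr_pct = 100 * mean(pos),
              stem_lines = stem,
              n_stem_lines = k,
              ploidy = stem$ploidy[stem$dominant],
              any_cig_below = min(stem$cig, na.rm = TRUE) < cig_cutoff,
              cig_cutoff = cig_cutoff,
              qc = qc)
  structure(out, class = "dnacig_profile")
}

#' @export
print.dnacig_profile <- function(x, ...) {
  cat("DNA/CIg profile\n")
  cat(sprintf("  involved chain : %s\n", x$involved_chain))
  if (x$n_stem_lines > 0) {
    cat(sprintf("  LCR%%           : %.1f\n", x$lcr_pct))
    cat(sprintf("  ploidy         : %s (dominant DI %.3f)\n",
                x$ploidy, x$stem_lines$di[x$stem_lines$dominant]))
    cat(sprintf("  stem lines     : %d\n", x$n_stem_lines))
    for (i in seq_len(nrow(x$stem_lines)))
      cat(sprintf("    DI %.3f  %5.1f%% of gated  CIg %.2f%s\n",
                  x$stem_lines$di[i], x$stem_lines$pct_of_gated[i],
                  x$stem_lines$cig[i],
                  if (x$stem_lines$dominant[i]) "  [dominant]" else ""))
    cat(sprintf("  any CIg < %.1f  : %s\n", x$cig_cutoff, x$any_cig_below))
  }
  invisible(x)
}
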