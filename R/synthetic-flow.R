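## Synthetic two-tube DNA/CIg flow-cytometry specimens.
##
## One specimen is measured as two stained tubes (kappa and lambda).  The
## clonal, light-chain-restricted (LCR) population appears light-chain
## positive only in the tube stained for its involved chain; in the other
## tube the same cells carry only background staining.  Each DNA stem line
## is a Gaussian G0/1 peak at DI x reference channel, with a uniform S-phase
## plateau up to 2x and a G2/M peak at 2x.  Doublets are sums of two random
## singlets with an inflated pulse width.

#' Parameters for a simulated DNA/CIg specimen
#'
#' @param n_events total events recorded per tube (doublets included).
#' @param stem_lines list of stem lines, each a list with elements `di`
#'   (DNA index, ratio to the diploid reference), `fraction` (share of the
#'   LCR population) and `cig` (target cytoplasmic immunoglobulin index,
#'   a geometric-mean ratio to the light-chain-negative population).
#' @param involved_chain `"kappa"` or `"lambda"`.
#' @param lcr_fraction proportion of gated events that belong to the LCR
#'   (clonal) population.
#' @param dna_cv coefficient of variation of G0/1 DNA peaks.  Instrument
#'   standardisation in the emulated assay required CVs below 3\%.
#' @param s_phase_fraction,g2m_fraction cell-cycle proportions within every
#'   compartment.
#' @param doublet_rate proportion of recorded events that are doublets.
#' @param background_cig geometric-mean ratio of background light-chain
#'   staining to the nominal background channel (about 1).
#' @param dna_ref_channel linear DNA channel of the diploid G0/1 peak.
#' @param lc_ref_geomean geometric mean of background light-chain
#'   fluorescence at `background_cig = 1`.
#' @param lc_sdlog log-scale SD of light-chain fluorescence within a
#'   compartment.  The default (0.08) emulates bright, well-resolved
#'   staining with daily-control calibration, giving the bimodal
#'   light-chain histograms the analyser assumes.
#' @param width_mode,width_sd pulse-width location and spread of singlets.
#' @param doublet_width_mode,doublet_width_sd pulse-width location and
#'   spread of doublets (separated from the singlet mode by design).
#' @param seed integer seed; fixing it fixes every generated value.
#' @return an object of class `flow_sim_params`.
#' @export
flow_sim_params <- function(n_events = 10000,
                            stem_lines = list(list(di = 1.0, fraction = 1.0, cig = 4.0)),
                            involved_chain = c("kappa", "lambda"),
                            lcr_fraction = 0.4,
                            dna_cv = 0.03,
                            s_phase_fraction = 0.06,
                            g2m_fraction = 0.03,
                            doublet_rate = 0.03,
                            background_cig = 1.0,
                            dna_ref_channel = 200,
                            lc_ref_geomean = 100,
                            lc_sdlog = 0.08,
                            width_mode = 1.0,
                            width_sd = 0.05,
                            doublet_width_mode = 1.8,
                            doublet_width_sd = 0.12,
                            seed = NULL) {
  involved_chain <- match.arg(involved_chain)
  if (!is.numeric(n_events) || n_events <= 0)
    stop("'n_events' must be a positive count")
  if (length(stem_lines) < 1L) stop("at least one stem line is required")
  fr <- vapply(stem_lines, function(s) s$fraction, numeric(1))
  di <- vapply(stem_lines, function(s) s$di, numeric(1))
  cig <- vapply(stem_lines, function(s) s$cig, numeric(1))
  if (any(fr < 0) || sum(fr) > 1 + 1e-8)
    stop("stem-line fractions must be non-negative and sum to at most 1")
  if (any(di <= 0) || any(cig <= 0))
    stop("stem-line 'di' and 'cig' must be positive")
  for (nm in c("lcr_fraction", "dna_cv", "s_phase_fraction",
               "g2m_fraction", "doublet_rate"))
    stopifnot_proportion(get(nm), nm)
  if (s_phase_fraction + g2m_fraction >= 1)
    stop("cell-cycle fractions must leave room for the G0/1 compartment")
  p <- list(n_events = as.integer(n_events), stem_lines = stem_lines,
            involved_chain = involved_chain, lcr_fraction = lcr_fraction,
            dna_cv = dna_cv, s_phase_fraction = s_phase_fraction,
            g2m_fraction = g2m_fraction, doublet_rate = doublet_rate,
            background_cig = background_cig,
            dna_ref_channel = dna_ref_channel,
            lc_ref_geomean = lc_ref_geomean, lc_sdlog = lc_sdlog,
            width_mode = width_mode, width_sd = width_sd,
            doublet_width_mode = doublet_width_mode,
            doublet_width_sd = doublet_width_sd, seed = seed)
  class(p) <- "flow_sim_params"
  p
}

## Draw one compartment: G0/1 Gaussian at `g01_mean`, uniform S plateau to
## 2x, G2/M Gaussian at 2x.  Returns DNA channel values.
.sim_dna <- function(n, g01_mean, cv, s_frac, g2m_frac) {
  phase <- sample.int(3L, n, replace = TRUE,
                      prob = c(1 - s_frac - g2m_frac, s_frac, g2m_frac))
  dna <- numeric(n)
  n1 <- sum(phase == 1L); n2 <- sum(phase == 2L); n3 <- sum(phase == 3L)
  if (n1) dna[phase == 1L] <- stats::rnorm(n1, g01_mean, cv * g01_mean)
  if (n2) dna[phase == 2L] <- stats::runif(n2, g01_mean, 2 * g01_mean)
  if (n3) dna[phase == 3L] <- stats::rnorm(n3, 2 * g01_mean, cv * 2 * g01_mean)
  list(dna = pmax(dna, 1e-6), phase = phase)
}

.sim_tube <- function(p, carries_lcr) {
  n_doub <- round(p$n_events * p$doublet_rate)
  n_sing <- p$n_events - n_doub

  fr <- vapply(p$stem_lines, function(s) s$fraction, numeric(1))
  if (sum(fr) > 0) fr <- fr / sum(fr)
  k <- length(p$stem_lines)
  ## compartment 0 = LC-negative normal diploid; 1..k = stem lines
  comp <- sample.int(k + 1L, n_sing, replace = TRUE,
                     prob = c(1 - p$lcr_fraction, p$lcr_fraction * fr)) - 1L
  dna <- numeric(n_sing)
  lc <- numeric(n_sing)
  bg_log <- log(p$lc_ref_geomean * p$background_cig)
  for (j in 0:k) {
    idx <- which(comp == j)
    if (!length(idx)) next
    g01 <- if (j == 0L) p$dna_ref_channel else
      p$stem_lines[[j]]$di * p$dna_ref_channel
    dna[idx] <- .sim_dna(length(idx), g01, p$dna_cv,
                         p$s_phase_fraction, p$g2m_fraction)$dna
    ## light chain: positive only for stem lines in the involved tube
    mulog <- if (j > 0L && carries_lcr)
      bg_log + log(p$stem_lines[[j]]$cig) else bg_log
    lc[idx] <- stats::rlnorm(length(idx), mulog, p$lc_sdlog)
  }
  width <- pmax(stats::rnorm(n_sing, p$width_mode, p$width_sd), 1e-3)

  if (n_doub > 0L) {
    i1 <- sample.int(n_sing, n_doub, replace = TRUE)
    i2 <- sample.int(n_sing, n_doub, replace = TRUE)
    dna <- c(dna, dna[i1] + dna[i2])
    lc <- c(lc, lc[i1] + lc[i2])
    width <- c(width, pmax(stats::rnorm(n_doub, p$doublet_width_mode,
                                        p$doublet_width_sd), 1e-3))
    comp <- c(comp, rep(-1L, n_doub))
  }
  ord <- sample.int(length(dna))
  tab <- data.frame(dna = dna[ord], lc = lc[ord], width = width[ord])
  attr(tab, "truth") <- data.frame(
    compartment = comp[ord], is_doublet = comp[ord] == -1L)
  tab
}

#' Simulate the kappa- and lambda-stained tubes of one specimen
#'
#' @param params a [flow_sim_params()] object.
#' @return a list with elements `kappa` and `lambda`, each a data frame
#'   with columns `dna`, `lc` and `width` and a `"truth"` attribute giving
#'   each event's generating compartment (`-1` doublet, `0` light-chain
#'   negative, `1..k` stem line) for validation.
#' @export
gen_flow_tubes <- function(params) {
  stopifnot(inherits(params, "flow_sim_params"))
  with_seed(params$seed, {
    kappa <- .sim_tube(params, carries_lcr = params$involved_chain == "kappa")
    lambda <- .sim_tube(params, carries_lcr = params$involved_chain == "lambda")
    attr(kappa, "tube") <- "kappa"
    attr(lambda, "tube") <- "lambda"
    list(kappa = kappa, lambda = lambda)
  })
}
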