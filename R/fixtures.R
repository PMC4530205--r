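## Packaged summary-level fixtures: the 12-probe CIg signature (probe
## identifiers, gene symbols and the two group mean log2 signals) and the
## 2x2 association tables of adverse covariates against low-CIg status.
## Both are summary tables; no patient-level data are shipped.

#' The 12-probe CIg expression signature table
#'
#' Twelve Affymetrix probe sets (11 genes) differentially expressed
#' between low-CIg (< 2.8) and high-CIg myeloma, with the mean log2
#' signal of each group.  Three probes (SLC19A1, BCCIP, CEP164) are
#' over-expressed in the low-CIg group; the other nine are
#' under-expressed.
#'
#' @return data frame with columns `probe_id`, `symbol`, `chromosome`,
#'   `mean_low_cig`, `mean_high_cig`.
#' @export
cig12_probes <- function() {
  utils::read.delim(system.file("extdata", "cig12_signature.tsv",
                                package = "dnacig"),
                    stringsAsFactors = FALSE)
}

#' The 12-probe signature as a directional signature object
#'
#' Directions are assigned from the group means of the packaged table: a
#' probe is `up_in_low` when its mean signal in the low-CIg group exceeds
#' its mean in the high-CIg group.
#'
#' @return a [signature_def()].
#' @export
cig12_signature <- function() {
  tab <- cig12_probes()
  up <- tab$mean_low_cig > tab$mean_high_cig
  signature_def(up_in_low = tab$probe_id[up],
                down_in_low = tab$probe_id[!up])
}

#' Covariate associations with low CIg as 2x2 counts
#'
#' Univariate 2x2 tables of adverse baseline covariates against low-CIg
#' (< 2.8) status in the defining cohort, reconstructed from the published
#' n/N summaries, together with the published odds ratios and Wald 95\%
#' confidence limits for comparison.
#'
#' @return data frame with one row per covariate: `factor`, `n`, the
#'   counts `low_exposed`, `n_exposed`, `low_unexposed`, `n_unexposed`,
#'   and the published `or_printed`, `ci_lo_printed`, `ci_hi_printed`.
#' @export
low_cig_assoc_tables <- function() {
  utils::read.delim(system.file("extdata", "low_cig_assoc.tsv",
                                package = "dnacig"),
                    stringsAsFactors = FALSE)
}

#' Odds ratios for the packaged association tables
#'
#' Recomputes [odds_ratio_2x2()] for every packaged covariate table
#' (a = low-CIg among exposed, b = exposed without low CIg, c = low-CIg
#' among unexposed, d = unexposed without).
#'
#' @return data frame with `factor`, `or`, `ci_lo`, `ci_hi`, `p` and the
#'   published values alongside.
#' @export
low_cig_assoc_odds_ratios <- function() {
  tab <- low_cig_assoc_tables()
  res <- lapply(seq_len(nrow(tab)), function(i) {
    a <- tab$low_exposed[i]
    b <- tab$n_exposed[i] - tab$low_exposed[i]
    c <- tab$low_unexposed[i]
    d <- tab$n_unexposed[i] - tab$low_unexposed[i]
    o <- odds_ratio_2x2(a, b, c, d)
    data.frame(factor = tab$factor[i], or = o$or, ci_lo = o$ci[1],
               ci_hi = o$ci[2], p = o$p)
  })
  cbind(do.call(rbind, res),
        tab[, c("or_printed", "ci_lo_printed", "ci_hi_printed")])
}
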