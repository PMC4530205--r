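# Shared simulation fixtures, built in code at test time.

# The reference two-stem-line specimen: diploid line at CIg 1.5 and a
# hyperdiploid line (DI 1.10) at CIg 4.0, each half of an LCR population
# covering 40% of events.
two_line_params <- function(seed, n_events = 10000, ...) {
  flow_sim_params(
    n_events = n_events,
    stem_lines = list(list(di = 1.00, fraction = 0.5, cig = 1.5),
                      list(di = 1.10, fraction = 0.5, cig = 4.0)),
    involved_chain = "kappa",
    lcr_fraction = 0.4,
    seed = seed, ...)
}

profile_from_seed <- function(seed, ...) {
  tubes <- gen_flow_tubes(two_line_params(seed, ...))
  build_profile(tubes$kappa, tubes$lambda)
}

# Small two-group expression matrix with `n_shift` shifted probes.
shifted_matrix <- function(seed, n_null = 200, n_shift = 5, shift = 2,
                           n1 = 20, n2 = 20, sd = 1) {
  withr::with_seed(seed, {
    lab <- rep(c(TRUE, FALSE), c(n1, n2))
    mat <- matrix(rnorm((n_null + n_shift) * (n1 + n2), 0, sd),
                  nrow = n_null + n_shift)
    mat[seq_len(n_shift), lab] <- mat[seq_len(n_shift), lab] + shift
    rownames(mat) <- c(sprintf("shift_%02d", seq_len(n_shift)),
                       sprintf("null_%03d", seq_len(n_null)))
    colnames(mat) <- sprintf("S%02d", seq_len(n1 + n2))
    list(mat = mat, low = lab)
  })
}
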