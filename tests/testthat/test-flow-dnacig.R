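make_events <- function(n, dna = 200, lc = 100, width = 1) {
  data.frame(dna = rep(dna, length.out = n), lc = rep(lc, length.out = n),
             width = rep(width, length.out = n))
}

test_that("qc gate enforces the 500-event minimum at the boundary", {
  expect_error(qc_gate(make_events(499)), class = "dnacig_rejected_low_events")
  expect_identical(nrow(qc_gate(make_events(500))), 500L)
})

test_that("qc gate drops saturated and non-finite rows and reports counts", {
  ev <- make_events(10000)
  ev$dna[1:100] <- 1023        # saturated
  ev$lc[101:150] <- NA
  out <- qc_gate(ev)
  expect_identical(nrow(out), 9850L)
  expect_identical(attr(out, "n_dropped"), 150L)
})

test_that("doublet gate removes injected doublets and spares singlets", {
  # under the null, at most ~1% of singlets fall above the gate
  p0 <- flow_sim_params(n_events = 10000, doublet_rate = 0, seed = 21)
  t0 <- gen_flow_tubes(p0)$kappa
  g0 <- discriminate_doublets(qc_gate(t0))
  expect_lte(attr(g0, "removed_fraction"), 0.01)

  p1 <- flow_sim_params(n_events = 10000, doublet_rate = 0.10, seed = 22)
  t1 <- gen_flow_tubes(p1)$kappa
  q1 <- qc_gate(t1)
  g1 <- discriminate_doublets(q1)
  expect_gt(attr(g1, "removed_fraction"), 0.08)
  expect_lt(attr(g1, "removed_fraction"), 0.12)
  # at least 95% of the injected doublets lie above the fitted gate
  truth <- attr(q1, "truth")
  flagged <- q1$width > attr(g1, "width_gate")
  expect_gte(mean(flagged[truth$is_doublet]), 0.95)
})

test_that("a degenerate width distribution disables the gate", {
  ev <- make_events(1000)
  expect_warning(out <- discriminate_doublets(ev), "disabled")
  expect_identical(nrow(out), 1000L)
})

test_that("peak finding resolves single and double Gaussians", {
  set.seed(31)
  one <- find_g01_peaks(rnorm(5000, 200, 4))
  expect_identical(nrow(one), 1L)
  expect_equal(one$mean, 200, tolerance = 1 / 200)
  expect_false(one$flagged)

  two <- find_g01_peaks(c(rnorm(4000, 200, 4), rnorm(4000, 220, 4.4)))
  expect_identical(nrow(two), 2L)
  expect_equal(two$mean, c(200, 220), tolerance = 1 / 200)

  expect_error(find_g01_peaks(runif(5000, 0, 1000)), "no detectable")
  expect_error(find_g01_peaks(rnorm(100, 200, 4)), "at least")
})

test_that("involved-chain calls follow dominance with a tie guard", {
  p <- flow_sim_params(n_events = 6000,
                       stem_lines = list(list(di = 1, fraction = 1, cig = 4)),
                       involved_chain = "kappa", lcr_fraction = 0.40,
                       seed = 41)
  tubes <- gen_flow_tubes(p)
  kg <- discriminate_doublets(qc_gate(tubes$kappa))
  lg <- discriminate_doublets(qc_gate(tubes$lambda))
  cl <- classify_light_chain(kg, lg)
  expect_identical(cl$involved, "kappa")
  expect_lt(cl$fraction[["lambda"]], 0.02)

  # simulated LCR fraction recovered within 2 percentage points
  p20 <- flow_sim_params(n_events = 10000,
                         stem_lines = list(list(di = 1, fraction = 1, cig = 4)),
                         lcr_fraction = 0.20, seed = 42)
  t20 <- gen_flow_tubes(p20)
  cl20 <- classify_light_chain(discriminate_doublets(qc_gate(t20$kappa)),
                               discriminate_doublets(qc_gate(t20$lambda)))
  expect_lt(abs(cl20$fraction[["kappa"]] - 0.20), 0.02)
})

test_that("DNA index and ploidy thresholds follow the published rules", {
  expect_equal(compute_di(220, 200), 1.10)
  expect_equal(compute_di(200, 200), 1.00)
  expect_error(compute_di(200, 0), "positive")
  expect_identical(classify_ploidy(c(1.00, 0.99, 1.01, 1.02, 0.95, 1.10)),
                   c("diploid", "diploid", "diploid", "hyperdiploid",
                     "hypodiploid", "hyperdiploid"))
  expect_identical(classify_ploidy(compute_di(190, 200)), "hypodiploid")
})

test_that("CIg is a geometric-mean ratio with zero flooring", {
  expect_equal(compute_cig(rep(280, 50), rep(100, 50)), 2.8)
  set.seed(51)
  x <- rlnorm(2000, log(100), 0.1)
  expect_equal(compute_cig(x, x), 1.0)
  withz <- c(x, 0)   # zero floored, not fatal
  expect_true(is.finite(compute_cig(withz, x)))
  expect_error(compute_cig(numeric(0), x), "empty")
})

test_that("a two-stem-line specimen is profiled end to end", {
  # diploid line at 25% of gated events, hyperdiploid at 15%: the diploid
  # line dominates and sets the ploidy class
  p <- flow_sim_params(
    n_events = 10000,
    stem_lines = list(list(di = 1.00, fraction = 0.625, cig = 1.5),
                      list(di = 1.10, fraction = 0.375, cig = 4.0)),
    involved_chain = "kappa", lcr_fraction = 0.4, seed = 61)
  tubes <- gen_flow_tubes(p)
  pr <- build_profile(tubes$kappa, tubes$lambda)
  expect_identical(pr$n_stem_lines, 2L)
  expect_identical(pr$involved_chain, "kappa")
  expect_identical(pr$ploidy, "diploid")
  expect_true(pr$stem_lines$dominant[1])
  expect_equal(pr$stem_lines$di, c(1.00, 1.10), tolerance = 0.01)
  expect_equal(pr$stem_lines$cig, c(1.5, 4.0), tolerance = 0.05)
  expect_equal(pr$lcr_pct, 40, tolerance = 2 / 40)
  expect_true(pr$any_cig_below)            # min CIg 1.5 < 2.8
  expect_identical(sum(pr$stem_lines$dominant), 1L)
  expect_lte(sum(pr$stem_lines$pct_of_gated), pr$lcr_pct)
  expect_lte(pr$lcr_pct, 100)
})

test_that("DI and CIg are invariant to common channel rescaling", {
  tubes <- gen_flow_tubes(two_line_params(71, n_events = 8000))
  # a wide linear range keeps the rescaled channels inside the QC gate,
  # so the comparison isolates the ratio estimators themselves
  base <- build_profile(tubes$kappa, tubes$lambda, linear_max = 1e9)
  scale_ch <- function(ev, dna_f, lc_f) {
    ev$dna <- ev$dna * dna_f; ev$lc <- ev$lc * lc_f; ev
  }
  # rescale DNA on both tubes: DI unchanged (ratio estimator)
  resc <- build_profile(scale_ch(tubes$kappa, 1.5, 1),
                        scale_ch(tubes$lambda, 1.5, 1), linear_max = 1e9)
  expect_equal(resc$stem_lines$di, base$stem_lines$di, tolerance = 1e-6)
  # rescale the light chain: CIg unchanged
  resc2 <- build_profile(scale_ch(tubes$kappa, 1, 2.5),
                         scale_ch(tubes$lambda, 1, 2.5), linear_max = 1e9)
  expect_equal(resc2$stem_lines$cig, base$stem_lines$cig, tolerance = 1e-6)
})

test_that("a single diploid clone gives a minimal profile", {
  p <- flow_sim_params(n_events = 8000,
                       stem_lines = list(list(di = 1, fraction = 1, cig = 3.5)),
                       involved_chain = "lambda", lcr_fraction = 0.30,
                       seed = 81)
  tubes <- gen_flow_tubes(p)
  pr <- build_profile(tubes$kappa, tubes$lambda)
  expect_identical(pr$n_stem_lines, 1L)
  expect_identical(pr$involved_chain, "lambda")
  expect_identical(pr$ploidy, "diploid")
  expect_false(pr$any_cig_below)
  expect_equal(pr$lcr_pct, 30, tolerance = 2 / 30)
})
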