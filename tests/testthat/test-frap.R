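make_trace <- function(bleach, reference = rep(500, length(bleach)),
                       dt = 1, id = "w1", group = "g") {
  frap_trace(id, group, (seq_along(bleach) - 1) * dt, bleach, reference)
}

test_that("bleach frame detection finds the earliest global minimum", {
  tr <- make_trace(c(100, 100, 100, 100, 100, 10, 40, 70, 80, 90))
  expect_equal(detect_bleach_index(tr), 6L)
  tie <- make_trace(c(100, 100, 100, 100, 100, 10, 10, 70, 80, 90))
  expect_equal(detect_bleach_index(tie), 6L)
  early <- make_trace(c(10, 100, 100, 100, 100, 100, 100, 100, 100, 100))
  expect_error(detect_bleach_index(early), "pre-bleach window")
})

test_that("acquisition-bleaching correction is exact on linear decay", {
  t <- 0:19
  flat <- make_trace(rep(100, 20), rep(500, 20))
  expect_equal(correct_acquisition_bleaching(flat)$bleach_roi, flat$bleach_roi)

  decayed <- make_trace(100 * (1 - 0.01 * t), 500 * (1 - 0.01 * t))
  corr <- correct_acquisition_bleaching(decayed)
  expect_equal(corr$bleach_roi, rep(100, 20), tolerance = 1e-12)
  # corrected reference has (numerically) zero slope
  fit <- lm(corr$reference_roi ~ corr$times)
  expect_lt(abs(coef(fit)[2]), 1e-9)

  # synthetic trace with acquisition bleaching corrects to the bleach-free one
  p_s <- frap_sim_params(acq_bleach_slope = 0.005, noise_sd = 0, n_worms = 1)
  p_0 <- frap_sim_params(acq_bleach_slope = 0, noise_sd = 0, n_worms = 1)
  tr_s <- correct_acquisition_bleaching(gen_frap_traces(p_s)$traces[[1]])
  tr_0 <- gen_frap_traces(p_0)$traces[[1]]
  expect_equal(tr_s$bleach_roi, tr_0$bleach_roi, tolerance = 1e-9)

  # a reference trend crossing zero is nonsense
  neg <- make_trace(rep(100, 20), 500 - 30 * t)
  expect_error(correct_acquisition_bleaching(neg), "not positive")
})

test_that("normalization pins the bleach frame at 0 and the pre-bleach mean at 1", {
  tr <- make_trace(c(rep(100, 5), 20, 60, 80, 90, 95))
  norm <- normalize_trace(tr)
  expect_equal(norm$bleach_index, 6L)
  expect_equal(norm$f_norm[7], 0.5)  # (60 - 20) / (100 - 20)
  expect_equal(norm$f_norm[norm$bleach_index], 0)
  expect_equal(mean(norm$f_norm[norm$prebleach_window]), 1)

  flatzero <- make_trace(rep(100, 10))
  expect_error(normalize_trace(flatzero, bleach_index = 6L), "dynamic range")
})

test_that("normalization invariants hold on randomized legal traces", {
  for (seed in 1:25) {
    p <- with_seed_params <- frap_sim_params(
      prebleach_level = 500 + 100 * (seed %% 5),
      bleach_depth = 0.1 + 0.05 * (seed %% 4),
      mobile_fraction_true = 0.2 + 0.15 * (seed %% 5),
      t_half_true = 1 + seed %% 7,
      acq_bleach_slope = 0.002 * (seed %% 3),
      noise_sd = 5 + seed %% 10,
      n_worms = 1, seed = seed)
    tr <- gen_frap_traces(p)$traces[[1]]
    norm <- normalize_trace(correct_acquisition_bleaching(tr))
    expect_equal(norm$f_norm[norm$bleach_index], 0)
    expect_equal(mean(norm$f_norm[norm$prebleach_window]), 1, tolerance = 1e-9)
  }
})

test_that("estimates are equivariant to time rescaling and invariant to intensity scale", {
  p <- frap_sim_params(acq_bleach_slope = 0.003, noise_sd = 8, n_worms = 1,
                       seed = 13)
  tr <- gen_frap_traces(p)$traces[[1]]
  base <- estimate_recovery(normalize_trace(correct_acquisition_bleaching(tr)))

  for (c_scale in c(0.5, 3)) {
    tscaled <- frap_trace(tr$worm_id, tr$group, tr$times * c_scale,
                          tr$bleach_roi, tr$reference_roi)
    est <- estimate_recovery(normalize_trace(correct_acquisition_bleaching(tscaled)))
    expect_equal(est$t_half, base$t_half * c_scale, tolerance = 1e-9)
    expect_equal(est$mobile_fraction, base$mobile_fraction, tolerance = 1e-12)

    iscaled <- frap_trace(tr$worm_id, tr$group, tr$times,
                          tr$bleach_roi * c_scale, tr$reference_roi * c_scale)
    est_i <- estimate_recovery(normalize_trace(correct_acquisition_bleaching(iscaled)))
    expect_equal(est_i$t_half, base$t_half, tolerance = 1e-9)
    expect_equal(est_i$mobile_fraction, base$mobile_fraction, tolerance = 1e-12)
  }
})

test_that("model-free estimates handle degenerate recoveries", {
  frozen <- make_trace(c(rep(100, 5), rep(20, 10)))
  est <- estimate_recovery(normalize_trace(frozen))
  expect_equal(est$mobile_fraction, 0)
  expect_true(is.na(est$t_half))
  expect_true("never_reaches_half_recovery" %in% est$qc_flags)

  jump <- make_trace(c(rep(100, 5), 20, rep(100, 9)), dt = 0.5)
  est_j <- estimate_recovery(normalize_trace(jump))
  expect_equal(est_j$mobile_fraction, 1)
  expect_lte(est_j$t_half, 0.5)
})

test_that("model-free estimates recover generator truth on noise-free traces", {
  p <- frap_sim_params(mobile_fraction_true = 0.8, t_half_true = 5,
                       frame_interval = 0.5, noise_sd = 0, n_worms = 1)
  tr <- gen_frap_traces(p)$traces[[1]]
  est <- estimate_recovery(normalize_trace(tr))
  expect_equal(est$t_half, 5, tolerance = 0.05 / 5)
  expect_equal(est$mobile_fraction, 0.8, tolerance = 0.01 / 0.8)
})

test_that("exponential fit recovers generator truth and flags degenerate input", {
  p <- frap_sim_params(mobile_fraction_true = 0.8, t_half_true = 5,
                       noise_sd = 0, n_worms = 1)
  norm <- normalize_trace(gen_frap_traces(p)$traces[[1]])
  fit <- fit_exponential(norm)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), c(0.8, 5), tolerance = 1e-6)
  # consistency with the model-free estimator within grid tolerance
  est <- estimate_recovery(norm)
  expect_equal(est$t_half, fit$tau_fit, tolerance = 0.05)
  expect_equal(est$mobile_fraction, fit$m_fit, tolerance = 0.01)

  frozen <- make_trace(c(rep(100, 5), rep(20, 15)))
  ffit <- fit_exponential(normalize_trace(frozen))
  expect_lt(ffit$m_fit, 1e-3)
  expect_true("tau_unidentifiable" %in% ffit$qc_flags)
})

test_that("exponential fit is nearly unbiased for tau at 2% noise", {
  taus <- vapply(1:12, function(s) {
    p <- frap_sim_params(noise_sd = 20, n_worms = 1, seed = 100 + s)
    fit_exponential(normalize_trace(gen_frap_traces(p)$traces[[1]]))$tau_fit
  }, 0)
  expect_lt(abs(mean(taus) - 5) / 5, 0.10)
})

test_that("group summaries report mean, sem and Welch contrasts", {
  # two identical constant groups: zero difference, p = 1 by convention
  tr <- gen_frap_traces(frap_sim_params(noise_sd = 0, n_worms = 4))$traces
  gs <- summarize_group(tr, groups = rep(c("a", "b"), 2))
  expect_equal(gs$tests$p, c(1, 1))
  expect_true(all(gs$curves$a$sem == 0))

  # sem = sd/sqrt(n) on a 3-trace group
  sims <- gen_frap_traces(frap_sim_params(noise_sd = 10, n_worms = 3, seed = 8))
  gs3 <- summarize_group(c(sims$traces, tr[1:2]),
                         groups = c("x", "x", "x", "y", "y"))
  norms <- lapply(sims$traces, function(t) {
    normalize_trace(correct_acquisition_bleaching(t))
  })
  k0 <- which(gs3$curves$x$time_rel == 0)
  vals <- vapply(norms, function(n) n$f_norm[n$bleach_index], 0)
  expect_equal(gs3$curves$x$sem[k0], sd(vals) / sqrt(3))

  # strong true difference in mobile fraction rejects decisively
  ga <- gen_frap_traces(frap_sim_params(mobile_fraction_true = 0.8,
                                        noise_sd = 20, n_worms = 10, seed = 21))
  gb <- gen_frap_traces(frap_sim_params(mobile_fraction_true = 0.4,
                                        noise_sd = 20, n_worms = 10, seed = 22))
  gs2 <- summarize_group(c(ga$traces, gb$traces), rep(c("hi", "lo"), each = 10))
  pm <- gs2$tests$p[gs2$tests$metric == "mobile_fraction"]
  expect_lt(pm, 0.001)

  # mixed frame intervals are refused
  slow <- gen_frap_traces(frap_sim_params(frame_interval = 1, n_worms = 2))$traces
  expect_error(summarize_group(c(tr[1:2], slow), rep(c("a", "b"), each = 2)),
               "mixed frame intervals")
})
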