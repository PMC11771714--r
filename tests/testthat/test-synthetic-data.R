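test_that("synthetic trace encodes the relaxation curve exactly when noiseless", {
  truth <- toy_truth()
  tr <- simulate_trace(truth, noise_cv = 0, seed = 1)
  s <- compute_npq(tr)
  relax <- s$pulses[s$pulses$phase == "lowlight2", ]
  # direct evaluation of the relaxation model at the first pulse
  expect_equal(relax$npq[relax$t_min == 2.5],
               0.5 + 2.0 * exp(-2.5 / 1.0) + 1.6 * exp(-2.5 / 23),
               tolerance = 1e-12)
  # asymptote: only qI remains at long times
  expect_equal(npq_relaxation(1e9, 2, 1.6, 0.5, 1, 23), 0.5)
  # every pulse matches the true curve when noise is off
  expect_equal(relax$npq,
               npq_relaxation(relax$t_min, truth$a_qe, truth$a_qm, truth$a_qi,
                              truth$tau_qe, truth$tau_qm),
               tolerance = 1e-12)
})

test_that("trace generation is deterministic given a seed and validates input", {
  a <- simulate_trace(toy_truth(), noise_cv = 0.05, seed = 42)
  b <- simulate_trace(toy_truth(), noise_cv = 0.05, seed = 42)
  expect_identical(a, b)
  expect_false(identical(
    a$pulses$fm_prime,
    simulate_trace(toy_truth(), noise_cv = 0.05, seed = 43)$pulses$fm_prime))
  expect_error(simulate_trace(toy_truth(), noise_cv = -0.1), "noise_cv")
  expect_error(kinetics_truth(a_qe = -1), "amplitudes")
  expect_error(kinetics_truth(tau_qe = 30, tau_qm = 20), "tau_qe < tau_qm")
  expect_error(npq_protocol(pulses = list(lowlight1 = c(5, 2.5),
                                          highlight = 5, lowlight2 = c(5, 10))),
               "strictly increasing")
})

test_that("trace CSV round-trips losslessly through the reader", {
  tr <- simulate_trace(toy_truth(), noise_cv = 0.02, seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_traces(list(tr), path)
  back <- read_traces(path)[[1]]
  expect_equal(back$fm_dark, tr$fm_dark)
  expect_equal(back$pulses$fm_prime, tr$pulses$fm_prime, tolerance = 1e-12)
  expect_equal(back$pulses$phase, tr$pulses$phase)
  expect_equal(compute_npq(back)$pulses$npq, compute_npq(tr)$pulses$npq,
               tolerance = 1e-12)
})

test_that("wide-format trace tables are accepted", {
  tr <- simulate_trace(toy_truth(), noise_cv = 0, seed = 1)
  wide <- data.frame(disk_id = "d1", plot_id = "p1", genotype = "RC",
                     date = "2021-07-01", fm_dark = 4000, f0_dark = 800)
  for (i in seq_len(nrow(tr$pulses))) {
    wide[[paste0(tr$pulses$phase[i], "_", tr$pulses$t_min[i])]] <- tr$pulses$fm_prime[i]
  }
  back <- read_traces(wide)[[1]]
  f_long <- fit_relaxation(compute_npq(tr))
  f_wide <- fit_relaxation(compute_npq(back))
  expect_equal(f_wide$tau_qm, f_long$tau_qm, tolerance = 1e-9)
})

test_that("synthetic weather has full 30-min coverage and seeded determinism", {
  w <- simulate_weather("2021-07-01", "2021-07-02", seed = 5)
  expect_equal(nrow(w), 2 * 48)
  expect_true(all(diff(as.numeric(w$timestamp)) == 1800))
  expect_true(all(w$rh_pct >= 0 & w$rh_pct <= 100))
  expect_true(all(w$fsd_wm2 >= 0))
  expect_identical(w, simulate_weather("2021-07-01", "2021-07-02", seed = 5))
  expect_error(simulate_weather("2021-07-02", "2021-07-01"), "precede")
})

test_that("experiment with all effects at zero reproduces the baseline exactly", {
  base <- kinetics_truth(induction_tau = 0.4)  # saturated induction
  des <- experiment_design(genotypes = c("RC", "NAM1"),
                           plots_per_genotype = 2, disks_per_plot = 2,
                           sampling_days = as.Date("2021-07-01") + c(0, 7),
                           baseline = base, seed = 3)
  ex <- generate_experiment(des, traces = TRUE)
  for (p in c("a_qe", "a_qm", "a_qi", "tau_qe", "tau_qm")) {
    expect_true(all(ex$truth[[p]] == base[[p]]))
  }
  # fitting the noiseless traces returns the baseline too
  fits <- fit_relaxation_table(ex$trace_objects[1:3])
  expect_equal(fits$a_qi, rep(base$a_qi, 3), tolerance = 1e-6)
  expect_equal(fits$tau_qm, rep(base$tau_qm, 3), tolerance = 1e-6)
})

test_that("a genotype shift on a_qi propagates exactly through fitting", {
  des <- experiment_design(genotypes = c("RC", "NAM1"),
                           plots_per_genotype = 1, disks_per_plot = 1,
                           sampling_days = as.Date("2021-07-01") + c(0, 7),
                           baseline = kinetics_truth(induction_tau = 0.4),
                           genotype_effects = list(NAM1 = c(a_qi = -0.1)),
                           seed = 3)
  ex <- generate_experiment(des)
  fits <- fit_relaxation_table(ex$trace_objects)
  m <- tapply(fits$a_qi, fits$genotype, mean)
  expect_equal(unname(m["NAM1"] - m["RC"]), -0.1, tolerance = 1e-6)
})

test_that("unknown genotype labels in the effects map are rejected", {
  expect_error(experiment_design(genotype_effects = list(NOPE = c(a_qi = 1))),
               "unknown genotype")
})
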