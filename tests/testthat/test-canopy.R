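const_light <- function(ppfd, hours = 2, area = 5e-6) {
  tm <- seq(6 * 60, 6 * 60 + hours * 60)
  data.frame(pixel_id = "px1", area_m2 = area, time_min = tm, ppfd = ppfd)
}

test_that("steady-state leaf model matches hand-computed FvCB values", {
  cst <- leaf_constants()
  expect_equal(steady_state_leaf(0, cst)$a, -cst$rd)  # dark respiration only
  # hand evaluation at 500 umol
  i2 <- 0.5 * 0.85 * 500
  j <- ((i2 + 180) - sqrt((i2 + 180)^2 - 4 * 0.7 * i2 * 180)) / (2 * 0.7)
  wj <- j * (270 - 38.6) / (4 * 270 + 8 * 38.6)
  act <- 0.3 + 0.7 * 500 / 650
  wc <- 100 * act * (270 - 38.6) / (270 + 710)
  expect_equal(steady_state_leaf(500, cst)$a, min(wc, wj) - 1.5, tolerance = 1e-9)
  # saturating light with a large Jmax is Rubisco-limited
  big_j <- leaf_constants(jmax = 1e4)
  ss <- steady_state_leaf(5e4, big_j)
  expect_equal(ss$a, ss$wc - big_j$rd, tolerance = 1e-6)
  expect_error(leaf_constants(gamma_star = 300, ci = 270), "nonphysical")
})

test_that("steady-state NPQ is anchored at the assay's high-light level", {
  kin <- toy_truth()
  cst <- leaf_constants()
  expect_equal(steady_state_leaf(2000, cst, kin)$npq,
               kin$a_qe + kin$a_qm + kin$a_qi, tolerance = 1e-12)
  # qI persists in darkness; only qE+qM are light-dependent
  expect_equal(steady_state_leaf(0, cst, kin)$npq, kin$a_qi)
})

test_that("constant light from steady state is a fixed point of the dynamics", {
  kin <- toy_truth(); cst <- leaf_constants()
  tot <- steady_state_leaf(700, cst, kin)$npq
  w <- kin$a_qe / (kin$a_qe + kin$a_qm)
  st <- list(e = w * (tot - kin$a_qi), m = (1 - w) * (tot - kin$a_qi),
             act = steady_state_leaf(700, cst, kin)$vc_act)
  st2 <- step_dynamics(st, 700, kin, cst, dt = 10)
  expect_equal(st2$e, st$e, tolerance = 1e-12)
  expect_equal(st2$m, st$m, tolerance = 1e-12)
  expect_equal(st2$act, st$act, tolerance = 1e-12)
})

test_that("a high-to-low light step relaxes along the analytic double exponential", {
  kin <- toy_truth(); cst <- leaf_constants()
  hi <- steady_state_leaf(2000, cst, kin)$npq
  lo <- steady_state_leaf(50, cst, kin)$npq
  w <- kin$a_qe / (kin$a_qe + kin$a_qm)
  st <- list(e = w * (hi - kin$a_qi), m = (1 - w) * (hi - kin$a_qi), act = 1)
  e_lo <- w * (lo - kin$a_qi); m_lo <- (1 - w) * (lo - kin$a_qi)
  excess0 <- hi - lo
  for (step in 1:600) {  # 10 min at dt = 1 s
    st <- step_dynamics(st, 50, kin, cst, dt = 1)
    t_min <- step / 60
    expected <- excess0 * (w * exp(-t_min / kin$tau_qe) +
                             (1 - w) * exp(-t_min / kin$tau_qm))
    npq_excess <- (st$e - e_lo) + (st$m - m_lo)
    expect_equal(npq_excess, expected, tolerance = 1e-6)
  }
})

test_that("canopy Ac is linear in pixels and steady under constant light", {
  kin <- toy_truth()
  one <- const_light(800)
  sc1 <- canopy_scenario(one, ground_area = 1e-5, kinetics = kin)
  r1 <- simulate_canopy(sc1)
  two <- rbind(one, transform(one, pixel_id = "px2"))
  r2 <- simulate_canopy(canopy_scenario(two, ground_area = 1e-5, kinetics = kin))
  expect_equal(r2$daily_ac, 2 * r1$daily_ac, tolerance = 1e-12)
  # constant light: Ac(t) equals the steady-state rate throughout
  a_ss <- steady_state_leaf(800, leaf_constants(), kin)$a
  expect_equal(r1$timeseries$ac, rep(a_ss * 5e-6 / 1e-5, nrow(r1$timeseries)),
               tolerance = 1e-9)
  # trapezoidal integral consistency
  expect_equal(r1$daily_ac,
               pracma::trapz(r1$timeseries$time_min * 60, r1$timeseries$ac) * 1e-6)
})

test_that("mismatched pixel time ranges are rejected", {
  a <- const_light(800)
  b <- transform(const_light(800), pixel_id = "px2")
  b <- b[-3, ]
  expect_error(canopy_scenario(rbind(a, b), 1e-5), "mismatched")
})

fluct_light <- function(hours = 3) {
  tm <- seq(8 * 60, 8 * 60 + hours * 60)
  ppfd <- ifelse((tm %/% 8) %% 2 == 0, 1500, 250)
  data.frame(pixel_id = "px1", area_m2 = 5e-6, time_min = tm, ppfd = ppfd)
}

test_that("with instantaneous kinetics the dynamic model tracks the steady state", {
  pl <- fluct_light()
  inst <- kinetics_truth(tau_qe = 1e-4, tau_qm = 1.1e-4)
  r <- simulate_canopy(canopy_scenario(pl, 5e-6, inst, tau_act = 1e-4, dt = 1))
  # steady-state-tracking reference on the same interpolated light grid
  grid_ppfd <- stats::approx(pl$time_min, pl$ppfd, xout = r$timeseries$time_min)$y
  ss <- steady_state_leaf(grid_ppfd, leaf_constants(), inst)$a
  ref <- pracma::trapz(r$timeseries$time_min * 60, ss) * 1e-6
  expect_lt(abs(r$daily_ac - ref) / abs(ref), 0.001)
})

test_that("daily Ac never exceeds the instantaneous steady-state rate", {
  pl <- fluct_light()
  kin <- toy_truth()
  r <- simulate_canopy(canopy_scenario(pl, 5e-6, kin))
  grid_ppfd <- stats::approx(pl$time_min, pl$ppfd, xout = r$timeseries$time_min)$y
  a_ss <- steady_state_leaf(grid_ppfd, leaf_constants(), kin)$a
  expect_true(all(r$timeseries$ac <= a_ss + 1e-9))
})

test_that("daily Ac is non-increasing in each relaxation time constant", {
  pl <- fluct_light()
  ac_of <- function(te, tm) {
    simulate_canopy(canopy_scenario(pl, 5e-6, kinetics_truth(tau_qe = te, tau_qm = tm)))$daily_ac
  }
  by_te <- vapply(c(0.5, 1, 2, 4), ac_of, numeric(1), tm = 25)
  expect_true(all(diff(by_te) <= 1e-12))
  by_tm <- vapply(c(10, 20, 30, 45), function(tm) ac_of(1, tm), numeric(1))
  expect_true(all(diff(by_tm) <= 1e-12))
})

test_that("the integration converges in the timestep", {
  pl <- fluct_light(hours = 2)
  kin <- toy_truth()
  a10 <- simulate_canopy(canopy_scenario(pl, 5e-6, kin, dt = 10))$daily_ac
  a5 <- simulate_canopy(canopy_scenario(pl, 5e-6, kin, dt = 5))$daily_ac
  a1 <- simulate_canopy(canopy_scenario(pl, 5e-6, kin, dt = 1))$daily_ac
  expect_lt(abs(a10 - a5) / abs(a5), 0.001)
  expect_lt(abs(a10 - a1) / abs(a1), 0.002)
  expect_error(canopy_scenario(pl, 5e-6, kin, dt = 7), "divide")
})

test_that("loss report: zero for the reference, ~zero without fluctuations", {
  kin_sets <- list(ref = toy_truth(),
                   slow = kinetics_truth(tau_qe = 1.29, tau_qm = 29.23))
  lr <- loss_report(kin_sets, "ref", list(day = const_light(900)), 1e-5)
  expect_equal(lr$loss_pct[lr$scenario == "ref"], 0)
  expect_lt(abs(lr$loss_pct[lr$scenario == "slow"]), 0.01)
  lr2 <- loss_report(kin_sets, "ref", list(day = fluct_light()), 1e-5)
  expect_gt(lr2$loss_pct[lr2$scenario == "slow"], 0)
})

test_that("synthetic light drivers are reproducible and well-formed", {
  p1 <- synth_par_day("cloudy", seed = 5)
  expect_identical(p1, synth_par_day("cloudy", seed = 5))
  expect_true(all(p1$par >= 0))
  sunny <- synth_par_day("sunny")
  expect_true(all(p1$par <= sunny$par + 1e-9))  # clouds only attenuate
  toy <- make_toy_canopy(p1, n_pixels = 10, seed = 3)
  expect_identical(toy, make_toy_canopy(p1, n_pixels = 10, seed = 3))
  expect_equal(length(unique(toy$pixel_light$pixel_id)), 10)
  expect_true(all(toy$pixel_light$ppfd >= 0))
})
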