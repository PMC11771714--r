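#' Leaf biochemical constants for the dynamic canopy model
#'
#' Farquhar-von Caemmerer-Berry (FvCB) constants for a sunlit soybean leaf,
#' with intercellular CO2 held constant (the simulation isolates NPQ and
#' Rubisco kinetics from stomatal dynamics). Electron transport follows the
#' non-rectangular hyperbola of PSII-absorbed light; the Rubisco activation
#' state in darkness and its half-saturation light, and the NPQ
#' half-saturation light, define the steady-state targets the dynamic states
#' relax toward.
#'
#' @param vcmax maximum carboxylation rate (umol m-2 s-1).
#' @param jmax maximum electron transport rate (umol m-2 s-1).
#' @param rd day respiration (umol m-2 s-1).
#' @param ci intercellular CO2 (ubar), held constant.
#' @param gamma_star CO2 compensation point without Rd (ubar).
#' @param kco effective Michaelis constant Kc(1 + O/Ko) (ubar).
#' @param phi_psii_max maximum PSII quantum yield (dimensionless).
#' @param theta curvature of the electron-transport light response.
#' @param act_min Rubisco activation state in darkness (fraction).
#' @param k_act half-saturation PPFD of the activation target (umol m-2 s-1).
#' @param k_npq half-saturation PPFD of steady-state NPQ (umol m-2 s-1).
#' @return named list of constants.
#' @export
leaf_constants <- function(vcmax = 100, jmax = 180, rd = 1.5, ci = 270,
                           gamma_star = 38.6, kco = 710,
                           phi_psii_max = 0.85, theta = 0.7,
                           act_min = 0.3, k_act = 150, k_npq = 500) {
  if (gamma_star >= ci) stop("nonphysical constants: gamma_star >= ci")
  as.list(environment())
}

# steady-state NPQ at a given absorbed PPFD: the qI amplitude persists as a
# light-independent baseline (photoinhibitory quenching does not relax on
# the simulated timescale); the qE+qM part saturates with light, scaled so
# the value at 2000 umol m-2 s-1 (the assay's high-light level) equals the
# amplitude sum of the kinetic parameter set
npq_ss <- function(ppfd, kinetics, constants) {
  total <- kinetics$a_qe + kinetics$a_qm + kinetics$a_qi
  k <- constants$k_npq
  kinetics$a_qi + (total - kinetics$a_qi) *
    (ppfd / (ppfd + k)) / (2000 / (2000 + k))
}

act_ss <- function(ppfd, constants) {
  constants$act_min + (1 - constants$act_min) * ppfd / (ppfd + constants$k_act)
}

fvcb_j <- function(i2, jmax, theta) {
  ((i2 + jmax) - sqrt((i2 + jmax)^2 - 4 * theta * i2 * jmax)) / (2 * theta)
}

#' Steady-state leaf assimilation, NPQ and Rubisco activation
#'
#' FvCB assimilation `A = min(Wc, Wj) - Rd` at a given absorbed PPFD, with
#' the Rubisco-limited rate scaled by the steady-state activation state and
#' the electron-transport-limited rate driven by the non-rectangular
#' hyperbola solution for J.
#'
#' @param ppfd absorbed photosynthetic photon flux density (umol m-2 s-1,
#'   >= 0); vectorised.
#' @param constants from [leaf_constants()].
#' @param kinetics a [kinetics_truth()] (used for the steady-state NPQ).
#' @return list with `a` (net assimilation, umol m-2 s-1), `npq`, `vc_act`,
#'   `wc`, `wj`.
#' @export
steady_state_leaf <- function(ppfd, constants = leaf_constants(),
                              kinetics = kinetics_truth()) {
  if (any(ppfd < 0)) stop("ppfd must be >= 0")
  act <- act_ss(ppfd, constants)
  wc <- constants$vcmax * act * (constants$ci - constants$gamma_star) /
    (constants$ci + constants$kco)
  i2 <- 0.5 * constants$phi_psii_max * ppfd
  j <- fvcb_j(i2, constants$jmax, constants$theta)
  wj <- j * (constants$ci - constants$gamma_star) /
    (4 * constants$ci + 8 * constants$gamma_star)
  list(a = pmin(wc, wj) - constants$rd,
       npq = npq_ss(ppfd, kinetics, constants),
       vc_act = act, wc = wc, wj = wj)
}

#' One integration step of the dynamic leaf states
#'
#' Exponential-Euler update (exact for a constant target over the step,
#' unconditionally stable) of the three first-order states: the fast (qE)
#' and intermediate (qM) NPQ pools relax toward their light-dependent
#' targets with their relaxation time constants when the target falls and
#' `induction_factor` times those constants when it rises; the Rubisco
#' activation state rises with `tau_act` and falls with `2 * tau_act`.
#'
#' @param state list with `e`, `m` (NPQ pools) and `act`; vectorised over
#'   pixels.
#' @param ppfd absorbed PPFD during the step.
#' @param kinetics a [kinetics_truth()].
#' @param constants from [leaf_constants()].
#' @param dt step length (seconds, <= 60).
#' @param tau_act Rubisco activation time constant (minutes).
#' @param induction_factor ratio of induction to relaxation time constants
#'   for the NPQ pools (default 0.5).
#' @return updated state.
#' @export
step_dynamics <- function(state, ppfd, kinetics, constants = leaf_constants(),
                          dt = 10, tau_act = 4, induction_factor = 0.5) {
  if (dt > 60) stop("dt must be <= 60 s")
  tot <- npq_ss(ppfd, kinetics, constants)
  wfrac <- kinetics$a_qe / (kinetics$a_qe + kinetics$a_qm)
  excess <- tot - kinetics$a_qi  # >= 0 by construction of npq_ss
  e_t <- wfrac * excess
  m_t <- (1 - wfrac) * excess
  relax <- function(x, target, tau_down, tau_up) {
    tau <- ifelse(target < x, tau_down, tau_up) * 60  # minutes -> s
    target + (x - target) * exp(-dt / tau)
  }
  a_t <- act_ss(ppfd, constants)
  list(e = relax(state$e, e_t, kinetics$tau_qe, induction_factor * kinetics$tau_qe),
       m = relax(state$m, m_t, kinetics$tau_qm, induction_factor * kinetics$tau_qm),
       act = relax(state$act, a_t, 2 * tau_act, tau_act))
}

dynamic_assim <- function(state, ppfd, kinetics, constants) {
  ss <- steady_state_leaf(ppfd, constants, kinetics)
  npq_now <- kinetics$a_qi + state$e + state$m
  f <- pmin(1, (1 + ss$npq) / (1 + npq_now))
  i2 <- 0.5 * constants$phi_psii_max * ppfd * f
  j <- fvcb_j(i2, constants$jmax, constants$theta)
  wj <- j * (constants$ci - constants$gamma_star) /
    (4 * constants$ci + 8 * constants$gamma_star)
  wc <- constants$vcmax * state$act * (constants$ci - constants$gamma_star) /
    (constants$ci + constants$kco)
  # dynamic limitations only ever reduce assimilation below the steady
  # state at the instantaneous light (excess activation carried over from
  # brighter periods cannot be exploited: RuBP regeneration caps it)
  pmin(wc, wj, ss$a + constants$rd) - constants$rd
}

#' Canopy scenario: pixel light drivers plus one kinetic parameter set
#'
#' @param pixel_light long data frame of absorbed light per leaf pixel:
#'   `pixel_id`, `area_m2`, `time_min` (minutes since midnight, common
#'   1-min grid across pixels) and `ppfd`.
#' @param ground_area occupied ground area of the simulated canopy (m2).
#' @param kinetics a [kinetics_truth()].
#' @param tau_act Rubisco activation time constant (minutes); deactivation
#'   is fixed at twice this value.
#' @param constants from [leaf_constants()].
#' @param dt integration timestep (seconds, must divide 60).
#' @param induction_factor see [step_dynamics()].
#' @return a `canopy_scenario` list.
#' @export
canopy_scenario <- function(pixel_light, ground_area, kinetics = kinetics_truth(),
                            tau_act = 4, constants = leaf_constants(), dt = 10,
                            induction_factor = 0.5) {
  if (60 %% dt != 0) stop("dt must divide 60 s")
  times <- sort(unique(pixel_light$time_min))
  ids <- unique(pixel_light$pixel_id)
  for (id in ids) {
    tt <- pixel_light$time_min[pixel_light$pixel_id == id]
    if (!identical(sort(tt), times)) stop("pixels cover mismatched time ranges")
  }
  if (any(pixel_light$ppfd < 0)) stop("ppfd must be >= 0")
  structure(list(pixel_light = pixel_light, ground_area = ground_area,
                 kinetics = kinetics, tau_act = tau_act, constants = constants,
                 dt = dt, induction_factor = induction_factor),
            class = "canopy_scenario")
}

#' Simulate daily canopy assimilation under fluctuating light
#'
#' Integrates the dynamic leaf model for every pixel (light linearly
#' interpolated from the 1-min input onto the `dt` grid, states initialised
#' at their steady state for the first light value) and aggregates the
#' canopy CO2 uptake per ground area, `Ac(t) = sum_i A_i(t) S_i / S_ground`.
#'
#' @param scenario a [canopy_scenario()].
#' @return an `ac_summary`: `daily_ac` (mol CO2 m-2 ground day-1, trapezoidal
#'   integral), `timeseries` (data frame `time_min`, `ac` in
#'   umol m-2 ground s-1), `n_pixels`.
#' @export
simulate_canopy <- function(scenario) {
  stopifnot(inherits(scenario, "canopy_scenario"))
  pl <- scenario$pixel_light
  times <- sort(unique(pl$time_min))
  ids <- unique(pl$pixel_id)
  light <- matrix(0, length(ids), length(times), dimnames = list(ids, NULL))
  area <- numeric(length(ids))
  for (k in seq_along(ids)) {
    d <- pl[pl$pixel_id == ids[k], ]
    d <- d[order(d$time_min), ]
    light[k, ] <- d$ppfd
    area[k] <- d$area_m2[1]
  }
  dt_min <- scenario$dt / 60
  grid <- seq(times[1], times[length(times)], by = dt_min)
  li <- t(apply(light, 1, function(x) stats::approx(times, x, xout = grid)$y))
  if (length(ids) == 1) li <- matrix(li, nrow = 1)

  kin <- scenario$kinetics; cst <- scenario$constants
  tot0 <- npq_ss(li[, 1], kin, cst)
  wfrac <- kin$a_qe / (kin$a_qe + kin$a_qm)
  ex0 <- tot0 - kin$a_qi
  state <- list(e = wfrac * ex0, m = (1 - wfrac) * ex0,
                act = act_ss(li[, 1], cst))
  ac <- numeric(length(grid))
  ac[1] <- sum(dynamic_assim(state, li[, 1], kin, cst) * area) / scenario$ground_area
  for (s in 2:length(grid)) {
    state <- step_dynamics(state, li[, s], kin, cst, dt = scenario$dt,
                           tau_act = scenario$tau_act,
                           induction_factor = scenario$induction_factor)
    ac[s] <- sum(dynamic_assim(state, li[, s], kin, cst) * area) / scenario$ground_area
  }
  daily <- pracma::trapz(grid * 60, ac) * 1e-6  # umol s -> mol
  structure(list(daily_ac = daily,
                 timeseries = data.frame(time_min = grid, ac = ac),
                 n_pixels = length(ids)),
            class = "ac_summary")
}

#' Percent daily assimilation loss of kinetic scenarios vs a reference
#'
#' Runs [simulate_canopy()] for each named kinetic parameter set over each
#' named light driver (all sharing pixels, ground area and leaf constants)
#' and reports `100 * (Ac_ref - Ac_scenario) / Ac_ref`.
#'
#' @param kinetics_sets named list of [kinetics_truth()] objects (e.g.
#'   `slowest`, `fastest`, `mean`, `RC`).
#' @param reference name of the reference set within `kinetics_sets`.
#' @param lights named list of pixel-light data frames (e.g. `cloudy`,
#'   `sunny`).
#' @param ground_area,tau_act,constants,dt,induction_factor passed to
#'   [canopy_scenario()].
#' @return data frame: `day`, `scenario`, `daily_ac`, `loss_pct`.
#' @export
loss_report <- function(kinetics_sets, reference, lights, ground_area,
                        tau_act = 4, constants = leaf_constants(), dt = 10,
                        induction_factor = 0.5) {
  stopifnot(reference %in% names(kinetics_sets))
  rows <- list()
  for (day in names(lights)) {
    ac <- vapply(kinetics_sets, function(kin) {
      simulate_canopy(canopy_scenario(lights[[day]], ground_area, kin,
                                      tau_act, constants, dt,
                                      induction_factor))$daily_ac
    }, numeric(1))
    ref <- ac[[reference]]
    rows[[day]] <- data.frame(day = day, scenario = names(ac),
                              daily_ac = unname(ac),
                              loss_pct = 100 * (ref - unname(ac)) / ref)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Synthetic incident PAR for a cloudy or sunny day
#'
#' A 1-min incident PAR series from 05:00 to 19:00: a clear-sky half-sine
#' envelope peaking at `peak` umol m-2 s-1, and on cloudy days a seeded
#' two-state (clear/overcast) cloud process with episode lengths of a few
#' minutes to tens of minutes attenuating it, smoothed over 3 min.
#'
#' @param type `"sunny"` or `"cloudy"`.
#' @param seed integer seed (cloud process).
#' @param peak clear-sky midday PAR (umol m-2 s-1).
#' @return data frame `time_min` (minutes since midnight), `par`.
#' @export
synth_par_day <- function(type = c("cloudy", "sunny"), seed = 1L, peak = 1800) {
  type <- match.arg(type)
  time_min <- seq(5 * 60, 19 * 60)
  hour <- time_min / 60
  clear <- peak * pmax(0, sin(pi * (hour - 5) / 14))
  if (type == "sunny") {
    return(data.frame(time_min = time_min, par = clear))
  }
  n <- length(time_min)
  trans <- withr::with_seed(seed, {
    state <- numeric(n)
    s <- 1  # 1 = clear, 0 = overcast
    i <- 1
    while (i <= n) {
      len <- round(stats::rexp(1, rate = 1 / 8)) + 1
      state[i:min(n, i + len - 1)] <- s
      i <- i + len
      s <- 1 - s
    }
    depth <- stats::runif(n, 0.10, 0.30)
    ifelse(state == 1, 1, depth)
  })
  sm <- stats::filter(trans, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- trans[is.na(sm)]
  data.frame(time_min = time_min, par = clear * as.numeric(sm))
}

#' Toy layered canopy light driver
#'
#' Expands an incident PAR series into per-pixel absorbed light for a small
#' synthetic canopy: pixels are spread over cumulative leaf area index
#' depths; each pixel alternates between sunlit and shaded states (seeded
#' two-state process, sunfleck scale of about 2 min, stationary sunlit
#' fraction `exp(-0.5 L)`), receiving `absorptance * PAR` when sunlit and
#' the exponentially attenuated diffuse level `absorptance * PAR *
#' exp(-k L)` when shaded.
#'
#' @param par data frame from [synth_par_day()] (`time_min`, `par`).
#' @param n_pixels number of leaf pixels.
#' @param lai canopy leaf area index spanned by the pixels (default 5.5, a
#'   soybean canopy near the R5 stage).
#' @param seed integer seed.
#' @param absorptance leaf absorptance.
#' @param k extinction coefficient for shade light.
#' @param depth_offset self-shading depth added to every pixel (leaf
#'   flutter and within-plant shading keep even top-of-canopy pixels from
#'   being permanently sunlit).
#' @param pixel_area area per pixel (m2).
#' @return list with `pixel_light` (long data frame for
#'   [canopy_scenario()]) and `ground_area` (m2, set so that total leaf
#'   area / ground area = `lai`).
#' @export
make_toy_canopy <- function(par, n_pixels = 40, lai = 5.5, seed = 1L,
                            absorptance = 0.85, k = 0.7, depth_offset = 0.5,
                            pixel_area = 5e-6) {
  n_t <- nrow(par)
  depths <- (seq_len(n_pixels) - 0.5) / n_pixels * lai + depth_offset
  sun <- withr::with_seed(seed, {
    m <- matrix(0, n_pixels, n_t)
    for (i in seq_len(n_pixels)) {
      p_sun <- exp(-0.5 * depths[i])
      # two-state chain, mean sunlit run ~2 min, stationary prob p_sun
      stay_sun <- exp(-1 / 2)
      stay_shade <- 1 - (1 - stay_sun) * p_sun / (1 - p_sun + 1e-9)
      stay_shade <- min(max(stay_shade, 0), 0.999)
      s <- stats::rbinom(1, 1, p_sun)
      for (j in seq_len(n_t)) {
        m[i, j] <- s
        stay <- if (s == 1) stay_sun else stay_shade
        if (stats::runif(1) > stay) s <- 1 - s
      }
    }
    m
  })
  rows <- lapply(seq_len(n_pixels), function(i) {
    shade <- exp(-k * depths[i])
    ppfd <- absorptance * par$par * ifelse(sun[i, ] == 1, 1, shade)
    data.frame(pixel_id = paste0("px", i), area_m2 = pixel_area,
               time_min = par$time_min, ppfd = ppfd)
  })
  list(pixel_light = do.call(rbind, rows),
       ground_area = n_pixels * pixel_area / lai)
}
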