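#' Synthesise a fluorescence pulse trace from known kinetics
#'
#' Inverts the NPQ definition to produce the Fm' value measured at every
#' saturating pulse of the protocol: `Fm'(t) = Fm_dark / (1 + NPQ(t))`,
#' perturbed by multiplicative Gaussian noise (fluorescence noise scales with
#' signal). True NPQ is zero in the first low-light phase, rises
#' mono-exponentially toward the amplitude sum during high light, and decays
#' along the double-exponential relaxation curve (plus the qI offset) after
#' the return to low light.
#'
#' @param truth a [kinetics_truth()] object.
#' @param protocol an [npq_protocol()] object.
#' @param noise_cv coefficient of variation of the multiplicative Fm' noise
#'   (fraction, >= 0).
#' @param seed integer seed; every stochastic generator in this package takes
#'   an explicit seed and leaves the global RNG untouched.
#' @param fm_dark,f0_dark dark-adapted maximal and minimal fluorescence
#'   (arbitrary units, `fm_dark > f0_dark > 0`).
#' @param disk_id,plot_id,genotype,date identifiers carried through to the
#'   trace.
#' @return a `fluorescence_trace`: list with the identifiers, `fm_dark`,
#'   `f0_dark` and a `pulses` data frame (`phase`, `t_min`, `fm_prime`).
#' @examples
#' tr <- simulate_trace(kinetics_truth(), noise_cv = 0, seed = 1)
#' compute_npq(tr)
#' @export
simulate_trace <- function(truth, protocol = npq_protocol(), noise_cv = 0,
                           seed = 1L, fm_dark = 4000, f0_dark = 800,
                           disk_id = "d1", plot_id = "p1",
                           genotype = "RC", date = as.Date("2021-07-01")) {
  stopifnot(inherits(truth, "kinetics_truth"), inherits(protocol, "npq_protocol"))
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (!(fm_dark > f0_dark && f0_dark > 0)) stop("need fm_dark > f0_dark > 0")
  pulses <- protocol_pulse_table(protocol)
  npq <- npq_true_at(pulses$phase, pulses$t_min, truth)
  fm_prime <- fm_dark / (1 + npq)
  if (noise_cv > 0) {
    eps <- withr::with_seed(seed, stats::rnorm(length(fm_prime), 0, noise_cv))
    fm_prime <- fm_prime * (1 + eps)
  }
  pulses$fm_prime <- fm_prime
  structure(list(disk_id = disk_id, plot_id = plot_id, genotype = genotype,
                 date = as.Date(date), fm_dark = fm_dark, f0_dark = f0_dark,
                 pulses = pulses),
            class = "fluorescence_trace")
}

#' Synthetic 30-minute weather series
#'
#' Emulates a mid-western growing-season weather station record: sinusoidal
#' diurnal air temperature (minimum near 06:00) riding on a shallow seasonal
#' trend plus day-to-day weather noise, relative humidity anticorrelated with
#' temperature, clear-sky shortwave radiation attenuated by persistent cloud
#' states, and stochastic precipitation events concentrated on cloudy days.
#' The series is gap-free at an exact 30-minute cadence.
#'
#' @param start,end first and last calendar day (inclusive), `Date` or
#'   coercible.
#' @param seed integer seed.
#' @return a `weather_series` data frame: `timestamp` (POSIXct, UTC),
#'   `ta_c`, `rh_pct`, `fsd_wm2`, `precip_mm`, `gap_filled` (logical).
#' @export
simulate_weather <- function(start, end, seed = 1L) {
  start <- as.Date(start); end <- as.Date(end)
  if (!(start < end)) stop("start must precede end")
  ts <- seq(as.POSIXct(paste(start, "00:00:00"), tz = "UTC"),
            as.POSIXct(paste(end, "23:30:00"), tz = "UTC"), by = "30 min")
  hour <- as.numeric(format(ts, "%H")) + as.numeric(format(ts, "%M")) / 60
  doy <- as.numeric(format(ts, "%j"))
  day_index <- as.numeric(as.Date(ts) - start) + 1
  n_days <- max(day_index)
  withr::with_seed(seed, {
    day_anom <- stats::filter(stats::rnorm(n_days, 0, 2.5), 0.6,
                              method = "recursive")
    cloudiness <- stats::plogis(stats::filter(stats::rnorm(n_days, 0, 1.5),
                                              0.5, method = "recursive"))
    rain_day <- stats::rbinom(n_days, 1, 0.12 + 0.5 * cloudiness)
    rain_amount <- stats::rgamma(n_days, shape = 1.2, scale = 6)
    within_noise <- stats::rnorm(length(ts), 0, 0.4)
    rain_slot <- sample.int(34, n_days, replace = TRUE)  # 30-min slots 0-17h
  })
  seasonal <- 24 + 4 * sin(2 * pi * (doy - 196) / 365)
  diurnal <- 6 * sin(2 * pi * (hour - 9) / 24)
  ta <- seasonal + diurnal + day_anom[day_index] + within_noise
  rh <- pmin(100, pmax(20, 95 - 2.8 * (ta - 15) + 20 * cloudiness[day_index]))
  clear <- pmax(0, sin(pi * (hour - 5.5) / 13.5)) * 950
  fsd <- clear * (1 - 0.75 * cloudiness[day_index])
  precip <- numeric(length(ts))
  slot <- floor(hour * 2) + 1
  hit <- rain_day[day_index] == 1 & slot == rain_slot[day_index]
  precip[hit] <- rain_amount[day_index[hit]]
  structure(data.frame(timestamp = ts, ta_c = ta, rh_pct = rh,
                       fsd_wm2 = fsd, precip_mm = precip,
                       gap_filled = FALSE),
            class = c("weather_series", "data.frame"))
}

#' Multi-genotype experiment design
#'
#' The layout of a leaf-disk phenotyping experiment: genotypes (including the
#' reference line `"RC"`), replicate plots per genotype, technical-replicate
#' disks per plot, sampling days, and the effect structure used to build each
#' disk's true kinetic parameters:
#' `truth = baseline + genotype effect + env coefficients x scaled daily
#' features + plot random effect + disk random effect`.
#'
#' @param genotypes character vector of genotype labels; must include `"RC"`.
#' @param groups named character vector assigning each genotype a panel group
#'   (`"elite"`, `"diverse"`, `"PI"`, `"RC"`); defaults to `"diverse"` for all
#'   but RC.
#' @param plots_per_genotype,disks_per_plot replication (defaults 5 and 5,
#'   the field design of the assay this emulates).
#' @param sampling_days `Date` vector of sampling days.
#' @param baseline a [kinetics_truth()] giving the population baseline.
#' @param genotype_effects named list: per genotype, a named numeric of
#'   additive shifts on any of `a_qe, a_qm, a_qi, tau_qe, tau_qm`.
#' @param env_effects named list: per kinetic parameter, a named numeric of
#'   linear coefficients on the centred/scaled daily environmental features
#'   (names among `morning_Ta, morning_VPD, morning_Fsd, precip_to_10am,
#'   Ta_3day, VPD_3day, Fsd_3day, Precip_3day_sum`).
#' @param plot_sd,disk_sd standard deviations of the Gaussian plot and disk
#'   random effects, additive on every kinetic parameter (>= 0).
#' @param noise_cv multiplicative Fm' measurement noise passed to
#'   [simulate_trace()].
#' @param seed integer seed.
#' @return an `experiment_design` list.
#' @export
experiment_design <- function(genotypes = c("RC", paste0("NAM", 1:5)),
                              groups = NULL,
                              plots_per_genotype = 5, disks_per_plot = 5,
                              sampling_days = as.Date("2021-06-24") + seq(0, 35, by = 7),
                              baseline = kinetics_truth(),
                              genotype_effects = list(),
                              env_effects = list(),
                              plot_sd = 0, disk_sd = 0, noise_cv = 0,
                              seed = 1L) {
  if (!"RC" %in% genotypes) stop("genotypes must include the reference line 'RC'")
  if (any(c(plot_sd, disk_sd, noise_cv) < 0)) stop("dispersion parameters must be >= 0")
  bad <- setdiff(names(genotype_effects), genotypes)
  if (length(bad)) stop("genotype_effects for unknown genotype(s): ",
                        paste(bad, collapse = ", "))
  if (is.null(groups)) {
    groups <- stats::setNames(ifelse(genotypes == "RC", "RC", "diverse"), genotypes)
  }
  structure(list(genotypes = genotypes, groups = groups,
                 plots_per_genotype = plots_per_genotype,
                 disks_per_plot = disks_per_plot,
                 sampling_days = as.Date(sampling_days),
                 baseline = baseline,
                 genotype_effects = genotype_effects,
                 env_effects = env_effects,
                 plot_sd = plot_sd, disk_sd = disk_sd, noise_cv = noise_cv,
                 seed = as.integer(seed)),
            class = "experiment_design")
}

kin_params <- c("a_qe", "a_qm", "a_qi", "tau_qe", "tau_qm")

#' Generate a full synthetic experiment with known ground truth
#'
#' Builds the per-disk true kinetic parameters from the design's effect
#' structure, then (optionally) synthesises the fluorescence trace of every
#' disk. Amplitudes are floored at 0 and the time-constant ordering
#' `tau_qe < tau_qm` is preserved by construction; effect sizes that would
#' violate it are rejected.
#'
#' @param design an [experiment_design()].
#' @param weather a `weather_series` covering all sampling days plus the 3
#'   preceding days (from [simulate_weather()] or [read_weather()]).
#' @param traces if `FALSE`, skip trace synthesis and return only the hidden
#'   truth table (fast path for calibration simulations).
#' @return list with `truth` (per-disk parameter table with identifiers, NAM
#'   group, date and joined daily features) and, when `traces = TRUE`,
#'   `traces` (long-format pulse table, the on-disk CSV schema) and
#'   `trace_objects` (list of `fluorescence_trace`).
#' @export
generate_experiment <- function(design, weather = NULL, traces = TRUE) {
  stopifnot(inherits(design, "experiment_design"))
  if (is.null(weather)) {
    weather <- simulate_weather(min(design$sampling_days) - 4,
                                max(design$sampling_days) + 1,
                                seed = design$seed + 1000L)
  }
  feats <- daily_env_features(weather)
  need <- design$sampling_days
  if (!all(need %in% feats$date)) stop("weather does not cover all sampling days")
  feats <- feats[match(need, feats$date), , drop = FALSE]
  feat_cols <- setdiff(names(feats), "date")
  # centred/scaled features across sampling days (constant feature -> 0)
  zfeats <- as.data.frame(lapply(feats[feat_cols], function(x) {
    s <- stats::sd(x)
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))

  grid <- expand.grid(disk = seq_len(design$disks_per_plot),
                      plot = seq_len(design$plots_per_genotype),
                      genotype = design$genotypes,
                      day = seq_along(need),
                      stringsAsFactors = FALSE)
  # plots are re-randomized every season: plot random effects are nested
  # within year, so a genotype's plot draw in one year says nothing about
  # its plots in the next
  years <- format(need, "%Y")
  plot_key <- paste(grid$genotype, grid$plot, years[grid$day], sep = "_")
  plot_levels <- unique(plot_key)
  n_plots <- length(plot_levels)
  withr::with_seed(design$seed, {
    plot_re <- matrix(stats::rnorm(n_plots * 5, 0, design$plot_sd), n_plots, 5)
    disk_re <- matrix(stats::rnorm(nrow(grid) * 5, 0, design$disk_sd), nrow(grid), 5)
    trace_seeds <- sample.int(.Machine$integer.max - 1L, nrow(grid))
  })
  colnames(plot_re) <- colnames(disk_re) <- kin_params
  plot_idx <- match(plot_key, plot_levels)
  base <- unlist(design$baseline[kin_params])
  truth <- matrix(rep(base, each = nrow(grid)), nrow(grid), 5,
                  dimnames = list(NULL, kin_params))
  for (g in names(design$genotype_effects)) {
    eff <- design$genotype_effects[[g]]
    rows <- grid$genotype == g
    for (p in names(eff)) truth[rows, p] <- truth[rows, p] + eff[[p]]
  }
  for (p in names(design$env_effects)) {
    coefs <- design$env_effects[[p]]
    bad <- setdiff(names(coefs), feat_cols)
    if (length(bad)) stop("env_effects name(s) not a daily feature: ",
                          paste(bad, collapse = ", "))
    shift <- as.matrix(zfeats[, names(coefs), drop = FALSE]) %*% coefs
    truth[, p] <- truth[, p] + shift[grid$day]
  }
  truth <- truth + plot_re[plot_idx, , drop = FALSE] + disk_re
  truth[, c("a_qe", "a_qm", "a_qi")] <- pmax(truth[, c("a_qe", "a_qm", "a_qi")], 0)
  truth[, "tau_qe"] <- pmax(truth[, "tau_qe"], 0.05)
  truth[, "tau_qm"] <- pmax(truth[, "tau_qm"], truth[, "tau_qe"] + 0.5)

  out <- data.frame(disk_id = paste(plot_key, grid$disk, format(need[grid$day]), sep = "_"),
                    plot_id = plot_key,
                    genotype = grid$genotype,
                    group = unname(design$groups[grid$genotype]),
                    date = need[grid$day],
                    as.data.frame(truth),
                    stringsAsFactors = FALSE)
  out <- cbind(out, feats[grid$day, feat_cols, drop = FALSE])
  rownames(out) <- NULL
  res <- list(truth = out, features = feats, weather = weather)

  if (traces) {
    tr <- vector("list", nrow(out))
    for (i in seq_len(nrow(out))) {
      ktr <- kinetics_truth(a_qe = truth[i, "a_qe"], a_qm = truth[i, "a_qm"],
                            a_qi = truth[i, "a_qi"], tau_qe = truth[i, "tau_qe"],
                            tau_qm = truth[i, "tau_qm"],
                            induction_tau = design$baseline$induction_tau)
      tr[[i]] <- simulate_trace(ktr, noise_cv = design$noise_cv,
                                seed = trace_seeds[i],
                                disk_id = out$disk_id[i], plot_id = out$plot_id[i],
                                genotype = out$genotype[i], date = out$date[i])
    }
    res$trace_objects <- tr
    res$traces <- traces_to_table(tr)
  }
  res
}

#' @rdname generate_experiment
#' @param trace_objects list of `fluorescence_trace` objects.
#' @export
traces_to_table <- function(trace_objects) {
  do.call(rbind, lapply(trace_objects, function(x) {
    data.frame(disk_id = x$disk_id, plot_id = x$plot_id, genotype = x$genotype,
               date = format(x$date), fm_dark = x$fm_dark, f0_dark = x$f0_dark,
               phase = x$pulses$phase, t_min = x$pulses$t_min,
               fm_prime = x$pulses$fm_prime, stringsAsFactors = FALSE)
  }))
}
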