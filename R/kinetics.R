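#' Ground-truth NPQ kinetic parameter set
#'
#' Bundles the amplitudes and time constants of the three relaxation
#' components of NPQ -- energy-dependent quenching qE (fast, < 2 min),
#' the intermediate component qM (2-30 min) and slowly reversible
#' photoinhibitory quenching qI (> 30 min) -- together with the
#' mono-exponential induction time constant used when synthesising the
#' high-light phase. Defaults are the population medians observed across the
#' SoyNAM founder panel.
#'
#' @param a_qe,a_qm,a_qi component amplitudes (NPQ units, >= 0).
#' @param tau_qe,tau_qm relaxation time constants (minutes); must satisfy
#'   `0 < tau_qe < tau_qm`.
#' @param induction_tau time constant of NPQ induction under high light
#'   (minutes).
#' @return an object of class `kinetics_truth`.
#' @export
kinetics_truth <- function(a_qe = 1.96, a_qm = 1.58, a_qi = 0.47,
                           tau_qe = 1.05, tau_qm = 23.51,
                           induction_tau = 1.5) {
  if (any(c(a_qe, a_qm, a_qi) < 0)) stop("amplitudes must be >= 0")
  if (!(tau_qe > 0 && tau_qm > tau_qe)) stop("need 0 < tau_qe < tau_qm")
  if (induction_tau <= 0) stop("induction_tau must be > 0")
  structure(list(a_qe = a_qe, a_qm = a_qm, a_qi = a_qi,
                 tau_qe = tau_qe, tau_qm = tau_qm,
                 induction_tau = induction_tau),
            class = "kinetics_truth")
}

#' Double-exponential NPQ relaxation curve
#'
#' NPQ(t) = A_qI + A_qE exp(-t/tau_qE) + A_qM exp(-t/tau_qM), the standard
#' decomposition of NPQ decay after the actinic light is switched from high
#' to low, with t in minutes from the transition.
#'
#' @param t time since the high-to-low light transition (minutes).
#' @param a_qe,a_qm,a_qi amplitudes (NPQ units).
#' @param tau_qe,tau_qm time constants (minutes).
#' @return NPQ value(s), dimensionless.
#' @export
npq_relaxation <- function(t, a_qe, a_qm, a_qi, tau_qe, tau_qm) {
  a_qi + a_qe * exp(-t / tau_qe) + a_qm * exp(-t / tau_qm)
}

# NPQ during the high-light phase: mono-exponential rise toward the
# amplitude sum (induction is not decomposed; only relaxation is fit).
npq_induction <- function(t, truth) {
  total <- truth$a_qe + truth$a_qm + truth$a_qi
  total * (1 - exp(-t / truth$induction_tau))
}

# true NPQ at a (phase, t_min-within-phase) pulse position
npq_true_at <- function(phase, t_min, truth) {
  out <- numeric(length(phase))
  out[phase == "lowlight1"] <- 0
  hi <- phase == "highlight"
  out[hi] <- npq_induction(t_min[hi], truth)
  lo2 <- phase == "lowlight2"
  out[lo2] <- npq_relaxation(t_min[lo2], truth$a_qe, truth$a_qm, truth$a_qi,
                             truth$tau_qe, truth$tau_qm)
  out
}
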