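#' Saturating-pulse measurement protocol
#'
#' Describes the low-high-low actinic light sequence applied to dark-adapted
#' leaf disks and the saturating-pulse schedule used to measure Fm' in each
#' phase. The default is the standard leaf-disk assay: 10 min at 50, 15 min at
#' 2000 and 50 min at 50 umol m-2 s-1 actinic light, with 4000 umol m-2 s-1
#' saturating pulses at 2.5, 5, 7.5 and 10 min (first low-light phase), every
#' 2.5 min during high light, and at 2.5, 5 and then every 5 min up to 50 min
#' of the relaxation phase.
#'
#' @param durations numeric length 3, phase durations in minutes
#'   (lowlight1, highlight, lowlight2).
#' @param actinic numeric length 3, actinic irradiance per phase
#'   (umol m-2 s-1).
#' @param pulse_intensity saturating pulse irradiance (umol m-2 s-1).
#' @param pulses named list of pulse time offsets (minutes from the start of
#'   each phase) for phases `lowlight1`, `highlight`, `lowlight2`. Offsets
#'   must be strictly increasing and no later than the phase duration.
#' @return an object of class `npq_protocol`.
#' @export
npq_protocol <- function(durations = c(lowlight1 = 10, highlight = 15, lowlight2 = 50),
                         actinic = c(lowlight1 = 50, highlight = 2000, lowlight2 = 50),
                         pulse_intensity = 4000,
                         pulses = list(
                           lowlight1 = c(2.5, 5, 7.5, 10),
                           highlight = c(2.5, 5, 7.5, 10, 12.5, 15),
                           lowlight2 = c(2.5, 5, 10, 15, 20, 25, 30, 35, 40, 45, 50)
                         )) {
  stopifnot(length(durations) == 3, length(actinic) == 3,
            is.list(pulses), length(pulses) == 3)
  phases <- c("lowlight1", "highlight", "lowlight2")
  names(durations) <- names(actinic) <- names(pulses) <- phases
  for (ph in phases) {
    off <- pulses[[ph]]
    if (length(off) == 0) next
    if (any(diff(off) <= 0)) {
      stop("pulse offsets in phase '", ph, "' must be strictly increasing")
    }
    if (any(off <= 0) || any(off > durations[[ph]])) {
      stop("pulse offsets in phase '", ph, "' must lie in (0, duration]")
    }
  }
  structure(list(durations = durations, actinic = actinic,
                 pulse_intensity = pulse_intensity, pulses = pulses),
            class = "npq_protocol")
}

#' @export
print.npq_protocol <- function(x, ...) {
  cat("<npq_protocol>\n")
  for (ph in names(x$durations)) {
    cat(sprintf("  %-9s %4.0f min @ %4.0f umol m-2 s-1, pulses at %s\n",
                ph, x$durations[[ph]], x$actinic[[ph]],
                paste(x$pulses[[ph]], collapse = ", ")))
  }
  cat(sprintf("  saturating pulses: %.0f umol m-2 s-1\n", x$pulse_intensity))
  invisible(x)
}

# long-format pulse table (phase, t_min within phase) for a protocol
protocol_pulse_table <- function(protocol) {
  do.call(rbind, lapply(names(protocol$pulses), function(ph) {
    off <- protocol$pulses[[ph]]
    if (length(off) == 0) return(NULL)
    data.frame(phase = ph, t_min = off, stringsAsFactors = FALSE)
  }))
}
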