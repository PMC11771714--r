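#' NPQ and Fv/Fm from a fluorescence pulse trace
#'
#' Applies the Stern-Volmer definition at every saturating pulse,
#' `NPQ(t) = Fm/Fm'(t) - 1`, with Fm the dark-adapted maximal fluorescence
#' measured before the actinic sequence, and computes the maximum potential
#' PSII quantum efficiency `Fv/Fm = (Fm - F0)/Fm` from the dark-adapted pair.
#' Both quantities are ratios, so they are invariant to any common rescaling
#' of the fluorescence signal.
#'
#' @param trace a `fluorescence_trace` (see [simulate_trace()] /
#'   [read_traces()]).
#' @return an `npq_series`: identifiers, `fv_fm`, and a `pulses` data frame
#'   with `phase`, `t_min`, `npq`.
#' @export
compute_npq <- function(trace) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  if (is.null(trace$fm_dark) || is.null(trace$f0_dark) ||
      is.na(trace$fm_dark) || is.na(trace$f0_dark)) {
    stop("dark-adapted Fm/F0 missing for disk ", trace$disk_id)
  }
  if (!(trace$fm_dark > trace$f0_dark && trace$f0_dark > 0)) {
    stop("need fm_dark > f0_dark > 0 for disk ", trace$disk_id)
  }
  if (any(trace$pulses$fm_prime <= 0)) {
    stop("non-positive Fm' in disk ", trace$disk_id)
  }
  pulses <- trace$pulses[c("phase", "t_min")]
  pulses$npq <- trace$fm_dark / trace$pulses$fm_prime - 1
  structure(list(disk_id = trace$disk_id, plot_id = trace$plot_id,
                 genotype = trace$genotype, date = trace$date,
                 fv_fm = (trace$fm_dark - trace$f0_dark) / trace$fm_dark,
                 pulses = pulses),
            class = "npq_series")
}

#' Read / write fluorescence trace tables
#'
#' The long CSV dialect has one row per saturating pulse: `disk_id`,
#' `plot_id`, `genotype`, `date`, `fm_dark`, `f0_dark`, `phase` (one of
#' `lowlight1`, `highlight`, `lowlight2`), `t_min` (minutes from phase
#' start) and `fm_prime`. A wide dialect (one row per disk, pulse columns
#' named `<phase>_<t_min>`, e.g. `lowlight2_2.5`) is also accepted.
#'
#' @param path CSV path, or a data frame already in either dialect.
#' @return [read_traces()] returns a list of `fluorescence_trace` objects.
#' @export
read_traces <- function(path) {
  tab <- if (is.data.frame(path)) path else utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"fm_prime" %in% names(tab)) tab <- wide_to_long_traces(tab)
  split_rows <- split(seq_len(nrow(tab)), tab$disk_id)
  out <- lapply(split_rows, function(i) {
    d <- tab[i, ]
    structure(list(disk_id = d$disk_id[1], plot_id = d$plot_id[1],
                   genotype = d$genotype[1], date = as.Date(d$date[1]),
                   fm_dark = d$fm_dark[1], f0_dark = d$f0_dark[1],
                   pulses = data.frame(phase = d$phase, t_min = d$t_min,
                                       fm_prime = d$fm_prime)),
              class = "fluorescence_trace")
  })
  out[order(vapply(out, function(x) x$disk_id, character(1)))]
}

wide_to_long_traces <- function(tab) {
  pulse_cols <- grep("^(lowlight1|highlight|lowlight2)_[0-9.]+$", names(tab), value = TRUE)
  if (!length(pulse_cols)) stop("unrecognised trace table layout")
  id_cols <- intersect(c("disk_id", "plot_id", "genotype", "date", "fm_dark", "f0_dark"),
                       names(tab))
  long <- do.call(rbind, lapply(pulse_cols, function(cn) {
    parts <- regmatches(cn, regexec("^(lowlight1|highlight|lowlight2)_([0-9.]+)$", cn))[[1]]
    cbind(tab[id_cols],
          data.frame(phase = parts[2], t_min = as.numeric(parts[3]),
                     fm_prime = tab[[cn]]))
  }))
  long[order(long$disk_id), ]
}

#' @rdname read_traces
#' @param trace_objects list of `fluorescence_trace` objects.
#' @export
write_traces <- function(trace_objects, path) {
  utils::write.csv(traces_to_table(trace_objects), path, row.names = FALSE)
  invisible(path)
}

#' Quality filtering of fitted leaf disks
#'
#' Applies the two exclusion rules used before any statistics: leaf disks
#' with `Fv/Fm < 0.75` are removed (unhealthy tissue), and disks whose
#' fitted parameter set contains any negative value are removed as fit
#' outliers. The filter is idempotent and every exclusion is logged with its
#' reason.
#'
#' @param fits data frame with one row per disk holding `disk_id`, `fv_fm`
#'   and the fitted parameters (`a_qe`, `a_qm`, `a_qi`, `tau_qe`, `tau_qm`,
#'   `max_npq`; missing columns are skipped). Rows with `converged = FALSE`
#'   (if present) are also excluded.
#' @param fv_fm_min exclusion threshold on Fv/Fm (default 0.75).
#' @return list with `kept` (surviving rows) and `log` (data frame
#'   `disk_id`, `reason`). `nrow(kept) + nrow(log) == nrow(fits)`.
#' @export
qc_filter <- function(fits, fv_fm_min = 0.75) {
  param_cols <- intersect(c("a_qe", "a_qm", "a_qi", "tau_qe", "tau_qm", "max_npq"),
                          names(fits))
  reason <- rep(NA_character_, nrow(fits))
  if ("converged" %in% names(fits)) {
    reason[is.na(reason) & !fits$converged] <- "non-converged fit"
  }
  reason[is.na(reason) & fits$fv_fm < fv_fm_min] <-
    sprintf("fv_fm<%.2f", fv_fm_min)
  neg <- rowSums(sapply(param_cols, function(p) fits[[p]] < 0)) > 0
  reason[is.na(reason) & neg] <- "negative parameter"
  keep <- is.na(reason)
  if (!any(keep)) warning("qc_filter removed every disk")
  list(kept = fits[keep, , drop = FALSE],
       log = data.frame(disk_id = fits$disk_id[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE))
}

#' Average technical replicates to plot level
#'
#' Arithmetic mean of each fitted parameter over the surviving disks within
#' a plot on a sampling day. Plots with zero surviving disks are dropped
#' with a warning rather than imputed.
#'
#' @param kept surviving disk-level fits (the `kept` element of
#'   [qc_filter()]); must carry `plot_id`, `genotype`, `date`.
#' @return plot-level data frame with the averaged parameters and `n_disks`.
#' @export
average_replicates <- function(kept) {
  if (nrow(kept) == 0) {
    warning("no surviving disks to average")
    return(kept)
  }
  param_cols <- intersect(c("a_qe", "a_qm", "a_qi", "tau_qe", "tau_qm",
                            "max_npq", "fv_fm"), names(kept))
  key <- interaction(kept$plot_id, format(kept$date), drop = TRUE)
  rows <- lapply(split(seq_len(nrow(kept)), key), function(i) {
    d <- kept[i, ]
    out <- d[1, c("plot_id", "genotype", "date"), drop = FALSE]
    if ("group" %in% names(d)) out$group <- d$group[1]
    for (p in param_cols) out[[p]] <- mean(d[[p]])
    out$n_disks <- length(i)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
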