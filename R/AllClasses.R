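#' @import methods
#' @importFrom stats rexp rgamma optim optimize uniroot runif rnorm rlnorm
#'   convolve setNames approx ks.test chisq.test var sd
#' @importFrom utils write.table read.table modifyList
#' @importFrom Rcpp evalCpp
#' @useDynLib eventburst, .registration = TRUE
NULL

DUR_FAMILIES <- c("exponential", "gamma", "delayed-exponential", "point")

#' Duration distribution of a single transcriptional event
#'
#' Describes the dwell-time distribution of one promoter event. The
#' exponential family is the default throughout (a single rate-limiting
#' step); the gamma family represents multistep events with coefficient of
#' variation below one, and the delayed-exponential family adds a hard
#' refractory offset before an exponential tail. The point family is a
#' degenerate fixed duration used for initial-condition distributions.
#'
#' @slot family one of \code{"exponential"}, \code{"gamma"},
#'   \code{"delayed-exponential"}, \code{"point"}.
#' @slot mean mean duration in minutes.
#' @slot cv coefficient of variation (dimensionless); 1 for exponential,
#'   0 for point.
#' @slot delay refractory offset in minutes (delayed-exponential only).
#' @export
setClass("EventDurationModel",
  representation(family = "character", mean = "numeric", cv = "numeric",
                 delay = "numeric"),
  prototype(family = "exponential", mean = 1, cv = 1, delay = 0))

setValidity("EventDurationModel", function(object) {
  msg <- character()
  if (!object@family %in% DUR_FAMILIES)
    msg <- c(msg, sprintf("unknown duration family '%s'", object@family))
  if (!is.finite(object@mean) || object@mean < 0 ||
      (object@mean == 0 && object@family != "point"))
    msg <- c(msg, "mean must be a positive finite number")
  if (object@family == "exponential" && abs(object@cv - 1) > 1e-12)
    msg <- c(msg, "exponential family forces cv = 1")
  if (object@family == "point") {
    if (object@cv != 0) msg <- c(msg, "point family forces cv = 0")
  } else if (!is.finite(object@cv) || object@cv <= 0) {
    msg <- c(msg, "cv must be positive")
  }
  if (object@family == "delayed-exponential") {
    if (object@delay < 0 || object@delay >= object@mean)
      msg <- c(msg, "delayed-exponential requires 0 <= delay < mean")
  } else if (object@delay != 0) {
    msg <- c(msg, "delay is only meaningful for delayed-exponential")
  }
  if (length(msg)) msg else TRUE
})

#' Kinetic parameters of a bursting gene
#'
#' The single source of truth for a gene's bursting kinetics: mean durations
#' (minutes) of the productive event and the three silent events, the two
#' checkpoint repetition probabilities, and the mRNA lifetime. The silent
#' (inactive) cycle can alternatively be specified directly through a single
#' composite mean \code{tau_S}, in which case each inactive cycle is one
#' exponential draw (the convention used for the reference mean-Fano curve
#' families).
#'
#' @slot tau_P mean duration of the productive event (min).
#' @slot tau_S1,tau_S2,tau_S3 mean durations of the silent events (min);
#'   \code{NA} in direct-\code{tau_S} mode.
#' @slot p1 probability of repeating the productive event (and of entering a
#'   burst after a completed inactive cycle).
#' @slot p2 probability of repeating the third silent event; \code{NA} in
#'   direct mode.
#' @slot tau_m mean mRNA lifetime (min).
#' @slot tau_S composite mean inactive-cycle duration (min) in direct mode,
#'   otherwise \code{NA}.
#' @slot durationModels named list of \linkS4class{EventDurationModel}
#'   overrides (names among \code{P}, \code{S1}, \code{S2}, \code{S3},
#'   \code{S}); means must equal the corresponding tau slots.
#' @export
setClass("BurstParams",
  representation(tau_P = "numeric", tau_S1 = "numeric", tau_S2 = "numeric",
                 tau_S3 = "numeric", p1 = "numeric", p2 = "numeric",
                 tau_m = "numeric", tau_S = "numeric",
                 durationModels = "list"))

setValidity("BurstParams", function(object) {
  msg <- character()
  chk_pos <- function(x, nm) {
    if (!is.na(x) && (!is.finite(x) || x <= 0))
      sprintf("%s must be positive and finite", nm)
  }
  msg <- c(msg, chk_pos(object@tau_P, "tau_P"), chk_pos(object@tau_m, "tau_m"))
  if (!is.na(object@p1) && (object@p1 < 0 || object@p1 >= 1))
    msg <- c(msg, "p1 must lie in [0, 1)")
  direct <- !is.na(object@tau_S)
  if (direct) {
    msg <- c(msg, chk_pos(object@tau_S, "tau_S"))
    if (!all(is.na(c(object@tau_S1, object@tau_S2, object@tau_S3, object@p2))))
      msg <- c(msg, "direct tau_S mode excludes component fields")
  } else {
    msg <- c(msg, chk_pos(object@tau_S1, "tau_S1"),
             chk_pos(object@tau_S2, "tau_S2"),
             chk_pos(object@tau_S3, "tau_S3"))
    if (is.na(object@p2) || object@p2 < 0 || object@p2 >= 1)
      msg <- c(msg, "p2 must lie in [0, 1)")
  }
  dm <- object@durationModels
  if (length(dm)) {
    if (is.null(names(dm)) || !all(names(dm) %in% c("P", "S1", "S2", "S3", "S")))
      msg <- c(msg, "durationModels names must be among P, S1, S2, S3, S")
    tau_of <- c(P = object@tau_P, S1 = object@tau_S1, S2 = object@tau_S2,
                S3 = object@tau_S3, S = object@tau_S)
    for (nm in names(dm)) {
      m <- dm[[nm]]
      if (!is(m, "EventDurationModel")) {
        msg <- c(msg, "durationModels entries must be EventDurationModel")
      } else if (!isTRUE(all.equal(m@mean, unname(tau_of[nm]), tolerance = 1e-8))) {
        msg <- c(msg, sprintf("duration model '%s' mean differs from tau field", nm))
      }
    }
  }
  msg <- msg[!vapply(msg, is.null, logical(1))]
  if (length(msg)) unlist(msg) else TRUE
})

#' Derived steady-state burst quantities
#'
#' @slot tau_S composite mean inactive-cycle duration (min).
#' @slot tau_A mean active-phase duration (min).
#' @slot tau_I mean inactive-phase duration (min).
#' @slot period mean burst period T = tau_A + tau_I (min).
#' @slot b mean burst size (mRNAs per burst).
#' @slot f burst frequency (1/min).
#' @slot m_mean steady-state mean mRNA copy number.
#' @slot c,d dimensionless ratios tau_A/tau_m and tau_I/tau_m.
#' @export
setClass("DerivedQuantities",
  representation(tau_S = "numeric", tau_A = "numeric", tau_I = "numeric",
                 period = "numeric", b = "numeric", f = "numeric",
                 m_mean = "numeric", c = "numeric", d = "numeric"))

#' A simulated single-gene trajectory
#'
#' @slot events data.frame with columns \code{event_kind}, \code{start},
#'   \code{duration}, \code{produced_mrna}.
#' @slot synthesis_times,degradation_times times (min) of transcript
#'   appearance and decay.
#' @slot seed integer seed used for the run.
#' @slot params the \linkS4class{BurstParams} snapshot.
#' @slot t_end simulated horizon (min).
#' @export
setClass("Trajectory",
  representation(events = "data.frame", synthesis_times = "numeric",
                 degradation_times = "numeric", seed = "integer",
                 params = "BurstParams", t_end = "numeric"))

setValidity("Trajectory", function(object) {
  ev <- object@events
  msg <- character()
  need <- c("event_kind", "start", "duration", "produced_mrna")
  if (!all(need %in% names(ev))) {
    msg <- c(msg, "events must have event_kind/start/duration/produced_mrna")
  } else if (nrow(ev)) {
    if (any(ev$duration <= 0)) msg <- c(msg, "durations must be positive")
    if (any((ev$produced_mrna == 1) != (ev$event_kind == "E_P")))
      msg <- c(msg, "produced_mrna must be 1 exactly for E_P events")
    gaps <- abs(ev$start[-1] - (ev$start[-nrow(ev)] + ev$duration[-nrow(ev)]))
    if (length(gaps) && max(gaps) > 1e-8)
      msg <- c(msg, "events must be contiguous and non-overlapping")
  }
  if (length(msg)) msg else TRUE
})

#' Per-burst summary statistics of a trajectory
#'
#' @slot burst_sizes transcripts per burst (complete bursts only).
#' @slot active_durations,inactive_durations phase durations (min).
#' @slot mean_burst_size,mean_active,mean_inactive summary means.
#' @slot n_bursts number of complete bursts.
#' @export
setClass("BurstSummary",
  representation(burst_sizes = "numeric", active_durations = "numeric",
                 inactive_durations = "numeric", mean_burst_size = "numeric",
                 mean_active = "numeric", mean_inactive = "numeric",
                 n_bursts = "integer"))

#' A regulatory mode: how regulator occupancy remaps bursting parameters
#'
#' A non-empty combination of basic modes, each scaling one bursting
#' parameter between its regulator-unbound value and its regulator-bound
#' endpoint. Duration-targeting modes scale an event's mean duration by an
#' efficacy below one (binding accelerates the event); checkpoint modes
#' rescale one of the probability flows so that the bound-state probability
#' is efficacy times the unbound one.
#'
#' @slot basic_modes character vector among MEE, MEA, MFI, MCC, MIE, MIA,
#'   MFC, MFA, and MTS (direct composite tau_S regulation).
#' @slot efficacies named numeric vector, one per basic mode.
#' @slot K_d dissociation constant of cognate regulator binding
#'   (concentration, arbitrary units).
#' @slot n_H Hill coefficient of the occupancy function.
#' @export
setClass("RegulatoryMode",
  representation(basic_modes = "character", efficacies = "numeric",
                 K_d = "numeric", n_H = "numeric"))

MODE_NAMES <- c("MEE", "MEA", "MFI", "MCC", "MIE", "MIA", "MFC", "MFA", "MTS")
MODE_PARAM <- c(MEE = "tau_P", MEA = "tau_S1", MFI = "tau_S2", MCC = "tau_S3",
                MIE = "p1", MIA = "p1", MFC = "p2", MFA = "p2", MTS = "tau_S")

setValidity("RegulatoryMode", function(object) {
  msg <- character()
  bm <- object@basic_modes
  if (!length(bm)) msg <- c(msg, "at least one basic mode is required")
  if (!all(bm %in% MODE_NAMES))
    msg <- c(msg, "unknown basic mode name")
  if (anyDuplicated(bm)) msg <- c(msg, "duplicated basic mode")
  if (anyDuplicated(MODE_PARAM[bm]))
    msg <- c(msg, "combined modes must touch disjoint parameters")
  eff <- object@efficacies
  if (length(eff) != length(bm) || !setequal(names(eff), bm))
    msg <- c(msg, "efficacies must be named after the basic modes")
  for (nm in bm) {
    e <- eff[[nm]]
    if (!is.finite(e) || e <= 0) {
      msg <- c(msg, sprintf("efficacy for %s must be positive", nm))
    } else if (nm %in% c("MIE", "MIA")) {
      if (e < 1) msg <- c(msg, sprintf("%s requires efficacy >= 1", nm))
    } else if (e > 1) {
      msg <- c(msg, sprintf("%s requires efficacy <= 1", nm))
    }
  }
  if (length(object@K_d) != 1 || !is.finite(object@K_d) || object@K_d <= 0)
    msg <- c(msg, "K_d must be a positive number")
  if (length(object@n_H) != 1 || !is.finite(object@n_H) || object@n_H <= 0)
    msg <- c(msg, "n_H must be a positive number")
  if (length(msg)) msg else TRUE
})

#' Analytic transient-response curves
#'
#' Time courses of the activation probability P_A(t) and the mean mRNA
#' number after a step stimulus, with overshoot metrics and response times.
#'
#' @slot t time grid (min).
#' @slot P_A activation probability per grid time.
#' @slot m_mean mean mRNA count per grid time.
#' @slot P_AP,P_Ass peak and steady-state activation probability.
#' @slot m_peak,m_ss peak and steady-state mean count.
#' @slot H_P,H_m relative overshoots.
#' @slot t_GA,t_re half-response times of P_A and of the mean count (min).
#' @slot overshoot_P,overshoot_m logical overshoot flags.
#' @slot tau_A,tau_P,tau_m the kinetic constants used (min).
#' @export
setClass("TransientCurves",
  representation(t = "numeric", P_A = "numeric", m_mean = "numeric",
                 P_AP = "numeric", P_Ass = "numeric", m_peak = "numeric",
                 m_ss = "numeric", H_P = "numeric", H_m = "numeric",
                 t_GA = "numeric", t_re = "numeric", overshoot_P = "logical",
                 overshoot_m = "logical", tau_A = "numeric",
                 tau_P = "numeric", tau_m = "numeric"))

setMethod("show", "EventDurationModel", function(object) {
  cat(sprintf("EventDurationModel: %s(mean = %g min, cv = %g%s)\n",
              object@family, object@mean, object@cv,
              if (object@family == "delayed-exponential")
                sprintf(", delay = %g", object@delay) else ""))
})

setMethod("show", "BurstParams", function(object) {
  cat("BurstParams (times in minutes)\n")
  cat(sprintf("  tau_P = %g, p1 = %g, tau_m = %g\n",
              object@tau_P, object@p1, object@tau_m))
  if (isDirectTauS(object)) {
    cat(sprintf("  inactive cycle: direct tau_S = %g\n", object@tau_S))
  } else {
    cat(sprintf("  tau_S1 = %g, tau_S2 = %g, tau_S3 = %g, p2 = %g (tau_S = %g)\n",
                object@tau_S1, object@tau_S2, object@tau_S3, object@p2,
                tauS(object)))
  }
  if (length(object@durationModels))
    cat("  non-default duration families:",
        paste(names(object@durationModels), collapse = ", "), "\n")
})

setMethod("show", "DerivedQuantities", function(object) {
  cat(sprintf(paste0("DerivedQuantities: tau_S = %g, tau_A = %g, tau_I = %g, ",
                     "T = %g, b = %g, f = %g, <m> = %g\n"),
              object@tau_S, object@tau_A, object@tau_I, object@period,
              object@b, object@f, object@m_mean))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d events, %d transcripts, horizon %g min (seed %d)\n",
              nrow(object@events), length(object@synthesis_times),
              object@t_end, object@seed))
})

setMethod("show", "BurstSummary", function(object) {
  if (object@n_bursts == 0L) {
    cat("BurstSummary: no complete bursts\n")
  } else {
    cat(sprintf(paste0("BurstSummary: %d bursts, mean size %.3g, ",
                       "mean active %.3g min, mean inactive %.3g min\n"),
                object@n_bursts, object@mean_burst_size, object@mean_active,
                object@mean_inactive))
  }
})

setMethod("show", "RegulatoryMode", function(object) {
  cat(sprintf("RegulatoryMode: %s (K_d = %g, n_H = %g)\n",
              paste(sprintf("%s[%g]", object@basic_modes,
                            object@efficacies[object@basic_modes]),
                    collapse = " + "),
              object@K_d, object@n_H))
})

setMethod("show", "TransientCurves", function(object) {
  cat(sprintf(paste0("TransientCurves: %d grid points to %g min; P_Ass = %.4g, ",
                     "m_ss = %.4g\n  H_P = %.3g (overshoot %s), H_m = %.3g ",
                     "(overshoot %s), t_GA = %.4g, t_re = %.4g\n"),
              length(object@t), max(object@t), object@P_Ass, object@m_ss,
              object@H_P, object@overshoot_P, object@H_m, object@overshoot_m,
              object@t_GA, object@t_re))
})
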