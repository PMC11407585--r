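KIND_LABELS <- c("E_P", "E_S1", "E_S2", "E_S3")

init_code <- function(init) {
  if (is.character(init))
    return(switch(match.arg(init, c("inactive-cycle", "burst", "silent")),
                  "inactive-cycle" = list(code = 0L, spec = dur_row(eventDuration(mean = 1))),
                  "burst" = list(code = 1L, spec = dur_row(eventDuration(mean = 1))),
                  "silent" = stop("init = \"silent\" requires an ",
                                  "EventDurationModel for the first inactive ",
                                  "interval")))
  if (is(init, "EventDurationModel"))
    return(list(code = 2L, spec = dur_row(init)))
  stop("invalid initial-condition spec")
}

#' Simulate a single bursting trajectory
#'
#' Event-driven stochastic simulation of the burst cycle: silent cycles
#' (first silent event, a geometric number of repeats of the third, the
#' second) alternate with bursts (a geometric number of productive events);
#' one transcript appears at the completion of each productive event and
#' decays after an independent exponential lifetime.
#'
#' @param params a \linkS4class{BurstParams}.
#' @param t_end simulation horizon (min, > 0).
#' @param seed integer seed (recorded in the result).
#' @param init initial condition: \code{"inactive-cycle"} (default, start of
#'   a silent cycle), \code{"burst"} (start of a burst), or an
#'   \linkS4class{EventDurationModel} giving the distribution of a first
#'   silent interval after which a burst begins.
#' @return a \linkS4class{Trajectory}.
#' @examples
#' p <- burstParams(tau_P = 0.165, p1 = 0.95, tau_S = 100)
#' tr <- simulateTrajectory(p, t_end = 2000, seed = 1)
#' tr
#' @export
simulateTrajectory <- function(params, t_end, seed,
                               init = "inactive-cycle") {
  stopifnot(t_end > 0)
  validObject(params)
  ic <- init_code(init)
  set.seed(seed)
  raw <- cpp_simulate_trajectory(dur_matrix(params), params@p1,
                                 if (isDirectTauS(params)) 0 else params@p2,
                                 isDirectTauS(params), params@tau_m, t_end,
                                 ic$code, ic$spec)
  events <- data.frame(event_kind = KIND_LABELS[raw$kind + 1L],
                       start = raw$start, duration = raw$duration,
                       produced_mrna = raw$produced)
  new("Trajectory", events = events, synthesis_times = raw$synthesis,
      degradation_times = raw$degradation, seed = as.integer(seed),
      params = params, t_end = t_end)
}

#' mRNA copy number of a trajectory at given times
#' @param traj a \linkS4class{Trajectory}.
#' @param times numeric vector of times (min).
#' @return integer copy numbers.
#' @export
mrnaCount <- function(traj, times) {
  vapply(times, function(t)
    sum(traj@synthesis_times <= t) - sum(traj@degradation_times <= t),
    numeric(1))
}

#' Per-burst statistics of a trajectory
#'
#' A burst is a maximal run of consecutive productive events; the inactive
#' phase between bursts is the span of the intervening silent events.
#' Incomplete first and last phases are discarded.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @return a \linkS4class{BurstSummary}; with no complete burst an empty
#'   summary (\code{n_bursts = 0}) is returned.
#' @export
burstStatistics <- function(traj) {
  ev <- traj@events
  if (!nrow(ev))
    return(new("BurstSummary", burst_sizes = numeric(), n_bursts = 0L,
               active_durations = numeric(), inactive_durations = numeric(),
               mean_burst_size = NA_real_, mean_active = NA_real_,
               mean_inactive = NA_real_))
  active <- ev$event_kind == "E_P"
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n_runs <- length(r$lengths)
  ## a run is complete when it neither starts the record nor is cut by t_end
  run_end_time <- ev$start[ends] + ev$duration[ends]
  complete <- starts > 1L & run_end_time <= traj@t_end & ends < nrow(ev)
  keep_a <- which(r$values & complete)
  keep_i <- which(!r$values & complete)
  burst_sizes <- r$lengths[keep_a]
  active_dur <- run_end_time[keep_a] - ev$start[starts[keep_a]]
  inactive_dur <- run_end_time[keep_i] - ev$start[starts[keep_i]]
  if (!length(burst_sizes))
    return(new("BurstSummary", burst_sizes = numeric(), n_bursts = 0L,
               active_durations = numeric(), inactive_durations = numeric(),
               mean_burst_size = NA_real_, mean_active = NA_real_,
               mean_inactive = NA_real_))
  new("BurstSummary", burst_sizes = as.numeric(burst_sizes),
      active_durations = active_dur, inactive_durations = inactive_dur,
      mean_burst_size = mean(burst_sizes), mean_active = mean(active_dur),
      mean_inactive = if (length(inactive_dur)) mean(inactive_dur) else NA_real_,
      n_bursts = length(burst_sizes))
}

#' Ensemble moments of the mRNA copy number
#'
#' Simulates \code{n_traj} independent trajectories (all started at the
#' beginning of an inactive cycle with zero transcripts unless \code{init}
#' says otherwise) and returns per-time mean, variance and Fano factor with
#' Monte Carlo standard errors.
#'
#' @inheritParams simulateTrajectory
#' @param n_traj number of trajectories (>= 2).
#' @param t_grid increasing vector of times (min).
#' @return data.frame with columns \code{time}, \code{mean}, \code{var},
#'   \code{fano}, \code{se_mean}, \code{se_var}, \code{se_fano}.
#' @export
ensembleMoments <- function(params, n_traj, t_grid, seed,
                            init = "inactive-cycle") {
  stopifnot(n_traj >= 2, all(diff(t_grid) > 0))
  validObject(params)
  ic <- init_code(init)
  if (ic$code == 2L) stop("silent init is handled by simulatePhaseRenewal")
  set.seed(seed)
  raw <- cpp_ensemble_moments(dur_matrix(params), params@p1,
                              if (isDirectTauS(params)) 0 else params@p2,
                              isDirectTauS(params), params@tau_m, t_grid,
                              as.integer(n_traj), ic$code)
  moments_frame(t_grid, raw)
}

## turn raw moment sums into a tidy frame with delta-method errors
moments_frame <- function(t_grid, raw) {
  n <- raw$n
  m1 <- raw$s1 / n
  m2 <- raw$s2 / n
  m3 <- raw$s3 / n
  m4 <- raw$s4 / n
  mu2 <- pmax(m2 - m1^2, 0)
  mu4 <- m4 - 4 * m1 * m3 + 6 * m1^2 * m2 - 3 * m1^4
  v <- mu2 * n / (n - 1)
  se_mean <- sqrt(mu2 / n)
  se_var <- sqrt(pmax(mu4 - mu2^2, 0) / n)
  fano <- ifelse(m1 > 0, v / m1, NA_real_)
  se_fano <- ifelse(m1 > 0,
                    sqrt((se_var / m1)^2 + (fano * se_mean / m1)^2), NA_real_)
  data.frame(time = t_grid, mean = m1, var = v, fano = fano,
             se_mean = se_mean, se_var = se_var, se_fano = se_fano)
}

#' Time-averaged copy number of one long trajectory
#'
#' @inheritParams simulateTrajectory
#' @param burnin portion of the trajectory discarded before averaging (min).
#' @return the time-averaged mRNA count over \code{[burnin, t_end]}.
#' @export
timeAverageMrna <- function(params, t_end, seed, burnin = 0.05 * t_end) {
  validObject(params)
  set.seed(seed)
  cpp_time_average(dur_matrix(params), params@p1,
                   if (isDirectTauS(params)) 0 else params@p2,
                   isDirectTauS(params), params@tau_m, t_end, burnin)
}

#' Simulate the alternating-phase renewal approximation
#'
#' Monte Carlo counterpart of the analytic transient curves: the first
#' activation time is drawn from \code{g0}, active phases are exponential
#' with mean \code{tau_A}, inactive phases are drawn from \code{f_I};
#' transcripts appear as a Poisson process with rate \code{1/tau_P} while
#' active and decay with exponential lifetime \code{tau_m}.
#'
#' @param g0 \linkS4class{EventDurationModel} for the first activation time
#'   (use \code{eventDuration("point", mean = 0)} for an immediately poised
#'   gene).
#' @param f_I \linkS4class{EventDurationModel} for the inactive phase.
#' @param tau_A,tau_P,tau_m kinetic constants (min).
#' @param t_grid increasing times (min).
#' @param n_traj number of replicates.
#' @param seed integer seed.
#' @return data.frame with columns \code{time}, \code{P_A}, \code{se_P_A},
#'   \code{mean}, \code{se_mean}.
#' @export
simulatePhaseRenewal <- function(g0, f_I, tau_A, tau_P, tau_m, t_grid,
                                 n_traj, seed) {
  stopifnot(tau_A > 0, tau_P > 0, tau_m > 0, all(diff(t_grid) > 0))
  set.seed(seed)
  raw <- cpp_phase_renewal(dur_row(g0), dur_row(f_I), tau_A, tau_P, tau_m,
                           t_grid, as.integer(n_traj))
  pa <- raw$active / raw$n
  m1 <- raw$s1 / raw$n
  mu2 <- pmax(raw$s2 / raw$n - m1^2, 0)
  data.frame(time = t_grid, P_A = pa, se_P_A = sqrt(pa * (1 - pa) / raw$n),
             mean = m1, se_mean = sqrt(mu2 / raw$n))
}

#' Simulate the two-state telegraph model
#'
#' The classical Markov comparator: a promoter switches OFF -> ON at rate
#' \code{k_on} and ON -> OFF at rate \code{k_off}, synthesises at rate
#' \code{k_syn} while ON, and transcripts decay at rate \code{1/tau_m}.
#'
#' @param k_on,k_off,k_syn rates (1/min, > 0).
#' @param tau_m mRNA lifetime (min).
#' @param t_end horizon for the single-trajectory record (min).
#' @param seed integer seed.
#' @return list with \code{switches} (data.frame time/state),
#'   \code{synthesis_times} and \code{degradation_times}.
#' @export
simulateTelegraph <- function(k_on, k_off, k_syn, tau_m, t_end, seed) {
  stopifnot(k_on > 0, k_off > 0, k_syn > 0, tau_m > 0, t_end > 0)
  set.seed(seed)
  raw <- cpp_telegraph_trajectory(k_on, k_off, k_syn, tau_m, t_end, 0L)
  list(switches = data.frame(time = raw$switch_time, state = raw$switch_state),
       synthesis_times = raw$synthesis, degradation_times = raw$degradation)
}

#' Ensemble moments of the telegraph model
#'
#' @inheritParams simulateTelegraph
#' @param t_grid increasing times (min).
#' @param n_traj number of trajectories.
#' @return data.frame as in \code{\link{ensembleMoments}}.
#' @export
telegraphEnsembleMoments <- function(k_on, k_off, k_syn, tau_m, t_grid,
                                     n_traj, seed) {
  stopifnot(all(diff(t_grid) > 0), n_traj >= 2)
  set.seed(seed)
  raw <- cpp_telegraph_moments(k_on, k_off, k_syn, tau_m, t_grid,
                               as.integer(n_traj), 0L)
  moments_frame(t_grid, raw)
}
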