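#' Construct an event duration model
#'
#' @param family distribution family: \code{"exponential"} (default),
#'   \code{"gamma"}, \code{"delayed-exponential"} or \code{"point"}.
#' @param mean mean duration in minutes (> 0).
#' @param cv coefficient of variation; required for the gamma family,
#'   forced to 1 (exponential), 0 (point) or derived (delayed-exponential)
#'   otherwise.
#' @param delay refractory offset in minutes for the delayed-exponential
#'   family (0 <= delay < mean).
#' @return an \linkS4class{EventDurationModel}.
#' @examples
#' eventDuration("gamma", mean = 10, cv = 0.5)
#' eventDuration("delayed-exponential", mean = 10, delay = 2)
#' @export
eventDuration <- function(family = "exponential", mean, cv = NULL, delay = 0) {
  family <- match.arg(family, DUR_FAMILIES)
  cv <- switch(family,
    "exponential" = 1,
    "point" = 0,
    "delayed-exponential" = (mean - delay) / mean,
    "gamma" = {
      if (is.null(cv)) stop("gamma family requires an explicit cv")
      cv
    })
  new("EventDurationModel", family = family, mean = as.numeric(mean),
      cv = as.numeric(cv), delay = as.numeric(delay))
}

#' Compose the mean inactive-cycle duration from its event components
#'
#' One silent cycle visits the first silent event, a geometric number of
#' repetitions of the third silent event (continuation probability
#' \code{p2}), and the second silent event, so its mean is
#' \deqn{\tau_S = \tau_{S1} + \tau_{S2} + p_2 \tau_{S3} / (1 - p_2).}
#'
#' @param tau_S1,tau_S2,tau_S3 mean event durations (min, > 0).
#' @param p2 repetition probability of the third silent event in [0, 1).
#' @return the composite mean \code{tau_S} in minutes.
#' @examples
#' composeTauS(10, 30, 60, 0.5)  # 100
#' @export
composeTauS <- function(tau_S1, tau_S2, tau_S3, p2) {
  stopifnot(tau_S1 > 0, tau_S2 > 0, tau_S3 > 0)
  if (any(p2 < 0 | p2 >= 1)) stop("p2 must lie in [0, 1)")
  tau_S1 + tau_S2 + p2 * tau_S3 / (1 - p2)
}

#' Construct a set of bursting parameters
#'
#' Either the three silent-event means and \code{p2} are given, or a single
#' composite mean \code{tau_S} (direct mode, in which every inactive cycle
#' is a single exponential draw).
#'
#' @param tau_P mean productive-event duration (min).
#' @param p1 repetition probability of the productive event in [0, 1);
#'   also gates burst entry after a completed inactive cycle.
#' @param tau_m mean mRNA lifetime (min); defaults to 5.
#' @param tau_S1,tau_S2,tau_S3,p2 silent-cycle components (component mode).
#' @param tau_S composite mean inactive-cycle duration (direct mode).
#' @param durationModels optional named list of
#'   \linkS4class{EventDurationModel} overrides (names among \code{P},
#'   \code{S1}, \code{S2}, \code{S3}, \code{S}).
#' @return a validated \linkS4class{BurstParams}.
#' @examples
#' burstParams(tau_P = 0.165, p1 = 0.95, tau_S = 100)          # direct
#' burstParams(tau_P = 1, p1 = 0.9, tau_S1 = 15, tau_S2 = 2,
#'             tau_S3 = 4, p2 = 0.5, tau_m = 10)               # components
#' @export
burstParams <- function(tau_P, p1, tau_m = 5, tau_S1 = NULL, tau_S2 = NULL,
                        tau_S3 = NULL, p2 = NULL, tau_S = NULL,
                        durationModels = list()) {
  direct <- !is.null(tau_S)
  if (direct && !all(vapply(list(tau_S1, tau_S2, tau_S3, p2), is.null,
                            logical(1))))
    stop("give either tau_S (direct mode) or the tau_S1/tau_S2/tau_S3/p2 ",
         "components, not both")
  if (!direct && any(vapply(list(tau_S1, tau_S2, tau_S3, p2), is.null,
                            logical(1))))
    stop("component mode requires tau_S1, tau_S2, tau_S3 and p2")
  na <- NA_real_
  new("BurstParams", tau_P = as.numeric(tau_P), p1 = as.numeric(p1),
      tau_m = as.numeric(tau_m),
      tau_S1 = if (direct) na else as.numeric(tau_S1),
      tau_S2 = if (direct) na else as.numeric(tau_S2),
      tau_S3 = if (direct) na else as.numeric(tau_S3),
      p2 = if (direct) na else as.numeric(p2),
      tau_S = if (direct) as.numeric(tau_S) else na,
      durationModels = durationModels)
}

#' @rdname burstParams
#' @param params a \linkS4class{BurstParams} object.
#' @export
isDirectTauS <- function(params) !is.na(params@tau_S)

#' Composite mean inactive-cycle duration of a parameter set
#' @param params a \linkS4class{BurstParams}.
#' @return tau_S in minutes.
#' @export
tauS <- function(params) {
  if (isDirectTauS(params)) params@tau_S
  else composeTauS(params@tau_S1, params@tau_S2, params@tau_S3, params@p2)
}

#' Derive burst-cycle quantities from bursting parameters
#'
#' Computes the composite silent-cycle mean, active and inactive phase
#' durations \eqn{\tau_A = \tau_P/(1-p_1)} and \eqn{\tau_I = \tau_S/p_1},
#' the burst period, size, frequency, and the steady-state mean copy number
#' \eqn{\langle m\rangle = b f \tau_m}.
#'
#' @param params a \linkS4class{BurstParams}.
#' @return a \linkS4class{DerivedQuantities}. With \code{p1 = 0} the gene
#'   never bursts: the inactive phase and period are infinite and
#'   \code{m_mean = 0}.
#' @export
deriveQuantities <- function(params) {
  ts <- tauS(params)
  tau_A <- params@tau_P / (1 - params@p1)
  tau_I <- if (params@p1 > 0) ts / params@p1 else Inf
  period <- tau_A + tau_I
  b <- 1 / (1 - params@p1)
  f <- if (is.finite(period)) 1 / period else 0
  new("DerivedQuantities", tau_S = ts, tau_A = tau_A, tau_I = tau_I,
      period = period, b = b, f = f, m_mean = b * f * params@tau_m,
      c = tau_A / params@tau_m, d = tau_I / params@tau_m)
}

#' Sample durations from an event duration model
#'
#' @param model an \linkS4class{EventDurationModel}.
#' @param n number of draws.
#' @return numeric vector of \code{n} nonnegative durations (min). Seed the
#'   R RNG with \code{set.seed} for reproducibility.
#' @export
sampleDuration <- function(model, n = 1) {
  switch(model@family,
    "exponential" = rexp(n, rate = 1 / model@mean),
    "gamma" = {
      shape <- 1 / model@cv^2
      rgamma(n, shape = shape, scale = model@mean / shape)
    },
    "delayed-exponential" = model@delay + rexp(n, 1 / (model@mean - model@delay)),
    "point" = rep(model@mean, n))
}

## ------------------------------------------------------------------
## internal helpers shared by the simulator and the analytics

FAM_CODE <- c("exponential" = 0, "gamma" = 1, "delayed-exponential" = 2,
              "point" = 3)

dur_row <- function(model) {
  c(FAM_CODE[[model@family]], model@mean, model@cv, model@delay)
}

## effective duration model for one event slot, honouring overrides
event_model_of <- function(params, which) {
  dm <- params@durationModels
  if (!is.null(dm[[which]])) return(dm[[which]])
  mean <- switch(which, P = params@tau_P, S1 = params@tau_S1,
                 S2 = params@tau_S2, S3 = params@tau_S3, S = params@tau_S)
  eventDuration("exponential", mean = mean)
}

## 4 x 4 matrix (rows P, S1/S, S2, S3) consumed by the C++ simulator
dur_matrix <- function(params) {
  direct <- isDirectTauS(params)
  rows <- list(event_model_of(params, "P"),
               if (direct) event_model_of(params, "S")
               else event_model_of(params, "S1"),
               if (direct) eventDuration(mean = 1)
               else event_model_of(params, "S2"),
               if (direct) eventDuration(mean = 1)
               else event_model_of(params, "S3"))
  do.call(rbind, lapply(rows, dur_row))
}

## mean / variance / third central moment of a duration model
dur_moments <- function(model) {
  m <- model@mean
  switch(model@family,
    "exponential" = c(mean = m, var = m^2, k3 = 2 * m^3),
    "gamma" = {
      shape <- 1 / model@cv^2
      theta <- m / shape
      c(mean = m, var = shape * theta^2, k3 = 2 * shape * theta^3)
    },
    "delayed-exponential" = {
      s <- m - model@delay
      c(mean = m, var = s^2, k3 = 2 * s^3)
    },
    "point" = c(mean = m, var = 0, k3 = 0))
}

## Laplace transform of a duration model at s
dur_lt <- function(model, s) {
  m <- model@mean
  switch(model@family,
    "exponential" = 1 / (1 + s * m),
    "gamma" = {
      shape <- 1 / model@cv^2
      (1 + s * m / shape)^(-shape)
    },
    "delayed-exponential" = exp(-s * model@delay) / (1 + s * (m - model@delay)),
    "point" = exp(-s * m))
}

## Cumulants (mean, var, k3) of one full inactive cycle
cycle_moments <- function(params) {
  if (isDirectTauS(params)) return(dur_moments(event_model_of(params, "S")))
  m1 <- dur_moments(event_model_of(params, "S1"))
  m2 <- dur_moments(event_model_of(params, "S2"))
  m3 <- dur_moments(event_model_of(params, "S3"))
  p2 <- params@p2
  ## geometric (continuation p2) number of S3 repeats: compound cumulants
  ## from raw moments of the S3 block
  r1 <- m3[["mean"]]; r2 <- m3[["var"]] + r1^2
  r3 <- m3[["k3"]] + 3 * r1 * r2 - 2 * r1^3
  ## raw moments of the geometric sum (prob (1-p2) of zero, else one block
  ## plus an independent geometric sum again): solve the renewal identities
  ## numerically is overkill -- for the exponential default the block sum is
  ## a mixture of 0 and an exponential; in general use compound-geometric
  ## cumulant formulas with N ~ Geom0(p2): E N = p2/(1-p2),
  ## Var N = p2/(1-p2)^2, k3(N) = p2(1+p2)/(1-p2)^3.
  EN <- p2 / (1 - p2); VN <- p2 / (1 - p2)^2
  k3N <- p2 * (1 + p2) / (1 - p2)^3
  mu <- r1; sig2 <- r2 - r1^2; k3x <- r3 - 3 * r1 * r2 + 2 * r1^3
  g_mean <- EN * mu
  g_var <- EN * sig2 + VN * mu^2
  g_k3 <- EN * k3x + 3 * VN * mu * sig2 + k3N * mu^3
  c(mean = m1[["mean"]] + m2[["mean"]] + g_mean,
    var = m1[["var"]] + m2[["var"]] + g_var,
    k3 = m1[["k3"]] + m2[["k3"]] + g_k3)
}

## Laplace transform of one full inactive cycle
cycle_lt <- function(params, s) {
  if (isDirectTauS(params)) return(dur_lt(event_model_of(params, "S"), s))
  L1 <- dur_lt(event_model_of(params, "S1"), s)
  L2 <- dur_lt(event_model_of(params, "S2"), s)
  L3 <- dur_lt(event_model_of(params, "S3"), s)
  L1 * L2 * (1 - params@p2) / (1 - params@p2 * L3)
}

## Mean and variance of the full inactive phase (geometric number of cycles
## with success probability p1)
inactive_phase_moments <- function(params) {
  cm <- cycle_moments(params)
  p1 <- params@p1
  EN <- 1 / p1; VN <- (1 - p1) / p1^2
  c(mean = EN * cm[["mean"]],
    var = EN * cm[["var"]] + VN * cm[["mean"]]^2)
}

#' Read bursting parameters from a JSON configuration file
#'
#' Keys mirror the \code{\link{burstParams}} arguments (\code{tau_P},
#' \code{tau_S1}, \code{tau_S2}, \code{tau_S3}, \code{tau_S}, \code{p1},
#' \code{p2}, \code{tau_m}), plus an optional \code{seed}. Unknown keys are
#' rejected.
#'
#' @param path path to a JSON file.
#' @return list with elements \code{params} (a \linkS4class{BurstParams})
#'   and \code{seed} (integer or \code{NULL}).
#' @export
readBurstConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("tau_P", "tau_S1", "tau_S2", "tau_S3", "tau_S", "p1", "p2",
             "tau_m", "seed")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  seed <- if (!is.null(cfg$seed)) as.integer(cfg$seed) else NULL
  cfg$seed <- NULL
  params <- do.call(burstParams, cfg)
  list(params = params, seed = seed)
}
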