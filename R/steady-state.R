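#' Steady-state mean mRNA copy number
#'
#' \deqn{\langle m\rangle = \frac{\tau_m}{\tau_P + \frac{1-p_1}{p_1}\tau_S},}
#' identically equal to \eqn{b f \tau_m}.
#'
#' @param params a \linkS4class{BurstParams}.
#' @return the mean copy number; 0 when \code{p1 = 0}.
#' @examples
#' meanMrna(burstParams(tau_P = 0.165, p1 = 0.95, tau_S = 100))  # ~0.921
#' @export
meanMrna <- function(params) {
  if (params@p1 == 0) return(0)
  params@tau_m / (params@tau_P + (1 - params@p1) / params@p1 * tauS(params))
}

## Fano factor in terms of burst size b and the dimensionless phase ratios
## c = tau_A/tau_m, d = tau_I/tau_m (exponential phases).  This is the
## burst-parameter form of the stationary noise expression.
fano_bcd <- function(b, c, d) {
  1 + d * ((b - 1) * d - c) / ((c + d) * (c + d + c * d))
}

## Renewal-theory exact Fano factor: transcript completions form an ordinary
## renewal process with inter-arrival X = D_P + Bernoulli(1 - p1) * J where
## J is the full inactive phase; for any duration families
## F = 1 + X*/(1 - X*) - <m> evaluated at s = 1/tau_m.
fano_renewal <- function(params) {
  s <- 1 / params@tau_m
  LP <- dur_lt(event_model_of(params, "P"), s)
  C <- cycle_lt(params, s)
  p1 <- params@p1
  J <- p1 * C / (1 - (1 - p1) * C)
  X <- LP * (p1 + (1 - p1) * J)
  m <- meanMrna(params)
  1 + X / (1 - X) - m
}

#' Steady-state variance and Fano factor
#'
#' Two algebraically equivalent closed forms of the stationary
#' noise are provided. \code{method = "closed"} evaluates
#' \deqn{\sigma_m^2 = \langle m\rangle + \langle m\rangle^2
#'   \frac{(\tau_I/\tau_m + \tau_A/\tau_m)(\tau_S/\tau_m) -
#'         \tau_A\tau_I/\tau_m^2}
#'        {\tau_I/\tau_m + \tau_A/\tau_m + \tau_A\tau_I/\tau_m^2}}
#' and the matching burst-parameter Fano form
#' \eqn{F = 1 + d[(b-1)d - c] / [(c+d)(c+d+cd)]}; both are exact when the
#' productive event and the inactive cycle are exponential with the cycle
#' drawn directly (direct \code{tau_S} mode), and are the standard
#' approximation otherwise. \code{method = "renewal"} evaluates the exact
#' renewal-theory expression for the actual event structure (components,
#' non-exponential families, refractory offsets).
#'
#' @param params a \linkS4class{BurstParams}.
#' @param method \code{"closed"} (default) or \code{"renewal"}.
#' @return named vector \code{c(variance, fano)}; with \code{m_mean = 0} the
#'   Fano factor is \code{NA}.
#' @export
varianceFano <- function(params, method = c("closed", "renewal")) {
  method <- match.arg(method)
  m <- meanMrna(params)
  if (m == 0) return(c(variance = 0, fano = NA_real_))
  dq <- deriveQuantities(params)
  fano <- if (method == "closed") fano_bcd(dq@b, dq@c, dq@d)
          else fano_renewal(params)
  c(variance = fano * m, fano = fano)
}

#' @rdname varianceFano
#' @export
fanoFactor <- function(params, method = c("closed", "renewal")) {
  unname(varianceFano(params, method)[["fano"]])
}

#' Slope of the Fano factor along the tau_S-regulated path
#'
#' With \code{tau_P} and \code{p1} fixed and the inactive-cycle mean varied,
#' the mean-Fano curve has slope \eqn{dF/d\langle m\rangle}; the analytic
#' chain-rule derivative \eqn{(dF/d\tau_S)/(d\langle m\rangle/d\tau_S)} of
#' the closed-form Fano factor is returned. The slope is negative at large
#' means: noise falls toward the Poisson limit as expression rises along
#' this path.
#'
#' @param params a \linkS4class{BurstParams}; its \code{tauS(params)} sets
#'   the evaluation point.
#' @return the dimensionless slope.
#' @export
fanoSlope <- function(params) {
  p1 <- params@p1
  if (p1 <= 0) stop("fanoSlope requires p1 > 0")
  tau_m <- params@tau_m
  ts <- tauS(params)
  b <- 1 / (1 - p1)
  cc <- params@tau_P / ((1 - p1) * tau_m)   # fixed along the path
  d <- ts / (p1 * tau_m)
  ## F = 1 + N(d)/D(d)
  N <- (b - 1) * d^2 - cc * d
  D <- (cc + d) * (cc + d + cc * d)
  dN <- 2 * (b - 1) * d - cc
  dD <- (cc + d + cc * d) + (cc + d) * (1 + cc)
  dF_dd <- (dN * D - N * dD) / D^2
  dF_dts <- dF_dd / (p1 * tau_m)
  m <- meanMrna(params)
  dm_dts <- -(1 - p1) / p1 * m^2 / tau_m
  dF_dts / dm_dts
}

#' Mean burst-profile height
#'
#' Piecewise approximation of the mean height of individual burst profiles:
#' \eqn{h \approx \tau_m (1 - e^{-c})(1 - e^{-d}) / [\tau_P (1 - e^{-c-d})]}
#' for \eqn{\tau_P < \tau_m}, and \eqn{h \approx 1} otherwise.
#'
#' @param params a \linkS4class{BurstParams}.
#' @return the approximate mean burst height (transcripts).
#' @export
burstHeight <- function(params) {
  if (params@tau_P >= params@tau_m) return(1)
  dq <- deriveQuantities(params)
  c <- dq@c; d <- dq@d
  params@tau_m * (1 - exp(-c)) * (1 - exp(-d)) /
    (params@tau_P * (1 - exp(-c - d)))
}

#' Upper bounds on expression and noise at fixed tau_P
#'
#' With the productive-event duration fixed, the mean copy number cannot
#' exceed \eqn{\tau_m/\tau_P} and the Fano factor cannot exceed
#' \eqn{1 + \tau_m/\tau_P}.
#'
#' @param tau_P,tau_m times (min, > 0).
#' @return named vector \code{c(m_max, F_max)}.
#' @export
expressionBounds <- function(tau_P, tau_m) {
  stopifnot(tau_P > 0, tau_m > 0)
  c(m_max = tau_m / tau_P, F_max = 1 + tau_m / tau_P)
}

#' Lower bound on the Fano factor at fixed mean expression
#'
#' Eliminating \eqn{\tau_P} through the mean-expression identity, the Fano
#' factor at given \eqn{\langle m\rangle} is minimised (in the
#' high-expression regime \eqn{\langle m\rangle > \tau_m/(2\tau_S)}) at the
#' smallest attainable inactive-cycle mean \code{tau_S0} and the largest
#' attainable \code{p10}.
#'
#' @param m_mean target mean copy number (> 0).
#' @param tau_S0 minimum attainable composite inactive-cycle mean (min).
#' @param p10 maximum attainable repetition probability, in (0, 1).
#' @param tau_m mRNA lifetime (min).
#' @return the bound on the Fano factor.
#' @export
fanoLowerBound <- function(m_mean, tau_S0, p10, tau_m = 5) {
  stopifnot(m_mean > 0, tau_S0 > 0, p10 > 0, p10 < 1, tau_m > 0)
  tau_P <- tau_m / m_mean - (1 - p10) / p10 * tau_S0
  if (tau_P <= 0)
    stop("infeasible mean: implied tau_P would be non-positive")
  fanoFactor(burstParams(tau_P = tau_P, p1 = p10, tau_m = tau_m,
                         tau_S = tau_S0))
}

#' Closed-form steady-state moments of the telegraph model
#'
#' @param k_on,k_off,k_syn rates (1/min).
#' @param tau_m mRNA lifetime (min).
#' @return named vector \code{c(mean, variance, fano)}.
#' @export
telegraphMoments <- function(k_on, k_off, k_syn, tau_m) {
  stopifnot(k_on > 0, k_off > 0, k_syn > 0, tau_m > 0)
  pon <- k_on / (k_on + k_off)
  m <- k_syn * tau_m * pon
  fano <- 1 + k_syn * k_off /
    ((k_on + k_off) * (k_on + k_off + 1 / tau_m))
  c(mean = m, variance = fano * m, fano = fano)
}

#' Genome-scale constraint scan of noise versus expression
#'
#' Samples bursting parameter sets with the burst duration and the
#' transcription rate drawn log-uniformly, keeps sets with a shorter active
#' than inactive phase, optionally prepends a refractory period to the
#' silent cycle, and evaluates the analytic mean and Fano factor under both
#' the event model and a mean-matched telegraph comparator
#' (\code{k_on = 1/tau_I}, \code{k_off = 1/tau_A}, \code{k_syn = 1/tau_P}).
#'
#' @param n_sets number of accepted parameter sets.
#' @param burst_duration_range range (min) of the log-uniform burst
#'   duration draw.
#' @param rate_range range (1/min) of the log-uniform transcription rate.
#' @param refractory refractory period (min, >= 0) prepended to the silent
#'   cycle as a delayed-exponential offset.
#' @param tau_m mRNA lifetime (min).
#' @param seed integer seed.
#' @param duration_is one of \code{"period"} (the sampled burst duration is
#'   the full burst period, split into active and inactive parts by a
#'   uniform fraction) or \code{"active"} (it is the active phase alone,
#'   with the inactive phase drawn from the same range).
#' @param telegraph \code{"independent"} (default): the comparator draws its
#'   ON/OFF durations and synthesis rate independently from the same ranges,
#'   without the event model's coupling of burst size to the phase
#'   durations and without the phase-ordering rejection -- the telegraph
#'   model's defining independence of bursting parameters.
#'   \code{"matched"}: the comparator reuses each accepted event-model set
#'   (\code{k_on = 1/tau_I}, \code{k_off = 1/tau_A},
#'   \code{k_syn = 1/tau_P}).
#' @return data.frame with columns \code{model}, \code{set_id},
#'   \code{m_mean}, \code{fano}, \code{tau_A}, \code{tau_I}, \code{tau_P},
#'   \code{p1}, \code{refractory}.
#' @export
constraintScan <- function(n_sets, burst_duration_range = c(1, 1000),
                           rate_range = c(0.1, 100), refractory = 0,
                           tau_m = 5, seed = 1,
                           duration_is = c("period", "active"),
                           telegraph = c("independent", "matched")) {
  duration_is <- match.arg(duration_is)
  telegraph <- match.arg(telegraph)
  stopifnot(n_sets >= 1, refractory >= 0,
            all(burst_duration_range > 0), all(rate_range > 0))
  set.seed(seed)
  runif_log <- function(n, rng) exp(runif(n, log(rng[1]), log(rng[2])))
  acc <- list()
  got <- 0L
  tries <- 0L
  while (got < n_sets) {
    n_draw <- max(1000L, 2L * (n_sets - got))
    tries <- tries + n_draw
    if (tries > 1e8) stop("empty feasible region for the requested scan")
    dur <- runif_log(n_draw, burst_duration_range)
    tau_P <- 1 / runif_log(n_draw, rate_range)
    if (duration_is == "period") {
      u <- runif(n_draw)
      tau_A <- u * dur
      tau_I <- dur - tau_A
    } else {
      tau_A <- dur
      tau_I <- runif_log(n_draw, burst_duration_range)
    }
    ok <- tau_A < tau_I & tau_P < tau_A
    p1 <- 1 - tau_P / tau_A
    tau_S <- p1 * tau_I
    ok <- ok & p1 > 0 & p1 < 1 & tau_S > refractory
    idx <- which(ok)
    if (length(idx)) {
      take <- idx[seq_len(min(length(idx), n_sets - got))]
      acc[[length(acc) + 1L]] <-
        data.frame(tau_A = tau_A[take], tau_I = tau_I[take],
                   tau_P = tau_P[take], p1 = p1[take], tau_S = tau_S[take])
      got <- got + length(take)
    }
  }
  sets <- do.call(rbind, acc)
  n <- nrow(sets)
  ev_f <- numeric(n); ev_m <- numeric(n)
  for (i in seq_len(n)) {
    dm <- if (refractory > 0)
      list(S = eventDuration("delayed-exponential", mean = sets$tau_S[i],
                             delay = refractory))
    else list()
    p <- burstParams(tau_P = sets$tau_P[i], p1 = sets$p1[i], tau_m = tau_m,
                     tau_S = sets$tau_S[i], durationModels = dm)
    ev_m[i] <- meanMrna(p)
    ev_f[i] <- fanoFactor(p, method = "renewal")
  }
  if (telegraph == "matched") {
    tg_A <- sets$tau_A; tg_I <- sets$tau_I; tg_P <- sets$tau_P
  } else {
    tg_A <- runif_log(n, burst_duration_range)
    tg_I <- runif_log(n, burst_duration_range)
    tg_P <- 1 / runif_log(n, rate_range)
  }
  k_on <- 1 / tg_I; k_off <- 1 / tg_A; k_syn <- 1 / tg_P
  tg_m <- k_syn * tau_m * k_on / (k_on + k_off)
  tg_f <- 1 + k_syn * k_off / ((k_on + k_off) * (k_on + k_off + 1 / tau_m))
  rbind(
    data.frame(model = "event", set_id = seq_len(n), m_mean = ev_m,
               fano = ev_f, tau_A = sets$tau_A, tau_I = sets$tau_I,
               tau_P = sets$tau_P, p1 = sets$p1, refractory = refractory),
    data.frame(model = "telegraph", set_id = seq_len(n), m_mean = tg_m,
               fano = tg_f, tau_A = tg_A, tau_I = tg_I,
               tau_P = tg_P, p1 = NA_real_, refractory = refractory))
}

#' Lower-envelope summary of a constraint scan
#'
#' Helper used to quantify the rising noise floor: bins the scan by mean
#' expression quartiles and returns the lower decile of the Fano factor in
#' the bottom and top quartile.
#'
#' @param scan one model's rows from \code{\link{constraintScan}}.
#' @return named vector \code{c(low = ..., high = ...)} of lower-decile
#'   Fano factors.
#' @export
fanoEnvelope <- function(scan) {
  qs <- stats::quantile(scan$m_mean, c(0.25, 0.75))
  lo <- scan$fano[scan$m_mean <= qs[1]]
  hi <- scan$fano[scan$m_mean >= qs[2]]
  c(low = unname(stats::quantile(lo, 0.1)),
    high = unname(stats::quantile(hi, 0.1)))
}
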