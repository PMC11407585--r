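## density of a duration model on the grid nodes t (t[1] = 0), with the
## node-0 value replaced by the equivalent first-half-cell mass so that
## trapezoidal quadrature integrates correctly near an endpoint or a mild
## power-law singularity
dens_grid <- function(model, t) {
  dt <- t[2] - t[1]
  m <- model@mean
  d <- switch(model@family,
    "exponential" = stats::dexp(t, 1 / m),
    "gamma" = {
      shape <- 1 / model@cv^2
      stats::dgamma(t, shape = shape, scale = m / shape)
    },
    "delayed-exponential" = {
      s <- m - model@delay
      ifelse(t >= model@delay, stats::dexp(t - model@delay, 1 / s), 0)
    },
    "point" = stop("point distributions are handled as atoms"))
  cdf_half <- switch(model@family,
    "exponential" = stats::pexp(dt / 2, 1 / m),
    "gamma" = {
      shape <- 1 / model@cv^2
      stats::pgamma(dt / 2, shape = shape, scale = m / shape)
    },
    "delayed-exponential" = {
      s <- m - model@delay
      if (model@delay < dt / 2) stats::pexp(dt / 2 - model@delay, 1 / s) else 0
    })
  d[1] <- 2 * cdf_half / dt
  d
}

dist_mean_var <- function(model) {
  mo <- dur_moments(model)
  c(mean = mo[["mean"]], var = mo[["var"]])
}

## trapezoidal convolution of two density vectors on a uniform grid
conv_dens <- function(x, y, dt) {
  n <- length(x)
  np <- 2 * n
  fx <- stats::fft(c(x, numeric(np - n)))
  fy <- stats::fft(c(y, numeric(np - n)))
  z <- Re(stats::fft(fx * fy, inverse = TRUE)) / np
  ## left-endpoint sum corrected to trapezoid weights
  dt * (z[seq_len(n)] - (x[seq_len(n)] * y[1] + x[1] * y[seq_len(n)]) / 2)
}

## exponential-kernel convolution I(t) = int_0^t u(s) exp(-(t-s)/tau) ds by
## second-order recursion
exp_smooth <- function(u, dt, tau) {
  n <- length(u)
  out <- numeric(n)
  e <- exp(-dt / tau)
  for (k in 2:n) out[k] <- e * out[k - 1] + dt / 2 * (e * u[k - 1] + u[k])
  out
}

#' Moment-match the phase distributions used by the transient theory
#'
#' The inactive phase (a geometric number of silent cycles) and the first
#' burst are approximated by Gamma distributions matched to their exact
#' first two moments.
#'
#' @param params a \linkS4class{BurstParams}.
#' @param which \code{"inactive"} for the steady-state inactive phase, or
#'   \code{"first"} for the first burst (requires \code{f_I_init}).
#' @param f_I_init \linkS4class{EventDurationModel} of the first silent
#'   interval (time from stimulus onset to the first activation).
#' @return list with the matched Gamma \code{shape} and \code{scale}, the
#'   target \code{mean} and \code{var}, and for \code{which = "first"} also
#'   \code{tau_first} and \code{cv_first}.
#' @export
gammaMatch <- function(params, which = c("inactive", "first"),
                       f_I_init = NULL) {
  which <- match.arg(which)
  if (which == "inactive") {
    mo <- inactive_phase_moments(params)
    mean <- mo[["mean"]]; v <- mo[["var"]]
  } else {
    if (is.null(f_I_init))
      stop("which = \"first\" requires f_I_init")
    iv <- dist_mean_var(f_I_init)
    tau_A <- params@tau_P / (1 - params@p1)
    mean <- iv[["mean"]] + tau_A
    v <- iv[["var"]] + tau_A^2
  }
  if (v <= 0)
    return(list(shape = Inf, scale = 0, mean = mean, var = 0,
                degenerate = TRUE))
  out <- list(shape = mean^2 / v, scale = v / mean, mean = mean, var = v,
              degenerate = FALSE)
  if (which == "first") {
    out$tau_first <- mean
    out$cv_first <- sqrt(v) / mean
  }
  out
}

#' Analytic transient response after a step stimulus
#'
#' Evaluates the renewal series for the activation probability
#' \deqn{P_A(t) = g_0 * \textstyle\sum_{i\ge 0} (f_A * f_I)^{*i} *
#'       e^{-t/\tau_A}}
#' (with \eqn{g_0} the distribution of the first activation time) by
#' solving the equivalent renewal integral equation with trapezoidal
#' quadrature, and the mean count
#' \eqn{\langle m\rangle(t) = \tau_P^{-1}\,(P_A * e^{-t/\tau_m})(t)}.
#' Steady-state values are \eqn{P_{Ass} = \tau_A/T} and
#' \eqn{\langle m\rangle_{ss} = b\tau_m/T} with \eqn{T = \tau_A + \tau_I}
#' and \eqn{b = \tau_A/\tau_P}.
#'
#' @param g0 \linkS4class{EventDurationModel} of the initial-condition
#'   distribution; with \code{g0_type = "activation"} it is the first
#'   activation time (a \code{"point"} model with mean 0 describes a gene
#'   poised to fire immediately), with \code{g0_type = "first-burst-end"}
#'   it is the first-burst completion time \eqn{f_{first}} and the series
#'   is evaluated as
#'   \eqn{P_A(t) = \tau_A\, f_{first} * \sum_{i\ge 0}(f_I * f_A)^{*i}},
#'   whose leading term \eqn{\tau_A f_{first}(t)} underlies the overshoot
#'   criterion.
#' @param f_I \linkS4class{EventDurationModel} of the steady-state inactive
#'   phase (typically the Gamma from \code{\link{gammaMatch}}).
#' @param tau_A,tau_P,tau_m kinetic constants (min).
#' @param g0_type how \code{g0} parameterises the initial condition.
#' @param dt grid step (min); default
#'   \code{min(tau_A, f_I scale, tau_m)/50}.
#' @param horizon grid end (min); default \code{10 max(T, tau_m)} plus five
#'   times the mean of \code{g0}.
#' @param overshoot_tol relative margin above the steady state required to
#'   flag an overshoot (guards against grid noise).
#' @return a \linkS4class{TransientCurves}.
#' @export
transientCurves <- function(g0, f_I, tau_A, tau_P, tau_m, dt = NULL,
                            horizon = NULL, overshoot_tol = 0.005,
                            g0_type = c("activation", "first-burst-end")) {
  g0_type <- match.arg(g0_type)
  stopifnot(tau_A > 0, tau_P > 0, tau_m > 0)
  tau_I <- f_I@mean
  period <- tau_A + tau_I
  g0m <- dist_mean_var(g0)
  if (is.null(dt)) {
    theta_I <- f_I@cv^2 * tau_I       # gamma scale of the inactive phase
    dt <- min(tau_A, max(theta_I, 1e-3), tau_m) / 50
  }
  if (is.null(horizon))
    horizon <- 10 * max(period, tau_m) + 5 * g0m[["mean"]]
  t <- seq(0, horizon, by = dt)
  n <- length(t)

  fA <- dens_grid(eventDuration("exponential", mean = tau_A), t)
  fI <- dens_grid(f_I, t)
  q <- conv_dens(fA, fI, dt)
  q <- pmax(q, 0)

  if (g0@family == "point") {
    if (g0_type == "first-burst-end")
      stop("a point-mass first-burst-end distribution is not supported")
    atom <- 1
    atom_idx <- which.min(abs(t - g0@mean))
    if (abs(t[atom_idx] - g0@mean) > dt)
      stop("point-mass g0 must lie on the grid")
    forcing <- atom * c(numeric(atom_idx - 1), q[seq_len(n - atom_idx + 1)])
  } else {
    atom <- 0
    atom_idx <- 1L
    forcing <- dens_grid(g0, t)
  }
  ## renewal equation u = forcing + u * q (u excludes any t = g0 atom)
  u <- numeric(n)
  denom <- 1 - dt * q[1] / 2
  u[1] <- forcing[1] / denom
  for (k in 2:n) {
    s <- dt * (sum(u[1:(k - 1)] * q[k:2]) - u[1] * q[k] / 2)
    u[k] <- (forcing[k] + s) / denom
  }

  if (g0_type == "activation") {
    ## activity = activation density smoothed by the exponential survival
    P_A <- exp_smooth(u, dt, tau_A)
    if (atom > 0) {
      shift <- numeric(n)
      shift[atom_idx:n] <- exp(-(t[atom_idx:n] - t[atom_idx]) / tau_A)
      P_A <- P_A + atom * shift
    }
  } else {
    ## activity = tau_A times the burst-completion density
    P_A <- tau_A * u
  }
  m <- exp_smooth(P_A, dt, tau_m) / tau_P

  P_Ass <- tau_A / period
  m_ss <- (tau_A / tau_P) * tau_m / period
  P_AP <- max(P_A)
  m_peak <- max(m)
  H_P <- max(0, (P_AP - P_Ass) / P_Ass)
  H_m <- max(0, (m_peak - m_ss) / m_ss)
  cross <- function(y, level) {
    i <- which(y >= level)[1]
    if (is.na(i)) return(NA_real_)
    if (i == 1) return(t[1])
    t[i - 1] + dt * (level - y[i - 1]) / (y[i] - y[i - 1])
  }
  t_GA <- cross(P_A, P_Ass / 2)
  t_re <- cross(m, m_ss / 2)
  if (is.na(t_re) || is.na(t_GA))
    stop("steady state not reached on the grid; extend the horizon")
  new("TransientCurves", t = t, P_A = P_A, m_mean = m, P_AP = P_AP,
      P_Ass = P_Ass, m_peak = m_peak, m_ss = m_ss, H_P = H_P, H_m = H_m,
      t_GA = t_GA, t_re = t_re, overshoot_P = H_P > overshoot_tol,
      overshoot_m = H_m > overshoot_tol, tau_A = tau_A, tau_P = tau_P,
      tau_m = tau_m)
}

#' Overshoot criterion from first-burst statistics
#'
#' The activation probability (mean count) must overshoot its steady state
#' when \eqn{h_P T > 1} (\eqn{h_m T > 1}), where
#' \deqn{h_x = \frac{\alpha_x}{\delta_x + \tau_{first}}
#'   \frac{(\alpha_x - 1)^{\alpha_x - 1}}{\Gamma(\alpha_x)} e^{-(\alpha_x - 1)}}
#' with \eqn{\alpha_P = 1/CV_{first}^2},
#' \eqn{\alpha_m = (\tau_m + \tau_{first})^2 /
#'      (\tau_m^2 + \tau_{first}^2 CV_{first}^2)},
#' \eqn{\delta_P = 0} and \eqn{\delta_m = \tau_m}.
#'
#' @param tau_first mean time to the end of the first burst (min).
#' @param cv_first its coefficient of variation.
#' @param T_period mean burst period (min).
#' @param tau_m mRNA lifetime (min).
#' @return list with \code{h_P}, \code{h_m} (1/min), \code{predict_P},
#'   \code{predict_m}. An \eqn{\alpha_x \le 1} yields no overshoot
#'   prediction (\code{h = 0}).
#' @examples
#' overshootCriterion(tau_first = 15, cv_first = sqrt(1/3),
#'                    T_period = 30, tau_m = 20)
#' @export
overshootCriterion <- function(tau_first, cv_first, T_period, tau_m) {
  stopifnot(tau_first > 0, cv_first > 0, T_period > 0, tau_m > 0)
  h_of <- function(alpha, delta) {
    if (alpha <= 1) return(0)
    alpha / (delta + tau_first) *
      exp((alpha - 1) * log(alpha - 1) - lgamma(alpha) - (alpha - 1))
  }
  a_P <- 1 / cv_first^2
  a_m <- (tau_m + tau_first)^2 / (tau_m^2 + tau_first^2 * cv_first^2)
  h_P <- h_of(a_P, 0)
  h_m <- h_of(a_m, tau_m)
  list(h_P = h_P, h_m = h_m, predict_P = h_P * T_period > 1,
       predict_m = h_m * T_period > 1)
}

#' Half-response times and kinetic regime of a transient
#'
#' @param curves a \linkS4class{TransientCurves}.
#' @param tau_m mRNA lifetime (min); defaults to the one in \code{curves}.
#' @return list with \code{t_GA}, \code{t_re} (min) and \code{regime}:
#'   \code{"production-limited"} when \eqn{t_{re} < \tau_m \ln 2} (burst
#'   correlation drives the rise faster than degradation equilibration),
#'   else \code{"degradation-limited"}.
#' @export
responseTimes <- function(curves, tau_m = curves@tau_m) {
  list(t_GA = curves@t_GA, t_re = curves@t_re,
       regime = if (curves@t_re < tau_m * log(2)) "production-limited"
                else "degradation-limited")
}

SCENARIO_ORDERINGS <- c(
  "MEE < MFI < MFA,MCC < MIE < MEA",
  "MEE < MFI < MIE < MFA,MCC < MEA",
  "MEE < MFI < MIE < MEA < MFA,MCC",
  "MEE < MFI < MEA < MIE < MFA,MCC")

#' Classify the transient-response scenario of a silent-cycle composition
#'
#' The ordering of half-response times across the six activating basic
#' modes falls into four scenarios determined by
#' \eqn{x = \tau_{S2}/\tau_{S1}}, \eqn{y = \tau_{S3}/\tau_{S1}} and
#' \eqn{p_2}: region 1 for \eqn{y < 1/(x+1)}, region 2 for
#' \eqn{1/(x+1) < y < 1}, region 3 for
#' \eqn{1 < y < [1 + \sqrt{1 + 4x(1-p_2)/p_2}]/2}, region 4 above.
#'
#' @param tau_S1,tau_S2,tau_S3 silent-event means (min, > 0).
#' @param p2 silent-repeat probability in (0, 1).
#' @return list with \code{region} (1-4, or \code{NA} exactly on a
#'   boundary), \code{x}, \code{y}, \code{p2}, \code{ordering} (the
#'   half-response-time ranking associated with the region's reference
#'   reference parameter set), and \code{boundary} (logical).
#' @export
classifyScenario <- function(tau_S1, tau_S2, tau_S3, p2) {
  stopifnot(tau_S1 > 0, tau_S2 > 0, tau_S3 > 0, p2 > 0, p2 < 1)
  x <- tau_S2 / tau_S1
  y <- tau_S3 / tau_S1
  b1 <- 1 / (x + 1)
  b3 <- (1 + sqrt(1 + 4 * x * (1 - p2) / p2)) / 2
  region <- if (y == b1 || y == 1 || y == b3) NA_integer_
            else if (y < b1) 1L
            else if (y < 1) 2L
            else if (y < b3) 3L
            else 4L
  list(region = region, x = x, y = y, p2 = p2,
       ordering = if (is.na(region)) NA_character_
                  else SCENARIO_ORDERINGS[region],
       boundary = is.na(region))
}

## distribution of the first activation time after stimulus onset, given
## that the named parameter was held at its fully silent value before the
## step; all silent events exponential.  Every phase distribution in the
## transient pipeline is represented by its first two moments (the Gamma
## moment-matching scheme), so the stationary-residual moments for the MIE
## initial state are likewise taken from the Gamma-matched silent cycle.
modeInitDistribution <- function(mode_name, params) {
  if (isDirectTauS(params) || length(params@durationModels))
    stop("mode initial conditions require an exponential component baseline")
  p1 <- params@p1; p2 <- params@p2
  t1 <- params@tau_S1; t2 <- params@tau_S2; t3 <- params@tau_S3
  cm <- cycle_moments(params)
  EC <- cm[["mean"]]; VC <- cm[["var"]]
  ## extra full cycles before the checkpoint finally passes
  EN0 <- (1 - p1) / p1
  VN0 <- (1 - p1) / p1^2
  g_mean <- p2 * t3 / (1 - p2)
  g_var <- p2 * (2 - p2) * t3^2 / (1 - p2)^2
  mv <- switch(mode_name,
    MEE = c(0, 0),
    MFI = c(t2 + EN0 * EC, t2^2 + EN0 * VC + VN0 * EC^2),
    MEA = {
      ## full inactive phase: geometric (success p1) number of cycles
      EN1 <- 1 / p1; VN1 <- (1 - p1) / p1^2
      c(EN1 * EC, EN1 * VC + VN1 * EC^2)
    },
    MCC = ,
    MFA = c(t3 + g_mean + t2 + EN0 * EC,
            t3^2 + g_var + t2^2 + EN0 * VC + VN0 * EC^2),
    MIE = {
      ## equilibrium residual of the interrupted cycle (moments of the
      ## Gamma-matched cycle), then extra cycles
      alpha <- EC^2 / VC; theta <- VC / EC
      rm_ <- (alpha + 1) * theta / 2
      rv <- (alpha + 1) * (alpha + 5) * theta^2 / 12
      c(rm_ + EN0 * EC, rv + EN0 * VC + VN0 * EC^2)
    },
    stop("unsupported mode for a silent initial condition: ", mode_name))
  if (mv[1] == 0) return(eventDuration("point", mean = 0))
  cv <- sqrt(mv[2]) / mv[1]
  eventDuration("gamma", mean = mv[1], cv = cv)
}

#' Compare transient responses across regulatory modes
#'
#' Activates the gene from the fully silent state to the common steady
#' state defined by \code{params} under each requested basic mode, using
#' the mode-specific first-activation distribution (the event at which the
#' silent parameter had blocked the cycle), and returns the
#' half-response-time table.
#'
#' @param params target (post-stimulus) \linkS4class{BurstParams} in
#'   component mode with exponential events.
#' @param modes basic modes to compare.
#' @param dt,horizon grid controls passed to \code{\link{transientCurves}}.
#' @param tie_tol half-response times closer than this fraction of the
#'   burst period are reported as tied.
#' @return data.frame (sorted by \code{t_re}) with columns \code{mode},
#'   \code{t_re}, \code{t_GA}, \code{m_ss}, \code{overshoot_P},
#'   \code{overshoot_m}, \code{group} (tie group index); the canonical
#'   ordering string is in \code{attr(, "ordering")}.
#' @export
compareModes <- function(params,
                         modes = c("MEE", "MFI", "MIE", "MEA", "MFA", "MCC"),
                         dt = NULL, horizon = NULL, tie_tol = 0.01) {
  dq <- deriveQuantities(params)
  im <- inactive_phase_moments(params)
  f_I <- eventDuration("gamma", mean = im[["mean"]],
                       cv = sqrt(im[["var"]]) / im[["mean"]])
  rows <- lapply(modes, function(nm) {
    g0 <- modeInitDistribution(nm, params)
    cv <- transientCurves(g0, f_I, tau_A = dq@tau_A, tau_P = params@tau_P,
                          tau_m = params@tau_m, dt = dt, horizon = horizon)
    data.frame(mode = nm, t_re = cv@t_re, t_GA = cv@t_GA, m_ss = cv@m_ss,
               overshoot_P = cv@overshoot_P, overshoot_m = cv@overshoot_m)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$t_re), ]
  thr <- tie_tol * dq@period
  group <- integer(nrow(out))
  g <- 1L
  group[1] <- g
  for (i in seq_len(nrow(out))[-1]) {
    if (out$t_re[i] - out$t_re[i - 1] > thr) g <- g + 1L
    group[i] <- g
  }
  out$group <- group
  rownames(out) <- NULL
  attr(out, "ordering") <- orderingString(out)
  out
}

#' @rdname compareModes
#' @param comparison a \code{compareModes} result.
#' @export
orderingString <- function(comparison) {
  parts <- vapply(split(comparison$mode, comparison$group), function(ms)
    paste(sort(ms), collapse = ","), character(1))
  paste(parts, collapse = " < ")
}
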