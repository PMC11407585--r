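#' Regulator occupancy
#'
#' Fraction of time the regulatory site is bound,
#' \eqn{O([R]) = [R]^{n_H} / ([R]^{n_H} + K_d^{n_H})}.
#'
#' @param R regulator concentration(s), >= 0 (arbitrary units).
#' @param K_d dissociation constant (> 0, same units).
#' @param n_H Hill coefficient (> 0).
#' @return occupancies in [0, 1].
#' @examples
#' occupancy(1, K_d = 1)            # 0.5
#' occupancy(0.5, K_d = 1, n_H = 2) # 0.2
#' @export
occupancy <- function(R, K_d, n_H = 1) {
  stopifnot(all(R >= 0), K_d > 0, n_H > 0)
  x <- (R / K_d)^n_H
  ifelse(is.infinite(x), 1, x / (1 + x))
}

#' Construct a regulatory mode
#'
#' Each basic mode targets one bursting parameter. Duration modes (MEE for
#' \code{tau_P}, MEA for \code{tau_S1}, MFI for \code{tau_S2}, MCC for
#' \code{tau_S3}, MTS for a direct composite \code{tau_S}) scale the event's
#' completion rate so that the bound-state mean duration is
#' \code{efficacy * unbound} with efficacy in (0, 1]. Checkpoint modes remap
#' a probability through its flow ratio \eqn{p = J^+/(J^+ + J^-)}: MIE
#' raises the forward flow of the productive checkpoint (bound
#' \code{p1B = efficacy * p1U}, efficacy >= 1), MIA lowers its backward
#' flow (same endpoint convention), MFC lowers the forward flow of the
#' silent-repeat checkpoint and MFA raises its backward flow (bound
#' \code{p2B = efficacy * p2U}, efficacy <= 1).
#'
#' @param basic_modes character vector of mode names.
#' @param efficacies numeric vector (recycled names from
#'   \code{basic_modes} if unnamed).
#' @param K_d dissociation constant (> 0).
#' @param n_H Hill coefficient (> 0).
#' @return a validated \linkS4class{RegulatoryMode}.
#' @examples
#' regulatoryMode("MEE", efficacies = 0.1, K_d = 1)
#' regulatoryMode(c("MIE", "MTS"), efficacies = c(MIE = 1.99, MTS = 0.02))
#' @export
regulatoryMode <- function(basic_modes, efficacies, K_d = 1, n_H = 1) {
  if (is.null(names(efficacies))) names(efficacies) <- basic_modes
  new("RegulatoryMode", basic_modes = basic_modes,
      efficacies = efficacies[basic_modes], K_d = as.numeric(K_d),
      n_H = as.numeric(n_H))
}

#' All combinations of the eight basic regulatory modes
#'
#' @return list of the 255 non-empty subsets of
#'   \code{c("MEE","MEA","MFI","MCC","MIE","MIA","MFC","MFA")}.
#' @export
modeCombinations <- function() {
  basic <- MODE_NAMES[MODE_NAMES != "MTS"]
  out <- list()
  for (k in seq_along(basic))
    out <- c(out, utils::combn(basic, k, simplify = FALSE))
  out
}

#' Do the given basic modes touch disjoint parameters?
#'
#' @param basic_modes character vector of mode names.
#' @return \code{TRUE} when no two modes target the same bursting
#'   parameter (the two \code{p1} flows conflict, as do the two \code{p2}
#'   flows and MTS with any silent-component mode).
#' @export
validModeCombination <- function(basic_modes) {
  if (!length(basic_modes) || !all(basic_modes %in% MODE_NAMES)) return(FALSE)
  pars <- MODE_PARAM[basic_modes]
  if (anyDuplicated(pars) > 0) return(FALSE)
  if ("MTS" %in% basic_modes &&
      any(c("MEA", "MFI", "MCC", "MFC", "MFA") %in% basic_modes))
    return(FALSE)
  TRUE
}

## flow-scale for endpoint p_B = eps * p_U reached by scaling one flow
## linearly in occupancy; "plus": forward flow scaled, "minus": backward.
flow_lambda <- function(p_U, eps, side) {
  p_B <- eps * p_U
  if (p_B >= 1) stop("efficacy drives the probability to 1 or beyond")
  if (side == "plus") eps * (1 - p_U) / (1 - p_B)
  else (1 - p_B) / (eps * (1 - p_U))
}

## mean duration at occupancy O under rate-linear interpolation
interp_duration <- function(tau_U, eps, O) {
  tau_U * eps / (eps + O * (1 - eps))
}

#' Apply a regulatory mode at a given occupancy
#'
#' Event completion rates and checkpoint flows are linear in the occupancy
#' \code{O}: a regulated duration becomes
#' \eqn{\tau(O) = [\,(1-O)/\tau_U + O/\tau_B\,]^{-1}} and a regulated flow
#' \eqn{J(O) = (1-O)J_U + O J_B}, with probabilities recovered as
#' \eqn{J^+/(J^+ + J^-)}. \code{O = 0} returns the baseline and \code{O = 1}
#' the bound-state endpoint exactly.
#'
#' @param mode a \linkS4class{RegulatoryMode}.
#' @param O occupancy in [0, 1] (scalar).
#' @param baseline unbound-state \linkS4class{BurstParams}.
#' @return the interpolated \linkS4class{BurstParams}.
#' @export
applyModes <- function(mode, O, baseline) {
  stopifnot(O >= 0, O <= 1)
  validObject(mode)
  p <- baseline
  direct <- isDirectTauS(baseline)
  for (nm in mode@basic_modes) {
    eps <- mode@efficacies[[nm]]
    tgt <- MODE_PARAM[[nm]]
    if (tgt %in% c("tau_P", "tau_S1", "tau_S2", "tau_S3", "tau_S")) {
      if (tgt == "tau_S" && !direct)
        stop("MTS requires a direct-tau_S baseline")
      if (tgt %in% c("tau_S1", "tau_S2", "tau_S3") && direct)
        stop(nm, " requires a component-mode baseline")
      slot(p, tgt) <- interp_duration(slot(baseline, tgt), eps, O)
    } else if (tgt == "p1") {
      J_U <- baseline@p1 / (1 - baseline@p1)
      lam <- flow_lambda(baseline@p1, eps, if (nm == "MIE") "plus" else "minus")
      if (nm == "MIE") {
        J <- J_U * ((1 - O) + O * lam)
        p@p1 <- J / (J + 1)
      } else {
        Jm <- (1 - O) + O * lam
        p@p1 <- J_U / (J_U + Jm)
      }
    } else {  # p2
      if (direct) stop(nm, " requires a component-mode baseline")
      J_U <- baseline@p2 / (1 - baseline@p2)
      lam <- flow_lambda(baseline@p2, eps, if (nm == "MFC") "plus" else "minus")
      if (nm == "MFC") {
        J <- J_U * ((1 - O) + O * lam)
        p@p2 <- J / (J + 1)
      } else {
        Jm <- (1 - O) + O * lam
        p@p2 <- J_U / (J_U + Jm)
      }
    }
  }
  validObject(p)
  p
}

#' Build a regulatory mode from explicit bound-state endpoints
#'
#' Convenience wrapper for parameter sets quoted as
#' unbound/bound pairs: each supplied endpoint is converted to the efficacy
#' of the corresponding basic mode (\code{tau_P} to MEE, \code{tau_S} to
#' MTS, \code{p1} to MIE, component taus to MEA/MFI/MCC, \code{p2} to MFA).
#'
#' @param baseline unbound \linkS4class{BurstParams}.
#' @param tau_PB,tau_S1B,tau_S2B,tau_S3B,tau_SB,p1B,p2B bound-state values
#'   (give only the regulated ones).
#' @param K_d,n_H occupancy parameters.
#' @return a \linkS4class{RegulatoryMode}.
#' @export
modeFromEndpoints <- function(baseline, tau_PB = NULL, tau_S1B = NULL,
                              tau_S2B = NULL, tau_S3B = NULL, tau_SB = NULL,
                              p1B = NULL, p2B = NULL, K_d = 1, n_H = 1) {
  bm <- character(); eff <- numeric()
  add <- function(bm0, e) {
    bm <<- c(bm, bm0); eff <<- c(eff, setNames(e, bm0))
  }
  if (!is.null(tau_PB)) add("MEE", tau_PB / baseline@tau_P)
  if (!is.null(tau_S1B)) add("MEA", tau_S1B / baseline@tau_S1)
  if (!is.null(tau_S2B)) add("MFI", tau_S2B / baseline@tau_S2)
  if (!is.null(tau_S3B)) add("MCC", tau_S3B / baseline@tau_S3)
  if (!is.null(tau_SB)) add("MTS", tau_SB / baseline@tau_S)
  if (!is.null(p1B)) add("MIE", p1B / baseline@p1)
  if (!is.null(p2B)) add("MFA", p2B / baseline@p2)
  regulatoryMode(bm, eff, K_d = K_d, n_H = n_H)
}

## mean transcription rate v(R) = <m>/tau_m under a mode
rate_at <- function(mode, baseline, R) {
  vapply(R, function(r)
    meanMrna(applyModes(mode, occupancy(r, mode@K_d, mode@n_H), baseline)) /
      baseline@tau_m, numeric(1))
}

#' Gene-regulatory function of a mode
#'
#' Characterises the steady-state mean transcription rate
#' \eqn{\upsilon([R]) \approx \upsilon_{max}(\beta^n + R^n)/(\Omega^n + R^n)}:
#' its extreme rates, half-response concentration \eqn{\Omega}, basal-offset
#' concentration \eqn{\beta}, fitted exponent \eqn{n}, fold change
#' \eqn{F_\upsilon} and sensitivity \eqn{K_d/\Omega}. For a single basic
#' mode with \code{n_H = 1} the rate is an exact first-order rational
#' function of \eqn{[R]} and the parameters are recovered exactly from
#' three evaluations; otherwise \eqn{\Omega} is located by root finding on
#' a log-concentration grid and \eqn{n} by least squares
#' (\code{\link{fitHillExponent}}).
#'
#' @param mode a \linkS4class{RegulatoryMode}.
#' @param baseline unbound \linkS4class{BurstParams}.
#' @return list with \code{v_min}, \code{v_max}, \code{beta}, \code{omega},
#'   \code{n}, \code{F_v}, \code{sensitivity}.
#' @export
regulatoryFunction <- function(mode, baseline) {
  v0 <- meanMrna(applyModes(mode, 0, baseline)) / baseline@tau_m
  v1 <- meanMrna(applyModes(mode, 1, baseline)) / baseline@tau_m
  exact <- length(mode@basic_modes) == 1L && abs(mode@n_H - 1) < 1e-12
  if (abs(v1 - v0) < 1e-14 * max(v0, v1)) {
    return(list(v_min = min(v0, v1), v_max = max(v0, v1), beta = mode@K_d,
                omega = mode@K_d, n = 1, F_v = 1, sensitivity = 1))
  }
  if (exact) {
    vK <- rate_at(mode, baseline, mode@K_d)
    omega <- mode@K_d * (v1 - vK) / (vK - v0)
    beta <- omega * v0 / v1
    n <- 1
  } else {
    Rg <- mode@K_d * 10^seq(-6, 6, length.out = 481)
    vg <- rate_at(mode, baseline, Rg)
    half <- (v0 + v1) / 2
    fcross <- function(r) rate_at(mode, baseline, r) - half
    sgn <- sign(vg - half)
    i <- which(diff(sgn) != 0)[1]
    if (is.na(i)) stop("half-response concentration not bracketed")
    omega <- uniroot(fcross, c(Rg[i], Rg[i + 1]), tol = 1e-12 * mode@K_d)$root
    n <- fitHillExponent(Rg, vg, v_min = min(v0, v1), v_max = max(v0, v1),
                         omega = omega)
    beta <- omega * (v0 / v1)^(1 / n)
  }
  list(v_min = min(v0, v1), v_max = max(v0, v1), beta = beta, omega = omega,
       n = n, F_v = v1 / v0, sensitivity = mode@K_d / omega)
}

#' Fit the effective Hill exponent of a regulatory function
#'
#' Least-squares fit of
#' \eqn{v(R) = (v_{min}\Omega^n + v_{max}R^n)/(\Omega^n + R^n)} in \eqn{n},
#' with the other parameters fixed.
#'
#' @param R_grid concentrations (> 0).
#' @param v_values rates at \code{R_grid}; must be monotone.
#' @param v_min,v_max limiting rates.
#' @param omega half-response concentration.
#' @return fitted exponent \code{n}.
#' @export
fitHillExponent <- function(R_grid, v_values, v_min, v_max, omega) {
  d <- diff(v_values)
  if (!(all(d >= -1e-12 * max(abs(v_values)))
        || all(d <= 1e-12 * max(abs(v_values)))))
    stop("fit failure: v_values are not monotone")
  sse <- function(n) {
    x <- (R_grid / omega)^n
    pred <- (v_min + v_max * x) / (1 + x)
    sum((pred - v_values)^2)
  }
  optimize(sse, c(0.05, 10), tol = 1e-10)$minimum
}

#' Specificity of cognate versus nontarget regulation
#'
#' \eqn{S([R])} is the ratio of the mean transcription rate driven through
#' the cognate site (dissociation constant \code{K_d}) to that driven
#' through a nontarget site with \code{nontarget_fold}-fold weaker binding.
#' For a nonzero basal rate, S is unimodal in \eqn{[R]}; its maximum
#' \eqn{S_m} approaches the fold change \eqn{F_\upsilon} as the affinity
#' separation grows.
#'
#' @param mode a \linkS4class{RegulatoryMode}.
#' @param baseline unbound \linkS4class{BurstParams}.
#' @param nontarget_fold affinity ratio of nontarget to cognate binding
#'   (> 1), 100 by default.
#' @param R_grid concentrations; defaults to a log grid spanning both
#'   dissociation constants.
#' @return list with \code{R_grid}, \code{S}, \code{S_m}, \code{R_at_Sm}.
#' @export
specificityCurve <- function(mode, baseline, nontarget_fold = 100,
                             R_grid = NULL) {
  stopifnot(nontarget_fold > 1)
  if (is.null(R_grid))
    R_grid <- mode@K_d * 10^seq(-4, log10(nontarget_fold) + 4,
                                length.out = 301)
  off_mode <- mode
  off_mode@K_d <- mode@K_d * nontarget_fold
  Sfun <- function(r)
    rate_at(mode, baseline, r) / rate_at(off_mode, baseline, r)
  S <- Sfun(R_grid)
  i <- which.max(S)
  lo <- R_grid[max(1, i - 1)]; hi <- R_grid[min(length(R_grid), i + 1)]
  opt <- optimize(function(lr) Sfun(exp(lr)), c(log(lo), log(hi)),
                  maximum = TRUE, tol = 1e-10)
  list(R_grid = R_grid, S = S, S_m = opt$objective, R_at_Sm = exp(opt$maximum))
}

## analytic derivatives of the regulated parameters with respect to O;
## p_now is the parameter set already interpolated to O
param_derivs <- function(mode, baseline, O, p_now) {
  out <- list(dtau_P = 0, dtau_S = 0, dp1 = 0)
  for (nm in mode@basic_modes) {
    eps <- mode@efficacies[[nm]]
    tgt <- MODE_PARAM[[nm]]
    if (tgt %in% c("tau_P", "tau_S")) {
      tau_U <- slot(baseline, tgt)
      dtau <- -tau_U * eps * (1 - eps) / (eps + O * (1 - eps))^2
      if (tgt == "tau_P") out$dtau_P <- dtau else out$dtau_S <- dtau
    } else if (tgt %in% c("tau_S1", "tau_S2", "tau_S3")) {
      tau_U <- slot(baseline, tgt)
      dtau <- -tau_U * eps * (1 - eps) / (eps + O * (1 - eps))^2
      w <- if (tgt == "tau_S3") p_now@p2 / (1 - p_now@p2) else 1
      out$dtau_S <- out$dtau_S + w * dtau
    } else if (tgt == "p1") {
      J_U <- baseline@p1 / (1 - baseline@p1)
      lam <- flow_lambda(baseline@p1, eps, if (nm == "MIE") "plus" else "minus")
      if (nm == "MIE") {
        J <- J_U * ((1 - O) + O * lam)
        out$dp1 <- J_U * (lam - 1) / (J + 1)^2
      } else {
        Jm <- (1 - O) + O * lam
        out$dp1 <- -J_U * (lam - 1) / (J_U + Jm)^2
      }
    } else if (tgt == "p2") {
      J_U <- baseline@p2 / (1 - baseline@p2)
      lam <- flow_lambda(baseline@p2, eps, if (nm == "MFC") "plus" else "minus")
      dp2 <- if (nm == "MFC") {
        J <- J_U * ((1 - O) + O * lam)
        J_U * (lam - 1) / (J + 1)^2
      } else {
        Jm <- (1 - O) + O * lam
        -J_U * (lam - 1) / (J_U + Jm)^2
      }
      ## tau_S depends on p2 through the silent-repeat weight
      out$dtau_S <- out$dtau_S +
        p_now@tau_S3 / (1 - p_now@p2)^2 * dp2
    }
  }
  out
}

#' Dose-response curves of mean, burst size and burst frequency
#'
#' Evaluates \eqn{\langle m\rangle}, \eqn{b = 1/(1-p_1)} and \eqn{f = 1/T}
#' along the regulator axis, locates the half-maximum operating points
#' \eqn{\Omega_m}, \eqn{\Omega_b}, \eqn{\Omega_f} (first upward crossing,
#' refined by root finding), and computes the logarithmic sensitivities
#' \eqn{S_b = d\ln b/d\ln\langle m\rangle} and
#' \eqn{S_f = d\ln f/d\ln\langle m\rangle} by the analytic chain rule
#' (\eqn{S_b + S_f = 1} identically since
#' \eqn{\langle m\rangle = b f \tau_m}).
#'
#' @param mode a \linkS4class{RegulatoryMode}.
#' @param baseline unbound \linkS4class{BurstParams}.
#' @param R_grid concentrations; defaults to a log grid around \code{K_d}.
#' @return list with a \code{curves} data.frame (\code{R}, \code{O},
#'   \code{tau_P}, \code{tau_S}, \code{p1}, \code{p2}, \code{m}, \code{b},
#'   \code{f}, \code{tau_A}, \code{tau_I}, \code{S_b}, \code{S_f}) and the
#'   operating points \code{omega_m}, \code{omega_b}, \code{omega_f}
#'   (\code{NA} when a curve is flat).
#' @export
doseResponse <- function(mode, baseline, R_grid = NULL) {
  if (is.null(R_grid))
    R_grid <- mode@K_d * 10^seq(-5, 5, length.out = 601)
  rows <- lapply(R_grid, function(r) {
    O <- occupancy(r, mode@K_d, mode@n_H)
    p <- applyModes(mode, O, baseline)
    dq <- deriveQuantities(p)
    dO <- mode@n_H * (r / mode@K_d)^(mode@n_H - 1) / mode@K_d /
      (1 + (r / mode@K_d)^mode@n_H)^2
    dv <- param_derivs(mode, baseline, O, p)
    p1 <- p@p1
    dlnb_dO <- dv$dp1 / (1 - p1)
    ## T = tau_P/(1-p1) + tau_S/p1
    dT_dO <- dv$dtau_P / (1 - p1) + p@tau_P * dv$dp1 / (1 - p1)^2 +
      dv$dtau_S / p1 - tauS(p) * dv$dp1 / p1^2
    dlnf_dO <- -dT_dO / dq@period
    dlnm_dO <- dlnb_dO + dlnf_dO
    Sb <- if (abs(dlnm_dO) > 0) dlnb_dO / dlnm_dO else NA_real_
    data.frame(R = r, O = O, tau_P = p@tau_P, tau_S = tauS(p), p1 = p1,
               p2 = p@p2, m = dq@m_mean, b = dq@b, f = dq@f,
               tau_A = dq@tau_A, tau_I = dq@tau_I, S_b = Sb,
               S_f = if (is.na(Sb)) NA_real_ else 1 - Sb,
               dO_dR = dO)
  })
  curves <- do.call(rbind, rows)
  half_point <- function(y) {
    ymax <- max(y)
    if (ymax <= 0 || diff(range(y)) < 1e-12 * ymax) return(NA_real_)
    half <- ymax / 2
    i <- which(y[-1] >= half & y[-length(y)] < half)[1]
    if (is.na(i)) return(NA_real_)
    ## linear interpolation in log R
    lr <- log(curves$R[i]) + (half - y[i]) / (y[i + 1] - y[i]) *
      (log(curves$R[i + 1]) - log(curves$R[i]))
    exp(lr)
  }
  list(curves = curves,
       omega_m = half_point(curves$m),
       omega_b = half_point(curves$b),
       omega_f = half_point(curves$f))
}
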