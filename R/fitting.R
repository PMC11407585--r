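#' Mean-Fano curve of a regulatory mode
#'
#' Traces the steady-state \eqn{(\langle m\rangle, F)} curve as the
#' occupancy runs from 0 to 1 under a regulatory mode.
#'
#' @param mode a \linkS4class{RegulatoryMode}.
#' @param baseline unbound \linkS4class{BurstParams}.
#' @param O_grid increasing occupancies in [0, 1].
#' @return data.frame with columns \code{O}, \code{m_mean}, \code{fano}.
#' @export
mfCurve <- function(mode, baseline, O_grid = seq(0, 1, length.out = 201)) {
  stopifnot(all(O_grid >= 0 & O_grid <= 1))
  rows <- vapply(O_grid, function(O) {
    p <- applyModes(mode, O, baseline)
    c(meanMrna(p), fanoFactor(p))
  }, numeric(2))
  data.frame(O = O_grid, m_mean = rows[1, ], fano = rows[2, ])
}

#' Generate a synthetic mean-Fano dataset
#'
#' Samples regulator concentrations log-uniformly over six decades around
#' \eqn{K_d} (the way dose-response curves are traversed experimentally),
#' converts them to occupancies, evaluates the analytic
#' \eqn{(\langle m\rangle, F)} pairs under the given mode, and applies
#' multiplicative log-normal noise with coefficient of variation
#' \code{noise_cv} (unit mean) to both coordinates independently.
#'
#' @param mode a \linkS4class{RegulatoryMode}.
#' @param baseline unbound \linkS4class{BurstParams}.
#' @param n_points number of records.
#' @param noise_cv multiplicative noise CV (>= 0).
#' @param seed integer seed.
#' @return data.frame with columns \code{m_mean}, \code{fano} and
#'   attribute \code{provenance = "synthetic"}.
#' @export
synthMFDataset <- function(mode, baseline, n_points, noise_cv = 0, seed = 1) {
  stopifnot(noise_cv >= 0, n_points >= 1)
  set.seed(seed)
  R <- mode@K_d * 10^runif(n_points, -5, 5)
  O <- sort(occupancy(R, mode@K_d, mode@n_H))
  mf <- mfCurve(mode, baseline, O_grid = O)
  m <- mf$m_mean; f <- mf$fano
  if (noise_cv > 0) {
    s <- sqrt(log(1 + noise_cv^2))
    m <- m * rlnorm(n_points, -s^2 / 2, s)
    f <- f * rlnorm(n_points, -s^2 / 2, s)
  }
  out <- data.frame(m_mean = m, fano = f)
  attr(out, "provenance") <- "synthetic"
  out
}

## parameter vector <-> unconstrained coordinates
.fit_names <- function(regulated) {
  nm <- character()
  if ("tau_P" %in% regulated) nm <- c(nm, "tau_PU", "tau_PB")
  if ("p1" %in% regulated) nm <- c(nm, "p1U", "p1B")
  if ("tau_S" %in% regulated) nm <- c(nm, "tau_SU", "tau_SB")
  nm
}

.to_unconstrained <- function(par) {
  x <- par
  for (nm in names(par))
    x[nm] <- if (grepl("^p1", nm)) stats::qlogis(par[nm]) else log(par[nm])
  x
}

.from_unconstrained <- function(x) {
  par <- x
  for (nm in names(x))
    par[nm] <- if (grepl("^p1", nm)) stats::plogis(x[nm]) else exp(x[nm])
  par
}

## fast vectorised (m, F) curve for the direct-tau_S parameterisation used
## by the fitter: rate-linear duration interpolation, flow-linear p1
.curve_of <- function(par, regulated, fixed, O_grid) {
  g <- function(nm, def) if (nm %in% names(par)) par[[nm]] else def
  tau_PU <- g("tau_PU", fixed$tau_P)
  p1U <- g("p1U", fixed$p1)
  tau_SU <- g("tau_SU", fixed$tau_S)
  tau_m <- fixed$tau_m
  O <- O_grid
  tau_P <- if ("tau_P" %in% regulated) {
    eps <- par[["tau_PB"]] / tau_PU
    if (eps > 1 || eps <= 0) return(NULL)
    interp_duration(tau_PU, eps, O)
  } else rep(tau_PU, length(O))
  tau_S <- if ("tau_S" %in% regulated) {
    eps <- par[["tau_SB"]] / tau_SU
    if (eps > 1 || eps <= 0) return(NULL)
    interp_duration(tau_SU, eps, O)
  } else rep(tau_SU, length(O))
  p1 <- if ("p1" %in% regulated) {
    eps <- par[["p1B"]] / p1U
    if (eps < 1 || eps * p1U >= 1) return(NULL)
    J_U <- p1U / (1 - p1U)
    lam <- flow_lambda(p1U, eps, "plus")
    J <- J_U * ((1 - O) + O * lam)
    J / (J + 1)
  } else rep(p1U, length(O))
  m <- tau_m / (tau_P + (1 - p1) / p1 * tau_S)
  b <- 1 / (1 - p1)
  cc <- tau_P / ((1 - p1) * tau_m)
  d <- tau_S / (p1 * tau_m)
  data.frame(O = O, m_mean = m, fano = fano_bcd(b, cc, d))
}

## summed squared orthogonal distance from (log m, log F) data to the
## piecewise-linear curve (projection onto each segment, then the minimum)
.mf_loss <- function(par, regulated, fixed, data, O_grid, weights) {
  mf <- .curve_of(par, regulated, fixed, O_grid)
  if (is.null(mf)) return(1e10)
  cx <- log(mf$m_mean); cy <- log(mf$fano)
  if (any(!is.finite(cx)) || any(!is.finite(cy))) return(1e10)
  n <- length(cx)
  ax <- cx[-n]; ay <- cy[-n]
  ex <- diff(cx); ey <- diff(cy)
  len2 <- pmax(ex * ex + ey * ey, 1e-300)
  px <- log(data$m_mean); py <- log(data$fano)
  tot <- 0
  for (i in seq_along(px)) {
    tt <- pmin(pmax(((px[i] - ax) * ex + (py[i] - ay) * ey) / len2, 0), 1)
    dxx <- ax + tt * ex - px[i]
    dyy <- ay + tt * ey - py[i]
    tot <- tot + weights[i] * min(dxx * dxx + dyy * dyy)
  }
  ## anchor the trajectory ends to the data cloud: without this, any curve
  ## containing the data's arc as a subset has zero set distance and the
  ## endpoint parameters are unidentifiable
  w_end <- mean(weights)
  for (j in c(1L, n)) {
    tot <- tot + w_end * min((cx[j] - px)^2 + (cy[j] - py)^2)
  }
  tot
}

#' Fit event-model parameter trajectories to mean-Fano data
#'
#' Finds the regulated-parameter trajectory whose
#' \eqn{(\langle m\rangle, F)} curve passes closest (summed squared
#' distances in log-log space, nearest curve point per datum) to the data.
#' Optimisation uses the Nelder-Mead simplex in unconstrained coordinates
#' (log durations, logit probabilities) with seeded multi-starts.
#'
#' @param data data.frame with columns \code{m_mean}, \code{fano} and an
#'   optional \code{weight}.
#' @param regulated subset of \code{c("tau_P", "p1", "tau_S")}: which
#'   parameters the regulator moves between unbound (\code{U}) and bound
#'   (\code{B}) values; each contributes its \code{U} and \code{B} value to
#'   the fit.
#' @param fixed named list of the non-regulated parameter values; must
#'   contain \code{tau_m} and any of \code{tau_P}, \code{p1}, \code{tau_S}
#'   not being fitted.
#' @param start optional named starting vector.
#' @param n_restarts number of jittered multi-starts.
#' @param seed integer seed for start jitter.
#' @param O_grid occupancy grid used to discretise the curve.
#' @return list with \code{par} (fitted values), \code{loss},
#'   \code{converged}, \code{n_restarts}, \code{regulated}, \code{fixed}.
#' @export
fitMFData <- function(data, regulated, fixed, start = NULL, n_restarts = 10,
                      seed = 1,
                      O_grid = c(0, occupancy(10^seq(-4, 4, length.out = 299),
                                              K_d = 1), 1)) {
  stopifnot(all(c("m_mean", "fano") %in% names(data)),
            all(data$m_mean > 0), all(data$fano > 0),
            all(regulated %in% c("tau_P", "p1", "tau_S")),
            "tau_m" %in% names(fixed))
  nms <- .fit_names(regulated)
  if (length(nms) == 0) stop("nothing to fit")
  if (nrow(data) < length(nms) - 1)
    stop("too few data points for a ", length(nms), "-parameter fit")
  weights <- if ("weight" %in% names(data)) data$weight else rep(1, nrow(data))

  if (is.null(start)) {
    m_lo <- min(data$m_mean); m_hi <- max(data$m_mean)
    tau_m <- fixed$tau_m
    p1U0 <- if ("p1" %in% names(fixed)) fixed$p1 else 0.5
    tau_P0 <- if ("tau_P" %in% names(fixed)) fixed$tau_P
              else 0.5 * tau_m / m_hi
    tau_SU0 <- max(p1U0 / (1 - p1U0) * (tau_m / m_lo - tau_P0), 1e-3)
    start <- c(tau_PU = tau_P0, tau_PB = 0.2 * tau_P0,
               p1U = p1U0, p1B = 0.99,
               tau_SU = tau_SU0, tau_SB = 0.05 * tau_SU0)[nms]
  } else start <- start[nms]

  set.seed(seed)
  x0 <- .to_unconstrained(start)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    xs <- if (r == 1) x0 else x0 + rnorm(length(x0), 0, 0.8)
    fit <- try(optim(xs, function(x)
      .mf_loss(.from_unconstrained(setNames(x, nms)), regulated, fixed,
               data, O_grid, weights),
      method = "Nelder-Mead",
      control = list(maxit = 4000, reltol = 1e-14)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimisation starts failed")
  ## polish from the best point
  for (k in 1:2) {
    pol <- optim(best$par, function(x)
      .mf_loss(.from_unconstrained(setNames(x, nms)), regulated, fixed,
               data, O_grid, weights),
      method = "Nelder-Mead", control = list(maxit = 4000, reltol = 1e-15))
    if (pol$value < best$value) best <- pol
  }
  par <- .from_unconstrained(setNames(best$par, nms))
  list(par = par, loss = best$value,
       converged = best$convergence == 0 || best$value < 1e-10,
       n_restarts = n_restarts, regulated = regulated, fixed = fixed)
}

#' Read and write mean-Fano datasets as TSV
#'
#' @param path file path.
#' @return \code{readMFData}: data.frame with \code{m_mean}, \code{fano}
#'   (and \code{weight} when present).
#' @export
readMFData <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  stopifnot(all(c("m_mean", "fano") %in% names(d)))
  d
}

#' @rdname readMFData
#' @param data data.frame with \code{m_mean} and \code{fano}.
#' @export
writeMFData <- function(data, path) {
  write.table(data, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
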