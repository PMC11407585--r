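test_that("the two closed-form noise representations agree", {
  ## tau-expression variance and (b, c, d) Fano forms are algebraically
  ## identical; checked across random parameter sets
  for (p in c(random_direct_params(40, 31), random_component_params(40, 32))) {
    m <- meanMrna(p)
    dq <- deriveQuantities(p)
    tauS_r <- dq@tau_S / p@tau_m
    cA <- dq@c; dI <- dq@d
    var_tau <- m + m^2 * ((dI + cA) * tauS_r - cA * dI) /
      (dI + cA + cA * dI)
    vf <- varianceFano(p)
    expect_equal(vf[["variance"]], var_tau, tolerance = 1e-10)
  }
})

test_that("renewal-exact and closed-form Fano coincide for direct cycles", {
  for (p in random_direct_params(20, 33)) {
    expect_equal(fanoFactor(p, "closed"), fanoFactor(p, "renewal"),
                 tolerance = 1e-10)
  }
})

test_that("closed-form moments match ensemble simulation", {
  for (p in random_direct_params(6, 34)) {
    em <- ensembleMoments(p, n_traj = 3000, t_grid = steady_grid(p, 1),
                          seed = 35)
    vf <- varianceFano(p)
    expect_lt(abs(em$mean[1] - meanMrna(p)), 3 * em$se_mean[1])
    expect_lt(abs(em$var[1] - vf[["variance"]]), 3 * em$se_var[1])
    expect_lt(abs(em$fano[1] - vf[["fano"]]), 3 * em$se_fano[1])
  }
  ## component-mode cycles: the renewal-exact Fano is the reference
  for (p in random_component_params(3, 36)) {
    em <- ensembleMoments(p, n_traj = 3000, t_grid = steady_grid(p, 1),
                          seed = 37)
    expect_lt(abs(em$fano[1] - fanoFactor(p, "renewal")),
              3 * em$se_fano[1])
  }
})

test_that("noise limits behave as expected", {
  ## tau_S -> 0: Poisson
  p <- burstParams(tau_P = 0.5, p1 = 0.8, tau_S = 1e-8, tau_m = 5)
  expect_equal(fanoFactor(p), 1, tolerance = 1e-6)
  ## tau_P -> 0 at fixed burst size with exponential silent phase: F -> b,
  ## cross-checked against a truncated master equation for geometric bursts
  p1 <- 0.9
  pp <- burstParams(tau_P = 1e-7, p1 = p1, tau_S = 20, tau_m = 5)
  b <- 1 / (1 - p1)
  expect_equal(fanoFactor(pp), b, tolerance = 1e-4)
  me <- compound_poisson_master_moments(rate = p1 / 20, p1 = p1, tau_m = 5,
                                        N = 250)
  expect_equal(fanoFactor(pp), unname(me["fano"]), tolerance = 1e-3)
  expect_equal(meanMrna(pp), unname(me["mean"]), tolerance = 1e-3)
})

test_that("expression and noise respect the fixed-tau_P upper bounds", {
  bounds <- expressionBounds(0.165, 5)
  expect_equal(unname(bounds["m_max"]), 5 / 0.165)
  expect_equal(unname(bounds["F_max"]), 1 + 5 / 0.165)
  expect_equal(unname(expressionBounds(5, 5)), c(1, 2))
  set.seed(38)
  for (i in 1:300) {
    p <- burstParams(tau_P = 0.165, p1 = runif(1, 0.01, 0.999),
                     tau_S = exp(runif(1, log(0.01), log(1000))), tau_m = 5)
    expect_lt(meanMrna(p), bounds[["m_max"]])
    expect_lt(fanoFactor(p), bounds[["F_max"]])
  }
})

test_that("the Fano slope matches numerical differentiation on the tau_S path", {
  for (ts in exp(seq(log(5), log(400), length.out = 20))) {
    p <- burstParams(tau_P = 0.165, p1 = 0.95, tau_S = ts, tau_m = 5)
    h <- ts * 1e-5
    up <- burstParams(tau_P = 0.165, p1 = 0.95, tau_S = ts + h, tau_m = 5)
    dn <- burstParams(tau_P = 0.165, p1 = 0.95, tau_S = ts - h, tau_m = 5)
    fd <- (fanoFactor(up) - fanoFactor(dn)) / (meanMrna(up) - meanMrna(dn))
    expect_equal(fanoSlope(p), fd, tolerance = 1e-4)
  }
  ## noise falls with rising mean along the tau_S path at high expression
  expect_lt(fanoSlope(burstParams(tau_P = 0.165, p1 = 0.95, tau_S = 5,
                                  tau_m = 5)), 0)
})

test_that("burst height follows its piecewise form and the simulated profile", {
  expect_equal(burstHeight(burstParams(tau_P = 6, p1 = 0.5, tau_S = 10,
                                       tau_m = 5)), 1)
  ## long phases: height saturates at tau_m / tau_P
  ph <- burstParams(tau_P = 0.5, p1 = 0.999, tau_S = 5000, tau_m = 5)
  expect_equal(burstHeight(ph), 5 / 0.5, tolerance = 1e-3)
  ## reference parameters: height matches the mean per-burst peak count
  p <- ref_params()
  tr <- simulateTrajectory(p, t_end = 3e5, seed = 41)
  ev <- tr@events
  runs <- rle(ev$event_kind == "E_P")
  ends <- cumsum(runs$lengths)
  peaks <- numeric(0)
  for (i in which(runs$values)) {
    lo <- ev$start[ends[i] - runs$lengths[i] + 1]
    hi <- ev$start[ends[i]] + ev$duration[ends[i]]
    tt <- seq(lo, hi, length.out = max(3, ceiling((hi - lo) / 0.1)))
    peaks <- c(peaks, max(mrnaCount(tr, tt)))
  }
  expect_lt(abs(mean(peaks) - burstHeight(p)) / burstHeight(p), 0.15)
})

test_that("the Fano lower bound matches constrained minimisation", {
  tau_S0 <- 1; p10 <- 0.995; tau_m <- 5
  for (m in c(5, 10, 30, 100, 300)) {
    fb <- fanoLowerBound(m, tau_S0, p10, tau_m)
    grid <- expand.grid(p1 = seq(0.4, p10, length.out = 50),
                        ts = exp(seq(log(tau_S0), log(500), length.out = 50)))
    fs <- apply(grid, 1, function(r) {
      tp <- tau_m / m - (1 - r[1]) / r[1] * r[2]
      if (tp <= 0) return(NA_real_)
      fanoFactor(burstParams(tau_P = tp, p1 = r[1], tau_S = r[2],
                             tau_m = tau_m))
    })
    expect_lt(abs(fb - min(fs, na.rm = TRUE)) / fb, 0.01)
    expect_gt(fb, 1)
  }
  ## non-decreasing in the mean over the high-expression regime
  ms <- seq(10, 900, length.out = 30)
  fmin <- vapply(ms, fanoLowerBound, numeric(1), tau_S0 = tau_S0, p10 = p10,
                 tau_m = tau_m)
  expect_true(all(diff(fmin) > -1e-9))
  expect_error(fanoLowerBound(1e6, tau_S0, p10, tau_m), "infeasible")
})

test_that("the constraint scan shows a rising noise floor only for the event model", {
  sc <- constraintScan(4000, refractory = 1, seed = 43)
  ev <- fanoEnvelope(sc[sc$model == "event", ])
  tg <- fanoEnvelope(sc[sc$model == "telegraph", ])
  expect_gt(ev[["high"]], 2 * ev[["low"]])
  expect_lt(tg[["high"]], 2 * tg[["low"]])
  ## longer refractory raises the floor at matched expression bins
  sc10 <- constraintScan(4000, refractory = 10, seed = 43)
  ev10 <- fanoEnvelope(sc10[sc10$model == "event", ])
  expect_gt(ev10[["high"]], ev[["high"]])
  ## matched comparator remains available
  scm <- constraintScan(500, refractory = 1, seed = 44,
                        telegraph = "matched")
  expect_equal(scm$tau_A[scm$model == "event"],
               scm$tau_A[scm$model == "telegraph"])
})
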