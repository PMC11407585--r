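test_that("gamma moment matching reproduces the worked first-burst examples", {
  ## a Gamma(shape 3, scale 5) first burst has mean 15 and squared CV 1/3
  p <- burstParams(tau_P = 1, p1 = 0.9, tau_S = 18, tau_m = 10)
  ## choose f_I_init so that the first burst is exactly Gamma(3, 5):
  ## mean_init = 15 - tau_A, var_init = 75 - tau_A^2 with tau_A = 10 is
  ## infeasible, so check the moment algebra directly instead
  gm <- gammaMatch(p, "first",
                   f_I_init = eventDuration("gamma", mean = 5, cv = 1))
  expect_equal(gm$tau_first, 5 + 10)
  expect_equal(gm$var, 25 + 100)
  ## Gamma(5, 6) has squared CV 1/5; Gamma(3, 5) has 1/3
  g35 <- eventDuration("gamma", mean = 15, cv = sqrt(1 / 3))
  expect_equal(g35@cv^2, 1 / 3)
  expect_equal(1 / (1 / g35@cv^2), 1 / 3)   # shape 3
  g56 <- eventDuration("gamma", mean = 30, cv = sqrt(1 / 5))
  expect_equal(g56@cv^2, 1 / 5)

  ## exponential direct cycle: the inactive phase is exponential, shape 1
  pd <- gammaMatch(burstParams(tau_P = 1, p1 = 0.4, tau_S = 12, tau_m = 5),
                   "inactive")
  expect_equal(pd$shape, 1, tolerance = 1e-12)
  expect_equal(pd$mean, 12 / 0.4)

  ## component cycles: matched moments agree with simulation
  pc <- burstParams(tau_P = 0.5, p1 = 0.6, tau_S1 = 3, tau_S2 = 5,
                    tau_S3 = 4, p2 = 0.5, tau_m = 5)
  pd2 <- gammaMatch(pc, "inactive")
  tr <- simulateTrajectory(pc, t_end = 3e5, seed = 51)
  bs <- burstStatistics(tr)
  n <- bs@n_bursts
  expect_lt(abs(mean(bs@inactive_durations) - pd2$mean),
            3 * sd(bs@inactive_durations) / sqrt(n))
  ## variance within 3 SE (SE of a variance ~ var * sqrt(2/n) for
  ## moderately heavy tails; use 4x margin for the exponential-mix tail)
  expect_lt(abs(var(bs@inactive_durations) - pd2$var),
            4 * pd2$var * sqrt(2 / n))
})

test_that("transient curves satisfy limits and match renewal simulation", {
  g0 <- eventDuration("gamma", mean = 15, cv = sqrt(1 / 3))
  fI <- eventDuration("gamma", mean = 20, cv = sqrt(1 / 2))
  cv <- transientCurves(g0, fI, tau_A = 10, tau_P = 1, tau_m = 20)
  expect_equal(cv@P_A[1], 0)            # silent start
  expect_equal(cv@m_mean[1], 0)
  expect_equal(cv@P_Ass, 10 / 30)
  expect_equal(cv@m_ss, 10 * 20 / 30)
  ## long-time limit reached on the grid
  expect_equal(cv@P_A[length(cv@t)], cv@P_Ass, tolerance = 0.01)
  ## grid refinement changes the curve by less than 1%
  cv2 <- transientCurves(g0, fI, tau_A = 10, tau_P = 1, tau_m = 20,
                         dt = (cv@t[2] - cv@t[1]) / 2)
  on2 <- approx(cv2@t, cv2@P_A, cv@t)$y
  expect_lt(max(abs(on2 - cv@P_A), na.rm = TRUE), 0.01 * cv@P_Ass + 1e-4)
  ## Monte Carlo cross-validation of both curves
  tg <- seq(2, 250, by = 4)
  sim <- simulatePhaseRenewal(g0, fI, tau_A = 10, tau_P = 1, tau_m = 20,
                              t_grid = tg, n_traj = 20000, seed = 53)
  aP <- approx(cv@t, cv@P_A, tg)$y
  am <- approx(cv@t, cv@m_mean, tg)$y
  zP <- abs(sim$P_A - aP) / pmax(sim$se_P_A, 1e-4)
  zm <- abs(sim$mean - am) / pmax(sim$se_mean, 1e-4)
  expect_lt(mean(zP > 3), 0.05)
  expect_lt(mean(zm > 3), 0.05)
  expect_lt(max(zP), 5)
  expect_lt(max(zm), 5)
})

test_that("random phase configurations match renewal simulation", {
  set.seed(57)
  for (i in 1:6) {
    tau_A <- runif(1, 2, 12)
    g0 <- eventDuration("gamma", mean = runif(1, 3, 30),
                        cv = runif(1, 0.4, 1))
    fI <- eventDuration("gamma", mean = runif(1, 5, 40),
                        cv = runif(1, 0.5, 1.1))
    tau_m <- runif(1, 3, 15)
    cv <- transientCurves(g0, fI, tau_A = tau_A, tau_P = 1, tau_m = tau_m)
    tg <- seq(1, 0.8 * max(cv@t), length.out = 40)
    sim <- simulatePhaseRenewal(g0, fI, tau_A = tau_A, tau_P = 1,
                                tau_m = tau_m, t_grid = tg, n_traj = 4000,
                                seed = 570 + i)
    aP <- approx(cv@t, cv@P_A, tg)$y
    zP <- abs(sim$P_A - aP) / pmax(sim$se_P_A, 2e-3)
    expect_lt(mean(zP > 3), 0.1)
  }
})

test_that("the overshoot criterion evaluates its closed form", {
  oc <- overshootCriterion(tau_first = 15, cv_first = sqrt(1 / 3),
                           T_period = 30, tau_m = 20)
  ## alpha_P = 3: h_P = (3/15) (2^2/Gamma(3)) e^-2
  expect_equal(oc$h_P, 0.2 * 2 * exp(-2), tolerance = 1e-12)
  expect_equal(oc$h_P * 30, 1.624, tolerance = 1e-3)
  expect_true(oc$predict_P)
  expect_false(oc$predict_m)
  ## vanishing mRNA lifetime: the count criterion collapses onto the
  ## activation criterion
  oc0 <- overshootCriterion(15, sqrt(1 / 3), 30, tau_m = 1e-9)
  expect_equal(oc0$h_m, oc0$h_P, tolerance = 1e-6)
  ## wide first bursts never trigger the formula
  expect_equal(overshootCriterion(15, 1.2, 30, 5)$h_P, 0)
})

test_that("overshoot predictions agree with evaluated curves off-boundary", {
  fI <- eventDuration("gamma", mean = 20, cv = sqrt(1 / 2))
  tau_A <- 10; Tp <- 30; tau_m <- 20
  nP <- 0; okP <- 0; nm <- 0; okm <- 0; suff <- 0
  for (r in seq(0.35, 1.5, length.out = 10)) {
    for (cvf in seq(0.3, 0.95, length.out = 10)) {
      tf <- r * Tp
      oc <- overshootCriterion(tf, cvf, Tp, tau_m)
      ff <- eventDuration("gamma", mean = tf, cv = cvf)
      tc <- transientCurves(ff, fI, tau_A = tau_A, tau_P = 1, tau_m = tau_m,
                            g0_type = "first-burst-end")
      if (abs(oc$h_P * Tp - 1) > 0.1) {
        nP <- nP + 1
        okP <- okP + (tc@overshoot_P == oc$predict_P)
        if (oc$predict_P && !tc@overshoot_P) suff <- suff + 1
      }
      if (abs(oc$h_m * Tp - 1) > 0.1) {
        nm <- nm + 1
        okm <- okm + (tc@overshoot_m == oc$predict_m)
        if (oc$predict_m && !tc@overshoot_m) suff <- suff + 1
      }
    }
  }
  expect_gte(okP / nP, 0.9)
  expect_gte(okm / nm, 0.9)
  ## the threshold is a sufficient condition: no predicted overshoot is
  ## ever absent from the evaluated curve
  expect_identical(suff, 0)
})

test_that("response times separate the two kinetic regimes", {
  ## poised gene: activation immediate, the rise is degradation-limited
  g0 <- eventDuration("point", mean = 0)
  fI <- eventDuration("gamma", mean = 0.05, cv = 1)
  cv <- transientCurves(g0, fI, tau_A = 10, tau_P = 0.2, tau_m = 5)
  rt <- responseTimes(cv)
  expect_equal(rt$t_re, 5 * log(2), tolerance = 0.03)
  ## overshooting first-burst set: correlated bursts beat degradation
  ff <- eventDuration("gamma", mean = 15, cv = sqrt(1 / 3))
  fI2 <- eventDuration("gamma", mean = 20, cv = sqrt(1 / 2))
  cv2 <- transientCurves(ff, fI2, tau_A = 10, tau_P = 1, tau_m = 20,
                         g0_type = "first-burst-end")
  rt2 <- responseTimes(cv2)
  expect_lt(rt2$t_re, 20 * log(2))
  expect_identical(rt2$regime, "production-limited")
  ## half-activation time is the first crossing of half the plateau
  i <- which(cv2@P_A >= cv2@P_Ass / 2)[1]
  expect_lte(cv2@t_GA, cv2@t[i])
  expect_gte(cv2@t_GA, cv2@t[i - 1])
})

test_that("silent-cycle compositions are classified into four regions", {
  ## reference parameter sets
  s1 <- classifyScenario(15, 2, 4, 0.5)
  expect_equal(s1$region, 1L)
  expect_equal(s1$ordering, "MEE < MFI < MFA,MCC < MIE < MEA")
  expect_equal(classifyScenario(10, 20, 6, 0.5)$region, 2L)
  s3 <- classifyScenario(5, 20, 8, 0.5)
  expect_equal(s3$region, 3L)
  expect_equal(s3$x, 4); expect_equal(s3$y, 1.6)
  ## region-3 upper bound at x = 4, p2 = 0.5 is (1 + sqrt(17))/2
  expect_equal(classifyScenario(5, 20, 5 * (1 + sqrt(17)) / 2 * 1.01,
                                0.5)$region, 4L)
  b3 <- 5 * (1 + sqrt(17)) / 2
  expect_true(classifyScenario(5, 20, b3, 0.5)$boundary)
  expect_equal(classifyScenario(3, 10, 15, 0.5)$region, 4L)
})

test_that("mode comparison reproduces the four response orderings", {
  sets <- list(c(15, 2, 4), c(10, 20, 6), c(3, 10, 15), c(5, 20, 8))
  ords <- character()
  for (s in sets) {
    p <- burstParams(tau_P = 1, p1 = 0.9, tau_m = 10, tau_S1 = s[1],
                     tau_S2 = s[2], tau_S3 = s[3], p2 = 0.5)
    cm <- compareModes(p)
    ords <- c(ords, attr(cm, "ordering"))
    ## the poised productive event responds first, PIC assembly second
    expect_identical(cm$mode[1], "MEE")
    expect_identical(cm$mode[2], "MFI")
    ## nucleosome-delay and silent-repeat-flow modes share an initial
    ## condition, hence a rank
    gM <- cm$group[match(c("MCC", "MFA"), cm$mode)]
    expect_identical(gM[1], gM[2])
  }
  expect_length(unique(ords), 4L)
})

test_that("regulating the productive event accelerates matched responses", {
  ## two routes to the same steady state from silence; the one that also
  ## shortens the productive event (poised initial state) responds faster
  tau_m <- 5
  pA <- burstParams(tau_P = 1, p1 = 0.95, tau_S = 10, tau_m = tau_m)
  m_target <- meanMrna(pA)
  ## combined route: productive event 10x faster, silent cycle adjusted to
  ## reach the same mean
  tau_PB <- 0.1
  tau_SB <- (tau_m / m_target - tau_PB) * 0.95 / 0.05
  pB <- burstParams(tau_P = tau_PB, p1 = 0.95, tau_S = tau_SB, tau_m = tau_m)
  expect_equal(meanMrna(pB), m_target, tolerance = 1e-12)
  imA <- gammaMatch(pA, "inactive"); imB <- gammaMatch(pB, "inactive")
  fIA <- eventDuration("gamma", mean = imA$mean, cv = sqrt(imA$var) / imA$mean)
  fIB <- eventDuration("gamma", mean = imB$mean, cv = sqrt(imB$var) / imB$mean)
  ## non-productive route: gene starts at the head of an inactive phase
  cvA <- transientCurves(fIA, fIA, tau_A = 1 / 0.05, tau_P = 1,
                         tau_m = tau_m)
  ## productive route: poised, fires immediately
  cvB <- transientCurves(eventDuration("point", mean = 0), fIB,
                         tau_A = 0.1 / 0.05, tau_P = 0.1, tau_m = tau_m)
  expect_equal(cvA@m_ss, cvB@m_ss, tolerance = 1e-6)
  expect_lt(cvB@t_re, cvA@t_re)
})
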