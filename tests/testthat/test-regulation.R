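test_that("occupancy is a Hill function with the expected anchors", {
  expect_equal(occupancy(2, 2), 0.5)
  expect_equal(occupancy(2, 2, n_H = 3.7), 0.5)
  expect_equal(occupancy(0, 5), 0)
  expect_equal(occupancy(Inf, 5), 1)
  expect_equal(occupancy(0.5, 1, n_H = 2), 0.2)
  R <- 10^seq(-3, 3, length.out = 50)
  expect_true(all(diff(occupancy(R, 1, 2)) > 0))
})

test_that("generic regulatory function reproduces the per-mode closed forms", {
  base <- burstParams(tau_P = 1, p1 = 0.5, tau_S1 = 5, tau_S2 = 10,
                      tau_S3 = 20, p2 = 0.5, tau_m = 5)
  K_d <- 2
  eff <- c(MEE = 0.2, MEA = 0.3, MFI = 0.25, MCC = 0.15, MIE = 1.6,
           MIA = 1.6, MFC = 0.3, MFA = 0.3)
  for (nm in names(eff)) {
    mode <- regulatoryMode(nm, efficacies = eff[[nm]], K_d = K_d)
    rf <- regulatoryFunction(mode, base)
    oracle <- table_closed_forms(nm, eff[[nm]], base, K_d)
    expect_equal(rf$v_max, oracle$v_max, tolerance = 1e-6,
                 label = paste(nm, "v_max"))
    expect_equal(rf$omega, oracle$omega, tolerance = 1e-6,
                 label = paste(nm, "omega"))
    expect_equal(rf$beta, oracle$beta, tolerance = 1e-6,
                 label = paste(nm, "beta"))
    ## the half-response concentration sits below K_d for the
    ## acceleration-type modes and above it for the deceleration-type ones
    if (nm %in% c("MIA", "MFC")) expect_gt(rf$omega, K_d)
    else expect_lt(rf$omega, K_d)
  }
})

test_that("mode interpolation hits its boundary conditions", {
  base <- burstParams(tau_P = 1, p1 = 0.5, tau_S1 = 5, tau_S2 = 10,
                      tau_S3 = 20, p2 = 0.5, tau_m = 5)
  mode <- regulatoryMode(c("MEE", "MIE", "MFA"),
                         efficacies = c(MEE = 0.2, MIE = 1.8, MFA = 0.4))
  at0 <- applyModes(mode, 0, base)
  expect_equal(at0@tau_P, 1); expect_equal(at0@p1, 0.5)
  expect_equal(at0@p2, 0.5)
  at1 <- applyModes(mode, 1, base)
  expect_equal(at1@tau_P, 0.2)
  expect_equal(at1@p1, 0.9)      # 1.8 * 0.5
  expect_equal(at1@p2, 0.2)      # 0.4 * 0.5
  ## completion rates are linear in occupancy
  atH <- applyModes(mode, 0.5, base)
  expect_equal(1 / atH@tau_P, 0.5 * (1 / 1 + 1 / 0.2))
  ## continuity in O
  Os <- seq(0, 1, length.out = 30)
  ps <- vapply(Os, function(O) applyModes(mode, O, base)@p1, numeric(1))
  expect_true(all(diff(ps) > 0))
  expect_lt(max(abs(diff(ps))), 0.1)
})

test_that("mode combinations are counted and validated correctly", {
  combos <- modeCombinations()
  expect_length(combos, 255)
  ok <- vapply(combos, validModeCombination, logical(1))
  ## invalid combinations are exactly those pairing the two p1 flows or
  ## the two p2 flows
  bad <- vapply(combos, function(s)
    all(c("MIE", "MIA") %in% s) || all(c("MFC", "MFA") %in% s), logical(1))
  expect_identical(ok, !bad)
  expect_error(regulatoryMode(c("MIE", "MIA"),
                              efficacies = c(MIE = 1.5, MIA = 1.5)),
               "disjoint")
})

test_that("the fitted Hill exponent recovers generating exponents", {
  base <- burstParams(tau_P = 1, p1 = 0.5, tau_S1 = 5, tau_S2 = 10,
                      tau_S3 = 20, p2 = 0.5, tau_m = 5)
  ## single-site curves have exponent one exactly
  mode1 <- regulatoryMode("MEE", efficacies = 0.1, K_d = 1)
  expect_equal(regulatoryFunction(mode1, base)$n, 1)
  ## occupancy itself as the rate recovers n_H
  R <- 10^seq(-3, 3, length.out = 200)
  v <- occupancy(R, 1, 2.5)
  expect_equal(fitHillExponent(R, v, 0, 1, omega = 1), 2.5, tolerance = 1e-4)
  ## a two-site mode yields an effective exponent between 1 and n_H
  mode2 <- regulatoryMode("MEE", efficacies = 0.1, K_d = 1, n_H = 2)
  n2 <- regulatoryFunction(mode2, base)$n
  expect_gt(n2, 1); expect_lt(n2, 2 + 1e-9)
  expect_error(fitHillExponent(R, sin(R), 0, 1, 1), "monotone")
})

test_that("specificity is unimodal with maximum near the fold change", {
  base <- burstParams(tau_P = 8, p1 = 0.9, tau_S1 = 1, tau_S2 = 2,
                      tau_S3 = 2, p2 = 0.3, tau_m = 5)
  ## strong activation through the productive event
  mode <- regulatoryMode("MEE", efficacies = 0.02, K_d = 1)
  rf <- regulatoryFunction(mode, base)
  expect_gt(rf$F_v, 5)
  sp <- specificityCurve(mode, base, nontarget_fold = 1e4)
  expect_equal(sp$S_m, rf$F_v, tolerance = 0.1)
  expect_lt(sp$S_m, rf$F_v)
  ## convergence toward the fold change as the affinity separation grows
  sp6 <- specificityCurve(mode, base, nontarget_fold = 1e6)
  expect_lt(abs(sp6$S_m - rf$F_v), abs(sp$S_m - rf$F_v))
  expect_equal(sp6$S_m, rf$F_v, tolerance = 0.01)
  ## ends of the concentration axis are nonspecific
  expect_equal(sp$S[1], 1, tolerance = 0.01)
  expect_equal(sp$S[length(sp$S)], 1, tolerance = 0.01)
  ## unimodal on the grid
  d <- diff(sp$S)
  expect_lt(sum(diff(sign(d[abs(d) > 1e-12])) != 0), 2)
  ## no regulation, no specificity
  none <- regulatoryMode("MEE", efficacies = 1, K_d = 1)
  sp0 <- specificityCurve(none, base)
  expect_true(all(abs(sp0$S - 1) < 1e-12))
})

test_that("dose-response operating points are ordered and sensitivities split", {
  base <- burstParams(tau_P = 0.2, p1 = 0.5, tau_S = 250, tau_m = 5)
  mode <- modeFromEndpoints(base, p1B = 0.995, tau_SB = 5, K_d = 1)
  dr <- doseResponse(mode, base)
  expect_lt(dr$omega_f, dr$omega_m)
  expect_lt(dr$omega_m, dr$omega_b)
  cu <- dr$curves
  expect_true(all(abs(cu$S_b + cu$S_f - 1) < 1e-9, na.rm = TRUE))
  ## burst frequency peaks where the active and inactive phases balance
  i_peak <- which.max(cu$f)
  i_bal <- which.min(abs(cu$tau_A - cu$tau_I))
  expect_lte(abs(i_peak - i_bal), 1)
  ## frequency modulation dominates at low expression, size at high
  lo <- cu$m < quantile(cu$m, 0.05)
  hi <- cu$m > 0.9 * max(cu$m) & cu$m < 0.99 * max(cu$m)
  expect_true(all(cu$S_f[lo] > cu$S_b[lo]))
  expect_true(all(cu$S_b[hi] > cu$S_f[hi]))
})

test_that("mean-Fano curve families show the documented shapes", {
  base <- burstParams(tau_P = 0.165, p1 = 0.95, tau_S = 100, tau_m = 5)
  ## silent-phase regulation: noise falls toward Poisson as the mean
  ## approaches its ceiling tau_m / tau_P
  Og <- c(0, occupancy(10^seq(-6, 6, length.out = 400), K_d = 1), 1)
  mS <- modeFromEndpoints(base, tau_SB = 0.01)
  cS <- mfCurve(mS, base, O_grid = Og)
  ## super-Poisson branch decreases monotonically toward the Poisson line
  above <- cS$fano > 1.02
  expect_true(all(diff(cS$fano[above]) < 1e-9))
  expect_lt(abs(cS$fano[nrow(cS)] - 1), 0.05)
  expect_equal(max(cS$m_mean), 5 / 0.165, tolerance = 0.01)
  ## burst-entry regulation: noise first rises then falls
  b2 <- burstParams(tau_P = 0.165, p1 = 0.3, tau_S = 100, tau_m = 5)
  mP1 <- modeFromEndpoints(b2, p1B = 0.9999)
  cP1 <- mfCurve(mP1, b2, O_grid = occupancy(10^seq(-6, 6, length.out = 300),
                                             K_d = 1))
  i_max <- which.max(cP1$fano)
  expect_gt(i_max, 5)
  expect_lt(i_max, nrow(cP1) - 5)
  ## combined curves lie between the duration-only boundary curves:
  ## above the silent-phase-only curve and below the productive-event-only
  ## curve at matched mean expression (checked on each pairwise overlap)
  mT <- modeFromEndpoints(base, tau_PB = 0.0165)
  cT <- mfCurve(mT, base, O_grid = Og)
  both <- modeFromEndpoints(base, tau_PB = 0.0165, tau_SB = 0.01)
  cB <- mfCurve(both, base, O_grid = Og)
  selS <- cB$m_mean > min(cS$m_mean) & cB$m_mean < max(cS$m_mean)
  fS <- approx(cS$m_mean, cS$fano, cB$m_mean[selS])$y
  expect_true(all(cB$fano[selS] >= fS - 1e-6))
  selT <- cB$m_mean > min(cT$m_mean) & cB$m_mean < max(cT$m_mean)
  expect_gt(sum(selT), 0)
  fT <- approx(cT$m_mean, cT$fano, cB$m_mean[selT])$y
  expect_true(all(cB$fano[selT] <= fT + 1e-6))
})
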