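test_that("unbinding detection returns the first crossing of the z threshold", {
  expect_equal(detectUnbinding(tinyTrajectory()), 20)
  # never crosses
  low <- tinyTrajectory(z = c(5, 10, 14.9, 12))
  expect_true(is.na(detectUnbinding(low)))
  # noisy z with multiple crossings: earliest crossing, against a linear scan
  for (s in 1:20) {
    set.seed(s)
    z <- 10 + cumsum(rnorm(200, 0.2, 2))
    tr <- tinyTrajectory(time = seq(0, by = 10, length.out = 200), z = z,
                         contacts = rep(1, 200), bias = rep(0, 200))
    oracle <- NA_real_
    for (i in seq_along(z)) if (z[i] > 15) { oracle <- tr@frames$time[i]; break }
    expect_identical(detectUnbinding(tr), oracle)
  }
})

test_that("rescaled time reduces to wall-clock time at zero bias", {
  for (s in 1:10) {
    tr <- randomTrajectory(n = 40, seed = s, maxBias = 0)
    ev <- detectUnbinding(tr)
    expect_equal(rescaleTime(tr, ev) * 1e12, ev - tr@frames$time[1L])
  }
})

test_that("rescaled time matches analytic sums and the exponential-ramp integral", {
  # two 10 ps strides with beta*V = (0, ln 2): 10*1 + 10*2 = 30 ps
  tr <- tinyTrajectory(time = c(0, 10, 20), z = c(5, 10, 16),
                       bias = c(0, 0, kT(300) * log(2)),
                       contacts = c(2, 1, 0))
  expect_equal(rescaleTime(tr, 20), 30e-12)
  # linear ramp V(t) = c*t at 1 ps resolution vs closed-form integral
  cc <- 2e-3                               # kcal/mol per ps
  tm <- 0:1000
  beta <- 1 / kT(300)
  tr <- tinyTrajectory(time = tm, z = c(rep(5, 1000), 16),
                       bias = cc * tm, contacts = rep(1, 1001))
  closed <- (exp(beta * cc * 1000) - 1) / (beta * cc)   # ps
  expect_equal(rescaleTime(tr, 1000) * 1e12, closed, tolerance = 0.01)
})

test_that("rescaled time is monotone in the deposited bias", {
  tr <- randomTrajectory(n = 60, seed = 3)
  ev <- detectUnbinding(tr)
  base <- rescaleTime(tr, ev)
  bumped <- tr
  bumped@frames$bias[25] <- bumped@frames$bias[25] + 1.5
  expect_gt(rescaleTime(bumped, ev), base)
})

test_that("rescale and detection reject invalid inputs", {
  tr <- tinyTrajectory()
  expect_error(rescaleTime(tr, -5), "before the first frame")
  expect_error(rescaleTime(tr, 1e6), "beyond the trajectory")
  expect_error(BiasedTrajectory("x", data.frame(time = 1, z = 1,
                                                contacts = 1, bias = 0)),
               "2 frames")
})

test_that("ECDF fit recovers tau from exponential quantiles and scales correctly", {
  n <- 100
  ts <- -1 * log(1 - (seq_len(n) - 0.5) / n)   # exact Exp(1) quantiles
  smp <- DissociationSample("q", ts, ts * 1e9)
  expect_equal(tauHat(fitPoissonCDF(smp)), 1, tolerance = 0.02)
  # scale equivariance
  smp10 <- DissociationSample("q", ts * 10, ts * 1e10)
  expect_equal(tauHat(fitPoissonCDF(smp10)),
               10 * tauHat(fitPoissonCDF(smp)), tolerance = 1e-6)
  # agreement with the ML estimator (sample mean) at n >= 100
  set.seed(4)
  ts2 <- rexp(200, 1 / 3)
  smp2 <- DissociationSample("m", ts2, ts2 * 1e9)
  expect_equal(tauHat(fitPoissonCDF(smp2)), mean(ts2), tolerance = 0.05)
  expect_equal(tauHat(fitPoissonCDF(smp2, method = "mle")), mean(ts2))
})

test_that("ECDF fit is well-calibrated at the protocol's sample size", {
  # 15 draws from Exp(240 s): median fitted tau within 10% of the truth
  set.seed(11)
  est <- replicate(500, {
    ts <- rexp(15, 1 / 240)
    tauHat(fitPoissonCDF(DissociationSample("mc", ts, ts)))
  })
  expect_lt(abs(median(est) / 240 - 1), 0.10)
})

test_that("the Poisson fit rejects degenerate samples", {
  expect_error(fitPoissonCDF(DissociationSample("x", c(1, 2), c(1, 2))),
               "insufficient data")
  expect_error(fitPoissonCDF(DissociationSample("x", rep(2, 5), rep(2, 5))),
               "degenerate")
})

test_that("KS reliability is calibrated under the null and detects misfit", {
  set.seed(21)
  nullP <- replicate(60, {
    ts <- rexp(15)
    smp <- DissociationSample("n", ts, ts)
    pValue(ksReliability(smp, fitPoissonCDF(smp), nRandom = 2e4,
                         seed = sample.int(1e6, 1)))
  })
  expect_gte(mean(nullP > 0.05), 0.9)
  # bimodal mixture far from exponential is flagged
  set.seed(22)
  altP <- replicate(60, {
    ts <- c(rexp(8, 100), rexp(7, 1 / 100))   # Exp(tau/100) + Exp(100 tau)
    smp <- DissociationSample("a", ts, ts)
    pValue(ksReliability(smp, fitPoissonCDF(smp), nRandom = 2e4,
                         seed = sample.int(1e6, 1)))
  })
  expect_gte(mean(altP < 0.05), 0.8)
})

test_that("reliability uses a strict inequality at the threshold", {
  set.seed(31)
  ts <- rexp(15)
  smp <- DissociationSample("b", ts, ts)
  fit <- ksReliability(smp, fitPoissonCDF(smp), nRandom = 1e4, seed = 5)
  # re-test with the threshold set to the achieved p-value: p > p is FALSE
  atBoundary <- fitPoissonCDF(smp, threshold = pValue(fit))
  atBoundary <- ksReliability(smp, atBoundary, nRandom = 1e4, seed = 5)
  expect_false(isReliable(atBoundary))
  expect_error(ksReliability(smp, fit, nRandom = 5), "must be >=")
})

test_that("bootstrap is deterministic and handles degenerate samples", {
  smp <- DissociationSample("c", rep(2.5, 8), rep(1, 8))
  bt <- bootstrapTau(smp, nBoot = 50, size = 5, seed = 9)
  expect_equal(meanTau(bt), 2.5)
  expect_equal(semTau(bt), 0)
  set.seed(41)
  ts <- rexp(15)
  smp2 <- DissociationSample("d", ts, ts)
  b1 <- bootstrapTau(smp2, nBoot = 200, size = 15, seed = 7)
  b2 <- bootstrapTau(smp2, nBoot = 200, size = 15, seed = 7)
  expect_identical(meanTau(b1), meanTau(b2))
  expect_identical(semTau(b1), semTau(b2))
  expect_error(bootstrapTau(smp2, size = 2), "insufficient data")
})

test_that("the full kinetics summary emits one validated row per ligand", {
  sims <- lapply(c(A = 0.5, B = 2), function(tau)
    genUnbindingTrajectories(tau, BiasSchedule(), nTraj = 8, seed = round(tau * 100),
                             ligandId = paste0("L", tau))$trajectories)
  kin <- kineticsSummary(sims, nRandom = 5e3, nBoot = 100, size = 8, seed = 3)
  expect_equal(nrow(kin), 2L)
  expect_true(all(kin$tau_hat_s > 0))
  expect_true(all(kin$n_events == 8))
  expect_true(all(kin$ks_p >= 0 & kin$ks_p <= 1))
})
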