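test_that("ADC transform inverts the MSD definition", {
  dt <- 1e-4
  tn <- dt * (1:50)
  D <- 3e-12
  # MSD(t) = 4 D t with R = 0: D_app is identically D
  curve <- new("MsdCurve", lags = tn, values = 4 * D * tn,
               nTrackPoints = 51L)
  expect_equal(msdValues(computeADC(curve, R = 0)), rep(D, 50))
  # R = 0.25 at n = 1: D_app = D / (1 - 0.5) = 2 D
  adc <- computeADC(curve, R = 0.25)
  expect_equal(msdValues(adc)[1], 2 * D)
  # zero MSD stays zero
  z <- new("MsdCurve", lags = tn, values = rep(0, 50), nTrackPoints = 51L)
  expect_equal(msdValues(computeADC(z, R = 0.1)), rep(0, 50))
})

test_that("ADC transform recovers an arbitrary embedded curve exactly", {
  # feeding MSD(t_n) = 4 t_n (1 - 2R/n) f(t_n) must return f
  dt <- 2e-4; R <- 0.2
  nIdx <- 1:40
  tn <- dt * nIdx
  f <- 1e-12 * (1 + sin(nIdx / 5)^2)
  curve <- new("MsdCurve", lags = tn, values = 4 * tn * (1 - 2 * R / nIdx) * f,
               nTrackPoints = 41L)
  expect_equal(msdValues(computeADC(curve, R = R)), f, tolerance = 1e-12)
})

test_that("BIC arithmetic matches its closed form", {
  expect_equal(bicScore(rss = 10, n = 10, k = 2), 2 * log(10))
  expect_equal(bicScore(rss = 5, n = 20, k = 3),
               3 * log(20) + 20 * log(0.25))
})

test_that("built-in models have the documented forms and limits", {
  reg <- builtinModels()
  expect_equal(modelNames(reg), c("brownian", "confined", "hop"))
  b <- reg@models$brownian; cfd <- reg@models$confined; hop <- reg@models$hop
  t <- c(1e-4, 1e-3, 1e-2)
  # brownian with delta = 0 is constant D at any t
  expect_equal(b@fun(t, list(D = 2e-12, delta = 0), 0, 1e-4),
               rep(2e-12, 3))
  # confined small-t limit tends to D_mu: (tau/t)(1 - exp(-t/tau)) -> 1
  # with truncation error t/(2 tau), so t = 2e-6 tau gives 1e-6 accuracy
  tau <- 0.01; Dmu <- 1.5e-12
  expect_equal(cfd@fun(tau * 2e-6, list(D = Dmu, delta = 0, tau = tau),
                       0, 1e-4),
               Dmu, tolerance = 1e-6)
  # confined long-t limit decays to zero transport (evaluated at 100 tau)
  expect_lt(cfd@fun(100 * tau, list(D = Dmu, delta = 0, tau = tau), 0, 1e-4),
            Dmu / 90)
  # hop = brownian + confined
  p <- list(Dm = 1e-12, Dmu = 2e-12, delta = 0, tau = tau)
  expect_equal(hop@fun(t, p, 0, 1e-4),
               1e-12 + cfd@fun(t, list(D = 2e-12, delta = 0, tau = tau),
                               0, 1e-4))
  # the localisation-error term follows delta^2 / (2 t (1 - 2 R dt / t))
  dt <- 1e-4; R <- 0.25; delta <- 3e-9
  expect_equal(b@fun(t, list(D = 0, delta = delta), R, dt),
               delta^2 / (2 * t * (1 - 2 * R * dt / t)))
})

test_that("model registry enforces unique names and valid bounds", {
  reg <- builtinModels()
  expect_error(registerModel(reg, reg@models$brownian), "already registered")
  expect_error(
    DiffusionModel("bad", c("D"), function(t, p, R, dt) p[["D"]],
                   lower = 0, upper = 1, initial = 2),
    "lower <= initial <= upper")
  custom <- DiffusionModel("flat", "D",
                           function(t, p, R, dt) rep(p[["D"]], length(t)),
                           lower = 0, upper = Inf, initial = 1e-12)
  reg2 <- registerModel(emptyRegistry(), custom)
  expect_equal(modelNames(reg2), "flat")
})

test_that("exact brownian ADC data select brownian and recover D_M", {
  tr <- simulateBrownian(Tmax = 0.05, dt = 1e-4, D = 1e-12, L = 1e-5,
                         seed = 5)
  # replace MSD with exact model data by building a synthetic track whose
  # MSD is exactly linear: use the model-curve path through adcAnalysis on
  # real data instead, and separately check the exact-data fit machinery
  dt <- 1e-4
  tn <- dt * (1:100)
  yv <- rep(1e-12, 100)  # exact D_app of a brownian particle, delta = 0
  fits <- lapply(builtinModels()@models, spt2d:::.fitAdcModel,
                 tn = tn, yv = yv, R = 0, dt = dt)
  expect_equal(fits$brownian$par[["D"]], 1e-12, tolerance = 1e-6)
  bics <- vapply(fits, function(f) f$bic, numeric(1))
  expect_equal(names(which.min(bics)), "brownian")
})

test_that("a registered copy of brownian ties with it to 1e-9 in BIC", {
  b <- builtinModels()@models$brownian
  clone <- DiffusionModel("brownian2", b@paramNames, b@fun, b@lower,
                          b@upper, b@initial)
  reg <- registerModel(builtinModels(), clone)
  tr <- simulateBrownian(Tmax = 0.05, dt = 1e-4, D = 1e-12, L = 1e-5,
                         seed = 8)
  rep <- adcReport(adcAnalysis(tr, registry = reg, fitMaxTime = 5e-3))
  f <- modelFits(rep)
  expect_lt(abs(f$brownian$bic - f$brownian2$bic), 1e-9)
  # tie goes to the first-registered model and is flagged
  if (rep@bestModel %in% c("brownian", "brownian2")) {
    expect_equal(rep@bestModel, "brownian")
    expect_true(rep@tie)
  }
})

test_that("an analysis restricted to one custom model reports only it", {
  custom <- DiffusionModel("flat", "D",
                           function(t, p, R, dt) rep(p[["D"]], length(t)),
                           lower = 0, upper = Inf, initial = 1e-12)
  tr <- simulateBrownian(Tmax = 0.02, dt = 1e-4, D = 1e-12, L = 1e-5,
                         seed = 2)
  rep <- adcReport(adcAnalysis(tr, registry = registerModel(emptyRegistry(),
                                                            custom),
                               fitMaxTime = 5e-3))
  expect_equal(names(modelFits(rep)), "flat")
  expect_equal(bestModel(rep), "flat")
})

test_that("adcSummary counts best models and averages D_app", {
  tracks <- TrackSet(lapply(1:3, function(i)
    simulateBrownian(Tmax = 0.02, dt = 1e-4, D = 1e-12, L = 1e-5,
                     seed = i, id = i)))
  analysed <- adcAnalysis(tracks, fitMaxTime = 5e-3)
  sm <- adcSummary(analysed)
  expect_equal(sum(sm$counts), 3)
  expect_equal(sum(sm$fractions), 1)
  expect_equal(nrow(sm$perTrack), 3)
  # averaged D_app of identical tracks equals the individual curve
  same <- TrackSet(lapply(1:3, function(i) {
    tr <- simulateBrownian(Tmax = 0.02, dt = 1e-4, D = 1e-12, L = 1e-5,
                           seed = 99, id = i)
    adcAnalysis(tr, fitMaxTime = 5e-3)
  }))
  smSame <- adcSummary(same)
  expect_equal(msdValues(smSame$meanAdc),
               msdValues(adcReport(same[[1]])@adc))
  # unanalysed tracks are reported by id
  raw <- TrackSet(list(simulateBrownian(Tmax = 0.02, dt = 1e-4, D = 1e-12,
                                        L = 1e-5, seed = 1, id = 7L)))
  expect_error(adcSummary(raw), "7")
})

test_that("KS statistics are recorded per model without overriding BIC", {
  tr <- simulateBrownian(Tmax = 0.05, dt = 1e-4, D = 1e-12, L = 1e-5,
                         seed = 12)
  rep <- adcReport(adcAnalysis(tr, fitMaxTime = 5e-3))
  for (f in modelFits(rep)) {
    if (isTRUE(f$converged)) {
      expect_true(is.finite(f$ksStat) && f$ksStat >= 0 && f$ksStat <= 1)
      expect_true(is.finite(f$ksP))
    }
  }
  bics <- vapply(modelFits(rep), function(f) f$bic, numeric(1))
  expect_equal(bestModel(rep), names(which.min(bics)))
})
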