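test_that("trapezoidal AUC handles constant, exponential and linear segments", {
  const <- data.frame(time_h = 0:5, conc_ng_per_ml = rep(10, 6))
  expect_equal(aucTrapezoid(const), 50)

  tt <- seq(0, 48, by = 0.25)
  mono <- data.frame(time_h = tt, conc_ng_per_ml = 100 * exp(-0.2 * tt))
  analytic <- 100 / 0.2 * (1 - exp(-9.6))
  expect_equal(aucTrapezoid(mono), analytic, tolerance = 5e-3)

  rising <- data.frame(time_h = c(0, 0.5, 1), conc_ng_per_ml = c(0, 5, 10))
  expect_equal(aucTrapezoid(rising), 5)   # linear-up rule

  expect_error(aucTrapezoid(data.frame(time_h = c(0, 1, 1),
                                       conc_ng_per_ml = c(1, 2, 3))),
               "increasing")
  expect_error(aucTrapezoid(const[1:2, ]), "3")
})

test_that("AUC is additive over contiguous segments", {
  tt <- seq(0, 24, by = 0.1)
  cc <- 90 * exp(-1.5 * tt) + 10 * exp(-0.18 * tt)
  prof <- data.frame(time_h = tt, conc_ng_per_ml = cc)
  cut <- which(tt == 6)
  expect_equal(aucTrapezoid(prof),
               aucTrapezoid(prof[1:cut, ]) +
                 aucTrapezoid(prof[cut:nrow(prof), ]),
               tolerance = 1e-12)
})

test_that("terminal slope recovery is exact on log-linear data", {
  tt <- seq(0, 24, by = 0.5)
  pure <- data.frame(time_h = tt, conc_ng_per_ml = 50 * exp(-0.18 * tt))
  lz <- lambdaZ(pure)
  expect_equal(lz$lambda_z, 0.18, tolerance = 1e-6)

  tt <- seq(0, 48, by = 0.5)
  bi <- data.frame(time_h = tt,
                   conc_ng_per_ml = 90 * exp(-1.5 * tt) + 10 * exp(-0.18 * tt))
  expect_equal(lambdaZ(bi)$lambda_z, 0.18, tolerance = 0.02)

  still_rising <- data.frame(time_h = 0:5, conc_ng_per_ml = c(1, 2, 4, 6, 8, 9))
  expect_error(lambdaZ(still_rising), "rising")
})

test_that("clearance follows dose / AUC0-inf with per-kg scaling", {
  # clearance implied by an exposure of 279 ng.h/mL after 8 mg in a 73-kg adult
  tt <- seq(0, 96, by = 0.1)
  k <- 0.18
  c0 <- 279 * k      # makes AUC0-inf = 279 exactly for a mono-exponential
  prof <- data.frame(time_h = tt, conc_ng_per_ml = c0 * exp(-k * tt))
  pk <- pkSummary(prof, newDosingRegimen("iv_infusion", 8), 73)
  expect_equal(pk$auc_0inf, 279, tolerance = 1e-3)
  expect_equal(pk$cl, 6.5465, tolerance = 1e-3)
  expect_equal(pk$t_half, log(2) / k, tolerance = 1e-6)

  prof2 <- prof; prof2$conc_ng_per_ml <- prof$conc_ng_per_ml * 312.4 / 279
  pk2 <- pkSummary(prof2, newDosingRegimen("iv_infusion", 8), 73)
  expect_equal(pk2$cl, 5.8466, tolerance = 1e-3)

  # doubling dose on a doubled profile doubles AUC, leaves CL unchanged
  prof3 <- prof; prof3$conc_ng_per_ml <- 2 * prof$conc_ng_per_ml
  pk3 <- pkSummary(prof3, newDosingRegimen("iv_infusion", 16), 73)
  expect_equal(pk3$auc_0inf, 2 * pk$auc_0inf, tolerance = 1e-9)
  expect_equal(pk3$cl, pk$cl, tolerance = 1e-9)
})

test_that("heavy extrapolation is flagged", {
  tt <- seq(0, 4, by = 0.5)     # window far shorter than the half-life
  prof <- data.frame(time_h = tt, conc_ng_per_ml = 100 * exp(-0.1 * tt))
  pk <- pkSummary(prof, newDosingRegimen("iv_infusion", 8), 73)
  expect_true(pk$extrap_warning)
  expect_gt(pk$extrapolated_fraction, 0.2)
})

test_that("Cmax can follow a discrete clinical sampling schedule", {
  tt <- c(seq(0, 0.5, by = 0.01), seq(0.6, 12, by = 0.1))
  cc <- 300 * (exp(-0.3 * tt) - exp(-8 * tt))   # early sharp peak
  prof <- data.frame(time_h = tt, conc_ng_per_ml = cc)
  full <- pkSummary(prof, newDosingRegimen("iv_infusion", 8), 73)
  clin <- pkSummary(prof, newDosingRegimen("iv_infusion", 8), 73,
                    cmax_times = seq(0, 12, by = 0.5))
  expect_gt(full$cmax, clin$cmax)
  expect_equal(full$auc_0inf, clin$auc_0inf)   # AUC unaffected
  expect_true(clin$tmax %in% seq(0, 12, by = 0.5))
})

test_that("NCA on the noise-free engine output recovers the model clearance", {
  pk <- refPk("healthy")
  mod <- buildModel(.drug, .ref, .iv5)
  cl_model <- (wellStirredHepaticCL(liverInflow(.ref), mod@fu_blood,
                                    mod@clint_total) *
                 mod@blood_plasma_ratio * 1000 + mod@cl_renal) / 73
  expect_equal(pk$cl, cl_model, tolerance = 0.02)
})
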