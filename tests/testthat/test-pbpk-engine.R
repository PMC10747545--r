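test_that("model construction exposes the documented structure", {
  mod <- buildModel(.drug, .ref, .iv5)
  expect_s4_class(mod, "PBPKModel")
  expect_length(mod@kp, 12)
  # state dimension: 14 organs + depot + eliminated audit state
  st <- cirrhPBPK:::.simulateStates(mod, 8, 1, 0.1)
  expect_equal(ncol(st) - 1, 16)
  # IV simulation leaves the absorption depot untouched
  expect_true(all(st[, "depot"] == 0))
  expect_equal(liverInflow(mod@physiology),
               portalFlow(mod@physiology) + hepaticArterialFlow(mod@physiology))
})

test_that("kinetics are linear: dose doubling and superposition", {
  m1 <- buildModel(.drug, .ref, .iv5)
  m2 <- buildModel(.drug, .ref,
                   newDosingRegimen("iv_infusion", 16, infusion_duration = 5))
  p1 <- simulateIndividual(m1, t_end = 24)
  p2 <- simulateIndividual(m2, t_end = 24)
  scale <- max(p1@concentrations)
  expect_lt(max(abs(p2@concentrations - 2 * p1@concentrations)) / (2 * scale),
            1e-6)

  # two doses q12h equal the sum of time-shifted single-dose profiles
  mm <- buildModel(.drug, .ref,
                   newDosingRegimen("iv_infusion", 8, infusion_duration = 5,
                                    n_doses = 2, dosing_interval = 12))
  pm <- simulateIndividual(mm, t_end = 24)
  single <- simulateIndividual(m1, t_end = 24)
  ## compare on the grid points shared by the shifted and unshifted profiles
  r6 <- function(x) round(x, 6)
  shared <- intersect(r6(pm@times), intersect(r6(single@times),
                                              r6(single@times + 12)))
  base <- single@concentrations[match(shared, r6(single@times))]
  shifted <- single@concentrations[match(r6(shared - 12), r6(single@times))]
  combined <- pm@concentrations[match(shared, r6(pm@times))]
  expect_gt(length(shared), 50)
  expect_lt(max(abs(combined - (base + shifted))) / max(combined), 1e-6)
})

test_that("AUC0-inf equals dose over the model's plasma clearance", {
  mod <- buildModel(.drug, .ref, .iv5)
  pk <- refPk("healthy")
  cl_blood <- wellStirredHepaticCL(liverInflow(.ref), mod@fu_blood,
                                   mod@clint_total)
  cl_plasma <- cl_blood * mod@blood_plasma_ratio * 1000 + mod@cl_renal # mL/min
  expect_equal(8e6 / pk$auc_0inf / 60, cl_plasma, tolerance = 5e-3)
})

test_that("mass is conserved through the simulation", {
  expect_lt(massBalanceAudit(buildModel(.drug, .ref, .iv5)), 1e-6)
  expect_lt(massBalanceAudit(buildModel(.drug, .ref, .oral8)), 1e-6)
  cpc <- applyCirrhosis(.ref, loadCpScalers("C"))
  expect_lt(massBalanceAudit(buildModel(.drug, cpc, .iv5), t_end = 96), 1e-6)
})

test_that("oral dosing is near-completely eliminated after ten half-lives", {
  mod <- buildModel(.drug, .ref, .oral8)
  t_half <- refPk("healthy")$t_half
  st <- cirrhPBPK:::.simulateStates(mod, 8, ceiling(10 * t_half + 5), 0.5)
  eliminated <- st[nrow(st), "eliminated"]
  expect_gte(eliminated, 0.999 * mod@fa * 8000)
})

test_that("a clearance-free model eliminates nothing", {
  d0 <- .drug
  d0@renal_clearance_specific <- 0
  mod <- buildModel(d0, .ref, .iv5, calibration_factor = 0)
  st <- cirrhPBPK:::.simulateStates(mod, 8, 12, 0.1)
  expect_true(all(st[, "eliminated"] == 0))
  expect_lt(massBalanceAudit(mod, t_end = 12), 1e-6)
})

test_that("compiled and pure-R right-hand sides agree", {
  mod <- buildModel(.drug, .ref, .oral8)
  p <- cirrhPBPK:::.modelParms(mod, 8)
  set.seed(42)
  for (i in 1:10) {
    y <- runif(16, 0, 500)
    t <- runif(1, 0, 12)
    rR <- cirrhPBPK:::.pbpkDerivsR(t, y, p)[[1]]
    ## one explicit Euler step of length 1 returns y + f(t, y) exactly
    rC <- deSolve::ode(y = stats::setNames(y, cirrhPBPK:::.stateNames),
                       times = c(t, t + 1), func = "pbpk_derivs",
                       parms = p, dllname = "cirrhPBPK",
                       initfunc = "pbpk_initmod", method = "euler")
    dC <- rC[2, -1] - rC[1, -1]
    expect_equal(unname(dC), rR, tolerance = 1e-10)
  }
})

test_that("healthy disposition matches the drug's known kinetics", {
  pk_iv <- refPk("healthy")
  # terminal half-life within 2-fold of the reported 3.8 h
  expect_gt(pk_iv$t_half, 3.8 / 2)
  expect_lt(pk_iv$t_half, 3.8 * 2)
  # oral bioavailability brackets the reported 60-70%
  pk_po <- refPk("healthy", .oral8)
  f <- pk_po$auc_0inf / pk_iv$auc_0inf
  expect_gt(f, 0.5)
  expect_lt(f, 0.8)
})

test_that("simulation is deterministic for fixed inputs", {
  mod <- buildModel(.drug, .ref, .iv5)
  p1 <- simulateIndividual(mod, t_end = 12)
  p2 <- simulateIndividual(mod, t_end = 12)
  expect_identical(p1@concentrations, p2@concentrations)
})
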