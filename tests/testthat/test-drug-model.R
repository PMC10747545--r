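test_that("packaged drug parameters match the input-parameter table", {
  d <- loadDrugParameters()
  expect_equal(d@molecular_weight, 293.4)
  expect_equal(d@log_p, 2.25)
  expect_equal(d@pka_base, 7.40)
  expect_equal(d@fu_plasma, 0.27)
  expect_equal(d@clint_cyp1a2, 0.21)
  expect_equal(d@clint_cyp3a4, 0.03)
  expect_equal(d@renal_clearance_specific, 0.13)
  expect_equal(d@binding_protein, "albumin")
})

test_that("partition coefficient has the symmetry, monotonicity and frozen value", {
  d <- loadDrugParameters()
  plasma <- c(f_water = 0.96, f_nlipid = 0.0035, f_plipid = 0.00225)
  # tissue identical to plasma with fu_t = fu_p gives Kp = 1
  expect_equal(poulinTheilKp(d, plasma), 1)
  # increasing neutral lipid strictly increases Kp at logP 2.25
  kps <- vapply(c(0.01, 0.05, 0.1, 0.3), function(nl)
    poulinTheilKp(d, c(f_water = 0.6, f_nlipid = nl, f_plipid = 0.007)),
    numeric(1))
  expect_true(all(diff(kps) > 0))
  # muscle-like composition: frozen direct evaluation of the formula
  kp <- poulinTheilKp(d, c(f_water = 0.76, f_nlipid = 0.022,
                           f_plipid = 0.0072),
                      plasma_composition = plasma)
  expect_equal(kp, 2.9702719, tolerance = 1e-6)
  expect_error(poulinTheilKp(d, c(f_water = 0, f_nlipid = 0.1,
                                  f_plipid = 0.01)), "water")
})

test_that("well-stirred clearance has its limits, frozen value and bounds", {
  expect_equal(wellStirredHepaticCL(1.5, 0.27, 0), 0)
  # flow-limited ceiling, within 0.1% at CLint 1e6
  expect_equal(wellStirredHepaticCL(1.5, 0.27, 1e6), 1.5, tolerance = 1e-3)
  expect_equal(wellStirredHepaticCL(1.5, 0.27, 0.24), 0.06211656,
               tolerance = 1e-6)
  expect_error(wellStirredHepaticCL(-1, 0.27, 0.24), "q_liver")
  # strictly increasing in each argument, bounded above by Q (random grid)
  set.seed(11)
  for (i in 1:50) {
    q <- runif(1, 0.5, 3); fu <- runif(1, 0.05, 1); ci <- runif(1, 0.01, 10)
    base <- wellStirredHepaticCL(q, fu, ci)
    expect_lt(base, q)
    expect_gt(wellStirredHepaticCL(q * 1.1, fu, ci), base)
    expect_gt(wellStirredHepaticCL(q, fu * 1.1, ci), base)
    expect_gt(wellStirredHepaticCL(q, fu, ci * 1.1), base)
  }
})

test_that("intrinsic and renal clearances combine abundances as specified", {
  d <- loadDrugParameters()
  healthy <- buildReferencePhysiology()
  expect_equal(totalIntrinsicClearance(d, healthy), 0.24)  # 0.21 + 0.03
  cpc <- applyCirrhosis(healthy, loadCpScalers("C"))
  expect_equal(totalIntrinsicClearance(d, cpc, include_liver_mass = TRUE),
               (0.21 * 0.12 + 0.03 * 0.4) * 0.28, tolerance = 1e-12)
  zero <- healthy; zero@cyp1a2_abundance <- 0; zero@cyp3a4_abundance <- 0
  expect_equal(totalIntrinsicClearance(d, zero), 0)
  expect_equal(renalClAbsolute(d, 70), 9.1)
  expect_equal(renalClAbsolute(d, 70, 0), 0)
  expect_equal(renalClAbsolute(d, 70, 0.55), 5.005)
})

test_that("albumin adjustment of the unbound fraction behaves as specified", {
  expect_equal(fuAdjusted(0.27, 1), 0.27)
  expect_equal(fuAdjusted(0.27, 0.53), 0.27 / (0.53 * 0.73 + 0.27),
               tolerance = 1e-12)   # 0.411
  expect_equal(fuAdjusted(1, 0.3), 1)
  expect_error(fuAdjusted(0.27, 0), "albumin_factor")
  # monotone decreasing in albumin_factor
  af <- seq(0.3, 2, by = 0.1)
  expect_true(all(diff(vapply(af, fuAdjusted, numeric(1), fu = 0.27)) < 0))
  fb <- fuBlood(loadDrugParameters(), 0.47)
  expect_true(fb$fu_blood > 0 && fb$fu_blood <= 1)
})

test_that("partitioning reproduces a physiologic volume of distribution", {
  d <- loadDrugParameters(); phys <- buildReferencePhysiology()
  kp <- partitionSet(d, phys)
  org <- organTable(phys)
  v_blood <- sum(org$volume_l[org$organ %in% c("arterial blood", "venous blood")])
  vss <- sum(kp * org$volume_l[match(names(kp), org$organ)]) + v_blood
  vss_kg <- vss / bodyWeight(phys)
  expect_gt(vss_kg, 1.8 / 2)   # within 2-fold of 1.8 L/kg
  expect_lt(vss_kg, 1.8 * 2)
})

test_that("the frozen clearance calibration reproduces the healthy exposure target", {
  fac <- ondansetronCalibration()
  expect_true(is.finite(fac) && fac > 0)
  expect_equal(refPk("healthy")$auc_0inf, 312.4, tolerance = 5e-3)
  expect_equal(refPk("healthy")$cl, 5.847, tolerance = 5e-3)
})
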