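test_that("reference physiology is anatomically consistent", {
  phys <- buildReferencePhysiology(73, 30, "male")
  org <- organTable(phys)
  # total body volume within 5% of weight at density 1.05 kg/L
  expect_lt(abs(sum(org$volume_l) - 73 / 1.05), 0.05 * 73 / 1.05)
  expect_equal(hematocrit(phys), 0.47)
  expect_equal(gfr(phys), 116)
  expect_equal(liverInflow(phys), portalFlow(phys) + hepaticArterialFlow(phys))
  # flow conservation: cardiac output equals sum of regional flows
  systemic <- sum(org$flow_l_min[!org$organ %in%
                                   c("lung", "arterial blood", "venous blood")])
  expect_equal(cardiacOutput(phys), systemic, tolerance = 1e-10)
})

test_that("organ volumes and flows scale linearly with body weight", {
  p1 <- buildReferencePhysiology(60, 30, "female")
  p2 <- buildReferencePhysiology(120, 30, "female")
  expect_equal(organTable(p2)$volume_l, 2 * organTable(p1)$volume_l)
  expect_equal(cardiacOutput(p2), 2 * cardiacOutput(p1))
})

test_that("out-of-range demographics are rejected with the parameter named", {
  expect_error(buildReferencePhysiology(30, 30, "male"), "body_weight")
  expect_error(buildReferencePhysiology(200, 30, "male"), "body_weight")
  expect_error(buildReferencePhysiology(73, 10, "male"), "age")
  expect_error(buildReferencePhysiology(73, 99, "male"), "age")
})

test_that("packaged Child-Pugh scalers match the cirrhosis scaling table", {
  a <- loadCpScalers("A"); b <- loadCpScalers("B"); c3 <- loadCpScalers("C")
  expect_equal(a@functional_liver_mass, 0.69)
  expect_equal(a@cyp1a2_fraction, 0.63)
  expect_equal(a@cyp3a4_fraction, 0.589)
  expect_equal(a@albumin_fraction, 0.84)
  expect_equal(a@gfr_fraction, 0.7)
  expect_equal(b@hepatic_arterial_flow_factor, 2.3)
  expect_equal(c3@cyp1a2_fraction, 0.12)
  expect_equal(c3@hematocrit_value, 0.35)
  expect_error(loadCpScalers("D"), "cp_class")
})

test_that("cirrhosis scaling transforms the physiology as specified", {
  phys <- buildReferencePhysiology(73, 30, "male")
  cpc <- applyCirrhosis(phys, loadCpScalers("C"))
  expect_equal(gfr(cpc), 116 * 0.55)          # 63.8 mL/min
  expect_equal(hematocrit(cpc), 0.35)
  expect_equal(cpClass(cpc), "C")
  # input unmodified, organ identities and compartment count preserved
  expect_equal(gfr(phys), 116)
  expect_identical(organTable(cpc)$organ, organTable(phys)$organ)
  expect_equal(nrow(organTable(cpc)), 14)
  # flow groups
  expect_equal(portalFlow(cpc), portalFlow(phys) * 0.04)
  expect_equal(hepaticArterialFlow(cpc), hepaticArterialFlow(phys) * 3.4)
  expect_equal(renalFlow(cpc), renalFlow(phys) * 0.48)
  # cardiac output recomputed: flow conservation still holds
  org <- organTable(cpc)
  systemic <- sum(org$flow_l_min[!org$organ %in%
                                   c("lung", "arterial blood", "venous blood")])
  expect_equal(cardiacOutput(cpc), systemic, tolerance = 1e-10)
  # liver volume carries the functional-mass reduction
  expect_equal(org$volume_l[org$organ == "liver"],
               organTable(phys)$volume_l[organTable(phys)$organ == "liver"] * 0.28)
})

test_that("identity scalers return the input physiology field-by-field", {
  phys <- buildReferencePhysiology(80, 45, "female")
  out <- applyCirrhosis(phys, identityScalers("A"))
  expect_equal(organTable(out), organTable(phys))
  expect_equal(hematocrit(out), hematocrit(phys))
  expect_equal(gfr(out), gfr(phys))
  expect_equal(out@albumin_factor, 1)
})

test_that("scaling an already-scaled physiology is refused", {
  cpa <- applyCirrhosis(buildReferencePhysiology(), loadCpScalers("A"))
  expect_error(applyCirrhosis(cpa, loadCpScalers("B")), "already")
})

test_that("eliminating pathways decline monotonically with severity", {
  drug <- loadDrugParameters()
  phys <- list(healthy = buildReferencePhysiology())
  for (cl in c("A", "B", "C"))
    phys[[cl]] <- applyCirrhosis(phys$healthy, loadCpScalers(cl))
  cyp_capacity <- vapply(phys, function(p)
    totalIntrinsicClearance(drug, p, include_liver_mass = TRUE), numeric(1))
  gfrs <- vapply(phys, gfr, numeric(1))
  expect_true(all(diff(cyp_capacity) < 0))   # healthy > A > B > C
  expect_true(all(diff(gfrs) < 0))
})
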