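# Shared objects for the test suite; built once per test run.
.drug <- loadDrugParameters()
.ref <- buildReferencePhysiology(73, 30, "male")
.iv5 <- newDosingRegimen("iv_infusion", 8, infusion_duration = 5)
.oral8 <- newDosingRegimen("oral", 8)

# typical-subject PK on the production grids
refPk <- local({
  cache <- new.env()
  function(cp_class = "healthy", regimen = .iv5) {
    key <- paste(cp_class, regimen@route, regimen@dose)
    if (is.null(cache[[key]])) {
      phys <- if (cp_class == "healthy") .ref
              else applyCirrhosis(.ref, loadCpScalers(cp_class))
      t_end <- if (cp_class == "healthy") 48 else 96
      prof <- simulateIndividual(buildModel(.drug, phys, regimen),
                                 t_end = t_end)
      cache[[key]] <- pkSummary(prof, regimen, 73,
                                cmax_times = seq(0, t_end, by = 0.1))
    }
    cache[[key]]
  }
})
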