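## Default adult weight range used when a study reports no body weights
## (pooled healthy range; midpoint 73 kg = reference anatomy).
.DEFAULT_WT <- c(55, 91)
.DEFAULT_AGE <- c(18, 43)

#' Population specification matching one packaged study design
#'
#' Builds a [PopulationSpec-class] from the packaged trial-design table:
#' female fraction from the reported counts, age and weight sampled from the
#' reported range (or mean/SD where ranges are not given). Studies that do
#' not report weights (and the cirrhosis study, which reports none) use the
#' pooled healthy adult range 55-91 kg.
#'
#' @param study_id a `study_id` of the packaged trial-design table.
#' @param n subjects (production default 1000).
#' @param seed RNG seed.
#' @param cp_class Child-Pugh class for the disease study.
#' @return a [PopulationSpec-class].
#' @export
studyPopulationSpec <- function(study_id, n = 1000, seed = 1,
                                cp_class = "healthy") {
  t4 <- loadFixture("table4")
  row <- t4[t4$study_id == study_id, ]
  if (nrow(row) != 1) stop("unknown study_id: ", study_id)
  has_age_range <- !is.na(row$age_min)
  has_wt_range <- !is.na(row$wt_min)
  has_wt_norm <- !is.na(row$wt_mean)
  populationSpec(
    n = n, female_fraction = row$n_female / row$n,
    age_range = if (has_age_range) c(row$age_min, row$age_max)
                else if (is.na(row$age_mean)) .DEFAULT_AGE else NULL,
    age_mean = if (!has_age_range) row$age_mean else NA,
    age_sd = if (!has_age_range) row$age_sd else NA,
    wt_range = if (has_wt_range) c(row$wt_min, row$wt_max)
               else if (!has_wt_norm) .DEFAULT_WT else NULL,
    wt_mean = if (!has_wt_range) row$wt_mean else NA,
    wt_sd = if (!has_wt_range) row$wt_sd else NA,
    cp_class = cp_class, seed = seed)
}

#' Dosing regimen of one packaged study design
#'
#' @inheritParams studyPopulationSpec
#' @return a [DosingRegimen-class].
#' @export
studyRegimen <- function(study_id) {
  t4 <- loadFixture("table4")
  row <- t4[t4$study_id == study_id, ]
  if (nrow(row) != 1) stop("unknown study_id: ", study_id)
  if (row$route == "iv") {
    newDosingRegimen("iv_infusion", row$dose,
                     dose_per_kg = row$dose_unit == "mg_per_kg",
                     infusion_duration = row$infusion_min)
  } else {
    newDosingRegimen("oral", row$dose,
                     dose_per_kg = row$dose_unit == "mg_per_kg")
  }
}

## NCA window (h): covers >= 5 terminal half-lives (CP-C t1/2 ~ 20 h).
.scenarioWindow <- function(cp_class) if (cp_class == "healthy") 48 else 96

#' Simulate one study scenario
#'
#' Generates the study-matched virtual population, simulates it and returns
#' the per-subject PK table plus population mean/median summaries of
#' AUC0-inf, Cmax and CL.
#'
#' @inheritParams studyPopulationSpec
#' @param drug a [DrugParameters-class] (default: packaged ondansetron).
#' @return list with `pk`, `envelope`, `mean` and `median` (named numeric:
#'   `auc_0inf`, `cmax`, `cl`).
#' @export
runStudyScenario <- function(study_id, n = 1000, seed = 1,
                             cp_class = "healthy",
                             drug = loadDrugParameters()) {
  spec <- studyPopulationSpec(study_id, n = n, seed = seed,
                              cp_class = cp_class)
  res <- simulatePopulation(generatePopulation(spec), drug,
                            studyRegimen(study_id),
                            t_end = .scenarioWindow(cp_class))
  pars <- c("auc_0inf", "cmax", "cl")
  res$mean <- vapply(res$pk[pars], mean, numeric(1))
  res$median <- vapply(res$pk[pars], stats::median, numeric(1))
  res
}

#' Full model qualification against the packaged observed tables
#'
#' Simulates a matched virtual population for every packaged study scenario
#' (five healthy IV, five healthy oral, and the cirrhosis study under
#' Child-Pugh A, B and C), takes the population-mean predicted AUC0-inf,
#' Cmax and CL, and pairs them with the packaged observed values.
#'
#' @param n subjects per scenario (production default 1000).
#' @param seed base RNG seed (each scenario derives its own sub-seed).
#' @return an [EvaluationReport-class]; its comparisons carry the simulated
#'   predictions, not the reference model's.
#' @export
runModelQualification <- function(n = 1000, seed = 1) {
  t1 <- loadFixture("table1")
  t3 <- loadFixture("table3")
  healthy_ids <- unique(t1$study_id)
  rows <- list(); i <- 0
  for (sid in healthy_ids) {
    i <- i + 1
    res <- runStudyScenario(sid, n = n, seed = seed * 100 + i)
    obs <- t1[t1$study_id == sid, ]
    obs$predicted <- unname(res$mean[obs$parameter])
    rows[[length(rows) + 1]] <- obs[c("study_id", "route", "parameter",
                                      "observed", "predicted")]
  }
  for (cp in c("A", "B", "C")) {
    i <- i + 1
    res <- runStudyScenario("cir", n = n, seed = seed * 100 + i,
                            cp_class = cp)
    sid <- paste0("cir_cp", tolower(cp))
    obs <- t3[t3$study_id == sid, ]
    obs$predicted <- unname(res$mean[obs$parameter])
    rows[[length(rows) + 1]] <- obs[c("study_id", "route", "parameter",
                                      "observed", "predicted")]
  }
  evaluateStudies(do.call(rbind, rows))
}

#' Production exposure summary for one scenario
#'
#' Median AUC0-inf (with the 5-95 percentile interval) of the production
#' population (pooled demographics, n subjects) for a route and Child-Pugh
#' class; the building block for exposure-increase and dose-adjustment
#' analyses.
#'
#' @param cp_class "healthy", "A", "B" or "C".
#' @param route "iv_infusion" or "oral".
#' @param dose mg.
#' @param n subjects. @param seed RNG seed.
#' @param subjects optional pre-generated subject table (overrides n/seed).
#' @param drug a [DrugParameters-class].
#' @return list with `summary` (a [summarizeBoxwhisker()] row), `pk`, and
#'   the `subjects` used.
#' @export
runExposureScenario <- function(cp_class = "healthy",
                                route = c("iv_infusion", "oral"), dose = 8,
                                n = 1000, seed = 1, subjects = NULL,
                                drug = loadDrugParameters()) {
  route <- match.arg(route)
  reg <- if (route == "iv_infusion")
    newDosingRegimen("iv_infusion", dose, infusion_duration = 5)
  else newDosingRegimen("oral", dose)
  if (is.null(subjects))
    subjects <- generatePopulation(healthyPopulationSpec(n, seed = seed,
                                                         cp_class = cp_class))
  res <- simulatePopulation(subjects, drug, reg,
                            t_end = .scenarioWindow(cp_class))
  list(summary = summarizeBoxwhisker(res$pk$auc_0inf,
                                     label = paste(cp_class, route, dose)),
       pk = res$pk, subjects = subjects)
}
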