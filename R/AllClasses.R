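#' @import methods
NULL

## Canonical organ order used throughout the ODE system. The first twelve are
## perfusion-limited tissues; the two blood pools close the circulatory loop.
.TISSUES <- c("lung", "heart", "brain", "muscle", "adipose", "skin", "bone",
              "liver", "gut", "spleen", "kidney", "rest-of-body")
.BLOOD   <- c("arterial blood", "venous blood")
.ORGANS  <- c(.TISSUES, .BLOOD)

## Poulin-Theil plasma composition (volume fractions).
.PLASMA_COMPOSITION <- c(f_water = 0.96, f_nlipid = 0.0035, f_plipid = 0.00225)

#' DrugParameters: physicochemical and ADME inputs for one compound
#'
#' Mirrors the packaged ondansetron definition field-for-field; any small
#' molecule with the same fields can be supplied. Intrinsic clearances are
#' whole-liver values (L/min) for the two eliminating CYP pathways; renal
#' clearance is specific (mL/min/kg body weight).
#'
#' @slot name compound label.
#' @slot molecular_weight g/mol.
#' @slot log_p octanol:water log partition coefficient.
#' @slot pka_base basic pKa (Henderson-Hasselbalch ionization at pH 7.4).
#' @slot fu_plasma fraction unbound in plasma (0-1].
#' @slot solubility mg/L aqueous solubility (carried, not rate-limiting here).
#' @slot binding_protein "albumin" or "AGP".
#' @slot specific_intestinal_permeability cm/min.
#' @slot specific_organ_permeability cm/min.
#' @slot clint_cyp1a2,clint_cyp3a4 intrinsic clearance, L/min.
#' @slot renal_clearance_specific mL/min/kg.
#' @exportClass DrugParameters
setClass("DrugParameters",
  representation(
    name = "character",
    molecular_weight = "numeric",
    log_p = "numeric",
    pka_base = "numeric",
    fu_plasma = "numeric",
    solubility = "numeric",
    binding_protein = "character",
    specific_intestinal_permeability = "numeric",
    specific_organ_permeability = "numeric",
    clint_cyp1a2 = "numeric",
    clint_cyp3a4 = "numeric",
    renal_clearance_specific = "numeric"
  )
)

setValidity("DrugParameters", function(object) {
  msg <- character()
  if (object@molecular_weight <= 0) msg <- c(msg, "molecular_weight must be > 0")
  if (object@fu_plasma <= 0 || object@fu_plasma > 1)
    msg <- c(msg, "fu_plasma must be in (0, 1]")
  if (object@clint_cyp1a2 < 0 || object@clint_cyp3a4 < 0 ||
      object@renal_clearance_specific < 0)
    msg <- c(msg, "clearances must be >= 0")
  if (!object@binding_protein %in% c("albumin", "AGP"))
    msg <- c(msg, "binding_protein must be 'albumin' or 'AGP'")
  if (length(msg)) msg else TRUE
})

#' Physiology: organ-level description of one (virtual) subject
#'
#' Organ volumes, regional blood flows and tissue composition for the fixed
#' 14-compartment organ set, plus whole-body covariates. A healthy subject has
#' all relative factors (albumin, CYP abundances, functional liver mass) at 1;
#' [applyCirrhosis()] produces a Child-Pugh scaled copy and stamps `cp_class`.
#'
#' @slot organs data.frame with columns organ, volume_l, flow_l_min, f_water,
#'   f_nlipid, f_plipid (flow is NA for the two blood pools; the lung row
#'   carries total cardiac output).
#' @slot body_weight kg.
#' @slot age years. @slot sex "male" or "female".
#' @slot hematocrit fraction (0-1).
#' @slot gfr glomerular filtration rate, mL/min.
#' @slot albumin_factor relative plasma albumin concentration (1 = healthy).
#' @slot cyp1a2_abundance,cyp3a4_abundance relative hepatic pathway activity.
#' @slot functional_liver_mass_factor relative functional liver mass.
#' @slot cp_class "healthy", "A", "B" or "C".
#' @exportClass Physiology
setClass("Physiology",
  representation(
    organs = "data.frame",
    body_weight = "numeric",
    age = "numeric",
    sex = "character",
    hematocrit = "numeric",
    gfr = "numeric",
    albumin_factor = "numeric",
    cyp1a2_abundance = "numeric",
    cyp3a4_abundance = "numeric",
    functional_liver_mass_factor = "numeric",
    cp_class = "character"
  )
)

setValidity("Physiology", function(object) {
  msg <- character()
  org <- object@organs
  need <- c("organ", "volume_l", "flow_l_min", "f_water", "f_nlipid", "f_plipid")
  if (!all(need %in% names(org)))
    return(paste("organs table must have columns:", paste(need, collapse = ", ")))
  if (!identical(org$organ, .ORGANS))
    return("organs must be exactly the canonical 14-organ set, in order")
  if (any(org$volume_l <= 0)) msg <- c(msg, "all organ volumes must be > 0")
  flows <- org$flow_l_min[match(.TISSUES, org$organ)]
  if (any(flows < 0)) msg <- c(msg, "blood flows must be >= 0")
  comp <- org[org$organ %in% .TISSUES,
              c("f_water", "f_nlipid", "f_plipid")]
  if (any(rowSums(comp) > 1 + 1e-9))
    msg <- c(msg, "tissue composition fractions must sum to <= 1")
  if (object@hematocrit <= 0 || object@hematocrit >= 1)
    msg <- c(msg, "hematocrit must be in (0, 1)")
  ## flow conservation: cardiac output (lung row) equals the sum of systemic
  ## regional flows within 1%
  co <- org$flow_l_min[org$organ == "lung"]
  systemic <- sum(org$flow_l_min[org$organ %in% setdiff(.TISSUES, "lung")])
  if (abs(co - systemic) > 0.01 * co)
    msg <- c(msg, "cardiac output must equal the sum of regional flows within 1%")
  if (!object@cp_class %in% c("healthy", "A", "B", "C"))
    msg <- c(msg, "cp_class must be 'healthy', 'A', 'B' or 'C'")
  if (length(msg)) msg else TRUE
})

#' CirrhosisScalers: Child-Pugh physiological scaling factors
#'
#' One row of the packaged cirrhosis scaling table: multiplicative fractions of
#' healthy control for liver mass, hepatic CYP activities, albumin, flows and
#' GFR, plus the absolute cirrhotic hematocrit.
#'
#' @slot cp_class "A", "B" or "C".
#' @slot functional_liver_mass,cyp3a4_fraction,cyp1a2_fraction fractions of control.
#' @slot albumin_fraction fraction of control plasma albumin.
#' @slot hematocrit_value absolute hematocrit (not a multiplier).
#' @slot portal_flow_fraction,hepatic_arterial_flow_factor,other_organs_flow_factor,renal_flow_fraction
#'   multipliers on the healthy regional flows.
#' @slot gfr_fraction fraction of control GFR.
#' @exportClass CirrhosisScalers
setClass("CirrhosisScalers",
  representation(
    cp_class = "character",
    functional_liver_mass = "numeric",
    cyp3a4_fraction = "numeric",
    cyp1a2_fraction = "numeric",
    albumin_fraction = "numeric",
    hematocrit_value = "numeric",
    portal_flow_fraction = "numeric",
    hepatic_arterial_flow_factor = "numeric",
    other_organs_flow_factor = "numeric",
    renal_flow_fraction = "numeric",
    gfr_fraction = "numeric"
  )
)

setValidity("CirrhosisScalers", function(object) {
  msg <- character()
  if (!object@cp_class %in% c("A", "B", "C"))
    msg <- c(msg, "cp_class must be 'A', 'B' or 'C'")
  vals <- c(object@functional_liver_mass, object@cyp3a4_fraction,
            object@cyp1a2_fraction, object@albumin_fraction,
            object@hematocrit_value, object@portal_flow_fraction,
            object@hepatic_arterial_flow_factor, object@other_organs_flow_factor,
            object@renal_flow_fraction, object@gfr_fraction)
  if (any(vals <= 0)) msg <- c(msg, "all scaling factors must be > 0")
  if (object@hematocrit_value >= 1)
    msg <- c(msg, "hematocrit_value is an absolute fraction and must be < 1")
  if (length(msg)) msg else TRUE
})

#' DosingRegimen: route, dose and schedule
#'
#' @slot route "iv_infusion" or "oral".
#' @slot dose mg (or mg/kg when `dose_per_kg` is TRUE; resolved per subject).
#' @slot dose_per_kg logical.
#' @slot infusion_duration minutes (IV only; ignored for oral).
#' @slot n_doses number of administrations.
#' @slot dosing_interval hours between administrations.
#' @exportClass DosingRegimen
setClass("DosingRegimen",
  representation(
    route = "character",
    dose = "numeric",
    dose_per_kg = "logical",
    infusion_duration = "numeric",
    n_doses = "numeric",
    dosing_interval = "numeric"
  )
)

setValidity("DosingRegimen", function(object) {
  msg <- character()
  if (!object@route %in% c("iv_infusion", "oral"))
    msg <- c(msg, "route must be 'iv_infusion' or 'oral'")
  if (object@dose <= 0) msg <- c(msg, "dose must be > 0")
  if (object@route == "iv_infusion" && object@infusion_duration <= 0)
    msg <- c(msg, "infusion_duration must be > 0 for IV infusion")
  if (object@n_doses < 1) msg <- c(msg, "n_doses must be >= 1")
  if (object@n_doses > 1 && object@dosing_interval <= 0)
    msg <- c(msg, "dosing_interval must be > 0 for multiple doses")
  if (length(msg)) msg else TRUE
})

#' PBPKModel: assembled whole-body model for one subject and regimen
#'
#' Produced by [buildModel()]. Holds the physiology, drug, derived partition
#' coefficients, effective clearance terms and absorption parameters that the
#' ODE integrator consumes. The state dimension is the 14 organs plus a gut
#' lumen depot and a cumulative-eliminated audit state (16).
#'
#' @slot physiology a [Physiology-class].
#' @slot drug a [DrugParameters-class].
#' @slot regimen a [DosingRegimen-class].
#' @slot kp named numeric, tissue:plasma partition coefficient per tissue.
#' @slot blood_plasma_ratio blood:plasma total concentration ratio.
#' @slot fu_blood unbound fraction in whole blood.
#' @slot clint_total effective hepatic intrinsic clearance, L/min (calibrated).
#' @slot cl_renal renal plasma clearance, mL/min.
#' @slot ka first-order absorption rate constant, 1/h.
#' @slot fa fraction of an oral dose reaching the gut lumen depot.
#' @slot calibration_factor global multiplier applied to the summed pathway
#'   intrinsic clearances (fixed once, see vignette).
#' @exportClass PBPKModel
setClass("PBPKModel",
  representation(
    physiology = "Physiology",
    drug = "DrugParameters",
    regimen = "DosingRegimen",
    kp = "numeric",
    blood_plasma_ratio = "numeric",
    fu_blood = "numeric",
    clint_total = "numeric",
    cl_renal = "numeric",
    ka = "numeric",
    fa = "numeric",
    calibration_factor = "numeric"
  )
)

setValidity("PBPKModel", function(object) {
  msg <- character()
  if (!identical(sort(names(object@kp)), sort(.TISSUES)))
    msg <- c(msg, "kp must be named with the 12 perfusion-limited tissues")
  if (any(!is.finite(object@kp)) || any(object@kp <= 0))
    msg <- c(msg, "all Kp must be positive and finite")
  if (object@blood_plasma_ratio <= 0)
    msg <- c(msg, "blood_plasma_ratio must be > 0")
  if (object@fu_blood <= 0 || object@fu_blood > 1)
    msg <- c(msg, "fu_blood must be in (0, 1]")
  if (object@clint_total < 0 || object@cl_renal < 0)
    msg <- c(msg, "clearances must be >= 0")
  if (length(msg)) msg else TRUE
})

#' ConcentrationTimeProfile: venous plasma concentration versus time
#'
#' @slot times hours, strictly increasing.
#' @slot concentrations ng/mL, same length as times, all >= 0.
#' @slot label subject or percentile identifier.
#' @slot dose_record the [DosingRegimen-class] that produced the profile.
#' @exportClass ConcentrationTimeProfile
setClass("ConcentrationTimeProfile",
  representation(
    times = "numeric",
    concentrations = "numeric",
    label = "character",
    dose_record = "DosingRegimen"
  )
)

setValidity("ConcentrationTimeProfile", function(object) {
  msg <- character()
  if (length(object@times) != length(object@concentrations))
    msg <- c(msg, "times and concentrations must have equal length")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (any(object@concentrations < 0))
    msg <- c(msg, "concentrations must be >= 0")
  if (length(msg)) msg else TRUE
})

#' PercentileEnvelope: pointwise population prediction envelope
#'
#' @slot times hours.
#' @slot median,p5,p95,p10,p90,min,max ng/mL arrays, one value per time point.
#' @exportClass PercentileEnvelope
setClass("PercentileEnvelope",
  representation(
    times = "numeric",
    median = "numeric",
    p5 = "numeric",
    p95 = "numeric",
    p10 = "numeric",
    p90 = "numeric",
    min = "numeric",
    max = "numeric"
  )
)

setValidity("PercentileEnvelope", function(object) {
  n <- length(object@times)
  if (any(vapply(list(object@median, object@p5, object@p95, object@p10,
                      object@p90, object@min, object@max),
                 length, 1L) != n))
    return("all envelope arrays must match the length of times")
  eps <- 1e-9
  ok <- all(object@min <= object@p5 + eps) && all(object@p5 <= object@median + eps) &&
    all(object@median <= object@p95 + eps) && all(object@p95 <= object@max + eps)
  if (!ok) return("envelope ordering min <= p5 <= median <= p95 <= max violated")
  TRUE
})

#' EvaluationReport: model-qualification statistics for a set of studies
#'
#' Per-study observed/predicted ratios with twofold flags, and per-parameter
#' summaries: arithmetic mean ratio (the as-printed "AFE" convention),
#' geometric average fold error, and RMSE.
#'
#' @slot comparisons data.frame: study_id, route, parameter, observed,
#'   predicted, ratio, fold_error, twofold_pass.
#' @slot summary data.frame: route, parameter, n, mean_ratio, afe_geometric,
#'   rmse, min_ratio, max_ratio, all_twofold.
#' @exportClass EvaluationReport
setClass("EvaluationReport",
  representation(comparisons = "data.frame", summary = "data.frame")
)

#' PopulationSpec: demographic recipe for a virtual population
#'
#' Age and weight are sampled uniformly within `[age_min, age_max]` /
#' `[wt_min, wt_max]`, or normally (truncated to the physiological adult
#' range) when `age_mean`/`wt_mean` and SDs are given instead. Log-normal
#' inter-individual variability multipliers (median 1) are drawn for hepatic
#' intrinsic clearance, absorption rate and the Kp scale.
#'
#' @slot n subjects. @slot female_fraction 0-1.
#' @slot age_min,age_max,age_mean,age_sd years (range or mean/sd; NA unused).
#' @slot wt_min,wt_max,wt_mean,wt_sd kg.
#' @slot cp_class "healthy", "A", "B" or "C".
#' @slot seed integer RNG seed.
#' @slot cv_clint,cv_ka,cv_kp coefficients of variation of the log-normal
#'   inter-individual multipliers.
#' @exportClass PopulationSpec
setClass("PopulationSpec",
  representation(
    n = "numeric",
    female_fraction = "numeric",
    age_min = "numeric", age_max = "numeric",
    age_mean = "numeric", age_sd = "numeric",
    wt_min = "numeric", wt_max = "numeric",
    wt_mean = "numeric", wt_sd = "numeric",
    cp_class = "character",
    seed = "numeric",
    cv_clint = "numeric", cv_ka = "numeric", cv_kp = "numeric"
  )
)

setValidity("PopulationSpec", function(object) {
  msg <- character()
  if (object@n < 1) msg <- c(msg, "n must be >= 1")
  if (object@female_fraction < 0 || object@female_fraction > 1)
    msg <- c(msg, "female_fraction must be in [0, 1]")
  has_age_range <- !is.na(object@age_min) && !is.na(object@age_max)
  has_age_norm <- !is.na(object@age_mean) && !is.na(object@age_sd)
  if (!has_age_range && !has_age_norm)
    msg <- c(msg, "age must be given as a range or mean/sd")
  if (has_age_range && object@age_max < object@age_min)
    msg <- c(msg, "empty age range")
  has_wt_range <- !is.na(object@wt_min) && !is.na(object@wt_max)
  has_wt_norm <- !is.na(object@wt_mean) && !is.na(object@wt_sd)
  if (!has_wt_range && !has_wt_norm)
    msg <- c(msg, "weight must be given as a range or mean/sd")
  if (has_wt_range && object@wt_max < object@wt_min)
    msg <- c(msg, "empty weight range")
  if (!object@cp_class %in% c("healthy", "A", "B", "C"))
    msg <- c(msg, "cp_class must be 'healthy', 'A', 'B' or 'C'")
  if (any(c(object@cv_clint, object@cv_ka, object@cv_kp) < 0))
    msg <- c(msg, "CVs must be >= 0")
  if (length(msg)) msg else TRUE
})

#' SyntheticProfileSpec: recipe for a synthetic "observed" profile
#'
#' Closed-form one- or two-compartment disposition with multiplicative
#' log-normal residual noise and a lower limit of quantification, emulating
#' clinical concentration-time data digitized from literature figures.
#'
#' @slot model "one_compartment" or "two_compartment".
#' @slot cl clearance, L/h. @slot v1 central volume, L.
#' @slot q inter-compartmental clearance, L/h (two-compartment only).
#' @slot v2 peripheral volume, L (two-compartment only).
#' @slot ka 1/h (oral only). @slot f bioavailable fraction (oral only).
#' @slot noise_cv multiplicative log-normal CV (0 disables noise).
#' @slot lloq ng/mL; sampled values below it are dropped.
#' @slot sampling_times hours.
#' @slot seed integer RNG seed.
#' @exportClass SyntheticProfileSpec
setClass("SyntheticProfileSpec",
  representation(
    model = "character",
    cl = "numeric", v1 = "numeric", q = "numeric", v2 = "numeric",
    ka = "numeric", f = "numeric",
    noise_cv = "numeric", lloq = "numeric",
    sampling_times = "numeric", seed = "numeric"
  )
)

setValidity("SyntheticProfileSpec", function(object) {
  msg <- character()
  if (!object@model %in% c("one_compartment", "two_compartment"))
    msg <- c(msg, "model must be 'one_compartment' or 'two_compartment'")
  if (object@cl <= 0 || object@v1 <= 0)
    msg <- c(msg, "CL and V1 must be > 0")
  if (object@model == "two_compartment" && (object@q <= 0 || object@v2 <= 0))
    msg <- c(msg, "Q and V2 must be > 0 for the two-compartment model")
  if (object@noise_cv < 0) msg <- c(msg, "noise_cv must be >= 0")
  if (length(object@sampling_times) < 1 || any(object@sampling_times < 0))
    msg <- c(msg, "sampling_times must be non-negative")
  if (length(msg)) msg else TRUE
})
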