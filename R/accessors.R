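#' Accessors for physiology objects
#'
#' Slot access goes through these functions rather than `@`. Flows are
#' reported in L/min. The portal flow is the sum of the gut and spleen
#' regional flows (both drain into the portal vein); the liver row of the
#' organ table carries the hepatic arterial flow only.
#'
#' @param object a [Physiology-class].
#' @return numeric scalar (flows, weight, hematocrit, GFR) or data.frame
#'   (`organTable`).
#' @name physiology-accessors
NULL

#' @rdname physiology-accessors
#' @export
setGeneric("organTable", function(object) standardGeneric("organTable"))
#' @rdname physiology-accessors
#' @export
setMethod("organTable", "Physiology", function(object) object@organs)

#' @rdname physiology-accessors
#' @export
setGeneric("bodyWeight", function(object) standardGeneric("bodyWeight"))
#' @rdname physiology-accessors
#' @export
setMethod("bodyWeight", "Physiology", function(object) object@body_weight)

#' @rdname physiology-accessors
#' @export
setGeneric("hematocrit", function(object) standardGeneric("hematocrit"))
#' @rdname physiology-accessors
#' @export
setMethod("hematocrit", "Physiology", function(object) object@hematocrit)

#' @rdname physiology-accessors
#' @export
setGeneric("gfr", function(object) standardGeneric("gfr"))
#' @rdname physiology-accessors
#' @export
setMethod("gfr", "Physiology", function(object) object@gfr)

#' @rdname physiology-accessors
#' @export
setGeneric("cpClass", function(object) standardGeneric("cpClass"))
#' @rdname physiology-accessors
#' @export
setMethod("cpClass", "Physiology", function(object) object@cp_class)

.organFlow <- function(phys, organ) {
  org <- phys@organs
  org$flow_l_min[org$organ == organ]
}

#' @rdname physiology-accessors
#' @export
setGeneric("portalFlow", function(object) standardGeneric("portalFlow"))
#' @rdname physiology-accessors
#' @export
setMethod("portalFlow", "Physiology", function(object)
  .organFlow(object, "gut") + .organFlow(object, "spleen"))

#' @rdname physiology-accessors
#' @export
setGeneric("hepaticArterialFlow",
           function(object) standardGeneric("hepaticArterialFlow"))
#' @rdname physiology-accessors
#' @export
setMethod("hepaticArterialFlow", "Physiology", function(object)
  .organFlow(object, "liver"))

#' @rdname physiology-accessors
#' @export
setGeneric("renalFlow", function(object) standardGeneric("renalFlow"))
#' @rdname physiology-accessors
#' @export
setMethod("renalFlow", "Physiology", function(object)
  .organFlow(object, "kidney"))

#' @rdname physiology-accessors
#' @export
setGeneric("cardiacOutput", function(object) standardGeneric("cardiacOutput"))
#' @rdname physiology-accessors
#' @export
setMethod("cardiacOutput", "Physiology", function(object)
  .organFlow(object, "lung"))

#' Total hepatic blood inflow (portal + hepatic arterial), L/min
#' @param object a [Physiology-class].
#' @export
setGeneric("liverInflow", function(object) standardGeneric("liverInflow"))
#' @rdname liverInflow
#' @export
setMethod("liverInflow", "Physiology", function(object)
  portalFlow(object) + hepaticArterialFlow(object))

#' Coerce a concentration-time profile to a tidy data.frame
#'
#' Columns: `label`, `time_h`, `conc_ng_per_ml` (the tidy profile interchange
#' format used for CSV export/import).
#'
#' @param x a [ConcentrationTimeProfile-class].
#' @param row.names,optional,... ignored (S3 signature compatibility).
#' @exportS3Method base::as.data.frame
as.data.frame.ConcentrationTimeProfile <- function(x, row.names = NULL,
                                                   optional = FALSE, ...) {
  data.frame(label = x@label, time_h = x@times,
             conc_ng_per_ml = x@concentrations)
}

#' Coerce a percentile envelope to a tidy data.frame
#'
#' One row per time point, columns for each envelope statistic.
#'
#' @param x a [PercentileEnvelope-class].
#' @param row.names,optional,... ignored (S3 signature compatibility).
#' @exportS3Method base::as.data.frame
as.data.frame.PercentileEnvelope <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  data.frame(time_h = x@times, median = x@median, p5 = x@p5, p95 = x@p95,
             p10 = x@p10, p90 = x@p90, min = x@min, max = x@max)
}

setMethod("show", "DrugParameters", function(object) {
  cat("DrugParameters:", object@name, "\n")
  cat(sprintf("  MW %.1f g/mol | logP %.2f | pKa(base) %.2f | fu,p %.2f (%s)\n",
              object@molecular_weight, object@log_p, object@pka_base,
              object@fu_plasma, object@binding_protein))
  cat(sprintf("  CLint CYP1A2 %.3f, CYP3A4 %.3f L/min | renal %.2f mL/min/kg\n",
              object@clint_cyp1a2, object@clint_cyp3a4,
              object@renal_clearance_specific))
})

setMethod("show", "Physiology", function(object) {
  cat(sprintf("Physiology (%s): %s, %.0f y, %.1f kg\n",
              object@cp_class, object@sex, object@age, object@body_weight))
  cat(sprintf("  cardiac output %.2f L/min | liver inflow %.2f (portal %.2f + arterial %.2f)\n",
              cardiacOutput(object), liverInflow(object), portalFlow(object),
              hepaticArterialFlow(object)))
  cat(sprintf("  hematocrit %.2f | GFR %.1f mL/min | albumin x%.2f | CYP1A2 x%.2f CYP3A4 x%.2f | liver mass x%.2f\n",
              object@hematocrit, object@gfr, object@albumin_factor,
              object@cyp1a2_abundance, object@cyp3a4_abundance,
              object@functional_liver_mass_factor))
})

setMethod("show", "CirrhosisScalers", function(object) {
  cat(sprintf("CirrhosisScalers CP-%s: liver mass %.2f | CYP1A2 %.2f CYP3A4 %.3f | albumin %.2f\n",
              object@cp_class, object@functional_liver_mass,
              object@cyp1a2_fraction, object@cyp3a4_fraction,
              object@albumin_fraction))
  cat(sprintf("  hematocrit %.2f | flows: portal x%.2f, hepatic arterial x%.2f, other x%.2f, renal x%.2f | GFR x%.2f\n",
              object@hematocrit_value, object@portal_flow_fraction,
              object@hepatic_arterial_flow_factor,
              object@other_organs_flow_factor, object@renal_flow_fraction,
              object@gfr_fraction))
})

setMethod("show", "DosingRegimen", function(object) {
  dose <- if (object@dose_per_kg) sprintf("%.2f mg/kg", object@dose)
          else sprintf("%g mg", object@dose)
  sched <- if (object@n_doses > 1)
    sprintf(", %d doses q%gh", as.integer(object@n_doses), object@dosing_interval)
  else ""
  extra <- if (object@route == "iv_infusion")
    sprintf(" over %g min", object@infusion_duration) else ""
  cat(sprintf("DosingRegimen: %s %s%s%s\n", object@route, dose, extra, sched))
})

setMethod("show", "PBPKModel", function(object) {
  cat("PBPKModel (16-state whole-body, perfusion-limited)\n")
  show(object@drug)
  show(object@physiology)
  show(object@regimen)
  cat(sprintf("  B:P %.3f | fu,blood %.3f | CLint,total %.3f L/min (calibration x%.2f) | renal CL %.2f mL/min | ka %.2f /h, Fa %.2f\n",
              object@blood_plasma_ratio, object@fu_blood, object@clint_total,
              object@calibration_factor, object@cl_renal, object@ka, object@fa))
})

setMethod("show", "ConcentrationTimeProfile", function(object) {
  cat(sprintf("ConcentrationTimeProfile '%s': %d points, %.2f-%.2f h, Cmax %.2f ng/mL\n",
              object@label, length(object@times), min(object@times),
              max(object@times), max(object@concentrations)))
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport:", nrow(object@comparisons), "study comparisons\n")
  print(object@summary, row.names = FALSE, digits = 4)
})
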