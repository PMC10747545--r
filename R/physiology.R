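#' Build a reference healthy adult physiology
#'
#' Constructs the 14-compartment healthy physiology from the packaged
#' reference-human table (ICRP-style organ volumes, regional blood flows and
#' Poulin-Theil tissue composition for a 73-kg adult). Organ volumes and
#' regional flows scale linearly with body weight (cardiac output
#' proportional to weight); tissue composition, hematocrit (0.47) and GFR
#' (116 mL/min) are weight-invariant defaults of the reference table. Age and
#' sex are validated covariates carried on the object; within the supported
#' adult range the anatomy is driven by weight alone (see the methods
#' vignette).
#'
#' @param body_weight kg, in `[40, 150]`.
#' @param age years, in `[18, 85]`.
#' @param sex "male" or "female".
#' @return a [Physiology-class] with all disease factors at 1.
#' @examples
#' phys <- buildReferencePhysiology(73, 30, "male")
#' cardiacOutput(phys)
#' @export
buildReferencePhysiology <- function(body_weight = 73, age = 30,
                                     sex = c("male", "female")) {
  sex <- match.arg(sex)
  if (!is.numeric(body_weight) || length(body_weight) != 1 ||
      body_weight < 40 || body_weight > 150)
    stop("body_weight must be a single value in [40, 150] kg")
  if (!is.numeric(age) || length(age) != 1 || age < 18 || age > 85)
    stop("age must be a single value in [18, 85] years")

  ref <- utils::read.delim(
    system.file("extdata", "reference_human.tsv", package = "cirrhPBPK"),
    check.names = FALSE)
  stopifnot(identical(ref$organ, .ORGANS))
  scale <- body_weight / 73
  ref$volume_l <- ref$volume_l * scale
  ref$flow_l_min <- ref$flow_l_min * scale

  new("Physiology",
      organs = ref, body_weight = body_weight, age = age, sex = sex,
      hematocrit = 0.47, gfr = 116 * scale, albumin_factor = 1,
      cyp1a2_abundance = 1, cyp3a4_abundance = 1,
      functional_liver_mass_factor = 1, cp_class = "healthy")
}

#' Load the packaged Child-Pugh physiological scaling factors
#'
#' Returns the packaged scaler set for one Child-Pugh class: functional liver
#' mass, per-enzyme CYP activity, albumin and GFR as fractions of healthy
#' control; regional blood flows as multipliers; hematocrit as an absolute
#' value. The Child-Pugh columns are interpreted as multiplicative fractions
#' of control throughout, except hematocrit (absolute); the control column of
#' the source table mixes absolute values with simulator-internal quantities
#' and is carried for reference only (see vignette).
#'
#' @param cp_class "A", "B" or "C".
#' @return a [CirrhosisScalers-class].
#' @examples
#' loadCpScalers("C")
#' @export
loadCpScalers <- function(cp_class) {
  if (!is.character(cp_class) || length(cp_class) != 1 ||
      !cp_class %in% c("A", "B", "C"))
    stop("cp_class must be one of 'A', 'B', 'C'")
  tab <- loadFixture("table6")
  col <- paste0("cp_", tolower(cp_class))
  val <- function(p) tab[[col]][tab$parameter == p]
  new("CirrhosisScalers",
      cp_class = cp_class,
      functional_liver_mass = val("functional_liver_mass"),
      cyp3a4_fraction = val("cyp3a4"),
      cyp1a2_fraction = val("cyp1a2"),
      albumin_fraction = val("albumin"),
      hematocrit_value = val("hematocrit"),
      portal_flow_fraction = val("portal_flow"),
      hepatic_arterial_flow_factor = val("hepatic_arterial_flow"),
      other_organs_flow_factor = val("other_organs_flow"),
      renal_flow_fraction = val("renal_flow"),
      gfr_fraction = val("gfr"))
}

#' Transform a healthy physiology into a Child-Pugh cirrhotic one
#'
#' Returns a new [Physiology-class] with
#' \itemize{
#'   \item portal (gut + spleen) flow multiplied by the portal fraction,
#'   \item hepatic arterial flow multiplied by its factor,
#'   \item renal flow multiplied by its fraction,
#'   \item all other systemic organ flows multiplied by the single
#'     "other organs" factor (hyperdynamic circulation),
#'   \item cardiac output (lung flow) recomputed as the sum of the scaled
#'     regional flows,
#'   \item GFR, albumin factor and CYP pathway activities multiplied by their
#'     fractions,
#'   \item liver volume scaled by the functional liver mass fraction,
#'   \item hematocrit set to the absolute cirrhotic value.
#' }
#' The input object is unmodified. Applying scalers to an already-scaled
#' physiology is an error.
#'
#' @param phys a healthy [Physiology-class] (all relative factors at 1).
#' @param scalers a [CirrhosisScalers-class], e.g. from [loadCpScalers()].
#' @return a new [Physiology-class] with `cpClass(phys)` set to the class.
#' @examples
#' cpC <- applyCirrhosis(buildReferencePhysiology(73, 30, "male"),
#'                       loadCpScalers("C"))
#' gfr(cpC)
#' @export
applyCirrhosis <- function(phys, scalers) {
  stopifnot(is(phys, "Physiology"), is(scalers, "CirrhosisScalers"))
  if (phys@cp_class != "healthy" ||
      phys@albumin_factor != 1 || phys@cyp1a2_abundance != 1 ||
      phys@cyp3a4_abundance != 1 || phys@functional_liver_mass_factor != 1)
    stop("physiology is already scaled; cirrhosis scalers apply to a healthy physiology only")

  org <- phys@organs
  i <- function(name) which(org$organ == name)
  other <- setdiff(.TISSUES, c("lung", "liver", "gut", "spleen", "kidney"))

  org$flow_l_min[org$organ %in% other] <-
    org$flow_l_min[org$organ %in% other] * scalers@other_organs_flow_factor
  org$flow_l_min[i("gut")] <- org$flow_l_min[i("gut")] * scalers@portal_flow_fraction
  org$flow_l_min[i("spleen")] <- org$flow_l_min[i("spleen")] * scalers@portal_flow_fraction
  org$flow_l_min[i("liver")] <- org$flow_l_min[i("liver")] * scalers@hepatic_arterial_flow_factor
  org$flow_l_min[i("kidney")] <- org$flow_l_min[i("kidney")] * scalers@renal_flow_fraction
  org$flow_l_min[i("lung")] <-
    sum(org$flow_l_min[org$organ %in% setdiff(.TISSUES, "lung")])
  org$volume_l[i("liver")] <- org$volume_l[i("liver")] * scalers@functional_liver_mass

  new("Physiology",
      organs = org, body_weight = phys@body_weight, age = phys@age,
      sex = phys@sex,
      hematocrit = scalers@hematocrit_value,
      gfr = phys@gfr * scalers@gfr_fraction,
      albumin_factor = phys@albumin_factor * scalers@albumin_fraction,
      cyp1a2_abundance = phys@cyp1a2_abundance * scalers@cyp1a2_fraction,
      cyp3a4_abundance = phys@cyp3a4_abundance * scalers@cyp3a4_fraction,
      functional_liver_mass_factor =
        phys@functional_liver_mass_factor * scalers@functional_liver_mass,
      cp_class = scalers@cp_class)
}

#' Identity scalers (testing aid)
#'
#' All multipliers 1 and hematocrit at the healthy 0.47, so that
#' [applyCirrhosis()] returns a physiology equal to its input field-by-field
#' (apart from the stamped class label).
#'
#' @param cp_class label to stamp on the result.
#' @return a [CirrhosisScalers-class].
#' @export
identityScalers <- function(cp_class = "A") {
  new("CirrhosisScalers", cp_class = cp_class,
      functional_liver_mass = 1, cyp3a4_fraction = 1, cyp1a2_fraction = 1,
      albumin_fraction = 1, hematocrit_value = 0.47,
      portal_flow_fraction = 1, hepatic_arterial_flow_factor = 1,
      other_organs_flow_factor = 1, renal_flow_fraction = 1, gfr_fraction = 1)
}
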