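## package-level cache (reference tables, calibration constant)
.pkgCache <- new.env(parent = emptyenv())

## First-order absorption rate constant (1/h) of the packaged ondansetron
## model, fixed once so that the reference healthy adult's predicted oral
## 8 mg Cmax falls at the centre of the reference predictions (~29 ng/mL);
## see the methods vignette ("Absorption calibration").
.ONDANSETRON_KA <- 0.9

#' Construct a dosing regimen
#'
#' @param route "iv_infusion" or "oral".
#' @param dose mg, or mg/kg when `dose_per_kg = TRUE` (resolved against each
#'   subject's body weight at simulation time).
#' @param dose_per_kg logical.
#' @param infusion_duration minutes (IV only).
#' @param n_doses number of administrations.
#' @param dosing_interval hours between administrations.
#' @return a [DosingRegimen-class].
#' @examples
#' newDosingRegimen("iv_infusion", 8, infusion_duration = 5)
#' @export
newDosingRegimen <- function(route = c("iv_infusion", "oral"), dose,
                             dose_per_kg = FALSE, infusion_duration = 5,
                             n_doses = 1, dosing_interval = 24) {
  route <- match.arg(route)
  new("DosingRegimen", route = route, dose = dose, dose_per_kg = dose_per_kg,
      infusion_duration = infusion_duration, n_doses = n_doses,
      dosing_interval = dosing_interval)
}

#' Fixed clearance calibration factor of the packaged ondansetron model
#'
#' Computed once per session from the reference healthy adult (see
#' [calibrationFactor()]) and cached; a pure function of the packaged drug
#' and reference-physiology tables, so it is a model constant.
#' @return dimensionless scalar.
#' @export
ondansetronCalibration <- function() {
  if (is.null(.pkgCache$calib)) {
    .pkgCache$calib <- calibrationFactor(loadDrugParameters(),
                                         buildReferencePhysiology())
  }
  .pkgCache$calib
}

#' Assemble the whole-body PBPK model for one subject
#'
#' Combines drug, physiology and regimen into the 16-state perfusion-limited
#' model: for every tissue
#' \deqn{V_t dC_t/dt = Q_t (C_{art} - C_t \cdot B\!:\!P / Kp_t),}
#' the liver receives portal (gut + spleen) plus arterial inflow and carries
#' the well-stirred elimination term on its outflow blood concentration, the
#' kidney carries renal clearance on arterial plasma, and for the oral route
#' a first-order gut-lumen depot feeds the portal stream so that first-pass
#' extraction emerges mechanistically.
#'
#' @param drug a [DrugParameters-class].
#' @param phys a [Physiology-class] (healthy or Child-Pugh scaled).
#' @param regimen a [DosingRegimen-class].
#' @param ka first-order absorption rate constant, 1/h.
#' @param fa fraction of the oral dose reaching the gut lumen depot.
#' @param calibration_factor global intrinsic-clearance multiplier; default
#'   is the frozen package calibration ([ondansetronCalibration()]).
#' @param albumin_effect apply the albumin-driven unbound-fraction adjustment
#'   inside the clearance model (off by default; see vignette).
#' @param clint_multiplier,ka_multiplier,kp_scale inter-individual
#'   variability multipliers (1 = typical subject).
#' @return a [PBPKModel-class].
#' @examples
#' mod <- buildModel(loadDrugParameters(), buildReferencePhysiology(),
#'                   newDosingRegimen("iv_infusion", 8, infusion_duration = 5))
#' @export
buildModel <- function(drug, phys, regimen, ka = .ONDANSETRON_KA, fa = 1,
                       calibration_factor = NULL, albumin_effect = FALSE,
                       clint_multiplier = 1, ka_multiplier = 1, kp_scale = 1) {
  stopifnot(is(drug, "DrugParameters"), is(phys, "Physiology"),
            is(regimen, "DosingRegimen"))
  if (is.null(calibration_factor)) calibration_factor <- ondansetronCalibration()

  alb <- if (albumin_effect) phys@albumin_factor else 1
  fb <- fuBlood(drug, hematocrit(phys), albumin_factor = alb)
  kp <- partitionSet(drug, phys) * kp_scale
  if (any(is.na(kp))) stop("missing Kp for at least one organ")

  clint <- totalIntrinsicClearance(drug, phys, calibration_factor) *
    clint_multiplier
  ## renal clearance scales with body weight and the GFR fraction of control
  gfr_fraction <- gfr(phys) / (116 * bodyWeight(phys) / 73)
  cl_renal <- renalClAbsolute(drug, bodyWeight(phys), gfr_fraction)

  new("PBPKModel",
      physiology = phys, drug = drug, regimen = regimen,
      kp = kp, blood_plasma_ratio = fb$blood_plasma_ratio,
      fu_blood = fb$fu_blood, clint_total = clint, cl_renal = cl_renal,
      ka = ka * ka_multiplier, fa = fa,
      calibration_factor = calibration_factor)
}

## Flatten a PBPKModel + resolved dose into the parameter vector consumed by
## the compiled right-hand side (units: L, h, ug).
.modelParms <- function(model, dose_mg) {
  phys <- model@physiology
  org <- phys@organs
  ti <- match(.TISSUES, org$organ)
  Q <- org$flow_l_min[ti] * 60                      # L/h
  V <- org$volume_l[ti]
  R <- model@blood_plasma_ratio / model@kp[.TISSUES]
  reg <- model@regimen
  oral <- reg@route == "oral"
  t_inf <- if (oral) 0 else reg@infusion_duration / 60
  dose_ug <- dose_mg * 1000
  rate <- if (oral) 0 else dose_ug / t_inf
  c(Q, V, R,
    org$volume_l[org$organ == "arterial blood"],
    org$volume_l[org$organ == "venous blood"],
    model@clint_total * model@fu_blood * 60,        # L/h, unbound hepatic
    model@cl_renal * 60 / 1000,                     # L/h, plasma
    model@blood_plasma_ratio,
    model@ka, as.numeric(oral), rate, t_inf,
    reg@n_doses, reg@dosing_interval)
}

.stateNames <- c(.TISSUES, "arterial", "venous", "depot", "eliminated")

## Output grid: regular reporting grid (dt_out) augmented, for IV infusions,
## with a dense window over the infusion and early distribution phase so that
## the end-of-infusion peak and the steep early decay are resolved (otherwise
## the trapezoidal AUC of a short infusion loses several percent).
.outputTimes <- function(regimen, t_end, dt_out) {
  times <- seq(0, t_end, by = dt_out)
  if (regimen@route == "iv_infusion") {
    t_inf <- regimen@infusion_duration / 60
    starts <- (seq_len(regimen@n_doses) - 1) * regimen@dosing_interval
    dense <- unlist(lapply(starts, function(s)
      s + c(seq(0, 2 * t_inf, by = t_inf / 25),
            seq(2 * t_inf, min(1, t_end), by = 0.01))))
    times <- sort(unique(c(times, dense[dense <= t_end])))
  }
  times
}

## Integrate the model; returns the full deSolve matrix on the requested
## output grid (internal union with dose-boundary times is dropped).
.simulateStates <- function(model, dose_mg, t_end, dt_out,
                            rtol = 1e-9, atol = 1e-6) {
  reg <- model@regimen
  oral <- reg@route == "oral"
  times <- .outputTimes(reg, t_end, dt_out)
  bounds <- if (oral) numeric() else {
    k <- seq_len(reg@n_doses) - 1
    c(k * reg@dosing_interval, k * reg@dosing_interval +
        reg@infusion_duration / 60)
  }
  all_t <- sort(unique(c(times, bounds[bounds <= t_end])))
  y0 <- stats::setNames(numeric(16), .stateNames)
  events <- NULL
  if (oral) {
    dose_times <- (seq_len(reg@n_doses) - 1) * reg@dosing_interval
    dose_times <- dose_times[dose_times <= t_end]
    events <- list(data = data.frame(
      var = "depot", time = dose_times,
      value = model@fa * dose_mg * 1000, method = "add"))
    all_t <- sort(unique(c(all_t, dose_times)))
  }
  out <- deSolve::ode(y = y0, times = all_t, func = "pbpk_derivs",
                      parms = .modelParms(model, dose_mg),
                      dllname = "cirrhPBPK", initfunc = "pbpk_initmod",
                      method = "lsoda", rtol = rtol, atol = atol,
                      events = events, maxsteps = 50000)
  if (attr(out, "istate")[1] < 0)
    stop("ODE solver failed to converge (istate ",
         attr(out, "istate")[1], ")")
  out[out[, "time"] %in% times, , drop = FALSE]
}

## Resolve a regimen's dose in mg for a given subject weight.
.resolveDose <- function(regimen, body_weight) {
  if (regimen@dose_per_kg) regimen@dose * body_weight else regimen@dose
}

#' Simulate one subject's concentration-time profile
#'
#' Integrates the whole-body ODE system with a stiff-capable adaptive solver
#' (lsoda, relative tolerance 1e-9) and returns the venous plasma
#' concentration in ng/mL on a regular output grid. Deterministic for fixed
#' inputs.
#'
#' @param model a [PBPKModel-class] from [buildModel()].
#' @param t_end simulation end, h.
#' @param dt_out output grid step, h (default 0.1 h over 0-24 h).
#' @param label profile label.
#' @return a [ConcentrationTimeProfile-class].
#' @examples
#' mod <- buildModel(loadDrugParameters(), buildReferencePhysiology(),
#'                   newDosingRegimen("iv_infusion", 8, infusion_duration = 5))
#' prof <- simulateIndividual(mod)
#' prof
#' @export
simulateIndividual <- function(model, t_end = 24, dt_out = 0.1,
                               label = "subject") {
  stopifnot(is(model, "PBPKModel"), t_end > 0)
  dose_mg <- .resolveDose(model@regimen, bodyWeight(model@physiology))
  out <- .simulateStates(model, dose_mg, t_end, dt_out)
  v_ven <- model@physiology@organs$volume_l[
    model@physiology@organs$organ == "venous blood"]
  conc <- out[, "venous"] / v_ven / model@blood_plasma_ratio  # ug/L = ng/mL
  conc[conc < 0] <- 0   # clip solver noise at the atol scale
  new("ConcentrationTimeProfile", times = as.numeric(out[, "time"]),
      concentrations = as.numeric(conc), label = label,
      dose_record = model@regimen)
}

#' Mass-balance audit of a simulation
#'
#' Re-integrates the model and checks, at every output time, that the
#' administered amount equals the drug in all compartments plus the
#' cumulative eliminated amount. Returns the maximum relative residual
#' (should be at the solver-tolerance scale, <= 1e-6).
#'
#' @param model a [PBPKModel-class].
#' @param t_end,dt_out output grid (defaults as in [simulateIndividual()]).
#' @return maximum relative mass-balance residual (dimensionless).
#' @export
massBalanceAudit <- function(model, t_end = 24, dt_out = 0.1) {
  reg <- model@regimen
  dose_mg <- .resolveDose(reg, bodyWeight(model@physiology))
  dose_ug <- dose_mg * 1000
  out <- .simulateStates(model, dose_mg, t_end, dt_out)
  t <- out[, "time"]
  in_system <- rowSums(out[, .stateNames, drop = FALSE])
  if (reg@route == "oral") {
    ## a depot event at exactly t reports pre-event state on that output row
    n_given <- vapply(t, function(tt)
      sum((seq_len(reg@n_doses) - 1) * reg@dosing_interval < tt), numeric(1))
    administered <- model@fa * dose_ug * n_given
  } else {
    t_inf <- reg@infusion_duration / 60
    administered <- vapply(t, function(tt) {
      starts <- (seq_len(reg@n_doses) - 1) * reg@dosing_interval
      sum(pmin(pmax(tt - starts, 0), t_inf)) / t_inf * dose_ug
    }, numeric(1))
  }
  keep <- administered > 0
  max(abs(administered[keep] - in_system[keep]) / administered[keep])
}

## Pure-R mirror of the compiled right-hand side; retained as an independent
## implementation for cross-checking the C code in the test suite.
.pbpkDerivsR <- function(t, y, p) {
  Q <- p[1:12]; V <- p[13:24]; R <- p[25:36]
  v_art <- p[37]; v_ven <- p[38]; clh <- p[39]; clr <- p[40]; bp <- p[41]
  ka <- p[42]; oral <- p[43] > 0.5; rate0 <- p[44]; t_inf <- p[45]
  nd <- p[46]; tau <- p[47]
  Cart <- y[13] / v_art; Cven <- y[14] / v_ven
  Cv <- y[1:12] / V * R
  dy <- numeric(16)
  dy[1] <- Q[1] * (Cven - Cv[1])
  simple <- c(2, 3, 4, 5, 6, 7, 12)
  dy[simple] <- Q[simple] * (Cart - Cv[simple])
  dy[9] <- Q[9] * (Cart - Cv[9])
  dy[10] <- Q[10] * (Cart - Cv[10])
  q_out <- Q[8] + Q[9] + Q[10]
  absorb <- if (oral) ka * y[15] else 0
  dy[8] <- Q[8] * Cart + Q[9] * Cv[9] + Q[10] * Cv[10] + absorb -
    q_out * Cv[8] - clh * Cv[8]
  dy[11] <- Q[11] * (Cart - Cv[11]) - clr * Cart / bp
  venous_in <- sum(Q[simple] * Cv[simple]) + Q[11] * Cv[11] + q_out * Cv[8]
  dy[13] <- Q[1] * Cv[1] - sum(Q[2:12]) * Cart
  rate <- 0
  if (!oral) {
    starts <- (seq_len(nd) - 1) * tau
    rate <- rate0 * sum(t >= starts & t < starts + t_inf)
  }
  dy[14] <- venous_in - Q[1] * Cven + rate
  dy[15] <- if (oral) -ka * y[15] else 0
  dy[16] <- clh * Cv[8] + clr * Cart / bp
  list(dy)
}
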