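.profileVectors <- function(profile) {
  if (is(profile, "ConcentrationTimeProfile"))
    list(t = profile@times, c = profile@concentrations)
  else if (is.data.frame(profile))
    list(t = profile$time_h, c = profile$conc_ng_per_ml)
  else stop("profile must be a ConcentrationTimeProfile or a tidy data.frame")
}

#' Linear-up / log-down trapezoidal AUC
#'
#' Area under the concentration-time curve over the observed range. Rising or
#' flat segments (and segments touching zero) use the linear trapezoid;
#' strictly decreasing positive segments use the log trapezoid
#' `(C1 - C2) / ln(C1/C2) * dt` — standard noncompartmental practice.
#'
#' @param profile a [ConcentrationTimeProfile-class] or a tidy data.frame
#'   with columns `time_h`, `conc_ng_per_ml`.
#' @return AUC0-t, ng.h/mL.
#' @examples
#' prof <- data.frame(time_h = 0:5, conc_ng_per_ml = rep(10, 6))
#' aucTrapezoid(prof)  # 50
#' @export
aucTrapezoid <- function(profile) {
  pv <- .profileVectors(profile)
  t <- pv$t; cc <- pv$c
  if (length(t) < 3) stop("at least 3 profile points are required")
  if (any(diff(t) <= 0)) stop("times must be strictly increasing")
  dt <- diff(t)
  c1 <- cc[-length(cc)]; c2 <- cc[-1]
  lin <- (c1 + c2) / 2 * dt
  logd <- c2 < c1 & c2 > 0 & c1 > 0
  lin[logd] <- (c1[logd] - c2[logd]) / log(c1[logd] / c2[logd]) * dt[logd]
  sum(lin)
}

#' Terminal elimination rate constant
#'
#' Log-linear regression on the terminal phase. Candidate windows are the
#' suffixes of the profile strictly after Tmax with at least `min_points`
#' points; the window maximizing the adjusted R-squared of the
#' log-concentration regression is selected (ties broken toward the longer
#' window). Errors if fewer than 3 usable points remain, if terminal
#' concentrations are non-positive, or if the profile is still rising at the
#' last sample (no terminal phase).
#'
#' @inheritParams aucTrapezoid
#' @param min_points minimum window size (>= 3).
#' @return list with `lambda_z` (1/h), `intercept` (log ng/mL), `n_points`,
#'   `adj_r_squared`.
#' @export
lambdaZ <- function(profile, min_points = 3) {
  pv <- .profileVectors(profile)
  t <- pv$t; cc <- pv$c
  imax <- which.max(cc)
  idx <- seq.int(imax + 1L, length(cc))
  if (imax >= length(cc) || length(idx) < min_points)
    stop("no terminal phase: profile still rising near the last sample")
  t <- t[idx]; cc <- cc[idx]
  if (any(cc <= 0)) {
    keep <- cc > 0
    ## trailing BLQ values are dropped; embedded non-positives are an error
    if (any(diff(keep) == 1)) stop("non-positive terminal concentrations")
    t <- t[keep]; cc <- cc[keep]
    if (length(t) < min_points) stop("non-positive terminal concentrations")
  }
  y <- log(cc)
  n <- length(t)
  ## all suffix windows ending at the last sample, evaluated at once via
  ## reverse cumulative sums (regression statistics in closed form)
  rc <- function(v) rev(cumsum(rev(v)))
  ni <- n - seq_len(n) + 1
  Sx <- rc(t); Sy <- rc(y); Sxx <- rc(t^2); Sxy <- rc(t * y); Syy <- rc(y^2)
  vx <- Sxx - Sx^2 / ni
  vy <- Syy - Sy^2 / ni
  cxy <- Sxy - Sx * Sy / ni
  slope <- cxy / vx
  r2 <- ifelse(vy > 0, cxy^2 / (vx * vy), 1)
  adj <- 1 - (1 - r2) * (ni - 1) / (ni - 2)
  ok <- ni >= min_points & slope < 0 & is.finite(adj)
  if (!any(ok)) stop("no negative-slope terminal window found")
  adj[!ok] <- -Inf
  ## ties in adjusted R-squared go to the longer window (earlier start)
  start <- which(adj >= max(adj) - 1e-12)[1]
  list(lambda_z = -slope[start],
       intercept = (Sy[start] - slope[start] * Sx[start]) / ni[start],
       n_points = ni[start], adj_r_squared = adj[start])
}

#' Noncompartmental PK summary of one profile
#'
#' Computes AUC0-t (linear-up/log-down), the terminal rate constant and
#' half-life, AUC0-inf = AUC0-t + Clast/lambda_z, Cmax/Tmax, and clearance
#' `CL = dose / AUC0-inf` scaled to mL/min/kg (CL for IV, CL/F for oral —
#' the apparent oral clearance uncorrected for bioavailability). A warning
#' flag is set when the extrapolated AUC fraction exceeds 0.2.
#'
#' @inheritParams aucTrapezoid
#' @param regimen the [DosingRegimen-class] administered (dose resolved per
#'   kg when applicable).
#' @param body_weight subject body weight, kg.
#' @param cmax_times optional clinical sampling schedule (hours): when given,
#'   Cmax and Tmax are read only at profile points on this schedule, mirroring
#'   discrete clinical sampling; AUC and the terminal fit still use the full
#'   profile. Used by the population layer, where the solver output is dense
#'   (exact AUC) but peak statistics follow the reporting grid.
#' @return one-row data.frame: `auc_0t`, `auc_0inf`, `cmax`, `tmax`,
#'   `lambda_z`, `t_half`, `cl`, `extrapolated_fraction`, `extrap_warning`.
#' @examples
#' tt <- seq(0, 48, 0.25)
#' prof <- data.frame(time_h = tt, conc_ng_per_ml = 100 * exp(-0.2 * tt))
#' pkSummary(prof, newDosingRegimen("iv_infusion", 8), 73)
#' @export
pkSummary <- function(profile, regimen, body_weight, cmax_times = NULL) {
  pv <- .profileVectors(profile)
  auc_t <- aucTrapezoid(profile)
  lz <- lambdaZ(profile)
  c_last <- pv$c[length(pv$c)]
  auc_inf <- auc_t + c_last / lz$lambda_z
  extrap <- (c_last / lz$lambda_z) / auc_inf
  dose_mg <- .resolveDose(regimen, body_weight)
  cl <- dose_mg * 1e6 / auc_inf / body_weight / 60   # mL/min/kg
  sel <- if (is.null(cmax_times)) seq_along(pv$t)
         else which(pv$t %in% cmax_times)
  if (!length(sel)) sel <- seq_along(pv$t)
  imax <- sel[which.max(pv$c[sel])]
  data.frame(
    auc_0t = auc_t, auc_0inf = auc_inf,
    cmax = pv$c[imax], tmax = pv$t[imax],
    lambda_z = lz$lambda_z, t_half = log(2) / lz$lambda_z,
    cl = cl, extrapolated_fraction = extrap,
    extrap_warning = extrap > 0.2)
}
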