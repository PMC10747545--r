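#' Construct a virtual-population specification
#'
#' Age and weight can be given either as a closed range (sampled uniformly)
#' or as mean and SD (sampled normally, truncated to the supported adult
#' range: 18-85 y, 40-150 kg). Inter-individual variability is log-normal
#' with median 1 on hepatic intrinsic clearance, absorption rate and the Kp
#' scale (defaults CV 30%/20%/15%; see vignette).
#'
#' @param n number of subjects.
#' @param female_fraction fraction of female subjects.
#' @param age_range,wt_range length-2 numeric ranges (years, kg); give
#'   either these or the mean/sd pair.
#' @param age_mean,age_sd,wt_mean,wt_sd normal demographics.
#' @param cp_class "healthy", "A", "B" or "C".
#' @param seed integer RNG seed.
#' @param cv_clint,cv_ka,cv_kp variability CVs (0 disables).
#' @return a [PopulationSpec-class].
#' @export
populationSpec <- function(n, female_fraction = 0.5,
                           age_range = NULL, wt_range = NULL,
                           age_mean = NA, age_sd = NA,
                           wt_mean = NA, wt_sd = NA,
                           cp_class = "healthy", seed = 1,
                           cv_clint = 0.30, cv_ka = 0.20, cv_kp = 0.15) {
  new("PopulationSpec", n = n, female_fraction = female_fraction,
      age_min = if (is.null(age_range)) NA_real_ else age_range[1],
      age_max = if (is.null(age_range)) NA_real_ else age_range[2],
      age_mean = as.numeric(age_mean), age_sd = as.numeric(age_sd),
      wt_min = if (is.null(wt_range)) NA_real_ else wt_range[1],
      wt_max = if (is.null(wt_range)) NA_real_ else wt_range[2],
      wt_mean = as.numeric(wt_mean), wt_sd = as.numeric(wt_sd),
      cp_class = cp_class, seed = seed,
      cv_clint = cv_clint, cv_ka = cv_ka, cv_kp = cv_kp)
}

#' Pooled healthy reference population
#'
#' The production healthy-adult population used for exposure summaries:
#' pooled demographics of the healthy reference studies (ages 18-43 y,
#' weights 55-91 kg — midpoint 73 kg, matching the reference anatomy — and
#' 20% female).
#'
#' @param n subjects. @param seed RNG seed. @param cp_class optional
#'   Child-Pugh class for the same demographics (the cirrhosis reference
#'   study reports ages 20-69 y, 42% female, weights not reported — sampled
#'   from the healthy adult range; see vignette).
#' @return a [PopulationSpec-class].
#' @export
healthyPopulationSpec <- function(n = 1000, seed = 1, cp_class = "healthy") {
  if (cp_class == "healthy")
    populationSpec(n, female_fraction = 0.2, age_range = c(18, 43),
                   wt_range = c(55, 91), seed = seed)
  else
    populationSpec(n, female_fraction = 8 / 19, age_range = c(20, 69),
                   wt_range = c(55, 91), cp_class = cp_class, seed = seed)
}

.truncSample <- function(n, lo, hi, mean = NA, sd = NA, hard_lo, hard_hi) {
  if (!is.na(mean) && !is.na(sd)) {
    x <- stats::rnorm(n, mean, sd)
    bad <- x < hard_lo | x > hard_hi
    while (any(bad)) {
      x[bad] <- stats::rnorm(sum(bad), mean, sd)
      bad <- x < hard_lo | x > hard_hi
    }
    x
  } else {
    stats::runif(n, lo, hi)
  }
}

.lnMult <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  stats::rlnorm(n, meanlog = 0, sdlog = sqrt(log(1 + cv^2)))  # median 1
}

#' Generate a virtual population
#'
#' Samples demographics and inter-individual variability multipliers,
#' reproducibly for a fixed seed (the caller's RNG state is untouched).
#'
#' @param spec a [PopulationSpec-class].
#' @return data.frame with one row per subject: `id`, `sex`, `age`,
#'   `weight`, `m_clint`, `m_ka`, `m_kp`; the spec is attached as attribute
#'   `"spec"`.
#' @examples
#' subj <- generatePopulation(populationSpec(5, age_range = c(20, 40),
#'                                           wt_range = c(60, 90), seed = 7))
#' @export
generatePopulation <- function(spec) {
  stopifnot(is(spec, "PopulationSpec"))
  validObject(spec)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(spec@seed)
  n <- spec@n
  n_f <- round(spec@female_fraction * n)
  sex <- sample(c(rep("female", n_f), rep("male", n - n_f)))
  age <- .truncSample(n, spec@age_min, spec@age_max, spec@age_mean,
                      spec@age_sd, 18, 85)
  wt <- .truncSample(n, spec@wt_min, spec@wt_max, spec@wt_mean,
                     spec@wt_sd, 40, 150)
  subj <- data.frame(
    id = seq_len(n), sex = sex, age = age, weight = wt,
    m_clint = .lnMult(n, spec@cv_clint),
    m_ka = .lnMult(n, spec@cv_ka),
    m_kp = .lnMult(n, spec@cv_kp))
  attr(subj, "spec") <- spec
  subj
}

.quantileEnvelope <- function(times, conc_mat) {
  qs <- apply(conc_mat, 2, stats::quantile,
              probs = c(0, 0.05, 0.10, 0.5, 0.90, 0.95, 1), type = 7,
              names = FALSE)
  new("PercentileEnvelope", times = times,
      min = qs[1, ], p5 = qs[2, ], p10 = qs[3, ], median = qs[4, ],
      p90 = qs[5, ], p95 = qs[6, ], max = qs[7, ])
}

#' Simulate a virtual population
#'
#' Builds and integrates one PBPK model per subject (each with its own
#' body-weight-scaled physiology, optional Child-Pugh scaling, and sampled
#' variability multipliers), then computes the pointwise prediction envelope
#' and per-subject noncompartmental PK parameters.
#'
#' @param subjects subject table from [generatePopulation()].
#' @param drug a [DrugParameters-class].
#' @param regimen a [DosingRegimen-class].
#' @param cp_class optional override of the spec's Child-Pugh class.
#' @param t_end,dt_out output grid passed to [simulateIndividual()].
#' @return list with `pk` (data.frame, one row per subject: demographics +
#'   [pkSummary()] columns), `envelope` (a [PercentileEnvelope-class]), and
#'   `profiles` (matrix subjects x times of ng/mL).
#' @export
simulatePopulation <- function(subjects, drug, regimen, cp_class = NULL,
                               t_end = 24, dt_out = 0.1) {
  if (nrow(subjects) < 2) stop("at least 2 subjects are required")
  spec <- attr(subjects, "spec")
  if (is.null(cp_class))
    cp_class <- if (!is.null(spec)) spec@cp_class else "healthy"
  scalers <- if (cp_class != "healthy") loadCpScalers(cp_class) else NULL

  times <- .outputTimes(regimen, t_end, dt_out)
  conc <- matrix(NA_real_, nrow(subjects), length(times))
  pk <- vector("list", nrow(subjects))
  for (j in seq_len(nrow(subjects))) {
    s <- subjects[j, ]
    phys <- buildReferencePhysiology(s$weight, s$age, s$sex)
    if (!is.null(scalers)) phys <- applyCirrhosis(phys, scalers)
    mod <- buildModel(drug, phys, regimen,
                      clint_multiplier = s$m_clint,
                      ka_multiplier = s$m_ka, kp_scale = s$m_kp)
    prof <- tryCatch(
      simulateIndividual(mod, t_end = t_end, dt_out = dt_out,
                         label = as.character(s$id)),
      error = function(e) stop("subject ", s$id, ": ", conditionMessage(e)))
    conc[j, ] <- prof@concentrations
    pk[[j]] <- cbind(s, pkSummary(prof, regimen, s$weight,
                                  cmax_times = seq(0, t_end, by = dt_out)))
  }
  list(pk = do.call(rbind, pk),
       envelope = .quantileEnvelope(times, conc),
       profiles = conc)
}
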