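#' Construct a synthetic-profile specification
#'
#' @param model "one_compartment" or "two_compartment".
#' @param cl clearance, L/h. @param v1 central volume, L.
#' @param q,v2 inter-compartmental clearance (L/h) and peripheral volume (L).
#' @param ka absorption rate, 1/h. @param f oral bioavailable fraction.
#' @param noise_cv multiplicative log-normal CV (0 = noise-free).
#' @param lloq lower limit of quantification, ng/mL (values below are
#'   dropped; default 0.5 ng/mL, a typical bioanalytical floor).
#' @param sampling_times hours.
#' @param seed RNG seed.
#' @return a [SyntheticProfileSpec-class].
#' @export
syntheticProfileSpec <- function(model = c("two_compartment", "one_compartment"),
                                 cl, v1, q = NA_real_, v2 = NA_real_,
                                 ka = 1, f = 1, noise_cv = 0, lloq = 0.5,
                                 sampling_times = c(0.25, 0.5, 1, 2, 4, 6,
                                                    8, 12, 16, 24),
                                 seed = 1) {
  model <- match.arg(model)
  new("SyntheticProfileSpec", model = model, cl = cl, v1 = v1, q = q,
      v2 = v2, ka = ka, f = f, noise_cv = noise_cv, lloq = lloq,
      sampling_times = sampling_times, seed = seed)
}

## Closed-form disposition of a unit-coefficient compartmental model:
## returns exponential rates (1/h) and bolus coefficients (fractions of
## D/V1) for the central compartment.
.dispositionTerms <- function(spec) {
  if (spec@model == "one_compartment") {
    k <- spec@cl / spec@v1
    list(rates = k, coefs = 1)
  } else {
    k10 <- spec@cl / spec@v1
    k12 <- spec@q / spec@v1
    k21 <- spec@q / spec@v2
    s <- k10 + k12 + k21
    disc <- sqrt(s^2 - 4 * k10 * k21)
    alpha <- (s + disc) / 2
    beta <- (s - disc) / 2
    list(rates = c(alpha, beta),
         coefs = c((alpha - k21) / (alpha - beta),
                   (k21 - beta) / (alpha - beta)))
  }
}

## Noise-free central concentration (ng/mL) of one dose at times t (h).
.cmtConcOne <- function(spec, regimen, dose_ug, t) {
  dt <- .dispositionTerms(spec)
  lam <- dt$rates; A <- dt$coefs
  conc <- numeric(length(t))
  pos <- t >= 0
  tp <- t[pos]
  if (regimen@route == "iv_infusion") {
    t_inf <- regimen@infusion_duration / 60
    rate <- dose_ug / t_inf
    during <- vapply(tp, function(tt) {
      tt1 <- min(tt, t_inf)
      sum(rate / spec@v1 * A / lam * (1 - exp(-lam * tt1)) *
            exp(-lam * max(tt - t_inf, 0)))
    }, numeric(1))
    conc[pos] <- during
  } else {
    ka <- spec@ka
    if (any(abs(ka - lam) < 1e-10))
      stop("ka coincides with a disposition rate; perturb ka")
    conc[pos] <- vapply(tp, function(tt) {
      sum(spec@f * dose_ug * ka / spec@v1 * A / (ka - lam) *
            (exp(-lam * tt) - exp(-ka * tt)))
    }, numeric(1))
  }
  conc
}

#' Generate a synthetic "observed" concentration-time profile
#'
#' Evaluates the closed-form compartmental solution at the sampling times
#' (superposing doses for multi-dose regimens), multiplies by log-normal
#' residual noise with the requested CV (median 1), and censors values below
#' the LLOQ. Reproducible under the spec's seed; the caller's RNG state is
#' untouched. Emulates clinical profiles digitized from published figures.
#'
#' @param spec a [SyntheticProfileSpec-class].
#' @param regimen a [DosingRegimen-class] (dose in mg; `dose_per_kg`
#'   regimens are resolved with `body_weight`).
#' @param body_weight kg, used only for mg/kg dosing.
#' @param label profile label.
#' @return a [ConcentrationTimeProfile-class] (points below LLOQ removed).
#' @examples
#' spec <- syntheticProfileSpec("two_compartment", cl = 28.5, v1 = 15,
#'                              q = 30, v2 = 120, noise_cv = 0.15, seed = 3)
#' generateProfile(spec, newDosingRegimen("iv_infusion", 8,
#'                                        infusion_duration = 5))
#' @export
generateProfile <- function(spec, regimen, body_weight = 73,
                            label = "synthetic") {
  stopifnot(is(spec, "SyntheticProfileSpec"), is(regimen, "DosingRegimen"))
  validObject(spec)
  dose_ug <- .resolveDose(regimen, body_weight) * 1000
  t <- sort(unique(spec@sampling_times))
  conc <- numeric(length(t))
  for (k in seq_len(regimen@n_doses)) {
    offs <- (k - 1) * regimen@dosing_interval
    conc <- conc + .cmtConcOne(spec, regimen, dose_ug, t - offs)
  }
  if (spec@noise_cv > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
    })
    set.seed(spec@seed)
    sdlog <- sqrt(log(1 + spec@noise_cv^2))
    conc <- conc * stats::rlnorm(length(conc), 0, sdlog)
  }
  keep <- conc >= spec@lloq
  if (!any(keep)) stop("all sampled concentrations fall below the LLOQ")
  new("ConcentrationTimeProfile", times = t[keep],
      concentrations = conc[keep], label = label, dose_record = regimen)
}

.FIXTURES <- c("table1", "table3", "table4", "table5", "table6", "medians")

#' Load a packaged data fixture
#'
#' Typed records of the packaged evaluation tables: study observed/predicted
#' PK parameters (`table1` healthy, `table3` cirrhosis), trial designs and
#' demographics (`table4`), the ondansetron parameter set (`table5`), the
#' Child-Pugh physiology scalers (`table6`), and the reported exposure
#' medians with percentile intervals (`medians`). Each file is verified
#' against its packaged MD5 checksum at load time.
#'
#' @param table_id one of `"table1"`, `"table3"`, `"table4"`, `"table5"`,
#'   `"table6"`, `"medians"`.
#' @return data.frame of typed records.
#' @examples
#' loadFixture("table5")
#' @export
loadFixture <- function(table_id) {
  if (!is.character(table_id) || length(table_id) != 1 ||
      !table_id %in% .FIXTURES)
    stop("unknown fixture id: must be one of ",
         paste(.FIXTURES, collapse = ", "))
  path <- system.file("extdata", paste0(table_id, ".tsv"),
                      package = "cirrhPBPK")
  sums <- utils::read.delim(system.file("extdata", "checksums.tsv",
                                        package = "cirrhPBPK"),
                            colClasses = "character")
  expected <- sums$md5[sums$file == paste0(table_id, ".tsv")]
  actual <- unname(tools::md5sum(path))
  if (!identical(actual, expected))
    stop("fixture ", table_id, " failed its checksum (corrupted install?)")
  utils::read.delim(path, check.names = FALSE)
}
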