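# Seeded synthetic-data generators for every assay the analysis chain
# consumes.  Defaults emulate the magnitudes reported for the assays
# being modelled; they are generator parameters, recovered (never
# asserted) by the analysis stages.

#' Default generator configuration
#'
#' Clonogenic: linear-quadratic survival (alpha 0.35 /Gy, beta
#' 0.055 /Gy^2, plating efficiency 0.5) with per-arm dose-modifying
#' factors; the goserelin-conjugated arm is 1.10 on the copper beam and
#' 1.14 with the erbium filter.  Foci: negative-binomial per-nucleus
#' counts.  Uptake: lognormal per-dish relative concentrations.
#' Growth: piecewise log-linear volumes (response phase to day 14, then
#' arm-specific regrowth), multiplicative lognormal measurement noise,
#' four arms of 7 animals measured thrice weekly to day 64; the RT and
#' RT+gGNR regrowth slopes put the day-64 expected relative volumes at
#' about 4.0 and 1.9.
#'
#' @param rng_seed Integer seed used by all generators.
#' @return Nested configuration list.
#' @export
generator_config <- function(rng_seed = 1) {
  list(
    rng_seed = rng_seed,
    clonogenic = list(
      alpha = 0.35, beta = 0.055, plating_efficiency = 0.5,
      doses = c(0, 2, 4, 6),
      seeded = c(200, 500, 1000, 4000),
      replicates = 6,
      dmf = list(control = 1.0, free_goserelin = 1.0, pGNR = 1.05,
                 gGNR_Cu = 1.10, gGNR_CuEr = 1.14)
    ),
    foci = list(
      means = c(RT = 12.0, pGNR_RT = 19.1, gGNR_RT = 30.1,
                gGNR_RT_Cu = 29.8, gGNR_RT_CuEr = 30.4),
      dispersion = 8,
      nuclei = 50
    ),
    uptake = list(
      log_mean = log(c(control = 1, pGNR = 64.6, gGNR = 92.2)),
      log_sd = 0.15,
      dishes = 3
    ),
    growth = list(
      arms = c("control", "gGNR", "RT", "RT+gGNR"),
      animals = 7,
      v0_mean_mm3 = 170, v0_log_sd = 0.25,
      response_slope = c(control = 0.07, gGNR = 0.07,
                         RT = -0.02, `RT+gGNR` = -0.02),
      regrowth_slope = c(control = 0.07, gGNR = 0.07,
                         RT = 0.0334, `RT+gGNR` = 0.0181),
      phase_day = 14,
      noise_sd = 0.2,
      aspect_ratio = 1.3,
      days = sort(c(seq(1, 64, by = 7), seq(3, 64, by = 7),
                    seq(5, 64, by = 7)))
    )
  )
}

#' Generate clonogenic colony-count records
#'
#' Per well, expected colonies = seeded * PE *
#' `exp(-alpha (f D) - beta (f D)^2)` with `f` the arm's dose-modifying
#' factor; counts are Poisson (`noise = "poisson"`) or exact
#' expectations (`noise = "none"`, in which case the analysis chain
#' inverts the generator exactly).
#'
#' @param config A [generator_config()].
#' @param arms Arm/beam labels drawn from the configured dose-modifying
#'   factors.
#' @param noise `"poisson"` or `"none"`.
#' @return Clonogenic record data frame (see [validate_clonogenic()]).
#' @export
gen_clonogenic <- function(config = generator_config(),
                           arms = c("control", "gGNR_CuEr"),
                           noise = c("poisson", "none")) {
  noise <- match.arg(noise)
  cc <- config$clonogenic
  set.seed(config$rng_seed)
  rows <- list()
  for (arm in arms) {
    f <- cc$dmf[[arm]]
    if (is.null(f)) stop("no dose-modifying factor configured for ", arm)
    for (i in seq_along(cc$doses)) {
      d <- cc$doses[i]
      mu <- cc$seeded[i] * cc$plating_efficiency *
        exp(-cc$alpha * (f * d) - cc$beta * (f * d)^2)
      for (r in seq_len(cc$replicates)) {
        n <- if (noise == "poisson") stats::rpois(1, mu) else mu
        rows[[length(rows) + 1L]] <- data.frame(
          arm = arm, beam = if (grepl("CuEr", arm)) "Cu+Er" else "Cu",
          dose_gy = d, seeded = cc$seeded[i], colonies = n, replicate = r)
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate per-nucleus gamma-H2AX focus counts
#'
#' Negative-binomial counts (Poisson in the `dispersion = Inf` limit)
#' per condition.
#'
#' @param config A [generator_config()].
#' @param conditions Condition labels drawn from the configured means.
#' @return Data frame `condition`, `nucleus_id`, `count`.
#' @export
gen_foci <- function(config = generator_config(),
                     conditions = c("pGNR_RT", "gGNR_RT")) {
  fc <- config$foci
  if (fc$nuclei < 50) stop("protocol scores at least 50 nuclei")
  set.seed(config$rng_seed)
  out <- lapply(conditions, function(cn) {
    m <- fc$means[[cn]]
    if (is.null(m)) stop("no focus mean configured for ", cn)
    counts <- if (is.finite(fc$dispersion)) {
      stats::rnbinom(fc$nuclei, size = fc$dispersion, mu = m)
    } else {
      stats::rpois(fc$nuclei, m)
    }
    data.frame(condition = cn, nucleus_id = seq_len(fc$nuclei),
               count = counts)
  })
  do.call(rbind, out)
}

#' Generate per-dish gold-uptake values
#'
#' Lognormal relative intracellular gold concentrations per dish.
#'
#' @param config A [generator_config()].
#' @param conditions Condition labels drawn from the configured
#'   log-means.
#' @return Data frame `condition`, `dish_id`, `value`.
#' @export
gen_uptake <- function(config = generator_config(),
                       conditions = c("pGNR", "gGNR")) {
  uc <- config$uptake
  set.seed(config$rng_seed)
  out <- lapply(conditions, function(cn) {
    lm <- uc$log_mean[[cn]]
    if (is.null(lm)) stop("no uptake mean configured for ", cn)
    data.frame(condition = cn, dish_id = seq_len(uc$dishes),
               value = exp(stats::rnorm(uc$dishes, lm, uc$log_sd)))
  })
  do.call(rbind, out)
}

#' Generate caliper tumor-measurement tables
#'
#' Per animal, the latent log relative volume follows the arm's response
#' slope before the phase day and its regrowth slope after; each
#' measurement gets multiplicative lognormal noise, and the caliper axes
#' are back-computed from the noisy volume assuming a fixed aspect ratio
#' `L/S` so that `L S^2 / 2` reproduces it.  A baseline measurement at
#' day -1 is included per animal.
#'
#' @param config A [generator_config()].
#' @param noise_sd Override the configured measurement noise (0 gives
#'   exact latent volumes).
#' @return Tumor measurement data frame: `animal_id`, `arm`, `day`,
#'   `l_mm`, `s_mm`, `baseline`.
#' @export
gen_growth <- function(config = generator_config(), noise_sd = NULL) {
  gc <- config$growth
  if (is.null(noise_sd)) noise_sd <- gc$noise_sd
  set.seed(config$rng_seed)
  rows <- list()
  id <- 0
  for (arm in gc$arms) {
    for (an in seq_len(gc$animals)) {
      id <- id + 1
      v0 <- gc$v0_mean_mm3 * exp(stats::rnorm(1, 0, gc$v0_log_sd))
      days <- c(-1, gc$days)
      for (day in days) {
        t_resp <- min(max(day, 0), gc$phase_day)
        t_regr <- max(day - gc$phase_day, 0)
        logrel <- gc$response_slope[[arm]] * t_resp +
          gc$regrowth_slope[[arm]] * t_regr
        v <- v0 * exp(logrel + stats::rnorm(1, 0, noise_sd))
        s <- (2 * v / gc$aspect_ratio)^(1 / 3)
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = sprintf("A%03d", id), arm = arm, day = day,
          l_mm = gc$aspect_ratio * s, s_mm = s, baseline = day == -1)
      }
    }
  }
  do.call(rbind, rows)
}
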