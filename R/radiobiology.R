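# In vitro analysis chain: plating efficiency, surviving fractions,
# linear-quadratic fits, dose-enhancement factors, focus statistics and
# the in vivo dosing arithmetic.

#' Validate a clonogenic record table
#'
#' Expected columns: `arm`, `beam`, `dose_gy`, `seeded`, `colonies`,
#' `replicate`.
#'
#' @param records Data frame of clonogenic records.
#' @return The validated data frame (invisibly usable in a pipe).
#' @export
validate_clonogenic <- function(records) {
  need <- c("arm", "beam", "dose_gy", "seeded", "colonies", "replicate")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(records$colonies < 0)) stop("negative colony count")
  if (any(records$seeded <= 0)) stop("non-positive seeded count")
  if (any(records$dose_gy < 0)) stop("negative dose")
  records
}

#' Plating efficiency
#'
#' Pooled colonies in unirradiated wells divided by pooled cells seeded.
#'
#' @param records Clonogenic records (see [validate_clonogenic()]);
#'   only rows with `dose_gy == 0` are used.
#' @return Fraction in (0, 1].
#' @export
plating_efficiency <- function(records) {
  records <- validate_clonogenic(records)
  r0 <- records[records$dose_gy == 0, , drop = FALSE]
  if (!nrow(r0)) stop("no unirradiated (0 Gy) records")
  col <- sum(r0$colonies)
  if (col == 0) stop("no colonies in unirradiated wells: plating efficiency degenerate")
  col / sum(r0$seeded)
}

#' Per-dose surviving fractions
#'
#' Per replicate, SF = colonies / (seeded * plating efficiency); per
#' dose, the mean and standard error over replicates.
#'
#' @param records Clonogenic records.
#' @param pe Plating efficiency (fraction > 0); computed from the 0 Gy
#'   wells when omitted.
#' @return Data frame with `dose_gy`, `sf`, `sem`, `n`.
#' @export
surviving_fraction <- function(records, pe = NULL) {
  records <- validate_clonogenic(records)
  if (is.null(pe)) pe <- plating_efficiency(records)
  if (pe <= 0) stop("plating efficiency must be > 0")
  sf_rep <- records$colonies / (records$seeded * pe)
  agg <- split(sf_rep, records$dose_gy)
  out <- data.frame(
    dose_gy = as.numeric(names(agg)),
    sf = vapply(agg, mean, numeric(1)),
    sem = vapply(agg, function(x) {
      if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
    }, numeric(1)),
    n = vapply(agg, length, numeric(1)),
    row.names = NULL
  )
  out[order(out$dose_gy), ]
}

#' Fit the linear-quadratic survival model
#'
#' Weighted least squares of `ln SF = -alpha D - beta D^2` with
#' non-negativity bounds on both coefficients; noiseless
#' linear-quadratic data are recovered exactly.  Doses with SF = 0 are
#' excluded with a warning (their log is undefined).
#'
#' @param doses Doses, Gy (>= 3 distinct positive values after
#'   exclusions).
#' @param sf Surviving fractions at those doses.
#' @param weights Optional fit weights (default equal).
#' @return Object of class `lq_fit`: `alpha` (1/Gy), `beta` (1/Gy^2),
#'   `covariance`, plus the fitted data.
#' @export
fit_lq <- function(doses, sf, weights = NULL) {
  stopifnot(length(doses) == length(sf))
  keep <- doses > 0
  if (any(sf[keep] <= 0)) {
    warning("excluding dose(s) with zero surviving fraction")
    keep <- keep & sf > 0
  }
  d <- doses[keep]
  y <- log(sf[keep])
  w <- if (is.null(weights)) rep(1, length(d)) else weights[keep]
  if (length(unique(d)) < 3) stop("need at least 3 distinct positive doses")
  fit2 <- function(formula_terms) {
    X <- do.call(cbind, formula_terms)
    qr.coef(qr(sqrt(w) * X), sqrt(w) * y)
  }
  co <- fit2(list(-d, -d^2))
  alpha <- co[1]; beta <- co[2]
  if (alpha < 0 || beta < 0) {
    # clamp the offending coefficient at zero and refit the other
    fa <- max(0, fit2(list(-d))[1])              # beta = 0
    fb <- max(0, fit2(list(-(d^2)))[1])          # alpha = 0
    rss_a <- sum(w * (y + fa * d)^2)
    rss_b <- sum(w * (y + fb * d^2)^2)
    if (rss_a <= rss_b) { alpha <- fa; beta <- 0 } else { alpha <- 0; beta <- fb }
  }
  resid <- y + alpha * d + beta * d^2
  dof <- max(1, length(d) - 2)
  s2 <- sum(w * resid^2) / dof
  X <- cbind(-d, -d^2)
  xtx <- crossprod(sqrt(w) * X)
  covm <- tryCatch(s2 * solve(xtx), error = function(e) matrix(NA, 2, 2))
  structure(list(alpha = unname(alpha), beta = unname(beta),
                 covariance = covm, doses = d, sf = exp(y)),
            class = "lq_fit")
}

#' @export
print.lq_fit <- function(x, ...) {
  cat(sprintf("<lq_fit> alpha = %.4g /Gy, beta = %.4g /Gy^2\n",
              x$alpha, x$beta))
  invisible(x)
}

#' Dose at a given surviving fraction for an LQ fit
#'
#' Inverts `SF = exp(-alpha D - beta D^2)`:
#' `D = (-alpha + sqrt(alpha^2 - 4 beta ln(level))) / (2 beta)`, with the
#' `-ln(level)/alpha` limit at `beta = 0`.
#'
#' @param fit An `lq_fit`.
#' @param level Surviving-fraction level in (0, 1), default 0.10.
#' @return Dose in Gy.
#' @export
dose_at_sf <- function(fit, level = 0.10) {
  stopifnot(level > 0, level < 1)
  a <- fit$alpha; b <- fit$beta
  if (a <= 0 && b <= 0) stop("curve is flat; dose undefined")
  if (b == 0) return(-log(level) / a)
  (-a + sqrt(a^2 - 4 * b * log(level))) / (2 * b)
}

#' Dose-enhancement factor at a surviving-fraction level
#'
#' Ratio of the dose needed to reach `level` on the reference
#' (radiation-only) curve to the dose needed on the treated
#' (radiation + sensitizer) curve.
#'
#' @param reference,treated `lq_fit` objects.
#' @param level Surviving-fraction endpoint, default 10%.
#' @return The DEF (dimensionless; > 1 means sensitization).
#' @export
def_at_sf <- function(reference, treated, level = 0.10) {
  dose_at_sf(reference, level) / dose_at_sf(treated, level)
}

#' Model-free DEF by log-linear interpolation
#'
#' Interpolates ln SF linearly between the measured doses bracketing the
#' endpoint on each curve; an alternative to the LQ inversion that makes
#' no model assumption.
#'
#' @param ref_doses,ref_sf Reference curve points.
#' @param trt_doses,trt_sf Treated curve points.
#' @param level Surviving-fraction endpoint.
#' @return The DEF.
#' @export
def_interp <- function(ref_doses, ref_sf, trt_doses, trt_sf, level = 0.10) {
  d_at <- function(d, s) {
    s <- log(s)
    o <- order(s)
    d <- d[o]; s <- s[o]
    if (log(level) > max(s) || log(level) < min(s)) {
      stop("endpoint outside the measured surviving-fraction range")
    }
    stats::approx(s, d, xout = log(level))$y
  }
  d_at(ref_doses, ref_sf) / d_at(trt_doses, trt_sf)
}

#' Two-sample comparison of means (Student's t)
#'
#' Classical pooled-variance two-tailed t-test by default (Welch by
#' flag), plus the mean difference and its standard error.
#'
#' @param a,b Numeric samples (n >= 2 each).
#' @param paired Paired test?
#' @param welch Use the Welch (unequal-variance) form?
#' @return List with `t`, `p`, `difference`, `se`, `df`.
#' @export
compare_means <- function(a, b, paired = FALSE, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per sample")
  ht <- stats::t.test(a, b, paired = paired, var.equal = !welch)
  se <- unname(ht$stderr)
  list(t = unname(ht$statistic), p = unname(ht$p.value),
       difference = mean(a) - mean(b), se = se,
       df = unname(ht$parameter))
}

#' Summarise per-nucleus focus counts
#'
#' @param counts Non-negative integer focus counts (>= 50 nuclei for
#'   the standard scoring protocol; fewer raises a warning).
#' @return List with `mean`, `sem`, `n`.
#' @export
foci_summary <- function(counts) {
  if (any(counts < 0)) stop("negative focus count")
  if (length(counts) < 50) {
    warning("fewer than 50 nuclei; protocol scores at least 50")
  }
  list(mean = mean(counts), sem = stats::sd(counts) / sqrt(length(counts)),
       n = length(counts))
}

#' Injected gold dose per unit body weight
#'
#' `volume (mL) * OD * concentration-per-OD / body mass`, e.g. 100 uL of
#' a 10 OD suspension at 42.6 ug gold/mL per OD into a 30 g mouse gives
#' 1.42 ug/g.  With `od_is_total = TRUE` the concentration argument is
#' read as the total ug/mL of the injected suspension and the OD factor
#' is ignored.
#'
#' @param volume_ul Injected volume, microlitres.
#' @param od Optical density of the suspension.
#' @param conc_per_od Gold concentration per OD unit, ug/mL.
#' @param body_mass_g Body mass, g.
#' @param od_is_total Interpret `conc_per_od` as the total concentration?
#' @return Dose in micrograms of gold per gram of body weight.
#' @export
gold_dose_per_weight <- function(volume_ul, od, conc_per_od, body_mass_g,
                                 od_is_total = FALSE) {
  vals <- c(volume_ul, od, conc_per_od, body_mass_g)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all inputs must be positive")
  }
  conc <- if (od_is_total) conc_per_od else od * conc_per_od
  (volume_ul / 1000) * conc / body_mass_g
}
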