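# In vivo analysis: caliper volumes, baseline normalisation, mean
# log-relative-volume curves, and the post-day-14 regrowth-slope
# comparison.

#' Caliper tumor volume
#'
#' `V = L * S^2 / 2` with `L` the long and `S` the short axis.
#'
#' @param l_mm Long axis, mm.
#' @param s_mm Short axis, mm (must not exceed `l_mm`).
#' @return Volume in mm^3.
#' @export
tumor_volume <- function(l_mm, s_mm) {
  if (any(s_mm <= 0)) stop("axes must be positive")
  if (any(s_mm > l_mm)) stop("short axis exceeds long axis (axes swapped?)")
  l_mm * s_mm^2 / 2
}

#' Normalise one animal's volume series to its baseline
#'
#' @param measurements Data frame with columns `day`, `l_mm`, `s_mm`
#'   and a logical `baseline` flag (exactly one TRUE row, the
#'   pre-treatment measurement).
#' @return The data frame with added `volume_mm3` and `rel_volume`
#'   (baseline maps to 1).
#' @export
normalize_series <- function(measurements) {
  need <- c("day", "l_mm", "s_mm", "baseline")
  miss <- setdiff(need, names(measurements))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (sum(measurements$baseline) != 1) {
    stop("need exactly one baseline measurement per animal")
  }
  v <- tumor_volume(measurements$l_mm, measurements$s_mm)
  v0 <- v[measurements$baseline]
  if (v0 <= 0) stop("non-positive baseline volume")
  measurements$volume_mm3 <- v
  measurements$rel_volume <- v / v0
  measurements
}

#' Group mean log relative volume by day
#'
#' @param measurements Data frame with columns `animal_id`, `arm`,
#'   `day`, `l_mm`, `s_mm`, `baseline`.
#' @param arm Optional arm filter.
#' @return Data frame `day`, `mean_log_rel`, `n_animals`.
#' @export
mean_log_rel_volume <- function(measurements, arm = NULL) {
  if (!is.null(arm)) {
    measurements <- measurements[measurements$arm %in% arm, , drop = FALSE]
  }
  per_animal <- lapply(split(measurements, measurements$animal_id),
                       normalize_series)
  all <- do.call(rbind, per_animal)
  post <- all[!all$baseline, , drop = FALSE]
  agg <- split(log(post$rel_volume), round(post$day))
  data.frame(day = as.numeric(names(agg)),
             mean_log_rel = vapply(agg, mean, numeric(1)),
             n_animals = vapply(agg, length, numeric(1)),
             row.names = NULL)
}

#' Regrowth slope of a treatment arm
#'
#' Ordinary least squares of the day-wise mean (over animals) of the
#' natural-log relative tumor volume against day, restricted to days
#' `>= day_min`.
#'
#' @inheritParams mean_log_rel_volume
#' @param day_min First day included (default 14, the regrowth phase).
#' @return Object of class `growth_fit`: `slope` (per day, log scale),
#'   `slope_se`, `intercept`, `day_min`, `n_points`, `df`,
#'   `residual_ss`.
#' @export
regrowth_slope <- function(measurements, arm = NULL, day_min = 14) {
  curve <- mean_log_rel_volume(measurements, arm)
  curve <- curve[curve$day >= day_min, , drop = FALSE]
  if (nrow(curve) < 3) stop("need at least 3 time points at day >= ", day_min)
  fit <- stats::lm(mean_log_rel ~ day, data = curve)
  s <- summary(fit)$coefficients
  structure(list(arm = if (is.null(arm)) "all" else paste(arm, collapse = "+"),
                 day_min = day_min,
                 slope = unname(s["day", "Estimate"]),
                 slope_se = unname(s["day", "Std. Error"]),
                 intercept = unname(s["(Intercept)", "Estimate"]),
                 n_points = nrow(curve),
                 df = fit$df.residual,
                 residual_ss = sum(fit$residuals^2)),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> %s: slope %.4g +/- %.2g per day (days >= %g, %d points)\n",
              x$arm, x$slope, x$slope_se, x$day_min, x$n_points))
  invisible(x)
}

#' Compare two regrowth slopes
#'
#' Two-regression slope contrast: difference of slopes with standard
#' error `sqrt(se_a^2 + se_b^2)`, a t statistic on the pooled residual
#' degrees of freedom, and a two-tailed p value.
#'
#' @param fit_a,fit_b `growth_fit` objects fitted with the same
#'   `day_min`.
#' @return List with `difference`, `se`, `t`, `df`, `p`.
#' @export
compare_slopes <- function(fit_a, fit_b) {
  if (fit_a$day_min != fit_b$day_min) {
    stop("fits use different day_min; not comparable")
  }
  diff <- fit_a$slope - fit_b$slope
  se <- sqrt(fit_a$slope_se^2 + fit_b$slope_se^2)
  df <- fit_a$df + fit_b$df
  t <- diff / se
  list(difference = diff, se = se, t = t, df = df,
       p = 2 * stats::pt(-abs(t), df))
}
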