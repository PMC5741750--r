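# Material mixtures by mass fraction.

#' Define a material by element mass fractions
#'
#' @param name Material name.
#' @param composition Named numeric vector of element mass fractions;
#'   must sum to 1 within 1e-9.
#' @param density Bulk density, g/cm^3.
#' @return Object of class `material_spec`.
#' @export
material_spec <- function(name, composition, density) {
  if (is.null(names(composition)) || any(!nzchar(names(composition)))) {
    stop("composition must be a named vector of mass fractions")
  }
  if (abs(sum(composition) - 1) > 1e-9) {
    stop("mass fractions must sum to 1 (got ", format(sum(composition)), ")")
  }
  if (any(composition < 0)) stop("negative mass fraction")
  if (!is.numeric(density) || density <= 0) stop("density must be > 0")
  structure(list(name = name, composition = as.list(composition),
                 density = density),
            class = "material_spec")
}

#' @export
print.material_spec <- function(x, ...) {
  cat("<material_spec>", x$name, " rho =", x$density, "g/cm^3\n")
  w <- unlist(x$composition)
  cat(paste0("  ", names(w), ": ", signif(w, 6), collapse = "\n"), "\n")
  invisible(x)
}

#' Four-component ICRU soft tissue
#'
#' 10.1% hydrogen, 11.1% carbon, 2.6% nitrogen and 76.2% oxygen by mass,
#' density 1 g/cm^3.
#' @return A [material_spec()].
#' @export
icru_tissue <- function() {
  material_spec("ICRU four-component tissue",
                c(H = 0.101, C = 0.111, N = 0.026, O = 0.762), 1.0)
}

#' Water
#' @return A [material_spec()].
#' @export
water <- function() {
  material_spec("water", c(H = 0.111898, O = 0.888102), 1.0)
}

#' Gold-loaded tumor material
#'
#' Uniform mixture of gold and ICRU four-component tissue.  A loading of
#' `x` mg of gold per gram of tissue gives a gold mass fraction
#' `x / (1000 + x)`; with `per = "mixture"` the loading is read as mg of
#' gold per gram of mixture (fraction `x / 1000`).  The mixture density
#' is kept at the tissue density of 1 g/cm^3: at the loadings of interest
#' (a few mg/g) the density increment is below one percent.
#'
#' @param loading mg of gold per gram (of tissue by default).
#' @param per Denominator convention, `"tissue"` or `"mixture"`.
#' @return A [material_spec()].
#' @export
make_gnp_tumor_material <- function(loading, per = c("tissue", "mixture")) {
  per <- match.arg(per)
  if (!is.numeric(loading) || length(loading) != 1 || loading < 0) {
    stop("loading must be a single non-negative number (mg/g)")
  }
  f_au <- if (per == "tissue") loading / (1000 + loading) else loading / 1000
  t <- icru_tissue()
  comp <- c(unlist(t$composition) * (1 - f_au), Au = f_au)
  comp <- comp[comp > 0]
  material_spec(sprintf("tumor + %g mg Au/g (%s)", loading, per),
                comp, 1.0)
}
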