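# Metal filtration with K-edge fluorescence re-emission.

#' Build a filter stack
#'
#' @param ... Layers, each a list or pairlist `layer(symbol, mm)`;
#'   convenience: a character vector like `c(Cu = 0.35, Er = 0.25)` of
#'   thicknesses in mm named by element symbol.
#' @return Object of class `filter_stack`.
#' @export
filter_stack <- function(...) {
  args <- list(...)
  layers <- list()
  for (a in args) {
    if (is.numeric(a) && !is.null(names(a))) {
      for (i in seq_along(a)) {
        layers[[length(layers) + 1L]] <- list(symbol = names(a)[i],
                                              thickness_mm = unname(a[i]))
      }
    } else if (is.list(a) && !is.null(a$symbol)) {
      layers[[length(layers) + 1L]] <- a
    } else stop("unrecognised layer specification")
  }
  for (l in layers) {
    if (l$thickness_mm < 0) stop("layer thickness must be >= 0")
    rec <- element_record(l$symbol)
    if (is.null(rec$density)) {
      stop("no packaged density for filter element ", l$symbol)
    }
  }
  structure(list(layers = layers), class = "filter_stack")
}

#' One filter layer
#' @param symbol Element symbol.
#' @param thickness_mm Thickness in mm.
#' @return A layer list for [filter_stack()].
#' @export
layer <- function(symbol, thickness_mm) {
  list(symbol = symbol, thickness_mm = thickness_mm)
}

# areal density of a layer, g/cm^2
layer_rho_t <- function(l) element_record(l$symbol)$density * l$thickness_mm / 10

elem_material <- function(symbol) {
  material_spec(symbol, stats::setNames(1, symbol),
                element_record(symbol)$density)
}

#' Transmit a beam through a filter stack
#'
#' Each bin is attenuated by `exp(-sum_l (mu/rho)_l(E) rho_l t_l)`.  With
#' `fluorescence = TRUE` (the default), every layer with tabulated K-shell
#' data additionally re-emits its K-fluorescence lines: the number of
#' K-shell photoelectric absorptions per incident photon is
#' `(tau_K / mu) (1 - exp(-mu rho t))`, a fraction `omega_K` of those
#' relax radiatively over the packaged line branching, and the emitted
#' photons escape forward with the analytic factor of
#' [kedge_escape_factor()] before being attenuated by any downstream
#' layers.  L fluorescence (below 10 keV for the filters of interest) is
#' not re-emitted.
#'
#' @param beam A [photon_spectrum()].
#' @param stack A [filter_stack()].
#' @param fluorescence Model K-fluorescence re-emission?
#' @return The filtered `photon_spectrum`.
#' @export
apply_filter <- function(beam, stack, fluorescence = TRUE) {
  stopifnot(inherits(beam, "photon_spectrum"), inherits(stack, "filter_stack"))
  mids <- bin_mids(beam)
  fl <- beam$fluence
  for (l in stack$layers) {
    if (l$thickness_mm == 0) next
    rec <- element_record(l$symbol)
    rt <- layer_rho_t(l)
    mu <- interp_xs(rec, mids, "photoelectric") +
      interp_xs(rec, mids, "incoherent") + interp_xs(rec, mids, "coherent")
    transmitted <- fl * exp(-mu * rt)
    if (fluorescence && "K" %in% names(rec$jump_ratios)) {
      wk <- rec$fluorescence_yield[["K"]]
      if (is.null(wk)) {
        stop("element ", l$symbol, " lacks K fluorescence data")
      }
      ek <- rec$shell_binding[["K"]]
      tau <- interp_xs(rec, mids, "photoelectric")
      jk <- rec$jump_ratios[["K"]]
      above <- mids >= ek
      abs_k <- fl * ifelse(above, (tau / mu) * (1 - 1 / jk), 0) *
        (1 - exp(-mu * rt))
      n_k <- sum(abs_k) * wk
      kl <- rec$emission_lines[rec$emission_lines$shell == "K", ]
      br <- kl$intensity / sum(kl$intensity)
      for (i in seq_len(nrow(kl))) {
        ef <- kedge_escape_factor(rec, incident_energy = mids,
                                  weights = abs_k,
                                  line_energy = kl$energy[i],
                                  thickness_mm = l$thickness_mm)
        b <- findInterval(kl$energy[i], beam$bin_edges)
        if (b >= 1 && b <= length(transmitted)) {
          transmitted[b] <- transmitted[b] + n_k * br[i] * ef
        }
      }
    }
    fl <- transmitted
  }
  meta <- beam$metadata
  meta$filters <- paste(c(meta$filters, vapply(stack$layers, function(l) {
    sprintf("%s:%gmm", l$symbol, l$thickness_mm)
  }, character(1))), collapse = "+")
  photon_spectrum(beam$bin_edges, fl, meta)
}

#' Forward escape factor for K fluorescence from a filter foil
#'
#' Fluorescence is emitted isotropically at the absorption depth, whose
#' distribution is the (truncated) exponential of the incident photon;
#' half the photons travel into the forward hemisphere.  Because the
#' transmitted beam is a fluence spectrum, the forward escape through
#' the remaining thickness `d` is the plane-fluence kernel of an
#' isotropic emitter, `E1(mu_f d)` integrated over the absorption-depth
#' distribution (oblique crossings of the exit plane count with their
#' secant weight):
#' \deqn{\frac12 \int_0^T \frac{\mu e^{-\mu x}}{1 - e^{-\mu T}}
#'       E_1\!\big(\mu_f (T - x)\big)\, dx,}
#' with \eqn{\mu} the attenuation at the absorbing energy and
#' \eqn{\mu_f} at the fluorescence line energy (areal densities).
#' When `weights` spans several incident energies the factor is their
#' weighted average.
#'
#' @param rec An [element_record()].
#' @param incident_energy Incident photon energies, keV.
#' @param weights Absorption weights at those energies.
#' @param line_energy Fluorescence line energy, keV.
#' @param thickness_mm Foil thickness, mm.
#' @return Scalar escape factor in `[0, 0.5]`.
#' @export
kedge_escape_factor <- function(rec, incident_energy, weights, line_energy,
                                thickness_mm) {
  rt <- rec$density * thickness_mm / 10
  mu <- (interp_xs(rec, incident_energy, "photoelectric") +
           interp_xs(rec, incident_energy, "incoherent") +
           interp_xs(rec, incident_energy, "coherent")) * rt
  muf <- (interp_xs(rec, line_energy, "photoelectric") +
            interp_xs(rec, line_energy, "incoherent") +
            interp_xs(rec, line_energy, "coherent")) * rt
  # 24-point Gauss-Legendre over the normalised depth u = x/T
  gl <- statmod_gauss24()
  u <- gl$nodes
  wq <- gl$weights
  f <- vapply(seq_along(mu), function(i) {
    pdf <- mu[i] * exp(-mu[i] * u) / (1 - exp(-mu[i]))
    sum(wq * pdf * expint_e1(pmax(muf * (1 - u), 1e-8)))
  }, numeric(1))
  f <- pmin(f, 1)
  w <- weights
  if (sum(w) <= 0) return(0.25)  # inert fallback; no absorptions anyway
  0.5 * sum(f * w) / sum(w)
}

# exponential integral E1 via the standard rational approximations
# (Abramowitz & Stegun 5.1.53/5.1.56); vectorised, 1e-7 accuracy
expint_e1 <- function(x) {
  out <- numeric(length(x))
  lo <- x <= 1
  if (any(lo)) {
    z <- x[lo]
    out[lo] <- -log(z) - 0.57721566 + z * (0.99999193 + z *
      (-0.24991055 + z * (0.05519968 + z * (-0.00976004 + z * 0.00107857))))
  }
  if (any(!lo)) {
    z <- x[!lo]
    num <- z^2 + 4.03640 * z + 1.15198
    den <- z^2 + 5.03637 * z + 4.19160
    out[!lo] <- exp(-z) / z * num / den
  }
  out
}

# fixed 24-point Gauss-Legendre rule on (0, 1)
statmod_gauss24 <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    n <- 24
    # Golub-Welsch from the Jacobi matrix of Legendre polynomials
    i <- seq_len(n - 1)
    b <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1)] <- b
    J[cbind(i + 1, i)] <- b
    e <- eigen(J, symmetric = TRUE)
    x <- e$values
    w <- 2 * e$vectors[1, ]^2
    cache <<- list(nodes = (x + 1) / 2, weights = w / 2)
    cache
  }
})

# Klein-Nishina mean recoil (energy-transfer) fraction, vectorised.
kn_recoil_fraction <- function(energy, n = 400) {
  th <- (seq_len(n) - 0.5) * pi / n
  dth <- pi / n
  vapply(energy, function(e) {
    k <- e / 510.998946
    r <- 1 / (1 + k * (1 - cos(th)))
    kn <- r^2 * (r + 1 / r - sin(th)^2) * sin(th) * dth
    sum((1 - r) * kn) / sum(kn)
  }, numeric(1))
}

#' Water-kerma weighted quantities of a beam
#'
#' Uses an energy-transfer coefficient for water built from the packaged
#' tables: the full photoelectric coefficient plus the incoherent
#' coefficient scaled by the Klein-Nishina mean recoil fraction
#' (radiative losses and water fluorescence are negligible below
#' 250 keV).
#'
#' @param spectrum A `photon_spectrum`.
#' @return Total water kerma per unit fluence normalisation
#'   (arbitrary units, comparable across beams on the same grid).
#' @export
water_kerma <- function(spectrum) {
  mids <- bin_mids(spectrum)
  w <- water()
  mutr <- mass_coefficient(w, mids, "photoelectric") +
    mass_coefficient(w, mids, "incoherent") * kn_recoil_fraction(mids)
  sum(spectrum$fluence * mids * mutr)
}

#' Kerma-weighted transmission of a filter
#'
#' Ratio of water kerma after and before the filter: the model analogue
#' of the ratio of two measured dose rates.
#'
#' @param beam A `photon_spectrum`.
#' @param stack A [filter_stack()].
#' @param fluorescence Passed to [apply_filter()].
#' @return Dimensionless transmission factor.
#' @export
kerma_transmission <- function(beam, stack, fluorescence = TRUE) {
  water_kerma(apply_filter(beam, stack, fluorescence)) / water_kerma(beam)
}
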