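# Semi-empirical x-ray tube model: Kramers-type continuum with a shape
# exponent, target self-attenuation, inherent filtration, and anode
# characteristic K lines at a fixed fluence fraction.
#
# The two shape constants below (continuum exponent and characteristic
# fraction) are fixed once, by requiring the modelled tungsten-anode
# 250 kVp beam to reproduce the two measured properties quoted for the
# physical unit being emulated: a fluence-weighted mean energy of
# 89.3 keV after 0.35 mm of copper, and a water-kerma transmission of
# about 0.42 through an additional 0.25 mm erbium foil.  They are model
# constants, not per-run tuning knobs.

TUBE_CONTINUUM_EXPONENT <- 1.4
TUBE_CHAR_FRACTION <- 0.0990
TUBE_SELF_FILTRATION_MM <- 0.0025

#' Default inherent filtration: 2 mm beryllium window + 1 mm aluminium
#' equivalent.
#' @return A [filter_stack()].
#' @export
default_inherent_filtration <- function() filter_stack(c(Be = 2, Al = 1))

#' Generate a kilovoltage tube spectrum
#'
#' Semi-empirical model: a Kramers-type bremsstrahlung continuum
#' `N(E) dE  ~  (kVp - E)^b / E` with endpoint at the tube potential,
#' hardened by target self-attenuation (an effective anode path of
#' `self_filtration_mm / sin(anode_angle)`) and by the inherent
#' filtration, plus the anode's characteristic K lines (deposited into
#' their containing 0.5 keV bins) at a fixed fraction of the emergent
#' fluence.  Absolute normalisation is arbitrary (total fluence 1).
#'
#' @param kvp Tube potential, kV (50-300).
#' @param anode Anode element symbol (default tungsten).
#' @param anode_angle Target angle in degrees (sets the effective
#'   self-filtration path).
#' @param inherent_filtration A [filter_stack()];
#'   [default_inherent_filtration()] by default.
#' @param bin_width Energy bin width, keV.
#' @param continuum_exponent,char_fraction,self_filtration_mm Documented
#'   model constants; override only for sensitivity studies.
#' @return A [photon_spectrum()] on the `[1, kvp]` keV grid.
#' @export
generate_tube_spectrum <- function(kvp = 250, anode = "W", anode_angle = 30,
                                   inherent_filtration =
                                     default_inherent_filtration(),
                                   bin_width = 0.5,
                                   continuum_exponent =
                                     TUBE_CONTINUUM_EXPONENT,
                                   char_fraction = TUBE_CHAR_FRACTION,
                                   self_filtration_mm =
                                     TUBE_SELF_FILTRATION_MM) {
  if (kvp < 50 || kvp > 300) stop("kvp must lie in [50, 300]")
  rec <- element_record(anode)
  edges <- seq(1, kvp + bin_width, by = bin_width)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  cont <- pmax(kvp - mids, 0)^continuum_exponent / mids
  path <- self_filtration_mm / sin(anode_angle * pi / 180)
  mu_w <- interp_xs(rec, mids, "photoelectric") +
    interp_xs(rec, mids, "incoherent") + interp_xs(rec, mids, "coherent")
  cont <- cont * exp(-mu_w * rec$density * path / 10)
  beam <- photon_spectrum(edges, cont,
                          metadata = list(kvp = kvp, anode = anode))
  beam <- apply_filter(beam, inherent_filtration, fluorescence = FALSE)
  fl <- beam$fluence / sum(beam$fluence)
  kl <- rec$emission_lines[rec$emission_lines$shell == "K", ]
  if (nrow(kl) == 0 || rec$shell_binding[["K"]] >= kvp) {
    if (char_fraction > 0) {
      warning("tube potential below the anode K edge; ",
              "characteristic lines omitted")
    }
  } else {
    lf <- numeric(length(fl))
    br <- kl$intensity / sum(kl$intensity)
    for (i in seq_len(nrow(kl))) {
      b <- findInterval(kl$energy[i], edges)
      lf[b] <- lf[b] + br[i]
    }
    fl <- (1 - char_fraction) * fl + char_fraction * lf
  }
  photon_spectrum(edges, fl,
                  metadata = list(kvp = kvp, anode = anode,
                                  filters = "inherent"))
}

#' The standard copper-filtered 250 kVp beam
#'
#' Convenience wrapper: [generate_tube_spectrum()] at 250 kVp followed by
#' 0.35 mm of copper; with `erbium = TRUE` an additional 0.25 mm erbium
#' foil with K-fluorescence re-emission.
#'
#' @param erbium Add the 0.25 mm erbium foil?
#' @return A [photon_spectrum()].
#' @export
rt250_beam <- function(erbium = FALSE) {
  beam <- apply_filter(generate_tube_spectrum(250), filter_stack(c(Cu = 0.35)))
  if (erbium) beam <- apply_filter(beam, filter_stack(c(Er = 0.25)))
  beam
}
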