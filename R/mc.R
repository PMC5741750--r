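# Desk-scale Monte Carlo of secondary-electron release in a gold-loaded
# tumor sitting on a tissue phantom.

SHELL_ORDER <- c("K", "L1", "L2", "L3", "M1", "M2", "M3", "M4", "M5", "N")

#' Tumor-on-phantom simulation geometry
#'
#' A rectangular tumor (gold-loaded tissue) centred on the top face of a
#' rectangular tissue phantom, irradiated by a parallel beam travelling
#' downward along the tumor axis.  The default reproduces a 1 cm^3 tumor
#' on a 30 x 30 x 29 cm^3 phantom with the field congruent with the
#' tumor face at 50 cm source-to-surface distance (the SSD is recorded
#' but has no effect for a parallel beam).
#'
#' @param tumor_dims c(x, y, z) tumor dimensions, cm.
#' @param tumor_material [material_spec()] of the tumor.
#' @param phantom_dims c(x, y, z) phantom dimensions, cm.
#' @param phantom_material [material_spec()] of the phantom.
#' @param field c(x, y) field size at the tumor face, cm.
#' @param ssd Source-to-surface distance, cm (documentation only).
#' @return Object of class `simulation_geometry`.
#' @export
simulation_geometry <- function(tumor_dims = c(1, 1, 1),
                                tumor_material = make_gnp_tumor_material(7),
                                phantom_dims = c(30, 30, 29),
                                phantom_material = icru_tissue(),
                                field = c(1, 1), ssd = 50) {
  stopifnot(all(tumor_dims > 0), all(phantom_dims > 0), all(field > 0))
  if (any(tumor_dims[1:2] > phantom_dims[1:2])) {
    stop("tumor must not overhang the phantom")
  }
  structure(list(tumor_dims = tumor_dims, tumor_material = tumor_material,
                 phantom_dims = phantom_dims,
                 phantom_material = phantom_material,
                 field = field, ssd = ssd),
            class = "simulation_geometry")
}

#' Transport configuration
#'
#' @param histories Number of source photons.
#' @param rng_seed Integer seed (R RNG; identical seed and configuration
#'   give bit-identical tallies).
#' @param electron_cutoff_kev Electron scoring cutoff, keV
#'   (default 25 eV).
#' @param photon_cutoff_kev Photon transport cutoff, keV; photons below
#'   it deposit locally into the sub-threshold residual.
#' @param coherent Include coherent scattering?
#' @param batches History batches for statistical standard errors.
#' @return Object of class `transport_config`.
#' @export
transport_config <- function(histories, rng_seed = 1,
                             electron_cutoff_kev = 25e-3,
                             photon_cutoff_kev = 1,
                             coherent = TRUE, batches = 10) {
  stopifnot(histories >= 1, electron_cutoff_kev > 0, photon_cutoff_kev > 0,
            electron_cutoff_kev <= photon_cutoff_kev, batches >= 2)
  structure(list(histories = histories, rng_seed = rng_seed,
                 electron_cutoff_kev = electron_cutoff_kev,
                 photon_cutoff_kev = photon_cutoff_kev,
                 coherent = coherent, batches = batches),
            class = "transport_config")
}

# ---- physics bundle -------------------------------------------------------

# Relaxation branch table for one shell: radiative branches carry the
# fluorescence yield split over the line branching; non-radiative
# branches carry the Coster-Kronig factors and the Auger remainder.
build_branches <- function(rec, shells, shell) {
  b <- rec$shell_binding
  omega <- unname(rec$fluorescence_yield[shell])
  if (is.null(omega) || length(omega) == 0 || is.na(omega)) omega <- 0
  idx <- function(s) match(s, shells) - 1L
  rows <- list()
  ln <- rec$emission_lines
  ln <- ln[ln$shell == shell, , drop = FALSE]
  if (omega > 0 && nrow(ln)) {
    p <- omega * ln$intensity / sum(ln$intensity)
    for (i in seq_len(nrow(ln))) {
      rows[[length(rows) + 1L]] <- list(prob = p[i], kind = 0L,
                                        energy = ln$energy[i],
                                        vac1 = idx(ln$final[i]), vac2 = -1L)
    }
  } else omega <- 0
  au <- rec$auger
  ckv <- function(nm) {
    v <- unname(rec$coster_kronig[nm])
    if (is.null(v) || length(v) == 0 || is.na(v)) 0 else v
  }
  groups <- if (shell == "L1") {
    list(list(tag = "L1ck2", p = ckv("f12")),
         list(tag = "L1ck3", p = ckv("f13")),
         list(tag = "L1", p = 1 - omega - ckv("f12") - ckv("f13")))
  } else if (shell == "L2") {
    list(list(tag = "L2ck3", p = ckv("f23")),
         list(tag = "L2", p = 1 - omega - ckv("f23")))
  } else {
    list(list(tag = shell, p = 1 - omega))
  }
  for (g in groups) {
    if (is.na(g$p) || g$p <= 0) next
    rows_g <- au[au$shell == g$tag, , drop = FALSE]
    if (!nrow(rows_g)) next
    w <- rows_g$weight / sum(rows_g$weight)
    for (i in seq_len(nrow(rows_g))) {
      a_sh <- rows_g$a[i]
      b_sh <- rows_g$b[i]
      e <- b[[shell]] - b[[a_sh]] - b[[b_sh]]
      if (e < 0 && b_sh != "N") {
        # ejection from that shell is energetically forbidden for this
        # element; eject from the effective outer shell instead
        b_sh <- "N"
        e <- b[[shell]] - b[[a_sh]] - b[["N"]]
      }
      if (e < 0) next
      rows[[length(rows) + 1L]] <- list(prob = g$p * w[i], kind = 1L,
                                        energy = e,
                                        vac1 = idx(a_sh),
                                        vac2 = idx(b_sh))
    }
  }
  if (!length(rows)) return(NULL)
  tot <- sum(vapply(rows, `[[`, numeric(1), "prob"))
  list(prob = vapply(rows, `[[`, numeric(1), "prob") / tot,
       kind = vapply(rows, `[[`, integer(1), "kind"),
       energy = vapply(rows, `[[`, numeric(1), "energy"),
       vac1 = vapply(rows, `[[`, integer(1), "vac1"),
       vac2 = vapply(rows, `[[`, integer(1), "vac2"))
}

# Assemble the per-element data block consumed by the C++ transport core.
element_physics <- function(symbol) {
  rec <- element_record(symbol)
  shells <- intersect(SHELL_ORDER, names(rec$shell_binding))
  binding <- unname(rec$shell_binding[shells])
  has_relax <- nrow(rec$auger) > 0
  branches <- vector("list", length(shells))
  terminal <- integer(length(shells))
  for (i in seq_along(shells)) {
    if (shells[i] == "N" || !has_relax) {
      terminal[i] <- 1L
      next
    }
    br <- build_branches(rec, shells, shells[i])
    if (is.null(br)) terminal[i] <- 1L else branches[[i]] <- br
  }
  sel <- intersect(SHELL_ORDER, names(rec$jump_ratios))
  outer <- if ("N" %in% shells) match("N", shells) - 1L else
    which.min(binding) - 1L
  # coherent angular sampling: cumulative integral of f0^2 over v = s^2
  s <- rec$f0$s
  f2 <- rec$f0$value^2
  v <- s^2
  if (max(v) < 630) { v <- c(v, 630); f2 <- c(f2, f2[length(f2)]) }
  cum <- cumsum(c(0, diff(v) * (f2[-1] + f2[-length(f2)]) / 2))
  clamp <- function(x) pmax(x, 1e-30)
  list(symbol = symbol,
       logE = log(rec$xs$energy),
       logTau = log(clamp(rec$xs$photoelectric)),
       logInc = log(clamp(rec$xs$incoherent)),
       logCoh = log(clamp(rec$xs$coherent)),
       binding = binding,
       terminal = terminal,
       branches = branches,
       sel_shell = match(sel, shells) - 1L,
       sel_jump = as.numeric(rec$jump_ratios[sel]),
       outer_shell = outer,
       coh_v = v, coh_cum = cum,
       is_gold = identical(symbol, "Au"))
}

build_physics <- function(geometry) {
  syms <- union(names(geometry$tumor_material$composition),
                names(geometry$phantom_material$composition))
  elements <- lapply(syms, element_physics)
  mix <- function(mat) {
    list(el = match(names(mat$composition), syms) - 1L,
         w = unname(unlist(mat$composition)))
  }
  list(elements = elements,
       tumor = mix(geometry$tumor_material),
       phantom = mix(geometry$phantom_material),
       tumor_density = geometry$tumor_material$density,
       phantom_density = geometry$phantom_material$density)
}

beam_sampler <- function(beam) {
  if (inherits(beam, "photon_spectrum")) {
    fl <- beam$fluence
    if (sum(fl) <= 0) stop("empty beam")
    list(type = 0L, edges = beam$bin_edges, cdf = cumsum(fl) / sum(fl))
  } else if (inherits(beam, "line_spectrum")) {
    w <- beam$lines$intensity
    list(type = 1L, energy = beam$lines$energy, cdf = cumsum(w) / sum(w))
  } else stop("beam must be a photon_spectrum or line_spectrum")
}

#' Run the Monte Carlo simulation
#'
#' Scores, per source photon, the yield, total energy and creation
#' spectrum of photoelectrons by origin element class (gold vs tissue)
#' and of gold Auger/Coster-Kronig electrons released inside the tumor.
#' Compton recoil electrons are excluded from the PE/AE tallies (they
#' are tracked for energy bookkeeping), electrons are scored at creation
#' without transport, and fluorescence photons re-enter transport.
#'
#' @param beam A [photon_spectrum()] or [line_spectrum()].
#' @param geometry A [simulation_geometry()].
#' @param config A [transport_config()].
#' @return Object of class `tally_result`: per-class `yield`, `energy`
#'   (keV, both per source photon) with batch standard errors, electron
#'   creation histograms (0.5 keV bins), escaped / residual / bookkeeping
#'   energies per source photon, and the maximum per-history energy
#'   conservation violation.
#' @export
run_simulation <- function(beam, geometry, config) {
  stopifnot(inherits(geometry, "simulation_geometry"),
            inherits(config, "transport_config"))
  set.seed(config$rng_seed)
  td <- geometry$tumor_dims
  pd <- geometry$phantom_dims
  geom <- list(
    tumor_lo = c(-td[1] / 2, -td[2] / 2, 0),
    tumor_hi = c(td[1] / 2, td[2] / 2, td[3]),
    phantom_lo = c(-pd[1] / 2, -pd[2] / 2, td[3]),
    phantom_hi = c(pd[1] / 2, pd[2] / 2, td[3] + pd[3]),
    field = c(geometry$field[1] / 2, geometry$field[2] / 2, -0.01)
  )
  res <- cpp_run_mc(build_physics(geometry), beam_sampler(beam), geom,
                    config$histories, config$batches,
                    config$electron_cutoff_kev, config$photon_cutoff_kev,
                    config$coherent, 1e-9)
  n <- res$histories
  nb <- config$batches
  bs <- rep(floor(n / nb), nb)
  extra <- n - sum(bs)
  if (extra > 0) bs[seq_len(extra)] <- bs[seq_len(extra)] + 1
  classes <- c("gold_PE", "tissue_PE", "gold_AE")
  per_class <- lapply(seq_along(classes), function(i) {
    ry <- res$batch_yield[, i] / bs
    re <- res$batch_energy[, i] / bs
    list(yield = sum(res$batch_yield[, i]) / n,
         yield_se = stats::sd(ry) / sqrt(nb),
         energy = sum(res$batch_energy[, i]) / n,
         energy_se = stats::sd(re) / sqrt(nb),
         spectrum = res$histogram[i, ] / n)
  })
  names(per_class) <- classes
  structure(list(
    classes = per_class,
    spectrum_edges = seq(0, 310, by = 0.5),
    escaped = res$escaped / n,
    residual = res$residual / n,
    compton_electron_energy = res$compton_electron_energy / n,
    outside_electron_energy = res$outside_electron_energy / n,
    max_conservation_violation = res$max_conservation_violation,
    histories = n,
    config = config
  ), class = "tally_result")
}

#' @export
print.tally_result <- function(x, ...) {
  cat("<tally_result>", format(x$histories, big.mark = ","), "histories\n")
  for (cl in names(x$classes)) {
    c0 <- x$classes[[cl]]
    cat(sprintf("  %-10s yield %.5g (SE %.2g)  energy %.5g keV (SE %.2g)\n",
                cl, c0$yield, c0$yield_se, c0$energy, c0$energy_se))
  }
  cat(sprintf("  escaped %.4g  residual %.4g  max |dE|/E %.2g\n",
              x$escaped, x$residual, x$max_conservation_violation))
  invisible(x)
}

#' Total released-electron energy per source photon
#'
#' Sum of the gold and tissue photoelectron energies plus the gold
#' Auger/Coster-Kronig energy: the per-beam "total deposition" used for
#' beam-to-beam comparisons.
#'
#' @param tally A `tally_result`.
#' @return keV per source photon.
#' @export
total_electron_energy <- function(tally) {
  sum(vapply(tally$classes, `[[`, numeric(1), "energy"))
}

#' Simulate one relaxation cascade
#'
#' Runs the vacancy cascade for a single inner-shell vacancy: radiative
#' branches emit fluorescence photons (leaving the line's final-shell
#' vacancy), non-radiative branches emit an Auger or Coster-Kronig
#' electron (leaving two vacancies); vacancies below the modelled M
#' shells contribute their binding energy to the residual.  The initial
#' binding energy equals the sum of emitted photon energies, electron
#' energies, and residual, exactly.
#'
#' @param element An [element_record()] or symbol.
#' @param shell Shell label, e.g. `"K"`.
#' @return List with `photons`, `electrons` (energies, keV) and
#'   `residual` (keV).
#' @export
relax_vacancy <- function(element, shell) {
  sym <- if (inherits(element, "element_record")) element$symbol else element
  ep <- element_physics(sym)
  shells <- intersect(SHELL_ORDER, names(element_record(sym)$shell_binding))
  i <- match(shell, shells)
  if (is.na(i)) stop("unknown shell '", shell, "' for ", sym)
  cpp_relax(ep, i - 1L)
}

#' Sample Compton scattering (free-electron Klein-Nishina)
#'
#' @param energy Incident photon energy, keV.
#' @param n Number of samples.
#' @return Data frame with `scattered` and `recoil` energies (keV,
#'   summing to `energy`) and `cos_theta` of the scattered photon.
#' @export
sample_compton <- function(energy, n = 1) {
  stopifnot(energy > 0)
  as.data.frame(cpp_sample_compton(energy, n))
}

#' Tabulate beam-to-beam comparisons
#'
#' @param tallies Named list of `tally_result` objects.
#' @param reference Name of the reference beam in `tallies`.
#' @return Data frame with per-beam yields and energies (per source
#'   photon) and the percent deviation of each beam's total
#'   released-electron energy from the reference beam.
#' @export
summarize_table <- function(tallies, reference) {
  if (!reference %in% names(tallies)) stop("missing reference beam")
  ref_total <- total_electron_energy(tallies[[reference]])
  rows <- lapply(names(tallies), function(nm) {
    t <- tallies[[nm]]
    cl <- t$classes
    data.frame(
      beam = nm,
      gold_pe_yield = cl$gold_PE$yield,
      gold_pe_energy = cl$gold_PE$energy,
      tissue_pe_yield = cl$tissue_PE$yield,
      tissue_pe_energy = cl$tissue_PE$energy,
      total_pe_energy = cl$gold_PE$energy + cl$tissue_PE$energy,
      gold_ae_yield = cl$gold_AE$yield,
      gold_ae_energy = cl$gold_AE$energy,
      total_electron_energy = total_electron_energy(t),
      pct_dev_from_ref = 100 * (total_electron_energy(t) / ref_total - 1)
    )
  })
  do.call(rbind, rows)
}
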