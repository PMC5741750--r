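# Spectrum model: tube, filtration with K fluorescence, summaries.

test_that("tube spectrum respects the Duane-Hunt limit", {
  for (kvp in c(120, 250)) {
    sp <- generate_tube_spectrum(kvp)
    mids <- (sp$bin_edges[-1] + sp$bin_edges[-length(sp$bin_edges)]) / 2
    expect_true(all(sp$fluence[mids > kvp] == 0))
    expect_gt(sum(sp$fluence), 0)
  }
})

test_that("tungsten K lines stand above the local continuum", {
  sp <- generate_tube_spectrum(250)
  mids <- (sp$bin_edges[-1] + sp$bin_edges[-length(sp$bin_edges)]) / 2
  for (el in c(59.318, 67.244)) {
    i <- findInterval(el, sp$bin_edges)
    local_bg <- mean(sp$fluence[c(i - 3, i - 2, i + 2, i + 3)])
    expect_gt(sp$fluence[i], 3 * local_bg)
  }
})

test_that("a tube potential below the anode K edge drops the lines", {
  expect_warning(sp <- generate_tube_spectrum(60), "below the anode K edge")
  mids <- (sp$bin_edges[-1] + sp$bin_edges[-length(sp$bin_edges)]) / 2
  i <- findInterval(59.318, sp$bin_edges)
  local_bg <- mean(sp$fluence[c(i - 2, i + 2)])
  expect_lt(sp$fluence[i], 2 * local_bg)
})

test_that("mean energy and band fraction behave on degenerate spectra", {
  one <- line_spectrum(75, 1)
  expect_equal(mean_energy(one), 75)
  two <- line_spectrum(c(40, 60), c(1, 1))
  expect_equal(mean_energy(two), 50)
  expect_equal(band_fraction(two, 1, 300), 1)
  expect_equal(band_fraction(two, 100, 200), 0)
  expect_error(mean_energy(photon_spectrum(c(1, 2), 0)), "empty")
  expect_error(line_spectrum(c(10, -5), c(1, 1)), "positive")
})

test_that("packaged Yb-169 list reproduces its frozen summaries", {
  yb <- yb169_spectrum()
  # frozen from the packaged compilation: mean 93.197 keV, 68.6% in band
  expect_equal(mean_energy(yb), 93.197, tolerance = 1e-4)
  expect_equal(band_fraction(yb, 49, 63.2), 0.6860, tolerance = 1e-3)
  e <- yb$lines$energy
  i <- yb$lines$intensity
  # strongest lines near 49-51 and 63 keV
  expect_true(all(sort(e[order(-i)][1:3]) %in%
                    c(49.772, 50.742, 63.12)))
})

test_that("monoenergetic transmission is exact Beer-Lambert", {
  edges <- seq(99, 101, by = 0.5)
  sp <- photon_spectrum(edges, c(0, 1, 0, 0))  # single bin [99.5, 100)
  out <- apply_filter(sp, filter_stack(c(Cu = 0.35)), fluorescence = FALSE)
  mid <- 99.75
  mu <- mass_coefficient(material_spec("cu", c(Cu = 1), 8.96), mid, "total")
  expect_equal(out$fluence[2], exp(-mu * 8.96 * 0.035), tolerance = 1e-12)
})

test_that("filtration composes multiplicatively and is contractive", {
  sp <- generate_tube_spectrum(250)
  two <- apply_filter(apply_filter(sp, filter_stack(c(Cu = 0.2)),
                                   fluorescence = FALSE),
                      filter_stack(c(Cu = 0.15)), fluorescence = FALSE)
  one <- apply_filter(sp, filter_stack(c(Cu = 0.35)), fluorescence = FALSE)
  expect_equal(two$fluence, one$fluence, tolerance = 1e-12)
  expect_true(all(one$fluence <= sp$fluence + 1e-15))
  # zero-thickness stack is the identity
  same <- apply_filter(sp, filter_stack(c(Cu = 0)))
  expect_identical(same$fluence, sp$fluence)
})

test_that("re-emitted fluorescence never exceeds the absorption budget", {
  cu <- rt250_beam()
  noem <- apply_filter(cu, filter_stack(c(Er = 0.25)), fluorescence = FALSE)
  em <- apply_filter(cu, filter_stack(c(Er = 0.25)))
  added <- sum(em$fluence) - sum(noem$fluence)
  er <- element_record("Er")
  mids <- (cu$bin_edges[-1] + cu$bin_edges[-length(cu$bin_edges)]) / 2
  mu <- mass_coefficient(material_spec("er", c(Er = 1), er$density),
                         mids, "total")
  rt <- er$density * 0.025
  interacting <- sum(cu$fluence * (1 - exp(-mu * rt)))
  expect_gt(added, 0)
  expect_lt(added, interacting * er$fluorescence_yield[["K"]] * 0.5)
})

test_that("erbium filtration swaps tungsten lines for erbium lines", {
  cu <- rt250_beam()
  cuer <- rt250_beam(erbium = TRUE)
  b <- function(sp, e) sp$fluence[findInterval(e, sp$bin_edges)]
  # tungsten K-alpha bins strongly suppressed (beyond plain attenuation
  # of the neighbourhood)
  expect_lt(b(cuer, 59.3) / b(cu, 59.3), 0.1)
  # new erbium peaks at 49.1 and 55.7 keV stand above their neighbours
  for (e in c(49.128, 55.674)) {
    i <- findInterval(e, cuer$bin_edges)
    expect_gt(cuer$fluence[i], 2 * mean(cuer$fluence[c(i - 2, i + 3)]))
  }
})

test_that("pure attenuation by a sub-edge filter hardens a sub-edge beam", {
  edges <- seq(20, 55.5, by = 0.5)  # entirely below the Al K grid top etc.
  fl <- exp(-((seq_along(edges[-1]) - 30) / 15)^2)
  sp <- photon_spectrum(edges, fl)
  out <- apply_filter(sp, filter_stack(c(Al = 3)), fluorescence = FALSE)
  expect_gt(mean_energy(out), mean_energy(sp))
})

test_that("spectral distance is a normalised L1 with the right extremes", {
  sp <- generate_tube_spectrum(250)
  expect_equal(spectral_distance(sp, sp), 0)
  a <- photon_spectrum(seq(1, 101, 0.5), c(rep(1, 100), rep(0, 100)))
  b <- photon_spectrum(seq(1, 101, 0.5), c(rep(0, 100), rep(1, 100)))
  expect_equal(spectral_distance(a, b), 2)
  # line projection: identical after projection -> 0
  l <- line_spectrum(c(10.2, 50.3), c(2, 1))
  proj <- project_lines(l, a$bin_edges)
  expect_equal(spectral_distance(proj, l), 0)
  expect_error(spectral_distance(l, l), "binned")
})

test_that("the erbium-filtered beam sits closer to Yb-169 than the copper beam", {
  yb <- yb169_spectrum()
  cu <- rebin_spectrum(rt250_beam(), 2)
  cuer <- rebin_spectrum(rt250_beam(erbium = TRUE), 2)
  expect_lt(spectral_distance(cuer, yb), spectral_distance(cu, yb))
})

test_that("spectrum files round-trip bit-identically", {
  sp <- rt250_beam()
  path <- tempfile(fileext = ".tsv")
  write_spectrum(sp, path)
  back <- read_spectrum(path)
  expect_identical(back$bin_edges, sp$bin_edges)
  expect_identical(back$fluence, sp$fluence)
  unlink(path)
})

test_that("rebinning conserves total fluence", {
  sp <- rt250_beam()
  rb <- rebin_spectrum(sp, 5)
  expect_equal(sum(rb$fluence), sum(sp$fluence))
  expect_equal(mean_energy(rb), mean_energy(sp), tolerance = 0.03)
})
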