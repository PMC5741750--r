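# Atomic data: interpolation, mixtures, shell selection.

test_that("packaged element records satisfy their structural invariants", {
  for (sym in c("H", "C", "N", "O", "Be", "Al", "Cu", "Er", "W", "Au")) {
    rec <- element_record(sym)
    expect_s3_class(rec, "element_record")
    b <- rec$shell_binding
    main <- intersect(c("K", "L1", "L2", "L3", "M1", "M2", "M3", "M4", "M5"),
                      names(b))
    if (length(main) > 1) expect_true(all(diff(b[main]) < 0))
    probs <- c(rec$fluorescence_yield, rec$coster_kronig)
    if (length(probs)) expect_true(all(probs >= 0 & probs <= 1))
    ln <- rec$emission_lines
    if (nrow(ln)) expect_true(all(ln$energy < b[ln$shell]))
    expect_true(all(unlist(rec$xs[-1]) >= 0))
  }
})

test_that("interpolation reproduces every tabulated node exactly", {
  for (sym in c("O", "Cu", "Au")) {
    rec <- element_record(sym)
    e <- rec$xs$energy
    # away from duplicated edge abscissae a node query returns the node
    dup <- e %in% e[duplicated(e)]
    got <- ybsurrogate:::interp_xs(rec, e[!dup], "photoelectric")
    expect_equal(got, rec$xs$photoelectric[!dup], tolerance = 1e-12)
    # at a duplicated edge the above-branch row is returned
    if (any(dup)) {
      ed <- unique(e[dup])[1]
      above <- max(rec$xs$photoelectric[e == ed])
      expect_equal(ybsurrogate:::interp_xs(rec, ed, "photoelectric"), above)
    }
  }
})

test_that("mixture coefficient is linear in mass fractions", {
  au <- material_spec("au", c(Au = 1), 19.32)
  ox <- material_spec("o", c(O = 1), 1)
  set.seed(7)
  for (w in runif(5)) {
    mix <- material_spec("mix", c(Au = w, O = 1 - w), 1)
    for (pr in c("photoelectric", "incoherent", "coherent", "total")) {
      e <- c(25, 60, 110, 240)
      expect_equal(mass_coefficient(mix, e, pr),
                   w * mass_coefficient(au, e, pr) +
                     (1 - w) * mass_coefficient(ox, e, pr),
                   tolerance = 1e-12)
    }
  }
})

test_that("identity mixture equals the element and 50/50 is the mean", {
  cu <- material_spec("cu", c(Cu = 1), 8.96)
  rec <- element_record("Cu")
  expect_equal(mass_coefficient(cu, 80, "photoelectric"),
               ybsurrogate:::interp_xs(rec, 80, "photoelectric"))
  half <- material_spec("half", c(Cu = 0.5, O = 0.5), 1)
  o <- material_spec("o", c(O = 1), 1)
  expect_equal(mass_coefficient(half, 80, "total"),
               (mass_coefficient(cu, 80, "total") +
                  mass_coefficient(o, 80, "total")) / 2)
})

test_that("erbium photoelectric coefficient jumps by the packaged K ratio", {
  er <- element_record("Er")
  ek <- er$shell_binding[["K"]]
  mat <- material_spec("er", c(Er = 1), er$density)
  below <- mass_coefficient(mat, ek * (1 - 1e-6), "photoelectric")
  above <- mass_coefficient(mat, ek, "photoelectric")  # edge -> above branch
  expect_gt(above / below, 1)
  expect_equal(above / below, er$jump_ratios[["K"]], tolerance = 2e-3)
})

test_that("energy outside the table range and unknown elements error", {
  o <- material_spec("o", c(O = 1), 1)
  expect_error(mass_coefficient(o, 0.5), "outside")
  expect_error(mass_coefficient(o, 400), "outside")
  expect_error(element_record("Xx"), "no packaged data")
  expect_error(material_spec("bad", c(O = 0.5), 1), "sum to 1")
  expect_error(material_spec("bad", c(O = 1), -1), "density")
})

test_that("gold-loaded tumor material follows the mg-per-g-tissue convention", {
  t0 <- make_gnp_tumor_material(0)
  expect_equal(unlist(t0$composition), unlist(icru_tissue()$composition))
  t7 <- make_gnp_tumor_material(7)
  expect_equal(t7$composition$Au, 7 / 1007)
  expect_equal(sum(unlist(t7$composition)), 1, tolerance = 1e-12)
  expect_equal(make_gnp_tumor_material(1000)$composition$Au, 0.5)
  expect_equal(make_gnp_tumor_material(7, per = "mixture")$composition$Au,
               0.007)
  expect_error(make_gnp_tumor_material(-1), "non-negative")
  # tissue fractions scale together
  expect_equal(t7$composition$H / t7$composition$O, 0.101 / 0.762)
})

test_that("shell selection is energetically consistent and normalised", {
  au <- element_record("Au")
  # below the K edge no K-shell events
  p <- shell_probabilities(au, 79)
  expect_false("K" %in% names(p))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # at 93 keV the K probability is 1 - 1/J_K
  p93 <- shell_probabilities(au, 93)
  expect_equal(unname(p93["K"]), 1 - 1 / au$jump_ratios[["K"]])
  # normalisation across elements and energies
  for (sym in c("O", "Cu", "Er", "W", "Au")) {
    for (e in c(2, 8, 15, 60, 85, 200)) {
      expect_equal(sum(shell_probabilities(sym, e)), 1, tolerance = 1e-12)
    }
  }
})

test_that("sampled shell frequencies match the analytic probabilities", {
  au <- element_record("Au")
  p <- shell_probabilities(au, 100)
  set.seed(11)
  n <- 1e5
  draws <- select_shell(au, 100, n = n)
  for (s in names(p)) {
    obs <- mean(draws == s)
    se <- sqrt(p[[s]] * (1 - p[[s]]) / n)
    expect_lt(abs(obs - p[[s]]), 3 * se + 1e-12)
  }
})
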