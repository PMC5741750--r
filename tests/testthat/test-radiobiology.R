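# Clonogenic chain, LQ fits, DEF, comparisons, dosing arithmetic.

clono_row <- function(dose, seeded, colonies, rep = 1, arm = "control") {
  data.frame(arm = arm, beam = "Cu", dose_gy = dose, seeded = seeded,
             colonies = colonies, replicate = rep)
}

test_that("plating efficiency pools unirradiated wells", {
  expect_equal(plating_efficiency(clono_row(0, 100, 50)), 0.5)
  two <- rbind(clono_row(0, 100, 30, 1), clono_row(0, 100, 20, 2))
  expect_equal(plating_efficiency(two), 0.25)
  expect_error(plating_efficiency(clono_row(2, 100, 10)), "no unirradiated")
  expect_error(plating_efficiency(clono_row(0, 100, 0)), "degenerate")
})

test_that("plating efficiency recovers the truth on simulated wells", {
  set.seed(21)
  hits <- replicate(50, {
    n <- stats::rbinom(6, 100, 0.4)
    pe <- plating_efficiency(do.call(rbind, lapply(seq_along(n), function(i)
      clono_row(0, 100, n[i], i))))
    ci <- stats::binom.test(sum(n), 600)$conf.int
    pe >= ci[1] && pe <= ci[2]
  })
  expect_gt(mean(hits), 0.9)
})

test_that("surviving fractions invert the definition", {
  rec <- rbind(clono_row(0, 100, 50),
               clono_row(2, 100, 50),     # colonies = seeded * pe -> SF 1
               clono_row(4, 100, 0))
  sf <- surviving_fraction(rec)
  expect_equal(sf$sf[sf$dose_gy == 2], 1)
  expect_equal(sf$sf[sf$dose_gy == 4], 0)
  # noiseless LQ data at alpha = 0.3, beta = 0.03
  d <- 4
  col <- 100 * 0.5 * exp(-0.3 * d - 0.03 * d^2)
  rec2 <- rbind(clono_row(0, 100, 50), clono_row(4, 100, col))
  sf2 <- surviving_fraction(rec2)
  expect_equal(sf2$sf[sf2$dose_gy == 4], exp(-1.68), tolerance = 1e-12)
})

test_that("LQ fits recover noiseless parameters to machine precision", {
  d <- c(1, 2, 4, 6, 8)
  fit <- fit_lq(d, exp(-0.3 * d - 0.03 * d^2))
  expect_equal(fit$alpha, 0.3, tolerance = 1e-10)
  expect_equal(fit$beta, 0.03, tolerance = 1e-10)
  # pure-exponential data pin beta at its bound
  fit0 <- fit_lq(d, exp(-0.42 * d))
  expect_equal(fit0$beta, 0)
  expect_equal(fit0$alpha, 0.42, tolerance = 1e-10)
  expect_error(fit_lq(c(2, 4), exp(-c(2, 4) * 0.3)), "3 distinct")
  expect_warning(fit_lq(c(2, 4, 6, 8), c(0.5, 0.2, 0.05, 0)), "zero surviving")
})

test_that("DEF identities hold", {
  ref <- fit_lq(c(2, 4, 6), exp(-0.3 * c(2, 4, 6) - 0.03 * c(2, 4, 6)^2))
  expect_equal(def_at_sf(ref, ref), 1)
  # treated = reference evaluated at 1.2 x dose -> DEF 1.2 exactly
  d <- c(2, 4, 6)
  trt <- fit_lq(d, exp(-0.3 * (1.2 * d) - 0.03 * (1.2 * d)^2))
  expect_equal(def_at_sf(ref, trt), 1.2, tolerance = 1e-9)
  # invariance under common dose rescaling
  c2 <- 2.5
  ref2 <- fit_lq(d * c2, exp(-0.3 * d - 0.03 * d^2))
  trt2 <- fit_lq(d * c2, exp(-0.3 * 1.2 * d - 0.03 * (1.2 * d)^2))
  expect_equal(def_at_sf(ref2, trt2), def_at_sf(ref, trt), tolerance = 1e-9)
})

test_that("model-free interpolation agrees with the LQ inversion", {
  d <- c(0, 2, 4, 6)
  sf_ref <- exp(-0.35 * d - 0.055 * d^2)
  sf_trt <- exp(-0.35 * 1.14 * d - 0.055 * (1.14 * d)^2)
  ref <- fit_lq(d, sf_ref)
  trt <- fit_lq(d, sf_trt)
  d1 <- def_at_sf(ref, trt)
  d2 <- def_interp(d, sf_ref, d, sf_trt)
  expect_lt(abs(d1 - d2) / d1, 0.05)
})

test_that("DEF recovery from noisy synthetic curves is unbiased", {
  cfg <- generator_config(rng_seed = 99)
  defs <- vapply(1:40, function(i) {
    cfg$rng_seed <- 1000 + i
    rec <- gen_clonogenic(cfg, arms = c("control", "gGNR_CuEr"))
    pe <- plating_efficiency(rec[rec$arm == "control", ])
    sf_c <- surviving_fraction(rec[rec$arm == "control", ], pe)
    pe_t <- plating_efficiency(rec[rec$arm == "gGNR_CuEr", ])
    sf_t <- surviving_fraction(rec[rec$arm == "gGNR_CuEr", ], pe_t)
    def_at_sf(fit_lq(sf_c$dose_gy, sf_c$sf), fit_lq(sf_t$dose_gy, sf_t$sf))
  }, numeric(1))
  expect_lt(abs(mean(defs) - 1.14), 3 * stats::sd(defs) / sqrt(40))
})

test_that("Student's t comparison is calibrated", {
  a <- c(1, 2, 3, 4)
  r <- compare_means(a, a)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  set.seed(17)
  reps <- 2000
  pv <- replicate(reps, compare_means(rnorm(6), rnorm(6))$p)
  rate <- mean(pv < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
  expect_gt(stats::ks.test(pv, "punif")$p.value, 1e-3)
  expect_error(compare_means(1, c(1, 2)), "n >= 2")
})

test_that("two-sample power matches the noncentral-t oracle", {
  set.seed(18)
  n <- 6; delta <- 2   # means shifted by 2 pooled SD
  reps <- 1500
  hits <- replicate(reps, compare_means(rnorm(n, delta), rnorm(n))$p < 0.05)
  ncp <- delta / sqrt(2 / n)
  tc <- stats::qt(0.975, 2 * n - 2)
  power <- 1 - stats::pt(tc, 2 * n - 2, ncp) + stats::pt(-tc, 2 * n - 2, ncp)
  expect_lt(abs(mean(hits) - power), 3 * sqrt(power * (1 - power) / reps))
})

test_that("injected gold dose arithmetic reproduces the worked example", {
  expect_equal(gold_dose_per_weight(100, 10, 42.6, 30), 1.42)
  expect_equal(gold_dose_per_weight(100, 10, 42.6, 60),
               gold_dose_per_weight(100, 10, 42.6, 30) / 2)
  expect_equal(gold_dose_per_weight(100, 5, 100, 10, od_is_total = TRUE), 1.0)
  expect_error(gold_dose_per_weight(-1, 10, 42.6, 30), "positive")
})

test_that("focus summaries flag short samples", {
  expect_warning(foci_summary(rep(10, 20)), "50 nuclei")
  s <- foci_summary(rep(c(10, 20), 30))
  expect_equal(s$mean, 15)
  expect_equal(s$n, 60)
})
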