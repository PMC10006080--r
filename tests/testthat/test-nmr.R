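test_that("secondary shifts remove a global referencing offset", {
  ref <- data.frame(residue_index = 1:8, ca = rnorm(8, 58, 2),
                    cb = rnorm(8, 32, 2), ha = rnorm(8, 4.3, 0.2))
  # observed identical to reference -> all zero
  ss <- secondary_shifts(ref, ref)
  expect_equal(ss$ca, rep(0, 8))
  # constant +0.5 ppm offset removed by median correction
  obs <- ref
  obs$ca <- obs$ca + 0.5
  ss <- secondary_shifts(obs, ref)
  expect_equal(ss$ca, rep(0, 8))
  # single shifted residue survives, others ~0 (median-offset oracle: the
  # median of (0,...,0,1) is 0, so nothing is subtracted)
  obs <- ref
  obs$ca[3] <- obs$ca[3] + 1
  ss <- secondary_shifts(obs, ref)
  expect_equal(ss$ca[3], 1)
  expect_equal(ss$ca[-3], rep(0, 7))
})

test_that("missing reference shifts propagate as absent, never zero", {
  ref <- data.frame(residue_index = c(1, 2, 4), ca = c(58, 57, 59))
  obs <- data.frame(residue_index = 1:4, ca = c(58.2, 57.1, 58.8, 59.5))
  ss <- secondary_shifts(obs, ref, nuclei = "ca")
  expect_true(is.na(ss$ca[3]))
  expect_false(anyNA(ss$ca[-3]))
})

test_that("RCI order parameters are bounded, baseline-uniform, and monotone", {
  # uniform zero secondary shifts -> uniform maximal RCI, uniform baseline S2
  zero <- data.frame(residue_index = 1:6, ca = 0, cb = 0, ha = 0)
  op <- rci_s2(zero)
  cfg <- rci_config()
  expect_equal(op$rci, rep(cfg$rci_scale / cfg$floor_ppm, 6))
  expect_equal(op$s2, rep(op$s2[1], 6))
  expect_true(all(op$s2 >= 0 & op$s2 <= 1))
  # large deviations from random coil mean more order
  two <- data.frame(residue_index = 1:2, ca = c(0, 2.5), cb = c(0, 2.5),
                    ha = c(0, 0.5))
  op2 <- rci_s2(two)
  expect_gt(op2$s2[2], op2$s2[1])
  # two-population profile keeps the level ordering (monotone-map oracle)
  set.seed(31)
  mag <- rep(c(0.8, 3), each = 5)
  prof <- data.frame(residue_index = 1:10, ca = mag, cb = mag,
                     ha = mag / 6)
  op3 <- rci_s2(prof)
  expect_true(all(op3$s2[6:10] > op3$s2[1:5]))
  # property: s2 non-increasing in rci over random profiles
  for (i in 1:20) {
    p <- data.frame(residue_index = 1:2,
                    ca = runif(2, 0, 4), cb = runif(2, 0, 4),
                    ha = runif(2, 0, 1))
    op <- rci_s2(p)
    expect_equal(order(op$rci), order(-op$s2))
    expect_true(all(op$s2 >= 0 & op$s2 <= 1))
  }
  # residue with all nuclei missing is absent
  holed <- data.frame(residue_index = 1:3, ca = c(1, NA, 1),
                      cb = c(1, NA, 1), ha = c(0.2, NA, 0.2))
  expect_equal(rci_s2(holed)$residue_index, c(1, 3))
})

test_that("monoexponential fits recover T exactly on noiseless decays", {
  for (t_true in c(150, 400, 1200)) {
    g <- gen_relaxation(32, t_ms = t_true, delays_ms = t1_delay_schedule())
    fit <- suppressWarnings(fit_monoexponential(g$delays_ms, g$intensities))
    expect_true(fit$ok)
    expect_equal(fit$time_constant_ms, t_true, tolerance = 1e-8)
  }
  # the T2 (CPMG) schedule as well
  g <- gen_relaxation(33, t_ms = 120, delays_ms = t2_delay_schedule())
  fit <- suppressWarnings(fit_monoexponential(g$delays_ms, g$intensities))
  expect_equal(fit$time_constant_ms, 120, tolerance = 1e-8)
})

test_that("degenerate relaxation series are flagged, not clamped", {
  flat <- fit_monoexponential(c(10, 20, 40), c(1, 1, 1))
  expect_false(flat$ok)
  expect_true(is.na(flat$time_constant_ms))
  rising <- fit_monoexponential(c(10, 20, 40), c(1, 2, 3))
  expect_false(rising$ok)
})

test_that("noisy relaxation decays are recovered within 3 standard errors", {
  t_true <- 150
  hit <- 0
  for (s in 1:25) {
    g <- gen_relaxation(100 + s, t_ms = t_true, noise_frac = 0.02)
    fit <- fit_monoexponential(g$delays_ms, g$intensities)
    if (fit$ok &&
        abs(fit$time_constant_ms - t_true) <= 3 * fit$se_ms) hit <- hit + 1
  }
  expect_gte(hit, 24)   # ~99.7% nominal coverage
})

test_that("R2/R1 equals T1/T2 and is invariant to intensity rescaling", {
  expect_equal(r2_over_r1(500, 100), 5)
  expect_equal(r2_over_r1(200, 200), 1)
  g1 <- gen_relaxation(34, t_ms = 300, noise_frac = 0.01)
  f1 <- fit_monoexponential(g1$delays_ms, g1$intensities)
  f2 <- fit_monoexponential(g1$delays_ms, 37.5 * g1$intensities)
  expect_equal(f1$time_constant_ms, f2$time_constant_ms, tolerance = 1e-6)
})

test_that("per-residue relaxation fitting handles sparse leucine coverage", {
  delays <- t1_delay_schedule()
  truths <- c(`270` = 350, `281` = 500, `292` = 420)   # leucine positions
  mat <- t(vapply(truths, function(tt) exp(-delays / tt),
                  numeric(length(delays))))
  res <- suppressWarnings(fit_relaxation_series(delays, mat))
  expect_equal(res$residue_index, c(270L, 281L, 292L))
  expect_equal(res$t_ms, unname(truths), tolerance = 1e-7)
})

test_that("reduced spectral density mapping has its closed-form properties", {
  # NOE = 1 -> no cross relaxation -> J(0.87 wH) = 0
  j <- reduced_spectral_density(r1 = 1.5, r2 = 4, noe = 1)
  expect_equal(j$j_wh, 0)
  # doubling R2 at fixed R1, NOE raises J(0)
  j2 <- reduced_spectral_density(r1 = 1.5, r2 = 8, noe = 1)
  expect_gt(j2$j0, j$j0)
  expect_error(reduced_spectral_density(-1, 4, 1))
})

test_that("spectral density mapping round-trips a single Lorentzian", {
  for (tau_c in c(1e-9, 5e-9, 20e-9)) {
    jfun <- function(w) (2 / 5) * tau_c / (1 + (w * tau_c)^2)
    fwd <- relaxation_from_spectral_density(jfun, field_mhz = 700)
    back <- reduced_spectral_density(fwd$r1, fwd$r2, fwd$noe,
                                     field_mhz = 700)
    w_h <- 2 * pi * 700e6
    w_n <- w_h * 2.7126e7 / 2.6752218744e8
    expect_equal(back$j0, jfun(0), tolerance = 1e-10)
    expect_equal(back$j_wn, jfun(w_n), tolerance = 1e-10)
    expect_equal(back$j_wh, jfun(0.87 * w_h), tolerance = 1e-10)
    expect_true(back$physical)
  }
})

test_that("Stejskal-Tanner fits recover the printed diffusion coefficients exactly", {
  # noiseless forward decays at the default acquisition schedule, generated
  # with the reported wild-type and var8 diffusion coefficients
  for (d_true in c(1.54e-10, 2.95e-10)) {
    g <- gen_dosy(41, d_m2_s = d_true)
    expect_equal(g$intensities[1] > g$intensities[32], TRUE)
    for (m in c("log", "nls")) {
      fit <- suppressWarnings(
        fit_dosy(g$gradients_g_cm, g$intensities, method = m))
      expect_true(fit$ok)
      expect_equal(fit$d_m2_s, d_true, tolerance = 1e-10)
    }
  }
})

test_that("noisy DOSY decays are recovered within 3 standard errors", {
  d_true <- 2.95e-10
  hit <- 0
  for (s in 1:25) {
    g <- gen_dosy(200 + s, d_m2_s = d_true, noise_frac = 0.02)
    fit <- fit_dosy(g$gradients_g_cm, g$intensities)
    if (fit$ok && abs(fit$d_m2_s - d_true) <= 3 * fit$se_m2_s) hit <- hit + 1
  }
  expect_gte(hit, 23)
})

test_that("the DOSY gradient schedule spans 5-95% of the probe maximum", {
  g <- dosy_gradient_schedule()
  expect_length(g, 32)
  expect_equal(g[1], 0.05 * 57.7)
  expect_equal(g[32], 0.95 * 57.7)
  expect_true(all(diff(g) > 0))
})
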