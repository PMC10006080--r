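#' Acquisition schedules used for the peptide relaxation experiments
#'
#' Delay lists of the longitudinal (T1) inversion-recovery series and the
#' CPMG transverse (T2) series, in milliseconds, and the DOSY gradient
#' schedule (32 increments linearly spanning 5-95% of the 57.7 G/cm maximum).
#'
#' @return Numeric vector of delays (ms) or gradient strengths (G/cm).
#' @export
t1_delay_schedule <- function() {
  c(10, 20, 40, 80, 120, 160, 200, 300, 400, 600, 1200, 2400)
}

#' @rdname t1_delay_schedule
#' @export
t2_delay_schedule <- function() {
  c(17, 34, 51, 68, 85, 102, 119, 153, 204, 254, 305)
}

#' @rdname t1_delay_schedule
#' @param n number of gradient increments.
#' @param g_max maximum gradient strength of the probe (G/cm).
#' @param range fractional span of `g_max` covered.
#' @export
dosy_gradient_schedule <- function(n = 32, g_max = 57.7,
                                   range = c(0.05, 0.95)) {
  seq(range[1] * g_max, range[2] * g_max, length.out = n)
}

#' Secondary chemical shifts with scalar offset correction
#'
#' Computes per-residue secondary shifts `observed - random_coil` for each
#' nucleus after removing a single scalar referencing offset per nucleus (the
#' median of observed-minus-reference over residues with both values). A
#' residue missing its reference shift yields `NA` for that nucleus — absent,
#' never zero.
#'
#' @param observed,reference data frames aligned on `residue_index`, with
#'   shift columns among `ca`, `cb`, `ha` (ppm).
#' @param nuclei shift columns to use.
#' @param offset_correct apply the median offset correction (default TRUE).
#' @return Data frame with `residue_index` and one secondary-shift column per
#'   nucleus (ppm).
#' @export
secondary_shifts <- function(observed, reference, nuclei = c("ca", "cb", "ha"),
                             offset_correct = TRUE) {
  stopifnot("residue_index" %in% names(observed),
            "residue_index" %in% names(reference))
  idx <- observed$residue_index
  ref <- reference[match(idx, reference$residue_index), , drop = FALSE]
  out <- data.frame(residue_index = idx)
  for (nu in nuclei) {
    if (!nu %in% names(observed) || !nu %in% names(ref)) next
    d <- observed[[nu]] - ref[[nu]]
    if (offset_correct) {
      off <- stats::median(d, na.rm = TRUE)
      if (is.finite(off)) d <- d - off
    }
    out[[nu]] <- d
  }
  out
}

#' Random-coil-index configuration
#'
#' Coefficients of the RCI computation and of the monotone RCI-to-S2 map.
#' The functional form `S2 = 1 - a * log(1 + b * RCI)` follows the published
#' random-coil-index order-parameter relation (a = 0.4, b = 17.7); the
#' per-nucleus weights (Halpha shifts up-weighted to the carbon ppm scale),
#' the denominator floor that caps RCI for vanishing secondary shifts, and
#' the RCI scale are package configuration, recorded here rather than
#' hard-coded, and replaceable wholesale when a different published
#' coefficient set is preferred.
#'
#' @param weights named per-nucleus weights for the |secondary shift| average.
#' @param floor_ppm minimum weighted shift magnitude (ppm); caps RCI.
#' @param rci_scale numerator of `RCI = rci_scale / weighted_shift`.
#' @param s2_a,s2_b coefficients of the RCI-to-S2 map.
#' @return A list of class `rci_config`.
#' @export
rci_config <- function(weights = c(ca = 1, cb = 1, ha = 5),
                       floor_ppm = 0.5, rci_scale = 0.1,
                       s2_a = 0.4, s2_b = 17.7) {
  structure(list(weights = weights, floor_ppm = floor_ppm,
                 rci_scale = rci_scale, s2_a = s2_a, s2_b = s2_b),
            class = "rci_config")
}

#' Random coil index and backbone order parameters from secondary shifts
#'
#' Per residue, the weighted mean of available |secondary shift| values is
#' floored at `floor_ppm` and inverted to the random coil index
#' `RCI = rci_scale / weighted_shift`; large deviations from random-coil
#' shifts give small RCI. Order parameters follow the monotone map
#' `S2 = 1 - a*log(1 + b*RCI)` clamped to \[0, 1\], so S2 is non-increasing
#' in RCI: 1 = rigid, 0 = fully flexible. Residues with no nucleus observed
#' are absent from the output.
#'
#' @param secondary data frame from [secondary_shifts()].
#' @param config an [rci_config()].
#' @return Data frame with `residue_index`, `rci`, `s2`.
#' @export
rci_s2 <- function(secondary, config = rci_config()) {
  nuclei <- intersect(names(config$weights), names(secondary))
  if (!length(nuclei)) stop("no recognised nucleus columns in input")
  ss <- abs(as.matrix(secondary[nuclei]))
  w <- config$weights[nuclei]
  wsum <- apply(ss, 1, function(row) {
    ok <- !is.na(row)
    if (!any(ok)) return(NA_real_)
    sum(w[ok] * row[ok]) / sum(w[ok])
  })
  keep <- !is.na(wsum)
  rci <- config$rci_scale / pmax(wsum[keep], config$floor_ppm)
  s2 <- pmin(pmax(1 - config$s2_a * log(1 + config$s2_b * rci), 0), 1)
  data.frame(residue_index = secondary$residue_index[keep],
             rci = rci, s2 = s2)
}

#' Fit a monoexponential relaxation decay
#'
#' Nonlinear least-squares fit of `I(t) = I0 * exp(-t / T)` to an
#' intensity-versus-delay series (Levenberg-Marquardt, started from the
#' log-linear regression). Non-decaying data are flagged as failures rather
#' than clamped.
#'
#' @param delays_ms relaxation delays (ms), at least 3, positive, distinct.
#' @param intensities peak intensities (arbitrary units), positive.
#' @return List with `time_constant_ms`, `se_ms`, `i0`, `rate_s` (= 1000/T),
#'   and `ok`; on failure `ok = FALSE` and the estimates are `NA`.
#' @export
fit_monoexponential <- function(delays_ms, intensities) {
  stopifnot(length(delays_ms) >= 3, length(delays_ms) == length(intensities),
            all(delays_ms > 0), !anyDuplicated(delays_ms))
  fail <- list(time_constant_ms = NA_real_, se_ms = NA_real_, i0 = NA_real_,
               rate_s = NA_real_, ok = FALSE)
  if (any(intensities <= 0)) return(fail)
  lf <- stats::lm(log(intensities) ~ delays_ms)
  slope <- stats::coef(lf)[2]
  if (!is.finite(slope) || slope >= 0) return(fail)    # non-decaying
  start <- list(i0 = exp(unname(stats::coef(lf)[1])), rate = unname(-slope))
  fit <- tryCatch(
    minpack.lm::nlsLM(intensities ~ i0 * exp(-rate * delays_ms),
                      start = start,
                      lower = c(i0 = 0, rate = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail)
  cf <- stats::coef(fit)
  rate <- cf[["rate"]]
  se_rate <- tryCatch(summary(fit)$coefficients["rate", "Std. Error"],
                      error = function(e) NA_real_)
  t_ms <- 1 / rate
  list(time_constant_ms = t_ms,
       se_ms = if (is.finite(se_rate)) se_rate / rate^2 else NA_real_,
       i0 = cf[["i0"]], rate_s = 1000 * rate, ok = TRUE)
}

#' Fit T1/T2 relaxation series for many residues
#'
#' Applies [fit_monoexponential()] per residue (sparse residue coverage is
#' expected: only leucines are 15N-labelled in these peptides) and derives
#' rates and their ratio.
#'
#' @param delays_ms delay schedule (ms).
#' @param intensity_matrix residues x delays intensity matrix with residue
#'   indices as row names.
#' @return Data frame with per-residue `t_ms`, `se_ms`, `rate_s`, `ok`.
#' @export
fit_relaxation_series <- function(delays_ms, intensity_matrix) {
  res <- lapply(seq_len(nrow(intensity_matrix)), function(r)
    fit_monoexponential(delays_ms, intensity_matrix[r, ]))
  data.frame(
    residue_index = if (!is.null(rownames(intensity_matrix)))
      as.integer(rownames(intensity_matrix)) else seq_along(res),
    t_ms = vapply(res, `[[`, 0, "time_constant_ms"),
    se_ms = vapply(res, `[[`, 0, "se_ms"),
    rate_s = vapply(res, `[[`, 0, "rate_s"),
    ok = vapply(res, `[[`, TRUE, "ok"))
}

#' R2/R1 relaxation-rate ratio
#'
#' `R2/R1 = T1/T2`, per residue; elevated values flag conformational
#' exchange. Residues where either fit failed are absent (`NA`).
#'
#' @param t1_ms,t2_ms fitted time constants (ms), aligned on residues.
#' @return Numeric vector of ratios.
#' @export
r2_over_r1 <- function(t1_ms, t2_ms) t1_ms / t2_ms

# physical constants for the 15N-1H spin pair
.nmr_const <- list(
  gamma_h = 2.6752218744e8,   # rad s-1 T-1
  gamma_n = -2.7126e7,        # rad s-1 T-1
  r_nh = 1.02e-10,            # m
  csa_n = -160e-6,            # unitless (ppm * 1e-6)
  mu0 = 4e-7 * pi, hbar = 1.054571817e-34)

#' Reduced spectral density mapping for 15N relaxation
#'
#' Maps `R1`, `R2` and the heteronuclear NOE at one field to the spectral
#' density sampled at three frequencies, using the standard high-frequency
#' reduction `J(wH +/- wN) ~ J(0.87 wH)`:
#' \deqn{\sigma = R_1 (NOE - 1) \gamma_N/\gamma_H,\quad
#'       J(0.87\omega_H) = 4\sigma/(5d^2)}
#' \deqn{J(\omega_N) = (R_1 - 7 d^2 J_h/4)/(3d^2/4 + c^2)}
#' \deqn{J(0) = (R_2 - d^2(3 J_N + 13 J_h)/8 - c^2 J_N/2)/(d^2/2 + 2c^2/3)}
#' with dipolar constant `d` (1.02 A NH bond) and CSA constant
#' `c = wN * delta_sigma / sqrt(3)` (-160 ppm). Physically impossible inputs
#' can yield negative densities; these are flagged but still reported.
#'
#' @param r1,r2 longitudinal and transverse rates (s-1), positive.
#' @param noe heteronuclear NOE ratio.
#' @param field_mhz 1H frequency (default 700).
#' @return Data frame with `j0`, `j_wn`, `j_wh` (s/rad) and `physical`
#'   (all three non-negative).
#' @export
reduced_spectral_density <- function(r1, r2, noe, field_mhz = 700) {
  stopifnot(all(r1 > 0), all(r2 > 0))
  k <- .nmr_const
  d <- k$mu0 * k$hbar * k$gamma_h * abs(k$gamma_n) / (4 * pi * k$r_nh^3)
  w_h <- 2 * pi * field_mhz * 1e6
  w_n <- w_h * abs(k$gamma_n) / k$gamma_h
  cc <- w_n * abs(k$csa_n) / sqrt(3)
  sigma <- r1 * (noe - 1) * abs(k$gamma_n) / k$gamma_h
  j_wh <- 4 * sigma / (5 * d^2)
  j_wn <- (r1 - 7 * d^2 * j_wh / 4) / (3 * d^2 / 4 + cc^2)
  j0 <- (r2 - d^2 * (3 * j_wn + 13 * j_wh) / 8 - cc^2 * j_wn / 2) /
    (d^2 / 2 + 2 * cc^2 / 3)
  data.frame(j0 = j0, j_wn = j_wn, j_wh = j_wh,
             physical = j0 >= 0 & j_wn >= 0 & j_wh >= 0)
}

#' Forward relaxation rates from a spectral density function
#'
#' Computes `R1`, `R2` and the NOE from a spectral density `J(w)` under the
#' same reduced (three-frequency) approximation that
#' [reduced_spectral_density()] inverts, so the pair round-trips exactly.
#' Used to simulate relaxation observables from model spectral densities such
#' as a single Lorentzian `J(w) = (2/5) tau_c / (1 + (w tau_c)^2)`.
#'
#' @param j_fun function of angular frequency (rad/s) returning J (s/rad).
#' @param field_mhz 1H frequency (default 700).
#' @return List with `r1`, `r2` (s-1) and `noe`.
#' @export
relaxation_from_spectral_density <- function(j_fun, field_mhz = 700) {
  k <- .nmr_const
  d <- k$mu0 * k$hbar * k$gamma_h * abs(k$gamma_n) / (4 * pi * k$r_nh^3)
  w_h <- 2 * pi * field_mhz * 1e6
  w_n <- w_h * abs(k$gamma_n) / k$gamma_h
  cc <- w_n * abs(k$csa_n) / sqrt(3)
  j0 <- j_fun(0); j_wn <- j_fun(w_n); j_wh <- j_fun(0.87 * w_h)
  r1 <- d^2 / 4 * (7 * j_wh + 3 * j_wn) + cc^2 * j_wn
  r2 <- d^2 / 8 * (4 * j0 + 3 * j_wn + 13 * j_wh) +
    cc^2 / 6 * (4 * j0 + 3 * j_wn)
  sigma <- d^2 / 4 * 5 * j_wh
  list(r1 = r1, r2 = r2, noe = 1 + sigma / r1 * k$gamma_h / abs(k$gamma_n))
}

#' Fit a Stejskal-Tanner DOSY gradient decay
#'
#' Fits `I(g) = I0 * exp(-D * (gamma * g * delta)^2 * (Delta - delta/3))` to
#' a pulsed-field-gradient intensity decay. The default route is weighted
#' linear least squares in the log-intensity domain (weights `I^2`, the
#' delta-method variance of `log I` under additive noise); `method = "nls"`
#' fits the raw exponential by Levenberg-Marquardt. The rectangular
#' bipolar-gradient diffusion-time correction `Delta - delta/3` is the
#' default; pass `diffusion_time_s` to substitute another convention.
#'
#' @param gradients_g_cm gradient strengths (G/cm), strictly increasing, at
#'   least 5 values.
#' @param intensities signal intensities, positive.
#' @param delta_s gradient pulse length (s), default 2 ms.
#' @param big_delta_s diffusion delay (s), default 75 ms.
#' @param gamma_rad_s_g gyromagnetic ratio of the observed nucleus in
#'   rad s-1 G-1 (default 1H, 26752.2).
#' @param method `"log"` (weighted log-domain, default) or `"nls"`.
#' @param diffusion_time_s effective diffusion time (s); default
#'   `big_delta_s - delta_s / 3`.
#' @return List with `d_m2_s`, `se_m2_s`, `i0`, `ok`; severely non-monotone
#'   decays are flagged `ok = FALSE`.
#' @export
fit_dosy <- function(gradients_g_cm, intensities, delta_s = 2e-3,
                     big_delta_s = 75e-3, gamma_rad_s_g = 26752.2187,
                     method = c("log", "nls"), diffusion_time_s = NULL) {
  method <- match.arg(method)
  stopifnot(length(gradients_g_cm) >= 5,
            length(gradients_g_cm) == length(intensities),
            all(diff(gradients_g_cm) > 0), all(intensities > 0))
  td <- diffusion_time_s %||% (big_delta_s - delta_s / 3)
  b <- (gamma_rad_s_g * gradients_g_cm * delta_s)^2 * td   # s / cm^2
  fail <- list(d_m2_s = NA_real_, se_m2_s = NA_real_, i0 = NA_real_,
               ok = FALSE)
  if (method == "log") {
    fit <- stats::lm(log(intensities) ~ b, weights = intensities^2)
    d_cm <- -stats::coef(fit)[[2]]
    se_cm <- summary(fit)$coefficients[2, 2]
    i0 <- exp(stats::coef(fit)[[1]])
  } else {
    lf <- stats::lm(log(intensities) ~ b)
    start <- list(i0 = exp(unname(stats::coef(lf)[1])),
                  d_cm = max(unname(-stats::coef(lf)[2]), 1e-12))
    fit <- tryCatch(
      minpack.lm::nlsLM(intensities ~ i0 * exp(-d_cm * b), start = start,
                        lower = c(i0 = 0, d_cm = 0)),
      error = function(e) NULL)
    if (is.null(fit)) return(fail)
    d_cm <- stats::coef(fit)[["d_cm"]]
    se_cm <- tryCatch(summary(fit)$coefficients["d_cm", "Std. Error"],
                      error = function(e) NA_real_)
    i0 <- stats::coef(fit)[["i0"]]
  }
  if (!is.finite(d_cm) || d_cm <= 0) return(fail)
  # cm^2/s -> m^2/s
  list(d_m2_s = d_cm * 1e-4, se_m2_s = se_cm * 1e-4, i0 = i0, ok = TRUE)
}
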