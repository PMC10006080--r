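#' FRAP intensity trace
#'
#' Raw fluorescence-recovery-after-photobleaching record: bleach-ROI,
#' whole-structure-ROI and camera-background intensities versus time, with
#' the pre-bleach frames marked. The two ROIs may differ in area, so no
#' ordering between them is assumed. Traces are assumed drift-corrected.
#'
#' @param time_s acquisition times (s).
#' @param i_bleach bleach-ROI intensity.
#' @param i_total whole-structure ROI intensity.
#' @param i_background camera-offset background.
#' @param pre_bleach logical vector marking pre-bleach frames (at least one),
#'   or the number of leading pre-bleach frames.
#' @return An object of class `frap_trace`.
#' @export
frap_trace <- function(time_s, i_bleach, i_total, i_background, pre_bleach) {
  n <- length(time_s)
  stopifnot(length(i_bleach) == n, length(i_total) == n,
            length(i_background) == n)
  if (is.numeric(pre_bleach) && length(pre_bleach) == 1L)
    pre_bleach <- seq_len(n) <= pre_bleach
  stopifnot(length(pre_bleach) == n, any(pre_bleach))
  if (any(c(i_bleach, i_total, i_background) < 0))
    stop("intensities must be non-negative")
  structure(list(time_s = as.numeric(time_s), i_bleach = as.numeric(i_bleach),
                 i_total = as.numeric(i_total),
                 i_background = as.numeric(i_background),
                 pre_bleach = as.logical(pre_bleach)),
            class = "frap_trace")
}

#' Read FRAP traces from CSV
#'
#' Expects columns `time_s`, `i_bleach`, `i_total`, `i_background` and
#' `phase` (`pre` or `post`).
#'
#' @param path CSV path.
#' @return A [frap_trace].
#' @export
read_frap_csv <- function(path) {
  tab <- utils::read.csv(path)
  frap_trace(tab$time_s, tab$i_bleach, tab$i_total, tab$i_background,
             pre_bleach = tab$phase == "pre")
}

#' Double-normalize a FRAP trace
#'
#' The double-normalization used for these recovery curves:
#' \deqn{N(t) = \frac{(I_{bleach}(t) - I_{bg}(t)) / (I_{bleach}(t_0) -
#'   I_{bg}(t_0))}{(I_{total}(t) - I_{bg}(t)) / (I_{total}(t_0) -
#'   I_{bg}(t_0))}}
#' where the `t0` quantities are means over the pre-bleach frames. The
#' whole-structure denominator corrects for bleaching during acquisition:
#' any multiplicative loss hitting both ROIs equally cancels exactly.
#' By construction the pre-bleach reference level is 1.
#'
#' @param trace a [frap_trace].
#' @return Data frame with `time_s`, `normalized`, `pre_bleach`.
#' @export
normalize_trace <- function(trace) {
  pre <- trace$pre_bleach
  b0 <- mean(trace$i_bleach[pre]) - mean(trace$i_background[pre])
  t0 <- mean(trace$i_total[pre]) - mean(trace$i_background[pre])
  if (b0 <= 0) stop("pre-bleach bleach-ROI intensity does not exceed ",
                    "background; cannot normalize (bleach ROI)")
  if (t0 <= 0) stop("pre-bleach whole-structure intensity does not exceed ",
                    "background; cannot normalize (total ROI)")
  num <- (trace$i_bleach - trace$i_background) / b0
  den <- (trace$i_total - trace$i_background) / t0
  if (any(den == 0)) stop("whole-structure ROI equals background at some ",
                          "frame; normalization undefined (total ROI)")
  data.frame(time_s = trace$time_s, normalized = num / den,
             pre_bleach = pre)
}

#' Average normalized FRAP curves
#'
#' Pointwise mean and standard error of the mean over replicate normalized
#' curves sharing a time base; curves on different grids are linearly
#' resampled onto the first curve's times.
#'
#' @param curves list of data frames with `time_s` and `normalized` (as from
#'   [normalize_trace()]).
#' @return Data frame with `time_s`, `mean`, `sem`, `n`; `sem` is `NA` for a
#'   single curve.
#' @export
average_curves <- function(curves) {
  stopifnot(length(curves) >= 1)
  tb <- curves[[1]]$time_s
  vals <- vapply(curves, function(cv) {
    if (length(cv$time_s) == length(tb) && all(cv$time_s == tb))
      cv$normalized
    else stats::approx(cv$time_s, cv$normalized, xout = tb, rule = 2)$y
  }, numeric(length(tb)))
  vals <- matrix(vals, nrow = length(tb))
  n <- ncol(vals)
  data.frame(time_s = tb, mean = rowMeans(vals),
             sem = if (n > 1) apply(vals, 1, stats::sd) / sqrt(n)
                   else NA_real_,
             n = n)
}

#' Fit single-exponential FRAP recovery kinetics
#'
#' Fits `N(t) = N_inf - (N_inf - N_0) * exp(-(t - t_bleach)/tau)` to the
#' post-bleach part of a normalized curve and reports the mobile fraction
#' `(N_inf - N_0)/(N_pre - N_0)` with the pre-bleach level `N_pre = 1`, and
#' the recovery half-time `tau * log(2)`. A flat, non-recovering curve is
#' reported with mobile fraction ~0, `tau` absent and `flat = TRUE`.
#' A double-exponential model (`model = "double"`) is available; its
#' half-time is then located numerically on the fitted curve.
#'
#' @param time_s,normalized normalized curve (full trace; post-bleach points
#'   are selected via `post`).
#' @param post logical vector marking post-bleach frames; default all frames
#'   (pass `!pre_bleach` from [normalize_trace()] output).
#' @param model `"single"` (default) or `"double"`.
#' @return List with `mobile_fraction`, `half_time_s`, `tau_s`, `n0`, `n_inf`,
#'   `se_mobile`, `flat`, `ok`.
#' @export
fit_recovery <- function(time_s, normalized, post = NULL,
                         model = c("single", "double")) {
  model <- match.arg(model)
  if (is.null(post)) post <- rep(TRUE, length(time_s))
  tt <- time_s[post]; yy <- normalized[post]
  stopifnot(length(tt) >= 10)
  tt <- tt - tt[1]
  out <- list(mobile_fraction = NA_real_, half_time_s = NA_real_,
              tau_s = NA_real_, n0 = yy[1], n_inf = NA_real_,
              se_mobile = NA_real_, flat = FALSE, ok = FALSE)
  # flat curve: recovery amplitude indistinguishable from noise
  amp <- mean(utils::tail(yy, max(3L, length(yy) %/% 10))) - yy[1]
  if (abs(amp) <= 2 * stats::sd(diff(yy)) / sqrt(2) || amp < 0) {
    out$mobile_fraction <- 0
    out$n_inf <- mean(yy)
    out$flat <- TRUE
    out$ok <- TRUE
    return(out)
  }
  n0_start <- yy[1]
  ninf_start <- mean(utils::tail(yy, max(3L, length(yy) %/% 10)))
  tau_start <- max(tt[min(which(yy >= n0_start + 0.63 * amp))], tt[2])
  if (model == "single") {
    fit <- tryCatch(minpack.lm::nlsLM(
      yy ~ ninf - (ninf - n0) * exp(-tt / tau),
      start = list(ninf = ninf_start, n0 = n0_start, tau = tau_start),
      lower = c(ninf = -Inf, n0 = -Inf, tau = 1e-9)),
      error = function(e) NULL)
    if (is.null(fit)) return(out)
    cf <- stats::coef(fit)
    out$tau_s <- cf[["tau"]]
    out$half_time_s <- cf[["tau"]] * log(2)
    out$n0 <- cf[["n0"]]; out$n_inf <- cf[["ninf"]]
  } else {
    fit <- tryCatch(minpack.lm::nlsLM(
      yy ~ ninf - a1 * exp(-tt / tau1) - a2 * exp(-tt / tau2),
      start = list(ninf = ninf_start, a1 = amp / 2, a2 = amp / 2,
                   tau1 = tau_start / 3, tau2 = tau_start * 3),
      lower = c(ninf = -Inf, a1 = 0, a2 = 0, tau1 = 1e-9, tau2 = 1e-9)),
      error = function(e) NULL)
    if (is.null(fit)) return(out)
    cf <- stats::coef(fit)
    out$n0 <- cf[["ninf"]] - cf[["a1"]] - cf[["a2"]]
    out$n_inf <- cf[["ninf"]]
    half_level <- (out$n_inf + out$n0) / 2
    pred <- function(t) cf[["ninf"]] - cf[["a1"]] * exp(-t / cf[["tau1"]]) -
      cf[["a2"]] * exp(-t / cf[["tau2"]])
    out$half_time_s <- tryCatch(
      stats::uniroot(function(t) pred(t) - half_level,
                     c(0, max(tt)))$root, error = function(e) NA_real_)
    out$tau_s <- NA_real_
  }
  out$mobile_fraction <- (out$n_inf - out$n0) / (1 - out$n0)
  se <- tryCatch({
    sm <- summary(fit)$coefficients
    if (model == "single")
      sqrt(sm["ninf", 2]^2 + sm["n0", 2]^2) / abs(1 - out$n0)
    else NA_real_
  }, error = function(e) NA_real_)
  out$se_mobile <- se
  out$ok <- TRUE
  out
}

#' Classify focus mobility from FRAP recovery
#'
#' A focus recovering at least `threshold` of its mobile pool within the
#' observation horizon is liquid-like (rapid exchange with the surrounding
#' pool, as for phase-separated condensates); otherwise solid-like. The
#' boundary is inclusive: a mobile fraction exactly at the threshold is
#' liquid-like.
#'
#' @param mobile_fraction fitted mobile fraction.
#' @param threshold classification threshold (default 0.5).
#' @param half_time_s optional recovery half-time; recovery slower than the
#'   horizon is treated as immobile within it.
#' @param horizon_s observation horizon (default 120 s, the standard
#'   acquisition length here).
#' @return `"liquid-like"` or `"solid-like"`.
#' @export
classify_mobility <- function(mobile_fraction, threshold = 0.5,
                              half_time_s = NA, horizon_s = 120) {
  if (is.na(mobile_fraction)) return(NA_character_)
  reached <- is.na(half_time_s) || half_time_s <= horizon_s
  if (reached && mobile_fraction >= threshold) "liquid-like" else "solid-like"
}

#' End-to-end FRAP analysis of one focus
#'
#' Normalizes a raw trace, fits recovery kinetics and classifies mobility.
#'
#' @param trace a [frap_trace].
#' @param threshold,horizon_s see [classify_mobility()].
#' @param model recovery model, see [fit_recovery()].
#' @return List of class `frap_result`: the normalized curve plus the fit
#'   fields and `mobility_class`.
#' @export
analyze_frap <- function(trace, threshold = 0.5, horizon_s = 120,
                         model = "single") {
  nc <- normalize_trace(trace)
  fit <- fit_recovery(nc$time_s, nc$normalized, post = !nc$pre_bleach,
                      model = model)
  fit$mobility_class <- classify_mobility(fit$mobile_fraction, threshold,
                                          fit$half_time_s, horizon_s)
  fit$curve <- nc
  class(fit) <- "frap_result"
  fit
}

#' @export
print.frap_result <- function(x, ...) {
  cat(sprintf("frap_result: mobile fraction %.3f, half-time %s s -> %s\n",
              x$mobile_fraction,
              if (is.na(x$half_time_s)) "--" else sprintf("%.1f",
                                                          x$half_time_s),
              x$mobility_class))
  invisible(x)
}
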