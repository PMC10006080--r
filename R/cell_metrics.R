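#' Myotube fusion index
#'
#' Fraction of nuclei residing in multinucleated myocytes: nuclei counted in
#' myocytes with two or more nuclei over the total nuclei in the visual
#' field. The standard readout of differentiation progress.
#'
#' @param multinucleated nuclei in myocytes with >= 2 nuclei (per field).
#' @param total total nuclei in the field, > 0.
#' @return Fusion index in \[0, 1\] (vectorised over fields).
#' @export
fusion_index <- function(multinucleated, total) {
  if (any(total <= 0)) stop("total nuclei count must be positive")
  if (any(multinucleated < 0 | multinucleated > total))
    stop("multinucleated count must lie in [0, total]")
  multinucleated / total
}

#' Pool fusion indices over visual fields
#'
#' Pooling fields is the totals-weighted mean of per-field indices, which
#' equals the index of the pooled counts exactly.
#'
#' @param multinucleated,total per-field counts.
#' @return Single pooled fusion index.
#' @export
pool_fusion_index <- function(multinucleated, total) {
  fusion_index(sum(multinucleated), sum(total))
}

#' Weighted mean and weighted standard error
#'
#' Summary convention for pooled data: weighted mean with weights
#' proportional to the number of samples per group, and the weighted standard
#' error `sqrt(sum w^2 se^2) / sum w` of independent group means.
#'
#' @param means group means.
#' @param ses group standard errors.
#' @param weights group weights (e.g. sample counts).
#' @return List with `mean` and `se`.
#' @export
weighted_mean_se <- function(means, ses, weights) {
  w <- weights / sum(weights)
  list(mean = sum(w * means), se = sqrt(sum(w^2 * ses^2)))
}

#' Normalize reporter activity to the wild-type control
#'
#' Per-sample transcription activity is the luciferase/galactosidase signal
#' ratio; within each experiment batch the ratios are divided by the batch's
#' wild-type mean ratio and scaled to percent, so wild type averages 100% in
#' every batch. Batches lacking a wild-type sample are dropped with a
#' warning. Per-variant summaries are mean +/- standard error over samples.
#'
#' @param readings data frame with columns `variant`, `luciferase`,
#'   `galactosidase` and `batch` (experiment identifier).
#' @param wt_label wild-type level of `variant` (default `"wt"`).
#' @return List of class `activity_summary`: `samples` (per-sample
#'   `percent_wt`) and `summary` (per-variant `mean`, `se`, `n`).
#' @export
normalize_activity <- function(readings, wt_label = "wt") {
  stopifnot(all(c("variant", "luciferase", "galactosidase", "batch") %in%
                  names(readings)),
            all(readings$luciferase > 0), all(readings$galactosidase > 0))
  readings$ratio <- readings$luciferase / readings$galactosidase
  keep <- vapply(split(readings, readings$batch),
                 function(b) wt_label %in% b$variant, TRUE)
  drop <- names(keep)[!keep]
  if (length(drop)) {
    warning("batch(es) without a wild-type sample excluded: ",
            paste(drop, collapse = ", "))
    readings <- readings[!readings$batch %in% drop, , drop = FALSE]
  }
  if (!nrow(readings)) stop("no batch contains the wild-type label")
  parts <- lapply(split(readings, readings$batch), function(b) {
    wt_mean <- mean(b$ratio[b$variant == wt_label])
    b$percent_wt <- 100 * b$ratio / wt_mean
    b
  })
  samples <- do.call(rbind, parts)
  rownames(samples) <- NULL
  by_var <- split(samples$percent_wt, samples$variant)
  summary <- data.frame(
    variant = names(by_var),
    mean = vapply(by_var, mean, 0),
    se = vapply(by_var, function(v)
      if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_, 0),
    n = lengths(by_var), row.names = NULL)
  structure(list(samples = samples, summary = summary, wt_label = wt_label),
            class = "activity_summary")
}

#' @export
print.activity_summary <- function(x, ...) {
  cat("activity_summary (% of", x$wt_label, "control):\n")
  s <- x$summary
  for (r in seq_len(nrow(s)))
    cat(sprintf("  %-8s %6.1f +/- %4.1f %% (n = %d)\n", s$variant[r],
                s$mean[r], s$se[r], s$n[r]))
  invisible(x)
}

#' Compare variant groups against a reference
#'
#' Either independent two-sided t-tests of each group versus the reference
#' (`"t_test"`), or a one-way ANOVA followed by pairwise posthoc comparisons
#' versus the reference using the pooled residual variance, with Holm
#' (step-down Bonferroni) adjustment (`"anova_holm"`). Groups with fewer
#' than two observations or zero variance are flagged.
#'
#' @param values numeric observations.
#' @param group group labels, one per observation.
#' @param reference reference group label (default `"wt"`).
#' @param method `"t_test"` or `"anova_holm"`.
#' @return Data frame with `group`, `p_value`, `p_adjusted` (Holm for
#'   `anova_holm`, unadjusted copy for `t_test`), `flag`.
#' @export
compare_groups <- function(values, group, reference = "wt",
                           method = c("t_test", "anova_holm")) {
  method <- match.arg(method)
  group <- as.character(group)
  stopifnot(reference %in% group)
  others <- setdiff(unique(group), reference)
  ref_v <- values[group == reference]
  degen <- function(v) length(v) < 2 || stats::sd(v) == 0
  if (method == "t_test") {
    res <- lapply(others, function(g) {
      v <- values[group == g]
      if (degen(v) || degen(ref_v))
        return(list(p = NA_real_, flag = "degenerate"))
      list(p = stats::t.test(v, ref_v)$p.value, flag = "")
    })
    p <- vapply(res, `[[`, 0, "p")
    data.frame(group = others, p_value = p, p_adjusted = p,
               flag = vapply(res, `[[`, "", "flag"))
  } else {
    fit <- stats::aov(values ~ factor(group))
    msr <- summary(fit)[[1]]["Residuals", "Mean Sq"]
    dfr <- summary(fit)[[1]]["Residuals", "Df"]
    res <- lapply(others, function(g) {
      v <- values[group == g]
      if (degen(v) || degen(ref_v))
        return(list(p = NA_real_, flag = "degenerate"))
      se <- sqrt(msr * (1 / length(v) + 1 / length(ref_v)))
      tstat <- (mean(v) - mean(ref_v)) / se
      list(p = 2 * stats::pt(-abs(tstat), dfr), flag = "")
    })
    p <- vapply(res, `[[`, 0, "p")
    data.frame(group = others, p_value = p,
               p_adjusted = stats::p.adjust(p, "holm"),
               flag = vapply(res, `[[`, "", "flag"))
  }
}

#' Correlation between beta-domain disorder and transcription activity
#'
#' Rank correlation (Spearman, default) between per-variant window-mean
#' disorder probability and normalized activity; the sign carries the
#' biology (a negative coefficient means more disordered beta-domains are
#' less active). Rank correlation is invariant under monotone transforms of
#' either axis. Constant input is flagged as undefined.
#'
#' @param mean_p_d per-variant window-mean disorder probabilities (>= 3).
#' @param activity per-variant normalized activities.
#' @param method correlation method (default `"spearman"`).
#' @return List with `estimate`, `p_value`, `method`, `ok`.
#' @export
dynamics_activity_correlation <- function(mean_p_d, activity,
                                          method = "spearman") {
  stopifnot(length(mean_p_d) == length(activity), length(mean_p_d) >= 3)
  if (stats::sd(mean_p_d) == 0 || stats::sd(activity) == 0)
    return(list(estimate = NA_real_, p_value = NA_real_, method = method,
                ok = FALSE))
  ct <- suppressWarnings(stats::cor.test(mean_p_d, activity,
                                         method = method))
  list(estimate = unname(ct$estimate), p_value = ct$p.value, method = method,
       ok = TRUE)
}
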