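#' Average dynamics descriptors over a sequence window
#'
#' Arithmetic means of the per-residue descriptors `p_d`, `p_dd` and `p_dp`
#' over a residue window, the aggregation used to characterise beta-domain
#' dynamics (default window: residues 286-292).
#'
#' @param profile a [residue_profile].
#' @param window a [domain_window]; must lie inside the profile.
#' @return Named numeric vector `c(mean_p_d, mean_p_dd, mean_p_dp)`.
#' @examples
#' pr <- residue_profile(strrep("A", 10), p_d = rep(0.4, 10))
#' average_window(pr, domain_window(3, 7))
#' @export
average_window <- function(profile, window) {
  idx <- window_index(profile, window)
  c(mean_p_d = mean(profile$p_d[idx]),
    mean_p_dd = mean(profile$p_dd[idx]),
    mean_p_dp = mean(profile$p_dp[idx]))
}

#' Classify a window as ordered or disordered
#'
#' A window-mean disorder probability at or above the threshold is classified
#' as disordered. The default threshold 0.3085 is the published order/disorder
#' decision boundary of the disorder predictor; the boundary itself is
#' inclusive (a mean exactly at the threshold is disordered).
#'
#' @param mean_p_d window-mean disorder probability in \[0, 1\].
#' @param threshold decision threshold, default 0.3085.
#' @return `"disordered"` or `"ordered"`.
#' @export
classify_disorder <- function(mean_p_d, threshold = 0.3085) {
  stopifnot(all(mean_p_d >= 0), all(mean_p_d <= 1))
  ifelse(mean_p_d >= threshold, "disordered", "ordered")
}

#' Mutant-minus-wild-type window dynamics differences
#'
#' Computes `delta_p_d = mean_p_d(mut) - mean_p_d(wt)` (and likewise for
#' `p_dd`, `p_dp`) over a common window. Positive `delta_p_d` means the mutant
#' window is more mobile (disordered) than the reference; negative means more
#' rigid.
#'
#' @param mut,wt [residue_profile] objects sharing length and numbering.
#' @param window a [domain_window].
#' @return Named numeric vector `c(delta_p_d, delta_p_dd, delta_p_dp)`.
#' @export
delta_dynamics <- function(mut, wt, window) {
  if (length(mut) != length(wt) || !all(mut$positions == wt$positions))
    stop("mutant and wild-type profiles must share length and numbering")
  d <- average_window(mut, window) - average_window(wt, window)
  names(d) <- c("delta_p_d", "delta_p_dd", "delta_p_dp")
  d
}

#' Classify a variant's window dynamics relative to the reference
#'
#' Variants are grouped by the sign and size of the disorder change
#' `delta_p_d`: `"similar"` if |delta_p_d| < epsilon, `"mobile"` if the window
#' became more disordered by at least epsilon, `"rigid"` if it became more
#' ordered by at least epsilon.
#'
#' @param delta_p_d signed window-mean disorder difference.
#' @param epsilon classification tolerance, > 0 (default 0.05).
#' @return `"similar"`, `"mobile"` or `"rigid"` (vectorised).
#' @export
classify_variant <- function(delta_p_d, epsilon = 0.05) {
  stopifnot(epsilon > 0)
  ifelse(abs(delta_p_d) < epsilon, "similar",
         ifelse(delta_p_d >= epsilon, "mobile", "rigid"))
}

#' Place a variant on the droplet landscape
#'
#' The droplet landscape plots droplet-promoting probability (p_dp) against
#' the multiplicity-of-binding-modes (MBM) coordinate. Assemblies above the
#' identity diagonal are more liquid-like, below more solid-like; points within
#' `boundary_tolerance` of the diagonal sit at the liquid/solid boundary and
#' are the ones most able to convert between the two forms.
#'
#' @param p_dp droplet-promoting coordinate in \[0, 1\].
#' @param mbm MBM coordinate in \[0, 1\].
#' @param boundary_tolerance half-width of the boundary band in normalized
#'   units (default 0.05).
#' @return List with `class` (`"liquid-favoring"`, `"solid-favoring"` or
#'   `"boundary"`) and `signed_distance`, the signed perpendicular distance to
#'   the diagonal (positive above).
#' @export
droplet_landscape <- function(p_dp, mbm, boundary_tolerance = 0.05) {
  if (p_dp < 0 || p_dp > 1 || mbm < 0 || mbm > 1)
    stop("landscape coordinates must lie in [0, 1]")
  d <- (p_dp - mbm) / sqrt(2)
  cls <- if (d > boundary_tolerance) "liquid-favoring"
         else if (d < -boundary_tolerance) "solid-favoring"
         else "boundary"
  list(class = cls, signed_distance = d)
}

#' Variant specification
#'
#' A named set of point mutations against a reference sequence. Each mutation
#' is checked against the reference: the stated wild-type residue must occupy
#' the stated position.
#'
#' @param name variant label.
#' @param mutations data frame with columns `position`, `wt`, `mut`
#'   (full-protein numbering, one-letter codes).
#' @param reference optional reference [residue_profile] or sequence string for
#'   wild-type residue validation.
#' @return An object of class `variant_spec`.
#' @export
variant_spec <- function(name, mutations, reference = NULL) {
  stopifnot(all(c("position", "wt", "mut") %in% names(mutations)))
  if (!is.null(reference)) {
    if (inherits(reference, "residue_profile")) {
      seq <- reference$sequence
      pos <- reference$positions
    } else {
      seq <- strsplit(reference, "")[[1]]
      pos <- seq_along(seq)
    }
    idx <- match(mutations$position, pos)
    if (anyNA(idx))
      stop("mutation positions outside the reference sequence")
    bad <- seq[idx] != mutations$wt
    if (any(bad))
      stop("wild-type residue mismatch at position(s) ",
           paste(mutations$position[bad], collapse = ", "))
  }
  structure(list(name = name, mutations = mutations), class = "variant_spec")
}

#' Apply a variant's mutations to a sequence
#'
#' @param sequence amino-acid string or character vector.
#' @param spec a [variant_spec].
#' @param positions residue numbering of `sequence` (default `1:n`).
#' @return Mutated sequence in the same form as the input.
#' @export
apply_variant <- function(sequence, spec, positions = NULL) {
  as_string <- length(sequence) == 1L && nchar(sequence) > 1L
  if (as_string) sequence <- strsplit(sequence, "")[[1]]
  if (is.null(positions)) positions <- seq_along(sequence)
  idx <- match(spec$mutations$position, positions)
  if (anyNA(idx)) stop("mutation positions outside the sequence")
  sequence[idx] <- spec$mutations$mut
  if (as_string) paste(sequence, collapse = "") else sequence
}

#' Summarise a variant's window dynamics against a reference
#'
#' Runs the full per-variant characterisation: window means, mutant-minus-
#' wild-type deltas, order/disorder call, dynamics class and droplet-landscape
#' placement. The MBM landscape coordinate is taken from `mbm` if given,
#' otherwise from the window's flagged-residue fraction in the mutant profile.
#'
#' @param mut,wt [residue_profile] objects on common numbering.
#' @param window a [domain_window] (default beta-domain 286-292).
#' @param threshold disorder threshold (default 0.3085).
#' @param epsilon dynamics-class tolerance (default 0.05).
#' @param mbm optional scalar MBM landscape coordinate in \[0, 1\].
#' @param boundary_tolerance droplet-landscape band half-width (default 0.05).
#' @return An object of class `dynamics_summary`: window means, deltas,
#'   `disorder_class`, `dynamics_class`, `landscape` class and signed diagonal
#'   distance.
#' @export
dynamics_summary <- function(mut, wt, window = domain_window(),
                             threshold = 0.3085, epsilon = 0.05,
                             mbm = NULL, boundary_tolerance = 0.05) {
  means <- average_window(mut, window)
  deltas <- delta_dynamics(mut, wt, window)
  idx <- window_index(mut, window)
  if (is.null(mbm)) mbm <- mean(mut$mbm_flag[idx])
  land <- droplet_landscape(means[["mean_p_dp"]], mbm, boundary_tolerance)
  structure(list(
    mean_p_d = means[["mean_p_d"]], mean_p_dd = means[["mean_p_dd"]],
    mean_p_dp = means[["mean_p_dp"]],
    delta_p_d = deltas[["delta_p_d"]], delta_p_dd = deltas[["delta_p_dd"]],
    delta_p_dp = deltas[["delta_p_dp"]],
    disorder_class = classify_disorder(means[["mean_p_d"]], threshold),
    dynamics_class = classify_variant(deltas[["delta_p_d"]], epsilon),
    mbm = mbm, landscape = land$class,
    landscape_distance = land$signed_distance
  ), class = "dynamics_summary")
}

#' @export
print.dynamics_summary <- function(x, ...) {
  cat(sprintf("dynamics_summary: mean p_D %.3f (%s), delta p_D %+0.3f (%s)\n",
              x$mean_p_d, x$disorder_class, x$delta_p_d, x$dynamics_class))
  cat(sprintf("  landscape: %s (signed distance %+0.3f, MBM %.3f)\n",
              x$landscape, x$landscape_distance, x$mbm))
  invisible(x)
}

#' Rank variant candidates by dynamics impact
#'
#' Stable sort with structural disorder as the primary criterion: decreasing
#' |delta_p_d|, ties broken by decreasing |delta_p_dp|, remaining ties by
#' original input position (deterministic).
#'
#' @param candidates list of `list(spec = variant_spec, summary =
#'   dynamics_summary)` entries (or any list whose elements carry a
#'   `summary` with `delta_p_d` and `delta_p_dp`).
#' @return The same list, reordered; an empty list is returned unchanged.
#' @export
rank_candidates <- function(candidates) {
  if (!length(candidates)) return(candidates)
  dpd <- vapply(candidates, function(x) abs(x$summary$delta_p_d), 0)
  dpp <- vapply(candidates, function(x) abs(x$summary$delta_p_dp), 0)
  dpp[is.na(dpp)] <- 0
  ord <- order(-dpd, -dpp, seq_along(candidates))
  candidates[ord]
}

#' Toy sequence-to-profile surrogate predictor
#'
#' A deliberately simple charge/hydropathy heuristic mapping a sequence to
#' plausible `p_d`/`p_dd`/`p_dp` profiles, provided so the design stage can be
#' exercised end-to-end on sequences alone. It is NOT the published predictor
#' and its absolute values carry no meaning; real analyses must supply profiles
#' computed by the external predictors.
#'
#' Charged and small polar residues raise local disorder; aromatic and
#' aliphatic residues lower it. Profiles are smoothed over a 5-residue window
#' and squashed into (0, 1).
#'
#' @param sequence amino-acid string.
#' @param positions residue numbering (default `1:n`).
#' @return A [residue_profile] with heuristic `p_d`, `p_dd`, `p_dp`.
#' @export
toy_profile_predictor <- function(sequence, positions = NULL) {
  if (length(sequence) == 1L) sequence <- strsplit(sequence, "")[[1]]
  # Kyte-Doolittle hydropathy; disorder tracks low hydropathy + charge
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
          E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2)
  charge <- c(D = 1, E = 1, K = 1, R = 1, H = 0.5)
  h <- kd[sequence]; h[is.na(h)] <- 0
  q <- charge[sequence]; q[is.na(q)] <- 0
  raw <- -h / 4.5 + q
  sm <- stats::filter(raw, rep(1 / 5, 5), sides = 2)
  sm[is.na(sm)] <- raw[is.na(sm)]
  squash <- function(x, k = 1.5) 1 / (1 + exp(-k * x))
  residue_profile(sequence, positions,
                  p_d = squash(as.numeric(sm)),
                  p_dd = squash(as.numeric(sm) + 0.3 * q),
                  p_dp = squash(0.7 * as.numeric(sm) + 0.6 * q - 0.2))
}
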