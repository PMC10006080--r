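# Seeded generators for every pipeline stage. Each generator takes an
# explicit `seed`, restores the caller's RNG state on exit, and returns its
# ground truth alongside the data so downstream stages are testable as
# recover(generate(theta)) ~ theta.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate wild-type and variant residue profiles
#'
#' Emulates predictor output for a reference sequence plus variants whose
#' window-mean disorder is shifted by a requested effect, so the design
#' stage's similar/mobile/rigid calls can be validated round-trip. The
#' default geometry matches the experimental design: the 37-residue peptide
#' region (positions
#' 265-301) with the beta-domain window 286-292. Effects pushing a
#' probability outside \[0, 1\] are clipped with a warning.
#'
#' @param seed integer seed.
#' @param effects named numeric vector of window delta_p_d effects, one per
#'   variant (name = variant label). Positive = more mobile.
#' @param window a [domain_window] (full-protein numbering).
#' @param positions residue positions covered (default 265:301).
#' @param base_p_d wild-type window-level disorder (default 0.35, just above
#'   the 0.3085 order/disorder boundary, as for this disordered region).
#' @param roughness sd of smooth per-residue variation (default 0.02).
#' @return List with `wt` ([residue_profile]), `variants` (named list of
#'   profiles) and `truth` (requested effects).
#' @export
gen_profiles <- function(seed = 1, effects = c(var_mobile = 0.2,
                                               var_rigid = -0.2,
                                               var_similar = 0),
                         window = domain_window(),
                         positions = 265:301, base_p_d = 0.35,
                         roughness = 0.02) {
  with_seed(seed, {
    n <- length(positions)
    seqaa <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
                    replace = TRUE)
    wiggle <- function() as.numeric(stats::filter(
      stats::rnorm(n, 0, roughness), rep(1 / 3, 3), circular = TRUE))
    clip <- function(p, what) {
      if (any(p < 0 | p > 1))
        warning("requested effect pushes ", what,
                " outside [0, 1]; values clipped")
      pmin(pmax(p, 0), 1)
    }
    p_d <- clip(base_p_d + wiggle(), "p_d")
    p_dd <- clip(0.5 + wiggle(), "p_dd")
    p_dp <- clip(0.45 + wiggle(), "p_dp")
    wt <- residue_profile(seqaa, positions, p_d, p_dd, p_dp)
    widx <- which(positions >= window$start & positions <= window$end)
    variants <- lapply(effects, function(eff) {
      pv <- p_d
      pv[widx] <- clip(pv[widx] + eff, "p_d")
      residue_profile(seqaa, positions, pv,
                      clip(p_dd + 0.3 * eff * (seq_len(n) %in% widx), "p_dd"),
                      clip(p_dp + 0.5 * eff * (seq_len(n) %in% widx), "p_dp"))
    })
    names(variants) <- names(effects)
    list(wt = wt, variants = variants, truth = effects)
  })
}

#' Generate a contact trajectory with planted clusters
#'
#' Frames are drawn from `k` disjoint contact motifs (the planted clusters)
#' plus independent Bernoulli noise contacts from a pool disjoint from every
#' motif. With the noise rate below the separation bound, similarity-graph
#' clustering recovers the planted memberships exactly.
#'
#' @param seed integer seed.
#' @param n_snapshots number of frames.
#' @param k number of motifs.
#' @param motif_size contacts per motif (default 8).
#' @param n_res residues available (default 37).
#' @param noise_rate per-frame expected number of noise contacts (default 0).
#' @param weights motif sampling weights (default equal).
#' @return List with `ct` ([contact_trajectory]), `labels` (planted motif of
#'   each frame) and `motifs` (list of key vectors).
#' @export
gen_contact_trajectory <- function(seed = 1, n_snapshots = 60, k = 2,
                                   motif_size = 8, n_res = 37,
                                   noise_rate = 0, weights = NULL) {
  with_seed(seed, {
    all_pairs <- which(upper.tri(matrix(0, n_res, n_res)), arr.ind = TRUE)
    all_pairs <- all_pairs[abs(all_pairs[, 1] - all_pairs[, 2]) >= 3, ,
                           drop = FALSE]
    keys <- pair_key(all_pairs[, 1], all_pairs[, 2])
    need <- k * motif_size
    if (need > length(keys)) stop("not enough residue pairs for the motifs")
    picked <- sample(keys, need)
    motifs <- split(picked, rep(seq_len(k), each = motif_size))
    pool <- setdiff(keys, picked)
    # exact recovery needs within-motif similarity to stay above the 0.5
    # threshold: ~2 noise contacts per frame against motif_size shared ones
    if (noise_rate >= motif_size / 4)
      warning("noise rate at or above the separation bound; ",
              "exact recovery is not guaranteed")
    if (is.null(weights)) weights <- rep(1, k)
    labels <- sample(seq_len(k), n_snapshots, replace = TRUE, prob = weights)
    labels[seq_len(min(k, n_snapshots))] <- seq_len(min(k, n_snapshots))
    snaps <- lapply(labels, function(l) {
      extra <- if (noise_rate > 0)
        sample(pool, min(stats::rpois(1, noise_rate), length(pool)))
      else integer()
      sort(unique(c(motifs[[l]], extra)))
    })
    list(ct = contact_trajectory(snaps), labels = labels, motifs = motifs)
  })
}

#' Generate bead-chain conformer trajectories of tunable compactness
#'
#' Self-avoiding off-lattice random walks with a collapse bias: each step
#' mixes a random direction with the unit vector toward the current chain
#' centroid. Bias 0 gives extended coil-like chains, bias near 1 collapsed
#' globule-like chains; median radius of gyration is monotone decreasing in
#' the bias (in expectation). One bead per residue, 3.8 Angstrom virtual
#' bonds, 4.0 Angstrom excluded-volume diameter.
#'
#' @param seed integer seed.
#' @param n_frames frames to generate.
#' @param n_res chain length (default 37, the peptide length).
#' @param collapse_bias in \[0, 1\].
#' @param bond_a virtual bond length (Angstrom).
#' @param min_dist_a excluded-volume diameter (Angstrom).
#' @param max_retry per-step retry limit before the frame is restarted.
#' @return An [md_trajectory] with `collapse_bias` attached as attribute
#'   `"truth"`.
#' @export
gen_conformers <- function(seed = 1, n_frames = 50, n_res = 37,
                           collapse_bias = 0, bond_a = 3.8, min_dist_a = 4.0,
                           max_retry = 200) {
  stopifnot(collapse_bias >= 0, collapse_bias <= 1)
  with_seed(seed, {
    rand_unit <- function() {
      v <- stats::rnorm(3)
      v / sqrt(sum(v^2))
    }
    grow <- function() {
      xyz <- matrix(0, n_res, 3)
      if (n_res == 1L) return(xyz)
      xyz[2, ] <- bond_a * rand_unit()
      for (i in seq_len(n_res - 2L) + 2L) {
        placed <- FALSE
        for (try in seq_len(max_retry)) {
          # anneal the bias over retries so dense chains can still grow
          bias <- collapse_bias * (1 - (try - 1) / max_retry)
          cen <- colMeans(xyz[seq_len(i - 1L), , drop = FALSE])
          pull <- cen - xyz[i - 1L, ]
          np <- sqrt(sum(pull^2))
          if (np > 0) pull <- pull / np else pull <- rand_unit()
          dir <- (1 - bias) * rand_unit() + bias * pull
          dir <- dir / sqrt(sum(dir^2))
          cand <- xyz[i - 1L, ] + bond_a * dir
          d2 <- rowSums((xyz[seq_len(i - 2L), , drop = FALSE] -
                           matrix(cand, i - 2L, 3, byrow = TRUE))^2)
          if (all(d2 >= min_dist_a^2)) {
            xyz[i, ] <- cand
            placed <- TRUE
            break
          }
        }
        if (!placed) return(NULL)
      }
      xyz
    }
    coords <- array(NA_real_, c(n_frames, n_res, 3))
    for (f in seq_len(n_frames)) {
      xyz <- NULL
      for (attempt in seq_len(max_retry)) {
        xyz <- grow()
        if (!is.null(xyz)) break
      }
      if (is.null(xyz))
        stop("self-avoidance retry limit exceeded; lower the collapse bias")
      coords[f, , ] <- xyz
    }
    tr <- md_trajectory(coords, mass = rep(110, n_res), resid = seq_len(n_res))
    attr(tr, "truth") <- list(collapse_bias = collapse_bias)
    tr
  })
}

#' Generate a monoexponential relaxation decay series
#'
#' Forward model `I(t) = i0 * exp(-t / t_ms)` on a delay schedule (default:
#' the T1 list) with optional multiplicative Gaussian noise.
#'
#' @param seed integer seed.
#' @param t_ms true time constant (ms).
#' @param delays_ms delay schedule (default [t1_delay_schedule()]).
#' @param i0 initial intensity.
#' @param noise_frac noise sd as a fraction of `i0` (default 0); must be
#'   non-negative.
#' @return List with `delays_ms`, `intensities`, `truth`.
#' @export
gen_relaxation <- function(seed = 1, t_ms = 400,
                           delays_ms = t1_delay_schedule(), i0 = 1,
                           noise_frac = 0) {
  if (noise_frac < 0) stop("noise level must be non-negative")
  with_seed(seed, {
    ii <- i0 * exp(-delays_ms / t_ms)
    if (noise_frac > 0)
      ii <- pmax(ii + stats::rnorm(length(ii), 0, noise_frac * i0), 1e-9)
    list(delays_ms = delays_ms, intensities = ii,
         truth = list(t_ms = t_ms, i0 = i0))
  })
}

#' Generate a Stejskal-Tanner DOSY gradient decay
#'
#' Forward model `I(g) = i0 * exp(-D (gamma g delta)^2 (Delta - delta/3))`
#' on the default gradient schedule, with optional multiplicative noise.
#'
#' @param seed integer seed.
#' @param d_m2_s true diffusion coefficient (m^2/s).
#' @param gradients_g_cm gradient schedule (default
#'   [dosy_gradient_schedule()]).
#' @param delta_s,big_delta_s gradient pulse length and diffusion delay (s).
#' @param i0 intensity at zero gradient.
#' @param noise_frac multiplicative noise sd (default 0).
#' @return List with `gradients_g_cm`, `intensities`, acquisition fields and
#'   `truth`.
#' @export
gen_dosy <- function(seed = 1, d_m2_s = 1.54e-10,
                     gradients_g_cm = dosy_gradient_schedule(),
                     delta_s = 2e-3, big_delta_s = 75e-3, i0 = 1,
                     noise_frac = 0) {
  if (noise_frac < 0) stop("noise level must be non-negative")
  with_seed(seed, {
    gamma <- 26752.2187
    b <- (gamma * gradients_g_cm * delta_s)^2 * (big_delta_s - delta_s / 3)
    ii <- i0 * exp(-(d_m2_s * 1e4) * b)
    if (noise_frac > 0)
      ii <- pmax(ii * (1 + stats::rnorm(length(ii), 0, noise_frac)), 1e-12)
    list(gradients_g_cm = gradients_g_cm, intensities = ii,
         delta_s = delta_s, big_delta_s = big_delta_s,
         truth = list(d_m2_s = d_m2_s, i0 = i0))
  })
}

#' Generate a raw two-ROI FRAP trace with known kinetics
#'
#' Builds the true normalized recovery `n(t) = n0 + mobile * (1 - n0) *
#' (1 - exp(-t/tau))` and wraps it into raw bleach-ROI / whole-structure /
#' background intensity channels, including a shared multiplicative
#' acquisition-bleaching decay (which double normalization must cancel), a
#' camera offset and optional additive noise. Defaults follow the standard
#' acquisition: 120 post-bleach points over 120 s.
#'
#' @param seed integer seed.
#' @param mobile_fraction true mobile fraction in \[0, 1\].
#' @param tau_s true recovery time constant (s).
#' @param bleach_depth normalized level immediately after bleaching
#'   (default 0.2).
#' @param n_pre pre-bleach frames (default 10).
#' @param n_post post-bleach frames (default 120).
#' @param dt_s frame interval (default 1 s).
#' @param acq_bleach_rate acquisition photobleaching rate (1/s), applied
#'   multiplicatively to both ROIs (default 0).
#' @param background camera offset (default 50).
#' @param amp_bleach,amp_total pre-bleach ROI amplitudes above background.
#' @param noise_frac additive noise sd as a fraction of the ROI amplitude.
#' @return A [frap_trace] with `truth` attached as an attribute.
#' @export
gen_frap <- function(seed = 1, mobile_fraction = 0.6, tau_s = 15,
                     bleach_depth = 0.2, n_pre = 10, n_post = 120, dt_s = 1,
                     acq_bleach_rate = 0, background = 50,
                     amp_bleach = 1000, amp_total = 4000, noise_frac = 0) {
  if (noise_frac < 0) stop("noise level must be non-negative")
  stopifnot(mobile_fraction >= 0, mobile_fraction <= 1, tau_s > 0)
  with_seed(seed, {
    t_all <- dt_s * (seq_len(n_pre + n_post) - 1)
    pre <- seq_len(n_pre + n_post) <= n_pre
    tp <- t_all - t_all[n_pre + 1L]          # 0 at first post-bleach frame
    n0 <- bleach_depth
    n_true <- ifelse(pre, 1,
                     n0 + mobile_fraction * (1 - n0) * (1 - exp(-tp / tau_s)))
    acq <- exp(-acq_bleach_rate * t_all)
    ib <- background + amp_bleach * n_true * acq
    it <- background + amp_total * acq
    if (noise_frac > 0) {
      ib <- pmax(ib + stats::rnorm(length(ib), 0, noise_frac * amp_bleach), 0)
      it <- pmax(it + stats::rnorm(length(it), 0, noise_frac * amp_total), 0)
    }
    tr <- frap_trace(t_all, ib, it, rep(background, length(t_all)), pre)
    attr(tr, "truth") <- list(mobile_fraction = mobile_fraction,
                              tau_s = tau_s, bleach_depth = bleach_depth,
                              normalized = n_true)
    tr
  })
}

#' Generate nuclei-count and reporter-reading tables
#'
#' Seeded tables emulating differentiation and transcription assays: per
#' field, total nuclei ~ Poisson and multinucleated nuclei ~ Binomial(total,
#' true fusion index); per sample, luciferase and galactosidase signals with
#' lognormal batch factors and noise, where each variant's true activity is
#' `effect x` wild type.
#'
#' @param seed integer seed.
#' @param effects named per-variant activity multipliers relative to wild
#'   type (wild type itself is added automatically at 1).
#' @param fusion_true named per-variant true fusion indices.
#' @param n_experiments biological replicates (default 4).
#' @param n_tech technical replicates per experiment (default 3).
#' @param n_fields visual fields per variant (default 15).
#' @param mean_total mean nuclei per field (default 120).
#' @param noise_cv coefficient of variation of reporter signals
#'   (default 0.05).
#' @return List with `readings`, `counts` data frames and `truth`.
#' @export
gen_counts_and_readings <- function(seed = 1,
                                    effects = c(var5 = 1.78, var8 = 1.408),
                                    fusion_true = c(wt = 0.3, var8 = 0.45),
                                    n_experiments = 4, n_tech = 3,
                                    n_fields = 15, mean_total = 120,
                                    noise_cv = 0.05) {
  with_seed(seed, {
    eff <- c(wt = 1, effects)
    rows <- list()
    for (b in seq_len(n_experiments)) {
      batch_luc <- stats::rlnorm(1, 0, 0.2)
      batch_gal <- stats::rlnorm(1, 0, 0.2)
      for (v in names(eff)) for (r in seq_len(n_tech)) {
        gal <- 1000 * batch_gal * (1 + stats::rnorm(1, 0, noise_cv))
        luc <- 5000 * eff[[v]] * batch_luc * (1 + stats::rnorm(1, 0, noise_cv))
        rows[[length(rows) + 1L]] <- data.frame(
          variant = v, batch = paste0("exp", b), replicate = r,
          luciferase = luc, galactosidase = gal)
      }
    }
    readings <- do.call(rbind, rows)
    counts <- do.call(rbind, lapply(names(fusion_true), function(v) {
      tot <- stats::rpois(n_fields, mean_total) + 1L
      multi <- stats::rbinom(n_fields, tot, fusion_true[[v]])
      data.frame(variant = v, field = seq_len(n_fields),
                 multinucleated = multi, total = tot)
    }))
    list(readings = readings, counts = counts,
         truth = list(activity_percent = 100 * eff,
                      fusion_index = fusion_true))
  })
}
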