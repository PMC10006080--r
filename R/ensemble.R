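#' Molecular-dynamics trajectory container
#'
#' Lightweight in-memory trajectory: an ordered stack of coordinate frames
#' with per-atom metadata. Coordinates are in Angstrom throughout; derived
#' quantities (radius of gyration, RMSD) inherit that unit.
#'
#' @param coords numeric array `frames x atoms x 3` (Angstrom).
#' @param mass per-atom masses (amu); default 1 for coarse bead chains.
#' @param resid per-atom residue indices (peptide-local, 1-based).
#' @param timestep_ps time between saved frames in picoseconds (default 10, a
#'   common save interval for peptide simulations).
#' @param time_ps optional explicit frame times; default
#'   `timestep_ps * (0:(frames-1))` (first saved frame at t = 0).
#' @param replica replica label.
#' @return An object of class `md_trajectory`.
#' @export
md_trajectory <- function(coords, mass = NULL, resid = NULL,
                          timestep_ps = 10, time_ps = NULL, replica = "r1") {
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("coords must be a frames x atoms x 3 array")
  nf <- dim(coords)[1]; na <- dim(coords)[2]
  if (is.null(mass)) mass <- rep(1, na)
  if (is.null(resid)) resid <- seq_len(na)
  if (length(mass) != na || length(resid) != na)
    stop("mass and resid must have one entry per atom")
  stopifnot(timestep_ps > 0)
  if (is.null(time_ps)) time_ps <- timestep_ps * (seq_len(nf) - 1)
  if (length(time_ps) != nf) stop("time_ps must have one entry per frame")
  structure(list(coords = coords, mass = as.numeric(mass),
                 resid = as.integer(resid), timestep_ps = timestep_ps,
                 time_ps = as.numeric(time_ps), replica = replica),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("md_trajectory:", dim(x$coords)[1], "frames,", dim(x$coords)[2],
      "atoms,", length(unique(x$resid)), "residues, save interval",
      x$timestep_ps, "ps, replica", x$replica, "\n")
  invisible(x)
}

#' Read a trajectory from PDB topology + DCD coordinates
#'
#' Thin wrapper over bio3d for deposited trajectory files. Masses are assigned
#' by element from the topology.
#'
#' @param pdb path to a PDB topology file.
#' @param dcd path to a DCD trajectory file.
#' @param timestep_ps save interval (ps).
#' @param replica replica label.
#' @return An [md_trajectory].
#' @export
read_trajectory <- function(pdb, dcd, timestep_ps = 10, replica = "r1") {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading PDB/DCD files requires the bio3d package")
  top <- bio3d::read.pdb(pdb)
  xyz <- bio3d::read.dcd(dcd, verbose = FALSE)
  na <- nrow(top$atom)
  el <- toupper(substr(trimws(top$atom$elesy %||% top$atom$elety), 1, 1))
  amu <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
           P = 30.974)
  mass <- amu[el]; mass[is.na(mass)] <- 12.011
  coords <- array(NA_real_, c(nrow(xyz), na, 3))
  coords[, , 1] <- xyz[, seq(1, 3 * na, 3)]
  coords[, , 2] <- xyz[, seq(2, 3 * na, 3)]
  coords[, , 3] <- xyz[, seq(3, 3 * na, 3)]
  md_trajectory(coords, mass = mass, resid = top$atom$resno,
                timestep_ps = timestep_ps, replica = replica)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select the equilibrated analysis window of a trajectory
#'
#' Returns the indices of frames whose times fall in the half-open interval
#' `[start, end)` nanoseconds. The default 70-100 ns window discards the
#' first 70 ns as equilibration, the standard choice for these peptide
#' simulations; with a 10 ps save interval each 100 ns replica contributes
#' exactly 3000 snapshots.
#'
#' @param traj an [md_trajectory].
#' @param window_ns `c(start, end)` in nanoseconds, end exclusive.
#' @return Integer frame indices.
#' @export
select_equilibrated_window <- function(traj, window_ns = c(70, 100)) {
  lo <- window_ns[1] * 1000; hi <- window_ns[2] * 1000
  if (lo > max(traj$time_ps))
    stop("analysis window starts beyond the end of the trajectory (",
         max(traj$time_ps) / 1000, " ns)")
  which(traj$time_ps >= lo & traj$time_ps < hi)
}

#' Per-frame mass-weighted radius of gyration
#'
#' `Rg = sqrt( sum_i m_i |r_i - r_com|^2 / sum_i m_i )` per frame, the
#' compactness measure used for disordered chains.
#'
#' @param traj an [md_trajectory] (or a single `atoms x 3` frame matrix, in
#'   which case `mass` may be supplied).
#' @param mass per-atom masses when `traj` is a bare matrix.
#' @return Numeric vector of per-frame Rg values, in the coordinate unit.
#' @export
radius_of_gyration <- function(traj, mass = NULL) {
  if (is.matrix(traj)) {
    frames <- array(traj, c(1, nrow(traj), 3))
    m <- mass %||% rep(1, nrow(traj))
  } else {
    frames <- traj$coords
    m <- traj$mass
  }
  if (sum(m) <= 0) stop("total mass must be positive")
  w <- m / sum(m)
  vapply(seq_len(dim(frames)[1]), function(f) {
    xyz <- frames[f, , , drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    com <- colSums(xyz * w)
    sq <- (xyz[, 1] - com[1])^2 + (xyz[, 2] - com[2])^2 +
      (xyz[, 3] - com[3])^2
    sqrt(sum(w * sq))
  }, 0)
}

#' Per-frame RMSD to the ensemble-average structure
#'
#' RMSD of each frame to the unweighted mean structure over the selected
#' frames, without superposition (frames are assumed translation/rotation
#' processed upstream). Used to judge equilibration.
#'
#' @param traj an [md_trajectory].
#' @return Numeric vector of per-frame RMSD values (coordinate unit).
#' @export
rmsd_to_average <- function(traj) {
  avg <- apply(traj$coords, c(2, 3), mean)
  vapply(seq_len(dim(traj$coords)[1]), function(f) {
    d <- traj$coords[f, , , drop = TRUE] - avg
    sqrt(mean(rowSums(matrix(d, ncol = 3)^2)))
  }, 0)
}

# Contact pairs are encoded as integer keys i * 10000 + j (i < j) so contact
# sets are plain sorted integer vectors and set algebra stays vectorised.
pair_key <- function(i, j) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  as.integer(lo) * 10000L + as.integer(hi)
}

key_pair <- function(k) cbind(i = k %/% 10000L, j = k %% 10000L)

#' Construct a contact set
#'
#' An unordered set of residue-index pairs (i, j), i < j, in peptide-local
#' numbering. Self-pairs are rejected; duplicates collapse.
#'
#' @param i,j parallel integer vectors of residue indices.
#' @return Sorted integer key vector of class `contact_set`.
#' @export
contact_set <- function(i = integer(), j = integer()) {
  if (any(i == j)) stop("contact sets cannot contain self-pairs")
  structure(sort(unique(pair_key(i, j))), class = "contact_set")
}

#' @export
print.contact_set <- function(x, ...) {
  cat("contact_set:", length(x), "residue pairs\n")
  if (length(x)) {
    p <- key_pair(utils::head(unclass(x), 10))
    cat("  ", paste(sprintf("(%d,%d)", p[, 1], p[, 2]), collapse = " "),
        if (length(x) > 10) "...", "\n")
  }
  invisible(x)
}

#' Extract residue contacts from a coordinate frame
#'
#' Default distance criterion: residues i, j with `|i - j| >=
#' min_separation` are in contact when any inter-residue heavy-atom distance
#' is at most `cutoff` (Angstrom). The criterion is pluggable: pass a
#' function `(dist_matrix, resid) -> logical residue-pair matrix` as
#' `criterion` to substitute a different contact engine.
#'
#' @param frame `atoms x 3` coordinate matrix (Angstrom).
#' @param resid per-atom residue indices.
#' @param cutoff distance cutoff in Angstrom (default 4.5).
#' @param min_separation minimum sequence separation |i - j| (default 3,
#'   excluding trivially bonded neighbours).
#' @param criterion optional replacement criterion function.
#' @return A [contact_set].
#' @export
extract_contacts <- function(frame, resid, cutoff = 4.5, min_separation = 3,
                             criterion = NULL) {
  if (cutoff <= 0) stop("cutoff must be positive")
  resid <- as.integer(resid)
  dm <- as.matrix(stats::dist(frame))
  res <- sort(unique(resid))
  nr <- length(res)
  if (!is.null(criterion)) {
    adj <- criterion(dm, resid)
  } else {
    # residue-pair minimum heavy-atom distance via group-wise reduction
    grp <- match(resid, res)
    adj <- matrix(Inf, nr, nr)
    for (a in seq_len(nr)) {
      rows <- grp == a
      sub <- dm[rows, , drop = FALSE]
      adj[a, ] <- vapply(seq_len(nr),
                         function(b) min(sub[, grp == b, drop = FALSE]), 0)
    }
    adj <- adj <= cutoff
  }
  sep <- abs(outer(res, res, "-")) >= min_separation
  hit <- which(adj & sep & upper.tri(adj), arr.ind = TRUE)
  contact_set(res[hit[, 1]], res[hit[, 2]])
}

#' Contact trajectory
#'
#' Ordered sequence of per-snapshot contact sets with frame times.
#'
#' @param snapshots list of [contact_set] objects (or raw key vectors).
#' @param time_ps optional strictly increasing frame times.
#' @return An object of class `contact_trajectory`.
#' @export
contact_trajectory <- function(snapshots, time_ps = NULL) {
  if (!length(snapshots)) stop("contact trajectory must contain snapshots")
  if (is.null(time_ps)) time_ps <- seq_along(snapshots)
  if (length(time_ps) != length(snapshots) ||
      (length(time_ps) > 1 && any(diff(time_ps) <= 0)))
    stop("times must be strictly increasing, one per snapshot")
  structure(list(snapshots = lapply(snapshots, function(s)
    sort(unique(as.integer(s)))), time_ps = as.numeric(time_ps)),
    class = "contact_trajectory")
}

#' @export
print.contact_trajectory <- function(x, ...) {
  cat("contact_trajectory:", length(x$snapshots), "snapshots, mean",
      sprintf("%.1f", mean(lengths(x$snapshots))), "contacts/snapshot\n")
  invisible(x)
}

#' Compute the contact trajectory of an MD trajectory
#'
#' Applies [extract_contacts()] to every frame in the selected window,
#' pooling windows across replicas when a list of trajectories is given (the
#' analysis convention: three 100 ns replicas, 70-100 ns windows, 9000
#' pooled snapshots).
#'
#' @param traj an [md_trajectory] or list of them.
#' @param window_ns analysis window in ns (half-open); `NULL` for all frames.
#' @param ... passed to [extract_contacts()].
#' @return A [contact_trajectory] over the pooled window frames.
#' @export
compute_contact_trajectory <- function(traj, window_ns = c(70, 100), ...) {
  trajs <- if (inherits(traj, "md_trajectory")) list(traj) else traj
  snaps <- list(); times <- numeric(); t_off <- 0
  for (tr in trajs) {
    idx <- if (is.null(window_ns)) seq_along(tr$time_ps)
           else select_equilibrated_window(tr, window_ns)
    for (f in idx)
      snaps[[length(snaps) + 1L]] <-
        extract_contacts(matrix(tr$coords[f, , ], ncol = 3), tr$resid, ...)
    times <- c(times, t_off + tr$time_ps[idx])
    t_off <- t_off + max(tr$time_ps)
  }
  contact_trajectory(snaps, times)
}

#' Contact-map similarity between two snapshots
#'
#' `f_S = |Ci intersect Cj| / |(Ci union Cj) - (Ci intersect Cj)|`: shared
#' contacts over non-shared contacts, related to the Jaccard index J by
#' `f_S = J / (1 - J)`. Identical sets (empty or not) have no non-shared
#' contacts and return `+Inf` — they co-cluster at any threshold; disjoint
#' non-empty sets return 0.
#'
#' @param ci,cj [contact_set] objects or integer key vectors.
#' @return Non-negative numeric scalar (possibly `Inf`).
#' @export
contact_similarity <- function(ci, cj) {
  ci <- unique(as.integer(ci)); cj <- unique(as.integer(cj))
  inter <- length(intersect(ci, cj))
  sym <- length(ci) + length(cj) - 2L * inter
  if (sym == 0L) return(Inf)
  inter / sym
}

#' Cluster snapshots by contact-map similarity
#'
#' Two-stage clustering of a contact trajectory. Stage 1 links snapshots i, j
#' whenever `f_S(Ci, Cj) > threshold` and takes connected components of the
#' resulting graph. Stage 2 joins components by the frequencies of their
#' common contacts: each component is represented by its high-frequency
#' contact set (pairs present in at least `merge_fraction` of member
#' snapshots) and component pairs whose representative sets again satisfy
#' `f_S > threshold` are merged, iterated to a fixed point. Clusters are
#' ranked by population (1 = largest); the procedure is deterministic given
#' the input order.
#'
#' @param ct a [contact_trajectory].
#' @param threshold similarity threshold (default 0.5; equivalent to Jaccard
#'   > 1/3).
#' @param merge_fraction frequency cutoff defining a component's
#'   high-frequency contact set in stage 2 (default 0.5).
#' @param join logical; set `FALSE` to stop after stage 1.
#' @return An object of class `cluster_result`: `assignment` (per-snapshot
#'   cluster rank), `clusters` (list with `members`, `population`,
#'   `contact_freq` named by pair key), `n_snapshots`.
#' @export
cluster_snapshots <- function(ct, threshold = 0.5, merge_fraction = 0.5,
                              join = TRUE) {
  stopifnot(threshold > 0)
  snaps <- ct$snapshots
  n <- length(snaps)
  keys <- sort(unique(unlist(snaps)))
  m <- Matrix::sparseMatrix(
    i = rep(seq_len(n), lengths(snaps)),
    j = match(unlist(snaps), keys),
    x = 1, dims = c(n, max(1L, length(keys))))
  inter <- as.matrix(Matrix::tcrossprod(m))
  sizes <- lengths(snaps)
  sym <- outer(sizes, sizes, "+") - 2 * inter
  adj <- (inter > threshold * sym) | (sym == 0)   # f_S > thr, Inf co-clusters
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership

  members <- split(seq_len(n), comp)
  if (join && length(members) > 1L) {
    hf_set <- function(mem) {
      freq <- Matrix::colSums(m[mem, , drop = FALSE])
      keys[freq >= merge_fraction * length(mem)]
    }
    reps <- lapply(members, hf_set)
    repeat {
      k <- length(members)
      merged <- FALSE
      for (a in seq_len(k - 1L)) {
        for (b in seq.int(a + 1L, k)) {
          if (contact_similarity(reps[[a]], reps[[b]]) > threshold) {
            members[[a]] <- sort(c(members[[a]], members[[b]]))
            members[[b]] <- NULL
            reps[[a]] <- hf_set(members[[a]])
            reps[[b]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
      if (!merged) break
    }
  }

  ord <- order(-lengths(members), vapply(members, min, 0L))
  members <- members[ord]
  assignment <- integer(n)
  clusters <- vector("list", length(members))
  for (c_i in seq_along(members)) {
    mem <- members[[c_i]]
    assignment[mem] <- c_i
    freq <- Matrix::colSums(m[mem, , drop = FALSE])
    keep <- freq > 0
    cf <- as.integer(freq[keep]); names(cf) <- keys[keep]
    clusters[[c_i]] <- list(members = mem, population = length(mem),
                            contact_freq = cf)
  }
  structure(list(assignment = assignment, clusters = clusters,
                 n_snapshots = n),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  pops <- vapply(x$clusters, `[[`, 0L, "population")
  cat("cluster_result:", x$n_snapshots, "snapshots in", length(pops),
      "clusters; populations:",
      paste(utils::head(pops, 8), collapse = ", "),
      if (length(pops) > 8) "...", "\n")
  invisible(x)
}

#' Contact-frequency map of a cluster
#'
#' Symmetric residue-by-residue matrix counting, for each contact pair, the
#' number of member snapshots in which it is sampled — the per-cluster contact
#' map. By convention only the few most populated clusters are visualised
#' (default: the four largest).
#'
#' @param result a `cluster_result`.
#' @param cluster cluster rank (1 = most populated).
#' @param n_res matrix dimension; default the largest residue index seen.
#' @return Symmetric integer matrix `n_res x n_res`.
#' @export
cluster_contact_map <- function(result, cluster = 1L, n_res = NULL) {
  cl <- result$clusters[[cluster]]
  keys <- as.integer(names(cl$contact_freq))
  pr <- key_pair(keys)
  if (is.null(n_res)) n_res <- if (length(keys)) max(pr) else 1L
  mat <- matrix(0L, n_res, n_res)
  if (length(keys)) {
    mat[pr] <- as.integer(cl$contact_freq)
    mat[pr[, c(2, 1), drop = FALSE]] <- as.integer(cl$contact_freq)
  }
  mat
}

#' Fraction of contact occurrences involving a residue window
#'
#' Share of all contact occurrences (each pair weighted by the number of
#' snapshots sampling it, summed over clusters) whose residues fall in the
#' window: `mode = "both_in"` requires both partners inside the window (a
#' within-domain contact), `"any_in"` at least one. Both definitions are
#' reported in analyses because domain-restricted contact shares are quoted
#' without stating the membership rule.
#'
#' @param result a `cluster_result`.
#' @param window a [domain_window] in peptide-local numbering.
#' @param mode `"both_in"` or `"any_in"`.
#' @return Fraction in \[0, 1\] (`NaN` if there are no contacts at all).
#' @export
domain_contact_fraction <- function(result, window,
                                    mode = c("both_in", "any_in")) {
  mode <- match.arg(mode)
  tot <- 0; hit <- 0
  for (cl in result$clusters) {
    if (!length(cl$contact_freq)) next
    pr <- key_pair(as.integer(names(cl$contact_freq)))
    w <- as.numeric(cl$contact_freq)
    in_i <- pr[, 1] >= window$start & pr[, 1] <= window$end
    in_j <- pr[, 2] >= window$start & pr[, 2] <= window$end
    sel <- if (mode == "both_in") in_i & in_j else in_i | in_j
    tot <- tot + sum(w)
    hit <- hit + sum(w[sel])
  }
  hit / tot
}

#' Classify chain compactness against a reference Rg
#'
#' `"compact"` if the median radius of gyration is below the reference by
#' more than `tolerance`, `"extended"` if above it by more than `tolerance`,
#' `"mixed"` otherwise.
#'
#' @param rg_series per-frame Rg values.
#' @param reference_rg reference Rg (same unit).
#' @param tolerance classification band half-width; default 5% of the
#'   reference.
#' @return `"compact"`, `"extended"` or `"mixed"`.
#' @export
classify_compactness <- function(rg_series, reference_rg,
                                 tolerance = 0.05 * reference_rg) {
  stopifnot(length(rg_series) > 0)
  med <- stats::median(rg_series)
  if (med < reference_rg - tolerance) "compact"
  else if (med > reference_rg + tolerance) "extended"
  else "mixed"
}

#' Read / write contact trajectories as tab-separated records
#'
#' The interchange format is one row per contact occurrence: columns `frame`,
#' `res_i`, `res_j`. Frames with no contacts are preserved via `n_snapshots`.
#'
#' @param ct a [contact_trajectory].
#' @param path file path.
#' @return `write_contact_table()` the path invisibly;
#'   `read_contact_table()` a [contact_trajectory].
#' @export
write_contact_table <- function(ct, path) {
  rows <- lapply(seq_along(ct$snapshots), function(f) {
    k <- ct$snapshots[[f]]
    if (!length(k)) return(NULL)
    pr <- key_pair(k)
    data.frame(frame = f, res_i = pr[, 1], res_j = pr[, 2])
  })
  tab <- do.call(rbind, c(rows, list(data.frame(frame = integer(),
                                                res_i = integer(),
                                                res_j = integer()))))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contact_table
#' @param n_snapshots total number of snapshots (frames without contacts are
#'   not present in the table); default the largest frame index.
#' @export
read_contact_table <- function(path, n_snapshots = NULL) {
  tab <- utils::read.delim(path)
  if (is.null(n_snapshots)) n_snapshots <- max(tab$frame)
  snaps <- rep(list(integer()), n_snapshots)
  if (nrow(tab)) {
    by_f <- split(pair_key(tab$res_i, tab$res_j), tab$frame)
    for (f in names(by_f)) snaps[[as.integer(f)]] <- sort(unique(by_f[[f]]))
  }
  contact_trajectory(snaps)
}
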