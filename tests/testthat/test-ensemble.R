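test_that("window selection counts frames exactly on the half-open interval", {
  tr <- md_trajectory(array(0, c(10000, 2, 3)), timestep_ps = 10)
  idx <- select_equilibrated_window(tr, c(70, 100))
  expect_length(idx, 3000)
  expect_length(select_equilibrated_window(tr, c(0, 100)), 10000)
  expect_length(select_equilibrated_window(tr, c(0, 0)), 0)
  expect_error(select_equilibrated_window(tr, c(150, 200)), "beyond")
})

test_that("radius of gyration matches closed forms and the double-loop oracle", {
  # coincident atoms
  xyz <- matrix(1, 4, 3)
  expect_equal(radius_of_gyration(xyz), 0)
  # two equal masses distance d apart -> d/2
  two <- rbind(c(0, 0, 0), c(3, 0, 0))
  expect_equal(radius_of_gyration(two), 1.5)
  # unequal masses, oracle check
  set.seed(21)
  for (i in 1:5) {
    n <- sample(5:40, 1)
    xyz <- matrix(rnorm(3 * n, sd = 5), n, 3)
    m <- runif(n, 1, 20)
    expect_equal(radius_of_gyration(xyz, mass = m), oracle_rg(xyz, m))
  }
  expect_error(radius_of_gyration(two, mass = c(0, 0)), "mass")
})

test_that("Rg is homogeneous of degree one in coordinates", {
  tr <- gen_conformers(22, n_frames = 4, collapse_bias = 0.3)
  tr2 <- tr
  tr2$coords <- 2 * tr$coords
  expect_equal(radius_of_gyration(tr2), 2 * radius_of_gyration(tr))
})

test_that("contact extraction agrees with the exhaustive pairwise oracle", {
  set.seed(23)
  for (i in 1:4) {
    tr <- gen_conformers(seed = 230 + i, n_frames = 1, n_res = 20,
                         collapse_bias = 0.7)
    xyz <- matrix(tr$coords[1, , ], ncol = 3)
    got <- extract_contacts(xyz, tr$resid)
    want <- oracle_contacts(xyz, tr$resid)
    if (is.null(want)) {
      expect_length(got, 0)
    } else {
      expect_equal(unclass(got), sort(want[, 1] * 10000 + want[, 2]),
                   ignore_attr = TRUE)
    }
  }
  # constructed pair: two residues 3 A apart
  xyz <- rbind(c(0, 0, 0), c(3, 0, 0))
  cs <- extract_contacts(xyz, resid = c(1, 5), cutoff = 4.5,
                         min_separation = 3)
  expect_equal(unclass(cs), 1 * 10000 + 5, ignore_attr = TRUE)
  # extended chain far beyond cutoff has no distal contacts
  line <- cbind(seq(0, 190, by = 10), 0, 0)
  expect_length(extract_contacts(line, 1:20), 0)
  expect_error(extract_contacts(xyz, c(1, 5), cutoff = -1), "cutoff")
})

test_that("contact similarity implements shared-over-nonshared with its conventions", {
  ab <- contact_set(c(1, 2, 3), c(5, 6, 7))
  expect_equal(contact_similarity(ab, ab), Inf)
  expect_equal(contact_similarity(contact_set(), contact_set()), Inf)
  expect_equal(contact_similarity(ab, contact_set(10, 14)), 0)
  expect_equal(contact_similarity(ab, contact_set()), 0)
  # {AB,BC,CD} vs {AB,BC,DE}: 2 shared / 2 non-shared = 1
  a <- contact_set(c(1, 2, 3), c(5, 6, 7))
  b <- contact_set(c(1, 2, 4), c(5, 6, 8))
  expect_equal(contact_similarity(a, b), 1)
})

test_that("f_S equals J/(1-J) and is symmetric over random set pairs", {
  set.seed(24)
  for (i in 1:50) {
    s <- random_contact_sets(2)
    fs <- contact_similarity(s[[1]], s[[2]])
    expect_identical(fs, contact_similarity(s[[2]], s[[1]]))
    uni <- length(union(s[[1]], s[[2]]))
    if (uni == 0) next
    jac <- length(intersect(s[[1]], s[[2]])) / uni
    if (jac == 1) expect_equal(fs, Inf) else expect_equal(fs, jac / (1 - jac))
    # threshold equivalence: f_S > 0.5 <=> J > 1/3
    expect_equal(fs > 0.5, jac > 1 / 3)
  }
})

test_that("stage-1 clustering equals brute-force threshold-graph components", {
  set.seed(25)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    snaps <- random_contact_sets(n, n_keys = sample(10:40, 1),
                                 p = runif(1, 0.1, 0.6))
    ct <- contact_trajectory(snaps)
    got <- cluster_snapshots(ct, join = FALSE)$assignment
    want <- oracle_components(snaps)
    expect_true(same_partition(got, want))
  }
})

test_that("clustering is deterministic and accounts for every snapshot", {
  g <- gen_contact_trajectory(26, n_snapshots = 100, k = 3, noise_rate = 1)
  r1 <- cluster_snapshots(g$ct)
  r2 <- cluster_snapshots(g$ct)
  expect_identical(r1$assignment, r2$assignment)
  expect_equal(sum(vapply(r1$clusters, `[[`, 0L, "population")),
               r1$n_snapshots)
  expect_true(all(r1$assignment >= 1))
  # populations are rank-ordered
  pops <- vapply(r1$clusters, `[[`, 0L, "population")
  expect_true(all(diff(pops) <= 0))
  # contact frequency never exceeds cluster population
  for (cl in r1$clusters)
    expect_true(all(cl$contact_freq <= cl$population))
})

test_that("identical snapshots form a single cluster; planted motifs are recovered", {
  same <- contact_trajectory(rep(list(c(10005L, 20007L)), 12))
  expect_length(cluster_snapshots(same)$clusters, 1)
  # two disjoint alternating motifs -> exactly the planted two clusters
  m1 <- c(10005L, 20008L, 30011L)
  m2 <- c(40009L, 50012L, 60015L)
  alt <- contact_trajectory(rep(list(m1, m2), 10))
  res <- cluster_snapshots(alt)
  expect_length(res$clusters, 2)
  expect_true(same_partition(res$assignment, rep(c(1, 2), 10)))
})

test_that("cluster joining merges components sharing high-frequency contacts", {
  # Two groups share a 4-contact core. Each group adds 2 group-specific
  # persistent contacts plus 2 rotating one-off contacts per frame. Across
  # groups, frames share 4 of 12 distinct contacts (f_S = 4/8 = 0.5, at the
  # threshold, so stage 1 keeps the groups apart), while the >=50%-frequency
  # sets are core+persistent (f_S = 4/4 = 1 > 0.5), so stage 2 joins them.
  core <- c(10005L, 20008L, 30011L, 40014L)
  pers_a <- c(50017L, 60020L)
  pers_b <- c(70023L, 80026L)
  fr_a <- lapply(1:6, function(i) c(core, pers_a, 90000L + c(2L * i, 100L + 2L * i)))
  fr_b <- lapply(1:6, function(i) c(core, pers_b, 95000L + c(2L * i, 100L + 2L * i)))
  ct <- contact_trajectory(c(fr_a, fr_b))
  staged <- cluster_snapshots(ct, join = FALSE)
  joined <- cluster_snapshots(ct, join = TRUE)
  expect_length(staged$clusters, 2)
  expect_length(joined$clusters, 1)
})

test_that("cluster contact maps tally member snapshots per pair", {
  g <- gen_contact_trajectory(27, n_snapshots = 40, k = 2, noise_rate = 0.5)
  res <- cluster_snapshots(g$ct)
  cm <- cluster_contact_map(res, 1, n_res = 37)
  expect_true(isSymmetric(cm))
  cl <- res$clusters[[1]]
  # brute-force tally over members
  tal <- new.env()
  for (mem in cl$members) {
    for (k in g$ct$snapshots[[mem]]) {
      key <- as.character(k)
      assign(key, (if (exists(key, tal)) get(key, tal) else 0L) + 1L, tal)
    }
  }
  for (key in ls(tal)) {
    k <- as.integer(key)
    expect_equal(cm[k %/% 10000L, k %% 10000L], get(key, tal))
  }
  # single-snapshot cluster map is 0/1 matching its contact set
  one <- cluster_snapshots(contact_trajectory(list(c(10004L, 20008L))))
  cm1 <- cluster_contact_map(one, 1, n_res = 10)
  expect_equal(sort(unique(as.vector(cm1))), c(0L, 1L))
  expect_equal(cm1[1, 4], 1L)
  # pair present in all m members counts m
  all_m <- cluster_snapshots(contact_trajectory(rep(list(c(10004L)), 7)))
  expect_equal(cluster_contact_map(all_m, 1, n_res = 5)[1, 4], 7L)
})

test_that("domain contact fractions respect the membership mode", {
  w <- domain_window(3, 8)
  inside <- cluster_snapshots(contact_trajectory(
    rep(list(c(pair_key_test(3, 6), pair_key_test(4, 8))), 5)))
  expect_equal(domain_contact_fraction(inside, w, "both_in"), 1)
  expect_equal(domain_contact_fraction(inside, w, "any_in"), 1)
  outside <- cluster_snapshots(contact_trajectory(
    rep(list(c(pair_key_test(10, 14), pair_key_test(12, 20))), 5)))
  expect_equal(domain_contact_fraction(outside, w, "both_in"), 0)
  expect_equal(domain_contact_fraction(outside, w, "any_in"), 0)
  # straddling contact counts under any_in only
  straddle <- cluster_snapshots(contact_trajectory(
    rep(list(c(pair_key_test(4, 20), pair_key_test(10, 14))), 3)))
  expect_equal(domain_contact_fraction(straddle, w, "both_in"), 0)
  expect_equal(domain_contact_fraction(straddle, w, "any_in"), 0.5)
})

test_that("compactness classification brackets the reference Rg", {
  expect_equal(classify_compactness(rep(10, 5), 10), "mixed")
  compact <- gen_conformers(28, n_frames = 15, collapse_bias = 0.9)
  extended <- gen_conformers(28, n_frames = 15, collapse_bias = 0)
  ref <- median(radius_of_gyration(extended))
  expect_equal(classify_compactness(radius_of_gyration(compact), ref),
               "compact")
  expect_equal(classify_compactness(radius_of_gyration(extended) * 2, ref),
               "extended")
})

test_that("contact trajectories pool replica windows and round-trip TSV", {
  mk <- function(rep, seed) {
    tr <- gen_conformers(seed, n_frames = 40, n_res = 12,
                         collapse_bias = 0.6)
    tr$time_ps <- 250 * seq_len(40)   # 10 ns replica
    tr$replica <- rep
    tr
  }
  trajs <- list(mk("r1", 291), mk("r2", 292), mk("r3", 293))
  ct <- compute_contact_trajectory(trajs, window_ns = c(7, 10))
  expect_length(ct$snapshots, 3 * 12)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_contact_table(ct, path)
  back <- read_contact_table(path, n_snapshots = length(ct$snapshots))
  expect_equal(back$snapshots, ct$snapshots)
})
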