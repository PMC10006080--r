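# Independent brute-force oracles, deliberately naive and separate from the
# package's vectorised/graph-library code paths.

# f_S from first principles on two integer key sets
oracle_fs <- function(a, b) {
  a <- unique(a); b <- unique(b)
  inter <- sum(a %in% b)
  sym <- length(a) + length(b) - 2 * inter
  if (sym == 0) Inf else inter / sym
}

# stage-1 clustering: O(n^2) threshold graph + hand-rolled BFS components
oracle_components <- function(snaps, threshold = 0.5) {
  n <- length(snaps)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    adj[i, j] <- oracle_fs(snaps[[i]], snaps[[j]]) > threshold
  }
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] != 0L) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

# mass-weighted Rg by direct double loop over atoms
oracle_rg <- function(xyz, mass) {
  com <- c(0, 0, 0)
  for (i in seq_len(nrow(xyz))) com <- com + mass[i] * xyz[i, ]
  com <- com / sum(mass)
  s <- 0
  for (i in seq_len(nrow(xyz)))
    s <- s + mass[i] * sum((xyz[i, ] - com)^2)
  sqrt(s / sum(mass))
}

# exhaustive all-pairs residue contact scan
oracle_contacts <- function(xyz, resid, cutoff = 4.5, min_sep = 3) {
  res <- sort(unique(resid))
  out <- NULL
  for (a in seq_along(res)) for (b in seq_along(res)) {
    if (b <= a) next
    if (abs(res[b] - res[a]) < min_sep) next
    hit <- FALSE
    for (i in which(resid == res[a])) for (j in which(resid == res[b])) {
      if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= cutoff) hit <- TRUE
    }
    if (hit) out <- rbind(out, c(res[a], res[b]))
  }
  out
}

# do two partitions describe the same grouping?
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}

pair_key_test <- function(i, j) as.integer(i) * 10000L + as.integer(j)

random_contact_sets <- function(n, n_keys = 40, p = 0.2) {
  keys <- sample.int(9999L, n_keys)
  lapply(seq_len(n), function(i) sort(keys[runif(n_keys) < p]))
}
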