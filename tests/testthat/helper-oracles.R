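# Brute-force reference implementations used to cross-check the
# package's vectorised code paths. These deliberately use plain loops
# and direct definitions.

# Exhaustive false-nearest-neighbour fraction: explicit embedding,
# all-pairs nearest-neighbour search, direct criterion evaluation.
fnn_oracle <- function(x, m, tau, r_tol = 10, a_tol = 2,
                       metric = "euclidean") {
  n <- length(x)
  sigma <- sd(x)
  floor_eps <- 1e-8 * sigma
  n_ext <- n - m * tau
  point <- function(i, dim) x[i + (seq_len(dim) - 1L) * tau]
  dist2 <- function(p, q) {
    if (metric == "maximum") max(abs(p - q)) else sqrt(sum((p - q)^2))
  }
  n_false <- 0L; n_tested <- 0L
  for (i in seq_len(n_ext)) {
    best_j <- NA_integer_; best_d <- Inf
    for (j in seq_len(n_ext)) {
      if (j == i) next
      dij <- dist2(point(i, m), point(j, m))
      if (dij <= floor_eps) next             # coincident: like a self-match
      if (dij < best_d) { best_d <- dij; best_j <- j }
    }
    if (is.na(best_j)) next
    n_tested <- n_tested + 1L
    delta <- abs(x[i + m * tau] - x[best_j + m * tau])
    d_m1 <- if (metric == "maximum") max(best_d, delta) else {
      sqrt(best_d^2 + delta^2)
    }
    if (delta > r_tol * best_d || d_m1 / sigma > a_tol) {
      n_false <- n_false + 1L
    }
  }
  if (n_tested == 0L) stop("oracle: no tested points")
  n_false / n_tested
}

# Transitivity by explicit enumeration of ordered triples.
transitivity_oracle <- function(A) {
  n <- nrow(A)
  closed <- 0; paths <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i == k) next
    if (A[i, j] == 1 && A[j, k] == 1) {
      paths <- paths + 1
      if (A[k, i] == 1) closed <- closed + 1
    }
  }
  if (paths == 0) stop("oracle: no length-2 paths")
  closed / paths
}

# Exact two-sided rank-sum p-value by recursive enumeration of which
# pooled observations fall in group A (independent of the combn-based
# implementation); two-sided via deviation of the rank sum from its
# permutation mean.
ranksum_oracle <- function(a, b) {
  r <- rank(c(a, b))
  n <- length(r); n_a <- length(a)
  mu <- n_a * (n + 1) / 2
  dev_obs <- abs(sum(r[seq_along(a)]) - mu)
  count <- 0L; total <- 0L
  recurse <- function(idx, remaining, acc) {
    if (remaining == 0L) {
      total <<- total + 1L
      if (abs(acc - mu) >= dev_obs - 1e-9) count <<- count + 1L
      return(invisible())
    }
    if (n - idx + 1L < remaining) return(invisible())
    recurse(idx + 1L, remaining - 1L, acc + r[idx])  # idx in A
    recurse(idx + 1L, remaining, acc)                # idx not in A
  }
  recurse(1L, n_a, 0)
  count / total
}

# All valid reference-window starts by direct index intersection:
# mark excluded indices, find maximal allowed runs, then stride + flush.
partition_oracle_b_starts <- function(len, onsets, w, step) {
  excluded <- rep(FALSE, len)
  for (t in onsets) {
    lo <- max(0L, t - w); hi <- min(len, t + w)   # [lo, hi) 0-based
    if (hi > lo) excluded[(lo + 1L):hi] <- TRUE
  }
  starts <- integer(0)
  run_start <- NA_integer_
  for (pos in 0:(len)) {
    inside <- pos < len && !excluded[pos + 1L]
    if (inside && is.na(run_start)) run_start <- pos
    if (!inside && !is.na(run_start)) {
      run_len <- pos - run_start
      if (run_len >= w) {
        s <- seq.int(run_start, pos - w, by = step)
        if (s[length(s)] != pos - w) s <- c(s, pos - w)
        starts <- c(starts, s)
      }
      run_start <- NA_integer_
    }
  }
  as.integer(starts)
}

# Small random symmetric 0/1 graphs for property tests.
random_graph <- function(n, p = 0.4) {
  A <- matrix(0L, n, n)
  up <- which(upper.tri(A))
  A[up] <- as.integer(runif(length(up)) < p)
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  diag(A) <- 0L
  A
}
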