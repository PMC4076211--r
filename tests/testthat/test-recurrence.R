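test_that("recurrence matrix follows the threshold definition", {
  traj <- rbind(c(0, 0), c(0.3, 0.4))   # distance 0.5
  g <- recurrence_matrix(traj, recurrence_config(1, "absolute",
                                                 norm = "euclidean",
                                                 theiler = 0))
  expect_identical(g$matrix, matrix(c(0L, 1L, 1L, 0L), 2))
})

test_that("epsilon above the diameter saturates all off-Theiler entries", {
  set.seed(1)
  traj <- delay_embed(rnorm(30), 2, 1)
  g <- recurrence_matrix(traj, recurrence_config(1e6, "absolute", theiler = 1))
  A <- g$matrix
  expect_true(all(A[abs(row(A) - col(A)) > 1] == 1L))
  expect_true(all(A[abs(row(A) - col(A)) <= 1] == 0L))
})

test_that("recurrence-rate mode hits the target density", {
  set.seed(5)
  g <- recurrence_matrix(matrix(runif(100), ncol = 1),
                         recurrence_config(0.1, theiler = 0))
  A <- g$matrix
  dens <- sum(A) / (100 * 99)
  expect_gte(dens, 0.09); expect_lte(dens, 0.11)
})

test_that("identical points are degenerate in recurrence-rate mode", {
  expect_error(recurrence_matrix(matrix(1, 10, 1),
                                 recurrence_config(0.1)),
               "degenerate")
})

test_that("recurrence matrix is symmetric, binary, Theiler-zeroed", {
  set.seed(8)
  traj <- delay_embed(ar1(80, seed = 1), 3, 2)
  for (th in 0:2) {
    g <- recurrence_matrix(traj, recurrence_config(0.15, theiler = th))
    A <- g$matrix
    expect_identical(A, t(A))
    expect_true(all(A %in% c(0L, 1L)))
    expect_true(all(A[abs(row(A) - col(A)) <= th] == 0L))
  }
})

test_that("transitivity matches closed-form small graphs", {
  K5 <- matrix(1L, 5, 5); diag(K5) <- 0L
  expect_equal(transitivity(K5), 1)
  P3 <- matrix(0L, 3, 3); P3[1, 2] <- P3[2, 1] <- P3[2, 3] <- P3[3, 2] <- 1L
  expect_equal(transitivity(P3), 0)
  tp <- matrix(0L, 4, 4)
  tp[1, 2] <- tp[1, 3] <- tp[2, 3] <- tp[3, 4] <- 1L
  tp[lower.tri(tp)] <- t(tp)[lower.tri(tp)]
  expect_equal(transitivity(tp), 0.6)
})

test_that("transitivity equals brute-force triple enumeration on random graphs", {
  set.seed(13)
  for (rep in 1:25) {
    n <- sample(4:30, 1)
    A <- random_graph(n, p = runif(1, 0.2, 0.7))
    deg <- rowSums(A)
    if (sum(deg * (deg - 1)) == 0) next
    expect_identical(transitivity(A), transitivity_oracle(A))
  }
})

test_that("transitivity agrees with igraph's global clustering", {
  skip_if_not_installed("igraph")
  set.seed(17)
  for (rep in 1:10) {
    A <- random_graph(sample(5:25, 1), p = 0.5)
    deg <- rowSums(A)
    if (sum(deg * (deg - 1)) == 0) next
    ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    expect_equal(transitivity(A),
                 igraph::transitivity(ig, type = "global"))
  }
})

test_that("edgeless or starless graphs have undefined transitivity", {
  A <- matrix(0L, 4, 4)
  expect_error(transitivity(A), "undefined")
  A[1, 2] <- A[2, 1] <- A[3, 4] <- A[4, 3] <- 1L  # two disjoint edges
  expect_error(transitivity(A), "undefined")
})

test_that("transitivity dimension inverts (3/4)^m exactly", {
  for (m in 1:10) {
    expect_equal(transitivity_dimension((3 / 4)^m), m, tolerance = 1e-12)
  }
  expect_equal(transitivity_dimension(1), 0)
  expect_error(transitivity_dimension(0), "transitivity")
  expect_error(transitivity_dimension(1.2), "transitivity")
})

test_that("transitivity dimension is strictly decreasing in T", {
  Ts <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(sapply(Ts, transitivity_dimension)) < 0))
})

test_that("node relabelling permutes R and leaves transitivity unchanged", {
  set.seed(21)
  traj <- delay_embed(rnorm(60), 2, 1)
  cfg <- recurrence_config(0.5, "absolute", theiler = 0)
  g <- recurrence_matrix(traj, cfg)
  perm <- sample(nrow(traj))
  g_perm <- recurrence_matrix(traj[perm, ], cfg)
  expect_identical(g_perm$matrix, g$matrix[perm, perm])
  expect_equal(transitivity(g_perm), transitivity(g))
})

test_that("uniform scalars give transitivity dimension near 1", {
  set.seed(31)
  u <- runif(2000)
  dt <- window_transitivity_dimension(u, 1, 1,
                                      recurrence_config(0.05, norm = "maximum"))
  expect_gt(dt, 0.9); expect_lt(dt, 1.1)
})

test_that("a closed sine loop gives transitivity dimension near 1", {
  # incommensurate period so samples fill the curve without exact revisits
  s <- sin(2 * pi * (1:2000) / 23.7)
  dt <- window_transitivity_dimension(s, 2, 6,
                                      recurrence_config(0.05, norm = "maximum"))
  expect_gt(dt, 0.8); expect_lt(dt, 1.2)
})

test_that("constant windows are rejected", {
  expect_error(window_transitivity_dimension(rep(2, 50), 2, 1,
                                             recurrence_config(0.1)),
               "degenerate")
})

test_that("recurrence export round-trips dense and edge-list formats", {
  set.seed(2)
  g <- recurrence_matrix(delay_embed(rnorm(20), 2, 1),
                         recurrence_config(0.2))
  dense <- tempfile(fileext = ".csv")
  write_recurrence(g, dense, "dense")
  A <- as.matrix(utils::read.csv(dense, header = FALSE))
  dimnames(A) <- NULL
  expect_equal(A, g$matrix, ignore_attr = TRUE)
  edges <- tempfile(fileext = ".tsv")
  write_recurrence(g, edges, "edges")
  ed <- utils::read.table(edges, sep = "\t")
  expect_equal(nrow(ed), sum(g$matrix) / 2)
  expect_true(all(g$matrix[cbind(ed$V1 + 1, ed$V2 + 1)] == 1L))
})
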