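#' Configuration for recurrence-matrix construction
#'
#' The recurrence threshold can be given in signal units
#' (`epsilon_mode = "absolute"`) or as a target off-diagonal recurrence
#' rate in `(0, 1)` (`epsilon_mode = "recurrence_rate"`), in which case
#' the threshold is the distance quantile achieving that density within
#' one matrix cell. The Theiler window removes the main diagonal and,
#' for `theiler > 1`, a band of trivially recurrent temporal neighbours.
#'
#' @param epsilon threshold in signal units, or target recurrence rate.
#' @param epsilon_mode `"recurrence_rate"` (default) or `"absolute"`.
#' @param norm `"maximum"` (default) or `"euclidean"` point-distance norm.
#'   The maximum norm is the default because the transitivity-dimension
#'   identity `T = (3/4)^m` for uniform m-dimensional sets is exact for
#'   max-norm neighbourhoods.
#' @param theiler non-negative integer: pairs with `|i - j| <= theiler`
#'   are never recurrent. Default 1 (main diagonal only).
#' @return an object of class `recurrence_config`.
#' @export
recurrence_config <- function(epsilon = 0.10,
                              epsilon_mode = c("recurrence_rate", "absolute"),
                              norm = c("maximum", "euclidean"),
                              theiler = 1L) {
  epsilon_mode <- match.arg(epsilon_mode)
  norm <- match.arg(norm)
  theiler <- as.integer(theiler)
  stopifnot(theiler >= 0L)
  if (epsilon_mode == "recurrence_rate") {
    if (!(epsilon > 0 && epsilon < 1)) {
      stop("in recurrence_rate mode epsilon must lie strictly in (0, 1)")
    }
  } else if (epsilon <= 0) {
    stop("absolute epsilon must be positive")
  }
  structure(list(epsilon = epsilon, epsilon_mode = epsilon_mode,
                 norm = norm, theiler = theiler),
            class = "recurrence_config")
}

#' Recurrence matrix of an embedded trajectory
#'
#' Builds the symmetric binary matrix `R[i, j] = 1` iff the trajectory
#' points `i` and `j` are closer than the threshold under the configured
#' norm and lie outside the Theiler band. The matrix doubles as the
#' adjacency matrix of the recurrence network.
#'
#' @param traj trajectory matrix (one point per row), e.g. from
#'   [delay_embed()]; a plain numeric vector is treated as a
#'   one-dimensional trajectory.
#' @param cfg a [recurrence_config()].
#' @return an object of class `recurrence_graph`: list with `matrix`
#'   (0/1 integer matrix), `epsilon_used`, `n`, `theiler`.
#' @export
recurrence_matrix <- function(traj, cfg = recurrence_config()) {
  if (is.null(dim(traj))) traj <- matrix(as.numeric(traj), ncol = 1L)
  n <- nrow(traj)
  if (n < 2L) stop("trajectory must contain at least 2 points")
  d <- pairwise_dist(traj, cfg$norm)
  off_band <- abs(row(d) - col(d)) > cfg$theiler

  if (cfg$epsilon_mode == "recurrence_rate") {
    dv <- d[off_band & upper.tri(d)]
    if (length(dv) == 0L) {
      stop("Theiler window leaves no admissible pairs; reduce theiler")
    }
    if (max(dv) == 0) {
      stop("degenerate input: all trajectory points identical, recurrence-rate quantile undefined")
    }
    k <- max(1L, round(cfg$epsilon * length(dv)))
    eps <- sort(dv, partial = k)[k]
  } else {
    eps <- cfg$epsilon
  }

  R <- matrix(0L, n, n)
  R[d <= eps & off_band] <- 1L
  structure(list(matrix = R, epsilon_used = eps, n = n,
                 theiler = cfg$theiler),
            class = "recurrence_graph")
}

graph_adjacency <- function(graph) {
  if (inherits(graph, "recurrence_graph")) return(graph$matrix)
  A <- as.matrix(graph)
  if (nrow(A) != ncol(A)) stop("adjacency matrix must be square")
  if (!isTRUE(all.equal(A, t(A)))) stop("adjacency matrix must be symmetric")
  storage.mode(A) <- "integer"
  diag(A) <- 0L
  A
}

#' Global transitivity coefficient of a recurrence network
#'
#' The global clustering coefficient: the number of closed length-2
#' paths divided by the number of all length-2 paths,
#' `sum_ijk A_ij A_jk A_ki / sum_j deg_j (deg_j - 1)`.
#'
#' @param graph a `recurrence_graph` or a symmetric 0/1 adjacency matrix.
#' @return transitivity coefficient in `[0, 1]`.
#' @export
transitivity <- function(graph) {
  A <- graph_adjacency(graph)
  deg <- rowSums(A)
  paths2 <- sum(deg * (deg - 1))
  if (paths2 == 0) {
    stop("transitivity undefined: network has no length-2 paths")
  }
  Am <- A * 1.0
  closed <- sum(diag(Am %*% Am %*% Am))
  closed / paths2
}

#' Transitivity dimension
#'
#' Maps a transitivity coefficient `T` to a geometric dimension estimate
#' `log(T) / log(3/4)`, calibrated so that uniform m-dimensional sets
#' under the maximum norm (whose transitivity tends to `(3/4)^m`) map to
#' dimension `m`. Requires no scaling analysis.
#'
#' @param T transitivity coefficient in `(0, 1]`.
#' @return non-negative dimension estimate.
#' @examples
#' transitivity_dimension(0.75)    # 1
#' transitivity_dimension(0.5625)  # 2
#' @export
transitivity_dimension <- function(T) {
  if (!is.numeric(T) || length(T) != 1L || !is.finite(T)) {
    stop("T must be a single finite number")
  }
  if (T <= 0 || T > 1) stop("transitivity must lie in (0, 1], got ", T)
  log(T) / log(3 / 4)
}

#' Transitivity dimension of one series window
#'
#' Convenience composition: delay-embed the window, build the recurrence
#' network, and return the transitivity dimension. Degenerate windows
#' (constant, or without any length-2 network path) raise errors that
#' callers such as [operand_analyze()] convert to missing values.
#'
#' @param x numeric series window.
#' @param m embedding dimension.
#' @param tau time delay.
#' @param cfg a [recurrence_config()].
#' @return transitivity-dimension estimate (single number).
#' @export
window_transitivity_dimension <- function(x, m, tau,
                                          cfg = recurrence_config()) {
  traj <- delay_embed(as_series(x), m, tau)
  g <- recurrence_matrix(traj, cfg)
  transitivity_dimension(transitivity(g))
}

#' Export a recurrence matrix
#'
#' Writes either the dense 0/1 matrix as CSV or the sparse edge list as
#' a two-column TSV of 0-based indices `i < j`.
#'
#' @param graph a `recurrence_graph`.
#' @param path destination path.
#' @param format `"dense"` (CSV) or `"edges"` (TSV).
#' @export
write_recurrence <- function(graph, path, format = c("dense", "edges")) {
  format <- match.arg(format)
  A <- graph_adjacency(graph)
  if (format == "dense") {
    utils::write.table(A, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else {
    idx <- which(A == 1L & upper.tri(A), arr.ind = TRUE)
    edges <- data.frame(i = idx[, 1L] - 1L, j = idx[, 2L] - 1L)
    edges <- edges[order(edges$i, edges$j), , drop = FALSE]
    utils::write.table(edges, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}
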