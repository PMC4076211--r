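#' Configuration for false-nearest-neighbour embedding estimation
#'
#' Bundles the delay-embedding and FNN parameters. The false-neighbour
#' test is the classical dual criterion: a nearest neighbour at dimension
#' `m` is declared false when either the relative distance increase on
#' extending to `m + 1` exceeds `r_tol`, or the extended distance exceeds
#' `a_tol` times the attractor size (the standard deviation of the
#' series). The optimal dimension is the smallest `m` whose false-neighbour
#' fraction drops to `vanish_fraction` or below.
#'
#' @param tau positive integer time delay, in index units.
#' @param max_m largest trial embedding dimension.
#' @param r_tol distance-ratio tolerance (dimensionless), default 10.
#' @param a_tol attractor-size tolerance (dimensionless), default 2.
#' @param vanish_fraction fraction of false neighbours regarded as
#'   "vanished", in `[0, 1)`; default 0.01.
#' @param metric `"euclidean"` or `"maximum"` norm for neighbour distances.
#' @return an object of class `embedding_config`.
#' @export
embedding_config <- function(tau = 1L, max_m = 20L, r_tol = 10, a_tol = 2,
                             vanish_fraction = 0.01,
                             metric = c("euclidean", "maximum")) {
  tau <- as.integer(tau)
  max_m <- as.integer(max_m)
  stopifnot(tau >= 1L, max_m >= 1L, r_tol > 0, a_tol > 0)
  if (vanish_fraction < 0 || vanish_fraction >= 1) {
    stop("vanish_fraction must lie in [0, 1)")
  }
  structure(
    list(tau = tau, max_m = max_m, r_tol = r_tol, a_tol = a_tol,
         vanish_fraction = vanish_fraction, metric = match.arg(metric)),
    class = "embedding_config"
  )
}

#' Time-delay embedding of a scalar series
#'
#' Reconstructs an `m`-dimensional trajectory from a scalar series by
#' stacking delayed copies: point `i` has coordinates
#' `(x[i], x[i + tau], ..., x[i + (m - 1) tau])`. The result has
#' `N - (m - 1) * tau` points (rows), in series order.
#'
#' @param x numeric series.
#' @param m embedding dimension (positive integer).
#' @param tau time delay in index units (positive integer).
#' @return numeric matrix with one point per row and attributes `m`, `tau`.
#' @examples
#' delay_embed(1:5, m = 2, tau = 1)
#' @export
delay_embed <- function(x, m, tau) {
  x <- as_series(x, min_length = 1L)
  m <- as.integer(m); tau <- as.integer(tau)
  stopifnot(m >= 1L, tau >= 1L)
  n_pts <- length(x) - (m - 1L) * tau
  if (n_pts < 1L) {
    stop(sprintf(
      "series of length %d too short to embed at m = %d, tau = %d (needs at least %d points)",
      length(x), m, tau, (m - 1L) * tau + 1L))
  }
  traj <- vapply(seq_len(m) - 1L,
                 function(k) x[seq_len(n_pts) + k * tau],
                 numeric(n_pts))
  if (n_pts == 1L) traj <- matrix(traj, nrow = 1L)
  attr(traj, "m") <- m
  attr(traj, "tau") <- tau
  traj
}

# Pairwise distance matrix under the configured norm, as a dense matrix.
pairwise_dist <- function(pts, metric) {
  method <- if (metric == "maximum") "maximum" else "euclidean"
  as.matrix(stats::dist(pts, method = method))
}

#' Fraction of false nearest neighbours at a given dimension
#'
#' Embeds the series at dimension `m`, finds each point's nearest
#' neighbour (self-matches excluded, ties broken towards the smallest
#' index), and tests whether the neighbour remains close when the
#' embedding is extended to `m + 1`. Only points that can be extended to
#' `m + 1` take part. A neighbour is false when
#' `|x[i + m tau] - x[j + m tau]| / d_m(i, j) > r_tol` or when
#' `d_{m+1}(i, j) / sd(x) > a_tol`.
#'
#' @param x numeric series.
#' @param m trial embedding dimension.
#' @param cfg an [embedding_config()].
#' @return fraction in `[0, 1]` of tested points with a false neighbour.
#' @export
fnn_fraction <- function(x, m, cfg = embedding_config()) {
  x <- as_series(x)
  m <- as.integer(m)
  stopifnot(m >= 1L)
  sigma <- stats::sd(x)
  if (sigma == 0) stop("degenerate input: constant series has zero attractor size")
  n_ext <- length(x) - m * cfg$tau   # points embeddable at m + 1
  if (n_ext < 2L) {
    stop(sprintf(
      "series of length %d too short for FNN at m = %d, tau = %d (needs at least %d points)",
      length(x), m, cfg$tau, m * cfg$tau + 2L))
  }
  traj <- delay_embed(x, m, cfg$tau)[seq_len(n_ext), , drop = FALSE]
  ext <- x[seq_len(n_ext) + m * cfg$tau]   # the (m+1)-th coordinate

  d <- pairwise_dist(traj, cfg$metric)
  # Coincident points (distance at rounding scale relative to the
  # attractor size, e.g. exact revisits of a periodic orbit) carry no
  # information about local geometry; exclude them from the neighbour
  # search like self-matches.
  floor_eps <- 1e-8 * sigma
  d[d <= floor_eps] <- Inf
  diag(d) <- Inf
  tested <- rowSums(is.finite(d)) > 0L
  if (!any(tested)) {
    stop("degenerate input: no distinct neighbours available at m = ", m)
  }
  nn <- max.col(-d, ties.method = "first")  # smallest index wins ties
  d_m <- d[cbind(seq_len(n_ext), nn)]
  delta <- abs(ext - ext[nn])
  d_m1 <- if (cfg$metric == "maximum") pmax(d_m, delta) else sqrt(d_m^2 + delta^2)

  false_ratio <- delta > cfg$r_tol * d_m
  false_size <- d_m1 / sigma > cfg$a_tol
  mean((false_ratio | false_size)[tested])
}

#' Optimal embedding dimension by false nearest neighbours
#'
#' Evaluates [fnn_fraction()] for `m = 1, 2, ...` up to `cfg$max_m` (or up
#' to the largest dimension the series length permits) and returns the
#' smallest `m` whose false-neighbour fraction is at most
#' `cfg$vanish_fraction`. If no dimension qualifies, the dimension with
#' the smallest fraction is returned and `converged` is `FALSE`.
#'
#' @param x numeric series.
#' @param cfg an [embedding_config()].
#' @return list with `m_star` (integer), `fractions` (numeric vector, one
#'   entry per evaluated dimension) and `converged` (logical).
#' @export
optimal_embedding_dimension <- function(x, cfg = embedding_config()) {
  x <- as_series(x)
  # need at least 2 points embeddable at m + 1 to test dimension m
  m_feasible <- (length(x) - 2L) %/% cfg$tau
  m_max <- min(cfg$max_m, m_feasible)
  if (m_max < 1L) {
    stop(sprintf("series of length %d too short for FNN at tau = %d",
                 length(x), cfg$tau))
  }
  fractions <- numeric(m_max)
  for (m in seq_len(m_max)) {
    fractions[m] <- fnn_fraction(x, m, cfg)
    if (fractions[m] <= cfg$vanish_fraction) {
      return(list(m_star = m, fractions = fractions[seq_len(m)],
                  converged = TRUE))
    }
  }
  list(m_star = which.min(fractions), fractions = fractions,
       converged = FALSE)
}

#' Suggest a time delay from the autocorrelation function
#'
#' Returns the lag of the first local minimum of the sample
#' autocorrelation, a common heuristic for the embedding delay. Falls
#' back to the lag where the autocorrelation first drops below `1/e`,
#' then to 1.
#'
#' @param x numeric series.
#' @param max_lag largest lag examined (default `length(x) %/% 4`).
#' @return a positive integer delay.
#' @export
suggest_tau <- function(x, max_lag = NULL) {
  x <- as_series(x)
  if (is.null(max_lag)) max_lag <- max(2L, length(x) %/% 4L)
  max_lag <- min(max_lag, length(x) - 2L)
  rho <- as.numeric(stats::acf(x, lag.max = max_lag, plot = FALSE,
                               demean = TRUE)$acf)[-1L]
  if (length(rho) >= 3L) {
    dips <- which(diff(sign(diff(rho))) > 0) + 1L
    if (length(dips) > 0L) return(dips[[1L]])
  }
  below <- which(rho < exp(-1))
  if (length(below) > 0L) return(below[[1L]])
  1L
}
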