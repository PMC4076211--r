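#' Piecewise-constant series with planted level jumps
#'
#' Levels alternate between 0 and `jump_size` at each onset, so every
#' onset carries a first-difference of magnitude exactly `jump_size`
#' (before noise). With `noise_sd = 0` the only super-threshold
#' differences are at the onsets.
#'
#' @param length series length.
#' @param onsets integer vector of 0-based onset indices (each `>= 1`).
#' @param jump_size level jump magnitude (> 0 unless both jump and noise
#'   are 0).
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param seed integer RNG seed.
#' @return numeric vector.
#' @export
make_step_series <- function(length, onsets, jump_size, noise_sd = 0,
                             seed = 1L) {
  length <- as.integer(length)
  onsets <- sort(as.integer(onsets))
  stopifnot(length >= 2L, jump_size >= 0, noise_sd >= 0)
  if (any(onsets < 1L | onsets >= length)) stop("onsets out of bounds")
  level <- integer(length)           # number of onsets at or before t
  for (t in onsets) level[(t + 1L):length] <- level[(t + 1L):length] + 1L
  x <- jump_size * (level %% 2L)
  if (noise_sd > 0) {
    x <- x + with_seed(seed, stats::rnorm(length, sd = noise_sd))
  }
  x
}

# evaluate `expr` under a local, restored RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Standardised Lorenz x-coordinate series
#'
#' Integrates the Lorenz system (sigma = 10, rho = 28, beta = 8/3) with
#' fixed-step fourth-order Runge-Kutta at step `dt`, discards a
#' transient, subsamples, and standardises the x-coordinate to zero mean
#' and unit variance. The initial condition is jittered from the seed so
#' different seeds give different stretches of the attractor.
#'
#' @param n number of output samples.
#' @param seed integer RNG seed (initial-condition jitter).
#' @param dt integration step (default 0.01).
#' @param subsample keep every `subsample`-th integration step (default 25).
#' @param transient integration steps discarded before sampling.
#' @return numeric vector of length `n`, mean 0, sd 1.
#' @export
lorenz_x <- function(n, seed = 1L, dt = 0.01, subsample = 25L,
                     transient = 1000L) {
  n <- as.integer(n)
  stopifnot(n >= 2L)
  init <- with_seed(seed, c(x = 1 + stats::rnorm(1, sd = 0.5),
                            y = 1 + stats::rnorm(1, sd = 0.5),
                            z = 20 + stats::rnorm(1, sd = 0.5)))
  deriv <- function(t, state, parms) {
    with(as.list(state), list(c(
      10 * (y - x),
      x * (28 - z) - y,
      x * y - (8 / 3) * z
    )))
  }
  n_steps <- transient + n * subsample
  times <- seq(0, by = dt, length.out = n_steps + 1L)
  sol <- deSolve::rk4(init, times, deriv, parms = NULL)
  xs <- sol[, "x"]
  xs <- xs[seq(transient + 1L, by = subsample, length.out = n)]
  as.numeric(scale(xs))
}

#' Standardised Henon-map x series
#'
#' Iterates the Henon map (a = 1.4, b = 0.3) from a seed-jittered
#' initial condition, discards a transient, and standardises.
#'
#' @inheritParams lorenz_x
#' @param transient iterations discarded.
#' @return numeric vector of length `n`, mean 0, sd 1.
#' @export
henon_x <- function(n, seed = 1L, transient = 500L) {
  n <- as.integer(n)
  stopifnot(n >= 2L)
  st <- with_seed(seed, stats::runif(2, -0.1, 0.1))
  x <- st[[1L]]; y <- st[[2L]]
  out <- numeric(n)
  total <- transient + n
  for (i in seq_len(total)) {
    x_new <- 1 - 1.4 * x^2 + y
    y <- 0.3 * x
    x <- x_new
    if (i > transient) out[i - transient] <- x
  }
  as.numeric(scale(out))
}

#' Noisy sine series
#'
#' A unit-amplitude sine of the given period (in samples) plus Gaussian
#' observation noise, with a seed-jittered phase.
#'
#' @param n number of samples.
#' @param seed integer RNG seed (phase and noise).
#' @param period samples per cycle (default 25).
#' @param noise_sd observation-noise standard deviation (default 0).
#' @return numeric vector of length `n`.
#' @export
noisy_sine <- function(n, seed = 1L, period = 25, noise_sd = 0) {
  n <- as.integer(n)
  stopifnot(n >= 2L, period > 0, noise_sd >= 0)
  with_seed(seed, {
    phase <- stats::runif(1, 0, 2 * pi)
    x <- sin(2 * pi * seq_len(n) / period + phase)
    if (noise_sd > 0) x <- x + stats::rnorm(n, sd = noise_sd)
    x
  })
}

#' Stationary AR(1) series
#'
#' `x[t] = phi x[t-1] + e[t]`, innovations standard normal scaled so the
#' stationary standard deviation is `sd`; burn-in discarded.
#'
#' @param n number of samples.
#' @param seed integer RNG seed.
#' @param phi autoregressive coefficient, `|phi| < 1` (default 0.6).
#' @param sd stationary standard deviation (default 1).
#' @return numeric vector of length `n`.
#' @export
ar1 <- function(n, seed = 1L, phi = 0.6, sd = 1) {
  n <- as.integer(n)
  stopifnot(n >= 2L, abs(phi) < 1, sd > 0)
  innov_sd <- sd * sqrt(1 - phi^2)
  with_seed(seed, {
    e <- stats::rnorm(n + 100L, sd = innov_sd)
    x <- as.numeric(stats::filter(e, phi, method = "recursive"))
    x[(length(x) - n + 1L):length(x)]
  })
}

source_series <- function(name, n, seed, noise_sd) {
  switch(name,
         lorenz_x = lorenz_x(n, seed = seed),
         henon_x = henon_x(n, seed = seed),
         noisy_sine = noisy_sine(n, seed = seed, noise_sd = noise_sd),
         ar1 = ar1(n, seed = seed),
         stop("unknown source: ", name))
}

#' Synthetic co-occurrence model for the two demo sentences
#'
#' Builds a small, fully synthetic word-context joint-probability model
#' whose rows cover the content lemmas of the bundled demo sentences
#' ("It was a sunny day and the friendly child travelled...") plus the
#' default paradigm words. Each word's context profile mixes a positive
#' and a negative context column according to a planted polarity, chosen
#' so that the most positively associated lemmas are "travel" and
#' "sunny" and the most negative are "vicious" and "violent". The model
#' stands in for a corpus-trained co-occurrence matrix in examples and
#' tests; it encodes designed associations, not corpus statistics.
#'
#' @return list with `model` (a `cooccurrence_model`), `paradigms`
#'   (default [paradigm_sets()]), and `polarity` (the planted scores).
#' @export
make_demo_polarity_model <- function() {
  pars <- paradigm_sets()
  polarity <- c(
    travel = 0.95, sunny = 0.90, friendly = 0.60, green = 0.50,
    child = 0.40, day = 0.30, dog = 0.20, yard = 0.10, voice = 0.00,
    hear = 0.00, look = 0.00, fence = 0.00, notice = -0.05,
    suddenly = -0.10, bark = -0.50, frighten = -0.60, violent = -0.90,
    vicious = -0.95
  )
  rows <- c(names(polarity), pars$positives, pars$negatives)
  ctx <- c("goodthings", "badthings", "neutralthings")
  probs <- matrix(0, length(rows), length(ctx),
                  dimnames = list(rows, ctx))
  mix <- function(s) c((1 + s) / 2 * 0.8, (1 - s) / 2 * 0.8, 0.2)
  for (w in names(polarity)) probs[w, ] <- mix(polarity[[w]])
  for (w in pars$positives) probs[w, ] <- mix(0.92)
  for (w in pars$negatives) probs[w, ] <- mix(-0.92)
  probs <- probs / sum(probs)
  list(model = new_cooccurrence_model(probs, rows, ctx),
       paradigms = pars, polarity = polarity)
}

#' The two demo sentences used in examples
#'
#' @return character scalar with two sentences about a sunny day and a
#'   barking dog, exercising POS filtering, lemmatisation and scoring.
#' @export
demo_sentences <- function() {
  paste(
    "It was a sunny day and the friendly child travelled in the green",
    "yard. Suddenly he heard a frightening voice and noticed that a",
    "vicious looking and violent dog is barking behind the fence."
  )
}

#' Specification of the dimension-shift benchmark
#'
#' Describes a piecewise series in which reference stretches follow
#' low-dimensional dynamics and the `w` points immediately before each
#' planted onset follow a higher-dimensional chaotic source, with a
#' level jump at the onset so a first-difference detector finds exactly
#' the planted onsets. Defaults plant 10 onsets 360 samples apart in a
#' series of length 3700 with pre-onset window length 100 — the regime
#' the sliding-window analysis (w = 100, step = 20) is designed for.
#'
#' @param length total series length.
#' @param onset_times 0-based onset indices, each at least `w` from the
#'   start and `w` apart.
#' @param w length of the pre-onset chaotic stretch (matches the
#'   analysis window length).
#' @param pre_onset_source,reference_source one of `"lorenz_x"`,
#'   `"henon_x"`, `"noisy_sine"`, `"ar1"`.
#' @param jump_size level jump at each onset (default 10).
#' @param noise_sd observation noise passed to a `noisy_sine` source
#'   (default 0: the reference is a clean sine).
#' @param seed integer RNG seed.
#' @return an object of class `benchmark_spec`.
#' @export
benchmark_spec <- function(length = 3700L,
                           onset_times = seq(360L, 3600L, by = 360L),
                           w = 100L,
                           pre_onset_source = "lorenz_x",
                           reference_source = "noisy_sine",
                           jump_size = 10,
                           noise_sd = 0,
                           seed = 1L) {
  length <- as.integer(length); w <- as.integer(w)
  onset_times <- sort(as.integer(onset_times))
  stopifnot(length >= 3L * w, w >= 2L, jump_size > 0, noise_sd >= 0)
  if (any(onset_times < w) || any(onset_times >= length)) {
    stop("infeasible spec: onsets must lie in [w, length)")
  }
  if (any(diff(onset_times) < w)) {
    stop("infeasible spec: pre-onset segments overlap")
  }
  structure(list(length = length, onset_times = onset_times, w = w,
                 pre_onset_source = pre_onset_source,
                 reference_source = reference_source,
                 jump_size = jump_size, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "benchmark_spec")
}

#' Dimension-shift benchmark series
#'
#' Builds the series described by a [benchmark_spec()]: the reference
#' source everywhere, overwritten by the chaotic pre-onset source on
#' `[t - w, t)` for each onset `t`, plus a level alternating between 0
#' and `jump_size` switching at each onset. Both sources are
#' standardised, so with the default `jump_size = 10` a detector at
#' `theta = jump_size / 2` recovers exactly the planted onsets.
#'
#' @param spec a [benchmark_spec()].
#' @return list with `series` (numeric vector) and `onsets`
#'   (the planted 0-based onset indices).
#' @export
make_dimension_shift_series <- function(spec = benchmark_spec()) {
  stopifnot(inherits(spec, "benchmark_spec"))
  n <- spec$length; w <- spec$w
  x <- source_series(spec$reference_source, n, spec$seed, spec$noise_sd)
  for (k in seq_along(spec$onset_times)) {
    t <- spec$onset_times[[k]]
    seg_seed <- as.integer((as.numeric(spec$seed) * 1009 + k) %% 2147483647)
    seg <- source_series(spec$pre_onset_source, w,
                         seed = seg_seed, spec$noise_sd)
    x[(t - w + 1L):t] <- seg
  }
  level <- integer(n)
  for (t in spec$onset_times) {
    level[(t + 1L):n] <- level[(t + 1L):n] + 1L
  }
  x <- x + spec$jump_size * (level %% 2L)
  list(series = x, onsets = spec$onset_times)
}
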