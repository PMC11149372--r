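# Allele-frequency profiles for the five simulated populations, and the
# genetic-distance -> effect-correlation schedule that encodes the degree of
# genotype-phenotype distribution shift between the European-ancestry (EUR)
# population and each data-disadvantaged population (DDP).

FREQ_LO <- 0.05
FREQ_HI <- 0.95

#' Table of printed EUR-to-DDP genetic distances
#'
#' Sum-of-absolute-frequency-difference distances (over 500 SNPs) between the
#' EUR population and each data-disadvantaged population, in increasing order:
#' AMR 42.7, SAS 46.1, EAS 80.6, AFR 94.1. When profiles are simulated with a
#' different SNP count `m`, the targets scale proportionally (`m/500`), which
#' leaves the distance *ratios* -- and hence the effect-size correlations of
#' [rho_schedule()] -- unchanged.
#'
#' @param m SNP count the distances should refer to (default 500).
#' @return Named numeric vector of distances for AMR, SAS, EAS, AFR.
#' @export
#' @examples
#' reference_distances()
#' reference_distances(m = 100)
reference_distances <- function(m = 500) {
  c(AMR = 42.7, SAS = 46.1, EAS = 80.6, AFR = 94.1) * (m / 500)
}

new_freq_profile <- function(population, frequencies) {
  stopifnot(is.character(population), length(population) == 1L,
            is.numeric(frequencies), length(frequencies) >= 1L)
  if (any(frequencies < FREQ_LO - 1e-12 | frequencies > FREQ_HI + 1e-12))
    stop("frequencies outside [", FREQ_LO, ", ", FREQ_HI, "]")
  structure(list(population = population,
                 frequencies = as.numeric(frequencies)),
            class = "freq_profile")
}

#' @export
print.freq_profile <- function(x, ...) {
  cat("<freq_profile> ", x$population, ": ", length(x$frequencies),
      " SNPs, mean frequency ", round(mean(x$frequencies), 3), "\n", sep = "")
  invisible(x)
}

# Balding-Nichols-style divergence: conditional on the EUR frequency f, the
# DDP frequency is Beta(f(1-c)/c, (1-f)(1-c)/c) -- mean f, variance
# c*f*(1-f) -- then clipped to the declared frequency bounds. `u` optionally
# supplies uniform deviates so calibration can vary c under common random
# numbers.
bn_shift <- function(f, c, u = NULL) {
  if (c <= 0) return(f)
  if (is.null(u)) u <- runif(length(f))
  nu <- (1 - c) / c
  # qbeta warns about precision at extreme shape parameters; clipping below
  # makes the affected tail values irrelevant
  shifted <- suppressWarnings(stats::qbeta(u, f * nu, (1 - f) * nu))
  pmin(pmax(shifted, FREQ_LO), FREQ_HI)
}

#' Simulate per-population minor-allele-frequency profiles
#'
#' Draws an EUR profile uniformly on `[0.05, 0.95]` and derives one profile per
#' data-disadvantaged population by a Balding-Nichols-style shift: the DDP
#' frequency at each SNP is a Beta draw centred on the EUR frequency with
#' variance `c * f * (1 - f)`, where `c` is that population's divergence
#' scalar, clipped back to the bounds. A divergence of 0 reproduces the EUR
#' profile exactly; larger divergence yields a larger expected genetic
#' distance (see [calibrate_divergence()]).
#'
#' @param m Number of SNPs (>= 1).
#' @param divergence Named numeric vector of divergence scalars in `[0, 1)`,
#'   one per non-EUR population; default is calibrated so realized distances
#'   match [reference_distances()] for this `m`.
#' @param seed Integer seed; the whole set of profiles is reproducible.
#' @return Named list of `freq_profile` objects (EUR first).
#' @export
#' @examples
#' pr <- simulate_frequency_profiles(50, c(AMR = 0, AFR = 0.2), seed = 1)
#' genetic_distance(pr$EUR, pr$AMR)   # 0: zero divergence copies EUR
simulate_frequency_profiles <- function(m, divergence = NULL, seed = 1L) {
  if (!is.numeric(m) || length(m) != 1L || m < 1) stop("m must be >= 1")
  m <- as.integer(m)
  if (is.null(divergence)) {
    targets <- reference_distances(m)
    divergence <- vapply(names(targets), function(p)
      calibrate_divergence(targets[[p]], m,
                           seed = derive_seed(seed, "calibrate", match(p, names(targets)))),
      numeric(1))
  }
  if (is.null(names(divergence)) || any(!nzchar(names(divergence))))
    stop("divergence scalars must be named by population")
  if (any(divergence < 0)) stop("divergence scalars must be >= 0")
  if (any(divergence >= 1)) stop("divergence scalars must be < 1")

  eur <- with_seed(derive_seed(seed, "freq-eur"),
                   runif(m, FREQ_LO, FREQ_HI))
  profiles <- list(EUR = new_freq_profile("EUR", eur))
  for (i in seq_along(divergence)) {
    pop <- names(divergence)[i]
    ci <- divergence[[i]]
    fi <- with_seed(derive_seed(seed, paste0("freq-", pop)), {
      f <- bn_shift(eur, ci)
      attempts <- 0L
      while (sd(f) == 0 && attempts < 10L) {   # degenerate: redraw
        f <- bn_shift(eur, ci)
        attempts <- attempts + 1L
      }
      if (sd(f) == 0) stop("divergence for ", pop,
                           " produced a degenerate (constant) profile")
      f
    })
    profiles[[pop]] <- new_freq_profile(pop, fi)
  }
  profiles
}

#' Genetic distance between two frequency profiles
#'
#' The sum over SNPs of absolute minor-allele-frequency differences,
#' `d = sum_j |F_j - F'_j|`.
#'
#' @param f_a,f_b `freq_profile` objects (or bare numeric frequency vectors)
#'   of equal length.
#' @return Non-negative scalar distance; symmetric in its arguments.
#' @export
#' @examples
#' genetic_distance(c(0.1, 0.5), c(0.3, 0.2))  # 0.5
genetic_distance <- function(f_a, f_b) {
  a <- if (inherits(f_a, "freq_profile")) f_a$frequencies else as.numeric(f_a)
  b <- if (inherits(f_b, "freq_profile")) f_b$frequencies else as.numeric(f_b)
  if (length(a) != length(b)) stop("frequency profiles differ in length")
  sum(abs(a - b))
}

#' Calibrate a divergence scalar to a target genetic distance
#'
#' Finds the Balding-Nichols divergence `c` whose *expected* genetic distance
#' to a uniform EUR profile equals `target_distance`, by Monte-Carlo averaging
#' over profile draws under common random numbers and root finding in `c`.
#'
#' @param target_distance Desired expected distance (>= 0; must be attainable
#'   under the frequency bounds, i.e. below roughly `0.3 * m`).
#' @param m SNP count.
#' @param seed Integer seed for the Monte-Carlo draws.
#' @param n_draws Profiles averaged per candidate `c` (default 20).
#' @return Divergence scalar in `[0, 1)`.
#' @export
#' @examples
#' calibrate_divergence(0, m = 100)   # 0
calibrate_divergence <- function(target_distance, m, seed = 1L, n_draws = 20L) {
  if (target_distance < 0) stop("target_distance must be >= 0")
  if (target_distance == 0) return(0)
  if (target_distance >= 0.9 * m)
    stop("target distance ", target_distance, " exceeds the attainable bound")
  m <- as.integer(m)

  draws <- with_seed(derive_seed(seed, "calibrate-crn"), {
    list(f = matrix(runif(m * n_draws, FREQ_LO, FREQ_HI), m, n_draws),
         u = matrix(runif(m * n_draws), m, n_draws))
  })
  expected_distance <- function(c) {
    d <- vapply(seq_len(n_draws), function(k) {
      sum(abs(bn_shift(draws$f[, k], c, draws$u[, k]) - draws$f[, k]))
    }, numeric(1))
    mean(d)
  }
  c_hi <- 0.98
  if (expected_distance(c_hi) < target_distance)
    stop("target distance ", target_distance,
         " is unattainable under the frequency bounds")
  stats::uniroot(function(c) expected_distance(c) - target_distance,
                 lower = 1e-8, upper = c_hi, tol = 1e-9)$root
}

#' Effect-size correlation as a function of genetic distance
#'
#' Maps the genetic distance `d_k` between EUR and the k-th DDP to the
#' cross-population correlation of per-SNP effect sizes:
#' `rho_k = rho0 * (d0 / d_k)^r`, where `d0` is the smallest (EUR-AMR)
#' distance and `rho0` the correlation assigned at that distance (0.8).
#' Larger distances give smaller correlations, i.e. stronger
#' genotype-phenotype distribution shift; `r` controls how fast the
#' correlation decays.
#'
#' @param d0 Reference distance (> 0).
#' @param dk Distance of the population of interest (> 0).
#' @param rho0 Correlation at the reference distance, in `(0, 1]`.
#' @param r Decay exponent (>= 0).
#' @return Correlation `rho_k`.
#' @export
#' @examples
#' rho_schedule(42.7, 94.1, r = 0.5)  # 0.54 at 2 dp
rho_schedule <- function(d0, dk, rho0 = 0.8, r = 0.5) {
  if (any(c(d0, dk) <= 0)) stop("distances must be positive")
  if (rho0 <= 0 || rho0 > 1) stop("rho0 must be in (0, 1]")
  rho0 * (d0 / dk)^r
}
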