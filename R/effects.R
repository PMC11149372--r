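# Per-SNP effect sizes: the EUR effect vector W and, for each DDP, a shifted
# vector W' correlated with W at the level set by the rho schedule.

# standard normal truncated to [-1, 1]: inverse-CDF sampling
rtruncnorm_unit <- function(n) {
  lo <- pnorm(-1); hi <- pnorm(1)
  qnorm(runif(n, lo, hi))
}

# sd of the standard normal truncated to [-1, 1]; the variance-normalization
# scalar applied to liability noise is its reciprocal
TRUNCNORM_SD <- sqrt(1 - 2 * dnorm(1) / (pnorm(1) - pnorm(-1)))

#' Draw a per-SNP effect-size vector
#'
#' Effect sizes are drawn from a standard normal truncated to `[-1, 1]`
#' (keeping the bounded support of the generating model; set
#' `truncate = FALSE` for a plain standard normal). The overall scale of the
#' effects is irrelevant downstream because the weighted genetic score is
#' variance-standardized before entering the liability.
#'
#' @param m Number of SNPs (>= 1).
#' @param seed Integer seed.
#' @param truncate Truncate to `[-1, 1]` (default TRUE).
#' @return Numeric vector of length `m`.
#' @export
#' @examples
#' w <- draw_effects(10, seed = 1)
#' range(w)   # within [-1, 1]
draw_effects <- function(m, seed = 1L, truncate = TRUE) {
  if (!is.numeric(m) || length(m) != 1L || m < 1) stop("m must be >= 1")
  with_seed(seed, if (truncate) rtruncnorm_unit(m) else rnorm(m))
}

#' Derive a correlated effect vector for a shifted population
#'
#' Given the EUR effects `W` and a target correlation `rho`, returns
#' `W' = rho * W + sqrt(1 - rho^2) * zeta'`, with the perturbation `zeta'`
#' drawn from the same distribution as `W` so that `cor(W, W')` has
#' expectation `rho`. `rho = 1` returns `W` unchanged; `rho = 0` gives an
#' independent vector.
#'
#' @param W Numeric effect vector.
#' @param rho Correlation in `[0, 1]`.
#' @param seed Integer seed for the perturbation draw.
#' @param truncate Passed to the perturbation draw (see [draw_effects()]).
#' @return Numeric vector `W'` of the same length as `W`.
#' @export
#' @examples
#' W <- draw_effects(500, seed = 1)
#' Wp <- correlate_effects(W, 0.8, seed = 2)
#' cor(W, Wp)   # near 0.8
correlate_effects <- function(W, rho, seed = 1L, truncate = TRUE) {
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho > 1)
    stop("rho must be a scalar in [0, 1]")
  if (rho == 1) return(W)
  zeta <- with_seed(seed,
                    if (truncate) rtruncnorm_unit(length(W)) else rnorm(length(W)))
  rho * W + sqrt(1 - rho^2) * zeta
}

#' Construct the effect model for a dataset
#'
#' Bundles the EUR effect vector with per-DDP shifted vectors at the
#' correlations implied by the genetic distances and the decay exponent `r`.
#'
#' @param m SNP count.
#' @param distances Named vector of EUR-to-DDP genetic distances (the smallest
#'   is used as the reference `d0`).
#' @param r Decay exponent of [rho_schedule()].
#' @param h2 Heritability carried along for liability generation.
#' @param rho0 Correlation at the reference distance.
#' @param seed Integer seed.
#' @param truncate Passed to the effect draws.
#' @return Object of class `effect_model`: list with `W`, `W_prime` (named
#'   list per DDP), `rho` (named vector), `h2`, `m`.
#' @export
effect_model <- function(m, distances = reference_distances(m), r = 0.5,
                         h2 = 0.5, rho0 = 0.8, seed = 1L, truncate = TRUE) {
  if (h2 < 0 || h2 > 1) stop("h2 must be in [0, 1]")
  d0 <- min(distances)
  rho <- vapply(distances, function(d) rho_schedule(d0, d, rho0, r), numeric(1))
  W <- draw_effects(m, seed = derive_seed(seed, "effects-eur"),
                    truncate = truncate)
  W_prime <- lapply(seq_along(rho), function(i)
    correlate_effects(W, rho[[i]],
                      seed = derive_seed(seed, paste0("effects-", names(rho)[i])),
                      truncate = truncate))
  names(W_prime) <- names(rho)
  structure(list(W = W, W_prime = W_prime, rho = rho, h2 = h2, m = m,
                 r = r, rho0 = rho0, distances = distances),
            class = "effect_model")
}

#' @export
print.effect_model <- function(x, ...) {
  cat("<effect_model> ", x$m, " SNPs, h2 = ", x$h2, "\n", sep = "")
  cat("  rho:", paste(names(x$rho), round(x$rho, 2), sep = "=",
                      collapse = ", "), "\n")
  invisible(x)
}
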