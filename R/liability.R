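# Liability-threshold phenotype model: a latent liability g combines a
# variance-standardized weighted genetic score with independent noise; case
# status is liability above a population-specific threshold chosen to realize
# the requested case:control ratio.

#' Compute latent liabilities from genotypes and effect sizes
#'
#' The weighted genetic score `s_i = sum_j w_j x_ij` is standardized to zero
#' mean and unit variance across individuals, then combined with independent
#' noise: `g = sqrt(h2) * z(s) + sqrt(1 - h2) * a * zeta`, where `zeta` is a
#' standard normal truncated to `[-1, 1]` and the variance-normalization
#' scalar `a = 1/sd(zeta)` restores the noise to unit variance. Consequently
#' `Var(g) ~ 1` and the fraction of liability variance explained by the
#' genetic score is `h2` -- the heritability.
#'
#' @param X Genotype dosage matrix (individuals x SNPs).
#' @param W Effect vector, `length(W) == ncol(X)`.
#' @param h2 Heritability in `[0, 1]`.
#' @param seed Integer seed for the noise draw.
#' @param truncate Use the truncated-normal noise (default); `FALSE` draws
#'   plain standard normal noise with `a = 1`.
#' @return Numeric liability vector of length `nrow(X)`.
#' @export
#' @examples
#' X <- matrix(rbinom(200, 2, 0.3), 20, 10)
#' g <- compute_liability(X, rnorm(10), h2 = 1)  # pure standardized score
compute_liability <- function(X, W, h2, seed = 1L, truncate = TRUE) {
  if (ncol(X) != length(W)) stop("ncol(X) must equal length(W)")
  if (h2 < 0 || h2 > 1) stop("h2 must be in [0, 1]")
  s <- as.numeric(X %*% W)
  if (sd(s) == 0) stop("genetic component has zero variance")
  z <- (s - mean(s)) / sd(s)
  if (h2 == 1) return(z)
  noise <- with_seed(seed, {
    if (truncate) rtruncnorm_unit(nrow(X)) / TRUNCNORM_SD else rnorm(nrow(X))
  })
  sqrt(h2) * z + sqrt(1 - h2) * noise
}

# parse "1:4", c(1, 4), or a case fraction into the case fraction
case_fraction <- function(ratio) {
  if (is.character(ratio)) {
    parts <- as.numeric(strsplit(ratio, ":", fixed = TRUE)[[1]])
    if (length(parts) != 2 || any(is.na(parts)) || any(parts <= 0))
      stop("case_control_ratio string must look like '1:4'")
    parts[1] / sum(parts)
  } else if (length(ratio) == 2) {
    if (any(ratio <= 0)) stop("ratio parts must be positive")
    ratio[1] / sum(ratio)
  } else if (length(ratio) == 1) {
    if (ratio <= 0 || ratio >= 1) stop("case fraction must be in (0, 1)")
    ratio
  } else stop("unrecognized case_control_ratio")
}

#' Assign case/control labels from liabilities
#'
#' The threshold is the empirical order statistic of `g` at the control
#' fraction; an individual is a case iff its liability is strictly above the
#' threshold. With no ties this realizes the requested case:control ratio
#' exactly (up to one individual from rounding); tied liabilities at the
#' threshold all fall to the control side (strict `>`), a deterministic
#' tie-break.
#'
#' @param g Numeric liability vector.
#' @param case_control_ratio `"1:1"`-style string, length-2 numeric, or a
#'   case fraction in `(0, 1)`.
#' @return List with `y` (integer 0/1 labels) and `thr` (the threshold).
#' @export
#' @examples
#' assign_labels(rnorm(1000), "1:4")$thr
assign_labels <- function(g, case_control_ratio = "1:1") {
  if (length(g) == 0) stop("empty liability vector")
  if (any(!is.finite(g))) stop("non-finite liabilities")
  frac <- case_fraction(case_control_ratio)
  n <- length(g)
  n_controls <- n - round(n * frac)
  if (n_controls < 1 || n_controls >= n)
    stop("ratio leaves no individuals on one side")
  thr <- sort(g)[n_controls]
  list(y = as.integer(g > thr), thr = thr)
}
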