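# Assembly of a two-population case-control dataset: genotypes drawn from
# per-population allele frequencies, phenotypes from the liability-threshold
# model, and a fixed 80/10/10 train/validation/test split stratified jointly
# by ancestry and class label.

#' Draw a genotype dosage matrix from a frequency profile
#'
#' Independent SNPs: dosage of SNP `j` is Binomial(2, F_j).
#'
#' @param n Number of individuals.
#' @param profile `freq_profile` (or numeric frequency vector).
#' @param seed Integer seed.
#' @return Integer matrix `n x m` with entries in `{0, 1, 2}`.
#' @export
draw_genotypes <- function(n, profile, seed = 1L) {
  f <- if (inherits(profile, "freq_profile")) profile$frequencies else profile
  m <- length(f)
  with_seed(seed, matrix(rbinom(n * m, 2L, rep(f, each = n)), n, m))
}

# stratified 80/10/10 split; returns factor train/validation/test
make_split <- function(ancestry, y, seed, proportions = c(0.8, 0.1, 0.1)) {
  stopifnot(abs(sum(proportions) - 1) < 1e-9)
  split <- character(length(y))
  strata <- interaction(ancestry, y, drop = TRUE)
  with_seed(seed, {
    for (s in levels(strata)) {
      idx <- which(strata == s)
      if (length(idx) < 10L)
        stop("stratum ", s, " has fewer than 10 individuals; split undefined")
      idx <- sample(idx)
      n <- length(idx)
      n_val <- round(proportions[2] * n)
      n_test <- round(proportions[3] * n)
      n_train <- n - n_val - n_test
      split[idx] <- rep(c("train", "validation", "test"),
                        c(n_train, n_val, n_test))
    }
  })
  factor(split, levels = c("train", "validation", "test"))
}

#' Build a multi-ancestry case-control dataset
#'
#' Draws genotypes per population from its frequency profile, computes
#' liabilities with the population's own effect vector (EUR uses `W`, each
#' DDP its shifted `W'`), thresholds liabilities per population at the
#' requested case:control ratio, and attaches a stratified 80/10/10 split.
#' Optionally appends two simulated clinical covariates (one continuous, one
#' binary) that contribute to the liability before noise.
#'
#' @param profiles Named list of `freq_profile`s (must contain `EUR` and every
#'   population in `n_per_pop`).
#' @param effects `effect_model` (see [effect_model()]).
#' @param n_per_pop Named integer vector of cohort sizes, e.g.
#'   `c(EUR = 10000, AMR = 2000)`.
#' @param case_control_ratio `"1:1"`-style ratio (see [assign_labels()]).
#' @param seed Integer master seed; expands into per-stage streams.
#' @param truncate Noise distribution flag (see [compute_liability()]).
#' @param clinical `NULL` (default, off) or a list
#'   `list(effect_cont =, effect_bin =)` giving liability effects of a
#'   standard-normal continuous covariate and a centred Bernoulli(0.5) binary
#'   covariate; when on, the covariates are appended as the last two feature
#'   columns.
#' @return Object of class `ma_dataset`: list with feature matrix `X`, labels
#'   `y`, `ancestry`, `split`, latent liabilities `g` (retained for testing),
#'   per-population thresholds `thr`, and the generating `effects`/`profiles`.
#' @export
#' @examples
#' pr <- simulate_frequency_profiles(30, c(AMR = 0.02), seed = 1)
#' em <- effect_model(30, distances = c(AMR = 3), seed = 1)
#' d <- build_dataset(pr, em, c(EUR = 200, AMR = 80), seed = 1)
#' table(d$ancestry, d$y)
build_dataset <- function(profiles, effects, n_per_pop,
                          case_control_ratio = "1:1", seed = 1L,
                          truncate = TRUE, clinical = NULL) {
  pops <- names(n_per_pop)
  if (is.null(pops) || !"EUR" %in% pops)
    stop("n_per_pop must be named and include EUR")
  missing_p <- setdiff(pops, names(profiles))
  if (length(missing_p)) stop("profiles missing: ", paste(missing_p, collapse = ", "))

  m <- effects$m
  X_list <- list(); y_list <- list(); g_list <- list()
  anc_list <- list(); thr <- numeric(0)
  for (pop in pops) {
    n <- as.integer(n_per_pop[[pop]])
    Xp <- draw_genotypes(n, profiles[[pop]], derive_seed(seed, paste0("geno-", pop)))
    W <- if (pop == "EUR") effects$W else {
      if (is.null(effects$W_prime[[pop]]))
        stop("effect model has no shifted effects for ", pop)
      effects$W_prime[[pop]]
    }
    g <- compute_liability(Xp, W, effects$h2,
                           seed = derive_seed(seed, paste0("noise-", pop)),
                           truncate = truncate)
    if (!is.null(clinical)) {
      cc <- with_seed(derive_seed(seed, paste0("clin-", pop)), {
        list(cont = rnorm(n), bin = rbinom(n, 1L, 0.5))
      })
      g <- g + clinical$effect_cont * cc$cont +
        clinical$effect_bin * (cc$bin - 0.5) * 2
      Xp <- cbind(Xp, clin_cont = cc$cont, clin_bin = cc$bin)
    }
    lab <- assign_labels(g, case_control_ratio)
    X_list[[pop]] <- Xp; y_list[[pop]] <- lab$y; g_list[[pop]] <- g
    anc_list[[pop]] <- rep(pop, n); thr[pop] <- lab$thr
  }
  X <- do.call(rbind, X_list)
  colnames(X) <- c(paste0("snp", seq_len(m)),
                   if (!is.null(clinical)) c("clin_cont", "clin_bin"))
  y <- unlist(y_list, use.names = FALSE)
  ancestry <- factor(unlist(anc_list, use.names = FALSE), levels = pops)
  split <- make_split(ancestry, y, derive_seed(seed, "split"))
  structure(list(X = X, y = y, ancestry = ancestry, split = split,
                 g = unlist(g_list, use.names = FALSE), thr = thr,
                 effects = effects, profiles = profiles[pops],
                 case_control_ratio = case_control_ratio, seed = seed),
            class = "ma_dataset")
}

#' Simulate a complete two-population dataset in one call
#'
#' Convenience wrapper running the full generator: frequency profiles
#' (divergence calibrated to the printed genetic distances unless supplied),
#' effect model (`rho` from [rho_schedule()] applied to the target distances),
#' genotypes, liabilities, labels, and split. Defaults reproduce the study
#' conditions of the 1:1 compendium's first dataset: 500 SNPs, 10,000 EUR and
#' 2,000 DDP individuals, heritability 0.5, decay exponent 0.5.
#'
#' @param ddp Data-disadvantaged population (`"AMR"`, `"SAS"`, `"EAS"`,
#'   `"AFR"`).
#' @param m SNP count.
#' @param n_eur,n_ddp Cohort sizes.
#' @param h2 Heritability.
#' @param r Decay exponent of the rho schedule.
#' @param case_control_ratio `"1:1"` or `"1:4"` (or a case fraction).
#' @param seed Integer master seed.
#' @param divergence Optional pre-calibrated divergence scalar for the DDP
#'   (skips calibration; see [calibrate_divergence()]).
#' @param truncate,clinical Passed to [build_dataset()].
#' @return An `ma_dataset`.
#' @export
#' @examples
#' d <- simulate_dataset("AMR", m = 40, n_eur = 300, n_ddp = 120, seed = 1)
#' summary(d)
simulate_dataset <- function(ddp = "AMR", m = 500, n_eur = 10000,
                             n_ddp = 2000, h2 = 0.5, r = 0.5,
                             case_control_ratio = "1:1", seed = 1L,
                             divergence = NULL, truncate = TRUE,
                             clinical = NULL) {
  ddp <- match.arg(ddp, setdiff(populations(), "EUR"))
  targets <- reference_distances(m)
  if (is.null(divergence))
    divergence <- calibrate_divergence(targets[[ddp]], m,
                                       seed = derive_seed(seed, "calibrate"))
  div <- c(divergence); names(div) <- ddp
  profiles <- simulate_frequency_profiles(m, div, seed = seed)
  em <- effect_model(m, distances = targets[c("AMR", ddp)], r = r, h2 = h2,
                     seed = seed, truncate = truncate)
  n_per_pop <- c(EUR = n_eur, n_ddp); names(n_per_pop)[2] <- ddp
  build_dataset(profiles, em, n_per_pop, case_control_ratio, seed = seed,
                truncate = truncate, clinical = clinical)
}

#' @export
print.ma_dataset <- function(x, ...) {
  cat("<ma_dataset> ", nrow(x$X), " individuals x ", ncol(x$X), " features\n",
      sep = "")
  tab <- table(x$ancestry, x$y)
  print(tab)
  cat("rho:", paste(names(x$effects$rho), round(x$effects$rho, 2),
                    sep = "=", collapse = ", "),
      " h2:", x$effects$h2, " ratio:", x$case_control_ratio, "\n")
  invisible(x)
}

#' @export
summary.ma_dataset <- function(object, ...) {
  df <- data.frame(ancestry = object$ancestry, y = object$y,
                   split = object$split)
  out <- aggregate(y ~ ancestry + split, df,
                   FUN = function(v) c(n = length(v), cases = sum(v)))
  out <- cbind(out[c("ancestry", "split")], as.data.frame(out$y))
  out[order(out$ancestry, out$split), ]
}

# subset helper: feature matrix/labels for a population and split
# (population NULL = all). Used by every scheme; validation/test labels are
# only read at evaluation time by callers.
dataset_part <- function(data, population = NULL, split = NULL) {
  keep <- rep(TRUE, length(data$y))
  if (!is.null(population)) keep <- keep & data$ancestry %in% population
  if (!is.null(split)) keep <- keep & data$split %in% split
  list(X = data$X[keep, , drop = FALSE], y = data$y[keep])
}
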