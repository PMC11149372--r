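# Genotype quality control: per-SNP missingness/MAF/Hardy-Weinberg filters,
# per-sample missingness filter, windowed greedy LD pruning, and ANOVA-F
# feature ranking. All computations accept missing dosages (NA) and use
# pairwise-complete observations.

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact two-sided HWE test for a biallelic SNP (Wigginton-style): the
#' p-value is the total probability, under the conditional distribution of
#' heterozygote counts given the allele counts, of all genotype
#' configurations no more probable than the observed one. A chi-square
#' (1 d.f.) goodness-of-fit alternative is available.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts.
#' @param method `"exact"` (default) or `"chisq"`.
#' @return p-value in `(0, 1]`.
#' @export
#' @examples
#' hwe_test(25, 50, 25)          # perfect HWE proportions
#' hwe_test(0, 100, 0) < 1e-5    # all-heterozygote column fails
hwe_test <- function(n_hom_ref, n_het, n_hom_alt,
                     method = c("exact", "chisq")) {
  method <- match.arg(method)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0) return(NA_real_)
  if (method == "chisq") {
    p <- (2 * n_hom_ref + n_het) / (2 * n)
    expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    if (any(expd == 0)) return(1)
    x2 <- sum((c(n_hom_ref, n_het, n_hom_alt) - expd)^2 / expd)
    return(pmax(stats::pchisq(x2, 1, lower.tail = FALSE), .Machine$double.xmin))
  }
  # rare allele count and feasible heterozygote counts (same parity)
  n_rare <- 2 * min(n_hom_ref, n_hom_alt) + n_het
  het_obs <- n_het
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  # unnormalized probabilities via the recurrence
  # P(h+2)/P(h) = [ (nr-h)(2n-nr-h) ] / [ (h+2)(h+1)/4 * 4 ] -- computed in log
  logp <- numeric(length(hets))
  for (i in seq_along(hets)) {
    h <- hets[i]
    hom_rare <- (n_rare - h) / 2
    hom_common <- n - h - hom_rare
    logp[i] <- lgamma(n + 1) - lgamma(hom_rare + 1) - lgamma(h + 1) -
      lgamma(hom_common + 1) + h * log(2) +
      lgamma(n_rare + 1) + lgamma(2 * n - n_rare + 1) - lgamma(2 * n + 1)
  }
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  p_obs <- prob[match(het_obs, hets)]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-9)]))
}

#' Per-SNP quality-control filter
#'
#' Flags SNPs for removal when the missing rate exceeds `missing_max`
#' (strict `>`), the minor allele frequency falls below `maf_min`
#' (strict `<`), or the Hardy-Weinberg exact-test p-value falls below
#' `hwe_p_min` (strict `<`). An all-missing SNP is always dropped. The HWE
#' test is computed on all samples by default; `hwe_sample = "controls"`
#' restricts it to controls (requires `y`).
#'
#' @param X Dosage matrix with entries in `{0, 1, 2, NA}`.
#' @param missing_max,maf_min,hwe_p_min Thresholds (defaults 0.20, 0.05,
#'   1e-5; pass `hwe_p_min = 1e-4` for the stricter synthetic-source rule).
#' @param hwe_method `"exact"` or `"chisq"` (see [hwe_test()]).
#' @param hwe_sample `"all"` or `"controls"`.
#' @param y Labels, required for `hwe_sample = "controls"`.
#' @return Data frame of class `snp_qc_report`: per-SNP `missing_rate`,
#'   `maf`, `hwe_p`, `kept`, `reason` (NA when kept).
#' @export
qc_filter <- function(X, missing_max = 0.20, maf_min = 0.05,
                      hwe_p_min = 1e-5, hwe_method = c("exact", "chisq"),
                      hwe_sample = c("all", "controls"), y = NULL) {
  hwe_method <- match.arg(hwe_method)
  hwe_sample <- match.arg(hwe_sample)
  vals <- X[!is.na(X)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    stop("dosages must be 0, 1, 2 or NA")
  Xh <- X
  if (hwe_sample == "controls") {
    if (is.null(y)) stop("hwe_sample='controls' requires y")
    Xh <- X[y == 0, , drop = FALSE]
  }
  m <- ncol(X)
  rep_df <- data.frame(
    snp = if (!is.null(colnames(X))) colnames(X) else paste0("snp", seq_len(m)),
    missing_rate = NA_real_, maf = NA_real_, hwe_p = NA_real_,
    kept = FALSE, reason = NA_character_, stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    x <- X[, j]
    miss <- mean(is.na(x))
    rep_df$missing_rate[j] <- miss
    if (miss == 1) { rep_df$reason[j] <- "all_missing"; next }
    x_ok <- x[!is.na(x)]
    p_allele <- mean(x_ok) / 2
    maf <- min(p_allele, 1 - p_allele)
    rep_df$maf[j] <- maf
    xh <- Xh[, j]; xh <- xh[!is.na(xh)]
    hwe <- if (length(xh)) hwe_test(sum(xh == 0), sum(xh == 1), sum(xh == 2),
                                    method = hwe_method) else NA_real_
    rep_df$hwe_p[j] <- hwe
    if (miss > missing_max) rep_df$reason[j] <- "missing_rate"
    else if (maf < maf_min) rep_df$reason[j] <- "maf"
    else if (!is.na(hwe) && hwe < hwe_p_min) rep_df$reason[j] <- "hwe"
    else rep_df$kept[j] <- TRUE
  }
  class(rep_df) <- c("snp_qc_report", "data.frame")
  rep_df
}

#' @export
print.snp_qc_report <- function(x, ...) {
  cat("<snp_qc_report> ", nrow(x), " SNPs, ", sum(x$kept), " kept\n", sep = "")
  if (any(!x$kept)) print(table(dropped = x$reason[!x$kept]))
  invisible(x)
}

#' Write a QC report as tab-separated text
#' @param report A `snp_qc_report`.
#' @param path Output path.
#' @export
write_qc_report <- function(report, path) {
  write.table(report, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Per-sample missingness filter
#'
#' Removes individuals whose fraction of missing dosages is strictly greater
#' than `missing_max`.
#'
#' @param X Dosage matrix.
#' @param missing_max Threshold (default 0.20; a row exactly at the threshold
#'   is kept).
#' @return Logical keep mask over rows.
#' @export
sample_filter <- function(X, missing_max = 0.20) {
  keep <- rowMeans(is.na(X)) <= missing_max
  if (!any(keep)) stop("sample filter removed every individual")
  keep
}

#' Greedy windowed LD pruning
#'
#' Slides a window of `window` SNPs with step `step` along the SNP order.
#' Within each window position, pairs of retained SNPs with squared Pearson
#' correlation (pairwise-complete) above `r2_max` are pruned greedily: pairs
#' are scanned in index order, the member with the higher association p-value
#' is dropped (the later-ordered member when p-values are absent or tied),
#' and the scan restarts until the window is clean.
#'
#' @param X Dosage matrix; columns carry the linear SNP order.
#' @param window Window size in SNPs (>= 2).
#' @param step Step length in SNPs.
#' @param r2_max Squared-correlation cut-off.
#' @param p_values Optional per-SNP association p-values driving the
#'   retention rule.
#' @return Logical keep mask over columns.
#' @export
ld_prune <- function(X, window = 50, step = 5, r2_max = 0.2,
                     p_values = NULL) {
  m <- ncol(X)
  if (window < 2) stop("window must be >= 2")
  if (!is.null(p_values) && length(p_values) != m)
    stop("p_values length must match SNP count")
  keep <- rep(TRUE, m)
  starts <- seq(1L, m, by = step)
  for (s in starts) {
    win <- s:min(s + window - 1L, m)
    repeat {
      idx <- win[keep[win]]
      if (length(idx) < 2) break
      r2 <- suppressWarnings(cor(X[, idx, drop = FALSE],
                                 use = "pairwise.complete.obs"))^2
      r2[!is.finite(r2)] <- 0
      dropped <- FALSE
      for (a in seq_len(length(idx) - 1L)) {
        for (b in (a + 1L):length(idx)) {
          if (r2[a, b] > r2_max) {
            i <- idx[a]; j <- idx[b]
            drop <- if (!is.null(p_values) && !isTRUE(all.equal(p_values[i],
                                                                p_values[j]))) {
              if (p_values[i] > p_values[j]) i else j
            } else j
            keep[drop] <- FALSE
            dropped <- TRUE
            break
          }
        }
        if (dropped) break
      }
      if (!dropped) break
    }
  }
  keep
}

# vectorized one-way (two-group) ANOVA F per column, pairwise-complete
anova_f_columns <- function(X, y) {
  stats_j <- function(x) {
    ok <- !is.na(x)
    x <- x[ok]; g <- y[ok]
    n1 <- sum(g == 1); n0 <- sum(g == 0); n <- n1 + n0
    if (n1 < 2 || n0 < 2) return(c(NA_real_, NA_real_))
    m1 <- mean(x[g == 1]); m0 <- mean(x[g == 0]); mm <- mean(x)
    ssb <- n1 * (m1 - mm)^2 + n0 * (m0 - mm)^2
    ssw <- sum((x[g == 1] - m1)^2) + sum((x[g == 0] - m0)^2)
    if (ssw == 0) {
      if (ssb == 0) return(c(0, 1))      # constant column
      return(c(Inf, 0))
    }
    f <- ssb / (ssw / (n - 2))
    c(f, stats::pf(f, 1, n - 2, lower.tail = FALSE))
  }
  t(apply(X, 2, stats_j))
}

#' ANOVA-F feature ranking and top-K selection
#'
#' Computes the one-way ANOVA F statistic between cases and controls for each
#' feature column of the *training* data (never the validation or test
#' splits, to prevent information leakage), ranks features by decreasing F
#' (ties broken by lower column index), and selects the top `K`.
#'
#' @param X_train Feature matrix (training split).
#' @param y_train 0/1 labels (training split).
#' @param K Number of features to select.
#' @return Data frame of class `feature_ranking`: per-feature `f_stat`,
#'   `p_value`, `rank`, `selected`.
#' @export
rank_and_select <- function(X_train, y_train, K) {
  if (length(unique(y_train[!is.na(y_train)])) < 2)
    stop("training data contain a single class")
  if (min(table(y_train)) < 2)
    stop("need at least 2 individuals per class")
  fp <- anova_f_columns(X_train, y_train)
  f <- fp[, 1]
  ord <- order(-f, seq_along(f))   # ties -> lower index first
  rank_v <- integer(length(f)); rank_v[ord] <- seq_along(f)
  k_eff <- min(K, sum(!is.na(f)))
  out <- data.frame(
    feature = if (!is.null(colnames(X_train))) colnames(X_train)
              else paste0("snp", seq_along(f)),
    f_stat = f, p_value = fp[, 2], rank = rank_v,
    selected = rank_v <= k_eff, stringsAsFactors = FALSE)
  class(out) <- c("feature_ranking", "data.frame")
  out
}
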