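# Disparity detection and mitigation statistics: the EUR-DDP performance gap
# G, transfer-learning improvements I over the DDP baselines, the DL-vs-LR
# transfer difference D, and the associated one-sided Wilcoxon tests.

#' One-sided Wilcoxon tests over replicate runs
#'
#' `wilcoxon_rank_sum` compares two independent run vectors; the p-value is
#' exact (enumeration) when both groups have at most 12 observations and no
#' ties occur, and otherwise uses the normal approximation with tie and
#' continuity correction. `wilcoxon_signed_rank` is the paired analogue used
#' across matched datasets.
#'
#' @param x,y Numeric vectors (e.g. per-run AUROCs).
#' @param alternative `"greater"` (default), `"less"`, or `"two.sided"`;
#'   `"greater"` tests whether `x` tends to exceed `y`.
#' @return The p-value.
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = "greater") {
  use_exact <- length(x) <= 12 && length(y) <= 12 &&
    !any(duplicated(c(x, y)))
  suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = use_exact,
                correct = TRUE)$p.value)
}

#' @rdname wilcoxon_rank_sum
#' @export
wilcoxon_signed_rank <- function(x, y, alternative = "greater") {
  if (length(x) != length(y)) stop("paired test needs equal lengths")
  d <- x - y
  use_exact <- length(d) <= 12 && !any(d == 0) && !any(duplicated(abs(d)))
  suppressWarnings(
    wilcox.test(x, y, paired = TRUE, alternative = alternative,
                exact = use_exact, correct = TRUE)$p.value)
}

#' Disparity summary over replicate runs
#'
#' Given per-run test AUROCs, computes the performance disparity gap
#' `G = mean(AUROC_EUR) - mean(AUROC_DDP)`, the transfer-learning
#' improvements `I = mean(AUROC_TL) - mean(AUROC_baseline)` for each supplied
#' DDP baseline (e.g. Mix2, Ind2, NT), and -- when both transfer variants are
#' supplied -- the difference `D = mean(AUROC_TL_DL) - mean(AUROC_TL_LR)`.
#' Each difference carries a one-sided Wilcoxon rank-sum p-value across runs
#' (gap: EUR > DDP; improvements: TL > baseline; D: DL > LR).
#'
#' @param auroc_eur,auroc_ddp Per-run AUROCs of the EUR- and DDP-facing
#'   evaluations of one experiment (for `G`).
#' @param tl Per-run AUROCs of the transfer-learning experiment (for `I`).
#' @param baselines Named list of per-run AUROC vectors (for `I`).
#' @param tl_dl,tl_lr Per-run AUROCs of the two transfer variants (for `D`).
#' @return Object of class `eqg_disparity`: `G`, `p_G`, data frame
#'   `improvements`, `D`, `p_D`.
#' @export
disparity_stats <- function(auroc_eur = NULL, auroc_ddp = NULL, tl = NULL,
                            baselines = list(), tl_dl = NULL, tl_lr = NULL) {
  out <- list(G = NA_real_, p_G = NA_real_, improvements = NULL,
              D = NA_real_, p_D = NA_real_)
  if (!is.null(auroc_eur) && !is.null(auroc_ddp)) {
    out$G <- mean(auroc_eur) - mean(auroc_ddp)
    out$p_G <- wilcoxon_rank_sum(auroc_eur, auroc_ddp, "greater")
  }
  if (!is.null(tl) && length(baselines)) {
    out$improvements <- data.frame(
      baseline = names(baselines),
      I = vapply(baselines, function(b) mean(tl) - mean(b), numeric(1)),
      p = vapply(baselines, function(b) wilcoxon_rank_sum(tl, b, "greater"),
                 numeric(1)),
      row.names = NULL)
  }
  if (!is.null(tl_dl) && !is.null(tl_lr)) {
    out$D <- mean(tl_dl) - mean(tl_lr)
    out$p_D <- wilcoxon_rank_sum(tl_dl, tl_lr, "greater")
  }
  class(out) <- "eqg_disparity"
  out
}

#' @export
print.eqg_disparity <- function(x, ...) {
  cat("<eqg_disparity>\n")
  if (!is.na(x$G))
    cat("  gap G (EUR - DDP): ", round(x$G, 3), " (p = ",
        format(x$p_G, digits = 3), ")\n", sep = "")
  if (!is.null(x$improvements)) {
    cat("  transfer improvements:\n")
    print(cbind(x$improvements[1],
                I = round(x$improvements$I, 3),
                p = signif(x$improvements$p, 3)))
  }
  if (!is.na(x$D))
    cat("  D (TL_DL - TL_LR): ", round(x$D, 3), " (p = ",
        format(x$p_D, digits = 3), ")\n", sep = "")
  invisible(x)
}
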