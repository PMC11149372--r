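# The seven multi-ancestral learning-scheme experiments, replicated over
# runs, for both predictor kinds. Data splits stay frozen across runs; run-
# to-run variation comes from model initialization, batch order and dropout
# (the logistic fits are deterministic given the data, so their runs
# coincide). The EUR-facing models never depend on whether transfer
# experiments are requested.

#' Names and composition of the experiment schemes
#'
#' `scheme_names()` lists the seven experiments; `scheme_table()` gives
#' their training/testing ancestry composition: the three mixture
#' experiments share one model trained on pooled EUR + DDP data evaluated on
#' the combined, EUR-only and DDP-only test subsets; independent learning
#' trains and tests within one population; naive transfer applies the
#' EUR-trained model to the DDP unchanged; transfer learning pretrains on
#' EUR and adapts on DDP training/validation data.
#'
#' @return `scheme_names()`: character vector. `scheme_table()`: data frame
#'   with `scheme`, `training`, `testing`.
#' @export
scheme_names <- function() c("Mix0", "Mix1", "Mix2", "Ind1", "Ind2", "NT", "TL")

#' @rdname scheme_names
#' @export
scheme_table <- function() {
  data.frame(
    scheme = scheme_names(),
    training = c("EUR + DDP", "EUR + DDP", "EUR + DDP", "EUR", "DDP",
                 "EUR", "EUR (source), DDP (target)"),
    testing = c("EUR + DDP", "EUR", "DDP", "EUR", "DDP", "DDP", "DDP"))
}

# which base model a scheme evaluates, and on which population's test split
scheme_plan <- function(ddp) {
  list(Mix0 = list(model = "mix", pop = c("EUR", ddp)),
       Mix1 = list(model = "mix", pop = "EUR"),
       Mix2 = list(model = "mix", pop = ddp),
       Ind1 = list(model = "eur", pop = "EUR"),
       Ind2 = list(model = "ddp", pop = ddp),
       NT   = list(model = "eur", pop = ddp),
       TL   = list(model = "tl",  pop = ddp))
}

#' Run the learning-scheme experiments on a dataset
#'
#' Executes the requested schemes for each model kind over `n_runs`
#' replicate runs and evaluates every run on the scheme's test subset with
#' the full metric panel. Per run, at most four base fits are made and
#' shared: the pooled mixture model (evaluated by Mix0/Mix1/Mix2), the
#' EUR-only model (Ind1 and NT, and the source model for TL), the DDP-only
#' model (Ind2), and the transferred model (TL). Training and threshold
#' selection never touch test labels; the Youden threshold is chosen on the
#' evaluated population's validation split and applied to its test split.
#'
#' @param data An `ma_dataset` with exactly two populations.
#' @param models Character subset of `c("LR", "DL")`.
#' @param schemes Character subset of [scheme_names()].
#' @param n_runs Replicate runs (default 20).
#' @param seed Master seed; per-run fit seeds are derived from it.
#' @param dnn A [dnn_config()] used for every DL fit (its `seed` field is
#'   overridden per run).
#' @param lr_l2 L2 strength of the logistic fits.
#' @param tl_penalty_grid Penalty grid for the linear transfer fit.
#' @param prevalence Optional named vector of per-population disease
#'   prevalences for adjusted PPV/NPV.
#' @param threshold_on `"validation"` (default) or `"test"`:
#'   where the Youden threshold is selected.
#' @param keep_scores Also return the raw per-run test scores (used for
#'   reproducibility audits).
#' @return Object of class `eqg_runs`: a data frame of per-run, per-scheme
#'   metric rows with the run configuration attached as attributes.
#' @export
#' @examples
#' d <- make_fixture("tiny", seed = 1)
#' r <- run_experiments(d, models = "LR", schemes = c("Ind1", "Ind2"),
#'                      n_runs = 2, seed = 1)
#' summary(r)
run_experiments <- function(data, models = c("LR", "DL"),
                            schemes = scheme_names(), n_runs = 20, seed = 1,
                            dnn = dnn_config(), lr_l2 = 1,
                            tl_penalty_grid = 10^seq(-1, 4),
                            prevalence = NULL,
                            threshold_on = c("validation", "test"),
                            keep_scores = FALSE) {
  stopifnot(inherits(data, "ma_dataset"))
  threshold_on <- match.arg(threshold_on)
  models <- match.arg(models, c("LR", "DL"), several.ok = TRUE)
  schemes <- match.arg(schemes, scheme_names(), several.ok = TRUE)
  pops <- levels(data$ancestry)
  if (length(pops) != 2) stop("run_experiments expects exactly two populations")
  ddp <- setdiff(pops, "EUR")
  plan <- scheme_plan(ddp)[schemes]
  roles <- unique(vapply(plan, `[[`, "", "model"))
  if ("tl" %in% roles) roles <- union(roles, "eur")

  # frozen split subsets
  role_pop <- list(mix = pops, eur = "EUR", ddp = ddp)
  tr <- lapply(role_pop, function(p) dataset_part(data, p, "train"))
  va <- lapply(role_pop, function(p) dataset_part(data, p, "validation"))
  for (sc in schemes) {
    pop <- plan[[sc]]$pop
    if (!sum(data$split == "test" & data$ancestry %in% pop))
      stop("empty test subset for scheme ", sc)
  }

  rows <- list()
  scores_out <- list()
  lr_cache <- new.env(parent = emptyenv())

  fit_role <- function(role, kind, run) {
    if (kind == "LR") {
      key <- role
      if (!is.null(lr_cache[[key]])) return(lr_cache[[key]])
      fit <- if (role == "tl") {
        src <- fit_role("eur", "LR", run)
        fit_linear_transfer(src, tr$ddp$X, tr$ddp$y, penalty = NULL,
                            X_val = va$ddp$X, y_val = va$ddp$y,
                            penalty_grid = tl_penalty_grid)
      } else {
        train_lr(tr[[role]]$X, tr[[role]]$y, l2_strength = lr_l2)
      }
      lr_cache[[key]] <- fit
      return(fit)
    }
    cfg <- dnn
    cfg$seed <- derive_seed(seed, paste0("dl-", role), run)
    if (role == "tl") {
      src <- fit_role("eur", "DL", run)
      fine_tune_dnn(src, tr$ddp$X, tr$ddp$y, va$ddp$X, va$ddp$y,
                    config = cfg)
    } else {
      train_dnn(tr[[role]]$X, tr[[role]]$y, va[[role]]$X, va[[role]]$y,
                config = cfg)
    }
  }

  for (kind in models) {
    for (run in seq_len(n_runs)) {
      fits <- list()
      for (role in roles) fits[[role]] <- fit_role(role, kind, run)
      for (sc in schemes) {
        role <- plan[[sc]]$model
        pop <- plan[[sc]]$pop
        model <- fits[[role]]
        te <- dataset_part(data, pop, "test")
        scores <- predict(model, te$X)
        if (threshold_on == "validation") {
          vp <- dataset_part(data, pop, "validation")
          thr_scores <- predict(model, vp$X); thr_labels <- vp$y
        } else {
          thr_scores <- scores; thr_labels <- te$y
        }
        prev <- if (!is.null(prevalence) && length(pop) == 1)
          unname(prevalence[pop]) else NULL
        rep_m <- metric_report(scores, te$y, thr_scores, thr_labels,
                               prevalence = prev)
        rows[[length(rows) + 1L]] <- data.frame(
          run = run, model = kind, scheme = sc,
          population = paste(pop, collapse = "+"),
          auroc = rep_m$auroc, aupr = rep_m$aupr, tjur_r2 = rep_m$tjur_r2,
          youden_threshold = rep_m$youden_threshold,
          sensitivity = rep_m$sensitivity, specificity = rep_m$specificity,
          ppv = rep_m$ppv, npv = rep_m$npv,
          adjusted_ppv = rep_m$adjusted_ppv,
          adjusted_npv = rep_m$adjusted_npv,
          stringsAsFactors = FALSE)
        if (keep_scores)
          scores_out[[paste(kind, sc, run, sep = ".")]] <- scores
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- list(ddp = ddp, models = models, schemes = schemes,
                              n_runs = n_runs, seed = seed,
                              threshold_on = threshold_on,
                              dataset_seed = data$seed,
                              h2 = data$effects$h2, rho = data$effects$rho,
                              case_control_ratio = data$case_control_ratio)
  if (keep_scores) attr(out, "scores") <- scores_out
  class(out) <- c("eqg_runs", "data.frame")
  out
}

#' @export
summary.eqg_runs <- function(object, metric = "auroc", ...) {
  agg <- aggregate(object[[metric]],
                   by = list(model = object$model, scheme = object$scheme,
                             population = object$population),
                   FUN = mean)
  names(agg)[4] <- paste0("mean_", metric)
  agg$scheme <- factor(agg$scheme, levels = scheme_names())
  agg[order(agg$model, agg$scheme), ]
}

#' @export
print.eqg_runs <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("<eqg_runs> ", cfg$n_runs, " runs x {",
      paste(cfg$models, collapse = ","), "} x {",
      paste(cfg$schemes, collapse = ","), "}, DDP = ", cfg$ddp, "\n",
      sep = "")
  print(summary(x))
  invisible(x)
}

#' Definition of the synthetic-dataset compendium
#'
#' Sixteen dataset configurations: the four DDPs crossed with heritability
#' 0.5/0.25 at decay exponent r = 0.5 (datasets 1-8) and r = 1.0 (datasets
#' 9-16), with the effect-size correlation implied by the printed genetic
#' distances. Datasets 9 and 13 coincide with 1 and 5 because r does not
#' change the correlation at the reference distance. `case_control_ratio`
#' "1:1" gives the SD compendium, "1:4" the SD* compendium. `m`, `n_eur`,
#' `n_ddp` may be reduced for scaled-down analogues (distance targets scale
#' with `m`, so `rho` is unchanged).
#'
#' @param case_control_ratio `"1:1"` or `"1:4"`.
#' @param m,n_eur,n_ddp Dataset dimensions (defaults: the full study sizes).
#' @param ids Subset of dataset indices 1..16 (default all).
#' @return Data frame with one row per dataset: `id`, `ddp`, `h2`, `r`,
#'   `rho`, sizes and ratio.
#' @export
#' @examples
#' sd_compendium(ids = 1:4)[, c("id", "ddp", "h2", "rho")]
sd_compendium <- function(case_control_ratio = "1:1", m = 500,
                          n_eur = 10000, n_ddp = 2000, ids = 1:16) {
  ddps <- c("AMR", "SAS", "EAS", "AFR")
  grid <- expand.grid(ddp = ddps, h2 = c(0.5, 0.25), r = c(0.5, 1.0),
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$r, -grid$h2), ]
  grid$id <- paste0("SD", 1:16,
                    if (identical(case_fraction(case_control_ratio), 0.5)) ""
                    else "*")
  d <- reference_distances(m)
  grid$rho <- mapply(function(ddp, r) rho_schedule(d[["AMR"]], d[[ddp]],
                                                   rho0 = 0.8, r = r),
                     grid$ddp, grid$r)
  grid$m <- m; grid$n_eur <- n_eur; grid$n_ddp <- n_ddp
  grid$case_control_ratio <- case_control_ratio
  rownames(grid) <- NULL
  grid[grid$id %in% grid$id[ids],
       c("id", "ddp", "h2", "r", "rho", "m", "n_eur", "n_ddp",
         "case_control_ratio")]
}

#' Run the experiments over a compendium of dataset configurations
#'
#' Simulates each configured dataset and runs [run_experiments()] on it.
#' Divergence calibration is cached per (DDP, m) since the distance targets
#' do not depend on heritability or ratio.
#'
#' @param configs Data frame as returned by [sd_compendium()] (any subset of
#'   rows).
#' @param ... Passed on to [run_experiments()] (`models`, `schemes`,
#'   `n_runs`, `dnn`, ...).
#' @param seed Master seed covering both simulation and runs.
#' @return Object of class `eqg_compendium`: named list of `eqg_runs`, with
#'   the config table attached.
#' @export
run_compendium <- function(configs, ..., seed = 1) {
  div_cache <- list()
  out <- vector("list", nrow(configs))
  names(out) <- configs$id
  for (i in seq_len(nrow(configs))) {
    cf <- configs[i, ]
    key <- paste(cf$ddp, cf$m)
    if (is.null(div_cache[[key]]))
      div_cache[[key]] <- calibrate_divergence(
        reference_distances(cf$m)[[cf$ddp]], cf$m,
        seed = derive_seed(seed, paste0("cal-", cf$ddp)))
    data <- simulate_dataset(cf$ddp, m = cf$m, n_eur = cf$n_eur,
                             n_ddp = cf$n_ddp, h2 = cf$h2, r = cf$r,
                             case_control_ratio = cf$case_control_ratio,
                             seed = derive_seed(seed, paste0("data-", cf$id)),
                             divergence = div_cache[[key]])
    out[[i]] <- run_experiments(data, ...,
                                seed = derive_seed(seed, paste0("runs-", cf$id)))
  }
  structure(out, configs = configs, class = "eqg_compendium")
}

#' @export
print.eqg_compendium <- function(x, ...) {
  cat("<eqg_compendium> ", length(x), " datasets\n", sep = "")
  print(report_performance(x))
  invisible(x)
}

#' Per-dataset performance table (compendium layout)
#'
#' One row per dataset with its DDP, heritability and rho, and one column
#' per scheme holding the run-mean test AUROC formatted as "LR, DL" (or a
#' single number when only one model kind was run).
#'
#' @param compendium An `eqg_compendium`.
#' @param metric Metric column to summarize (default `"auroc"`).
#' @param digits Rounding for the formatted cells.
#' @return Data frame.
#' @export
report_performance <- function(compendium, metric = "auroc", digits = 2) {
  configs <- attr(compendium, "configs")
  rows <- lapply(seq_along(compendium), function(i) {
    runs <- compendium[[i]]
    agg <- aggregate(runs[[metric]],
                     by = list(model = runs$model, scheme = runs$scheme),
                     FUN = mean)
    schemes <- intersect(scheme_names(), unique(agg$scheme))
    cells <- vapply(schemes, function(sc) {
      v <- agg$x[agg$scheme == sc][order(match(agg$model[agg$scheme == sc],
                                               c("LR", "DL")))]
      paste(formatC(round(v, digits), format = "f", digits = digits),
            collapse = ", ")
    }, character(1))
    cbind(configs[i, c("id", "ddp", "h2", "rho")],
          as.data.frame(as.list(cells), stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$rho <- round(out$rho, 2)
  out
}

# the eleven standard comparisons of the disparity analysis
comparison_table <- function() {
  data.frame(
    comparison = c("Mix1_LR vs Mix2_LR", "Mix1_DL vs Mix2_DL",
                   "Ind1_LR vs Ind2_LR", "Ind1_DL vs Ind2_DL",
                   "TL_DL vs Mix2_DL", "TL_DL vs Ind2_DL", "TL_DL vs NT_DL",
                   "TL_LR vs Mix2_LR", "TL_LR vs Ind2_LR", "TL_LR vs NT_LR",
                   "TL_DL vs TL_LR"),
    scheme_a = c("Mix1", "Mix1", "Ind1", "Ind1", "TL", "TL", "TL",
                 "TL", "TL", "TL", "TL"),
    model_a = c("LR", "DL", "LR", "DL", "DL", "DL", "DL", "LR", "LR", "LR",
                "DL"),
    scheme_b = c("Mix2", "Mix2", "Ind2", "Ind2", "Mix2", "Ind2", "NT",
                 "Mix2", "Ind2", "NT", "TL"),
    model_b = c("LR", "DL", "LR", "DL", "DL", "DL", "DL", "LR", "LR", "LR",
                "LR"),
    stringsAsFactors = FALSE)
}

#' Disparity-comparison table over a compendium
#'
#' For each standard comparison (disparity gaps Mix1 vs Mix2 and Ind1 vs
#' Ind2 per model kind; transfer improvements over Mix2/Ind2/NT; DL-vs-LR
#' transfer difference), computes the per-dataset difference of run-mean
#' AUROCs, averages it across datasets, and attaches a one-sided Wilcoxon
#' signed-rank p-value across the matched datasets.
#'
#' @param compendium An `eqg_compendium`.
#' @param metric Metric to compare (default `"auroc"`).
#' @param alpha Significance level for the `significant` flag.
#' @return Data frame with `comparison`, `mean_diff`, `p`, `significant`.
#' @export
report_comparisons <- function(compendium, metric = "auroc", alpha = 0.05) {
  cmp <- comparison_table()
  run_mean <- function(runs, scheme, model) {
    v <- runs[[metric]][runs$scheme == scheme & runs$model == model]
    if (!length(v)) NA_real_ else mean(v)
  }
  res <- lapply(seq_len(nrow(cmp)), function(i) {
    a <- vapply(compendium, run_mean, numeric(1),
                scheme = cmp$scheme_a[i], model = cmp$model_a[i])
    b <- vapply(compendium, run_mean, numeric(1),
                scheme = cmp$scheme_b[i], model = cmp$model_b[i])
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) return(NULL)
    p <- if (sum(ok) >= 2) wilcoxon_signed_rank(a[ok], b[ok], "greater")
         else NA_real_
    data.frame(comparison = cmp$comparison[i],
               mean_diff = mean(a[ok] - b[ok]), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) return(out)
  out$significant <- !is.na(out$p) & out$p < alpha
  rownames(out) <- NULL
  out
}

#' Deterministic toy dataset exercising the whole pipeline
#'
#' `"tiny"`: 200 EUR + 60 AMR individuals, 20 SNPs -- every downstream stage
#' (QC, both predictors, all seven schemes) runs in seconds. `"small"`:
#' 1000 EUR + 300 AMR, 100 SNPs.
#'
#' @param size `"tiny"` or `"small"`.
#' @param seed Integer seed (same seed, identical fixture).
#' @return An `ma_dataset`.
#' @export
make_fixture <- function(size = c("tiny", "small"), seed = 1L) {
  size <- match.arg(size)
  if (size == "tiny")
    simulate_dataset("AMR", m = 20, n_eur = 200, n_ddp = 60, h2 = 0.5,
                     r = 0.5, seed = seed)
  else
    simulate_dataset("AMR", m = 100, n_eur = 1000, n_ddp = 300, h2 = 0.5,
                     r = 0.5, seed = seed)
}

#' Persist and summarize experiment runs
#'
#' `save_runs()` writes one metrics CSV per dataset plus a YAML manifest of
#' the configurations and seeds (sufficient to reproduce the session
#' byte-identically); `report_runs()` reads a directory written that way and
#' rebuilds the performance and comparison tables.
#'
#' @param compendium An `eqg_compendium`.
#' @param dir Output directory (created if needed).
#' @return `save_runs()`: the directory, invisibly. `report_runs()`: list
#'   with `performance`, `comparisons`, `manifest`.
#' @export
save_runs <- function(compendium, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  configs <- attr(compendium, "configs")
  for (i in seq_along(compendium)) {
    id <- names(compendium)[i]
    write.csv(as.data.frame(compendium[[i]]),
              file.path(dir, paste0(gsub("\\*", "star", id), "_metrics.csv")),
              row.names = FALSE)
  }
  manifest <- list(datasets = lapply(seq_len(nrow(configs)), function(i)
    as.list(configs[i, ])),
    run_config = lapply(compendium, attr, "config"))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname save_runs
#' @export
report_runs <- function(dir) {
  manifest_path <- file.path(dir, "manifest.yaml")
  files <- list.files(dir, pattern = "_metrics\\.csv$", full.names = TRUE)
  if (!file.exists(manifest_path) || !length(files))
    stop("no runs found in ", dir)
  manifest <- yaml::read_yaml(manifest_path)
  configs <- do.call(rbind, lapply(manifest$datasets, as.data.frame))
  runs <- lapply(files, read.csv, stringsAsFactors = FALSE)
  ids <- sub("_metrics\\.csv$", "", basename(files))
  ids <- sub("star$", "*", ids)
  names(runs) <- ids
  runs <- runs[match(configs$id, names(runs))]
  runs <- lapply(runs, function(r) { class(r) <- c("eqg_runs", "data.frame"); r })
  comp <- structure(runs, configs = configs, class = "eqg_compendium")
  list(performance = report_performance(comp),
       comparisons = report_comparisons(comp),
       manifest = manifest)
}
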