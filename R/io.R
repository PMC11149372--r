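# Text interchange: an additively-coded dosage table (PLINK-raw-style
# dialect), truth sidecar files for simulated datasets, and YAML experiment
# configs.

#' Write a dataset as an additive dosage text table
#'
#' Writes `<basename>.raw` in a PLINK-raw-style dialect: a header row, then
#' one row per individual with family ID (the ancestry label), individual ID,
#' phenotype (0 control / 1 case), and the 0/1/2 dosage per SNP, whitespace
#' separated. For simulated datasets two tab-separated truth sidecars are
#' written as well: `<basename>.truth_snps.tsv` (per-SNP effect sizes `W` and
#' the shifted `W'` per DDP, with `h2`, `rho`, genetic distances and
#' thresholds in `#`-comment header lines) and
#' `<basename>.truth_individuals.tsv` (latent liability `g` and split per
#' individual).
#'
#' @param data An `ma_dataset`, or a list with at least `X`, `y`, `ancestry`.
#' @param basename Output path prefix.
#' @param truth Write the truth sidecars (default: yes for `ma_dataset`).
#' @return Invisibly, the paths written.
#' @export
write_raw <- function(data, basename, truth = inherits(data, "ma_dataset")) {
  X <- data$X
  iid <- sprintf("I%05d", seq_len(nrow(X)))
  tab <- data.frame(FID = as.character(data$ancestry), IID = iid,
                    PHENOTYPE = data$y, check.names = FALSE)
  tab <- cbind(tab, as.data.frame(X))
  raw_path <- paste0(basename, ".raw")
  write.table(tab, raw_path, quote = FALSE, row.names = FALSE, sep = " ")
  paths <- raw_path
  if (truth) {
    em <- data$effects
    snp_tab <- data.frame(snp = paste0("snp", seq_len(em$m)), W = em$W)
    for (pop in names(em$W_prime))
      snp_tab[[paste0("W_", pop)]] <- em$W_prime[[pop]]
    snp_path <- paste0(basename, ".truth_snps.tsv")
    hdr <- c(sprintf("# h2\t%.17g", em$h2),
             sprintf("# rho_%s\t%.17g", names(em$rho), em$rho),
             sprintf("# d_%s\t%.17g", names(em$distances), em$distances),
             sprintf("# thr_%s\t%.17g", names(data$thr), data$thr))
    writeLines(hdr, snp_path)
    suppressWarnings(write.table(snp_tab, snp_path, quote = FALSE, sep = "\t",
                                 row.names = FALSE, append = TRUE))
    ind_path <- paste0(basename, ".truth_individuals.tsv")
    write.table(data.frame(FID = as.character(data$ancestry), IID = iid,
                           g = data$g, split = data$split),
                ind_path, quote = FALSE, sep = "\t", row.names = FALSE)
    paths <- c(paths, snp_path, ind_path)
  }
  invisible(paths)
}

#' Read an additive dosage text table
#'
#' Reads the dialect written by [write_raw()] (and tolerates the extra
#' PAT/MAT/SEX columns of full PLINK `.raw` exports). Dosage columns are
#' everything after the ID/phenotype block; missing dosages may be coded `NA`.
#'
#' @param path Path to the `.raw` file.
#' @return List with `X` (numeric matrix), `y` (integer), `ancestry`
#'   (character, from FID).
#' @export
read_raw <- function(path) {
  tab <- read.table(path, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  id_cols <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"),
                       colnames(tab))
  if (!all(c("FID", "IID", "PHENOTYPE") %in% id_cols))
    stop("not a recognizable dosage table: needs FID, IID, PHENOTYPE columns")
  dosage <- setdiff(colnames(tab), id_cols)
  X <- as.matrix(tab[dosage])
  storage.mode(X) <- "double"
  y <- as.integer(tab$PHENOTYPE)
  # tolerate PLINK's 1/2 phenotype coding
  if (all(y %in% c(1L, 2L)) && any(y == 2L)) y <- y - 1L
  list(X = X, y = y, ancestry = tab$FID)
}

#' Experiment configuration
#'
#' A plain list capturing everything needed to reproduce a simulation +
#' experiment session: dataset parameters, schemes, model kinds, run count
#' and master seed. Round-trips losslessly through YAML via
#' [write_config()] / [read_config()].
#'
#' @param ddp,m,n_eur,n_ddp,h2,r,case_control_ratio Dataset parameters
#'   (see [simulate_dataset()]).
#' @param schemes Character vector of scheme names (see [run_experiments()]).
#' @param models Character vector among `"LR"`, `"DL"`.
#' @param n_runs Replicate runs per experiment.
#' @param seed Master seed.
#' @return Object of class `experiment_config` (a list).
#' @export
experiment_config <- function(ddp = "AMR", m = 500, n_eur = 10000,
                              n_ddp = 2000, h2 = 0.5, r = 0.5,
                              case_control_ratio = "1:1",
                              schemes = scheme_names(), models = c("LR", "DL"),
                              n_runs = 20, seed = 1) {
  structure(list(ddp = ddp, m = m, n_eur = n_eur, n_ddp = n_ddp, h2 = h2,
                 r = r, case_control_ratio = case_control_ratio,
                 schemes = schemes, models = models, n_runs = n_runs,
                 seed = seed),
            class = "experiment_config")
}

#' @rdname experiment_config
#' @param config An `experiment_config`.
#' @param path File path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname experiment_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(experiment_config, raw)
  cfg
}
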