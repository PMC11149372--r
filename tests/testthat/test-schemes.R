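# experiment orchestration: scheme composition, isolation, determinism

test_that("scheme table matches the seven-experiment design", {
  tab <- scheme_table()
  expect_equal(tab$scheme, c("Mix0", "Mix1", "Mix2", "Ind1", "Ind2", "NT",
                             "TL"))
  expect_equal(tab$training[tab$scheme == "NT"], "EUR")
  expect_equal(tab$testing[tab$scheme == "NT"], "DDP")
})

test_that("all seven schemes run on the tiny fixture", {
  d <- tiny_dataset(seed = 3)
  r <- run_experiments(d, models = "LR", n_runs = 2, seed = 5)
  expect_s3_class(r, "eqg_runs")
  expect_equal(nrow(r), 2 * 7)
  expect_true(all(r$auroc >= 0 & r$auroc <= 1))
  expect_equal(sort(unique(r$scheme)), sort(scheme_names()))
  # population routing
  expect_equal(unique(r$population[r$scheme == "Mix0"]), "EUR+AMR")
  expect_equal(unique(r$population[r$scheme == "NT"]), "AMR")
  expect_equal(unique(r$population[r$scheme == "Ind1"]), "EUR")
})

test_that("NT and Ind1 never touch DDP or test labels (poison audit)", {
  d <- tiny_dataset(seed = 4)
  r1 <- run_experiments(d, models = "LR", schemes = c("Ind1", "NT"),
                        n_runs = 1, seed = 9, keep_scores = TRUE)
  # poison every DDP-train label and every test label (both populations)
  d2 <- d
  poison <- (d2$ancestry == "AMR" & d2$split != "test") | d2$split == "test"
  d2$y[poison & d2$split == "test"] <- 1 - d2$y[poison & d2$split == "test"]
  d2$y[d2$ancestry == "AMR" & d2$split == "train"] <-
    1 - d2$y[d2$ancestry == "AMR" & d2$split == "train"]
  r2 <- run_experiments(d2, models = "LR", schemes = c("Ind1", "NT"),
                        n_runs = 1, seed = 9, keep_scores = TRUE)
  # identical trained model => identical test scores
  expect_identical(attr(r1, "scores")[["LR.NT.1"]],
                   attr(r2, "scores")[["LR.NT.1"]])
  expect_identical(attr(r1, "scores")[["LR.Ind1.1"]],
                   attr(r2, "scores")[["LR.Ind1.1"]])
})

test_that("the mixture schemes share one model per run", {
  d <- tiny_dataset(seed = 5)
  r <- run_experiments(d, models = "DL", schemes = c("Mix1", "Mix2"),
                       n_runs = 2, seed = 3,
                       dnn = dnn_config(max_epochs = 5), keep_scores = TRUE)
  # same model => Mix1 EUR scores and Mix2 DDP scores come from one fit;
  # check via determinism: rerunning Mix2 alone reproduces its scores
  r2 <- run_experiments(d, models = "DL", schemes = "Mix2", n_runs = 2,
                        seed = 3, dnn = dnn_config(max_epochs = 5),
                        keep_scores = TRUE)
  expect_identical(attr(r, "scores")[["DL.Mix2.1"]],
                   attr(r2, "scores")[["DL.Mix2.1"]])
})

test_that("experiment runs are deterministic given the master seed", {
  d <- tiny_dataset(seed = 6)
  r1 <- run_experiments(d, models = "DL", schemes = c("Ind2", "TL"),
                        n_runs = 2, seed = 17,
                        dnn = dnn_config(max_epochs = 5))
  r2 <- run_experiments(d, models = "DL", schemes = c("Ind2", "TL"),
                        n_runs = 2, seed = 17,
                        dnn = dnn_config(max_epochs = 5))
  expect_equal(as.data.frame(r1), as.data.frame(r2))
})

test_that("degenerate transfer (source = target population) tracks Ind1", {
  # two identical-distribution populations: TL on the "DDP" should match an
  # independent fit there, up to run noise
  pr <- simulate_frequency_profiles(40, c(AMR = 0), seed = 7)
  em <- effect_model(40, distances = c(AMR = 3.416), r = 0.5, h2 = 0.8,
                     seed = 7)
  em$W_prime$AMR <- em$W          # no effect shift either
  d <- build_dataset(pr, em, c(EUR = 600, AMR = 600), seed = 7)
  r <- run_experiments(d, models = "LR", schemes = c("Ind1", "TL"),
                       n_runs = 1, seed = 2)
  a_ind1 <- r$auroc[r$scheme == "Ind1"]
  a_tl <- r$auroc[r$scheme == "TL"]
  expect_lt(abs(a_ind1 - a_tl), 0.12)
})

test_that("compendium definition matches the printed design", {
  sd <- sd_compendium()
  expect_equal(nrow(sd), 16)
  expect_equal(sd$id[1], "SD1")
  expect_equal(round(sd$rho[sd$id %in% paste0("SD", 1:4)], 2),
               c(0.80, 0.77, 0.58, 0.54))
  expect_equal(round(sd$rho[sd$id %in% paste0("SD", 9:12)], 2),
               c(0.80, 0.74, 0.42, 0.36))
  # SD9/SD13 duplicate SD1/SD5 configurations
  expect_equal(sd[sd$id == "SD9", c("ddp", "h2", "rho")],
               sd[sd$id == "SD1", c("ddp", "h2", "rho")],
               ignore_attr = TRUE)
  expect_equal(sd[sd$id == "SD13", c("ddp", "h2", "rho")],
               sd[sd$id == "SD5", c("ddp", "h2", "rho")],
               ignore_attr = TRUE)
  sd_star <- sd_compendium("1:4")
  expect_true(all(grepl("\\*$", sd_star$id)))
  expect_equal(sd_star$case_control_ratio[1], "1:4")
})

test_that("a tiny smoke compendium runs end to end and reports", {
  cfgs <- sd_compendium(ids = 1:2, m = 20, n_eur = 200, n_ddp = 80)
  comp <- run_compendium(cfgs, models = "LR",
                         schemes = c("Ind1", "Ind2", "NT", "TL"),
                         n_runs = 2, seed = 31)
  perf <- report_performance(comp)
  expect_equal(nrow(perf), 2)
  expect_true(all(c("Ind1", "TL") %in% colnames(perf)))
  cmps <- report_comparisons(comp)
  expect_true("Ind1_LR vs Ind2_LR" %in% cmps$comparison)
  expect_true(all(is.finite(cmps$mean_diff)))
  # persistence round-trip
  dir <- file.path(tempdir(), "runs-smoke")
  save_runs(comp, dir)
  rep2 <- report_runs(dir)
  expect_equal(rep2$performance, perf)
  expect_error(report_runs(file.path(tempdir(), "no-such-dir")), "no runs")
})

test_that("fixtures are deterministic and QC-survivable", {
  f1 <- make_fixture("tiny", seed = 2)
  f2 <- make_fixture("tiny", seed = 2)
  expect_identical(f1, f2)
  qc <- qc_filter(f1$X)
  expect_gt(sum(qc$kept), 0)
})
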