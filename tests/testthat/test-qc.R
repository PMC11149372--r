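# QC filters, HWE exact test, LD pruning, ANOVA-F feature ranking

test_that("HWE exact test matches enumeration and flags het excess", {
  # all-heterozygote column: grossly out of equilibrium
  expect_lt(hwe_test(0, 100, 0), 1e-5)
  # perfect proportions: not significant
  expect_gt(hwe_test(25, 50, 25), 0.5)
  # enumeration oracle at small counts: P(config) under conditional
  # distribution of het count given allele counts; p = sum of configs no
  # more probable than observed
  n_aa <- 3; n_ab <- 4; n_bb <- 5
  n <- n_aa + n_ab + n_bb; n_rare <- 2 * n_aa + n_ab
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  pr <- vapply(hets, function(h) {
    hr <- (n_rare - h) / 2; hc <- n - h - hr
    exp(lfactorial(n) - lfactorial(hr) - lfactorial(h) - lfactorial(hc) +
          h * log(2) + lfactorial(n_rare) + lfactorial(2 * n - n_rare) -
          lfactorial(2 * n))
  }, numeric(1))
  p_oracle <- sum(pr[pr <= pr[hets == n_ab] * (1 + 1e-9)])
  expect_equal(hwe_test(n_aa, n_ab, n_bb), p_oracle, tolerance = 1e-10)
  # chi-square fallback agrees in order of magnitude
  expect_lt(hwe_test(0, 100, 0, method = "chisq"), 1e-5)
})

test_that("qc_filter applies MAF, missingness and HWE rules", {
  X <- cbind(mono = rep(0, 120),
             rare = c(rep(0, 108), rep(1, 12)),      # maf 0.05 boundary: kept
             het = rep(1, 120),                      # HWE failure
             miss = c(rep(NA, 30), rbinom(90, 2, 0.4)),
             gone = rep(NA, 120),
             good = rbinom(120, 2, 0.3))
  rep_qc <- qc_filter(X, missing_max = 0.20, maf_min = 0.05,
                      hwe_p_min = 1e-5)
  expect_equal(rep_qc$reason[1], "maf")
  expect_true(rep_qc$kept[2])          # maf exactly 0.05 is not < 0.05
  expect_equal(rep_qc$reason[3], "hwe")
  expect_equal(rep_qc$reason[4], "missing_rate")  # 25% > 20%
  expect_equal(rep_qc$reason[5], "all_missing")
  expect_true(rep_qc$kept[6])
  expect_equal(rep_qc$maf[2], 0.05)
  # example column: MAF = 2/12, kept
  one <- qc_filter(cbind(c(0, 0, 0, 0, 0, 2)), maf_min = 0.05,
                   hwe_p_min = 1e-10)
  expect_equal(one$maf, 2 / 12)
  expect_true(one$kept)
  expect_error(qc_filter(cbind(c(0, 3, 1))), "dosages")
})

test_that("qc_filter is idempotent on the kept set", {
  set.seed(3)
  X <- matrix(rbinom(200 * 40, 2, runif(40, 0.02, 0.5)), 200, 40,
              byrow = TRUE)
  r1 <- qc_filter(X)
  X2 <- X[, r1$kept, drop = FALSE]
  r2 <- qc_filter(X2)
  expect_true(all(r2$kept))
})

test_that("sample filter drops rows above the missingness threshold", {
  X <- matrix(rbinom(100, 2, 0.5), 10, 10)
  expect_true(all(sample_filter(X)))
  X[1, 1:5] <- NA          # 50% missing
  X[2, 1:2] <- NA          # exactly 20%: kept (strict >)
  keep <- sample_filter(X, missing_max = 0.20)
  expect_false(keep[1])
  expect_true(keep[2])
  X_all <- matrix(NA_real_, 3, 4)
  expect_error(sample_filter(X_all), "every individual")
})

test_that("LD pruning removes correlated pairs and honors p-values", {
  set.seed(5)
  base <- rbinom(300, 2, 0.5)
  X <- cbind(a = base, b = base, c = rbinom(300, 2, 0.5))
  keep <- ld_prune(X, window = 3, step = 1, r2_max = 0.2)
  expect_equal(sum(keep[1:2]), 1)   # exactly one of the duplicates
  expect_true(keep[3])
  # later-ordered member dropped without p-values
  expect_true(keep[1]); expect_false(keep[2])
  # with p-values, the higher-p member is dropped instead
  keep_p <- ld_prune(X, window = 3, step = 1, r2_max = 0.2,
                     p_values = c(0.5, 0.01, 0.3))
  expect_false(keep_p[1]); expect_true(keep_p[2])
  # independent columns all survive
  Xi <- matrix(rbinom(300 * 10, 2, 0.5), 300, 10)
  expect_true(all(ld_prune(Xi, window = 5, step = 2, r2_max = 0.2)))
  expect_error(ld_prune(Xi, window = 1), "window")
})

test_that("pruned sets contain no within-window pair above the cut-off", {
  set.seed(8)
  m <- 200; n <- 150
  base <- matrix(rbinom(n * m, 2, 0.4), n, m)
  # plant correlated blocks
  for (j in seq(5, m, by = 7)) base[, j] <- base[, j - 1]
  keep <- ld_prune(base, window = 50, step = 5, r2_max = 0.2)
  kept_idx <- which(keep)
  # exhaustive pair scan over every window position
  for (s in seq(1, m, by = 5)) {
    win <- intersect(s:min(s + 49, m), kept_idx)
    if (length(win) < 2) next
    r2 <- cor(base[, win])^2
    diag(r2) <- 0
    expect_lt(max(r2), 0.2 + 1e-12)
  }
})

test_that("ANOVA-F ranking matches aov and selects top-K on training data", {
  set.seed(9)
  n <- 80
  y <- rep(0:1, each = n / 2)
  X <- cbind(signal = y + rnorm(n, sd = 0.1),
             konst = rep(1, n),
             matrix(rnorm(n * 8), n, 8))
  fr <- rank_and_select(X, y, K = 3)
  expect_equal(fr$rank[1], 1L)                 # label-like column first
  expect_equal(fr$f_stat[2], 0)                # constant column F = 0
  expect_equal(fr$rank[2], 10L)                # ... ranked last
  expect_equal(sum(fr$selected), 3)
  expect_true(all(sort(fr$rank) == 1:10))      # ranks are a permutation
  # brute-force oracle: per-column aov
  for (j in c(1, 3, 7)) {
    a <- anova(aov(X[, j] ~ factor(y)))
    expect_equal(fr$f_stat[j], a$`F value`[1], tolerance = 1e-10)
    expect_equal(fr$p_value[j], a$`Pr(>F)`[1], tolerance = 1e-10)
  }
  expect_error(rank_and_select(X, rep(1, n), K = 2), "single class")
})

test_that("a column equal to the label ranks first with infinite F", {
  y <- rep(0:1, each = 10)
  X <- cbind(exact = y, noise = rnorm(20))
  fr <- rank_and_select(X, y, K = 1)
  expect_equal(fr$rank[1], 1L)
  expect_true(fr$selected[1])
})
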