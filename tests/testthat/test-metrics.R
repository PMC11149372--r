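# evaluation metrics against brute-force oracles

brute_auroc <- function(scores, labels) {
  cs <- scores[labels == 1]; ct <- scores[labels == 0]
  tot <- 0
  for (a in cs) for (b in ct) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}

test_that("AUROC equals pairwise concordance counting", {
  expect_equal(auroc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1)
  set.seed(4)
  scores <- sample(seq(0, 1, by = 0.05), 50, replace = TRUE)  # with ties
  labels <- rbinom(50, 1, 0.4)
  expect_equal(auroc(scores, labels), brute_auroc(scores, labels))
  # invariance under strictly monotone transform
  expect_equal(auroc(qlogis(pmin(pmax(scores, 0.01), 0.99)), labels),
               auroc(pmin(pmax(scores, 0.01), 0.99), labels))
  # null scores ~ 0.5 at n = 10^4
  set.seed(5)
  s <- rnorm(1e4); l <- rbinom(1e4, 1, 0.5)
  expect_lt(abs(auroc(s, l) - 0.5), 0.02)
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(6)
  scores <- rnorm(200); labels <- rbinom(200, 1, 0.3)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auroc(scores, labels), ref, tolerance = 1e-12)
})

test_that("AUPR equals brute-force step integration", {
  brute_aupr <- function(scores, labels) {
    thr <- sort(unique(scores), decreasing = TRUE)
    prev_rec <- 0; area <- 0
    for (t in thr) {
      pos <- scores >= t
      prec <- sum(labels[pos]) / sum(pos)
      rec <- sum(labels[pos]) / sum(labels)
      area <- area + prec * (rec - prev_rec)
      prev_rec <- rec
    }
    area
  }
  expect_equal(aupr(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1)
  set.seed(7)
  scores <- sample(seq(0, 1, 0.1), 60, replace = TRUE)
  labels <- rbinom(60, 1, 0.4)
  expect_equal(aupr(scores, labels), brute_aupr(scores, labels))
})

test_that("Tjur's R2 is the two-group mean difference", {
  y <- c(1, 1, 0, 0)
  expect_equal(tjur_r2(c(1, 1, 0, 0), y), 1)
  expect_equal(tjur_r2(rep(0.7, 4), y), 0)
  set.seed(8)
  p <- runif(100); yy <- rbinom(100, 1, 0.5)
  expect_equal(tjur_r2(p, yy), mean(p[yy == 1]) - mean(p[yy == 0]))
  expect_gte(tjur_r2(p, yy), -1); expect_lte(tjur_r2(p, yy), 1)
})

test_that("Youden threshold matches an exhaustive scan", {
  set.seed(9)
  scores <- round(runif(100), 2)
  labels <- rbinom(100, 1, 0.5)
  yt <- youden_threshold(scores, labels)
  cand <- sort(unique(scores))
  j_all <- vapply(cand, function(t) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    sens + spec - 1
  }, numeric(1))
  expect_equal(yt$j, max(j_all))
  expect_equal(yt$threshold, cand[which.max(j_all)])  # lowest on ties
  expect_equal(yt$j, yt$sensitivity + yt$specificity - 1)
  # perfectly separated: J = 1
  expect_equal(youden_threshold(c(1, 2, 3, 11, 12), c(0, 0, 0, 1, 1))$j, 1)
  # label-independent scores: J near 0
  set.seed(10)
  j_null <- youden_threshold(rnorm(5000), rbinom(5000, 1, 0.5))$j
  expect_lt(j_null, 0.1)
})

test_that("prevalence-adjusted predictive values follow the formulas", {
  expect_equal(adjusted_ppv_npv(1, 1, 0.3), list(ppv = 1, npv = 1))
  # confusion-table oracle at prevalence 10.3%
  adj <- adjusted_ppv_npv(0.8, 0.9, 0.103)
  n <- 1e6; ncase <- n * 0.103
  tp <- 0.8 * ncase; fn <- 0.2 * ncase
  tn <- 0.9 * (n - ncase); fp <- 0.1 * (n - ncase)
  expect_equal(adj$ppv, tp / (tp + fp))
  expect_equal(adj$npv, tn / (tn + fn))
  expect_equal(round(adj$ppv, 3), 0.479)
  expect_equal(round(adj$npv, 3), 0.975)
  # prevalence 1/2 reduces PPV to sens / (sens + 1 - spec)
  expect_equal(adjusted_ppv_npv(0.7, 0.6, 0.5)$ppv, 0.7 / (0.7 + 0.4))
  # undefined case reported as NaN
  expect_true(is.nan(adjusted_ppv_npv(0, 1, 0)$ppv))
})

test_that("metric report at empirical prevalence matches raw PPV/NPV", {
  set.seed(11)
  scores <- runif(300)
  labels <- as.integer(scores + rnorm(300, sd = 0.4) > 0.6)
  rep_m <- metric_report(scores, labels, prevalence = mean(labels))
  expect_equal(rep_m$adjusted_ppv, rep_m$ppv, tolerance = 1e-12)
  expect_equal(rep_m$adjusted_npv, rep_m$npv, tolerance = 1e-12)
  expect_true(all(unlist(rep_m[c("auroc", "aupr", "sensitivity",
                                 "specificity", "ppv", "npv")]) >= 0))
})
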