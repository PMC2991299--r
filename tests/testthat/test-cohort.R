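test_that("overlap_percentage handles identity, disjointness and emptiness", {
  a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE
  b <- matrix(FALSE, 4, 4); b[3:4, 3:4] <- TRUE
  expect_equal(overlap_percentage(a, a), 100)
  expect_equal(overlap_percentage(a, b), 0)
  e <- matrix(FALSE, 4, 4)
  expect_equal(overlap_percentage(e, e), 100)
  # half-overlapping: Dice 200*2/(4+4) = 50, Jaccard 100*2/6
  c2 <- matrix(FALSE, 4, 4); c2[1:2, 2:3] <- TRUE
  expect_equal(overlap_percentage(a, c2), 50)
  expect_equal(overlap_percentage(a, c2, "jaccard"), 100 * 2 / 6)
  expect_error(overlap_percentage(a, matrix(FALSE, 3, 3)), "shapes differ")
})

test_that("variability_pct is the pair difference over the pair mean", {
  expect_equal(variability_pct(10, 11), 100 * 1 / 10.5)
  expect_equal(variability_pct(5, 5), 0)
  expect_equal(variability_pct(0, 0), 0)
  expect_equal(variability_pct(c(2, 4), c(2, 5)), c(0, 100 * 1 / 4.5))
  expect_error(variability_pct(-1, 1), "undefined")
})

test_that("mann_whitney matches hand-computed U and the enumeration oracle", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  mw <- mann_whitney(a, b)
  expect_equal(mw$U, 0)
  expect_equal(mw$method, "exact")
  expect_equal(mw$p, oracle_mw_exact_p(a, b))
  expect_equal(mw$p, 0.1, tolerance = 1e-12)  # 2 * 1/choose(6,3)

  # large tie-free samples switch to the normal approximation
  set.seed(4)
  x <- rnorm(20); y <- rnorm(20) + 1
  mw2 <- mann_whitney(x, y)
  expect_equal(mw2$method, "normal approximation")
  wt <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(mw2$p, wt$p.value)
  expect_equal(mw2$U, unname(wt$statistic))
})

test_that("pearson recovers an exact linear relation", {
  x <- c(1, 2, 3, 4, 5)
  y <- 2 * x + 3
  pr <- pearson(x, y)
  expect_equal(pr$r, 1)
  expect_equal(pr$slope, 2)
  expect_equal(pr$intercept, 3)
  expect_equal(pr$n, 5)
  set.seed(9)
  x2 <- rnorm(30); y2 <- 1.5 * x2 + rnorm(30)
  ct <- cor.test(x2, y2)
  pr2 <- pearson(x2, y2)
  expect_equal(pr2$r, unname(ct$estimate))
  expect_equal(pr2$p, ct$p.value)
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("roc finds the Youden-optimal point in both orientations", {
  vals <- c(1, 2, 3, 10, 11, 12)
  labs <- c("ctl", "ctl", "ctl", "pat", "pat", "pat")
  rr <- roc(vals, labs, "pat")
  expect_equal(rr$auc, 1)
  expect_equal(rr$direction, ">=")
  expect_equal(rr$sensitivity, 1)
  expect_equal(rr$specificity, 1)
  expect_gt(rr$optimal_threshold, 3)
  expect_lt(rr$optimal_threshold, 10)

  # inverted marker: lower values indicate disease
  rr2 <- roc(-vals, labs, "pat")
  expect_equal(rr2$auc, 1)
  expect_equal(rr2$direction, "<=")
  expect_equal(rr2$sensitivity, 1)

  # cross-check AUC against pROC on an imperfect marker
  set.seed(21)
  v <- c(rnorm(15, 1), rnorm(12, 0))
  l <- rep(c("pat", "ctl"), c(15, 12))
  rr3 <- roc(v, l, "pat")
  pr <- pROC::roc(response = l, predictor = v, levels = c("ctl", "pat"),
                  quiet = TRUE)
  expect_equal(rr3$auc, as.numeric(pROC::auc(pr)))
})

test_that("cohort_stats builds the per-parameter comparison table", {
  set.seed(31)
  tab <- data.frame(
    group = rep(c("control", "patient"), c(20, 12)),
    DT = c(rnorm(20, 185, 20), rnorm(12, 140, 20)),
    IVRT = c(rnorm(20, 78, 10), rnorm(12, 60, 10)))
  st <- cohort_stats(tab)   # positive defaults to the rarer group
  expect_equal(nrow(st), 2)
  expect_equal(st$parameter, c("DT", "IVRT"))
  expect_true(all(c("Sensitivity", "Specificity", "NPV", "PPV", "Accuracy",
                    "ROC_threshold", "AUC") %in% names(st)))
  expect_equal(st$mean_neg[1], mean(tab$DT[tab$group == "control"]))
  expect_equal(st$mean_pos[1], mean(tab$DT[tab$group == "patient"]))
  expect_equal(st$p_value[1],
               mann_whitney(tab$DT[tab$group == "control"],
                            tab$DT[tab$group == "patient"])$p)
  expect_error(cohort_stats(data.frame(group = "a", x = 1)),
               "two levels")
})
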