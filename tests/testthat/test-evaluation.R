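test_that("ROC basics: separation, orientation, class checks", {
  scores <- c(1, 2, 3, 11, 12, 13)
  labels <- rep(c("suspect", "glaucoma"), each = 3)
  r <- suppressWarnings(roc(scores, labels))
  expect_equal(r$auc, 1)
  expect_equal(r$n_pos, 3); expect_equal(r$n_neg, 3)
  # reversed orientation via direction = "<"
  r2 <- suppressWarnings(roc(-scores, labels, direction = "<"))
  expect_equal(r2$auc, 1)
  expect_error(roc(scores, rep("glaucoma", 6)), "non-empty")
  # sensitivity non-increasing along ascending thresholds
  set.seed(6)
  r3 <- roc(rnorm(100), sample(c("suspect", "glaucoma"), 100, TRUE))
  expect_true(all(diff(r3$sensitivity) <= 0))
  expect_true(all(diff(r3$specificity) >= 0))
})

test_that("AUC equals the pairwise Mann-Whitney statistic exactly", {
  set.seed(7)
  for (i in 1:10) {
    n1 <- sample(5:50, 1); n2 <- sample(5:50, 1)
    scores <- c(rnorm(n1, 1), rnorm(n2))
    scores <- round(scores, sample(0:1, 1))  # induce ties
    labels <- c(rep("glaucoma", n1), rep("suspect", n2))
    r <- suppressWarnings(roc(scores, labels))
    expect_equal(r$auc, brute_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  scores <- c(rnorm(60, 1), rnorm(80))
  labels <- c(rep("glaucoma", 60), rep("suspect", 80))
  r <- roc(scores, labels)
  ref <- pROC::roc(response = labels, predictor = scores,
                   levels = c("suspect", "glaucoma"), direction = "<",
                   quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})

test_that("Hanley-McNeil SE follows the published variance formula", {
  # all scores tied: AUC is exactly 0.5
  r <- roc(rep(1, 200), rep(c("glaucoma", "suspect"), each = 100))
  expect_equal(r$auc, 0.5)
  expected <- sqrt((0.25 + 99 * (1 / 3 - 0.25) + 99 * (1 / 3 - 0.25)) / 1e4)
  expect_equal(auc_se(r), expected, tolerance = 1e-12)
  # general plug-in check at the measured AUC
  set.seed(9)
  r2 <- roc(c(rnorm(40, 1.2), rnorm(60)),
            c(rep("glaucoma", 40), rep("suspect", 60)))
  a <- r2$auc; q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
  expect_equal(r2$auc_se,
               sqrt((a * (1 - a) + 39 * (q1 - a^2) + 59 * (q2 - a^2)) / 2400),
               tolerance = 1e-12)
  # SE shrinks with n at fixed AUC
  r_small <- roc(rep(1, 20), rep(c("glaucoma", "suspect"), each = 10))
  expect_gt(auc_se(r_small), auc_se(r))
  expect_warning(se0 <- auc_se(suppressWarnings(
    roc(c(0, 0, 1, 1), c("suspect", "suspect", "glaucoma", "glaucoma")))),
    "degenerate")
  expect_equal(se0, 0)
})

test_that("paired AUC comparison: identity, antisymmetry, unpaired identity", {
  set.seed(10)
  labels <- c(rep("glaucoma", 50), rep("suspect", 50))
  a <- c(rnorm(50, 1), rnorm(50))
  b <- a + rnorm(100, 0, 0.5)
  ra <- roc(a, labels); rb <- roc(b, labels)
  same <- compare_auc(ra, ra, a, a, labels)
  expect_equal(same$z, 0); expect_equal(same$p, 1)
  ab <- compare_auc(ra, rb, a, b, labels)
  ba <- compare_auc(rb, ra, b, a, labels)
  expect_equal(ab$z, -ba$z, tolerance = 1e-12)
  expect_gt(ab$r, 0)  # correlated scores
  unp <- compare_auc(ra, rb, paired = FALSE)
  expect_equal(unp$z,
               (ra$auc - rb$auc) / sqrt(ra$auc_se^2 + rb$auc_se^2),
               tolerance = 1e-12)
  expect_error(compare_auc(ra, rb, a, b[-1], labels), "aligned")
})

test_that("binary test performance: counts, exact CIs, OR-combination", {
  labels <- c(rep("glaucoma", 100), rep("suspect", 50))
  predicted <- c(rep(TRUE, 58), rep(FALSE, 42), rep(FALSE, 45), rep(TRUE, 5))
  perf <- binary_performance(predicted, labels)
  expect_equal(perf$tp, 58); expect_equal(perf$fn, 42)
  expect_equal(perf$sensitivity, 0.58)
  expect_equal(perf$specificity, 0.9)
  bt <- stats::binom.test(58, 100)
  expect_equal(perf$sensitivity_ci, as.numeric(bt$conf.int), tolerance = 1e-12)
  expect_true(perf$sensitivity_ci[1] <= 0.58 & 0.58 <= perf$sensitivity_ci[2])
  # declaring positive when either of two tests is positive can only
  # increase sensitivity
  set.seed(11)
  t1 <- runif(150) < 0.5; t2 <- runif(150) < 0.5
  s_or <- binary_performance(t1 | t2, labels)$sensitivity
  expect_gte(s_or, binary_performance(t1, labels)$sensitivity)
  expect_gte(s_or, binary_performance(t2, labels)$sensitivity)
  allright <- binary_performance(labels == "glaucoma", labels)
  expect_equal(allright$sensitivity, 1); expect_equal(allright$specificity, 1)
})

test_that("optimal operating point: distance rule and tie-break", {
  scores <- c(1, 2, 3, 11, 12, 13)
  labels <- rep(c("suspect", "glaucoma"), each = 3)
  r <- suppressWarnings(roc(scores, labels))
  opt <- optimal_point(r)
  expect_equal(opt$distance, 0)
  expect_equal(opt$sensitivity, 1); expect_equal(opt$specificity, 1)
  # symmetric two-point tie resolves to the lower threshold
  r2 <- roc(c(1, 2, 3, 4), c("suspect", "glaucoma", "suspect", "glaucoma"))
  d <- sqrt((1 - r2$sensitivity)^2 + (1 - r2$specificity)^2)
  ties <- which(d == min(d))
  expect_gt(length(ties), 1)
  expect_equal(opt2 <- optimal_point(r2)$threshold, r2$thresholds[ties[1]])
  # brute-force scan oracle
  set.seed(12)
  r3 <- roc(rnorm(80), sample(c("suspect", "glaucoma"), 80, TRUE))
  opt3 <- optimal_point(r3)
  d3 <- sqrt((1 - r3$sensitivity)^2 + (1 - r3$specificity)^2)
  expect_equal(opt3$distance, min(d3), tolerance = 1e-12)
})

test_that("concordance tables conserve n and match a per-eye tally", {
  set.seed(13)
  n <- 120
  outcomes <- list(sfi = runif(n) < 0.4, ght = runif(n) < 0.3,
                   mfc = runif(n) < 0.5)
  tab <- concordance_table(outcomes)
  expect_equal(sum(tab$count), n)
  # brute-force pattern tally
  pat <- paste(outcomes$sfi, outcomes$ght, outcomes$mfc)
  for (i in seq_len(nrow(tab))) {
    key <- paste(tab$sfi[i], tab$ght[i], tab$mfc[i])
    expect_equal(tab$count[i], sum(pat == key))
  }
  # single-cell degenerate case
  tab1 <- concordance_table(list(a = rep(TRUE, 7)))
  expect_equal(nrow(tab1), 1); expect_equal(tab1$count, 7)
  # MD stratification keeps only eyes inside the band
  md <- runif(n, -20, 5)
  tabm <- concordance_table(outcomes, md = md, md_range = c(-5, Inf))
  expect_equal(sum(tabm$count), sum(md > -5))
  expect_error(concordance_table(list(a = c(TRUE), b = c(TRUE, FALSE))),
               "aligned")
  expect_error(concordance_table(outcomes, md_range = c(-5, Inf)),
               "md values")
})
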