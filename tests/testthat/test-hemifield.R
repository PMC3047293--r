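# build an sfi_result with prescribed SFI values
fake_result <- function(sfi_by_key, laterality = "right") {
  grid <- grid_24_2(laterality)
  sfi <- rep(0, nrow(grid))
  names(sfi) <- grid$key
  sfi[names(sfi_by_key)] <- sfi_by_key
  out <- data.frame(x = grid$x, y = grid$y, key = grid$key,
                    td = 0, p_field_abn = 0, sfi = unname(sfi))
  structure(out, laterality = laterality,
            class = c("sfi_result", "data.frame"))
}

test_that("per-point scores follow 1/(10(1-SFI)) with the cap at 100", {
  expect_equal(point_score(0.999), 100)
  expect_equal(point_score(1), 100)
  expect_equal(point_score(0), 0.1)
  expect_equal(point_score(0.9), 1.0)
  expect_equal(point_score(0.5), 0.2)
  s <- point_score(seq(0, 1, by = 0.01))
  expect_true(all(diff(s) >= 0))
  expect_true(all(s <= 100))
  expect_error(point_score(-0.1), "\\[0, 1\\]")
})

test_that("region scores reach 300 for region 1 and 600 for region 4", {
  reg <- ght_regions("right")
  res <- fake_result(stats::setNames(rep(0.999, 52), grid_24_2("right")$key))
  k1 <- reg$key[reg$region == 1 & reg$hemifield == "superior"]
  k4 <- reg$key[reg$region == 4 & reg$hemifield == "superior"]
  expect_equal(region_score(res, k1), 300)
  expect_equal(region_score(res, k4), 600)
  zeros <- fake_result(c(td_3_3 = 0))
  expect_equal(region_score(zeros, k1), 0.3)
  expect_error(region_score(res, c("td_0_0")), "missing")
})

test_that("hemifield statistics: symmetry, asymmetry arithmetic, totals", {
  # symmetric field: all paired differences vanish
  sym <- fake_result(stats::setNames(rep(0.4, 52), grid_24_2("right")$key))
  st <- ht_statistics(sym)
  expect_equal(unname(st$diffs), rep(0, 5))
  # superior-only damage: each difference = 0.9 per point x cluster size
  reg <- ght_regions("right")
  sup_keys <- reg$key[reg$hemifield == "superior"]
  dam <- fake_result(stats::setNames(rep(0.9, length(sup_keys)), sup_keys))
  st <- ht_statistics(dam)
  sizes <- table(reg$region[reg$hemifield == "superior"])
  expect_equal(unname(st$diffs),
               unname(as.vector(sizes[as.character(1:5)])) * 0.9)
  # all-zero SFI: every point contributes the 0.1 floor
  zero <- fake_result(c(td_3_3 = 0))
  expect_equal(ht_statistics(zero)$total, 52 * 0.1)
})

test_that("SFI-HT reference fitting stores six samples of the cohort size", {
  fx <- make_fitted_model(n = 40, seed = 51, with_ht = TRUE)
  ht <- fx$model$ht_reference
  expect_named(ht, c(paste0("d", 1:5), "total"))
  expect_true(all(vapply(ht, `[[`, 0, "n") == 40))
  # refit on permuted results is identical
  scores <- score_cohort(fx$records, fx$model, fx$linkage)
  set.seed(1)
  m2 <- fit_ht_reference(fx$model, sample(scores))
  expect_identical(m2$ht_reference$total$sample, ht$total$sample)
  expect_error(ht_summary(ht_statistics(scores[[1]]),
                          make_fitted_model(n = 25, seed = 52)$model),
               "no fitted SFI-HT")
})

test_that("ht_summary measures two-sided extremity against the reference", {
  fx <- make_fitted_model(n = 40, seed = 53, with_ht = TRUE)
  n <- 40
  # a difference at the reference median is unremarkable
  st <- list(diffs = stats::setNames(
    vapply(1:5, function(k)
      median(fx$model$ht_reference[[paste0("d", k)]]$sample), 0),
    paste0("d", 1:5)),
    total = median(fx$model$ht_reference$total$sample))
  s <- ht_summary(st, fx$model)
  expect_true(all(s$abnormality_probs[paste0("d", 1:5)] < 0.05))
  # a difference beyond every reference value attains the clamp bound
  st$diffs[] <- max(fx$model$ht_reference$d1$sample) + 1000
  st$total <- max(fx$model$ht_reference$total$sample) + 1000
  s <- ht_summary(st, fx$model)
  expect_equal(unname(s$abnormality_probs[["d1"]]), 1 - 1 / n)
  expect_equal(unname(s$abnormality_probs[["total"]]), 1 - 1 / (2 * n))
  expect_lt(s$summary, 1)
  expect_equal(s$summary, max(s$abnormality_probs))
  expect_equal(s$most_abnormal,
               names(s$abnormality_probs)[which.max(s$abnormality_probs)])
})

test_that("summary is monotone under worsening superior damage", {
  fx <- make_fitted_model(n = 40, seed = 54, with_ht = TRUE)
  reg <- ght_regions("right")
  sup_keys <- reg$key[reg$hemifield == "superior"]
  vals <- c(0.2, 0.5, 0.8, 0.95)
  summaries <- vapply(vals, function(v) {
    res <- fake_result(stats::setNames(rep(v, length(sup_keys)), sup_keys))
    ht_summary(res, fx$model)$summary
  }, 0)
  expect_true(all(diff(summaries) >= 0))
})
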