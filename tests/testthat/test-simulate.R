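test_that("simulation is reproducible from the seed", {
  a <- simulate_cohort(cohort_config(12, "glaucoma", 61))
  b <- simulate_cohort(cohort_config(12, "glaucoma", 61))
  c <- simulate_cohort(cohort_config(12, "glaucoma", 62))
  expect_identical(a$records[[5]]$td, b$records[[5]]$td)
  expect_identical(a$truth$eyes, b$truth$eyes)
  expect_false(identical(a$records[[5]]$td, c$records[[5]]$td))
  empty <- simulate_cohort(cohort_config(0, "suspect", 1))
  expect_length(empty$records, 0)
})

test_that("truth deltas are consistent with the emitted records", {
  sim <- simulate_cohort(cohort_config(30, "glaucoma", 63,
                                       laterality_mix = c(right = 1, left = 0),
                                       defect_prob = 1))
  expect_true(all(sim$truth$eyes$defect))
  for (i in c(1, 15, 30)) {
    fd <- sim$truth$field_delta[[i]]
    expect_true(all(fd <= 0))
    expect_true(all(sim$truth$rim_delta[[i]] <= 0))
  }
})

test_that("defect injection arithmetic", {
  eye <- make_flat_eye(0, "right", "e1", "glaucoma")
  map <- default_map("right")
  # zero depth leaves the record untouched
  inj0 <- inject_defect(eye, 292.5, 60, 0, map)
  expect_identical(inj0$record$td, eye$td)
  expect_identical(inj0$record$rim, eye$rim)
  expect_true(all(inj0$field_delta == 0))
  # a deep inferotemporal arc depresses only linked points
  inj <- inject_defect(eye, 292.5, 60, 10, map)
  expect_true(all(inj$field_delta <= 0))
  overlap <- -inj$field_delta / 10
  sup <- grid_24_2("right")$y > 0
  expect_gt(mean(overlap[sup]), mean(overlap[!sup]))  # superior field hit
  # points with no insertion mass near the arc are untouched
  far <- map$mean_angle > 90 & map$mean_angle < 180  # superonasal entries
  expect_true(all(abs(inj$field_delta[far]) < 1e-6))
  # rim loss proportional to arc-in-sector fraction: the 60-degree arc at
  # 292.5 covers [262.5, 322.5): 1/8 IN, 3/4 IT, 1/8 T
  rd <- inj$rim_delta
  expect_equal(unname(rd[["inferotemporal"]]), -0.015 * 10 * 0.75)
  expect_equal(unname(rd[["inferonasal"]]), -0.015 * 10 * 0.125)
  expect_equal(unname(rd[["temporal"]]), -0.015 * 10 * 0.125)
  expect_equal(unname(rd[["nasal"]]), 0)
  # a point whose insertion mass lies fully inside the arc takes full depth
  ov <- data.frame(x = 3, y = 15, mean_angle = 292.5, sd_angle = 1)
  map_ov <- default_map("right", override = ov)
  inj2 <- inject_defect(eye, 292.5, 60, 10, map_ov)
  expect_equal(unname(inj2$field_delta["td_3_15"]), -10, tolerance = 1e-6)
  expect_error(inject_defect(eye, 0, 60, -1, map), "depth")
})

test_that("discordant mode moves rim loss to the opposite arc", {
  con <- simulate_cohort(cohort_config(10, "glaucoma", 64, defect_prob = 1,
                                       laterality_mix = c(right = 1, left = 0)))
  dis <- simulate_cohort(cohort_config(10, "glaucoma", 64, defect_prob = 1,
                                       laterality_mix = c(right = 1, left = 0),
                                       discordant = TRUE))
  for (i in c(2, 7)) {
    expect_identical(con$truth$field_delta[[i]], dis$truth$field_delta[[i]])
    center <- con$truth$eyes$arc_center[i]
    # discordant rim deltas equal concordant ones for the rotated arc
    expect_false(identical(con$truth$rim_delta[[i]], dis$truth$rim_delta[[i]]))
    eye <- make_flat_eye(0, "right", "x", "glaucoma")
    map <- default_map("right")
    d <- con$truth$eyes$depth[i]
    rot <- inject_defect(eye, (center + 180) %% 360, 60, d, map)
    expect_equal(dis$truth$rim_delta[[i]], rot$rim_delta, tolerance = 1e-12)
  }
})

test_that("suspect cohorts sit near the calibrated MD moments", {
  sus <- sim_records(300, "suspect", 65)
  md <- vapply(sus, `[[`, 0, "md")
  expect_lt(abs(mean(md) - (-0.46)), 0.4)
  expect_lt(abs(sd(md) - 1.7), 0.6)
})

test_that("reference eyes score uniform field abnormality against an independent model", {
  fit <- sim_records(500, "reference", 66)
  fresh <- sim_records(500, "reference", 67)
  model <- fit_reference_model(fit, "right")
  linkage <- build_linkage(default_map("right"))
  scores <- score_cohort(fresh, model, linkage)
  p <- vapply(scores, function(s) s$p_field_abn[s$key == "td_3_15"], 0)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})
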