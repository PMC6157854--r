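test_that("scan mode follows the heart-rate rule with inclusive boundary", {
  expect_equal(assign_scan_mode(64), "high_pitch")
  expect_equal(assign_scan_mode(70), "high_pitch")
  expect_equal(assign_scan_mode(70.5), "adaptive_sequence")
  expect_equal(assign_scan_mode(90), "adaptive_sequence")
  expect_error(assign_scan_mode(95), "helical",
    class = "contrastflow_scope_error")
  expect_error(assign_scan_mode(NA_real_), "mode",
    class = "contrastflow_validation_error")
})

test_that("reference patient protocol reproduces the anchor numbers", {
  p <- generate_protocol(
    data.frame(sex = "M", height_m = 1.80, weight_kg = 80),
    default_cal, kv = 120, mode = "high_pitch")
  expect_equal(p$flow_ml_s, 7.0)
  expect_equal(p$idr_gi_s, 2.1)
  expect_equal(p$main_bolus_ml, 56.0)
  expect_equal(p$til_g, 16.8)
  expect_equal(p$test_bolus_ml, 14.7) # 7.0 mL/s x 2.1 s
  expect_equal(p$injection_time_s, 8)
  expect_false(p$flow_warning)
})

test_that("iodine bookkeeping matches injector-report arithmetic", {
  agent <- contrast_agent()
  expect_equal(iodine_load(25.1, agent), 7.5) # 25.1 x 0.3 = 7.53
  expect_equal(iodine_load(61.0, agent), 18.3)
  expect_equal(iodine_load(56.0, agent), 16.8)
  expect_equal(iodine_delivery_rate(7.0, agent), 2.1)
  expect_equal(iodine_load(25.1, agent, round = FALSE), 7.53)
})

test_that("protocol invariants hold across a mixed cohort", {
  pts <- sample_cohort(cohort_config(n_male = 30, n_female = 30), seed = 3)
  pts <- add_blood_volume(pts)
  pts$kv <- assign_kv(pts$bv_l, pts$sex)
  p <- generate_protocol(pts, default_cal)
  agent <- default_cal$agent
  # main bolus = flow x injection time, within rounding
  expect_true(all(abs(p$main_bolus_ml -
    p$flow_ml_s * p$injection_time_s) <= 0.05 + 1e-9))
  # IDR/flow is the iodine concentration in g/mL for every protocol
  expect_equal(iodine_delivery_rate(p$flow_ml_s, agent, round = FALSE) /
    p$flow_ml_s, rep(agent$iodine_mg_ml / 1000, nrow(p)))
  # TIL covers the main bolus only; adding the test bolus gives the
  # total injected iodine
  total <- iodine_load(p$main_bolus_ml + p$test_bolus_ml, agent,
    round = FALSE)
  expect_equal(total,
    iodine_load(p$main_bolus_ml, agent, round = FALSE) +
      iodine_load(p$test_bolus_ml, agent, round = FALSE),
    tolerance = 1e-12)
  expect_true(all(p$til_g < total))
})

test_that("adaptive-sequence bolus is 10/8 of high-pitch pre-rounding", {
  pt <- data.frame(sex = "F", height_m = 1.68, weight_kg = 67)
  hp <- generate_protocol(pt, default_cal, kv = 80, mode = "high_pitch",
    round = FALSE)
  as_ <- generate_protocol(pt, default_cal, kv = 80,
    mode = "adaptive_sequence", round = FALSE)
  expect_equal(as_$main_bolus_ml, hp$main_bolus_ml * 10 / 8,
    tolerance = 1e-12)
  expect_equal(as_$flow_ml_s, hp$flow_ml_s)
})

test_that("injection-time buffer and test-bolus duration are configurable", {
  pt <- data.frame(sex = "M", height_m = 1.80, weight_kg = 80)
  p <- generate_protocol(pt, default_cal, kv = 120, mode = "high_pitch",
    injection_time_buffer_s = 1, test_bolus_s = 2.0)
  expect_equal(p$injection_time_s, 9)
  expect_equal(p$main_bolus_ml, 63.0)
  expect_equal(p$test_bolus_ml, 14.0)
})

test_that("flows above the cannula ceiling are flagged with a warning", {
  pt <- data.frame(sex = "M", height_m = 2.0, weight_kg = 120)
  expect_warning(
    p <- generate_protocol(pt, default_cal, kv = 120, mode = "high_pitch"),
    "ceiling")
  expect_true(p$flow_warning)
})

test_that("missing tube voltage or scan mode raise instructive errors", {
  pt <- data.frame(sex = "M", height_m = 1.80, weight_kg = 80)
  expect_error(generate_protocol(pt, default_cal, mode = "high_pitch"),
    "kv", class = "contrastflow_validation_error")
  expect_error(generate_protocol(pt, default_cal, kv = 120),
    "mode", class = "contrastflow_validation_error")
})

test_that("protocol table collapses degenerate groups correctly", {
  pt <- data.frame(sex = "M", height_m = 1.80, weight_kg = 80)
  p1 <- generate_protocol(pt, default_cal, kv = 120, mode = "high_pitch")
  t1 <- protocol_table(p1)
  expect_true(all(t1$mean == t1$min & t1$mean == t1$max))
  # duplicating the patient changes n but no statistic
  p2 <- generate_protocol(pt[c(1, 1), , drop = FALSE], default_cal,
    kv = 120, mode = "high_pitch")
  t2 <- protocol_table(p2)
  expect_equal(t2$mean, t1$mean)
  expect_equal(t2$n, rep(2L, nrow(t2)))
  expect_error(protocol_table(p1[0, ]),
    class = "contrastflow_validation_error")
})

test_that("protocol table is ordered by mode, kV, sex", {
  pts <- sample_cohort(cohort_config(n_male = 40, n_female = 40), seed = 5)
  pts <- add_blood_volume(pts)
  pts$kv <- assign_kv(pts$bv_l, pts$sex)
  tab <- protocol_table(generate_protocol(pts, default_cal))
  key <- paste(tab$mode, tab$kv, tab$sex)
  expect_equal(key, key[order(tab$mode, tab$kv, tab$sex)])
})
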