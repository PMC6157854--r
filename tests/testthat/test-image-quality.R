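test_that("CNR and SNR follow their defining formulas", {
  expect_equal(cnr(360, -80, 30), 440 / 30)
  expect_equal(cnr(100, 100, 25), 0)
  expect_equal(snr(350, 35), 10)
  expect_equal(snr(367, 43), 367 / 43)
  expect_error(cnr(360, -80, 0), class = "contrastflow_validation_error")
  expect_error(snr(350, 0), class = "contrastflow_validation_error")
})

test_that("metrics agree with brute-force recomputation on random ROIs", {
  set.seed(21)
  rois <- tibble::tibble(
    segment_id = 1:17,
    vessel_mean_hu = rnorm(17, 350, 50),
    vessel_sd_hu = runif(17, 20, 60),
    fat_mean_hu = rnorm(17, -80, 15),
    fat_sd_hu = runif(17, 15, 45)
  )
  out <- classify_iq(rois)
  expect_equal(out$cnr,
    (rois$vessel_mean_hu - rois$fat_mean_hu) / rois$fat_sd_hu)
  expect_equal(out$snr, rois$vessel_mean_hu / rois$vessel_sd_hu)
  # shifting both means by a constant changes CNR by c/fat_sd exactly
  shifted <- classify_iq(dplyr::mutate(rois,
    vessel_mean_hu = vessel_mean_hu + 100,
    fat_mean_hu = fat_mean_hu + 100))
  expect_equal(shifted$cnr, out$cnr)
  shifted_vessel <- classify_iq(dplyr::mutate(rois,
    vessel_mean_hu = vessel_mean_hu + 100))
  expect_equal(shifted_vessel$cnr, out$cnr + 100 / rois$fat_sd_hu)
})

test_that("diagnostic boundaries: attenuation inclusive, CNR strict", {
  seg <- tibble::tibble(
    vessel_mean_hu = c(300, 299.9, 263, 400),
    vessel_sd_hu = 40,
    fat_mean_hu = c(-80, -80, -80, 0),
    fat_sd_hu = c(38, 38, 34.3, 40)
  )
  out <- classify_iq(seg)
  expect_equal(out$diagnostic_attenuation, c(TRUE, FALSE, FALSE, TRUE))
  # fourth row: CNR = 400/40 = 10 exactly -> not diagnostic (strict >)
  expect_equal(out$cnr[4], 10)
  expect_false(out$diagnostic_cnr[4])
})

test_that("classification is pure and idempotent", {
  set.seed(3)
  rois <- tibble::tibble(
    vessel_mean_hu = rnorm(5, 330, 40), vessel_sd_hu = runif(5, 30, 50),
    fat_mean_hu = rnorm(5, -80, 10), fat_sd_hu = runif(5, 20, 40),
    assessable = c(TRUE, TRUE, FALSE, TRUE, TRUE)
  )
  once <- classify_iq(rois)
  twice <- classify_iq(once)
  expect_identical(once, twice)
  expect_true(is.na(once$cnr[3]))
  expect_false(once$diagnostic_attenuation[3])
})

test_that("ROI simulation is seeded, complete and degenerate-safe", {
  a <- simulate_roi_set(7.0, 120, 5.319, default_cal, seed = 42)
  b <- simulate_roi_set(7.0, 120, 5.319, default_cal, seed = 42)
  expect_identical(a, b)
  expect_equal(a$segment_id, 1:17)
  expect_equal(sort(unique(a$vessel)), c("Cx", "LAD", "LM", "RCA", "RI"))
  # no dropout -> all assessable
  nz <- iq_noise_config(dropout = rep(0, 17))
  expect_true(all(
    simulate_roi_set(7.0, 120, 5.319, default_cal, nz, seed = 1)$assessable))
  # zero spread -> every segment at the model prediction
  det <- iq_noise_config(sigma_hu = 0, noise_sd_hu = 0,
    fat_sd_hu = 0, fat_noise_sd_hu = 0, dropout = rep(0, 17))
  rois <- simulate_roi_set(7.0, 120, 5.3190608, default_cal, det, seed = 1)
  expect_equal(rois$vessel_mean_hu, rep(350, 17), tolerance = 1e-9)
  expect_equal(rois$fat_mean_hu, rep(-80, 17))
})

test_that("cohort assessable fraction matches the configured dropout", {
  s <- simulate_study(seed = 17)
  segs <- simulate_cohort_iq(s$protocols, default_cal, seed = 18)
  expected <- 1 - mean(default_segment_dropout()) # 0.961
  expect_equal(mean(segs$assessable), expected, tolerance = 0.015)
  expect_equal(nrow(segs), 114 * 17)
})

test_that("cohort summary aggregates per-patient overall quality", {
  # one patient, every assessable segment at 350 HU
  segs <- tibble::tibble(
    patient_id = "A", segment_id = 1:17, assessable = TRUE,
    vessel_mean_hu = 350, vessel_sd_hu = 35, fat_mean_hu = -80,
    fat_sd_hu = 30)
  s1 <- cohort_iq_summary(segs)
  expect_equal(s1$per_patient$mean_hu, 350)
  expect_equal(s1$overall$pct_patients_diagnostic_hu, 100)
  expect_equal(s1$per_patient$mean_snr, 10)
  # two patients at 290 and 310 HU overall -> 50% diagnostic
  segs2 <- dplyr::bind_rows(
    dplyr::mutate(segs, patient_id = "lo", vessel_mean_hu = 290),
    dplyr::mutate(segs, patient_id = "hi", vessel_mean_hu = 310))
  expect_equal(
    cohort_iq_summary(segs2)$overall$pct_patients_diagnostic_hu, 50)
  # a patient with no assessable segments is excluded with a warning
  segs3 <- dplyr::bind_rows(segs,
    dplyr::mutate(segs, patient_id = "none", assessable = FALSE))
  expect_warning(s3 <- cohort_iq_summary(segs3), "excluded")
  expect_equal(nrow(s3$per_patient), 1)
})

test_that("segment CSV reader validates the schema", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "patient_id,segment_id,vessel,vessel_mean_hu,vessel_sd_hu,fat_mean_hu,fat_sd_hu,likert",
    "P1,1,RCA,360,40,-85,30,4",
    "P1,5,LM,340,38,-78,28,"
  ), path)
  segs <- read_segments(path)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$likert[1], 4)
  writeLines(c("patient_id,segment_id", "P1,18"), path)
  expect_error(read_segments(path),
    class = "contrastflow_validation_error")
})
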