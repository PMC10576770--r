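test_that("feature windows enforce the strict 90% coverage gate", {
  series <- rnorm(300, 100, 5)
  # assessment before baseline establishment is rejected
  r <- extract_window(series, t = 30, established_at = 60)
  expect_false(r$ok)
  expect_equal(r$reason, "before_baseline")
  # fully observed window: identity completion of [t-60, t)
  r2 <- extract_window(series, t = 200, established_at = 60)
  expect_true(r2$ok)
  expect_identical(r2$values, series[141:200])
  # 54/60 present (exactly 0.90) rejected; 55/60 accepted
  s54 <- series; s54[141:146] <- NA
  expect_false(extract_window(s54, 200, 60)$ok)
  s55 <- series; s55[141:145] <- NA
  expect_true(extract_window(s55, 200, 60)$ok)
})

test_that("deviation areas match trapezoidal integration of the deviation", {
  # series identical to baseline: all zeros
  z <- deviation_areas(rep(100, 60), 100)
  expect_equal(unlist(z), c(area_above = 0, area_below = 0, mean_dev = 0,
                            dev_at_t = 0))
  # constant +10 deviation: 59 trapezoids of height 10
  d <- deviation_areas(rep(110, 60), 100)
  expect_equal(d$area_above, 590)
  expect_equal(d$area_below, 0)
  expect_equal(d$mean_dev, 10)
  expect_equal(d$dev_at_t, 10)
  # antisymmetric deviation: equal areas
  s <- 100 + seq(-5, 5, length.out = 60)
  d2 <- deviation_areas(s, 100)
  expect_equal(d2$area_above, d2$area_below)
  # random series agree with the brute-force oracle
  set.seed(4)
  for (i in 1:25) {
    x <- rnorm(60, 100, 8)
    got <- deviation_areas(x, 100)
    want <- areas_brute(x, 100)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("deviation features conserve area and are translation-equivariant", {
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(60, 100, 8)
    b <- rnorm(1, 100, 5)
    d <- deviation_areas(x, b)
    # conservation: above - below = trapezoid of d
    dd <- x - b
    expect_equal(d$area_above - d$area_below, sum((dd[-1] + dd[-60]) / 2),
                 tolerance = 1e-10)
    # translation equivariance
    d2 <- deviation_areas(x + 37.5, b + 37.5)
    expect_equal(d, d2, tolerance = 1e-9)
  }
})

test_that("age stratification uses the study's inclusive bounds", {
  expect_equal(stratify_age(44), "20-44")
  expect_equal(stratify_age(45), "45-64")
  expect_equal(stratify_age(64), "45-64")
  expect_equal(stratify_age(65), "65+")
  expect_equal(stratify_age(20), "20-44")
  expect_error(stratify_age(19), "20")
})

test_that("the pain label is CPOT >= 3 on all nine CPOT values", {
  lab <- label_assessment(0:8)
  expect_equal(as.character(lab),
               c(rep("negative", 3), rep("positive", 6)))
  expect_equal(as.character(label_assessment(3)), "positive")
  expect_equal(as.character(label_assessment(2)), "negative")
})

test_that("the feature table has the documented schema and drop logging", {
  v <- data.frame(patient_id = "P1", t_min = 0:299, hr = 80, sbp = 120,
                  mbp = 93, dbp = 65, rr = 16, spo2 = 97)
  a <- data.frame(patient_id = "P1", t_min = c(120L, 30L, 250L),
                  cpot = c(4L, 2L, 1L), rass = c(0L, 0L, NA),
                  cam_icu = NA_character_)
  demo <- data.frame(patient_id = "P1", age = 50, sex = "female")
  bl <- establish_baselines(v)
  ft <- build_feature_table(v, bl, a, demo)
  # one retained assessment: 5 vitals x 5 deviation features + sex,
  # age_group, rass; plus identifiers, cpot and the label.
  # t=30 precedes the baseline; t=250 has no RASS within 60 min.
  expect_equal(nrow(ft$features), 1)
  expect_equal(ft$features$t_min, 120L)
  feat_cols <- setdiff(names(ft$features),
                       c("patient_id", "t_min", "cpot", "label"))
  expect_length(feat_cols, 28)
  expect_true(all(c("hr_value", "hr_dev", "hr_area_above", "hr_area_below",
                    "hr_mean_dev", "sex", "age_group", "rass") %in% feat_cols))
  expect_equal(names(ft$features)[ncol(ft$features)], "label")
  expect_setequal(ft$drops$reason, c("before_baseline", "no_rass"))
})

test_that("assessments lacking RASS within tolerance are dropped and logged", {
  v <- data.frame(patient_id = "P1", t_min = 0:299, hr = 80, sbp = 120,
                  mbp = 93, dbp = 65, rr = 16, spo2 = 97)
  a <- data.frame(patient_id = "P1", t_min = c(120L, 250L),
                  cpot = c(4L, 5L), rass = c(0L, NA), cam_icu = NA_character_)
  demo <- data.frame(patient_id = "P1", age = 70, sex = "male")
  bl <- establish_baselines(v)
  ft <- build_feature_table(v, bl, a, demo)
  expect_equal(nrow(ft$features), 1)
  expect_equal(ft$features$t_min, 120L)
  expect_equal(ft$drops$reason, "no_rass")
  # with a RASS within the tolerance the nearest value is borrowed
  a2 <- data.frame(patient_id = "P1", t_min = c(200L, 250L),
                   cpot = c(4L, 5L), rass = c(-2L, NA), cam_icu = NA_character_)
  ft2 <- build_feature_table(v, bl, a2, demo)
  expect_equal(nrow(ft2$features), 2)
  expect_equal(ft2$features$rass, c(-2L, -2L))
  # unknown patient errors
  a3 <- data.frame(patient_id = "P9", t_min = 120L, cpot = 4L, rass = 0L,
                   cam_icu = NA_character_)
  expect_error(build_feature_table(v, bl, a3, demo), "unknown patient")
})

test_that("feature rows equal an independent window recomputation on a cohort", {
  pr <- small_products()
  ft <- pr$features
  bl <- pr$baselines$objects
  for (i in seq_len(min(nrow(ft), 40))) {
    pid <- ft$patient_id[i]; t <- ft$t_min[i]
    pv <- pr$filtered[pr$filtered$patient_id == pid, ]
    for (v in c("hr", "sbp", "mbp", "dbp", "rr")) {
      raw <- rep(NA_real_, 60)
      sel <- pv$t_min >= t - 60 & pv$t_min < t
      raw[pv$t_min[sel] - (t - 60) + 1] <- pv[[v]][sel]
      comp <- interp_brute(raw)
      want <- areas_brute(comp, bl[[pid]]$baselines[[v]])
      expect_equal(ft[[paste0(v, "_area_above")]][i], want$area_above,
                   tolerance = 1e-9)
      expect_equal(ft[[paste0(v, "_area_below")]][i], want$area_below,
                   tolerance = 1e-9)
      expect_equal(ft[[paste0(v, "_mean_dev")]][i], want$mean_dev,
                   tolerance = 1e-9)
      expect_equal(ft[[paste0(v, "_dev")]][i], want$dev_at_t, tolerance = 1e-9)
      expect_equal(ft[[paste0(v, "_value")]][i], comp[60], tolerance = 1e-9)
    }
  }
})
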