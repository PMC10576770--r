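test_that("roc_auc equals pairwise concordance on known cases", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1.0)
  expect_equal(roc_auc(c(5, 5, 5, 5), c(0, 1, 0, 1)), 0.5)  # all tied
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("roc_auc matches the brute-force oracle, pROC, and symmetry", {
  set.seed(21)
  for (i in 1:60) {
    n <- sample(5:200, 1)
    labs <- c(TRUE, FALSE, runif(n - 2) < 0.4)
    scores <- round(rnorm(n), sample(c(1, 2, 8), 1))  # induce ties sometimes
    a <- roc_auc(scores, labs)
    expect_equal(a, auc_brute(scores, labs), tolerance = 1e-12)
    # complement symmetry (holds with ties at 1/2 too)
    expect_equal(roc_auc(-scores, labs), 1 - a, tolerance = 1e-12)
  }
  set.seed(22)
  labs <- runif(500) < 0.3
  scores <- rnorm(500)
  expect_equal(roc_auc(scores, labs),
               as.numeric(pROC::auc(pROC::roc(labs, scores, quiet = TRUE))),
               tolerance = 1e-10)
  # label-independent scores give chance performance
  set.seed(23)
  labs2 <- runif(10000) < 0.5
  expect_lt(abs(roc_auc(rnorm(10000), labs2) - 0.5), 0.02)
})

test_that("confusion metrics follow the 2x2 arithmetic at any threshold", {
  scores <- c(0.9, 0.8, 0.7, 0.2, 0.8, 0.9, rep(0.1, 8))
  labels <- c(rep("positive", 4), rep("negative", 10))
  r <- confusion_at_threshold(scores, labels, threshold = 0.6)
  # TP=3, FN=1, TN=8, FP=2
  expect_equal(r$sensitivity, 0.75)
  expect_equal(r$specificity, 0.8)
  expect_equal(r$ppv, 0.6)
  expect_equal(r$npv, 8 / 9)
  # threshold extremes
  r0 <- confusion_at_threshold(scores, labels, threshold = 0)
  expect_equal(c(r0$sensitivity, r0$specificity), c(1, 0))
  r1 <- confusion_at_threshold(scores, labels, threshold = 1 + 1e-9)
  expect_equal(c(r1$sensitivity, r1$specificity), c(0, 1))
  # default threshold is the Youden point
  ry <- confusion_at_threshold(scores, labels)
  js <- sapply(sort(unique(scores)), function(th) {
    p <- scores >= th
    sum(p & labels == "positive") / 4 + sum(!p & labels == "negative") / 10 - 1
  })
  expect_equal(ry$sensitivity + ry$specificity - 1, max(js))
})

test_that("harmonic mean matches the closed form and its inequalities", {
  expect_equal(harmonic_mean_metrics(0.8, 0.8), 0.8)
  expect_equal(harmonic_mean_metrics(0.730, 0.945),
               2 * 0.730 * 0.945 / (0.730 + 0.945))
  expect_equal(round(harmonic_mean_metrics(0.730, 0.945), 4), 0.8237)
  set.seed(31)
  for (i in 1:20) {
    ab <- runif(2, 0.05, 1)
    h <- harmonic_mean_metrics(ab[1], ab[2])
    expect_lte(h, sqrt(prod(ab)) + 1e-12)          # <= geometric
    expect_lte(sqrt(prod(ab)), mean(ab) + 1e-12)   # <= arithmetic
  }
  expect_error(harmonic_mean_metrics(0, 0.5), "non-positive")
})

test_that("AUROC banding uses 0.7/0.8 boundaries falling upward", {
  expect_equal(classify_auroc(0.903), "high")
  expect_equal(classify_auroc(0.75), "moderate")
  expect_equal(classify_auroc(0.5), "low")
  expect_equal(classify_auroc(0.7), "moderate")
  expect_equal(classify_auroc(0.8), "high")
})

test_that("CPOT improvement grouping is a decrease of at least 1", {
  expect_equal(group_by_cpot_improvement(4, 2), "improvement")
  expect_equal(group_by_cpot_improvement(2, 2), "non_improvement")
  expect_equal(group_by_cpot_improvement(3, 2), "improvement")
  expect_equal(group_by_cpot_improvement(2, 4), "non_improvement")
  # exhaustive and exclusive over all score pairs
  g <- outer(0:8, 0:8, group_by_cpot_improvement)
  expect_true(all(g %in% c("improvement", "non_improvement")))
})

test_that("a single flat bolus yields one non-improvement record", {
  pi <- data.frame(patient_id = "P1", t_min = 0:400,
                   pain_index = rep(0.5, 401))
  ev <- data.frame(patient_id = "P1", t_min = 200L, drug = "fentanyl",
                   dose_ug = 50)
  a <- data.frame(patient_id = "P1", t_min = c(190L, 260L), cpot = c(5L, 5L),
                  rass = 0L, cam_icu = NA_character_)
  r <- fentanyl_response_analysis(pi, ev, a)
  expect_equal(nrow(r$records), 1)
  expect_equal(r$records$group, "non_improvement")
  expect_equal(r$records$cpot_pre, 5L)
  expect_equal(r$records$cpot_post, 5L)
  expect_equal(nrow(r$dropped), 0)
})

test_that("boluses without pre/post CPOT or with co-analgesia are excluded", {
  pi <- data.frame(patient_id = "P1", t_min = 0:600,
                   pain_index = rep(0.4, 601))
  a <- data.frame(patient_id = "P1", t_min = c(190L, 260L), cpot = c(5L, 3L),
                  rass = 0L, cam_icu = NA_character_)
  # no post CPOT (last assessment at 260 precedes the bolus at 280)
  ev1 <- data.frame(patient_id = "P1", t_min = 280L, drug = "fentanyl",
                    dose_ug = 50)
  r1 <- fentanyl_response_analysis(pi, ev1, a)
  expect_equal(nrow(r1$records), 0)
  expect_equal(r1$dropped$reason, "no_post_cpot")
  # another analgesic inside the window
  ev2 <- data.frame(patient_id = c("P1", "P1"), t_min = c(200L, 230L),
                    drug = c("fentanyl", "ketamine"), dose_ug = c(50, 10))
  r2 <- fentanyl_response_analysis(pi, ev2, a)
  expect_true("other_analgesic_in_window" %in% r2$dropped$reason)
  # dose outside 25-100 ug
  ev3 <- data.frame(patient_id = "P1", t_min = 200L, drug = "fentanyl",
                    dose_ug = 500)
  r3 <- fentanyl_response_analysis(pi, ev3, a)
  expect_equal(r3$dropped$reason, "dose_out_of_range")
})

test_that("group trajectories are invariant to record ordering", {
  set.seed(41)
  mk <- function(pid, t0, drop) {
    data.frame(patient_id = pid, t_min = (t0 - 60):(t0 + 60),
               pain_index = 0.6 - drop * pmax(0, ((t0 - 60):(t0 + 60)) - t0) / 600)
  }
  pi <- rbind(mk("P1", 100, 1), mk("P2", 300, 0))
  ev <- data.frame(patient_id = c("P1", "P2"), t_min = c(100L, 300L),
                   drug = "fentanyl", dose_ug = 50)
  a <- data.frame(patient_id = c("P1", "P1", "P2", "P2"),
                  t_min = c(90L, 160L, 290L, 360L),
                  cpot = c(5L, 2L, 4L, 4L), rass = 0L, cam_icu = NA_character_)
  r1 <- fentanyl_response_analysis(pi, ev, a)
  shuffle <- sample(nrow(pi))
  r2 <- fentanyl_response_analysis(pi[shuffle, ], ev[2:1, ], a)
  expect_equal(r1$trajectories,
               r2$trajectories[order(r2$trajectories$group,
                                     r2$trajectories$minute_rel), ],
               ignore_attr = TRUE)
  # grouping exhaustive and exclusive
  expect_setequal(r1$records$group, c("improvement", "non_improvement"))
})
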