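test_that("risk levels follow the interval-touching rule with closed boundaries", {
  # Estimate at the threshold is the canonical doubtful case.
  r <- classify_sample(11, threshold = 11, etr = 1)
  expect_identical(r$level, "doubtful")
  expect_true(r$suspect)
  expect_identical(classify_sample(8, 11, 1)$level, "high_risk")
  expect_identical(classify_sample(13.5, 11, 1)$level, "low_risk")
  # Boundary contact (|est - T| = 2 ETR) counts as suspect on both sides.
  expect_identical(classify_sample(9, 11, 1)$level, "doubtful")
  expect_identical(classify_sample(13, 11, 1)$level, "doubtful")
  expect_identical(classify_sample(c(8.999, 13.001), 11, 1)$level,
                   c("high_risk", "low_risk"))
})

test_that("every sample lands in exactly one level and counts partition", {
  withr::with_seed(1, {
    est <- runif(200, 4, 18)
    cls <- classify_sample(est, threshold = 11, etr = 0.8)
    counts <- table(factor(cls$level,
                           levels = c("high_risk", "doubtful", "low_risk")))
    expect_identical(sum(counts), 200L)
    expect_identical(sum(cls$suspect), unname(counts[["doubtful"]]))
  })
})

test_that("zero ETR reduces the scheme to the two-class rule except at the threshold", {
  est <- c(10.999999, 11.000001, 11, 9, 14)
  cls <- classify_sample(est, threshold = 11, etr = 0)
  expect_identical(cls$level,
                   c("high_risk", "low_risk", "doubtful", "high_risk",
                     "low_risk"))
})

test_that("aggregate indices reproduce their defining ratios", {
  # Three high-risk samples, all truly anemic.
  o <- outcome_table(rep("high_risk", 3), rep("anemic", 3))
  expect_equal(compute_indices(o)$high_risk_index, 1)
  # 10 samples with 4 suspect: doubtful index 0.6.
  o2 <- outcome_table(c(rep("doubtful", 4), rep("high_risk", 3),
                        rep("low_risk", 3)),
                      c("anemic", "anemic", "nonanemic", "nonanemic",
                        rep("anemic", 3),
                        "nonanemic", "nonanemic", "anemic"))
  idx <- compute_indices(o2)
  expect_equal(idx$doubtful_index, 0.6)
  expect_identical(idx$n_suspect, 4L)
  expect_equal(idx$high_risk_index, 1)
  expect_equal(idx$low_risk_index, 2 / 3)
  expect_error(compute_indices(o2[0, ]), "empty")
})

test_that("an all-suspect outcome set leaves the confident indices undefined", {
  o <- outcome_table(rep("doubtful", 5),
                     c("anemic", "anemic", "nonanemic", "nonanemic",
                       "anemic"))
  idx <- compute_indices(o)
  expect_true(is.nan(idx$high_risk_index))
  expect_true(is.nan(idx$low_risk_index))
  expect_true(idx$undefined_high && idx$undefined_low)
  expect_equal(idx$doubtful_index, 0)
  conf <- nonsuspect_confusion(o)
  expect_true(is.nan(conf$sensitivity) && is.nan(conf$specificity))
  expect_true(conf$undefined_sensitivity && conf$undefined_specificity)
})

test_that("nonsuspect sensitivity and specificity follow the usual definitions", {
  o <- outcome_table(c(rep("high_risk", 5), rep("low_risk", 5)),
                     c(rep("anemic", 5), rep("nonanemic", 5)))
  conf <- nonsuspect_confusion(o)
  expect_equal(conf$sensitivity, 1)
  expect_equal(conf$specificity, 1)
  # 4 anemic nonsuspect samples, 3 caught in high risk: sensitivity 0.75.
  o2 <- outcome_table(c("high_risk", "high_risk", "high_risk", "low_risk",
                        "low_risk"),
                      c(rep("anemic", 4), "nonanemic"))
  expect_equal(nonsuspect_confusion(o2)$sensitivity, 0.75)
  # Suspect samples are excluded from the confusion counts entirely.
  o3 <- rbind(o2, outcome_table(rep("doubtful", 10), rep("anemic", 10)))
  expect_equal(nonsuspect_confusion(o3)$sensitivity, 0.75)
  # No nonsuspect anemic samples: sensitivity undefined and flagged.
  o4 <- outcome_table(c("low_risk", "doubtful"), c("nonanemic", "anemic"))
  conf4 <- nonsuspect_confusion(o4)
  expect_true(is.nan(conf4$sensitivity))
  expect_true(conf4$undefined_sensitivity)
})

test_that("the error tolerance range comes from training Hb or the config", {
  expect_equal(compute_etr(c(10, 12)), sqrt(2))
  expect_equal(compute_etr(rep(9, 5)), 0)
  expect_equal(compute_etr(c(1, 2, 3), res_config(etr = 0.5)), 0.5)
  expect_error(compute_etr(10), "at least 2")
  expect_error(res_config(etr = -1), "nonnegative")
  expect_error(res_config(threshold = 0), "positive")
})

test_that("suspect count is monotone nondecreasing in the ETR", {
  for (seed in 1:25) {
    withr::with_seed(seed, {
      est <- runif(40, 4, 18)
      etr <- runif(1, 0.1, 2)
      n1 <- sum(classify_sample(est, 11, etr)$suspect)
      n2 <- sum(classify_sample(est, 11, 2 * etr)$suspect)
      expect_gte(n2, n1)
    })
  }
})

test_that("the aggregate report prints and serializes", {
  o <- outcome_table(c("high_risk", "low_risk", "doubtful"),
                     c("anemic", "nonanemic", "anemic"))
  rep <- res_report(o, etr = 0.7)
  expect_s3_class(rep, "res_report")
  expect_output(print(rep), "doubtful index", ignore.case = TRUE)
  json <- withr::local_tempfile(fileext = ".json")
  csvf <- withr::local_tempfile(fileext = ".csv")
  write_res_outputs(o, rep, csv_path = csvf, json_path = json)
  back <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(back$n_suspect, 1)
  expect_identical(nrow(read.csv(csvf)), 3L)
})
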