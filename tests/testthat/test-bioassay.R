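test_that("net SSR response is stimulation minus spontaneous rate", {
  expect_equal(ssr_response(120, 20), 100)
  expect_equal(ssr_response(10, 40), -30) # inhibition is legal
  # 60 and 10 spikes in 500 ms windows scale to 120 and 20 spikes/s
  expect_equal(ssr_response(60 / 0.5, 10 / 0.5), 100)
  expect_error(ssr_response(-1, 0), "non-negative")
})

test_that("Kruskal-Wallis H matches the hand rank computation", {
  panel <- data.frame(stimulus = c("solvent", "solvent", "odor_01", "odor_01"),
                      role = c("solvent_control", "solvent_control",
                               "odorant", "odorant"),
                      response = c(1, 2, 9, 10))
  out <- activity_call(panel)
  # ranks 1,2 vs 3,4; H = 12/(4*5) * (2*(1.5-2.5)^2 + 2*(3.5-2.5)^2) = 2.4
  expect_equal(attr(out, "kw_statistic"), 2.4, tolerance = 1e-12)
})

test_that("a fully tied panel yields H = 0 and no active flags", {
  panel <- data.frame(stimulus = rep(c("solvent", "odor_01"), each = 3),
                      role = rep(c("solvent_control", "odorant"), each = 3),
                      response = rep(5, 6))
  out <- activity_call(panel)
  expect_equal(attr(out, "kw_statistic"), 0)
  expect_false(any(out$active))
})

test_that("a clearly separated odorant is called active at alpha 0.05", {
  panel <- data.frame(
    stimulus = rep(c("solvent", "odor_01"), each = 10),
    role = rep(c("solvent_control", "odorant"), each = 10),
    response = c(rnorm(10, 0, 1) |> (\(x) x - max(x))(), # all below zero
                 seq(50, 59)))
  out <- activity_call(panel, alpha = 0.05)
  expect_true(out$active[out$stimulus == "odor_01"])
  # exact rank-sum tail for complete separation at n = 10 vs 10
  expect_lt(out$p[1], 2 / choose(20, 10) + 1e-12)
})

test_that("under-replicated odorants are excluded with a warning", {
  panel <- data.frame(stimulus = c("solvent", "solvent", "odor_01", "odor_02",
                                   "odor_02"),
                      role = c("solvent_control", "solvent_control", "odorant",
                               "odorant", "odorant"),
                      response = c(0, 1, 50, 60, 70))
  expect_warning(out <- activity_call(panel), "odor_01")
  expect_equal(out$stimulus, "odor_02")
})

test_that("choice test matches the closed-form chi-squared", {
  ct <- choice_test(20, 10)
  expect_equal(ct$chi2, 10 / 3, tolerance = 1e-9)
  expect_equal(ct$p, pchisq(10 / 3, 1, lower.tail = FALSE), tolerance = 1e-9)
  expect_equal(round(ct$p, 3), 0.068)

  expect_equal(choice_test(15, 15)$chi2, 0)
  expect_equal(choice_test(15, 15)$p, 1)

  ct10 <- choice_test(10, 0)
  expect_equal(ct10$chi2, 10)
  expect_equal(round(ct10$p, 4), 0.0016)

  sym <- choice_test(10, 20)
  expect_equal(sym$chi2, ct$chi2)
  expect_equal(sym$p, ct$p)

  expect_error(choice_test(0, 0), "both counts zero")
})

test_that("choice test holds its type-I error under the binomial null", {
  set.seed(2024)
  rejections <- vapply(1:2000, function(i) {
    k <- rbinom(1, 30, 0.5)
    choice_test(k, 30 - k)$p < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.035)
  expect_lt(mean(rejections), 0.065)
})

test_that("paired arm-time test matches the closed form and is antisymmetric", {
  odor <- c(2, 3, 5); ctrl <- c(1, 2, 3) # differences 1, 1, 2
  tt <- arm_time_test(odor, ctrl)
  expect_equal(tt$t, 4, tolerance = 1e-9)
  expect_equal(tt$df, 2)
  expect_equal(round(tt$p, 3), 0.057)
  expect_equal(tt$mean_diff, 4 / 3, tolerance = 1e-12)

  swapped <- arm_time_test(ctrl, odor)
  expect_equal(swapped$t, -tt$t, tolerance = 1e-12)
  expect_equal(swapped$p, tt$p, tolerance = 1e-12)

  expect_error(arm_time_test(odor, odor), "degenerate")
  expect_error(arm_time_test(1, 2), "at least 2")
})

test_that("familywise error stays controlled when nothing is active", {
  flagged <- vapply(1:500, function(s) {
    assay <- gen_bioassay(n_odorants = 5, n_replicates = 6,
                          active_ids = integer(0), effect = 0, rate_sd = 10,
                          seed = 7000 + s)
    any(activity_call(assay$panel)$active)
  }, logical(1))
  expect_lte(mean(flagged), 0.07)
})

test_that("a strong agonist is detected with high power", {
  hit <- vapply(1:200, function(s) {
    assay <- gen_bioassay(n_odorants = 3, n_replicates = 10,
                          active_ids = 2, effect = 100, rate_sd = 10,
                          seed = 8000 + s)
    out <- activity_call(assay$panel)
    out$active[out$stimulus == "odor_02"]
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("bioassay csv dialects read back as analyzable structures", {
  assay <- gen_bioassay(2, 5, active_ids = 1, seed = 3)
  ssr_path <- withr::local_tempfile(fileext = ".csv")
  write.csv(assay$panel, ssr_path, row.names = FALSE)
  panel <- read_ssr_panel(ssr_path)
  expect_s3_class(activity_call(panel), "data.frame")

  beh_path <- withr::local_tempfile(fileext = ".csv")
  beh <- data.frame(larva_id = sprintf("l%d", 1:5),
                    choice = c("odorant", "odorant", "control", "none", "odorant"),
                    time_odorant = c(100, 150, 30, 0, 200),
                    time_control = c(50, 60, 90, 0, 40))
  write.csv(beh, beh_path, row.names = FALSE)
  ch <- read_choice_assay(beh_path)
  expect_equal(unname(ch$counts), c(3, 1))
  expect_equal(ch$n_no_choice, 1)
  expect_equal(nrow(ch$times), 4)
})
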