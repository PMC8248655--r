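# Baseline medians and PPP score arithmetic.

test_that("baseline discharge median uses discharging arrivals only", {
  pop <- toy_arrivals(5, vessel_type = "container", gross_tonnage = 30000,
                      bwd_volume = c(0, 0, 500, 1000, 1500))
  base <- compute_baseline(pop)
  expect_identical(base$med_bwd, 1000)
  expect_identical(base$n_discharging, 3L)
  expect_identical(base$n_arrivals, 5L)
})

test_that("baseline TWSA median is the median of per-arrival TWSA", {
  gt <- c(1000, 8000, 27000)
  pop <- toy_arrivals(3, vessel_type = "container", gross_tonnage = gt,
                      bwd_volume = 100)
  base <- compute_baseline(pop)
  expect_equal(base$med_twsa, 10.66 * 8000^0.6501 * 1.09, tolerance = 1e-12)
})

test_that("even-count medians are midpoints of the central values", {
  pop <- toy_arrivals(4, vessel_type = "container", gross_tonnage = 30000,
                      bwd_volume = c(100, 200, 400, 800))
  expect_identical(compute_baseline(pop)$med_bwd, 300)
})

test_that("an all-zero-discharge population is a loud error, not a fallback", {
  pop <- toy_arrivals(4, vessel_type = "tanker", gross_tonnage = 20000,
                      bwd_volume = 0)
  expect_error(compute_baseline(pop), class = "pppscore_validation_error")
  expect_error(compute_baseline(pop, bwd_policy = "all"),
               class = "pppscore_validation_error")
  expect_error(compute_baseline(pop[0, ]),
               class = "pppscore_validation_error")
})

test_that("the all-arrivals policy uses zeros when the median stays positive", {
  pop <- toy_arrivals(5, vessel_type = "container", gross_tonnage = 30000,
                      bwd_volume = c(0, 0, 500, 1000, 1500))
  expect_identical(compute_baseline(pop, bwd_policy = "all")$med_bwd, 500)
})

test_that("per-vessel medians damp frequent callers", {
  pop <- toy_arrivals(4, vessel_type = "container", gross_tonnage = 30000,
                      bwd_volume = c(100, 200, 300, 1000),
                      vessel_id = c("A", "A", "A", "B"))
  base <- compute_baseline(pop, median_unit = "vessel")
  # vessel medians {200, 1000} -> 600; per-arrival would give 250
  expect_identical(base$med_bwd, 600)
  expect_identical(compute_baseline(pop)$med_bwd, 250)
})

test_that("an arrival at both medians scores exactly 2", {
  pop <- toy_arrivals(7, vessel_type = "container",
                      gross_tonnage = c(1e3, 5e3, 2e4, 3e4, 5e4, 8e4, 1e5),
                      bwd_volume = c(0, 0, 100, 900, 400, 1600, 2500))
  base <- compute_baseline(pop)
  at_median <- toy_arrivals(1, vessel_type = "container",
                            gross_tonnage = 3e4, bwd_volume = 900)
  scored <- score_arrival(at_median, base)
  expect_identical(scored$ppp_score, 2)
  expect_identical(scored$bw_component, 1)
  expect_identical(scored$bf_component, 1)
})

test_that("a zero-discharge arrival's score is its biofouling component", {
  base <- fixed_baseline(med_bwd = 800, med_twsa = 8000)
  scored <- score_arrival(toy_arrivals(1, bwd_volume = 0), base)
  expect_identical(scored$bw_component, 0)
  expect_identical(scored$ppp_score, scored$bf_component)
})

test_that("score arithmetic matches the hand-worked example", {
  # BWD 2000 against median 800, TWSA 12094 against median 8000
  base <- fixed_baseline(med_bwd = 800, med_twsa = 8000)
  arr <- barge_arrival(twsa = 12094, bwd_volume = 2000)
  scored <- score_arrival(arr, base)
  expect_equal(scored$bw_component, 2.5, tolerance = 1e-12)
  expect_equal(scored$bf_component, 1.51175, tolerance = 1e-12)
  expect_equal(scored$ppp_score, 4.01175, tolerance = 1e-12)
  # the score is the exact sum of its components
  expect_identical(scored$ppp_score,
                   scored$bw_component + scored$bf_component)
})

test_that("components are scale invariant in their own units", {
  fleet <- generate_fleet(fleet_config(n_arrivals = 120), seed = 5)
  base <- compute_baseline(fleet)
  scored <- score_batch(fleet, base)
  for (c in c(0.25, 3, 1000)) {
    scaled <- fleet
    scaled$bwd_volume <- scaled$bwd_volume * c
    rescored <- score_batch(scaled, compute_baseline(scaled))
    expect_equal(rescored$bw_component, scored$bw_component,
                 tolerance = 1e-12)
  }
})

test_that("scores increase with discharge volume and with tonnage", {
  base <- fixed_baseline(med_bwd = 500, med_twsa = 5000)
  bwd <- seq(0, 5000, by = 500)
  s1 <- score_batch(toy_arrivals(length(bwd), bwd_volume = bwd,
                                 gross_tonnage = 30000), base)
  expect_true(all(diff(s1$ppp_score) > 0))
  gt <- seq(5000, 100000, by = 5000)
  s2 <- score_batch(toy_arrivals(length(gt), gross_tonnage = gt,
                                 bwd_volume = 100), base)
  expect_true(all(diff(s2$ppp_score) > 0))
})

test_that("scoring is pure: identical inputs give identical outputs", {
  fleet <- generate_fleet(fleet_config(n_arrivals = 60), seed = 9)
  base <- compute_baseline(fleet)
  expect_identical(score_batch(fleet, base), score_batch(fleet, base))
})

test_that("batch scoring preserves order, collects failures, honors strict", {
  base <- fixed_baseline(med_bwd = 500, med_twsa = 5000)
  good <- toy_arrivals(3, gross_tonnage = c(2e4, 4e4, 6e4),
                       bwd_volume = 100, arrival_id = c("A1", "A2", "A3"))
  bad <- toy_arrivals(1, vessel_type = "barge_tug", arrival_id = "A9")
  batch <- dplyr::bind_rows(good[1:2, ], bad, good[3, ])
  expect_warning(scored <- score_batch(batch, base), "could not be scored")
  expect_identical(scored$arrival_id, c("A1", "A2", "A3"))
  failures <- attr(scored, "failures")
  expect_identical(failures$arrival_id, "A9")
  err <- expect_error(score_batch(batch, base, strict = TRUE),
                      class = "pppscore_scoring_error")
  expect_identical(err$arrival_id, "A9")
  # empty in, empty out
  empty <- score_batch(batch[0, ], base)
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("twsa", "ppp_score") %in% names(empty)))
})

test_that("scoring the baseline population gives median bf component 1", {
  pop <- toy_arrivals(7, vessel_type = "tanker",
                      gross_tonnage = c(5e3, 1e4, 2e4, 3e4, 5e4, 7e4, 9e4),
                      bwd_volume = c(0, 0, 100, 300, 700, 1500, 3100))
  scored <- score_batch(pop, compute_baseline(pop))
  expect_identical(stats::median(scored$bf_component), 1)
})

test_that("baselines freeze to YAML and restore intact", {
  pop <- toy_arrivals(5, gross_tonnage = c(1, 2, 3, 4, 5) * 1e4,
                      bwd_volume = c(0, 10, 20, 30, 40),
                      arrival_date = as.Date("2015-06-01") + 0:4)
  base <- compute_baseline(pop)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_baseline(base, path)
  back <- read_baseline(path)
  expect_equal(back$med_bwd, base$med_bwd)
  expect_equal(back$med_twsa, base$med_twsa)
  expect_identical(back$window_start, base$window_start)
  expect_identical(back$bwd_policy, base$bwd_policy)
})
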