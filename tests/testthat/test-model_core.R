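# Wetted surface area estimation, niche augmentation, regression refits.

test_that("power-law WSA matches hand-calculator values", {
  # frozen from independent evaluation of m * GT^b
  expect_equal(estimate_wsa_from_gt(50000, "container"),
               12093.655816909999, tolerance = 1e-12)
  expect_equal(estimate_wsa_from_gt(50000, "passenger"),
               10079.678792058321, tolerance = 1e-12)
  expect_equal(estimate_wsa_from_gt(50000, "general"),
               9840.88352554884, tolerance = 1e-12)
  expect_equal(estimate_wsa_from_gt(c(1e3, 1e4, 1e5), "bulker"),
               c(1159.5547494016994, 4939.594052628126, 21042.205568429363),
               tolerance = 1e-12)
})

test_that("WSA at GT = 1 returns the slope m for every regression type", {
  params <- vessel_type_params()
  for (t in c("general", "passenger", "roro", "bulker", "container",
              "tanker")) {
    expect_identical(estimate_wsa_from_gt(1, t),
                     params$m[params$type_code == t])
  }
})

test_that("WSA is strictly increasing in gross tonnage for every type", {
  gt <- sort(exp(stats::runif(50, log(100), log(2e5))))
  for (t in c("general", "passenger", "roro", "bulker", "container",
              "tanker")) {
    wsa <- estimate_wsa_from_gt(gt, t)
    expect_true(all(diff(wsa) > 0), info = t)
  }
})

test_that("WSA estimation rejects bad tonnage and direct-route types", {
  expect_error(estimate_wsa_from_gt(0, "tanker"),
               class = "pppscore_domain_error")
  expect_error(estimate_wsa_from_gt(-10, "tanker"),
               class = "pppscore_domain_error")
  expect_error(estimate_wsa_from_gt(5000, "atb"),
               class = "pppscore_unsupported_route")
  expect_error(estimate_wsa_from_gt(5000, "Barge+Tug"),
               class = "pppscore_unsupported_route")
})

test_that("direct hull WSA matches the spreadsheet oracle", {
  # frozen from an independent spreadsheet evaluation of the formula
  h <- hull_params(100, 30, 5, 0.99, 0.90, 0.92)
  expect_equal(compute_direct_wsa(h), 3530.7805797185642, tolerance = 1e-12)
  hb <- hull_params(100, 30, 5, 0.99, 0.90, 0.92, bulb_transverse_area = 40)
  expect_equal(compute_direct_wsa(hb), 3636.558357496342, tolerance = 1e-12)
})

test_that("direct hull WSA is linear in length when the bulb term vanishes", {
  h1 <- hull_params(100, 30, 5, 0.99, 0.90, 0.92)
  h2 <- hull_params(200, 30, 5, 0.99, 0.90, 0.92)
  expect_equal(compute_direct_wsa(h2), 2 * compute_direct_wsa(h1))
})

test_that("direct hull WSA agrees with a one-line evaluation on random hulls", {
  set.seed(11)
  for (i in 1:100) {
    L <- stats::runif(1, 20, 300)
    B <- stats::runif(1, 5, 50)
    T <- stats::runif(1, 2, 15)
    cm <- stats::runif(1, 0.7, 1)
    cb <- stats::runif(1, 0.4, 0.99)
    cwp <- stats::runif(1, 0.6, 1)
    abt <- stats::runif(1, 0, 60)
    oracle <- L * (2 * T + B) * sqrt(cm) *
      (0.453 + 0.4425 * cb - 0.2862 * cm - 0.003467 * B / T +
         0.3696 * cwp) + 2.38 * abt / cb
    expect_equal(compute_direct_wsa(hull_params(L, B, T, cm, cb, cwp, abt)),
                 oracle, tolerance = 1e-15)
  }
})

test_that("hull validation names missing fields and rejects bad values", {
  err <- expect_error(
    compute_direct_wsa(list(length_waterline = 100, beam = 30)),
    class = "pppscore_validation_error")
  expect_match(conditionMessage(err), "draft")
  expect_match(conditionMessage(err), "midship_coeff")
  expect_error(hull_params(100, 30, 5, 1.2, 0.9, 0.92),
               class = "pppscore_validation_error")
  expect_error(hull_params(-5, 30, 5, 0.99, 0.9, 0.92),
               class = "pppscore_validation_error")
})

test_that("TWSA augments WSA by the niche proportion", {
  expect_identical(compute_twsa(1000, 0), 1000)
  expect_identical(compute_twsa(1000, 0.09), 1090)
  expect_identical(compute_twsa(10000, 0.27), 12700)
  # TWSA >= WSA, equality iff niche proportion is zero
  w <- stats::runif(50, 1, 1e5)
  p <- stats::runif(50, 0, 0.99)
  expect_true(all(compute_twsa(w, p) >= w))
  expect_true(all(compute_twsa(w, p)[p > 0] > w[p > 0]))
  expect_error(compute_twsa(-1, 0.1), class = "pppscore_domain_error")
  expect_error(compute_twsa(100, 1), class = "pppscore_domain_error")
})

test_that("barge+tug TWSA applies per-component niche proportions", {
  expect_equal(compute_twsa_composite(1000, 100), 1033 + 125)
  expect_equal(compute_twsa_composite(2000, 200),
               2 * compute_twsa_composite(1000, 100))
  expect_equal(compute_twsa_composite(1000, 100, niche_mode = "summed"),
               1100 * 1.283)
  expect_error(compute_twsa_composite(1000, 0),
               class = "pppscore_domain_error")
  expect_error(compute_twsa_composite(1000, NA),
               class = "pppscore_domain_error")
})

test_that("regression refit recovers noiseless power-law parameters", {
  gt <- c(1e3, 1e4, 1e5)
  fit <- refit_regression(gt, 15 * gt^0.6294)
  expect_equal(fit$m, 15, tolerance = 1e-7)
  expect_equal(fit$b, 0.6294, tolerance = 1e-7)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # every packaged regression type is recoverable from its own curve
  params <- vessel_type_params()
  gt <- exp(seq(log(500), log(2e5), length.out = 20))
  for (t in c("general", "passenger", "roro", "bulker", "container",
              "tanker")) {
    fit <- refit_regression(gt, estimate_wsa_from_gt(gt, t))
    expect_equal(fit$m, params$m[params$type_code == t], tolerance = 1e-6)
    expect_equal(fit$b, params$b[params$type_code == t], tolerance = 1e-6)
  }
})

test_that("regression refit tolerates multiplicative lognormal noise", {
  set.seed(21)
  gt <- exp(stats::runif(500, log(1e3), log(1e5)))
  wsa <- 15 * gt^0.6294 * stats::rlnorm(500, 0, 0.2)
  fit <- refit_regression(gt, wsa)
  expect_lt(abs(fit$b - 0.6294), 0.02)
})

test_that("regression refit validates its inputs", {
  expect_error(refit_regression(c(1e3, 1e4), c(100, 200)),
               class = "pppscore_validation_error")
  expect_error(refit_regression(c(1e3, -1, 1e5), c(100, 200, 300)),
               class = "pppscore_validation_error")
  expect_error(refit_regression(c(1e3, 1e4, 1e5), c(100, 200)),
               class = "pppscore_validation_error")
})

test_that("vessel-type normalization maps synonyms and rejects strangers", {
  expect_identical(normalize_vessel_type(c("RO-RO", "roro", "Auto Carrier")),
                   rep("roro", 3))
  expect_identical(normalize_vessel_type("Barge+Tug"), "barge_tug")
  expect_identical(normalize_vessel_type("BULK CARRIER"), "bulker")
  expect_error(normalize_vessel_type("hovercraft"),
               class = "pppscore_validation_error")
  expect_identical(
    normalize_vessel_type("hovercraft",
                          extra_aliases = c("hovercraft" = "general")),
    "general")
})

test_that("parameter table round-trips through its CSV config format", {
  path <- withr::local_tempfile(fileext = ".csv")
  custom <- vessel_type_params()
  custom$m[custom$type_code == "tanker"] <- 18.2
  write_vessel_type_params(custom, path)
  back <- read_vessel_type_params(path)
  expect_equal(back$m[back$type_code == "tanker"], 18.2)
  expect_equal(back[back$type_code != "tanker", ],
               custom[custom$type_code != "tanker", ])
})
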