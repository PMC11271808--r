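test_that("reference numerosities follow the +/-12.5%, +/-25% rule", {
  expect_equal(reference_numerosities(40), c(30L, 35L, 40L, 45L, 50L))
  expect_equal(reference_numerosities(59), c(44L, 52L, 59L, 66L, 74L))
})

test_that("session plans have the printed trial counts and structure", {
  p1 <- design_session("1a", seed = 1)
  expect_equal(sum(!p1$is_control), 300)
  expect_equal(sum(p1$is_control), 30)
  expect_equal(sort(unique(p1$true_numerosity[!p1$is_control])),
               seq(34, 44, 2))
  expect_true(all(table(p1$true_numerosity[!p1$is_control]) == 50))
  expect_equal(sort(unique(p1$percent_pairs[!p1$is_control])),
               c(0, 25, 50, 75, 100))
  expect_true(all(p1$true_numerosity[p1$is_control] %in% 2:4))
  expect_equal(attr(p1, "references")[["1"]], c(29L, 34L, 39L, 44L, 49L))

  p1b <- design_session("1b", seed = 1)
  expect_equal(sort(unique(p1b$true_numerosity[!p1b$is_control])),
               seq(54, 64, 2))
  expect_equal(attr(p1b, "references")[["1"]], c(44L, 52L, 59L, 66L, 74L))

  p2 <- design_session("2", seed = 1)
  expect_equal(sum(!p2$is_control), 6 * 80)
  main2 <- p2[!p2$is_control, ]
  expect_equal(length(unique(main2$block)), 6)
  expect_true(all(table(main2$block) == 80))
  expect_equal(sort(unique(main2$numerosity_range)), c("large", "small"))
  small_nums <- unique(main2$true_numerosity[main2$numerosity_range ==
                                               "small"])
  expect_true(all(small_nums %in% c(51, 54, 57, 60, 63, 69, 72)))

  p4 <- design_session("4", seed = 1)
  expect_equal(sum(!p4$is_control), 8 * 144)
  main4 <- p4[!p4$is_control, ]
  expect_true(all(table(main4$block) == 144))
  expect_equal(sort(unique(main4$polarity_scheme)),
               c("mixed", "uniform_dark", "uniform_light"))
  # uniform trials split between all-dark and all-light
  expect_equal(sum(main4$polarity_scheme == "uniform_dark"),
               sum(main4$polarity_scheme == "uniform_light"))
  expect_equal(sum(main4$polarity_scheme == "mixed"), 8 * 72)
  expect_error(design_session("9"), "arg")
})

test_that("contrast codes are +/-0.5 and centered", {
  expect_equal(code_contrasts("radial", "arrangement"), -0.5)
  expect_equal(code_contrasts("tangential", "arrangement"), 0.5)
  expect_equal(code_contrasts("uniform_dark", "polarity"), 0.5)
  expect_equal(code_contrasts("mixed", "polarity"), -0.5)
  expect_equal(code_contrasts("large", "numerosity_range"), 0.5)
  expect_equal(sum(code_contrasts(c("radial", "tangential"), "arrangement")),
               0)
  expect_error(code_contrasts("diagonal", "arrangement"), "unknown level")
})

test_that("noiseless observers reproduce the closed-form limits", {
  plan <- design_session("1a", seed = 2)
  zero <- observer_params(beta0 = 0, beta_arr = 0, beta_pol = 0,
                          beta_num = 0, sd_intercept = 0, sd_arr_slope = 0,
                          resid_sd = 0, regression_weight = 0,
                          subitizing_error_rate = 0, invalid_rate = 0)
  tr <- simulate_trials(plan, zero, 3, seed = 1)
  main <- tr[!tr$is_control, ]
  expect_true(all(main$response == main$true_numerosity))
  expect_true(all(tr$response[tr$is_control] ==
                    tr$true_numerosity[tr$is_control]))

  arr2 <- observer_params(beta0 = 0, beta_arr = 2, beta_pol = 0,
                          beta_num = 0, sd_intercept = 0, sd_arr_slope = 0,
                          resid_sd = 0, regression_weight = 0,
                          subitizing_error_rate = 0, invalid_rate = 0)
  tr <- simulate_trials(plan, arr2, 3, seed = 1)
  main <- tr[!tr$is_control, ]
  dv <- main$response - main$true_numerosity
  expect_equal(mean(dv[main$arrangement == "tangential"]) -
                 mean(dv[main$arrangement == "radial"]), 2)

  full_ct <- observer_params(beta0 = 0, beta_arr = 0, beta_pol = 0,
                             beta_num = 0, sd_intercept = 0,
                             sd_arr_slope = 0, resid_sd = 0,
                             regression_weight = 1,
                             subitizing_error_rate = 0, invalid_rate = 0)
  tr <- simulate_trials(plan, full_ct, 2, seed = 1)
  main <- tr[!tr$is_control, ]
  expect_true(all(main$response == round(main$block_mean)))
})

test_that("marginal DV mean equals beta0 under balanced contrasts", {
  plan <- design_session("1a", seed = 4)
  p <- observer_params(beta0 = -3, beta_arr = 2, beta_pol = 0, beta_num = 0,
                       sd_intercept = 0, sd_arr_slope = 0, resid_sd = 0,
                       regression_weight = 0, subitizing_error_rate = 0,
                       invalid_rate = 0)
  tr <- simulate_trials(plan, p, 2, seed = 3)
  main <- tr[!tr$is_control, ]
  expect_equal(mean(main$response - main$true_numerosity), -3,
               tolerance = 1e-12)
})

test_that("invalid markers appear at the configured rate", {
  plan <- design_session("1a", seed = 6)
  p <- observer_params(invalid_rate = 0.05)
  tr <- simulate_trials(plan, p, 20, seed = 8)
  n <- nrow(tr)
  got <- sum(tr$invalid)
  expect_true(all(is.na(tr$response[tr$invalid])))
  band <- qbinom(c(0.0005, 0.9995), n, 0.05)
  expect_gte(got, band[1])
  expect_lte(got, band[2])
})

test_that("the simulated arrangement gap tracks the injected effect", {
  plan <- design_session("1a", seed = 10)
  p <- observer_params(beta_arr = 0.89, invalid_rate = 0,
                       subitizing_error_rate = 0)
  gaps <- vapply(1:10, function(s) {
    tr <- simulate_trials(plan, p, 12, seed = 100 + s)
    main <- tr[!tr$is_control, ]
    dv <- main$response - main$true_numerosity
    mean(dv[main$arrangement == "tangential"]) -
      mean(dv[main$arrangement == "radial"])
  }, numeric(1))
  se <- sd(gaps) / sqrt(length(gaps))
  expect_lt(abs(mean(gaps) - 0.89), 3 * se + 0.05)
})

test_that("simulate_trials is reproducible from its seed", {
  plan <- design_session("2", seed = 2)
  a <- simulate_trials(plan, observer_params(), 4, seed = 7)
  b <- simulate_trials(plan, observer_params(), 4, seed = 7)
  expect_identical(a, b)
})
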