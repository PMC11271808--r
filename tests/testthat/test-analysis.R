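test_that("compute_dv has the signed convention and rejects invalids", {
  expect_equal(compute_dv(38, 40), -2)
  expect_equal(compute_dv(40, 40), 0)
  expect_equal(compute_dv(45, 40), 5)
  expect_error(compute_dv(NA_integer_, 40), "invalid")
})

test_that("screening applies the exact printed boundaries", {
  # 27/30 control trials correct is exactly 10% incorrect: excluded
  t1 <- make_screening_table(n_ctrl_wrong = 3)
  s1 <- screen_participants(t1)
  expect_equal(s1$excluded$reason, "subitizing_fail")
  t2 <- make_screening_table(n_ctrl_wrong = 2)
  expect_equal(screen_participants(t2)$kept, "P1")
  # exactly 5% invalid kept, one more excluded (300-trial session)
  t3 <- make_screening_table(n_main = 300, n_ctrl = 0, n_invalid = 15)
  expect_equal(screen_participants(t3)$kept, "P1")
  t4 <- make_screening_table(n_main = 300, n_ctrl = 0, n_invalid = 16)
  expect_equal(screen_participants(t4)$excluded$reason, "invalid_responses")
  # incomplete sessions go first
  t5 <- rbind(make_screening_table(),
              make_screening_table(n_main = 100, participant = "P2"))
  s5 <- screen_participants(t5)
  expect_equal(s5$kept, "P1")
  expect_equal(s5$excluded$reason, "incomplete")
  expect_error(screen_participants(t5[0, ]), "empty")
})

test_that("screening is idempotent", {
  plan <- design_session("1a", seed = 3)
  tr <- simulate_trials(plan, observer_params(subitizing_error_rate = 0.1),
                        10, seed = 5)
  s1 <- screen_participants(tr)
  kept_trials <- tr[tr$participant %in% s1$kept, ]
  s2 <- screen_participants(kept_trials)
  expect_identical(sort(s2$kept), sort(s1$kept))
  expect_equal(nrow(s2$excluded), 0)
})

test_that("fit_lmm recovers a noiseless effect at machine precision", {
  plan <- design_session("1a", seed = 2)
  p <- observer_params(beta0 = 0, beta_arr = 2, beta_pol = 0, beta_num = 0,
                       sd_intercept = 0, sd_arr_slope = 0, resid_sd = 0,
                       regression_weight = 0, subitizing_error_rate = 0,
                       invalid_rate = 0)
  tab <- prepare_trials(simulate_trials(plan, p, 4, seed = 1))
  fit <- fit_lmm(tab, "arrangement")
  expect_equal(fit$terms$estimate[fit$terms$term == "arr"], 2,
               tolerance = 1e-10)
  expect_equal(fit$terms$estimate[fit$terms$term == "(Intercept)"], 0,
               tolerance = 1e-10)
  expect_error(fit_lmm(tab[tab$participant == "P001", ], "arrangement"),
               "at least 2")
})

test_that("printed effect sizes are recovered without bias (Monte-Carlo oracle)", {
  plan <- mini_plan(n_reps = 8)
  n_rep <- 50
  for (beta in c(0.89, 1.35, 2.73, 0.65, 1.44)) {
    p <- observer_params(beta_arr = beta, invalid_rate = 0,
                         subitizing_error_rate = 0)
    est <- vapply(seq_len(n_rep), function(i) {
      tab <- prepare_trials(simulate_trials(plan, p, 12,
                                            seed = derive_seed(1000 * beta, i)))
      f <- fit_lmm(tab, "arrangement")
      f$terms$estimate[f$terms$term == "arr"]
    }, numeric(1))
    mc_se <- sd(est) / sqrt(n_rep)
    expect_lt(abs(mean(est) - beta), 2 * mc_se + 1e-3,
              label = sprintf("recovery of %.2f (got %.3f +/- %.3f)", beta,
                              mean(est), mc_se))
  }
  # polarity effect (uniform - mixed), within-subjects design
  plan_p <- mini_plan_pol(n_reps = 6)
  p <- observer_params(beta_pol = 1.64, invalid_rate = 0,
                       subitizing_error_rate = 0)
  est <- vapply(seq_len(n_rep), function(i) {
    tab <- prepare_trials(simulate_trials(plan_p, p, 12,
                                          seed = derive_seed(777, i)))
    f <- fit_lmm(tab, c("arrangement", "polarity"))
    f$terms$estimate[f$terms$term == "pol"]
  }, numeric(1))
  mc_se <- sd(est) / sqrt(n_rep)
  expect_lt(abs(mean(est) - 1.64), 2 * mc_se + 1e-3)
})

test_that("permuting arrangement labels within participant kills the effect", {
  plan <- mini_plan(n_reps = 15)
  p <- observer_params(beta_arr = 2, invalid_rate = 0,
                       subitizing_error_rate = 0)
  tab <- prepare_trials(simulate_trials(plan, p, 14, seed = 31))
  fit0 <- fit_lmm(tab, "arrangement")
  expect_gt(fit0$terms$estimate[fit0$terms$term == "arr"], 1)
  set.seed(99)
  perm <- tab
  for (id in unique(perm$participant)) {
    sel <- perm$participant == id
    perm$arr[sel] <- sample(perm$arr[sel])
  }
  fitp <- fit_lmm(perm, "arrangement")
  row <- fitp$terms[fitp$terms$term == "arr", ]
  expect_lt(abs(row$estimate), 3 * row$se)
  expect_lt(abs(row$estimate), 0.6)
})

test_that("lrt_interaction follows the chi-square tail and its contracts", {
  fake <- function(ll, terms, method = "ml") {
    structure(list(terms = data.frame(term = terms), log_likelihood = ll,
                   method = method), class = "na_fit")
  }
  same <- lrt_interaction(fake(-100, c("a", "b")), fake(-100, "a"))
  expect_equal(same$chi_square, 0)
  expect_equal(same$p, 1)
  lrt <- lrt_interaction(fake(-99.875, c("a", "b")), fake(-100, "a"))
  expect_equal(lrt$chi_square, 0.25)
  expect_equal(lrt$df, 1)
  expect_equal(lrt$p, 0.617, tolerance = 1e-3)
  # clipped at zero when the "full" likelihood is lower
  neg <- lrt_interaction(fake(-101, c("a", "b")), fake(-100, "a"))
  expect_equal(neg$chi_square, 0)
  expect_error(lrt_interaction(fake(-99, c("a", "b"), "reml"),
                               fake(-100, "a")), "ML")
  expect_error(lrt_interaction(fake(-99, c("a", "b")), fake(-100, "c")),
               "nested")
})

test_that("the LRT detects a simulated arrangement-by-polarity interaction", {
  plan <- mini_plan_pol(n_reps = 6)
  p_alt <- observer_params(beta_arr = 0.89, beta_arr_pol = 2,
                           invalid_rate = 0, subitizing_error_rate = 0)
  n_rep <- 100
  rej <- vapply(seq_len(n_rep), function(i) {
    tab <- prepare_trials(simulate_trials(plan, p_alt, 12,
                                          seed = derive_seed(55, i)))
    full <- fit_lmm(tab, c("arrangement", "polarity",
                           "arrangement:polarity"), method = "ml")
    red <- fit_lmm(tab, c("arrangement", "polarity"), method = "ml")
    lrt_interaction(full, red)$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.8)
})

test_that("compare_experiments: exchangeability, grand mean, |DV| symmetry", {
  plan <- mini_plan(n_reps = 8)
  p <- observer_params(beta0 = -6, invalid_rate = 0,
                       subitizing_error_rate = 0)
  t1 <- prepare_trials(simulate_trials(plan, p, 10, seed = 1))
  t2 <- prepare_trials(simulate_trials(plan, p, 10, seed = 2))
  t2$participant <- sub("^P", "Q", t2$participant)
  cmp <- compare_experiments(list(A = t1, B = t2), coding = "simple")
  row <- cmp$dv$terms[cmp$dv$terms$term == "exp", ]
  expect_lt(abs(row$estimate), 3 * row$se)
  cmp_sum <- compare_experiments(list(A = t1, B = t2), coding = "sum")
  gm <- cmp_sum$dv$terms[cmp_sum$dv$terms$term == "(Intercept)", ]
  expect_lt(abs(gm$estimate - (-6)), 3 * gm$se + 0.5)
  # |DV| outcome is invariant to flipping the sign of every DV
  t1f <- t1; t1f$dv <- -t1f$dv; t1f$abs_dv <- abs(t1f$dv)
  t2f <- t2; t2f$dv <- -t2f$dv; t2f$abs_dv <- abs(t2f$dv)
  cmp_f <- compare_experiments(list(A = t1f, B = t2f), coding = "simple")
  expect_equal(cmp_f$abs_dv$terms$estimate, cmp$abs_dv$terms$estimate,
               tolerance = 1e-8)
  t2$participant <- t1$participant[seq_len(nrow(t2))]
  expect_error(compare_experiments(list(A = t1, B = t2)), "overlap")
})

test_that("power saturates for huge effects and is seed-reproducible", {
  plan <- mini_plan(n_reps = 5)
  p <- observer_params(beta_arr = 10, sd_intercept = 0.5, sd_arr_slope = 0.2,
                       resid_sd = 1, invalid_rate = 0,
                       subitizing_error_rate = 0)
  pw <- power_simulation(p, 8, plan, n_reps = 10, seed = 3)
  expect_equal(pw$power, 1)
  pw2 <- power_simulation(p, 8, plan, n_reps = 10, seed = 3)
  expect_identical(pw$estimates, pw2$estimates)
})
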