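#' Synthetic-observer parameters
#'
#' The observer simulator is the analysis model run forward, not a
#' perceptual theory: a trial response is the true numerosity plus fixed
#' effects of arrangement/polarity/numerosity range (on +/-0.5 contrast
#' codes), participant-level random intercept and arrangement slope, a
#' central-tendency pull toward the block mean, and Gaussian trial noise,
#' rounded half-up and floored at 1.
#'
#' Defaults: the arrangement effect (tangential minus radial deviation
#' score) defaults to 0.89 items, the small-numerosity headline estimate of
#' the study design this package models; the polarity effect (uniform minus
#' mixed) to 1.64 and the numerosity-range effect to 1.08, the
#' within-subjects estimates; the baseline deviation to -4 items (overall
#' underestimation). The variance components (intercept SD 2, slope SD 1,
#' residual SD 4 items) are package choices tuned so simulated t-statistics
#' are of the order reported in that literature; no variance components are
#' printed there. Central tendency defaults to 0.3.
#'
#' @param beta0 baseline deviation score, items.
#' @param beta_arr arrangement effect (tangential - radial), items.
#' @param beta_pol polarity effect (uniform - mixed), items.
#' @param beta_num numerosity-range effect (large - small), items.
#' @param beta_arr_pol arrangement-by-polarity interaction on the product
#'   of the two contrast codes (default 0; used to simulate data under the
#'   interaction alternative for the likelihood-ratio test).
#' @param sd_intercept,sd_arr_slope participant random-effect SDs, items.
#' @param resid_sd trial residual SD, items.
#' @param regression_weight in [0,1]; pull toward the block-mean numerosity.
#' @param subitizing_error_rate probability of an incorrect control-trial
#'   response.
#' @param invalid_rate probability any response is replaced by an invalid
#'   marker.
#' @return a `na_observer_params` list.
#' @export
observer_params <- function(beta0 = -4, beta_arr = 0.89, beta_pol = 1.64,
                            beta_num = 1.08, beta_arr_pol = 0,
                            sd_intercept = 2,
                            sd_arr_slope = 1, resid_sd = 4,
                            regression_weight = 0.3,
                            subitizing_error_rate = 0.02,
                            invalid_rate = 0.01) {
  stopifnot(sd_intercept >= 0, sd_arr_slope >= 0, resid_sd >= 0,
            regression_weight >= 0, regression_weight <= 1,
            subitizing_error_rate >= 0, subitizing_error_rate <= 1,
            invalid_rate >= 0, invalid_rate <= 1)
  structure(list(beta0 = beta0, beta_arr = beta_arr, beta_pol = beta_pol,
                 beta_num = beta_num, beta_arr_pol = beta_arr_pol,
                 sd_intercept = sd_intercept,
                 sd_arr_slope = sd_arr_slope, resid_sd = resid_sd,
                 regression_weight = regression_weight,
                 subitizing_error_rate = subitizing_error_rate,
                 invalid_rate = invalid_rate),
            class = "na_observer_params")
}

#' Reference numerosities for a block
#'
#' The five reference displays shown before a block are spread at
#' -25%, -12.5%, 0, +12.5%, +25% around the block-mean numerosity,
#' rounded half-up to integers.
#'
#' @param block_mean mean numerosity of the block.
#' @return integer vector of length 5.
#' @examples
#' reference_numerosities(40)  # 30 35 40 45 50
#' @export
reference_numerosities <- function(block_mean) {
  as.integer(round_half_up(block_mean * c(0.75, 0.875, 1, 1.125, 1.25)))
}

.num_grids <- list(
  "1" = list(small = seq(34, 44, 2), large = seq(54, 64, 2)),
  "2" = list(small = c(51, 54, 57, 60, 63, 69, 72),
             large = c(78, 81, 84, 87, 90, 93, 96, 99))
)

.intersperse_controls <- function(main, n_control) {
  # 30 subitizing trials (numerosities 2-4, balanced) inserted at random
  # positions among the main trials
  ctrl <- data.frame(block = sample(unique(main$block), n_control,
                                    replace = TRUE),
                     arrangement = sample(c("radial", "tangential"),
                                          n_control, replace = TRUE),
                     polarity_scheme = main$polarity_scheme[1],
                     numerosity_range = "control",
                     percent_pairs = NA_real_,
                     true_numerosity = sample(rep(2:4,
                                                  length.out = n_control)),
                     block_mean = NA_real_,
                     is_control = TRUE)
  main$is_control <- FALSE
  out <- rbind(main, ctrl)
  out <- out[sample(nrow(out)), ]
  out$trial <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Build the per-experiment trial plan
#'
#' Session layouts:
#' \itemize{
#'   \item tags `"1a"`/`"3a"` (small range 34-44) and `"1b"`/`"3b"` (large
#'     range 54-64): 300 main trials (6 numerosities x 50, arrangement and
#'     the five percent-pairs conditions balanced within numerosity) plus 30
#'     interspersed subitizing control trials; polarity uniform (1a/1b) or
#'     mixed (3a/3b).
#'   \item tag `"2"`: six blocks of 80 trials (three small blocks drawn from
#'     \{51,...,72\}, three large from \{78,...,99\}; all-triplet displays),
#'     plus 30 control trials.
#'   \item tag `"4"`: eight blocks of 144 trials (four small, four large;
#'     within a block arrangement x polarity x percent-pairs \{0,50,100\} x
#'     numerosity fully crossed; uniform-polarity trials split between
#'     all-dark and all-light), plus 30 control trials.
#' }
#' Each block carries its mean numerosity and the five reference
#' numerosities (attribute `"references"`).
#'
#' @param experiment_tag one of "1a", "1b", "2", "3a", "3b", "4".
#' @param seed integer seed for trial-order randomization.
#' @return data.frame of trials (block, trial, arrangement, polarity_scheme,
#'   numerosity_range, percent_pairs, true_numerosity, block_mean,
#'   is_control) with attributes `"tag"` and `"references"`.
#' @export
design_session <- function(experiment_tag = c("1a", "1b", "2", "3a", "3b", "4"),
                           seed = 1L) {
  tag <- match.arg(experiment_tag)
  set.seed(seed)
  pp_levels <- c(0, 25, 50, 75, 100)
  if (tag %in% c("1a", "1b", "3a", "3b")) {
    rng <- if (tag %in% c("1a", "3a")) "small" else "large"
    nums <- .num_grids[["1"]][[rng]]
    pol <- if (tag %in% c("1a", "1b")) "uniform_dark" else "mixed"
    main <- expand.grid(true_numerosity = nums,
                        arrangement = c("radial", "tangential"),
                        percent_pairs = pp_levels,
                        rep = 1:5, stringsAsFactors = FALSE)
    main$rep <- NULL
    main$block <- 1L
    main$polarity_scheme <- pol
    main$numerosity_range <- rng
    main$block_mean <- mean(nums)
    refs <- list(`1` = reference_numerosities(mean(nums)))
  } else if (tag == "2") {
    ranges <- sample(rep(c("small", "large"), each = 3))
    rows <- list()
    refs <- list()
    for (b in seq_along(ranges)) {
      nums <- .num_grids[["2"]][[ranges[b]]]
      k <- length(nums)
      counts <- rep(80L %/% k, k)
      extra <- sample(k, 80L %% k)
      counts[extra] <- counts[extra] + 1L
      tn <- rep(nums, counts)
      rows[[b]] <- data.frame(true_numerosity = sample(tn),
                              arrangement = sample(rep(c("radial",
                                                         "tangential"), 40)),
                              percent_pairs = NA_real_,
                              block = b,
                              polarity_scheme = "uniform_dark",
                              numerosity_range = ranges[b],
                              block_mean = mean(nums))
      refs[[as.character(b)]] <- reference_numerosities(mean(nums))
    }
    main <- do.call(rbind, rows)
  } else { # tag 4
    ranges <- sample(rep(c("small", "large"), each = 4))
    rows <- list()
    refs <- list()
    for (b in seq_along(ranges)) {
      nums <- .num_grids[["1"]][[ranges[b]]]
      g <- expand.grid(true_numerosity = nums,
                       arrangement = c("radial", "tangential"),
                       percent_pairs = c(0, 50, 100),
                       polarity_scheme = c("uniform_dark", "uniform_light",
                                           "mixed", "mixed"),
                       stringsAsFactors = FALSE)
      g <- g[sample(nrow(g)), ]
      g$block <- b
      g$numerosity_range <- ranges[b]
      g$block_mean <- mean(nums)
      rows[[b]] <- g
      refs[[as.character(b)]] <- reference_numerosities(mean(nums))
    }
    main <- do.call(rbind, rows)
  }
  main <- main[, c("block", "arrangement", "polarity_scheme",
                   "numerosity_range", "percent_pairs", "true_numerosity",
                   "block_mean")]
  plan <- .intersperse_controls(main, 30L)
  plan <- plan[, c("block", "trial", "arrangement", "polarity_scheme",
                   "numerosity_range", "percent_pairs", "true_numerosity",
                   "block_mean", "is_control")]
  attr(plan, "tag") <- tag
  attr(plan, "references") <- refs
  plan
}

#' Contrast codes for the design factors
#'
#' Simple contrast coding assigns -0.5 to the radial arrangement, mixed
#' polarity, and the small numerosity range, and +0.5 to the tangential
#' arrangement, uniform polarity, and the large range, so a fixed-effect
#' coefficient equals the between-level difference. Sum coding (for the
#' grand-mean cross-experiment model) is provided by
#' [compare_experiments()].
#'
#' @param level factor level(s).
#' @param factor one of "arrangement", "polarity", "numerosity_range".
#' @return numeric vector of codes.
#' @export
code_contrasts <- function(level, factor = c("arrangement", "polarity",
                                             "numerosity_range")) {
  factor <- match.arg(factor)
  map <- switch(factor,
    arrangement = c(radial = -0.5, tangential = 0.5),
    polarity = c(mixed = -0.5, uniform = 0.5,
                 uniform_dark = 0.5, uniform_light = 0.5),
    numerosity_range = c(small = -0.5, large = 0.5))
  out <- unname(map[as.character(level)])
  if (anyNA(out)) stop("unknown level for factor ", factor, ": ",
                       paste(unique(level[is.na(out)]), collapse = ", "))
  out
}

#' Simulate trial responses from a plan
#'
#' Applies the generative model described in [observer_params()] to a trial
#' plan for `n_participants` synthetic participants. Control (subitizing)
#' trials are answered correctly with probability
#' `1 - subitizing_error_rate`, otherwise off by one. Each response is
#' independently replaced by an invalid marker (`NA` response,
#' `invalid = TRUE`) with probability `invalid_rate`.
#'
#' @param plan a trial plan from [design_session()] (or any data.frame with
#'   the same columns).
#' @param params a [observer_params()].
#' @param n_participants number of synthetic participants.
#' @param seed integer seed; the trial table is a pure function of
#'   (plan, params, n_participants, seed).
#' @return data.frame of trial records: participant, experiment,
#'   plan columns, response, invalid.
#' @export
simulate_trials <- function(plan, params = observer_params(),
                            n_participants, seed = 1L) {
  stopifnot(inherits(params, "na_observer_params"), n_participants >= 1)
  set.seed(seed)
  tag <- attr(plan, "tag")
  if (is.null(tag)) tag <- "custom"
  nt <- nrow(plan)
  main <- !plan$is_control
  x_arr <- code_contrasts(plan$arrangement, "arrangement")
  x_pol <- code_contrasts(plan$polarity_scheme, "polarity")
  x_num <- ifelse(plan$numerosity_range == "large", 0.5,
                  ifelse(plan$numerosity_range == "small", -0.5, 0))
  out <- vector("list", n_participants)
  for (j in seq_len(n_participants)) {
    u0 <- stats::rnorm(1, 0, params$sd_intercept)
    u1 <- stats::rnorm(1, 0, params$sd_arr_slope)
    eps <- stats::rnorm(nt, 0, params$resid_sd)
    raw <- plan$true_numerosity +
      params$beta0 + params$beta_arr * x_arr + params$beta_pol * x_pol +
      params$beta_num * x_num + params$beta_arr_pol * x_arr * x_pol +
      u0 + u1 * x_arr +
      params$regression_weight * (plan$block_mean - plan$true_numerosity) +
      eps
    response <- pmax(1, round_half_up(raw))
    if (any(!main)) {
      nctrl <- sum(!main)
      err <- stats::runif(nctrl) < params$subitizing_error_rate
      off <- sample(c(-1, 1), nctrl, replace = TRUE) * err
      response[!main] <- pmax(1, plan$true_numerosity[!main] + off)
    }
    invalid <- stats::runif(nt) < params$invalid_rate
    response[invalid] <- NA_real_
    rec <- plan
    rec$participant <- sprintf("P%03d", j)
    rec$experiment <- tag
    rec$response <- as.integer(response)
    rec$invalid <- invalid
    out[[j]] <- rec
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("participant", "experiment", "block", "trial", "arrangement",
          "polarity_scheme", "numerosity_range", "percent_pairs",
          "true_numerosity", "block_mean", "is_control", "response",
          "invalid")]
}
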