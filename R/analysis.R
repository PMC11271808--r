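#' Deviation score
#'
#' DV = reported numerosity minus true numerosity; negative values are
#' underestimations. Invalid (non-numeric) responses must be removed
#' upstream (see [screen_participants()]); they are an error here.
#'
#' @param response reported numerosity (vectorized).
#' @param true_n true numerosity.
#' @return signed deviation in items.
#' @export
compute_dv <- function(response, true_n) {
  if (!is.numeric(response) || anyNA(response)) {
    stop("compute_dv: invalid (non-numeric or missing) response")
  }
  response - true_n
}

#' Screen participants
#'
#' Applies the three exclusion rules, in order: (1) incomplete sessions
#' (fewer trials than the fullest session in the table); (2) strictly more
#' than 5% invalid responses (exactly 5% is kept); (3) control-trial
#' accuracy below 90% correct, i.e. 10% or more incorrect (exactly 90%
#' correct is excluded). Invalid responses on control trials count as
#' incorrect. Screening is idempotent. Each excluded participant is
#' reported with the first rule it violated.
#'
#' @param trials a trial table from [simulate_trials()].
#' @return a `na_screening` list: `kept` (participant ids), `excluded`
#'   (data.frame participant, reason).
#' @export
screen_participants <- function(trials) {
  if (!nrow(trials)) stop("screen_participants: empty trial table")
  ids <- unique(trials$participant)
  n_tr <- tapply(trials$trial, trials$participant, length)
  expected <- max(n_tr)
  excluded <- list()
  kept <- character(0)
  for (id in ids) {
    tt <- trials[trials$participant == id, ]
    reason <- NULL
    if (nrow(tt) < expected) {
      reason <- "incomplete"
    } else if (sum(tt$invalid) > 0.05 * nrow(tt) + 1e-9) {
      reason <- "invalid_responses"
    } else {
      ctrl <- tt[tt$is_control, ]
      if (nrow(ctrl)) {
        n_inc <- sum(ctrl$invalid) +
          sum(!ctrl$invalid & ctrl$response != ctrl$true_numerosity)
        if (n_inc >= 0.10 * nrow(ctrl) - 1e-9) reason <- "subitizing_fail"
      }
    }
    if (is.null(reason)) kept <- c(kept, id)
    else excluded[[length(excluded) + 1L]] <- data.frame(participant = id,
                                                         reason = reason)
  }
  structure(list(kept = kept,
                 excluded = if (length(excluded)) do.call(rbind, excluded)
                            else data.frame(participant = character(0),
                                            reason = character(0))),
            class = "na_screening")
}

#' Keep only screened participants' valid main trials
#'
#' Convenience wrapper: applies [screen_participants()], drops excluded
#' participants, control trials and invalid responses, and adds the
#' analysis columns: `dv`, `abs_dv`, and the +/-0.5 contrast codes `arr`,
#' `pol`, `num` (see [code_contrasts()]).
#'
#' @param trials a trial table.
#' @return analyzable data.frame.
#' @export
prepare_trials <- function(trials) {
  rep <- screen_participants(trials)
  tt <- trials[trials$participant %in% rep$kept & !trials$is_control &
                 !trials$invalid, ]
  tt$dv <- compute_dv(tt$response, tt$true_numerosity)
  tt$abs_dv <- abs(tt$dv)
  tt$arr <- code_contrasts(tt$arrangement, "arrangement")
  tt$pol <- code_contrasts(tt$polarity_scheme, "polarity")
  tt$num <- ifelse(tt$numerosity_range == "large", 0.5, -0.5)
  tt
}

.term_map <- c(arrangement = "arr", polarity = "pol",
               numerosity_range = "num", experiment = "exp")

.map_terms <- function(terms) {
  vapply(terms, function(t) {
    parts <- strsplit(t, ":", fixed = TRUE)[[1]]
    paste(ifelse(parts %in% names(.term_map), .term_map[parts], parts),
          collapse = ":")
  }, character(1), USE.NAMES = FALSE)
}

#' Fit a contrast-coded linear mixed model
#'
#' Fits `outcome ~ fixed terms + random terms` with \pkg{lme4}. The fixed
#' factors are entered as their +/-0.5 contrast codes so each coefficient
#' is the between-level difference. REML is the default for reported
#' estimates; use `method = "ml"` for any model that will enter a
#' likelihood-ratio comparison. t-test degrees of freedom use the
#' between-within fallback (participants - 1), recorded in `df_method`;
#' non-convergence and singular fits are flagged, not dropped.
#'
#' @param trials an analyzable table from [prepare_trials()] (or any
#'   data.frame with the needed columns).
#' @param fixed_terms character vector of fixed effects, e.g.
#'   `c("arrangement", "polarity", "arrangement:polarity")`.
#' @param random_spec lme4 random-terms string over the contrast-code
#'   column names; default `"(1 + arr | participant)"` (participant-level
#'   intercept and arrangement slope). A crossed numerosity intercept
#'   variant is e.g. `"(1 + arr | participant) + (1 | true_numerosity)"`.
#' @param outcome `"dv"` (signed) or `"abs_dv"` (accuracy).
#' @param method `"reml"` or `"ml"`.
#' @return a `na_fit`: list with `terms` (data.frame term, estimate, se, t,
#'   df, p), `log_likelihood`, `method`, `converged`, `singular`,
#'   `n_participants`, `df_method`, `formula`, `model` (the lmerMod).
#' @export
fit_lmm <- function(trials, fixed_terms = "arrangement",
                    random_spec = "(1 + arr | participant)",
                    outcome = c("dv", "abs_dv"),
                    method = c("reml", "ml")) {
  outcome <- match.arg(outcome)
  method <- match.arg(method)
  if (length(unique(trials$participant)) < 2) {
    stop("fit_lmm: need at least 2 participants")
  }
  rhs <- paste(c(.map_terms(fixed_terms), random_spec), collapse = " + ")
  form <- stats::as.formula(paste(outcome, "~", rhs))
  fit <- lme4::lmer(form, data = trials, REML = (method == "reml"),
                    control = lme4::lmerControl(calc.derivs = FALSE))
  est <- lme4::fixef(fit)
  # vcov can degenerate on noise-free data; report NA uncertainty then
  se <- tryCatch(suppressWarnings(sqrt(diag(as.matrix(stats::vcov(fit))))),
                 error = function(e) rep(NA_real_, length(est)))
  n_p <- length(unique(trials$participant))
  df <- n_p - 1
  tval <- est / se
  tab <- data.frame(term = names(est),
                    estimate = unname(est),
                    se = unname(se),
                    t = unname(tval),
                    df = df,
                    p = unname(2 * stats::pt(-abs(tval), df)),
                    row.names = NULL)
  conv <- length(fit@optinfo$conv$lme4$messages) == 0
  structure(list(terms = tab,
                 log_likelihood = as.numeric(stats::logLik(fit)),
                 method = method,
                 converged = conv,
                 singular = lme4::isSingular(fit),
                 n_participants = n_p,
                 df_method = "between-within fallback (participants - 1)",
                 formula = deparse(form),
                 model = fit),
            class = "na_fit")
}

#' @export
print.na_fit <- function(x, ...) {
  cat(sprintf("<na_fit> %s, logLik %.2f, %d participants%s%s\n", x$formula,
              x$log_likelihood, x$n_participants,
              if (!x$converged) ", NOT CONVERGED" else "",
              if (x$singular) ", singular" else ""))
  print(x$terms, digits = 3)
  invisible(x)
}

#' Likelihood-ratio test between nested fits
#'
#' Both fits must be ML (REML likelihoods are not comparable across fixed
#' structures) and the reduced model's fixed terms must be a subset of the
#' full model's. The statistic is clipped at zero.
#'
#' @param full,reduced `na_fit` objects from [fit_lmm()] with
#'   `method = "ml"`.
#' @return list (class `na_lrt`) with `chi_square`, `df`, `p`.
#' @export
lrt_interaction <- function(full, reduced) {
  stopifnot(inherits(full, "na_fit"), inherits(reduced, "na_fit"))
  if (full$method != "ml" || reduced$method != "ml") {
    stop("lrt_interaction: both fits must be ML")
  }
  if (!all(reduced$terms$term %in% full$terms$term)) {
    stop("lrt_interaction: models are not nested")
  }
  df <- nrow(full$terms) - nrow(reduced$terms)
  if (df < 1) stop("lrt_interaction: full model has no extra terms")
  chi <- max(0, 2 * (full$log_likelihood - reduced$log_likelihood))
  structure(list(chi_square = chi, df = df,
                 p = stats::pchisq(chi, df, lower.tail = FALSE)),
            class = "na_lrt")
}

#' @export
print.na_lrt <- function(x, ...) {
  cat(sprintf("chi-square(%d) = %.3f, p = %.3g\n", x$df, x$chi_square, x$p))
  invisible(x)
}

#' Cross-experiment comparison models
#'
#' Stacks analyzable tables from several experiments (participants must be
#' disjoint), codes the experiment factor with simple (+/-0.5, two
#' experiments) or sum contrasts (against the grand mean), and fits both
#' the signed-DV model and the |DV| accuracy model with arrangement and
#' experiment as fixed factors. The random structure lets each
#' participant's baseline differ between radial and tangential displays
#' (intercept by participant plus intercept by participant-within-
#' arrangement).
#'
#' @param tables list of analyzable tables (see [prepare_trials()]), one
#'   per experiment; element names are used as experiment labels.
#' @param coding `"simple"` or `"sum"`.
#' @param method `"reml"` (default) or `"ml"`.
#' @return list with elements `dv` and `abs_dv`, each a `na_fit`.
#' @export
compare_experiments <- function(tables, coding = c("simple", "sum"),
                                method = "reml") {
  coding <- match.arg(coding)
  stopifnot(length(tables) >= 2)
  if (is.null(names(tables)) || any(names(tables) == "")) {
    names(tables) <- paste0("exp", seq_along(tables))
  }
  ids <- lapply(tables, function(t) unique(t$participant))
  if (length(unlist(ids)) != length(unique(unlist(ids)))) {
    stop("compare_experiments: participant ids overlap across experiments")
  }
  for (i in seq_along(tables)) tables[[i]]$experiment <- names(tables)[i]
  keep <- c("participant", "experiment", "arrangement", "true_numerosity",
            "dv", "abs_dv", "arr")
  stacked <- do.call(rbind, lapply(tables, function(t) t[, keep]))
  if (coding == "simple") {
    if (length(tables) != 2) stop("simple coding requires exactly 2 experiments")
    stacked$exp <- ifelse(stacked$experiment == names(tables)[1], -0.5, 0.5)
  } else {
    f <- factor(stacked$experiment, levels = names(tables))
    stats::contrasts(f) <- stats::contr.sum(nlevels(f))
    stacked$exp <- f
  }
  random_spec <- "(1 | participant) + (1 | participant:arrangement)"
  list(dv = fit_lmm(stacked, c("arrangement", "experiment"), random_spec,
                    outcome = "dv", method = method),
       abs_dv = fit_lmm(stacked, c("arrangement", "experiment"), random_spec,
                        outcome = "abs_dv", method = method))
}

#' Simulation-based power for the arrangement effect
#'
#' Simulates `n_reps` datasets from the synthetic observer, fits the
#' experiment's contrast-coded mixed model to each, and returns the
#' proportion of replicates whose arrangement term reaches `p < alpha`,
#' with an exact binomial confidence interval. Replicate seeds are derived
#' deterministically from `seed`.
#'
#' @param params a [observer_params()].
#' @param n_participants participants per simulated dataset.
#' @param plan trial plan from [design_session()].
#' @param n_reps number of replicates.
#' @param alpha significance level (default 0.05).
#' @param seed integer seed.
#' @param random_spec random structure passed to [fit_lmm()].
#' @return list (class `na_power`): `power`, `ci` (95% exact binomial),
#'   `n_sig`, `n_reps`, `alpha`, `estimates` (per-replicate arrangement
#'   estimates).
#' @export
power_simulation <- function(params, n_participants, plan, n_reps,
                             alpha = 0.05, seed = 1L,
                             random_spec = "(1 + arr | participant)") {
  stopifnot(n_reps >= 1)
  pvals <- numeric(n_reps)
  ests <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    tr <- simulate_trials(plan, params, n_participants,
                          seed = derive_seed(seed, i))
    tab <- prepare_trials(tr)
    fit <- fit_lmm(tab, "arrangement", random_spec, outcome = "dv",
                   method = "reml")
    row <- fit$terms[fit$terms$term == "arr", ]
    pvals[i] <- row$p
    ests[i] <- row$estimate
  }
  n_sig <- sum(pvals < alpha)
  ci <- as.numeric(stats::binom.test(n_sig, n_reps)$conf.int)
  structure(list(power = n_sig / n_reps, ci = ci, n_sig = n_sig,
                 n_reps = n_reps, alpha = alpha, estimates = ests,
                 p_values = pvals),
            class = "na_power")
}

#' @export
print.na_power <- function(x, ...) {
  cat(sprintf("power = %.3f [%.3f, %.3f] (%d/%d reps, alpha = %g)\n",
              x$power, x$ci[1], x$ci[2], x$n_sig, x$n_reps, x$alpha))
  invisible(x)
}
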