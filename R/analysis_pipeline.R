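#' Convert elicited counts to a belief about cooperativeness
#'
#' Participants estimate how many of 30 others choose each action; the belief
#' \eqn{\gamma} relevant to the group outcome is the implied cooperation rate
#' among those who matter for provision:
#' * mandatory conditions: `est_C / 30` (everyone is in a group);
#' * voluntary main-design conditions: `est_C / (est_C + est_D)`
#'   (cooperativeness within groups, loners excluded);
#' * externality conditions: `est_C / (est_C + est_D + rho * est_L)`
#'   (the effective cooperation rate).
#'
#' When the denominator is zero (no one believed to opt in) the belief is
#' undefined and `NA` is returned rather than an error.
#'
#' @param records A cohort tibble (see [generate_cohort()] for the schema);
#'   rows with a non-`NA` `rho` use the externality conversion.
#' @param total Number of others estimated (default 30).
#' @return The input with an added numeric column `gamma`.
#' @export
elicited_belief_to_gamma <- function(records, total = 30L) {
  est_C <- records$est_C
  est_D <- records$est_D
  est_L <- records$est_L
  gamma <- ifelse(
    records$regime == "mandatory",
    est_C / total,
    ifelse(
      is.na(records$rho),
      ifelse(est_C + est_D > 0, est_C / (est_C + est_D), NA_real_),
      effective_count_rate(est_C, est_D, est_L, records$rho)
    )
  )
  dplyr::mutate(records, gamma = gamma)
}

#' Summarize experimental conditions
#'
#' Per condition (regime by threshold, or by \eqn{\rho} for the externality
#' design): action counts, the within-group cooperation rate
#' `n_C / (n_C + n_D)` (or its \eqn{\rho}-weighted effective version), the
#' analytic group success rate implied by that cooperation rate, and the
#' normalized efficiencies computed from the empirical action shares.
#'
#' @param records A cohort tibble.
#' @param ... Game constants passed to [game_spec()] (endowment,
#'   group_reward, outside_payoff, group_size).
#' @return A tibble with one row per condition: `regime`, `threshold`,
#'   `rho`, `n_C`, `n_D`, `n_L`, `p_coop`, `p_success`, `efficiency_within`,
#'   `efficiency_population`.
#' @export
summarize_conditions <- function(records, ...) {
  grp <- dplyr::group_by(records, .data$regime, .data$threshold, .data$rho)
  counts <- dplyr::summarise(
    grp,
    n_C = sum(.data$action == "C"),
    n_D = sum(.data$action == "D"),
    n_L = sum(.data$action == "L"),
    .groups = "drop"
  )
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    row <- counts[i, ]
    spec <- game_spec(row$threshold, row$regime, ...)
    n_tot <- row$n_C + row$n_D + row$n_L
    if (n_tot == 0) {
      return(dplyr::mutate(row, p_coop = NA_real_, p_success = NA_real_,
                           efficiency_within = NA_real_,
                           efficiency_population = NA_real_))
    }
    shares <- c(C = row$n_C, D = row$n_D, L = row$n_L) / n_tot
    rho <- row$rho
    p <- if (is.na(rho)) cooperation_rate(shares)
         else effective_cooperation_rate(shares, rho)
    dplyr::mutate(
      row,
      p_coop = p,
      p_success = group_success_rate(p, spec),
      efficiency_within = expected_efficiency(shares, spec, include_loners = FALSE),
      efficiency_population = expected_efficiency(shares, spec, include_loners = TRUE)
    )
  })
  dplyr::bind_rows(rows)
}

#' Participant-resampled bootstrap confidence intervals
#'
#' The experiment's unit of clustering is the participant (a within-subject
#' design with randomized order), so resampling draws whole participants with
#' replacement: all of a resampled participant's condition rows move
#' together, and each draw counts as a new participant. One resampling
#' stream drives all statistics jointly, rather than resampling independently
#' per statistic. The 95% interval is the 2.5 and 97.5 percentile of the
#' bootstrap distribution; resamples on which a statistic is undefined
#' (`NA`, e.g. everyone leaves) are excluded from its percentiles and
#' counted.
#'
#' @param records A cohort tibble with a `participant_id` column.
#' @param statistic Function taking a records tibble and returning a named
#'   numeric vector (or a single number) of statistics; `NA` components flag
#'   undefined values on that resample.
#' @param B Number of bootstrap iterations (default 1000).
#' @param seed Optional integer seed for the resampling stream.
#' @param level Confidence level (default 0.95).
#' @return A tibble with one row per statistic: `statistic`, `point` (from
#'   the original data), `ci_low`, `ci_high`, `n_iterations`,
#'   `n_undefined`.
#' @export
bootstrap_ci <- function(records, statistic, B = 1000L, seed = NULL,
                         level = 0.95) {
  stopifnot(is.function(statistic), B >= 1L)
  run <- function() {
    ids <- sort(unique(records$participant_id))
    idx_by_id <- split(seq_len(nrow(records)), records$participant_id)
    idx_by_id <- idx_by_id[as.character(ids)]
    point <- statistic(records)
    if (is.null(names(point))) {
      names(point) <- if (length(point) == 1L) "statistic"
                      else paste0("statistic_", seq_along(point))
    }
    draws <- matrix(NA_real_, nrow = B, ncol = length(point))
    for (b in seq_len(B)) {
      take <- sample.int(length(ids), replace = TRUE)
      rows <- unlist(idx_by_id[take], use.names = FALSE)
      resampled <- records[rows, , drop = FALSE]
      # each draw is a new participant, even if the same person recurs
      resampled$participant_id <- rep(seq_along(take),
                                      lengths(idx_by_id)[take])
      val <- statistic(resampled)
      draws[b, ] <- as.numeric(val)[seq_along(point)]
    }
    alpha <- (1 - level) / 2
    tibble::tibble(
      statistic = names(point),
      point = as.numeric(point),
      ci_low = apply(draws, 2L, stats::quantile, probs = alpha, na.rm = TRUE,
                     names = FALSE),
      ci_high = apply(draws, 2L, stats::quantile, probs = 1 - alpha,
                      na.rm = TRUE, names = FALSE),
      n_iterations = B,
      n_undefined = apply(draws, 2L, function(x) sum(is.na(x)))
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Random-intercept logistic regression
#'
#' Maximum-likelihood logistic regression with a participant-level random
#' intercept, the model family used for all individual-level contrasts
#' (defection on beliefs and threshold, leaving on mandatory-condition
#' beliefs or actions, belief change on action change). A thin wrapper over
#' [lme4::glmer()] that returns Wald summaries and surfaces convergence or
#' separation problems instead of hiding them.
#'
#' @param data A data frame.
#' @param formula Model formula including the random intercept term, e.g.
#'   `defect ~ gamma + threshold + (1 | participant_id)`.
#' @param ... Passed to [lme4::glmer()].
#' @return An object of class `ri_logit`: a list with `coefficients` (tibble
#'   with `term`, `estimate`, `std_error`, `z`, `p_value`, `ci_low`,
#'   `ci_high`), `ranef_variance`, `n_obs`, `n_groups`, `messages`
#'   (convergence/separation diagnostics, empty when clean), and `fit` (the
#'   underlying `glmerMod`).
#' @export
fit_random_intercept_logit <- function(data, formula, ...) {
  msgs <- character()
  collect <- function(expr) {
    withCallingHandlers(
      expr,
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        msgs <<- c(msgs, conditionMessage(m))
        invokeRestart("muffleMessage")
      }
    )
  }
  fit <- collect(lme4::glmer(formula, data = data, family = stats::binomial(), ...))
  sm <- collect(summary(fit)$coefficients)
  est <- sm[, "Estimate"]
  se <- sm[, "Std. Error"]
  zcrit <- stats::qnorm(0.975)
  coefs <- tibble::tibble(
    term = rownames(sm),
    estimate = est,
    std_error = se,
    z = sm[, "z value"],
    p_value = sm[, "Pr(>|z|)"],
    ci_low = est - zcrit * se,
    ci_high = est + zcrit * se
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(
    list(
      coefficients = coefs,
      ranef_variance = vc$vcov[1L],
      n_obs = stats::nobs(fit),
      n_groups = lme4::ngrps(fit)[[1L]],
      messages = msgs,
      fit = fit
    ),
    class = "ri_logit"
  )
}

#' @export
print.ri_logit <- function(x, ...) {
  cat(sprintf(
    "Random-intercept logistic regression (%d obs, %d participants)\n",
    x$n_obs, x$n_groups
  ))
  print(x$coefficients)
  cat(sprintf("Random-intercept variance: %.4g\n", x$ranef_variance))
  if (length(x$messages) > 0) {
    cat("Diagnostics:\n")
    for (m in x$messages) cat("  -", trimws(m), "\n")
  }
  invisible(x)
}

#' Compare belief-based predictors of cooperation by ROC-AUC
#'
#' Among participants who opted in (action C or D), compares how well two
#' predictors rank cooperators above defectors: the raw belief \eqn{\gamma}
#' itself and the pivotal probability computed from it. The AUC is the
#' rank-based (midrank-tied) area under the ROC curve. Because the pivotal
#' probability is a strictly increasing function of \eqn{\gamma} when the
#' threshold equals the group size, the two AUCs coincide exactly there; the
#' comparison is informative only at lower thresholds.
#'
#' @param records Cohort rows of a single condition, with a `gamma` column
#'   (see [elicited_belief_to_gamma()]).
#' @param spec A [game_spec()] for the condition.
#' @return A tibble with rows for `"raw_belief"` and `"pivotal_probability"`:
#'   `predictor`, `auc` (`NA` when only one class is present), `n`,
#'   `threshold`, `regime`.
#' @export
roc_compare <- function(records, spec) {
  stopifnot(is_game_spec(spec), "gamma" %in% names(records))
  d <- records[records$action %in% c("C", "D") & !is.na(records$gamma), ]
  out <- tibble::tibble(
    predictor = c("raw_belief", "pivotal_probability"),
    auc = NA_real_,
    n = nrow(d),
    threshold = spec$threshold,
    regime = spec$regime
  )
  if (length(unique(d$action)) < 2L) return(out)
  resp <- factor(d$action, levels = c("D", "C"))
  preds <- list(
    raw_belief = d$gamma,
    pivotal_probability = pivotal_probability(d$gamma, spec)
  )
  out$auc <- unname(vapply(preds, function(p) {
    as.numeric(pROC::auc(resp, p, direction = "<", quiet = TRUE))
  }, numeric(1)))
  out
}

#' Pair mandatory and voluntary rows: belief and action changes
#'
#' For the main design, pairs each participant's mandatory and voluntary
#' rows at equal threshold and classifies the action change: `"positive"`
#' for defection turning into cooperation, `"negative"` for the opposite,
#' `"none"` otherwise. Participants who left under the voluntary condition
#' are flagged (`loner = TRUE`); belief change \eqn{\Delta\gamma =
#' \gamma_{voluntary} - \gamma_{mandatory}} is reported for non-loners, the
#' population on which belief-change analyses run.
#'
#' @param records A main-design cohort tibble with a `gamma` column.
#' @return A tibble with one row per participant per threshold:
#'   `participant_id`, `threshold`, `action_mandatory`, `action_voluntary`,
#'   `gamma_mandatory`, `gamma_voluntary`, `delta_gamma`, `change`
#'   (`"positive"`, `"none"`, `"negative"`), `loner`.
#' @export
belief_action_change <- function(records) {
  stopifnot(all(c("gamma", "regime") %in% names(records)))
  keep <- c("participant_id", "threshold", "action", "gamma")
  mand <- dplyr::filter(records, .data$regime == "mandatory")[, keep]
  vol <- dplyr::filter(records, .data$regime == "voluntary")[, keep]
  paired <- dplyr::inner_join(
    mand, vol,
    by = c("participant_id", "threshold"),
    suffix = c("_mandatory", "_voluntary")
  )
  n_expected <- length(unique(records$participant_id)) *
    length(unique(records$threshold))
  if (nrow(paired) < n_expected) {
    warning(sprintf("%d participant-threshold pairs are incomplete and dropped",
                    n_expected - nrow(paired)), call. = FALSE)
  }
  dplyr::mutate(
    paired,
    loner = .data$action_voluntary == "L",
    delta_gamma = ifelse(.data$loner, NA_real_,
                         .data$gamma_voluntary - .data$gamma_mandatory),
    change = dplyr::case_when(
      loner ~ "none",
      action_mandatory == "D" & action_voluntary == "C" ~ "positive",
      action_mandatory == "C" & action_voluntary == "D" ~ "negative",
      TRUE ~ "none"
    )
  )
}
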