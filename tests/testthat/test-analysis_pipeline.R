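make_records <- function(regime, threshold, est, action, rho = NA_real_) {
  tibble::tibble(
    participant_id = seq_along(action),
    session_id = 1L,
    regime = regime,
    threshold = threshold,
    rho = rho,
    est_C = est[1], est_D = est[2], est_L = est[3],
    confidence = 50L,
    action = action,
    condition_order = 1L
  )
}

test_that("elicited counts convert to beliefs per regime", {
  mand <- make_records("mandatory", 2L, c(15L, 15L, 0L), c("C", "D"))
  expect_equal(elicited_belief_to_gamma(mand)$gamma, c(0.5, 0.5))
  vol <- make_records("voluntary", 2L, c(10L, 5L, 15L), c("C", "D"))
  expect_equal(elicited_belief_to_gamma(vol)$gamma, c(2 / 3, 2 / 3))
  rho1 <- make_records("voluntary", 4L, c(10L, 10L, 10L), "C", rho = 1)
  expect_equal(elicited_belief_to_gamma(rho1)$gamma, 1 / 3)
  # no opt-ins believed: undefined, flagged not thrown
  allL <- make_records("voluntary", 2L, c(0L, 0L, 30L), "L")
  expect_true(is.na(elicited_belief_to_gamma(allL)$gamma))
  # zero externality equals the voluntary main-design conversion
  rho0 <- make_records("voluntary", 4L, c(10L, 5L, 15L), "C", rho = 0)
  expect_equal(elicited_belief_to_gamma(rho0)$gamma, 2 / 3)
})

test_that("condition summaries aggregate counts into rates and efficiencies", {
  rec <- make_records("voluntary", 5L, c(20L, 5L, 5L), rep("C", 10))
  s <- summarize_conditions(rec)
  expect_equal(s$n_C, 10)
  expect_equal(s$p_coop, 1)
  expect_equal(s$p_success, 1)
  rec2 <- make_records("mandatory", 5L, c(15L, 15L, 0L),
                       rep(c("C", "D"), each = 5))
  s2 <- summarize_conditions(rec2)
  expect_equal(s2$p_coop, 0.5)
  expect_equal(s2$p_success, 0.03125)
  # externality conditions use the rho-weighted rate
  rec3 <- make_records("voluntary", 4L, c(10L, 10L, 10L),
                       rep(c("C", "D", "L"), each = 4), rho = 1)
  s3 <- summarize_conditions(rec3)
  expect_equal(s3$p_coop, 1 / 3)
})

test_that("summaries of a known generator match its analytic prediction", {
  cfg <- default_main_config(
    n_participants = 4000, belief_mean = 0.5, belief_concentration = 4,
    optimism_shift = 0, decision_noise = 0, belief_correlation = 0, seed = 55
  )
  s <- summarize_conditions(generate_cohort(cfg))
  for (q in c(2, 4, 5)) {
    spec <- game_spec(q, "mandatory")
    p_ana <- cooperation_rate(action_shares(beta_belief(2, 2), spec))
    p_emp <- s$p_coop[s$regime == "mandatory" & s$threshold == q]
    se <- sqrt(p_ana * (1 - p_ana) / 4000)
    expect_lt(abs(p_emp - p_ana), 3 * se)
  }
})

test_that("bootstrap CIs are percentile intervals over participants", {
  rec <- tibble::tibble(
    participant_id = rep(1:50, each = 2),
    value = rnorm(100)
  )
  # a constant statistic has a degenerate interval
  ci <- bootstrap_ci(rec, function(d) c(k = 3.5), B = 50, seed = 1)
  expect_equal(ci$ci_low, 3.5)
  expect_equal(ci$ci_high, 3.5)
  expect_equal(ci$point, 3.5)
  # interval orientation and point inclusion for a smooth statistic
  ci2 <- bootstrap_ci(rec, function(d) c(m = mean(d$value)), B = 400, seed = 2)
  expect_lte(ci2$ci_low, ci2$ci_high)
  expect_lte(ci2$ci_low, ci2$point)
  expect_gte(ci2$ci_high, ci2$point)
  # invariant to row order, and to order-preserving relabeling
  perm <- rec[sample(nrow(rec)), ]
  expect_equal(
    bootstrap_ci(rec, function(d) c(m = mean(d$value)), B = 100, seed = 3),
    bootstrap_ci(perm, function(d) c(m = mean(d$value)), B = 100, seed = 3)
  )
  relab <- dplyr::mutate(rec, participant_id = participant_id * 10L)
  expect_equal(
    bootstrap_ci(rec, function(d) c(m = mean(d$value)), B = 100, seed = 3)[-1],
    bootstrap_ci(relab, function(d) c(m = mean(d$value)), B = 100, seed = 3)[-1]
  )
  # undefined resamples are counted and excluded, not fatal
  ci3 <- bootstrap_ci(
    rec,
    function(d) c(u = if (stats::runif(1) < 0.3) NA_real_ else mean(d$value)),
    B = 200, seed = 4
  )
  expect_gt(ci3$n_undefined, 0)
  expect_false(is.na(ci3$ci_low))
  expect_error(bootstrap_ci(rec, mean, B = 0), "B")
})

test_that("participants resample as whole blocks", {
  rec <- tibble::tibble(
    participant_id = rep(1:20, each = 3),
    condition = rep(1:3, 20),
    value = rep(1:20, each = 3) # identical across a participant's rows
  )
  # a statistic detecting broken blocks: within-participant spread must be 0
  stat <- function(d) {
    spread <- tapply(d$value, d$participant_id, function(v) diff(range(v)))
    c(broken = max(spread), n = length(unique(d$participant_id)))
  }
  ci <- bootstrap_ci(rec, stat, B = 100, seed = 5)
  expect_equal(ci$ci_low[ci$statistic == "broken"], 0)
  expect_equal(ci$ci_high[ci$statistic == "broken"], 0)
  # each draw counts as a new participant: always 20 of them
  expect_equal(ci$ci_low[ci$statistic == "n"], 20)
  expect_equal(ci$ci_high[ci$statistic == "n"], 20)
})

test_that("random-intercept logistic regression recovers known coefficients", {
  set.seed(42)
  n_part <- 400
  per <- 6
  id <- rep(seq_len(n_part), each = per)
  x <- rnorm(n_part * per)
  b_true <- -2
  u <- rep(rnorm(n_part, sd = 0.5), each = per)
  y <- rbinom(n_part * per, 1, plogis(1 + b_true * x + u))
  d <- data.frame(y = y, x = x, participant_id = id)
  fit <- fit_random_intercept_logit(d, y ~ x + (1 | participant_id))
  row <- fit$coefficients[fit$coefficients$term == "x", ]
  expect_lt(row$ci_low, b_true + 0.5)
  expect_gt(row$ci_high, b_true - 0.5)
  expect_true(row$ci_low <= row$estimate & row$estimate <= row$ci_high)
  expect_equal(row$z, row$estimate / row$std_error)
  expect_equal(fit$n_obs, n_part * per)
  expect_equal(fit$n_groups, n_part)
})

test_that("separable data surfaces a diagnostic instead of failing silently", {
  d <- data.frame(
    y = rep(c(0, 1), each = 20),
    x = rep(c(-1, 1), each = 20),
    participant_id = rep(1:20, 2)
  )
  fit <- fit_random_intercept_logit(d, y ~ x + (1 | participant_id))
  expect_gt(length(fit$messages), 0)
})

test_that("ROC comparison: midranks, coincidence at threshold 5, and nulls", {
  # brute-force pair counting agrees with the AUC on tied data
  set.seed(8)
  rec <- make_records("mandatory", 2L, c(15L, 15L, 0L),
                      sample(c("C", "D"), 40, replace = TRUE))
  rec$gamma <- round(runif(40), 1) # force ties
  spec <- game_spec(2, "mandatory")
  rc <- roc_compare(rec, spec)
  expect_equal(
    rc$auc[rc$predictor == "raw_belief"],
    pairwise_auc(rec$gamma, rec$action == "C")
  )
  # at threshold 5 the pivotal probability is increasing in gamma, so the
  # two rankings and hence the two AUCs coincide exactly
  spec5 <- game_spec(5, "mandatory")
  rec5 <- rec
  rc5 <- roc_compare(rec5, spec5)
  expect_identical(rc5$auc[1], rc5$auc[2])
  # AUC is invariant under strictly increasing transforms of the predictor
  rec_t <- rec
  rec_t$gamma <- plogis(5 * rec$gamma)
  rc_t <- roc_compare(rec_t, spec)
  expect_equal(rc_t$auc[rc_t$predictor == "raw_belief"],
               rc$auc[rc$predictor == "raw_belief"])
  # an uninformative predictor drifts to 0.5
  set.seed(9)
  big <- make_records("mandatory", 2L, c(15L, 15L, 0L),
                      sample(c("C", "D"), 4000, replace = TRUE))
  big$gamma <- runif(4000)
  rc_null <- roc_compare(big, spec)
  expect_lt(abs(rc_null$auc[1] - 0.5), 0.03)
  # noiseless thresholding of the predictor gives a perfect AUC
  det <- big
  det$action <- ifelse(det$gamma > 0.6, "C", "D")
  rc_det <- roc_compare(det, spec)
  expect_equal(rc_det$auc[rc_det$predictor == "raw_belief"], 1)
  # single-class conditions are flagged undefined
  onec <- make_records("mandatory", 2L, c(15L, 15L, 0L), rep("C", 5))
  onec$gamma <- runif(5)
  expect_true(all(is.na(roc_compare(onec, spec)$auc)))
})

test_that("belief and action changes pair regimes within participant and threshold", {
  rec <- tibble::tibble(
    participant_id = rep(1:3, each = 2),
    session_id = 1L,
    regime = rep(c("mandatory", "voluntary"), 3),
    threshold = 4L,
    rho = NA_real_,
    est_C = 1L, est_D = 1L, est_L = 0L,
    confidence = 50L,
    action = c("D", "C", "C", "C", "C", "L"),
    condition_order = 1L,
    gamma = c(0.3, 0.8, 0.5, 0.5, 0.6, 0.2)
  )
  ch <- belief_action_change(rec)
  expect_equal(nrow(ch), 3)
  p1 <- ch[ch$participant_id == 1, ]
  expect_equal(p1$change, "positive")
  expect_equal(p1$delta_gamma, 0.5)
  p2 <- ch[ch$participant_id == 2, ]
  expect_equal(p2$change, "none")
  expect_equal(p2$delta_gamma, 0)
  p3 <- ch[ch$participant_id == 3, ]
  expect_true(p3$loner)
  expect_true(is.na(p3$delta_gamma))
  # a missing pair is flagged
  expect_warning(belief_action_change(rec[-2, ]), "incomplete")
})
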