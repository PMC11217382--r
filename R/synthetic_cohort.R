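#' Configuration for the synthetic cohort generator
#'
#' Describes a synthetic experiment emulating the within-subject session
#' design: around 30 participants per session, each playing either the
#' 2 (mandatory/voluntary) x 3 (threshold 2, 4, 5) main design or the
#' three-level loner-externality design (threshold 4, \eqn{\rho \in \{0,
#' 0.5, 1\}}). Latent beliefs about others' cooperativeness are Beta
#' distributed per condition, correlated within participant through a shared
#' latent quantile; moving from mandatory to voluntary participation shifts a
#' configurable fraction of participants' beliefs upward on the logit scale
#' (the optimism mechanism); actions are drawn by a softmax over expected
#' payoffs, which nests the exact best response at zero noise. Elicited
#' beliefs are integer counts of 30 others per action, drawn multinomially
#' from each participant's implied action-share expectations.
#'
#' All generative parameters are synthetic stand-ins chosen to reproduce the
#' qualitative structure of such experiments, not estimates from any dataset.
#'
#' @param design `"main"` (2 x 3 regime-by-threshold) or `"externality"`
#'   (three \eqn{\rho} levels at threshold 4).
#' @param n_participants Cohort size; defaults to 191 for the main design and
#'   182 for the externality design.
#' @param n_sessions Number of sessions the cohort is split into (default 6,
#'   giving sessions of about 30).
#' @param thresholds Thresholds of the main design (default `c(2, 4, 5)`).
#' @param rho_levels Externality levels of the additional design
#'   (default `c(0, 0.5, 1)`).
#' @param belief_mean Mean of the latent belief Beta distribution. For the
#'   main design, a single value or one per threshold (mandatory baseline;
#'   default 0.6). For the externality design, one value per `rho_levels`
#'   (default `c(0.7, 0.5, 0.35)`: optimism falls as loners weigh more).
#' @param belief_concentration Beta concentration \eqn{\nu} (default 5).
#' @param optimism_shift Additive logit-scale belief shift \eqn{\delta}
#'   applied when moving mandatory to voluntary (default 0.8).
#' @param shift_fraction Fraction of participants receiving the optimism
#'   shift (default 0.5).
#' @param decision_noise Softmax temperature \eqn{\lambda \ge 0} in points;
#'   0 gives the exact best response (default 2).
#' @param belief_correlation Correlation of the shared participant-level
#'   latent quantile across conditions, in \[0, 1) (default 0.7).
#' @param leave_share_belief Believed population share of leavers used when
#'   converting beliefs to counts. For the main design `NULL` (computed
#'   analytically from the belief distribution per threshold); for the
#'   externality design one value per `rho_levels`
#'   (default `c(0.3, 0.55, 0.7)`).
#' @param endowment,group_reward,outside_payoff,group_size Game constants
#'   passed to [game_spec()].
#' @param seed Integer RNG seed; the generator is deterministic given the
#'   configuration.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(design = c("main", "externality"),
                          n_participants = NULL,
                          n_sessions = 6L,
                          thresholds = c(2L, 4L, 5L),
                          rho_levels = c(0, 0.5, 1),
                          belief_mean = NULL,
                          belief_concentration = 5,
                          optimism_shift = 0.8,
                          shift_fraction = 0.5,
                          decision_noise = 2,
                          belief_correlation = 0.7,
                          leave_share_belief = NULL,
                          endowment = 10, group_reward = 30,
                          outside_payoff = 10, group_size = 5L,
                          seed = 1L) {
  design <- match.arg(design)
  if (is.null(n_participants)) {
    n_participants <- if (design == "main") 191L else 182L
  }
  if (is.null(belief_mean)) {
    belief_mean <- if (design == "main") 0.6 else c(0.7, 0.5, 0.35)
  }
  if (design == "main") {
    belief_mean <- rep_len(belief_mean, length(thresholds))
  } else {
    belief_mean <- rep_len(belief_mean, length(rho_levels))
    if (is.null(leave_share_belief)) leave_share_belief <- c(0.3, 0.55, 0.7)
    leave_share_belief <- rep_len(leave_share_belief, length(rho_levels))
    stopifnot(all(leave_share_belief >= 0 & leave_share_belief < 1))
  }
  stopifnot(
    n_participants >= 1L, n_sessions >= 1L,
    all(belief_mean > 0 & belief_mean < 1),
    belief_concentration > 0,
    shift_fraction >= 0, shift_fraction <= 1,
    decision_noise >= 0,
    belief_correlation >= 0, belief_correlation < 1,
    all(rho_levels >= 0 & rho_levels <= 1)
  )
  structure(
    list(
      design = design,
      n_participants = as.integer(n_participants),
      n_sessions = as.integer(n_sessions),
      thresholds = as.integer(thresholds),
      rho_levels = rho_levels,
      belief_mean = belief_mean,
      belief_concentration = belief_concentration,
      optimism_shift = optimism_shift,
      shift_fraction = shift_fraction,
      decision_noise = decision_noise,
      belief_correlation = belief_correlation,
      leave_share_belief = leave_share_belief,
      endowment = endowment, group_reward = group_reward,
      outside_payoff = outside_payoff, group_size = as.integer(group_size),
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

# Split n participants into n_sessions near-equal sessions.
session_sizes <- function(n, n_sessions) {
  base <- n %/% n_sessions
  extra <- n %% n_sessions
  rep(base, n_sessions) + c(rep(1L, extra), rep(0L, n_sessions - extra))
}

logit_shift <- function(gamma, delta, eps = 1e-6) {
  g <- pmin(pmax(gamma, eps), 1 - eps)
  stats::plogis(stats::qlogis(g) + delta)
}

# Draw one action per row by softmax over expected payoffs (rows of `ep`);
# lambda = 0 collapses to the argmax with the C > L > D tie rule.
softmax_actions <- function(ep, lambda) {
  acts <- colnames(ep)
  if (lambda == 0) {
    pref <- intersect(.tie_order, acts)
    ep <- ep[, pref, drop = FALSE]
    return(pref[max.col(ep, ties.method = "first")])
  }
  z <- exp((ep - apply(ep, 1L, max)) / lambda)
  p <- z / rowSums(z)
  u <- stats::runif(nrow(ep))
  cum <- t(apply(p, 1L, cumsum))
  acts[max.col(u < cum, ties.method = "first")]
}

# Multinomial belief-elicitation counts, one draw of `total` per row of probs.
draw_counts <- function(probs, total = 30L) {
  t(apply(probs, 1L, function(p) stats::rmultinom(1L, total, p)[, 1L]))
}

#' Generate a synthetic main-design cohort
#'
#' Produces one participant record per participant per condition of the
#' 2 (regime) x 3 (threshold) within-subject design: elicited counts of 30
#' others per action, a confidence rating, the chosen action, and the
#' condition position. Half of the cohort plays all voluntary conditions
#' first and half all mandatory conditions first, with threshold order
#' shuffled within block. The output is byte-identical across calls with the
#' same configuration.
#'
#' @param config A [cohort_config()] with `design = "main"`.
#' @return A tibble with columns `participant_id`, `session_id`, `regime`,
#'   `threshold`, `rho` (`NA` for the main design), `est_C`, `est_D`,
#'   `est_L`, `confidence`, `action`, `condition_order`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"), config$design == "main")
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_participants
  qs <- config$thresholds
  nu <- config$belief_concentration
  sizes <- session_sizes(n, config$n_sessions)
  session_id <- rep(seq_along(sizes), sizes)
  vol_first <- sample(rep_len(c(TRUE, FALSE), n))
  shifted <- stats::runif(n) < config$shift_fraction
  z_shared <- stats::rnorm(n)
  r <- config$belief_correlation

  specs <- list()
  leave_share <- numeric(length(qs))
  for (j in seq_along(qs)) {
    sp_v <- game_spec(qs[j], "voluntary",
                      group_size = config$group_size,
                      endowment = config$endowment,
                      group_reward = config$group_reward,
                      outside_payoff = config$outside_payoff)
    sp_m <- sp_v; sp_m$regime <- "mandatory"
    specs[[j]] <- list(voluntary = sp_v, mandatory = sp_m)
    # believed population share of leavers: analytic share implied by the
    # condition's belief distribution under the voluntary game
    dist <- beta_belief_mc(config$belief_mean[j], nu)
    leave_share[j] <- action_shares(dist, sp_v)[["L"]]
  }

  # per-participant condition order: regime blocks, thresholds shuffled within
  order_tbl <- lapply(seq_len(n), function(i) {
    blocks <- if (vol_first[i]) c("voluntary", "mandatory") else c("mandatory", "voluntary")
    tibble::tibble(
      participant_id = i,
      regime = rep(blocks, each = length(qs)),
      threshold = c(qs[sample.int(length(qs))], qs[sample.int(length(qs))]),
      condition_order = seq_len(2L * length(qs))
    )
  })
  order_tbl <- dplyr::bind_rows(order_tbl)

  rows <- list()
  for (j in seq_along(qs)) {
    q <- qs[j]
    alpha <- config$belief_mean[j] * nu
    beta <- (1 - config$belief_mean[j]) * nu
    eps_q <- stats::rnorm(n)
    u <- stats::pnorm(r * z_shared + sqrt(1 - r^2) * eps_q)
    gamma_mand <- stats::qbeta(u, alpha, beta)
    gamma_vol <- ifelse(shifted,
                        logit_shift(gamma_mand, config$optimism_shift),
                        gamma_mand)
    for (reg in c("mandatory", "voluntary")) {
      gm <- if (reg == "mandatory") gamma_mand else gamma_vol
      sp <- specs[[j]][[reg]]
      if (reg == "mandatory") {
        probs <- cbind(gm, 1 - gm, 0)
      } else {
        l <- leave_share[j]
        probs <- cbind((1 - l) * gm, (1 - l) * (1 - gm), l)
      }
      counts <- draw_counts(probs)
      ep <- expected_payoffs(gm, sp)
      action <- softmax_actions(ep, config$decision_noise)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        participant_id = seq_len(n),
        session_id = session_id,
        regime = reg,
        threshold = q,
        rho = NA_real_,
        est_C = counts[, 1L],
        est_D = counts[, 2L],
        est_L = counts[, 3L],
        confidence = as.integer(round(100 * stats::rbeta(n, 5, 2))),
        action = action
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::inner_join(out, order_tbl,
                           by = c("participant_id", "regime", "threshold"))
  dplyr::arrange(out, .data$participant_id, .data$condition_order)
}

#' Generate a synthetic loner-externality cohort
#'
#' Produces one record per participant per \eqn{\rho} level of the
#' externality design (voluntary participation, threshold 4). Beliefs grow
#' more pessimistic and the believed share of leavers grows as \eqn{\rho}
#' rises, per the configuration. Each participant's decision is evaluated
#' against the effective cooperation rate implied by their own elicited
#' counts, \eqn{e_C / (e_C + e_D + \rho\, e_L)}, so loner externality enters
#' the decision problem exactly as it enters the group outcome.
#'
#' @param config A [cohort_config()] with `design = "externality"`.
#' @inherit generate_cohort return
#' @export
generate_externality_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"), config$design == "externality")
  withr::with_seed(config$seed, generate_externality_cohort_impl(config))
}

generate_externality_cohort_impl <- function(config) {
  n <- config$n_participants
  rhos <- config$rho_levels
  nu <- config$belief_concentration
  sizes <- session_sizes(n, config$n_sessions)
  session_id <- rep(seq_along(sizes), sizes)
  z_shared <- stats::rnorm(n)
  r <- config$belief_correlation
  sp <- game_spec(4L, "voluntary",
                  group_size = config$group_size,
                  endowment = config$endowment,
                  group_reward = config$group_reward,
                  outside_payoff = config$outside_payoff)

  order_tbl <- lapply(seq_len(n), function(i) {
    tibble::tibble(participant_id = i, rho = sample(rhos),
                   condition_order = seq_along(rhos))
  })
  order_tbl <- dplyr::bind_rows(order_tbl)

  rows <- list()
  for (j in seq_along(rhos)) {
    rho <- rhos[j]
    alpha <- config$belief_mean[j] * nu
    beta <- (1 - config$belief_mean[j]) * nu
    eps_j <- stats::rnorm(n)
    u <- stats::pnorm(r * z_shared + sqrt(1 - r^2) * eps_j)
    gamma <- stats::qbeta(u, alpha, beta)
    l <- config$leave_share_belief[j]
    probs <- cbind((1 - l) * gamma, (1 - l) * (1 - gamma), l)
    counts <- draw_counts(probs)
    gamma_eff <- effective_count_rate(counts[, 1L], counts[, 2L], counts[, 3L], rho)
    gamma_eff[is.na(gamma_eff)] <- 0
    ep <- expected_payoffs(gamma_eff, sp)
    action <- softmax_actions(ep, config$decision_noise)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      participant_id = seq_len(n),
      session_id = session_id,
      regime = "voluntary",
      threshold = 4L,
      rho = rho,
      est_C = counts[, 1L],
      est_D = counts[, 2L],
      est_L = counts[, 3L],
      confidence = as.integer(round(100 * stats::rbeta(n, 5, 2))),
      action = action
    )
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::inner_join(out, order_tbl, by = c("participant_id", "rho"))
  dplyr::arrange(out, .data$participant_id, .data$condition_order)
}

# rho-weighted cooperation rate on elicited counts; NA when the denominator
# vanishes (no one believed to opt in).
effective_count_rate <- function(est_C, est_D, est_L, rho) {
  denom <- est_C + est_D + rho * est_L
  ifelse(denom > 0, est_C / denom, NA_real_)
}
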