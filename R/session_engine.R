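#' Assign participants to groups, with loner inclusion under externality
#'
#' Implements the group-formation stage: participants who opted in enter the
#' assignment pool, and each leaver independently enters with probability
#' `rho` (the loner externality). The pool is shuffled, groups of
#' `group_size` are formed, and the remainder (`pool size mod group_size`)
#' is sent to the individual option, chosen uniformly at random. Included
#' leavers occupy seats but contribute nothing to the group outcome.
#'
#' @param opt_in_ids Identifiers of participants choosing C or D.
#' @param leaver_ids Identifiers of participants choosing L (disjoint from
#'   `opt_in_ids`).
#' @param rho Loner externality in \[0, 1\]: inclusion probability of each
#'   leaver in the assignment pool.
#' @param spec A [game_spec()].
#' @param seed Optional integer seed; when supplied the assignment is
#'   reproducible and the caller's RNG state is untouched.
#' @return A tibble with columns `participant_id`, `group_id` (`NA` for the
#'   individual option), and `included_loner` (leaver seated in a group).
#' @examples
#' assign_groups(1:7, integer(0), rho = 0, game_spec(4, "voluntary"), seed = 1)
#' @export
assign_groups <- function(opt_in_ids, leaver_ids, rho, spec, seed = NULL) {
  stopifnot(is_game_spec(spec), length(rho) == 1L, rho >= 0, rho <= 1,
            !anyDuplicated(c(opt_in_ids, leaver_ids)))
  run <- function() {
    included <- leaver_ids[stats::runif(length(leaver_ids)) < rho]
    pool <- c(opt_in_ids, included)
    n_groups <- length(pool) %/% spec$group_size
    shuffled <- if (length(pool) > 0) sample(pool) else pool
    grouped <- utils::head(shuffled, n_groups * spec$group_size)
    group_of <- rep(seq_len(n_groups), each = spec$group_size)
    out <- tibble::tibble(
      participant_id = c(opt_in_ids, leaver_ids),
      group_id = NA_integer_,
      included_loner = c(rep(FALSE, length(opt_in_ids)),
                         leaver_ids %in% included)
    )
    idx <- match(grouped, out$participant_id)
    out$group_id[idx] <- group_of
    # an included leaver left out by the remainder rule is just a loner
    out$included_loner <- out$included_loner & !is.na(out$group_id)
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Realize payoffs from a group assignment and actions
#'
#' Evaluates each group's success against the threshold, counting only C
#' actions (included leavers occupy seats and contribute nothing), and pays
#' every participant: group members via [realized_payoff()], leavers and
#' remainder participants the individual-option payoff
#' `endowment + outside_payoff`.
#'
#' @param assignment Output of [assign_groups()].
#' @param actions Named character vector or tibble (`participant_id`,
#'   `action`) giving each participant's action.
#' @param spec A [game_spec()].
#' @return A tibble with columns `participant_id`, `group_id`, `action`,
#'   `group_success` (`NA` for the individual option), `payoff`.
#' @export
realize_outcomes <- function(assignment, actions, spec) {
  stopifnot(is_game_spec(spec))
  if (is.data.frame(actions)) {
    actions <- stats::setNames(actions$action, actions$participant_id)
  }
  act <- actions[as.character(assignment$participant_id)]
  if (any(is.na(act))) {
    stop("every assigned participant needs an action", call. = FALSE)
  }
  if (any(act == "L" & !assignment$included_loner & !is.na(assignment$group_id))) {
    stop("a leaver was seated without being flagged as an included loner",
         call. = FALSE)
  }
  out <- tibble::tibble(
    participant_id = assignment$participant_id,
    group_id = assignment$group_id,
    action = unname(act)
  )
  coop_by_group <- tapply(out$action == "C", out$group_id, sum)
  n_coop <- as.integer(coop_by_group[as.character(out$group_id)])
  out$group_success <- ifelse(is.na(out$group_id), NA,
                              n_coop >= spec$threshold)
  loner_pay <- spec$endowment + spec$outside_payoff
  pay <- numeric(nrow(out))
  in_group <- !is.na(out$group_id)
  seated_loner <- in_group & out$action == "L"
  pay[!in_group] <- loner_pay       # loners and remainder participants
  pay[seated_loner] <- loner_pay    # included leavers keep the loner payoff
  rest <- in_group & !seated_loner
  pay[rest] <- realized_payoff(out$action[rest], n_coop[rest], spec)
  out$payoff <- pay
  out
}

#' Simulate one condition: assignment plus payoff realization
#'
#' Convenience wrapper running [assign_groups()] and [realize_outcomes()] on
#' the rows of a cohort table belonging to a single condition.
#'
#' @param records Participant records of one condition (columns
#'   `participant_id`, `action`).
#' @param spec A [game_spec()].
#' @param rho Loner externality used for the assignment (default 0).
#' @param seed Optional integer seed for the assignment.
#' @return The payoff table of [realize_outcomes()].
#' @export
simulate_condition <- function(records, spec, rho = 0, seed = NULL) {
  opt_in <- records$participant_id[records$action != "L"]
  leavers <- records$participant_id[records$action == "L"]
  asg <- assign_groups(opt_in, leavers, rho, spec, seed = seed)
  realize_outcomes(asg, records, spec)
}

#' Estimation-accuracy bonus
#'
#' The incentive for belief elicitation: a participant estimating counts
#' \eqn{e_x} of 30 others per action earns
#' \deqn{v = 800 - \frac{80}{6} \sum_x \left| \frac{e_x}{30} -
#'   \hat p_x \right|}
#' JPY, where \eqn{\hat p_x} is the realized proportion of action \eqn{x}
#' among the other participants. A perfectly calibrated estimate earns 800.
#' Note the formula's floor for a single condition is
#' \eqn{800 - (80/6)\cdot 2 \approx 773.3} JPY, since the L1 distance
#' between two probability vectors is at most 2.
#'
#' @param est Named integer counts (names among `"C"`, `"D"`, `"L"`) summing
#'   to 30 over the actions available in the condition.
#' @param realized_actions Character vector of the other participants'
#'   actions.
#' @return Bonus amount in JPY (single number).
#' @examples
#' estimation_bonus(c(C = 20, D = 10, L = 0), rep(c("C", "D"), c(20, 10)))
#' @export
estimation_bonus <- function(est, realized_actions) {
  acts <- names(est)
  stopifnot(!is.null(acts), all(acts %in% c("C", "D", "L")),
            length(realized_actions) >= 1L,
            all(realized_actions %in% acts))
  if (sum(est) != 30L) {
    stop("estimated counts must sum to 30", call. = FALSE)
  }
  realized <- vapply(acts, function(a) mean(realized_actions == a), numeric(1))
  800 - (80 / 6) * sum(abs(est / 30 - realized))
}

#' Points-based bonus
#'
#' The action incentive: 20 JPY per point earned in the selected condition,
#' so payoffs of 0 to 40 points map onto 0 to 800 JPY.
#'
#' @param points Points earned (non-negative; vectorized).
#' @return Bonus amount in JPY.
#' @examples
#' points_bonus(c(0, 20, 40))
#' @export
points_bonus <- function(points) {
  stopifnot(all(points >= 0))
  20 * points
}
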