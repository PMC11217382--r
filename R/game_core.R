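#' Probability that at least k of the other group members cooperate
#'
#' Upper binomial tail in the subjective belief `gamma`: the probability that
#' at least `k` of the `n_others` co-players cooperate when each cooperates
#' independently with probability `gamma`. This is the building block of the
#' expected payoffs: a cooperator needs at least `q - 1` of the others, a
#' defector at least `q`.
#'
#' @param gamma Belief about others' cooperativeness, in \[0, 1\]. Vectorized.
#' @param k Minimum number of cooperating others; `k <= 0` gives 1 and
#'   `k > n_others` gives 0.
#' @param n_others Number of other group members (4 in a five-member group).
#' @return Probability (same length as `gamma`).
#' @examples
#' tail_prob_others(0.5, k = 3, n_others = 4) # 0.3125
#' @export
tail_prob_others <- function(gamma, k, n_others) {
  stopifnot(length(k) == 1L, length(n_others) == 1L, n_others >= 0)
  if (any(is.na(gamma)) || any(gamma < 0 | gamma > 1)) {
    stop("`gamma` must lie in [0, 1]", call. = FALSE)
  }
  if (k <= 0) return(rep(1, length(gamma)))
  if (k > n_others) return(rep(0, length(gamma)))
  stats::pbinom(k - 1, size = n_others, prob = gamma, lower.tail = FALSE)
}

#' Expected payoff of each action given a belief
#'
#' Expected total points for cooperating, defecting, and (under voluntary
#' participation) leaving, when each of the other `group_size - 1` members is
#' believed to cooperate independently with probability `gamma`:
#' \deqn{E[\pi | C] = R\,\Gamma_{q-1}, \quad
#'       E[\pi | D] = e + R\,\Gamma_{q}, \quad
#'       E[\pi | L] = e + s,}
#' where \eqn{R} is the group reward, \eqn{e} the endowment, \eqn{s} the
#' outside payoff, and \eqn{\Gamma_k} = [tail_prob_others()]. The leave payoff
#' is constant in `gamma`; it is omitted under mandatory participation.
#'
#' @param gamma Belief in \[0, 1\]; may be a vector.
#' @param spec A [game_spec()].
#' @return For scalar `gamma`, a named numeric vector over the available
#'   actions; for vector `gamma`, a matrix with one row per belief and one
#'   column per action.
#' @examples
#' expected_payoffs(0.5, game_spec(4, "mandatory"))
#' @export
expected_payoffs <- function(gamma, spec) {
  stopifnot(is_game_spec(spec))
  n_others <- spec$group_size - 1L
  q <- spec$threshold
  out <- cbind(
    C = spec$group_reward * tail_prob_others(gamma, q - 1L, n_others),
    D = spec$endowment + spec$group_reward * tail_prob_others(gamma, q, n_others)
  )
  if (spec$regime == "voluntary") {
    out <- cbind(out, L = rep(spec$endowment + spec$outside_payoff, length(gamma)))
  }
  if (length(gamma) == 1L) out[1L, ] else out
}

# Preference order used to resolve exact expected-payoff ties: the prosocial
# action wins, then the outside option, then defection. Ties are measure-zero
# under any continuous belief distribution, so the rule only pins down
# interval boundaries reproducibly.
.tie_order <- c("C", "L", "D")

#' Best response to a belief
#'
#' The action maximizing [expected_payoffs()] at belief `gamma`. Exact ties
#' are broken in the fixed order C over L over D, so that region boundaries
#' are reproducible; ties have probability zero under continuous beliefs.
#'
#' @inheritParams expected_payoffs
#' @return Character vector of actions (`"C"`, `"D"`, or `"L"`), one per
#'   element of `gamma`.
#' @examples
#' best_response(c(0, 0.6, 1), game_spec(2, "mandatory"))
#' @export
best_response <- function(gamma, spec) {
  stopifnot(is_game_spec(spec))
  ep <- expected_payoffs(gamma, spec)
  if (is.null(dim(ep))) ep <- matrix(ep, nrow = 1L, dimnames = list(NULL, names(ep)))
  pref <- intersect(.tie_order, colnames(ep))
  ep <- ep[, pref, drop = FALSE]
  pref[max.col(ep, ties.method = "first")]
}

#' Probability of being pivotal
#'
#' The probability that exactly `q - 1` of the other group members cooperate,
#' so that the focal player's own cooperation is both necessary and sufficient
#' for the group to reach the threshold.
#'
#' @inheritParams expected_payoffs
#' @return Probability (vectorized over `gamma`).
#' @examples
#' pivotal_probability(0.5, game_spec(2, "mandatory")) # 0.25
#' @export
pivotal_probability <- function(gamma, spec) {
  stopifnot(is_game_spec(spec))
  if (any(is.na(gamma)) || any(gamma < 0 | gamma > 1)) {
    stop("`gamma` must lie in [0, 1]", call. = FALSE)
  }
  stats::dbinom(spec$threshold - 1L, size = spec$group_size - 1L, prob = gamma)
}

#' Realized payoff of an action given the group outcome
#'
#' Total points after the round for a player taking `action` in a group that
#' ended up with `n_cooperators` cooperators (the count includes the focal
#' player when `action = "C"`). The group succeeds when
#' `n_cooperators >= threshold`; cooperators then earn the group reward (their
#' endowment is invested either way), defectors keep the endowment and add the
#' reward on success, and loners earn `endowment + outside_payoff` regardless.
#'
#' @param action `"C"`, `"D"`, or `"L"` (vectorized).
#' @param n_cooperators Number of cooperators in the group, between 0 and
#'   `group_size` (vectorized; ignored for `"L"`).
#' @param spec A [game_spec()].
#' @return Points (numeric, vectorized).
#' @examples
#' realized_payoff(c("C", "D", "L"), 4, game_spec(4, "voluntary"))
#' @export
realized_payoff <- function(action, n_cooperators, spec) {
  stopifnot(is_game_spec(spec), all(action %in% c("C", "D", "L")))
  if (any(action == "L") && spec$regime == "mandatory") {
    stop("action \"L\" is unavailable under mandatory participation", call. = FALSE)
  }
  n <- rep_len(n_cooperators, length(action))
  chk <- action != "L"
  if (any(chk & (is.na(n) | n < 0 | n > spec$group_size))) {
    stop("`n_cooperators` must lie in [0, group_size]", call. = FALSE)
  }
  success <- !is.na(n) & n >= spec$threshold
  out <- numeric(length(action))
  out[action == "C"] <- ifelse(success[action == "C"], spec$group_reward, 0)
  out[action == "D"] <- spec$endowment +
    ifelse(success[action == "D"], spec$group_reward, 0)
  out[action == "L"] <- spec$endowment + spec$outside_payoff
  out
}
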