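#' Define a threshold public goods game
#'
#' A `game_spec` bundles the constants of the one-shot threshold public goods
#' game: five-member groups by default, a provision threshold `q`, and the
#' point values of the endowment, the group reward, and the outside individual
#' option. The `regime` determines whether the individual option ("leave", L)
#' is available: under `"mandatory"` participation the action set is \{C, D\},
#' under `"voluntary"` participation it is \{C, D, L\}.
#'
#' Payoffs are accounted as total points after the round, endowment fate
#' included: a loner always earns `endowment + outside_payoff` (20 under the
#' defaults), a defector keeps the endowment and adds the group reward on
#' success, a cooperator invests the endowment and earns the group reward only
#' on success.
#'
#' @param threshold Integer `q`: the minimum number of cooperators (out of
#'   `group_size`) needed for the group to produce the reward.
#' @param regime `"voluntary"` (outside option available) or `"mandatory"`.
#' @param group_size Number of members per group (default 5).
#' @param endowment Initial endowment in points (default 10).
#' @param group_reward Points added to every group member on success
#'   (default 30).
#' @param outside_payoff Extra points for choosing the individual option
#'   (default 10).
#'
#' @return An object of class `game_spec`.
#' @examples
#' game_spec(threshold = 5, regime = "voluntary")
#' @export
game_spec <- function(threshold,
                      regime = c("voluntary", "mandatory"),
                      group_size = 5L,
                      endowment = 10,
                      group_reward = 30,
                      outside_payoff = 10) {
  regime <- match.arg(regime)
  group_size <- as.integer(group_size)
  threshold <- as.integer(threshold)
  stopifnot(
    length(threshold) == 1L, length(group_size) == 1L,
    group_size >= 2L,
    threshold >= 1L, threshold <= group_size,
    endowment >= 0, group_reward >= 0, outside_payoff >= 0
  )
  structure(
    list(
      group_size = group_size,
      threshold = threshold,
      endowment = endowment,
      group_reward = group_reward,
      outside_payoff = outside_payoff,
      regime = regime
    ),
    class = "game_spec"
  )
}

#' @export
print.game_spec <- function(x, ...) {
  cat(sprintf(
    "Threshold public goods game: q = %d of %d, %s participation\n",
    x$threshold, x$group_size, x$regime
  ))
  cat(sprintf(
    "  endowment %g, group reward %g, outside option %g (loner total %g)\n",
    x$endowment, x$group_reward, x$outside_payoff,
    x$endowment + x$outside_payoff
  ))
  invisible(x)
}

#' Actions available under a game specification
#'
#' @param spec A [game_spec()].
#' @return Character vector: `c("C", "D", "L")` under voluntary participation,
#'   `c("C", "D")` under mandatory participation.
#' @export
available_actions <- function(spec) {
  stopifnot(inherits(spec, "game_spec"))
  if (spec$regime == "voluntary") c("C", "D", "L") else c("C", "D")
}

is_game_spec <- function(x) inherits(x, "game_spec")
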