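#' Beta model of the population belief distribution
#'
#' Beliefs about others' cooperativeness are heterogeneous across the
#' population; a Beta(\eqn{\alpha}, \eqn{\beta}) distribution on \[0, 1\] is a
#' flexible two-parameter model of that heterogeneity. `beta_belief()` takes
#' the shapes directly; `beta_belief_mc()` parameterizes by mean
#' \eqn{\mu = \alpha/(\alpha+\beta)} and concentration
#' \eqn{\nu = \alpha + \beta}, which is the parameterization used by the
#' default sweep grid.
#'
#' @param alpha,beta Positive Beta shape parameters.
#' @return An object of class `beta_belief`.
#' @examples
#' beta_belief(2, 2)
#' beta_belief_mc(mean = 0.5, concentration = 4)
#' @export
beta_belief <- function(alpha, beta) {
  stopifnot(length(alpha) == 1L, length(beta) == 1L, alpha > 0, beta > 0)
  structure(list(alpha = alpha, beta = beta), class = "beta_belief")
}

#' @rdname beta_belief
#' @param mean Mean belief \eqn{\mu} in (0, 1).
#' @param concentration Concentration \eqn{\nu > 0}; larger values give a
#'   tighter distribution around the mean.
#' @export
beta_belief_mc <- function(mean, concentration) {
  stopifnot(mean > 0, mean < 1, concentration > 0)
  beta_belief(mean * concentration, (1 - mean) * concentration)
}

#' @export
print.beta_belief <- function(x, ...) {
  cat(sprintf(
    "Beta belief distribution: alpha = %g, beta = %g (mean %.3f)\n",
    x$alpha, x$beta, x$alpha / (x$alpha + x$beta)
  ))
  invisible(x)
}

#' Best-response partition of the belief interval
#'
#' Partitions \[0, 1\] into maximal intervals on which each available action
#' maximizes expected payoff. Candidate boundaries are located on a fine grid
#' and refined by bisection on the change of the best response, so boundaries
#' are accurate to `tol`; at each interior boundary the payoffs of the two
#' adjacent actions tie.
#'
#' @param spec A [game_spec()].
#' @param grid_n Number of grid points used to locate boundary candidates.
#' @param tol Absolute tolerance for boundary positions.
#' @return A tibble with columns `lower`, `upper`, `action`, the intervals in
#'   increasing order covering \[0, 1\].
#' @examples
#' best_response_regions(game_spec(5, "voluntary"))
#' @export
best_response_regions <- function(spec, grid_n = 10001L, tol = 1e-10) {
  stopifnot(is_game_spec(spec), grid_n >= 3L)
  grid <- seq(0, 1, length.out = grid_n)
  br <- best_response(grid, spec)
  change <- which(br[-1L] != br[-grid_n])
  bounds <- vapply(change, function(i) {
    lo <- grid[i]
    hi <- grid[i + 1L]
    left <- br[i]
    # bisection on the first grid action vs. whatever follows
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (best_response(mid, spec) == left) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
  lower <- c(0, bounds)
  upper <- c(bounds, 1)
  tibble::tibble(lower = lower, upper = upper, action = br[c(1L, change + 1L)])
}

#' Population action shares under a belief distribution
#'
#' Integrates the best-response partition against a Beta belief distribution:
#' the share choosing action \eqn{x} is the Beta probability mass of the
#' belief intervals where \eqn{x} is the best response. Evaluated analytically
#' from the region boundaries and the Beta distribution function (no
#' quadrature), so shares sum to 1 up to boundary tolerance.
#'
#' @param dist A [beta_belief()].
#' @param spec A [game_spec()].
#' @param regions Optionally a precomputed [best_response_regions()] table.
#' @return A named numeric vector `c(C = , D = , L = )` of population shares
#'   (`L` is 0 under mandatory participation).
#' @examples
#' action_shares(beta_belief(1, 1), game_spec(5, "voluntary"))
#' @export
action_shares <- function(dist, spec, regions = NULL) {
  stopifnot(inherits(dist, "beta_belief"), is_game_spec(spec))
  if (is.null(regions)) regions <- best_response_regions(spec)
  mass <- stats::pbeta(regions$upper, dist$alpha, dist$beta) -
    stats::pbeta(regions$lower, dist$alpha, dist$beta)
  out <- c(C = 0, D = 0, L = 0)
  for (a in unique(regions$action)) {
    out[a] <- sum(mass[regions$action == a])
  }
  out
}

#' Within-group cooperation rate from action shares
#'
#' The cooperation rate that determines group outcomes is the share of
#' cooperators among those who opt in: \eqn{r_C / (r_C + r_D)}. When everyone
#' leaves (\eqn{r_C + r_D = 0}) the rate is undefined and `NA` is returned.
#'
#' @param shares Named shares as returned by [action_shares()] (names `C`,
#'   `D`, and optionally `L`).
#' @return Probability, or `NA_real_` when no one opts in.
#' @export
cooperation_rate <- function(shares) {
  denom <- shares[["C"]] + shares[["D"]]
  if (denom <= 0) return(NA_real_)
  shares[["C"]] / denom
}

#' Effective cooperation rate under loner externality
#'
#' When loners still weigh on group outcomes with externality
#' \eqn{\rho \in [0, 1]}, the cooperation rate that effectively determines
#' provision is \eqn{r_C / (r_C + r_D + \rho\, r_L)}. At \eqn{\rho = 0} this
#' is [cooperation_rate()] (flexible groups exclude loners); at
#' \eqn{\rho = 1} it equals \eqn{r_C} when shares sum to 1 (loners count like
#' defectors, as in fixed-boundary groups).
#'
#' @inheritParams cooperation_rate
#' @param rho Loner externality in \[0, 1\].
#' @return Probability, or `NA_real_` when the denominator is 0.
#' @export
effective_cooperation_rate <- function(shares, rho) {
  stopifnot(length(rho) == 1L, rho >= 0, rho <= 1)
  denom <- shares[["C"]] + shares[["D"]] + rho * shares[["L"]]
  if (denom <= 0) return(NA_real_)
  shares[["C"]] / denom
}

#' Group success rate implied by a cooperation rate
#'
#' Probability that a group whose members cooperate i.i.d. with probability
#' `p_coop` gathers at least the threshold number of cooperators:
#' the binomial upper tail
#' \eqn{\sum_{k=q}^{n} \binom{n}{k} p^k (1-p)^{n-k}} with `n = group_size`.
#'
#' @param p_coop Within-group cooperation rate in \[0, 1\] (vectorized; `NA`
#'   propagates).
#' @param spec A [game_spec()].
#' @return Probability of group success.
#' @examples
#' group_success_rate(0.5, game_spec(5, "mandatory")) # 0.5^5
#' @export
group_success_rate <- function(p_coop, spec) {
  stopifnot(is_game_spec(spec))
  if (any(!is.na(p_coop) & (p_coop < 0 | p_coop > 1))) {
    stop("`p_coop` must lie in [0, 1]", call. = FALSE)
  }
  stats::pbinom(spec$threshold - 1L, size = spec$group_size, prob = p_coop,
                lower.tail = FALSE)
}

# Highest possible per-capita payoff: a group with exactly q cooperators
# (q members at group_reward, the rest at endowment + group_reward).
# Under default payoffs this is 40 - 2q points per head.
max_feasible_payoff <- function(spec) {
  n <- spec$group_size
  (spec$threshold * spec$group_reward +
     (n - spec$threshold) * (spec$endowment + spec$group_reward)) / n
}

#' Normalized expected efficiency of a population
#'
#' Mean expected payoff per person, normalized by the per-capita payoff of
#' the most efficient feasible group (exactly the threshold number of
#' cooperators; 40 - 2q points under default payoffs). Group members' expected
#' payoffs are evaluated under the independent-composition approximation: each
#' opt-in's co-members cooperate i.i.d. with probability equal to the
#' within-group cooperation rate, the same approximation used for the group
#' success rate. Loners contribute their sure payoff when
#' `include_loners = TRUE`.
#'
#' @inheritParams cooperation_rate
#' @param spec A [game_spec()].
#' @param include_loners If `TRUE`, average over the entire population with
#'   loners at `endowment + outside_payoff`; if `FALSE`, average within
#'   groups only.
#' @return Normalized efficiency, or `NA_real_` when no one opts in and
#'   loners are excluded.
#' @export
expected_efficiency <- function(shares, spec, include_loners = FALSE) {
  stopifnot(is_game_spec(spec))
  p <- cooperation_rate(shares)
  r_in <- shares[["C"]] + shares[["D"]]
  r_l <- if ("L" %in% names(shares)) shares[["L"]] else 0
  loner_pay <- spec$endowment + spec$outside_payoff
  if (r_in <= 0) {
    if (!include_loners || r_l <= 0) return(NA_real_)
    return(loner_pay / max_feasible_payoff(spec))
  }
  spec_m <- spec
  ep <- expected_payoffs(p, spec_m)
  group_pay <- shares[["C"]] * ep[["C"]] + shares[["D"]] * ep[["D"]]
  mean_pay <- if (include_loners) {
    (group_pay + r_l * loner_pay) / (r_in + r_l)
  } else {
    group_pay / r_in
  }
  mean_pay / max_feasible_payoff(spec)
}

#' Population-level prediction under a belief distribution
#'
#' Convenience wrapper combining [action_shares()], [cooperation_rate()],
#' [group_success_rate()], and [expected_efficiency()] into one row.
#'
#' @param dist A [beta_belief()].
#' @param spec A [game_spec()].
#' @return A one-row tibble with the shares, `p_coop`, `p_success`, and both
#'   efficiencies.
#' @export
predict_population <- function(dist, spec) {
  sh <- action_shares(dist, spec)
  p <- cooperation_rate(sh)
  tibble::tibble(
    regime = spec$regime,
    threshold = spec$threshold,
    alpha = dist$alpha,
    beta = dist$beta,
    r_C = sh[["C"]], r_D = sh[["D"]], r_L = sh[["L"]],
    p_coop = p,
    p_success = group_success_rate(p, spec),
    efficiency_within = expected_efficiency(sh, spec, include_loners = FALSE),
    efficiency_population = expected_efficiency(sh, spec, include_loners = TRUE)
  )
}

#' Sweep Beta belief parameters and compare participation regimes
#'
#' Computes the predicted within-group cooperation rate under mandatory and
#' voluntary participation over a grid of Beta belief distributions, one row
#' per (mean, concentration, threshold) cell. Cells where everyone leaves
#' under the voluntary regime have an undefined cooperation rate; they are
#' flagged (`undefined = TRUE`), not dropped.
#'
#' @param thresholds Integer thresholds to sweep (default `c(2, 4, 5)`).
#' @param mu Grid of Beta means (default 0.05 to 0.95 in steps of 0.05).
#' @param nu Grid of Beta concentrations (default `c(1, 2, 5, 10, 20)`).
#' @param ... Payoff constants passed to [game_spec()] (endowment,
#'   group_reward, outside_payoff, group_size).
#' @return A tibble with columns `threshold`, `mu`, `nu`, `alpha`, `beta`,
#'   `p_coop_mandatory`, `p_coop_voluntary`, `delta_p_coop`, `undefined`.
#' @export
sweep_beta <- function(thresholds = c(2L, 4L, 5L),
                       mu = seq(0.05, 0.95, by = 0.05),
                       nu = c(1, 2, 5, 10, 20),
                       ...) {
  cells <- tidyr::expand_grid(threshold = thresholds, mu = mu, nu = nu)
  regions <- lapply(stats::setNames(thresholds, thresholds), function(q) {
    list(
      mandatory = best_response_regions(game_spec(q, "mandatory", ...)),
      voluntary = best_response_regions(game_spec(q, "voluntary", ...))
    )
  })
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    q <- cells$threshold[i]
    dist <- beta_belief_mc(cells$mu[i], cells$nu[i])
    reg <- regions[[as.character(q)]]
    sh_m <- action_shares(dist, game_spec(q, "mandatory", ...), reg$mandatory)
    sh_v <- action_shares(dist, game_spec(q, "voluntary", ...), reg$voluntary)
    p_m <- cooperation_rate(sh_m)
    p_v <- cooperation_rate(sh_v)
    tibble::tibble(
      threshold = q, mu = cells$mu[i], nu = cells$nu[i],
      alpha = dist$alpha, beta = dist$beta,
      p_coop_mandatory = p_m, p_coop_voluntary = p_v,
      delta_p_coop = p_v - p_m,
      undefined = is.na(p_m) || is.na(p_v)
    )
  })
  dplyr::bind_rows(rows)
}

#' Symmetric belief-consistent equilibria
#'
#' Searches for beliefs \eqn{\gamma^*} that reproduce themselves: when every
#' player holds belief \eqn{\gamma^*} and plays the best response, the
#' implied within-group cooperation probability equals \eqn{\gamma^*}. The
#' consistency map sends \eqn{\gamma} to 1 where the best response is C, to 0
#' where it is D, and is undefined where it is L (no one opts in, so there is
#' no within-group rate). Fixed points are found by scanning a fine grid and
#' refining sign changes by bisection; boundary (indifference) fixed points
#' correspond to mixed play and are annotated by the local behaviour of the
#' map (attracting when the map crosses the diagonal downward).
#'
#' Under mandatory regimes the all-defect point \eqn{\gamma^* = 0} is always
#' a fixed point; under voluntary regimes with default payoffs it is
#' eliminated, because a group of defectors earns less than the outside
#' option, so pessimists leave rather than defect.
#'
#' @param spec A [game_spec()].
#' @param grid_n Grid resolution for the initial scan.
#' @param tol Bisection tolerance for fixed-point location.
#' @return A tibble with columns `gamma_star`, `type` (`"all-defect"`,
#'   `"all-cooperate"`, or `"mixed"`), and `stability` (`"stable"` or
#'   `"unstable"`).
#' @export
find_symmetric_equilibria <- function(spec, grid_n = 10001L, tol = 1e-8) {
  stopifnot(is_game_spec(spec))
  cmap <- function(g) {
    br <- best_response(g, spec)
    ifelse(br == "C", 1, ifelse(br == "D", 0, NA_real_))
  }
  grid <- seq(0, 1, length.out = grid_n)
  tg <- cmap(grid)
  f <- tg - grid
  res <- list()
  add <- function(g) {
    t_at <- cmap(g)
    if (is.na(t_at)) return(invisible(NULL))
    type <- if (abs(g) < 1e-6 && t_at == 0) "all-defect"
            else if (abs(g - 1) < 1e-6 && t_at == 1) "all-cooperate"
            else "mixed"
    eps <- max(tol, 1e-7)
    below <- cmap(max(0, g - eps))
    above <- cmap(min(1, g + eps))
    # attracting when the map sits above the diagonal to the left and below
    # it to the right of the fixed point
    stab <- if (!is.na(below) && !is.na(above) &&
                below >= g - eps && above <= g + eps) "stable" else "unstable"
    res[[length(res) + 1L]] <<- tibble::tibble(
      gamma_star = g, type = type, stability = stab
    )
  }
  # exact endpoints
  if (!is.na(tg[1L]) && tg[1L] == 0) add(0)
  if (!is.na(tg[grid_n]) && tg[grid_n] == 1) add(1)
  # interior: sign changes of f across defined grid cells
  for (i in seq_len(grid_n - 1L)) {
    f1 <- f[i]; f2 <- f[i + 1L]
    if (is.na(f1) || is.na(f2)) next
    if (f1 == 0 && grid[i] > 0 && grid[i] < 1) { add(grid[i]); next }
    if (f1 * f2 < 0) {
      lo <- grid[i]; hi <- grid[i + 1L]
      while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        fm <- cmap(mid) - mid
        if (is.na(fm)) break
        if (sign(fm) == sign(f1)) lo <- mid else hi <- mid
      }
      add((lo + hi) / 2)
    }
  }
  if (length(res) == 0L) {
    return(tibble::tibble(gamma_star = numeric(), type = character(),
                          stability = character()))
  }
  out <- dplyr::bind_rows(res)
  dplyr::distinct(
    dplyr::arrange(out, .data$gamma_star),
    dplyr::across(dplyr::everything())
  )
}
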