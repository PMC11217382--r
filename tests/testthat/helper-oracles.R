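# Independent oracles used across the suite.

# Brute-force expected payoffs: enumerate every cooperate/defect profile of
# the other group members and weight by the belief gamma.
brute_expected_payoffs <- function(gamma, spec) {
  n_others <- spec$group_size - 1L
  profiles <- as.matrix(expand.grid(rep(list(0:1), n_others)))
  w <- apply(profiles, 1L, function(p) {
    prod(ifelse(p == 1, gamma, 1 - gamma))
  })
  k <- rowSums(profiles)
  q <- spec$threshold
  e_C <- sum(w * ifelse(k + 1 >= q, spec$group_reward, 0))
  e_D <- sum(w * (spec$endowment + ifelse(k >= q, spec$group_reward, 0)))
  out <- c(C = e_C, D = e_D)
  if (spec$regime == "voluntary") {
    out <- c(out, L = spec$endowment + spec$outside_payoff)
  }
  out
}

# Monte-Carlo integration of the best-response partition against a Beta
# belief distribution.
mc_action_shares <- function(dist, spec, n_draws) {
  g <- rbeta(n_draws, dist$alpha, dist$beta)
  br <- best_response(g, spec)
  c(C = mean(br == "C"), D = mean(br == "D"), L = mean(br == "L"))
}

# Rank-free AUC by direct pair counting: P(pred_C > pred_D) + 0.5 P(tie).
pairwise_auc <- function(predictor, is_positive) {
  pos <- predictor[is_positive]
  neg <- predictor[!is_positive]
  cmp <- outer(pos, neg, `-`)
  (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / (length(pos) * length(neg))
}

default_main_config <- function(...) {
  cohort_config(design = "main", ...)
}
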