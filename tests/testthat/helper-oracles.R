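# Independent analytic / numerical oracles for the Monte-Carlo machinery.
# These derive everything from Dirichlet moment formulas or dense grid
# integration and never call the package's sampling paths.

# E[U] and Var(U) for U = w*theta2 + (1 - theta1), theta ~ Dirichlet(alpha)
dirichlet_mean_utility <- function(alpha, w = 0.75) {
  a0 <- sum(alpha)
  w * alpha[2] / a0 + 1 - alpha[1] / a0
}

dirichlet_var_utility <- function(alpha, w = 0.75) {
  a0 <- sum(alpha)
  v <- function(ai) ai * (a0 - ai) / (a0^2 * (a0 + 1))
  cov12 <- -alpha[1] * alpha[2] / (a0^2 * (a0 + 1))
  w^2 * v(alpha[2]) + v(alpha[1]) - 2 * w * cov12
}

# Discretized distribution of U under Dirichlet(alpha): midpoint grid over
# the (theta1, theta2) simplex, density weights normalized to 1.
grid_utility_dist <- function(alpha, K = 500, w = 0.75) {
  h <- 1 / K
  mid <- (seq_len(K) - 0.5) * h
  g <- expand.grid(t1 = mid, t2 = mid)
  g <- g[g$t1 + g$t2 < 1, ]
  t3 <- 1 - g$t1 - g$t2
  logw <- (alpha[1] - 1) * log(g$t1) + (alpha[2] - 1) * log(g$t2) +
    (alpha[3] - 1) * log(t3)
  wts <- exp(logw - max(logw))
  list(u = w * g$t2 + (1 - g$t1), w = wts / sum(wts))
}

# P(U_A > U_B) for independent Dirichlet arms, by grid integration:
# sum_i wA_i * P(U_B < uA_i) using the weighted ECDF of arm B.
pmax_two_arm_grid <- function(alphaA, alphaB, K = 500, w = 0.75) {
  A <- grid_utility_dist(alphaA, K, w)
  B <- grid_utility_dist(alphaB, K, w)
  ord <- order(B$u)
  ub <- B$u[ord]
  cw <- cumsum(B$w[ord])
  pos <- findInterval(A$u, ub)
  FB <- c(0, cw)[pos + 1]
  sum(A$w * FB)
}
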