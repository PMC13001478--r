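# Independent oracles. These deliberately avoid the package's fitting and
# scoring code paths: convolution is done through an explicit circulant
# matrix, profiling through a scalar Newton iteration, AUC through exhaustive
# pair enumeration, and Ward merges through direct evaluation of the
# variance-increase criterion.

# Maximum Poisson log-likelihood over a dense (tau1, tau2, alpha1) grid with
# the overall amplitude and flat background profiled at every grid point
# (under the Poisson stationarity constraint that total expected counts
# equal total observed counts).
grid_loglik_max <- function(y, irf,
                            tau1_grid = seq(100, 1000, by = 25),
                            tau2_grid = seq(1200, 4000, by = 50),
                            alpha_grid = seq(0, 1, by = 0.02)) {
  n <- length(y)
  t <- irf$time_ps
  h <- irf$weights
  Cm <- matrix(0, n, n)
  for (k in seq_len(n)) Cm[, k] <- h[((seq_len(n) - k) %% n) + 1L]
  shape <- function(tau) { s <- exp(-(t - t[1]) / tau); s / sum(s) }
  G1 <- Cm %*% sapply(tau1_grid, shape)
  G2 <- Cm %*% sapply(tau2_grid, shape)
  N <- sum(y)
  A1 <- G1[, rep(seq_along(tau1_grid), times = length(tau2_grid))]
  A2 <- G2[, rep(seq_along(tau2_grid), each = length(tau1_grid))]
  const <- -sum(lfactorial(y)) - N + N * log(N)
  best <- -Inf
  for (a in alpha_grid) {
    S <- a * A1 + (1 - a) * A2
    U <- 1 / n - S
    beta <- rep(0.01, ncol(S))
    for (it in 1:10) {
      Mu <- S + U * rep(beta, each = n)
      R <- y / Mu
      UR <- U * R
      g <- -.colSums(UR, n, ncol(S))
      hss <- .colSums(UR * (U / Mu), n, ncol(S))
      beta <- pmin(pmax(beta - g / pmax(hss, 1e-12), 0), 0.9999)
    }
    Mu <- S + U * rep(beta, each = n)
    best <- max(best, max(.colSums(y * log(Mu), n, ncol(S)) + const))
  }
  best
}

# AUC as the Mann-Whitney pairwise-ordering statistic: fraction of
# (positive, negative) pairs ranked correctly, ties counting one half.
auc_pairwise <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# First Ward merge on a tiny point set by direct evaluation of the merge
# cost (the increase in within-cluster sum of squares when singletons i and
# j fuse): n_i n_j / (n_i + n_j) * ||x_i - x_j||^2.
ward_first_merge <- function(x) {
  n <- nrow(x)
  best <- NULL; best_cost <- Inf
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    cost <- 0.5 * sum((x[i, ] - x[j, ])^2)
    if (cost < best_cost) { best_cost <- cost; best <- c(i, j) }
  }
  list(pair = best, height = sqrt(2 * best_cost))  # ward.D2 height scale
}
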