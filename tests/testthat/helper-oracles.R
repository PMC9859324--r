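# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# Mann-Whitney U of group a against group b by direct pair counting.
oracle_u <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

# Exact two-sided Mann-Whitney p-value by enumerating all C(n, n_a) group
# labelings of the pooled data (tie-free inputs).
oracle_mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  n_a <- length(a)
  u_obs <- oracle_u(a, b)
  combos <- combn(n, n_a)
  u_all <- apply(combos, 2, function(idx) {
    oracle_u(pooled[idx], pooled[-idx])
  })
  mu <- length(a) * length(b) / 2
  # two-sided: permutations at least as far from the null mean
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Kruskal-Wallis H by the rank formula with tie correction, written directly.
oracle_kw_h <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  rs <- tapply(r, groups, sum)
  ns <- tapply(r, groups, length)
  h <- 12 / (n * (n + 1)) * sum(rs^2 / ns) - 3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Moran's I computed as an explicit double sum (no matrix algebra).
oracle_moran_i <- function(x, w) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + w[i, j] * z[i] * z[j]
  (n / sum(w)) * num / sum(z^2)
}

# Greedy Ward clustering by exhaustive search over cluster pairs, tracking
# the total within-cluster error sum of squares (ESS). Returns the member
# sets merged at each step and the ESS increase of each merge.
oracle_ward <- function(X) {
  X <- as.matrix(X)
  clusters <- lapply(seq_len(nrow(X)), function(i) i)
  ess <- function(idx) {
    if (length(idx) == 1) return(0)
    sub <- X[idx, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL
    best_cost <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        cost <- ess(c(clusters[[i]], clusters[[j]])) -
          ess(clusters[[i]]) - ess(clusters[[j]])
        if (cost < best_cost - 1e-12) {
          best_cost <- cost
          best <- c(i, j)
        }
      }
    }
    merges[[length(merges) + 1]] <- list(
      members = sort(c(clusters[[best[1]]], clusters[[best[2]]])),
      delta_ess = best_cost)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  merges
}

# Leaf sets below each internal node of an hclust tree, in merge order.
hclust_merge_sets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    members <- unlist(lapply(hc$merge[i, ], function(s) {
      if (s < 0) -s else sets[[s]]
    }))
    sets[[i]] <- sort(members)
  }
  sets
}

# Reduced MCMC settings for tests that need many fits.
quick_spec <- function(model = "IID", seed = 1L, n_chains = 1,
                       n_iter = 1200, n_burnin = 400) {
  model_spec(model, n_chains = n_chains, n_iter = n_iter,
             n_burnin = n_burnin, seed = seed)
}
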