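# Gibbs sampler: conjugate full conditionals, nesting, DIC, adjusted R2.

test_that("coefficient full conditional matches the closed-form posterior", {
  set.seed(21)
  n <- 60
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  beta_true <- c(1.5, -0.8)
  y <- 2 + X %*% beta_true + rnorm(n, 0, 1)
  Z <- cbind(1, X)
  tau_v <- 1
  # near-flat prior: the conditional mean approaches the OLS estimate
  prior_prec <- rep(1e-10, 3)
  q <- tau_v * crossprod(Z) + diag(prior_prec)
  mean_cf <- solve(q, tau_v * crossprod(Z, y))
  ols <- coef(lm(y ~ X))
  expect_equal(as.numeric(mean_cf), as.numeric(ols), tolerance = 1e-6)

  draws <- t(replicate(20000, oxylife:::.draw_coefs(
    crossprod(Z), crossprod(Z, y), tau_v, prior_prec)))
  cov_cf <- solve(q)
  for (j in 1:3) {
    mc_se <- sqrt(cov_cf[j, j] / 20000)
    expect_lt(abs(mean(draws[, j]) - mean_cf[j]), 3 * mc_se)
    expect_equal(var(draws[, j]), cov_cf[j, j], tolerance = 0.05)
  }
})

test_that("intercept-only conditional with a flat prior centers on the mean", {
  set.seed(22)
  y <- rnorm(40, 76, 2)
  draws <- replicate(20000, oxylife:::.draw_coefs(
    matrix(length(y)), matrix(sum(y)), 1, 1e-12))
  mc_se <- sqrt(1 / length(y) / 20000)
  expect_lt(abs(mean(draws) - mean(y)), 4 * mc_se)
})

test_that("precision full conditional matches the closed-form Gamma", {
  set.seed(23)
  shape0 <- 1; rate0 <- 0.05; k <- 30; ss <- 12.5
  draws <- replicate(20000, oxylife:::.draw_precision(shape0, rate0, k, ss))
  shape <- shape0 + k / 2; rate <- rate0 + ss / 2
  expect_lt(abs(mean(draws) - shape / rate),
            3 * sqrt(shape / rate^2 / 20000))
  expect_equal(var(draws), shape / rate^2, tolerance = 0.05)
})

test_that("CAR field conditional matches its closed form and sums to zero", {
  set.seed(24)
  pts <- data.frame(region_id = 1:12, lon = runif(12, 80, 120),
                    lat = runif(12, 20, 45))
  W <- inverse_distance_weights(pts)
  K <- diag(rowSums(W$w_raw)) - W$w_raw
  eig <- eigen(K, symmetric = TRUE)
  lambda <- pmax(eig$values, 0); V <- eig$vectors
  tau_u <- 5; tau_v <- 2
  r <- rnorm(12)
  q <- tau_u * K + tau_v * diag(12)
  m <- solve(q, tau_v * r)
  cen <- diag(12) - matrix(1 / 12, 12, 12)
  m_cen <- as.numeric(cen %*% m)
  cov_cen <- cen %*% solve(q) %*% t(cen)
  draws <- t(replicate(20000, oxylife:::.draw_u(r, tau_u, tau_v, V, lambda)))
  expect_true(all(abs(rowSums(draws)) < 1e-8))
  for (j in c(1, 5, 12)) {
    mc_se <- sqrt(cov_cen[j, j] / 20000)
    expect_lt(abs(mean(draws[, j]) - m_cen[j]), 3.5 * mc_se)
    expect_equal(var(draws[, j]), cov_cen[j, j], tolerance = 0.06)
  }
})

test_that("IID fit recovers strong fixed effects and agrees across chains", {
  set.seed(25)
  n <- 200
  X <- cbind(a = rnorm(n), b = rnorm(n))
  y <- 5 + X %*% c(0.15, 1.4) + rnorm(n, 0, 1)
  spec <- model_spec("IID", n_chains = 2, n_iter = 2500, n_burnin = 500, seed = 9)
  fit <- fit_iid(y, X, spec)
  s <- fit$summaries
  for (p in c("beta_a", "beta_b")) {
    row <- s[s$parameter == p, ]
    truth <- c(beta_a = 0.15, beta_b = 1.4)[[p]]
    expect_lt(abs(row$mean - truth), 3 * row$sd)
    expect_lt(row$rhat, 1.05)
  }
  # equal-tailed interval brackets the posterior mean
  expect_true(all(s$lower_95 <= s$mean & s$mean <= s$upper_95))

  # two seeds agree within combined MC error
  fit2 <- fit_iid(y, X, model_spec("IID", n_chains = 2, n_iter = 2500,
                                   n_burnin = 500, seed = 77))
  for (p in c("alpha", "beta_a", "beta_b")) {
    a <- fit$summaries[fit$summaries$parameter == p, ]
    b <- fit2$summaries[fit2$summaries$parameter == p, ]
    n_eff_guess <- 400 # conservative for autocorrelated chains
    se <- sqrt(a$sd^2 + b$sd^2) / sqrt(n_eff_guess)
    expect_lt(abs(a$mean - b$mean), 5 * se)
  }
})

test_that("CAR nests IID when the spatial precision is pinned high", {
  set.seed(26)
  gen <- generate_regions(synthetic_config(seed = 26, sigma_u = 0))
  r <- gen$regions
  X <- cbind(oxygen = r$oxygen, health = r$health_tech_per_1000)
  y <- r$life_expectancy
  base <- quick_spec(seed = 5, n_iter = 3000, n_burnin = 1000)
  pinned <- base
  pinned$priors$u <- c(1e8, 1) # tau_u concentrated near 1e8: u collapses to 0
  fit_c <- fit_car(y, X, gen$W, pinned)
  fit_i <- fit_iid(y, X, base)
  u_cols <- grep("^u_", colnames(fit_c$draws))
  expect_lt(max(abs(fit_c$draws[, u_cols])), 1e-2)
  for (p in c("beta_oxygen", "beta_health")) {
    a <- fit_c$summaries[fit_c$summaries$parameter == p, ]
    b <- fit_i$summaries[fit_i$summaries$parameter == p, ]
    expect_lt(abs(a$mean - b$mean), 3 * sqrt(a$sd^2 + b$sd^2) / sqrt(50))
  }
  # every retained u draw respects the sum-to-zero constraint
  expect_true(all(abs(rowSums(fit_c$draws[, u_cols])) < 1e-8))
})

test_that("DIC falls for real covariates, rises for pure noise, p_D positive", {
  set.seed(27)
  n <- 120
  wins_signal <- 0; wins_noise <- 0
  reps <- 20
  for (k in seq_len(reps)) {
    x <- rnorm(n)
    y <- 70 + 5 * x + rnorm(n, 0, 0.5) # effect 10 noise SDs
    noise <- rnorm(n)
    sp <- quick_spec(seed = 100 + k)
    f_base <- fit_iid(y, cbind(x = x), sp)
    f_noise <- fit_iid(y, cbind(x = x, z = noise), sp)
    f_none <- fit_iid(y, cbind(z = noise), sp)
    expect_gt(f_base$p_d, 0)
    if (f_noise$dic > f_base$dic) wins_noise <- wins_noise + 1
    if (f_base$dic < f_none$dic) wins_signal <- wins_signal + 1
  }
  expect_equal(wins_signal, reps) # 10-SD effect: always detected
  expect_gt(wins_noise, 0.5 * reps)
})

test_that("adjusted R2 matches hand arithmetic and degenerate cases", {
  mk_fit <- function(y, mu) {
    # constant draws so posterior means give exactly mu = 0 + 1 * mu
    draws <- matrix(rep(c(0, 1, 1), each = 150), 150,
                    dimnames = list(NULL, c("alpha", "beta_x", "tau_v")))
    structure(list(model = "IID", draws = draws, y = y,
                   X = cbind(x = mu), covariates = "x"),
              class = "oxy_fit")
  }
  y <- c(1, 2, 3, 4, 5)
  expect_equal(adjusted_r2(mk_fit(y, c(1.1, 1.9, 3.2, 3.8, 5.0))),
               1 - (0.10 / 10) * (4 / 3), tolerance = 1e-5)
  expect_equal(adjusted_r2(mk_fit(y, y)), 1)
  # constant fitted values: R2 = 0, adjusted negative
  y2 <- c(1, 2, 3, 4, 5, 6)
  expect_lt(adjusted_r2(mk_fit(y2, rep(3.5, 6) + 1e-12 * seq_len(6))), 0)
  expect_error(adjusted_r2(mk_fit(c(1, 2), c(1, 2))),
               class = "oxylife_input_error")
})

test_that("the Moran gate picks CAR below alpha, IID at or above it", {
  mk <- function(p) structure(list(I = 0.3, expected_I = -0.03, p_value = p,
                                   n_permutations = 999, seed = 1,
                                   alternative = "greater"),
                              class = "moran_result")
  expect_equal(select_spatial_model(mk(0.0004)), "CAR")
  expect_equal(select_spatial_model(mk(0.238)), "IID")
  expect_equal(select_spatial_model(mk(0.05)), "IID") # strict inequality
})

test_that("degenerate designs are rejected before sampling", {
  y <- rnorm(30)
  expect_error(fit_iid(y, cbind(a = rep(1, 30))), "zero-variance")
  x <- rnorm(30)
  expect_error(fit_iid(y, cbind(a = x, b = 2 * x)), "collinear")
  expect_error(fit_iid(c(y[-1], NA), cbind(a = x)), "missing")
})
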