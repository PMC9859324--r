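# Bayesian ecological regression of life expectancy: CAR and IID random
# effects, fitted by Gibbs sampling with fully conjugate updates.
#
# Model:  y_i = alpha + X_i beta + u_i + v_i
#   v_i ~ N(0, 1/tau_v)                                   (IID and CAR)
#   u   ~ intrinsic CAR, joint precision tau_u (D - W)    (CAR only)
#   alpha ~ N(0, 1/tau_alpha), beta_j ~ N(0, 1/tau_beta)
#   tau_alpha, tau_beta ~ Gamma(1, 0.1); tau_u, tau_v ~ Gamma(1, 0.05)
# (Gamma(shape, rate) priors on precisions, the INLA "logGamma" convention.)

#' Specify a Bayesian regression model
#'
#' Captures the model family, hyperpriors and MCMC settings. Priors are
#' Gamma(shape, rate) on precisions: `Gamma(1, 0.1)` for the intercept and
#' slope precisions, `Gamma(1, 0.05)` for the structured (`u`) and
#' unstructured (`v`) random-effect precisions — weakly informative on the
#' log-precision scale.
#'
#' @param model `"CAR"` (spatially structured + unstructured random effects)
#'   or `"IID"` (unstructured only).
#' @param priors Named list of `c(shape, rate)` pairs for `alpha`, `beta`,
#'   `u`, `v` precisions.
#' @param n_chains,n_iter,n_burnin,thin MCMC settings; `n_iter` counts
#'   iterations per chain including burn-in.
#' @param seed Integer seed; chain `c` runs with `seed + c - 1`.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(model = c("CAR", "IID"),
                       priors = list(alpha = c(1, 0.1), beta = c(1, 0.1),
                                     u = c(1, 0.05), v = c(1, 0.05)),
                       n_chains = 4, n_iter = 15000, n_burnin = 5000,
                       thin = 1, seed = 1L) {
  model <- match.arg(model)
  stopifnot(n_iter > n_burnin, n_burnin >= 0, thin >= 1)
  for (p in priors) {
    if (any(p <= 0)) abort_input("prior shapes and rates must be positive")
  }
  structure(list(model = model, priors = priors, n_chains = n_chains,
                 n_iter = n_iter, n_burnin = n_burnin, thin = thin,
                 seed = as.integer(seed)),
            class = "model_spec")
}

# --- full conditionals (kept as free functions so their conjugacy can be
# --- verified against closed forms) ------------------------------------

# Gaussian full conditional of the regression block theta = (alpha, beta):
# Q = tau_v Z'Z + diag(prior_prec), b = tau_v Z'y_eff;  theta ~ N(Q^-1 b, Q^-1).
.draw_coefs <- function(ZtZ, Zty_eff, tau_v, prior_prec) {
  q <- tau_v * ZtZ + diag(prior_prec, nrow = length(prior_prec))
  ch <- chol(q)
  mean <- backsolve(ch, forwardsolve(t(ch), tau_v * Zty_eff))
  as.numeric(mean + backsolve(ch, rnorm(length(prior_prec))))
}

# Gamma full conditional of a precision: Gamma(shape0 + k/2, rate0 + ss/2).
.draw_precision <- function(shape0, rate0, k, ss) {
  rgamma(1, shape = shape0 + k / 2, rate = rate0 + ss / 2)
}

# Gaussian full conditional of the CAR field u given residual r = y - Z theta:
# precision tau_u K + tau_v I, mean (tau_u K + tau_v I)^-1 tau_v r, evaluated
# in the eigenbasis K = V diag(lambda) V'. The draw is centered afterwards
# (sum-to-zero identifiability constraint of the intrinsic CAR).
.draw_u <- function(resid, tau_u, tau_v, V, lambda) {
  dvec <- tau_u * lambda + tau_v
  m <- V %*% ((tau_v * crossprod(V, resid)) / dvec)
  u <- as.numeric(m + V %*% (rnorm(length(resid)) / sqrt(dvec)))
  u - mean(u)
}

.check_design <- function(y, X) {
  X <- as.matrix(X)
  if (anyNA(y) || anyNA(X)) abort_input("missing values in y or X")
  if (length(y) != nrow(X)) abort_input("y and X disagree on n")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    abort_input("zero-variance design column: '%s'",
                colnames(X)[which(sds == 0)[1]] %||% which(sds == 0)[1])
  }
  if (ncol(X) > 1 && qr(cbind(1, X))$rank < ncol(X) + 1) {
    abort_input("design matrix is collinear to machine precision")
  }
  X
}

# Shared Gibbs engine. K is the (unscaled) intrinsic-CAR structure matrix
# D - W_raw, or NULL for the IID model.
.gibbs <- function(y, X, spec, K = NULL) {
  y <- as.numeric(y)
  X <- .check_design(y, X)
  n <- length(y)
  p <- ncol(X)
  xn <- colnames(X) %||% paste0("x", seq_len(p))
  # sample in the centered-covariate parameterization: the zero-centered
  # hierarchical intercept prior then shrinks the mean level, not the slopes
  # (with raw covariates the slack would leak into beta on positive-mean
  # covariates such as oxygen); the reported intercept is mapped back to the
  # raw scale per draw, leaving the linear predictor unchanged.
  x_means <- colMeans(X)
  Z <- cbind(1, sweep(X, 2, x_means))
  ZtZ <- crossprod(Z)
  Zt <- t(Z)
  car <- !is.null(K)
  if (car) {
    eig <- eigen(K, symmetric = TRUE)
    lambda <- pmax(eig$values, 0)
    n_null <- sum(eig$values < max(eig$values) * 1e-10)
    if (n_null > 1) {
      abort_input("weight graph is disconnected (intrinsic CAR rank deficiency %d)", n_null)
    }
    V <- eig$vectors
  }
  pr <- spec$priors
  keep <- seq(spec$n_burnin + 1, spec$n_iter, by = spec$thin)
  par_names <- c("alpha", paste0("beta_", xn),
                 if (car) paste0("u_", seq_len(n)),
                 if (car) "tau_u", "tau_v", "tau_alpha", "tau_beta")
  draws <- matrix(NA_real_, length(keep) * spec$n_chains, length(par_names),
                  dimnames = list(NULL, par_names))
  chain_id <- rep(seq_len(spec$n_chains), each = length(keep))
  row <- 1L
  for (ch in seq_len(spec$n_chains)) {
    set.seed(spec$seed + ch - 1L)
    # diffuse but finite starting values
    theta <- c(mean(y), rep(0, p)) + rnorm(p + 1, 0, 0.1)
    u <- rep(0, n)
    tau_v <- 1; tau_u <- 1; tau_alpha <- 0.01; tau_beta <- 0.01
    for (it in seq_len(spec$n_iter)) {
      y_eff <- y - u
      theta <- .draw_coefs(ZtZ, Zt %*% y_eff, tau_v,
                           c(tau_alpha, rep(tau_beta, p)))
      tau_alpha <- .draw_precision(pr$alpha[1], pr$alpha[2], 1, theta[1]^2)
      tau_beta <- .draw_precision(pr$beta[1], pr$beta[2], p,
                                  sum(theta[-1]^2))
      mu_fix <- as.numeric(Z %*% theta)
      if (car) {
        u <- .draw_u(y - mu_fix, tau_u, tau_v, V, lambda)
        tau_u <- .draw_precision(pr$u[1], pr$u[2], n - 1,
                                 sum(u * (K %*% u)))
      }
      resid <- y - mu_fix - u
      tau_v <- .draw_precision(pr$v[1], pr$v[2], n, sum(resid^2))
      if (it > spec$n_burnin && (it - spec$n_burnin - 1) %% spec$thin == 0) {
        alpha_raw <- theta[1] - sum(x_means * theta[-1])
        draws[row, ] <- c(alpha_raw, theta[-1], if (car) u, if (car) tau_u,
                          tau_v, tau_alpha, tau_beta)
        row <- row + 1L
      }
    }
  }
  list(draws = draws, chain = chain_id, y = y, X = X, Z = Z, car = car,
       par_names = par_names, n = n, p = p)
}

# Split-Rhat (Gelman-Rubin on split half-chains) for one draws column.
.split_rhat <- function(x, chain) {
  halves <- lapply(split(x, chain), function(v) {
    h <- length(v) %/% 2
    list(v[seq_len(h)], v[(h + 1):(2 * h)])
  })
  chains <- unlist(halves, recursive = FALSE)
  m <- length(chains)
  n <- length(chains[[1]])
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, var, numeric(1))
  w <- mean(vars)
  b <- n * var(means)
  if (w == 0) return(NA_real_)
  sqrt(((n - 1) / n * w + b / n) / w)
}

.summarize_fit <- function(eng, spec) {
  draws <- eng$draws
  qs <- apply(draws, 2, quantile, probs = c(0.025, 0.975))
  summaries <- data.frame(
    parameter = colnames(draws),
    mean = colMeans(draws),
    sd = apply(draws, 2, sd),
    lower_95 = qs[1, ],
    upper_95 = qs[2, ],
    rhat = apply(draws, 2, .split_rhat, chain = eng$chain),
    row.names = NULL
  )
  fit <- structure(list(model = if (eng$car) "CAR" else "IID",
                        draws = draws, chain = eng$chain,
                        y = eng$y, X = eng$X, covariates = colnames(eng$X),
                        summaries = summaries, spec = spec),
                   class = "oxy_fit")
  d <- dic(fit)
  fit$dic <- d[["dic"]]
  fit$p_d <- d[["p_d"]]
  fit$adjusted_r2_fixed <- adjusted_r2(fit, include_spatial = FALSE)
  fit$adjusted_r2_full <- adjusted_r2(fit, include_spatial = TRUE)
  fit
}

#' Fit the IID-random-effect regression by Gibbs sampling
#'
#' `y_i = alpha + X_i beta + v_i`, with exchangeable Gaussian region effects
#' `v_i ~ N(0, 1/tau_v)` and hierarchical Gaussian priors on the intercept
#' and slopes. All updates are conjugate.
#'
#' @param y Numeric outcome vector (life expectancy, years).
#' @param X Numeric covariate matrix (or data frame), one column per fixed
#'   effect; standardize columns beforehand where per-SD effects are wanted.
#' @param spec A [model_spec()]; its `model` field is ignored here.
#' @return An object of class `oxy_fit` with elements `draws` (retained
#'   posterior draws, one column per scalar), `summaries` (posterior mean,
#'   SD, equal-tailed 95% credible interval, split-Rhat), `dic`, `p_d`,
#'   `adjusted_r2_fixed`, `adjusted_r2_full`.
#' @export
fit_iid <- function(y, X, spec = model_spec("IID")) {
  eng <- .gibbs(y, as.matrix(X), spec, K = NULL)
  .summarize_fit(eng, spec)
}

#' Fit the CAR spatial regression by Gibbs sampling
#'
#' `y_i = alpha + X_i beta + u_i + v_i`, where `u` carries the intrinsic
#' conditional-autoregressive (Gaussian Markov random field) prior with
#' joint precision `tau_u (D - W)` built from the raw symmetric
#' inverse-distance weights (`D = diag(rowSums(W))`), and `v` is exchangeable
#' noise. `u` is block-sampled from its Gaussian full conditional in the
#' eigenbasis of `D - W` and centered to sum to zero at every iteration (the
#' intrinsic prior is improper; the intercept absorbs the level). The `u`
#' precision's Gamma full conditional uses rank `n - 1`.
#'
#' @param y Numeric outcome vector.
#' @param X Numeric covariate matrix.
#' @param W A [inverse_distance_weights()] object (its raw symmetric weights
#'   are used for the CAR precision).
#' @param spec A [model_spec()].
#' @return An `oxy_fit` (see [fit_iid()]); additionally contains the `u_i`
#'   columns in `draws`.
#' @export
fit_car <- function(y, X, W, spec = model_spec("CAR")) {
  if (!inherits(W, "weight_matrix")) abort_input("W must be a weight_matrix")
  if (length(y) != W$n) abort_input("y length != weight matrix size")
  K <- diag(rowSums(W$w_raw)) - W$w_raw
  eng <- .gibbs(y, as.matrix(X), spec, K = K)
  .summarize_fit(eng, spec)
}

#' @export
print.oxy_fit <- function(x, ...) {
  cat(sprintf("%s model: n = %d, %d covariate(s), %d retained draws\n",
              x$model, length(x$y), length(x$covariates), nrow(x$draws)))
  cat(sprintf("DIC = %.2f (p_D = %.2f), adjusted R2 (fixed) = %.3f, (full) = %.3f\n",
              x$dic, x$p_d, x$adjusted_r2_fixed, x$adjusted_r2_full))
  sel <- x$summaries[!grepl("^u_", x$summaries$parameter), ]
  print(sel, digits = 4, row.names = FALSE)
  invisible(x)
}

# Posterior-mean linear predictor, optionally including the spatial field.
.fitted_means <- function(fit, include_spatial = TRUE) {
  m <- colMeans(fit$draws)
  theta <- m[c("alpha", paste0("beta_", fit$covariates))]
  mu <- as.numeric(cbind(1, fit$X) %*% theta)
  if (include_spatial && fit$model == "CAR") {
    mu <- mu + m[paste0("u_", seq_along(fit$y))]
  }
  mu
}

#' Deviance information criterion of a fitted model
#'
#' `D(theta) = -2 sum_i log N(y_i | mu_i(theta), 1/tau_v)`; DIC is the
#' posterior mean deviance plus the effective number of parameters
#' `p_D = mean(D) - D(posterior means)`.
#'
#' @param fit An `oxy_fit` with at least 100 retained draws.
#' @return Named numeric vector `c(dic, p_d)`.
#' @export
dic <- function(fit) {
  draws <- fit$draws
  if (nrow(draws) < 100) abort_input("need >= 100 retained draws for DIC")
  Z <- cbind(1, fit$X)
  theta_cols <- c("alpha", paste0("beta_", fit$covariates))
  mu <- Z %*% t(draws[, theta_cols, drop = FALSE])
  if (fit$model == "CAR") {
    mu <- mu + t(draws[, paste0("u_", seq_along(fit$y)), drop = FALSE])
  }
  tau_v <- draws[, "tau_v"]
  n <- length(fit$y)
  # deviance per draw, vectorized over iterations
  sse <- colSums((fit$y - mu)^2)
  dev <- n * log(2 * pi) - n * log(tau_v) + tau_v * sse
  mu_hat <- .fitted_means(fit, include_spatial = TRUE)
  tau_hat <- mean(tau_v)
  dev_hat <- n * log(2 * pi) - n * log(tau_hat) +
    tau_hat * sum((fit$y - mu_hat)^2)
  dbar <- mean(dev)
  p_d <- dbar - dev_hat
  c(dic = dbar + p_d, p_d = p_d)
}

#' Adjusted R-squared of a fitted model
#'
#' R-squared of the posterior-mean fitted values against the observed
#' outcome, adjusted for the number of fixed-effect covariates:
#' `1 - (1 - R2) (n - 1) / (n - p - 1)`. The spatial field can be included
#' in the fitted values (`include_spatial = TRUE`, "full") or not ("fixed");
#' both variants are stored on every fit.
#'
#' @param fit An `oxy_fit`.
#' @param include_spatial Include the posterior-mean `u` in fitted values?
#' @return Adjusted R-squared (can be negative for a fit worse than the
#'   mean-only model).
#' @export
adjusted_r2 <- function(fit, include_spatial = TRUE) {
  n <- length(fit$y)
  p <- length(fit$covariates)
  if (n <= p + 1) abort_input("adjusted R2 requires n > p + 1")
  mu <- .fitted_means(fit, include_spatial)
  r2 <- 1 - sum((fit$y - mu)^2) / sum((fit$y - mean(fit$y))^2)
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Choose the spatial model from a Moran's I gate
#'
#' The CAR model is selected when the Moran permutation test rejects at
#' level `alpha` (strict inequality: `p == alpha` keeps the IID model).
#'
#' @param moran A [morans_i()] result.
#' @param alpha Significance level, default 0.05.
#' @return `"CAR"` or `"IID"`.
#' @export
select_spatial_model <- function(moran, alpha = 0.05) {
  if (!inherits(moran, "moran_result")) abort_input("expected a moran_result")
  if (moran$p_value < alpha) "CAR" else "IID"
}

#' Serialize fit summaries and draws
#'
#' Writes the posterior summaries (plus DIC and adjusted R-squared) to JSON
#' and, optionally, the retained draws to CSV (one column per scalar
#' parameter).
#'
#' @param fit An `oxy_fit`.
#' @param json_path Output JSON path.
#' @param draws_csv Optional CSV path for the draws.
#' @return `json_path`, invisibly.
#' @export
write_fit <- function(fit, json_path, draws_csv = NULL) {
  payload <- list(model = fit$model, dic = fit$dic, p_d = fit$p_d,
                  adjusted_r2_fixed = fit$adjusted_r2_fixed,
                  adjusted_r2_full = fit$adjusted_r2_full,
                  summaries = fit$summaries)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  if (!is.null(draws_csv)) write.csv(as.data.frame(fit$draws), draws_csv,
                                     row.names = FALSE)
  invisible(json_path)
}
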