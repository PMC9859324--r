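# Synthetic region, YLL and station generators with known ground truth.
# Every generator is a pure function of (config, seed): the same config
# yields bit-identical output.

.covariate_names <- c("gdp_per_capita", "health_tech_per_1000", "edu_years",
                      "sunshine_h", "temperature_C", "rel_humidity_pct",
                      "wind_speed_mps")

# Default covariate correlation structure: GDP per capita and average years
# of education are strongly collinear (the planted |r| > 0.7 pair), health
# resources track the economy, and the meteorological variables are mildly
# interdependent.
.default_correlation <- function() {
  r <- diag(7)
  dimnames(r) <- list(.covariate_names, .covariate_names)
  set_r <- function(a, b, v) {
    r[a, b] <<- v; r[b, a] <<- v
  }
  set_r("gdp_per_capita", "edu_years", 0.80)
  set_r("gdp_per_capita", "health_tech_per_1000", 0.50)
  set_r("edu_years", "health_tech_per_1000", 0.45)
  set_r("temperature_C", "rel_humidity_pct", 0.40)
  set_r("sunshine_h", "rel_humidity_pct", -0.40)
  r
}

#' Configuration for the synthetic-data generators
#'
#' Defaults emulate a province-scale ecological dataset: 34 regions, true
#' fixed effects on the reported-coefficient scale (oxygen +0.15 years of
#' life expectancy per mmHg, GDP +0.877 per SD, health technicians +0.752
#' per unit), a spatially structured effect of typical marginal SD
#' `sigma_u = 1` and exchangeable noise `sigma_v = 0.5`, one covariate pair
#' with correlation 0.8, oxygen spanning the 140 mmHg hypoxia cut-off with
#' exactly `n_low_oxygen = 6` regions below it, and a 20-cause YLL matrix
#' with three planted clusters of sizes 12/16/6.
#'
#' @param n_regions Number of spatial units (default 34).
#' @param seed Integer seed; all generators derive their streams from it.
#' @param alpha_true True intercept (default 50).
#' @param beta_true Named vector of true effects; names from `"oxygen"` and
#'   the covariate names; unnamed covariates have effect 0. GDP enters the
#'   outcome standardized, so its effect is per SD.
#' @param sigma_u,sigma_v Structured / unstructured noise SDs.
#' @param covariate_correlation Target correlation matrix of the 7 non-oxygen
#'   covariates (symmetric positive-definite; must be kept that way if
#'   overridden).
#' @param oxygen_range mmHg interval the generated oxygen spans.
#' @param n_low_oxygen How many regions fall strictly below 140 mmHg.
#' @param n_causes,cluster_sizes,between_cluster_shift,sigma_log YLL matrix
#'   shape: number of causes, planted cluster sizes (must sum to
#'   `n_regions`), between-cluster shift in within-cluster SD units (on the
#'   log scale), and the within-cluster lognormal SD.
#' @param car_cutoff_km Dependence range of the generating CAR graph: the
#'   spatial effect `u` is drawn from the intrinsic CAR on the
#'   inverse-distance graph truncated at this distance, so dependence is
#'   local (as in real regional mortality fields) rather than diluted over
#'   all pairs. `NULL` (default) picks 1.2 times the largest
#'   minimum-spanning-tree edge, the smallest scale that keeps the graph
#'   connected at any `n_regions`; `Inf` uses the dense graph.
#' @param stations_per_region Range of stations per region.
#' @param uninhabited_fraction Probability a station is flagged uninhabited.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_regions = 34, seed = 1L,
                             alpha_true = 50,
                             beta_true = c(oxygen = 0.15,
                                           gdp_per_capita = 0.877,
                                           health_tech_per_1000 = 0.752),
                             sigma_u = 1, sigma_v = 0.5,
                             covariate_correlation = .default_correlation(),
                             oxygen_range = c(105, 160),
                             n_low_oxygen = 6,
                             n_causes = 20,
                             cluster_sizes = c(12, 16, 6),
                             between_cluster_shift = 5,
                             sigma_log = 0.25,
                             car_cutoff_km = NULL,
                             stations_per_region = c(1, 5),
                             uninhabited_fraction = 0.05) {
  r <- covariate_correlation
  if (!isSymmetric(unname(r))) abort_input("correlation matrix must be symmetric")
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    abort_input("correlation matrix is not positive definite (eigenvalue %g)",
                min(ev))
  }
  if (sum(cluster_sizes) != n_regions) {
    abort_input("cluster_sizes must sum to n_regions (%d != %d)",
                sum(cluster_sizes), n_regions)
  }
  if (n_low_oxygen < 1 || n_low_oxygen >= n_regions) {
    abort_input("n_low_oxygen must be in [1, n_regions - 1]")
  }
  structure(list(n_regions = n_regions, seed = as.integer(seed),
                 alpha_true = alpha_true, beta_true = beta_true,
                 sigma_u = sigma_u, sigma_v = sigma_v,
                 covariate_correlation = r, oxygen_range = oxygen_range,
                 n_low_oxygen = n_low_oxygen, n_causes = n_causes,
                 cluster_sizes = cluster_sizes,
                 between_cluster_shift = between_cluster_shift,
                 sigma_log = sigma_log, car_cutoff_km = car_cutoff_km,
                 stations_per_region = stations_per_region,
                 uninhabited_fraction = uninhabited_fraction),
            class = "synthetic_config")
}

# Largest edge of the minimum spanning tree of a distance matrix (Prim's
# algorithm); the smallest cutoff keeping the graph connected.
.max_mst_edge <- function(d) {
  n <- nrow(d)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best <- d[1, ]
  max_edge <- 0
  for (step in seq_len(n - 1)) {
    cand <- which(!in_tree)
    nxt <- cand[which.min(best[cand])]
    max_edge <- max(max_edge, best[nxt])
    in_tree[nxt] <- TRUE
    best <- pmin(best, d[nxt, ])
  }
  max_edge
}

# Draw the intrinsic CAR field with typical marginal SD sigma_u on the graph
# of K = D - W_raw. The structure matrix is rescaled so the geometric mean
# of the marginal variances of the unit-precision field is 1 (the usual
# scaling that makes the precision parameter interpretable); the zero
# eigenvector (constant) is excluded, so the draw sums to zero.
.draw_icar <- function(K, sigma_u) {
  n <- nrow(K)
  if (sigma_u == 0) return(rep(0, n))
  eig <- eigen(K, symmetric = TRUE)
  pos <- eig$values > max(eig$values) * 1e-10
  v <- eig$vectors[, pos, drop = FALSE]
  lam <- eig$values[pos]
  marg_var <- rowSums(sweep(v^2, 2, lam, "/"))
  gv <- exp(mean(log(marg_var)))
  u <- as.numeric(v %*% (rnorm(sum(pos)) / sqrt(lam))) * sigma_u / sqrt(gv)
  u - mean(u)
}

#' Generate a synthetic region table with known ground truth
#'
#' Centroids sit on a jittered grid over a China-scale lon/lat box with a
#' southwest-high "altitude" gradient; oxygen decreases along it, affinely
#' calibrated so exactly `n_low_oxygen` regions fall strictly below
#' 140 mmHg. The other covariates come from a Gaussian copula matching the
#' target correlations, mapped to plausible marginal ranges. The outcome is
#' `Y = alpha + X beta + u + v` with `u` from the intrinsic CAR prior on the
#' generated inverse-distance weights and `v` iid normal.
#'
#' @param config A [synthetic_config()].
#' @return List with `regions` (validated region data frame), `W` (the
#'   `weight_matrix` used for `u`), and `truth` (`alpha`, `beta`, `u`, `v`,
#'   `gdp_scaled` — the standardized GDP column the outcome used — plus the
#'   seed and the low-oxygen region ids).
#' @export
generate_regions <- function(config = synthetic_config()) {
  n <- config$n_regions
  set.seed(config$seed)
  # jittered grid of centroids over a China-scale box
  ncol_grid <- ceiling(sqrt(n))
  nrow_grid <- ceiling(n / ncol_grid)
  gx <- ((seq_len(n) - 1) %% ncol_grid + 0.5) / ncol_grid
  gy <- ((seq_len(n) - 1) %/% ncol_grid + 0.5) / nrow_grid
  lon <- 78 + 50 * (gx + runif(n, -0.3, 0.3) / ncol_grid)
  lat <- 20 + 28 * (gy + runif(n, -0.3, 0.3) / nrow_grid)
  # altitude-like score: high in the (south)west
  score <- 0.7 * (128 - lon) / 50 + 0.3 * (48 - lat) / 28 + rnorm(n, 0, 0.1)
  # oxygen decreasing in the score, calibrated so exactly n_low fall below 140
  n_low <- config$n_low_oxygen
  lo <- config$oxygen_range[1]; hi <- config$oxygen_range[2]
  ord <- order(score, decreasing = TRUE) # highest altitude first
  oxygen <- numeric(n)
  oxygen[ord[seq_len(n_low)]] <-
    seq(lo, 138.5, length.out = n_low) + runif(n_low, -0.5, 0.5)
  oxygen[ord[(n_low + 1):n]] <-
    sort(seq(141.5, hi, length.out = n - n_low) + runif(n - n_low, -0.5, 0.5))
  # covariates via Gaussian copula
  r <- config$covariate_correlation
  z <- matrix(rnorm(n * ncol(r)), n) %*% chol(r)
  p <- pnorm(z)
  cov_tab <- data.frame(
    gdp_per_capita = stats::qlnorm(p[, 1], log(5), 0.45),
    health_tech_per_1000 = stats::qunif(p[, 2], 4, 9),
    edu_years = stats::qunif(p[, 3], 7, 12),
    sunshine_h = stats::qunif(p[, 4], 4.5, 8.5),
    temperature_C = stats::qunif(p[, 5], 8, 23),
    rel_humidity_pct = stats::qunif(p[, 6], 50, 80),
    wind_speed_mps = stats::qunif(p[, 7], 2, 5)
  )
  ids <- sprintf("R%02d", seq_len(n))
  centroids <- data.frame(region_id = ids, lon = lon, lat = lat)
  W <- inverse_distance_weights(centroids)
  # the spatial effect lives on a locally-truncated graph (see synthetic_config)
  cutoff <- config$car_cutoff_km %||% (1.2 * .max_mst_edge(1 / (W$w_raw + diag(n))))
  Wg <- if (is.finite(cutoff)) {
    inverse_distance_weights(centroids, cutoff_km = cutoff)
  } else {
    W
  }
  K <- diag(rowSums(Wg$w_raw)) - Wg$w_raw
  u <- .draw_icar(K, config$sigma_u)
  v <- rnorm(n, 0, config$sigma_v)
  # linear predictor: GDP enters standardized (per-SD effect)
  gdp_scaled <- as.numeric(scale(cov_tab$gdp_per_capita))
  design <- cbind(oxygen = oxygen,
                  gdp_per_capita = gdp_scaled,
                  health_tech_per_1000 = cov_tab$health_tech_per_1000,
                  edu_years = cov_tab$edu_years,
                  sunshine_h = cov_tab$sunshine_h,
                  temperature_C = cov_tab$temperature_C,
                  rel_humidity_pct = cov_tab$rel_humidity_pct,
                  wind_speed_mps = cov_tab$wind_speed_mps)
  beta <- setNames(rep(0, ncol(design)), colnames(design))
  beta[names(config$beta_true)] <- config$beta_true
  y <- config$alpha_true + as.numeric(design %*% beta) + u + v
  regions <- cbind(
    data.frame(region_id = ids, name = paste("Region", seq_len(n)),
               level = "provincial", lon = lon, lat = lat,
               life_expectancy = y, oxygen = oxygen,
               stringsAsFactors = FALSE),
    cov_tab)
  validate_region_table(regions)
  list(regions = regions, W = W,
       truth = list(alpha = config$alpha_true, beta = beta, u = u, v = v,
                    gdp_scaled = gdp_scaled, seed = config$seed,
                    car_cutoff_km = cutoff,
                    low_oxygen_ids = ids[oxygen < 140]))
}

.elevated_causes <- c("lower_respiratory_infection", "neonatal_disorders",
                      "hypertensive_heart_disease", "copd", "cirrhosis_cld",
                      "chronic_kidney_disease")
.depressed_cause <- "lung_cancer"

.cause_names <- function(n_causes) {
  others <- c("stroke", "ischemic_heart_disease", "stomach_cancer",
              "leukemia", "road_injury", "falls", "congenital_defects",
              "liver_cancer", "esophageal_cancer", "diabetes", "self_harm",
              "alzheimer", "drowning", "colorectal_cancer", "tuberculosis",
              "breast_cancer", "asthma", "pancreatic_cancer")
  base <- c(.elevated_causes, .depressed_cause)
  if (n_causes < length(base)) return(base[seq_len(n_causes)])
  c(base, others)[seq_len(n_causes)]
}

#' Generate a synthetic YLL matrix with planted clusters
#'
#' Per-cause lognormal baselines with cluster-specific multiplicative
#' shifts. The planted low-oxygen cluster (the last entry of
#' `cluster_sizes`, assigned to the lowest-oxygen regions when `regions` is
#' supplied) gets elevated means for a designated hypoxia-linked cause
#' subset (lower respiratory infection, neonatal disorders, hypertensive
#' heart disease, COPD, cirrhosis/chronic liver disease, chronic kidney
#' disease) and a depressed mean for lung cancer. The shift magnitude is
#' `between_cluster_shift` within-cluster SDs on the log scale; 0 yields an
#' unclusterable null matrix.
#'
#' @param config A [synthetic_config()].
#' @param regions Optional region table from [generate_regions()]; when
#'   given, planted cluster membership follows the oxygen ordering
#'   (lowest-oxygen regions form the last cluster), otherwise labels are
#'   assigned in row order.
#' @return List with `yll` (regions x causes matrix), `labels` (planted
#'   cluster ids), `elevated_causes`, `depressed_cause`, `seed`.
#' @export
generate_yll <- function(config = synthetic_config(), regions = NULL) {
  n <- config$n_regions
  sizes <- config$cluster_sizes
  g <- length(sizes)
  set.seed(config$seed + 1000L)
  labels <- integer(n)
  if (!is.null(regions)) {
    stopifnot(nrow(regions) == n)
    ord <- order(regions$oxygen, decreasing = TRUE)
    ids <- regions$region_id
  } else {
    ord <- seq_len(n)
    ids <- sprintf("R%02d", seq_len(n))
  }
  labels[ord] <- rep(seq_len(g), times = sizes)
  causes <- .cause_names(config$n_causes)
  baselines <- rlnorm(length(causes), log(500), 0.6)
  names(baselines) <- causes
  # per-cause cluster offset pattern (multiples of the within-cluster SD on
  # the log scale); hypoxia-linked causes are forced monotone in cluster id
  offsets <- matrix(0, g, length(causes), dimnames = list(NULL, causes))
  for (c_ in causes) {
    if (c_ %in% .elevated_causes) {
      offsets[, c_] <- seq(0, 1, length.out = g) # last (low-oxygen) cluster highest
    } else if (c_ == .depressed_cause) {
      offsets[, c_] <- seq(1, 0, length.out = g) # last cluster lowest
    } else {
      offsets[, c_] <- sample(seq(0, 1, length.out = g))
    }
  }
  shift <- config$between_cluster_shift * config$sigma_log
  yll <- matrix(0, n, length(causes), dimnames = list(ids, causes))
  for (j in seq_along(causes)) {
    mu <- log(baselines[j]) + shift * offsets[labels, j]
    yll[, j] <- rlnorm(n, mu, config$sigma_log)
  }
  list(yll = yll, labels = setNames(labels, ids),
       elevated_causes = intersect(.elevated_causes, causes),
       depressed_cause = if (.depressed_cause %in% causes) .depressed_cause else NULL,
       seed = config$seed + 1000L)
}

#' Generate synthetic daily station records
#'
#' Per region, 1-5 stations each contribute 365 daily records whose values
#' are the region's covariate values plus zero-mean daily noise; pressure is
#' back-derived from the region's oxygen. A configurable fraction of
#' stations is flagged uninhabited.
#'
#' @param config A [synthetic_config()].
#' @param regions Region table from [generate_regions()].
#' @return Data frame of `StationRecord` rows: `station_id`, `date`,
#'   `region_id`, `inhabited`, `pressure`, `sunshine`, `wind`,
#'   `rel_humidity`, `temperature`.
#' @export
generate_stations <- function(config = synthetic_config(), regions) {
  set.seed(config$seed + 2000L)
  dates <- format(as.Date("2015-01-01") + 0:364)
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    rg <- regions[i, ]
    n_st <- sample(seq(config$stations_per_region[1],
                       config$stations_per_region[2]), 1)
    st <- lapply(seq_len(n_st), function(s) {
      inhabited <- runif(1) >= config$uninhabited_fraction
      data.frame(
        station_id = sprintf("%s_S%d", rg$region_id, s),
        date = dates,
        region_id = rg$region_id,
        inhabited = inhabited,
        pressure = rg$oxygen / (0.2093 * 7.5) + rnorm(365, 0, 0.8),
        sunshine = pmax(0, rg$sunshine_h + rnorm(365, 0, 1.5)),
        wind = pmax(0, rg$wind_speed_mps + rnorm(365, 0, 0.8)),
        rel_humidity = pmin(100, pmax(0, rg$rel_humidity_pct + rnorm(365, 0, 6))),
        temperature = rg$temperature_C + rnorm(365, 0, 5),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, st)
  })
  do.call(rbind, rows)
}

#' Write a full synthetic dataset to disk
#'
#' Writes the region CSV, station CSV, YLL CSV, a GeoJSON of centroid
#' points, and a ground-truth JSON into `dir`.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if missing).
#' @return Named list of written paths, invisibly.
#' @export
write_synthetic_dataset <- function(config = synthetic_config(), dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gen <- generate_regions(config)
  yll <- generate_yll(config, gen$regions)
  st <- generate_stations(config, gen$regions)
  paths <- list(
    regions = file.path(dir, "regions.csv"),
    stations = file.path(dir, "stations.csv"),
    yll = file.path(dir, "yll.csv"),
    geojson = file.path(dir, "centroids.geojson"),
    truth = file.path(dir, "truth.json")
  )
  write.csv(gen$regions, paths$regions, row.names = FALSE)
  write.csv(st, paths$stations, row.names = FALSE)
  yll_df <- cbind(data.frame(region_id = rownames(yll$yll)),
                  as.data.frame(yll$yll))
  write.csv(yll_df, paths$yll, row.names = FALSE)
  features <- lapply(seq_len(nrow(gen$regions)), function(i) {
    list(type = "Feature",
         properties = list(region_id = gen$regions$region_id[i]),
         geometry = list(type = "Point",
                         coordinates = c(gen$regions$lon[i], gen$regions$lat[i])))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       paths$geojson, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(alpha = gen$truth$alpha, beta = as.list(gen$truth$beta),
         u = gen$truth$u, v = gen$truth$v, seed = config$seed,
         low_oxygen_ids = gen$truth$low_oxygen_ids,
         yll_labels = as.list(yll$labels)),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
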