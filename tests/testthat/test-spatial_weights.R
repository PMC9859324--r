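# Inverse-distance weights and Global Moran's I.

test_that("great-circle distances hit closed-form values", {
  expect_equal(great_circle_km(c(10, 20), c(10, 20)), 0)
  expect_equal(great_circle_km(c(0, 0), c(180, 0)), pi * 6371.0088,
               tolerance = 0.1 / 20015)
  expect_equal(great_circle_km(c(0, 0), c(0, 90)), pi * 6371.0088 / 2,
               tolerance = 0.1 / 10007)
})

test_that("inverse-distance weights have the documented structure", {
  two <- data.frame(region_id = c("a", "b"), lon = c(100, 110), lat = c(30, 30))
  W2 <- inverse_distance_weights(two)
  expect_equal(W2$w, matrix(c(0, 1, 1, 0), 2))

  # three collinear points at 0, 1, 3 degrees of longitude on the equator:
  # distances are proportional to degree gaps, so raw row 1 = (0, 1, 1/3)/d
  three <- data.frame(region_id = c("p", "q", "r"),
                      lon = c(0, 1, 3), lat = c(0, 0, 0))
  W3 <- inverse_distance_weights(three, row_standardize = FALSE)
  d1 <- great_circle_km(c(0, 0), c(1, 0))
  expect_equal(W3$w[1, ], c(0, 1 / d1, 1 / (3 * d1)))
  W3s <- inverse_distance_weights(three)
  expect_equal(W3s$w[1, ], c(0, 0.75, 0.25))
  expect_equal(rowSums(W3s$w), rep(1, 3))

  # raw symmetry and zero diagonal for an arbitrary centroid set
  set.seed(4)
  pts <- data.frame(region_id = letters[1:8], lon = runif(8, 80, 120),
                    lat = runif(8, 20, 45))
  Wr <- inverse_distance_weights(pts, row_standardize = FALSE)
  expect_equal(Wr$w_raw, t(Wr$w_raw))
  expect_equal(diag(Wr$w_raw), rep(0, 8))
  expect_equal(Wr$neighbor_counts, rep(7L, 8))
  expect_true(all(Wr$w_raw >= 0))

  dup <- rbind(pts, pts[1, ]); dup$region_id[9] <- "z"
  expect_error(inverse_distance_weights(dup), "coincident")
})

test_that("Moran's I closed forms: n = 2 and the 4-cycle alternating pattern", {
  two <- data.frame(region_id = c("a", "b"), lon = c(100, 110), lat = c(30, 30))
  W2 <- inverse_distance_weights(two)
  m <- morans_i(c(1, 5), W2, n_permutations = 99, seed = 1)
  expect_equal(m$I, -1)
  expect_equal(m$expected_I, -1)

  # ring of 4 with equal weights on adjacent units, z = (1,-1,1,-1)
  w_ring <- matrix(0, 4, 4)
  for (i in 1:4) {
    w_ring[i, (i %% 4) + 1] <- 0.5
    w_ring[i, ((i - 2) %% 4) + 1] <- 0.5
  }
  m4 <- morans_i(c(1, -1, 1, -1), w_ring, n_permutations = 99, seed = 1)
  expect_equal(m4$I, -1)
})

test_that("Moran's I and its exhaustive p-value match a brute-force oracle", {
  set.seed(11)
  for (n in c(5, 6)) {
    pts <- data.frame(region_id = seq_len(n), lon = runif(n, 80, 120),
                      lat = runif(n, 20, 45))
    W <- inverse_distance_weights(pts)
    x <- rnorm(n)
    m <- morans_i(x, W, exhaustive = TRUE)
    expect_equal(m$I, oracle_moran_i(x, W$w), tolerance = 1e-12)

    # oracle p: enumerate all permutations with the double-sum statistic
    perms <- oxylife:::.permutations(n)
    i_all <- apply(perms, 1, function(p) oracle_moran_i(x[p], W$w))
    expect_equal(m$p_value, mean(i_all >= m$I - 1e-12))
    expect_equal(m$n_permutations, factorial(n))

    # permutation-mean identity E[I] = -1/(n-1)
    expect_equal(mean(i_all), -1 / (n - 1), tolerance = 1e-10)
  }
})

test_that("Moran's I is invariant to affine transforms of the values", {
  set.seed(12)
  pts <- data.frame(region_id = 1:10, lon = runif(10, 80, 120),
                    lat = runif(10, 20, 45))
  W <- inverse_distance_weights(pts)
  x <- rnorm(10)
  base <- morans_i(x, W, n_permutations = 199, seed = 5)
  for (a in c(3, -2)) {
    tr <- morans_i(a * x + 7, W, n_permutations = 199, seed = 5)
    expect_equal(tr$I, base$I, tolerance = 1e-12)
  }
  expect_error(morans_i(rep(1, 10), W), class = "oxylife_input_error")
})

test_that("re-projected permutations restore the size of the residual test", {
  set.seed(14)
  pts <- data.frame(region_id = 1:12, lon = runif(12, 80, 120),
                    lat = runif(12, 20, 45))
  W <- inverse_distance_weights(pts)
  x <- rnorm(12)
  # an identity projection reproduces the plain value permutation exactly
  plain <- morans_i(x, W, n_permutations = 199, seed = 7)
  ident <- morans_i(x, W, n_permutations = 199, seed = 7,
                    projection = diag(12))
  expect_equal(ident$I, plain$I, tolerance = 1e-12)
  expect_equal(ident$p_value, plain$p_value)
  # residual-maker projection: I of the observed vector is I of its residuals
  X <- cbind(1, pts$lon)
  M <- diag(12) - X %*% solve(crossprod(X), t(X))
  proj <- morans_i(x, W, n_permutations = 199, seed = 7, projection = M)
  expect_equal(proj$I, morans_i(as.numeric(M %*% x), W,
                                n_permutations = 9)$I, tolerance = 1e-12)
  expect_error(morans_i(x, W, projection = diag(5)),
               class = "oxylife_input_error")
})

test_that("weights round-trip through dense and triplet CSV", {
  set.seed(13)
  pts <- data.frame(region_id = paste0("r", 1:6), lon = runif(6, 80, 120),
                    lat = runif(6, 20, 45))
  W <- inverse_distance_weights(pts)
  for (fmt in c("dense", "triplet")) {
    tf <- tempfile(fileext = ".csv")
    write_weights(W, tf, format = fmt)
    back <- read_weights(tf)
    expect_equal(unname(back$w_raw[order(back$ids), order(back$ids)]),
                 unname(W$w_raw[order(W$ids), order(W$ids)]),
                 tolerance = 1e-12)
  }
  tf <- tempfile(fileext = ".json")
  m <- morans_i(rnorm(6), W, n_permutations = 99, seed = 2)
  write_moran_json(m, tf)
  back <- jsonlite::read_json(tf)
  expect_equal(back$I, m$I)
  expect_equal(back$seed, 2L)
})
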