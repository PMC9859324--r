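# Inverse-distance spatial weights and Global Moran's I.

.earth_radius_km <- 6371.0088

#' Great-circle distance between points
#'
#' Haversine distance on a sphere of radius 6371.0088 km (the IUGG mean
#' Earth radius).
#'
#' @param a,b Two-column matrices (or length-2 vectors) of lon/lat in
#'   decimal degrees.
#' @return Distance(s) in km.
#' @export
great_circle_km <- function(a, b) {
  geosphere::distHaversine(a, b, r = .earth_radius_km)
}

#' Build an inverse-distance spatial weight matrix
#'
#' Raw weights are `w_ij = 1 / d_ij` (km) off the diagonal and zero on it;
#' the raw matrix is symmetric by construction. With `row_standardize = TRUE`
#' (the default, and what Moran's I and the CAR conditional mean expect) each
#' row with at least one neighbor is divided by its sum. With inverse-distance
#' weights every pair is a neighbor unless a finite `cutoff_km` zeroes
#' long-range pairs.
#'
#' @param centroids Data frame with columns `region_id`, `lon`, `lat`, or a
#'   two-column lon/lat matrix.
#' @param row_standardize Standardize rows to sum to one? Default `TRUE`.
#' @param cutoff_km Distances beyond this get weight zero. Default `Inf`
#'   (off).
#' @return An object of class `weight_matrix`: a list with `n`, `w` (the
#'   matrix actually requested), `w_raw` (always the symmetric raw weights),
#'   `row_standardized`, `neighbor_counts` and `ids`.
#' @export
inverse_distance_weights <- function(centroids, row_standardize = TRUE,
                                     cutoff_km = Inf) {
  if (is.data.frame(centroids)) {
    ids <- as.character(centroids$region_id %||% seq_len(nrow(centroids)))
    xy <- as.matrix(centroids[, c("lon", "lat")])
  } else {
    xy <- as.matrix(centroids)
    ids <- rownames(xy) %||% as.character(seq_len(nrow(xy)))
  }
  n <- nrow(xy)
  if (n < 2) abort_input("need at least 2 centroids")
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    dij <- great_circle_km(xy[i, , drop = FALSE], xy[j, , drop = FALSE])
    d[i, j] <- dij
    d[j, i] <- dij
  }
  off <- which(d == 0 & row(d) != col(d), arr.ind = TRUE)
  if (nrow(off) > 0) {
    abort_input("coincident centroids: '%s' and '%s'",
                ids[off[1, 1]], ids[off[1, 2]])
  }
  w_raw <- ifelse(row(d) == col(d), 0, 1 / d)
  if (is.finite(cutoff_km)) w_raw[d > cutoff_km] <- 0
  nbr <- rowSums(w_raw > 0)
  w <- w_raw
  if (row_standardize) {
    rs <- rowSums(w_raw)
    pos <- rs > 0
    w[pos, ] <- w_raw[pos, , drop = FALSE] / rs[pos]
  }
  structure(list(n = n, w = w, w_raw = w_raw,
                 row_standardized = row_standardize,
                 neighbor_counts = nbr, ids = ids),
            class = "weight_matrix")
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf("Inverse-distance weight matrix: %d regions, %s\n", x$n,
              if (x$row_standardized) "row-standardized" else "raw"))
  invisible(x)
}

# All permutations of 1..n (n small); used for the exhaustive Moran null.
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

# Moran's I statistic for centered values z under weight matrix w.
.moran_stat <- function(z, w, s0) {
  (length(z) / s0) * sum(z * (w %*% z)) / sum(z^2)
}

#' Global Moran's I with a permutation null
#'
#' Computes `I = (n/S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with
#' `z = x - mean(x)` and `S0 = sum_ij w_ij`, and a permutation p-value with
#' the add-one correction `p = (1 + #{I_perm >= I_obs}) / (1 + n_perm)`
#' (one-sided "greater" by default; "two_sided" doubles the smaller tail).
#' For `n <= 7`, `exhaustive = TRUE` enumerates all `n!` permutations and the
#' p-value is the exact fraction of permutations at least as extreme.
#'
#' When `values` are residuals of a regression whose covariates are
#' themselves spatially structured, plain value permutation is conservative:
#' the projection that produced the residuals shifts their Moran's I below
#' the exchangeable null. Supplying the residual-maker matrix
#' `M = I - X (X'X)^-1 X'` as `projection` applies it to every permuted
#' vector before computing I (the Freedman-Lane scheme for permutation tests
#' with nuisance regressors), which restores the nominal size. The default
#' (`NULL`) is the plain value permutation.
#'
#' @param values Numeric vector, one value per region; must not be constant.
#' @param W A [inverse_distance_weights()] object or a plain numeric matrix.
#' @param n_permutations Number of random permutations (default 9999).
#' @param seed Integer seed for the permutation draw (recorded in the result).
#' @param alternative `"greater"` (default) or `"two_sided"`.
#' @param exhaustive Enumerate all permutations (n <= 9 only).
#' @param projection Optional n-by-n matrix applied to the observed and every
#'   permuted value vector before computing I (see Details); it should
#'   annihilate the intercept (rows summing to zero), as a residual-maker
#'   matrix does.
#' @return An object of class `moran_result`: list with `I`, `expected_I`
#'   (`-1/(n-1)`), `p_value`, `n_permutations`, `seed`, `alternative`.
#' @export
morans_i <- function(values, W, n_permutations = 9999, seed = 1L,
                     alternative = c("greater", "two_sided"),
                     exhaustive = FALSE, projection = NULL) {
  alternative <- match.arg(alternative)
  w <- if (inherits(W, "weight_matrix")) W$w else as.matrix(W)
  n <- length(values)
  if (n != nrow(w)) abort_input("values length (%d) != weight matrix size (%d)", n, nrow(w))
  if (!is.null(projection)) {
    projection <- as.matrix(projection)
    if (!all(dim(projection) == c(n, n))) {
      abort_input("projection must be %d x %d", n, n)
    }
    values <- as.numeric(projection %*% values)
  }
  if (sd(values) == 0) abort_input("Moran's I undefined for constant values")
  z <- values - mean(values)
  s0 <- sum(w)
  i_obs <- .moran_stat(z, w, s0)
  extreme <- function(i_perm) {
    if (alternative == "greater") i_perm >= i_obs - 1e-12
    else abs(i_perm - (-1 / (n - 1))) >= abs(i_obs - (-1 / (n - 1))) - 1e-12
  }
  perm_stat <- function(zp) {
    if (!is.null(projection)) zp <- as.numeric(projection %*% zp)
    .moran_stat(zp - mean(zp), w, s0)
  }
  if (exhaustive) {
    if (n > 9) abort_input("exhaustive enumeration limited to n <= 9")
    perms <- .permutations(n)
    i_all <- apply(perms, 1, function(p) perm_stat(z[p]))
    p_value <- mean(extreme(i_all))
    n_perm <- nrow(perms)
  } else {
    set.seed(seed)
    zmat <- replicate(n_permutations, z[sample.int(n)])
    if (!is.null(projection)) {
      zmat <- projection %*% zmat
      zmat <- sweep(zmat, 2, colMeans(zmat))
      ssq <- colSums(zmat^2)
    } else {
      ssq <- sum(z^2)
    }
    i_perm <- (n / s0) * colSums(zmat * (w %*% zmat)) / ssq
    p_value <- (1 + sum(extreme(i_perm))) / (1 + n_permutations)
    n_perm <- n_permutations
  }
  structure(list(I = i_obs, expected_I = -1 / (n - 1), p_value = p_value,
                 n_permutations = n_perm, seed = seed,
                 alternative = alternative),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Global Moran's I = %.4f (E[I] = %.4f), p = %.4g [%s, %d permutations]\n",
              x$I, x$expected_I, x$p_value, x$alternative, x$n_permutations))
  invisible(x)
}

#' Export / import spatial weights
#'
#' `write_weights` serializes the raw weight matrix to CSV, either dense
#' (row per region) or as sparse triplets `(i, j, w)` keeping only positive
#' weights; `read_weights` reads either format back into a `weight_matrix`.
#'
#' @param W A `weight_matrix`.
#' @param path Output CSV path.
#' @param format `"dense"` or `"triplet"`.
#' @return `write_weights` returns `path` invisibly; `read_weights` a
#'   `weight_matrix`.
#' @export
write_weights <- function(W, path, format = c("dense", "triplet")) {
  format <- match.arg(format)
  if (format == "dense") {
    df <- as.data.frame(W$w_raw)
    names(df) <- W$ids
    df <- cbind(region_id = W$ids, df)
    write.csv(df, path, row.names = FALSE)
  } else {
    idx <- which(W$w_raw > 0, arr.ind = TRUE)
    df <- data.frame(i = W$ids[idx[, 1]], j = W$ids[idx[, 2]],
                     w = W$w_raw[idx])
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_weights
#' @param row_standardize Standardize rows of the matrix read back in.
#' @export
read_weights <- function(path, row_standardize = TRUE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (identical(names(df)[1:3], c("i", "j", "w"))) {
    ids <- sort(unique(c(df$i, df$j)))
    n <- length(ids)
    w_raw <- matrix(0, n, n, dimnames = list(ids, ids))
    w_raw[cbind(match(df$i, ids), match(df$j, ids))] <- df$w
  } else {
    ids <- df$region_id
    w_raw <- as.matrix(df[, -1, drop = FALSE])
    dimnames(w_raw) <- list(ids, ids)
  }
  nbr <- rowSums(w_raw > 0)
  w <- w_raw
  if (row_standardize) {
    rs <- rowSums(w_raw)
    pos <- rs > 0
    w[pos, ] <- w_raw[pos, , drop = FALSE] / rs[pos]
  }
  structure(list(n = nrow(w_raw), w = w, w_raw = w_raw,
                 row_standardized = row_standardize,
                 neighbor_counts = nbr, ids = as.character(ids)),
            class = "weight_matrix")
}

#' Serialize a Moran's I result to JSON
#'
#' @param x A `moran_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_moran_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
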