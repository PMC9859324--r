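# Hierarchical clustering of cause-of-death YLL profiles and between-cluster
# testing.

#' Ward-linkage hierarchical clustering of YLL profiles
#'
#' Agglomerative clustering of regions by their age-standardized
#' years-of-life-lost profiles, using Euclidean distance and Ward's
#' minimum-variance criterion (the merge chosen at every step is the one
#' that minimally increases the total within-cluster error sum of squares).
#' Rows are clustered on their raw scale by default; `standardize = TRUE`
#' z-scores each cause first.
#'
#' @param Y Numeric matrix, regions x causes (rownames = region ids); no
#'   missing cells, values >= 0.
#' @param k Number of clusters to cut the tree into (default 3).
#' @param standardize Z-score each cause column first? Default `FALSE`.
#' @return Object of class `yll_clusters`: list with `hclust` (the fitted
#'   tree; heights on the Ward.D2 scale, so the ESS increase of a merge is
#'   `height^2 / 2`), `merges` (data frame: left, right, height, size),
#'   `labels` (named cluster id per region) and `k`.
#' @export
ward_cluster <- function(Y, k = 3, standardize = FALSE) {
  Y <- as.matrix(Y)
  if (anyNA(Y)) abort_input("YLL matrix has missing cells")
  if (any(Y < 0)) abort_input("YLL values must be non-negative")
  if (k > nrow(Y)) abort_input("k (%d) exceeds number of regions (%d)", k, nrow(Y))
  if (is.null(rownames(Y))) rownames(Y) <- paste0("R", seq_len(nrow(Y)))
  Ys <- if (standardize) scale(Y) else Y
  hc <- hclust(dist(Ys), method = "ward.D2")
  labels <- cutree(hc, k = k)
  sizes <- .merge_sizes(hc$merge)
  merges <- data.frame(left = hc$merge[, 1], right = hc$merge[, 2],
                       height = hc$height, size = sizes)
  structure(list(hclust = hc, merges = merges,
                 labels = labels, k = k, standardized = standardize),
            class = "yll_clusters")
}

.merge_sizes <- function(merge) {
  sizes <- integer(nrow(merge))
  for (i in seq_len(nrow(merge))) {
    s <- 0L
    for (side in merge[i, ]) s <- s + if (side < 0) 1L else sizes[side]
    sizes[i] <- s
  }
  sizes
}

#' @export
print.yll_clusters <- function(x, ...) {
  cat(sprintf("Ward clustering of %d regions into %d clusters (sizes: %s)\n",
              length(x$labels), x$k,
              paste(table(x$labels), collapse = "/")))
  invisible(x)
}

# Route one cause's values through the ANOVA prerequisites: every group of
# size >= 3 passes Shapiro-Wilk AND Levene's test (center = median) at alpha.
.anova_ok <- function(values, groups, alpha = 0.05) {
  by_g <- split(values, groups)
  if (any(lengths(by_g) < 3)) return(FALSE)
  sw <- vapply(by_g, function(v) {
    if (sd(v) == 0) return(0) # degenerate group: not plausibly normal
    shapiro.test(v)$p.value
  }, numeric(1))
  if (any(sw < alpha)) return(FALSE)
  lv <- car::leveneTest(values ~ factor(groups), center = median)[1, "Pr(>F)"]
  lv >= alpha
}

#' Between-cluster tests of YLLs (and oxygen)
#'
#' For each cause (column of `Y`), tests whether the clusters differ. Causes
#' whose per-group values satisfy the ANOVA prerequisites (Shapiro-Wilk
#' normality in every group and Levene homogeneity of variance, both at
#' `alpha`) get a one-way ANOVA followed by pairwise two-sample t-tests;
#' otherwise a Kruskal-Wallis test (tie-corrected H) followed by pairwise
#' Wilcoxon rank-sum tests. All pairwise p-values are Bonferroni-adjusted:
#' multiplied by the number of cluster pairs and capped at 1. An `oxygen`
#' vector can be appended as an extra tested variable. Pairwise tests
#' involving singleton clusters are skipped with a warning.
#'
#' @param Y Regions x causes YLL matrix.
#' @param labels Cluster labels (same order as rows of `Y`).
#' @param alpha Level for the prerequisite tests (default 0.05).
#' @param oxygen Optional per-region oxygen vector tested the same way.
#' @return Data frame with one row per variable: `variable`, `route`
#'   (`"ANOVA"`/`"KruskalWallis"`), `statistic` (F or H), `p_value`, and one
#'   Bonferroni-adjusted column per cluster pair.
#' @export
compare_clusters <- function(Y, labels, alpha = 0.05, oxygen = NULL) {
  Y <- as.matrix(Y)
  groups <- factor(labels)
  if (nlevels(groups) < 2) abort_input("need at least 2 clusters")
  if (any(table(groups) < 2)) {
    warning("cluster(s) of size 1: their pairwise tests are skipped")
  }
  vars <- colnames(Y) %||% paste0("cause_", seq_len(ncol(Y)))
  mats <- lapply(seq_len(ncol(Y)), function(j) Y[, j])
  names(mats) <- vars
  if (!is.null(oxygen)) mats$oxygen <- oxygen
  pair_idx <- combn(levels(groups), 2)
  n_pairs <- ncol(pair_idx)
  rows <- lapply(names(mats), function(v) {
    vals <- mats[[v]]
    use_anova <- .anova_ok(vals, groups, alpha)
    if (use_anova) {
      fit <- aov(vals ~ groups)
      tab <- anova(fit)
      stat <- tab[1, "F value"]; p <- tab[1, "Pr(>F)"]
      pair_p <- apply(pair_idx, 2, function(pr) {
        ga <- vals[groups == pr[1]]; gb <- vals[groups == pr[2]]
        if (length(ga) < 2 || length(gb) < 2) return(NA_real_)
        min(1, t.test(ga, gb)$p.value * n_pairs)
      })
    } else {
      kw <- kruskal.test(vals, groups)
      stat <- unname(kw$statistic); p <- kw$p.value
      pair_p <- apply(pair_idx, 2, function(pr) {
        ga <- vals[groups == pr[1]]; gb <- vals[groups == pr[2]]
        if (length(ga) < 2 || length(gb) < 2) return(NA_real_)
        raw <- suppressWarnings(wilcox.test(ga, gb)$p.value)
        min(1, raw * n_pairs)
      })
    }
    row <- data.frame(variable = v,
                      route = if (use_anova) "ANOVA" else "KruskalWallis",
                      statistic = stat, p_value = p,
                      stringsAsFactors = FALSE)
    for (m in seq_len(n_pairs)) {
      row[[sprintf("p_adj_%s_vs_%s", pair_idx[1, m], pair_idx[2, m])]] <- pair_p[m]
    }
    row
  })
  do.call(rbind, rows)
}

#' Export a dendrogram as Newick and a linkage table
#'
#' The Newick string uses the standard ultrametric convention: a leaf under
#' a merge at height `h` gets branch length `h/2`, so two leaves merging at
#' height `h` render as `(A:h/2,B:h/2);`. The string round-trips through
#' re-parsing (topology preserved).
#'
#' @param result A [ward_cluster()] result.
#' @param newick_path,linkage_path Optional output paths; when given the
#'   Newick string / linkage CSV are written there.
#' @return List with `newick` (string) and `linkage` (data frame).
#' @export
export_dendrogram <- function(result, newick_path = NULL, linkage_path = NULL) {
  phy <- ape::as.phylo(result$hclust)
  newick <- ape::write.tree(phy)
  if (!is.null(newick_path)) writeLines(newick, newick_path)
  if (!is.null(linkage_path)) write.csv(result$merges, linkage_path, row.names = FALSE)
  list(newick = newick, linkage = result$merges)
}
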