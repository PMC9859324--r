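# Ward clustering of YLL profiles and between-cluster tests.

test_that("identical rows merge first at height zero", {
  Y <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(10, 10, 10))
  cl <- ward_cluster(Y, k = 2)
  expect_equal(cl$merges$height[1], 0)
  expect_equal(cl$labels[["a"]], cl$labels[["b"]])
})

test_that("merge structure equals the brute-force minimum-ESS oracle", {
  # three 1-D points: {0, 1} must merge first
  Y1 <- matrix(c(0, 1, 10), dimnames = list(c("p", "q", "r"), NULL))
  cl1 <- ward_cluster(Y1, k = 2)
  sets1 <- hclust_merge_sets(cl1$hclust)
  expect_equal(sets1[[1]], c(1, 2))

  o1 <- oracle_ward(Y1)
  for (i in seq_along(o1)) {
    expect_equal(sets1[[i]], o1[[i]]$members)
    # ward.D2 heights encode the ESS increase as height^2 / 2
    expect_equal(cl1$merges$height[i]^2 / 2, o1[[i]]$delta_ess,
                 tolerance = 1e-10)
  }

  # random multivariate configurations up to 6 points
  set.seed(51)
  for (rep in 1:5) {
    n <- sample(4:6, 1)
    Y <- matrix(rnorm(n * 3), n)
    rownames(Y) <- paste0("r", seq_len(n))
    cl <- ward_cluster(abs(Y), k = 2)
    sets <- hclust_merge_sets(cl$hclust)
    oracle <- oracle_ward(abs(Y))
    for (i in seq_along(oracle)) {
      expect_equal(sets[[i]], oracle[[i]]$members)
      expect_equal(cl$merges$height[i]^2 / 2, oracle[[i]]$delta_ess,
                   tolerance = 1e-10)
    }
  }
})

test_that("Ward merge heights are non-decreasing and labels partition", {
  cfg <- synthetic_config(seed = 52)
  yll <- generate_yll(cfg)
  cl <- ward_cluster(yll$yll, k = 3)
  expect_true(all(diff(cl$merges$height) >= -1e-10))
  expect_equal(sort(unique(cl$labels)), 1:3)
  expect_equal(length(cl$labels), nrow(yll$yll))
  expect_error(ward_cluster(yll$yll, k = 99), class = "oxylife_input_error")
})

test_that("labels are invariant to row order up to relabeling", {
  skip_if_not_installed("mclust")
  cfg <- synthetic_config(seed = 53)
  yll <- generate_yll(cfg)
  cl <- ward_cluster(yll$yll, k = 3)
  perm <- sample(nrow(yll$yll))
  cl_p <- ward_cluster(yll$yll[perm, ], k = 3)
  ari <- mclust::adjustedRandIndex(cl$labels[perm], cl_p$labels)
  expect_equal(ari, 1)
})

test_that("planted clusters are recovered exactly at a 5-SD shift", {
  skip_if_not_installed("mclust")
  hits <- 0
  for (s in 1:10) {
    cfg <- synthetic_config(seed = 500 + s)
    yll <- generate_yll(cfg)
    cl <- ward_cluster(yll$yll, k = 3)
    if (mclust::adjustedRandIndex(cl$labels, yll$labels) == 1) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("cluster tests route by prerequisites and adjust pairwise p-values", {
  # 3 groups of 2: too small for normality checks, so Kruskal-Wallis
  Y <- matrix(c(1, 2, 3, 4, 5, 6), dimnames = list(paste0("r", 1:6), "cause_a"))
  labels <- c(1, 1, 2, 2, 3, 3)
  tests <- compare_clusters(Y, labels)
  expect_equal(tests$route, "KruskalWallis")
  expect_equal(tests$statistic, oracle_kw_h(Y[, 1], labels), tolerance = 1e-3)
  expect_equal(tests$statistic, 4.5714, tolerance = 1e-3)

  # Bonferroni arithmetic: adjusted = min(1, raw * n_pairs)
  set.seed(54)
  Yn <- matrix(rnorm(30, 100, 5), dimnames = list(paste0("r", 1:30), "cause_b"))
  lab <- rep(1:3, each = 10)
  tn <- compare_clusters(Yn, lab)
  raw12 <- if (tn$route == "ANOVA") {
    t.test(Yn[lab == 1, 1], Yn[lab == 2, 1])$p.value
  } else {
    wilcox.test(Yn[lab == 1, 1], Yn[lab == 2, 1])$p.value
  }
  expect_equal(tn$p_adj_1_vs_2, min(1, raw12 * 3), tolerance = 1e-12)
  expect_gte(tn$p_adj_1_vs_2, raw12)

  # singleton clusters: pairwise tests involving them are skipped
  expect_warning(
    t1 <- compare_clusters(Yn, c(rep(1, 15), rep(2, 14), 3)),
    "size 1")
  expect_true(is.na(t1$p_adj_1_vs_3))
})

test_that("the low-oxygen planted cluster shows its designed YLL contrasts", {
  cfg <- synthetic_config(seed = 55)
  gen <- generate_regions(cfg)
  yll <- generate_yll(cfg, gen$regions)
  tests <- compare_clusters(yll$yll, yll$labels,
                            oxygen = gen$regions$oxygen)
  low <- max(yll$labels) # the planted low-oxygen cluster
  for (cause in yll$elevated_causes) {
    vals <- yll$yll[, cause]
    m_low <- mean(vals[yll$labels == low])
    m_rest <- tapply(vals[yll$labels != low], yll$labels[yll$labels != low], mean)
    expect_true(all(m_low > m_rest))
    expect_lt(tests$p_value[tests$variable == cause], 0.05)
  }
  vals <- yll$yll[, yll$depressed_cause]
  expect_true(all(mean(vals[yll$labels == low]) <
                  tapply(vals[yll$labels != low], yll$labels[yll$labels != low], mean)))
  # oxygen itself separates the clusters
  expect_lt(tests$p_value[tests$variable == "oxygen"], 0.05)
})

test_that("dendrogram export round-trips through Newick", {
  # two leaves merging at height h render as (A:h/2,B:h/2);
  Y2 <- matrix(c(0, 3), dimnames = list(c("A", "B"), NULL))
  d2 <- export_dendrogram(ward_cluster(Y2, k = 1))
  expect_equal(d2$newick, "(A:1.5,B:1.5);")

  cfg <- synthetic_config(seed = 56)
  yll <- generate_yll(cfg)
  cl <- ward_cluster(yll$yll, k = 3)
  nt <- tempfile(fileext = ".nwk"); lt <- tempfile(fileext = ".csv")
  d <- export_dendrogram(cl, nt, lt)
  phy <- ape::read.tree(text = d$newick)
  expect_equal(sort(phy$tip.label), sort(rownames(yll$yll)))
  # topology preserved under re-parse: re-serializing is the identity
  reread <- ape::read.tree(nt)
  expect_identical(ape::write.tree(reread), d$newick)
  expect_equal(nrow(read.csv(lt)), nrow(yll$yll) - 1)
})
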