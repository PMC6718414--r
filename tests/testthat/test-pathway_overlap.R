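# Over-representation analysis, localization binning, overlap/concordance,
# KS comparison, hierarchical clustering.

test_that("ORA p-values equal exact combinatorial enumeration", {
  universe <- sprintf("g%02d", 1:20)
  sets <- list(S = universe[1:5])
  res <- ora(universe[1:5], sets, universe, min_size = 1, max_size = 500)
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$fold_enrichment, 4)
  expect_equal(res$overlap_k, 5L)

  # disjoint hits: upper-tail convention gives p = 1
  res0 <- ora(universe[6:10], sets, universe, min_size = 1)
  expect_equal(res0$p_value, 1)

  set.seed(41)
  for (i in 1:40) {
    N <- sample(8:25, 1)
    uni <- sprintf("x%03d", 1:N)
    K <- sample(2:(N - 2), 1)
    n <- sample(2:(N - 2), 1)
    sets <- list(S = sample(uni, K))
    hits <- sample(uni, n)
    res <- ora(hits, sets, uni, min_size = 1, max_size = 500)
    k <- length(intersect(hits, sets$S))
    expect_equal(res$p_value, oracle_hyper_upper(k, K, n, N),
                 tolerance = 1e-12)
  }
})

test_that("ORA restricts sets to the universe and filters by size", {
  uni <- sprintf("u%02d", 1:30)
  sets <- list(small = uni[1:3], ok = uni[1:10],
               outside = c(uni[1:6], "alien1", "alien2"))
  res <- ora(uni[1:5], sets, uni)
  expect_setequal(res$pathway_id, c("ok", "outside"))
  expect_equal(res$set_K[res$pathway_id == "outside"], 6L)  # aliens dropped
  expect_warning(ora(c(uni[1], "stranger"), sets, uni), "outside the universe")
  expect_warning(empty <- ora(character(), sets, uni), "empty hit list")
  expect_equal(nrow(empty), 0L)
  # explicit universe size (protein-coding reference mode)
  res_big <- ora(uni[1:5], sets["ok"], uni, universe_size = 1000)
  expect_equal(res_big$universe_N, 1000L)
  expect_lt(res_big$p_value, res$p_value[res$pathway_id == "ok"])
})

test_that("adding a member hit never increases a pathway's p-value", {
  set.seed(42)
  uni <- sprintf("u%02d", 1:40)
  sets <- list(S = uni[1:12])
  hits <- sample(uni[13:40], 6)
  for (extra in uni[1:5]) {
    p_before <- ora(hits, sets, uni)$p_value
    hits <- c(hits, extra)
    p_after <- ora(hits, sets, uni)$p_value
    expect_lte(p_after, p_before)
  }
})

test_that("BH adjustment reproduces the hand-applied step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(43)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p & adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})

test_that("BH controls the all-null any-rejection rate at 0.05", {
  set.seed(44)
  any_rej <- vapply(1:1000, function(i) any(bh_adjust(runif(100)) < 0.05),
                    logical(1))
  expect_lte(mean(any_rej), 0.05 + 2 * sqrt(0.05 * 0.95 / 1000))
})

test_that("localization terms map to the four compartment bins", {
  expect_equal(assign_localization("Golgi apparatus"), "secretory")
  expect_equal(assign_localization("endoplasmic reticulum"), "secretory")
  expect_equal(assign_localization(c("proteasome", "lysosome", "secreted")),
               rep("secretory", 3))
  expect_equal(assign_localization("chromosome"), "nucleus")
  expect_equal(assign_localization("Mitochondrion"), "mitochondria")
  expect_equal(assign_localization(c("cytosol", "ribosome", "cytoskeleton")),
               rep("cytoplasm", 3))
  expect_warning(bin <- assign_localization("peroxisome"), "unmatched")
  expect_equal(bin, "cytoplasm")
  expect_error(assign_localization(""), "empty")
})

test_that("overlap concordance counts shared signed changes", {
  s <- overlap_concordance(c(s1 = 5, s2 = -3), c(s1 = -2, s2 = -1))
  expect_equal(s$n_both, 2L)
  expect_equal(s$concordant, 1L)
  expect_equal(s$discordant, 1L)
  expect_equal(overlap_concordance(c(a = 1), c(b = 1))$n_both, 0L)
  expect_warning(overlap_concordance(c(a = 0, b = 1), c(b = 2)), "zero change")
})

test_that("overlap concordance matches brute force and is symmetric", {
  set.seed(45)
  for (i in 1:20) {
    ids <- sprintf("s%03d", 1:60)
    a <- setNames(sample(c(-1, 1), 25, TRUE) * runif(25, 1, 9), sample(ids, 25))
    b <- setNames(sample(c(-1, 1), 25, TRUE) * runif(25, 1, 9), sample(ids, 25))
    s <- overlap_concordance(a, b)
    conc <- disc <- 0L
    for (id in names(a)) for (jd in names(b)) {
      if (id != jd) next
      if (sign(a[id]) == sign(b[jd])) conc <- conc + 1L else disc <- disc + 1L
    }
    expect_equal(s$concordant, conc)
    expect_equal(s$discordant, disc)
    expect_equal(s$n_both, conc + disc)
    expect_equal(s$n_both + s$n_only_a, length(a))
    sw <- overlap_concordance(b, a)
    expect_equal(sw$concordant, s$concordant)
    expect_equal(sw$discordant, s$discordant)
    expect_equal(sw$n_only_a, s$n_only_b)
  }
})

test_that("KS statistic equals exhaustive ECDF-difference maximisation", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ks_two_sample(c(1, 2), c(3, 4))$D, 1)
  set.seed(46)
  for (i in 1:30) {
    x <- sample(1:10, sample(2:6, 1), replace = TRUE)
    y <- sample(1:10, sample(2:6, 1), replace = TRUE)
    expect_equal(ks_two_sample(x, y)$D, oracle_ks_d(x, y), tolerance = 1e-12)
  }
  expect_error(ks_two_sample(1, c(1, 2)), ">= 2")
})

test_that("complete-linkage clustering matches the O(n^3) oracle", {
  m <- rbind(a = c(0, 0), b = c(0, 0), c = c(5, 5))
  cl <- hierarchical_cluster(m)
  expect_equal(min(cl$hclust$height), 0)  # identical rows merge at 0

  set.seed(47)
  for (i in 1:10) {
    m <- matrix(rnorm(6 * 4), 6, 4)
    cl <- hierarchical_cluster(m)
    expect_equal(sort(cl$hclust$height), oracle_complete_linkage_heights(m),
                 tolerance = 1e-10)
  }
})

test_that("clustering is permutation-invariant and handles edge cases", {
  set.seed(48)
  m <- matrix(rnorm(8 * 3), 8, 3, dimnames = list(sprintf("r%d", 1:8), NULL))
  cl <- hierarchical_cluster(m)
  perm <- sample(8)
  cl2 <- hierarchical_cluster(m[perm, ])
  expect_equal(sort(cl$hclust$height), sort(cl2$hclust$height),
               tolerance = 1e-10)
  # leaves adjacent in one tree stay in the same merged groups: compare
  # cophenetic distances under the relabeling
  coph1 <- as.matrix(cophenetic(cl$hclust))
  coph2 <- as.matrix(cophenetic(cl2$hclust))
  expect_equal(coph2[rownames(coph1), rownames(coph1)], coph1,
               tolerance = 1e-10)

  single <- hierarchical_cluster(m[1, , drop = FALSE])
  expect_null(single$hclust)
  expect_equal(single$order, 1L)
  m_na <- m; m_na[2, 1] <- NA
  expect_warning(hierarchical_cluster(m_na), "imputed")
})

test_that("dendrograms export as Newick with the row labels as tips", {
  set.seed(49)
  m <- matrix(rnorm(5 * 3), 5, 3, dimnames = list(sprintf("p%d", 1:5), NULL))
  cl <- hierarchical_cluster(m)
  path <- tempfile(fileext = ".nwk")
  write_dendrogram_newick(cl, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, rownames(m))
  expect_error(write_dendrogram_newick(hierarchical_cluster(m[1, , drop = FALSE]),
                                       path), "fewer than 2")
})
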