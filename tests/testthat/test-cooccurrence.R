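# Co-occurrence scores, bee similarity, Markov clustering, cluster stats.

test_that("the co-occurrence score follows 2*bAB/(bA+bB) with its endpoints", {
  expect_equal(cooccurrence_score(5, 5, 5), 1)
  expect_equal(cooccurrence_score(0, 4, 6), 0)
  expect_equal(cooccurrence_score(3, 4, 6), 0.6)
  expect_error(cooccurrence_score(5, 4, 6), "inconsistent")
  expect_error(cooccurrence_score(1, 0, 3), ">= 1")
})

test_that("the co-occurrence graph is symmetric with unit diagonal and exact endpoints", {
  # two strains always together in 10 bees, one loner elsewhere
  P <- matrix(FALSE, 3, 12,
              dimnames = list(c("s1", "s2", "s3"), sprintf("b%02d", 1:12)))
  P[1, 1:10] <- TRUE; P[2, 1:10] <- TRUE; P[3, 11:12] <- TRUE
  g <- build_cooccurrence_graph(strain_table_from_presence(P), "m")
  expect_equal(g$S["s1", "s2"], 1)
  expect_equal(g$S["s1", "s3"], 0)
  expect_identical(g$S, t(g$S))
  expect_equal(unname(diag(g$S)), rep(1, 3))
  # fewer than two strains: empty graph with a warning
  P1 <- P[1, , drop = FALSE]
  expect_warning(g1 <- build_cooccurrence_graph(strain_table_from_presence(P1), "m"),
                 "fewer than 2")
  expect_equal(nrow(g1$S), 0)
})

test_that("bee similarity is the Dice score on strain sets", {
  P <- matrix(FALSE, 4, 3, dimnames = list(sprintf("s%d", 1:4), c("u", "v", "w")))
  P[c(1, 2), "u"] <- TRUE          # {s1,s2}
  P[1:4, "v"] <- TRUE              # {s1..s4}
  P[c(3, 4), "w"] <- TRUE          # {s3,s4}
  S <- bee_similarity_matrix(strain_table_from_presence(P), "m")
  expect_equal(S["u", "v"], 2 * 2 / 6, tolerance = 1e-12)
  expect_equal(S["u", "w"], 0)
  expect_equal(S["v", "v"], 1)
})

test_that("MCL separates disconnected cliques and isolates singletons", {
  # two disconnected 4-cliques
  S <- matrix(0, 8, 8, dimnames = list(sprintf("s%d", 1:8), sprintf("s%d", 1:8)))
  S[1:4, 1:4] <- 1; S[5:8, 5:8] <- 1
  cl <- mcl_cluster(S, inflation = 2)
  expect_equal(length(cl$clusters), 2)
  expect_equal(sort(lengths(cl$clusters)), c(4, 4))
  expect_true(cl$converged)
  # identity-like graph: all singletons
  I8 <- diag(8); dimnames(I8) <- dimnames(S)
  cl0 <- mcl_cluster(I8, inflation = 2)
  expect_equal(length(cl0$clusters), 8)
})

test_that("MCL is scale-invariant and invariant to node reordering", {
  set.seed(31)
  S <- random_community_graph(20, 3)
  dimnames(S) <- list(sprintf("s%02d", 1:20), sprintf("s%02d", 1:20))
  m1 <- mcl_cluster(S, inflation = 2)$membership
  m2 <- mcl_cluster(S * 7.3, inflation = 2)$membership
  expect_true(same_partition(m1, m2))
  perm <- sample.int(20)
  m3 <- mcl_cluster(S[perm, perm], inflation = 2)$membership
  expect_true(same_partition(m1, m3[match(names(m1), names(m3))]))
})

test_that("in-package MCL matches the independent reference implementation", {
  skip_if(Sys.which("python") == "", "python not available")
  set.seed(32)
  for (g in 1:5) {
    S <- random_community_graph(30, sample(3:6, 1))
    for (I in c(1.2, 2, 4, 6)) {
      mine <- unname(mcl_cluster(S, inflation = I)$membership)
      ref <- oracle_mcl(S, I)
      expect_true(same_partition(mine, ref),
                  label = sprintf("partition match (graph %d, I=%g)", g, I))
    }
  }
})

test_that("well-separated planted clusters are recovered exactly at I=2", {
  truth <- small_truth(n_bees = 12, n_clusters = 5, strains_per_cluster = 4,
                       markers = "m1", seed = 33)
  tab <- strain_table_from_truth(truth)
  g <- build_cooccurrence_graph(tab, "m1")
  # planted structure: high within-cluster, low between-cluster scores
  lab <- planted_labels(tab, truth, "m1", g$strains)
  same <- outer(lab, lab, "==")
  ut <- upper.tri(g$S)
  expect_gt(min(g$S[ut & same]), 0.8)
  expect_lt(max(g$S[ut & !same]), 0.1)
  cl <- mcl_cluster(g, inflation = 2)
  expect_equal(ari(lab, cl$membership[g$strains]), 1)
})

test_that("cluster statistics report sizes, clusters per bee and within-SNP means", {
  truth <- small_truth(n_bees = 12, n_clusters = 4, strains_per_cluster = 4,
                       markers = "m1", seed = 34)
  tab <- strain_table_from_truth(truth)
  cl <- mcl_cluster(build_cooccurrence_graph(tab, "m1"), inflation = 2)
  st <- cluster_stats(cl, tab, "m1")
  expect_equal(sort(unique(st$sizes)), 4)
  expect_equal(unname(sort(unique(st$clusters_per_bee))), 1)
  # planted within-cluster distances are 1 (founder) or 2 (mutant pairs)
  expect_true(all(st$within_cluster_snp_means >= 1 &
                    st$within_cluster_snp_means <= 2))
  # singleton clustering: clusters per bee equals strains per bee
  singletons <- structure(list(
    membership = stats::setNames(seq_along(cl$membership), names(cl$membership)),
    clusters = as.list(names(cl$membership))), class = "strain_clusters")
  st1 <- cluster_stats(singletons, tab, "m1")
  P <- presence_matrix(tab, "m1")
  expect_equal(unname(st1$clusters_per_bee), unname(colSums(P)))
})

test_that("the rank-sum test matches the classic normal approximation", {
  set.seed(35)
  for (i in 1:5) {
    x <- sample(0:10, 20, replace = TRUE)  # heavy ties, like SNP distances
    y <- sample(2:14, 30, replace = TRUE)
    mine <- ranksum_test(x, y)
    ref <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("within-cluster SNP distances are smaller than between-cluster ones", {
  truth <- small_truth(n_bees = 12, n_clusters = 5, strains_per_cluster = 4,
                       markers = "m1", seed = 36)
  tab <- strain_table_from_truth(truth)
  cl <- mcl_cluster(build_cooccurrence_graph(tab, "m1"), inflation = 2)
  wb <- within_vs_between_snps(cl, tab, "m1")
  expect_true(wb$applicable)
  expect_lt(wb$within_mean, wb$between_mean)
  expect_lt(wb$p_value, 1e-10)
  # one single cluster: not applicable
  allone <- structure(list(
    membership = stats::setNames(rep(1L, length(cl$membership)),
                                 names(cl$membership)),
    clusters = list(names(cl$membership))), class = "strain_clusters")
  expect_false(within_vs_between_snps(allone, tab, "m1")$applicable)
})

test_that("label-shuffled clusterings yield calibrated rank-sum p-values", {
  truth <- small_truth(n_bees = 12, n_clusters = 5, strains_per_cluster = 4,
                       markers = "m1", seed = 37)
  tab <- strain_table_from_truth(truth)
  cl <- mcl_cluster(build_cooccurrence_graph(tab, "m1"), inflation = 2)
  set.seed(38)
  ps <- replicate(200, {
    shuffled <- cl
    shuffled$membership <- stats::setNames(sample(cl$membership),
                                           names(cl$membership))
    within_vs_between_snps(shuffled, tab, "m1")$p_value
  })
  # under the null p should be roughly uniform: mean near 0.5 and
  # small-p rate near nominal
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  expect_lt(mean(ps <= 0.05), 0.12)
})
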