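test_that("pearson matches the textbook formula and handles edge cases", {
  expect_equal(pearson(c(1, 2, 3), c(2, 4, 6)), 1.0)
  expect_equal(pearson(c(1, 2, 3), c(3, 2, 1)), -1.0)
  set.seed(2)
  for (rep in 1:10) {
    x <- rnorm(10); y <- rnorm(10)
    expect_equal(pearson(x, y), oracle_pearson(x, y), tolerance = 1e-12)
  }
  # zero variance and insufficient overlap are undefined
  expect_true(is.na(pearson(rep(1, 5), rnorm(5))))
  expect_true(is.na(pearson(c(1, 2, NA, NA, NA), c(2, 1, NA, NA, NA))))
})

test_that("seed grouping equals the transitive closure of the r-graph", {
  set.seed(14)
  for (rep in 1:10) {
    profiles <- matrix(rnorm(8 * 12), 8, 12,
                       dimnames = list(sprintf("s%d", 1:8), NULL))
    # make a few deliberate near-duplicates
    profiles[2, ] <- profiles[1, ] + rnorm(12, sd = 0.05)
    profiles[5, ] <- profiles[4, ] + rnorm(12, sd = 0.05)
    g <- dedupe_seeds(profiles, cluster_config())
    # brute-force closure
    r <- cor(t(profiles))
    adj <- r >= 0.9; diag(adj) <- TRUE
    reach <- adj
    for (i in 1:8) reach <- reach | (reach %*% adj > 0)
    for (i in 1:8) for (j in 1:8) {
      same <- g$group[i] == g$group[j]
      expect_equal(same, unname(reach[i, j]))
    }
    # representatives are members of their own group
    expect_true(all(mapply(function(s, r) g$group[g$seed == r] == g$group[g$seed == s],
                           g$seed, g$representative)))
  }
})

test_that("uncorrelated seeds are self-represented, duplicates collapse", {
  set.seed(15)
  profiles <- matrix(rnorm(4 * 10), 4, 10,
                     dimnames = list(c("a", "b", "c", "d"), NULL))
  g <- dedupe_seeds(profiles)
  expect_equal(g$representative, c("a", "b", "c", "d"))
  profiles2 <- rbind(x = profiles[1, ], y = profiles[1, ])
  g2 <- dedupe_seeds(profiles2)
  expect_equal(unique(g2$group), 1L)
  expect_equal(unique(g2$representative), "x")   # lexicographic tie-break
})

test_that("cluster growth recruits exactly the genes above seed_r", {
  set.seed(16)
  x <- latent_profiles(300, 18, m = 40, rho = 0.97)
  cl <- grow_cluster(x, "g0001", cluster_config(), seed_ids = c("g0001", "g0002"))
  r <- apply(x, 1, function(v) cor(v, x["g0001", ]))
  expect_setequal(cl$members, sort(unique(c("g0001", names(r)[r >= 0.9]))))
  expect_true(all(cl$seeds %in% c("g0001", "g0002")))
  # nothing correlates: singleton
  iso <- grow_cluster(x[c(1, 250:300), ], "g0250", cluster_config(seed_r = 0.9999,
                                                                  avg_r = 0.5))
  expect_equal(iso$members, "g0250")
  expect_error(grow_cluster(x, "absent"), "not in matrix")
})

test_that("planted clusters are recovered with no false members", {
  hits <- replicate(5, {
    x <- latent_profiles(1040, 18, m = 40, rho = 0.97)
    cl <- adjust_cluster(grow_cluster(x, "g0001"), x)
    c(sum(cl$members %in% sprintf("g%04d", 1:40)),
      sum(!cl$members %in% sprintf("g%04d", 1:40)))
  })
  expect_gte(mean(hits[1, ]), 36)      # >= 90% of 40 on average
  expect_equal(sum(hits[2, ]), 0)      # no noise gene recruited
})

test_that("adjustment removes low-correlation members until avg_r is met", {
  # construct profiles with r(g1,g2) high, r(g1,g3) and r(g2,g3) low
  set.seed(17)
  base <- rnorm(12)
  x <- rbind(g1 = base + rnorm(12, sd = 0.1),
             g2 = base + rnorm(12, sd = 0.1),
             g3 = rnorm(12))
  cl <- structure(list(members = c("g1", "g2", "g3"), seeds = "g1",
                       representative = "g1", avg_r = NA, warning_flag = FALSE),
                  class = "gene_cluster")
  adj <- adjust_cluster(cl, x, cluster_config())
  expect_setequal(adj$members, c("g1", "g2"))
  expect_gte(adj$avg_r, 0.75)
  # exhaustive subset oracle: some subset containing the seed meets the
  # threshold, and the greedy result does too (with maximal achievable size)
  subsets <- list(c("g1", "g2"), c("g1", "g3"), c("g1", "g2", "g3"))
  ok_sizes <- vapply(subsets, function(s) {
    r <- cor(t(x[s, ]))
    if (mean(r[upper.tri(r)]) >= 0.75) length(s) else 0L
  }, integer(1))
  expect_equal(length(adj$members), max(ok_sizes))
})

test_that("already-conforming clusters are untouched, seeds protected", {
  set.seed(18)
  x <- latent_profiles(10, 18, m = 10, rho = 0.95)
  cl <- grow_cluster(x, "g0001")
  adj <- adjust_cluster(cl, x)
  expect_identical(adj$members, cl$members)
  expect_false(adj$warning_flag)
  # all-seed cluster below threshold: unchanged with warning flag
  y <- rbind(a = rnorm(12), b = rnorm(12), c = rnorm(12))
  cl2 <- structure(list(members = c("a", "b", "c"), seeds = c("a", "b", "c"),
                        representative = "a", avg_r = NA, warning_flag = FALSE),
                   class = "gene_cluster")
  adj2 <- adjust_cluster(cl2, y, cluster_config())
  expect_setequal(adj2$members, c("a", "b", "c"))
  expect_true(adj2$warning_flag)
})

test_that("membership is invariant to gene input order", {
  set.seed(19)
  x <- latent_profiles(200, 18, m = 30, rho = 0.9)
  cl1 <- adjust_cluster(grow_cluster(x, "g0001"), x)
  perm <- sample(nrow(x))
  cl2 <- adjust_cluster(grow_cluster(x[perm, ], "g0001"), x[perm, ])
  expect_identical(cl1$members, cl2$members)
})

test_that("tissue preferentiality uses an inclusive 2-fold boundary", {
  vals <- rbind(g1 = c(500, 250, 100), g2 = c(499, 250, 100),
                g3 = c(300, 300, 300))
  colnames(vals) <- c("s1", "s2", "s3")
  meta <- data.frame(sample = c("s1", "s2", "s3"),
                     tissue = c("placentome", "liver", "thymus"))
  m <- new_expression_matrix(vals, meta)
  expect_true(tissue_preferential(m, "g1", "placentome"))
  expect_false(tissue_preferential(m, "g2", "placentome"))
  for (t in meta$tissue) expect_false(tissue_preferential(m, "g3", t))
  expect_error(tissue_preferential(m, "g1", "kidney"), "unknown tissue")
})

test_that("hierarchical clustering matches an independent UPGMA", {
  set.seed(21)
  x <- matrix(rnorm(8 * 6), 8, 6, dimnames = list(sprintf("g%d", 1:8), NULL))
  dend <- hcluster(x, "genes")
  d <- 1 - cor(t(x))
  coph_oracle <- oracle_upgma_cophenetic(stats::as.dist(d))
  coph_hc <- as.matrix(stats::cophenetic(dend$hclust))
  o <- match(sprintf("g%d", 1:8), dend$hclust$labels)
  expect_equal(unname(coph_hc[o, o][upper.tri(coph_oracle)]),
               coph_oracle[upper.tri(coph_oracle)], tolerance = 1e-12)
  expect_equal(dend$branch_correlation, 1 - dend$hclust$height)
})

test_that("identical profiles merge first and at height zero", {
  x <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(4, 3, 2, 1))
  dend <- hcluster(x, "genes")
  expect_equal(min(dend$hclust$height), 0, tolerance = 1e-12)
  first <- dend$hclust$merge[1, ]
  expect_setequal(dend$hclust$labels[-first], c("a", "b"))
  # newick export covers all leaves
  nw <- dendrogram_newick(dend)
  expect_true(all(vapply(c("a", "b", "c"), grepl, TRUE, x = nw, fixed = TRUE)))
})

test_that("overlapping clusters resolve by keeping the largest", {
  set.seed(22)
  x <- latent_profiles(400, 18, m = 60, rho = 0.95)
  # two seeds inside the same planted cluster -> overlapping grown clusters
  cls <- seed_clusters(x, c("g0001", "g0002", "g0399"), overlap = "keep-largest")
  overlap <- outer(seq_along(cls), seq_along(cls), Vectorize(function(i, j) {
    i != j && length(intersect(cls[[i]]$members, cls[[j]]$members)) > 0
  }))
  expect_false(any(overlap))
})
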