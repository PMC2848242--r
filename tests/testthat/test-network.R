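test_that("power adjacency follows |r|^beta", {
  set.seed(41)
  x <- matrix(rnorm(10 * 6), 10, 6, dimnames = list(sprintf("g%d", 1:10), NULL))
  net <- power_adjacency(x, beta = 8)
  r <- cor(t(x))
  expect_equal(unname(net$adjacency[2, 7]), abs(r[2, 7])^8, tolerance = 1e-12)
  expect_equal(unname(power_adjacency(x, 1)$adjacency[3, 4]), abs(r[3, 4]),
               tolerance = 1e-12)
  # the worked constant: r = 0.9 at beta = 8
  expect_equal(0.9^8, 0.43046721)
  # symmetric, in [0,1], connectivity excludes the diagonal
  expect_equal(net$adjacency, t(net$adjacency))
  expect_true(all(net$adjacency >= 0 & net$adjacency <= 1))
  a0 <- net$adjacency; diag(a0) <- 0
  expect_equal(unname(net$connectivity), unname(colSums(a0)), tolerance = 1e-12)
})

test_that("adjacency weakly decreases as beta grows", {
  set.seed(42)
  x <- matrix(rnorm(8 * 10), 8, 10, dimnames = list(letters[1:8], NULL))
  a2 <- power_adjacency(x, 2)$adjacency
  a6 <- power_adjacency(x, 6)$adjacency
  off <- upper.tri(a2)
  expect_true(all(a6[off] <= a2[off] + 1e-12))
})

test_that("zero-variance genes are excluded with a warning", {
  x <- rbind(a = c(1, 1, 1, 1), b = rnorm(4), c = rnorm(4))
  expect_warning(net <- power_adjacency(x, 2), "zero-variance")
  expect_equal(net$genes, c("b", "c"))
})

test_that("TOM equals the direct-formula oracle on random graphs", {
  set.seed(43)
  for (rep in 1:5) {
    a <- matrix(runif(64), 8, 8)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    dimnames(a) <- list(sprintf("g%d", 1:8), sprintf("g%d", 1:8))
    tom <- tom_similarity(a)
    # brute-force evaluation
    for (i in 1:8) for (j in 1:8) {
      if (i == j) { expect_equal(unname(tom[i, j]), 1); next }
      num <- sum(sapply(setdiff(1:8, c(i, j)), function(u) a[i, u] * a[u, j])) +
        a[i, j]
      ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
      expect_equal(unname(tom[i, j]), num / (min(ki, kj) + 1 - a[i, j]),
                   tolerance = 1e-12)
    }
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  }
})

test_that("TOM limits: complete graph gives 1, empty graph gives 0", {
  a1 <- matrix(1, 5, 5)
  expect_true(all(abs(tom_similarity(a1) - 1) < 1e-12))
  a0 <- diag(5)
  t0 <- tom_similarity(a0)
  expect_true(all(t0[upper.tri(t0)] == 0))
})

test_that("connectivity is conserved: sum k = 2 * sum of off-diagonal a", {
  set.seed(44)
  x <- matrix(rnorm(12 * 8), 12, 8, dimnames = list(sprintf("g%d", 1:12), NULL))
  net <- power_adjacency(x, 4)
  a0 <- net$adjacency; diag(a0) <- 0
  expect_equal(sum(net$connectivity), 2 * sum(a0[upper.tri(a0)]),
               tolerance = 1e-9)
})

test_that("a single planted module of 212 genes is detected intact", {
  set.seed(45)
  x <- latent_profiles(212, 14, m = 212, rho = 0.9)
  net <- detect_modules(tom_similarity(power_adjacency(x, 8)))
  expect_equal(length(setdiff(unique(net$modules), 0L)), 1L)
  expect_equal(sum(net$modules == 1L), 212L)
})

test_that("well-separated planted modules are recovered; noise is unassigned", {
  set.seed(46)
  z1 <- rnorm(14); z2 <- rnorm(14)
  x <- matrix(rnorm(120 * 14, sd = 1), 120, 14,
              dimnames = list(sprintf("g%03d", 1:120), NULL))
  x[1:50, ] <- sqrt(0.9) * matrix(z1, 50, 14, byrow = TRUE) + sqrt(0.1) * x[1:50, ]
  x[51:100, ] <- sqrt(0.9) * matrix(z2, 50, 14, byrow = TRUE) + sqrt(0.1) * x[51:100, ]
  net <- detect_modules(tom_similarity(power_adjacency(x, 8)))
  m1 <- net$modules[sprintf("g%03d", 1:50)]
  m2 <- net$modules[sprintf("g%03d", 51:100)]
  lab1 <- as.integer(names(which.max(table(m1))))
  lab2 <- as.integer(names(which.max(table(m2))))
  expect_true(lab1 > 0 && lab2 > 0 && lab1 != lab2)
  expect_gte(mean(m1 == lab1), 0.95)
  expect_gte(mean(m2 == lab2), 0.95)
  # pure-noise genes: no module of their own
  noise_mods <- net$modules[sprintf("g%03d", 101:120)]
  expect_true(all(noise_mods %in% c(0L, lab1, lab2)))
})

test_that("hub selection honors the GS and K/Kmax cutoffs", {
  set.seed(47)
  x <- latent_profiles(60, 14, m = 60, rho = 0.85)
  net <- detect_modules(tom_similarity(power_adjacency(x, 8)))
  gs <- stats::setNames(rep(2, 60), rownames(x))
  # cutoff-free limit: top 5 by connectivity
  h0 <- hub_genes(net, gs, hub_config(gs_cutoff = 0, k_ratio_cutoff = 0))
  expect_equal(h0$gene,
               names(sort(net$connectivity[net$modules == 1], decreasing = TRUE))[1:5])
  # all genes below the GS cutoff: empty with warning
  expect_warning(h1 <- hub_genes(net, gs * 0, hub_config()), "no gene passes")
  expect_equal(nrow(h1), 0)
})

test_that("planted hubs are recovered by connectivity ranking", {
  recover <- vapply(1:10, function(sd) {
    set.seed(sd + 400)
    z <- rnorm(14)
    x <- matrix(rnorm(200 * 14), 200, 14,
                dimnames = list(sprintf("g%03d", 1:200), NULL))
    # 5 hubs track the latent factor tightly, the rest loosely
    x[1:5, ] <- sqrt(0.995) * matrix(z, 5, 14, byrow = TRUE) + sqrt(0.005) * x[1:5, ]
    x[6:200, ] <- sqrt(0.7) * matrix(z, 195, 14, byrow = TRUE) + sqrt(0.3) * x[6:200, ]
    net <- detect_modules(tom_similarity(power_adjacency(x, 8)))
    gs <- stats::setNames(rep(2, 200), rownames(x))
    h <- suppressWarnings(hub_genes(net, gs, hub_config()))
    sum(h$gene %in% sprintf("g%03d", 1:5))
  }, numeric(1))
  expect_gte(sum(recover == 5), 8)
})

test_that("beta selection follows the scale-free criterion", {
  expect_equal(pick_beta(latent_profiles(50, 10, 0, 0),
                         hub_config(beta_grid = 8))$beta, 8)
  # independent noise genes rarely reach the fit target: warning path
  set.seed(48)
  x <- matrix(rnorm(60 * 8), 60, 8, dimnames = list(sprintf("g%d", 1:60), NULL))
  res <- withCallingHandlers(
    pick_beta(x, hub_config(beta_grid = 1:3, rsq_target = 0.999)),
    warning = function(w) {
      expect_match(conditionMessage(w), "scale-free")
      invokeRestart("muffleWarning")
    })
  expect_true(res$beta %in% 1:3)
  expect_error(pick_beta(x[1:5, ], hub_config()), ">= 10 genes")
})

test_that("MatrixMarket export round-trips through an independent reader", {
  set.seed(50)
  x <- latent_profiles(12, 10, m = 12, rho = 0.8)
  net <- tom_similarity(power_adjacency(x, 4))
  pa <- withr::local_tempfile(fileext = ".mtx")
  pt <- withr::local_tempfile(fileext = ".mtx")
  write_network_mtx(net, pa, pt, min_weight = 0)
  a_back <- as.matrix(Matrix::readMM(pa))
  t_back <- as.matrix(Matrix::readMM(pt))
  expect_equal(a_back, unname(net$adjacency), tolerance = 1e-9)
  expect_equal(t_back, unname(net$tom), tolerance = 1e-9)
})
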