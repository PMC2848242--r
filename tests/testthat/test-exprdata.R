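panel_sim <- function(seed = 1, n_genes = 120) {
  gen_expression(sim_config(seed = seed, n_genes = n_genes,
                            cluster_specs = list(list(size = 20, latent_r = 0.9,
                                                      preferred_tissue = "tissue2",
                                                      fold = 2))),
                 mode = "panel")
}

test_that("expression tables round-trip through TSV", {
  ge <- panel_sim()
  dir <- withr::local_tempdir()
  paths <- write_expression(ge$expr, dir, "toy")
  back <- read_expression(paths["values"], paths["metadata"],
                          paths["present"], intensity_path = paths["intensity"])
  expect_equal(back$values, ge$expr$values)
  expect_equal(back$present, ge$expr$present)
  expect_equal(back$control_median, ge$expr$control_median)
  expect_equal(back$metadata$tissue, ge$expr$metadata$tissue)
})

test_that("readers catch duplicate genes and missing metadata", {
  dir <- withr::local_tempdir()
  vp <- file.path(dir, "v.tsv"); mp <- file.path(dir, "m.tsv")
  writeLines(c("gene\ts1\ts2", "g1\t1\t2", "g1\t3\t4"), vp)
  writeLines(c("sample\ttissue", "s1\tliver", "s2\theart"), mp)
  expect_error(read_expression(vp, mp), "duplicate gene")
  writeLines(c("gene\ts1\ts2", "g1\t1\t2", "g2\t3\t"), vp)
  writeLines(c("sample\ttissue", "s1\tliver"), mp)
  expect_error(read_expression(vp, mp), "without metadata")
  # a missing cell stays missing, the rest intact
  writeLines(c("sample\ttissue", "s1\tliver", "s2\theart"), mp)
  m <- read_expression(vp, mp)
  expect_true(is.na(m$values["g2", "s2"]))
  expect_equal(m$values["g2", "s1"], 3)
})

test_that("panel filter applies the 250-unit rule with inclusive boundary", {
  vals <- rbind(g_low = c(249, 240), g_edge = c(250, 10), g_ctrl = c(260, 10))
  colnames(vals) <- c("s1", "s2")
  meta <- data.frame(sample = c("s1", "s2"), tissue = c("a", "b"))
  m <- new_expression_matrix(vals, meta,
                             control_median = c(s1 = 260, s2 = 50))
  f <- filter_panel(m, filter_config(min_intensity = 250))
  # g_low: below 250 everywhere; g_edge: exactly 250, above control 260? no ->
  # s1 control is 260 so g_edge (250) fails "above control" but g_ctrl (260)
  # equals the control median and must fail the strict inequality too
  expect_equal(nrow(f$values), 0)
  m2 <- new_expression_matrix(vals, meta, control_median = c(s1 = 100, s2 = 50))
  f2 <- filter_panel(m2, filter_config(min_intensity = 250))
  expect_setequal(rownames(f2$values), c("g_edge", "g_ctrl"))
})

test_that("time-series filter evaluates its two conditions independently", {
  vals <- rbind(g1 = c(0.5, 0.2), g2 = c(0.1, 0.1), g3 = c(1.0, 1.0))
  colnames(vals) <- c("s1", "s2")
  meta <- data.frame(sample = c("s1", "s2"), time = c(1, 1), diet = c("AD", "RS"))
  intens <- rbind(g1 = c(150, 20), g2 = c(200, 200), g3 = c(20, 30))
  pv <- rbind(g1 = c(0.9, 0.049), g2 = c(0.06, 0.07), g3 = c(0.01, 0.01))
  m <- new_expression_matrix(vals, meta, pvalues = pv, intensity = intens,
                             control_median = c(s1 = 50, s2 = 50),
                             kind = "log2ratio")
  f <- filter_timeseries(m, filter_config(min_intensity = 150))
  # g1 passes: intensity 150 at s1, p 0.049 at s2 (different sample-points)
  # g2 fails: min p 0.06; g3 fails: intensity never reaches 150
  expect_equal(rownames(f$values), "g1")
})

test_that("filters agree with a brute-force row scan and are idempotent", {
  ge <- panel_sim(seed = 9, n_genes = 200)
  m <- ge$expr
  cfg <- filter_config(min_intensity = 250)
  f <- filter_panel(m, cfg)
  ctrl <- m$control_median[colnames(m$intensity)]
  keep <- vapply(rownames(m$values), function(g) {
    any(m$present[g, ] & m$intensity[g, ] > ctrl & m$intensity[g, ] >= 250)
  }, logical(1))
  expect_identical(rownames(f$values), rownames(m$values)[keep])
  expect_identical(rownames(filter_panel(f, cfg)$values), rownames(f$values))
})

ts_sim <- function(seed, n_genes = 100, fold = 1.8, sigma = 0.3, n_reps = 5) {
  gen_expression(
    sim_config(seed = seed, n_genes = n_genes, n_reps = n_reps,
               noise_sd = sigma,
               diet_effect_specs = list(list(genes = seq_len(n_genes %/% 2),
                                             times = c(1, 14), fold = fold,
                                             direction = "down"))),
    mode = "timeseries")
}

test_that("diet contrasts recover a planted 1.8-fold effect", {
  # Monte-Carlo parameter recovery at n = 5 per cell
  ests <- vapply(1:40, function(sd) {
    ge <- ts_sim(seed = 100 + sd, n_genes = 10, sigma = 0.2)
    dt <- diet_within_time(ge$expr, sprintf("g%05d", 1:5))
    mean(dt$estimate[dt$time %in% c(1, 14)])
  }, numeric(1))
  expect_lt(abs(mean(ests) - (-log2(1.8))), 0.05)
})

test_that("diet model handles degenerate and null cases", {
  vals <- matrix(c(1, 2, 1, 2, 1, 2, 1, 2), 1,
                 dimnames = list("g1", sprintf("s%d", 1:8)))
  meta <- data.frame(sample = sprintf("s%d", 1:8),
                     time = rep(c(1, 14), each = 4),
                     diet = rep(c("AD", "AD", "RS", "RS"), 2))
  m <- new_expression_matrix(vals, meta, kind = "log2ratio")
  dt <- diet_within_time(m)
  # identical group means with nonzero pooled variance: estimate 0, p = 1
  expect_equal(dt$estimate, c(0, 0))
  expect_equal(dt$p, c(1, 1))
  # single-gene BH over its tests maps the smallest p to itself at m = 1
  one <- dt[1, ]
  expect_equal(bh_adjust(one$p), one$p)
  # empty cell: not estimable, not an error
  meta2 <- meta; meta2$diet[5:8] <- "AD"
  m2 <- new_expression_matrix(vals, meta2, kind = "log2ratio")
  dt2 <- diet_within_time(m2)
  expect_true(is.na(dt2$estimate[dt2$time == 14]))
})

test_that("diet estimates are exact under zero noise", {
  ge <- ts_sim(seed = 7, n_genes = 20, sigma = 0)
  dt <- diet_within_time(ge$expr, "g00001")
  # exact up to the 4-decimal precision of the emitted ratio table
  expect_equal(dt$estimate[dt$time == 1], -log2(1.8), tolerance = 1e-4)
  expect_equal(dt$estimate[dt$time == 28], 0, tolerance = 1e-12)
})

test_that("BH-adjusted p-values are monotone in the raw ordering", {
  ge <- ts_sim(seed = 8, n_genes = 60)
  dt <- diet_within_time(ge$expr)
  dt <- dt[!is.na(dt$p), ]
  o <- order(dt$p)
  expect_true(all(diff(dt$p_adj[o]) >= -1e-12))
  expect_true(all(dt$p_adj >= dt$p - 1e-12))
})

test_that("mean cluster fold returns 2^(mean log2 difference)", {
  vals <- matrix(rep(c(1, 0), each = 2), 2, 4, byrow = TRUE,
                 dimnames = list(c("g1", "g2"), sprintf("s%d", 1:4)))
  vals["g2", ] <- c(1, 1, 0, 0)
  vals["g1", ] <- c(1, 1, 0, 0)
  meta <- data.frame(sample = sprintf("s%d", 1:4), time = c(1, 14, 1, 14),
                     diet = c("AD", "AD", "RS", "RS"))
  m <- new_expression_matrix(vals, meta, kind = "log2ratio")
  expect_equal(mean_cluster_fold(m, c("g1", "g2"), c(1, 14), c("AD", "RS")), 2)
  expect_error(mean_cluster_fold(m, c("g1"), 99), "no data")
  expect_error(mean_cluster_fold(m, character(0), 1), "empty")
  # planted 1.8-fold at simulation scale
  ge <- ts_sim(seed = 5, n_genes = 400, sigma = 0.3)
  fold <- mean_cluster_fold(ge$expr, sprintf("g%05d", 1:200), c(1, 14),
                            c("AD", "RS"))
  expect_lt(abs(fold - 1.8), 0.1)
})
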