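test_that("configuration invariants are enforced", {
  expect_error(sim_config(plant_specs = list(list(pwm_ids = "M1", rate = 1.2,
                                                  gap_range = c(20, 50)))),
               "rate")
  expect_error(sim_config(plant_specs = list(list(pwm_ids = "M1", rate = 0.5,
                                                  gap_range = c(20, 300)))),
               "gap range")
  expect_error(sim_config(n_genes = 10,
                          cluster_specs = list(list(size = 20, latent_r = 0.9))),
               "cluster size")
})

test_that("promoter generation is seed-deterministic with exact planted truth", {
  lib <- gen_pwm_library(3, c(8, 10), seed = 51)
  spec <- list(n_fg = 30, n_bg = 20, length = 1100, gc = 0.5,
               masked_fraction = 0.1)
  plant <- list(list(pwm_ids = c("M0001", "M0002"), rate = 0.5,
                     gap_range = c(20, 250), ordered = TRUE))
  p1 <- gen_promoters(lib, spec, plant, seed = 52)
  p2 <- gen_promoters(lib, spec, plant, seed = 52)
  expect_identical(p1, p2)
  # every truth record points at a real promoter and an exact consensus word
  for (i in seq_len(nrow(p1$truth))) {
    rec <- p1$truth[i, ]
    s <- toupper(p1$fg[[rec$promoter]])
    ids <- strsplit(rec$pwms, ",")[[1]]
    starts <- as.integer(strsplit(rec$starts, ",")[[1]])
    for (j in seq_along(ids)) {
      word <- pwm_consensus(lib[[ids[j]]])
      expect_equal(substr(s, starts[j], starts[j] + nchar(word) - 1L), word)
    }
    # recorded gaps are consistent with the recorded starts
    gaps <- as.integer(strsplit(rec$gaps, ",")[[1]])
    widths <- vapply(ids, function(id) lib[[id]]$width, integer(1))
    expect_equal(unname(starts[-1] - (starts[-length(starts)] + widths[-length(widths)])),
                 gaps)
  }
})

test_that("plant rate 1 puts a perfect-similarity site in every promoter", {
  lib <- gen_pwm_library(1, c(8, 8), seed = 53)
  p <- gen_promoters(lib, list(n_fg = 10, n_bg = 0, length = 300, gc = 0.5,
                               masked_fraction = 0),
                     list(list(pwm_ids = "M0001", rate = 1,
                               gap_range = c(0, 0), ordered = FALSE)),
                     seed = 54)
  for (s in p$fg) {
    h <- scan_pwm(lib[[1]], s)
    expect_gte(max(h$matrix_sim), 1 - 1e-12)
  }
})

test_that("masked fraction controls the lowercase content", {
  lib <- gen_pwm_library(1, c(6, 6), seed = 55)
  spec0 <- list(n_fg = 5, n_bg = 5, length = 500, gc = 0.5, masked_fraction = 0)
  p0 <- gen_promoters(lib, spec0, seed = 56)
  expect_false(any(grepl("[a-z]", c(p0$fg, p0$bg))))
  spec3 <- list(n_fg = 5, n_bg = 5, length = 500, gc = 0.5, masked_fraction = 0.3)
  p3 <- gen_promoters(lib, spec3, seed = 56)
  n_lower <- vapply(p3$bg, function(s) sum(grepl("[a-z]",
                                                 strsplit(s, "")[[1]])), 0)
  expect_true(all(n_lower == 150))
})

test_that("promoter length must accommodate the planted span", {
  lib <- gen_pwm_library(2, c(10, 10), seed = 57)
  expect_error(
    gen_promoters(lib, list(n_fg = 2, n_bg = 0, length = 100, gc = 0.5,
                            masked_fraction = 0),
                  list(list(pwm_ids = c("M0001", "M0002"), rate = 1,
                            gap_range = c(200, 250), ordered = TRUE)),
                  seed = 58),
    "span")
})

test_that("expression generation reproduces itself and its planted clusters", {
  sim <- sim_config(seed = 61, n_genes = 150, intensity_floor = 0.01,
                    cluster_specs = list(list(size = 25, latent_r = 1,
                                              preferred_tissue = NULL)))
  g1 <- gen_expression(sim, "panel")
  g2 <- gen_expression(sim, "panel")
  expect_identical(g1$expr$values, g2$expr$values)
  # latent_r = 1: planted pairwise correlations are 1 up to intensity rounding
  r <- cor(t(log2(g1$expr$values[g1$truth$clusters[[1]], ])))
  expect_true(all(r > 1 - 1e-4))
})

test_that("within-cluster correlation tracks latent_r across seeds", {
  rs <- vapply(1:20, function(sd) {
    sim <- sim_config(seed = 700 + sd, n_genes = 60,
                      cluster_specs = list(list(size = 50, latent_r = 0.95)))
    ge <- gen_expression(sim, "panel")
    r <- cor(t(log2(ge$expr$values[ge$truth$clusters[[1]], ])))
    mean(r[upper.tri(r)])
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.95), 0.05)
})

test_that("tissue-preferential planting passes the 2-fold test by construction", {
  sim <- sim_config(seed = 62, n_genes = 100,
                    cluster_specs = list(list(size = 15, latent_r = 0.9,
                                              preferred_tissue = "tissue5",
                                              fold = 2)))
  ge <- gen_expression(sim, "panel")
  for (g in ge$truth$clusters[[1]]) {
    expect_true(tissue_preferential(ge$expr, g, "tissue5"))
  }
  expect_setequal(ge$truth$tissue_preferential, ge$truth$clusters[[1]])
})

test_that("annotation respects genome bounds and both strands", {
  expect_error(gen_annotation(10, 10 * 1300, seed = 63), "insufficient|length")
  ann <- gen_annotation(8, 8 * 1300 + 100, seed = 64, masked_fraction = 0.05)
  expect_setequal(unique(ann$tss$strand), c("+", "-"))
  tssrec <- data.frame(chrom = ann$tss$chrom,
                       tss = ifelse(ann$tss$strand == "+", ann$tss$start + 1L,
                                    ann$tss$end),
                       strand = ann$tss$strand, gene = ann$tss$gene,
                       stringsAsFactors = FALSE)
  proms <- extract_promoters(ann$genome, tssrec)
  expect_true(all(vapply(proms, function(p) nchar(p$seq), 1L) == 1100L))
  expect_false(any(vapply(proms, `[[`, TRUE, "clipped")))
  # minus-strand promoters are reverse-complemented genome slices
  minus <- proms[[which(tssrec$strand == "-")[1]]]
  i <- which(ann$tss$gene == minus$gene)
  slice <- substr(ann$genome[["chr1"]], tssrec$tss[i] - 99L, tssrec$tss[i] + 1000L)
  expect_equal(minus$seq, revcomp(slice))
})

test_that("FASTA and BED artifacts are byte-stable under a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  gen_annotation(3, 3 * 1300 + 50, seed = 65, masked_fraction = 0.1,
                 fasta_path = file.path(d1, "g.fa"),
                 bed_path = file.path(d1, "t.bed"))
  gen_annotation(3, 3 * 1300 + 50, seed = 65, masked_fraction = 0.1,
                 fasta_path = file.path(d2, "g.fa"),
                 bed_path = file.path(d2, "t.bed"))
  expect_identical(readLines(file.path(d1, "g.fa")),
                   readLines(file.path(d2, "g.fa")))
  expect_identical(readLines(file.path(d1, "t.bed")),
                   readLines(file.path(d2, "t.bed")))
  # soft-mask case survives the FASTA round trip
  back <- read_fasta(file.path(d1, "g.fa"))
  expect_true(any(grepl("[a-z]", back)))
})
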