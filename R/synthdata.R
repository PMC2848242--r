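#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate the
#' study design the pipeline targets: an 18-tissue expression panel and a
#' peripartal liver time series with 7 time points (days -65, -30, -14, +1,
#' +14, +28, +49 relative to parturition) under two diets.
#'
#' @param seed integer RNG seed; the same config yields byte-identical output
#' @param n_genes number of genes on the simulated array
#' @param n_tissues tissue-panel sample count (default 18)
#' @param timepoints time-point labels in days (default the 7 peripartal days)
#' @param diets diet labels (default "AD" ad libitum, "RS" restricted)
#' @param n_reps replicates (animals) per diet at each time point (default 5)
#' @param cluster_specs list of lists with fields `size`, `latent_r`,
#'   `preferred_tissue` (or NULL), `fold`
#' @param diet_effect_specs list of lists with fields `genes` (indices into
#'   the first cluster or gene ids), `times`, `fold`, `direction` ("down"
#'   means lower under the restricted diet)
#' @param promoter_specs list with `n_fg`, `n_bg`, `length` (default 1100),
#'   `gc`, `masked_fraction`
#' @param plant_specs list of lists with `pwm_ids`, `rate`, `gap_range`,
#'   `ordered`
#' @param noise_sd residual noise SD on the log2 scale (default 0.3)
#' @param intensity_floor lowest emitted panel intensity in fluorescence
#'   units (default 20), so low expressors sit in the filterable range
#' @return list of class `sim_config`
#' @export
sim_config <- function(seed = 1L, n_genes = 1000L, n_tissues = 18L,
                       timepoints = c(-65, -30, -14, 1, 14, 28, 49),
                       diets = c("AD", "RS"), n_reps = 5L,
                       cluster_specs = list(), diet_effect_specs = list(),
                       promoter_specs = list(n_fg = 100L, n_bg = 1000L,
                                             length = 1100L, gc = 0.5,
                                             masked_fraction = 0.1),
                       plant_specs = list(), noise_sd = 0.3,
                       intensity_floor = 20) {
  for (ps in plant_specs) {
    if (ps$rate < 0 || ps$rate > 1) stop_cfg("plant rate must be in [0,1]")
    if (min(ps$gap_range) < 0 || max(ps$gap_range) > 250)
      stop_cfg("gap range must lie within [0, 250]")
  }
  for (cs in cluster_specs) {
    if (cs$size > n_genes) stop_cfg("cluster size exceeds n_genes")
    if (cs$latent_r < 0 || cs$latent_r > 1) stop_cfg("latent_r must be in [0,1]")
  }
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 n_tissues = as.integer(n_tissues), timepoints = timepoints,
                 diets = diets, n_reps = as.integer(n_reps),
                 cluster_specs = cluster_specs,
                 diet_effect_specs = diet_effect_specs,
                 promoter_specs = promoter_specs, plant_specs = plant_specs,
                 noise_sd = noise_sd, intensity_floor = intensity_floor),
            class = "sim_config")
}

#' Generate a synthetic PWM library
#'
#' Each matrix has per-position counts summing to a constant depth and a
#' sharp consensus at most positions, so that planted consensus words score
#' a matrix similarity of 1 and scanning recovers them. Emulates a
#' vertebrate non-redundant scanning library at configurable size.
#'
#' @param n number of matrices
#' @param width_range inclusive width interval, e.g. `c(6, 12)`; widths >= 4
#' @param seed RNG seed
#' @param depth per-position count depth (default 100)
#' @param strong_fraction fraction of positions with a sharp (88%) dominant
#'   base; the rest are two-base degenerate positions. The default 1 mimics
#'   a false-positive-minimized scanning profile: degenerate positions
#'   carry so little information weight that they make random sequence pass
#'   the similarity thresholds at far higher rates than a curated minFP
#'   library exhibits.
#' @param path optional TRANSFAC flat file to write
#' @return `lsg_pwm_library`
#' @export
gen_pwm_library <- function(n, width_range = c(6, 12), seed = 1L,
                            depth = 100L, strong_fraction = 1, path = NULL) {
  if (length(width_range) != 2 || width_range[2] < width_range[1])
    stop_cfg("width_range is empty")
  if (width_range[1] < 4) stop_cfg("PWM widths must be >= 4")
  set.seed(seed)
  pwms <- list()
  for (i in seq_len(n)) {
    w <- sample_from(width_range[1]:width_range[2], 1L)
    counts <- matrix(0, 4L, w)
    strong <- stats::runif(w) < strong_fraction
    if (!any(strong)) strong[1] <- TRUE   # at least one informative position
    for (j in seq_len(w)) {
      dom <- sample(4L, 1L)
      if (strong[j]) {
        counts[, j] <- floor(depth * 0.04)
        counts[dom, j] <- depth - 3 * floor(depth * 0.04)
      } else {
        second <- sample_from(setdiff(1:4, dom), 1L)
        counts[, j] <- floor(depth * 0.1)
        counts[dom, j] <- floor(depth * 0.4)
        counts[second, j] <- depth - floor(depth * 0.4) - 2 * floor(depth * 0.1)
      }
    }
    id <- sprintf("M%04d", i)
    pwms[[id]] <- new_pwm(counts, id, sprintf("SYN_%04d", i))
  }
  lib <- structure(pwms, class = "lsg_pwm_library")
  if (!is.null(path)) write_transfac(lib, path)
  lib
}

#' Generate foreground and background promoter sets with planted motifs
#'
#' Background promoters are random sequence at the configured GC fraction.
#' Foreground promoters additionally carry planted motif instances: exact
#' consensus words of the named PWMs, optionally as ordered composites at a
#' controlled gap distance, at a per-promoter planting rate. A configurable
#' fraction of each promoter is soft-masked (lowercase). All planting is on
#' the forward strand; every planted instance is recorded in the returned
#' truth table.
#'
#' @param pwms `lsg_pwm_library` supplying consensus words
#' @param spec promoter spec list: `n_fg`, `n_bg`, `length`, `gc`,
#'   `masked_fraction`
#' @param plant_specs list of lists with `pwm_ids` (1..3 matrix ids),
#'   `rate`, `gap_range` (inclusive), `ordered`
#' @param seed RNG seed
#' @param max_retries retries when a planting collides with a previous one
#' @return list with `fg`, `bg` (named character vectors) and `truth`
#'   (data.frame: promoter, pwm ids, starts, gaps)
#' @export
gen_promoters <- function(pwms, spec, plant_specs = list(), seed = 1L,
                          max_retries = 50L) {
  set.seed(seed)
  L <- spec$length %||% 1100L
  words <- lapply(pwms, pwm_consensus)
  for (ps in plant_specs) {
    span <- sum(nchar(unlist(words[ps$pwm_ids]))) +
      (length(ps$pwm_ids) - 1L) * max(ps$gap_range)
    if (L < span) stop_cfg("promoter length %d below max planted span %d", L, span)
  }
  mk_bg <- function(n, prefix) {
    s <- vapply(seq_len(n), function(i) random_dna(L, spec$gc %||% 0.5),
                character(1))
    stats::setNames(s, sprintf("%s%04d", prefix, seq_len(n)))
  }
  fg <- mk_bg(spec$n_fg, "fg")
  bg <- mk_bg(spec$n_bg, "bg")
  truth <- list()
  occupied <- lapply(fg, function(x) integer(0))
  for (ps in plant_specs) {
    ws <- unlist(words[ps$pwm_ids])
    if (anyNA(names(ws)) || length(ws) != length(ps$pwm_ids))
      stop_cfg("plant spec names unknown PWM id")
    plant_in <- which(stats::runif(length(fg)) < ps$rate)
    for (i in plant_in) {
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        gaps <- if (length(ws) > 1)
          sample_from(ps$gap_range[1]:ps$gap_range[2], length(ws) - 1L, replace = TRUE)
        else integer(0)
        span <- sum(nchar(ws)) + sum(gaps)
        start1 <- sample(L - span + 1L, 1L)
        starts <- start1 + c(0L, cumsum(nchar(ws)[-length(ws)] + gaps))
        pos <- unlist(mapply(function(s, w) s:(s + nchar(w) - 1L), starts, ws,
                             SIMPLIFY = FALSE))
        if (!any(pos %in% occupied[[i]])) { ok <- TRUE; break }
      }
      if (!ok) stop_cfg("planting collision in promoter '%s' after %d retries",
                        names(fg)[i], max_retries)
      s <- fg[[i]]
      for (k in seq_along(ws)) {
        substr(s, starts[k], starts[k] + nchar(ws[k]) - 1L) <- ws[k]
      }
      fg[[i]] <- s
      occupied[[i]] <- c(occupied[[i]], pos)
      truth[[length(truth) + 1L]] <- data.frame(
        promoter = names(fg)[i],
        pwms = paste(ps$pwm_ids, collapse = ","),
        starts = paste(starts, collapse = ","),
        gaps = paste(gaps, collapse = ","),
        ordered = isTRUE(ps$ordered), stringsAsFactors = FALSE)
    }
  }
  mask <- function(s) {
    mf <- spec$masked_fraction %||% 0
    if (mf <= 0) return(s)
    n_mask <- round(mf * L)
    if (n_mask == 0) return(s)
    start <- sample(L - n_mask + 1L, 1L)
    repl <- tolower(substr(s, start, start + n_mask - 1L))
    paste0(substr(s, 1, start - 1L), repl, substr(s, start + n_mask, L))
  }
  # mask only outside planted instances is not guaranteed; background masking
  # can hide planted sites, which is exactly the masked/unmasked consistency
  # situation the enrichment filter handles. Foreground masking avoids the
  # planted windows so planted truth stays recoverable from the masked view.
  fg_masked <- vapply(seq_along(fg), function(i) {
    s <- fg[[i]]
    mf <- spec$masked_fraction %||% 0
    if (mf <= 0) return(s)
    n_mask <- round(mf * L)
    if (n_mask == 0) return(s)
    for (try in seq_len(50L)) {
      start <- sample(L - n_mask + 1L, 1L)
      if (!any(start:(start + n_mask - 1L) %in% occupied[[i]])) break
      start <- NA_integer_
    }
    if (is.na(start)) return(s)
    repl <- tolower(substr(s, start, start + n_mask - 1L))
    paste0(substr(s, 1, start - 1L), repl, substr(s, start + n_mask, L))
  }, character(1))
  names(fg_masked) <- names(fg)
  bg <- vapply(bg, mask, character(1))
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(promoter = character(0), pwms = character(0),
               starts = character(0), gaps = character(0),
               ordered = logical(0), stringsAsFactors = FALSE)
  list(fg = fg_masked, bg = bg, truth = truth)
}

#' Generate a synthetic expression dataset with planted structure
#'
#' Produces either an intensity panel over tissues or a log2-ratio time
#' series over (time, diet, replicate) samples, with planted co-expression
#' clusters, tissue-preferential genes, and diet effects, plus the
#' present/absent flags, per-spot significance p-values and negative-control
#' medians the filtering rules need.
#'
#' Cluster co-expression uses a latent-factor model on the log2 scale:
#' \eqn{x_g = \sqrt{\rho} z + \sqrt{1-\rho}\,\epsilon_g}, so the expected
#' pairwise Pearson correlation within a cluster equals \eqn{\rho}.
#'
#' @param sim a [sim_config()]
#' @param mode "panel" (tissues, raw intensities) or "timeseries" (log2
#'   ratios over time x diet x replicate)
#' @return list with `expr` (an `expression_matrix`), `truth` (cluster
#'   membership, tissue-preferential genes, diet effects)
#' @export
gen_expression <- function(sim, mode = c("panel", "timeseries")) {
  mode <- match.arg(mode)
  set.seed(derive_seed(sim$seed, if (mode == "panel") 11L else 12L))
  genes <- sprintf("g%05d", seq_len(sim$n_genes))
  if (mode == "panel") {
    samples <- sprintf("T%02d", seq_len(sim$n_tissues))
    meta <- data.frame(sample = samples,
                       tissue = paste0("tissue", seq_len(sim$n_tissues)),
                       stringsAsFactors = FALSE)
    n_s <- sim$n_tissues
  } else {
    meta <- expand.grid(replicate = seq_len(sim$n_reps), diet = sim$diets,
                        time = sim$timepoints, stringsAsFactors = FALSE)
    meta <- meta[, c("time", "diet", "replicate")]
    meta$sample <- sprintf("t%+03d_%s_r%d", meta$time, meta$diet, meta$replicate)
    n_s <- nrow(meta)
  }
  # baseline log2 expression: gene-specific level + noise
  base_level <- stats::rnorm(sim$n_genes, mean = if (mode == "panel") 9 else 0,
                             sd = if (mode == "panel") 1.5 else 0)
  x <- matrix(stats::rnorm(sim$n_genes * n_s, sd = 1), sim$n_genes, n_s)
  cluster_members <- list()
  for (ci in seq_along(sim$cluster_specs)) {
    cs <- sim$cluster_specs[[ci]]
    idx <- if (!is.null(cs$genes)) cs$genes else {
      used <- unlist(cluster_members)
      setdiff(seq_len(sim$n_genes), used)[seq_len(cs$size)]
    }
    z <- stats::rnorm(n_s)
    rho <- cs$latent_r
    x[idx, ] <- sqrt(rho) * matrix(z, length(idx), n_s, byrow = TRUE) +
      sqrt(1 - rho) * x[idx, , drop = FALSE]
    cluster_members[[ci]] <- idx
  }
  log2expr <- base_level + x * if (mode == "panel") 1 else sim$noise_sd

  pref_genes <- character(0)
  if (mode == "panel") {
    values <- round(2^log2expr, 2)
    values[values < sim$intensity_floor] <- sim$intensity_floor
    for (ci in seq_along(sim$cluster_specs)) {
      cs <- sim$cluster_specs[[ci]]
      if (is.null(cs$preferred_tissue)) next
      ti <- match(cs$preferred_tissue, meta$tissue)
      if (is.na(ti)) stop_cfg("unknown preferred tissue '%s'", cs$preferred_tissue)
      idx <- cluster_members[[ci]]
      # force the preference exactly: preferred tissue sits fold x the max of
      # the other tissues (boundary inclusive downstream)
      other_max <- apply(values[idx, -ti, drop = FALSE], 1L, max)
      values[idx, ti] <- (cs$fold %||% 2) * other_max
      pref_genes <- c(pref_genes, genes[idx])
    }
  } else {
    diet_truth <- list()
    for (ds in sim$diet_effect_specs) {
      idx <- if (is.character(ds$genes)) match(ds$genes, genes) else ds$genes
      eff <- log2(ds$fold) * if (identical(ds$direction, "down")) -1 else 1
      cols <- which(meta$time %in% ds$times & meta$diet == sim$diets[2])
      log2expr[idx, cols] <- log2expr[idx, cols] + eff
      diet_truth[[length(diet_truth) + 1L]] <- data.frame(
        gene = genes[idx], times = paste(ds$times, collapse = ","),
        log2_effect = eff, stringsAsFactors = FALSE)
    }
    values <- round(log2expr, 4)
  }

  # plumbing for the filters: present flags, intensities, control medians,
  # per-spot significance p-values (time series)
  present <- matrix(stats::runif(sim$n_genes * n_s) < 0.98, sim$n_genes, n_s)
  ctrl_median <- stats::setNames(rep(50, n_s), meta$sample)
  pvals <- NULL
  intensity <- values
  if (mode == "timeseries") {
    intensity <- round(2^(8 + stats::rnorm(sim$n_genes * n_s, sd = 1)), 1)
    dim(intensity) <- c(sim$n_genes, n_s)
    pvals <- matrix(stats::runif(sim$n_genes * n_s), sim$n_genes, n_s)
    # genes with real signal get at least one significant spot
    sig <- abs(values) > 0.2
    pvals[sig] <- pvals[sig] * 0.05
  }
  dimnames(values) <- list(genes, meta$sample)
  dimnames(intensity) <- list(genes, meta$sample)
  dimnames(present) <- list(genes, meta$sample)
  if (!is.null(pvals)) dimnames(pvals) <- list(genes, meta$sample)

  expr <- new_expression_matrix(values = values, metadata = meta,
                                present = present, pvalues = pvals,
                                intensity = intensity,
                                control_median = ctrl_median,
                                kind = if (mode == "panel") "intensity" else "log2ratio")
  truth <- list(
    clusters = lapply(cluster_members, function(i) genes[i]),
    tissue_preferential = pref_genes,
    diet_effects = if (mode == "timeseries" && length(sim$diet_effect_specs))
      do.call(rbind, diet_truth) else NULL)
  list(expr = expr, truth = truth)
}

#' Generate a synthetic soft-masked genome with TSS annotation
#'
#' Places one TSS per gene, spaced and offset so that every promoter window
#' \[−1000, +100\] lies inside the contig, with strands alternating between
#' + and −. Writes FASTA and BED6 when paths are given. BED rows are 0-based
#' half-open single-base intervals at the TSS, so `chromStart + 1` is the
#' 1-based TSS on the + strand and `chromEnd` on the − strand.
#'
#' @param n_genes number of genes
#' @param genome_len contig length; must exceed `n_genes * 1300`
#' @param seed RNG seed
#' @param gc GC fraction
#' @param masked_fraction fraction of the contig soft-masked (lowercase)
#' @param fasta_path,bed_path optional output paths
#' @return list with `genome` (named character), `tss` (data.frame: chrom,
#'   start, end, gene, score, strand)
#' @export
gen_annotation <- function(n_genes, genome_len, seed = 1L, gc = 0.5,
                           masked_fraction = 0, fasta_path = NULL,
                           bed_path = NULL) {
  if (genome_len <= n_genes * 1300) {
    stop_cfg("genome length %d insufficient for %d genes (need > %d)",
             genome_len, n_genes, n_genes * 1300)
  }
  set.seed(seed)
  g <- random_dna(genome_len, gc)
  if (masked_fraction > 0) {
    n_mask <- round(masked_fraction * genome_len)
    start <- sample(genome_len - n_mask + 1L, 1L)
    g <- paste0(substr(g, 1, start - 1L),
                tolower(substr(g, start, start + n_mask - 1L)),
                substr(g, start + n_mask, genome_len))
  }
  # slot i occupies [1300(i-1)+1, 1300 i]; TSS placed so [-1000,+100] fits
  strand <- rep(c("+", "-"), length.out = n_genes)
  tss <- integer(n_genes)
  for (i in seq_len(n_genes)) {
    lo <- 1300L * (i - 1L) + 1L
    tss[i] <- if (strand[i] == "+") lo + 1000L + sample(100L, 1L) - 1L
              else lo + 100L + sample(100L, 1L) - 1L
  }
  bed <- data.frame(chrom = "chr1", start = tss - 1L, end = tss,
                    gene = sprintf("g%05d", seq_len(n_genes)), score = 0L,
                    strand = strand, stringsAsFactors = FALSE)
  genome <- c(chr1 = g)
  if (!is.null(fasta_path)) write_fasta(genome, fasta_path)
  if (!is.null(bed_path)) {
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  list(genome = genome, tss = bed)
}

#' Write named sequences to FASTA
#' @param seqs named character vector
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 70L)
  invisible(path)
}

#' Read FASTA preserving soft-mask case
#' @param path FASTA path
#' @return named character vector
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(s), names(s))
}
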