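#' Pipeline configuration
#'
#' Collects input paths, stage configurations, the RNG seed and the output
#' directory for an end-to-end run.
#'
#' @param expression_path values TSV (tissue panel or time series)
#' @param metadata_path sample metadata TSV
#' @param genome_path soft-masked genome FASTA
#' @param tss_path TSS BED6 (background promoter universe)
#' @param pwm_path TRANSFAC flat matrix file
#' @param seed_genes character vector of seed (lineage-specific) gene ids
#' @param outdir output directory
#' @param seed RNG seed
#' @param filter a [filter_config()]
#' @param cluster a [cluster_config()]
#' @param match a [match_config()]
#' @param denovo a [denovo_config()]
#' @param hub a [hub_config()]
#' @param composite_alpha BH-adjusted significance level for composites
#' @param d_min_classes composite minimum-gap classes
#' @param present_path,pvalues_path,intensity_path optional parallel TSVs
#' @param kind expression kind ("intensity" or "log2ratio")
#' @param run_denovo,run_network toggles for the slow stages
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(expression_path, metadata_path, genome_path,
                            tss_path, pwm_path, seed_genes, outdir,
                            seed = 1L,
                            filter = filter_config(min_intensity = 250),
                            cluster = cluster_config(),
                            match = match_config(),
                            denovo = denovo_config(),
                            hub = hub_config(),
                            composite_alpha = 0.1,
                            d_min_classes = c(20L, 50L, 100L),
                            present_path = NULL, pvalues_path = NULL,
                            intensity_path = NULL,
                            kind = "intensity",
                            run_denovo = TRUE, run_network = TRUE) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Validate a pipeline configuration without running it
#'
#' @param config a [pipeline_config()]
#' @return character vector of issues (empty when the config is clean)
#' @export
validate_pipeline <- function(config) {
  issues <- character(0)
  for (f in c("expression_path", "metadata_path", "genome_path", "tss_path",
              "pwm_path")) {
    p <- config[[f]]
    if (is.null(p) || !file.exists(p)) {
      issues <- c(issues, sprintf("%s: file not found (%s)", f, p %||% "NULL"))
    }
  }
  cl <- config$cluster
  if (cl$avg_r > cl$seed_r) issues <- c(issues, "avg_r exceeds seed_r")
  if (any(config$d_min_classes > 250)) {
    issues <- c(issues, "composite d_min exceeds the 250 bp maximum gap")
  }
  if (config$composite_alpha <= 0 || config$composite_alpha > 1) {
    issues <- c(issues, "composite alpha outside (0, 1]")
  }
  if (!length(config$seed_genes)) issues <- c(issues, "no seed genes given")
  issues
}

log_stage <- function(fmt, ...) {
  message(sprintf("[lsgpipe %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

#' Run the full inference pipeline
#'
#' Stages: read and filter expression -> seed-based clustering -> promoter
#' extraction (masked and unmasked views) -> PWM scanning -> single-TFBS
#' and composite over-representation -> de novo motif discovery and
#' matching -> weighted co-expression network with hub genes. Intermediate
#' artifacts are written under `config$outdir`; rerunning with the same
#' config and seed reproduces them exactly.
#'
#' @param config a [pipeline_config()]
#' @return list of class `run_report`
#' @export
run_lsg_pipeline <- function(config) {
  issues <- validate_pipeline(config)
  if (length(issues)) {
    stop_cfg("invalid pipeline config:\n  - %s", paste(issues, collapse = "\n  - "))
  }
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed, stages = list())

  log_stage("stage filter: reading %s", config$expression_path)
  expr <- read_expression(config$expression_path, config$metadata_path,
                          config$present_path, config$pvalues_path,
                          config$intensity_path, kind = config$kind)
  filtered <- if (config$kind == "log2ratio" && !is.null(expr$pvalues)) {
    filter_timeseries(expr, config$filter)
  } else {
    filter_panel(expr, config$filter)
  }
  report$stages$filter <- list(n_in = nrow(expr$values),
                               n_out = nrow(filtered$values))
  log_stage("stage filter: %d of %d genes retained",
            nrow(filtered$values), nrow(expr$values))

  log_stage("stage cluster: %d seed genes", length(config$seed_genes))
  clusters <- seed_clusters(filtered$values, config$seed_genes,
                            config$cluster, overlap = "keep-largest")
  write_clusters(clusters, filtered$values,
                 file.path(outdir, "clusters.tsv"), config$cluster)
  report$stages$cluster <- lapply(clusters, function(cl) {
    list(size = length(cl$members), seeds = length(cl$seeds),
         avg_r = cl$avg_r, degenerate = cl$warning_flag)
  })

  log_stage("stage promoters: extracting windows")
  genome <- read_fasta(config$genome_path)
  tss <- read_tss(config$tss_path)
  background <- build_background(tss, genome)
  set.seed(config$seed)
  pwms <- parse_transfac(config$pwm_path)

  report$stages$enrichment <- list()
  report$stages$denovo <- list()
  for (ci in seq_along(clusters)) {
    cl <- clusters[[ci]]
    recs <- tss[tss$gene %in% cl$members, , drop = FALSE]
    if (nrow(recs) < 2) next
    cluster_prom <- extract_promoters(genome, recs)
    cl_masked <- promoter_strings(cluster_prom, "masked")
    cl_unmasked <- promoter_strings(cluster_prom, "unmasked")
    bg_masked <- promoter_strings(background, "masked")

    log_stage("stage scan: cluster %d (%d promoters) vs %d background",
              ci, length(cl_masked), length(bg_masked))
    hits_cl <- scan_promoters(pwms, cl_masked, config$match)
    hits_cl_un <- scan_promoters(pwms, cl_unmasked, config$match)
    hits_bg <- scan_promoters(pwms, bg_masked, config$match)
    write_hits(hits_cl, file.path(outdir, sprintf("hits_cluster%d.tsv", ci)))

    single <- single_tfbs_enrichment(
      presence_map(hits_cl, names(cl_masked)),
      presence_map(hits_bg, names(bg_masked)),
      alpha = config$composite_alpha)
    pairs <- composite_analysis(hits_cl, hits_cl_un, hits_bg,
                                length(cl_masked), length(bg_masked),
                                arity = 2L, d_min_classes = config$d_min_classes,
                                alpha = config$composite_alpha)
    triplets <- composite_analysis(hits_cl, hits_cl_un, hits_bg,
                                   length(cl_masked), length(bg_masked),
                                   arity = 3L, d_min_classes = config$d_min_classes,
                                   alpha = config$composite_alpha)
    utils::write.table(pairs, file.path(outdir, sprintf("pairs_cluster%d.tsv", ci)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$stages$enrichment[[ci]] <- list(
      single_significant = sum(single$significant, na.rm = TRUE),
      pair_keys = nrow(pairs), pair_significant = sum(pairs$significant, na.rm = TRUE),
      triplet_keys = if (is.null(triplets)) 0L else nrow(triplets),
      triplet_significant = if (is.null(triplets)) 0L
        else sum(triplets$significant, na.rm = TRUE))

    if (config$run_denovo) {
      log_stage("stage denovo: cluster %d", ci)
      bg_for_denovo <- promoter_strings(
        background[setdiff(names(background), cl$members)], "unmasked")
      dn_cfg <- config$denovo
      dn_cfg$seed <- derive_seed(config$seed, 100L + ci)
      motifs <- discover_all(cl_unmasked, bg_for_denovo, dn_cfg)
      write_meme(motifs, file.path(outdir, sprintf("denovo_cluster%d.meme", ci)))
      mm <- match_motifs(motifs[1], pwms, seed = derive_seed(config$seed, 200L + ci))
      report$stages$denovo[[ci]] <- list(
        n_motifs = length(motifs),
        best_width = motifs[[1]]$width,
        best_objective = motifs[[1]]$objective,
        best_match = mm$target[which.min(mm$p)],
        best_match_p = min(mm$p))
    }
  }

  if (config$run_network && length(clusters)) {
    log_stage("stage network: cluster 1 (%d genes)",
              length(clusters[[1]]$members))
    vals <- filtered$values[clusters[[1]]$members, , drop = FALSE]
    net <- power_adjacency(vals, config$hub$beta)
    net <- tom_similarity(net)
    net <- detect_modules(net, config$hub)
    gs <- if (config$kind == "log2ratio") {
      gene_significance(diet_within_time(filtered, clusters[[1]]$members))
    } else {
      stats::setNames(rep(Inf, length(net$genes)), net$genes)
    }
    hubs <- tryCatch(hub_genes(net, gs, config$hub),
                     error = function(e) NULL)
    write_edges(net, file.path(outdir, "network_edges.tsv"))
    report$stages$network <- list(
      beta = net$beta, n_modules = length(setdiff(unique(net$modules), 0L)),
      module_sizes = as.integer(table(net$modules[net$modules > 0])),
      hubs = if (is.null(hubs)) character(0) else hubs$gene)
  }

  report$config_digest <- digest_config(config)
  class(report) <- "run_report"
  saveRDS_free_report(report, file.path(outdir, "report.json"))
  report
}

# JSON report keeps the deliverable text-only
saveRDS_free_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

digest_config <- function(config) {
  s <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 2147483647
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("lsgpipe run report (seed %s)\n", x$seed))
  if (!is.null(x$stages$filter)) {
    cat(sprintf("  filter: %d -> %d genes\n", x$stages$filter$n_in,
                x$stages$filter$n_out))
  }
  for (ci in seq_along(x$stages$cluster)) {
    cl <- x$stages$cluster[[ci]]
    cat(sprintf("  cluster %d: %d members (%d seeds), avg r %.3f\n",
                ci, cl$size, cl$seeds, cl$avg_r))
  }
  for (ci in seq_along(x$stages$enrichment)) {
    e <- x$stages$enrichment[[ci]]
    if (is.null(e)) next
    cat(sprintf("  enrichment %d: %d significant single, %d/%d significant pairs\n",
                ci, e$single_significant, e$pair_significant, e$pair_keys))
  }
  if (!is.null(x$stages$network)) {
    cat(sprintf("  network: %d module(s); hubs: %s\n",
                x$stages$network$n_modules,
                paste(x$stages$network$hubs, collapse = ", ")))
  }
  invisible(x)
}
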