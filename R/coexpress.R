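#' Clustering configuration
#'
#' @param seed_r correlation threshold for seed grouping and cluster growth
#'   (default 0.90)
#' @param avg_r minimum average pairwise correlation after adjustment
#'   (default 0.75)
#' @param fold tissue-preferentiality ratio (default 2)
#' @param min_overlap minimum pairwise-complete observations for a defined
#'   correlation (default 3)
#' @return list of class `cluster_config`
#' @export
cluster_config <- function(seed_r = 0.90, avg_r = 0.75, fold = 2,
                           min_overlap = 3L) {
  if (!(avg_r > 0 && avg_r <= seed_r && seed_r <= 1))
    stop_cfg("need 0 < avg_r <= seed_r <= 1")
  if (fold < 1) stop_cfg("fold must be >= 1")
  structure(list(seed_r = seed_r, avg_r = avg_r, fold = fold,
                 min_overlap = as.integer(min_overlap)),
            class = "cluster_config")
}

#' Pairwise Pearson correlation with pairwise-complete observations
#'
#' Correlations with fewer than `min_overlap` complete pairs, or with zero
#' variance in either vector, are undefined and reported as NA.
#'
#' @param x numeric vector, or a genes x samples matrix (rows correlated)
#' @param y numeric vector (ignored when `x` is a matrix)
#' @param min_overlap minimum complete pairs (default 3)
#' @return scalar r, or a symmetric correlation matrix
#' @export
pearson <- function(x, y = NULL, min_overlap = 3L) {
  if (is.matrix(x)) {
    r <- suppressWarnings(stats::cor(t(x), use = "pairwise.complete.obs"))
    n_ok <- crossprod(!is.na(t(x)))
    r[n_ok < min_overlap] <- NA
    return(r)
  }
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_overlap) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok])
}

#' Group seed genes and pick representatives
#'
#' Seeds are grouped by single linkage at `r >= seed_r` (the transitive
#' closure of the threshold graph); seeds correlated with no other seed are
#' self-represented. Each group's representative is its medoid: the seed
#' with the highest mean correlation to the rest of the group, ties broken
#' by the lexicographically smallest id.
#'
#' @param seed_profiles numeric matrix, one row per seed gene
#' @param cfg a [cluster_config()]
#' @return data.frame with columns seed, group, representative
#' @export
dedupe_seeds <- function(seed_profiles, cfg = cluster_config()) {
  ids <- rownames(seed_profiles)
  if (is.null(ids) || length(ids) < 1) stop_cfg("need named seed profiles")
  n <- length(ids)
  r <- pearson(seed_profiles, min_overlap = cfg$min_overlap)
  adj <- !is.na(r) & r >= cfg$seed_r
  diag(adj) <- TRUE
  # connected components by label propagation
  grp <- seq_len(n)
  repeat {
    new <- vapply(seq_len(n), function(i) min(grp[adj[i, ]]), numeric(1))
    if (identical(new, grp)) break
    grp <- new
  }
  rep_of <- vapply(split(seq_len(n), grp), function(members) {
    if (length(members) == 1) return(ids[members])
    meanr <- vapply(members, function(i) {
      mean(r[i, setdiff(members, i)], na.rm = TRUE)
    }, numeric(1))
    cand <- ids[members][meanr == max(meanr)]
    sort(cand)[1]
  }, character(1))
  data.frame(seed = ids, group = match(grp, sort(unique(grp))),
             representative = rep_of[as.character(grp)],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Grow a co-expression cluster around a representative seed
#'
#' Members are the representative plus every gene in the matrix whose
#' correlation with the representative reaches `seed_r`. Genes from the
#' seed set that meet the threshold are flagged as seeds of the cluster.
#'
#' @param values genes x samples numeric matrix (rownames gene ids)
#' @param representative gene id present in `values`
#' @param cfg a [cluster_config()]
#' @param seed_ids ids of the full seed set (default: just the representative)
#' @return object of class `gene_cluster`: list with `members`, `seeds`,
#'   `representative`, `avg_r`, `warning_flag`
#' @export
grow_cluster <- function(values, representative, cfg = cluster_config(),
                         seed_ids = representative) {
  if (!representative %in% rownames(values))
    stop_cfg("representative '%s' not in matrix (filtered out upstream?)",
             representative)
  rp <- values[representative, ]
  r <- apply(values, 1L, pearson, y = rp, min_overlap = cfg$min_overlap)
  members <- sort(unique(c(representative,
                           rownames(values)[!is.na(r) & r >= cfg$seed_r])))
  seeds <- sort(unique(c(representative, intersect(seed_ids, members))))
  cl <- structure(list(members = members, seeds = seeds,
                       representative = representative,
                       avg_r = avg_pairwise_r(values, members, cfg),
                       warning_flag = FALSE, preferred_tissue = NULL),
                  class = "gene_cluster")
  cl
}

#' Average pairwise correlation among a set of genes
#' @param values genes x samples matrix
#' @param members gene ids
#' @param cfg a [cluster_config()]
#' @return mean of the off-diagonal pairwise correlations (NA pairs dropped);
#'   NA for fewer than 2 members
#' @export
avg_pairwise_r <- function(values, members, cfg = cluster_config()) {
  if (length(members) < 2) return(NA_real_)
  r <- pearson(values[members, , drop = FALSE], min_overlap = cfg$min_overlap)
  mean(r[upper.tri(r)], na.rm = TRUE)
}

#' Adjust a cluster to reach the average-correlation threshold
#'
#' Greedily removes the non-seed member with the lowest mean correlation to
#' the rest of the cluster (ties broken by removing the lexicographically
#' last id) until the average pairwise correlation reaches
#' `avg_r`. Seeds are never removed; if only seeds remain and the threshold
#' is still not met, the seeds-only cluster is returned with `warning_flag`
#' set.
#'
#' @param cluster a `gene_cluster`
#' @param values genes x samples matrix
#' @param cfg a [cluster_config()]
#' @return the adjusted `gene_cluster`
#' @export
adjust_cluster <- function(cluster, values, cfg = cluster_config()) {
  members <- cluster$members
  if (length(members) < 2) return(cluster)
  r <- pearson(values[members, , drop = FALSE], min_overlap = cfg$min_overlap)
  repeat {
    avg <- mean(r[upper.tri(r)], na.rm = TRUE)
    if (!is.na(avg) && avg >= cfg$avg_r) break
    removable <- setdiff(members, cluster$seeds)
    if (!length(removable)) {
      members <- sort(cluster$seeds)
      cluster$warning_flag <- TRUE
      r <- pearson(values[members, , drop = FALSE], min_overlap = cfg$min_overlap)
      break
    }
    meanr <- vapply(removable, function(g) {
      mean(r[g, setdiff(members, g)], na.rm = TRUE)
    }, numeric(1))
    worst <- removable[meanr == min(meanr)]
    drop_id <- sort(worst)[length(worst)]
    members <- setdiff(members, drop_id)
    r <- r[members, members, drop = FALSE]
    if (length(members) < 2) break
  }
  cluster$members <- members
  cluster$avg_r <- if (length(members) >= 2)
    mean(r[upper.tri(r)], na.rm = TRUE) else NA_real_
  cluster
}

#' Tissue preferentiality of a gene
#'
#' TRUE iff the gene's intensity in the target tissue is at least `fold`
#' times its maximum intensity over every other tissue (boundary
#' inclusive). Tissues with several samples are summarized by their mean.
#'
#' @param m an `expression_matrix` with tissue metadata
#' @param gene gene id
#' @param tissue target tissue name
#' @param cfg a [cluster_config()] supplying `fold`
#' @return logical
#' @export
tissue_preferential <- function(m, gene, tissue, cfg = cluster_config()) {
  if (!"tissue" %in% names(m$metadata)) stop_cfg("metadata has no tissue column")
  if (!tissue %in% m$metadata$tissue) stop_cfg("unknown tissue '%s'", tissue)
  v <- tapply(m$values[gene, ], m$metadata$tissue, mean)
  target <- v[[tissue]]
  other <- max(v[names(v) != tissue])
  target >= cfg$fold * other
}

#' Hierarchical gene or condition clustering
#'
#' Agglomerative average-linkage clustering at distance `1 - r`; the branch
#' correlation of each merge is `1 - height`. Items whose correlation with
#' every other item is undefined are excluded with a warning.
#'
#' @param values genes x samples matrix
#' @param axis "genes" (rows) or "conditions" (columns)
#' @param min_overlap minimum complete pairs per correlation
#' @return list of class `lsg_dendrogram` with `hclust`, `branch_correlation`
#' @export
hcluster <- function(values, axis = c("genes", "conditions"), min_overlap = 3L) {
  axis <- match.arg(axis)
  m <- if (axis == "genes") values else t(values)
  if (nrow(m) < 2) stop_cfg("need at least 2 items to cluster")
  r <- pearson(m, min_overlap = min_overlap)
  diag(r) <- 1
  undef <- rowSums(!is.na(r)) <= 1
  if (any(undef)) {
    warning(sprintf("%d item(s) with undefined correlations excluded", sum(undef)))
    r <- r[!undef, !undef, drop = FALSE]
  }
  d <- stats::as.dist(1 - r)
  hc <- stats::hclust(d, method = "average")
  structure(list(hclust = hc, branch_correlation = 1 - hc$height),
            class = "lsg_dendrogram")
}

#' @export
print.lsg_dendrogram <- function(x, ...) {
  cat(sprintf("average-linkage dendrogram over %d items; branch correlations %s\n",
              length(x$hclust$labels),
              paste(round(range(x$branch_correlation), 3), collapse = " to ")))
  invisible(x)
}

#' Export a dendrogram as a Newick string
#' @param dend an `lsg_dendrogram`
#' @param path optional file to write
#' @return Newick string, invisibly when writing
#' @export
dendrogram_newick <- function(dend, path = NULL) {
  phy <- ape::as.phylo(dend$hclust)
  if (!is.null(path)) {
    ape::write.tree(phy, file = path)
    return(invisible(ape::write.tree(phy)))
  }
  ape::write.tree(phy)
}

#' @export
print.gene_cluster <- function(x, ...) {
  cat(sprintf("gene_cluster: %d members (%d seeds), avg pairwise r = %.3f%s\n",
              length(x$members), length(x$seeds), x$avg_r,
              if (x$warning_flag) " [below avg_r threshold: seeds-only]" else ""))
  if (!is.null(x$preferred_tissue))
    cat("preferred tissue:", x$preferred_tissue, "\n")
  invisible(x)
}

#' Build all clusters from a seed set
#'
#' Runs the full seed-based procedure: group the seed genes at `seed_r`,
#' pick a representative per group, grow a cluster around each
#' representative, and adjust each cluster to the average-correlation
#' threshold. Overlapping clusters are optionally resolved by keeping the
#' largest (ties: most seeds, then first representative id).
#'
#' @param values genes x samples matrix
#' @param seed_ids ids of the seed (lineage-specific) genes
#' @param cfg a [cluster_config()]
#' @param overlap "keep-all" or "keep-largest"
#' @return list of `gene_cluster`
#' @export
seed_clusters <- function(values, seed_ids, cfg = cluster_config(),
                          overlap = c("keep-all", "keep-largest")) {
  overlap <- match.arg(overlap)
  seed_ids <- intersect(seed_ids, rownames(values))
  if (!length(seed_ids)) stop_cfg("no seed gene present in the matrix")
  groups <- dedupe_seeds(values[seed_ids, , drop = FALSE], cfg)
  reps <- unique(groups$representative)
  clusters <- lapply(reps, function(rep) {
    adjust_cluster(grow_cluster(values, rep, cfg, seed_ids), values, cfg)
  })
  if (overlap == "keep-largest" && length(clusters) > 1) {
    sizes <- vapply(clusters, function(c) length(c$members), integer(1))
    keep <- rep(TRUE, length(clusters))
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i == j || !keep[i] || !keep[j]) next
        if (length(intersect(clusters[[i]]$members, clusters[[j]]$members))) {
          drop <- if (sizes[i] < sizes[j]) i else j
          keep[drop] <- FALSE
        }
      }
    }
    clusters <- clusters[keep]
  }
  clusters
}

#' Write clusters as TSV (cluster id, gene id, is_seed, mean r to cluster)
#' @param clusters list of `gene_cluster`
#' @param values genes x samples matrix
#' @param path output TSV
#' @param cfg a [cluster_config()]
#' @return `path`, invisibly
#' @export
write_clusters <- function(clusters, values, path, cfg = cluster_config()) {
  rows <- list()
  for (ci in seq_along(clusters)) {
    cl <- clusters[[ci]]
    r <- pearson(values[cl$members, , drop = FALSE], min_overlap = cfg$min_overlap)
    diag(r) <- NA
    rows[[ci]] <- data.frame(cluster = ci, gene = cl$members,
                             is_seed = cl$members %in% cl$seeds,
                             mean_r = if (length(cl$members) > 1)
                               rowMeans(r, na.rm = TRUE) else NA_real_,
                             stringsAsFactors = FALSE)
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
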