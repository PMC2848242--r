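#' Composite-TFBS configuration
#'
#' Composites are pairs or triplets of distinct, non-overlapping TFBS hits
#' on one promoter whose consecutive gaps (nearest-edge distance,
#' `start_next - end_prev - 1`) all lie in `[d_min, d_max]`. The analysis is
#' run once per minimum-distance class (20, 50 and 100 bp) with the maximum
#' inter-TFBS distance fixed at 250 bp. Orientation of hits is ignored.
#'
#' @param arity 2 (pairs) or 3 (triplets)
#' @param ordered ordered keys (A*B, positional order relative to the TSS)
#'   or unordered (sorted, A,B). Default: pairs ordered, triplets unordered.
#' @param d_min minimum gap in bp (one of 20, 50, 100 in the standard runs)
#' @param d_max maximum gap in bp (default 250)
#' @param min_cell minimum total composite count required for testing
#'   (default 5)
#' @param min_cell_on which count the rule applies to: "total" (k + K),
#'   "cluster" (k) or "all" (both)
#' @param alpha BH-adjusted significance level (default 0.1)
#' @param sided "greater" (over-representation, default) or "two.sided"
#' @param distance "edge" (nearest-edge gap, default) or "start"
#'   (start-to-start distance) for the `[d_min, d_max]` constraint
#' @return list of class `composite_config`
#' @export
composite_config <- function(arity = 2L, ordered = (arity == 2L), d_min = 20L,
                             d_max = 250L, min_cell = 5L,
                             min_cell_on = c("total", "cluster", "all"),
                             alpha = 0.1, sided = c("greater", "two.sided"),
                             distance = c("edge", "start")) {
  if (!arity %in% c(2L, 3L)) stop_cfg("arity must be 2 or 3")
  if (d_min < 0 || d_min > d_max) stop_cfg("need 0 <= d_min <= d_max")
  structure(list(arity = as.integer(arity), ordered = isTRUE(ordered),
                 d_min = as.integer(d_min), d_max = as.integer(d_max),
                 min_cell = as.integer(min_cell),
                 min_cell_on = match.arg(min_cell_on),
                 alpha = alpha, sided = match.arg(sided),
                 distance = match.arg(distance)),
            class = "composite_config")
}

#' Enumerate the composite keys realized on one promoter
#'
#' Considers every tuple of hits (pairs or triplets, taken in positional
#' order of their start coordinates) with pairwise-distinct matrix ids,
#' non-overlapping intervals, and every consecutive nearest-edge gap within
#' `[d_min, d_max]`. Ordered keys join ids with `*` in positional order;
#' unordered keys sort the ids and join with `,`. Each key is counted at
#' most once per promoter.
#'
#' @param hits `tfbs_hits` rows for a single promoter
#' @param cfg a [composite_config()]
#' @return character vector of unique keys
#' @export
find_composites <- function(hits, cfg = composite_config()) {
  n <- nrow(hits)
  if (n < cfg$arity) return(character(0))
  ord <- order(hits$start, hits$end)
  st <- hits$start[ord]; en <- hits$end[ord]; id <- hits$matrix[ord]
  keys <- character(0)
  edge_mode <- is.null(cfg$distance) || cfg$distance == "edge"
  gap_ok <- function(i, j) {
    g <- if (edge_mode) st[j] - en[i] - 1L else st[j] - st[i]
    ok <- g >= cfg$d_min && g <= cfg$d_max
    if (!edge_mode) ok <- ok && st[j] > en[i]   # still non-overlapping
    ok
  }
  if (cfg$arity == 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (id[i] == id[j]) next
      if (!gap_ok(i, j)) next
      keys <- c(keys, if (cfg$ordered) paste(id[i], id[j], sep = "*")
                else paste(sort(c(id[i], id[j])), collapse = ","))
    }
  } else {
    if (n >= 3L) {
      for (i in seq_len(n - 2L)) for (j in (i + 1L):(n - 1L)) for (k in (j + 1L):n) {
        ids <- c(id[i], id[j], id[k])
        if (anyDuplicated(ids)) next
        if (!gap_ok(i, j) || !gap_ok(j, k)) next
        keys <- c(keys, if (cfg$ordered) paste(ids, collapse = "*")
                  else paste(sort(ids), collapse = ","))
      }
    }
  }
  sort(unique(keys))
}

#' Count composite occurrences in cluster and background promoter sets
#'
#' Both sets must have been scanned with the same Match configuration. The
#' counts `k` and `K` are numbers of promoters containing each key (a single
#' occurrence per promoter), not occurrence counts. Every key observed in
#' the cluster is tabulated.
#'
#' @param cluster_hits `tfbs_hits` for the cluster promoters
#' @param background_hits `tfbs_hits` for the background promoters
#' @param cfg a [composite_config()]
#' @param n_cluster,n_background promoter counts (needed because promoters
#'   with no hits do not appear in the hit tables)
#' @return data.frame: key, k, n, K, N
#' @export
count_composites <- function(cluster_hits, background_hits, cfg,
                             n_cluster, n_background) {
  if (n_cluster < 1) stop_cfg("empty cluster")
  per_prom_keys <- function(hits) {
    if (!nrow(hits)) return(list())
    lapply(split(hits, hits$promoter), find_composites, cfg = cfg)
  }
  ck <- per_prom_keys(cluster_hits)
  bk <- per_prom_keys(background_hits)
  tab <- function(keysets) {
    k <- unlist(keysets, use.names = FALSE)
    if (!length(k)) return(integer(0))
    table(k)
  }
  ct <- tab(ck); bt <- tab(bk)
  keys <- sort(names(ct))
  data.frame(key = as.character(keys),
             k = as.integer(ct[keys]),
             n = rep(as.integer(n_cluster), length(keys)),
             K = as.integer(ifelse(is.na(bt[keys]), 0L, bt[keys])),
             N = rep(as.integer(n_background), length(keys)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' One-sided Fisher enrichment p-value
#'
#' Hypergeometric tail probability \eqn{P(X \ge k)} for drawing the cluster
#' (`n` promoters) from the pooled population of `n + N` promoters of which
#' `k + K` contain the composite.
#'
#' @param k cluster promoters containing the key
#' @param n cluster promoter count
#' @param K background promoters containing the key
#' @param N background promoter count
#' @param sided "greater" (enrichment tail) or "two.sided"
#'   (stats::fisher.test convention)
#' @return p-value
#' @export
fisher_enrichment <- function(k, n, K, N, sided = "greater") {
  stopifnot(k >= 0, k <= n, K >= 0, K <= N)
  if (sided == "greater") {
    stats::phyper(k - 1, k + K, n + N - k - K, n, lower.tail = FALSE)
  } else {
    tb <- matrix(c(k, n - k, K, N - K), 2L)
    stats::fisher.test(tb, alternative = "two.sided")$p.value
  }
}

#' Benjamini-Hochberg adjusted p-values
#' @param p numeric vector of p-values in \[0,1\]
#' @return adjusted p-values in the input order
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Test composite over-representation and apply the selection rules
#'
#' Computes Fisher enrichment p-values for every cluster-observed key,
#' BH-adjusts them within the analysis family, applies the minimum-cell
#' rule, and — when an unmasked-promoter key set is supplied — requires each
#' significant key to also occur in the unmasked cluster promoters, so no
#' accepted composite lies inside a repeat.
#'
#' @param tables data.frame from [count_composites()] (masked promoters)
#' @param cfg a [composite_config()]
#' @param unmasked_keys character vector of keys observed in the unmasked
#'   cluster promoters, or NULL to skip the consistency rule
#' @return data.frame of class `enrichment_result`: key, k, n, K, N, p,
#'   p_adj, passed_min_cell, unmasked_consistent, significant
#' @export
composite_enrichment <- function(tables, cfg, unmasked_keys = NULL) {
  res <- tables
  passed <- switch(cfg$min_cell_on,
                   total = (res$k + res$K) >= cfg$min_cell,
                   cluster = res$k >= cfg$min_cell,
                   all = res$k >= cfg$min_cell & (res$k + res$K) >= cfg$min_cell)
  res$p <- NA_real_
  res$p_adj <- NA_real_
  test <- which(passed)
  if (length(test)) {
    res$p[test] <- mapply(fisher_enrichment, res$k[test], res$n[test],
                          res$K[test], res$N[test],
                          MoreArgs = list(sided = cfg$sided))
    res$p_adj[test] <- bh_adjust(res$p[test])
  }
  res$passed_min_cell <- passed
  res$unmasked_consistent <- if (is.null(unmasked_keys)) TRUE
    else res$key %in% unmasked_keys
  res$significant <- passed & !is.na(res$p_adj) & res$p_adj <= cfg$alpha &
    res$unmasked_consistent
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Single-TFBS over-representation
#'
#' Per-matrix 2x2 Fisher enrichment of binary TFBS presence in cluster
#' versus background promoters, BH-adjusted across the tested matrices.
#' Matrices absent from every cluster promoter are not tested.
#'
#' @param cluster_presence presence map (list promoter -> matrix ids) for
#'   the cluster (see [presence_map()])
#' @param background_presence presence map for the background
#' @param alpha BH-adjusted significance level (default 0.1)
#' @param sided test sidedness (default "greater")
#' @return `enrichment_result` data.frame keyed by matrix id
#' @export
single_tfbs_enrichment <- function(cluster_presence, background_presence,
                                   alpha = 0.1, sided = "greater") {
  n <- length(cluster_presence); N <- length(background_presence)
  if (n < 1) stop_cfg("empty cluster")
  ct <- table(unlist(cluster_presence, use.names = FALSE))
  bt <- table(unlist(background_presence, use.names = FALSE))
  keys <- sort(names(ct))
  res <- data.frame(key = keys, k = as.integer(ct[keys]), n = n,
                    K = as.integer(ifelse(is.na(bt[keys]), 0L, bt[keys])),
                    N = N, stringsAsFactors = FALSE, row.names = NULL)
  res$p <- mapply(fisher_enrichment, res$k, res$n, res$K, res$N,
                  MoreArgs = list(sided = sided))
  res$p_adj <- bh_adjust(res$p)
  res$passed_min_cell <- TRUE
  res$unmasked_consistent <- TRUE
  res$significant <- res$p_adj <= alpha
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result: %d keys tested, %d significant\n",
              sum(!is.na(x$p)), sum(x$significant, na.rm = TRUE)))
  sig <- x[which(x$significant), c("key", "k", "n", "K", "N", "p", "p_adj")]
  if (nrow(sig)) print(utils::head(sig[order(sig$p_adj), ], 10), row.names = FALSE)
  invisible(x)
}

#' Run the composite over-representation analysis end to end
#'
#' Scans are assumed done; this takes hit tables for masked cluster,
#' unmasked cluster and masked background promoters and runs the analysis
#' for each requested minimum-distance class.
#'
#' @param cluster_hits,cluster_hits_unmasked,background_hits `tfbs_hits`
#' @param n_cluster,n_background promoter counts
#' @param arity 2 or 3
#' @param ordered key order mode (default: pairs ordered, triplets unordered)
#' @param d_min_classes minimum-gap classes (default c(20, 50, 100))
#' @param ... passed to [composite_config()]
#' @return `enrichment_result` with a `d_min` column, all classes stacked
#' @export
composite_analysis <- function(cluster_hits, cluster_hits_unmasked,
                               background_hits, n_cluster, n_background,
                               arity = 2L, ordered = (arity == 2L),
                               d_min_classes = c(20L, 50L, 100L), ...) {
  out <- lapply(d_min_classes, function(dm) {
    cfg <- composite_config(arity = arity, ordered = ordered, d_min = dm, ...)
    tabs <- count_composites(cluster_hits, background_hits, cfg,
                             n_cluster, n_background)
    if (!nrow(tabs)) return(NULL)
    unmasked_keys <- unique(unlist(lapply(
      split(cluster_hits_unmasked, cluster_hits_unmasked$promoter),
      find_composites, cfg = cfg)))
    r <- composite_enrichment(tabs, cfg, unmasked_keys)
    r$d_min <- dm
    r
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    res <- data.frame(key = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p = numeric(0),
                      p_adj = numeric(0), passed_min_cell = logical(0),
                      unmasked_consistent = logical(0),
                      significant = logical(0), d_min = integer(0),
                      stringsAsFactors = FALSE)
  } else {
    res <- do.call(rbind, out)
  }
  class(res) <- c("enrichment_result", "data.frame")
  res
}
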