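#' Hub-gene configuration
#'
#' @param n_hubs number of hub genes to report (default 5)
#' @param gs_cutoff gene-significance cutoff on the −log10 p scale
#'   (default 1.2, i.e. p <= 10^-1.2 ≈ 0.063)
#' @param k_ratio_cutoff intramodular connectivity ratio K/Kmax cutoff
#'   (default 0.95)
#' @param beta default soft-threshold power (default 8)
#' @param rsq_target scale-free fit R-squared target for beta selection
#'   (default 0.8)
#' @param beta_grid candidate powers (default 1:20)
#' @param min_module_size smallest reported module (default 30)
#' @param cut_height static tree-cut height on 1 − TOM (default 0.95)
#' @return list of class `hub_config`
#' @export
hub_config <- function(n_hubs = 5L, gs_cutoff = 1.2, k_ratio_cutoff = 0.95,
                       beta = 8, rsq_target = 0.8, beta_grid = 1:20,
                       min_module_size = 30L, cut_height = 0.95) {
  stopifnot(gs_cutoff >= 0, k_ratio_cutoff >= 0)
  structure(list(n_hubs = as.integer(n_hubs), gs_cutoff = gs_cutoff,
                 k_ratio_cutoff = k_ratio_cutoff, beta = beta,
                 rsq_target = rsq_target, beta_grid = beta_grid,
                 min_module_size = as.integer(min_module_size),
                 cut_height = cut_height),
            class = "hub_config")
}

#' Power adjacency network
#'
#' Unsigned weighted adjacency \eqn{a_{ij} = |cor(x_i, x_j)|^\beta}. The
#' diagonal is set to 1 but excluded from connectivity
#' \eqn{k_i = \sum_{j \ne i} a_{ij}}. Genes with zero variance (undefined
#' correlations) are excluded with a warning.
#'
#' @param values genes x samples matrix (>= 3 samples)
#' @param beta soft-threshold power
#' @return object of class `coexpression_network`: `adjacency`,
#'   `connectivity`, `beta`, `genes`
#' @export
power_adjacency <- function(values, beta = 8) {
  if (ncol(values) < 3) stop_cfg("need >= 3 samples per gene")
  sds <- apply(values, 1L, stats::sd, na.rm = TRUE)
  bad <- is.na(sds) | sds == 0
  if (any(bad)) {
    warning(sprintf("%d zero-variance gene(s) excluded", sum(bad)))
    values <- values[!bad, , drop = FALSE]
  }
  r <- pearson(values)
  a <- abs(r)^beta
  diag(a) <- 1
  a[is.na(a)] <- 0
  k <- colSums(a) - 1   # diagonal excluded
  structure(list(adjacency = a, connectivity = k, beta = beta,
                 genes = rownames(values), tom = NULL, modules = NULL,
                 rsq = NA_real_),
            class = "coexpression_network")
}

#' Scale-free topology fit of a connectivity vector
#'
#' R-squared of the regression of log10 p(k) on log10 k over
#' equal-occupancy connectivity bins (zero-count bins dropped).
#'
#' @param k connectivity vector
#' @param n_bins bin count (default 10)
#' @return R-squared in \[0,1\] (NA when fewer than 3 usable bins)
#' @export
scale_free_rsq <- function(k, n_bins = 10L) {
  k <- k[k > 0]
  if (length(k) < n_bins) return(NA_real_)
  br <- unique(stats::quantile(k, probs = seq(0, 1, length.out = n_bins + 1L)))
  if (length(br) < 4) return(NA_real_)
  bin <- cut(k, br, include.lowest = TRUE)
  kb <- tapply(k, bin, mean)
  pb <- tapply(k, bin, length) / length(k)
  keep <- !is.na(kb) & pb > 0
  if (sum(keep) < 3) return(NA_real_)
  fit <- stats::lm(log10(pb[keep]) ~ log10(kb[keep]))
  suppressWarnings(summary(fit)$r.squared)   # perfect fits are fine here
}

#' Select the soft-threshold power by the scale-free criterion
#'
#' Returns the smallest power on the grid whose connectivity distribution
#' reaches the scale-free fit target; when none does, the power with the
#' maximum fit is returned with a warning.
#'
#' @param values genes x samples matrix (>= 10 genes)
#' @param cfg a [hub_config()] (grid and R-squared target)
#' @return list: `beta`, `rsq`, `fit_table` (beta, rsq)
#' @export
pick_beta <- function(values, cfg = hub_config()) {
  if (nrow(values) < 10) stop_cfg("need >= 10 genes to assess scale-free fit")
  if (!length(cfg$beta_grid)) stop_cfg("empty beta grid")
  r <- abs(pearson(values))
  diag(r) <- 0
  r[is.na(r)] <- 0
  fits <- vapply(cfg$beta_grid, function(b) {
    scale_free_rsq(colSums(r^b))
  }, numeric(1))
  tab <- data.frame(beta = cfg$beta_grid, rsq = fits)
  ok <- which(!is.na(fits) & fits >= cfg$rsq_target)
  if (length(ok)) {
    i <- ok[1]
  } else {
    warning("no power reaches the scale-free fit target; using the best fit")
    i <- which.max(fits)
  }
  list(beta = cfg$beta_grid[i], rsq = fits[i], fit_table = tab)
}

#' Topological overlap matrix
#'
#' \deqn{TOM_{ij} = (\sum_u a_{iu} a_{uj} + a_{ij}) / (\min(k_i,k_j) + 1 - a_{ij})}
#' with \eqn{TOM_{ii} = 1}; the sum runs over \eqn{u \ne i, j}.
#'
#' @param net a `coexpression_network` (or a plain adjacency matrix)
#' @return the network with `tom` filled in (or the TOM matrix when given a
#'   matrix)
#' @export
tom_similarity <- function(net) {
  a <- if (inherits(net, "coexpression_network")) net$adjacency else as.matrix(net)
  a0 <- a
  diag(a0) <- 0
  k <- colSums(a0)
  L <- a0 %*% a0                         # sum_u a_iu a_uj, u != i,j by diag 0
  kmin <- outer(k, k, pmin)
  tom <- (L + a0) / (kmin + 1 - a0)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  if (inherits(net, "coexpression_network")) {
    net$tom <- tom
    net
  } else tom
}

#' Detect modules by static cut of the TOM dendrogram
#'
#' Average-linkage clustering of 1 − TOM, cut at a fixed height; clusters
#' below the minimum size are labelled 0 (unassigned). Module labels are
#' renumbered by decreasing size.
#'
#' @param net a `coexpression_network` with TOM computed (see
#'   [tom_similarity()]), or a TOM matrix
#' @param cfg a [hub_config()] (cut height, min module size)
#' @return the network with `modules` (named integer vector), or the label
#'   vector when given a matrix
#' @export
detect_modules <- function(net, cfg = hub_config()) {
  tom <- if (inherits(net, "coexpression_network")) net$tom else as.matrix(net)
  if (is.null(tom)) stop_cfg("TOM not computed; call tom_similarity() first")
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  raw <- stats::cutree(hc, h = cfg$cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= cfg$min_module_size]
  labels <- integer(length(raw))
  ord <- names(sort(sizes[keep], decreasing = TRUE))
  for (m in seq_along(ord)) labels[raw == as.integer(ord[m])] <- m
  names(labels) <- rownames(tom)
  if (inherits(net, "coexpression_network")) {
    net$modules <- labels
    net
  } else labels
}

#' Identify hub genes
#'
#' Within each module, hubs are the genes passing both the gene-significance
#' cutoff (GS, on the −log10 p scale) and the intramodular connectivity
#' ratio cutoff \eqn{k_i / k_{max} \ge} `k_ratio_cutoff` (with
#' \eqn{k_{max}} the maximum connectivity in the gene's module); the top
#' `n_hubs` by connectivity are reported. When fewer genes qualify, all
#' qualifying genes are returned with a warning.
#'
#' @param net a `coexpression_network` with modules assigned
#' @param gene_significance named vector of GS values (−log10 p), aligned by
#'   gene id; missing genes get GS 0
#' @param cfg a [hub_config()]
#' @param module module label to search (default 1, the largest)
#' @return data.frame: gene, module, connectivity, k_ratio, gs
#' @export
hub_genes <- function(net, gene_significance, cfg = hub_config(), module = 1L) {
  if (is.null(net$modules)) stop_cfg("modules not assigned; run detect_modules()")
  in_mod <- names(net$modules)[net$modules == module]
  if (!length(in_mod)) stop_cfg("module %d is empty", module)
  k <- net$connectivity[in_mod]
  kmax <- max(k)
  gs <- gene_significance[in_mod]
  gs[is.na(gs)] <- 0
  qual <- gs >= cfg$gs_cutoff & (k / kmax) >= cfg$k_ratio_cutoff
  cand <- in_mod[qual]
  if (!length(cand)) {
    warning("no gene passes the hub cutoffs; returning empty hub list")
  } else if (length(cand) < cfg$n_hubs) {
    warning(sprintf("only %d gene(s) pass the hub cutoffs", length(cand)))
  }
  cand <- cand[order(k[cand], decreasing = TRUE)]
  top <- utils::head(cand, cfg$n_hubs)
  data.frame(gene = top, module = rep(module, length(top)),
             connectivity = unname(k[top]), k_ratio = unname(k[top] / kmax),
             gs = unname(gs[top]), stringsAsFactors = FALSE, row.names = NULL)
}

#' Gene significance from diet-within-time results
#'
#' GS_i is the maximum over time points of −log10(raw p) for gene i, the
#' scale on which the 1.2 hub cutoff is applied.
#'
#' @param diet_result a `diet_time_result` data.frame
#' @param agg "max" (default) or "mean" over time points
#' @return named numeric vector of GS values
#' @export
gene_significance <- function(diet_result, agg = c("max", "mean")) {
  agg <- match.arg(agg)
  f <- if (agg == "max") function(p) max(-log10(p), na.rm = TRUE)
       else function(p) mean(-log10(p), na.rm = TRUE)
  out <- tapply(diet_result$p, diet_result$gene, function(p) {
    p <- p[!is.na(p)]
    if (!length(p)) return(NA_real_)
    f(p)
  })
  stats::setNames(as.numeric(out), names(out))
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("coexpression_network: %d genes, beta = %g\n",
              length(x$genes), x$beta))
  if (!is.null(x$modules)) {
    t <- table(x$modules)
    cat("modules:", paste(sprintf("%s (n=%d)", names(t), t), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write adjacency and TOM as MatrixMarket sparse files
#'
#' Entries below `min_weight` are dropped; only the upper triangle is
#' stored (the matrices are symmetric).
#'
#' @param net a `coexpression_network`
#' @param adjacency_path,tom_path output .mtx paths (either may be NULL)
#' @param min_weight sparsity threshold (default 1e-6)
#' @return invisibly, the written paths
#' @export
write_network_mtx <- function(net, adjacency_path = NULL, tom_path = NULL,
                              min_weight = 1e-6) {
  wr <- function(a, path) {
    idx <- which(upper.tri(a, diag = TRUE) & abs(a) >= min_weight,
                 arr.ind = TRUE)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("%%MatrixMarket matrix coordinate real symmetric",
                 sprintf("%d %d %d", nrow(a), ncol(a), nrow(idx))), con)
    writeLines(sprintf("%d %d %.10g", idx[, 2], idx[, 1], a[idx]), con)
    path
  }
  out <- character(0)
  if (!is.null(adjacency_path)) out <- c(out, wr(net$adjacency, adjacency_path))
  if (!is.null(tom_path)) {
    if (is.null(net$tom)) stop_cfg("TOM not computed; call tom_similarity() first")
    out <- c(out, wr(net$tom, tom_path))
  }
  invisible(out)
}

#' Write the network edge list as TSV
#' @param net a `coexpression_network` (TOM optional)
#' @param path output TSV
#' @param min_weight drop edges with adjacency below this (default 1e-6)
#' @return `path`, invisibly
#' @export
write_edges <- function(net, path, min_weight = 1e-6) {
  a <- net$adjacency
  idx <- which(upper.tri(a) & a >= min_weight, arr.ind = TRUE)
  d <- data.frame(gene_i = rownames(a)[idx[, 1]], gene_j = colnames(a)[idx[, 2]],
                  adjacency = a[idx],
                  tom = if (!is.null(net$tom)) net$tom[idx] else NA_real_,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
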