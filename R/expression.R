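#' Expression matrix container
#'
#' Holds a genes x samples matrix of values (raw intensities for the tissue
#' panel, log2 ratios versus the reference for the time series) together
#' with the annotations the filtering rules need: per-spot present/absent
#' flags, per-spot significance p-values (time series only), per-sample
#' negative-control medians, and sample metadata (tissue, or time/diet/
#' replicate).
#'
#' @param values numeric matrix, rownames gene ids, colnames sample ids
#' @param metadata data.frame with a `sample` column matching colnames
#' @param present logical matrix of present flags (default all TRUE)
#' @param pvalues per-spot significance p-values, or NULL
#' @param intensity raw intensity matrix; defaults to `values` (panel data)
#' @param control_median named numeric vector of per-sample negative-control
#'   medians, or NULL
#' @param kind "intensity" or "log2ratio"
#' @return object of class `expression_matrix`
#' @export
new_expression_matrix <- function(values, metadata, present = NULL,
                                  pvalues = NULL, intensity = NULL,
                                  control_median = NULL,
                                  kind = c("intensity", "log2ratio")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    if (nrow(values) > 0) stop_cfg("values must have gene ids as rownames")
    rownames(values) <- character(0)   # empty subset after filtering
  }
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop_cfg("duplicate gene id(s): %s", paste(utils::head(dup, 5), collapse = ", "))
  }
  missing_meta <- setdiff(colnames(values), metadata$sample)
  if (length(missing_meta)) {
    stop_cfg("sample(s) without metadata: %s", paste(missing_meta, collapse = ", "))
  }
  metadata <- metadata[match(colnames(values), metadata$sample), , drop = FALSE]
  if (is.null(present)) {
    present <- matrix(TRUE, nrow(values), ncol(values), dimnames = dimnames(values))
  }
  if (!is.null(pvalues)) {
    pr <- range(pvalues, na.rm = TRUE)
    if (pr[1] < 0 || pr[2] > 1) stop_cfg("p-values outside [0,1]")
  }
  # parallel matrices inherit the main dimnames when unnamed
  align <- function(mat) {
    if (is.null(mat)) return(NULL)
    mat <- as.matrix(mat)
    if (!identical(dim(mat), dim(values)))
      stop_cfg("parallel matrix shape %dx%d does not match values %dx%d",
               nrow(mat), ncol(mat), nrow(values), ncol(values))
    dimnames(mat) <- dimnames(values)
    mat
  }
  structure(list(values = values, metadata = metadata,
                 present = align(present), pvalues = align(pvalues),
                 intensity = if (is.null(intensity)) values else align(intensity),
                 control_median = control_median, kind = kind),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix (%s): %d genes x %d samples\n",
              x$kind, nrow(x$values), ncol(x$values)))
  cat("metadata:", paste(setdiff(names(x$metadata), "sample"), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

# subset an expression_matrix by gene ids, keeping all parallel matrices
subset_genes <- function(m, genes) {
  sub <- function(mat) if (is.null(mat)) NULL else mat[genes, , drop = FALSE]
  new_expression_matrix(values = sub(m$values), metadata = m$metadata,
                        present = sub(m$present), pvalues = sub(m$pvalues),
                        intensity = sub(m$intensity),
                        control_median = m$control_median, kind = m$kind)
}

#' Read an expression matrix from TSV
#'
#' The main table is tab-delimited, UTF-8, '.' decimal; first column gene
#' id, header row sample ids; empty cells are missing. Parallel tables with
#' the same shape may supply present flags (0/1) and per-spot p-values. The
#' metadata TSV has one row per sample (columns: sample, then tissue, or
#' time/diet/replicate) and may carry a `control_median` column.
#'
#' @param path main values TSV
#' @param metadata_path sample metadata TSV
#' @param present_path,pvalues_path,intensity_path optional parallel TSVs
#' @param kind "intensity" or "log2ratio"
#' @return an `expression_matrix`
#' @export
read_expression <- function(path, metadata_path, present_path = NULL,
                            pvalues_path = NULL, intensity_path = NULL,
                            kind = c("intensity", "log2ratio")) {
  kind <- match.arg(kind)
  read_mat <- function(p) {
    d <- utils::read.delim(p, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(d[[1]])
    if (anyDuplicated(ids)) {
      dup <- unique(ids[duplicated(ids)])
      stop_cfg("duplicate gene id(s) in %s: %s", p,
               paste(utils::head(dup, 5), collapse = ", "))
    }
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- ids
    m
  }
  values <- read_mat(path)
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  ctrl <- NULL
  if ("control_median" %in% names(meta)) {
    ctrl <- stats::setNames(meta$control_median, meta$sample)
  }
  present <- if (!is.null(present_path)) read_mat(present_path) > 0 else NULL
  pvals <- if (!is.null(pvalues_path)) read_mat(pvalues_path) else NULL
  intens <- if (!is.null(intensity_path)) read_mat(intensity_path) else NULL
  new_expression_matrix(values, meta, present, pvals, intens, ctrl, kind)
}

#' Write an expression matrix (and parallel tables) as TSV
#' @param m an `expression_matrix`
#' @param dir output directory
#' @param prefix file-name prefix
#' @return named vector of written paths, invisibly
#' @export
write_expression <- function(m, dir, prefix = "expr") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(mat, name) {
    p <- file.path(dir, sprintf("%s_%s.tsv", prefix, name))
    d <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                    stringsAsFactors = FALSE)
    utils::write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(values = wr(m$values, "values"))
  paths["present"] <- wr(m$present * 1L, "present")
  if (!is.null(m$pvalues)) paths["pvalues"] <- wr(m$pvalues, "pvalues")
  paths["intensity"] <- wr(m$intensity, "intensity")
  meta <- m$metadata
  if (!is.null(m$control_median)) meta$control_median <- m$control_median[meta$sample]
  pm <- file.path(dir, sprintf("%s_metadata.tsv", prefix))
  utils::write.table(meta, pm, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["metadata"] <- pm
  invisible(paths)
}

#' Filtering configuration
#'
#' @param min_intensity intensity floor in fluorescence units: 250 for the
#'   tissue panel, 150 for the liver time series
#' @param require_present require the present flag
#' @param require_above_control require intensity strictly above the sample's
#'   negative-control median
#' @param sig_p per-spot significance threshold (time series only; 0.05)
#' @return list of class `filter_config`
#' @export
filter_config <- function(min_intensity, require_present = TRUE,
                          require_above_control = TRUE, sig_p = 0.05) {
  if (missing(min_intensity) || is.null(min_intensity) || min_intensity <= 0)
    stop_cfg("min_intensity must be a positive threshold")
  stopifnot(sig_p > 0, sig_p <= 1)
  structure(list(min_intensity = min_intensity,
                 require_present = require_present,
                 require_above_control = require_above_control,
                 sig_p = sig_p), class = "filter_config")
}

# per-spot qualification: present AND above control median AND >= floor
qualified_spots <- function(m, cfg) {
  ok <- m$intensity >= cfg$min_intensity
  if (cfg$require_present) ok <- ok & m$present
  if (cfg$require_above_control) {
    if (is.null(m$control_median)) stop_cfg("negative-control medians unavailable")
    ctrl <- matrix(m$control_median[colnames(m$intensity)],
                   nrow(m$intensity), ncol(m$intensity), byrow = TRUE)
    ok <- ok & (m$intensity > ctrl)   # strictly above the control median
  }
  ok & !is.na(m$intensity)
}

#' Filter a tissue-panel expression matrix
#'
#' Keeps genes with at least one sample that is simultaneously flagged
#' present, strictly above that sample's negative-control median, and at or
#' above the minimum intensity (250 units by default for the panel).
#'
#' @param m an `expression_matrix` of raw intensities
#' @param cfg a [filter_config()]
#' @return the filtered `expression_matrix`
#' @export
filter_panel <- function(m, cfg = filter_config(min_intensity = 250)) {
  keep <- rowSums(qualified_spots(m, cfg)) >= 1L
  subset_genes(m, rownames(m$values)[keep])
}

#' Filter a time-series expression matrix
#'
#' As [filter_panel()] (intensity floor 150 by default) plus the requirement
#' that the gene is statistically significant versus the reference in at
#' least one sample-point with a raw p-value below `sig_p`. The intensity
#' condition and the significance condition are each evaluated over all
#' sample-points independently: they need not hold at the same sample-point.
#'
#' @param m an `expression_matrix` with per-spot p-values
#' @param cfg a [filter_config()]
#' @return the filtered `expression_matrix`
#' @export
filter_timeseries <- function(m, cfg = filter_config(min_intensity = 150)) {
  if (is.null(m$pvalues)) stop_cfg("time-series filtering needs per-spot p-values")
  keep_int <- rowSums(qualified_spots(m, cfg)) >= 1L
  keep_sig <- rowSums(m$pvalues < cfg$sig_p, na.rm = TRUE) >= 1L
  subset_genes(m, rownames(m$values)[keep_int & keep_sig])
}

#' Per-gene diet-within-time analysis of log2 ratios
#'
#' For each gene, fits ordinary least squares on the (time, diet) cell means
#' and reports the diet difference at each time point (diet 2 minus diet 1,
#' log2 units) with its standard error, a two-sided p-value from the pooled
#' residual variance, and Benjamini-Hochberg adjusted p-values computed
#' jointly across all gene x time tests. A contrast whose cell is empty is
#' reported as not estimable (NA) rather than an error.
#'
#' @param m an `expression_matrix` of kind "log2ratio" with time and diet
#'   metadata
#' @param genes optional subset of gene ids (default all)
#' @return data.frame of class `diet_time_result` with columns gene, time,
#'   estimate, se, df, p, p_adj
#' @export
diet_within_time <- function(m, genes = NULL) {
  if (m$kind != "log2ratio") stop_cfg("diet analysis expects log2 ratios")
  md <- m$metadata
  if (!all(c("time", "diet") %in% names(md))) stop_cfg("metadata needs time and diet")
  genes <- genes %||% rownames(m$values)
  diets <- sort(unique(md$diet))
  if (length(diets) != 2) stop_cfg("exactly two diets expected")
  times <- sort(unique(md$time))
  cell <- interaction(md$time, md$diet, drop = FALSE)
  res <- vector("list", length(genes))
  for (gi in seq_along(genes)) {
    y <- m$values[genes[gi], ]
    ok <- !is.na(y)
    n_cells <- length(unique(cell[ok]))
    fit_df <- sum(ok) - n_cells
    mse <- if (fit_df > 0) {
      sum(tapply(y[ok], droplevels(cell[ok]),
                 function(v) sum((v - mean(v))^2))) / fit_df
    } else NA_real_
    est <- se <- p <- rep(NA_real_, length(times))
    for (ti in seq_along(times)) {
      i1 <- ok & md$time == times[ti] & md$diet == diets[1]
      i2 <- ok & md$time == times[ti] & md$diet == diets[2]
      if (!any(i1) || !any(i2) || is.na(mse)) next  # not estimable
      est[ti] <- mean(y[i2]) - mean(y[i1])
      se[ti] <- sqrt(mse * (1 / sum(i1) + 1 / sum(i2)))
      p[ti] <- if (se[ti] > 0) {
        2 * stats::pt(abs(est[ti] / se[ti]), df = fit_df, lower.tail = FALSE)
      } else if (est[ti] == 0) 1 else 0
    }
    res[[gi]] <- data.frame(gene = genes[gi], time = times, estimate = est,
                            se = se, df = fit_df, p = p,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$p_adj <- NA_real_
  tested <- !is.na(out$p)
  out$p_adj[tested] <- stats::p.adjust(out$p[tested], method = "BH")
  rownames(out) <- NULL
  class(out) <- c("diet_time_result", "data.frame")
  out
}

#' Mean diet fold change of a cluster over selected time points
#'
#' Returns \eqn{2^{\bar d}} where \eqn{\bar d} is the mean log2 diet
#' difference (first diet minus second, by default the higher-plane diet
#' minus the restricted one) over the named time points across all cluster
#' genes.
#'
#' @param m an `expression_matrix` of log2 ratios
#' @param cluster character vector of gene ids
#' @param times time points (days) to average over
#' @param diets length-2 vector: numerator diet, denominator diet
#' @return fold change (numerator over denominator)
#' @export
mean_cluster_fold <- function(m, cluster, times,
                              diets = sort(unique(m$metadata$diet))) {
  if (!length(cluster)) stop_cfg("empty cluster")
  md <- m$metadata
  sel1 <- md$time %in% times & md$diet == diets[1]
  sel2 <- md$time %in% times & md$diet == diets[2]
  if (!any(sel1) || !any(sel2)) stop_cfg("no data at the selected time points")
  v <- m$values[cluster, , drop = FALSE]
  d <- rowMeans(v[, sel1, drop = FALSE], na.rm = TRUE) -
    rowMeans(v[, sel2, drop = FALSE], na.rm = TRUE)
  2^mean(d, na.rm = TRUE)
}
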