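#' Read TSS records from a BED6 file
#'
#' BED is 0-based half-open. The TSS is taken as `chromStart + 1` (1-based)
#' on the + strand and `chromEnd` on the − strand, so a single-base BED
#' interval marks the TSS on either strand.
#'
#' @param path BED6 file
#' @param unique_genes error on duplicate gene ids (background-set mode)
#' @return data.frame with columns chrom, tss (1-based), strand, gene
#' @export
read_tss <- function(path, unique_genes = FALSE) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 6) stop_cfg("BED6 required (6 columns), got %d", ncol(bed))
  names(bed)[1:6] <- c("chrom", "start", "end", "gene", "score", "strand")
  bad <- which(!bed$strand %in% c("+", "-"))
  if (length(bad)) stop_cfg("malformed strand '%s' at line %d", bed$strand[bad[1]], bad[1])
  tss <- ifelse(bed$strand == "+", bed$start + 1L, bed$end)
  if (unique_genes && anyDuplicated(bed$gene)) {
    stop_cfg("duplicate gene id(s) in background TSS set: %s",
             paste(utils::head(unique(bed$gene[duplicated(bed$gene)]), 5),
                   collapse = ", "))
  }
  data.frame(chrom = bed$chrom, tss = as.integer(tss), strand = bed$strand,
             gene = bed$gene, stringsAsFactors = FALSE)
}

#' Extract a proximal promoter around a TSS
#'
#' The default window is \[−1000, +100\] in promoter coordinates with no
#' position 0 (−1 abuts +1), i.e. 1100 nt. On the + strand this is genomic
#' `[TSS-1000, TSS+99]` (1-based inclusive); on the − strand, genomic
#' `[TSS-99, TSS+1000]` reverse-complemented, so the returned sequence is
#' always 5'→3' on the transcribed strand. Lowercase genome bases are
#' recorded as repeat-masked and preserved in the output. Windows running
#' past a contig end are clipped and flagged, never padded.
#'
#' @param genome named character vector of contig sequences (soft-masked)
#' @param rec one-row data.frame (or list) with chrom, tss, strand, gene
#' @param window length-2 integer vector `c(upstream, downstream)` in
#'   promoter coordinates, default `c(-1000, 100)`
#' @return list of class `promoter_seq`: gene, seq, masked (logical vector),
#'   clipped, chrom, tss, strand
#' @export
extract_promoter <- function(genome, rec, window = c(-1000L, 100L)) {
  if (window[1] >= 0 || window[2] <= 0) stop_cfg("window must span the TSS (no position 0)")
  chrom_seq <- unname(genome[rec$chrom])
  if (is.na(chrom_seq)) stop_cfg("unknown contig '%s'", rec$chrom)
  L <- nchar(chrom_seq)
  up <- -window[1]; down <- window[2]
  if (rec$strand == "+") {
    g_start <- rec$tss - up
    g_end <- rec$tss + down - 1L
  } else {
    g_start <- rec$tss - down + 1L
    g_end <- rec$tss + up
  }
  clipped <- g_start < 1L || g_end > L
  s <- substr(chrom_seq, max(1L, g_start), min(L, g_end))
  if (rec$strand == "-") s <- revcomp(s)
  masked <- grepl("[acgtn]", strsplit(s, "", fixed = TRUE)[[1]])
  structure(list(gene = rec$gene, seq = s, masked = masked, clipped = clipped,
                 chrom = rec$chrom, tss = rec$tss, strand = rec$strand,
                 window = window),
            class = "promoter_seq")
}

#' Masked and unmasked views of a promoter
#'
#' The masked view substitutes N at every repeat-flagged base; the unmasked
#' view uppercases everything.
#'
#' @param p a `promoter_seq`
#' @return list with `masked` and `unmasked` strings
#' @export
masked_view <- function(p) {
  chars <- strsplit(toupper(p$seq), "", fixed = TRUE)[[1]]
  masked <- chars
  masked[p$masked] <- "N"
  list(masked = paste(masked, collapse = ""),
       unmasked = paste(chars, collapse = ""))
}

#' Extract promoters for a set of TSS records
#'
#' @param genome named character vector of contigs
#' @param records data.frame from [read_tss()]
#' @param window promoter window (see [extract_promoter()])
#' @param dedupe drop duplicated gene ids (keeping the first) with a warning
#' @return named list of `promoter_seq`
#' @export
extract_promoters <- function(genome, records, window = c(-1000L, 100L),
                              dedupe = TRUE) {
  if (dedupe && anyDuplicated(records$gene)) {
    warning(sprintf("%d duplicated gene id(s) deduplicated",
                    sum(duplicated(records$gene))))
    records <- records[!duplicated(records$gene), , drop = FALSE]
  }
  out <- lapply(seq_len(nrow(records)), function(i) {
    extract_promoter(genome, records[i, ], window)
  })
  stats::setNames(out, records$gene)
}

#' Build the background promoter set
#'
#' One promoter per unique gene in the annotation. Genes that also belong
#' to a query cluster are retained by default; pass `exclude` to subtract
#' them (used for de novo motif discovery).
#'
#' @param records TSS data.frame
#' @param genome named character vector of contigs
#' @param window promoter window
#' @param exclude gene ids to remove (default none)
#' @return named list of `promoter_seq`
#' @export
build_background <- function(records, genome, window = c(-1000L, 100L),
                             exclude = character(0)) {
  records <- records[!records$gene %in% exclude, , drop = FALSE]
  extract_promoters(genome, records, window, dedupe = TRUE)
}

#' Promoter sequences as a named character vector
#' @param promoters list of `promoter_seq`
#' @param view "masked" (repeats as N), "unmasked", or "soft" (as extracted)
#' @return named character vector
#' @export
promoter_strings <- function(promoters, view = c("masked", "unmasked", "soft")) {
  view <- match.arg(view)
  vapply(promoters, function(p) {
    switch(view,
           soft = p$seq,
           masked = masked_view(p)$masked,
           unmasked = masked_view(p)$unmasked)
  }, character(1))
}

#' Write promoters as FASTA with descriptive headers
#'
#' Headers follow `geneid|chrom|tss|strand|clipflag`.
#' @param promoters list of `promoter_seq`
#' @param path output FASTA
#' @param view which view to write (see [promoter_strings()])
#' @return `path`, invisibly
#' @export
write_promoters <- function(promoters, path, view = "soft") {
  seqs <- promoter_strings(promoters, view)
  names(seqs) <- vapply(promoters, function(p) {
    sprintf("%s|%s|%d|%s|%d", p$gene, p$chrom, p$tss, p$strand, as.integer(p$clipped))
  }, character(1))
  write_fasta(seqs, path)
}

#' @export
print.promoter_seq <- function(x, ...) {
  cat(sprintf("promoter %s: %s:%d(%s), %d nt, %d masked%s\n", x$gene, x$chrom,
              x$tss, x$strand, nchar(x$seq), sum(x$masked),
              if (x$clipped) " [clipped]" else ""))
  invisible(x)
}
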