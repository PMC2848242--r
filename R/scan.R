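#' Scanning configuration (Match-style thresholds)
#'
#' @param core_threshold minimum core similarity (default 0.9)
#' @param matrix_threshold minimum matrix similarity (default 0.85)
#' @param core_len core window length (default 5)
#' @param both_strands scan the reverse strand too (default TRUE)
#' @return list of class `match_config`
#' @export
match_config <- function(core_threshold = 0.9, matrix_threshold = 0.85,
                         core_len = 5L, both_strands = TRUE) {
  stopifnot(core_threshold > 0, core_threshold <= 1,
            matrix_threshold > 0, matrix_threshold <= 1)
  structure(list(core_threshold = core_threshold,
                 matrix_threshold = matrix_threshold,
                 core_len = as.integer(core_len),
                 both_strands = isTRUE(both_strands)),
            class = "match_config")
}

# score every window of an encoded sequence against the PWM; NA where the
# window overlaps a non-ACGT base. Returns list(mss=, css=).
score_windows <- function(pwm, code) {
  w <- pwm$width
  n <- length(code) - w + 1L
  if (n < 1L) return(list(mss = numeric(0), css = numeric(0)))
  Wv <- as.vector(pwm$scoremat)               # column-major: base + 4*(j-1)
  cur <- numeric(n)
  curC <- numeric(n)
  idx <- seq_len(n)
  core <- pwm$core
  for (j in seq_len(w)) {
    s <- Wv[code[idx + j - 1L] + 4L * (j - 1L)]   # NA propagates from N
    cur <- cur + s
    if (j %in% core) curC <- curC + s
  }
  mn <- pwm$score_min; mx <- pwm$score_max
  if (mx - mn <= 0) stop_cfg("degenerate matrix '%s': no informative position", pwm$id)
  list(mss = (cur - mn) / (mx - mn),
       css = if (pwm$core_max > pwm$core_min)
         (curC - pwm$core_min) / (pwm$core_max - pwm$core_min) else rep(1, n))
}

#' Scan a promoter with one PWM
#'
#' Slides the PWM over every window on the forward strand and (by default)
#' the reverse strand, keeping windows whose core similarity and matrix
#' similarity both reach the configured thresholds. Windows containing any
#' non-ACGT base (e.g. hard-masked N) are skipped. Coordinates are reported
#' on the promoter's forward (TSS-oriented) coordinate system for both
#' strands.
#'
#' @param pwm an `lsg_pwm`
#' @param promoter DNA string (TSS-oriented); case is ignored, N skips windows
#' @param cfg a [match_config()]
#' @param promoter_id id recorded in the hit table
#' @return data.frame with columns promoter, matrix, start, end, strand,
#'   core_sim, matrix_sim (class `tfbs_hits`)
#' @export
scan_pwm <- function(pwm, promoter, cfg = match_config(), promoter_id = "promoter") {
  code <- seq_encode(promoter)
  scan_code(pwm, code, cfg, promoter_id)
}

# internal workhorse on a pre-encoded sequence (avoids re-encoding the same
# promoter for every matrix in a library scan)
scan_code <- function(pwm, code, cfg, promoter_id) {
  hit1 <- function(code, strand, L) {
    sc <- score_windows(pwm, code)
    keep <- which(!is.na(sc$mss) &
                    sc$css >= cfg$core_threshold &
                    sc$mss >= cfg$matrix_threshold)
    if (!length(keep)) return(NULL)
    w <- pwm$width
    if (strand == "+") {
      start <- keep
    } else {
      start <- L - (keep + w - 1L) + 1L   # map reverse-strand window back
    }
    data.frame(promoter = promoter_id, matrix = pwm$id,
               start = start, end = start + w - 1L, strand = strand,
               core_sim = sc$css[keep], matrix_sim = sc$mss[keep],
               stringsAsFactors = FALSE)
  }
  L <- length(code)
  out <- list(hit1(code, "+", L))
  if (cfg$both_strands) {
    out[[2]] <- hit1(rev(5L - code), "-", L)  # revcomp in code space (A<->T, C<->G)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(promoter = character(0), matrix = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), core_sim = numeric(0),
                      matrix_sim = numeric(0), stringsAsFactors = FALSE)
  }
  res <- res[order(res$start, res$end, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("tfbs_hits", "data.frame")
  res
}

#' Scan a set of promoters with a PWM library
#'
#' @param pwms `lsg_pwm_library` or list of `lsg_pwm`
#' @param promoters named character vector of DNA strings
#' @param cfg a [match_config()]
#' @return `tfbs_hits` data.frame of all hits across promoters and matrices
#' @export
scan_promoters <- function(pwms, promoters, cfg = match_config()) {
  stopifnot(!is.null(names(promoters)))
  out <- vector("list", length(promoters) * length(pwms))
  k <- 0L
  for (i in seq_along(promoters)) {
    code <- seq_encode(promoters[[i]])
    for (p in pwms) {
      k <- k + 1L
      h <- scan_code(p, code, cfg, promoter_id = names(promoters)[i])
      if (nrow(h)) out[[k]] <- h
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- scan_code(pwms[[1]], integer(0), cfg, "none")[0, ]
  }
  rownames(res) <- NULL
  class(res) <- c("tfbs_hits", "data.frame")
  res
}

#' Per-promoter TFBS presence map
#'
#' Collapses a hit table to binary presence: only a single occurrence of a
#' TFBS is counted in each promoter, regardless of strand or multiplicity.
#'
#' @param hits a `tfbs_hits` data.frame (from [scan_promoters()])
#' @param promoter_ids optional full universe of promoter ids, so promoters
#'   with zero hits appear with empty sets
#' @return named list mapping promoter id -> character vector of matrix ids
#' @export
presence_map <- function(hits, promoter_ids = NULL) {
  ids <- promoter_ids %||% unique(hits$promoter)
  m <- lapply(stats::setNames(ids, ids), function(p) {
    sort(unique(hits$matrix[hits$promoter == p]))
  })
  m
}

#' Write a hit table as TSV and (optionally) GFF3 with promoter-relative
#' coordinates
#' @param hits `tfbs_hits`
#' @param tsv_path TSV output path
#' @param gff_path optional GFF3 output path
#' @return `tsv_path`, invisibly
#' @export
write_hits <- function(hits, tsv_path, gff_path = NULL) {
  utils::write.table(hits, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(gff_path)) {
    gff <- sprintf("%s\tlsgpipe\tTF_binding_site\t%d\t%d\t%.4f\t%s\t.\tName=%s;core_sim=%.4f",
                   hits$promoter, hits$start, hits$end, hits$matrix_sim,
                   hits$strand, hits$matrix, hits$core_sim)
    writeLines(c("##gff-version 3", gff), gff_path)
  }
  invisible(tsv_path)
}
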