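#' Position weight matrix objects
#'
#' A PWM holds per-position nucleotide counts together with derived
#' per-position frequencies, the information vector
#' \eqn{I(i) = \sum_b f(i,b) \ln(4 f(i,b))} (with \eqn{0\ln 0 = 0}), and the
#' core: the 5 consecutive positions maximizing \eqn{\sum_i I(i)}.
#'
#' @param counts 4 x width numeric matrix of non-negative counts, rows A,C,G,T
#' @param id matrix accession (e.g. "M0001")
#' @param name factor name (optional)
#' @return object of class `lsg_pwm` with elements `id`, `name`, `counts`,
#'   `freq`, `info`, `core` (integer positions), `width`
#' @examples
#' m <- matrix(c(10,0,0,0, 0,10,0,0, 0,0,5,5, 0,0,0,10), nrow = 4)
#' rownames(m) <- c("A","C","G","T")
#' p <- new_pwm(m, "M0001")
#' pwm_consensus(p)
#' @export
new_pwm <- function(counts, id, name = id) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop_cfg("PWM '%s': counts must have 4 rows (A,C,G,T)", id)
  rownames(counts) <- DNA_BASES
  cs <- colSums(counts)
  if (any(cs <= 0)) {
    stop_cfg("PWM '%s': zero count sum at position(s) %s", id,
             paste(which(cs <= 0), collapse = ","))
  }
  freq <- sweep(counts, 2L, cs, "/")
  info <- pwm_information(freq)
  w <- ncol(counts)
  core <- core_positions_(info)
  # cached scan quantities: information-weighted frequencies and the
  # per-position score bounds entering the similarity denominators
  W <- sweep(freq, 2L, info, "*")
  structure(
    list(id = id, name = name, counts = counts, freq = freq,
         info = info, width = w, core = core,
         scoremat = W,
         score_min = sum(info * apply(freq, 2L, min)),
         score_max = sum(info * apply(freq, 2L, max)),
         core_min = sum(info[core] * apply(freq[, core, drop = FALSE], 2L, min)),
         core_max = sum(info[core] * apply(freq[, core, drop = FALSE], 2L, max))),
    class = "lsg_pwm")
}

# I(i) = sum_b f(i,b) * ln(4 f(i,b)), 0*ln0 = 0; in [0, ln 4]
pwm_information <- function(freq) {
  apply(freq, 2L, function(f) {
    f <- f[f > 0]
    sum(f * log(4 * f))
  })
}

core_positions_ <- function(info, core_len = 5L) {
  w <- length(info)
  if (w < core_len) return(seq_len(w))
  sums <- vapply(seq_len(w - core_len + 1L),
                 function(s) sum(info[s:(s + core_len - 1L)]), numeric(1))
  s <- which.max(sums)  # which.max takes the leftmost tie
  s:(s + core_len - 1L)
}

#' Core positions of a PWM
#'
#' The window of 5 consecutive positions maximizing the summed information
#' content; ties resolved to the leftmost window. Matrices narrower than the
#' core length use the full width (with a warning).
#'
#' @param pwm an `lsg_pwm`
#' @param core_len core window length (default 5)
#' @return integer vector of positions
#' @export
core_positions <- function(pwm, core_len = 5L) {
  if (pwm$width < core_len) {
    warning(sprintf("PWM '%s' narrower than core length %d; using full width",
                    pwm$id, core_len))
    return(seq_len(pwm$width))
  }
  core_positions_(pwm$info, core_len)
}

#' Consensus word of a PWM (highest-frequency base per position, ties -> first
#' of A,C,G,T)
#' @param pwm an `lsg_pwm`
#' @return character string of length `pwm$width`
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$freq, 2L, which.max)], collapse = "")
}

#' Matrix similarity score of a word against a PWM
#'
#' Match-convention information-weighted similarity
#' \deqn{MSS = (Current - Min)/(Max - Min)} with
#' \eqn{Current = \sum_i I(i) f(i, w_i)},
#' \eqn{Min = \sum_i I(i) \min_b f(i,b)}, \eqn{Max = \sum_i I(i) \max_b f(i,b)}.
#' Positions are optionally restricted (used for the core similarity).
#'
#' @param pwm an `lsg_pwm`
#' @param word character string over A,C,G,T with nchar equal to the PWM width
#' @param positions positions to score over (default all)
#' @return similarity in [0,1]
#' @export
mss <- function(pwm, word, positions = seq_len(pwm$width)) {
  code <- seq_encode(word)
  if (length(code) != pwm$width) stop_cfg("word length != PWM width")
  if (anyNA(code)) stop_cfg("word contains non-ACGT characters")
  info <- pwm$info[positions]
  f <- pwm$freq[, positions, drop = FALSE]
  cur <- sum(info * f[cbind(code[positions], seq_along(positions))])
  mn <- sum(info * apply(f, 2L, min))
  mx <- sum(info * apply(f, 2L, max))
  if (mx - mn <= 0) stop_cfg("degenerate matrix '%s': no informative position", pwm$id)
  (cur - mn) / (mx - mn)
}

#' Core similarity score of a word against a PWM
#' @inheritParams mss
#' @return similarity over the 5 core positions, in [0,1]
#' @export
css <- function(pwm, word) mss(pwm, word, positions = pwm$core)

#' Reverse-complement a PWM
#' @param pwm an `lsg_pwm`
#' @return the reverse-complemented `lsg_pwm`
#' @export
pwm_revcomp <- function(pwm) {
  counts <- pwm$counts[4:1, rev(seq_len(pwm$width)), drop = FALSE]
  new_pwm(counts, pwm$id, pwm$name)
}

#' @export
print.lsg_pwm <- function(x, ...) {
  cat(sprintf("PWM %s (%s), width %d, consensus %s, core %d-%d\n",
              x$id, x$name, x$width, pwm_consensus(x),
              min(x$core), max(x$core)))
  invisible(x)
}

#' Parse a TRANSFAC flat-format matrix file
#'
#' Reads AC / ID / NA records and the P0-headed count table. The column
#' order is taken from the P0 header line, so files with a non-ACGT column
#' order are normalized. Counts are preserved exactly; frequencies are
#' counts divided by the per-position row sum.
#'
#' @param path file path
#' @return list of `lsg_pwm` (class `lsg_pwm_library`)
#' @export
parse_transfac <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- split(lines, cumsum(grepl("^//", lines)))
  pwms <- list()
  for (rec in recs) {
    rec <- rec[!grepl("^//", rec)]
    acl <- grep("^AC\\s", rec, value = TRUE)
    if (length(acl) == 0) next
    ac <- sub("^AC\\s+", "", acl[1])
    nal <- grep("^NA\\s", rec, value = TRUE)
    nm <- if (length(nal)) sub("^NA\\s+", "", nal[1]) else ac
    p0 <- grep("^P0|^PO", rec)
    if (length(p0) == 0) stop_cfg("matrix '%s': missing P0 header", ac)
    hdr <- strsplit(trimws(sub("^P[0O]\\s+", "", rec[p0[1]])), "\\s+")[[1]]
    ord <- match(DNA_BASES, toupper(hdr))
    if (anyNA(ord)) stop_cfg("matrix '%s': P0 header must name A C G T", ac)
    rows <- grep("^[0-9]+\\s", rec)
    rows <- rows[rows > p0[1]]
    if (length(rows) == 0) stop_cfg("matrix '%s': no count rows", ac)
    counts <- t(vapply(rec[rows], function(l) {
      fields <- strsplit(trimws(l), "\\s+")[[1]]
      as.numeric(fields[2:5])[ord]
    }, numeric(4), USE.NAMES = FALSE))
    bad <- which(rowSums(counts) <= 0)
    if (length(bad)) stop_cfg("matrix '%s': zero row sum at position %d", ac, bad[1])
    pwms[[ac]] <- new_pwm(t(counts), ac, nm)
  }
  structure(pwms, class = "lsg_pwm_library")
}

#' Write a PWM library to TRANSFAC flat format
#' @param pwms list of `lsg_pwm` (or `lsg_pwm_library`)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_transfac <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("VV  lsgpipe PWM library", "XX", "//"), con)
  for (p in pwms) {
    writeLines(c(sprintf("AC  %s", p$id), "XX",
                 sprintf("ID  %s", p$id), "XX",
                 sprintf("NA  %s", p$name), "XX",
                 "P0      A      C      G      T"), con)
    for (i in seq_len(p$width)) {
      writeLines(sprintf("%02d %6g %6g %6g %6g %s", i,
                         p$counts[1, i], p$counts[2, i],
                         p$counts[3, i], p$counts[4, i],
                         DNA_BASES[which.max(p$freq[, i])]), con)
    }
    writeLines(c("XX", "//"), con)
  }
  invisible(path)
}

#' @export
print.lsg_pwm_library <- function(x, ...) {
  cat(sprintf("PWM library: %d matrices (widths %s)\n", length(x),
              if (length(x)) paste(range(vapply(x, `[[`, 0L, "width")),
                                   collapse = "-") else "-"))
  invisible(x)
}
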