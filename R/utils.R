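#' @keywords internal
"_PACKAGE"

# DNA alphabet used throughout; index 1..4 = A,C,G,T
DNA_BASES <- c("A", "C", "G", "T")

#' Encode a DNA string as integer codes
#'
#' A/C/G/T (either case) map to 1..4; anything else (N, gaps) to NA.
#' @param x single character string
#' @return integer vector of length nchar(x)
#' @keywords internal
seq_encode <- function(x) {
  v <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  match(v, DNA_BASES)
}

#' Reverse-complement a DNA string, preserving case
#'
#' Soft-mask (lowercase) annotation travels with the base.
#' @param x character vector of DNA strings
#' @return character vector
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("ACGTacgtNn", "TGCAtgcaNn", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Draw a random DNA sequence with a given GC fraction
#' @param n length
#' @param gc GC fraction in [0,1]
#' @return single DNA string (uppercase)
#' @keywords internal
random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# deterministic sub-seed derivation; keeps results < 2^31
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample from the values of v even when length(v) == 1 (avoids the
# sample(n, ...) scalar expansion)
sample_from <- function(v, n = 1L, replace = FALSE) {
  if (length(v) == 1L) return(rep(v, n))
  sample(v, n, replace = replace)
}

stop_cfg <- function(...) stop(sprintf(...), call. = FALSE)
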