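# Independent oracle implementations used to cross-check the package's
# primitives. These deliberately share no code with the implementation:
# scalar loops and textbook formulas only.

# hypergeometric upper-tail P(X >= k) by direct choose-sum
oracle_hyper_tail <- function(k, n, K, N) {
  total <- n + N
  succ <- k + K
  xs <- max(k, 0):min(n, succ)
  if (!length(xs) || k > min(n, succ)) return(if (k <= 0) 1 else 0)
  terms <- exp(lchoose(succ, xs) + lchoose(total - succ, n - xs) - lchoose(total, n))
  sum(terms)
}

# textbook BH step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- Inf
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- min(prev, 1)
  }
  adj
}

# textbook Pearson correlation
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# exhaustive-window PWM scan: every start, both strands, scored with the
# scalar mss()/css() entry points
oracle_scan <- function(pwm, promoter, core_threshold = 0.9,
                        matrix_threshold = 0.85) {
  L <- nchar(promoter)
  w <- pwm$width
  rc <- revcomp(promoter)
  hits <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") toupper(promoter) else toupper(rc)
    for (st in seq_len(L - w + 1L)) {
      word <- substr(s, st, st + w - 1L)
      if (grepl("[^ACGT]", word)) next
      ms <- mss(pwm, word)
      cs <- css(pwm, word)
      if (cs >= core_threshold && ms >= matrix_threshold) {
        fwd_start <- if (strand == "+") st else L - (st + w - 1L) + 1L
        hits[[length(hits) + 1L]] <- data.frame(
          start = fwd_start, end = fwd_start + w - 1L, strand = strand,
          core_sim = cs, matrix_sim = ms, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), core_sim = numeric(0),
                      matrix_sim = numeric(0)))
  }
  out <- do.call(rbind, hits)
  out[order(out$start, out$end, out$strand), , drop = FALSE]
}

# brute-force composite enumeration over all hit tuples
oracle_composites <- function(hits, arity, ordered, d_min, d_max) {
  n <- nrow(hits)
  if (n < arity) return(character(0))
  keys <- character(0)
  combs <- utils::combn(n, arity)
  for (ci in seq_len(ncol(combs))) {
    rows <- hits[combs[, ci], , drop = FALSE]
    rows <- rows[order(rows$start, rows$end), , drop = FALSE]
    if (anyDuplicated(rows$matrix)) next
    ok <- TRUE
    for (i in seq_len(arity - 1L)) {
      gap <- rows$start[i + 1L] - rows$end[i] - 1L
      if (gap < d_min || gap > d_max) { ok <- FALSE; break }
    }
    if (!ok) next
    keys <- c(keys, if (ordered) paste(rows$matrix, collapse = "*")
              else paste(sort(rows$matrix), collapse = ","))
  }
  sort(unique(keys))
}

# naive UPGMA agglomerator returning the cophenetic distance matrix
oracle_upgma_cophenetic <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  groups <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  act <- rep(TRUE, length(groups))
  dist_g <- function(a, b) {
    mean(d[groups[[a]], groups[[b]]])
  }
  while (sum(act) > 1) {
    ids <- which(act)
    best <- c(NA, NA); bd <- Inf
    for (i in ids) for (j in ids) {
      if (i >= j) next
      dd <- dist_g(i, j)
      if (dd < bd) { bd <- dd; best <- c(i, j) }
    }
    a <- best[1]; b <- best[2]
    coph[groups[[a]], groups[[b]]] <- bd
    coph[groups[[b]], groups[[a]]] <- bd
    groups[[a]] <- c(groups[[a]], groups[[b]])
    act[b] <- FALSE
  }
  coph
}

# random hit table for composite tests
random_hits <- function(n_hits, n_matrices = 6, promoter_len = 1100,
                        width_range = c(6, 14)) {
  if (n_hits == 0) {
    return(data.frame(promoter = character(0), matrix = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  w <- sample(width_range[1]:width_range[2], n_hits, replace = TRUE)
  start <- sample(promoter_len - max(w), n_hits, replace = TRUE)
  data.frame(promoter = "p1",
             matrix = sprintf("M%02d", sample(n_matrices, n_hits, replace = TRUE)),
             start = start, end = start + w - 1L,
             strand = sample(c("+", "-"), n_hits, replace = TRUE),
             stringsAsFactors = FALSE)
}

# correlated gene profiles: first `m` rows share a latent factor at rho
latent_profiles <- function(n_genes, n_samples, m, rho) {
  z <- rnorm(n_samples)
  x <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples)
  x[seq_len(m), ] <- sqrt(rho) * matrix(z, m, n_samples, byrow = TRUE) +
    sqrt(1 - rho) * x[seq_len(m), , drop = FALSE]
  rownames(x) <- sprintf("g%04d", seq_len(n_genes))
  x
}
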