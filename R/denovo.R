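#' De novo discovery configuration
#'
#' @param widths motif widths to try (default 6:16)
#' @param restarts independent sampler restarts per width (default 100)
#' @param seed RNG seed
#' @param pseudocount added to each base count when re-estimating the PWM
#'   (default 0.5)
#' @param sweeps Gibbs sweeps per restart (default 30); sampling stops early
#'   once an entire sweep changes no site
#' @param site_prior prior probability gamma that a foreground sequence
#'   carries a site (ZOOPS; default 0.99). The no-site option gets weight
#'   1 - gamma against gamma/N per window. The high default keeps sites in
#'   play during early sweeps so that motifs can nucleate in kilobase-scale
#'   promoters; lower values drop weakly supported sites more aggressively.
#' @return list of class `denovo_config`
#' @export
denovo_config <- function(widths = 6:16, restarts = 100L, seed = 1L,
                          pseudocount = 0.5, sweeps = 30L, site_prior = 0.99) {
  if (min(widths) < 4) stop_cfg("motif widths must be >= 4")
  if (restarts < 1) stop_cfg("restarts must be >= 1")
  if (site_prior <= 0 || site_prior >= 1) stop_cfg("site_prior must be in (0,1)")
  structure(list(widths = as.integer(widths), restarts = as.integer(restarts),
                 seed = as.integer(seed), pseudocount = pseudocount,
                 sweeps = as.integer(sweeps), site_prior = site_prior),
            class = "denovo_config")
}

#' 0-order background base frequencies
#'
#' Frequencies of A, C, G, T over a promoter set; N and other characters are
#' excluded from the tally.
#'
#' @param promoters character vector of sequences
#' @return named numeric vector over A,C,G,T summing to 1
#' @export
estimate_background <- function(promoters) {
  if (!length(promoters)) stop_cfg("empty background set")
  counts <- integer(4)
  for (s in promoters) {
    code <- seq_encode(s)
    counts <- counts + tabulate(code, nbins = 4L)
  }
  if (sum(counts) == 0) stop_cfg("no informative (A/C/G/T) bases in background")
  stats::setNames(counts / sum(counts), DNA_BASES)
}

# log-odds scores of all windows of an encoded sequence under pwm freq vs
# 0-order background; NA for windows overlapping non-ACGT
window_logodds <- function(code, logW) {
  w <- ncol(logW)
  n <- length(code) - w + 1L
  if (n < 1L) return(numeric(0))
  sc <- numeric(n)
  idx <- seq_len(n)
  for (j in seq_len(w)) sc <- sc + logW[cbind(code[idx + j - 1L], j)]
  sc
}

# precompute, for one encoded sequence, the (n_windows x w) matrix of linear
# indices into as.vector(logW); scoring a PWM is then one lookup + rowSums
window_index <- function(code, w) {
  n <- length(code) - w + 1L
  if (n < 1L) return(matrix(integer(0), 0L, w))
  idx <- outer(seq_len(n), 0:(w - 1L), "+")
  matrix(code[idx], n, w) + matrix(4L * (0:(w - 1L)), n, w, byrow = TRUE)
}

score_by_index <- function(lin, logW_vec) {
  if (!nrow(lin)) return(numeric(0))
  rowSums(matrix(logW_vec[lin], nrow(lin), ncol(lin)))
}

# re-estimate PWM frequencies from the currently assigned sites
sites_to_freq <- function(codes, sites, w, pseudocount) {
  counts <- matrix(pseudocount, 4L, w)
  for (i in seq_along(codes)) {
    s <- sites[i]
    if (is.na(s)) next
    win <- codes[[i]][s:(s + w - 1L)]
    counts[cbind(win, seq_len(w))] <- counts[cbind(win, seq_len(w))] + 1
  }
  sweep(counts, 2L, colSums(counts), "/")
}

#' Discriminative Gibbs motif discovery at one width
#'
#' Searches for the motif of width `width` that best separates the
#' foreground promoters from the background base composition. Each restart
#' runs a ZOOPS Gibbs sampler (zero or one site per foreground sequence; a
#' no-site option competes with every window): one sequence at a time, its
#' site is re-sampled from the posterior given the PWM re-estimated from
#' the other sequences' sites. The reported motif is the best across
#' restarts by the objective: mean foreground best-site log-odds minus mean
#' background best-site log-odds (nats), computed against the 0-order
#' background model. Deterministic given the seed.
#'
#' @param foreground character vector of >= 5 promoter sequences
#' @param background character vector of background promoters (also used to
#'   estimate the 0-order base model)
#' @param width motif width
#' @param cfg a [denovo_config()]
#' @return object of class `discovered_motif`: `freq` (4 x width), `width`,
#'   `objective`, `sites` (per-foreground start or NA), `consensus`
#' @export
discover <- function(foreground, background, width, cfg = denovo_config()) {
  if (length(foreground) < 5) stop_cfg("need >= 5 foreground sequences")
  short <- nchar(foreground) < width
  if (any(short)) {
    warning(sprintf("%d sequence(s) shorter than width %d excluded",
                    sum(short), width))
    foreground <- foreground[!short]
  }
  if (!length(foreground)) stop_cfg("no foreground sequence long enough")
  set.seed(derive_seed(cfg$seed, width))
  bg <- estimate_background(background)
  log_bg <- log(bg)
  codes <- lapply(foreground, seq_encode)
  bg_codes <- lapply(background, seq_encode)
  n <- length(codes)
  # window-index matrices make each scoring pass a single lookup + rowSums
  fg_lin <- lapply(codes, window_index, w = width)
  bg_lin <- lapply(bg_codes, window_index, w = width)
  bg_big <- do.call(rbind, bg_lin)
  bg_grp <- rep(seq_along(bg_lin), vapply(bg_lin, nrow, integer(1)))
  best <- NULL
  for (rs in seq_len(cfg$restarts)) {
    sites <- vapply(codes, function(cd) {
      nmax <- length(cd) - width + 1L
      if (nmax < 1L) NA_integer_ else sample.int(nmax, 1L)
    }, integer(1))
    # maintain site counts incrementally; counts includes the pseudocounts
    counts <- matrix(cfg$pseudocount, 4L, width)
    add_site <- function(counts, cd, s, sign) {
      if (is.na(s)) return(counts)
      win <- cd[s:(s + width - 1L)]
      counts[cbind(win, seq_len(width))] <- counts[cbind(win, seq_len(width))] + sign
      counts
    }
    for (i in seq_len(n)) counts <- add_site(counts, codes[[i]], sites[i], 1)
    for (sweep_i in seq_len(cfg$sweeps)) {
      changed <- FALSE
      for (i in seq_len(n)) {
        counts <- add_site(counts, codes[[i]], sites[i], -1)
        freq <- sweep(counts, 2L, colSums(counts), "/")
        logW <- log(freq) - log_bg  # per-base log-odds vs 0-order background
        sc <- score_by_index(fg_lin[[i]], as.vector(logW))
        ok <- which(!is.na(sc))
        # ZOOPS posterior: no-site weight (1 - gamma), window j weight
        # (gamma / N) exp(sc_j); computed on the log scale for stability
        lw <- c(log(1 - cfg$site_prior),
                log(cfg$site_prior) - log(length(ok)) + sc[ok])
        weights <- exp(lw - max(lw))
        pick <- sample.int(length(weights), 1L, prob = weights)
        new_site <- if (pick == 1L) NA_integer_ else ok[pick - 1L]
        if (!identical(new_site, sites[i])) changed <- TRUE
        sites[i] <- new_site
        counts <- add_site(counts, codes[[i]], sites[i], 1)
      }
      if (!changed) break
    }
    freq <- sites_to_freq(codes, sites, width, cfg$pseudocount)
    obj <- motif_objective_fast(freq, fg_lin, bg_big, bg_grp, log_bg)
    if (is.null(best) || obj > best$objective) {
      best <- list(freq = freq, width = width, objective = obj,
                   sites = sites)
    }
  }
  rownames(best$freq) <- DNA_BASES
  best$consensus <- paste(DNA_BASES[apply(best$freq, 2L, which.max)],
                          collapse = "")
  class(best) <- "discovered_motif"
  best
}

# objective: mean foreground best-window log-odds - mean background
# best-window log-odds, in nats
motif_objective <- function(freq, fg_codes, bg_codes, log_bg) {
  logW <- log(freq) - log_bg
  best_of <- function(cd) {
    sc <- window_logodds(cd, logW)
    sc <- sc[!is.na(sc)]
    if (!length(sc)) NA_real_ else max(sc)
  }
  mean(vapply(fg_codes, best_of, numeric(1)), na.rm = TRUE) -
    mean(vapply(bg_codes, best_of, numeric(1)), na.rm = TRUE)
}

# same objective on precomputed window-index structures
motif_objective_fast <- function(freq, fg_lin, bg_big, bg_grp, log_bg) {
  logW_vec <- as.vector(log(freq) - log_bg)
  fg_best <- vapply(fg_lin, function(lin) {
    sc <- score_by_index(lin, logW_vec)
    sc <- sc[!is.na(sc)]
    if (!length(sc)) NA_real_ else max(sc)
  }, numeric(1))
  bg_sc <- score_by_index(bg_big, logW_vec)
  ok <- !is.na(bg_sc)
  bg_best <- tapply_max(bg_sc[ok], bg_grp[ok])
  mean(fg_best, na.rm = TRUE) - mean(bg_best, na.rm = TRUE)
}

# fast grouped max for integer group labels
tapply_max <- function(x, g) {
  o <- order(g, x)                 # within each group the max comes last
  g_o <- g[o]; x_o <- x[o]
  x_o[c(g_o[-1] != g_o[-length(g_o)], TRUE)]
}

#' @export
print.discovered_motif <- function(x, ...) {
  cat(sprintf("discovered motif: width %d, consensus %s, objective %.3f nats, %d sites\n",
              x$width, x$consensus, x$objective, sum(!is.na(x$sites))))
  invisible(x)
}

#' Discover motifs over a width range
#'
#' Runs [discover()] at every width and returns the motifs ranked by
#' objective (best first).
#'
#' @inheritParams discover
#' @param cfg a [denovo_config()]; `cfg$widths` sets the range (default 6:16)
#' @return list of `discovered_motif`, ranked by objective
#' @export
discover_all <- function(foreground, background, cfg = denovo_config()) {
  if (!length(foreground)) stop_cfg("empty foreground set")
  motifs <- lapply(cfg$widths, function(w) discover(foreground, background, w, cfg))
  motifs[order(vapply(motifs, `[[`, numeric(1), "objective"), decreasing = TRUE)]
}

#' Compare a discovered PWM to a known PWM
#'
#' Aligns the query to the target over all offsets and both orientations
#' (minimum overlap 4 columns) and scores each alignment by the mean
#' Pearson correlation between aligned frequency columns. Significance is
#' an empirical p-value from shuffling the target's columns:
#' \eqn{p = (1 + \#\{shuffles \ge observed\})/(n_{shuffles}+1)}.
#'
#' @param query 4 x w frequency matrix, or `discovered_motif`, or `lsg_pwm`
#' @param target same types as `query`
#' @param n_shuffles shuffle count for the null (default 1000)
#' @param seed RNG seed
#' @param alpha significance level on the empirical p (default 0.01)
#' @return list of class `motif_match`: `score`, `offset`, `orientation`,
#'   `p`, `significant`
#' @export
pwm_compare <- function(query, target, n_shuffles = 1000L, seed = 1L,
                        alpha = 0.01) {
  qf <- as_freq_matrix(query)
  tf <- as_freq_matrix(target)
  if (ncol(qf) < 4 || ncol(tf) < 4) stop_cfg("both PWMs need >= 4 columns")
  obs <- best_alignment(qf, tf)
  set.seed(seed)
  null_scores <- vapply(seq_len(n_shuffles), function(i) {
    best_alignment(qf, tf[, sample(ncol(tf)), drop = FALSE])$score
  }, numeric(1))
  p <- (1 + sum(null_scores >= obs$score)) / (n_shuffles + 1)
  structure(list(score = obs$score, offset = obs$offset,
                 orientation = obs$orientation, p = p,
                 significant = p < alpha),
            class = "motif_match")
}

as_freq_matrix <- function(x) {
  if (inherits(x, "lsg_pwm")) return(x$freq)
  if (inherits(x, "discovered_motif")) return(x$freq)
  as.matrix(x)
}

# best aligned-column Pearson correlation over offsets/orientations.
# Aligned-column correlations are summed and normalized by the query width,
# so query columns left unaligned contribute zero: a 4-column overlap of two
# width-8 motifs can score at most 0.5 even when the overlapping columns
# match perfectly. This keeps self-matches at 1.0 while preventing
# spuriously perfect short-overlap alignments from dominating the shuffle
# null.
best_alignment <- function(qf, tf, min_overlap = 4L) {
  wq <- ncol(qf); wt <- ncol(tf)
  if (min(wq, wt) < min_overlap)
    stop_cfg("no alignment with >= %d overlapping columns", min_overlap)
  score_at <- function(qf, tf, off) {
    # offset off: query column i aligns to target column i + off
    qi <- seq_len(ncol(qf))
    ti <- qi + off
    keep <- ti >= 1 & ti <= ncol(tf)
    if (sum(keep) < min_overlap) return(NA_real_)
    cors <- vapply(which(keep), function(i) {
      a <- qf[, i]; b <- tf[, ti[i]]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
      stats::cor(a, b)
    }, numeric(1))
    sum(cors) / ncol(qf)
  }
  best <- list(score = -Inf, offset = 0L, orientation = "forward")
  for (orient in c("forward", "reverse")) {
    t2 <- if (orient == "forward") tf else tf[4:1, rev(seq_len(wt)), drop = FALSE]
    for (off in seq(-(wq - min_overlap), wt - min_overlap)) {
      s <- score_at(qf, t2, off)
      if (!is.na(s) && s > best$score) {
        best <- list(score = s, offset = off, orientation = orient)
      }
    }
  }
  best
}

#' Match discovered motifs against a PWM library
#' @param motifs list of `discovered_motif`
#' @param library `lsg_pwm_library`
#' @param ... passed to [pwm_compare()]
#' @return data.frame: motif (index), width, target, score, p, significant
#' @export
match_motifs <- function(motifs, library, ...) {
  rows <- list()
  for (mi in seq_along(motifs)) {
    for (t in library) {
      m <- pwm_compare(motifs[[mi]], t, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        motif = mi, width = motifs[[mi]]$width, target = t$id,
        score = m$score, p = m$p, significant = m$significant,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Convert a discovered motif to a PWM object
#'
#' Frequencies are scaled to integer-like counts at the given depth so the
#' motif can be written in TRANSFAC flat format or compared like any other
#' matrix.
#'
#' @param motif a `discovered_motif`
#' @param id matrix accession to assign
#' @param depth count depth (default 100)
#' @return an `lsg_pwm`
#' @export
motif_to_pwm <- function(motif, id = "DENOVO", depth = 100) {
  new_pwm(motif$freq * depth, id, name = motif$consensus)
}

#' Write discovered motifs in MEME minimal format
#' @param motifs list of `discovered_motif`
#' @param path output path
#' @param background named background frequencies (default uniform)
#' @return `path`, invisibly
#' @export
write_meme <- function(motifs, path, background = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  bg <- background %||% stats::setNames(rep(0.25, 4), DNA_BASES)
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f",
                       bg["A"], bg["C"], bg["G"], bg["T"]), ""), con)
  for (i in seq_along(motifs)) {
    m <- motifs[[i]]
    writeLines(sprintf("MOTIF denovo_%d %s", i, m$consensus), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       m$width, sum(!is.na(m$sites))), con)
    for (j in seq_len(m$width)) {
      writeLines(sprintf(" %8.6f %8.6f %8.6f %8.6f",
                         m$freq[1, j], m$freq[2, j], m$freq[3, j], m$freq[4, j]), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
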