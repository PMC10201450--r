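# Background-matched enrichment machinery: length-matched background
# sampling, 2x2 contingency enrichment scores with a ratio-of-proportions
# test, and the bootstrap ratio comparison.

#' Sample a length-matched random background
#'
#' For each sampled query interval one random interval of identical length
#' is drawn (uniform start; same chromosome when `match_chrom`, otherwise
#' a length-weighted random chromosome), rejecting draws that overlap the
#' exclusion set or contain N. Deterministic per seed.
#'
#' @param query_intervals interval data.frame.
#' @param genome named character vector (or named vector of chromosome
#'   lengths when N-checking is not needed).
#' @param n number of background intervals (default: one per query).
#' @param match_chrom keep each draw on its query's chromosome.
#' @param exclusion_set intervals the background must not overlap
#'   (typically the full query pool).
#' @param seed integer seed.
#' @param max_attempts_factor attempt budget, `max_attempts_factor * n`.
#' @return interval data.frame of background draws.
#' @export
sample_background <- function(query_intervals, genome, n = NULL,
                              match_chrom = TRUE, exclusion_set = NULL,
                              seed = 1, max_attempts_factor = 1000) {
  is_seq <- is.character(genome)
  chrom_len <- if (is_seq) vapply(genome, nchar, integer(1)) else genome
  if (is.null(n)) n <- nrow(query_intervals)
  if (n > nrow(query_intervals))
    stop("n exceeds the query pool size")
  with_seed(seed, {
    picked <- if (n == nrow(query_intervals)) seq_len(n)
              else sample.int(nrow(query_intervals), n)
    q <- query_intervals[picked, , drop = FALSE]
    excl_gr <- if (!is.null(exclusion_set) && nrow(exclusion_set) > 0)
      as_granges(exclusion_set, ignore_strand = TRUE) else NULL
    len <- q$end - q$start
    chrom <- rep(NA_character_, n)
    start <- rep(NA_integer_, n)
    todo <- seq_len(n)
    drawn <- 0
    # batch rejection sampling: redraw all unfilled slots each round
    while (length(todo) > 0) {
      if (drawn >= max_attempts_factor * n)
        stop("background sampling failed: exclusion/N constraints ",
             "unsatisfiable within the attempt budget")
      drawn <- drawn + length(todo)
      cand_chr <- if (match_chrom) q$chrom[todo] else
        sample(names(chrom_len), length(todo), replace = TRUE,
               prob = chrom_len)
      room <- chrom_len[cand_chr] - len[todo]
      if (any(room < 0))
        stop("background sampling failed: an interval is longer than ",
             "its chromosome")
      cand_s <- floor(stats::runif(length(todo), 0, room + 1))
      ok <- rep(TRUE, length(todo))
      if (!is.null(excl_gr)) {
        g <- GenomicRanges::GRanges(
          cand_chr, IRanges::IRanges(cand_s + 1L, cand_s + len[todo]))
        bad <- unique(S4Vectors::queryHits(
          GenomicRanges::findOverlaps(g, excl_gr, minoverlap = 1L)))
        ok[bad] <- FALSE
      }
      if (is_seq) {
        has_n <- vapply(which(ok), function(k) {
          grepl("N", substr(genome[[cand_chr[k]]], cand_s[k] + 1L,
                            cand_s[k] + len[todo[k]]), fixed = TRUE)
        }, logical(1))
        ok[which(ok)[has_n]] <- FALSE
      }
      chrom[todo[ok]] <- cand_chr[ok]
      start[todo[ok]] <- as.integer(cand_s[ok])
      todo <- todo[!ok]
    }
    data.frame(chrom = chrom, start = start, end = start + len,
               strand = ".", stringsAsFactors = FALSE)
  })
}

#' Flag intervals overlapping a peak set
#'
#' An interval is positive when it shares at least one nucleotide with any
#' peak; peak sets are treated as unstranded.
#'
#' @param intervals interval data.frame.
#' @param peaks interval data.frame.
#' @return logical vector along `intervals`.
#' @export
overlap_flags <- function(intervals, peaks) {
  flags <- rep(FALSE, nrow(intervals))
  flags[overlap_hits_idx(intervals, peaks)] <- TRUE
  flags
}

# exact conditional two-sided p for a 2x2 table, by enumerating the
# hypergeometric null at fixed margins (probability-mass criterion)
exact_ratio_p <- function(a, n1, b, n2) {
  m <- a + b
  lo <- max(0L, m - n2)
  hi <- min(n1, m)
  k <- lo:hi
  pk <- stats::dhyper(k, n1, n2, m)
  sum(pk[pk <= stats::dhyper(a, n1, n2, m) * (1 + 1e-7)])
}

#' Enrichment score from a 2x2 contingency table
#'
#' ES = (a/n1) / (b/n2), the ratio of positive-overlap proportions between
#' a query set and its matched background. The 95% CI uses the Katz
#' log-ratio method; the two-sided p-value is a pooled-proportion score
#' test, falling back on the exact conditional (hypergeometric) test when
#' any table cell is below 5. With b = 0 the ES is infinite and only the
#' exact p is returned.
#'
#' @param a positive query overlaps; `n1` query sample size.
#' @param b positive background overlaps; `n2` background sample size.
#' @return list(a, n1, b, n2, es, ci_lower, ci_upper, p, method).
#' @export
enrichment_score <- function(a, n1, b, n2) {
  stopifnot(n1 > 0, n2 > 0, a >= 0, b >= 0, a <= n1, b <= n2)
  p1 <- a / n1
  p2 <- b / n2
  if (b == 0) {
    return(list(a = a, n1 = n1, b = b, n2 = n2, es = Inf,
                ci_lower = NA_real_, ci_upper = NA_real_,
                p = exact_ratio_p(a, n1, b, n2), method = "exact"))
  }
  es <- p1 / p2
  ci <- if (a == 0) c(0, NA_real_) else {
    se <- sqrt(1 / a - 1 / n1 + 1 / b - 1 / n2)
    exp(log(es) + c(-1, 1) * stats::qnorm(0.975) * se)
  }
  cells <- c(a, n1 - a, b, n2 - b)
  if (any(cells < 5)) {
    p <- exact_ratio_p(a, n1, b, n2)
    method <- "exact"
  } else {
    pp <- (a + b) / (n1 + n2)
    z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    p <- 2 * stats::pnorm(-abs(z))
    method <- "score"
  }
  list(a = a, n1 = n1, b = b, n2 = n2, es = es,
       ci_lower = ci[1], ci_upper = ci[2], p = p, method = method)
}

#' Enrichment of a query interval set in a peak set
#'
#' Convenience wrapper: samples a matched background, flags overlaps on
#' both sets and scores the resulting 2x2 table.
#'
#' @param query intervals to test.
#' @param peaks peak intervals.
#' @param genome genome sequences or chromosome lengths.
#' @param n sample size per group (default: all of `query`).
#' @param match_chrom,seed passed to [sample_background()].
#' @param exclusion_set background exclusion (default: the query pool).
#' @return [enrichment_score()] result plus the background intervals.
#' @export
enrich_in_peaks <- function(query, peaks, genome, n = NULL,
                            match_chrom = TRUE, exclusion_set = query,
                            seed = 1) {
  with_seed(seed, {
    if (is.null(n)) n <- nrow(query)
    picked <- if (n == nrow(query)) seq_len(nrow(query))
              else sample.int(nrow(query), n)
    q <- query[picked, , drop = FALSE]
    bg <- sample_background(q, genome, n = n, match_chrom = match_chrom,
                            exclusion_set = exclusion_set,
                            seed = sample.int(.Machine$integer.max, 1))
    res <- enrichment_score(sum(overlap_flags(q, peaks)), n,
                            sum(overlap_flags(bg, peaks)), n)
    res$background <- bg
    res
  })
}

#' Two-sample Mann-Whitney comparison
#'
#' Exact two-sided p when both samples have at most 8 observations and no
#' ties; tie-corrected normal approximation otherwise.
#'
#' @param x,y numeric vectors.
#' @return list(U, p).
#' @export
mann_whitney <- function(x, y) {
  exact <- min(length(x), length(y)) <= 8 &&
    !anyDuplicated(c(x, y))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = !exact))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Bootstrap comparison of positive-overlap ratios
#'
#' Draws `n_samples` subsamples of `sample_size` intervals without
#' replacement from the query pool; for each, a length/chromosome-matched
#' background sample is generated with `background_sampler`. Per-sample
#' positive ratios against the peak set are compared between the two
#' groups with a two-sided Mann-Whitney test.
#'
#' @param query_pool interval data.frame (e.g. RLFS regions).
#' @param background_sampler function(sampled_query, seed) returning a
#'   matched background interval data.frame; see [sample_background()].
#' @param peaks peak intervals overlap is scored against.
#' @param n_samples number of bootstrap samples (default 100).
#' @param sample_size intervals per sample (default 1000).
#' @param seed integer seed.
#' @return list(query_ratios, background_ratios, U, p, medians).
#' @export
bootstrap_ratio_test <- function(query_pool, background_sampler, peaks,
                                 n_samples = 100, sample_size = 1000,
                                 seed = 1) {
  if (sample_size > nrow(query_pool))
    stop("sample_size exceeds the query pool")
  with_seed(seed, {
    qr <- numeric(n_samples)
    br <- numeric(n_samples)
    for (s in seq_len(n_samples)) {
      idx <- sample.int(nrow(query_pool), sample_size)
      q <- query_pool[idx, , drop = FALSE]
      bg <- background_sampler(q, sample.int(.Machine$integer.max, 1))
      qr[s] <- mean(overlap_flags(q, peaks))
      br[s] <- mean(overlap_flags(bg, peaks))
    }
    mw <- mann_whitney(qr, br)
    list(query_ratios = qr, background_ratios = br, U = mw$U, p = mw$p,
         medians = c(query = stats::median(qr),
                     background = stats::median(br)))
  })
}
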