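# Post-scan set algebra: canonical-overlap exclusion, repeat exclusion,
# strand-specific merging, and length-distribution statistics.
# "Overlap" always means >= 1 shared base under half-open arithmetic;
# book-ended intervals share nothing and are never merged.

#' Remove bulged hits that clash with canonical hits
#'
#' Drops bulged hits whose core is itself a canonical match, and bulged
#' hits sharing at least one nucleotide with a same-strand canonical hit.
#' Opposite-strand overlap never removes a hit.
#'
#' @param bs_hits,cs_hits hit data.frames (strand-resolved, same genome).
#' @return filtered bs_hits.
#' @export
exclude_vs_canonical <- function(bs_hits, cs_hits) {
  if (nrow(bs_hits) == 0) return(bs_hits)
  is_canon <- vapply(bs_hits$core_seq, function(s) {
    !is.na(s) && nrow(scan_canonical(s)) > 0
  }, logical(1))
  drop <- which(is_canon)
  drop <- union(drop, overlap_hits_idx(bs_hits, cs_hits, same_strand = TRUE))
  if (length(drop)) bs_hits[-drop, , drop = FALSE] else bs_hits
}

#' Remove hits overlapping a repeat track
#'
#' Any hit sharing at least one nucleotide with a repeat interval is
#' removed, regardless of strand (repeat annotation is treated as
#' unstranded).
#'
#' @param hits hit data.frame.
#' @param repeat_bed interval data.frame of repeats/low-complexity regions.
#' @return filtered hits.
#' @export
exclude_repeats <- function(hits, repeat_bed) {
  if (nrow(hits) == 0 || nrow(repeat_bed) == 0) return(hits)
  drop <- overlap_hits_idx(hits, repeat_bed, same_strand = FALSE)
  if (length(drop)) hits[-drop, , drop = FALSE] else hits
}

#' Merge overlapping hits into strand-specific regions
#'
#' Per strand, overlapping (>= 1 shared base) hits are consolidated into
#' one region spanning their union; book-ended hits stay separate. The
#' operation is idempotent.
#'
#' @param hits hit or interval data.frame with chrom/start/end/strand.
#' @return region data.frame with n_members (merged hit count) and models
#'   (comma-separated labels of the members, when hits carry a model).
#' @export
merge_regions <- function(hits) {
  if (nrow(hits) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      n_members = integer(), models = character(),
                      stringsAsFactors = FALSE))
  gr <- as_granges(hits)
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L, ignore.strand = FALSE)
  ov <- GenomicRanges::findOverlaps(gr, red, minoverlap = 1L,
                                    ignore.strand = FALSE)
  memb <- split(S4Vectors::queryHits(ov),
                factor(S4Vectors::subjectHits(ov),
                       levels = seq_along(red)))
  models <- if ("model" %in% names(hits)) {
    vapply(memb, function(ix)
      paste(sort(hits$model[ix]), collapse = ","), character(1))
  } else rep("", length(red))
  out <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red),
    strand = as.character(GenomicRanges::strand(red)),
    n_members = as.integer(lengths(memb)),
    models = models,
    stringsAsFactors = FALSE
  )
  out$strand[out$strand == "*"] <- "."
  sort_intervals(out)
}

#' Descriptive statistics of interval lengths
#'
#' @param items interval data.frame (lengths are end - start) or a numeric
#'   vector of lengths.
#' @return list with mean, median, mode (ties broken toward the smaller
#'   length), sd, n, and a normalized length histogram (named vector).
#' @export
length_stats <- function(items) {
  len <- if (is.data.frame(items)) items$end - items$start else items
  if (length(len) == 0) stop("length_stats needs a non-empty input")
  tab <- table(len)
  mode_val <- as.numeric(names(tab)[which.max(tab)])  # which.max: first max
  hist <- as.numeric(tab) / length(len)
  names(hist) <- names(tab)
  list(mean = mean(len), median = stats::median(len), mode = mode_val,
       sd = if (length(len) > 1) stats::sd(len) else 0,
       n = length(len), histogram = hist)
}

#' Two-sample Kolmogorov-Smirnov comparison of length distributions
#'
#' D is the supremum distance between the two empirical CDFs; the p-value
#' comes from the asymptotic Kolmogorov distribution. When `sample_n` is
#' given, both samples are first subsampled without replacement under the
#' seed (size-matched comparison).
#'
#' @param x_lengths,y_lengths numeric vectors.
#' @param sample_n optional common subsample size.
#' @param seed integer seed for the subsampling.
#' @return list(D, p, n_x, n_y).
#' @export
ks_two_sample <- function(x_lengths, y_lengths, sample_n = NULL, seed = 1) {
  stopifnot(length(x_lengths) > 0, length(y_lengths) > 0)
  if (!is.null(sample_n)) {
    if (sample_n > length(x_lengths) || sample_n > length(y_lengths))
      stop("sample_n exceeds a population size")
    with_seed(seed, {
      x_lengths <- sample(x_lengths, sample_n)
      y_lengths <- sample(y_lengths, sample_n)
    })
  }
  kt <- suppressWarnings(stats::ks.test(x_lengths, y_lengths,
                                        exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value,
       n_x = length(x_lengths), n_y = length(y_lengths))
}

#' Full motif-to-region pipeline
#'
#' scan -> canonical-overlap exclusion -> repeat exclusion (both sets) ->
#' strand-specific merging, for one genome.
#'
#' @param genome named character vector.
#' @param repeat_bed optional repeat track (may be empty).
#' @param ... scanner options passed to [scan_genome()].
#' @return list with bs_hits, cs_hits (post-exclusion) and bs_regions,
#'   cs_regions (merged).
#' @export
g4_pipeline <- function(genome, repeat_bed = NULL, ...) {
  bs <- scan_genome(genome, which = "BS", ...)
  cs <- scan_genome(genome, which = "CS")
  bs <- exclude_vs_canonical(bs, cs)
  if (!is.null(repeat_bed) && nrow(repeat_bed) > 0) {
    bs <- exclude_repeats(bs, repeat_bed)
    cs <- exclude_repeats(cs, repeat_bed)
  }
  list(bs_hits = bs, cs_hits = cs,
       bs_regions = merge_regions(bs), cs_regions = merge_regions(cs))
}
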