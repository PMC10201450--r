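#' @importFrom GenomicRanges GRanges reduce findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Construct an interval table
#'
#' Intervals are plain data.frames in BED convention: 0-based half-open
#' `[start, end)` coordinates, strand one of `"+"`, `"-"`, `"."`.
#'
#' @param chrom character chromosome names.
#' @param start,end integer 0-based half-open coordinates, `start < end`.
#' @param strand strand per interval (recycled).
#' @param name optional feature names (recycled).
#' @param score optional numeric scores (recycled).
#' @return data.frame with columns chrom, start, end, strand, name, score.
#' @export
intervals <- function(chrom, start, end, strand = ".", name = "", score = 0) {
  n <- length(chrom)
  out <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = rep_len(as.character(strand), n),
    name = rep_len(as.character(name), n),
    score = rep_len(as.numeric(score), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(out)
  out
}

validate_intervals <- function(x) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0) return(invisible(x))
  if (any(x$start < 0)) stop("negative coordinates are not allowed")
  if (any(x$start >= x$end)) stop("intervals must satisfy start < end")
  if ("strand" %in% names(x) && !all(x$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  invisible(x)
}

empty_intervals <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), name = character(), score = numeric(),
             stringsAsFactors = FALSE)
}

# BED data.frame (0-based half-open) -> GRanges (1-based closed)
as_granges <- function(x, ignore_strand = FALSE) {
  if (nrow(x) == 0) {
    return(GenomicRanges::GRanges())
  }
  strand <- if (ignore_strand || !"strand" %in% names(x)) "*" else {
    ifelse(x$strand == ".", "*", x$strand)
  }
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

# indices of `x` rows overlapping >=1 interval of `y` by >=1 base
overlap_hits_idx <- function(x, y, same_strand = FALSE) {
  if (nrow(x) == 0 || nrow(y) == 0) return(integer(0))
  gx <- as_granges(x, ignore_strand = !same_strand)
  gy <- as_granges(y, ignore_strand = !same_strand)
  ov <- GenomicRanges::findOverlaps(gx, gy, minoverlap = 1L,
                                    ignore.strand = !same_strand)
  sort(unique(S4Vectors::queryHits(ov)))
}

sort_intervals <- function(x) {
  if (nrow(x) == 0) return(x)
  x[order(x$chrom, x$start, x$end), , drop = FALSE]
}
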