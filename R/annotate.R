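# Gene-segment assignment, strand classification and anchored profiles.
#
# TSS convention: the stored tss is the gene-oriented transcript boundary
# coordinate (the 0-based start for + genes, the half-open end for -
# genes), so the promoter is always [tss - L, tss) for + genes and
# [tss, tss + L) for - genes.  The non-template strand of a gene is the
# strand carrying the mRNA-like sequence, i.e. the gene's own strand.

SEGMENT_CLASSES <- c("promoter", "utr5", "exon", "intron", "utr3")

#' Derive gene segments from gene models
#'
#' Builds, per gene: promoter (`promoter_len` bp upstream of the TSS in
#' gene orientation, clipped at chromosome edges), 5'/3' UTR (exon parts
#' outside the CDS span), coding exon parts, introns (transcript span minus
#' exons) and the transcript span itself (gene_body). All segments carry
#' the gene's strand.
#'
#' @param gene_models list(genes, exons) as from [simulate_gene_models()].
#' @param promoter_len promoter length in bp (default 2000).
#' @param chrom_lengths optional named vector for right-edge clipping.
#' @return data.frame (gene_id, segment, chrom, start, end, strand).
#' @export
build_segments <- function(gene_models, promoter_len = 2000,
                           chrom_lengths = NULL) {
  genes <- gene_models$genes
  exons <- gene_models$exons
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ex <- exons[exons$gene_id == g$gene_id, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) == 0) stop("gene without exons: ", g$gene_id)
    if (any(ex$start < g$start | ex$end > g$end))
      stop("exon outside transcript span in ", g$gene_id)
    seg <- function(segment, start, end) {
      start <- pmax(start, 0L)
      if (!is.null(chrom_lengths))
        end <- pmin(end, unname(chrom_lengths[g$chrom]))
      keep <- start < end
      if (!any(keep)) return(NULL)
      data.frame(gene_id = g$gene_id, segment = segment,
                 chrom = g$chrom, start = as.integer(start[keep]),
                 end = as.integer(end[keep]), strand = g$strand,
                 stringsAsFactors = FALSE)
    }
    prom <- if (g$strand == "+")
      seg("promoter", g$tss - promoter_len, g$tss)
    else
      seg("promoter", g$tss, g$tss + promoter_len)
    introns <- if (nrow(ex) > 1)
      seg("intron", ex$end[-nrow(ex)], ex$start[-1]) else NULL
    has_cds <- !is.null(g$cds_start) && !is.na(g$cds_start)
    if (has_cds) {
      clip <- function(s, e) {  # exon pieces inside [s, e)
        ps <- pmax(ex$start, s); pe <- pmin(ex$end, e)
        list(start = ps[ps < pe], end = pe[ps < pe])
      }
      left <- clip(g$start, g$cds_start)
      mid <- clip(g$cds_start, g$cds_end)
      right <- clip(g$cds_end, g$end)
      utr5 <- if (g$strand == "+") left else right
      utr3 <- if (g$strand == "+") right else left
      pieces <- list(seg("utr5", utr5$start, utr5$end),
                     seg("exon", mid$start, mid$end),
                     seg("utr3", utr3$start, utr3$end))
    } else {
      pieces <- list(seg("exon", ex$start, ex$end))
    }
    out[[i]] <- do.call(rbind, c(list(prom), pieces, list(introns),
                                 list(seg("gene_body", g$start, g$end))))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# region x gene overlap table over the granular classes; internal
region_gene_classes <- function(regions, segments) {
  gran <- segments[segments$segment %in% SEGMENT_CLASSES, , drop = FALSE]
  if (nrow(regions) == 0 || nrow(gran) == 0)
    return(data.frame(region = integer(), gene_id = character(),
                      segment = character(), stringsAsFactors = FALSE))
  ov <- GenomicRanges::findOverlaps(as_granges(regions, ignore_strand = TRUE),
                                    as_granges(gran, ignore_strand = TRUE),
                                    minoverlap = 1L, ignore.strand = TRUE)
  df <- data.frame(region = S4Vectors::queryHits(ov),
                   gene_id = gran$gene_id[S4Vectors::subjectHits(ov)],
                   segment = gran$segment[S4Vectors::subjectHits(ov)],
                   stringsAsFactors = FALSE)
  unique(df)
}

#' Uniquely assign regions to gene segments
#'
#' A region is assigned to a segment class of a gene iff it overlaps
#' exactly one granular class (promoter/5'UTR/exon/intron/3'UTR) of that
#' gene; regions touching several classes are dropped from segment-level
#' assignment. Orientation is sense when the region strand equals the gene
#' strand, antisense otherwise. A region overlapping two genes is assigned
#' for both genes independently.
#'
#' @param regions region data.frame (strand-resolved).
#' @param segments output of [build_segments()].
#' @return data.frame (region, gene_id, segment, orientation).
#' @export
assign_unique <- function(regions, segments) {
  df <- region_gene_classes(regions, segments)
  if (nrow(df) == 0)
    return(data.frame(region = integer(), gene_id = character(),
                      segment = character(), orientation = character(),
                      stringsAsFactors = FALSE))
  key <- paste(df$region, df$gene_id)
  nclass <- stats::ave(seq_len(nrow(df)), key, FUN = length)
  df <- df[nclass == 1, , drop = FALSE]
  gene_strand <- segments$strand[match(df$gene_id, segments$gene_id)]
  df$orientation <- ifelse(regions$strand[df$region] == gene_strand,
                           "sense", "antisense")
  rownames(df) <- NULL
  df
}

#' Gene-level summary of region-to-segment assignments
#'
#' Per segment class: sense and antisense assignment counts, the number of
#' genes with at least one assigned region, and that number as a proportion
#' of all genes. The gene_body row counts regions overlapping the
#' transcript span but not the promoter of the gene; the genic_or_promoter
#' row counts any overlap with the gene span or promoter (no uniqueness
#' filter), mirroring gene-positivity counting.
#'
#' @param regions region data.frame.
#' @param segments output of [build_segments()].
#' @param gene_models the gene models the segments came from.
#' @return data.frame (segment, sense, antisense, n_genes, prop_genes).
#' @export
gene_counts <- function(regions, segments, gene_models) {
  n_genes_all <- nrow(gene_models$genes)
  asg <- assign_unique(regions, segments)
  rows <- lapply(SEGMENT_CLASSES, function(cl) {
    d <- asg[asg$segment == cl, , drop = FALSE]
    data.frame(segment = cl, sense = sum(d$orientation == "sense"),
               antisense = sum(d$orientation == "antisense"),
               n_genes = length(unique(d$gene_id)),
               stringsAsFactors = FALSE)
  })
  # gene_body: overlaps the span, not the promoter of the same gene
  pairs <- function(class) {
    seg <- segments[segments$segment == class, , drop = FALSE]
    if (nrow(regions) == 0 || nrow(seg) == 0)
      return(data.frame(region = integer(), gene_id = character(),
                        strand = character(), stringsAsFactors = FALSE))
    ov <- GenomicRanges::findOverlaps(
      as_granges(regions, ignore_strand = TRUE),
      as_granges(seg, ignore_strand = TRUE),
      minoverlap = 1L, ignore.strand = TRUE)
    unique(data.frame(region = S4Vectors::queryHits(ov),
                      gene_id = seg$gene_id[S4Vectors::subjectHits(ov)],
                      strand = seg$strand[S4Vectors::subjectHits(ov)],
                      stringsAsFactors = FALSE))
  }
  body <- pairs("gene_body")
  prom <- pairs("promoter")
  in_prom <- paste(body$region, body$gene_id) %in%
    paste(prom$region, prom$gene_id)
  body_only <- body[!in_prom, , drop = FALSE]
  genic <- unique(rbind(body, prom))
  to_row <- function(segment, d) {
    sense <- regions$strand[d$region] == d$strand
    data.frame(segment = segment, sense = sum(sense),
               antisense = sum(!sense),
               n_genes = length(unique(d$gene_id)),
               stringsAsFactors = FALSE)
  }
  out <- rbind(to_row("genic_or_promoter", genic),
               do.call(rbind, rows[1]),               # promoter
               to_row("gene_body", body_only),
               do.call(rbind, rows[-1]))
  out$prop_genes <- out$n_genes / n_genes_all
  rownames(out) <- NULL
  out
}

#' Ratio of gene proportions between two summaries
#'
#' @param bs_counts,cs_counts outputs of [gene_counts()] for two region
#'   sets (e.g. bulged vs canonical).
#' @return `bs_counts` with an extra prop_ratio column
#'   (bs proportion / cs proportion; NA where the denominator is 0).
#' @export
proportion_ratio <- function(bs_counts, cs_counts) {
  m <- match(bs_counts$segment, cs_counts$segment)
  denom <- cs_counts$prop_genes[m]
  bs_counts$prop_ratio <- ifelse(denom > 0,
                                 bs_counts$prop_genes / denom, NA_real_)
  bs_counts
}

#' Flag regions overlapping regulatory tracks
#'
#' A region is regulatory when it shares at least one nucleotide with a
#' transcription-factor-binding-site or DNase-hypersensitive interval
#' (strand-blind).
#'
#' @param regions region data.frame.
#' @param tfbs_bed,dnase_bed interval data.frames (either may be empty).
#' @return logical vector along `regions`.
#' @export
flag_regulatory <- function(regions, tfbs_bed, dnase_bed) {
  flags <- rep(FALSE, nrow(regions))
  flags[overlap_hits_idx(regions, tfbs_bed)] <- TRUE
  flags[overlap_hits_idx(regions, dnase_bed)] <- TRUE
  flags
}

#' Classify promoter G4 occupancy per gene (back-forward pairing)
#'
#' For each gene, promoter-overlapping regions are classified by strand:
#' none / non-template only (region strand equals gene strand) / template
#' only / both. "bf" (back-forward) genes carry promoter regions on both
#' strands simultaneously.
#'
#' @param regions region data.frame.
#' @param segments output of [build_segments()].
#' @return data.frame (gene_id, n_non_template, n_template, class).
#' @export
find_bf_genes <- function(regions, segments) {
  prom <- segments[segments$segment == "promoter", , drop = FALSE]
  res <- lapply(seq_len(nrow(prom)), function(i) {
    p <- prom[i, , drop = FALSE]
    idx <- overlap_hits_idx(regions, p)
    nt <- sum(regions$strand[idx] == p$strand)
    tp <- sum(regions$strand[idx] != p$strand)
    data.frame(gene_id = p$gene_id, n_non_template = nt, n_template = tp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- do.call(rbind, lapply(split(out, out$gene_id), function(d)
    data.frame(gene_id = d$gene_id[1],
               n_non_template = sum(d$n_non_template),
               n_template = sum(d$n_template), stringsAsFactors = FALSE)))
  out$class <- with(out, ifelse(n_non_template > 0 & n_template > 0, "bf",
                    ifelse(n_non_template > 0, "non_template_only",
                    ifelse(n_template > 0, "template_only", "none"))))
  rownames(out) <- NULL
  out[match(unique(prom$gene_id), out$gene_id), , drop = FALSE]
}

#' Anchored per-nucleotide coverage profile
#'
#' For every anchor and every offset in \\[-flank, flank), the profile adds
#' one when any region base covers that genomic position (coverage
#' counting, not start counting). Offsets of minus-strand anchors run in
#' gene orientation, so profiles from opposite strands superpose. The
#' normalized track sums to one when any position is covered.
#'
#' @param regions region data.frame.
#' @param anchors data.frame (chrom, pos, strand); `pos` is the 0-based
#'   anchor coordinate (offset 0 covers the anchor base for + anchors and
#'   the base at pos-1 for - anchors, i.e. the first base in gene
#'   orientation when `pos` is a TSS-style boundary).
#' @param flank half-window size in bp (default 2000).
#' @return data.frame (offset, count, freq).
#' @export
anchored_profile <- function(regions, anchors, flank = 2000) {
  if (nrow(anchors) == 0) stop("anchored_profile needs at least one anchor")
  offsets <- seq(-flank, flank - 1)
  counts <- numeric(2 * flank)
  cov_by_chrom <- list()
  for (chr in unique(anchors$chrom)) {
    d <- regions[regions$chrom == chr, , drop = FALSE]
    cov_by_chrom[[chr]] <- if (nrow(d) == 0) NULL else {
      IRanges::coverage(IRanges::IRanges(start = d$start + 1L, end = d$end))
    }
  }
  for (i in seq_len(nrow(anchors))) {
    cov <- cov_by_chrom[[anchors$chrom[i]]]
    if (is.null(cov)) next
    pos <- anchors$pos[i]
    w <- (pos - flank + 1L):(pos + flank)  # 1-based coverage indices
    ok <- w >= 1L & w <= length(cov)
    vals <- numeric(2 * flank)
    if (any(ok)) vals[ok] <- as.numeric(cov[w[ok]] > 0)
    if (!is.null(anchors$strand) && anchors$strand[i] == "-")
      vals <- rev(vals)
    counts <- counts + vals
  }
  tot <- sum(counts)
  data.frame(offset = offsets, count = counts,
             freq = if (tot > 0) counts / tot else counts)
}

#' TSS anchor table for a set of gene models
#'
#' @param gene_models list(genes, exons).
#' @return data.frame (chrom, pos, strand) usable with
#'   [anchored_profile()].
#' @export
tss_anchors <- function(gene_models) {
  g <- gene_models$genes
  data.frame(chrom = g$chrom, pos = g$tss, strand = g$strand,
             stringsAsFactors = FALSE)
}

#' Count regions per gene within a scope
#'
#' Counts, for every gene, the regions overlapping the selected scope
#' (promoter, gene body, or their union) on the selected strand(s); a
#' region overlapping several scope windows of one gene counts once.
#'
#' @param regions region data.frame.
#' @param gene_models list(genes, exons).
#' @param scope one of "promoter", "gene_body", "promoter+gene_body".
#' @param strand_mode one of "non_template" (region strand equals gene
#'   strand), "template", "both".
#' @param promoter_len promoter length in bp.
#' @return named integer vector, one count per gene.
#' @export
counts_per_gene <- function(regions, gene_models,
                            scope = "promoter+gene_body",
                            strand_mode = "non_template",
                            promoter_len = 2000) {
  scope <- match.arg(scope, c("promoter", "gene_body",
                              "promoter+gene_body"))
  strand_mode <- match.arg(strand_mode, c("non_template", "template",
                                          "both"))
  genes <- gene_models$genes
  counts <- integer(nrow(genes))
  names(counts) <- genes$gene_id
  if (nrow(regions) == 0) return(counts)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    win <- NULL
    if (scope != "gene_body") {
      win <- rbind(win, data.frame(
        chrom = g$chrom,
        start = max(0L, if (g$strand == "+") g$tss - promoter_len
                    else g$tss),
        end = if (g$strand == "+") g$tss else g$tss + promoter_len,
        strand = g$strand, stringsAsFactors = FALSE))
    }
    if (scope != "promoter") {
      win <- rbind(win, data.frame(chrom = g$chrom, start = g$start,
                                   end = g$end, strand = g$strand,
                                   stringsAsFactors = FALSE))
    }
    win <- win[win$start < win$end, , drop = FALSE]
    idx <- overlap_hits_idx(regions, win)
    keep <- switch(strand_mode,
      non_template = regions$strand[idx] == g$strand,
      template = regions$strand[idx] != g$strand,
      both = rep(TRUE, length(idx)))
    counts[i] <- length(unique(idx[keep]))
  }
  counts
}
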