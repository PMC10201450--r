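#' @importFrom Biostrings readDNAStringSet DNAStringSet reverseComplement
#' @importFrom utils read.delim write.table
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched. All stochastic fixtures go through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Reverse complement of DNA strings
#'
#' @param x character vector over A, C, G, T, N.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read a genome from FASTA
#'
#' Sequences are uppercased and any character outside A/C/G/T/N (including
#' IUPAC ambiguity codes) is mapped to N.
#'
#' @param path path to a FASTA file (plain or gzip).
#' @return named character vector, one uppercase sequence per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop("FASTA parse error in '", path, "': ",
                             conditionMessage(e))
  )
  if (length(seqs) == 0) stop("FASTA parse error: no records in ", path)
  if (any(nchar(names(seqs)) == 0)) stop("FASTA parse error: empty header")
  out <- toupper(as.character(seqs))
  out <- gsub("[^ACGTN]", "N", out)
  names(out) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(out))) stop("duplicate sequence names in ", path)
  if (any(nchar(out) == 0)) stop("FASTA parse error: empty sequence record")
  out
}

#' Write a genome to FASTA
#'
#' @param genome named character vector of sequences.
#' @param path output path.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome)) {
    writeLines(paste0(">", nm), con)
    s <- genome[[nm]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Write intervals as BED6
#'
#' Output is sorted by (chrom, start); coordinates stay 0-based half-open.
#' The name column carries the model label when present.
#'
#' @param x interval data.frame (chrom, start, end, strand; optionally
#'   name/model and score).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  if (nrow(x) > 0) {
    validate_intervals(x)
    name <- if ("model" %in% names(x)) x$model
            else if ("name" %in% names(x) && any(nzchar(x$name))) x$name
            else "."
    score <- if ("score" %in% names(x)) x$score else 0
    out <- data.frame(chrom = x$chrom, start = x$start, end = x$end,
                      name = name, score = score, strand = x$strand,
                      stringsAsFactors = FALSE)
    out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  } else {
    out <- data.frame()
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file
#'
#' @param path path to a BED3..BED6 file.
#' @return interval data.frame; the BED name column is exposed as both
#'   `name` and `model`.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0) return(empty_intervals())
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                         comment.char = "#")
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  names(x) <- cols[seq_len(min(ncol(x), 6))]
  if (!"name" %in% names(x)) x$name <- "."
  if (!"score" %in% names(x)) x$score <- 0
  if (!"strand" %in% names(x)) x$strand <- "."
  x$model <- x$name
  validate_intervals(x)
  x
}

#' Simulate an i.i.d. random genome
#'
#' Per-base independent draws with P(G) = P(C) = gc_fraction/2 and
#' P(A) = P(T) = (1-gc_fraction)/2. Deterministic for a fixed seed.
#'
#' @param n_chrom number of chromosomes (named chr1, chr2, ...).
#' @param length length of each chromosome in bp.
#' @param gc_fraction target GC content in \\[0, 1\\].
#' @param seed integer seed.
#' @return named character vector of sequences.
#' @export
simulate_genome <- function(n_chrom, length, gc_fraction = 0.41, seed = 1) {
  if (length <= 0) stop("chromosome length must be positive")
  if (gc_fraction < 0 || gc_fraction > 1) stop("gc_fraction must be in [0,1]")
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  with_seed(seed, {
    out <- vapply(seq_len(n_chrom), function(i) {
      paste(sample(names(p), length, replace = TRUE, prob = p),
            collapse = "")
    }, character(1))
    names(out) <- paste0("chr", seq_len(n_chrom))
    out
  })
}

#' Generate a random motif string for a sequence model
#'
#' CANONICAL strings are four G-runs of >= 3 G separated by 1-7 nt loops;
#' bulged models carry the stated number of intact stems and bulges with
#' 1-3 nt loops, no contiguous cytosines in the core and at most one G per
#' loop. G1B3/G0B4 strings are negative controls: they contain at most one
#' GGG run, so no sub-decomposition can reach the two-intact-stem minimum
#' of the accepted models.
#'
#' @param model one of CANONICAL, G3B1, G3B2, G2B2, G1B3, G0B4.
#' @param seed integer seed (NULL to use the current RNG stream).
#' @return motif string.
#' @export
random_motif_string <- function(model, seed = NULL) {
  with_seed(seed, {
    loop <- function(maxlen, alphabet = c("A", "T")) {
      paste(sample(alphabet, sample.int(maxlen, 1), replace = TRUE),
            collapse = "")
    }
    bulged_stem <- function(n_bulges) {
      # one or two non-empty insertion slots, each 1-3 nt over {A,T}
      # (C avoided so fixture cores never trip the CC filter)
      slots <- c("", "")
      fill <- sample(1:2, n_bulges)
      for (i in fill) slots[i] <- loop(3, c("A", "T"))
      paste0("G", slots[1], "G", slots[2], "G")
    }
    if (model == "CANONICAL") {
      runs <- replicate(4, strrep("G", sample(3:4, 1)))
      return(paste0(runs[1], loop(7), runs[2], loop(7), runs[3], loop(7),
                    runs[4]))
    }
    layout <- switch(model,
      G3B1 = c(1, 0, 0, 0),  # bulge counts per stem (shuffled below)
      G3B2 = c(2, 0, 0, 0),
      G2B2 = c(1, 1, 0, 0),
      G1B3 = c(1, 1, 1, 0),
      G0B4 = c(1, 1, 1, 1),
      stop("unknown model: ", model))
    layout <- sample(layout)
    stems <- vapply(layout, function(b) {
      if (b == 0) "GGG" else bulged_stem(b)
    }, character(1))
    paste0(stems[1], loop(3), stems[2], loop(3), stems[3], loop(3), stems[4])
  })
}

#' Plant motif instances into a genome
#'
#' Planted windows must not overlap. Minus-strand motifs are written as the
#' reverse complement of the motif string; all bases outside the planted
#' windows are left untouched.
#'
#' @param genome named character vector of sequences.
#' @param specs data.frame with columns chrom, start, strand, model, seq.
#' @return list with `genome` (modified) and `truth` (interval data.frame of
#'   planted instances, name = model).
#' @export
plant_motifs <- function(genome, specs) {
  stopifnot(all(c("chrom", "start", "strand", "model", "seq") %in%
                  names(specs)))
  specs$end <- specs$start + nchar(specs$seq)
  for (chr in unique(specs$chrom)) {
    s <- specs[specs$chrom == chr, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
      stop("planted windows overlap on ", chr)
    if (any(s$end > nchar(genome[[chr]])))
      stop("planted motif does not fit chromosome ", chr)
  }
  for (i in seq_len(nrow(specs))) {
    chr <- specs$chrom[i]
    ins <- if (specs$strand[i] == "-") revcomp(specs$seq[i]) else specs$seq[i]
    substr(genome[[chr]], specs$start[i] + 1L, specs$end[i]) <- ins
  }
  truth <- intervals(specs$chrom, specs$start, specs$end,
                     strand = specs$strand, name = specs$model)
  truth$model <- specs$model
  list(genome = genome, truth = sort_intervals(truth))
}

#' Rewrite a genome so neither scanner reports any hit
#'
#' Iteratively scans both strands with the canonical and bulged scanners and
#' redraws every hit window over the {A, T} alphabet until a full scan is
#' clean. Used to build motif-free backgrounds for precision fixtures.
#'
#' @param genome named character vector.
#' @param max_iter iteration cap.
#' @param seed integer seed for the redraws.
#' @return motif-free genome.
#' @export
scrub_motifs <- function(genome, max_iter = 20, seed = 1) {
  with_seed(seed, {
    for (iter in seq_len(max_iter)) {
      hits <- rbind(scan_genome(genome, which = "CS"),
                    scan_genome(genome, which = "BS"))
      if (nrow(hits) == 0) return(genome)
      for (i in seq_len(nrow(hits))) {
        w <- hits$end[i] - hits$start[i]
        substr(genome[[hits$chrom[i]]], hits$start[i] + 1L, hits$end[i]) <-
          paste(sample(c("A", "T"), w, replace = TRUE), collapse = "")
      }
    }
    stop("could not scrub all motifs within ", max_iter, " iterations")
  })
}

#' Simulate gene models
#'
#' Places non-overlapping genes on both strands, each with a transcript of
#' `n_exons` exons and a CDS nested inside it so that 5'/3' UTRs exist.
#' TSS is the leftmost transcript base for + genes and the rightmost for -
#' genes. Deterministic per seed.
#'
#' @param genome named character vector (lengths taken from it).
#' @param n_genes number of genes.
#' @param n_exons exons per gene.
#' @param exon_len,intron_len typical exon/intron lengths (bp).
#' @param utr_len UTR length carved from the terminal exons (bp).
#' @param seed integer seed.
#' @return list with data.frames `genes` (gene_id, chrom, start, end,
#'   strand, tss, tts) and `exons` (gene_id, chrom, start, end, strand,
#'   exon_rank, cds_start, cds_end per gene in `genes`).
#' @export
simulate_gene_models <- function(genome, n_genes, n_exons = 3,
                                 exon_len = 300, intron_len = 500,
                                 utr_len = 100, seed = 1) {
  stopifnot(n_exons >= 1, utr_len < exon_len)
  span <- n_exons * exon_len + (n_exons - 1) * intron_len
  with_seed(seed, {
    genes <- NULL
    exons <- NULL
    chroms <- names(genome)
    # lay genes on a deterministic grid with 2.5 kb gaps (room for promoters)
    gap <- 2500
    slots <- do.call(rbind, lapply(chroms, function(chr) {
      L <- nchar(genome[[chr]])
      starts <- seq(gap, L - span - gap, by = span + gap)
      if (length(starts) == 0) return(NULL)
      data.frame(chrom = chr, start = starts, stringsAsFactors = FALSE)
    }))
    if (is.null(slots) || nrow(slots) < n_genes)
      stop("genome too small to place ", n_genes, " genes")
    slots <- slots[seq_len(n_genes), , drop = FALSE]
    strands <- rep(c("+", "-"), length.out = n_genes)[sample.int(n_genes)]
    for (i in seq_len(n_genes)) {
      g_start <- slots$start[i]
      ex_starts <- g_start + (seq_len(n_exons) - 1) * (exon_len + intron_len)
      ex <- data.frame(
        gene_id = sprintf("gene%03d", i), chrom = slots$chrom[i],
        start = ex_starts, end = ex_starts + exon_len,
        strand = strands[i], exon_rank = seq_len(n_exons),
        stringsAsFactors = FALSE
      )
      if (strands[i] == "-") ex$exon_rank <- rev(ex$exon_rank)
      g_end <- g_start + span
      genes <- rbind(genes, data.frame(
        gene_id = sprintf("gene%03d", i), chrom = slots$chrom[i],
        start = g_start, end = g_end, strand = strands[i],
        tss = if (strands[i] == "+") g_start else g_end,
        tts = if (strands[i] == "+") g_end else g_start,
        cds_start = g_start + utr_len, cds_end = g_end - utr_len,
        stringsAsFactors = FALSE
      ))
      exons <- rbind(exons, ex)
    }
    list(genes = genes, exons = exons)
  })
}

#' Read gene models from GTF/GFF
#'
#' Consumes gene/transcript/exon/CDS features. When a gene has multiple
#' transcripts the longest one is used.
#'
#' @param path GTF/GFF3 file.
#' @return list of `genes` and `exons` data.frames as in
#'   [simulate_gene_models()].
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  if (!"gene_id" %in% names(df)) stop("no gene_id attribute in ", path)
  tx <- df[df$type == "transcript" | df$type == "mRNA", , drop = FALSE]
  if (nrow(tx) == 0) tx <- df[df$type == "gene", , drop = FALSE]
  # longest transcript per gene
  tx <- tx[order(tx$gene_id, -(tx$end - tx$start)), , drop = FALSE]
  tx <- tx[!duplicated(tx$gene_id), , drop = FALSE]
  keep_tx <- if ("transcript_id" %in% names(tx)) tx$transcript_id else NULL
  ex <- df[df$type == "exon", , drop = FALSE]
  if (!is.null(keep_tx) && "transcript_id" %in% names(ex))
    ex <- ex[ex$transcript_id %in% keep_tx, , drop = FALSE]
  cds <- df[df$type == "CDS", , drop = FALSE]
  if (!is.null(keep_tx) && "transcript_id" %in% names(cds))
    cds <- cds[cds$transcript_id %in% keep_tx, , drop = FALSE]
  genes <- data.frame(
    gene_id = tx$gene_id, chrom = as.character(tx$seqnames),
    start = tx$start - 1L, end = tx$end, strand = as.character(tx$strand),
    stringsAsFactors = FALSE
  )
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  genes$tts <- ifelse(genes$strand == "+", genes$end, genes$start)
  cds_rng <- if (nrow(cds)) {
    stats::aggregate(cbind(start, end) ~ gene_id, data = cds,
                     FUN = function(v) v)
  } else NULL
  genes$cds_start <- NA_integer_
  genes$cds_end <- NA_integer_
  if (nrow(cds)) {
    agg <- do.call(rbind, lapply(split(cds, cds$gene_id), function(d) {
      data.frame(gene_id = d$gene_id[1], cds_start = min(d$start) - 1L,
                 cds_end = max(d$end), stringsAsFactors = FALSE)
    }))
    m <- match(genes$gene_id, agg$gene_id)
    genes$cds_start <- agg$cds_start[m]
    genes$cds_end <- agg$cds_end[m]
  }
  exons <- data.frame(
    gene_id = ex$gene_id, chrom = as.character(ex$seqnames),
    start = ex$start - 1L, end = ex$end, strand = as.character(ex$strand),
    stringsAsFactors = FALSE
  )
  exons <- exons[order(exons$gene_id, exons$start), , drop = FALSE]
  exons$exon_rank <- stats::ave(exons$start, exons$gene_id,
                                FUN = seq_along)
  neg <- exons$strand == "-"
  exons$exon_rank[neg] <- stats::ave(exons$start[neg], exons$gene_id[neg],
                                     FUN = function(v) rev(seq_along(v)))
  list(genes = genes, exons = exons)
}
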