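# Independent oracles and fixture builders shared by the test files.

# Brute-force enumerator of accepted bulged-G4 decompositions of a short
# string.  Written as naive per-position recursion over (stem layout x
# loop length) choices, independent of the scanner's vectorized
# stems-and-edges construction.  Returns a sorted character vector of
# signatures "start:end|s:b1:b2;..." (0-based half-open), one per
# accepted decomposition, mirroring scan_bulged's (start, end, layout)
# identity.
oracle_scan_bulged <- function(sequence, bulge_max = 3, loop_min = 1,
                               loop_max = 3) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  L <- length(chars)
  is_ins <- function(v) all(v %in% c("A", "C", "T"))
  # stem at position p (1-based) with insertion lengths (b1, b2)?
  stem_at <- function(p, b1, b2) {
    e <- p + 2 + b1 + b2
    if (e > L) return(FALSE)
    chars[p] == "G" &&
      chars[p + 1 + b1] == "G" &&
      chars[p + 2 + b1 + b2] == "G" &&
      (b1 == 0 || is_ins(chars[(p + 1):(p + b1)])) &&
      (b2 == 0 || is_ins(chars[(p + 2 + b1):(p + 1 + b1 + b2)]))
  }
  loop_ok <- function(a, b) {  # 1-based inclusive window
    v <- chars[a:b]
    all(v %in% c("A", "C", "G", "T")) && sum(v == "G") <= 1
  }
  results <- character(0)
  recurse <- function(p, stems_so_far) {
    depth <- length(stems_so_far)
    if (depth == 4) {
      first <- stems_so_far[[1]]
      last <- stems_so_far[[4]]
      s0 <- first[1]
      e0 <- last[1] + 2 + last[2] + last[3]
      nb <- sum(vapply(stems_so_far, function(x) (x[2] > 0) + (x[3] > 0),
                       numeric(1)))
      n_bulged <- sum(vapply(stems_so_far,
                             function(x) x[2] > 0 || x[3] > 0, logical(1)))
      core <- paste(chars[s0:e0], collapse = "")
      if (nb >= 1 && nb <= 2 && (4 - n_bulged) >= 2 &&
          !grepl("CC", core, fixed = TRUE)) {
        sig <- paste0(s0 - 1, ":", e0, "|",
                      paste(vapply(stems_so_far, function(x)
                        paste(x[1] - 1, x[2], x[3], sep = ":"),
                        character(1)), collapse = ";"))
        results[[length(results) + 1]] <<- sig
      }
      return(invisible())
    }
    for (b1 in 0:bulge_max) for (b2 in 0:bulge_max) {
      if (!stem_at(p, b1, b2)) next
      stem <- c(p, b1, b2)
      e <- p + 2 + b1 + b2  # last stem base, 1-based
      if (depth == 3) {
        recurse_done <- recurse(NA, c(stems_so_far, list(stem)))
      } else {
        for (l in loop_min:loop_max) {
          nxt <- e + l + 1
          if (nxt > L || !loop_ok(e + 1, e + l)) next
          recurse(nxt, c(stems_so_far, list(stem)))
        }
      }
    }
    invisible()
  }
  for (p in seq_len(L)) recurse(p, list())
  sort(unique(results))
}

scanner_signatures <- function(hits) {
  if (nrow(hits) == 0) return(character(0))
  sort(unique(paste0(hits$start, ":", hits$end, "|", hits$layout)))
}

# random test sequence; G-biased so stems actually occur
random_seq <- function(len, probs = c(A = 0.25, C = 0.15, G = 0.40,
                                      T = 0.20)) {
  paste(sample(names(probs), len, replace = TRUE, prob = probs),
        collapse = "")
}

# exact two-sided p for a 2x2 table by explicit hypergeometric
# enumeration with choose() (probability-mass criterion)
oracle_exact_p <- function(a, n1, b, n2) {
  m <- a + b
  ks <- max(0, m - n2):min(n1, m)
  pk <- choose(n1, ks) * choose(n2, m - ks) / choose(n1 + n2, m)
  p_obs <- choose(n1, a) * choose(n2, m - a) / choose(n1 + n2, m)
  sum(pk[pk <= p_obs * (1 + 1e-7)])
}

# A scrubbed genome with planted motifs of the given models, each motif
# isolated by `pad` bases of A/T so chains cannot recruit background Gs.
# Returns list(genome, truth).
make_planted_genome <- function(chrom_len = 50000, n_per_model = 5,
                                models = c("CANONICAL", "G3B1", "G3B2",
                                           "G2B2", "G1B3", "G0B4"),
                                pad = 20, seed = 42) {
  genome <- simulate_genome(1, chrom_len, gc_fraction = 0.41, seed = seed)
  genome <- scrub_motifs(genome, seed = seed + 1)
  specs <- NULL
  withr::with_seed(seed + 2, {
    motifs <- expand.grid(model = models,
                          rep = seq_len(n_per_model),
                          stringsAsFactors = FALSE)
    motifs$seq <- vapply(motifs$model, random_motif_string, character(1))
    motifs$strand <- sample(c("+", "-"), nrow(motifs), replace = TRUE)
    slot_w <- floor(chrom_len / nrow(motifs))
    stopifnot(slot_w > max(nchar(motifs$seq)) + 2 * pad + 10)
    offs <- sample.int(slot_w - max(nchar(motifs$seq)) - 2 * pad - 1,
                       nrow(motifs), replace = TRUE)
    motifs$start <- (seq_len(nrow(motifs)) - 1) * slot_w + offs + pad
    specs <- data.frame(chrom = "chr1", start = motifs$start,
                        strand = motifs$strand, model = motifs$model,
                        seq = motifs$seq, stringsAsFactors = FALSE)
  })
  # pads: overwrite the flanks of each planted window with A/T
  pad_specs <- specs
  pad_specs$seq <- vapply(nchar(specs$seq), function(w)
    strrep("A", w + 2 * pad), character(1))
  pad_specs$start <- specs$start - pad
  pad_specs$model <- "PAD"
  padded <- plant_motifs(genome, pad_specs)
  plant_motifs(padded$genome, specs)
}

# small two-gene annotation fixture used across annotate tests:
# one + gene and one - gene with known coordinates
toy_gene_models <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB"),
    chrom = "chr1",
    start = c(5000L, 20000L),
    end = c(8000L, 23000L),
    strand = c("+", "-"),
    tss = c(5000L, 23000L),
    tts = c(8000L, 20000L),
    cds_start = c(5200L, 20200L),
    cds_end = c(7800L, 22800L),
    stringsAsFactors = FALSE
  )
  exons <- data.frame(
    gene_id = rep(c("gA", "gB"), each = 2),
    chrom = "chr1",
    start = c(5000L, 7000L, 20000L, 22000L),
    end = c(6000L, 8000L, 21000L, 23000L),
    strand = rep(c("+", "-"), each = 2),
    exon_rank = c(1L, 2L, 2L, 1L),
    stringsAsFactors = FALSE
  )
  list(genes = genes, exons = exons)
}
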