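# Motif grammar
# ------------
# A bulged-G4 candidate is four G-stems joined by three loops of
# loop_min..loop_max bases.  Each stem holds exactly three tetrad guanines
# G[I_x]G[I_x]G, where each insertion slot I is 0-3 bases over {A,C,T}; a
# non-empty slot is one bulge.  Accepted hits have at least two intact
# stems (no insertion), at most two bulges in total, at most one G per
# loop, and no CC dinucleotide anywhere in the core.  The three retained
# models are G3B1 (3 intact stems / 1 bulge), G3B2 (3 intact / 2 bulges,
# necessarily in one stem) and G2B2 (2 intact / 2 bulges in two stems).
# A canonical candidate is four maximal G-runs of >= 3 G joined by loops
# of 1-7 bases.  N never matches any motif position.

BS_MODELS <- c("G3B1", "G3B2", "G2B2")

empty_hits <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), model = character(),
             n_intact_stems = integer(), n_bulges = integer(),
             bulge_seqs = character(), loops = character(),
             core_seq = character(), layout = character(),
             stringsAsFactors = FALSE)
}

# enumerate all single-stem matches; returns data.frame
# (s = 1-based start, len, b1, b2, nb = number of non-empty slots)
find_stems <- function(chars, bulge_max) {
  L <- length(chars)
  if (L < 3) return(data.frame(s = integer(), len = integer(),
                               b1 = integer(), b2 = integer(),
                               nb = integer()))
  isG <- chars == "G"
  isI <- chars %in% c("A", "C", "T")
  cumI <- c(0L, cumsum(isI))
  out <- vector("list", (bulge_max + 1)^2)
  k <- 0
  for (b1 in 0:bulge_max) for (b2 in 0:bulge_max) {
    len <- 3L + b1 + b2
    if (len > L) next
    s <- seq_len(L - len + 1L)
    ok <- isG[s] & isG[s + 1L + b1] & isG[s + 2L + b1 + b2]
    if (b1 > 0) ok <- ok & (cumI[s + b1 + 1L] - cumI[s + 1L]) == b1
    if (b2 > 0) ok <- ok & (cumI[s + 2L + b1 + b2] - cumI[s + 2L + b1]) == b2
    s <- s[ok]
    if (length(s)) {
      k <- k + 1
      out[[k]] <- data.frame(s = s, len = len, b1 = b1, b2 = b2,
                             nb = (b1 > 0) + (b2 > 0))
    }
  }
  if (k == 0) return(data.frame(s = integer(), len = integer(),
                                b1 = integer(), b2 = integer(),
                                nb = integer()))
  res <- do.call(rbind, out[seq_len(k)])
  res[order(res$s, res$len), , drop = FALSE]
}

# stem-to-stem adjacency under the loop rule; returns data.frame (i, j)
stem_edges <- function(stems, chars, loop_min, loop_max, max_loop_g = 1) {
  n <- nrow(stems)
  if (n == 0) return(data.frame(i = integer(), j = integer()))
  isG <- chars == "G"
  isN <- !(chars %in% c("A", "C", "G", "T"))
  cumG <- c(0L, cumsum(isG))
  cumN <- c(0L, cumsum(isN))
  ends <- stems$s + stems$len  # first position after the stem, 1-based
  by_start <- split(seq_len(n), stems$s)
  res <- vector("list", loop_max - loop_min + 1)
  for (l in loop_min:loop_max) {
    key <- ends + l
    # loop window is [ends, ends + l - 1]; must be N-free with <= 1 G
    loop_ok <- (cumN[pmin(key, length(cumN))] - cumN[ends]) == 0 &
      (cumG[pmin(key, length(cumG))] - cumG[ends]) <= max_loop_g &
      key <= length(chars) + 1L
    idx <- which(loop_ok)
    m <- by_start[as.character(key[idx])]
    lens <- lengths(m)
    keep <- lens > 0
    res[[l - loop_min + 1]] <- data.frame(
      i = rep(idx[keep], lens[keep]),
      j = unlist(m[keep], use.names = FALSE)
    )
  }
  do.call(rbind, res)
}

#' Scan a sequence for bulged-G4 motifs
#'
#' Enumerates every four-stem placement under the bulged grammar, applies
#' the acceptance filters ([apply_bs_filters()]) and labels each hit with
#' its model ([classify_model()]). All valid placements are reported (stems
#' may be shared between hits); rows are unique by (start, end, stem/bulge
#' layout). All-intact placements are canonical, not bulged, and are not
#' reported here.
#'
#' @param sequence a single DNA string over A/C/G/T/N.
#' @param bulge_max maximum insertion length per slot (default 3).
#' @param loop_min,loop_max loop length bounds (defaults 1 and 3).
#' @return hit data.frame with columns chrom (NA here), start, end (0-based
#'   half-open), strand, model, n_intact_stems, n_bulges, bulge_seqs,
#'   loops, core_seq, layout.
#' @export
scan_bulged <- function(sequence, bulge_max = 3, loop_min = 1,
                        loop_max = 3) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  stems <- find_stems(chars, bulge_max)
  if (nrow(stems) < 4) return(empty_hits())
  edges <- stem_edges(stems, chars, loop_min, loop_max)
  if (nrow(edges) == 0) return(empty_hits())
  nb <- stems$nb
  # grow chains left to right, pruning on the two-bulge budget
  p2 <- edges[nb[edges$i] + nb[edges$j] <= 2, , drop = FALSE]
  names(p2) <- c("a", "b")
  p3 <- merge(p2, edges, by.x = "b", by.y = "i")
  names(p3)[names(p3) == "j"] <- "c"
  p3 <- p3[nb[p3$a] + nb[p3$b] + nb[p3$c] <= 2, , drop = FALSE]
  if (nrow(p3) == 0) return(empty_hits())
  p4 <- merge(p3, edges, by.x = "c", by.y = "i")
  names(p4)[names(p4) == "j"] <- "d"
  tot <- nb[p4$a] + nb[p4$b] + nb[p4$c] + nb[p4$d]
  p4 <- p4[tot <= 2 & tot >= 1, , drop = FALSE]
  if (nrow(p4) == 0) return(empty_hits())
  build_bs_hits(p4[, c("a", "b", "c", "d")], stems, chars)
}

# assemble, filter (CC rule) and annotate accepted chains
build_bs_hits <- function(chains, stems, chars) {
  seqstr <- paste(chars, collapse = "")
  idx <- as.matrix(chains)
  s1 <- stems$s[idx[, 1]]
  e4 <- stems$s[idx[, 4]] + stems$len[idx[, 4]]  # 1-based exclusive
  core <- substring(seqstr, s1, e4 - 1L)
  keep <- !grepl("CC", core, fixed = TRUE)
  if (!any(keep)) return(empty_hits())
  idx <- idx[keep, , drop = FALSE]
  s1 <- s1[keep]; e4 <- e4[keep]; core <- core[keep]
  n <- nrow(idx)
  stem_nb <- matrix(stems$nb[idx], ncol = 4)
  n_bulged_stems <- rowSums(stem_nb > 0)
  n_intact <- 4L - n_bulged_stems
  n_bulges <- rowSums(stem_nb)
  model <- classify_layout(n_intact, n_bulges, n_bulged_stems)
  loops <- character(n)
  bulges <- character(n)
  layout <- character(n)
  for (r in seq_len(n)) {
    st <- idx[r, ]
    ls <- stems$s[st] + stems$len[st]          # loop starts (1-based)
    le <- stems$s[st][-1] - 1L                 # loop ends
    loops[r] <- paste(substring(seqstr, ls[-4], le), collapse = ",")
    bs <- character(0)
    for (k in st) {
      p <- stems$s[k]
      if (stems$b1[k] > 0)
        bs <- c(bs, substring(seqstr, p + 1L, p + stems$b1[k]))
      if (stems$b2[k] > 0)
        bs <- c(bs, substring(seqstr, p + 2L + stems$b1[k],
                              p + 1L + stems$b1[k] + stems$b2[k]))
    }
    bulges[r] <- paste(bs, collapse = ",")
    layout[r] <- paste(stems$s[st] - 1L, stems$b1[st], stems$b2[st],
                       sep = ":", collapse = ";")
  }
  out <- data.frame(
    chrom = NA_character_, start = s1 - 1L, end = e4 - 1L,
    strand = "+", model = model, n_intact_stems = n_intact,
    n_bulges = n_bulges, bulge_seqs = bulges, loops = loops,
    core_seq = core, layout = layout, stringsAsFactors = FALSE
  )
  out <- out[out$model %in% BS_MODELS, , drop = FALSE]
  out[order(out$start, out$end, out$layout), , drop = FALSE]
}

classify_layout <- function(n_intact, n_bulges, n_bulged_stems) {
  ifelse(n_intact == 4 & n_bulges == 0, "CANONICAL",
  ifelse(n_intact == 3 & n_bulges == 1, "G3B1",
  ifelse(n_intact == 3 & n_bulges == 2 & n_bulged_stems == 1, "G3B2",
  ifelse(n_intact == 2 & n_bulges == 2 & n_bulged_stems == 2, "G2B2",
         "REJECTED"))))
}

#' Classify a scanned hit into a sequence model
#'
#' GxBy labels: x = number of intact G-stems, y = number of bulges. Four
#' intact stems with no insertion signal a canonical match ("CANONICAL");
#' layouts outside the three retained models return "REJECTED".
#'
#' @param hit a single row from [scan_bulged()] (or a list with
#'   n_intact_stems and n_bulges; the bulged-stem count is derived).
#' @return one of "G3B1", "G3B2", "G2B2", "CANONICAL", "REJECTED".
#' @export
classify_model <- function(hit) {
  ni <- hit$n_intact_stems
  nbul <- hit$n_bulges
  classify_layout(ni, nbul, 4L - ni)
}

#' Acceptance filters for bulged-G4 candidates
#'
#' Rejects a candidate when it has more than two bulges, fewer than two
#' intact stems, any loop with more than one G, a CC dinucleotide in the
#' core, or an insertion/loop length out of bounds. The filters apply to
#' the match core only, never to flanking bases.
#'
#' @param hit one hit row (as produced by [scan_bulged()]).
#' @param loop_min,loop_max,bulge_max bounds used for the length checks.
#' @return list(accept = logical, reason = character); reason is "ok" on
#'   acceptance, otherwise one of too_many_bulges, too_few_intact_stems,
#'   g_rich_loop, contiguous_cytosines, bad_loop_length, bad_bulge_length.
#' @export
apply_bs_filters <- function(hit, loop_min = 1, loop_max = 3,
                             bulge_max = 3) {
  loops <- strsplit(hit$loops, ",", fixed = TRUE)[[1]]
  bulges <- if (nzchar(hit$bulge_seqs))
    strsplit(hit$bulge_seqs, ",", fixed = TRUE)[[1]] else character(0)
  reject <- function(reason) list(accept = FALSE, reason = reason)
  if (hit$n_bulges > 2) return(reject("too_many_bulges"))
  if (hit$n_intact_stems < 2) return(reject("too_few_intact_stems"))
  if (any(vapply(gregexpr("G", loops, fixed = TRUE),
                 function(m) sum(m > 0), numeric(1)) > 1))
    return(reject("g_rich_loop"))
  if (grepl("CC", hit$core_seq, fixed = TRUE))
    return(reject("contiguous_cytosines"))
  if (any(nchar(loops) < loop_min | nchar(loops) > loop_max))
    return(reject("bad_loop_length"))
  if (length(bulges) && any(nchar(bulges) < 1 | nchar(bulges) > bulge_max))
    return(reject("bad_bulge_length"))
  list(accept = TRUE, reason = "ok")
}

#' Scan a sequence for canonical G4 motifs
#'
#' Four maximal G-runs of at least `min_stem` guanines separated by loops
#' of `loop_min`-`loop_max` bases. Every window of four consecutive
#' candidate runs is enumerated (runs may be shared between hits); hits
#' are unique by coordinates.
#'
#' @param sequence a single DNA string.
#' @param min_stem minimum G-run length (default 3).
#' @param loop_min,loop_max loop bounds (defaults 1 and 7).
#' @return hit data.frame in the same layout as [scan_bulged()].
#' @export
scan_canonical <- function(sequence, min_stem = 3, loop_min = 1,
                           loop_max = 7) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (length(chars) < 4 * min_stem + 3 * loop_min) return(empty_hits())
  isG <- chars == "G"
  isN <- !(chars %in% c("A", "C", "G", "T"))
  r <- rle(isG)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  keep <- r$values & r$lengths >= min_stem
  rs <- run_start[keep]; re <- run_end[keep]  # 1-based inclusive
  nr <- length(rs)
  if (nr < 4) return(empty_hits())
  cumN <- c(0L, cumsum(isN))
  gap_ok <- function(i, j) {  # loop between run i end and run j start
    g <- rs[j] - re[i] - 1L
    g >= loop_min & g <= loop_max &
      (cumN[rs[j]] - cumN[re[i] + 1L]) == 0
  }
  i <- seq_len(nr - 3)
  ok <- gap_ok(i, i + 1) & gap_ok(i + 1, i + 2) & gap_ok(i + 2, i + 3)
  i <- i[ok]
  if (length(i) == 0) return(empty_hits())
  seqstr <- paste(chars, collapse = "")
  loops <- paste(substring(seqstr, re[i] + 1L, rs[i + 1] - 1L),
                 substring(seqstr, re[i + 1] + 1L, rs[i + 2] - 1L),
                 substring(seqstr, re[i + 2] + 1L, rs[i + 3] - 1L),
                 sep = ",")
  data.frame(
    chrom = NA_character_, start = rs[i] - 1L, end = re[i + 3],
    strand = "+", model = "CANONICAL", n_intact_stems = 4L,
    n_bulges = 0L, bulge_seqs = "", loops = loops,
    core_seq = substring(seqstr, rs[i], re[i + 3]),
    layout = paste(rs[i] - 1L, re[i + 3], sep = ":"),
    stringsAsFactors = FALSE
  )
}

#' Scan a whole genome on both strands
#'
#' The forward sequence yields + strand hits; the reverse complement is
#' scanned for - strand hits, which are reported in forward genomic
#' coordinates (core_seq/loops/bulges stay in the motif's own 5'->3'
#' orientation).
#'
#' @param genome named character vector of chromosome sequences.
#' @param which "BS" (bulged models) or "CS" (canonical).
#' @param ... passed to [scan_bulged()] or [scan_canonical()].
#' @return sorted hit data.frame with genomic chrom/start/end/strand.
#' @export
scan_genome <- function(genome, which = c("BS", "CS"), ...) {
  which <- match.arg(which)
  scan1 <- if (which == "BS") scan_bulged else scan_canonical
  res <- lapply(names(genome), function(chr) {
    s <- genome[[chr]]
    L <- nchar(s)
    fwd <- scan1(s, ...)
    if (nrow(fwd)) {
      fwd$chrom <- chr
      fwd$strand <- "+"
    }
    rev <- scan1(revcomp(s), ...)
    if (nrow(rev)) {
      rev$chrom <- chr
      rev$strand <- "-"
      new_start <- L - rev$end
      rev$end <- L - rev$start
      rev$start <- new_start
    }
    rbind(fwd, rev)
  })
  out <- do.call(rbind, res)
  if (is.null(out) || nrow(out) == 0) return(empty_hits())
  out[order(out$chrom, out$start, out$end, out$strand, out$layout), ,
      drop = FALSE]
}

#' Pick the best-ranked hit of a scanned sequence
#'
#' When several decompositions are accepted the preferred label follows
#' the fixed order G3B1 > G3B2 > G2B2 (fewest bulges, most intact stems:
#' fewer bulges imply higher structural stability).
#'
#' @param hits hit data.frame from [scan_bulged()].
#' @return the single top-ranked row (or NULL when empty).
#' @export
best_bs_hit <- function(hits) {
  if (nrow(hits) == 0) return(NULL)
  rank <- match(hits$model, BS_MODELS)
  ord <- order(rank, hits$n_bulges, -(hits$end - hits$start), hits$start)
  hits[ord[1], , drop = FALSE]
}
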