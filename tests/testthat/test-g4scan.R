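# Worked examples: four experimentally validated bulged-G4 sequences
# (flanking dinucleotides included) with their published stem/bulge
# annotation, plus canonical-scanner basics.

test_that("validated promoter/intron sequences reproduce their published
           stem and bulge annotation", {
  ex <- bulged_g4_examples()
  for (i in seq_len(nrow(ex))) {
    best <- best_bs_hit(scan_bulged(ex$sequence[i]))
    expect_false(is.null(best), info = ex$id[i])
    expect_equal(best$model, ex$model[i], info = ex$id[i])
    expect_equal(best$n_intact_stems, ex$n_intact_stems[i],
                 info = ex$id[i])
    expect_equal(best$n_bulges, ex$n_bulges[i], info = ex$id[i])
    expect_equal(best$bulge_seqs, ex$bulges[i], info = ex$id[i])
  }
})

test_that("canonical scanner enumerates consecutive run windows", {
  one <- scan_canonical("GGGAGGGAGGGAGGG")
  expect_equal(nrow(one), 1)
  expect_equal(c(one$start, one$end), c(0, 15))

  expect_equal(nrow(scan_canonical("ATATATAT")), 0)

  # five G-runs: windows 1-4 and 2-5 share three runs
  two <- scan_canonical("GGGAGGGAGGGAGGGAGGG")
  expect_equal(nrow(two), 2)
  expect_equal(two$start, c(0, 4))
  expect_equal(two$end, c(15, 19))

  # loops above 7 nt break the chain
  expect_equal(nrow(scan_canonical(
    paste0("GGGAGGG", strrep("T", 8), "GGGAGGG"))), 0)
})

test_that("bulged-candidate filters reject on the stated reasons", {
  ex <- bulged_g4_examples()
  bs33 <- best_bs_hit(scan_bulged(ex$sequence[ex$id == "BS33"]))
  expect_true(apply_bs_filters(bs33)$accept)

  # contiguous cytosines in the core (not in the flanks) reject
  fake <- bs33
  fake$core_seq <- sub("^GAGG", "GCCG", fake$core_seq)
  expect_equal(apply_bs_filters(fake)$reason, "contiguous_cytosines")
  # ... but a CC flank does not (the EGR1 example ends with flank CC)
  bs15 <- best_bs_hit(scan_bulged("CTGAGGTGGGCGGGCGGGCC"))
  expect_equal(bs15$model, "G3B1")

  fake <- bs33; fake$n_bulges <- 3L
  expect_equal(apply_bs_filters(fake)$reason, "too_many_bulges")
  fake <- bs33; fake$n_intact_stems <- 1L
  expect_equal(apply_bs_filters(fake)$reason, "too_few_intact_stems")
  fake <- bs33; fake$loops <- "GG,A,A"
  expect_equal(apply_bs_filters(fake)$reason, "g_rich_loop")
  fake <- bs33; fake$loops <- "AAAA,A,A"
  expect_equal(apply_bs_filters(fake)$reason, "bad_loop_length")

  expect_gt(nrow(scan_bulged("GAGGAGGGAGGGAGGGA")), 0)
})

test_that("model classification follows the GxBy rule", {
  expect_equal(classify_model(list(n_intact_stems = 3, n_bulges = 1)),
               "G3B1")
  expect_equal(classify_model(list(n_intact_stems = 3, n_bulges = 2)),
               "G3B2")
  expect_equal(classify_model(list(n_intact_stems = 2, n_bulges = 2)),
               "G2B2")
  expect_equal(classify_model(list(n_intact_stems = 4, n_bulges = 0)),
               "CANONICAL")
  expect_equal(classify_model(list(n_intact_stems = 1, n_bulges = 3)),
               "REJECTED")
})

test_that("scanner agrees with the brute-force oracle on short strings", {
  ex <- bulged_g4_examples()
  for (s in ex$sequence)
    expect_identical(scanner_signatures(scan_bulged(s)),
                     oracle_scan_bulged(s))
  withr::with_seed(101, {
    for (r in 1:120) {
      s <- random_seq(sample(15:60, 1))
      expect_identical(scanner_signatures(scan_bulged(s)),
                       oracle_scan_bulged(s), info = s)
    }
  })
})

test_that("both scanners are strand symmetric", {
  withr::with_seed(77, {
    for (r in 1:40) {
      s <- random_seq(80)
      g <- c(chr1 = s)
      for (w in c("BS", "CS")) {
        hits <- scan_genome(g, w)
        mirr <- scan_genome(c(chr1 = revcomp(s)), w)
        # mirror-map: (start, end, strand) -> (L-end, L-start, flip)
        remap <- data.frame(start = 80 - mirr$end, end = 80 - mirr$start,
                            strand = ifelse(mirr$strand == "+", "-", "+"))
        expect_setequal(paste(hits$start, hits$end, hits$strand),
                        paste(remap$start, remap$end, remap$strand))
      }
    }
  })
})

test_that("accepted hits obey the core invariants", {
  withr::with_seed(55, {
    for (r in 1:30) {
      s <- random_seq(120)
      hits <- scan_bulged(s)
      if (nrow(hits) == 0) next
      expect_false(any(grepl("CC", hits$core_seq, fixed = TRUE)))
      # exactly 12 tetrad guanines: core G count = 12 + loop Gs
      loop_g <- vapply(gregexpr("G", hits$loops), function(m)
        sum(m > 0), numeric(1))
      core_g <- vapply(gregexpr("G", hits$core_seq), function(m)
        sum(m > 0), numeric(1))
      expect_equal(core_g - loop_g, rep(12, nrow(hits)))
      expect_true(all(hits$n_bulges >= 1 & hits$n_bulges <= 2))
      expect_true(all(hits$n_intact_stems >= 2))
      expect_true(all(hits$model %in% c("G3B1", "G3B2", "G2B2")))
      # bulge strings consistent with the bulge count
      nb_str <- lengths(strsplit(hits$bulge_seqs, ",", fixed = TRUE))
      expect_equal(nb_str, hits$n_bulges)
    }
  })
})

test_that("tightening loop_max only removes hits", {
  withr::with_seed(31, {
    for (r in 1:20) {
      s <- random_seq(100)
      h3 <- scanner_signatures(scan_bulged(s, loop_max = 3))
      h2 <- scanner_signatures(scan_bulged(s, loop_max = 2))
      expect_true(all(h2 %in% h3))
    }
  })
})

test_that("N never matches any motif position", {
  expect_equal(nrow(scan_bulged("GAGGNGGGAGGGAGGGA")), 0)  # N loop
  expect_gt(nrow(scan_bulged("GAGGAGGGAGGGAGGGA")), 0)
  expect_equal(nrow(scan_canonical("GGGNGGGAGGGAGGG")), 0)
  expect_equal(nrow(scan_bulged("GNGGAGGGAGGGAGGGA")), 0)  # N bulge
})

test_that("minus-strand hits come back in forward coordinates", {
  bs33 <- "TAGAGGCGGGAGTGGAGGGCG"
  pad <- strrep("T", 30)
  g <- c(chrZ = paste0(pad, revcomp(bs33), pad))
  hits <- scan_genome(g, "BS")
  best <- best_bs_hit(hits)
  expect_equal(best$strand, "-")
  expect_equal(best$model, "G2B2")
  # published core occupies positions 2..19 of the 21-mer
  expect_equal(best$start, 30 + (21 - 19))
  expect_equal(best$end, 30 + (21 - 2))
  # scanning twice is deterministic
  expect_identical(hits, scan_genome(g, "BS"))
})
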