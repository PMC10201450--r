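test_that("promoters are gene-oriented and clipped at the chromosome", {
  gm <- toy_gene_models()
  segs <- build_segments(gm)
  promA <- segs[segs$gene_id == "gA" & segs$segment == "promoter", ]
  expect_equal(c(promA$start, promA$end), c(3000, 5000))  # + gene
  promB <- segs[segs$gene_id == "gB" & segs$segment == "promoter", ]
  expect_equal(c(promB$start, promB$end), c(23000, 25000))  # - gene

  near_edge <- gm
  near_edge$genes <- near_edge$genes[1, ]
  near_edge$genes$start <- 500L; near_edge$genes$end <- 3500L
  near_edge$genes$tss <- 500L; near_edge$genes$tts <- 3500L
  near_edge$genes$cds_start <- 700L; near_edge$genes$cds_end <- 3300L
  near_edge$exons <- data.frame(gene_id = "gA", chrom = "chr1",
                                start = 500L, end = 3500L, strand = "+",
                                exon_rank = 1L)
  clipped <- build_segments(near_edge)
  prom <- clipped[clipped$segment == "promoter", ]
  expect_equal(c(prom$start, prom$end), c(0, 500))

  bad <- gm
  bad$exons$start[1] <- 4000L
  expect_error(build_segments(bad), "outside")
})

test_that("UTRs, coding exons and introns partition the transcript", {
  segs <- build_segments(toy_gene_models())
  a <- segs[segs$gene_id == "gA", ]
  expect_equal(a[a$segment == "utr5", c("start", "end")],
               data.frame(start = 5000L, end = 5200L),
               ignore_attr = TRUE)
  expect_equal(a[a$segment == "utr3", c("start", "end")],
               data.frame(start = 7800L, end = 8000L),
               ignore_attr = TRUE)
  expect_equal(a[a$segment == "intron", c("start", "end")],
               data.frame(start = 6000L, end = 7000L),
               ignore_attr = TRUE)
  # - gene: utr5 at the right end
  b <- segs[segs$gene_id == "gB", ]
  expect_equal(b[b$segment == "utr5", c("start", "end")],
               data.frame(start = 22800L, end = 23000L),
               ignore_attr = TRUE)
})

test_that("unique assignment drops multi-segment straddlers", {
  gm <- toy_gene_models()
  segs <- build_segments(gm)
  regions <- intervals(
    rep("chr1", 3),
    c(6200, 5950, 4000),        # intron-only, exon/intron straddle, promoter
    c(6300, 6100, 4050),
    strand = c("+", "+", "-")
  )
  asg <- assign_unique(regions, segs)
  expect_equal(nrow(asg), 2)
  expect_equal(asg$segment[asg$region == 1], "intron")
  expect_equal(asg$orientation[asg$region == 1], "sense")
  expect_false(2 %in% asg$region)  # straddler excluded from both classes
  expect_equal(asg$segment[asg$region == 3], "promoter")
  expect_equal(asg$orientation[asg$region == 3], "antisense")
})

test_that("gene counts report sense/antisense hits and gene proportions", {
  gm <- toy_gene_models()
  segs <- build_segments(gm)
  regions <- intervals("chr1", 4000, 4050, strand = "+")  # promoter of gA
  gc <- gene_counts(regions, segs, gm)
  prom <- gc[gc$segment == "promoter", ]
  expect_equal(prom$sense, 1)
  expect_equal(prom$antisense, 0)
  expect_equal(prom$n_genes, 1)
  expect_equal(prom$prop_genes, 0.5)
  genic <- gc[gc$segment == "genic_or_promoter", ]
  expect_equal(genic$n_genes, 1)

  none <- gene_counts(g4bulge:::empty_intervals(), segs, gm)
  expect_true(all(none$sense == 0 & none$n_genes == 0))

  # ratio of proportions between two summaries
  cs <- gene_counts(intervals("chr1", 24000, 24050, strand = "-"),
                    segs, gm)
  pr <- proportion_ratio(gc, cs)
  expect_equal(pr$prop_ratio[pr$segment == "promoter"], 1)  # 0.5 / 0.5
})

test_that("regulatory flags require >=1 nt overlap with either track", {
  regions <- intervals(rep("chr1", 3), c(10, 100, 200), c(20, 120, 220))
  tfbs <- intervals("chr1", 15, 30)
  dnase <- intervals("chr1", 110, 130)
  f <- flag_regulatory(regions, tfbs, dnase)
  expect_equal(f, c(TRUE, TRUE, FALSE))
  both <- flag_regulatory(intervals("chr1", 14, 115), tfbs, dnase)
  expect_equal(both, TRUE)
})

test_that("back-forward classification and its strand-swap symmetry", {
  gm <- toy_gene_models()
  segs <- build_segments(gm)
  regions <- intervals(rep("chr1", 3), c(3100, 3500, 24000),
                       c(3150, 3550, 24040),
                       strand = c("+", "-", "-"))
  bf <- find_bf_genes(regions, segs)
  expect_equal(bf$class[bf$gene_id == "gA"], "bf")
  expect_equal(bf$class[bf$gene_id == "gB"], "non_template_only")

  # template-only when the single promoter region opposes the gene
  t_only <- find_bf_genes(intervals("chr1", 3100, 3150, strand = "-"),
                          segs)
  expect_equal(t_only$class[t_only$gene_id == "gA"], "template_only")
  expect_equal(t_only$class[t_only$gene_id == "gB"], "none")

  # flipping every strand label (promoter geometry held fixed) leaves
  # the occupancy classes invariant: non-template stays non-template
  flip <- function(s) ifelse(s == "+", "-", "+")
  segs2 <- segs
  segs2$strand <- flip(segs2$strand)
  regions2 <- regions
  regions2$strand <- flip(regions2$strand)
  bf2 <- find_bf_genes(regions2, segs2)
  expect_equal(bf2$class, bf$class)
})

test_that("anchored profiles count coverage with strand mirroring", {
  regions <- intervals("chr1", 95, 105)
  plus <- data.frame(chrom = "chr1", pos = 100, strand = "+")
  pr <- anchored_profile(regions, plus, flank = 10)
  expect_equal(pr$count[pr$offset %in% -5:4], rep(1, 10))
  expect_equal(sum(pr$count), 10)
  expect_equal(sum(pr$freq), 1)

  # minus anchors mirror: offset o reads the base at pos - 1 - o, so an
  # asymmetric window flips around the anchor
  asym <- intervals("chr1", 98, 105)
  pa <- anchored_profile(asym, plus, flank = 10)
  expect_equal(pa$offset[pa$count == 1], -2:4)
  minus <- data.frame(chrom = "chr1", pos = 100, strand = "-")
  pm <- anchored_profile(asym, minus, flank = 10)
  expect_equal(pm$offset[pm$count == 1], -5:1)

  # duplicate anchors double counts but not the normalized track
  two <- rbind(plus, plus)
  p2 <- anchored_profile(regions, two, flank = 10)
  expect_equal(p2$count, 2 * pr$count)
  expect_equal(p2$freq, pr$freq)

  expect_error(anchored_profile(regions, plus[0, ], flank = 10),
               "anchor")
})

test_that("anchored profiles are translation invariant", {
  withr::with_seed(3, {
    s <- sample.int(5000, 20)
    regions <- intervals("chr1", s, s + 25)
    anchors <- data.frame(chrom = "chr1", pos = c(1000, 3000),
                          strand = c("+", "-"))
    base <- anchored_profile(regions, anchors, flank = 200)
    shift <- 137
    regions2 <- regions
    regions2$start <- regions2$start + shift
    regions2$end <- regions2$end + shift
    anchors2 <- anchors
    anchors2$pos <- anchors2$pos + shift
    expect_equal(anchored_profile(regions2, anchors2, flank = 200), base)
  })
})

test_that("per-gene counts respect scope and strand mode", {
  gm <- toy_gene_models()
  regions <- intervals(rep("chr1", 4),
                       c(3100, 3600, 6200, 24000),
                       c(3150, 3650, 6250, 24040),
                       strand = c("+", "+", "+", "-"))
  cnt <- counts_per_gene(regions, gm, scope = "promoter+gene_body",
                         strand_mode = "non_template")
  expect_equal(unname(cnt["gA"]), 3)
  expect_equal(unname(cnt["gB"]), 1)
  expect_equal(unname(counts_per_gene(regions, gm, scope = "promoter",
                                      strand_mode = "non_template")["gA"]),
               2)
  expect_equal(unname(counts_per_gene(regions, gm,
                                      strand_mode = "template")["gA"]), 0)
  # a region overlapping both promoter and body counts once
  straddle <- intervals("chr1", 4990, 5010, strand = "+")
  expect_equal(unname(counts_per_gene(straddle, gm)["gA"]), 1)
})
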