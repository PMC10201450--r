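---
title: "Discovering bulged G-quadruplex motifs: models, filters and statistics"
author: "g4bulge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering bulged G-quadruplex motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4bulge)
```

## The problem

G-quadruplexes (G4s) are four-stranded DNA secondary structures built
from stacked G-tetrads. The classic sequence model used by genome
scanners — four uninterrupted runs of at least three guanines separated
by loops of 1–7 bases (`G3+N1-7` × 4) — misses *bulged* G4s (G4-Bs), in
which one or two non-guanine bases protrude from a G-stem without
destroying the tetrad core. Structural work (NMR, CD, UV melting) shows
that such sequences can fold into stable three-layer G4s, so purely
canonical scanning systematically under-counts potential G4-forming
sites, particularly in gene regulatory regions.

`g4bulge` implements a sequence-model approach to this gap: a grammar
and scanner for bulged G4 motifs restricted to the three model classes
with experimental support, the filtering and merging rules needed to
turn raw matches into genomic regions, gene-level annotation and
anchored coverage profiles, background-matched enrichment statistics
against experimental peak sets (G4-seq, G4 CUT&Tag style data consumed
as BED), Kolmogorov–Waring fitting of per-gene counts, and
diagnostic-accuracy evaluation against experimental G4-formation calls.

## The motif grammar

A bulged candidate is four G-stems joined by three loops:

```
G I(x) G I(x) G   N(y)   G I(x) G I(x) G   N(y)   ...   (4 stems)
```

* Each stem contributes exactly **three tetrad guanines**. A stem has
  two insertion slots (between G1–G2 and G2–G3); each slot holds 0–3
  bases over `{A, C, T}` (`I`). A non-empty slot is one **bulge** —
  a slot with a 3-base insertion is still a single bulge. A stem with
  empty slots is **intact**.
* **Loops** (`N`, any base) are 1–3 nt for bulged models, 1–7 nt for the
  canonical scanner. `N` (the ambiguity base) never matches any motif
  position.

Accepted hits must satisfy all filters (`apply_bs_filters()`):

* at least two intact stems and at most two bulges in total;
* at most one G per loop (the "single G linker" rule, applied per loop:
  loop `AG` is legal, `GG` is not — an adjacent GG would rather be part
  of a stem);
* no `CC` dinucleotide anywhere in the match core (contiguous cytosines
  favour duplex formation over G4 folding); the filter sees only the
  core — stems, bulges and loops — never the flanking bases, which is
  why validated sequences with a `CC` flank are accepted;
* every insertion and loop within its length bounds.

The three retained model classes are labelled GxBy (x intact stems,
y bulges): **G3B1** (one single- or multi-base bulge), **G3B2** (two
bulges in the same stem) and **G2B2** (two bulges in two different
stems). Layouts with fewer intact stems (G1B3, G0B4) did not form
stable G4s experimentally and are rejected; the fixture generator emits
them only as negative controls.

```{r}
best_bs_hit(scan_bulged("TAGAGGCGGGAGTGGAGGGCG"))[,
  c("start", "end", "model", "n_intact_stems", "n_bulges",
    "bulge_seqs", "loops", "core_seq")]
```

### Enumeration and ambiguity

All valid stem placements are enumerated: stems may be shared between
hits, and when a maximal G-run is longer than 3 every 3-G window within
it is a candidate stem. Distinct decompositions with identical
coordinates are kept as separate rows (identity is `(start, end,
stem/bulge layout)`); merging makes the choice immaterial at region
level. When one sequence admits several model labels, `best_bs_hit()`
ranks them G3B1 > G3B2 > G2B2 — fewest bulges and most intact stems
first, because fewer bulges imply higher structural stability.

The canonical scanner (`scan_canonical()`) enumerates maximal G-runs of
length ≥ 3 and reports every window of four consecutive runs whose
three gaps are 1–7 nt; two hits are distinct iff their run sets differ.

Scanning is strand-complete (`scan_genome()`): the forward sequence
gives + strand hits and the reverse complement gives − strand hits
reported in forward coordinates.

## From hits to regions

The post-scan pipeline (`g4_pipeline()`) follows a fixed order:

1. `exclude_vs_canonical()` — bulged hits whose core is itself a
   canonical match, or that share ≥ 1 nt with a same-strand canonical
   hit, are removed (opposite-strand overlap never removes);
2. `exclude_repeats()` — hits overlapping repeat/low-complexity
   intervals by ≥ 1 nt are removed from both sets, strand-blind
   (RepeatMasker-style annotation is effectively unstranded);
3. `merge_regions()` — per strand, overlapping hits are consolidated
   into regions. Overlap always means at least one shared base under
   half-open arithmetic; book-ended intervals are never bridged.
   Merging is idempotent and conserves covered bases.

All coordinates inside the package are 0-based half-open (BED
convention); conversion to 1-based inclusive coordinates is left to
report formatting. Descriptive statistics of hit/region lengths
(`length_stats()`) use deterministic conventions: even-sample medians
are midpoints, mode ties break toward the smaller length. Two length
distributions are compared with a two-sample Kolmogorov–Smirnov test
(`ks_two_sample()`), optionally on seeded same-size subsamples since
sample-size imbalance otherwise dominates the D statistic.

## Gene annotation and profiles

`build_segments()` derives per-gene segments: a 2 kb promoter upstream
of the TSS in gene orientation (clipped at chromosome edges), 5′/3′
UTRs (exon parts outside the CDS span), coding exon parts, introns and
the transcript span. When a gene has several transcripts the longest
one is used (the collapse rule is otherwise underdetermined). The
"non-template" strand of a gene is the strand carrying the mRNA-like
sequence, i.e. the gene's own strand.

`assign_unique()` implements unique mapping: a region counts for a
segment class only when it overlaps exactly one granular class
(promoter/5′UTR/exon/intron/3′UTR) of that gene; straddlers are
dropped from segment-level counts but still count for gene-level
positivity ("genic or promoter"), which uses any overlap. A region
overlapping two genes counts for both. `find_bf_genes()` classifies
promoter G4 occupancy per gene as none / non-template only / template
only / both ("back-forward", bf) — bf promoters carry G4 motifs on
both strands simultaneously.

`anchored_profile()` computes per-nucleotide frequency tracks around
anchors (TSS, segment boundaries, peak centers, RLFS edges): for every
anchor and offset in `[-flank, flank)` it adds one when any region base
covers that position — coverage counting, not start counting. Offsets
of minus-strand anchors run in gene orientation (offset `o` reads the
base at `pos - 1 - o`, with `pos` the boundary-style anchor
coordinate), so profiles from the two strands superpose; the
normalized track sums to one.

## Enrichment statistics

Enrichment of a region set in an experimental peak set is scored
against a matched random background (`sample_background()`): one
random interval per query, of identical length, on the same chromosome
when requested, rejecting draws that overlap the original query
positions or contain N. Overlap flags are binary at ≥ 1 shared
nucleotide, and the enrichment score is the ratio of positive
proportions,

$$ES = \frac{a/n_1}{b/n_2}.$$

The 95% CI uses the Katz log-ratio method and the two-sided p-value a
pooled-proportion score test, with an exact conditional
(hypergeometric) fallback whenever a table cell is below 5; the
original analysis used a proprietary ratio-of-two-binomials
implementation, and this combination is specified here as a
reproducible equivalent. Both directions of support (regions per peak,
peaks per region) are available since `overlap_flags()` is symmetric
in its arguments' roles.

`bootstrap_ratio_test()` implements the subsampling comparison used
for RLFS-style co-localization claims: repeated samples (default 100 ×
1000) from a query pool and matched backgrounds, per-sample positive
ratios, and a two-sided Mann–Whitney comparison (exact for samples of
≤ 8 without ties, tie-corrected normal approximation otherwise).

## Kolmogorov–Waring counts per gene

Counts of bulged-G4 regions per gene (promoter + gene body,
non-template strand; `counts_per_gene()`) form a right-skewed
distribution with a power-law-like tail. Such laws arise as the
stationary distribution of a birth–death process and are modelled by
the Kolmogorov–Waring family through the recurrence

$$p_{k+1} = p_k\,\theta\,\frac{k+\alpha}{k+1+\beta},\qquad
p_0 \text{ by normalization}.$$

`fit_kw()` obtains maximum-likelihood estimates by multi-start
Nelder–Mead on transformed parameters (logit θ, log α, log (β − α); the
constraint β > α keeps the zero class meaningful), with a 3 × 3 start
grid over θ and the α/β ratio. The zero-class probability is reported
two ways: the closed form $p_0 = 1 - \alpha/\beta$ and the normalized
PMF value — they differ slightly for finite truncation and imperfect
fits, and with rounded published parameters (θ = 0.99, α = 27.2,
β = 30) the closed form gives 0.093 where curve fitting reports 0.0925;
both are exposed rather than reconciled. $p_0$ estimates the fraction
of genes whose motif content the scanner cannot observe, i.e. the
capture rate of the search models is about $1 - p_0$.

Numerical choices: the PMF truncation point auto-extends until the
estimated tail mass is below $10^{-9}$; θ = 1 with β − α ≤ 1 has no
normalizable solution and errors; all-equal count vectors are rejected
as degenerate.

## Diagnostic accuracy

`evaluate_predictions()` scores the scanner against experimental calls
for a table of tested oligomers. A sequence is predicted positive when
the bulged scanner accepts it under any model; the experimental call is
positive for single-major, major+minor or multiple G4 conformations and
negative for weak G4, duplex + G4, two-layer G4, duplex and non-G4.
Sequences matched only by the canonical scanner are flagged and
excluded from the bulged-model confusion table. `confusion_metrics()`
reports accuracy/sensitivity/specificity (percent), the positive
likelihood ratio on the proportion scale, and Cohen's kappa — on a 2 × 2
table the weighted kappa equals the unweighted one, and the CI uses the
large-sample standard error
$\sqrt{p_o(1-p_o)}\,/\,\bigl(\sqrt{n}\,(1-p_e)\bigr)$.

```{r}
m <- confusion_metrics(tp = 56, fp = 7, tn = 19, fn = 0)
round(c(accuracy = m$accuracy, specificity = m$specificity,
        sensitivity = m$sensitivity, lr_pos = m$lr_pos,
        kappa = m$kappa), 3)
```

## What the synthetic data emulates — and what it does not

Every downstream module is testable without downloads through the
fixture generator: i.i.d. genomes at a target GC content (41% by
default, the human bulk value), planted motif instances drawn from the
model grammars (`random_motif_string()`, `plant_motifs()`), single
transcript gene models with UTR-bearing exon/intron geometry, and
motif-free backgrounds produced by iteratively re-scanning and
redrawing hit windows over an A/T alphabet (`scrub_motifs()`) — a
window-level rejection-sampling scheme against both scanners. Planted
negative controls (G1B3/G0B4) contain at most one `GGG` run, so no
sub-decomposition can reach the two-intact-stem minimum; planted
motifs are padded with A/T so chains cannot recruit background
guanines. All randomness flows through explicit seeds.

These fixtures establish correctness of the algorithms — exact recall
of planted instances, precision against motif-free background,
calibration of the enrichment test under an exchangeable null,
parameter recovery for the count model. They do not emulate real
genomes: no repeat structure, GC isochores, CpG islands, or the
correlated G-richness of real promoters. Genome-scale census numbers
therefore require real annotation (assembly FASTA, RepeatMasker track,
gene models, peak sets); the pipeline supports that computation but
the test battery does not claim it.

Problem sizes in the test suite were chosen to make the statistical
assertions sharp at interactive runtimes: oracle equivalence on 1000
random + 50 adversarial strings of ≤ 60 nt against a brute-force
enumerator, strand symmetry on 500 random sequences, a 1-Mb planted
genome with ~200 motifs, 1000 null draws at n = 500 per arm for
calibration, 10 seeds at n = 5000 for planted enrichment (peaks sized
so the background rate is 2% and the planted footprint cannot distort
it), and 20 seeds at n = 5000 for Kolmogorov–Waring recovery.

## Known limitations

* No thermodynamic scoring (G4Hunter-style) — the scanner is a grammar,
  not a stability predictor; RNA G4s, two-layer G4s and duplex
  stem-loop G4s are out of scope, as are bulged candidates with loops
  above 3 nt (validated examples with 4-nt loops exist but exceed the
  model bounds by construction).
* Bulged-model stems are fixed at exactly three guanines; stems carved
  from longer G-runs are enumerated as all 3-G windows and collapse
  under merging, but a 4-G "intact stem" reading of a single hit is not
  reported.
* The kappa CI formula is a design choice; published CIs computed with
  unnamed software may differ in the third decimal.
* Repeat exclusion uses ≥ 1 nt overlap; a containment-based rule would
  retain slightly more hits near repeat edges.
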