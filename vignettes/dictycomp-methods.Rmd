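---
title: "Methods and design of the dictycomp pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the dictycomp pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dictycomp` re-implements, as a tested pipeline, the bespoke
comparative-genomics computations used to contrast a pair of AT-rich
social-amoeba genomes: repeat and homopolymer statistics, synteny blocks
with permutation nulls, a DUSE-anchored ncRNA screen, and per-ortholog
molecular evolution against social-stage expression. This vignette
records the models, the parameters that matter, the numerical choices,
and the reasoning behind design decisions that were genuinely open.

## Coordinates and containers

All genomic intervals are 1-based and closed, the IRanges convention.
GFF3 therefore needs no conversion at the boundary; BED export converts
through `rtracklayer`. The alternative (0-based half-open internally)
buys nothing once all interval arithmetic is delegated to IRanges, and
would put the package at odds with every Bioconductor container it uses.
Genomes are `DNAStringSet`s whose soft-mask state (lowercase on input)
is carried as per-scaffold masked ranges in `metadata()`; a `hard_mask`
flag additionally treats `N` runs as masked, because "masked genome" is
a procedure-dependent notion and both conventions arrive in the wild.

## Simple sequence repeats

A tract of unit length $k$ is a maximal run in which every base equals
the base $k$ positions before it. Detection scans, per $k \in 1..20$,
the lag-$k$ equality vector and its runs; this finds exactly the maximal
tracts, including fractional trailing units. A tract *qualifies* when
its whole-copy count reaches the unit-length-specific minimum (10, 7, 5,
4, then 3 for units of 5-20 bp). Choices worth stating:

* **Fractional tails** count toward tract length and the reported copy
  number, but qualification uses whole copies, keeping the threshold
  crisp while preserving maximality.
* **Canonical phase**: the reported unit is the lexicographically least
  rotation, so the same tract never appears under two phases.
* **Non-primitive units** (a unit that is itself a repetition of a
  shorter unit) are reported only at the shortest unit length.
* **Masked or `N` positions terminate tracts** so repeats never bridge
  assembly gaps.
* **Strand**: forward only; a motif and its reverse complement are
  distinct units. Composition statistics are strand-symmetric in
  aggregate, and no strand rule is part of the method.
* **Genome fraction** uses union bp (overlapping tracts counted once);
  a `summed_bp` flag provides the summed-tract-length alternative since
  published genome-percentage figures rarely say which they used.
* The count of "long" tracts uses a strict > 100 bp rule.

The detector is held equal, case by case, to a brute-force per-position
greedy scanner in the test suite (5 kb instances per module test, a
50 kb instance in the acceptance suite).

## Amino-acid homopolymers

The chance model asks how long a run of amino acid $a$ must be before
fewer than $\alpha$ such runs are expected in the whole proteome: with
proteome frequency $f_a$ and $N$ total residues, the threshold is the
smallest $L \ge 2$ with $N f_a^L \le \alpha$, default $\alpha = 0.01$.
This is an upper bound on the expected number of runs of length $\ge L$
(every run start is counted, maximality ignored), which errs slightly
conservative. On an asparagine-dominated AT-rich composition of
$6.4\times10^6$ residues the thresholds for amino acids at 2% frequency
or more span 6 through 10 residues: the least frequent need runs longer
than 5, asparagine (~11%) needs runs longer than 9 — in particular an
8-residue asparagine run is excluded as a chance event at $P > 0.01$.

Runs of length ≥ 2 are reported; only *significant* runs (length at or
above the threshold) enter densities, homology calls and dN masking.
Density of amino acid $a$ is the summed length of its significant runs
per 1,000 residues of coding sequence. Codon diversity of a run is
normalized as $(\text{distinct}-1)/(\min(L, c_a)-1)$ with $c_a$ the
codons available for $a$, defined as 0 when the denominator vanishes
(methionine/tryptophan runs).

Cross-species run homology uses global protein alignment
(Needleman-Wunsch via `Biostrings::pairwiseAlignment`, BLOSUM62, gap
open 11, extend 1 — the conventional cross-species scoring; the method
used originally is unstated, so the scoring is configurable). Two
significant runs are homologous when they are runs of the same amino
acid sharing at least one aligned column; a configurable minimum
overlap is provided, with 1 as the strictest-minimal default since no
overlap rule is part of the published description. Because the
denominator of "fraction of repeats in genes without homologs" is
ambiguous (orthologs only vs all genes), the summary reports the raw
counts and both fractions.

## Synteny blocks

Ortholog pairs are indexed in the *ortholog-restricted* gene order:
genes without a 1:1 partner are invisible, so "at most $w$ intervening
genes" means intervening ortholog-bearing genes. Two pairs link when
their index gap is at most $w+1$ on the same genome-A scaffold **and**
their partners' gap is at most $w+1$ on the same genome-B chromosome.
Blocks are connected components with ≥ 2 members (singletons are
unclustered). Linkage is orientation-free — the criteria count genes,
and a reversed segment must still cluster; a strict co-orientation mode
sits behind a flag.

The permutation control scrambles gene order uniformly and
independently within each scaffold/chromosome, preserving scaffold
membership and the pairing; a whole-genome shuffle mode is offered
because the scramble granularity is not pinned down by the phrase
"artificially scrambled". Null participation at $w$ is summarized by
its mean and SD over `n_perm` permutations (default 100, seed
recorded). Exhaustive enumeration for $n=4$ genes on one scaffold gives
mean null participation of exactly $2/3$ at $w=0$, and a preserved
adjacency survives a uniform permutation of $n$ genes with probability
$2/n$ — both are asserted in the tests.

Window selection scans $w = 0..w_{max}$ and picks the largest $w$ whose
participation *growth* $p(w) - p(w-1)$ exceeds the null growth mean by
at least $k$ null SDs ($k = 2$ by default); $w = 0$ is judged on its
level. The published account says only that clusters "grow
significantly faster" than the randomized control, so the $k$-SD rule
is this package's explicit stand-in; it is monotone-sane (identical
orders select $w=0$; pure noise selects nothing and is flagged). The
gene-wise false positive rate is null mean participation divided by
real participation.

## The DUSE-anchored ncRNA screen

The screen follows the published geometry: the DUSE
(`[AT]CCCA[AT]AA`, IUPAC `WCCCAWAA`) sits roughly 63 bp upstream of
dictyostelid ncRNAs; class I/II ncRNAs carry a 5-bp 5' stem, then
immediately the 12-bp non-self-binding bulge `CCTTACAGCCAA` (which
contains the enriched 8-mers `CCTTACAG` and `CTTACAGC`), and a 3' stem
— the exact reverse complement of the 5' stem — 40-70 bp downstream of
the 5' stem's end.

* **k-mer enrichment**: every k-mer occurrence (default $k=8$) is
  tested for a DUSE starting 40-90 bp upstream; the window brackets the
  canonical ~63 bp with slack on both sides since only the ~63 figure
  is stated. The null is positional: the genome-wide probability that a
  position has a DUSE in its upstream window; each k-mer is scored by
  an upper-tail binomial test, ranked by $-\log_{10} p$, ties broken
  lexicographically.
* **Structural filter**: anchors (occurrences of a chosen 8-mer) emit a
  candidate for every 5-bp stem starting within 15 bp upstream of (or
  at) the anchor whose reverse complement occurs 40-70 bp downstream —
  the bulge geometry puts the 5' stem immediately before the anchor,
  but exact offsets are not stated, so all qualifying placements are
  emitted rather than one guessed placement. Bulge presence is recorded,
  not required (several published members lack the canonical bulge).
* **Classes** come from a 5' stem lookup (`GTTGA` class I, `GCTCG`
  class II by default); everything else stays "putative". Scanning is
  forward-strand by default; a both-strands analysis reverse-complements
  the genome and repeats.

The chance rate of the stem rule is appreciable — a random 5-mer's
reverse complement lands in a 31-position window with probability
$1-(1-p_5)^{31}$, where $p_5 = (\sum_b p_b p_{\bar b})^5$ — about 13%
per placement on AT-rich composition. The tests verify this analytic
rate by simulation, which is also why the screen is anchored on rare
8-mers rather than run genome-wide.

## Molecular evolution and social expression

dN/dS uses Nei-Gojobori proportional counting, the minimal standard
method fully specifiable from first principles (no method is named in
the published analysis): per-codon synonymous site fractions (changes
producing stops count as nonsynonymous), sites averaged over the two
sequences; observed differences classified by enumerating substitution
paths between the codons, discarding paths through stops and averaging
the rest (all paths if every path is blocked); the one-parameter
correction $d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$, with $p \ge 3/4$
flagged as saturated rather than returned as a number. The difference
tables are verified against an independent recursive path-enumeration
oracle over all $61 \times 61$ sense-codon pairs. Codon alignments are
back-translated from the protein alignment (protein gaps become
whole-codon gaps), and codons of significant homopolymer runs are
masked before counting, implementing dN "excluding repeat sequences".

The conservation score is identical aligned residues divided by the
length of the longer unaligned sequence, an explicit stand-in for the
published score, which is described only as declining with both point
differences and non-aligned sequence; this formula is 1 exactly for
identical sequences and decreases under any mismatch or gap.

The social expression index is $S/(S+V)$: mean percentage
representation across the six social time points (4-24 h after
starvation) over that mean plus the vegetative percentage. QC keeps
genes with at least 20 reads summed over libraries and, where replicate
libraries exist, replicate correlation ≥ 0.8; the thresholds are stated
defaults, not inferred ones, since the original QC lives in
supplementary material. Regressions are ordinary least squares with the
two-sided slope test; group comparisons use Student's t or the
Mann-Whitney U with normal approximation and tie correction.
Per-time-point analyses reuse the same regression machinery with
single-time-point indices; gene-set comparisons (e.g. meiosis genes)
reuse the generic group-comparison operation on a user-supplied list.

## The synthetic data generator

The generator is first-class, tested code: it emits the exact formats
the readers consume and a truth record that `truth_check()` verifies by
independent re-parsing. Its defaults are the package's fixed study
conditions: 300 genes per genome on 4 (A) and 6 (B) scaffolds, target
A+T 0.776 (dictyostelid-like), 15% gene turnover per species, 8
rearrangement breakpoints, slippage repeats at 0.4 tracts/kb of
intergenic sequence with unit length uniform on 1-6 and geometric extra
copies, homopolymer runs at 0.5 per protein (drawn from the dominant
N/Q/S/T, lengths 10 plus a geometric tail so every planted run clears
the composition thresholds), dN targets 0.15 (vegetative class) and
0.35 (social class) spanning a realistic divergence range, a social
index separation of 0.3 between classes, negative-binomial counts with
dispersion 0.5, and 12 planted ncRNA loci. Genes unique to one species
are drawn social with probability 0.8, planting the
orthologless-genes-are-more-social signal.

Details that make the planted truth exact:

* **Composition calibration.** Excluding stop codons depletes A+T
  relative to iid base sampling, so the per-base bias used inside
  coding sequence is calibrated (by root finding) so the sense-codon
  composition hits the target; divergence substitutions are weighted by
  the same AT-biased mutation spectrum so genome B does not drift away
  from it. Realized A+T tracks the target within 2 points at
  ≥ 100 kb.
* **Divergence to a dN target.** The number of nonsynonymous changes is
  Poisson with mean $p_N N$ ($p_N$ inverted from the target through the
  multiple-hit correction, $N$ the gene's nonsynonymous sites), applied
  as single-nucleotide nonsynonymous non-stop changes at distinct
  codons. No synonymous divergence is simulated: the analyses need
  controlled dN, not realistic dS. Class mean dN is recovered within
  15% at ≥ 200 pairs.
* **Countable rearrangements.** Rather than applying operator sequences
  whose breakpoints can collide, the generator cuts the ortholog order
  at `rearrangement_ops` sampled non-adjacent adjacencies, then
  permutes and/or flips the segments, re-drawing any arrangement that
  rejoins a cut. Flips are inversions and moves are translocations, and
  the block count at $w=0$ on a single-scaffold pair is exactly
  $r + 1$. The truth record stores the cut list and the
  preserved/broken state of every ortholog adjacency in the realized
  layout.
* **Background scrubbing.** Planted-truth recall and precision of
  exactly 1 are only well-posed if chance features do not arise in the
  background, which at A+T 0.776 they otherwise would (a mononucleotide
  tract of ≥ 10 identical bases arises at rate
  $2 p^{10}(1-p)^2$ per position, $p$ the per-base A or T probability —
  dozens per megabase). With `scrub_background = TRUE` (default) the
  generator rejection-samples background sequence so that qualifying
  repeat tracts, homopolymer runs of ≥ 6 residues, DUSE matches and
  NSBR anchor 8-mers occur only where planted; planted features carry
  flank guards so they are exactly maximal; assembled scaffolds are
  re-checked whole (junctions between pieces, and stem search windows
  that cross segment boundaries, are re-validated) and rebuilt on
  failure. With scrubbing off, the background false-find rate of the
  detectors matches the analytic expectation, which the tests verify.
* **Determinism.** Everything flows from one seed through R's RNG;
  the same seed reproduces every output file byte for byte.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: intergenic composition beyond the A+T
fraction (no transposons, no isochores), indel evolution within coding
sequence (alignment gap handling is exercised by constructed cases and
by homopolymer insertions instead), synonymous divergence, codon usage
bias beyond the AT bias, multi-exon gene structure (the readers handle
it; the generator emits single-CDS genes), expression replicates, and
coding SSR tracts outside homopolymer context. Real-genome runs
additionally face assembly artifacts the scrubbed background cannot
represent; on real data the repeat and screen outputs should be read as
detector output, not as recovered truth.

## Problem sizes and budgets

Module tests run on 40-150 gene genomes (tens to hundreds of kb),
5 kb oracle comparisons, and tiny constructed cases. The acceptance
suite uses a 50 kb repeat-oracle instance, 1,000 random synteny
instances of ≤ 12 genes against the component oracle, the full
$61\times61$ codon-pair oracle, a 150-gene recovery dataset, 220 pairs
for dN recovery, 100 seeds of 100 pairs for slope-sign recovery, and
1,000 replicates for test calibration — sizes chosen so the whole suite
runs in a few minutes on one CPU while leaving the Monte-Carlo noise
well below the asserted tolerances.

## Known limitations

* The Nei-Gojobori estimator differs numerically from
  maximum-likelihood codon models; regression coefficients on real data
  will not match analyses that used a different dN method.
* The conservation score is a stated, simple formula; published values
  computed with an unspecified score are not expected to match it
  numerically.
* The w-selection rule, QC thresholds, alignment scoring and the
  enrichment null are explicit stand-ins wherever the original
  procedure is unstated; all are configurable, and defaults are
  recorded in every provenance block.
* dS is reported but unreliable at dictyostelid divergence depths
  (saturation is flagged, not corrected).
* The 8-mer enrichment ranking assumes positional independence of
  k-mer occurrences; heavily repetitive unmasked genomes violate this,
  which is why masked input is the intended use.
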