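---
title: "Detecting recombination mosaics in transposable-element alleles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting recombination mosaics in transposable-element alleles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(temosaic)
```

## The problem

*Pokey* is a piggyBac-superfamily DNA transposon of *Daphnia* that inserts
site-specifically at a TTAA motif in 28S ribosomal RNA genes. Because rDNA
evolves in concert — unequal crossing-over and gene conversion continually
homogenise the tandem repeats — elements inserted there are repeatedly
shuffled between chromosomes and lineages. Alleles cloned from a single
isolate can therefore be mosaics: sequences whose left and right portions
descend from different, well-diverged parental lineages. `temosaic`
implements the complete analysis used to characterise such mosaics from a
multiple alignment of element sequences: diversity statistics, four
complementary recombination detectors, fragment-wise dendrograms with
parental-donor assignment, and an in-silico PCR-RFLP screen — plus a
simulator that generates mosaic datasets with known ground truth so every
stage can be validated.

## Input preparation

All analyses run on an `aln` object: a rectangular matrix of uppercase
IUPAC nucleotides with a `column_map` that records, for every current
column, its coordinate in the *source* alignment. `strip_columns()`
removes every column containing a gap or an ambiguity code before any
recombination statistic is computed; a single misaligned indel region can
otherwise masquerade as a breakpoint. Because coordinates are carried
through the map, breakpoints are always reported in source coordinates, no
matter how many columns were stripped. We treat *any* non-ACGT code as
grounds to drop the whole column: conservative, but recombination
detection is far more sensitive to artefactual columns than to the small
loss of signal.

Partitions (`exon1`, `intron`, `exon2`, `ncr3`) are 1-based inclusive
intervals in source coordinates with an optional reading-frame offset.
Amino-acid tabulation translates each sequence's ungapped region
separately and flags a sequence as frameshifted when its ungapped length
differs from the region's modal length by a non-multiple of three; this is
a pragmatic rule (the alternative — codon-aware realignment — is out of
scope), and positions are indexed per sequence, so counts downstream of an
in-frame indel can be offset by a codon. Stop codons are reported, not
rejected: elements inserted in rDNA are frequently pseudogenised.

## The simulator and what it emulates

`simulate_parent_pools()` evolves `n_parents` lineages from a random root
under a K80 substitution model (transition/transversion ratio `kappa`,
default 2) with among-site rate heterogeneity: each site is invariant with
probability `p_inv` (default 0.633) or draws its rate from a 4-category
discrete gamma with shape `alpha` (default 0.8423). Defaults mirror the
substitution regime estimated for the element: ~1450 bp, pooled diversity
around 5%, strong rate heterogeneity. The divergence parameter `d`
(default 0.06) is the *target expected p-distance between parents*; branch
lengths are solved numerically under the site-rate mixture, so realized
divergence matches `d` up to sampling error rather than undershooting it
through unmodelled multiple hits (at this heterogeneity the naive
"substitutions per site" reading would lose almost 20% of the divergence
to multiple hits, which is exactly the kind of silent miscalibration we
want to avoid). Requesting `d >= 0.75 * (1 - p_inv)` is a configuration
error: that much observable divergence cannot exist under the model.

Each lineage carries a small allele pool (default 3 alleles at
within-lineage divergence `within_group_theta = 0.01`, i.e. ~99%
within-group identity, matching the tight sequence groups seen in cloned
element data). `simulate_recombinants()` splices donor alleles exactly at
given breakpoints and records every donor segment; donors may themselves
be recombinants, in which case the truth record composes their segments —
this reproduces the observed pattern of recombinants built from sequences
that were already recombinant. `simulate_mosaic_scenario()` is the default
study configuration: 5 parents, 10 single-breakpoint mosaics between
random parent pairs, breakpoints uniform in the central 41–59% of the
sequence (bp ~595–855 at 1450 bp, where inter-allelic exchange clusters in
the element's transposase region). `inject_pcr_chimeras()` adds the
laboratory confound — single-crossover template switches at *uniform*
positions — which is distinguishable from real events precisely because
planted events concentrate while chimera crossovers do not.
`sample_isolates()` emulates the cloning screen: each isolate holds 1–5
alleles and clones are drawn with replacement (10–12 per isolate), so rare
alleles are under-sampled exactly as in a plasmid screen.

What the simulator does *not* emulate: coalescent ancestry within
lineages, selection, gene conversion tracts, alignment error, and indel
structure beyond simple random deletions. Passing tests therefore
demonstrate that the detectors work when their model assumptions hold;
they do not certify performance on badly aligned or saturated real data.

## Diversity statistics

`nucleotide_diversity()` and `watterson_theta()` are the textbook
estimators (per site, complete deletion by default; a pairwise-deletion
option exists because published totals computed on full-length sequences
may have used it — a documented source of small discrepancies when
comparing to published values). `partition_diversity()` reproduces the
per-region table layout (coding/non-coding aggregates plus one row per
region; display rounding to 3 decimals for diversity and 1 for percent
similarity, full precision retained). `recombination_rate()` performs the
arithmetic combination `R = theta_LAM x r_LAM = 4 Ne c` of externally
estimated coalescent parameters; the MCMC estimation itself is out of
scope, the inputs are taken as given.

## Recombination detection

**PHI test.** Parsimony-informative sites are recoded to their two most
frequent states; the statistic is the mean four-gamete incompatibility
over pairs of informative sites within `window_w` bp (default 100) of one
another. Under clonality incompatibility does not depend on distance;
under recombination nearby sites are more compatible than distant ones, so
a *low* observed statistic relative to site-order permutations signals
recombination. The p-value is the fraction of permutations with a
statistic at or below the observed one (add-one corrected).

**Stepwise maximum chi-square.** For every unordered sequence pair, a
candidate breakpoint between two columns splits a window of `h`
segregating sites each side into a 2x2 match/mismatch table; the scan
reports the maximal chi-square (no continuity correction; leftmost
position wins ties) and assesses it against a Monte-Carlo null in which
site columns are permuted and the statistic re-maximized. Half-windows are
counted in *segregating sites of the alignment*, not raw bp: with
divergence varying along the sequence, bp windows have wildly varying
information content and the 2x2 margins become incomparable across
positions. Four half-widths (70, 80, 90, 100) are scanned by default;
a half-width is skipped with a log entry when fewer than `2h` segregating
sites exist. Per-pair p-values are Bonferroni-corrected by the number of
pairs scanned in the step — note the permutation resolution bound: with
`n_perm` permutations the smallest achievable p is `1/(n_perm + 1)`, so
`n_perm` must exceed `n_pairs / alpha` for any call to survive correction
(the default 10,000 supports up to ~500 pairs at alpha = 0.05). Accepted
breakpoints condition the next round: permutations are restricted to the
segments they delimit — a breakpoint already explained then no longer
beats its own conditional null, which terminates the stepwise loop
naturally. The reported interval runs between the pair's mismatch sites
flanking the optimal boundary, falling back to the alignment ends when no
flanking mismatch exists on one side. A key implementation detail: the
permutation null depends only on the per-segment mismatch *counts* of a
pair, so nulls are cached and shared across pairs and half-widths, which
makes the 10,000-replicate scan of ~100 pairs a matter of seconds.

`merge_calls()` groups calls into events under interval *identity* by
default: overlapping-but-distinct intervals remain separate events (the
data this models kept two events at 815–856 and 825–856 apart), and events
are labelled I, II, ... by left coordinate. A Jaccard-overlap rule is
available as an alternative.

**Rm and Rh.** `hudson_kaplan_rm()` applies the four-gamete test to all
pairs of biallelic sites, reduces to minimal incompatible intervals, and
counts the maximum number of pairwise-disjoint open intervals (greedy by
right endpoint; verified exactly equal to an exhaustive
disjoint-interval optimum on hundreds of random instances in the test
suite). `haplotype_bound_rh()` combines local bounds by dynamic
programming over segregating-site intervals. The haplotype local bound is
`max(0, H - S - 1)`; we strengthen it with the local Hudson–Kaplan count
inside the same DP. This is deliberate: the pure haplotype bound does
*not* dominate Rm — there are four-sequence configurations with one
incompatible site pair in which every interval satisfies `H <= S + 1` —
and a combined lower bound should never be weaker than the cheaper one.
With the combination, `Rh >= Rm` holds by construction and the haplotype
term frequently tightens the bound well beyond Rm. Rh here is the
classical haplotype-excess bound, not the event count of a sampled
ancestral-recombination-graph history; numerical agreement with
history-sampling tools is not expected.

**Fragment scan.** A deliberately simple whole-alignment segmentation
standing in for genetic-algorithm breakpoint searches: all 0-, 1- and
2-breakpoint segmentations over candidate positions (midpoints between
informative sites, thinned to at most `max_candidates`) are scored by the
parsimony length of each segment on its own NJ topology plus a penalty per
breakpoint (default 2% of the unsegmented score — on tree-like data a
split recovers only a percent or two of steps through topology
overfitting, while a genuine donor switch recovers far more). Chosen
boundaries are then localized exactly: holding the two flanking topologies
fixed, each column is assigned to the tree that explains it in fewer
steps, with per-site parsimony prefix sums giving the argmin over all
candidate positions in one pass. The scan is deterministic and returns an
empty set when no split pays for its penalty.

## Fragment trees and parental assignment

`fragment_trees()` builds one neighbor-joining tree (via `ape::nj`;
negative branch lengths clamped to zero and counted) per span between
breakpoints; p-distance is the default model because the distances are
small and the trees are read qualitatively — JC69 and K2P are available.
Fragments with fewer than 3 variable sites are skipped with a warning.
`assign_parents()` reads donor pairs off the fragment distance matrices:
per fragment, the donor is the group (excluding the recombinant's own)
with the smallest mean distance to the recombinant; groups within 10% of
the best distance are reported as alternatives (`"h : c or i : c"` style),
because group structure in real data is partly a judgment call and
near-ties should be surfaced, not hidden. Group membership is an input —
the package does not attempt to re-derive by algorithm what was originally
delineated by eye on a phylogenetic network.

## In-silico PCR-RFLP

`in_silico_pcr()` anchors a forward primer and the reverse complement of a
reverse primer (IUPAC-aware matching; when mismatches are allowed the
3'-terminal 5 bases must still match exactly, since 3' mismatches kill
extension) and returns all pairings within a 300–5000 bp window. `digest()`
cuts at every degenerate-pattern match of the panel — DraI (TTT^AAA),
BspHI (T^CATGA), BstEII (G^GTNACC), all palindromic so one strand suffices
— and always conserves total length. `haplotype_code()` turns cut presence
in three diagnostic windows (±25 bp around 380, 790 and 1080 bp; the
published positions are approximate, hence windows) into codes 1–8, and
`gel_pattern()` models a 3% agarose gel by collapsing fragments within
40 bp (a modelling choice, not a measured value). The screen detects
mosaics mechanically: a splice carries the left-of-crossover bits of one
template and the right-of-crossover bits of the other, producing codes
absent from either parent. `synth_rflp_templates()` builds a synthetic
~1600 bp amplicon free of panel sites and plants all 8 site combinations,
which is how the 8-conformation combinatorics is exercised without the
original amplicons.

## Pipeline and reproducibility

`run_pipeline()` sequences the stages (strip → diversity → PHI → max-chi2
→ Rm/Rh → fragment scan → fragment trees → assignment → RFLP) from a
single `run_config()`; every stage is present in the report or explicitly
skipped with a reason, and artifacts are written as FASTA/TSV/JSON/
newick/BED. One global seed fans out to per-stage seeds by stable hashing
of stage names, so a fixed seed gives byte-identical reports and any stage
can be re-run in isolation. The report carries no timestamps; the output
directory is not echoed into it for the same reason. A thin command-line
wrapper (`inst/cli/temosaic.R`, verbs `simulate` / `analyze` / `rflp`)
exposes the same functions to shell users.

## Validation strategy and problem sizes

The test suite validates each stage against independent oracles (explicit
pairwise loops for diversity; an exhaustive disjoint-interval optimum for
Rm; `ape::dist.dna` for distance formulas; `seqinr::translate` for the
genetic code) and against planted truth from the simulator. The headline
performance checks run at the study conditions — d = 0.06, alpha = 0.8423,
p_inv = 0.633, L = 1450, half-widths 70–100, 10,000 permutations — with
100 seeded recovery runs and 100 recombination-free null runs for the
max-chi2 scan, 500 random instances for the oracle and bound-ordering
properties, and 100 mosaics for donor-assignment accuracy. Smaller
per-module checks use reduced replicate counts; replicate counts are
chosen so the full suite stays in the minutes range on one CPU while
keeping binomial noise well below the margins being asserted.

## Known limitations

- Breakpoint intervals are as tight as the flanking mismatch sites allow;
  with a clean splice against the exact donor allele one flank can extend
  to the alignment end.
- The max-chi2 scan cannot orient a pair (derived vs parental); orientation
  comes from the fragment trees.
- The fragment scan considers at most two breakpoints and carries no
  significance test; it localizes well only when divergence between the
  involved lineages is a few percent or more.
- Amino-acid position indexing is per sequence after in-frame indels.
- The PHI statistic uses binary recoding of informative sites; sites with
  three or more well-populated states contribute only their two most
  frequent states.
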