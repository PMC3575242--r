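# temosaic

Recombination mosaic analysis for transposable-element alleles.

*Pokey* is a piggyBac-superfamily DNA transposon of *Daphnia* that inserts
at a TTAA motif inside 28S ribosomal RNA genes. Ribosomal DNA evolves in
concert — unequal crossing-over and gene conversion keep the tandem
repeats homogenised — so elements inserted there are continually shuffled
between lineages, and alleles cloned from a single isolate are often
**mosaics**: part of the sequence descends from one divergent parental
lineage, the rest from another. `temosaic` is for population geneticists
who have an alignment of such element sequences (or any set of homologous
sequences suspected of inter-allelic recombination) and want to quantify
diversity, detect and localise recombination breakpoints, identify the
parental donors of each mosaic, and design/interpret a PCR-RFLP screen —
with a fully seeded simulator providing ground truth for validation.

## What it computes

**Diversity.** Nucleotide diversity
π = [2/(n(n−1))] Σ_{i<j} d_ij / L, Watterson's estimator
θ_W = S / (a_{n−1} L) with a_{n−1} = Σ_{k=1}^{n−1} 1/k, segregating sites,
mean pairwise similarity, per-partition summaries, and the population
recombination rate R = θ_LAM · r_LAM = (4N_e μ)(c/μ) = 4N_e c from
externally estimated coalescent parameters.

**Recombination detection.**

- *PHI test*: mean four-gamete incompatibility over nearby
  parsimony-informative site pairs, with site-order permutation p-values.
- *Stepwise maximum chi-square*: for every sequence pair, a sliding
  boundary splits a window of h segregating sites per side into a 2×2
  match/mismatch table; the maximal χ² is tested against a Monte-Carlo
  permutation null, significant breakpoints condition the next round
  (within-segment permutation), and pairwise calls merge into events
  I, II, … under interval identity.
- *Hudson–Kaplan R_m*: maximum number of disjoint site intervals failing
  the four-gamete test (verified against an exhaustive optimum).
- *Haplotype bound R_h*: local bounds max(0, H − S − 1) combined with
  local R_m by dynamic programming, so R_h ≥ R_m always.
- *Fragment scan*: exhaustive 0/1/2-breakpoint segmentation scored by
  per-segment parsimony on NJ topologies, with exact per-site boundary
  refinement.

**Phylogenetics.** p/JC69/K2P distances, neighbor-joining dendrograms per
recombination fragment, and per-fragment nearest-donor-group assignment
with tie reporting ("h : c or i : c" style).

**RFLP.** In-silico PCR (degenerate, 3'-anchored primers), DraI + BspHI +
BstEII digestion, the 8-state haplotype code from three diagnostic cut
windows (~380/790/1080 bp), gel co-migration modelling, and per-isolate
haplotype summaries.

## Worked example

Simulate the default mosaic scenario (5 parental lineages at 6%
divergence, strong rate heterogeneity, 3 single-breakpoint mosaics) and
run the full pipeline:

```r
library(temosaic)
cfg <- run_config(simulation = sim_config(seed = 42), n_recombinants = 3,
                  n_perm = 10000, phi_perm = 1000, seed = 42)
rep <- run_pipeline(cfg)
print(rep)
#> temosaic run report
#>   alignment: 18 sequences, 1450/1450 columns kept
#>   pi = 0.0594, theta_w = 0.0467, S = 233
#>   phi test: p = 0.000999
#>   max-chi2: 75 calls, 27 merged events
#>   Rm = 23, Rh = 86
```

π ≈ 0.059 and θ_W ≈ 0.047 say the pooled alleles are a few percent
diverged with an excess of intermediate-frequency variants (π > θ_W, as
expected when deep lineages are pooled). The PHI p-value ≈ 0.001 rejects
clonality. R_m = 23 incompatible-interval events is a lower bound driven
by the three splices cutting across 15 parental alleles; R_h = 86
tightens it. The planted truth and the recovered calls line up:

```r
rep$simulation$planted
#>   seq_id breakpoint parent_a parent_b
#> 1     R1        607       P5       P1
#> 2     R2        706       P5       P3
#> 3     R3        709       P2       P4
head(rep$events[, 1:4], 3)
#>   label left right n_calls
#> 1     I    1   616       2
#> 2    II    1   714       4
#> 3   III    1   744       4
rep$assignments
#>    recomb_id assignment
#> R1        R1    P5 : P1
#> R2        R2    P5 : P3
#> R3        R3    P2 : P4
```

Each planted breakpoint is covered by merged events (e.g. event intervals
566–608, 688–714 and 701–744 contain the planted 607, 706 and 709), and
the per-fragment donor assignment names the true parental pair of every
mosaic.

RFLP typing of a template set:

```r
tpl <- synth_rflp_templates()
h <- rflp_type(tpl$templates[["code6"]])
h$code           # 6: DraI cuts, BspHI does not, BstEII cuts
gel_pattern(h$fragments)
#> [1] 700 520 380
```

## Command line

```sh
Rscript inst/cli/temosaic.R simulate --seed 7 --outdir run/
Rscript inst/cli/temosaic.R analyze --alignment aln.fasta --groups groups.tsv --outdir run/
Rscript inst/cli/temosaic.R rflp --fasta templates.fasta --out haplotypes.tsv
```

The run directory contains the stripped alignment, call/event tables
(TSV + BED), per-fragment newick trees, assignment tables, the simulation
truth (for synthetic runs) and a timestamp-free `report.json` that is
byte-identical across reruns with the same seed.
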