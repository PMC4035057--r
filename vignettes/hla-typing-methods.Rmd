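---
title: "Diploid HLA typing by candidate selection and pairwise likelihood: models and design"
author: "HLApair authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diploid HLA typing by candidate selection and pairwise likelihood: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HLApair)
```

## The problem

The classical HLA loci are diploid and hyper-polymorphic: each locus has
thousands of documented alleles, most differing at a handful of coding
positions concentrated in the peptide-binding exons. A short sequencing
read therefore rarely identifies one allele; it is compatible with many.
HLApair turns reads aligned against an allele reference into the most
probable *pair* of alleles per locus, evaluated jointly rather than one
allele at a time, and reports the call at the deepest nomenclature
resolution the data support.

Two ideas carry the method. First, most alleles of a locus are plainly
wrong for a given sample, and the reads that support them are the noisy,
cross-mapped ones; a count-based candidate selection removes both before
any model is fit. Second, among the few surviving candidates, a full
likelihood over all C(n,2)+n unordered pairs — self-pairs included —
lets homozygous and heterozygous explanations compete on equal terms.

## Candidate selection

Selection operates on read counts in three tiers, each with a tunable
threshold (all exposed through `hlaConfig()`):

1. **Quantile pre-selection** (`preselect_quantile`, default 0.90).
   Alleles whose raw mapped-read count reaches the locus's empirical
   90th percentile (type-7 quantile, linear interpolation; threshold
   ties are all kept) are retained, plus every allele sharing a
   four-digit identity with a retained allele. This mirrors the role the
   step plays at real scale: with thousands of database alleles, a top-decile
   cut is a coarse filter that true alleles pass comfortably.
2. **Optimal-read marking** (`min_identity`, default 0.99). SNP sites
   are the polymorphic CDS positions among retained alleles, minus any
   position coinciding with an indel (a frame column not covered by
   every retained allele's CDS). Each read is credited only to the
   allele(s) with maximal identity over the SNP sites it covers, and
   only when that identity is at least 99%. The threshold is applied
   literally even for reads covering a single site, where identity is 0
   or 1. Mismatches outside SNP sites never matter; alignment indels
   contribute no base at the affected site.
3. **Leveled protein-group ranking** (`unique_frac` 0.01,
   `explain_frac` 0.90, `account_frac` 0.10). Optimal reads are pooled
   non-redundantly per protein group. Level 0 takes the top group(s) and
   a runner-up holding more than 1% unique reads — measured against the
   union of all level-0 selections when the top is a tie. Level 1
   re-ranks the remainder after removing every read counted for a
   level-0 group, and selects the top only if its adjusted count is
   positive (a zero-count "top" would admit arbitrary alleles). Level 2
   runs at most once, when the selections explain under 90% of the
   locus's reads, and admits a group accounting for more than 10% of
   them.

Selected groups receive one-tailed Gaussian z-test p-values against the
background formed by the never-selected groups' counts at the same
level (sample variance; fewer than `min_background = 3` background
groups yields `NA`; a zero-variance background yields the smallest
representable positive value with a warning). These p-values describe
how far a selected group sits above the background. They never
influence which pair is called — the caller's decision path reads only
the likelihood table — and the test suite asserts exactly that.

## The likelihood model

For a candidate pair \((a, b)\) the score is
\[
LL_{total} = LL_{geno} + LL_{phase} + LL_{freq},
\]
all in natural logs, computed over CDS SNP sites only.

**Genotype term.** At site \(i\) the pair defines a genotype
\(G^i = \{b_1, b_2\}\). Each read base \(d\) with Phred-derived error
rate \(q = 10^{-Q/10}\) contributes
\[
P(d \mid G^i) = \tfrac12 f(d \mid b_1) + \tfrac12 f(d \mid b_2),
\qquad
f(d \mid b) = \begin{cases} 1-q & d = b\\ q/3 & d \ne b,\end{cases}
\]
the standard diploid pileup model: one matching and three mismatching
states per site, the four-outcome distribution summing to one. The
genotype prior is taken constant across genotypes, so no prior term
appears. Sites without coverage contribute nothing.

**Phase term.** A read — or a linked mate pair, merged by name so that
paired-end data effectively double the span — covering at least two SNP
sites is phase-informative. For an observed base pair \((d_i, d_j)\)
against a phased haplotype \(h\) there are \(4 \times 4 = 16\) joint
states: one in-phase state with probability \(1 - q_{ij}\) and fifteen
out-of-phase states with \(q_{ij}/15\) each, where
\(q_{ij} = 1 - (1-q_i)(1-q_j)\) combines the two bases' independent
error rates (and reduces to the single-site model when one base is
error-free). The pair's two haplotypes are mixed evenly, as in the
genotype term. Each informative unit contributes its *consecutive*
covered-site pairs (`phase_pairing = "adjacent"`); enumerating all
pairs is available as an option but re-counts the same evidence
quadratically, which overweights long reads. A site covered by both
mates keeps the higher-quality base.

**Frequency term.** \(LL_{freq} = \log f(a) + \log f(b)\), where a
protein group's frequency is the maximum reported over populations and
unrecorded groups sit at `freq_floor` (default \(10^{-6}\), far below
any realistic recorded frequency, keeping the term finite while
guaranteeing it cannot outvote data). In practice \(LL_{freq}\) is
orders of magnitude smaller than the data terms; it matters only when
candidates are tied at the data level, e.g. alleles identical over all
covered SNP sites, where it acts as a population-prior tie-break.

**Ties and collapse.** Pairs within `tie_tol` (\(10^{-9}\), absolute,
in log space) of the maximum are treated as equally likely. A unique
best pair is reported at full resolution; otherwise renderings descend
eight → six → four digits (never deeper than the shallowest tied name)
until the tied pairs agree, and a locus with no agreement at four
digits is reported ambiguous with all tied pairs listed. The accuracy
definition counts ambiguous loci as wrong.

### Which reads enter the likelihood

SNP sites are computed once per locus, from the quantile-retained
allele set, and reused for optimal marking and scoring; restricting
them further to candidate-only polymorphism would add the same constant
to every pair and cannot change the argmax. The likelihood consumes
every read optimal for at least one candidate — the pair must explain
the locus's evidence, not just its own reads.

## The synthetic data generator

`buildToyDb()` manufactures, per locus, a random ancestor with a
two-exon layout (CDS ≈ 70% of the locus). Protein groups are
distinguished by their base patterns over a set of shared polymorphic
sites (`group_sites`, default 40) clustered in a hypervariable coding
window (`hypervar_window`, default 150 bp): this emulates the dense
exon-2/3 polymorphism of real class I/II loci, where allele groups
differ at many nearby positions, and it is what makes count-based
selection meaningful — a read overlapping the window is compatible with
few groups, a read outside it with all. Within a group, six-digit
variants add scattered synonymous-role coding substitutions and
eight-digit variants add intronic ones, so every nomenclature tier
exists by construction. Group frequencies follow a jittered geometric
decay — a few common groups and a long tail — recorded for two
populations with the larger value operative.

Default study conditions (`simConfig()`): 6 loci, 70 alleles in 32
protein groups per locus, 1 kb loci, 2×100 bp paired-end fragments of
300 ± 30 bp, 100× coverage, per-base substitution error 0.001 (Phred
30), uniform fragment sampling with an even haplotype mixture. Read
lengths 37–250 bp and coverages in the tens-to-hundreds are the
intended range. The seed determines everything. The built-in aligner is
a deliberately simple placement scheme: each read is placed at its true
frame interval on every same-locus allele within `k = 4` mismatches
(best match first), which exercises multi-hit handling; real data
should come pre-aligned by a genuine aligner.

What the generator does *not* emulate: RNA splicing and
expression-level bias, indels (the inference skips indel sites
regardless), base-quality miscalibration, amplification artifacts, and
— importantly — cross-locus mis-mapping from homologous genes outside
the reference (in real data, paralogues such as the DQA2/DQB2 region
can donate reads to DQA1/DQB1 and are a known source of systematic
mistypes). Passing simulations therefore demonstrate the correctness of
the selection and likelihood machinery under calibrated errors, not
robustness to reference incompleteness.

## Numerical and degenerate-input choices

* All internal coordinates are 0-based half-open; SAM's 1-based
  positions are converted at ingestion, honouring CIGAR (insertions and
  soft clips consume read bases, deletions/skips consume frame).
* Missing base qualities (`*`, or BAM's 0xff filler) become
  `default_phred = 30`.
* Read units are single mates (`qname/mate`); mates re-link for phase.
* An empty alignment, an empty candidate set, or a locus absent from
  the input yields an explicit no-call row, never an error.
* If all retained alleles are CDS-identical (no SNP sites), the data
  cannot rank them: all retained alleles become candidates, data terms
  vanish and the frequency prior decides, typically collapsing to a
  consensus rendering.
* Identity ties in optimal marking use a \(10^{-12}\) tolerance below
  the maximum to absorb float noise in the division.
* Duplicate full allele names, empty sequences, and CDS lengths
  incompatible with the exon layout are rejected at construction.

## Problem sizes in the test suite

The suite verifies the likelihood against an independent brute-force
scorer on randomized instances up to 8 alleles × 30 sites × 500 reads
(tolerance \(10^{-9}\)), the selection rules against a step-by-step
oracle on ≥ 50 random group configurations, and end-to-end parameter
recovery on 20 seeded replicates of the 6-locus toy at 2×100 bp and
100×, with coverage and pairing trends measured over 10-seed batches at
25×/50×/100× and 2×37 bp. These sizes were chosen to exercise every
code path at desk scale while keeping the whole suite comfortably
reproducible on a single CPU.

## Known limitations

* Inference is CDS-only; intron-only variants are reported as ties
  collapsed to six digits. Including intronic SNPs would sharpen
  eight-digit calls.
* Indel polymorphism is masked, not genotyped.
* Prior frequencies enter as max-over-population group values; no
  population-specific or haplotype-linkage priors.
* The Gaussian background for the descriptive p-values degenerates on
  very clean data (zero background variance), where the p-value
  saturates at the smallest representable value.
* The placement aligner is for self-contained testing only; it assumes
  colinear toy alleles and no sequencing indels.
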