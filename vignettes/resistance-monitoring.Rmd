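---
title: "Monitoring insecticide-resistance mutations from population resequencing data"
author: "resistscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring insecticide-resistance mutations from population resequencing data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resistscan)
```

## The monitoring problem

Field populations of crop pests such as the fall armyworm (*Spodoptera
frugiperda*) evolve resistance to insecticides through two broad
mechanisms: **target-site mutations** — amino-acid changes in the protein
the insecticide binds (the ABCC2 midgut receptor for Bt toxins,
acetylcholinesterase for organophosphates and carbamates, the
voltage-gated sodium channel for pyrethroids, the ryanodine receptor for
diamides) — and **metabolic resistance**, most prominently copy-number
expansion of cytochrome P450 detoxification gene families. Because the
fall armyworm recently invaded Africa and Asia from the Americas, a
central surveillance question is whether known resistance alleles rode
along with the invasion.

`resistscan` implements the statistical core of such a survey as a
reusable pipeline over standard file formats. Given a multi-sample diploid
VCF, a sample-to-population-to-cohort map, a curated resistance-mutation
catalog, gene models and per-gene copy-number calls, it answers four
questions:

1. **Who carries which cataloged mutation?** Genotype screening with
   codon-level consequence annotation, summarised as carrier counts and
   proportions per population and cohort (native vs invasive).
2. **Is a candidate gene unusually differentiated** between resistant and
   susceptible groups? Weir–Cockerham $F_{ST}$ with a genome-resampling
   empirical null.
3. **Do cohorts differ in gene-family CNV burden?** Duplicated/deleted
   event counts per clan with a two-tailed Fisher exact test.
4. **Could we have missed a rare allele?** Analytic detection power under
   binomial sampling.

## Genotype screening and consequence annotation

Catalog entries carry two keys: a genomic spec (chrom, pos, ref, alt) and
a protein spec (e.g. substitution F209V, in-frame deletion of G,Y,
frameshift). Genomic matching is performed after **normalization** — both
the catalog entry and every VCF site are trimmed of shared prefix/suffix
bases and indels are left-aligned against the reference context — because
different variant callers emit the same indel in different coordinate
conventions and matching a "2 bp GC insertion" across representations
requires a canonical form. When an entry has no genomic spec (no assembly
coordinates are published for several catalog mutations, so protein-level
specs are the primary keys), every site inside the gene is
consequence-annotated and any site whose protein-level consequence equals
the spec matches; a multi-alternate entry such as P799K/R matches either
residue.

Consequence calling rebuilds the mutant coding sequence from the gene
model (minus-strand genes are reverse-complemented; codon indices always
count from the initiator Met) and translates it under the standard genetic
code. For frameshifts the downstream sequence is re-read in the shifted
frame until the first stop codon, reported as the premature-stop codon
index; the scan never runs past the annotated CDS end — when no stop
appears the change is flagged as an extension rather than inventing one.
A variant spanning a CDS/intron boundary raises an explicit error instead
of a silent misannotation. One deliberate modelling choice: a 12 bp
insertion cannot shift the reading frame (12 is a multiple of 3), so the
cataloged 12 bp ABCC2 insertion is encoded as an in-frame insertion whose
inserted sequence carries an in-frame stop codon — reproducing the
premature-stop consequence reported for it while keeping the catalog's
frame-arithmetic invariant consistent.

Counting conventions:

* **Carrier** = at least one resistance allele (heterozygous or
  homozygous); allele frequencies are reported alongside.
* Samples with a **missing genotype** at a mutation's site are excluded
  from that mutation's denominator; denominators are always emitted with
  proportions, because carrier percentages are meaningless without them.
* A cataloged site with **no VCF record** is reported absent in every
  sample: a resequencing VCF carries only variant sites.
* **Codon spectra** (which codons does a population carry at one residue)
  are phased naively: an individual heterozygous at two or more sites
  within a codon is reported as `ambiguous`, never resolved by guesswork —
  an unphased VCF cannot distinguish the haplotypes (read-level inspection
  could, but this pipeline does not consume reads).

## Weir–Cockerham $F_{ST}$ and the resampling null

Per biallelic locus, the 1984 estimator's variance components are computed
for $r = 2$ groups of diploids from group sample sizes $n_i$, allele
frequencies $p_i$ and observed heterozygote frequencies $h_i$:
$a$ (among groups), $b$ (among individuals within groups) and
$c$ (within individuals), with $\hat\theta = a/(a+b+c)$. Multi-locus
$\hat\theta$ is the **ratio of sums** $\sum a / \sum(a+b+c)$ — the
convention of the common command-line tools — with the per-locus-mean
variant available behind a flag for comparison only. Numerical choices:

* Per-locus estimates are **not truncated at zero**; truncation would bias
  the multi-locus ratio. Identical groups therefore give $a \le 0$.
* A locus where either group has fewer than two callable genotypes is
  flagged uninformative and excluded from the sums; a monomorphic locus
  has $a+b+c = 0$ and an undefined (NA) $\hat\theta$, never a silent 0.
* "Complete differentiation" means $\hat\theta = 1$ within $10^{-12}$.

The **empirical null** asks how often a random genomic window of the same
length $L$ as the candidate gene reaches the observed multi-locus
$\hat\theta$. Each replicate draws a chromosome with probability
proportional to its placeable length ($\mathrm{len}-L+1$), then a uniform
start so the window fits entirely. Windows with no informative SNP are
**redrawn** (and counted): scoring them 0 would deflate the null and
overstate significance. Replicates are drawn with replacement and may
overlap the target; excluding the target window is available behind a
flag. Ties count as exceedances at tolerance $10^{-12}$ (conservative).
Two p-values are reported: $p_\mathrm{plain} = \#\{\hat\theta_\mathrm{rep}
\ge \hat\theta_\mathrm{obs}\}/n_\mathrm{valid}$, matching the published
convention (7,700 exceedances in 100,000 replicates read as $p = 0.077$),
and $p_\mathrm{conservative} = (\#+1)/(n+1)$, which is never exactly zero.
Replicates are drawn sequentially from a single seeded RNG stream; the
seed is logged in the result object so every run is reproducible.

## CNV burden and the exact test

Copy-number input is per sample per gene, either trinary states or integer
copy numbers mapped by the diploid convention (<2 deleted, =2 neutral,
>2 duplicated). A gene counts **once per individual** regardless of
magnitude. Burden is summarised per cohort and P450 clan as event totals
and per-individual means; the cohort contrast pools gene-level events into
a 2×2 table (cohorts × duplicated/deleted). Pooled events within an
individual are not independent, which is why the per-individual means are
always reported next to the test.

The two-tailed Fisher exact test is implemented from first principles:
conditioning on the margins, the p-value sums hypergeometric point
probabilities over all tables no more probable than the observed one, with
a $1 + 10^{-7}$ relative tie tolerance — the convention of the R
environment in which such tests are conventionally run. Probabilities are
evaluated in log space via `lchoose`, so pooled event totals up to
$\sim 10^5$ remain exact to double precision. The odds ratio is the
conditional maximum-likelihood estimate under the noncentral
hypergeometric model. Degenerate tables (a zero row or column margin)
return $p = 1$ with a flag. Raw p-values are reported without
multiple-testing correction, as is conventional in this monitoring
setting; the run report prints the number of tests performed.

## Detection power

A sample of $N$ diploids carries $2N$ alleles; under binomial sampling the
probability of observing **no copy** of an allele at frequency $p$ is
$(1-p)^{2N}$, evaluated in log space. At $p = 0.01$ and $N = 99$ this is
13.67% — the survey-design number for "could a rare resistance allele
have been missed". The inverse, the smallest $N$ with miss probability at
most $\alpha$, is $\lceil \ln\alpha / (2\ln(1-p)) \rceil$. The formula
assumes independent alleles (no inbreeding, no pooled sequencing); this is
documented as an assumption, not corrected for.

## What the synthetic data emulate — and what they do not

All stages are exercised on generated data with recorded ground truth:

* **Catalog sites**: Hardy–Weinberg genotypes at specified per-population
  allele frequencies; the truth file records every planted carrier, so
  screening can be scored for exact recovery.
* **Background SNPs**: ancestral frequency uniform on [0.05, 0.95],
  per-population frequencies Beta-distributed around it under the
  **Balding–Nichols** model. Balding–Nichols was chosen because its $F$
  parameter is exactly the Weir–Cockerham estimand, enabling direct
  parameter-recovery checks ($F \in \{0.05, 0.2, 0.5\}$, 5,000 loci,
  50 diploids per group, recovered within ±0.02).
* **CNV events**: Poisson counts per individual per clan at
  cohort-specific duplication/deletion rates, assigned to distinct genes.
* **The worked-example fixture**: a deterministic two-chromosome synthetic
  genome (synthetic stand-in coordinates; no real assembly positions are
  published for the catalog) carrying the four target genes, the 13-entry
  catalog, and 177 individuals matching the study structure — 78 invasive
  (29 corn-strain + 49 rice-strain) and 99 native (70 + 29), with the
  published ABCC2 carrier table encoded exactly and every other individual
  mutation-free. Population sizes beyond the named carriers are a design
  choice of this package (Puerto Rico is sized to 33 so all named carriers
  exist; the remainder is spread over the other populations) — the paper's
  per-population sizes are not printed, so cohort-level proportions from
  the fixture have realistic but not reproduced denominators.

Loci are placed uniformly at random with no linkage disequilibrium, no
recombination map and no demographic history; genotypes have no calling
error. Passing tests therefore demonstrate correctness of the estimators
and bookkeeping under the models they assume — exchangeable loci for the
resampling null, HWE within populations — not robustness to LD, batch
effects or genotyping error in real resequencing data. The null-calibration
check (empirical p of an ordinary window approximately uniform over 200
experiments of 500 replicates each) holds by construction on exchangeable
loci; on real genomes with LD the effective number of independent windows
is smaller and the null is coarser.

## Problem sizes and tolerances used by the test suite

Estimator equivalence is asserted to $10^{-12}$ against an independent
transcription of the published formulas (1,000 random loci); the exact
test to $10^{-10}$ against full enumeration (500 random tables, totals
≤ 80). Stochastic checks use 3-standard-error bands. The suite runs
5,000-locus differentiation simulations, a 200 × 500-replicate null
calibration, and 50 seeded screening-recovery runs — sizes chosen so the
whole suite completes in a couple of minutes while leaving the binomial
error bands narrow.

## Known limitations

* Screening matches biallelic records; multi-allelic records are split
  alt-by-alt at ingestion (policy configurable).
* Consequence annotation refuses variants spanning exon boundaries rather
  than modelling splice disruption.
* The resampling null treats loci as exchangeable; it does not model LD
  or local recombination-rate variation.
* Codon spectra cannot resolve multi-site heterozygous codons without
  phased data.
* The detection-power formula ignores inbreeding and pooling.
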