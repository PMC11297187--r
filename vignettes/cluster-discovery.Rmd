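---
title: "Discovering a degradation gene cluster by comparative genomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering a degradation gene cluster by comparative genomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bxdseeker)
```

## The problem

Maize roots exude benzoxazinoids, and their dominant stable breakdown
product in the rhizosphere, MBOA (6-methoxybenzoxazolin-2(3H)-one,
an 8-carbon molecule), selects for bacteria that can metabolise it.
Some root bacteria — notably microbacteria — convert MBOA into the
dark-red aminophenoxazinone AMPO; this visible phenotype splits a strain
panel into AMPO-formers ("positive") and non-formers ("negative"). The
question `bxdseeker` answers is genomic: *which genes make a strain an
AMPO-former?* Given a panel of annotated genomes with a binary
phenotype, the package triangulates candidate genes through three
independent evidence channels and then exploits the tendency of
bacterial catabolic genes to sit in operons: true hits should be
*adjacent* in the genome, forming a degradation (bxd) gene cluster.

The three channels are deliberately different in what they assume:

1. **Kmer association** — alignment-free. Every genome is decomposed
   into canonical 21-mers; each kmer gets a phenotype score
   (#positive genomes containing it − #negative genomes containing it);
   genes of a reference strain containing high-scoring kmers (score ≥ 7
   by default) are candidates. Because exact kmer matching is brittle
   across diverged strains, candidate genes are greedily clustered at
   70% nucleotide identity and each cluster centroid is expanded into a
   hit list across all genomes (kmer containment ≥ 0.1 of the centroid's
   kmers *and* global identity ≥ 0.7). Each hit list yields a 2×2
   presence/phenotype table tested with Fisher's exact test,
   Benjamini–Hochberg corrected across centroids.
2. **Gene-family association** — orthology-aware. Genes are grouped
   into families (an external orthogroup table, or the package's greedy
   protein clustering at 50% identity), and families *unique and
   specific* to positives (present in all positives, absent from all
   negatives, both fractions relaxable) are called, again with
   Fisher/BH statistics reported for every family.
3. **Differential expression** — condition-responsive. A count matrix
   from the reference strain exposed to the compound versus control is
   normalized by median-of-ratios size factors and tested per gene
   (Welch t on `log2(normalized + 1)`, BH across genes).

Candidates are intersected (a seven-region Venn report), merged (union
by default), and runs of candidates separated by at most `max_gap = 2`
non-candidate genes with at least `min_genes = 3` members are called as
clusters. Cluster genes are named systematically (`bxdA`, `bxdB`, …,
continuing `bxdAA` beyond Z), and the cluster region is typed across
carrier strains by its family-label sequence, treating a fully reversed
sequence as the same architecture.

## A complete run on synthetic data

The generator plants a known cluster so that recovery can be verified
against ground truth. Defaults mirror the study design the package
targets: 16 positive and 23 negative strains, 300 background genes per
genome, and a contiguous 15-gene cluster carried only by positives.

```{r, eval = FALSE}
sim <- simulateGenomeSet(SimParams())       # seed 42 by default
gset <- sim$genomes
ref <- referenceStrain(sim$truth)           # first cluster carrier
counts <- simulateCountMatrix(gset, sim$truth, seed = 1)
report <- runFullPipeline(gset, ref, counts = counts)
report
#> ClusterReport | reference: S02
#>   candidates: 17 | clusters called: 1
#>   GeneCluster on c1: 15 genes (bxdA..bxdO), type I
#>   stages: kmer=ok, family=ok, de=ok, integration=ok
```

The single called cluster coincides exactly with the planted genes.
Note that individual channels are *not* expected to be clean: at this
design size an accessory decoy family present in, say, 7 positives and
1 negative reaches raw p < 0.05 in the kmer channel, exactly as chance
associations do in real pan-genomes. The adjacency step is what removes
them — scattered false candidates do not form runs.

## What the generator emulates, and what it does not

Each background gene family receives a random ancestral coding
sequence; every strain's copy is mutated independently by substitutions
at `per_site_divergence = 0.02` per site. Substitution-only mutation
(no indels) keeps gene lengths stable and makes pairwise identity
approximately `1 − 2d`, so the 70% clustering threshold and the 50%
protein-family threshold operate far from their boundaries.
Design choices the data model leaves open were fixed once:

* **Core/accessory structure.** `core_fraction = 0.8` of the 300
  background genes are core (present in every strain); the remaining 60
  slots are drawn per strain from a pool of 180 accessory decoy
  families. Accessory families carried by phenotype-blind random strain
  subsets give the Fisher tests genuine true negatives — and
  occasionally, genuine chance associates.
* **Cluster placement.** The 15 cluster genes are additional to the 300
  background genes and are inserted as one block at a random inter-gene
  position per carrier, so adjacency calling is tested independently of
  genomic position. Genes sit on one contig per strain with random
  50–200 nt spacers and random strands.
* **Counts.** Negative binomial around log-normal baseline means
  (log-mean `log(200)`, log-sd 1), dispersion 0.05, with cluster-gene
  means multiplied by `2^lfc_cluster` under treatment. The planted
  `lfc_cluster = 3` is a choice — the magnitude of real cluster
  upregulation is not prescribed anywhere — and is exposed as a
  parameter; with 4 replicates per condition it is comfortably above
  the detection limit of the Welch stage.
* **Assay tables.** Metabolite concentrations are drawn to satisfy the
  strong/non classification bands (positives degrade > 90% of the
  control MBOA and form > 10% of the maximal AMPO; negatives < 30% and
  essentially none), and growth curves are logistic with a capacity
  benefit on MBOA only for positives. They close the loop:
  classifying the emitted tables reproduces the generated labels.

What the generator does **not** model: recombination, rearrangement,
horizontal transfer, indels, assembly artefacts, paralog expansion
beyond copy-1 families, or compositional biases. A pipeline that
recovers the planted cluster here has demonstrated its statistical and
combinatorial machinery, not robustness to every property of real
assemblies.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `k` | 21 | kmer length; canonical (min of window and reverse complement), windows with N skipped |
| `min_score` | 7 | phenotype-score threshold for "high" kmers; bounded by the class sizes (+16/−23 at defaults) |
| `cluster_identity` | 0.70 | greedy clustering threshold for candidate genes |
| `hit_min_identity` | 0.70 | identity for a gene to join a centroid's hit list |
| `hit_min_containment` | 0.1 | fraction of centroid kmers a gene must share before alignment is attempted |
| `alpha` | 0.05 | significance level (raw p by default; BH-adjusted values always reported) |
| `max_gap` | 2 | tolerated non-candidate genes inside a cluster run |
| `min_genes` | 3 | minimum cluster size |

Significance of centroids uses the raw Fisher p by default, with the
BH-adjusted value reported alongside and selectable
(`significance = "adjusted"`); with a handful of centroids the two
rarely disagree. Fisher tests are two-sided by default;
`alternative = "greater"` restricts to enrichment in positives.

## Numerical and algorithmic choices

* **Kmers** are 2-bit packed into doubles (exact below 2^53, so
  numeric order equals lexicographic order on A<C<G<T); presence is a
  sparse kmer × strain pattern matrix, and rescoring under a permuted
  phenotype is a single sparse matrix–vector product. Matrix
  construction refuses inputs whose estimated distinct-kmer count
  exceeds `max_kmers` (default 1e8) rather than thrash memory.
* **Identity** everywhere means matches / alignment columns of an
  end-gap-free global alignment (nucleotide match 1 / mismatch −1, gap
  open 2 / extend 1; protein BLOSUM62, gap 11 / 1), with unaligned
  terminal stretches counted as gap columns. Without that last rule, a
  short spurious overlap between unrelated sequences would score as
  high identity.
* **Greedy clustering** processes sequences longest-first and assigns
  each to the first accepting centroid. It is implemented
  centroid-first (batch-aligning all unassigned sequences against each
  new centroid), which yields the identical partition with far fewer
  alignment calls; for whole-proteome family building an amino-acid
  4-mer sharing prescreen (≥ 0.02 of the centroid's words) skips
  alignments that cannot succeed at the 50% threshold.
* **Best-hit screening** uses Smith–Waterman to find the hit but
  expresses identity/similarity over the full extent of both sequences;
  similarity is the fraction of positive-scoring BLOSUM62 columns. The
  high/low category boundaries (≥ 60% / < 25%) are inclusive/exclusive
  respectively and configurable.
* **Ties and degeneracies.** Best hits tie-break by score then gene id;
  the all-or-nothing 2×2 tables (p = 1 and p = 1/C(39,16)) are exercised
  in the tests against closed forms; a zero-variance gene with equal
  means gets p = 1, with different means p = 0; classification
  boundaries fall into the weaker class because three strict
  inequalities cannot tile the line.
* **Architecture types** are labelled I, II, … by decreasing class
  size, ties by first occurrence. Chemical phenotype is *not* part of
  the equivalence — it is reported separately by the phenotyping tools.

## Phenotyping toolkit

The genotype labels come from assay classifications that the package
also implements: percent-degraded and percent-of-max AMPO bands
(`classifyDegrader()`, `classifyAmpoFormer()`), trapezoidal growth AUC
with per-strain one-sample t-tests of treatment/control ratios
(`growthBenefitTest()`, BH across strains), glucose carbon-equivalents
for carbon-source experiments (`carbonEquivalentGlucose()`: 500 µM of
an 8-carbon compound ↔ 667 µM glucose), and 16S-based strain abundance
as the sum of amplicon variants above 99% global identity
(`estimateStrainAbundance()`).

## Scale of the shipped validations

The test suite runs the full pipeline at the default design
(39 genomes × ~300 genes, ~10 million distinct 21-mers), sweeps every
2×2 table with class sizes up to 30 against an exhaustive
hypergeometric enumeration, permutes the phenotype 100 times to verify
that cluster calls are quiet under the null, and simulates 50 null and
50 signal count matrices for the differential-expression stage. These
sizes were chosen so the whole suite completes in well under half an
hour on one core while still exercising the defaults end to end.

## Known limitations

* The kmer matrix is held in memory; real assemblies at scale would
  need a disk-backed counter in front, with the association stages
  unchanged.
* The differential-expression stage is honest plumbing (normalization +
  Welch t), not a negative-binomial GLM; for real RNA-seq, import an
  external table with `readDETable()`.
* De-novo families are greedy single-linkage-to-centroid clusters, not
  phylogenetic orthology; paralogs collapse into one family when above
  the identity threshold.
* Architecture typing compares family-label sequences only; it does not
  attempt synteny alignment across rearrangement breakpoints.
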