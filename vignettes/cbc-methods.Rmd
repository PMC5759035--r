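---
title: "Deconvolving community-based culture collections and designing abundance-ranked synthetic communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolving community-based culture collections and designing abundance-ranked synthetic communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A community-based culture collection (CBC) trades colony purification for
throughput: colonies are picked into plate wells *regardless of whether
they contain one or several microbes*, and the composition of each well is
resolved afterwards by sequencing. This package implements the
computational side of that strategy for plant-associated bacteria:

1. **Well deconvolution.** Long-amplicon 16S consensus reads (one per
   sequencing pass group, carrying a pass count) are demultiplexed to
   wells, filtered by coverage (pass count &ge; 2) and by reliability
   (similarity to a curated reference and/or to a read from a different
   well), and clustered *within* each well into well-level OTUs (wOTUs).
   The number of wOTUs is the number of co-cultured members of that well.
2. **Collection-level dereplication.** wOTU centroid sequences are
   re-clustered across wells into collection-level OTUs (cOTUs), the unit
   in which the collection's unique bacteria are counted, their redundancy
   across wells measured, and their culture-media preferences summarised.
3. **Cross-referencing.** cOTUs are linked to the OTUs of an independent,
   culture-independent microbiome survey (mOTUs) by aligning the short
   mOTU representatives against the collection's consensus reads and
   mapping those reads back to their cOTUs. With per-habitat mOTU
   abundances this yields the *recovery*: the share of each habitat's
   core-microbiome abundance that has a cultured representative.
4. **Synthetic community (SynCom) design.** Cultured cOTUs are ranked by
   the core abundance of their linked mOTUs across target habitats; the
   top *k* are covered by a minimal set of culture wells (greedy set
   cover), so one multi-member well can contribute several members.
5. **Colonization analysis.** Inoculated and uninoculated plants are
   profiled from short 16S reads (expected-error, length and plastid
   filters; UPARSE-style OTU calling; read-back mapping) and compared by
   Bray–Curtis dissimilarity, PCoA, ANOSIM, per-OTU Kruskal–Wallis
   screens, displacement summaries and a biomass response.

All stages run end to end on a seeded synthetic world with a ground-truth
manifest, so every inference step can be scored against what was planted.

## Sequence identity: the convention that matters

Every threshold in the pipeline (0.97 OTU radius, 0.80/0.97 reliability,
0.75 reference screen, 0.97 cross-reference match) is an *identity*, and
identity is not a single convention. This package computes optimal global
(Needleman–Wunsch) or semiglobal alignments with affine gap costs
(match +1, mismatch −2, gap open 10, gap extend 1; a gap of length
*L* costs 10 + *L*) and defines

> identity = matching columns / alignment columns, after stripping
> terminal-gap columns,

the USEARCH-like "internal" identity. `N` never matches. All thresholds
are inclusive (&ge;). The semiglobal mode leaves gaps at the *target's*
ends free, which is how a 250-base mOTU representative is located inside a
full-length consensus read; identity is then computed over the query's
aligned span and a query-coverage fraction is reported. The aligner is
implemented in C++ (`src/alignment.cpp`); its scores are cross-checked in
the test suite against both an exhaustive alignment enumerator (short
sequences) and an independent implementation (Biostrings).

## Greedy centroid clustering

`greedy_cluster()` processes sequences in decreasing size order
(dereplicated short reads, UPARSE convention) or decreasing length order
(long consensus reads), assigning each sequence to the **best-identity**
existing centroid at or above the threshold — not the first qualifying
one — with ties broken toward the earliest-created centroid; otherwise the
sequence founds a new cluster. Best-match assignment makes the partition
robust to the order in which near-threshold centroids were created; the
deliberate divergence from strict first-hit UCLUST behaviour is asserted
against an exhaustive oracle in the tests. Centroids are pairwise below
the threshold by construction. A k-mer screen (8-mers, with a
conservative shared-count bound derived from the threshold: an alignment
at identity *t* over a query of length *L* can destroy at most
8·(⌈(1−*t*)·*L*⌉+1) of the query's 8-mers) restricts which
centroids are aligned at all; the screen is superset-safe, so it never
changes the result, only the cost.

Singletons are retained in well clustering (a single colony member may be
real) but excluded as OTU seeds in short-read profiling, where a
post-clustering two-parent crossover test (`flag_chimera()`) also removes
chimeric seeds; both follow common amplicon practice and are
configurable.

## Taxonomy

One k-mer bootstrap classifier serves all levels: each of 100 bootstraps
draws 32 of the query's 8-mers (with replacement), scores references by
shared k-mer count, and votes with the top reference's lineage. Per-rank
confidence is the fraction of bootstraps agreeing with the modal label;
ranks below the 0.9 cutoff become unknown, and unknowns propagate
downward. Display labels collapse to the deepest known rank with a `u_`
prefix when that rank is above genus (`u_Rhizobiaceae`), or `u_Bacteria`
when nothing is confident.

## Core microbiome, recovery and design choices

The *core* of a habitat is the minimal abundance-ranked prefix of its
mOTUs whose cumulative relative abundance reaches 0.90 (boundary ties all
included). Recovery is the linked share of that core abundance, in
percent; a flag switches to whole-community denominators. When ranking
SynCom candidates the default aggregation across target habitats is the
maximum of a cOTU's linked core abundances (`mode = "sum"` is available);
the choice matters only when a taxon is abundant in several habitats at
once, and the maximum was preferred because an inoculant candidate is
interesting wherever it peaks.

## The synthetic world

The generator plants, in order: (i) a clade-structured reference universe
(default 30 taxa in 6 clades, 750 bp, 2% within-clade and 25%
between-clade substitution divergence) with phylum-to-genus labels per
clade; (ii) log-normal habitat profiles (σ = 2.5), giving the
core-microbiome skew in which the top 20% of taxa hold &ge; 80% of the
abundance in over 95% of draws; (iii) a culture collection (default 400
wells sourced from rhizosphere, endophytic root and endophytic stalk at
weights 1717:923:302, the well provenance of the study the generator
emulates) in which each well is single-member with probability 0.5,
otherwise holds 2–4 members drawn abundance-weighted among the taxa able
to grow on the well's medium (LB8 / LB35 / YPD; each taxon grows on a
given medium with probability 0.6, and on at least one). Members emit
3–8 consensus-like reads with substitution:insertion:deletion errors at
80:10:10 of a 0.5% per-base rate, a pass count of 1 + Geometric
(mean 5), and a 12-base well barcode prefix; (iv) a short-read survey
(250-base window of the reference, 1% error, per-base Phred drawn
uniformly from 25–40, a 5% plastid read fraction) and mOTU truth; (v) an
inoculation experiment in which SynCom members are multiplicatively
enriched (×50) in inoculated samples and multinomially sampled, with
five replicates per group. SynCom members are additionally down-weighted
(×0.05) in the *baseline* profiles of the inoculated-plant host, because
the community is assembled from another host's microbiome and is naturally
rare before inoculation — this is what makes displacement measurable.
Plant biomass is drawn around group means of 7.82 g and 2.31 g fresh
weight, the means of the inoculation experiment the generator emulates.

The default problem sizes (400 wells, 3,000 survey reads per habitat,
800 profiling reads per sample) are the package's demonstration scale:
large enough for every statistic to be exercised, small enough to run
interactively. The acceptance checks use their own stated sizes (e.g.
300 wells with 20 well-separated taxa for deconvolution recovery).

What the generator does *not* emulate: chimera formation during PCR,
primer/PCR bias, length heterogeneity of real 16S regions, fungal (ITS)
data, and phylogenetic signal beyond the clade hierarchy. Passing tests
therefore demonstrate correctness of the inference machinery under a
known model, not performance on real sequencing data.

## Numerical and statistical choices

* Filters are inclusive at their boundaries (passes &ge; 2, EE &le; 0.25,
  lengths 230–270, identities &ge; threshold).
* The expected error of a read is Σ 10^(−Q/10) over its Phred scores.
* The plastid screen replaces an external k-mer tool with an explicit
  21-mer set screen at a 5% shared-fraction threshold.
* Reliability defaults: database identity 0.80, cross-well peer identity
  0.97 (within-well peers cannot self-validate); the source study does
  not print these, so they are declared assumptions, configurable.
* Bray–Curtis, PCoA, ANOSIM, Kruskal–Wallis, Welch t, Spearman are
  delegated to vegan and base R; PCoA keeps negative eigenvalues visible
  and scales axes by the square roots of the positive ones; ANOSIM p
  carries the +1 permutation correction. Per-OTU Kruskal–Wallis is
  reported at unadjusted p &lt; 0.05 to match the emulated analysis; a
  BH-FDR flag exists but is off by default.
* All randomness flows through `derive_seed(master_seed, stream_label)`,
  so one seed fixes the world, the classifier bootstraps, the
  permutations and the simulated experiment, and any stage can be re-run
  in isolation.

## Known limitations

* Greedy centroid clustering is order-dependent by design; the package
  fixes the order (size, then length, then id) so results are
  reproducible, but a different order convention would give slightly
  different partitions near the threshold.
* Identity thresholds act on the *internal* identity; pipelines using
  BLAST-style or shortest-sequence denominators will disagree on
  borderline pairs.
* The k-mer bootstrap classifier is a deliberately small stand-in for
  utax/SINTAX-class tools; it is accurate on the generator's
  clade-structured worlds but has no species-level resolution and no
  database curation.
* Recovery estimates inherit every upstream threshold; they are exact on
  the generator's truth but are estimates, not counts, on real data.
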