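---
title: "Tracing improved intermediate wheatgrass to its founder accessions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing improved intermediate wheatgrass to its founder accessions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iwgorigin)
```

## The problem

Intermediate wheatgrass (IWG, *Thinopyrum intermedium*) is an outcrossing
perennial grass under domestication as a grain crop; grain from
food-improved varieties is marketed as Kernza. The modern breeding pools
descend from a 1980s recurrent phenotypic selection program that intermated
a small number of genebank plant introductions (PIs) in open-pollinated
polycross blocks, but the list of selected parents was lost. Two
independent lines of evidence can recover it:

* **molecular** — assign present-day breeding genets to their most related
  PI accession using genotyping-by-sequencing (GBS) SNP profiles, and count
  which PIs accumulate assignments; and
* **historical** — search surviving phenotype records for the parent subset
  whose trait means match the recorded averages of the selected set.

`iwgorigin` implements both routes plus a synthetic data generator that
reproduces the statistical structure the molecular route relies on, so
every stage can be validated without any external genotype data.

## Genotype model and observation layer

The simulator works on diploid-style biallelic dosages $g \in \{0,1,2\}$,
matching the data model of the GBS SNP-calling pipelines used for IWG even
though the species is allohexaploid: what matters for assignment is the
genome-wide profile, not subgenome dosage resolution.

Accession structure follows the Balding–Nichols model. Each locus has an
ancestral frequency $p \sim \mathrm{Unif}(0.05, 0.5)$ and each accession an
allele frequency

$$\pi \sim \mathrm{Beta}\!\left(p\,\tfrac{1-F_{ST}}{F_{ST}},\;
  (1-p)\,\tfrac{1-F_{ST}}{F_{ST}}\right),$$

so $\mathrm{E}[\pi] = p$ and $\mathrm{Var}[\pi] = F_{ST}\,p(1-p)$. Genets
within an accession are Hardy–Weinberg draws $g \sim \mathrm{Bin}(2,\pi)$.
The default $F_{ST} = 0.15$ keeps most genetic variation *within*
accessions (for $F_{ST}=0.15$, about 85% of the variance at a locus is
within-accession), consistent with what is reported for the IWG genebank
collection; no quantitative within/between decomposition is published for
that collection, so the value is a calibration to that qualitative
statement, not an empirical fit.

Polycross descent draws, per progeny, two distinct parents uniformly at
random (no selfing — polycross blocks are arranged so all entries
intermate) and one Mendelian gamete per parent per locus, with loci
independent. No linkage map is modelled: assignment uses genome-wide
distance only, to which LD is irrelevant. After each cycle the progeny
become the next parent pool, as with bulked Syn-0/Syn-1 seed.

The GBS observation layer gives each genet–locus cell a total read depth
$d \sim \mathrm{Pois}(\lambda)$, zeroed with probability $m$ (library
dropout, independent across cells — no missingness structure is reported
for the real data), and alternate-allele reads
$a \sim \mathrm{Bin}(d, g/2)$. Defaults $\lambda = 8$, $m = 0.3$ bracket
the read depths reported for genebank and breeding-program GBS data.

Between-cycle phenotypic selection is deliberately absent: the validation
benchmarks need neutral drift as the baseline, and truncation selection
would only concentrate assignments further onto true founders.

## Depth-gated calling and filtering

Calling is cell-wise from the (ref, alt) read pair:

* at least one read of **each** allele → heterozygote (dosage 1);
* otherwise at least 4 reads of a single allele → homozygote (0 or 2);
* otherwise missing.

The heterozygote rule takes precedence whenever both alleles are observed,
so (ref = 4, alt = 1) is heterozygous. The original pipelines do not state
the precedence; fixing it this way follows the "two contrasting reads"
wording literally and makes calling deterministic.

Marker filters keep loci that are strictly biallelic, have folded minor
allele frequency **strictly greater than** 0.05 (computed over non-missing
calls; the published wording is "greater than 0.05" and is taken
literally), and are called in **at least** 30% of genets. Genets with
**more than** 95% missing data are removed. The strict/inclusive choices at
each boundary follow the source wording exactly and are pinned by tests
(a locus at MAF exactly 0.05 is removed; a genet at exactly 95% missing is
retained).

## Profiles, distances and assignment

Each reference accession is summarised as a composite profile: the
per-locus mean of its member genets' non-missing dosages. Pooling averages
dosages rather than summing reads, which makes the profile robust to depth
imbalance between members.

The relationship between two dosage/profile vectors is the Euclidean
distance over the loci where both are non-missing, rescaled by
$\sqrt{L_{\text{total}}/L_{\text{shared}}}$ — the missing-data scaling of
the standard R distance routine, and exactly the plain Euclidean distance
when nothing is missing. Pairs sharing no loci get a missing distance and a
warning.

A query genet is assigned to the accession whose composite profile is
nearest; the first and second ranked accessions and the shared-locus count
are reported. Ties are broken lexicographically on accession id and
logged. A per-genet mode (nearest member genet instead of composite) is
available through the distance functions, but composites are the default
because they roughly triple the number of loci with a usable reference
value at genebank depths.

The leave-one-out masking validation masks each reference genet in turn,
**recomputes its own accession's composite without it** (leaving it in
would leak the answer; the published description is ambiguous on this
point, and excluding it is the conservative choice), assigns the genet
against all composites, and tallies accuracy. Accessions reduced to an
empty composite by masking (single-genet accessions) are skipped and
counted separately.

## Founder counting and availability

Candidate founders are first restricted to accessions that were obtainable
before the program started: accessions *collected* ex situ strictly after
the cutoff year (default 1990) are excluded; donated material is exempt,
and unknown acquisition years are retained with a note — exclusion demands
positive evidence. Assignment counts are then tallied per accession, and
the top-*k* set (default *k* = 20, the documented size of the first
polycross) is reported with the fraction of queries it covers and the
accessions with at most 10 assignments flagged as minor. Ties at rank *k*
extend the set rather than being silently dropped. If assignments were made
against an unrestricted reference panel, best accessions outside the
allowed set are re-assigned to their second-ranked accession when that one
is allowed (restricting the panel *before* assignment is the preferred
route and what the pipeline does).

Cross-source consistency is summarised by full Venn regions over named
founder sets (historical reconstruction, remnant-seed assignments,
breeding-cycle assignments); the packaged source-set fixture carries the
published joint memberships, with the unpublished single-source
attributions fixed arbitrarily and documented as synthetic.

## Historical phenotype reconstruction

Three yield-component traits drive the reconstruction: 100-seed weight
(mean of three 100-seed samples at 12% moisture, g), seed set rating (clean
seed weight as a percentage of unthreshed 10-head weight), and yield per 10
heads (g). Combined-year summaries compute each year's mean over the
accessions observed that year and then average the year means with equal
weight. This choice is forced by the structure of the surviving records:
the drought-year yield column exists for only half the panel, and equal
year weighting reproduces the recorded combined average (2.67 g) where
pooling all cells does not (2.59 g); pooling remains available as an
option.

The selected-parent reconstruction minimises the weighted relative squared
deviation

$$\sum_t w_t \left(\frac{\bar{x}_t(S) - \tau_t}{\tau_t}\right)^2$$

over size-$k$ subsets $S$, with equal default weights (the historical
search was informal, so the loss is a package design choice; relative
deviations put grams and percentages on one scale). All subsets are
enumerated when $\binom{n}{k} \le 10^6$; otherwise greedy construction
followed by pairwise-swap local search with seeded random restarts is used
— $\binom{139}{20} \approx 10^{24}$ rules out enumeration at the historical
problem size. Tests pin the local search to the exhaustive optimum on 20
random instances with $n \le 12$. The accession donated without passport
papers participates like any other candidate; its missing passport only
affects the passport summaries.

## Passport summaries

A passport record is location-reliable iff it names a present-day country
("Former USSR"-style labels fail), and the collection site is not a
botanical garden or institute — material that reached a genebank through a
garden was typically collected elsewhere with the natural origin
unrecorded. Country counts are taken over reliable records only, with
unreliable/missing records tallied separately so the two always add up to
the accession set. Per-country tallies across *combined* tables depend on
unstated reliability judgments in the source and are deliberately not
reproduced; the single-table counts are pinned by tests.

## Validation benchmarks and problem sizes

Two simulation benchmarks anchor the stochastic behaviour, both chosen to
mirror the documented study design (≈6 genets per genebank accession, a
139-accession candidate panel, 20 selected parents, two polycross cycles):

* **Assignment sensitivity.** 50 accessions × 6 genets, 2,000 loci,
  $F_{ST} = 0.15$, depth 8, 30% dropout; depth-gated calling and standard
  filters; leave-one-out accuracy averaged over 10 seeded replicates. The
  package attains 100% here, comfortably above the 99% reported for real
  genebank data at larger scale.
* **Founder recovery.** 20 true founders among 139 candidate accessions,
  2 polycross cycles of 300 progeny, same observation model; precision of
  the top-20 counted founder set against the true founders (the packaged
  seed gives precision 1.0; the test requires ≥ 0.8).

These sizes run the full suite in well under a minute while leaving the
binomial/Poisson standard errors far smaller than the effects being
checked.

## Limitations

* Diploid dosages stand in for allohexaploid genotypes; subgenome
  structure, paralog collapse and reference bias in real GBS data are not
  emulated.
* Loci are unlinked and accession divergence is exchangeable
  Balding–Nichols; real collections show geography-correlated structure
  and shared haplotypes within collection series, which makes real
  accessions *harder* to separate than simulated ones. Passing the
  synthetic benchmarks therefore demonstrates correctness of the
  machinery, not field accuracy on any particular collection.
* Genebank regeneration admixture (pre-isolation-protocol seed increases)
  and field/labeling errors are not modelled.
* The phenotype generator is a Gaussian main-effects + interaction model;
  it emulates rank instability across years, not trait distributions.
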