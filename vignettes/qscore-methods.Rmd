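---
title: "Scoring 16S amplicon sequencing strategies in silico"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring 16S amplicon sequencing strategies in silico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qscorekit)
```

## The problem

Amplicon sequencing of the 16S rRNA gene remains the workhorse of microbiome
profiling, but its resolution depends on a bundle of choices made before any
sample is sequenced: which hypervariable region to amplify (via the primer
pair), single-end or paired-end layout, and read length. Different taxa are
discriminable in different regions, different primer pairs fail on different
genomes, and longer or paired reads buy precision at higher sequencing cost.
`qscorekit` evaluates these choices end to end, entirely in silico: it
simulates the amplification and sequencing of genomes with known taxonomy,
annotates the simulated reads against a reference database, and condenses the
outcome into a single comparable score per configuration.

## The Qscore model

For a collection of $n$ 16S gene copies (a database or a community) under
amplification configuration $j$, each copy $i$ receives two binary
indicators: *PAE*, whether the configuration's primer pair amplifies the
copy by exact degenerate-primer matching, and *SMR*, whether the simulated
read from that copy maps back to the reference at or above the identity
cutoff (0.99). Their product is the copy's completeness. With per-copy
relative abundances $\mathrm{Abd}(i)$:

$$\mathrm{sensitivity}(j) = \sum_i \mathrm{Abd}(i)\,
  \mathrm{PAE}(i,j)\,\mathrm{SMR}(i,j)$$

Taxonomic precision is multitier: the predicted lineage of a mapped read is
compared to the truth at the six ranks phylum, class, order, family, genus,
species; each rank scores 1 if correct, 0 if wrong *or missing*, and a
copy's precision is the mean of the six. The average precision renormalizes
the abundance-weighted precision mass by the sensitivity (and is defined as
0 when sensitivity is 0), so it answers: *of what was amplified and mapped,
how well was it named?* Cost depends only on the effective read length
$\ell$ (total sequenced bases; for paired-end, twice the read length):

$$\mathrm{cost}(j) = \frac{1000}{1000 + \ell}$$

The Qscore is the weighted mean of the three components, weights 1:1:1 by
default. The weights are exposed everywhere (`weights =` in
`evaluate_config()`, `--weights` on the command line); `(1, 1, 0)` gives
the "regardless of cost" ranking.

## Pipeline mechanics and the choices behind them

**Primer matching is exact.** IUPAC-degenerate primers are compiled to
regular expressions (`R -> [AG]`, `N -> [ATCG]`, ...) and matched literally
against genome text on both strands; ambiguity codes *in the genome* never
satisfy a primer class. There is no mismatch tolerance and no thermodynamic
model — a site either matches the expression or it does not. Forward sites
are paired with the nearest downstream reverse-complemented reverse-primer
site within 3,000 bp (configurable); the bound prevents cross-operon
pairings on multi-copy genomes while comfortably admitting the ~1.5-kb gene.

**Read simulation.** Quality decays quadratically with position:
$Q(n) = 37 - 1.88\times10^{-4} n^2$ for read 1 and single-end reads,
intercept 33 for read 2 (the conventionally lower-quality end). Each input
base errs with probability $10^{-Q(n)/10}$; an erring base suffers exactly
one event — insertion (5%), deletion (5%), or substitution to a different
base (90%). Positions for the error draw are input positions from the
read's own 5' end; emitted qualities follow the model over output
positions, so inserted bases take the quality of the slot they occupy.
Errors are introduced first, then amplicon reads are trimmed by 30 bases
(20-bp primer region at the front, 10-bp low-quality tail); shotgun reads
by 10 + 10. Shotgun windows advance by the read length plus a uniform
random slide of 0 to 2,000 bp. All randomness flows through R's RNG, so a
single `set.seed()` (or `--seed`) makes every FASTQ byte-reproducible.

**Annotation.** Paired ends are merged by their best overlap (at least 10
bases, at most 25% mismatching — the defaults of the common merging tools),
disagreements resolved toward the higher-quality base. Merge failure is not
an error: the fragment is simply unclassified, which is exactly how
paired-end layouts lose sensitivity. Merged or single reads are aligned
semi-globally (query end-gap free) against the reference in both
orientations; identity is matching columns over alignment columns, the top
hit wins, and ties break deterministically toward the lexicographically
smaller record id (flagged ambiguous when the tied records disagree on
species). The 0.99 cutoff is inclusive. Databases beyond 200 records are
prescreened by shared 8-mers before alignment.

A consequence worth knowing: because trimming precedes merging, a
paired-end configuration whose insert length minus 60 trimmed bases leaves
less than the minimum overlap cannot merge at all and scores sensitivity 0
(on the synthetic gene below this happens to V5-V6 PE 150 bp, insert 286).
This is the end-merging failure mode made visible, and it is why short-insert
paired-end layouts should be judged carefully against their single-end
counterparts.

**Copy-number correction.** Species abundances from classified reads are
divided by the species' mean 16S copies per genome before renormalizing.
Copy numbers enter the reference database as metadata (a `copy_number`
column), expected to come from a primer-independent count of annotated 16S
loci — estimating them by HMM search is deliberately out of scope, but the
contract (no amplification preference in the counts) is preserved.

**Reference curation.** Sequences shorter than 1,000 bp are dropped, then
exact duplicates are collapsed to a single record that keeps the retained
record's annotation (conflicts are logged and counted). Collapsing exact
*substrings* onto the longest record is available but off by default, since
100%-identity clustering of equal-content records is the conventional
behaviour and containment handling varies between clustering tools.

**Habitat abundances.** Multi-configuration OTU count tables are filtered
per specimen (drop OTUs under 10 reads or 0.01% relative abundance), then
pooled. An OTU's richness is its pooled count divided by the summed
sequencing depth of only those configurations that detected it at all — the
compatibility indicator is what keeps primer-incompatible configurations
from diluting the estimate. The denominator reading (compatibility times
*column total*, summed over configurations) is the one that makes the
indicator meaningful; it is isolated in `otu_richness()` so it can be
swapped if a different reading is ever preferred. Normalized richness
becomes the habitat abundance vector that `rank_configs_for_habitat()`
injects into the Qscore, which is how the recommended region becomes
ecosystem-aware.

## The synthetic fixture generator

Testing any of this against live databases would need external corpora, so
the package generates its own ground truth. `generate_fixture_genomes()`
builds species genomes embedding a ~1.44-kb synthetic 16S gene: conserved
blocks are concrete expansions of the built-in primers placed with
realistic overlap geometry (the 341F site contains the 357R binding site,
the 515F site *is* the 518R site, U789F sits inside the 806R site — as on
the real gene), interleaved with species-specific variable regions derived
from a common ancestral template at a chosen per-base divergence (default
8%, a between-species distance at which species are cleanly separable at
0.99 identity). Copies within a genome are identical; the copy count is the
generator's ground-truth `copy_number`. Every genome is validated after
generation: the full-length 8F/1492R pair must recover exactly the embedded
copies, so a divergence specification that touched a primer site fails
loudly rather than silently skewing results.

`generate_divergent_pair()` builds the sharpest test of region choice: two
congeneric species identical in every region except one. Reads covering
only shared regions tie at identity 1.0 against both references and the tie
break misnames one species; reads covering the divergent region separate
them. Ranking configurations over such a pair reproduces, in miniature, why
the optimal amplification region depends on which taxa a habitat actually
contains.

What the generator does *not* emulate: within-genome copy heterogeneity,
primer-template mismatches (real primer bias), chimeras and PCR artifacts,
GC-dependent coverage, and instrument-specific quality profiles. Green
tests on fixtures therefore certify the scoring machinery and the pipeline
contracts, not field performance of any particular primer pair on real
communities.

## Numerical choices and degenerate inputs

* Qualities are rounded to the nearest integer only at FASTQ encoding
  (Phred+33); the error draw uses the exact real-valued model.
* The quality model errors out if a requested length drives $Q(n)$ below 0
  (at the default decay this caps reads near 440 bp — beyond every
  supported read length).
* Abundance vectors must sum to 1 within 1e-6; profiles renormalize over
  classified reads only.
* Alignment scoring is match 1, mismatch −1, gap open 4, gap extend 2;
  identity ties between references resolve lexicographically so reruns are
  stable.
* An amplicon shorter than the read length is skipped and tallied
  (`amplicon_too_short`), not an error; likewise reads trimmed to nothing.
* Empty curation input yields an empty database with a warning; an
  all-unclassified read set yields an empty profile with a warning;
  all-zero richness is an error since nothing can be normalized.

## Problem sizes

The shipped tests and the acceptance script run on fixture communities of
2–8 species with 1–3 identical 16S copies per genome and replication counts
of 1–5 — about 15 gene copies and under a hundred read fragments per
scenario, with 10^5-base draws for the error-model statistics. These sizes
give exact or 3-sigma-bounded checks for every contract while keeping a
full run in the low minutes on one CPU; every quantity scales to larger
communities by changing the generator arguments.
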