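# qscorekit

In silico evaluation of 16S rRNA gene amplicon sequencing strategies.

## The problem

Before a microbiome study sequences a single sample, three design choices
are locked in: the amplified hypervariable region (via the primer pair),
the sequencing layout (single-end or paired-end), and the read length.
These choices trade off against each other — some taxa are only
discriminable in particular regions, primer pairs fail to amplify some
genomes at all, and paired or longer reads improve taxonomic precision at
higher sequencing cost. `qscorekit` is for researchers designing (or
re-evaluating) amplicon studies: it simulates the whole pipeline —
degenerate-primer amplification, Illumina-like read errors, trimming,
paired-end merging, best-hit taxonomic annotation, 16S copy-number-corrected
profiling — on genomes of known taxonomy, and condenses each configuration's
performance into one score.

## The Qscore

For $n$ 16S gene copies with relative abundances $\mathrm{Abd}(i)$ under
configuration $j$:

- **Sensitivity** $= \sum_i \mathrm{Abd}(i) \cdot \mathrm{PAE}(i,j) \cdot
  \mathrm{SMR}(i,j)$, where PAE (primer amplification efficiency) and SMR
  (sequence matching rate at identity ≥ 0.99) are binary per copy.
- **Precision**: each mapped read's predicted lineage is scored at the six
  ranks phylum…species (missing = incorrect), averaged per read, then
  abundance-weighted and renormalized by the sensitivity (0 if sensitivity
  is 0).
- **Cost** $= 1000 / (1000 + \ell)$ with $\ell$ the effective read length
  (total sequenced bases; 2× read length for paired-end).

$$\mathrm{Qscore}(j) = \frac{w_1 S + w_2 P + w_3 C}{w_1 + w_2 + w_3},
\qquad w_{1:3} = 1{:}1{:}1 \text{ by default.}$$

Habitat-aware scoring replaces the uniform $\mathrm{Abd}$ with abundances
estimated from multi-configuration OTU count tables
(`habitat_abundance()`), so the recommended region follows the taxa a
habitat actually contains.

## Worked example

```r
library(qscorekit)
set.seed(42)

# five synthetic species, two identical 16S copies each, 8% divergence
fx <- generate_fixture_genomes(n_species = 5, copies_per_genome = 2,
                               divergence = 0.08)
db <- fixture_reference_db(fx)   # embedded 16S genes, curated
db
#> reference_db: 5 sequences, 5 species, 5 species with copy-number data

for (lb in c("V4 SE 150 bp", "V4 PE 150 bp", "V3-V4 PE 250 bp")) {
  b <- evaluate_config(fx$genomes, fx$lineages, db,
                       builtin_config(lb))$breakdown
  cat(sprintf("%-16s S = %.4f  P = %.4f  C = %.4f  Qscore = %.2f%%\n",
              b$config_label, b$sensitivity, b$precision, b$cost,
              100 * b$qscore))
}
#> V4 SE 150 bp     S = 1.0000  P = 1.0000  C = 0.8696  Qscore = 95.65%
#> V4 PE 150 bp     S = 1.0000  P = 1.0000  C = 0.7692  Qscore = 92.31%
#> V3-V4 PE 250 bp  S = 1.0000  P = 1.0000  C = 0.6667  Qscore = 88.89%
```

Every copy amplifies and maps with a fully correct lineage here (the
reference holds each fixture gene verbatim, and 8% divergence separates
species cleanly at the 0.99 cutoff), so the three configurations differ
only in cost: the single-end 150-bp assay sequences the fewest bases and
wins. On harder inputs — confusable species, error-prone long reads,
short-insert paired layouts whose trimmed reads fail to merge — sensitivity
and precision drop and reorder the ranking; `generate_divergent_pair()`
constructs the sharpest such case.

Habitat math on a 2×2 OTU count table (two OTUs, two configurations):

```r
m <- matrix(c(10, 0, 30, 60), 2, byrow = TRUE,
            dimnames = list(c("otu1", "otu2"), c("cfgA", "cfgB")))
round(habitat_abundance(m), 4)
#>   otu1   otu2
#> 0.2174 0.7826
```

otu1 is only compatible with cfgA, so its pooled count of 10 is normalized
by cfgA's depth alone (richness 10/40); otu2 is seen by both (richness
90/100); abundances are normalized richness.

## Command line

A thin wrapper over the same functions is installed with the package:

```sh
QK=$(Rscript -e 'cat(system.file("cli", "qscore-kit", package = "qscorekit"))')
$QK make-fixtures --n-species 4 --copies 2 --seed 7 --out fixtures/
$QK curate-db --fasta ref.fasta --lineage ref.tsv --out db/
$QK simulate --mode amplicon --config "V4 PE 150 bp" --design design.tsv \
    --genomes fixtures/genomes.fasta --lineage fixtures/lineage.tsv \
    --seed 7 --out sim/
$QK annotate --reads sim/reads.fastq --db db/ --copy-correct --out profile.tsv
$QK score --genomes fixtures/genomes.fasta --lineage fixtures/lineage.tsv \
    --db db/ --configs all --weights 1,1,1 --seed 7 --out qscores.tsv
```

Subcommands: `make-fixtures`, `curate-db`, `amplify`, `simulate`,
`annotate`, `score`, `habitat-abd`, `recommend`, `compare-profiles`. Every
stochastic subcommand takes `--seed` and writes its resolved options next
to its outputs (`run_config.json`); identical seeds give byte-identical
outputs.

## Documentation

See the methods vignette (`vignettes/qscore-methods.Rmd`) for the model,
the simulator's assumptions, what the synthetic fixtures do and do not
emulate, and the numerical choices.
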