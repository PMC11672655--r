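# hindgutMAG

Downstream analysis of hindgut metagenome-assembled genome (MAG) catalogs,
built for microbiome studies of hindgut-fermenting herbivores such as the
donkey. Starting from genome bins with CheckM-style quality estimates,
DIAMOND-style best-hit tables and per-sample relative-abundance matrices, the
package covers four stages that normally live in ad-hoc scripts:

1. **Catalog** — quality filtering (completeness ≥ 50%, contamination ≤ 10%),
   pairwise average nucleotide identity (ANI) by MinHash k-mer sketches,
   dereplication at 99% ANI / 30% overlap into non-redundant clusters, and
   species-level novelty calls (a MAG is an undescribed species when its best
   reference ANI is below 95% or undefined).
2. **Annotation** — e-value screening (≤ 1e-3) and per-query best-hit
   selection of CAZyme/PUL hit tables, CAZy class tallies (GH, GT, PL, CE,
   AA, CBM), and known/novel binning at 95% identity.
3. **Diversity & differential abundance** — richness/Shannon/Simpson indices,
   Bray–Curtis PCoA, PERMANOVA, and paired per-MAG testing (paired t-test +
   Mann–Whitney) between hindgut segments: cecum (C), ventral colon (VC),
   dorsal colon (DC).
4. **Co-occurrence network** — Spearman correlations among MAGs above a
   0.005% mean-abundance floor in the cecum, edges at ρ > 0.85 with
   Bonferroni-corrected p < 0.05, Louvain modules, and node roles from the
   within-module degree z-score and participation coefficient.

A seeded synthetic-data generator (`synth_config()`,
`generate_genome_set()`, `generate_hit_table()`,
`generate_abundance_matrix()`) plants known genome clusters, bimodal hit
identities, correlated abundance blocks and segment-specific shifts, so every
stage is validated against ground truth.

## The statistics at the core

*ANI.* For genomes A, B with canonical k-mer sets (k = 16), the Jaccard
similarity J of their bottom-5000 MinHash sketches gives the Mash distance
D = −(1/k)·ln(2J/(1+J)) and ANI = 1 − D. The aligned-fraction proxy is the
full-set k-mer containment |A∩B| / min(|A|, |B|). A global-alignment oracle
(`ani_oracle()`) validates the estimator on substitution-only pairs.

*Dereplication.* Single-linkage components of the graph with edges at
ANI ≥ 0.99 and overlap ≥ 0.30; representatives maximize
completeness − 5 × contamination (ties: longer genome, then MAG id).

*PERMANOVA.* Anderson's pseudo-F on Bray–Curtis dissimilarities with
p = (1 + #{F\* ≥ F}) / (1 + n_perm) over seeded label permutations.

*Node roles.* For node i in module s, z_i = (k_is − mean k_·s)/sd k_·s and
c_i = 1 − Σ_t (k_it/k_i)²; module (provincial) hubs have z ≥ 2.5, connectors
c > 0.62, network hubs both, peripheral otherwise.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data; each writes its tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_catalog.R
```

prints

```
generated 9 genomes in 3 planted clusters
hit table: 20000 records, 60 planted in the known stratum
abundance matrix: 78 samples x 60 MAGs; 2 planted blocks, 10 shifted MAGs
quality filter: 9 of 9 bins retained
dereplication: 3 clusters from 9 MAGs
planted clusters recovered exactly: TRUE
MAG catalog: 9 input, 9 retained, 3 non-redundant clusters
  length 0.03-0.03 Mb (mean 0.03), N50 6466-16844 bp
  novel species: 2 (67%)
```

i.e. the nine bins collapse to the three planted species clusters, and with
a reference genome matching only the first cluster, two of the three
representatives are called undescribed species. The later stages recover the
planted differential MAGs (`analysis/04_diffabund.R`: all 10 MAGs shifted up
in the cecum are significant by the paired t-test, PERMANOVA C vs DC
p = 0.001) and the planted co-occurrence blocks as network modules
(`analysis/05_network.R`: 16 of 1770 tested pairs kept, 2 modules matching
the 2 planted blocks).

The same thing as a single call:

```r
library(hindgutMAG)
report <- run_demo("demo_out", seed = 1)
```

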