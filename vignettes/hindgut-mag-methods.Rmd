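---
title: "Methods: MAG catalogs, novelty, diversity and co-occurrence roles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MAG catalogs, novelty, diversity and co-occurrence roles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hindgutMAG)
```

# Scope

hindgutMAG implements the downstream, desk-scale half of a hindgut
metagenome-assembled genome (MAG) study: everything after assembly, binning,
alignment and abundance estimation have produced genome bins, best-hit
tables and relative-abundance matrices. Read QC, assembly, binning, CheckM,
taxonomy assignment and aligner execution are deliberately out of scope —
their outputs are this package's inputs.

# The catalog model

## ANI estimation

The pairwise relatedness statistic throughout is average nucleotide identity
(ANI). We estimate it with a MinHash bottom-sketch over canonical k-mers
(k = 16, sketch size 5000): the Jaccard similarity $J$ of two sketches gives
the Mash distance

$$D = -\frac{1}{k}\,\ln\frac{2J}{1+J}, \qquad \widehat{ANI} = 1 - D,$$

clamped to $[0, 1]$ and undefined (NA) when the sketch union shares no
k-mer. The NA branch is semantically load-bearing: a MAG with no detectable
k-mer overlap against any reference is treated as an undescribed species,
exactly like one whose best ANI falls below the 95% species threshold.

Genome-overlap tools additionally require that two genomes share enough of
their length before an ANI value is trusted. As a proxy for
alignment-coverage we use full-set k-mer containment relative to the smaller
genome, $|A \cap B| / \min(|A|, |B|)$, with the conventional 0.30 floor.
This is a proxy, not an alignment fraction: it is monotone in true overlap
but numerically smaller at higher divergence (at 1% divergence about
$(1 - 0.01)^{16} \approx 0.85$ of k-mers survive). The 0.30 floor leaves
ample headroom for strain-level pairs while still severing species-level
ones, which at ≥ 5% divergence retain under 5% containment.

The estimator is validated against an independent oracle: global
Needleman–Wunsch identity (match +1, mismatch 0, affine gaps) computed on
matched windows of substitution-only synthetic pairs, where alignment
identity equals one minus the substitution fraction by construction. The
test suite requires agreement within 0.01 across 20 seeded pairs at
0.5–5% divergence; observed deviations are typically below 0.005.

## Quality filtering, dereplication, novelty

Bins enter the catalog when completeness ≥ 50% and contamination ≤ 10%.
The boundaries are inclusive (a 50.0/10.0 bin passes); a `strict` flag
switches to strict inequalities for users who read the thresholds as open
bounds.

Dereplication builds a graph with an edge whenever ANI ≥ 0.99 and
containment ≥ 0.30 and takes connected components (single linkage) as
clusters. Single linkage is chosen over average linkage for determinism and
because the planted evaluation regime (within-cluster ANI ≈ 99.5%,
between-cluster ≈ 81%) leaves a wide margin where the linkage choice cannot
matter. Representatives maximize the dRep-style score
$\text{completeness} - 5 \times \text{contamination}$, with ties broken by
total length and then lexicographic MAG id so the result is a pure function
of its inputs.

Novelty calls compare each representative against a reference set: the best
ANI over references passing the containment floor decides, with
`novel = best_ani < 0.95 or best_ani undefined`. An empty reference set
marks everything novel — the honest answer when no database is supplied.

# Annotation summaries

Hit tables are 12-column BLAST/DIAMOND tabular files. Screening keeps
e-value ≤ 1e-3 (inclusive) and then, per query, the hit with maximal percent
identity — "highest similarity" is read as identity, not bit score, because
the downstream novelty statistic is an identity. Ties fall to smaller
e-value, then lexicographic subject id. The filter is idempotent.

Known/novel binning is strict at the cutoff: known means identity **greater
than** 95%, so a hit at exactly 95.0 is novel. The summary's mean identity is
the unweighted arithmetic mean over all classified records; a flag excludes
the known stratum for users who want the novel-only average (at realistic
known fractions of ~0.3% the two differ by less than 0.2 points). Proteins
with no hit at all never enter the table, so all rates are over classified
proteins; the separate `annotation_rate()` handles predicted-vs-annotated
arithmetic.

# Diversity and differential abundance

Alpha diversity reports richness, Shannon ($-\sum p_i \ln p_i$, natural
log) and Simpson. Simpson defaults to the Gini–Simpson form
$1 - \sum p_i^2$; the dominance form $\sum p_i^2$ is available because
toolchains differ silently on this point.

Beta diversity uses Bray–Curtis dissimilarity and classical metric scaling
(PCoA). Negative eigenvalues — expected, since Bray–Curtis is not Euclidean
— are dropped from the proportion-explained denominator. Axis signs are
fixed by making the first nonzero coordinate of each axis positive, purely
for reproducibility.

PERMANOVA uses Anderson's pseudo-F with
$p = (1 + \#\{F^* \ge F\}) / (1 + n_{perm})$, delegated to `vegan::adonis2`
behind the package's interface and cross-checked in the tests against a
from-scratch permutation oracle. One practical subtlety the tests document:
under perfect group separation the attainable minimum p is not exactly
$1/(1+n_{perm})$, because permutations that happen to preserve the group
partition reproduce the observed F and tie under the $\ge$ counting rule.

Differential MAG testing between two segments is paired by subject: a
paired two-sided t-test on per-donkey abundance differences plus an
unpaired two-sided Mann–Whitney test, both flagged independently at raw
p < 0.05. No multiplicity correction is applied by default — the analysis
this mirrors reports raw p-values over hundreds of MAGs — but a
Benjamini–Hochberg option is provided. Zero-variance differences make the
t-test undefined (flagged NA, never significant); a fully tied Mann–Whitney
normal approximation is reported as p = 1, since tied data carry no
evidence. Two-sidedness is a deliberate choice where the direction is not
pre-registered.

A compositional caveat that the synthetic experiments make explicit:
because rows are renormalized to sum to one, planting a positive shift on
ten MAGs in the cecum *depresses every other MAG's relative abundance
there*. Un-shifted MAGs are therefore not null on the relative scale — they
carry a genuine opposite-direction shift. Recovery checks consequently count
false positives directionally (a null MAG wrongly called *higher in the
cecum*), and the suite requires ≥ 90% planted recovery with zero directional
false calls at a 0.05/50 Bonferroni check level.

# Co-occurrence network and node roles

Cecum-network nodes are MAGs whose mean relative abundance across cecum
samples strictly exceeds 0.005%. Edges require Spearman ρ > 0.85 — read
literally as positive-only, with an absolute-value mode available — and
Bonferroni-corrected p < 0.05, where the corrected p multiplies the
t-approximation p-value ($t = \rho\sqrt{(n-2)/(1-\rho^2)}$) by the number of
*tested* pairs $m(m-1)/2$, not only those passing the ρ filter; correcting
over all tested pairs is the conservative and deterministic reading.
Constant abundance vectors have undefined correlations and are excluded with
a warning rather than silently treated as zero.

Modules come from Louvain modularity maximization on the unweighted kept
graph, with the vertex order shuffled once by the seed and then frozen, and
module labels canonicalized by smallest member id — two runs of the same
input are byte-identical. Node roles use the within-module degree z-score
and participation coefficient pair: for node $i$ in module $s$,
$z_i = (k_{is} - \bar{k}_{\cdot s})/\sigma(k_{\cdot s})$ (0 when the sd is
0) and $c_i = 1 - \sum_t (k_{it}/k_i)^2$. This is the standard formulation
that accompanies the connector / provincial-hub taxonomy; a "z-score versus
randomized networks" formulation is sometimes described verbally in
applications but has no canonical randomization scheme, so the
degree-based z is implemented and documented here as the package's choice.
Role cutoffs are the cartographic defaults z = 2.5 and c = 0.62, exposed as
parameters: provincial (module) hubs at high z / low c, connectors at high
c, network hubs at both, peripheral otherwise.

# The synthetic-data generator

The generator exists so that every stage has ground truth. Its design:

- **Genomes.** Each cluster is one ancestor sequence; ancestors are
  independent `between_divergence` (default 0.10) mutants of a shared root,
  members independent `within_divergence` mutants of their ancestor.
  Mutation is substitution-only — no indels — so the true alignment identity
  of any pair is known exactly and the alignment oracle stays exact and
  fast. A within-cluster pair carries two independent loads: divergence
  $\approx 2d$, so $d = 0.0025$ yields the ≈ 99.5% within-cluster ANI of a
  strain-level cluster and $d = 0.005$ yields ≈ 99.0%. Completeness is
  uniform on [50, 100] and contamination on [0, 10] unless overridden.
- **Hit tables.** Identities are a two-component truncated-normal mixture:
  a known stratum (mean 97, sd 1, ceiling 100) and a novel stratum
  (mean 41, sd 8, floor 20), with exactly `round(n × frac_known)` known
  records; class labels follow a configurable proportion table whose default
  matches a fiber-degrading community dominated by glycoside hydrolases and
  glycosyl transferases. All e-values pass the 1e-3 screen by construction.
- **Abundances.** Log-normal base abundances; MAGs in a block share a latent
  per-sample Gaussian factor with weight $s$ and residual noise scaled by
  $\sqrt{1-s^2}$, a Gaussian-copula construction giving within-block
  correlation $s^2$ while preserving Spearman structure under the log-normal
  marginal ($s = 1$ makes block members exact monotone transforms of one
  factor, Spearman ρ = 1). Group effects add natural-log fold shifts to
  chosen MAGs in chosen segments; rows are then renormalized to sum to one
  within 1e-12. Every donkey contributes one sample per segment (C, VC,
  DC), so paired designs are automatic.
- **Seeding.** Each artifact draws from its own RNG stream derived by a
  stable string hash of the master seed and the artifact name
  (`derive_seed()`), so adding one generator can never perturb another's
  output, and a fixed configuration reproduces every file byte-for-byte.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: indels and rearrangements (real ANI estimators
face alignment ambiguity the oracle sidesteps), zero inflation and
sequencing-depth variation in abundances (all synthetic abundances are
strictly positive), taxonomy beyond free-text labels, phylogenetic
correlation between MAGs, and the compositional biases of read-mapping
abundance estimation. Per-MAG abundance dispersion has no published
reference value here; the log-scale noise defaults (sd 1, with 0.2–0.3 used
in the planted-recovery experiments) are conventions chosen to represent
moderate between-donkey variability, and are flagged as such.

# Validation problem sizes

The shipped suites run at deliberately compact sizes chosen as adequate for
their statistical purpose: ANI accuracy on 20 pairs of 100 kb genomes;
dereplication recovery across 20 seeds of 3 × 2 genomes at 12 kb; module and
role recovery across 20 seeds of planted graphs; PERMANOVA type-I error from
500 null datasets at 199 permutations (12 samples × 30 MAGs); differential
recovery over 5 seeds of 8 donkeys × 60 MAGs; and an end-to-end demo at 9
genomes × 30 kb, 20,000 hits and 26 donkeys × 3 segments × 60 MAGs. The
demo completes in well under a minute on one core.

# Known limitations

- The containment overlap proxy is not an alignment fraction; its 0.30
  floor is calibrated for the substitution-only regime and conservative
  elsewhere.
- Single-linkage dereplication can chain through intermediate genomes in
  continua of relatedness; the planted regime avoids this by construction,
  real data may not.
- Compositional effects are handled by documentation and directional
  evaluation, not by a log-ratio transformation; no SparCC-style correction
  is applied to the network stage.
- The Mann–Whitney test uses the tie-corrected normal approximation (exact
  only for small untied samples via `stats::wilcox.test`); p-values near
  machine resolution should not be over-interpreted.
- Constrained ordination is not implemented; group separation is quantified
  by PERMANOVA on the unconstrained Bray–Curtis space.
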