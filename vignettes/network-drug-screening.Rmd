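---
title: "Network-based drug screening against a seed-gene module: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-based drug screening against a seed-gene module}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netrepurpose)
```

## The problem

Immune-checkpoint regulators such as PD-L1 (gene symbol CD274) sit inside a
neighborhood of the protein–protein interactome whose members collectively
shape its expression and stability. A drug whose targets engage that
neighborhood is a plausible candidate for modulating the checkpoint even if
it was developed for something else entirely. `netrepurpose` implements this
network-medicine screening logic end to end:

1. **Module identification.** Personalized network propagation from the
   seed gene scores every protein's influence; the top-*k* genes (default
   *k* = 200) form the seed-associated module.
2. **Three independent screens** of every drug's target set against that
   module, each with a permutation null:
   * closest network proximity (hop distances, degree-matched null),
   * GO functional similarity (Wang's semantic similarity with
     best-match averaging across BP/MF/CC),
   * random-walk-with-restart diffusion correlation.
3. **Intersection.** Only drugs significant under all three are final
   candidates.

## Models and statistics

### Personalized propagation

Scores solve the fixed point of

$$p = \alpha\, W p + (1-\alpha)\, v,$$

with $W$ the column-normalized adjacency of the undirected interactome,
$\alpha$ the damping (default 0.85, the convention of standard PageRank
implementations), and $v$ the personalization vector — all restart mass on
the seed gene(s). A published variant of this formula teleports uniformly
($1/n$); we implement teleport-to-personalization because the screening
experiment it supports assigns weight one to the seed and zero elsewhere.
Uniform personalization recovers the classic form. The iteration runs to an
L1 tolerance of $10^{-10}$ (configurable) in a compiled kernel and is
checked in the test suite against dense linear solves to $10^{-8}$.

Boundary ties at rank *k* break lexicographically by gene symbol so module
extraction is deterministic; the seed gene itself is excluded from module
membership by default (the module is the seed's *associates*; a flag
retains it).

### Closest proximity

$$d_{AB} = \frac{1}{|A|+|B|}\Big(\sum_{a\in A}\min_{b\in B} d(a,b)
  + \sum_{b\in B}\min_{a\in A} d(a,b)\Big)$$

with unweighted hop distances. Significance comes from permutation:
degree-matched random sets are drawn for both sides (the literal published
procedure; `randomize = "targets"` holds the module fixed), giving
$Z_{NP} = (d - \mu_{null})/\sigma_{null}$ and empirical
$P = \#\{d_{random} < d\}/N$. Candidates need $Z_{NP} < -3$ **and**
$P < 0.05$.

Two notes on this formula as printed. First, the strict-inequality count
means small $P$ corresponds to an observed distance smaller than nearly all
null draws — the proximal tail — so it is directionally consistent with the
$Z$ rule; a `p_tail = "proximal"` option counts ties ($\le$) instead, which
differs only on the hop-distance lattice. Second, no smoothing is applied
($+1$ numerator corrections are common elsewhere), so $P = 0$ is reportable.

Degree-matched sampling bins nodes by ascending degree, merging adjacent
degree values until each bin holds at least 100 nodes (the final bin absorbs
the remainder) — the standard scheme on heavy-tailed degree distributions.
Sampling is without replacement within a permutation and independent across
permutations, with per-permutation child seeds spawned from one master seed.

An important calibration subtlety: with both sets randomized, the observed
statistic references the *cohesive* module while the null references its
*scattered* degree-matched randomization — two different distribution
families — so $Z_{NP}$ under random target sets is not standard normal in
that mode (we measure mean $\approx -2$, sd $\approx 2.6$ on the synthetic
fixture). Under targets-only randomization, observed and null draws are
exchangeable and the calibration is exact (measured mean 0.02, sd 1.00);
the calibration tests therefore run in that mode, while the screen's
default follows the published both-sets procedure.

### Functional similarity

Wang's DAG-based term similarity propagates S-values from each term up its
ancestors, multiplying by an edge-type contribution weight
(`is_a` = 0.8, `part_of` = 0.6, the published constants), and scores a term
pair by the shared ancestors' S-mass over both terms' total semantic value.
Gene pairs aggregate their term-pair matrix by best-match averaging (BMA:
mean of row maxima and column maxima, halved); sets of genes aggregate their
gene-pair BMA matrix with BMA again, mirroring gene-cluster similarity
semantics of the standard GO-similarity tooling. The final score averages
the available namespaces,

$$FS = (Sim_{BP} + Sim_{MF} + Sim_{CC})/3,$$

where a namespace with no annotation on either side is *excluded* rather
than zero-imputed — missing annotation is not evidence of dissimilarity.
The null draws gene lists size-matched to the drug's annotated target set
uniformly from annotated genes, holding the module fixed: annotation
coverage, not degree, is the confounder here (a degree-matched pool can be
supplied). $P = \#\{FS_{random} > FS\}/N$; candidates need $FS > 0.6$ and
$P < 0.05$.

For desk-scale ontologies the full term-by-term similarity matrix per
namespace is precomputed and cached (up to 3000 terms); beyond that the
implementation falls back to lazily cached pairwise evaluation.

### Diffusion correlation

Random walk with restart,

$$p_{t+1} = (1-\gamma) W p_t + \gamma p_0,$$

restart probability $\gamma = 0.75$ by default (the convention of the
diffusion package the method builds on), run once from the module members
and once from each drug's targets; the Pearson correlation of the two
stationary vectors over all nodes is the statistic. The null reruns the
walk from degree-matched random target sets with the module vector fixed.
Candidates need $Z_{RWR} > 3$ and $P < 0.05$.

The published convergence threshold of $10^{-30}$ lies far below what
double-precision L1 differences can resolve; the kernel therefore also
stops at numerical stagnation (L1 change below $8\,\varepsilon\,\|p\|_1$,
which also catches last-bit two-cycles), so arbitrarily small tolerances
terminate at the numerical fixed point. Default tolerance is $10^{-12}$
with a cap of $10^4$ iterations; isolated nodes receive a unit self-loop
column to keep $W$ stochastic.

### Module localization and tissue specificity

`lcc_significance()` tests whether a gene set induces a larger connected
subgraph than degree-matched chance (empirical $P$ = fraction of null LCCs
at least as large; degenerate nulls report an undefined-$Z$ sentinel with
$P$ still valid). `tissue_z()` computes
$Z_{i,t} = (E(i,t) - \bar E_i)/\delta_i$ per gene across tissues, with the
sample (n−1) standard deviation by default (population available, under
which each gene's Z sums to zero); genes with zero spread get `NA`, never 0
or $\pm\infty$. `specific_genes()` applies a strict threshold, customarily
2.5. The expression matrix is taken as per-tissue means on whatever scale
the caller chose (recorded, never transformed).

## The synthetic study system

Real screens of this design run on a ~18,000-protein interactome, a
~3,000-drug library, GO, and GTEx — external, version-dependent inputs.
The generator (`fixture_spec()` and friends) builds a self-contained analog
with known ground truth so every statistic is testable offline:

* **Interactome**: preferential-attachment background (1000 nodes, 3 edges
  per arrival — heavy-tailed like a real interactome), with a 25-gene
  planted module drawn from the interquartile degree range and densified to
  100× the background edge density. The seed gene is the planted member
  with the most within-module edges. The density contrast is deliberately
  strong: disease modules identified by propagation are, by construction,
  far denser than background (a curated 200-gene module of ~3,240 edges is
  ~57× denser than a genome-scale interactome), and at desk scale the
  contrast must additionally beat the hubs, which absorb proportionally
  more restart mass in a 1000-node graph than in an 18,000-node one.
  Module recovery by propagation holds across master seeds at these
  settings.
* **Drug library**: 50 drugs of 6 targets each — 3 "planted" drugs whose
  targets lie inside the module, 47 decoys whose targets are degree-matched
  *outside* it (hubness without cohesion), truth-labelled at overlap ≥ 0.5.
* **Ontology**: three disjoint rooted trees (BP/MF/CC), depth 4, branching
  3, 20% `part_of` edges; planted genes co-annotate to a designated subtree
  so they are functionally coherent by design.
* **Expression**: log2-scale background with gene-level baselines
  (N(5, 1.5²)) and per-tissue noise (sd 0.5) over 30 tissues; 20 planted
  genes gain log2(8) in the first tissue.

What passing on this system does and does not show: it demonstrates that
the statistics recover planted structure and that the permutation machinery
is calibrated and reproducible; it does not certify performance on real
interactomes, whose literature ascertainment bias, edge noise, and
annotation depth the generator deliberately does not emulate.

## Numerical and design choices

* All randomness flows from explicit master seeds; per-drug child seeds are
  derived by hashing `(master, drug id)`, so library composition never
  perturbs another drug's null, and screen reports are byte-for-byte
  reproducible.
* Unreachable distances are an error, not a silent drop — proximity is
  defined within one connected interactome, and silent exclusion would mask
  data problems. Drug targets absent from the graph *are* dropped with a
  count (real libraries always have unmapped targets); a drug with no
  mapped target is skipped with a recorded reason.
* Problem sizes used by the test suite and acceptance script — a 1000-node
  screen fixture (50 drugs × 3 methods × 200 permutations) and a 2000-node,
  500-replicate calibration at 200 permutations — were chosen as the
  smallest systems on which the planted-recovery and calibration properties
  are stable.
* When no ontology is supplied the FS method is skipped with a recorded
  reason and the final-candidate rule reduces to the AND of the two
  executed methods.
* The report exposes every pairwise intersection of the three candidate
  sets, not only the three-way one: advancing two-method candidates on
  external evidence is a judgment call that belongs to the user.

## Known limitations

* The full distance matrix (used to accelerate proximity nulls) and the
  dense term-similarity cache are desk-scale conveniences; both fall back
  to lazy evaluation on large inputs, at a large speed cost.
* The FS permutation null is annotation-uniform, not degree-aware; on real
  GO data annotation depth correlates with study bias, which size-matching
  only partly controls.
* Empirical P-values are unsmoothed counts; at 1000 permutations the
  smallest nonzero P is 0.001 and P = 0 must be read as "below resolution".
* The interactome is treated as undirected and unweighted; confidence
  weights and signed/directed edges are out of scope.
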