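# netrepurpose

Network-based drug repurposing against a seed-gene interactome module.

## What it does, and for whom

Genes do not act alone: a phenotype-relevant gene (say, the immune
checkpoint ligand PD-L1/CD274) sits inside a neighborhood of the
protein–protein interactome whose members collectively regulate it. A drug
whose targets engage that neighborhood is a candidate for modulating the
phenotype, whatever the drug was developed for. `netrepurpose` is for
computational biologists who want to run that screening logic on their own
interactome, seed gene(s), and drug-target library:

1. **Module identification** — personalized network propagation
   (personalized PageRank) from the seed gene(s),
   `p = α W p + (1 − α) v` with damping α = 0.85 and all restart mass on
   the seed; the top-*k* genes (default *k* = 200) form the
   seed-associated module. Module quality can be checked by LCC
   localization (`lcc_significance()`) and benchmark-set AUC
   (`evaluate_module_auc()`).
2. **Three independent screens** of every drug, each with a permutation
   null and the printed decision rule:
   * **NP** — closest network proximity
     `d_AB = [Σ_a min_b d(a,b) + Σ_b min_a d(a,b)] / (|A|+|B|)`, with a
     degree-matched null; pass if `Z_NP < −3` and `P < 0.05`;
   * **FS** — GO functional similarity: Wang semantic similarity with
     best-match averaging, averaged over BP/MF/CC,
     `FS = (Sim_BP + Sim_MF + Sim_CC)/3`; pass if `FS > 0.6` and
     `P < 0.05`;
   * **RWR** — random walk with restart
     `p_{t+1} = (1−γ) W p_t + γ p_0` (γ = 0.75) from module and from drug
     targets, Pearson correlation of the two influence vectors; pass if
     `Z_RWR > 3` and `P < 0.05`.
3. **Intersection** — only drugs passing all three screens are final
   candidates (`candidate_sets()` also exposes every pairwise
   intersection).

It also ships per-gene tissue-specificity Z-scores
(`Z_{i,t} = (E(i,t) − Ē_i)/δ_i`, threshold 2.5) and a synthetic-fixture
generator with planted ground truth (scale-free interactome + cohesive
module, labelled drug library, three-namespace ontology, expression
matrix), so the whole pipeline is testable without any downloads.

## Worked example

Screen a synthetic 1000-node study system (3 drugs target the planted
module, 47 degree-matched decoys do not):

```r
library(netrepurpose)

spec <- fixture_spec(master_seed = 7)
fx <- simulate_fixture(spec, "demo")                 # writes all input files

graph  <- load_edge_list("demo/interactome.tsv")
lib    <- load_drug_library("demo/drug_targets.tsv")
dag    <- read_obo("demo/ontology.obo")
annot  <- read_annotations("demo/annotations.tsv", dag)

module <- identify_module(graph, fx$seed_gene, k = 25)
module
#> Gene module: 25 members (seed: G0836)
#>   top: G0622, G0839, G0654, G0673, G0807 ...

lcc_significance(graph, module$members, n_perm = 200, rng_seed = 2)
#> LCC localization: observed=23 null mean=5.96 sd=2.94 z=5.79 P=0

report <- run_screen(graph, module, lib, dag, annot,
                     n_perm = 200, rng_seed = 11)
report
#> Screen report: 50 drugs | NP 3, FS 3, RWR 3, intersection 3

r <- report$report
head(r[order(r$z_np), c("drug", "d", "z_np", "p_np", "fs", "p_fs",
                        "z_rwr", "p_rwr", "final_candidate")], 5)
#>    drug     d  z_np  p_np    fs  p_fs  z_rwr p_rwr final_candidate
#> 2  D002 0.677 -6.61 0.000 0.908 0.000  6.673 0.000            TRUE
#> 1  D001 0.677 -6.30 0.000 0.906 0.000  5.078 0.000            TRUE
#> 3  D003 0.742 -6.09 0.000 0.887 0.000  5.511 0.000            TRUE
#> 22 D022 1.645 -1.17 0.115 0.443 0.170  0.151 0.450           FALSE
#> 21 D021 1.806 -0.34 0.345 0.423 0.285 -0.836 0.595           FALSE

candidate_sets(report)$all_three
#> [1] "D001" "D002" "D003"
```

Reading the numbers: the module's 25 genes induce a 23-node connected
component where degree-matched chance gives ~6 (z = 5.8, empirical P = 0 at
200 permutations) — the module is topologically coherent. The three
module-targeting drugs sit far closer to the module than their
degree-matched nulls (`z_np ≤ −6`, observed distance below every null
draw), are functionally similar to it (`FS ≈ 0.9`), and their diffusion
profiles correlate with the module's (`z_rwr > 5`); all three pass all
three screens, every decoy fails at least one, and the final intersection
is exactly the planted set. `write_screen_report()` writes the per-drug TSV
and a JSON manifest of all parameters and seeds; identical inputs and
master seed reproduce it byte for byte.

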