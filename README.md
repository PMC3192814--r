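# metabochem

Tools for studying the **chemical basis of metabolic network
organization**: why the hubs of metabolic networks — the metabolites that
take part in very many reactions — are systematically more polar and more
water-soluble than peripheral metabolites, and how that chemistry explains
the scale-free (power-law) degree structure of metabolism without any
metabolite needing to "know" who is well connected.

The package is aimed at systems biologists and chemoinformaticians who
want to run topology-vs-chemistry analyses on reaction databases, and at
anyone who wants a fully testable, seedable implementation of the
concentration-governed growth model.

## What it implements

**Network reconstruction.** Reaction lists (`id<TAB>A + B = C + D`) are
screened — reactions with macromolecules or R-group compounds deleted,
currency metabolites (ATP, NAD, water, ions, ...) stripped — and each
surviving reaction contributes an undirected edge for every
substrate–product pair. Degree histograms are fitted as

    N = a · D^(−b)

by least squares of log10 N on log10 D.

**Chemistry.** An open descriptor panel from SMILES (via OpenBabel):
Wildman–Crippen logP, the charged-partial-surface-area family
(PPSA3/PNSA3/FPSA3/FNSA3/RPCG from Gasteiger charges and a deterministic
2D surface scheme), ESOL logS, and substructure counts (H-bond donors,
N atoms, amides, six-membered rings, hydrophobic atoms, a Lipinski
measure).

**Statistics.** Degree-group means ± SE, tie-corrected Kruskal–Wallis and
Mann–Whitney tests, correlations of bin means against bin rank, and
early/late metabolome classification (metabolites of the oldest enzyme
class, minus aerobic metabolites).

**Concentration models.** The published polarity equation

    −LogC = 6.105 + 0.431·ClogP + 15.595·FNSA3 + 16.727·FPSA3 − 5.333·RPCG

as a fixed evaluator; stepwise multiple linear regression (partial-F,
Bonferroni-adjusted entry); ε-SVR with RBF kernel (defaults γ = 0.01,
ε = 0.22, C = 7.9) scored by leave-one-out cross validation; exhaustive
grid search; and descriptor-deletion importance.

**Growth simulation.** Network expansion under three rules — one new
metabolite per step; declining concentrations `C_k = C_i − k·d ± f/2`;
edge endpoints drawn with probability proportional to concentration —
run from `C_i = 10^6` down to `C_f = 10` (five orders of magnitude, the
measured span of bacterial metabolite concentrations).

**Synthetic data.** Seeded generators for every input: screened reaction
sets with known ground truth, molecule sets spanning a polarity gradient,
concentrations linear in polarity descriptors, degree-linked chemistry,
and enzyme-age annotations.

## Worked example

```r
library(metabochem)

# grow a network under the concentration rules
res <- run_simulation(sim_config(seed = 42))
res
#> growth simulation: 1001 steps, 1002 metabolites, 4995 edges
#> power law N = 567.7 * D^-1.433  (r^2 = 0.8520, 55 degree bins)
```

The run added one metabolite per step for 1001 steps (stopping when a new
metabolite's concentration reached 10 or below), and its degree histogram
follows a power law with exponent b ≈ 1.4 and log–log r² ≈ 0.85: the
concentration rules alone produce scale-free structure.

```r
# descriptors from SMILES
build_panel(data.frame(id = c("ethanol", "glycine"),
                       smiles = c("CCO", "NCC(=O)O")))
#>        id    logp    logs  fpsa3   fnsa3  rpcg hbd_count ...
#> 1 ethanol -0.0014 -0.1247 0.0462 -0.0725 0.479         1
#> 2 glycine -0.2700 -0.0693 0.0920 -0.1402 0.303         2

# the published concentration equation at hub-like polarity values
apply_linear_model(published_concentration_model(),
                   c(ClogP = -1.2, FNSA3 = -0.11, FPSA3 = 0.08, RPCG = 0.16))
#> [1] 4.35723
```

Glycine is more polar than ethanol on every axis (lower logP, larger
charged surface fractions, two H-bond donors), and a metabolite with
hub-like polarity descriptors is predicted at −LogC ≈ 4.4, i.e. a
concentration around 4×10⁻⁵ mol/L.

## The analysis workflow

The numbered scripts under `analysis/` run the five pipeline stages on
generated data and write their tables under `results/`:

```sh
Rscript analysis/01_reconstruct_network.R    # screen reactions, build graph
Rscript analysis/02_descriptor_panel.R       # descriptor panel + polarity gradient
Rscript analysis/03_topology_chemistry.R     # degree-chemistry statistics
Rscript analysis/04_concentration_models.R   # stepwise MLR + SVR/LOOCV
Rscript analysis/05_growth_simulation.R      # 20-seed replicate simulations
```

Each script states what it found; point the read functions at your own
reaction/SMILES/concentration TSVs to run on real extracts. The methods
vignette (`vignettes/metabochem-methods.Rmd`) documents the models,
conventions and limitations.

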