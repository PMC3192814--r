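---
title: "Methods: topology, chemistry and concentration in metabolic networks"
author: "metabochem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: topology, chemistry and concentration in metabolic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Metabolic networks across all domains of life are scale-free: a few
metabolites (hubs) take part in very many reactions while most take part in
one or two. The classical explanation is preferential attachment — new
metabolites connect to already well-connected ones — but that begs a
mechanistic question: a newly recruited metabolite cannot "know" which
partners are well connected. This package implements a chemical reading of
the phenomenon: hubs must drive many reactions, driving reactions requires
high concentration, high aqueous concentration requires polarity, and
abundance *is* observable by reaction chemistry. The pipeline therefore
has five stages, each exposed as package functions and driven by the
numbered scripts under `analysis/`:

1. reconstruct a substrate–product network from a screened reaction list;
2. compute polarity/solubility descriptors from structures;
3. relate degree to chemistry with rank statistics and binned correlations;
4. model concentrations from chemistry (stepwise regression, ε-SVR);
5. simulate concentration-governed network growth.

## Network reconstruction

A reaction list (TSV, `id<TAB>A + B = C + D`) is screened by three rules:
reactions containing macromolecules or R-group (unspecified-residue)
compounds are deleted whole; currency metabolites — ubiquitous carriers
such as ATP, NAD, water, protons and metal ions — are removed from the
remaining reactions so they cannot create spurious shortcut edges; and
reactions left with an empty side are dropped. Each surviving reaction
contributes an edge for every substrate–product pair (complete bipartite
expansion); self-pairs are dropped and parallel edges merged, so the
result is a simple undirected graph and *degree* is "the number of edges
linked to a node". Stoichiometry, directionality and compartments are
deliberately out of scope.

Two conventions are worth calling out because the screening literature
leaves them open. First, a currency metabolite occasionally *is* the
chemistry of a particular reaction; `filter_reactions()` takes an explicit
per-reaction override list rather than inferring exceptions. Second,
metabolites isolated after screening are excluded from the node set.

Degree histograms are fitted as `N = a * D^-b` by ordinary least squares
of `log10(count)` on `log10(degree)` over degrees with nonzero counts —
the straight-line-on-log-log presentation conventional for degree
distributions. No `xmin` search or CCDF transformation is applied; the
`r_squared` of that regression is the reported goodness of fit.

## The descriptor panel

Commercial engines (Cerius2, Sybyl, Pipeline Pilot) are not reproducible
here, so the panel is built from open components with the explicit goal of
preserving *polarity ordering*, not engine-exact values:

- **logP** — the Wildman–Crippen atomic-contribution octanol/water
  partition coefficient, as implemented by OpenBabel. One open logP serves
  wherever ClogP or ALogP would appear; LogD (ionisation-aware) would need
  a pKa engine and is out of scope.
- **CPSA family** — Gasteiger partial charges are assigned with explicit
  hydrogens, and each atom receives an approximate accessible surface
  area: its van der Waals sphere minus the spherical caps occluded by
  bonded neighbours placed at idealised bond lengths (sum of covalent
  radii). Because no 3D conformer is ever generated, every descriptor is
  a deterministic function of the molecular graph. Then
  `PPSA3 = Σ q⁺·SA`, `PNSA3 = Σ q⁻·SA`, `FPSA3 = PPSA3/TMSA`,
  `FNSA3 = PNSA3/TMSA`, and `RPCG = max(q⁺)/Σ q⁺`. A molecule with no
  positive partial charge has an undefined (0/0) RPCG; it is recorded as
  `NA` and excluded pairwise from statistics.
- **logS** — the ESOL regression
  `logS = 0.16 − 0.63·logP − 0.0062·MW + 0.066·RB − 0.74·AP`
  (molecular weight, rotatable bonds, aromatic proportion), a stand-in
  for the commercial solubility model.
- **counts** — hydrogen-bond donors (N/O bearing hydrogen), nitrogen
  atoms, amide linkages, six-membered rings (simple cycles of length 6 in
  the heavy-atom graph), and a "hydrophobe" count. The latter and the
  "floating-point Lipinski measure" have no published definition, so this
  package documents its own: hydrophobic atoms are carbons/halogens with
  no N/O/S/P neighbour, and the Lipinski score is the summed fractional
  excess over the four rule-of-five bounds. Neither claims to reproduce
  the commercial quantity.

## Topology–chemistry statistics

Descriptors are compared across degree groups (e.g. degree 1 / 2–6 / >6)
as mean ± standard error, with a tie-corrected Kruskal–Wallis test across
groups and Mann–Whitney for two-set comparisons (early vs late
metabolites, hubs vs non-hubs). Correlations in the degree–property
figures are computed over *bin means*, with the ordinal bin rank as the
x-coordinate — an open-ended top bin (">6") has no midpoint, and rank
makes the statistic insensitive to that choice. Both the coarse
table-style bins and finer per-degree bins are available; bin edges are a
configuration item because no canonical set exists. p-values are
two-sided normal/χ² approximations throughout (matching common
statistical-package defaults); exact small-sample enumeration appears
only inside the test suite as an oracle.

Early metabolites are defined operationally: metabolites of the oldest
enzyme age class, minus aerobic metabolites (which cannot predate
oxygenic metabolism), intersected with the network; everything else is
late. The two sets partition the node set by construction.

## Concentration models

The published polarity equation
`−LogC = 6.105 + 0.431·ClogP + 15.595·FNSA3 + 16.727·FPSA3 − 5.333·RPCG`
ships as a fixed evaluator (`published_concentration_model()`); it is a
published fit and is never refit from this package's synthetic data.

`stepwise_mlr()` performs forward selection with backward elimination by
partial-F tests, thresholds 0.05 to enter and 0.10 to remove. One design
choice deserves its own paragraph: by default the entry p-value is
**Bonferroni-adjusted** for the number of candidates examined at that
step. With many candidate descriptors, an unadjusted per-candidate 0.05
rule admits at least one pure-noise descriptor in most runs (with 16
decoys, `1 − 0.95^16 ≈ 56%` of them), which makes selected models
unreliable as statements about which descriptors matter. The adjusted
rule controls the *family-wise* entry probability at 0.05 per step — under
a pure-noise response the expected rate of non-empty models equals the
nominal threshold — at a modest power cost for genuinely weak predictors.
`adjust = "none"` restores the classical behaviour.

The ε-SVR uses an RBF kernel `exp(−γ‖u−v‖²)` with the published optimum
(γ = 0.01, ε = 0.22, C = 7.9) as default. Features are z-standardised
internally — an unscaled RBF over mixed-unit features is dominated by the
widest-ranging column — using the population (1/n) standard deviation,
which makes the transform invariant under duplication of the training
set; ε is an insensitivity band in response units. Models are scored by
leave-one-out cross validation: squared Pearson correlation between
held-out predictions and observations ("squared correlation
coefficient"), the plain mean of squared held-out residuals ("total mean
squared error"), and the through-origin slope `Σŷy/Σy²`. Grid search is
exhaustive with ties broken by lower MSE then smaller cost; the default
grids bracket the published optimum. Descriptor-deletion importance
removes one feature at a time, re-optimises on the reduced set, and ranks
features ascending by the resulting squared correlation — the descriptor
whose removal hurts most matters most.

## The growth simulation

Three rules: (i) one new metabolite per step; (ii) the metabolite added at
step *k* gets concentration `C_k = max(1, C_i − k·d + U)` with
`U ~ Uniform(−f/2, +f/2)`; (iii) each step adds *m* edges whose endpoints
are drawn with probability proportional to current concentration. The
run stops at the end of the step whose new concentration first reaches
`C_f` or below. Reference parameters: `C_i = 1e6`, `d = 1000`,
`f = 1500`, `C_f = 10` (a five-orders-of-magnitude concentration span,
matching the measured range of bacterial metabolite concentrations) and
`m = 5` or `10`. With `f = 0` the run terminates at exactly
`1 + ceil((C_i − C_f)/d) = 1001` metabolites; with the reference
fluctuation the mean count over seeds is ≈ 1000, the biologically
plausible metabolome size.

Conventions chosen where the three rules are silent, each deliberately
minimal: the fluctuation is additive, symmetric and bounded (uniform,
mean-preserving); only the *first* of the *m* edges is forced to touch
the newly added metabolite (guaranteeing a connected network while
letting the rest of the edge budget follow concentration freely);
concentrations are floored at 1 so sampling weights stay positive near
termination; existing concentrations never change during a run, so
termination is checked only on newly assigned values; duplicate edges are
resampled up to a retry cap and then skipped. A single seeded random
stream drives the whole run, so results are bit-reproducible.

Under these rules the degree histogram of a reference run follows a
power law with positive exponent and log-log `r² ≥ 0.8` in essentially
every seed — concentration-biased partner choice alone produces the
scale-free organisation, because early (abundant) metabolites keep
acquiring edges for the entire run.

## The synthetic-data generators

Every stage is testable without database access because the generators
emit inputs *with known ground truth*:

- `gen_reaction_set()` embeds known numbers of macromolecule-, R-group-
  and currency-containing reactions and reports the expected post-screen
  reaction and edge counts, computed from its own bookkeeping rather than
  by calling the screening functions — so screening can be validated
  against it.
- `gen_molecule_set()` builds molecules from a fragment grammar: alkyl
  chains (2–8 carbons) decorated with 0–4 polar groups and 0–2 weakly
  polar ones. Molecules are drawn from three chemical archetypes —
  donor-rich (hydroxyl, amine, acid, phosphate, amide, urea, carbamate,
  guanidine), acceptor-only (ketone, nitrile, nitro, ester, acetoxy) and
  mixed — mirroring the split of real metabolomes into amine-, acid- and
  sugar-like classes. The archetypes matter statistically: for neutral
  molecules, positively and negatively charged surface grow together, so
  a grammar without donor/acceptor contrast makes FPSA3 and FNSA3
  near-collinear (r ≈ −0.99) and the four-descriptor concentration model
  unidentifiable. With the archetypes the four descriptors carry
  independent signal, and mean logP falls monotonically with the
  polar-group count.
- `gen_concentration_data()` draws `−LogC = β₀ + Σβ·x + ε` with Gaussian
  noise on the −Log10 scale (log-normal concentrations, consistent with
  abundances spanning orders of magnitude); the default β is the
  published equation, making recovery studies a direct analogue of the
  real regression. Decoy descriptors are independent standard normals.
- `gen_degree_linked_network()` grows a preferential-attachment graph and
  assigns polar molecules to hubs with configurable rank-coupling
  strength, so the degree–chemistry statistics can be exercised at known
  effect size.
- `gen_age_annotations()` emits an enzyme→metabolite map, age classes and
  aerobic flags together with the early/late partition they imply.

What the generators do **not** emulate: biochemical plausibility of
reaction stoichiometry, ring-rich natural-product chemistry, ionisation
states, measurement error in concentrations, or the correlation structure
of 83 commercial descriptors. A passing suite therefore demonstrates
that the *procedures* behave as specified on data with the assumed
structure — not that the original database-scale numbers are reproduced,
which would require the KEGG/EcoCyc/YEASTNET extracts, measured
concentrations and commercial descriptor engines.

## Problem sizes and numerical choices

The reference analyses use 200–400 molecules, networks of a few hundred
nodes, 20 simulation replicates and 50-seed recovery studies — sizes at
which every stage completes in seconds to a couple of minutes on one CPU
while keeping the statistics well-resolved. Other conventions: power-law
fits require at least three distinct positive degrees; binned correlation
reports R = 0 with a warning when bin means are constant (the estimate is
otherwise undefined); LOOCV reports squared correlation 0 with a warning
for constant predictions; single-member groups carry `se = 0` and a
degeneracy flag; grid-search ties prefer lower MSE, then lower cost; and
all generators are pure functions of their seed.

## Known limitations

Descriptor values are open-source equivalents, not reproductions: only
polarity orderings, not absolute means, transfer to the commercial
panels. The 2D surface-area scheme underestimates steric occlusion
between non-bonded atoms. The stepwise default deviates from classical
SPSS-style selection (see above) — set `adjust = "none"` to compare. The
simulation carries no chemistry on its nodes; it tests the concentration
mechanism, not reaction feasibility.
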