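---
title: "Methods: dating cartilaginous-fish divergences from nuclear genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dating cartilaginous-fish divergences from nuclear genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`chondroclock` re-implements, as a tested and reusable pipeline, a
phylogenomic workflow for dating the deep divergences of cartilaginous
fishes (Chondrichthyes: chimaeras, sharks, rays and skates) from nuclear
protein-coding genes. The pipeline has four scientific stages, each a
module of the package:

1. **Orthology screening** (`screenGenes` and friends): candidate chimaera
   genes are scored against outgroup, shark and ray/skate peptide
   databases by local-alignment bit score, and kept only when the
   outgroup score is strictly smaller than both ingroup scores; families
   expanded to huge copy numbers are excluded, and gappy alignment ends
   are trimmed.
2. **Likelihood phylogenetics** (`siteLogLikelihoods`,
   `optimizeBranchLengths`, `njTree`, `mlSearchNNI`): amino-acid
   likelihood under JTT(+I)+Gamma, neighbor-joining starting trees, and a
   nearest-neighbor-interchange ML search.
3. **Topology acceptance** (`khCompare`, `acceptanceRule`): the
   Kishino–Hasegawa comparison of a gene's ML tree against the accepted
   species phylogeny; a gene is kept for dating when the log-likelihood
   difference is within one standard error.
4. **Relaxed-clock dating and rate quantification** (`runClockMCMC`,
   `summarizeTrace`, `buildRateTable`): Bayesian node dating under fossil
   calibrations with independent log-normal branch rates, followed by a
   relative-rate decomposition that converts pairwise distances and node
   ages into absolute substitution rates per lineage.

A synthetic-data module generates every input the pipeline needs —
alignments evolved along calibrated timetrees with lineage-specific
rates, paralog-bearing gene families, and a 12-taxon calibration
scenario — so the whole chain can be validated without any external
download.

# The substitution model

The likelihood engine uses the JTT amino-acid exchangeabilities and
frequencies (the canonical published 20×20 table, embedded in the
source). The generator is assembled as \(q_{ij} = s_{ij}\pi_j\) and
normalized so that \(-\sum_i \pi_i q_{ii} = 1\): branch lengths are
expected substitutions per site. Among-site rate variation uses discrete
gamma categories with **equal probabilities and category means** (the
CODEML/PHYML convention, not medians); an optional invariant class of
probability `pInv` removes mass from the gamma classes, whose rates are
rescaled by \(1/(1-p_{inv})\) so the mixture's mean rate stays exactly 1.
Transition probabilities come from a single eigendecomposition of the
\(\Pi^{1/2}\)-symmetrized generator, computed once per model.

Gaps (`-`) and unknowns (`X`/`N`) are treated as missing data: fully
ambiguous in likelihood computation (partial likelihood 1 for every
state) and equivalent to gaps for complete deletion and end trimming.

Per-site likelihoods follow Felsenstein's pruning recursion over
compressed site patterns, without intermediate rescaling; this is
accurate for the tree depths this package targets (tens of taxa at up to
a few substitutions per site root-to-tip). The engine is verified against
brute-force summation over all ancestral states on small instances and
against an independent implementation (phangorn) on larger ones.

Branch lengths are optimized coordinate-wise by Brent search on each
branch's profile likelihood, using cached "flank" vectors so one branch's
profile is cheap; sweeps repeat until the total log-likelihood improves
by less than `tol` (default 1e-6). Because the two branches incident to a
binary root are confounded under a reversible model, rooted input trees
are unrooted before optimization. Branch lengths are clamped to
[1e-8, 20]; a pairwise distance reaching 19+ substitutions/site triggers
a saturation warning.

# The orthology screen

The screen consumes peptides, not reads: local-alignment scores are
computed by affine-gap Smith–Waterman (BLOSUM62, gap open 11, extend 1)
and converted to bits with the standard Karlin–Altschul rescaling
\(S' = (\lambda S - \ln\kappa)/\ln 2\) with gapped constants
\(\lambda = 0.267\), \(\kappa = 0.041\). No external search engine or
E-value machinery is involved — the decision rule uses only score
comparisons, and a precomputed score table can be supplied instead
(`readScoreTriples`).

The rule is strict: a gene passes only if \(S_{co} < S_{cs}\) **and**
\(S_{co} < S_{cr}\); ties fail. The copy-number filter excludes genes
with more than 500 database hits (strictly greater). End trimming removes
leading/trailing columns until a run of `window = 20` consecutive columns
each reaches `minOccupancy = 0.9` non-missing fraction among the
reference (chondrichthyan) taxa; both thresholds are user-settable
because no published values exist for them, and interior columns are
never touched.

# The topology-acceptance test

For a gene whose ML topology conflicts with the accepted species
phylogeny, branch lengths are re-optimized independently on both
topologies and the per-site log-likelihood differences \(d_i\) are
summarized as \(\Delta\log L = \sum_i d_i\) and
\(SE = \sqrt{n\,\widehat{\mathrm{Var}}(d_i)}\) — the Kishino–Hasegawa
normal approximation. The gene is accepted when
\(|\Delta\log L|/SE < 1\); a ratio of exactly 1 is rejected
(conservative; the rule's source defines only the two strict
inequalities). A RELL-style site bootstrap of the fixed per-site
differences is available as a cross-check (`rell = TRUE`) and agrees
with the analytic SE within sampling error.

# Relaxed-clock dating

The dating model follows the independent-rates relaxed clock: a fixed
rooted topology, internal-node ages \(t\) in units of 100 My (the age of
interest should fall between 0.01 and 10 time units; all user-facing
values are in Ma), and per-branch rates with
\(\log r_e \sim N(\log\mu, \sigma^2)\) — no mean-correction term, so
\(\mu\) is the median rate. Hyperpriors are gamma: by default
\(\mu \sim G(1, 5.2)\) and \(\sigma^2 \sim G(1, 5.6)\) per 100-My time
unit, matched to a ~3000-site amino-acid supermatrix. The expected
number of substitutions on a branch is \(r_e \times \Delta t_e\).

**Calibrations.** Soft min/max bounds place probability 0.95 uniformly
between the bounds, a power-decay tail below the minimum and a
shifted-exponential tail above the maximum, each holding 0.025 and
continuous at the bounds; `softBoundCDF` gives the matching CDF.
Upper-only soft bounds use a plateau from 0 with the same exponential
tail. Inside the chondrichthyan clade only hard lower bounds are used:
\(-\infty\) below the bound, flat above, made proper by the conditional
node-age prior. Uncalibrated (and hard-bounded) node ages are uniform
conditional on the root age — the joint prior carries a
\(t_{root}^{-(m-1)}\) factor plus the ordering indicator — which is
simpler than a birth–death prior and adequate for a topology this size.
The root must have an upper bound; if none is calibrated, 1.5× the oldest
calibration is imposed with a loud message.

**Sampling.** Metropolis-within-Gibbs: sliding-window proposals on each
node age (rejected outside the parent/child bracket), on each log branch
rate (vectorized over branches under the approximate likelihood, where
branch likelihood terms are independent), and on \(\log\mu\),
\(\log\sigma^2\). Windows are auto-tuned every 100 sweeps during burn-in
towards 20–40% acceptance and frozen afterwards. The chain is
deterministic given the seed.

**Likelihood modes.** Three modes exist because their roles differ:
`"exact"` evaluates the full pruning likelihood at every proposal
(practical for small trees), `"approx"` — the default — maximizes the
unrooted-tree likelihood once, maps rooted branches onto unrooted
coordinates (the two root branches share the coordinate of their merged
branch, which is what makes the root age identifiable only through the
prior), and replaces the likelihood with a Gaussian in branch lengths
using **per-branch curvatures** (a diagonal-Hessian variant of the usual
normal approximation; the full covariance is deliberately not used —
the diagonal keeps every MCMC update O(1), and on the 12-taxon validation
scenario exact and approximate posteriors agree to a few percent).
`"prior"` switches the likelihood off entirely; sampling then reproduces
the calibration densities at nodes whose calibrations do not abut their
neighbours' — the standard check that the sampler targets the stated
prior. Where calibrations interact (e.g. nested bounds a few My apart),
the sampled marginal is the *joint* prior's marginal, which legitimately
differs from the user-specified density; validation therefore uses a
well-separated node.

**Schedule.** The production configuration — 50,000 burn-in cycles and
200,000 samples taken every 20 cycles, in two replicate chains with
different seeds — is expressible through `chainSettings`. The package's
testing default is a desk-scale chain (5,000 burn-in, 20,000 samples,
thinning 2), which the validation studies below use.

# Rate quantification

For two ingroup species A, B and an outgroup C, the three pairwise ML
distances are decomposed into ancestor-to-tip path lengths:
\[K_{OA} = (K_{AB} + K_{AC} - K_{BC})/2,\qquad
  K_{OB} = (K_{AB} + K_{BC} - K_{AC})/2,\]
which conserve \(K_{OA} + K_{OB} = K_{AB}\) exactly. Negative values
(relative-rate violations) are reported as-is with a warning, never
clamped, so users see them. Absolute rates divide \(K_O\) by the
divergence time and are expressed in \(10^{-8}\) substitutions/site/year;
reporting rounds distances and rates to 3 decimals and fold ratios to 1
decimal (ratios are computed from the *reported* rates, matching the
convention of the published table this layout mirrors), while internal
computation keeps full precision. The same machinery accepts p-distances
from whole-cluster nucleotide alignments after complete deletion.

# The synthetic-data module

`simulateAlignment` draws root states from the model frequencies,
assigns each site one rate class (gamma category or invariant), and
evolves states down the tree with \(P(t) = e^{Qtr}\) per branch — the
same generative assumptions the dating model makes (JTT+Gamma,
independent branch rates). All randomness flows from one master seed via
a counter-based splitting scheme (`splitSeed`), so each sub-simulation is
independently reproducible.

`makeFig4Scenario` builds the 12-taxon vertebrate scenario used to
validate the dating machinery: 4 tetrapods, 3 teleosts, 3
chondrichthyans and 2 outgroups, with internal nodes n1–n11. Truth ages
are set to representative published divergence-time estimates (e.g. 421
Ma for the
chimaera–elasmobranch split n10, 306 Ma for the shark–ray split n11
under constraint set I, 261 Ma under set II) — these are **simulation
parameters**, not reproduction targets. The calibration table carries 19
constraints at the 11 nodes: eight soft min/max pairs, one soft
upper-only bound at the chordate node, and hard lower bounds of 410 Ma
(n10) and 250/190 Ma (n11, sets I/II). Only the chondrichthyan lower
bounds and the bound style are documented facts; the soft bounds are
**synthetic reconstructions** bracketing the truth ages (the shipped
fixtures are suffixed `_synthetic` accordingly). Scenario defaults —
2000 sites, gamma shape 0.6 (mid-range of the per-gene estimates),
median rate 0.2 substitutions/site per 100 My (the prior mean), drift
\(\sigma^2 = 0.1\) — were chosen once as plausible study conditions.

`makeGeneFamily` exercises the orthology screen on a calibrated
gnathostome gene tree (gnathostome split 460 Ma, chimaera–elasmobranch
421 Ma, shark–ray 306 Ma; one outgroup, two shark and two ray database
species, mirroring the available sequence resources). Defaults are a
1200-residue peptide — the screened candidate set is dominated by long
multi-domain proteins — evolving at 0.1 substitutions/site per 100 My
(1×10⁻⁹/site/year, a typical vertebrate nuclear protein rate) with gamma
shape 1.5. The hidden-paralogy trap deletes the ortholog in the chimaera
and the outgroup after a pre-gnathostome duplication (550 Ma by
default): the query and the outgroup sequence are then out-paralogs
while the elasmobranch databases keep orthologs, so the query scores
*higher* against the outgroup and the screen correctly fails the gene.
Note the geometry of this trap: if instead only the outgroup ortholog
were replaced by a paralog, the outgroup score would drop and the screen
would (wrongly but inevitably) pass the gene — the rule can only see
score reversals, which is exactly the hazard it was designed around.

**What the generator does not emulate** — and hence what passing tests
do not establish about real data: alignment error and alignment-column
ambiguity (alignments are consumed as given), EST sequencing error and
fragmentary coverage, compositional heterogeneity across lineages,
site-specific profiles beyond one gamma-distributed rate, gene-tree
discordance from incomplete lineage sorting, and fossil-calibration
misspecification. Results on synthetic data validate the *computations*,
not the biological conclusions.

# Validation studies and problem sizes

The test suite runs the following studies (sizes are the package's
desk-scale choices; all are seeded and deterministic):

- Oracle equivalences: pruning vs brute-force state enumeration (≤4
  taxa, ≤3 sites, agreement < 1e-8); gamma discretization vs quadrature
  (1e-6); NJ exact on additive matrices; Smith–Waterman scores vs
  exhaustive alignment enumeration for peptides of length ≤ 6.
- Parameter recovery: branch lengths within 5% at 3×10⁴ sites; alpha
  within ±0.1 at 10⁴ sites; pairwise distance 0.2 within ±0.02 at 10⁴
  sites.
- Tree search: 6-taxon NNI recovery from NJ starts in ≥4/5 replicates at
  1500 sites; KH acceptance frequency ≥ 0.8 over 15 replicates when data
  are simulated on the species topology; KH SE within 15% of a 4000–5000
  replicate site bootstrap.
- Dating: prior-only Kolmogorov–Smirnov distance < 0.05 against the
  calibration CDF at 10⁴ samples; 95% CI coverage of the true n10/n11
  ages in ≥ 16/20 replicates of the 2000-site scenario under the scaled
  chain; replicate chains agreeing within 2% on posterior age means;
  exact vs approximate likelihood agreement on a 4-taxon scenario.
- Screen: ortholog/trap classification measured on seeded families
  (0.94 / 1.00 correct at the defaults over large batches).

# Known limitations

- The pruning engine does not rescale partial likelihoods, so extremely
  divergent alignments (hundreds of taxa or root-to-tip depths far
  beyond those studied here) could underflow.
- The approximate dating likelihood ignores covariance between branch
  lengths; strongly correlated branch estimates (very short internal
  branches) would widen or shift posteriors relative to the exact mode.
- The node-age prior is uniform-conditional-on-root rather than
  birth–death; with few calibrations this choice influences uncalibrated
  node marginals.
- The NNI search is a greedy hill-climb without randomized restarts; for
  large trees it can stop in local optima (the pipeline's use case —
  small per-gene trees with an accepted reference topology — does not
  require more).
- `p_inv` is estimated only through the model object; no joint
  `alpha`/`p_inv` optimizer is provided.
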