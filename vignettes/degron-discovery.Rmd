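---
title: "Discovering C-terminal degrons: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering C-terminal degrons: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degronscan)
```

## The scientific problem

Bacterial aldehyde decarbonylases (ADs) — the alkane-forming enzymes of
cyanobacteria — are short-lived in *E. coli* because their C-terminus acts
as a degron: a peptide signal recognized by ATP-dependent proteases (ClpAP
and Lon for this family, much as the ssrA tag is handled by ClpXP/ClpAP).
The family-wide consensus of this signal, `RMSAYGLAAA`, emerges from a
comparative workflow: collect homologs, remove redundancy, align, build a
neighbor-joining (NJ) tree with bootstrap supports, pick branch
representatives, and profile the residue usage of the last *k* positions.
Degron activity is then quantified in reporter assays: GFP fused to a
candidate tag, fluorescence normalized by OD600, and expressed as a
percentage of an untagged control. `degronscan` implements both halves as a
reusable pipeline and pairs them with a synthetic-data module that supplies
ground truth for every stage.

## The core statistic

For a family of $n$ sequences, let $x_{i}$ be the terminal $k$-mer of
sequence $i$ (default $k = 10$). The terminal profile is the $k \times 20$
frequency matrix

$$ f_{j}(a) = \frac{1}{n'} \sum_{i=1}^{n'} \mathbf{1}[x_{i,j} = a], $$

over the $n'$ sequences that are at least $k$ long and X-free in the
window. The consensus motif takes the modal residue at each position, and a
position is called *conserved* when its modal frequency strictly exceeds
the threshold (default 0.5 — the ">50%" rule, deliberately strict so a
50/50 split does not count). Frequencies are computed on **unaligned**
terminal windows, not on alignment columns: the windows are anchored at the
C-terminus, which is the biologically meaningful frame for a C-terminal
degron, and it keeps every position's denominator identical. Whether the
original tabulation used aligned columns is unknowable from the published
description; this package's choice is declared, and the per-position
denominators make it auditable.

Exclusion is all-or-none per sequence (too short, or X anywhere in the
window). A per-position policy would make column counts unequal and the
"frequencies sum to 1" invariant conditional; the cost — discarding a
sequence for a single ambiguous residue — is small at family scale.

## Alignment and phylogeny

* **Pairwise alignment** is global Needleman–Wunsch/Gotoh with affine gaps
  (BLOSUM62, gap open 10, extend 1; a gap of length $L$ costs
  `open + (L-1)·extend`). Ties are resolved deterministically: the DP runs
  on reversed sequences so that, at equal score, matches land as early as
  possible and gaps as late as possible in the output. The scores agree
  with `Biostrings::pairwiseAlignment` under the equivalent (9, 1)
  parameterization, which the test suite uses as an independent oracle.
* **Distances** are p-distances (mismatched columns over columns outside
  terminal-gap runs; internal gaps count as mismatches), with an optional
  Poisson correction $-\ln(1-p)$. The published analysis names only the NJ
  method of a MEGA release, not its distance model; p-distance is the
  simplest fully specifiable choice, and for topology recovery on a
  family of moderate divergence the difference is immaterial.
* **The guide tree and the final tree** use an original implementation of
  Saitou–Nei neighbor joining: iterative Q-minimization with lexicographic
  tie-breaking (bit-reproducible regardless of input row order), standard
  branch-length formulas, negative lengths clamped to zero with the total
  deficit recorded on the tree. NJ is exact on additive matrices —
  topology and branch lengths — and that property is the module's primary
  oracle: tests build random trees, derive distances by path summation,
  and require exact reconstruction to 1e-9.
* **Progressive MSA** merges single-sequence profiles up the guide tree by
  profile–profile alignment with sum-of-pairs column scoring (gap symbols
  score 0 against residues; the column score is averaged over sequence
  pairs so gap penalties stay on the pairwise scale). No optimality claim
  is made beyond the tested invariant: ungapping any row reproduces its
  input exactly.
* **Bootstrap** is the Felsenstein column bootstrap (resampling alignment
  columns, not sequences, which is what "bootstrap replications" means for
  tree support): 100 replicates by default, p-distance + NJ per replicate,
  support = percentage of replicates containing the same bipartition.
  Columns are put in a canonical order before resampling; since pairwise
  distances are column-order invariant this changes nothing statistically,
  but it makes the *seeded realization* — not merely its distribution —
  invariant to how the input alignment happens to be arranged.
* **Representatives** ("from different branches"): the `n_groups - 1`
  longest internal edges are cut, and each resulting leaf group returns
  its medoid (smallest mean within-group distance, ties by label). Eight
  groups is the default, mirroring the original selection of eight
  representative sequences.

## Reporter-assay quantification

Fluorescence is divided by OD600 per time point within each replicate
("normalized to the number of cells"), then replicates are averaged —
in that order, because OD trajectories differ per replicate. Points with
OD below 0.01 are masked: early-culture readings amplify noise
catastrophically under division. Endpoint readouts
(`percent_of_control`, `degradation_percent = 100 - percent_of_control`)
interpolate linearly to the stated hour, since published figures do not
reveal their sampling grids. The two quantities sum to 100 exactly, by
construction.

`fit_decay_rate` regresses log(normalized signal) on time over the
post-peak segment and negates the slope; it refuses series with fewer than
3 points after the peak and flags non-degrading (flat or rising) series.

`fold_change` reports `max/min` with the direction taken from the
ordering, and a display value **truncated** (not rounded) to two decimals:
the published activity comparisons print 90.9/16.6 = 5.4759… as 5.47 and
49.1/42.7 = 1.1499 as 1.14, which only truncation reproduces. The raw
ratio is always retained alongside. `net_effect` formalizes the
compensation argument — predicted production fold = abundance fold ÷
activity fold — so that a 2.65-fold abundance gain against a 5.47-fold
activity loss correctly predicts a net production decrease.

No significance test is attached to `recovery_index` (degradation in WT
minus degradation in a knockout): the original comparison reports
"not significant" without naming a test, so the index stays descriptive
and per-replicate values remain available for any downstream test.

## The synthetic world

The generator states one world and the tests live in it; its parameters
were fixed before any test outcome was seen and are not tuned.

* **Tree**: pure-birth (Yule) topology, branch lengths i.i.d.
  Exponential(mean 0.1) substitution units. With a 100-leaf tree and a
  body rate of 0.3 substitutions/site per unit length this yields typical
  pairwise p-distances around 0.3–0.4 — a realistic divergence for a
  conserved enzyme family drawn from one database search.
* **Sequences**: uniform replacement among the 20 residues, no rate
  matrix, no indels. The downstream statistic depends only on conservation
  *level*, not on which residues exchange with which, so realistic
  exchangeabilities would add parameters without adding test power.
* **Planted motif**: the terminal 10 positions substitute at 0.02/site
  per unit length versus 0.3 in the body — the differential conservation
  the discovery rests on. Defaults: 100 taxa, 200 residues, 62 exact
  duplicates (reproducing the roughly 600-to-371 redundancy ratio of the
  original download).
* **Time courses**: GFP synthesis is coupled to the instantaneous logistic
  growth rate, `dF/dt = s·g(t) − kF` with `g(t)` the normalized dOD/dt.
  A constant-synthesis model can only rise to an asymptote; coupling to
  growth reproduces the observed rise-then-fall of tagged GFP and
  rise-then-plateau of untagged GFP while preserving the closed form
  `F(t) = F0·e^{−kt}` exactly when synthesis is zero (the integrator uses
  exact exponential stepping, so this identity holds to machine
  precision). Noise is multiplicative lognormal (mean 1, CV 5% by
  default) independently on fluorescence and OD — both readouts are
  strictly positive. Three biological replicates by default: the source
  figures mix five-replicate and three-replicate designs, and the
  three-replicate convention dominates.
* **What the generator does not emulate**: indels, compositional bias,
  growth-phase lag, plasmid-copy-number drift, instrument drift. A green
  consensus-recovery test therefore establishes that the statistics
  recover a planted signal under idealized evolution — not that they would
  survive alignment artefacts real indel-rich families can produce.

Decay-rate recovery tests use a constant-OD configuration (`od_r = 0`,
synthesis 0): `fit_decay_rate` operates on the OD-normalized series, so a
growing culture would deliberately confound the estimate; constant OD
isolates the closed-form identity being tested.

## Numerical and degenerate-input conventions

* Consensus ties: lexicographically smallest residue wins *and* the
  position is flagged ambiguous — deterministic without hiding ambiguity.
* `right_anchored_identity` divides matches by the shorter motif's length;
  penalizing overhang would conflate length difference with dissimilarity.
* `cluster_identity` divides by alignment columns excluding terminal gaps
  (the least length-biased common convention).
* Poisson correction of p ≥ 1 is flagged and returned as a maximal
  distance rather than silently capped.
* Redundancy removal defaults to verbatim-identical sequences — the
  minimal reading of "removing redundant sequences"; threshold-based
  clustering is available but opt-in, because no threshold was published.
* The pipeline records its own reduction counts rather than targeting the
  published 371: how that count arose (tool, threshold) is unstated, so
  reproducing it is not a meaningful check.

## Known limitations

* Progressive MSA has no iterative refinement; pathological guide trees
  can propagate early gap placement errors.
* NJ is O(n³) in pure R; families beyond ~300 sequences will feel it
  (the bootstrap multiplies this by the replicate count).
* The dataset-scale published numbers (371 homologs, Ala at 67.92% at
  position 7, the "half of positions > 50%" count) require the original
  undeposited sequence set and are treated as reference values only;
  nothing in this package claims to reproduce them.
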