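---
title: "Constraint network analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint network analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnar)
```

## The model

`cnar` treats a protein structure as a *body-and-bar* constraint network.
Every atom is a rigid body with six degrees of freedom; interactions are
sets of bars, each bar removing one relative degree of freedom between its
two endpoint bodies:

* a rotatable single covalent bond contributes **5 bars** (one torsion
  remains);
* a locked covalent bond — the peptide bond, bonds inside conjugated sp2
  groups (carboxylate, amide, guanidinium, aromatic rings), and terminal
  bonds such as N–H or C=O — contributes **6 bars**;
* a hydrogen bond or salt bridge contributes **5 bars** between the donor
  heavy atom and the acceptor, and carries an energy;
* a hydrophobic tether contributes **2 bars** between carbon/sulfur atoms
  in van der Waals contact.

The generic rigidity of such a network is a purely combinatorial property
(the (6,6)-sparsity matroid), decided by a pebble game: each body starts
with six pebbles; a bar is independent exactly when seven pebbles can be
gathered on its endpoints, and accepting it consumes one. The network
decomposes into *rigid clusters* — maximal body sets with zero internal
degrees of freedom — and flexible links between them. The implementation
is certified against an independent oracle: the rank of a dense 6-DOF
rigidity matrix with generic bar placements must equal the pebble game's
independent-bar count on every instance tested, and pairwise
mutual-rigidity decisions must agree as well.

## Thermal unfolding by constraint dilution

Hydrogen bonds break at temperatures that increase with their strength, so
removing them from the network in order of increasing strength simulates
heating. A network *state* $\sigma$ keeps all covalent bonds, all tethers
(hydrophobic contacts do not weaken with temperature; their set is held
fixed), and the hydrogen bonds with energy $E_{HB} \le E_{cut}(\sigma)$,
ties included. The default ladder lowers $E_{cut}$ from $-0.1$ to $-6.0$
kcal/mol in steps of $0.1$ (60 states), and the calibrated linear map

$$T = -20\,\mathrm{K\,mol\,kcal^{-1}}\cdot E_{cut} + 300\,\mathrm{K}$$

places those states at 302 K to 420 K in 2 K steps. Ladder values are
computed from integer multiples of the step so state boundaries are
bit-stable.

Hydrogen-bond energies follow a Mayo-type 12-10 potential,
$E_{HB} = V_0\{5(d_0/d)^{12} - 6(d_0/d)^{10}\}F$, with $V_0 = 8$ kcal/mol
and $d_0 = 2.8$ Å on the donor–acceptor distance, so the well depth is
$-8$ kcal/mol at ideal geometry. The angular factor $F \in [0,1]$ combines
a $\cos^2\theta\,e^{-(\pi-\theta)^6}$ term on the donor–hydrogen–acceptor
angle with a $\cos^2(\phi - \phi_0)$ term on the hydrogen–acceptor–base
angle ($\phi_0$ = 109.5° for sp3, 120° for sp2 acceptors). The form sits
behind the single function `mayo_angular_factor()` so alternative angular
terms can be swapped without touching detection. The geometric prescreen
(donor–acceptor ≤ 3.6 Å, angle ≥ 100°) and the inclusion cutoff
($E_{HB} \le -0.1$ kcal/mol) are `network_params()` fields. Salt bridges
between charged side-chain groups are pinned at $-10$ kcal/mol so they
survive the whole ladder, whose floor is $-6$.

Two exclusion rules are worth stating because the tool's own fixtures
depend on them. Hydrogen-bond partners fewer than three covalent bonds
apart are skipped (they cannot be genuine hydrogen bonds and would create
degenerate constraints). Tether partners must be *more* than three bonds
apart: without this, backbone atoms of adjacent residues (e.g. C(i) and
CA(i+1), 2.4 Å apart) would receive 2-bar tethers that lock every backbone
torsion and make any chain spuriously rigid.

## Indices

**Cluster configuration entropy.** For one decomposition with cluster
sizes $s_c$, $H = -\sum_c w_c \ln w_c$ with $w_c = s_c^2/\sum s_{c'}^2$
(singletons included). $H = 0$ when one cluster holds everything and grows
as the giant cluster shatters. The squared-size weighting is exposed as a
parameter; absolute $H$ values depend on that normalization and are
therefore used only comparatively, never as external reference numbers.

**Phase transition temperature $T_p$.** The temperature of the state just
after the largest single-step jump in $H$ along the ladder. Protein
networks are modular and often show several comparable jumps; ties break
toward the lower temperature, and when the two largest jumps differ by
less than 10% the result carries a low-confidence flag.

**Percolation profile $p_i$.** Per backbone bond (N–CA and CA–C), the
temperature of the first state at which its two atoms no longer sit
jointly in the current largest rigid cluster; the residue takes the lower
of its two bond values, and never-segregating bonds take the top ladder
temperature. The largest cluster is re-identified per state (the simplest
reading of the definition); lineage tracking across states was considered
and rejected as under-determined when clusters split evenly.

**Stability map and neighbor median.** Residues $i,j$ have a rigid contact
at a state iff at least one atom of each shares a rigid cluster — side
chains included, since mutations act through side chains. $rc_{ij}$ is the
$E_{cut}$ of the last state where the contact exists. Pairs never in
contact carry the ladder start ($-0.1$, 302 K) and contacts that survive
the floor carry $-6.0$ (420 K); both sentinels keep the median
well-defined. The *median* of $rc_{ij}$ over neighbor pairs (any-atom
distance ≤ 5 Å) is the package's local thermostability measure: the median
resists the extreme values that tether-dense regions produce, and a
residue-pair summary does not require identifying a single global
transition, which makes it robust to pathway details. Sequence-adjacent
pairs are included by default (`include_adjacent = FALSE` to drop them);
since the median and the linear temperature map commute, either scale
gives the same ranking.

## Fuzzy-constraint ensembles

Rigidity analysis of a single topology is sensitive to the input
conformation. Instead of sampling conformations, the ensemble module
redraws the *constraint set*: hydrogen-bond energies are perturbed by a
uniform draw in $\pm 0.3$ kcal/mol (bonds pushed past the $-0.1$ cutoff
drop out), and candidate tethers within $\pm 0.25$ Å of their distance
cutoff are included with probability falling linearly across that band.
The production ensemble size is 2000 topologies. The exact modulation
ranges used by the original fuzzy-constraint scheme are not restated in
the sources this package follows; the defaults above are this package's
own documented choices, fully exposed in `fuzzy_params()` and intended to
be recalibrated if reference ranges become available. Per-topology seeds
are drawn once from the master seed, so ensembles are reproducible and
trivially parallelizable; a zero-fuzz ensemble collapses exactly onto the
deterministic single run.

## Pathway clustering and prediction reliability

Residue-wise $p_i$ profiles encode the order in which structure is lost.
Profiles from all variants' topologies are pooled and clustered by
Partitioning Around Medoids under Manhattan distance (k = 10 by default;
chosen by scanning the objective — the mean dissimilarity to the nearest
medoid — against k and reading the elbow). Each variant then has a
distribution of its topologies over the clusters, and the Pearson
correlation between two variants' distributions measures how similarly
they unfold. Low mean correlation against the other variants flags a
variant whose relative thermostability prediction should not be trusted;
`pathway_reliability()` uses a default flag threshold of 0.16 on the mean
correlation.

## What the synthetic fixtures do and do not show

The generator builds ideal poly-alanine helices (standard bond lengths and
angles, $\phi = -57^\circ$, $\psi = -47^\circ$, planar trans amides, no
side chain beyond C$\beta$). These have textbook i → i−4 hydrogen-bond
geometry (N···O 3.09 Å, D–H···A 165°) and, by construction, no hydrophobic
tethers, so helix rigidity is attributable to covalent bars and backbone
hydrogen bonds alone. Toy networks with explicit body/bar lists exercise
the pebble game directly, and a packaged variant table (17 lipase A
variants with experimental melting temperatures and published median
contact stabilities) drives the report module without downloads.

Passing tests on these fixtures certify the combinatorics, the detection
rules, the index definitions, and the statistical machinery. They do not
certify prediction quality on real proteins: real structures bring
protonation ambiguities, salt-bridge networks, tether-dense cores, and
conformational strain that ideal fixtures by design do not contain.

### The helix rigidity threshold

A well-known rule of thumb says an isolated helix becomes rigid at seven
residues. Under this package's bar conventions the combinatorial threshold
falls at *six*: each i → i−4 hydrogen bond closes a ring of six rotatable
backbone torsions, leaving one internal degree of freedom, and the two
rings of a six-residue helix share four torsions — ten hydrogen-bond bars
against eight torsional freedoms — so the pebble game (and the rank
oracle, independently) finds the span rigid. Seven residues add a third
bond and redundancy. The discrepancy with the seven-residue rule is a
property of the 5-bar hydrogen-bond convention, not of the implementation;
the corresponding regression test records the rule as stated and is
expected to flag the six-residue boundary case. Relatedly, a helix is
"backbone-spanning rigid" here when one rigid cluster contains atoms of
every residue; the terminal torsions ($\phi_1$, $\psi_1$, $\phi_n$) sit in
no hydrogen-bond ring, so the first and last backbone atoms always dangle
regardless of helix length.

## Numerical choices

* Bars are processed in sorted `(body_a, body_b, kind)` order and cluster
  labels are assigned by decreasing size (ties to the smallest member), so
  decompositions are bit-reproducible; the mathematics is
  order-independent, the labels are not.
* Ties at $E_{HB} = E_{cut}$ include the bond (the inequality is ≤).
* Consecutive ladder states with identical active sets share one
  decomposition; the contract — verified by test — is equality with an
  independent per-state run.
* The rank oracle uses seeded random bar attachment points (generic
  placements) and a QR rank with the default tolerance; it is restricted
  to small instances by design.
* Alternate locations other than blank/'A' are dropped; all protein
  chains are merged into one gap-free residue index, with author numbering
  kept as metadata.
* PAM is deterministic (BUILD initialization plus swap phase), so the
  `seed` argument of the clustering functions is accepted but unused.

## Problem sizes

Examples and tests run at desk scale: helices of 4–10 residues (23–59
atoms), toy networks of up to 10 bodies for oracle sweeps (120+ seeded
instances), ensembles of 10–90 topologies over the full 60-state ladder,
and planted-group clustering with 30–50 profiles. The production settings
(2000 topologies, 181-residue proteins, k = 10) use the same code paths;
the pebble-game core is compiled, and a full-protein ensemble is an
embarrassingly parallel loop over topologies.

## Known limitations

* Structures must arrive protonated; the package checks for hydrogens but
  does not add them, flip amides, or minimize.
* Covalent bonds are detected within and between adjacent residues only,
  so disulfide bridges between sequence-distant cysteines are not formed.
* No pi-stacking or cation-pi constraints, and no explicit water-mediated
  constraints.
* The energy-to-temperature map was calibrated for transition-temperature
  prediction; applying it to median contact stabilities compresses the
  scale (slopes well below one against experimental melting temperatures),
  so converted values are comparative, not absolute.

## A worked example

```{r example}
h <- make_ideal_helix(9)
net <- build_network(h)
net

traj <- run_unfolding(net)
tail(traj$summary[, c("e_cut", "temperature", "n_hbonds_active",
                      "largest_cluster_size")], 3)

nm <- neighbor_median_stability(stability_map(traj))
c(rc_median = nm$rc_median, rc_median_K = nm$rc_median_K)

ens <- run_ensemble(net, params = fuzzy_params(n_topologies = 20, seed = 7))
ens
```
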