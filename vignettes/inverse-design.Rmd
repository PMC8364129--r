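---
title: "Inverse design of acyclic chemical graphs with bounded branch-height"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverse design of acyclic chemical graphs with bounded branch-height}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treeqsar)
```

## The problem

Quantitative structure–property modelling (QSPR) learns a map from a
molecule's structure to a measured property; *inverse* QSPR asks for
structures that realise a prescribed property value. `treeqsar` implements a
two-phase pipeline for hydrogen-suppressed **acyclic** chemical graphs:

1. **Forward phase.** Compute a purely graph-theoretical descriptor vector
   $x = f(G)$ for each training molecule and fit a single-hidden-layer ReLU
   network $\psi$ with cross-validation, recording a range-based
   applicability domain (AD).
2. **Inverse phase.** For a target value $y^*$, solve one mixed-integer
   linear program whose solution is simultaneously (a) a descriptor vector
   $x^*$ in the AD with $(1-\varepsilon)y^* \le \psi(x^*) \le
   (1+\varepsilon)y^*$ and (b) a certificate that a chemical acyclic graph
   with $f(G) = x^*$ exists, then enumerate further graphs with the same
   descriptor vector by a dynamic program over frequency vectors.

Everything is organised around a structural parameter: for a
branch-parameter $k$, root a tree at its center and call a non-root vertex
a **leaf $k$-branch** if its height is exactly $k$, and a **non-leaf
$k$-branch** if it has at least two children, all of height $\ge k$.
Contracting the paths between branches gives the $k$-branch-tree; its
height is $\mathrm{bh}_k$ and its leaf count $\mathrm{bl}_k$. The material
hanging off the branch-subtree forms $k$-fringe-trees of height $\le k$.
The target class fixes the vertex count $n^*$, maximum degree $d_{\max}$
(at most 3 when $d_{\max}=3$, exactly 4 when $d_{\max}=4$), the exact
diameter $\mathrm{dia}^*$, $\mathrm{bh}_{k^*} = \mathrm{bh}^*$,
$\mathrm{bl}_{k^*} = \mathrm{bl}^*$, and the fringe size rule
$n(T) \le 2\deg_T(r) + 2$ for every 2-fringe-tree. Most acyclic compounds
in public databases fall in this class for $k^* = 2$ with
$\mathrm{bl}_2 \le 3$, which is what makes it a useful restriction: it
buys a linear-size MILP and a practical enumeration scheme without giving
up much chemical coverage.

## Descriptors

With an element alphabet $\Lambda$ (a valence in $[1,4]$ and a mass per
element; the order over $\Lambda$ follows mass) and an
adjacency-configuration set $\Gamma$ (edge types $(a, b, m)$ with bond
multiplicity $m \le 3$, normalised so the lighter element comes first),
the feature vector contains $K = 2|\Lambda| + 2|\Gamma| + 50$ entries:

* $n$, $\overline{\mathrm{dia}} = \mathrm{dia}/n$, average integer mass
  $\overline{\mathrm{ms}}$, implicit hydrogen count $n_{\mathrm H}$,
  $\mathrm{bl}_{k^*}$, $\mathrm{bh}_{k^*}$;
* degree counts $\mathrm{dg}_i^t$, element counts $\mathrm{ce}_a^t$,
  multiple-bond counts $\mathrm{bd}_m^t$, adjacency-configuration counts
  $\mathrm{ac}_\gamma^t$ and bond-configuration counts
  $\mathrm{bc}_\mu^t$, each split by $t \in \{\mathrm{in}, \mathrm{ex}\}$
  over the $k^*$-internal/external partition.

The bond-configuration domain is the set $\{(d_1, d_2, m): d_1 \le d_2,\
\max(d_1,d_2)+m \le 5\}$ **minus** the three $(1,1,m)$ members, i.e. 16
entries. The full 19-member set would give $K = 2|\Lambda| + 2|\Gamma| +
56$; the $(1,1,m)$ configurations are realisable only by two-vertex
graphs, outside every target class ($n^* \ge 3$), and dropping them is the
unique reading under which the descriptor count comes out as
$2|\Lambda|+2|\Gamma|+50$ (76 with $|\Lambda| = 3$, $|\Gamma| = 10$; 68
with $|\Gamma| = 6$), which the package asserts at construction.

$\overline{\mathrm{dia}}$ and $\overline{\mathrm{ms}}$ are stored as
doubles, but every consumer works from their exact integer numerators
(the diameter, the mass sum) with $n$ fixed, so floating error cannot
change a feasibility or matching decision.

```{r descriptors}
elements <- default_elements()
gamma <- all_adjacency_configs(elements)
dspec <- descriptor_spec(elements, gamma, k_star = 2)
dspec$K
g <- random_graph(generator_config(elements, gamma, n = 12, d_max = 3), seed = 1)
head(tidy(feature_vector(g, dspec)))
```

## The regressor

`train()` fits the `(K, h, 1)` ReLU network by full-batch BFGS with
analytic gradients on standardised inputs; the standardisation is folded
back into the exported weights so that the weight matrices act on raw
descriptors, exactly as the MILP encoder assumes. Training is
deterministic given the seed. A small L2 penalty on the weight matrices
(default `lambda = 1e-3` on the standardised scale, biases unpenalised)
matters more than it looks: descriptor sets are highly collinear, so the
least-squares problem is underdetermined at typical training sizes and
an unregularised exact fit wanders along unpinned directions off-sample;
the decay selects the minimal-norm solution, which for a linear
ground-truth is the linear map itself. `cross_validate()` reports the five-fold
test $R^2$ (mean and best fold); `ad_bounds()` records per-descriptor
min/max over training data, with every element count `ce_*` normalised by
$n$ (the package default; configurable). A hidden width of 10 is the
default architecture. The choice of a quasi-Newton full-batch fit over a
stochastic optimiser is deliberate: the training sets here are small
(hundreds of rows), reproducibility matters more than wall time, and the
MILP only needs the weights, not the training path.

## The existence MILP

The published constraint listings for the graph-existence block are not
reproduced here; the encoding below is this package's own, built from the
scheme-graph idea, and its contract is checked behaviourally (soundness by
re-validating decoded graphs with the independent graph modules,
completeness by embedding exhaustively generated small graphs).

**Scheme graph.** A base tree $T_B = T(d_{\max}, d_{\max}-1,
\mathrm{bh}^*)$ hosts the $k^*$-branch-tree as a prefix-closed vertex
selection (symmetry-broken with a proper precedence set: parent–child
pairs plus consecutive-sibling pairs). Each selected base edge is either
kept or replaced by a window of a link path $P_{t^*}$; entry/exit arc
binaries attach window ends to the edge's endpoints, per-position
ownership binaries keep windows contiguous and disjoint, and a
non-decreasing owner index packs them canonically. Every spine vertex
(root(s), selected base vertices, used path positions) carries a fringe
skeleton of height $k^*$ whose node selections form the fringe trees.
Label, degree-indicator and per-edge multiplicity /
adjacency-configuration / bond-configuration binaries are linked by
standard two-sided rows, and linear counting rows tie the whole selection
to every descriptor variable. For fixed class parameters the model size
is exactly affine in $n^*$.

Design points that were genuinely open and the choices made:

* **Odd diameters.** A tree with odd diameter has an adjacent *pair*
  center. The encoder then uses two copies of
  $T(d_{\max}-1, d_{\max}-1, \mathrm{bh}^*)$ joined by an always-selected
  root edge (assigned to the internal edge set), mirroring how heights
  are computed on either side of a pair root.
* **Diameter and center without distance variables.** Every leaf branch's
  arm depth (path length from the root plus $k^*$ for its mandatory
  height-exactly-$k^*$ fringe) is bounded by the radius
  $R = \lfloor \mathrm{dia}^*/2 \rfloor$ (per side, for pair roots), and
  attainment indicators force two distinct root directions (or both
  sides) to reach $R$. A short argument shows this pins the diameter to
  $\mathrm{dia}^*$ exactly and makes the chosen root the center: paths
  through the root are at most $2R$, paths inside one direction lose at
  least 2 by their lowest common ancestor, and fringe material can never
  out-reach an arm.
* **Branching vertices carry no fringe.** A non-leaf $k$-branch requires
  *all* children to have height $\ge k$, and any fringe child of a
  branching spine vertex has height $\le k-1$; so selected non-leaf
  branch vertices get empty skeletons. This is a theorem of the class,
  not a restriction. One consequence worth knowing: $\mathrm{bl}^* = 2$
  forces $\mathrm{bh}^* = 1$ (a second-level branching point would need a
  third leaf branch), so a $(\mathrm{bl}^*, \mathrm{bh}^*) = (2, 2)$
  specification is correctly reported infeasible.
* **Big-M constants** for the ReLU rows come from interval propagation of
  the descriptor-variable bounds (tightened by the AD box) through the
  first layer; units whose pre-activation interval does not cross zero
  are encoded linearly without a binary.
* **Supported branch-parameters.** The encoder accepts $k^* \in \{1,2\}$;
  the fringe size rule is imposed for $k^* = 2$ only, where it is stated.
  All shipped study settings use $k^* = 2$.
* The solver layer serialises the model and runs the HiGHS engine through
  a bundled driver; any engine exposing the same JSON contract can be
  dropped in. Engine failures surface as a distinct status, never as
  "infeasible".

`decode()` rebuilds the graph from the selection binaries and then
re-checks every class feature — validity, $n^*$, diameter, maximum
degree, $\mathrm{bh}$, $\mathrm{bl}$, fringe sizes, and
descriptor-by-descriptor equality with the model's $x$ variables — using
the independent graph/decomposition/descriptor code paths, naming the
offending feature on any mismatch.

## The enumeration stage

For $k^* = 2$ and $\mathrm{bl}^* \in \{2, 3\}$ the targets have a rigid
shape: a **caterpillar** (two leaf 2-branches joined by the 2-internal
spine through the center, every spine vertex carrying a fringe tree of
height $\le 2$, the two tips carrying fringes of height exactly 2), or a
**three-armed** variant whose arms meet at a junction. The dynamic program
works on integer *frequency vectors* (the count sub-vector of $f$: element,
adjacency-configuration, degree and bond-configuration counts, split
internal/external) and never materialises intermediate graphs:

1. `generate_fringe_set()` enumerates the pool FT of valence-valid
   chemical rooted trees of height $\le 2$ under the size rule, in
   canonical child order, grouped by frequency signature; group sizes are
   the multiplicities $W(\mathrm{FT})$.
2. Chains of $p$ fringe trees (tip first, so chain 1 is always a
   height-exactly-2 tree) are extended one tree at a time. A subtlety the
   state carries explicitly: a spine vertex's degree is final only once
   its last spine edge arrives, so each chain keeps the *pending*
   bond-configuration entries of its exposed end (its fringe edges and
   the last spine edge) and settles them on the next join.
3. For $\mathrm{bl}^* = 2$ the spine has $s = \mathrm{dia}^* - 3$
   vertices and chains of $\lfloor s/2 \rfloor$ and $\lceil s/2 \rceil$
   trees are closed with the middle bond; for $\mathrm{bl}^* = 3$, arm
   lengths $c_1 \ge c_2 \ge c_3$ satisfy $c_1 + c_2 = \mathrm{dia}^* - 4$
   with $c_3$ fixed by the internal-vertex count, and the junction's
   fringe entry must respect valence, degree and the branch-height
   constraint ($\mathrm{bh} = 2$ exactly when the junction is non-central
   and fringe-free).

The chain index convention differs from one common presentation in which
the two tip trees are accounted separately (making the loop run to
$\lceil(\mathrm{dia}^*-5)/2\rceil$); including the tips in the chains is
algebraically the same join and keeps one code path for both ends.

**Counting.** `#FP` counts feasible vector tuples. The lower bound `G-LB`
on the number of target graphs is computed from multiplicity products:
for an even spine split the count per pair is exact
($M_1 M_2$ for distinct chain vectors, $M(M+1)/2$ for a self-paired
vector); for an odd split each graph corresponds to one or two oriented
assemblies, so half the ordered total, rounded up, is a valid lower
bound; for three arms the product is divided by the permutations of
equal-length, equal-vector arms. The reported bound is the maximum of
this vector-level count and the number of distinct reconstructed graphs,
so it is simultaneously $\ge$ the emitted set and $\le$ the true count —
both directions are asserted against the exhaustive oracle in the tests.
Reconstruction back-traces predecessor links, deduplicates by a canonical
tree encoding, and stops at the cap (default 100, as in the
experimental protocol this mirrors; the vector-set size is capped by the
escalating schedule $10^6, 10^7, 10^8$ and time limits default to 600 s
per stage).

## Synthetic data and what the tests show

`random_graph()` builds class members constructively — a spine (or three
arms) realising the requested diameter, tip fringes of height exactly 2,
then random valence-feasible fringe material — so class membership holds
by construction rather than rejection sampling, which would be hopeless
at exact $\mathrm{bl}_2/\mathrm{bh}_2$ targets. Default sizes draw
$n \in [10, 16]$ with $d_{\max} = 3$, single bonds upgraded with
probability 0.15 where valence headroom and $\Gamma$ allow — values
chosen once to resemble the mid-size acyclic compounds the method aims
at. `synthetic_property()` is linear in the descriptors plus Gaussian
noise; with zero noise a trained network should and does reach
$R^2 \ge 0.99$, which validates the training plumbing, not chemistry.
What the synthetic generator does **not** emulate: the long-tailed size
distributions, label correlations and measurement noise of curated
property databases. Green tests certify the algorithms' contracts
(equality with exhaustive oracles, feasibility/decoding round trips), not
predictive accuracy on real compounds.

`exhaustive_graphs()` provides the ground truth at desk scale via
canonical centroid-rooted generation (with a bicentroid pass for even
$n$); its single-bond carbon counts at $n = 4..11$ reproduce the known
alkane-skeleton isomer numbers (2, 3, 5, 9, 18, 35, 75, 159), an
independent corroboration.

Problem sizes exercised by the shipped suite, chosen to keep the whole
run at desk scale: the enumerator is compared with the oracle over the
full $n = 7$ census over $\{C, O\}$ with all multiplicities (846 in-class
graphs, a sampled 80 of the 665 distinct vectors in the acceptance run
and all of them in the development run) and the complete single-bond
carbon censuses at $n = 9$ and $11$; the existence MILP round-trips
twenty random class members with $n^* \in [8, 13]$ and both $d_{\max}$
settings; inversion and the three-property joint run use 200 noiseless
training graphs and $n^* \in \{11, 12\}$.

## Known limitations

* Cyclic graphs, charges, aromaticity and stereochemistry are out of
  scope; elements are limited to unique valences in $[1, 4]$.
* The enumerator requires $k^* = 2$ and $\mathrm{bl}^* \in \{2, 3\}$ (by
  design of the class); the MILP encoder accepts $k^* \in \{1, 2\}$.
* MILP solve times grow quickly once $n^*$ reaches the high teens with a
  free descriptor vector; the feasibility formulation carries no
  objective and inherits whatever solution the engine finds first.
* `G-LB` is exact for even spine splits but only a (valid) lower bound
  for odd splits and three-armed targets.
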