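---
title: "Scanning genomes for introgression with a coalescent phylo-HMM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning genomes for introgression with a coalescent phylo-HMM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introscan)
```

## The problem and the model

After hybridization and back-crossing, a genome is a mosaic: most regions
descend "vertically" within the species tree, while introgressed regions
descend through the hybridization edge of a phylogenetic network. Walking
along a multi-genome alignment, the local genealogy changes at
recombination breakpoints for two very different reasons: incomplete
lineage sorting (ILS; ancestral polymorphism sorting across deep splits)
and introgression. A scan must separate the two.

`introscan` models the alignment with a hidden Markov model whose hidden
state at site $t$ is a *pair*: a parental tree $T_c$ (one of the trees
displayed by the network; "class" $c$) and a rooted gene genealogy $g$ on
the sampled alleles. Every genealogy is allowed inside every class; what
differs is its weight $P(g \mid T_c)$, the multispecies-coalescent
probability of the topology given the parental tree, computed exactly by
enumerating coalescent histories (assignments of gene-tree coalescences to
species-tree branches, with Tavaré's lineage-count probabilities per
branch). ILS therefore lives *inside* a class, while transitions *between*
classes represent introgression breakpoints.

With $K$ classes and $n$ alleles there are $1 + K \cdot (2n-3)!!$ states:
one silent start state plus one state per (class, rooted topology) pair
— 7 states for three species with one allele each and two parental trees,
31 for the two-species, two-alleles-each configuration used for
chromosome-scale scans.

Transitions use three free parameters:

* $\gamma$ — the probability that consecutive sites switch parental class
  (split as $\gamma/(K-1)$ per target class when $K > 2$);
* $s_1$ — the genealogy-switching factor out of a *congruent* genealogy
  (one whose topology matches its containing parental tree, with each
  species' alleles monophyletic);
* $s_2$ — the factor out of an *incongruent* genealogy.

Within class $c$, the transition $(c, g_i) \to (c, g_j)$, $j \neq i$, has
probability $(1-\gamma)\, s(g_i)\, \tilde P_c(g_j)$ with $\tilde P_c$ the
class-normalized topology probability; cross-class moves get
$\gamma/(K-1) \cdot \tilde P_{c'}(g_j)$; the diagonal takes the remainder,
so every row sums to one for any valid $(\gamma, s_1, s_2)$. Only two
switch factors are modeled — one per congruence status of the *source*
genealogy — so $s_2$ governs all moves out of an incongruent genealogy,
the minimal two-parameter rule consistent with both factors' definitions. The start state distributes over all non-start states by
normalized gene-tree probability, which (since each class's table sums to
one) is uniform over classes and $P_c(g)$-weighted within a class.

Emissions are alignment columns: the likelihood of a column on the state's
gene tree under a GTR substitution model (stationary frequencies plus six
exchangeabilities, rate matrix normalized to mean rate one so branch
lengths are expected substitutions per site), computed with Felsenstein
pruning. `N`, gaps and IUPAC ambiguity codes are marginalized over their
compatible bases; an all-missing column emits probability one. Because the
model is reversible, likelihoods depend only on the unrooted genealogy, so
states whose rooted topologies unroot identically share one block of
branch-length parameters (three blocks for the 15 rooted four-leaf
topologies). For three-leaf genealogies every rooted topology unroots to
the same star, which would make all states emission-identical and the
transition parameters unidentifiable, so three-leaf blocks are keyed by
rooted topology instead. Parental-tree branch lengths are shared per
class; sharing them per *topology* would merge the two classes of the
standard two-species network (same topology, different divergence times)
and collapse the model.

The per-site quantity of interest is the introgression posterior: the
forward–backward posterior mass summed over every state whose class is
flagged introgressed. Regions are maximal runs of sites above a posterior
threshold (default 0.9, with `min_sites = 2` and no gap merging by
default; there is no field-standard calling rule, so the defaults are
conservative and configurable).

## Training

All free parameters — $\gamma, s_1, s_2$, GTR frequencies (via three
stick-breaking scalars in $(0,1)$), five free exchangeabilities (GT is the
reference), the shared gene-tree branch-length blocks, and optionally the
parental branch lengths — are estimated by coordinate-ascent hill
climbing: each round sweeps the scalars in a fixed order (transition
parameters, then GTR, then branch lengths) and optimizes each on its
profile log-likelihood with Brent's method over the scalar's bound
interval (branch lengths in $[10^{-6}, 10]$ substitutions/site, parental
lengths in $[10^{-3}, 20]$ coalescent units, probabilities in
$[10^{-6}, 1-10^{-6}]$). Topology-probability tables are *not* free
parameters; they are recomputed whenever a parental branch length moves.
Convergence is declared when a full round improves the log-likelihood by
less than `tolerance` (default $10^{-6}$); restarts redraw the
probability-scale scalars ($\gamma, s_1, s_2$ and the GTR block)
uniformly within their bounds while branch lengths restart from their
data-seeded values, and the best final likelihood wins. Restarting branch
lengths from uniform draws over $[10^{-6}, 10]$ substitutions/site was
considered and rejected: such points sit orders of magnitude beyond any
data scale and land the ascent in label-switched local basins, which
defeats the purpose of multi-start robustness (checking that searches
from different sensible starting points agree). None of the sweep order,
bounds, tolerance or restart count affects the estimator in a way the
model itself dictates; all are implementation choices, fixed here for
reproducibility.
An all-missing alignment makes every profile flat; the fitter detects
this and reports `flat_profile` rather than pretending to converge.

Coordinate ascent on this likelihood has a well-defined failure mode: if
every branch-length block starts from the same values, states in
different classes are emission-identical, the introgression classes are
initially unused, and the ascent can stall in a no-introgression local
optimum. Scans therefore seed each block before fitting
(`init_gene_blocks()`), balancing two requirements that pull in opposite
directions. Blocks must be *distinct* enough for the first sweep to
separate the classes, but their *pendant* edges must agree across blocks:
a singleton site (one allele carrying a private base) is explained only
by that allele's pendant, so if some block offers a longer pendant than
the congruent block, every rare pendant mutation hands the introgressed
class spurious evidence and the isolation control accumulates false
region calls. The initializer therefore (i) fixes every pendant at a
shared data-driven reference — half the observed JC distance to the
allele's nearest neighbor; (ii) attributes each block's topology to the
parental class giving it the highest coalescent probability and fits the
block's *internal* edges by least squares to the expected pairwise
coalescent path times under that class ($2(\tau+1)$ for species diverging
at $\tau$, scaled by a mutation parameter estimated from the *deepest*
class-1 pairs — the outgroup comparisons when present — whose divergence
is unaffected by introgression, so the scale stays calibrated even when
most of the genome is of introgressive descent); (iii) when the
introgressed class is genuinely shallow relative to class 1, caps its
blocks' internal edges at the mutation scale of one coalescent unit,
since under a shallow hypothesis no in-group internal edge can be deep —
without the cap, deep outgroup distances leak into in-group internal
edges through the least squares and re-open the false-positive channel
via chance homoplasies; and (iv) shrinks cross-species cherry pendants
(factor 0.25 on the pair's distance, never above the reference) —
conditional on a genealogy, its cherry coalesced before the other pairs.
The cherry shrink is what breaks symmetry for three-leaf genealogies,
where every rooted topology unroots to the same star and any
initialization from global average distances would be provably identical
across blocks.

## The synthetic-data generator

`simulate_replicate()` implements a standard validation design for
introgression scans: two in-group populations A and B plus an outgroup, a
structured
coalescent with isolation, and unidirectional migration (B into A forward
in time, i.e. each A lineage moves to B backwards in time) at rate $m$
per lineage during a window $[t_{\mathrm{start}}, t_{\mathrm{end}}]$ that
closes before the A/B split. Time is in coalescent units (one unit = 2N
generations; a pair coalesces at rate 1). Recombination is approximated by
sequentially *independent* segments: breakpoints fall as a Poisson process
with rate $\rho$ per bp and each segment draws its own genealogy — a
deliberate simplification of the ancestral recombination graph that
preserves the ILS-plus-migration signal structure while staying desk-scale
(an `ms`-format reader is provided so an external simulator's output can
be swapped in). Sequences evolve under Jukes–Cantor with branch lengths
converted as substitutions/site $= (\theta/2) \times$ coalescent time.

Defaults are anchored to published house-mouse population-genetic
estimates: in-group divergence 1.5 Mya at 2 generations/year with
$N_e = 50{,}000$ gives $t_{\mathrm{split}} = 30$ units; the outgroup
splits at 45; $\theta = 4.5 \times 10^{-4}$/bp reproduces a mutation rate
near $4.5 \times 10^{-9}$/site/year; $\rho = 2 \times 10^{-4}$/bp gives a
mean segment of 5 kb, consistent with a ~0.5 cM/Mb map over the relevant
time scale; sequences are 100 kb and experiments use 20 replicates per
condition with migration rates $\{0, 0.5, 5\}$ and windows $[0, 0.5]$ or
$[0, 1.5]$. The migration rates and windows themselves have no canonical
literature values; they were fixed once from the anchors above.

Each segment carries a truth label: `TRUE` iff the genealogy contains a
clade of exactly one A lineage plus one or more B lineages whose root
time lies strictly inside the migration window. Such a clade is
impossible under isolation, so the per-site frequency of `TRUE` labels is
a sound lower bound on the migration-affected fraction — and a strict
one, since migrant lineages that coalesce after the window escape it.
What passing the validation experiment shows is therefore bracketing
(inferred percentage at or above the bound, near zero under isolation,
increasing with $m$), not site-exact accuracy. The generator also departs
from real SNP-array data in ways worth keeping in mind: sites are
contiguous rather than array-spaced, there is no genotyping or phasing
error, and segments are independent rather than autocorrelated.

## The validation experiment

`migration_experiment()` runs the full pipeline per replicate — simulate,
seed blocks, fit, decode — and compares the percentage of sites with
introgression posterior above 0.9 against the truth-track bound. Two
pipeline choices matter here:

* **The outgroup is included in the scanned model** (five alleles, 211
  states). With only the four in-group alleles, a migrant lineage that
  captures *both* B lineages forms a shallow clade whose quartet topology
  is congruent, leaving only branch-length signal, which cross-class
  shared blocks cannot express; with the outgroup, the non-migrant deep A
  lineage attaches on the outgroup side and such segments become
  topologically incongruent and detectable.
* **Replicate fits free only $\gamma, s_1, s_2$, two sweeps.** Emissions
  come from the distance-based block seeding; this keeps sixty 211-state
  fits on 100 kb alignments tractable on one CPU. The tighter `"full"`
  preset optimizes every group at $10^{-6}$ tolerance and is the default
  for single-dataset scans.

Problem sizes used by the shipped experiments: 20 replicates x 100 kb per
migration rate for the validation experiment; 5 replicates x 100 kb for
substitution-model recovery; 20 replicates x 10 kb, three restarts each,
for transition-parameter recovery on data generated directly from a known
7-state model.

The recovery experiment's generating model is designed to be
statistically identifiable: its per-topology branch lengths sit at
typical phylogenetic divergences (cherry pendants 0.05, other edges 0.25
substitutions/site) so that the shared blocks — and through them the
switch factors — are determined by 10 kb of data. Profile analysis shows
that at several-fold smaller divergences the joint likelihood in
$(s_1, s_2, \text{blocks})$ is a near-flat ridge: within-class topology
stickiness can then imitate class switching and the maximum-likelihood
switch factors are no longer pinned by the data, so a recovery
experiment there would measure optimizer behavior rather than estimator
behavior.

## Numerical choices and degenerate inputs

* Forward/backward run in linear space with per-site rescaling (emissions
  additionally rescaled per site pattern), exploiting the class structure
  of the transition matrix for an $O(\text{states})$ step; Viterbi runs
  in log space with ties broken toward the lowest state index. Forward
  and backward totals agree to $10^{-8}$ and are tested against
  exhaustive path enumeration.
* For large state-space x alignment products the posterior matrix is
  never materialized; a fused pass returns the introgression track and
  per-state total mass.
* Zero-length species-tree branches are exact (lineage-count probability
  collapses to the identity), so star trees work; an empty population
  contributes nothing.
* Unique-site-pattern compression makes emission cost independent of
  alignment length.
* Alignments with unknown symbols code them to `N` (with a message);
  columns of all-`N` are likelihood-neutral, and long missing stretches
  are reported as a mask rather than interpolated.

## Scope and limitations

Gene-tree probabilities are computed on parental trees only (at most six
alleles, enumeration-based); networks whose lineages cannot be decomposed
into displayed parental trees need the MUL-tree machinery, of which only
the conversion and allele-mapping enumeration are provided
(`network_to_multree()`) — the general-case topology probabilities on
MUL-trees are delegated to prior work and are outside this package's
scope, as is network topology search, GTR+Gamma rate variation, and any
genotyping/phasing of raw array data. Root placement above the MRCA does
not contribute to topology probabilities. The inheritance probabilities
carried on MUL-tree edges are annotations only in the parental-tree
regime.
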