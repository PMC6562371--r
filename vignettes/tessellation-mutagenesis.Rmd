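---
title: "Four-body potentials, computational mutagenesis and fitness prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Four-body potentials, computational mutagenesis and fitness prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`tessmut` implements a coarse-grained, knowledge-based description of
protein structure built on the Delaunay tessellation of the C-alpha trace.
Each residue is reduced to its C-alpha coordinate; the Delaunay tessellation
of those points tiles the convex hull with irregular tetrahedra whose
circumspheres contain no other residue (the empty-circumsphere property).
Each tetrahedron objectively identifies a quadruplet of four spatially
interacting residues. Because convexity occasionally produces long edges
between surface residues that do not physically interact, any tetrahedron
containing an edge longer than a cutoff (12 &Aring; by default) is discarded
before scoring. The filter is expressed on whole simplices rather than bare
edges because only complete tetrahedra carry quadruplet scores; a simplex
with one long edge is not a credible four-body contact.

## The four-body statistical potential

There are $\binom{20+3}{4} = 8855$ unordered residue quadruplets over the
20-letter amino-acid alphabet. Given a training set of structures, the
observed relative frequency $f_{ijkl}$ of each quadruplet is the proportion
of all retained tetrahedra displaying it at their vertices. The chance
expectation is multinomial,

$$p_{ijkl} = \frac{4!}{\prod_n t_n!} \prod_n a_n^{t_n},$$

where $a_n$ is the background frequency of residue type $n$ over **all**
residues of the training structures (not only those appearing in retained
simplices) and $t_n$ counts the occurrences of type $n$ in the quadruplet.
Following the inverted Boltzmann principle, the interaction score is the
log-likelihood ratio

$$s_{ijkl} = \log_{10}\!\frac{f_{ijkl}}{p_{ijkl}}.$$

Two numerical conventions deserve mention:

* **Logarithm base.** Base 10 is the convention of the four-body-potential
  literature this method descends from; the base is a `log_base` argument
  because changing it only rescales every score by a constant factor.
* **Unobserved quadruplets.** When $f = 0$ the logarithm is undefined. The
  package assigns a sentinel score (default 0) and keeps an `observed`
  flag on each row, so total potentials stay finite and the convention is
  visible to the user rather than buried. A quadruplet containing a residue
  type absent from the training background ($p = 0$) is necessarily
  unobserved and receives the same sentinel.

## Computational mutagenesis

The *total potential* of a sequence-structure pair is the sum of the scores
of all retained tetrahedra. The *residue environment score* (RES) at a
position is the partial sum over the tetrahedra incident to it; since every
tetrahedron touches four positions, $\sum_p \mathrm{RES}(p) = 4 \times$
total potential. The ordered RES vector is the 3D-1D potential profile.

A point mutation is modeled by relabeling one vertex: the geometry is left
untouched (no repacking, no minimization), only the residue identity at the
mutated C-alpha changes. The *residual profile* is the component-wise
difference between mutant and native potential profiles; its entries are
*environmental perturbation* (EP) scores. Only tetrahedra incident to the
mutated site change their score, which has two consequences the test suite
verifies against naive full recomputation:

* the EP vector is supported on the mutated position and its tessellation
  neighbors, and
* the *residual score* (mutant total minus native total) equals the EP
  entry at the mutated position exactly, with
  $\sum_p \mathrm{EP}(p) = 4 \times$ residual score.

The *comprehensive mutational profile* (CMP) at a position is the mean
residual score over the 19 possible substitutions, optionally split into
conservative (C) and non-conservative (NC) sub-means using the six
physicochemical classes (A,S,T,G,P), (D,E,N,Q), (R,K,H), (F,Y,W),
(V,L,I,M), (C).

## Feature vectors

Two designs feed the predictive models:

* **Residual-profile design**: position, native and replacement residues,
  the full EP vector (one column per structure position), and the fitness
  output attribute — 170 columns for a 166-residue chain.
* **Local-profile design** (28 columns): the three identity components; the
  residual score; EP scores at the six nearest tessellation neighbors,
  ordered by edge length; the six neighbor residue identities; the six
  sequence separations; mean volume and mean tetrahedrality of the incident
  tetrahedra; tessellation depth class and surface-contact count; secondary
  structure; fitness. Variants at positions with fewer than six neighbors
  are excluded, with the reason recorded.

Design choices that were genuinely open:

* **Depth classes.** Surface/undersurface/buried are names without an
  agreed definition; the package uses the only purely tessellation-derived
  one: *surface* positions touch a boundary triangular face (a face
  belonging to exactly one retained tetrahedron), *undersurface* positions
  are non-surface with at least one surface neighbor, everything else is
  *buried*. The surface-contact count is the number of neighbors classified
  surface.
* **Tetrahedrality.** Computed as
  $T = \sum_{i<j} (\ell_i - \ell_j)^2 / (15\,\bar{\ell}^2)$ over the six
  edge lengths, the standard irregularity measure of the tessellation
  literature (0 for a regular tetrahedron, scale-invariant).
* **Secondary structure.** Assigned from HELIX/SHEET header records mapped
  to three classes (helix, strand, coil); an explicit per-position table
  can override this, since header records and DSSP-style assignments can
  disagree.
* **Sequence separations** are stored signed (neighbor minus mutated
  position); an unsigned difference would discard chain directionality.
* **Median ties.** Dichotomizing fitness at the median assigns values
  exactly at the threshold alternately (starting with `decreased`, in input
  order), which guarantees class sizes differing by at most one without a
  stochastic tie-break.

## Models and evaluation

Classification uses a random forest of 50 trees with
$\lfloor\sqrt{p}\rfloor$ candidate attributes per split; class
probabilities are tree-vote fractions, and all categorical attributes are
one-hot encoded first (the nominal-to-binary convention). Regression uses
ten reduced-error-pruned trees grown on bootstrap resamples, with the
ensemble prediction the mean of the ten; each tree is grown on two thirds
of its resample and pruned along its cost-complexity path against the
held-out third, which emulates reduced-error pruning without claiming
bit-compatibility with any particular toolkit. Before regression, a
correlation-based feature-subset selector (CFS) with merit
$k\,\bar{r}_{cf} / \sqrt{k + k(k-1)\bar{r}_{ff}}$ runs a best-first forward
search that stops after five non-improving expansions; correlations are
symmetrical uncertainties computed after equal-frequency discretization
into ten bins.

Evaluation follows the standard protocol: leave-one-out or 10-fold
cross-validation (unstratified by default, stratification available), with
sensitivity, specificity, precision, balanced accuracy (BAR), Matthews
correlation (MCC) and rank-statistic AUC for classification, and Pearson
r / RMSE (plus median-thresholded classification metrics) for regression.
Metrics with zero denominators are reported as `NA`, never coerced to 0.
Statistical significance is assessed by label-permutation controls: the
output attribute is shuffled, the whole cross-validation repeated, and the
empirical p-value computed as $(1 + \#\{\text{permuted} \ge
\text{observed}\})/(n+1)$. All randomness — fold assignment, bootstrap
resamples, subset draws, permutations, tree seeds — flows from a single
integer seed recorded in every report.

# The synthetic generator

Real inputs to this workflow are a corpus of experimental structures and a
deep-mutational-scanning fitness table; neither is required for testing.
The generator emulates both:

* **Chains** are collapsed self-avoiding random walks: successive C-alpha
  sites 3.8 &Aring; apart (the canonical virtual-bond length), non-successive
  pairs kept beyond 3.6 &Aring; (a clash distance just under the bond
  length), each step biased toward the running centroid with a compactness
  weight of 0.5. These defaults make 30-60-residue chains globular enough
  that the 12 &Aring;-filtered tessellation covers every position, which the
  tests pin as a property.
* **Fitness** is planted as a monotone function of the residual score plus
  Gaussian noise: `fitness = residual_score + N(0, sd)`. The direction is
  increasing — structurally detrimental substitutions (negative residual
  scores) get lower fitness — matching the direction of the empirical
  structure-function relationship this method exploits. The default noise
  (sd 0.75, about half the typical residual-score spread) was calibrated
  once so that the planted fitness-residual correlation (≈0.84) and the
  resulting 10-fold CV balanced accuracy (≈0.80) sit at the discrimination
  level the method attains on real deep-mutational-scanning data, rather
  than at an unrealistically clean optimum.

What passing tests on this generator do **not** show: chains have no
secondary-structure realism (labels are random), no side chains, and
residue composition is uniform by default; the planted fitness has additive
Gaussian noise only, whereas real fitness landscapes contain epistatic and
position-specific effects. Recovery of the planted signal demonstrates that
the pipeline is wired correctly end to end, not that the potential trained
on ten synthetic chains is a good energy function.

# Problem sizes and reproducibility

The test suite and the acceptance script run the full pipeline at desk
scale: ten training chains of 30-60 residues, a 50-residue target chain
(950 saturation variants), 10-fold cross-validation, 100 label
permutations for the classification control and 5 for the regression
control on a 300-variant subsample, and learning-curve endpoints at 200
and 950 variants with five subsets each. These sizes keep a complete run
in the low minutes on a single CPU while leaving every statistical
property comfortably resolvable. `scripts/acceptance.R` recomputes all
headline quantities from scratch under a caller-supplied seed.

The tessellation backend is an incremental Bowyer-Watson construction with
an infinite vertex, written for this package because no Delaunay-3D
provider was available as a dependency; it is validated in the tests
against a brute-force empty-circumsphere oracle on small instances.
Predicates are double precision with relative-error filters; exactly
cospherical point sets (measure zero for experimental coordinates, absent
from the generator's output) may be triangulated in any consistent way, so
simplex counts on pathological inputs can differ from other backends by
the degenerate cells. Duplicate, collinear and coplanar inputs are
rejected with descriptive errors.

# Known limitations

* Mutations are vertex relabelings; no coordinate relaxation is modeled.
* Single-residue variants only; composing double mutants is out of scope.
* First NMR model only; no insertion codes, no mmCIF, no multi-chain
  complexes.
* The depth and secondary-structure attributes depend on the documented
  conventions above; alternative definitions can shift stratified
  performance breakdowns.
* Potentials trained on small synthetic corpora leave most of the 8855
  quadruplets unobserved; the sentinel convention makes this explicit, but
  serious applications should train on a large diverse structure set or
  load a published potential table via `read_potential()`.
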