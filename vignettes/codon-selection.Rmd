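---
title: "Detecting ortholog families and lineage-specific selection with cogselect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting ortholog families and lineage-specific selection with cogselect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogselect)
```

## What the package does

`cogselect` chains together the classic comparative-genomics workflow for
asking whether a gene family evolves under different selective pressures in
different lineages:

1. **Ortholog family detection** across several genomes by the
   reciprocal-best-hit (COG) construction: all-against-all protein
   similarity, collapsing of obvious within-genome paralogs, cross-genome
   best hits (BeTs), and clusters formed by merging three-genome best-hit
   triangles that share an edge.
2. **Phylogeny estimation** for the family by neighbor joining on pairwise
   maximum-likelihood JTT protein distances with pairwise deletion of
   gaps, plus nonparametric bootstrap supports.
3. **Codon-model selection analysis** under the Goldman–Yang (GY94) codon
   substitution model: branch-specific $\omega = d_N/d_S$ ratios compared
   by likelihood ratio tests (LRTs), the branch-site model A test of
   positive selection on a chosen foreground lineage, per-site posterior
   probabilities of selection (naive and Bayes empirical Bayes), and
   pairwise $d_N/d_S$ estimation with a $d_S > 2$ saturation filter.
4. **A synthetic-data generator** that produces multi-genome gene sets and
   codon alignments with known ground truth, so that every stage of the
   pipeline can be validated end to end.

## The substitution model

The GY94 model works on the 61 sense codons of the universal code. The
instantaneous rate from codon $i$ to codon $j$ is

$$
q_{ij} \;=\;
\begin{cases}
0 & \text{more than one position differs,}\\
\pi_j & \text{synonymous transversion,}\\
\kappa \pi_j & \text{synonymous transition,}\\
\omega \pi_j & \text{nonsynonymous transversion,}\\
\omega \kappa \pi_j & \text{nonsynonymous transition,}
\end{cases}
$$

with $\kappa$ the transition/transversion rate ratio, $\omega$ the
nonsynonymous/synonymous rate ratio, and $\pi_j$ the equilibrium frequency
of the target codon. Equilibrium frequencies are computed from the data,
either as `F3x4` (products of the observed nucleotide frequencies at the
three codon positions, the default) or `F61` (empirical codon
proportions); both receive a small pseudocount so every sense codon has
strictly positive frequency. The matrix is time-reversible; likelihoods
are computed by Felsenstein pruning over compressed site patterns, with
transition probabilities $P(t) = e^{Qt}$ obtained from the
eigendecomposition of the $\pi$-symmetrized generator.

### Rate scaling conventions

Two scaling conventions coexist, deliberately:

* **Branch models** (one $\omega$ per branch class, a single class of
  sites): each class's generator is normalized to one expected
  substitution per codon per unit time at stationarity, so every branch
  length is in expected substitutions/codon under its own $\omega$. This
  is the convention under which fitted branch lengths are reported.
* **Branch-site model A** (four site classes): the classes share a
  *common* mutation-rate scale — the proportion-weighted average rate of
  the background mixture. Sites with a higher $\omega$ therefore evolve
  proportionally faster, which is where much of the detectable signal of
  positive selection lives. Normalizing each class separately would
  equalize total rates across classes and reduce the model to a pure
  composition contrast; during development this variant showed almost no
  power against planted selection, which is why the shared scale is used.
  The simulator applies the same convention to multi-class regimes, and
  the NEB/BEB site posteriors freeze the scale at the maximum-likelihood
  estimates so the prior grid factorizes over $(\omega_0, \omega_2)$.

### Branch-site model A and its test

Model A has four site classes: conserved sites with ratio
$\omega_0 \in (0,1)$ everywhere; neutral sites with $\omega_1 = 1$
everywhere; and two selected classes in which background branches keep
$\omega_0$ (class 2a) or $1$ (class 2b) while foreground branches switch
to $\omega_2 \ge 1$. The proportions obey
$p_{2a} : p_{2b} = p_0 : p_1$. The null model fixes $\omega_2 = 1$; the
LRT statistic $2\Delta\ell$ is referred to $\chi^2_1$, the standard,
mildly conservative choice for this boundary problem. $\omega_2$ is
bounded above at 999 during optimization, and boundary estimates are
reported as 999. For nested branch-specific models the degrees of freedom
equal the difference in the number of $\omega$ classes.

### dN/dS decomposition and the saturation filter

For a fitted pairwise model $(\hat t, \hat\kappa, \hat\omega)$ the
divergence $\hat t$ (substitutions/codon) is split into per-site rates:
expected synonymous and nonsynonymous substitution counts are taken from
the fitted generator, while the synonymous/nonsynonymous *site fractions*
come from the same mutation process with $\omega = 1$. Under this
convention $d_N/d_S = \hat\omega$ holds as an algebraic identity, which
the test suite asserts to $10^{-8}$. An alternative "physical"
equal-weight site counting is available behind a flag; it does not
preserve the identity and is provided for comparison only. Pairs with
$d_S > 2$ are flagged `retained = FALSE` — synonymous distances beyond
that level are saturated and unreliable, and downstream summaries discard
them.

### Bayes empirical Bayes site posteriors

NEB applies Bayes' rule across the four site classes at the MLEs. BEB
additionally averages over a discrete uniform prior grid on the mixture
parameters: a triangle grid on $(p_0, p_1)$ and ten levels each for
$\omega_0 \in (0,1)$ and $\omega_2 \in (1,11)$, with $\kappa$ and branch
lengths held at their MLEs; each grid point is weighted by its whole-data
likelihood. Reported per site is the posterior probability of membership
in classes 2a or 2b — the probability the site evolved under positive
selection on the foreground lineage.

## Ortholog detection choices

* The similarity engine is local Smith–Waterman alignment with BLOSUM62
  and affine gaps (open 11, extend 1). Only the *ranking* of scores
  matters for best-hit detection — the COG construction is built on the
  consistency of genome-specific best hits rather than absolute
  similarity — so raw alignment scores are used without bit-score
  calibration.
* The default score threshold is the 99th percentile of a null
  distribution obtained by scoring residue-shuffled input proteins
  against each other. It prunes background pairs; it is not load-bearing
  for correctness, because best hits are rank-based.
* "Obvious paralogs" are collapsed by mutual within-genome dominance: two
  same-genome genes are grouped when each scores higher with the other
  than with any foreign gene. Each group is represented by its member
  with the best cross-genome score (ties broken lexicographically).
* Clusters are formed from best-hit triangles (which necessarily span
  three genomes, since every BeT edge crosses genomes) merged when they
  share an *edge*. Triangles sharing only a vertex stay separate, the
  conservative reading of the classic construction.
* Manual case-by-case curation is replaced by a per-cluster diagnostic
  table (genome coverage, within-cluster score range); nothing is deleted
  automatically.
* Best-hit ties are broken by lexicographic gene identifier, making every
  stage deterministic.

## Tree estimation choices

Pairwise protein distances are maximum-likelihood distances under the JTT
amino-acid model, computed with `phangorn::dist.ml`. Gaps and ambiguity
codes enter the likelihood as fully ambiguous states, whose contribution
to a two-sequence likelihood is constant in the divergence time — exactly
the pairwise-deletion treatment. Distances are capped at 10
substitutions/site (with a warning) to keep saturated pairs finite, and
each pair must share at least one informative site. Neighbor joining is
Saitou–Nei (via `ape::nj`); negative branch lengths, which NJ can produce
on non-additive inputs, are clamped to zero. Bootstrap supports resample
alignment columns with replacement and report, for each internal node of
the original tree, the fraction of replicate trees containing that split
(default 1000 replicates). Trees are written in Newick with PAML-style
`#k` branch-class tags and supports as percentage node labels.

The package does not root trees or infer which lineage to test: branch
classes and foreground sets are user annotations, supplied as tip sets
(`labelClade()`) or `#k` tags in Newick.

## The synthetic-data generator

`simulateGenomes()` emulates a set of proteomes that contain one (or a
few) target gene families plus unrelated decoy families:

* Each family starts from an independent random root coding sequence over
  the sense codons and evolves down a balanced species tree (default
  branch length 0.2 substitutions/codon). Equal, moderate branch lengths
  keep within-family identity realistically high (roughly the divergence
  of a conserved plant gene family) while decoys remain at background
  similarity; near-saturating branch lengths would contradict the premise
  of a recognizable family.
* Duplications are Poisson events and losses exponential-survival events
  per branch, both applied at the start of a branch, after which every
  surviving lineage evolves independently along it. The event log replays
  to the exact member set. Default rates are zero; the non-zero defaults
  used in tests (0.5–1.5 per unit branch length) were chosen once to
  exercise multi-copy and missing-genome cases, not to match any
  organism's empirical rates, which the source analysis does not provide.
* Simulation is indel-free, so family alignments are exact by
  construction — the multiple-alignment step of a real analysis (an
  external codon-aware aligner) is out of scope, and `backmapCodons()` /
  `stripGapColumns()` consume its output instead. Consequently, passing
  tests say nothing about alignment error, a real and known failure mode
  of selection analyses on real data.
* One root seed determines everything; per-family seeds are derived by
  fixed arithmetic (`seed * 1000003 + index * 7919 mod 2^31 - 1`), so
  runs are byte-reproducible.

What the generator does **not** emulate: indels and alignment
uncertainty, codon usage bias beyond the chosen equilibrium frequencies,
rate variation outside the modeled site classes, gene conversion,
and genome-scale proteome content (decoys are a stand-in for "everything
else in the proteome").

## Numerical choices

* Optimization is bounded quasi-Newton (L-BFGS-B) on log- or
  logit-transformed parameters with jittered multi-start (default 3
  starts for branch models, 2 for model A); the reported fit is the best
  start, and the monotone best-so-far trace is kept in the convergence
  diagnostics. Branch lengths are bounded to $[10^{-6}, 50]$,
  $\kappa \in [0.05, 100]$, $\omega \in [10^{-4}, 999]$.
* The alternative branch-site fit is started from the null fit's
  $\omega_0$ and $\kappa$ but with the selected-class proportion pulled
  away from the $p_2 = 0$ boundary, where the likelihood is flat in
  $\omega_2$ and a gradient method cannot move.
* Branch-site fits can hold branch lengths at one-ratio (M0) estimates
  and $\kappa$ at the M0 value — the standard speed mode for simulation
  studies; both full and fixed modes are exposed.
* Site patterns are compressed with weights; partial likelihoods are
  rescaled per node only if the root likelihood underflows, which for the
  tree sizes targeted here is rare.
* Likelihood convergence tolerance is $\sim 10^{-9}$ relative
  (`factr = 1e7`); simulation studies in the test suite use a looser
  `1e8` for speed.

## Validation performed by the test suite

The suite validates each stage against independent oracles: pruning
likelihoods against explicit enumeration of ancestral states on 3–4 taxon
trees (to $10^{-10}$); transition matrices against a scaling-and-squaring
Taylor exponential; COG formation against exhaustive triangle enumeration
with union-find merging on hundreds of random best-hit graphs; NJ against
path-length additivity on random additive matrices; and the
simulator against zero-rate, stationarity and monotonicity properties.
Statistical behavior is checked by simulation at deliberately moderate
problem sizes — two-class $\omega$ recovery (500 codons, 8 taxa, 20
replicates), branch-site type-I error (200 replicates of 100 codons on a
4-taxon tree, rejection rate compared with the nominal 5% plus three
binomial standard errors; the $\chi^2_1$ reference makes the test
conservative, and most null statistics are exactly 0) and power against
$\omega_2 = 8$ with ~10% selected sites (500 codons, 20 replicates,
expected ≥ 80%). These sizes are the package's chosen study conditions
for a desk-scale validation; estimates at these sizes carry visible Monte
Carlo noise, which the acceptance thresholds account for.

## Known limitations

* No multiple alignment: families with indels require an external
  protein alignment to back-map.
* The branch-site test's $\chi^2_1$ reference is conservative at the
  boundary; power figures here should be read as lower bounds for the
  mixture-reference variant.
* BEB integrates over the mixture prior only; $\kappa$ and branch lengths
  stay at their MLEs, so posterior uncertainty in those is ignored (as in
  the original construction).
* The COG procedure assumes proteome-scale inputs are reduced to a
  manageable gene set beforehand; no E-value statistics or profile
  searches are provided.
* Bayesian tree inference is intentionally absent; the NJ arm is the
  supported path.
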