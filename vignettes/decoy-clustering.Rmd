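---
title: "Exact threshold clustering of protein decoys: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact threshold clustering of protein decoys: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Ab initio protein structure prediction produces large ensembles of candidate
conformations ("decoys") of one protein. A standard model-selection criterion
is density in conformation space: fix a threshold distance $d$ and report the
decoy with the most neighbors within C$_\alpha$ RMSD $d$, remove that decoy
and its neighbors, and repeat to obtain a ranking. Computing this naively
costs all $\binom{n}{2}$ pairwise RMSDs, each an optimal-superposition
problem, which becomes the bottleneck as $n$ reaches tens of thousands.

`decoyclust` computes the same ranking — element for element identical to the
brute-force computation — while avoiding most exact RMSD evaluations.

## The metric and its bounds

For equal-length C$_\alpha$ traces $S_1, S_2$ with points $s_{i,j}$, the
distance is

$$\mathrm{RMSD}(S_1,S_2) \;=\; \min_{R,\,T}\;
\sqrt{\tfrac1n \sum_{j=1}^n \lVert R\,s_{1,j} + T - s_{2,j}\rVert^2}$$

minimized over proper rotations $R$ and translations $T$. The minimizing
translation superposes the centroids; the rotation is the Kabsch SVD solution
with a determinant sign correction that excludes reflections. This RMSD is a
metric on equal-length traces, so the triangle inequality holds — the fact
every screening step below relies on.

Three cheap bounds screen a pair $(X, Y)$ before any superposition:

* **Reference bounds.** For reference decoys $O_1,\dots,O_m$ with
  precomputed distances, $|d(X,O_k) - d(Y,O_k)| \le d(X,Y) \le d(X,O_k) +
  d(Y,O_k)$. We default to $m = 3$ references chosen by a deterministic
  max-min spread (first decoy; farthest from it; farthest from that one):
  spread references make the lower bounds tight more often. The count and
  rule are free parameters of `precompute_metrics()`.
* **Signature lower bound.** The signature of a trace is the vector
  $v_{x,i} = \lVert s_{x,i} - c_x \rVert$ of distances to the centroid, kept
  in residue order. Since optimal superposition makes centroids coincide,
  each per-residue deviation is at least $|v_{1,k} - v_{2,k}|$, hence
  $\sqrt{\tfrac1n\sum_k (v_{1,k}-v_{2,k})^2} \le \mathrm{RMSD}$. The exact
  printed form of this distance is reconstructed from the bound's proof (the
  root-mean normalization is the only form the proof supports); it is
  implemented as `signature_distance()` and documented as such.
* **rRMSD upper bound.** Orient every decoy once onto a fixed anchor (the
  first reference); the plain Euclidean RMS deviation between two oriented
  coordinate sets needs no further superposition and upper-bounds the true
  RMSD, with equality when one of the pair is the anchor. Orientation is
  linear in $n$ and precomputed; the per-pair rRMSD is evaluated lazily —
  materializing all pairs would itself be quadratic.

Per pair the cascade is fixed: reference upper bounds, rRMSD (accepts), then
reference lower bounds, signature distance (rejects), then the exact RMSD.
A single fixed order is used at every threshold; adapting the order to $d$
would only change speed, never output.

## Auxiliary grouping

Before neighbor search the decoys are partitioned by a sequential leader
algorithm with radius $r = d/2$: scan decoys in input order, assign each to
the first existing center within exact RMSD $r$ (centers scanned in creation
order), else create a new center, recording every member-to-center distance.
$r = d/2$ is the unique radius making a decoy's own group wholly acceptable:
two members within $r$ of the same center are within $2r = d$ of each other.
The radius factor is exposed (`radius_factor`); above 0.5 the own-group
shortcut is disabled and correctness is preserved. Which qualifying center
wins when several do is not fixed by the construction; first-in-creation-order
makes the partition deterministic and oracle-comparable.

For a query decoy $A$ and each group with center $C$ the five cases are
checked in order: (1) $A$'s own group (radius factor $\le 0.5$ only);
(2) $d(A,C) + r \le d$ — accept the group; (3) $d(A,C) > d + r$ — reject the
group; per member $X$, (4) $d(A,C) + d(C,X) \le d$ — accept; (5)
$|d(A,C) - d(C,X)| > d$ — reject. Cases 2 and 3 are first tried with the
cheap bounds of $d(A,C)$ and only then with its exact value; members
surviving cases 4–5 go through the per-pair cascade. Every branch decides a
pair exactly as the brute-force comparison would, which is why the output is
bit-identical — the package's central invariant, asserted across ensembles,
thresholds and ablations in the test suite.

## Outlier filtering

Decoys far from everything cannot affect the top clusters. Assuming every
high-ranking decoy has at least 10% of the set within $d$, a decoy within
$d$ of such a decoy is within $2d$ of each of that decoy's neighbors, and
the probability that a random sample of $n$ decoys misses all of them is
$0.9^n$ — below $10^{-4}$ at the default sample size 100. The filter keeps a
decoy iff it is within $2d$ of some sampled decoy. One boundary case is
resolved here as a design choice: when the sample covers the whole set
(inputs of $\le$ 100 decoys), "every sampled decoy keeps itself" would make
the filter vacuous, so self-matches are excluded and a decoy is removed iff
it is farther than $2d$ from every *other* decoy. Filtered decoys are
reported separately and never re-enter the counts.

## Threshold discovery

Two automatic rules, both estimated from sampled pairwise distances (10
rounds of 100 decoys by default):

* **Percentile** (default): $d$ = the $x$-percentile of pairwise distances,
  $x = \min\{100\,n^{-1/4}, 10\}$ (10 at $n = 10^4$, 5 at $n = 1.6\times
  10^5$). Each round takes the percentile of its within-sample distances
  (linear interpolation between order statistics); rounds are combined by
  the median, a robust choice the sampling description leaves open. An exact
  full-matrix variant exists for validation (`exact_percentile_threshold`).
* **Mode-based**: $d = c f + b$ with $f$ the most frequent sampled distance
  (Freedman–Diaconis histogram, densest-bin center; degenerate spreads fall
  back to the median), $b$ the minimum sampled distance. The coefficient $c$
  is not recoverable from the method's description; the default $2/3$ is a
  documented guess, configurable, and the method itself is non-default.

## Synthetic decoy ensembles

`make_ensemble()` states the world the tests run in: a few center backbones
(self-avoiding 3.8 Å-step random walks, 30 residues by default) pairwise
farther than `separation` = 8 Å; per cluster, members perturbed by isotropic
Gaussian noise (σ = 0.5 Å default, giving member–center RMSD ≈ σ√3 after
superposition); outliers as independent walks kept 8 Å from centers and 4 Å
(= `separation`/2) from each other — mutual 8 Å among tens of independent
30-residue walks is unreachable by rejection sampling, and outliers only
need to stay unclustered at the thresholds in use. Every decoy receives a
random rigid transform, so any pose dependence in the pipeline would surface
as a test failure. Labels live in a sidecar JSON, never in PDB fields.

What a green test does *not* establish: these ensembles have isotropic,
uncorrelated noise, no Ramachandran statistics, no side chains, and cluster
populations far more balanced than real decoy sets; they validate exactness
and recovery logic, not predictive performance on real predictions.

## Numerical choices and degenerate inputs

* "Zero" RMSD tolerance is $10^{-9}$ Å; rotation properness is checked to
  the same tolerance. Rank-deficient (e.g. collinear) point sets are handled
  by the SVD without special-casing.
* Traces need $\ge 3$ residues (superposition underdetermined below that);
  sets need equal lengths — mismatches are fatal, naming both decoys.
* PDB reading: fixed-width v3.3 columns with a whitespace-split fallback;
  first model, first chain (stop at TER), altloc blank or A. Multi-chain
  and multi-model handling is a package convention, not part of the method.
* Ties in cluster extraction break toward the lowest input index;
  `which.max` semantics make this explicit and reproducible.
* All sampling (threshold, filter) draws from the session RNG; the pipeline
  seeds once at entry, so a seed plus an input yields a byte-identical
  report, including between strategies-on and brute-force runs.

## Limitations

* The neighbor-set representation is worst-case quadratic in memory; the
  `best_only` mode keeps only counts (linear) and reproduces round 1.
* Per-query work still visits every group; there is no sublinear index, and
  none is possible without approximating (RMSD space is not a vector space).
* Unequal-length decoys are out of scope: no sequence alignment is
  attempted before superposition.
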