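---
title: "Minimal cycle representatives for persistent homology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimal cycle representatives for persistent homology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optcycle)
```

## The problem

Persistent homology summarizes the multi-scale topology of a point cloud or
dissimilarity matrix as a *barcode*: a multiset of half-open intervals
$[b, d)$, each witnessing a one-dimensional hole that appears at scale $b$
and fills in at scale $d$.  The matrix reduction that produces the barcode
also produces a *cycle representative* for each interval -- a formal sum of
edges with rational coefficients whose class generates the corresponding
homology -- but these raw representatives are an accident of the elimination
order: they are often long, winding, and poorly localized around the hole
they witness.  For interpretation (which edges of a biological network close
a loop? which points of a cloud ring a cavity?) one wants the *smallest*
representative, measured by a loss function of scientific interest.

`optcycle` computes dimension-one persistent homology of Vietoris-Rips (VR)
filtrations with exact rational coefficients and then minimizes each
representative by linear or mixed-integer programming, under four losses:

* **edge-uniform** -- the number of edges, $\|x\|_0$;
* **edge-length** -- the total length $\sum_{\sigma} \mathrm{Length}(\sigma)$
  over the support;
* **triangle-uniform** -- the number of triangles in a bounding 2-chain (a
  *persistent volume*) whose boundary replaces the representative;
* **triangle-area** -- the Heron area of that bounding chain.

Because $\ell_0$ minimization is NP-hard, the programs minimize the weighted
$\ell_1$ norm $\|Wx\|_1$ instead, splitting $x = x^+ - x^-$ with
$x^\pm \ge 0$.  Empirically almost all optima have coefficients in
$\{-1, 0, 1\}$, where $\ell_1$ and $\ell_0$ coincide, so the tractable
relaxation usually delivers the interpretable answer; the package's
coefficient-profiling tools quantify exactly how often.

## Filtrations and persistence over the rationals

`vietoris_rips()` builds the filtration: a simplex enters at the maximum
pairwise dissimilarity among its vertices, vertices at 0.  Within each
dimension, simplices are ordered by (birth, lexicographic vertex tuple); the
interleaved order by (birth, dimension, tuple) is a simplex-wise refinement
in which every face precedes every coface.  Any filtration-preserving total
order would do for correctness; this particular tie-break is deterministic
and reproducible, and the test suite verifies that the barcode is invariant
under relabeling-induced permutations of tied simplices.  The default scale
cap is the largest pairwise dissimilarity, at which the 2-skeleton is
complete and every dimension-one class has died -- so every bar is finite
and every bar can be optimized by all four losses.

`persistent_homology()` reduces the boundary matrices by the standard
left-to-right column algorithm, $R = DV$, entirely over exact rationals
(64-bit numerator/denominator pairs with 128-bit intermediates; overflow is
a hard error rather than a silent wrap, and never occurred on any corpus in
the test suite).  Exactness matters here for two reasons: pivot decisions in
floating point can corrupt the pairing, and the headline coefficient
statistics -- is a representative's coefficient $\tfrac12$ or merely close
to it? -- are meaningless under rounding.  The $V$ matrix is not
materialized during reduction; each column keeps its operation log, and the
columns actually needed (essential representatives, original bounding
volumes) are expanded from the log on demand.

Representative conventions: a finite bar paired $(\sigma, \tau)$ takes the
reduced column of $\tau$ (a cycle born exactly at $\mathrm{Birth}(\sigma)$)
as its initial representative, and the corresponding $V$ column as its
*original bounding volume* -- the unoptimized 2-chain whose boundary it is,
which serves as the baseline for the triangle-loss reduction ratios.
Essential bars take the kernel columns of the dimension-one reduction.
Zero-length intervals (birth equal to death) witness no feature at any
parameter and are discarded before optimization.  Duplicate intervals are
kept as distinct basis elements; the replacement step below is what keeps
them independent.

## The optimization programs

**Edge loss over a persistent basis.**  For the $j$-th bar, with
$x_{\mathrm{Orig}}$ its current representative, the program is

$$\min \|W x\|_1 \quad \text{s.t.} \quad x = x_{\mathrm{Orig}} + \partial_2 q + A p,$$

where $q$ ranges over the triangles born by $\mathrm{Birth}(x_{\mathrm{Orig}})$
and $p$ over the *other* basis cycles whose birth and death both precede (or
equal) the bar's own.  Adding such cycles can change the homology class of
$x$, but not the lifespan, and the output set remains a persistent homology
cycle basis.  The loop in `optimize_persistent_basis()` *replaces* each
representative before optimizing the next; without replacement the optimized
set can, in rare duplicate-interval situations, fail to be a basis
(`replacement = FALSE` is available to study exactly this).  Two index-set
conventions are worth stating: birth/death comparisons defining the eligible
set use filtration *values* (with ties included), and essential bars treat
$\infty \le \infty$ as true, so an essential bar may draw on all
earlier-born cycles.

The triangle block $\partial_2$ is restricted to the column basis
$\hat{\mathcal{R}} = \{\tau : R[, \tau] \neq 0\}$, which leaves the feasible
set for $x$ unchanged (the nonzero reduced columns of a prefix span the same
boundary space as the full prefix) while cutting the variable count by an
order of magnitude; the test suite asserts objective equality against the
unaccelerated program on every fixture.

**Edge loss over a filtered basis.**  `optimize_filtered_basis()` solves the
per-step variant: corrections come from a basis of the boundary space just
before the bar's birth edge enters, extended by the cycles alive at that
step, both read off the $R = DV$ matrices.  This program is less
constrained: births are preserved but the optimum may outlive its bar (the
`fcb_extends_death` fixture shows an optimized $[1,2)$ class becoming
$[1,\infty)$), so the output is a filtered cycle basis, not necessarily a
persistent one.  Its optima consequently lower-bound the persistent-basis
optima, which is also asserted on fixtures.

**Triangle loss (persistent volumes).**  For a finite bar with pair
$(\sigma, \tau)$, `optimize_volume_basis()` searches over 2-chains $v$
supported on the triangles born in the bar's closed window and no later than
$\tau$ in the refined order, with $v_\tau = 1$ pinned and $(\partial v)$
constrained to vanish on every edge after $\sigma$.  The remaining defining
condition, $(\partial v)_\sigma \neq 0$, is not expressible as a linear
constraint; it is instead verified on the solution, which is sound because a
persistent volume always exists for a finite bar -- a zero coefficient there
would signal a pairing bug, and the package treats it as a hard error.  The
boundary of the solved volume has exactly the bar's lifespan (also
re-verified by exact reduction when `verify_lifespans = TRUE`), and swapping
it in, while keeping the $R = DV$ representatives of essential bars, again
yields a persistent homology cycle basis.  One printed-convention ambiguity
deserves a note: the window definition reads "$\sigma \le \sigma'$" for the
constrained rows, yet $\sigma$ itself must be exempt for the program to be
feasible at all; the package uses the strict exclusion, resolving
equal-birth comparisons by order position -- precisely what the simplex-wise
refinement exists to make well-defined.

Two assembly strategies are provided (`build_mode`): slice a precomputed
full $\partial_2$, or rebuild the window columns per bar.  They produce
identical programs -- asserted on fixtures -- and differ only in their
speed/memory trade-off; a `var_cap` guard (default $2 \times 10^7$
variables) skips pathologically wide windows with a warning rather than
exhausting memory.

**Solver backend.**  Programs are solved by HiGHS, reached through SciPy in
a persistent worker process over a localhost socket (one interpreter start
per session; a binary wire format keeps the per-program overhead near a
millisecond).  Statuses are reported faithfully -- infeasibility or solver
failure is surfaced, never silently patched.  Solutions are lifted back to
exact rationals: values within the integrality tolerance ($10^{-7}$,
matching solver feasibility tolerances of $10^{-6}$-$10^{-9}$) snap to
integers, anything else to a continued-fraction convergent.  The LP-method
hint (`optcycle.lp_method`) selects simplex or interior-point-with-crossover;
uniform-weighted programs are highly degenerate and markedly faster under
the latter, with identical optima (asserted in the tests).  When two
co-optimal vertices exist the solver's choice is accepted as-is, so
statistics that compare solution *vectors* (rather than costs) are
solver-dependent and labeled as such.

## Losses, eligibility, and statistics

`edge_losses()`, `triangle_losses()` and `surveyor_area()` evaluate the loss
functions on arbitrary chains.  Heron's formula computes triangle areas from
the three edge dissimilarities; for non-metric inputs (the Erdős-Rényi
model) a violated triangle inequality clamps the radicand to zero with a
logged count, and area weighting is simply not meaningful there.  The
Surveyor (shoelace) area is computed only when the cloud is planar, the
support is a single graph-theoretic cycle, and no two closed segments cross
except at shared endpoints; ineligibility is a reported value with a reason
code, not an error, and the segment tests use orientation predicates with a
$10^{-12}$ guard so eligibility is deterministic.

`count_loops()` (the nullity of the boundary matrix restricted to the
support, computed as $E - V + C$), `coefficient_profile()`,
`reduction_ratio()`, `lp_mip_agreement()` and `duplicate_bars()` provide the
descriptive statistics used to profile optimized corpora.  `brute_force_l0()`
is the package's independent certificate: on windows of at most a few dozen
candidate chains it enumerates $\{-1, 0, 1\}$-supported chains in increasing
support size and confirms, by exact linear algebra only, that no feasible
chain beats the LP optimum.

## The synthetic corpora

`sample_cloud()` draws 100-point clouds with i.i.d. coordinates in ambient
dimensions 2 through 10 from four families -- standard normal, gamma,
logistic and exponential -- and `sample_er_dissimilarity()` draws symmetric
$100 \times 100$ matrices with off-diagonal entries i.i.d. uniform on
$[0, 1]$, a non-geometric null model whose clique complexes are deliberately
free of triangle-inequality structure.  Distribution location and scale are
conventions, not parameters of interest: the VR bar count is invariant to
rescaling a cloud (asserted in the tests), so the normal, logistic and
exponential counts are comparable across any choice; the gamma family's
shape genuinely changes the answer, and its defaults (shape 2, scale 1) are
a fixed convention of this package rather than a reproducible target.
Per-replicate seeds derive from the corpus seed by a counter so any single
input regenerates in isolation.

These corpora emulate the *sampling* structure of real data -- geometric
clouds with genuine cavities at many scales, and a combinatorial null model
-- but not its correlations: real point clouds concentrate on
lower-dimensional structures, and real dissimilarity data (genomic Hamming
distances, network weights) carry block and cluster structure that i.i.d.
entries cannot.  Passing corpus-level checks therefore validates the
machinery and its statistical profile under the stated models, not any claim
about a particular scientific dataset; real data enter the same pipeline as
plain CSV clouds or dissimilarity matrices.

## Problem sizes and numerical choices

The package's own reference computations use: 10 replicates per dimension
and family (90 filtrations per family, 100 Erdős-Rényi matrices) for the
interval counts, and a reduced corpus of 2 replicates per dimension for the
optimization aggregates, where every bar is optimized under the
edge-uniform, edge-length (LP and MIP) and triangle-uniform programs -- a
few thousand linear programs per run.  The test suite exercises the same
code paths at smaller sizes (clouds of 8-30 points for exact oracles, the
reduced corpora for statistics).

Numerical conventions collected in one place: exact rational arithmetic
everywhere in persistence and in all post-hoc verification; solver doubles
only inside the LP/MIP; integrality tolerance $10^{-7}$ applied after
rounding, shared by the $\{-1, 0, 1\}$ membership audits; duplicate-interval
grouping by exact value equality; lexicographic-then-dimension tie-breaks;
zero-length bars dropped; original-loss-zero ratios reported as missing
rather than infinite.

## Known limitations

Only dimension-one homology is exercised and reported, though the
construction and reduction are generic in the dimension.  The $\ell_1$
programs do not certify $\ell_0$ optimality over all integer chains -- the
brute-force certificate covers $\{-1,0,1\}$ coefficients on small windows
only, and total unimodularity of boundary matrices (which would make LP and
MIP agree always) fails in general, notably on Erdős-Rényi complexes where
non-orientable subcomplexes produce coefficients outside $\{-1,0,1\}$ for a
few percent of representatives.  Periodic-boundary metrics, alpha/Čech
complexes and sparsified Rips constructions are out of scope; restricted
neighborhood accelerations for the volume programs are not implemented.
Wall-clock comparisons between solver brands are deliberately not part of
the package's claims.
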