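---
title: "Clipping trajectory time series that match a SAXS profile: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clipping trajectory time series that match a SAXS profile: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sasclip)
```

## The problem

A solution SAXS measurement of a flexible multi-domain protein reports a
single ensemble-averaged intensity curve $I_\mathrm{exp}(Q)$, while a
molecular-dynamics trajectory of the same molecule provides an ordered
sequence of conformations. Most ensemble-fitting approaches select or
reweight *individual* snapshots to match the measurement, which discards
the dynamics connecting them. This package instead extracts the longest
*contiguous* stretch of trajectory whose time-averaged scattering
reproduces the measured profile: a candidate piece of real dynamics,
not just a bag of structures. Several such clipped series, from the same
or different trajectories, form alternative "elements of motion" whose
convex mixture can then be matched against secondary observables.

## Scattering model

Per-frame intensities come from the Debye equation over beads with
constant form factors,

$$ I(Q) = \sum_i \sum_j f_i f_j \frac{\sin(Q r_{ij})}{Q r_{ij}}, $$

with the $i = j$ and $Q \to 0$ terms evaluated as the analytic limit
$\mathrm{sinc} \to 1$, so $I(0) = (\sum_i f_i)^2$ exactly. Form factors
are Q-independent electron counts (valid in the small-angle regime), and
no excluded-volume or hydration-shell corrections are applied: the
fitted scale factor absorbs overall amplitude differences, and the
offset absorbs buffer-subtraction mismatch. Hydrogens can be given zero
weight, the same convention used for the electron-weighted pair distance
distribution $p(r)$, which bins $f_i f_j$ over unordered pairs into
left-closed 1 Å bins by default (the binning is a parameter; the
conservation identity $\sum_r p(r) = ((\sum f)^2 - \sum f^2)/2$ pins
the convention and is asserted in the tests).

Each frame's curve is evaluated directly on the experimental Q grid
(there is no interpolation step anywhere) and normalized by its own
forward scattering $I(0)$.

## The window fit and acceptance criteria

For a window of $M$ frames the model is the *sum* of normalized
per-frame curves, fitted as $I_\mathrm{sim}(Q_i) = c \sum_j
I_{\mathrm{sim},j}(Q_i) - \mathrm{offs}$; the scale $c$ therefore
absorbs the $1/M$ averaging factor. Both parameters solve the weighted
($1/\sigma^2$) normal equations in closed form, minimizing

$$ \chi^2 = \frac{1}{N-1} \sum_{i=1}^{N}
   \left( \frac{I_\mathrm{exp}(Q_i) - I_\mathrm{sim}(Q_i)}{\sigma(Q_i)}
   \right)^2 . $$

The divisor is $N - 1$ by definition of this statistic as used here; it
is deliberately not "corrected" to $N - 2$ for the two fitted
parameters. $c$ is unconstrained in sign, but a negative fit triggers a
warning since it is physically unreasonable.

A window is accepted when $\chi^2 < 3.0$ (first-pass criterion) and,
under the improved dual criteria (the default), additionally every
per-point squared residual at $Q < 0.25\ \mathrm{Å}^{-1}$ stays below
12.5. The band matters because $Q = 0.1$–$0.2\ \mathrm{Å}^{-1}$ probes
real-space correlation lengths $2\pi/Q \approx 62.8$–$31.4$ Å — the
scale of inter-domain arrangement for 20–30 Å globular domains — so a
window can have acceptable global $\chi^2$ while misplacing domains;
the band cap catches exactly that. All inequalities are strict, and the
band is $Q$ *strictly* below the limit. Whether the cap applies
per-point or to the band maximum is equivalent (max < threshold), and
that is how it is implemented.

A clipped window's duration is $L_t = M \times$ frame interval (2
ns/frame by default; 1345 snapshots give 2690 ns). A minimum duration
(default 700 ns) is a *reporting* filter, not a search constraint, so
complete listings of acceptable windows remain available.

## The search

Acceptance is **not monotone** in window extent: a window can pass while
a sub-window fails (averaging washes out individual outliers) and vice
versa. The test suite contains a constructed counterexample. Pruned or
two-pointer searches are therefore unsound, and the search is
exhaustive over all $O(n^2)$ contiguous windows. Cumulative prefix sums
make each window's summed profile an $O(N_Q)$ difference of two rows,
and the scan itself is compiled code; the 2,500-frame, 100-point
default problem completes in seconds on one core. Ties in maximal
length break to the earliest start, making the output deterministic.

## Conformation descriptors and probability maps

Domain centres are unweighted means of backbone-bead coordinates over
inclusive residue ranges (not mass-weighted). From the four-domain
chain a, b, b′, a′ the package computes per frame: the angles
$\theta_{a\text{-}b\text{-}b'}$ and $\theta_{b\text{-}b'\text{-}a'}$,
the torsion $\varphi_{a\text{-}b\text{-}b'\text{-}a'}$, two
domain-orientation torsions that use the redox-motif centre as fourth
point, and the open–close coordinate $D_{a\text{-}a'}$. Torsions follow
the IUPAC sign convention (cis = 0°, range (−180°, 180°]); the
handedness of published ranges such as "−15° to 75°" depends on this
choice, so it is fixed and documented rather than configurable.
Probability maps bin $(\theta, \theta)$ space and normalize counts to
sum to 1; the default 5° bin width is an explicit parameter everywhere
a divergence is reported, because published heatmaps do not state
their binning.

## The support-restricted KL divergence

A clipped series should occupy a *subset* of its source trajectory's
states without distorting their local shape. The divergence therefore
sums only over the clipped support C1 (occupied cells) plus its
adjacent shell C2 (8-neighbourhood by default, switchable to 4), with
the source distribution renormalized to unit mass on C1 ∪ C2:

$$ \mathrm{KL} = \sum_{C1 \cup C2} P_\mathrm{clip}
   \log \frac{P_\mathrm{clip}}{\tilde P_\mathrm{orig}}, \qquad 0 \log 0 = 0 . $$

Both distributions sum to 1 on the region, so the divergence is
non-negative by Gibbs' inequality, and zero iff they agree there. A
clipped cell empty in the source signals inconsistent inputs and is an
error; it cannot occur when the clipped frames are a subset of the
source frames under identical binning. The logarithm base defaults to
natural log and is configurable — published divergence values are
base-dependent, so the base is always part of a reported result. On
multi-state systems the median divergence falls as clipped duration
grows, which motivates pairing a divergence cap (≈ 0.5) with a minimum
duration when deciding whether a clip still represents its force
field's distribution.

## Isosbestic points, linear response, recombination

If a single conformational coordinate $X$ modulates the curves
approximately linearly, $I(Q, X) \approx I(Q, X_0) + (X - X_0)\,
\partial I/\partial X$, then all members' curves intersect where the
sensitivity $\partial I/\partial X$ vanishes — an isosbestic point.
Detection is operationalized as local minima of the per-Q standard
deviation of $\log_{10} I$ across frames, accepted when below a
tolerance factor (default 0.25) times the band's median spread; the
statistic is invariant to uniform intensity rescaling. The per-Q
ordinary least-squares fit of $I$ on $X$ (unweighted — per-frame
curves carry no $\sigma$) reports intercept at $X_0 = \bar X$, slope
and $R^2$; columns with zero residual variance get $R^2 = 1$ so that
an exactly linear family reads as such even at the isosbestic point
where the column is constant.

Recombination solves $X \approx \sum_i c_i X_i$ over per-series
averaged observables. The weights are constrained to the probability
simplex ($c_i \ge 0$, $\sum c_i = 1$) because they represent the
population of each candidate dynamics in a mixture; an unconstrained
mode is provided. The simplex-constrained convex QP is solved exactly
by enumerating active sets, which is cheap for the handful of series
this method produces (and is guarded above 20 series); a dense simplex
grid search cross-checks it in the tests.

## The synthetic hinge system

The generator is first-class, tested code, not a fixture. It emulates
the one feature of real data the clipping method feeds on — a
multi-domain protein switching between open and closed hinge states at
a fixed sampling interval — and deliberately nothing else. Rigid bead
clouds (15 beads in a 10 Å ball per domain, four domains spaced 24 Å
along a chain) swing about hinge pivots so that the hinge angle equals
the $\theta$ descriptors at the adjacent centres and $D_{a\text{-}a'}$
opens monotonically with it. The per-frame angle follows a
discrete-state Markov process (closed 90° ± 4°, open 140° ± 4°,
geometric dwells of mean 50 frames) over 2,500 frames at 2 ns/frame.
All randomness flows through one seed; identical seeds give
bit-identical trajectories.

Target profiles average the normalized curves of a *planted window*,
apply an arbitrary scale and offset, and add Gaussian noise with
$\sigma(Q) = \mathrm{nf} \cdot I(Q)$ — multiplicative Gaussian noise,
matching the $\chi^2$ weighting model. Two design rules make "recover
exactly this window" well-posed:

* **Boundary alignment.** The planted window's edges coincide with
  state-run boundaries, so the frames immediately outside differ in
  state from the edge frames inside; otherwise a one-frame shift is
  nearly indistinguishable in the average.
* **Noise below the swap contrast.** Replacing one window frame
  changes the window average by roughly the inter-state curve contrast
  divided by the window length, part of which the scale/offset fit
  absorbs. The default noise fraction ($10^{-6}$) is set so that the
  smallest competitor window's systematic misfit exceeds the $\chi^2$
  threshold by two orders of magnitude, while the true window's
  $\chi^2$ stays $\approx 1$ (its expectation) at any noise level. The
  planted target is a validation construct, not an emulation of
  beamline noise; with realistic percent-level noise many neighbouring
  windows are legitimately indistinguishable and exact recovery is the
  wrong question.

Recovery checks use the $\chi^2$-only criterion: the construction's
noise is i.i.d. Gaussian, for which $\chi^2$ is the matched statistic,
whereas the per-point band cap would reject the true window whenever
the largest of ~80 standard-normal draws exceeds $\sqrt{12.5} \approx
3.5\sigma$ — about 3% of realizations — i.e. it would test the noise
tail, not the clipping. The improved dual criteria remain the package
default for real data, where residual structure, not Gaussian tails,
dominates the band.

What passing these tests does *not* show: anything about force-field
realism, solvent effects, form-factor Q dependence, or the behaviour of
the method when the experimental ensemble mixes dynamics absent from
the trajectory. The generator has no excluded volume between domains
and its states are exactly two; real hinge proteins populate continua.

A practical note on file round trips: PDB coordinates carry three
decimals, so a trajectory written to PDB and re-read reproduces curves
only to ~$10^{-5}$ relative. Targets built with noise fractions at or
below that floor must be generated and clipped in memory (as the tests
and the acceptance script do), or written via the full-precision
tabular frame format.

## Numerical choices, in one place

* sinc singularity at $Q r = 0$: evaluated as 1 (analytic limit).
* Frame indices 0-based; windows half-open $[s, e)$; residue ranges
  inclusive at both ends.
* $p(r)$: unordered pairs, no self-term, left-closed bins.
* Probability maps: left-closed cells, last cell closed; points outside
  the outermost edges are clipped into edge cells with a warning.
* Constant model curves make the fit's normal equations singular — an
  error, not a silent pseudo-inverse.
* Degenerate per-frame geometry (coincident or collinear centres) flags
  the frame rather than aborting a whole descriptor series.
* Problem sizes used by the tests and acceptance script — 2,500-frame
  recovery runs, a 300-frame system for divergence-versus-duration,
  50–100 Q points — are the package's validation operating points,
  chosen to exercise every code path at full algorithmic scale
  ($O(n^2)$ windows) while staying desk-scale.

## Known limitations

* No excluded-volume/hydration corrections: absolute intensities are
  not comparable to solvent-corrected predictors; only shapes after
  scale/offset fitting are.
* Non-contiguous frame selection (reweighting, ensemble-optimization
  subset picking) is deliberately out of scope — contiguity is the
  point.
* Binary trajectory formats (XTC/DCD) are not read; convert to
  multi-model PDB, XYZ, or the tabular frame format.
* The b/b′ split of a combined b-b′ domain is a required user input
  for four-domain analyses; no automated domain detection is attempted.
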