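---
title: "Moment-based molecular similarity with PCA reference frames"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moment-based molecular similarity with PCA reference frames}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsr)
```

## The model

Moment-based similarity methods compress a 3D structure into a short
vector of statistical moments of atom-to-reference-point distances and
compare those vectors with a Manhattan metric. The classic family (USR
and its descendants) anchors the reference points on atoms of the
molecule itself — the centroid, the atom closest to it, the atom
farthest from it, and the atom farthest from that one. This is fast but
has two structural weaknesses: a small conformational change can hand a
reference role to a different atom, producing a discontinuous jump in
the score, and symmetric molecules make the atom selection ambiguous.

This package implements the hypershape approach instead. A molecule
with $A$ atoms becomes an $A \times N$ point cloud in which each row is
$(x, y, z, f_1, \dots, f_F)$, $N = 3 + F$: the Cartesian coordinates
plus any per-atom numerical features, treated as additional independent
dimensions. The default scheme uses three features,

$$F_1 = \sqrt{p}, \qquad
  F_2 = \mathrm{sign}(n - n_{ci})\sqrt{|n - n_{ci}|}, \qquad
  F_3 = q,$$

with $p$ the proton count, $n$ the neutron count, $n_{ci}$ the neutron
count of the element's most common isotope, and $q$ the formal charge.
The square roots keep the count-valued features on a scale comparable
to centred coordinates of small and mid-size molecules; unlabelled,
neutral atoms contribute $F_2 = F_3 = 0$. Because the features enter as
plain extra dimensions, any user-supplied per-atom quantity (partial
charges, steric parameters, pharmacophore weights on dummy atoms) can
be used instead, and any rescaling is legitimate *provided it is
applied identically to every molecule in the comparison set*.

The reference frame is derived from the cloud itself. The centred
hypershape is eigendecomposed (population covariance, divisor $A$) and
the principal components are ordered by descending absolute eigenvalue.
Each eigenvector's sign is then fixed deterministically: walk the
projections onto the axis by descending magnitude, skip symmetric
$\pm$ pairs, and flip the axis if the first unpaired projection is
negative. If the walk exhausts all projections the cloud has a mirror
plane orthogonal to that axis (the molecular axis of acetylene is the
canonical case); the sign of such an *undetermined* axis provably
cannot affect distances, so it is left alone and flagged.

The $N+1$ reference points are the geometric centre plus, on each
oriented axis, a point at the largest positive projection (optionally
rescaled by `ref_scale`). The Euclidean distances in $N$-space from
each reference point to every atom give $N+1$ distributions, and their
first three moments — mean, population standard deviation, skewness —
concatenated centre-first then per axis, form the $3(N+1)$-number
fingerprint: 12 numbers for a pure-3D scheme, 21 for the default 6D
one. Two fingerprints $q, t$ are compared by

$$S_{qt} = \frac{1}{1 + d_M(q,t)/K}, \qquad
  d_M(q,t) = \sum_i |q_i - t_i|,$$

with $K$ the fingerprint length. $S \in (0, 1]$ and $S = 1$ exactly for
identical fingerprints. Since $K$ depends on $N$, scores computed under
different schemes are never comparable; the package refuses such
comparisons at a metadata check and offers raw Manhattan distances
(`pairwise_matrix(value = "distance")`) for cross-dimensionality
studies, where distances — unlike scores — grow monotonically as
discriminating dimensions are added.

## Chirality

With sign orientation alone, mirror-image molecules get mirror-image
frames and therefore identical fingerprints. Enantiomer discrimination
is optional: the determinant of the oriented eigenvector matrix is
$\pm 1$, and the bookkeeping identity
$\det_f = \det_i \cdot (-1)^{n_c}$ (initial determinant times one sign
change per flip) is asserted after every orientation. When enforcement
is requested and $\det_f = -1$, the axis whose projections have the
largest absolute standardized skewness is flipped once more, forcing
$\det_f = +1$; the frames of two enantiomers are then no longer mirror
images and their fingerprints differ.

Chirality is off by default and *refused* (warning, frame unchanged)
whenever any axis is undetermined or has zero variance. The rationale:
such clouds have a mirror symmetry or a constant dimension, so they are
not chiral in the represented space and a determinant convention would
inject arbitrary sign choices. A practical consequence worth knowing:
an $A$-atom molecule spans at most $A - 1$ dimensions after centring,
so a four-atom chiral cloud can be separated from its mirror under the
3D scheme but not under the 6D one (three of its six axes are
necessarily empty). The skewness measure used to pick the flip axis is
configurable (`"standardized"` or raw `"third_moment"`); the default is
standardized because it is scale-free across dimensions of different
units.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `scheme` | `"default6d"` | feature scheme; built-ins `3d`, `4d`, `5d`, `default6d`, `electroshape4d` |
| `chirality` | `FALSE` | enforce determinant $+1$ |
| `symmetry_tolerance` | `1e-4` | relative tolerance declaring two projections a symmetric pair |
| `skewness` | `"standardized"` | moment-3 convention; `"cube_root"` for strict USR-literature emulation |
| `ref_scale` | `1` | multiplier on reference-point distances from the centre |

The symmetric-pair tolerance is relative ($|a+b| \le
\mathrm{tol}\cdot\max(1, |a|)$) and defaults to $10^{-4}$, the order of
the relative coordinate noise of crystallographic structures: tighter
values make near-symmetric experimental geometries look asymmetric and
reintroduce the sign instability the cascade exists to remove; looser
values start pairing genuinely distinct projections. Eigenvalue ties
are broken by descending largest absolute projection and then original
column order, so symmetric molecules still yield one deterministic
frame. Zero-variance dimensions are kept as trailing axes with
eigenvalue 0 and contribute a duplicate-of-centre moment triplet, so
fingerprint length — and hence $K$ — is constant across a comparison
set even when some molecules are flat, neutral or isotopically uniform.

## Baselines and emulation modes

For comparative work the package ships the heuristic methods it is an
alternative to: `usr_fingerprint()` (12 moments), `csr_fingerprint()`
(cross-product reference point, reflection-sensitive),
`optiso_fingerprint()` (USR plus a scalar-triple-product 13th
descriptor), `subset_fingerprint()` (USRCAT-style per-atom-type blocks,
60 moments with four predicates, with either the USR heuristic or the
PCA engine per block), and `electroshape_fingerprint()` (the PCA engine
on coordinates plus an unscaled user-supplied partial-charge column).
All heuristic atom selections break ties by lowest atom index and
record that a tie occurred — scores can legitimately depend on input
order in tied geometries, and a flagged deterministic answer is the
safest contract. The shipped atom-type predicates are deliberately
element-based (not the Credo SMARTS set, which requires bond perception
that is ill-defined for inorganic and organometallic species) and are
labelled as such.

## What the synthetic fixtures emulate

All tests run on seedable generated inputs (`generate_fixture()`),
written to SDF and re-read so the I/O layer is always on the tested
path:

* `chiral_tetrahedron` / `mirror_pair` — enantiomer discrimination and
  reflection invariance;
* `linear_symmetric` — the acetylene case: an axis with no sign
  discriminant;
* `planar` — the achiral control with an empty dimension;
* `torsion_sweep` — a 7-atom cloud with one rotor atom engineered so
  the closest-to-centroid selection switches between two well-separated
  atoms mid-sweep (the rotor stays the farthest atom throughout). The
  crossover angle was placed analytically from the
  perpendicular-bisector condition of the two candidate atoms, and the
  sweep window ($\pm 0.08$ rad, scaffold jitter 0.005 Å) brackets it
  for every seed. Along this path the heuristic score jumps by an order
  of magnitude more than its median step while the PCA-based score
  moves in near-uniform steps;
* `isotopologue_series` / `protonation_series` — amine chains pairing
  each molecule with a terminally ^13^C-labelled or N-protonated
  partner. Default chain lengths are the odd series 3, 5, …, 13:
  growing by two backbone atoms keeps the terminal carbon in the same
  zig-zag orientation, so the series is genuinely homologous and the
  label's effect dilutes monotonically with size; one-atom increments
  alternate the end-group parity and superimpose an oscillation on that
  trend.

These fixtures are idealized point clouds: bond lengths are plausible
but geometries are not energy-minimized, there are no conformational
ensembles, and element assignments are arbitrary. Passing tests
therefore demonstrate the mathematical contracts of the method —
invariances, continuity, determinant bookkeeping, moment definitions —
not screening performance on real chemical libraries, which depends on
the data and on feature choices outside the package's control.

## Numerical choices and degenerate inputs

* Covariance uses divisor $A$; eigenvectors are identical either way
  and only the eigenvalue scale changes (documented, asserted against
  an SVD oracle).
* Skewness is $m_3 / m_2^{3/2}$ with the convention $0$ when
  $m_2 = 0$ (constant distributions otherwise have undefined skewness).
* A single atom, or coincident atoms, yields a degenerate frame
  (identity axes, zero eigenvalues, all reference points at the
  origin) and an all-zero-variance fingerprint rather than an error.
* Distances are always measured in the same (scaled) space used for
  the PCA, so feature scalers affect frame and distances consistently.
* Problem sizes in the test suite were chosen for coverage at desk
  scale: clouds of 4–10 atoms, 1000 seeded clouds for the determinant
  identity, 100 rigid motions per invariance fixture, 20 seeds for the
  continuity contrast, chains up to 13 heavy atoms.

## Known limitations

* No conformer generation, bond perception, charge calculation or
  implicit-hydrogen handling: the point cloud is taken exactly as
  supplied, and hydrogens present or absent in the input change the
  fingerprint accordingly.
* The feature-dimension unit question has no first-principles answer;
  the default identity scaling (raw value per unit) is a convention,
  and `autoscale_hypershapes()` is provided only as a set-level
  opt-in.
* Chirality enforcement identifies *that* two mirror images differ,
  not the type of optical isomerism, and scores across different kinds
  of chirality are hard to interpret.
* A feature's impact depends on where in the molecule it sits
  (position dependence is inherent to moment-based methods), and
  adding features breaks the purely geometric reading of the centre
  moments (size, compactness, asymmetry).
* SDF support is V2000 only; V3000 files are rejected with an explicit
  error.

## A worked example

```{r example}
pair <- generate_fixture("mirror_pair", n_atoms = 8, seed = 7)
fp_a <- hsr_fingerprint(pair$original, scheme = "3d")
fp_b <- hsr_fingerprint(pair$mirror, scheme = "3d")
similarity_score(fp_a, fp_b)  # reflections are identical by default

ga <- hsr_fingerprint(pair$original, scheme = "3d", chirality = TRUE)
gb <- hsr_fingerprint(pair$mirror, scheme = "3d", chirality = TRUE)
similarity_score(ga, gb)      # and separated once chirality is enforced
```
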