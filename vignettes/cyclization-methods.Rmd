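---
title: "DNA cyclization J-factors in a rigid-basepair model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DNA cyclization J-factors in a rigid-basepair model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnacyclize)
```

## The model

A DNA molecule of $N$ basepairs is a chain of rigid frames: frame $i$ has an
origin $\mathbf r^i$ (Å) and an orthonormal director triad
$R^i = [\mathbf d_1^i\,\mathbf d_2^i\,\mathbf d_3^i]$, with frame 1 fixed at
the origin with identity orientation. Consecutive frames are related by six
internal coordinates: a Cayley rotation vector
$\boldsymbol\theta^i$ (roll, tilt, twist; magnitude $2\tan(\varphi/2)$ for a
rotation angle $\varphi$) and a translation $\mathbf a^i$ (shift, slide,
rise) expressed in the *midframe*, the current frame rotated by half the
step rotation. The elastic energy is diagonal quadratic about the intrinsic
(minimum-energy) step coordinates
$(\hat{\boldsymbol\theta}^i, \hat{\mathbf a}^i)$:

$$E \;=\; \tfrac12 \sum_{i=1}^{N} \sum_{j=1}^{3}
  \Big[ K_j\,(\theta^i_j - \hat\theta^i_j)^2
      + A_j\,(a^i_j - \hat a^i_j)^2 \Big] \quad (\text{units of } RT),$$

with no cross-couplings and no sequence dependence. Baseline values:
$K_1 = K_2 = 46.3/0.34\,RT$ (an isotropic rod; the small-angle reading of a
46.3 nm persistence length at 3.4 Å rise), $K_3/K_1 = 1.5$, and
$(A_1, A_2, A_3) = (14, 24, 85)\,RT/\text{Å}^2$. A global factor `scale_beta`
multiplies all six stiffnesses, and an inextensible mode freezes the
translations. Because the energy is an independent-coordinate quadratic, the
Boltzmann distribution factorizes exactly and sampling is direct Gaussian —
no Markov chain, no equilibration, no autocorrelation.

Intrinsic shapes are built from segments that are helical, circular-arc, or
straight, all with constant intrinsic twist $2\pi/\text{(helical repeat)}$
per basepair. A helical segment is parameterized by $\psi$ (half the bend
per basepair, to leading order), $\alpha$ (helicity; 0 gives a planar arc)
and the twist rate; user-facing constructors instead take the total bend
angle, the number of basepairs carrying it, and the signed
pitch-to-circumference ratio of the bend, solving
$\cos(\text{bend/bp}) = \cos^2\!\alpha\,\cos 2\psi + \sin^2\!\alpha$ and
$\text{Pitch}/\text{Circumference} = \tan\alpha\,\sin\psi/\psi$
for $(\alpha, \psi)$ by 1-D root finding (residual $<10^{-12}$; positive
ratio = left-handed).

### Pinning the composition convention

The Cayley normalization and the midframe rule are not free choices here:
they are pinned by requiring that the closed-form intrinsic steps of a
helical segment compose, from the identity start frame, to the closed-form
helix origins. The test suite verifies this to $10^{-8}$ Å over 100 random
parameter sets. One wrinkle discovered in that verification: the axis-aligned
closed form (helix axis parallel to $y$) corresponds to a start frame whose
tangent is $(0, \sin\alpha, \cos\alpha)$, not $\mathbf e_3$; composing from
the identity frame therefore reproduces that helix *rotated rigidly by*
$\alpha$ *about the x-axis*. The oracle compares in axis-aligned coordinates.
Nothing downstream is affected — the J-factor sees only relative geometry.

## J-factor and its Monte Carlo estimator

Cyclization is described by appending a fictitious frame $N{+}1$ and asking
for frames 1 and $N{+}1$ to coincide. The J-factor is the probability
density of frame $N{+}1$'s end state at the closure point
$(\mathbf 0, I) \in \mathbb R^3 \times SO(3)$, with volume measure on
$\mathbb R^3$ (giving concentration units; reported in nM) and the
*normalized Haar measure* on $SO(3)$. The orientational closeness of two
frames is measured by $d(R_1, R_2) = \sin(\varphi/2)$, $\varphi$ the
relative rotation angle — the rotation-invariant distance whose
$\delta$-ball has Haar volume
$\tfrac2\pi(\arcsin\delta - \delta\sqrt{1-\delta^2})$ (an algebraic identity
with the Haar angle measure $(\varphi - \sin\varphi)/\pi$, tested as such).
For small tolerances this matches the older two-angle (tangent-angle +
torsion) convention, whose region has Haar volume
$\nu_\varepsilon\tau_\varepsilon/2\pi$ to leading order; the package
verifies that limit by Haar Monte Carlo.

The estimator uses the half-molecule trick: $M$ independent first halves
(steps $1..m{-}1$) and $M$ second halves (steps $m..N$) give $M^2$
composable molecules. First halves store $-T_{1:m}^{-1}\mathbf r_{1:m}$ so
that a pair closes exactly when the two stored end positions are within
$\varepsilon$ (Å) *and* the composed rotation $T_{1:m}T_{m:N+1}$ is within
$\delta$ of the identity. Then

$$\hat J = \frac{\text{hits}}
   {M^2 \cdot \tfrac43\pi\varepsilon^3 \cdot
    \tfrac2\pi(\arcsin\delta - \delta\sqrt{1-\delta^2})}$$

converted from Å$^{-3}$ to nM. Pair search is cube-binned: ends are sorted
into cells at least $\varepsilon$ wide (z-slabs capped at 128, x/y cells of
width $\varepsilon$), so only the 3×3×3 neighborhood of each end is
scanned, with a cheap z-difference test before the full Euclidean and
rotational tests. The binned count is *exactly* the all-pairs count, and the
tests assert that equality against a vectorized brute-force oracle at
$M = 2000$. Rotations are carried as unit quaternions end to end; the
rotational test is a single 4-term dot product per surviving pair.

### Tolerances, bias and the convergence check

The closure ball averages the end-state density over its volume, so finite
tolerances bias $\hat J$ wherever the density curves — at a profile peak the
bias is upward. `tolerance_convergence()` recounts the same ensembles at
halved tolerances and flags a shift beyond the combined Poisson errors.
Measured at the baseline peak molecule (90° bend over 63 bp, $N = 147$,
$M = 2^{21}$), log$_{10}J$ reads 1.540 at $(\varepsilon, \delta) = (30, 0.3)$,
1.471 at $(20, 0.2)$, 1.446 at $(15, 0.15)$ and 1.441 at $(12, 0.12)$: the
$(30, 0.3)$ setting fails the halving check decisively (~+0.10 bias), while
$(15, 0.15)$ passes it at $M \ge 2^{19}$. The package therefore uses
$(30, 0.3)$ — and even $(45, 0.45)$ — only for *differential* work
(profile shapes and knob trends, where the smoothing is common mode), and
$(15, 0.15)$ for absolute comparisons at $M = 2^{20}$. At those settings the
baseline peak reads log$_{10}J \approx 1.43$–$1.46$, versus a published peak
height of 1.35 with a stated accuracy target of 0.1.

Two statistical caveats are worth knowing. First, hits sharing a half are
correlated, so errors are super-Poisson: the run-to-run scatter behaves like
$\sqrt{2c_v^2/M}$ with $c_v^2 \sim 400$ at the baseline molecule, dwarfing
the Poisson term at small $M$. The per-run `stderr_log10` is the Poisson
floor, not the full error; trend tests pool hits over several seeds.
Second, an unbalanced split (e.g. $m = N/3$) leaves one half short and
stiff, collapsing the effective pair diversity; the default balanced split
$m = \lceil (N{+}1)/2 \rceil$ is both the fastest and the most statistically
efficient, and split-invariance is asserted with pooled seeds at a band set
by the measured scatter.

Step $N$ (into the fictitious frame) is sampled thermally like every other
step, reading the energy sum literally; freezing it instead would change the
closure density by roughly $(147/146)^{3/2}$-type factors, well below the
stochastic error at these scales.

## Cyclization profiles and the periodic fit

`cyclization_profile()` computes log$_{10}J$ over $N = 146..170$ (a bit more
than two helical-repeat periods), with independent per-length seed pairs
derived from one master seed; zero-hit lengths are censored and excluded
from fitting. Profiles are fit to

$$y = a + b\,(N - \varphi) + c\,f(N, \varphi, p)^2, \qquad
  f = \mathrm{mod}(N - \varphi + p/2,\, p) - p/2,$$

so $\varphi$ is the first peak after $N = 145$, $p$ the period, $a$ the peak
height, $b$ the drift and $-c\,(p/2)^2$ the peak-to-trough difference. For
fixed $(\varphi, p)$ the model is linear and solved in closed form
(vectorized over a dense grid: $\varphi$ step 0.02 bp over
$(145, 145{+}p]$, $p$ step 0.01 bp over $[9.5, 11.5]$), then polished by
Nelder–Mead on the projected objective; noiseless data are recovered to
machine precision, and $\varphi$ is reported wrapped into $(145, 145{+}p]$
(ties to the smallest admissible value). The form has a near-degenerate
mirror branch — $c > 0$ with $\varphi$ shifted half a period — that sparse,
noisy profiles can fall into; `c_sign = "nonpositive"` removes it, since
every molecule in the studied regime genuinely peaks at $f = 0$.

## Knob regressions, degeneracy, calibration

The downstream layer regresses fitted parameters against single model knobs
about the reference molecule (90° planar bend, repeat 10.5, $K_3/K_1 = 1.5$,
$\beta = 1$), using the published per-molecule fit tables shipped in
`inst/extdata/` as inputs. The headline relations are
$a \approx 1.31 + 0.021(\text{bend} - 90)$,
$a \approx 1.34 - 4.45(\beta - 1)$,
$\varphi \approx 147.2 + 14.3(\text{repeat} - 10.5)$,
$\varphi$ and $a$ linear in Pitch/Circumf (slopes $\approx 2.45$ and
$\mp 0.3$ by handedness), and
$c \approx -0.114 - 0.077(K_3/K_1 - 1.5)$. Three of the sixteen published
coefficients (left-handed $\varphi$ slope 2.49, right-handed $a$ intercept
1.37, twist-stiffness $a$ slope 0.30) do not re-derive exactly from the
rounded table entries (OLS gives 2.484, 1.376, 0.294); the acceptance test
holds those three to ±0.011 and the rest to printed precision.

`degenerate_family()` builds molecule families predicted to share a profile:
bend angle $= 90 + 212(\beta - 1)$ trades intrinsic bend against stiffness
(212 = 4.45/0.021 at printed precision), and the three-knob family sets
Pitch/Circumf $= -5.84(\text{repeat} - 10.5)$ with bend
$= 90 + 14.3\,|\text{Pitch}/\text{Circumf}|$ — the constant 14.3 is the
published rounding of 0.3/0.021, kept as published so the worked examples
(98.4° at ratio 0.584, 102.5° at 0.876) reproduce exactly. Validity is
enforced (bend within 60–120°, $|$Pitch/Circumf$| \le 1$).
`calibrate_simple_model()` inverts the relations: $K_3/K_1$ from the fitted
$c$, then $\beta$ from the fitted $a$ given an independently estimated
intrinsic bend, optionally shifting the baseline by $0.30\,(K_3/K_1 - 1.5)$
first.

## What the synthetic data emulate — and what they do not

Two generators feed the tests. The Monte Carlo sampler *is* the model: its
draws are exact Boltzmann samples of the idealized uniform elastic rod, so
passing tests certify the machinery (geometry, sampling, counting,
normalization, fitting), not the realism of the rod. Real DNA has
sequence-dependent intrinsic shape and stiffness, roll–twist couplings,
anisotropic bending only partially averaged by twist, and excluded-volume
and knotting constraints — all outside this model. `generate_profile_fixture()`
simply evaluates the periodic fit form plus Gaussian noise; it exercises the
fitting layer without Monte Carlo and carries no physics at all.

One genuine model subtlety: with the energy quadratic in *Cayley*
components and a full intrinsic twist of $2\pi/10.5$ per step, the measured
tangent persistence length of the straight baseline molecule is 50.7 nm,
not the small-angle $K_1\ell = 46.3$ nm reading (without intrinsic twist it
is 46.8 nm). The tests assert the exact single-step-expectation decay and
the quoted 46.3 nm only to within 10%.

## Problem sizes and reproducibility

Desk-scale sizes used by the tests and the acceptance script: $M = 2^{20}$
half-molecules for the absolute baseline comparison; $M = 2^{15}$–$2^{16}$
per length with tolerances $(45, 0.45)$ for the qualitative knob trends;
$M = 2000$ for exact brute-force pairing equality; $10^5$–$10^6$ samples for
the Haar and persistence properties. Published-scale profiles
($M = 2^{23}$–$2^{28}$, accuracy 0.1 in log$_{10}J$ across full profiles)
are out of scope. Every stochastic step is seeded: one master seed spawns
per-(length, half) substreams, and identical configurations reproduce
byte-identical artifacts.

## Known limitations

* Absolute J-factors carry the residual finite-tolerance and model
  conventions discussed above (~0.1 in log$_{10}J$ at the baseline peak);
  differential results (trends, degeneracies, calibration) are considerably
  more robust.
* Poisson `stderr_log10` underestimates run-to-run error at small $M$
  (shared-half correlations).
* No excluded volume, no supercoiling/linking-number bookkeeping, no
  sequence dependence, no anisotropic or coupled stiffness blocks
  (`anisotropic_pair()` only documents the isotropic-equivalence reading).
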