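---
title: "Methods: cartilage material uncertainty in a hybrid knee model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cartilage material uncertainty in a hybrid knee model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneeuq)
```

## The question the package answers

Articular cartilage properties measured on excised tissue scatter widely,
and osteoarthritis (OA) shifts and reshapes that scatter. `kneeuq` asks
how much of this material uncertainty propagates into the mechanics of a
whole knee joint, in two loading scenarios:

1. **Compression** — a condylar contact pair loaded to a prescribed
   indentation, as in standing;
2. **Flexion–extension** — a planar tibiofemoral joint driven by external
   moments of up to ±3.5 N m, as in passive motion.

The study is two-staged. Stage 1 samples the cartilage constitutive
parameters with a quasi-Monte Carlo design and solves a layered
sphere–plane contact problem for every sample, yielding force–indentation
curves. Stage 2 embeds those curves as the condylar contact law of a
planar multibody knee and samples the ligament system, so that the
material effect can be isolated within many plausible knees.

## Constitutive model

Cartilage is modelled as an incompressible second-order Yeoh solid,

$$W = C_{10}\,(\bar I_1 - 3) + C_{20}\,(\bar I_1 - 3)^2 ,$$

where $\bar I_1 = \lambda_1^2+\lambda_2^2+\lambda_3^2$ is the first
deviatoric invariant. Incompressibility is enforced exactly: uniaxial
loading has $\lambda_2=\lambda_3=\lambda^{-1/2}$, hence
$\bar I_1 = \lambda^2 + 2/\lambda$ and the axial Cauchy stress

$$\sigma(\lambda) = 2\left(\lambda^2 - \tfrac1\lambda\right)
  \left(C_{10} + 2C_{20}(\bar I_1 - 3)\right).$$

Compression is $\lambda < 1$ with $\sigma < 0$; the contact pressure used
downstream is $-\sigma$. The small-strain limit is the incompressible
Young's modulus $E = 6C_{10}$, which the test suite verifies numerically.
Anisotropy, rate dependence and poroelasticity are out of scope: their
parameter counts would defeat the sampling budget that is the point of
the study.

The sampled ranges (MPa, per tissue group, mean ± 1 SD of experimental
fits) are built into `material_ranges()`:

```{r}
material_ranges()
```

## Contact stage: a nonlinear elastic-foundation solver

The reference study solved the layered sphere–plane indentation with a
large FE model. Here that stage is replaced by a bespoke desk-scale
solver so that the 128-run design (and its oracles) run in seconds: a
**nonlinear elastic foundation** (Winkler) model. Each surface point is
an independent column of the femoral (2.3 mm) and tibial (2.1 mm)
cartilage layers in series on rigid bone; the column pressure is the
incompressible uniaxial Yeoh response. For a rigid sphere of radius
$R = 40$ mm at indentation $\delta$, the local interpenetration is
$u(r) = \delta - (R - \sqrt{R^2-r^2})$ and the contact force is

$$F(\delta) = \int_0^{a} p(u(r))\, 2\pi r \, dr, \qquad u(a) = 0 .$$

Two root-finding layers sit under this quadrature, both bracketed
Newton iterations with bisection safeguarding: the stretch solve
$-\sigma(\lambda)=p$ on $\lambda\in[0.2,1]$ (absolute tolerance
$10^{-10}$; $\lambda<0.2$ signals indentation beyond model validity) and
the series-column solve for the shared pressure (tolerance $10^{-8}$
MPa). The radial quadrature is a fixed 400-interval trapezoid rule; the
test suite holds it to 0.1 % against a 10×-finer grid, and the
small-indentation limit to 2 % against the closed linear-foundation form
$F = \pi R \delta^2 / (t_f/E_f + t_t/E_t)$ with $E_i = 6C_{10,i}$.

**What the surrogate preserves and what it does not.** Because each
column is independent, lateral confinement of the incompressible layer
is neglected. Confinement stiffens a bonded thin layer once the contact
radius exceeds a few layer thicknesses (here $a/t \approx 4$ at 1 mm),
so the foundation model systematically underestimates absolute forces —
by roughly 20 % at 1 mm indentation relative to the reference FE values —
and slightly compresses the spread of the softest samples. Scale-free
dispersion statistics (CV) are far less affected, which is why they are
the primary quantities of the study. The curve shapes, the
healthy-versus-OA ordering, and the relative variability that the second
stage consumes are all preserved.

Curves are solved on the printed grid — 20 steps to 1.00 mm — plus an
explicit zero point so that interpolation is anchored at the origin;
between and beyond grid points the curve is piecewise linear with
last-segment extrapolation, and non-positive indentation transmits no
force (no tension through contact).

## Sampling

Both stages use deterministic, unscrambled base-2 Sobol sequences with
Joe–Kuo direction numbers, including the origin point (the all-minima
material corner, which is physically valid since $C_{20}=0$ is an
allowed bound). No scrambling is applied: determinism makes every run
exactly repeatable, and power-of-two sizes (64 and 32) give perfectly
balanced one-dimensional stratification, which the tests check
bin-by-bin. The same 64-point unit design is scaled to both tissue
groups, so healthy and OA samples are paired sample-by-sample; the
stage-1 column order is fixed as (femoral $C_{10}$, femoral $C_{20}$,
tibial $C_{10}$, tibial $C_{20}$).

The stage-2 design is 20-dimensional with 32 samples: 16 attachment
offsets — (ACL, PCL, MCL, LCL) × (femoral, tibial) × (x, y) — scaled to
±1.0 mm, and 4 stiffness multipliers scaled to ±10 %. Offsets are
applied in each bone's own frame.

## The planar hybrid knee

The knee is a rigid femur moving in the sagittal plane above a fixed
tibia whose plateau is the line $y=0$. Four tension-only cables stand in
for the ACL, PCL, MCL and LCL, with the standard quadratic-toe/linear
law in strain $\varepsilon$ (toe parameter $\varepsilon_l = 0.03$):
zero force when slack, $k\varepsilon^2/(4\varepsilon_l)$ for
$0<\varepsilon\le2\varepsilon_l$, and $k(\varepsilon-\varepsilon_l)$
beyond, continuously differentiable at the transition. Two condylar
circles of radius 40 mm contact the plateau; the normal force at
penetration $\delta$ is read from the stage-1 curve of the current
material sample (the full curve is applied to each condylar pair).
Dynamics are integrated with the semi-implicit (symplectic) Euler
method at $dt = 1$ ms: velocities update first, positions second, which
keeps the stiff unilateral contact stable over the 16 s horizon — the
suite checks boundedness of an undamped stiff oscillator over the full
horizon and exactness of the constant-force closed form.

Each branch applies the external moment in five equal increments (0.7 N m
every 3.2 s, extension positive up to +3.5 N m, flexion to −3.5 N m),
starting from the neutral pose near 55° of flexion; global viscous
damping (600 N s/m translational, 0.25 N m s/rad angular) lets every
plateau settle — end-of-plateau residual generalized force below
$10^{-3}$ (N, N m) and terminal kinetic energy below $10^{-6}$ J are
asserted, not assumed. Gravity is omitted: the protocol is purely
moment-driven. Units are SI internally and mm/deg at every interface.

## The synthetic nominal knee and its calibration

The reference planar knee's ligament attachments, stiffnesses, masses
and damping are not printed in the sources this package is built from,
so `default_model()` is an honest synthetic stand-in, calibrated once so
that the printed anchors hold and then frozen:

* neutral pose ≈ 55° flexion; condyle radius 40 mm (printed values);
* flexion–extension range ≈ 74° under ±3.5 N m with mid-range healthy
  cartilage (the nominal model lands at 80.4°, inside the ±15 %
  acceptance band [63, 85]°);
* the ACL carries exactly zero force throughout the flexion branch, for
  the nominal model and all 32 perturbed variants;
* OA curves always yield a more compliant joint than healthy curves.

The calibration explored the attachment geometry against simulated
trajectories rather than static sketches, because the femur rocks
between its two condyles and the instantaneous pivot — not the femur
origin — governs how each cable's length changes with angle. Three
geometric choices do the heavy lifting and are worth recording:

1. **The extension pivot sits under the femur reference** (anterior
   condyle center at $x=0$). At full extension the moment balance then
   pins the ACL force at $M_{\text{ext}}$ divided by its arm, with no
   material-sensitive collateral torque in the balance: the ACL force
   CV across cartilage samples stays below 0.5 %, reproducing the
   "ACL indifferent to cartilage" pattern.
2. **The flexion pivot sits 16 mm posterior**, so flexing lifts the
   femur origin by $16\sin\psi$; the preloaded collaterals stretch over
   this rise and the cartilage indentation enters their length
   directly, which couples the material sample into the flexion-side
   equilibrium (the source of the OA-versus-healthy range effect).
3. **The MCL femoral attachment lies at the posterior condyle center**,
   i.e. at the flexion pivot: its length is then insensitive to the
   rotation itself but fully exposed to the indentation depth, making
   its maximum flexion force an indentation sensor with CV above 1 %,
   while the LCL (attached at the origin) stays comparatively
   indifferent — the same ligament-by-ligament asymmetry the reference
   study reports.

Ligament slacks are chosen so the ACL engages only below ≈ 40° (its
9 % slack margin also absorbs the worst of the ±1 mm stage-2 attachment
offsets, keeping it silent in flexion for every variant), the PCL only
near deep flexion, and the collaterals are pre-strained to seat the
joint. `nominal_provenance()` labels every parameter `printed` or
`synthetic`. A verification script that re-checks all anchors against
the frozen values ships as `inst/scripts/calibration_check.R`.

Because the nominal knee is synthetic, downstream flexion–extension
numbers are *property anchors*, not exact targets: orderings, CV
patterns and ratios are compared, absolute RDiff values are not.

## Statistics

For each batch the package reports the mean, the sample ($n-1$) standard
deviation — the sources do not state the denominator; $n-1$ is recorded
as our choice — the coefficient of variation $\mathrm{CV} = 100\,
\mathrm{SD}/\mathrm{mean}$, and for angular ranges the relative change

$$\mathrm{RDiff}_i = 100\,\frac{\mathrm{range}_{\max,i} -
\mathrm{range}_{\min,i}}{\mathrm{range}_{\mathrm{mean},i}} \% .$$

Table-style variant summaries interpret the per-group CV as the CV of
the 64 angular ranges (consistent with RDiff acting on the same
batch), and ligament CVs are computed from each model's maximum
flexion-branch force for PCL, MCL and LCL and maximum extension-branch
force for the ACL, which is inactive in flexion.

## Problem sizes used by the tests

The full compression stage (2 × 64 contact solves, 21-point curves)
runs in a few seconds and is exercised at full scale. The
flexion–extension stage is exercised at 2 variants × 8 samples × 2
groups (64 branch simulations of 16 s each); this scaled design covers
every code path of the full 32 × 64 × 2 study, whose complete run is a
straightforward but longer loop over the same functions. All runs are
deterministic, so repeated executions are byte-identical, which the
pipeline tests assert on the exported CSV files.

## Known limitations

* The foundation contact model underestimates absolute forces by the
  confinement effect discussed above; compare CVs, not Newtons, against
  confined-layer FE results.
* The knee is strictly sagittal-plane: no out-of-plane motion, menisci,
  patellofemoral joint, muscle wrapping or friction.
* The nominal knee reproduces printed behavioural anchors, not any
  specific subject's geometry; per-ligament force magnitudes are
  indicative only.
* Passing tests demonstrate internal consistency and the reproduction
  of the reference study's dispersion structure under the stated
  generator conditions — not predictive validity for physiological
  knees.
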