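---
title: "Methods: carotid hemodynamics, plaque stress and event-risk modelling at desk scale"
author: "carotidrisk authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: carotid hemodynamics, plaque stress and event-risk modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and modelling idea

`carotidrisk` implements, end to end and at desk scale, a cerebrovascular
event-risk methodology for asymptomatic carotid artery disease: pulsatile
blood-flow simulation on the carotid bifurcation driven by Doppler ultrasound
landmarks, wall-shear-derived hemodynamic markers, hyperelastic structural
analysis of the plaque-bearing cross-section, and a gradient-boosted-tree
classifier over imaging, simulation-derived and clinical (eCRF) features with
Shapley attribution. Because no patient data ship with the package, a
synthetic-data layer generates every input the clinical workflow would
provide: planar bifurcation lumens (standing in for MRI-reconstructed
vessels), plaque cross-sections, ultrasound measurement records, and an
imbalanced cohort with a *known* logistic ground-truth risk model so recovery
of the feature-importance ranking can be tested rather than asserted.

The deliberate reduction from the clinical 3D workflow to 2D is the central
design decision. The governing equations, boundary scheme, material models,
metric definitions and the entire ML stage are the same; vessel "areas"
become wall-boundary-length fractions, and flow rates are per unit
out-of-plane depth. Nothing in the package claims clinical resolution; it
claims faithful equations and testable arithmetic.

# Synthetic geometries and cohorts

The bifurcation is parameterized by vertical cross-sections: a straight
common-carotid (CCA) inlet, a smooth carotid-bulb flare up to the flow
divider apex, and two branches (ICA, ECA) spreading at 18-24 degrees. A
stenosis is a cosine-bump narrowing of the ICA, so walls stay differentiable
and the minimal lumen width is exactly `(1 - s)` times the reference width.
Cross-sections are annular wall rings with a fibrous plaque shaped as an
annular sector behind a cap of wall tissue; the plaque area fraction is the
package's stand-in for the (never quantitatively defined) "plaque burden".

Cohort feature marginals are drawn once from ranges consistent with the study
demographics (hypertension prevalence 0.83, smoking 0.70, BMI 26.5 +/- 3.4,
median-age cohort with >50% ICA stenosis) and with physiologic ranges of the
simulation outputs (plaque structural stress log-normal around 60 kPa,
matching the tens-of-kPa scale of the representative case). Event labels come
from a logistic model on standardized features; `generate_cohort()`
rejection-samples to exactly 115 event-free and 19 event rows, the study's
class imbalance. The default effect vector makes plaque structural stress the
strongest predictor - the population structure the method was designed to
exploit - with moderate clinical effects around it. A single master seed
feeds per-component substreams (`substream_seed`), so changing one stage
never shifts another stage's draws.

# Boundary conditions

Only two printed Doppler landmarks constrain the inflow waveform: peak
systolic velocity (PSV) and end-diastolic velocity (EDV), with the cycle
duration `T = 60 / pulse rate`. The shape between the landmarks is not
published, so the package uses the simplest continuous periodic waveform
matching both: a half-sine systolic pulse of duration
`systolic_fraction * T` (default 0.3, exposed as a parameter rather than
guessed as truth) over a constant diastolic baseline, starting the cycle at
end-diastole. Velocity converts to mass flow pointwise via
`mdot = rho V A` with blood density 1050 kg/m^3; in 2D the measured site
area maps to an equivalent channel width times unit depth. Inflow enters as
a parabolic (Poiseuille-type) profile scaled to the target flux; the ECA
outlet receives the same treatment (a prescribed outflow profile), and the
ICA outlet is the traction-free, zero-gauge-pressure reference, with no-slip
walls.

# Flow solver

Transient incompressible Newtonian Navier-Stokes (viscosity 0.0035 Pa s) is
discretized with triangular Taylor-Hood elements (quadratic velocity, linear
pressure) - an inf-sup stable mixed pair - on a structured multiblock mesh
whose blocks share bit-identical interface nodes. Time stepping is implicit
Euler with per-step Picard linearization of convection, terminating at a
relative velocity-increment of 1e-4 or 150 iterations (the limit is logged,
not fatal: at peak systole through a tight stenosis the Reynolds number
reaches the physically unsteady regime and the stationary fixed point may
not exist). Adaptive under-relaxation handles limit-cycling iterations.

Numerical choices worth knowing:

* the default timestep is `T/50` in the pipeline configuration (`T/100` in
  the solver) - enough to resolve the systolic pulse at desk scale;
* three cycles are simulated by default and metrics use the final one. Two
  cycles were not enough: the start-from-rest transient decays on the
  channel viscous time `rho w^2 / mu`, comparable to one cardiac cycle, and
  the measured cycle-1-to-2 time-averaged wall shear difference was ~3%.
  With three cycles the last two agree within 2%;
* wall shear is a signed scalar (magnitude with streamwise sign), so the
  oscillatory-shear numerator/denominator distinction is meaningful in 2D;
* the solver's weak incompressibility residual and the inlet/outlet flux
  balance are recorded per step and asserted in the tests (<= 1e-6 and <= 1%).

Verification rests on plane-Poiseuille closed forms (centerline/mean = 1.5,
wall shear `6 mu U / h`, pressure drop `12 mu L U / h^2`), a creeping-flow
reversal test, and self-convergence of peak wall shear on a constricted
channel.

# Hemodynamic metrics

TAWSS is the per-point time average of |wall shear| over one cycle by
trapezoidal quadrature. The printed definition omits the magnitude bars, but
the 0.4 Pa atherogenic threshold and the OSI denominator only make sense for
the magnitude, so the magnitude convention is used. OSI is
`0.5 (1 - |mean tau| / mean |tau|)`, in [0, 0.5]; wall points with
identically zero shear get OSI 0 (the 0/0 resolved toward "no oscillation").
The feature set comprises peak and length-weighted vessel averages, the
normalized wall-length fractions below 0.4 Pa TAWSS and above the OSI
threshold (0.2 - never stated in print; a common literature cut, exposed in
configuration), and cycle-mean absolute pressure ratios of each outlet to
the inlet. Because the ICA outlet is the zero-gauge-pressure reference, the
ratios use absolute pressures: gauge plus a configurable diastolic reference
offset (default 80 mmHg). Whether the published ratios were systolic-peak or
cycle-mean is unstated; cycle-mean is the default and the alternative is one
argument away. The fraction of wall above 40 Pa is computed as a diagnostic
only - it is not part of the feature schema.

# Plaque structural mechanics

The cross-section problem is plane strain (standard for vessel
cross-sections; the published analysis says only "2D"), total-Lagrangian,
with polynomial Mooney-Rivlin materials
`W = sum C_ij (I1bar - 3)^i (I2bar - 3)^j + (1/d)(J - 1)^2` supporting
`i + j <= 3` so the printed arterial-wall constants (C10 = 0.07 MPa,
C20 = 3.2 MPa, C21 = 0.0716 MPa, d = 1e-5 1/Pa) and the five-parameter
fibrosis constants are representable verbatim. The second Piola-Kirchhoff
stress is derived analytically from `W` and verified against finite
differences to 1e-6 relative. With d = 1e-5 1/Pa the initial bulk modulus is
2/d = 0.2 MPa - comparable to the shear modulus, so the printed materials
are only mildly compressible and displacement-based quadratic triangles do
not lock.

Boundary conditions follow the published scheme: the outer perimeter is a
frictionless support, implemented as an exact constraint by rotating
outer-node dofs into tangent/normal components and fixing the normal one
(a penalty spring was tried first and abandoned: the stiffness needed to
keep the support rigid degraded the linear solves enough to stall Newton
near 1e-6 residuals). One tangential dof is pinned to remove the free rigid
rotation. The plaque is bonded to the wall by shared interface nodes. The
lumen carries the cycle-maximum absolute pressure from the flow stage as a
follower load on the deformed boundary. Loading proceeds in increments with
automatic halving; each increment runs Newton with a central-difference
element tangent and a backtracking line search, converging to 1e-6 relative
residual.

PSS is defined here as the maximum first principal Cauchy stress over plaque
elements and the cap band (wall elements between lumen and plaque) - the
publication never defines it mathematically - with the von Mises maximum
reported alongside for sensitivity. Mesh faces default to 0.05 mm at the op
level with graded half-size layers at the lumen and plaque interfaces
standing in for the published inflation layers (their counts/ratios are
unstated).

# Risk model

The classifier is gradient-boosted trees implemented from first principles:
base score at the training log-odds, pseudo-residuals `y - sigmoid(F)` under
logarithmic loss, depth-3 regression trees grown with Friedman's MSE
improvement score, leaf values refined by one Newton step (toggleable to the
literal least-squares leaf mean), learning rate 0.1, 100 stages. It is
cross-checked - never replaced - against scikit-learn's
`GradientBoostingClassifier` with identical hyperparameters: test AUC within
0.02 and median per-sample probability difference within 0.05 on synthetic
datasets.

The 70-30 stratified split assigns per-class floors to the training side, so
115/19 subjects reproduce the published partition (80, 13)/(35, 6). SMOTE
synthesizes minority rows as `x_i + u (x_nn - x_i)` with `u ~ U(0, 1)` over
`k = 5` minority neighbours (k is unstated in print; 5 is the standard
default, auto-reduced for tiny minorities), then rounds binary columns
half-up and clips - the printed rule says "rounded and clipped" without a
tie rule. Undersampling draws the majority class down to the minority count
without replacement. Cross-validation is stratified 5-fold with the
imbalance correction applied inside each training fold only - applying it
before folding leaks synthetic copies of validation points into training,
which is the arithmetic reason published per-fold tables on a pre-balanced
160-row set (folds of 32) look more optimistic than held-out results. Both
conventions are reachable: pass a pre-balanced set with method `"none"` to
reproduce the fold sizes of the published tables.

The aggregated test-table accuracy/recall/F1 are reproducible from printed
confusion matrices only as support-weighted averages (e.g. (32+4)/41 = 0.88
overall vs per-class recall 4/6), so the report carries both the macro
(balanced) and weighted variants and the aggregated table uses the weighted
ones. The decision threshold defaults to 0.5 (unstated in print; exposed).

# Attribution

Shapley values are computed on the log-odds scale (additive in the model's
natural output) with interventional marginalization over a fixed background
sample (capped at 100 rows): exact subset enumeration up to 15 encoded
features, and an unbiased permutation-sampling estimator with per-feature
standard errors beyond that. Efficiency, null-player and symmetry axioms are
tested exactly for the enumeration path; the sampled path is tested to agree
within three standard errors. Global importance is the mean |value| per
feature, ties broken lexicographically. The recovery experiment - cohorts
generated with a dominant PSS effect must put PSS at rank 1 in at least 90
of 100 seeded runs - is what passing tests actually demonstrate about the
attribution stage; no claim is made about matching any particular ranking
on real patients.

# Problem sizes and limitations

Default test and acceptance runs use coarse desk-scale sizes chosen once:
flow meshes around 1-4 thousand triangles (h_max 0.9-1.3 mm), 40-50 steps
per cycle, three cycles; structural meshes of 1-2 thousand quadratic
triangles; 100-tree ensembles on 134-subject cohorts; Shapley with 10-2000
permutations depending on the check. The op-level defaults keep the finer
anchored values (0.16 mm flow elements, 0.05 mm faces) for users with more
patience.

What the synthetic layer does *not* emulate: real lumen segmentations (no
MRI, no 3D), plaque composition heterogeneity (lipid, hemorrhage,
calcification - only wall and fibrous-plaque materials are published),
fluid-structure coupling, non-Newtonian rheology, and any correlation
structure between imaging and clinical covariates beyond the generative
logistic model. Passing tests therefore demonstrate correct equations,
arithmetic and recovery behaviour under known ground truth - not clinical
performance. The published headline classification numbers were obtained on
a 134-patient dataset that is not distributable; the package reproduces
their arithmetic (confusion-matrix metrics, split counts, fold means)
exactly, and everything else as properties.
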