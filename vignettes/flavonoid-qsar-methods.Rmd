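---
title: "Methods: linear and neural-network QSAR models of flavonoid ORAC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linear and neural-network QSAR models of flavonoid ORAC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flavqsar)
```

## The modelling problem

The oxygen radical absorbance capacity (ORAC) of a flavonoid measures how
many peroxyl radicals it can scavenge, in Trolox equivalents.  Mechanistic
theory says this capacity is controlled by the enthalpies of the elementary
steps available to the phenolic O–H groups: homolytic cleavage
(BDE<sub>min</sub>(1), the HAT pathway), deprotonation followed by electron
transfer (PA(1) and ETE(1), the SPLET pathway), and — because the assay runs
in water and SPLET proceeds through an ion pair — the hydration energy HE.
The package regresses ln(ORAC) on these four descriptors for the bundled
36-compound set, using a linear and a non-linear model, and then interprets
both.

Activities are modelled on the natural log scale (the raw ORAC distribution
is strongly right-skewed).  The bundled table stores ln(ORAC) directly, with
the reported replicate standard deviations carried along but never used as
fitting weights (all fits are unweighted).  A structural fact about the
bundled descriptors worth knowing: PA(1) + ETE(1) − BDE<sub>min</sub>(1) is
the same constant (38.818 kcal/mol) for every compound, because the three
descriptors share their proton/electron/hydrogen-atom reference enthalpies.
The centred descriptor matrix is therefore rank 3 up to the tables' 0.001
rounding noise, and four-component fits or hat-matrix inversions operate on
an ill-conditioned (though numerically non-singular) matrix.  This is a
property of the data, not of the implementation; the PLS model selected by
cross-validation uses 2 latent variables and never probes that direction.

## Data splitting

The linear model uses the Kennard–Stone max–min algorithm to pick a
space-covering training set: distances are Euclidean on the autoscaled
descriptors (the metric space is a modelling choice; autoscaling keeps any
one kcal/mol-scaled descriptor from dominating), the seed pair is the most
distant pair of compounds, each later pick maximises its minimum distance to
the selected set, and ties break deterministically to the lowest row index.
With 25 of 36 compounds selected, the remaining 11 form the external
validation set.  Response values play no role in the selection.

The neural-network protocol instead re-draws a uniformly random, disjoint
26/5/5 partition every cycle, so that across 1000 cycles each compound is
trained on in roughly 72% of the cycles and predicted out-of-train in the
rest.

## The PLS model

`qsar_pls()` autoscales both descriptors and response (standard deviations
use the n−1 divisor) and runs de Jong's SIMPLS: latent variables are
extracted by deflating the descriptor–response cross-product vector against
an orthonormal basis of loading directions.  At full rank the coefficients
equal ordinary least squares (a property the test suite checks against
`lm()`), and the reported coefficients are standardised, which makes their
magnitudes comparable across descriptors; `coef(fit, raw = TRUE)` converts
to raw units.

The number of latent variables is chosen by leave-one-out cross-validation
over 1 to 4 components.  Scaling parameters are re-estimated inside every
fold — the held-out compound contributes nothing to the fold's model — and
RMSECV is the root mean square of the held-out residuals.  On the bundled
training set the minimum is at 2 latent variables, and all four standardised
coefficients are negative, matching the mechanistic expectation that lower
barriers and stronger hydration raise ORAC.

Model significance is summarised by a cross-validated variance ratio: the
mean squared LOO residuals of the mean-only null model over those of the
fitted model, referred to the upper F tail with the residual counts as
default degrees of freedom.  Jackknife (leave-one-out) standard errors of
the standardised coefficients, times the t quantile at N−1 degrees of
freedom, give the coefficient confidence half-widths.  Two caveats worth
stating plainly: the half-widths are on the standardised scale and remain
finite even for noiseless data, because the scaling itself is refit on every
jackknife subset (the raw-unit coefficients *are* recovered exactly in that
case); and the variance-ratio convention here is one of several in use, so
its absolute value should be compared across models fitted by this package,
not across software.

## The neural-network model and its training protocol

The non-linear model is a single-hidden-layer perceptron — four inputs,
eight tanh hidden neurons, one linear output; 49 trainable parameters.
Inputs and targets are min–max scaled to [−1, 1] on each cycle's training
set, which matches the saturation range of tanh.  Weights initialise
uniformly in [−0.5, 0.5] with zero biases, from per-cycle seeds spawned
deterministically from the master seed.

Training is Levenberg–Marquardt: damped Gauss–Newton steps on all weights,
accepting a step only when the training sum of squares decreases (damping
÷10 on acceptance, ×10 on rejection), stopping at 1000 epochs, at a 1e−7
gradient norm, when the damping exceeds 1e10 (a local minimum), or when the
5-compound test set's error has risen on six consecutive evaluations.  The
test set is thus the early-stopping monitor; the validation set is never
seen during training.  The trained network returned is the one holding the
weights at termination.  We examined the alternative of rewinding to the
epoch with the lowest stop-set error and rejected it: with only five
stop-set compounds that minimum falls very early and systematically returns
underfit networks (mean training RMSE ≈ 0.35 instead of ≈ 0.15), while the
patience rule already prevents runaway overfitting.  Divergent cycles
(non-finite loss) are dropped and counted; protocol statistics require at
least 95% completed cycles.

### Two views of the protocol errors

For every cycle the protocol records the training RMSEE and the test and
validation RMSEPs of that cycle's network; it also records every compound's
prediction in every cycle.  These support two different summaries:

* **per-cycle means** — the average of the 1000 single-network errors.  The
  out-of-train ones (test ≈ 0.80, validation ≈ 0.89 ln units at the default
  seed) measure true generalisation of a single 26-compound fit, and they
  are consistent with the five-fold cross-validation error (≈ 1.0): with 36
  compounds and a flexible network, predicting genuinely unseen flavonoids
  is hard.
* **cycle-averaged predictions** — each compound's mean prediction over all
  cycles (the ensemble view; most cycles had the compound in training).
  The RMSE of these averages is far smaller (≈ 0.2 over all compounds)
  because in-train predictions dominate each average.  This view is the one
  that makes per-compound error bars meaningful, but it must not be read as
  an out-of-sample error.

Both are reported in the fitted object (`$summary`, `$ensemble_rmse`,
`$predictions`) precisely because conflating them overstates a small
data set's predictive power.

Five-fold cross-validation of the network (`kfold_cv_ann()`) trains on four
folds with a small internal stop split and predicts the held-out fold, so
each compound is predicted exactly once per repetition; on 36 compounds it
is a deliberately harsh benchmark that the resampling protocol should beat,
and does.

## PaD interpretation

The partial-derivative method differentiates the trained network
analytically: for tanh hidden units and a linear output,
∂ŷ/∂x<sub>j</sub> = Σ<sub>i</sub> w<sup>ho</sup><sub>i</sub>
(1 − tanh²(a<sub>i</sub>)) w<sup>ih</sup><sub>ij</sub>, with the min–max
scaling Jacobians folded in so derivatives come out in raw units (ln ORAC
per kcal/mol).  Raw units make derivative-versus-descriptor scatter plots
physically readable; note that the normalised SSD ranking is invariant to
rescaling the output but *not* to per-input rescaling, so the raw-unit
convention is fixed and documented rather than optional.  Derivatives are
evaluated at all 36 bundled compounds for every cycle, each cycle's SSD
vector is normalised to sum to one, and cycles are averaged with equal
weight (the mean then still sums to one).  The test suite verifies the
analytic derivatives against high-order finite differences on random
networks, and the linear-regime closed form (normalised SSD equals the
squared effective linear coefficients) as a limiting case.

At the default seed the aggregate ranking is PA(1) ≈ 0.47 > HE ≈ 0.41 ≫
BDE(1) ≈ 0.08 > ETE(1) ≈ 0.05: proton affinity governs, hydration energy is
second — the SPLET-plus-solvation picture — and the two remaining
descriptors contribute little, with their mutual order inside one standard
deviation of each other across cycles (and sensitive to the derivative-unit
convention).  Most proton-affinity derivatives are negative or zero, the
expected direction.

## Applicability domain

Leverages are the diagonal of X₂(X₁ᵀX₁)⁻¹X₂ᵀ with both matrices autoscaled
by the training parameters; no intercept column is added (the matrices are
centred), yet the conventional warning limit keeps its K+1 numerator,
h* = 3(K+1)/N — with K = 4 descriptors this gives 0.600 for the 25-compound
PLS training set and 0.577 for the 26-compound network cycles.  Residual
warnings use standardised residuals (centred, unit-sd) beyond ±3.  For the
network protocol, leverages against each cycle's training subset and each
cycle's standardised residuals are averaged over cycles before flagging, so
the domain reflects the protocol rather than any single network.  Averaging
per-cycle standardised residuals is a conservative choice: a compound must
be mispredicted *relative to its peers* consistently across cycles to
approach the ±3 limit, and on the bundled data only the leverage flag fires
(tectochrysin, mean leverage 0.82 — by far the most extreme descriptors in
the set).  Epicatechin shows the largest residual (its cycle-averaged
standardised residual ≈ 2) without crossing the hard ±3 limit.

## Thermochemistry bookkeeping

The descriptor definitions are fixed enthalpy differences (BDE, PA, ETE,
IP, PDE as written in `?descriptor_enthalpies`; HE as the aqueous-minus-gas
enthalpy of the neutral parent, which is what makes every bundled HE
negative).  The reference constants are the gas-phase proton and electron
enthalpies (1.481 and 0.752 kcal/mol) and their water-phase counterparts
(−250.574 and −17.816 kcal/mol); the water hydrogen-atom enthalpy is fixed
by the 38.818 identity of the bundled table, the gas value by the hydrogen
atom's electronic-plus-thermal enthalpy.  Pathway assembly telescopes the
HAT/SPLET/SETPL steps from one species set, so steps always sum to the
overall reaction enthalpy exactly and the overall value is
mechanism-independent by construction; the bundled genistein/quercetin step
table closes its Hess cycles within 0.15 kcal/mol, the tolerance implied by
one-decimal rounding of two addends.  Species enthalpies are *inputs* here:
the package deliberately contains no electronic-structure or solvation
computation, and the bundled species sets are synthetic anchors
reconstructed from the printed step enthalpies (absolute enthalpies are not
recoverable from differences, so arbitrary anchors are documented as such).

## Combinatorial design

Flavone has ten aromatic C–H sites (3; 5–8; 2′–6′).  Because the B ring
rotates freely, patterns related by the 2′↔6′/3′↔5′ mirror are the same
molecule; enumeration therefore counts mirror orbits, and 1–3 hydroxyls give
115 distinct structures (175 raw subsets; the suite cross-checks the orbit
count by brute force).  SMILES are emitted from a fixed template and the
formula follows by substitution arithmetic (C15H10O(2+k)).  Predicting the
designs' activities requires their quantum-chemical descriptors, which must
be supplied by the user — the package's contract is the enumeration and the
frequency bookkeeping (counting hydroxyl positions among high- and
low-predicted designs), with the prediction step pluggable.

## Synthetic data and what the tests show

`generate_dataset()` draws the four descriptors from independent normals
whose means and standard deviations default to the bundled table's column
statistics, and builds the activity as a linear term plus an optional
bounded non-linearity, γ·tanh(δ·z<sub>PA</sub>), plus Gaussian noise —
smooth, saturating, and centred on the proton-affinity axis, mimicking the
saturating derivative trends seen on the real data.  Defaults: γ = 1,
δ = 2, noise sd 0.1 ln units (about the replicate noise scale of a careful
assay, and small against the ~1.0 spread of the bundled activities), and
negative linear coefficients mirroring the real model's signs.

What the generator does *not* emulate: the strong mutual correlation of the
real descriptors (including the exact PA+ETE−BDE identity), the skewness of
real activity distributions, and any structure–descriptor coupling.
Passing recovery tests therefore demonstrate that the estimators are
implemented correctly (coefficients recovered within their confidence
intervals, noise floors reached, the network beating the linear model when
the truth is non-linear) — not that the bundled 36-compound models
generalise to new chemistry.

## Reproducibility and numerical choices

Every stochastic function takes an explicit seed; protocol-level functions
spawn per-cycle seeds from a master seed, so reports are bit-reproducible.
Default problem sizes used by the package's own analyses: 1000 resampling
cycles for protocol statistics, 20 repetitions of five-fold CV, 50 seeds
for the synthetic coverage study — each chosen so the Monte Carlo error is
well below the standard deviations being reported.  Tolerances: SIMPLS rank
deficiency is declared below a 1e-10 score norm; Hess closure of printed
tables at 0.15 kcal/mol; the descriptor identity at 0.002 kcal/mol (the
rounding of three three-decimal addends).  Kennard–Stone ties and
max–min ties resolve to the lowest row index; mechanism-comparison ties
break alphabetically.  Degenerate inputs are flagged rather than fatal
where a flag is more useful (all-zero PaD matrices, zero-spread residuals),
and fatal where silence would corrupt results (zero-variance descriptor
columns, rank-deficient leverage computations, non-finite training loss).

## Known limitations

* Thirty-six compounds is a small modelling set; the honest out-of-sample
  error of the network protocol is the per-cycle one (~0.8 ln units), and
  the applicability domain should be consulted before trusting any
  prediction.
* The published study that this data set reproduces reports smaller
  external errors for its network model than any disjoint-split protocol
  can achieve on these data; its printed per-compound means are consistent
  with cycle-averaged predictions, which is why this package reports both
  aggregations explicitly and labels them.  Likewise its exact
  training/validation split membership for the linear model is not
  recoverable, so external-set error levels differ from the printed ones
  even though the model itself (2 latent variables, all-negative
  coefficients, identical critical leverages) reproduces.
* Descriptors for new compounds must come from the user's own
  quantum-chemistry pipeline, computed at a level consistent with the
  bundled values.
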