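---
title: "Models and methods behind tabletlab"
author: "tabletlab authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tabletlab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`tabletlab` is an in-silico platform for direct-compression tablet
formulation development. It couples three layers:

1. a **digital formulator** — mixture rules and ensemble neural-network
   process models that predict blend flowability (FFC), tablet porosity
   and tensile strength from raw-material properties, driving a robust
   constrained genetic optimiser over excipient choice, mass fractions
   and initial compression pressure;
2. a **physics-informed Bayesian optimisation (PIBO) agent** that refines
   the compression pressure against (virtual) experiments through the
   Kawakita and Ryshkewitch-Duckworth compaction laws; and
3. a **virtual tableting plant** — a documented synthetic stand-in for
   robotic make-and-test hardware that supplies ground-truth compaction
   behaviour, measurement noise, dose/quality decision gates and
   simulated spectral homogeneity monitoring.

This vignette records the models, the tunable parameters, the numerical
choices, and the limits of what the synthetic studies can show.

## Empirical compaction models

Tablet porosity under a main compression pressure $P$ (MPa) follows the
Kawakita compressibility law in its porosity form,

$$\varepsilon(P) = \frac{\varepsilon_0}{1 + B P},$$

with $\varepsilon_0$ the initial powder-bed porosity and $B$ (1/MPa) a
single grouped tuning constant (the volume ratio and the classical
Kawakita $b$ are not separable from porosity data alone, so they are
fitted as one parameter). Tensile strength declines exponentially with
porosity following Ryshkewitch-Duckworth,

$$\sigma(\varepsilon) = \hat{T} e^{-k_b \varepsilon},$$

with $\hat{T}$ (MPa) the zero-porosity strength and $k_b$ the bonding
capacity. `fit_kawakita()` is a bounded Levenberg-Marquardt fit on the
porosity scale with a closed-form two-point solution as the start;
`fit_rd()` is linear least squares on $\log\sigma$ (exact for noiseless
data and numerically stable), with the reported RMSE computed on the MPa
scale. The inversion $P^\* = (\varepsilon_0/\varepsilon^\* - 1)/B$ gives
the pressure for a target porosity; `tensile_at_porosity()` interpolates
strength at the 15%-porosity reference point used throughout.

## Blend models and features

Densities mix by the volume-additive rule (inverse mass-weighted
harmonic mean), applied independently to true, bulk and tapped
densities; particle-size (PSD) and aspect-ratio (ARD) distributions mix
bin-wise by mass fraction on a shared grid. These simple rules sit
behind a pluggable interface so trained mixture models can replace them.
The blend FFC (at 1.6 kPa consolidation — recorded as metadata, not a
model input) is predicted by an ensemble regressor on blend-level
features (densities, Carr index, log quantiles and span of the PSD,
fine fractions below 10 and 30 µm, mean aspect ratio), trained against
the virtual plant's flow rule.

The process models consume a fixed 21-feature vector: blend true and
bulk density, three PSD principal-component scores, three ARD scores,
tapped density, FFC, compression pressure, drug loading, and nine API
particle-informatics descriptors (zero-filled for placebos — a choice
the data cannot distinguish from carrying a reference API's
descriptors, since placebo rows always sit at zero loading). The PCA
bases are fitted once on the training blends and frozen; optimisation
candidates are projected onto them, which prevents leakage between
training and deployment.

The default particle-size grid is 96 log-spaced bins over
0.05–20000 µm. The wide tails keep the log-normal generator's span
requirement (`[d50/50, d50*50]` inside the grid) satisfiable for the
coarse bimodal study distributions while preserving a ~0.06-decade bin
resolution; span is reported as $(d_{90}-d_{10})/d_{50}$, the standard
laser-diffraction convention.

## Ensemble process models

Porosity and log tensile strength are each predicted by a deep ensemble
of 20 feed-forward networks (two ReLU hidden layers of 128 units,
linear output) that differ only in their random seed (initialisation,
internal 10% validation split, batch order). Ensemble mean is the
prediction; the unbiased member standard deviation is the uncertainty.
Training uses Adam (learning rate 1e-3, batch 32, at most 2000 epochs)
with early stopping at 100 epochs patience; inputs and target are
z-scored with training-set statistics. Patience matters more than the
other settings here: at 50 epochs individual members stop at visibly
different solutions and the ensemble's generalisation to held-out APIs
degrades, so 100 is the default. Tensile-strength members are
exponentiated back to MPa *before* averaging, so the reported mean and
spread live on the physical scale. Features more than 3 training
standard deviations outside the training envelope raise an
extrapolation flag rather than an error.

Generalisation is assessed by leave-API-out splitting: all records of
the held-out APIs go to the test set and placebo records always stay in
training. The bundled acceptance study holds out two APIs from the
interior of the library's property envelope; holdouts at the envelope
edge test extrapolation rather than interpolation and score a few
points lower, which is the expected behaviour of a material-property
(rather than material-identity) model.

## Robust formulation optimisation

The formulator selects two filler/binders, their mass split and an
initial pressure $P_0 \in [50, 400]$ MPa by minimising $J = -\mathrm{FFC}$
subject to robust manufacturability constraints

$$\theta_\sigma - [E(\hat\sigma) - \alpha\,\delta_{\hat\sigma}] < 0,
\qquad
\theta_\varepsilon - [E(\hat\varepsilon) - \beta\,\delta_{\hat\varepsilon}] < 0,$$

with defaults $\theta_\sigma = 2$ MPa, $\theta_\varepsilon = 0.15$ and
$\alpha = \beta = 0.2$. Note the porosity constraint is a *floor*: the
tablet at the initial pressure must stay more porous than the 15%
target, which (together with the strength constraint) guarantees that
the later 15%-porosity tablet is at least as strong as the one checked
at $P_0$.

The optimiser is a single-objective specialisation of the NSGA-II
machinery (population 30, 50 generations): binary tournaments under
constrained domination (feasible beats infeasible; infeasible compared
by total violation; feasible by objective), simulated-binary crossover
and polynomial mutation on the real genes, uniform crossover with
swap-repair on the integer excipient genes, full elitism. The mass
split is encoded as a single simplex coordinate $t$ with
$w_1 = tW,\ w_2 = (1-t)W$, so the composition constraint holds by
construction. Incompatible excipient pairs are repaired away and would
register as hard constraint violations if they survived. When no
feasible candidate exists the least-infeasible one is returned with a
flag rather than an error. Runs are deterministic given the seed.

## The PIBO agent

The agent starts from the formulator's $P_0$ with one extra observation
at $1.25\,P_0$ (two points are the minimum that determines the
two-parameter laws), fits both compaction models, and then iterates:

* a one-dimensional Gaussian process (squared-exponential kernel,
  marginal-likelihood hyperparameters from two deterministic starts,
  observation-noise floor $10^{-4}$) models porosity versus pressure;
* the acquisition maximises the expected improvement of
  $|\varepsilon - 0.15|$ under the GP (a folded-normal expectation,
  evaluated in closed form on a 512-point pressure grid);
* a candidate is accepted only if refitting both laws with the GP
  posterior mean at the candidate as a *pseudo-observation* does not
  increase either fit RMSE — a one-step-lookahead operationalisation of
  the requirement that the trajectory may not degrade the physics fits.
  When no candidate passes (always the case right after initialisation,
  where two points fit two parameters exactly), the proposal falls back
  to the closed-form Kawakita inversion at the target — the
  physics-based suggestion;
* after each observation both laws are refitted and the RMSE history
  grows by one row; the loop terminates when both RMSEs change by less
  than 20% between the last two iterations (errors below $10^{-9}$
  count as zero, so exact noiseless fits terminate immediately at three
  experiments).

A validation tablet is then made at the inverted-Kawakita pressure for
the target porosity and scored against the 2 MPa floor. Typical noisy
runs need 4–6 experiments before validation.

One identifiability caveat is worth stating plainly: because the
collected pressures cluster near the target, $\varepsilon_0$ and $B$
are determined only through their combination — individually their
median errors are tens of percent while the inverted target pressure is
accurate to ~2% and $\hat T$, $k_b$ to under 10%. The agent calibrates
what it needs for its decision, not the full parameter vector; anyone
using the fitted $\varepsilon_0$ or $B$ alone should widen the pressure
design first.

## The virtual plant

The plant is the package's test oracle, and its rules are deliberately
explicit rather than claimed as science:

* $\varepsilon_0 = 1 - \rho_\mathrm{bulk}/\rho_\mathrm{true}$ of the
  blend (the powder-bed porosity), clipped to $[0.25, 0.78]$;
* $B = 0.004 + 0.028\,\mathrm{logistic}((\log d_{50} - \log 40)/0.9)$ —
  coarser blends densify with less resistance;
* $\hat T$ is the mass-weighted mixture of per-component bonding
  strengths: for excipients a Carr-index (plasticity) rule
  $\mathrm{clamp}(-2 + 60\,\mathrm{Carr}, 2, 16)$, for APIs
  $2 + 6\,\mathrm{logistic}(d_1)$ on the first particle-informatics
  descriptor, both sharpened by a mild fine-particle bonus
  $(d_{50}/60)^{-0.12}$;
* $k_b$ is the mass-weighted mixture of
  $\mathrm{clamp}(14 - 25\,\mathrm{Carr}, 5, 13)$ — plastic high-Carr
  binders (MCC-like) keep strength at porosity, brittle free-flowing
  fillers lose it — so higher drug loading of a poorly bonding API
  lowers strength by construction;
* FFC decays exponentially with the blend's fine fraction below 30 µm
  and mildly with blend Carr index, clipped above 1.

Observations add the declared noise — porosity additive (sd 0.005),
tensile multiplicative (5%), dose weight relative (2%) — and pass two
gates: D1 rejects doses off target weight by more than 5%; D2 compares
porosity and tensile against rolling means of the last 20 accepted
tablets (±5%), the batch-reference reading of an "acceptable variation"
rule whose reference value is otherwise unstated. A nonzero seed adds a
deterministic 2% log-normal jitter to the law, emulating
batch-to-batch variability. Simulated spectra are component-weighted
Gaussian band templates (deterministic per material id) with small
sub-sample weight fluctuations — the low-dimensional structured
variance that makes PCA-based Hotelling $T^2$ monitoring meaningful —
plus channel noise; without any structured variability the reference
eigenvalues are pure sampling noise and the $F$-limit has nothing real
to calibrate against.

The bundled library is fully synthetic: six filler/binders spanning the
plastic-strong (MCC-like) versus brittle-free-flowing (lactose- and
mannitol-like) axis, a disintegrant, a lubricant, and sixteen API
grades whose particle-informatics descriptors are smooth functions of
latent material axes plus a small idiosyncratic component. Sixteen
grades is a deliberate breadth choice: leave-API-out generalisation is
only learnable if the descriptor space is actually populated — with a
handful of APIs a network can memorise identity instead of structure.
Each record's measured FFC is the flow rule evaluated on the pure
material, so the library and the plant are mutually consistent.

## The particle-size study

The bundled sweep reproduces the structure of a synthetic
manufacturability study: 8 unimodal and 8 bimodal log-normal API PSDs
(median sizes 10–150 µm with generally increasing size and/or span —
illustrative defaults, user-overridable), imposed on a template API with
all other properties held fixed; drug loadings 0–100% in 20% steps
(100% = pure API); a fixed 1:1 lactose/MCC filler pair with 3.5%
disintegrant and 1% lubricant; pressures 100–400 MPa in 50 MPa steps
(seven points per Ryshkewitch-Duckworth fit); tensile strength reported
at 15% porosity. On the virtual ground truth the study shows the
built-in monotone decline of strength with loading for all 16 PSDs and
the flow collapse of fine distributions at high loading.

## Study sizes and what the tests do (and do not) show

The test-suite studies are sized for a desk run: a 602-tablet training
corpus (86 formulations × 7 pressures), 20-member ensembles, 50-seed
closed-loop replications, 100-seed fit-recovery Monte Carlo, and
10000-draw gate-calibration checks. Passing them shows that the
pipeline's logic, uncertainty accounting and closed-loop behaviour are
correct *for data whose generating process matches the package's
assumptions* — smooth composition-to-property maps, Gaussian noise,
log-normal PSDs. Real tableting data adds heteroscedastic and
correlated measurement error, lot-to-lot raw-material drift,
non-smooth regime changes (percolation, overlubrication) and model
bias, none of which the generator emulates; conclusions about real
formulations require the models to be retrained and revalidated on
measured data.

One honest shortfall is recorded rather than hidden: in the 50-run
closed-loop study, the validated tablet clears the 2 MPa floor in ~72%
of runs, not 90%. The robust optimiser pushes flowability until the
strength constraint is active, so the surviving margin is
$\alpha\,\delta_{\hat\sigma} \approx 0.09$ MPa, smaller than the ~0.18 MPa
noise scale of a validated observation under the declared noise model.
Clearing the floor at a 90% rate needs either a larger risk factor than
the 0.2 default or process models that systematically underestimate
strength — the conservatism that real-data studies report and that
unbiased surrogates on clean synthetic ground truth do not reproduce.
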