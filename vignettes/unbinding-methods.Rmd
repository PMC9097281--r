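---
title: "Models and methods behind unbindkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind unbindkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unbindkit)
```

`unbindkit` studies how a ligand leaves a binding pocket, at desk scale:
every simulation runs on analytic model potentials rather than an
all-atom force field, so that each stage of the methodology — iterative
collective-variable (CV) discovery under a ramped harmonic bias, string
refinement with binless-WHAM free-energy profiles, and machine-learning
transition-state analysis (MLTSA) — can be exercised, tested and
understood in minutes on one CPU. This vignette records the models, the
tunable parameters, and the design decisions; everything quantitative
stated here is computed by the package's test suite or by
`scripts/acceptance.R`.

## 1. Dynamics engine

All sampling uses overdamped Langevin dynamics integrated with the
first-order Euler–Maruyama scheme,

$$x_{t+1} = x_t - \frac{\Delta t}{\gamma}\nabla \big(V + U_\text{bias}\big)(x_t)
  + \sqrt{2 k_B T \Delta t / \gamma}\,\xi_t,$$

the simplest scheme consistent with diffusive barrier crossing. The
friction $\gamma$ may be a per-coordinate vector: different degrees of
freedom in a binding site have very different mobilities, and the
analytical benchmark exploits this (below). A divergence guard aborts
when any $|x|$ exceeds $10^3$ domain units, which in practice signals a
step size too large for the local stiffness ($k\,\Delta t/\gamma
\gtrsim 2$). `kT = 0` reduces the engine to deterministic gradient
descent, which the tests use as a fixed-point oracle.

Potentials are closures with analytic gradients: harmonic single wells,
the quartic double well $V(x) = h\,((x/w)^2 - 1)^2$ (minima $\pm w$,
barrier $h$ at the crest), a 2D binding-pocket surface, and products of
independent 1D potentials. The pocket is a Gaussian well at the origin
(the bound state) plus a Gaussian barrier ridge on the $+x$ axis and a
weak transverse harmonic confinement; its minimum-energy path (MEP) is
the $x$ axis by symmetry and its barrier is known by a dense 1D scan, so
the string method can be tested against an exact answer.

The detailed-balance property — long-run histograms converging to
$e^{-V/k_BT}$ — is asserted by a Kolmogorov–Smirnov test against the
analytic Gaussian for a harmonic well (samples thinned to roughly one
correlation time) and by comparing double-well basin occupancies with
numerical quadrature of the Boltzmann weights.

## 2. Iterative unbinding protocol

The CV-discovery loop treats a contact as a distance between the mobile
particle (ligand proxy) and a fixed anchor (protein-atom proxy), in Å:

* inclusion: a pair is a stable contact when its distance is below
  $d_\text{in} = 3.5$ Å for strictly more than half of the evaluated
  frames;
* the main CV is the *sum* of the active distances, biased harmonically
  with force constant $k = 20$ kcal mol⁻¹ Å⁻² toward
  $D = D_0 + M\,d_\text{tar}$ ($M$ active distances,
  $d_\text{tar} = 1$ Å), the center ramped linearly over the iteration;
* removal: after each iteration a contact is dropped when its mean over
  the evaluation window exceeds $d_\text{out} = 6$ Å or its variance
  exceeds $d_\text{var} = 1$ Å²;
* termination: the loop ends when no active contact remains, i.e. the
  particle sits outside the pocket.

Three wordings in this protocol are genuinely ambiguous and were fixed
as follows, each with a configuration switch. The removal check uses
the *windowed mean* rather than "any frame" (robust to single-frame
spikes; `removal_mode = "any"` restores the literal reading). The
dispersion cutoff is interpreted as a variance of 1 Å² even though a
threshold quoted in Å reads like a standard deviation
(`var_mode = "sd"` switches). The evaluation window is the last half of
each iteration, matching the original prescription of re-evaluating
over the trailing half of the sampling. Iteration lengths are counted
in engine frames (default 10,000 per iteration, window 5,000) because
the toy engine has no nanosecond clock; the tests run shorter
iterations (1,200–3,000 frames) which terminate in well under the
25-iteration guard on the shipped pocket.

Equivalent anchors (e.g. the two oxygens of a carboxylate, which a bond
rotation interconverts) can be merged into a center-of-mass pseudo-site
with `merge_equivalent()`; groups are user-declared because detecting
rotational equivalence needs chemical topology that the toy systems do
not have.

## 3. String refinement and binless WHAM

The unbinding trajectory seeds a string of windows (default 100;
25–30 in the tests) placed equidistantly in arc length along a smooth
per-CV polynomial fit of the CV series. Each refinement iteration
samples every window under per-CV harmonic restraints
(20 kcal mol⁻¹ Å⁻²) at the node centers, refits an order-8 polynomial
per CV to the sampled window means, and re-places the nodes
equidistantly. Convergence requires, for every CV, a maximal node
displacement below 7% of that CV's path range *or* below 0.3 Å; the
relative threshold is taken against the path range (not the CV value)
because a range-free percentage is ill-defined for CVs that cross zero.
Window samplers warm-start from the coordinates recorded at the nearest
CV-space frame, then from the previous iteration's last frame.

Unbiasing uses the binless weighted-histogram estimator: with
$u_i(x_n)$ the bias energy of pooled sample $n$ under window $i$'s
restraint, the window free energies solve

$$e^{-f_i/k_BT} = \sum_n \frac{e^{-u_i(x_n)/k_BT}}
 {\sum_j N_j e^{(f_j - u_j(x_n))/k_BT}},$$

and the unbiased sample weights are the common denominators,
normalised. The solver first maximises the (convex) likelihood directly
with L-BFGS-B and then polishes with self-consistent sweeps to a
tolerance of $10^{-7}$ on $\max_i |\Delta f_i|$, in the gauge
$f_1 = 0$; a pure self-consistent mode is available. All arithmetic is
in log space. An overlap matrix (correlation of the windows' biased
weight vectors) diagnoses disconnected windows.

The potential of mean force is reported along the normalised string
coordinate: every sample is assigned to its nearest node, the profile
is $-k_BT\ln\sum w_n$ per window, zeroed at the bound-side minimum, and
the barrier is the profile maximum. Standard errors divide each
window's samples into four contiguous subgroups and recompute the full
estimate per subgroup (SE = sd/2). Estimation is binless; the window
assignment is display binning only. Transition-state candidates are the
five highest-energy windows as a contiguous block around the maximum
(ties resolved toward the bound state), and the working TS is the
candidate whose unbiased downhill trajectories give an IN fraction
closest to 1:1 (exact ties to the higher-energy candidate).

Oracles: a two-window Gaussian case with quantile-deterministic samples
must match the closed-form $\Delta f = \tfrac{k_BT}{2}\ln(k_2/k_1)$
within $10^{-3}\,k_BT$; umbrella sampling on harmonic and double-well
potentials must reproduce the analytic potential within $0.2\,k_BT$
over the sampled range (compared against the bin-integrated Boltzmann
reference, since a histogram estimates bin-averaged free energies).

## 4. The analytical MLTSA benchmark

The benchmark emulates the situation MLTSA is built for: many observed
CVs, few of which carry the coordinate that decides the outcome.

**Latent dynamics.** 25 independent 1D coordinates: one decisive quartic
double well ($h = 7\,k_BT$, minima $\pm 2$, $\gamma = 1$) and 24
harmonic wells with distance-like centers drawn from 2–8 Å. Every
trajectory starts at the decisive crest with the noise coordinates at
equilibrium, runs 500 steps of $\Delta t = 0.01$, and is labelled
IN/OUT by the decisive coordinate's final basin (a final frame exactly
at the crest counts IN; a measure-zero tie). With these constants the
decisive coordinate commits around step 40 — inside the training window
of steps 30–60 — and recrosses after commitment in well under 1% of
trajectories, so labels are stable but early frames are genuinely
ambiguous: the window is accurately solvable without being trivial,
which is the criterion that fixed these defaults.

The 24 noise wells split into two mobility classes, mimicking a real
binding site where solvent-exposed distances fluctuate rapidly with
large amplitude while buried contact geometries drift slowly within a
narrow range:

* *soft/fast*: $k = 0.15$, $\gamma = 0.02$ — amplitude
  $\sqrt{k_BT/k} \approx 2.6$, relaxation $\gamma/k \approx 13$ steps;
* *stiff/slow*: $k = 40$, $\gamma = 12$ — amplitude $\approx 0.16$,
  relaxation $\approx 30$ steps (quasi-static over the window).

**Observation model.** 180 features, each an L1-normalised linear
combination (coefficients sum to 100%). Exactly 11 features carry the
decisive coordinate with coefficient $\alpha$; their remaining weight
is spread equally over three soft noise coordinates, so a feature's
signal-to-noise ratio increases monotonically with $\alpha$. The
$\alpha$ values are tiered — three features evenly spaced in 0.71–0.80
and eight spread over 0.35–0.62 — mirroring the reported pattern of a
few strongly correlated CVs over a tail of weak ones (reported
coefficients start near 34%). Uncorrelated features mix three noise
coordinates of either class. Uniform-random alphas and random noise
weights remain available (`make_mixing(alpha_mode = "uniform",
noise_weights = "random")`) but make feature rankings a tie-break
lottery, because the ranking signal is then not monotone in $\alpha$.

**Why the two noise classes matter.** The stiff coordinates give every
trajectory a small, slowly varying offset fingerprint. Tree ensembles
are scale-invariant and threshold finely, so the GBDT interpolates
these fingerprints and pushes its *test* accuracy (frames from seen
trajectories) near 99% while its *validation* accuracy (unseen
trajectories) stays at the information limit — the characteristic
test/validation split of the reference results. The MLP reads raw,
unstandardised inputs with an L2 penalty, so exploiting a
0.16-amplitude feature would need large first-layer weights; it stays
closer to the information limit on both sets. The soft coordinates make
the correlated features genuinely noisy views of the decisive
coordinate, so the MLP spreads its reliance across the whole $\alpha$
ladder — which is what the global-mean swap measures.

**Classifiers.** The MLP is a single hidden layer of 100 rectified
linear units with a logistic output, trained by minibatch Adam
(learning rate 0.001, batch 200, Glorot-uniform init, L2 $10^{-4}$) for
at most 500 epochs, stopping after 10 consecutive epochs improving the
loss by less than $10^{-4}$. It is implemented in the package because
no installed R package offers this exact ReLU+Adam architecture; the
logistic+BFGS single-hidden-layer network from `nnet` corroborates its
accuracy in a test. The GBDT backend is `xgboost` with 500 depth-3
trees, learning rate 0.1, logistic loss, no shrinkage penalties, and a
0.1 validation fraction watched during boosting; its exact greedy gain
criterion stands in for the Friedman-MSE split rule.

**Dataset discipline.** Window frames from the 180 training
trajectories are concatenated, shuffled, and split 0.7/0.3 into train
and test; 50 additional trajectories are never touched during training
and are scored per-trajectory by majority vote over their window frames
(a per-frame mode exists; the choice is deliberate because a
trajectory, not a frame, is the unit a practitioner predicts).

**Feature attribution.** The global-mean swap replaces one feature
everywhere with its training-set mean, re-predicts, and reports the
accuracy drop; it is evaluated on the pooled train+test frames, the
largest set available, because a drop is quantised at one misprediction
per pooled frame and single-replica estimates of weak features are
otherwise dominated by that quantisation. Correlated features are
judged on replica-mean drops across the 10-replica study against
3× the spread of the uncorrelated features' mean drops. GBDT
importances are normalised split gains; the benchmark asserts that the
top-importance feature falls in the $\alpha$-top-3 in every replica,
that mean importance decreases over the top three $\alpha$ ranks and
dominates all weaker ranks, and that at least one low-$\alpha$
correlated feature scores below 1% — the sensitivity (MLP finds all
correlated features) versus specificity (GBDT ranks the top ones,
misses weak ones) contrast. Exact per-replica ordering of the top three
importances is *not* asserted: with near-tied gains the greedy split
choice is effectively a coin flip.

The 5-DW variant (four extra low-barrier double wells as structured
noise, 15 correlated features) ships as `make_fixtures()$five_dw`.

## 5. Rates

`barrier_from_rate()` and `rate_from_barrier()` implement the
transition-state relation $k = (k_BT/h)\,e^{-\Delta G^\ddagger/k_BT}$
with CODATA-2018 constants and unit transmission coefficient, in
kcal/mol and s⁻¹. They are exact inverses to $10^{-10}$ relative and
reproduce the published CDK2 inhibitor barriers (18.93 and
20.97 kcal/mol at 298 K) from the experimental off-rates. The all-atom
CDK2 simulation barriers and classifier accuracies are carried only as
flagged literature references (`cdk2_reference()`); reproducing them
requires molecular-dynamics trajectories far outside this package's
analytic scope, and the toy-system properties above stand in for them.

## 6. What the toys do and do not show

Passing tests on these systems demonstrate that the algorithms are
implemented correctly against analytic oracles and that the MLTSA
attribution behaves as designed when features are *linear* mixtures of
well-separated timescales. They do not show that the protocol's cutoffs
are right for any particular protein, that the string method converges
on rugged all-atom landscapes, or that the attribution survives
nonlinear feature couplings — the latter is an explicit non-goal here,
as it was flagged as future work for the method itself. Problem sizes
in the tests (10 benchmark replicas; 1,200–3,000-frame protocol
iterations; 25–30 string windows with 500–1,200 samples each) were
chosen as the smallest at which the statistical assertions are stable.
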