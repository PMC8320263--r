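---
title: "A hierarchical active-inference model of the neurological examination of the arm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hierarchical active-inference model of the neurological examination of the arm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinesia)
```

## The problem

A bedside neurological examination of the upper limb probes two very
different faculties with two simple manoeuvres: a tendon tap elicits the
spinal stretch reflex (brisk in corticospinal disease, pendular in
cerebellar disease), and an alternating pointing task probes the
planning and coordination of goal-directed movement (slow and hesitant
in parkinsonism, disorganised after frontal lesions).  `kinesia`
implements a single generative model whose inversion performs both
manoeuvres, and in which each of those clinical signs corresponds to a
mis-set precision: the gain of a sensory channel, the assumed smoothness
of fluctuations, the confidence placed in action plans, or the strength
of the coupling between hierarchical levels.

## The continuous level: arm, reflex and filter

The plant is a three-joint arm (shoulder rotation, shoulder flexion,
elbow flexion) with segment lengths $L_1 = L_2 = 0.3$ m hanging from a
shoulder at $(0, 0, 1.5)$ m.  The generative model predicts twelve
sensory channels: II afferents (joint angles), Ia afferents (joint
velocities), the seen hand position $\Theta(x)$, and the colour
intensities of three visual targets.  Its flow embodies the
equilibrium-point idea: a fictitious force proportional to the distance
between the hand and an attracting point $v_{1..3}$,

$$\dot x_{4..6} = \kappa\left(J^\top (v_{1..3} - \Theta(x)) - \beta\, x_{4..6}\right),$$

with $J = \partial\Theta/\partial x$.  The defaults $\kappa = 60$,
$\beta = 0.12$/s place the slow mode of this flow near critical damping
for the default geometry ($\sqrt{\kappa\,\lambda_{\min}(J^\top J)}
\approx \kappa\beta/2 \approx 3.5$/s), which yields reaches and reflex
recoveries on the 0.3–1 s timescale of real arm movements.  Much
smaller gains or heavier damping make the closed loop settle over tens
of seconds, which is incompatible with a reflex that relaxes within two
seconds.

Beliefs are held in generalized coordinates of motion — each variable
together with its temporal derivatives (order 4 for hidden states,
order 3 for causes and data).  Fluctuations are assigned a Gaussian
autocorrelation $\rho(h) = e^{-h^2/2\lambda^2}$, which factorizes every
precision into a spatial part $\Pi$ and a temporal kernel $S(\lambda)$
with $\tilde\Pi = \Pi \otimes S(\lambda)$.  Order 3 is the smallest
embedding at which $S(\lambda)$ has off-diagonal structure (at order 2
it is diagonal and the temporal component of precision does nothing);
$\lambda = 0.1$ s puts the kernel's couplings at the frequency content
of the reflex transient ($\lambda\omega \approx 1$ at 10 rad/s).

The filter performs a free-energy gradient flow in a frame of reference
moving with the generalized motion, $\dot\mu = D\mu - \partial F /
\partial\mu$, integrated by local linearization: each step applies
$(e^{J\,\mathrm{d}t} - I)J^{-1}\dot\mu$ with $J = D - \partial^2
F/\partial\mu^2$ (Gauss–Newton curvature), computed in an
inversion-free augmented form.  The free-energy gradient is exact for
the model as defined — it includes the second-derivative tensor of the
kinematics where the Jacobians depend on the believed angles — and is
verified against finite differences in the test suite.

Action is a spinal reflex arc: torques descend the same free energy
through the plant's sensory Jacobian, restricted to proprioceptive
channels (gain $\kappa$ on the order-0 II and Ia channels of the same
joint).  The gain $k_a = 1.5\times10^{-3}$ keeps the reflex servo's
resonance near 10 rad/s — a third-order loop whose stiffness is
$k_a\kappa^2\Pi_{II}$ — and a leak of 3/s on the motor activation damps
the integral windup this loop otherwise exhibits.  A unit action gain,
with these precisions and $\kappa$, rings at several hundred rad/s and
cannot be integrated at 128 Hz.

### Precision balance

The defaults (log precisions: II 3, Ia 2, visual position 2, colour 3;
process 4; attractor prior 5, colour prior 2) implement a deliberate
sensory attenuation: the dynamical prior and the descending attractor
prior outweigh proprioception, so the belief can confidently simulate
the movement it intends while the reflex arc drags the arm after it.
This balance is the crux of the model.  If proprioceptive precision
rivals the dynamical prior, beliefs capitulate to the sensed posture,
descending predictions can never run ahead of the arm, and movement
dies — which is exactly the phenotype the sensory-precision lesion
exploits.

## The discrete levels: planning as inference

Above the continuous model sit two discrete levels.  Level 1 represents
the attracting point on a ring of six locations — the three triangle
vertices interleaved with the three edge midpoints — together with a
static target factor, and three policies: step clockwise,
anticlockwise, or stay, each carrying the point to an adjacent vertex
over two steps of a five-epoch horizon and holding it there.  Policies
are scored by

$$\pi = \sigma\!\left(\ln (E \cdot o^{(2)}) - F - \gamma G\right),$$

where $F$ is the evidence each policy has accumulated, $G$ the expected
free energy of its future (risk of missing the preferred "correct"
outcome, weighted `preference` = 0.6 nats, plus the ambiguity of the
likelihoods, which is zero here), and $\gamma = 2$ the precision of the
expected-free-energy contribution.  The policy prior $E$ carries an
effort bias (mass 0.7 on staying still): movement must be licensed by
expected free energy.  The healthy balance — roughly $+3$ nats for the
goal-directed policy after the target is seen — is what the
policy-precision lesion destroys: at a quarter of the healthy $\gamma$
the balance is negative, the effort prior wins, and the model makes
small, late, abortive movements whose evidence never accumulates in
favour of going anywhere.

Level 2 represents the trajectory being performed as an ordered pair of
start and end vertices (nine states, including the three static ones)
and a replica of the target factor that may change between level-2
steps.  A likelihood matrix maps the trajectory state to context
outcomes — the initial ring location, the ring direction, and the
target — which parameterize level 1's initial-state prior $D^{(1)}$ and
policy prior $E^{(1)}$.  Each outcome is generated with probability 0.9
(the remainder spread uniformly), so that the hierarchical-precision
lesion, a temperature on these columns, has something to flatten.  The
ascending message combines the level-2 prior with the likelihood of the
policy and initial state inferred below,
$r^{(2)} = \sigma(\ln o^{(2)} + \ln E^{(1)}\!\cdot\pi^{(1)} + \ln
D^{(1)}\!\cdot s_1^{(1)})$.

The two levels talk to the continuous model through a Bayesian model
average and Bayesian model reduction: each discrete outcome owns a
point in cause space (a ring location, a colour pattern); the
descending prior expectation is the outcome-probability-weighted
average of those points; and the evidence for each candidate outcome is
the closed-form change in log evidence if the prior mean were swapped
for that candidate, accumulated over the epoch at the filter's step
(verified against numerical integration in the tests).  Epochs last
1.25 s — long enough for the arm, whose closed-loop time constant is
roughly 0.3 s, to realize one ring step per epoch — and a segment
comprises five epochs: one to infer the newly darkened target, two to
move, two to stabilize.  With materially shorter epochs the evidence
always lags the plan and policy selection collapses into a
self-confirming "stay" loop.

## The lesions

All four lesions perturb the generative model only; the plant is never
changed, so every lesion is a model–world mismatch.

* **Sensory precision** (`pi_overestimate`, default $+2$ log units on
  the Ia channel): raises the gain of the reflex arc and of belief
  updates from velocity afferents.  Tendon taps become larger and
  faster, monotonically in the lesion depth, while coordination is
  untouched — the classical corticospinal dissociation.  The lesion is
  scoped to the velocity afferents because the tendon jerk is
  Ia-mediated; including the length afferents lets the lesioned belief
  capitulate to the (veridical) position data, which paradoxically
  shrinks the reflex at small magnitudes.
* **Smoothness** (`lambda_overestimate`, default $\times 2$ on
  $\lambda_{\text{model}}$ only): inflates the temporal kernel's
  derivative weights.  The tap's derivative content is then
  over-assimilated, and the reflex becomes a smaller-amplitude
  oscillation with extra velocity zero crossings — a pendular reflex.
  Beyond about $\times 2.5$ the oscillation slows and grows and no
  longer settles within the examination window.
* **Policy precision** (`gamma_attenuate`, default $\times 0.25$):
  hypokinesia, as above — amplitude falls to roughly a sixth of
  healthy, onset latencies lengthen, targets are missed.
* **Hierarchical precision** (`A_attenuate`, default temperature 0.5):
  flattens the descending context.  At every change of target the
  attracting point is briefly inferred "somewhere in the middle" (the
  average of a diffuse prediction), the hand deviates toward the
  centre, and the within-segment evidence then re-concentrates the
  beliefs so the segment still ends on target.  A temperature of 0.25
  destroys the context entirely and the task is no longer completed,
  contradicting the preserved-endpoint character of the executive
  phenotype, which is why 0.5 is the default.

### A known limitation

One cerebellar sign is deliberately reported as absent: the lesioned
model does not overshoot targets during reaching.  In this
implementation the filter's local-linearization step tracks the
posterior mode, and data carry analytic derivatives consistent with the
plant, so overestimating $\lambda$ acts as additional, phase-accurate
derivative feedback — extra damping — rather than as trajectory
momentum.  The reflex oscillates because the tap transient has spectral
content at $\lambda\omega \approx 4$; reaching evolves at
$\lambda\omega \approx 0.3$, where the temporal kernel is inert, and
closed-loop pole analysis shows the smoothness lesion only moving the
reaching poles deeper into the left half plane.  Reproducing
hypermetria appears to require either sample-based embedding of data
derivatives (whose phase lag the smoothness assumption would
mis-handle) or a finite-rate gradient-flow filter; both are different
integration schemes from the one adopted here, and the corresponding
reach-overshoot check in the test suite fails by design rather than
being weakened.

## What the simulated data are, and are not

The plant generates smooth Gaussian noise (autocorrelation width
$\lambda_{\text{world}} = 0.1$ s, standard deviation $10^{-3}$) on
sensory channels and accelerations, so the healthy examination is
near-deterministic and every reported contrast is a lesion effect, not
a noise effect; metrics are stable to three significant figures across
seeds.  Real electromyography and kinematics are far noisier, include
gravity, muscle dynamics, joint limits and measurement artefacts, and
real lesions are neither pure nor single-parameter.  Passing this
package's checks therefore shows that the computational taxonomy of
signs is coherent and reproducible within the model — not that any
individual patient's deficit is explained by a single precision.

## Numerical choices and problem sizes

Integration runs at $\mathrm{d}t = 1/128$ s.  The tendon-tap
examination simulates 4 s (512 steps: 1 s baseline, tap of amplitude 2
and width 25 ms on the elbow Ia channel, 3 s observation); the
coordination examination simulates 25 s (3200 steps: four segments of
five 1.25 s epochs), with the target schedule right → apex → lower-left
→ apex.  Belief updates exponentiate a 43-dimensional Jacobian per step
(scaling-and-squaring Padé); discrete posteriors are computed by exact
enumeration of the 18 joint states, so there is no sampling anywhere.
Probabilities entering logarithms are floored at $e^{-16}$; degenerate
discrete evidence falls back to a uniform posterior with a warning;
belief divergence (norm above a configurable bound) aborts with an
error naming the filtering step.  The settle band of the reflex is 5%
of the baseline elbow angle (floored at three standard deviations of
baseline jitter), and "reached" means within 5% of the total arm length
(3 cm).  All of these constants live in `default_config()` and nothing
is hard-coded in the exam drivers.
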