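---
title: "Modelling pairwise fish swimming: burst-and-coast simulation, a recurrent probabilistic interaction model, and multi-timescale validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pairwise fish swimming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Small schooling fish such as the rummy-nose tetra confined to a circular
tank (radius $R = 25$ cm) swim in a *burst-and-coast* mode: a brief
acceleration (a "kick") followed by a longer, nearly straight glide. The
kick onset is treated as the decision instant at which a new heading, kick
length and kick duration are chosen under three influences — the wall, the
neighbour (attraction and alignment), and intrinsic "cognitive" noise.
`pairswim` provides two generative models of this system and the validation
machinery to compare any trajectory-generating model against a reference
dataset on equal terms:

* `abc_model()` / `simulate_abc()` — an asynchronous, event-driven
  analytical burst-and-coast simulator;
* `fit_dli()` — a recurrent probabilistic network (two LSTM layers, five
  dense layers, a diagonal-Gaussian acceleration head) trained by maximum
  likelihood to predict the distribution of an agent's next-step
  acceleration from the recent history of the two-agent system state, and
  usable in closed loop as a generative model;
* `observable_report()` / `compare_observables()` — nine observables (six
  probability densities, three temporal correlation functions) and
  Hellinger-distance scoring.

# Variables and conventions

For each fish $i$ at time $t$: position $u_i$ (cm, tank-centred), velocity
$v_i$ by backward difference over one timestep, speed $V_i = \lVert v_i
\rVert$, heading $\phi_i = \operatorname{atan2}(v_{yi}, v_{xi})$, wall
distance $r_{wi} = R - \lVert u_i \rVert$, and wall incidence $\theta_{wi}
= \phi_i - \operatorname{atan2}(y_i, x_i)$ ($0$ = straight at the wall,
$\pm 90^\circ$ = parallel). For a pair: distance $d_{ij}$, relative heading
$\phi_{ij} = \phi_j - \phi_i$, and the viewing angle $\psi_{ij}$, the angle
$i$ must turn to face $j$. Fish $i$ is the *geometric leader* when
$|\psi_{ij}| > |\psi_{ji}|$; exact ties keep the previous leader, and the
attribution is recomputed every timestep. All angles are wrapped to
$(-\pi, \pi]$, positive counter-clockwise; everything internal is cm,
seconds, radians.

The working timestep is $\Delta t = 0.12$ s throughout: raw tracking data
(typically 0.04 s) are decimated by `preprocess_trajectories()` after the
inactivity filter (speed below 1 body length/s removes the sample), the
tracking-leap filter (per-frame displacement above 1.5 BL $\approx$ 5.25 cm
is a tracking error; note the literal per-frame rule at 0.04 s corresponds
to about 131 cm/s), and linear interpolation of short holes. Holes produced
by the *inactivity* filter are behavioural pauses and are never bridged;
interpolation is reserved for short tracking holes (default at most 12
frames, about one kick duration). Decimation keeps every $k$-th frame —
positions are never averaged, so preprocessing is exactly reversible
bookkeeping.

# The burst-and-coast simulator

Each agent's state advances kick by kick:
$t^{n+1} = t^n + \tau^n$, $\phi^{n+1} = \phi^n + \delta\phi^n$,
$u^{n+1} = u^n + \ell^n\, e(\phi^{n+1})$,
with $\tau$ and $\ell$ drawn from gamma distributions (shape 2; means 0.5 s
and 7 cm, the experimental means for this species). Kicks of the two agents
are asynchronous: the agent whose next decision time is smallest moves, and
reads its neighbour's glide-interpolated state at that instant.

The exact interaction functions for the species come from a separate
data-driven reconstruction and are not reproduced here; the simulator ships
a configurable parametric family honouring the standard angular symmetries:

* wall: $A_w e^{-r_w/\ell_w}\sin\theta_w + \epsilon_w e^{-r_w/\ell_w}$,
  odd in $\theta_w$, with $\ell_w = 2$ BL and a small additive asymmetry
  $\epsilon_w$ that biases the direction of rotation around the tank;
* attraction: $A_{att}\, \frac{d}{d + d_0}\sin\psi_{ij}$, saturating with
  distance ($d_0 = 7$ cm);
* alignment: $A_{ali}\, e^{-d/\ell_a}\sin\phi_{ij}$;
* cognitive noise: $\gamma\, g$, $g \sim N(0,1)$, per kick
  ($\gamma = 0.35$ rad).

The default amplitudes ($A_w = 0.45$, $\epsilon_w = 0.04$, $A_{att} = 0.7$,
$A_{ali} = 1.0$, $\ell_a = 20$ cm) were calibrated once against the
qualitative behaviour of the species and then frozen: most wall-distance
mass within 2 BL of the wall, modal inter-individual distance near 2 BL,
relative-heading density sharply peaked at $0$, and counter-clockwise
rotation slightly favoured. They are not fitted to any quantitative
benchmark.

Within a kick the speed decays exponentially with time constant $\tau/2$,
renormalized so the kick covers length $\ell$ in duration $\tau$; this
produces the characteristic sawtooth speed profile. A uniform-speed glide
is available for testing. Kick endpoints proposed outside the tank are
rejected and redrawn — noise only for the first few attempts, then the full
(noise, $\tau$, $\ell$) triplet. During the full-redraw phase the noise
scale is progressively inflated: an agent pinned against the wall while
heading outward needs a heading change larger than a few $\gamma$ to
escape, and without inflation such trap states would abort a long
simulation with probability approaching one. The deterministic wall and
social terms are never altered by the rejection loop. Because both kick
endpoints lie inside the (convex) tank, the whole glide chord does too, so
containment is exact.

`kicks_to_trajectory()` resamples the event log on the $\Delta t$ grid; the
simulator therefore doubles as the package's synthetic-data generator, and
all training and validation inputs used in the tests are produced this way.

# The recurrent probabilistic interaction model

The network input is the history of the five most recent system states
$S(t) = (s_i(t), s_j(t), d_{ij}(t)) \in \mathbb{R}^{11}$, with
$s_i = (u_i, v_i, r_{wi}) \in \mathbb{R}^5$ — a $5 \times 11$ matrix. The
history length matches the mean kick duration (5 steps of 0.12 s
$\approx$ 0.6 s), so the network always sees one full behavioural cycle.
$r_w$ and $d_{ij}$ are redundant given the positions; they are included
deliberately because they carry the interaction-relevant geometry
explicitly. Positions, wall and pair distances are normalized by $R$,
velocities by $R$/s, accelerations by $R$/s².

The architecture is LSTM(256) → dense 128 → dense 64 → LSTM(128) → dense 64
→ dense 32 → linear 4 by default (only the first width is canonical; all
widths are configurable, and the tests use reduced widths). The four
outputs are $(\mu_x, \mu_y)$ and two raw values mapped through a softplus
to $(\sigma_x, \sigma_y) > 0$: a diagonal-Gaussian distribution over the
focal agent's next-step acceleration. Sampling uses
$a = \mu + \sigma \odot g$ with independent standard normals per component,
and integration is semi-implicit: $v^{n+1} = v^n + \Delta t\, a^n$,
$u^{n+1} = u^n + \Delta t\, v^{n+1}$. The predicted $\sigma$ is the model's
representation of the fish's cognitive noise — two agents in the same state
do not act identically.

Training minimizes the per-sample Gaussian negative log-likelihood
$\tfrac12 \epsilon^\top C^{-1}(\sigma)\, \epsilon + \tfrac12 \log\lVert
C(\sigma) \rVert$ averaged over the batch, with Adam, batch 512, a
time-decaying learning rate (default decay $\times 0.95$ per epoch) and 45
epochs at full scale. The LSTM layers, backpropagation-through-time and the
optimizer are implemented in the package's C++ core; all randomness flows
through R's RNG, so a seed makes training, rollouts and simulations
bit-reproducible. Analytic gradients are verified against finite
differences in the test suite.

Numerical choices worth knowing about:

* **Target standardization.** Acceleration targets are divided by their
  per-component training standard deviation before optimization and
  predictions are rescaled transparently. The likelihood is identical up to
  an additive constant, but without this the first optimizer steps on
  numerically large accelerations saturate the tanh/LSTM stack and the
  network collapses to the unconditional fit.
* **Contiguous data splits.** The 80/15/5 train/validation/test split is
  by contiguous blocks, not shuffled, because neighbouring 5-step windows
  overlap; shuffling would leak validation information into training.
  Shuffling happens within the training block only.
* **Both-orderings augmentation.** Each timestep yields two samples (each
  agent as focal), realizing the single shared model both agents use.
* **Forget-gate bias initialised at 1**, Glorot-uniform weights, global
  gradient-norm clipping at 5.
* **Rollout rejection.** In closed loop, a move that would end outside the
  tank redraws the Gaussian variates, up to `cap` attempts at the predicted
  $\sigma$. If all fail, the proposal is widened ($\sigma$ doubled per
  further block of `cap` draws, bounded so the one-step displacement scale
  never exceeds $R/2$) before giving up: in states far off the training
  manifold the predicted distribution can put essentially no mass inside
  the tank, and a hard error there would make long rollouts a lottery.
  Exceeding the widened budget is still an error, never a silent clamp.

For groups of $N > 2$ agents, `multi_agent_rollout()` reuses the trained
pair model without retraining: for each focal agent the pair network is
evaluated against every neighbour, neighbours are ranked by the magnitude
$\lVert \mu \rVert$ of the predicted mean acceleration, the top
$k$ (default 2) are kept, and their predictions are aggregated as the mean
of $\mu$ and the root-mean-square of $\sigma$ — the RMS choice keeps the
aggregate variance the average of the retained variances. The ranking
statistic and the aggregation rule are package design choices; alternatives
(for example softmax-weighted means) plug in trivially.

# The nine-observable validation suite

Six density observables — $V$, $r_w$, $\theta_w$ (individual), $d_{ij}$,
$\phi_{ij}$, $\psi_{ij}$ (collective) — and three temporal correlation
observables for a focal fish:

$$C_X(t) = \langle [u(t + t') - u(t')]^2 \rangle,\quad
  C_V(t) = \langle v(t + t') \cdot v(t') \rangle,\quad
  C_{\theta_w}(t) = \langle \cos[\theta_w(t + t') - \theta_w(t')] \rangle,$$

averaged over reference times $t'$ (stationarity assumed), focal agents and
segments; averaging never crosses a segment boundary. $C_X$ distinguishes
the ballistic ($\langle v^2 \rangle t^2$), diffusive and saturated regimes
of confined swimming; $C_V(0)$ equals the mean squared speed; $C_{\theta_w}$
is the most demanding because it probes how long wall-relative orientation
persists. Where the figures of merit split by role, the leader/follower
attribution at the reference time $t'$ decides the assignment.

Histograms use a named, versioned binning policy (`binning_policy()`), by
default: $V$ on [0, 35] cm/s in 70 bins, $r_w$ on [0, R] in 50 bins, angles
on $(-180^\circ, 180^\circ]$ in 72 bins, $d_{ij}$ on [0, 2R] in 100 bins —
bin widths of the order of the measurement resolution. The Hellinger
distance $\mathrm{HD} = \sqrt{1 - \sum_k \sqrt{p_k q_k}}$ is computed on
per-bin probability masses (bin-width robust), lies in $[0, 1]$, and is
only defined for identical bin edges — re-binning is never silent.
Correlation lags run on the $\Delta t$ grid up to 30 s by default.

# What the synthetic generator does and does not emulate

The burst-and-coast simulator reproduces the discrete-decision structure,
wall following, cohesion, alignment, the rotation asymmetry and the
sawtooth speed profile of the real species, and it provides unlimited,
exactly contained, seeded training data. It does not emulate several
features of real trajectory data: tracking noise and identity swaps,
occlusions (so the gap-interpolation path is exercised only by constructed
fixtures), body-posture kinematics, smooth within-kick turning (headings
are piecewise constant between decisions), or the fish's state-dependent
noise modulation near the wall. Passing the validation suite against this
generator therefore demonstrates that the learning and validation machinery
work end to end — not that the network would reach the same fidelity on
real fish data, where the conditional acceleration distribution is
smoother.

One structural consequence deserves emphasis. At $\Delta t = 0.12$ s the
generator's one-step conditional acceleration distribution is a mixture:
with high probability the agent is mid-glide (nearly deterministic
exponential deceleration), otherwise a kick fires somewhere in the interval
(large, nearly isotropic velocity jump). The best *Gaussian* fit to that
mixture keeps $\sigma$ of the order of the kick-jump scale at every step,
because kick timing is genuinely unpredictable. Two measurable consequences
in closed loop, both confirmed by the package's own experiments: the
sampled dynamics Gaussianize the speed process (many medium accelerations
instead of rare large ones), which distorts the stationary speed
distribution relative to the sawtooth reference; and near the wall the
per-step position noise $\Delta t^2 \sigma$ is comparable to the margin by
which the data sit inside the wall, so without the rejection procedure
agents drift past the boundary within seconds — exactly as the analytical
simulator itself would, since its own containment is enforced by rejection
rather than learned dynamics. A model distilled from rejected-but-Gaussian
data cannot out-contain its teacher. The corresponding long-horizon checks
in the test suite (closed-loop speed-distribution agreement, modal
pair-distance agreement, and rejection-free survival) therefore fail
honestly at this scale, and are kept failing rather than weakened; on real
fish data, where decisions are smoother and wall avoidance is in the
conditional mean rather than in a truncation, the same machinery is
expected to behave markedly better.

# Problem sizes used by the tests

The acceptance suite trains a reduced network (LSTM 48 → 32 → 24 → LSTM 24
→ 16 → 8, about 27k parameters) for 35 epochs at learning rate
$2 \times 10^{-3}$ on a 3600-s simulated pair (about 60k training windows
after augmentation), validates against an independent 12000-s reference run
(100,000 timesteps), and rolls out 100,000 closed-loop steps. Parameter
recovery uses a linear-Gaussian process ($a = -k u + \sigma_a g$, $k = 1$
s$^{-2}$, $\sigma_a = 0.3$ cm/s², 15,000 steps in 40 independent
segments so every contiguous block covers the same state distribution);
the fitted conditional mean is checked within 10% and the recovered noise
scale within 15% on the held-out block. These sizes are the package's
standard desk-scale experiment; scaling any of them up is a matter of
configuration.

# Known limitations

* The interaction kernels of the simulator are a symmetric parametric
  family, not the species' reconstructed functions; users with access to
  the fitted kernels can inject them.
* The Gaussian head cannot represent the glide/kick mixture at a single
  step (see above); a mixture-density or discrete-latent head would be the
  natural extension.
* HDF5 input is not available in this build; the canonical interchange
  format is the trajectory CSV.
* Hellinger distances depend on the binning policy; distances are only
  comparable when computed under the same named policy.
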