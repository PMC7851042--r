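---
title: "A biomimetic stretch-reflex controller for a cable-driven hand: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A biomimetic stretch-reflex controller for a cable-driven hand: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reflexsim)
```

# The problem

A cable-driven prosthetic hand is controlled the way a muscle controls a
tendon: a motor winds a cable, the cable flexes the finger, and extension
springs reopen it. `reflexsim` simulates a controller for such a hand that is
not a linear filter but a model of the spinal monosynaptic reflex arc itself:

1. surface EMG from a wrist flexor is decoded into a scalar *alpha motor
   command* (0--20 mA of equivalent drive);
2. the command is converted to an excitatory post-synaptic current (EPSC)
   and distributed to 768 Izhikevich spiking motoneurons in six size-ranked
   pools of 128;
3. motoneuron spikes drive a Hill-type muscle whose tension is applied to
   the cable by a torque motor;
4. cable length (the musculotendinous length, `L_mtu`) is read back from the
   motor encoder, the contractile-element length `L_ce` is reconstructed from
   it, and a bag1/bag2/chain muscle spindle turns `L_ce` and its velocity
   into Group Ia afferent firing;
5. 128 Ia afferent spike trains are fed back as synaptic current onto the
   motoneuron pools, closing the loop, so that an imposed stretch of the
   cable excites the muscle that resists it.

Group II (secondary ending) rates are computed and recorded but are never
fed back: the monosynaptic circuit uses Ia only.

Everything below the skin is virtual: the package also contains a plant
model (motor with static-friction dead zone, cable and winder kinematics,
return springs, contactable objects) so the whole loop runs closed in
software, faster than real time.

# Model components

## EMG synthesis and Bayesian decoding

Surface EMG is modeled as amplitude-modulated band-limited noise:
`synth_emg()` multiplies a unit-RMS Gaussian carrier, band-limited by
spectral masking to 30--300 Hz by default, with the normalized drive
envelope. A constant drive of 0.5 therefore yields a trace of RMS 0.5,
which gives the decoder a well-defined ground truth.

The decoder (`bayes_init()`, `bayes_update()`, `decode_alpha()`) is a grid
filter over the latent drive on [0, 1] (100 points): per sample the
posterior diffuses (forward-Euler Laplacian with reflecting boundaries,
default 1e-2 drive-units^2/s), a uniform jump mixture re-seeds a small mass
(default 0.1/s) so that abrupt command changes can be tracked, and the
rectified sample enters through a half-Gaussian likelihood whose scale grows
with the drive (`sigma = x + 0.02`). The posterior mode, scaled linearly to
0--20 mA, is the alpha command. With these defaults a full-range step is
crossed in well under 100 ms at 1 kHz. The original system cites this
decoder family without printing its rates, so the defaults here are package
choices, exposed in the `bayes` configuration block.

## Motoneuron pools and the size principle

All 768 neurons use the canonical regular-spiking Izhikevich parameters
(`a = 0.02, b = 0.2, c = -65, d = 8`, 30 mV cutoff), integrated by forward
Euler at 1 ms with the conventional two half-steps on the membrane equation.
Initial membrane and adaptation states are staggered deterministically
across the population; without this, a command step fires every neuron at
once and produces an artificial population volley several times the steady
tension.

Recruitment order emerges from per-pool input gains: pool *p* receives
`k * alpha_norm * gain_p` plus independent Gaussian EPSC noise (SD 2, i.e.
5% of `k = 40`). The gains are `2 / threshold_mA` with thresholds spread
over 5--15 mA, so the first pool reaches rheobase around the 5 mA
static-friction dead zone and recruitment continues across the command range
used in the experiments. The EPSC noise is defined at the 1 kHz reference
rate and rescaled by `sqrt(dt_ref/dt)` if the model step is refined, keeping
its spectral density step-invariant.

## Spike-driven Hill-type muscle

Activation follows first-order twitch dynamics with the 30 ms time constant:
each motoneuron spike adds a quantal increment weighted by the rank of its
source pool (later-recruited, larger units contribute more force), and the
activation decays exponentially between spikes. At 100 Hz periodic input the
plateau is `q / (1 - exp(-0.01/0.03))`, the closed-form used in the tests.

The active force is scaled by the printed force-length law (three-branch
piecewise quadratic on [0.5, 1.6] of optimal length; the two branches give
1.024 and 1.002 at the junction -- the 0.022 discontinuity is kept as
published) and by the linear force-velocity law capped at `1.8 * F0`.

Tension delivered to the cable comes from a dynamic formulation
(`muscle_dynamics_step()`): the contractile element (CE) is an internal
state; the series-elastic element (tendon plus cable compliance, default
30 N/cm) is stretched by the difference between cable displacement and CE
displacement, and its tension drives the CE through the force balance
`b*V + Fmax*A*FL(L)*(F0 + s*V) + F_pe = T_se`, which is linear in the CE
velocity and hence solved in closed form (unconditionally stable). This
makes tension depend on the muscle's history of length and velocity: an
imposed stretch raises tension immediately through the series spring and
then relaxes as the CE yields, which is what the quasi-static stiffness
probe measures.

Parameter notes: the CE optimal length is 4.5 cm (a typical wrist-flexor
fascicle length, much shorter than the 39.7 cm cable), so the 1.57 cm
closure excursion spans a meaningful part of the force-length curve and
muscle stiffness varies with posture; `Vm = 3` optimal lengths/s keeps the
force-velocity law away from saturation at the cable speeds the plant
reaches; `Fmax = 50 N` sets the overall scale.

## Proprioception reconstructed from motor rotation

The cable length is `L_mtu = L_mtu(0) - r * theta` with `L_mtu(0) = 39.7 cm`
and winder radius `r = 0.25 cm` (one revolution shortens the cable by
2*pi*r = 1.57 cm). During free motion the CE estimate simply tracks the
cable. During contact the muscle is treated as the series chain of the
tendon spring `Kse` and the parallel combination of `Kpe` with an
activation-adjustable spring `K_alpha(alpha, L_mtu)` given by a printed
piecewise-linear law (clamped at zero; only positive stiffness is
effective); the CE then takes the fraction `Kse / (Kse + Kpe + K_alpha)` of
the MTU length. Two package conventions are documented here because the
source leaves them open:

* The same three-decimal coefficient set is used both in `k_alpha()` and in
  the expanded one-line contact formula (`lce_direct()`), so the two
  evaluation routes agree to 1e-9 (a tested invariant). The published text
  prints the coefficients twice at different roundings, which cannot satisfy
  that identity.
* `Kse = 60` and `Kpe = 15` are chosen on the same scale as the printed
  `K_alpha` coefficients (about 48 near the initial length): all three enter
  a single formula and must share units. With stiffnesses of order unity
  against a `K_alpha` of 48 the divider would freeze the CE during contact
  and silence spindle feedback entirely.
* The closed loop applies the divider *incrementally*
  (`dL_ce = frac * dL_mtu` while pressing), which is the exact series-spring
  displacement relation and is continuous at contact onset; the absolute
  printed form is implemented verbatim in `lce_estimate()` as the module
  contract. The reconstructed CE length is normalized by the 23.6 cm muscle
  resting length before it enters the spindle, as specified.

## Muscle spindle and afferent encoding

The spindle is the standard three-fiber intrafusal model (dynamic bag1,
static bag2, chain): each fiber is a sensory-region spring in series with a
polar region whose fractional-power damping (`|v|^0.3`) and fusimotor
dependence produce the classic velocity-sensitive primary response. The
fiber constants live in `inst/extdata/spindle_params.csv`, not in code. Ia
firing combines the bag1 ending with the bag2+chain ending through the
partial-occlusion rule (occlusion factor 0.156); secondary (II) rates come
from bag2 and chain only. Fusimotor drives default to zero (the source
models them but reports no operating values).

Numerics: the sensory-region tension oscillator is fast
(`sqrt(K_SR/M) ~ 230 rad/s`), so each 1 ms step is internally sub-stepped
four times with a semi-implicit update, and the fractional-power damping is
regularized to a linear viscous law below 0.01 lengths/s. Without the
regularization the integrator chatters around the zero-velocity
discontinuity and settles visibly above the true equilibrium; with it, the
resting Ia rate matches the closed-form static solution exactly (a tested
oracle, ~12.2 imp/s at resting length).

Rates are encoded into 128 afferent spike trains either as independent
Poisson processes (default) or by a deterministic per-unit
integrate-to-threshold encoder (used by the convergence tests). Each Ia
spike injects an exponentially decaying synaptic current
(`tau = 5 ms`, increment 0.002 current units, times the loop gain).

The default loop gain is deliberately conservative. The recruitment curve is
steep near the operating commands, so even fractions of a current unit of
tonic Ia feedback translate into percent-level grasp-force drift while the
spindle slowly recovers from the unloading it suffers during closure
(spindle re-tensioning after shortening takes several hundred
milliseconds). At the default gain the reflex is present and sign-correct
but does not disturb grasp settling; the stretch-resistance demonstrations
raise `loop$ia_gain` explicitly (the tests use 25), which is the honest
statement that the reflex pathway, not a hidden constant, produces the
resistance.

## Plant: motor, cable, objects

The motor is a tension source with a first-order torque-controller lag
(`tau_motor = 0.1 s`) driving a winder whose velocity relaxes toward
`mobility * net force` (10 ms velocity lag). Friction is Coulomb with
stiction hysteresis: kinetic friction 1.75 N at the cable, breakaway 1.4x
that, plus the empirical rule that a resting motor does not move for
commands below 5 mA (the dead zone reported for the physical device). A
velocity zero-crossing under sub-kinetic drive re-engages the stick state
rather than chattering across the Coulomb discontinuity -- without this the
settled grasp ratchets forward on command noise for hundreds of
milliseconds and the force never settles.

Fingertip travel is `ratio = 2` times cable travel; the return springs are
one lumped linear spring (2.8 N/cm at the cable). The aperture is an affine
map of cable length calibrated so that one full winder revolution spans
100% to 0%. Objects are `none`, a rigid gauge (travel clamps at the gap;
the reaction force is whatever the cable delivers), or an elastic beam
(Hookean beyond the hover gap, with a latching breakage flag at 4.4 N).

## Scheduling

The loop runs at two rates, mirroring the hardware split: neurons, synapse,
twitch activation and muscle tension at 1 kHz; motor, objects, length
reconstruction, spindle input refresh and afferent encoding at 100 Hz (the
spindle state itself advances at the model rate along the interpolated
length trajectory). All randomness flows from the single `loop$seed`, so a
run is bitwise reproducible.

# Virtual experiments

* `exp_aperture_curve()` -- static command levels from full extension; the
  settled aperture falls linearly with the command above the 5 mA dead zone
  (R^2 > 0.95 with 3 repetitions per level) and the hand fully closes near
  8.5--9 mA.
* `exp_stiffness()` -- the finger settles against a rigid gauge at a target
  aperture, the gauge is elevated 5 mm, and the settled force change gives
  the fingertip stiffness. Stiffness increases with the command at every
  probed aperture, because activation scales the muscle's short-range
  elastic response; probing uses paired seeds and replicate averaging
  because single probes carry a few N/m of spiking noise.
* `exp_beam_press()` -- a 6.5 mA step with the fingertip hovering 1 cm above
  an elastic beam; `detect_events()` extracts the timeline: t1 tension rise,
  t2 first cable motion, t3 contact, t4 end of deformation (smoothed
  deformation rate below 5% of its peak, sustained), t5 force settlement
  (entry into a +-5% band around the final value held for 200 ms). The
  plant constants (motor lag, friction, mobility, beam stiffness, return
  spring) are the free calibration of the virtual hardware and were chosen
  once so that the default protocol reproduces the reference timeline
  t2 = 0.09, t3 = 0.24, t4 = 0.30, t5 = 0.52 s within its tolerance band;
  they are ordinary configuration values, not hidden constants.
* `fitts_metrics()` -- the press-without-break task metrics:
  `ID = log2(2D/W)` per target and throughput `TP = (1/N) sum ID_i / CT_i`
  over the N = 6 difficulty levels. `fitts_demo_trials()` generates
  demonstration trials with a synthetic integral force-seeking policy; it is
  labeled synthetic and is not a model of human operators, whose published
  throughputs are not comparable to it.

# What the synthetic data do and do not show

The EMG generator produces exactly the amplitude-modulated band-limited
noise the decoder assumes; real surface EMG adds motion artifacts,
non-Gaussian bursts, electrode drift and crosstalk, so decoder accuracy here
is an upper bound. The plant is desk-scale: forces are a few newtons, one
finger, one afferented flexor, lumped transmission. Hardware-scale results
(tens of newtons of grip, hundreds of N/m of stiffness span) are therefore
echoed only qualitatively -- linearity, dead zone, monotone stiffness, the
event ordering -- not numerically. Passing tests demonstrate internal
consistency of the reflex architecture under these study conditions, not
performance of any physical device.

# Problem sizes used by the test-suite and scripts

Tests and the acceptance script run the full-size population (768
motoneurons, 128 afferents) but short episodes: 1.3 s beam presses over 10
seeds, 2 s settles for nine command levels with 3 repetitions, and a
3 x 3 stiffness grid with 3 probe pairs per cell. One simulated second of
the full loop takes well under a second of CPU, so the complete suite stays
within a few minutes on one core.

# Known limitations

* Single fiber type; fatigue and history-dependent force are not modeled.
* Gamma drive is a constant parameter, not a spiking pathway; alpha-gamma
  coactivation is absent, which is why the spindle unloads during closure.
* The contact model is one-dimensional (no per-joint kinematics, no grasp
  wrenches); the rigid gauge reports force only while the plant presses.
* The press-without-break policy is a convenience generator for trial data,
  not a human model.
* Trace export is CSV; large binary containers are intentionally avoided.
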