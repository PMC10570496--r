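---
title: "Delayed-feedback control of beta oscillations in an STN-GPe-PPN neural mass model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delayed-feedback control of beta oscillations in an STN-GPe-PPN neural mass model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmmstim)
```

## The model

`nmmstim` simulates three lumped neural populations — the subthalamic
nucleus (STN, excitatory), the external globus pallidus (GPe, inhibitory
and self-inhibiting) and the pedunculopontine nucleus (PPN, excitatory) —
each described by an average membrane potential and an average pulse
density, in the neural-mass tradition of Jansen-Rit-style models.

Two elements define a population. The *nonlinear block* maps potential to
pulse density through the sigmoid $S_i(v) = r_i / (1 + e^{-y_i (v + w_i)})$,
where $r_i$ (s$^{-1}$) is the saturation pulse density, $y_i$ (mV$^{-1}$)
the slope, and $w_i$ (mV) the stimulation offset discussed below. The
*linear block* converts an afferent pulse density $u$ into a postsynaptic
potential contribution through second-order synaptic kinetics
$$ \ddot v = \frac{\lambda H_i}{x_i} u - \frac{2}{x_i} \dot v - \frac{1}{x_i^2} v, $$
the time-domain form of the transfer function $H_i x_i/(x_i s + 1)^2$
scaled by the pathway coupling $\lambda$. Its DC gain is $\lambda H_i x_i$,
which the test suite uses as an analytic oracle for the integrator.

Eight channels wire the network: GPe→STN ($\lambda_1$, inhibitory),
Cor→STN, PPN→STN ($\lambda_5$), STN→GPe ($\lambda_2$), GPe→GPe
($\lambda_3$), Str→GPe, GPi→PPN and STN→PPN ($\lambda_4$). Each nucleus's
LFP is the signed sum of its afferent channel potentials, inhibitory
channels entering negatively:
$v_\mathrm{STN} = v_3 + v_2 - v_1$, $v_\mathrm{GPe} = v_1 - v_2 - v_3$,
$v_\mathrm{PPN} = v_2 - v_1$.

### Parameters

| parameter | value | units | role |
|---|---|---|---|
| $H_s, H_g, H_p$ | 20, 20, 20 | mV | synaptic gains |
| $x_s, x_g, x_p$ | 0.006, 0.014, 0.005 | s | synaptic time constants |
| $r_s, r_g, r_p$ | 300, 400, 200 | s$^{-1}$ | sigmoid ceilings |
| $y_s, y_g, y_p$ | 0.1 | mV$^{-1}$ | sigmoid slopes |
| $\lambda_{1..5}$ normal | 1.12, 19, 6.6, 10, 3 | — | healthy coupling |
| $\lambda_{1..5}$ pathological | 5, 20, 2, 13, 1 | — | parkinsonian coupling |
| external drives | 27, 2, 20 (SD 0.1) | s$^{-1}$ | Cor, Str, GPi inputs |

The pathological set strengthens GPe→STN inhibition and weakens GPe
self-inhibition, destabilizing the STN-GPe loop into a limit cycle whose
LFPs oscillate at ~22 Hz (21.67 Hz at the 1/3 Hz resolution of a 3 s
window) in all three nuclei. Under the normal set the network relaxes to
a fixed point and the LFPs show only noise-level fluctuation — oscillation
indices differ between the regimes by some nine orders of magnitude.

## Delayed-feedback stimulation

The control law is the classic delayed linear feedback
$$ w(t) = K\,\big(v_\mathrm{src}(t-\tau) - v_\mathrm{src}(t)\big), $$
computed from the LFP of a *source* nucleus and delivered to a *target*
nucleus from `onset` (default 1 s) onward. It vanishes identically on any
$\tau$-periodic signal, so a successful controller quenches itself — the
energy index of a well-parameterized scheme is small.

**Injection convention.** The stimulation enters as the offset $w_i$ in
the target's sigmoid, i.e. it shifts the potential-to-rate mapping of the
target population at the same integration step at which it is computed.
We also evaluated the alternative of adding $w$ to the target's pulse-
density *output*; it fails to reproduce the published suppression of
three of the four strategies and was rejected. In unstimulated runs all
$w_i \equiv 0$.

**The four strategies.**

* **A** — STN ← STN, $K = 0.4$, $\tau = 25$ ms (the traditional
  self-feedback scheme; $\tau$ near half the 45 ms oscillation period);
* **B** — GPe ← GPe, $K = -2$, $\tau = 2$ ms;
* **C** — GPe ← PPN, $K = -2$, $\tau = 4$ ms;
* **D** — STN ← PPN, $K = 3$, $\tau = 8$ ms.

**Reading of strategy C.** Strategy C is described in the source
literature as pairing the PPN with the GPe LFP, with the direction of the
pairing left ambiguous in prose. We implement it as *stimulate GPe with
the PPN LFP* for two reasons. First, the sign structure: the stated
finding that positive intensities work for the excitatory targets (A, D)
and negative ones for the inhibitory target (B) is only coherent for C at
$K = -2$ if C's target is the inhibitory GPe. Second, the dynamics: with
GPe as target the scheme suppresses the rhythm by many orders of
magnitude with its delay optimum at 2–4 ms, exactly where reported,
whereas the reverse wiring (PPN target) barely suppresses at small
delays because PPN feeds back into the loop only through the weak
pathological $\lambda_5 = 1$ pathway, and its delay optimum sits near
25 ms instead. `stim_scheme()` builds any custom wiring, so both
readings remain available to users.

Positive $K$ destabilizes the inhibitory target and vice versa: applied
with the wrong sign, every scheme *amplifies* the rhythm, which is the
sign structure the K-sweep tests assert.

## Numerical choices

* **Integrator.** Forward Euler with $T = 3$ s, $dt = 10^{-4}$ s
  (30 000 steps), the scheme under which the model and its published
  parameter optima were characterized; no adaptive or implicit solver is
  offered on purpose, since the delay term and per-step noise redraw make
  classic ODE machinery a poor fit and the acceptance surface assumes
  Euler. Halving $dt$ under common coarse-grid noise leaves the dominant
  frequency in the same 1/3 Hz bin; the oscillation index shifts by ~5 %
  (the first-order amplitude bias of Euler on a limit cycle) and the
  error shrinks under further refinement, which the test suite asserts.
* **Initial conditions.** All 16 state variables start at 0. The metrics
  exclude the transient (OI uses the final second only), so
  initialization affects nothing that is scored.
* **Noise.** The three external drives are redrawn independently every
  step as $\mu + \sigma\,\mathcal N(0,1)$, three draws per step in fixed
  order (Cor, Str, GPi) from R's seeded generator; a run is bit-for-bit
  reproducible from `(seed, config)`. Replicates differ only in their
  noise realization.
* **Delay discretization.** $\tau$ is rounded to
  $\mathrm{round}(\tau/dt)$ steps; all preset delays are exact multiples
  of $dt$. The delay history is the actually simulated LFP from $t = 0$
  (onset 1 s far exceeds the largest preset delay, and shorter onsets
  are rejected if $\tau >$ onset).
* **Spectra.** Rectangular window, mean subtracted, one-sided power
  normalized so summed power equals the windowed variance; dominant
  frequency is the raw argmax bin (no interpolation). Unstimulated runs
  are analyzed over the full 3 s (1/3 Hz bins), stimulated runs over the
  post-onset 2 s.
* **Oscillation index.** Implemented literally as the printed index —
  summed squared deviation over the final second divided by $1/dt$, i.e.
  a mean *squared* deviation — although the surrounding prose says
  "standard deviations". The formula wins; `sqrt = TRUE` gives the RMS
  variant for anyone preferring the prose reading.
* **Energy index.** Mean squared stimulation signal over
  $t \in (1\,\mathrm s, 3\,\mathrm s]$. No amplitude limiter is applied
  to the feedback signal (real stimulators clip; the model does not).
* **Divergence.** A non-finite state aborts the run with the offending
  step index; sweep cells average over completed replicates and record
  `n_ok`.

## Sweeps and suppression islands

`run_sweep()` averages OI and EI over seeded replicates on a
$(K, \tau)$ grid. Replicate seeds are hashed from the base seed and the
cell's parameter *values*, so refining a grid never changes existing
cells. "Suppressed" is defined as summed OI (three nuclei) below 10 % of
the summed unstimulated pathological baseline — the source figures show
near-flat LFPs under successful control, implying at least an
order-of-magnitude OI drop, and in practice successful cells sit many
orders below the threshold, so the result is insensitive to the exact
fraction (it is configurable regardless). `island_center()` takes the
largest 4-connected suppressed component and calls its center the
OI-minimizing cell, ties broken by smaller EI, then smaller $\tau$, then
smaller $|K|$; an all-clear grid returns `found = FALSE` rather than an
error. The island-"center" notion in the source literature is visual
(heat-map inspection); the argmin is our operationalization, and on very
flat suppression floors the two can differ — see limitations.

The default reproduction grids are $\tau \in \{1,\dots,50\}$ ms in 1 ms
steps and $K \in [-5, 5]$ in 0.1 steps, with 5 replicates per cell for
everyday use and 20 for final figures, matching the 20-repetition
protocol of the study; with the compiled core a 250-cell sweep at 5
replicates runs in a few seconds.

## What the noise generator does and does not emulate

The external inputs model the aggregate cortical, striatal and GPi drives
as white Gaussian pulse-density fluctuation about fixed means. This
captures the trial-to-trial variability the replicate averaging is meant
to tame, but not slow drifts, state transitions, 1/f structure or
correlated inputs of real recordings. Consequently, passing tests show
that the *model circuit* behaves as published under its own stated drive,
not that the controller would perform identically on physiological LFPs.

## Known limitations

* The network has exactly three nuclei; thalamocortical feedback, GPi
  dynamics and plasticity are out of scope, as are spiking or
  conductance-based descriptions.
* Strategy D's delay profile has an extremely flat suppression floor
  (roughly $\tau \in 5$–$14$ ms all within a few percent of the minimum,
  OI some nine orders below baseline). The argmin of such a floor is a
  fragile summary: we reproducibly find it at 12–13 ms, while visual
  island-center readings place it at 8 ms — both inside the same deeply
  suppressed interval. Interpret 1-D delay optima of deeply suppressed
  schemes as intervals, not points.
* Euler at $dt = 10^{-4}$ s carries a ~5 % amplitude bias on the
  pathological limit cycle relative to a twice-refined grid; frequencies
  and all suppression conclusions are unaffected.
* Only linear delayed feedback is implemented; nonlinear delayed
  feedback, threshold-triggered and phase-locked stimulation are not.

## Session info

```{r}
sessionInfo()
```
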