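---
title: "Methods: canonical-microcircuit DCM of mismatch responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: canonical-microcircuit DCM of mismatch responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmndcm)
```

## The scientific problem

The mismatch negativity (MMN, or MMNm for its magnetic counterpart) is the
evoked difference between rare deviant sounds and frequent standards.
`mmndcm` asks *which changes in effective connectivity generate it*: does a
deviant transiently disinhibit auditory cortex (an intrinsic gain change),
alter the ascending (forward) drive, alter the descending (backward)
predictions, or recruit the frontal operculum? The package implements the
whole chain needed to answer that question on data with known ground
truth: a biophysical generative model of evoked fields, Bayesian inversion
of condition-specific connectivity changes, and hierarchical group
inference over a factorial design (stimulus deviance, melodic
predictability, musicianship, and their interaction).

## Generative model

### Neural dynamics

Each cortical source is a canonical microcircuit of four populations —
spiny stellate cells (ss), superficial pyramidal cells (sp), inhibitory
interneurons (ii) and deep pyramidal cells (dp) — with second-order
(current/voltage) kinetics per population:

$$\dot v_p = i_p,\qquad
  \dot i_p = \frac{U_p - 2 i_p - v_p/\tau_p}{\tau_p},$$

where $U_p$ collects synaptic input: fixed-sign intrinsic couplings times
the presynaptic firing rates, extrinsic afferents, and (for spiny cells of
A1) the thalamic drive. Firing rates come from a baseline-subtracted
sigmoid $\sigma(v) = s_{\max}(\operatorname{logistic}(\rho v) - 1/2)$, so
the origin is an exact fixed point of the unforced system and all
responses are deviations from rest.

Connectivity follows the canonical layout: forward connections arise from
superficial pyramidal cells and excite spiny stellate and deep pyramidal
cells of higher areas; backward connections arise from deep pyramidal
cells and inhibit superficial pyramidal cells and interneurons of lower
areas. Within a source, ten fixed-sign couplings produce net inhibition;
the superficial-pyramidal self-inhibition is the "gain" whose modulation
implements disinhibition.

All free parameters are **log-scalings of signed bases**: a connection's
effective strength is `base * exp(theta)`, so excitatory connections can
never become inhibitory (and vice versa), and a condition modulation `B`
multiplies a strength by `exp(B)` during deviant processing only. The
difference wave is therefore *identically zero* when `B = 0` — a property
the test suite asserts end to end.

### Base values and calibration

The base couplings are not estimated; they define the operating point.
They are recorded, versioned, in
`inst/extdata/cmc_defaults.yaml`: time constants
$\tau = (4, 8, 16, 20)$ ms for (ss, sp, ii, dp), sigmoid slope 2/3 per mV
with unit maximum, intrinsic gains 100–800, forward bases 1600/800 (to
ss/dp), backward bases −800/−400 (to sp/ii), and a Gaussian thalamic bump
peaking at 60 ms (SD 16 ms, amplitude 100) entering both A1 nodes. These
magnitudes were calibrated once, as a package design decision, against
four qualitative requirements and then frozen:

* the origin is locally stable (all Jacobian eigenvalues have negative
  real part) and trajectories stay bounded;
* responses are approximately linear in input amplitude at the default
  drive;
* activity propagates up the hierarchy with plausible latencies (A1
  peaking near 75 ms, STG later);
* a single intrinsic disinhibition (`B = ln 0.7` on rA1) yields a
  difference wave with one dominant peak between 100 and 250 ms — the
  latency band where melodic pitch MMNm responses live.

The input width/amplitude and the conduction delays (1 ms intrinsic, 8 ms
extrinsic) are likewise package defaults: only the 60 ms input peak is
externally constrained.

### Network and model space

The default network has five sources at fixed MNI coordinate priors —
bilateral primary auditory cortex (lA1 −50 −16 −4; rA1 46 −16 0),
bilateral anterior STG (lSTG −58 −6 6; rSTG 56 2 −1) and the right
frontal operculum (rFOP 50 4 12) — wired forward lA1→lSTG, rA1→rSTG,
rSTG→rFOP and backward along the reversed edges. Both A1 nodes receive
the thalamic input. Two open choices were resolved as follows and are
configurable through the network object: opercular connections are
restricted to the right hemisphere (the operculum node is right-lateral
and has no left homologue), and the modulable intrinsic connection is the
superficial-pyramidal self-inhibition gain only.

Condition modulations are grouped into four families — intrinsic (gains
of lA1, rA1, lSTG, rSTG), forward (lA1→lSTG, rA1→rSTG), backward
(lSTG→lA1, rSTG→rA1) and opercular (rSTG→rFOP, rFOP→rSTG, rFOP gain; the
interpretation of "connections within, to, and from" the operculum).
Switching each family on or off yields $2^4 = 16$ models, a null model
with nothing modulated, and overlapping families of 8 models each. Model
ordering is binary counting with the first family least significant — a
package convention, fixed so that enumeration is reproducible.

A three-source option (`reduced_network()`: lA1, rA1, rSTG) drops the
operculum and the left STG; it exists purely to make simulation studies
cheap, and the family machinery degrades gracefully to $2^3 = 8$ models.

### Observation model

Sources are point current dipoles at the coordinate priors inside a
single-sphere conductor; the sensor-level field is the analytic
spherical-conductor (Sarvas) solution evaluated along the radial normals
of a synthetic 102-magnetometer cap (shipped as a plain-text fixture and
reproducible from `make_sensor_layout()`). Homologous left/right pairs
are constrained to mirrored locations and orientations
(inter-hemispheric dipole symmetry); the unpaired operculum is free. The
left/right coordinate priors are not exact mirror images, so symmetry is
imposed by moving each pair to the mirrored mean of its priors. A
realistic boundary-element head model is out of scope by design: the
single sphere preserves the properties that matter here (linearity,
silent radial dipoles, mirror topographies).

Sensor data are reduced to the `k` leading spatial singular vectors
before inversion (default `k = 8` for the five-source network, a
conventional choice; the retained-variance fraction is reported), and
each channel/mode is mean-centred over the 0–300 ms fit window, matching
how the data are prepared.

## Inversion

`fit_dcm()` inverts standard and deviant responses jointly per subject
and condition: the standard is generated by the baseline connectivity,
the deviant by baseline plus `B`. The optimiser is a variational-Laplace
scheme: Gauss–Newton ascent on the free energy

$$F = \underbrace{\Big\langle \log p(y\,|\,\theta,\lambda)\Big\rangle_q}_{\text{accuracy}}
 - \operatorname{KL}\big[q(\theta)\,\|\,p(\theta)\big]
 - \operatorname{KL}\big[q(\lambda)\,\|\,p(\lambda)\big],$$

with central finite-difference Jacobians (steps scaled to 1/16 of each
prior SD), Levenberg–Marquardt regularisation, and a Newton update for
the shared log noise precision $\lambda$ per spatial mode. Steps that
would decrease $F$ are rejected and the regulariser inflated, so the
accepted-step $F$ sequence is non-decreasing by construction.
Convergence is declared after three consecutive accepted improvements
below 0.01 nats (at most 64 iterations by default; the simulation suites
cap at 12–16, which the linear-rate of the scheme makes ample at these
problem sizes). Data are rescaled to unit variance before fitting (the
scale is folded back into predictions), which keeps the $\lambda$
hyperprior (`N(0, 16)`) weakly informative across SNRs.

Priors are zero-mean Gaussians on the log-scalings, with variance 1/16
for the B-parameters freed by a model and exact zeros (pinned, excluded
from the optimisation) elsewhere. Only the full model is ever fitted;
evidence for the other 15 models comes from Bayesian model reduction at
the group level. Optional parameter families (baseline extrinsic
strengths, intrinsic gains, input gains and timing, time constants,
dipole moment-vectors and locations with an 8 mm location prior SD) can
be freed through `default_priors(free = ...)`; the recovery suites keep
them pinned because the generator uses the prior-mean values — the
defensible choice when the generative observation model is known exactly,
and the reason a recovery replicate costs seconds rather than hours.

On a linear observation model this machinery is exact, which provides its
strongest test: posterior mean, covariance and the free energy agree with
closed-form Bayesian linear regression to ~1e−9 relative, and the
analytic reduced-model evidence agrees with explicit refits to 1e−6.

## Group level

First-level B posteriors enter a parametric-empirical-Bayes GLM with two
rows per subject (HP and LP conditions) and four columns: a constant (the
deviance/MMN effect — B already encodes the standard→deviant change),
predictability (±0.5), musicianship (±0.5, both mean-centred) and their
product. Because everything is Gaussian, the second level is conjugate:
each subject's likelihood precision is recovered from its posterior by
subtracting the prior precision (eigenvalue-clipped at zero), and the
posterior over group effects $\beta$ and the exact marginal likelihood
are available in closed form given the between-subject covariance. That
covariance is `exp(-γ) * (prior variance / 16)` with scalar `γ` estimated
by maximising the second-level free energy under a `N(0, 1)` hyperprior —
wide enough that realistic between-subject SDs (the generator's 0.15) are
recovered rather than shrunk away.

Downstream inference is entirely evidence-based, via Bayesian model
reduction (never refitting):

* **Factor comparison** pools the evidence of all models in which a
  factor modulates something against those in which it does not (the
  null model alone, or the family-off half when comparing one family),
  with equal prior mass on the two pools and uniform weights within a
  pool — so perfectly symmetric evidence gives probability 0.5.
* **Family posteriors** sum posterior model probabilities of members
  under uniform model priors; families overlap, so the four
  probabilities may sum above 1.
* **BMA** averages reduced posteriors over the 16 models weighted by
  their posterior probability; intervals are exact quantiles of the
  Gaussian mixture (root-finding on the mixture CDF), not a normal
  approximation.
* **Greedy BMR** prunes, one at a time, the β entry whose removal most
  increases evidence (ties broken in canonical parameter order) until no
  removal helps; a parameter's probability is the sigmoid of the final
  with-vs-without log-evidence difference, and pruned entries are
  reported as exactly 0. The retained set is invariant to parameter
  permutation, which the suite checks.

Parameters are pinned with a variance floor of 1e−8 rather than exact
zeros, used consistently on both sides of every comparison; at that floor
the approximation error is far below every tolerance used.

## The synthetic study

The generator reproduces the study conditions end to end, and its
defaults are fixed in the shipped configuration:

* **Paradigm**: 32-note, 8 s, gapless melodies of 250 ms tones from a
  31-semitone pool (B3 ≈ 247 Hz to F6 ≈ 1397 Hz, 12-TET, A4 = 440 Hz);
  high-predictability melodies are Alberti-bass figures (4-periodic in
  pitch, two octaves), low-predictability melodies a seeded random walk
  over a diatonic scale — a statistical emulation with lower
  repetitiveness and broader local range, not a note-for-note score.
  Each melody is transposed upward 0–5 semitones. Deviants (pitch = +50
  cents, plus timbre/intensity/glide labels) are placed one per feature
  per melody, uniformly within distinct four-note groups, with no
  same-feature succession anywhere in a session; each of three blocks
  opens with a deviant-free melody. The default 48 deviant-bearing
  melodies per block yields 144 deviants per feature per condition. (The
  two published counts — melodies per block vs deviants per condition —
  cannot both hold with three blocks; the per-condition total is taken
  as authoritative and the per-block count is the configurable knob.)
  Only pitch deviants feed the modelling path.
* **Cohort**: 20 musicians + 20 nonmusicians by default; each design
  row's true `B` is `X β_true` plus `N(0, 0.15²)` between-subject noise.
  Effect magnitudes default to 0.5 log-units (≈ ×0.6 disinhibition when
  negative) — comfortably above the 0.3 threshold at which sign recovery
  is expected, and of the order such modulations take in evoked-response
  studies.
* **Sensor noise**: white Gaussian noise scaled so the grand-average
  difference-wave RMS over noise RMS equals the reference SNR of 5, the
  regime in which single-subject B recovery is strong but not trivial.
  Trial-level epochs (for the preprocessing pipeline) add noise scaled
  by √n so that averaging n trials reproduces the evoked-level noise.

What passing recovery tests does **not** show about real data: the
generator shares the inversion's forward model (no head-model mismatch),
its noise is white (no 1/f or physiological artefacts), between-subject
variation enters only through B (anatomy and baseline dynamics are
common), and deviant features other than pitch carry no acoustic
content. Recovery here validates the inference machinery, not the
biology.

## Problem sizes

The shipped suites use sizes chosen to exercise every claim at desk
scale: recovery replicates run 10+10 subjects × 2 conditions on the
three-source network with 4 spatial modes and a 12-iteration cap (about
ten seconds each; 10 replicates per scenario, 20 for null calibration);
oracle suites use 40–80-sample linear models; paradigm constraint scans
cover 10,000 melodies. The five-source network with freed dipole
parameters is the same code path and is exercised by the smoke tests;
full-scale inversions of it are minutes per subject and left to the
user.

## Known limitations

* The single-sphere forward model and synthetic cap cannot capture
  individual head geometry; gain columns are realistic in structure but
  not subject-specific.
* One shared noise log-precision across modes (configurable in
  principle, fixed here) understates structured noise.
* Greedy BMR explores a nested path, not all $2^{mp}$ models; with
  strongly correlated posteriors the retained set can differ from
  exhaustive search.
* LP melodies are statistically, not literally, the published stimuli;
  information-theoretic predictability modelling is out of scope.
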