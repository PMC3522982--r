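---
title: "The swipe-card model of odorant recognition: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The swipe-card model of odorant recognition: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ietolf)
```

## The model

In the swipe-card picture of olfaction, molecular shape gets an odorant into
the receptor's binding pocket, but the identifying information is read out by
another property: the odorant's vibrational spectrum. The receptor holds two
localized electronic sites, a donor D and an acceptor A, with discrete
energies separated by a gap $\Delta\varepsilon$. An electron can only move
from D to A if the energy it releases is absorbed somewhere. If the gap
matches a vibrational quantum $\hbar\omega_0$ of the docked odorant, the
electron tunnels inelastically, depositing one quantum into that mode — the
*discriminating* channel. The competing *non-discriminating* channel dumps
the energy into environment (host) modes instead and carries no information
about the odorant.

The per-channel transfer rate is a golden-rule, Marcus-type expression with
Franck–Condon vibronic weights:

$$
\frac{1}{\tau_{D,0 \to A,n}} \;=\;
\frac{2\pi}{\hbar}\,|t|^2\,\sigma_n\,
\frac{1}{\sqrt{4\pi k_B T \lambda}}\,
\exp\!\left(-\frac{(\varepsilon_n - \lambda)^2}{4 k_B T \lambda}\right),
\qquad
\varepsilon_n = \Delta\varepsilon - n\,\hbar\omega_0 .
$$

Here $|t|$ is the electronic matrix element, $\lambda$ the environment
reorganization energy, $k_BT$ the thermal energy, and $\sigma_n$ the weight
of the channel in which the odorant mode absorbs $n$ quanta. For a displaced
harmonic mode with Huang–Rhys coupling $S$ at low temperature these weights
are Poissonian, $\sigma_n = e^{-S}S^n/n!$; the thermal occupation of a
0.2 eV mode at $k_BT = 0.027$ eV is $e^{-\hbar\omega_0/k_BT} \approx 6\times
10^{-4}$, so the low-temperature form is appropriate and upward (anti-Stokes)
channels are neglected. `vibronic_weights()` exposes the weights;
`transfer_rate()` evaluates the rate.

A *tuned* receptor has $\Delta\varepsilon = \hbar\omega_0$, making the
$n=1$ channel activationless ($\varepsilon_1 = 0$ is close to the small
$\lambda$) while the $n=0$ channel must push the full quantum into
environment modes and pays a Marcus penalty $\exp(-(\hbar\omega_0 -
\lambda)^2/4k_BT\lambda)$.

## Parameters and defaults

`receptor_params()` defaults to the working parameter set of the model:

| parameter | symbol | default | meaning |
|---|---|---|---|
| vibrational quantum | $\hbar\omega_0$ | 200 meV | detected odorant mode (~1600 cm$^{-1}$) |
| Huang–Rhys factor | $S$ | 0.1 | electron–odorant-mode coupling |
| reorganization energy | $\lambda$ | 30 meV | environment coupling, inner + outer shell |
| matrix element | $\vert t\vert$ | 1 meV | D–A electronic coupling |
| thermal energy | $k_BT$ | 0.027 eV | physiological temperature |
| D–A gap | $\Delta\varepsilon$ | $=\hbar\omega_0$ | tuned receptor |

With these values the package computes $\tau_{T0} \approx 87$ ns and
$\tau_{T1} \approx 0.15$ ns:

```{r}
channel_comparison(receptor_params())
```

The ratio of the two times is exactly independent of $|t|$ (both rates scale
as $|t|^2$), so the channel contrast survives the large uncertainty in the
electronic coupling.

The thermal energy default is the conventional printed value 0.027 eV rather
than $k_B \cdot 310\,\mathrm{K} = 26.7$ meV; the difference is below a
percent in the rates and every argument is overridable.

## The crossover in $\lambda$

Discrimination requires weak environment coupling. Setting the two channel
rates equal for the tuned receptor gives a closed form for the crossover
reorganization energy

$$
\lambda^* = \frac{(\hbar\omega_0)^2}{2\hbar\omega_0 - 4k_BT\ln S},
$$

about 62 meV for the defaults — above it the non-discriminating channel wins.
`crossover_lambda()` implements the closed form and, as an independent
numerical cross-check, a bisection (`uniroot`) on the log rate ratio over
(1 meV, $\hbar\omega_0 - 1\,\mu$eV); the two agree to better than $10^{-9}$ eV.
For $S = 1$ the formula degenerates to $\hbar\omega_0/2$; for $S > 1$ the
inelastic weight already exceeds the elastic one and no crossover exists in
$(0, \hbar\omega_0)$, which the function reports as an error rather than a
number. `lambda_sweep()` tabulates both channel times over a $\lambda$ grid
for plotting.

The reorganization energy itself can be estimated from its parts:
`inner_shell_reorganization()` sums harmonic-mode contributions
$\tfrac12\sum_\alpha k_\alpha Q_\alpha^2$, and
`outer_shell_reorganization()` evaluates the two-sphere dielectric-continuum
form. The printed form of that continuum expression carries $+1/r_{12}$ where
the conventional two-sphere Marcus formula has $-1/r_{12}$; both sign
conventions are implemented, with `as_printed` the default for fidelity to
the source model and `standard_marcus` available. In a non-polar pocket
($D_{op} = D_S$) both give zero, which is the regime the model needs.

## Supporting estimates

* `rms_displacement()` — thermal rms amplitude
  $\sqrt{(\hbar/2M\omega)\coth(\hbar\omega/2k_BT)}$ of an oscillating atom.
  The default mass convention is $M = 1$ amu for a hydrogen stretch (only
  the proton moves); a reduced mass can be passed instead.
* `coulomb_splitting()` — the D–A gap produced by a nearby point charge,
  $(e^2/4\pi\varepsilon_0)(1/R_A - 1/R_D)/\varepsilon$: a plausible tuning
  mechanism, giving 0.24 eV (1935 cm$^{-1}$) for a proton at 4 Å/5 Å with
  $\varepsilon = 3$.
* `diffusive_rate()` / `biased_rate()` — order-of-magnitude charge-supply
  rates $D/L^2$ and $(qU/k_BT)\,D/L^2$; the bias wins exactly when
  $qU > k_BT$. Units follow the worked estimate they reproduce
  (D in cm²/s, L in nm).
* `multiphonon_suppression()` — the one-quantum : two-quantum probability
  ratio $S_M/(\tfrac12 S'S'')$, the margin by which single-mode detection
  stands above the two-phonon background.
* `matrix_element_suppression()` — rate factor $f^2$ for a coupling reduced
  by $f$.

## Kinetic race models

Tunnelling competes with other receptor processes — the donor electron can
drain back to its reservoir, or the odorant can leave. With every process
memoryless (the unique realization of "constant probability per unit time",
implemented as exponential holding times), tunnelling with mean time
$\tau_X$ beats a competing process with mean time $\tau_R$ with probability
$\tau_R/(\tau_R + \tau_X)$ (`success_probability()`). The ratio of
successful dockings for a right molecule ($\tau_M$) versus a wrong one
($\tau_W$) is $(\tau_R + \tau_W)/(\tau_R + \tau_M)$
(`frustration_ratio()`): a short window passes only the fast discriminating
channel.

When each attempt additionally requires a slow donor-replenishment step
$\tau_D$, the expected time to the first successful transfer is
$\tau_D(1 + \tau_X/\tau_R)$ (`delayed_transfer_time()`), and the separation
between wrong- and right-molecule signal times,
$(\tau_W - \tau_M)\tau_D/\tau_R$ (`signal_separation()`), can dwarf the raw
tunnelling-time difference when $\tau_D \gg \tau_R$.

`simulate_receptor_cycle()` realizes the race stochastically. Defaults for
the slow timescales ($\tau_R$, $\tau_D$ = 30 µs) are the geometric midpoint
of the 1 µs–1 ms range characteristic of charge transport along the
receptor, and the integration window defaults to 1 ms (the neural
timescale); all are user-settable, since the model fixes only their orders
of magnitude. Two modes are provided because the underlying question — can
one residence fire more than once per millisecond? — is open:

* `single_shot` (default): one race per docking, at most one influx.
* `multi_shot`: after each successful influx the donor is replenished
  ($\tau_D$) and the race repeats until a race is lost or the integration
  window closes.

The simulator takes a mandatory seed, restores the caller's RNG state, and
its single-shot influx fraction is tested against the analytic race
probability at $n = 10^5$ dockings within three binomial standard errors.

## Spectral discrimination layer

An odorant is reduced to its mode table (label, frequency in cm$^{-1}$,
Huang–Rhys factor, optional reduced mass and hydrogen flag); a receptor to a
tuned frequency, a resolution window, and an acceptable coupling range.
`receptor_activation()` declares activation when at least one mode falls
inside both windows. Design choices:

* **Resolution window default ±25 cm⁻¹**, boundary inclusive (a mode exactly
  at the edge counts as detected — the tie-break is documented rather than
  left to floating-point accident). This is the empirical detection limit
  suggested by odorant pairs such as hydrogen sulphide and decaborane, whose
  shared ~2600 cm$^{-1}$ stretches differ by about that much yet both smell
  sulphurous.
* **Coupling acceptance default [0.01, 0.3]** (the broad plausible range of
  Huang–Rhys factors), with the narrower efficient-detection band
  [0.05, 0.3] available as `coupling_range_preset("useful")`.
* **Activation is binary here.** Graded efficacy is obtained by composing
  `receptor_activation()` with `transfer_rate()` on the matching mode's
  $S$; it is deliberately not baked into this layer, keeping the
  binary-versus-graded question a caller decision.
* Activation depends only on the (frequency, $S$) multiset: permuting or
  relabelling modes can never change a decision, so two spectra with
  identical multisets — enantiomers, whose frequencies are identical by
  symmetry — produce identical activation rows. Differing enantiomer
  percepts would have to enter through differing $S$ or $|t|$ inputs, which
  is the caller's modelling responsibility. Receptor antagonism (occupancy
  without activation) is not modelled.

`activation_matrix()` assembles the combinatorial code of a panel:
two odorants "smell different" at this level exactly when their rows differ.
`apply_isotope_substitution()` scales hydrogen-flagged mode frequencies by
the factor from `isotope_frequency_factor()` (H→D: $1/\sqrt{2}$, a ~29%
drop, about 800 cm$^{-1}$ on a 2730 cm$^{-1}$ stretch — far beyond the
25 cm$^{-1}$ window), and `isotope_discrimination()` asks whether the
deuterated twin's activation row differs. The factor, not an absolute
800 cm$^{-1}$ shift, is the ground truth: the shift a given mode shows
depends on its own frequency.

```{r}
ace <- odorant_spectrum("acetophenone-like", data.frame(
  label = c("CH-stretch", "CO-stretch"),
  freq_cm1 = c(2730, 1690), huang_rhys = c(0.1, 0.15),
  has_H = c(TRUE, FALSE)))
isotope_discrimination(ace, list(receptor_definition("CH-band", 2730),
                                 receptor_definition("carbonyl", 1690)))
```

## Synthetic spectra

`generate_synthetic_spectrum()` is the fixture generator used throughout the
test suite: frequencies uniform within user bands (defaulting to a
fingerprint band, 500–1700 cm$^{-1}$, and a stretch band, 2200–3100
cm$^{-1}$, where real odorant modes concentrate), couplings uniform in
[0.01, 0.3], hydrogen flags Bernoulli(0.5), all under a mandatory seed. For
each mode a band is first chosen uniformly among the supplied bands, then
the frequency uniformly within it. What it does *not* emulate: correlated
mode clusters, IR-intensity structure, anharmonicity, or any relation
between frequency and coupling — so tests passing on synthetic spectra
demonstrate the decision logic and its invariances, not fidelity to any
particular molecule's spectrum. Real mode tables (e.g. from quantum
chemistry) enter through `read_spectrum()`'s TSV format; computing them is
out of scope.

## Numerical choices

* Constants are CODATA 2018 (`physical_constants()`); the standard
  1 eV = 8065.543937 cm$^{-1}$ factor is used everywhere, including where
  rounded or slightly inconsistent conversions circulate in the literature
  (a 0.36 eV C–H stretch is 2903.6 cm$^{-1}$ under the standard factor).
* Energy quantities carry explicit units (`energy()`, `convert_energy()`),
  and CLI/config inputs *require* unit suffixes (`200meV`, `0.15ns`).
  Conversions round-trip to $10^{-12}$ relative.
* Vibronic weight truncation defaults to $n_{\max} = 10$, losing under
  $10^{-10}$ of the normalization for $S \le 0.3$.
* Bisection cross-check bracket (1 meV, $\hbar\omega_0 - 1\,\mu$eV),
  `uniroot` tolerance $10^{-12}$.
* Human-readable output rounds to 2 significant figures (the precision at
  which the model's numbers are meaningful); machine output (JSON/TSV) is
  full precision.
* Test and simulation problem sizes: $10^5$ dockings for the
  simulator-versus-analytic check, $10^4$ draws for generator band
  properties — enough for three-sigma binomial bounds while keeping the
  whole suite in seconds.

## Limitations

The package computes the physics of a *hypothesis*: it takes vibrational
quanta, couplings and reorganization energies as inputs and tells you what
the inelastic-tunnelling mechanism would do with them. It does not compute
spectra or Huang–Rhys factors from molecular structure, does not model
binding affinity, receptor structure, antagonism, or anything downstream of
the ion influx, and treats $|t|$ as a free parameter throughout.
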