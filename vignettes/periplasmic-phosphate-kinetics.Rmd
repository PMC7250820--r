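---
title: "Modelling periplasmic phosphate accumulation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling periplasmic phosphate accumulation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periphos)
```

## The scientific problem

Marine bacteria such as *Synechococcus*, *Prochlorococcus* and SAR11 take up
inorganic phosphate (Pi) from seawater that can be phosphate-depleted down to
nanomolar — and transiently femtomolar — concentrations. The textbook picture
has Pi diffusing through outer-membrane porins into the periplasm and being
handed directly to the ATP-driven PstSCAB transporter by the periplasmic
binding protein PstS. That picture struggles with three quantitative
observations:

1. cells sustain inward diffusion while *holding millions of labile Pi
   molecules* in a periplasm of only ~2e-17 l, where even a couple of free
   molecules already exceed the 1e-7 mol/l concentration scale of efficient
   PstS-mediated import;
2. the periplasm is far too small to bind that stock one-to-one on PstS:
   packing ~5.1e-23 l subunits into 2e-17 l caps the capacity near 4e5,
   roughly 17x short;
3. in dual-isotope pulse-chase experiments, assimilation of a 33P pulse into
   macromolecules continues at an unchanged rate after a 100x 32P chase —
   the opposite of the abrupt halt a direct-import model predicts.

The working model is therefore a *periplasmic buffer*: PMF-energised mass
transfer accumulates Pi (paired with chemiosmotic cations) in the periplasm,
and the importer draws on that buffered stock. This package implements the
quantitative framework around that model: the feasibility arithmetic, the
diffusion-theory clearance ceilings, the pulse-chase compartment model with
its measurement operators, and the estimators used on such data.

## The compartment model

Per isotope channel $c \in \{^{33}\mathrm{P}, ^{32}\mathrm{P}\}$ the model
tracks seawater tracer $C_{sw,c}$ (mol/l) and four per-cell pools
(molecules/cell): surface-adsorbed $A_c$, periplasmic buffer $P_c$,
cytoplasmic labile $L_c$, macromolecule-bound $M_c$:

$$
\begin{aligned}
a_c &= g(t)\,\ell(t)\,\mathrm{CL}\; C_{sw,c} N_A
  &\text{(accumulation)}\\
v_c &= V_{max} \frac{P_c}{K + P_c}, \qquad K = K_m N_A V_{peri}
  &\text{(import)}\\
\dot P_c &= a_c - v_c, \quad
\dot L_c = v_c - k_{assim} L_c, \quad
\dot M_c = k_{assim} L_c,\\
\dot C_{sw,c} &= -\rho\, a_c / N_A,
\end{aligned}
$$

with cell density $\rho$, inhibitor gate $g(t)$, light multiplier $\ell(t)$,
and optional adsorption ($k_{ads}, k_{des}$) and periplasmic leak terms that
default to zero (retention of the buffered stock is PMF-independent, so no
leak is the reference behaviour). Additions are instantaneous seawater
increments. Between additions the model conserves label exactly, per
channel.

### Why import is per-channel saturable

The one genuinely open design choice was how the two isotope channels share
the import flux once the importer is saturated. A single shared
Michaelis–Menten flux split in proportion to the channels' buffered
fractions, $v_c = V_{max} P_c / (K + P_{tot})$, looks natural for a
well-mixed buffer — but it cannot reproduce the defining pulse-chase
observation. With $K_m = 10^{-7}$ mol/l referenced to a 2e-17 l periplasm,
$K$ is of order *one molecule*: the importer is saturated from the first
minutes, and a 100-fold chase floods the buffer so that the pulse's share
$P_{33}/P_{tot}$ — and with it the pulse's assimilation rate — collapses
roughly a hundredfold within minutes, for any parameter set that also leaves
the observed 45–70% pulse residue at 2 h. The experiments show the opposite:
pulse assimilation continues at an unchanged rate while the chase is
imported *in parallel*.

The default import law is therefore per-channel saturable,
$v_c = V_{max} P_c/(K + P_c)$: each channel's buffered stock, being far
above $K$, keeps its own import running at capacity, undisturbed by the
other channel. This is a phenomenological statement — mechanistically one
would expect competition at a shared transporter, and precisely that tension
is what motivates the buffer-plus-ion-pairing interpretation in the first
place. The competitive law remains available
(`import_sharing = "proportional"`), and the two coincide in the linear
regime $P \ll K$, which is where the simulator is verified against an
independent matrix-exponential solution of the linearised chain.

### The unbuffered ("direct-import") comparison model

`buffer_bypass = TRUE` simulates the classical topology in which diffusion
is coupled directly to import: nothing accumulates, and the channels compete
for the saturated importer in proportion to their instantaneous delivery
$T_c = g\,\ell\,\mathrm{CL}\,\rho S_c$, i.e.
$u_c = T_c \min(1, V_{max}/\sum T)$. Under a 100x chase the diluted pulse is
out-competed at the transporter and its assimilation slope collapses more
than tenfold — the behaviour classical pulse-chase logic expects, and the
foil against which the buffered model's unchanged slope is the headline. (A
literal reading — keeping mass-transfer delivery but routing it straight to
the cytoplasm with no transporter in the way — would leave the pulse's
uptake untouched by the chase and distinguish nothing; the defining feature
of the unbuffered model is that the transporter, with its competition, is
in the direct path.)

### Measurement operators

Each laboratory protocol observes a different pool combination:

| protocol | measures | rationale |
|---|---|---|
| `ASW` | $A + P + L + M$ | seawater wash leaves all cell-associated label |
| `DW` | $L + M$ | hypotonic shock strips adsorbed label and empties the periplasm |
| `PFA` | $M + f_{pfa} P$ | aldehyde fixation keeps macromolecules plus the protein-crosslinked periplasmic fraction |
| `TCA` | $M$ | acid precipitation keeps macromolecules only |
| `effluent` | seawater residue | the filtrate's remaining tracer |

On noiseless data these nest: ASW ≥ DW ≥ TCA and ASW ≥ PFA ≥ TCA, and
cell-associated plus effluent label sums to 100% of the added tracer.

### Inhibitor events

Metabolic inhibitors enter as gating events, not new kinetics: CCCP and
DBMIB (PMF dissipation) zero the accumulation gate after a 4-min onset
delay, leaving import from the buffer running (a flag reverses that, since
PMF collapse also halts ATP synthesis and the data do not fully resolve
whether import continues); DCCD (ATPase inhibition) zeroes both gates after
a 3x longer delay; cation ionophores scale the clearance by a user-supplied
factor from their addition time. No inhibitor induces a periplasmic leak.
The onset delay is recoverable from a control/treated pair as
*treated plateau / control accumulation rate*
(`estimate_inhibition_delay()`), mirroring how such delays are derived
experimentally.

## The calibrated default experiment

`fig3_parameters()` and `fig3_design()` encode the reference dual-isotope
experiment: a 1e-8 mol/l 33Pi pulse at 0 h, a 1e-6 mol/l 32Pi chase at 2 h,
sampling to 23 h in technical duplicate. The calibration was fixed once,
from printed constraints, in this order:

* **Clearance** CL = 1.78e-13 l/cell/min — the value implied by doubling a
  1.93e7-atom cell quota in ~3 h at 1e-6 mol/l Pi (`quota_doubling_time()`).
* **Cell density** 2.5e10 cells/l (2.5e7 cells/ml, inside the 0.3–3e7/ml
  range of such experiments) — together with CL this leaves a 5.9e-9 mol/l
  pulse residue at 2 h, inside the reported 4.5–7e-9 window, and a chase
  dilution factor of ~170.
* **Import capacity** $V_{max}$ = 15 molecules/min and $f_{pfa}$ = 0.05 —
  place the labile:assimilated ratio at the 3 h point near 13–14, inside
  the observed 10–20x band. (The ratio's ceiling is
  $(1-f_{pfa})/f_{pfa} = 19$, so $f_{pfa}$ and $V_{max}$ are jointly
  constrained.)
* **Assimilation** $k_{assim}$ = 0.2/min — fast enough that the labile
  cytoplasmic pool stays small and the direct-import comparison model shows
  its >10x post-chase collapse; with per-channel import the buffered model's
  pre/post-chase slope ratio is ~1 for any $k_{assim}$, so this parameter is
  set by the comparison model, not by the headline benchmark.
* **$K_m$** stays at its physiological 1e-7 mol/l; referenced to the
  2e-17 l periplasm this saturates import within minutes, which is the
  intended regime ("the buffer keeps the transporter saturated").

## Estimators

**Isotope-dilution bioassay** (`isotope_dilution_fit()`): at added carrier
concentration $C_a$ the tracer turnover time is
$T = (C_{amb} + C_a)/v$. Per concentration, $T$ comes from a through-origin
regression of $\log(1-f)$ on time (all time points; the single-point variant
`turnover_time()` serves two-point field designs); the $T$ vs $C_a$ line is
then fitted by ordinary least squares, giving $\hat C_{amb}$ =
intercept/slope and $\hat v$ = 1/slope with delta-method errors. The
regression (rather than single-point) default is the lower-variance choice
among the variants in circulation; an inverse-variance weighted option
exists for series with ≥3 time points. The reference check runs a series of
six added concentrations (0–2e-8 mol/l, bracketing a 5e-9 ambient) by five
incubation times (15–120 min); at 5% multiplicative noise the median
ambient-concentration error over 100 draws is under 10%.

**Tracer-depletion clearance** (`clearance_from_depletion()`): a
through-origin fit of $\log F$ on $t$ gives $\mathrm{CL} = -$slope$/\rho$.
Fractions below a detection floor (default 1e-6, the ratio of a femtomolar
instrument floor to a nanomolar start) are censored; an increase in tracer
beyond 3 robust standard deviations (MAD) of the fit residuals raises a
non-monotonicity warning flag rather than an error. Because the remaining
fraction is concentration-free, the estimator is invariant to the starting
concentration across at least seven orders of magnitude — the property that
makes "clearance" the right currency for these organisms.

**X-ray fluorescence quota** (`sxrf_calibration()`, `sxrf_quantify()`):
phosphorus mass vs sorted-cell-number least squares with a free intercept
(the blank-filter background; a through-origin slope is also reported),
conversion to atoms/cell via the phosphorus molar mass and $N_A$, and hard
flags outside the validated 2e4–7.5e5 cell window. A non-positive net
signal is a *below-detection result*, not an error.
`genome_p_equivalents()` uses 2 phosphorus atoms per base pair; the
convention is an argument because published genome-equivalent figures are
not all reconcilable under one value.

## Fitting and identifiability

`fit_kinetics()` performs multi-start (default 8, log-uniform between
bounds, seeded) L-BFGS-B minimisation of square-root-scale residuals — the
variance-stabilising transform for Poisson-like scintillation counts — over
all (time, channel, protocol, replicate) records, with ties broken by
objective then by lowest clearance. $K_m$ is deliberately fixed: pulse-chase
data at two concentrations cannot separate it from $V_{max}$ when the buffer
saturates the importer throughout.

Recovery studies with the shipped generator (Poisson noise, 1e4 expected
counts at full signal, technical duplicates, ten seeds) show what such data
can and cannot support: clearance is recovered to a few tenths of a percent,
$V_{max}$ and $f_{pfa}$ to about a percent, but the assimilation rate only
to several tens of percent. The reason is structural, not numerical: with
fast assimilation the labile cytoplasmic pool holds
$V_{max}/k_{assim} \approx 75$ molecules — about 3 expected scintillation
counts — so the one pool that carries $k_{assim}$ information sits below the
counting noise. Slowing assimilation would fix this but would erase the
very collapse that distinguishes the direct-import model. Claims about
$k_{assim}$ from count-limited pulse-chase data should therefore be treated
as order-of-magnitude; `bootstrap_ci()` (case-resampling over records,
refit from the point estimates) makes the width of that uncertainty
explicit.

## The synthetic-data generator

`generate_pulse_chase()` emulates: the pulse/chase schedule, all five
measurement protocols, technical duplicates, and scintillation counting as
Poisson draws on expected counts (default 1e4 at 100% of added tracer),
rescaled to percent; a unit-mean lognormal alternative models pipetting
error. Seeds are explicit arguments, never global state. It does *not*
emulate filter-retention losses, flow-sorting noise, isotope decay
corrections, or biological between-replicate variation (replicates differ
only by counting noise) — so passing tests demonstrate correctness of the
estimators under the stated error model, not robustness to every field
artefact. Noisy bioassay fractions that exceed 1 are clipped to
$1 - 10^{-6}$ and flagged rather than resampled; this keeps generation
deterministic per seed at the cost of a small bias where uptake is nearly
complete.

## Numerical choices

* Integration: `deSolve::lsoda`, relative tolerance 1e-8, absolute
  tolerance 1e-3 molecules; additions, inhibitor onsets and light switches
  are exact breakpoints (integration restarts, events are never smoothed
  over).
* Seawater is carried as molecules-per-cell ($C N_A/\rho$) so that all ten
  state variables share one unit and the per-channel mass balance is a
  plain sum; tiny negative excursions (> −1e-6 molecules) are clamped to
  zero, larger ones raise an error.
* The linear-regime verification compares both import-sharing laws against
  a `Matrix::expm` solution of the linearised chain at $P/K \sim 10^{-8}$,
  with all pools ≥ 1e5 molecules so the absolute tolerance is negligible;
  agreement is required to 1e-6 relative.
* Optimiser termination at an essentially zero objective (≤ 1e-10) counts
  as convergence: L-BFGS-B reports an abnormal line search when started at
  a perfect fit.
* Reference problem sizes: pulse-chase runs use the 11-point sampling grid
  to 23 h; recovery studies use ten seeds with the default 8 starts;
  bootstrap checks use 100 resamples on a reduced 4-time-point design.

## Limitations

The model deliberately omits PMF electrophysiology (pH and potential enter
only through gates and factors), Pi speciation chemistry, polyphosphate
synthesis, and growth during the experiment (accumulation is
growth-decoupled on these time scales). The per-channel import law is a
phenomenological resolution of an observation that a shared-transporter
picture cannot produce; mechanistic work on how a saturated importer can
serve both isotope pools independently is exactly the open question the
buffer hypothesis raises. The diffusion ceilings use the equivalent-sphere
radius for rods; exact capacitance corrections are out of scope.
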