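---
title: "The fidproc processing engine: models, conventions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The fidproc processing engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fidproc)
```

## The signal model

An NMR free-induction decay is modelled as a sum of exponentially
decaying complex sinusoids sampled at the dwell time $\Delta t = 1/sw$:

$$x(t_i) = \sum_k A_k\, e^{i(2\pi f_k t_i + \varphi_k)}\, e^{-\pi\,
\mathrm{lw}_k\, t_i} + \varepsilon_i, \qquad t_i = i/sw,$$

where $f_k$ is the offset of resonance $k$ from the carrier in Hz and
$\mathrm{lw}_k$ the Lorentzian full width at half maximum in Hz (the
decay rate $\pi\,\mathrm{lw}$ makes this exact on the transformed line).
$\varepsilon$ is complex white Gaussian noise. This is exactly what
`simulate_fid()` generates, so every property the tests establish on
simulated data concerns this model. Real data additionally contain
baseline roll from receiver transients, solvent signals far stronger
than the analytes, digital-filter group delays, and lineshape
imperfections; the generator emulates the first two only through
explicit test constructions (polynomial/sinusoidal baselines, on-carrier
peaks) and the third through the `group_delay` field of raw traces.
Passing tests therefore demonstrate correctness of the transforms and
the engine's bookkeeping, not robustness to every pathology of
experimental data.

## Spectral conventions

* **Ordering.** After `ft()`, index 0 (0-based) is the most downfield
  (highest ppm, highest frequency offset) point; the carrier sits at the
  centre, `ref_point = n/2`. Bin $k$ holds offset $(n/2 - k)\,sw/n$ Hz.
  Chemical shift is strictly decreasing in index:
  $\delta(p) = \delta_{\mathrm{ref}} + (sw/sf)\,(p_{\mathrm{ref}} -
  p)/n$.
* **Normalization.** The forward transform is unnormalized; the inverse
  carries $1/n$. Parseval then reads $\sum|x|^2 = \sum|X|^2/n$, which
  the suite asserts exactly.
* **First point.** The $t = 0$ sample is halved before the forward
  transform (its discrete half-weight; otherwise a constant offset is
  added to the spectrum baseline) and doubled after the inverse, so the
  pair is exactly inverse. The correction is skipped when a digital
  group delay is present — the delay is instead corrected in the
  frequency domain as the first-order phase $e^{i 2\pi f \tau}$,
  $\tau = \mathrm{gd}/sw$, and cleared. Both behaviours can be disabled
  with `fp_half = FALSE`.
* **Hilbert regeneration.** `hft()` assumes a causal FID (zero over the
  second half of the time grid): the real spectrum is inverse
  transformed, points $1..n/2-1$ doubled, the second half zeroed, and
  the result transformed back. The operation is a projection
  (idempotent), exact for causal inputs, and `fused_hilbert_ift()`
  performs the Hilbert step and the inverse transform with a single
  inverse FFT since the intermediate forward transform cancels.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `SB` offset / end / power | 0.5 / 1.0 / 1 | window `sin(pi*offset + pi*(1-offset)*i/(end*(n-1)))^power`; the default is a cosine bell whose first point is 1 |
| `EXPD` lb | — | exponential broadening in Hz, `exp(-pi*lb*t)` |
| `GM` g1, g2 | — | Lorentz-to-Gauss `exp(pi*g1*t - g2^2 t^2 pi/(2 ln 2))` |
| `ZF` factor / size | next power of two, doubled | appended zeros before transform |
| IST iterations | 500 | thresholding iterations |
| IST threshold fraction | 0.98 | per-iteration threshold = fraction × current max absolute real intensity |
| `BCWHIT` lambda / p | 1e7 / 0.001 | second-difference smoothness and asymmetry of the Whittaker baseline |
| LP order | 8 | autoregressive coefficients, SVD-truncated at 1e-10 relative |
| threads | detected cores | worker processes; results are thread-count invariant |
| vectors per request | min(total/threads, 64) | traces per work unit |

The sine-bell defaults (offset 0.5, end 1.0, power 1) are the
conventional cosine apodization; note that with `end = 1.0` the window's
last point is exactly zero, so a sine-bell applied with the default
extent cannot be inverted by `UNDODIM` — use `end < 1` when an undo pass
is planned (the engine checks `min|w| > 1e-6` and refuses otherwise,
since division by a near-zero window value produces artifacts).

## The execution model

A processing script has three sections: file commands (`FID`, `CREATE`,
or `SIMFID` for simulated input), referencing commands (`sw`, `sf`,
`ref`, `label`, `skip`), and per-dimension operation lists opened by
`DIM(n)` and closed by the mandatory final `run()`. The dialect is
executed, not merely parsed: commands are functions in a locked-down
interpreter environment, so numeric arguments may be arithmetic over
`p('name')` parameter lookups, while any other function call is rejected
with a clear error. Regenerating text from a parsed plan and re-parsing
it is a fixed point (eagerly evaluated `p()` lookups stay resolved as
numbers).

`run_plan()` first performs a sizing pass over all operation lists to
establish final axis sizes (zero filling and linear prediction grow
axes; extraction shrinks them), then creates the destination with those
sizes. Dimension 1 is processed from the raw traces; every later
dimension reads its traces from the destination and writes them back in
place. Storage is hypercomplex: each processed axis keeps real and
imaginary parts interleaved (the axis's `complex` flag), which is what
makes later passes — and `UNDODIM`, which executes the recorded
operations' inverses in reverse order — possible. Data shorter than the
final axis size sit zero-padded; the run state tracks per-axis valid
sizes.

Parallel execution partitions traces into batches of
`vectors_per_request` and maps them over a worker pool; workers are pure
(they only compute), the parent writes results in a fixed order, so
output files are identical for any thread count. The suite asserts
byte-level equality for 1, 2 and 4 workers.

### Skipping and undoing

`skip(0,1,0)` marks dimension 2 as untouched; its `DIM` block may remain
in the script. The delayed linear-prediction workflow for 3D data —
process dimension 2 without LP, process dimension 3 with LP, undo
dimension 2, reprocess it with LP — is supported end to end and matches
direct dimension-3-first processing to within storage precision on
noiseless data, because LP prediction of noiseless exponential sums is
their analytic continuation and therefore commutes with processing of
the other dimensions.

## Referencing

Carrier shifts may be given as numbers (ppm at the axis centre),
vendor-parameter symbols, `'h2o'` (the water shift at the experiment
temperature via $\delta = 7.83 - T/96.9$, $T$ in kelvin, overridable),
an anchored `"ppm@MHz"` pair, or a nucleus letter. Letters use indirect
referencing: the zero-ppm proton frequency $f_0^H = sf_H/(1 +
\delta_H\cdot 10^{-6})$ is scaled by the published frequency ratios
($^2$H 0.153506088, $^{13}$C 0.251449530, $^{15}$N 0.101329118, $^{31}$P
0.404808636; Wishart et al., J. Biomol. NMR 6 (1995) 135) to give the
heteronucleus zero-ppm frequency, from which the axis's carrier shift
follows. Nucleus-letter axes therefore require dimension 1 to carry a
resolved proton reference.

## Iterative soft thresholding for non-uniform sampling

Only a subset of indirect-dimension increments is measured; missing
increments are zeros on the Nyquist grid. Each iteration of
`ist_reconstruct()`:

1. Fourier transforms the working trace and takes the **real** part
   (thresholding real values avoids the broad dispersive tails; the
   imaginaries are regenerated by the Hilbert transform under the
   causal-FID assumption);
2. moves the portion of every value beyond ±(0.98 × current max) into an
   add buffer, clipping the spectrum at the threshold (so clipped value
   + buffered excess equals the original — signal is conserved);
3. applies the fused Hilbert + inverse transform and zeroes the
   non-sampled time points.

After the final iteration the buffer is Hilbert-transformed, inverse
transformed, and the measured values are copied over the sampled
positions, so sampled points are returned bit-exactly and only missing
points are synthesized.

**Error metric.** Convergence is quantified as the normalized RMS
spectral error: the RMS difference between the reconstruction's real
spectrum and the fully sampled reference's, divided by the reference
peak height. Under this definition the single-resonance scenario
(600 MHz, 4000 Hz sweep width, 10 Hz linewidth, 4096 complex points, 20%
uniform sampling) is visibly incomplete at 64 iterations and first drops
below $10^{-2}$ at a median of roughly five to six hundred iterations
over random schedules — the package's reproduction of the method's
expected behaviour, recomputed by `scripts/acceptance.R`. The
alternative normalization by the reference's RMS is substantially
stricter and is dominated by how well the largest sampling gaps happen
to fall; with unlucky uniform schedules it plateaus at the percent
level, which is one reason gap-controlled (Poisson-gap) schedules are
preferred in practice. `make_schedule(mode = "poisson-gap")` provides
them.

The threshold schedule (a fixed fraction of the *current* maximum) and
the stopping rule (iteration count, or `stop_below` on the recorded
error) are parameters, not claims about any other implementation's
internals.

## Numerical choices

* Linear prediction fits autoregressive coefficients by least squares
  with SVD truncation at $10^{-10}$ relative; forward extension reflects
  characteristic roots outside the unit circle into it (`stabilize`),
  so predictions of decaying data cannot grow. Backward prediction for
  initial-point replacement deliberately does **not** reflect roots: on
  the reversed trace a decay is a growth, and reflecting would bias the
  few re-predicted points.
* The Whittaker baseline solves $(W + \lambda D_2^\top D_2) z = W y$ on
  mean-centred data with a banded sparse system (`Matrix`), iterating
  asymmetric weights ($p$ above the smooth, $1-p$ below) to a $10^{-6}$
  weight change or 50 iterations. Centring makes a flat spectrum correct
  to machine precision despite the large $\lambda$.
* `autophase` minimizes the negative-area penalty $\sum \min(\Re -
  \mathrm{median}, 0)^2$ over a 5° grid refined by golden-section
  (`p0`) or Nelder-Mead (`p0+p1`); entropy objectives were considered
  and left out of scope. The optimizer is deterministic.
* Datasets store big-endian float32 tiles (at most 32768 samples per
  tile, powers of two per axis). Read-after-write is exact at 32-bit
  precision; axis metadata round-trips exactly because the headers
  carry double-precision copies (in the `.ucsf` dialect these live in
  unused axis-header bytes that third-party readers ignore). Because
  storage is float32, round trips *through the file* — including
  `UNDODIM` — are accurate to about $10^{-7}$ relative, not machine
  epsilon; the in-memory operation inverses themselves are exact to
  $10^{-12}$.

## Problem sizes

The suite and the acceptance script run on deliberately small problems:
4096-point vectors for the reconstruction scenario, 64×32 and smaller 2D
fixtures, 16×16×16 3D arrays, ten random schedules for the iteration
median. These sizes make every property cheap to verify while keeping
the FFT-dominated reconstruction workload representative.

## Known limitations

* Interleaved pseudo-3D acquisitions and memory-resident whole-dataset
  processing are not implemented.
* IST operates on 1D indirect traces (2D datasets); an n-dimensional
  matrix variant would follow the same step structure with a
  per-dimension Hilbert convention but is not included.
* JCAMP support covers 1D AFFN tables (real or two-page complex), not
  compressed (DIFDUP) forms.
* Bruker group delays are taken from `GRPDLY`; the legacy DECIM/DSPFVS
  lookup table is not bundled.
* The `.nv` header layout is this package's documented convention — a
  self-consistent sub-matrix dialect, not a bit-compatibility claim
  about any external program's files.
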