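---
title: "Methods: mechanics and expression analysis of 3D tendon constructs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mechanics and expression analysis of 3D tendon constructs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tenomech)
```

tenomech quantifies how cylindrical collagen constructs seeded with human
adipose-derived stromal cells (hASCs) stiffen, become more solid-like, and
turn on a tendon gene program over three weeks of static-tension culture.
This vignette explains the models behind each stage, the tunable
parameters and their defaults, what the synthetic-data generator does and
does not emulate, and the numerical choices made where the underlying
experimental reports leave the design open.

## Spherical indentation and the effective Young's modulus

An indentation record is the triple (t, z, F): time in seconds, cantilever
*base* position in µm, and force in µN. Because the cantilever is a spring
of stiffness `k_cant` (N/m), the sample indentation is the base travel
past contact minus the cantilever deflection:

$$h = (z - z_c) - F / k_\mathrm{cant}.$$

Over the first micron of indentation the force of a sphere of radius $R$
on a soft elastic half-space follows the Hertz relation

$$F = \tfrac{4}{3}\, E_\mathrm{eff}\, \sqrt{R}\, h^{3/2},$$

where the Poisson-ratio factor $1/(1-\nu^2)$ is absorbed into the
*effective* modulus $E_\mathrm{eff}$ — the convention used by
soft-tissue nanoindentation instruments. `fit_hertz()` exposes an optional
`nu` argument that divides it back out, off by default. The model is
linear in $E_\mathrm{eff}$, so the least-squares estimator is closed form,

$$\hat E_\mathrm{eff} = \frac{\sum_i F_i g_i}{\sum_i g_i^2},
\qquad g_i = \tfrac{4}{3}\sqrt{R}\, h_i^{3/2},$$

which the test suite cross-checks against an iterative nonlinear fit.

**Fit window.** The window is 0–1 µm of *indentation* (not piezo travel),
the `h_max` parameter. Curves whose deepest in-window indentation falls in
[0.8, 1) µm are fitted over the available range with a warning; below
0.8 µm they are rejected rather than extrapolated.

**Contact point.** The instrument literature rarely states a contact-point
procedure, so the package defines one: a grid search at 10 nm resolution
(the piezo-resolution scale; `resolution` argument) over the loading
phase. Each candidate $z_c$ gets the pre-contact mean force subtracted as
a baseline, the window re-derived, and the closed-form fit scored by its
residual; the smallest residual wins, ties breaking to the smallest
$z_c$. Two guards make the search well-posed:

* a record whose force never rises above 3× the pre-contact noise SD is
  reported as `no_contact` rather than fitted;
* a candidate is only admissible if its *fitted* model amplitude at the
  window top exceeds 3× the noise SD. Without this, any candidate placed
  a full window before the true contact sees only pre-contact samples and
  "fits" them with $E = 0$ and zero residual.

On noiseless simulated curves the detector recovers the programmed
contact position to the grid resolution and the modulus to machine
precision; at 1 nN force noise on a 1.3 kPa curve it stays within 0.2 µm
and a few percent of modulus.

**Aggregation.** Five indents are performed along a construct and
averaged (`construct_modulus()`; a count other than five warns). Per-day
distributions are summarised with a plotting-position CDF,
$p_i = (i - 0.5)/n$, so the middle value of an odd-sized sample sits
exactly at 0.5 and the reported median is the CDF-0.5 value
(`modulus_cdf()`), interpolated linearly for even $n$. The CDFs pool
per-construct means, not individual indents, matching the five-site
averaging contract.

## Stress relaxation

After the loading ramp the cantilever base is held fixed for 10 s
(open-loop hold) and the relaxation percentage is

$$r_\mathrm{relax} = 100 \cdot \frac{F_\mathrm{max} - F_{t=10\,\mathrm{s}}}{F_\mathrm{max}},$$

with $F_\mathrm{max}$ the peak at the end of the ramp — implemented as the
maximum within ±0.1 s of hold onset, a window that tolerates one-sample
ambiguity in where segmentation places the boundary — and $F_{10s}$ the
force linearly interpolated at exactly 10 s after onset. An optional
±0.25 s averaging window (`smooth_window`) is available for noisy data
but off by default: the instantaneous reading is the defined statistic.
Negative percentages (upward creep) are reported with a warning, never
clipped — visible QC beats silent truncation. A higher percentage means
more liquid-like; lower, more solid- and elastic-like.

The simulator's material is a standard linear solid (SLS): instantaneous
modulus $E_0$, long-time modulus $E_\infty$, time constant $\tau$, and
$\alpha = E_\infty/E_0$. Its rigid-hold force decay is

$$F(t) = F_\mathrm{max}\left[\alpha + (1-\alpha) e^{-t/\tau}\right],
\qquad r_\mathrm{relax} = 100\,(1-\alpha)\left(1 - e^{-10/\tau}\right),$$

a closed form the pipeline must reproduce to within 0.1 percentage point.
Two hold modes are provided because the experimental hold fixes the
*base*, not the tip:

* **rigid** (default): tip frozen, exact exponential decay — the
  analytically testable reference;
* **compliant**: base frozen, so the tip creeps forward as the force
  decays; the SLS hereditary integral is advanced with an
  exponential-integrator step and the constraint
  $h = z - z_c - F/k_\mathrm{cant}$ is enforced by per-step fixed-point
  iteration.

Separating the two keeps physics fidelity (compliant) apart from pipeline
correctness (rigid): tests that need an exact oracle use the rigid mode,
and the compliant mode is verified qualitatively (monotone decay, forward
creep, less total relaxation than the rigid closed form predicts, since
creep partially re-loads the sample). `fit_sls_inverse()` recovers
$(\alpha, \tau)$ from a hold by nonlinear least squares
(Levenberg–Marquardt) and flags non-decaying holds as degenerate with
$\alpha = 1$.

## Relative gene expression (2^−ΔΔCt)

Cycle thresholds are normalised per sample to the reference gene YWHAZ
(`delta_ct()`), then per gene to the mean ΔCt of a control group
(`fold_change_ddct()`): ΔΔCt = ΔCt − mean(ΔCt~control~), fold = 2^−ΔΔCt.
Using the control *mean* (not per-sample pairing) makes the control
group's summary fold exactly 1 — the summary subtracts the stored control
mean from the group mean of the identical numbers, so the difference is
bitwise zero, not merely small. The control group is Day 0 by default, or
each gene's first detection day (`control_day = "first_detection"`), the
convention used for genes that switch on mid-culture.

* **Detection**: a gene counts as detected on a day when at least half
  its replicates have Ct below the cutoff. The cutoff defaults to 35
  cycles — the experiments report genes as "not detected" without stating
  one, and 35 is the conventional qPCR limit — and is configurable.
* **Outlier exclusion**: values more than 2 sample SDs from their group
  mean are dropped in a single pass (per gene × day, on ΔCt, before any
  testing). The rule is deliberately not iterated: recomputing mean and
  SD after each drop would over-trim, and a single pass can provably
  remove at most ⌊n/4⌋ values.
* **Testing**: two-sided Mann–Whitney throughout, exact when the smaller
  group has ≤ 8 observations and there are no ties (evaluated from the
  exact U null distribution; the suite checks it against full
  enumeration of labelings), otherwise the normal approximation with tie
  and continuity correction. Significance tiers \*, \*\*, \*\*\*, \*\*\*\*
  at 0.05, 0.01, 0.001, 0.0001; no multiple-testing correction is
  applied, faithful to the source analysis.

## Geometry and cell organisation

Construct diameters (mm) give cross-sectional areas $\pi d^2/4$ and —
because the constructs are pinned between fixed anchors so length is
constant — a volume fold change of $(d_0/d_1)^2$. The measured means
(2.08 mm at Day 0, 0.55 mm at Day 21) give 14.3, the "about 15-fold"
compaction. Cell orientation is the acute angle (0–90°) between a cell's
major axis and the construct axis, orientation-insensitive by
construction; per-construct means over 15 cells are plain arithmetic
means, not circular statistics, mirroring how the measurements are
reported. Regional cell density is count/area with the centre/periphery
boundary taken as an input annotation: the dense surface layer is only
three to four cells deep and no pixel rule is available, so segmentation
is out of scope.

## The synthetic-data generator

The generator exists so every stage can be exercised end-to-end with no
external data, under the same conditions the analysis assumes:

* **Elastic curves** obey the Hertz force law with cantilever compliance
  solved self-consistently per sample (vectorised Newton iteration),
  10 µm/s base speed, 1 kHz sampling, bead radius 37.5 µm (the middle of
  the 50–100 µm bead-diameter range), additive white Gaussian force
  noise, and a seeded RNG — every generator is a pure function of
  (parameters, seed). The default cantilever stiffness of 0.5 N/m is
  typical for the instrument class; it is recorded in every file header
  so the analysis never assumes it. No drift term is simulated: white
  noise is the simplest model that exercises contact-point robustness.
* **Relaxation records** ramp at the instantaneous modulus, hold 10 s
  (rigid or compliant, above), and retract with a schematic elastic
  unload so segmentation sees all three phases.
* **Ct tables** impose per-gene log2 trajectories on a baseline Ct
  (default 25; reference gene at 18), per-day replicate counts matching
  the expression experiments (29/19/18/25/17/16 for days 0/2/4/7/14/21),
  and encode undetected wells at the cutoff with a flag.
* **Orientations** are folded-normal angles about 0° with per-day
  dispersion; the defaults (SD 55° at Day 0 falling to 12° at Day 21)
  were chosen once as a realistic progressive-alignment series — the
  experimental reports give no numeric dispersions — and give per-day
  means falling from roughly 40° toward 10°. A dispersion of `Inf`
  produces the uniform distribution on [0°, 90°] (mean 45°), the
  no-alignment reference.
* **Diameters** are truncated-at-zero Gaussian draws at the printed
  per-day means and SDs (2.08 ± 0.08, 0.67 ± 0.02, 0.59 ± 0.02,
  0.55 ± 0.04 mm); **densities** are Poisson counts at centre
  1500/periphery 3000 cells/mm² over 0.02 mm² regions — the periphery
  excess is reported as significant but unquantified, so a two-fold
  ratio was fixed as the emulated effect.

`make_fixture()` assembles a full bundle: per-day median moduli doubling
every 7 days from 1.3 to 9.2 kPa for the cell-seeded arm (0.4 kPa
constant for the no-cell arm), per-day relaxation percentages 35/31/27/24
(cells; the two interior days interpolate the reported endpoints) and
23/15/15/15 (no-cell), τ = 2 s, and lognormal construct-to-construct
scatter (SD of log 0.25, consistent with the reported Day-21 spread of
5.6–18.3 kPa).

What passing tests on these data do **not** show: real force curves have
drift, adhesion hysteresis and surface roughness the generator omits;
real Ct tables have amplification-efficiency differences; real angle data
come from segmented images with their own biases. The generator
demonstrates that the *analysis* is correct under its stated model, not
that the model captures every artefact of real instruments.

## Numerical choices and degenerate inputs

* Interchange units are fixed by the file format (s, µm, µN); contact
  mechanics converts to SI internally. Records are written with 17
  significant digits so write→read round trips are bit-identical.
* Phase segmentation reads the base position only, so force noise cannot
  move phase boundaries; the hold plateau tolerance is 5 nm.
* `F ≡ 0` fits to `E_eff = 0` with zero residual rather than erroring —
  a flat record is a valid (empty) measurement for `fit_hertz()`, while
  the detector reports it as `no_contact`.
* The 10-s interpolation clamps to the final hold sample when the target
  overshoots the hold end by at most two sample periods (segmentation may
  place onset one sample late on a hold of exactly 10 s); larger
  shortfalls raise `insufficient_hold`.
* Statistical recovery properties (e.g. injected log2 effects recovered
  as fold changes within 5 % at 0.2-cycle noise and n = 14 per day) are
  asserted on the *expected* estimate — averaged over 20 independent
  seeded experiments — because a single experiment's group-mean ΔΔCt has
  a standard error near 0.11 cycles, i.e. ~8 % on the fold scale, and a
  single-draw assertion at 5 % would be a coin flip rather than a test
  of correctness.
* Problem sizes in the test suite are scaled for speed (2 constructs ×
  2 sites per arm and day at 200 Hz for pipeline tests); defaults for
  interactive use are 3 × 5 at 1 kHz.

## Known limitations

No adhesion (JKR/DMT) or finite-thickness corrections; no depth-dependent
modulus profiling; no full hereditary-integral (Ting) inversion or
frequency-domain viscoelasticity; no amplification-efficiency correction
or standard curves in the qPCR stage; no image processing anywhere — the
pipeline starts from measurement tables. These mirror the scope of the
measurements themselves rather than accidental omissions.
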