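---
title: "Methods: pencil-beam field characterization with pbfield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pencil-beam field characterization with pbfield}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbfield)
library(dplyr)
```

## The physical picture

A scanned proton pencil beam (PB) deposits most of its dose in a central,
Gaussian-shaped *core* whose lateral width $\sigma_C(z)$ grows with depth
$z$ through multiple Coulomb scattering (MCS). Around the core sits the
*halo*: a non-Gaussian envelope of dose from nuclear-scattered secondaries
and single large-angle scatters, extending to roughly a third of the beam
range laterally and peaking (relative to the central-axis dose) around
midrange. Though faint pointwise, the halo covers so much area that it
carries a non-negligible fraction of the integrated dose — which is why the
central-axis dose of a composed field keeps growing with field size well
beyond the core's reach.

`pbfield` implements the analysis chain that quantifies these effects from
tabular data (lateral profiles, frame-dose tables) and, because real
facility data are not distributable, a phenomenological generator that
emulates such data closely enough to exercise every analysis branch.

## The two-step core fit

`fit_core()` estimates $\sigma_C$ by unweighted nonlinear least squares of
$A\,G(t \mid \mu, \sigma^2)$ in two passes:

1. fit all points with dose $\ge$ 5% of the profile maximum, giving
   $\sigma_\mathrm{init}$ and the lateral peak offset $\mu$;
2. refit restricted to $|t - \mu| \le 2.5\,\sigma_\mathrm{init}$.

The rationale: a PB profile is Gaussian out to $\approx 2.5\,\sigma_C$; a
single-pass fit over the full scan range would absorb halo dose and inflate
the width. The 5% threshold is relative to the observed maximum (not the
fitted amplitude), ties in the maximum are broken toward the axis, and the
second-pass window is centered on the first-pass $\mu$. For annular
(radial) profiles $\mu$ is fixed at 0 and the window is $r \le
2.5\,\sigma_\mathrm{init}$. Initial values are deterministic (peak
position, FWHM/2.355 by interpolation, peak dose), and the optimizer is
Levenberg–Marquardt via `minpack.lm::nls.lm`, chosen because it remains
well-behaved at the zero-residual optima that noiseless synthetic profiles
produce. No outlier rejection and no weights are applied.

The width growth is summarized by the quadrature transform
$$\sigma_{sc}(z) = \sqrt{\sigma_C^2(z) - \sigma_C^2(z_0)},$$
which removes the initial beam width: two beams differing only in
$\sigma_C(z_0)$ have the same $\sigma_{sc}$ curve. A property test asserts
this to 0.5% on paired synthetic beams with 4 mm and 9 mm initial widths.
If a fitted $\sigma_C(z)$ falls below the reference width, `sigma_sc()`
raises an error rather than returning an imaginary number — that situation
signals a failed fit upstream.

## Halo width metrics

`fwxm()` extracts the full width at a fraction $x$ of the maximum. Levels
$x \ge 1\%$ use the outermost linearly interpolated crossings of
$x \cdot D_\mathrm{max}$ on each side ("outermost" guards against
noise-induced multiple crossings). Levels below 1% live deep in the halo,
where the profile decays exponentially and sampling is sparse; they are
derived from a linear-exponential fit $a\,e^{-b|t|}$ to all points with
dose within $\pm 50\%$ of the target level, solved for the crossing radius.
The $\pm 50\%$ band is read in dose, not position. The fit is ordinary
least squares on the log dose (deterministic, no starting values needed;
positivity is guaranteed by the band). Linear scans fit each side
separately and sum the two radii, which tolerates residual asymmetry;
annular profiles fit once and double the radius. Fewer than three points
in a band is an error naming the band rather than a silent extrapolation.

Misalignment (offsets up to ~0.6 mm occur in practice) is corrected before
width extraction by shifting positions by the fitted $\mu$
(`correct_offset()`), and the measurement-reproducibility confidence
interval combines the relative SD of repeated readings with an assumed
0.6% day-to-day dose delivery reproducibility in quadrature
(`ci_reproducibility()`).

## Output factors

The 20 cm field decomposes into nine square frames
$\{[0,2.0], [2.4,3.2], \ldots, [16.0,20.0]\}$ cm on the 2 mm spot grid.
The membership convention is strict at the inner side and inclusive at the
outer side, with a spot at the exact origin: this is the unique convention
that reproduces the published frame combinatorics (the 15.6 cm frame has
2680 more spots than the 10 cm frame, 4.6× as many; an inclusive-inner
variant gives +2720 and 3.96×). Grid rings falling exactly on an inner
boundary belong to no frame, mirroring the 0.4 cm physical gaps between
consecutive frames.

With frame doses $D_i$ and the 10 cm normalization $D_N = \sum_{i=1}^7
D_i$:
$$FF_i = D_i / D_N, \qquad FSF_i = \sum_{k \le i} D_k / D_N,$$
$$\Delta FSF_i = \sqrt{\frac{\sum_{k\le i} \Delta D_k^2}{D_N^2} +
  \frac{\left(\sum_{k\le i} D_k\right)^2 \Delta D_N^2}{D_N^4}}, \qquad
  \Delta D_N = \sqrt{\textstyle\sum_{i=1}^7 \Delta D_i^2}.$$
The uncertainty formula ignores the correlation between the cumulative
numerator and $D_N$; this is the only reading dimensionally consistent
with $\Delta FSF$ being a fraction, and a $10^5$-draw resampling test
confirms it within 5% wherever the numerator is not dominated by $D_N$
itself (for $FSF_7 \equiv 1$ the correlation is total and the true
uncertainty is 0 — the formula is deliberately conservative there). The
RMSD agreement statistic uses frames 3–9 (fields $\ge$ 4.4 cm, where the
halo dominates) with denominator 7. $FSF_7 = 1$ holds exactly in floating
point because the normalization reuses the same cumulative sum.

## The core-only FSF forward model

To separate core from halo contributions, `core_only_fsf()` computes FSFs
for a hypothetical beam that is purely Gaussian: each spot contributes
$\exp(-d^2/2\sigma_C^2)$ at Euclidean distance $d$, summed over the
detector's sensitive disc subdivided into 0.1 mm bins (bin centers
strictly inside the disc; the default detector is the 2.75 mm-radius
thimble chamber used for output-factor measurements, centered on the
central axis). The kernel is deliberately unnormalized: any fixed-$\sigma$
normalization cancels in every FSF ratio, so the one-dimensional-versus-
two-dimensional Gaussian normalization ambiguity is provably immaterial (a
test multiplies the kernel by $10^6$ and checks FSFs are unchanged). Spots
farther than $6\sigma + r_\mathrm{cav}$ from the axis are skipped; their
relative contribution is below $10^{-7}$.

`core_fsf_deviation()` evaluates how a core-width error alone distorts
FSFs. A narrower core scatters less dose out of the in-field frame and
collects less from distal frames, overestimating FSFs; the extremum over
frames is reported as an output (it lands on the in-field frame for all
width pairs we evaluate, but this is not assumed). For the published width
shifts, the model yields a maximum overestimation of +3.46 percentage
points for 9.09 → 8.62 mm and a most negative deviation of −0.74
percentage points for 8.80 → 8.90 mm. We note the two published reference
values for these shifts (3.7 and −1.2) imply mutually inconsistent
sensitivities $dFSF/d\sigma$ at nearly the same width (≈7.9 vs 12 pp/mm),
so no smooth model reproduces both simultaneously; our model's sensitivity
(≈7.4 pp/mm) is stable to within 0.02 pp across detector-geometry variants
(point, square, 1.45 mm and 3.05 mm discs).

## The synthetic-data generator

The generator stands in for both measurements and Monte-Carlo output. What
it emulates, and how:

**Core width over depth.** $\sigma_C^2(z) = \sigma_C^2(z_0) +
\sigma_{MCS}^2(z) + \theta_0^2 (z - z_0)^2$ with a power-law MCS term
$\sigma_{MCS}(z) = m \left((z - z_0)/(R_{80} - z_0)\right)^p$ (zero at the
reference depth $z_0$, $m$ at the end of range $R_{80}$, default exponent
$p = 0.9$ for Highland-like growth). Beams with published width
measurements are *anchored* instead: $\sigma_{sc}^2(z)$ is interpolated by
a monotone Hermite spline through $(z_0, 0)$ and the anchors, continued
linearly beyond the deepest anchor. We chose interpolation over fitting
because the published growth of the mid-energy beam has a local growth
exponent that increases toward the end of range beyond what the
two-parameter power-law-plus-drift family can represent (best attainable
residual 0.039 mm, versus the 0.01 mm reproduction the fixtures guarantee
by construction).

**Halo tail.** Outside the core, dose follows $a\,e^{-b r}$ with the log
amplitude anchored to the Gaussian value at $2.5\,\sigma_C$ and scaled by
a midrange-peaking amplitude profile
$h(u) = h_\mathrm{floor} + (h_\mathrm{peak} - h_\mathrm{floor})\,4u(1-u)$,
$u = z/R_{80}$. The junction sits at the *outer* intersection of core and
tail, $r_c = \sigma^2 b + \sqrt{(\sigma^2 b)^2 - 2\sigma^2 \ln a}$, which
keeps the profile continuous for any amplitude and reduces exactly to
$2.5\,\sigma_C$ at unit amplitude. (Attaching the tail pointwise wherever
it exceeds the core looks equivalent but is not: for wide cores the scaled
tail re-crosses the Gaussian *inside* the core and corrupts the peak
region.) Tail slopes are calibrated per beam so that the midrange profile
crosses 0.1% of the central-axis dose at a stated reach — 10 core widths
for the highest-energy fixture, 7 for the mid-energy one; range-shifted
fixtures use a higher, flatter amplitude profile
($h_\mathrm{floor} = 0.8$, $h_\mathrm{peak} = 2$) emulating the extra
spray from the degrader. Beams for which no reach or amplitude was ever
published (97.4/124.7 MeV RaShi, 198.0 MeV, and the 62.4 MeV halo) carry
illustrative values chosen once: their fixtures are plausible, not
reconstructions.

**Detector response and sampling.** Scans average the superposed dose over
a disc of the detector's nominal active radius on a 0.1 mm sub-grid (a
zero radius gives a point detector); annular profiles integrate
$2\pi r D(r)$ per annulus with adaptive quadrature and report the
mid-radius, with 2.5 mm the default annulus width (the side of a square
matching a typical thimble-chamber cross-section). Frame-dose simulation
uses a 0.5 mm sub-grid by default — frame doses vary slowly across the
disc, and the coarser grid keeps full-field superposition cheap.

**Noise and misalignment.** Dose noise is multiplicative Gaussian with
relative SD 0.006 (the day-to-day delivery reproducibility), truncated so
doses stay non-negative; lateral misalignment up to 0.6 mm is supported
and recorded in the profile metadata so recovery can be tested. All
randomness flows through an explicit integer seed with a fixed default.

**What the generator does not emulate.** No particle transport: the halo
is a single exponential, whereas real halos have structure (elastic vs
non-elastic components, the aura beyond); no spray from the delivery
nozzle; no detector-specific energy dependence or effective-point-of-
measurement shifts; no absolute dosimetry (profiles are normalized to the
central axis). Passing tests therefore demonstrate that the *analysis*
operations are correct and calibrated against closed forms and
brute-force oracles — not that the generator predicts any particular
facility's beams.

## Numerical choices and degenerate inputs

- Depths outside $[z_0, R_{80}]$ are domain errors, not extrapolations.
- `fit_core()` requires ≥ 4 points above the first-pass threshold and ≥ 4
  in the refit window; optimizer non-convergence is reported via
  `converged = FALSE` with best-effort values rather than an error.
- Frame-dose tables must contain all nine frames exactly once with
  non-negative doses and $D_N > 0$; sub-detection-limit doses are kept,
  not zeroed.
- `fwxm()` levels never reached, or tail bands with < 3 points, raise
  errors naming the level/band.
- The annular scorer is conservative by construction: total scored energy
  is invariant under annulus refinement to 0.01% (tested at 4× refinement).
- The far-spot cutoff in the core-only model ($6\sigma + r_\mathrm{cav}$)
  bounds the neglected relative contribution by $10^{-7}$.

## Problem sizes

The shipped tests and the acceptance script run the full chain at the
sizes a desk analysis uses: profiles of 161–481 points, the complete
10201-spot field decomposition, $10^4$–$10^5$-draw Monte-Carlo oracles for
the uncertainty propagation and reproducibility checks, and core-only FSF
evaluations over all nine frames with 0.1 mm detector binning. A full test
run completes in well under a minute.

## Worked pipeline run

```{r pipeline, eval = FALSE}
beams <- beam_library()
cfg <- run_config(beams["open_148"], depths = c("z0", 0.5, 0.8, 0.97),
                  analyses = c("core", "of"), seed = 1234,
                  output_dir = "run-148")
res <- run_pipeline(cfg)
res$results$open_148$core$widths |> select(beam, depth_z_mm, sigma_c)
```

The run writes one CSV per analysis plus a JSON log (effective
configuration, seed, package version, file list); re-running with the same
configuration and seed reproduces every output byte-identically.
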