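---
title: "Noise-letter acuity in silico: stimuli, staircases and simulated cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise-letter acuity in silico: stimuli, staircases and simulated cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement this package simulates

Clinical letter charts present dark letters on a bright background: the
letter is defined by a *luminance* difference, a first-order (LM,
luminance-modulated) signal that the early visual cortex reads out with
essentially linear mechanisms. A letter can instead be defined purely by a
difference in local *contrast* on a noisy carrier, with no change in mean
luminance anywhere — a second-order (CM, contrast-modulated) signal. CM
stimuli are believed to require an extra rectifying (filter–rectify–filter)
stage attributed to higher, more binocular cortical areas, which makes CM
acuity an interesting probe of ageing and of binocular combination beyond
what standard charts can show.

The experimental chain simulated here is the one used in studies that
compare LM and CM letter acuity between older and younger adults under
monocular and binocular viewing:

1. **Stimuli** — HOTV optotypes drawn into a binary ±1 noise carrier.
2. **Geometry** — letter size on a physical display converted to logMAR.
3. **Procedure** — a two-down/one-up, four-alternative forced-choice
   adaptive staircase, threshold from the last six of eight reversals,
   four runs averaged per condition.
4. **Observers and cohorts** — parametric psychometric observers standing
   in for human participants; two groups of five, four conditions each.
5. **Analysis** — group means ± SE, binocular summation ratios
   (monocular MAR / binocular MAR), and a mixed-design ANOVA.

## The stimulus model

Every pixel of a frame obeys

$$I(x,y) = I\,[\,1 + n\,N(x,y) + l\,L(x,y) + m\,n\,M(x,y)\,N(x,y)\,]$$

with mean luminance $I$, carrier contrast $n$ (0.2 by default), binary
noise $N \in \{-1,+1\}$ drawn i.i.d. per check and refreshed independently
every frame, and square-wave modulation supports $L$ (luminance) and $M$
(contrast). LM letters set $m = 0$, CM letters set $l = 0$; the constraint
$|l| + n(1+|m|) \le 1$ keeps every pixel inside the displayable range
$[0, 2I]$.

Design choices where the convention is genuinely open:

* **Support levels.** $L$ and $M$ are taken as $1$ on letter ink and $0$
  elsewhere. This keeps the background statistically identical for LM and
  CM stimuli (carrier-only, Michelson contrast $n$) and makes the CM
  letter region a pure contrast increment, $n(1+m)$. A bipolar
  ($\pm 1$) convention is available as `bipolar_modulation = TRUE` for
  exploration, with no claim of fidelity to any particular lab's code.
* **Modulation depths.** Acuity experiments vary letter *size* at fixed,
  clearly suprathreshold modulation; the depths themselves are rarely
  reported. Defaults are $l = 0.3$ and $m = 1.0$, chosen once as visibly
  suprathreshold at $n = 0.2$ while satisfying the gamut constraint
  ($0.3 + 0.2 \le 1$ and $0.2(1+1) \le 1$).
* **Letterforms.** The four HOTV letters are fixed 5×5 stroke grids
  (stroke width = 1/5 letter height, the Sloan proportion), documented
  cell by cell in `R/letters.R`, expanded 3× to the 15-check letter
  size by nearest-neighbour replication.
* **Units.** Images are generated in normalised linear luminance
  ($I = 1$); 8-bit quantisation is available (`quantize_frame`) but off
  by default, and display gamma is out of scope.

Two consequences of the model are worth stating because the test suite
verifies them: a single frame contains at most four distinct luminance
values, and the *expected* luminance of a CM frame equals $I$ both inside
and outside the letter — which is exactly why a linear (unrectified)
template matcher is at chance on CM letters in expectation while a
rectified contrast map $|I(x,y) - I|$ reads them trivially.

## Geometry and the achievable acuity grid

For a letter of side $s$ pixels at distance $d$, the stroke subtends
$\arctan\!\big(\tfrac{s}{5}\,p / (1000\,d)\big)$ (pixel pitch $p$ in mm),
expressed in arcminutes; logMAR is its $\log_{10}$. The exact `atan` is
used — at 4.5–9 m the small-angle error is below $10^{-7}$ logMAR, and
exactness costs nothing.

A display can only draw whole-pixel letters, so only a discrete set of
levels is *achievable*. `viewing_geometry` carries a `side_quantum`:

* `side_quantum = 15` (the default, = 5 strokes × 3 checks) restricts
  letters to whole-pixel noise checks. This is the strictest rendering
  grid, but at 9 m/4.5 m with 0.47 mm pixels its levels near threshold
  are 0.13–0.30 logMAR apart — far coarser than the 0.125 staircase
  step, so no adaptive procedure could resolve thresholds on it.
* `side_quantum = 1` (used by the simulated staircases,
  `default_geometries()`) allows any whole-pixel letter side, i.e.
  noise checks of fractional pixel size, as display hardware that scales
  a pre-rendered noise matrix effectively does. Near every threshold of
  interest the resulting grid is ≤ 0.03 logMAR fine.

`logmar_to_size` snaps a requested level to the nearest achievable one,
breaking exact ties toward the *larger* letter (conservative: avoids
floor effects), and errors below the one-check floor unless asked to
clamp. The staircase tracks nominal levels and logs the achieved ones.

## The staircase and its estimator

Letter size drops 0.125 logMAR after two consecutive correct responses
and rises 0.125 after any error; the counter resets after every step.
Such a rule equilibrates where $p^2 = \tfrac12$, i.e. at
$p = \sqrt{0.5} \approx 70.7\%$ correct ($0.5^{1/3} \approx 79.4\%$ for
the 3-down variant; `updown_equilibrium_p`). A run stops at eight
reversals (or a 200-trial safety cap, flagged unconverged — real
protocols have no cap, but simulations need one); the threshold is the
mean of the last six reversal levels, and four runs are averaged per
condition.

Bookkeeping conventions the procedure description leaves open:

* A **reversal** is logged when a level change reverses the direction of
  the previous change, at the level the new step departs from (the
  oscillation extremum). For an even number of reversals this is
  equivalent to logging the arrival level.
* The starting plateau contributes no direction; the first step sets it.
* At the geometry floor, downward steps are clamped; a level that does
  not actually change records no direction. A literally perfect observer
  therefore rides the floor without reversals and yields an `NA`
  threshold flagged unconverged, rather than a fake estimate.

## Simulated observers

The parametric observer answers a 4AFC trial correctly with probability

$$p(\ell) = \gamma + (1-\gamma-\lambda)\,F\!\big((\ell-\alpha)/s\big),
\qquad F(z) = 1 - e^{-k\,10^{z}},$$

with guess rate $\gamma = 0.25$, lapse rate $\lambda = 0.01$, and $k$
chosen so that $p(\alpha) = \sqrt{0.5}$ *exactly*. Anchoring the function
at the 70.7% point makes $\alpha$ the quantity the staircase is supposed
to recover, so recovery error is directly interpretable. Wrong responses
are uniform over the other three letters.

The slope default is $s = 0.16$ logMAR. In this parametrisation $1/s$ is
the equivalent Weibull exponent over letter size; $s = 0.16$ corresponds
to $\beta \approx 6$, the steep end of published letter-identification
functions. Markedly steeper observers (e.g. $s = 0.08$,
$\beta \approx 12.5$) jump from ~30% to ~99% correct across a single
0.125 step, which turns the staircase into a one-bit quantiser: in
simulation the reversal-mean estimator then acquires a bias of up to
0.03 logMAR whose sign depends on where the true threshold falls between
staircase levels. At $s = 0.16$ the measured residual bias is about
−0.005 to −0.01 logMAR (a known small pessimism of reversal averaging in
transformed up-down rules), and median run length is ~27 trials,
consistent with the 30–40 trials such experiments report.

The image-domain `template_observer` exists to demonstrate the
second-order point computationally: its `pixel_correlation` rule
correlates the luminance image with the four templates (sufficient for
LM letters at $l = 0.3$), while CM letters require the
`rectified_contrast_correlation` rule; the linear rule is exactly at
chance on CM in expectation because the presented letter is independent
of the noise and all four letters yield identically distributed decision
variables.

## The cohort generator

`simulate_cohort` emulates the study design: 2 groups × 5 participants ×
(LM/CM × monocular/binocular) × 4 staircase runs. Per participant and
condition a true threshold is drawn from
$\mathcal N(\text{cell mean}, \sigma_b)$; the cell means default to the
published group means and $\sigma_b = \mathrm{SE}\cdot\sqrt{5}$ per cell
(the SEs are the only between-subject spread information available —
individual thresholds live in external deposited datasets, which
`read_cohort_csv` can also ingest). Run-to-run threshold jitter is
$\sigma_r = 0.05$ logMAR, a conventional within-observer variability not
stated in any source. LM staircases start at 0.2 logMAR and run at 9 m;
CM at 0.8 logMAR and 4.5 m.

The ND-filter scenario (85N6, 19% transmission, re-testing three younger
participants) is modelled as a threshold shift
$c \cdot \log_{10}(1/T)$ with $c = 0$ by default — i.e. the filter does
nothing, which is the empirical outcome the control experiment emulates;
image-level attenuation is deliberately not modelled. Everything is
driven by order-independent sub-seeds (`derive_seed`), so cohorts are
bit-reproducible.

What the generator does **not** emulate: optical ageing (miosis, media
opacity), psychometric slope differences between groups or conditions,
learning/fatigue across runs, response biases among letters, and any
correlation structure between a participant's four conditions. Passing
recovery tests therefore show that the *pipeline* is calibrated — that
staircase plus averaging returns the thresholds fed in — not that real
ageing data would behave this way.

## Analysis conventions

* Binocular summation ratio $= 10^{\,\text{mono} - \text{bino}}$ (MAR
  ratio), per participant first, then group mean ± SE — the aggregation
  an SE on the ratio implies. The ratio of group-mean acuities is
  reported alongside (`ratio_of_means`); on heterogeneous data the two
  differ, which is why a table of mean ratios need not equal the ratio
  computed from a table of mean acuities.
* Fold-differences between groups are exact exponentials of logMAR
  differences; 0.1 logMAR is one chart line.
* The mixed ANOVA uses the standard two-stratum decomposition
  (`aov` with `Error(subject/within)`); with two within-levels no
  sphericity correction exists to apply. Reported against an independent
  textbook sums-of-squares oracle in the tests. Published F statistics
  themselves are not reproducible from group summaries and are not
  targeted.
* Table-style reporting rounds half away from zero to 2 decimals
  (`round_half_up`).

## Problem sizes and tolerances used by the checks

The package's own acceptance checks run a 50,000-trial convergence probe
(±1 percentage point around 70.71%), four sweeps of 500 staircase runs
each across 70.7%-points in $[-0.25, 0.50]$ logMAR (mean recovery within
±0.03), 20 replicate cohorts (every cell mean within 2 SE of its target
— note that with eight cells tested at ±2 SE an ideal pipeline still has
roughly a one-in-three chance of one cell straying at any given seed),
and a 500-frame CM movie for mean-luminance conservation (±3 SE), with
1000-trial template-observer runs. These sizes were chosen so each claim
is testable with comfortable statistical margin.

## Known limitations

* The achievable-level grid at `side_quantum = 15` is too coarse for
  adaptive testing at the study distances; fractional-check scaling
  (`side_quantum = 1`) is the package's resolution of that tension.
* The reversal-mean estimator retains a small negative bias
  (≈ −0.01 logMAR at the default slope); it is reported, not corrected.
* Template observers operate at check resolution on single frames or
  frame-averaged maps; they are demonstration observers, not models of
  human spatial integration.
* No real-time presentation, display calibration, or optics.
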