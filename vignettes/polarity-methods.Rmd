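---
title: "Models and methods behind mxpolarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mxpolarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mxpolarity)
```

mxpolarity studies the front-rear polarity module of *Myxococcus xanthus*:
the small GTPase MglA (leading-pole marker), its GAP MglB (lagging pole)
and the RomR/RomX GEF complex (lagging pole, treated as a single species
"R"). The package has three layers: an ODE model of polar protein
fractions with fitting and stability analysis; an image-quantification
and tracking pipeline for polar fluorescent clusters; and synthetic-data
generators that produce images, time-lapses and strain tables with known
ground truth, so that every pipeline stage is testable without external
data.

## The polarity model

Each species $X \in \{A, B, R\}$ is split into pole fractions $X_1, X_2$
and a cytoplasmic remainder $X_c = 1 - X_1 - X_2$; exchange with the
poles is fast compared to synthesis and turnover, so total amounts are
conserved and the system has six degrees of freedom. The rates (per
minute, per pole $i$) are

$$
\begin{aligned}
\dot A_i &= A_c\,(a_A + c_A R_i) - d_A A_i - d_{AB} A_i B_i^2,\\
\dot B_i &= B_c\,(a_B + c_B R_i) - d_B B_i - d_{BA} A_i B_i^2,\\
\dot R_i &= R_c\,\Big(a_R + b_R R_i + c_R B_i \tfrac{K}{K + A_i}\Big)
            - d_{R,i} R_i.
\end{aligned}
$$

The terms encode, in their lowest-order forms: basal polar binding
($a_X$); cooperative RomR self-recruitment ($b_R$); mutual RomR/MglB
recruitment ($c_B$, $c_R$); RomR/RomX-mediated recruitment of MglA
($c_A$, subsuming GEF activity and direct recruitment — nucleotide
states are not modelled explicitly); GAP-driven dissociation of MglA by
MglB, quadratic in MglB because its active form is multimeric
($d_{AB}$), with a matching co-dissociation of MglB in MglA-containing
complexes ($d_{BA}$); and suppression of MglB-driven RomR recruitment by
MglA through the saturation factor $K/(K+A_i)$. Setting $d_{BA} = 0$ or
$K \to \infty$ switches off one of the two modes of MglA action.
Deletions fix all pools of a species at zero. An old-pole bias —
RomR's intrinsic preference for the old cell pole, observable only when
MglA and MglB are absent — is a factor $\beta \le 1$ on the pole-1 RomR
dissociation rate, applied in every mutant condition and never in wild
type.

Integration offers the Dormand–Prince 5th-order Runge–Kutta pair and
`lsoda`; `lsoda` is the default because the fitted regime's large
quadratic dissociation terms ($d_{AB} B^2$ up to several hundred per
minute) are stiff, where the explicit pair needs prohibitively small
steps. The two agree to tolerance in the non-stiff regime, where the
Runge–Kutta pair is the natural choice. The default
initial condition seeds 1.1% of each present species at pole 1 and 1% at
pole 2 and runs 1000 min. `steady_state()` integrates in doubling chunks
until $\max|\dot X| < 10^{-9}$/min (cap $10^5$ min) and classifies the
state polarized when any species has pole asymmetry
$|X_1 - X_2|/(X_1 + X_2) > 0.05$; both thresholds are package choices,
not measured quantities.

### Fitting to strain means

The data are per-strain, per-reporter printed means: total polar
fraction $m$ and asymmetry $\omega$, split into pole means
$m(1 \pm \omega)/2$. The objective is the summed squared deviation
between these and the model's steady-state fractions over strains,
species and poles, with model poles oriented per reporter (brighter pole
against data pole 1). Three strain/reporter rows lack a printed
$\omega$; they contribute a single squared term on the total fraction.
Dissociation rates are fixed from polar-exchange times measured by FRAP
(RomR ~28 s, hence $d_R = 60/28 \approx 2.14\,\mathrm{min}^{-1}$; MglA
and MglB are set to the same order, $2\,\mathrm{min}^{-1}$,
config-overridable).

Fitting is staged to mirror the mutant hierarchy: (1) $a_R, b_R, \beta$
against the RomR-only strain; (2) the recruitment coefficients against
the single mutants; (3) the feedback parameters $d_{AB}, d_{BA}, K$
against wild type; (4) joint Nelder–Mead refinement on log-scale
parameters ($\beta$ on the logit scale) from 50 restarts.

Plain multi-start refinement fails here for a structural reason: large
parameter regions leave the wild-type model monostable-symmetric, the
least-squares surface has a broad local optimum there, and a simplex
started in it never encounters the polarized branch. Stage 4 therefore
seeds its restarts with parameter sets whose symmetric wild-type fixed
point is linearly unstable. These are generated analytically: sample the
symmetric fixed point and the feedback parameters, solve the (linear)
stationarity conditions for the recruitment coefficients, and keep draws
whose $3\times3$ antisymmetric-mode Jacobian has an eigenvalue with
positive real part. Candidates are screened by the objective, refined by
Nelder–Mead under a unit penalty on falling back to a symmetric
wild-type state (applied only while the wild-type data are asymmetric;
reported losses are always the pure objective), and the best restarts
are polished with two fresh-simplex rounds. The whole fit runs in a few
minutes on one CPU and is deterministic given its seed.

The package's default `polarity_parameters()` are one such fitted set.
With them the wild type polarizes spontaneously from the 1.1%/1% seed;
every mutant condition with $\beta = 1$ has a stable symmetric fixed
point; $K \to \infty$ from a polarized start decays to symmetry; and
polar differentiation survives only in an intermediate band of $K$
(`bifurcation_scan()`). Parameters themselves are not identifiable from
eleven mean values — only steady-state predictions are asserted anywhere
in the package.

## Image quantification

The pipeline follows a standard spot-quantification design for polar
clusters in rod-shaped bacteria. Background is the dominant-weight mean
of a two-component Gaussian mixture fitted to out-of-mask pixel
intensities (fallback: median, with a warning, when the fit
degenerates). Spot detection convolves the background-subtracted image
with a negative Laplacian-of-Gaussian kernel
$K(i,j) = \frac{2\sigma^2 - (i^2+j^2)}{2\pi\sigma^6}
e^{-(i^2+j^2)/2\sigma^2}$ with $L = 9$, $\sigma = 1.75$ px; pixels in
other cells' masks are zeroed first, and the convolution is zero-padded.
Circular search regions of radius 10 px are centred on the 5th
centerline segment from each pole (1-px segments along the mask's
principal-axis centerline; the discs intentionally extend outside the
mask). The detection threshold is three standard deviations above the
mean of the cell-mask pixels outside both search regions, computed on
the filtered image (a `threshold_on = "raw"` switch exists). A spot
needs at least three 8-connected supra-threshold pixels; the largest
group wins. Polar fluorescence is the sum of *unfiltered*
background-subtracted intensities over the spot pixels; $P_1 \ge P_2$
are the polar fractions and $\omega = (P_1 - P_2)/(P_1 + P_2)$, set to 0
for cluster-free cells. Records where the spot sums exceed the cell
total (spot pixels extend outside the mask) are rescaled to 1 and
flagged.

Connectivity (8 vs 4) and border handling are deliberate choices
exposed in `filter_config()`; contiguity and padding conventions are
otherwise undocumented in this problem domain's tooling.

## Tracking

Cells are linked between frames by summed pole-to-pole distance under
the optimal pole pairing; below 40 px is the same cell (greedy
assignment, one claim per previous cell, ties to the lower id). A cell
failing that but with a single pole within the threshold is a daughter;
the matching pole is its old pole. Tracks absent for exactly one frame
are merged when their poles align. Per track, pole A is the brighter
pole in the first frame. Inversions are flips of the dominant pole
between consecutive frames (ties are not inversions — conservative, and
ties have measure zero in real data). Old-pole bias is the fraction of
daughters whose larger cluster sits at the old pole immediately after
division, tested with an exact two-sided binomial test. Autocorrelation
standardizes fractions per frame across all poles (population SD) and
averages lag products; $C(0) = 1$ by construction. Leading/lagging
labels require centroid displacement of at least 10% of cell length and
take the pole whose body-axis direction aligns with the motion.

## Synthetic data

The generators emulate the statistical structure of the study's data,
not its optics. Cells are capsules about 70 × 11 px (roughly a
4.5 µm × 0.7 µm rod at 65 nm/px), placed without overlap; polar clusters
are isotropic 2-D Gaussians ($\sigma = 1$ px) centred 2 px inside each
pole tip; noise is Poisson on the expected counts plus Gaussian read
noise (SD 5 at background 100, integrated cell intensity ~20,000 —
polar SNR well above 5 at fractions of 0.05). Per-cell $(P_1, P_2)$ are
drawn from a bivariate normal truncated to the simplex by rejection;
the defaults emulate a RomR-like reporter ($m = 0.212$,
$\omega = 0.5$). Time-lapses use Bernoulli polarity inversions per
10-min interval (default 0.12, the stable-polarity regime), midcell
divisions with each daughter keeping one old pole, a 64% probability
that the dominant cluster starts at the old pole, and rigid drift.
Induction series rise linearly in concentration and place a fraction
$\mathrm{cap}\cdot c^{h-1}/(c^{h-1} + K_{1/2}^{h-1})$ at each pole, so
$h = 1$ gives the concentration-independent (non-cooperative) null
exactly.

What passing tests on these data do *not* show: robustness to
segmentation errors, uneven illumination, focus drift, filamentous or
curved cells, or crowded fields — the masks are inputs by design, and
cluster shape is idealized. The pipeline's accuracy numbers (spot recall
≥ 0.95, polar-fraction RMSE ≤ 0.03 on 100 cells) are statements about
this generative model.

## Statistics

Strain-to-strain localization distributions are compared with the
two-sample two-dimensional Kolmogorov–Smirnov test in the
Fasano–Franceschini form: D averages the two sample-anchored maxima of
quadrant-fraction differences (computed in C; points on dividing lines
split evenly between sides — source texts differ on ties), and the
p-value uses the asymptotic Kolmogorov distribution with the
$\sqrt{1-\rho^2}$ correlation correction. Welch's *t* (with a bootstrap
check of p-value magnitude), the exact binomial test (two-sided by
summing outcomes no more likely than observed) and Pearson's $\chi^2$
without continuity correction wrap the corresponding base-R functions.
No multiple-testing correction is applied anywhere.

## Problem sizes and reproducibility

Defaults used by the packaged benchmarks: 100-cell scenes at
1024 × 1024 px for detector recovery; ~1000 pole transitions per
switching rate for inversion estimates; 1000 null replicates for test
calibration; 50 fit restarts. Every stochastic component takes a seed,
and one pipeline seed derives per-stage substreams, so identical
configurations reproduce byte-identical outputs.

## Known limitations

The model is spatially implicit (two poles and a well-mixed cytoplasm;
no reaction–diffusion), has no Frz signaling input, and treats RomR/RomX
as one species. Fitted parameters are a point estimate of a
non-identifiable system. The tracker performs no manual-review
corrections; after a division whose daughters stay within the link
threshold, the parent id continues through one daughter, matching the
behaviour of threshold-based linking. The induction generator models
steady-state occupancy, not expression kinetics.
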