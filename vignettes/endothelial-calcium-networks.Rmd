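---
title: "Models and methods: endothelial Ca2+ network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: endothelial Ca2+ network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endoCaNet)
```

# Scope

endoCaNet analyses agonist-evoked Ca^2+^ dynamics across an endothelial
sheet imaged *en face*: per-cell F/F~0~ fluorescence traces plus an
integer-labelled cell mask go in; event tables, a structural
cell-adjacency network, responder-community statistics with permutation
nulls, centrality enrichment, neighbour-influence probability curves,
cross-correlation summaries and a concentration-response encoding verdict
come out. A synthetic tissue generator produces all of these inputs with
exported ground truth, so every stage of the pipeline can be validated
without imaging data. This vignette documents the models, the tunable
parameters and the design decisions; the README shows a worked example.

# Event detection and transient model

Each cell's raw trace is normalized to F/F~0~ using the mean of the raw
trace over the selected baseline window, then smoothed with a 21-point,
third-order Savitzky–Golay filter. The baseline is the 10-s window with
the lowest activity before the stimulus onset. "Activity" is
operationalized as the window standard deviation of the smoothed trace
(earliest window on ties). The detection threshold is 5 baseline SDs
above the baseline mean.

One deliberate asymmetry: the window is *selected* by the smoothed-trace
SD, but the SD entering the threshold is computed from the **raw**
normalized trace over that window. Selecting a minimum-SD window biases
the smoothed-window SD roughly 50% low (it is the minimum of ~100
correlated sliding estimates), which would silently turn the nominal 5-SD
threshold into ~2 SDs of the smoothed noise and flood the event list with
noise ripples. The raw-trace SD in the same window is essentially
unbiased, and "baseline fluctuation" naturally refers to the F/F~0~
signal itself.

Suprathreshold runs separated by less than 0.5 s are merged; within a
run, an additional event is split at any local minimum that drops below
half of the smaller adjacent peak's height above the threshold level.
Local maxima must clear the threshold by at least 3 baseline SDs to count
as peaks for splitting — without this floor, noise ripples on decay tails
fragment single transients.

Each event is fitted by least squares with an exponentially modified
Gaussian (EMG; Gaussian of width $\sigma$ convolved with an exponential
decay of time constant $\tau$), over the segment extended by 3 s on each
side. The fit runs on the **raw** normalized trace: the 21-point smoother
broadens sharp transients and would bias $\sigma$ upward by tens of
percent at 10 Hz. Rise time (10→90%), fall time (90→10%) and FDHM (width
at half maximum) are measured on the fitted curve and then re-measured at
the same fractional levels on the smoothed real signal, anchored at the
detected peak; the re-measured values are what the event table reports,
with the fitted parameters kept alongside. The 10–90% levels are a
convention choice (the fractional levels are not standardized in this
field). Fits on segments shorter than 5 frames, or non-convergent fits,
fall back to empirical threshold-crossing metrics with `fit_ok = FALSE`.

# Tissue graph

Background pixels of the label mask are assigned to the nearest labelled
pixel (Euclidean distance, ties to the lowest label id) — a deterministic,
parameter-free formalization of "expand cell boundaries until they
touch". Two cells are neighbours when their expanded regions share at
least 2 four-connected pixel contacts; the 2-contact floor suppresses
corner-only artifacts.

Field-of-view boundary cells are flagged with a concave hull: the
cell-pixel foreground is morphologically closed with a disc of radius
$\alpha/2$ ($\alpha$ defaults to twice the median equivalent cell
diameter) and hole-filled; a cell is a boundary cell when any of its
pixels lies on the outline of the closed region or touches the image
frame. This raster closing is the standard pixel-data equivalent of an
alpha shape. If closing leaves more than one component ($\alpha$ too
small for the mask), the convex hull is used instead, with a warning.
Every downstream analysis uses interior (non-boundary) cells only.

# Responder communities and permutation nulls

Cells are ranked by response frequency (events/min over the exposure
interval, which defaults to stimulus onset → end of recording); the top
20% are the responders, with ties broken by mean amplitude then cell id.
A community is a connected component (size ≥ 2) of the responder-induced
subgraph; responders without responding neighbours are isolated. The
degree of clustering is the mean within-subgraph degree of community
members; the clustering coefficient is their mean local clustering
coefficient on the same induced subgraph (degree < 2 members contribute
0). Members of communities only — isolated cells are excluded from both
averages, matching the per-community framing of the metrics.

Significance is empirical: 100 label permutations draw responder sets of
identical size uniformly from the interior cells, and the observed metric
is reported against the null mean/SD and its empirical percentile
(midrank convention). No parametric tests are performed.

# Centrality and spectral structure

Betweenness is the unnormalized shortest-path form on the interior
subgraph (normalization cancels in group-vs-null comparisons).
Eigenvector centrality is the leading eigenvector of the interior
adjacency matrix, sign-fixed nonnegative; since the matrix is symmetric,
left and right eigenvectors coincide. The dominant local community scale
$i^\*$ is the largest eigengap $\lambda_i - \lambda_{i+1}$ over
$1 < i \le \min(n-1, 20)$ (smallest $i$ on ties; the cap guards against
noise in the tail of the spectrum). Local influence is each node's L2
norm across the first $i^\*$ eigenvectors. A node's
community-of-influence is reported as the argmax of $|v_j|$ over
$j \le i^\*$; this is a stated approximation of eigenvector-based
community assignment, not a reference algorithm.

Group centrality splits two agonists' responder sets into ACh-only,
BK-only and multisensitive (intersection) groups, and compares group
means against 100 uniform resamplings of matched size.

# Neighbour influence: case–control design

The analysis window is $t_w = 3\times$ the median FDHM of all detected
events. Every target event at time $t$ with at least one distinct
neighbour event peak in $[t - t_w, t)$ is a positive case with $k$ = the
number of such neighbours (each neighbour counted once). Negative cases
group neighbour events into non-overlapping windows $[t_0, t_0 + t_w]$
started at the first ungrouped neighbour event; a group is negative iff
the target has no event peak in that window — the target check spans the
same window used for grouping. Event timing is the fitted peak time.
With a community partition supplied, cases are cluster / non-cluster /
mixed according to whether all / none / some of the case's neighbours
share the target's community; mixed cases stay in the overall curve but
are excluded from the cluster comparison. Each target event generates
exactly one positive case even when neighbour windows overlap.

$P(\text{event}\mid k)$ is positives over positives + negatives per $k$,
with an unweighted linear regression of $P$ on $k$. Aggregation across
datasets restricts $k$ to values represented in every dataset. The
temporal permutation null shuffles the pooled event times across events
(per-cell event counts, topology and community labels untouched) and
rebuilds the cases per permutation.

Two structural caveats, established on synthetic data and worth knowing
when interpreting real data: (i) with spatially clustered sensitivity the
count-preserving null inherits a between-cell confound (active cells have
active neighbours), so the null curve itself rises with $k$; (ii) because
coupled cells concentrate their events in high-$k$ episodes while the
null spreads them uniformly, the observed curve can sit slightly below
the null at $k = 1$ even when coupling is real. The regression slope and
the $k \ge 2$ bins carry the signal.

# Cross-correlation

Aligned segments cover 10 s of pre-onset baseline plus the activity
period, truncated to the shortest combined duration across compared
datasets; activity onset is the configured stimulus time, else the first
detected event. Each pair of equal-length segments is split into two
halves; per half, both signals are demeaned and the Pearson correlation
on the overlapping support is evaluated at every integer-frame shift
within $\pm 3\times$ the median FDHM, the maximum is taken and floored at
0; the reported coefficient is the median of the two half values
(the mean, for two values), hence in [0, 1]. Per-node connectivity is
summarized as the 75th percentile (linear interpolation between order
statistics, type 7) of the node's coefficients to the comparison set,
self-pairs excluded.

# Concentration-response encoding

Frequency and amplitude summaries per concentration are fitted on log10
concentration: a four-parameter logistic
$R = b + (t-b)/(1 + 10^{(\log EC_{50} - \log C)\,h})$
for monotone responses and a log-Gaussian bell
$R = a + h\,e^{-(\log C - c)^2/(2w^2)}$ for non-monotone ones.
EC~25~ follows from $\log EC_{25} = \log EC_{50} - \log(3)/h$. Fits are
box-constrained (nonnegative responses, EC~50~ within two decades of the
tested range, Hill slope in [0.1, 6], bell width in [0.5, 4] decades)
because unconstrained 4PL/bell fits on noisy near-flat data are
ridge-degenerate and produce arbitrary spans; a second start is tried on
non-convergence. The dynamic range of a modality is the normalized span
of the **fitted curve over the tested concentrations** — not the raw
top/bottom parameters, for the same degeneracy reason. A response is
frequency-encoded when the frequency range exceeds the amplitude range
by a factor ≥ 2 (configurable operationalization of a qualitative
distinction), amplitude-encoded in the reverse case, else indeterminate.
Relaxation data are related to Ca^2+^ metrics by ordinary least squares
with r² reported; per-concentration summaries are treated as independent
measurements (non-cumulative application protocol).

# Synthetic tissue generator

The generator is first-class, tested code, and its defaults define the
conditions under which the pipeline is validated.

**Geometry.** Voronoi tessellation of a jittered lattice rendered at
512×512 (default), lattice pitch along x scaled by `elongation`
(1 = polygonal venous cells, ~3 = elongated arterial cells), 1-pixel
background borders between regions so neighbour detection exercises the
expansion rule. Interior cells average close to six neighbours, the
planar-tessellation expectation.

**Sensitivity maps.** One clustered set per agonist, grown from seeded
cells by stochastic neighbour recruitment (`growthProb`, default 0.8) to
`sensitiveFrac` of the interior (default 0.17 — so that each agonist's
responsive set, including cross-multisensitive cells, fits within the
top-20% responder cut while total activation stays near 20%). The two
agonists are seeded on opposite sides of the field, giving spatially
distinct territories that meet along a central interface, as imaged
sheets show. Multisensitive cells (`overlapFrac`, default 0.05 of
interior) are placed at inter-community bridges: sensitive cells nearest
in graph distance to the other agonist's community, taking the highest-
betweenness candidates — so the centrality enrichment the analysis
probes is recoverable by construction. `bridgePlacement = FALSE`
disables this for null experiments (random members of either set).

**Dynamics.** Discrete-time hazard at the frame rate,
$\lambda_i(t) = \text{base} + s_i\, r(C)\, (1 + \beta k_i(t))$, where
$s_i$ indicates sensitivity to the applied agonist, $r(C)$ the drive, and
$k_i(t)$ counts neighbours with an onset within the coupling window
(default 6 s ≈ the duration a transient stays elevated, the same
timescale the influence analysis uses to define active neighbours). After
each onset a cell is refractory for 2.5 s — transients closer than the
rise + peak time are neither physiologically plausible (store depletion)
nor resolvable as distinct events, so allowing them would make
ground-truth recall ill-defined. The default $\beta = 0.25$ keeps the
within-cluster cascade branching factor (sensitive-neighbour degree ×
rate × window × $\beta$) below ~0.35 at maximal drive; larger values push
clustered tissue toward criticality, where burst amplification, not the
drive curve, sets the event rate. The simulation refuses configurations
with $\lambda\,\Delta t > 0.5$.

**Encoding modes.** Venous: the event rate follows a 4PL of concentration
(bottom 0.004/s, top 0.04/s ≈ 0.2–2.4 events/min, logEC50 −6.5, Hill 1)
with a fixed amplitude distribution (mean 1.0 F/F~0~). Arterial: the
amplitude mean follows a 4PL (0.6 → 2.0 F/F~0~; the lower bound keeps
low-concentration events clear of the detection threshold so censoring
does not distort the frequency curve) while the rate follows a shallow
bell (base 0.04/s, height 0.005/s) — frequency saturates early at a
moderate level. Amplitude noise is multiplicative (CV 0.25) with an
absolute floor of 0.1 F/F~0~; $\sigma \sim N(0.5, 0.1)$ s,
$\tau \sim N(1.5, 0.3)$ s, giving FDHM ≈ 2 s. Baseline is 1 plus white
Gaussian noise (SD 0.05 F/F~0~); stimulus onset at 20 s leaves the 10-s
baseline search a guaranteed pre-stimulus region.

**What the generator does not emulate:** photophysics (bleaching, shot
noise), motion artifacts, subcellular events, smooth-muscle feedback or
hemodynamics, and the unknown spatial statistics of real sensitivity
communities (sizes and compactness are placeholder choices exposed in the
configuration). Passing tests therefore demonstrate that the pipeline
recovers the structures this model defines, not that real vessels have
them.

# Validation problem sizes

The automated checks run the pipeline end to end at desk scale, chosen to
keep the full suite within minutes while leaving clear statistical
margins: detection on 200 cells × 10 min; permutation-calibration and
centrality-enrichment runs on 150-cell sheets × 20 seeds × 100
permutations; neighbour-influence power runs pooling 3 replicate
120-cell datasets per seed (the pooled-replicate design mirrors how the
analysis is applied across animals); encoding classification on 110-cell
sheets over 9 half-log concentrations (1 nM–10 µM) × 20 seeds per vessel
mode; overlap recovery through the full detect→rank→overlap chain on 400
cells. Identical configurations (including seeds) reproduce bit-identical
masks, maps, traces and null distributions.

# Known limitations

* The hazard model is a phenomenological point process; it reproduces the
  statistical structure the analysis measures, not IP~3~/SR biophysics.
* The raster concave hull depends on the closing radius; masks with
  very uneven cell sizes may need an explicit `alpha`.
* The case–control influence readout has the structural $k = 1$ bias
  described above; comparisons should lean on the slope and on $k \ge 2$.
* Empirical percentiles from 100 permutations have a resolution of 1%;
  raise `nPerm` for finer claims.
* The count-preserving temporal permutation destroys within-cell temporal
  structure (refractory regularity, peak-time offsets) along with the
  neighbour relationships it targets. On synthetic data this produces a
  small conservative-negative drift of the observed slope's null
  percentile (mean ~0.43 instead of 0.50) even without coupling; the
  2.5–97.5 band still covers ~92–95% of uncoupled runs.
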