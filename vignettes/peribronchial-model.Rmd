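---
title: "A stochastic lattice model of fibrocyte-CD8 T cell dynamics in peribronchial tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stochastic lattice model of fibrocyte-CD8 T cell dynamics in peribronchial tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(fibrocyteCA)
```

## The biological question and the model

In chronic obstructive pulmonary disease (COPD), the subepithelial layer of
distal bronchi (the peribronchial lamina propria) accumulates both CD8+ T
cells and fibrocytes — circulating, fibroblast-like leukocytes.  The two cell
types are found closer together and in more shared clusters in diseased
tissue, and in vitro their contact drives CD8+ T-cell proliferation while
CD8-secreted CXCL8 attracts fibrocytes through CXCR1/2.  `fibrocyteCA` models
this interplay as a probabilistic cellular automaton and provides the spatial
statistics needed to compare simulated tissue states with segmented
histology.

Two agent types, C (CD8+ T cell) and F (fibrocyte), live on a crown-shaped
(annular) lattice of 3652 square sites of 7 um — one lymphocyte-sized cell
per site, about 0.179 mm^2 of tissue — with reflecting (zero-flux) borders at
the epithelial and muscular rims.  Time advances in 3-minute steps; a
20-year run is 3,504,000 iterations and one month is exactly 14,600
iterations (175,200/12).  Each step:

1. **Infiltration.**  With probability `p_ista_C` (`p_ista_F`) one C (F)
   cell enters on a uniformly chosen empty site.  Once per simulated year an
   exacerbation event offers `exac_burst` additional entry slots, each
   taken with probability `p_iexa_F` (`p_iexa_C`); in the control scenario
   these are zero.
2. **Per-cell actions.**  Every cell, visited in a fresh uniform random
   order, attempts exactly one action with the fixed priority *death >
   division > movement*:
   - a C cell dies with probability `p_dC`, raised to `p_dC_plus` when at
     least `k_crowd` of its 8 Moore neighbours are C cells
     (crowding-induced death); an F cell dies with `p_dF`;
   - a surviving C cell divides with probability `p_C`, raised to `p_C_F`
     when at least one F cell is adjacent (contact-induced proliferation);
     the daughter takes a uniformly chosen empty Moore neighbour, and the
     division fails silently if there is none.  Fibrocytes do not
     proliferate;
   - otherwise the cell moves, with probability `p_move_C` / `p_move_F`, to
     an empty Moore neighbour chosen with weight `exp(beta * n_opp)`, where
     `n_opp` counts opposite-type cells around the candidate site.
     `beta = 0` is an unbiased walk; a positive `beta_F` encodes the
     CXCL8-driven chemotaxis of fibrocytes towards CD8+ T cells and is the
     only movement asymmetry between scenarios.

Control and COPD are the same model with different rates; therapy scenarios
are parameter edits of the COPD set (`apply_therapy()`): restoring `p_C_F`
to its control value (CD54 blockade), restoring the fibrocyte displacement
behaviour (CXCR1/2 blockade), both, or the full control set ("total
inhibition").

Design choices the update rule had to fix, because a per-step composition is
not uniquely determined by per-process probabilities: actions within one step
are exclusive, with the death > division > movement priority; the update is
asynchronous over a fresh random permutation each step (fixed sweeps leave
lattice artifacts); an attempted division that finds no empty neighbour
consumes the step's action.  With per-step probabilities of order 1e-5 these
composition choices are second-order; they are fixed for reproducibility.

## Parameters, units, defaults

All rates are probabilities per 3-minute step.  Shipped defaults
(`default_params()`):

| parameter | control | COPD | rationale |
|---|---|---|---|
| `p_dC` | 1/43200 | same | 90-day mean tissue residence of CD8+ T cells |
| `p_dC_plus` | 6 x `p_dC` | same | crowding-induced death, `k_crowd = 2` |
| `p_C` | 1/144000 | same | basal division roughly every 300 days |
| `p_C_F` | 10 x `p_C` | calibrated | contact-induced proliferation |
| `p_ista_C` | calibrated | same | entry balancing turnover |
| `p_dF` | `log(20)`/7 y | same | F population stationary (95%) after ~7 y |
| `p_ista_F` | `p_dF` x 19 | same | holds 106 F/mm^2 stationary |
| `p_iexa_F` | 0 | calibrated | annual exacerbation bursts, `exac_burst` 20 |
| `p_move_C` | 0.5 | same | ~1.2 um/min effective speed, tissue-confined |
| `p_move_F` | 0.1 | same | fibrocytes adhere and move slowly |
| `beta_C` | 0 | 0 | no CD8 chemotaxis towards F |
| `beta_F` | 0 | 0.5 | CXCL8/CXCR1-2 fibrocyte chemotaxis |

The initial state seeds 660 C/mm^2 and 106 F/mm^2 uniformly at random (118 C
and 19 F cells on the default domain), the mean healthy densities.

The crowding threshold and its death multiplier deserve a note: they are the
model's density regulation, and their product sets how strongly the CD8
population damps its own fluctuations.  With weak damping the COPD endpoint
inherits the fibrocyte population's Poisson noise through the
contact-division lever (a one-fibrocyte fluctuation moves the quasi-static
CD8 equilibrium by several cells), producing between-replicate spreads far
wider than observed.  `k_crowd = 2` with a six-fold death raise brings the
replicate-to-replicate standard deviation of the COPD endpoint to the
observed scale (~100 cells/mm^2) while leaving mean behaviour calibratable;
both knobs are configurable.

## Calibration

The free rates are not directly measurable, so `calibrate()` fits them
against observed density endpoints: starting from the healthy state, 20
years of control dynamics should land at 754 C/mm^2 and 106 F/mm^2, and 20
years of COPD dynamics at 1187 C/mm^2 and 212 F/mm^2 (reported medians in
control subjects and COPD patients).

The fit uses a deterministic mean-field companion model
(`mean_field_rhs()`): the probability that a C cell has at least one F
neighbour is closed as `q_F = 1 - (1 - N_F/S)^8` and the crowding
probability as a binomial tail, i.e. neighbourhood composition is replaced
by its expectation under independent site occupancy.  Fibrocyte kinetics are
linear (immigration-death) and solve in closed form; `p_ista_C`, `p_iexa_F`
and the COPD `p_C_F` are then one-dimensional root-finding problems on the
integrated endpoints.  The independent-site closure ignores the spatial
correlations the automaton builds up (daughters are born adjacent,
chemotaxis pulls F towards C), so rates fitted purely on the mean field
leave the stochastic model a few percent off target;
`refine_calibration()` therefore measures the ensemble-mean endpoint
offsets of full stochastic runs and re-solves the two CD8-side rates
against offset-compensated targets; because the stochastic response to a
rate change is damped relative to the mean-field response (roughly 60%
here), the step is applied iteratively, pooling ensembles across
iterations to keep the offset estimates above their own noise.  The
shipped defaults are the converged values, and the full stochastic model
reproduces the four endpoint targets to within ensemble noise (see
`scripts/acceptance.R`).

The exacerbation schedule enters the mean-field model as discrete annual
impulses (integration events), not as a continuous inflow.  This matters:
the fibrocyte population follows an annual sawtooth under COPD dynamics, and
the 20-year endpoint falls exactly at a burst, so a calibration against the
cycle-average would overshoot the endpoint by the burst size (~20 cells per
mm^2).  Matching the impulse phase keeps the deterministic and stochastic
endpoints aligned.

A deliberate simplification: fibrocyte death uses a single `p_dF` per
scenario.  The observed early-COPD dip in fibrocyte death arises in the
model anyway, because deaths are proportional to a still-small population;
a two-phase `p_dF(t)` was judged an unnecessary extra parameter.

Because the annular domain holds only ~150-250 cells, endpoint densities
fluctuate strongly between replicates (the CD8 endpoint has a
between-replicate standard deviation of roughly 70-100 cells/mm^2, close to
the Poisson floor of the population size).  Medians over feasible ensemble
sizes (8-24 replicates here, versus 160 in the reference analysis)
therefore carry standard errors of tens of cells/mm^2; the acceptance
checks on endpoint medians operate near this noise floor, which is a
property of the study design, not of the implementation.

## Monthly ledgers

Every infiltration, division and death is tagged basal versus induced and
aggregated per calendar month (`MonthlyLedger` columns of the trajectory).
The split uses the natural decomposition of the raised probabilities: a
death that would have occurred at the basal rate is always booked as basal,
only the crowding excess (`p_dC_plus - p_dC`) is booked as induced, and
likewise for contact-induced divisions.  The ledgers satisfy exact
conservation — monthly population change equals entries plus births minus
deaths — which the test suite asserts for every replicate.

## The spatial quantification suite

The same metrics are applied to simulated lattice snapshots (points at site
centres) and to continuous histology-like patterns:

- `interacting_density()`: a C point is *interacting* when an F point lies
  within 3.6 um — the point-process counterpart of the 8-pixel mask
  dilation used on segmented images (4 px = 1.8 um; `dilation_px_to_um()`).
  For near-circular cells of that radius, centre distance below the
  dilation radius and mask overlap coincide; a mask-based mode is out of
  scope.  Note that on lattice snapshots the centre-to-centre distance of
  distinct cells is at least the 7-um site length, so the 3.6-um radius can
  never fire; cells rendered as site-filling squares touch exactly when
  they occupy adjacent sites, and the matching criterion for lattice
  patterns is a radius covering the Moore adjacency (10 um).
- `min_distance_stats()`: nearest-neighbour distances between types, with
  7-um binned histograms; same-type mode excludes the self-match.
- `delaunay_threshold_clusters()`: Delaunay triangulation of all centroids
  (Bowyer-Watson, built in compiled code and cross-checked in the tests
  against a brute-force empty-circumcircle oracle), removal of triangles
  touching the ROI boundary (any edge whose midpoint falls outside the ROI
  or within 1e-6 um of it — the lumen hole of the annulus is what this
  prunes in practice), strict `< 40 um` edge threshold, connected
  components with at least `min_cluster_size = 2` members (singletons are
  not groups), classified as CD8-only, Fib-only or mixed.  Near-cocircular
  quadruples (ubiquitous for lattice patterns) are resolved by insertion
  order; either diagonal of a 7-um lattice square is far below the
  threshold, so component structure is unaffected.
- `random_null_mixed_density()`: complete-spatial-randomness null — uniform
  placement at given intensities in the same ROI, same cluster pipeline,
  median mixed-cluster density over replicates.
- `track_contact_metrics()`: live-imaging readouts (mean, free and contact
  speed; contact coefficient; contact durations as run lengths of flagged
  frames at the 2-minute frame interval), with interval speeds attributed
  to the contact state of the starting frame and empty partitions reported
  as absent rather than zero.

### Percolation and the 40-um null model

A caution that matters when interpreting mixed-cluster densities: the
40-um-thresholded Delaunay graph of a *random* pattern percolates near
total intensities of ~900 points/mm^2.  Below that, mixed-cluster density
rises with intensity (more cells, more small groups); above it, components
merge and the count *falls* — at 1400 points/mm^2 a CSR pattern typically
collapses into one giant component plus fragments.  Null-model comparisons
at the 40-um threshold are therefore only monotone and informative in the
subcritical regime, and the package's property tests pin the monotone
behaviour there.  Simulated tissue states escape the collapse only insofar
as the dynamics concentrate cells into well-separated aggregates.

## The synthetic-data generators

`generate_pattern()` emulates segmented immunohistochemistry centroids:
CD8 points are a Poisson process (optionally Thomas-clustered), and each
fibrocyte is relocated, with probability `attraction / (1 + attraction)`,
to a Gaussian offset (default 10 um) from a random CD8 point — a cross-type
Neyman-Scott construction chosen over Gibbs interaction models because it
samples exactly and fast, and because the feature to emulate is simply the
increased proximity and co-clustering of fibrocytes around CD8 cells at
elevated densities.  Counts are Poisson by default to honour replicate
variability (fixed-count mode available).  `generate_track()` builds
alternating free/contact bouts with geometric lengths whose means hit the
target contact coefficient in expectation, gamma-distributed step lengths
and uniform directions.

What these generators do *not* emulate: segmentation artifacts (merged or
split particles, the 64-um^2 particle-area filter is assumed already
applied upstream), irregular hand-drawn ROI geometry, anisotropy along the
epithelium, and measurement noise in track positions.  Round-trip tests
(generator to metrics to recovered parameters) therefore validate the
analysis machinery, not the realism of any particular tissue section.

## Numerical choices

- All randomness flows from R's RNG: `set.seed()` plus one drawn
  sub-seed per replicate determines every trajectory bit-for-bit.  The
  compiled engine seeds a xoshiro256++ stream from R's RNG at entry, so
  the determinism contract survives the move to compiled code.
- Rasterizing the annulus ranks candidate sites by centre radius with a
  deterministic index tie-break, which makes any site count exactly
  attainable (equivalent to bisection on the outer radius, with ties
  resolved); the outer radius is then the largest included centre radius.
- The mean-field system integrates in years with `deSolve::ode`
  (`rtol = atol = 1e-8`); root-finding uses `stats::uniroot` at 1e-10
  tolerance on endpoints.
- Degenerate inputs resolve explicitly: fewer than 3 points (or collinear
  sets) fall back to pairwise-distance edges with a `degenerate` flag;
  missing cell types yield empty results, not errors; an all-contact track
  reports its free-speed partition as `NA`.
- Problem sizes in the shipped tests and acceptance script: 16 and 20 replicates respectively
  of the 20-year scenarios, 100-replicate null models, and small-domain
  ensembles for the property checks; these sizes keep the median standard
  errors within the tolerance discussion above.

## Known limitations

- The closure correction calibrates the stochastic model at the endpoint
  targets, not along the whole trajectory; transient shapes (plateau times
  of induced proliferation and mixed-cluster growth) are emergent and only
  qualitatively constrained.
- Fibrocyte recovery under "total inhibition" relaxes with the same time
  constant as disease onset (linear kinetics); an asymmetric, faster
  recovery would need a state-dependent `p_dF`.
- The movement kernel is a stand-in for chemotaxis along a resolved
  chemokine field; `beta_F` is an effective, not a measured, quantity.
- Two-dimensional tissue only; no CD4 cells, no cytokine dynamics, no
  fibrocyte differentiation.
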