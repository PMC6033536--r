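---
title: "A two-species exclusion model of ribosome traffic at a single uORF"
author: "uorfsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-species exclusion model of ribosome traffic at a single uORF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uorfsim)
```

## The model

During the Integrated Stress Response (ISR), phosphorylation of eIF2
depletes the ternary complex and so lowers the rate at which 43S
preinitiation complexes (PICs) are loaded onto mRNAs. Most mRNAs lose
translation under these conditions, yet a small group — typically
carrying a translated upstream open reading frame (uORF) in the 5'
leader — maintain or even increase initiation at their main coding ORF.
`uorfsim` implements a parsimonious mechanistic model of this behaviour:
a discrete-time, two-species totally asymmetric simple exclusion process
(TASEP) on a codon lattice.

The lattice has `L1` codons of 5' leader upstream of the uORF start,
`L2` codons of uORF (start and stop included), and `L3` codons
downstream, the last being the exit site. Two particle species move 3'
along it, each occupying `D` consecutive codons (default 10, the
ribosome footprint):

* **scanning ribosomes** (PICs), loaded at the 5' end with probability
  `lambda_load` (= `r_in`) per tact whenever the first `D_sigma` sites
  are free, advancing one site with probability `m_sigma` when the site
  ahead is empty;
* **elongating ribosomes**, created when a scanning ribosome initiates
  at the uORF start (probability `t_init` per arriving ribosome),
  advancing with probability `m_eps`, and resolved at the uORF stop —
  reinitiated as a scanning ribosome with probability `t_reinit`, else
  terminated and removed.

The one non-standard interaction, and the heart of the model, is
**collision dissociation**: when an elongating ribosome's forward move
lands on a site covered by a scanning ribosome, that scanning ribosome
is knocked off the mRNA (the elongating ribosome advances). Scanning
ribosomes blocked by anything ahead simply queue; they are never removed
by their own collisions. Optional spontaneous drop-off probabilities
(`P_sigma_spont`, `P_eps_spont`) and an initiation pause (`delta_eps`,
the movement multiplier of a freshly converted elongating ribosome until
its first successful move; 1 = no pause) complete the parameter set.

One tact applies six routines in a fixed order: loading, initiation,
termination/reinitiation, exit registration, movement, spontaneous
dissociation. Movement visits particles in decreasing position, so no
particle moves twice in a tact and a trailing particle may enter a site
vacated in the same tact — the ordered-sequential update convention of
discrete TASEPs. The quantity of interest is `r_out`, the rate at which
scanning ribosomes reach the exit site (a proxy for main-ORF initiation
flux), as a function of `r_in` (a proxy for PIC availability, reduced
under stress). *Stress resistance* in this model is a non-monotonic
response curve: `r_out` rising as `r_in` falls below its unstressed
level.

## Units and default rates

A movement probability of 0.3 per tact for an elongating ribosome,
together with a physiological elongation speed of 5 codons/s, fixes the
tact at `0.3 / 5 = 0.06` s (`tact_seconds()`). A measured mean loading
interval of 0.8 s then corresponds to a loading probability of
`0.06 / 0.8 = 0.075` per tact (`per_tact_probability()`), which is why
response curves scan `r_in` over `[0, 0.1]`: the upper anchor 0.1
represents an unstressed mRNA and `r_in -> 0` deep stress. Default
initiation efficiency is `t_init = 0.8` (20% leaky scanning) with no
reinitiation.

## Initiation-draw semantics

A subtle but consequential choice is *when* the initiation Bernoulli
draw happens. Read literally, a per-tact test at the start site would
compound: a ribosome dwelling at the start (it moves away only with
probability `(1 - t_init) * m_sigma` per tact) would face repeated
draws, making the realized per-ribosome initiation efficiency
`t_init / (t_init + (1 - t_init) * m_sigma)` — about 0.93 at the
defaults, so a nominally 20%-leaky start would pass only ~7% of
ribosomes. That reading is inconsistent with the behaviour this model
family is known for: initiation thresholds quoted on the nominal scale,
and an isolated-ribosome passage probability of exactly
`(1 - t_init) + t_init * t_reinit`. `uorfsim` therefore draws **once per
arriving ribosome**: a scanning ribosome that fails its single draw is
marked leaky and scans on, facing no further tests at the start. The
closed form above (`single_particle_passage()`) is then exact, and the
engine demonstrably converges to it as `r_in -> 0`. The exact
Markov-chain oracle encodes the failed-at-start scanner as a fourth
lattice symbol so that both implementations share the semantics while
sharing no code.

Termination needs no such distinction: an elongating ribosome fronting
the stop site is resolved — reinitiated or removed — within the same
tact, so `t_reinit` is a per-ribosome probability under either reading.

## Geometry conventions

Positions are 1-based; a particle's position is its leading (3'-most)
edge, and it covers the `D` sites ending there. Conversions at the start
and stop keep the leading edge fixed and regrow the footprint backwards;
if unequal footprints would require trailing sites that are occupied,
the conversion is deferred to a later tact rather than cancelled. The
flank lengths are not dictated by the biology of the uORF itself and
default to `L1 = L3 = 100` codons; they are configurable, and the
response curves do depend quantitatively (not qualitatively) on them
because upstream queue capacity scales with `L1`.

## Estimation and uncertainty

`run_simulation()` counts events over `n_tacts` tacts from an empty
lattice (burn-in excluded if requested; the default `burn_in = 0`
matches whole-run counting, so the standard error honestly includes the
short filling transient). `r_out` comes with a batch-means standard
error over 20 equal batches. Response curves report `r_out` both
absolutely and relative to the `r_in = 0.1` anchor; the relative error
combines both points by the delta method, with the anchor itself pinned
at exactly 1.

Two summary decisions deserve note:

* `find_max()` searches all grid points with `r_in > 0` (the `r_in = 0`
  endpoint carries no flux identically), breaking ties toward the
  smallest `r_in`; absolute and relative maxima coincide because the
  normalization is a single constant.
* `detect_nonmonotonic(curve, k)` flags a curve when any *interior*
  point exceeds 1 by more than `k` of its own standard errors. The
  default `k = 2` is a per-point test; a 20-point grid has 18 interior
  points, so at `k = 2` a *flat* curve is falsely flagged roughly a
  third of the time. For threshold scans, where one spurious flag
  relocates the reported boundary, the package's scan protocols use
  `k = 3` — numerically the Bonferroni-style correction of the per-point
  test for 18 simultaneous comparisons (one-sided family-wise error
  about 2%). This is a property of the detector, fixed in advance of any
  comparison, not a tuning knob.

## Problem sizes

Each published-style data point corresponds to a run of 10^6 tacts, and
a response curve to 20 points evenly spaced over `[0, 0.1]`. The package
defaults to 10^5 tacts (fast exploration); the threshold scans and
acceptance computations use between 10^6 and a few 10^7 tacts per point,
chosen by power analysis: the weakest real effects that the scans must
resolve are relative-flux excesses of 2–4% (uORF length 30; initiation
efficiency 0.5), so per-point relative standard errors must sit below
about 1% for a `k = 3` detector to see them reliably. Those sizes are
stated in `scripts/acceptance.R` next to each computation.

## The exact oracle

For unit footprints (`D = 1`), no initiation pause, and lattices of at
most 12 sites, the model is a finite Markov chain whose state is the
site string plus the leaky flag of a scanner at the start.
`transition_matrix()` enumerates the reachable states from the empty
lattice and every Bernoulli branch of a tact — including the
decreasing-position movement sweep — in pure R, sharing nothing with the
C++ engine. `stationary_flux()` solves the stationary linear system
(with a Cesàro time-average fallback for degenerate cases) and returns
the exact `r_out`, against which the engine is tested on instances
spanning initiation, reinitiation and both collision modes. Footprint-10
dynamics are validated instead by the structural invariants (site-string
/ registry consistency, non-overlap, elongation confined to the uORF)
and by exact integer conservation ledgers audited every 10^4 tacts:
every loaded ribosome is accounted for as exited, collision-dissociated,
spontaneously dissociated, net-converted, or still on the lattice; every
initiation as terminated, reinitiated, dropped off, or still elongating.

## Ribosome-profiling metrics

The profiling module applies the model's observational counterparts to
per-transcript count tables:

* `translation_efficiency()` — CDS footprints normalized by mean RNA-seq
  density and CDS length;
* `pause_score()` — the highest single-position uORF density over the
  mean of the remaining positions (first-argmax tie break; exactly one
  position excluded);
* `binned_zscores()` — transcripts sorted by expression, split into bins
  of 300, and the log2 TE fold change standardized within each bin
  (sample SD; a trailing bin smaller than half the bin size is merged
  into its neighbour, and the rule applied is recorded on the output);
* `correlate_features()` — Pearson and Spearman correlations with
  two-sided p-values plus the OLS slope, the statistics conventionally
  reported for uORF feature–response relations.

`generate_synthetic_profiles()` builds a cohort emulating the *structure*
of such data — log-scale uORF lengths, broad expression range, uORF
density profiles with one dominant peak, and a TE log fold change
carrying a planted linear effect of standardized log uORF length plus
Gaussian noise (defaults: 325 transcripts, effect 0.5, noise SD 1,
giving a planted length–response correlation near 0.45). It emulates
none of the hard parts of real ribo-seq — mappability bias, short-uORF
quantification noise, selection effects in transcript curation — so
recovering the planted effect shows the analysis chain is correct, not
that real-data correlations of any particular size should be expected.

## Known limitations

* Discrete time with ordered-sequential updates is a convention; other
  update orders (random-sequential, parallel) give quantitatively
  different fluxes for the same rates.
* One uORF, one scanning speed, one elongation speed: no
  codon-resolved rates, no multiple uORFs, no 43S/80S compositional
  detail.
* The exact oracle covers only unit footprints; extended-footprint
  dynamics are validated by invariants, conservation and limits, not by
  enumeration.
* Flank lengths are free parameters of the geometry; quantitative
  curve features (anchor flux, maximum location) shift with them.
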