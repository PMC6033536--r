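# uorfsim

Stochastic simulation of scanning and elongating ribosome interference
at a single upstream open reading frame (uORF).

## The problem

During the Integrated Stress Response, phosphorylation of eIF2 depletes
the ternary complex and lowers the rate at which scanning preinitiation
complexes load onto mRNAs. Translation of most mRNAs falls — yet a small
set of mRNAs, typically carrying one translated uORF, hold or *increase*
main-ORF initiation. `uorfsim` is for modellers and RNA biologists who
want to explore the mechanistic hypothesis behind this paradox: that
elongating ribosomes on a uORF knock scanning ribosomes off the mRNA, so
that *lowering* the loading rate can *raise* the flux of scanning
ribosomes that survive to the main ORF.

## The model

A discrete-time, two-species TASEP on a codon lattice of
`L1 + L2 + L3` sites (5' flank, uORF, 3' flank). Both species are
extended particles of footprint `D = 10` codons. Per tact (time step),
in fixed order:

1. a scanning ribosome loads onto sites `1..D_σ` with probability
   `λ = r_in` if they are free;
2. a scanning ribosome fronting the uORF start converts to an
   elongating ribosome with probability `t_σ>ε` — one draw per arriving
   ribosome; a ribosome that fails scans on (leaky scanning);
3. an elongating ribosome fronting the uORF stop reinitiates
   (probability `t_ε>σ`) or terminates;
4. a scanning ribosome fronting the last site exits and is counted
   (this defines `r_out`);
5. every particle makes one movement attempt (probabilities `m_σ`,
   `m_ε`), visited in decreasing position; an elongating ribosome whose
   move lands on a scanning ribosome dissociates it;
6. optional spontaneous drop-off (`P_σ`, `P_ε`).

With `m_ε = 0.3` and 5 codons/s elongation, one tact is 0.06 s, and a
0.8 s loading interval maps to `r_in = 0.075`, which motivates scanning
`r_in` over `[0, 0.1]`. *Stress resistance* is a non-monotonic
`r_out(r_in)` response: more downstream flux under less loading.

The core engine is C++ (via Rcpp); an exact Markov-chain oracle (pure
R, full enumeration of unit-footprint instances) and closed-form limits
validate it independently.

## A worked example

```r
library(uorfsim)

p <- sim_params(L2 = 100, n_tacts = 1e6, seed = 100)
curve <- sweep_rin(p)           # 20-point r_in sweep, [0, 0.1]
find_max(curve)
#> $r_in_at_max
#> [1] 0.03157895
#> $max_absolute
#> [1] 0.001489
#> $max_absolute_se
#> [1] 3.391863e-05
#> $max_relative
#> [1] 1.440039
#> $max_relative_se
#> [1] 0.05329598
detect_nonmonotonic(curve)
#> [1] TRUE
```

For a 100-codon uORF with an 80%-efficient start and no reinitiation,
the downstream flux `r_out` does not fall monotonically with the loading
rate: it *peaks* at `r_in ≈ 0.02–0.03` — at roughly 1.4× its unstressed
(`r_in = 0.1`) level in this run — which is the model's signature of
uORF-mediated stress resistance. (At 10^6 tacts per point the peak
location still wanders over the flat optimum; longer runs place the
plateau at `r_in ≈ 0.021–0.026`.)

```r
single_particle_passage(p)   # isolated-ribosome limit of r_out/r_in
#> [1] 0.2
oracle_check()[, c("exact", "simulated", "z")]  # engine vs exact chain
#>        exact simulated          z
#> 1 0.18905713  0.188585 -0.8079257
#> 2 0.09097283  0.090715 -0.4574267
#> 3 0.00000000  0.000000        NaN
#> 4 0.13500562  0.135530  1.0113259
#> 5 0.03945145  0.038225 -2.8653788
```

Threshold scans reproduce the model's qualitative structure — e.g. the
uORF length at which the response turns non-monotonic:

```r
ts <- threshold_scan("L2", c(10, 20, 30, 40), criterion_nonmonotonic(k = 3),
                     sim_params(n_tacts = 4e7, seed = 42))
ts$threshold
#> [1] 30
```

The profiling module computes the observational statistics used to
confront the model with ribosome-profiling data — translation
efficiency, uORF pause scores, and expression-binned Z-scores of TE fold
changes — plus a synthetic cohort generator with a planted uORF-length
effect for validating the analysis chain. A thin command-line wrapper
(`inst/cli/uorfsim.R`, driven by YAML configs via `run_cli()`) exposes
runs, sweeps, grids, threshold scans, oracle checks and the profiling
pipeline for shell use.

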