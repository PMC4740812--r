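# tbpnoise

Gene expression noise — cell-to-cell variability in expression among
genetically identical cells — is strongly associated with having a
TATA-box in the promoter, but the association by itself says nothing
about mechanism. `tbpnoise` implements a mechanistic account in which
noise emerges from three molecular determinants acting on the TATA-box
binding protein (TBP): its **affinity** for the binding-site sequence,
the **competition** between Mot1p (which evicts DNA-bound monomeric
TBP) and the SAGA co-activator (which completes an initiation-competent
assembly) for the same surface on TBP, and the **residence times** of
the resulting complexes. The package is aimed at quantitative/systems
biologists who want to simulate these regimes, and at anyone
reproducing the surrounding analysis stages on tabular data.

## The model

A promoter is a discrete-time Markov chain over five microstates —
free (`f`), monomeric TBP:TBS (`T`), Mot1p-bound (`M`), SAGA-bound
(`S`), TFIID-bound (`D`) — with `S` and `D` the transcribing ("On")
states. With affinity *a*, direct TFIID recruitment *p<sub>D</sub>*,
engagement *p<sub>e</sub>*, competition *c*, dissociation
*t<sub>off</sub>* and mean residences *r<sub>M</sub>*, *r<sub>S</sub>*,
*r<sub>D</sub>*, the transition matrix is

```
f:  [ 1 - a - p_D,  a,             0,        0,            p_D       ]
T:  [ t_off,        1 - t_off - p_e,  p_e c,  p_e (1 - c),  0         ]
M:  [ 1/r_M,        0,             1 - 1/r_M, 0,            0         ]
S:  [ 1/r_S,        0,             0,        1 - 1/r_S,     0         ]
D:  [ 1/r_D,        0,             0,        0,            1 - 1/r_D  ]
```

Populations of cells are simulated (500 cells × 150 steps by default,
no degradation), expression accrues per step spent On (with a larger
SAGA burst), and noise is the CV of per-cell totals. Around the
simulator sit the analysis stages that connect promoter identity to
noise: TATA-box/TATA-like/other classification against the `TATAWAWR`
consensus (with the position-5 T5/A5 subsets), median-split
co-activator regulation classes from ChIP occupancy, PBM 8-mer signal
aggregation, the abundance-independent DM noise metric (residual of
log CV from a running median over abundance), and a flow-cytometry
chain (ADC filtering, scatter-tail trimming, small-cell gating,
linear-model size correction, replicate-averaged CV). Synthetic-data
generators with planted truth make the whole pipeline testable without
any external dataset.

## Worked example

```r
library(tbpnoise)
library(dplyr)

bind_rows(
  glance(simulate_population(params_tata_box(),  seed = 1)),
  glance(simulate_population(params_tata_like(), seed = 2))
)
#>       label n_cells n_steps mean_expression sd_expression     cv turnover frac_on
#> 1  TATA-box     500     150             131          68.4 0.5228   0.1183   0.480
#> 2 TATA-like     500     150             133          13.3 0.0999   0.0259   0.883
```

Both archetypes express at the same mean level, but the TATA-box
promoter is five-fold noisier (CV 0.52 vs 0.10) and binds fresh TBP an
order of magnitude more often (turnover 0.118 vs 0.026 per step): under
Mot1p-dominant competition it cycles futilely between free and
monomer-bound states, waiting for rare large SAGA bursts, while the
TATA-like promoter sits stably in the long-lived TFIID state (On 88% of
the time).

```r
waiting_time_stats(simulate_population(params_tata_box(), seed = 1))
#> <waiting_times: 1051 complete Off runs | mean 19, median 13>

pd <- sweep_phase_diagram(competition_grid = c(0.1, 0.9),
                          residence_grid = c(5, 80),
                          n_replicates = 2, seed = 3)
as.data.frame(pd)
#>   competition residence cv_tata cv_talike cv_diff n_replicates
#> 1         0.1         5   0.254     0.108   0.146            2
#> 2         0.1        80   0.155     0.673  -0.518            2
#> 3         0.9         5   0.416     0.090   0.326            2
#> 4         0.9        80   0.649     0.298   0.350            2
```

The phase diagram exposes both regimes: when Mot1p dominates
(competition 0.9) the TATA-box gene is the noisy one, but when SAGA
usually wins and stays long (competition 0.1, residence 80) the sign
flips — the TATA-box gene becomes the *quiet* one (`cv_diff` −0.52),
because stable SAGA occupancy gives it a steady output while the
TATA-like gene still waits on sparse TFIID arrivals.
`autoplot(pd)` draws the diagram; `autoplot()` methods, `tidy()` and
`glance()` exist for the other result types, and `run_pipeline(out_dir)`
writes a complete synthetic bundle (FASTA + TSV/CSV + manifest) through
every analysis stage.

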