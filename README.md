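# loopnlock

Closed-loop and lock-residue analysis of protein folding topology.

## The problem

The closed-loop ("loop-n-lock") picture of protein folding proposes
that folded proteins are organised around chain segments of roughly 25
residues whose ends meet in space, held shut by small clusters of
interacting residues — the *locks*. If locks matter for folding, then a
contact-topology metric restricted to lock-associated contacts should
predict folding kinetics as well as, or better than, the same metric
over all contacts.

`loopnlock` is for structural bioinformaticians who want to test that
idea quantitatively. It detects closed loops (12–50 residues, ends
within 6 Å heavy-atom distance) and their locks in PDB/mmCIF
structures, refines locks against NMR ensembles, reduces them to
minimal residue pairs, and builds the *locks-plus-neighbours core* (the
minimal pairs plus every residue contacting them). On top of that it
computes contact order and total contact distance,

    CO  = (1 / (L·N)) · Σ |i − j|        over contacting pairs (i, j)
    TCD = (1 / L²)    · Σ |i − j|        (ACO = CO·L, ATCD = TCD·L)

over full or restricted contact sets, correlates them with ln k_f
across a protein set under Monte-Carlo null controls, runs
property-ranked residue-elimination analyses, derives per-residue
rigidity profiles from coarse-grain elastic-network Brownian dynamics
(with a permutation test for the ~24-residue spacing of rigid
residues), and scores contact persistence in trajectory snapshots
against the core. Synthetic generators with planted ground truth make
every stage testable without downloading structures, and a
transcription of a published 43-protein two-state folding set ships as
a fixture.

## Worked example

Detect a planted loop, build its core, and compare core-restricted
against all-contacts TCD correlations on a synthetic 43-protein cohort
whose rates are generated from core contacts:

```r
library(loopnlock)
library(dplyr)

s  <- make_loop_protein(70, loops = data.frame(start = 10, end = 35),
                        seed = 7)
fl <- find_loops(s)
fl[, c("loop", "start", "end", "length", "score", "pair_start", "pair_end")]
#> # A tibble: 1 × 7
#>    loop start   end length score pair_start pair_end
#>   <int> <int> <int>  <dbl> <dbl>      <int>    <int>
#> 1     1    10    35     26 0.714         13       33

build_core(c(fl$pair_start, fl$pair_end), attr(fl, "contacts"))
#> <locks-plus-neighbours core> synthetic: 10 core residues (of L=70),
#>   10 core contacts, 2 minimal-pair residues

cohort <- synth_folding_cohort(n_proteins = 43, seed = 1)
rates  <- make_rate_table(cohort, seed = 2)
tcd_full <- tibble(protein_id = cohort$protein_id,
                   value = sapply(cohort$contacts, total_contact_distance))
tcd_core <- tibble(protein_id = cohort$protein_id,
                   value = sapply(seq_len(nrow(cohort)), function(p)
                     total_contact_distance(cohort$core[[p]]$contacts,
                                            cohort$L[p])))
correlate_lnkf(tcd_full, rates)
#> <ln k_f ~ metric> n = 43 proteins, r^2 = 0.590, slope = -42, intercept = 10.5
correlate_lnkf(tcd_core, rates)
#> <ln k_f ~ metric> n = 43 proteins, r^2 = 0.796, slope = -97.4, intercept = 9.95
```

The loop is recovered at its planted boundaries (10–35, length 26), the
minimal lock pair (13, 33) sits inside the planted lock clusters, and
restricting TCD to the core lifts r² from 0.59 to 0.80 — the rates were
built from core contacts, and the all-contacts metric reads that signal
only through dilution.

The bundled two-state table summarises the same way real data would:

```r
summarize_core_stats(two_state_cores())
#> <core summary> 43 proteins
#>   mean core: 101.0 contacts, 29.9 residues
#>   aggregate core share: 37.8% of contacts, 42.6% of residues
#>   per-protein core residues: 41.2 +/- 10.6% (range 24.1-64.5%)
```

Each result type has `autoplot()` (contact maps, correlations,
elimination envelopes, autocorrelation curves) and the correlation fits
support `tidy()`/`glance()`. `run_pipeline()` chains generation, loop
finding, metrics and controls end to end from a config list or YAML
file, writing TSV/JSON artifacts and a run log.

See the vignette (`vignettes/closed-loop-analysis.Rmd`) for the model,
the null constructions, parameter defaults and design rationale.

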