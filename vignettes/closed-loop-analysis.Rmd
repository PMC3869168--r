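---
title: "Closed loops, locks and folding topology: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed loops, locks and folding topology: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopnlock)
library(dplyr)
```

## The scientific question

The closed-loop (loop-n-lock) picture of protein folding holds that the
basic structural unit of a folded protein is a *closed loop*: a
contiguous chain segment of roughly 25 residues whose two ends are
brought together in space by a cluster of mutually interacting residues,
the *lock*. If locks nucleate folding, then topology metrics computed
only over lock-associated contacts should explain folding kinetics at
least as well as metrics over all contacts.

`loopnlock` implements the full analysis chain needed to put that idea
under quantitative pressure:

1. **Loop and lock detection** — enumerate closed loops (12-50 residues,
   ends within 6 Å heavy-atom distance), score their end regions by
   connectivity, hydrophobicity and conservation, select a
   non-overlapping set greedily, optionally refine the locks against an
   NMR ensemble, and reduce each lock to a minimal residue pair.
2. **Topology metrics vs. kinetics** — contact order
   $\mathrm{CO} = \frac{1}{L N} \sum_{(i,j)} |i-j|$ and total contact
   distance $\mathrm{TCD} = \frac{1}{L^2} \sum_{(i,j)} |i-j|$ (with
   $\mathrm{ACO} = \mathrm{CO} \cdot L$,
   $\mathrm{ATCD} = \mathrm{TCD} \cdot L$), over all contacts or over
   the *locks-plus-neighbours core* (minimal pairs plus every contact
   touching them), correlated with $\ln k_f$ across a protein set, with
   Monte-Carlo controls over random contact subsets.
3. **Residue elimination** — remove residues in order of increasing
   hydrophobicity, connectivity, or their product, and track the
   TCD–$\ln k_f$ correlation against percentile envelopes from random
   removals.
4. **Elastic-network rigidity** — coarse-grain Brownian dynamics, per
   residue force constants, and the sequence autocorrelation of reduced
   force constants, testing the ~24-residue spacing of rigid residues
   with a within-protein permutation null.
5. **MD contact persistence** — per-pair contact fractions from
   trajectory snapshots, compared to a per-separation baseline, with a
   hypergeometric test of the enriched pairs' overlap with the core.

Every arm can run on real structures (PDB/mmCIF via bio3d) or on the
package's synthetic generators, which plant known ground truth.

## Normalisation choices

TCD is normalised by $L^2$ rather than $L N$. This is the convention of
the kinetics literature that introduced the metric, and it is the
property that makes TCD usable on restricted subsets: adding or removing
near-neighbour contacts barely moves $\sum |i-j| / L^2$, whereas CO's
$1/N$ prefactor re-weights every remaining contact. The identities
$\mathrm{ACO} = \mathrm{CO} \cdot L$ and
$\mathrm{ATCD} = \mathrm{TCD} \cdot L$ hold exactly for every subset and
are enforced by tests.

Contact maps default to a 6 Å minimum heavy-atom distance with
$|i-j| \ge 3$ (1,2 and 1,3 contacts excluded) for metrics, and
$|i-j| \ge 2$ for the connectivity count — the two definitions the
analysis arms require. Heavy atoms are all non-hydrogen atoms; alternate
locations resolve to the highest-occupancy conformer; residues are
renumbered 1..L over observed residues (author numbering is kept in an
attribute, and a gap in the author numbering therefore shortens $|i-j|$
— a documented limitation for structures with unmodelled segments).

## Lock scoring and selection

The combination rule for end-region scoring is multiplicative:
each loop end is scored as window-averaged scaled connectivity ×
scaled hydrophobicity × conservation, and the loop score is the mean of
its two end scores. A product was chosen over a sum because a lock
plausibly requires *all three* signals — a highly conserved but fully
exposed polar residue should not score as half a lock. With uniform
hydrophobicity and conservation the ranking degenerates to connectivity
alone, which the tests pin down. Hydrophobicity is scaled over the range
of the embedded octanol–water partition scale (so tryptophan is 1 in any
protein), while connectivity is scaled within the protein (so "most
connected residue here" is 1); conservation is an optional 0-1 input
column defaulting to 1.

Greedy selection accepts loops in descending score order when their
*interiors* overlap every accepted loop by at most 5 residues; shared
endpoints are always allowed, so one lock region can close two loops.
Ties break toward shorter loops, then smaller start index. Candidates
with score exactly zero are discarded: a loop end carrying no property
weight is, by the scoring model's own logic, no lock.

The lock-region growth rule (left open by the qualitative description of
locks as 2–8 residue clusters) is: around each loop end, take the
maximal contiguous run of residues — at most 3 on either side — each of
which contacts the opposite end's ±2 window within 6 Å; a region that
would end up as a single residue is padded with its closest flanking
neighbour. NMR refinement keeps a lock residue when it contacts the
opposite region in at least half the models (threshold configurable);
locks reduced below two residues are flagged rather than silently
dropped. The minimal pair maximises summed connectivity over
cross-region residue pairs in contact, breaking ties by smallest
distance and then lowest indices, so results are deterministic.

## Monte-Carlo machinery

Three null constructions appear, all seeded and all using add-one
smoothing $(1 + \#\{\text{null} \ge \text{obs}\})/(n+1)$:

* **Random contact subsets** (`random_contact_control`): residues are
  drawn uniformly without replacement until the contacts induced among
  them reach the target count, then the induced set is thinned to
  exactly that count. Matching the *count* rather than the residue
  number keeps the null comparable to the core subset it shadows.
* **Random removals** (`elimination_curve`): at each removal percentage,
  percentile envelopes (1/5/50/95/99) over uniformly random removals of
  the same per-protein counts. Rank ties at the removal boundary are
  resolved by uniform sampling with the mean correlation over
  `tie_reps` draws reported. Removal drops contacts touching removed
  residues but keeps $L$ fixed in the TCD denominator — removal acts on
  the contact subset, in line with how restricted subsets are used
  elsewhere in the package; shrinking $L$ as well would conflate subset
  choice with chain-length rescaling.
* **Within-protein permutations** (`randomization_test`): the reduced
  force constants are shuffled within each protein, preserving each
  protein's value distribution while destroying sequence structure. The
  statistic is mean C(L) over lags 22–27 against the flanking lags
  15–20 and 30–35. The default is 9,999 shuffles; a final analysis
  should use 99,999.

The autocorrelation C(L) pools products across proteins and normalises
by the total number of residue pairs at lag L. The alternative —
averaging per-protein autocorrelations — is available via
`pool = FALSE`; pooling was made the default because it matches the
"normalised by the number of residues at distance L" convention and
keeps short proteins from dominating through noisy per-protein curves.

## Elastic-network Brownian dynamics

Structures are reduced to one to three beads per residue: the C$\alpha$,
a side-chain centroid for residues with more than one side-chain heavy
atom, and a second (distal) centroid for large side chains (Trp, Tyr,
Phe, Arg). All bead pairs closer than 9 Å are joined by identical
harmonic springs, $\gamma = 0.6$ kcal mol$^{-1}$ Å$^{-2}$, rest length
equal to the build-time distance, so the network starts at equilibrium.

The integrator is plain overdamped (Euler–Maruyama) Langevin:
$x \leftarrow x - (\Delta t/\zeta)\nabla U + \sqrt{2 k_B T \Delta t/\zeta}\,\eta$,
implemented in C++ with noise drawn from R's RNG, so `set.seed()` gives
bitwise-reproducible trajectories. The scheme is stable for
$\Delta t < 2\zeta/k_{\max}$ and carries an $O(\Delta t)$ bias in the
stationary variance of order $\gamma\Delta t/2\zeta$; the defaults
($\Delta t = 0.01$, $\zeta = 1$, reduced time units) keep that bias
well below the 5% tolerance at which the integrator is validated
against the exact stationary bond-length variance $k_B T/\gamma$ of an
isolated pair. Divergence (a bead beyond $10^8$ Å or non-finite) aborts
with a diagnostic naming the step.

Per-residue force constants use the rigidity-profile convention
$k_i = 3 k_B T / \mathrm{Var}(d_i)$, where $d_i$ is the mean distance
from residue $i$'s C$\alpha$ bead to all other residues' C$\alpha$
beads over saved frames. $d_i$ is invariant under global translation
but not rotation; since the elastic network has no net torque and the
equilibration discard removes the transient, residual rigid-body
rotation inflates all variances roughly equally and cancels in the
per-protein Z-scoring ($k_z$, mean 0, s.d. 1), whose negative values
are clipped to zero to give the reduced force constants $k'$.

## What the synthetic generators emulate — and what they do not

`make_loop_protein` builds a bead chain (one heavy atom per residue,
3.8 Å virtual bonds) whose planted loops are geometric, not statistical:
each loop's ends form a two-square antiprism-like cluster in which the
end pair sits at the requested gap (default 3.9 Å) and every cluster
residue genuinely has ≥ 4 spatial neighbours, the loop interior runs
around a circular arc, and the rest of the chain is routed along
collision-checked corridors. Planted loop ends are named TRP (the
octanol scale maximum) on an ARG background (the scale minimum), so the
hydrophobicity signal of a lock is maximal and *decoy* loops — same
geometry, background naming — contribute contacts without ever winning
selection. Generation retries with fresh jitter until self-avoidance
(≥ 3 Å non-bonded) and the planted contacts hold, then fails loudly.

`synth_folding_cohort` draws 43 such proteins (60–130 residues, 1–3
lock loops of 15–40 residues, 0–2 decoys) and records the ground-truth
core. `make_rate_table` then generates
$\ln k_f = \text{slope} \cdot \mathrm{TCD}_{\text{core}} + \text{intercept} + \mathcal{N}(0, \sigma^2)$.
The defaults (slope $-100$, intercept 10, $\sigma = 0.5$) were fixed
once so that on the reference cohort the *all-contacts* correlation
lands near $r^2 = 0.6$ — i.e. the full map is a diluted readout of the
core signal — which is the regime in which comparing core-restricted
and full correlations is informative. The slope is negative because
higher TCD (more long-range structure to assemble) means slower
folding.

`make_ensemble` perturbs coordinates with Gaussian jitter and breaks
listed contacts in exactly $\lceil(1-p)M\rceil$ of $M$ models, so
planted persistence is realised exactly. `make_trajectory` alternates
an extended conformer with a helical one (the helix supplies a uniform
(i, i+3) contact baseline) and places each planted pair in contact in an
exact number of extended frames — making the planted pairs the only
separation-enriched contacts by construction.
`make_rigidity_profiles` plants triangular k' peaks every `period`
residues at random phase plus clipped noise, and
`synth_elimination_cohort` grows compact self-avoiding globules with
residue identities assigned independently of geometry, so
hydrophobicity and connectivity are uncorrelated by construction and
the "hydrophobic core" signal (contacts within the top 40% most
hydrophobic residues) is invisible to connectivity ranking.

None of these emulate real protein statistics: no secondary-structure
propensities, no realistic packing density gradients, no correlated
conservation, no force-field physics. Passing the synthetic recovery
tests demonstrates that the *machinery* — detection, restriction,
correlation, nulls — does what it claims under known truth; it does not
by itself validate the closed-loop hypothesis on real proteins. The
bundled 43-protein table carries the real-data side of the analysis
that is reproducible without structure downloads (the core-size
arithmetic); the headline real-data correlations ($r^2 = 0.65$ all
contacts vs $0.76$ core-restricted) require the 43 PDB/NMR entries and
are deliberately out of desk scope.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use: 20 replicate cohorts
of 43 proteins for the core-vs-full comparison; 20 seeds for loop
recovery; 400,000 BD steps for the equipartition check; 50 profiles of
150 residues with 9,999 shuffles for the rigidity peak (and 200 null
datasets at 999 shuffles for p-value calibration); 30 globules of 60
residues with 200 random removals per 2% grid step for the elimination
arm; 500-frame trajectories for the MD arm. All randomness flows from
explicit seeds through one derivation function, so any stage can be
reproduced in isolation; `elimination_curve` additionally derives a
sub-stream per grid point, making single points reproducible without
recomputing the curve.

## A compact end-to-end example

```{r example, eval = FALSE}
res <- run_pipeline(list(
  seed = 2, out_dir = tempfile(),
  stages = list(synth = TRUE, loops = TRUE, metrics = TRUE,
                control = TRUE),
  synth = list(n_proteins = 8, n_residues = c(60, 110))))
glance(res$correlations$core)
summarize_core_stats(two_state_cores())
```

## Known limitations

* Single-chain analysis only; inter-chain contacts are ignored.
* Missing residues are renumbered over observed residues, compressing
  $|i-j|$ across gaps (a warning-level concern for real crystal
  structures with disordered segments).
* The exact lock-scoring weights of the original qualitative
  description are unknowable; the multiplicative rule here is a
  documented design choice, validated only in the sense that planted
  locks are recovered and zero-signal decoys are not.
* The MD arm consumes snapshot coordinates; it does not run or validate
  the simulations that produce them.
* The enrichment flag convention for contact log ratios defaults to
  `log_ratio > +0.3` (pairs *more* likely in contact than their
  separation baseline); the mirrored convention is available as
  `convention = "depletion_sign"` for comparability with analyses that
  report the ratio with the opposite sign.
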