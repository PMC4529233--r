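---
title: "Replica exchange Monte Carlo peptide design: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replica exchange Monte Carlo peptide design: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepremc)
```

## The model

`pepremc` treats peptide design as Markov chain Monte Carlo over sequence
space. The state of one chain (a *replica*) is a fixed-length amino-acid
sequence together with its last accepted docking score $S$ (kcal/mol; more
negative = better predicted binding). Each optimisation step proposes a
single-point mutation — position uniform over the chain, replacement residue
uniform over the alphabet excluding the incumbent — scores the mutant, and
accepts with the Metropolis probability

$$P_{\mathrm{acc}} = \min\left[1, \exp\!\left(-\frac{S_{\mathrm{new}} - S_{\mathrm{old}}}{k_B T}\right)\right].$$

The single-point kernel is symmetric ($P(p \to q) = P(q \to p)$ for all
Hamming-1 pairs) and connects sequence space in at most $L$ moves, which
together with the Metropolis rule makes the per-temperature chain target the
Boltzmann measure $\pi(s) \propto e^{-S(s)/k_B T}$ when scoring is
deterministic. Three replicas run at $k_B T = 0.2, 0.4, 0.6$ kcal/mol, and
after every mutation sweep one swap is attempted between two uniformly
chosen distinct temperatures with the parallel-tempering criterion

$$P_{\mathrm{swap}} = \min\left[1, \exp\!\left(\left(\tfrac{1}{k_B T_a} - \tfrac{1}{k_B T_b}\right)(S_a - S_b)\right)\right],$$

which preserves the product of the per-temperature stationary measures: a
better score moving to the colder slot is always accepted, the reverse pays
the corresponding Boltzmann factor. A campaign repeats the run (default 9
times, 100 steps, octa-alanine start) and selects each run's lowest-scoring
final-step replica.

Two conventions deserve a note. First, the acceptance rule is sometimes
printed in the literature with the sign inside the exponential flipped
and/or the temperature dividing outside it; both readings would drive the
chain toward *worse* scores, contradicting the intent and the observed
downhill trajectories, so the package implements the minimisation form
above. Second, no published swap criterion accompanies the protocol this
package implements; the standard parallel-tempering rule is used because it
is the unique choice preserving detailed balance for the product measure.

## Scoring backends

The engine never sees structures: a backend is any object with a
`score_sequence(backend, sequence, site, config)` method returning a score
and an opaque pose handle. Structure relaxation and docking are folded
behind this contract; a backend that cannot produce a pose signals a
classed failure condition, which the engine logs and treats as a rejected
proposal (the optimisation loop has no failure branch by design). Adapter
metadata for external docking engines — a 25 Å cubic search box centred on
a target atom, exhaustiveness 10, energy range 4 — is carried verbatim in
`docking_config()` and ignored by the synthetic backend.

### The synthetic landscape

`generate_landscape()` draws an additive table: one term per (position,
residue), i.i.d. $\mathcal{N}(\mu_t, \sigma_t)$, with defaults
$\mu_t = -1.5$, $\sigma_t = 0.5$ kcal/mol. The mean score of a sequence is
the sum of its terms (plus any pairwise epistasis supplied), and each
scoring call adds fresh Gaussian noise (default SD 1 kcal/mol, configurable
per site; zero makes the backend deterministic). The negative-control site
is either the binding mean shifted by a constant (default +4 kcal/mol) or
an independently drawn table — the first mode is needed to test the
corrected binding energy under a known alternative, the second under
site-specific structure.

These defaults emulate the score scales of ensemble-docked octapeptides:
typical sequence means near −12 kcal/mol, additive optima near −19 to −20
kcal/mol, a baseline-to-optimised gap of about 7.5 kcal/mol, per-docking
dispersion of 5–15% of the mean, and a binding-vs-control gap of a few
kcal/mol. What the generator does *not* emulate: real docking scores are
not additive over residues (conformational coupling), their noise is not
Gaussian or homoscedastic, failures are not independent of sequence, and
the control site of a real receptor differs by structure, not by a constant
shift. Tests passing on the synthetic backend therefore validate the Monte
Carlo machinery, the estimator algebra and the pipeline plumbing — not the
accuracy of any docking engine.

For additive (epistasis-free) landscapes the generator records the global
optimum (per-position argmin), giving an exact reference for optimiser
benchmarks; `synthetic_landscape()` builds landscapes from explicit term
tables for constructions such as two-basin decoys.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `ladder` | 0.2, 0.4, 0.6 | kcal/mol | protocol ladder; spans near-greedy to exploratory acceptance on the docking-score scale |
| `n_steps` | 100 | steps | protocol run length; one mutation sweep + one swap attempt per step |
| `n_runs` | 9 | runs | protocol campaign size |
| rescore `kBT` | 0.6 | kcal/mol | mutation-off rescoring temperature |
| rescore `n_runs`, `n_steps`, `retain_last` | 10, 100, 10 | — | "last 10 configurations of 10 runs" averaging convention |
| `rt` | 0.593 | kcal/mol | RT at 298 K for $\Delta G = RT\ln K_D$; 0.6 also exposed (see below) |
| `term_mean`, `term_sd` | −1.5, 0.5 | kcal/mol | landscape calibration (above) |
| `noise_sd` | 1.0 | kcal/mol | ~5–15% relative per-docking dispersion |
| `control_offset` | +4.0 | kcal/mol | binding-vs-control score gap |

`kBT` is dimensionally matched to the scores (kcal/mol); it is a tunable
acceptance scale, not a physical temperature.

## Rescoring and the corrected binding energy

With the mutation step switched off, each of `n_runs` chains repeatedly
re-scores the *same* sequence and applies Metropolis acceptance at
$k_B T = 0.6$. For Gaussian per-call noise this is an independence-proposal
Metropolis sampler whose stationary law is exactly
$\mathcal{N}(\mu - \sigma^2/k_B T, \sigma^2)$: the selection walks the
chain $\sigma^2/k_B T$ into the low tail (e.g. −16.67 for $\mu = -15$,
$\sigma = 1$). The retained sample is the chain state at each of the last
`retain_last` steps — duplicates included when proposals were rejected,
because a Monte Carlo average is defined over chain states, not distinct
poses.

The corrected binding energy of a peptide is
$\mathrm{BE} = \langle E_{\text{binding site}}\rangle - \langle E_{\text{no binding site}}\rangle$,
and because the Metropolis selection shift $\sigma^2/k_B T$ is the same at
both sites (equal noise), it cancels in the difference — the package tests
this cancellation explicitly. Reported uncertainty is the *sum* of the two
sites' standard errors (the convention used for published error bars of
this statistic), with quadrature available as an explicitly non-default
option.

**Standard errors.** Consecutive retained states of one chain are strongly
autocorrelated (a low state survives many rejections), so the naive
$\mathrm{sd}/\sqrt{n}$ over all retained samples understates the standard
error of the site mean roughly threefold. The package therefore estimates
the SEM by batch means over the independent runs,
$\mathrm{sd}(\text{run means})/\sqrt{n_{\text{runs}}}$ — the standard error
analysis for averages over independent chains, and the reading consistent
with errors "calculated over the last 10 configurations of 10 runs". The
naive variant is kept as `sem_samples`; descriptive SDs remain over all
retained samples.

A related subtlety: the *dispersion* of retained samples equals the noise
SD only at stationarity. At fixed $k_B T$ the stationary target shifts
$\sigma^2/k_B T$ below the proposal mean, so equilibration slows sharply
as noise grows (at $\sigma = 2$, $k_B T = 0.6$ the shift is $3.3\sigma$ and
100 steps are nowhere near enough). The clean, exactly testable statement
is scale equivariance: scaling $k_B T$ with $\sigma$ leaves the acceptance
decisions identical, so the retained SD is exactly proportional to
$\sigma$. The test suite verifies that form, plus monotone growth of the
SD in $\sigma$ at fixed $k_B T$.

## Affinity conversion

$\Delta G = RT \ln K_D$ with $K_D$ in molar units and RT = 0.593 kcal/mol
(298 K). Published affinity windows for this class of peptides are
sometimes quoted on the rounded RT = 0.6 scale — the 3.28–5.11 kcal/mol
window for the packaged table reproduces only with 0.6 — so both values are
exposed and the validation pins RT per quantity. The error formula
$\sigma_{\Delta G} = 0.434\,(\sigma_{K_D}/K_D)$ is applied verbatim: the
constant is $\log_{10} e$, i.e. the absolute error of $\log_{10} K_D$,
nominally in kcal/mol only if one omits a $2.303\,RT$ factor that a
first-order propagation of $RT \ln K_D$ would carry. The package does not
"correct" the convention, so converted error bars are directly comparable
with published ones; users propagating errors ab initio should multiply by
$2.303\,RT$ themselves. Entries that cannot be converted ("CBE", "No
binding") are never dropped silently: they are flagged and listed
separately by `convert_affinities()` and `compare_theory_experiment()`.

## Numerical and design choices

* **Draw order** is fixed and documented: per step, for each replica in
  ladder order — mutation position, mutation residue, one score draw, one
  acceptance uniform — then one swap-pair draw and one swap uniform. Every
  Metropolis decision consumes exactly one uniform (even certain
  acceptances), and every synthetic scoring call consumes exactly one
  normal (even at zero noise), so trajectories are bit-reproducible given a
  seed and draw order does not depend on parameter values.
* **Score caching**: a replica's current score is never re-evaluated; only
  proposals trigger scoring. With a stochastic backend the chain would
  otherwise be ill-defined; this is the standard noisy-Metropolis
  convention.
* **Campaign seeds** derive deterministically from the campaign seed (one
  `sample.int` stream), so campaigns parallelise without seed collisions.
* **Selection tie-breaks**: lowest final score, then lower $k_B T$, then
  lexicographic sequence — fully deterministic selection.
* **Degenerate inputs**: a 0-step run returns the scored start sequence
  (with a warning at the CLI); single-temperature ladders skip swap
  attempts; a backend failure on the very first scoring aborts (there is no
  state to fall back to), later failures reject the proposal and are
  logged.
* **Unresolved-candidate flag**: ranking flags every candidate whose
  $[\mathrm{BE} \pm \mathrm{err}]$ interval overlaps the best entry's
  (including the best itself when any other overlaps), making "winner not
  statistically separated" explicit in the output table.
* **Config files** must state `ladder` and `backend` explicitly — a run
  configuration is a complete record of a campaign — while all other fields
  default to the protocol values. Outputs carry tool version, seed and a
  configuration hash; FASTA records carry them as `key=value` description
  fields since FASTA has no comment syntax. No timestamps are written, so
  identical config + seed gives byte-identical outputs.

## Validation suite and problem sizes

The statistical validation runs at these sizes, chosen to put Monte Carlo
error well below each tolerance while keeping the suite fast:

* Metropolis and swap acceptance laws: $10^5$ decisions against the closed
  forms ($3\sigma$ binomial bands).
* Boltzmann sampling: a 64-state landscape (length 3, 4-letter alphabet,
  noise 0) whose partition function is exactly enumerable; $2\times 10^5$
  steps; total-variation distance below 0.02 (single chain) and 0.03
  (per-temperature marginals with swaps enabled).
* Corrected binding energy: 500 seeded repetitions of the full rescoring
  protocol under a known site difference (−4 kcal/mol) and under the
  identical-site null.
* Replica-exchange benefit: 50 runs on a two-basin landscape (global
  optimum at −6, decoy at −5.5 behind a ~1 kcal/mol-per-move barrier built
  from pairwise couplings), REMC versus equal-budget cold-only search
  started in the decoy.
* Determinism: a full default campaign written twice and byte-compared.

## Known limitations

* **Finite-temperature sampling is not ground-state recovery.** Under the
  realistic landscape calibration above, the exact Boltzmann measure of the
  coldest replica ($k_B T = 0.2$) keeps a mean gap of ~1.3 kcal/mol to the
  additive optimum — more than the 5%-of-optimum (~0.95 kcal/mol) radius —
  so a 9-run campaign at the protocol ladder recovers scores *near* but not
  *at* the optimum (median relative gap ~9% at 100 steps; the validation
  suite records the recovery fractions rather than asserting near-certain
  recovery, and the corresponding strict recovery check fails by design of
  the study conditions). The engine itself reaches the global optimum
  reliably when run colder and longer (e.g. ladder 0.02/0.05/0.1, 400
  steps), confirming the gap is thermodynamic, not algorithmic.
* The synthetic backend's additivity makes optimisation easier than real
  docking landscapes; the two-basin construction probes barrier crossing
  but real ruggedness is richer.
* No external docking adapter is bundled: executing a docking engine,
  structure preparation and pose refinement are outside the package's
  scope. The adapter contract (scoring method + failure semantics +
  `docking_config` metadata) is the supported integration point, and the
  engine is verified against a recorded-replay fake to be indifferent to
  the backend behind it.
* Insertions, deletions, cyclic peptides and non-natural residues are out
  of scope; the mutation kernel preserves length and alphabet.
* Isoelectric points in the packaged affinity table are reproduced as
  published, not computed.
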