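---
title: "Boolean network models of drug-combination synergy: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boolean network models of drug-combination synergy: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnsynergy)
```

This vignette explains the model behind `bnsynergy`, its assumptions, the
tunable parameters and their defaults, the numerical choices made where
the method leaves room, and what the synthetic-data tests do and do not
demonstrate about real data.

## 1. The Boolean model and its assumptions

A signalling network is a signed directed graph over merged protein
entities (complexes conventionally suffixed `_c`, isoform groups `_i`).
Each node holds a Boolean activity; `compile_default_rules()` translates
topology into update rules under three conventions:

* several activators combine with **OR** — any active upstream signal
  suffices;
* an **inhibitor wins** over all activators:
  `(A or B) and not (C or D)`;
* ligand nodes marked as self-loops include themselves among their
  activators, modelling autocrine production.

Regulator-free nodes that are not self-loops receive an *identity* rule
(they hold their state). The alternative — decay to 0 — would silence
every unlisted input; holding state is the conservative choice for
boundary nodes, and persistent inputs can still be modelled explicitly via
self-loops. Curated refinements (e.g. an AND requirement for dual
phosphorylation) enter as rule-table inputs or per-cell-line overrides,
not as compiler heuristics.

Dual-sign regulation (both an activating and an inhibitory edge between
the same pair, as can arise when merging interaction databases) is kept:
both edges enter the default rule and the inhibitor-wins convention
resolves the conflict dynamically. Precedence across model layers is
fixed: mutation clamps > rule overrides > compiled defaults. A clamped
node never updates, so overriding a clamped node's rule is accepted only
with a warning and has no dynamical effect.

## 2. Cell-line personalisation

* **Mutations**: gain-of-function clamps the node to 1, loss-of-function
  to 0, for the whole simulation. Conflicting annotations for the same
  node are an error, not a silent choice.
* **Expression**: values (TPM-like, non-negative) are min–max scaled per
  gene *across* the cell-line panel; the scaled value is the probability
  the node starts on. A gene constant across the panel carries no
  contrast, so it receives 0.5 (with a warning) rather than forcing the
  node on or off. Nodes without any measured gene (complexes, ligands)
  default to 0.5 — the maximum-entropy choice — and complex/isoform nodes
  mapped to several genes take the mean of the members' scaled values.
  All three conventions are overridable inputs, because they are
  substitutes for information the data do not provide.

## 3. Simulation and steady-state detection

Trajectories use the uniform asynchronous scheme: among nodes whose rule
output differs from their state, one is flipped, chosen uniformly. The
ensemble default is `repeats = 100` trajectories of `steps = 5000`
updates; both are configurable everywhere.

The entropy profile is computed on the empirical distribution of full
network states **pooled over repeats and over steps 0..t**. Pooling is a
deliberate reading of the steady-state criterion: a per-trajectory
distribution at a single time point is one observation and has no usable
entropy, while the pooled distribution is well sampled and decays smoothly
as a dominant state takes over. Entropy is recorded every
`entropy_stride = 10` steps, and the steady state is declared at the
checkpoint where the centred finite-difference slope over
`entropy_window = 100` steps is most negative (ties break to the earliest
time; raw one-step slopes of an empirical entropy are noise-dominated,
hence the window). Activities from that step to the end are averaged into
steady-state activities. Fixed points are detected exactly: once no node
can change, the remaining steps are filled analytically.

Seeds: one root seed per run; every consumer (initial-state sampling, the
engine's per-repeat streams, drug draws per dose cell, the GA) gets a
deterministic child seed derived by hashing the root with a stage tag, so
identical configurations are bit-reproducible and sub-stages stay
decoupled.

## 4. Drug perturbation

A drug is a set of (target node, agonist/antagonist) pairs. Dose d ∈
[0,1] is the probability that a target becomes clamped (agonist to 1,
antagonist to 0), drawn **once per repeat at application time** — the
natural reading of an occupancy-style perturbation; per-step redrawing
would model a fluctuating drug instead. Multi-target drugs draw
independently per target by default (`shared_draw = TRUE` collapses this
to one draw), since nothing in the dose-as-probability picture couples
distinct targets. A drug can never displace a mutation clamp: genetic
lesions are constitutive, and conflicts are logged as warnings.

The two-phase protocol first simulates the unperturbed model to its
entropy-detected steady state, then, per dose cell and repeat, applies the
drawn clamps to the pre-treatment end state and simulates a second phase
of the same length with the same steady-state criterion. The default grid
is {0, 0.25, 0.75, 1}² with `repeats = 30` per cell (the unperturbed
phase uses 100); the grid is configurable — four doses per drug is a
compute compromise, not a modelling claim. Monotherapy activities are
read from the grid edges, never re-simulated, so the PSS at cell (a, b)
always compares against exactly the monotherapies (a, 0) and (0, b).

## 5. Synergy scoring

For an oncoprotein, `PSS = min(X1, X2) − X12`; for a tumor suppressor,
`PSS = Y12 − max(Y1, Y2)`. Activities in [0,1] bound the score to
[−1, 1]; 0 is additivity in the highest-single-agent sense. The consensus
per protein is the **75th percentile** of its PSS over all grid cells,
with linear interpolation between order statistics (R's default quantile
definition, pinned for reproducibility). Zero-dose cells are included in
the consensus; their PSS is additive by construction, which shrinks the
consensus toward 0 — documented behaviour, consistent with reading "all
dose combinations" literally. The predicted HSA score of a pair is the
sum of consensus PSS over the selected panel; the bundled 13-protein
default spans apoptosis, cell-cycle, hormone and PI3K/AKT readouts. The
onco/tumor-suppressor role table is a required, auditable input: the
packaged default covers the commonly scored nodes and can be replaced
wholesale.

## 6. Genetic-algorithm selection

Chromosomes are variable-length protein subsets that always contain the
mandatory members (default E2F1 and CASP3 — the proliferation and
apoptosis readouts); fitness is the Pearson correlation between summed
consensus PSS and observed scores, with zero-variance predictions
assigned −1. Per generation: rank, keep the top 30 as parents, produce 30
offspring (uniform set-crossover, then one add/remove/swap mutation, each
operator applied with probability 0.9), and add 30 fresh random
chromosomes. The next population is offspring + fresh — parents do not
re-enter. That literal, non-elitist bookkeeping can lose the best
chromosome, so a hall of fame of size one tracks the best-ever subset,
which is what `ga_evolve()` returns; the best-ever fitness trace is
therefore non-decreasing by construction. Fitness values are cached by
protein set, since later generations re-propose duplicates heavily.
Initial lengths are uniform in [3, 20]. The default budget is 500
generations — on candidate pools of tens of proteins the best-ever
fitness plateaus well before that, and the test suite's
brute-force-vs-GA comparisons confirm convergence at this scale; the
full-scale setting of 10,000 generations remains one argument away.

## 7. Evaluation and mechanism clustering

Observed scores label a pair synergistic when positive; predictions are
thresholded at 0 as well — with both scores centred on additivity, zero
is the only principled cut. Reported metrics: Pearson r on the continuous
scores, ranking AUC (undefined with one class, reported as NA),
sensitivity, specificity and the confusion counts. Min–max rescaling to
[−1, 1] is provided for presentation and leaves Pearson r and AUC
unchanged (affine invariance; this is asserted in the tests).

Mechanism groups come from hierarchical clustering of selected-protein
PSS vectors under correlation distance (1 − r, range [0, 2]) with
**average linkage** — the customary partner of correlation distance;
the cut defaults follow the reported group structure of synergy screens
(5 groups for true positives, 3 for true negatives) but `k` is always
user-set, with no automatic selection. A zero-variance profile has no
defined correlation; its distance is set to the maximum (2) with a
warning. Group signatures are the proteins whose group-mean PSS exceeds a
configurable magnitude (default 0.1).

## 8. The synthetic-data module and the exact oracle

`generate_scenario()` produces every pipeline input with known ground
truth: a random weakly connected signed digraph (random chain plus extra
edges to the requested density, defaults: 10 nodes, density 0.18, 70%
activating edges, 25% of multi-activator nodes rewritten to AND logic to
emulate curated refinements); per-gene expression uniform on [0, max]
with gene-specific maxima; sparse GOF/LOF mutations (rate 0.08 per
cell-line × node); and a drug panel of 1–2-target drugs, 80% antagonist.
The reporter is the regulated node with the deepest upstream pathway, and
drugs target that pathway — mirroring a targeted-therapy screen, and
ensuring perturbations can propagate to the readout at all. Ground-truth
observed scores are computed from the hidden model, never hand-assigned:
a treatment's effect is 1 − reporter occupancy under full-dose clamps
(the reporter plays the proliferation-readout role), the pair's score is
the HSA statistic of those effects, plus Gaussian noise of configurable
SD (default 0.05, the scale of replicate variability relative to the
ground-truth signal SD of ~0.1–0.2 under these defaults).

The oracle, `exact_occupancy()`, builds the full uniform-asynchronous
transition matrix over the 2^n state space (n ≤ 12) and power-iterates
the initial distribution through the half-damped operator (I + P)/2 to
tolerance 1e-10. Damping removes periodicity while preserving absorbing
and stationary structure, so the limit equals the time-averaged occupancy
that the stochastic engine estimates — this is what makes the
ensemble-vs-oracle comparisons in the test suite exact rather than
approximate. Power iteration is used instead of eigen-decomposition
because it is robust for absorbing chains with several fixed points.

**What passing tests show — and what they do not.** The synthetic screen
exercises the full contract surface: logic compilation, clamping,
asynchronous dynamics, entropy detection, dose draws, PSS algebra, GA
recovery of planted signal, clustering recovery of planted blocks. It
does not emulate realistic TPM distributions, mutation signatures,
linkage between expression and mutations, or the biology of any specific
cell line; a high synthetic recovery rate therefore validates the
machinery, not the biological fidelity of any particular curated network.

## 9. Problem sizes and numerical details

The test suite and the acceptance script run at desk scale by choice:
oracle comparisons use 20 random 4–10-node models at 500 repeats × 2000
steps; the pipeline study uses a 10-node hidden model, 3 cell lines, 10
drugs, 25 pairs per line, 1000-step phases, 30 repeats per dose cell, and
a 300-generation GA. Full-scale settings (5000 steps, 100 unperturbed
repeats, 10,000 generations) are the documented defaults of the
corresponding functions.

Other numerical choices: entropy in bits (log₂); state identity for the
entropy bookkeeping is the full node vector including clamped nodes,
hashed as a byte string; quantiles use linear interpolation (type 7);
degenerate min–max ranges fall back to 0.5; seeds below 2³¹ throughout;
all delimited outputs are plain TSV with JSON manifest sidecars, so every
artifact is regenerable from its manifest.

## 10. Known limitations

* Only the uniform-asynchronous scheme is implemented; reaction
  time-scales (synthesis vs phosphorylation) are not modelled.
* No pharmacokinetics: dose-as-probability abstracts concentration into
  target occupancy at application time.
* Pairs only — the data model stops at two drugs per combination.
* The Loewe/ZIP/Bliss reference models are out of scope; all scoring is
  HSA-based.
* The GA fits on all supplied pairs; it performs selection, not
  cross-validated generalisation.
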