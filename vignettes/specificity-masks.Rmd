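---
title: "Evolving specificity masks: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving specificity masks: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Peptide specificity of a kinase domain — which substrate motifs it
phosphorylates — is encoded somewhere in its sequence, but the responsible
residues (determinants of specificity, DoS) are mostly unknown. SpecMask
searches for them with a learning classifier system over a domain alignment.

The central hypothesis object is a *specificity mask* `m`, one score in
[0, 1] per alignment column. A mask induces a similarity between two aligned
domains,

$$\mathrm{sim}_m(i,j) \;=\; \frac{\sum_p m_p\, s(x_{ip}, x_{jp})}{\sum_p m_p},$$

where $s(a,b)$ is the BLOSUM62 score min–max rescaled to [0, 1] over the
20×20 matrix (so W/W, the matrix maximum, maps to 1) and pairs involving a
gap contribute `gapSimilarity` (default 0). High-scoring mask columns
reinforce similarity; low-scoring columns silence it, and the ratio form
makes the similarity invariant to rescaling the mask by any positive
constant — only the *relative* weighting of columns matters.

A query kinase's PSSM is predicted from the experimentally profiled kinases
outside its own family (leave-family-out, so close homologs cannot trivially
leak the answer):

$$\hat P_q \;=\; \frac{\sum_j w_j^{\alpha} P_j}{\sum_j w_j^{\alpha}},
  \qquad w_j = \mathrm{sim}_m(q, j).$$

The exponent $\alpha$ sharpens the weighting: $\alpha = 0$ is the plain donor
mean, large $\alpha$ approaches nearest-neighbour prediction. `selectAlpha()`
reproduces the scan that selects $\alpha$ by converged fitness; 3 — the value
that wins on the kinase domain — is the package default.

A mask's *fitness* is the median over profiled kinases of the Frobenius
distance $\lVert \hat P_q - P_q\rVert_F$ between predicted and observed
PSSMs; the system evolves by minimisation. The median (not the mean) keeps a
few poorly predictable kinases from dominating the search.

### Assumptions

* The alignment is trusted: column correspondence is the coordinate system
  for everything, and no realignment is attempted.
* PSSM values are used exactly as loaded; profiles must share one position
  layout but may cover any subset of the alignment's records.
* Donor sets are defined by the family annotation; with
  `excludeSameFamily = TRUE` (default) a kinase in a singleton family still
  has donors, while a family covering *all* profiles would leave none (a
  hard error).

## The genetic algorithm

`evolve()` runs: random initial population (i.i.d. uniform [0, 1] entries);
fitness evaluation; elite copy-through; offspring by single-point cross-over
of two distinct elite parents and by per-position mutation (resampling
uniform [0, 1]). Parameters, with defaults:

| parameter | default | meaning |
|---|---|---|
| `populationSize` | 100 | masks per generation (kinome-campaign value) |
| `eliteFraction` | 0.2 | share copied unchanged; guarantees monotone best fitness |
| `mutationRate` | 0.02 | per-position resampling probability |
| `crossoverRate` | 0.5 | share of offspring from cross-over |
| `maxGenerations` | 2500 | ≈ generations-to-convergence on the human kinome |
| `convergenceWindow` | 250 | stop after this many stalled generations |
| `nRuns` | 10 | independent deployments for aggregation |

Elite fraction, mutation rate, cross-over share and the stall window are
standard GA practice values chosen here and exposed in the configuration:
the behaviour that matters (elitism, mutation, cross-over, population 100,
thousands of generations, ten deployments) is fixed, the operator constants
are tunable. "Convergence" is operationalised as `convergenceWindow`
generations without a best-fitness improvement greater than 1e-9.

Every run is a pure function of its inputs and seed: tie-breaks use stable,
index-based ordering, multi-run campaigns use seeds `seed + 0:(nRuns-1)`, and
fitnesses are memoised within a run (elites are never re-evaluated — a speed
contract only). `aggregateRuns()` averages the runs' final best masks per
column and reports a per-generation mean pairwise Frobenius dissimilarity
between runs' best masks, padding early-converged runs with their final mask.

## The synthetic kinome

`generateSyntheticKinome()` emulates the statistical structure the method
needs: families of related sequences whose specificity is a controlled
function of a few *planted* columns.

* Sequences: per-family random consensus, 10% per-site substitutions per
  kinase. Family structure matters — leave-family-out prediction only works
  if signal crosses family boundaries.
* Planted columns draw residues i.i.d. from a 4-letter alphabet (A, R, D, W)
  shared across families; the k-th planted column's residue adds +1
  preference for a residue-keyed amino acid at the k-th peptide position
  (one column drives one position, for clean identifiability at desk scale).
* Decoy `conservedColumns` are invariant kinome-wide but have no effect on
  profiles — they separate "important for specificity" from "conserved".
* Gaussian noise (sd `noiseSd`) is added to every PSSM entry.

The standard fixture `fixtureA()` uses 8 families × 4 kinases, L = 60, 3
planted columns, 6 decoys, 9 peptide positions, noise sd 0.05 (small against
the unit planted signal, as expected of averaged experimental profiles) and
seed 7. The test and acceptance campaigns run 3 deployments of 40 masks ×
300 generations on it — sizes chosen so a desk-scale machine reproduces the
behaviour of the kinome-scale campaign (recovery of all planted columns
ahead of every decoy) in seconds to minutes.

What the generator does **not** emulate: real kinome phylogeny, realistic
PSSM value distributions, alignment gaps, multi-column epistasis (each
planted column acts additively and independently), or partial profile
coverage. Passing tests therefore demonstrate the machinery's correctness
and its ability to recover planted signal under family structure and
conservation decoys — not performance on real kinomes.

Two control sets mirror the negative controls of the original study design:
`makeUniformControl()` (all profiles identical; every prediction is a convex
combination of identical matrices, so fitness is exactly 0 forever and there
is nothing to optimise) and `makeShuffledControl()` (profiles permuted
across kinases; the sequence–specificity linkage is destroyed and the
achievable fitness improvement collapses relative to the true set).

## Downstream analyses and numerical choices

* **Columns are 1-based everywhere**, in code and in files (file headers say
  so); thresholding with `callDoS()` is strict (`score > t`).
* **Subset correlation** compares, over all kinase pairs, subset-restricted
  BLOSUM62 similarity against specificity similarity defined as the
  *negative Frobenius distance* between PSSMs, by Spearman correlation with
  average-rank ties; a constant vector yields `NA` with a warning rather
  than a fabricated value.
* **Enrichment** uses the one-sided (greater) Fisher exact p — the
  hypergeometric tail — and reports the sample odds ratio `(ad)/(bc)`
  (which may be infinite when a margin is empty).
* **Conservation** is the negative Shannon entropy (bits) of the residue
  frequencies among non-gap symbols — the unweighted entropy measure of
  AL2CO-style conservation; gaps are not counted as a 21st symbol, and
  all-gap columns are missing. Set comparison uses a Wilcoxon rank-sum test
  with an *exact* null enumerated over all group assignments (average-rank
  ties) for combined n ≤ 20 — base R's exact path refuses ties, and the
  identical-sets case must give p = 1 — and a tie-corrected normal
  approximation with continuity correction above.
* **BLOSUM distance** between domains over a column subset is
  $\sum_p (s_{\max} - s(a,b))$ with gap pairs at the matrix minimum. It is a
  pseudo-distance: symmetric, non-negative, but triangle-inequality
  violations are permitted, and self-distance is zero only for residues
  attaining the matrix maximum. Trees are built by Saitou–Nei neighbor
  joining (exact on additive matrices); negative branch lengths are clamped
  to zero with a message.
* **Structure mapping** is all-atom by default (`caOnly` exposed), first
  model only, highest-occupancy altloc, hydrogens/waters/ligands excluded.
  Chain residues map to columns by ungapped index correspondence; a
  structure disagreeing with its alignment record in more than 5% of
  residues is skipped with a warning (length differences count toward the
  budget, compared over the common prefix).
* **Degenerate inputs**: an all-zero mask silences everything
  (similarity 0); if every donor weight is exactly 0 the prediction falls
  back to the unweighted donor mean, keeping fitness defined for
  pathological masks; `0^0` is taken as 1 so $\alpha = 0$ is the plain mean.

## Design decisions that were genuinely open

The per-column similarity functional form (rescaled BLOSUM62 vs identity)
and the donor-weight sharpening scheme (power $w^\alpha$) were open choices;
the implemented forms are scale-free, bounded, reproduce the qualitative
silencing/reinforcing behaviour and the nearest-neighbour limit at large
$\alpha$, and follow the NetMHC-style weighting tradition for pooling donor
matrices. Whether the mask-weighted sum is normalised by $\sum m_p$ or by L
is immaterial for the GA (scale invariance); the $\sum m_p$ form keeps the
similarity in [0, 1]. Aggregation uses the per-run best mask (not the whole
elite) — the elite is partially redundant with it and the mean of best masks
is the simplest consensus with the in-range guarantee.

## Limitations

* Real-data constants (Spearman 0.69 on 5.73% of columns, 82 columns above
  0.8, golden-list enrichment p = 8.4e-7) require the human kinome alignment
  and the full experimental PSSM collection, which are not bundled; the
  package reproduces the *properties* of the method on synthetic data, not
  those numbers.
* The GA explores a 60–600-dimensional continuous space with a modest
  population; different operator constants change convergence speed, though
  elitism guarantees monotone best fitness regardless.
* Profiles are treated as arbitrary finite matrices; no scale or
  normalisation is assumed or imposed.
* The exact Wilcoxon enumeration is quadratic-exponential in set sizes and
  is intentionally capped at combined n = 20.
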