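---
title: "Predicting conformational B-cell epitopes from mimotopes on a pruned antigen surface"
author: "mimoprune authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting conformational B-cell epitopes from mimotopes on a pruned antigen surface}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mimoprune)
```

## The problem

Most B-cell epitopes are conformational: the residues an antibody touches
are scattered along the antigen sequence and only come together on the
folded surface. Phage-display biopanning offers an indirect experimental
handle — short peptides (mimotopes) selected for binding the same antibody
mimic the epitope — and mimotope-based predictors map those peptides back
onto the antigen surface to localise the epitope. Patch-and-graph mapping
of this kind is sensitive but unspecific: the candidate patch carries many
bystander residues.

`mimoprune` implements a two-stage remedy. Stage one classifies every
solvent-exposed residue as "epitope-like" or not from six structural
propensity features, using an ensemble of random forests trained on
class-balanced subsamples, and deletes the "nonepitope" residues. Stage two
runs the patch-graph mimotope search on the pruned surface only: patches
shrink, bystanders disappear, and specificity rises at a small cost in
sensitivity (pruning occasionally discards a true epitope residue — on the
classic VEGF example one of nineteen).

## Definitions and stage one

**Surface.** A residue is a surface residue when the relative accessibility
(RSA) of its side chain exceeds 5% under a rolling-probe accessible surface
area (ASA) computation with a 1.4 Å probe. ASA is computed by the
Shrake–Rupley construction: each heavy atom is covered with a deterministic
Fibonacci lattice of sample points (default 960) on its probe-expanded
sphere, and the accessible fraction is the fraction of points inside no
neighbouring sphere. The point count is configurable; at 960 points
per-residue ASA is converged to better than 2% against a 4× denser lattice.
RSA normalises side-chain ASA by a per-amino-acid reference maximum. The
shipped reference table (`maxAsaReference()`) uses theoretical
Gly-X-Gly tripeptide whole-residue maxima with side-chain reference =
whole-residue maximum minus the glycine value (glycine, having no side
chain, keeps its whole-residue reference); any two-column TSV can replace
it. RSA computed this way can exceed 1 for unusually exposed groups; the
5% default threshold is unaffected.

**Epitope annotation.** Given the antigen–antibody complex, a residue is
annotated epitopic when its total ASA drops by more than 1 Å² once the
antibody chains enter the occlusion context (`annotateEpitope()`). The
4 Å heavy-atom contact definition is available as `mode = "contact"` but is
not the default. An annotated epitope residue that fails the surface filter
is kept in the evaluation universe, flagged, so sensitivity denominators
never silently lose true positives.

**Features.** Six per-residue features drive the classifier: residue
epitope propensity, conservation, side-chain energy, contact number,
surface planarity, and secondary-structure composition (helix/strand/coil
fractions, summing to one — eight scalar columns in total). Concrete
default definitions sit behind a provider interface so alternatives can be
swapped without touching the classifier:

* propensity and side-chain energy are per-amino-acid table lookups
  smoothed by averaging over spatial neighbours (Cα within 10 Å, self
  included). The shipped defaults are a hydrophilicity scale (propensity)
  and a hydropathy scale (energy surrogate), both editable TSVs; a
  log-odds propensity can be derived from any labelled table with
  `propensityFromTable()`. Whether the original feature set smoothed over
  neighbourhoods is not derivable from its description; the 10 Å smoothing
  radius matches the spatial scale of an epitope patch and the choice is
  recorded in the table provenance.
* conservation is Shannon-entropy conservation per alignment column
  rescaled to [0, 1]; without an alignment every residue scores a neutral
  0.5 and the table is flagged `conservation:fallback`.
* contact number counts Cα neighbours strictly within 10 Å; planarity is
  the RMSD of neighbourhood Cα coordinates from their least-squares plane;
  secondary structure is assigned from backbone dihedrals (helix
  φ ∈ [−120°, −30°], ψ ∈ [−80°, −5°]; strand φ ≤ −90° with extended ψ;
  else coil), or taken from a user-supplied per-residue assignment.

All features are rigid-motion invariant (tested to 1e-6).

**Balanced ensemble.** Real training data run about eight nonepitope
residues per epitope residue. Rather than weighting, the classifier
re-balances: `balancedSubsets()` draws n subsets (default 10), each holding
every positive row plus an equal-size without-replacement sample of
negatives; `trainEnsemble()` fits one random forest per subset (5 trees,
features-per-split = ⌊log2(M)+1⌋ for M features — the "automatic" setting
of the originating toolkit; seed 1). `classifySurface()` keeps a residue
when at least half the member forests vote "epitope"; a split vote keeps
the residue, because a wrongly pruned epitope residue is unrecoverable
downstream while a wrongly kept one merely survives to the patch search.
The ensemble size n is not derivable from the method description; 10 is a
standard bagging scale and is configurable. Models serialise to a portable
JSON tree-by-tree descriptor (`writeEnsembleJSON()`) whose restored
predictions are bit-identical to the in-memory forests.

## Stage two: patch graphs and mimotope alignment

**Patches.** One patch per surface residue: the centre plus all surface
residues with Cα within 12 Å (`makePatches()`). Patches overlap by
construction; Euclidean seeding is used rather than geodesic surface
distance for determinism (a documented extension point).

**Adaptive distance threshold.** Each patch's residue graph connects pairs
at Cα distance ≤ ADT, where the ADT is the smallest value on a 4–9 Å grid
(0.5 Å steps) that yields a connected graph whose compactness factor — edge
density relative to the complete graph, CF = |E| / C(m, 2) — reaches the
target (default 0.35). Sparse patches therefore get larger thresholds,
compact patches prune spurious edges. If no grid value meets the target the
largest-threshold connected graph is returned flagged `cf unmet`; if even
the largest threshold leaves the patch disconnected, the component
containing the centre is kept, with a warning. The numeric CF target used
by the original implementation is not published; 0.35 spans typical
residue-contact densities and is exposed in the configuration.

**Alignment.** A mimotope is aligned to a patch by finding the simple path
that maximises the summed substitution score of peptide positions against
path residues, with up to `maxSkips` positions (default 2) skippable at the
gap penalty (default −4 with BLOSUM62; the matrix is swappable, including
NCBI-format files). The search is a depth-first enumeration over
(skip-set, path) pairs — complete by construction — with two exact
accelerations: a greedy seed alignment provides an incumbent, and a
branch-and-bound cut discards partial solutions whose optimistic completion
(suffix sums of per-position best gains) cannot beat it. Neither changes
the optimum; the node-expansion counter is exposed and property-tested
against exhaustive enumeration. When the peptide cannot be placed in full
(longer than any simple path plus allowed skips), the best
shorter-coverage alignment is returned flagged incomplete.

**Scores to P-values.** Raw path scores of different lengths are not
comparable, so each patch is calibrated: `calibrateEVD()` aligns
`nSamples` random peptides (uniform composition; default 1000,
xorshift-seeded in compiled code so the draw is platform-independent) of
each observed length and fits a Gumbel law by moments
(β = s·√6/π, μ = m − γβ). The P-value of a score is
1 − exp(−exp(−(s−μ)/β)), clamped to [1e-300, 1]. A patch's score is the
Fisher-style Σ −ln P over its best complete alignments, which makes
mixed-length mimotope libraries commensurable. Patches with no complete
alignment are dropped; if none remain the method reports "no prediction"
(the honest failure mode for epitopes it cannot map). Ranking ties break
toward the larger patch, then residue-id order.

A caveat the tests quantify rather than hide: the true null of
best-alignment scores is a maximum over correlated, integer-valued path
sums, and the Gumbel family only approximates it. Where the null really is
Gumbel the fitted P-values are exactly uniform (Kolmogorov–Smirnov
verified); on graph nulls the continuity-corrected P-value distribution
deviates from uniform by up to ~0.1 in sup norm. The transform is monotone,
so patch *ranking* is unaffected; the absolute P-values should be read as
calibrated scores, not frequentist tail probabilities.

**Prediction.** By default every residue of the highest-scoring patch is
the predicted epitope (`mode = "patch"`; published per-case prediction
sizes, ~30–40 residues, are patch-scale). `mode = "paths"` restricts to the
union of best-alignment paths for precision-oriented use. Peptides are
aligned in the given orientation; reverse-orientation search is off by
default.

## Evaluation

`confusionCounts()` counts TP/FP/FN over the antigen surface universe and
defines TN as the remainder, so TP+FP+TN+FN equals the surface size.
`epitopeMetrics()` derives sensitivity, specificity, precision (PPV),
accuracy, F-measure and the Matthews correlation coefficient. Two MCC
denominators are implemented: the standard
√((TP+FP)(TP+FN)(TN+FP)(TN+FN)), and a "paper" variant with (TP+TN) in
place of (TP+FN), which is the form the published benchmark table of this
method family was computed with — the variant reproduces the printed VEGF
value (0.19) while the standard form does not, and both are exposed rather
than silently reconciled. Zero denominators yield flagged zeros. Display
rounding is half-up to two decimals; full precision is always carried
alongside. Published per-case results of the method on its 18-complex
benchmark ship as a plain-text table (`benchmarkScores()`), of which only
the internally consistent aggregates are asserted in tests (the printed
sensitivity average of that table does not equal its column mean; the F
and PPV averages do).

## The synthetic study system

Because real antigen–antibody complexes and biopanning panels cannot ship
with the package, `syntheticAntigen()` builds toy antigens: an ideal
backbone (N, Cα, C placed by standard bond geometry from φ/ψ — pure helix,
pure strand, or a mixed "blob") with one pseudo-side-chain atom per residue
1.53 Å along the outward normal, a uniform random sequence, and a planted
epitope: the k surface residues nearest a random anchor.
`syntheticMimotopes()` emulates biopanning output by reading amino acids
along random simple paths in the planted epitope's adjacency graph and
applying a fixed number of random substitutions. `syntheticLabelledTable()`
draws labelled feature rows from two normal populations at the 8:1
imbalance of the real training data, with a configurable mean shift.

What these fixtures do and do not show: they exercise the full geometric
and statistical pipeline (ASA, features, imbalance handling, patch
graphs, alignment, ranking, metrics) under a known ground truth, so a
passing suite demonstrates the machinery recovers planted signal at
realistic noise. They are not folded proteins: side chains are single
pseudo-atoms, sequences are random, and the feature–label association in
end-to-end runs is learned from the case itself. Performance numbers on
synthetic cases therefore validate correctness and calibration, not
expected accuracy on real complexes.

Study sizes used by the test suite and acceptance script (chosen to keep
the full run in minutes on one CPU while leaving every statistical check
well-powered): 20 seeded replicates of 40–80-residue antigens with
8–12-residue epitopes and 10 noisy mimotopes for the end-to-end recovery
study (observed mean winning-patch coverage ≈ 0.85, threshold 0.8); 100+
random graphs of ≤8 vertices for the exhaustive-oracle comparison; 10⁵
samples for Gumbel parameter recovery (±0.05); 200 extreme-value
calibration samples per patch in end-to-end runs and 1000 in the
single-patch statistical checks (the calibration invariant requires
≥100).

## Numerical choices and degenerate inputs

* Coincident atoms in the ASA computation count their shared surface once
  (later duplicates score zero).
* Alternate locations: highest occupancy wins, first on ties; hydrogens,
  waters and hetero records are dropped; NMR model 1 only. Author
  numbering with insertion codes is preserved verbatim, so published
  residue lists (`parseResidueList()`, both "I80" and "80V" dialects)
  address residues directly.
* Residues lacking a Cα use their side-chain centroid, flagged;
  neighbourhoods of fewer than three residues get planarity 0, flagged;
  missing backbone atoms assign coil, flagged.
* A zero-variance calibration sample floors β at 1e-6 and flags the null
  degenerate. Empty surfaces, empty rankings and all-pruned antigens all
  flow to an explicit "no prediction" result; metrics with empty
  denominators are flagged zeros.
* Every stochastic step (subsampling, forests, calibration, generators)
  is seed-determined; pipeline runs emit a manifest with the resolved
  configuration and input hashes, and identical seeds reproduce outputs
  bit-identically.

## Known limitations

The six feature definitions are faithful to their published *names* but
necessarily re-specified in detail; absolute feature values will differ
from the original implementations. The Gumbel calibration is an
approximation (see above). Patch seeding is Euclidean, not geodesic, so
patches can bridge across thin clefts. mmCIF input, multi-model ensemble
averaging, hydrogen placement, antibody docking, and benchmarking against
external prediction servers are out of scope.

## A minimal session

```{r example, eval = FALSE}
case <- syntheticAntigen(nResidues = 60, epitopeSize = 10, seed = 1)
mims <- syntheticMimotopes(case, count = 10, length = 6, noise = 1,
                           seed = 2)
feats <- buildFeatureTable(case$surface)
labelled <- data.frame(feats,
                       label = as.integer(rownames(feats) %in%
                                            case$epitope))
model <- trainEnsemble(labelled, n = 10, trees = 5, seed = 1)
res <- runPipeline(case$structure, mimotopes = mims, model = model,
                   truth = case$epitope)
res$status
res$evaluation$rounded
```
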