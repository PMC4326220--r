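# mimoprune

Conformational B-cell epitope prediction from an antigen 3D structure and a
phage-display mimotope set, by antigen-surface pruning followed by
patch-graph mimotope alignment.

## Who this is for

Most B-cell epitopes are discontinuous: the antibody-contacted residues are
scattered along the sequence and assemble only on the folded antigen
surface. Mimotope-based predictors localise such epitopes by mapping short
antibody-selected peptides (mimotopes, from phage-display biopanning) back
onto the antigen surface. Plain patch-graph mapping is sensitive but drags
in bystander residues; `mimoprune` adds a structure-based preprocessing
stage that removes surface residues an ensemble classifier calls
"nonepitope" before the mimotope search runs, improving specificity and
precision. The package is for structural immunologists and method
developers who have an antigen structure (PDB) and a mimotope panel and
want a candidate epitope residue set, plus the standard residue-level
evaluation metrics when a co-crystal ground truth exists.

## The method

**Stage one — antigen processing.** Surface residues (side-chain relative
accessibility > 5%, rolling-probe ASA with a 1.4 Å probe) are described by
six features: residue epitope propensity, conservation, side-chain energy,
contact number, surface planarity, and secondary-structure composition.
Training data are ~8:1 imbalanced (nonepitope : epitope), so the classifier
is an ensemble of *n* random forests (defaults *n* = 10, 5 trees each,
⌊log₂ M + 1⌋ features per split, seed 1), each trained on all positives
plus an equal-size random draw of negatives; a surface residue survives
when at least half the forests vote "epitope" (ties keep). Voted
"nonepitope" residues are deleted from the surface.

**Stage two — mimotope analysis.** The pruned surface is divided into
overlapping patches (one per residue, 12 Å Cα radius). Each patch becomes
an undirected residue graph whose edges join Cα pairs within an adaptive
distance threshold (ADT) — the smallest 4–9 Å grid value giving a connected
graph whose compactness factor CF = |E|/C(m,2) reaches the target (0.35).
Every mimotope is aligned to every patch graph by a complete simple-path
search (depth-first over skip-set/path pairs, ≤2 skipped positions at gap
penalty −4, BLOSUM62 by default) accelerated by exact branch-and-bound.
Raw scores become P-values under a per-patch Gumbel null fitted by moments
to random-peptide score samples, and each patch is scored Σ −ln P over its
best complete alignments. The residues of the highest-scoring patch are
the predicted epitope; if no patch aligns anything, the method reports "no
prediction".

**Evaluation.** Over the antigen-surface universe (TP+FP+TN+FN = surface
size): sensitivity, specificity, PPV, accuracy, F-measure, and MCC in both
the standard form and the published table's variant denominator.

## Worked example

A self-contained run on a synthetic antigen with a planted epitope:

```r
library(mimoprune)

case  <- syntheticAntigen(nResidues = 60, epitopeSize = 10, seed = 1)
mims  <- syntheticMimotopes(case, count = 10, length = 6, noise = 1, seed = 2)
feats <- buildFeatureTable(case$surface)
labelled <- data.frame(feats,
                       label = as.integer(rownames(feats) %in% case$epitope))
model <- trainEnsemble(labelled, n = 10, trees = 5, seed = 1)

res <- runPipeline(case$structure, mimotopes = mims, model = model,
                   truth = case$epitope)
#> stage input: 60 antigen residues, 10 mimotopes
#> stage surface: 60 surface residues
#> pruning removed 41 of 60 surface residues
#> stage patches: 19 patch graphs
#> stage predict: prediction made (11 residues)

res$prediction
#> EpitopePrediction (mode patch): 11 residues, winning patch A:35 (score 40.734)
res$evaluation$rounded
#>   sen  spe  ppv  mcc  acc    f mcc_variant
#> 1   1 0.98 0.91 0.94 0.98 0.95    standard
```

The pruning stage removed 41 of 60 surface residues; the winning patch of
the mimotope search contains all 10 planted epitope residues plus one
bystander, giving sensitivity 1.00 and precision 0.91 over the 60-residue
surface universe.

The published vascular endothelial growth factor example ships as a
fixture: intersecting its 32-residue prediction list with its 19-residue
epitope list gives TP = 13, FP = 19, FN = 6, hence sensitivity 0.68,
precision 0.41 and F = 0.51 at two decimals:

```r
wx <- vegfWorkedExample()
surface <- paste0("W:", sort(union(1:69, union(wx$predicted$resno,
                                               wx$epitope$resno))))
counts <- confusionCounts(paste0("W:", wx$predicted$resno),
                          paste0("W:", wx$epitope$resno), surface)
counts
#> tp fp tn fn
#> 13 19 49  6
epitopeMetrics(counts)[, c("sen", "ppv", "f")]
#>         sen     ppv         f
#> 1 0.6842105 0.40625 0.5098039
```

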