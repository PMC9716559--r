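#!/usr/bin/env Rscript
# Regenerates the classifier shipped in inst/extdata/default_classifier.json:
# the reference configuration — default synthetic labelled dataset (seed 1),
# group-aware balanced 80:20 split, 200-iteration random search, seed 1.
# Run from the repository root after any change to the synthetic generator,
# the metrics or the training pipeline.

library(registercheck)

ds <- generateLabelledDataset(nChains = 40L, seed = 1L)
sp <- makeBalancedSplit(ds, seed = 1L, byGroup = TRUE)
clf <- trainErrorClassifier(sp$train, nIter = 200L, seed = 1L)

auc <- aucScore(scoreResidues(clf, sp$test@features), sp$test@labels)
message(sprintf("held-out AUC of the shipped classifier: %.4f", auc))

writeClassifier(clf, file.path("inst", "extdata",
                               "default_classifier.json"))
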