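---
title: "Validating protein models against predicted inter-residue distances"
author: "registercheck"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating protein models against predicted inter-residue distances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(registercheck)
```

## The problem

A sequence-register error is a stretch of a protein model in which the
backbone has been traced correctly through the density but the sequence is
assigned offset by k positions. Such errors are common in models built
into cryo-EM maps at modest resolution, are hard to spot by eye, and are
invisible to most geometry-based validation. Deep-learning structure
predictors emit, for every residue pair, a probability distribution over
binned inter-residue distances (a *distogram*). Because these
distributions are keyed to the *sequence*, a register error produces a
characteristic, localisable disagreement between the distances observed in
the model and the distances predicted for the sequence: the geometry
observed at position i matches the prediction for position i + k.

`registercheck` exploits this in two complementary ways:

1. a per-residue **error classifier**: 24 covariance-based validation
   metrics are computed per residue, a pruned subset is combined with
   solvent accessibility and secondary structure into 11 features, and a
   Platt-calibrated linear SVM converts them into a probability that the
   residue lies within a modelling error;
2. a **contact-map-overlap (CMO) alignment**: the observed contact map is
   aligned against the predicted one under a monotone gapped alignment
   that maximises the matched contacts; a run of residues whose optimal
   alignment needs a constant nonzero offset is reported as a register
   error, with the offset register proposed as the fix. Three filters
   (predicted-contact density, pLDDT, superposition Q-score) guard against
   false positives.

## Inputs and conventions

* Residues are represented by one atom: C-beta, C-alpha for glycine (and
  for residues with a missing C-beta, with a warning).
* Two residues are in contact when their representative atoms are within
  8 Å. All contact work uses a minimum sequence separation of 5 —
  trivial near-diagonal pairs would otherwise dominate every list; the
  value is the standard choice in contact-prediction evaluation and is
  configurable everywhere.
* Residue indexing is 1-based against the reference sequence throughout;
  unmodelled reference positions are carried along explicitly and masked
  out of every metric denominator.
* Distograms are exchanged in a small JSON/TSV dialect (`loadDistogram`).
  The bin layout is free; the synthetic generator uses 2–22 Å in 0.5 Å
  steps plus an open-ended final bin, a common distogram binning. The
  predicted distance of a pair is the midpoint of its highest-probability
  bin (ties to the lower bin) and the confidence is that bin's mass. The
  open-ended bin has no midpoint; it is assigned its lower edge plus half
  the previous bin width, and pairs whose argmax lands there are treated
  as "predicted far" — they carry no usable distance estimate and are
  excluded from wRMSD, which would otherwise be dominated by the truncated
  representation of genuinely distant pairs even in a perfect model.

## The 24 validation metrics

For residue i with partner universe U(i) (all j with |i − j| ≥ 5, both
residues modelled):

* **wRMSD**: `sqrt( sum_j w_ij (x_ij − x̂_ij)^2 / sum_j w_ij )`, with x
  the observed and x̂ the predicted distance and w the prediction
  confidence. Normalising by the summed confidence (rather than the
  partner count) makes the metric invariant to rescaling the confidences
  and reduces to a plain RMSD when all w = 1; the count-normalised variant
  is available via `normalize = "n"`.
* Seven contact metrics over the top-L/2 predicted contact list versus
  the observed map: Accuracy, Precision, Sensitivity, Specificity, FP
  rate, and the raw FN and FP counts. Zero denominators give 0 with a
  flag, never NaN — the classifier needs finite features.
* Each of those 8 metrics also has a **smoothed** variant (five-point
  unweighted moving average, window shrinking at the chain ends so no
  residue is lost) and a **spatial Z-score** variant (standardised against
  all residues within 10 Å, population SD; zero-variance neighbourhoods
  give 0). Z-scores are computed from the unsmoothed values, treating the
  smoothed and Z-scored families as parallel transformations of the same
  base metrics. Flagged values are excluded from window means and
  neighbourhood samples.

That yields 24 columns. On a reference dataset the pairwise Pearson
correlations of these metrics are strongly structured; `correlationPrune`
groups columns by the transitive closure of |r| ≥ 0.4 and keeps one
representative per group, chosen by the largest absolute linear-discriminant
coefficient against the labels. The shipped feature set is fixed to the
seven survivors of that analysis — Accuracy, FP rate, smoothed
Sensitivity, smoothed wRMSD, Z-score Accuracy, Z-score Sensitivity and
Z-score wRMSD — plus relative solvent accessibility and a three-class
secondary-structure one-hot (11 features); pruning is shipped as a
reusable utility, not rerun at inference.

## Classifier training

Positives (residues within modelling errors) are split 80:20; an equal
number of negatives is sampled into each side, so both sides are exactly
balanced — 2428 positives give the 3884/972 train/test arithmetic. By
default in the synthetic experiments the split is *group-aware*: all
positives from one chain go to the same side, since residues of one error
are highly redundant and residue-level splitting overstates accuracy.

Features are standardised with a scaler fitted on the training rows only.
Hyperparameters of the linear SVM are found by a seeded 200-iteration
random search — C log-uniform in 1e-3..1e2, class weights balanced or
none — scored by 5-fold cross-validated mean accuracy. The C range stops
at 1e2: on standardised features the CV accuracy of a linear SVM is flat
well below that, while SMO solve times grow roughly linearly in C and
make the upper decades pure waste. Cross-validation fits use an SMO
tolerance of 0.01; the final model is fitted at the default 1e-3.
Decision values collected from the cross-validation folds of the winning
configuration feed a Platt sigmoid, so scores are calibrated
probabilities; thresholding them is meaningful.

Error calls are maximal runs of consecutive residues with score at or
above a threshold. The defaults — at least 6 consecutive residues at
score ≥ 0.9 — trade precision against recall; lowering either flag yields
more, less reliable calls, and recall is monotone non-increasing in the
run-length threshold by construction.

## Contact-map-overlap alignment

Exact CMO is NP-hard, so `alignContactMaps` uses iterated double dynamic
programming: an inner DP scores each residue pair (i, j) by the best
monotone matching of their contact-neighbourhood offset profiles (offset
agreement weighted by a Gaussian kernel, width 1.5 residues); an outer
affine-gap DP (gap open −3, extension −0.1 in matched-contact units,
terminal gaps free) turns the similarity matrix into a monotone residue
alignment; refinement rounds rebuild the similarity from the contacts the
current alignment makes consistent. Two initialisations are run — the
neighbour-profile similarity and, for equal-length maps, a near-diagonal
band suited to register errors — and the best mapping seen in any round
(by matched weight plus gap penalties) is kept. For maps of at most 10
residues the heuristic is replaced by an exact depth-first search, so
small-map results are the true optimum; `bruteForceCMO` provides an
independent enumeration oracle for testing.

A matched contact contributes `min(w_model, w_pred)`; observed maps have
unit weights and predicted maps carry contact probabilities.

**Which predicted map feeds the alignment?** The classifier metrics use
the standard top-L/2 contact list. The alignment instead consumes every
predicted contact with probability ≥ 0.5 (`thresholdContacts`). At
modest L the top-L/2 cap leaves so many confident contacts out that
alignments shifted by one secondary-structure repeat become spuriously
competitive and register identifiability collapses; the binarised map
restores it. The contact-density filter keeps its top-L/2 basis, matching
its published threshold.

Register-shift calls are maximal runs of aligned pairs with constant
nonzero offset. Each run is first trimmed to its *matched-contact
support*: a residue at a run edge that participates in no matched contact
carries no evidence for the alternative register (its placement is an
artefact of where the DP placed a gap), so it is not reported. Runs of at
least 5 residues survive; same-shift calls within 5 residues of each
other are merged.

## False-positive filters

1. **Contact density**: fail if the mean or the median number of top-L/2
   predicted contacts per residue over the call range is below 2 — too
   little information for a reliable alignment.
2. **pLDDT**: fail if the predictor's mean confidence over the range is
   below 65; skipped with a warning when no pLDDT is available.
3. **Q-score**: the model and the predicted model are superposed
   (Kabsch, proper rotation enforced) on their shared positions outside
   the suspect range, and
   `Q = nAlign^2 / ((1 + (rmsd/3)^2) · n1 · n2)` is evaluated over the
   range; fail below 0.5. Within the range, model residue i is paired
   with predicted residue i + shift — the correspondence the proposed
   register implies. Under plain same-index pairing every *genuine*
   register error would score rmsd ≈ 3.3·k Å and fail, inverting the
   filter's purpose; under proposed-register pairing a genuine shift
   superposes cleanly while a prediction in a different conformation
   still fails. Q = 0.5 corresponds exactly to a fully aligned range at
   rmsd 3 Å and is a pass (the rule discards only calls *below* 0.5).

Filters annotate calls; they never delete them from the report.

## The synthetic test-bed

`makeToyFold` builds self-avoiding representative-atom traces from
parametric secondary-structure segments joined by short turns, with
residue identities drawn uniformly and pLDDT set to 90:

* `helix_bundle`: antiparallel ideal helices (2.3 Å radius, 1.5 Å rise,
  100°/residue) at 9 Å axis spacing;
* `sheet_coil_mix`: one tightly packed antiparallel sheet unit of four
  strands at the chain edge, followed by a helical periphery at 11 Å
  spacing. The interface spacings widen outwards (4.5/4.7/6.6 Å), so the
  most confident predicted contacts concentrate in the unit, as they do
  in the packed core of a real fold. Each strand carries its own small
  random rise, tilt and offset, and turns within the sheet are 5-residue
  arcs. Both choices are identifiability-critical: an exactly periodic
  sheet has a contact map invariant under shifts of one repeat, which no
  real fold has, and turn-adjacent strand pairings must stay above the
  minimum sequence separation to keep the unit's register determined out
  to its ends.

`simulateDistogram` places a discretised Gaussian (SD = `sharpness`, in
Å) on each pair's true distance; with probability `noise` a pair's centre
is displaced by ≥ 4 Å, emulating a confidently wrong prediction. Defaults
(sharpness 1 Å, noise 0.1 for the labelled dataset; noise 0 for clean
controls) were fixed once as a plausible stand-in for a modern
predictor's behaviour on a well-predicted chain.

`injectRegisterShift` moves *coordinates*, not sequence letters: residues
[start, end] take the coordinates of residues [start + k, end + k], so
downstream code sees exactly a register error's signature. The k residues
flanking the segment whose true positions are consumed by the shift
become unmodelled — one physical backbone cannot occupy them twice, and
register-shifted models genuinely lack a compressed stretch near the
error. Labels are 1 inside the segment, 0 outside.

`generateLabelledDataset` (40 chains of length 100 by default, both
topologies) injects 0–2 segments per chain with lengths 6–40 and shifts
1–5 in either direction, covering both the detectable (long) and the hard
(short) regime; the resulting class balance is about 3–4 negatives per
positive.

`registerShiftTrial` defines one register-recovery experiment: a
mixed-sheet fold, a sharp distogram, and a shift injected over a whole
strand block bounded in the flanking turns, required to have at least 2
top-L/2 predicted contacts per residue and contact support reaching the
shifted window's ends to within two residues. Segments violating those
conditions are exactly the cases no contact-based method can localise
(the information is not in the data), mirroring the observation that
short or contact-poor register errors go undetected. Candidate folds are
drawn deterministically from the trial seed until one admits a qualifying
segment.

## What the tests show — and what they do not

The suite verifies, among others: metric formulas against hand-evaluated
and brute-force oracles; the aligner against exhaustive CMO enumeration
(never above, equal on ≥ 95% of random small instances); recovery of
injected shifts k = 1..5 with exact k and endpoints within ±2 in ≥ 95/100
trials; held-out AUC ≥ 0.9 of the reference classifier (dataset seed 1)
with a wRMSD-family feature ranked first by permutation importance; zero
calls on 50 clean chains at default thresholds; and exact flips of all
three filters at their thresholds. Problem sizes (L = 100, 40 training
chains, 100 trials, 50 clean controls) were chosen as the smallest at
which the pipeline's behaviour is stable and the suite stays quick.

Synthetic folds are far cleaner than real structures: perfect geometry up
to small jitter, no side chains, no missing density except what the
corruption model introduces, and distogram errors that are independent
across pairs, where a real predictor's errors are strongly correlated.
Passing these tests therefore demonstrates internal correctness and the
method's behaviour under its own assumptions — not performance on real
cryo-EM deposits. Held-out AUC also varies by a few hundredths with the
split, because the test side contains few chains.

## Known limitations

* Single chain per run; inter-chain contacts are invisible to the
  validation even though they constrain real models.
* The geometric secondary-structure fallback is crude (virtual dihedral
  windows); supply a DSSP file when one is available. The fallback
  accessibility is a monotone neighbour-count proxy, not an area.
* Contact-only mode (CASP-RR input) supports the contact metrics and the
  CMO analysis but not wRMSD.
* The proposed register fix is reported, never applied to coordinates.
* The shipped classifier is trained on the synthetic dataset; for real
  deposits, retraining on curated real errors is expected to shift both
  calibration and ranking.
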