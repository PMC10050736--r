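---
title: "Decoding detector output into RUS-CHN bone age: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding detector output into RUS-CHN bone age: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(kbsage)
```

## The problem

The RUS-CHN variant of the TW-style maturity methods assesses bone age
from 13 key bones of a left-hand radiograph. Each bone is staged on an
ordinal developmental scale starting at grade 0 (ossification centre not
yet visible) and ending at a bone-specific ceiling; each (bone, grade,
sex) triple carries a maturity score; the 13 scores are summed and the
total is converted to bone age through a sex-specific standard curve.

A detection-based automation of this procedure trains an object detector
whose target classes are the (bone, grade) pairs themselves. The detector
is then responsible for *where* and *what stage* simultaneously, and the
remaining work — the subject of this package — is symbolic: turn a bag of
scored candidate boxes into exactly one grade and box per key bone, then
into a bone age, and quantify how well each stage performs.

## The class schema

`build_class_catalog()` enumerates bones in a fixed canonical order
(radius, ulna, then metacarpals and phalanges of rays 1/3/5) with grades
ascending within each bone, yielding 163 classes under the standard
ranges. Two conventions deserve comment:

* **Grade 0 is a detectable class.** An absent ossification centre is a
  stage, not an absence of annotation; without it the class count would
  not reach 163.
* **The class-id order is a package convention.** Decoding works purely
  on the `bone_grade` label string, so any detector class ordering is
  compatible; the catalog fixes one order only so that serialized
  catalogs are byte-stable.

## Key Bone Search

Raw detector output for one image typically contains several candidates
per bone — neighbouring grades, duplicated boxes, low-confidence noise.
The decoder does two things:

1. **Confidence suppression.** Candidates with confidence below a
   threshold are dropped before any decoding. The comparison is
   `>=` (keep-at-boundary) so that threshold 0.0 is a true no-op.
2. **Per-bone argmax.** Each surviving label is split into (bone, grade);
   for each of the 13 bones the candidate with maximum confidence wins
   and contributes its grade, confidence and box. Bones with no survivor
   are reported in an explicit `missing` list, never imputed.

The output therefore always partitions the 13 bones between `findings`
and `missing` — the invariant every downstream stage relies on. Contrast
with per-class NMS (`nms_decode()`), under which two different grades of
the same bone survive as separate classes ("repeat") while aggressive
thresholds can silence a bone entirely ("lack"); `threshold_sweep()`
totals both failure modes over an image set on the standard grid
0.0, 0.1, …, 0.5.

**Tie-breaking.** Confidence ties are resolved toward the lower grade,
then the larger box area. Any fixed rule would do; this one makes the
decoder deterministic and invariant to input record order, which the
property tests assert by permutation.

**Operating threshold.** The default is 0.1: high enough to discard the
bulk of noise candidates cheaply, low enough that fully covered images
lose nothing. The sweep exists precisely to let users re-derive this
point on their own detector's output.

**NMS dialect.** The baseline is class-aware greedy NMS at IoU 0.5, the
standard detector convention; a class-agnostic variant would conflate
neighbouring grades and no longer exhibit the repeat phenomenon the
baseline exists to demonstrate.

## From grades to bone age

*Scheme 1* is the tabular method: per-sex score-table lookup, sum,
standard-curve query. The curve query is piecewise-linear interpolation
between knots with clamping beyond the first/last knot — a total score
slightly above the table maximum should read the maximum age, not
extrapolate. Missing bones abort scoring with an explicit error: the
decoder's job is to make sure nothing is missing, and silently imputing a
stage would bias the total score.

*Schemes 2 and 3* replace table + curve with a gradient-boosted
regression on the raw 13-grade vector, fitted separately per sex (the
tabular method is sex-specific everywhere, so the regression is too;
this also sidesteps encoding sex as a feature). Scheme 2 trains on
expert-rated grades, scheme 3 on decoder-inferred grades; the fitting
code is identical. The implementation uses xgboost histogram trees with
loss-guided (leaf-wise) growth, so the familiar boosting knobs keep
their conventional names and meanings: `num_leaves` (default 31),
`max_depth` (6), `learning_rate` (0.1) and `stopping_rounds` (300,
early-stop patience on the validation RMSE). A small search hook
(`search =` a list of candidate parameter lists) picks the candidate
with the lowest validation MAE; no searched values are baked in.

## The synthetic benchmark

Real radiographs, expert gradings and trained detector weights are all
private to clinical sites, so the package carries a seeded generative
model (`sim_config()`, `simulate_cases()`, `simulate_detector_output()`)
of the *statistical structure* the pipeline assumes. Defaults describe a
450-image evaluation split with balanced sexes and ages uniform over the
assessable range (under 18 years for males, under 17 for females).

**Grades.** The expected grade of bone $b$ at age $a$ is a linear ramp
rounded to the ordinal scale,
$g_b(a) = \mathrm{round}(G_b \cdot a / A_{\max} + \phi_b)$ clipped to
$[0, G_b]$, with $G_b$ the ceiling and $A_{\max}$ the sex's maximum age.
Linearity is chosen for analyzability — any monotone map would serve.
The small fixed per-bone phases $|\phi_b| < 0.5$ stagger the ages at
which different bones step to their next grade; without them all bones
sharing a ceiling would step simultaneously and the total-score step
function would be needlessly coarse. The phases leave the anchors intact:
grade 0 exactly at age 0, the ceiling exactly at $A_{\max}$. Truth
grades optionally deviate by ±1 with probability `truth_grade_jitter`
(default 0.05), emulating biological spread around the age trend.

**Boxes.** Thirteen disjoint rectangles on a schematic hand layout
(distal phalanges at the top, radius/ulna at the wrist) under a common
per-image affine jitter. The layout is deliberately schematic, not
anatomically calibrated — IoU statistics exercise the evaluation code,
not radiological realism.

**Detector noise.** Per (image, bone): with probability `1 − drop_rate`
a primary candidate whose grade is correct with probability
`1 − p_confuse` (default 0.1) and otherwise a neighbouring grade (offset
up to `max_grade_offset`, never equal to the truth after clipping — so
the configured confusion rate is exactly the per-bone error rate, which
the recovery tests exploit); box corners jittered by `box_jitter_sd`
(default 3%) of the box size; confidence drawn from a high-mode
Beta(8, 2). Plus Poisson(`spurious_rate`) extra candidates with low-mode
Beta(2, 8) confidences. The two confidence modes overlap just enough
that raising the suppression threshold past ≈0.3 begins to lose real
bones — reproducing qualitatively the lack-count pattern that motivates
the 0.1 operating point.

**What passing tests do and do not show.** The simulator validates the
*logic* of decoding, scoring and evaluation under a known generative
model. It does not render pixels, model inter-device image quality,
inter-rater grading disagreement, age-dependent detector difficulty, or
correlated multi-bone failures; agreement here says nothing about
accuracy on clinical radiographs.

## The synthetic reference tables

The China-05 score tables and standard curves are copyrighted and
unpublished, so `make_toy_reference()` builds stand-ins with the right
structure: scores $s_b(g) = w_b \, g$, strictly increasing in grade with
grade 0 scoring 0, radius and ulna weighted above the short bones and
sex-specific weights; curves built by inverting the simulator's own
grade ramp — for every attainable total score, one knot at the mean age
attaining it, with the end knots pinned to age 0 and the sex's maximum
age so the all-ceiling score maps exactly to 18 (male) / 17 (female)
years. Because grades quantize age, Scheme 1 on noise-free input carries
an irreducible interpolation error of roughly a quarter of the mean
grade-step spacing (about 0.05 years here); the zero-noise end-to-end
test bounds exactly this quantity. The shipped CSVs under `inst/extdata/`
are generated by this function and are labelled synthetic; they must not
be used to produce clinical bone ages.

## Evaluation conventions

* Boxes are corner-format continuous pixel coordinates; area carries no
  `+1`. IoU of disjoint boxes is 0.
* Grade confusion matrices match predictions to truth **by bone
  identity**, not box overlap — KBS guarantees at most one finding per
  bone, and this mirrors per-bone clinical reporting. Missing bones are
  excluded from a bone's statistics and counted, never scored as 0.
* Weighted precision is support-weighted one-vs-rest precision; grades
  predicted but absent from truth contribute through false positives
  only.
* mAP@0.5 uses all-point interpolation and greedy confidence-ranked
  matching with each truth box matched at most once, macro-averaged over
  classes with at least one truth instance.
* RMSPE is undefined at true age 0 and raises an explicit error; in
  stratified tables such strata report `NA` with a note. Age bands are
  half-open $[k, k+1)$ years.
* CLAHE uses clip limit 2.0 on an 8×8 tile grid; constant images pass
  through unchanged (nothing to equalize). Resizing stretches to a
  square (640 or 416 presets) rather than letterboxing — synthetic box
  coordinates are generated in the target frame, so aspect handling is a
  user-side concern for real images.

## Problem sizes and determinism

The test-suite and acceptance-script runs use 450-image simulated splits
(the size of a 10% evaluation split of a ~4,500-image dataset), 2,000
training cases for the regression consistency check, and 1,000 random
decoder instances across 10 seeds for the argmax-oracle equivalence.
Every stochastic step is seeded; the whole chain — simulation, decoding,
scoring, evaluation — is a pure function of (configuration, seed), which
the determinism tests assert byte-for-byte.

## Known limitations

* The shipped score tables and curves are synthetic; clinical use
  requires the licensed China-05 tables supplied as config files.
* The detector adapter is the interchange-file loader; wiring a live
  exported model is left to the user behind the same candidate-list
  interface.
* The simulator's grade noise is independent across bones and symmetric
  near the truth; real detector confusions are grade-asymmetric and
  correlated within an image.
* DICOM handling is out of scope; images enter as grayscale arrays/PNG.
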