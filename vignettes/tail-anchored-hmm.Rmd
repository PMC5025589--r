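---
title: "Region-structured HMMs for tail-anchored protein prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-structured HMMs for tail-anchored protein prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tailanchor)
```

## The problem

Tail-anchored (TA) proteins are membrane proteins with a single
transmembrane domain (TMD) close to the C-terminus and no N-terminal signal
sequence. Because the TMD emerges from the ribosome only after translation
terminates, TA proteins are inserted post-translationally (the GET/TRC40
pathway) and cannot be recognised by the signal recognition particle.
Predicting them from sequence alone is harder than generic TMD prediction:
the decisive features are the *position* of the TMD (within ~30 residues of
the C-terminus), the short hydrophilic tail after it, and the *absence* of
an N-terminal signal peptide.

`tailanchor` classifies a protein by comparing its likelihood under three
region-structured hidden Markov models:

* a **TA model**, read from the C-terminus, with regions tail → TMD → cap →
  globular;
* an **SP model** (single-pass with signal peptide), read N-to-C, with
  regions signal peptide → globular(1) → cap → TMD → globular(2);
* an **MP model** (multi-pass with signal peptide), like the SP model but
  with a loop region after the TMD that can re-enter the cap, producing any
  number of membrane passes.

Non-membrane (NO) proteins have no model of their own; they are scored
against the TA and MP models.

## Model architecture

Each region is a chain of discrete states over the 20-letter amino-acid
alphabet. Region grammar is enforced by *structural zeros* — transitions
absent from the diagrams are absent from the parameter matrices and stay
absent through training:

* **TMD**: 25 states; the first 14 advance deterministically, states 15–25
  may exit. Every membrane-spanning run therefore has 15–25 residues, by
  construction, in every model.
* **tail** (TA model): 2 or 4 states, each with self, advance, and
  enter-TMD transitions. The initial distribution puts 0.5 on the tail
  start and 0.5 on the TMD start, so a protein may have no decoded tail at
  all.
* **cap**: up to 5 basic-biased states flanking the TMD (thought to anchor
  the helix via lipid interactions).
* **signal peptide** (SP/MP): a 40-state chain — 10 basic-biased, 15
  hydrophobic-biased, 15 polar-biased states — with exits allowed from
  state 15 on, so decoded signals span 15–40 residues.
* **loop** (MP): a 20-state hydrophilic chain; each state may advance,
  re-enter the cap (next membrane pass), or exit to the globular state,
  with equal initial probability.
* **globular**: single self-looping hydrophilic states.

Untrained emission rows place 70 % of their mass uniformly on the region's
favoured residue class (hydrophobic `A C F I L M V W` for the TMD, basic
`K R H` for cap and signal N-block, the remaining nine hydrophilic letters
elsewhere) and 30 % on the rest. The 70/30 split is a symmetry-breaking
starting point for training, not a claim about real compositions; training
re-estimates every row. Where the published description of the SP-model TMD
is internally inconsistent (a forced prefix of 15 would make a 15-residue
TMD impossible), we use the same first-14-forced structure as the TA model,
which realises the stated 15–25 range.

## Algorithms

All dynamic programming runs in log space with log–sum–exp, in a small C++
kernel; sequences of at least 5,000 residues run without underflow (a test
compares the log-space forward value against a scaled-arithmetic
implementation). The models have no end state: the forward likelihood sums,
and Viterbi maximises, over all states at the last position. Viterbi ties
break toward the lowest state index, so decodings are deterministic across
platforms.

Training is Baum–Welch with a pseudocount of 1e-6 added at every M-step to
all emission cells and to structurally allowed transition/initial cells
only. A state whose total expected occupancy in an iteration is below one
observation keeps its previous rows instead of collapsing to the
near-uniform pseudocount distribution; because retaining a parameter block
cannot lower the EM Q-function, monotonicity of the log-likelihood trace is
preserved (asserted in every test fit). Defaults: relative tolerance 1e-6,
at most 100 iterations.

Ambiguous residues (`B Z X U O J`) are emitted with probability 1/20 in
every state of every model, so they contribute identically to all
likelihoods and can never decide a classification; they are excluded from
emission counts during training.

## Scores and decision rules

For a sequence of length $L$, with $\ln l_{ta}$ computed on the reversed
sequence (the TA model reads C-to-N) and taking the maximum over the
2- and 4-state tail variants:

$$S_{sp} = \frac{\ln l_{ta} - \ln l_{sp}}{L}, \qquad
  S_{mp} = \frac{\ln l_{ta} - \ln l_{mp}}{L}$$

Positive scores favour the TA model; dividing by $L$ removes the linear
growth of log-likelihood magnitudes with length. "Likelihood" defaults to
the Viterbi joint log-probability, since the likelihoods are obtained by
decoding; a switch (`likelihood = "forward"`) selects the all-paths forward
probability instead. The published description states the score difference
in both orientations in different sentences; we adopt TA-minus-competitor
(positive = TA-like), which is the mirror image of the other convention
with a flipped threshold and yields identical classifications.

Three decision rules:

* **decoding rule** — accept if the Viterbi segmentation under the
  2-tail-state TA model has a TMD segment of ≥ 15 residues and a
  C-terminal tail segment of ≤ 30 residues (a missing tail counts as
  length 0; failure reasons distinguish *all-tail*, *no-TMD* and
  *tail-too-long*). This rule has no threshold.
* **score rule** — accept if the score is at least a threshold fitted by
  minimising the balanced error rate, BER = (FNR + FPR)/2, over candidate
  thresholds at midpoints between adjacent distinct pooled scores (±∞
  sentinels; ties toward the smallest candidate; `score ≥ threshold` is
  positive so boundary cases are deterministic).
* **combined rule** — the conjunction of the two, so combined positives
  are always a subset of each single rule's positives and combined
  specificity can only be at least either single rule's.

For evaluation against the non-membrane set or pooled negatives, the MP
score and MP-fitted threshold are used, as those sets have no model of
their own. Cross-validated scoring follows the published protocol: a
sequence's likelihood under its *own* class's model comes from a fold model
that never saw it (folds by canonical id sort, seeded shuffle, round-robin,
so results are independent of input order), while likelihoods under the
other models come from full-data fits.

Coordinates are 0-based half-open internally; the command-line output uses
1-based inclusive positions. A decoded run occupying reversed positions
$[s, e)$ of a length-$L$ sequence maps back to $[L-e,\, L-s)$.

## The synthetic-data generators

There is no public curated TA corpus shipped with this package, so training
and evaluation use labelled synthetic data from generative HMMs with known
region annotations (`make_generator()`, `generate_dataset()`). Design
choices, each made once:

* **Lengths**: log-normal, median 250 residues (TA proteins are most
  abundant in the 200–300 range), `sdlog` 0.45 so the truncation range
  50–1000 sits at roughly ±3 standard deviations.
* **Dwell times** (generators only; predictive models always start from
  equal transitions): TA tail self-transition 0.8 (mean tail ≈ 8; real TA
  tails are mostly ≤ 10 residues), SP globular(1) self-transition 0.99
  (long ectodomains — about 12 % of SP records end up with a TMD within 30
  residues of the C-terminus, matching the ~15 % of structurally TA-like
  hard negatives in the real single-pass set), MP globular self-transition
  0.95 (inter-pass soluble segments ≈ 20 residues).
* **TMD lengths** follow the empirically observed distribution (mode
  17–18, shoulder at 21, range 15–25) via per-state exit hazards, rather
  than the geometric law equal exits would give; without this the deep TMD
  states receive almost no training data.
* **Difficulty** is the separation of class emission profiles. At
  `difficulty = 1` every region places 0.9 of its mass on its favoured
  class, and the soluble regions additionally carry compartment-specific
  hydrophilic sub-profiles: cytosolic (TA tail/globular) mass mainly on
  `N Q S T Y`, secretory-pathway (SP/MP soluble regions and the NO class)
  mainly on `D E G P`. Lower difficulty interpolates all rows linearly
  toward uniform; at 0 the classes are indistinguishable.
* **Admissibility**: records are resampled until they show their class's
  defining architecture (TA: one complete TMD ending within 30 residues of
  the C-terminus followed by a 1–30-residue tail; SP: signal plus one TMD;
  MP: signal plus ≥ 2 complete TMDs; NO: no TMD), i.e. the generator is the
  topology HMM conditioned on class-defining events.

What the generators deliberately do **not** emulate: annotation noise,
homology between records, real compositional subtlety (the
compartment-specific profiles exaggerate weak real-world biases to the
point of near-full separability), or the curated datasets' size imbalance.
Consequently, passing the end-to-end separability test at difficulty 1.0
(combined sensitivity and specificity ≥ 0.95 on held-out records)
demonstrates that the pipeline is correct and self-consistent — it does
*not* predict performance on real proteomes, where the effective difficulty
is far lower. The structural decoding weakness is visible even here: on
synthetic data the decode rule alone accepts many multi-pass records whose
last TMD lies near the C-terminus, and it is the score rule that removes
them, reproducing the qualitative pattern of the published combined-rule
results (specificity rises, sensitivity can fall).

## Numerical and procedural choices

* Thresholds, tie-breaks and rounding: BER threshold ties toward the
  smallest candidate; Viterbi ties toward the lowest state index; reported
  metrics round to 3 decimal places (round-half-even); AUC uses the
  Mann–Whitney ½-credit convention for tied scores and equals the
  trapezoidal area under the stepwise ROC (a two-oracle identity asserted
  on random instances).
* Degenerate inputs: empty sequences and empty datasets are validation
  errors; hand-made zero emissions that make every path impossible raise a
  distinct "no admissible path" error; training sets in which every
  sequence is shorter than the model's forced chains trigger a
  "model longer than data" warning but still converge.
* Serialization: model bundles are JSON with linear-space probabilities at
  17 significant digits, giving bit-exact round-trips; bundles with a
  different topology-version string or a missing model entry are refused.
* Problem sizes used by the shipped experiments (chosen to make the full
  suite a few minutes of desk-scale computation): brute-force oracle
  equivalence is exhaustive for ≤ 3 states × length ≤ 7; structural
  run-length guarantees are checked over 500 random decodes per model;
  parameter recovery trains on 500 generator samples (the TMD-region mean
  hydrophobic emission mass is recovered within 0.05 of the generator's
  0.9); the end-to-end experiment trains on 30 records per class
  (Baum–Welch, tolerance 1e-4, ≤ 15 iterations) and evaluates on 125
  held-out records.

## Known limitations

* The exact initial emission tables of the original system are in
  supplementary material not available here; the 70/30 initialisation is a
  documented stand-in, and training re-estimates all values.
* Two printed specificity cells of the published decoding-results table are
  inconsistent with their own TP/FP/FN/TN counts; the package reproduces
  the tables' arithmetic from the counts and the formula block, which
  matches every count-consistent printed value to 3 decimal places.
* Real-data performance (the published AUC ≈ 0.96 on curated UniProt
  datasets) is out of scope: those datasets are not redistributable, and
  the synthetic world is easier than real proteomes by construction.
* Emissions are untied across states within a region; the original
  description never mentions tying, and untied states are what allow the
  TMD length distribution to be learned.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
train <- list(ta = dataset_sequences(generate_dataset("TA", 30, seed = 1001)),
              sp = dataset_sequences(generate_dataset("SP", 30, seed = 1002)),
              mp = dataset_sequences(generate_dataset("MP", 30, seed = 1003)))
bundle <- train_models(train$ta, train$sp, train$mp,
                       max_iter = 15, tol = 1e-4)

# fit the BER-optimal score thresholds on the training scores
s <- function(set) do.call(rbind, lapply(set, likelihood_scores, bundle = bundle))
th_mp <- select_threshold(s(train$ta)$S_mp, s(train$mp)$S_mp)$threshold

# classify a held-out record
rec <- generate_dataset("TA", 1, seed = 42)[[1]]
classify(bundle, rec$sequence, mode = "combined", negative_context = "mp",
         threshold_mp = th_mp, id = rec$id)
```
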