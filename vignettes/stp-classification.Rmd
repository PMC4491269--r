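---
title: "Classifying sequential tri-disulfide peptides from primary sequence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying sequential tri-disulfide peptides from primary sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stpsvm)
```

## The problem

Sequential tri-disulfide peptides (STPs) — knottins/inhibitor cystine
knots, cyclotides and non-knotted scorpion-toxin-like peptides — are small
toxins stabilized by three disulfides whose six cysteines pair
sequentially: C1–C4, C2–C5, C3–C6. The pairing produces an unusually
compact, protease- and pH-resistant fold, which is why this class keeps
producing insecticidal, antimicrobial and therapeutic leads. The same
class is, however, nearly invisible to similarity search: members share
the fold, not the sequence. `stpsvm` classifies chains as STP or non-STP
using only features of cysteine geometry and coarse composition, so that
it generalizes across the sequence diversity of the class.

## The motif grammar

All structure lives in the *cysteine loops* ∆C(i,i+1): the number of
residues strictly between consecutive cysteines (adjacent cysteines have
loop 0; positions are 1-based). The grammar applies, in order:

1. **Cardinality.** Fewer than six cysteines: no motif.
2. **Minimum-loop rule.** If the smallest loop anywhere in the chain
   exceeds 3 residues, the chain lacks the tight turn characteristic of
   the sequential fold and is discarded.
3. **Anchoring.** One six-cysteine window is chosen so that the
   minimum-loop pair plays the C3–C4 role (the pair at the centre of the
   sequential array). If fewer than two cysteines lie downstream of the
   pair, its role shifts upward — C4–C5 with one downstream cysteine,
   C5–C6 with none — drawing correspondingly more upstream cysteines.
   In a chain with exactly six cysteines the window is the whole chain
   and roles are positional. A chain whose minimum pair lacks the
   required upstream cysteines cannot be anchored and is discarded.
4. **Positional discard.** If the anchored window's own minimum loop lies
   between C1–C2 or C2–C3 the motif is disregarded: N-terminal CXXC/CXC
   spacings are the fingerprint of ferredoxin-, rubredoxin- and other
   iron–sulfur electron-transport proteins, the main source of false
   motifs among small cysteine-rich chains.

Ties for a minimum loop always resolve to the most N-terminal pair. Both
the tie-break and the treatment of >6-cysteine chains (exactly one
anchored window, centred on the global minimum pair) are design choices:
the prose description of the motif admits a per-window reading of the
minimum-loop search, but the global reading adopted here is the one
consistent with a single feature vector per chain, and the test-suite
oracle implements the same reading so that the equivalence check is
meaningful. Where the upward-shift rule cannot apply (a minimum pair too
close to the N-terminus of a >6-cysteine chain), the chain is treated as
unanchorable rather than silently re-centred; for six-cysteine chains the
question does not arise because there is only one window, and the
positional discard then handles N-terminal minima.

Invalidity is always a *value* (`valid = FALSE` plus a reject reason),
never an exception — downstream features depend on it.

## Features

For a valid anchored window the *proximity lengths*
P₁ = ∆C(1,4), P₂ = ∆C(2,5), P₃ = ∆C(3,6) count the residues spanned
between the cysteines that would bond in the sequential array. Invalid
motifs are assigned P₁ = P₂ = P₃ = 0, and the zeros flow through the same
normalization as real values:

$$\mathrm{NP}_j = \frac{100}{\lvert P_j - \bar{x}P_j\rvert + 10}, \qquad j \in \{1,2,3\}$$

where $\bar{x}P_j$ is the mean of $P_j$ over the *valid* positive
training chains. NP is bounded in (0, 10], peaks at 10 exactly when the
observed proximity matches the training mean, and decreases strictly in
the deviation. Keeping the single formula path for invalid motifs (rather
than special-casing them) means rejected chains land at
$100/(\bar{x}P_j + 10)$ — typically 3–4 — which is itself an informative
signal for the classifier.

The remaining components: the least-loop-length ratio
min ∆C / chain length (0 for invalid motifs); a 0/1 flag for at least one
residue in each of the last two loops C4–C5 and C5–C6 (knotted STPs
always have them); and residue frequencies (count / chain length) for
C, S, H, K, L. Frequencies are fractions, not counts, so chains from
9 to 160 residues are comparable.

Feature sets 1–5 are nested subsets kept for model comparison (set 1 =
frequencies only, 2 = NP only, 3 = NP + freq C, 4 = NP + ratio + flag,
5 = set 4 + freq C); only **set 6** — all motif features plus the five
frequencies — is the canonical default, and the others are explicitly
non-canonical configurations of this package.

## Classifier and evaluation

Features are standardized (training mean/sd; constant columns are left
unscaled) and fed to a C-classification SVM with an RBF kernel
(`e1071`, the libsvm backend). Defaults are γ = 0.1 and C = 0.1; a tuned
kernel width of 0.0587 is exposed as the constant `STP_TUNED_GAMMA` but
never applied silently, because tuning should be a visible choice. The
decision rule is the sign of the margin — no probability calibration.
The normalization constants $\bar{x}P_j$ and the scaling statistics are
persisted inside the model artifact (a plain-text R expression with exact
hexadecimal numerics), so a reloaded model featurizes and scores new
sequences bit-identically.

`stp_evaluate()` implements two protocols:

* **Repeated random subsampling** (default): each iteration draws 100
  positives and 300 negatives *without replacement* for training and
  scores the complement (44/93 under the default class sizes). Draws are
  independent across iterations. Both per-iteration means ± sd and
  pooled-confusion-matrix metrics are reported, because either
  aggregation is defensible and they differ at small test sizes.
* **Stratified k-fold CV** (default k = 10): every chain is scored
  exactly once; the pooled matrix is reported.

Metrics are computed from the printed 2×2 formulas; any zero denominator
yields `NaN` with a warning, never a silent zero. ROC curves sweep the
unique decision values with tied scores grouped into one step, and AUC is
the trapezoidal area. With a fixed seed the entire train/evaluate path is
reproducible.

The normalization constants are refitted from the sampled training
positives of each iteration (not fixed once from the full positive set):
this keeps every iteration a faithful end-to-end fit with no information
leaking from held-out chains into $\bar{x}P_j$.

## The synthetic generator

`simulate_positives()` emits chains whose geometry matches the study
conditions the classifier family was developed under: lengths drawn from
Normal(42.2, 15.7) clipped to 23–143 residues; exactly six cysteines; the
minimum loop (0–3 residues) at C3–C4 with every other loop strictly
longer (1–7 residues longer), so both C-terminal loops are populated;
flanks of non-cysteine residues drawn uniformly. `simulate_negatives()`
mirrors the negative class (lengths Normal(63.2, 25.9) clipped to 9–160)
as a mixture of three structured failure modes: ferredoxin-like decoys
whose shortest loop sits at the first pair near the N-terminus (30 % by
default), six-cysteine chains with all loops longer than 3 (40 % of the
remainder), and random peptides with 0–6 unconstrained cysteines (the
remaining 60 %), with a deterministic redraw in the rare case a
random chain satisfies the grammar by chance. `hard = TRUE` instead emits
negatives that *pass* the grammar but with loops 8–20 residues longer
than the minimum, pushing their proximity lengths far above the positive
means so that only the NP/ratio features can separate them.

What the generator emulates is cysteine geometry and class sizes
(144/393) only. Background composition is uniform over the 19
non-cysteine residues; real STPs have biased composition, real negatives
contain homology structure, and real positives include chains whose
motifs fail the grammar (the published positive set itself contains such
chains — visible in its sub-100 % training sensitivity). Passing the
synthetic end-to-end check therefore demonstrates that the pipeline is
wired correctly and that the features carry the intended signal, not that
these operating characteristics transfer to real collections. On the
default conditions the motif-validity bit alone separates the classes,
so near-perfect held-out metrics are the *expected* outcome; the
hard-mode negatives give an intermediate operating point that
specifically exercises the proximity features.

## Numerical and design notes

* Coordinates are 1-based everywhere a user sees them; loops count
  residues strictly *between* cysteines, and the same convention feeds
  P_j, so the model is self-consistent.
* Ambiguity codes X/B/Z/U/O are accepted and treated as ordinary
  non-cysteine residues; only cysteine identity matters to the grammar.
* The redundancy filter (`dedup_by_identity()`) is a greedy scan in input
  order over global Needleman–Wunsch identity (match 1 / mismatch 0 /
  linear gap −1; identity = matches / alignment length). It is a
  deterministic stand-in for word-based clustering tools, documented as
  *not* reproducing their cluster definitions.
* Problem sizes in the test-suite: the grammar is checked against an
  independently written brute-force oracle on 10,000 random chains
  (length 20–160, 0–12 cysteines), metric formulas against brute-force
  recomputation on 1,000 random confusion matrices, and the full
  200-iteration protocol runs on the default 144/393 conditions — a few
  seconds each on a single core.
* Known limitations: no probability outputs; no multi-window reporting
  for chains with several plausible motifs; the SVM hyperparameters are
  taken as given rather than re-tuned; and the published training chains
  are not redistributed here, so the package's shipped defaults are
  validated on synthetic conditions rather than on the original corpus.
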