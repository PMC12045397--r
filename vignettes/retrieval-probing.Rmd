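---
title: "Probing in-context retrieval in masked sequence models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probing in-context retrieval in masked sequence models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maskprobe)
library(dplyr)
```

## The problem

Masked language models trained on protein or RNA sequences are widely used to
score sequence plausibility: mask each residue in turn, ask the model for the
probability of the true residue, and summarise the result as a
*pseudo-perplexity*

$$\mathrm{PPL}(S) = \exp\Big(-\tfrac{1}{|S|}\sum_{i \in S} \ln p_i(x_i)\Big),$$

where $p_i(\cdot)$ is the model's predictive distribution at position $i$ and
$x_i$ the true residue. A value of 1 means complete certainty; for a model
that falls back on a uniform prior over a $k$-letter alphabet the value is
$k$. These scores correlate with experimental fitness — which is exactly why
a failure mode matters: transformer-based masked models can *look up* the
identity of a masked residue from another copy of the same motif elsewhere in
the input. This in-context retrieval drives the pseudo-perplexity of repeated
sequences toward 1 regardless of whether the sequence makes any biological
sense, decoupling the score from fitness. The same machinery turns out to be
tolerant of mutations between the copies, to operate across long intervening
stretches, to work from alternating-position matches without any contiguous
identical chunk, and — in RNA models — to recognize the reverse-complement
(hairpin) relationship while ignoring plain reversals or complements.

This package implements the full probing methodology for detecting and
characterizing that behaviour: seeded generators for every sequence
construction involved, the scoring measures, eight probe pipelines that emit
tidy result tables, and an embedding-information regression. All probes run
against any model that satisfies a three-function contract
(`predict_masked()`, `predict_unmasked_profile()`, `embed_sequence()`), and
the package ships a configurable *mock retrieval model* that reproduces the
qualitative retrieval regimes deterministically, so the entire pipeline is
testable without model downloads.

## The mock retrieval model

`mock_model()` makes the hypothesised retrieval mechanism explicit. For a
queried position $i$ it scans candidate source positions $j \ne i$ with
$|j - i| \le$ `memory_limit` and scores, for each allowed transform, the
fraction of agreeing residues between the window of half-width $w$
(`window_halfwidth`) around $i$ and the (transformed) window around $j$.
Comparisons never involve the queried position itself — on either side of the
comparison — and never involve masked positions; the source residue must be
unmasked. Candidates reaching `match_threshold` are ordered by score, then
absolute offset, then source position, then transform (identity before
reverse complement).

Predictions mix a point mass on the retrieved symbol with the model's prior
$\pi$:

* **collapse** mode: $p = (1-\varepsilon)\,\delta_{\hat x} +
  \varepsilon\,\pi$ with $\varepsilon = 1 - \lambda$
  (`retrieval_strength` $\lambda$), winner-take-all on the best candidate;
* **progressive** mode: with $m$ candidates supporting the retrieved symbol,
  the retrieved weight is $1 - (1-\lambda)^m$, so confidence accumulates with
  the number of supporting copies. At $m = 1$ the two modes coincide.

With no admissible candidate the prediction *is* the prior, exactly. Three
consequences are worth spelling out because the probes rely on them:

* **Single-pass equals one-at-a-time.** Because matching windows exclude the
  query position on both sides, masking only position $i$ changes nothing the
  scan can see. The unmasked single-pass profile therefore equals the
  one-at-a-time masked profile *exactly* on the mock — a free regression test
  for the fast scoring path, checked in the test suite.
* **Masking the source restores the prior.** If the equivalent position of
  the second copy is masked too, the only supporting candidate loses its
  source and the prediction falls back to the prior; a mask anywhere else in
  the second copy is simply ignored by the window comparison.
* **Left-context evaluation comes for free.** Masking $\{i, \dots, L\}$ and
  querying $i$ restricts matching to the preceding context, which is how
  `autoregressive_perplexity()` evaluates the left-to-right perplexity
  $\exp(-\tfrac1L \sum_i \ln p(x_i \mid x_{<i}))$ on the mock.

### Minimum window evidence

Windows are clipped at sequence ends, and a clipped window with one or two
valid comparisons can reach a perfect score by chance — over the 4-letter RNA
alphabet a single chance agreement has probability 1/4, and mirrored
constructions (a sequence next to its reverse complement) even duplicate the
same comparison on both sides of a degenerate window. Candidates therefore
need at least `min_comparisons` valid pairs (default: the window half-width)
before their score counts. Every intended retrieval in the probes retains at
least that much evidence even at sequence ends, while one-pair flukes are
rejected.

### Choosing the window for the alphabet

The default half-width of 3 (six comparisons) suits the 20-letter protein
alphabet, where a chance agreement has probability 1/20 and a six-of-six
chance match is vanishingly rare. Over the RNA alphabet chance agreement is
1/4 per residue, so `rna_context_mock()` widens the window to half-width 5.
Even so, occasional chance matches remain possible in principle; they
slightly *raise* measured perplexity above the prior level (a wrong retrieval
is worse than no retrieval), which is why non-collapsing RNA contexts sit
near — not exactly at — the prior perplexity of 4.

## The probes

Every probe is a pure function of its configuration and seed, emits a tidy
tibble with `model` and `seed` columns, covers its full parameter grid, and
has an `autoplot()` method. Closed-form expectations under the mock are
asserted in the test suite; the headline phenomena are:

* `probe_doubling()` — appending a copy of a random sequence to itself drops
  the one-at-a-time pseudo-perplexity from the prior level ($k = 20$) to
  $1/(\lambda + \varepsilon/k) \approx 1.05$ at the default
  $\lambda = 0.95$.
* `probe_multiplicity()` — a grid over repeating-unit sizes and copy numbers.
  With a finite `memory_limit` the collapse is gated by the unit offset
  (units of 20 and 70 collapse inside an 85-residue memory, units of 100 do
  not); in progressive mode the perplexity declines strictly with
  multiplicity following $1-(1-\lambda)^{m-1}$.
* `probe_equivalent_mask()` — the uncertainty (entropy) at a masked position
  returns to the prior $\ln 20$ only when the *equivalent* position of the
  second copy is also masked; a non-equivalent second mask leaves the
  collapse intact.
* `probe_flip_profile()` — substituting the equivalent position to each of
  the 20 amino acids in turn drags the prediction along: the averaged
  20×20 profile matrix is diagonal-dominated with diagonal entries
  $\lambda + (1-\lambda)\pi_a$.
* `probe_contralateral()` — a doubled unit whose second copy offers two
  adjacent inserted residues at the equivalent locus. For interior masks the
  mock is symmetric (neither insert reaches the threshold; preference is
  exactly 0 with a uniform prior). At the extreme ends, window clipping
  leaves only the insert on the far side aligned with the visible window, so
  the mock itself prefers the right insert at the left end and vice versa —
  the contra-lateral sign pattern arises from the geometry of one-sided
  context, consistent with retrieval siding with the longer contiguous
  repeat. Swapping the inserted symbols leaves the positional preference
  invariant, which is the same statement as the fixed-symbol readout
  changing sign.
* `probe_imperfect_repeat()` — local single-pass pseudo-perplexity of a
  mutated copy, alone versus concatenated after its original (see the
  parameter derivation below).
* `probe_needle_sweep()` — two identical needles flanking an unrelated
  haystack; the local pseudo-perplexity of the *first* needle maps the
  operational memory: cells with needle-to-needle offset (needle + haystack
  length) within `memory_limit` collapse, cells beyond stay at the prior.
* `probe_skip()` — one-skip pairs match at alternating positions only. With
  a tolerant threshold (0.45 at window half-width 2, where every aligned
  window agrees at about half its residues) the mock retrieves the
  equivalent residue at every position; the correct-residue profile then
  spikes exactly at the agreement positions. Under strict matching
  (threshold 1) the pair behaves like the unrelated-halves control,
  separating alignment-like matching from exact-substring matching.
* `probe_rna_context()` — a random RNA segment scored under five appended
  contexts. With transforms `{identity, reverse_complement}`, the repeat and
  the hairpin-like reverse complement collapse; the complement, the plain
  reversal and the random context do not. Restricting the transforms to
  `{identity}` removes the hairpin collapse, emulating a model that has not
  acquired that skill.

### Why the imperfect-repeat probe uses a moderate retrieval strength

At substitution rate $r$, a window around a position of the mutated copy
agrees with the original at an expected fraction $1 - r$ of residues, so a
threshold of 0.45 admits matches at $r = 0.5$. But for the *substituted*
positions themselves the retrieved residue is the original one — the wrong
answer — and a winner-take-all retrieval then scores
$p(x_i) = \varepsilon \pi_{x_i}$. At the doubling-probe default
$\lambda = 0.95$ the penalty $-\ln(\varepsilon/20) \approx 6.0$ at wrong
retrievals almost exactly cancels the gain at right retrievals
($-\ln 0.9525 \approx 0.05$ versus the prior's $\ln 20 \approx 3.0$), and the
paired comparison washes out. Retrieval from half-matching context should
shift the prior, not annihilate it: `imperfect_repeat_mock()` therefore uses
$\lambda = 0.5$, for which a retrieved position contributes
$\tfrac12(-\ln 0.525) + \tfrac12(-\ln 0.025) \approx 2.17 < 3.0$ on average,
and a window half-width of 4 (eight comparisons), which stabilises the
agreement estimate at the lenient threshold and keeps chance matches rare
over the protein alphabet. With roughly 60% of positions retrieving, the
expected per-position log-score margin is about 0.5 nats; at sequence length
100 the paired difference is positive in essentially every sequence at
$r = 0.5$, while at $r = 1$ substitutions agree only by chance (1/19), no
window passes the threshold systematically, and the paired difference is
centred at zero. At $r = 0$ the probe reduces to the doubling experiment at
this model's moderate strength: local PPL $= 1/(0.5 + 0.025) \approx 1.90$.

## Scoring conventions

Natural logarithms throughout; perplexities are $\ge 1$ and entropies live in
$[0, \ln k]$ nats. A zero probability on a true residue propagates as `Inf`
with a warning — never clipped — and downstream summaries use medians and
quantiles, not means. The first sequence position can be excluded from score
sets (`exclude_first`) to sidestep the initiator-methionine bias of natural
protein sequences; the exclusion is off by default because the package's
built-in inputs are synthetic, and the setting is an explicit argument so it
is visible at every call site. Coordinates are 1-based closed intervals, the
convention of the R/Bioconductor ecosystem the package lives in; the
equivalent position of $i$ in the second copy of a length-$L$ unit is
$i + L$ in either convention, and the one-skip construction pins its
agreement set to the odd (first, third, ...) positions.

## The embedding-information regression

Masked models are mostly consumed through their residue-level embeddings, so
the package also measures what repetition does to embedding information
content. The task: predict a sequence's one-at-a-time masked profile from
per-position input vectors, with the cross-entropy
$H(t, p) = -\sum_a t_a \ln p_a$ as the loss; predicting the target itself
scores the target's own entropy, the achievable floor. Input groups share
identical targets (the 1x profile), so any loss difference is attributable to
the inputs:

* `one_hot` — residue identity only, the information-free-context baseline;
* `1x` — embeddings of the sequence itself;
* `2x` … `5x` — embeddings of the *first* unit of the tandem-repeated
  sequence;
* `control_2x` … `control_5x` — embeddings of the sequence prefix after
  padding with random residues to the matched total length.

The readout is a single-hidden-layer softmax network (hidden width 4× the
input dimension, ReLU, full-batch Adam), fixed across groups; one readout per
group per run, five runs by default, an 80–20 split whose indices are shared
by all groups within a run (a paired design, with the validation indices
logged in the returned object). There is no early stopping: the full
per-epoch validation curve is the reported quantity, which is also why the
readout is implemented in-package with plain matrix operations rather than
delegated to a fitting routine that only returns a converged model.

Two design points deserve emphasis. First, the 1x sequences are generated by
`internal_repeat_sequence()`: a random half followed by a
substitution-mutated copy (rate 0.3). On a retrieval-capable model such
sequences have *context-dependent* one-at-a-time profiles — positions
retrieve across the internal imperfect repeat — whereas plain random
sequences would have the flat prior as their profile everywhere and every
input group would trivially reach the floor. Second, the degradation
mechanism is concrete in the mock: tandem-repeating the sequence gives every
first-unit position a perfect-scoring match in the exact copy, which
displaces the informative internal partner as best candidate; the retrieved
block of the embedding then merely duplicates the own-symbol block. The
length-matched controls keep their internal matches (losing only positions
whose windows spill into the padding), so the observed ordering — 1x below
control below multiplicity below one-hot — is the package's acceptance
property, mirroring the finding that repetition harms embeddings far more
than appending random sequence does. Beyond the first extra copy the
corruption is already total in the mock, so the multiplicity groups are
expected to be statistically indistinguishable from each other; the
monotonicity summary in `compare_groups()` therefore carries a small noise
tolerance.

The mock for this task (`regression_mock()`) uses threshold 0.6: internal
matches at rate 0.3 agree at ~0.7 per residue and pass
($P(\ge 4/6) \approx 0.74$), while chance matches against the random padding
of control sequences ($P \approx 10^{-4}$ per candidate) stay negligible.

## What the synthetic generators do and do not emulate

Random sequences stand in for natural protein domains throughout. For
retrieval probes this is a *feature*: a random sequence has no learnable
grammar, so any confidence gain must come from context matching, and the
doubling collapse is known to behave equivalently for random and natural
inputs. What random inputs do not reproduce: the up-shifted baseline
perplexity distribution of natural sequences under a real model, per-family
composition biases, the weaker substitution-flip response of the rarest amino
acids (W, C) on natural domains — the flip probe measures per-symbol diagonal
mass so a real model's asymmetry is visible, but the mock has no mechanism to
produce it — and any real model's soft, graded window matching. Passing the
phenomenon suite on the mock validates the *pipeline and its logic*, not any
claim about a particular pretrained model; real models plug in through the
adapter contract (`register_adapter()`), must emit distributions over the
canonical alphabet only (dropping special tokens and renormalizing), and are
scored by exactly the same probes. For natural FASTA inputs,
`apply_baseline_filters()` implements the standard input filters: length
within [20, 1000] and a single-pass pseudo-perplexity above 5, the latter to
exclude sequences that already contain repeats and would contaminate the 1x
baselines.

## Numerical choices and degenerate inputs

* Candidate ties are broken by (score, |offset|, source position, transform);
  determinism everywhere is a hard requirement, and `run_pipeline()`
  re-executed on the same configuration reproduces its tables byte for byte.
* All randomness flows from a single integer seed through named substreams
  (probe index × replicate), kept below $2^{31}$; generators save and restore
  the session RNG state, so library calls never perturb user code.
* Degenerate inputs fail loudly: empty mask sets, zero-length sequences,
  spans outside the sequence, insertions outside the alphabet, a
  non-equivalent mask colliding with the equivalent position, equal inserted
  symbols in the contra-lateral probe (preference undefined).
* `mutate_copy()` draws all per-position decisions up front and applies them
  left to right in one pass, so indel-induced shifts cannot bias later
  mutation decisions; substitutions always change the residue, making the
  rate-1 case exactly alphabet-disjoint position-wise.
* Problem sizes in the shipped tests — 30-residue units for collapse probes,
  length-100 imperfect repeats over 100 seeds, a needle grid up to offset
  500, 25 sequences × 10 groups × 3 runs for the regression — are chosen so
  every qualitative regime is exercised with comfortable statistical margins
  on a single CPU; all sizes are arguments, and desk-scale defaults are not
  magic numbers but documented choices.

## Limitations

The mock's matching is a hard threshold on window agreement; real attention
is soft, so boundary behaviour (e.g. the exact shape of the recognition
boundary in the needle sweep) is sharper in the mock than in any real model.
The contra-lateral effect in the mock arises purely from window clipping at
sequence ends; a real model's preference pattern may extend further inward
and is measured, not assumed, by the probe. The left-to-right evaluation
warms up at the prior for the first half-window of a repeated unit, which
slightly inflates the mock's autoregressive perplexity relative to an ideal
induction mechanism. And the embedding regression's absolute loss values are
properties of the synthetic construction; only the orderings between groups
are meaningful claims.
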