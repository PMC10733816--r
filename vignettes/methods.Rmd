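---
title: "De-identification of clinical free text with deidr: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{De-identification of clinical free text with deidr: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deidr)
```

## The problem

Unstructured clinical notes — pathology reports in particular — contain
sensitive health information (SHI): patient and clinician names, dates,
medical record and laboratory identifiers, contact details, addresses, ages
and occupations. Before such notes can be reused for research, SHI spans
must be located and removed or replaced with realistic surrogates. deidr
implements a complete desk-scale pipeline for this task: stand-off XML I/O,
tokenization with repair rules for fused ("cascaded") tokens, BIESO
sequence tagging with a trainable reference tagger, regular-expression
post-detection for dates, phone numbers and URLs, surrogate generation, and
strict/relaxed micro-averaged span evaluation. A synthetic report generator
with exact gold offsets stands in for restricted clinical corpora, so every
component is testable end to end.

## Data model and offsets

All annotations are stand-off: a document is its raw text plus a table of
entity spans with 0-based, end-exclusive character offsets counted in
Unicode code points, newlines included. The invariant enforced everywhere
is `text == substr(doc, start, end)` — no operation ever edits document
text; repairs only subdivide spans. The taxonomy has eight categories,
five of which carry subcategories (`shi_taxonomy()`); annotation depth is
the subcategory where one exists. `LOCATION:ROOM` and `ID:BIOID` are
representable but excluded from the default label alphabet because they
are vanishingly rare in practice; the exclusion list is a parameter of
`label_scheme()`. A bare `OTHER` annotation is distinguished from
`LOCATION:OTHER` by the XML element name, which carries the category while
the `TYPE` attribute carries the subcategory.

Gold corpora occasionally overlap entities; this is permitted with a
warning, and evaluation treats each span independently.

## Tokenization and cascaded-token repair

Clinical text is rife with missing-space fusions. The base tokenizer
splits on whitespace and detaches punctuation, with one deliberate
exception: commas, semicolons and periods flanked by alphanumerics stay
attached. These are exactly the fused forms the repair rules exist for
(`"12G00123,12N01234"`, `"JMH.Does"`) — and decimals, which must not be
shredded. Four ordered rules then subdivide token spans:

* **R1** detaches a comma or semicolon strictly inside a token;
* **R2** detaches a period whose neighbours are both alphabetic
  (`JMH.Does`), leaving `3.5` alone;
* **R3** splits a lowercase-to-uppercase boundary (`PsychiatryChief`)
  only when the trailing lowercase run and the right alphabetic fragment
  both reach `min_camel_fragment` characters (default 2). The
  trailing-run guard is what protects `McDonald`: its boundary is
  preceded by a single lowercase letter;
* **R4** splits a digit-to-letter boundary only when the letter side
  opens Uppercase-then-lowercase (`39Sex` splits; the `G` in `12G00123`
  is followed by a digit, so identifiers survive).

Splitting is idempotent and tiles the parent span exactly, so offsets into
the original text remain valid — the reason repairs subdivide spans instead
of inserting characters.

Sentence segmentation breaks at newlines and after terminal punctuation
followed by whitespace, guarded by an abbreviation list. There is no
length cap: a single unbroken line is a single sentence regardless of
length.

## Label schemes and the codec

Entity spans convert to per-token labels under BIESO (default) or BIO.
BIESO marks a single-token mention `S-<type>` and a multi-token mention
`B ... I* ... E`. Entities whose boundaries fall inside tokens are
clipped *outward* to the minimal covering token run — the recall-preserving
choice, and the damage mode the cascade rules exist to prevent. When
entities compete for a token, the longer span wins.

Classifiers can emit invalid label sequences, so decoding first applies a
deterministic repair convention: each maximal same-type run of entity
labels is rewritten with the canonical prefix pattern (`S` if isolated,
otherwise `B I* E`). Repair is idempotent and the identity on valid
sequences; the tests check decode output against an independently written
finite-state reference decoder on random label sequences.

## The reference tagger

The modelling layer is a pluggable contract: anything that maps a sentence
to a label sequence can sit behind `predict()`, including external
fine-tuned transformer models through an adapter. The package ships a
trainable reference implementation designed to be faithful to the feature
engineering while remaining trainable on a laptop CPU:

* **Features.** Each token is represented by the concatenated embeddings
  of itself and `window = 2` neighbours each side (zero padding at
  sentence boundaries), concatenated with 20 orthographic one-hot flags
  of the token itself (capitalisation, digit patterns, length buckets,
  date/phone/postcode/identifier shape matches), passed through a
  rectified-linear activation. Embedding tables load from plain-text
  vector files (optional `count dim` header) and concatenate; the package
  can also train skip-gram negative-sampling embeddings on the corpus
  itself, single-threaded and seeded (dimension 25 by default — small
  enough to train in seconds at desk scale, large enough to separate the
  template vocabulary).
* **Scorer.** A multinomial logistic model over these features, trained
  by minibatch Adam (batch 4096 tokens, step size 0.05, up to 20 epochs,
  early-stopping patience 5 — the schedule lengths mirror common
  practice for this task family). Early stopping monitors span-level
  micro-F1 on the validation split under the full decoder, and the
  best-scoring epoch's weights are kept.
* **Decoding.** Exact Viterbi dynamic programming over the label lattice
  combines three quantities: prior-corrected emissions
  `log P(label | x) − log P(label)`, label-transition log-probabilities
  estimated from training bigrams with add-one smoothing, and hard
  scheme-validity constraints (forbidden transitions at probability
  zero). The prior correction matters: with around 96% of tokens labelled
  `O`, raw posteriors double-count the class prior already embedded in
  the generative transition model and suppress rare labels; dividing the
  prior out converts the posterior into a likelihood-proportional score,
  the standard correction in hybrid discriminative/generative decoders.
  Constrained decoding guarantees predictions never need repair, and the
  tests verify it against exhaustive enumeration on small lattices.

Training is deterministic under a fixed seed: shuffling is seeded,
embedding training uses its own fixed-seed generator, and models
serialize and reload bit-exactly.

## Rule-based post-detection and merging

Six lexical date shapes (`1/12/2000`, `1-12-2000`, and 3-letter month
names on either side of the day with either separator), three 10-digit
phone shapes (`1234567890`, `123.456.7890`, `123-456-7890`, with digit
boundary guards), and scheme- or `www.`-prefixed URLs are detected on the
raw text. Fields are lexical — day and month are 1-2 digits, year exactly
4, no calendar validation. The rule inventory is a data frame that sites
can extend.

Merging is additive recall, not override: a rule hit disjoint from model
output is added; a hit that strictly contains a same-category model span
replaces it; on any other overlap the model wins. The URL pattern and the
merge policy are declared conventions of this package, as is running the
detectors on raw text rather than on the tagger's sentences.

## Surrogates

Replacement is keyed: every draw is a deterministic hash of
`(surface, type, seed)`, so identical mentions map identically within a
run with no global state.

* **Names**: the initial letter is shifted by a fixed alphabet shift
  (1-25, derived from the seed), mapped through a keyed random alphabet
  permutation, and a replacement is drawn from the dictionary bucket for
  the resulting letter, preserving Title/ALLCAPS case. Replacements never
  equal originals.
* **Dates**: parsed lexically (numeric fields read day-first, as in
  Australian practice), shifted *backward* by a per-document shift of
  1-730 days — backward so no record becomes future-dated, per-document
  so all intervals between a document's dates survive — and re-rendered
  in the same shape, separator, padding and month case.
* **IDs and contacts**: format-preserving randomization — digits to
  digits, letters to same-case letters, punctuation untouched.
* **Ages**: jitter of up to ±2 years, never zero, floored at 1.
  **Locations**: dictionary swap within subcategory (hospital for
  hospital, city for city), postcodes digit-randomized.

After replacement the text is re-flowed, offsets recomputed, and the
output scanned for leaks: no original surface of 3 or more characters may
survive anywhere in the output. A replacement drawn from a dictionary can
collide with a *different* original mention in the same document; the
keyed draw is re-salted until clear. Dates are exempt from re-salting
because the shared shift is what preserves intervals — two dates exactly
one shift apart can therefore still collide, which the leak scan would
surface; this is a known, vanishingly rare limitation.

The bundled dictionaries are generated programmatically and are entirely
fictional (stem-suffix combinations with at least 10 surnames per initial
letter and 20 entries per location subcategory); sites should supply their
own lists for production use.

## Evaluation

Precision, recall and F1 are micro-averaged: TP/FP/FN pool over all
documents and types before the ratios. Matching is one-to-one and greedy
in offset order with gold-order priority. Strict matching requires exact
offsets and type; relaxed matching requires the same type, overlap, and
both boundary deltas within `tol` characters (default 2 — the smallest
integer tolerance that accepts the canonical trailing-`s`
over-segmentation with a margin; configurable). `tol = 0` coincides with
strict. Because both gold and decoded prediction sets are non-overlapping
sorted intervals, the greedy assignment attains the maximum bipartite
matching; the tests verify this against an exhaustive matcher. Default
type granularity is the subcategory, matching annotation depth. Cells
with zero denominators report 0 and are flagged rather than erroring.

## The synthetic corpus generator

The generator emulates the *structure* of a pathology de-identification
corpus, not its lexical distribution: templated sentences (macroscopic /
microscopic description blocks, referral and authorisation lines)
averaging 11 tokens; reports averaging 755 tokens; roughly 18 SHI
entities per report across six categories, with dates and clinician names
most frequent and professions rare; dates in the six lexical shapes,
phones in the three, identifiers shaped like `12G00123`. Gold offsets are
exact by construction and every generated document validates.

Cascaded-token noise is injected at probability 0.05 per eligible site
(the package's chosen default noise level): deleting the space between
two capitalizable words, fusing a number with a following capitalized
word (`Age: 39Sex`), or joining two adjacent identifiers across their
comma. Spaces inside entity spans are never deleted, so gold surfaces
remain intact and offsets recompute exactly; a ledger records every
corrupted site so rule recovery is measurable. Passing tests on this
corpus demonstrate mechanical correctness and recovery of the planted
structure; they do not demonstrate performance on real clinical text,
whose spelling variation, section structure and lexical diversity the
generator deliberately does not model.

## Problem sizes and numerical choices

The test suite trains the reference tagger on 500 synthetic reports with
100 validation and 100 test reports (the package's standard experiment
size), where it must reach strict micro-F1 of at least 0.85 on the held-out
split; the cascade-recovery bar (at least 95% of injected boundaries
restored) runs over 200 reports; the end-to-end comparison of training and
evaluating with and without cascade rules uses 60/20/30 reports. Lattice
and matcher oracle checks enumerate exhaustively up to 6 tokens x 7 labels
and 10 entities per document. Transition and prior estimates use add-one
smoothing; Viterbi ties break deterministically toward the lower label
index; the emission floor in training log-loss is 1e-12.

## Known limitations

* The reference tagger is a linear-chain model; it captures the feature
  engineering and the decoding constraints, not the capacity of recurrent
  or transformer sequence models. The tagger contract is the intended
  integration point for those.
* Rule inventories cover the six printed date shapes, the three 10-digit
  phone shapes, and common URL prefixes only; site-specific formats
  should be added to the inventory.
* Surrogate quality ("realism") is not quantitatively evaluated, and no
  re-identification risk scoring is attempted.
* Relaxed-match tolerance and the URL/merge conventions are package
  decisions where the field has no single standard; both are
  configurable.
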