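# deidr — hybrid de-identification of clinical free text

Unstructured clinical notes — pathology reports in particular — contain
sensitive health information (SHI): patient and clinician names, dates,
record and laboratory identifiers, contact details, addresses, ages and
occupations. Before such notes can be reused for research, every SHI span
must be found and removed or replaced with a realistic surrogate. `deidr`
is an R implementation of a complete, rule-augmented de-identification
pipeline for people building or evaluating such systems: clinical NLP
researchers, health data custodians, and anyone who needs a testable
reference for stand-off SHI annotation, sequence tagging and surrogate
generation.

## What it does

* **Stand-off XML I/O** — i2b2-style reports (`<TEXT>` CDATA + `<TAGS>`
  with character offsets), deterministic serialization, offset-integrity
  checking, seeded corpus splits.
* **Preprocessing** — sentence segmentation and span-faithful
  tokenization, plus cascaded-token repair rules that split fused forms
  such as `PsychiatryChief`, `39Sex` and `12G00123,12N01234` without ever
  editing the text (repairs only subdivide spans, so offsets stay valid).
* **BIESO/BIO codec** — entity spans ⇄ per-token labels, with a
  deterministic repair convention for invalid label sequences.
* **A trainable reference tagger** — window word-embeddings (loadable
  vector files, or skip-gram negative-sampling embeddings trained on the
  corpus) concatenated with 20 orthographic one-hot features and passed
  through a rectified-linear activation; a multinomial logistic scorer
  trained by minibatch Adam with early stopping; exact constrained
  Viterbi decoding so predictions are valid label sequences by
  construction. Any external model (e.g. a fine-tuned transformer) can be
  plugged in behind the same `predict()` contract.
* **Rule post-detection** — regular-expression detectors for six date
  shapes (`1/12/2000`, `12-Jan-2000`, ...), three 10-digit phone shapes
  and URLs, merged additively with model output.
* **Surrogates** — keyed, deterministic replacement: alphabet-shifted
  dictionary names, per-document backward date shifts of 1-730 days
  (preserving all within-document intervals), format-preserving
  randomization of IDs and contacts, age jitter, location dictionary
  swaps — with a leak scan proving no original surface survives.
* **Evaluation** — micro-averaged precision/recall/F1 with strict
  (exact-offset) and relaxed (±`tol` characters per boundary) matching:
  P = TP/(TP+FP), R = TP/(TP+FN), F1 = 2PR/(P+R), pooled over documents
  and types, overall and per category/subcategory.
* **A synthetic corpus generator** — pathology-style reports with exact
  gold offsets, configurable per-category entity rates, and injectable
  cascaded-token noise with a ledger, so rule recovery is measurable.

## Worked example

```r
library(deidr)

# a synthetic annotated corpus stands in for a restricted clinical one
docs <- generate_corpus(generator_config(n_reports = 45, seed = 42))$documents
splits <- list(train = docs[1:25], validation = docs[26:35], test = docs[36:45])

fit <- run_train(splits, seed = 1, refit = FALSE)
fit$metrics$strict
#> <deid_eval: strict matching, subcategory granularity, 10 documents>
#>   TP=176 FP=1 FN=1  P=0.9944 R=0.9944 F1=0.9944

# de-identify a new note: preprocess -> predict -> merge with rules
note <- deid_document("note1",
  "Seen by Dr Anna Kendrew on 3/11/2019. Lab No: 45K00981.")
pred <- predict(fit$model, preprocess_document(note))
out <- finalize_document("note1", note$text, pred, scheme = fit$model$scheme)
out$entities
#> # A tibble: 3 × 5
#>   category subcategory start   end text
#> 1 NAME     DOCTOR         11    23 Anna Kendrew
#> 2 DATE     <NA>           27    36 3/11/2019
#> 3 ID       IDNUM          46    54 45K00981

# replace with surrogates (keyed, deterministic)
sur <- apply_surrogates(out, surrogate_key(7))
sur$text
#> "Seen by Dr Buduna Fobmere on 22/12/2018. Lab No: 58X52131."
```

The strict report counts a true positive only when predicted start, end
and type all match the gold span exactly; the one FP/FN pair here is a
single boundary disagreement. In the surrogated note the name is redrawn
from a synthetic dictionary, the date moved backward by the document's
day shift (here 316 days — the same shift applies to every date in the
document, so intervals survive), and the identifier re-randomized with
its `digit-digit-letter-digits` pattern intact.

`tidy()`, `glance()` and `autoplot()` methods are provided for fitted
taggers and evaluation reports.

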