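---
title: "Joint entity and relation extraction with token-pair global matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint entity and relation extraction with token-pair global matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tripletag)
```

## The extraction problem and the one-step tagging scheme

Clinical text mining for venous thromboembolism (VTE) needs typed entities
(diseases, symptoms, drugs, risk factors, treatments, tests, patient
advisories) and the relations between them, e.g. *(pulmonary embolism, DIS,
chest pain)* — "the disease causes the symptom". Pipeline systems that first
recognize entities and then classify relations suffer error propagation: a
missed span can never yield a correct triple. `tripletag` instead scores
**three families of token-pair matrices** for a sentence of `s` tokens and
reads entities and triples off them in a single step:

* **entity head–tail**: cell `(k, i, j)` scores "tokens `i..j` form an
  entity of type `k`" (only `i <= j` is valid — a span cannot end before it
  starts; those cells are masked, never trained or decoded);
* **subject-head–object-head**: cell `(r, i, j)` scores "an entity starting
  at `i` is the subject of relation `r` whose object starts at `j`";
* **subject-tail–object-tail**: the same link expressed between span ends.

A triple `(sub, r, obj)` is decoded when the subject and object spans decode
as entities *and* both the head-pair and tail-pair cells for `r` clear the
threshold. Tokenization is per character, the standard choice for Chinese
clinical text; ASCII corpora are tokenized the same way so that fixtures are
language-agnostic. Spans are 0-based inclusive in memory (matching matrix
cell indexing) and 0-based half-open on disk (JSONL corpus files);
conversion happens only in `read_corpus()`/`write_corpus()`.

## Model

The scoring model is a composition of five parts.

1. **Embedding.** A trainable lookup table over the character vocabulary
   (`d` columns, one shared UNK row). A pretrained contextual encoder can be
   plugged in through `encoder_config(backend = "pretrained", embed_fn =)`;
   nothing in the package requires it, and the desk-scale experiments below
   use the lookup backend so the whole pipeline trains on one CPU in
   minutes.
2. **BiGRU context layer.** One forward and one backward GRU of width
   `gru_hidden`; position `t` concatenates a state that depends only on
   tokens `1..t` with one that depends only on `t..s` (verified by causality
   probes in the tests). A single layer with dropout-free deterministic
   arithmetic keeps training reproducible; `use_bigru = FALSE` ablates the
   layer to the identity.
3. **Common-sequence self-attention.** Scaled dot-product self-attention
   augmented with a learnable, input-independent matrix `C` of `n_slots`
   rows capturing corpus-wide regularities. The printed algebra of the
   source formulation (projecting keys and values through `C`) is
   dimensionally inconsistent as stated, so the default here treats the
   rows of `C` as **persistent key/value slots**: keys become
   `rbind(K, C)`, values `rbind(V, C)`, every query attends over `s + n`
   positions, and the output stays `s x d`. This keeps every stated
   property: `C` is `n x d`, input-independent, trained by all data,
   matched against queries, and higher correlation puts more weight on its
   value rows. With `n_slots = 0` the layer is exactly vanilla
   self-attention. The literal projected reading is kept behind
   `csa_formulation = "literal"` as a best-effort alternative. Scores are
   scaled by `sqrt(d_k)` (the variance-stabilizing convention);
   `attn_scale = "dk"` switches to plain `d_k` division.
4. **Biaffine span scorer.** Two feedforward heads (single `tanh` layer of
   width `p`) produce start and end representations `h_s`, `h_e`; cell
   scores are the biaffine form `[h_s(i); 1]^T U_k [h_e(j); 1] + b_k`. Each
   of the three families gets its own head pair and `U` tensor by default
   (`share_ffnn = TRUE` shares the heads), and the entity family is typed
   (one channel per entity type; `untyped_entity_matrix = TRUE` collapses it
   to one channel).
5. **Rotary global pointer.** A second, position-aware scorer applied
   directly to the encoder output: per family and channel, linear query/key
   maps of even width `p_gp` are rotated by rotary position embeddings
   (base 10000) so that `(R_i q_i)^T (R_j k_j)` depends on `j - i` only —
   uniform position shifts leave every score unchanged (a tested property).
   The two branches are **fused additively** on the logit scale:
   commutative, shape-preserving, and ablation-friendly (dropping either
   branch leaves the other unchanged). A sigmoid-gated convex combination is
   available as `fusion = "learned_gate"` but off by default.

### Loss

Token-pair tagging creates an extreme positive/negative imbalance (a few
positive cells among `~35 * s^2`). The training loss is the multi-label
cross-entropy

`loss = log(1 + sum_{i in P} exp(-S_i)) + log(1 + sum_{i in N} exp(S_i))`

applied per (sentence, family, channel) group and summed. Within a group
all negatives compete through one log-sum-exp instead of each contributing
an independent penalty, which is what makes the loss robust to imbalance;
its optimum pushes positive scores above 0 and negative scores below 0, so
**0 is the decoding threshold** (strict `>`; ties are excluded). The
grouping unit is not stated by the source formulation; per-channel grouping
is the granularity at which classes compete in the circle-loss family this
equation follows. Evaluation is log-sum-exp stabilized and the stabilized
value agrees with the naive formula to 1e-6 wherever the latter does not
overflow. Element-wise binary cross-entropy over valid cells
(`loss = "bce"`) is retained as the ablation alternative.

### Optimization

Adam (no scheduler), global gradient-norm clipping at 1.0, mini-batches of
16 sentences. All forward/backward passes are hand-written matrix algebra;
every gradient path (embedding, BiGRU, both attention formulations, both
heads, both losses, gated fusion) is validated against central finite
differences in the test suite. Defaults mirror the reference regime
(`max_len` 256, batch 16, learning rate 1e-4, 100 epochs). For the
desk-scale lookup model the experiments below use `lr = 1e-3`: 1e-4 is a
fine-tuning rate for a pretrained encoder, while a randomly initialized
embedding trains from scratch. When a validation corpus is supplied the
trainer keeps the best-by-validation-F1 parameters and stops early after
`patience` epochs without improvement (or once validation is perfect).

## The synthetic corpus generator

The corpus the original model was built on is private hospital EMR data, so
the package ships a generator that emulates its *structure*, not its
language: character-tokenized sentences, 7 entity types, 14 relation types
with fixed subject/object type signatures, sentences of at most `max_len`
tokens, and the one-subject-many-objects pattern. Defaults, chosen once:

* `relation_profile`: the training-split relation counts of the emulated
  corpus (TrAS 1406 ... DM 88), so relation imbalance is realistic;
* `p_multi_object = 0.3`: a visible minority of sentences carry one subject
  with two objects under the same relation, the pattern that stresses joint
  decoding;
* `p_entity_only = 0.1`: some sentences carry an entity but no triple,
  providing whole-sentence negatives;
* `max_len = 64`, 12 surfaces per entity type, each surface tagged by a
  type-initial character, one distinctive marker character per relation,
  and random filler characters — enough signal that a character-level model
  *can* learn the task, which is exactly what a recovery experiment needs.

What the generator does **not** model: real clinical language statistics,
negation, section structure, annotation noise, nested or discontinuous
mentions, and surface ambiguity between types. Passing the recovery
experiment therefore shows that the architecture, losses, decoding and
training loop are implemented correctly and can fit the tagging scheme —
not that the model reaches any particular accuracy on real medical records.

## Numerical and design choices

* Entity-family cells with `i > j` are invalid: excluded from the loss
  partition (stored as 0 in the sign-valued gold encoding) and never
  decoded; the decoder output is invariant to arbitrary perturbations of
  those cells.
* `tanh` activations in the span heads keep the loss surface smooth, which
  also makes finite-difference gradient validation exact to ~1e-6.
* Relation decoding pairs only *decoded entities*, never raw head/tail
  indices, and optional schema-signature filtering is off by default (gold
  annotations are allowed to violate signatures; validation warns).
* Head/tail pair factorization has a known ambiguity: when entities share
  head tokens and other entities share tail tokens, two gold triples of the
  same relation can license a spurious cross-combination. The test suite
  constructs such a counterexample and documents it; with non-overlapping
  entities (the generator's regime, and the common case in flat NER) the
  codec `decode(encode_gold(S)) == S` is exactly lossless, which the suite
  verifies on 500 generated sentences covering all 14 relations.
* Training is deterministic given the seed (single-threaded R arithmetic,
  no nondeterministic kernels).

## Desk-scale problem sizes

The bundled experiments use sizes at which the full pipeline runs in
minutes on one CPU: recovery trains `d = 32`, `gru_hidden = 16`,
`n_slots = 4` on 300 generated sentences with 60 held-out sentences, at
most 100 epochs with patience 12. At the fixed seeds used in the acceptance
test this reaches held-out exact-match triple F1 in the low 90s within
~25 epochs. The quantity is stochastic: across other seeds we observed
roughly 87–96 F1, so the per-seed spread is several F1 points — the
behavior to expect when re-running `scripts/acceptance.R` under different
`--seed` values.

## Knowledge graph and question answering

Extracted triples aggregate into a typed graph: nodes deduplicated by
(surface, type), directed edges deduplicated by (subject, relation, object)
with support counts, exported as `nodes.csv`/`edges.csv` in graph-database
bulk-import layout with deterministic ids. The question answerer mirrors a
template QA front end: longest-dictionary-match entity linking against node
surfaces, first-feature-word question classification (14 categories, one
per relation), neighbor lookup in the rule's direction, and template-based
answer generation. The equivalent Cypher text is emitted for auditability
but executed against the in-memory graph, keeping the package
self-contained. Feature words and templates are configuration
(`inst/extdata/qa_rules.yaml`), not code: the original system's trigger
words are not published, so the defaults are replaceable inventions; rule
order defines matching precedence.

## Known limitations

* No nested or discontinuous entities; no beam decoding.
* The pretrained-encoder backend is pass-through only (no fine-tuning
  recipes beyond ordinary gradients).
* The cross-combination ambiguity above is inherent to the head/tail
  factorization, not fixable by thresholding.
* Recovery F1 on synthetic data says nothing quantitative about real EMR
  performance (see the generator section).
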