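---
title: "Prompt-aware context retrieval from biomedical knowledge graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prompt-aware context retrieval from biomedical knowledge graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kgrag)
```

## The problem and the model

Chat models answer biomedical questions fluently and sometimes wrongly. A
curated knowledge graph is the opposite: correct, attributable, and mute. The
pipeline in this package connects the two by treating the graph as a source
of *context sentences* and the question as a query against them. The
governing constraint is the model's token budget: a disease node in a
SPOKE-scale graph can have thousands of neighbors, and shipping them all is
both expensive and counterproductive. The package's job is therefore not
just retrieval but *selection* — finding the few graph associations that are
actually about the question.

The pipeline has five fixed stages, each behind a small contract so that
heavyweight components (sentence transformers, hosted chat models, a live
graph API) can be swapped in without touching the logic:

1. **Disease entity recognition** (`extract_disease_entities()`,
   `link_entities()`). Extraction is pluggable: a zero-shot LLM adapter in
   production, a deterministic dictionary matcher in tests. Linking embeds
   each mention and takes the nearest disease-name vector; a failed
   extraction falls back to the five nearest concepts for the whole
   question. We deliberately impose no minimum-similarity floor on linking —
   the contract is argmax — though a floor is configurable.
2. **Filtered neighborhood retrieval** (`neighborhood()` with
   `context_filter()`). The defaults encode three quality rules: treatment
   edges need clinical phase ≥ 3, Protein neighbors must be curated, and
   text-mined Disease–Gene edges are excluded. Phase filtering only touches
   edges that carry a phase attribute; others pass untouched.
3. **Verbalization** (`verbalize_triples()`). The predicate schema
   (`ASSOCIATES_DaG` = ASSOCIATES, Disease → Gene) makes this a mechanical
   rewrite: `"<subject type> <subject name> <predicate words> <object type>
   <object name>"`. Node types render verbatim as stored.
4. **Pruning** (`prune_context()`). Per linked disease node, a sentence
   survives when its cosine similarity to the question is strictly greater
   than the 75th percentile of that node's similarity distribution *and* at
   least 0.5. Survivors from all nodes are pooled by similarity rank and
   truncated to the context volume.
5. **Assembly and generation** (`assemble_prompt()`, `answer_question()`).
   The prompt lists sentences in pruned order, optionally re-attaching
   provenance and evidence clauses; the backend is called once at
   temperature 0; cited provenance is collected from the completion.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `percentile` | 75 | Per-node similarity percentile a sentence must strictly exceed. Dimensionless (0–100). |
| `min_similarity` | 0.5 | Absolute cosine floor, applied alongside the percentile. |
| `context_volume` | 150 | Global cap on context sentences entering the prompt; 100 is the conventional choice for True/False runs; 0 is allowed and means no context flows. |
| `min_clinical_phase` | 3 | Phase floor for treatment edges (0–4 scale). |
| `require_curated_protein` | TRUE | Drop uncurated Protein neighbors. |
| `exclude_textmining_disease_gene` | TRUE | Drop text-mined Disease–Gene edges. |
| `fallback_k` | 5 | Whole-question matches returned when extraction fails. |
| `temperature` | 0 | Passed to the backend; the bundled mocks are deterministic at 0. |

The percentile + floor pair is the load-bearing choice: the percentile
adapts to each node's similarity distribution (a node whose whole
neighborhood is on-topic keeps more), while the floor guards against
questions where nothing is relevant and the top quartile is still junk.

## The reference embedder

`reference_embedder()` is a real, deterministic sentence embedder — not a
stub: the case-folded, NFC-normalized text is decomposed into its character
trigram multiset, each trigram hashed (polynomial rolling hash, base 31)
into one of 256 buckets, and the count vector L2-normalized so cosine
similarity is a dot product. Its properties are exactly what the pipeline's
invariants need: it is case-insensitive by construction (which is what makes
embedding-based retrieval immune to the lowercase perturbation that zeroes
out exact-string matching), identical inputs give identical vectors across
platforms (integer arithmetic until the final normalization), and
lexically close strings score higher than unrelated ones. What it does not
capture is synonymy: "high blood pressure" and "hypertension" share almost
no trigrams. Production deployments should plug a sentence-transformer
adapter into the same `embedder()` contract (a small general model for
disease names, a biomedical model for context sentences); every test that
relies on case-invariance or determinism holds for any embedder with those
two properties.

## Numerical choices and degenerate inputs

* **Percentile definition.** Linear interpolation between order statistics
  (`stats::quantile` type 7), the common default. "Greater than" is strict:
  with a single sentence in a group, the threshold equals its own
  similarity and the sentence is dropped. The suite pins this definition
  against an independently coded oracle, so a change here fails loudly.
* **Tie-breaking.** Pooled sentences sort by similarity descending, then
  sentence text ascending; index queries break similarity ties by entry id
  ascending. All orderings are total, so runs are reproducible.
* **Zero vectors.** The empty string embeds to the zero vector; its cosine
  against anything is defined as 0.
* **Evidence rendering.** `" (evidence: p-value = p, z-score = z)"` with six
  significant digits; absent fields are omitted; absent evidence contributes
  no clause. Provenance renders as `" (Provenance: s1, s2)"` in stored
  order. These templates are this package's own formatting choices; only
  the bare sentence grammar is fixed by the predicate schema.
* **Predicate suffix grammar.** One letter per type initial by default;
  graphs whose schema abbreviates types with several letters (e.g. a
  side-effect type) can pass an abbreviation table to `parse_predicate()`.
  Longest abbreviations are tried first so parsing stays unambiguous.
* **Counting tokens.** The default tokenizer splits on whitespace and
  punctuation; model-specific tokenizers plug in as functions. Completion
  tokens are counted with the same tokenizer as the prompt so usage
  comparisons are internally consistent.

## Design choices where the design was open

* **Per-node percentile, pooled cap.** The similarity distribution is
  computed per linked disease node, not pooled across nodes — each node's
  context competes against itself — while the context-volume cap applies
  globally by similarity rank. For two-disease questions an alternative
  would split the volume per disease; the pooled reading is the default and
  the per-disease behavior can be emulated by calling `prune_context()` per
  match.
* **Similarity is computed on the bare sentence.** Provenance and evidence
  clauses are re-attached at assembly time, never scored: source-database
  names would otherwise perturb relevance ranking.
* **Edges keep their stored orientation.** `neighborhood()` returns incoming
  and outgoing edges without reorienting them, because verbalization needs
  the true subject/object roles (`TREATS_CtD` is stored Compound → Disease
  even when retrieved from the disease side).
* **Mock backends.** `echo` (returns the context block), `mcq-lookup`
  (answers with the first option occurring in the context, falling back to
  the first listed option), `tf-lookup` (True iff the asserted sentence
  occurs in the context). They answer *from the supplied context only*,
  which is precisely what makes them useful: they measure whether retrieval,
  verbalization and assembly put the right facts in the prompt, independent
  of any model's reasoning. Real adapters (OpenAI-style APIs, local Llama
  servers) implement the same `chat_backend()` contract and are deliberately
  outside the test matrix.
* **Jaccard of two empty sets is 1** (perfect agreement on nothing); the
  benchmark never hits this case because retrieval records require
  non-empty ground truth.
* **Retrieval correctness** defaults to subset containment of the truth set
  (an "any overlap" mode is available), and the sweep's Jaccard comparison
  is computed over neighbors of the ground-truth node type (genes), so the
  curve measures recall of the associations the questions ask about.

## What the synthetic generator emulates — and what it does not

`simulate_graph()` produces a structurally faithful miniature of a curated
biomedical graph: typed nodes with mixed-case names, schema-compliant
predicates, provenance lists, p-value/z-score evidence on gene
associations, clinical phases on treatment edges, a text-mined fraction of
disease–gene edges and a curated fraction of proteins. The default shape —
20 diseases, 120 genes, 40 compounds, 40 proteins, 8/3/2 associations per
disease, 20% text-mined, 70% curated, phases weighted toward 3–4 — is small
enough to enumerate by hand yet large enough that filtering, pruning and
ranking all have work to do. `simulate_questions()` derives True/False
(balanced, with negatives rewired to unlinked genes so labels are correct
by construction), five-option MCQ (distractors never linked to the
disease), and retrieval questions (template bank naming the disease
verbatim) from the graph's *filtered* associations, so ground truth and
retrievable context coincide exactly.

That coincidence is the point, and also the caveat: passing tests show the
*machinery* composes correctly — they do not show that a trigram embedder
resolves real clinical phrasing, that real question distributions match the
template bank, or that real graphs are as cleanly typed as the synthetic
ones. Biological realism of the generated associations is explicitly a
non-goal. The test suite and the acceptance script use graphs of 200–1000
nodes and question sets of 10–500 items, sizes chosen so every oracle can
be brute-forced and hand-checked.

## Known limitations

* One-hop neighborhoods only; no multi-hop path retrieval.
* Exact cosine scan, no approximate-nearest-neighbor index — appropriate at
  the scales above, and the `kg_index` persistence format is deliberately
  plain text.
* The zero-shot extraction prompt and the chat-model answer templates ship
  as editable defaults with no claim of optimality.
* Entity linking indexes one node type at a time (diseases by default);
  other types are supported only by building further indexes.
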