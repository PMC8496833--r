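---
title: "Mining the 510(k) predicate genealogy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining the 510(k) predicate genealogy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predigree)
```

## The problem

A device cleared through the US FDA 510(k) pathway is marketed on the
strength of *substantial equivalence* to one or more previously cleared
predicate devices. Because each public summary lists only the immediate
predicates, the full ancestry of a device — possibly a long daisy-chain
reaching back to a De Novo founder — is not reported anywhere and must be
reconstructed. `predigree` rebuilds that ancestry from summary documents,
quantifies how similar each device's claims are to its predicates', and
joins post-market surveillance (complaints and recalls per product code)
to the reconstructed genealogy.

The pipeline has five stages, each exposed as plain functions with
file-based hand-offs so any stage can be run, inspected and tested alone:

1. **Ingest** (`parse_summary`, `parse_corpus_dir`): extract device IDs
   (`K` or `DEN` followed by six digits), segment the *Indications for
   Use* and *Device Description* sections, tokenise and drop stop words.
2. **Genealogy** (`build_graph`, `ancestral_closure`, `traverse_from`):
   a directed graph with edges descendant → predicate, so a device's
   *branching factor* (number of predicates it cites) is its out-degree.
3. **Equivalence** (`bow_vector`, `train_embeddings`, `device_similarity`,
   `equivalence_by_year`): cosine similarity between section-level
   document vectors,
   $\cos(\vec A, \vec B) = \dfrac{\vec A \cdot \vec B}{\lVert \vec A\rVert\,\lVert \vec B\rVert}.$
4. **Surveillance** (`identify_outliers`, `recalled_vs_marketed`,
   `scatter_table`): complaint-to-device ratios per product code and
   text-similarity comparison of Class-1-recalled against marketed
   devices.
5. **Orchestration** (`run_pipeline`) plus the numbered drivers under
   `analysis/`.

## Similarity model

Two document representations are supported, selected by `method`:

* **Bag of words** (`"bow"`): raw token counts per section. Cosine on
  count vectors lies in $[0, 1]$; it is the transparent, parameter-free
  route and the default throughout.
* **Shallow word embeddings** (`"embedding"`): a two-layer
  continuous-bag-of-words network with negative sampling, trained on the
  whole summary corpus, embedding each word in a 500-dimensional space
  (`dimension = 500` is the one architecture choice we treat as fixed;
  everything else is a tunable). A section is represented by the
  unweighted mean of its in-vocabulary word vectors. Words never seen in
  training cannot be represented — a real limitation for device-specific
  jargon — so an all-out-of-vocabulary section maps to the zero vector
  and is flagged rather than scored.

Defaults for the trainer: window 5, 10 epochs, 5 negative samples,
`min_count` 1, initial learning rate 0.05 with linear decay. These are
conventional small-corpus settings; the architecture is fixed but the
published record for this kind of analysis leaves the remaining
hyperparameters open, so exact numeric reproduction of any particular
published similarity table is not expected, and the bag-of-words route is
retained as the reference method. Training is single-threaded with a
private linear-congruential RNG, which makes the vector table a pure
function of (corpus, hyperparameters, seed) — a property the tests and
the acceptance checks rely on.

Per-pair scoring applies the method separately to the two sections and
reports their arithmetic mean as the `combined` score (both per-section
values are always available; the combination rule is a config option, not
a hidden constant). A pair in which either summary failed to parse is
*unscorable*: an explicit flag, never a number. Cosine of a zero-norm
vector is defined as 0 and flagged `zero_norm` for the same reason —
these cases arise routinely from unreadable scans and out-of-vocabulary
sections and must not poison downstream means.

`equivalence_by_year` first averages each device's combined similarity
over its predicates, then summarises the per-device values by decision
year (five-number summary plus mean), excluding and counting devices with
no scorable edge. Averaging per device first keeps prolific citers from
dominating a year.

## The genealogy graph

Edges are stored descendant → predicate, matching the direction of
citation; forward ("who descends from this De Novo?") views reverse it.
Design choices worth stating:

* Cited predicates with no metadata become **stub nodes** (year unknown,
  no summary). They terminate closure expansion when they cite nothing.
* `branching_histogram` attributes each ancestral-tree member to **its own
  decision year**; published per-year branching histograms are ambiguous
  about both the cohort and the year attribution, so both are explicit
  parameters rather than baked-in choices.
* Real scraped citation data can contain errors that create cycles, so
  `detect_cycles` reports them and every traversal refuses to revisit a
  node; on generated corpora the graph is acyclic by construction and the
  cycle list is empty.
* Sankey export gives unscorable links weight 0 and `scored = false` so a
  renderer can style them distinctly — lineages routinely contain devices
  whose summary statements are not public (e.g. K033779 in the bundled
  nitric-oxide lineage `mrn_lineage()`), and a fabricated weight would be
  worse than a flagged default.

## The synthetic corpus: what it emulates, and what it does not

Real 510(k) summaries cannot be redistributed at useful scale, and the
interesting claims (edge recovery, similarity–mutation response, outlier
detection) need known ground truth, so `generate_corpus` plants it:

* **Sparse genealogy.** Each non-root device cites a number of predicates
  drawn from `predicate_count_pmf`; the default puts 0.8 of the mass on
  one or two predicates with a geometric-style tail, the qualitative
  shape seen in real predicate networks. All predicates are earlier,
  same-product-code devices, so edges point strictly backward in time and
  the graph is acyclic by construction.
* **De Novo-rooted lineages.** Each product code is founded by a
  `DEN`-prefixed root cleared in `year_min`; the generator requires
  `n_roots >= n_procodes` so every code has a founder and the
  surveillance invariant (no complaints without devices) holds by
  construction.
* **Controlled similarity.** A root's sections are bags of content words
  drawn without replacement from a shared pool (20% of each section)
  plus code-specific jargon. A descendant copies the sections of its
  first-listed predicate (the *text donor*) and substitutes each word
  independently with probability drawn from `mutation_rate_range`,
  replacements coming from a disjoint novel-jargon pool. With no repeated
  words, the expected bag-of-words cosine across a donor edge is
  approximately $1 - p$, so similarity is analytically monotone in the
  mutation rate — used as a monotonicity check, not an exact target. The
  mutation rate is recorded in the ground truth for donor edges only
  (secondary citations carry `NA`: no text flows along them).
* **Heavy-tailed surveillance.** Complaint counts are log-normal; planted
  outlier codes are rescaled so their complaint-to-device ratio strictly
  exceeds every other code's, and the Class-1-recalled devices are drawn
  from the outlier codes, mirroring the real-world pattern where severe
  recalls concentrate in high-complaint codes.
* **Determinism.** One RNG stream per corpus, split hierarchically per
  device and stage, so the corpus is byte-reproducible from
  (config, seed).

Defaults — 500 devices, 12 codes, years 1997–2020, mutation in
[0.05, 0.5], 2 outlier codes, 8 recalled devices, 60/80-word sections —
are fixed study conditions chosen to match the qualitative structure of
the real predicate network (sections of 50–100 words, most devices with
1–2 predicates, a handful of dominant complaint codes) at a size every
test can afford.

What the generator does **not** emulate: real regulatory prose (sections
are word bags, so lexical overlap is the only signal — which is exactly
the assumption behind bag-of-words scoring), OCR noise beyond a crude
garbage-character flag (`ocr_noise_frac`) that exercises the unreadable
path, citation errors, and devices spanning product codes. Passing tests
therefore demonstrate that the machinery is correct under the stated text
model, not that cosine similarity is a valid proxy for regulatory
equivalence on real prose.

## Numerical and degenerate-case choices

* Unreadable text: a document whose fraction of characters outside
  letters, digits, whitespace and basic punctuation exceeds 0.3 is
  `unreadable` (no sections); a missing heading gives `missing_section`
  with the found section retained.
* Tokens shorter than two characters are dropped; no stemming or
  lemmatisation (lexical overlap is the object of study, and stemming
  synthetic jargon would be meaningless).
* Outlier identification is top-*k* by complaint-to-device ratio
  (default *k* = 7), ties broken by total complaints then code, so the
  ranking is deterministic and row-order invariant. The ratio rule with a
  configurable *k* was chosen because any fixed cutoff on the ratio scale
  would be arbitrary for heavy-tailed counts.
* The recalled-vs-marketed flag is `TRUE` when **every** recalled
  device's mean combined similarity to the marketed set is below the
  threshold (default 0.5); it is therefore monotone in the threshold.
* Self-citations are removed by exact ID match only; every other ID
  occurrence counts as a citation (nothing distinguishes citation
  sentences from incidental mentions, and the synthetic renderer never
  emits incidental ones).

## Problem sizes

The bundled analyses and tests run at: 500-device corpora for edge
recovery, mutation response (rates spanning [0, 0.9], ~490 donor edges)
and outlier recovery; an 80-device corpus with a 100-dimensional model
for the byte-determinism check of the full pipeline; the 500-dimensional
model trained on the full 500-device corpus (~70k tokens) in the analysis
scripts. These sizes give stable statistics (Spearman correlations near
0.99 against planted rates) while keeping any single stage under a
minute on one core.

## Known limitations

Parsing assumes heading-delimited plain text; PDF extraction and OCR are
out of scope. The embedding route shares the usual small-corpus caveats:
vectors for rare jargon are poorly estimated, and mean-of-vectors
document representations compress long sections aggressively — on the
synthetic corpus embedding cosines sit much higher than bag-of-words
cosines while preserving rank order, so cross-method comparisons should
be made on ranks, not raw values. Surveillance joins are per product
code, not per device, because that is the granularity of TPLC-style
tables; complaint–recall causality (lagged or otherwise) is deliberately
not modelled.
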