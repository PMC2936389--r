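---
title: "Empirical search-filter development with hedgedev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Empirical search-filter development with hedgedev}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hedgedev)
```

## The problem

Topic-specific literature in bibliographic databases such as PubMed/Medline
is hard to retrieve when the field's methods and vocabulary are
heterogeneous. Nurse staffing research — the study of how nurse-to-patient
ratios relate to nursing and patient outcomes — is a canonical example: the
studies are mostly observational, use many designs and data sources, and no
single MeSH heading covers them. A *search filter* (or *hedge*) is a reusable
Boolean combination of free-text terms and MeSH headings designed to
retrieve such a class of publications with known sensitivity and precision.

`hedgedev` implements an empirical development workflow for such filters:

1. **Development set.** Assemble a pool of known-relevant references (for
   the bundled case study, 78 papers drawn from systematic reviews) as a
   gold standard.
2. **Population set.** Draw a random sample of database records (here,
   10,000) that represents the database at large and is assumed
   non-relevant.
3. **Term mining.** Tokenize titles and abstracts, build a binary
   term-document matrix, and compute each term's *document prevalence* —
   the fraction of records containing it at least once — in both sets
   (`build_tdm()`, `term_prevalence()`).
4. **Term selection.** Keep terms prevalent in at least 5% of the
   development set, discard any prevalent in more than 2% of the population
   sample, rank the survivors by development-set document count, and keep
   the top 25 (`select_overrepresented()`). The two thresholds are
   inclusive. This differential rule is what removes ubiquitous words: a
   word like *patients* can appear in 65% of relevant papers and still be
   useless, because it also appears in 77% of the database at large.
5. **Strategy construction.** Combine selected free-text terms and
   manually curated frequent MeSH headings (`mesh_frequency()` ranks them;
   the relevance judgement stays human) into Boolean strategies in PubMed's
   numbered-line syntax (`parse_strategy()`).
6. **Evaluation.** Execute the strategies against labelled corpora
   (`execute_strategy()`) and report sensitivity, precision and number
   needed to read (`evaluate_strategy()`, `compare_strategies()`).
7. **Population estimate.** OR all candidate strategies together, screen a
   random sample of the joint retrieval, and scale the sample's relevance
   proportion up to the pool size to estimate how many relevant references
   the database holds (`estimate_total_relevant()`).

## Evaluation metrics

For a retrieval $R$ and a gold-standard set $G$:

$$\mathrm{sensitivity} = \frac{|R \cap G|}{|G|}, \qquad
  \mathrm{precision} = \frac{|R \cap G|}{|R|}, \qquad
  \mathrm{NNR} = \frac{|R|}{|R \cap G|} = \frac{1}{\mathrm{precision}}.$$

The overlap $|R \cap G|$ is always recomputed from the two id sets;
callers cannot inject an inconsistent count. Reports show sensitivity and
precision as percentages with one decimal and NNR rounded to the nearest
integer, half away from zero. A zero denominator is an error in the scalar
accessors (`precision()` on an empty retrieval does not return 0 or
infinity); in report rows and comparison tables the same situation appears
as `NA`, so that a no-hit strategy can sit in a table without either
crashing it or contaminating averages with sentinels.

## The query engine and how it differs from PubMed

Strategies are ordered, numbered Boolean expressions over field-tagged
terms; `#n` references earlier lines only, and the last line is the result.
Operator precedence is `NOT` > `AND` > `OR`, left-associative, with
parentheses overriding; operators and field tags are case-insensitive.
`compile_single_line()` substitutes all line references to produce the
equivalent stand-alone expression.

Matching semantics are deliberately explicit and reproducible rather than
an emulation of PubMed's query preprocessor:

* `[tiab]` terms match exact tokens, case-insensitively, with no stemming
  and no automatic term mapping — `staff` does not match `staffing`.
  Filters built this way spell out every variant (`nurse`, `nurses`,
  `nursing`), so exact-token semantics is faithful to how the strategies
  are written.
* Phrases (`skill mix[tiab]`) must occur as consecutive tokens within the
  title or within the abstract; a phrase never spans the title/abstract
  boundary.
* `[mh]` terms match a record's MeSH descriptors by case-insensitive
  equality; `"Descriptor/qualifier"[mh]` additionally requires the
  qualifier on the same heading. PubMed explodes headings over the MeSH
  tree by default; `hedgedev` must run without a tree file, so explosion is
  **off** by default and is enabled per run (`explode = TRUE`) when a
  two-column tree table is supplied (`read_mesh_tree()`). Descendance is
  tree-number prefix extension.
* Untagged terms are parse errors rather than an "all fields" search:
  silent field guessing is exactly the kind of irreproducibility the local
  engine exists to avoid.

Date limits (`year_range`) drop records outside the inclusive year window,
and records with no parseable publication year, before any matching —
mirroring a database date restriction.

## The tokenizer

Titles and abstracts are lowercased and split on every non-alphanumeric
ASCII character; purely numeric tokens and single-character tokens are
dropped; there is no stemming and no stopword list. Single-word terms only:
multi-word free-text mining is out of scope (phrase *matching* is
supported, phrase *mining* is not). These defaults are declared package
behaviour — reported term counts depend on them, and other tokenizers will
give somewhat different candidate lists. Stopwords are not needed because
the population-prevalence ceiling removes ubiquitous words empirically.

## The population-size estimator

If the OR of all tested strategies (assumed to have sensitivity near 1)
retrieves $N$ records, and screening a uniform random sample of $n$ of them
finds $k$ relevant, the expected number of relevant references is
$\hat{T} = N\,k/n$, here `r round(estimate_total_relevant(35708, 2195, 6)$point, 1)`
for the case study's $N = 35{,}708$, $n = 2{,}195$, $k = 6$. The confidence
interval is a binomial interval on $k/n$ scaled by $N$ and truncated below
at zero. The default is the Wald (normal-approximation) interval; Wilson
(`prop.test` score interval) and Clopper–Pearson (`binom.test` exact) are
selectable via `ci_method` because the Wald interval is known to undercover
at small $k$. At $k = 6$ all three are wide; the choice of method matters
less than the message that single-digit relevant counts in a screened
sample pin the total down only loosely.

## The synthetic-corpus generator

Real development corpora cannot be redistributed, so testing is built on a
seeded generator (`generate_corpus()`) that emulates the *statistical*
structure the pipeline consumes:

* Every profiled term is included in a record's abstract independently
  with its class-conditional probability (relevant vs background) —
  per-term document prevalences are therefore exactly the profile values
  in expectation, with binomial sampling noise.
* Abstracts are padded to a uniform random length (default 80–200 tokens)
  with filler drawn from a vocabulary of 2,000 pronounceable nonsense
  tokens, enumerated deterministically and disjoint from profiled terms —
  so profile prevalence accounting stays exact, and every filler token's
  prevalence (≈7% in both classes) fails the 2% population ceiling,
  keeping fillers out of term selection.
* Each profiled term present in a record also appears in its title with
  probability 0.3 (plus 3–6 filler tokens), so `[tiab]`
  title-versus-abstract matching is exercised.
* MeSH headings are assigned analogously from a descriptor profile with
  optional subheading attachment; publication years are uniform in
  1982–2006.

The bundled `nurse_staffing_spec()` uses the case study's observed term
prevalences (counts over 78 and 10,000) as the generating profile, plus two
frequent-but-unspecific words — *patients* at its observed 65%/77% rates
and *outcomes* at 70%/10% — which real abstracts contain and which the
selection rule must reject; without them the bundled precise strategy,
which requires `outcomes[tiab]`, would be degenerate on generated data. The
MeSH profile assigns the descriptors used by the bundled strategies at
rates chosen once for plausibility (e.g. "Nursing Staff, Hospital" on 60%
of relevant and 0.5% of background records; "Health Services
Administration" on 90% of relevant records, standing in for the fact that
PubMed would explode this very broad branch).

**What the generator does not model:** natural language, topic correlation
between terms (all inclusions are independent Bernoulli draws), duplicate
records, indexing lag, or PubMed's query preprocessing. Tests passing on
synthetic corpora therefore validate the *mechanics* — selection
arithmetic, Boolean semantics, metric computation, estimator calibration —
not the real-world performance of any particular filter, which only
screening real retrievals can establish.

## Numerical and design choices

* Prevalences are reported at 2 decimals, percentages at 1 decimal, NNR as
  an integer; all rounding of reported values is half away from zero.
  Internally everything is kept at full precision.
* Ranking ties (equal document counts) break alphabetically ascending, so
  every ranking is a total order and outputs are byte-reproducible.
* Thresholds are inclusive: development prevalence ≥ 5%, population
  prevalence ≤ 2% ("at least", "or fewer"). Terms absent from the
  population sample count as prevalence 0 and are eligible.
* The term-document matrix is binary presence, not counts: every
  downstream statistic uses document frequency only.
* `sample_corpus()` and `generate_corpus()` take explicit seeds and
  restore the caller's RNG state; identical seeds give bit-identical
  output.
* MEDLINE output is written unwrapped (one line per field), so
  write-then-parse is the exact identity; parsing accepts wrapped input
  with indented continuation lines. An empty abstract round-trips as an
  absent `AB` line; the publication year is the first 4-digit token of
  `DP`.

## Test-bench problem sizes

The test suite and the acceptance script work at sizes chosen to exercise
the statistics while staying quick on one core: query-engine/oracle
equivalence over 1,000 random strategies on 100-record corpora;
term-selection recovery over 20 seeds of the full 78 + 10,000-record
case-study spec (at these sizes a handful of terms sit within one binomial
standard error of the 2% ceiling, so recovering at least 20 of the 25
profiled terms per seed is the calibrated expectation); estimator
calibration over a few hundred hypergeometric screening replicates.

## Known limitations

* No OVID or other non-PubMed dialects; no truncation (`*`), proximity
  operators, `[majr]`/`[ti]`/`[tw]` tags, or publication-type filters.
* PubMed's automatic term mapping is not emulated, so retrieval counts
  against a live database will differ from local counts on exported
  records.
* MeSH explosion is only as good as the supplied tree table, and real
  PubMed explosion behaviour for subheading-qualified terms is
  version-dependent.
* Development-set precision is biased downward when non-retrieved records
  are assumed non-relevant without screening; the package reports what the
  sets imply and leaves the bias to the study design.
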