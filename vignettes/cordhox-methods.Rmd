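---
title: "Methods: region-specific expression, interactome crossing and antagonism screening"
author: "cordhox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: region-specific expression, interactome crossing and antagonism screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cordhox)
```

## Scope and model

`cordhox` chains several independent pieces of evidence into one claim
about regional susceptibility: that the human spinal cord constitutively
overexpresses a small family of homeobox transcription factors whose
protein neighbourhood feeds into a gliosis-associated, TGF-beta-linked
module, and that this module's signalling is opposed by the androgen
receptor. None of the individual steps is exotic — set crossing, exact
over-representation, a two-group location test, graph neighbourhoods,
annotation co-occurrence — and the package's job is to make each of them
explicit, typed, and testable on local files, where the original analysis
chained web services whose internals are not fully documented.

Throughout, gene identity is the normalized (upper-cased,
whitespace-stripped) HGNC-style symbol. No identifier mapping is
performed: the inputs this pipeline consumes (signature libraries, median
tables, interaction exports, TF catalogs) already speak symbols, and
pulling in a mapping service would make the package network-dependent
without changing any statistic.

## Region-specificity filter

A gene counts as region-specific when its median expression is at least
`minTarget` (default 5 TPM) in the target region and strictly below
`maxOther` in every other region. The `maxOther` default of 1 TPM
deserves a note: the qualitative requirement is "not or only very poorly
expressed" off-target, and on the ten worked-example genes the largest
off-target median is 0.54 TPM while the smallest on-target median is
5.37 TPM, so 1 TPM separates the two regimes with a wide margin on both
sides. Both thresholds are plain arguments; the filter is monotone in
each (raising `minTarget` or lowering `maxOther` can only remove genes),
which the tests exercise on random tables.

The companion `lowExpressionCheck()` classifies each cell of an FPKM
table against a detection floor (default 0.1 FPKM) as below / at / above,
where "at" extends to `atTolerance` times the floor (default 1.5). The
tolerance exists because expression "equal to or slightly above" a
detection threshold is a band, not a point; 1.5x is a deliberately tight
reading of "slightly".

## Exact over-representation

All enrichment questions reduce to the hypergeometric upper tail
$P(X \ge k) = \sum_{i=k}^{\min(n,K)} \binom{K}{i}\binom{N-K}{n-i} /
\binom{N}{n}$, the one-sided Fisher exact test. The implementation sums
in log space via `lgamma`, subtracting the largest log-term before
exponentiating, so universes of tens of thousands of genes cannot
overflow and small tails keep relative precision. Only the
over-representation side is implemented; a two-sided Fisher test answers
a different question than any step of this pipeline asks.

Fold enrichment is defined as $(k/n)/(K/N)$. On the module worked
example (2 of HOXA5's 7 TF partners inside a 12-TF module from a 1211-TF
catalog) this gives 28.83, while the originally reported factor for the
same counts is 31.74; no combination of the printed counts reproduces
31.74, so the package defines fold by the standard formula above and
treats the discrepancy as a documented reporting artefact. The p-value
itself (0.00184, printed 0.002) is exactly reproducible, and the
worked-example test asserts it. The same counts also settle a second
ambiguity: with all 14 HOX TF partners instead of HOXA5's 7, the tail
probability is 0.0077, not 0.002, so the reported statistic corresponds
to the 7-partner query and that is what the example uses.

Multiple-testing corrections delegate to `stats::p.adjust`
(Benjamini–Hochberg step-up and Bonferroni); the tests pin the step-up
arithmetic on hand-computed cases and the standard invariances
(never below raw p, capped at 1, permutation-equivariant).

## Welch differential expression

The two-group confirmation uses the unequal-variance two-sided t-test
with Welch–Satterthwaite degrees of freedom, vectorized over genes, with
Bonferroni correction across all genes tested and the fold ratio on the
linear scale (the worked-example ratios are linear-scale ratios of group
means). Degenerate inputs have explicit conventions: both groups constant
and equal gives p = 1; both constant but different gives a p at the
smallest positive double (the statistic is infinite); a zero group-2 mean
flags the ratio as `NaN` rather than failing.

Technical replicates are a genuine design fork: the source two-group
comparison included three replicate spinal-cord samples, and whether
they were collapsed before testing is not stated. The package defaults
to treating columns as independent and accepts a `replicateMap` that
averages replicate columns per biological specimen first — the
conservative choice is one argument away, and the tests verify the
collapsed path equals testing the pre-averaged matrix.

## Interactome crossing

`firstShell()` returns all proteins adjacent to each query in a cleaned
interaction network; cleaning happens at ingestion (non-human taxa,
unpublished interactions, self-edges dropped; endpoints stored in
lexicographic order so the edge set is independent of partner order in
the file). Queries may legitimately appear as partners of other queries
— homeobox proteins heterodimerize — so no query-exclusion is applied.
`crossWithTfs()` is a pure filter against the TF catalog, and distinct-TF
counting is by partner symbol, not by (query, partner) row: the worked
example has 15 rows but 14 distinct TFs because PBX1 partners two
queries. The TF catalog is always a user-supplied file (its curation
history cannot be reconstructed from a count), and the catalog object
simply records its members; 1211 is the size used throughout the worked
examples.

## GO co-occurrence and the antagonism screen

The original screen used a web service's "co-occurring terms" listing
whose statistic is not published. The package therefore defines the
statistics it ranks by — percent Jaccard similarity
$100\,c_{ab}/(c_a+c_b-c_{ab})$ and the probability ratio
$(c_{ab}/c_b)/(c_a/N)$ — and documents them as a reconstruction: ranks
from the original corpus snapshot (23rd of 743, 4th of 562) are treated
as corpus-dependent expectations, not assertions the tests could check.
Ties are broken by probability ratio, then term id, so rankings are
deterministic.

Annotation ingestion reads the GAF 2.1 columns for database object id,
symbol and GO id, drops `NOT`-qualified rows, optionally filters by
evidence code, and identifies proteins by database object id to avoid
symbol ambiguity. Annotations are not propagated up the ontology unless
an OBO file is supplied and propagation requested (is_a and part_of
only); the original tool's behaviour on this point is unknown, so the
flag defaults to off and the choice is visible in the API.

The screen itself examines the four cross-pathway pairs of two
(positive, negative) regulation-term pairs. Overlap between opposite
polarities is antagonistic evidence, between same polarities agonistic;
the verdict is `antagonism-only` when at least one overlap is observed
and every observed overlap is antagonistic. A term absent from the
corpus contributes "no overlap"; only a pathway with both terms absent
is an error, because then the screen has nothing to say about that
pathway at all.

## Synthetic data: what it emulates and what it does not

The generators are pure functions of (config, seed) and default to the
study conditions of the worked examples: the ten printed median-TPM rows
embedded among 19 distractor genes whose target-region TPM is uniform on
[0, 4.9]; two arms of 10 samples with planted linear-scale fold ratios
(234.9 for HOXA5, down to 1.74); 85 first-shell partners of which 14 are
catalogued TFs, inside a 1211-member catalog padded with decoys; and a
GO corpus where exactly the cross-polarity focal pairs share 5 annotated
proteins each.

Per-sample noise is log-normal with `noiseSdLog = 0.25` (about a 25%
coefficient of variation). That value was fixed from the reported
statistics, not from test outcomes: adjusted p-values of the order
1e-7 to 1e-5 at ten samples per arm are only attainable when
within-group dispersion is modest, and a 25% CV reproduces that order
for the planted fold sizes. The log-normal mean is parameterized so the
group *mean* ratio equals the planted fold exactly
(`meanlog = log(mu) - sd^2/2`), which makes the zero-noise limit exact
and keeps ratio recovery unbiased.

What the generators do not emulate: count-level sampling (library size,
overdispersion), correlated genes, batch structure, annotation bias in
GO corpora, or interactome degree distributions. Passing the recovery
tests therefore shows the statistics behave correctly on cleanly planted
effects of realistic size — it does not certify performance on raw
RNA-seq counts, which are out of scope by design.

## Problem sizes and determinism

The test suite runs entirely on generated data: the hypergeometric
implementation is checked against exact coefficient arithmetic for every
parameterization with N ≤ 30 and against full draw enumeration at tiny
N; Welch recovery uses 200 seeded 10-vs-10 simulations; the antagonism
screen 100 seeded corpora of 44 terms over 500 proteins. These sizes
give the property checks comfortable statistical resolution (a 95%
recovery criterion is estimated from 200 trials) while keeping the whole
suite in the minutes range on one core. Every stochastic step takes an
explicit integer seed, the pipeline manifest records seeds, thresholds
and output checksums, and reruns with an identical config are
byte-identical.

## Known limitations

* Symbols are the only gene identity; inputs using probe ids or
  accession numbers must be mapped upstream.
* The interactome reader speaks a 6-column dialect; full database
  exports need pre-projection or a column map.
* The co-occurrence statistic is a reconstruction (see above); absolute
  ranks from external corpus snapshots are not comparable targets.
* SIF export cannot carry provenance or node roles; GraphML preserves
  both.
* The physical-edge layer of the worked-example network ships as an
  editable fixture file rather than code, because that evidence layer is
  curated and partly enumerated only in supplementary material.
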