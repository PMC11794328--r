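---
title: "Scoring phenotype-drug associations over tripartite networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring phenotype-drug associations over tripartite networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenodrug)
```

## The problem and the model

Drugs act on protein targets; diseases annotate both the genes that harbour
their causal variants and the pathological phenotypes (HPO terms) they
present. phenodrug connects the two ends of this chain: phenotypes are
associated with targets through shared diseases, drugs are associated with
targets through binding assays, and phenotype–drug pairs are then read off
the resulting tripartite phenotype–target–drug network. Such pairs are
candidate drug effects — adverse effects and intended indications are both
captured, since the network carries no sign.

Every projection step uses the same statistic. For outer-layer entities A
and B with $|A|$ and $|B|$ neighbours in a shared middle layer of $N$
entities, of which $k$ are common, the upper-tail hypergeometric
probability

$$P(X \ge k) = \sum_{i=k}^{\min(|A|,|B|)} \frac{\binom{|A|}{i}\binom{N-|A|}{|B|-i}}{\binom{N}{|B|}}$$

measures how surprising the observed overlap is under random draws, and the
hypergeometric index $\mathrm{HyI} = -\log_{10} P(X \ge k)$ puts it on a
filterable scale: thresholds between 2 and 3.5 correspond to p-values of
0.01 down to roughly 0.0003. The index deliberately penalizes promiscuous
nodes — a phenotype annotated to very many diseases needs a proportionally
larger overlap to score well, which is what removes unspecific phenotypes.

Two target notions are supported. The *protein* chain treats genes/proteins
as targets directly. The *domain* chain maps each gene to the CATH
functional families (FunFams) of its protein's domains, scores
phenotype–FunFam pairs with the same index, and derives drug–FunFam pairs
by asking which FunFams are overrepresented among a drug's filtered
targets: with $n$ distinct targets, $x$ of them carrying the FunFam, and a
background proportion $q$ of the target universe carrying it, the binomial
tail $P(\mathrm{Bin}(n, q) \ge x)$ is thresholded strictly at 0.05. The two
chains give deliberately different, complementary pair lists — domains
generalize across homologous off-targets that the protein chain treats as
unrelated.

## Assumptions and key parameters

* **Population size $N$.** Every projection needs a population. The package
  defines $N$ per projection as the number of distinct middle-layer
  entities in the union of the two edge lists being projected. This is
  self-contained and reproducible from the inputs alone; callers with an
  externally defined universe (e.g. all annotated diseases, not only those
  appearing in the extract) can pass `universe =` to override it. The
  override can only enlarge $N$, which makes every p-value smaller — users
  should sweep thresholds rather than compare indices across different
  universe conventions.
* **Index thresholds** (`threshold`, default 2 for the intermediate layers,
  swept over {0, 2, 3, 3.5} for the final phenotype–drug scores; unitless,
  $-\log_{10} p$). The intermediate default keeps pairs with $p \le 0.01$;
  the final sweep reproduces the usual count-versus-stringency table.
  Whether the sweep re-thresholds intermediate layers or only the final
  scores is configurable (`pheno_threshold`, `funfam_threshold`); by
  default the intermediate layers stay at 2 and only the final scores are
  swept.
* **Activity filters** (`filter_activities()`): therapeutic flag 1, assay
  type B, relationship type D, target type "Single Protein"
  (case-insensitive), pChEMBL ≥ 6 — i.e. direct, binding-assay-supported
  interaction with a single protein at ≤ 1 µM potency. The pChEMBL bound is
  inclusive; drugs at any development stage are kept.
* **Enrichment background $q$** (`drug_funfam_enrichment()`): the fraction
  of the *filtered target universe* carrying the FunFam — the enrichment
  question is "among targets", so the druggable universe observed in the
  activity table is the natural reference; `background =` accepts external
  proportions (e.g. whole-proteome frequencies) when available. The 0.05
  threshold is applied to raw p-values (strict inequality); a
  Benjamini–Hochberg option exists but is off by default, matching the
  method's raw-threshold convention.
* **Validation** (`overlap_ratio()`, `literature_overlap()`): predictions
  are first restricted to drugs and phenotypes that occur at least once in
  the gold standard (membership per entity, not per pair), then compared
  with the gold pair set; the null redistributes the predicted connections
  while preserving every node's pair count, 100 replicates by default.
  Which list is randomized is a genuine ambiguity; the package randomizes
  the restricted *predicted* list — the null asks "would degree-matched
  arbitrary predictions hit the gold standard this often?" — and exposes the
  replicate machinery so the alternative can be assembled if wanted. The
  literature test uses the hypergeometric/Fisher upper tail on per-pair
  article counts with corpus size as population, significant below 0.001.

## Numerical choices

Tail probabilities are computed on the log scale (`phyper(..., log.p =
TRUE)`), so overlaps whose p-value underflows a double (below ~1e-308) still
yield finite indices; indices are capped at 300 with a warning rather than
reported as infinite, and the stored `p_value` is derived back from the
capped index so the pair (p, HyI) stays consistent. Emitted pair lists are
sorted by descending index, ties broken lexicographically by the two IDs —
outputs are byte-stable and diff-able. Pairs sharing no middle entity are
never materialized (the projection joins on the middle layer, so the
cross-product of unconnected pairs is never built). Duplicate input edges
are dropped with a message; empty-string IDs are rejected.

The link-randomization sampler performs attempted double-edge swaps
(10×|pairs| attempts by default), rejecting swaps that would duplicate an
existing pair, with each attempt additionally accepted with probability
1/2. The lazy step matters: on small, tightly constrained pair sets the
plain swap chain is periodic (a two-pair matching toggles deterministically
under a fixed even attempt budget), while the lazy chain is aperiodic and
converges to the uniform distribution over degree-preserving
configurations; the tests verify uniformity against exhaustive
configuration enumeration. When no swap succeeds the input is returned with
a warning, which covers rigid degree sequences (e.g. complete bipartite
sets) honestly. A zero random mean yields an infinite ratio, serialized as
the sentinel `"inf"` rather than raising.

## What the synthetic universe emulates

`generate_universe()` draws independent Bernoulli background edges per node
pair in each layer — the simplest exchangeable null, consistent with the
degree-preserving randomization used for validation — and overlays planted
chains: each planted (phenotype, drug) pair is wired through a dedicated
block of 6 diseases shared by its 3 planted target genes, a dedicated
FunFam on those genes, fully criteria-compliant activity records, gold
entries (corrupted at rate 0.1 to emulate gold-standard noise), and
co-mention counts constructed significant. Defaults (60 diseases, 80
genes, 40 phenotypes, 30 FunFams, 30 drugs, densities 0.03–0.05, 5 planted
chains) are sized so the planted phenotype–gene scores clear the index-2
threshold with large analytic margin (per-chain failure probability about
3×10⁻⁴ under the background model) while background pairs mostly do not;
these sizes also keep the full test suite fast. IDs mimic the real formats
(HP:0000001, CHEMBL101, 1.10.8.1-ff-1, OMIM:100001) so format validators
are exercised.

What the fixtures do *not* emulate: the heavy-tailed degree distributions
of real OMIM/ChEMBL extracts, correlated annotations (ontology structure
among HPO terms, FunFam co-occurrence within multidomain proteins),
pharmacological promiscuity classes, or literature-mining biases. Passing
tests therefore demonstrate correctness of the statistics, the filtering
contracts and the recovery machinery — not that the method's real-data
precision generalizes; real-scale pair counts and ratios depend on the
full databases and are out of scope here.

## Design notes and limitations

* The exact form of the co-occurrence statistic and of the enrichment background
  are both delegated to method references in the original description of
  this workflow; the package fixes them to the one-sided
  hypergeometric/Fisher tail and the target-universe proportion
  respectively, and records both in output metadata via provenance
  headers.
* OMIM-like and Orphanet-like annotation sets are processed through the
  same code path but never merged; run them separately and compare.
* No propagation of HPO annotations to ancestor terms is performed; the
  pairing is exactly as annotated.
* The package consumes pre-made extracts (TSV edge lists and count
  tables); it does not query OMIM, Orphanet, ChEMBL, CATH, SIDER, MyChem,
  OxO or PubMed.
* Problem sizes in the tests: exhaustive-enumeration checks run over all
  admissible hypergeometric tuples with $N \le 12$ and binomial settings
  with $n \le 12$; randomization uniformity uses 1,000 seeded replicates on
  ≤8-pair sets against full configuration enumeration; planted-signal
  recovery runs 20 generator seeds at the default configuration. These are
  the package's chosen study conditions for desk-scale verification.
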