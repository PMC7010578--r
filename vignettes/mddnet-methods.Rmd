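---
title: "Methods: pathway cross-talk and interactome subnetwork extraction"
author: "mddnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathway cross-talk and interactome subnetwork extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mddnet implements a three-stage analysis of a curated disease-gene list,
developed around a candidate-gene compilation for major depressive disorder
(MDD): over-representation analysis of the seed genes against gene-set
annotations, construction of a pathway cross-talk network from the enriched
sets, and extraction of a disease-specific subnetwork from a protein-protein
interactome with an approximate Steiner minimal tree. This vignette explains
each model, the tunable parameters and their defaults, the synthetic-data
generator used for validation, and the numerical and design choices made
where the procedure was genuinely open.

## Seed lists, gene sets, and the packaged fixtures

Gene identity throughout is the uppercase symbol string: symbols are trimmed,
case-folded and deduplicated on every input path (`normalize_symbols()`), and
no remote identifier resolution is performed. Gene sets travel in GMT format
(`id`, free-text description, members), seed lists as one-symbol-per-line
text.

`load_mdd_fixtures()` returns the package's transcription of the motivating
MDD study's printed tables:

* **seeds** - 131 candidate genes: the union of every pathway's printed
  seed-gene column plus the genes named in the study's results narrative.
  The study's full curation (255 genes) was published only as supplementary
  material that is not machine-readable, so the packaged seed list is the
  printed subset; analyses that need the full list cannot be reproduced from
  the package alone and are not claimed.
* **pathways** - the 73 significantly enriched KEGG pathways, each restricted
  to its seed-gene members (5 to 32 genes per set). These restrictions, not
  full pathway memberships, are what the cross-talk stage consumes.
* **connectors** - the 35 genes the study's subnetwork introduced from
  outside the seed list. The fixtures are internally consistent: every
  pathway gene is a seed, and no connector is (both are asserted in the test
  suite).

## Over-representation analysis

For a seed list restricted to a background universe of $N$ genes containing
$n$ seeds, a gene set with $K$ members in the universe and $k$ seed members
is scored with the one-sided Fisher exact test of enrichment, which is the
hypergeometric upper tail

$$p = P(X \ge k), \qquad X \sim \mathrm{Hypergeometric}(N, K, n),$$

computed exactly with `stats::phyper` (`hypergeom_sf()`). The test suite
verifies the tail against brute-force enumeration of every $\binom{N}{n}$
seed draw for all valid configurations up to $N = 12$. A two-sided
alternative (`stats::fisher.test`) is available behind the `alternative`
flag; one-sided is the default because enrichment, not depletion, is the
scientific question.

Multiple testing is controlled with the Benjamini-Hochberg step-up
adjustment applied across **all** sets tested in a collection run, not only
the survivors. `run_enrichment()` then applies the study's reporting
filters: keep a set when $k \ge$ `min_seed_genes` (default 5) and FDR $<$
`fdr_threshold` (default 0.05), ordered by ascending $p$ with ties broken by
set id.

Two points deserve emphasis:

* **The background universe matters.** The default universe is the union of
  all genes in the annotation collection, because that is the only universe
  derivable from the inputs themselves; a user-supplied universe overrides
  it. Annotation services use their own (usually undocumented) backgrounds,
  so printed p-values from such services are not expected to be reproduced
  exactly, and the package does not treat them as targets.
* `fdr_threshold = 1` disables the FDR filter entirely (an adjusted value
  can equal 1, so a strict `< 1` comparison would silently drop tied sets).

An optional `prune_subsets` rule (drop a kept set whose seed members are a
subset of a kept set with smaller $p$) stands in for semantic-similarity
redundancy pruning of GO terms; it is off by default and makes no claim to
emulate any specific service.

## Pathway cross-talk network

Two pathways $A$ and $B$ (as seed-gene restrictions) are connected when they
share at least `min_shared` seed genes (default 3), a count rule meant to
keep only biologically meaningful co-membership. Each edge is weighted by

$$J = \frac{|A \cap B|}{|A \cup B|}, \qquad
  O = \frac{|A \cap B|}{\min(|A|, |B|)}, \qquad
  \mathrm{score} = \frac{J + O}{2},$$

and edges are ranked by descending score. For any pair,
$J \le \mathrm{score} \le O$, a property the suite checks on random sets.
The coefficients only weight and rank edges; no score cutoff is applied by
default (`min_score` exposes one for users who want sparser figures).
Pathways left without any edge are dropped from the node list.

### A documented discrepancy

The motivating study reports a cross-talk network of 68 pathways and 325
edges. Applying its stated rule (at least three shared seed genes) to its
own printed pathway tables - transcribed verbatim into the packaged fixture
and corroborated by the independently derived pair checks (the circadian
entrainment / glutamatergic synapse pair shares exactly 14 genes, giving
$J = 14/23$, $O = 14/15$, score $\approx 0.771$) - yields **72 nodes and 877
edges**, with a single isolated pathway (circadian rhythm). No natural
variant we examined reproduces the reported pair of counts: `min_shared = 4`
gives exactly 68 nodes but 548 edges, and no threshold on the shared count,
Jaccard, Overlap, or mean score lands on 325 edges except a circular
"keep the top 325 pairs" cut, which we rejected. The package therefore
implements the stated rule, reports the counts it actually computes, and the
corresponding acceptance test fails loudly with a per-threshold audit rather
than hiding the difference. The per-edge arithmetic is the part that is
independently verifiable, and it checks out exactly.

## Interactome handling

Interactomes are simple undirected `igraph` graphs over gene symbols. Ingest
(`read_interactions()`, TSV or SIF) uppercases symbols, drops
self-interactions, collapses duplicate pairs regardless of orientation, and
records the dropped counts as graph attributes. Merging
(`merge_networks()`) unions nodes and edges and re-asserts the cleaning
invariants; it is commutative, associative and idempotent, and the handshake
identity ($\sum_v \deg v = 2|E|$) is checked after every ingest in the
suite. Vertices are kept in sorted name order - a canonical ordering that
downstream tie-breaking relies on. Source databases are deliberately out of
scope: the interactome is user input, and only synthetic interactomes ship
with the package.

## Approximate Steiner minimal tree

Given an interactome $G$ and terminal set $T$ (the seeds present in $G$),
the Steiner minimal tree problem asks for the smallest tree in $G$ spanning
$T$; it is NP-hard, and mddnet uses the classical shortest-path
2-approximation:

1. restrict to the connected component containing the most terminals
   (ties: the component with the lexicographically smallest member);
2. build the metric closure of the terminals (all pairwise shortest-path
   distances) and take its minimum spanning tree;
3. expand each closure edge back into a concrete shortest path in $G$;
4. take a spanning tree of the union of those paths and repeatedly prune
   non-terminal leaves.

With unit edge weights the result has at most twice the edge count of the
optimal Steiner tree. The suite verifies the bound empirically against an
exhaustive oracle (`brute_force_steiner()`, which enumerates connector
subsets in increasing size and is limited to 16 nodes) on 100 random
instances, and verifies exact optimality on trees, where connecting paths
are unique. Minimizing edges is the tractable proxy for "fewest introduced
connectors"; a `node_weighted` flag reweights edges by their number of
non-terminal endpoints to press harder on connector count specifically.

Choices worth knowing:

* **Determinism.** All graphs are canonicalized to sorted vertex order, so
  identical inputs give identical trees and byte-identical exports; this is
  asserted in the suite.
* **Partial coverage is normal.** Terminals absent from the interactome or
  outside the richest component are reported in `unreachable_terminals`,
  never fatal - curated disease lists routinely contain genes with no
  catalogued interaction. A `forest` mode instead builds one tree per
  component holding at least two terminals.
* **`induce_edges`.** A tree on $m$ nodes has exactly $m - 1$ edges, yet
  published "Steiner subnetworks" often report more edges than that - the
  motivating study's 203-node, 415-edge subnetwork cannot be a tree. The
  likely explanation is re-induction of all interactome edges among tree
  nodes after extraction; `induce_edges = TRUE` reproduces that behaviour
  while the tree itself stays available in the result. The discrepancy is
  surfaced here rather than silently resolved.
* The study's exact subnetwork (203 nodes, 415 edges, 35 connectors) and
  its hub-neighborhood ratio (54 of 69 interactors being seeds) depend on
  an unreleased merged interactome and are therefore not reproduction
  targets; the corresponding *properties* (tree identity, approximation
  bound, connector identification, neighborhood seed fraction) are checked
  on planted synthetic ground truth instead, including a planted
  69-interactor hub with 54 seed neighbors.

`key_node_neighborhood()` reports, for a set of focus genes (e.g.
high-degree hubs of the extracted subnetwork), the fraction of their direct
interactors that are seeds. A focus set with no outside interactors reports
a fraction of 0 with a warning rather than NaN. The choice of focus genes
is the analyst's: the package does not guess a hub-selection rule.

## Synthetic data with known ground truth

`synthetic_config()` fixes the simulated study conditions; the defaults are
the conditions under which the pipeline's recovery claims are made:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 2000 | interactome size (desk-scale stand-in for a ~16k-node merged interactome) |
| `attachment_edges` | 3 | preferential-attachment edges per node (mean degree just under 6, the sparse regime of curated physical interactomes) |
| `n_pathways` | 50 | annotation sets |
| `pathway_size_range` | 5-40 | set sizes, uniform |
| `n_seed_genes` | 150 | seed-list size |
| `n_enriched_pathways` | 5 | planted truly-enriched sets |
| `enrichment_fraction` | 0.6 | fraction of each planted set forced into the seeds (0 = pure null) |
| `crosstalk_core` | 0 | shared core planted across enriched sets (guarantees cross-talk edges) |
| `connector_hub_leaves` | 0 | leaf terminals attached to the top hub (makes the exact Steiner connector known) |

One `rng_seed` drives everything, with per-stage sub-streams derived
deterministically so regenerating one stage does not perturb the others;
every emitted file is byte-identical across runs with the same
configuration.

Under the default conditions, the suite requires that all five planted
pathways rank in the top ten by FDR in at least 95 of 100 replicates, and
that pure-null runs show a raw $p < 0.05$ fraction between 0.02 and 0.09
averaged over 100 replicates (the hypergeometric test is discrete, so the
null rate sits below the nominal 0.05 - around 0.03 at these set and seed
sizes - rather than at it).

What the generator does **not** emulate: literature-curation bias,
annotation databases' real topology and redundancy structure, false-positive
interactions, and any correlation between pathway membership and interactome
topology (memberships are sampled independently of the graph except under
explicit connector planting). Passing recovery tests therefore demonstrates
the statistical machinery on clean, well-specified signals, not performance
on real curation noise.

## Pipeline and reproducibility

`run_pipeline()` orchestrates the stages from a validated `run_config()` (or
a YAML file): input acquisition (packaged fixtures, simulation, or explicit
files), enrichment, cross-talk, and - when an interactome is supplied -
Steiner extraction. Fixtures mode skips enrichment because the packaged
pathway sets are already the enriched, seed-restricted sets. Every output
file is recorded in a JSON manifest with an md5 checksum, the manifest's
summary counts equal counts recomputable from the output files, and a stage
failure aborts with the stage name and a `run.failed` marker. Thresholds
are validated before any stage runs.

Problem sizes used in the test suite - 2000-gene interactomes for the
recovery and null batteries, graphs of at most 14 nodes wherever the
exhaustive Steiner oracle is involved, and 100-replicate simulation
batteries - were chosen so the full suite exercises every claim at
comfortable desk scale.

## Known limitations

* The packaged seed list is the printed 131-gene subset of a 255-gene
  curation; fixture completeness is inherently partial.
* The headline cross-talk counts of the motivating study are not reproduced
  from its printed tables under its stated rule (see the discrepancy note
  above); mddnet reports what the data and the rule actually give.
* Enrichment p-values depend on the chosen universe; agreement with any
  external service requires that service's universe.
* The 2-approximation is a heuristic: on worst-case instances it can return
  up to twice the optimal edge count, and the node-weighted variant remains
  a heuristic for the (also NP-hard) node-weighted problem.
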