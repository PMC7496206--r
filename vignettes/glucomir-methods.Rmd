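---
title: "Methods: glucose-response network reconstruction in glucomir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: glucose-response network reconstruction in glucomir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucomir)
```

## The experimental design this package models

The pipeline targets a three-condition beta-cell profiling design: one
mRNA library (FPKM) and one small-RNA library (RPM) per glucose
concentration — low, moderate, high — with the moderate condition as the
reference. The crucial consequence of one library per condition is that
there is **no replicate variance**: differential expression cannot be a
statistical test and is, by design, a fold-change rule with an abundance
floor. All thresholds are explicit configuration so that other designs can
adjust them; the shipped defaults are the constants of the study design
the package implements.

| Parameter | Default | Unit / meaning |
|---|---|---|
| gene up / down fold change | 1.5 / 0.67 | FC vs moderate, inclusive |
| miRNA up / down fold change | 1.4 / 0.71 | FC vs moderate, inclusive |
| abundance floor | 10 | FPKM (genes), RPM (miRNAs); strict `<` filters, applied per comparison when **both** compared samples are below |
| consensus tools | ≥ 3 of 4 | miRanda, PITA, TargetScan, RNAhybrid |
| miRanda score | ≥ 140 | applied when miRanda supports the pair |
| duplex MFE | ≤ −10 | kcal/mol |
| Ago2 IP floors | 8 / 100 | FPKM (genes) / RPM (miRNAs), `≥` retained |
| hub degree | > 10 | strict, targets per miRNA |
| enrichment top-k | 20 | rows after ranking by raw p |

A stricter gene preset (1.2 / 0.83), the kind of cutoff used at the
quantification step rather than for network construction, is available via
`gene_thresholds("methods")`.

Two wordings of the fold-change bounds circulate in this study design
("exceeded or was equal to" vs "exceeded"); we default to **inclusive**
bounds — an entity exactly at 1.4 is up — with a flag to switch. Similarly,
the abundance floor is a strict "less than" filter, so an entity exactly at
FPKM 10 (or IP FPKM 8, RPM 100) is retained.

### Zero handling

Fold change is `(s + c) / (r + c)` with pseudocount `c = 0` by default;
with `c = 0` and reference 0, the result is `Inf` for a positive sample
and 1 when both are zero. The pseudocount matters little in practice
because the both-samples abundance floor removes double-low entities
before the fold change is interpreted.

## The profile taxonomy

Each entity's verdict pair (low vs moderate, high vs moderate) indexes a
3×3 grid:

|            | high: up | high: nc | high: down |
|------------|----------|----------|------------|
| **low: up**   | V | LI | D |
| **low: nc**   | HI | FLAT | HD |
| **low: down** | I | LD | M |

The named types follow the field's reading of the shapes across
low→moderate→high: I increases continuously (so it is *below* the
reference at low glucose), D decreases continuously, M dips at both
extremes, V peaks at both, and the L/H prefixed types change in only one
comparison. The grid itself is our codification — each legend phrase fixes
its cell uniquely, but the mapping is stated nowhere as a table, which is
why `classify_profile()` spells it out and the tests enumerate all nine
cells.

`inverse_type()` realises the biological pairing assumption (miRNAs act as
negative regulators): I↔D, M↔V, LD↔LI, HI↔HD. It is a fixed-point-free
involution on the eight non-FLAT types, and classification commutes with
verdict flipping: classifying the mirror-image expression equals inverting
the class.

Entities filtered in exactly one comparison have no defined cell. We
assign them FLAT with a recorded note (`filtered_one`) rather than
dropping them: bookkeeping stays total over the input, and FLAT already
excludes them from pairing. The original design is silent on this case;
this is our choice.

## Evidence resolution and the consensus rule

Experimental evidence takes precedence over prediction: Level 1 (reporter
assay / Western blot class) over Level 2 (CLIP-seq class) over Level 3
(consensus prediction). Merging evidence fragments ORs the experimental
flags — a duplicate row can never downgrade a pair — and unions per-tool
hits, keeping the best duplicate hit per tool (lowest MFE, then highest
score). Merged tables are sorted, so merging is order-independent.

Three points in the consensus rule were genuinely open and are resolved as
explicit, flagged choices:

* **MFE sign.** The rule is quoted as "minimum free energy ≤ 10", but
  hybridisation energies are negative and a literal `≤ 10` would accept
  every duplex; we read it as MFE ≤ −10 kcal/mol (equivalently |MFE| ≥ 10).
* **Which tool's MFE.** Unstated; by default **any** supporting hit may
  satisfy the cutoff (`mfe_all_hits = TRUE` switches to all-hits).
* **Is miRanda mandatory?** The score constraint cannot bind for pairs
  miRanda never predicted, and "≥ 3 of 4 tools" must remain satisfiable
  without it, so by default the score bound applies only when a miRanda
  hit is present (`require_miranda = TRUE` makes it mandatory).

The predicate is tested against an independent brute-force oracle over all
tool subsets crossed with boundary score/MFE values (> 600 cases).

## Network construction

An MTI edge (m, g) for condition *c* requires: resolved level ∈ {1, 2, 3};
both entities non-FLAT; `profile(g) = inverse_type(profile(m))`; and m
actually changed under *c*. The last clause implements the condition
semantics: an HD miRNA (changed only at high glucose) appears only in the
high-glucose network, while types changed in both comparisons (I, D, M, V)
contribute to both conditions' networks with their per-condition
direction. Whether such types should be double-counted across
condition-specific views is not decidable from the design; we include
them in both and record that choice in the run manifest.

Edges partition into four sub-networks by (condition, miRNA direction).
Hubs are miRNAs with out-degree strictly greater than 10. The TF→miRNA
layer keeps a table row when the TF gene and the miRNA are both
differentially expressed, carrying the regulation sign. All orderings are
lexicographic, so outputs are reproducible byte for byte.

Ago2 IP intersection is **entity-level**: an edge is promoted to Level 4
when its miRNA and its gene are each detected in the IP libraries above
the floors. The alternative — interaction-level intersection — would need
binding-site calls the IP expression tables do not contain. A consequence
worth knowing: a pair can be promoted although it was not itself planted
as IP-supported, if both endpoints participate in other IP pairs; the
tests score the level-4 set at entity level accordingly. Promotion is
monotone (output ⊆ input; raising either floor never adds edges), which is
the substance behind the large MTI-set reductions this design reports.

## Enrichment

Functional over-representation is the exact upper-tail hypergeometric
test, P(X ≥ k) for X ~ Hypergeom(N, K, n), implemented via the stats
distribution functions and verified in tests against direct combinatorial
enumeration for N ≤ 25 (tolerance 1e-12). We deliberately do not emulate
any web-service enrichment score: those depend on proprietary backgrounds
and versions and are not reproducible offline, so their printed p-values
are not comparison targets. BH correction is the default (Bonferroni
available) and raw p-values are always emitted. The background universe
defaults to the filter-passing expressed genes — not the whole genome —
because that is the set from which network genes could have been drawn;
it is configurable. Term sets come either from the annotation table or
from a user GMT file.

## The synthetic-data generator

The generator emulates what the pipeline consumes, with known truth:

* **Abundances.** Moderate-condition abundances are log2-normal (mean 7,
  sd 1 on the log2 scale, i.e. a median around 128 FPKM/RPM), floored at
  40 so that planted entities always survive the abundance filters — the
  floor makes "planted implies recoverable" a construction, not a
  probabilistic hope. No published abundance distribution exists for this
  design; log-normal is a stand-in, not a claim about the data.
* **Effects.** Each entity gets a profile type by deterministic
  largest-remainder allocation of the mix (so planted counts are exact),
  then low/high values are the moderate value times
  `2^(±effect_size_log2)` along the type's signature, times multiplicative
  log-normal noise (`noise_log2_sd`, default 0). Noise is multiplicative
  because abundances are positive and the analysis lives in log2
  fold-change space. The configuration refuses effect sizes that do not
  strictly exceed the calling bounds, since such a study could not recover
  its own plants.
* **True MTIs** are sampled only among non-FLAT inverse-profile pairs.
  This is deliberate: the planted network must be recoverable by the
  inverse-expression rule for precision/recall against truth to measure
  the pipeline rather than the plant. Tiers (strong/weak/predicted,
  default 20/20/60%) are allocated deterministically; predicted-tier pairs
  get 3–4 tool hits with passing scores and MFEs. Decoys (default 0.5 per
  true pair, uniform over non-true pairs) are constructed to fail the
  consensus rule by exactly one of three modes: two tools only, a
  sub-threshold miRanda score, or all MFEs above the cutoff.
* **IP support** is an independent coin per true pair (default 0.4);
  supported entities receive IP abundances above the floors, all others
  strictly below.
* **TF layer and annotations**: planted DE hub TFs plus FLAT decoy TFs;
  G/O/E/C keywords and term memberships as independent Bernoulli draws.
  `plant_enriched_term()` provides the positive control for enrichment
  (a term five-fold denser inside a query set).

Everything derives its stream from one seed (per-stage offsets), so a
simulation is bit-reproducible and stages remain individually
deterministic.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: count-level sampling noise (no negative
binomial), miRNA family structure and shared seed sites, correlated
targets, abundance-dependent detection, batch effects, or the fact that
real inverse-expression pairs may arise indirectly. The synthetic study
validates the machinery, not the biology.

## Problem sizes and determinism

The reference study is 200 genes × 60 miRNAs with 50 planted MTIs — large
enough that every profile class, evidence tier and sub-network is
populated, small enough that exact enumeration oracles (consensus
truth-table, hypergeometric enumeration, brute-force degree counts) stay
practical in the test suite. Noise-robustness checks use 20 seeds at
`noise_log2_sd = 0.1`, where profile recovery stays essentially complete
(the nearest calling bound is ~0.49 log2 units away, almost five noise
standard deviations). Pipeline runs write a manifest with a parameter
fingerprint (file locations excluded, so relocated reruns match), the
seed, and per-stage row counts; reruns with identical configuration and
seed are byte-identical.

## Known limitations

* Fold-change-only calling cannot separate biological change from
  single-library technical variation; that is inherent to the
  no-replicate design, not a software choice.
* Entity-level Ago2 intersection over-approximates interaction-level
  support (see above).
* The condition semantics double-count both-comparison types across the
  condition views; consumers who want disjoint views can filter on
  profile type.
* Headline counts from any particular wet-lab study (total DEG/DEmiR
  numbers, specific network sizes) depend on its libraries and database
  versions and are not recomputable from synthetic data; the package's
  claims are the property-level ones its tests and acceptance script
  actually compute.
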