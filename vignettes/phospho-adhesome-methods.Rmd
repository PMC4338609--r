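---
title: "Methods: subtractive spectral-count enrichment and phospho-adhesome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subtractive spectral-count enrichment and phospho-adhesome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adhesiomics)
```

## The analysis problem

Adhesion-complex isolations are compared against a control pulldown under
label-free spectral counting: two conditions (treatment = ligand-engaged
integrin isolation, control), each with biological replicate LC-MS/MS runs.
Because both isolations carry abundant contaminants, specificity is defined
subtractively: an identification is condition-specific only if it is
sufficiently *enriched* in treatment over control and supported by a minimum
number of spectra. This vignette documents the models, parameter choices and
numerical conventions the package uses, and what its synthetic-data tests do
and do not demonstrate.

## Normalization and fold change

Protein-level abundance is the normalized spectral abundance factor,
`NSAF = (SC/MW) / Σ(SC/MW)` per run (`nsaf()`), with molecular weight in
kDa. Dividing by molecular weight corrects the length bias of spectral
counts; dividing by the run total corrects run-to-run loading, and makes the
values sum to one per run — an invariant the test suite checks to 1e-9.
The run-total normalizer is deliberately the summed `SC/MW`, not the number
of distinct identifications: the two readings differ only by a per-run
constant, which cancels in every fold change, so the choice cannot affect
any downstream pass/fail decision.

Fold change is the ratio of condition means across replicates. When the
control mean is zero and the treatment mean positive, the fold change is
`+Inf`: control-absent identifications are the strongest evidence of
specificity, and the filters treat them as passing the fold criterion. An
optional pseudocount (`threshold_policy(pseudocount = c)`) adds `c` to both
means for users who prefer finite ratios; it is off by default because the
default reproduces the subtractive semantics exactly. Entities with no
spectra in either condition carry no evidence and are dropped with a
message.

Phosphosites are compared on mean *raw* spectral counts, not NSAF: a site
has no molecular weight of its own, and within-site comparisons across runs
need no length correction.

## Threshold policy

`threshold_policy()` encodes the filters:

| parameter | default | role |
|---|---|---|
| `protein_min_fold` | 2 | minimum NSAF fold change for proteins |
| `protein_min_spectra` | 6 | minimum summed treatment spectra per protein |
| `site_fixed_fold` | 9 | fixed site fold threshold |
| `site_fold_rule` | `"fixed"` | or `"mean_plus_2sd"` |
| `sd_multiplier` | 2 | multiplier for the adaptive rule |
| `site_min_spectra` | 2 | minimum summed treatment spectra per site |

All comparisons are inclusive (`>=`), reading the thresholds as "at least".
The two site rules coexist because a ninefold cutoff and a
mean + 2 s.d. criterion coincide on the data the defaults were modelled on;
whether the ninefold value was the computed criterion rounded or an
independent floor is not determinable, so both are implemented and the fixed
rule — which is reproducible without access to the fold-change distribution
— is the default. The adaptive threshold uses the sample (n−1) standard
deviation on the *linear* fold-change scale, over finite fold changes only
(infinite ones are excluded from the distribution but auto-satisfy the fold
criterion); a log2-scale variant is available via `sd_log_scale = TRUE`
since fold-change distributions are right-skewed, but the linear scale is
the default because it preserves "ninefold" semantics directly.

When both gates fail, `fail_reason` reports `below_fold` — the gates are
evaluated in the order the policy states them, and only one reason is
recorded per entity.

Sites are filtered after aggregating peptide-level rows to unique
(accession, position) records, summing counts per run. Site-level filtering
is the level at which every downstream analysis (residue composition,
kinase prediction) operates; the per-peptide alternative can be recovered by
passing unaggregated records with distinct positions.

## Merging and composition

A phosphoprotein is any accession with at least one passing site, whether or
not it passed the proteomic filter. `merge_catalogues()` partitions the
union into proteomic-only / both / phospho-only compartments and reports the
percentage increase contributed by phospho-only identifications.
Percentages in `residue_composition()` are rounded half away from zero to
one decimal, which reproduces integer summaries exactly; an empty subset is
flagged undefined rather than reported as zeros-that-sum-to-zero.

## Network analysis

The interactome is a simple undirected graph (self-loops dropped, duplicate
and reversed edges collapsed). Hop distances from the seed protein are
breadth-first geodesics; unreachable proteins are reported in a separate
bucket, never dropped. Composition bands are *cumulative* (hop ≤ k),
matching "within k binding interactions" phrasing; exact-hop bands are also
emitted for diagnostics. The seed is excluded from every band — the
neighbourhood is *of* the seed, not including it.

By default `run_pipeline()` restricts the graph to detected proteins before
computing distances, since neighbourhood counts refer to identified
proteins; `restrict = "full"` computes distances on the complete interactome
instead. The seed protein is always retained in the restricted graph, even
when it fails the filters, because it anchors the decomposition. Both modes
are exposed because published neighbourhood counts do not state which graph
they were computed on.

## Term enrichment

`term_test()` is the one-tailed hypergeometric upper tail `P(X ≥ k)` with
universe size `N`, term size `K`, query size `n` and overlap `k`, computed
through `stats::phyper` (exact log-gamma arithmetic — no normal
approximation, since small counts dominate). The `"ease"` variant replaces
`k` by `k − 1` (floored at zero), the conservative convention of chart-style
enrichment reports, and is the default. Bonferroni correction multiplies by
`m` = the number of terms with at least one query member, matching how
chart reports count their tests; `correct_over = "all"` uses every annotated
term instead. Reported terms need corrected p below `alpha` (default 0.05)
and at least `min_count` (default 2) query proteins. Term hierarchies are
not modelled: annotation maps are flat sets over an explicit background
universe, which is an input precisely because "the genome" is
environment-dependent.

## Kinase prediction

A site's 15-mer window (±7 residues, site at index 8, `-` padding protein
termini) is scored against a kinase model as the mean over the model's
substrate windows of the summed position-wise substitution-matrix
similarity; the gap symbol contributes zero. The bundled matrix is BLOSUM62
(plain-text data under `inst/extdata/`); the group-based idea — similarity
to known substrates of a kinase or family, not a trained motif model — is
implemented transparently rather than reproducing any particular tool's
trained internals.

Per-kinase cutoffs are calibrated to a target empirical false-positive rate
on background windows: the threshold is the smallest background score `t`
with `frac(score > t) ≤ target`, ties broken upward (conservative), with
`target = 0` giving the background maximum and `target = 1` giving `-Inf`.
Passing requires a score *strictly above* the cutoff, consistent with
"cut-off" semantics. The stringent convention is 2% for serine/threonine
kinases and 4% for tyrosine kinases. S/T models never score
tyrosine-centred windows and vice versa. Calibration requires at least 100
matching-class background windows; the pipeline draws its backgrounds from
the proteome-frequency window generator, seeded from the run seed, and the
source is recorded in the manifest.

Known-pair validation classifies each (site, kinase) pair as `correct` (the
known kinase passes at that site), `different_family_member` (a passing
prediction shares the known kinase's group), `kinase_not_in_tool`, or
`no_prediction` (no passing prediction matches the kinase or, under family
credit, its group — including the case where unrelated kinases pass; the
four-category scheme has no separate slot for that outcome).

## The synthetic-data generator

`simulate_counts()` draws negative-binomial counts with per-protein mean
`baseline_mean` (default 10 spectra/run), multiplied by `enrichment_factor`
(default 8) for enriched proteins in treatment runs; non-enriched proteins
behave identically in both conditions, supplying contaminant-style
negatives. The default dispersion 0.02 (variance = mean + 0.02·mean²,
BCV ≈ 0.14) reflects the low biological variability of replicate isolations
from a single cell line under a controlled workflow; dispersion 0 recovers
the Poisson limit, and the test suite checks the variance/mean ratio in both
regimes. The default design is 2,000 proteins, 10% enriched, three
replicates per condition, molecular weights uniform on 10–300 kDa.

`simulate_interactome()` grows a preferential-attachment graph (two edges
per new node), giving a connected simple graph with hubs — the degree shape
PPI networks show. `simulate_phosphosites()` places sites on proteins within
the hop range covered by `residue_profile_by_hop`, draws each acceptor
residue from the profile at the protein's hop distance, and plants kinase
motifs on a stated fraction of sites by copying a substrate window with a
per-position mutation probability (centre never mutated). A gap in the
profile for an occurring hop distance is fatal rather than silently
extrapolated. Site counts are control-absent-dominated (treatment mean 3,
control mean 0.1 spectra/run), the regime subtractive phosphoproteomics
operates in.

What the generator does *not* emulate: peptide-level missingness and
misidentification, site-localization ambiguity (localization scores are
simulated as plain annotations), shared peptides and protein inference,
biases in protease accessibility, and any real interactome's topology
beyond heavy-tailed degree. Passing recovery tests therefore demonstrates
that the *implemented rules* behave as designed under their own stated
assumptions — not that the rules are optimal for any particular real
dataset.

## Problem sizes and numerical conventions in the test suite

The suite exercises: filter equivalence against independently coded
brute-force oracles on 200 random toy tables per level; NSAF conservation
on 100 random matrices; recovery on the default 2,000-protein design
(sensitivity and false-discovery proportion of the protein filter) plus 20
null simulations; breadth-first distances against a Floyd–Warshall oracle
on 200 random graphs of up to 20 nodes; hypergeometric and EASE p-values
against subset-enumeration for every configuration with a universe of at
most 12 (tolerance 1e-12); a designed cumulative phosphotyrosine gradient
(25% → 5% over hops 1–3, 3,000 sites) recovered within binomial 99%
confidence intervals; planted-motif recovery (three kinases, 10% per-position
mutation, 500 sites) with top-ranked assignment checked against the
generating kinase, and the calibration contract (held-out FPR at most 1.5×
target) over 20 seeds with 8,000 calibration and 4,000 held-out windows per
class; and byte-identical outputs for repeated pipeline runs at a fixed
seed. These sizes keep each property statistically meaningful at desk
scale.

## Limitations

* The filters are deterministic rules, not statistical tests: no p-values,
  no FDR control at the protein level. That is faithful to the subtractive
  design the package implements.
* Accessions are opaque strings; a two-column mapping table can bridge
  identifier namespaces, but no live identifier service is consulted.
* The kinase scorer is a transparent similarity model; it will not
  reproduce the per-kinase site counts of trained tools whose internal
  matrices and backgrounds are not public.
* Real enriched-term lists and neighbourhood counts depend on specific
  annotation and interactome releases, which are inputs here, not bundled
  resources.
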