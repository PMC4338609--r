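# adhesiomics

Label-free proteomics and phosphoproteomics of isolated integrin adhesion
complexes face one central analysis problem: a pulldown is never clean, so
"adhesion-complex protein" must be defined *subtractively* — by enrichment of
spectral counts in the adhesion-complex isolation (e.g. fibronectin-ligated
integrins) over a control isolation (e.g. transferrin receptor), across
biological replicates. `adhesiomics` implements that subtractive analysis as
a tested, reusable R pipeline, together with the downstream stages used to
characterize a condition-specific "phospho-adhesome": merging of proteomic
and phosphoproteomic identification sets, interactome hop-neighbourhood
analysis around a seed receptor, term over-representation, and kinase-
substrate prediction calibrated to a target false-positive rate. A
synthetic-data generator with known ground truth makes the whole pipeline
testable end to end without any external download.

It is written for proteomics bioinformaticians and cell-adhesion labs who
want the filtering rules explicit, auditable and reproducible rather than
buried in a spreadsheet.

## The model

**Normalization.** Protein abundance uses the normalized spectral abundance
factor. For protein *p* with molecular weight *MW_p* and spectral count
*SC_{p,r}* in run *r*:

```
NSAF_{p,r} = (SC_{p,r} / MW_p) / Σ_q (SC_{q,r} / MW_q)
```

so each run's NSAF values sum to 1.

**Subtractive filters.** With mean NSAF per condition across replicates,
`FC = mean_treatment / mean_control` (infinite when control-absent):

* a **protein** is adhesion-complex-specific iff `FC ≥ 2` **and** its summed
  raw treatment spectra are `≥ 6`;
* a **phosphosite** (compared on mean raw spectral counts) is specific iff
  `FC ≥ 9` — or, under the adaptive rule, `FC ≥ mean + 2·sd` of the finite
  fold-change distribution — **and** its summed treatment spectra are `≥ 2`.

All comparisons are inclusive ("at least"); both site rules are provided
because a fixed ninefold cutoff coincides with a mean + 2 s.d. criterion on
the original data.

**Downstream.** The union of passing proteins and phosphoproteins is
partitioned Venn-style and cross-referenced against an adhesome annotation;
phospho-residue composition (pS/pT/pY) is computed per protein subset and
per k-hop band of a protein-interaction network around a seed (breadth-first
geodesics, cumulative bands "within k interactions"). Term enrichment is the
one-tailed hypergeometric upper tail `P(X ≥ k)` (or the conservative EASE
variant, `k → k−1`) with Bonferroni correction over terms that overlap the
query. Kinase prediction scores each ±7-residue site window by mean
BLOSUM62 similarity to a kinase's substrate windows, with per-kinase cutoffs
set to an empirical background false-positive rate (2% for S/T kinases, 4%
for tyrosine kinases) and known-pair validation in four outcome categories.

## Worked example

```r
library(adhesiomics)

demo <- make_demo("demo", seed = 1)          # synthetic inputs + ground truth
counts <- read_spectral_counts(demo$counts_path)
counts
#> <spectral_counts> 800 proteins x 6 runs (3 treatment, 3 control); total spectra 64862

res <- filter_proteins(counts)               # twofold + six-spectra gates
glance(res)
#> # A tibble: 1 × 6
#>   level       n n_pass n_control_absent fold_threshold min_spectra
#> 1 protein   800     80                0              2           6

sites <- read_phosphosites(demo$sites_path)
site_res <- filter_sites(sites)              # ninefold + two-spectra gates
catalogue <- merge_catalogues(res, site_res)
catalogue
#> <merged_catalogue> total 315: proteomic-only 51, both 29, phospho-only 235 (catalogue increase 293.8%)

edges <- read_edge_list(demo$edges_path)
g <- build_graph(edges, detected = union(catalogue_accessions(catalogue), demo$seed_node))
decomp <- hop_distances(g, demo$seed_node)
glance(decomp)
#> # A tibble: 1 × 6
#>   seed   n_nodes n_hop1 n_hop2 n_within2 n_unreachable
#> 1 P00001     315     18     38        56            87
```

The 80 passing proteins are exactly the 80 proteins the generator enriched
eightfold (sensitivity 1, no false discoveries at this scale); merging adds
235 phosphoproteins never seen proteomically, and 56 detected proteins lie
within two binding interactions of the seed. `run_pipeline()` chains every
stage and writes per-stage TSVs plus a JSON manifest; `autoplot()` methods
and `plot_hop_composition()` give quick ggplot2 views of each result.

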