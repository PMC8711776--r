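# nnpclust

Protein complexes — stable assemblies of physically interacting proteins —
show up in protein–protein interaction (PPI) networks as dense subgraphs,
but high-throughput interaction data are noisy enough that density alone is
a poor detector. **nnpclust** is an R package for researchers who want to
predict complexes from an interaction list plus Gene Ontology annotations,
and to benchmark those predictions against a curated catalogue. It
implements a two-stage method:

1. **Similarity weighting.** Every edge *(u, v)* is re-scored by averaging,
   over the neighbour pairs *(u₁, v₁) ∈ N(u) × N(v)*, the mean of a
   topological and a functional similarity:

   - Jaccard coefficient  *J(u₁, v₁) = |N(u₁) ∩ N(v₁)| / |N(u₁) ∪ N(v₁)|*
   - simGIC-style semantic similarity
     *se(u₁, v₁) = Σ_{T ∈ A∩B} IC(T) / max{IC(A), IC(B)}*, with
     *IC(T) = −log p(T)* the information content of a GO term and *A, B* the
     proteins' ancestor-closed annotation sets.

   Within-module edges score high, spurious edges score low; an optional
   conditional threshold (a two-component Gaussian-mixture boundary on the
   weight distribution) removes the noise mode.

2. **Seed-and-extend clustering.** Nodes are ranked by average weighted
   degree *AWD(v) = Σᵢ w(v, vᵢ)/|V|* and grown into complexes: a candidate
   is admitted when its weighted neighbour ratio
   *WN(v) = WD(v) / (WD(v) + cut₂(v))* — its weighted degree relative to the
   leakage from its neighbourhood into the second-order shell — reaches the
   threshold `wnt` (default 0.22), both globally and relative to the growing
   complex. Candidate complexes below the size floor are dropped, and of any
   two complexes with overlap ratio
   *OL(C₁, C₂) = |C₁ ∩ C₂|² / (|C₁|·|C₂|) ≥ 0.2* only the tighter
   (higher weighted density *WDt = 2Σw / (n(n−1))*) survives.

Predictions are scored by overlap matching against a reference set
(recall / precision / F1 at *OL ≥ 0.2*, perfect matches at *OL = 1*) and by
hypergeometric term enrichment. A planted-complex generator emulates all
four input formats (pair list, OBO, GAF, complex catalogue), so the whole
pipeline runs and tests itself without any download.

## Worked example

```r
library(nnpclust)

spec <- fixture_spec(rng_seed = 7)              # 15 planted complexes
sim  <- generate_network(spec)
go   <- generate_ontology_and_annotations(spec, sim$truth, sim$membership)
ann  <- propagate_annotations(go$annotations, go$ontology)

weighted <- weight_network(sim$network, ann,
                           config = similarity_config(threshold_mode = "mixture"))
weighted
#> <ppi_network> 89 nodes, 264 edges (weighted)
#>   weight range: [0.1699, 0.5791]

found <- detect_complexes(weighted)             # wnt = 0.22, ol = 0.2
head(glance(found), 3)
#> # A tibble: 3 × 4
#>   complex_id  size seed  tightness
#>   <chr>      <int> <chr>     <dbl>
#> 1 C001           8 P0025     0.468
#> 2 C002           6 P0055     0.425
#> 3 C003           4 P0065     0.423

evaluate_complexes(found, sim$truth)
#> <evaluation_report> (OL >= 0.20)
#>   predicted: 12 (matched 12)   reference: 15 (matched 12)
#>   recall 0.8000   precision 1.0000   F1 0.8889
#>   perfect matches 6   average size 5.00   coverage 60

head(enrich_complexes(found, ann, universe = network_nodes(sim$network)), 3)
#> # A tibble: 3 × 7
#>   complex_id term           m n_term  size  p_value significant
#>   <chr>      <chr>      <int>  <int> <int>    <dbl> <lgl>
#> 1 C001       GO:1000006     8      8     8 1.18e-11 TRUE
#> 2 C002       GO:1000011     6      6     6 1.50e- 9 TRUE
#> 3 C003       GO:1000013     3      4     4 1.31e- 4 TRUE
```

Reading: 12 complexes were predicted, every one of them overlaps a planted
complex at *OL ≥ 0.2* (precision 1.00), 12 of the 15 planted complexes were
recovered (recall 0.80), six are exact member-for-member matches, and each
predicted complex is most enriched for its complex's signature GO term at
*p < 0.01*. The three missed complexes are small, weakly annotated ones
whose internal edges fall into the noise mode — see the methods vignette
(`vignettes/complex-detection.Rmd`) for what the synthetic benchmark does
and does not demonstrate.

Real data go through the same verbs: `read_interactions()` +
`build_network()` for a two-column pair list, `parse_obo()` / `parse_gaf()`
for GO inputs, `read_complexes()` for a reference catalogue.

## Command line

A thin CLI over the same functions ships in `inst/cli/nnp.R`:

```sh
Rscript inst/cli/nnp.R simulate --out-dir demo --seed 7
Rscript inst/cli/nnp.R weight   --network demo/pairs.tsv --obo demo/ontology.obo \
                                --gaf demo/annotations.gaf --threshold-mode mixture \
                                --out demo/weighted.tsv
Rscript inst/cli/nnp.R detect   --weighted demo/weighted.tsv --out demo/complexes.txt
Rscript inst/cli/nnp.R evaluate --pred demo/complexes.txt \
                                --ref demo/reference_complexes.txt --out demo/report.tsv
```

Every stage writes a JSON manifest (input checksums, parameters, counts)
next to its output, and repeated runs are byte-identical.

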