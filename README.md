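# psychrobin

Pulling one genome out of a simple metagenome — and asking what keeps its
owner alive in the cold.

Sequencing a cyanobacterium from a non-axenic culture yields the target
organism plus its commensal microbiota. In the de Bruijn assembly graph,
each organism tends to occupy its own connected component, and its contigs
share a characteristic read depth. psychrobin automates the
genome-extraction procedure built on those two signals, and then
characterises the extracted genome the way cold-adaptation studies do. It
is aimed at microbial genomicists working with enrichment cultures or
simple metagenomes who want the extraction to be scripted, parameterised
and testable rather than performed by eye in a graph viewer.

## The method

Given an undirected contig graph with per-node length `l_v` and read depth
`d_v`:

1. **Seed** nodes carrying marker-gene BLAST hits (e ≤ 1e-10); for
   cyanobacteria, the core CyOGs — orthologous groups exclusive to
   cyanobacteria and plastids — are natural markers.
2. **Fit** the depth model: centre `c` = length-weighted median of seed
   depths; depth `d` is *similar* iff `c/f ≤ d ≤ c·f` (fold `f` = 2).
3. **Propagate** labels from seeds by breadth-first search, crossing an
   edge only into depth-similar nodes (or sweep whole seeded components,
   gating by depth — both conventions provided).
4. **Rescue** unconnected depth-similar contigs through a classification
   table (target-taxon / other / unknown).
5. **Filter**: drop bin members with depth < 10, then length < 200 bp
   (strict cuts, in that order).

Downstream characterisation: assembly statistics (N50, GC%, coding
density), proteome amino-acid indices used in cold-adaptation analyses
(Pro%, Arg:Lys), a configurable cold-shock gene-family census, and
rule-based detectors for Wzy- and ABC-dependent exopolysaccharide-export
clusters, Wsp chemosensory cassettes, GGDEF-domain diguanylate cyclases
and alg44-like HlyD genes. Synthetic-data generators with truth labels
(`simulate_community()`, `simulate_proteome()`, `simulate_annotation()`)
make every stage testable without downloads.

## Worked example

Simulate a two-organism community (target at depth ~15, contaminant at
~150, three spurious bridge edges between them), then extract the target:

```r
library(psychrobin)

spec <- community_spec(
  list(organism("cyano", 40, depth_mean = 15, depth_sd = 1, target = TRUE),
       organism("contam", 30, depth_mean = 150, depth_sd = 1)),
  n_cross_edges = 3, cross_style = "bridge", markers_per_target = 5,
  seed = 1)
sim <- simulate_community(spec, dir = tempfile())

bin <- extract_genome(sim$graph, sim$paths$hits,
                      classifier = sim$paths$classifier)
bin
#> genome bin extracted by marker-seeded depth-gated propagation
#>   seeds: 5 nodes; depth band [7.316, 29.27] (center 14.63, fold 2)
#>   bin: 40 contigs, 131,780 bp, N50 3,546, mean depth 15.12, GC 50.12%
#>   labels: target 40, unassigned 33

bin_metrics(bin$assignment, sim$truth$target_nodes)
#> $precision  [1] 1
#> $recall     [1] 1
```

The five marker hits seed five nodes; the fitted band `[7.3, 29.3]`
contains every target node and excludes both the depth-150 contaminant
and the depth-3 bridge nodes, so gated propagation recovers exactly the
40 planted target contigs (precision = recall = 1). `plot(bin)` shows the
depth/length scatter with the band; `summary(bin)` breaks the labels down
by provenance; `run_bin()` / `run_report()` drive the same pipeline from
a YAML config and write TSV/JSON/FASTA outputs.

On the characterisation side:

```r
hl <- read_gene_table(system.file("extdata", "bc1401_hlyd_genes.tsv",
                                  package = "psychrobin"))
length(find_alg44_like(hl))
#> [1] 14
```

— the scan over the published HlyD-gene complement of *Phormidesmis
priestleyi* BC1401 (an Arctic cyanobacterium from a Greenland cryoconite
hole) returns its 14 alg44-like genes: candidate c-di-GMP-pathway
components in a genome whose annotation lacks canonical PilZ receptors.

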