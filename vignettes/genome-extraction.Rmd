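---
title: "Extracting one genome from a metagenome assembly graph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting one genome from a metagenome assembly graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psychrobin)
```

## The problem

Sequencing a cyanobacterium straight from a non-axenic culture yields a
*simple metagenome*: the organism of interest plus its commensal
microbiota. In a de Bruijn assembly graph the organisms tend to occupy
distinct connected components, and each organism's contigs share a
characteristic read depth, because depth scales with the organism's
abundance in the culture. psychrobin turns those two signals — graph
connectivity and depth similarity — into an automated, testable
genome-extraction procedure, and then characterises the extracted genome
(assembly statistics, cold-adaptation proteome indices, cold-shock gene
census, polysaccharide-export and chemosensory gene clusters).

## The binning model

Let $G = (V, E)$ be the undirected contig graph, where each node $v$ has a
length $\ell_v$ (bp) and a read depth $d_v$ (the k-mer coverage printed in
the assembler's output, taken verbatim). The procedure:

1. **Seeding.** Marker genes — in the motivating application, the core
   cyanobacterial orthologous groups (core CyOGs), which occur only in
   cyanobacteria and plastids — are searched against the assembly with
   tBLASTn, and hits with $e \le 10^{-10}$ mark their contigs as *seeds*.
2. **Depth model.** The centre $c$ is the *length-weighted median* of seed
   depths (each seed contributes one observation per bp). A depth $d$ is
   *similar* iff $c/f \le d \le c \cdot f$ with band fold $f = 2$ by
   default. The seed-depth mean is reported alongside, but the weighted
   median drives the gate: it is robust to the occasional mis-seeded
   repeat contig, which a mean is not.
3. **Propagation.** Labels spread from all seeds by breadth-first search,
   crossing an edge only into depth-similar nodes (`gated-bfs`). A
   `component` mode is also provided: every node sharing a component with a
   seed is swept in if depth-similar, and marked contaminant otherwise.
   The two modes differ exactly on *bridge* topologies — a spurious edge
   through a low-depth node: gated propagation stops at the bridge, while
   component mode relies on the depth gate alone.
4. **Rescue.** Unconnected nodes whose depth is in-band are looked up in a
   classification table (automating a manual BLAST check): `target-taxon`
   joins the bin, `other` is rejected, `unknown` is left for review
   (strict mode) or rejected (conservative mode).
5. **Filter cascade.** Finally, bin members with depth $< 10$ are dropped
   (residual contamination), then members shorter than $200$ bp
   (repository standards). Both cuts are strict inequalities, applied in
   that order, and the cascade is idempotent.

Seeds are always labelled target by stage 3 regardless of their own depth;
only the filter cascade can remove them.

### Parameters

| parameter    | default    | units | meaning                                        |
|--------------|-----------|-------|------------------------------------------------|
| `evalue_max` | $10^{-10}$ | –     | marker-hit retention threshold                 |
| `fold`       | 2.0        | ×     | multiplicative half-width of the depth band    |
| `min_depth`  | 10         | ×     | strict lower depth cut after propagation       |
| `min_length` | 200        | bp    | strict lower length cut after the depth cut    |
| `mode`       | gated-bfs  | –     | propagation convention                         |
| `unknown`    | strict     | –     | handling of classifier-unknown rescued nodes   |

The fold-2 default is chosen so that a seed population centred near depth
14–16 keeps its whole depth band above the fixed cut at 10 while excluding
organisms a few-fold more or less abundant; any contaminant separated by
more than ~4× in depth falls outside the band on every edge crossing.

### A worked run on synthetic data

```{r binning}
spec <- community_spec(
  list(organism("cyano", 40, depth_mean = 15, depth_sd = 1, target = TRUE),
       organism("contam", 30, depth_mean = 150, depth_sd = 1)),
  n_cross_edges = 3, cross_style = "bridge", markers_per_target = 5,
  seed = 1)
sim <- simulate_community(spec, dir = tempfile())
bin <- extract_genome(sim$graph, sim$paths$hits,
                      classifier = sim$paths$classifier)
bin
bin_metrics(bin$assignment, sim$truth$target_nodes)
```

```{r plot, fig.width = 6, fig.height = 4}
plot(bin)
```

## What the generator emulates — and what it does not

`simulate_community()` produces each organism as a random spanning tree
plus extra edges, with depths drawn from a truncated normal around the
organism's mean, sequences at its GC target, markers planted on random
target nodes, and optional spurious cross-organism edges (directly or
through short low-depth bridge nodes). Depth noise is modelled as a
truncated normal because only a unimodal spread around an
organism-specific mean is needed; real depth distributions are
over-dispersed and repeat contigs carry multiplied depths, which the
generator does not emulate. Nor does it produce k-mer-level assembly
artefacts, shared (horizontally transferred) sequence between organisms,
or composition signals. Passing the recovery tests therefore shows the
procedure is correct *given* depth-separated organisms and
component-respecting topology — the regime the method assumes — not that
it would disentangle organisms of equal abundance, which no depth gate
can.

The default study conditions used across the test-suite recovery checks
are two organisms at mean depths 15 and 150 (sd 1), five marker hits, and
40 + 30 nodes per graph — sizes chosen so a full twenty-replicate sweep
runs in seconds while leaving each graph large enough for non-trivial
topology.

## Genome characterisation

**Assembly statistics** (`assembly_summary()`): N50 uses the
cumulative-sum $\ge$ half-total convention; GC% is computed over
unambiguous A/C/G/T only (Ns and IUPAC ambiguity codes are excluded from
numerator and denominator); coding % is the per-contig interval *union*
of CDS features, so overlapping gene models cannot push it past 100 %.
GFF3 coordinates are treated as 1-based inclusive throughout.

**Cold-adaptation indices** (`aa_composition()`): proteome-wide proline
percentage and arginine:lysine ratio. Both arginine and proline rigidify
protein structure; cold-adapted proteomes tend to show reduced Pro% and
Arg:Lys relative to mesophilic relatives. Counts run over the 20 standard
residues only — `*`, X, B, Z, J, U, O are excluded from numerator *and*
denominator (a documented choice; including X in the denominator would
deflate every index on draft annotations). Arg:Lys is reported as
undefined, not infinity, for a lysine-free input. Display rounding is
2 dp; full precision is kept internally.

```{r aacomp}
f <- setNames(rep((1 - 0.0476 - 0.07 - 0.05) / 17, 20),
              strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
f[c("P", "R", "K")] <- c(0.0476, 0.07, 0.05)   # Arg:Lys planted at 1.4
aa_composition(simulate_proteome(f, 400, 250, seed = 7))
```

## Gene-cluster detection

The census and the five cluster detectors run over a [gene_records] table
(GFF3 gene features merged with a per-gene domain-label table) and a YAML
rule configuration mapping *roles* (wza, wzc, kpsM, wspA, ...) to product
regexes and domain labels. Rules are configuration, not code, because
annotation vocabularies differ between pipelines; the shipped defaults
encode a typical IMG-style vocabulary, with domain evidence listed before
product text as the more specific signal.

Detector conventions, where the design was genuinely open:

* *Adjacency* means consecutive gene records on a contig, irrespective of
  strand — except the Wsp cassette, which requires one strand throughout
  because the cassette is transcribed as a unit.
* The **WZY** detector anchors on the adjacent wza/wzc pair (the invariant
  arrangement), then accepts wzx/wzy within a 10-gene window; partial
  clusters are reported as incomplete rather than dropped.
* The **ABC** detector groups kps-role genes within a 100 kb span, because
  the outer-membrane (kpsD/E) and transporter (kpsM/T) halves of one
  system can sit ~80 kb apart; two adjacent kpsM fragments count once,
  flagged `split-kpsM` (draft annotations often split that gene).
* The **Wsp** detector demands the exact role order
  wspB–wspC–wspA–wspD–wspE–wspF with no intervening gene, and inspects
  the next gene downstream as the response-regulator slot, flagging
  `non-canonical-regulator` when it lacks a GGDEF domain (e.g. an
  adenylate cyclase in that position).
* **GGDEF** motif evidence is three-state: a supplied protein sequence is
  scanned for a literal GGDEF/GGEEF substring (authoritative); otherwise
  explicit per-gene motif flags decide; with no evidence, no
  `degenerate-motif` flag is raised — flagging on ignorance would mislabel
  every unannotated gene.
* **alg44-like** genes are HlyD-family-domain genes (HlyD_3,
  Biotin_lipoyl_2, HlyD_D23) lacking PilZ, flagged `abc-associated` when
  an ABC-transporter gene lies within five gene positions.

```{r clusters}
ann <- simulate_annotation(
  planted = list(list(type = "WZY"),
                 list(type = "WSP", regulator = "adenylate-cyclase")),
  families = c(dnaK = 5, hupB = 4), seed = 11)
find_wzy_clusters(ann$genes)
find_wsp_cassette(ann$genes)
census <- cold_shock_census(ann$genes)
census$counts[census$counts > 0]
```

The package ships two small annotation tables for the Arctic
cyanobacterium *Phormidesmis priestleyi* BC1401 (the organism that
motivated this pipeline): its GGDEF-domain genes and its HlyD/alg44-like
genes, with published gene ids, products and Pfam labels. Coordinates in
those files are synthetic placeholders — the ids encode only contig
membership and order, which is all the scans use.

```{r fixtures}
hl <- read_gene_table(system.file("extdata", "bc1401_hlyd_genes.tsv",
                                  package = "psychrobin"))
length(find_alg44_like(hl))
```

## Numerical choices and degenerate inputs

* The weighted median interpolates (averages the two central
  order statistics) when the total weight is even, matching the plain
  median of the unit-weight expansion exactly.
* Edges are undirected and de-duplicated across orientations; a node and
  its reverse-complement twin collapse to one canonical node, so node and
  edge counts match what a graph viewer displays.
* Nodes appearing only in adjacency lists are an error, not silently
  created: a truncated graph file should fail fast.
* An empty seed set, an empty proteome, a zero-gene denominator and an
  all-ambiguous sequence set are all errors, not NaNs.
* Depths are carried verbatim from the graph file; no re-estimation.

## Limitations

Depth gating cannot separate organisms of similar abundance; the rescue
stage is only as good as its classifier table; rule-based cluster calls
inherit the annotation's vocabulary and cannot recover genes the
annotation missed; and the census counts annotation matches, not fresh
homology search results.
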