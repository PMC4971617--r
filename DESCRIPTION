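Package: psychrobin
Title: Marker-Seeded Genome Extraction from Metagenome Assembly Graphs
    and Cold-Adaptation Genome Profiling
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Extracts a single genome from the assembly graph of a simple
    metagenome (for example a non-axenic cyanobacterial culture) by seeding
    on marker-gene BLAST hits, propagating labels along graph edges gated by
    read-depth similarity, rescuing unconnected depth-similar contigs through
    a classification table, and applying a depth/length filter cascade.
    Parses SPAdes FASTG and GFA1 assembly graphs. Also provides assembly
    statistics (N50, GC content, coding density), proteome amino-acid
    composition indices used in cold-adaptation studies (proline percentage,
    arginine:lysine ratio), a configurable census of cold-shock gene
    families, rule-based detectors for exopolysaccharide export gene
    clusters (Wzy- and ABC-dependent), Wsp chemosensory cassettes,
    GGDEF-domain diguanylate cyclases and alg44-like HlyD genes, and
    synthetic-data generators with known truth labels for end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    rtracklayer,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
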