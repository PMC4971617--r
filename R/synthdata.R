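# Synthetic inputs with known truth for every pipeline stage: community
# assembly graphs, proteomes with specified residue frequencies, and
# annotation tables with planted gene clusters and decoys.
#
# Every generator is bit-reproducible under its seed (the RNG state of the
# caller is preserved).

#' Describe one organism of a synthetic community
#'
#' @param name organism name (alphanumeric/underscore; becomes the node-id
#'   prefix and the truth label).
#' @param n_nodes number of contig nodes.
#' @param depth_mean,depth_sd read-depth distribution (normal truncated at
#'   zero); `depth_mean` must be positive.
#' @param gc GC target of generated sequences (0-1).
#' @param target is this the organism the pipeline should recover? Exactly
#'   one organism per community.
#' @param len_meanlog,len_sdlog log-normal node-length parameters.
#' @param min_len floor on node length in bp.
#' @param extra_edges edges added on top of the random spanning tree.
#' @return list of class `community_organism`.
#' @export
organism <- function(name, n_nodes, depth_mean, depth_sd, gc = 0.5,
                     target = FALSE, len_meanlog = log(3000),
                     len_sdlog = 0.4, min_len = 500L,
                     extra_edges = max(0L, round(n_nodes / 5))) {
  stopifnot(grepl("^[A-Za-z0-9_]+$", name), n_nodes >= 1, depth_mean > 0,
            depth_sd >= 0, gc > 0, gc < 1)
  structure(list(name = name, n_nodes = as.integer(n_nodes),
                 depth_mean = depth_mean, depth_sd = depth_sd, gc = gc,
                 target = isTRUE(target), len_meanlog = len_meanlog,
                 len_sdlog = len_sdlog, min_len = as.integer(min_len),
                 extra_edges = as.integer(extra_edges)),
            class = "community_organism")
}

#' Describe a synthetic metagenome community
#'
#' A community is a set of organisms, each occupying its own connected
#' subgraph (random spanning tree plus extra edges) with its own depth
#' distribution and GC target, plus optional spurious cross-organism edges
#' and marker hits planted on target-organism nodes.
#'
#' @param organisms list of [organism()] objects; exactly one with
#'   `target = TRUE`.
#' @param n_cross_edges spurious inter-organism edges (default 0).
#' @param markers_per_target marker-hit rows emitted for random target
#'   nodes (default 5).
#' @param seed integer RNG seed; identical seeds give byte-identical output
#'   files.
#' @param cross_style `"direct"` joins a target and a contaminant node with
#'   one edge; `"bridge"` routes each cross edge through a new short
#'   low-depth bridge node (truth label `"bridge"`).
#' @param bridge_depth,bridge_len depth and length of bridge nodes.
#' @return list of class `community_spec`.
#' @export
community_spec <- function(organisms, n_cross_edges = 0L,
                           markers_per_target = 5L, seed = 1L,
                           cross_style = c("direct", "bridge"),
                           bridge_depth = 3.0, bridge_len = 300L) {
  cross_style <- match.arg(cross_style)
  stopifnot(length(organisms) >= 1,
            all(vapply(organisms, inherits, logical(1),
                       "community_organism")))
  tgt <- vapply(organisms, `[[`, logical(1), "target")
  if (sum(tgt) != 1L)
    stop("community_spec: exactly one organism must be the target")
  nm <- vapply(organisms, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("community_spec: duplicate organism names")
  structure(list(organisms = organisms, n_cross_edges = as.integer(n_cross_edges),
                 markers_per_target = as.integer(markers_per_target),
                 seed = as.integer(seed), cross_style = cross_style,
                 bridge_depth = bridge_depth,
                 bridge_len = as.integer(bridge_len)),
            class = "community_spec")
}

# seed the RNG for the calling scope and restore the caller's state on exit
local_rng_seed <- function(seed, envir = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  withr::defer({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, envir = envir)
  set.seed(seed)
}

rtnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

random_seq <- function(len, gc) {
  paste(sample(c("G", "C", "A", "T"), len, replace = TRUE,
               prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Simulate a multi-organism assembly graph with truth labels
#'
#' Writes the graph (GFA1 or FASTG), a 12-column marker hit table, a
#' truthful classifier table and a JSON truth record into `dir`, and also
#' returns everything in memory. Marker hits are planted on random
#' target-organism nodes with e-values well below 1e-10.
#'
#' @param spec a [community_spec()].
#' @param dir output directory (created if needed).
#' @param format `"gfa"` (default) or `"fastg"`.
#' @param sequences attach random sequences at each organism's GC target?
#'   (Default TRUE; binning itself never needs them.)
#' @return list with `graph` (the [assembly_graph]), `truth` (list:
#'   `node_truth` named by node id, `target`, `target_nodes`), `paths`
#'   (graph/hits/classifier/truth files) and `spec`.
#' @export
simulate_community <- function(spec, dir = tempfile("community"),
                               format = c("gfa", "fastg"),
                               sequences = TRUE) {
  stopifnot(inherits(spec, "community_spec"))
  format <- match.arg(format)
  local_rng_seed(spec$seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  ids <- character(0); lens <- integer(0); deps <- numeric(0)
  truth <- character(0)
  ef <- et <- character(0)
  seqs <- character(0)

  for (org in spec$organisms) {
    oid <- sprintf("%s_%03d", org$name, seq_len(org$n_nodes))
    olen <- pmax(org$min_len,
                 as.integer(round(stats::rlnorm(org$n_nodes,
                                                org$len_meanlog,
                                                org$len_sdlog))))
    odep <- round(rtnorm_pos(org$n_nodes, org$depth_mean, org$depth_sd), 4)
    ids <- c(ids, oid); lens <- c(lens, olen); deps <- c(deps, odep)
    truth[oid] <- org$name
    if (org$n_nodes >= 2L) {
      parent <- vapply(2:org$n_nodes,
                       function(k) sample.int(k - 1L, 1L), integer(1))
      ef <- c(ef, oid[parent]); et <- c(et, oid[2:org$n_nodes])
      if (org$extra_edges > 0L) {
        for (k in seq_len(org$extra_edges)) {
          p <- sample.int(org$n_nodes, 2L)
          ef <- c(ef, oid[p[1]]); et <- c(et, oid[p[2]])
        }
      }
    }
    if (sequences)
      for (i in seq_along(oid)) seqs[oid[i]] <- random_seq(olen[i], org$gc)
  }

  target_org <- spec$organisms[[which(vapply(spec$organisms, `[[`,
                                             logical(1), "target"))]]
  tgt_ids <- ids[truth[ids] == target_org$name]
  oth_ids <- ids[truth[ids] != target_org$name]

  if (spec$n_cross_edges > 0L) {
    if (!length(oth_ids))
      stop("simulate_community: cross edges need >= 2 organisms")
    if (spec$cross_style == "direct" &&
        spec$n_cross_edges > length(tgt_ids) * length(oth_ids))
      stop("simulate_community: more cross edges requested than possible")
    for (k in seq_len(spec$n_cross_edges)) {
      a <- sample(tgt_ids, 1L); b <- sample(oth_ids, 1L)
      if (spec$cross_style == "direct") {
        ef <- c(ef, a); et <- c(et, b)
      } else {
        bid <- sprintf("bridge_%03d", k)
        ids <- c(ids, bid); lens <- c(lens, spec$bridge_len)
        deps <- c(deps, spec$bridge_depth)
        truth[bid] <- "bridge"
        if (sequences) seqs[bid] <- random_seq(spec$bridge_len, 0.5)
        ef <- c(ef, a, bid); et <- c(et, bid, b)
      }
    }
  }

  graph <- assembly_graph(
    nodes = data.frame(node_id = ids, length = lens, depth = deps,
                       stringsAsFactors = FALSE),
    edges = if (length(ef)) data.frame(from = ef, to = et,
                                       stringsAsFactors = FALSE) else NULL,
    sequences = if (sequences) seqs else NULL)

  graph_path <- file.path(dir, paste0("graph.", format))
  if (format == "gfa") write_gfa(graph, graph_path)
  else write_fastg(graph, graph_path)

  m <- spec$markers_per_target
  hit_nodes <- sample(tgt_ids, m, replace = m > length(tgt_ids))
  hits <- data.frame(
    qseqid = sprintf("CyOG_%04d", seq_len(m)),
    sseqid = hit_nodes,
    pident = round(stats::runif(m, 80, 100), 1),
    length = 250L, mismatch = 5L, gapopen = 0L,
    qstart = 1L, qend = 250L, sstart = 1L, send = 750L,
    evalue = signif(10^-stats::runif(m, 15, 60), 3),
    bitscore = round(stats::runif(m, 200, 500), 1),
    stringsAsFactors = FALSE)
  hits_path <- file.path(dir, "marker_hits.tsv")
  utils::write.table(hits, hits_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  classifier <- data.frame(
    node_id = ids,
    verdict = ifelse(truth[ids] == target_org$name, "target-taxon", "other"),
    stringsAsFactors = FALSE)
  classifier_path <- file.path(dir, "classifier.tsv")
  utils::write.table(classifier, classifier_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  truth_rec <- list(target = target_org$name,
                    node_truth = as.list(truth[ids]),
                    target_nodes = tgt_ids)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(truth_rec, truth_path, auto_unbox = TRUE)

  list(graph = graph,
       truth = list(target = target_org$name,
                    node_truth = truth[ids],
                    target_nodes = tgt_ids),
       paths = list(graph = graph_path, hits = hits_path,
                    classifier = classifier_path, truth = truth_path),
       spec = spec)
}

#' Simulate a proteome with specified residue frequencies
#'
#' Residues are drawn i.i.d. from the supplied 20-residue frequency vector.
#'
#' @param freqs numeric vector of 20 non-negative frequencies summing to 1
#'   (within 1e-9); names default to the standard residues in alphabetical
#'   order (A C D E F G H I K L M N P Q R S T V W Y).
#' @param n_proteins number of sequences.
#' @param mean_len mean protein length (Poisson, floored at 30).
#' @param seed RNG seed.
#' @param path optional FASTA output path.
#' @return an `AAStringSet` (invisibly written to `path` when given).
#' @export
simulate_proteome <- function(freqs, n_proteins = 1000L, mean_len = 300L,
                              seed = 1L, path = NULL) {
  if (length(freqs) != 20L)
    stop("simulate_proteome: freqs must have 20 entries")
  if (is.null(names(freqs))) names(freqs) <- .aa_standard
  stopifnot(setequal(names(freqs), .aa_standard))
  if (any(freqs < 0) || abs(sum(freqs) - 1) > 1e-9)
    stop("simulate_proteome: freqs must be non-negative and sum to 1")
  local_rng_seed(seed)
  lens <- pmax(30L, stats::rpois(n_proteins, mean_len))
  res <- sample(names(freqs), sum(lens), replace = TRUE, prob = freqs)
  big <- paste(res, collapse = "")
  ends <- cumsum(lens)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  seqs <- Biostrings::AAStringSet(substring(big, starts, ends))
  names(seqs) <- sprintf("prot_%05d", seq_len(n_proteins))
  if (!is.null(path)) Biostrings::writeXStringSet(seqs, path)
  seqs
}

# canonical accession <-> name pairs for generated domain tables
.domain_vocab <- c(pfam00990 = "GGDEF", pfam07238 = "PilZ",
                   pfam13437 = "HlyD_3", pfam13533 = "Biotin_lipoyl_2",
                   pfam16576 = "HlyD_D23", pfam00005 = "ABC_tran",
                   pfam00015 = "MCPsignal", pfam02563 = "Poly_export")

.role_products <- c(
  wza = "polysaccharide export protein Wza",
  wzc = "tyrosine-protein kinase Wzc",
  wzx = "lipopolysaccharide biosynthesis flippase Wzx",
  wzy = "O-antigen polymerase Wzy",
  kpsD = "capsular polysaccharide export protein KpsD",
  kpsE = "capsular polysaccharide export inner-membrane protein KpsE",
  kpsM = "capsular polysaccharide ABC transporter permease KpsM",
  kpsT = "capsular polysaccharide ABC transporter ATP-binding protein KpsT",
  wspA = "methyl-accepting chemotaxis protein WspA",
  wspB = "chemosensory scaffold protein WspB",
  wspC = "chemoreceptor methyltransferase WspC",
  wspD = "chemosensory scaffold protein WspD",
  wspE = "chemosensory hybrid histidine kinase WspE",
  wspF = "chemoreceptor methylesterase WspF")

.family_products <- c(
  aceE = "pyruvate dehydrogenase E1 component",
  aceF = "dihydrolipoamide acetyltransferase",
  "csp-family" = "cold-shock DNA-binding protein CspA",
  deaD = "ATP-dependent RNA helicase DeaD",
  desAB = "fatty acid desaturase DesA",
  dnaA = "chromosomal replication initiator protein DnaA",
  gyrA = "DNA gyrase subunit A",
  dnaK = "chaperone protein DnaK",
  dnaJ = "chaperone protein DnaJ",
  hupB = "DNA-binding protein HU-beta",
  "infA/IF-1" = "translation initiation factor IF-1",
  "infB/IF-2" = "translation initiation factor IF-2",
  "infC/IF-3" = "translation initiation factor IF-3",
  nusA = "transcription termination factor NusA",
  otsA = "trehalose-6-phosphate synthase",
  pnp = "polyribonucleotide nucleotidyltransferase",
  rnr = "ribonuclease R",
  rbfA = "ribosome-binding factor A",
  recA = "protein RecA",
  tig = "trigger factor",
  yfiA = "ribosome-associated inhibitor A")

#' Simulate an annotation table with planted gene clusters and decoys
#'
#' Each planted cluster (and each decoy) is laid out on its own contig with
#' neutral filler genes ("hypothetical protein") interleaved; planted
#' clusters satisfy the corresponding detection rule, and each decoy
#' violates exactly the rule named in its `violation` field. Gene-family
#' counts can be planted for the cold-shock census.
#'
#' Cluster specs are lists with a `type` field:
#' * `WZY`: optional `missing` (one of wza/wzc/wzx/wzy to leave out).
#' * `ABC`: optional `split_kpsM` (logical), `gap_bp` (distance between the
#'   kpsD/E and kpsM/T sub-clusters, default 80000).
#' * `WSP`: optional `regulator` = `"diguanylate-cyclase"` (canonical) or
#'   `"adenylate-cyclase"`.
#' * `GGDEF`: optional `motif` (logical, default TRUE).
#' * `ALG44LIKE`: optional `pilz` (logical, default FALSE) and
#'   `abc_neighbor` (logical, default FALSE).
#'
#' Decoys use the same `type` plus `violation`: `"separated-anchor"`,
#' `"missing-role"` (WZY); `"span-exceeded"`, `"missing-role"` (ABC);
#' `"order-swapped"` (WSP); `"no-domain"` (GGDEF); `"pilz-present"`
#' (ALG44LIKE).
#'
#' @param planted list of cluster specs (see Details).
#' @param decoys list of decoy specs.
#' @param families named integer vector: planted gene count per cold-shock
#'   family.
#' @param seed RNG seed.
#' @param dir optional output directory; when given, writes
#'   `annotation.gff3`, `domains.tsv`, `motif_flags.tsv` and `truth.json`.
#' @param fillers filler genes inserted at contig ends (default 3).
#' @return list with `genes` (a [gene_records] table), `truth`
#'   (`planted_clusters`, `planted_family_counts`) and `paths` (or `NULL`).
#' @export
simulate_annotation <- function(planted = list(), decoys = list(),
                                families = integer(0), seed = 1L,
                                dir = NULL, fillers = 3L) {
  local_rng_seed(seed)
  rows <- list()
  gene_n <- 0L
  cursor <- new.env(parent = emptyenv())

  add_gene <- function(contig, product = "hypothetical protein",
                       domains = character(0), strand = "+",
                       len = 900L, gap = 150L, motif = character(0)) {
    pos <- if (is.null(cursor[[contig]])) 1L else cursor[[contig]]
    start <- pos + gap
    end <- start + len - 1L
    cursor[[contig]] <- end
    gene_n <<- gene_n + 1L
    rows[[length(rows) + 1L]] <<- list(
      gene_id = sprintf("sg%05d", gene_n), contig = contig,
      start = start, end = end, strand = strand, product = product,
      domains = domains, motif_flags = motif)
    sprintf("sg%05d", gene_n)
  }
  add_fillers <- function(contig, k = fillers)
    for (i in seq_len(k)) add_gene(contig)

  truth_clusters <- list()
  emit <- function(spec, contig, ids, decoy = FALSE) {
    truth_clusters[[length(truth_clusters) + 1L]] <<- list(
      cluster_type = spec$type, contig = contig, gene_ids = ids,
      decoy = decoy, violation = spec$violation)
  }

  lay_cluster <- function(spec, contig, decoy = FALSE) {
    type <- spec$type
    ids <- character(0)
    add_fillers(contig)
    if (type == "WZY") {
      missing <- spec$missing
      viol <- identical(spec$violation, "separated-anchor")
      if (identical(spec$violation, "missing-role"))
        missing <- if (is.null(spec$missing)) "wzy" else spec$missing
      put <- function(role) {
        if (!is.null(missing) && role %in% missing) return(invisible(NULL))
        ids <<- c(ids, add_gene(contig, .role_products[[role]]))
      }
      put("wza")
      if (viol) add_fillers(contig, 12L)
      put("wzc")
      add_fillers(contig, 2L)
      put("wzx")
      put("wzy")
    } else if (type == "ABC") {
      gap_bp <- if (!is.null(spec$gap_bp)) spec$gap_bp else 80000L
      if (identical(spec$violation, "span-exceeded")) gap_bp <- 150000L
      missing <- if (identical(spec$violation, "missing-role")) {
        if (is.null(spec$missing)) c("kpsD", "kpsE", "kpsM") else spec$missing
      } else spec$missing
      put <- function(role, gap = 150L) {
        if (!is.null(missing) && role %in% missing) return(invisible(NULL))
        ids <<- c(ids, add_gene(contig, .role_products[[role]], gap = gap))
      }
      put("kpsD"); put("kpsE")
      if (isTRUE(spec$split_kpsM)) {
        if (is.null(missing) || !"kpsM" %in% missing) {
          ids <- c(ids, add_gene(contig, paste(.role_products[["kpsM"]],
                                               "fragment"), gap = gap_bp))
          ids <- c(ids, add_gene(contig, paste(.role_products[["kpsM"]],
                                               "fragment")))
        }
      } else {
        put("kpsM", gap = gap_bp)
      }
      put("kpsT")
    } else if (type == "WSP") {
      reg <- if (is.null(spec$regulator)) "diguanylate-cyclase"
             else spec$regulator
      order_roles <- c("wspB", "wspC", "wspA", "wspD", "wspE", "wspF")
      if (identical(spec$violation, "order-swapped"))
        order_roles <- c("wspB", "wspC", "wspA", "wspD", "wspF", "wspE")
      ids <- c(ids, add_gene(contig, "cyclic nucleotide-binding protein"))
      for (role in order_roles) {
        dom <- if (role == "wspA") c("pfam00015", "MCPsignal")
               else character(0)
        ids <- c(ids, add_gene(contig, .role_products[[role]],
                               domains = dom))
      }
      if (reg == "diguanylate-cyclase") {
        ids <- c(ids, add_gene(contig,
                               "response regulator diguanylate cyclase WspR",
                               domains = c("pfam00990", "GGDEF"),
                               motif = "has-GGDEF-motif"))
      } else {
        ids <- c(ids, add_gene(contig, "class 3 adenylate cyclase"))
      }
    } else if (type == "GGDEF") {
      motif_present <- !isFALSE(spec$motif)
      dom <- if (identical(spec$violation, "no-domain")) character(0)
             else c("pfam00990", "GGDEF")
      ids <- c(ids, add_gene(
        contig, "response regulator receiver modulated diguanylate cyclase",
        domains = dom,
        motif = if (motif_present) "has-GGDEF-motif"
                else "ggdef-motif-absent"))
    } else if (type == "ALG44LIKE") {
      dom <- c("pfam13437", "HlyD_3", "pfam13533", "Biotin_lipoyl_2")
      if (isTRUE(spec$pilz) || identical(spec$violation, "pilz-present"))
        dom <- c(dom, "pfam07238", "PilZ")
      ids <- c(ids, add_gene(contig, "HlyD family secretion protein",
                             domains = dom))
      if (isTRUE(spec$abc_neighbor))
        add_gene(contig, "ABC transporter ATP-binding protein",
                 domains = c("pfam00005", "ABC_tran"))
    } else {
      stop("simulate_annotation: unknown cluster type '", type, "'")
    }
    add_fillers(contig)
    emit(spec, contig, ids, decoy)
  }

  for (k in seq_along(planted))
    lay_cluster(planted[[k]],
                sprintf("ctg_%s_%02d", tolower(planted[[k]]$type), k))
  for (k in seq_along(decoys))
    lay_cluster(decoys[[k]],
                sprintf("ctg_decoy_%s_%02d", tolower(decoys[[k]]$type), k),
                decoy = TRUE)

  if (length(families)) {
    bad <- setdiff(names(families), names(.family_products))
    if (length(bad))
      stop("simulate_annotation: unknown family: ",
           paste(bad, collapse = ", "))
    ctg <- "ctg_census_01"
    add_fillers(ctg)
    for (fam in names(families))
      for (i in seq_len(families[[fam]])) {
        add_gene(ctg, .family_products[[fam]])
        add_gene(ctg)
      }
  }

  genes <- gene_records(
    gene_id = vapply(rows, `[[`, character(1), "gene_id"),
    contig = vapply(rows, `[[`, character(1), "contig"),
    start = vapply(rows, `[[`, integer(1), "start"),
    end = vapply(rows, `[[`, integer(1), "end"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    product = vapply(rows, `[[`, character(1), "product"),
    domains = lapply(rows, `[[`, "domains"),
    motif_flags = lapply(rows, `[[`, "motif_flags"))

  truth <- list(planted_clusters = truth_clusters,
                planted_family_counts = as.list(families))

  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    gr <- GenomicRanges::GRanges(
      seqnames = genes$contig,
      ranges = IRanges::IRanges(genes$start, genes$end),
      strand = genes$strand)
    gr$type <- "gene"
    gr$ID <- genes$gene_id
    gr$product <- genes$product
    gff_path <- file.path(dir, "annotation.gff3")
    rtracklayer::export(gr, gff_path, format = "gff3")

    acc <- lapply(genes$domains,
                  function(d) d[d %in% names(.domain_vocab)])
    dom_df <- data.frame(
      gene_id = rep(genes$gene_id, lengths(acc)),
      domain_accession = unlist(acc, use.names = FALSE),
      stringsAsFactors = FALSE)
    dom_df$domain_name <- unname(.domain_vocab[dom_df$domain_accession])
    dom_path <- file.path(dir, "domains.tsv")
    utils::write.table(dom_df, dom_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)

    mf <- data.frame(
      gene_id = rep(genes$gene_id, lengths(genes$motif_flags)),
      flag = unlist(genes$motif_flags, use.names = FALSE),
      stringsAsFactors = FALSE)
    mf_path <- file.path(dir, "motif_flags.tsv")
    utils::write.table(mf, mf_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)

    truth_path <- file.path(dir, "truth.json")
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE)
    paths <- list(gff = gff_path, domains = dom_path,
                  motif_flags = mf_path, truth = truth_path)
  }

  list(genes = genes, truth = truth, paths = paths)
}
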