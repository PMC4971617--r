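make_hits <- function(marker, node, evalue, bitscore = 100) {
  data.frame(qseqid = marker, sseqid = node, pident = 90, length = 100,
             mismatch = 1, gapopen = 0, qstart = 1, qend = 100, sstart = 1,
             send = 300, evalue = evalue, bitscore = bitscore,
             stringsAsFactors = FALSE)
}

test_that("marker-hit loading thresholds e-values and keeps best hit per pair", {
  h <- load_marker_hits(make_hits("m1", "a", 1e-12))
  expect_equal(nrow(h), 1L)
  expect_equal(nrow(load_marker_hits(make_hits("m1", "a", 1e-5))), 0L)
  # 3 hits of one marker to one node -> the minimum e-value survives
  h3 <- load_marker_hits(make_hits(rep("m1", 3), rep("a", 3),
                                   c(1e-20, 1e-40, 1e-30)))
  expect_equal(nrow(h3), 1L)
  expect_equal(h3$evalue, 1e-40)
})

test_that("unresolvable subject ids are skipped with a warning; bad e-values error", {
  g <- toy_graph()
  expect_warning(
    h <- load_marker_hits(make_hits(c("m1", "m2"), c("a", "nope"),
                                    c(1e-20, 1e-20)), graph = g),
    "unresolvable")
  expect_equal(h$node_id, "a")
  expect_equal(attr(h, "skip_report"), "nope")
  f <- withr::local_tempfile(fileext = ".tsv")
  bad <- make_hits("m1", "a", 1e-20); bad$evalue <- "not-a-number"
  utils::write.table(bad, f, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  expect_error(load_marker_hits(f), "non-numeric")
})

test_that("seed nodes deduplicate and an empty seed set is fatal", {
  g <- toy_graph()
  h <- load_marker_hits(make_hits(c("m1", "m2", "m3"), c("a", "a", "b"),
                                  rep(1e-20, 3)))
  expect_setequal(seed_nodes(h, g), c("a", "b"))
  h0 <- load_marker_hits(make_hits("m1", "a", 1e-3))
  expect_error(seed_nodes(h0, g), "no seeds")
})

test_that("depth model centre is the length-weighted median of seed depths", {
  g1 <- assembly_graph(data.frame(node_id = c("s1", "s2", "s3"),
                                  length = 500L, depth = 14.1))
  expect_equal(fit_depth_model(g1, c("s1", "s2", "s3"))$center, 14.1)

  g2 <- assembly_graph(data.frame(node_id = c("s1", "s2"),
                                  length = c(100L, 300L),
                                  depth = c(10, 20)))
  m <- fit_depth_model(g2, c("s1", "s2"))
  # oracle: expand lengths to unit weights and take the plain median
  expect_equal(m$center, stats::median(rep(c(10, 20), c(100, 300))))
  expect_equal(m$center, 20)
  expect_equal(m$seed_depth_mean, 15)

  g3 <- assembly_graph(data.frame(node_id = "s", length = 50L, depth = 5))
  expect_equal(fit_depth_model(g3, "s")$center, 5)
  expect_error(fit_depth_model(g3, "s", fold = 1), "fold")

  g0 <- assembly_graph(data.frame(node_id = c("s", "t"), length = 10L,
                                  depth = c(0, 0)))
  expect_error(fit_depth_model(g0, c("s", "t")), "zero")
  g4 <- assembly_graph(data.frame(node_id = c("s", "t"), length = 10L,
                                  depth = c(0, 8)))
  expect_warning(fit_depth_model(g4, c("s", "t")), "zero depth")
})

test_that("gated propagation crosses edges only into depth-similar nodes", {
  g <- toy_graph()  # a(12)-b(11)-c(50)
  m <- fit_depth_model(g, "a")  # centre 12, band [6, 24]
  expect_equal(m$center / m$fold, 6)
  expect_equal(m$center * m$fold, 24)
  a <- assign_bins(g, "a", m)
  expect_equal(a$label, c("target", "target", "unassigned"))
  expect_equal(a$provenance, c("seed", "propagated", NA))
})

test_that("isolated seeds stay target and seedless components stay unassigned", {
  g <- assembly_graph(
    nodes = data.frame(node_id = c("s", "x", "y"), length = 1000L,
                       depth = c(15, 14, 16)),
    edges = data.frame(from = "x", to = "y"))
  a <- assign_bins(g, "s", fit_depth_model(g, "s"))
  expect_equal(a$label[a$node_id == "s"], "target")
  expect_true(all(a$label[a$node_id %in% c("x", "y")] == "unassigned"))
})

test_that("component mode labels depth-dissimilar component members contaminant", {
  g <- toy_graph()
  a <- assign_bins(g, "a", fit_depth_model(g, "a"), mode = "component")
  expect_equal(a$label, c("target", "target", "contaminant"))
  expect_false(any(a$label == "target" &
                     a$provenance %in% c("filtered-depth", "filtered-length",
                                         "classifier-rejected")))
})

test_that("rescue applies classifier verdicts to unassigned in-band nodes only", {
  g <- assembly_graph(data.frame(
    node_id = c("s", "good", "bad", "far", "mystery"),
    length = 1000L, depth = c(15, 14, 16, 200, 15)))
  m <- fit_depth_model(g, "s")
  a <- assign_bins(g, "s", m)
  cls <- data.frame(node_id = c("good", "bad"),
                    verdict = c("target-taxon", "other"))
  r <- rescue_unconnected(a, cls)
  expect_equal(r$label[r$node_id == "good"], "target")
  expect_equal(r$provenance[r$node_id == "good"], "rescued")
  expect_equal(r$label[r$node_id == "bad"], "contaminant")
  expect_equal(r$provenance[r$node_id == "bad"], "classifier-rejected")
  expect_equal(r$label[r$node_id == "far"], "unassigned")   # out of band
  expect_equal(r$label[r$node_id == "mystery"], "unassigned")
  expect_true("mystery" %in% attr(r, "needs_review"))
  r2 <- rescue_unconnected(a, cls, unknown = "conservative")
  expect_equal(r2$label[r2$node_id == "mystery"], "contaminant")
})

test_that("filter cascade is strict, ordered depth-then-length, and idempotent", {
  g <- assembly_graph(data.frame(
    node_id = c("s", "shallow", "short", "edge"),
    length = c(1000L, 1000L, 199L, 200L),
    depth = c(15, 9.9, 15, 10.0)))
  m <- fit_depth_model(g, "s")
  a <- assign_bins(g, c("s", "shallow", "short", "edge"), m)
  f <- apply_filters(a)
  expect_equal(f$label[f$node_id == "shallow"], "contaminant")
  expect_equal(f$provenance[f$node_id == "shallow"], "filtered-depth")
  expect_equal(f$label[f$node_id == "short"], "contaminant")
  expect_equal(f$provenance[f$node_id == "short"], "filtered-length")
  # boundary of a strict inequality: retained
  expect_equal(f$label[f$node_id == "edge"], "target")
  expect_identical(apply_filters(f), f)
  # labels partition the nodes: one label per node, only via filters can a
  # seed leave the bin
  expect_true(all(table(f$node_id) == 1))
})

test_that("widening the depth band never shrinks the gated-propagation bin", {
  for (s in 1:5) {
    set.seed(s)
    ids <- sprintf("n%02d", 1:30)
    edges <- unique(data.frame(from = sample(ids, 40, replace = TRUE),
                               to = sample(ids, 40, replace = TRUE)))
    edges <- edges[edges$from != edges$to, ]
    g <- assembly_graph(
      data.frame(node_id = ids, length = 1000L,
                 depth = stats::rlnorm(30, log(15), 0.8)),
      edges)
    seeds <- sample(ids, 3)
    narrow <- assign_bins(g, seeds, fit_depth_model(g, seeds, fold = 1.5))
    wide <- assign_bins(g, seeds, fit_depth_model(g, seeds, fold = 3))
    expect_true(all(narrow$node_id[narrow$label == "target"] %in%
                      wide$node_id[wide$label == "target"]))
  }
})

test_that("bin FASTA export is ordered, annotated and fails without sequences", {
  spec <- two_org_spec(3, n_target = 10L, n_other = 5L)
  sim <- simulate_community(spec, dir = withr::local_tempdir())
  bin <- extract_genome(sim$graph, sim$paths$hits)
  p <- withr::local_tempfile(fileext = ".fasta")
  write_bin_fasta(sim$graph, bin$assignment, p)
  seqs <- Biostrings::readDNAStringSet(p)
  tgt <- bin$assignment[bin$assignment$label == "target", ]
  expect_equal(length(seqs), nrow(tgt))
  lens <- Biostrings::width(seqs)
  expect_true(all(diff(lens) <= 0))  # descending length
  expect_match(names(seqs)[1], "provenance=")

  gnoseq <- assembly_graph(sim$graph$nodes, sim$graph$edges)
  expect_error(write_bin_fasta(gnoseq, bin$assignment, p),
               "without sequence")
  empty <- bin$assignment
  empty$label[] <- "unassigned"
  expect_warning(write_bin_fasta(sim$graph, empty, p), "no target")
})
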