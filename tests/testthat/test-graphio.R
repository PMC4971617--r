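test_that("FASTG parsing collapses orientations onto canonical nodes", {
  fg <- withr::local_tempfile(fileext = ".fastg")
  write_two_node_fastg(fg)
  g <- parse_fastg(fg)
  expect_equal(nrow(g$nodes), 2L)
  expect_equal(nrow(g$edges), 1L)
  expect_setequal(g$nodes$depth, c(12.0, 11.5))
  expect_equal(g$nodes$length[g$nodes$node_id == "1"], 300L)
  # hand-collapsed adjacency of the mirrored records is the single pair {1,2}
  expect_equal(g$edges, data.frame(from = "1", to = "2"))
  # primary-orientation sequences are attached and length-consistent
  expect_equal(unname(nchar(g$sequences[g$nodes$node_id])), g$nodes$length)
})

test_that("FASTG single record gives an isolated node", {
  fg <- withr::local_tempfile(fileext = ".fastg")
  writeLines(">EDGE_7_length_500_cov_30.2;", fg)
  g <- parse_fastg(fg)
  expect_equal(g$nodes$node_id, "7")
  expect_equal(g$nodes$depth, 30.2)
  expect_equal(nrow(g$edges), 0L)
})

test_that("FASTG parse errors name the offending header", {
  fg <- withr::local_tempfile(fileext = ".fastg")
  writeLines(">EDGE_1_cov_5.0;", fg)
  expect_error(parse_fastg(fg), "EDGE_1_cov_5.0")
  writeLines(">EDGE_1_length_100_cov_5.0:EDGE_9_length_50_cov_2.0;", fg)
  expect_error(parse_fastg(fg), "undeclared")
})

test_that("GFA1 parsing reads segments, depth tags and deduplicates links", {
  gf <- withr::local_tempfile(fileext = ".gfa")
  writeLines(c("H\tVN:Z:1.0",
               "S\tn1\t*\tLN:i:400\tdp:f:16.5",
               "S\tn2\tACGTACGT",
               "L\tn1\t+\tn2\t-\t0M",
               "L\tn2\t+\tn1\t-\t0M"), gf)
  g <- parse_gfa(gf)
  expect_equal(nrow(g$nodes), 2L)
  expect_equal(g$nodes$depth[g$nodes$node_id == "n1"], 16.5)
  expect_equal(g$nodes$depth[g$nodes$node_id == "n2"], 0)
  expect_equal(g$nodes$length[g$nodes$node_id == "n2"], 8L)
  # the same link in both orientations collapses to one undirected edge
  expect_equal(nrow(g$edges), 1L)
})

test_that("GFA link to an absent segment is an error", {
  gf <- withr::local_tempfile(fileext = ".gfa")
  writeLines(c("S\tn1\tACGT", "L\tn1\t+\tmissing\t+\t0M"), gf)
  expect_error(parse_gfa(gf), "missing")
})

test_that("connected components match a transitive-closure oracle", {
  g <- toy_graph()
  # chain a-b-c is one component; drop b-c to split
  g2 <- assembly_graph(g$nodes, data.frame(from = "a", to = "b"))
  expect_equal(canon_partition(connected_components(g2)),
               canon_partition(list(c("a", "b"), "c")))
  empty <- assembly_graph(data.frame(node_id = character(),
                                     length = integer(), depth = numeric()))
  expect_equal(connected_components(empty), list())

  set.seed(101)
  ids <- sprintf("v%02d", 1:50)
  edges <- unique(data.frame(
    from = sample(ids, 60, replace = TRUE),
    to = sample(ids, 60, replace = TRUE)))
  edges <- edges[edges$from != edges$to, ]
  gr <- assembly_graph(data.frame(node_id = ids, length = 100L, depth = 1),
                       edges)
  expect_equal(canon_partition(connected_components(gr)),
               canon_partition(components_brute(ids, gr$edges)))
})

test_that("graph summary counts nodes, undirected edges and total bp", {
  fg <- withr::local_tempfile(fileext = ".fastg")
  write_two_node_fastg(fg)
  s <- graph_summary(parse_fastg(fg))
  expect_equal(s$node_count, 2L)
  expect_equal(s$edge_count, 1L)
  expect_equal(s$total_bp, 550)
})

test_that("total bp is conserved under the component partition", {
  spec <- community_spec(list(
    organism("orgA", 20, 15, 1, target = TRUE),
    organism("orgB", 15, 80, 2)), seed = 5)
  g <- simulate_community(spec, dir = withr::local_tempdir(),
                          sequences = FALSE)$graph
  comp_bp <- vapply(connected_components(g), function(cc)
    sum(as.numeric(g$nodes$length[g$nodes$node_id %in% cc])), numeric(1))
  expect_equal(sum(comp_bp), graph_summary(g)$total_bp)
})

test_that("FASTG and GFA encodings of one graph parse identically, and GFA round-trips", {
  spec <- community_spec(list(
    organism("orgA", 12, 15, 1, target = TRUE),
    organism("orgB", 8, 80, 2)), n_cross_edges = 2, seed = 9)
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  g_gfa <- parse_gfa(simulate_community(spec, dir1,
                                        format = "gfa")$paths$graph)
  g_fastg <- parse_fastg(simulate_community(spec, dir2,
                                            format = "fastg")$paths$graph)
  for (g in list(g_gfa, g_fastg)) {
    g$nodes <- g$nodes[order(g$nodes$node_id), ]
    rownames(g$nodes) <- NULL
  }
  expect_equal(g_gfa$nodes[order(g_gfa$nodes$node_id), ]$depth,
               g_fastg$nodes[order(g_fastg$nodes$node_id), ]$depth)
  expect_equal(g_gfa$edges, g_fastg$edges)
  expect_equal(sort(names(g_gfa$sequences)), sort(names(g_fastg$sequences)))
  expect_equal(g_gfa$sequences[sort(names(g_gfa$sequences))],
               g_fastg$sequences[sort(names(g_fastg$sequences))])

  # write -> parse round trip preserves ids, lengths, depths, edges
  p <- withr::local_tempfile(fileext = ".gfa")
  write_gfa(g_gfa, p)
  g3 <- parse_gfa(p)
  expect_equal(g3$nodes, g_gfa$nodes)
  expect_equal(g3$edges, g_gfa$edges)
})
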