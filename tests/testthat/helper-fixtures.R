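# shared in-code fixtures: toy graphs, toy graph files, frequency vectors

aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

toy_graph <- function() {
  assembly_graph(
    nodes = data.frame(node_id = c("a", "b", "c"),
                       length = c(1000L, 800L, 600L),
                       depth = c(12, 11, 50)),
    edges = data.frame(from = c("a", "b"), to = c("b", "c")))
}

# two-node FASTG in the SPAdes dialect, both orientations with mirrored links
write_two_node_fastg <- function(path) {
  writeLines(c(
    ">EDGE_1_length_300_cov_12.0:EDGE_2_length_250_cov_11.5;",
    paste(rep("ACGTACGTAC", 30), collapse = ""),
    ">EDGE_2_length_250_cov_11.5:EDGE_1_length_300_cov_12.0;",
    paste(rep("GGCCAGGCCA", 25), collapse = ""),
    ">EDGE_1_length_300_cov_12.0':EDGE_2_length_250_cov_11.5';",
    paste(rep("GTACGTACGT", 30), collapse = ""),
    ">EDGE_2_length_250_cov_11.5':EDGE_1_length_300_cov_12.0';",
    paste(rep("TGGCCTGGCC", 25), collapse = "")), path)
  path
}

# amino-acid frequency vector with planted Pro, Arg and Lys frequencies and
# the remaining mass spread uniformly
planted_freqs <- function(pro = 0.0476, arg = 0.07, lys = 0.05) {
  f <- stats::setNames(rep(0, 20), aa20)
  f["P"] <- pro; f["R"] <- arg; f["K"] <- lys
  rest <- setdiff(aa20, c("P", "R", "K"))
  f[rest] <- (1 - pro - arg - lys) / length(rest)
  f
}

# independent N50 oracle: scan the descending sort until half-total reached
n50_brute <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  half <- sum(s) / 2
  for (k in seq_along(s)) if (sum(s[1:k]) >= half) return(s[k])
}

# independent connected-components oracle: boolean transitive closure
components_brute <- function(ids, edges) {
  n <- length(ids)
  A <- diag(n) > 0
  dimnames(A) <- list(ids, ids)
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      A[edges$from[k], edges$to[k]] <- TRUE
      A[edges$to[k], edges$from[k]] <- TRUE
    }
  }
  repeat {
    B <- A | ((A %*% A) > 0)
    if (identical(B, A)) break
    A <- B
  }
  key <- apply(A, 1L, function(r) paste(which(r), collapse = ","))
  unname(split(ids, key))
}

# canonical form of a partition for comparison
canon_partition <- function(p) {
  p <- lapply(p, sort)
  p[order(vapply(p, `[`, character(1), 1))]
}

two_org_spec <- function(seed, n_cross = 0L, style = "direct",
                         n_target = 40L, n_other = 30L) {
  community_spec(
    list(organism("cyano", n_target, depth_mean = 15, depth_sd = 1,
                  target = TRUE),
         organism("contam", n_other, depth_mean = 150, depth_sd = 1)),
    n_cross_edges = n_cross, markers_per_target = 5L, seed = seed,
    cross_style = style)
}

target_agreement <- function(assignment, truth_target_nodes) {
  pred <- assignment$label == "target"
  truth <- assignment$node_id %in% truth_target_nodes
  mean(pred == truth)
}
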