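# Assembly-graph container and parsers (SPAdes FASTG, GFA1).
#
# The graph is undirected: reverse-complement twins from FASTG and the two
# orientations of a GFA link collapse onto one canonical node / one edge, so
# node and edge counts match what an assembly-graph viewer displays.

#' Construct an assembly graph
#'
#' The canonical contig-graph container used throughout the package: one row
#' per contig node (orientation-stripped id, length in bp, read depth) and an
#' undirected, de-duplicated edge set. Sequences are optional; only bin-FASTA
#' export requires them.
#'
#' @param nodes data.frame with columns `node_id`, `length`, `depth`.
#' @param edges data.frame with columns `from`, `to` (node ids); may be `NULL`
#'   or empty. Edges are stored as unordered pairs and de-duplicated.
#' @param sequences optional named character vector of nucleotide sequences;
#'   names must be node ids and each sequence length must equal the node's
#'   `length` field.
#'
#' @return an object of class `assembly_graph`: a list with elements `nodes`,
#'   `edges` and `sequences`.
#' @export
assembly_graph <- function(nodes, edges = NULL, sequences = NULL) {
  stopifnot(is.data.frame(nodes),
            all(c("node_id", "length", "depth") %in% names(nodes)))
  nodes <- data.frame(node_id = as.character(nodes$node_id),
                      length  = as.integer(nodes$length),
                      depth   = as.numeric(nodes$depth),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(nodes$node_id))
    stop("duplicate node ids: ",
         paste(unique(nodes$node_id[duplicated(nodes$node_id)]), collapse = ", "))
  if (nrow(nodes) && any(nodes$length < 1L))
    stop("node lengths must be >= 1")
  if (nrow(nodes) && any(nodes$depth < 0))
    stop("node depths must be >= 0")

  if (is.null(edges) || !nrow(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        stringsAsFactors = FALSE)
  } else {
    a <- as.character(edges$from)
    b <- as.character(edges$to)
    bad <- setdiff(c(a, b), nodes$node_id)
    if (length(bad))
      stop("edge endpoint(s) not declared as nodes: ",
           paste(unique(bad), collapse = ", "))
    edges <- unique(data.frame(from = pmin(a, b), to = pmax(a, b),
                               stringsAsFactors = FALSE))
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }

  if (!is.null(sequences)) {
    if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
      stop("sequences must be a named character vector")
    bad <- setdiff(names(sequences), nodes$node_id)
    if (length(bad))
      stop("sequences supplied for unknown node(s): ",
           paste(bad, collapse = ", "))
    ln <- nodes$length[match(names(sequences), nodes$node_id)]
    off <- nchar(sequences) != ln
    if (any(off))
      stop("sequence length disagrees with node length for: ",
           paste(names(sequences)[off], collapse = ", "))
  }

  structure(list(nodes = nodes, edges = edges, sequences = sequences),
            class = "assembly_graph")
}

#' @export
print.assembly_graph <- function(x, ...) {
  s <- graph_summary(x)
  cat("assembly graph:", s$node_count, "nodes,", s$edge_count, "edges,",
      format(s$total_bp, big.mark = ","), "bp\n")
  if (!is.null(x$sequences))
    cat("  sequences attached for", length(x$sequences), "node(s)\n")
  invisible(x)
}

.fastg_label_re <- "^EDGE_(.+)_length_([0-9]+)_cov_([0-9.eE+-]+)('?)$"

.parse_fastg_label <- function(lab, header) {
  m <- regmatches(lab, regexec(.fastg_label_re, lab))[[1]]
  if (length(m) != 5L)
    stop("malformed FASTG header token '", lab, "' in record '>", header, "'")
  list(id = m[2], length = as.integer(m[3]), cov = as.numeric(m[4]),
       rc = nzchar(m[5]))
}

#' Parse a SPAdes FASTG assembly graph
#'
#' Reads the SPAdes FASTG dialect: record headers of the form
#' `EDGE_<id>_length_<L>_cov_<C>`, a trailing apostrophe marking the
#' reverse-complement orientation, an optional colon-separated adjacency list,
#' and records terminated by `;`. A node and its reverse-complement twin
#' collapse to one canonical node; each adjacency entry contributes one
#' undirected edge. Sequences are attached when present (the plain-orientation
#' record wins; a reverse-complement-only record is stored reverse
#' complemented).
#'
#' Adjacency entries naming a node that never appears as a record header are
#' an error (fail-fast on truncated files), as are headers missing the length
#' or coverage tokens.
#'
#' @param path path to a FASTG file.
#' @return an [assembly_graph].
#' @export
parse_fastg <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hidx <- grep("^>", lines)
  if (!length(hidx)) stop("no FASTG records found in ", path)
  ends <- c(hidx[-1L] - 1L, length(lines))

  node_len <- integer(0); node_cov <- numeric(0)
  seq_plain <- character(0); seq_rc <- character(0)
  ef <- et <- character(0)
  declared <- character(0)

  for (k in seq_along(hidx)) {
    header <- sub("^>", "", lines[hidx[k]])
    if (!grepl(";\\s*$", header))
      stop("FASTG record not terminated by ';': '>", header, "'")
    body <- sub(";\\s*$", "", header)
    cpos <- regexpr(":", body, fixed = TRUE)
    self_lab <- if (cpos > 0L) substr(body, 1L, cpos - 1L) else body
    adj_str  <- if (cpos > 0L) substr(body, cpos + 1L, nchar(body)) else ""
    self <- .parse_fastg_label(trimws(self_lab), header)

    if (!self$id %in% declared) {
      declared <- c(declared, self$id)
      node_len[self$id] <- self$length
      node_cov[self$id] <- self$cov
    }
    sq <- if (ends[k] > hidx[k])
      paste(lines[(hidx[k] + 1L):ends[k]], collapse = "") else ""
    if (nzchar(sq)) {
      if (self$rc) seq_rc[self$id] <- sq else seq_plain[self$id] <- sq
    }

    if (nzchar(adj_str)) {
      for (lab in trimws(strsplit(adj_str, ",", fixed = TRUE)[[1]])) {
        al <- .parse_fastg_label(lab, header)
        ef <- c(ef, self$id); et <- c(et, al$id)
      }
    }
  }

  missing <- setdiff(unique(et), declared)
  if (length(missing))
    stop("FASTG adjacency references undeclared node(s): ",
         paste(missing, collapse = ", "))

  seqs <- seq_plain
  only_rc <- setdiff(names(seq_rc), names(seq_plain))
  if (length(only_rc)) seqs[only_rc] <- revcomp(seq_rc[only_rc])

  assembly_graph(
    nodes = data.frame(node_id = declared,
                       length = unname(node_len[declared]),
                       depth = unname(node_cov[declared]),
                       stringsAsFactors = FALSE),
    edges = if (length(ef)) data.frame(from = ef, to = et,
                                       stringsAsFactors = FALSE) else NULL,
    sequences = if (length(seqs)) seqs else NULL)
}

#' Parse a GFA1 assembly graph
#'
#' `S` lines become nodes (depth taken from a `dp:f:`/`DP:f:` tag when
#' present, else 0; length from the sequence or from an `LN:i:` tag) and `L`
#' lines become undirected edges, de-duplicated across orientations. A link
#' naming an absent segment is an error.
#'
#' @param path path to a GFA1 file.
#' @return an [assembly_graph].
#' @export
parse_gfa <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  ids <- character(0); lens <- integer(0); deps <- numeric(0)
  seqs <- character(0)
  lf <- lt <- character(0)

  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (f[1] == "S") {
      if (length(f) < 3L) stop("malformed GFA S line: ", ln)
      name <- f[2]; sq <- f[3]
      tags <- if (length(f) > 3L) f[-(1:3)] else character(0)
      dp <- grep("^(dp|DP):f:", tags, value = TRUE)
      depth <- if (length(dp)) as.numeric(sub("^(dp|DP):f:", "", dp[1])) else 0
      if (!identical(sq, "*")) {
        len <- nchar(sq)
        seqs[name] <- sq
      } else {
        lntag <- grep("^LN:i:", tags, value = TRUE)
        if (!length(lntag))
          stop("GFA segment '", name, "' has no sequence and no LN:i: tag")
        len <- as.integer(sub("^LN:i:", "", lntag[1]))
      }
      ids <- c(ids, name); lens <- c(lens, len); deps <- c(deps, depth)
    } else if (f[1] == "L") {
      if (length(f) < 5L) stop("malformed GFA L line: ", ln)
      lf <- c(lf, f[2]); lt <- c(lt, f[4])
    }
  }

  missing <- setdiff(unique(c(lf, lt)), ids)
  if (length(missing))
    stop("GFA link references absent segment(s): ",
         paste(missing, collapse = ", "))

  assembly_graph(
    nodes = data.frame(node_id = ids, length = lens, depth = deps,
                       stringsAsFactors = FALSE),
    edges = if (length(lf)) data.frame(from = lf, to = lt,
                                       stringsAsFactors = FALSE) else NULL,
    sequences = if (length(seqs)) seqs else NULL)
}

#' Write an assembly graph as GFA1
#'
#' @param graph an [assembly_graph].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gfa <- function(graph, path) {
  stopifnot(inherits(graph, "assembly_graph"))
  n <- graph$nodes
  sq <- graph$sequences
  slines <- vapply(seq_len(nrow(n)), function(i) {
    id <- n$node_id[i]
    s <- if (!is.null(sq) && id %in% names(sq)) sq[[id]] else "*"
    paste("S", id, s, sprintf("LN:i:%d", n$length[i]),
          sprintf("dp:f:%.10g", n$depth[i]), sep = "\t")
  }, character(1))
  e <- graph$edges
  llines <- if (nrow(e))
    paste("L", e$from, "+", e$to, "+", "0M", sep = "\t") else character(0)
  writeLines(c("H\tVN:Z:1.0", slines, llines), path)
  invisible(path)
}

#' Write an assembly graph in the SPAdes FASTG dialect
#'
#' Emits both orientations of every node with mirrored adjacency lists, the
#' way SPAdes does, so the file round-trips through [parse_fastg()].
#'
#' @inheritParams write_gfa
#' @return `path`, invisibly.
#' @export
write_fastg <- function(graph, path) {
  stopifnot(inherits(graph, "assembly_graph"))
  lab <- function(id) {
    i <- match(id, graph$nodes$node_id)
    sprintf("EDGE_%s_length_%d_cov_%.10g", id,
            graph$nodes$length[i], graph$nodes$depth[i])
  }
  adj <- adjacency_list(graph)
  out <- character(0)
  for (id in graph$nodes$node_id) {
    nb <- adj[[id]]
    for (orient in c("", "'")) {
      hdr <- paste0(">", lab(id), orient)
      if (length(nb))
        hdr <- paste0(hdr, ":", paste0(vapply(nb, lab, character(1)), orient,
                                       collapse = ","))
      hdr <- paste0(hdr, ";")
      out <- c(out, hdr)
      if (!is.null(graph$sequences) && id %in% names(graph$sequences)) {
        s <- graph$sequences[[id]]
        if (orient == "'") s <- revcomp(s)
        out <- c(out, s)
      }
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Connected components of an assembly graph
#'
#' @param graph an [assembly_graph].
#' @return a list of character vectors of node ids; every node appears in
#'   exactly one component. The empty graph yields an empty list.
#' @export
connected_components <- function(graph) {
  stopifnot(inherits(graph, "assembly_graph"))
  ids <- graph$nodes$node_id
  if (!length(ids)) return(list())
  g <- igraph::graph_from_data_frame(graph$edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  m <- igraph::components(g)$membership
  unname(split(names(m), m))
}

#' Graph-level summary counts
#'
#' @param graph an [assembly_graph].
#' @return list with `node_count` (after reverse-complement collapsing),
#'   `edge_count` (distinct undirected links) and `total_bp` (sum of node
#'   lengths).
#' @export
graph_summary <- function(graph) {
  stopifnot(inherits(graph, "assembly_graph"))
  list(node_count = nrow(graph$nodes),
       edge_count = nrow(graph$edges),
       total_bp = sum(as.numeric(graph$nodes$length)))
}

# adjacency as a named list of neighbour vectors; isolated nodes -> character(0)
adjacency_list <- function(graph) {
  ids <- graph$nodes$node_id
  adj <- stats::setNames(rep(list(character(0)), length(ids)), ids)
  e <- graph$edges
  if (nrow(e)) {
    a <- split(e$to, factor(e$from, levels = ids))
    b <- split(e$from, factor(e$to, levels = ids))
    for (id in ids) adj[[id]] <- unique(c(a[[id]], b[[id]]))
  }
  adj
}

# reverse complement of plain character DNA (IUPAC upper/lower preserved)
revcomp <- function(x) {
  comp <- chartr("ACGTUacgtuRYSWKMBDHVNryswkmbdhvn",
                 "TGCAAtgcaaYRSWMKVHDBNyrswmkvhdbn", x)
  vapply(strsplit(comp, ""), function(s) paste(rev(s), collapse = ""),
         character(1))
}
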