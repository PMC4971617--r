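#' Extract a single genome from a metagenome assembly graph
#'
#' The central fitting function of the package. Runs the whole binning
#' procedure in one call: load and threshold marker hits, seed the graph,
#' fit the depth-similarity model, propagate labels, optionally rescue
#' unconnected depth-similar nodes through a classifier table, and apply the
#' depth/length filter cascade.
#'
#' @param graph an [assembly_graph] (see [parse_fastg()], [parse_gfa()]).
#' @param hits marker hit table: path to a 12-column BLAST tabular file or a
#'   data.frame (see [load_marker_hits()]).
#' @param classifier optional classification table for
#'   [rescue_unconnected()]; `NULL` skips the rescue stage.
#' @param evalue_max marker e-value threshold (default 1e-10).
#' @param fold multiplicative depth-similarity band half-width (default 2).
#' @param min_depth,min_length final filter thresholds (defaults 10, 200;
#'   strict less-than).
#' @param mode propagation mode, `"gated-bfs"` (default) or `"component"`.
#' @param unknown handling of classifier-unknown nodes in the rescue stage.
#' @param node_pattern optional regex mapping hit subject ids to node ids.
#'
#' @return an object of class `genome_bin`: a list with `assignment` (the
#'   [assign_bins()] result after all stages), `model`, `seeds`, `stats`
#'   (contig count, total bp, N50 and mean depth of the bin, plus GC% when
#'   sequences are attached) and `params`.
#' @seealso [print.genome_bin()], [summary.genome_bin()], [plot.genome_bin()]
#' @export
extract_genome <- function(graph, hits, classifier = NULL,
                           evalue_max = 1e-10, fold = 2.0,
                           min_depth = 10.0, min_length = 200L,
                           mode = c("gated-bfs", "component"),
                           unknown = c("strict", "conservative"),
                           node_pattern = NULL) {
  mode <- match.arg(mode)
  unknown <- match.arg(unknown)
  stopifnot(inherits(graph, "assembly_graph"))

  hits <- load_marker_hits(hits, evalue_max = evalue_max, graph = graph,
                           node_pattern = node_pattern)
  seeds <- seed_nodes(hits, graph)
  model <- fit_depth_model(graph, seeds, fold = fold)
  asn <- assign_bins(graph, seeds, model, mode = mode)
  if (!is.null(classifier))
    asn <- rescue_unconnected(asn, classifier, unknown = unknown)
  asn <- apply_filters(asn, min_depth = min_depth, min_length = min_length)

  tgt <- asn[asn$label == "target", , drop = FALSE]
  stats <- list(
    n_contigs = nrow(tgt),
    total_bp = sum(as.numeric(tgt$length)),
    n50 = if (nrow(tgt)) n50(tgt$length) else NA_integer_,
    mean_depth = if (nrow(tgt)) mean(tgt$depth) else NA_real_,
    gc_percent = if (!is.null(graph$sequences) && nrow(tgt) &&
                     all(tgt$node_id %in% names(graph$sequences)))
      gc_percent(graph$sequences[tgt$node_id]) else NA_real_)

  structure(list(assignment = asn, model = model, seeds = seeds,
                 stats = stats,
                 params = list(evalue_max = evalue_max, fold = fold,
                               min_depth = min_depth,
                               min_length = min_length, mode = mode,
                               unknown = unknown)),
            class = "genome_bin")
}

#' @export
print.genome_bin <- function(x, ...) {
  cat("genome bin extracted by marker-seeded depth-gated propagation\n")
  cat(sprintf("  seeds: %d nodes; depth band [%.4g, %.4g] (center %.4g, fold %.3g)\n",
              length(x$seeds), x$model$center / x$model$fold,
              x$model$center * x$model$fold, x$model$center, x$model$fold))
  s <- x$stats
  cat(sprintf("  bin: %d contigs, %s bp, N50 %s, mean depth %.4g",
              s$n_contigs, format(s$total_bp, big.mark = ","),
              format(s$n50, big.mark = ","), s$mean_depth))
  if (!is.na(s$gc_percent)) cat(sprintf(", GC %.2f%%", s$gc_percent))
  cat("\n")
  lt <- table(x$assignment$label)
  cat("  labels:", paste(names(lt), as.integer(lt), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.genome_bin <- function(object, ...) {
  out <- list(stats = object$stats, model = object$model,
              seeds = object$seeds,
              assignment = summary(object$assignment),
              params = object$params)
  class(out) <- "summary.genome_bin"
  out
}

#' @export
print.summary.genome_bin <- function(x, ...) {
  print(x$model)
  print(x$assignment)
  s <- x$stats
  cat(sprintf("bin: %d contigs, %s bp, N50 %s\n", s$n_contigs,
              format(s$total_bp, big.mark = ","),
              format(s$n50, big.mark = ",")))
  invisible(x)
}

#' Depth/length plot of a binned assembly graph
#'
#' Scatter of node depth against node length (log-log), coloured by bin
#' label, with the depth-similarity band drawn as horizontal lines.
#'
#' @param x a `genome_bin`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.genome_bin <- function(x, ...) {
  a <- x$assignment
  col <- c(target = "#1b7837", contaminant = "#b2182b",
           unassigned = "grey60")[a$label]
  pch <- ifelse(a$provenance %in% "seed", 17, 16)
  graphics::plot(a$length, a$depth, log = "xy", col = col, pch = pch,
                 xlab = "node length (bp)", ylab = "read depth", ...)
  graphics::abline(h = c(x$model$center / x$model$fold, x$model$center,
                         x$model$center * x$model$fold),
                   lty = c(2, 1, 2), col = "grey30")
  graphics::legend("topright", bty = "n",
                   legend = c("target", "contaminant", "unassigned", "seed"),
                   col = c("#1b7837", "#b2182b", "grey60", "#1b7837"),
                   pch = c(16, 16, 16, 17))
  invisible(x)
}
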