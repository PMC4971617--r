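# Assembly statistics: N50, GC content, coding density, category proportions.

#' N50 of a set of contig lengths
#'
#' Length of the shortest contig in the smallest set of longest contigs whose
#' summed length reaches at least half the assembly total (cumulative-sum
#' `>=` convention).
#'
#' @param lengths non-empty vector of positive integer lengths.
#' @return integer N50 in bp.
#' @export
n50 <- function(lengths) {
  if (!length(lengths)) stop("n50: empty length list")
  stopifnot(all(lengths > 0))
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  as.integer(s[which(cumsum(s) >= sum(s) / 2)[1]])
}

#' GC content of a set of nucleotide sequences
#'
#' `100 * (G + C) / (A + C + G + T)`, case-insensitive; ambiguity codes and N
#' are excluded from both numerator and denominator.
#'
#' @param sequences character vector of IUPAC nucleotide sequences, a
#'   `DNAStringSet`, or a path to a FASTA file.
#' @return GC percentage (0-100).
#' @export
gc_percent <- function(sequences) {
  seqs <- .as_dna(sequences)
  cnt <- colSums(Biostrings::letterFrequency(seqs, c("A", "C", "G", "T")))
  tot <- sum(cnt)
  if (tot == 0) stop("gc_percent: no unambiguous bases")
  100 * (cnt[["G"]] + cnt[["C"]]) / tot
}

.as_dna <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x))
    return(Biostrings::readDNAStringSet(x))
  Biostrings::DNAStringSet(toupper(x))
}

#' Assembly summary statistics
#'
#' Contig count, total length, N50, GC%, length range, and (when a GFF3
#' annotation is supplied) the percentage of bases covered by at least one
#' CDS feature, computed as a per-contig interval union so overlapping
#' features are not double counted. If the annotation has no CDS features,
#' `gene` features are used directly.
#'
#' @param contigs FASTA path, `DNAStringSet`, or character vector of
#'   sequences (named).
#' @param annotation optional GFF3 path or `GRanges`. CDS/gene coordinates
#'   must lie on known contigs (1-based inclusive).
#' @return object of class `genome_stats`: list with `n_contigs`,
#'   `total_bp`, `n50`, `gc_percent`, `min_len`, `max_len`,
#'   `coding_percent` (NA without annotation).
#' @export
assembly_summary <- function(contigs, annotation = NULL) {
  seqs <- .as_dna(contigs)
  lens <- Biostrings::width(seqs)
  if (!length(lens)) stop("assembly_summary: no contigs")
  cn <- sub("\\s.*$", "", names(seqs))

  coding <- NA_real_
  if (!is.null(annotation)) {
    gr <- if (is.character(annotation)) rtracklayer::import(annotation)
          else annotation
    feats <- gr[gr$type == "CDS"]
    if (!length(feats)) feats <- gr[gr$type == "gene"]
    bad <- setdiff(as.character(unique(GenomicRanges::seqnames(feats))), cn)
    if (length(bad))
      stop("assembly_summary: CDS on unknown contig(s): ",
           paste(bad, collapse = ", "))
    covered <- sum(as.numeric(IRanges::width(
      GenomicRanges::reduce(feats, ignore.strand = TRUE))))
    coding <- 100 * covered / sum(as.numeric(lens))
  }

  structure(list(n_contigs = length(lens),
                 total_bp = sum(as.numeric(lens)),
                 n50 = n50(lens),
                 gc_percent = gc_percent(seqs),
                 min_len = min(lens), max_len = max(lens),
                 coding_percent = coding),
            class = "genome_stats")
}

#' @export
print.genome_stats <- function(x, ...) {
  cat(sprintf("contigs: %d  total: %s bp  N50: %s  GC: %.2f%%\n",
              x$n_contigs, format(x$total_bp, big.mark = ","),
              format(x$n50, big.mark = ","), x$gc_percent))
  cat(sprintf("length range: %s - %s bp\n",
              format(x$min_len, big.mark = ","),
              format(x$max_len, big.mark = ",")))
  if (!is.na(x$coding_percent))
    cat(sprintf("coding: %.2f%%\n", x$coding_percent))
  invisible(x)
}

#' Percentage of genes in a functional category
#'
#' @param category_count genes in the category (0..total).
#' @param total_genes total genes (> 0).
#' @return percentage rounded to 2 decimals.
#' @export
category_proportion <- function(category_count, total_genes) {
  stopifnot(length(category_count) == 1L, length(total_genes) == 1L)
  if (total_genes <= 0) stop("category_proportion: total_genes must be > 0")
  if (category_count < 0 || category_count > total_genes)
    stop("category_proportion: category_count outside [0, total_genes]")
  round(100 * category_count / total_genes, 2)
}
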