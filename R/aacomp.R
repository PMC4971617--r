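# Proteome amino-acid composition indices used in cold-adaptation analyses.
#
# Cold-adapted proteomes tend to trade arginine for lysine and to carry less
# proline, both of which loosen protein secondary structure at low
# temperature; Pro% and the Arg:Lys ratio summarise those signals at the
# whole-proteome level.

.aa_standard <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.as_aa <- function(x) {
  if (methods::is(x, "AAStringSet")) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x))
    return(Biostrings::readAAStringSet(x))
  Biostrings::AAStringSet(toupper(x))
}

#' Amino-acid composition of a proteome
#'
#' Counts residues over the 20 standard amino acids, case-insensitively.
#' Stop symbols (`*`) and the non-standard letters X, B, Z, J, U, O are
#' excluded from both the counts and the total, so frequencies are relative
#' to standard residues only.
#'
#' @param proteome protein FASTA path, `AAStringSet`, or character vector of
#'   sequences.
#' @return object of class `aa_composition`: list with `counts` (named,
#'   20 residues), `total`, `freqs`, `pro_percent` and `arg_lys`
#'   (`NA` when the proteome has no lysine, rather than infinity).
#' @export
aa_composition <- function(proteome) {
  seqs <- .as_aa(proteome)
  if (!length(seqs) || sum(Biostrings::width(seqs)) == 0)
    stop("aa_composition: empty proteome")
  counts <- colSums(Biostrings::letterFrequency(seqs, .aa_standard))
  total <- sum(counts)
  if (total == 0) stop("aa_composition: no standard residues in proteome")
  structure(list(counts = counts, total = total, freqs = counts / total,
                 pro_percent = 100 * counts[["P"]] / total,
                 arg_lys = if (counts[["K"]] > 0)
                   counts[["R"]] / counts[["K"]] else NA_real_),
            class = "aa_composition")
}

#' @export
print.aa_composition <- function(x, ...) {
  cat(sprintf("proteome composition over %s standard residues\n",
              format(x$total, big.mark = ",")))
  cat(sprintf("  Pro%%  = %.2f\n", x$pro_percent))
  cat(sprintf("  Arg:Lys = %s\n",
              if (is.na(x$arg_lys)) "undefined (no Lys)"
              else sprintf("%.2f", x$arg_lys)))
  invisible(x)
}

#' Compare amino-acid composition indices across proteomes
#'
#' One row per proteome, in input order, with the total residue count and
#' the display-rounded (2 dp) Pro% and Arg:Lys indices.
#'
#' @param proteomes named list of proteome inputs (each as accepted by
#'   [aa_composition()]); at least one, names unique.
#' @return data.frame with columns `name`, `total`, `pro_percent`,
#'   `arg_lys`.
#' @export
compare_compositions <- function(proteomes) {
  stopifnot(length(proteomes) >= 1)
  nm <- names(proteomes)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("compare_compositions: proteomes must be named")
  if (anyDuplicated(nm))
    stop("compare_compositions: duplicate proteome names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  rows <- lapply(nm, function(n) {
    cmp <- aa_composition(proteomes[[n]])
    data.frame(name = n, total = cmp$total,
               pro_percent = round(cmp$pro_percent, 2),
               arg_lys = round(cmp$arg_lys, 2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
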