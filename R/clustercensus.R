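# Rule-based gene-cluster detection and cold-shock gene census over
# annotation tables (GFF3 gene features + per-gene domain labels).
#
# All detectors are configuration-driven: role recognition combines product
# regexes and domain labels (see inst/extdata/cluster_rules.yaml), so the
# same scans work on any annotation vocabulary once the rules are adapted.
# "Adjacent" always means consecutive gene records on a contig with no
# intervening gene, irrespective of strand unless a detector states
# otherwise.

#' Build a gene-record table
#'
#' The annotation container used by the census and cluster detectors: one
#' row per gene, sorted by contig and start, with list-columns for domain
#' labels and optional motif flags.
#'
#' @param gene_id,contig character vectors.
#' @param start,end integer coordinates, 1-based inclusive, `start <= end`.
#' @param strand `"+"` or `"-"` (recycled).
#' @param product free-text product annotation (recycled).
#' @param domains list of character vectors of domain labels (Pfam accession
#'   and/or name), or a character vector of `;`-separated labels.
#' @param motif_flags optional list of character vectors (e.g.
#'   `"has-GGDEF-motif"`, `"ggdef-motif-absent"`).
#' @return data.frame of class `gene_records`.
#' @export
gene_records <- function(gene_id, contig, start, end, strand = "+",
                         product = "", domains = NULL, motif_flags = NULL) {
  n <- length(gene_id)
  start <- as.integer(start); end <- as.integer(end)
  contig <- rep_len(as.character(contig), n)
  stopifnot(length(start) == n, length(end) == n)
  if (any(start > end)) stop("gene_records: start > end")
  strand <- rep_len(as.character(strand), n)
  if (!all(strand %in% c("+", "-")))
    stop("gene_records: strand must be '+' or '-'")
  product <- rep_len(as.character(product), n)
  if (is.null(domains)) domains <- rep(list(character(0)), n)
  if (is.character(domains))
    domains <- lapply(strsplit(domains, ";", fixed = TRUE),
                      function(d) trimws(d[nzchar(trimws(d))]))
  stopifnot(length(domains) == n)
  if (is.null(motif_flags)) motif_flags <- rep(list(character(0)), n)
  if (is.character(motif_flags))
    motif_flags <- lapply(strsplit(motif_flags, ";", fixed = TRUE),
                          function(d) trimws(d[nzchar(trimws(d))]))

  df <- data.frame(gene_id = as.character(gene_id),
                   contig = as.character(contig),
                   start = start, end = end, strand = strand,
                   product = product, stringsAsFactors = FALSE)
  df$domains <- domains
  df$motif_flags <- motif_flags
  df <- df[order(df$contig, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gene_records", "data.frame")
  df
}

#' Load an annotation: GFF3 gene features plus a domain-hit table
#'
#' Gene coordinates come from the GFF3 `gene` features (or from `CDS`
#' features when no `gene` features exist); domain labels are merged in from
#' a TSV with header columns `gene_id`, `domain_accession`, `domain_name`.
#' Domain rows naming an unknown gene id are skipped with a warning. Genes
#' without any domain row are kept with an empty domain set.
#'
#' @param gff GFF3 path or `GRanges`; gene ids taken from the `ID` (or
#'   `locus_tag`) attribute.
#' @param domains path to the domain TSV, or a data.frame; `NULL` for none.
#' @param motif_flags optional path/data.frame with columns `gene_id`,
#'   `flag`.
#' @return a [gene_records] table.
#' @export
load_annotation <- function(gff, domains = NULL, motif_flags = NULL) {
  gr <- if (is.character(gff)) rtracklayer::import(gff) else gff
  feats <- gr[gr$type == "gene"]
  if (!length(feats)) feats <- gr[gr$type == "CDS"]
  if (!length(feats)) stop("load_annotation: no gene or CDS features")
  mc <- S4Vectors::mcols(feats)
  id <- if ("ID" %in% names(mc) && !all(is.na(mc$ID))) mc$ID
        else if ("locus_tag" %in% names(mc)) mc$locus_tag
        else stop("load_annotation: gene features lack ID/locus_tag")
  product <- if ("product" %in% names(mc)) as.character(mc$product)
             else if ("Name" %in% names(mc)) as.character(mc$Name) else ""
  product[is.na(product)] <- ""
  strand <- as.character(GenomicRanges::strand(feats))
  strand[strand == "*"] <- "+"

  dom_list <- stats::setNames(rep(list(character(0)), length(feats)),
                              as.character(id))
  if (!is.null(domains)) {
    dt <- if (is.character(domains))
      utils::read.delim(domains, stringsAsFactors = FALSE,
                        comment.char = "#") else domains
    stopifnot(all(c("gene_id", "domain_accession", "domain_name")
                  %in% names(dt)))
    unknown <- !dt$gene_id %in% names(dom_list)
    if (any(unknown))
      warning("load_annotation: skipped ", sum(unknown),
              " domain row(s) with unknown gene id(s)")
    dt <- dt[!unknown, , drop = FALSE]
    for (g in unique(dt$gene_id)) {
      r <- dt[dt$gene_id == g, , drop = FALSE]
      dom_list[[g]] <- unique(c(r$domain_accession, r$domain_name))
    }
  }

  mf_list <- NULL
  if (!is.null(motif_flags)) {
    mt <- if (is.character(motif_flags))
      utils::read.delim(motif_flags, stringsAsFactors = FALSE) else motif_flags
    stopifnot(all(c("gene_id", "flag") %in% names(mt)))
    mf_list <- stats::setNames(rep(list(character(0)), length(feats)),
                               as.character(id))
    for (g in unique(mt$gene_id))
      if (g %in% names(mf_list))
        mf_list[[g]] <- unique(mt$flag[mt$gene_id == g])
  }

  gene_records(gene_id = as.character(id),
               contig = as.character(GenomicRanges::seqnames(feats)),
               start = GenomicRanges::start(feats),
               end = GenomicRanges::end(feats),
               strand = strand, product = product,
               domains = unname(dom_list),
               motif_flags = if (is.null(mf_list)) NULL else unname(mf_list))
}

#' Read a flat gene table into gene records
#'
#' Loads a TSV with header columns `gene_id`, `contig`, `start`, `end`,
#' `strand`, `product`, `domains` (`;`-separated labels) and optionally
#' `motif` (`present`/`absent`, converted to motif flags). `#` lines are
#' comments. This is the format of the annotation tables shipped under
#' `inst/extdata` (published gene ids, products and domains from the
#' P. priestleyi BC1401 IMG annotation; coordinates in those files are
#' synthetic placeholders).
#'
#' @param path TSV path.
#' @return a [gene_records] table.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#")
  need <- c("gene_id", "contig", "start", "end", "strand", "product",
            "domains")
  stopifnot(all(need %in% names(df)))
  mf <- NULL
  if ("motif" %in% names(df))
    mf <- ifelse(df$motif == "present", "has-GGDEF-motif",
                 ifelse(df$motif == "absent", "ggdef-motif-absent", ""))
  gene_records(df$gene_id, df$contig, df$start, df$end, df$strand,
               df$product, domains = df$domains, motif_flags = mf)
}

#' Default gene-cluster role rules
#'
#' Reads the rule configuration shipped with the package (see
#' `system.file("extdata", "cluster_rules.yaml", package = "psychrobin")`).
#'
#' @param path optional path to an alternative YAML rule file.
#' @return nested list of rules.
#' @export
default_cluster_rules <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cluster_rules.yaml",
                        package = "psychrobin")
  yaml::read_yaml(path)
}

#' Default cold-shock family census rules
#'
#' @param path optional path to an alternative YAML rule file.
#' @return named list: one rule per gene family.
#' @export
default_family_rules <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "family_rules.yaml",
                        package = "psychrobin")
  yaml::read_yaml(path)
}

# does each gene satisfy a rule (product regex OR domain label)?
gene_matches <- function(genes, rule) {
  hit <- rep(FALSE, nrow(genes))
  if (!is.null(rule$domains) && length(rule$domains))
    hit <- hit | vapply(genes$domains,
                        function(d) any(d %in% rule$domains), logical(1))
  if (!is.null(rule$product) && nzchar(rule$product))
    hit <- hit | grepl(rule$product, genes$product,
                       ignore.case = TRUE, perl = TRUE)
  hit
}

#' Census result container
#'
#' @param counts named non-negative integer vector of per-family hit counts.
#' @return object of class `census_result` with fields `counts` and `total`
#'   (`total` is always the sum of the counts).
#' @export
census_result <- function(counts) {
  stopifnot(!is.null(names(counts)), all(counts >= 0))
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(list(counts = counts, total = sum(counts)),
            class = "census_result")
}

#' @export
print.census_result <- function(x, ...) {
  print(data.frame(family = names(x$counts), hits = unname(x$counts),
                   stringsAsFactors = FALSE), row.names = FALSE)
  cat("total:", x$total, "\n")
  invisible(x)
}

#' Cold-shock gene-family census
#'
#' Counts, for each configured gene family, the annotated genes matching the
#' family's product/domain rule. Counts reflect the supplied annotation (no
#' fresh homology search is run).
#'
#' @param genes a [gene_records] table.
#' @param family_rules named rule list; default
#'   [default_family_rules()]. A family whose entry carries neither a
#'   product regex nor domain labels is a configuration error.
#' @return a [census_result].
#' @export
cold_shock_census <- function(genes, family_rules = default_family_rules()) {
  stopifnot(inherits(genes, "gene_records"), length(family_rules) > 0)
  for (fam in names(family_rules)) {
    r <- family_rules[[fam]]
    if ((is.null(r$product) || !nzchar(r$product)) &&
        (is.null(r$domains) || !length(r$domains)))
      stop("cold_shock_census: no rule for family '", fam, "'")
  }
  counts <- vapply(family_rules,
                   function(r) sum(gene_matches(genes, r)), numeric(1))
  census_result(counts)
}

new_cluster_call <- function(type, contig, members, complete,
                             flags = character(0)) {
  members <- members[order(members$start), , drop = FALSE]
  rownames(members) <- NULL
  structure(list(cluster_type = type, contig = contig, members = members,
                 complete = complete, flags = flags),
            class = "cluster_call")
}

#' @export
print.cluster_call <- function(x, ...) {
  cat(sprintf("%s cluster on %s (%s%s): %s\n", x$cluster_type, x$contig,
              if (x$complete) "complete" else "incomplete",
              if (length(x$flags))
                paste0("; ", paste(x$flags, collapse = ",")) else "",
              paste(sprintf("%s=%s", x$members$role, x$members$gene_id),
                    collapse = " ")))
  invisible(x)
}

cluster_calls <- function(calls) structure(calls, class = "cluster_calls")

#' @export
print.cluster_calls <- function(x, ...) {
  cat(length(x), "cluster call(s)\n")
  for (cl in x) print(cl)
  invisible(x)
}

#' @export
as.data.frame.cluster_calls <- function(x, ...) {
  if (!length(x))
    return(data.frame(cluster_type = character(), contig = character(),
                      n_members = integer(), complete = logical(),
                      flags = character(), members = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(x, function(cl) data.frame(
    cluster_type = cl$cluster_type, contig = cl$contig,
    n_members = nrow(cl$members), complete = cl$complete,
    flags = paste(cl$flags, collapse = ";"),
    members = paste(sprintf("%s:%s", cl$members$role, cl$members$gene_id),
                    collapse = ";"),
    stringsAsFactors = FALSE)))
}

#' @export
length.cluster_calls <- function(x) length(unclass(x))

.member_row <- function(genes, i, role)
  data.frame(role = role, gene_id = genes$gene_id[i],
             start = genes$start[i], stringsAsFactors = FALSE)

#' Detect Wzy-dependent polysaccharide-export gene clusters
#'
#' A WZY call is anchored on an adjacent `wza`/`wzc` gene pair (consecutive
#' gene records, either order) and collects `wzx` and `wzy` role genes lying
#' within `max_gap_genes` gene positions of the anchor on the same contig.
#' `complete` is TRUE iff all four roles are present; partial clusters are
#' reported with `complete = FALSE`. Without the adjacent anchor there is no
#' call.
#'
#' @param genes a [gene_records] table.
#' @param max_gap_genes window (in gene positions) around the anchor pair
#'   for `wzx`/`wzy` (default 10).
#' @param rules role-recognition rules, see [default_cluster_rules()].
#' @return a `cluster_calls` list.
#' @export
find_wzy_clusters <- function(genes, max_gap_genes = 10L,
                              rules = default_cluster_rules()) {
  stopifnot(inherits(genes, "gene_records"))
  calls <- list()
  for (ct in split(genes, genes$contig)) {
    ct <- ct[order(ct$start), , drop = FALSE]
    n <- nrow(ct)
    if (n < 2L) next
    is_role <- lapply(rules$roles[c("wza", "wzc", "wzx", "wzy")],
                      function(r) gene_matches(ct, r))
    anchors <- which((is_role$wza[-n] & is_role$wzc[-1]) |
                       (is_role$wzc[-n] & is_role$wza[-1]))
    for (i in anchors) {
      lo <- max(1L, i - max_gap_genes)
      hi <- min(n, i + 1L + max_gap_genes)
      win <- setdiff(lo:hi, c(i, i + 1L))
      members <- rbind(
        .member_row(ct, i, if (is_role$wza[i]) "wza" else "wzc"),
        .member_row(ct, i + 1L, if (is_role$wza[i]) "wzc" else "wza"))
      for (j in win[is_role$wzx[win]])
        members <- rbind(members, .member_row(ct, j, "wzx"))
      for (j in win[is_role$wzy[win]])
        members <- rbind(members, .member_row(ct, j, "wzy"))
      calls[[length(calls) + 1L]] <- new_cluster_call(
        "WZY", ct$contig[1], members,
        complete = all(c("wza", "wzc", "wzx", "wzy") %in% members$role))
    }
  }
  cluster_calls(calls)
}

#' Detect ABC-dependent polysaccharide-export gene clusters
#'
#' Groups `kpsD`/`kpsE`/`kpsM`/`kpsT` role genes on one contig so that each
#' group spans at most `max_span_bp` (the subunits of one export system can
#' sit tens of kb apart). Two adjacent `kpsM` fragments (consecutive gene
#' records) count as one transporter gene and raise the `split-kpsM` flag.
#' `complete` is TRUE iff all four roles are covered.
#'
#' @param genes a [gene_records] table.
#' @param max_span_bp maximum bp span of one cluster (default 100000).
#' @param rules role-recognition rules.
#' @return a `cluster_calls` list.
#' @export
find_abc_clusters <- function(genes, max_span_bp = 100000L,
                              rules = default_cluster_rules()) {
  stopifnot(inherits(genes, "gene_records"))
  roles <- c("kpsD", "kpsE", "kpsM", "kpsT")
  calls <- list()
  for (ct in split(genes, genes$contig)) {
    ct <- ct[order(ct$start), , drop = FALSE]
    m <- vapply(rules$roles[roles], function(r) gene_matches(ct, r),
                logical(nrow(ct)))
    if (nrow(ct) == 1L) m <- matrix(m, nrow = 1, dimnames = list(NULL, roles))
    role_of <- apply(m, 1L, function(z) if (any(z)) roles[which(z)[1]]
                     else NA_character_)
    idx <- which(!is.na(role_of))
    if (!length(idx)) next
    grp <- integer(length(idx))
    g <- 1L; grp[1] <- 1L; grp_start <- ct$start[idx[1]]
    for (k in seq_along(idx)[-1]) {
      if (ct$end[idx[k]] - grp_start <= max_span_bp) grp[k] <- g
      else { g <- g + 1L; grp[k] <- g; grp_start <- ct$start[idx[k]] }
    }
    for (gg in unique(grp)) {
      sel <- idx[grp == gg]
      members <- do.call(rbind, lapply(sel, function(j)
        .member_row(ct, j, role_of[j])))
      flags <- character(0)
      km <- sel[role_of[sel] == "kpsM"]
      if (length(km) >= 2L && any(diff(km) == 1L))
        flags <- "split-kpsM"
      calls[[length(calls) + 1L]] <- new_cluster_call(
        "ABC", ct$contig[1], members,
        complete = all(roles %in% role_of[sel]), flags = flags)
    }
  }
  cluster_calls(calls)
}

#' Detect Wsp chemosensory cassettes
#'
#' A WSP call requires six consecutive same-strand gene records matching the
#' role sequence `wspB, wspC, wspA, wspD, wspE, wspF` (reversed in
#' coordinate order for a minus-strand cassette) with no intervening
#' unrelated gene. The next gene downstream of the cassette (in the
#' cassette's reading direction) is reported as the response-regulator-slot
#' occupant, and the `non-canonical-regulator` flag is raised when that
#' occupant lacks a GGDEF domain.
#'
#' @param genes a [gene_records] table.
#' @param rules role-recognition rules.
#' @return a `cluster_calls` list.
#' @export
find_wsp_cassette <- function(genes, rules = default_cluster_rules()) {
  stopifnot(inherits(genes, "gene_records"))
  order_roles <- c("wspB", "wspC", "wspA", "wspD", "wspE", "wspF")
  calls <- list()
  for (ct in split(genes, genes$contig)) {
    ct <- ct[order(ct$start), , drop = FALSE]
    n <- nrow(ct)
    if (n < 6L) next
    m <- vapply(rules$roles[order_roles], function(r) gene_matches(ct, r),
                logical(n))
    role_of <- apply(m, 1L, function(z) if (any(z)) order_roles[which(z)[1]]
                     else NA_character_)
    for (i in seq_len(n - 5L)) {
      r <- role_of[i:(i + 5L)]
      s <- ct$strand[i:(i + 5L)]
      if (anyNA(r) || length(unique(s)) != 1L) next
      fwd <- identical(unname(r), order_roles)
      rev_ <- identical(unname(r), rev(order_roles))
      if (!(fwd && s[1] == "+") && !(rev_ && s[1] == "-")) next
      members <- do.call(rbind, lapply(0:5, function(k)
        .member_row(ct, i + k, role_of[i + k])))
      occ <- if (s[1] == "+") {
        if (i + 6L <= n) i + 6L else NA_integer_
      } else {
        if (i - 1L >= 1L) i - 1L else NA_integer_
      }
      flags <- character(0)
      if (!is.na(occ)) {
        members <- rbind(members, .member_row(ct, occ, "regulator-slot"))
        if (!gene_matches(ct[occ, , drop = FALSE], rules$ggdef))
          flags <- "non-canonical-regulator"
      }
      calls[[length(calls) + 1L]] <- new_cluster_call(
        "WSP", ct$contig[1], members, complete = TRUE, flags = flags)
    }
  }
  cluster_calls(calls)
}

#' Detect GGDEF-domain diguanylate-cyclase genes
#'
#' One call per gene carrying a GGDEF domain label. Motif evidence is
#' three-state: a supplied protein sequence is scanned for a literal
#' `GGDEF`/`GGEEF` motif (authoritative); otherwise explicit motif flags on
#' the gene (`has-GGDEF-motif` / `ggdef-motif-absent`) decide; with no
#' evidence the motif status is unknown and no flag is raised. The
#' `degenerate-motif` flag marks genes whose domain is present but whose
#' motif is known absent.
#'
#' @param genes a [gene_records] table.
#' @param proteins optional named character vector or `AAStringSet` of
#'   protein sequences keyed by gene id.
#' @param rules role-recognition rules.
#' @return a `cluster_calls` list.
#' @export
find_ggdef_genes <- function(genes, proteins = NULL,
                             rules = default_cluster_rules()) {
  stopifnot(inherits(genes, "gene_records"))
  if (!is.null(proteins) && methods::is(proteins, "AAStringSet"))
    proteins <- stats::setNames(as.character(proteins), names(proteins))
  hit <- which(gene_matches(genes, rules$ggdef))
  calls <- lapply(hit, function(i) {
    motif <- NA
    id <- genes$gene_id[i]
    if (!is.null(proteins) && id %in% names(proteins)) {
      motif <- grepl("GG[DE]EF", toupper(proteins[[id]]))
    } else {
      fl <- genes$motif_flags[[i]]
      if (length(fl)) motif <- "has-GGDEF-motif" %in% fl
    }
    new_cluster_call("GGDEF", genes$contig[i], .member_row(genes, i, "ggdef"),
                     complete = TRUE,
                     flags = if (isFALSE(motif)) "degenerate-motif"
                             else character(0))
  })
  cluster_calls(calls)
}

#' Detect alg44-like genes: HlyD-family domain present, PilZ absent
#'
#' One call per gene holding at least one HlyD-family domain
#' (HlyD_3/pfam13437, Biotin_lipoyl_2/pfam13533, HlyD_D23/pfam16576) and no
#' PilZ domain. The `abc-associated` flag is raised when an
#' ABC-transporter-annotated gene lies within `window_genes` gene positions
#' on the same contig.
#'
#' @param genes a [gene_records] table.
#' @param window_genes neighbourhood (gene positions) for the ABC
#'   association flag (default 5).
#' @param rules role-recognition rules.
#' @return a `cluster_calls` list.
#' @export
find_alg44_like <- function(genes, window_genes = 5L,
                            rules = default_cluster_rules()) {
  stopifnot(inherits(genes, "gene_records"))
  calls <- list()
  for (ct in split(genes, genes$contig)) {
    ct <- ct[order(ct$start), , drop = FALSE]
    hl <- gene_matches(ct, rules$hlyd)
    pz <- gene_matches(ct, rules$pilz)
    abc <- gene_matches(ct, rules$abc_transporter)
    for (i in which(hl & !pz)) {
      nb <- setdiff(max(1L, i - window_genes):min(nrow(ct), i + window_genes),
                    i)
      flags <- if (any(abc[nb])) "abc-associated" else character(0)
      calls[[length(calls) + 1L]] <- new_cluster_call(
        "ALG44LIKE", ct$contig[1], .member_row(ct, i, "alg44-like"),
        complete = TRUE, flags = flags)
    }
  }
  cluster_calls(calls)
}
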