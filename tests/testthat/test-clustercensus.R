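test_that("annotation loading merges GFF genes with domain rows", {
  ann <- simulate_annotation(
    planted = list(list(type = "GGDEF", motif = TRUE),
                   list(type = "ALG44LIKE")),
    seed = 41, dir = withr::local_tempdir())
  genes <- load_annotation(ann$paths$gff, ann$paths$domains,
                           ann$paths$motif_flags)
  expect_s3_class(genes, "gene_records")
  expect_equal(nrow(genes), nrow(ann$genes))
  expect_equal(genes$gene_id[order(genes$gene_id)],
               ann$genes$gene_id[order(ann$genes$gene_id)])
  i <- match(ann$genes$gene_id, genes$gene_id)
  expect_equal(genes$start[i], ann$genes$start)
  expect_equal(lapply(genes$domains[i], sort),
               lapply(ann$genes$domains, sort))
  # a domain row with an unknown gene id is skipped with a warning
  dt <- utils::read.delim(ann$paths$domains)
  dt <- rbind(dt, data.frame(gene_id = "ghost",
                             domain_accession = "pfam00990",
                             domain_name = "GGDEF"))
  expect_warning(load_annotation(ann$paths$gff, dt), "unknown gene id")
})

test_that("cold-shock census counts rule matches and checks the config", {
  g <- gene_records(c("g1", "g2", "g3"), "c1",
                    c(1, 1000, 2000), c(900, 1900, 2900),
                    product = c("chaperone protein DnaK",
                                "hypothetical protein",
                                "trigger factor"))
  cs <- cold_shock_census(g)
  expect_equal(cs$counts[["dnaK"]], 1L)
  expect_equal(cs$counts[["tig"]], 1L)
  expect_equal(cs$total, sum(cs$counts))
  expect_error(cold_shock_census(g, list(dnaK = list())), "no rule")
})

test_that("published per-family counts aggregate to the printed totals", {
  tab <- utils::read.delim(
    system.file("extdata", "bc1401_cold_shock_counts.tsv",
                package = "psychrobin"), comment.char = "#")
  expect_equal(nrow(tab), 21L)
  totals <- vapply(c("BC1401", "PCC6306", "JSC12", "PCC7407"), function(s)
    census_result(setNames(tab[[s]], tab$family))$total, integer(1))
  expect_equal(unname(totals), c(29L, 29L, 29L, 27L))
})

test_that("Wzy detection needs the adjacent wza/wzc anchor and reports partial sets", {
  ann <- simulate_annotation(
    planted = list(list(type = "WZY")),
    decoys = list(list(type = "WZY", violation = "missing-role"),
                  list(type = "WZY", violation = "separated-anchor")),
    seed = 42)
  calls <- find_wzy_clusters(ann$genes)
  expect_equal(length(calls), 2L)  # separated anchor yields no call at all
  complete <- vapply(calls, `[[`, logical(1), "complete")
  expect_equal(sum(complete), 1L)
  full <- calls[complete][[1]]
  expect_setequal(full$members$role, c("wza", "wzc", "wzx", "wzy"))
  expect_false(is.unsorted(full$members$start))
  partial <- calls[!complete][[1]]
  expect_false("wzy" %in% partial$members$role)
})

test_that("ABC detection spans ~80 kb, merges split kpsM, reports lone roles", {
  ann <- simulate_annotation(
    planted = list(list(type = "ABC"),
                   list(type = "ABC", split_kpsM = TRUE)),
    decoys = list(list(type = "ABC", violation = "missing-role")),
    seed = 43)
  calls <- find_abc_clusters(ann$genes)
  complete <- vapply(calls, `[[`, logical(1), "complete")
  expect_equal(sum(complete), 2L)
  flags <- lapply(calls, `[[`, "flags")
  expect_equal(sum(vapply(flags, function(f) "split-kpsM" %in% f,
                          logical(1))), 1L)
  # the decoy kept only kpsT: an incomplete call, never a complete one
  expect_true(any(!complete))
  lone <- calls[!complete][[1]]
  expect_equal(unique(lone$members$role), "kpsT")
  # a span violation splits one cluster into incomplete groups
  wide <- simulate_annotation(
    decoys = list(list(type = "ABC", violation = "span-exceeded")),
    seed = 44)
  wcalls <- find_abc_clusters(wide$genes)
  expect_true(length(wcalls) >= 2L)
  expect_false(any(vapply(wcalls, `[[`, logical(1), "complete")))
})

test_that("Wsp cassette requires the exact same-strand role order", {
  ann <- simulate_annotation(
    planted = list(list(type = "WSP", regulator = "adenylate-cyclase"),
                   list(type = "WSP", regulator = "diguanylate-cyclase")),
    decoys = list(list(type = "WSP", violation = "order-swapped")),
    seed = 45)
  calls <- find_wsp_cassette(ann$genes)
  expect_equal(length(calls), 2L)
  flagged <- vapply(calls, function(x)
    "non-canonical-regulator" %in% x$flags, logical(1))
  expect_equal(sum(flagged), 1L)   # the adenylate-cyclase slot occupant
  occ <- lapply(calls, function(x)
    x$members$role[nrow(x$members)])
  expect_true(all(vapply(calls, function(x)
    "regulator-slot" %in% x$members$role, logical(1))))
})

test_that("GGDEF calls flag degenerate motifs only on explicit evidence", {
  ann <- simulate_annotation(
    planted = list(list(type = "GGDEF", motif = TRUE),
                   list(type = "GGDEF", motif = FALSE)),
    decoys = list(list(type = "GGDEF", violation = "no-domain")),
    seed = 46)
  calls <- find_ggdef_genes(ann$genes)
  expect_equal(length(calls), 2L)  # decoy without the domain is not called
  degen <- vapply(calls, function(x) "degenerate-motif" %in% x$flags,
                  logical(1))
  expect_equal(sum(degen), 1L)
  # protein sequence evidence overrides flags
  g <- gene_records("g1", "c1", 1, 900, domains = "pfam00990")
  expect_equal(find_ggdef_genes(g, proteins = c(g1 = "MAGGDEFAA"))[[1]]$flags,
               character(0))
  expect_equal(find_ggdef_genes(g, proteins = c(g1 = "MAGGAEFAA"))[[1]]$flags,
               "degenerate-motif")
  # no evidence at all: motif unknown, no flag
  expect_equal(find_ggdef_genes(g)[[1]]$flags, character(0))
})

test_that("GGDEF scan over the published BC1401 domain table yields 7 calls", {
  gg <- read_gene_table(system.file("extdata", "bc1401_ggdef_genes.tsv",
                                    package = "psychrobin"))
  calls <- find_ggdef_genes(gg)
  expect_equal(length(calls), 7L)
  degen <- vapply(calls, function(x) "degenerate-motif" %in% x$flags,
                  logical(1))
  expect_equal(vapply(calls, function(x) x$members$gene_id,
                      character(1))[degen], "Ga0079976_10297")
})

test_that("alg44-like scan requires an HlyD-family domain and excludes PilZ", {
  g <- gene_records(
    c("hly", "both", "neither"), "c1", c(1, 2000, 4000),
    c(900, 2900, 4900),
    product = "membrane fusion protein",
    domains = list("pfam13437", c("pfam13437", "PilZ"), character(0)))
  calls <- find_alg44_like(g)
  expect_equal(length(calls), 1L)
  expect_equal(calls[[1]]$members$gene_id, "hly")
  # ABC-transporter neighbourhood flag honours the gene window
  ann <- simulate_annotation(
    planted = list(list(type = "ALG44LIKE", abc_neighbor = TRUE),
                   list(type = "ALG44LIKE")),
    seed = 47)
  ac <- find_alg44_like(ann$genes)
  expect_equal(sum(vapply(ac, function(x) "abc-associated" %in% x$flags,
                          logical(1))), 1L)
})

test_that("cluster calls are deterministic and sorted within contigs", {
  ann <- simulate_annotation(
    planted = list(list(type = "WZY"), list(type = "ABC")), seed = 48)
  c1 <- find_wzy_clusters(ann$genes)
  c2 <- find_wzy_clusters(ann$genes[sample.int(nrow(ann$genes)), ])
  expect_equal(as.data.frame(c1), as.data.frame(c2))
  for (cl in c(c1, find_abc_clusters(ann$genes))) {
    expect_equal(length(unique(cl$contig)), 1L)
    expect_false(is.unsorted(cl$members$start))
  }
})
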