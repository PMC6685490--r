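make_demo_catalog <- function(n = 40, seed = 2) {
  px <- make_prediction_tables(n_genes = n, seed = seed)
  calls <- classify_targeting(tally_votes(px$predictions,
                                          genes = px$ledger$gene_id))
  sc <- interaction_scheme()
  set.seed(seed)
  pick <- sample(nrow(sc), 12, replace = TRUE)
  ann <- data.frame(gene_id = calls$gene_id[1:12],
                    category = sc$category[pick],
                    subcategory = sc$subcategory[pick],
                    interaction_organelle = sample(
                      c("mitochondrial", "plastid", "dual"), 12,
                      replace = TRUE))
  sites <- data.frame(target_gene = rep(calls$gene_id[1:2], c(3, 2)),
                      target_pos = c(4L, 9L, 20L, 7L, 8L),
                      source_chain = "A",
                      source_residue = as.character(c(4, 9, 20, 7, 8)),
                      tier = "confident")
  list(calls = calls, ann = ann, sites = sites,
       catalog = build_catalog(calls, ann, sites))
}

test_that("the scheme has 11 categories and 27 scoped subcategories", {
  sc <- interaction_scheme()
  expect_equal(length(unique(sc$category)), 11L)
  expect_equal(nrow(sc), 27L)
  expect_false(any(duplicated(paste(sc$category, sc$subcategory))))
  # both ribosomes split into large/small; OXPHOS into its four complexes
  expect_equal(sum(sc$category == "OXPHOS"), 4L)
  expect_equal(sum(sc$category == "Photosynthesis"), 6L)
  expect_equal(sum(sc$category == "Transcription and transcript maturation"),
               7L)
})

test_that("scheme validation catches planted violations", {
  good <- data.frame(gene_id = "g1", category = "OXPHOS",
                     subcategory = "Complex I",
                     interaction_organelle = "mitochondrial")
  expect_true(validate_scheme(good)$valid)

  bad <- data.frame(
    gene_id = c("g1", "g2", "g3", "g3", "g4"),
    category = c("OXPHOS", "Ribozyme", "PPR", "PPR", "OXPHOS"),
    subcategory = c("PSI", "", "", "", "Complex I"),
    interaction_organelle = c(rep("mitochondrial", 4), "golgi"))
  v <- validate_scheme(bad)
  expect_false(v$valid)
  expect_setequal(
    unique(v$flags$flag),
    c("subcategory_mismatch", "unknown_category", "duplicate_gene",
      "unknown_organelle"))
})

test_that("catalog build enforces referential integrity", {
  d <- make_demo_catalog()
  expect_equal(nrow(d$catalog$genes), nrow(d$calls))
  expect_equal(sum(d$catalog$genes$n_contact_sites), nrow(d$sites))
  expect_true(all(d$catalog$contact_sites$target_gene %in%
                    d$catalog$genes$gene_id))

  dangling <- rbind(d$ann, data.frame(
    gene_id = "ATnotacall", category = "PPR", subcategory = "PPR",
    interaction_organelle = "mitochondrial"))
  expect_error(build_catalog(d$calls, dangling, d$sites), "ATnotacall")
  bad_site <- data.frame(target_gene = "ATghost", target_pos = 1L,
                         source_chain = "A", source_residue = "1",
                         tier = "confident")
  expect_error(build_catalog(d$calls, d$ann, bad_site), "ATghost")
})

test_that("queries equal brute-force filtering and reject unknown values", {
  d <- make_demo_catalog(n = 60, seed = 9)
  g <- d$catalog$genes
  cases <- list(
    list(category = "PPR"),
    list(targeting = "dual"),
    list(category = "OXPHOS", targeting = "mitochondrial"),
    list(subcategory = "Complex I"),
    list())
  for (cs in cases) {
    got <- do.call(query_catalog, c(list(d$catalog), cs))
    keep <- rep(TRUE, nrow(g))
    if (!is.null(cs$category))
      keep <- keep & !is.na(g$category) & g$category == cs$category
    if (!is.null(cs$subcategory))
      keep <- keep & !is.na(g$subcategory) & g$subcategory == cs$subcategory
    if (!is.null(cs$targeting)) keep <- keep & g$targeting == cs$targeting
    want <- g[keep, ]
    want <- want[order(want$gene_id), ]
    rownames(want) <- NULL
    expect_equal(got, want)
  }
  expect_error(query_catalog(d$catalog, category = "Spliceosome"),
               "unknown category")
  expect_error(query_catalog(d$catalog, targeting = "golgi"),
               "unknown targeting")
})

test_that("catalog TSV round trip is byte-exact", {
  d <- make_demo_catalog(n = 30, seed = 4)
  d1 <- file.path(tempdir(), "cat1"); d2 <- file.path(tempdir(), "cat2")
  write_catalog(d$catalog, d1)
  back <- read_catalog(d1)
  write_catalog(back, d2)
  for (f in c("catalog_genes.tsv", "catalog_contact_sites.tsv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  expect_equal(back$genes$gene_id, d$catalog$genes$gene_id)
})

test_that("partner lists are symmetric and compartment-filtered", {
  calls <- data.frame(
    gene_id = c("m1", "m2", "p1", "d1", "u1"),
    category = c("mitochondrial", "mitochondrial", "plastid", "dual",
                 "unknown"),
    mito_support = 2L, plastid_support = 0L, provenance = "automated")
  pairs <- data.frame(gene_a = c("m1", "m1", "m1", "p1", "u1"),
                      gene_b = c("m2", "p1", "d1", "d1", "m1"))
  pl <- refine_partner_lists(pairs, calls)
  row <- function(g) pl[pl$gene_id == g, ]
  # symmetry
  for (g in pl$gene_id) {
    partners <- strsplit(row(g)$partners, ";")[[1]]
    for (p in partners)
      expect_true(g %in% strsplit(row(p)$partners, ";")[[1]])
  }
  # same-compartment refinement: mito keeps mito+dual, drops plastid/unknown
  expect_equal(row("m1")$same_compartment_partners, "d1;m2")
  expect_equal(row("p1")$same_compartment_partners, "d1")
  expect_equal(row("d1")$same_compartment_partners, "m1;p1")
  expect_equal(row("u1")$n_same_compartment, 0L)
})
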