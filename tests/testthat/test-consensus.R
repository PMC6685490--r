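tally_one <- function(...) {
  preds <- c(...)
  tally_votes(data.frame(database = names(preds), gene_id = "g",
                         prediction = unname(preds)))
}

test_that("vote tallies count databases per organelle, dual counting both", {
  t1 <- tally_one(DB1 = "mito", DB2 = "mito")
  expect_equal(t1$mito_support, 2L)
  expect_equal(t1$plastid_support, 0L)
  expect_equal(t1$mito_dbs, "DB1,DB2")

  t2 <- tally_one(DB1 = "dual")
  expect_equal(t2$mito_support, 1L)
  expect_equal(t2$plastid_support, 1L)

  t3 <- tally_one(DB1 = "dual", DB2 = "dual")
  expect_equal(t3$mito_support, 2L)
  expect_equal(t3$plastid_support, 2L)
  expect_equal(classify_targeting(t3)$category, "dual")
})

test_that("duplicate (database, gene) rows are rejected", {
  expect_error(tally_votes(data.frame(
    database = c("DB1", "DB1"), gene_id = c("g", "g"),
    prediction = c("mito", "mito"))), "duplicate")
})

test_that("classification matches the transcribed rule for forced cases", {
  expect_equal(classify_targeting(tally_one(DB1 = "mito", DB2 = "mito"))$category,
               "mitochondrial")
  expect_equal(classify_targeting(tally_one(DB1 = "mito", DB2 = "mito",
                                            DB3 = "plastid",
                                            DB4 = "plastid"))$category,
               "dual")
  expect_equal(classify_targeting(tally_one(DB1 = "mito", DB2 = "plastid",
                                            DB3 = "other"))$category,
               "other")
  expect_equal(classify_targeting(tally_one(DB1 = "mito"))$category, "other")
  t <- tally_votes(data.frame(database = "DB1", gene_id = "x",
                              prediction = "none"), genes = "x")
  expect_equal(classify_targeting(t)$category, "unknown")
})

test_that("exhaustive three-database enumeration matches the rule oracle", {
  vals <- c("mito", "plastid", "dual", "other", "none")
  grid <- expand.grid(d1 = vals, d2 = vals, d3 = vals,
                      stringsAsFactors = FALSE)
  genes <- sprintf("g%03d", seq_len(nrow(grid)))
  long <- data.frame(
    database = rep(c("D1", "D2", "D3"), each = nrow(grid)),
    gene_id = rep(genes, 3),
    prediction = c(grid$d1, grid$d2, grid$d3))
  calls <- classify_targeting(tally_votes(long, genes = genes))
  want <- apply(grid, 1, oracle_classify)
  expect_equal(calls$category[match(genes, calls$gene_id)], unname(want))
})

test_that("scenario fixture classification matches the generator ledger", {
  px <- make_prediction_tables(n_genes = 400, seed = 12)
  calls <- classify_targeting(tally_votes(px$predictions,
                                          genes = px$ledger$gene_id))
  got <- calls$category[match(px$ledger$gene_id, calls$gene_id)]
  expect_equal(got, px$ledger$true_category)
})

test_that("manual overlay adds organelles, never removes, and is idempotent", {
  calls <- classify_targeting(tally_votes(data.frame(
    database = rep(c("D1", "D2"), 3),
    gene_id = rep(c("gm", "gp", "gd"), each = 2),
    prediction = c("mito", "mito", "plastid", "plastid", "dual", "dual"))))
  ov <- data.frame(gene_id = c("gm", "gd", "gnew"),
                   interaction_organelle = c("plastid", "mitochondrial",
                                             "mitochondrial"))
  r <- apply_manual_overlay(calls, ov)
  expect_equal(r$calls$category[r$calls$gene_id == "gm"], "dual")
  expect_equal(r$calls$provenance[r$calls$gene_id == "gm"],
               "manual_upgraded")
  expect_equal(r$calls$category[r$calls$gene_id == "gd"], "dual")  # unchanged
  expect_equal(r$calls$category[r$calls$gene_id == "gnew"],
               "mitochondrial")
  expect_equal(r$calls$provenance[r$calls$gene_id == "gnew"],
               "manual_added")
  expect_setequal(r$changes$gene_id, c("gm", "gnew"))

  r2 <- apply_manual_overlay(r$calls, ov)
  expect_equal(nrow(r2$changes), 0L)
  expect_identical(r2$calls, r$calls)

  expect_error(apply_manual_overlay(calls, data.frame(
    gene_id = "g", interaction_organelle = "nucleolus")), "unknown")
})

test_that("organelle support is monotone under added predictions", {
  set.seed(99)
  vals <- c("mito", "plastid", "dual", "other")
  for (rep_i in 1:20) {
    k <- sample(1:4, 1)
    preds <- sample(vals, k, replace = TRUE)
    names(preds) <- paste0("D", seq_len(k))
    before <- classify_targeting(tally_one(preds))$category
    preds2 <- c(preds, structure("mito", names = paste0("D", k + 1)))
    after <- classify_targeting(tally_one(preds2))$category
    before_set <- cynteract:::.org_set(before)
    after_set <- cynteract:::.org_set(after)
    # the new mito vote may only add support: every organelle present
    # before (including mito itself) must survive
    expect_true(all(before_set %in% union(after_set, "M")))
    expect_true(all(setdiff(before_set, "M") %in% after_set))
  }
})

test_that("GO reassignment covers family members and excludes the rest", {
  calls <- classify_targeting(tally_votes(
    data.frame(database = "D1", gene_id = c("f1", "f2", "f3"),
               prediction = "mito"),
    genes = c("f1", "f2", "f3", "f4", "outside")))
  go <- data.frame(gene_id = c("f1", "f2", "f2", "f3"),
                   cc_term = c("mitochondrion", "chloroplast stroma",
                               "mitochondrion inner membrane", "cytosol"))
  r <- reassign_by_go(calls, c("f1", "f2", "f3", "f4"), go)
  expect_equal(r$calls$category[r$calls$gene_id == "f1"], "mitochondrial")
  expect_equal(r$calls$category[r$calls$gene_id == "f2"], "dual")
  expect_equal(r$calls$provenance[r$calls$gene_id == "f2"], "go_reassigned")
  expect_setequal(r$excluded, c("f3", "f4"))
  expect_equal(r$calls$category[r$calls$gene_id == "outside"], "unknown")
})

test_that("summaries conserve counts across categories", {
  px <- make_prediction_tables(n_genes = 300, seed = 6)
  calls <- classify_targeting(tally_votes(px$predictions,
                                          genes = px$ledger$gene_id))
  sm <- summarize_calls(calls)
  expect_equal(sum(sm$targeting$n_genes), nrow(calls))
  expect_equal(sm$n_organellar,
               sum(calls$category %in% c("mitochondrial", "plastid", "dual")))

  ann <- data.frame(gene_id = calls$gene_id[1:6],
                    category = c(rep("OXPHOS", 3), rep("PPR", 3)),
                    subcategory = c(rep("Complex I", 3), rep("", 3)))
  sm2 <- summarize_calls(calls, ann)
  expect_equal(sum(unlist(sm2$interactions[, c("mitochondrial", "plastid",
                                               "dual", "other", "unknown")])),
               6L)
  expect_equal(sm2$n_direct_interaction, 6L)
})
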