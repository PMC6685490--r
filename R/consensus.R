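
.PREDICTIONS <- c("mito", "plastid", "dual", "other", "none")
.TARGETING <- c("mitochondrial", "plastid", "dual", "other", "unknown")
.ORGANELLES <- c("mitochondrial", "plastid", "dual")

# organelle set encoded in a targeting category
.org_set <- function(category) {
  switch(category,
         mitochondrial = "M", plastid = "P", dual = c("M", "P"),
         character(0))
}
.set_to_category <- function(s, fallback) {
  if (all(c("M", "P") %in% s)) "dual"
  else if ("M" %in% s) "mitochondrial"
  else if ("P" %in% s) "plastid"
  else fallback
}

#' Tally per-database organelle-targeting votes
#'
#' Counts, for each gene, how many databases support mitochondrial and how
#' many support plastid targeting. A database's `dual` prediction counts
#' once toward each organelle (it remains a single database, so on its own
#' it cannot satisfy the two-database rule); `none` rows are treated as the
#' absence of a prediction.
#'
#' @param predictions Long-format data frame with columns `database`,
#'   `gene_id`, `prediction` (one of `mito`, `plastid`, `dual`, `other`,
#'   `none`), e.g. from [read_prediction_tables()] or
#'   [make_prediction_tables()]. Duplicate (database, gene) rows are an
#'   error.
#' @param genes Optional character vector of the gene universe; genes
#'   absent from all databases get zero tallies.
#' @return Data frame of class `cyn_tally`: `gene_id`, `mito_support`,
#'   `plastid_support`, `other_support`, `n_predictions`, `mito_dbs`,
#'   `plastid_dbs` (comma-joined database names).
#' @export
tally_votes <- function(predictions, genes = NULL) {
  need <- c("database", "gene_id", "prediction")
  if (!all(need %in% names(predictions)))
    stop("predictions must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(predictions$prediction), .PREDICTIONS)
  if (length(bad))
    stop("unknown prediction value(s): ", paste(bad, collapse = ", "))
  key <- paste(predictions$database, predictions$gene_id)
  if (anyDuplicated(key))
    stop("duplicate (database, gene) prediction row(s): ",
         paste(utils::head(unique(key[duplicated(key)]), 5), collapse = "; "))
  p <- predictions[predictions$prediction != "none", , drop = FALSE]

  all_genes <- unique(c(p$gene_id, genes))
  mito <- p$prediction %in% c("mito", "dual")
  plas <- p$prediction %in% c("plastid", "dual")

  count_by <- function(sel) {
    tb <- table(p$gene_id[sel])
    n <- integer(length(all_genes))
    hit <- match(all_genes, names(tb))
    n[!is.na(hit)] <- as.integer(tb)[hit[!is.na(hit)]]
    n
  }
  dbs_by <- function(sel) {
    sp <- split(p$database[sel], p$gene_id[sel])
    out <- character(length(all_genes))
    hit <- match(all_genes, names(sp))
    out[!is.na(hit)] <- vapply(sp[hit[!is.na(hit)]], function(d)
      paste(sort(d), collapse = ","), character(1))
    out
  }
  out <- data.frame(
    gene_id = all_genes,
    mito_support = count_by(mito),
    plastid_support = count_by(plas),
    other_support = count_by(p$prediction == "other"),
    n_predictions = count_by(rep(TRUE, nrow(p))),
    mito_dbs = dbs_by(mito),
    plastid_dbs = dbs_by(plas),
    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("cyn_tally", "data.frame"))
}

#' Classify genes into the five organelle-targeting categories
#'
#' Applies the two-database consensus rule to a vote tally: a gene is
#' organelle-targeted only when at least two databases support that
#' organelle; it is `dual` when both the mitochondrial and the plastid
#' support independently reach two (the two pairs of databases may
#' coincide, since a single database can itself predict dual targeting).
#' Genes with some recorded localization but sub-threshold organellar
#' support are `other`; genes with no prediction anywhere are `unknown`.
#'
#' @param tally A `cyn_tally` from [tally_votes()].
#' @return Data frame of class `cyn_calls`: `gene_id`, `category`,
#'   `mito_support`, `plastid_support`, `provenance` (`automated`).
#' @export
classify_targeting <- function(tally) {
  stopifnot(is.data.frame(tally),
            all(c("gene_id", "mito_support", "plastid_support") %in%
                  names(tally)))
  m <- tally$mito_support >= 2L
  p <- tally$plastid_support >= 2L
  any_pred <- if ("n_predictions" %in% names(tally))
    tally$n_predictions > 0L
  else tally$mito_support + tally$plastid_support +
    (if ("other_support" %in% names(tally)) tally$other_support else 0L) > 0L
  category <- ifelse(m & p, "dual",
              ifelse(m, "mitochondrial",
              ifelse(p, "plastid",
              ifelse(any_pred, "other", "unknown"))))
  out <- data.frame(gene_id = tally$gene_id, category = category,
                    mito_support = tally$mito_support,
                    plastid_support = tally$plastid_support,
                    provenance = "automated", stringsAsFactors = FALSE)
  structure(out, class = c("cyn_calls", "data.frame"))
}

#' Apply a manual-curation overlay to targeting calls
#'
#' Curated direct-interaction evidence adds organelles to the automated
#' calls but never removes any: a gene already called to one organelle
#' that is curated to the other becomes `dual`; an `other`/`unknown` gene
#' gains the curated organelle(s). Genes named only in the overlay are
#' appended. Re-applying the same overlay is a no-op.
#'
#' @param calls A `cyn_calls` data frame.
#' @param overlay Data frame with columns `gene_id` and
#'   `interaction_organelle` (`mitochondrial`, `plastid`, or `dual`);
#'   multiple rows per gene are unioned.
#' @return List with `calls` (updated, provenance set to `manual_added` /
#'   `manual_upgraded` where changed) and `changes` (data frame `gene_id`,
#'   `old_category`, `new_category`, `change`).
#' @export
apply_manual_overlay <- function(calls, overlay) {
  stopifnot(is.data.frame(calls), is.data.frame(overlay),
            all(c("gene_id", "interaction_organelle") %in% names(overlay)))
  bad <- setdiff(unique(overlay$interaction_organelle), .ORGANELLES)
  if (length(bad))
    stop("unknown interaction organelle(s): ", paste(bad, collapse = ", "))

  add <- lapply(split(overlay$interaction_organelle, overlay$gene_id),
                function(o) unique(unlist(lapply(o, .org_set))))
  new_genes <- setdiff(names(add), calls$gene_id)
  if (length(new_genes)) {
    calls <- rbind(as.data.frame(calls), data.frame(
      gene_id = new_genes, category = "unknown",
      mito_support = 0L, plastid_support = 0L,
      provenance = "automated", stringsAsFactors = FALSE))
  }
  changes <- data.frame(gene_id = character(0), old_category = character(0),
                        new_category = character(0), change = character(0),
                        stringsAsFactors = FALSE)
  idx <- match(names(add), calls$gene_id)
  for (k in seq_along(add)) {
    i <- idx[k]
    old <- calls$category[i]
    old_set <- .org_set(old)
    new_set <- union(old_set, add[[k]])
    new <- .set_to_category(new_set, old)
    if (!identical(new, old)) {
      change <- if (length(old_set) == 0L) "manual_added" else "manual_upgraded"
      calls$category[i] <- new
      calls$provenance[i] <- change
      changes <- rbind(changes, data.frame(
        gene_id = calls$gene_id[i], old_category = old, new_category = new,
        change = change, stringsAsFactors = FALSE))
    }
  }
  calls <- calls[order(calls$gene_id), , drop = FALSE]
  rownames(calls) <- NULL
  class(calls) <- c("cyn_calls", "data.frame")
  list(calls = calls, changes = changes)
}

#' Reassign targeting of family members via GO cellular-component terms
#'
#' Large organelle-targeted families (e.g. pentatricopeptide-repeat
#' proteins) contain many members that the database consensus leaves
#' without an organellar call. For the listed family members, cellular-
#' component annotations naming the mitochondrion or the plastid/
#' chloroplast are used to assign an organellar category; members with no
#' organellar term are returned in an exclusion list (they cannot be
#' placed in the direct-interaction set).
#'
#' @param calls A `cyn_calls` data frame.
#' @param family_members Character vector of gene ids in the family.
#' @param go_table Data frame `gene_id`, `cc_term` (one term per row).
#' @return List with `calls` (updated, provenance `go_reassigned`),
#'   `reassigned` (gene ids whose category changed), and `excluded`
#'   (family members that still lack any organellar assignment).
#' @export
reassign_by_go <- function(calls, family_members, go_table) {
  stopifnot(is.data.frame(go_table),
            all(c("gene_id", "cc_term") %in% names(go_table)))
  calls <- as.data.frame(calls)
  reassigned <- character(0)
  excluded <- character(0)
  for (g in unique(family_members)) {
    i <- match(g, calls$gene_id)
    cur <- if (is.na(i)) "unknown" else calls$category[i]
    if (cur %in% .ORGANELLES) next
    terms <- go_table$cc_term[go_table$gene_id == g]
    s <- c(if (any(grepl("mitochondri", terms, ignore.case = TRUE))) "M",
           if (any(grepl("plastid|chloroplast", terms, ignore.case = TRUE))) "P")
    if (length(s) == 0L) {
      excluded <- c(excluded, g)
      next
    }
    new <- .set_to_category(s, cur)
    if (is.na(i)) {
      calls <- rbind(calls, data.frame(
        gene_id = g, category = new, mito_support = 0L, plastid_support = 0L,
        provenance = "go_reassigned", stringsAsFactors = FALSE))
    } else {
      calls$category[i] <- new
      calls$provenance[i] <- "go_reassigned"
    }
    reassigned <- c(reassigned, g)
  }
  calls <- calls[order(calls$gene_id), , drop = FALSE]
  rownames(calls) <- NULL
  class(calls) <- c("cyn_calls", "data.frame")
  list(calls = calls, reassigned = reassigned, excluded = excluded)
}

#' Summarize targeting calls and interaction annotations
#'
#' @param calls A `cyn_calls` data frame.
#' @param annotations Optional interaction-annotation data frame
#'   (`gene_id`, `category`, `subcategory`); when given, a cross-tabulation
#'   of interaction category/subcategory by targeting category is included.
#' @return List with `targeting` (count per targeting category, all five
#'   categories always present), `n_genes`, `n_organellar`, and, when
#'   annotations are supplied, `interactions` (per category/subcategory
#'   counts by targeting).
#' @export
summarize_calls <- function(calls, annotations = NULL) {
  stopifnot(is.data.frame(calls))
  tb <- table(factor(calls$category, levels = .TARGETING))
  targeting <- data.frame(category = names(tb), n_genes = as.integer(tb),
                          stringsAsFactors = FALSE)
  out <- list(targeting = targeting,
              n_genes = nrow(calls),
              n_organellar = sum(calls$category %in% .ORGANELLES))
  if (!is.null(annotations)) {
    ann <- as.data.frame(annotations)
    tc <- calls$category[match(ann$gene_id, calls$gene_id)]
    sub <- ifelse(is.na(ann$subcategory) | !nzchar(ann$subcategory),
                  ann$category, ann$subcategory)
    agg <- stats::aggregate(
      list(n = rep(1L, nrow(ann))),
      by = list(category = ann$category, subcategory = sub,
                targeting = factor(tc, levels = .TARGETING)),
      FUN = sum, drop = TRUE)
    wide <- stats::reshape(agg, idvar = c("category", "subcategory"),
                           timevar = "targeting", direction = "wide")
    names(wide) <- sub("^n\\.", "", names(wide))
    for (lv in .TARGETING) {
      if (!lv %in% names(wide)) wide[[lv]] <- 0L
      wide[[lv]][is.na(wide[[lv]])] <- 0L
    }
    wide <- wide[order(wide$category, wide$subcategory),
                 c("category", "subcategory", .TARGETING)]
    rownames(wide) <- NULL
    out$interactions <- wide
    out$n_direct_interaction <- length(unique(ann$gene_id))
  }
  out
}
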