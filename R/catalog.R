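
#' The interaction classification scheme
#'
#' The fixed scheme of 11 categories of direct cytonuclear molecular
#' interaction, subdivided into 27 subcategories. Undivided categories
#' (ACCase, Clp protease, DNA-RRR, TAT complex, PPR, tRNA aminoacylation)
#' count as their own singleton subcategory; the organellar ribosomes split
#' into large/small subunits, OXPHOS into its four chimeric complexes,
#' photosynthesis into six complexes, and transcription/transcript
#' maturation into seven functional classes. Subcategory names are scoped
#' to their category (both ribosome categories have a "Large subunit").
#'
#' @return Data frame with columns `category` and `subcategory` (27 rows,
#'   11 distinct categories).
#' @export
interaction_scheme <- function() {
  sub <- list(
    "ACCase" = "ACCase",
    "Chlororibosome" = c("Large subunit", "Small subunit"),
    "Clp protease" = "Clp protease",
    "DNA-RRR" = "DNA-RRR",
    "TAT complex" = "TAT complex",
    "Mitoribosome" = c("Large subunit", "Small subunit"),
    "OXPHOS" = c("Complex I", "Complex III", "Complex IV", "Complex V"),
    "Photosynthesis" = c("ATP synthase", "Cytochrome b6f", "NDH", "PSI",
                         "PSII", "Rubisco"),
    "PPR" = "PPR",
    "Transcription and transcript maturation" = c(
      "Intron splicing", "mTERF", "RNA polymerase", "rRNA base modification",
      "Sigma factor", "Transcript end processing", "tRNA base modification"),
    "tRNA aminoacylation" = "tRNA aminoacylation"
  )
  data.frame(category = rep(names(sub), lengths(sub)),
             subcategory = unlist(sub, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Validate interaction annotations against the scheme
#'
#' Checks a table of gene-level interaction annotations for unknown
#' categories, unknown or mismatched subcategories (a subcategory must
#' belong to its row's category), and duplicate gene rows. A missing/empty
#' subcategory is interpreted as the category's own singleton subcategory.
#'
#' @param annotations Data frame with columns `gene_id`, `category`,
#'   `subcategory`, and optionally `interaction_organelle`.
#' @return List with `valid` (logical) and `flags` (data frame `gene_id`,
#'   `flag`, `detail`; zero rows when valid).
#' @export
validate_scheme <- function(annotations) {
  need <- c("gene_id", "category", "subcategory")
  if (!all(need %in% names(annotations)))
    stop("annotations must have columns: ", paste(need, collapse = ", "))
  sc <- interaction_scheme()
  ann <- as.data.frame(annotations)
  sub <- ifelse(is.na(ann$subcategory) | !nzchar(ann$subcategory),
                ann$category, ann$subcategory)
  flags <- data.frame(gene_id = character(0), flag = character(0),
                      detail = character(0), stringsAsFactors = FALSE)
  add_flag <- function(sel, flag, detail) {
    if (any(sel)) flags <<- rbind(flags, data.frame(
      gene_id = ann$gene_id[sel], flag = flag, detail = detail[sel],
      stringsAsFactors = FALSE))
  }
  unk_cat <- !ann$category %in% sc$category
  add_flag(unk_cat, "unknown_category", ann$category)
  ok_pair <- paste(ann$category, sub, sep = "\r") %in%
    paste(sc$category, sc$subcategory, sep = "\r")
  unk_sub <- !unk_cat & !sub %in% sc$subcategory
  add_flag(unk_sub, "unknown_subcategory", sub)
  mism <- !unk_cat & !unk_sub & !ok_pair
  add_flag(mism, "subcategory_mismatch",
           paste0(sub, " does not belong to ", ann$category))
  add_flag(duplicated(ann$gene_id), "duplicate_gene", ann$gene_id)
  if ("interaction_organelle" %in% names(ann)) {
    bad_org <- !ann$interaction_organelle %in% .ORGANELLES
    add_flag(bad_org, "unknown_organelle", ann$interaction_organelle)
  }
  rownames(flags) <- NULL
  list(valid = nrow(flags) == 0L, flags = flags)
}

#' Assemble the gene-level and residue-level catalog tables
#'
#' Joins targeting calls, interaction annotations, subunit contact
#' statuses, and mapped contact sites into the two catalog tables: one
#' master row per classified gene, and one row per transferred contact
#' site. Referential integrity is enforced: every annotated gene and every
#' contact-site gene must exist among the calls.
#'
#' @param calls A `cyn_calls` data frame (post-overlay).
#' @param annotations Interaction annotations (`gene_id`, `category`,
#'   `subcategory`, `interaction_organelle`); validated against the scheme.
#' @param mapped_sites Optional data frame of mapped contact sites
#'   (`target_gene`, `target_pos`, `source_chain`, `source_residue`,
#'   `tier`, and optionally `source_structure`), e.g. accumulated
#'   [map_residues()] output.
#' @param statuses Optional `cyn_subunit_status` data frame (or rbind of
#'   several); joined by `gene_label`.
#' @return Object of class `cyn_catalog`: list with `genes` (data frame
#'   `gene_id`, `targeting`, `category`, `subcategory`,
#'   `interaction_organelle`, `contact_status`, `n_contact_sites`),
#'   `contact_sites`, and `meta` (schema version).
#' @export
build_catalog <- function(calls, annotations, mapped_sites = NULL,
                          statuses = NULL) {
  v <- validate_scheme(annotations)
  if (!v$valid)
    stop("interaction annotations fail scheme validation (",
         nrow(v$flags), " flag(s)); first: ",
         paste(v$flags$flag[1], v$flags$gene_id[1]))
  ann <- as.data.frame(annotations)
  dangling <- setdiff(ann$gene_id, calls$gene_id)
  if (length(dangling))
    stop("annotated gene(s) absent from targeting calls: ",
         paste(dangling, collapse = ", "))

  genes <- data.frame(gene_id = calls$gene_id, targeting = calls$category,
                      stringsAsFactors = FALSE)
  hit <- match(genes$gene_id, ann$gene_id)
  genes$category <- ann$category[hit]
  sub <- ifelse(is.na(ann$subcategory) | !nzchar(ann$subcategory),
                ann$category, ann$subcategory)
  genes$subcategory <- sub[hit]
  genes$interaction_organelle <- if ("interaction_organelle" %in% names(ann))
    ann$interaction_organelle[hit] else NA_character_

  genes$contact_status <- NA_character_
  if (!is.null(statuses)) {
    st <- as.data.frame(statuses)
    genes$contact_status <- st$status[match(genes$gene_id, st$gene_label)]
  }

  sites <- if (is.null(mapped_sites) || nrow(mapped_sites) == 0L) {
    data.frame(target_gene = character(0), target_pos = integer(0),
               source_structure = character(0), source_chain = character(0),
               source_residue = character(0), tier = character(0),
               stringsAsFactors = FALSE)
  } else {
    ms <- as.data.frame(mapped_sites)
    if (!"source_structure" %in% names(ms))
      ms$source_structure <- NA_character_
    ms <- ms[, c("target_gene", "target_pos", "source_structure",
                 "source_chain", "source_residue", "tier")]
    bad <- setdiff(ms$target_gene, genes$gene_id)
    if (length(bad))
      stop("contact-site gene(s) absent from targeting calls: ",
           paste(bad, collapse = ", "))
    ms <- ms[order(ms$target_gene, ms$target_pos), , drop = FALSE]
    rownames(ms) <- NULL
    ms
  }
  tb <- table(sites$target_gene)
  genes$n_contact_sites <- 0L
  hit <- match(genes$gene_id, names(tb))
  genes$n_contact_sites[!is.na(hit)] <- as.integer(tb)[hit[!is.na(hit)]]
  genes <- genes[order(genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL

  structure(list(genes = genes, contact_sites = sites,
                 meta = list(schema_version = 1L)),
            class = "cyn_catalog")
}

#' @export
print.cyn_catalog <- function(x, ...) {
  cat("<cyn_catalog>", nrow(x$genes), "genes,",
      sum(!is.na(x$genes$category)), "with interaction annotations,",
      nrow(x$contact_sites), "contact sites\n")
  invisible(x)
}

#' Query the catalog
#'
#' Conjunctive filtering of the gene-level catalog table by interaction
#' category, subcategory, targeting category, and contact status. Filter
#' values are checked against the scheme/enumerations and an unknown value
#' is an error (not an empty result). Rows come back sorted by `gene_id`.
#'
#' @param catalog A `cyn_catalog`.
#' @param category,subcategory,targeting,contact_status Optional filter
#'   values (each may be a vector; `NULL` means no constraint).
#' @return A data frame of matching gene rows.
#' @export
query_catalog <- function(catalog, category = NULL, subcategory = NULL,
                          targeting = NULL, contact_status = NULL) {
  stopifnot(inherits(catalog, "cyn_catalog"))
  sc <- interaction_scheme()
  check <- function(vals, allowed, what) {
    bad <- setdiff(vals, allowed)
    if (length(bad))
      stop("unknown ", what, " value(s): ", paste(bad, collapse = ", "))
  }
  g <- catalog$genes
  keep <- rep(TRUE, nrow(g))
  if (!is.null(category)) {
    check(category, unique(sc$category), "category")
    keep <- keep & !is.na(g$category) & g$category %in% category
  }
  if (!is.null(subcategory)) {
    check(subcategory, unique(sc$subcategory), "subcategory")
    keep <- keep & !is.na(g$subcategory) & g$subcategory %in% subcategory
  }
  if (!is.null(targeting)) {
    check(targeting, .TARGETING, "targeting")
    keep <- keep & g$targeting %in% targeting
  }
  if (!is.null(contact_status)) {
    check(contact_status, c("contact", "no_contact", "likely", "not_likely",
                            "NA"), "contact_status")
    keep <- keep & !is.na(g$contact_status) & g$contact_status %in%
      contact_status
  }
  out <- g[keep, , drop = FALSE]
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build and compartment-filter protein-interaction partner lists
#'
#' From unordered interactome pairs, builds the symmetric partner list of
#' every gene, then refines it to the partners sharing at least one
#' organellar compartment with the gene (a dual-targeted partner shares
#' with both mitochondrial- and plastid-targeted genes). Genes without an
#' organellar call get an empty filtered list.
#'
#' @param pairs Data frame of unordered pairs, columns `gene_a`, `gene_b`.
#' @param calls A `cyn_calls` data frame supplying targeting categories.
#' @return Data frame of class `cyn_partners`: `gene_id`, `n_partners`,
#'   `partners`, `n_same_compartment`, `same_compartment_partners`
#'   (semicolon-joined, sorted).
#' @export
refine_partner_lists <- function(pairs, calls) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(pairs)))
  pr <- pairs[pairs$gene_a != pairs$gene_b, , drop = FALSE]
  edges <- rbind(data.frame(g = pr$gene_a, p = pr$gene_b,
                            stringsAsFactors = FALSE),
                 data.frame(g = pr$gene_b, p = pr$gene_a,
                            stringsAsFactors = FALSE))
  edges <- unique(edges)
  cat_of <- calls$category[match(edges$p, calls$gene_id)]
  own <- function(g) calls$category[match(g, calls$gene_id)]

  sp <- split(seq_len(nrow(edges)), edges$g)
  genes <- names(sp)
  own_cat <- own(genes)
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  out$n_partners <- vapply(sp, length, integer(1))
  out$partners <- vapply(sp, function(ix)
    paste(sort(edges$p[ix]), collapse = ";"), character(1))
  shared <- lapply(seq_along(sp), function(k) {
    os <- .org_set(if (is.na(own_cat[k])) "unknown" else own_cat[k])
    ix <- sp[[k]]
    if (length(os) == 0L) return(character(0))
    keep <- vapply(ix, function(e) {
      pc <- cat_of[e]
      length(intersect(os, .org_set(if (is.na(pc)) "unknown" else pc))) > 0L
    }, logical(1))
    sort(edges$p[ix][keep])
  })
  out$n_same_compartment <- lengths(shared)
  out$same_compartment_partners <- vapply(shared, paste, character(1),
                                          collapse = ";")
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("cyn_partners", "data.frame"))
}
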