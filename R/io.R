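
#' Write a table as TSV with a `#` metadata header
#'
#' All tabular outputs share this format: `#key: value` metadata lines,
#' then a tab-separated table with a header row, unquoted fields, and `NA`
#' for missing values. Contact tables automatically record the cutoff,
#' radii-table version, and element skip report carried on their
#' attributes.
#'
#' @param x A data frame (possibly with `cyn_contacts`-style attributes).
#' @param path Output file path.
#' @param meta Named list of additional metadata values.
#' @return `path`, invisibly.
#' @export
write_tsv_meta <- function(x, path, meta = list()) {
  auto <- list()
  for (a in c("structure_id", "cutoff", "radii_name"))
    if (!is.null(attr(x, a))) auto[[a]] <- attr(x, a)
  sk <- attr(x, "skip_report")
  if (!is.null(sk) && nrow(sk) > 0)
    auto$skipped_elements <- paste(sprintf("%s=%d", sk$element, sk$n_atoms),
                                   collapse = ",")
  meta <- utils::modifyList(auto, meta)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("#%s: %s", k, paste(meta[[k]], collapse = ",")), con)
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a TSV written by [write_tsv_meta()]
#'
#' @param path File path.
#' @return Data frame; metadata lines are returned in the `meta` attribute
#'   as a named character vector.
#' @export
read_tsv_meta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- character(0)
  if (length(hdr)) {
    kv <- sub("^#", "", lines[hdr])
    meta <- trimws(sub("^[^:]*:", "", kv))
    names(meta) <- trimws(sub(":.*$", "", kv))
  }
  df <- utils::read.delim(text = lines[setdiff(seq_along(lines), hdr)],
                          stringsAsFactors = FALSE)
  attr(df, "meta") <- meta
  df
}

.CATALOG_HEADER <- "#cynteract-catalog-schema: 1"

#' Write the catalog tables to a directory
#'
#' Serializes a catalog as `catalog_genes.tsv` and
#' `catalog_contact_sites.tsv`, each starting with a schema-version header
#' line. The format is deterministic (fixed column order, sorted rows,
#' unquoted fields), so exporting, re-importing with [read_catalog()], and
#' exporting again reproduces the files byte for byte.
#'
#' @param catalog A `cyn_catalog`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_catalog <- function(catalog, dir) {
  stopifnot(inherits(catalog, "cyn_catalog"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, file) {
    con <- file(file.path(dir, file), open = "wt")
    on.exit(close(con))
    writeLines(.CATALOG_HEADER, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  }
  wr(catalog$genes, "catalog_genes.tsv")
  wr(catalog$contact_sites, "catalog_contact_sites.tsv")
  invisible(dir)
}

#' Read catalog tables written by [write_catalog()]
#'
#' @param dir Directory containing the catalog TSVs.
#' @return A `cyn_catalog`.
#' @export
read_catalog <- function(dir) {
  rd <- function(file, int_cols) {
    path <- file.path(dir, file)
    first <- readLines(path, n = 1L)
    if (!identical(first, .CATALOG_HEADER))
      stop("not a catalog table (missing schema header): ", path)
    df <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE,
                            colClasses = "character")
    for (cc in intersect(int_cols, names(df)))
      df[[cc]] <- as.integer(df[[cc]])
    df
  }
  genes <- rd("catalog_genes.tsv", c("n_contact_sites"))
  sites <- rd("catalog_contact_sites.tsv", c("target_pos"))
  structure(list(genes = genes, contact_sites = sites,
                 meta = list(schema_version = 1L)),
            class = "cyn_catalog")
}

#' Read per-database targeting-prediction tables
#'
#' Each database is a two-column TSV (`gene_id`, `prediction`); the set of
#' databases is either given directly as named paths or through a manifest
#' YAML file mapping database names to file paths (top-level key
#' `databases`).
#'
#' @param paths Named character vector of TSV paths (names are database
#'   names), or `NULL` when `manifest` is used.
#' @param manifest Path to a manifest YAML with a `databases` mapping.
#' @return Long-format data frame `database`, `gene_id`, `prediction`
#'   suitable for [tally_votes()].
#' @export
read_prediction_tables <- function(paths = NULL, manifest = NULL) {
  if (is.null(paths)) {
    if (is.null(manifest)) stop("give either named paths or a manifest")
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a manifest requires the yaml package")
    m <- yaml::read_yaml(manifest)
    if (is.null(m$databases)) stop("manifest lacks a 'databases' mapping")
    paths <- unlist(m$databases)
    paths <- vapply(paths, function(p)
      if (file.exists(p)) p else file.path(dirname(manifest), p),
      character(1))
  }
  if (is.null(names(paths)) || any(!nzchar(names(paths))))
    stop("prediction tables must be named by database")
  do.call(rbind, lapply(names(paths), function(db) {
    df <- utils::read.delim(paths[[db]], comment.char = "#",
                            stringsAsFactors = FALSE,
                            colClasses = "character")
    if (!all(c("gene_id", "prediction") %in% names(df)))
      stop("prediction table for ", db,
           " must have columns gene_id, prediction")
    data.frame(database = db, gene_id = df$gene_id,
               prediction = df$prediction, stringsAsFactors = FALSE)
  }))
}

#' Read a FASTA proteome as a named character vector
#'
#' @param path FASTA file path.
#' @return Named character vector of protein sequences (names are the
#'   first whitespace-delimited token of each header).
#' @export
read_proteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  out <- as.character(aa)
  names(out) <- sub("\\s.*$", "", names(aa))
  out
}
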