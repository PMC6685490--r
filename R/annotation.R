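
.COMPARTMENTS <- c("nuclear", "mitochondrial", "plastid")

#' Build a chain-annotation table
#'
#' Maps each polymer chain of a structure to the genomic compartment that
#' encodes it (nuclear, mitochondrial, or plastid), its molecule type, and a
#' gene label used downstream to join contact results to the catalog.
#'
#' @param structure_id Structure identifier(s).
#' @param chain_id Chain identifier(s).
#' @param compartment One of `"nuclear"`, `"mitochondrial"`, `"plastid"`.
#' @param molecule_type `"protein"` or `"RNA"`.
#' @param gene_label Free-text gene label; defaults to
#'   `<structure_id>_<chain_id>`.
#' @return A data frame of class `cyn_chain_annotation`.
#' @export
chain_annotation <- function(structure_id, chain_id, compartment,
                             molecule_type = "protein",
                             gene_label = NULL) {
  df <- data.frame(structure_id = as.character(structure_id),
                   chain_id = as.character(chain_id),
                   compartment = as.character(compartment),
                   molecule_type = as.character(molecule_type),
                   stringsAsFactors = FALSE)
  df$gene_label <- if (is.null(gene_label))
    paste0(df$structure_id, "_", df$chain_id) else as.character(gene_label)
  validate_chain_annotation(df)
}

#' Read a chain-annotation TSV
#'
#' Expects tab-separated columns `structure_id`, `chain_id`, `compartment`,
#' `molecule_type`, `gene_label`; `#` lines are ignored.
#'
#' @param path Path to the TSV file.
#' @return A data frame of class `cyn_chain_annotation`.
#' @export
read_chain_annotation <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  validate_chain_annotation(df)
}

validate_chain_annotation <- function(df) {
  need <- c("structure_id", "chain_id", "compartment", "molecule_type",
            "gene_label")
  if (!all(need %in% names(df)))
    stop("chain annotation must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(df$compartment), .COMPARTMENTS)
  if (length(bad))
    stop("unknown compartment value(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(.COMPARTMENTS, collapse = "/"), ")")
  bad <- setdiff(unique(df$molecule_type), c("protein", "RNA"))
  if (length(bad))
    stop("unknown molecule_type value(s): ", paste(bad, collapse = ", "))
  key <- paste(df$structure_id, df$chain_id)
  if (anyDuplicated(key))
    stop("duplicate chain annotation for: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  class(df) <- c("cyn_chain_annotation", "data.frame")
  df
}

# annotation rows for one structure, indexed by chain; errors (naming the
# chains) if any chain carrying atoms lacks an annotation. A single-structure
# annotation table is accepted regardless of its structure_id value, so file
# renames do not break the join.
annotation_for_structure <- function(structure, annotation) {
  ann <- annotation[annotation$structure_id == structure$structure_id |
                      !nzchar(annotation$structure_id), , drop = FALSE]
  if (nrow(ann) == 0L &&
      length(unique(annotation$structure_id)) == 1L)
    ann <- annotation
  missing <- setdiff(structure$chains$chain_id, ann$chain_id)
  if (length(missing))
    stop("no chain annotation for chain(s) ", paste(missing, collapse = ", "),
         " of structure ", structure$structure_id)
  ann[match(structure$chains$chain_id, ann$chain_id), , drop = FALSE]
}
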