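
.AA_ALPHABET <- "ACDEFGHIKLMNPQRSTVWYBZXUO*"

.submat_cache <- new.env(parent = emptyenv())
.get_submat <- function(name) {
  if (!exists(name, envir = .submat_cache)) {
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    assign(name, get(name, envir = e), envir = .submat_cache)
  }
  get(name, envir = .submat_cache)
}

.check_seq <- function(seq, what) {
  if (!is.character(seq) || length(seq) != 1 || is.na(seq) || !nzchar(seq))
    stop("empty ", what, " sequence")
  chars <- strsplit(toupper(seq), "")[[1]]
  bad <- which(!chars %in% strsplit(.AA_ALPHABET, "")[[1]])
  if (length(bad))
    stop("non-amino-acid character '", chars[bad[1]], "' at position ",
         bad[1], " of ", what, " sequence")
  toupper(seq)
}

#' Deterministic pairwise global alignment of two protein sequences
#'
#' Needleman-Wunsch global alignment under a fixed substitution matrix and
#' affine gap penalties (defaults: BLOSUM62, gap open 11, gap extension 1 -
#' the familiar protein-search defaults). This is the mapping stage used to
#' transfer contact residues from a reference-structure chain to its
#' homolog in a target proteome: the aligned column pairs give a strictly
#' increasing, injective correspondence between reference and target
#' positions.
#'
#' @param ref_seq Reference (structure-chain) protein sequence.
#' @param target_seq Target (proteome) protein sequence.
#' @param ref_id,target_id Identifiers recorded on the result.
#' @param substitution_matrix Name of a substitution matrix shipped with
#'   Biostrings (e.g. `"BLOSUM62"`, `"BLOSUM45"`).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return An object of class `cyn_alignment`: list with `ref_id`,
#'   `target_id`, `columns` (data frame `ref_pos`, `target_pos` over 1-based
#'   ungapped positions, strictly increasing in both), `percent_identity`
#'   (over aligned columns), `ref_coverage` (fraction of reference residues
#'   aligned), `score`, and `params`.
#' @examples
#' a <- align_pair("MKVL", "MKAVL")
#' a$columns
#' @export
align_pair <- function(ref_seq, target_seq, ref_id = "ref",
                       target_id = "target",
                       substitution_matrix = "BLOSUM62",
                       gap_open = 11, gap_extend = 1) {
  ref_seq <- .check_seq(ref_seq, "reference")
  target_seq <- .check_seq(target_seq, "target")
  mat <- .get_submat(substitution_matrix)
  aln <- Biostrings::pairwiseAlignment(
    pattern = ref_seq, subject = target_seq, type = "global",
    substitutionMatrix = mat, gapOpening = gap_open, gapExtension = gap_extend)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  rp <- cumsum(p != "-")
  tp <- cumsum(s != "-")
  both <- p != "-" & s != "-"
  columns <- data.frame(ref_pos = rp[both], target_pos = tp[both])
  structure(
    list(ref_id = ref_id, target_id = target_id, columns = columns,
         percent_identity = if (any(both)) 100 * mean(p[both] == s[both])
                            else NA_real_,
         ref_coverage = sum(both) / nchar(ref_seq),
         ref_length = nchar(ref_seq),
         target_length = nchar(target_seq),
         score = as.numeric(Biostrings::score(aln)),
         params = list(substitution_matrix = substitution_matrix,
                       gap_open = gap_open, gap_extend = gap_extend)),
    class = "cyn_alignment")
}

#' @export
print.cyn_alignment <- function(x, ...) {
  cat(sprintf("<cyn_alignment> %s ~ %s: score %.1f, identity %.1f%%, ref coverage %.2f, %d aligned columns\n",
              x$ref_id, x$target_id, x$score, x$percent_identity,
              x$ref_coverage, nrow(x$columns)))
  invisible(x)
}

#' Best proteome hit for a reference chain sequence
#'
#' Aligns a reference sequence against every entry of a target proteome and
#' returns the highest-scoring target (ties broken by percent identity,
#' then by the lexicographically smaller identifier). Hits below the
#' confidence floor are still returned, flagged by their tier, so callers
#' can decide whether to annotate through them.
#'
#' @param ref_seq Reference protein sequence.
#' @param proteome Named character vector or `Biostrings::AAStringSet` of
#'   target sequences; names are the gene identifiers.
#' @param ref_id Identifier for the reference sequence.
#' @param ... Alignment parameters passed to [align_pair()] and tier
#'   thresholds passed to [confidence_tier()].
#' @return List with `target_id`, `alignment` (a `cyn_alignment` against
#'   the winning target), and `tier`.
#' @export
best_hit <- function(ref_seq, proteome, ref_id = "ref", ...) {
  if (inherits(proteome, "AAStringSet")) {
    nm <- names(proteome)
    proteome <- as.character(proteome)
    names(proteome) <- nm
  }
  if (length(proteome) == 0L) stop("empty proteome")
  if (is.null(names(proteome)) || any(!nzchar(names(proteome))))
    stop("proteome sequences must be named")
  args <- list(...)
  aln_args <- args[names(args) %in%
                     c("substitution_matrix", "gap_open", "gap_extend")]
  tier_args <- args[names(args) %in%
                      c("identity_confident", "coverage_confident",
                        "identity_floor", "coverage_floor")]
  alns <- lapply(names(proteome), function(id)
    do.call(align_pair, c(list(ref_seq, proteome[[id]], ref_id = ref_id,
                               target_id = id), aln_args)))
  scores <- vapply(alns, `[[`, numeric(1), "score")
  tied <- which(scores == max(scores))
  if (length(tied) > 1L) {
    ident <- vapply(alns[tied], `[[`, numeric(1), "percent_identity")
    tied <- tied[ident == max(ident)]
    if (length(tied) > 1L)
      tied <- tied[order(names(proteome)[tied])][1L]
  }
  best <- alns[[tied[1L]]]
  list(target_id = best$target_id, alignment = best,
       tier = do.call(confidence_tier, c(list(best), tier_args)))
}

#' Assign a mapping-confidence tier to an alignment
#'
#' `confident` requires both percent identity and reference coverage above
#' the main thresholds; `tentative` requires them above the floor
#' thresholds; anything weaker is `below_floor`. The thresholds are
#' operational defaults (there is no community standard for when a
#' structure-to-proteome mapping is trustworthy); they are configurable and
#' are echoed into output metadata by the writers.
#'
#' @param alignment A `cyn_alignment`.
#' @param identity_confident,coverage_confident Thresholds for `confident`
#'   (percent, fraction).
#' @param identity_floor,coverage_floor Thresholds for `tentative`.
#' @return One of `"confident"`, `"tentative"`, `"below_floor"`.
#' @export
confidence_tier <- function(alignment, identity_confident = 30,
                            coverage_confident = 0.5,
                            identity_floor = 20, coverage_floor = 0.3) {
  stopifnot(identity_floor < identity_confident)
  id <- alignment$percent_identity
  cov <- alignment$ref_coverage
  if (is.na(id)) return("below_floor")
  if (id >= identity_confident && cov >= coverage_confident) "confident"
  else if (id >= identity_floor && cov >= coverage_floor) "tentative"
  else "below_floor"
}

#' Transfer contact residues through an alignment
#'
#' Maps each contact residue of a reference chain to its aligned position
#' in the target protein. Only residues falling in non-gap aligned columns
#' are transferred; the rest are returned in a drop ledger with a reason
#' (`"gap"` for residues opposite a gap in the target, `"unresolved"` for
#' residues whose sequential reference position could not be determined),
#' so no contact residue is ever silently lost.
#'
#' @param alignment A `cyn_alignment` whose reference is the structure
#'   chain.
#' @param contact_residues A `cyn_contact_residues` data frame (typically
#'   pre-filtered to one chain); its `seq_index` column is the sequential
#'   reference position unless `chain_seq_index` overrides it.
#' @param chain_seq_index Optional named integer vector mapping residue
#'   labels (`residue_seq`) to sequential reference positions.
#' @param tier Optional tier string stored on each mapped site (defaults to
#'   [confidence_tier()] of the alignment).
#' @return List with `sites` (data frame `target_gene`, `target_pos`,
#'   `source_chain`, `source_residue`, `ref_pos`, `tier`) and `dropped`
#'   (same source columns plus `reason`).
#' @export
map_residues <- function(alignment, contact_residues, chain_seq_index = NULL,
                         tier = NULL) {
  stopifnot(inherits(alignment, "cyn_alignment"))
  if (is.null(tier)) tier <- confidence_tier(alignment)
  cr <- as.data.frame(contact_residues)
  ref_pos <- if (!is.null(chain_seq_index))
    unname(chain_seq_index[cr$residue_seq]) else cr$seq_index
  ref_pos <- as.integer(ref_pos)
  ref_pos[!is.na(ref_pos) &
            (ref_pos < 1L | ref_pos > alignment$ref_length)] <- NA_integer_

  hit <- match(ref_pos, alignment$columns$ref_pos)
  mapped <- !is.na(ref_pos) & !is.na(hit)
  sites <- data.frame(
    target_gene = rep(alignment$target_id, sum(mapped)),
    target_pos = alignment$columns$target_pos[hit[mapped]],
    source_chain = cr$chain_id[mapped],
    source_residue = cr$residue_seq[mapped],
    ref_pos = ref_pos[mapped],
    tier = rep(tier, sum(mapped)),
    stringsAsFactors = FALSE)
  dropped <- data.frame(
    source_chain = cr$chain_id[!mapped],
    source_residue = cr$residue_seq[!mapped],
    ref_pos = ref_pos[!mapped],
    reason = ifelse(is.na(ref_pos[!mapped]), "unresolved", "gap"),
    stringsAsFactors = FALSE)
  rownames(sites) <- rownames(dropped) <- NULL
  list(sites = sites, dropped = dropped)
}
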