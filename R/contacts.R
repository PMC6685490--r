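
# Comparison slack at the contact boundary, in angstrom. PDB coordinates
# carry 1e-3 A precision, so decimal boundary cases (e.g. two carbons with
# r = 1.70 at exactly 4.40 A, overlap -1.0) must not be lost to the last
# bit of IEEE arithmetic; 1e-9 is six orders below the data precision.
.CONTACT_EPS <- 1e-9

#' Detect inter-chain atomic contacts by van der Waals overlap
#'
#' Two atoms are in contact when their van der Waals overlap,
#' `overlap = r_i + r_j - d_ij`, is at least `cutoff`. The default cutoff of
#' -1.0 angstrom accepts atom pairs whose VDW surfaces are separated by up
#' to 1 angstrom, which picks up weakly interacting residues across subunit
#' interfaces in addition to tightly packed ones. Only pairs from different
#' chains are considered; with `inter_compartment_only` the pair must also
#' span different genomic compartments (e.g. a nuclear-encoded chain against
#' a plastid-encoded one), which is the criterion for cytonuclear contact
#' sites.
#'
#' The default search uses a cell-list spatial index (atoms binned into
#' cubic cells no smaller than the maximal interaction distance, candidate
#' pairs drawn from adjacent cells only). Both search methods feed the same
#' candidate pairs through the same distance/overlap arithmetic, so their
#' results are identical bit for bit; `method = "exhaustive"` scores all
#' atom pairs and serves as the reference path.
#'
#' @param structure A `cyn_structure` from [read_structure()] or a fixture
#'   generator.
#' @param annotation A `cyn_chain_annotation`; required when
#'   `inter_compartment_only = TRUE`, optional otherwise (when present,
#'   compartments are carried into the output).
#' @param radii A `cyn_radii` table; atoms whose element is absent from the
#'   table are excluded from the search and listed in the skip report
#'   attached to the result.
#' @param cutoff Minimal VDW overlap in angstrom (boundary inclusive).
#' @param inter_compartment_only Keep only pairs whose chains are encoded in
#'   different genomic compartments.
#' @param method `"cell"` (spatial index) or `"exhaustive"` (all pairs).
#' @return A data frame of class `cyn_contacts`, one row per contacting atom
#'   pair, canonically ordered (lower serial first, sorted). Attributes:
#'   `structure_id`, `cutoff`, `radii_name`, `inter_compartment_only`,
#'   `skip_report` (elements excluded and atom counts).
#' @examples
#' fx <- make_toy_complex(tempfile(fileext = ".pdb"), seed = 1)
#' s <- read_structure(fx$structure_file)
#' ctc <- find_contacts(s, fx$annotation, inter_compartment_only = TRUE)
#' nrow(ctc)
#' @export
find_contacts <- function(structure, annotation = NULL, radii = vdw_radii(),
                          cutoff = -1.0, inter_compartment_only = FALSE,
                          method = c("cell", "exhaustive")) {
  stopifnot(inherits(structure, "cyn_structure"), is.finite(cutoff))
  method <- match.arg(method)
  at <- structure$atoms

  comp <- NULL
  if (inter_compartment_only && is.null(annotation))
    stop("inter_compartment_only requires a chain annotation")
  if (!is.null(annotation)) {
    ann <- annotation_for_structure(structure, annotation)
    comp <- ann$compartment[match(at$chain_id, ann$chain_id)]
  }

  known <- at$element %in% names(radii)
  skip_report <- data.frame(element = character(0), n_atoms = integer(0),
                            stringsAsFactors = FALSE)
  if (any(!known)) {
    tb <- table(at$element[!known])
    skip_report <- data.frame(element = names(tb), n_atoms = as.integer(tb),
                              stringsAsFactors = FALSE)
    skip_report$element[!nzchar(skip_report$element)] <- "?"
    at <- at[known, , drop = FALSE]
    if (!is.null(comp)) comp <- comp[known]
  }
  n <- nrow(at)
  r <- unname(as.numeric(radii)[match(at$element, names(radii))])
  max_dist <- if (n > 0L) 2 * max(r) - cutoff + .CONTACT_EPS else 1.0

  cand <- if (n < 2L) {
    cbind(integer(0), integer(0))
  } else if (method == "exhaustive") {
    i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
    cbind(i, i + sequence((n - 1L):1L))
  } else {
    .cell_candidates(cbind(at$x, at$y, at$z), max(max_dist, 0.1))
  }

  i <- cand[, 1L]; j <- cand[, 2L]
  keep <- at$chain_id[i] != at$chain_id[j]
  if (inter_compartment_only) keep <- keep & comp[i] != comp[j]
  i <- i[keep]; j <- j[keep]

  dx <- at$x[i] - at$x[j]; dy <- at$y[i] - at$y[j]; dz <- at$z[i] - at$z[j]
  d <- sqrt(dx * dx + dy * dy + dz * dz)
  overlap <- r[i] + r[j] - d
  hit <- overlap >= cutoff - .CONTACT_EPS
  i <- i[hit]; j <- j[hit]; d <- d[hit]; overlap <- overlap[hit]

  # canonical orientation: lower serial first, then sorted
  swap <- at$serial[i] > at$serial[j]
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  ord <- order(at$serial[i], at$serial[j])
  i <- i[ord]; j <- j[ord]; d <- d[ord]; overlap <- overlap[ord]

  out <- data.frame(
    serial_i = at$serial[i], serial_j = at$serial[j],
    chain_i = at$chain_id[i], residue_i = at$residue_label[i],
    resname_i = at$residue_name[i], seq_index_i = at$seq_index[i],
    chain_j = at$chain_id[j], residue_j = at$residue_label[j],
    resname_j = at$residue_name[j], seq_index_j = at$seq_index[j],
    distance_A = d, overlap_A = overlap,
    stringsAsFactors = FALSE
  )
  if (!is.null(comp)) {
    out$compartment_i <- comp[i]
    out$compartment_j <- comp[j]
  }
  structure(out,
            class = c("cyn_contacts", "data.frame"),
            structure_id = structure$structure_id,
            cutoff = cutoff,
            radii_name = attr(radii, "name"),
            inter_compartment_only = inter_compartment_only,
            skip_report = skip_report)
}

# candidate atom pairs from a cell list; guaranteed superset of all pairs
# closer than cell_size (integer cell adjacency, no floating-point pruning)
.cell_candidates <- function(xyz, cell_size) {
  n <- nrow(xyz)
  cx <- as.integer(floor(xyz[, 1] / cell_size))
  cy <- as.integer(floor(xyz[, 2] / cell_size))
  cz <- as.integer(floor(xyz[, 3] / cell_size))
  key <- paste(cx, cy, cz, sep = ",")
  cells <- split(seq_len(n), key)
  cell_pos <- seq_along(cells)
  names(cell_pos) <- names(cells)
  cc <- do.call(rbind, lapply(strsplit(names(cells), ",", fixed = TRUE),
                              as.integer))

  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[off$dx > 0 | (off$dx == 0 & off$dy > 0) |
               (off$dx == 0 & off$dy == 0 & off$dz > 0), , drop = FALSE]

  ii <- vector("list", length(cells) * 14L)
  jj <- vector("list", length(cells) * 14L)
  k <- 0L
  for (ci in seq_along(cells)) {
    m <- cells[[ci]]
    nm <- length(m)
    if (nm > 1L) {
      a <- rep.int(seq_len(nm - 1L), times = (nm - 1L):1L)
      b <- a + sequence((nm - 1L):1L)
      k <- k + 1L
      ii[[k]] <- m[a]; jj[[k]] <- m[b]
    }
    for (o in seq_len(nrow(off))) {
      nk <- paste(cc[ci, 1L] + off$dx[o], cc[ci, 2L] + off$dy[o],
                  cc[ci, 3L] + off$dz[o], sep = ",")
      pos <- cell_pos[nk]
      if (!is.na(pos)) {
        m2 <- cells[[pos]]
        k <- k + 1L
        ii[[k]] <- rep(m, times = length(m2))
        jj[[k]] <- rep(m2, each = length(m))
      }
    }
  }
  if (k == 0L) return(cbind(integer(0), integer(0)))
  cbind(unlist(ii[seq_len(k)], use.names = FALSE),
        unlist(jj[seq_len(k)], use.names = FALSE))
}

#' Aggregate atomic contact pairs to contact residues
#'
#' Folds a set of contacting atom pairs into one record per (chain, residue)
#' involved in at least one pair, with its partner chains/compartments and
#' the number of supporting atom pairs. Every atom pair supports exactly two
#' residue records (one per side), so the column sum of
#' `n_supporting_atom_pairs` is twice the number of input pairs.
#'
#' @param pairs A `cyn_contacts` data frame (from one structure).
#' @return A data frame of class `cyn_contact_residues`: `chain_id`,
#'   `residue_seq` (author numbering + insertion code), `residue_name`,
#'   `seq_index`, `partner_chains`, `partner_compartments` (comma-joined,
#'   `NA` when the pairs carry no compartment information), and
#'   `n_supporting_atom_pairs`. Contact-criterion attributes are carried
#'   over from `pairs`.
#' @export
aggregate_residues <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  has_comp <- "compartment_i" %in% names(pairs)
  empty <- data.frame(chain_id = character(0), residue_seq = character(0),
                      residue_name = character(0), seq_index = integer(0),
                      partner_chains = character(0),
                      partner_compartments = character(0),
                      n_supporting_atom_pairs = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L)
    return(structure(empty, class = c("cyn_contact_residues", "data.frame"),
                     structure_id = attr(pairs, "structure_id"),
                     cutoff = attr(pairs, "cutoff"),
                     radii_name = attr(pairs, "radii_name")))

  side <- function(a, b) data.frame(
    chain_id = pairs[[paste0("chain_", a)]],
    residue_seq = pairs[[paste0("residue_", a)]],
    residue_name = pairs[[paste0("resname_", a)]],
    seq_index = pairs[[paste0("seq_index_", a)]],
    partner_chain = pairs[[paste0("chain_", b)]],
    partner_compartment = if (has_comp)
      pairs[[paste0("compartment_", b)]] else NA_character_,
    stringsAsFactors = FALSE)
  both <- rbind(side("i", "j"), side("j", "i"))
  key <- paste(both$chain_id, both$residue_seq, sep = "\r")
  first <- !duplicated(key)
  out <- both[first, c("chain_id", "residue_seq", "residue_name", "seq_index")]
  ks <- split(seq_len(nrow(both)), key)[unique(key)]
  out$partner_chains <- vapply(ks, function(ix)
    paste(sort(unique(both$partner_chain[ix])), collapse = ","), character(1))
  out$partner_compartments <- vapply(ks, function(ix) {
    pc <- both$partner_compartment[ix]
    if (all(is.na(pc))) NA_character_
    else paste(sort(unique(pc[!is.na(pc)])), collapse = ",")
  }, character(1))
  out$n_supporting_atom_pairs <- vapply(ks, length, integer(1))
  out <- out[order(out$chain_id, out$seq_index), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("cyn_contact_residues", "data.frame"),
            structure_id = attr(pairs, "structure_id"),
            cutoff = attr(pairs, "cutoff"),
            radii_name = attr(pairs, "radii_name"))
}

#' Classify each subunit's cytonuclear contact status
#'
#' Combines chain annotations, inter-compartment contact residues, and the
#' per-chain mapping-confidence tier into a contact status for every
#' annotated subunit. Nuclear-encoded chains with a confident reference
#' mapping are called `contact` (at least one inter-compartment contact
#' residue) or `no_contact`; chains with only a tentative mapping are
#' downgraded to `likely` / `not_likely`; chains absent from the structure
#' or whose mapping falls below the similarity floor are `NA`.
#' Organellar-encoded chains are the reference side of the analysis: they
#' are reported (with their residue counts) but never given a contact
#' status.
#'
#' @param structure A `cyn_structure`.
#' @param annotation A `cyn_chain_annotation`; may include chains absent
#'   from the structure (subunits missing from the reference model).
#' @param contact_residues Result of [aggregate_residues()] on contacts
#'   computed with `inter_compartment_only = TRUE`.
#' @param confidence Data frame `chain_id`, `tier` with tier in
#'   `confident` / `tentative` / `below_floor`, or a named character vector.
#'   Must cover every annotated nuclear chain present in the structure.
#' @return Data frame of class `cyn_subunit_status`: `chain_id`,
#'   `gene_label`, `compartment`, `molecule_type`, `present`,
#'   `mapping_tier`, `n_contact_residues`, `status` (the literal string
#'   `"NA"` encodes the not-available tier; organellar chains carry a
#'   missing status).
#' @export
subunit_status <- function(structure, annotation, contact_residues,
                           confidence) {
  stopifnot(inherits(structure, "cyn_structure"))
  ann <- annotation[annotation$structure_id == structure$structure_id |
                      !nzchar(annotation$structure_id), , drop = FALSE]
  if (nrow(ann) == 0L && length(unique(annotation$structure_id)) == 1L)
    ann <- annotation
  if (nrow(ann) == 0L) stop("annotation contains no chains for structure ",
                            structure$structure_id)
  if (is.character(confidence) && !is.null(names(confidence)))
    confidence <- data.frame(chain_id = names(confidence),
                             tier = unname(confidence),
                             stringsAsFactors = FALSE)
  stopifnot(is.data.frame(confidence),
            all(c("chain_id", "tier") %in% names(confidence)))
  bad <- setdiff(unique(confidence$tier),
                 c("confident", "tentative", "below_floor"))
  if (length(bad)) stop("unknown confidence tier(s): ",
                        paste(bad, collapse = ", "))

  present <- ann$chain_id %in% structure$chains$chain_id
  tier <- confidence$tier[match(ann$chain_id, confidence$chain_id)]
  missing_conf <- present & ann$compartment == "nuclear" & is.na(tier)
  if (any(missing_conf))
    stop("no mapping-confidence record for nuclear chain(s): ",
         paste(ann$chain_id[missing_conf], collapse = ", "))

  ncr <- integer(nrow(ann))
  if (nrow(contact_residues) > 0) {
    tb <- table(contact_residues$chain_id)
    hit <- match(ann$chain_id, names(tb))
    ncr <- ifelse(is.na(hit), 0L, as.integer(tb)[hit])
  }

  status <- rep(NA_character_, nrow(ann))
  nuc <- ann$compartment == "nuclear"
  status[nuc & !present] <- "NA"
  sel <- nuc & present
  status[sel] <- ifelse(
    tier[sel] == "confident", ifelse(ncr[sel] >= 1L, "contact", "no_contact"),
    ifelse(tier[sel] == "tentative",
           ifelse(ncr[sel] >= 1L, "likely", "not_likely"), "NA"))

  out <- data.frame(
    chain_id = ann$chain_id, gene_label = ann$gene_label,
    compartment = ann$compartment, molecule_type = ann$molecule_type,
    present = present, mapping_tier = tier, n_contact_residues = ncr,
    status = status, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("cyn_subunit_status", "data.frame"),
            structure_id = structure$structure_id)
}
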