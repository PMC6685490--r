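
# residue names treated as water / as covalently modified polymer residues
.WATER_RESIDUES <- c("HOH", "WAT", "DOD", "H2O", "DIS", "MTO")
.MODIFIED_POLYMER <- c("MSE", "SEC", "PYL", "SEP", "TPO", "PTR", "CSO",
                       "HYP", "MLY", "M3L", "KCX", "FME", "PSU", "5MC",
                       "7MG", "2MG", "1MA", "OMC", "OMG", "H2U")
# canonical nucleotide residue names, used for molecule-type inference
.NUCLEOTIDES <- c("A", "C", "G", "U", "I", "N",
                  "DA", "DC", "DG", "DT", "DI", "DU")

#' Read a macromolecular structure from a PDB file
#'
#' Parses a PDB-format coordinate file and reduces it to the polymer content
#' used for contact analysis: model 1 only; alternate locations resolved to
#' the highest-occupancy altloc (ties broken by the lexicographically first
#' altloc identifier); waters and non-polymer heteroatoms (ligands, ions
#' recorded as HETATM) excluded, except for common covalently modified
#' polymer residues (e.g. MSE selenomethionine), which are retained.
#' Hydrogens are kept if present; no hydrogen placement is performed.
#'
#' Each chain is typed as `protein` or `RNA` from its residue names, and each
#' residue receives a sequential 1-based index (`seq_index`, the order of
#' polymer residues in the file) alongside its author number and insertion
#' code, so contact residues can later be mapped through sequence alignments.
#'
#' @param path Path to a PDB-format file.
#' @param structure_id Identifier recorded on the structure; defaults to the
#'   file name without extension.
#' @return An object of class `cyn_structure`: a list with elements
#'   `structure_id`; `atoms`, a data frame with one row per retained atom
#'   (`serial`, `element`, `x`, `y`, `z`, `chain_id`, `residue_seq`,
#'   `insert`, `residue_label`, `residue_name`, `seq_index`, `occupancy`,
#'   `altloc`, `molecule_type`); `chains`, one row per chain
#'   (`chain_id`, `molecule_type`, `n_residues`, `n_atoms`); and
#'   `skip_report`, counts of records excluded at parse time.
#' @examples
#' pdb <- make_toy_complex(tempfile(fileext = ".pdb"), seed = 1)
#' s <- read_structure(pdb$structure_file)
#' s$chains
#' @export
read_structure <- function(path, structure_id = NULL) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path))
    stop("cannot read structure file: ", path)
  if (is.null(structure_id))
    structure_id <- sub("\\.[^.]*$", "", basename(path))
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, rm.insert = FALSE,
                    verbose = FALSE),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e)))
  at <- pdb$atom
  n0 <- nrow(at)
  if (n0 == 0L) stop("empty structure: no atom records in ", path)

  is_water <- at$resid %in% .WATER_RESIDUES
  is_het_ligand <- at$type == "HETATM" & !(at$resid %in% .MODIFIED_POLYMER) &
    !is_water
  skip_report <- data.frame(
    reason = c("water", "non_polymer_hetatm"),
    n_atoms = c(sum(is_water), sum(is_het_ligand)),
    stringsAsFactors = FALSE
  )
  at <- at[!is_water & !is_het_ligand, , drop = FALSE]
  if (nrow(at) == 0L)
    stop("empty structure: no polymer atoms after excluding waters/ligands in ",
         path)

  at$alt <- ifelse(is.na(at$alt), "", at$alt)
  at$insert <- ifelse(is.na(at$insert), "", at$insert)
  at$chain <- ifelse(is.na(at$chain), " ", at$chain)
  at$o <- ifelse(is.na(at$o), 1.0, at$o)

  # altloc resolution: among records carrying an altloc code, keep one per
  # (chain, residue, atom name) - the highest-occupancy record, ties
  # broken by the lexicographically first altloc
  has_alt <- nzchar(at$alt)
  if (any(has_alt)) {
    sub <- at[has_alt, , drop = FALSE]
    akey <- paste(sub$chain, sub$resno, sub$insert, sub$resid, sub$elety,
                  sep = "\r")
    ord <- order(akey, -sub$o, sub$alt)
    sub <- sub[ord, , drop = FALSE]
    sub <- sub[!duplicated(akey[ord]), , drop = FALSE]
    at <- rbind(at[!has_alt, , drop = FALSE], sub)
    at <- at[order(at$eleno), , drop = FALSE]
  }

  elem <- toupper(ifelse(is.na(at$elesy), "", trimws(at$elesy)))
  if (any(!nzchar(elem))) {
    guess <- suppressWarnings(tryCatch(
      bio3d::atom2ele(at$elety[!nzchar(elem)], rescue = TRUE),
      error = function(e) rep("", sum(!nzchar(elem)))))
    guess[is.na(guess)] <- ""
    elem[!nzchar(elem)] <- toupper(guess)
  }

  rkey <- paste(at$chain, at$resno, at$insert, sep = "\r")
  seq_index <- integer(nrow(at))
  for (ch in unique(at$chain)) {
    sel <- at$chain == ch
    seq_index[sel] <- match(rkey[sel], unique(rkey[sel]))
  }

  res_first <- !duplicated(rkey)
  chain_type <- vapply(unique(at$chain), function(ch) {
    resn <- at$resid[res_first & at$chain == ch]
    if (mean(resn %in% .NUCLEOTIDES) > 0.5) "RNA" else "protein"
  }, character(1))

  atoms <- data.frame(
    serial = at$eleno,
    element = elem,
    x = at$x, y = at$y, z = at$z,
    chain_id = at$chain,
    residue_seq = at$resno,
    insert = at$insert,
    residue_label = paste0(at$resno, at$insert),
    residue_name = at$resid,
    seq_index = seq_index,
    occupancy = at$o,
    altloc = at$alt,
    molecule_type = unname(chain_type[at$chain]),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite atom coordinates in ", path)

  chains <- data.frame(
    chain_id = unique(atoms$chain_id),
    stringsAsFactors = FALSE
  )
  chains$molecule_type <- unname(chain_type[chains$chain_id])
  chains$n_residues <- vapply(chains$chain_id, function(ch)
    max(atoms$seq_index[atoms$chain_id == ch]), integer(1))
  chains$n_atoms <- as.integer(table(atoms$chain_id)[chains$chain_id])

  structure(
    list(structure_id = structure_id, atoms = atoms, chains = chains,
         skip_report = skip_report),
    class = "cyn_structure"
  )
}

#' Extract per-chain polymer sequences from a structure
#'
#' One-letter sequences in the order of polymer residues in the coordinate
#' file (the same order as `seq_index`), for use as alignment references.
#' Unknown residue names become `X` (protein) or `N` (RNA).
#'
#' @param structure A `cyn_structure`.
#' @return Named character vector, one sequence per chain.
#' @export
chain_sequences <- function(structure) {
  stopifnot(inherits(structure, "cyn_structure"))
  aa3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
           GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
           MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
           TYR = "Y", VAL = "V", MSE = "M", SEC = "U", PYL = "O", SEP = "S",
           TPO = "T", PTR = "Y", CSO = "C", HYP = "P", MLY = "K", M3L = "K",
           KCX = "K", FME = "M")
  at <- structure$atoms
  res <- at[!duplicated(paste(at$chain_id, at$seq_index, sep = "\r")), ,
            drop = FALSE]
  out <- vapply(structure$chains$chain_id, function(ch) {
    r <- res[res$chain_id == ch, , drop = FALSE]
    r <- r[order(r$seq_index), , drop = FALSE]
    if (structure$chains$molecule_type[structure$chains$chain_id == ch] == "RNA") {
      one <- ifelse(r$residue_name %in% .NUCLEOTIDES,
                    substr(r$residue_name, nchar(r$residue_name), nchar(r$residue_name)),
                    "N")
    } else {
      one <- unname(aa3[r$residue_name])
      one[is.na(one)] <- "X"
    }
    paste(one, collapse = "")
  }, character(1))
  names(out) <- structure$chains$chain_id
  out
}

#' @export
print.cyn_structure <- function(x, ...) {
  cat("<cyn_structure>", x$structure_id, "-", nrow(x$atoms), "atoms,",
      nrow(x$chains), "chains\n")
  print(x$chains, row.names = FALSE)
  if (sum(x$skip_report$n_atoms) > 0) {
    cat("excluded at parse:",
        paste(sprintf("%s=%d", x$skip_report$reason, x$skip_report$n_atoms),
              collapse = ", "), "\n")
  }
  invisible(x)
}
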