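# Independent reference implementations used to cross-check the package.

# Brute-force contact oracle: full distance matrix via dist(), no spatial
# index, no shared code with find_contacts(). Returns the canonical pair
# set (serial_i < serial_j) with distances and overlaps.
oracle_contacts <- function(structure, radii = vdw_radii(), cutoff = -1.0,
                            annotation = NULL,
                            inter_compartment_only = FALSE) {
  at <- structure$atoms
  at <- at[at$element %in% names(radii), , drop = FALSE]
  r <- as.numeric(radii)[match(at$element, names(radii))]
  D <- as.matrix(stats::dist(cbind(at$x, at$y, at$z)))
  OV <- outer(r, r, "+") - D
  hit <- which(upper.tri(OV) & OV >= cutoff - 1e-9, arr.ind = TRUE)
  i <- hit[, 1]; j <- hit[, 2]
  keep <- at$chain_id[i] != at$chain_id[j]
  if (inter_compartment_only) {
    comp <- annotation$compartment[match(at$chain_id, annotation$chain_id)]
    keep <- keep & comp[i] != comp[j]
  }
  i <- i[keep]; j <- j[keep]
  out <- data.frame(serial_i = pmin(at$serial[i], at$serial[j]),
                    serial_j = pmax(at$serial[i], at$serial[j]),
                    distance_A = D[cbind(i, j)],
                    overlap_A = OV[cbind(i, j)])
  out[order(out$serial_i, out$serial_j), , drop = FALSE]
}

# Straight transcription of the two-database consensus rule for one gene's
# vector of per-database predictions.
oracle_classify <- function(preds) {
  m <- sum(preds %in% c("mito", "dual"))
  p <- sum(preds %in% c("plastid", "dual"))
  if (m >= 2 && p >= 2) "dual"
  else if (m >= 2) "mitochondrial"
  else if (p >= 2) "plastid"
  else if (any(preds != "none")) "other"
  else "unknown"
}

# One fixed-format PDB ATOM line (columns per the format spec).
pdb_atom_line <- function(serial, name, alt, resn, chain, resno, x, y, z,
                          occ = 1, b = 0, elem = "C", icode = "") {
  sprintf("ATOM  %5d  %-3s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, resn, chain, resno, icode, x, y, z, occ, b,
          elem)
}

write_pdb_text <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), f)
  f
}

# In-memory two-atom structure at a chosen center distance, for boundary
# arithmetic tests.
two_atom_structure <- function(d, elements = c("C", "C")) {
  atoms <- data.frame(
    serial = 1:2, element = elements, x = c(0, d), y = 0, z = 0,
    chain_id = c("A", "B"), residue_seq = 1L, insert = "",
    residue_label = "1", residue_name = "ALA", seq_index = 1L,
    occupancy = 1, altloc = "", molecule_type = "protein",
    stringsAsFactors = FALSE)
  cynteract:::as_cyn_structure(atoms, "pair")
}
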