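
.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# internal constructor used by in-memory fixture structures
as_cyn_structure <- function(atoms, structure_id) {
  chains <- data.frame(chain_id = unique(atoms$chain_id),
                       stringsAsFactors = FALSE)
  chains$molecule_type <- atoms$molecule_type[
    match(chains$chain_id, atoms$chain_id)]
  chains$n_residues <- vapply(chains$chain_id, function(ch)
    max(atoms$seq_index[atoms$chain_id == ch]), integer(1))
  chains$n_atoms <- as.integer(table(atoms$chain_id)[chains$chain_id])
  structure(list(structure_id = structure_id, atoms = atoms,
                 chains = chains,
                 skip_report = data.frame(reason = character(0),
                                          n_atoms = integer(0))),
            class = "cyn_structure")
}

#' Generate a toy chimeric complex with a planted interface
#'
#' Builds an idealized multi-chain structure (two pseudo-atoms per residue,
#' a C-alpha and a C-beta, both carbon) in which a chosen pair of chains
#' shares a designed interface: for each interface residue, the two
#' C-beta atoms face each other with their VDW surfaces exactly
#' `separation` angstrom apart (center distance `2 * 1.70 + separation`),
#' while every other inter-chain atom pair is kept several angstrom
#' outside the default contact envelope. The planted contact geometry is
#' therefore fully known: at the default cutoff of -1.0, the interface
#' residues are contacts precisely when `separation <= 1.0`.
#'
#' Regeneration with the same arguments and seed is byte-identical.
#'
#' @param file Output PDB path.
#' @param n_chains Number of chains (>= 2); chain ids are `A`, `B`, ...
#' @param residues_per_chain Residues per chain.
#' @param interface_chains Indices of the two chains forming the interface.
#' @param interface_residues Number of interface residue pairs.
#' @param separation Designed VDW-surface separation in angstrom (>= 0).
#' @param compartments Genomic compartment per chain; defaults to chain 1
#'   nuclear, chain 2 plastid, remaining chains nuclear.
#' @param seed Integer seed (chooses which residues form the interface).
#' @param structure_id Identifier; defaults to `toy<seed>`.
#' @return List with `structure_file`, `annotation`
#'   (a `cyn_chain_annotation`), and `ledger`: seed, parameters, the
#'   planted residue pairs (`planted_pairs`), the planted contact-residue
#'   set (`planted_residues`), and the written atom count (`n_atoms`).
#' @export
make_toy_complex <- function(file, n_chains = 3, residues_per_chain = 20,
                             interface_chains = c(1, 2),
                             interface_residues = 6, separation = 0.5,
                             compartments = NULL, seed = 1,
                             structure_id = NULL) {
  if (n_chains < 2) stop("need at least two chains")
  if (separation < 0) stop("separation must be >= 0")
  if (interface_residues > residues_per_chain)
    stop("infeasible geometry: more interface residues than chain length")
  stopifnot(length(interface_chains) == 2,
            all(interface_chains %in% seq_len(n_chains)))
  if (is.null(structure_id)) structure_id <- paste0("toy", seed)
  if (is.null(compartments))
    compartments <- c("nuclear", "plastid",
                      rep("nuclear", max(0, n_chains - 2)))
  stopifnot(length(compartments) == n_chains)

  set.seed(seed)
  iface <- sort(sample.int(residues_per_chain, interface_residues))
  chains <- LETTERS[seq_len(n_chains)]
  c1 <- min(interface_chains); c2 <- max(interface_chains)
  d_center <- 2 * 1.70 + separation   # C-C center distance at the interface

  rows <- list()
  for (ci in seq_len(n_chains)) {
    y0 <- 40 * (ci - 1)
    for (r in seq_len(residues_per_chain)) {
      x <- 5 * r
      at_iface <- r %in% iface && ci %in% c(c1, c2)
      if (at_iface && ci == c1) {
        ya <- 18.5; yb <- 20.0
      } else if (at_iface && ci == c2) {
        yb <- 20.0 + d_center; ya <- yb + 1.5
      } else {
        ya <- y0; yb <- y0 + 1.5
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chain = chains[ci], resno = r,
        elety = c("CA", "CB"), x = x, y = c(ya, yb), z = 0,
        stringsAsFactors = FALSE)
    }
  }
  at <- do.call(rbind, rows)
  at$eleno <- seq_len(nrow(at))
  n <- nrow(at)
  bio3d::write.pdb(file = file, xyz = as.numeric(t(as.matrix(
    at[, c("x", "y", "z")]))), resno = at$resno,
    resid = rep("ALA", n), eleno = at$eleno, elety = at$elety,
    chain = at$chain, o = rep(1, n), b = rep(0, n),
    elesy = rep("C", n))

  annotation <- chain_annotation(structure_id, chains, compartments,
                                 "protein")
  planted_pairs <- data.frame(
    chain_i = chains[c1], residue_i = iface,
    chain_j = chains[c2], residue_j = iface,
    separation = separation, stringsAsFactors = FALSE)
  planted_residues <- data.frame(
    chain_id = rep(chains[c(c1, c2)], each = length(iface)),
    residue_seq = as.character(rep(iface, 2)), stringsAsFactors = FALSE)
  list(structure_file = file, annotation = annotation,
       ledger = list(seed = seed, separation = separation,
                     interface_chains = chains[c(c1, c2)],
                     interface_residues = iface,
                     inter_compartment =
                       compartments[c1] != compartments[c2],
                     planted_pairs = planted_pairs,
                     planted_residues = planted_residues,
                     n_atoms = nrow(at)))
}

#' Generate a random multi-chain atom cloud
#'
#' Uniform random atoms in a cubic box, split into contiguous chains with
#' alternating compartments, with coordinates rounded to the 1e-3 angstrom
#' precision of the PDB format. Used to exercise the contact search where
#' no geometry is planted: the reference answer comes from the exhaustive
#' all-pairs method.
#'
#' @param n_atoms Number of atoms.
#' @param n_chains Number of chains.
#' @param box Box edge length in angstrom (smaller boxes give denser
#'   clouds and more contacts).
#' @param elements Element symbols to draw from (must be in the active
#'   radii table).
#' @param seed Integer seed.
#' @param file Optional path; when given the cloud is also written as PDB.
#' @return List with `structure` (a `cyn_structure`), `annotation`, and
#'   `seed`.
#' @export
make_random_cloud <- function(n_atoms = 500, n_chains = 3, box = 20,
                              elements = c("C", "N", "O", "S"), seed = 42,
                              file = NULL) {
  stopifnot(n_atoms >= 2, n_chains >= 2, box > 0)
  set.seed(seed)
  chains <- LETTERS[ceiling(seq_len(n_atoms) / ceiling(n_atoms / n_chains))]
  el <- sample(elements, n_atoms, replace = TRUE)
  xyz <- matrix(round(stats::runif(3 * n_atoms, 0, box), 3), ncol = 3)
  resno <- stats::ave(seq_len(n_atoms), chains,
                      FUN = function(i) ceiling(seq_along(i) / 3))
  atoms <- data.frame(
    serial = seq_len(n_atoms), element = el,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    chain_id = chains, residue_seq = as.integer(resno), insert = "",
    residue_label = as.character(resno), residue_name = "ALA",
    seq_index = as.integer(resno), occupancy = 1, altloc = "",
    molecule_type = "protein", stringsAsFactors = FALSE)
  sid <- paste0("cloud", seed)
  s <- as_cyn_structure(atoms, sid)
  comp <- rep(c("nuclear", "plastid", "mitochondrial"),
              length.out = length(unique(chains)))
  ann <- chain_annotation(sid, unique(chains), comp, "protein")
  if (!is.null(file)) {
    # atom names unique within each residue (element + ordinal)
    elety <- paste0(el, stats::ave(seq_len(n_atoms), paste(chains, resno),
                                   FUN = seq_along))
    bio3d::write.pdb(file = file, xyz = as.numeric(t(xyz)),
                     resno = atoms$residue_seq,
                     resid = rep("ALA", n_atoms),
                     eleno = atoms$serial, elety = elety,
                     chain = atoms$chain_id, o = rep(1, n_atoms),
                     b = rep(0, n_atoms), elesy = atoms$element)
  }
  list(structure = s, annotation = ann, seed = seed)
}

#' Generate per-database targeting-prediction tables with known truth
#'
#' Emulates the input of the consensus stage: several localization
#' databases voting on a set of genes, under a mix of scenarios whose true
#' consensus category is known by construction and recorded in the ledger.
#' Scenarios: `strong_mito` / `strong_plastid` (2-4 supporting databases,
#' occasionally one stray vote for the other organelle), `dual` (either
#' two or more databases voting dual, or two databases per organelle),
#' `single_vote` (exactly one database votes for an organelle - below the
#' two-database rule, so the true category is `other`), and `none` (no
#' prediction anywhere: `unknown`).
#'
#' @param n_genes Number of genes.
#' @param n_databases Number of databases (>= 4).
#' @param mix Named fractions over the five scenarios; must sum to 1.
#' @param seed Integer seed.
#' @param dir Optional directory: writes one `<database>.tsv` per database
#'   plus `manifest.yaml` (requires the yaml package).
#' @return List with `predictions` (long data frame `database`, `gene_id`,
#'   `prediction`), `ledger` (data frame `gene_id`, `scenario`,
#'   `true_category`), `databases`, and `seed`.
#' @export
make_prediction_tables <- function(n_genes = 1000, n_databases = 9,
                                   mix = c(strong_mito = 0.25,
                                           strong_plastid = 0.30,
                                           dual = 0.10,
                                           single_vote = 0.15,
                                           none = 0.20),
                                   seed = 5, dir = NULL) {
  scen_names <- c("strong_mito", "strong_plastid", "dual", "single_vote",
                  "none")
  stopifnot(setequal(names(mix), scen_names), n_databases >= 4)
  if (abs(sum(mix) - 1) > 1e-8) stop("scenario fractions must sum to 1")
  set.seed(seed)
  counts <- diff(c(0, round(cumsum(mix[scen_names]) * n_genes)))
  scenario <- sample(rep(scen_names, counts))
  genes <- sprintf("AT%dG%05d", ((seq_len(n_genes) - 1) %% 5) + 1,
                   10000 + seq_len(n_genes))
  dbs <- sprintf("db%02d", seq_len(n_databases))

  votes <- vector("list", n_genes)
  truth <- character(n_genes)
  for (g in seq_len(n_genes)) {
    v <- NULL
    sc <- scenario[g]
    if (sc %in% c("strong_mito", "strong_plastid")) {
      org <- if (sc == "strong_mito") "mito" else "plastid"
      k <- sample(2:min(4, n_databases), 1)
      sup <- sample(dbs, k)
      v <- data.frame(database = sup, prediction = org,
                      stringsAsFactors = FALSE)
      rest <- setdiff(dbs, sup)
      if (length(rest) > 0 && stats::runif(1) < 0.3) {
        stray <- rest[sample.int(length(rest), 1)]
        v <- rbind(v, data.frame(
          database = stray,
          prediction = if (org == "mito") "plastid" else "mito",
          stringsAsFactors = FALSE))
      }
      truth[g] <- if (org == "mito") "mitochondrial" else "plastid"
    } else if (sc == "dual") {
      if (stats::runif(1) < 0.5) {
        sup <- sample(dbs, sample(2:3, 1))
        v <- data.frame(database = sup, prediction = "dual",
                        stringsAsFactors = FALSE)
      } else {
        sup <- sample(dbs, 4)
        v <- data.frame(database = sup,
                        prediction = rep(c("mito", "plastid"), each = 2),
                        stringsAsFactors = FALSE)
      }
      truth[g] <- "dual"
    } else if (sc == "single_vote") {
      v <- data.frame(database = sample(dbs, 1),
                      prediction = sample(c("mito", "plastid"), 1),
                      stringsAsFactors = FALSE)
      truth[g] <- "other"
    } else {
      truth[g] <- "unknown"
    }
    if (!is.null(v)) {
      v$gene_id <- genes[g]
      votes[[g]] <- v
    }
  }
  predictions <- do.call(rbind, votes[!vapply(votes, is.null, logical(1))])
  predictions <- predictions[, c("database", "gene_id", "prediction")]
  rownames(predictions) <- NULL
  ledger <- data.frame(gene_id = genes, scenario = scenario,
                       true_category = truth, stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("writing a manifest requires the yaml package")
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- list()
    for (db in dbs) {
      f <- file.path(dir, paste0(db, ".tsv"))
      sel <- predictions$database == db
      utils::write.table(predictions[sel, c("gene_id", "prediction")], f,
                         sep = "\t", quote = FALSE, row.names = FALSE)
      files[[db]] <- paste0(db, ".tsv")
    }
    yaml::write_yaml(list(databases = files),
                     file.path(dir, "manifest.yaml"))
  }
  list(predictions = predictions, ledger = ledger, databases = dbs,
       seed = seed)
}

#' Random protein sequence
#'
#' @param n_residues Sequence length.
#' @param seed Optional integer seed; when `NULL` the current RNG stream
#'   is used.
#' @return A single protein sequence string.
#' @export
random_protein <- function(n_residues, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(.AA20, n_residues, replace = TRUE), collapse = "")
}

#' Random toy proteome
#'
#' @param n_seqs Number of sequences.
#' @param length_range Range of sequence lengths (inclusive).
#' @param seed Integer seed.
#' @return Named character vector with AGI-style locus identifiers.
#' @export
make_toy_proteome <- function(n_seqs = 50, length_range = c(150, 300),
                              seed = 3) {
  set.seed(seed)
  lens <- sample(length_range[1]:length_range[2], n_seqs, replace = TRUE)
  out <- vapply(lens, function(L) random_protein(L), character(1))
  names(out) <- sprintf("AT%dG%05d", ((seq_len(n_seqs) - 1) %% 5) + 1,
                        50000 + seq_len(n_seqs))
  out
}

#' Mutate a protein sequence with a recorded truth map
#'
#' Applies a planted number of substitutions (`round((1 - target_identity)
#' * length)`, each to a different residue, never the original one) and
#' optionally single-residue insertions/deletions, and records where every
#' original position ended up. The truth map is the ground truth against
#' which an alignment's transferred positions can be scored.
#'
#' @param seq Protein sequence.
#' @param target_identity Planted identity over original positions
#'   (0 < identity <= 1).
#' @param indel_rate Expected indel events per residue (each event is one
#'   inserted or one deleted residue).
#' @param seed Integer seed.
#' @return List with `sequence` (mutated), `truth_map` (data frame
#'   `orig_pos`, `new_pos`; `new_pos` is `NA` for deleted residues),
#'   `n_substitutions`, `n_insertions`, `n_deletions`, and `seed`.
#' @export
mutate_sequence <- function(seq, target_identity = 0.7, indel_rate = 0,
                            seed = 1) {
  stopifnot(target_identity > 0, target_identity <= 1, indel_rate >= 0)
  set.seed(seed)
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  n_sub <- round((1 - target_identity) * L)
  sub_pos <- if (n_sub > 0) sample.int(L, n_sub) else integer(0)
  for (p in sub_pos)
    chars[p] <- sample(setdiff(.AA20, chars[p]), 1)

  orig <- seq_len(L)
  n_ind <- round(indel_rate * L)
  n_ins <- 0L; n_del <- 0L
  for (k in seq_len(n_ind)) {
    if (stats::runif(1) < 0.5 && length(chars) > 1) {
      at <- sample.int(length(chars), 1)
      chars <- chars[-at]; orig <- orig[-at]
      n_del <- n_del + 1L
    } else {
      at <- sample.int(length(chars) + 1L, 1)
      chars <- append(chars, sample(.AA20, 1), after = at - 1L)
      orig <- append(orig, NA_integer_, after = at - 1L)
      n_ins <- n_ins + 1L
    }
  }
  truth_map <- data.frame(orig_pos = seq_len(L),
                          new_pos = match(seq_len(L), orig))
  list(sequence = paste(chars, collapse = ""), truth_map = truth_map,
       n_substitutions = n_sub, n_insertions = n_ins, n_deletions = n_del,
       seed = seed)
}
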