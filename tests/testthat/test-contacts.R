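test_that("touching and boundary-separated spheres follow the overlap criterion", {
  # two carbons (r = 1.70) with touching surfaces: overlap 0
  s <- two_atom_structure(3.4)
  ctc <- find_contacts(s)
  expect_equal(nrow(ctc), 1L)
  expect_equal(ctc$overlap_A, 0, tolerance = 1e-12)

  # surfaces 1.0 A apart: overlap -1.0, included at cutoff -1 (boundary)
  expect_equal(nrow(find_contacts(two_atom_structure(4.40))), 1L)
  # 1.01 A apart: excluded
  expect_equal(nrow(find_contacts(two_atom_structure(4.41))), 0L)

  # exact binary arithmetic at the boundary: r = 1.5 each, d = 4.0
  r <- vdw_radii(c(C = 1.5), name = "exact")
  at4 <- find_contacts(two_atom_structure(4.0), radii = r)
  expect_equal(nrow(at4), 1L)
  expect_identical(at4$overlap_A, -1.0)
})

test_that("indexed search equals the brute-force oracle on a random fixture", {
  rc <- make_random_cloud(n_atoms = 500, n_chains = 3, box = 18, seed = 42)
  got <- find_contacts(rc$structure, rc$annotation, method = "cell")
  ora <- oracle_contacts(rc$structure)
  expect_gt(nrow(got), 0)
  expect_equal(got$serial_i, ora$serial_i)
  expect_equal(got$serial_j, ora$serial_j)
  expect_equal(got$distance_A, ora$distance_A, tolerance = 1e-12)
  expect_equal(got$overlap_A, ora$overlap_A, tolerance = 1e-12)
})

test_that("pair set is canonical and symmetric", {
  rc <- make_random_cloud(n_atoms = 300, n_chains = 4, box = 15, seed = 1)
  ctc <- find_contacts(rc$structure)
  expect_true(all(ctc$serial_i < ctc$serial_j))
  expect_false(any(duplicated(paste(ctc$serial_i, ctc$serial_j))))
})

test_that("contacts shrink monotonically with stricter cutoffs and grow with radii", {
  rc <- make_random_cloud(n_atoms = 400, n_chains = 3, box = 16, seed = 8)
  key <- function(ctc) paste(ctc$serial_i, ctc$serial_j)
  cuts <- c(-2, -1, -0.5, 0, 0.5)
  sets <- lapply(cuts, function(cc)
    key(find_contacts(rc$structure, cutoff = cc)))
  for (k in seq_along(cuts)[-1])
    expect_true(all(sets[[k]] %in% sets[[k - 1]]))

  base <- key(find_contacts(rc$structure))
  for (delta in c(0.05, 0.2)) {
    r <- vdw_radii()
    inflated <- vdw_radii(structure(as.numeric(r) + delta, names = names(r)))
    expect_true(all(base %in%
                      key(find_contacts(rc$structure, radii = inflated))))
  }
})

test_that("unknown elements go to the skip report, not silently dropped", {
  s <- two_atom_structure(3.4, elements = c("C", "XX"))
  ctc <- find_contacts(s)
  expect_equal(nrow(ctc), 0L)
  sk <- attr(ctc, "skip_report")
  expect_equal(sk$element, "XX")
  expect_equal(sk$n_atoms, 1L)
})

test_that("missing chain annotation is an error naming the chain", {
  rc <- make_random_cloud(n_atoms = 50, n_chains = 3, box = 12, seed = 3)
  ann <- rc$annotation[rc$annotation$chain_id != "B", ]
  expect_error(
    find_contacts(rc$structure, ann, inter_compartment_only = TRUE), "B")
})

test_that("aggregation conserves supporting pairs and recovers planted interfaces", {
  expect_equal(nrow(aggregate_residues(
    find_contacts(two_atom_structure(10)))), 0L)

  fx <- make_toy_complex(tempfile(fileext = ".pdb"),
                         residues_per_chain = 30, interface_residues = 12,
                         separation = 0.5, seed = 21)
  s <- read_structure(fx$structure_file)
  ctc <- find_contacts(s, fx$annotation, inter_compartment_only = TRUE)
  cr <- aggregate_residues(ctc)
  expect_equal(sum(cr$n_supporting_atom_pairs), 2L * nrow(ctc))
  got <- cr[order(cr$chain_id, as.integer(cr$residue_seq)),
            c("chain_id", "residue_seq")]
  want <- fx$ledger$planted_residues
  want <- want[order(want$chain_id, as.integer(want$residue_seq)), ]
  expect_equal(unname(as.matrix(got)), unname(as.matrix(want)))

  # outside the envelope: zero contacts anywhere
  fx2 <- make_toy_complex(tempfile(fileext = ".pdb"), separation = 1.5,
                          seed = 22)
  s2 <- read_structure(fx2$structure_file)
  expect_equal(nrow(find_contacts(s2, fx2$annotation,
                                  inter_compartment_only = TRUE)), 0L)
})

test_that("multi-pair residues count their supporting atom pairs", {
  # three B atoms all contacting the single A atom's residue
  atoms <- data.frame(
    serial = 1:4, element = "C",
    x = c(0, 3.4, 0, 0), y = c(0, 0, 3.4, 0), z = c(0, 0, 0, 3.4),
    chain_id = c("A", "B", "B", "B"),
    residue_seq = c(57L, 1L, 2L, 3L), insert = "",
    residue_label = c("57", "1", "2", "3"), residue_name = "ALA",
    seq_index = c(1L, 1L, 2L, 3L), occupancy = 1, altloc = "",
    molecule_type = "protein", stringsAsFactors = FALSE)
  s <- cynteract:::as_cyn_structure(atoms, "multi")
  cr <- aggregate_residues(find_contacts(s))
  a57 <- cr[cr$chain_id == "A", ]
  expect_equal(nrow(a57), 1L)
  expect_equal(a57$n_supporting_atom_pairs, 3L)
  expect_equal(a57$partner_chains, "B")
})

test_that("subunit status follows the confidence-tier rules", {
  fx <- make_toy_complex(tempfile(fileext = ".pdb"), n_chains = 4,
                         interface_residues = 5, separation = 0.5,
                         compartments = c("nuclear", "plastid", "nuclear",
                                          "nuclear"),
                         seed = 31)
  s <- read_structure(fx$structure_file)
  cr <- aggregate_residues(
    find_contacts(s, fx$annotation, inter_compartment_only = TRUE))
  # an annotated subunit absent from the model
  ann <- rbind(as.data.frame(fx$annotation),
               data.frame(structure_id = fx$annotation$structure_id[1],
                          chain_id = "Z", compartment = "nuclear",
                          molecule_type = "protein", gene_label = "geneZ"))
  class(ann) <- class(fx$annotation)
  conf <- c(A = "confident", C = "tentative", D = "below_floor")
  st <- subunit_status(s, ann, cr, conf)

  expect_equal(st$status[st$chain_id == "A"], "contact")       # 5 residues
  expect_equal(st$status[st$chain_id == "C"], "not_likely")    # tentative, 0
  expect_equal(st$status[st$chain_id == "D"], "NA")            # below floor
  expect_equal(st$status[st$chain_id == "Z"], "NA")            # absent
  expect_true(is.na(st$status[st$chain_id == "B"]))            # organellar side
  expect_error(subunit_status(s, ann, cr, c(A = "confident")),
               "mapping-confidence")
})

test_that("nuclear chains contacting only nuclear chains are no_contact", {
  fx <- make_toy_complex(tempfile(fileext = ".pdb"), n_chains = 3,
                         interface_chains = c(1, 3), separation = 0.5,
                         compartments = c("nuclear", "plastid", "nuclear"),
                         seed = 32)
  s <- read_structure(fx$structure_file)
  cr <- aggregate_residues(
    find_contacts(s, fx$annotation, inter_compartment_only = TRUE))
  st <- subunit_status(s, fx$annotation, cr,
                       c(A = "confident", C = "confident"))
  # interface is nuclear-nuclear: no inter-compartment contacts exist
  expect_equal(st$status[st$chain_id == "A"], "no_contact")
  expect_equal(st$status[st$chain_id == "C"], "no_contact")
})
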