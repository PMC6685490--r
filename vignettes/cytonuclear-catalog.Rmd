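---
title: "Cataloguing direct cytonuclear interactions: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cataloguing direct cytonuclear interactions: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cynteract)
```

## The problem

Mitochondria and plastids run on enzyme complexes that are *chimeric*:
OXPHOS complexes, the photosynthetic machinery, and the organellar
ribosomes mix subunits encoded in the nuclear genome with subunits (or
rRNAs) encoded in the organellar genomes. Beyond these complexes, many
nuclear-encoded proteins bind organellar DNA or transcripts directly
(replication/repair machinery, RNA polymerases, PPR and mTERF editing and
processing factors, aminoacyl-tRNA synthetases). Evolutionary studies of
cytonuclear coevolution need a consistent way to partition nuclear gene
content into (i) organelle-targeted versus not, and (ii) directly
interacting with cytoplasmic genomes/gene products versus merely
co-located — ideally down to the amino-acid residues at the physical
interface.

This package builds that partition from four ingredients: reference
structures of chimeric complexes, per-database subcellular-localization
predictions, curated interaction annotations, and a target proteome. Each
stage is exposed as ordinary functions over data frames, and each has a
seeded synthetic generator so the full pipeline can be exercised and
validated without any downloads.

## Contact detection

Two atoms are in contact when their van der Waals overlap

$$\mathrm{overlap}_{ij} \;=\; r_i + r_j - d_{ij}$$

is at least the cutoff, where $r_i$ is the element's VDW radius and
$d_{ij}$ the center distance. The default cutoff is **−1.0 Å**, i.e. VDW
surfaces up to 1 Å apart still count. This deliberately relaxed criterion
picks up weakly interacting interface residues that a strict
surface-touching criterion (cutoff 0) would miss. A *cytonuclear contact
residue* is a residue with at least one atom meeting the criterion against
an atom of a chain encoded in a different genomic compartment
(`inter_compartment_only = TRUE`).

Key numerical and modelling choices:

* **Radii.** A fixed Bondi-style element table (C 1.70, N 1.55, O 1.52,
  S 1.80, P 1.80, H 1.20 Å, plus common ions), user-replaceable via
  `read_radii_tsv()`. Some interactive tools use context-dependent radii
  (the radius of a carbon depends on its bonding environment); an
  element-only table trades a little physical nuance for exact
  reproducibility from the coordinate file alone. The table name is
  written into every output header.
* **Boundary arithmetic.** The criterion is boundary-inclusive
  (overlap ≥ cutoff). PDB coordinates carry 10⁻³ Å precision, and decimal
  boundary cases (two carbons at exactly 4.40 Å give overlap −1.0) land a
  few units in the last place below −1 in IEEE arithmetic. Contacts are
  therefore accepted at `overlap >= cutoff - 1e-9`; the slack is six
  orders of magnitude below the data precision, so it can only rescue
  true decimal boundary cases, never admit a genuinely separated pair.
* **Hydrogens.** Atoms present in the file are used as-is; no hydrogens
  are added. Crystal structures mostly lack them, so results are
  effectively heavy-atom.
* **Models and altlocs.** Model 1 only; among records carrying an altloc
  code, the highest-occupancy one wins, ties broken by the
  lexicographically first altloc.
* **Waters and ligands.** Excluded. Covalently modified polymer residues
  (MSE and friends) are retained as polymer.
* **RNA chains.** Organellar rRNA/tRNA chains participate as the
  cytoplasmic side of contacts (ribosome complexes are the main case);
  the molecule type is recorded so protein–RNA contacts can be filtered
  in reports.
* **Unknown elements.** Atoms whose element is missing from the radii
  table are excluded from the arithmetic but counted in a skip report
  attached to the result and written into output headers — never
  silently dropped.

The search uses a cell list: atoms are binned into cubic cells no smaller
than the maximal interaction distance ($2\,r_{\max} - \mathrm{cutoff}$),
and candidate pairs are drawn from each cell and its forward neighbours.
Cell membership is decided by integer arithmetic, so the candidate set is
a guaranteed superset of all qualifying pairs; candidates then pass
through exactly the same distance/overlap code as the exhaustive
all-pairs method. Both methods therefore agree *bitwise*, which the test
suite asserts on twenty random 200–900-atom clouds per run, alongside an
independent distance-matrix oracle.

## Subunit status

Per annotated subunit, the inter-compartment contact residues and the
mapping-confidence tier combine into a status: `contact` / `no_contact`
for confidently mapped nuclear chains, `likely` / `not_likely` when only
a tentative mapping exists, and the literal `"NA"` when the subunit is
absent from the reference structure or its mapping falls below the
similarity floor. Organellar chains are the reference side: reported,
never given a status.

## Residue mapping

Reference-chain sequences are taken from the coordinate file (the order
of polymer residues defines a sequential 1-based index; author numbering
plus insertion codes are kept for reporting only). Mapping onto a target
proteome uses deterministic pairwise global alignment
(Needleman–Wunsch via Biostrings; BLOSUM62, gap open 11, gap extension
1 — the familiar protein-search defaults). A heuristic search plus
multiple alignment would be the classical workflow; a deterministic
pairwise aligner keeps the stage self-contained, bit-reproducible, and
free of versioned-database drift, while `best_hit()` still scans a whole
proteome and breaks exact score ties by identity and then by the
lexicographically smaller identifier so results never depend on input
order.

Contact residues transfer through non-gap aligned columns only. Residues
opposite a gap, or whose sequential position cannot be resolved, go to a
drop ledger with a reason (`gap` / `unresolved`); the invariant `sites +
dropped = input` is tested, so no contact site is ever silently lost.

Confidence tiers default to: `confident` at ≥ 30 % identity and ≥ 0.5
reference coverage; `tentative` at ≥ 20 % identity and ≥ 0.3 coverage;
`below_floor` otherwise. There is no community standard for when a
structure-to-proteome mapping is trustworthy, so these are operational
defaults, deliberately configurable, and echoed into output metadata.
The tier rule is monotone: an alignment that is at least as identical
*and* at least as covering never gets a worse tier (in particular, high
identity with sub-threshold coverage is `tentative`, not `below_floor`).

## Targeting consensus

Each localization database contributes one prediction per gene (`mito`,
`plastid`, `dual`, `other`, `none`). The consensus rule:

* an organellar call requires **at least two databases** supporting that
  organelle;
* `dual` requires two supporters for the mitochondrion *and* two for the
  plastid — possibly the same two databases, since a single database's
  `dual` vote counts once toward each organelle (being one database, it
  can never satisfy the two-database rule alone);
* genes with some recorded localization but sub-threshold organellar
  support are `other`; genes with no prediction anywhere are `unknown`.

The boundary between `other` and `unknown` is genuinely underdetermined
by the five-category naming; we adopt the minimal reading in which *any*
recorded prediction (even a single organellar vote) distinguishes a gene
from one nothing is known about. The whole rule is verified against an
independently transcribed oracle by exhaustive enumeration of all $5^4$
vote combinations over four databases.

Two overlays refine the automated calls:

* **Manual curation** (`apply_manual_overlay()`): curated
  direct-interaction evidence *adds* organelles and never removes any —
  a single-organelle gene curated to the other organelle becomes `dual`;
  an `other`/`unknown` gene gains the curated organelle. The operation
  is idempotent and returns a change report (`manual_added` /
  `manual_upgraded`).
* **Family-level GO reassignment** (`reassign_by_go()`): for a named
  family (the motivating case is the PPR family, whose members
  overwhelmingly act on organellar transcripts), members still lacking
  an organellar call are assigned from cellular-component terms naming
  the mitochondrion or plastid/chloroplast; members with no organellar
  term land on an exclusion list rather than in the interaction set.

## The interaction catalog

The classification scheme is fixed: 11 categories, 27 subcategories.
Undivided categories (ACCase, Clp protease, DNA-RRR, TAT complex, PPR,
tRNA aminoacylation) count as their own singleton subcategory; the
subdivided ones contribute 2 (chlororibosome) + 2 (mitoribosome) +
4 (OXPHOS) + 6 (photosynthesis) + 7 (transcription and transcript
maturation) = 21. Subcategory names are scoped to their category, so the
two ribosomes can both have "Large subunit" without ambiguity. The schema
permits one category per gene; genes with plausible dual roles (e.g. the
handful of specialized PPRs inside the mitoribosome) must be placed in
one category, with cross-references carried in free-text reference keys.

`build_catalog()` enforces referential integrity (annotated genes and
contact-site genes must exist among the calls; scheme validation must
pass), `query_catalog()` does conjunctive filtering with strict
enumeration checking (an unknown filter value is an error, not an empty
result), and serialization is deterministic TSV with a schema-version
header so that export → import → export is byte-identical. Interactome
partner lists are symmetric by construction, and compartment filtering
keeps partners sharing at least one organellar compartment (dual shares
with both; genes without an organellar call get an empty filtered list).

## What the synthetic generators emulate — and what they do not

* `make_toy_complex()` builds idealized multi-chain structures (two
  carbon pseudo-atoms per residue) with a *planted* interface: designated
  residue pairs whose VDW surfaces sit at an exact separation, all other
  inter-chain atoms kept ≥ 3 Å outside the contact envelope. At the
  default cutoff the expected contact set is known exactly, so recovery
  can be asserted with zero tolerance. No stereochemistry is modelled —
  contact detection depends only on coordinates, elements, and labels,
  which is precisely what the generator controls.
* `make_random_cloud()` provides unstructured geometry for the
  index-versus-exhaustive equivalence checks.
* `make_prediction_tables()` draws genes from five vote scenarios
  (strong-mito, strong-plastid, dual, single-vote, none) whose true
  consensus category is recorded in a ledger. It does not model
  systematic disagreement biases between real databases (method-specific
  sensitivity, proteome-coverage differences); passing tests show the
  rule is implemented correctly, not that two databases are a good
  evidence threshold for real proteomes.
* `mutate_sequence()` plants substitutions and single-residue indels and
  emits the position truth map. Real homolog divergence is clumpier
  (domains, low-complexity regions); recovery rates on planted mutations
  are an upper bound on real-world transfer fidelity.

Test problem sizes — twenty random clouds of 200–900 atoms, thirteen toy
complexes, 1,000-gene prediction fixtures, 300-residue mapping pairs —
were chosen as the package's reference conditions: large enough that the
property checks are not vacuous, small enough to re-run on every test
invocation.

## Known limitations

* PDB format only (no mmCIF); one model; no hydrogen placement; no
  steric-clash or affinity scoring — the contact criterion is the whole
  structural model.
* Pairwise best-hit mapping does not disambiguate paralogs; for gene
  families a profile-based search would be more faithful.
* Confidence-tier thresholds are operational defaults, not calibrated
  probabilities.
* Gene identifiers are opaque locus strings; transcript isoforms must be
  collapsed upstream.
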