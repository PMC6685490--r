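# cynteract

Builds a queryable, residue-resolved catalog of **direct cytonuclear
molecular interactions** for a plant nuclear proteome.

Mitochondria and plastids are run by *chimeric* enzyme complexes — OXPHOS,
the photosynthetic machinery, and the organellar ribosomes mix
nuclear-encoded subunits with subunits and rRNAs encoded by the organellar
genomes — and by hundreds of nuclear proteins that bind organellar DNA and
transcripts directly (PPR and mTERF factors, organellar RNA polymerases,
aminoacyl-tRNA synthetases, replication/repair machinery). Evolutionary
studies of cytonuclear coevolution need to partition nuclear gene content
by (i) organelle targeting and (ii) direct molecular interaction with
cytoplasmic genomes or gene products, ideally down to the interface
residues. `cynteract` computes that partition from reference structures,
localization databases, curated annotations, and a target proteome.

## What it computes

**Contact detection.** Atoms *i*, *j* from chains encoded in different
genomic compartments are in contact when their van der Waals overlap
meets a cutoff:

    overlap_ij = r_i + r_j − d_ij ≥ cutoff     (default cutoff −1.0 Å)

i.e. VDW surfaces up to 1 Å apart still count, which catches weakly
interacting interface residues. A spatial cell index makes the search
fast while agreeing bit-for-bit with exhaustive all-pairs search.
Contacts aggregate to contact residues, and each annotated subunit gets a
status: `contact` / `no_contact` (confident mapping), `likely` /
`not_likely` (tentative mapping), or `NA` (absent from the reference
structure or below the similarity floor).

**Residue transfer.** Reference-chain sequences are aligned to a target
proteome (deterministic global alignment, BLOSUM62, gap 11/1); contact
residues transfer through non-gap aligned columns, with dropped residues
ledgered, never silently lost.

**Targeting consensus.** Per-database localization predictions combine
under a two-database rule (`dual` needs two supporters per organelle; one
database's `dual` vote counts once toward each) into five categories:
mitochondrial / plastid / dual / other / unknown. A manual-curation
overlay can only *add* organelles; family-level GO reassignment fills in
members of organelle-targeted families.

**Catalog.** Genes join into a fixed 11-category / 27-subcategory
interaction scheme with validation, conjunctive queries, byte-exact TSV
round trips, and compartment-filtered interactome partner lists.

## Worked example

Every stage has a seeded generator, so a full run needs no input files:

```r
library(cynteract)

pdb <- tempfile(fileext = ".pdb")
fx <- make_toy_complex(pdb, n_chains = 3, residues_per_chain = 25,
                       interface_residues = 6, separation = 0.5, seed = 42)
s <- read_structure(pdb)
s
#> <cyn_structure> file4d66c79b3e5 - 150 atoms, 3 chains
#>  chain_id molecule_type n_residues n_atoms
#>         A       protein         25      50
#>         B       protein         25      50
#>         C       protein         25      50

pairs <- find_contacts(s, fx$annotation, inter_compartment_only = TRUE)
head(as.data.frame(pairs)[, c("chain_i", "residue_i", "chain_j",
                              "residue_j", "distance_A", "overlap_A")], 3)
#>   chain_i residue_i chain_j residue_j distance_A overlap_A
#> 1       A         1       B         1        3.9      -0.5
#> 2       A         4       B         4        3.9      -0.5
#> 3       A         5       B         5        3.9      -0.5

residues <- aggregate_residues(pairs)
status <- subunit_status(s, fx$annotation, residues,
                         c(A = "confident", C = "confident"))
status[, c("chain_id", "compartment", "n_contact_residues", "status")]
#>   chain_id compartment n_contact_residues     status
#> 1        A     nuclear                  6    contact
#> 2        B     plastid                  6       <NA>
#> 3        C     nuclear                  0 no_contact
```

The six planted interface residues of nuclear chain A sit 0.5 Å from the
plastid-encoded chain B (overlap −0.5 ≥ −1.0, so they are contacts), chain
A is called `contact`, the non-interface nuclear chain C `no_contact`,
and organellar chain B — the reference side — gets no status. From here,
`best_hit()` + `map_residues()` transfer the six residues onto a
proteome, `classify_targeting()` builds the five-way targeting calls, and
`build_catalog()` / `query_catalog()` assemble and slice the final
tables.

A thin command-line front end wraps the same functions:

```sh
inst/exec/cynteract simulate complex --seed 4 --out sim
inst/exec/cynteract contacts --structure sim/complex.pdb \
    --chains sim/chains.tsv --inter-compartment-only --out ctc
```

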