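---
title: "Mapping antibody-antigen binding interfaces with abagmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping antibody-antigen binding interfaces with abagmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abagmap)
```

## The problem

Antibodies bind their antigens through a set of residues (the paratope)
contacting a set of antigen residues (the epitope). Characterizing these
interfaces across many experimentally determined antibody-antigen (Ab-Ag)
complexes — which positions bind, with which amino acids, through how many
atomic contacts — informs antibody engineering, library design and paratope
prediction. `abagmap` implements such an analysis as a reusable, tested
pipeline: from raw PDB structure files and a SAbDab-style chain-annotation
table to per-complex and per-group interface statistics.

The pipeline has five stages, each available as ordinary functions:

1. **Structure input and filters** (`load_annotation_summary()`,
   `parse_complex()`, `filter_dataset()`, `classify_group()`). One annotation
   row (structure ID, heavy/light chain labels, antigen chain labels, antigen
   type, resolution) defines one biological unit. Structures above the
   resolution cutoff (default 3 Å, inclusive) or on an explicit exclusion
   list are dropped, with every removal logged. Complexes are grouped by
   antibody format — Fv (VH + VL) versus single-domain (one variable domain)
   — and antigen type, peptides being antigen chains of fewer than 50
   residues when no annotation is available.
2. **Packing-duplicate elimination** (`mean_bfactor()`, `select_unit()`).
   When several co-crystallized Ab-Ag units share one file, only the unit
   with the lowest mean B-factor is kept, so the same physical interface is
   never counted twice.
3. **Redundancy removal** (`extract_variable_sequence()`,
   `cluster_sequences()`, `remove_redundant()`). Variable-domain sequences
   (IMGT residue identifiers ≤ 128) are clustered greedily at 95% identity,
   VH and VL populations separately; complexes whose chains all share
   clusters form a family of which one representative survives.
4. **Contact extraction** (`find_contacts()`, `summarize_interface()`).
   Every non-hydrogen amino-acid atom pair across the interface within 5 Å
   (Euclidean, inclusive) is one contact. Total contacts are distinguished
   from unique paratope/epitope residues (uPR/uER) and atoms (uPA/uEA) so
   that no statistic is biased towards multi-contact residues.
5. **Statistics** (`aa_frequencies()`, `class_frequencies()`,
   `cooccurrence_matrix()`, `epitope_segments()`, `hotspot_map()`,
   `cdr_capture_fraction()`, `position_aa_frequencies()`, `wu_kabat()`,
   `germline_mutation_fraction()`, `group_mean_ci()`), orchestrated by
   `run_pipeline()`.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `cutoff` | 5 Å | contact distance, boundary inclusive; sweeps over 2/3/4/5/6 Å are supported to check robustness |
| `max_resolution` | 3 Å | dataset quality filter, inclusive |
| `identity` | 0.95 | redundancy clustering threshold, inclusive |
| `peptide_max_len` | 50 residues | strict `< 50` defines a peptide antigen |
| CDR boundaries | 27–38, 56–65, 105–117 | IMGT definition; FR1–FR4 are the complement up to `vr_max = 128` |
| `min_occurrence` | 0.10 | hotspot positions present in fewer than 10% of a group's complexes are omitted (inclusive) |
| `n_boot`, `ci_level` | 5000, 0.95 | percentile bootstrap of group means |

Region membership is decided by the numeric part of the IMGT identifier
alone; insertion codes (111A) are preserved as distinct positions in hotspot
tables, but inherit their base number's region. The CDR boundaries are a
`region_scheme()` object, so experiments such as widening CDR2 from 56–65 to
55–66 are one argument away:

```{r}
ct <- data.frame(ab_chain = "H", ab_resno = 55, ab_insert = "",
                 ab_aa = "TYR", ab_atom = "CA", ab_domain = "VH",
                 ag_chain = "A", ag_resno = 1, ag_insert = "",
                 ag_aa = "ALA", ag_atom = "CA", distance = 4)
cdr_capture_fraction(list(ct))                                # 0
cdr_capture_fraction(list(ct), region_scheme(cdr2 = c(55, 66)))  # 100
```

## Statistical conventions

All frequency statistics are computed on unique residues, never raw
contacts: a residue mediating ten atomic contacts counts once. Group
averages follow a two-step scheme — per-complex percentages first, then the
unweighted mean over complexes — so large interfaces do not dominate. The
one deliberate exception is the paratope-epitope co-occurrence matrix, which
pools total atom-atom contacts across complexes and then normalizes each
paratope row to 100%.

Uncertainty on group means uses the percentile bootstrap (`group_mean_ci()`):
complexes are resampled with replacement `n_boot` times and the central
`level` percentile interval of the resampled means is reported. The
percentile method (rather than BCa) matches the convention of the plotting
stacks commonly used for such error bars. The default seed is fixed so
reruns are bit-for-bit reproducible; the caller's RNG stream is never
touched. A coverage simulation (500 standard-normal samples of n = 50,
`n_boot` = 1000) in the test suite confirms ~95% coverage (accepted band
92–98%).

Hotspot tables report, per (domain, IMGT position), the background
occurrence — the percentage of a group's complexes whose antibody has that
position at all — and the conditional uPR frequency, whose denominator is
the number of position-carrying complexes, never the group size. Epitope
discontinuity counts maximal runs of consecutive residue numbers among uERs
within each antigen chain; insertion-coded residues share their base number
and never break a run. Wu-Kabat variability is the standard `N * k / n_mode`
(sequences at the position × distinct amino acids ÷ count of the most
frequent one), with absent positions excluded from `N`; the germline
mutation analysis consumes externally supplied germline assignments — the
package does not compute germline alignments itself.

## Secondary structure

DSSP 8-state codes are consumed from input (`read_dssp()` for the classic
fixed-column format, `read_ss_table()` for a two-column table) and collapsed
to three classes: H/G/I → helix, E/B → strand, T/S/blank → loop. The newer
polyproline-II code P post-dates the 3-class scheme and maps to loop. The
DSSP algorithm itself is deliberately not reimplemented; when no codes are
supplied every epitope residue falls back to loop and the run summary
records a dataset-level warning, so only the secondary-structure table is
affected.

## Numerical and design choices

- **Boundary inclusivity** everywhere: distance = cutoff is a contact,
  resolution = 3 Å is retained, identity = 0.95 merges, occurrence = 10% is
  kept. These follow the "≤"/"≥" phrasings of the definitions.
- **Alternate locations**: the highest-occupancy copy wins, ties broken by
  alternate-location character order. **Nonstandard residues**: MSE → MET
  and other modified residues with a standard parent are mapped to the
  parent; unmappable residues are excluded from contact eligibility and
  logged. **Hydrogen detection** trusts the element field, falling back to
  the atom-name heuristic when blank.
- **Mean B-factor** is taken over non-hydrogen amino-acid atoms, consistent
  with contact eligibility; `bfactor_include_hydrogens` flips this. Ties in
  the unit selection keep the unit appearing first.
- **Sequence identity** is matched positions of a global alignment
  (match +1, mismatch 0, linear gap) divided by the shorter sequence length
  — the CD-HIT convention. Clustering is greedy on descending length against
  cluster founders. An external CD-HIT run can be substituted via
  `write_variable_fasta()` + `read_cdhit_clusters()`; the internal path is
  the default and the tested one. Word-filter heuristics of CD-HIT itself
  may differ marginally on edge cases.
- **Redundancy representative**: best resolution, then lowest mean B-factor,
  then lexicographic structure ID — deterministic and quality-first; the
  choice of which duplicate survives is otherwise arbitrary.
- **Which copy counts**: Fv complexes are duplicates only when both the VH
  and the VL clusters match; sharing one chain (common-light-chain
  antibodies) is not redundancy. Fv and single-domain antibodies never share
  a family.
- **Neighbor search**: contacts use a cubic cell grid with edge = cutoff
  (candidates live in the 27 neighboring cells); an all-pairs double-loop
  oracle ships in the test suite and the two are verified set-identical on
  100 random complexes.
- **Glycine** has no side-chain atoms, so its unique-atom main/side split is
  all-main by construction. Unrecognized atom names classify as side chain
  with a warning.
- **Multiple antigen chains** pool their contacts; uER keys include the
  chain label so identical residue numbers on different chains stay
  distinct.
- **Interfacial waters** are opt-in (`with_waters`) and reported separately:
  a water counts when its oxygen is within the cutoff of at least one
  eligible atom on each side; water-mediated pairs are counted against both
  sides. They never enter the contact table or any headline statistic.

## The synthetic generator

Because curated Ab-Ag snapshots cannot be redistributed or downloaded at
test time, `synthetic_spec()` + `generate_complex()` build ground-truthed
complexes: antibody and antigen chains sit on parallel rails separated far
beyond an 8 Å decoy margin, and each planted contact pair is moved onto its
own "stalk" in the gap, so the structure's contact set under the cutoff is
*exactly* the planted list (default planted distances 3.5–4.5 Å). The
generator emulates IMGT-consistent numbering, controllable amino-acid
composition, co-crystallized packing units with B-factor offsets
(`generate_packing_variants()`), and mutation-seeded redundancy families
whose within/across-family identities are verified against the clustering
threshold (`generate_redundant_dataset()`). Everything is deterministic per
seed, down to byte-identical PDB text.

What the generator does *not* emulate: realistic backbone geometry, side
chain rotamers, crystallographic artifacts, electron-density-driven altloc
patterns, or naturally graded sequence similarity around the 95% threshold.
Passing tests therefore certify the bookkeeping and the statistics — contact
sets, unit selection, family survivors, every normalization — not the
biology of real interfaces; on real data the same code paths run, but
distributional results will of course differ.

Test and acceptance runs use deliberately small problem sizes — complexes of
60–110 antibody residues, datasets of 10–25 structures, 100 random complexes
for the oracle comparison, 500 bootstrap-coverage replications — chosen so
the whole suite completes in a couple of minutes while still exercising
every code path.

## A worked run

```{r}
planted <- data.frame(ab_domain = c("VH", "VL"), ab_pos = c(30, 107),
                      ab_atom = c("CB", "O"), ag_pos = c(3, 9),
                      ag_atom = c("CB", "CB"), distance = c(3.6, 4.2))
ds <- generate_redundant_dataset(
  2, c(2, 1), seed = 42,
  base_spec = synthetic_spec(planted_contacts = planted))
dir <- tempfile(); dir.create(dir)
for (nm in names(ds$pdbs)) {
  writeLines(ds$pdbs[[nm]], file.path(dir, paste0(nm, ".pdb")))
}
write_annotation_summary(ds$annotation, file.path(dir, "summary.tsv"))

res <- run_pipeline(pipeline_config(
  summary = file.path(dir, "summary.tsv"), pdb_dir = dir,
  out_dir = file.path(dir, "out"), n_boot = 500, seed = 1))
res$reports[["5"]]$per_complex[, c("structure_id", "group",
                                   "total_contacts", "upr", "uer")]
```

Three structures enter; the two members of family 1 collapse to one
representative, so two complexes are analyzed, each with exactly the two
planted contacts.

## Known limitations

- IMGT numbering is assumed present in the input (as database exports
  deliver it); no renumbering is performed, and Kabat/Chothia schemes are
  out of scope.
- Contacts are geometric: no hydrogen-bond/salt-bridge typing, no
  buried-surface-area definition, no energetics.
- mmCIF input is not supported; chain roles must come from the annotation
  table.
- Headline numbers of any specific database snapshot (dataset sizes, total
  contact counts, group means) depend on that snapshot and are not
  reproducible from this package alone; the pipeline reproduces the method,
  not the download.
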