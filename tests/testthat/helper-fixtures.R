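# Fixture builders shared across the suite. Complexes are either built
# directly from atom tables (full control over geometry) or emitted by the
# synthetic generator (planted ground truth).

# Build an abag_complex straight from an atom table. `atoms` needs columns
# chain, resno, elety, x, y, z plus optionally insert, resid, elesy, o, b,
# alt, role, domain, is_hydrogen.
mk_complex <- function(atoms, structure_id = "TST1", resolution = 2.0,
                       antigen_type = NA_character_, solvent = NULL) {
  defaults <- list(insert = "", resid = "ALA", elesy = NA_character_,
                   o = 1, b = 20, alt = "", role = NA_character_,
                   domain = NA_character_, is_hydrogen = NA)
  for (nm in names(defaults)) {
    if (is.null(atoms[[nm]])) atoms[[nm]] <- defaults[[nm]]
  }
  atoms$elesy <- ifelse(is.na(atoms$elesy),
                        substr(gsub("[0-9]", "", atoms$elety), 1, 1),
                        atoms$elesy)
  if (anyNA(atoms$is_hydrogen)) {
    atoms$is_hydrogen <- abagmap:::.is_hydrogen(atoms$elety, atoms$elesy)
  }
  if (anyNA(atoms$role)) {
    atoms$role <- ifelse(!is.na(atoms$domain), "antibody",
                         ifelse(is.na(atoms$role), "antigen", atoms$role))
  }
  atoms$resid_orig <- atoms$resid
  atoms$eligible <- !atoms$is_hydrogen & atoms$resid %in% standard_aa()

  ab <- atoms[atoms$role == "antibody", , drop = FALSE]
  hc <- unique(ab$chain[ab$domain == "VH"])
  lc <- unique(ab$chain[ab$domain == "VL"])
  agc <- unique(atoms$chain[atoms$role == "antigen"])
  ann <- data.frame(
    structure_id = structure_id,
    heavy_chain = if (length(hc)) hc[1] else NA_character_,
    light_chain = if (length(lc)) lc[1] else NA_character_,
    antigen_chains = paste(agc, collapse = ";"),
    antigen_type = antigen_type,
    resolution = resolution, stringsAsFactors = FALSE)
  if (is.null(solvent)) {
    solvent <- atoms[0, c("chain", "resno", "insert", "resid", "elety",
                          "elesy", "x", "y", "z", "o", "b")]
  }
  structure(list(structure_id = structure_id, unit_index = 1L,
                 annotation = ann, atoms = atoms, solvent = solvent,
                 excluded = atoms[0, c("chain", "resno", "insert", "resid")]),
            class = "abag_complex")
}

# One atom row.
atom_row <- function(chain, resno, elety, x, y, z, resid = "ALA",
                     domain = NA_character_, role = NA_character_,
                     b = 20, o = 1, elesy = NA_character_) {
  data.frame(chain = chain, resno = resno, elety = elety, x = x, y = y,
             z = z, resid = resid, domain = domain, role = role, b = b,
             o = o, elesy = elesy, stringsAsFactors = FALSE)
}

# Antibody with one residue per given IMGT id (single CA atom each),
# plus a one-residue antigen far away; used for region/sequence tests.
mk_numbered_antibody <- function(ids, inserts = rep("", length(ids)),
                                 aa = rep("ALA", length(ids)),
                                 domain = "VH", structure_id = "TST1") {
  n <- length(ids)
  ab <- data.frame(chain = if (domain == "VH") "H" else "L", resno = ids,
                   insert = inserts, elety = "CA", resid = aa,
                   x = 3 * seq_len(n), y = 0, z = 0, domain = domain,
                   role = "antibody", stringsAsFactors = FALSE)
  ag <- data.frame(chain = "A", resno = 1, insert = "", elety = "CA",
                   resid = "GLY", x = 0, y = 500, z = 0,
                   domain = NA_character_, role = "antigen",
                   stringsAsFactors = FALSE)
  mk_complex(rbind(ab, ag), structure_id = structure_id)
}

# Independent all-pairs double-loop contact oracle: the correctness
# reference for find_contacts.
oracle_contacts <- function(complex, cutoff = 5.0) {
  a <- complex$atoms
  ab <- a[a$role == "antibody" & a$eligible, , drop = FALSE]
  ag <- a[a$role == "antigen" & a$eligible, , drop = FALSE]
  hits <- list()
  for (i in seq_len(nrow(ab))) {
    for (j in seq_len(nrow(ag))) {
      d <- sqrt((ab$x[i] - ag$x[j])^2 + (ab$y[i] - ag$y[j])^2 +
                  (ab$z[i] - ag$z[j])^2)
      if (d <= cutoff) {
        hits[[length(hits) + 1]] <- data.frame(
          ab_chain = ab$chain[i], ab_resno = ab$resno[i],
          ab_insert = ab$insert[i], ab_aa = ab$resid[i],
          ab_atom = ab$elety[i], ab_domain = ab$domain[i],
          ag_chain = ag$chain[j], ag_resno = ag$resno[j],
          ag_insert = ag$insert[j], ag_aa = ag$resid[j],
          ag_atom = ag$elety[j], distance = d, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0) return(NULL)
  out <- do.call(rbind, hits)
  out <- out[order(out$ab_chain, out$ab_resno, out$ab_insert, out$ab_atom,
                   out$ag_chain, out$ag_resno, out$ag_insert, out$ag_atom), ]
  rownames(out) <- NULL
  out
}

# Canonical key set of a contact table, for set comparisons.
contact_keys <- function(ct) {
  if (is.null(ct) || nrow(ct) == 0) return(character(0))
  sort(paste(ct$ab_chain, ct$ab_resno, ct$ab_insert, ct$ab_atom,
             ct$ag_chain, ct$ag_resno, ct$ag_insert, ct$ag_atom, sep = "|"))
}

# Random two-sided atom cloud (no planted structure): ~n_ab + n_ag atoms in
# overlapping boxes so a nontrivial contact set arises by chance.
mk_random_complex <- function(seed, n_ab = 50, n_ag = 40, box = 18) {
  set.seed(seed)
  ab <- data.frame(
    chain = "H", resno = rep(seq_len(ceiling(n_ab / 4)), each = 4)[1:n_ab],
    insert = "", elety = rep(c("N", "CA", "C", "O"), length.out = n_ab),
    resid = "TYR",
    x = runif(n_ab, 0, box), y = runif(n_ab, 0, box), z = runif(n_ab, 0, box),
    domain = "VH", role = "antibody", stringsAsFactors = FALSE)
  ag <- data.frame(
    chain = "A", resno = rep(seq_len(ceiling(n_ag / 4)), each = 4)[1:n_ag],
    insert = "", elety = rep(c("N", "CA", "C", "O"), length.out = n_ag),
    resid = "ALA",
    x = runif(n_ag, 2, box + 2), y = runif(n_ag, 2, box + 2),
    z = runif(n_ag, 2, box + 2),
    domain = NA_character_, role = "antigen", stringsAsFactors = FALSE)
  mk_complex(rbind(ab, ag))
}

# Default planted-contact table used by generator-based tests.
default_planted <- function() {
  data.frame(ab_domain = c("VH", "VH", "VL"),
             ab_pos = c(30, 107, 56), ab_atom = c("CB", "OH", "CB"),
             ag_pos = c(5, 12, 20), ag_atom = c("CB", "NZ", "O"),
             distance = c(3.5, 4.2, 4.4), stringsAsFactors = FALSE)
}

# Write a generated dataset (pdbs + annotation) to a temp dir for pipeline
# runs; returns list(summary=, pdb_dir=).
write_dataset <- function(pdbs, annotation, dir) {
  for (nm in names(pdbs)) {
    writeLines(sub("\n$", "", pdbs[[nm]]), file.path(dir, paste0(nm, ".pdb")))
  }
  write_annotation_summary(annotation, file.path(dir, "summary.tsv"))
  list(summary = file.path(dir, "summary.tsv"), pdb_dir = dir)
}
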