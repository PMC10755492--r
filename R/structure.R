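# Reading PDB structures into annotated antibody-antigen complexes.

#' Parse an antibody-antigen structure file into biological units
#'
#' Reads a PDB file (path or raw text) with [bio3d::read.pdb] and builds one
#' complex per annotation row: each row's heavy/light/antigen chain labels
#' define one biological unit. Alternate locations are resolved to a single
#' atom per name (highest occupancy, ties broken by alternate-location
#' character order); hydrogens and deuteriums are kept but flagged ineligible
#' for contacts; waters, ions and non-amino-acid heteroatoms go to a separate
#' solvent store; modified residues with a standard parent are mapped to the
#' parent and unmappable residues are excluded from the residue lists and
#' logged.
#'
#' @param pdb Path to a PDB file, or a character scalar of PDB-format text.
#' @param annotation An `abag_annotation` data frame (or subset of rows) whose
#'   rows all refer to this structure file.
#' @return A list of `abag_complex` objects, one per annotation row, each with
#'   elements `structure_id`, `unit_index`, `annotation` (one row), `atoms`
#'   (amino-acid atoms of the antibody and antigen chains), `solvent` and
#'   `excluded`.
#' @export
parse_complex <- function(pdb, annotation) {
  stopifnot(nrow(annotation) >= 1)
  path <- pdb
  if (length(pdb) == 1 && grepl("\n", pdb, fixed = TRUE)) {
    path <- tempfile(fileext = ".pdb")
    writeLines(sub("\n$", "", pdb), path)
    on.exit(unlink(path))
  }
  parsed <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  at <- parsed$atom
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$b[is.na(at$b)] <- 0

  at <- .resolve_altloc(at)
  at$resid_std <- map_residue_code(at$resid)
  at$is_hydrogen <- .is_hydrogen(at$elety, at$elesy)
  is_water <- toupper(at$resid) %in% c("HOH", "DOD", "WAT")
  is_aa <- !is.na(at$resid_std) & !is_water

  lapply(seq_len(nrow(annotation)), function(i) {
    ann <- annotation[i, , drop = FALSE]
    ab_chains <- .antibody_chain_ids(ann)
    ag_chains <- .antigen_chain_ids(ann)
    chains <- c(ab_chains, ag_chains)
    absent <- setdiff(chains, unique(at$chain))
    if (length(absent) > 0) {
      stop("structure ", ann$structure_id, ": annotated chain(s) ",
           paste(absent, collapse = ", "), " absent from file")
    }

    sel <- at$chain %in% chains & is_aa
    atoms <- at[sel, , drop = FALSE]
    role <- ifelse(atoms$chain %in% ab_chains, "antibody", "antigen")
    domain <- rep(NA_character_, nrow(atoms))
    for (d in names(ab_chains)) domain[atoms$chain == ab_chains[[d]]] <- d

    out <- data.frame(
      chain = atoms$chain, resno = atoms$resno, insert = atoms$insert,
      resid = atoms$resid_std, resid_orig = atoms$resid,
      elety = atoms$elety, elesy = atoms$elesy, alt = atoms$alt,
      x = atoms$x, y = atoms$y, z = atoms$z, o = atoms$o, b = atoms$b,
      role = role, domain = domain,
      is_hydrogen = atoms$is_hydrogen,
      eligible = !atoms$is_hydrogen,
      stringsAsFactors = FALSE)

    for (d in names(ab_chains)) {
      if (!any(out$chain == ab_chains[[d]])) {
        stop("structure ", ann$structure_id, ": chain ", ab_chains[[d]],
             " has no amino-acid residues")
      }
    }
    if (!any(out$role == "antigen")) {
      stop("structure ", ann$structure_id,
           ": no antigen amino-acid residues found")
    }

    solv_sel <- (is_water | (at$chain %in% chains & !is_aa))
    solvent <- at[solv_sel, c("chain", "resno", "insert", "resid", "elety",
                              "elesy", "x", "y", "z", "o", "b"), drop = FALSE]
    excl_sel <- at$chain %in% chains & !is_water & is.na(at$resid_std) &
      at$type == "ATOM"
    excluded <- at[excl_sel, c("chain", "resno", "insert", "resid"),
                   drop = FALSE]
    excluded <- unique(excluded)
    if (nrow(excluded) > 0) {
      message("structure ", ann$structure_id, ": ", nrow(excluded),
              " residue(s) with unmappable codes excluded (",
              paste(unique(excluded$resid), collapse = ", "), ")")
    }
    rownames(out) <- rownames(solvent) <- rownames(excluded) <- NULL

    structure(list(
      structure_id = ann$structure_id,
      unit_index = i,
      annotation = ann,
      atoms = out,
      solvent = solvent,
      excluded = excluded), class = "abag_complex")
  })
}

# Keep one copy per (chain, resno, insert, elety): highest occupancy,
# tie broken by altloc character order (blank sorts first).
.resolve_altloc <- function(at) {
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(key, -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  at[!duplicated(key[ord]), , drop = FALSE]
}

#' @export
print.abag_complex <- function(x, ...) {
  res <- unique_residues(x)
  cat("<abag_complex> ", x$structure_id, " unit ", x$unit_index, "\n", sep = "")
  cat("  antibody: ", sum(res$role == "antibody"), " residues (",
      paste(sort(unique(stats::na.omit(res$domain))), collapse = "+"),
      "), antigen: ", sum(res$role == "antigen"), " residues on ",
      length(unique(res$chain[res$role == "antigen"])), " chain(s)\n", sep = "")
  cat("  resolution: ", x$annotation$resolution, " A, antigen type: ",
      x$annotation$antigen_type, "\n", sep = "")
  invisible(x)
}

#' Unique residues of a complex
#'
#' @param complex An `abag_complex`.
#' @param role Optional filter: `"antibody"` or `"antigen"`.
#' @return Data frame with one row per (chain, resno, insert): columns
#'   `chain`, `resno`, `insert`, `resid`, `role`, `domain`.
#' @export
unique_residues <- function(complex, role = NULL) {
  a <- complex$atoms
  if (!is.null(role)) a <- a[a$role == role, , drop = FALSE]
  key <- .res_key(a$chain, a$resno, a$insert)
  a <- a[!duplicated(key), c("chain", "resno", "insert", "resid", "role",
                             "domain"), drop = FALSE]
  a <- a[order(a$chain, a$resno, a$insert), , drop = FALSE]
  rownames(a) <- NULL
  a
}

#' Write a complex back to PDB format
#'
#' Emits the amino-acid atoms of the antibody and antigen chains (and
#' optionally the solvent store) in wwPDB fixed-column layout via
#' [bio3d::write.pdb]. Coordinates keep format precision (3 decimals), so a
#' parse/write/parse round trip preserves the residue and atom inventory.
#'
#' @param complex An `abag_complex`.
#' @param path Output file path.
#' @param include_solvent Also write the solvent store as HETATM records.
#' @return `path`, invisibly.
#' @export
write_complex_pdb <- function(complex, path, include_solvent = FALSE) {
  a <- complex$atoms
  type <- rep("ATOM", nrow(a))
  if (include_solvent && nrow(complex$solvent) > 0) {
    s <- complex$solvent
    s2 <- data.frame(chain = s$chain, resno = s$resno, insert = s$insert,
                     resid = s$resid, resid_orig = s$resid, elety = s$elety,
                     elesy = s$elesy, alt = "", x = s$x, y = s$y, z = s$z,
                     o = s$o, b = s$b, role = NA, domain = NA,
                     is_hydrogen = FALSE, eligible = FALSE,
                     stringsAsFactors = FALSE)
    a <- rbind(a, s2)
    type <- c(type, rep("HETATM", nrow(s2)))
  }
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = type, resno = a$resno, resid = a$resid,
                   eleno = seq_len(nrow(a)), elety = a$elety,
                   chain = a$chain, insert = ifelse(a$insert == "", NA, a$insert),
                   alt = ifelse(a$alt == "", NA, a$alt),
                   o = a$o, b = a$b, elesy = a$elesy)
  invisible(path)
}

#' Filter complexes by resolution and exclusion list
#'
#' Retains complexes whose resolution is at most `max_resolution` (boundary
#' inclusive) and whose structure identifier is not on the exclusion list.
#'
#' @param complexes List of `abag_complex` objects, or the `$complexes`
#'   element of a previous `filter_dataset()` result.
#' @param max_resolution Maximum resolution in Angstrom (default 3.0).
#' @param exclusion_list Character vector of structure identifiers to drop.
#' @return List with `complexes` (retained, in input order) and `log`
#'   (data frame of removals: `structure_id`, `unit_index`, `reason`).
#' @export
filter_dataset <- function(complexes, max_resolution = 3.0,
                           exclusion_list = character()) {
  if (is.list(complexes) && !is.null(complexes$complexes)) {
    complexes <- complexes$complexes
  }
  exclusion_list <- toupper(exclusion_list)
  reasons <- vapply(complexes, function(cx) {
    if (cx$structure_id %in% exclusion_list) return("on exclusion list")
    if (cx$annotation$resolution > max_resolution) {
      return(sprintf("resolution %.2f A above cutoff %.2f A",
                     cx$annotation$resolution, max_resolution))
    }
    NA_character_
  }, character(1))
  keep <- is.na(reasons)
  log <- data.frame(
    structure_id = vapply(complexes, `[[`, "", "structure_id")[!keep],
    unit_index = vapply(complexes, `[[`, 1L, "unit_index")[!keep],
    reason = reasons[!keep], stringsAsFactors = FALSE)
  list(complexes = complexes[keep], log = log)
}

#' Classify a complex into an antibody/antigen group
#'
#' Groups follow the antibody format (Fv when both VH and VL are present,
#' single-domain otherwise) and the antigen type. The antigen type is taken
#' from the annotation when present; otherwise a complex is a peptide binder
#' iff every antigen chain is shorter than `peptide_max_len` residues
#' (strictly; chains of exactly `peptide_max_len` residues count as protein).
#'
#' @param complex An `abag_complex`.
#' @param peptide_max_len Peptide length threshold in residues (default 50).
#' @return One of `"protein_Fv"`, `"peptide_Fv"`, `"protein_VH_sdAb"`,
#'   `"peptide_VH_sdAb"`, `"protein_VL_sdAb"`, `"peptide_VL_sdAb"`.
#' @export
classify_group <- function(complex, peptide_max_len = 50) {
  res <- unique_residues(complex)
  domains <- sort(unique(stats::na.omit(res$domain[res$role == "antibody"])))
  if (length(domains) == 0) stop("complex has no variable domain")
  part <- if (all(c("VH", "VL") %in% domains)) "Fv"
          else paste0(domains[1], "_sdAb")

  type <- complex$annotation$antigen_type
  if (is.na(type) || !type %in% c("protein", "peptide")) {
    ag <- res[res$role == "antigen", , drop = FALSE]
    lens <- table(ag$chain)
    type <- if (all(lens < peptide_max_len)) "peptide" else "protein"
  }
  paste0(type, "_", part)
}
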