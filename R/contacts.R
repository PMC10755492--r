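# Interface definition: non-hydrogen atom-atom contacts across the
# antibody-antigen interface at a Euclidean distance cutoff (default 5 A,
# boundary inclusive).

#' Find atom-atom contacts across the antibody-antigen interface
#'
#' Every pair of one eligible antibody atom and one eligible antigen atom with
#' Euclidean distance less than or equal to `cutoff` yields exactly one
#' contact record. Eligible atoms are non-hydrogen atoms of standard (or
#' standard-mapped) amino acids; waters, ions and other heteroatoms never
#' appear. A cell-grid neighbor search is used; its output is set-identical to
#' an all-pairs scan.
#'
#' @param complex An `abag_complex`.
#' @param cutoff Distance cutoff in Angstrom (default 5.0, inclusive).
#' @return Data frame of contact records sorted by antibody then antigen
#'   endpoint: `ab_chain`, `ab_resno`, `ab_insert`, `ab_aa`, `ab_atom`,
#'   `ab_domain`, `ag_chain`, `ag_resno`, `ag_insert`, `ag_aa`, `ag_atom`,
#'   `distance`.
#' @export
find_contacts <- function(complex, cutoff = 5.0) {
  a <- complex$atoms
  ab <- a[a$role == "antibody" & a$eligible, , drop = FALSE]
  ag <- a[a$role == "antigen" & a$eligible, , drop = FALSE]
  if (nrow(ab) == 0 || nrow(ag) == 0) {
    stop("complex has no contact-eligible atoms on one side of the interface")
  }
  pairs <- .grid_pairs(as.matrix(ab[, c("x", "y", "z")]),
                       as.matrix(ag[, c("x", "y", "z")]), cutoff)
  i <- pairs$i; j <- pairs$j
  out <- data.frame(
    ab_chain = ab$chain[i], ab_resno = ab$resno[i], ab_insert = ab$insert[i],
    ab_aa = ab$resid[i], ab_atom = ab$elety[i], ab_domain = ab$domain[i],
    ag_chain = ag$chain[j], ag_resno = ag$resno[j], ag_insert = ag$insert[j],
    ag_aa = ag$resid[j], ag_atom = ag$elety[j],
    distance = pairs$d, stringsAsFactors = FALSE)
  out <- out[order(out$ab_chain, out$ab_resno, out$ab_insert, out$ab_atom,
                   out$ag_chain, out$ag_resno, out$ag_insert, out$ag_atom), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# Cell-grid neighbor search: bin both point sets into cubic cells of edge
# `cutoff`, then candidate pairs can only live in the same or an adjacent
# cell (27 offsets). Returns indices and distances of pairs with d <= cutoff.
.grid_pairs <- function(p, q, cutoff) {
  kp <- floor(p / cutoff)
  kq <- floor(q / cutoff)
  qkey <- paste(kq[, 1], kq[, 2], kq[, 3])
  m <- split(seq_len(nrow(q)), qkey)
  i_all <- integer(0); j_all <- integer(0); d_all <- numeric(0)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (r in seq_len(nrow(offs))) {
    pk <- paste(kp[, 1] + offs[r, 1], kp[, 2] + offs[r, 2], kp[, 3] + offs[r, 3])
    # all (i, j) with p-cell shifted onto q-cell
    hit <- pk %in% names(m)
    if (!any(hit)) next
    js <- m[pk[hit]]
    is <- rep(which(hit), lengths(js))
    js <- unlist(js, use.names = FALSE)
    d2 <- (p[is, 1] - q[js, 1])^2 + (p[is, 2] - q[js, 2])^2 +
      (p[is, 3] - q[js, 3])^2
    keep <- d2 <= cutoff^2
    i_all <- c(i_all, is[keep]); j_all <- c(j_all, js[keep])
    d_all <- c(d_all, sqrt(d2[keep]))
  }
  list(i = i_all, j = j_all, d = d_all)
}

#' Classify an atom name as main chain or side chain
#'
#' Backbone atoms are N, CA, C, O and the terminal carboxylate OXT; every
#' other standard amino-acid atom name is side chain. Names outside the
#' standard PDB nomenclature fall back to side chain with a warning.
#'
#' @param atom_name Character vector of PDB atom names.
#' @return Character vector, `"main_chain"` or `"side_chain"`.
#' @export
classify_atom_class <- function(atom_name) {
  nm <- toupper(trimws(atom_name))
  side <- c("CB", "CG", "CG1", "CG2", "CD", "CD1", "CD2", "CE", "CE1", "CE2",
            "CE3", "CZ", "CZ2", "CZ3", "CH2", "ND1", "ND2", "NE", "NE1",
            "NE2", "NZ", "NH1", "NH2", "OD1", "OD2", "OE1", "OE2", "OG",
            "OG1", "OH", "SD", "SG", "SE")
  unknown <- !(nm %in% c(.MAIN_CHAIN_ATOMS, side))
  if (any(unknown)) {
    warning("unrecognized atom name(s) treated as side chain: ",
            paste(unique(nm[unknown]), collapse = ", "))
  }
  ifelse(nm %in% .MAIN_CHAIN_ATOMS, "main_chain", "side_chain")
}

#' Summarize an interface contact table
#'
#' Distinguishes total atom-atom contacts from unique paratope/epitope
#' residues (uPR/uER) and atoms (uPA/uEA): a residue or atom is counted once
#' no matter how many contacts it mediates. Unique atoms on the paratope side
#' are additionally split into main-chain and side-chain atoms.
#'
#' @param contacts Contact table from [find_contacts()] (may be empty).
#' @return An `interface_summary` list: `total_contacts`, `upr`, `uer`, `upa`,
#'   `uea`, `upa_main`, `upa_side`, and `per_domain` (data frame with
#'   `domain`, `contacts`, `upr`, `upa`).
#' @export
summarize_interface <- function(contacts) {
  pr_key <- .res_key(contacts$ab_chain, contacts$ab_resno, contacts$ab_insert)
  er_key <- .res_key(contacts$ag_chain, contacts$ag_resno, contacts$ag_insert)
  if (nrow(contacts) > 0) {
    pa_key <- paste0(pr_key, "/", contacts$ab_atom)
    ea_key <- paste0(er_key, "/", contacts$ag_atom)
  } else {
    pa_key <- ea_key <- character(0)
  }

  upa_first <- !duplicated(pa_key)
  pa_class <- if (nrow(contacts) > 0) {
    classify_atom_class(contacts$ab_atom[upa_first])
  } else character(0)

  per_domain <- do.call(rbind, lapply(c("VH", "VL"), function(d) {
    sel <- !is.na(contacts$ab_domain) & contacts$ab_domain == d
    data.frame(domain = d,
               contacts = sum(sel),
               upr = length(unique(pr_key[sel])),
               upa = length(unique(pa_key[sel])),
               stringsAsFactors = FALSE)
  }))

  structure(list(
    total_contacts = nrow(contacts),
    upr = length(unique(pr_key)),
    uer = length(unique(er_key)),
    upa = length(unique(pa_key)),
    uea = length(unique(ea_key)),
    upa_main = sum(pa_class == "main_chain"),
    upa_side = sum(pa_class == "side_chain"),
    per_domain = per_domain), class = "interface_summary")
}

#' @export
print.interface_summary <- function(x, ...) {
  cat("<interface_summary> ", x$total_contacts, " contacts | uPR ", x$upr,
      ", uER ", x$uer, ", uPA ", x$upa, " (", x$upa_main, " main / ",
      x$upa_side, " side), uEA ", x$uea, "\n", sep = "")
  invisible(x)
}

#' Count interfacial waters
#'
#' A water is interfacial iff its oxygen lies within `cutoff` of at least one
#' eligible antibody atom AND at least one eligible antigen atom.
#' Water-mediated contacts count every (water oxygen, protein atom) pair
#' within the cutoff for interfacial waters, on both sides. These counts are
#' reported separately and never mixed into the contact table.
#'
#' @param complex An `abag_complex` (its solvent store must be present).
#' @param cutoff Distance cutoff in Angstrom (default 5.0).
#' @return List with `n_waters` and `n_water_mediated`.
#' @export
count_interfacial_waters <- function(complex, cutoff = 5.0) {
  s <- complex$solvent
  w <- s[toupper(s$resid) %in% c("HOH", "DOD", "WAT") &
           toupper(trimws(s$elesy)) %in% c("O", "") &
           !.is_hydrogen(s$elety, s$elesy), , drop = FALSE]
  if (nrow(w) == 0) return(list(n_waters = 0L, n_water_mediated = 0L))
  a <- complex$atoms[complex$atoms$eligible, , drop = FALSE]
  wm <- as.matrix(w[, c("x", "y", "z")])
  n_ab <- integer(nrow(w)); n_ag <- integer(nrow(w))
  for (side in c("antibody", "antigen")) {
    pm <- as.matrix(a[a$role == side, c("x", "y", "z")])
    pr <- .grid_pairs(wm, pm, cutoff)
    counts <- tabulate(pr$i, nbins = nrow(w))
    if (side == "antibody") n_ab <- counts else n_ag <- counts
  }
  interf <- n_ab > 0 & n_ag > 0
  list(n_waters = sum(interf),
       n_water_mediated = sum((n_ab + n_ag)[interf]))
}
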