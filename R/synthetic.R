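# Ground-truthed synthetic antibody-antigen complexes. Residues sit on a
# coarse backbone scaffold; chemical realism is not a goal - only the
# distance structure, IMGT-consistent numbering and PDB format validity
# matter. Antibody and antigen chains are laid out on parallel rails
# separated far beyond the decoy margin, and each planted contact pair is
# moved onto its own "stalk" in the gap, so that the contact set under the
# cutoff is exactly the planted list.

#' Specify a synthetic antibody-antigen complex
#'
#' @param seed RNG seed controlling residue composition and B-factor jitter.
#' @param n_ab_residues Variable-domain residue count per antibody domain
#'   (IMGT identifiers 1..n).
#' @param domains `c("VH", "VL")` for an Fv antibody, `"VH"` or `"VL"` for a
#'   single-domain one.
#' @param antigen_len Antigen chain length in residues.
#' @param planted_contacts `NULL` (no contacts) or a data frame with columns
#'   `ab_domain`, `ab_pos`, `ab_atom`, `ag_pos`, `ag_atom`, `distance`; each
#'   endpoint (position, atom) must be unique so it can occupy its own
#'   geometric slot, and every distance must satisfy
#'   `distance <= cutoff < decoy_margin`.
#' @param cutoff Contact cutoff the ground truth is defined for (default 5).
#' @param decoy_margin Minimum separation in Angstrom of every non-planted
#'   antibody/antigen atom pair (default 8, above the 6 A sweep maximum).
#' @param structure_id 4-character structure identifier.
#' @param resolution Nominal resolution recorded in the annotation row.
#' @param antigen_type `"protein"`, `"peptide"`, or `NA` to derive from
#'   `antigen_len` (< 50 residues = peptide).
#' @param ab_sequences Optional named list of 1-letter sequences per domain,
#'   overriding the random composition (used by the redundancy generator).
#' @param paratope_composition Optional data frame `domain`, `pos`, `aa`
#'   (3-letter) fixing amino acids at planted positions so frequency
#'   statistics have known expectations.
#' @param n_interface_waters Number of water molecules placed at planted-pair
#'   midpoints (requires at least that many planted contacts); each is within
#'   the cutoff of exactly one atom per side.
#' @param n_interface_hydrogens Number of hydrogen atoms placed within the
#'   cutoff of planted antigen atoms, to exercise hydrogen exclusion.
#' @param b_base Baseline B-factor; per-atom jitter in [0, 5) is added.
#' @return A validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(seed = 1, n_ab_residues = 110,
                           domains = c("VH", "VL"), antigen_len = 60,
                           planted_contacts = NULL, cutoff = 5.0,
                           decoy_margin = 8.0, structure_id = "SYN1",
                           resolution = 2.0, antigen_type = NA_character_,
                           ab_sequences = NULL, paratope_composition = NULL,
                           n_interface_waters = 0L,
                           n_interface_hydrogens = 0L, b_base = 20) {
  stopifnot(all(domains %in% c("VH", "VL")), length(domains) >= 1,
            n_ab_residues >= 10, antigen_len >= 1, nchar(structure_id) == 4,
            cutoff > 0, decoy_margin > cutoff)
  pc <- planted_contacts
  if (!is.null(pc) && nrow(pc) > 0) {
    need <- c("ab_domain", "ab_pos", "ab_atom", "ag_pos", "ag_atom", "distance")
    stopifnot(all(need %in% names(pc)))
    if (any(pc$distance > cutoff)) {
      stop("planted distance exceeds the cutoff: geometry infeasible")
    }
    if (any(pc$distance <= 0)) stop("planted distances must be positive")
    if (any(!pc$ab_domain %in% domains)) stop("planted domain not in spec")
    if (any(pc$ab_pos < 1 | pc$ab_pos > n_ab_residues) ||
        any(pc$ag_pos < 1 | pc$ag_pos > antigen_len)) {
      stop("planted position outside the chain")
    }
    if (anyDuplicated(pc[, c("ab_domain", "ab_pos", "ab_atom")]) ||
        anyDuplicated(pc[, c("ag_pos", "ag_atom")])) {
      stop("planted endpoints must be unique (one slot per planted atom)")
    }
  }
  if (n_interface_waters > 0 &&
      (is.null(pc) || nrow(pc) < n_interface_waters)) {
    stop("interface waters require at least as many planted contacts")
  }
  if (n_interface_hydrogens > 0 &&
      (is.null(pc) || nrow(pc) < n_interface_hydrogens)) {
    stop("interface hydrogens require at least as many planted contacts")
  }
  structure(list(
    seed = seed, n_ab_residues = n_ab_residues, domains = domains,
    antigen_len = antigen_len, planted_contacts = pc, cutoff = cutoff,
    decoy_margin = decoy_margin, structure_id = toupper(structure_id),
    resolution = resolution, antigen_type = antigen_type,
    ab_sequences = ab_sequences, paratope_composition = paratope_composition,
    n_interface_waters = as.integer(n_interface_waters),
    n_interface_hydrogens = as.integer(n_interface_hydrogens),
    b_base = b_base), class = "synthetic_spec")
}

# Scaffold atom offsets relative to CA (all within 1.7 A).
.RES_ATOMS <- list(
  N  = c(-1.3, 0.0,  0.5), CA = c(0, 0, 0), C = c(1.3, 0.0, 0.5),
  O  = c(1.3, 0.0, -1.0), CB = c(0.0, 1.0, 1.0))

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

# Build the atom table (before PDB formatting) of one synthetic unit.
.synth_atoms <- function(spec) {
  .with_seed(spec$seed, {
    s <- 6                      # residue spacing along x
    rails <- c(VH = 0, VL = -20)   # antibody rails (y)
    gap <- 2 * spec$decoy_margin + spec$cutoff + 2 * 1.7 + 1
    chain_of <- c(VH = "H", VL = "L")

    seq_for <- function(n, given) {
      if (!is.null(given)) {
        stopifnot(nchar(given) == n)
        unname(.AA_1TO3[strsplit(given, "")[[1]]])
      } else {
        sample(standard_aa(), n, replace = TRUE)
      }
    }

    rows <- list()
    add_residue <- function(chain, resno, aa, ca, role, domain) {
      atoms <- .RES_ATOMS
      if (aa == "GLY") atoms$CB <- NULL
      for (nm in names(atoms)) {
        rows[[length(rows) + 1]] <<- data.frame(
          chain = chain, resno = resno, insert = "", resid = aa,
          elety = nm, elesy = substr(nm, 1, 1),
          x = ca[1] + atoms[[nm]][1], y = ca[2] + atoms[[nm]][2],
          z = ca[3] + atoms[[nm]][3],
          o = 1, b = 0, role = role, domain = domain,
          stringsAsFactors = FALSE)
      }
    }

    for (d in spec$domains) {
      aa <- seq_for(spec$n_ab_residues, spec$ab_sequences[[d]])
      if (!is.null(spec$paratope_composition)) {
        pcmp <- spec$paratope_composition
        sel <- pcmp$domain == d
        aa[pcmp$pos[sel]] <- pcmp$aa[sel]
      }
      for (i in seq_len(spec$n_ab_residues)) {
        add_residue(chain_of[[d]], i, aa[i], c(s * i, rails[[d]], 0),
                    "antibody", d)
      }
    }
    ag_aa <- seq_for(spec$antigen_len, spec$ab_sequences[["AG"]])
    for (j in seq_len(spec$antigen_len)) {
      add_residue("A", j, ag_aa[j], c(s * j, gap, 0), "antigen", NA)
    }
    at <- do.call(rbind, rows)

    # move planted atoms onto their stalks in the inter-rail gap
    pc <- spec$planted_contacts
    x_wat <- numeric(0); y_wat <- numeric(0)
    if (!is.null(pc) && nrow(pc) > 0) {
      slot_w <- spec$decoy_margin + 2
      x0 <- s * (max(spec$n_ab_residues, spec$antigen_len) + 2)
      for (k in seq_len(nrow(pc))) {
        xk <- x0 + k * slot_w
        d <- pc$distance[k]
        y_ab <- gap / 2 - d / 2
        y_ag <- gap / 2 + d / 2
        ab_chain <- chain_of[[pc$ab_domain[k]]]
        move <- function(chain, resno, nm, xx, yy) {
          hit <- at$chain == chain & at$resno == resno & at$elety == nm
          if (any(hit)) {
            at$x[hit] <<- xx; at$y[hit] <<- yy; at$z[hit] <<- 0
          } else {
            tmpl <- at[at$chain == chain & at$resno == resno, ][1, ]
            tmpl$elety <- nm
            tmpl$elesy <- substr(gsub("[0-9]", "", nm), 1, 1)
            tmpl$x <- xx; tmpl$y <- yy; tmpl$z <- 0
            at <<- rbind(at, tmpl)
          }
        }
        move(ab_chain, pc$ab_pos[k], pc$ab_atom[k], xk, y_ab)
        move("A", pc$ag_pos[k], pc$ag_atom[k], xk, y_ag)
        if (k <= spec$n_interface_waters) {
          x_wat <- c(x_wat, xk); y_wat <- c(y_wat, gap / 2)
        }
        if (k <= spec$n_interface_hydrogens) {
          # hydrogen 2 A below the planted antigen atom: within the cutoff
          # of that atom yet never an eligible contact endpoint
          hrow <- at[at$chain == ab_chain & at$resno == pc$ab_pos[k], ][1, ]
          hrow$elety <- "HX"; hrow$elesy <- "H"
          hrow$x <- xk; hrow$y <- y_ag - 2; hrow$z <- 0
          at <- rbind(at, hrow)
        }
      }
    }

    at$b <- spec$b_base + round(stats::runif(nrow(at)) * 5, 2)
    at$x <- round(at$x, 3); at$y <- round(at$y, 3); at$z <- round(at$z, 3)
    waters <- NULL
    if (spec$n_interface_waters > 0) {
      waters <- data.frame(
        chain = "W", resno = seq_along(x_wat), insert = "", resid = "HOH",
        elety = "O", elesy = "O", x = round(x_wat, 3), y = round(y_wat, 3),
        z = 0, o = 1, b = spec$b_base, role = NA, domain = NA,
        stringsAsFactors = FALSE)
    }
    list(atoms = at, waters = waters)
  })
}

# Fixed-column PDB formatting of an atom table.
.format_pdb <- function(at, hetatm = NULL) {
  fmt <- function(df, rec, serial0) {
    nm <- ifelse(nchar(df$elety) < 4, paste0(" ", df$elety), df$elety)
    sprintf("%-6s%5d %-4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            rec, serial0 + seq_len(nrow(df)), nm, df$resid, df$chain,
            df$resno, ifelse(df$insert == "", " ", df$insert),
            df$x, df$y, df$z, df$o, df$b, df$elesy)
  }
  lines <- fmt(at, "ATOM", 0L)
  if (!is.null(hetatm) && nrow(hetatm) > 0) {
    lines <- c(lines, fmt(hetatm, "HETATM", nrow(at)))
  }
  paste(c(lines, "END", ""), collapse = "\n")
}

# Annotation row for a synthetic unit.
.synth_annotation <- function(spec, hchain = "H", lchain = "L",
                              agchain = "A") {
  type <- spec$antigen_type
  if (is.na(type)) type <- if (spec$antigen_len < 50) "peptide" else "protein"
  ann <- data.frame(
    structure_id = spec$structure_id,
    heavy_chain = if ("VH" %in% spec$domains) hchain else NA_character_,
    light_chain = if ("VL" %in% spec$domains) lchain else NA_character_,
    antigen_chains = agchain,
    antigen_type = type,
    resolution = spec$resolution,
    stringsAsFactors = FALSE)
  class(ann) <- c("abag_annotation", class(ann))
  ann
}

# Expected contact table from the planted list and the (rounded) atom table.
.synth_truth_contacts <- function(spec, at) {
  pc <- spec$planted_contacts
  if (is.null(pc) || nrow(pc) == 0) {
    return(data.frame(ab_chain = character(0), ab_resno = integer(0),
                      ab_insert = character(0), ab_aa = character(0),
                      ab_atom = character(0), ab_domain = character(0),
                      ag_chain = character(0), ag_resno = integer(0),
                      ag_insert = character(0), ag_aa = character(0),
                      ag_atom = character(0), distance = numeric(0),
                      stringsAsFactors = FALSE))
  }
  chain_of <- c(VH = "H", VL = "L")
  find_atom <- function(chain, resno, nm) {
    which(at$chain == chain & at$resno == resno & at$elety == nm)[1]
  }
  out <- do.call(rbind, lapply(seq_len(nrow(pc)), function(k) {
    i <- find_atom(chain_of[[pc$ab_domain[k]]], pc$ab_pos[k], pc$ab_atom[k])
    j <- find_atom("A", pc$ag_pos[k], pc$ag_atom[k])
    d <- sqrt(sum((unlist(at[i, c("x", "y", "z")]) -
                     unlist(at[j, c("x", "y", "z")]))^2))
    if (d > spec$cutoff) {
      stop("planted contact fell outside the cutoff after rounding")
    }
    data.frame(
      ab_chain = at$chain[i], ab_resno = at$resno[i], ab_insert = "",
      ab_aa = at$resid[i], ab_atom = at$elety[i], ab_domain = at$domain[i],
      ag_chain = "A", ag_resno = at$resno[j], ag_insert = "",
      ag_aa = at$resid[j], ag_atom = at$elety[j], distance = d,
      stringsAsFactors = FALSE)
  }))
  out <- out[order(out$ab_chain, out$ab_resno, out$ab_insert, out$ab_atom,
                   out$ag_chain, out$ag_resno, out$ag_insert, out$ag_atom), ]
  rownames(out) <- NULL
  out
}

#' Generate one synthetic antibody-antigen complex
#'
#' Deterministic for a fixed spec (byte-identical PDB text), with ground
#' truth: the contact set of the emitted structure under the spec's cutoff is
#' exactly the planted list, and every non-planted antibody/antigen atom pair
#' is separated by at least the decoy margin.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `pdb` (PDB-format text), `annotation` (one-row
#'   annotation table), and `truth` (list: `contacts`, `summary`,
#'   `n_waters`, `n_water_mediated`).
#' @export
generate_complex <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  built <- .synth_atoms(spec)
  truth_contacts <- .synth_truth_contacts(spec, built$atoms)
  list(
    pdb = .format_pdb(built$atoms, built$waters),
    annotation = .synth_annotation(spec),
    truth = list(
      contacts = truth_contacts,
      summary = summarize_interface(truth_contacts),
      n_waters = spec$n_interface_waters,
      n_water_mediated = 2L * spec$n_interface_waters))
}

#' Generate a structure file with several co-crystallized units
#'
#' Emits `length(b_offsets)` rigid copies of the base complex, each shifted
#' far along z and with all B-factors offset by the corresponding entry, plus
#' one annotation row per unit (distinct chain labels). Ground truth records
#' which unit carries the minimal mean B-factor (ties: first unit).
#'
#' @param spec A [synthetic_spec()].
#' @param b_offsets Numeric vector of per-unit B-factor shifts.
#' @return List with `pdb`, `annotation` (one row per unit) and `truth`
#'   (list with `selected_unit_index` and the base unit's `contacts`).
#' @export
generate_packing_variants <- function(spec, b_offsets) {
  stopifnot(inherits(spec, "synthetic_spec"), length(b_offsets) >= 1)
  built <- .synth_atoms(spec)
  base <- built$atoms
  heavy_pool <- strsplit("HIJKNOPQ", "")[[1]]
  light_pool <- strsplit("LMSTUVXY", "")[[1]]
  ag_pool <- strsplit("ABCDEFGR", "")[[1]]
  if (length(b_offsets) > length(ag_pool)) stop("too many units")

  units <- list(); anns <- list()
  for (u in seq_along(b_offsets)) {
    at <- base
    at$z <- at$z + 500 * (u - 1)
    at$b <- at$b + b_offsets[u]
    remap <- c(H = heavy_pool[u], L = light_pool[u], A = ag_pool[u])
    at$chain <- unname(remap[at$chain])
    units[[u]] <- at
    anns[[u]] <- .synth_annotation(spec, hchain = heavy_pool[u],
                                   lchain = light_pool[u],
                                   agchain = ag_pool[u])
  }
  ann <- do.call(rbind, anns)
  class(ann) <- c("abag_annotation", class(ann))
  sel <- order(b_offsets, seq_along(b_offsets))[1]
  truth_contacts <- .synth_truth_contacts(spec, base)
  # ground truth speaks in the selected unit's chain labels
  remap <- c(H = heavy_pool[sel], L = light_pool[sel], A = ag_pool[sel])
  truth_contacts$ab_chain <- unname(remap[truth_contacts$ab_chain])
  truth_contacts$ag_chain <- unname(remap[truth_contacts$ag_chain])
  list(
    pdb = .format_pdb(do.call(rbind, units)),
    annotation = ann,
    truth = list(
      selected_unit_index = sel,
      contacts = truth_contacts))
}

#' Generate a dataset with planted antibody redundancy families
#'
#' Builds `n_families` antibody families; members of a family share a base
#' variable-domain sequence with a few random substitutions, so within-family
#' identity stays at or above the clustering threshold while across-family
#' identity (random unrelated sequences) stays far below it. The generator
#' verifies both conditions with [seq_identity()] and re-draws with a derived
#' seed when violated (bounded retries). Member m of a family gets resolution
#' `2.0 + 0.05 * (m - 1)`, making the first member the expected survivor
#' under the keep-rule (best resolution first).
#'
#' @param n_families Number of families.
#' @param family_sizes Integer vector of family sizes (recycled to
#'   `n_families`).
#' @param mutation_rate Substitutions per mutated sequence (default 3).
#' @param seed RNG seed.
#' @param base_spec A [synthetic_spec()] used as template for every member
#'   (its `structure_id`, `seed`, `resolution` and `ab_sequences` are
#'   overridden per member).
#' @return List with `pdbs` (named list of PDB texts), `annotation` (one row
#'   per structure) and `truth` (list: `families` named integer vector,
#'   `survivors` character vector of expected representatives).
#' @export
generate_redundant_dataset <- function(n_families, family_sizes,
                                       mutation_rate = 3, seed = 1,
                                       base_spec = synthetic_spec()) {
  stopifnot(n_families >= 1, all(family_sizes >= 1))
  sizes <- rep_len(family_sizes, n_families)
  n_ab <- base_spec$n_ab_residues
  if (mutation_rate / n_ab > 0.05) {
    stop("mutation_rate too high to keep within-family identity >= 0.95")
  }
  letters20 <- unname(.AA_3TO1)

  seqs <- .with_seed(seed, {
    for (attempt in 1:10) {
      bases <- lapply(seq_len(n_families), function(f) {
        lapply(stats::setNames(base_spec$domains, base_spec$domains),
               function(d) paste(sample(letters20, n_ab, TRUE), collapse = ""))
      })
      cross_ok <- TRUE
      if (n_families > 1) {
        for (d in base_spec$domains) {
          for (f in seq_len(n_families - 1)) for (g in (f + 1):n_families) {
            if (seq_identity(bases[[f]][[d]], bases[[g]][[d]]) >= 0.95) {
              cross_ok <- FALSE
            }
          }
        }
      }
      if (!cross_ok) next
      members <- list()
      within_ok <- TRUE
      for (f in seq_len(n_families)) {
        for (m in seq_len(sizes[f])) {
          mem <- lapply(bases[[f]], function(sq) {
            if (m == 1) return(sq)
            ch <- strsplit(sq, "")[[1]]
            pos <- sample(n_ab, mutation_rate)
            ch[pos] <- sample(letters20, mutation_rate, TRUE)
            paste(ch, collapse = "")
          })
          for (d in base_spec$domains) {
            if (seq_identity(mem[[d]], bases[[f]][[d]]) < 0.95) {
              within_ok <- FALSE
            }
          }
          members[[sprintf("%02d%02d", f, m)]] <- mem
        }
      }
      if (within_ok) break
    }
    if (!cross_ok || !within_ok) stop("could not satisfy identity constraints")
    members
  })

  fam_of <- as.integer(substr(names(seqs), 1, 2))
  mem_of <- as.integer(substr(names(seqs), 3, 4))
  pdbs <- list(); anns <- list()
  for (i in seq_along(seqs)) {
    sp <- base_spec
    sp$structure_id <- names(seqs)[i]
    sp$seed <- seed + i
    sp$resolution <- 2.0 + 0.05 * (mem_of[i] - 1)
    sp$ab_sequences <- seqs[[i]]
    g <- generate_complex(sp)
    pdbs[[names(seqs)[i]]] <- g$pdb
    anns[[i]] <- g$annotation
  }
  ann <- do.call(rbind, anns)
  class(ann) <- c("abag_annotation", class(ann))
  list(
    pdbs = pdbs,
    annotation = ann,
    truth = list(
      families = stats::setNames(fam_of, names(seqs)),
      survivors = names(seqs)[mem_of == 1]))
}
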