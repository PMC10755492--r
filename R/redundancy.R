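# Antibody redundancy removal: variable-domain sequences (IMGT IDs <= 128)
# are clustered greedily at 95% identity, VH and VL populations separately;
# complexes whose chains all fall in the same clusters form a redundancy
# family of which one representative is kept.

#' Extract the variable-domain sequence of an antibody chain
#'
#' Builds the 1-letter sequence over residues whose numeric IMGT identifier is
#' at most `vr_max` (128: the variable domain), ordered by (numeric ID,
#' insertion code). Constant-domain residues are excluded; residues that
#' cannot be mapped to a standard amino acid are dropped with a warning.
#'
#' @param complex An `abag_complex`.
#' @param domain `"VH"` or `"VL"`.
#' @param vr_max Largest variable-domain residue identifier (default 128).
#' @return Character scalar (1-letter sequence) with attribute `source`
#'   `c(structure_id, domain)`.
#' @export
extract_variable_sequence <- function(complex, domain, vr_max = 128) {
  res <- unique_residues(complex, role = "antibody")
  res <- res[!is.na(res$domain) & res$domain == domain, , drop = FALSE]
  if (nrow(res) == 0) stop("complex has no ", domain, " residues")
  res <- res[res$resno <= vr_max, , drop = FALSE]
  if (nrow(res) == 0) {
    stop("no residues with IMGT ID <= ", vr_max, " in ", domain,
         " of ", complex$structure_id)
  }
  res <- res[order(res$resno, res$insert), , drop = FALSE]
  aa1 <- aa_three_to_one(res$resid)
  if (anyNA(aa1)) {
    warning("dropping ", sum(is.na(aa1)), " unmappable residue(s) from ",
            complex$structure_id, " ", domain)
    aa1 <- aa1[!is.na(aa1)]
  }
  if (length(aa1) == 0) stop("empty variable-domain sequence")
  structure(paste(aa1, collapse = ""),
            source = c(complex$structure_id, domain))
}

#' Global-alignment sequence identity
#'
#' Needleman-Wunsch global alignment with match +1, mismatch 0 and a linear
#' gap cost, via [Biostrings::pairwiseAlignment]; identity is the number of
#' matched positions divided by the length of the shorter sequence (the
#' CD-HIT convention).
#'
#' @param a,b 1-letter amino-acid sequences.
#' @return Identity fraction in `[0, 1]`.
#' @export
seq_identity <- function(a, b) {
  if (a == b) return(1)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = .identity_matrix(), type = "global",
    gapOpening = 0, gapExtension = 1)
  Biostrings::nmatch(aln) / min(nchar(a), nchar(b))
}

.identity_matrix <- function() {
  letters1 <- unname(.AA_3TO1)
  m <- matrix(0, 20, 20, dimnames = list(letters1, letters1))
  diag(m) <- 1
  m
}

#' Greedy sequence clustering at an identity threshold
#'
#' CD-HIT-style greedy clustering: sequences are sorted by descending length
#' (ties keep input order); each sequence joins the first existing cluster
#' whose representative (founder) has identity at least `threshold`
#' (inclusive) with it, otherwise it founds a new cluster. VH and VL
#' populations must be clustered separately by the caller.
#'
#' @param seqs Named character vector of 1-letter sequences (names are the
#'   sources, e.g. structure identifiers).
#' @param threshold Identity threshold in `[0, 1]` (default 0.95).
#' @return Named integer vector mapping each source to a cluster index, with
#'   attributes `threshold` and `representatives` (source of each founder).
#' @export
cluster_sequences <- function(seqs, threshold = 0.95) {
  if (length(seqs) == 0) stop("no sequences to cluster")
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == "")) {
    stop("sequences must be named by their source")
  }
  ord <- order(-nchar(seqs), seq_along(seqs))
  reps <- character(0)     # founder sequences
  rep_src <- character(0)
  assign <- integer(length(seqs))
  for (i in ord) {
    placed <- FALSE
    for (k in seq_along(reps)) {
      if (seq_identity(seqs[[i]], reps[[k]]) >= threshold) {
        assign[i] <- k
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, seqs[[i]])
      rep_src <- c(rep_src, names(seqs)[i])
      assign[i] <- length(reps)
    }
  }
  structure(stats::setNames(assign, names(seqs)),
            threshold = threshold, representatives = rep_src)
}

#' Remove redundant antibodies
#'
#' Complexes form a redundancy family when all their antibody chains fall in
#' the same clusters: Fv complexes must share both the VH and the VL cluster;
#' single-domain complexes share their one domain's cluster. Fv and
#' single-domain complexes are never in the same family, and Fv pairs sharing
#' only one chain's cluster are both kept. One representative survives per
#' family: best (numerically lowest) resolution, then lowest mean B-factor,
#' then lexicographically smallest structure identifier.
#'
#' @param complexes List of `abag_complex` objects (one per structure).
#' @param vh_clusters,vl_clusters Cluster assignments from
#'   [cluster_sequences()], named by structure identifier. Either may be
#'   `NULL` when no complex carries that domain.
#' @return List with `complexes` (survivors, input order) and `log`
#'   (data frame: `structure_id`, `family`, `kept`).
#' @export
remove_redundant <- function(complexes, vh_clusters = NULL,
                             vl_clusters = NULL) {
  ids <- vapply(complexes, `[[`, "", "structure_id")
  fam <- vapply(seq_along(complexes), function(i) {
    res <- unique_residues(complexes[[i]], role = "antibody")
    doms <- sort(unique(stats::na.omit(res$domain)))
    parts <- vapply(doms, function(d) {
      cl <- if (d == "VH") vh_clusters else vl_clusters
      if (is.null(cl) || !ids[i] %in% names(cl)) {
        stop("no ", d, " cluster assignment for ", ids[i])
      }
      paste0(d, cl[[ids[i]]])
    }, character(1))
    paste(parts, collapse = "|")
  }, character(1))

  resol <- vapply(complexes, function(cx) cx$annotation$resolution, numeric(1))
  meanb <- vapply(complexes, function(cx) mean_bfactor(cx)$mean_b, numeric(1))
  keep <- logical(length(complexes))
  for (f in unique(fam)) {
    members <- which(fam == f)
    best <- members[order(resol[members], meanb[members], ids[members])[1]]
    keep[best] <- TRUE
  }
  list(complexes = complexes[keep],
       log = data.frame(structure_id = ids, family = fam, kept = keep,
                        stringsAsFactors = FALSE))
}

#' Export variable-domain sequences as FASTA
#'
#' One record per structure/domain with header `structureID_domain`, for use
#' with an external clustering tool.
#'
#' @param seqs Named character vector as accepted by [cluster_sequences()];
#'   names should already be `structureID_domain` or plain structure IDs.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_variable_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(c(paste0(">", names(seqs)[i]), seqs[[i]]), con)
  }
  invisible(path)
}

#' Read a CD-HIT .clstr cluster file
#'
#' Adapter for the output of an external CD-HIT run, so its clusters can be
#' used in place of [cluster_sequences()].
#'
#' @param path Path to a `.clstr` file.
#' @return Named integer vector mapping sequence names to 1-based cluster
#'   indices.
#' @export
read_cdhit_clusters <- function(path) {
  lines <- readLines(path)
  cl <- cumsum(grepl("^>Cluster", lines))
  member <- !grepl("^>Cluster", lines)
  nm <- sub("^.*>([^.]+)\\.{3}.*$", "\\1", lines[member])
  stats::setNames(cl[member], nm)
}
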