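# Frequency, co-occurrence, segmentation, variability and uncertainty
# statistics over grouped interface data. All frequencies are computed on
# unique residues (uPR/uER), never on raw contacts, to avoid bias towards
# multi-contact residues; group averages take per-complex percentages first
# and then the unweighted mean over complexes. The one exception is the
# co-occurrence matrix, which by design pools total atom-atom contacts.

#' Amino-acid frequencies over a unique-residue set
#'
#' @param residues Character vector of 3-letter codes, one entry per unique
#'   residue (uPRs or uERs) of one complex or one domain.
#' @return Named numeric vector over the 20 standard amino acids, in percent,
#'   summing to 100.
#' @export
aa_frequencies <- function(residues) {
  if (length(residues) == 0) stop("no residues in scope")
  residues <- toupper(residues)
  bad <- !residues %in% standard_aa()
  if (any(bad)) stop("nonstandard residue code(s): ",
                     paste(unique(residues[bad]), collapse = ", "))
  tab <- table(factor(residues, levels = standard_aa()))
  stats::setNames(100 * as.vector(tab) / length(residues), standard_aa())
}

#' Physicochemical class frequencies
#'
#' Collapses a 20-amino-acid frequency vector into the five classes
#' nonpolar (ALA, VAL, PRO, LEU, ILE, TRP, PHE), polar (SER, THR, TYR, ASN,
#' GLN), positively charged (LYS, HIS, ARG), negatively charged (GLU, ASP)
#' and special (GLY, CYS, MET).
#'
#' @param freq Named frequency vector from [aa_frequencies()].
#' @return Named numeric vector over the five classes, summing to the same
#'   total (100 for a valid frequency vector).
#' @export
class_frequencies <- function(freq) {
  stopifnot(all(standard_aa() %in% names(freq)))
  vapply(.AA_CLASSES, function(members) sum(freq[members]), numeric(1))
}

#' Percentile bootstrap confidence interval for a group mean
#'
#' Resamples the per-complex values with replacement `n_boot` times and takes
#' the central `level` percentile interval of the resampled means.
#' Deterministic for a fixed seed; the calling RNG state is left untouched.
#'
#' @param values Numeric vector of per-complex values (length >= 2 for a
#'   nondegenerate interval; a single value yields a degenerate one with a
#'   warning).
#' @param n_boot Number of bootstrap resamples (default 5000).
#' @param level Coverage level (default 0.95).
#' @param seed RNG seed (default 20230131).
#' @return A `bootstrap_ci` list: `point` (sample mean), `lo`, `hi`, `n`,
#'   `n_boot`, `level`, `seed`.
#' @export
group_mean_ci <- function(values, n_boot = 5000, level = 0.95,
                          seed = 20230131) {
  if (length(values) == 0) stop("no values to bootstrap")
  if (length(values) == 1) warning("single value: degenerate interval")
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- length(values)
  means <- rowMeans(matrix(sample(values, n * n_boot, replace = TRUE),
                           nrow = n_boot))
  alpha <- (1 - level) / 2
  q <- stats::quantile(means, c(alpha, 1 - alpha), names = FALSE)
  structure(list(point = mean(values), lo = q[1], hi = q[2], n = n,
                 n_boot = n_boot, level = level, seed = seed),
            class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("mean %.4g, %g%% CI [%.4g, %.4g] (n = %d, n_boot = %d)\n",
              x$point, 100 * x$level, x$lo, x$hi, x$n, x$n_boot))
  invisible(x)
}

#' Paratope-epitope amino-acid co-occurrence matrix
#'
#' Counts total atom-atom contacts (not unique residues) between each
#' paratope amino acid (rows) and epitope amino acid (columns), pooled over
#' the supplied contacts, then normalizes each row to percent so populated
#' rows sum to 100. Rows without contacts stay all-zero and are listed in the
#' `empty_rows` attribute, keeping the 20 x 20 shape stable.
#'
#' @param contacts Pooled contact table (rows from one or many complexes).
#' @return 20 x 20 numeric matrix, rows = paratope amino acid, columns =
#'   epitope amino acid, with attribute `empty_rows`.
#' @export
cooccurrence_matrix <- function(contacts) {
  if (nrow(contacts) == 0) stop("no contacts to tabulate")
  counts <- table(factor(contacts$ab_aa, levels = standard_aa()),
                  factor(contacts$ag_aa, levels = standard_aa()))
  counts <- matrix(as.numeric(counts), 20, 20,
                   dimnames = list(paratope = standard_aa(),
                                   epitope = standard_aa()))
  rs <- rowSums(counts)
  out <- counts
  out[rs > 0, ] <- 100 * counts[rs > 0, , drop = FALSE] / rs[rs > 0]
  attr(out, "empty_rows") <- standard_aa()[rs == 0]
  out
}

#' Count discontinuous epitope segments
#'
#' Within each antigen chain, the unique epitope residue numbers are grouped
#' into maximal runs of consecutive numbers; two runs separated by one or
#' more non-epitope residues are distinct segments. Insertion-coded residues
#' share their base number and so never break a run. The total is summed over
#' chains.
#'
#' @param contacts Contact table of one complex.
#' @return Integer segment count.
#' @export
epitope_segments <- function(contacts) {
  if (nrow(contacts) == 0) stop("no epitope residues")
  per_chain <- split(contacts$ag_resno, contacts$ag_chain)
  sum(vapply(per_chain, function(r) {
    r <- sort(unique(r))
    1L + sum(diff(r) > 1)
  }, integer(1)))
}

#' Group table of unique paratope residues with IMGT positions
#'
#' Convenience builder joining per-complex contact tables into one table of
#' uPRs, keyed by structure, domain and IMGT position, as consumed by
#' [position_aa_frequencies()] and [germline_mutation_fraction()].
#'
#' @param contacts_list List of per-complex contact tables.
#' @param structure_ids Character vector of structure identifiers, parallel
#'   to `contacts_list`.
#' @param scheme A [region_scheme()].
#' @return Data frame `structure_id`, `domain`, `position`, `resno`, `aa`.
#' @export
group_upr_table <- function(contacts_list, structure_ids,
                            scheme = region_scheme()) {
  stopifnot(length(contacts_list) == length(structure_ids))
  do.call(rbind, lapply(seq_along(contacts_list), function(i) {
    u <- .upr_table(contacts_list[[i]], scheme)
    if (nrow(u) == 0) return(NULL)
    data.frame(structure_id = structure_ids[i], domain = u$ab_domain,
               position = u$position, resno = u$ab_resno, aa = u$ab_aa,
               stringsAsFactors = FALSE)
  }))
}

#' Position-specific amino-acid frequencies of uPRs
#'
#' For each (domain, IMGT position), the distribution of amino acids across
#' the complexes in which that position is a uPR. Positions that are never a
#' uPR are absent from the output; every emitted distribution sums to 100.
#'
#' @param group_upr Table from [group_upr_table()].
#' @return Data frame `domain`, `position`, `resno`, `aa`, `pct`, `n_complex`.
#' @export
position_aa_frequencies <- function(group_upr) {
  stopifnot(nrow(group_upr) >= 1)
  key <- paste(group_upr$domain, group_upr$position, sep = "\r")
  out <- do.call(rbind, lapply(split(group_upr, key), function(g) {
    tab <- table(g$aa)
    data.frame(domain = g$domain[1], position = g$position[1],
               resno = g$resno[1], aa = names(tab),
               pct = 100 * as.integer(tab) / nrow(g),
               n_complex = nrow(g), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$domain, out$resno, out$position, out$aa), ]
  rownames(out) <- NULL
  out
}

#' Wu-Kabat variability of one alignment column
#'
#' Variability = N * k / n_mode, where N is the number of sequences with a
#' residue at the position, k the number of distinct amino acids observed and
#' n_mode the count of the most frequent one. The minimum of 1 is attained
#' exactly on fully conserved columns; gaps/absent positions are excluded
#' from N by the caller.
#'
#' @param column Character vector of amino acids observed at one position.
#' @return List `N`, `k`, `n_mode`, `variability`.
#' @export
wu_kabat <- function(column) {
  if (length(column) == 0) stop("empty column")
  tab <- table(column)
  list(N = length(column), k = length(tab), n_mode = max(tab),
       variability = length(column) * length(tab) / max(tab))
}

#' Fraction of paratope residues mutated from the germline
#'
#' Per (domain, position): the percentage of complexes in which the uPR amino
#' acid differs from the externally supplied germline assignment, among
#' complexes where the position is a uPR and a germline residue is defined.
#' Positions without germline coverage are excluded. A pooled aggregate over
#' all covered uPR observations is attached as the `pooled_pct` attribute.
#'
#' @param group_upr Table from [group_upr_table()].
#' @param germline Data frame `structure_id`, `domain`, `position`, `aa`
#'   giving the germline amino acid per complex and IMGT position (1- or
#'   3-letter codes).
#' @return Data frame `domain`, `position`, `resno`, `n`, `n_mutated`, `pct`;
#'   empty with a warning when uPRs and germline assignments do not overlap.
#' @export
germline_mutation_fraction <- function(group_upr, germline) {
  need <- c("structure_id", "domain", "position", "aa")
  stopifnot(all(need %in% names(germline)))
  norm_aa <- function(x) ifelse(nchar(x) == 1, .AA_1TO3[toupper(x)], toupper(x))
  g <- germline
  g$aa <- norm_aa(g$aa)
  key <- function(d) paste(d$structure_id, d$domain, d$position, sep = "\r")
  idx <- match(key(group_upr), key(g))
  covered <- !is.na(idx)
  if (!any(covered)) {
    warning("no overlap between uPRs and germline assignments")
    return(data.frame(domain = character(0), position = character(0),
                      resno = integer(0), n = integer(0),
                      n_mutated = integer(0), pct = numeric(0)))
  }
  u <- group_upr[covered, , drop = FALSE]
  u$mutated <- norm_aa(u$aa) != g$aa[idx[covered]]
  pk <- paste(u$domain, u$position, sep = "\r")
  out <- do.call(rbind, lapply(split(u, pk), function(d) {
    data.frame(domain = d$domain[1], position = d$position[1],
               resno = d$resno[1], n = nrow(d), n_mutated = sum(d$mutated),
               pct = 100 * sum(d$mutated) / nrow(d), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$domain, out$resno, out$position), ]
  rownames(out) <- NULL
  attr(out, "pooled_pct") <- 100 * sum(u$mutated) / nrow(u)
  out
}

#' Secondary-structure class frequencies of the epitope
#'
#' Collapses per-residue DSSP codes to the three classes and tabulates their
#' shares over the unique epitope residues of one complex. Residues without
#' an assigned code fall back to loop (with a dataset-level warning upstream).
#'
#' @param contacts Contact table of one complex.
#' @param ss Data frame `chain`, `resno`, `insert`, `code` (e.g. from
#'   [read_dssp()]), or `NULL` for the all-loop fallback.
#' @return Named numeric vector `c(helix =, strand =, loop =)` in percent,
#'   summing to 100.
#' @export
epitope_ss_frequencies <- function(contacts, ss = NULL) {
  key <- .res_key(contacts$ag_chain, contacts$ag_resno, contacts$ag_insert)
  u <- contacts[!duplicated(key), , drop = FALSE]
  if (nrow(u) == 0) stop("no epitope residues")
  codes <- rep(" ", nrow(u))
  if (!is.null(ss)) {
    idx <- match(.res_key(u$ag_chain, u$ag_resno, u$ag_insert),
                 .res_key(ss$chain, ss$resno, ss$insert))
    codes[!is.na(idx)] <- ss$code[idx[!is.na(idx)]]
  }
  cls <- collapse_ss(codes)
  tab <- table(factor(cls, levels = c("helix", "strand", "loop")))
  stats::setNames(100 * as.vector(tab) / nrow(u), c("helix", "strand", "loop"))
}
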