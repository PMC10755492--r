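# IMGT region scheme, per-region paratope statistics, hotspot maps and
# secondary-structure class collapse.

#' Construct an IMGT region scheme
#'
#' Default CDR boundaries follow the IMGT definition (CDR1 27-38, CDR2 56-65,
#' CDR3 105-117, variable domain ending at ID 128); framework regions FR1-FR4
#' are derived as the complement. An alternative scheme (e.g. CDR2 expanded
#' to 55-66) is built by passing different ranges.
#'
#' @param cdr1,cdr2,cdr3 Integer vectors `c(start, end)`, inclusive.
#' @param vr_max Last variable-domain residue identifier (default 128).
#' @return A `region_scheme` list with elements `cdr1`, `cdr2`, `cdr3`,
#'   `vr_max` and derived `fr1`-`fr4`.
#' @export
region_scheme <- function(cdr1 = c(27, 38), cdr2 = c(56, 65),
                          cdr3 = c(105, 117), vr_max = 128) {
  r <- rbind(cdr1, cdr2, cdr3)
  stopifnot(ncol(r) == 2, all(r[, 1] <= r[, 2]), all(r >= 1), all(r <= vr_max))
  if (any(r[-1, 1] <= r[-3, 2])) stop("CDR ranges must be ascending and disjoint")
  if (cdr1[1] < 2 || cdr3[2] >= vr_max) {
    stop("CDR ranges must leave room for the framework regions")
  }
  structure(list(
    cdr1 = cdr1, cdr2 = cdr2, cdr3 = cdr3, vr_max = vr_max,
    fr1 = c(1, cdr1[1] - 1),
    fr2 = c(cdr1[2] + 1, cdr2[1] - 1),
    fr3 = c(cdr2[2] + 1, cdr3[1] - 1),
    fr4 = c(cdr3[2] + 1, vr_max)), class = "region_scheme")
}

.REGION_LEVELS <- c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4")

#' Assign IMGT positions to antibody regions
#'
#' The region is determined by the numeric part of the identifier alone;
#' insertion codes are ignored for membership (111A lies in CDR3).
#'
#' @param imgt_id Integer vector of numeric IMGT identifiers.
#' @param scheme A [region_scheme()].
#' @return Factor with levels FR1, CDR1, FR2, CDR2, FR3, CDR3, FR4.
#' @export
assign_region <- function(imgt_id, scheme = region_scheme()) {
  if (any(imgt_id < 1 | imgt_id > scheme$vr_max)) {
    stop("IMGT identifier outside the variable domain [1, ", scheme$vr_max, "]")
  }
  breaks <- c(0, scheme$cdr1[1] - 1, scheme$cdr1[2], scheme$cdr2[1] - 1,
              scheme$cdr2[2], scheme$cdr3[1] - 1, scheme$cdr3[2],
              scheme$vr_max)
  cut(imgt_id, breaks = breaks, labels = .REGION_LEVELS)
}

# Unique paratope residues of one contact table, with region labels.
# Residues outside the variable domain (ID > vr_max) are dropped with a
# warning since they have no region.
.upr_table <- function(contacts, scheme = region_scheme()) {
  key <- .res_key(contacts$ab_chain, contacts$ab_resno, contacts$ab_insert)
  u <- contacts[!duplicated(key), c("ab_chain", "ab_resno", "ab_insert",
                                    "ab_aa", "ab_domain"), drop = FALSE]
  over <- u$ab_resno > scheme$vr_max
  if (any(over)) {
    warning(sum(over), " paratope residue(s) outside the variable domain dropped")
    u <- u[!over, , drop = FALSE]
  }
  u$region <- assign_region(u$ab_resno, scheme)
  u$position <- .pos_key(u$ab_resno, u$ab_insert)
  rownames(u) <- NULL
  u
}

#' Per-complex uPR counts by antibody region
#'
#' @param contacts Contact table of one complex from [find_contacts()].
#' @param scheme A [region_scheme()].
#' @return Data frame `domain`, `region`, `n_upr` (all 7 regions per domain
#'   present in the contacts, zeros included).
#' @export
upr_region_counts <- function(contacts, scheme = region_scheme()) {
  u <- .upr_table(contacts, scheme)
  doms <- sort(unique(stats::na.omit(u$ab_domain)))
  out <- do.call(rbind, lapply(doms, function(d) {
    tab <- table(u$region[u$ab_domain == d])
    data.frame(domain = d, region = .REGION_LEVELS,
               n_upr = as.integer(tab[.REGION_LEVELS]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(domain = character(0), region = character(0),
                      n_upr = integer(0), stringsAsFactors = FALSE)
  }
  out
}

#' Group distribution of uPRs across antibody regions
#'
#' Per complex, each (domain, region)'s share of that complex's total uPRs is
#' computed first; the group value is the unweighted mean of those per-complex
#' proportions. Complexes with zero uPRs are excluded with a warning.
#'
#' @param counts_list List of per-complex tables from [upr_region_counts()].
#' @return List with `mean_pct` (data frame `domain`, `region`, `mean_pct`)
#'   and `per_complex` (long data frame with per-complex counts and
#'   percentages; column `complex` indexes the input list).
#' @export
region_distribution <- function(counts_list) {
  stopifnot(length(counts_list) >= 1)
  totals <- vapply(counts_list, function(x) sum(x$n_upr), numeric(1))
  if (any(totals == 0)) {
    warning(sum(totals == 0), " complex(es) with zero uPRs excluded")
    counts_list <- counts_list[totals > 0]
    if (length(counts_list) == 0) stop("no complex with uPRs")
  }
  per <- do.call(rbind, lapply(seq_along(counts_list), function(i) {
    x <- counts_list[[i]]
    x$complex <- i
    x$pct <- 100 * x$n_upr / sum(x$n_upr)
    x
  }))
  agg <- stats::aggregate(pct ~ domain + region, data = per, FUN = mean)
  names(agg)[names(agg) == "pct"] <- "mean_pct"
  agg <- agg[order(agg$domain, match(agg$region, .REGION_LEVELS)), ]
  rownames(agg) <- NULL
  list(mean_pct = agg, per_complex = per)
}

#' Fractions of variable-region, CDR and FR residues in the paratope
#'
#' Relates the paratope to the residues the antibody actually has: the VR
#' fraction is the number of uPRs over the number of variable-domain residues
#' present in the structure, and analogously for residues inside and outside
#' the CDR boundaries.
#'
#' @param complex An `abag_complex`.
#' @param contacts Its contact table from [find_contacts()].
#' @param scheme A [region_scheme()].
#' @return Named numeric vector `c(vr =, cdr =, fr =)` of fractions in
#'   `[0, 1]`; entries with a zero denominator are `NA` with a warning.
#' @export
paratope_proportions <- function(complex, contacts, scheme = region_scheme()) {
  res <- unique_residues(complex, role = "antibody")
  res <- res[res$resno <= scheme$vr_max, , drop = FALSE]
  reg <- assign_region(res$resno, scheme)
  in_cdr <- grepl("^CDR", reg)
  u <- .upr_table(contacts, scheme)
  upr_cdr <- grepl("^CDR", u$region)
  denom <- c(vr = nrow(res), cdr = sum(in_cdr), fr = sum(!in_cdr))
  num <- c(vr = nrow(u), cdr = sum(upr_cdr), fr = sum(!upr_cdr))
  if (any(denom == 0)) warning("zero-denominator proportion(s) returned as NA")
  out <- ifelse(denom > 0, num / denom, NA_real_)
  stats::setNames(out, names(denom))
}

#' Map paratope hotspots across a group of complexes
#'
#' For every (domain, IMGT position incl. insertion code) the background
#' occurrence (percent of complexes whose antibody has that position) and the
#' conditional uPR frequency (percent of position-carrying complexes where it
#' is a uPR) are tabulated. Positions present in fewer than `min_occurrence`
#' of the complexes are omitted (inclusive comparison), which naturally hides
#' rare CDR insertions.
#'
#' @param complexes List of `abag_complex` objects.
#' @param contacts_list Parallel list of contact tables.
#' @param scheme A [region_scheme()].
#' @param min_occurrence Minimum background occurrence fraction (default 0.10).
#' @return Data frame `domain`, `position`, `resno`, `region`, `n_present`,
#'   `n_contact`, `background_pct`, `conditional_pct`, sorted by domain and
#'   numeric position.
#' @export
hotspot_map <- function(complexes, contacts_list, scheme = region_scheme(),
                        min_occurrence = 0.10) {
  stopifnot(length(complexes) == length(contacts_list), length(complexes) >= 1)
  n_group <- length(complexes)
  present <- list(); contact <- list()
  for (i in seq_len(n_group)) {
    res <- unique_residues(complexes[[i]], role = "antibody")
    res <- res[res$resno <= scheme$vr_max, , drop = FALSE]
    pk <- unique(paste0(res$domain, "\r", .pos_key(res$resno, res$insert),
                        "\r", res$resno))
    present[[i]] <- pk
    u <- .upr_table(contacts_list[[i]], scheme)
    contact[[i]] <- unique(paste0(u$ab_domain, "\r", u$position, "\r",
                                  u$ab_resno))
  }
  n_present <- table(unlist(present))
  n_contact <- table(unlist(contact))
  keys <- names(n_present)
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  out <- data.frame(
    domain = parts[, 1], position = parts[, 2],
    resno = as.integer(parts[, 3]),
    n_present = as.integer(n_present),
    n_contact = as.integer(ifelse(keys %in% names(n_contact),
                                  n_contact[keys], 0L)),
    stringsAsFactors = FALSE)
  out$region <- as.character(assign_region(out$resno, scheme))
  out$background_pct <- 100 * out$n_present / n_group
  out$conditional_pct <- 100 * out$n_contact / out$n_present
  out <- out[out$n_present / n_group >= min_occurrence, , drop = FALSE]
  out <- out[order(out$domain, out$resno, out$position),
             c("domain", "position", "resno", "region", "n_present",
               "n_contact", "background_pct", "conditional_pct")]
  rownames(out) <- NULL
  out
}

#' Percentage of uPRs captured inside the CDR boundaries
#'
#' Pooled over a group: 100 x (uPRs whose region is CDR1/2/3) / (all uPRs),
#' evaluable under any [region_scheme()] so the effect of widening a CDR
#' definition (e.g. CDR2 56-65 vs 55-66) can be quantified.
#'
#' @param contacts_list List of contact tables (one per complex).
#' @param scheme A [region_scheme()].
#' @return Percentage in `[0, 100]`.
#' @export
cdr_capture_fraction <- function(contacts_list, scheme = region_scheme()) {
  u <- do.call(rbind, lapply(contacts_list, .upr_table, scheme = scheme))
  if (is.null(u) || nrow(u) == 0) stop("no uPRs in the group")
  100 * sum(grepl("^CDR", u$region)) / nrow(u)
}

#' Collapse DSSP 8-state codes to three classes
#'
#' H (alpha helix), G (3-10 helix) and I (pi helix) collapse to helix; E
#' (strand) and B (isolated beta bridge) to strand; T (turn), S (bend) and
#' blank/unassigned to loop. The newer polyproline-II code P also maps to
#' loop. Unknown codes map to loop with a warning.
#'
#' @param code Character vector of DSSP codes.
#' @return Character vector over `{"helix", "strand", "loop"}`.
#' @export
collapse_ss <- function(code) {
  code <- toupper(ifelse(is.na(code) | code == "", " ", code))
  known <- c(H = "helix", G = "helix", I = "helix", E = "strand",
             B = "strand", T = "loop", S = "loop", " " = "loop",
             "-" = "loop", P = "loop")
  unknown <- !code %in% names(known)
  if (any(unknown)) {
    warning("unknown DSSP code(s) treated as loop: ",
            paste(unique(code[unknown]), collapse = ", "))
  }
  out <- unname(known[code])
  out[unknown] <- "loop"
  out
}

#' CDR3 loop length of a chain
#'
#' Counts residues (insertion codes included) whose numeric identifier lies
#' in the scheme's CDR3 range.
#'
#' @param complex An `abag_complex`.
#' @param domain `"VH"` or `"VL"`.
#' @param scheme A [region_scheme()].
#' @return Integer residue count (0 when the loop is absent).
#' @export
cdr3_length <- function(complex, domain, scheme = region_scheme()) {
  res <- unique_residues(complex, role = "antibody")
  res <- res[!is.na(res$domain) & res$domain == domain, , drop = FALSE]
  sum(res$resno >= scheme$cdr3[1] & res$resno <= scheme$cdr3[2])
}

#' Read per-residue secondary-structure codes
#'
#' `read_dssp()` parses the classic fixed-column DSSP output; `read_ss_table()`
#' reads a simple two-column table (`chain:resid`, `code`), whitespace- or
#' tab-separated, `resid` being the residue number with optional insertion
#' code.
#'
#' @param path Input file path.
#' @return Data frame `chain`, `resno`, `insert`, `code`.
#' @export
read_dssp <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0) stop("not a DSSP file: no residue table header")
  body <- lines[(hdr[1] + 1):length(lines)]
  body <- body[nchar(body) >= 17]
  resno <- suppressWarnings(as.integer(substr(body, 6, 10)))
  keep <- !is.na(resno)  # chain breaks have blank residue fields
  body <- body[keep]
  data.frame(
    chain = trimws(substr(body, 12, 12)),
    resno = resno[keep],
    insert = trimws(substr(body, 11, 11)),
    code = substr(body, 17, 17),
    stringsAsFactors = FALSE)
}

#' @rdname read_dssp
#' @export
read_ss_table <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("key", "code"),
                           colClasses = "character")
  parts <- strsplit(tab$key, ":", fixed = TRUE)
  if (any(lengths(parts) != 2)) stop("expected 'chain:resid' keys")
  chain <- vapply(parts, `[`, "", 1)
  rid <- vapply(parts, `[`, "", 2)
  data.frame(
    chain = chain,
    resno = as.integer(sub("([0-9]+).*", "\\1", rid)),
    insert = sub("^[0-9]+", "", rid),
    code = tab$code, stringsAsFactors = FALSE)
}
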