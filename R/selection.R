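# Elimination of crystal-packing duplicates: when one structure file holds
# several co-crystallized antibody-antigen units, only the best-ordered copy
# (lowest mean B-factor) is analyzed, so the same interface is never counted
# twice.

#' Mean B-factor of a complex
#'
#' Arithmetic mean of the atomic displacement (B-factor) over all non-hydrogen
#' amino-acid atoms of the unit's antibody and antigen chains. Hydrogens are
#' excluded by default, consistent with contact eligibility; set
#' `include_hydrogens = TRUE` to average over every amino-acid atom.
#'
#' @param complex An `abag_complex`.
#' @param include_hydrogens Include hydrogen/deuterium atoms in the mean.
#' @return List with `unit_index`, `mean_b` and `n_atoms`.
#' @export
mean_bfactor <- function(complex, include_hydrogens = FALSE) {
  a <- complex$atoms
  if (!include_hydrogens) a <- a[a$eligible, , drop = FALSE]
  if (nrow(a) == 0) stop("no eligible atoms to average B-factor over")
  list(unit_index = complex$unit_index,
       mean_b = mean(a$b),
       n_atoms = nrow(a))
}

#' Select the biological unit with the lowest mean B-factor
#'
#' @param units List of `abag_complex` objects from one structure file.
#' @param include_hydrogens Passed to [mean_bfactor()].
#' @return The selected `abag_complex`, with attribute `selection_log`:
#'   a data frame of `unit_index`, `mean_b` and `selected`. Ties in mean
#'   B-factor are broken by the lowest unit index.
#' @export
select_unit <- function(units, include_hydrogens = FALSE) {
  if (length(units) == 0) stop("no units to select from")
  scores <- vapply(units, function(u) {
    mean_bfactor(u, include_hydrogens = include_hydrogens)$mean_b
  }, numeric(1))
  idx <- vapply(units, `[[`, 1L, "unit_index")
  best <- order(scores, idx)[1]
  out <- units[[best]]
  attr(out, "selection_log") <- data.frame(
    unit_index = idx, mean_b = scores,
    selected = seq_along(units) == best)
  out
}
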