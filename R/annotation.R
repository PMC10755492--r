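# Chain-annotation summary table (SAbDab-style TSV).

#' Load a chain-annotation summary table
#'
#' Reads a tab-separated summary file in the style of the SAbDab metadata
#' export, with columns `pdb`, `Hchain`, `Lchain`, `antigen_chain`,
#' `antigen_type` and `resolution`. One row describes one antibody within one
#' structure file, i.e. one candidate biological unit.
#'
#' Rows are validated: an antibody must have at least one of a heavy or light
#' chain; rows where the heavy and light chain carry the same chain label
#' (e.g. some single-chain constructs) are rejected because heavy and light
#' residues cannot be told apart; rows with an unparseable resolution are
#' skipped with a warning. Antigen chain labels may be separated by `|`, `;`
#' or `,`.
#'
#' @param path Path to the tab-separated annotation file.
#' @return A data frame of class `abag_annotation` with columns
#'   `structure_id`, `heavy_chain`, `light_chain` (`NA` when absent),
#'   `antigen_chains` (labels joined by `;`), `antigen_type` and `resolution`,
#'   one row per accepted annotation. Skipped rows are attached as the
#'   `skipped` attribute (data frame with a `reason` column).
#' @export
load_annotation_summary <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  required <- c("pdb", "Hchain", "Lchain", "antigen_chain", "antigen_type",
                "resolution")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("annotation summary is missing required column(s): ",
         paste(missing, collapse = ", "))
  }

  norm <- function(x) {
    x <- trimws(x)
    x[x %in% c("", "NA", "NaN", "None", "nan")] <- NA_character_
    x
  }
  h <- norm(raw$Hchain)
  l <- norm(raw$Lchain)
  ag <- norm(raw$antigen_chain)
  ag <- vapply(strsplit(ifelse(is.na(ag), "", ag), "[|;,]"), function(p) {
    paste(trimws(p[nzchar(trimws(p))]), collapse = ";")
  }, character(1))
  res <- suppressWarnings(as.numeric(norm(raw$resolution)))

  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(h) & is.na(l)] <- "no antibody chain"
  reason[!is.na(h) & !is.na(l) & h == l] <- "heavy and light chain share one chain ID"
  reason[is.na(reason) & (is.na(res) | res <= 0)] <- "unparseable resolution"
  reason[is.na(reason) & !nzchar(ag)] <- "no antigen chain"

  ok <- is.na(reason)
  if (any(reason %in% "unparseable resolution")) {
    warning(sum(reason %in% "unparseable resolution"),
            " row(s) skipped: unparseable resolution")
  }

  ann <- data.frame(
    structure_id = toupper(norm(raw$pdb))[ok],
    heavy_chain = h[ok],
    light_chain = l[ok],
    antigen_chains = ag[ok],
    antigen_type = tolower(norm(raw$antigen_type))[ok],
    resolution = res[ok],
    stringsAsFactors = FALSE)

  # antibody labels must not double as antigen labels
  agl <- strsplit(ann$antigen_chains, ";")
  clash <- mapply(function(hc, lc, a) any(stats::na.omit(c(hc, lc)) %in% a),
                  ann$heavy_chain, ann$light_chain, agl)
  if (any(clash)) {
    skipped_clash <- ann[clash, , drop = FALSE]
    ann <- ann[!clash, , drop = FALSE]
  } else {
    skipped_clash <- ann[0, , drop = FALSE]
  }

  skipped <- data.frame(
    structure_id = toupper(norm(raw$pdb))[!ok],
    reason = reason[!ok], stringsAsFactors = FALSE)
  if (nrow(skipped_clash) > 0) {
    skipped <- rbind(skipped, data.frame(
      structure_id = skipped_clash$structure_id,
      reason = "antibody chain label also annotated as antigen",
      stringsAsFactors = FALSE))
  }

  rownames(ann) <- NULL
  attr(ann, "skipped") <- skipped
  class(ann) <- c("abag_annotation", class(ann))
  ann
}

#' Write an annotation table back to the summary TSV layout
#'
#' Inverse of [load_annotation_summary()]: writes the tab-separated layout
#' with columns `pdb`, `Hchain`, `Lchain`, `antigen_chain`, `antigen_type`,
#' `resolution` (antigen chains joined by ` | `).
#'
#' @param annotation An `abag_annotation` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_summary <- function(annotation, path) {
  out <- data.frame(
    pdb = annotation$structure_id,
    Hchain = ifelse(is.na(annotation$heavy_chain), "NA",
                    annotation$heavy_chain),
    Lchain = ifelse(is.na(annotation$light_chain), "NA",
                    annotation$light_chain),
    antigen_chain = gsub(";", " | ", annotation$antigen_chains, fixed = TRUE),
    antigen_type = annotation$antigen_type,
    resolution = annotation$resolution,
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Antigen chain labels of one annotation row, as a character vector.
.antigen_chain_ids <- function(annotation_row) {
  strsplit(annotation_row$antigen_chains, ";")[[1]]
}

# Antibody chain labels (named by domain) of one annotation row.
.antibody_chain_ids <- function(annotation_row) {
  out <- c(VH = annotation_row$heavy_chain, VL = annotation_row$light_chain)
  out[!is.na(out)]
}
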