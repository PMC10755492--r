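# End-to-end orchestration: annotation + structures in, statistics tables out.

#' Configure an interface-mapping pipeline run
#'
#' @param summary Path to the tab-separated chain-annotation summary.
#' @param pdb_dir Directory of PDB files named `<structure_id>.pdb`
#'   (identifier case-insensitive).
#' @param out_dir Output directory (created if needed).
#' @param cutoff Contact cutoff(s) in Angstrom; a vector runs a sweep with
#'   one report set per cutoff in subdirectories `cutoff_<c>`.
#' @param max_resolution Resolution filter in Angstrom (default 3.0).
#' @param exclusion_list Structure identifiers to drop.
#' @param identity Redundancy clustering identity threshold (default 0.95).
#' @param scheme A [region_scheme()].
#' @param min_occurrence Hotspot background-occurrence filter (default 0.10).
#' @param n_boot,ci_level,seed Bootstrap settings for group means.
#' @param with_waters Also count interfacial waters (reported separately).
#' @param bfactor_include_hydrogens Include hydrogens in unit-selection means.
#' @param ss Optional per-residue secondary-structure codes (data frame from
#'   [read_dssp()]/[read_ss_table()]); when absent every epitope residue is
#'   treated as loop and a dataset-level warning is recorded.
#' @param germline Optional germline assignment table (see
#'   [germline_mutation_fraction()]).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(summary, pdb_dir, out_dir,
                            cutoff = 5.0, max_resolution = 3.0,
                            exclusion_list = character(), identity = 0.95,
                            scheme = region_scheme(), min_occurrence = 0.10,
                            n_boot = 5000, ci_level = 0.95, seed = 20230131,
                            with_waters = FALSE,
                            bfactor_include_hydrogens = FALSE,
                            ss = NULL, germline = NULL) {
  stopifnot(all(cutoff > 0), max_resolution > 0,
            identity > 0, identity <= 1,
            min_occurrence >= 0, min_occurrence <= 1,
            n_boot >= 1, ci_level > 0, ci_level < 1)
  structure(list(
    summary = summary, pdb_dir = pdb_dir, out_dir = out_dir,
    cutoff = cutoff, max_resolution = max_resolution,
    exclusion_list = exclusion_list, identity = identity, scheme = scheme,
    min_occurrence = min_occurrence, n_boot = n_boot, ci_level = ci_level,
    seed = seed, with_waters = with_waters,
    bfactor_include_hydrogens = bfactor_include_hydrogens,
    ss = ss, germline = germline), class = "pipeline_config")
}

#' Read a flat key=value pipeline configuration file
#'
#' Each line is `key = value`; keys mirror the [pipeline_config()] arguments
#' (comma-separated lists for `cutoff` and `exclusion_list`). Arguments given
#' directly to this function override the file.
#'
#' @param path Config file path.
#' @param ... Overrides passed on to [pipeline_config()].
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path, ...) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- regmatches(lines, regexec("^\\s*([a-z_]+)\\s*=\\s*(.*?)\\s*$", lines))
  args <- stats::setNames(lapply(kv, `[`, 3), vapply(kv, `[`, "", 2))
  num <- c("max_resolution", "identity", "min_occurrence", "n_boot",
           "ci_level", "seed")
  lgl <- c("with_waters", "bfactor_include_hydrogens")
  for (k in names(args)) {
    if (k %in% num) args[[k]] <- as.numeric(args[[k]])
    if (k %in% lgl) args[[k]] <- toupper(args[[k]]) %in% c("TRUE", "1", "YES")
    if (k == "cutoff") args[[k]] <- as.numeric(strsplit(args[[k]], ",")[[1]])
    if (k == "exclusion_list") args[[k]] <- strsplit(args[[k]], ",")[[1]]
  }
  over <- list(...)
  args[names(over)] <- over
  do.call(pipeline_config, args)
}

#' Run the interface-mapping pipeline
#'
#' Executes resolution/exclusion filtering, packing-unit selection,
#' redundancy removal, contact extraction, region annotation and group
#' statistics, and writes one report set of CSV tables plus a JSON run
#' summary per cutoff. Every input unit is accounted for exactly once:
#' retained, or logged with one exclusion reason.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `status` (`"ok"` or `"empty"`), the
#'   retained `complexes`, per-cutoff `reports` and the exclusion `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- data.frame(structure_id = character(0), unit_index = integer(0),
                    reason = character(0), stringsAsFactors = FALSE)
  note <- function(id, unit, reason) {
    log <<- rbind(log, data.frame(structure_id = id, unit_index = unit,
                                  reason = reason, stringsAsFactors = FALSE))
  }

  ann <- load_annotation_summary(config$summary)
  sk <- attr(ann, "skipped")
  if (nrow(sk) > 0) for (i in seq_len(nrow(sk))) {
    note(sk$structure_id[i], NA_integer_, sk$reason[i])
  }

  # parse each structure file into its biological units
  units_by_structure <- list()
  for (id in unique(ann$structure_id)) {
    rows <- ann[ann$structure_id == id, , drop = FALSE]
    f <- file.path(config$pdb_dir, paste0(c(id, tolower(id)), ".pdb"))
    f <- f[file.exists(f)][1]
    if (is.na(f)) {
      note(id, NA_integer_, "PDB file not found")
      next
    }
    units_by_structure[[id]] <- tryCatch(
      parse_complex(f, rows),
      error = function(e) {
        note(id, NA_integer_, conditionMessage(e))
        NULL
      })
  }

  # resolution/exclusion filter, then one unit per structure file
  complexes <- list()
  for (id in names(units_by_structure)) {
    fl <- filter_dataset(units_by_structure[[id]], config$max_resolution,
                         config$exclusion_list)
    if (nrow(fl$log) > 0) for (i in seq_len(nrow(fl$log))) {
      note(fl$log$structure_id[i], fl$log$unit_index[i], fl$log$reason[i])
    }
    if (length(fl$complexes) == 0) next
    sel <- select_unit(fl$complexes,
                       include_hydrogens = config$bfactor_include_hydrogens)
    slog <- attr(sel, "selection_log")
    for (i in which(!slog$selected)) {
      note(id, slog$unit_index[i],
           sprintf("packing duplicate (mean B %.2f > selected %.2f)",
                   slog$mean_b[i], min(slog$mean_b)))
    }
    complexes[[id]] <- sel
  }

  # redundancy removal on variable-domain sequences
  if (length(complexes) > 0) {
    get_seqs <- function(domain) {
      out <- character(0)
      for (cx in complexes) {
        res <- unique_residues(cx, role = "antibody")
        if (domain %in% res$domain) {
          out[cx$structure_id] <-
            extract_variable_sequence(cx, domain,
                                      vr_max = config$scheme$vr_max)
        }
      }
      out
    }
    vh <- get_seqs("VH"); vl <- get_seqs("VL")
    vhc <- if (length(vh)) cluster_sequences(vh, config$identity) else NULL
    vlc <- if (length(vl)) cluster_sequences(vl, config$identity) else NULL
    rr <- remove_redundant(unname(complexes), vhc, vlc)
    for (i in which(!rr$log$kept)) {
      note(rr$log$structure_id[i], NA_integer_,
           paste0("redundant antibody (family ", rr$log$family[i], ")"))
    }
    complexes <- rr$complexes
  }

  if (length(complexes) == 0) {
    write.csv(log, file.path(config$out_dir, "exclusions.csv"),
              row.names = FALSE)
    jsonlite::write_json(list(status = "empty", n_complexes = 0),
                         file.path(config$out_dir, "run_summary.json"),
                         auto_unbox = TRUE)
    return(invisible(list(status = "empty", complexes = list(),
                          reports = list(), log = log)))
  }

  groups <- vapply(complexes, classify_group, character(1))
  reports <- list()
  for (cu in sort(config$cutoff)) {
    sub <- if (length(config$cutoff) > 1) {
      file.path(config$out_dir, sprintf("cutoff_%g", cu))
    } else config$out_dir
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    reports[[sprintf("%g", cu)]] <-
      .emit_report(complexes, groups, cu, sub, config)
  }
  write.csv(log, file.path(config$out_dir, "exclusions.csv"),
            row.names = FALSE)
  invisible(list(status = "ok", complexes = complexes, groups = groups,
                 reports = reports, log = log))
}

# One report set (fixed filenames) for one cutoff.
.emit_report <- function(complexes, groups, cutoff, out_dir, config) {
  scheme <- config$scheme
  ids <- vapply(complexes, `[[`, "", "structure_id")
  contacts_list <- lapply(complexes, find_contacts, cutoff = cutoff)
  summaries <- lapply(contacts_list, summarize_interface)

  per <- data.frame(
    structure_id = ids, group = groups,
    resolution = vapply(complexes, function(cx) cx$annotation$resolution,
                        numeric(1)),
    total_contacts = vapply(summaries, `[[`, 0L, "total_contacts"),
    upr = vapply(summaries, `[[`, 0L, "upr"),
    upa = vapply(summaries, `[[`, 0L, "upa"),
    uer = vapply(summaries, `[[`, 0L, "uer"),
    uea = vapply(summaries, `[[`, 0L, "uea"),
    upa_main = vapply(summaries, `[[`, 0L, "upa_main"),
    upa_side = vapply(summaries, `[[`, 0L, "upa_side"),
    epitope_segments = vapply(contacts_list, function(ct) {
      if (nrow(ct) == 0) NA_integer_ else epitope_segments(ct)
    }, integer(1)),
    stringsAsFactors = FALSE)
  if (config$with_waters) {
    wat <- lapply(complexes, count_interfacial_waters, cutoff = cutoff)
    per$interfacial_waters <- vapply(wat, `[[`, 0L, "n_waters")
    per$water_mediated <- vapply(wat, `[[`, 0L, "n_water_mediated")
  }
  rownames(per) <- NULL

  grp_rows <- lapply(unique(groups), function(g) {
    p <- per[per$group == g, , drop = FALSE]
    data.frame(group = g, n_structures = nrow(p),
               total_contacts = sum(p$total_contacts),
               upr = sum(p$upr), upa = sum(p$upa),
               uer = sum(p$uer), uea = sum(p$uea),
               mean_resolution = mean(p$resolution),
               stringsAsFactors = FALSE)
  })
  grp <- do.call(rbind, grp_rows)
  grp <- rbind(grp, data.frame(
    group = "Total", n_structures = nrow(per),
    total_contacts = sum(per$total_contacts), upr = sum(per$upr),
    upa = sum(per$upa), uer = sum(per$uer), uea = sum(per$uea),
    mean_resolution = mean(per$resolution), stringsAsFactors = FALSE))

  all_contacts <- do.call(rbind, lapply(seq_along(contacts_list), function(i) {
    ct <- contacts_list[[i]]
    if (nrow(ct) == 0) return(NULL)
    cbind(structure_id = ids[i], group = groups[i], ct,
          stringsAsFactors = FALSE)
  }))

  ci_cols <- function(values) {
    ci <- suppressWarnings(
      group_mean_ci(values, n_boot = config$n_boot,
                    level = config$ci_level, seed = config$seed))
    c(mean = ci$point, lo = ci$lo, hi = ci$hi)
  }

  # per-group frequency tables with bootstrap CIs
  aa_tab <- list(); class_tab <- list(); ss_tab <- list(); seg_tab <- list()
  region_tab <- list(); capture_tab <- list(); hot_tab <- list()
  posaa_tab <- list(); germ_tab <- list()
  for (g in unique(groups)) {
    in_g <- which(groups == g & vapply(contacts_list, nrow, 0L) > 0)
    if (length(in_g) == 0) next
    cl <- contacts_list[in_g]

    upr_freqs <- lapply(cl, function(ct) {
      key <- .res_key(ct$ab_chain, ct$ab_resno, ct$ab_insert)
      aa_frequencies(ct$ab_aa[!duplicated(key)])
    })
    uer_freqs <- lapply(cl, function(ct) {
      key <- .res_key(ct$ag_chain, ct$ag_resno, ct$ag_insert)
      aa_frequencies(ct$ag_aa[!duplicated(key)])
    })
    for (basis in c("uPR", "uER")) {
      freqs <- if (basis == "uPR") upr_freqs else uer_freqs
      m <- do.call(rbind, freqs)
      for (aa in standard_aa()) {
        aa_tab[[length(aa_tab) + 1]] <- data.frame(
          group = g, basis = basis, aa = aa, t(ci_cols(m[, aa])),
          stringsAsFactors = FALSE)
      }
    }
    cm <- do.call(rbind, lapply(upr_freqs, class_frequencies))
    for (cls in colnames(cm)) {
      class_tab[[length(class_tab) + 1]] <- data.frame(
        group = g, class = cls, t(ci_cols(cm[, cls])),
        stringsAsFactors = FALSE)
    }

    sm <- do.call(rbind, lapply(cl, epitope_ss_frequencies, ss = config$ss))
    for (cls in colnames(sm)) {
      ss_tab[[length(ss_tab) + 1]] <- data.frame(
        group = g, ss_class = cls, t(ci_cols(sm[, cls])),
        stringsAsFactors = FALSE)
    }

    seg_tab[[length(seg_tab) + 1]] <- data.frame(
      group = g, t(ci_cols(vapply(cl, epitope_segments, integer(1)))),
      stringsAsFactors = FALSE)

    counts <- lapply(cl, upr_region_counts, scheme = scheme)
    rd <- suppressWarnings(region_distribution(counts))
    region_tab[[length(region_tab) + 1]] <-
      cbind(group = g, rd$mean_pct, stringsAsFactors = FALSE)

    capture_tab[[length(capture_tab) + 1]] <- data.frame(
      group = g,
      cdr_capture_pct = suppressWarnings(cdr_capture_fraction(cl, scheme)),
      stringsAsFactors = FALSE)

    hs <- hotspot_map(complexes[in_g], cl, scheme, config$min_occurrence)
    if (nrow(hs) > 0) {
      hot_tab[[length(hot_tab) + 1]] <-
        cbind(group = g, hs, stringsAsFactors = FALSE)
    }

    gu <- suppressWarnings(group_upr_table(cl, ids[in_g], scheme))
    if (!is.null(gu) && nrow(gu) > 0) {
      posaa_tab[[length(posaa_tab) + 1]] <-
        cbind(group = g, position_aa_frequencies(gu),
              stringsAsFactors = FALSE)
      if (!is.null(config$germline)) {
        gm <- germline_mutation_fraction(gu, config$germline)
        if (nrow(gm) > 0) {
          germ_tab[[length(germ_tab) + 1]] <-
            cbind(group = g, gm, pooled_pct = attr(gm, "pooled_pct"),
                  stringsAsFactors = FALSE)
        }
      }
    }
  }

  co <- if (!is.null(all_contacts) && nrow(all_contacts) > 0) {
    cooccurrence_matrix(all_contacts)
  } else NULL

  emit <- function(x, name) {
    if (is.null(x) || (is.list(x) && length(x) == 0)) return(invisible())
    if (is.list(x) && !is.data.frame(x) && !is.matrix(x)) {
      x <- do.call(rbind, x)
    }
    write.csv(x, file.path(out_dir, name), row.names = is.matrix(x))
  }
  emit(per, "complex_summary.csv")
  emit(grp, "group_summary.csv")
  emit(all_contacts, "contacts.csv")
  emit(aa_tab, "aa_frequencies.csv")
  emit(class_tab, "class_frequencies.csv")
  emit(ss_tab, "epitope_ss_frequencies.csv")
  emit(seg_tab, "epitope_segments.csv")
  emit(region_tab, "region_distribution.csv")
  emit(capture_tab, "cdr_capture.csv")
  emit(hot_tab, "hotspots.csv")
  emit(posaa_tab, "position_aa_frequencies.csv")
  emit(germ_tab, "germline_mutation.csv")
  if (!is.null(co)) emit(co, "cooccurrence.csv")

  run_summary <- list(
    status = "ok", cutoff = cutoff, n_complexes = nrow(per),
    groups = as.list(table(per$group)),
    total_contacts = sum(per$total_contacts),
    upr = sum(per$upr), upa = sum(per$upa),
    uer = sum(per$uer), uea = sum(per$uea),
    mean_resolution = mean(per$resolution),
    ss_codes_supplied = !is.null(config$ss))
  if (is.null(config$ss)) {
    run_summary$warning <-
      "no secondary-structure codes supplied; epitope residues labelled loop"
  }
  jsonlite::write_json(run_summary,
                       file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA)

  list(per_complex = per, group_summary = grp,
       contacts = all_contacts, cooccurrence = co,
       aa_frequencies = if (length(aa_tab)) do.call(rbind, aa_tab),
       class_frequencies = if (length(class_tab)) do.call(rbind, class_tab),
       region_distribution = if (length(region_tab)) do.call(rbind, region_tab),
       cdr_capture = if (length(capture_tab)) do.call(rbind, capture_tab),
       hotspots = if (length(hot_tab)) do.call(rbind, hot_tab),
       epitope_segments = if (length(seg_tab)) do.call(rbind, seg_tab),
       epitope_ss = if (length(ss_tab)) do.call(rbind, ss_tab),
       position_aa = if (length(posaa_tab)) do.call(rbind, posaa_tab),
       germline = if (length(germ_tab)) do.call(rbind, germ_tab),
       run_summary = run_summary)
}
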