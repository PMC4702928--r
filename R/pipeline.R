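# End-to-end analysis: structures + domain definitions -> contacts, modes,
# classes and shape statistics.

#' Analyze one structure against its domain definitions
#'
#' Runs duplex detection, secondary-structure assignment, contact
#' detection and mode derivation for every domain instance defined on the
#' structure.
#'
#' @param structure a `pdna_structure` (bonds are computed if missing).
#' @param domains domain-definition data frame
#'   (see [load_domain_definitions()]); only rows matching the structure's
#'   id and assembly are used, unless `all_rows = TRUE`.
#' @param ss_source `"internal"`, or an `ss_assignment` from
#'   [import_external_ss()].
#' @param min_bp minimum duplex length in base pairs.
#' @param all_rows use every row of `domains` regardless of ids.
#' @param shape also compute contact-zone shape parameters.
#' @return object of class `dpi_structure_report`: list with `id`,
#'   `duplexes`, `ss`, and `domains` (per instance: contacts, mode, zone,
#'   shape).
#' @export
analyze_structure <- function(structure, domains, ss_source = "internal",
                              min_bp = 10, all_rows = FALSE, shape = TRUE) {
  if (is.null(structure$bonds)) structure <- covalent_neighbors(structure)
  dd <- if (all_rows) domains else
    domains[domains$structure_id == structure$id &
              domains$assembly_id == structure$assembly_id, , drop = FALSE]
  bp <- detect_base_pairs(structure)
  dup <- detect_duplexes(bp, structure, min_bp = min_bp)
  ss <- if (inherits(ss_source, "ss_assignment")) ss_source
  else if (inherits(attr(structure, "ss"), "ss_assignment")) attr(structure, "ss")
  else assign_secondary_structure(structure)
  clusters <- hydrophobic_clusters(structure)
  out <- list()
  for (r in seq_len(nrow(dd))) {
    dom <- dd[r, ]
    rows <- .domain_atoms(structure, dom)
    cts <- domain_contacts(structure, rows, dup, ss, clusters)
    mode <- interaction_mode(cts)
    rec <- list(domain_id = dom$domain_id, family_id = dom$family_id,
                contacts = cts, mode = mode)
    if (shape && length(dup)) {
      shp <- list(ax_bend = NA_real_, MnW = NA_real_, MnD = NA_real_,
                  MjW = NA_real_, MjD = NA_real_)
      best <- NULL
      for (d in dup) {
        zn <- contact_zone(cts, d, structure)
        if (length(zn$pair_idx) >= 3 &&
            (is.null(best) || length(zn$pair_idx) > length(best$pair_idx)))
          best <- zn
      }
      if (!is.null(best)) {
        fr <- base_pair_frames(best$duplex, structure, best$pair_idx)
        shp <- groove_geometry(best, structure, frames = fr)
        shp$ax_bend <- ax_bend(fr)
        rec$zone <- best
      }
      rec$shape <- shp
    }
    out[[length(out) + 1]] <- rec
  }
  res <- list(id = structure$id, assembly_id = structure$assembly_id,
              n_duplexes = length(dup), duplexes = dup, ss = ss,
              domains = out)
  class(res) <- "dpi_structure_report"
  res
}

#' @export
print.dpi_structure_report <- function(x, ...) {
  cat("structure ", x$id, ": ", x$n_duplexes, " duplex(es)\n", sep = "")
  for (d in x$domains) {
    cat("  ", d$domain_id, " [", d$family_id, "]: ",
        if (d$mode$non_interacting) "<non-interacting>" else d$mode$label,
        "\n", sep = "")
  }
  invisible(x)
}

#' Analyze a corpus of structures and classify families
#'
#' @param structures named list of `pdna_structure` objects (or file
#'   paths, loaded on the fly).
#' @param domains full domain-definition data frame.
#' @param min_domains minimum family representatives for classification.
#' @param ... passed to [analyze_structure()].
#' @return object of class `dpi_corpus`: list with `modes` (one row per
#'   domain instance), `unions` (per domain), `classes` (one row per
#'   classifiable family), `unclassified` (family ids with too few
#'   domains), `shape` data frame, aggregated `shape_stats`, and the
#'   summary `tables`.
#' @export
analyze_corpus <- function(structures, domains, min_domains = 3, ...) {
  mode_rows <- list(); shape_rows <- list(); type_sets <- list()
  for (nm in names(structures)) {
    st <- structures[[nm]]
    if (is.character(st)) st <- load_structure(st)
    rep <- analyze_structure(st, domains, ...)
    for (d in rep$domains) {
      key <- length(mode_rows) + 1
      mode_rows[[key]] <- data.frame(
        structure_id = rep$id, domain_id = d$domain_id,
        family_id = d$family_id, mode = d$mode$label,
        non_interacting = d$mode$non_interacting)
      type_sets[[key]] <- d$mode$types
      if (!is.null(d$shape))
        shape_rows[[length(shape_rows) + 1]] <- data.frame(
          structure_id = rep$id, domain_id = d$domain_id,
          family_id = d$family_id,
          ax_bend = d$shape$ax_bend, MnW = d$shape$MnW, MnD = d$shape$MnD,
          MjW = d$shape$MjW, MjD = d$shape$MjD)
    }
  }
  modes <- if (length(mode_rows)) do.call(rbind, mode_rows) else
    data.frame(structure_id = character(0), domain_id = character(0),
               family_id = character(0), mode = character(0),
               non_interacting = logical(0))
  shape_df <- if (length(shape_rows)) do.call(rbind, shape_rows) else NULL
  # per-domain unions
  unions <- list()
  for (k in seq_len(nrow(modes))) {
    d <- modes$domain_id[k]
    unions[[d]] <- sort_types(c(unions[[d]], type_sets[[k]]))
  }
  # per-family classes
  fam_dom <- unique(modes[, c("domain_id", "family_id")])
  classes <- list(); unclassified <- character(0)
  for (f in unique(fam_dom$family_id)) {
    ds <- fam_dom$domain_id[fam_dom$family_id == f]
    if (length(ds) < min_domains) { unclassified <- c(unclassified, f); next }
    cl <- family_interaction_class(unions[ds], f, min_domains)
    classes[[f]] <- data.frame(
      family_id = f,
      class = if (cl$miscellaneous) "miscellaneous" else mode_label(cl$characteristic_types),
      miscellaneous = cl$miscellaneous, n_domains = cl$n_domains)
  }
  classes <- if (length(classes)) do.call(rbind, classes) else
    data.frame(family_id = character(0), class = character(0),
               miscellaneous = logical(0), n_domains = integer(0))
  rownames(classes) <- NULL
  shape_stats <- if (!is.null(shape_df)) aggregate_shape(shape_df) else NULL
  structure(list(modes = modes, unions = unions, classes = classes,
                 unclassified = unclassified, shape = shape_df,
                 shape_stats = shape_stats,
                 tables = build_reports(modes, classes)),
            class = "dpi_corpus")
}

#' @export
print.dpi_corpus <- function(x, ...) {
  cat("dpi_corpus: ", nrow(x$modes), " domain instances, ",
      length(x$unions), " domains, ",
      length(unique(x$modes$family_id)), " families\n", sep = "")
  if (nrow(x$classes)) {
    cat("interaction classes:\n")
    for (r in seq_len(nrow(x$classes)))
      cat("  ", x$classes$family_id[r], ": ", x$classes$class[r], "\n", sep = "")
  }
  if (length(x$unclassified))
    cat("unclassified (too few domains):",
        paste(x$unclassified, collapse = ", "), "\n")
  invisible(x)
}

#' Write corpus reports
#'
#' Writes per-structure JSON (domain to mode), per-family JSON (class,
#' per-domain unions) and the TSV summary tables.
#'
#' @param corpus a `dpi_corpus`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus_reports <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  per_struct <- split(corpus$modes, corpus$modes$structure_id)
  jsonlite::write_json(
    lapply(per_struct, function(d)
      stats::setNames(as.list(d$mode), d$domain_id)),
    file.path(dir, "modes_by_structure.json"), auto_unbox = TRUE, pretty = TRUE)
  fam <- lapply(split(corpus$modes, corpus$modes$family_id), function(d) {
    f <- d$family_id[1]
    cl <- corpus$classes[corpus$classes$family_id == f, ]
    list(class = if (nrow(cl)) cl$class else "unclassified (too few domains)",
         domains = lapply(corpus$unions[unique(d$domain_id)], mode_label),
         structures = stats::setNames(as.list(d$mode),
                                      paste(d$structure_id, d$domain_id)))
  })
  jsonlite::write_json(fam, file.path(dir, "classes_by_family.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  utils::write.table(corpus$tables$mode_table,
                     file.path(dir, "mode_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(corpus$tables$class_table,
                     file.path(dir, "class_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(corpus$shape_stats)) {
    utils::write.table(format(corpus$shape_stats$family, digits = 3),
                       file.path(dir, "family_shape.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
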