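# Interaction modes of domain-DNA structures and interaction classes of
# domain families.

#' The nine contact types
#'
#' Crossing the three protein elements (helix `H`, strand `S`, loop `L`)
#' with the three DNA elements (backbone `Bb`, major groove `Mj`, minor
#' groove `Mn`) in canonical order.
#'
#' @return character vector of nine machine labels (`"H-Bb"`, ...).
#' @export
contact_types <- function() {
  as.vector(t(outer(.prot_elements, .dna_elements, paste, sep = "-")))
}

.elem_abbr <- c(Helix = "H", Strand = "S", Loop = "L",
                Backbone = "Bb", MajorGroove = "Mj", MinorGroove = "Mn")

#' Type of one contact
#'
#' The (protein element, DNA element) pair of a contact; contacts whose
#' DNA atom is unclassified are discarded (`NA`).
#'
#' @param protein_element `"Helix"`, `"Strand"` or `"Loop"` (vectorized).
#' @param dna_element `"Backbone"`, `"MajorGroove"`, `"MinorGroove"` or
#'   `"Unclassified"`.
#' @return machine labels such as `"H-Mj"`; `NA` for discarded contacts.
#' @export
contact_type <- function(protein_element, dna_element) {
  p <- .elem_abbr[protein_element]
  d <- .elem_abbr[dna_element]
  out <- paste(p, d, sep = "-")
  out[is.na(p) | is.na(d)] <- NA_character_
  out
}

#' Canonical ordering and rendering of a set of contact types
#'
#' Types sort by protein element H < S < L, then DNA element Bb < Mj < Mn.
#'
#' @param types character vector of machine labels.
#' @param display if `TRUE`, renders `"(H - Bb) (L - Mn)"`; otherwise the
#'   machine form `"(H-Bb) (L-Mn)"`.
#' @return a single string (empty string for an empty set).
#' @export
mode_label <- function(types, display = FALSE) {
  types <- sort_types(types)
  if (!length(types)) return("")
  if (display)
    paste(sprintf("(%s - %s)", sub("-.*", "", types), sub(".*-", "", types)),
          collapse = " ")
  else paste(sprintf("(%s)", types), collapse = " ")
}

#' @rdname mode_label
#' @export
sort_types <- function(types) {
  types <- unique(types[!is.na(types)])
  all9 <- contact_types()
  bad <- setdiff(types, all9)
  if (length(bad)) stop("unknown contact type(s): ", paste(bad, collapse = ", "))
  all9[all9 %in% types]
}

#' Interaction mode of a domain instance
#'
#' The set of distinct contact types detected for one protein domain in
#' one structure, restricted to duplexes of the minimum length (enforced
#' upstream by [detect_duplexes()]).  A domain instance contacting two
#' duplexes yields one mode over the union of both contact sets.
#'
#' @param contacts a `dpi_contacts` data frame for the domain instance.
#' @return object of class `dpi_mode`: list with `types` (canonically
#'   sorted character vector), `label`, and `non_interacting` flag.
#' @export
interaction_mode <- function(contacts) {
  ty <- contact_type(contacts$protein_element, contacts$dna_element)
  ty <- sort_types(ty)
  structure(list(types = ty, label = mode_label(ty),
                 non_interacting = length(ty) == 0),
            class = "dpi_mode")
}

#' @export
print.dpi_mode <- function(x, ...) {
  if (x$non_interacting) cat("interaction mode: <non-interacting>\n")
  else cat("interaction mode:", mode_label(x$types, display = TRUE), "\n")
  invisible(x)
}

#' Number of formally possible interaction modes
#'
#' Non-empty subsets of the contact-type set: `2^9 - 1 = 511` for the nine
#' types.
#'
#' @param n_types number of contact types (default `length(contact_types())`).
#' @return integer count.
#' @export
enumerate_possible_modes <- function(n_types = length(contact_types())) {
  as.integer(2^n_types - 1)
}

#' Union of the modes of one domain
#'
#' A contact type seen in at least one structure of a domain is considered
#' possible for the domain in general.
#'
#' @param modes list of `dpi_mode` objects (or character vectors of types).
#' @return canonically sorted character vector of types.
#' @export
domain_union <- function(modes) {
  if (!length(modes)) stop("domain_union needs at least one mode")
  ty <- unlist(lapply(modes, function(m) if (inherits(m, "dpi_mode")) m$types else m))
  sort_types(ty)
}

#' Interaction class of a family
#'
#' The intersection of the per-domain unions of interaction modes; empty
#' intersections give the miscellaneous class.  Families with fewer than
#' `min_domains` distinct domains are refused as unclassified.
#'
#' @param unions named list: one canonically sorted type vector per domain.
#' @param family_id family label.
#' @param min_domains minimum number of domain representatives (default 3).
#' @return object of class `dpi_class`: list with `family_id`,
#'   `characteristic_types`, `miscellaneous`, `n_domains`.
#' @export
family_interaction_class <- function(unions, family_id, min_domains = 3) {
  if (length(unions) < min_domains)
    stop("unclassified (too few domains): family ", family_id, " has ",
         length(unions), " domain(s), needs ", min_domains)
  ch <- Reduce(intersect, unions)
  ch <- sort_types(ch)
  structure(list(family_id = family_id, characteristic_types = ch,
                 miscellaneous = length(ch) == 0,
                 n_domains = length(unions)),
            class = "dpi_class")
}

#' @export
print.dpi_class <- function(x, ...) {
  cat("family ", x$family_id, " (", x$n_domains, " domains): ", sep = "")
  if (x$miscellaneous) cat("miscellaneous\n")
  else cat(mode_label(x$characteristic_types, display = TRUE), "\n")
  invisible(x)
}

#' Summary tables of modes and classes
#'
#' The mode table has one row per observed interaction mode with the
#' number of families and structures presenting it, sorted by family count
#' (descending); the class table has one row per interaction class with
#' family, structure and domain counts.
#'
#' @param modes data frame with columns `structure_id`, `domain_id`,
#'   `family_id`, `mode` (mode label strings).
#' @param classes optional data frame with `family_id`, `class` (label or
#'   `"miscellaneous"`), used for the class table.
#' @return list with `mode_table` and `class_table` data frames.
#' @export
build_reports <- function(modes, classes = NULL) {
  if (nrow(modes) == 0) {
    mt <- data.frame(mode = character(0), n_families = integer(0),
                     n_structures = integer(0))
  } else {
    sp <- split(modes, modes$mode)
    mt <- data.frame(
      mode = names(sp),
      n_families = vapply(sp, function(d) length(unique(d$family_id)), 1L),
      n_structures = vapply(sp, nrow, 1L))
    mt <- mt[order(-mt$n_families, -mt$n_structures, mt$mode), , drop = FALSE]
    rownames(mt) <- NULL
  }
  ct <- data.frame(class = character(0), n_families = integer(0),
                   n_structures = integer(0), n_domains = integer(0))
  if (!is.null(classes) && nrow(classes)) {
    sp <- split(classes, classes$class)
    ct <- data.frame(
      class = names(sp),
      n_families = vapply(sp, function(d) length(unique(d$family_id)), 1L),
      n_structures = vapply(sp, function(d) {
        sum(vapply(unique(d$family_id), function(f)
          nrow(modes[modes$family_id == f, , drop = FALSE]), 1L))
      }, 1L),
      n_domains = vapply(sp, function(d) {
        length(unique(modes$domain_id[modes$family_id %in% d$family_id]))
      }, 1L))
    ct <- ct[order(-ct$n_families, ct$class), , drop = FALSE]
    rownames(ct) <- NULL
  }
  list(mode_table = mt, class_table = ct)
}
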