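# 2D templates: reference sequence + dot-bracket structure + fixed
# per-nucleotide coordinates + metadata. A template is the unit of the
# library; its layout defines the community-standard orientation for an RNA
# family. Coordinates are stored y-down (SVG convention).
#
# On disk a template is a pair of files:
#   * Vienna-style FASTA: ">{id}" / sequence line(s) / dot-bracket line(s)
#   * XML: <template id="..."><nucleotide index="1" base="G" x="1.000"
#     y="2.000"/>...</template>

COORD_DIGITS <- 3L  # serialisation precision; round trips are exact at this

#' Construct a 2D template
#'
#' @param id template identifier (non-empty string, unique library-wide).
#' @param sequence reference sequence; lowercase raised, T normalised to U.
#' @param structure an `rna_ss` or a dot-bracket string of equal length.
#' @param coords numeric matrix or data frame with columns `x`, `y`, one row
#'   per nucleotide (y increases downward).
#' @param metadata optional named list; recognised keys include `rna_type`,
#'   `source`, `taxid` and `structure_source` (one of `3D`, `covariation`,
#'   `consensus`).
#' @return object of class `rna_template`.
#' @export
rna_template <- function(id, sequence, structure, coords, metadata = list()) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("template id required")
  }
  sequence <- normalize_seq(sequence)
  if (is.character(structure)) structure <- parse_dotbracket(structure)
  stopifnot(inherits(structure, "rna_ss"))
  coords <- as.data.frame(coords)
  if (!all(c("x", "y") %in% names(coords))) {
    colnames(coords)[1:2] <- c("x", "y")
  }
  coords <- data.frame(x = as.numeric(coords$x), y = as.numeric(coords$y))
  n <- nchar(sequence)
  if (structure$length != n) {
    stop("structure length ", structure$length, " != sequence length ", n)
  }
  if (nrow(coords) != n) {
    stop("coordinate count ", nrow(coords), " != sequence length ", n)
  }
  ss3 <- metadata$structure_source
  if (!is.null(ss3) && !ss3 %in% c("3D", "covariation", "consensus")) {
    stop("structure_source must be one of 3D, covariation, consensus")
  }
  structure(list(id = id, sequence = sequence, structure = structure,
                 coords = coords, metadata = metadata),
            class = "rna_template")
}

#' @export
print.rna_template <- function(x, ...) {
  cat("RNA 2D template '", x$id, "': ", nchar(x$sequence), " nt, ",
      nrow(x$structure$pairs), " base pair(s)\n", sep = "")
  invisible(x)
}

#' Read a template from its FASTA + XML file pair
#'
#' @param fasta_path path to the Vienna-style FASTA (header, sequence,
#'   dot-bracket; sequence and structure may wrap over multiple lines).
#' @param xml_path path to the coordinate XML.
#' @return an [rna_template()].
#' @export
read_template <- function(fasta_path, xml_path) {
  lines <- readLines(fasta_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || !startsWith(lines[1], ">")) {
    stop("not a Vienna-style FASTA: ", fasta_path)
  }
  id <- trimws(sub("^>", "", lines[1]))
  id <- strsplit(id, "[[:space:]]+")[[1]][1]
  body <- trimws(lines[-1])
  # sequence lines (letters) come first, then dot-bracket lines
  is_struct <- !grepl("[A-Za-z]", body)
  first_struct <- which(is_struct)[1]
  if (is.na(first_struct) || first_struct == 1L) {
    stop("expected sequence line(s) followed by dot-bracket line(s) in ", fasta_path)
  }
  sequence <- paste(body[seq_len(first_struct - 1L)], collapse = "")
  db <- paste(body[first_struct:length(body)], collapse = "")

  doc <- xml2::read_xml(xml_path)
  if (xml2::xml_name(doc) != "template") stop("XML root must be <template>: ", xml_path)
  xml_id <- xml2::xml_attr(doc, "id")
  if (!is.na(xml_id) && nzchar(xml_id)) id <- xml_id
  nts <- xml2::xml_find_all(doc, "./nucleotide")
  idx <- as.integer(xml2::xml_attr(nts, "index"))
  base <- xml2::xml_attr(nts, "base")
  x <- as.numeric(xml2::xml_attr(nts, "x"))
  y <- as.numeric(xml2::xml_attr(nts, "y"))
  if (length(idx) != nchar(gsub("[[:space:]]", "", sequence))) {
    stop("coordinate count ", length(idx), " != sequence length ",
         nchar(sequence))
  }
  if (anyDuplicated(idx) || !identical(sort(idx), seq_along(idx))) {
    stop("nucleotide indices must be unique and contiguous 1..n in ", xml_path)
  }
  ord <- order(idx)
  rna_template(id, sequence, db, data.frame(x = x[ord], y = y[ord]))
}

#' Write a template to its FASTA + XML file pair
#'
#' Coordinates are serialised with 3 decimal places; reading the files back
#' reproduces the template exactly at that precision.
#'
#' @param t an [rna_template()].
#' @param fasta_path,xml_path output paths.
#' @return invisibly, the two paths.
#' @export
write_template <- function(t, fasta_path, xml_path) {
  stopifnot(inherits(t, "rna_template"))
  writeLines(c(paste0(">", t$id), t$sequence, write_dotbracket(t$structure)),
             fasta_path)
  bases <- strsplit(t$sequence, "", fixed = TRUE)[[1]]
  fmt <- paste0("%.", COORD_DIGITS, "f")
  nts <- sprintf('  <nucleotide index="%d" base="%s" x="%s" y="%s"/>',
                 seq_along(bases), bases,
                 sprintf(fmt, t$coords$x), sprintf(fmt, t$coords$y))
  writeLines(c(sprintf('<template id="%s">', t$id), nts, "</template>"),
             xml_path)
  invisible(c(fasta_path, xml_path))
}

WATSON_CRICK <- c("AU", "UA", "CG", "GC")
WOBBLE <- c("GU", "UG")

#' Validate a template
#'
#' Checks structural consistency and reports problems without raising.
#' Errors: length mismatches, duplicate indices, non-finite coordinates.
#' Warnings: base pairs that are neither Watson-Crick nor GU wobble (only
#' canonical pairs belong in templates), and distinct nucleotides sharing
#' identical coordinates.
#'
#' @param t an [rna_template()].
#' @return list of class `validation_report` with character vectors `errors`
#'   and `warnings` and logical `ok` (no errors).
#' @export
validate_template <- function(t) {
  errors <- character(0); warnings <- character(0)
  n <- nchar(t$sequence)
  if (t$structure$length != n) {
    errors <- c(errors, sprintf("structure length %d != sequence length %d",
                                t$structure$length, n))
  }
  if (nrow(t$coords) != n) {
    errors <- c(errors, sprintf("coordinate count %d != sequence length %d",
                                nrow(t$coords), n))
  }
  if (!all(is.finite(t$coords$x)) || !all(is.finite(t$coords$y))) {
    errors <- c(errors, "non-finite coordinates")
  }
  if (!length(errors)) {
    bases <- strsplit(t$sequence, "", fixed = TRUE)[[1]]
    p <- t$structure$pairs
    if (nrow(p)) {
      duo <- paste0(bases[p$five], bases[p$three])
      bad <- !(duo %in% c(WATSON_CRICK, WOBBLE))
      warnings <- c(warnings, sprintf("non-canonical pair %s at (%d,%d)",
                                      duo[bad], p$five[bad], p$three[bad]))
    }
    key <- paste(round(t$coords$x, COORD_DIGITS), round(t$coords$y, COORD_DIGITS))
    dup <- which(duplicated(key))
    if (length(dup)) {
      warnings <- c(warnings, sprintf(
        "duplicate coordinates for distinct nucleotides (e.g. position %d)", dup[1]))
    }
  }
  structure(list(ok = length(errors) == 0L, errors = errors,
                 warnings = warnings),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Template validation:", if (x$ok) "OK" else "FAILED", "\n")
  for (e in x$errors) cat("  error:", e, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Index a template library directory
#'
#' A library root contains one sub-directory per template group; each group
#' holds `<id>.fasta` / `<id>.xml` file pairs. Groups are searched
#' downstream in the order given (the order encodes search priority, so the
#' first group a query matches wins and later groups are skipped).
#'
#' @param root_dir library root directory.
#' @param group_order character vector of group (sub-directory) names; by
#'   default all sub-directories in lexicographic order.
#' @return object of class `library_index`: data frame with `id`, `group`,
#'   `fasta`, `xml`, plus the group order.
#' @export
index_library <- function(root_dir, group_order = NULL) {
  if (!dir.exists(root_dir)) stop("no such directory: ", root_dir)
  groups <- group_order %||% sort(list.dirs(root_dir, recursive = FALSE,
                                            full.names = FALSE))
  rows <- list()
  for (g in groups) {
    gdir <- file.path(root_dir, g)
    if (!dir.exists(gdir)) stop("no such group directory: ", gdir)
    fastas <- sort(list.files(gdir, pattern = "\\.(fasta|fa)$", full.names = TRUE))
    ids <- sub("\\.(fasta|fa)$", "", basename(fastas))
    xmls <- file.path(gdir, paste0(ids, ".xml"))
    missing <- !file.exists(xmls)
    if (any(missing)) stop("missing coordinate XML for template ", ids[missing][1])
    if (length(ids)) {
      rows[[g]] <- data.frame(id = ids, group = g, fasta = fastas, xml = xmls,
                              stringsAsFactors = FALSE)
    }
  }
  entries <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(id = character(0), group = character(0),
               fasta = character(0), xml = character(0))
  }
  rownames(entries) <- NULL
  if (anyDuplicated(entries$id)) {
    stop("duplicate template id: ", entries$id[duplicated(entries$id)][1])
  }
  structure(list(groups = groups, entries = entries), class = "library_index")
}

#' @export
print.library_index <- function(x, ...) {
  cat("Template library:", nrow(x$entries), "template(s) in",
      length(x$groups), "group(s)\n")
  invisible(x)
}

#' Load all templates of an indexed library into memory
#'
#' @param index a [index_library()] result.
#' @return object of class `template_library`: the index plus a named list
#'   of `rna_template` objects.
#' @export
load_library <- function(index) {
  stopifnot(inherits(index, "library_index"))
  templates <- lapply(seq_len(nrow(index$entries)), function(i) {
    read_template(index$entries$fasta[i], index$entries$xml[i])
  })
  names(templates) <- index$entries$id
  structure(list(index = index, templates = templates),
            class = "template_library")
}

# Accepts a library in any form (directory path, index, loaded library, a
# single template, or list of templates) and returns a template_library.
as_template_library <- function(library, group = "library") {
  if (inherits(library, "template_library")) return(library)
  if (inherits(library, "library_index")) return(load_library(library))
  if (is.character(library)) return(load_library(index_library(library)))
  if (inherits(library, "rna_template")) library <- list(library)
  if (is.list(library) && all(vapply(library, inherits, TRUE, "rna_template"))) {
    ids <- vapply(library, `[[`, "", "id")
    if (anyDuplicated(ids)) stop("duplicate template id: ", ids[duplicated(ids)][1])
    ord <- order(ids)
    entries <- data.frame(id = ids[ord], group = group,
                          fasta = NA_character_, xml = NA_character_)
    idx <- structure(list(groups = group, entries = entries),
                     class = "library_index")
    templates <- library[ord]
    names(templates) <- ids[ord]
    return(structure(list(index = idx, templates = templates),
                     class = "template_library"))
  }
  stop("cannot interpret 'library' as a template library")
}
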