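# SVG rendering of a finalised layout, plus the dot-bracket and
# per-nucleotide classification text outputs.
#
# Colour scheme (identity channel relative to the template): unchanged
# nucleotides black, inserted nucleotides magenta, changed nucleotides green;
# automatically repositioned nucleotides blue. Precedence when a nucleotide
# belongs to several classes: insertion > changed > repositioned > match
# (base identity is the rarer, more informative signal, so green wins over
# blue for a changed base that also moved). Each glyph carries a <title>
# child so that hovering in a browser reveals the position, the query base
# and, for changed bases, the template reference base.

#' Rendering options
#'
#' @param font_size glyph font size in layout units (default 8).
#' @param glyph `"letter"` (text glyphs) or `"circle"`.
#' @param colours named colour map for labels `match`, `changed`,
#'   `insertion`, `repositioned`.
#' @param show_pseudoknots draw dashed lines for higher-layer pairs
#'   (default TRUE).
#' @param margin canvas margin around the coordinate bounding box.
#' @return list of class `render_options`.
#' @export
render_options <- function(font_size = 8, glyph = c("letter", "circle"),
                           colours = c(match = "#000000", changed = "#008000",
                                       insertion = "#FF00FF",
                                       repositioned = "#0000FF"),
                           show_pseudoknots = TRUE, margin = 20) {
  glyph <- match.arg(glyph)
  required <- c("match", "changed", "insertion", "repositioned")
  if (!all(required %in% names(colours))) {
    stop("colour map must cover: ", paste(required, collapse = ", "))
  }
  structure(list(font_size = font_size, glyph = glyph, colours = colours,
                 show_pseudoknots = show_pseudoknots, margin = margin),
            class = "render_options")
}

#' Colour for a classified nucleotide
#'
#' Pure function of the label and the repositioned flag: match -> black,
#' insertion -> magenta, changed -> green; a repositioned match -> blue.
#'
#' @param label one of `match`, `changed`, `insertion`.
#' @param repositioned logical.
#' @param opts a [render_options()].
#' @return colour string.
#' @export
color_for <- function(label, repositioned = FALSE, opts = render_options()) {
  stopifnot(all(label %in% c("match", "changed", "insertion")))
  cols <- opts$colours[label]
  blue <- label == "match" & repositioned
  cols[blue] <- opts$colours[["repositioned"]]
  unname(cols)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render a layout as an SVG document
#'
#' Emits well-formed SVG 1.1 with one glyph per nucleotide at its final
#' coordinate, a backbone polyline through consecutive positions, a solid
#' line per nested (layer-0) base pair and a dashed line per pseudoknot
#' pair. The canvas is the coordinate bounding box plus a margin.
#'
#' @param layout a [finalize_layout()] result.
#' @param query the query sequence string.
#' @param template the template drawn against (for reference bases in hover
#'   titles).
#' @param aln the `rna_alignment` used (maps query positions to reference
#'   positions for the hover metadata); optional.
#' @param opts a [render_options()].
#' @return single string containing the SVG document.
#' @export
render_svg <- function(layout, query, template = NULL, aln = NULL,
                       opts = render_options()) {
  stopifnot(inherits(layout, "layout_result"))
  n <- length(layout$label)
  if (n == 0) stop("empty layout")
  if (anyNA(layout$xy)) stop("layout contains unplaced coordinates")
  bases <- strsplit(normalize_seq(query), "", fixed = TRUE)[[1]]
  if (length(bases) != n) stop("query length does not match layout")

  ref_base <- rep(NA_character_, n)
  if (!is.null(aln) && !is.null(template)) {
    tb <- strsplit(template$sequence, "", fixed = TRUE)[[1]]
    cols <- aln$columns
    both <- !is.na(cols$template) & !is.na(cols$query)
    ref_base[cols$query[both]] <- tb[cols$template[both]]
  }

  x <- layout$xy[, 1]; y <- layout$xy[, 2]
  mg <- opts$margin
  x0 <- min(x) - mg; y0 <- min(y) - mg
  w <- diff(range(x)) + 2 * mg; h <- diff(range(y)) + 2 * mg
  cols <- color_for(layout$label, layout$repositioned, opts)

  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
                   'viewBox="%.3f %.3f %.3f %.3f" width="%.0f" height="%.0f">'),
            x0, y0, w, h, w, h),
    sprintf('<polyline fill="none" stroke="#C0C0C0" stroke-width="1" points="%s"/>',
            paste(sprintf("%.3f,%.3f", x, y), collapse = " "))
  )
  p <- layout$ss$pairs
  if (nrow(p)) {
    nested <- p[p$layer == 0L, , drop = FALSE]
    out <- c(out, sprintf(
      '<line class="basepair" x1="%.3f" y1="%.3f" x2="%.3f" y2="%.3f" stroke="#808080" stroke-width="1"/>',
      x[nested$five], y[nested$five], x[nested$three], y[nested$three]))
    if (opts$show_pseudoknots) {
      pk <- p[p$layer > 0L, , drop = FALSE]
      if (nrow(pk)) {
        out <- c(out, sprintf(
          '<line class="pseudoknot" x1="%.3f" y1="%.3f" x2="%.3f" y2="%.3f" stroke="#808080" stroke-width="1" stroke-dasharray="3,3"/>',
          x[pk$five], y[pk$five], x[pk$three], y[pk$three]))
      }
    }
  }
  titles <- sprintf("position %d: %s", seq_len(n), bases)
  changed <- layout$label == "changed" & !is.na(ref_base)
  titles[changed] <- sprintf("position %d: %s (template: %s)",
                             which(changed), bases[changed], ref_base[changed])
  titles <- xml_escape(titles)
  glyphs <- if (opts$glyph == "letter") {
    sprintf(paste0('<text class="nt" x="%.3f" y="%.3f" fill="%s" font-size="%g" ',
                   'text-anchor="middle" dominant-baseline="middle" ',
                   'font-family="Helvetica,Arial,sans-serif">%s<title>%s</title></text>'),
            x, y, cols, opts$font_size, bases, titles)
  } else {
    sprintf('<circle class="nt" cx="%.3f" cy="%.3f" r="%g" fill="%s"><title>%s</title></circle>',
            x, y, opts$font_size / 2, cols, titles)
  }
  paste(c(out, glyphs, "</svg>"), collapse = "\n")
}

#' Write diagram output files
#'
#' Writes `<id>.svg`, `<id>.dbn` (header, sequence, dot-bracket) and
#' `<id>.labels.tsv` (position, base, label, repositioned, x, y) to
#' `out_dir`.
#'
#' @param layout a [finalize_layout()] result.
#' @param query query sequence string.
#' @param id output basename (typically the query sequence id).
#' @param out_dir output directory (created if needed).
#' @inheritParams render_svg
#' @return named character vector of the three paths, invisibly.
#' @export
write_outputs <- function(layout, query, id, out_dir, template = NULL,
                          aln = NULL, opts = render_options()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  safe <- gsub("[^A-Za-z0-9._-]", "_", id)
  svg_path <- file.path(out_dir, paste0(safe, ".svg"))
  dbn_path <- file.path(out_dir, paste0(safe, ".dbn"))
  tsv_path <- file.path(out_dir, paste0(safe, ".labels.tsv"))
  writeLines(render_svg(layout, query, template, aln, opts), svg_path)
  writeLines(c(paste0(">", id), normalize_seq(query),
               write_dotbracket(layout$ss)), dbn_path)
  df <- data.frame(
    position = seq_along(layout$label),
    base = strsplit(normalize_seq(query), "", fixed = TRUE)[[1]],
    label = layout$label,
    repositioned = layout$repositioned,
    x = round(layout$xy[, 1], 3),
    y = round(layout$xy[, 2], 3)
  )
  utils::write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(svg = svg_path, dbn = dbn_path, labels = tsv_path))
}
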