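# End-to-end orchestration: template selection -> structure transfer ->
# layout -> rendering, plus batch classification statistics.

read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no FASTA records in ", path)
  ids <- sub("^>\\s*", "", lines[heads])
  ids <- vapply(strsplit(ids, "[[:space:]]+"), `[[`, "", 1L)
  ends <- c(heads[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(heads), function(i) {
    paste(lines[(heads[i] + 1L):ends[i]], collapse = "")
  }, "")
  stats::setNames(gsub("[[:space:]]", "", seqs), ids)
}

#' Draw one query against one selected template
#'
#' The per-sequence core of [draw()]: global alignment to the template
#' reference, base-pair transfer, base classification, coordinate
#' inheritance, insertion placement, overlap resolution and finalisation.
#'
#' @param query query sequence string.
#' @param template the selected [rna_template()].
#' @param params a [scoring_params()].
#' @param d_min overlap threshold (default 0.7 x template median backbone
#'   spacing).
#' @param max_passes rotation passes for [resolve_overlaps()].
#' @param eps_repos repositioning displacement threshold.
#' @return list with `layout` ([finalize_layout()] result), `aln`, `labels`
#'   and the query structure `ss`.
#' @export
draw_structure <- function(query, template, params = scoring_params(),
                           d_min = NULL, max_passes = 5L, eps_repos = 1e-6) {
  aln <- align_global(query, template$sequence, params)
  qss <- transfer_pairs(aln, template$structure)
  labels <- classify_bases(aln, query, template$sequence)
  state <- initial_placement(aln, template, qss, labels)
  state <- place_insertions(state)
  state <- resolve_overlaps(state, d_min = d_min, max_passes = max_passes)
  layout <- finalize_layout(state, eps_repos = eps_repos)
  list(layout = layout, aln = aln, labels = labels, ss = qss)
}

#' Run the full drawing pipeline over a batch of queries
#'
#' For each query sequence: select a template (or honour a forced one),
#' then align, transfer the template base pairs, lay the query out on the
#' template coordinates and write the SVG diagram, dot-bracket file and
#' per-nucleotide classification TSV. Queries that match no template, or
#' that hit one template in multiple well-separated places, are skipped and
#' produce no output files.
#'
#' @param queries path to a query FASTA file, or a named character vector of
#'   sequences.
#' @param library template library (directory path, [index_library()],
#'   [load_library()] result, or list of templates).
#' @param out_dir output directory (created if needed).
#' @param params a [scoring_params()].
#' @param opts a [render_options()].
#' @param template_id optional template id forced for every query (bypasses
#'   selection).
#' @param d_min,max_passes,eps_repos layout engine settings, see
#'   [draw_structure()].
#' @param verbose log per-sequence progress to stderr.
#' @return a `run_report` data frame: one row per query with the selection
#'   outcome, score, nucleotide class counts, overlap counts before/after
#'   optimisation, output paths, and a `skip_reason` (NA when drawn).
#' @export
draw <- function(queries, library, out_dir, params = scoring_params(),
                 opts = render_options(), template_id = NULL, d_min = NULL,
                 max_passes = 5L, eps_repos = 1e-6, verbose = FALSE) {
  if (is.character(queries) && length(queries) == 1L && file.exists(queries)) {
    queries <- read_fasta(queries)
  }
  if (is.null(names(queries)) || any(!nzchar(names(queries)))) {
    names(queries) <- sprintf("query-%03d", seq_along(queries))
  }
  lib <- as_template_library(library)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  rows <- lapply(seq_along(queries), function(i) {
    qid <- names(queries)[i]
    query <- queries[[i]]
    if (verbose) message("[", i, "/", length(queries), "] ", qid)
    row <- data.frame(
      query_id = qid, template_id = NA_character_, group = NA_character_,
      score = NA_real_, n_nt = nchar(query), n_match = NA_integer_,
      n_changed = NA_integer_, n_inserted = NA_integer_,
      n_repositioned = NA_integer_, overlap_before = NA_integer_,
      overlap_after = NA_integer_, svg = NA_character_, dbn = NA_character_,
      labels = NA_character_, skip_reason = NA_character_
    )
    sel <- select_template(query, lib, params, template_id = template_id)
    row$score <- sel$score
    row$group <- sel$group
    if (is.na(sel$template_id)) {
      row$skip_reason <- if (sel$multiple_hits) "multiple hits" else "no template"
      if (verbose) message("  skipped: ", row$skip_reason)
      return(row)
    }
    row$template_id <- sel$template_id
    t <- lib$templates[[sel$template_id]]
    res <- draw_structure(query, t, params, d_min = d_min,
                          max_passes = max_passes, eps_repos = eps_repos)
    paths <- write_outputs(res$layout, query, qid, out_dir, t, res$aln, opts)
    row$n_match <- sum(res$labels == "match")
    row$n_changed <- sum(res$labels == "changed")
    row$n_inserted <- sum(res$labels == "insertion")
    row$n_repositioned <- sum(res$layout$repositioned)
    row$overlap_before <- res$layout$overlap_before
    row$overlap_after <- res$layout$overlap_after
    row$svg <- paths[["svg"]]; row$dbn <- paths[["dbn"]]
    row$labels <- paths[["labels"]]
    row
  })
  report <- do.call(rbind, rows)
  class(report) <- c("run_report", class(report))
  report
}

#' Summarise per-nucleotide classification over a batch of diagrams
#'
#' Produces a classification table over the drawn nucleotides: counts and
#' percentages of nucleotides positioned exactly as in the template,
#' inserted relative to it, or automatically repositioned, per data source
#' plus a Total row. "Positioned exactly" is a positional category: an
#' unmoved nucleotide counts as position-exact even when its base differs
#' from the template (base identity is the colour channel, not the
#' positional one). Percentages are of the total displayed nucleotides,
#' rounded to 1 decimal half-away-from-zero.
#'
#' @param x one of: a character vector of `labels.tsv` paths; a `run_report`
#'   from [draw()]; or a pre-aggregated counts data frame with columns
#'   `n_position_exact`, `n_inserted`, `n_repositioned` (and optionally
#'   `source`, `n_sequences`, `n_diagrams`).
#' @param grouping optional grouping vector (per file/row) naming the data
#'   source of each diagram; default one group named "all".
#' @return a `classification_summary` data frame with one row per source and
#'   a Total row: counts, percentages, `n_total_displayed`, `n_sequences`,
#'   `n_diagrams`.
#' @export
summarize_classification <- function(x, grouping = NULL) {
  counts <- NULL
  if (is.data.frame(x) && all(c("n_position_exact", "n_inserted",
                                "n_repositioned") %in% names(x))) {
    counts <- x
    if (is.null(counts$source)) {
      counts$source <- grouping %||% paste0("group", seq_len(nrow(counts)))
    }
    if (is.null(counts$n_sequences)) counts$n_sequences <- NA_integer_
    if (is.null(counts$n_diagrams)) counts$n_diagrams <- NA_integer_
  } else if (inherits(x, "run_report")) {
    drawn <- x[!is.na(x$template_id), , drop = FALSE]
    if (!nrow(drawn)) stop("no drawn diagrams to summarise")
    grouping <- grouping %||% rep("all", nrow(x))
    g <- grouping[!is.na(x$template_id)]
    counts <- do.call(rbind, lapply(split(seq_len(nrow(drawn)), g), function(ix) {
      d <- drawn[ix, , drop = FALSE]
      data.frame(source = g[ix[1]],
                 n_position_exact = sum(d$n_nt - d$n_inserted - d$n_repositioned),
                 n_inserted = sum(d$n_inserted),
                 n_repositioned = sum(d$n_repositioned),
                 n_sequences = nrow(d), n_diagrams = nrow(d))
    }))
  } else if (is.character(x)) {
    if (!length(x)) stop("no label files to summarise")
    grouping <- grouping %||% rep("all", length(x))
    stopifnot(length(grouping) %in% c(1L, length(x)))
    grouping <- rep_len(grouping, length(x))
    counts <- do.call(rbind, lapply(split(x, grouping), function(files) {
      tabs <- lapply(files, utils::read.delim)
      tab <- do.call(rbind, tabs)
      data.frame(source = grouping[match(files[1], x)],
                 n_position_exact = sum(tab$label != "insertion" & !tab$repositioned),
                 n_inserted = sum(tab$label == "insertion"),
                 n_repositioned = sum(tab$repositioned & tab$label != "insertion"),
                 n_sequences = length(files), n_diagrams = length(files))
    }))
  } else {
    stop("cannot summarise this input")
  }
  if (!nrow(counts)) stop("empty classification input")

  # pre-aggregated inputs may carry their own displayed-nucleotide total
  # (published tables occasionally count nucleotides outside the three
  # classes); otherwise the partition defines it
  if (is.null(counts$n_total_displayed)) {
    counts$n_total_displayed <- counts$n_position_exact + counts$n_inserted +
      counts$n_repositioned
  }
  if (nrow(counts) > 1L) {
    total <- data.frame(
      source = "Total",
      n_position_exact = sum(counts$n_position_exact),
      n_inserted = sum(counts$n_inserted),
      n_repositioned = sum(counts$n_repositioned),
      n_sequences = if (all(is.na(counts$n_sequences))) NA_integer_ else
        sum(counts$n_sequences, na.rm = TRUE),
      n_diagrams = if (all(is.na(counts$n_diagrams))) NA_integer_ else
        sum(counts$n_diagrams, na.rm = TRUE),
      n_total_displayed = sum(counts$n_total_displayed)
    )
    counts <- rbind(counts[, names(total)], total)
  }
  counts$pct_position_exact <- percentage(counts$n_position_exact,
                                          counts$n_total_displayed)
  counts$pct_inserted <- percentage(counts$n_inserted, counts$n_total_displayed)
  counts$pct_repositioned <- percentage(counts$n_repositioned,
                                        counts$n_total_displayed)
  rownames(counts) <- NULL
  out <- counts[, c("source", "n_position_exact", "pct_position_exact",
                    "n_inserted", "pct_inserted", "n_repositioned",
                    "pct_repositioned", "n_total_displayed", "n_sequences",
                    "n_diagrams")]
  class(out) <- c("classification_summary", class(out))
  out
}
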