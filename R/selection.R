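# Template selection: choose the best-matching template for a query, or
# report that none matches. Mirrors the upstream two-round classification
# logic with a profile-free local alignment score: groups are searched in
# index order and the first group containing an acceptable hit wins; a query
# matching the chosen template in two well-separated places is rejected
# (multiple hits), because part of the query is then either inserted relative
# to the template or not homologous to it, and no diagram should be drawn.

#' Score a query against one template
#'
#' Best local (Smith-Waterman) alignment score of the query against the
#' template reference sequence under the affine-gap scheme of
#' [scoring_params()].
#'
#' @param query query sequence string.
#' @param template an [rna_template()].
#' @param params a [scoring_params()].
#' @return numeric score (dimensionless).
#' @export
score_query <- function(query, template, params = scoring_params()) {
  if (!is.character(query) || length(query) != 1L || !nzchar(query)) {
    stop("query sequence is empty")
  }
  align_local(query, template$sequence, params)$score
}

#' Detect multiple well-separated hits to a template
#'
#' TRUE iff two disjoint local alignments of the query to the template
#' reference each clear the length-corrected acceptance line
#' (`accept_threshold + null_rate * min(length)`) and are separated by more
#' than `max_intervening` unaligned query nucleotides. The second hit is
#' probed by masking the query span of the first hit and re-aligning.
#'
#' @inheritParams score_query
#' @return logical.
#' @export
detect_multiple_hits <- function(query, template, params = scoring_params()) {
  line <- acceptance_line(query, template$sequence, params)
  first <- align_local(query, template$sequence, params)
  if (first$score < line) return(FALSE)
  if (first$query_span[1] == 0L) return(FALSE)
  span1 <- hit_core_span(first, query, template$sequence, params)
  if (span1[1] == 0L) return(FALSE)
  second <- align_local(query, template$sequence, params,
                        mask = seq.int(span1[1], span1[2]))
  if (second$score < line) return(FALSE)
  if (second$query_span[1] == 0L) return(FALSE)
  span2 <- hit_core_span(second, query, template$sequence, params)
  if (span2[1] == 0L) return(FALSE)
  if (span2[1] > span1[2]) {
    intervening <- span2[1] - span1[2] - 1L
  } else if (span1[1] > span2[2]) {
    intervening <- span1[1] - span2[2] - 1L
  } else {
    intervening <- 0L
  }
  intervening > params$max_intervening
}

# Null-corrected core of a local hit: per alignment column, the raw column
# score minus null_rate for every consumed query nucleotide; the best
# contiguous segment (Kadane) is the hit's core. Raw local alignments under
# this scoring profit from absorbing unrelated sequence at their edges
# (~null_rate per nucleotide), so spans must be trimmed to their significant
# cores before measuring the separation between two hits.
hit_core_span <- function(aln, query, reference, params) {
  cols <- aln$columns
  if (!nrow(cols)) return(c(0L, 0L))
  qc <- strsplit(normalize_seq(query), "", fixed = TRUE)[[1]]
  rc <- strsplit(normalize_seq(reference), "", fixed = TRUE)[[1]]
  has_t <- !is.na(cols$template); has_q <- !is.na(cols$query)
  colscore <- numeric(nrow(cols))
  both <- has_t & has_q
  colscore[both] <- ifelse(qc[cols$query[both]] == rc[cols$template[both]],
                           params$match, params$mismatch)
  gap <- !both
  if (any(gap)) {
    opens <- gap & !c(FALSE, gap[-length(gap)])
    colscore[gap] <- -ifelse(opens[gap], params$gap_open, params$gap_extend)
  }
  colscore[has_q] <- colscore[has_q] - params$null_rate
  # Kadane: best contiguous segment
  best <- 0; cur <- 0; cur_start <- 1L; b_start <- 0L; b_end <- 0L
  for (i in seq_along(colscore)) {
    if (cur <= 0) { cur <- 0; cur_start <- i }
    cur <- cur + colscore[i]
    if (cur > best) { best <- cur; b_start <- cur_start; b_end <- i }
  }
  if (b_start == 0L) return(c(0L, 0L))
  qs <- cols$query[b_start:b_end]
  qs <- qs[!is.na(qs)]
  if (!length(qs)) return(c(0L, 0L))
  c(min(qs), max(qs))
}

selection_result <- function(template_id = NA_character_, score = NA_real_,
                             multiple_hits = FALSE, group = NA_character_) {
  structure(list(template_id = template_id, score = score,
                 multiple_hits = multiple_hits, group = group),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  if (is.na(x$template_id)) {
    cat("Template selection: no template",
        if (isTRUE(x$multiple_hits)) "(multiple hits)" else
          sprintf("(best score %.1f below threshold)", x$score), "\n")
  } else {
    cat(sprintf("Template selection: '%s' (group %s, score %.1f)\n",
                x$template_id, x$group, x$score))
  }
  invisible(x)
}

#' Select the best-matching template for a query
#'
#' Groups are scanned in index order; within a group every template is
#' scored with [score_query()]. The group's best hit is accepted when its
#' raw score clears the length-corrected acceptance line
#' (`accept_threshold + null_rate * min(query length, reference length)`,
#' the stand-in for a profile bit-score significance cutoff) and the query
#' does not produce multiple well-separated hits to it; later groups are
#' then not searched. Among
#' templates within 1.0 of the group's best score, one whose metadata says
#' `structure_source = "3D"` is preferred (experimentally grounded layouts
#' win near-ties); remaining ties break lexicographically by template id.
#' A forced `template_id` bypasses scoring entirely.
#'
#' @param query query sequence string.
#' @param library a library directory path, [index_library()] result,
#'   [load_library()] result, or list of `rna_template` objects.
#' @param params a [scoring_params()].
#' @param template_id optional template id to force (bypass selection).
#' @return a `selection_result`: `template_id` (NA if nothing acceptable),
#'   `score`, `multiple_hits`, `group`.
#' @export
select_template <- function(query, library, params = scoring_params(),
                            template_id = NULL) {
  lib <- as_template_library(library)
  entries <- lib$index$entries
  if (!is.null(template_id)) {
    if (!template_id %in% entries$id) stop("forced template not in library: ", template_id)
    g <- entries$group[match(template_id, entries$id)]
    return(selection_result(template_id, NA_real_, FALSE, g))
  }
  if (!is.character(query) || length(query) != 1L || !nzchar(query)) {
    stop("query sequence is empty")
  }
  best_seen <- -Inf
  for (g in lib$index$groups) {
    ids <- entries$id[entries$group == g]
    if (!length(ids)) next
    scores <- vapply(ids, function(id) {
      score_query(query, lib$templates[[id]], params)
    }, numeric(1))
    lines <- vapply(ids, function(id) {
      acceptance_line(query, lib$templates[[id]]$sequence, params)
    }, numeric(1))
    best_seen <- max(best_seen, max(scores))
    accepted <- scores >= lines
    if (!any(accepted)) next
    ids <- ids[accepted]
    scores <- scores[accepted]
    best <- max(scores)
    cand <- ids[scores >= best - 1.0]
    is_3d <- vapply(cand, function(id) {
      identical(lib$templates[[id]]$metadata$structure_source, "3D")
    }, logical(1))
    pool <- if (any(is_3d)) cand[is_3d] else cand[scores[match(cand, ids)] == best]
    pool_scores <- scores[match(pool, ids)]
    chosen <- sort(pool[pool_scores == max(pool_scores)])[1]
    chosen_score <- unname(scores[match(chosen, ids)])
    if (detect_multiple_hits(query, lib$templates[[chosen]], params)) {
      return(selection_result(NA_character_, chosen_score,
                              multiple_hits = TRUE, group = g))
    }
    return(selection_result(chosen, chosen_score, FALSE, g))
  }
  selection_result(NA_character_, if (is.finite(best_seen)) best_seen else NA_real_,
                   FALSE, NA_character_)
}
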