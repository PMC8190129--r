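# Layout engine: inherit template coordinates for aligned nucleotides, place
# insertions by loop geometry, then minimise residual overlaps by exhaustive
# 30-degree rigid rotations of hairpin segments about the midpoint of their
# closing pair. Movement is deliberately conservative: deletions cause no
# compaction of the surviving coordinates, and only hairpin segments that
# participate in an overlap are ever rotated, so diagrams stay as close to
# the template as the query allows.

#' Initial placement from the alignment
#'
#' Every aligned query position receives, exactly, the template coordinate of
#' its aligned reference position; insertions remain unplaced. Deleted
#' template positions leave no hole-filling movement (no compaction).
#'
#' @param aln `rna_alignment` of the query against the template reference.
#' @param template the selected [rna_template()].
#' @param query_ss the query's transferred `rna_ss` (see [transfer_pairs()]).
#' @param labels optional per-position labels from [classify_bases()];
#'   defaults to `match` for aligned and `insertion` for unaligned positions.
#' @return object of class `layout_state`.
#' @export
initial_placement <- function(aln, template, query_ss, labels = NULL) {
  stopifnot(inherits(aln, "rna_alignment"), inherits(template, "rna_template"),
            inherits(query_ss, "rna_ss"))
  n <- query_ss$length
  cols <- aln$columns
  both <- !is.na(cols$template) & !is.na(cols$query)
  xy <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("x", "y")))
  xy[cols$query[both], 1] <- template$coords$x[cols$template[both]]
  xy[cols$query[both], 2] <- template$coords$y[cols$template[both]]
  if (is.null(labels)) {
    labels <- rep("insertion", n)
    labels[cols$query[both]] <- "match"
  }
  stopifnot(length(labels) == n)
  source <- ifelse(is.na(xy[, 1]), "unplaced", "template-inherited")
  tc <- as.matrix(template$coords[, c("x", "y")])
  spacing <- stats::median(sqrt(rowSums((tc[-1, , drop = FALSE] -
                                           tc[-nrow(tc), , drop = FALSE])^2)))
  structure(list(
    n = n, xy = xy, template_xy = xy, label = labels, source = source,
    ss = query_ss, tree = build_structure_tree(query_ss),
    spacing = spacing, rotations = list(),
    overlap_before = NA_integer_, overlap_after = NA_integer_
  ), class = "layout_state")
}

#' @export
print.layout_state <- function(x, ...) {
  cat("Layout state:", x$n, "positions,", sum(is.na(x$xy[, 1])), "unplaced\n")
  invisible(x)
}

# Ring positions of the loop closed by tree node `v`: the node's own pair
# bounds (absent for the exterior root), the boundary pairs of child helices,
# and the unpaired leaves.
loop_ring_positions <- function(tree, v) {
  pos <- integer(0)
  if (tree$kind[v] == "pair") pos <- c(tree$five[v], tree$three[v])
  for (ch in tree$children[[v]]) {
    if (tree$kind[ch] == "pair") pos <- c(pos, tree$five[ch], tree$three[ch])
    else pos <- c(pos, tree$five[ch])
  }
  sort(pos)
}

# Leaf parent lookup: node id of the parent of the leaf at position p.
leaf_parent <- function(tree, p) {
  leaf <- which(tree$kind == "leaf" & tree$five == p)
  tree$parent[leaf[1]]
}

#' Place insertions by loop geometry
#'
#' Interior insertions: the maximal run of consecutive unpaired query
#' positions containing the insertion is redistributed uniformly by angle on
#' a circle fitted to the loop's placed coordinates (centre = centroid,
#' radius = mean distance), between the two fixed anchor positions flanking
#' the run, which never move. In the exterior (root) loop the run is spaced
#' evenly on the straight segment between its anchors. 5'/3' tail insertions
#' extend along the direction of the terminal backbone segment at the
#' template's median backbone spacing. Non-insertion nucleotides moved by a
#' redistribution acquire the repositioned flag in [finalize_layout()].
#'
#' @param state a `layout_state` from [initial_placement()].
#' @return the updated `layout_state` with every position placed.
#' @export
place_insertions <- function(state) {
  stopifnot(inherits(state, "layout_state"))
  unplaced <- which(state$source == "unplaced")
  if (!length(unplaced)) return(state)
  n <- state$n
  if (length(unplaced) == n) stop("no placed coordinates to anchor insertions")
  runs <- split(unplaced, cumsum(c(1L, diff(unplaced) != 1L)))
  partner <- pairing_vector(state$ss)

  for (run in runs) {
    lo <- run[1]; hi <- run[length(run)]
    if (lo == 1L) {
      state <- place_tail(state, run, side = "five")
    } else if (hi == n) {
      state <- place_tail(state, run, side = "three")
    } else {
      # extend to the maximal unpaired run around the insertion
      loop_lo <- lo; loop_hi <- hi
      while (loop_lo > 1L && is.na(partner[loop_lo - 1L])) loop_lo <- loop_lo - 1L
      while (loop_hi < n && is.na(partner[loop_hi + 1L])) loop_hi <- loop_hi + 1L
      if (loop_lo == 1L || loop_hi == n) {
        # unpaired run touching a sequence end: treat as a tail
        state <- place_tail(state, run, side = if (loop_lo == 1L) "five" else "three")
        next
      }
      state <- place_loop_run(state, loop_lo, loop_hi)
    }
  }
  state$source[unplaced] <- "computed"
  stopifnot(all(is.finite(state$xy)))
  state
}

place_tail <- function(state, run, side) {
  s <- state$spacing
  n <- state$n
  if (side == "five") {
    base <- run[length(run)] + 1L
    ref <- base + 1L
    dirv <- if (ref <= n && !any(is.na(state$xy[ref, ]))) {
      state$xy[base, ] - state$xy[ref, ]
    } else c(-1, 0)
  } else {
    base <- run[1] - 1L
    ref <- base - 1L
    dirv <- if (ref >= 1L && !any(is.na(state$xy[ref, ]))) {
      state$xy[base, ] - state$xy[ref, ]
    } else c(1, 0)
  }
  nrm <- sqrt(sum(dirv^2))
  dirv <- if (nrm < 1e-12) c(if (side == "five") -1 else 1, 0) else dirv / nrm
  for (p in run) {
    k <- abs(p - base)
    state$xy[p, ] <- state$xy[base, ] + k * s * dirv
  }
  state
}

# Redistribute the unpaired run [loop_lo, loop_hi] between its anchors.
place_loop_run <- function(state, loop_lo, loop_hi) {
  a5 <- loop_lo - 1L; a3 <- loop_hi + 1L
  run <- loop_lo:loop_hi
  k <- length(run)
  p5 <- state$xy[a5, ]; p3 <- state$xy[a3, ]
  if (any(is.na(p5)) || any(is.na(p3))) {
    stop("anchors of an interior loop run are unplaced")
  }
  parent <- leaf_parent(state$tree, loop_lo)
  interior <- !is.na(parent) && state$tree$kind[parent] == "pair"

  if (interior) {
    ring <- loop_ring_positions(state$tree, parent)
    placed_ring <- ring[!is.na(state$xy[ring, 1])]
    guide <- setdiff(intersect(run, placed_ring), c(a5, a3))
    pts <- state$xy[placed_ring, , drop = FALSE]
    if (nrow(pts) >= 3) {
      centre <- colMeans(pts)
      radius <- mean(sqrt(rowSums(sweep(pts, 2, centre)^2)))
      if (radius > 1e-9) {
        th5 <- atan2(p5[2] - centre[2], p5[1] - centre[1])
        th3 <- atan2(p3[2] - centre[2], p3[1] - centre[1])
        d_ccw <- (th3 - th5) %% (2 * pi)
        ccw <- if (length(guide)) {
          ((atan2(state$xy[guide[1], 2] - centre[2],
                  state$xy[guide[1], 1] - centre[1]) - th5) %% (2 * pi)) <= d_ccw
        } else {
          # choose the arc free of the other ring members
          others <- setdiff(placed_ring, c(a5, a3))
          if (length(others)) {
            offs <- (atan2(state$xy[others, 2] - centre[2],
                           state$xy[others, 1] - centre[1]) - th5) %% (2 * pi)
            sum(offs < d_ccw) == 0
          } else d_ccw >= pi
        }
        sweep_angle <- if (ccw) d_ccw else d_ccw - 2 * pi
        t <- seq_len(k) / (k + 1)
        th <- th5 + sweep_angle * t
        state$xy[run, 1] <- centre[1] + radius * cos(th)
        state$xy[run, 2] <- centre[2] + radius * sin(th)
        return(state)
      }
    }
  }
  # exterior loop run or degenerate circle: even spacing on the chord
  t <- seq_len(k) / (k + 1)
  state$xy[run, 1] <- p5[1] + t * (p3[1] - p5[1])
  state$xy[run, 2] <- p5[2] + t * (p3[2] - p5[2])
  state
}

#' Count nucleotide overlaps
#'
#' Counts unordered position pairs closer than `d_min` (Euclidean),
#' excluding sequence-adjacent pairs and base-paired partners. Proximity of
#' nucleotide centres is the overlap metric; glyph outlines are not modelled.
#'
#' @param state a fully placed `layout_state`.
#' @param d_min distance threshold in template layout units; default 0.7 x
#'   the template's median backbone spacing.
#' @return list of class `overlap_report`: `count` and a two-column matrix
#'   `pairs` of offending positions (p < q).
#' @export
count_overlaps <- function(state, d_min = NULL) {
  stopifnot(inherits(state, "layout_state"))
  d_min <- d_min %||% (0.7 * state$spacing)
  if (anyNA(state$xy)) stop("all positions must be placed before overlap counting")
  count_overlaps_xy(state$xy, state$ss, d_min)
}

count_overlaps_xy <- function(xy, ss, d_min) {
  n <- nrow(xy)
  if (n < 2) {
    return(structure(list(count = 0L, pairs = matrix(integer(0), 0, 2)),
                     class = "overlap_report"))
  }
  close <- as.matrix(stats::dist(xy)) < d_min
  close[lower.tri(close, diag = TRUE)] <- FALSE
  idx <- which(close, arr.ind = TRUE)
  if (nrow(idx)) {
    p <- idx[, 1]; q <- idx[, 2]
    partner <- pairing_vector(ss)
    keep <- (q - p > 1L) & (is.na(partner[p]) | partner[p] != q)
    idx <- idx[keep, , drop = FALSE]
  }
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  dimnames(idx) <- NULL
  structure(list(count = nrow(idx), pairs = idx), class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("Overlaps:", x$count, "nucleotide pair(s) too close\n")
  invisible(x)
}

#' Enumerate hairpin segments
#'
#' A hairpin segment is a maximal stem-loop: the subtree under a pair node
#' containing no multibranch node (every node has at most one pair child),
#' whose parent is the exterior root or lies on a multibranch/non-linear
#' path. Segments are returned in 5'-to-3' order; each records the
#' contiguous member range and its rotation pivot, the midpoint of the root
#' pair's current coordinates.
#'
#' @param tree an `rna_tree`.
#' @param xy current coordinate matrix (used only for pivots; may be NULL).
#' @return list of `hairpin_segment` objects (`five`, `three`, `members`,
#'   `pivot`).
#' @export
enumerate_hairpins <- function(tree, xy = NULL) {
  stopifnot(inherits(tree, "rna_tree"))
  nn <- length(tree$kind)
  linear <- logical(nn)
  for (v in tree_postorder(tree)) {
    ch <- tree$children[[v]]
    pair_ch <- ch[tree$kind[ch] == "pair"]
    linear[v] <- tree$kind[v] != "root" &&
      length(pair_ch) <= 1L && all(linear[pair_ch])
  }
  roots <- which(tree$kind == "pair" & linear &
                   !linear[ifelse(is.na(tree$parent), 1L, tree$parent)])
  roots <- roots[order(tree$five[roots])]
  lapply(roots, function(v) {
    i <- tree$five[v]; j <- tree$three[v]
    pivot <- if (!is.null(xy)) (xy[i, ] + xy[j, ]) / 2 else c(NA_real_, NA_real_)
    structure(list(five = i, three = j, members = i:j, pivot = pivot),
              class = "hairpin_segment")
  })
}

#' Rigidly rotate a hairpin segment
#'
#' Rotates the segment's member coordinates about its pivot by `angle`
#' degrees; all other coordinates are untouched. Rigid: intra-segment
#' distances are preserved.
#'
#' @param state a `layout_state`.
#' @param segment a `hairpin_segment` from [enumerate_hairpins()].
#' @param angle rotation angle in degrees (counter-clockwise in a y-up frame;
#'   the stored y-down coordinates make it clockwise on screen).
#' @return the updated `layout_state`.
#' @export
rotate_segment <- function(state, segment, angle) {
  theta <- angle * pi / 180
  px <- segment$pivot[1]; py <- segment$pivot[2]
  m <- segment$members
  dx <- state$xy[m, 1] - px
  dy <- state$xy[m, 2] - py
  state$xy[m, 1] <- px + dx * cos(theta) - dy * sin(theta)
  state$xy[m, 2] <- py + dx * sin(theta) + dy * cos(theta)
  state
}

#' Resolve overlaps by exhaustive 30-degree hairpin rotations
#'
#' Repeats up to `max_passes` times: every hairpin segment (5' to 3') that
#' participates in at least one overlap is tested at all twelve 30-degree
#' rotations about its pivot; the rotation with the lowest global overlap
#' count is applied iff strictly lower than the current count. Ties prefer
#' the smaller rotation magnitude `min(theta, 360 - theta)`, then the
#' smaller angle. A pass that applies no rotation stops the search early.
#' The overlap count is non-increasing across accepted rotations.
#'
#' @param state a fully placed `layout_state`.
#' @param d_min overlap distance threshold (default 0.7 x median backbone
#'   spacing).
#' @param max_passes maximum number of sweeps over the hairpins (default 5).
#' @return the updated `layout_state`, carrying `overlap_before`,
#'   `overlap_after` and a log of applied `rotations`.
#' @export
resolve_overlaps <- function(state, d_min = NULL, max_passes = 5L) {
  stopifnot(inherits(state, "layout_state"))
  d_min <- d_min %||% (0.7 * state$spacing)
  current <- count_overlaps(state, d_min)
  state$overlap_before <- current$count
  state$overlap_after <- current$count
  if (current$count == 0L) return(state)

  hairpins <- enumerate_hairpins(state$tree, state$xy)
  angles <- seq(0, 330, by = 30)
  for (pass in seq_len(max_passes)) {
    applied <- FALSE
    for (h in hairpins) {
      current <- count_overlaps(state, d_min)
      if (current$count == 0L) break
      touches <- current$pairs[, 1] %in% h$members | current$pairs[, 2] %in% h$members
      if (!any(touches)) next
      counts <- vapply(angles, function(a) {
        if (a == 0) return(current$count)
        count_overlaps(rotate_segment(state, h, a), d_min)$count
      }, integer(1))
      best <- min(counts)
      if (best < current$count) {
        cand <- angles[counts == best]
        cand <- cand[order(pmin(cand, 360 - cand), cand)]
        chosen <- cand[1]
        state <- rotate_segment(state, h, chosen)
        state$rotations[[length(state$rotations) + 1L]] <-
          list(five = h$five, three = h$three, angle = chosen,
               overlaps_before = current$count, overlaps_after = best)
        applied <- TRUE
      }
    }
    state$overlap_after <- count_overlaps(state, d_min)$count
    if (state$overlap_after == 0L || !applied) break
  }
  state
}

#' Finalise the layout
#'
#' Flags as repositioned every non-insertion position whose final coordinate
#' is more than `eps_repos` away from its inherited template coordinate
#' (these are drawn blue unless their base also changed).
#'
#' @param state the optimised `layout_state`.
#' @param eps_repos displacement threshold in layout units (default 1e-6).
#' @return object of class `layout_result`: `xy`, `label`, `repositioned`,
#'   `overlap_before`, `overlap_after`, `rotations`.
#' @export
finalize_layout <- function(state, eps_repos = 1e-6) {
  stopifnot(inherits(state, "layout_state"))
  if (anyNA(state$xy)) stop("all positions must be placed before finalising")
  disp <- sqrt(rowSums((state$xy - state$template_xy)^2))
  repositioned <- state$label != "insertion" & !is.na(disp) & disp > eps_repos
  structure(list(
    xy = state$xy, label = state$label, repositioned = repositioned,
    ss = state$ss,
    overlap_before = state$overlap_before, overlap_after = state$overlap_after,
    rotations = state$rotations, spacing = state$spacing
  ), class = "layout_result")
}

#' @export
print.layout_result <- function(x, ...) {
  cat("Layout:", length(x$label), "nt;",
      sum(x$label == "insertion"), "inserted;",
      sum(x$repositioned), "repositioned; overlaps",
      x$overlap_before, "->", x$overlap_after, "\n")
  invisible(x)
}
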