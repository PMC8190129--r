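# Synthetic fixtures: random nested structures, a naive radial layout that
# turns them into templates, and a truth-tracked query mutator. Together they
# emulate a curated template library plus diverged family members, so every
# pipeline stage is testable without external data. Layout constants:
# backbone spacing 10 units, helix strand separation 8 units; the default
# overlap threshold downstream (0.7 x spacing = 7) matches these.

SYNTH_SPACING <- 10
SYNTH_PAIR_WIDTH <- 8

#' Generate a random nested secondary structure
#'
#' Samples a valid nested structure by stochastic-grammar expansion: at each
#' step the leading position either stays unpaired or (with probability
#' `pair_prob`, when at least 5 positions remain) opens a pair whose span is
#' chosen uniformly. Hairpin loops always contain at least 3 unpaired
#' nucleotides. Deterministic given `seed`.
#'
#' @param n structure length (>= 1).
#' @param seed integer seed.
#' @param pair_prob probability of opening a pair when geometrically
#'   possible (default 0.8; at this value roughly 45% of nucleotides
#'   end up paired, typical of structured RNAs).
#' @return an `rna_ss`.
#' @export
generate_random_structure <- function(n, seed = 1L, pair_prob = 0.8) {
  if (n < 1) stop("n must be >= 1")
  with_seed(seed, {
    gen <- function(L) {
      out <- character(0)
      while (L > 0) {
        if (L >= 5 && stats::runif(1) < pair_prob) {
          k <- if (L == 5) 5L else sample(5:L, 1L)
          out <- c(out, "(", gen(k - 2L), ")")
          L <- L - k
        } else {
          out <- c(out, ".")
          L <- L - 1L
        }
      }
      out
    }
    parse_dotbracket(paste(gen(as.integer(n)), collapse = ""))
  })
}

#' Random sequence compatible with a structure
#'
#' Unpaired positions draw uniformly from A/C/G/U; paired positions draw a
#' canonical duo (the four Watson-Crick duos with equal probability, or a
#' G-U wobble with probability `gu_prob`), so generated templates validate
#' with zero warnings about non-canonical pairs.
#'
#' @param ss an `rna_ss`.
#' @param seed integer seed.
#' @param gu_prob probability that a pair is a GU/UG wobble (default 0.1).
#' @return sequence string.
#' @export
random_sequence <- function(ss, seed = 1L, gu_prob = 0.1) {
  with_seed(seed, {
    bases <- sample(c("A", "C", "G", "U"), ss$length, replace = TRUE)
    p <- ss$pairs
    if (nrow(p)) {
      duos <- sample(c("AU", "UA", "CG", "GC", "GU", "UG"), nrow(p),
                     replace = TRUE,
                     prob = c(rep((1 - gu_prob) / 4, 4), gu_prob / 2, gu_prob / 2))
      bases[p$five] <- substr(duos, 1, 1)
      bases[p$three] <- substr(duos, 2, 2)
    }
    paste(bases, collapse = "")
  })
}

#' Classic radial layout of a structure
#'
#' Draws helices as parallel strand pairs (backbone spacing 10, inter-strand
#' width 8) and every loop as a circle sized to its member count; exterior
#' nucleotides lie on a horizontal line with helices extending upward.
#' Exterior subtrees are packed left-to-right with bounding-box separation so
#' neighbouring stem-loops cannot collide. Deterministic.
#'
#' @param ss an `rna_ss`.
#' @param sequence nucleotide string of equal length.
#' @param id template id for the resulting template.
#' @param metadata optional metadata list.
#' @return an [rna_template()] whose coordinates are the radial drawing.
#' @export
radial_layout <- function(ss, sequence, id = "synthetic", metadata = list(),
                          clearance = 8) {
  sequence <- normalize_seq(sequence)
  if (nchar(sequence) != ss$length) stop("sequence/structure length mismatch")
  s <- SYNTH_SPACING; w <- SYNTH_PAIR_WIDTH
  tree <- build_structure_tree(ss)
  n <- ss$length

  # Each stem subtree is laid out bottom-up in a local frame (entry pair at
  # (-w/2, 0) / (w/2, 0), growing towards -y) and summarised by a bounding
  # disc. Loops size their circle so that every child disc gets a
  # non-overlapping angular wedge (with `clearance` units of slack), which
  # makes the assembled drawing collision-free by construction.
  rot_move <- function(xy, theta, origin) {
    # map local frame so that local -y becomes the unit direction u(theta)
    alpha <- atan2(cos(theta), -sin(theta))
    R <- matrix(c(cos(alpha), sin(alpha), -sin(alpha), cos(alpha)), 2, 2)
    sweep_rows <- !is.na(xy[, 1])
    out <- xy
    out[sweep_rows, ] <- t(R %*% t(xy[sweep_rows, , drop = FALSE])) +
      matrix(origin, sum(sweep_rows), 2, byrow = TRUE)
    out
  }

  layout_pair <- function(v) {
    xy <- matrix(NA_real_, n, 2)
    xy[tree$five[v], ] <- c(-w / 2, 0)
    xy[tree$three[v], ] <- c(w / 2, 0)
    ch <- tree$children[[v]]
    if (length(ch) == 1L && tree$kind[ch] == "pair") {
      sub <- layout_pair(ch)
      filled <- !is.na(sub$xy[, 1])
      sub$xy[filled, 2] <- sub$xy[filled, 2] - s
      xy[filled, ] <- sub$xy[filled, ]
    } else if (length(ch)) {
      subs <- lapply(ch, function(ci) {
        if (tree$kind[ci] == "pair") layout_pair(ci) else NULL
      })
      m <- 2L + sum(ifelse(tree$kind[ch] == "pair", 2L, 1L))
      R <- max((w + (m - 1L) * s) / (2 * pi), w / 2 + 0.5)
      # grow the circle until every element's wedge fits
      for (iter in 1:60) {
        phi <- vapply(seq_along(ch), function(k) {
          if (tree$kind[ch[k]] == "leaf") return((s / 2) / R)
          d <- subs[[k]]$disc
          D <- sqrt((R - d[2])^2 + d[1]^2)  # distance of disc centre from loop centre
          ratio <- (d[3] + clearance) / max(D, 1e-9)
          # widen by the disc centre's lateral offset from the mount direction
          skew <- abs(atan2(d[1], R - d[2]))
          if (ratio >= 0.999) pi else asin(ratio) + skew
        }, numeric(1))
        needed <- 2 * (s / 2) / R + sum(2 * phi)  # chord-edge slack + wedges
        avail <- 2 * pi - 2 * asin(min(1, (w / 2) / R))
        if (needed <= avail) break
        R <- R * max(1.05, needed / avail)
      }
      h <- sqrt(R^2 - (w / 2)^2)
      centre <- c(0, -h)
      th5 <- atan2(0 - centre[2], -w / 2 - centre[1])
      th3 <- atan2(0 - centre[2], w / 2 - centre[1])
      d_ccw <- (th3 - th5) %% (2 * pi)
      sweep_dir <- if (d_ccw > pi) 1 else -1
      span_angle <- if (d_ccw > pi) d_ccw else 2 * pi - d_ccw
      # spare angle goes to the gaps flanking pair children (leaf runs keep
      # their natural backbone spacing, so the median step stays at s)
      kinds <- tree$kind[ch]
      gap_gets <- vapply(seq_len(length(ch) + 1L), function(g) {
        (g > 1L && kinds[g - 1L] == "pair") ||
          (g <= length(ch) && kinds[g] == "pair")
      }, logical(1))
      if (!any(gap_gets)) gap_gets[] <- TRUE
      slack <- (span_angle - needed) / sum(gap_gets)
      cur <- (s / 2) / R + if (gap_gets[1]) slack else 0
      for (k in seq_along(ch)) {
        ci <- ch[k]
        th <- th5 + sweep_dir * (cur + phi[k])
        u <- c(cos(th), sin(th))
        if (tree$kind[ci] == "leaf") {
          xy[tree$five[ci], ] <- centre + R * u
        } else {
          sub_xy <- rot_move(subs[[k]]$xy, th, centre + R * u)
          filled <- !is.na(sub_xy[, 1])
          xy[filled, ] <- sub_xy[filled, ]
        }
        cur <- cur + 2 * phi[k] + if (gap_gets[k + 1L]) slack else 0
      }
    }
    pts <- xy[!is.na(xy[, 1]), , drop = FALSE]
    cmid <- c((min(pts[, 1]) + max(pts[, 1])) / 2,
              (min(pts[, 2]) + max(pts[, 2])) / 2)
    rho <- max(sqrt((pts[, 1] - cmid[1])^2 + (pts[, 2] - cmid[2])^2))
    list(xy = xy, disc = c(cmid, rho))
  }

  # exterior line: leaves at spacing s, stem subtrees packed with disc
  # clearance against everything already placed
  xy <- matrix(NA_real_, n, 2)
  cursor <- 0
  discs <- matrix(numeric(0), 0, 3)  # cx, cy, rho of placed subtrees
  pts_x <- numeric(0)                # exterior leaf x positions (y = 0)
  for (ci in tree$children[[tree$root]]) {
    if (tree$kind[ci] == "leaf") {
      # clear any previously placed subtree disc
      if (nrow(discs)) {
        for (r in seq_len(nrow(discs))) {
          need <- discs[r, 3] + clearance
          if (abs(discs[r, 2]) < need) {
            xmin <- discs[r, 1] + sqrt(need^2 - discs[r, 2]^2)
            if (cursor < xmin && cursor > discs[r, 1] - need) cursor <- xmin
          }
        }
      }
      xy[tree$five[ci], ] <- c(cursor, 0)
      pts_x <- c(pts_x, cursor)
      cursor <- cursor + s
    } else {
      sub <- layout_pair(ci)
      # entry midpoint at (cursor + w/2, 0), growing upward (-y)
      entry <- c(cursor + w / 2, 0)
      d <- sub$disc
      shift <- 0
      repeat {
        cx <- entry[1] + shift + d[1]; cy <- d[2]
        delta <- 0
        if (nrow(discs)) {
          for (r in seq_len(nrow(discs))) {
            need <- d[3] + discs[r, 3] + clearance
            dy <- cy - discs[r, 2]
            if (abs(dy) < need) {
              xmin <- discs[r, 1] + sqrt(need^2 - dy^2)
              if (cx < xmin) delta <- max(delta, xmin - cx)
            }
          }
        }
        for (px in pts_x) {
          need <- d[3] + clearance
          if (abs(cy) < need) {
            xmin <- px + sqrt(need^2 - cy^2)
            if (cx < xmin) delta <- max(delta, xmin - cx)
          }
        }
        if (delta <= 1e-9) break
        shift <- shift + delta
      }
      entry[1] <- entry[1] + shift
      sub_xy <- sub$xy
      filled <- !is.na(sub_xy[, 1])
      sub_xy[filled, 1] <- sub_xy[filled, 1] + entry[1]
      sub_xy[filled, 2] <- sub_xy[filled, 2] + entry[2]
      xy[filled, ] <- sub_xy[filled, ]
      discs <- rbind(discs, c(entry[1] + d[1], d[2], d[3]))
      cursor <- xy[tree$three[ci], 1] + s
    }
  }
  rna_template(id, sequence, ss, data.frame(x = xy[, 1], y = xy[, 2]),
               metadata = metadata)
}

#' Synthesise a complete random template
#'
#' Convenience wrapper: random structure + compatible random sequence +
#' radial layout.
#'
#' @param n template length.
#' @param seed integer seed (drives structure and sequence).
#' @param pair_prob see [generate_random_structure()].
#' @param id template id; default derived from the seed.
#' @param metadata metadata list for the template.
#' @return an [rna_template()].
#' @export
synthesize_template <- function(n, seed = 1L, pair_prob = 0.8,
                                id = sprintf("synth-%05d", seed),
                                metadata = list(structure_source = "covariation")) {
  ss <- generate_random_structure(n, seed = seed, pair_prob = pair_prob)
  seq <- random_sequence(ss, seed = seed + 1L)
  radial_layout(ss, seq, id = id, metadata = metadata)
}

#' Mutation rates for the synthetic query generator
#'
#' @param sub_rate per-position substitution probability.
#' @param ins_rate probability of starting an insertion after each position;
#'   insertion lengths are geometric with mean 1.5 (small insertions, since
#'   large ones are poorly accommodated by template layouts).
#' @param del_rate per-position deletion probability.
#' @return list of class `mutation_rates`.
#' @export
mutation_rates <- function(sub_rate = 0.05, ins_rate = 0.02, del_rate = 0.02) {
  for (r in c(sub_rate, ins_rate, del_rate)) {
    if (r < 0 || r > 1) stop("rates must be in [0, 1]")
  }
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate, del_rate = del_rate),
            class = "mutation_rates")
}

#' Mutate a template reference into a synthetic query
#'
#' Applies i.i.d. per-position substitutions and deletions and geometric-
#' length insertions after positions, recording the ground truth per emitted
#' query position: its template position of origin (NA for insertions) and
#' its intended classification label. Deterministic given `seed`.
#'
#' When an inserted base equals a neighbouring base, several mutation
#' histories produce the same query and are observationally
#' indistinguishable; the truth table reports the canonical representative
#' of that equivalence class, with insertions placed leftmost within runs of
#' equal bases (the same convention the deterministic alignment traceback
#' uses for gap placement).
#'
#' @param template an [rna_template()].
#' @param rates a [mutation_rates()].
#' @param seed integer seed.
#' @return list with `query` (sequence string) and `truth` (data frame:
#'   `position`, `origin`, `label`).
#' @export
mutate_target <- function(template, rates = mutation_rates(), seed = 1L) {
  stopifnot(inherits(template, "rna_template"), inherits(rates, "mutation_rates"))
  ref <- strsplit(template$sequence, "", fixed = TRUE)[[1]]
  nts <- c("A", "C", "G", "U")
  with_seed(seed, {
    out <- character(0); origin <- integer(0); label <- character(0)
    for (i in seq_along(ref)) {
      if (stats::runif(1) < rates$del_rate) {
        # deleted: contributes nothing to the query
      } else if (stats::runif(1) < rates$sub_rate) {
        b <- sample(setdiff(nts, ref[i]), 1L)
        out <- c(out, b); origin <- c(origin, i); label <- c(label, "changed")
      } else {
        out <- c(out, ref[i]); origin <- c(origin, i); label <- c(label, "match")
      }
      if (stats::runif(1) < rates$ins_rate) {
        len <- stats::rgeom(1, 2 / 3) + 1L
        ins <- sample(nts, len, replace = TRUE)
        out <- c(out, ins)
        origin <- c(origin, rep(NA_integer_, len))
        label <- c(label, rep("insertion", len))
      }
    }
    # canonicalise: shift insertion runs leftmost; an insertion run [a..b]
    # can rotate one step left whenever the base before it equals its last
    # base (the two mutation histories emit the same query)
    repeat {
      moved <- FALSE
      is_ins <- label == "insertion"
      if (any(is_ins)) {
        runs <- split(which(is_ins), cumsum(c(1L, diff(which(is_ins)) != 1L)))
        for (run in runs) {
          a <- run[1]; b <- run[length(run)]
          # shift is history-preserving when the displaced base re-emits the
          # same character (equal bases), and always across a substituted
          # position (the substitution simply applies to the run's last base)
          while (a > 1L && label[a - 1L] != "insertion" &&
                 (out[a - 1L] == out[b] || label[a - 1L] == "changed")) {
            origin[b] <- origin[a - 1L]
            label[b] <- if (out[b] == ref[origin[b]]) "match" else "changed"
            origin[a - 1L] <- NA_integer_; label[a - 1L] <- "insertion"
            a <- a - 1L; b <- b - 1L
            moved <- TRUE
          }
        }
      }
      if (!moved) break
    }
    list(query = paste(out, collapse = ""),
         truth = data.frame(position = seq_along(out), origin = origin,
                            label = label))
  })
}

#' Simulate a template library plus mutated queries
#'
#' Generates `n_templates` random templates (one library group) and
#' `n_queries` queries, each obtained by mutating the reference of a
#' randomly chosen template; optionally writes the library directory, a
#' query FASTA and a truth TSV. The defaults (20 templates of 100-300 nt,
#' 200 queries at 5% substitutions, 2% insertions, 2% deletions) are the
#' study conditions used throughout the test-suite.
#'
#' @param out_dir optional output directory; when given, writes
#'   `library/synthetic/<id>.{fasta,xml}`, `queries.fasta` and `truth.tsv`.
#' @param n_templates number of templates (default 20).
#' @param length_range template length range (default 100-300 nt).
#' @param n_queries number of mutated queries (default 200).
#' @param rates a [mutation_rates()].
#' @param seed integer master seed.
#' @return list with `templates`, `queries` (named character vector),
#'   `truth` (list of per-query truth tables), `source` (named character
#'   vector: true source template per query), and file paths when written.
#' @export
simulate_dataset <- function(out_dir = NULL, n_templates = 20L,
                             length_range = c(100L, 300L), n_queries = 200L,
                             rates = mutation_rates(), seed = 1L) {
  lens <- with_seed(seed, sample(length_range[1]:length_range[2], n_templates,
                                 replace = TRUE))
  templates <- lapply(seq_len(n_templates), function(i) {
    synthesize_template(lens[i], seed = seed * 1000L + i,
                        id = sprintf("synth-%03d", i))
  })
  names(templates) <- vapply(templates, `[[`, "", "id")
  src_idx <- with_seed(seed + 1L, sample(n_templates, n_queries, replace = TRUE))
  queries <- character(n_queries); truth <- vector("list", n_queries)
  for (q in seq_len(n_queries)) {
    mt <- mutate_target(templates[[src_idx[q]]], rates, seed = seed * 2000L + q)
    queries[q] <- mt$query
    truth[[q]] <- mt$truth
  }
  qids <- sprintf("query-%03d", seq_len(n_queries))
  names(queries) <- qids
  names(truth) <- qids
  source <- stats::setNames(names(templates)[src_idx], qids)

  paths <- NULL
  if (!is.null(out_dir)) {
    gdir <- file.path(out_dir, "library", "synthetic")
    dir.create(gdir, showWarnings = FALSE, recursive = TRUE)
    for (t in templates) {
      write_template(t, file.path(gdir, paste0(t$id, ".fasta")),
                     file.path(gdir, paste0(t$id, ".xml")))
    }
    qfa <- file.path(out_dir, "queries.fasta")
    writeLines(as.vector(rbind(paste0(">", qids), queries)), qfa)
    ttsv <- file.path(out_dir, "truth.tsv")
    tt <- do.call(rbind, lapply(qids, function(id) {
      cbind(query_id = id, source_template = source[[id]], truth[[id]])
    }))
    utils::write.table(tt, ttsv, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- list(library = file.path(out_dir, "library"), queries = qfa,
                  truth = ttsv)
  }
  list(templates = templates, queries = queries, truth = truth,
       source = source, paths = paths)
}
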