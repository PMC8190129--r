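# A small single-hairpin template used by several layout tests:
# 5' tail - 2-pair stem - 4-nt loop - 3' tail.
hairpin_template <- function() {
  ss <- parse_dotbracket("..((....))..")
  radial_layout(ss, "GAGCAUUAGCAC", id = "hp")
}

test_that("identity placement inherits every template coordinate exactly", {
  tpl <- synthesize_template(70, seed = 5)
  aln <- align_global(tpl$sequence, tpl$sequence)
  st <- initial_placement(aln, tpl, tpl$structure)
  expect_identical(st$xy[, 1], tpl$coords$x)
  expect_identical(st$xy[, 2], tpl$coords$y)
  expect_true(all(st$source == "template-inherited"))

  # a deletion causes no compaction: surviving positions keep their own coords
  q <- paste(strsplit(tpl$sequence, "")[[1]][-10], collapse = "")
  a2 <- align_global(q, tpl$sequence)
  st2 <- initial_placement(a2, tpl, transfer_pairs(a2, tpl$structure))
  kept <- a2$columns[!is.na(a2$columns$template) & !is.na(a2$columns$query), ]
  expect_equal(st2$xy[kept$query, 1], tpl$coords$x[kept$template])
  expect_equal(st2$xy[kept$query, 2], tpl$coords$y[kept$template])
})

test_that("a loop insertion redistributes the loop on the fitted circle", {
  tpl <- hairpin_template()
  # insert one nucleotide into the middle of the 4-nt hairpin loop (after
  # template position 6)
  ref <- strsplit(tpl$sequence, "")[[1]]
  query <- paste(c(ref[1:6], "A", ref[7:12]), collapse = "")
  aln <- align_global(query, tpl$sequence)
  qss <- transfer_pairs(aln, tpl$structure)
  st <- initial_placement(aln, tpl, qss, classify_bases(aln, query, tpl$sequence))
  expect_equal(sum(st$source == "unplaced"), 1L)
  st <- place_insertions(st)

  # anchors (the closing pair of the query: positions 4 and 10) never move
  expect_equal(st$xy[4, ], st$template_xy[4, ])
  expect_equal(st$xy[10, ], st$template_xy[10, ])

  # geometric oracle: circle fitted to the placed loop ring (anchors + the
  # four placed loop nucleotides), five nucleotides equally spaced in angle
  ring_q <- c(4L, 5L, 6L, 8L, 9L, 10L)       # placed ring members (query idx)
  pts <- st$template_xy[ring_q, ]
  centre <- colMeans(pts)
  radius <- mean(sqrt(rowSums(sweep(pts, 2, centre)^2)))
  ang <- function(p) atan2(p[2] - centre[2], p[1] - centre[1])
  th5 <- ang(st$xy[4, ]); th3 <- ang(st$xy[10, ])
  guide <- ang(st$template_xy[5, ])
  d_ccw <- (th3 - th5) %% (2 * pi)
  sweep_a <- if (((guide - th5) %% (2 * pi)) <= d_ccw) d_ccw else d_ccw - 2 * pi
  expected <- t(vapply(1:5, function(t) {
    th <- th5 + sweep_a * t / 6
    centre + radius * c(cos(th), sin(th))
  }, numeric(2)))
  expect_equal(unname(st$xy[5:9, ]), unname(expected), tolerance = 1e-9)

  # classification coherence downstream
  st <- resolve_overlaps(st)
  lay <- finalize_layout(st)
  expect_equal(sum(lay$label == "insertion"), 1L)
  moved <- which(lay$repositioned)
  expect_equal(moved, setdiff(5:9, 7))  # the redistributed matched loop bases
})

test_that("tail insertions extend the terminal backbone segment", {
  tpl <- hairpin_template()
  ref <- tpl$sequence
  query <- paste0(ref, "GU")   # two 3' tail insertions
  aln <- align_global(query, ref)
  st <- initial_placement(aln, tpl, transfer_pairs(aln, tpl$structure),
                          classify_bases(aln, query, ref))
  st <- place_insertions(st)
  s <- st$spacing
  d <- st$xy[12, ] - st$xy[11, ]
  d <- d / sqrt(sum(d^2))
  expect_equal(st$xy[13, ], st$xy[12, ] + s * d, tolerance = 1e-9)
  expect_equal(st$xy[14, ], st$xy[12, ] + 2 * s * d, tolerance = 1e-9)

  query5 <- paste0("GU", ref)  # and at the 5' end
  a5 <- align_global(query5, ref)
  st5 <- initial_placement(a5, tpl, transfer_pairs(a5, tpl$structure),
                           classify_bases(a5, query5, ref))
  st5 <- place_insertions(st5)
  d5 <- st5$xy[3, ] - st5$xy[4, ]
  d5 <- d5 / sqrt(sum(d5^2))
  expect_equal(st5$xy[2, ], st5$xy[3, ] + s * d5, tolerance = 1e-9)
  expect_equal(st5$xy[1, ], st5$xy[3, ] + 2 * s * d5, tolerance = 1e-9)
})

test_that("zero insertions leave the layout untouched", {
  tpl <- synthesize_template(50, seed = 9)
  aln <- align_global(tpl$sequence, tpl$sequence)
  st <- initial_placement(aln, tpl, tpl$structure)
  st2 <- place_insertions(st)
  expect_identical(st$xy, st2$xy)
})

test_that("count_overlaps matches the O(n^2) reference on random layouts", {
  # hand-built: two non-adjacent nucleotides at identical coordinates
  ss <- secondary_structure(4)
  st <- structure(list(n = 4L,
                       xy = rbind(c(0, 0), c(10, 0), c(0, 0), c(30, 0)),
                       template_xy = NULL, label = rep("match", 4),
                       source = rep("template-inherited", 4), ss = ss,
                       tree = build_structure_tree(ss), spacing = 10,
                       rotations = list()), class = "layout_state")
  rep1 <- count_overlaps(st, 7)
  expect_equal(rep1$count, 1L)
  expect_equal(rep1$pairs, matrix(c(1L, 3L), 1))

  # base-paired partners and sequence neighbours are excluded
  ss2 <- parse_dotbracket("(..)")
  st$ss <- ss2; st$tree <- build_structure_tree(ss2)
  st$xy <- rbind(c(0, 0), c(3, 0), c(6, 0), c(0.5, 0))
  rep2 <- count_overlaps(st, 7)
  expect_equal(oracle_count_overlaps(st$xy, ss2, 7), rep2$count)

  # randomized equivalence with the double-loop oracle
  withr::local_seed(11)
  for (case in 1:100) {
    n <- sample(10:60, 1)
    ss <- generate_random_structure(n, seed = case)
    xy <- matrix(runif(2 * n, 0, 60), n, 2)
    st$ss <- ss; st$tree <- build_structure_tree(ss); st$n <- n
    st$xy <- xy; st$label <- rep("match", n); st$source <- rep("computed", n)
    d <- runif(1, 3, 12)
    expect_equal(count_overlaps(st, d)$count, oracle_count_overlaps(xy, ss, d))
  }
})

test_that("hairpin enumeration finds maximal stem-loops in order", {
  h1 <- enumerate_hairpins(build_structure_tree(parse_dotbracket("(((...)))")))
  expect_length(h1, 1L)
  expect_equal(h1[[1]]$members, 1:9)

  h2 <- enumerate_hairpins(build_structure_tree(parse_dotbracket("((...))((...))")))
  expect_length(h2, 2L)
  expect_equal(h2[[1]]$five, 1L); expect_equal(h2[[2]]$five, 8L)

  # multibranch: the hairpins root below the multiloop, not at it
  h3 <- enumerate_hairpins(build_structure_tree(parse_dotbracket("((...)(...))")))
  expect_length(h3, 2L)
  expect_equal(h3[[1]]$members, 2:6)
  expect_equal(h3[[2]]$members, 7:11)

  # bulged stems still form a single hairpin segment
  h4 <- enumerate_hairpins(build_structure_tree(parse_dotbracket("((.((...))))")))
  expect_length(h4, 1L)
  expect_equal(h4[[1]]$members, 1:12)
})

test_that("segment rotation is rigid and 360 degrees is the identity", {
  tpl <- synthesize_template(60, seed = 13)
  aln <- align_global(tpl$sequence, tpl$sequence)
  st <- initial_placement(aln, tpl, tpl$structure)
  hps <- enumerate_hairpins(st$tree, st$xy)
  expect_gt(length(hps), 0L)
  h <- hps[[1]]

  st360 <- rotate_segment(st, h, 360)
  expect_equal(st360$xy, st$xy, tolerance = 1e-9)

  # a point one unit right of the pivot moves to one unit "down" under +90
  st_probe <- st
  st_probe$xy[h$members[1], ] <- h$pivot + c(1, 0)
  out <- rotate_segment(st_probe, h, 90)
  expect_equal(out$xy[h$members[1], ], h$pivot + c(0, 1), tolerance = 1e-9)

  withr::local_seed(3)
  for (a in runif(5, 0, 360)) {
    rot <- rotate_segment(st, h, a)
    d0 <- dist(st$xy[h$members, ])
    d1 <- dist(rot$xy[h$members, ])
    expect_equal(as.vector(d1), as.vector(d0), tolerance = 1e-9)
    # non-members untouched
    expect_identical(rot$xy[-h$members, ], st$xy[-h$members, ])
  }
})

test_that("resolve_overlaps picks the 12-angle argmin and never regresses", {
  fixtures <- 0L
  seed <- 0L
  while (fixtures < 50L) {
    seed <- seed + 1L
    tpl <- synthesize_template(sample(40:90, 1), seed = 3000L + seed)
    aln <- align_global(tpl$sequence, tpl$sequence)
    st <- initial_placement(aln, tpl, tpl$structure)
    hps <- enumerate_hairpins(st$tree, st$xy)
    if (length(hps) < 2L) next
    # deliberately rotate one hairpin into the body of the structure
    h <- hps[[withr::with_seed(seed, sample(length(hps), 1))]]
    bad <- rotate_segment(st, h, withr::with_seed(seed, sample(c(90, 120, 150, 180), 1)))
    d_min <- 7
    before <- count_overlaps(bad, d_min)$count
    if (before == 0L) next
    fixtures <- fixtures + 1L

    solved <- resolve_overlaps(bad, d_min = d_min)
    expect_lte(solved$overlap_after, before)
    expect_equal(solved$overlap_before, before)
    expect_gt(length(solved$rotations), 0L)

    # the first applied rotation must equal the independent 12-angle argmin
    # for that hairpin evaluated on the pre-rotation state
    first <- solved$rotations[[1]]
    profile <- oracle_rotation_profile(bad$xy, bad$ss, first$five, first$three,
                                       d_min)
    angles <- seq(0, 330, by = 30)
    best <- min(profile)
    cand <- angles[profile == best]
    cand <- cand[order(pmin(cand, 360 - cand), cand)]
    expect_equal(first$angle, cand[1])
    expect_equal(first$overlaps_after, best)
  }
  expect_equal(fixtures, 50L)
})

test_that("zero-overlap layouts pass through resolve_overlaps unchanged", {
  tpl <- synthesize_template(60, seed = 17)
  aln <- align_global(tpl$sequence, tpl$sequence)
  st <- initial_placement(aln, tpl, tpl$structure)
  out <- resolve_overlaps(st)
  expect_identical(out$xy, st$xy)
  expect_equal(out$overlap_before, 0L)
  expect_equal(out$overlap_after, 0L)
  lay <- finalize_layout(out)
  expect_equal(sum(lay$repositioned), 0L)
})
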