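test_that("random structures are valid, deterministic and respect loop minimum", {
  expect_equal(nrow(generate_random_structure(1, seed = 1)$pairs), 0L)
  expect_error(generate_random_structure(0), ">= 1")

  a <- generate_random_structure(80, seed = 42)
  b <- generate_random_structure(80, seed = 42)
  expect_true(a == b)

  for (seed in 1:50) {
    ss <- generate_random_structure(sample(5:150, 1), seed = seed)
    tree <- build_structure_tree(ss)
    # hairpin loops (pair nodes with only leaf children) hold >= 3 leaves
    for (v in which(tree$kind == "pair")) {
      ch <- tree$children[[v]]
      if (all(tree$kind[ch] == "leaf")) expect_gte(length(ch), 3L)
    }
  }
})

test_that("pair fraction stays near the generator's calibrated expectation", {
  # frozen Monte-Carlo calibration of the default generator at n = 100:
  # paired fraction mean 0.4502, sd 0.0308 (2000 seeds)
  fractions <- vapply(2001:2300, function(s) {
    ss <- generate_random_structure(100, seed = s)
    2 * nrow(ss$pairs) / 100
  }, numeric(1))
  expect_lt(abs(mean(fractions) - 0.4502), 3 * 0.0308 / sqrt(300))
})

test_that("radial layouts satisfy the documented geometry", {
  tpl <- radial_layout(parse_dotbracket("((...))"), "GCAAAGC")
  xy <- as.matrix(tpl$coords)
  # helix strands collinear at spacing 10
  expect_equal(sqrt(sum((xy[2, ] - xy[1, ])^2)), 10)
  expect_equal(sqrt(sum((xy[7, ] - xy[6, ])^2)), 10)
  expect_equal(sqrt(sum((xy[1, ] - xy[7, ])^2)), 8)   # strand separation
  expect_equal(sqrt(sum((xy[2, ] - xy[6, ])^2)), 8)
  # loop nucleotides equidistant from the loop centre: take the circumcentre
  # of three ring points and check every ring point shares that radius
  ring <- xy[2:6, ]
  circumcentre <- function(a, b, c) {
    ax <- a[1]; ay <- a[2]; bx <- b[1]; by <- b[2]; cx <- c[1]; cy <- c[2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    c((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
        (cx^2 + cy^2) * (ay - by),
      (ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
        (cx^2 + cy^2) * (bx - ax)) / d
  }
  ctr <- circumcentre(ring[1, ], ring[3, ], ring[5, ])
  d <- sqrt(rowSums(sweep(ring, 2, ctr)^2))
  expect_lt(diff(range(d)), 1e-6)

  chain <- radial_layout(parse_dotbracket("...."), "ACGU")
  expect_equal(chain$coords$y, rep(0, 4))
  expect_equal(diff(chain$coords$x), rep(10, 3))
})

test_that("synthetic templates are overlap-free and validate cleanly", {
  for (seed in 1:100) {
    tpl <- synthesize_template(sample(20:60, 1), seed = 7000L + seed)
    rep <- validate_template(tpl)
    expect_true(rep$ok)
    expect_length(rep$warnings, 0L)
    aln <- align_global(tpl$sequence, tpl$sequence)
    st <- initial_placement(aln, tpl, tpl$structure)
    expect_equal(count_overlaps(st, 7)$count, 0L, info = paste("seed", seed))
  }
})

test_that("mutate_target is deterministic and honest about its truth table", {
  tpl <- synthesize_template(120, seed = 31)
  clean <- mutate_target(tpl, mutation_rates(0, 0, 0), seed = 1)
  expect_equal(clean$query, tpl$sequence)
  expect_true(all(clean$truth$label == "match"))
  expect_equal(clean$truth$origin, seq_len(120))

  m1 <- mutate_target(tpl, mutation_rates(0.1, 0.05, 0.05), seed = 9)
  m2 <- mutate_target(tpl, mutation_rates(0.1, 0.05, 0.05), seed = 9)
  expect_identical(m1, m2)
  expect_equal(nrow(m1$truth), nchar(m1$query))
  # truth labels are consistent with the recorded origins
  ref <- strsplit(tpl$sequence, "")[[1]]
  qc <- strsplit(m1$query, "")[[1]]
  ok <- !is.na(m1$truth$origin)
  expect_true(all((qc[ok] == ref[m1$truth$origin[ok]]) ==
                    (m1$truth$label[ok] == "match")))
})

test_that("classification recovers the mutation truth for non-inserted bases", {
  recovered <- 0L; total <- 0L
  for (seed in 1:30) {
    tpl <- synthesize_template(200, seed = 8000L + seed)
    mt <- mutate_target(tpl, mutation_rates(0.05, 0.02, 0.02),
                        seed = 9000L + seed)
    aln <- align_global(mt$query, tpl$sequence)
    labs <- classify_bases(aln, mt$query, tpl$sequence)
    keep <- mt$truth$label != "insertion"
    recovered <- recovered + sum(labs[keep] == mt$truth$label[keep])
    total <- total + sum(keep)
  }
  expect_gte(recovered / total, 0.99)
})
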