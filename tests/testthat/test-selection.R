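test_that("score_query equals brute-force local alignment on short sequences", {
  t_uuuu <- rna_template("u4", "UUUU", "....", data.frame(x = 0:3 * 10, y = 0))
  sc <- score_query("ACGU", t_uuuu)
  expect_gte(sc, 2)  # at least the single best match
  expect_lt(sc, 8)
  expect_equal(sc, oracle_local_score("ACGU", "UUUU"))

  withr::local_seed(7)
  for (case in 1:60) {
    q <- random_rna(sample(1:8, 1))
    r <- random_rna(sample(1:8, 1))
    tpl <- rna_template("t", r, strrep(".", nchar(r)),
                        data.frame(x = seq_len(nchar(r)) * 10, y = 0))
    expect_equal(score_query(q, tpl), oracle_local_score(q, r),
                 info = paste(q, r))
  }
  expect_error(score_query("", t_uuuu), "empty")
})

test_that("identical query scores 2n and selects its own template", {
  tpl <- synthesize_template(80, seed = 11)
  expect_equal(score_query(tpl$sequence, tpl), 2 * 80)
  sel <- select_template(tpl$sequence, list(tpl))
  expect_equal(sel$template_id, tpl$id)
  expect_equal(sel$score, 160)
  expect_false(sel$multiple_hits)
})

test_that("multiple well-separated hits are detected", {
  tpl <- synthesize_template(80, seed = 21)
  ref <- strsplit(tpl$sequence, "")[[1]]
  expect_false(detect_multiple_hits(tpl$sequence, tpl))

  spacer <- withr::with_seed(5, random_rna(80))
  split_query <- paste0(paste(ref[1:40], collapse = ""), spacer,
                        paste(ref[41:80], collapse = ""))
  expect_true(detect_multiple_hits(split_query, tpl))

  # a query shorter than the reference with one internal deletion: one hit
  del_query <- paste(ref[c(1:30, 45:80)], collapse = "")
  expect_false(detect_multiple_hits(del_query, tpl))
})

test_that("random queries match nothing: every score stays below acceptance", {
  lib <- lapply(1:6, function(i) synthesize_template(100, seed = 400L + i,
                                                     id = sprintf("t%02d", i)))
  p <- scoring_params()
  withr::local_seed(33)
  for (rep in 1:10) {
    q <- random_rna(100)
    scores <- vapply(lib, function(t) score_query(q, t), numeric(1))
    lines <- vapply(lib, function(t) {
      p$accept_threshold + p$null_rate * min(nchar(q), nchar(t$sequence))
    }, numeric(1))
    expect_true(all(scores < lines),
                info = paste("scores:", toString(round(scores, 1))))
    sel <- select_template(q, lib)
    expect_true(is.na(sel$template_id))
    expect_false(sel$multiple_hits)
  }
})

test_that("3D-based templates win near-ties and groups gate the search", {
  base <- synthesize_template(60, seed = 51, id = "cov-a")
  twin <- base
  twin$id <- "b-3d"
  twin$metadata$structure_source <- "3D"
  sel <- select_template(base$sequence, list(base, twin))
  expect_equal(sel$template_id, "b-3d")

  # without the 3D flag the lexicographically smaller id wins the exact tie
  twin2 <- base; twin2$id <- "zzz"
  sel2 <- select_template(base$sequence, list(base, twin2))
  expect_equal(sel2$template_id, "cov-a")

  # grouped search: a hit in the first group stops the scan
  root <- withr::local_tempdir()
  dir.create(file.path(root, "g1")); dir.create(file.path(root, "g2"))
  t1 <- synthesize_template(70, seed = 61, id = "first")
  write_template(t1, file.path(root, "g1", "first.fasta"),
                 file.path(root, "g1", "first.xml"))
  t2 <- t1; t2$id <- "second"
  write_template(t2, file.path(root, "g2", "second.fasta"),
                 file.path(root, "g2", "second.xml"))
  lib <- load_library(index_library(root, c("g1", "g2")))
  sel3 <- select_template(t1$sequence, lib)
  expect_equal(sel3$template_id, "first")
  expect_equal(sel3$group, "g1")
  sel4 <- select_template(t1$sequence, lib, template_id = "second")  # bypass
  expect_equal(sel4$template_id, "second")
  expect_true(is.na(sel4$score))
})

test_that("selection is deterministic and robust to mild mutation", {
  sim <- simulate_dataset(n_templates = 8, length_range = c(80L, 160L),
                          n_queries = 40, seed = 77)
  lib <- sim$templates
  hits <- 0L
  for (q in names(sim$queries)) {
    s1 <- select_template(sim$queries[[q]], lib)
    s2 <- select_template(sim$queries[[q]], lib)
    expect_identical(s1, s2)
    if (identical(s1$template_id, sim$source[[q]])) hits <- hits + 1L
  }
  expect_gte(hits / 40, 0.95)
})
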