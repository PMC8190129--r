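test_that("build_structure_tree produces the expected shapes", {
  t1 <- build_structure_tree(parse_dotbracket("."))
  expect_equal(sum(t1$kind == "leaf"), 1L)
  expect_equal(sum(t1$kind == "pair"), 0L)

  t2 <- build_structure_tree(parse_dotbracket("((...))"))
  # root -> pair(1,7) -> pair(2,6) -> three leaves
  expect_equal(sum(t2$kind == "pair"), 2L)
  expect_equal(sum(t2$kind == "leaf"), 3L)
  outer <- which(t2$kind == "pair" & t2$five == 1L)
  inner <- which(t2$kind == "pair" & t2$five == 2L)
  expect_equal(t2$parent[inner], outer)
  expect_equal(t2$three[outer], 7L)

  t3 <- build_structure_tree(parse_dotbracket("(...)(...)"))
  root_children <- t3$children[[t3$root]]
  expect_equal(t3$kind[root_children], c("pair", "pair"))
  expect_equal(vapply(root_children, function(v) length(t3$children[[v]]), 1L),
               c(3L, 3L))
})

test_that("in-order traversal recovers 1..length exactly once", {
  for (seed in 1:25) {
    n <- sample(5:100, 1)
    ss <- generate_random_structure(n, seed = seed)
    tree <- build_structure_tree(ss)
    expect_equal(rna2d:::tree_inorder_positions(tree), seq_len(n))
    # tree completeness: leaves + 2 * pair nodes == length
    expect_equal(sum(tree$kind == "leaf") + 2L * sum(tree$kind == "pair"), n)
  }
})

test_that("pseudoknot layers never enter the tree", {
  ss <- parse_dotbracket("((..[[..))..]]")
  tree <- build_structure_tree(ss)
  expect_equal(sum(tree$kind == "pair"), 2L)  # only the round-bracket pairs
  expect_equal(sum(tree$kind == "leaf"), 10L)
})

test_that("tree edit mapping handles the elementary cases", {
  ta <- build_structure_tree(parse_dotbracket("(...)"))
  expect_equal(tree_edit_mapping(ta, ta)$cost, 0L)
  m <- tree_edit_mapping(ta, ta)
  expect_equal(nrow(m$matched), 5L)  # identity mapping matches every node
  expect_true(all(m$matched$template_kind == m$matched$target_kind))

  empty <- build_structure_tree(secondary_structure(0))
  expect_equal(tree_edit_mapping(empty, ta)$cost, 4L)  # all non-root inserted
  expect_equal(tree_edit_mapping(ta, empty)$cost, 4L)

  tb <- build_structure_tree(parse_dotbracket("(..)"))
  expect_equal(tree_edit_mapping(ta, tb)$cost, 1L)  # one leaf deleted
})

test_that("mapping cost is symmetric and matches the mapping it returns", {
  for (seed in 1:30) {
    withr::with_seed(seed, {
      s1 <- generate_random_structure(sample(3:10, 1), seed = seed * 2L)
      s2 <- generate_random_structure(sample(3:10, 1), seed = seed * 2L + 1L)
    })
    t1 <- build_structure_tree(s1); t2 <- build_structure_tree(s2)
    m12 <- tree_edit_mapping(t1, t2)
    m21 <- tree_edit_mapping(t2, t1)
    expect_equal(m12$cost, m21$cost)
    # cost decomposition: unmatched + kind-mismatched matches
    n1 <- length(t1$kind); n2 <- length(t2$kind)
    k <- nrow(m12$matched)
    relabels <- sum(m12$matched$template_kind != m12$matched$target_kind)
    expect_equal(m12$cost, (n1 - k) + (n2 - k) + relabels)
    # one-to-one and order-preserving in postorder
    expect_false(anyDuplicated(m12$matched$template_post) > 0)
    expect_false(anyDuplicated(m12$matched$target_post) > 0)
    expect_true(all(diff(m12$matched$target_post) > 0))
  }
})

test_that("tree edit cost equals exhaustive search on small trees", {
  cases <- 0L
  seed <- 0L
  while (cases < 200L) {
    seed <- seed + 1L
    s1 <- generate_random_structure(sample(1:5, 1), seed = seed)
    s2 <- generate_random_structure(sample(1:5, 1), seed = seed + 1000L)
    t1 <- build_structure_tree(s1); t2 <- build_structure_tree(s2)
    if (length(t1$kind) > 6L || length(t2$kind) > 6L) next
    cases <- cases + 1L
    expect_equal(tree_edit_mapping(t1, t2)$cost, oracle_tree_cost(t1, t2),
                 info = paste("seed", seed))
  }
})
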