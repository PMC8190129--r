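# Ordered structure trees.
#
# The nested (layer-0) pairing of a secondary structure is represented as an
# ordered rooted tree: an exterior root node whose descendants are PairNodes
# (one per layer-0 base pair) and UnpairedLeaf nodes (one per unpaired
# position). Children are ordered by 5' position, so an in-order traversal of
# leaves and pair bounds recovers positions 1..length exactly once. This tree
# drives hairpin enumeration and layout; pseudoknot layers never enter it.

#' Build the ordered structure tree
#'
#' Builds the tree of layer-0 pairs by recursive descent. Higher-layer
#' (pseudoknot) pairs are deliberately excluded: they are carried as
#' annotations and drawn as dashed lines, keeping the layout planar.
#'
#' @param ss an `rna_ss` secondary structure.
#' @return an object of class `rna_tree`: parallel vectors `kind`
#'   (`root`/`pair`/`leaf`), `five`, `three`, `parent` plus a `children`
#'   list, all indexed by node id (root is node 1).
#' @export
build_structure_tree <- function(ss) {
  stopifnot(inherits(ss, "rna_ss"))
  partner <- pairing_vector(ss, layer = 0L)
  n_nodes_max <- ss$length + 1L
  kind <- character(n_nodes_max); five <- integer(n_nodes_max)
  three <- integer(n_nodes_max); parent <- integer(n_nodes_max)
  children <- vector("list", n_nodes_max)
  kind[1] <- "root"; five[1] <- NA_integer_; three[1] <- NA_integer_
  parent[1] <- NA_integer_; children[[1]] <- integer(0)
  n_nodes <- 1L

  descend <- function(lo, hi, par) {
    i <- lo
    while (i <= hi) {
      n_nodes <<- n_nodes + 1L
      id <- n_nodes
      parent[id] <<- par
      children[[par]] <<- c(children[[par]], id)
      children[[id]] <<- integer(0)
      j <- partner[i]
      if (!is.na(j) && j > i) {
        kind[id] <<- "pair"; five[id] <<- i; three[id] <<- j
        descend(i + 1L, j - 1L, id)
        i <- j + 1L
      } else {
        kind[id] <<- "leaf"; five[id] <<- i; three[id] <<- i
        i <- i + 1L
      }
    }
  }
  if (ss$length > 0) descend(1L, ss$length, 1L)

  structure(list(
    kind = kind[seq_len(n_nodes)],
    five = five[seq_len(n_nodes)],
    three = three[seq_len(n_nodes)],
    parent = parent[seq_len(n_nodes)],
    children = children[seq_len(n_nodes)],
    root = 1L,
    length = ss$length
  ), class = "rna_tree")
}

#' @export
print.rna_tree <- function(x, ...) {
  cat("RNA structure tree:", sum(x$kind == "pair"), "pair node(s),",
      sum(x$kind == "leaf"), "unpaired leaves over", x$length, "nt\n")
  invisible(x)
}

# Postorder node ids of the subtree rooted at `id`.
tree_postorder <- function(tree, id = tree$root) {
  out <- integer(0)
  walk <- function(v) {
    for (ch in tree$children[[v]]) walk(ch)
    out[[length(out) + 1L]] <<- v
  }
  walk(id)
  out
}

# In-order traversal of positions: leaves contribute their position, pair
# nodes contribute 5' bound before their children and 3' bound after.
tree_inorder_positions <- function(tree) {
  out <- integer(0)
  walk <- function(v) {
    if (tree$kind[v] == "leaf") {
      out[[length(out) + 1L]] <<- tree$five[v]
      return(invisible())
    }
    if (tree$kind[v] == "pair") out[[length(out) + 1L]] <<- tree$five[v]
    for (ch in tree$children[[v]]) walk(ch)
    if (tree$kind[v] == "pair") out[[length(out) + 1L]] <<- tree$three[v]
  }
  walk(tree$root)
  out
}

# --- Zhang-Shasha ordered tree edit distance -------------------------------

# Flatten a tree to the arrays the Zhang-Shasha recurrence needs:
# postorder node ids, kinds, and l(i) = postorder index of the leftmost
# node of the subtree rooted at postorder node i.
zs_arrays <- function(tree) {
  po <- tree_postorder(tree)
  n <- length(po)
  idx <- integer(length(tree$kind)); idx[po] <- seq_len(n)
  l <- integer(n)
  for (i in seq_len(n)) {
    v <- po[i]
    while (length(tree$children[[v]]) > 0) v <- tree$children[[v]][1]
    l[i] <- idx[v]
  }
  keyroots <- which(!duplicated(l, fromLast = TRUE))
  list(po = po, n = n, kind = tree$kind[po], l = l, keyroots = sort(keyroots))
}

zs_gamma <- function(k1, k2) as.integer(k1 != k2)

# Forest distance table for the subtree pair rooted at postorder (i, j).
# Rows/cols are 0-padded: fd[di + 1 - li1, dj + 1 - lj1] with an extra
# leading row/column for the empty forest. Returns the table and the
# (possibly updated) tree-distance matrix.
zs_forestdist <- function(a1, a2, i, j, td) {
  li <- a1$l[i]; lj <- a2$l[j]
  ni <- i - li + 2L; nj <- j - lj + 2L
  fd <- matrix(0L, ni, nj)
  for (di in 2:ni) fd[di, 1] <- fd[di - 1L, 1] + 1L
  for (dj in 2:nj) fd[1, dj] <- fd[1, dj - 1L] + 1L
  for (di in 2:ni) {
    pi <- li + di - 2L  # postorder index of template node
    for (dj in 2:nj) {
      pj <- lj + dj - 2L
      del <- fd[di - 1L, dj] + 1L
      ins <- fd[di, dj - 1L] + 1L
      if (a1$l[pi] == li && a2$l[pj] == lj) {
        sub <- fd[di - 1L, dj - 1L] + zs_gamma(a1$kind[pi], a2$kind[pj])
        fd[di, dj] <- min(del, ins, sub)
        td[pi, pj] <- fd[di, dj]
      } else {
        sub <- fd[a1$l[pi] - li + 1L, a2$l[pj] - lj + 1L] + td[pi, pj]
        fd[di, dj] <- min(del, ins, sub)
      }
    }
  }
  list(fd = fd, td = td)
}

#' Minimum ordered tree edit mapping
#'
#' Computes the minimum-cost edit mapping between two structure trees under
#' unit insert/delete/relabel costs (relabel costs 1 when node kinds differ,
#' 0 otherwise), using the Zhang-Shasha dynamic programme over leftmost-leaf
#' keyroots. Used as the fallback when no alignment-informed mapping is
#' available. Ties are broken deterministically by the fixed postorder
#' enumeration of keyroots and backtrack order.
#'
#' @param template_tree,target_tree `rna_tree` objects.
#' @return list of class `tree_mapping` with elements `cost` (integer) and
#'   `matched`, a data frame of matched node pairs (postorder indices and
#'   node descriptors in both trees, in template postorder).
#' @export
tree_edit_mapping <- function(template_tree, target_tree) {
  stopifnot(inherits(template_tree, "rna_tree"), inherits(target_tree, "rna_tree"))
  a1 <- zs_arrays(template_tree)
  a2 <- zs_arrays(target_tree)
  td <- matrix(0L, a1$n, a2$n)
  for (i in a1$keyroots) {
    for (j in a2$keyroots) {
      td <- zs_forestdist(a1, a2, i, j, td)$td
    }
  }
  # backtrack for the mapping: process subtree-pair subproblems
  matched_i <- integer(0); matched_j <- integer(0)
  todo <- list(c(a1$n, a2$n))
  while (length(todo)) {
    pr <- todo[[length(todo)]]; todo[[length(todo)]] <- NULL
    i <- pr[1]; j <- pr[2]
    li <- a1$l[i]; lj <- a2$l[j]
    fd <- zs_forestdist(a1, a2, i, j, td)$fd
    di <- i; dj <- j
    while (di >= li || dj >= lj) {
      ri <- di - li + 2L; rj <- dj - lj + 2L
      if (di >= li && fd[ri, rj] == fd[ri - 1L, rj] + 1L) {
        di <- di - 1L
      } else if (dj >= lj && fd[ri, rj] == fd[ri, rj - 1L] + 1L) {
        dj <- dj - 1L
      } else if (a1$l[di] == li && a2$l[dj] == lj) {
        matched_i <- c(matched_i, di); matched_j <- c(matched_j, dj)
        di <- di - 1L; dj <- dj - 1L
      } else {
        todo[[length(todo) + 1L]] <- c(di, dj)
        di <- a1$l[di] - 1L; dj <- a2$l[dj] - 1L
      }
    }
  }
  ord <- order(matched_i)
  matched_i <- matched_i[ord]; matched_j <- matched_j[ord]
  matched <- data.frame(
    template_post = matched_i,
    target_post = matched_j,
    template_kind = a1$kind[matched_i],
    target_kind = a2$kind[matched_j],
    template_five = template_tree$five[a1$po[matched_i]],
    template_three = template_tree$three[a1$po[matched_i]],
    target_five = target_tree$five[a2$po[matched_j]],
    target_three = target_tree$three[a2$po[matched_j]]
  )
  structure(list(cost = td[a1$n, a2$n], matched = matched), class = "tree_mapping")
}

#' @export
print.tree_mapping <- function(x, ...) {
  cat("Tree edit mapping: cost", x$cost, "with", nrow(x$matched), "matched node pair(s)\n")
  invisible(x)
}
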