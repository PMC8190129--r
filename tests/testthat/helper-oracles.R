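# Independent oracles used to cross-check the implementation. These stay
# deliberately naive: enumeration and closed forms, never the package's own
# dynamic programmes.

# Affine gap cost of a single gap block of length L.
oracle_gap_cost <- function(L, p) {
  if (L <= 0) 0 else p$gap_open + (L - 1) * p$gap_extend
}

# Brute-force optimal GLOBAL affine-gap alignment score by enumerating all
# monotone matchings (sets of aligned column pairs). Gaps between
# consecutive matched pairs are single blocks per sequence, which is always
# optimal under affine costs.
oracle_global_score <- function(query, ref, p = scoring_params()) {
  qc <- strsplit(toupper(query), "")[[1]]
  rc <- strsplit(toupper(ref), "")[[1]]
  n <- length(rc); m <- length(qc)
  subsc <- function(a, b) if (a == b) p$match else p$mismatch
  best <- -oracle_gap_cost(n, p) - oracle_gap_cost(m, p)  # empty matching
  for (k in seq_len(min(n, m))) {
    A <- utils::combn(n, k); B <- utils::combn(m, k)
    for (ai in seq_len(ncol(A))) {
      ii <- A[, ai]
      for (bi in seq_len(ncol(B))) {
        jj <- B[, bi]
        sc <- sum(vapply(seq_len(k), function(t) subsc(rc[ii[t]], qc[jj[t]]),
                         numeric(1)))
        bounds_i <- c(0L, ii, n + 1L); bounds_j <- c(0L, jj, m + 1L)
        for (t in seq_len(k + 1L)) {
          sc <- sc - oracle_gap_cost(bounds_i[t + 1L] - bounds_i[t] - 1L, p) -
            oracle_gap_cost(bounds_j[t + 1L] - bounds_j[t] - 1L, p)
        }
        if (sc > best) best <- sc
      }
    }
  }
  best
}

# Brute-force optimal LOCAL affine-gap alignment score: flanks are free, only
# gaps between matched pairs count; empty alignment scores 0.
oracle_local_score <- function(query, ref, p = scoring_params()) {
  qc <- strsplit(toupper(query), "")[[1]]
  rc <- strsplit(toupper(ref), "")[[1]]
  n <- length(rc); m <- length(qc)
  subsc <- function(a, b) if (a == b) p$match else p$mismatch
  best <- 0
  for (k in seq_len(min(n, m))) {
    A <- utils::combn(n, k); B <- utils::combn(m, k)
    for (ai in seq_len(ncol(A))) {
      ii <- A[, ai]
      for (bi in seq_len(ncol(B))) {
        jj <- B[, bi]
        sc <- sum(vapply(seq_len(k), function(t) subsc(rc[ii[t]], qc[jj[t]]),
                         numeric(1)))
        if (k > 1) {
          for (t in seq_len(k - 1L)) {
            sc <- sc - oracle_gap_cost(ii[t + 1L] - ii[t] - 1L, p) -
              oracle_gap_cost(jj[t + 1L] - jj[t] - 1L, p)
          }
        }
        if (sc > best) best <- sc
      }
    }
  }
  best
}

# Flatten a structure tree for the mapping oracle: postorder kinds plus an
# ancestor matrix.
oracle_tree_arrays <- function(tree) {
  po <- integer(0)
  walk <- function(v) {
    for (ch in tree$children[[v]]) walk(ch)
    po[[length(po) + 1L]] <<- v
  }
  walk(tree$root)
  N <- length(po)
  anc <- matrix(FALSE, N, N)
  for (a in seq_len(N)) {
    v <- po[a]
    desc <- c()
    stack <- tree$children[[v]]
    while (length(stack)) {
      u <- stack[[1]]; stack <- stack[-1]
      desc <- c(desc, u)
      stack <- c(stack, tree$children[[u]])
    }
    anc[a, match(desc, po)] <- TRUE
  }
  list(kind = tree$kind[po], anc = anc, N = N)
}

# Exhaustive minimum tree-mapping cost: enumerate every monotone injective
# pairing of postorder nodes and keep those preserving the ancestor relation
# both ways. Unit indel costs; relabel costs 1 for differing node kinds.
oracle_tree_cost <- function(t1, t2) {
  a1 <- oracle_tree_arrays(t1); a2 <- oracle_tree_arrays(t2)
  best <- a1$N + a2$N
  check <- function(ii, jj) {
    k <- length(ii)
    if (k > 1) {
      for (u in seq_len(k - 1)) for (v in (u + 1):k) {
        if (a1$anc[ii[u], ii[v]] != a2$anc[jj[u], jj[v]] ||
            a1$anc[ii[v], ii[u]] != a2$anc[jj[v], jj[u]]) return(FALSE)
      }
    }
    TRUE
  }
  for (k in seq_len(min(a1$N, a2$N))) {
    A <- utils::combn(a1$N, k); B <- utils::combn(a2$N, k)
    for (ai in seq_len(ncol(A))) {
      ii <- A[, ai]
      for (bi in seq_len(ncol(B))) {
        jj <- B[, bi]
        if (!check(ii, jj)) next
        cost <- (a1$N - k) + (a2$N - k) +
          sum(a1$kind[ii] != a2$kind[jj])
        if (cost < best) best <- cost
      }
    }
  }
  best
}

# Plain double-loop overlap counter (the O(n^2) reference).
oracle_count_overlaps <- function(xy, ss, d_min) {
  partner <- rep(NA_integer_, ss$length)
  if (nrow(ss$pairs)) {
    partner[ss$pairs$five] <- ss$pairs$three
    partner[ss$pairs$three] <- ss$pairs$five
  }
  cnt <- 0L
  n <- nrow(xy)
  for (p in seq_len(n - 1)) {
    for (q in (p + 1):n) {
      if (q - p == 1L) next
      if (!is.na(partner[p]) && partner[p] == q) next
      if (sqrt(sum((xy[p, ] - xy[q, ])^2)) < d_min) cnt <- cnt + 1L
    }
  }
  cnt
}

# Independent 12-angle evaluation for one hairpin: rotates member
# coordinates about the midpoint of the root pair with its own rotation
# arithmetic and counts overlaps with the double-loop reference.
oracle_rotation_profile <- function(xy, ss, five, three, d_min) {
  members <- five:three
  pivot <- (xy[five, ] + xy[three, ]) / 2
  vapply(seq(0, 330, by = 30), function(a) {
    th <- a * pi / 180
    m <- xy
    dx <- m[members, 1] - pivot[1]; dy <- m[members, 2] - pivot[2]
    m[members, 1] <- pivot[1] + dx * cos(th) - dy * sin(th)
    m[members, 2] <- pivot[2] + dx * sin(th) + dy * cos(th)
    oracle_count_overlaps(m, ss, d_min)
  }, integer(1))
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                                collapse = "")
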