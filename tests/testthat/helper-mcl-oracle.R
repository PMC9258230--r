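# Independent dense-matrix Markov clustering used as a reference on small
# graphs: no pruning, plain power iteration to the limit, clusters read as
# connected components of the limit matrix support. Shares no code with
# archfam::mcl().
mcl_oracle <- function(nodes, edges, inflation = 2, max_iter = 500,
                      tol = 1e-12) {
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (!is.null(edges) && nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      A[edges$from[r], edges$to[r]] <- edges$weight[r]
      A[edges$to[r], edges$from[r]] <- edges$weight[r]
    }
  }
  for (j in seq_len(n)) {
    mx <- max(A[, j])
    A[j, j] <- if (mx > 0) mx else 1
  }
  M <- A %*% diag(1 / colSums(A), n)
  for (it in seq_len(max_iter)) {
    Mn <- (M %*% M)^inflation
    Mn <- Mn %*% diag(1 / colSums(Mn), n)
    if (max(abs(Mn - M)) < tol) {
      M <- Mn
      break
    }
    M <- Mn
  }
  supp <- (M > 1e-6) | t(M > 1e-6)
  # union-find over the support graph
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (supp[i, j]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  split(nodes, roots)
}

# canonical form of a partition: sorted list of sorted member vectors,
# letting partitions from different implementations be compared directly
canonical_partition <- function(x) {
  if (is.list(x)) {
    parts <- lapply(x, sort)
  } else {
    parts <- lapply(split(names(x), x), sort)
  }
  parts <- parts[order(vapply(parts, `[`, character(1), 1L))]
  unname(parts)
}

# Jaccard overlap of two id sets
set_overlap <- function(a, b) length(intersect(a, b)) / length(union(a, b))

edge_df <- function(from, to, weight = 1) {
  data.frame(from = from, to = to, weight = weight,
             stringsAsFactors = FALSE)
}

# complete graph edge list over node names
clique_edges <- function(nodes, weight = 1) {
  pairs <- t(utils::combn(nodes, 2))
  edge_df(pairs[, 1], pairs[, 2], weight)
}
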