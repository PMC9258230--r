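#' Markov clustering (MCL) of a weighted undirected graph
#'
#' Standard MCL: the column-stochastic transition matrix (with self-loops
#' set to each node's maximum incident edge weight, a common
#' regularisation) is alternately expanded (matrix squaring) and inflated
#' (entrywise power, then column renormalisation), pruning entries below
#' `prune` after each inflation, until the iterate changes by less than
#' `tol` or `max_iter` is reached (an error reports the residual in the
#' latter case). Clusters are read from the attractor structure of the
#' limit matrix; a node reachable from several attractor systems is
#' assigned to the system receiving the largest flow, ties going to the
#' lowest cluster id. The graph is processed per connected component, so
#' disconnected components are never merged.
#'
#' @param graph an [igraph::igraph] with non-negative edge `weight`s, or a
#'   data frame with columns `from`, `to`, `weight`.
#' @param inflation inflation exponent (2.0 is the usual granularity).
#' @param prune entries below this value are dropped after each inflation.
#' @param tol convergence threshold on the maximum absolute entry change.
#' @param max_iter maximum number of expansion/inflation rounds.
#' @return named integer vector: cluster membership per node, cluster ids
#'   numbered 1..k in order of each cluster's lexicographically smallest
#'   member.
#' @export
mcl <- function(graph, inflation = 2, prune = 1e-6, tol = 1e-8,
                max_iter = 200L) {
  if (is.data.frame(graph)) {
    stopifnot(all(c("from", "to", "weight") %in% names(graph)))
    graph <- igraph::graph_from_data_frame(graph, directed = FALSE)
  }
  stopifnot(igraph::is_igraph(graph))
  w <- igraph::E(graph)$weight
  if (igraph::ecount(graph) > 0 && is.null(w)) {
    stop("graph edges must carry a 'weight' attribute", call. = FALSE)
  }
  if (any(w < 0)) stop("MCL requires non-negative edge weights", call. = FALSE)
  if (inflation <= 1) stop("'inflation' must be > 1", call. = FALSE)

  comp <- igraph::components(graph)
  nodes <- igraph::V(graph)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(graph)))
  membership <- integer(length(nodes))
  names(membership) <- nodes
  next_id <- 0L
  for (ci in seq_len(comp$no)) {
    vs <- which(comp$membership == ci)
    if (length(vs) == 1L) {
      next_id <- next_id + 1L
      membership[vs] <- next_id
      next
    }
    sub <- igraph::induced_subgraph(graph, vs)
    A <- as.matrix(igraph::as_adjacency_matrix(sub, attr = "weight",
                                               sparse = TRUE))
    cl <- mcl_component(A, inflation, prune, tol, max_iter)
    membership[vs] <- cl + next_id
    next_id <- next_id + max(cl)
  }
  relabel_clusters(membership)
}

# renumber clusters 1..k by lexicographically smallest member node
relabel_clusters <- function(membership) {
  firsts <- vapply(split(names(membership), membership),
                   function(m) min(m), character(1))
  new_id <- setNames(rank(firsts, ties.method = "first"), names(firsts))
  out <- as.integer(new_id[as.character(membership)])
  names(out) <- names(membership)
  out
}

mcl_component <- function(A, inflation, prune, tol, max_iter) {
  n <- nrow(A)
  # self-loop = max incident edge weight (regularisation)
  diag(A) <- apply(A, 2, max)
  diag(A)[diag(A) == 0] <- 1
  M <- sweep(A, 2, colSums(A), "/")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Mn <- M %*% M                 # expansion
    Mn <- Mn^inflation            # inflation
    cs <- colSums(Mn)
    Mn <- sweep(Mn, 2, cs, "/")
    Mn[Mn < prune] <- 0           # pruning
    cs <- colSums(Mn)
    zero <- cs == 0
    if (any(zero)) {              # fully pruned column: keep it at itself
      Mn[cbind(which(zero), which(zero))] <- 1
      cs[zero] <- 1
    }
    Mn <- sweep(Mn, 2, cs, "/")
    resid <- max(abs(Mn - M))
    M <- Mn
    if (resid < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop(sprintf("MCL did not converge within %d iterations (residual %.3g)",
                 max_iter, resid), call. = FALSE)
  }
  attractors <- which(diag(M) > 0)
  if (!length(attractors)) attractors <- seq_len(n)  # defensive; not expected
  # attractor systems: attractors sharing support in any column
  S <- M[attractors, , drop = FALSE] > 0
  co <- (S %*% t(S)) > 0
  sys <- components_from_adjacency(co)
  n_sys <- max(sys)
  flow <- matrix(0, n_sys, n)
  for (s in seq_len(n_sys)) {
    flow[s, ] <- colSums(M[attractors[sys == s], , drop = FALSE])
  }
  apply(flow, 2, which.max)  # ties -> lowest cluster id
}

components_from_adjacency <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}
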