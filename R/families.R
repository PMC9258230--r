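#' Greedy set cover of a sequence similarity network into subfamilies
#'
#' Iteratively selects the still-uncovered node whose closed neighbourhood
#' (itself plus its network neighbours) contains the most uncovered nodes;
#' that node becomes the representative of a subfamily consisting of
#' exactly those uncovered nodes, which are then marked covered. Ties are
#' broken by the lexicographically smallest node id. Isolated nodes end
#' as singleton subfamilies, and the subfamilies partition the network's
#' nodes.
#'
#' @param ssn an [igraph::igraph] from [build_ssn()].
#' @return an object of class `archfam_subfamilies`: a list with
#'   `members` (named list of protein-id vectors) and `representative`
#'   (named character vector). Subfamily ids are assigned by decreasing
#'   size, then representative id.
#' @export
greedy_set_cover <- function(ssn) {
  stopifnot(igraph::is_igraph(ssn))
  vn <- igraph::V(ssn)$name
  n <- length(vn)
  ord <- order(vn)
  pos <- integer(n)
  pos[ord] <- seq_len(n)                       # igraph index -> lexicographic rank
  name_sorted <- vn[ord]
  adj_raw <- igraph::as_adj_list(ssn, mode = "all")
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    adj[[pos[i]]] <- sort(pos[as.integer(adj_raw[[i]])])
  }

  covered <- logical(n)
  gain <- vapply(adj, length, integer(1)) + 1L  # closed-neighbourhood bound
  reps <- character(0)
  members <- list()
  while (!all(covered)) {
    cand <- which(!covered)
    mx <- max(gain[cand])
    b <- cand[gain[cand] == mx][1L]            # smallest rank among ties
    closed <- c(b, adj[[b]])
    new_members <- closed[!covered[closed]]
    g <- length(new_members)
    if (g == mx) {
      covered[new_members] <- TRUE
      reps <- c(reps, name_sorted[b])
      members <- c(members, list(sort(name_sorted[new_members])))
    } else {
      gain[b] <- g                             # lazy update; gains only shrink
    }
  }
  sizes <- lengths(members)
  o <- order(-sizes, reps)
  members <- members[o]
  reps <- reps[o]
  ids <- sprintf("sub%05d", seq_along(members))
  structure(list(members = setNames(members, ids),
                 representative = setNames(reps, ids)),
            class = "archfam_subfamilies")
}

#' @export
print.archfam_subfamilies <- function(x, ...) {
  sz <- lengths(x$members)
  cat(sprintf("%d subfamilies over %d proteins (largest %d, singletons %d)\n",
              length(sz), sum(sz), if (length(sz)) max(sz) else 0L,
              sum(sz == 1L)))
  invisible(x)
}

#' Subfamily membership as a data frame
#'
#' @param x an `archfam_subfamilies` object.
#' @param ... unused.
#' @return data frame: protein_id, subfamily_id, representative.
#' @export
as.data.frame.archfam_subfamilies <- function(x, ...) {
  data.frame(
    protein_id = unlist(x$members, use.names = FALSE),
    subfamily_id = rep.int(names(x$members), lengths(x$members)),
    representative = rep.int(unname(x$representative), lengths(x$members)),
    stringsAsFactors = FALSE)
}

subfamily_membership <- function(subfams) {
  setNames(rep.int(names(subfams$members), lengths(subfams$members)),
           unlist(subfams$members, use.names = FALSE))
}

#' Pairwise subfamily similarity edges
#'
#' Produces the weighted subfamily graph that feeds [mcl()]. In
#' `"builtin"` mode the probability proxy for a subfamily pair is 100
#' times the best cross-subfamily bitscore in the sequence similarity
#' network, with that best pair's coverage; only subfamilies with at
#' least two members are compared (singletons build no profile). In
#' `"table"` mode a data frame (or TSV path) of profile-profile
#' comparison results with columns query_subfamily, target_subfamily,
#' probability, coverage is ingested. Either way, edges are kept only at
#' probability >= `probability_min` (percent) and coverage >=
#' `coverage_min`, and the edge weight is probability x coverage.
#'
#' @param subfams an `archfam_subfamilies` object.
#' @param ssn the sequence similarity network (required in builtin mode).
#' @param mode `"builtin"` or `"table"`.
#' @param table data frame or TSV path of profile comparison results
#'   (table mode).
#' @param probability_min probability threshold on the 0-100 scale.
#' @param coverage_min coverage threshold in \[0, 1\].
#' @return data frame: subfamily_a, subfamily_b, probability, coverage,
#'   weight.
#' @export
subfamily_similarity <- function(subfams, ssn = NULL,
                                 mode = c("builtin", "table"),
                                 table = NULL,
                                 probability_min = 95,
                                 coverage_min = 0.5) {
  mode <- match.arg(mode)
  stopifnot(inherits(subfams, "archfam_subfamilies"))
  empty <- data.frame(subfamily_a = character(), subfamily_b = character(),
                      probability = numeric(), coverage = numeric(),
                      weight = numeric(), stringsAsFactors = FALSE)
  if (mode == "builtin") {
    stopifnot(igraph::is_igraph(ssn))
    if (igraph::ecount(ssn) == 0) return(empty)
    memb <- subfamily_membership(subfams)
    ed <- igraph::as_data_frame(ssn, what = "edges")
    sa <- unname(memb[ed$from])
    sb <- unname(memb[ed$to])
    sizes <- lengths(subfams$members)
    keep <- sa != sb & sizes[sa] >= 2L & sizes[sb] >= 2L
    if (!any(keep)) return(empty)
    ed <- ed[keep, , drop = FALSE]
    a <- pmin(sa[keep], sb[keep])
    b <- pmax(sa[keep], sb[keep])
    ord <- order(a, b, -ed$weight, -ed$coverage)
    a <- a[ord]; b <- b[ord]; ed <- ed[ord, , drop = FALSE]
    first <- !duplicated(paste(a, b, sep = "\r"))
    out <- data.frame(subfamily_a = a[first], subfamily_b = b[first],
                      probability = 100 * ed$weight[first],
                      coverage = ed$coverage[first],
                      stringsAsFactors = FALSE)
  } else {
    if (is.character(table)) {
      table <- read.table(table, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
    }
    need <- c("query_subfamily", "target_subfamily", "probability",
              "coverage")
    if (!all(need %in% names(table))) {
      stop("table must have columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    unknown <- setdiff(unique(c(table$query_subfamily,
                                table$target_subfamily)),
                       names(subfams$members))
    if (length(unknown)) {
      stop("table references unknown subfamily id(s): ",
           collapse_ids(unknown), call. = FALSE)
    }
    keep <- table$query_subfamily != table$target_subfamily &
      table$probability >= probability_min &
      table$coverage >= coverage_min
    table <- table[keep, , drop = FALSE]
    if (!nrow(table)) return(empty)
    a <- pmin(table$query_subfamily, table$target_subfamily)
    b <- pmax(table$query_subfamily, table$target_subfamily)
    ord <- order(a, b, -(table$probability * table$coverage))
    a <- a[ord]; b <- b[ord]; table <- table[ord, , drop = FALSE]
    first <- !duplicated(paste(a, b, sep = "\r"))
    out <- data.frame(subfamily_a = a[first], subfamily_b = b[first],
                      probability = table$probability[first],
                      coverage = table$coverage[first],
                      stringsAsFactors = FALSE)
  }
  out <- out[out$probability >= probability_min &
               out$coverage >= coverage_min, , drop = FALSE]
  out$weight <- out$probability * out$coverage
  rownames(out) <- NULL
  out
}

#' Group subfamilies into protein families with MCL
#'
#' Runs [mcl()] on the filtered, weighted subfamily graph; subfamilies
#' absent from the edge set (including all singleton subfamilies in
#' builtin comparison mode) become singleton families. Family ids are
#' assigned by decreasing protein count, then by the lexicographically
#' smallest representative; a family is "wide" when its member proteins
#' span at least `min_genomes` distinct genomes.
#'
#' @param subfams an `archfam_subfamilies` object.
#' @param edges subfamily edge data frame from [subfamily_similarity()].
#' @param proteins data frame with columns protein_id, genome_id.
#' @param min_genomes genome-span threshold for a wide family.
#' @param inflation MCL inflation parameter.
#' @return an object of classes `archfam_families`/`data.frame` with
#'   columns family_id, representative, n_subfamilies, n_proteins,
#'   n_genomes, is_wide and list columns subfamilies, proteins, genomes.
#' @export
build_families <- function(subfams, edges, proteins, min_genomes = 5L,
                           inflation = 2) {
  stopifnot(inherits(subfams, "archfam_subfamilies"),
            all(c("protein_id", "genome_id") %in% names(proteins)))
  genome_of <- setNames(proteins$genome_id, proteins$protein_id)
  all_subs <- names(subfams$members)

  clusters <- list()
  if (!is.null(edges) && nrow(edges)) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = edges$subfamily_a, to = edges$subfamily_b,
                 weight = edges$weight, stringsAsFactors = FALSE),
      directed = FALSE)
    memb <- mcl(g, inflation = inflation)
    clusters <- unname(split(names(memb), memb))
    in_graph <- names(memb)
  } else {
    in_graph <- character(0)
  }
  clusters <- c(clusters, as.list(setdiff(all_subs, in_graph)))

  fam_proteins <- lapply(clusters, function(subs) {
    sort(unlist(subfams$members[subs], use.names = FALSE))
  })
  fam_genomes <- lapply(fam_proteins, function(p) {
    sort(unique(unname(genome_of[p])))
  })
  fam_rep <- vapply(clusters, function(subs) {
    sz <- lengths(subfams$members[subs])
    cand <- sort(unname(subfams$representative[subs[sz == max(sz)]]))
    cand[1L]
  }, character(1))
  n_prot <- lengths(fam_proteins)
  o <- order(-n_prot, fam_rep)
  out <- data.frame(
    family_id = sprintf("fam%05d", seq_along(o)),
    representative = fam_rep[o],
    n_subfamilies = lengths(clusters)[o],
    n_proteins = n_prot[o],
    n_genomes = lengths(fam_genomes)[o],
    is_wide = lengths(fam_genomes)[o] >= min_genomes,
    stringsAsFactors = FALSE)
  out$subfamilies <- I(lapply(clusters[o], sort))
  out$proteins <- I(fam_proteins[o])
  out$genomes <- I(fam_genomes[o])
  class(out) <- c("archfam_families", "data.frame")
  out
}

#' Family membership as a protein-level data frame
#'
#' @param families an `archfam_families` object.
#' @return data frame: protein_id, family_id.
#' @export
family_membership <- function(families) {
  data.frame(
    protein_id = unlist(families$proteins, use.names = FALSE),
    family_id = rep.int(families$family_id, families$n_proteins),
    stringsAsFactors = FALSE)
}

#' @export
print.archfam_families <- function(x, ...) {
  cat(sprintf("%d protein families over %d proteins; %d wide (>= min_genomes)\n",
              nrow(x), sum(x$n_proteins), sum(x$is_wide)))
  invisible(x)
}
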