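#' Cluster genomes by protein-family content
#'
#' Jaccard distances over the genome rows of the presence/absence matrix,
#' followed by agglomerative clustering under the chosen linkage. A
#' genome carrying no family has undefined distances and raises an error
#' naming it.
#'
#' @param pa logical genome x family matrix.
#' @param linkage `"complete"`, `"average"` or `"single"`.
#' @return an `hclust` dendrogram over genomes.
#' @export
cluster_genomes <- function(pa, linkage = c("complete", "average",
                                            "single")) {
  linkage <- match.arg(linkage)
  if (nrow(pa) < 2L || ncol(pa) < 1L) {
    stop("need at least 2 genomes and 1 family", call. = FALSE)
  }
  empty <- rowSums(pa) == 0
  if (any(empty)) {
    stop("genome(s) with all-absent profile: ",
         collapse_ids(rownames(pa)[empty]), call. = FALSE)
  }
  hierarchical_cluster(pa_distances(pa, margin = "genomes"), linkage)
}

#' Export a dendrogram as a newick string
#'
#' Converts an `hclust` tree to [ape::phylo] (the resulting ultrametric
#' branch lengths reproduce the merge heights as leaf-pair path lengths)
#' and writes newick.
#'
#' @param dend an `hclust` object.
#' @return single newick string.
#' @export
dendrogram_newick <- function(dend) {
  stopifnot(inherits(dend, "hclust"))
  ape::write.tree(ape::as.phylo(dend))
}

# pairwise tree distances as a labelled matrix; trees without branch
# lengths get unit lengths with a warning
cophenetic_matrix <- function(x) {
  if (inherits(x, "hclust")) {
    return(as.matrix(cophenetic(x)))
  }
  if (inherits(x, "phylo")) {
    if (is.null(x$edge.length)) {
      warning("reference tree has no branch lengths; assuming unit lengths")
      x$edge.length <- rep(1, nrow(x$edge))
    }
    return(ape::cophenetic.phylo(x))
  }
  if (inherits(x, "dist")) return(as.matrix(x))
  if (is.matrix(x)) return(x)
  if (is.character(x) && length(x) == 1L) {
    return(cophenetic_matrix(ape::read.tree(text = x)))
  }
  stop("cannot derive cophenetic distances from class ",
       paste(class(x), collapse = "/"), call. = FALSE)
}

#' Cophenetic correlation between two trees
#'
#' Pearson (or Spearman) correlation between the pairwise cophenetic
#' distances of two trees over their shared leaves: merge heights for a
#' dendrogram, patristic distances for a phylogeny. Accepts `hclust`,
#' [ape::phylo], newick strings, `dist` objects or labelled matrices;
#' the comparison is restricted to the shared leaf set (at least 3
#' leaves required).
#'
#' @param x,y the two trees.
#' @param method correlation variant, `"pearson"` (default) or
#'   `"spearman"`.
#' @return correlation in \[-1, 1\].
#' @export
cophenetic_correlation <- function(x, y, method = c("pearson",
                                                    "spearman")) {
  method <- match.arg(method)
  mx <- cophenetic_matrix(x)
  my <- cophenetic_matrix(y)
  shared <- intersect(rownames(mx), rownames(my))
  if (length(shared) < 3L) {
    stop("fewer than 3 shared leaves between the two trees", call. = FALSE)
  }
  mx <- mx[shared, shared]
  my <- my[shared, shared]
  vx <- mx[upper.tri(mx)]
  vy <- my[upper.tri(my)]
  if (sd(vx) == 0 || sd(vy) == 0) {
    stop("zero-variance cophenetic distance vector; correlation undefined",
         call. = FALSE)
  }
  cor(vx, vy, method = method)
}

#' Genome quality from a single-copy gene profile
#'
#' Completeness and contamination are percentages of the 38 archaeal
#' single-copy genes (SCGs) present at least once and duplicated,
#' respectively. A non-DPANN genome passes draft quality with more than
#' 26 SCGs present and fewer than 4 duplicated; DPANN genomes, being
#' naturally reduced, pass with more than 22 SCGs present and fewer
#' than 4 duplicated. All comparisons are strict as stated.
#'
#' @param n_present number of SCGs present with at least one copy
#'   (vectorised).
#' @param n_duplicated number of SCGs present with at least two copies.
#' @param is_dpann logical, relaxed threshold applies.
#' @param n_scg total marker count (38).
#' @return data frame: n_present, n_duplicated, is_dpann, completeness,
#'   contamination, pass.
#' @export
scg_quality <- function(n_present, n_duplicated, is_dpann = FALSE,
                        n_scg = 38L) {
  k <- max(length(n_present), length(n_duplicated), length(is_dpann))
  n_present <- rep_len(n_present, k)
  n_duplicated <- rep_len(n_duplicated, k)
  is_dpann <- rep_len(is_dpann, k)
  bad <- n_present < 0 | n_present > n_scg | n_duplicated < 0 |
    n_duplicated > n_present
  if (any(bad)) {
    stop("SCG counts out of range: need 0 <= n_duplicated <= n_present <= ",
         n_scg, call. = FALSE)
  }
  min_present <- ifelse(is_dpann, 22L, 26L)
  data.frame(
    n_present = n_present,
    n_duplicated = n_duplicated,
    is_dpann = is_dpann,
    completeness = 100 * n_present / n_scg,
    contamination = 100 * n_duplicated / n_scg,
    pass = n_present > min_present & n_duplicated < 4L)
}

#' Summarise a per-genome SCG copy-count profile
#'
#' @param counts integer vector of copy counts, one per SCG marker
#'   (length 38 by convention).
#' @return list with n_present (markers with >= 1 copy) and n_duplicated
#'   (markers with >= 2 copies).
#' @export
scg_profile <- function(counts) {
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("SCG copy counts must be non-negative integers", call. = FALSE)
  }
  list(n_present = sum(counts >= 1L), n_duplicated = sum(counts >= 2L))
}

#' Pick the representative genome of an ANI cluster
#'
#' Sorts by completeness (descending), then contamination (ascending),
#' then genome id, and returns the first: the most complete, least
#' contaminated genome, deterministically.
#'
#' @param ani_cluster data frame with columns genome_id, completeness,
#'   contamination.
#' @return the representative genome id.
#' @export
select_representative <- function(ani_cluster) {
  stopifnot(all(c("genome_id", "completeness", "contamination") %in%
                  names(ani_cluster)))
  if (!nrow(ani_cluster)) {
    stop("empty ANI cluster: no genomes to select from", call. = FALSE)
  }
  ord <- order(-ani_cluster$completeness, ani_cluster$contamination,
               ani_cluster$genome_id)
  ani_cluster$genome_id[ord][1L]
}

#' Filter genomes by marker-alignment occupancy and marker synteny
#'
#' A genome is kept iff its row of the concatenated marker alignment has
#' at least `min_fraction` non-gap positions AND its marker-synteny flag
#' (all marker proteins co-encoded on one scaffold, supplied as a
#' boolean) is TRUE.
#'
#' @param alignment_rows named character vector of equal-length aligned
#'   sequences (gaps `-` or `.`).
#' @param synteny named logical vector over the same genomes.
#' @param min_fraction minimum non-gap fraction.
#' @return list with `kept` and `dropped` genome id vectors.
#' @export
alignment_row_filter <- function(alignment_rows, synteny,
                                 min_fraction = 0.5) {
  stopifnot(!is.null(names(alignment_rows)))
  lens <- nchar(alignment_rows)
  if (length(unique(lens)) > 1L) {
    stop("ragged alignment: rows differ in length", call. = FALSE)
  }
  miss <- setdiff(names(alignment_rows), names(synteny))
  if (length(miss)) {
    stop("genomes without a synteny flag: ", collapse_ids(miss),
         call. = FALSE)
  }
  non_gap <- vapply(alignment_rows, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    mean(!(ch %in% c("-", ".")))
  }, numeric(1))
  keep <- non_gap >= min_fraction & synteny[names(alignment_rows)]
  list(kept = names(alignment_rows)[keep],
       dropped = names(alignment_rows)[!keep])
}
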