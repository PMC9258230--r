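#' Genome-by-family presence/absence matrix
#'
#' A cell is TRUE iff at least one member protein of the family comes
#' from that genome. Row order follows the supplied genome list and
#' column order the family table (both stable).
#'
#' @param families an `archfam_families` object from [build_families()].
#' @param genomes character vector of genome ids defining the row set and
#'   order; must contain every genome any included family spans.
#' @param wide_only include only wide families (default, matching the
#'   at-least-five-genomes family filter).
#' @return logical matrix, genomes x families.
#' @export
build_matrix <- function(families, genomes, wide_only = TRUE) {
  stopifnot(inherits(families, "archfam_families"), is.character(genomes))
  if (wide_only) families <- families[families$is_wide, , drop = FALSE]
  unknown <- setdiff(unique(unlist(families$genomes, use.names = FALSE)),
                     genomes)
  if (length(unknown)) {
    stop("families reference unknown genome(s): ", collapse_ids(unknown),
         call. = FALSE)
  }
  pa <- matrix(FALSE, nrow = length(genomes), ncol = nrow(families),
               dimnames = list(genomes, families$family_id))
  for (i in seq_len(nrow(families))) {
    pa[families$genomes[[i]], i] <- TRUE
  }
  pa
}

#' Jaccard distance between two presence/absence profiles
#'
#' `1 - |intersection| / |union|` over two equal-length boolean vectors.
#' Undefined (an error) when both profiles are all-FALSE.
#'
#' @param profile_a,profile_b logical (or 0/1) vectors of equal length.
#' @return distance in \[0, 1\].
#' @export
jaccard_distance <- function(profile_a, profile_b) {
  if (length(profile_a) != length(profile_b)) {
    stop("profiles must have equal length", call. = FALSE)
  }
  a <- as.logical(profile_a)
  b <- as.logical(profile_b)
  uni <- sum(a | b)
  if (uni == 0) {
    stop("Jaccard distance undefined: both profiles are all-FALSE",
         call. = FALSE)
  }
  1 - sum(a & b) / uni
}

#' Pairwise Jaccard distances over matrix rows or columns
#'
#' Thin wrapper around [vegan::vegdist()] (binary Jaccard) over the
#' genome rows (`margin = "genomes"`) or family columns
#' (`margin = "families"`) of a presence/absence matrix. Errors if any
#' profile is all-FALSE (its distances are undefined).
#'
#' @param pa logical genome x family matrix from [build_matrix()].
#' @param margin `"families"` (distances between family profiles) or
#'   `"genomes"`.
#' @return a `dist` object.
#' @export
pa_distances <- function(pa, margin = c("families", "genomes")) {
  margin <- match.arg(margin)
  x <- if (margin == "families") t(pa) else pa
  empty <- rowSums(x) == 0
  if (any(empty)) {
    stop(sprintf("all-absent %s profile(s): %s", margin,
                 collapse_ids(rownames(x)[empty])), call. = FALSE)
  }
  vegan::vegdist(x * 1, method = "jaccard", binary = TRUE)
}

#' Agglomerative hierarchical clustering of a distance matrix
#'
#' Wraps [stats::hclust()] under one of the three linkages compared in
#' the analysis (complete, average, single); input must be a valid
#' `dist` with no missing values.
#'
#' @param distances a `dist` object (e.g. from [pa_distances()]).
#' @param linkage `"complete"`, `"average"` or `"single"`.
#' @return an `hclust` dendrogram.
#' @export
hierarchical_cluster <- function(distances,
                                 linkage = c("complete", "average",
                                             "single")) {
  linkage <- match.arg(linkage)
  if (!inherits(distances, "dist")) {
    stop("'distances' must be a dist object", call. = FALSE)
  }
  if (anyNA(distances)) stop("distances contain NA", call. = FALSE)
  hclust(distances, method = linkage)
}

#' Cut the family dendrogram into co-occurrence modules
#'
#' Flat clusters are the maximal subtrees whose internal merge heights
#' are all at or below `cutoff`; clusters with at least
#' `min_module_size` families become modules (ids by decreasing size,
#' then smallest family id), smaller clusters are reported as
#' unassigned.
#'
#' @param dend an `hclust` dendrogram over family profiles.
#' @param cutoff height threshold in \[0, 1\] (Jaccard scale).
#' @param min_module_size minimum number of families per module.
#' @return a list of class `archfam_modules`: `modules` (data frame with
#'   module_id, n_families and list column families) and `unassigned`
#'   (character vector of family ids).
#' @export
cut_modules <- function(dend, cutoff = 0.95, min_module_size = 20L) {
  stopifnot(inherits(dend, "hclust"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff < 0 ||
      cutoff > 1) {
    stop("'cutoff' must be in [0, 1] for Jaccard distances", call. = FALSE)
  }
  memb <- cutree(dend, h = cutoff)
  cl <- unname(split(names(memb), memb))
  cl <- lapply(cl, sort)
  big <- cl[lengths(cl) >= min_module_size]
  small <- cl[lengths(cl) < min_module_size]
  if (length(big)) {
    o <- order(-lengths(big), vapply(big, `[`, character(1), 1L))
    big <- big[o]
  }
  modules <- data.frame(module_id = sprintf("module%03d", seq_along(big)),
                        n_families = lengths(big),
                        stringsAsFactors = FALSE)
  modules$families <- I(big)
  structure(list(modules = modules,
                 unassigned = sort(as.character(
                   unlist(small, use.names = FALSE)))),
            class = "archfam_modules")
}

#' @export
print.archfam_modules <- function(x, ...) {
  cat(sprintf("%d modules (>= min size) over %d families; %d unassigned\n",
              nrow(x$modules), sum(x$modules$n_families),
              length(x$unassigned)))
  invisible(x)
}

#' Assign a taxonomic distribution to a module
#'
#' Implements the median-m / top-m rule: `m` is the median number of
#' genomes per module family (rounded half-up to an integer); genomes are
#' ranked by the number of module families they carry (descending, ties
#' by genome id ascending) and the top `m` genomes are retained; the
#' phylum counts of the retained genomes define the module's taxonomy.
#'
#' @param module_families character vector of the module's family ids.
#' @param pa presence/absence matrix containing those families.
#' @param taxonomy data frame with columns genome_id and phylum covering
#'   every matrix genome.
#' @param include_ties if TRUE, genomes tied with the m-th ranked genome
#'   are all retained (default FALSE: deterministic truncation).
#' @return a list with `m`, `retained_genomes` and
#'   `taxonomy_distribution` (named integer vector of phylum counts,
#'   decreasing).
#' @export
assign_module_taxonomy <- function(module_families, pa, taxonomy,
                                   include_ties = FALSE) {
  if (length(module_families) == 0) {
    stop("empty module: no families to assign taxonomy to", call. = FALSE)
  }
  missing_fams <- setdiff(module_families, colnames(pa))
  if (length(missing_fams)) {
    stop("module families absent from the matrix: ",
         collapse_ids(missing_fams), call. = FALSE)
  }
  missing_gen <- setdiff(rownames(pa), taxonomy$genome_id)
  if (length(missing_gen)) {
    stop("genomes without taxonomy: ", collapse_ids(missing_gen),
         call. = FALSE)
  }
  sub <- pa[, module_families, drop = FALSE]
  m <- round_half_up(median(colSums(sub)))
  per_genome <- rowSums(sub)
  ord <- order(-per_genome, rownames(sub))
  retained <- rownames(sub)[ord][seq_len(min(m, nrow(sub)))]
  if (include_ties && m >= 1L && m < nrow(sub)) {
    cut_count <- per_genome[[retained[length(retained)]]]
    retained <- rownames(sub)[ord][per_genome[ord] >= cut_count]
  }
  phyla <- taxonomy$phylum[match(retained, taxonomy$genome_id)]
  dist <- sort(table(phyla), decreasing = TRUE)
  dist <- setNames(as.integer(dist), names(dist))
  list(m = m, retained_genomes = retained, taxonomy_distribution = dist)
}

#' Taxonomy report for all modules
#'
#' @param modules an `archfam_modules` object.
#' @param pa presence/absence matrix.
#' @param taxonomy genome taxonomy table.
#' @param include_ties see [assign_module_taxonomy()].
#' @return data frame: module_id, n_families, m, n_retained, taxonomy
#'   (string "phylum:count;...").
#' @export
module_taxonomy_report <- function(modules, pa, taxonomy,
                                   include_ties = FALSE) {
  stopifnot(inherits(modules, "archfam_modules"))
  rows <- lapply(seq_len(nrow(modules$modules)), function(i) {
    fams <- modules$modules$families[[i]]
    tx <- assign_module_taxonomy(fams, pa, taxonomy, include_ties)
    data.frame(
      module_id = modules$modules$module_id[i],
      n_families = length(fams),
      m = tx$m,
      n_retained = length(tx$retained_genomes),
      taxonomy = paste(sprintf("%s:%d", names(tx$taxonomy_distribution),
                               tx$taxonomy_distribution), collapse = ";"),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
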