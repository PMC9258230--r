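#' Consistency between functional labels and family membership
#'
#' For each KEGG-style label, reports the family containing the highest
#' fraction of the proteins carrying that label. A clustering that
#' respects function concentrates each label in one family (best fraction
#' close to 1).
#'
#' @param membership data frame with columns protein_id, family_id (see
#'   [family_membership()]).
#' @param annotations annotation table with columns protein_id,
#'   kegg_label (NA = unannotated).
#' @return data frame: kegg_label, best_family, n_proteins,
#'   best_fraction; one row per observed label.
#' @export
annotation_consistency <- function(membership, annotations) {
  stopifnot(all(c("protein_id", "family_id") %in% names(membership)),
            all(c("protein_id", "kegg_label") %in% names(annotations)))
  ann <- annotations[!is.na(annotations$kegg_label), , drop = FALSE]
  if (!nrow(ann)) {
    stop("no annotated proteins in the annotation table", call. = FALSE)
  }
  fam <- membership$family_id[match(ann$protein_id, membership$protein_id)]
  fam[is.na(fam)] <- "<unclustered>"
  per_label <- split(fam, ann$kegg_label)
  out <- lapply(names(per_label), function(lab) {
    tt <- table(per_label[[lab]])
    best <- max(tt)
    best_fam <- sort(names(tt)[tt == best])[1L]
    data.frame(kegg_label = lab, best_family = best_fam,
               n_proteins = length(per_label[[lab]]),
               best_fraction = best / length(per_label[[lab]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$kegg_label), , drop = FALSE]
}

#' Fraction of labels concentrated above a threshold
#'
#' Summary statistic over [annotation_consistency()] output: the fraction
#' of labels whose best family holds more than `threshold` of the
#' label's proteins.
#'
#' @param consistency data frame from [annotation_consistency()].
#' @param threshold concentration threshold (default 0.8).
#' @return a single fraction in \[0, 1\].
#' @export
consistency_summary <- function(consistency, threshold = 0.8) {
  mean(consistency$best_fraction > threshold)
}

#' Annotation admixture of one family
#'
#' Over the KEGG-annotated members only: 100 x (1 - dominant-label count
#' / annotated count). 0 means all annotated members agree; the value is
#' well defined under dominant-label ties (the dominant count is the
#' maximum count). `NA` when no member is annotated.
#'
#' @param members character vector of the family's protein ids.
#' @param annotations annotation table with protein_id, kegg_label.
#' @return admixture percentage in \[0, 100\], or NA.
#' @export
family_admixture <- function(members, annotations) {
  lab <- annotations$kegg_label[match(members, annotations$protein_id)]
  lab <- lab[!is.na(lab)]
  if (!length(lab)) return(NA_real_)
  100 * (1 - max(table(lab)) / length(lab))
}

#' Classify a protein family from its members' annotations
#'
#' Applies the family-level classification rules: a signal-peptide family
#' has at least `sp_min` (default 25%) of members predicted with a signal
#' peptide (inclusive); a transmembrane family has more than `tm_min`
#' (default half) of members with at least one predicted TM helix
#' (strict); a hypothetical family has no KEGG label on any member and no
#' PFAM domain other than Domains of Unknown Function (domain accessions
#' starting "DUF"); a family has bacterial homologs when it matched at
#' least `bacterial_min` (default 10) distinct bacterial genomes
#' (inclusive).
#'
#' @param members character vector of member protein ids.
#' @param annotations annotation table with columns protein_id,
#'   kegg_label, pfam_domains (";"-separated accessions or NA),
#'   has_signal_peptide, tm_helix_count, length.
#' @param n_bacterial_genomes number of distinct bacterial genomes the
#'   family matched.
#' @param sp_min,tm_min,bacterial_min classification thresholds.
#' @return one-row data frame: n_proteins, is_hypothetical,
#'   signal_peptide_fraction, is_sp_family, tm_fraction, is_tm_family,
#'   n_bacterial_genomes_hit, has_bacterial_homologs, median_length.
#' @export
classify_family <- function(members, annotations, n_bacterial_genomes = 0L,
                            sp_min = 0.25, tm_min = 0.5,
                            bacterial_min = 10L) {
  need <- c("protein_id", "kegg_label", "pfam_domains",
            "has_signal_peptide", "tm_helix_count", "length")
  stopifnot(all(need %in% names(annotations)))
  idx <- match(members, annotations$protein_id)
  if (anyNA(idx)) {
    stop("member protein(s) missing from the annotation table: ",
         collapse_ids(members[is.na(idx)]), call. = FALSE)
  }
  a <- annotations[idx, , drop = FALSE]
  doms <- unlist(strsplit(a$pfam_domains[!is.na(a$pfam_domains)], ";",
                          fixed = TRUE), use.names = FALSE)
  doms <- doms[nzchar(doms)]
  has_informative_domain <- any(!grepl("^DUF", doms))
  sp_frac <- mean(a$has_signal_peptide)
  tm_frac <- mean(a$tm_helix_count >= 1L)
  data.frame(
    n_proteins = length(members),
    is_hypothetical = all(is.na(a$kegg_label)) && !has_informative_domain,
    signal_peptide_fraction = sp_frac,
    is_sp_family = sp_frac >= sp_min,
    tm_fraction = tm_frac,
    is_tm_family = tm_frac > tm_min,
    n_bacterial_genomes_hit = as.integer(n_bacterial_genomes),
    has_bacterial_homologs = n_bacterial_genomes >= bacterial_min,
    median_length = median(a$length),
    stringsAsFactors = FALSE)
}

#' Classify every family in a family table
#'
#' @param families an `archfam_families` object.
#' @param annotations annotation table (see [classify_family()]).
#' @param bacterial_hits optional data frame, either
#'   (family_id, n_bacterial_genomes) or (family_id,
#'   bacterial_genome_id) — the latter is counted to distinct genomes.
#'   Families absent from the table count 0.
#' @param ... thresholds passed to [classify_family()].
#' @return data frame with family_id plus the [classify_family()]
#'   columns.
#' @export
classify_families <- function(families, annotations, bacterial_hits = NULL,
                              ...) {
  stopifnot(inherits(families, "archfam_families"))
  n_bact <- setNames(rep(0L, nrow(families)), families$family_id)
  if (!is.null(bacterial_hits)) {
    if ("n_bacterial_genomes" %in% names(bacterial_hits)) {
      counts <- setNames(bacterial_hits$n_bacterial_genomes,
                         bacterial_hits$family_id)
    } else if ("bacterial_genome_id" %in% names(bacterial_hits)) {
      counts <- vapply(split(bacterial_hits$bacterial_genome_id,
                             bacterial_hits$family_id),
                       function(g) length(unique(g)), integer(1))
    } else {
      stop("bacterial_hits needs n_bacterial_genomes or bacterial_genome_id",
           call. = FALSE)
    }
    hit <- intersect(names(counts), names(n_bact))
    n_bact[hit] <- as.integer(counts[hit])
  }
  rows <- lapply(seq_len(nrow(families)), function(i) {
    cbind(data.frame(family_id = families$family_id[i],
                     stringsAsFactors = FALSE),
          classify_family(families$proteins[[i]], annotations,
                          n_bacterial_genomes = n_bact[[families$family_id[i]]],
                          ...))
  })
  do.call(rbind, rows)
}

#' Gene-neighbourhood summary for a query family
#'
#' For each gene of the query family, collects the up-to-`window` genes
#' up- and downstream on the same scaffold (truncated at scaffold ends),
#' and reports, for every neighbouring family, its co-localization
#' frequency: the fraction of query occurrences with that family in the
#' window.
#'
#' @param gene_order data frame with columns genome, scaffold, position,
#'   strand, protein_id, family_id; (scaffold, position) pairs must be
#'   unique.
#' @param query_family family id to anchor the windows on.
#' @param window number of genes on each side.
#' @return a list with `occurrences` (data frame: protein_id, genome,
#'   scaffold, position and list column neighbor_families) and
#'   `colocalization` (data frame: family_id, frequency, sorted
#'   decreasing).
#' @export
neighborhood_summary <- function(gene_order, query_family, window = 5L) {
  need <- c("genome", "scaffold", "position", "strand", "protein_id",
            "family_id")
  stopifnot(all(need %in% names(gene_order)))
  key <- paste(gene_order$scaffold, gene_order$position, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (scaffold, position) in gene order table: ",
         collapse_ids(unique(key[duplicated(key)])), call. = FALSE)
  }
  occ <- list()
  for (sc in unique(gene_order$scaffold)) {
    genes <- gene_order[gene_order$scaffold == sc, , drop = FALSE]
    genes <- genes[order(genes$position), , drop = FALSE]
    hits <- which(genes$family_id == query_family)
    for (h in hits) {
      lo <- max(1L, h - window)
      hi <- min(nrow(genes), h + window)
      nb <- setdiff(seq.int(lo, hi), h)
      occ[[length(occ) + 1L]] <- list(
        protein_id = genes$protein_id[h],
        genome = genes$genome[h],
        scaffold = sc,
        position = genes$position[h],
        neighbor_families = unique(genes$family_id[nb]))
    }
  }
  if (!length(occ)) {
    return(list(
      occurrences = data.frame(protein_id = character(), genome = character(),
                               scaffold = character(), position = integer(),
                               stringsAsFactors = FALSE),
      colocalization = data.frame(family_id = character(),
                                  frequency = numeric(),
                                  stringsAsFactors = FALSE)))
  }
  occurrences <- data.frame(
    protein_id = vapply(occ, `[[`, character(1), "protein_id"),
    genome = vapply(occ, `[[`, character(1), "genome"),
    scaffold = vapply(occ, `[[`, character(1), "scaffold"),
    position = vapply(occ, function(o) as.integer(o$position), integer(1)),
    stringsAsFactors = FALSE)
  occurrences$neighbor_families <- I(lapply(occ, `[[`, "neighbor_families"))
  nb_all <- unique(unlist(occurrences$neighbor_families, use.names = FALSE))
  freq <- vapply(nb_all, function(f) {
    mean(vapply(occurrences$neighbor_families, function(v) f %in% v,
                logical(1)))
  }, numeric(1))
  coloc <- data.frame(family_id = nb_all, frequency = unname(freq),
                      stringsAsFactors = FALSE)
  coloc <- coloc[order(-coloc$frequency, coloc$family_id), , drop = FALSE]
  rownames(coloc) <- NULL
  list(occurrences = occurrences, colocalization = coloc)
}
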