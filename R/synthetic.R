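#' Configuration for the synthetic pangenome generator
#'
#' Defines the statistical structure of a simulated pangenome: a set of
#' lineages, a block of broadly shared "core" families, one planted
#' lineage-specific module per lineage, sparse background occurrences of
#' module families outside their lineage, per-family sequence divergence,
#' and noisy functional labels. The defaults describe a small pangenome
#' of 5 lineages of 10 genomes each with a 40-family core and one
#' 30-family module per lineage, the geometry used throughout the test
#' suite for family recovery.
#'
#' @param n_lineages number of lineages (each lineage gets one planted
#'   module and is reported as a phylum in the taxonomy table).
#' @param genomes_per_lineage genomes simulated per lineage.
#' @param core_family_count number of core families shared across lineages.
#' @param module_sizes integer vector, one entry per lineage: the number of
#'   families in that lineage's planted module.
#' @param core_prevalence probability that a core family is present in any
#'   given genome.
#' @param within_lineage_prevalence probability that a module family is
#'   present in a genome of its own lineage. Observed lineage-specific
#'   modules have mean within-lineage prevalence in roughly the 0.65-1
#'   range; the default 0.9 represents a well-conserved module.
#' @param background_rate probability that a module family appears in a
#'   genome outside its lineage (noise).
#' @param seq_length length, in residues, of each family's ancestor
#'   sequence.
#' @param substitution_rate per-site probability that a residue of a copy
#'   differs from the ancestor (substitutions only, no indels); must be
#'   < 1.
#' @param kegg_label_rate probability that a protein receives a functional
#'   (KEGG-style) label.
#' @param admixture_rate probability that a labelled protein receives a
#'   uniformly chosen wrong label instead of its family's true label.
#' @param seed integer seed; all generator stages derive their streams
#'   from it, so a fixed seed gives bit-identical output.
#'
#' @return an object of class `synthetic_config`.
#' @seealso [simulate_presence_absence()], [simulate_proteomes()],
#'   [simulate_annotations()]
#' @export
synthetic_config <- function(n_lineages = 5L,
                             genomes_per_lineage = 10L,
                             core_family_count = 40L,
                             module_sizes = rep(30L, n_lineages),
                             core_prevalence = 0.95,
                             within_lineage_prevalence = 0.9,
                             background_rate = 0.01,
                             seq_length = 150L,
                             substitution_rate = 0.05,
                             kegg_label_rate = 0.6,
                             admixture_rate = 0.1,
                             seed = 1L) {
  n_lineages <- check_count(n_lineages, "n_lineages")
  genomes_per_lineage <- check_count(genomes_per_lineage, "genomes_per_lineage")
  core_family_count <- check_count(core_family_count, "core_family_count")
  if (length(module_sizes) != n_lineages) {
    stop("'module_sizes' must have one entry per lineage", call. = FALSE)
  }
  module_sizes <- vapply(seq_along(module_sizes), function(i) {
    check_count(module_sizes[i], sprintf("module_sizes[%d]", i))
  }, integer(1))
  check_probability(core_prevalence, "core_prevalence")
  check_probability(within_lineage_prevalence, "within_lineage_prevalence")
  check_probability(background_rate, "background_rate")
  check_probability(kegg_label_rate, "kegg_label_rate")
  check_probability(admixture_rate, "admixture_rate")
  check_probability(substitution_rate, "substitution_rate")
  if (substitution_rate >= 1) {
    stop("'substitution_rate' must be < 1", call. = FALSE)
  }
  seq_length <- check_count(seq_length, "seq_length")
  seed <- check_count(seed, "seed", min = 0L)
  structure(list(
    n_lineages = n_lineages,
    genomes_per_lineage = genomes_per_lineage,
    core_family_count = core_family_count,
    module_sizes = module_sizes,
    core_prevalence = core_prevalence,
    within_lineage_prevalence = within_lineage_prevalence,
    background_rate = background_rate,
    seq_length = seq_length,
    substitution_rate = substitution_rate,
    kegg_label_rate = kegg_label_rate,
    admixture_rate = admixture_rate,
    seed = seed
  ), class = "synthetic_config")
}

# fixed offsets give each generator stage its own reproducible stream
stage_seed <- function(seed, stage) {
  offsets <- c(presence = 101L, proteome = 211L, annotation = 307L,
               bacterial = 401L)
  as.integer((seed + offsets[[stage]]) %% .Machine$integer.max)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("synthetic pangenome configuration\n")
  cat(sprintf("  %d lineages x %d genomes; %d core + %d module families\n",
              x$n_lineages, x$genomes_per_lineage, x$core_family_count,
              sum(x$module_sizes)))
  cat(sprintf("  prevalence: core %.2f, within-lineage %.2f, background %.3f\n",
              x$core_prevalence, x$within_lineage_prevalence,
              x$background_rate))
  cat(sprintf("  sequences: %d aa, substitution rate %.3f; labels: rate %.2f, admixture %.2f; seed %d\n",
              x$seq_length, x$substitution_rate, x$kegg_label_rate,
              x$admixture_rate, x$seed))
  invisible(x)
}

#' Simulate a genome-by-family presence/absence matrix with planted modules
#'
#' Draws the planted pangenome structure: core families are present in each
#' genome with probability `core_prevalence`; each lineage's module
#' families are present in in-lineage genomes with probability
#' `within_lineage_prevalence` and in out-of-lineage genomes with
#' probability `background_rate`. Also returns the genome taxonomy table
#' and the ground-truth record (planted module of every family and the
#' generating tree: a star of lineage rakes with unit branch lengths).
#'
#' @param cfg a [synthetic_config()].
#' @return a list with elements `pa` (logical genome x family matrix),
#'   `taxonomy` (data frame: genome_id, phylum, superphylum, is_dpann) and
#'   `truth` (list: `planted_module_of_family`, `generating_tree`,
#'   `planted_family_of_protein` and `true_label_of_protein`, the last two
#'   filled by [simulate_proteomes()] / [simulate_annotations()]).
#' @export
simulate_presence_absence <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(stage_seed(cfg$seed, "presence"))
  lineages <- sprintf("Lineage%02d", seq_len(cfg$n_lineages))
  genome_ids <- unlist(lapply(lineages, function(l) {
    sprintf("%s_g%02d", l, seq_len(cfg$genomes_per_lineage))
  }), use.names = FALSE)
  phylum <- rep(lineages, each = cfg$genomes_per_lineage)
  superphylum <- rep(sprintf("Superphylum%02d",
                             ((seq_len(cfg$n_lineages) - 1L) %/% 2L) + 1L),
                     each = cfg$genomes_per_lineage)
  taxonomy <- data.frame(genome_id = genome_ids, phylum = phylum,
                         superphylum = superphylum, is_dpann = FALSE,
                         stringsAsFactors = FALSE)

  core_ids <- sprintf("coreF%03d", seq_len(cfg$core_family_count))
  module_ids <- lapply(seq_along(lineages), function(l) {
    sprintf("%sF%03d", lineages[l], seq_len(cfg$module_sizes[l]))
  })
  family_ids <- c(core_ids, unlist(module_ids, use.names = FALSE))

  n_genomes <- length(genome_ids)
  pa <- matrix(FALSE, nrow = n_genomes, ncol = length(family_ids),
               dimnames = list(genome_ids, family_ids))
  pa[, core_ids] <- runif(n_genomes * length(core_ids)) < cfg$core_prevalence
  for (l in seq_along(lineages)) {
    inside <- phylum == lineages[l]
    cols <- module_ids[[l]]
    pa[inside, cols] <-
      runif(sum(inside) * length(cols)) < cfg$within_lineage_prevalence
    pa[!inside, cols] <-
      runif(sum(!inside) * length(cols)) < cfg$background_rate
  }

  planted_module <- setNames(
    c(rep("core", length(core_ids)), rep(lineages, cfg$module_sizes)),
    family_ids)

  rake <- function(tips) paste0("(", paste0(tips, ":1", collapse = ","), ")")
  tree <- if (cfg$n_lineages > 1L) {
    sub <- vapply(lineages, function(l) {
      paste0(rake(genome_ids[phylum == l]), ":1")
    }, character(1))
    paste0("(", paste0(sub, collapse = ","), ");")
  } else {
    paste0(rake(genome_ids), ";")
  }

  truth <- list(planted_family_of_protein = NULL,
                planted_module_of_family = planted_module,
                generating_tree = tree,
                true_label_of_protein = NULL)
  list(pa = pa, taxonomy = taxonomy, truth = truth)
}

AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Simulate per-genome proteomes from a planted presence/absence matrix
#'
#' Each planted family receives one ancestor sequence of uniform random
#' residues; each genome carrying the family receives an independent copy
#' in which every site is substituted with probability
#' `substitution_rate`, the replacement being drawn uniformly from the 19
#' other residues (no indels), so the expected pairwise identity between
#' two members has the closed form `(1-s)^2 + s^2/19` per site.
#'
#' @param cfg a [synthetic_config()].
#' @param pa planted presence/absence matrix from
#'   [simulate_presence_absence()].
#' @param truth the truth record from the same call; it is returned with
#'   `planted_family_of_protein` filled in.
#' @return a list with `sequences` (named character vector of amino-acid
#'   strings), `proteins` (data frame: protein_id, genome_id) and the
#'   updated `truth`. Protein identifiers are opaque; genome and planted
#'   family are recorded in `proteins` and `truth` only.
#' @export
simulate_proteomes <- function(cfg, pa, truth) {
  stopifnot(inherits(cfg, "synthetic_config"), is.matrix(pa))
  if (cfg$substitution_rate >= 1) {
    stop("'substitution_rate' must be < 1", call. = FALSE)
  }
  set.seed(stage_seed(cfg$seed, "proteome"))
  fams <- colnames(pa)
  len <- cfg$seq_length
  ancestors <- lapply(fams, function(f) {
    sample(AA_ALPHABET20, len, replace = TRUE)
  })
  names(ancestors) <- fams

  n_prot <- sum(pa)
  seqs <- character(n_prot)
  prot_ids <- character(n_prot)
  prot_genome <- character(n_prot)
  prot_family <- character(n_prot)
  k <- 0L
  for (g in rownames(pa)) {
    present <- fams[pa[g, ]]
    for (f in present) {
      s <- ancestors[[f]]
      if (cfg$substitution_rate > 0) {
        hit <- which(runif(len) < cfg$substitution_rate)
        if (length(hit)) {
          cur <- match(s[hit], AA_ALPHABET20)
          alt <- sample.int(19L, length(hit), replace = TRUE)
          s[hit] <- AA_ALPHABET20[ifelse(alt < cur, alt, alt + 1L)]
        }
      }
      k <- k + 1L
      prot_ids[k] <- sprintf("p%06d", k)
      prot_genome[k] <- g
      prot_family[k] <- f
      seqs[k] <- paste(s, collapse = "")
    }
  }
  names(seqs) <- prot_ids
  truth$planted_family_of_protein <- setNames(prot_family, prot_ids)
  list(sequences = seqs,
       proteins = data.frame(protein_id = prot_ids, genome_id = prot_genome,
                             stringsAsFactors = FALSE),
       truth = truth)
}

#' Simulate a functional annotation table with controlled label admixture
#'
#' Every planted family owns one true KEGG-style label and one PFAM-style
#' domain. Each protein is labelled with its family's true label with
#' probability `kegg_label_rate`; labelled proteins are then corrupted,
#' with probability `admixture_rate`, to a label drawn uniformly from the
#' other families' labels. PFAM domains are drawn independently at the
#' same rate without corruption. Signal-peptide and transmembrane-helix
#' predictions follow family-level propensities (a minority of families is
#' SP-rich or TM-rich) so that family classification has signal to detect;
#' these per-family propensities are part of the generator model, not of
#' the planted module structure.
#'
#' @param truth truth record with `planted_family_of_protein` filled in
#'   (from [simulate_proteomes()]).
#' @param cfg a [synthetic_config()].
#' @param sequences optional named sequence vector; when given, protein
#'   lengths are taken from it, otherwise `cfg$seq_length` is used.
#' @return a list with `annotations` (data frame: protein_id, kegg_label,
#'   pfam_domains, has_signal_peptide, tm_helix_count, length) and the
#'   updated `truth` (with `true_label_of_protein`).
#' @export
simulate_annotations <- function(truth, cfg, sequences = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  prot <- names(truth$planted_family_of_protein)
  if (is.null(prot)) {
    stop("truth$planted_family_of_protein is empty; run simulate_proteomes() first",
         call. = FALSE)
  }
  set.seed(stage_seed(cfg$seed, "annotation"))
  fams <- names(truth$planted_module_of_family)
  labels <- setNames(sprintf("K%05d", seq_along(fams)), fams)
  domains <- setNames(sprintf("PF%05d", seq_along(fams)), fams)

  fam_of <- truth$planted_family_of_protein
  fam_idx <- match(fam_of, fams)
  n <- length(prot)
  true_label <- unname(labels[fam_of])

  annotated <- runif(n) < cfg$kegg_label_rate
  wrong <- annotated & (runif(n) < cfg$admixture_rate)
  kegg <- ifelse(annotated, true_label, NA_character_)
  if (length(fams) >= 2L && any(wrong)) {
    alt <- sample.int(length(fams) - 1L, sum(wrong), replace = TRUE)
    ti <- fam_idx[wrong]
    kegg[wrong] <- sprintf("K%05d", ifelse(alt < ti, alt, alt + 1L))
  }

  pfam <- ifelse(runif(n) < cfg$kegg_label_rate, unname(domains[fam_of]),
                 NA_character_)

  sp_prob <- ifelse(runif(length(fams)) < 0.2, 0.6, 0.02)
  tm_prob <- ifelse(runif(length(fams)) < 0.2, 0.8, 0.05)
  has_sp <- runif(n) < sp_prob[fam_idx]
  tm_count <- rbinom(n, size = 3L, prob = tm_prob[fam_idx])

  lengths <- if (!is.null(sequences)) {
    unname(nchar(sequences[prot]))
  } else {
    rep(cfg$seq_length, n)
  }

  truth$true_label_of_protein <- setNames(true_label, prot)
  list(annotations = data.frame(
         protein_id = prot,
         kegg_label = kegg,
         pfam_domains = pfam,
         has_signal_peptide = has_sp,
         tm_helix_count = tm_count,
         length = lengths,
         stringsAsFactors = FALSE),
       truth = truth)
}

#' Simulate a truth-consistent bacterial-homolog hit table
#'
#' Assigns each planted family a number of distinct bacterial genomes with
#' homologs: a fraction `hit_fraction` of families draws from
#' `[bacterial_min, max_genomes]` (true bacterial homologs), the rest from
#' below `bacterial_min`.
#'
#' @param truth truth record (planted families).
#' @param cfg a [synthetic_config()] (for the seed).
#' @param hit_fraction fraction of families with genuine bacterial homologs.
#' @param bacterial_min threshold number of bacterial genomes.
#' @param max_genomes largest simulated bacterial genome count.
#' @return data frame: family_id, n_bacterial_genomes.
#' @export
simulate_bacterial_hits <- function(truth, cfg, hit_fraction = 0.2,
                                    bacterial_min = 10L, max_genomes = 30L) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(stage_seed(cfg$seed, "bacterial"))
  fams <- names(truth$planted_module_of_family)
  is_hit <- runif(length(fams)) < hit_fraction
  n_bact <- integer(length(fams))
  n_bact[is_hit] <- sample(seq.int(bacterial_min, max_genomes),
                           sum(is_hit), replace = TRUE)
  n_bact[!is_hit] <- sample(seq.int(0L, bacterial_min - 1L),
                            sum(!is_hit), replace = TRUE)
  data.frame(family_id = fams, n_bacterial_genomes = n_bact,
             stringsAsFactors = FALSE)
}
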