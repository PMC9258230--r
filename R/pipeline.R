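#' Pipeline thresholds and settings
#'
#' Collects every tunable of the analysis with the published defaults:
#' e-value 0.001 and coverage 0.5 for the similarity network (external
#' search tables), subfamily-merge thresholds probability >= 95 (percent)
#' and coverage >= 0.50 with weight = probability x coverage, MCL
#' inflation 2.0, at least 5 distinct genomes for a wide family, module
#' cut at Jaccard height 0.95 with at least 20 families per module,
#' signal-peptide fraction 0.25 (inclusive), transmembrane fraction 0.5
#' (strict), bacterial homologs in at least 10 genomes, and SCG quality
#' thresholds >26 (non-DPANN) / >22 (DPANN) present with <4 duplicated.
#' The builtin k-mer scorer has its own settings (`kmer_k`,
#' `builtin_evalue_max`, `min_bitscore`) because its e-value proxy
#' (1 - bitscore) is not on the scale of search-tool E-values.
#'
#' @param evalue_max,cover_min SSN edge filters for external hit tables.
#' @param kmer_k k-mer length of the builtin scorer.
#' @param builtin_evalue_max e-value-proxy threshold used when the SSN is
#'   built from builtin k-mer hits.
#' @param min_bitscore builtin scorer prefilter (pairs below are not
#'   reported).
#' @param subfamily_probability_min,subfamily_coverage_min subfamily edge
#'   filters.
#' @param mcl_inflation MCL inflation parameter.
#' @param min_genomes genome span defining a wide family.
#' @param module_cutoff dendrogram cut height for modules.
#' @param min_module_size minimum families per module.
#' @param sp_fraction,tm_fraction,bacterial_min_genomes family
#'   classification thresholds.
#' @param scg_min_nondpann,scg_min_dpann,scg_max_dup SCG quality
#'   thresholds.
#' @param family_linkage,genome_linkage linkages for the two dendrograms.
#' @param coverage_mode coverage semantics of external hit tables
#'   (bidirectional = min of query and target coverage).
#' @param seed integer seed forwarded to every stochastic stage.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(evalue_max = 0.001,
                            cover_min = 0.5,
                            kmer_k = 4L,
                            builtin_evalue_max = 0.5,
                            min_bitscore = 0.1,
                            subfamily_probability_min = 95,
                            subfamily_coverage_min = 0.5,
                            mcl_inflation = 2,
                            min_genomes = 5L,
                            module_cutoff = 0.95,
                            min_module_size = 20L,
                            sp_fraction = 0.25,
                            tm_fraction = 0.5,
                            bacterial_min_genomes = 10L,
                            scg_min_nondpann = 26L,
                            scg_min_dpann = 22L,
                            scg_max_dup = 4L,
                            family_linkage = "complete",
                            genome_linkage = "complete",
                            coverage_mode = "bidirectional",
                            seed = 1L) {
  check_probability(cover_min, "cover_min")
  check_probability(builtin_evalue_max, "builtin_evalue_max")
  check_probability(min_bitscore, "min_bitscore")
  check_probability(subfamily_coverage_min, "subfamily_coverage_min")
  check_probability(module_cutoff, "module_cutoff")
  check_probability(sp_fraction, "sp_fraction")
  check_probability(tm_fraction, "tm_fraction")
  if (evalue_max < 0) stop("'evalue_max' must be >= 0", call. = FALSE)
  if (subfamily_probability_min < 0 || subfamily_probability_min > 100) {
    stop("'subfamily_probability_min' must be in [0, 100]", call. = FALSE)
  }
  if (mcl_inflation <= 1) stop("'mcl_inflation' must be > 1", call. = FALSE)
  structure(list(
    evalue_max = evalue_max, cover_min = cover_min,
    kmer_k = check_count(kmer_k, "kmer_k"),
    builtin_evalue_max = builtin_evalue_max,
    min_bitscore = min_bitscore,
    subfamily_probability_min = subfamily_probability_min,
    subfamily_coverage_min = subfamily_coverage_min,
    mcl_inflation = mcl_inflation,
    min_genomes = check_count(min_genomes, "min_genomes"),
    module_cutoff = module_cutoff,
    min_module_size = check_count(min_module_size, "min_module_size"),
    sp_fraction = sp_fraction, tm_fraction = tm_fraction,
    bacterial_min_genomes = check_count(bacterial_min_genomes,
                                        "bacterial_min_genomes"),
    scg_min_nondpann = check_count(scg_min_nondpann, "scg_min_nondpann"),
    scg_min_dpann = check_count(scg_min_dpann, "scg_min_dpann"),
    scg_max_dup = check_count(scg_max_dup, "scg_max_dup"),
    family_linkage = match.arg(family_linkage,
                               c("complete", "average", "single")),
    genome_linkage = match.arg(genome_linkage,
                               c("complete", "average", "single")),
    coverage_mode = match.arg(coverage_mode,
                              c("bidirectional", "query", "target")),
    seed = check_count(seed, "seed", min = 0L)
  ), class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `write_pipeline_config` returns the path invisibly;
#'   `read_pipeline_config` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full analysis end-to-end
#'
#' Executes similarity search, subfamily construction, family clustering,
#' presence/absence matrix, module detection, module taxonomy, annotation
#' metrics, family classification, and genome clustering, writing every
#' intermediate as TSV plus a JSON manifest (configuration, input
#' checksums, stage timings, versions) to `out_dir`. Inputs are either
#' supplied in `inputs` or simulated from `sim` (the default), making the
#' run fully self-contained and reproducible under a fixed seed.
#'
#' @param out_dir output directory (created; existing files overwritten).
#' @param config a [pipeline_config()].
#' @param sim a [synthetic_config()] used when `inputs` is NULL; defaults
#'   to the package defaults at the pipeline's seed.
#' @param inputs optional list with elements `sequences` (named character
#'   vector), `proteins` (protein_id, genome_id), `taxonomy` (genome_id,
#'   phylum, ...), and optionally `annotations`, `hits` (external hit
#'   table; builtin k-mer scoring is used otherwise), `bacterial_hits`
#'   (family-level counts), `ref_tree` (newick string or phylo).
#' @param quiet suppress stage progress messages.
#' @return invisibly, a list with all intermediate objects and the
#'   manifest.
#' @export
run_pipeline <- function(out_dir, config = pipeline_config(),
                         sim = NULL, inputs = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    say("[%s] done (%.1fs)", stage, timings[[stage]])
    val
  }

  truth <- NULL
  ref_tree <- NULL
  builtin_hits <- is.null(inputs) || is.null(inputs$hits)
  if (is.null(inputs)) {
    if (is.null(sim)) sim <- synthetic_config(seed = config$seed)
    sim_pa <- clock("simulate", {
      base <- simulate_presence_absence(sim)
      prot <- simulate_proteomes(sim, base$pa, base$truth)
      ann <- simulate_annotations(prot$truth, sim, prot$sequences)
      bact <- simulate_bacterial_hits(ann$truth, sim,
                                      bacterial_min = config$bacterial_min_genomes)
      list(pa = base$pa, taxonomy = base$taxonomy, truth = ann$truth,
           sequences = prot$sequences, proteins = prot$proteins,
           annotations = ann$annotations, planted_bacterial = bact)
    })
    sequences <- sim_pa$sequences
    proteins <- sim_pa$proteins
    taxonomy <- sim_pa$taxonomy
    annotations <- sim_pa$annotations
    truth <- sim_pa$truth
    planted_bacterial <- sim_pa$planted_bacterial
    ref_tree <- truth$generating_tree
    hits <- NULL
  } else {
    sequences <- inputs$sequences
    proteins <- inputs$proteins
    taxonomy <- inputs$taxonomy
    annotations <- inputs$annotations
    planted_bacterial <- inputs$bacterial_hits
    ref_tree <- inputs$ref_tree
    hits <- inputs$hits
    stopifnot(!is.null(proteins), !is.null(taxonomy))
  }

  if (builtin_hits) {
    hits <- clock("similarity", {
      compute_kmer_hits(sequences, k = config$kmer_k,
                        min_bitscore = config$min_bitscore)
    })
    evalue_max <- config$builtin_evalue_max
  } else {
    evalue_max <- config$evalue_max
  }

  ssn <- clock("ssn", build_ssn(hits, proteins, evalue_max = evalue_max,
                                cover_min = config$cover_min))
  subfams <- clock("subfamilies", greedy_set_cover(ssn))
  sedges <- clock("subfamily_edges", subfamily_similarity(
    subfams, ssn, mode = "builtin",
    probability_min = config$subfamily_probability_min,
    coverage_min = config$subfamily_coverage_min))
  families <- clock("families", build_families(
    subfams, sedges, proteins, min_genomes = config$min_genomes,
    inflation = config$mcl_inflation))
  pa <- clock("matrix", build_matrix(families, taxonomy$genome_id))

  modules <- NULL
  module_report <- NULL
  if (ncol(pa) >= 2L) {
    modules <- clock("modules", {
      dend <- hierarchical_cluster(pa_distances(pa, "families"),
                                   config$family_linkage)
      cut_modules(dend, cutoff = config$module_cutoff,
                  min_module_size = config$min_module_size)
    })
    module_report <- clock("module_taxonomy",
                           module_taxonomy_report(modules, pa, taxonomy))
  } else {
    say("[modules] skipped: fewer than 2 wide families")
  }

  metrics <- clock("metrics", {
    memb <- family_membership(families)
    consistency <- if (!is.null(annotations) &&
                       any(!is.na(annotations$kegg_label))) {
      annotation_consistency(memb, annotations)
    }
    admixture <- if (!is.null(annotations)) {
      data.frame(
        family_id = families$family_id,
        admixture = vapply(families$proteins, family_admixture,
                           numeric(1), annotations = annotations),
        stringsAsFactors = FALSE)
    }
    bact <- NULL
    if (!is.null(planted_bacterial) && !is.null(truth)) {
      # planted-family counts mapped to detected families by majority vote
      counts <- setNames(planted_bacterial$n_bacterial_genomes,
                         planted_bacterial$family_id)
      bact <- data.frame(
        family_id = families$family_id,
        n_bacterial_genomes = vapply(families$proteins, function(p) {
          planted <- truth$planted_family_of_protein[p]
          top <- names(sort(table(planted), decreasing = TRUE))[1L]
          as.integer(counts[[top]])
        }, integer(1)),
        stringsAsFactors = FALSE)
    } else if (!is.null(planted_bacterial)) {
      bact <- planted_bacterial
    }
    classification <- if (!is.null(annotations)) {
      classify_families(families, annotations, bact,
                        sp_min = config$sp_fraction,
                        tm_min = config$tm_fraction,
                        bacterial_min = config$bacterial_min_genomes)
    }
    list(consistency = consistency, admixture = admixture,
         classification = classification)
  })

  genome_dend <- NULL
  coph <- NULL
  if (ncol(pa) >= 1L && nrow(pa) >= 2L && all(rowSums(pa) > 0)) {
    genome_dend <- clock("genome_clustering",
                         cluster_genomes(pa, config$genome_linkage))
    if (!is.null(ref_tree)) {
      coph <- clock("cophenetic",
                    cophenetic_correlation(genome_dend, ref_tree))
    }
  } else {
    say("[genome_clustering] skipped: empty matrix or empty genome rows")
  }

  clock("write", {
    write_tsv(taxonomy, file.path(out_dir, "taxonomy.tsv"))
    memb <- merge(as.data.frame(subfams), family_membership(families),
                  by = "protein_id", sort = TRUE)
    memb <- merge(memb, proteins, by = "protein_id", sort = TRUE)
    write_tsv(memb[order(memb$protein_id),
                   c("protein_id", "genome_id", "subfamily_id",
                     "family_id")],
              file.path(out_dir, "membership.tsv"))
    fam_tab <- families[, c("family_id", "representative", "n_subfamilies",
                            "n_proteins", "n_genomes", "is_wide")]
    write_tsv(fam_tab, file.path(out_dir, "families.tsv"))
    write_tsv(sedges, file.path(out_dir, "subfamily_edges.tsv"))
    write_matrix_tsv(pa, file.path(out_dir, "matrix.tsv"))
    if (!is.null(modules)) {
      mod_tab <- module_report
      mod_tab$families <- vapply(modules$modules$families,
                                 paste, character(1), collapse = ";")
      write_tsv(mod_tab, file.path(out_dir, "modules.tsv"))
      writeLines(modules$unassigned,
                 file.path(out_dir, "unassigned_families.txt"))
    }
    if (!is.null(metrics$consistency)) {
      write_tsv(metrics$consistency, file.path(out_dir, "consistency.tsv"))
    }
    if (!is.null(metrics$admixture)) {
      write_tsv(metrics$admixture, file.path(out_dir, "admixture.tsv"))
    }
    if (!is.null(metrics$classification)) {
      write_tsv(metrics$classification,
                file.path(out_dir, "classification.tsv"))
    }
    if (!is.null(genome_dend)) {
      writeLines(dendrogram_newick(genome_dend),
                 file.path(out_dir, "genome_dendrogram.nwk"))
    }
    if (!is.null(ref_tree) && is.character(ref_tree)) {
      writeLines(ref_tree, file.path(out_dir, "reference_tree.nwk"))
    }
    NULL
  })

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package = "archfam",
    version = as.character(packageVersion("archfam")),
    r_version = R.version.string,
    seed = config$seed,
    config = unclass(config),
    synthetic = if (!is.null(sim)) unclass(sim),
    cophenetic_correlation = coph,
    stage_timings_s = timings,
    files = as.list(setNames(unname(tools::md5sum(files)),
                             basename(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  say("pipeline complete: %s", out_dir)

  invisible(list(
    out_dir = out_dir, config = config, sim = sim,
    sequences = sequences, proteins = proteins, taxonomy = taxonomy,
    annotations = annotations, truth = truth, hits = hits, ssn = ssn,
    subfamilies = subfams, subfamily_edges = sedges, families = families,
    pa = pa, modules = modules, module_report = module_report,
    metrics = metrics, genome_dendrogram = genome_dend,
    cophenetic_correlation = coph, manifest = manifest))
}
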