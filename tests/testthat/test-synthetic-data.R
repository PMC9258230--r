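test_that("configuration validation rejects out-of-range parameters", {
  expect_error(synthetic_config(within_lineage_prevalence = 1.2),
               "probability")
  expect_error(synthetic_config(background_rate = -0.1), "probability")
  expect_error(synthetic_config(n_lineages = 0), ">= 1")
  expect_error(synthetic_config(module_sizes = c(10L, 10L)),
               "one entry per lineage")
  expect_error(synthetic_config(substitution_rate = 1), "< 1|probability")
})

test_that("noise-free limit produces an exact block presence matrix", {
  cfg <- tiny_cfg(core_prevalence = 1, within_lineage_prevalence = 1,
                  background_rate = 0)
  sim <- simulate_presence_absence(cfg)
  core <- names(sim$truth$planted_module_of_family)[
    sim$truth$planted_module_of_family == "core"]
  expect_true(all(sim$pa[, core]))
  for (lin in unique(sim$taxonomy$phylum)) {
    fams <- names(sim$truth$planted_module_of_family)[
      sim$truth$planted_module_of_family == lin]
    inside <- sim$taxonomy$genome_id[sim$taxonomy$phylum == lin]
    outside <- setdiff(sim$taxonomy$genome_id, inside)
    expect_true(all(sim$pa[inside, fams]))
    expect_false(any(sim$pa[outside, fams]))
  }
})

test_that("block fill matches the configured prevalence within 3 binomial SEs", {
  cfg <- synthetic_config(n_lineages = 1L, genomes_per_lineage = 40L,
                          core_family_count = 1L, module_sizes = 100L,
                          within_lineage_prevalence = 0.65,
                          background_rate = 0, seed = 11L)
  sim <- simulate_presence_absence(cfg)
  block <- sim$pa[, grep("^Lineage01F", colnames(sim$pa))]
  se <- sqrt(0.65 * 0.35 / (40 * 100))
  expect_lt(abs(mean(block) - 0.65), 3 * se)
})

test_that("one planted non-core module label exists per lineage", {
  cfg <- synthetic_config(n_lineages = 5L, module_sizes = rep(30L, 5),
                          seed = 3L)
  sim <- simulate_presence_absence(cfg)
  labels <- setdiff(unique(sim$truth$planted_module_of_family), "core")
  expect_length(labels, 5L)
})

test_that("the generating tree covers every genome with lineage clades", {
  cfg <- tiny_cfg()
  sim <- simulate_presence_absence(cfg)
  tree <- ape::read.tree(text = sim$truth$generating_tree)
  expect_setequal(tree$tip.label, sim$taxonomy$genome_id)
  d <- ape::cophenetic.phylo(tree)
  same <- outer(sim$taxonomy$phylum, sim$taxonomy$phylum, "==")
  dimnames(same) <- list(sim$taxonomy$genome_id, sim$taxonomy$genome_id)
  same <- same[rownames(d), colnames(d)]
  expect_true(all(d[same & upper.tri(d)] < min(d[!same])))
})

test_that("substitution-free proteomes copy the ancestor exactly", {
  cfg <- tiny_cfg(substitution_rate = 0)
  sim <- simulate_presence_absence(cfg)
  prot <- simulate_proteomes(cfg, sim$pa, sim$truth)
  fam_of <- prot$truth$planted_family_of_protein
  for (f in unique(fam_of)) {
    members <- names(fam_of)[fam_of == f]
    expect_length(unique(prot$sequences[members]), 1L)
  }
})

test_that("no protein is emitted for an absent (genome, family) cell", {
  cfg <- tiny_cfg(within_lineage_prevalence = 0.5, background_rate = 0)
  sim <- simulate_presence_absence(cfg)
  prot <- simulate_proteomes(cfg, sim$pa, sim$truth)
  fam_of <- prot$truth$planted_family_of_protein
  genome_of <- setNames(prot$proteins$genome_id, prot$proteins$protein_id)
  emitted <- table(genome_of[names(fam_of)], fam_of)
  for (g in rownames(emitted)) {
    for (f in colnames(emitted)) {
      expect_identical(unname(emitted[g, f] > 0), unname(sim$pa[g, f]))
    }
  }
})

test_that("pairwise identity matches the closed-form substitution model", {
  s <- 0.05
  L <- 200L
  cfg <- synthetic_config(n_lineages = 1L, genomes_per_lineage = 2L,
                          core_family_count = 100L, module_sizes = 1L,
                          core_prevalence = 1, seq_length = L,
                          substitution_rate = s, seed = 5L)
  sim <- simulate_presence_absence(cfg)
  prot <- simulate_proteomes(cfg, sim$pa, sim$truth)
  fam_of <- prot$truth$planted_family_of_protein
  core <- grep("^coreF", unique(fam_of), value = TRUE)
  ident <- vapply(core, function(f) {
    m <- names(fam_of)[fam_of == f]
    a <- strsplit(prot$sequences[[m[1]]], "")[[1]]
    b <- strsplit(prot$sequences[[m[2]]], "")[[1]]
    mean(a == b)
  }, numeric(1))
  p <- (1 - s)^2 + s^2 / 19       # both copies mutate independently
  se <- sqrt(p * (1 - p) / (L * length(core)))
  expect_lt(abs(mean(ident) - p), 3 * se)
})

test_that("annotation admixture is exactly zero when the rate is zero", {
  cfg <- tiny_cfg(admixture_rate = 0, kegg_label_rate = 1)
  sim <- simulate_presence_absence(cfg)
  prot <- simulate_proteomes(cfg, sim$pa, sim$truth)
  ann <- simulate_annotations(prot$truth, cfg, prot$sequences)
  expect_identical(ann$annotations$kegg_label,
                   unname(ann$truth$true_label_of_protein))
})

test_that("zero label rate yields an unannotated table", {
  cfg <- tiny_cfg(kegg_label_rate = 0)
  sim <- simulate_presence_absence(cfg)
  prot <- simulate_proteomes(cfg, sim$pa, sim$truth)
  ann <- simulate_annotations(prot$truth, cfg, prot$sequences)
  expect_true(all(is.na(ann$annotations$kegg_label)))
})

test_that("realized admixture tracks the configured rate", {
  cfg <- synthetic_config(n_lineages = 2L, genomes_per_lineage = 50L,
                          core_family_count = 20L, module_sizes = c(1L, 1L),
                          core_prevalence = 1, kegg_label_rate = 1,
                          admixture_rate = 0.2, seq_length = 30L, seed = 9L)
  sim <- simulate_presence_absence(cfg)
  prot <- simulate_proteomes(cfg, sim$pa, sim$truth)
  ann <- simulate_annotations(prot$truth, cfg, prot$sequences)
  wrong <- ann$annotations$kegg_label !=
    unname(ann$truth$true_label_of_protein)
  se <- sqrt(0.2 * 0.8 / length(wrong))
  expect_lt(abs(mean(wrong) - 0.2), 3 * se)
  # a single 100-member family stays within 3 per-family binomial SEs
  fam_of <- prot$truth$planted_family_of_protein
  m100 <- names(fam_of)[fam_of == "coreF001"]
  adm <- family_admixture(m100, ann$annotations)
  expect_lt(abs(adm - 20), 3 * 100 * sqrt(0.2 * 0.8 / length(m100)))
})

test_that("a fixed seed reproduces every generator output bit-identically", {
  cfg <- tiny_cfg()
  run <- function() {
    sim <- simulate_presence_absence(cfg)
    prot <- simulate_proteomes(cfg, sim$pa, sim$truth)
    ann <- simulate_annotations(prot$truth, cfg, prot$sequences)
    bact <- simulate_bacterial_hits(ann$truth, cfg)
    list(sim$pa, sim$taxonomy, prot$sequences, ann$annotations, bact)
  }
  expect_identical(run(), run())
})

test_that("truth partitions the proteins with no orphans", {
  cfg <- tiny_cfg()
  sim <- simulate_presence_absence(cfg)
  prot <- simulate_proteomes(cfg, sim$pa, sim$truth)
  fam_of <- prot$truth$planted_family_of_protein
  expect_setequal(names(fam_of), prot$proteins$protein_id)
  expect_false(anyDuplicated(names(fam_of)) > 0)
  expect_true(all(fam_of %in% names(sim$truth$planted_module_of_family)))
})

test_that("FASTA round-trip preserves sequences and genome assignment", {
  cfg <- tiny_cfg()
  sim <- simulate_presence_absence(cfg)
  prot <- simulate_proteomes(cfg, sim$pa, sim$truth)
  dir <- withr::local_tempdir()
  paths <- write_proteomes(prot$sequences, prot$proteins, dir)
  back <- read_proteomes(paths)
  expect_identical(back$sequences[names(prot$sequences)], prot$sequences)
  expect_equal(
    back$proteins[order(back$proteins$protein_id), ],
    prot$proteins[order(prot$proteins$protein_id), ],
    ignore_attr = TRUE)
})
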