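toy_families <- function() {
  f <- data.frame(
    family_id = c("fam00001", "fam00002"),
    representative = c("p1", "p9"),
    n_subfamilies = 1L,
    n_proteins = c(2L, 1L),
    n_genomes = c(2L, 1L),
    is_wide = c(TRUE, FALSE),
    stringsAsFactors = FALSE)
  f$subfamilies <- I(list("sub00001", "sub00002"))
  f$proteins <- I(list(c("p1", "p2"), "p9"))
  f$genomes <- I(list(c("g1", "g2"), "g3"))
  class(f) <- c("archfam_families", "data.frame")
  f
}

test_that("presence/absence matrix marks member genomes per column", {
  fams <- toy_families()
  pa <- build_matrix(fams, c("g1", "g2", "g3"), wide_only = FALSE)
  expect_equal(unname(pa[, "fam00001"]), c(TRUE, TRUE, FALSE))
  expect_equal(unname(pa[, "fam00002"]), c(FALSE, FALSE, TRUE))
  # wide-only drops the 1-genome family
  expect_equal(colnames(build_matrix(fams, c("g1", "g2", "g3"))),
               "fam00001")
  # zero wide families is a valid degenerate matrix
  fams$is_wide <- FALSE
  expect_equal(ncol(build_matrix(fams, c("g1", "g2", "g3"))), 0L)
  expect_error(build_matrix(toy_families(), c("g1", "g2"),
                            wide_only = FALSE), "g3")
})

test_that("matrix round-trips through family construction when noise-free", {
  cfg <- tiny_cfg(substitution_rate = 0, genomes_per_lineage = 6L)
  sim <- simulate_presence_absence(cfg)
  prot <- simulate_proteomes(cfg, sim$pa, sim$truth)
  hits <- compute_kmer_hits(prot$sequences, min_bitscore = 0.1)
  net <- build_ssn(hits, prot$proteins, evalue_max = 0.5, cover_min = 0.5)
  fams <- build_families(greedy_set_cover(net), NULL, prot$proteins,
                         min_genomes = 1L)
  pa <- build_matrix(fams, rownames(sim$pa), wide_only = FALSE)
  # map detected columns to planted columns via their genome sets
  planted_cols <- apply(sim$pa, 2, function(col) {
    paste(sort(rownames(sim$pa)[col]), collapse = ",")
  })
  detected_cols <- apply(pa, 2, function(col) {
    paste(sort(rownames(pa)[col]), collapse = ",")
  })
  expect_equal(sort(unname(planted_cols)), sort(unname(detected_cols)))
})

test_that("Jaccard distance matches hand arithmetic and vegan", {
  expect_equal(jaccard_distance(c(1, 1, 0), c(1, 1, 0)), 0)
  expect_equal(jaccard_distance(c(1, 0, 0), c(0, 1, 1)), 1)
  expect_equal(jaccard_distance(c(1, 1, 0), c(1, 0, 1)), 2 / 3)
  expect_error(jaccard_distance(c(0, 0), c(0, 0)), "all-FALSE")
  expect_error(jaccard_distance(c(1, 0), c(1, 0, 1)), "equal length")

  set.seed(23)
  m <- matrix(runif(60) < 0.5, nrow = 6,
              dimnames = list(sprintf("g%d", 1:6), sprintf("f%d", 1:10)))
  m[rowSums(m) == 0, 1] <- TRUE
  d <- as.matrix(pa_distances(m, "genomes"))
  for (i in 1:5) {
    for (j in (i + 1):6) {
      expect_equal(d[i, j], jaccard_distance(m[i, ], m[j, ]))
    }
  }
})

test_that("hierarchical clustering reproduces hand-computed merge orders", {
  d <- as.dist(matrix(c(0, 0.1, 0.9,
                        0.1, 0, 0.9,
                        0.9, 0.9, 0), 3,
                      dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  hc <- hierarchical_cluster(d, "complete")
  expect_equal(hc$height, c(0.1, 0.9))
  expect_equal(sort(hc$merge[1, ]), sort(-match(c("A", "B"), hc$labels)))

  # two tight pairs then the root
  nm <- c("A", "B", "C", "D")
  m <- matrix(0.95, 4, 4, dimnames = list(nm, nm))
  m[cbind(c(1, 2), c(2, 1))] <- 0.05
  m[cbind(c(3, 4), c(4, 3))] <- 0.04
  diag(m) <- 0
  hc2 <- hierarchical_cluster(as.dist(m), "complete")
  expect_equal(hc2$height, c(0.04, 0.05, 0.95))

  # equidistant points all join at one height
  deq <- as.dist(matrix(0.5, 3, 3) - diag(0.5, 3))
  expect_true(all(hierarchical_cluster(deq, "average")$height == 0.5))
})

test_that("module cutting enforces cutoff and minimum size", {
  # 25 identical profiles plus 5 scattered families
  set.seed(41)
  genomes <- sprintf("g%02d", 1:20)
  bg <- matrix(FALSE, 20, 5,
               dimnames = list(genomes, sprintf("bg%02d", 1:5)))
  bg[11:20, ] <- runif(50) < 0.5            # disjoint from the module block
  bg[11, colSums(bg) == 0] <- TRUE
  pa <- cbind(
    matrix(rep(c(rep(TRUE, 10), rep(FALSE, 10)), 25), ncol = 25,
           dimnames = list(genomes, sprintf("mod%02d", 1:25))),
    bg)
  dend <- hierarchical_cluster(pa_distances(pa, "families"), "complete")
  mods <- cut_modules(dend, cutoff = 0.95, min_module_size = 20)
  expect_equal(nrow(mods$modules), 1L)
  expect_setequal(mods$modules$families[[1]], sprintf("mod%02d", 1:25))

  # 19 co-occurring families stay below the module size threshold
  pa19 <- pa[, c(1:19, 26:30)]
  dend19 <- hierarchical_cluster(pa_distances(pa19, "families"),
                                 "complete")
  mods19 <- cut_modules(dend19, cutoff = 0.95, min_module_size = 20)
  expect_equal(nrow(mods19$modules), 0L)
  expect_true(all(sprintf("mod%02d", 1:19) %in% mods19$unassigned))

  expect_error(cut_modules(dend, cutoff = 1.5), "0, 1")
})

test_that("degenerate cutoffs give one cluster or all singletons", {
  set.seed(13)
  pa <- matrix(runif(80) < 0.4, nrow = 8,
               dimnames = list(sprintf("g%d", 1:8), sprintf("f%02d", 1:10)))
  pa[, colSums(pa) == 0] <- TRUE
  dend <- hierarchical_cluster(pa_distances(pa, "families"), "complete")
  all_in_one <- cut_modules(dend, cutoff = 1, min_module_size = 1)
  expect_equal(nrow(all_in_one$modules), 1L)
  expect_equal(all_in_one$modules$n_families, 10L)
  # distinct profiles only merge above height zero
  if (min(dend$height) > 0) {
    singletons <- cut_modules(dend, cutoff = 0, min_module_size = 1)
    expect_equal(nrow(singletons$modules), 10L)
  }
})

test_that("module taxonomy follows the median-m top-m rule exactly", {
  genomes <- c("g1", "g2", "g3", "g4")
  pa <- matrix(FALSE, 4, 3, dimnames = list(genomes, c("f1", "f2", "f3")))
  pa[c("g1", "g2", "g3", "g4"), "f1"] <- TRUE
  pa[c("g1", "g2"), "f2"] <- TRUE
  pa[c("g1", "g2", "g3"), "f3"] <- TRUE
  taxonomy <- data.frame(genome_id = genomes,
                         phylum = c("P", "P", "Q", "Q"))
  tx <- assign_module_taxonomy(c("f1", "f2", "f3"), pa, taxonomy)
  expect_equal(tx$m, 3L)
  expect_setequal(tx$retained_genomes, c("g1", "g2", "g3"))
  expect_equal(tx$taxonomy_distribution, c(P = 2L, Q = 1L))

  # identical 10-genome families: m = 10, one-phylum distribution
  g10 <- sprintf("h%02d", 1:10)
  pa10 <- matrix(TRUE, 10, 21, dimnames = list(g10, sprintf("f%02d", 1:21)))
  tax10 <- data.frame(genome_id = g10, phylum = "R")
  tx10 <- assign_module_taxonomy(colnames(pa10), pa10, tax10)
  expect_equal(tx10$m, 10L)
  expect_equal(tx10$taxonomy_distribution, c(R = 10L))

  expect_error(assign_module_taxonomy(character(0), pa, taxonomy),
               "empty module")
})

test_that("module taxonomy is invariant to genome row order", {
  cfg <- module_cfg(seed = 21, n_lineages = 6L)
  sim <- simulate_presence_absence(cfg)
  fams <- names(sim$truth$planted_module_of_family)[
    sim$truth$planted_module_of_family == "Lineage03"]
  tx1 <- assign_module_taxonomy(fams, sim$pa, sim$taxonomy)
  perm <- sample(nrow(sim$pa))
  tx2 <- assign_module_taxonomy(fams, sim$pa[perm, ], sim$taxonomy)
  expect_equal(tx1, tx2)
})

test_that("planted lineage modules get a pure taxonomy when noise-free", {
  cfg <- tiny_cfg(core_prevalence = 1, within_lineage_prevalence = 1,
                  background_rate = 0)
  sim <- simulate_presence_absence(cfg)
  for (lin in unique(sim$taxonomy$phylum)) {
    fams <- names(sim$truth$planted_module_of_family)[
      sim$truth$planted_module_of_family == lin]
    tx <- assign_module_taxonomy(fams, sim$pa, sim$taxonomy)
    expect_equal(names(tx$taxonomy_distribution), lin)
  }
})

test_that("matrix TSV round-trips", {
  cfg <- tiny_cfg()
  sim <- simulate_presence_absence(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(sim$pa, path)
  expect_identical(read_matrix_tsv(path), sim$pa)
})
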