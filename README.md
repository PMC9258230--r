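# archfam

Protein families, co-occurrence modules and genome clustering for
microbial pangenomes.

## What it does

Comparative genomics of lineages dominated by hypothetical proteins
(archaea being the canonical case) works best when genomes are compared
by their *protein family* content rather than by functional annotation.
`archfam` implements that analysis end to end:

1. **Sequence similarity network** — all-vs-all protein hits filtered at
   e-value ≤ 0.001 and coverage ≥ 0.5 (external BLAST/MMseqs2 outfmt6
   tables, or a built-in k-mer scorer for desk-scale work).
2. **Subfamilies** — greedy set cover over the network: the node whose
   closed neighbourhood covers the most uncovered proteins becomes a
   representative; the result partitions the proteins.
3. **Families** — Markov clustering (inflation 2.0) of a subfamily graph
   whose edges require probability ≥ 95% and coverage ≥ 0.50 and are
   weighted by probability × coverage. Families spanning ≥ 5 distinct
   genomes are "wide".
4. **Modules** — genome × family presence/absence matrix; families
   clustered by Jaccard distance (complete linkage) and the dendrogram
   cut at height 0.95; clusters of ≥ 20 families are modules. Each
   module gets a taxonomy by the median-m rule: retain the m genomes
   carrying the most module families, where m is the median number of
   genomes per family.
5. **Quality and classification** — annotation consistency and
   admixture; family classification (signal peptide ≥ 25% of members,
   transmembrane > 50%, hypothetical = no KEGG and no non-DUF PFAM,
   bacterial homologs in ≥ 10 genomes); gene-neighbourhood summaries;
   SCG-based genome quality (> 26 of 38 SCGs present, > 22 for DPANN,
   < 4 duplicated) and ANI-cluster representative selection.
6. **Genome clustering** — genomes clustered by family content and
   compared with a reference phylogeny via the cophenetic correlation
   (Pearson over pairwise merge heights vs patristic distances).

A synthetic pangenome generator with planted ground truth (lineages,
core block, lineage-specific modules, sequence divergence, noisy
labels) makes every stage testable without downloading anything.

## Worked example

```r
library(archfam)

sim <- synthetic_config(seed = 42)       # 5 lineages x 10 genomes,
                                         # 40 core + 5 x 30 module families
res <- run_pipeline("archfam_run", config = pipeline_config(seed = 42),
                    sim = sim)

res$families
#> 191 protein families over 3307 proteins; 190 wide (>= min_genomes)

res$module_report[, c("module_id", "n_families", "m", "taxonomy")]
#>   module_id n_families  m                              taxonomy
#> 1 module001         70 46 Lineage01:10;Lineage04:10;Lineage02:9;...
#> 2 module002         30  9                           Lineage03:9
#> 3 module003         30  9                           Lineage05:9
#> 4 module004         30  9                           Lineage04:9
#> 5 module005         30 10                          Lineage02:10

res$cophenetic_correlation
#> [1] 0.9930686
```

The run recovers the planted families at adjusted Rand index 0.9999
(`mclust::adjustedRandIndex` against the generator's truth record), the
four smaller modules are the planted lineage modules with pure
taxonomies, and the genome dendrogram correlates at 0.99 with the
generating tree. `module001` illustrates a geometry effect worth knowing
about: with only five lineages each lineage is 20% of the matrix, so
the core block and its nearest lineage module sit closer than the 0.95
cut and merge — with many small lineages (the regime of real
domain-wide datasets) every planted module is recovered exactly. The
methods vignette (`vignettes/archfam-methods.Rmd`) works through the
model, the thresholds and this geometry argument in detail.

Each run directory contains the membership, family, matrix, module,
metric and classification tables as TSV, newick trees, and a
`manifest.json` with the configuration, seed, stage timings and output
checksums; reruns under the same seed are byte-identical.

A thin command-line wrapper ships in `inst/scripts/archfam.R`:

```sh
Rscript inst/scripts/archfam.R simulate --out sim --preset small --seed 42
Rscript inst/scripts/archfam.R run --out run1 --seed 42
```

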