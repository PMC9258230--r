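# file interfaces: FASTA proteomes, TSV tables, trees

#' Write per-genome proteome FASTA files
#'
#' One file per genome, headers `>proteinID genome=GENOMEID`.
#'
#' @param sequences named character vector of amino-acid strings.
#' @param proteins data frame: protein_id, genome_id.
#' @param dir output directory (created if absent).
#' @return invisibly, the written file paths.
#' @export
write_proteomes <- function(sequences, proteins, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (g in unique(proteins$genome_id)) {
    ids <- proteins$protein_id[proteins$genome_id == g]
    ss <- Biostrings::AAStringSet(sequences[ids])
    names(ss) <- sprintf("%s genome=%s", ids, g)
    path <- file.path(dir, paste0(g, ".faa"))
    Biostrings::writeXStringSet(ss, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read per-genome proteome FASTA files
#'
#' Accepts headers of the form `>proteinID genome=GENOMEID`; when the
#' `genome=` tag is absent, the genome id is taken from the file name.
#'
#' @param paths FASTA file paths.
#' @return list with `sequences` (named character vector) and `proteins`
#'   (data frame: protein_id, genome_id).
#' @export
read_proteomes <- function(paths) {
  seqs <- character(0)
  ids <- character(0)
  genomes <- character(0)
  for (p in paths) {
    ss <- Biostrings::readAAStringSet(p)
    header <- names(ss)
    pid <- sub("\\s.*$", "", header)
    g <- ifelse(grepl("genome=", header),
                sub(".*genome=([^ ]+).*", "\\1", header),
                tools::file_path_sans_ext(basename(p)))
    seqs <- c(seqs, setNames(as.character(ss), pid))
    ids <- c(ids, pid)
    genomes <- c(genomes, g)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate protein ids across FASTA files: ",
         collapse_ids(unique(ids[duplicated(ids)])), call. = FALSE)
  }
  list(sequences = seqs,
       proteins = data.frame(protein_id = ids, genome_id = genomes,
                             stringsAsFactors = FALSE))
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a presence/absence matrix as 0/1 TSV
#'
#' First column `genome_id`, one 0/1 column per family.
#'
#' @param pa logical genome x family matrix.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_matrix_tsv <- function(pa, path) {
  out <- data.frame(genome_id = rownames(pa), pa * 1L,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(out, path)
}

#' Read a presence/absence matrix from 0/1 TSV
#'
#' @param path file written by [write_matrix_tsv()].
#' @return logical genome x family matrix.
#' @export
read_matrix_tsv <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE]) == 1
  rownames(m) <- tab[[1]]
  m
}
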