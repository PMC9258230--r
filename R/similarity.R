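#' K-mer based similarity between two protein sequences
#'
#' A desk-scale stand-in for an all-vs-all homology search tool. The
#' bitscore is the number of distinct shared k-mers normalised by the
#' distinct k-mer count of the shorter sequence (ties: the smaller of the
#' two counts, keeping the score symmetric), the coverage is the fraction
#' of the shorter sequence's positions covered by occurrences of shared
#' k-mers (ties: the larger of the two coverages), and the e-value proxy
#' is `1 - bitscore`. Note the proxy is not on the scale of alignment
#' E-values; thresholds for it are configured separately (see
#' [pipeline_config()]).
#'
#' @param seq_a,seq_b amino-acid strings of length >= `k`.
#' @param k k-mer window length.
#' @return a list with `bitscore`, `coverage` and `evalue`, all in \[0, 1\].
#' @examples
#' kmer_similarity("ACDEFGHIK", "ACDEFWWWW", k = 4)$bitscore  # 2/6
#' @export
kmer_similarity <- function(seq_a, seq_b, k = 4L) {
  ka <- seq_kmers(seq_a, k, "seq_a")
  kb <- seq_kmers(seq_b, k, "seq_b")
  kmer_pair_stats(ka, kb, nchar(seq_a), nchar(seq_b), k)
}

seq_kmers <- function(x, k, name = deparse(substitute(x))) {
  n <- nchar(x)
  if (n < k) {
    stop(sprintf("sequence '%s' (length %d) is shorter than k = %d",
                 name, n, k), call. = FALSE)
  }
  substring(x, seq_len(n - k + 1L), seq.int(k, n))
}

# core pair statistics; kma/kmb are k-mer vectors in positional order
# (character or integer-coded, as long as both use the same coding)
kmer_pair_stats <- function(kma, kmb, la, lb, k) {
  ua <- unique(kma)
  ub <- unique(kmb)
  shared <- ua[ua %in% ub]
  n_short <- min(length(ua), length(ub))
  if (la < lb) n_short <- length(ua)
  if (lb < la) n_short <- length(ub)
  bitscore <- if (n_short > 0L) length(shared) / n_short else 0
  cov_of <- function(km, len) {
    pos <- which(km %in% shared)
    if (!length(pos)) return(0)
    covered <- unique(as.vector(outer(pos, seq_len(k) - 1L, `+`)))
    length(covered) / len
  }
  coverage <- if (la < lb) {
    cov_of(kma, la)
  } else if (lb < la) {
    cov_of(kmb, lb)
  } else {
    max(cov_of(kma, la), cov_of(kmb, lb))
  }
  list(bitscore = bitscore, coverage = coverage, evalue = 1 - bitscore)
}

#' All-vs-all k-mer similarity hits for a set of sequences
#'
#' Builds a sparse k-mer/protein incidence matrix and counts shared
#' distinct k-mers for every sequence pair in one sparse cross-product;
#' exact bitscore and coverage (as in [kmer_similarity()]) are then
#' computed for candidate pairs whose shared-k-mer bound reaches
#' `min_bitscore`. The bound is never below the true bitscore, so no
#' qualifying pair is lost to the prefilter.
#'
#' @param sequences named character vector of amino-acid strings.
#' @param k k-mer window length.
#' @param min_bitscore report only pairs with bitscore at or above this
#'   value (0 reports every pair sharing at least one k-mer).
#' @return data frame of similarity hits: query_id, target_id, bitscore,
#'   coverage, evalue; one row per unordered pair.
#' @export
compute_kmer_hits <- function(sequences, k = 4L, min_bitscore = 0.1) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  ids <- names(sequences)
  n <- length(sequences)
  lens <- nchar(sequences)
  short <- which(lens < k)
  if (length(short)) {
    stop(sprintf("sequence '%s' (length %d) is shorter than k = %d",
                 ids[short[1L]], lens[short[1L]], k), call. = FALSE)
  }
  if (n < 2L) {
    return(data.frame(query_id = character(), target_id = character(),
                      bitscore = numeric(), coverage = numeric(),
                      evalue = numeric(), stringsAsFactors = FALSE))
  }
  km <- lapply(seq_len(n), function(i) {
    substring(sequences[[i]], seq_len(lens[i] - k + 1L), seq.int(k, lens[i]))
  })
  all_k <- unique(unlist(km, use.names = FALSE))
  ikm <- lapply(km, match, table = all_k)        # integer-coded, positional
  ukm <- lapply(ikm, unique)
  nk <- lengths(ukm)

  M <- Matrix::sparseMatrix(
    i = unlist(ukm, use.names = FALSE),
    j = rep.int(seq_len(n), nk),
    x = 1,
    dims = c(length(all_k), n))
  C <- Matrix::crossprod(M)
  CT <- methods::as(Matrix::triu(C, k = 1), "TsparseMatrix")
  qi <- CT@i + 1L
  ti <- CT@j + 1L
  shared_n <- CT@x
  bound <- shared_n / pmin(nk[qi], nk[ti])
  keep <- which(bound >= min_bitscore)
  if (!length(keep)) {
    return(data.frame(query_id = character(), target_id = character(),
                      bitscore = numeric(), coverage = numeric(),
                      evalue = numeric(), stringsAsFactors = FALSE))
  }
  qi <- qi[keep]; ti <- ti[keep]
  res <- vapply(seq_along(qi), function(p) {
    s <- kmer_pair_stats(ikm[[qi[p]]], ikm[[ti[p]]],
                         lens[qi[p]], lens[ti[p]], k)
    c(s$bitscore, s$coverage)
  }, numeric(2))
  out <- data.frame(query_id = ids[qi], target_id = ids[ti],
                    bitscore = res[1L, ], coverage = res[2L, ],
                    evalue = 1 - res[1L, ], stringsAsFactors = FALSE)
  out <- out[out$bitscore >= min_bitscore, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a tabular all-vs-all hit table (BLAST/MMseqs2 outfmt6 dialect)
#'
#' The default column layout is the 12-column outfmt6 convention; extra
#' `qcov`/`tcov` columns are used when present. Coverage follows a
#' bidirectional reading: `min(qcov, tcov)` when both are available,
#' otherwise alignment length divided by the shorter sequence length when
#' `protein_lengths` is supplied. Hits whose coverage cannot be derived
#' are dropped with a warning (fail-closed).
#'
#' @param path tab-separated hit table, no header.
#' @param columns character vector naming the columns in file order;
#'   must include `query`, `target`, `evalue`, `bitscore` and either
#'   both `qcov` and `tcov` or `alnlen`.
#' @param protein_lengths optional named vector of sequence lengths used
#'   to derive coverage from `alnlen`.
#' @return data frame: query_id, target_id, bitscore, coverage, evalue.
#' @export
read_hit_table <- function(path,
                           columns = c("query", "target", "pident", "alnlen",
                                       "mismatch", "gapopen", "qstart",
                                       "qend", "tstart", "tend", "evalue",
                                       "bitscore"),
                           protein_lengths = NULL) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < length(columns)) {
    stop(sprintf("hit table has %d columns but %d column names were given",
                 ncol(tab), length(columns)), call. = FALSE)
  }
  names(tab)[seq_along(columns)] <- columns
  for (req in c("query", "target", "evalue", "bitscore")) {
    if (!req %in% columns) {
      stop(sprintf("column map must include '%s'", req), call. = FALSE)
    }
  }
  if (all(c("qcov", "tcov") %in% columns)) {
    coverage <- pmin(tab$qcov, tab$tcov)
  } else if ("alnlen" %in% columns && !is.null(protein_lengths)) {
    lq <- protein_lengths[tab$query]
    lt <- protein_lengths[tab$target]
    coverage <- tab$alnlen / pmin(lq, lt)
  } else {
    coverage <- rep(NA_real_, nrow(tab))
  }
  bad <- is.na(coverage)
  if (any(bad)) {
    warning(sprintf(
      "dropping %d hit(s) with underivable coverage (no qcov/tcov and no sequence lengths)",
      sum(bad)))
  }
  data.frame(query_id = tab$query[!bad], target_id = tab$target[!bad],
             bitscore = tab$bitscore[!bad],
             coverage = pmin(coverage[!bad], 1),
             evalue = tab$evalue[!bad], stringsAsFactors = FALSE)
}

#' Build the filtered protein sequence similarity network
#'
#' Retains a hit as an edge iff `evalue <= evalue_max` and
#' `coverage >= cover_min`; self-hits are dropped, reciprocal hits are
#' collapsed to one undirected edge keeping the hit with the highest
#' bitscore (ties: highest coverage), and proteins without any retained
#' hit stay in the network as isolated nodes. The result is independent
#' of the order of the hit list.
#'
#' @param hits data frame with columns query_id, target_id, evalue,
#'   coverage, bitscore (from [compute_kmer_hits()] or
#'   [read_hit_table()]).
#' @param proteins data frame with columns protein_id and genome_id
#'   listing every known protein.
#' @param evalue_max maximum e-value (or e-value proxy) for an edge.
#' @param cover_min minimum coverage for an edge.
#' @return an [igraph::igraph] with vertex attribute `genome` and edge
#'   attributes `weight` (bitscore) and `coverage`.
#' @export
build_ssn <- function(hits, proteins, evalue_max = 0.001, cover_min = 0.5) {
  stopifnot(is.data.frame(proteins),
            all(c("protein_id", "genome_id") %in% names(proteins)))
  need <- c("query_id", "target_id", "evalue", "coverage", "bitscore")
  if (!all(need %in% names(hits))) {
    stop("hits must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(unique(c(hits$query_id, hits$target_id)),
                     proteins$protein_id)
  if (length(unknown)) {
    stop("hits reference unknown protein id(s): ", collapse_ids(unknown),
         call. = FALSE)
  }
  keep <- hits$query_id != hits$target_id &
    hits$evalue <= evalue_max & hits$coverage >= cover_min
  ed <- hits[keep, , drop = FALSE]
  if (nrow(ed)) {
    a <- pmin(ed$query_id, ed$target_id)
    b <- pmax(ed$query_id, ed$target_id)
    ord <- order(a, b, -ed$bitscore, -ed$coverage)
    a <- a[ord]; b <- b[ord]; ed <- ed[ord, , drop = FALSE]
    first <- !duplicated(paste(a, b, sep = "\r"))
    edges <- data.frame(from = a[first], to = b[first],
                        weight = ed$bitscore[first],
                        coverage = ed$coverage[first],
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), coverage = numeric(),
                        stringsAsFactors = FALSE)
  }
  igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = proteins$protein_id,
                          genome = proteins$genome_id,
                          stringsAsFactors = FALSE))
}
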