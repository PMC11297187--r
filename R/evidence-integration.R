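#' Three-way intersection of candidate gene sets
#'
#' Computes the seven Venn region cardinalities over the kmer, family and
#' differential-expression candidate sets and returns the union with
#' per-gene evidence flags. With `de_set = NULL` the intersection runs in
#' two-set mode (the `de` regions are reported as `NA`).
#'
#' @param kmer_set,family_set,de_set character vectors of reference gene
#'   ids; `de_set` may be NULL.
#' @return list with `venn` (named numeric: `kmer_only`, `family_only`,
#'   `de_only`, `kmer_family`, `kmer_de`, `family_de`, `all_three`) and
#'   `candidates` ([S4Vectors::DataFrame]: `gene_id`, `from_kmer`,
#'   `from_family`, `from_de`).
#' @export
intersectCandidates <- function(kmer_set, family_set, de_set = NULL) {
  A <- unique(kmer_set)
  B <- unique(family_set)
  has_de <- !is.null(de_set)
  C <- if (has_de) unique(de_set) else character(0)
  u <- union(union(A, B), C)
  fa <- u %in% A
  fb <- u %in% B
  fc <- u %in% C
  venn <- c(
    kmer_only = sum(fa & !fb & !fc),
    family_only = sum(!fa & fb & !fc),
    de_only = if (has_de) sum(!fa & !fb & fc) else NA_real_,
    kmer_family = sum(fa & fb & !fc),
    kmer_de = if (has_de) sum(fa & !fb & fc) else NA_real_,
    family_de = if (has_de) sum(!fa & fb & fc) else NA_real_,
    all_three = if (has_de) sum(fa & fb & fc) else NA_real_)
  storage.mode(venn) <- "double"
  list(venn = venn,
       candidates = DataFrame(gene_id = u, from_kmer = fa, from_family = fb,
                              from_de = if (has_de) fc else rep(NA, length(u))))
}

#' Call gene clusters by genomic adjacency
#'
#' Per contig of the reference strain, finds maximal runs of candidate
#' genes in which consecutive candidates are separated by at most
#' `max_gap` non-candidate genes; runs with at least `min_genes` members
#' are returned, largest first.
#'
#' @param candidates character vector of candidate gene ids or the
#'   `candidates` DataFrame of [intersectCandidates()] (flags are then
#'   carried into the clusters).
#' @param reference a [StrainGenome].
#' @param max_gap maximum intervening non-candidate genes (default 2).
#' @param min_genes minimum cluster size (default 3).
#' @return list of [GeneCluster] objects.
#' @export
callAdjacentClusters <- function(candidates, reference, max_gap = 2L,
                                 min_genes = 3L) {
  flags <- NULL
  if (is(candidates, "DataFrame") || is.data.frame(candidates)) {
    flags <- candidates
    candidates <- candidates$gene_id
  }
  g <- reference@genes
  bad <- setdiff(candidates, g$gene_id)
  if (length(bad))
    stop("candidate gene(s) not in reference: ", paste(bad, collapse = ", "))
  is_cand <- g$gene_id %in% candidates
  clusters <- list()
  for (ct in unique(g$contig_id)) {
    on_ct <- which(g$contig_id == ct)   # already sorted by start
    idx <- on_ct[is_cand[on_ct]]
    if (!length(idx)) next
    ords <- match(idx, on_ct)           # gene-order indices on this contig
    run_break <- c(TRUE, diff(ords) - 1L > max_gap)
    run_id <- cumsum(run_break)
    for (r in unique(run_id)) {
      members <- idx[run_id == r]
      if (length(members) < min_genes) next
      ids <- g$gene_id[members]
      fl <- if (!is.null(flags))
        DataFrame(flags[match(ids, flags$gene_id),
                        setdiff(colnames(flags), "gene_id"), drop = FALSE])
      else DataFrame(from_kmer = rep(NA, length(ids)),
                     from_family = rep(NA, length(ids)),
                     from_de = rep(NA, length(ids)))
      clusters[[length(clusters) + 1L]] <-
        new("GeneCluster", contigId = ct, geneIds = ids,
            geneNames = character(0), flags = fl,
            architectureType = NA_character_)
    }
  }
  clusters[order(-vapply(clusters, function(cl) length(cl@geneIds),
                         integer(1)))]
}

#' Assign systematic names to cluster genes
#'
#' Genes are named `prefix` + A, B, ... in genomic order; beyond Z the
#' naming continues AA, AB, ... (bijective base 26).
#'
#' @param cluster a [GeneCluster].
#' @param prefix name prefix (default `"bxd"`).
#' @return the cluster with `geneNames` filled in.
#' @export
nameClusterGenes <- function(cluster, prefix = "bxd") {
  n <- length(cluster@geneIds)
  if (n == 0) stop("cannot name an empty cluster")
  cluster@geneNames <- paste0(prefix,
                              vapply(seq_len(n), .letter_name, character(1)))
  cluster
}

#' Type cluster architectures by family-label sequence
#'
#' Clusters are equivalent when their per-gene family-label sequences are
#' identical or one is the full reversal of the other (strand-insensitive
#' orientation invariance). Types are labelled with roman numerals I,
#' II, ... by decreasing class size, ties broken by first occurrence.
#'
#' @param label_seqs named list: cluster/strain id -> character vector of
#'   family labels in genomic order (no NA labels allowed).
#' @return named character vector of type labels per cluster.
#' @export
typeClusterArchitectures <- function(label_seqs) {
  if (!length(label_seqs)) return(stats::setNames(character(0), character(0)))
  if (any(vapply(label_seqs, anyNA, logical(1))))
    stop("unlabelled gene in cluster")
  canon <- vapply(label_seqs, function(x) {
    f <- paste(x, collapse = "|")
    r <- paste(rev(x), collapse = "|")
    min(f, r)
  }, character(1))
  sizes <- table(canon)
  first <- vapply(unique(canon), function(cn) match(cn, canon), integer(1))
  ord <- unique(canon)[order(-as.vector(sizes[unique(canon)]),
                             first[unique(canon)])]
  type_of <- stats::setNames(as.character(utils::as.roman(seq_along(ord))),
                             ord)
  stats::setNames(unname(type_of[canon]), names(label_seqs))
}
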