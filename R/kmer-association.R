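#' @importFrom Matrix sparseMatrix rowSums
#' @importFrom stats fisher.test p.adjust
NULL

#' Parameters of the kmer association pipeline
#'
#' @param k kmer length (8-26; default 21).
#' @param min_score minimum phenotype score for a kmer to count as
#'   high-scoring (default 7).
#' @param cluster_identity identity threshold of the greedy gene clustering
#'   (default 0.70).
#' @param hit_min_identity minimum global identity for a gene to enter a
#'   centroid's hit list (default 0.70).
#' @param hit_min_containment minimum fraction of the centroid's canonical
#'   kmers a gene must share before alignment is attempted (default 0.1).
#' @param alpha significance level for both raw-p and BH-adjusted calls
#'   (default 0.05).
#' @param canonical canonicalize kmers (min of forward / reverse
#'   complement); default TRUE.
#' @param alternative sidedness of the Fisher tests (`two.sided` or
#'   `greater`).
#' @param significance use raw `p` (default, mirroring score-and-test
#'   practice) or BH-adjusted `p_adj` to define the significant gene list.
#' @param max_kmers refuse to build matrices whose estimated number of
#'   distinct kmers (total sequence length) exceeds this cap.
#' @return validated parameter list of class `KmerParams`.
#' @export
kmerParams <- function(k = 21L, min_score = 7L, cluster_identity = 0.70,
                       hit_min_identity = 0.70, hit_min_containment = 0.1,
                       alpha = 0.05, canonical = TRUE,
                       alternative = c("two.sided", "greater"),
                       significance = c("raw", "adjusted"),
                       max_kmers = 1e8) {
  stopifnot(k >= 8, k <= 26,
            cluster_identity > 0, cluster_identity <= 1,
            hit_min_identity > 0, hit_min_identity <= 1,
            alpha > 0, alpha < 1)
  structure(list(k = as.integer(k), min_score = as.integer(min_score),
                 cluster_identity = cluster_identity,
                 hit_min_identity = hit_min_identity,
                 hit_min_containment = hit_min_containment,
                 alpha = alpha, canonical = isTRUE(canonical),
                 alternative = match.arg(alternative),
                 significance = match.arg(significance),
                 max_kmers = max_kmers),
            class = c("KmerParams", "list"))
}

#' Canonical kmer set of a sequence
#'
#' Every length-`k` window free of non-ACGT characters contributes the
#' lexicographic minimum of itself and its reverse complement (set
#' semantics: each kmer once). Windows containing `N` are skipped.
#'
#' @param seq nucleotide string.
#' @param k kmer length.
#' @param canonical canonicalize; set FALSE for plain forward kmers.
#' @return sorted character vector of kmers (empty if `nchar(seq) < k`).
#' @examples
#' canonicalKmers("ACGTA", 4)  # "ACGT" "CGTA"
#' @export
canonicalKmers <- function(seq, k, canonical = TRUE) {
  .decode_kmers(.kmer_codes(seq, as.integer(k), isTRUE(canonical)),
                as.integer(k))
}

# Sorted distinct kmer codes of one strain (union over contigs).
.strain_codes <- function(sg, k, canonical) {
  per <- lapply(as.character(sg@contigs), .kmer_codes, k = k,
                canonical = canonical)
  sort(unique(unlist(per, use.names = FALSE)))
}

#' Build the kmer presence matrix of a genome panel
#'
#' Takes the union of all strains' canonical kmer sets over whole contigs
#' (or, with `gene_only = TRUE`, over annotated gene sequences only),
#' records presence by exact membership, and scores every kmer as
#' (number of positive strains containing it) minus (number of negative
#' strains containing it).
#'
#' @param gset a [GenomeSet].
#' @param params a [kmerParams()] list.
#' @param gene_only count kmers of annotated genes instead of whole
#'   contigs (default FALSE: whole scaffolds).
#' @return a [KmerMatrix].
#' @export
buildKmerMatrix <- function(gset, params = kmerParams(), gene_only = FALSE) {
  stopifnot(length(gset@strains) >= 1)
  est <- sum(vapply(gset@strains, function(s)
    sum(Biostrings::width(s@contigs)), numeric(1)))
  if (est > params$max_kmers)
    stop("estimated distinct kmers (", est, ") exceed max_kmers cap (",
         params$max_kmers, ")")
  sids <- strainIds(gset)
  per_strain <- lapply(gset@strains, function(sg) {
    if (gene_only) {
      sort(unique(unlist(lapply(sg@genes$nt_seq, .kmer_codes, k = params$k,
                                canonical = params$canonical),
                         use.names = FALSE)))
    } else .strain_codes(sg, params$k, params$canonical)
  })
  all_codes <- sort(unique(unlist(per_strain, use.names = FALSE)))
  ii <- lapply(per_strain, function(v) match(v, all_codes))
  pres <- sparseMatrix(i = unlist(ii, use.names = FALSE),
                       j = rep.int(seq_along(sids), lengths(ii)),
                       dims = c(length(all_codes), length(sids)))
  pres <- as(pres, "nMatrix")
  km <- new("KmerMatrix", kmerCodes = all_codes, k = params$k,
            canonical = params$canonical, presence = as(pres, "CsparseMatrix"),
            scores = integer(length(all_codes)), strainIds = sids,
            phenotype = phenotypeLabels(gset))
  km@scores <- kmerScores(km, phenotypeLabels(gset))
  km
}

#' Precompute per-gene kmer code sets
#'
#' Returns, for every strain, a named list mapping gene id to the sorted
#' canonical kmer codes of its sequence. Computing this once and passing
#' it to [mapHighKmersToGenes()], [centroidHitLists()] and
#' [runKmerAssociation()] avoids recomputation across permutation runs.
#'
#' @param gset a [GenomeSet].
#' @param params a [kmerParams()] list.
#' @return nested named list: strain id -> gene id -> numeric codes.
#' @export
geneKmerIndex <- function(gset, params = kmerParams()) {
  lapply(gset@strains, function(sg) {
    v <- lapply(sg@genes$nt_seq, .kmer_codes, k = params$k,
                canonical = params$canonical)
    names(v) <- sg@genes$gene_id
    v
  })
}

#' Map high-scoring kmers to reference-strain genes
#'
#' Returns the genes of the reference strain whose sequence contains at
#' least one kmer with phenotype score >= `params$min_score` (exact
#' canonical match, so a kmer seen only on the gene's reverse strand still
#' counts).
#'
#' @param kmat a [KmerMatrix].
#' @param gset the [GenomeSet] the matrix was built from.
#' @param reference_strain reference strain id.
#' @param params a [kmerParams()] list.
#' @param gene_codes optional [geneKmerIndex()] result.
#' @param scores optional score vector overriding the stored one (e.g.
#'   rescored under a permuted phenotype).
#' @return character vector of gene ids (possibly empty).
#' @export
mapHighKmersToGenes <- function(kmat, gset, reference_strain,
                                params = kmerParams(), gene_codes = NULL,
                                scores = NULL) {
  if (!reference_strain %in% strainIds(gset))
    stop("unknown reference strain: ", reference_strain)
  if (is.null(scores)) scores <- kmat@scores
  high <- kmat@kmerCodes[scores >= params$min_score]
  if (!length(high)) return(character(0))
  sg <- gset@strains[[reference_strain]]
  codes <- if (!is.null(gene_codes)) gene_codes[[reference_strain]] else {
    v <- lapply(sg@genes$nt_seq, .kmer_codes, k = params$k,
                canonical = params$canonical)
    names(v) <- sg@genes$gene_id
    v
  }
  hit <- vapply(codes, function(v) .count_in_sorted(v, high) > 0, logical(1))
  sg@genes$gene_id[match(names(codes)[hit], sg@genes$gene_id)]
}

#' Greedy centroid clustering of sequences at an identity threshold
#'
#' Sequences are sorted by length (descending); each sequence joins the
#' first existing centroid whose end-gap-free global alignment identity
#' (matches / alignment columns) reaches `identity_threshold`, otherwise
#' it founds a new centroid. Processing is batched centroid-first, which
#' yields the identical partition. An optional kmer-sharing prescreen
#' (`prescreen_k`) skips alignments against centroids sharing fewer than
#' `prescreen_min` of their length-`prescreen_k` words - intended for
#' large protein collections where all-vs-centroid alignment is wasteful.
#'
#' @param gene_seqs named character vector (names = ids) or data.frame
#'   with columns `id`, `seq`.
#' @param identity_threshold identity in (0, 1].
#' @param type `"dna"` (match 1 / mismatch -1, gap 2/1) or `"protein"`
#'   (BLOSUM62, gap 11/1).
#' @param prescreen_k optional word length for the sharing prescreen
#'   (NULL = align against every centroid).
#' @param prescreen_min minimum shared-word fraction (of the centroid's
#'   word set) to attempt alignment.
#' @return list of clusters, each `list(centroid = id, members = ids)`;
#'   every input id is assigned exactly once.
#' @export
greedyClusterGenes <- function(gene_seqs, identity_threshold,
                               type = c("dna", "protein"),
                               prescreen_k = NULL, prescreen_min = 0.02) {
  type <- match.arg(type)
  if (is.data.frame(gene_seqs)) {
    seqs <- gene_seqs$seq
    names(seqs) <- gene_seqs$id
  } else seqs <- gene_seqs
  if (!length(seqs)) stop("no sequences to cluster")
  ord <- order(-nchar(seqs))
  seqs <- seqs[ord]
  n <- length(seqs)
  word_sets <- NULL
  postings <- NULL
  if (!is.null(prescreen_k)) {
    word_sets <- lapply(seqs, function(s) {
      L <- nchar(s)
      if (L < prescreen_k) return(character(0))
      unique(substring(s, 1:(L - prescreen_k + 1), prescreen_k:L))
    })
    postings <- split(rep.int(seq_len(n), lengths(word_sets)),
                      unlist(word_sets, use.names = FALSE))
  }
  assigned <- logical(n)
  clusters <- list()
  for (i in seq_len(n)) {
    if (assigned[i]) next
    assigned[i] <- TRUE
    members <- names(seqs)[i]
    rest <- which(!assigned)
    if (length(rest)) {
      cand <- rest
      if (!is.null(postings)) {
        w <- word_sets[[i]]
        if (length(w)) {
          hits <- unlist(postings[intersect(w, names(postings))],
                         use.names = FALSE)
          cnt <- tabulate(hits, nbins = n)
          cand <- rest[cnt[rest] / length(w) >= prescreen_min]
        } else cand <- integer(0)
      }
      if (length(cand)) {
        ids <- .identity_to(seqs[cand], seqs[[i]], type)
        ok <- cand[ids >= identity_threshold]
        if (length(ok)) {
          assigned[ok] <- TRUE
          members <- c(members, names(seqs)[ok])
        }
      }
    }
    clusters[[length(clusters) + 1L]] <-
      list(centroid = names(seqs)[i], members = members)
  }
  clusters
}

#' Hit lists of centroid genes across all strains
#'
#' A gene of any strain is a hit of a centroid when it shares at least
#' `hit_min_containment` of the centroid's canonical kmers AND its global
#' (end-gap-free) identity to the centroid reaches `hit_min_identity`.
#' Every centroid is a member of its own list.
#'
#' @param centroid_seqs named character vector of centroid nucleotide
#'   sequences (names = centroid gene ids).
#' @param gset a [GenomeSet] supplying all genes of all strains.
#' @param params a [kmerParams()] list.
#' @param gene_codes optional [geneKmerIndex()] result.
#' @param cache optional environment memoizing hit lists by centroid id
#'   (hit lists depend only on sequences, never on the phenotype, so they
#'   can be reused across permutation runs).
#' @return named list: centroid id -> data.frame(`strain_id`, `gene_id`).
#' @export
centroidHitLists <- function(centroid_seqs, gset, params = kmerParams(),
                             gene_codes = NULL, cache = NULL) {
  if (!length(centroid_seqs)) stop("no centroids")
  if (is.null(gene_codes)) gene_codes <- geneKmerIndex(gset, params)
  sids <- strainIds(gset)
  out <- vector("list", length(centroid_seqs))
  names(out) <- names(centroid_seqs)
  for (ci in seq_along(centroid_seqs)) {
    key <- names(centroid_seqs)[ci]
    if (!is.null(cache) && !is.null(cache[[key]])) {
      out[[ci]] <- cache[[key]]
      next
    }
    ccodes <- .kmer_codes(centroid_seqs[[ci]], params$k, params$canonical)
    cand_strain <- character(0)
    cand_gene <- character(0)
    cand_seq <- character(0)
    for (sid in sids) {
      codes <- gene_codes[[sid]]
      shared <- vapply(codes, .count_in_sorted, numeric(1), table = ccodes)
      keep <- which(shared / length(ccodes) >= params$hit_min_containment)
      if (length(keep)) {
        sg <- gset@strains[[sid]]
        idx <- match(names(codes)[keep], sg@genes$gene_id)
        cand_strain <- c(cand_strain, rep(sid, length(keep)))
        cand_gene <- c(cand_gene, sg@genes$gene_id[idx])
        cand_seq <- c(cand_seq, sg@genes$nt_seq[idx])
      }
    }
    if (length(cand_seq)) {
      ids <- .identity_to(cand_seq, centroid_seqs[[ci]], "dna")
      keep <- ids >= params$hit_min_identity
      hits <- data.frame(strain_id = cand_strain[keep],
                         gene_id = cand_gene[keep])
    } else hits <- data.frame(strain_id = character(0),
                              gene_id = character(0))
    if (!is.null(cache)) cache[[key]] <- hits
    out[[ci]] <- hits
  }
  out
}

#' Fisher's exact test on a 2x2 presence/phenotype table
#'
#' Table-level core of [presenceFisher()]: `a`/`b` are positive strains
#' with/without the unit, `c`/`d` negative strains with/without it.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @param alternative `"two.sided"` or `"greater"`.
#' @return list with `p` and `odds_ratio` (conditional MLE).
#' @export
fisherPresenceTest <- function(a, b, c, d,
                               alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  ft <- fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE),
                    alternative = alternative)
  list(p = ft$p.value, odds_ratio = unname(ft$estimate))
}

#' Fisher's exact test of presence against phenotype
#'
#' Builds the 2x2 table of phenotype (positive/negative strains) against
#' presence (strain has at least one hit gene) and applies Fisher's exact
#' test.
#'
#' @param hit_list character vector of strain ids carrying the unit, or a
#'   data.frame with a `strain_id` column.
#' @param gset a [GenomeSet] (supplies the phenotype and the margins).
#' @param alternative `"two.sided"` (default) or `"greater"` (enrichment
#'   in positives).
#' @param unit_id optional label carried through to the result.
#' @return list with `unit_id`, `table` (2x2 matrix, rows
#'   positive/negative, columns present/absent), `odds_ratio`
#'   (conditional MLE), `p`, and `p_adj` (NA until BH is applied across
#'   units).
#' @export
presenceFisher <- function(hit_list, gset,
                           alternative = c("two.sided", "greater"),
                           unit_id = NA_character_) {
  alternative <- match.arg(alternative)
  ph <- phenotypeLabels(gset)
  if (length(unique(ph)) < 2)
    stop("association needs both phenotype classes")
  strains <- if (is.data.frame(hit_list)) unique(hit_list$strain_id)
             else unique(hit_list)
  if (!all(strains %in% names(ph)))
    stop("hit list references strain(s) outside the genome set")
  present <- names(ph) %in% strains
  pos <- ph == "positive"
  tab <- matrix(c(sum(pos & present), sum(pos & !present),
                  sum(!pos & present), sum(!pos & !present)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("positive", "negative"),
                                c("present", "absent")))
  ft <- fisherPresenceTest(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2],
                           alternative)
  list(unit_id = unit_id, table = tab,
       odds_ratio = ft$odds_ratio, p = ft$p, p_adj = NA_real_)
}

# Assemble per-unit presenceFisher results into a BH-corrected DataFrame.
.assoc_table <- function(results) {
  if (!length(results))
    return(DataFrame(unit_id = character(0), a = integer(0), b = integer(0),
                     c = integer(0), d = integer(0), odds_ratio = numeric(0),
                     p = numeric(0), p_adj = numeric(0)))
  df <- DataFrame(
    unit_id = vapply(results, `[[`, character(1), "unit_id"),
    a = vapply(results, function(r) r$table[1, 1], numeric(1)),
    b = vapply(results, function(r) r$table[1, 2], numeric(1)),
    c = vapply(results, function(r) r$table[2, 1], numeric(1)),
    d = vapply(results, function(r) r$table[2, 2], numeric(1)),
    odds_ratio = vapply(results, `[[`, numeric(1), "odds_ratio"),
    p = vapply(results, `[[`, numeric(1), "p"))
  df$p_adj <- p.adjust(df$p, method = "BH")
  df
}

#' Run the kmer genotype-phenotype association pipeline
#'
#' Chains matrix construction, phenotype scoring, high-kmer gene mapping
#' on the reference strain, greedy clustering of the mapped genes at the
#' cluster identity threshold, centroid hit-list construction across all
#' strains, and per-centroid Fisher tests with BH correction. The
#' significant gene list contains the reference-strain genes belonging to
#' hit lists of significant centroids (raw p < alpha by default; set
#' `significance = "adjusted"` in the params to require BH-adjusted p).
#'
#' @param gset a [GenomeSet] with both phenotype classes.
#' @param reference_strain reference strain id.
#' @param params a [kmerParams()] list.
#' @param kmer_matrix optional prebuilt [KmerMatrix] (rescored under the
#'   genome set's phenotype if it differs).
#' @param gene_codes optional [geneKmerIndex()] result.
#' @param hit_cache optional environment forwarded to
#'   [centroidHitLists()] for memoization across permutation runs.
#' @return list with `assoc` (per-centroid association DataFrame),
#'   `significant_genes` (reference gene ids), `high_genes` (reference
#'   genes containing high-scoring kmers), `centroids` (greedy clusters),
#'   `hit_lists`, and the `kmer_matrix` used.
#' @export
runKmerAssociation <- function(gset, reference_strain, params = kmerParams(),
                               kmer_matrix = NULL, gene_codes = NULL,
                               hit_cache = NULL) {
  km <- if (is.null(kmer_matrix)) buildKmerMatrix(gset, params) else kmer_matrix
  ph <- phenotypeLabels(gset)
  scores <- if (identical(km@phenotype[km@strainIds], ph[km@strainIds]))
    km@scores else kmerScores(km, ph)
  high <- mapHighKmersToGenes(km, gset, reference_strain, params,
                              gene_codes = gene_codes, scores = scores)
  empty <- list(assoc = .assoc_table(list()),
                significant_genes = character(0), high_genes = high,
                centroids = list(), hit_lists = list(), kmer_matrix = km)
  if (!length(high)) return(empty)
  g <- gset@strains[[reference_strain]]@genes
  seqs <- g$nt_seq[match(high, g$gene_id)]
  names(seqs) <- high
  cents <- greedyClusterGenes(seqs, params$cluster_identity, type = "dna")
  cent_ids <- vapply(cents, `[[`, character(1), "centroid")
  cent_seqs <- seqs[cent_ids]
  hits <- centroidHitLists(cent_seqs, gset, params, gene_codes = gene_codes,
                           cache = hit_cache)
  res <- lapply(cent_ids, function(cid)
    presenceFisher(hits[[cid]], gset, alternative = params$alternative,
                   unit_id = cid))
  assoc <- .assoc_table(res)
  sig <- if (params$significance == "raw") assoc$p < params$alpha
         else assoc$p_adj < params$alpha
  sig_genes <- unique(unlist(lapply(which(sig), function(i) {
    h <- hits[[assoc$unit_id[i]]]
    h$gene_id[h$strain_id == reference_strain]
  }), use.names = FALSE))
  list(assoc = assoc, significant_genes = sort(sig_genes %||% character(0)),
       high_genes = high, centroids = cents, hit_lists = hits,
       kmer_matrix = km)
}
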