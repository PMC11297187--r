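#' Run the full cluster-discovery pipeline
#'
#' Orchestrates the three evidence channels and the integration steps:
#' (1) kmer genotype-phenotype association on the reference strain;
#' (2) gene-family presence/absence association (families supplied, or
#' built de novo from protein sequences); (3) an optional differential
#' expression stage from a count matrix or a precomputed DE table. The
#' candidate sets are intersected (seven-region Venn report), candidate
#' genes are merged (`union` by default, `intersection` to require every
#' available channel), clusters are called by genomic adjacency, named
#' systematically, and typed across carrier strains by family-label
#' architecture.
#'
#' A failing stage is recorded in the report's `status` and the remaining
#' stages run on what is available (partial report).
#'
#' @param gset a [GenomeSet] with both phenotype classes.
#' @param reference_strain reference strain id.
#' @param counts optional count matrix / SummarizedExperiment over the
#'   reference strain's genes.
#' @param de_table optional precomputed DE table ([readDETable()] shape);
#'   ignored when `counts` is given.
#' @param families optional [GeneFamilySet]; built with
#'   [buildFamiliesDenovo()] when NULL.
#' @param kmer_params a [kmerParams()] list.
#' @param family_params a [familyCallParams()] list.
#' @param protein_identity identity threshold for de-novo families.
#' @param max_gap,min_genes adjacency-calling parameters (defaults 2, 3).
#' @param candidate_mode `"union"` (default) or `"intersection"` of the
#'   available candidate sets.
#' @param name_prefix systematic gene-name prefix (default `"bxd"`).
#' @param alpha significance level for the DE stage.
#' @param kmer_matrix,gene_codes optional precomputed [buildKmerMatrix()]
#'   and [geneKmerIndex()] results (reused across permutation runs).
#' @param hit_cache optional environment forwarded to
#'   [centroidHitLists()].
#' @return a [ClusterReport].
#' @export
runFullPipeline <- function(gset, reference_strain, counts = NULL,
                            de_table = NULL, families = NULL,
                            kmer_params = kmerParams(),
                            family_params = familyCallParams(),
                            protein_identity = 0.5,
                            max_gap = 2L, min_genes = 3L,
                            candidate_mode = c("union", "intersection"),
                            name_prefix = "bxd", alpha = 0.05,
                            kmer_matrix = NULL, gene_codes = NULL,
                            hit_cache = NULL) {
  candidate_mode <- match.arg(candidate_mode)
  status <- c(kmer = "ok", family = "ok", de = "ok", integration = "ok")
  ref <- gset@strains[[reference_strain]]
  if (is.null(ref)) stop("unknown reference strain: ", reference_strain)

  kmer_res <- tryCatch(
    runKmerAssociation(gset, reference_strain, kmer_params,
                       kmer_matrix = kmer_matrix, gene_codes = gene_codes,
                       hit_cache = hit_cache),
    error = function(e) { status["kmer"] <<- paste("failed:", conditionMessage(e)); NULL })
  kmer_set <- if (is.null(kmer_res)) character(0) else kmer_res$significant_genes

  fam_res <- tryCatch({
    if (is.null(families))
      families <- buildFamiliesDenovo(gset, protein_identity)
    uniqueSpecificFamilies(families, gset, family_params)
  }, error = function(e) { status["family"] <<- paste("failed:", conditionMessage(e)); NULL })
  family_set <- character(0)
  if (!is.null(fam_res) && length(fam_res$called)) {
    family_set <- unique(unlist(lapply(fam_res$called, function(fid)
      families@families[[fid]][[reference_strain]]), use.names = FALSE))
    family_set <- family_set %||% character(0)
  }

  de_res <- NULL
  if (!is.null(counts)) {
    de_res <- tryCatch(deTest(counts, alpha = alpha),
      error = function(e) { status["de"] <<- paste("failed:", conditionMessage(e)); NULL })
  } else if (!is.null(de_table)) {
    de_res <- tryCatch(
      if (is.character(de_table)) readDETable(de_table, alpha) else de_table,
      error = function(e) { status["de"] <<- paste("failed:", conditionMessage(e)); NULL })
  } else status["de"] <- "skipped"
  de_set <- if (is.null(de_res)) NULL else de_res$gene_id[de_res$is_de]

  inter <- intersectCandidates(kmer_set, family_set, de_set)
  cand <- inter$candidates
  g <- ref@genes
  cand$contig_id <- g$contig_id[match(cand$gene_id, g$gene_id)]
  cand$gene_index <- match(cand$gene_id, g$gene_id)
  if (candidate_mode == "intersection") {
    keep <- cand$from_kmer & cand$from_family
    if (!is.null(de_set)) keep <- keep & cand$from_de
    cand <- cand[keep, , drop = FALSE]
  }

  clusters <- tryCatch(
    callAdjacentClusters(cand, ref, max_gap = max_gap, min_genes = min_genes),
    error = function(e) { status["integration"] <<- paste("failed:", conditionMessage(e)); list() })
  clusters <- lapply(clusters, nameClusterGenes, prefix = name_prefix)

  arch <- character(0)
  if (length(clusters) && !is.null(families)) {
    arch <- tryCatch(
      .type_across_strains(clusters[[1]], families, gset, reference_strain,
                           max_gap, min_genes),
      error = function(e) character(0))
    if (length(arch) && reference_strain %in% names(arch))
      clusters[[1]]@architectureType <- arch[[reference_strain]]
  }

  new("ClusterReport", candidates = cand, venn = inter$venn,
      clusters = clusters,
      kmerAssoc = if (is.null(kmer_res)) .assoc_table(list()) else kmer_res$assoc,
      familyAssoc = if (is.null(fam_res)) .assoc_table(list()) else fam_res$assoc,
      deTable = if (is.null(de_res)) NULL else DataFrame(de_res),
      architectures = arch, referenceStrain = reference_strain,
      params = list(kmer = unclass(kmer_params),
                    family = unclass(family_params),
                    max_gap = max_gap, min_genes = min_genes,
                    candidate_mode = candidate_mode, alpha = alpha),
      status = status)
}

# Locate the cluster's family-label region in every strain and type the
# architectures: reversal-invariant equivalence on family-label sequences.
.type_across_strains <- function(cluster, families, gset, reference_strain,
                                 max_gap, min_genes) {
  fam_of <- character(0)
  for (fid in names(families@families))
    for (sid in names(families@families[[fid]])) {
      genes <- families@families[[fid]][[sid]]
      fam_of[paste0(sid, "::", genes)] <- fid
    }
  clu_fams <- unique(fam_of[paste0(reference_strain, "::", cluster@geneIds)])
  clu_fams <- clu_fams[!is.na(clu_fams)]
  if (!length(clu_fams)) return(character(0))
  label_seqs <- list()
  for (sid in strainIds(gset)) {
    g <- gset@strains[[sid]]@genes
    fl <- unname(fam_of[paste0(sid, "::", g$gene_id)])
    idx <- which(fl %in% clu_fams)
    if (length(idx) < min_genes) next
    run_id <- cumsum(c(TRUE, diff(idx) - 1L > max_gap))
    largest <- as.integer(names(which.max(table(run_id))))
    members <- idx[run_id == largest]
    if (length(members) < min_genes) next
    label_seqs[[sid]] <- fl[members]
  }
  if (!length(label_seqs)) return(character(0))
  typeClusterArchitectures(label_seqs)
}

#' Null calibration of cluster calling under permuted phenotypes
#'
#' For each seed, randomly permutes the phenotype labels, reruns the
#' label-dependent pipeline stages (kmer rescoring and association,
#' family association, candidate integration, adjacency calling) on
#' precomputed structures, and records whether any cluster was called.
#'
#' @param gset a [GenomeSet].
#' @param reference_strain reference strain id.
#' @param seeds integer vector of permutation seeds (default 0:99).
#' @param kmer_params,family_params,max_gap,min_genes as in
#'   [runFullPipeline()].
#' @param kmer_matrix,gene_codes,families precomputed structures (built
#'   once here when NULL).
#' @return logical vector per seed: TRUE if at least one cluster was
#'   called under that permutation.
#' @export
nullClusterCalibration <- function(gset, reference_strain, seeds = 0:99,
                                   kmer_params = kmerParams(),
                                   family_params = familyCallParams(),
                                   max_gap = 2L, min_genes = 3L,
                                   kmer_matrix = NULL, gene_codes = NULL,
                                   families = NULL) {
  if (is.null(kmer_matrix)) kmer_matrix <- buildKmerMatrix(gset, kmer_params)
  if (is.null(gene_codes)) gene_codes <- geneKmerIndex(gset, kmer_params)
  if (is.null(families)) families <- buildFamiliesDenovo(gset)
  ph <- phenotypeLabels(gset)
  hit_cache <- new.env(parent = emptyenv())
  vapply(seeds, function(s) {
    set.seed(s)
    perm <- stats::setNames(sample(unname(ph)), names(ph))
    gperm <- new("GenomeSet", strains = gset@strains, phenotype = perm)
    out <- runFullPipeline(gperm, reference_strain,
                           families = families, kmer_params = kmer_params,
                           family_params = family_params,
                           max_gap = max_gap, min_genes = min_genes,
                           kmer_matrix = kmer_matrix,
                           gene_codes = gene_codes, hit_cache = hit_cache)
    length(out@clusters) > 0
  }, logical(1))
}

#' Export a pipeline report as JSON + TSV tables
#'
#' Writes `report.json` (candidates, Venn regions, clusters with names
#' and architecture types, stage status) and TSVs of the association and
#' DE tables under `dir`.
#'
#' @param report a [ClusterReport].
#' @param dir output directory (created if needed).
#' @return invisibly, the JSON path.
#' @export
exportReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (!is.null(df))
      write.table(as.data.frame(df), file.path(dir, name), sep = "\t",
                  quote = FALSE, row.names = FALSE)
  }
  wr(report@kmerAssoc, "kmer_association.tsv")
  wr(report@familyAssoc, "family_association.tsv")
  wr(report@deTable, "differential_expression.tsv")
  wr(report@candidates, "candidates.tsv")
  js <- list(
    reference_strain = report@referenceStrain,
    venn = as.list(report@venn),
    n_candidates = nrow(report@candidates),
    clusters = lapply(report@clusters, function(cl) list(
      contig = cl@contigId, gene_ids = cl@geneIds,
      gene_names = cl@geneNames, architecture_type = cl@architectureType)),
    architectures = as.list(report@architectures),
    status = as.list(report@status))
  path <- file.path(dir, "report.json")
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
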