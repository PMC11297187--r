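#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DFrame
#' @importClassesFrom Matrix ngCMatrix
#' @importClassesFrom Biostrings DNAStringSet
NULL

setClassUnion("DataFrameOrNull", c("DFrame", "NULL"))

#' StrainGenome: one annotated bacterial genome
#'
#' Holds the contig sequences of a single strain together with its ordered
#' gene table. Gene coordinates are 0-based half-open on the forward strand
#' of the contig; `ntSeq` is strand-corrected (reverse-complemented for
#' minus-strand genes) and `aaSeq` its translation.
#'
#' @slot strainId single strain identifier.
#' @slot contigs a [Biostrings::DNAStringSet] of contig sequences.
#' @slot genes a [S4Vectors::DataFrame] with columns `gene_id`, `contig_id`,
#'   `start`, `end` (0-based half-open), `strand` (`+`/`-`), `nt_seq`,
#'   `aa_seq`, sorted by `(contig_id, start)`.
#'
#' @export
setClass("StrainGenome",
  representation(strainId = "character",
                 contigs = "DNAStringSet",
                 genes = "DFrame"))

setValidity("StrainGenome", function(object) {
  g <- object@genes
  need <- c("gene_id", "contig_id", "start", "end", "strand", "nt_seq", "aa_seq")
  if (!all(need %in% colnames(g)))
    return(paste("gene table must have columns:", paste(need, collapse = ", ")))
  if (length(object@strainId) != 1L) return("strainId must be a single string")
  if (anyDuplicated(g$gene_id)) return("duplicate gene_id within strain")
  if (nrow(g) > 0) {
    if (any(g$end <= g$start)) return("gene end must exceed start")
    if (!all(g$strand %in% c("+", "-"))) return("strand must be + or -")
    if (!all(g$contig_id %in% names(object@contigs)))
      return("gene references unknown contig")
    clen <- Biostrings::width(object@contigs)[match(g$contig_id, names(object@contigs))]
    if (any(g$start < 0) || any(g$end > clen))
      return("gene coordinates outside contig bounds")
    if (any(nchar(g$nt_seq) != g$end - g$start))
      return("nt_seq length must equal end - start")
    o <- order(g$contig_id, g$start)
    if (!identical(o, seq_len(nrow(g))))
      return("genes must be sorted by (contig_id, start)")
  }
  TRUE
})

#' GenomeSet: a phenotyped panel of strain genomes
#'
#' The central container of the package: a list of [StrainGenome] objects
#' plus a binary phenotype label (`"positive"` = degrader/AMPO-former,
#' `"negative"` otherwise) per strain.
#'
#' @slot strains named list of [StrainGenome] objects.
#' @slot phenotype named character vector, values `positive`/`negative`,
#'   names matching the strain ids.
#'
#' @export
setClass("GenomeSet",
  representation(strains = "list", phenotype = "character"))

setValidity("GenomeSet", function(object) {
  ids <- vapply(object@strains, function(s) s@strainId, character(1))
  if (anyDuplicated(ids)) return("strain ids must be unique")
  if (!identical(names(object@strains), unname(ids)))
    return("strains list must be named by strain id")
  if (!setequal(names(object@phenotype), ids))
    return("phenotype must label exactly the strains in the set")
  if (!all(object@phenotype %in% c("positive", "negative")))
    return("phenotype values must be 'positive' or 'negative'")
  TRUE
})

#' KmerMatrix: canonical kmer presence across a genome panel
#'
#' Sparse boolean presence of every distinct canonical kmer (lexicographic
#' minimum of a k-window and its reverse complement; windows containing N
#' are skipped) across the strains of a [GenomeSet], with the per-kmer
#' phenotype score: (number of positive strains containing the kmer) minus
#' (number of negative strains containing it).
#'
#' Kmers are stored as 2-bit-packed numeric codes; use [kmerStrings()] to
#' decode (sub)sets back to character kmers.
#'
#' @slot kmerCodes sorted numeric codes of the distinct kmers.
#' @slot k kmer length.
#' @slot canonical whether kmers were canonicalized.
#' @slot presence a sparse pattern matrix (kmers x strains).
#' @slot scores integer phenotype score per kmer.
#' @slot strainIds column order of `presence`.
#' @slot phenotype the phenotype vector the scores were computed under.
#'
#' @export
setClass("KmerMatrix",
  representation(kmerCodes = "numeric", k = "integer", canonical = "logical",
                 presence = "ngCMatrix", scores = "integer",
                 strainIds = "character", phenotype = "character"))

setValidity("KmerMatrix", function(object) {
  if (nrow(object@presence) != length(object@kmerCodes))
    return("presence rows must match kmers")
  if (ncol(object@presence) != length(object@strainIds))
    return("presence columns must match strains")
  if (length(object@scores) != length(object@kmerCodes))
    return("one score per kmer")
  if (is.unsorted(object@kmerCodes, strictly = TRUE))
    return("kmer codes must be strictly sorted")
  TRUE
})

#' GeneFamilySet: gene families / orthogroups across a panel
#'
#' @slot families named list; each element is a named list mapping
#'   strain id to the character vector of member gene ids in that strain
#'   (copy number = vector length).
#' @slot strainIds strains the families are defined over.
#'
#' @export
setClass("GeneFamilySet",
  representation(families = "list", strainIds = "character"))

setValidity("GeneFamilySet", function(object) {
  if (is.null(names(object@families)) && length(object@families) > 0)
    return("families must be named")
  if (anyDuplicated(names(object@families))) return("duplicate family ids")
  ok <- vapply(object@families, function(f)
    all(names(f) %in% object@strainIds), logical(1))
  if (!all(ok)) return("family member strain not in strainIds")
  TRUE
})

#' GroundTruth: what the synthetic generator planted
#'
#' @slot plantedGeneIds named list: carrier strain id -> gene ids of the
#'   planted cluster, in genomic order.
#' @slot clusterPosition [S4Vectors::DataFrame] with one row per carrier:
#'   `strain_id`, `contig_id`, `first_index`, `last_index` (1-based indices
#'   into the strain's gene order).
#' @slot deGeneIds gene ids simulated as differentially expressed in the
#'   reference strain's count matrix.
#' @slot phenotype the generated phenotype labels.
#' @slot clusterFamilies ancestral family labels of the planted genes, in
#'   cluster order.
#'
#' @export
setClass("GroundTruth",
  representation(plantedGeneIds = "list", clusterPosition = "DFrame",
                 deGeneIds = "character", phenotype = "character",
                 clusterFamilies = "character"))

#' GeneCluster: an adjacency-called candidate gene cluster
#'
#' @slot contigId contig of the reference strain the cluster lies on.
#' @slot geneIds member gene ids in genomic order.
#' @slot geneNames systematic names (`prefix` + A, B, ...), empty until
#'   [nameClusterGenes()] is applied.
#' @slot flags [S4Vectors::DataFrame] of evidence flags (`from_kmer`,
#'   `from_family`, `from_de`) per member gene.
#' @slot architectureType optional architecture label (e.g. `"I"`).
#'
#' @export
setClass("GeneCluster",
  representation(contigId = "character", geneIds = "character",
                 geneNames = "character", flags = "DFrame",
                 architectureType = "character"),
  prototype(geneNames = character(0), architectureType = NA_character_))

#' ClusterReport: the integrated output of the discovery pipeline
#'
#' @slot candidates [S4Vectors::DataFrame] of candidate genes with evidence
#'   flags and reference gene-order indices.
#' @slot venn named numeric vector of the seven Venn region sizes over the
#'   kmer / family / differential-expression candidate sets.
#' @slot clusters list of [GeneCluster] objects, largest first.
#' @slot kmerAssoc per-centroid association table.
#' @slot familyAssoc per-family association table.
#' @slot deTable differential expression table, or NULL if the stage was
#'   not run.
#' @slot architectures named character: per-strain cluster architecture
#'   type labels.
#' @slot referenceStrain reference strain id.
#' @slot params the parameter list the pipeline ran with.
#' @slot status named character of per-stage completion status.
#'
#' @export
setClass("ClusterReport",
  representation(candidates = "DFrame", venn = "numeric", clusters = "list",
                 kmerAssoc = "DFrame", familyAssoc = "DFrame",
                 deTable = "DataFrameOrNull", architectures = "character",
                 referenceStrain = "character", params = "list",
                 status = "character"))

## ---- show methods ----

setMethod("show", "StrainGenome", function(object) {
  cat("StrainGenome", object@strainId, "|",
      length(object@contigs), "contig(s),",
      nrow(object@genes), "genes,",
      sum(Biostrings::width(object@contigs)), "bp\n")
})

setMethod("show", "GenomeSet", function(object) {
  ph <- table(factor(object@phenotype, c("positive", "negative")))
  cat("GenomeSet:", length(object@strains), "strains (",
      ph[["positive"]], "positive /", ph[["negative"]], "negative ),",
      sum(vapply(object@strains, function(s) nrow(s@genes), integer(1))),
      "genes total\n")
})

setMethod("show", "KmerMatrix", function(object) {
  cat("KmerMatrix: ", length(object@kmerCodes), " distinct ",
      if (object@canonical) "canonical " else "", object@k, "-mers x ",
      length(object@strainIds), " strains; score range [",
      min(object@scores), ", ", max(object@scores), "]\n", sep = "")
})

setMethod("show", "GeneFamilySet", function(object) {
  cat("GeneFamilySet:", length(object@families), "families over",
      length(object@strainIds), "strains\n")
})

setMethod("show", "GeneCluster", function(object) {
  nm <- if (length(object@geneNames)) paste0(" (", object@geneNames[1], "..",
        object@geneNames[length(object@geneNames)], ")") else ""
  cat("GeneCluster on ", object@contigId, ": ", length(object@geneIds),
      " genes", nm, if (!is.na(object@architectureType))
        paste0(", type ", object@architectureType) else "", "\n", sep = "")
})

setMethod("show", "ClusterReport", function(object) {
  cat("ClusterReport | reference:", object@referenceStrain, "\n")
  cat("  candidates:", nrow(object@candidates),
      "| clusters called:", length(object@clusters), "\n")
  for (cl in object@clusters) { cat("  "); show(cl) }
  cat("  stages:", paste(names(object@status), object@status,
                         sep = "=", collapse = ", "), "\n")
})
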