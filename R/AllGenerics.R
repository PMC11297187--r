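#' @rdname accessors
#' @export
setGeneric("strainIds", function(x) standardGeneric("strainIds"))

#' @rdname accessors
#' @export
setGeneric("phenotypeLabels", function(x) standardGeneric("phenotypeLabels"))

#' @rdname accessors
#' @export
setGeneric("geneTable", function(x, strain) standardGeneric("geneTable"))

#' @rdname accessors
#' @export
setGeneric("contigSeqs", function(x, strain) standardGeneric("contigSeqs"))

#' @rdname kmer-accessors
#' @export
setGeneric("kmerStrings", function(x, which = NULL) standardGeneric("kmerStrings"))

#' @rdname kmer-accessors
#' @export
setGeneric("kmerScores", function(x, phenotype = NULL) standardGeneric("kmerScores"))

#' @rdname family-accessors
#' @export
setGeneric("familyMembers", function(x, family) standardGeneric("familyMembers"))

#' @rdname family-accessors
#' @export
setGeneric("copyNumberMatrix", function(x) standardGeneric("copyNumberMatrix"))

#' Accessors for genome-set objects
#'
#' `strainIds()` returns strain identifiers; `phenotypeLabels()` the named
#' phenotype vector; `geneTable()` the gene [S4Vectors::DataFrame] of one
#' strain; `contigSeqs()` its contig [Biostrings::DNAStringSet].
#'
#' @param x a [GenomeSet], [StrainGenome], [KmerMatrix] or [GeneFamilySet].
#' @param strain strain id (for [GenomeSet] methods).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("strainIds", "GenomeSet", function(x) names(x@strains))

#' @rdname accessors
#' @export
setMethod("strainIds", "KmerMatrix", function(x) x@strainIds)

#' @rdname accessors
#' @export
setMethod("strainIds", "GeneFamilySet", function(x) x@strainIds)

#' @rdname accessors
#' @export
setMethod("phenotypeLabels", "GenomeSet", function(x) x@phenotype)

#' @rdname accessors
#' @export
setMethod("geneTable", "StrainGenome", function(x, strain) x@genes)

#' @rdname accessors
#' @export
setMethod("geneTable", "GenomeSet", function(x, strain) x@strains[[strain]]@genes)

#' @rdname accessors
#' @export
setMethod("contigSeqs", "StrainGenome", function(x, strain) x@contigs)

#' @rdname accessors
#' @export
setMethod("contigSeqs", "GenomeSet", function(x, strain) x@strains[[strain]]@contigs)

#' Kmer matrix accessors
#'
#' `kmerStrings()` decodes kmer codes back to character kmers;
#' `kmerScores()` returns the stored per-kmer phenotype scores, or, given a
#' phenotype vector, recomputes them from the presence matrix (used for
#' permutation testing without rebuilding the matrix).
#'
#' @param x a [KmerMatrix].
#' @param which optional integer/logical index of kmers to decode.
#' @param phenotype optional named phenotype vector (values
#'   `positive`/`negative`) to rescore under.
#' @name kmer-accessors
NULL

#' @rdname kmer-accessors
#' @export
setMethod("kmerStrings", "KmerMatrix", function(x, which = NULL) {
  codes <- if (is.null(which)) x@kmerCodes else x@kmerCodes[which]
  .decode_kmers(codes, x@k)
})

#' @rdname kmer-accessors
#' @export
setMethod("kmerScores", "KmerMatrix", function(x, phenotype = NULL) {
  if (is.null(phenotype)) return(x@scores)
  stopifnot(all(x@strainIds %in% names(phenotype)))
  sgn <- ifelse(phenotype[x@strainIds] == "positive", 1L, -1L)
  as.integer(as.vector(x@presence %*% sgn))
})

#' Gene-family accessors
#'
#' `familyMembers()` returns the strain -> gene-id member map of one family;
#' `copyNumberMatrix()` the integer family x strain copy-number matrix.
#'
#' @param x a [GeneFamilySet].
#' @param family family id.
#' @name family-accessors
NULL

#' @rdname family-accessors
#' @export
setMethod("familyMembers", "GeneFamilySet", function(x, family) x@families[[family]])

#' @rdname family-accessors
#' @export
setMethod("copyNumberMatrix", "GeneFamilySet", function(x) {
  m <- matrix(0L, nrow = length(x@families), ncol = length(x@strainIds),
              dimnames = list(names(x@families), x@strainIds))
  for (f in names(x@families)) {
    mem <- x@families[[f]]
    if (length(mem))
      m[f, names(mem)] <- vapply(mem, length, integer(1))
  }
  m
})
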