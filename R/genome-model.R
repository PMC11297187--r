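#' @importFrom Biostrings DNAStringSet DNAString AAString reverseComplement
#'   subseq width writeXStringSet readDNAStringSet getGeneticCode
#' @importFrom S4Vectors DataFrame
#' @importFrom utils read.delim write.table
NULL

GENETIC_CODE_11 <- Biostrings::getGeneticCode("11")

#' Construct a StrainGenome
#'
#' Builds a validated [StrainGenome] from contig sequences and a minimal
#' gene table. `nt_seq` (strand-corrected) and `aa_seq` are derived from
#' the contigs; coordinates are 0-based half-open.
#'
#' @param strainId strain identifier.
#' @param contigs named character vector or [Biostrings::DNAStringSet].
#' @param genes data.frame with columns `gene_id`, `contig_id`, `start`,
#'   `end`, `strand`.
#' @return a [StrainGenome].
#' @export
StrainGenome <- function(strainId, contigs, genes) {
  if (!is(contigs, "DNAStringSet")) contigs <- DNAStringSet(contigs)
  if (is.null(names(contigs))) stop("contigs must be named")
  genes <- as.data.frame(genes)
  bad <- setdiff(genes$contig_id, names(contigs))
  if (length(bad))
    stop("gene references unknown contig: ", paste(bad, collapse = ", "))
  clen <- width(contigs)[match(genes$contig_id, names(contigs))]
  if (nrow(genes) && (any(genes$start < 0) || any(genes$end > clen)))
    stop("gene coordinates outside contig bounds")
  genes <- genes[order(genes$contig_id, genes$start), , drop = FALSE]
  nt <- character(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    s <- subseq(contigs[[genes$contig_id[i]]],
                start = genes$start[i] + 1L, end = genes$end[i])
    if (genes$strand[i] == "-") s <- reverseComplement(s)
    nt[i] <- as.character(s)
  }
  aa <- vapply(nt, function(x) {
    if (nchar(x) %% 3L == 0L && !grepl("[^ACGT]", x))
      translateCDS(x, strip_stop = TRUE) else NA_character_
  }, character(1), USE.NAMES = FALSE)
  new("StrainGenome", strainId = strainId, contigs = contigs,
      genes = DataFrame(gene_id = genes$gene_id, contig_id = genes$contig_id,
                        start = as.integer(genes$start),
                        end = as.integer(genes$end),
                        strand = genes$strand, nt_seq = nt, aa_seq = aa))
}

#' Construct a GenomeSet
#'
#' @param strains list of [StrainGenome] objects.
#' @param phenotype named character vector (`positive`/`negative`), one
#'   entry per strain.
#' @return a [GenomeSet].
#' @export
GenomeSet <- function(strains, phenotype) {
  ids <- vapply(strains, function(s) s@strainId, character(1))
  names(strains) <- ids
  missing <- setdiff(ids, names(phenotype))
  if (length(missing))
    stop("phenotype missing for strain(s): ", paste(missing, collapse = ", "))
  new("GenomeSet", strains = strains, phenotype = phenotype[ids])
}

#' Translate a coding sequence (bacterial code, table 11)
#'
#' Translates an in-frame CDS under NCBI translation table 11. A single
#' trailing stop codon is removed when `strip_stop = TRUE`. Internal stops
#' are kept as `*` in the returned protein and reported through the
#' `internal_stop` attribute rather than silently dropped.
#'
#' @param nt_seq nucleotide string over ACGT; length must be a multiple
#'   of 3.
#' @param strip_stop drop a single trailing stop codon (default TRUE).
#' @return amino-acid string with logical attribute `internal_stop`.
#' @examples
#' translateCDS("ATGAAATAA")  # "MK"
#' @export
translateCDS <- function(nt_seq, strip_stop = TRUE) {
  if (nchar(nt_seq) %% 3L != 0L)
    stop("CDS length must be a multiple of 3")
  if (grepl("[^ACGTacgt]", nt_seq))
    stop("CDS must contain only A/C/G/T")
  aa <- as.character(Biostrings::translate(DNAString(nt_seq),
                                           genetic.code = GENETIC_CODE_11))
  if (strip_stop && nchar(aa) > 0 && substring(aa, nchar(aa)) == "*")
    aa <- substring(aa, 1L, nchar(aa) - 1L)
  attr(aa, "internal_stop") <- grepl("\\*", aa)
  aa
}

#' @describeIn reverseComplement-character Reverse-complement a nucleotide
#'   string (A/C/G/T/N), returned as a character string.
#' @export
setMethod("reverseComplement", "character", function(x, ...) {
  if (grepl("[^ACGTNacgtn]", x)) stop("invalid character in sequence")
  as.character(reverseComplement(DNAString(x)))
})

#' Reverse complement for plain character sequences
#'
#' Extends [Biostrings::reverseComplement()] to bare character strings so
#' kmer utilities can be used without wrapping sequences in `DNAString`.
#' The operation is an involution: applying it twice returns the input.
#'
#' @param x a nucleotide string over A/C/G/T/N.
#' @param ... unused.
#' @name reverseComplement-character
NULL

## ---- readers / writers ----

.read_phenotype_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("strain_id", "phenotype") %in% colnames(tab)))
    stop("phenotype table needs columns strain_id, phenotype")
  ph <- tab$phenotype
  names(ph) <- tab$strain_id
  ph
}

#' Read a genome set from FASTA + GFF3 + phenotype TSV
#'
#' One FASTA and one GFF3 per strain. GFF3 coordinates (1-based inclusive)
#' are converted to the internal 0-based half-open convention; minus-strand
#' gene sequences are reverse-complemented. Genes are taken from features
#' of `feature_type` (default `CDS`); the `ID` attribute (falling back to
#' `Name` / `locus_tag`) provides gene ids.
#'
#' @param fasta_paths named character vector of FASTA paths (names =
#'   strain ids).
#' @param gff_paths named character vector of GFF3 paths, same names.
#' @param phenotype_table path to a TSV with header
#'   `strain_id<TAB>phenotype`, phenotype in `positive`/`negative`.
#' @param feature_type GFF3 feature type to use as genes (`"CDS"` or
#'   `"gene"`).
#' @return a [GenomeSet].
#' @export
readGenomeSet <- function(fasta_paths, gff_paths, phenotype_table,
                          feature_type = "CDS") {
  stopifnot(!is.null(names(fasta_paths)), !is.null(names(gff_paths)))
  if (!setequal(names(fasta_paths), names(gff_paths)))
    stop("fasta and gff strain names must match")
  ph <- .read_phenotype_tsv(phenotype_table)
  missing <- setdiff(names(fasta_paths), names(ph))
  if (length(missing))
    stop("phenotype missing for strain(s): ", paste(missing, collapse = ", "))
  strains <- lapply(names(fasta_paths), function(sid) {
    contigs <- readDNAStringSet(fasta_paths[[sid]])
    names(contigs) <- sub("\\s.*$", "", names(contigs))
    gr <- rtracklayer::import(gff_paths[[sid]], format = "gff3")
    gr <- gr[as.character(gr$type) == feature_type]
    ids <- as.character(gr$ID)
    if (all(is.na(ids)) && !is.null(gr$Name)) ids <- as.character(gr$Name)
    if (anyNA(ids)) stop("GFF3 features of '", sid, "' lack ID attributes")
    bad <- setdiff(unique(as.character(GenomicRanges::seqnames(gr))),
                   names(contigs))
    if (length(bad))
      stop("GFF3 of '", sid, "' references unknown contig: ",
           paste(bad, collapse = ", "))
    StrainGenome(sid, contigs, data.frame(
      gene_id = ids,
      contig_id = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,   # 1-based incl -> 0-based half-open
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr))))
  })
  GenomeSet(strains, ph)
}

#' Write a genome set as per-strain FASTA + GFF3 + phenotype TSV
#'
#' Emits the same dialects [readGenomeSet()] consumes: `<strain>.fna`,
#' `<strain>.gff3` (type CDS, `ID` attribute) and `phenotype.tsv` under
#' `dir`. Writing then reading reproduces sequences, coordinates and
#' phenotypes exactly.
#'
#' @param gset a [GenomeSet].
#' @param dir output directory (created if needed).
#' @return invisibly, a list of the written paths (`fasta`, `gff`,
#'   `phenotype`).
#' @export
writeGenomeSet <- function(gset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- gff <- character(0)
  for (sid in strainIds(gset)) {
    sg <- gset@strains[[sid]]
    fa <- file.path(dir, paste0(sid, ".fna"))
    writeXStringSet(sg@contigs, fa)
    g <- sg@genes
    gr <- GenomicRanges::GRanges(
      seqnames = g$contig_id,
      ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
      strand = g$strand)
    gr$type <- "CDS"
    gr$source <- "bxdseeker"
    gr$phase <- 0L
    gr$ID <- g$gene_id
    gf <- file.path(dir, paste0(sid, ".gff3"))
    rtracklayer::export(gr, gf, format = "gff3")
    fasta[sid] <- fa
    gff[sid] <- gf
  }
  pt <- file.path(dir, "phenotype.tsv")
  write.table(data.frame(strain_id = strainIds(gset),
                         phenotype = unname(phenotypeLabels(gset))),
              pt, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(fasta = fasta, gff = gff, phenotype = pt))
}

#' Reverse-complement every contig of every strain
#'
#' Rewrites each contig as its reverse complement and remaps gene
#' coordinates and strands accordingly, so every gene's strand-corrected
#' sequence is preserved. Useful for checking strand invariance of
#' downstream analyses.
#'
#' @param gset a [GenomeSet].
#' @return a [GenomeSet] over the reverse-complemented contigs.
#' @export
reverseComplementGenomeSet <- function(gset) {
  strains <- lapply(gset@strains, function(sg) {
    contigs <- reverseComplement(sg@contigs)
    g <- as.data.frame(sg@genes[, c("gene_id", "contig_id", "start", "end",
                                    "strand")])
    clen <- width(contigs)[match(g$contig_id, names(contigs))]
    new_start <- clen - g$end
    new_end <- clen - g$start
    g$start <- new_start
    g$end <- new_end
    g$strand <- ifelse(g$strand == "+", "-", "+")
    StrainGenome(sg@strainId, contigs, g)
  })
  GenomeSet(strains, phenotypeLabels(gset))
}
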