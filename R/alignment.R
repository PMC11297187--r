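#' @importFrom Biostrings pairwiseAlignment nucleotideSubstitutionMatrix
#'   nmatch pattern subject score AAStringSet
NULL

.nt_submat <- local({
  m <- NULL
  function() {
    if (is.null(m))
      m <<- nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                         baseOnly = FALSE)
    m
  }
})

.blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

# Alignment parameters used throughout: nucleotide match 1 / mismatch -1,
# gap open 2 / extend 1; protein BLOSUM62, gap open 11 / extend 1.
.aln_args <- function(type) {
  if (type == "dna")
    list(substitutionMatrix = .nt_submat(), gapOpening = 2, gapExtension = 1)
  else
    list(substitutionMatrix = .blosum62(), gapOpening = 11, gapExtension = 1)
}

# Identity of many sequences against one subject under end-gap-free
# (overlap) global alignment: matches / alignment columns, where the
# columns span the FULL extent of both sequences - unaligned terminal
# stretches count as gap columns. This keeps a short spurious overlap
# between unrelated sequences from scoring as high identity.
.identity_to <- function(seqs, subject, type = c("dna", "protein")) {
  type <- match.arg(type)
  if (!length(seqs)) return(numeric(0))
  pat <- if (type == "dna") DNAStringSet(seqs) else AAStringSet(seqs)
  a <- .aln_args(type)
  aln <- pairwiseAlignment(pat, subject, type = "overlap",
                           substitutionMatrix = a$substitutionMatrix,
                           gapOpening = a$gapOpening,
                           gapExtension = a$gapExtension)
  region <- nchar(as.character(pattern(aln)))
  np <- nchar(seqs)
  ns <- nchar(as.character(subject))
  pflank <- (Biostrings::start(pattern(aln)) - 1L) +
    (np - Biostrings::end(pattern(aln)))
  sflank <- (Biostrings::start(subject(aln)) - 1L) +
    (ns - Biostrings::end(subject(aln)))
  cols <- region + pflank + sflank
  ifelse(cols > 0, nmatch(aln) / cols, 0)
}

#' Pairwise protein alignment with identity and similarity
#'
#' Aligns two protein sequences under BLOSUM62 with gap open 11 / extend 1,
#' either over their full lengths (`global`, Needleman-Wunsch, end gaps
#' penalized) or locally (`local`, Smith-Waterman). Identity is the
#' percentage of identical columns and similarity the percentage of columns
#' with a positive substitution score; both use the full set of alignment
#' columns as denominator, gap columns (including terminal gap columns in
#' global mode) counting as neither identical nor positive. In local mode
#' the metrics describe the best-scoring segment only; see
#' [bestHitScreen()] for full-extent screening metrics.
#'
#' @param a,b protein sequences (non-empty, standard amino-acid alphabet;
#'   `B`, `Z`, `X` and `*` are tolerated as BLOSUM62 defines them).
#' @param mode `"global"` or `"local"`.
#' @return list with elements `columns`, `identity` (%), `similarity` (%),
#'   `score`.
#' @examples
#' alignPair("MKV", "MRV")$similarity  # 100: K<->R scores +2
#' @export
alignPair <- function(a, b, mode = c("global", "local")) {
  mode <- match.arg(mode)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  ok <- rownames(.blosum62())
  resid <- unique(strsplit(paste0(a, b), "")[[1]])
  bad <- setdiff(resid, ok)
  if (length(bad)) stop("invalid residue(s): ", paste(bad, collapse = ", "))
  aln <- pairwiseAlignment(a, b, type = mode,
                           substitutionMatrix = .blosum62(),
                           gapOpening = 11, gapExtension = 1)
  pa <- strsplit(as.character(pattern(aln)), "")[[1]]
  pb <- strsplit(as.character(subject(aln)), "")[[1]]
  stopifnot(length(pa) == length(pb))
  # Biostrings clips the aligned strings to the aligned ranges; terminal
  # gap stretches (global) / unaligned termini (local) are added back as
  # gap columns so the denominator spans both sequences in full.
  flank <- (Biostrings::start(pattern(aln)) - 1L) +
    (nchar(a) - Biostrings::end(pattern(aln))) +
    (Biostrings::start(subject(aln)) - 1L) +
    (nchar(b) - Biostrings::end(subject(aln)))
  cols <- length(pa) + if (mode == "global") flank else 0L
  nongap <- pa != "-" & pb != "-"
  ident <- sum(pa[nongap] == pb[nongap])
  pos <- sum(.blosum62()[cbind(pa[nongap], pb[nongap])] > 0)
  list(columns = cols,
       identity = 100 * ident / cols,
       similarity = 100 * pos / cols,
       score = score(aln))
}

# Screen metrics for one query-target pair: Smith-Waterman finds the
# best-scoring segment, but identity and similarity are taken over the
# full extent of both sequences (unaligned residues count as gap
# columns). A short spurious segment between unrelated proteins thus
# yields a low similarity, while near-full-length homologs are barely
# affected.
.screen_metrics <- function(query, target) {
  aln <- pairwiseAlignment(query, target, type = "local",
                           substitutionMatrix = .blosum62(),
                           gapOpening = 11, gapExtension = 1)
  pa <- strsplit(as.character(pattern(aln)), "")[[1]]
  pb <- strsplit(as.character(subject(aln)), "")[[1]]
  nongap <- pa != "-" & pb != "-"
  ident <- sum(pa[nongap] == pb[nongap])
  pos <- sum(.blosum62()[cbind(pa[nongap], pb[nongap])] > 0)
  qflank <- nchar(query) - (Biostrings::end(pattern(aln)) -
                            Biostrings::start(pattern(aln)) + 1L)
  tflank <- nchar(target) - (Biostrings::end(subject(aln)) -
                             Biostrings::start(subject(aln)) + 1L)
  cols <- length(pa) + qflank + tflank
  list(identity = 100 * ident / cols, similarity = 100 * pos / cols,
       score = score(aln))
}

#' Best-hit protein homology screen across proteomes
#'
#' For each target strain, locally aligns the query against every protein
#' and keeps the hit with the highest similarity (ties broken by higher
#' alignment score, then lexicographic gene id). Identity and similarity
#' are expressed over the full extent of both sequences - unaligned
#' terminal residues count as gap columns - so a short chance segment
#' between unrelated proteins scores low while a full-length homolog is
#' essentially unaffected. Hits are categorized as `high` (similarity >=
#' `thresholds[1]`, default 60), `low_or_absent` (similarity <
#' `thresholds[2]`, default 25, or empty proteome) and `intermediate` in
#' between.
#'
#' @param query protein sequence.
#' @param proteomes named list: strain id -> named character vector of
#'   protein sequences (names = gene ids).
#' @param thresholds numeric length 2: the high and low similarity
#'   percentage boundaries.
#' @return [S4Vectors::DataFrame] with columns `strain_id`, `best_gene`,
#'   `identity`, `similarity`, `category`.
#' @export
bestHitScreen <- function(query, proteomes, thresholds = c(60, 25)) {
  if (!length(proteomes)) stop("empty proteomes")
  rows <- lapply(names(proteomes), function(sid) {
    prot <- proteomes[[sid]]
    if (!length(prot))
      return(data.frame(strain_id = sid, best_gene = NA_character_,
                        identity = NA_real_, similarity = NA_real_,
                        category = "low_or_absent"))
    res <- lapply(prot, function(p) .screen_metrics(query, p))
    sim <- vapply(res, `[[`, numeric(1), "similarity")
    sc <- vapply(res, `[[`, numeric(1), "score")
    ord <- order(-sim, -sc, names(prot))
    best <- ord[1]
    cat <- if (sim[best] >= thresholds[1]) "high"
           else if (sim[best] < thresholds[2]) "low_or_absent"
           else "intermediate"
    data.frame(strain_id = sid, best_gene = names(prot)[best],
               identity = res[[best]]$identity, similarity = sim[best],
               category = cat)
  })
  DataFrame(do.call(rbind, rows))
}
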