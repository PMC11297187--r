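#' Parameters for calling phenotype-specific gene families
#'
#' A family is called "unique and specific" to the positive phenotype when
#' the fraction of negative strains carrying it is at most
#' `specific_max_neg_fraction` (default 0: absent from all negatives) and
#' the fraction of positive strains carrying it is at least
#' `unique_min_pos_fraction` (default 1: present in all positives).
#'
#' @param specific_max_neg_fraction maximum carrier fraction among
#'   negatives (default 0).
#' @param unique_min_pos_fraction minimum carrier fraction among positives
#'   (default 1).
#' @param alpha BH significance level used in reporting (default 0.05).
#' @param alternative sidedness of the per-family Fisher test.
#' @return validated parameter list of class `FamilyCallParams`.
#' @export
familyCallParams <- function(specific_max_neg_fraction = 0,
                             unique_min_pos_fraction = 1,
                             alpha = 0.05,
                             alternative = c("two.sided", "greater")) {
  stopifnot(specific_max_neg_fraction >= 0, specific_max_neg_fraction <= 1,
            unique_min_pos_fraction >= 0, unique_min_pos_fraction <= 1)
  structure(list(specific_max_neg_fraction = specific_max_neg_fraction,
                 unique_min_pos_fraction = unique_min_pos_fraction,
                 alpha = alpha, alternative = match.arg(alternative)),
            class = c("FamilyCallParams", "list"))
}

#' Read an orthogroup table
#'
#' Reads the tab-separated orthogroup dialect: first column the orthogroup
#' id, one column per strain, cells holding comma-separated gene ids
#' (empty cell = copy number 0).
#'
#' @param path path to the TSV.
#' @param gset optional [GenomeSet] to validate gene ids against.
#' @return a [GeneFamilySet].
#' @export
readOrthogroupTable <- function(path, gset = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  strain_cols <- colnames(tab)[-1]
  if (!is.null(gset)) {
    bad <- setdiff(strain_cols, strainIds(gset))
    if (length(bad))
      stop("unknown strain column(s): ", paste(bad, collapse = ", "))
  }
  fams <- lapply(seq_len(nrow(tab)), function(i) {
    mem <- lapply(strain_cols, function(sc) {
      cell <- tab[i, sc]
      if (is.na(cell) || !nzchar(trimws(cell))) return(character(0))
      trimws(strsplit(cell, ",")[[1]])
    })
    names(mem) <- strain_cols
    mem[lengths(mem) > 0]
  })
  names(fams) <- tab[[1]]
  all_genes <- unlist(fams, use.names = FALSE)
  dup <- unique(all_genes[duplicated(all_genes)])
  if (length(dup))
    stop("gene id(s) assigned to more than one family: ",
         paste(utils::head(dup, 5), collapse = ", "))
  if (!is.null(gset)) {
    for (sid in strain_cols) {
      known <- gset@strains[[sid]]@genes$gene_id
      for (f in fams) {
        bad <- setdiff(f[[sid]] %||% character(0), known)
        if (length(bad))
          stop("family member gene(s) not in strain ", sid, ": ",
               paste(bad, collapse = ", "))
      }
    }
  }
  new("GeneFamilySet", families = fams, strainIds = strain_cols)
}

#' Greedy de-novo gene families from protein sequences
#'
#' A self-contained protein clustering that groups every translated gene
#' of every strain into families by greedy centroid clustering
#' ([greedyClusterGenes()] on amino-acid sequences), so the family
#' association stage can run without an external orthology tool. An
#' externally computed orthogroup table ([readOrthogroupTable()]) is a
#' drop-in replacement.
#'
#' @param gset a [GenomeSet]; every gene needs a translation (`aa_seq`).
#' @param protein_identity greedy identity threshold (default 0.5).
#' @param prescreen_k,prescreen_min word-sharing prescreen forwarded to
#'   [greedyClusterGenes()] (defaults 4 and 0.02).
#' @return a [GeneFamilySet] with families `FAM00001`, ... ordered by
#'   decreasing size.
#' @export
buildFamiliesDenovo <- function(gset, protein_identity = 0.5,
                                prescreen_k = 4L, prescreen_min = 0.02) {
  sids <- strainIds(gset)
  seqs <- character(0)
  strain_of <- character(0)
  gene_of <- character(0)
  for (sid in sids) {
    g <- gset@strains[[sid]]@genes
    if (anyNA(g$aa_seq))
      stop("strain ", sid, " has genes without translations")
    key <- paste0(sid, "::", g$gene_id)
    seqs[key] <- g$aa_seq
    strain_of[key] <- sid
    gene_of[key] <- g$gene_id
  }
  cl <- greedyClusterGenes(seqs, protein_identity, type = "protein",
                           prescreen_k = prescreen_k,
                           prescreen_min = prescreen_min)
  cl <- cl[order(-vapply(cl, function(x) length(x$members), integer(1)))]
  fams <- lapply(cl, function(x)
    split(unname(gene_of[x$members]), strain_of[x$members]))
  names(fams) <- sprintf("FAM%05d", seq_along(fams))
  new("GeneFamilySet", families = fams, strainIds = sids)
}

#' Phenotype-specific gene families with association statistics
#'
#' Computes, for every family, the carrier pattern (copy number >= 1 per
#' strain), the "unique and specific" call under the fraction thresholds
#' of [familyCallParams()], and a [presenceFisher()] association with BH
#' correction across families.
#'
#' @param families a [GeneFamilySet].
#' @param gset a [GenomeSet] with both phenotype classes.
#' @param params a [familyCallParams()] list.
#' @return list with `assoc` (DataFrame: `unit_id`, 2x2 counts,
#'   `odds_ratio`, `p`, `p_adj`, `pos_fraction`, `neg_fraction`,
#'   `called`), and `called` (ids of families passing the call rule).
#' @export
uniqueSpecificFamilies <- function(families, gset,
                                   params = familyCallParams()) {
  ph <- phenotypeLabels(gset)
  n_pos <- sum(ph == "positive")
  n_neg <- sum(ph == "negative")
  if (n_pos == 0 || n_neg == 0)
    stop("association needs both phenotype classes")
  res <- lapply(names(families@families), function(fid) {
    carriers <- names(families@families[[fid]])
    presenceFisher(carriers, gset, alternative = params$alternative,
                   unit_id = fid)
  })
  assoc <- .assoc_table(res)
  assoc$pos_fraction <- assoc$a / n_pos
  assoc$neg_fraction <- assoc$c / n_neg
  assoc$called <- assoc$pos_fraction >= params$unique_min_pos_fraction &
    assoc$neg_fraction <= params$specific_max_neg_fraction
  list(assoc = assoc, called = assoc$unit_id[assoc$called])
}
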