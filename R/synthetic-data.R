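#' @importFrom stats rbinom rgamma rlnorm rnbinom rpois runif rnorm median var
NULL

#' Simulation parameters for the synthetic genome panel
#'
#' Defaults reproduce the study design the pipeline targets: 16
#' phenotype-positive and 23 phenotype-negative strains, 300 background
#' genes per genome (80% core), 2% per-site divergence between strains,
#' and a contiguous 15-gene cluster planted only in positives.
#'
#' @param n_pos,n_neg number of positive / negative strains (defaults 16
#'   and 23).
#' @param genes_per_genome background genes per genome (default 300).
#' @param gene_len_mean mean gene length in nt (default 900; lengths are
#'   multiples of 3).
#' @param core_fraction fraction of background genes present in every
#'   strain (default 0.8); the rest are accessory decoys drawn per strain
#'   from a shared pool.
#' @param per_site_divergence substitution probability per site between a
#'   strain's gene copy and the ancestral sequence (default 0.02).
#' @param cluster_size planted cluster size (default 15).
#' @param cluster_noise_drop probability a positive strain lacks the
#'   cluster (default 0).
#' @param cluster_noise_gain probability a negative strain carries it
#'   (default 0).
#' @param seed RNG seed (default 42).
#' @return validated S4 `SimParams` object.
#' @export
SimParams <- function(n_pos = 16L, n_neg = 23L, genes_per_genome = 300L,
                      gene_len_mean = 900L, core_fraction = 0.8,
                      per_site_divergence = 0.02, cluster_size = 15L,
                      cluster_noise_drop = 0, cluster_noise_gain = 0,
                      seed = 42L) {
  new("SimParams", nPos = as.integer(n_pos), nNeg = as.integer(n_neg),
      genesPerGenome = as.integer(genes_per_genome),
      geneLenMean = as.integer(gene_len_mean),
      coreFraction = core_fraction,
      perSiteDivergence = per_site_divergence,
      clusterSize = as.integer(cluster_size),
      clusterNoiseDrop = cluster_noise_drop,
      clusterNoiseGain = cluster_noise_gain, seed = as.integer(seed))
}

#' @rdname SimParams
#' @slot nPos,nNeg,genesPerGenome,geneLenMean,coreFraction,perSiteDivergence,clusterSize,clusterNoiseDrop,clusterNoiseGain,seed see the constructor arguments.
#' @export
setClass("SimParams",
  representation(nPos = "integer", nNeg = "integer",
                 genesPerGenome = "integer", geneLenMean = "integer",
                 coreFraction = "numeric", perSiteDivergence = "numeric",
                 clusterSize = "integer", clusterNoiseDrop = "numeric",
                 clusterNoiseGain = "numeric", seed = "integer"))

setValidity("SimParams", function(object) {
  pr <- c(object@coreFraction, object@perSiteDivergence,
          object@clusterNoiseDrop, object@clusterNoiseGain)
  if (any(pr < 0 | pr > 1)) return("probabilities must lie in [0, 1]")
  if (object@clusterSize < 1) return("cluster_size must be >= 1")
  if (object@nPos < 1 || object@nNeg < 1) return("need >= 1 strain per class")
  if (object@clusterSize > object@genesPerGenome)
    return("cluster_size exceeds genes_per_genome")
  TRUE
})

.CODONS_NONSTOP <- {
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

# Random in-frame CDS: ATG + non-stop codons + TAA. len_nt multiple of 3.
.random_cds <- function(len_nt) {
  n_codons <- len_nt / 3L - 2L
  paste0("ATG",
         paste(sample(.CODONS_NONSTOP, n_codons, replace = TRUE),
               collapse = ""), "TAA")
}

# Substitution-only mutation at per-site rate d (no indels, so gene
# lengths are stable and identity ~ 1 - d).
.mutate_seq <- function(seq, d) {
  if (d <= 0) return(seq)
  L <- nchar(seq)
  n_mut <- rbinom(1, L, d)
  if (n_mut == 0) return(seq)
  pos <- sample.int(L, n_mut)
  chars <- strsplit(seq, "")[[1]]
  for (p in pos)
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  paste(chars, collapse = "")
}

.random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Simulate a phenotyped genome panel with a planted gene cluster
#'
#' Generates ancestral gene sequences (core families present in every
#' strain, accessory decoy families shared by random strain subsets, and
#' a separate set of cluster families), mutates each strain's copies
#' independently at the per-site divergence rate, shuffles background
#' gene order per strain, and inserts the cluster genes as one contiguous
#' block at a random inter-gene position in every carrier (positives,
#' modulo the noise probabilities). Genes are laid on a single contig per
#' strain, separated by 50-200 nt random spacers, with random strands.
#' Output is bit-for-bit reproducible for a given seed.
#'
#' @param params a [SimParams()] object.
#' @return list with `genomes` (a [GenomeSet]) and `truth`
#'   (a [GroundTruth]).
#' @export
simulateGenomeSet <- function(params = SimParams()) {
  validObject(params)
  set.seed(params@seed)
  n_core <- round(params@coreFraction * params@genesPerGenome)
  n_acc <- params@genesPerGenome - n_core
  pool_size <- max(3L * n_acc, n_acc)
  len_of <- function(n) 3L * pmax(60L, round(rgamma(n, shape = 9,
                                scale = params@geneLenMean / 27)))
  fam_core <- sprintf("core%04d", seq_len(n_core))
  fam_acc <- if (n_acc > 0) sprintf("acc%04d", seq_len(pool_size)) else character(0)
  fam_clu <- sprintf("clu%02d", seq_len(params@clusterSize))
  anc <- c(
    stats::setNames(vapply(len_of(n_core), .random_cds, character(1)), fam_core),
    stats::setNames(vapply(len_of(length(fam_acc)), .random_cds, character(1)),
                    fam_acc),
    stats::setNames(vapply(len_of(params@clusterSize), .random_cds,
                           character(1)), fam_clu))
  sids <- sprintf("S%02d", seq_len(params@nPos + params@nNeg))
  phen <- stats::setNames(
    sample(c(rep("positive", params@nPos), rep("negative", params@nNeg))),
    sids)
  carrier <- ifelse(phen == "positive",
                    runif(length(sids)) >= params@clusterNoiseDrop,
                    runif(length(sids)) < params@clusterNoiseGain)
  strains <- list()
  planted <- list()
  cpos <- data.frame(strain_id = character(0), contig_id = character(0),
                     first_index = integer(0), last_index = integer(0))
  for (sid in sids) {
    bg <- c(fam_core,
            if (n_acc > 0) sample(fam_acc, n_acc) else character(0))
    bg <- sample(bg)  # per-strain gene order
    fams <- bg
    first_idx <- NA_integer_
    if (carrier[[sid]]) {
      at <- sample.int(length(bg) + 1L, 1L) - 1L  # insert after position `at`
      fams <- append(bg, fam_clu, after = at)
      first_idx <- at + 1L
    }
    seqs <- vapply(anc[fams], .mutate_seq, character(1),
                   d = params@perSiteDivergence)
    strands <- sample(c("+", "-"), length(fams), replace = TRUE)
    spacers <- vapply(sample(50:200, length(fams) + 1L, replace = TRUE),
                      .random_dna, character(1))
    parts <- character(2L * length(fams) + 1L)
    starts <- integer(length(fams))
    ends <- integer(length(fams))
    pos <- 0L
    for (i in seq_along(fams)) {
      parts[2L * i - 1L] <- spacers[i]
      pos <- pos + nchar(spacers[i])
      starts[i] <- pos
      s <- seqs[[i]]
      if (strands[i] == "-") s <- reverseComplement(s)
      parts[2L * i] <- s
      pos <- pos + nchar(s)
      ends[i] <- pos
    }
    parts[2L * length(fams) + 1L] <- spacers[length(fams) + 1L]
    contig <- paste(parts, collapse = "")
    gene_ids <- sprintf("%s_g%04d", sid, seq_along(fams))
    sg <- StrainGenome(sid,
                       stats::setNames(DNAStringSet(contig), "c1"),
                       data.frame(gene_id = gene_ids, contig_id = "c1",
                                  start = starts, end = ends,
                                  strand = strands))
    sg@genes$family <- fams
    strains[[sid]] <- sg
    if (carrier[[sid]]) {
      planted[[sid]] <- gene_ids[first_idx:(first_idx + params@clusterSize - 1L)]
      cpos <- rbind(cpos, data.frame(
        strain_id = sid, contig_id = "c1", first_index = first_idx,
        last_index = first_idx + params@clusterSize - 1L))
    }
  }
  gset <- GenomeSet(strains, phen)
  ref <- names(planted)[1] %||% NA_character_
  truth <- new("GroundTruth", plantedGeneIds = planted,
               clusterPosition = DataFrame(cpos),
               deGeneIds = if (!is.na(ref)) planted[[ref]] else character(0),
               phenotype = phen, clusterFamilies = fam_clu)
  list(genomes = gset, truth = truth)
}

#' Default reference strain of a simulated panel
#'
#' The first cluster carrier, i.e. the strain whose genes are marked as
#' differentially expressed in [simulateCountMatrix()].
#'
#' @param truth a [GroundTruth].
#' @return strain id.
#' @export
referenceStrain <- function(truth) {
  if (!length(truth@plantedGeneIds)) stop("no carrier strain in truth")
  names(truth@plantedGeneIds)[1]
}

#' Simulate an RNA-seq style count matrix for the reference strain
#'
#' Counts are negative-binomial around log-normal baseline means (shared
#' across samples per gene); under the treatment condition the means of
#' the planted cluster genes are multiplied by `2^lfc_cluster`. With
#' `dispersion = 0` the Poisson limit is used.
#'
#' @param gset a [GenomeSet] from [simulateGenomeSet()].
#' @param truth the matching [GroundTruth]; the reference strain must be
#'   a cluster carrier.
#' @param n_reps_per_condition replicates per condition (>= 2, default 4).
#' @param lfc_cluster planted log2 fold change (default 3).
#' @param dispersion NB dispersion (default 0.05).
#' @param seed RNG seed (default 1).
#' @param reference reference strain id (default: first carrier).
#' @return a [SummarizedExperiment::SummarizedExperiment] (assay
#'   `counts`, colData `condition` in control/MBOA and `replicate`).
#' @export
simulateCountMatrix <- function(gset, truth, n_reps_per_condition = 4L,
                                lfc_cluster = 3, dispersion = 0.05,
                                seed = 1L, reference = referenceStrain(truth)) {
  if (n_reps_per_condition < 2) stop("need >= 2 replicates per condition")
  if (!reference %in% names(truth@plantedGeneIds))
    stop("reference strain must be a cluster carrier")
  set.seed(seed)
  g <- gset@strains[[reference]]@genes
  n_genes <- nrow(g)
  n <- 2L * n_reps_per_condition
  base_mu <- rlnorm(n_genes, meanlog = log(200), sdlog = 1)
  mu <- matrix(base_mu, n_genes, n)
  trt <- seq_len(n) > n_reps_per_condition
  de <- g$gene_id %in% truth@deGeneIds
  mu[de, trt] <- mu[de, trt] * 2^lfc_cluster
  counts <- if (dispersion > 0)
    matrix(rnbinom(n_genes * n, mu = mu, size = 1 / dispersion), n_genes, n)
  else matrix(rpois(n_genes * n, lambda = mu), n_genes, n)
  rownames(counts) <- g$gene_id
  colnames(counts) <- paste0(ifelse(trt, "MBOA", "control"), "_",
                             rep(seq_len(n_reps_per_condition), 2))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(
      condition = ifelse(trt, "MBOA", "control"),
      replicate = rep(seq_len(n_reps_per_condition), 2),
      row.names = colnames(counts)))
}

#' Simulate metabolite and growth-curve phenotyping assays
#'
#' Emits a long-format metabolite table (MBOA remaining and AMPO formed
#' per strain plus one no-bacteria control row per compound) in which
#' positive strains satisfy the "strong" classification cut-offs (> 90%
#' MBOA degraded, AMPO > 10% of the assay maximum) and negative strains
#' the "non" cut-offs, plus logistic growth curves (OD600 every 2 h for
#' 48 h, 4 replicates) on MBOA versus a DMSO control in which only
#' positive strains gain capacity from MBOA as carbon source.
#'
#' @param gset a [GenomeSet].
#' @param truth the matching [GroundTruth] (supplies the labels).
#' @param seed RNG seed (default 1).
#' @return list with `metabolites` (data.frame `strain_id`, `compound`,
#'   `concentration`, `is_control`) and `growth` (data.frame `strain_id`,
#'   `treatment`, `replicate`, `time_h`, `od600`).
#' @export
simulatePhenotypeAssays <- function(gset, truth, seed = 1L) {
  set.seed(seed)
  ph <- truth@phenotype
  sids <- names(ph)
  pos <- ph == "positive"
  ctrl_mboa <- 500
  mboa <- ifelse(pos, runif(length(sids), 0.005, 0.08),
                      runif(length(sids), 0.85, 1.0)) * ctrl_mboa
  ampo_scale <- 100
  ampo <- ifelse(pos, runif(length(sids), 0.2, 1.0) * ampo_scale, 0)
  metabolites <- rbind(
    data.frame(strain_id = "NBC", compound = c("MBOA", "AMPO"),
               concentration = c(ctrl_mboa, 0), is_control = TRUE),
    data.frame(strain_id = rep(sids, 2),
               compound = rep(c("MBOA", "AMPO"), each = length(sids)),
               concentration = c(mboa, ampo), is_control = FALSE))
  times <- seq(0, 48, by = 2)
  reps <- 1:4
  grid <- expand.grid(strain_id = sids, treatment = c("DMSO", "MBOA"),
                      replicate = reps, stringsAsFactors = FALSE)
  growth <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    sid <- grid$strain_id[i]
    K <- if (grid$treatment[i] == "MBOA" && ph[[sid]] == "positive") 0.9
         else 0.3
    od <- K / (1 + exp(-0.25 * (times - 12))) +
      pmax(rnorm(length(times), 0, 0.005), -0.01) + 0.02
    data.frame(strain_id = sid, treatment = grid$treatment[i],
               replicate = grid$replicate[i], time_h = times, od600 = od)
  }))
  list(metabolites = metabolites, growth = growth)
}

#' Write ground truth as JSON
#'
#' @param truth a [GroundTruth].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(list(
    planted_gene_ids = truth@plantedGeneIds,
    cluster_position = as.data.frame(truth@clusterPosition),
    de_gene_ids = truth@deGeneIds,
    phenotype = as.list(truth@phenotype),
    cluster_families = truth@clusterFamilies), path, auto_unbox = TRUE)
  invisible(path)
}
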